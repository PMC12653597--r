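# Cohort loading, marker-panel construction and the missingness filter.
#
# A cohort is the unit all splitting operates on: patients with one or more
# time-aligned (radiograph, blood panel) sample pairs, labelled SS (0) or
# PMF (1).

# Fixed candidate panel: 2 global counts, 5 absolute leukocyte-subset counts,
# 5 subset percentages, 6 derived inflammation indices, 3 serum enzymes.
.markers_raw <- c(
  "leukocytes", "platelets",
  "neutrophils_abs", "eosinophils_abs", "basophils_abs",
  "monocytes_abs", "lymphocytes_abs",
  "neutrophils_pct", "eosinophils_pct", "basophils_pct",
  "monocytes_pct", "lymphocytes_pct"
)
.markers_ratio <- c("NLR", "PLR", "LMR", "SII", "SIRI", "AISI")
.markers_enzyme <- c("ALP", "LDH", "ACE")

#' Candidate biomarker panel names
#'
#' The fixed, ordered 21-marker candidate panel: leukocyte and platelet
#' counts, absolute counts and percentages of the five leukocyte subsets,
#' the six derived systemic-inflammation indices, and the three serum
#' enzymes (ALP, LDH, ACE). Panel ordering is identical for every sample of
#' a cohort and is what makes downstream feature concatenation
#' deterministic.
#'
#' @return Character vector of length 21.
#' @export
marker_panel_names <- function() {
  c(.markers_raw, .markers_ratio, .markers_enzyme)
}

# Division that propagates missingness and never yields Inf: NA when any
# ingredient is NA or the denominator is zero.
.safe_ratio <- function(num, den) {
  out <- ifelse(is.na(num) | is.na(den) | den == 0, NA_real_, num / den)
  as.numeric(out)
}

#' Derived systemic-inflammation indices
#'
#' Computes the six composite white-blood-cell indices from absolute counts
#' (units 10^9 cells/L; platelets 10^9/L):
#' NLR = neutrophils/lymphocytes, PLR = platelets/lymphocytes,
#' LMR = lymphocytes/monocytes, SII = neutrophils x platelets / lymphocytes,
#' SIRI = neutrophils x monocytes / lymphocytes, and
#' AISI = neutrophils x monocytes x platelets / lymphocytes.
#'
#' Ratios are computed from absolute counts, never from percentages. An
#' index is missing (`NA`) whenever an ingredient is missing or its
#' denominator is zero; it is never infinite.
#'
#' @param counts Data frame (or named list) with columns
#'   `neutrophils_abs`, `lymphocytes_abs`, `monocytes_abs`, `platelets`.
#'   Vectorized over rows.
#' @return Data frame with columns `NLR`, `PLR`, `LMR`, `SII`, `SIRI`,
#'   `AISI`.
#' @export
compute_inflammation_indices <- function(counts) {
  counts <- as.data.frame(counts)
  need <- c("neutrophils_abs", "lymphocytes_abs", "monocytes_abs", "platelets")
  miss <- setdiff(need, names(counts))
  if (length(miss) > 0) {
    stop("compute_inflammation_indices: missing count columns: ",
         paste(miss, collapse = ", "))
  }
  neg <- vapply(need, function(v) any(counts[[v]] < 0, na.rm = TRUE), logical(1))
  if (any(neg)) {
    stop("compute_inflammation_indices: negative counts in: ",
         paste(need[neg], collapse = ", "))
  }
  n <- counts$neutrophils_abs
  l <- counts$lymphocytes_abs
  m <- counts$monocytes_abs
  p <- counts$platelets
  data.frame(
    NLR = .safe_ratio(n, l),
    PLR = .safe_ratio(p, l),
    LMR = .safe_ratio(l, m),
    SII = .safe_ratio(n * p, l),
    SIRI = .safe_ratio(n * m, l),
    AISI = .safe_ratio(n * m * p, l)
  )
}

# Internal constructor shared by load_cohort() and the synthetic generator.
# samples: data.frame(sample_id, patient_id, sample_index, label,
#          image_path, image_absent); raw: data.frame of the 15 raw marker
#          columns aligned to samples.
.assemble_cohort <- function(samples, raw, features = NULL) {
  stopifnot(nrow(samples) == nrow(raw))
  if (any(!samples$label %in% c(0L, 1L))) {
    stop("labels must be 0 (SS) or 1 (PMF)")
  }
  if (any(is.na(samples$patient_id) | samples$patient_id == "")) {
    stop("every sample needs a non-empty patient_id")
  }
  key <- paste(samples$patient_id, samples$sample_index, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (patient_id, sample_index) pair: ",
         samples$patient_id[which(duplicated(key))[1]])
  }
  markers <- matrix(NA_real_, nrow(samples), 21,
                    dimnames = list(NULL, marker_panel_names()))
  for (v in c(.markers_raw, .markers_enzyme)) {
    markers[, v] <- as.numeric(raw[[v]])
  }
  pct <- markers[, .markers_raw[grepl("_pct$", .markers_raw)], drop = FALSE]
  if (any(pct < 0 | pct > 100, na.rm = TRUE)) {
    stop("percentage markers must lie in [0, 100]")
  }
  if (any(markers < 0, na.rm = TRUE)) stop("marker values must be >= 0")
  cohort <- structure(
    list(samples = samples, markers = markers,
         marker_names = marker_panel_names(), features = features),
    class = "silica_cohort"
  )
  build_marker_panel(cohort)
}

#' Load a paired image/biomarker cohort from a manifest
#'
#' Reads a delimited manifest (comma default, tab accepted; header row
#' required) with one row per sample and columns `patient_id`, `label`
#' (`SS`/`PMF` or `0`/`1`), `image` (path relative to `image_root`; may be
#' empty), and the 15 raw measurement columns named as in
#' [marker_panel_names()] (the 6 index columns, if present, are ignored and
#' recomputed from the counts). Empty cells are recorded as missing, never
#' as zero.
#'
#' @param manifest_path Path to the manifest file.
#' @param image_root Directory that image paths are relative to. `NULL`
#'   means paths are used as written.
#' @param sep Field separator; `NULL` sniffs `\t` vs `,` from the header.
#' @return A `silica_cohort`: sample table, 21-column marker matrix with
#'   derived indices filled in, and fixed marker ordering. Unresolvable
#'   image paths raise a warning and are flagged absent so biomarker-only
#'   analyses can still run.
#' @export
load_cohort <- function(manifest_path, image_root = NULL, sep = NULL) {
  if (!file.exists(manifest_path)) stop("manifest not found: ", manifest_path)
  if (is.null(sep)) {
    hdr <- readLines(manifest_path, n = 1L)
    sep <- if (grepl("\t", hdr)) "\t" else ","
  }
  df <- utils::read.table(manifest_path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("", "NA"))
  need <- c("patient_id", "label", "image", .markers_raw, .markers_enzyme)
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("manifest is missing required columns: ", paste(miss, collapse = ", "))
  }
  lab_chr <- toupper(trimws(as.character(df$label)))
  map <- c(SS = 0L, PMF = 1L, "0" = 0L, "1" = 1L)
  label <- unname(map[lab_chr])
  if (any(is.na(label))) {
    bad <- which(is.na(label))[1]
    stop("unknown stage label ", shQuote(df$label[bad]), " at manifest row ",
         bad, " (expected SS or PMF)")
  }
  pid <- as.character(df$patient_id)
  sample_index <- if ("sample_index" %in% names(df)) {
    as.integer(df$sample_index)
  } else {
    stats::ave(seq_along(pid), pid, FUN = seq_along)
  }
  image_rel <- as.character(df$image)
  image_path <- ifelse(is.na(image_rel) | image_rel == "", NA_character_,
                       if (is.null(image_root)) image_rel
                       else file.path(image_root, image_rel))
  absent <- is.na(image_path)
  unresolved <- !absent & !file.exists(image_path)
  if (any(unresolved)) {
    warning(sum(unresolved), " image path(s) could not be resolved; ",
            "flagged absent (first: ", image_path[which(unresolved)[1]], ")")
    absent <- absent | unresolved
  }
  if (any(grepl("\\.dcm$", image_path[!absent], ignore.case = TRUE))) {
    stop("DICOM input is not supported; convert to 8-bit grayscale PNG/TIFF")
  }
  samples <- data.frame(
    sample_id = if ("sample_id" %in% names(df)) as.character(df$sample_id)
                else sprintf("%s_s%02d", pid, sample_index),
    patient_id = pid,
    sample_index = sample_index,
    label = label,
    image_path = image_path,
    image_absent = absent,
    stringsAsFactors = FALSE
  )
  .assemble_cohort(samples, df)
}

#' Fill the derived inflammation indices of every sample's panel
#'
#' Recomputes the NLR, PLR, LMR, SII, SIRI and AISI columns of the marker
#' matrix from the absolute counts via [compute_inflammation_indices()].
#' Missingness in any ingredient propagates into the derived index.
#'
#' @param cohort A `silica_cohort`.
#' @return The cohort with index columns populated.
#' @export
build_marker_panel <- function(cohort) {
  stopifnot(inherits(cohort, "silica_cohort"))
  idx <- compute_inflammation_indices(as.data.frame(cohort$markers))
  for (v in .markers_ratio) cohort$markers[, v] <- idx[[v]]
  cohort
}

#' Drop markers with excessive cohort-wide missingness
#'
#' Any marker whose fraction of missing values across the whole cohort is
#' greater than or equal to `threshold` (inclusive boundary) is removed
#' from every sample's panel; the ordering of the survivors is preserved.
#' On the study-shaped cohort this is the step that reduces the 21-marker
#' candidate panel to the 18 analysed biomarkers by excluding ALP, LDH and
#' ACE.
#'
#' @param cohort A `silica_cohort` with panels built.
#' @param threshold Missing-fraction cutoff in (0, 1]; default 0.20.
#' @return List with elements `cohort` (filtered) and `removed` (character
#'   vector of dropped marker names). Removing every marker is an error.
#' @export
filter_markers_by_missingness <- function(cohort, threshold = 0.20) {
  stopifnot(inherits(cohort, "silica_cohort"))
  if (!(threshold > 0 && threshold <= 1)) stop("threshold must be in (0, 1]")
  frac <- colMeans(is.na(cohort$markers))
  drop <- frac >= threshold
  if (all(drop)) stop("all markers exceed the missingness threshold; ",
                      "no biomarker modality left")
  removed <- colnames(cohort$markers)[drop]
  cohort$markers <- cohort$markers[, !drop, drop = FALSE]
  cohort$marker_names <- colnames(cohort$markers)
  list(cohort = cohort, removed = removed)
}

#' @export
print.silica_cohort <- function(x, ...) {
  n <- nrow(x$samples)
  tab <- table(factor(x$samples$label, levels = 0:1))
  cat(sprintf(paste0("<silica_cohort> %d samples / %d patients ",
                     "(%d SS, %d PMF), %d markers%s\n"),
              n, length(unique(x$samples$patient_id)), tab[1], tab[2],
              ncol(x$markers),
              if (is.null(x$features)) "" else
                sprintf(", %d synthetic image features", ncol(x$features))))
  invisible(x)
}

#' Number of samples / patients in a cohort
#' @param cohort A `silica_cohort`.
#' @return Integer count.
#' @export
n_samples <- function(cohort) nrow(cohort$samples)

#' @rdname n_samples
#' @export
n_patients <- function(cohort) length(unique(cohort$samples$patient_id))

#' Write a cohort back to the manifest format `load_cohort()` reads
#'
#' Columns: identifiers, stage label as `SS`/`PMF`, image path, the 15 raw
#' measurements and the 6 derived indices (recomputed on load, so the
#' round trip is exact for everything the loader consumes).
#'
#' @param cohort A `silica_cohort`.
#' @param path Output file; comma-separated with header.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(cohort, path) {
  s <- cohort$samples
  df <- data.frame(
    sample_id = s$sample_id, patient_id = s$patient_id,
    sample_index = s$sample_index,
    label = c("SS", "PMF")[s$label + 1L],
    image = ifelse(is.na(s$image_path), "", s$image_path),
    stringsAsFactors = FALSE
  )
  full <- matrix(NA_real_, nrow(df), 21,
                 dimnames = list(NULL, marker_panel_names()))
  full[, colnames(cohort$markers)] <- cohort$markers
  utils::write.csv(cbind(df, as.data.frame(full)), path,
                   row.names = FALSE, na = "")
  invisible(path)
}
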