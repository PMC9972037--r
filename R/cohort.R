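#' Construct a cohort table
#'
#' The universal pipeline input: a samples x markers matrix of NPX values
#' (log2 relative abundance) joined to clinical covariates and the
#' right-censored overall-survival outcome. Exactly one marker column is
#' flagged as the CA19-9 channel; its values are kept on the log2(U/ml)
#' scale so that all markers live on a common log2 scale and penalized
#' regression weights are comparable.
#'
#' @param npx Numeric matrix, samples x markers, with unique rownames
#'   (sample ids) and unique colnames (marker names). Values are log2 NPX
#'   for proteins and log2(U/ml) for the CA19-9 channel.
#' @param clinical Data frame with one row per sample and columns
#'   `sample_id`, `resectable` (logical), `os_months` (positive),
#'   `event` (0/1), `age_years`, `stage` (1-4), `asa` (1-4, NA allowed),
#'   `adjuvant_chemo` (character/factor), `ca199_uml` (raw U/ml).
#' @param ca199_marker Name of the marker column holding CA19-9.
#'
#' @return An object of class `cohort_table` with elements `npx`,
#'   `clinical`, `markers` and `ca199_marker`.
#' @export
cohort_table <- function(npx, clinical, ca199_marker = "CA19-9") {
  if (!is.matrix(npx) || !is.numeric(npx)) stop("`npx` must be a numeric matrix")
  if (is.null(rownames(npx))) stop("`npx` must carry sample ids as rownames")
  required <- c("sample_id", "resectable", "os_months", "event",
                "age_years", "stage", "asa", "adjuvant_chemo", "ca199_uml")
  missing_cols <- setdiff(required, names(clinical))
  if (length(missing_cols)) {
    stop("clinical table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  ids <- as.character(clinical$sample_id)
  if (anyDuplicated(ids)) {
    stop("duplicate sample ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (anyDuplicated(colnames(npx))) stop("duplicate marker names")
  if (!setequal(rownames(npx), ids) || nrow(npx) != nrow(clinical)) {
    only_npx <- setdiff(rownames(npx), ids)
    only_cli <- setdiff(ids, rownames(npx))
    stop("sample ids do not match between marker and clinical tables; ",
         "only in marker table: [", paste(only_npx, collapse = ", "),
         "]; only in clinical table: [", paste(only_cli, collapse = ", "), "]")
  }
  npx <- npx[ids, , drop = FALSE]
  if (!ca199_marker %in% colnames(npx)) {
    stop("CA19-9 channel '", ca199_marker, "' not found among markers")
  }
  if (any(!is.finite(npx) & !is.na(npx))) {
    stop("non-finite NPX values present (use NA for missing entries)")
  }
  if (any(!clinical$event %in% c(0, 1))) stop("`event` must be 0 or 1")
  if (any(clinical$os_months <= 0)) stop("`os_months` must be positive")
  clinical$sample_id <- ids
  clinical$resectable <- as.logical(clinical$resectable)
  structure(
    list(
      npx = npx,
      clinical = clinical,
      markers = colnames(npx),
      ca199_marker = ca199_marker
    ),
    class = "cohort_table"
  )
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf(
    "Cohort table: %d samples x %d markers (%d resectable / %d unresectable)\n",
    nrow(x$npx), ncol(x$npx),
    sum(x$clinical$resectable), sum(!x$clinical$resectable)
  ))
  cat(sprintf("  events observed: %d (%.0f%% censored)\n",
              sum(x$clinical$event),
              100 * mean(x$clinical$event == 0)))
  cat(sprintf("  CA19-9 channel: %s (log2 U/ml)\n", x$ca199_marker))
  invisible(x)
}

#' Number of samples in a cohort
#' @param x A `cohort_table`.
#' @export
n_samples <- function(x) nrow(x$npx)

sniff_delim <- function(path) {
  if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read a cohort from marker and clinical files
#'
#' Reads the samples x markers table (CSV or TSV by extension, sample ids
#' in the first column) and the clinical table, joins them on sample id and
#' validates the result. The CA19-9 column is expected in raw U/ml in the
#' marker file and is log2-transformed on ingest, recorded in the returned
#' object's `provenance` attribute.
#'
#' @param marker_path Path to the marker file (columns = markers,
#'   rows = samples, first column = sample id).
#' @param clinical_path Path to the clinical file.
#' @param ca199_marker Name of the CA19-9 column in the marker file.
#' @return A `cohort_table`.
#' @export
read_cohort <- function(marker_path, clinical_path, ca199_marker = "CA19-9") {
  for (p in c(marker_path, clinical_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  mk <- utils::read.table(marker_path, header = TRUE, sep = sniff_delim(marker_path),
                          check.names = FALSE, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  cl <- utils::read.table(clinical_path, header = TRUE, sep = sniff_delim(clinical_path),
                          check.names = FALSE, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  if (ncol(mk) < 3) stop("marker file must contain at least 2 markers")
  ids <- as.character(mk[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicate sample ids in marker file: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  vals <- mk[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))
      stop(sprintf("non-numeric marker value at row %d, column '%s'",
                   bad[1], names(vals)[j]))
    }
  }
  npx <- as.matrix(vals)
  rownames(npx) <- ids
  if (!ca199_marker %in% colnames(npx)) {
    stop("CA19-9 channel '", ca199_marker, "' not found in marker file")
  }
  if (any(npx[, ca199_marker] <= 0, na.rm = TRUE)) {
    stop("raw CA19-9 values must be positive U/ml before log2 transform")
  }
  npx[, ca199_marker] <- log2(npx[, ca199_marker])
  cohort <- cohort_table(npx, cl, ca199_marker = ca199_marker)
  attr(cohort, "provenance") <- sprintf(
    "CA19-9 column '%s' log2-transformed from U/ml on ingest", ca199_marker)
  cohort
}

#' Write a cohort to marker and clinical files
#'
#' Inverse of [read_cohort()]: the CA19-9 channel is back-transformed to
#' raw U/ml in the marker file so that a read/write cycle is the identity
#' up to float formatting.
#'
#' @param cohort A `cohort_table`.
#' @param marker_path,clinical_path Output paths (.csv or .tsv).
#' @param digits Significant digits used when formatting (default 6).
#' @export
write_cohort <- function(cohort, marker_path, clinical_path, digits = 6) {
  npx <- cohort$npx
  npx[, cohort$ca199_marker] <- 2^npx[, cohort$ca199_marker]
  mk <- data.frame(sample_id = rownames(npx),
                   signif(npx, digits), check.names = FALSE)
  utils::write.table(mk, marker_path, sep = sniff_delim(marker_path),
                     row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  utils::write.table(cohort$clinical, clinical_path,
                     sep = sniff_delim(clinical_path),
                     row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(c(marker_path, clinical_path))
}

#' Extract a design matrix and labels for a comparison
#'
#' Restricts the cohort to the members of a two-group comparison and
#' returns the marker matrix plus a 0/1 label vector, 1 for the group
#' flagged as positive. Row order follows the cohort's sample order and is
#' recorded in the rownames.
#'
#' @param cohort A `cohort_table`.
#' @param spec A `comparison_spec` from [build_comparison_catalog()].
#' @return List with `x` (matrix), `y` (0/1 integer vector, named) and
#'   `sample_id`.
#' @export
extract_design <- function(cohort, spec) {
  stopifnot(inherits(spec, "comparison_spec"))
  if (!spec$usable) stop("comparison '", spec$name, "' is flagged unusable")
  ids <- cohort$clinical$sample_id
  keep <- ids %in% c(spec$group1, spec$group2)
  sel <- ids[keep]
  pos <- if (spec$positive_label == "group1") spec$group1 else spec$group2
  y <- as.integer(sel %in% pos)
  names(y) <- sel
  list(x = cohort$npx[sel, , drop = FALSE], y = y, sample_id = sel)
}
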