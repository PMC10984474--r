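#' Construct a probe-by-sample expression matrix with sample metadata
#'
#' The central container of the package: a non-negative probe x sample signal
#' matrix with per-sample compartment labels (stroma / epithelium for paired
#' micro-dissected profiles, bulk for tumor cohorts) and optional probe
#' annotation mapping probe ids to gene symbols. One gene symbol may map to
#' several probes; multi-probe genes are first-class throughout.
#'
#' @param signals numeric matrix, probes in rows (rownames = probe ids),
#'   samples in columns (colnames = sample ids). All values must be finite
#'   and >= 0; missing values are rejected because downstream statistics
#'   assume complete per-probe vectors.
#' @param sample_meta data.frame with columns `sample_id`, `tumor_id`,
#'   `compartment` (one of `"stroma"`, `"epithelium"`, `"bulk"`) and
#'   `is_reference` (logical; at most one reference sample per compartment).
#'   Every column of `signals` must have a metadata row.
#' @param probe_anno optional data.frame with columns `probe_id`, `symbol`
#'   (`NA` allowed for unannotated probes).
#' @return an object of class `ExpressionMatrix`: a list with elements
#'   `signals`, `sample_meta`, `probe_anno`.
#' @export
expression_matrix <- function(signals, sample_meta, probe_anno = NULL) {
  if (!is.matrix(signals) || !is.numeric(signals))
    stop("`signals` must be a numeric matrix")
  if (is.null(rownames(signals)) || is.null(colnames(signals)))
    stop("`signals` must carry probe ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(signals)))
    stop("format error: duplicated probe ids in expression table")
  if (anyDuplicated(colnames(signals)))
    stop("format error: duplicated sample ids in expression table")
  if (anyNA(signals))
    stop("missing values are not allowed in the signal block")
  if (any(!is.finite(signals)))
    stop("non-finite signal values are not allowed")
  if (any(signals < 0))
    stop("value error: negative signal intensities")

  req <- c("sample_id", "tumor_id", "compartment", "is_reference")
  if (!is.data.frame(sample_meta) || !all(req %in% names(sample_meta)))
    stop("`sample_meta` must have columns ", paste(req, collapse = ", "))
  sample_meta <- as.data.frame(sample_meta)[, req]
  sample_meta$sample_id <- as.character(sample_meta$sample_id)
  sample_meta$compartment <- as.character(sample_meta$compartment)
  sample_meta$is_reference <- as.logical(sample_meta$is_reference)
  if (anyDuplicated(sample_meta$sample_id))
    stop("format error: duplicated sample ids in metadata")
  missing_meta <- setdiff(colnames(signals), sample_meta$sample_id)
  if (length(missing_meta))
    stop("samples present in the matrix but absent from metadata: ",
         paste(missing_meta, collapse = ", "))
  bad <- !sample_meta$compartment %in% c("stroma", "epithelium", "bulk")
  if (any(bad))
    stop("value error: unknown compartment(s): ",
         paste(unique(sample_meta$compartment[bad]), collapse = ", "))
  # keep metadata in matrix column order, drop rows for absent samples
  sample_meta <- sample_meta[match(colnames(signals), sample_meta$sample_id), ]
  rownames(sample_meta) <- NULL
  for (cp in unique(sample_meta$compartment)) {
    n_ref <- sum(sample_meta$is_reference[sample_meta$compartment == cp],
                 na.rm = TRUE)
    if (n_ref > 1)
      stop("at most one reference sample allowed per compartment (", cp, ")")
  }

  if (!is.null(probe_anno)) {
    if (!is.data.frame(probe_anno) ||
        !all(c("probe_id", "symbol") %in% names(probe_anno)))
      stop("`probe_anno` must have columns probe_id, symbol")
    probe_anno <- as.data.frame(probe_anno)[, c("probe_id", "symbol")]
    probe_anno$probe_id <- as.character(probe_anno$probe_id)
    probe_anno$symbol <- as.character(probe_anno$symbol)
    if (anyDuplicated(probe_anno$probe_id))
      stop("format error: duplicated probe ids in annotation")
    probe_anno <- probe_anno[match(rownames(signals), probe_anno$probe_id), ]
    probe_anno$probe_id <- rownames(signals)
    rownames(probe_anno) <- NULL
  } else {
    probe_anno <- data.frame(probe_id = rownames(signals),
                             symbol = NA_character_,
                             stringsAsFactors = FALSE)
  }

  structure(list(signals = signals,
                 sample_meta = sample_meta,
                 probe_anno = probe_anno),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("<%s> %d probes x %d samples\n", class(x)[1L],
              nrow(x$signals), ncol(x$signals)))
  tab <- table(x$sample_meta$compartment)
  cat("  compartments:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  hk <- attr(x, "housekeeping_probe")
  if (!is.null(hk)) cat("  normalized by housekeeping probe:", hk, "\n")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$signals)

#' Sample ids belonging to one compartment
#'
#' @param m an `ExpressionMatrix`
#' @param compartment `"stroma"`, `"epithelium"` or `"bulk"`
#' @return character vector of sample ids
#' @export
compartment_samples <- function(m, compartment) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  m$sample_meta$sample_id[m$sample_meta$compartment == compartment]
}

#' Id of the flagged reference sample of a compartment
#'
#' The designated reference sample plays the role of the study case used to
#' read off expression amounts (abundance) of each probe.
#'
#' @inheritParams compartment_samples
#' @return a single sample id
#' @export
reference_sample <- function(m, compartment = "stroma") {
  stopifnot(inherits(m, "ExpressionMatrix"))
  sel <- m$sample_meta$compartment == compartment &
    m$sample_meta$is_reference %in% TRUE
  ids <- m$sample_meta$sample_id[sel]
  if (length(ids) != 1L)
    stop("configuration error: no reference sample flagged for compartment ",
         compartment)
  ids
}

#' Read a probe-level expression table and its sample metadata
#'
#' Expects a plain TSV in the shape of a GEO series-matrix value block:
#' probe ids in column 1, sample ids in the header row, signal intensities in
#' the body. Use standard GEO fetch tools to convert a series matrix to this
#' shape. Metadata is a TSV with columns sample_id, tumor_id, compartment,
#' is_reference; annotation (optional) a TSV with columns probe_id, symbol.
#'
#' @param path TSV of signals (probes x samples).
#' @param meta_path TSV of sample metadata.
#' @param anno_path optional TSV of probe annotation.
#' @return an [expression_matrix()] object
#' @export
load_expression_table <- function(path, meta_path, anno_path = NULL) {
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = NA)
  if (ncol(raw) < 2L)
    stop("format error: expression table needs a probe column plus >= 1 sample")
  probe_ids <- as.character(raw[[1L]])
  if (anyDuplicated(probe_ids))
    stop("format error: duplicated probe ids in ", path)
  vals <- raw[, -1L, drop = FALSE]
  if (anyDuplicated(names(vals)))
    stop("format error: duplicated sample ids in ", path)
  sig <- as.matrix(vals)
  if (!is.numeric(sig)) stop("value error: non-numeric signal values in ", path)
  rownames(sig) <- probe_ids
  meta <- utils::read.delim(meta_path, check.names = FALSE,
                            stringsAsFactors = FALSE)
  anno <- if (!is.null(anno_path))
    utils::read.delim(anno_path, check.names = FALSE, stringsAsFactors = FALSE)
  expression_matrix(sig, meta, anno)
}

#' Write an expression table (and optionally metadata) back to TSV
#'
#' Values are written with full precision (`format(..., digits = 17)` via
#' `write.table`), so a write/read round-trip of decimal text values is
#' faithful.
#'
#' @param m an `ExpressionMatrix`
#' @param path output TSV for the signal block
#' @param meta_path optional output TSV for sample metadata
#' @return `path`, invisibly
#' @export
write_expression_table <- function(m, path, meta_path = NULL) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  df <- data.frame(probe_id = rownames(m$signals),
                   format(m$signals, digits = 17, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(meta_path))
    utils::write.table(m$sample_meta, meta_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(path)
}

#' Normalize signals by a single housekeeping probe
#'
#' Per-sample adjustment to housekeeping units: each value becomes
#' `100 * signal / housekeeping-signal` of the same sample, i.e. the
#' "signal/GAPDH x 100" unit used for all abundance thresholds downstream.
#' The housekeeping probe's own row is exactly 100 in every sample, and the
#' operation is idempotent (normalizing a normalized matrix by the same
#' probe returns it unchanged) and invariant to per-sample rescaling of the
#' raw signals.
#'
#' @param m an `ExpressionMatrix`
#' @param hk_probe id of the housekeeping probe (e.g. the single GAPDH probe
#'   of the platform). A configuration value, never hard-coded: typical
#'   choices are `"A_23_P13899"` (Agilent 4x44K) and `"212581_x_at"`
#'   (Affymetrix U133 Plus 2.0).
#' @return a `NormalizedMatrix` (inherits `ExpressionMatrix`), with the
#'   housekeeping probe id attached as attribute `housekeeping_probe`.
#' @export
normalize_by_housekeeping <- function(m, hk_probe) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (!hk_probe %in% rownames(m$signals))
    stop("key error: housekeeping probe ", hk_probe, " not in matrix")
  hk <- m$signals[hk_probe, ]
  bad <- which(hk <= 0)
  if (length(bad))
    stop("degenerate input: housekeeping signal not strictly positive in ",
         "sample(s) ", paste(colnames(m$signals)[bad], collapse = ", "))
  out <- m
  out$signals <- sweep(m$signals, 2L, hk, "/") * 100
  attr(out, "housekeeping_probe") <- hk_probe
  class(out) <- c("NormalizedMatrix", "ExpressionMatrix")
  out
}
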