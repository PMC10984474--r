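#' Classify a cancer-stroma/epithelium specificity ratio
#'
#' Ratios are binned into three specificity classes with inclusive lower
#' bounds: High for cS/E of 10 or beyond, Middle for 5 or beyond and below
#' 10, Low below 5. The classification is monotone in the ratio.
#'
#' @param r numeric vector of cS/E ratios; must be finite and >= 0.
#' @return ordered factor with levels Low < Middle < High
#' @export
classify_cse <- function(r) {
  if (!is.numeric(r)) stop("value error: cS/E ratio must be numeric")
  if (any(!is.finite(r)))
    stop("value error: cS/E ratio must be finite")
  if (any(r < 0))
    stop("value error: cS/E ratio must be >= 0")
  cls <- ifelse(r >= 10, "High", ifelse(r >= 5, "Middle", "Low"))
  factor(cls, levels = c("Low", "Middle", "High"), ordered = TRUE)
}

#' Per-probe expression amount in the designated reference stromal sample
#'
#' Abundance is read off a single designated reference case: the probe's
#' normalized value (signal/housekeeping x 100) in the flagged reference
#' stromal sample. Signature filters use this quantity with an inclusive
#' threshold (default 40 normalized units).
#'
#' @param nm a `NormalizedMatrix`
#' @param probe optional probe id(s); default all probes
#' @return named numeric vector of normalized units
#' @export
expression_amount <- function(nm, probe = NULL) {
  stopifnot(inherits(nm, "NormalizedMatrix"))
  ref <- reference_sample(nm, "stroma")
  if (is.null(probe)) probe <- rownames(nm$signals)
  missing <- setdiff(probe, rownames(nm$signals))
  if (length(missing))
    stop("key error: unknown probe(s): ", paste(missing, collapse = ", "))
  nm$signals[probe, ref]
}

#' Compute per-probe compartment specificity profiles
#'
#' For every probe, the mean normalized expression over all stromal samples
#' and over all epithelial samples, their quotient (the cS/E ratio), its
#' High/Middle/Low class, and the expression amount in the reference stromal
#' sample. A probe whose epithelial mean is exactly zero gets the sentinel
#' `cse_ratio = +Inf` with `excluded = TRUE` and a warning: an infinite
#' ratio would trivially pass any specificity threshold, so such probes are
#' kept in output tables but barred from signature membership.
#'
#' @param nm a `NormalizedMatrix` with >= 1 stroma and >= 1 epithelium sample.
#' @param mode `"ratio-of-means"` (default): quotient of compartment means,
#'   robust to near-zero single-tumor epithelial values. `"mean-of-ratios"`:
#'   mean over tumors of per-tumor stroma/epithelium ratios (tumors paired by
#'   `tumor_id`).
#' @return data.frame of class `CompartmentProfile` with columns `probe_id`,
#'   `symbol`, `mean_stroma`, `mean_epi`, `cse_ratio`, `cse_class`,
#'   `amount_ref`, `excluded`.
#' @export
compute_cse <- function(nm, mode = c("ratio-of-means", "mean-of-ratios")) {
  stopifnot(inherits(nm, "NormalizedMatrix"))
  mode <- match.arg(mode)
  str_ids <- compartment_samples(nm, "stroma")
  epi_ids <- compartment_samples(nm, "epithelium")
  if (length(epi_ids) == 0L)
    stop("configuration error: no epithelium samples in matrix")
  if (length(str_ids) == 0L)
    stop("configuration error: no stroma samples in matrix")

  mean_stroma <- rowMeans(nm$signals[, str_ids, drop = FALSE])
  mean_epi <- rowMeans(nm$signals[, epi_ids, drop = FALSE])

  if (mode == "ratio-of-means") {
    ratio <- mean_stroma / mean_epi
  } else {
    meta <- nm$sample_meta
    tumors <- intersect(meta$tumor_id[meta$compartment == "stroma"],
                        meta$tumor_id[meta$compartment == "epithelium"])
    if (length(tumors) == 0L)
      stop("configuration error: no tumor has both compartments")
    per_tumor <- vapply(tumors, function(tu) {
      s <- meta$sample_id[meta$tumor_id == tu & meta$compartment == "stroma"]
      e <- meta$sample_id[meta$tumor_id == tu & meta$compartment == "epithelium"]
      rowMeans(nm$signals[, s, drop = FALSE]) /
        rowMeans(nm$signals[, e, drop = FALSE])
    }, numeric(nrow(nm$signals)))
    if (is.null(dim(per_tumor))) per_tumor <- matrix(per_tumor, nrow = 1L)
    ratio <- apply(per_tumor, 1L, function(x) mean(x[is.finite(x)]))
  }

  excluded <- !is.finite(ratio)
  if (any(excluded)) {
    warning(sum(excluded), " probe(s) with zero epithelial mean excluded ",
            "from specificity classification (cse_ratio = Inf sentinel)")
    ratio[excluded] <- Inf
  }
  cls <- factor(rep(NA_character_, length(ratio)),
                levels = c("Low", "Middle", "High"), ordered = TRUE)
  cls[!excluded] <- classify_cse(ratio[!excluded])

  out <- data.frame(probe_id = rownames(nm$signals),
                    symbol = nm$probe_anno$symbol,
                    mean_stroma = unname(mean_stroma),
                    mean_epi = unname(mean_epi),
                    cse_ratio = unname(ratio),
                    cse_class = cls,
                    amount_ref = unname(expression_amount(nm)),
                    excluded = excluded,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("CompartmentProfile", "data.frame")
  out
}

#' Write a compartment profile table to TSV
#'
#' @param profiles a `CompartmentProfile` data.frame from [compute_cse()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_cse_table <- function(profiles, path) {
  utils::write.table(profiles, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
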