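#' Correlation of every probe with an anchor probe (the R-index)
#'
#' The R-index of a probe is its correlation with a chosen anchor marker
#' probe across the samples of one compartment — by default the stromal
#' samples, where the co-expression structure of the tumor microenvironment
#' lives. Pearson on normalized linear values is the default; Spearman is
#' available for sensitivity analysis.
#'
#' @param nm a `NormalizedMatrix`
#' @param anchor_probe probe id of the anchor marker
#' @param compartment compartment whose samples enter the correlation
#' @param method `"pearson"` (default) or `"spearman"`
#' @return named numeric vector of R-index values in \[-1, 1\], one per
#'   probe; probes with zero variance across the compartment get `NA` and
#'   are excluded from signature membership.
#' @export
compute_r_index <- function(nm, anchor_probe,
                            compartment = "stroma",
                            method = c("pearson", "spearman")) {
  stopifnot(inherits(nm, "NormalizedMatrix"))
  method <- match.arg(method)
  ids <- compartment_samples(nm, compartment)
  if (length(ids) < 3L)
    stop("need >= 3 samples in compartment ", compartment,
         " to compute correlations (got ", length(ids), ")")
  if (!anchor_probe %in% rownames(nm$signals))
    stop("key error: anchor probe ", anchor_probe, " not in matrix")
  x <- t(nm$signals[, ids, drop = FALSE])
  anchor <- x[, anchor_probe]
  if (stats::sd(anchor) == 0)
    stop("degenerate input: anchor probe ", anchor_probe,
         " has zero variance across ", compartment, " samples")
  r <- suppressWarnings(stats::cor(x, anchor, method = method))[, 1L]
  r[apply(x, 2L, stats::sd) == 0] <- NA_real_
  r
}

#' Pick the representative probe of a gene symbol
#'
#' When a symbol maps to several probes, the probe with the largest
#' expression amount in the reference stromal sample represents the gene
#' (the "most abundant on the array" rule). Ties break deterministically to
#' the lexicographically smaller probe id.
#'
#' @param nm a `NormalizedMatrix` with probe annotation
#' @param symbol gene symbol
#' @return a probe id
#' @export
choose_anchor_probe <- function(nm, symbol) {
  stopifnot(inherits(nm, "NormalizedMatrix"))
  probes <- nm$probe_anno$probe_id[nm$probe_anno$symbol %in% symbol]
  if (length(probes) == 0L)
    stop("key error: symbol ", symbol, " not found in probe annotation")
  amt <- expression_amount(nm, probes)
  probes <- probes[order(-amt, probes)]
  probes[1L]
}

#' Derive an anchor-marker co-expression signature
#'
#' A signature is the set of probes passing three inclusive filters against
#' a chosen anchor marker, evaluated on stromal samples:
#' \itemize{
#'   \item co-expression: R-index >= `r_min` (default 0.9) with the anchor
#'     probe;
#'   \item stroma specificity: cS/E ratio >= `cse_min` (default 10);
#'   \item abundance: expression amount >= `amount_min` normalized units
#'     (default 40) in the reference stromal sample.
#' }
#' The three filters commute; members are returned sorted by abundance,
#' descending. An anchor that fails its own cS/E filter (a low-specificity
#' marker can still define a co-expression axis) raises a warning, not an
#' error. Probes flagged `excluded` in the profile table (infinite cS/E
#' sentinel) or with undefined R-index never become members.
#'
#' @param nm a `NormalizedMatrix`
#' @param profiles the [compute_cse()] table computed on the same matrix
#' @param anchor_symbol gene symbol of the anchor marker (e.g. SPARC for
#'   cancer-associated fibroblasts, PECAM1 for tumor-associated endothelia)
#' @param r_min,cse_min,amount_min inclusive filter thresholds
#' @param name signature name; defaults to `<anchor_symbol>G`
#' @param method correlation method, see [compute_r_index()]
#' @return object of class `SignatureDefinition`: list with `name`,
#'   `anchor_symbol`, `anchor_probe`, `thresholds`, `members` (data.frame
#'   probe_id, symbol, r_value, cse_ratio, amount_ref) and `n_associated`
#'   (probes with R-index >= `r_min` regardless of the other filters).
#' @export
derive_signature <- function(nm, profiles, anchor_symbol,
                             r_min = 0.9, cse_min = 10, amount_min = 40,
                             name = NULL, method = "pearson") {
  stopifnot(inherits(nm, "NormalizedMatrix"),
            inherits(profiles, "CompartmentProfile"))
  if (!identical(profiles$probe_id, rownames(nm$signals)))
    stop("profiles were not computed on this matrix (probe ids differ)")
  if (is.null(name)) name <- paste0(anchor_symbol, "G")
  anchor_probe <- choose_anchor_probe(nm, anchor_symbol)
  r <- compute_r_index(nm, anchor_probe, method = method)

  anchor_row <- profiles[profiles$probe_id == anchor_probe, ]
  if (!anchor_row$excluded && anchor_row$cse_ratio < cse_min)
    warning("anchor ", anchor_symbol, " (", anchor_probe, ") has cS/E ",
            format(anchor_row$cse_ratio, digits = 3), " below threshold ",
            cse_min, "; it defines the axis but is not a member")

  keep <- !is.na(r) & r >= r_min &
    !profiles$excluded & profiles$cse_ratio >= cse_min &
    profiles$amount_ref >= amount_min
  members <- data.frame(probe_id = profiles$probe_id,
                        symbol = profiles$symbol,
                        r_value = unname(r),
                        cse_ratio = profiles$cse_ratio,
                        amount_ref = profiles$amount_ref,
                        stringsAsFactors = FALSE)[keep, , drop = FALSE]
  members <- members[order(-members$amount_ref, members$probe_id), ]
  rownames(members) <- NULL

  structure(list(name = name,
                 anchor_symbol = anchor_symbol,
                 anchor_probe = anchor_probe,
                 thresholds = list(r_min = r_min, cse_min = cse_min,
                                   amount_min = amount_min),
                 members = members,
                 n_associated = sum(!is.na(r) & r >= r_min)),
            class = "SignatureDefinition")
}

#' @export
print.SignatureDefinition <- function(x, ...) {
  cat(sprintf("<SignatureDefinition> %s (anchor %s / %s)\n", x$name,
              x$anchor_symbol, x$anchor_probe))
  cat(sprintf("  thresholds: R >= %g, cS/E >= %g, amount >= %g\n",
              x$thresholds$r_min, x$thresholds$cse_min,
              x$thresholds$amount_min))
  cat(sprintf("  members: %d probes (%d symbols); %d probes associated at R >= %g\n",
              nrow(x$members),
              length(unique(stats::na.omit(x$members$symbol))),
              x$n_associated, x$thresholds$r_min))
  invisible(x)
}

#' Collapse signature member probes to unique gene symbols
#'
#' Probes without a symbol are dropped (their count is reported via a
#' message). Symbols are ordered by the maximum reference-sample amount
#' among each symbol's member probes, descending; ties break alphabetically.
#'
#' @param sig a `SignatureDefinition`
#' @return character vector of unique symbols, most abundant first
#' @export
collapse_to_symbols <- function(sig) {
  stopifnot(inherits(sig, "SignatureDefinition"))
  m <- sig$members
  n_drop <- sum(is.na(m$symbol))
  if (n_drop > 0)
    message(n_drop, " member probe(s) without a symbol dropped from collapse")
  m <- m[!is.na(m$symbol), , drop = FALSE]
  if (nrow(m) == 0L) return(character(0))
  best <- tapply(m$amount_ref, m$symbol, max)
  syms <- names(best)
  syms[order(-unname(best), syms)]
}

#' Keep the top n symbols of an ordered list
#'
#' @param symbols ordered character vector (most abundant first)
#' @param n number to keep; `n = 0` gives an empty selection and `n` beyond
#'   the list length keeps everything.
#' @return first `min(n, length(symbols))` symbols
#' @export
select_top_by_amount <- function(symbols, n) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 0)
  utils::head(symbols, n)
}

#' Default fibrosis symbol rule
#'
#' Collagen-family symbols (prefix COL) plus configured additions; SPARC and
#' TAGLN are included by default as collagen-induction genes.
#'
#' @param symbols character vector of symbols
#' @param extra additional symbols treated as fibrosis
#' @return logical vector
#' @export
is_fibrosis_symbol <- function(symbols, extra = c("SPARC", "TAGLN")) {
  grepl("^COL", symbols) | symbols %in% extra
}

#' Cross-tabulate membership across several signatures
#'
#' Builds a per-symbol membership table over a list of signatures, pairwise
#' overlap counts, and — when one signature is designated as the CAF
#' signature — a subclass per symbol: `fibrosis` for CAF members matching
#' the fibrosis rule, `non_fibrosis` for other CAF members, `not_CAFG`
#' otherwise.
#'
#' @param sigs list of `SignatureDefinition` objects (>= 2)
#' @param cafg_name name of the signature designated as CAFG for
#'   subclassing; default picks a signature literally named "CAFG" if
#'   present, else subclassing is skipped. Requesting subclassing
#'   (`subclass = TRUE`) without a designated CAFG is a configuration error.
#' @param subclass logical; classify symbols relative to the CAF signature
#' @param fibrosis_extra extra symbols counted as fibrosis, see
#'   [is_fibrosis_symbol()]
#' @return object of class `OverlapTable`: list with `membership`
#'   (data.frame symbol x signature flags + `subclass`), `pairwise` (matrix
#'   of overlap counts), `signatures` (names).
#' @export
intersect_signatures <- function(sigs, cafg_name = NULL, subclass = TRUE,
                                 fibrosis_extra = c("SPARC", "TAGLN")) {
  stopifnot(is.list(sigs), length(sigs) >= 2L,
            all(vapply(sigs, inherits, logical(1), "SignatureDefinition")))
  nms <- vapply(sigs, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("signature names must be unique")
  names(sigs) <- nms
  sym_sets <- lapply(sigs, function(s)
    unique(stats::na.omit(s$members$symbol)))
  universe <- sort(unique(unlist(sym_sets)))
  flags <- vapply(sym_sets, function(s) universe %in% s,
                  logical(length(universe)))
  if (is.null(dim(flags)))
    flags <- matrix(flags, nrow = length(universe), dimnames = list(NULL, nms))

  pairwise <- crossprod(flags * 1L)
  dimnames(pairwise) <- list(nms, nms)

  membership <- data.frame(symbol = universe, flags, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (subclass) {
    if (is.null(cafg_name) && "CAFG" %in% nms) cafg_name <- "CAFG"
    if (is.null(cafg_name))
      stop("configuration error: subclassing requested but no signature ",
           "designated as CAFG")
    if (!cafg_name %in% nms)
      stop("configuration error: no signature named ", cafg_name)
    in_cafg <- membership[[cafg_name]]
    fib <- is_fibrosis_symbol(universe, extra = fibrosis_extra)
    membership$subclass <- ifelse(!in_cafg, "not_CAFG",
                                  ifelse(fib, "fibrosis", "non_fibrosis"))
  }
  structure(list(membership = membership, pairwise = pairwise,
                 signatures = nms, cafg = cafg_name),
            class = "OverlapTable")
}

#' @export
print.OverlapTable <- function(x, ...) {
  cat("<OverlapTable>", length(x$signatures), "signatures,",
      nrow(x$membership), "symbols\n")
  print(x$pairwise)
  invisible(x)
}
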