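# Programmatic fixtures: tiny expression matrices and on-disk TSVs built at
# test time.

toy_matrix <- function(values, compartments = NULL, reference = NULL,
                       symbols = NULL) {
  if (is.null(compartments))
    compartments <- rep(c("stroma", "epithelium"), length.out = ncol(values))
  meta <- data.frame(
    sample_id = colnames(values),
    tumor_id = paste0("T", seq_len(ncol(values))),
    compartment = compartments,
    is_reference = if (is.null(reference)) c(TRUE, rep(FALSE, ncol(values) - 1))
                   else colnames(values) == reference,
    stringsAsFactors = FALSE)
  anno <- if (!is.null(symbols))
    data.frame(probe_id = rownames(values), symbol = symbols,
               stringsAsFactors = FALSE)
  expression_matrix(values, meta, anno)
}

# paired stroma/epi matrix from stroma and epi value blocks; first stroma
# sample is the reference
paired_matrix <- function(stroma, epi, symbols = NULL, tumor_ids = NULL) {
  stopifnot(nrow(stroma) == nrow(epi))
  nt <- ncol(stroma)
  if (is.null(tumor_ids)) tumor_ids <- sprintf("T%02d", seq_len(nt))
  vals <- cbind(stroma, epi)
  colnames(vals) <- c(paste0("STR_", tumor_ids), paste0("EPI_", tumor_ids))
  meta <- data.frame(
    sample_id = colnames(vals),
    tumor_id = rep(tumor_ids, 2),
    compartment = rep(c("stroma", "epithelium"), each = nt),
    is_reference = colnames(vals) == paste0("STR_", tumor_ids[1]),
    stringsAsFactors = FALSE)
  anno <- if (!is.null(symbols))
    data.frame(probe_id = rownames(vals), symbol = symbols,
               stringsAsFactors = FALSE)
  expression_matrix(vals, meta, anno)
}

write_toy_tsvs <- function(values, meta, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  expr_path <- file.path(dir, "expr.tsv")
  meta_path <- file.path(dir, "meta.tsv")
  df <- data.frame(probe_id = rownames(values), values, check.names = FALSE)
  utils::write.table(df, expr_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(meta, meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  list(expr = expr_path, meta = meta_path, dir = dir)
}

# a minimal SignatureDefinition for overlap/collapse tests
fake_signature <- function(name, symbols, amounts = NULL,
                           probes = NULL, r = NULL, cse = NULL) {
  n <- length(symbols)
  if (is.null(amounts)) amounts <- seq(100, 50, length.out = n)
  if (is.null(probes)) probes <- sprintf("%s_p%02d", name, seq_len(n))
  if (is.null(r)) r <- rep(0.95, n)
  if (is.null(cse)) cse <- rep(12, n)
  structure(list(name = name, anchor_symbol = symbols[1],
                 anchor_probe = probes[1],
                 thresholds = list(r_min = 0.9, cse_min = 10, amount_min = 40),
                 members = data.frame(probe_id = probes, symbol = symbols,
                                      r_value = r, cse_ratio = cse,
                                      amount_ref = amounts,
                                      stringsAsFactors = FALSE),
                 n_associated = n),
            class = "SignatureDefinition")
}
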