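#' Configuration for the synthetic paired-compartment study
#'
#' Describes a synthetic study emulating the real design this package
#' targets: ~13 tumors with paired micro-dissected stroma/epithelium
#' profiles over a few thousand probes, latent co-expression factors
#' anchored on marker genes with designed stroma specificity (cS/E) and
#' abundance, a designated reference stromal sample, multiple probes per
#' gene, and a linked bulk survival cohort (default 232 patients) whose
#' hazard depends log-linearly on planted prognostic genes with independent
#' censoring.
#'
#' @param n_tumors number of tumors; each contributes one stroma and one
#'   epithelium sample (default 13)
#' @param n_probes total probes on the synthetic array, housekeeping and
#'   factor probes included (default 2000)
#' @param factors list of co-expression factor descriptions, each a list
#'   with `name`, `anchor_symbol`, `n_member_probes`, `planted_cse`
#'   (specificity of member probes), `anchor_cse` (specificity of the
#'   anchor probe itself; markers like CD8A are low-specificity yet anchor
#'   high-specificity signatures), `amount_range` (reference-sample
#'   normalized units of members). See [default_factor_panel()].
#' @param probes_per_gene integer vector of admissible probes-per-gene
#'   counts for member genes; multiple probes of one gene share the gene's
#'   latent signal with independent noise (default `c(1, 2, 3)`)
#' @param noise_sd relative multiplicative noise sd on probe signals
#'   (default 0.05)
#' @param hk_signal raw housekeeping signal before per-sample scaling
#' @param survival list: `n_patients` (default 232), `baseline_hazard` per
#'   month, `betas` (named log-hazard slopes per planted gene),
#'   `n_null_genes` pure-noise genes, `censor_rate` target censoring
#'   fraction, optional `interaction` list (`gene_a`, `gene_b`, `beta_a`,
#'   `hr_b_low`): gene B's hazard ratio applies only in patients whose
#'   latent A-value lies below its median, emulating conditional
#'   stratification.
#' @param seed integer RNG seed; identical seeds give byte-identical data
#' @return validated list of class `SyntheticConfig`
#' @export
synthetic_config <- function(n_tumors = 13,
                             n_probes = 2000,
                             factors = default_factor_panel(),
                             probes_per_gene = c(1, 2, 3),
                             noise_sd = 0.05,
                             hk_signal = 1000,
                             survival = list(),
                             seed = 1) {
  sv <- utils::modifyList(
    list(n_patients = 232, baseline_hazard = 0.02,
         betas = c(SPARC = 0.7), n_null_genes = 10,
         censor_rate = 0.4, interaction = NULL),
    survival)
  cfg <- list(n_tumors = as.integer(n_tumors),
              n_probes = as.integer(n_probes),
              factors = factors,
              probes_per_gene = as.integer(probes_per_gene),
              noise_sd = noise_sd,
              hk_signal = hk_signal,
              survival = sv,
              seed = as.integer(seed))
  validate_synthetic_config(cfg)
  structure(cfg, class = "SyntheticConfig")
}

validate_synthetic_config <- function(cfg) {
  if (cfg$n_tumors < 1L || cfg$n_probes < 1L)
    stop("validation error: counts must be >= 1")
  if (cfg$noise_sd < 0)
    stop("validation error: noise_sd must be >= 0")
  if (cfg$survival$censor_rate < 0 || cfg$survival$censor_rate > 1)
    stop("validation error: censor_rate must lie in [0, 1]")
  if (any(cfg$probes_per_gene < 1L))
    stop("validation error: probes_per_gene counts must be >= 1")
  anchors <- vapply(cfg$factors, `[[`, character(1), "anchor_symbol")
  if (anyDuplicated(anchors))
    stop("validation error: factor anchor symbols must be unique ",
         "(member sets are disjoint by construction)")
  n_factor_probes <- sum(vapply(cfg$factors, function(f)
    f$n_member_probes + 1L, numeric(1)))
  if (n_factor_probes + 1L > cfg$n_probes)
    stop("validation error: n_probes too small for the configured factors")
  invisible(cfg)
}

#' Default synthetic factor panel
#'
#' Four tumor-microenvironment axes mirroring the study design the
#' generator emulates: an abundant, highly stroma-specific fibroblast
#' factor (anchor SPARC), an endothelial factor (anchor PECAM1, planted
#' anchor specificity 15.2), and two immune factors whose anchors (CD8A,
#' CD14) are low-specificity (4.7) while their member genes are
#' high-specificity.
#'
#' @return list of factor descriptions for [synthetic_config()]
#' @export
default_factor_panel <- function() {
  list(
    list(name = "CAFG", anchor_symbol = "SPARC", n_member_probes = 30,
         planted_cse = 12, anchor_cse = 12, amount_range = c(50, 300)),
    list(name = "TAEG", anchor_symbol = "PECAM1", n_member_probes = 15,
         planted_cse = 15, anchor_cse = 15.2, amount_range = c(45, 150)),
    list(name = "CTLG", anchor_symbol = "CD8A", n_member_probes = 12,
         planted_cse = 12, anchor_cse = 4.7, amount_range = c(45, 120)),
    list(name = "TAMCG", anchor_symbol = "CD14", n_member_probes = 12,
         planted_cse = 11, anchor_cse = 4.7, amount_range = c(45, 120))
  )
}

#' Generate a paired stroma/epithelium expression dataset
#'
#' Per factor, a positive log-normal latent signal is drawn across the
#' stromal samples; member probes are `loading x latent x (1 + noise)`,
#' with loadings calibrated so each probe's normalized value in the
#' designated reference stromal sample hits its target amount. Epithelial
#' values are scaled copies of each probe's stroma mean so the realized
#' cS/E (ratio of compartment means) targets the planted specificity —
#' specificity and co-expression are controlled independently. Background
#' probes are independent noise with cS/E near 1. A housekeeping probe with
#' constant pre-scaling signal is included, and every sample's raw column is
#' multiplied by a random scale factor that housekeeping normalization must
#' remove. With `noise_sd = 0` every member probe correlates with its
#' anchor at exactly r = 1 and realizes its planted cS/E exactly.
#'
#' @param cfg a [synthetic_config()]
#' @return list with `matrix` (an [expression_matrix()]), `ground_truth`
#'   (data.frame probe_id, symbol, factor, role, planted_cse,
#'   amount_target; plus attributes) and `hk_probe`, `reference_sample`
#' @export
generate_compartment_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "SyntheticConfig"))
  set.seed(cfg$seed)
  nt <- cfg$n_tumors
  tumors <- sprintf("T%02d", seq_len(nt))
  str_ids <- paste0("STR_", tumors)
  epi_ids <- paste0("EPI_", tumors)
  ref_id <- str_ids[1L]
  hk_probe <- "HK_GAPDH"
  hk <- cfg$hk_signal

  rows <- list()
  truth <- list()
  probe_counter <- 0L
  next_probe <- function() {
    probe_counter <<- probe_counter + 1L
    sprintf("P_%05d", probe_counter)
  }
  noise <- function(n) 1 + stats::rnorm(n, sd = cfg$noise_sd)

  for (f in cfg$factors) {
    latent <- stats::rlnorm(nt, meanlog = 0, sdlog = 0.6)
    # anchor probe: most abundant of its factor
    specs <- data.frame(probe_id = next_probe(),
                        symbol = f$anchor_symbol,
                        role = "anchor",
                        planted_cse = f$anchor_cse,
                        amount_target = max(f$amount_range) * 1.2,
                        stringsAsFactors = FALSE)
    # member probes grouped into genes with 1..k probes each
    remaining <- f$n_member_probes
    gene_idx <- 0L
    while (remaining > 0L) {
      gene_idx <- gene_idx + 1L
      k <- if (length(cfg$probes_per_gene) == 1L) cfg$probes_per_gene
        else sample(cfg$probes_per_gene, 1L)
      k <- min(k, remaining)
      sym <- sprintf("%s_G%02d", f$name, gene_idx)
      amt <- stats::runif(1L, f$amount_range[1L], f$amount_range[2L])
      for (j in seq_len(k)) {
        specs <- rbind(specs, data.frame(
          probe_id = next_probe(), symbol = sym, role = "member",
          planted_cse = f$planted_cse, amount_target = amt,
          stringsAsFactors = FALSE))
      }
      remaining <- remaining - k
    }
    for (i in seq_len(nrow(specs))) {
      loading <- specs$amount_target[i] / 100 * hk / latent[1L]
      s_vals <- pmax(loading * latent * noise(nt), 1e-8)
      e_vals <- pmax(mean(s_vals) / specs$planted_cse[i] * noise(nt), 1e-8)
      rows[[specs$probe_id[i]]] <- c(s_vals, e_vals)
    }
    specs$factor <- f$name
    truth[[f$name]] <- specs
  }

  n_bg <- cfg$n_probes - probe_counter - 1L
  bg_truth <- NULL
  if (n_bg > 0L) {
    bg_ids <- character(n_bg)
    base <- stats::rlnorm(n_bg, meanlog = log(20), sdlog = 1)
    for (i in seq_len(n_bg)) {
      pid <- next_probe()
      bg_ids[i] <- pid
      s_vals <- base[i] / 100 * hk * stats::rlnorm(nt, 0, 0.5)
      e_vals <- base[i] / 100 * hk * stats::rlnorm(nt, 0, 0.5)
      rows[[pid]] <- c(s_vals, e_vals)
    }
    bg_truth <- data.frame(probe_id = bg_ids,
                           symbol = sprintf("BG_G%04d", seq_len(n_bg)),
                           role = "background", planted_cse = NA_real_,
                           amount_target = NA_real_, factor = NA_character_,
                           stringsAsFactors = FALSE)
  }

  sig <- do.call(rbind, rows)
  sig <- rbind(sig, HK_GAPDH = rep(hk, 2L * nt))
  rownames(sig)[nrow(sig)] <- hk_probe
  colnames(sig) <- c(str_ids, epi_ids)
  # per-sample scale factors that normalization must cancel
  scale_s <- stats::runif(2L * nt, 0.5, 2)
  sig <- sweep(sig, 2L, scale_s, "*")

  truth_df <- do.call(rbind, c(truth, list(bg_truth)))
  truth_df <- rbind(truth_df, data.frame(
    probe_id = hk_probe, symbol = "GAPDH", role = "housekeeping",
    planted_cse = NA_real_, amount_target = NA_real_,
    factor = NA_character_, stringsAsFactors = FALSE))
  rownames(truth_df) <- NULL

  meta <- data.frame(
    sample_id = colnames(sig),
    tumor_id = rep(tumors, 2L),
    compartment = rep(c("stroma", "epithelium"), each = nt),
    is_reference = colnames(sig) == ref_id,
    stringsAsFactors = FALSE)
  anno <- truth_df[match(rownames(sig), truth_df$probe_id),
                   c("probe_id", "symbol")]

  m <- expression_matrix(sig, meta, anno)
  list(matrix = m, ground_truth = truth_df,
       hk_probe = hk_probe, reference_sample = ref_id)
}

#' Generate a bulk survival cohort with planted prognostic genes
#'
#' Each gene g gets a standard-normal patient-level latent z; expression is
#' the monotone transform `50 * exp(0.6 z)` (log-normal, positive,
#' normalized-unit scale). The per-patient hazard is
#' `baseline_hazard x exp(sum_g beta_g z_g)`; event times are exponential
#' given the hazard and censoring is independent exponential calibrated to
#' approximately the configured censoring fraction (`censor_rate = 0`
#' yields a fully observed cohort). Clinical covariates (age, sex, T/N/M
#' stage) are drawn from simple distributions and recorded. An optional
#' interaction block makes gene B prognostic only in patients whose latent
#' A-value is below its median.
#'
#' @param cfg a [synthetic_config()]
#' @param extra_genes optional character vector of additional zero-effect
#'   genes to include in the expression block (e.g. signature member
#'   symbols, so compartment-derived signatures can be evaluated in the
#'   cohort)
#' @return list with `cohort` (class `SurvivalCohort`: `clinical`
#'   data.frame and `expression` gene x patient matrix) and `ground_truth`
#'   (named beta per gene; interaction spec and true A-stratum if
#'   configured)
#' @export
generate_survival_cohort <- function(cfg, extra_genes = NULL) {
  stopifnot(inherits(cfg, "SyntheticConfig"))
  sv <- cfg$survival
  set.seed(cfg$seed)
  n <- sv$n_patients
  betas <- sv$betas
  if (is.null(betas)) betas <- numeric(0)
  null_genes <- if (sv$n_null_genes > 0)
    sprintf("NULLG_%02d", seq_len(sv$n_null_genes)) else character(0)
  genes <- c(names(betas), null_genes, setdiff(extra_genes,
             c(names(betas), null_genes)))
  inter <- sv$interaction
  if (!is.null(inter))
    genes <- unique(c(genes, inter$gene_a, inter$gene_b))
  if (length(genes) == 0L) stop("no genes configured for the cohort")

  z <- matrix(stats::rnorm(n * length(genes)), nrow = n,
              dimnames = list(NULL, genes))
  beta_full <- stats::setNames(rep(0, length(genes)), genes)
  beta_full[names(betas)] <- betas
  lp <- as.vector(z %*% beta_full)
  a_low <- NULL
  if (!is.null(inter)) {
    za <- z[, inter$gene_a]
    zb <- z[, inter$gene_b]
    a_low <- za < stats::median(za)
    lp <- lp + inter$beta_a * za + ifelse(a_low, log(inter$hr_b_low), 0) * zb
  }
  hazard <- sv$baseline_hazard * exp(lp)

  if (all(beta_full == 0) && is.null(inter) && sv$censor_rate >= 1)
    warning("all betas zero and censor_rate = 1: no events possible")
  t_event <- stats::rexp(n, rate = hazard)
  t_cens <- if (sv$censor_rate <= 0) rep(Inf, n)
    else if (sv$censor_rate >= 1) rep(0, n)
    else stats::rexp(n, rate = sv$baseline_hazard *
                       sv$censor_rate / (1 - sv$censor_rate))
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)

  expr <- t(50 * exp(0.6 * z)) # genes x patients
  colnames(expr) <- sprintf("PT_%03d", seq_len(n))

  clinical <- data.frame(
    patient_id = colnames(expr),
    time = time, event = event,
    age = round(stats::rnorm(n, 65, 10)),
    sex = sample(c("M", "F"), n, replace = TRUE),
    t_stage = sample(1:4, n, replace = TRUE, prob = c(.1, .2, .45, .25)),
    n_stage = sample(0:2, n, replace = TRUE, prob = c(.45, .35, .2)),
    m_stage = sample(0:1, n, replace = TRUE, prob = c(.8, .2)),
    stringsAsFactors = FALSE)

  cohort <- structure(list(clinical = clinical, expression = expr),
                      class = "SurvivalCohort")
  gt <- list(betas = beta_full, interaction = inter, a_low = a_low)
  list(cohort = cohort, ground_truth = gt)
}

#' @export
print.SurvivalCohort <- function(x, ...) {
  cat(sprintf("<SurvivalCohort> %d patients, %d genes, %d events\n",
              nrow(x$clinical), nrow(x$expression), sum(x$clinical$event)))
  invisible(x)
}

#' Write a survival cohort to a single TSV
#'
#' Columns: patient_id, time_months, event, age, sex, t_stage, n_stage,
#' m_stage, then one column per gene.
#'
#' @param cohort a `SurvivalCohort`
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
write_survival_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "SurvivalCohort"))
  df <- cbind(data.frame(patient_id = cohort$clinical$patient_id,
                         time_months = cohort$clinical$time,
                         event = cohort$clinical$event,
                         age = cohort$clinical$age,
                         sex = cohort$clinical$sex,
                         t_stage = cohort$clinical$t_stage,
                         n_stage = cohort$clinical$n_stage,
                         m_stage = cohort$clinical$m_stage,
                         stringsAsFactors = FALSE),
              as.data.frame(t(cohort$expression)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a survival cohort from TSV
#'
#' @param path TSV written by [write_survival_cohort()] (clinical columns
#'   first, then expression columns)
#' @return a `SurvivalCohort`
#' @export
load_survival_cohort <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  clin_cols <- c("patient_id", "time_months", "event", "age", "sex",
                 "t_stage", "n_stage", "m_stage")
  if (!all(clin_cols %in% names(df)))
    stop("format error: cohort TSV must have columns ",
         paste(clin_cols, collapse = ", "))
  if (any(df$time_months < 0)) stop("value error: negative follow-up time")
  if (!all(df$event %in% c(0, 1))) stop("value error: event must be 0/1")
  expr <- t(as.matrix(df[, setdiff(names(df), clin_cols), drop = FALSE]))
  colnames(expr) <- df$patient_id
  clinical <- data.frame(patient_id = df$patient_id, time = df$time_months,
                         event = df$event, age = df$age, sex = df$sex,
                         t_stage = df$t_stage, n_stage = df$n_stage,
                         m_stage = df$m_stage, stringsAsFactors = FALSE)
  structure(list(clinical = clinical, expression = expr),
            class = "SurvivalCohort")
}
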