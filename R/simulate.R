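#' Configuration for the synthetic multi-omics cohort generator
#'
#' Builds a validated configuration for [simulate_cohort()]. Defaults describe
#' a head-and-neck-like tumor cohort in a strong-activation regime: a driver
#' gene amplified in a minority of tumors (8.6% high-level events), a further
#' fraction of non-amplified tumors activated through copy-number-independent
#' mechanisms, a planted downstream transcriptional program, subtype-dependent
#' survival, an HPV anti-association with activation, per-group mutation
#' rates taken from reported head-and-neck screens, differentially expressed
#' miRNAs including a copy-number-independent pair, and a depressed
#' interferon-gamma response under activation.
#'
#' @param n_tumors,n_normals Tumor / normal sample counts (normals appear in
#'   the miRNA layer only).
#' @param n_genes Total genes in the expression layer (driver + program +
#'   interferon panel + null genes).
#' @param n_signature_genes Size of the planted downstream program.
#' @param driver_name Driver gene symbol.
#' @param amp_fraction Fraction of tumors with high-level driver
#'   amplification (GISTIC 2).
#' @param cni_fraction Fraction of non-amplified tumors that are nonetheless
#'   activated (copy-number-independent activation).
#' @param dosage_effect Expression units (log2) per GISTIC level for the
#'   driver.
#' @param activation_effect Additive driver-expression shift (log2) under
#'   activation.
#' @param program_corr Target marginal Pearson correlation of each planted
#'   program gene with latent driver activity.
#' @param noise_sd Residual SD of driver expression.
#' @param hazard_ratio True hazard ratio of activated vs inactivated tumors.
#' @param baseline_hazard Baseline exponential hazard (events/month).
#' @param censor_rate Exponential censoring hazard (0 = no censoring).
#' @param radiation_fraction Fraction of tumors receiving radiation.
#' @param radiation_hr_ya,radiation_hr_yi Hazard multipliers for radiation
#'   within the activated / inactivated groups (1 = no effect).
#' @param hpv_base Probability of HPV positivity given activation.
#' @param hpv_odds Odds multiplier for HPV positivity given inactivation.
#' @param mutation_rates Named list; each element `c(active, inactive)`
#'   per-group mutation probabilities for one panel gene.
#' @param n_mirna Number of miRNA features.
#' @param mirna_fc Named numeric vector of planted log2 fold changes
#'   (activated vs inactivated) for miRNA features; names not already of the
#'   form `HSA-MIR-...` are assigned to the first features.
#' @param cni_mirna Character vector of miRNA ids elevated only in
#'   copy-number-independent activated tumors.
#' @param cni_mirna_shift Log2 shift of the CNI-specific miRNAs.
#' @param ifng_shift Mean depression (log2 units) of the six
#'   interferon-gamma-related genes in activated tumors.
#' @param cn_amp_rates,cn_del_rates Optional named lists planting per-gene
#'   copy-number event probabilities `c(active, inactive)` (amplification =
#'   GISTIC 2, deletion = GISTIC -1/-2).
#' @param name Cohort name.
#' @param seed Mandatory integer seed.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_tumors = 513, n_normals = 44, n_genes = 2000,
                       n_signature_genes = 200, driver_name = "YAP1",
                       amp_fraction = 0.086, cni_fraction = 0.3,
                       dosage_effect = 1, activation_effect = 5,
                       program_corr = 0.5, noise_sd = 1,
                       hazard_ratio = 2, baseline_hazard = 0.015,
                       censor_rate = 0.008, radiation_fraction = 0.5,
                       radiation_hr_ya = 1, radiation_hr_yi = 1,
                       hpv_base = 0.01, hpv_odds = 26,
                       mutation_rates = list(
                         TP53   = c(0.826, 0.644),
                         CDKN2A = c(0.283, 0.191),
                         NFE2L2 = c(0.011, 0.078),
                         PTEN   = c(0.005, 0.042),
                         SYNE1  = c(0.141, 0.223),
                         NSD1   = c(0.082, 0.149),
                         AJUBA  = c(0.071, 0.058)),
                       n_mirna = 150,
                       mirna_fc = stats::setNames(
                         c(rep(1.5, 8), rep(-1.5, 4)),
                         sprintf("HSA-MIR-DE%02d", 1:12)),
                       cni_mirna = c("HSA-MIR-187", "HSA-MIR-675"),
                       cni_mirna_shift = 1.5,
                       ifng_shift = 0.8,
                       cn_amp_rates = NULL, cn_del_rates = NULL,
                       name = "SIM", seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  cfg <- as.list(environment())
  frac <- c(amp_fraction = amp_fraction, cni_fraction = cni_fraction,
            radiation_fraction = radiation_fraction, hpv_base = hpv_base,
            censor = min(censor_rate, 1))
  if (any(frac < 0 | frac > 1)) stop("fractions must lie in [0, 1]")
  if (hazard_ratio <= 0) stop("hazard_ratio must be positive")
  if (n_signature_genes >= n_genes) {
    stop("n_signature_genes must be smaller than n_genes")
  }
  if (n_genes < n_signature_genes + length(ifng_genes()) + 1L) {
    stop("n_genes too small for program + interferon panel + driver")
  }
  if (length(mirna_fc) + length(cni_mirna) > n_mirna) {
    stop("more planted miRNAs than n_mirna")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' The six interferon-gamma-related genes of the composite immune score
#' @return Character vector of gene symbols.
#' @export
ifng_genes <- function() {
  c("CXCL9", "CXCL10", "IDO1", "IFNG", "HLA-DRA", "STAT1")
}

# GISTIC level distribution for non-amplified samples (levels -2..1),
# renormalized to 1 - amp_fraction at draw time.
.gistic_rest_probs <- c(`-2` = 0.015, `-1` = 0.08, `0` = 0.755, `1` = 0.15)

.draw_gistic <- function(n, amp_fraction) {
  p <- c(.gistic_rest_probs / sum(.gistic_rest_probs) * (1 - amp_fraction),
         `2` = amp_fraction)
  sample(c(-2L, -1L, 0L, 1L, 2L), n, replace = TRUE, prob = p)
}

#' Simulate one multi-omics cohort with planted ground truth
#'
#' Generates aligned expression, copy-number, mutation, miRNA and clinical
#' layers under the configured effects, plus a `ground_truth` object for
#' recovery testing. The generative model: the driver's GISTIC score is drawn
#' categorically with `amp_fraction` high-level amplifications; latent
#' activation is amplification OR (with probability `cni_fraction`) a
#' copy-number-independent event; driver expression is
#' `dosage_effect * gistic + activation_effect * activation + noise`; each
#' planted program gene loads on the standardized latent activity
#' (the systematic part of driver expression) with independent noise
#' calibrated so its marginal correlation with activity equals
#' `program_corr`; survival is exponential with hazard
#' `baseline_hazard * hazard_ratio^activation` and independent exponential
#' censoring; all other layers follow the per-group rates in the config.
#' Fully reproducible from `seed`.
#'
#' @param cfg A [sim_config()] object.
#' @return List with elements `cohort` (a [cohort()] bundle) and `truth`
#'   (class `ground_truth`: `activation`, `cni_labels`, `true_signature`,
#'   `hr_true`, `config`).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  # independent substreams per layer, all derived from the global seed
  sub <- sample.int(.Machine$integer.max - 1L, 8L)

  n <- cfg$n_tumors
  ids <- sprintf("%s-T%04d", cfg$name, seq_len(n))
  nrm_ids <- if (cfg$n_normals > 0) sprintf("%s-N%03d", cfg$name, seq_len(cfg$n_normals))

  ## latent structure -------------------------------------------------------
  set.seed(sub[1L])
  g_driver <- .draw_gistic(n, cfg$amp_fraction)
  amp <- g_driver >= 2L
  act <- amp | (!amp & stats::runif(n) < cfg$cni_fraction)
  cni_labels <- factor(ifelse(amp & act, "CND-YA",
                       ifelse(act, "CNI-YA", "YI")),
                       levels = c("CND-YA", "CNI-YA", "YI"))
  u <- cfg$dosage_effect * g_driver + cfg$activation_effect * as.numeric(act)

  ## expression layer -------------------------------------------------------
  set.seed(sub[2L])
  ifng <- ifng_genes()
  n_prog <- cfg$n_signature_genes
  n_null <- cfg$n_genes - n_prog - length(ifng) - 1L
  prog_genes <- sprintf("PRG%04d", seq_len(n_prog))
  null_genes <- sprintf("NUL%04d", seq_len(n_null))
  z_u <- if (stats::sd(u) > 0) (u - mean(u)) / stats::sd(u) else u * 0
  rho <- cfg$program_corr
  prog <- if (n_prog > 0) {
    stats::rnorm(n_prog, 8, 1) +
      rho * matrix(z_u, n_prog, n, byrow = TRUE) +
      sqrt(1 - rho^2) * matrix(stats::rnorm(n_prog * n), n_prog, n)
  } else matrix(numeric(0), 0L, n)
  null <- matrix(stats::rnorm(n_null * n, 8, 1), n_null, n)
  ifng_m <- matrix(stats::rnorm(length(ifng) * n, 8, 1), length(ifng), n) -
    cfg$ifng_shift * matrix(as.numeric(act), length(ifng), n, byrow = TRUE)
  y_driver <- 8 + u + stats::rnorm(n, 0, cfg$noise_sd)
  expr <- rbind(matrix(y_driver, 1L, n), prog, null, ifng_m)
  dimnames(expr) <- list(c(cfg$driver_name, prog_genes, null_genes, ifng),
                         ids)
  attr(expr, "standardized") <- FALSE

  ## copy-number layer ------------------------------------------------------
  set.seed(sub[3L])
  cn_genes <- rownames(expr)
  cn <- matrix(.draw_gistic(length(cn_genes) * n, cfg$amp_fraction),
               length(cn_genes), n, dimnames = list(cn_genes, ids))
  cn[cfg$driver_name, ] <- g_driver
  plant_cn <- function(m, rates, event_level) {
    for (gene in names(rates)) {
      p <- ifelse(act, rates[[gene]][1L], rates[[gene]][2L])
      hit <- stats::runif(n) < p
      row <- if (gene %in% rownames(m)) m[gene, ] else integer(n)
      row[hit] <- event_level
      row[!hit & row == event_level] <- 0L
      if (!gene %in% rownames(m)) {
        m <- rbind(m, matrix(row, 1L, n, dimnames = list(gene, ids)))
      } else m[gene, ] <- row
    }
    m
  }
  if (!is.null(cfg$cn_amp_rates)) cn <- plant_cn(cn, cfg$cn_amp_rates, 2L)
  if (!is.null(cfg$cn_del_rates)) cn <- plant_cn(cn, cfg$cn_del_rates, -2L)

  ## mutation layer ---------------------------------------------------------
  set.seed(sub[4L])
  mut_genes <- names(cfg$mutation_rates)
  mut <- matrix(0L, length(mut_genes), n, dimnames = list(mut_genes, ids))
  for (gene in mut_genes) {
    p <- ifelse(act, cfg$mutation_rates[[gene]][1L], cfg$mutation_rates[[gene]][2L])
    mut[gene, ] <- as.integer(stats::runif(n) < p)
  }

  ## miRNA layer (tumors + normals) -----------------------------------------
  set.seed(sub[5L])
  mir_planted <- c(names(cfg$mirna_fc), cfg$cni_mirna)
  mir_ids <- c(mir_planted,
               sprintf("HSA-MIR-N%03d", seq_len(cfg$n_mirna - length(mir_planted))))
  n_all <- n + cfg$n_normals
  mir <- matrix(stats::rnorm(cfg$n_mirna * n_all, 6, 1), cfg$n_mirna, n_all,
                dimnames = list(mir_ids, c(ids, nrm_ids)))
  tum <- seq_len(n)
  for (mid in names(cfg$mirna_fc)) {
    mir[mid, tum] <- mir[mid, tum] + cfg$mirna_fc[[mid]] * as.numeric(act)
  }
  is_cni <- cni_labels == "CNI-YA"
  for (mid in cfg$cni_mirna) {
    mir[mid, tum] <- mir[mid, tum] + cfg$cni_mirna_shift * as.numeric(is_cni)
  }
  mir_class <- stats::setNames(
    c(rep("tumor", n), rep("normal", cfg$n_normals)), colnames(mir))

  ## survival + clinical ----------------------------------------------------
  set.seed(sub[6L])
  rad <- stats::runif(n) < cfg$radiation_fraction
  haz <- cfg$baseline_hazard * cfg$hazard_ratio^as.numeric(act) *
    ifelse(rad, ifelse(act, cfg$radiation_hr_ya, cfg$radiation_hr_yi), 1)
  t_event <- stats::rexp(n, haz)
  t_cens <- if (cfg$censor_rate > 0) stats::rexp(n, cfg$censor_rate) else rep(Inf, n)
  os_time <- pmin(t_event, t_cens)
  os_event <- as.integer(t_event <= t_cens)

  set.seed(sub[7L])
  odds_act <- cfg$hpv_base / (1 - cfg$hpv_base)
  odds_inact <- odds_act * cfg$hpv_odds
  p_hpv <- ifelse(act, cfg$hpv_base, odds_inact / (1 + odds_inact))
  hpv <- ifelse(stats::runif(n) < p_hpv, "positive", "negative")
  clinical <- data.frame(
    sample_id = ids,
    os_time = os_time, os_event = os_event,
    dfs_time = NA_real_, dfs_event = NA_integer_,
    hpv_status = hpv,
    sex = sample(c("male", "female"), n, TRUE, prob = c(0.74, 0.26)),
    age = round(stats::rnorm(n, 61, 12), 1),
    anatomic_site = sample(c("oral_cavity", "oropharynx", "larynx", "hypopharynx"),
                           n, TRUE, prob = c(0.60, 0.16, 0.22, 0.02)),
    t_stage = sample(c("T1", "T2", "T3", "T4"), n, TRUE,
                     prob = c(0.07, 0.30, 0.27, 0.36)),
    n_stage = sample(c("N0", "N1", "N2", "N3"), n, TRUE,
                     prob = c(0.50, 0.16, 0.32, 0.02)),
    overall_stage = sample(c("I", "II", "III", "IV"), n, TRUE,
                           prob = c(0.04, 0.20, 0.21, 0.55)),
    radiation = ifelse(rad, "yes", "no"),
    cohort_name = cfg$name,
    stringsAsFactors = FALSE)

  truth <- structure(list(
    activation = stats::setNames(as.integer(act), ids),
    cni_labels = stats::setNames(cni_labels, ids),
    true_signature = prog_genes,
    hr_true = cfg$hazard_ratio,
    config = cfg), class = "ground_truth")

  bundle <- cohort(name = cfg$name, expression = expr, clinical = clinical,
                   cn = cn, mutations = mut, mirna = mir,
                   mirna_class = mir_class)
  list(cohort = bundle, truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Ground truth:", sum(x$activation), "of", length(x$activation),
      "tumors activated\n")
  print(table(x$cni_labels))
  cat("planted program:", length(x$true_signature),
      "genes; true HR:", x$hr_true, "\n")
  invisible(x)
}

#' Simulate several independent cohorts
#'
#' @param cfgs List of [sim_config()] objects with distinct names. Each
#'   cohort is generated independently from its own seed; set
#'   `missing_gene_frac` to drop a random fraction of non-driver genes from a
#'   cohort's expression panel, exercising signature-coverage handling.
#' @param missing_gene_frac Numeric vector (recycled over cohorts) of
#'   fractions of non-driver genes to drop from each cohort's platform.
#' @return Named list of `simulate_cohort()` results.
#' @export
simulate_multi_cohort <- function(cfgs, missing_gene_frac = 0) {
  if (length(cfgs) < 2L) stop("need at least two cohort configs")
  nms <- vapply(cfgs, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("duplicate cohort names")
  missing_gene_frac <- rep_len(missing_gene_frac, length(cfgs))
  out <- lapply(seq_along(cfgs), function(i) {
    sim <- simulate_cohort(cfgs[[i]])
    f <- missing_gene_frac[i]
    if (f > 0) {
      expr <- sim$cohort$expression
      cand <- setdiff(rownames(expr), cfgs[[i]]$driver_name)
      set.seed(cfgs[[i]]$seed + 1L)
      drop <- sample(cand, round(f * length(cand)))
      keep_rows <- setdiff(rownames(expr), drop)
      std <- attr(expr, "standardized")
      sim$cohort$expression <- expr[keep_rows, , drop = FALSE]
      attr(sim$cohort$expression, "standardized") <- isTRUE(std)
    }
    sim
  })
  stats::setNames(out, nms)
}

#' Write a simulated cohort to disk in the package's exchange formats
#'
#' Expression / copy-number / miRNA matrices and the clinical table are
#' written tab-delimited; ground truth goes to a sidecar table and the
#' configuration is echoed as YAML.
#'
#' @param sim A `simulate_cohort()` result.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  b <- sim$cohort
  write_expression(b$expression, file.path(dir, "expression.tsv"))
  if (!is.null(b$cn)) {
    utils::write.table(data.frame(gene = rownames(b$cn), b$cn, check.names = FALSE),
                       file.path(dir, "gistic.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(b$mutations)) {
    utils::write.table(data.frame(gene = rownames(b$mutations), b$mutations,
                                  check.names = FALSE),
                       file.path(dir, "mutations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(b$mirna)) {
    utils::write.table(data.frame(mirna = rownames(b$mirna), b$mirna,
                                  check.names = FALSE),
                       file.path(dir, "mirna.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(sample_id = names(b$mirna_class),
                                  class = b$mirna_class),
                       file.path(dir, "mirna_classes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(b$clinical, file.path(dir, "clinical.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  tr <- sim$truth
  utils::write.table(data.frame(sample_id = names(tr$activation),
                                activation = tr$activation,
                                cni_label = as.character(tr$cni_labels)),
                     file.path(dir, "ground_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(tr$true_signature, file.path(dir, "true_signature.txt"))
  cfg <- tr$config
  cfg$mutation_rates <- lapply(cfg$mutation_rates, as.numeric)
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(dir)
}
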