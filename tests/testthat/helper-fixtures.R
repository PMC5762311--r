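# shared fixture builders; all randomness is seeded by the caller

# random gene x sample matrix with dimnames
rand_matrix <- function(n_genes, n_samples, mean = 0, sd = 1) {
  matrix(rnorm(n_genes * n_samples, mean, sd), n_genes, n_samples,
         dimnames = list(sprintf("G%04d", seq_len(n_genes)),
                         sprintf("S%04d", seq_len(n_samples))))
}

# balanced two-class training labels over the columns of m
balanced_classes <- function(m, n_active = ncol(m) %/% 2) {
  cls <- factor(rep(c("active", "inactive"),
                    c(n_active, ncol(m) - n_active)),
                levels = c("active", "inactive"))
  names(cls) <- colnames(m)
  cls
}

# truth-based subtype calls for feeding the association screens directly
truth_calls <- function(truth) {
  data.frame(sample_id = names(truth$activation),
             score = as.numeric(truth$activation),
             posterior = as.numeric(truth$activation),
             label = ifelse(truth$activation == 1, "YA", "YI"),
             stringsAsFactors = FALSE)
}

# two-sided Fisher p by full enumeration of margin-consistent tables:
# sum of hypergeometric point probabilities <= observed (1e-7 relative slack)
fisher_enum_p <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# a small null configuration: no planted effects anywhere
null_config <- function(seed, n_tumors = 200, ...) {
  sim_config(seed = seed, n_tumors = n_tumors, n_genes = 300,
             n_signature_genes = 50, hazard_ratio = 1, ifng_shift = 0,
             hpv_base = 0.15, hpv_odds = 1,
             mirna_fc = stats::setNames(numeric(0), character(0)),
             cni_mirna_shift = 0,
             mutation_rates = list(TP53 = c(0.5, 0.5), CDKN2A = c(0.2, 0.2)),
             n_mirna = 100, ...)
}
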