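test_that("Fisher p agrees exactly with full enumeration on random tables", {
  set.seed(301)
  for (i in 1:100) {
    tab <- matrix(rpois(4, 6) + 1, 2, 2)
    ft <- fisher_exact_2x2(tab)
    expect_equal(ft$p_value, min(fisher_enum_p(tab), 1), tolerance = 1e-12)
  }
})

test_that("Fisher identities and degenerate handling", {
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2))$p_value, 1)
  expect_error(fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2)), "margin")
  expect_error(fisher_exact_2x2(matrix(c(1.5, 2, 3, 4), 2)), "integer")
  # invariant under simultaneous row and column swaps
  tab <- matrix(c(3, 9, 14, 2), 2, 2)
  a <- fisher_exact_2x2(tab)
  b <- fisher_exact_2x2(tab[2:1, 2:1])
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
  expect_equal(a$odds_ratio, b$odds_ratio, tolerance = 1e-12)
})

test_that("the HPV contingency reconstruction gives the reported association", {
  ft <- fisher_exact_2x2(matrix(c(1, 35, 104, 139), 2, 2))
  expect_equal(ft$p_value, 4.29e-7, tolerance = 0.02)
  expect_lt(ft$odds_ratio, 1)  # HPV positivity depleted under activation
})

test_that("copy-number screens use high-level gains and all losses", {
  cfg <- sim_config(n_tumors = 500, n_genes = 150, n_signature_genes = 30,
                    cn_amp_rates = list(EGFR = c(0.30, 0.05)),
                    cn_del_rates = list(CDKN2A = c(0.35, 0.08)),
                    seed = 302)
  sim <- simulate_cohort(cfg)
  calls <- truth_calls(sim$truth)
  res <- compare_cn_events(sim$cohort, calls)
  # the driver's own amplification defines activation, so rank planted
  # genes among the rest
  amp <- res$amplification[res$amplification$gene != "YAP1", ]
  expect_identical(amp$gene[1], "EGFR")
  expect_lt(amp$p_value[1], 1e-6)
  del <- res$deletion[res$deletion$gene != "YAP1", ]
  expect_identical(del$gene[1], "CDKN2A")
  expect_lt(del$p_value[1], 1e-6)
  # event definitions: amplification counts only GISTIC >= 2
  amp_row <- res$amplification[res$amplification$gene == "EGFR", ]
  cn <- sim$cohort$cn["EGFR", calls$sample_id]
  expect_identical(amp_row$n_ya_event + amp_row$n_yi_event,
                   sum(cn >= 2))
  del_row <- res$deletion[res$deletion$gene == "CDKN2A", ]
  cn_d <- sim$cohort$cn["CDKN2A", calls$sample_id]
  expect_identical(del_row$n_ya_event + del_row$n_yi_event, sum(cn_d <= -1))
})

test_that("a gene with no events yields an undefined OR and p = 1", {
  sim <- simulate_cohort(sim_config(n_tumors = 60, n_genes = 60,
                                    n_signature_genes = 10, seed = 303))
  sim$cohort$cn["NUL0001", ] <- 0L
  res <- compare_cn_events(sim$cohort, truth_calls(sim$truth))
  row <- res$amplification[res$amplification$gene == "NUL0001", ]
  expect_true(is.na(row$odds_ratio))
  expect_equal(row$p_value, 1)
})

test_that("mutation screen recovers planted per-group rates", {
  cfg <- sim_config(n_tumors = 500, n_genes = 120, n_signature_genes = 20,
                    mutation_rates = list(TP53 = c(0.8, 0.6),
                                          NULLG = c(0.3, 0.3)),
                    seed = 304)
  sim <- simulate_cohort(cfg)
  calls <- truth_calls(sim$truth)
  res <- compare_mutations(sim$cohort, calls)
  tp <- res[res$gene == "TP53", ]
  n_ya <- sum(calls$label == "YA"); n_yi <- sum(calls$label == "YI")
  expect_lt(abs(tp$pct_ya / 100 - 0.8), 3 * sqrt(0.8 * 0.2 / n_ya))
  expect_lt(abs(tp$pct_yi / 100 - 0.6), 3 * sqrt(0.6 * 0.4 / n_yi))
  expect_lt(tp$p_value, 0.01)
  expect_warning(compare_mutations(sim$cohort, calls,
                                   genes = c("TP53", "ABSENT")), "skipped")
})

test_that("differential miRNA filter applies the two-sided fold rule", {
  sim <- simulate_cohort(sim_config(n_tumors = 400, n_genes = 120,
                                    n_signature_genes = 20, seed = 305))
  calls <- truth_calls(sim$truth)
  dm <- differential_mirna(sim$cohort, calls)
  planted <- grep("DE", dm$mirna, value = TRUE)
  expect_true(all(dm$passes[dm$mirna %in% planted]))
  # agreement with a direct t-test recomputation
  tum <- names(sim$cohort$mirna_class)[sim$cohort$mirna_class == "tumor"]
  is_ya <- calls$label[match(tum, calls$sample_id)] == "YA"
  for (mid in dm$mirna[1:5]) {
    v <- sim$cohort$mirna[mid, tum]
    tt <- t.test(v[is_ya], v[!is_ya], var.equal = TRUE)
    row <- dm[dm$mirna == mid, ]
    expect_equal(row$t, unname(tt$statistic), tolerance = 1e-10)
    expect_equal(row$p_value, tt$p.value, tolerance = 1e-10)
    expect_equal(row$fc, 2^(mean(v[is_ya]) - mean(v[!is_ya])), tolerance = 1e-10)
  }
})

test_that("fold-change boundary is inclusive and identical means fail", {
  ids <- sprintf("S%03d", 1:24)
  m <- rbind(BOUND = c(rep(1, 12), rep(0, 12)),
             FLAT = rep(3, 24))
  colnames(m) <- ids
  clin <- data.frame(sample_id = ids, os_time = 1, os_event = 0)
  expr <- rand_matrix(4, 24); colnames(expr) <- ids
  b <- cohort("fc", expr, clin, mirna = m)
  calls <- data.frame(sample_id = ids, score = 0,
                      posterior = rep(c(1, 0), c(12, 12)),
                      label = rep(c("YA", "YI"), c(12, 12)))
  dm <- differential_mirna(b, calls)
  bound <- dm[dm$mirna == "BOUND", ]
  expect_equal(bound$fc, 2, tolerance = 1e-12)   # exact +1 log2 shift
  expect_true(bound$passes)                       # >= rule at the boundary
  flat <- dm[dm$mirna == "FLAT", ]
  expect_equal(flat$fc, 1, tolerance = 1e-12)
  expect_false(flat$passes)
})

test_that("the CNI miRNA screen returns nested lists and finds the planted pair", {
  sim <- simulate_cohort(sim_config(seed = 306))
  calls <- truth_calls(sim$truth)
  sc <- cni_mirna_screen(sim$cohort, calls)
  expect_true(all(sc$final$mirna %in% sc$stage2$mirna))
  expect_true(all(sc$stage2$mirna %in% sc$stage1$mirna))
  expect_setequal(sc$final$mirna, c("HSA-MIR-187", "HSA-MIR-675"))
  expect_identical(unname(table(sc$groups)[c("CND-YA", "CNI-YA", "YI")]),
                   unname(table(sim$truth$cni_labels)))
})

test_that("the CNI screen demands normals and a CNI group", {
  sim <- simulate_cohort(sim_config(n_tumors = 200, n_genes = 120,
                                    n_signature_genes = 20, n_normals = 0,
                                    seed = 307))
  calls <- truth_calls(sim$truth)
  expect_error(cni_mirna_screen(sim$cohort, calls), "normal")
  sim2 <- simulate_cohort(sim_config(n_tumors = 200, n_genes = 120,
                                     n_signature_genes = 20,
                                     cni_fraction = 0, seed = 308))
  expect_error(cni_mirna_screen(sim2$cohort, truth_calls(sim2$truth)), "CNI")
})

test_that("subtype cross-tabulation routes by level count", {
  set.seed(309)
  calls <- data.frame(sample_id = sprintf("S%03d", 1:279),
                      score = 0, posterior = 0.5,
                      label = rep(c("YA", "YI"), c(105, 174)))
  hpv <- setNames(rep(c("positive", "negative", "positive", "negative"),
                      c(1, 104, 35, 139)), calls$sample_id)
  xt <- crosstab_subtype(calls, hpv)
  expect_identical(xt$test, "fisher")
  expect_equal(xt$p_value, fisher_exact_2x2(matrix(c(1, 35, 104, 139), 2))$p_value,
               tolerance = 1e-12)

  four <- setNames(sample(c("atypical", "classical", "mesenchymal", "basal"),
                          279, TRUE), calls$sample_id)
  xt4 <- crosstab_subtype(calls, four)
  expect_identical(xt4$test, "chisq")
  expect_true(xt4$p_value >= 0 && xt4$p_value <= 1)
  expect_error(crosstab_subtype(calls, setNames(rep("x", 279), calls$sample_id)),
               "two")
})

test_that("a concentrated multi-level label is detected against subtype", {
  set.seed(310)
  n <- 400
  calls <- data.frame(sample_id = sprintf("S%03d", 1:n), score = 0,
                      posterior = 0.5, label = rep(c("YA", "YI"), each = n / 2))
  lab <- ifelse(calls$label == "YA",
                sample(c("basal", "atypical", "classical", "mesenchymal"),
                       n, TRUE, prob = c(0.6, 0.14, 0.13, 0.13)),
                sample(c("basal", "atypical", "classical", "mesenchymal"),
                       n, TRUE))
  xt <- crosstab_subtype(calls, setNames(lab, calls$sample_id))
  expect_lt(xt$p_value, 0.01)
})

test_that("the interferon-gamma score is the mean of available panel genes", {
  ids <- paste0("S", 1:3)
  m <- matrix(0, 6, 3, dimnames = list(ifng_genes(), ids))
  m[, 2] <- 2.5
  attr(m, "standardized") <- TRUE
  sc <- ifng_score(m)
  expect_equal(as.numeric(sc), c(0, 2.5, 0))

  m5 <- m[1:5, ]
  attr(m5, "standardized") <- TRUE
  expect_length(ifng_score(m5), 3)
  m4 <- m[1:4, ]
  attr(m4, "standardized") <- TRUE
  expect_error(ifng_score(m4), "missing")
})

test_that("activation depresses the interferon score and its correlation", {
  sim <- simulate_cohort(sim_config(n_tumors = 400, n_genes = 200,
                                    n_signature_genes = 40, seed = 311))
  calls <- truth_calls(sim$truth)
  sc <- ifng_score(sim$cohort)
  a <- ifng_association(sc, calls)
  expect_lt(a$t_p_value, 0.01)
  expect_lt(a$mean_ya, a$mean_yi)
  expect_lt(a$cor_r, 0)
})
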