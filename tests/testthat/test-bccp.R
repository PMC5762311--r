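# build a minimal fitted model with prescribed score-model parameters,
# bypassing fitting, to probe the posterior rule directly
manual_model <- function(mu_a, mu_i, sigma, weights = c(G1 = 1),
                         priors = c(0.5, 0.5)) {
  x <- matrix(0, length(weights), 4,
              dimnames = list(names(weights), paste0("S", 1:4)))
  attr(x, "standardized") <- TRUE
  cls <- factor(rep(c("active", "inactive"), 2),
                levels = c("active", "inactive"))
  names(cls) <- colnames(x)
  structure(list(genes = names(weights), weights = weights,
                 mu_a = mu_a, mu_i = mu_i, sigma = sigma,
                 priors = stats::setNames(priors, c("active", "inactive")),
                 training = list(x = x, classes = cls,
                                 scores = stats::setNames(rep(0, 4), colnames(x))),
                 coverage_floor = 0.5),
            class = "bccp")
}

score_matrix <- function(s) {
  m <- matrix(s, 1, length(s),
              dimnames = list("G1", sprintf("S%04d", seq_along(s))))
  attr(m, "standardized") <- TRUE
  m
}

test_that("training classes follow the amplification threshold", {
  cn <- matrix(c(2L, 1L, 0L, -1L, 2L), 1, 5,
               dimnames = list("YAP1", paste0("S", 1:5)))
  expect_error(training_classes(cn), "fewer than 3")
  cn6 <- cbind(cn, matrix(c(2L, 0L), 1, 2, dimnames = list("YAP1", c("S6", "S7"))))
  cls <- training_classes(cn6)
  expect_identical(as.character(cls[1:5]),
                   c("active", "inactive", "inactive", "inactive", "active"))
  cn0 <- matrix(0L, 1, 6, dimnames = list("YAP1", paste0("S", 1:6)))
  expect_error(training_classes(cn0), "active class empty")
})

test_that("training class sizes track the amplification fraction", {
  sim <- simulate_cohort(sim_config(n_tumors = 500, n_genes = 100,
                                    n_signature_genes = 20,
                                    amp_fraction = 0.1, seed = 71))
  cls <- training_classes(sim$cohort)
  env <- qbinom(c(0.005, 0.995), 500, 0.1)
  expect_gte(sum(cls == "active"), env[1])
  expect_lte(sum(cls == "active"), env[2])
})

test_that("fitted weights and score model match a direct computation", {
  set.seed(101)
  x <- standardize_genes(rand_matrix(20, 30))
  cls <- balanced_classes(x, 12)
  fit <- bccp(x, cls)
  a <- cls == "active"
  for (g in rownames(x)) {
    tt <- t.test(x[g, a], x[g, !a], var.equal = TRUE)
    expect_equal(unname(fit$weights[g]), unname(tt$statistic), tolerance = 1e-10)
  }
  s <- as.vector(crossprod(x, fit$weights))
  mu_a <- mean(s[a]); mu_i <- mean(s[!a])
  sigma <- sqrt((sum((s[a] - mu_a)^2) + sum((s[!a] - mu_i)^2)) / (30 - 2))
  expect_equal(fit$mu_a, mu_a, tolerance = 1e-10)
  expect_equal(fit$mu_i, mu_i, tolerance = 1e-10)
  expect_equal(fit$sigma, sigma, tolerance = 1e-10)
})

test_that("a positively shifted active class gives positive weights", {
  set.seed(102)
  x <- rand_matrix(1, 20)
  x[, 1:10] <- x[, 1:10] + 1
  x <- standardize_genes(x)
  fit <- bccp(x, balanced_classes(x, 10))
  expect_gt(fit$weights[1], 0)
  expect_gt(fit$mu_a, fit$mu_i)
})

test_that("label swap negates the model and complements posteriors", {
  set.seed(103)
  x <- standardize_genes(rand_matrix(15, 24))
  cls <- balanced_classes(x, 10)
  swapped <- factor(ifelse(cls == "active", "inactive", "active"),
                    levels = c("active", "inactive"))
  names(swapped) <- names(cls)
  f1 <- bccp(x, cls)
  f2 <- bccp(x, swapped)
  expect_equal(unname(f2$weights), unname(-f1$weights), tolerance = 1e-10)
  expect_equal(f2$mu_a, -f1$mu_i, tolerance = 1e-10)
  expect_equal(f2$mu_i, -f1$mu_a, tolerance = 1e-10)
  p1 <- predict(f1, x)$posterior
  p2 <- predict(f2, x)$posterior
  expect_equal(p2, 1 - p1, tolerance = 1e-10)
})

test_that("the Gaussian posterior matches its closed form", {
  m <- manual_model(mu_a = 1, mu_i = -1, sigma = 1)
  p <- predict(m, score_matrix(0.5))$posterior
  expect_equal(p, 1 / (1 + exp(-2 * 0.5)), tolerance = 1e-12)

  # midpoint: exactly 0.5, labelled YI by the strict > 0.5 rule
  mid <- predict(m, score_matrix(0))
  expect_equal(mid$posterior, 0.5, tolerance = 1e-12)
  expect_identical(mid$label, "YI")

  # 10-sigma separation limit
  m10 <- manual_model(mu_a = 5, mu_i = -5, sigma = 1)
  expect_gt(predict(m10, score_matrix(5))$posterior, 1 - 1e-10)
})

test_that("label equals the midpoint rule and posteriors normalize", {
  set.seed(104)
  for (i in 1:25) {
    mu_i <- rnorm(1); mu_a <- mu_i + rexp(1) + 0.1
    sigma <- rexp(1) + 0.2
    s <- rnorm(1, (mu_a + mu_i) / 2, 3 * sigma)
    m <- manual_model(mu_a, mu_i, sigma)
    call <- predict(m, score_matrix(s))
    expect_identical(call$label, if (s > (mu_a + mu_i) / 2) "YA" else "YI")
    m_sw <- manual_model(mu_i, mu_a, sigma)  # complementary class model
    expect_equal(call$posterior + predict(m_sw, score_matrix(s))$posterior, 1,
                 tolerance = 1e-12)
  }
})

test_that("rescaling all weights leaves posteriors unchanged", {
  set.seed(105)
  x <- standardize_genes(rand_matrix(12, 26))
  cls <- balanced_classes(x, 11)
  fit <- bccp(x, cls)
  p0 <- predict(fit, x)$posterior
  for (c_ in c(0.1, 3, 42)) {
    scaled <- fit
    scaled$weights <- fit$weights * c_
    scaled$mu_a <- fit$mu_a * c_
    scaled$mu_i <- fit$mu_i * c_
    scaled$sigma <- fit$sigma * c_
    expect_equal(predict(scaled, x)$posterior, p0, tolerance = 1e-9)
  }
})

test_that("prediction on a reduced platform refits the score Gaussians", {
  set.seed(106)
  x <- rand_matrix(40, 30)
  x[1:10, 1:12] <- x[1:10, 1:12] + 2
  x <- standardize_genes(x)
  cls <- balanced_classes(x, 12)
  fit <- bccp(x, cls)
  sub_genes <- rownames(x)[1:24]
  x_sub <- x[sub_genes, ]
  attr(x_sub, "standardized") <- TRUE
  calls <- predict(fit, x_sub)
  expect_equal(attr(calls, "coverage"), 0.6)
  # refit parameters equal a direct reduced-score computation
  w <- fit$weights[sub_genes]
  s_tr <- as.vector(crossprod(x[sub_genes, ], w))
  a <- cls == "active"
  mu_a <- mean(s_tr[a]); mu_i <- mean(s_tr[!a])
  sigma <- sqrt((sum((s_tr[a] - mu_a)^2) + sum((s_tr[!a] - mu_i)^2)) / (30 - 2))
  s_new <- as.vector(crossprod(x_sub, w))
  p_direct <- 0.5 * dnorm(s_new, mu_a, sigma) /
    (0.5 * dnorm(s_new, mu_a, sigma) + 0.5 * dnorm(s_new, mu_i, sigma))
  expect_equal(calls$posterior, p_direct, tolerance = 1e-10)
  # below the coverage floor prediction refuses
  x_tiny <- x[rownames(x)[1:10], ]
  attr(x_tiny, "standardized") <- TRUE
  expect_error(predict(fit, x_tiny), "coverage")
})

test_that("leave-one-out matches a brute-force fold enumeration", {
  set.seed(107)
  x <- rand_matrix(4, 6)
  x[, 1:3] <- x[, 1:3] + 1.5
  x <- standardize_genes(x)
  cls <- balanced_classes(x, 3)
  rate <- bccp_loocv(x, cls)
  # independent fold-by-fold oracle using t.test and explicit densities
  wrong <- 0
  for (j in 1:6) {
    xt <- x[, -j, drop = FALSE]
    ct <- cls[-j]
    w <- sapply(rownames(xt), function(g) {
      t.test(xt[g, ct == "active"], xt[g, ct == "inactive"],
             var.equal = TRUE)$statistic
    })
    st <- as.vector(t(xt) %*% w)
    mu_a <- mean(st[ct == "active"]); mu_i <- mean(st[ct == "inactive"])
    sg <- sqrt((sum((st[ct == "active"] - mu_a)^2) +
                  sum((st[ct == "inactive"] - mu_i)^2)) / (5 - 2))
    s_j <- sum(w * x[, j])
    p_j <- dnorm(s_j, mu_a, sg) / (dnorm(s_j, mu_a, sg) + dnorm(s_j, mu_i, sg))
    pred <- if (p_j > 0.5) "active" else "inactive"
    if (pred != as.character(cls[j])) wrong <- wrong + 1
  }
  expect_equal(as.numeric(rate), wrong / 6, tolerance = 1e-12)
})

test_that("leave-one-out is 0 under 10-sigma class separation", {
  set.seed(108)
  x <- rand_matrix(10, 40)
  x[, 1:20] <- x[, 1:20] + 10
  x <- standardize_genes(x)
  expect_equal(as.numeric(bccp_loocv(x, balanced_classes(x, 20))), 0)
})

test_that("folds that would empty a class are skipped with a warning", {
  set.seed(109)
  x <- standardize_genes(rand_matrix(5, 8))
  cls <- factor(rep(c("active", "inactive"), c(2, 6)),
                levels = c("active", "inactive"))
  names(cls) <- colnames(x)
  w <- capture_warnings(rate <- bccp_loocv(x, cls))
  expect_true(all(grepl("skipped", w)))
  expect_length(w, 2)          # both active-class folds collapse the class
  expect_identical(attr(rate, "n_folds"), 6L)
})

test_that("subtype assignment recovers latent activation on strong effects", {
  sim <- simulate_cohort(sim_config(n_tumors = 300, n_genes = 500,
                                    n_signature_genes = 100, seed = 110))
  cls <- training_classes(sim$cohort)
  expr <- standardize_genes(sim$cohort$expression)
  fit <- bccp(expr, cls, genes = sim$truth$true_signature)
  calls <- assign_subtypes(sim$cohort, fit)
  agree <- mean((calls$label == "YA") ==
                  (sim$truth$activation[calls$sample_id] == 1))
  expect_gte(agree, 0.9)
  expect_equal(attr(calls, "pct_ya"), 100 * mean(calls$label == "YA"))
})

test_that("two-class one-vs-rest reduces to the binary classifier", {
  set.seed(111)
  x <- rand_matrix(10, 30)
  x[, 1:14] <- x[, 1:14] + 1
  x <- standardize_genes(x)
  cls <- balanced_classes(x, 14)
  bin <- predict(bccp(x, cls), x)
  mc <- bccp_multiclass(x, cls)
  expect_identical(mc$label == "active", bin$label == "YA")
  expect_equal(mc$p_active, bin$posterior, tolerance = 1e-10)
})

test_that("well-separated multi-class labels are recovered", {
  set.seed(112)
  k <- 4; n_per <- 15; g <- 40
  lab <- factor(rep(paste0("K", 1:k), each = n_per))
  x <- matrix(rnorm(g * k * n_per), g, k * n_per,
              dimnames = list(sprintf("G%02d", 1:g),
                              sprintf("S%03d", 1:(k * n_per))))
  for (i in 1:k) {   # each class elevates its own block of 10 genes
    x[((i - 1) * 10 + 1):(i * 10), lab == paste0("K", i)] <-
      x[((i - 1) * 10 + 1):(i * 10), lab == paste0("K", i)] + 3
  }
  x <- standardize_genes(x)
  names(lab) <- colnames(x)
  mc <- bccp_multiclass(x, lab)
  expect_gte(mean(mc$label == as.character(lab)), 0.95)
})

test_that("multi-class ties go to the first declared class", {
  set.seed(113)
  x <- standardize_genes(rand_matrix(6, 12))
  lab <- factor(rep(c("A", "B"), 6), levels = c("A", "B"))
  names(lab) <- colnames(x)
  mc <- bccp_multiclass(x, lab)
  post <- as.matrix(mc[, c("p_A", "p_B")])
  tied <- abs(post[, 1] - post[, 2]) < 1e-15
  if (any(tied)) expect_true(all(mc$label[tied] == "A"))
  expect_identical(mc$label, ifelse(post[, 1] >= post[, 2], "A", "B"))
})

test_that("model serialization round-trips predictions", {
  set.seed(114)
  x <- rand_matrix(15, 20)
  x[, 1:8] <- x[, 1:8] + 1
  x <- standardize_genes(x)
  fit <- bccp(x, balanced_classes(x, 8))
  f <- withr::local_tempfile(fileext = ".txt")
  write_bccp(fit, f)
  fit2 <- read_bccp(f)
  expect_equal(fit2$weights, fit$weights, tolerance = 1e-12)
  expect_equal(predict(fit2, x)$posterior, predict(fit, x)$posterior,
               tolerance = 1e-12)
  # reduced-platform refit still works after the round trip
  x_sub <- x[rownames(x)[1:9], ]
  attr(x_sub, "standardized") <- TRUE
  expect_equal(predict(fit2, x_sub)$posterior, predict(fit, x_sub)$posterior,
               tolerance = 1e-12)
})

test_that("accessor methods are coherent with the fit", {
  set.seed(115)
  x <- rand_matrix(8, 20)
  x[, 1:10] <- x[, 1:10] + 2
  x <- standardize_genes(x)
  cls <- balanced_classes(x, 10)
  fit <- bccp(x, cls)
  expect_identical(coef(fit), fit$weights)
  r <- residuals(fit)
  expect_equal(unname(r[cls == "active"]),
               1 - predict(fit, x)$posterior[cls == "active"],
               tolerance = 1e-12)
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sims, 2)
  expect_identical(nrow(sims[[1]]), 20L)
  sm <- summary(fit)
  expect_gte(sm$training_agreement, 0.9)
})

test_that("degenerate fits are rejected", {
  x <- matrix(rep(c(0, 0), each = 8), 1, 16,
              dimnames = list("G1", paste0("S", 1:16)))
  attr(x, "standardized") <- TRUE
  cls <- balanced_classes(x, 8)
  expect_error(bccp(x, cls), "variance|degenerate")
  set.seed(116)
  xr <- standardize_genes(rand_matrix(3, 10))
  expect_error(bccp(xr, balanced_classes(xr, 2)), "at least 3")
  expect_error(bccp(unclass(xr)[, ], balanced_classes(xr, 5)), "standardized")
})
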