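#' Define training classes from the driver's copy number
#'
#' Tumors with a driver GISTIC score at or above `threshold` (high-level
#' amplification) form the active training class; all others are inactive.
#'
#' @param x A [cohort()] bundle with a copy-number layer, or a GISTIC matrix.
#' @param driver Driver gene symbol.
#' @param threshold GISTIC level defining amplification (default 2).
#' @return Named factor with levels `active`, `inactive`.
#' @export
training_classes <- function(x, driver = "YAP1", threshold = 2) {
  cn <- if (inherits(x, "cohort")) x$cn else x
  if (is.null(cn)) stop("no copy-number layer")
  driver <- toupper(driver)
  if (!driver %in% rownames(cn)) stop("driver '", driver, "' absent from copy-number layer")
  lab <- ifelse(cn[driver, ] >= threshold, "active", "inactive")
  cls <- factor(lab, levels = c("active", "inactive"))
  names(cls) <- colnames(cn)
  counts <- table(cls)
  for (lv in names(counts)) {
    if (counts[[lv]] == 0L) stop(lv, " class empty")
    if (counts[[lv]] < 3L) {
      stop(lv, " class has fewer than 3 samples; t-statistics unstable")
    }
  }
  cls
}

# pooled-variance two-sample t-statistics per row (active minus inactive)
row_tstats <- function(x, is_a) {
  na <- sum(is_a); ni <- sum(!is_a)
  ma <- rowMeans(x[, is_a, drop = FALSE])
  mi <- rowMeans(x[, !is_a, drop = FALSE])
  ssa <- rowSums((x[, is_a, drop = FALSE] - ma)^2)
  ssi <- rowSums((x[, !is_a, drop = FALSE] - mi)^2)
  sp <- sqrt((ssa + ssi) / (na + ni - 2))
  (ma - mi) / (sp * sqrt(1 / na + 1 / ni))
}

.score_params <- function(scores, is_a) {
  na <- sum(is_a); ni <- sum(!is_a)
  mu_a <- mean(scores[is_a]); mu_i <- mean(scores[!is_a])
  sigma <- sqrt((sum((scores[is_a] - mu_a)^2) + sum((scores[!is_a] - mu_i)^2)) /
                  (na + ni - 2))
  list(mu_a = mu_a, mu_i = mu_i, sigma = sigma)
}

#' Fit a Bayesian compound covariate predictor
#'
#' The compound covariate score of sample j is `s_j = sum_g w_g x_gj` over
#' the signature genes, with weights `w_g` the pooled-variance two-sample
#' t-statistics (active minus inactive) from the training classes. Training
#' scores are modelled as equal-variance Gaussians per class (class means
#' `mu_A`, `mu_I`; pooled within-class SD `sigma` on n-2 df) with priors
#' `pi_A`, `pi_I`, yielding the posterior probability of activation
#' `P(active | s) = pi_A phi(s; mu_A, sigma) / [pi_A phi(s; mu_A, sigma) +
#' pi_I phi(s; mu_I, sigma)]`.
#'
#' The fitted object retains the training expression over the signature
#' genes: compound scores scale with the number of genes, so when a test
#' platform covers only a subset of the signature the score-distribution
#' parameters are refit on the stored training data under the reduced gene
#' set before prediction.
#'
#' @param x Standardized expression matrix (genes x samples); see
#'   [standardize_genes()].
#' @param classes Named factor from [training_classes()] (levels `active`,
#'   `inactive`) covering the columns of `x`.
#' @param genes Signature gene symbols; defaults to all rows of `x`.
#' @param priors Class priors `c(active, inactive)`; must sum to 1.
#' @param coverage_floor Minimum signature coverage accepted at prediction.
#' @return Object of class `bccp` with elements `genes`, `weights`, `mu_a`,
#'   `mu_i`, `sigma`, `priors`, `training` (expression, classes, scores),
#'   `coverage_floor`.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(20 * 30), 20, 30,
#'             dimnames = list(sprintf("G%02d", 1:20), sprintf("S%02d", 1:30)))
#' x[, 1:10] <- x[, 1:10] + 1
#' x <- standardize_genes(x)
#' cls <- factor(rep(c("active", "inactive"), c(10, 20)),
#'               levels = c("active", "inactive"))
#' names(cls) <- colnames(x)
#' fit <- bccp(x, cls)
#' predict(fit)
#' @export
bccp <- function(x, classes, genes = rownames(x), priors = c(0.5, 0.5),
                 coverage_floor = 0.5) {
  if (!is_standardized(x)) {
    stop("expression must be standardized per cohort before fitting (standardize_genes)")
  }
  if (abs(sum(priors) - 1) > 1e-8) stop("priors must sum to 1")
  classes <- classes[colnames(x)]
  if (anyNA(classes)) stop("classes missing for some samples")
  genes <- intersect(toupper(genes), rownames(x))
  if (!length(genes)) stop("no signature genes present in the matrix")
  xs <- x[genes, , drop = FALSE]
  attr(xs, "standardized") <- TRUE
  is_a <- classes == "active"
  if (sum(is_a) < 3L || sum(!is_a) < 3L) stop("each class needs at least 3 samples")
  w <- row_tstats(xs, is_a)
  scores <- as.vector(crossprod(xs, w))
  names(scores) <- colnames(xs)
  pars <- .score_params(scores, is_a)
  if (!is.finite(pars$sigma) || pars$sigma <= 0) {
    stop("zero pooled score variance; classes are degenerate")
  }
  structure(list(genes = genes, weights = stats::setNames(w, genes),
                 mu_a = pars$mu_a, mu_i = pars$mu_i, sigma = pars$sigma,
                 priors = stats::setNames(priors, c("active", "inactive")),
                 training = list(x = xs, classes = classes, scores = scores),
                 coverage_floor = coverage_floor),
            class = "bccp")
}

# posterior P(active | s) under the two-Gaussian score model, computed on
# the log scale for numerical stability far from the decision boundary
.posterior <- function(s, mu_a, mu_i, sigma, priors) {
  la <- log(priors[[1L]]) + stats::dnorm(s, mu_a, sigma, log = TRUE)
  li <- log(priors[[2L]]) + stats::dnorm(s, mu_i, sigma, log = TRUE)
  1 / (1 + exp(li - la))
}

#' Posterior activation probabilities for new samples
#'
#' Computes compound scores and Gaussian posteriors for the columns of
#' `newdata` (default: the training samples). A sample is labelled `YA`
#' strictly when its posterior exceeds 0.5, `YI` otherwise (a posterior of
#' exactly 0.5 is `YI`). When `newdata` covers only a strict subset of the
#' model's genes (at least `coverage_floor` of them), the reduced-gene score
#' distribution is refit on the stored training expression first.
#'
#' @param object A fitted [bccp()] model.
#' @param newdata Standardized expression matrix or [cohort()] bundle.
#' @param ... Unused.
#' @return A data.frame of class `bccp_calls`: `sample_id`, `score`,
#'   `posterior`, `label` (`YA`/`YI`).
#' @export
predict.bccp <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$training$x
  if (inherits(newdata, "cohort")) newdata <- newdata$expression
  if (!is_standardized(newdata)) {
    stop("newdata must be standardized within its own cohort")
  }
  cov <- match_signature_genes(newdata, object$genes,
                               floor = object$coverage_floor)
  genes <- cov$genes
  w <- object$weights[genes]
  mu_a <- object$mu_a; mu_i <- object$mu_i; sigma <- object$sigma
  if (length(genes) < length(object$genes)) {
    tr_scores <- as.vector(crossprod(object$training$x[genes, , drop = FALSE], w))
    pars <- .score_params(tr_scores, object$training$classes == "active")
    if (!is.finite(pars$sigma) || pars$sigma <= 0) {
      stop("zero pooled score variance under the reduced gene set")
    }
    mu_a <- pars$mu_a; mu_i <- pars$mu_i; sigma <- pars$sigma
  }
  s <- as.vector(crossprod(newdata[genes, , drop = FALSE], w))
  p <- .posterior(s, mu_a, mu_i, sigma, object$priors)
  out <- data.frame(sample_id = colnames(newdata), score = s, posterior = p,
                    label = ifelse(p > 0.5, "YA", "YI"),
                    stringsAsFactors = FALSE)
  attr(out, "coverage") <- cov$coverage
  class(out) <- c("bccp_calls", "data.frame")
  out
}

#' @export
print.bccp <- function(x, ...) {
  cat("Bayesian compound covariate predictor\n")
  cat("  genes:", length(x$genes),
      " training:", sum(x$training$classes == "active"), "active /",
      sum(x$training$classes == "inactive"), "inactive\n")
  cat(sprintf("  score model: mu_A = %.3f, mu_I = %.3f, sigma = %.3f; priors %.2f/%.2f\n",
              x$mu_a, x$mu_i, x$sigma, x$priors[1L], x$priors[2L]))
  invisible(x)
}

#' @export
coef.bccp <- function(object, ...) object$weights

#' @export
summary.bccp <- function(object, ...) {
  calls <- predict(object)
  cls <- object$training$classes
  out <- list(model = object, calls = calls,
              training_agreement = mean((calls$label == "YA") == (cls == "active")),
              loocv = NULL)
  class(out) <- "summary.bccp"
  out
}

#' @export
print.summary.bccp <- function(x, ...) {
  print(x$model)
  cat(sprintf("  training-set agreement with copy-number classes: %.1f%%\n",
              100 * x$training_agreement))
  cat(sprintf("  training calls: %d YA (%.1f%%) of %d\n",
              sum(x$calls$label == "YA"),
              100 * mean(x$calls$label == "YA"), nrow(x$calls)))
  invisible(x)
}

#' @export
residuals.bccp <- function(object, ...) {
  calls <- predict(object)
  ind <- as.numeric(object$training$classes[calls$sample_id] == "active")
  stats::setNames(ind - calls$posterior, calls$sample_id)
}

#' @export
plot.bccp <- function(x, ...) {
  s <- x$training$scores
  cls <- x$training$classes
  graphics::hist(s, breaks = 30, freq = FALSE, col = "grey90",
                 main = "Compound covariate scores",
                 xlab = "score", ...)
  xx <- seq(min(s), max(s), length.out = 200)
  graphics::lines(xx, x$priors[1L] * stats::dnorm(xx, x$mu_a, x$sigma), col = 2)
  graphics::lines(xx, x$priors[2L] * stats::dnorm(xx, x$mu_i, x$sigma), col = 4)
  graphics::rug(s[cls == "active"], col = 2)
  graphics::rug(s[cls == "inactive"], col = 4)
  invisible(x)
}

#' Simulate scores and labels from a fitted score model
#'
#' Draws samples from the fitted two-Gaussian mixture: a latent class from
#' the priors, then a score from that class's Gaussian.
#'
#' @param object A fitted [bccp()] model.
#' @param nsim Number of replicate data sets.
#' @param seed Optional seed.
#' @param n Samples per replicate (default: training size).
#' @param ... Unused.
#' @return List of data.frames with `score` and `class`.
#' @export
simulate.bccp <- function(object, nsim = 1, seed = NULL,
                          n = length(object$training$scores), ...) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nsim), function(i) {
    cls <- sample(c("active", "inactive"), n, TRUE, prob = object$priors)
    mu <- ifelse(cls == "active", object$mu_a, object$mu_i)
    data.frame(score = stats::rnorm(n, mu, object$sigma), class = cls,
               stringsAsFactors = FALSE)
  })
}

#' Leave-one-out cross-validated misclassification rate
#'
#' For each training sample, the gene weights and the score-distribution
#' Gaussians are refit on the remaining n-1 samples (gene list held fixed,
#' as the signature is derived once on the full training cohort) and the
#' held-out sample is classified; the rate is the fraction misclassified
#' against the copy-number training classes. Folds that would empty a class
#' are skipped with a warning.
#'
#' @param x Standardized expression matrix.
#' @param classes Named factor (`active`/`inactive`) over columns of `x`.
#' @param genes Signature gene symbols.
#' @param priors Class priors.
#' @return Misclassification rate in `[0, 1]`, with attributes `n_folds`
#'   (evaluated folds) and `misclassified` (sample IDs).
#' @export
bccp_loocv <- function(x, classes, genes = rownames(x), priors = c(0.5, 0.5)) {
  classes <- classes[colnames(x)]
  genes <- intersect(toupper(genes), rownames(x))
  xs <- x[genes, , drop = FALSE]
  n <- ncol(xs)
  wrong <- character(0)
  folds <- 0L
  for (j in seq_len(n)) {
    cls_j <- classes[-j]
    if (min(table(cls_j)) < 2L) {
      warning("fold ", j, " skipped: a class would be empty or singleton")
      next
    }
    is_a <- cls_j == "active"
    xt <- xs[, -j, drop = FALSE]
    w <- row_tstats(xt, is_a)
    scores <- as.vector(crossprod(xt, w))
    pars <- .score_params(scores, is_a)
    if (!is.finite(pars$sigma) || pars$sigma <= 0) {
      warning("fold ", j, " skipped: degenerate score variance")
      next
    }
    s_j <- sum(w * xs[, j])
    p_j <- .posterior(s_j, pars$mu_a, pars$mu_i, pars$sigma, priors)
    call_j <- if (p_j > 0.5) "active" else "inactive"
    folds <- folds + 1L
    if (call_j != as.character(classes[j])) wrong <- c(wrong, colnames(xs)[j])
  }
  rate <- length(wrong) / folds
  attr(rate, "n_folds") <- folds
  attr(rate, "misclassified") <- wrong
  rate
}

#' Classify a cohort into activated / inactivated subtypes
#'
#' Standardizes the cohort's expression if necessary, checks signature
#' coverage, and returns per-sample posterior calls with a cohort summary.
#'
#' @param cohort A [cohort()] bundle.
#' @param model A fitted [bccp()] model.
#' @return A `bccp_calls` data.frame with attributes `cohort`, `n`,
#'   `pct_ya`, `coverage`.
#' @export
assign_subtypes <- function(cohort, model) {
  expr <- cohort$expression
  if (!is_standardized(expr)) expr <- standardize_genes(expr)
  calls <- predict(model, expr)
  attr(calls, "cohort") <- cohort$name
  attr(calls, "n") <- nrow(calls)
  attr(calls, "pct_ya") <- 100 * mean(calls$label == "YA")
  calls
}

#' @export
print.bccp_calls <- function(x, ...) {
  n <- nrow(x)
  nya <- sum(x$label == "YA")
  if (!is.null(attr(x, "cohort"))) cat("Cohort:", attr(x, "cohort"), "\n")
  cat(sprintf("%d of %d samples classified YA (%.1f%%)\n", nya, n, 100 * nya / n))
  if (!is.null(attr(x, "coverage"))) {
    cat(sprintf("signature coverage: %.3f\n", attr(x, "coverage")))
  }
  NextMethod()
}

#' One-vs-rest multi-class compound covariate classification
#'
#' Fits one binary compound covariate model per class (that class against
#' the rest); per-class posteriors are computed independently on each
#' class's score axis and the label is the class with the largest posterior,
#' ties broken by the declared class order (the factor levels).
#'
#' @param x Standardized expression matrix.
#' @param labels Named factor with K >= 2 levels over columns of `x`; every
#'   class needs at least 3 samples.
#' @param genes Predictor gene symbols.
#' @param priors Per-model binary priors `c(class, rest)`.
#' @return A data.frame: `sample_id`, one posterior column per class
#'   (`p_<class>`), and `label`; the fitted per-class models are attached as
#'   attribute `models`.
#' @export
bccp_multiclass <- function(x, labels, genes = rownames(x),
                            priors = c(0.5, 0.5)) {
  labels <- labels[colnames(x)]
  labels <- droplevels(as.factor(labels))
  lv <- levels(labels)
  if (length(lv) < 2L) stop("need at least two classes")
  if (any(table(labels) < 3L)) stop("every class needs at least 3 samples")
  models <- lapply(lv, function(k) {
    cls <- factor(ifelse(labels == k, "active", "inactive"),
                  levels = c("active", "inactive"))
    names(cls) <- names(labels)
    bccp(x, cls, genes = genes, priors = priors)
  })
  names(models) <- lv
  post <- vapply(models, function(m) predict(m, x)$posterior,
                 numeric(ncol(x)))
  if (is.null(dim(post))) post <- matrix(post, 1L, dimnames = list(NULL, lv))
  lab <- lv[apply(post, 1L, which.max)]   # which.max: first max wins ties
  out <- data.frame(sample_id = colnames(x), post, label = lab,
                    stringsAsFactors = FALSE, check.names = FALSE)
  names(out)[1L + seq_along(lv)] <- paste0("p_", lv)
  attr(out, "models") <- models
  out
}

#' Serialize / restore a fitted compound covariate model as structured text
#'
#' One `gene <tab> weight` line per gene plus a parameter block; the stored
#' training expression and classes are included so reduced-gene refits
#' survive a round trip.
#'
#' @param object A fitted [bccp()] model.
#' @param path Output path.
#' @export
write_bccp <- function(object, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# bccp model", con)
  writeLines(sprintf("param\tmu_a\t%.17g", object$mu_a), con)
  writeLines(sprintf("param\tmu_i\t%.17g", object$mu_i), con)
  writeLines(sprintf("param\tsigma\t%.17g", object$sigma), con)
  writeLines(sprintf("param\tprior_active\t%.17g", object$priors[1L]), con)
  writeLines(sprintf("param\tcoverage_floor\t%.17g", object$coverage_floor), con)
  writeLines(sprintf("weight\t%s\t%.17g", object$genes, object$weights), con)
  cls <- object$training$classes
  writeLines(sprintf("class\t%s\t%s", names(cls), as.character(cls)), con)
  xt <- object$training$x
  writeLines(sprintf("train\t%s\t%s", rownames(xt),
                     apply(xt, 1L, function(v) paste(sprintf("%.17g", v), collapse = ","))),
             con)
  writeLines(paste0("samples\t", paste(colnames(xt), collapse = "\t")), con)
  invisible(path)
}

#' @rdname write_bccp
#' @export
read_bccp <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  f <- strsplit(lines, "\t", fixed = TRUE)
  tag <- vapply(f, `[[`, "", 1L)
  par <- f[tag == "param"]
  pv <- stats::setNames(as.numeric(vapply(par, `[[`, "", 3L)),
                        vapply(par, `[[`, "", 2L))
  wf <- f[tag == "weight"]
  w <- stats::setNames(as.numeric(vapply(wf, `[[`, "", 3L)),
                       vapply(wf, `[[`, "", 2L))
  cf <- f[tag == "class"]
  cls <- factor(vapply(cf, `[[`, "", 3L), levels = c("active", "inactive"))
  names(cls) <- vapply(cf, `[[`, "", 2L)
  samples <- f[[which(tag == "samples")]][-1L]
  tf <- f[tag == "train"]
  xt <- t(vapply(tf, function(r) as.numeric(strsplit(r[[3L]], ",")[[1L]]),
                 numeric(length(samples))))
  dimnames(xt) <- list(vapply(tf, `[[`, "", 2L), samples)
  attr(xt, "standardized") <- TRUE
  scores <- as.vector(crossprod(xt, w))
  names(scores) <- samples
  structure(list(genes = names(w), weights = w,
                 mu_a = pv[["mu_a"]], mu_i = pv[["mu_i"]], sigma = pv[["sigma"]],
                 priors = stats::setNames(c(pv[["prior_active"]],
                                            1 - pv[["prior_active"]]),
                                          c("active", "inactive")),
                 training = list(x = xt, classes = cls, scores = scores),
                 coverage_floor = pv[["coverage_floor"]]),
            class = "bccp")
}
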