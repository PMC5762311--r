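#' Two-sided Fisher's exact test on a 2x2 table
#'
#' The two-sided p-value is the sum of hypergeometric probabilities, over
#' all tables with the observed margins, whose point probability does not
#' exceed that of the observed table (with the customary 1e-7 relative
#' tolerance for ties); this is the rule [stats::fisher.test()] implements
#' and it is used here. The odds ratio is reported as the cross-product
#' ratio `(a*d)/(b*c)` (not the conditional MLE); a `0/0` cross product is
#' reported as `NA`.
#'
#' @param tab 2x2 matrix (or something coercible) of non-negative integer
#'   counts with positive margins.
#' @return List with `odds_ratio` and `p_value`.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("need a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("counts must be non-negative integers")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero margin in contingency table")
  }
  p <- stats::fisher.test(tab)$p.value
  num <- tab[1, 1] * tab[2, 2]
  den <- tab[1, 2] * tab[2, 1]
  or <- if (num == 0 && den == 0) NA_real_ else num / den
  list(odds_ratio = or, p_value = min(p, 1))
}

# shared screen core: per-feature 2x2 Fisher tests of a binary event
# against YA/YI calls
.fisher_screen <- function(event_mat, is_ya, feature_label = "feature") {
  res <- lapply(rownames(event_mat), function(f) {
    ev <- event_mat[f, ] > 0
    a <- sum(ev & is_ya); b <- sum(!ev & is_ya)
    c_ <- sum(ev & !is_ya); d <- sum(!ev & !is_ya)
    tab <- matrix(c(a, c_, b, d), 2L)
    ft <- if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      list(odds_ratio = NA_real_, p_value = 1)
    } else fisher_exact_2x2(tab)
    data.frame(feature = f, n_ya_event = a, n_ya = a + b,
               n_yi_event = c_, n_yi = c_ + d,
               pct_ya = 100 * a / (a + b), pct_yi = 100 * c_ / (c_ + d),
               odds_ratio = ft$odds_ratio, p_value = ft$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  names(out)[1L] <- feature_label
  out$q_value <- stats::p.adjust(out$p_value, "BH")  # informational only
  out[order(out$p_value), , drop = FALSE]
}

.check_calls <- function(calls, samples) {
  shared <- intersect(samples, calls$sample_id)
  if (!length(shared)) stop("no samples overlap between layer and subtype calls")
  shared
}

#' Per-gene copy-number event screens between subtypes
#'
#' For every gene, cross-tabulates subtype (YA/YI) against two event
#' definitions with Fisher's exact test: amplification counts high-level
#' events only (GISTIC >= 2), deletion counts all loss events
#' (GISTIC <= -1).
#'
#' @param cohort A [cohort()] bundle with a copy-number layer.
#' @param calls Subtype calls ([assign_subtypes()] output).
#' @return List of two data.frames (`amplification`, `deletion`), each
#'   sorted by p-value with per-group event percentages, cross-product odds
#'   ratios and informational BH q-values.
#' @export
compare_cn_events <- function(cohort, calls) {
  if (is.null(cohort$cn)) stop("cohort has no copy-number layer")
  shared <- .check_calls(calls, colnames(cohort$cn))
  cn <- cohort$cn[, shared, drop = FALSE]
  is_ya <- calls$label[match(shared, calls$sample_id)] == "YA"
  list(amplification = .fisher_screen((cn >= 2) + 0L, is_ya, "gene"),
       deletion = .fisher_screen((cn <= -1) + 0L, is_ya, "gene"))
}

#' Per-gene mutation frequency screen between subtypes
#'
#' @param cohort A [cohort()] bundle with a mutation layer.
#' @param calls Subtype calls.
#' @param genes Gene panel (e.g. the recurrently mutated genes of the
#'   disease); defaults to all genes in the mutation matrix. Panel genes
#'   absent from the matrix are skipped with a warning.
#' @return Data.frame sorted by Fisher p with per-group mutation
#'   percentages.
#' @export
compare_mutations <- function(cohort, calls, genes = NULL) {
  if (is.null(cohort$mutations)) stop("cohort has no mutation layer")
  mut <- cohort$mutations
  if (!is.null(genes)) {
    genes <- toupper(genes)
    miss <- setdiff(genes, rownames(mut))
    if (length(miss)) {
      warning("panel genes absent from mutation matrix, skipped: ",
              paste(miss, collapse = ", "))
    }
    mut <- mut[intersect(genes, rownames(mut)), , drop = FALSE]
    if (!nrow(mut)) stop("no panel genes present in the mutation matrix")
  }
  shared <- .check_calls(calls, colnames(mut))
  is_ya <- calls$label[match(shared, calls$sample_id)] == "YA"
  .fisher_screen(mut[, shared, drop = FALSE], is_ya, "gene")
}

# vectorized pooled-variance two-sample t-test per row
.row_ttest <- function(m, is_a) {
  na <- sum(is_a); nb <- sum(!is_a)
  ma <- rowMeans(m[, is_a, drop = FALSE])
  mb <- rowMeans(m[, !is_a, drop = FALSE])
  ssa <- rowSums((m[, is_a, drop = FALSE] - ma)^2)
  ssb <- rowSums((m[, !is_a, drop = FALSE] - mb)^2)
  sp <- sqrt((ssa + ssb) / (na + nb - 2))
  se <- sp * sqrt(1 / na + 1 / nb)
  t <- ifelse(se > 0, (ma - mb) / se, 0)
  p <- 2 * stats::pt(abs(t), na + nb - 2, lower.tail = FALSE)
  p[se == 0 & ma != mb] <- 0
  data.frame(mean_a = ma, mean_b = mb, t = t, p = p)
}

#' Differential miRNA expression between subtypes
#'
#' Pooled-variance two-sample t-test per miRNA on log2 values (tumor samples
#' only), with fold change `2^(mean_YA - mean_YI)`. A miRNA passes when
#' `p < p_max` and the fold change is at least `fc_min` in either direction
#' (`FC >= fc_min` or `FC <= 1/fc_min`); the two-sided fold rule reflects
#' that subtype-associated miRNAs run in both directions.
#'
#' @param cohort A [cohort()] bundle with a miRNA layer.
#' @param calls Subtype calls.
#' @param fc_min Fold-change threshold (default 2).
#' @param p_max P-value threshold (default 0.001).
#' @return Data.frame: `mirna`, `mean_ya`, `mean_yi`, `fc`, `t`, `p_value`,
#'   `q_value` (informational), `passes`; sorted by p.
#' @export
differential_mirna <- function(cohort, calls, fc_min = 2, p_max = 0.001) {
  if (is.null(cohort$mirna)) stop("cohort has no miRNA layer")
  tum <- names(cohort$mirna_class)[cohort$mirna_class == "tumor"]
  shared <- .check_calls(calls, tum)
  m <- cohort$mirna[, shared, drop = FALSE]
  is_ya <- calls$label[match(shared, calls$sample_id)] == "YA"
  if (sum(is_ya) < 3L || sum(!is_ya) < 3L) {
    stop("fewer than 3 samples in a subtype group")
  }
  tt <- .row_ttest(m, is_ya)
  fc <- 2^(tt$mean_a - tt$mean_b)
  out <- data.frame(mirna = rownames(m), mean_ya = tt$mean_a,
                    mean_yi = tt$mean_b, fc = fc, t = tt$t, p_value = tt$p,
                    q_value = stats::p.adjust(tt$p, "BH"),
                    passes = tt$p < p_max & (fc >= fc_min | fc <= 1 / fc_min),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$p_value), ]
}

#' Staged screen for copy-number-independent activation miRNAs
#'
#' Partitions activated tumors into copy-number-dependent (driver GISTIC >=
#' `threshold`) and copy-number-independent (CNI) activation, then screens in
#' stages: (1) miRNAs differing between CNI and CND activated tumors (fold
#' ratio > `fr_min` in either direction, p < `p1`); (2) of those, miRNAs
#' differing between CNI tumors and normal tissue (p < `p2`); (3) the final
#' list keeps stage-2 miRNAs whose CNI mean exceeds both the inactivated
#' mean and the normal mean — candidates for a copy-number-independent
#' activation mechanism. The three lists are nested by construction.
#'
#' @param cohort A [cohort()] bundle with miRNA (including normals) and
#'   copy-number layers.
#' @param calls Subtype calls.
#' @param driver Driver gene symbol.
#' @param fr_min Stage-1 fold-ratio threshold (default 1.5).
#' @param p1,p2 Stage-1 / stage-2 p-value thresholds (0.01, 0.05).
#' @param threshold GISTIC amplification level (default 2).
#' @return List with `stage1`, `stage2`, `final` (data.frames of statistics)
#'   and `groups` (per-sample CND/CNI/YI partition).
#' @export
cni_mirna_screen <- function(cohort, calls, driver = "YAP1", fr_min = 1.5,
                             p1 = 0.01, p2 = 0.05, threshold = 2) {
  if (is.null(cohort$mirna)) stop("cohort has no miRNA layer")
  if (is.null(cohort$cn)) stop("cohort has no copy-number layer")
  driver <- toupper(driver)
  nrm <- names(cohort$mirna_class)[cohort$mirna_class == "normal"]
  if (!length(nrm)) stop("no normal samples in the miRNA layer")
  tum <- names(cohort$mirna_class)[cohort$mirna_class == "tumor"]
  shared <- intersect(.check_calls(calls, tum), colnames(cohort$cn))
  lab <- calls$label[match(shared, calls$sample_id)]
  amp <- cohort$cn[driver, shared] >= threshold
  grp <- ifelse(lab == "YA" & amp, "CND-YA",
         ifelse(lab == "YA", "CNI-YA", "YI"))
  names(grp) <- shared
  cni <- shared[grp == "CNI-YA"]; cnd <- shared[grp == "CND-YA"]
  yi <- shared[grp == "YI"]
  if (length(cni) < 3L) stop("empty or too-small CNI activation group")
  if (length(cnd) < 3L) stop("empty or too-small CND activation group")
  m <- cohort$mirna

  s1 <- .row_ttest(m[, c(cni, cnd), drop = FALSE],
                   c(rep(TRUE, length(cni)), rep(FALSE, length(cnd))))
  fr <- 2^(s1$mean_a - s1$mean_b)
  stage1 <- data.frame(mirna = rownames(m), mean_cni = s1$mean_a,
                       mean_cnd = s1$mean_b, fold_ratio = fr,
                       p_value = s1$p, stringsAsFactors = FALSE,
                       row.names = NULL)
  stage1 <- stage1[s1$p < p1 & (fr > fr_min | fr < 1 / fr_min), ]

  if (nrow(stage1)) {
    sub <- m[stage1$mirna, , drop = FALSE]
    s2 <- .row_ttest(sub[, c(cni, nrm), drop = FALSE],
                     c(rep(TRUE, length(cni)), rep(FALSE, length(nrm))))
    stage1$mean_normal <- s2$mean_b
    stage1$p_vs_normal <- s2$p
    stage2 <- stage1[s2$p < p2, , drop = FALSE]
  } else {
    stage1$mean_normal <- numeric(0); stage1$p_vs_normal <- numeric(0)
    stage2 <- stage1
  }

  if (nrow(stage2)) {
    mean_yi <- rowMeans(m[stage2$mirna, yi, drop = FALSE])
    stage2$mean_yi <- mean_yi
    final <- stage2[stage2$mean_cni > stage2$mean_yi &
                      stage2$mean_cni > stage2$mean_normal, , drop = FALSE]
  } else {
    stage2$mean_yi <- numeric(0)
    final <- stage2
  }
  list(stage1 = stage1, stage2 = stage2, final = final, groups = grp)
}

#' Cross-tabulate subtype calls against a categorical label
#'
#' Two-level labels route to Fisher's exact test; labels with more levels
#' use the chi-square test on the K x 2 table.
#'
#' @param calls Subtype calls.
#' @param labels Named vector (by sample id) or vector aligned with
#'   `calls$sample_id`; `NA` levels are dropped.
#' @return List with `table` (counts), `pct` (column percentages within
#'   subtype), `test` (`fisher` or `chisq`), `p_value`, and `odds_ratio`
#'   for the 2x2 case.
#' @export
crosstab_subtype <- function(calls, labels) {
  if (!is.null(names(labels))) labels <- labels[calls$sample_id]
  keep <- !is.na(labels)
  lab <- droplevels(as.factor(labels[keep]))
  sub <- factor(calls$label[keep], levels = c("YA", "YI"))
  if (nlevels(lab) < 2L) stop("label must have at least two observed levels")
  tab <- table(lab, sub)
  if (nlevels(lab) == 2L) {
    ft <- fisher_exact_2x2(tab)
    list(table = tab, pct = prop.table(tab, 2L) * 100, test = "fisher",
         p_value = ft$p_value, odds_ratio = ft$odds_ratio)
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab))
    list(table = tab, pct = prop.table(tab, 2L) * 100, test = "chisq",
         p_value = ct$p.value, odds_ratio = NA_real_)
  }
}

#' Interferon-gamma composite immune score
#'
#' Per-sample mean of the six interferon-gamma-related genes (CXCL9,
#' CXCL10, IDO1, IFNG, HLA-DRA, STAT1) on per-cohort standardized
#' expression. At least five of the six genes must be measured; the score
#' is the mean over those available.
#'
#' @param cohort A [cohort()] bundle (expression is standardized in place
#'   if it is not yet).
#' @return Named numeric vector of scores with attribute `genes_used`.
#' @export
ifng_score <- function(cohort) {
  expr <- if (inherits(cohort, "cohort")) cohort$expression else cohort
  if (!is_standardized(expr)) expr <- standardize_genes(expr)
  genes <- ifng_genes()
  present <- intersect(genes, rownames(expr))
  if (length(present) < 5L) {
    stop("interferon-gamma score needs at least 5 of the 6 genes; missing: ",
         paste(setdiff(genes, present), collapse = ", "))
  }
  sc <- colMeans(expr[present, , drop = FALSE])
  attr(sc, "genes_used") <- present
  sc
}

#' Association of the interferon-gamma score with activation
#'
#' Two-sample t-test of the score between the YA and YI groups and Pearson
#' correlation of the score with the posterior activation probability.
#'
#' @param scores Output of [ifng_score()].
#' @param calls Subtype calls.
#' @param var_equal Pooled-variance t-test (default TRUE).
#' @return List with `t_p_value`, `mean_ya`, `mean_yi`, `cor_r`,
#'   `cor_p_value`, `n`.
#' @export
ifng_association <- function(scores, calls, var_equal = TRUE) {
  shared <- intersect(names(scores), calls$sample_id)
  if (length(shared) < 6L) stop("too few samples shared between scores and calls")
  sc <- scores[shared]
  idx <- match(shared, calls$sample_id)
  is_ya <- calls$label[idx] == "YA"
  if (sum(is_ya) < 3L || sum(!is_ya) < 3L) stop("a subtype group is too small")
  tt <- stats::t.test(sc[is_ya], sc[!is_ya], var.equal = var_equal)
  ct <- stats::cor.test(sc, calls$posterior[idx])
  list(t_p_value = tt$p.value, mean_ya = mean(sc[is_ya]),
       mean_yi = mean(sc[!is_ya]), cor_r = unname(ct$estimate),
       cor_p_value = ct$p.value, n = length(shared))
}
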