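# Vectorized Pearson correlation of every matrix row against one vector,
# with two-sided p from the t distribution on n - 2 df. Constant rows get
# r = 0, p = 1.
row_cor <- function(m, v) {
  n <- length(v)
  if (n < 4L) stop("need at least 4 overlapping samples for the screen")
  vc <- v - mean(v)
  mc <- m - rowMeans(m)
  num <- as.vector(mc %*% vc)
  den <- sqrt(rowSums(mc^2) * sum(vc^2))
  r <- ifelse(den > 0, num / den, 0)
  r <- pmin(1, pmax(-1, r))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[abs(r) >= 1] <- 0
  p[den == 0] <- 1
  data.frame(r = r, p = p)
}

#' Genome-wide correlation of expression with a driver's copy number and mRNA
#'
#' For every gene in the cohort, computes the Pearson correlation (and
#' two-sided p-value from the t distribution with n-2 df) of its expression
#' with (a) the driver's thresholded GISTIC score treated as numeric and
#' (b) the driver's mRNA expression, over the samples shared between the
#' expression and copy-number layers. Pearson r is invariant to gene-wise
#' standardization, so the screen may be run on raw or standardized log2
#' values.
#'
#' @param cohort A [cohort()] bundle with expression and copy-number layers.
#' @param driver Driver gene symbol (must be present in both layers).
#' @return A data.frame with one row per gene: `gene`, `r_cn`, `p_cn`,
#'   `r_mrna`, `p_mrna`.
#' @export
driver_correlations <- function(cohort, driver = "YAP1") {
  if (is.null(cohort$cn)) stop("cohort has no copy-number layer")
  driver <- toupper(driver)
  if (!driver %in% rownames(cohort$expression)) {
    stop("driver '", driver, "' absent from expression layer")
  }
  if (!driver %in% rownames(cohort$cn)) {
    stop("driver '", driver, "' absent from copy-number layer")
  }
  shared <- intersect(colnames(cohort$expression), colnames(cohort$cn))
  if (length(shared) < 4L) stop("need at least 4 overlapping samples")
  expr <- cohort$expression[, shared, drop = FALSE]
  cn_v <- as.numeric(cohort$cn[driver, shared])
  mrna_v <- as.numeric(expr[driver, ])
  cn_cor <- row_cor(expr, cn_v)
  mrna_cor <- row_cor(expr, mrna_v)
  data.frame(gene = rownames(expr),
             r_cn = cn_cor$r, p_cn = cn_cor$p,
             r_mrna = mrna_cor$r, p_mrna = mrna_cor$p,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Derive an activation signature from the dual correlation screen
#'
#' Selects copy-number-associated genes (`p_cn < p_max` and `|r_cn| > r_min`)
#' and mRNA-associated genes (same rule on the mRNA correlations) and
#' intersects the two lists. The driver itself trivially passes both screens
#' and is excluded: the signature is meant to capture its downstream targets.
#' No multiple-testing correction is applied; the raw-threshold rule is a
#' deliberate fidelity choice of the screen.
#'
#' @param records Output of [driver_correlations()].
#' @param p_max Maximum raw p-value (default 0.001).
#' @param r_min Exclusive absolute-correlation threshold (default 0.2).
#' @param driver Driver symbol to exclude from the signature.
#' @return Object of class `signature_result`: list with `cn_associated`,
#'   `mrna_associated`, `signature` (character vectors), `records`,
#'   `thresholds`.
#' @export
derive_signature <- function(records, p_max = 0.001, r_min = 0.2,
                             driver = "YAP1") {
  if (!nrow(records)) stop("no correlation records")
  cn_set <- records$gene[records$p_cn < p_max & abs(records$r_cn) > r_min]
  mrna_set <- records$gene[records$p_mrna < p_max & abs(records$r_mrna) > r_min]
  sig <- setdiff(intersect(cn_set, mrna_set), toupper(driver))
  if (!length(sig)) {
    warning("empty signature: no gene passes both screens at the thresholds")
  }
  structure(list(cn_associated = cn_set, mrna_associated = mrna_set,
                 signature = sig, records = records,
                 thresholds = c(p_max = p_max, r_min = r_min)),
            class = "signature_result")
}

#' @export
print.signature_result <- function(x, ...) {
  cat("Dual correlation screen (p <", x$thresholds["p_max"],
      ", |r| >", x$thresholds["r_min"], "):\n")
  cat("  copy-number-associated:", length(x$cn_associated), "genes\n")
  cat("  mRNA-associated:       ", length(x$mrna_associated), "genes\n")
  cat("  signature (intersection, driver excluded):",
      length(x$signature), "genes\n")
  invisible(x)
}

#' Write the derived signature and its parent sets as GMT
#'
#' @param x A `signature_result`.
#' @param path Output GMT path.
#' @export
write_signature <- function(x, path) {
  sets <- list(cn_associated = x$cn_associated,
               mrna_associated = x$mrna_associated,
               signature = x$signature)
  sets <- sets[lengths(sets) > 0]
  if (!length(sets)) stop("nothing to write: all sets empty")
  write_gmt(sets, path, description = "dual-correlation screen")
  invisible(path)
}
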