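#' Kaplan-Meier product-limit estimate
#'
#' Wraps [survival::survfit()] with Greenwood standard errors and exposes
#' the curve coordinates plus survival at a queried time (e.g. 60 months for
#' 5-year rates). Ties are handled by simultaneous decrement.
#'
#' @param time Follow-up times (months, non-negative).
#' @param event Event indicators (1 = event, 0 = censored).
#' @param at Optional time(s) at which to report survival.
#' @return Object of class `km_curve`: `time`, `n_risk`, `n_event`, `surv`,
#'   `std_err` (Greenwood SE of S), and `surv_at` (named vector) if `at`
#'   was given.
#' @export
km_estimate <- function(time, event, at = NULL) {
  if (!length(time)) stop("no records")
  if (any(time < 0, na.rm = TRUE)) stop("negative survival times")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, conf.type = "log")
  out <- list(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
              surv = fit$surv, std_err = fit$std.err * fit$surv)
  if (!is.null(at)) {
    out$surv_at <- stats::setNames(
      vapply(at, function(t0) {
        idx <- fit$time <= t0 & fit$n.event > 0
        if (!any(idx)) 1 else fit$surv[max(which(idx))]
      }, 0), paste0("t", at))
  }
  class(out) <- "km_curve"
  out
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve:", length(x$time), "time points,",
      sum(x$n_event), "events\n")
  if (!is.null(x$surv_at)) {
    cat("  S at queried times:",
        paste(names(x$surv_at), sprintf("%.3f", x$surv_at), sep = "=",
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
plot.km_curve <- function(x, ...) {
  graphics::plot(stats::stepfun(x$time, c(1, x$surv)), do.points = FALSE,
                 ylim = c(0, 1), xlab = "time (months)", ylab = "S(t)",
                 main = "Kaplan-Meier estimate", ...)
  invisible(x)
}

#' Log-rank test for survival differences between groups
#'
#' @param time,event Survival data as in [km_estimate()].
#' @param group Group labels (two or more levels).
#' @return List with `chisq`, `df`, `p_value`, `n` per group.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(droplevels(as.factor(group)))
  if (nlevels(group) < 2L) stop("need at least two non-empty groups")
  if (any(table(group) == 0L)) stop("a group has zero subjects")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- nlevels(group) - 1L
  list(chisq = sd$chisq, df = df,
       p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
       n = table(group))
}

#' Cox proportional hazards fits over a covariate battery
#'
#' Fits partial-likelihood Cox models (Efron tie correction) and reports,
#' per covariate, the hazard ratio with Wald 95% CI and p-value. Univariate
#' mode fits one covariate at a time; multivariate fits all jointly. When
#' several cohorts are pooled, the baseline hazard may be stratified by
#' cohort (platforms and follow-up differ between cohorts). An optional
#' horizon administratively censors follow-up (e.g. 60 months for 5-year
#' analyses).
#'
#' @param data Data.frame with `time`, `event`, and covariate columns
#'   (binary indicators coded 0/1 or two-level factors).
#' @param covariates Character vector of covariate column names.
#' @param multivariate Fit all covariates jointly?
#' @param strata Optional column name stratifying the baseline hazard.
#' @param horizon Optional administrative censoring time (months).
#' @return Data.frame of class `cox_result`: `covariate`, `hr`, `ci_low`,
#'   `ci_high`, `p_value`, `model`, `n`.
#' @export
cox_fit <- function(data, covariates, multivariate = FALSE, strata = NULL,
                    horizon = NULL) {
  if (!all(c("time", "event") %in% names(data))) {
    stop("data needs 'time' and 'event' columns")
  }
  if (sum(data$event, na.rm = TRUE) < 1) stop("no events in the data")
  if (!is.null(horizon)) {
    over <- !is.na(data$time) & data$time > horizon
    data$event[over] <- 0
    data$time[over] <- horizon
  }
  for (v in covariates) {
    if (length(unique(stats::na.omit(data[[v]]))) < 2L) {
      stop("covariate '", v, "' has no contrast")
    }
  }
  strata_term <- if (is.null(strata)) NULL else
    sprintf("strata(%s)", strata)
  fit_one <- function(vars, model_label) {
    rhs <- paste(c(vars, strata_term), collapse = " + ")
    fml <- stats::as.formula(paste("survival::Surv(time, event) ~", rhs))
    fit <- tryCatch(
      survival::coxph(fml, data = data, ties = "efron"),
      error = function(e) stop("Cox fit failed for '",
                               paste(vars, collapse = ", "), "': ",
                               conditionMessage(e)))
    if (any(!is.finite(stats::coef(fit))) ||
        any(!is.finite(diag(stats::vcov(fit))))) {
      stop("Cox fit did not converge (separation?) for '",
           paste(vars, collapse = ", "), "'")
    }
    sm <- summary(fit)
    keep <- !grepl("^strata", rownames(sm$coefficients))
    co <- sm$coefficients[keep, , drop = FALSE]
    ci <- sm$conf.int[keep, , drop = FALSE]
    data.frame(covariate = rownames(co), hr = ci[, "exp(coef)"],
               ci_low = ci[, "lower .95"], ci_high = ci[, "upper .95"],
               p_value = co[, "Pr(>|z|)"], model = model_label,
               n = sm$n, stringsAsFactors = FALSE, row.names = NULL)
  }
  out <- if (multivariate) fit_one(covariates, "multivariate") else
    do.call(rbind, lapply(covariates, fit_one, model_label = "univariate"))
  class(out) <- c("cox_result", "data.frame")
  out
}

#' @export
print.cox_result <- function(x, ...) {
  y <- x
  y$hr <- sprintf("%.2f (%.2f-%.2f)", x$hr, x$ci_low, x$ci_high)
  y$p_value <- signif(x$p_value, 2)
  print.data.frame(y[, c("covariate", "hr", "p_value", "model", "n")],
                   row.names = FALSE)
  invisible(x)
}

#' Radiation subgroup comparisons and the subtype-by-radiation interaction
#'
#' Runs log-rank tests for (1) activated vs inactivated among irradiated
#' patients, (2) radiation vs none within the activated group, (3) radiation
#' vs none within the inactivated group, and (4) activated vs inactivated
#' among non-irradiated patients; plus a Cox model with subtype, radiation
#' and their interaction, whose interaction hazard ratio and p-value are
#' reported. Empty strata skip their comparison with a warning.
#'
#' @param data Data.frame with `time`, `event`, `subtype` (`YA`/`YI`),
#'   `radiation` (`yes`/`no`).
#' @return List with `comparisons` (data.frame of log-rank p-values) and
#'   `interaction` (`hr`, `ci_low`, `ci_high`, `p_value`).
#' @export
radiation_subgroup <- function(data) {
  stopifnot(all(c("time", "event", "subtype", "radiation") %in% names(data)))
  data <- data[stats::complete.cases(data[, c("time", "event", "subtype", "radiation")]), ]
  specs <- list(
    ya_vs_yi_irradiated = list(sub = data$radiation == "yes", grp = "subtype"),
    radiation_within_ya = list(sub = data$subtype == "YA", grp = "radiation"),
    radiation_within_yi = list(sub = data$subtype == "YI", grp = "radiation"),
    ya_vs_yi_no_radiation = list(sub = data$radiation == "no", grp = "subtype"))
  rows <- lapply(names(specs), function(nm) {
    sp <- specs[[nm]]
    d <- data[sp$sub, , drop = FALSE]
    g <- droplevels(as.factor(d[[sp$grp]]))
    if (nrow(d) == 0L || nlevels(g) < 2L) {
      warning("comparison '", nm, "' skipped: empty stratum")
      return(data.frame(comparison = nm, n = nrow(d), chisq = NA_real_,
                        p_value = NA_real_))
    }
    lr <- logrank_test(d$time, d$event, g)
    data.frame(comparison = nm, n = nrow(d), chisq = lr$chisq,
               p_value = lr$p_value)
  })
  comparisons <- do.call(rbind, rows)
  if (length(unique(data$radiation)) < 2L || length(unique(data$subtype)) < 2L) {
    stop("interaction model needs variation in both subtype and radiation")
  }
  d <- data
  d$ya <- as.numeric(d$subtype == "YA")
  d$rad <- as.numeric(d$radiation == "yes")
  fit <- survival::coxph(survival::Surv(time, event) ~ ya * rad, data = d,
                         ties = "efron")
  sm <- summary(fit)
  ix <- grep(":", rownames(sm$coefficients))
  interaction <- list(hr = sm$conf.int[ix, "exp(coef)"],
                      ci_low = sm$conf.int[ix, "lower .95"],
                      ci_high = sm$conf.int[ix, "upper .95"],
                      p_value = sm$coefficients[ix, "Pr(>|z|)"])
  list(comparisons = comparisons, interaction = interaction)
}

#' Join subtype calls onto a clinical table for survival analysis
#'
#' @param clinical Clinical data.frame with `sample_id`, `os_time`,
#'   `os_event` (or `dfs_*` with `endpoint = "dfs"`).
#' @param calls A `bccp_calls` data.frame.
#' @param endpoint `"os"` or `"dfs"`.
#' @return Data.frame with `time`, `event`, `subtype` plus clinical columns.
#' @export
survival_records <- function(clinical, calls, endpoint = c("os", "dfs")) {
  endpoint <- match.arg(endpoint)
  tcol <- paste0(endpoint, "_time"); ecol <- paste0(endpoint, "_event")
  m <- merge(clinical, calls[, c("sample_id", "posterior", "label")],
             by = "sample_id")
  out <- data.frame(m, time = m[[tcol]], event = m[[ecol]],
                    subtype = m$label, stringsAsFactors = FALSE)
  out[!is.na(out$time) & !is.na(out$event), ]
}
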