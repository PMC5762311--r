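#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory containing `expression.tsv`, `clinical.tsv` and
#'   optionally `gistic.tsv`, `mutations.tsv`, `mirna.tsv`,
#'   `mirna_classes.tsv`.
#' @param name Cohort name (default: directory basename).
#' @param id_prefix Barcode truncation passed to [cohort()].
#' @return A [cohort()] bundle.
#' @export
read_cohort <- function(dir, name = basename(dir), id_prefix = NULL) {
  pth <- function(f) file.path(dir, f)
  has <- function(f) file.exists(pth(f))
  if (!has("expression.tsv") || !has("clinical.tsv")) {
    stop("cohort directory needs expression.tsv and clinical.tsv: ", dir)
  }
  expr <- read_expression(pth("expression.tsv"))
  clinical <- read_clinical(pth("clinical.tsv"))
  cn <- if (has("gistic.tsv")) read_gistic(pth("gistic.tsv"))
  mut <- if (has("mutations.tsv")) {
    m <- read_expression(pth("mutations.tsv"))
    storage.mode(m) <- "integer"
    m
  }
  mirna <- NULL; mirna_class <- NULL
  if (has("mirna.tsv")) {
    mirna <- as.matrix(utils::read.delim(pth("mirna.tsv"), row.names = 1L,
                                         check.names = FALSE))
    if (has("mirna_classes.tsv")) {
      mc <- utils::read.delim(pth("mirna_classes.tsv"), stringsAsFactors = FALSE)
      mirna_class <- stats::setNames(mc$class, mc$sample_id)
    }
  }
  cohort(name = name, expression = expr, clinical = clinical, cn = cn,
         mutations = mut, mirna = mirna, mirna_class = mirna_class,
         id_prefix = id_prefix)
}

.load_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a YAML path or a list")
  defaults <- list(driver = "YAP1",
                   thresholds = list(p_max = 0.001, r_min = 0.2,
                                     gistic_amp = 2, prob_cutoff = 0.5,
                                     coverage_floor = 0.5))
  config <- utils::modifyList(defaults, config)
  if (is.null(config$seed)) stop("config field 'seed' is required")
  if (is.null(config$simulation) && is.null(config$cohorts)) {
    stop("config needs either a 'simulation' block or 'cohorts' paths")
  }
  config
}

.pipeline_cohorts <- function(config, outdir) {
  if (!is.null(config$simulation)) {
    dirs <- file.path(outdir, "cohorts",
                      vapply(config$simulation$cohorts, `[[`, "", "name"))
    if (!all(dir.exists(dirs))) {
      stop("missing simulated cohorts; run the 'simulate' subcommand first")
    }
    lapply(dirs, read_cohort)
  } else {
    lapply(config$cohorts, function(cc) {
      read_cohort(cc$path, name = cc$name,
                  id_prefix = cc$id_prefix)
    })
  }
}

#' Run the analysis pipeline
#'
#' Subcommand-driven orchestration over a YAML (or list) configuration.
#' `simulate` generates the configured synthetic cohorts; `derive-signature`
#' runs the dual correlation screen on the first (training) cohort; `fit`
#' builds copy-number training classes and fits the compound covariate
#' model; `classify` applies the model to every cohort; `survival` compares
#' the resulting subtypes by Kaplan-Meier/log-rank per cohort; `associate`
#' runs the copy-number, mutation, miRNA and HPV screens; `ifng` computes
#' the interferon-gamma composite score association; `full` runs everything
#' in order. Artifacts are written under `outdir` only, the resolved
#' configuration is echoed next to them, and identical config + seed yields
#' identical outputs.
#'
#' @param command One of `simulate`, `derive-signature`, `fit`, `classify`,
#'   `survival`, `associate`, `ifng`, `full`.
#' @param config YAML file path or config list. Required fields: `seed`,
#'   and either a `simulation` block (`cohorts`: list of [sim_config()]
#'   argument lists) or `cohorts` (list of `name`/`path` entries). Optional:
#'   `driver`, `thresholds` (`p_max`, `r_min`, `gistic_amp`, `prob_cutoff`,
#'   `coverage_floor`).
#' @param outdir Output directory (default: `config$outdir`).
#' @param seed Overrides `config$seed`.
#' @return Invisibly, a list of the artifacts the command produced.
#' @export
run_pipeline <- function(command = c("full", "simulate", "derive-signature",
                                     "fit", "classify", "survival",
                                     "associate", "ifng"),
                         config, outdir = NULL, seed = NULL) {
  command <- match.arg(command)
  config <- .load_pipeline_config(config)
  if (!is.null(seed)) config$seed <- seed
  if (is.null(outdir)) outdir <- config$outdir
  if (is.null(outdir)) stop("an output directory is required")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(config, file.path(outdir, "resolved_config.yaml"))
  th <- config$thresholds
  artifacts <- list()

  stage_simulate <- function() {
    specs <- config$simulation$cohorts
    if (is.null(specs)) stop("no simulation block in config")
    sims <- lapply(seq_along(specs), function(i) {
      args <- specs[[i]]
      if (is.null(args$seed)) args$seed <- config$seed + i - 1L
      do.call(sim_config, args)
    })
    if (length(sims) > 1L) {
      out <- simulate_multi_cohort(sims)
    } else {
      out <- stats::setNames(list(simulate_cohort(sims[[1L]])), sims[[1L]]$name)
    }
    for (nm in names(out)) {
      write_cohort(out[[nm]], file.path(outdir, "cohorts", nm))
    }
    out
  }

  stage_signature <- function(cohorts) {
    train <- cohorts[[1L]]
    rec <- driver_correlations(train, config$driver)
    sig <- derive_signature(rec, p_max = th$p_max, r_min = th$r_min,
                            driver = config$driver)
    utils::write.table(rec, file.path(outdir, "correlation_records.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_signature(sig, file.path(outdir, "signature.gmt"))
    sig
  }

  stage_fit <- function(cohorts) {
    gmt <- file.path(outdir, "signature.gmt")
    if (!file.exists(gmt)) {
      stop("missing signature artifact; run the 'derive-signature' subcommand first")
    }
    sig <- read_gmt(gmt)[["signature"]]
    train <- cohorts[[1L]]
    cls <- training_classes(train, config$driver, threshold = th$gistic_amp)
    expr <- standardize_genes(train$expression)
    model <- bccp(expr, cls, genes = sig,
                  coverage_floor = th$coverage_floor)
    write_bccp(model, file.path(outdir, "bccp_model.txt"))
    model
  }

  stage_classify <- function(cohorts) {
    mf <- file.path(outdir, "bccp_model.txt")
    if (!file.exists(mf)) {
      stop("missing model artifact; run the 'fit' subcommand first")
    }
    model <- read_bccp(mf)
    calls <- lapply(cohorts, assign_subtypes, model = model)
    names(calls) <- vapply(cohorts, `[[`, "", "name")
    for (nm in names(calls)) {
      utils::write.table(calls[[nm]],
                         file.path(outdir, sprintf("calls_%s.tsv", nm)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    calls
  }

  .read_calls <- function(cohorts) {
    files <- file.path(outdir, sprintf("calls_%s.tsv",
                                       vapply(cohorts, `[[`, "", "name")))
    if (!all(file.exists(files))) {
      stop("missing subtype calls; run the 'classify' subcommand first")
    }
    lapply(files, function(f) {
      d <- utils::read.delim(f, stringsAsFactors = FALSE)
      class(d) <- c("bccp_calls", "data.frame")
      d
    })
  }

  stage_survival <- function(cohorts) {
    calls <- .read_calls(cohorts)
    rows <- lapply(seq_along(cohorts), function(i) {
      rec <- survival_records(cohorts[[i]]$clinical, calls[[i]])
      if (!nrow(rec) || length(unique(rec$subtype)) < 2L) {
        return(data.frame(cohort = cohorts[[i]]$name, n = nrow(rec),
                          chisq = NA_real_, p_value = NA_real_))
      }
      lr <- logrank_test(rec$time, rec$event, rec$subtype)
      km <- lapply(split(rec, rec$subtype), function(d) {
        k <- km_estimate(d$time, d$event, at = 60)
        data.frame(subtype = d$subtype[1L], time = k$time, surv = k$surv)
      })
      utils::write.table(do.call(rbind, km),
                         file.path(outdir, sprintf("km_%s.tsv", cohorts[[i]]$name)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      data.frame(cohort = cohorts[[i]]$name, n = nrow(rec),
                 chisq = lr$chisq, p_value = lr$p_value)
    })
    res <- do.call(rbind, rows)
    utils::write.table(res, file.path(outdir, "survival_logrank.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res
  }

  stage_associate <- function(cohorts) {
    calls <- .read_calls(cohorts)
    train <- cohorts[[1L]]; cl <- calls[[1L]]
    out <- list()
    if (!is.null(train$cn)) {
      cne <- compare_cn_events(train, cl)
      utils::write.table(cne$amplification,
                         file.path(outdir, "cn_amplification.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(cne$deletion, file.path(outdir, "cn_deletion.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      out$cn <- cne
    }
    if (!is.null(train$mutations)) {
      mu <- compare_mutations(train, cl)
      utils::write.table(mu, file.path(outdir, "mutation_screen.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      out$mutations <- mu
    }
    if (!is.null(train$mirna)) {
      dm <- differential_mirna(train, cl)
      utils::write.table(dm, file.path(outdir, "mirna_differential.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      out$mirna <- dm
      if (!is.null(train$cn) && any(train$mirna_class == "normal")) {
        cni <- tryCatch(cni_mirna_screen(train, cl, config$driver),
                        error = function(e) NULL)
        if (!is.null(cni)) {
          utils::write.table(cni$stage2, file.path(outdir, "mirna_cni_stage2.tsv"),
                             sep = "\t", quote = FALSE, row.names = FALSE)
          writeLines(c(paste(c("cni_stage1", "na", cni$stage1$mirna), collapse = "\t"),
                       paste(c("cni_stage2", "na", cni$stage2$mirna), collapse = "\t"),
                       paste(c("cni_final", "na", cni$final$mirna), collapse = "\t")),
                     file.path(outdir, "mirna_cni_lists.gmt"))
          out$cni <- cni
        }
      }
    }
    if ("hpv_status" %in% names(train$clinical)) {
      hpv <- stats::setNames(train$clinical$hpv_status, train$clinical$sample_id)
      xt <- tryCatch(crosstab_subtype(cl, hpv), error = function(e) NULL)
      if (!is.null(xt)) {
        utils::write.table(data.frame(level = rownames(xt$table),
                                      as.data.frame.matrix(xt$table),
                                      p_value = xt$p_value),
                           file.path(outdir, "hpv_crosstab.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        out$hpv <- xt
      }
    }
    out
  }

  stage_ifng <- function(cohorts) {
    calls <- .read_calls(cohorts)
    res <- lapply(seq_along(cohorts), function(i) {
      sc <- tryCatch(ifng_score(cohorts[[i]]), error = function(e) NULL)
      if (is.null(sc)) return(NULL)
      a <- ifng_association(sc, calls[[i]])
      data.frame(cohort = cohorts[[i]]$name, t_p_value = a$t_p_value,
                 mean_ya = a$mean_ya, mean_yi = a$mean_yi,
                 cor_r = a$cor_r, cor_p_value = a$cor_p_value, n = a$n)
    })
    res <- do.call(rbind, res)
    if (!is.null(res)) {
      utils::write.table(res, file.path(outdir, "ifng_association.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    res
  }

  if (command %in% c("simulate", "full") && !is.null(config$simulation)) {
    artifacts$simulate <- stage_simulate()
  }
  if (command == "simulate") return(invisible(artifacts))
  cohorts <- .pipeline_cohorts(config, outdir)
  if (command %in% c("derive-signature", "full")) {
    artifacts$signature <- stage_signature(cohorts)
  }
  if (command %in% c("fit", "full")) artifacts$model <- stage_fit(cohorts)
  if (command %in% c("classify", "full")) {
    artifacts$calls <- stage_classify(cohorts)
  }
  if (command %in% c("survival", "full")) {
    artifacts$survival <- stage_survival(cohorts)
  }
  if (command %in% c("associate", "full")) {
    artifacts$association <- stage_associate(cohorts)
  }
  if (command %in% c("ifng", "full")) artifacts$ifng <- stage_ifng(cohorts)
  invisible(artifacts)
}
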