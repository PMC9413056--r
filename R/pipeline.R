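cohort_required_cols <- function(ef_times = 0:7) {
  c("age", "sex", "education", "apoe4", "hcv", "wbv", "wmh", "tiv",
    "abeta_ratio", "ptau_t0", "ptau_t1", "fdg_t0", "fdg_t2", "mem_t0",
    paste0("ef_t", ef_times))
}

#' Read a cohort table from delimited text
#'
#' Tab-separated wide format with a header row; empty cells and `"NA"` both
#' parse as missing.  Required columns are validated and non-numeric cells
#' in numeric columns are reported with their row and column.
#'
#' @param path file path.
#' @param required required column names (default the full cohort schema).
#' @return data frame of class `cohort_table`.
#' @export
read_cohort <- function(path, required = cohort_required_cols()) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           na.strings = c("", "NA"), quote = "",
                           comment.char = "")
  absent <- setdiff(required, names(raw))
  if (length(absent)) {
    stop("read_cohort: missing required column(s): ",
         paste(absent, collapse = ", "))
  }
  for (v in names(raw)) {
    col <- raw[[v]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(!is.na(col) & is.na(num))
    if (length(bad)) {
      stop(sprintf("read_cohort: non-numeric cell at row %d, column '%s'",
                   bad[1L], v))
    }
    raw[[v]] <- num
  }
  class(raw) <- c("cohort_table", "data.frame")
  raw
}

#' Write a cohort table as delimited text
#'
#' One row per subject, tab-separated, header row, empty cell for missing.
#'
#' @param table cohort table.
#' @param path output file path.
#' @export
write_cohort <- function(table, path) {
  utils::write.table(table, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

#' Pipeline configuration
#'
#' A single hierarchical configuration driving the end-to-end workflow.
#' Exactly one of `input` (path to a cohort file) or `simulation` (a list
#' with `config` and optional `truth` overrides for the generator) must be
#' given.
#'
#' @param input path to an existing cohort file, or `NULL`.
#' @param simulation list with elements passed to [cohort_config()] and
#'   [true_params()], or `NULL`.
#' @param decomposition list: `drop` predictors, `auto_zero_cov` flag.
#' @param mcmc list of [mcmc_config()] overrides.
#' @param effects list: `M` imputations, `B` bootstrap resamples, `w_grid`,
#'   `alpha`.
#' @param seed global seed; per-stage seeds are derived deterministically.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, simulation = NULL,
                            decomposition = list(), mcmc = list(),
                            effects = list(), seed = 1L) {
  if (is.null(input) == is.null(simulation)) {
    stop("pipeline_config: exactly one of input / simulation must be given")
  }
  decomposition <- utils::modifyList(
    list(drop = c("race", "ethnicity"), auto_zero_cov = TRUE), decomposition)
  effects <- utils::modifyList(
    list(M = 30L, B = 2000L, w_grid = c(-1, 0, 1), alpha = 0.05), effects)
  structure(list(input = input, simulation = simulation,
                 decomposition = decomposition, mcmc = mcmc,
                 effects = effects, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with top-level keys matching the
#'   [pipeline_config()] arguments.
#' @return list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y[intersect(names(y),
                                       names(formals(pipeline_config)))])
}

#' Run the full analysis pipeline
#'
#' Stages: simulate (or read) -> preprocess -> decompose -> impute plausible
#' values -> fit the moderated mediation per imputation with pooling ->
#' effects with bootstrap CIs -> report.  All numeric outputs are
#' reproducible bit-for-bit under a fixed configuration and seed.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if absent).
#' @param quiet suppress progress messages.
#' @return list of class `run_manifest` (also written to
#'   `manifest.yaml`): files, row counts, seeds, stage timings, and the
#'   in-memory stage results in `$results`.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config_seed = config$seed, files = list(),
                   counts = list(), timings = list())
  results <- list()
  say <- function(...) if (!quiet) message(...)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    manifest$timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    out
  }
  record <- function(key, path, n = NULL) {
    manifest$files[[key]] <<- basename(path)
    if (!is.null(n)) manifest$counts[[key]] <<- n
  }

  # --- simulate or read -----------------------------------------------
  table <- stage("input", {
    if (!is.null(config$simulation)) {
      sim <- config$simulation
      cfg_args <- sim$config %||% list()
      cfg_args$seed <- derive_seed(config$seed, 1L)
      cc <- do.call(cohort_config, cfg_args)
      tp <- do.call(true_params, sim$truth %||% list())
      tbl <- apply_missingness(generate_cohort(cc, tp), cc)
      path <- file.path(out_dir, "cohort.tsv")
      write_cohort(tbl, path)
      record("cohort", path, nrow(tbl))
      yaml::write_yaml(
        list(note = "synthetic ground truth used for this simulated run",
             truth = lapply(unclass(tp), function(z)
               if (is.matrix(z)) as.vector(z) else unname(z))),
        file.path(out_dir, "truth.yaml"))
      record("truth", file.path(out_dir, "truth.yaml"))
      results$cohort_config <- cc
      results$truth <- tp
      tbl
    } else {
      tbl <- read_cohort(config$input)
      record("cohort", config$input, nrow(tbl))
      tbl
    }
  })
  say(sprintf("cohort: %d subjects", nrow(table)))

  # --- preprocess -----------------------------------------------------
  table <- stage("preprocess", preprocess_cohort(table))
  results$table <- table

  # --- decomposition --------------------------------------------------
  dec <- stage("decompose", {
    dspec <- decomposition_spec(drop = config$decomposition$drop)
    if (isTRUE(config$decomposition$auto_zero_cov)) {
      zc <- auto_zero_cov(table, dspec)
      if (length(zc)) dspec <- decomposition_spec(
        drop = config$decomposition$drop, zero_cov = zc)
    }
    fit <- suppressWarnings(fit_decomposition_ml(table, dspec))
    path <- file.path(out_dir, "decomposition.tsv")
    utils::write.table(
      data.frame(term = names(fit$beta), estimate = fit$beta,
                 se = if (is.null(fit$se)) NA_real_ else
                   fit$se[seq_along(fit$beta)],
                 std = c(NA_real_, fit$std_beta)),
      path, sep = "\t", row.names = FALSE, quote = FALSE)
    record("decomposition", path, fit$n_used)
    scores <- factor_scores(fit, table)
    spath <- file.path(out_dir, "reserve_scores.tsv")
    utils::write.table(data.frame(id = table$id %||% seq_along(scores),
                                  memr_score = scores),
                       spath, sep = "\t", row.names = FALSE, quote = FALSE)
    record("scores", spath, sum(!is.na(scores)))
    fit
  })
  results$decomposition <- dec
  say(sprintf("decomposition: psi = %.3f (n = %d)", dec$psi_hat, dec$n_used))

  # --- plausible values -----------------------------------------------
  pv <- stage("impute", {
    margs <- utils::modifyList(list(seed = derive_seed(config$seed, 3L)),
                               config$mcmc)
    mc <- do.call(mcmc_config, margs)
    chains <- gibbs_decomposition(table, dec$spec, mc)
    pv <- draw_plausible_values(chains, M = config$effects$M)
    results$ppp <- ppp(chains, seed = derive_seed(config$seed, 4L))
    path <- file.path(out_dir, "plausible_values.tsv")
    utils::write.table(as.data.frame(pv$values), path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    record("plausible_values", path, nrow(pv$values))
    yaml::write_yaml(list(psrf = as.list(round(pv$psrf, 4)),
                          ppp = as.numeric(results$ppp),
                          icc2k = pv$icc$icc, icc_ci = pv$icc$ci,
                          theta_acceptance =
                            chains$chains[[1L]]$accept_theta),
                     file.path(out_dir, "mcmc_diagnostics.yaml"))
    record("mcmc_diagnostics", file.path(out_dir, "mcmc_diagnostics.yaml"))
    pv
  })
  results$plausible <- pv
  say(sprintf("plausible values: ICC(2,%d) = %.3f, max R-hat = %.3f",
              pv$M, pv$icc$icc, max(pv$psrf)))

  # --- mediation + effects --------------------------------------------
  mi <- stage("effects", {
    mspec <- mediation_spec(w = ".memr_pv")
    tbl <- table
    tbl$.memr_pv <- NA_real_
    mi <- run_mi_inference(pv, tbl, mspec,
                           w_grid = config$effects$w_grid,
                           B = config$effects$B,
                           alpha = config$effects$alpha,
                           seed = derive_seed(config$seed, 5L))
    cpath <- file.path(out_dir, "mediation_coefficients.tsv")
    utils::write.table(cbind(term = rownames(mi$pooled),
                             round(mi$pooled, 6)),
                       cpath, sep = "\t", row.names = FALSE, quote = FALSE)
    record("mediation_coefficients", cpath, mi$n_used)
    epath <- file.path(out_dir, "conditional_effects.tsv")
    utils::write.table(mi$effects, epath, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    record("conditional_effects", epath, nrow(mi$effects))
    if (!is.null(mi$boot_ci)) {
      bpath <- file.path(out_dir, "bootstrap_ci.tsv")
      utils::write.table(cbind(quantity = rownames(mi$boot_ci),
                               round(as.data.frame(mi$boot_ci), 6)),
                         bpath, sep = "\t", row.names = FALSE, quote = FALSE)
      record("bootstrap_ci", bpath, nrow(mi$boot_ci))
    }
    fi <- model_fit_indices(mi$fit_avg)
    yaml::write_yaml(list(chisq = fi$chisq, df = fi$df, rmsea = fi$rmsea,
                          rmsea_ci90 = fi$rmsea_ci90, cfi = fi$cfi,
                          tli = fi$tli, srmr = fi$srmr, n = fi$n_used),
                     file.path(out_dir, "mediation_fit_indices.yaml"))
    record("mediation_fit_indices",
           file.path(out_dir, "mediation_fit_indices.yaml"))
    results$mediation_fit_indices <- fi
    mi
  })
  results$mi <- mi
  say(sprintf("mediation: n = %d, IMM_AN(intercept) = %.3f",
              mi$n_used, mi$imm[["imm_an_intercept"]]))

  # --- report ---------------------------------------------------------
  manifest$results <- results
  class(manifest) <- "run_manifest"
  rep_lines <- stage("report", render_report(manifest))
  rpath <- file.path(out_dir, "report.txt")
  writeLines(rep_lines, rpath)
  manifest$files$report <- "report.txt"
  yaml::write_yaml(list(config_seed = manifest$config_seed,
                        files = manifest$files, counts = manifest$counts,
                        timings = manifest$timings),
                   file.path(out_dir, "manifest.yaml"))
  manifest$files$manifest <- "manifest.yaml"
  manifest
}

#' Render a human-readable report of a pipeline run
#'
#' Coefficient tables, fit indices, MCMC diagnostics and the
#' conditional-effect grid, as plain text lines.
#'
#' @param manifest a [run_pipeline()] manifest (with `$results`).
#' @return character vector of report lines.
#' @export
render_report <- function(manifest) {
  r <- manifest$results
  if (is.null(r)) stop("render_report: manifest has no stage results")
  ln <- character(0)
  add <- function(...) ln <<- c(ln, sprintf(...))
  add("Residual reserve and moderated sequential mediation: run report")
  add("================================================================")
  partial <- FALSE
  if (!is.null(r$decomposition)) {
    d <- r$decomposition
    add("")
    add("Memory decomposition (FIML), n = %d", d$n_used)
    add("  psi (reserve variance) = %.4f; theta (fixed error) = %.4f",
        d$psi_hat, d$theta)
    for (i in seq_along(d$beta)) {
      add("  %-14s %8.4f  (SE %.4f)", names(d$beta)[i], d$beta[i],
          if (is.null(d$se)) NA_real_ else d$se[i])
    }
    if (!is.null(d$fit)) {
      add("  fit: chisq(%d) = %.3f, RMSEA = %.3f, CFI = %.3f, TLI = %.3f, SRMR = %.3f",
          d$fit$df, d$fit$chisq, d$fit$rmsea, d$fit$cfi, d$fit$tli, d$srmr)
    }
  } else partial <- TRUE
  if (!is.null(r$plausible)) {
    add("")
    add("Plausible values: M = %d, ICC(2,%d) = %.3f (95%% CI %.3f-%.3f)",
        r$plausible$M, r$plausible$M, r$plausible$icc$icc,
        r$plausible$icc$ci[1], r$plausible$icc$ci[2])
    add("  max R-hat = %.3f; PPP = %.3f", max(r$plausible$psrf),
        as.numeric(r$ppp %||% NA))
  } else partial <- TRUE
  if (!is.null(r$mi)) {
    mi <- r$mi
    add("")
    add("Moderated sequential mediation, n analyzed = %d", mi$n_used)
    if (!is.null(r$mediation_fit_indices)) {
      fi <- r$mediation_fit_indices
      add("  fit: chisq(%d) = %.2f, RMSEA = %.3f (%.3f-%.3f), CFI = %.3f, TLI = %.3f, SRMR = %.3f",
          fi$df, fi$chisq, fi$rmsea, fi$rmsea_ci90[1], fi$rmsea_ci90[2],
          fi$cfi, fi$tli, fi$srmr)
    }
    add("  pooled coefficients (Rubin's rules, M = %d):", mi$M)
    for (i in seq_len(nrow(mi$pooled))) {
      add("  %-10s %8.4f  [%8.4f, %8.4f]", rownames(mi$pooled)[i],
          mi$pooled$qbar[i], mi$pooled$lower[i], mi$pooled$upper[i])
    }
    add("")
    add("Conditional effects over the moderator grid:")
    add("  %-9s %6s %8s %8s %8s %8s %8s", "outcome", "w", "direct",
        "B_AT", "B_ATN", "B_AN", "total")
    e <- mi$effects
    for (i in seq_len(nrow(e))) {
      add("  %-9s %6.2f %8.4f %8.4f %8.4f %8.4f %8.4f", e$outcome[i],
          e$w[i], e$direct[i], e$b_at[i], e$b_atn[i], e$b_an[i], e$total[i])
    }
    add("")
    add("Indices of moderated mediation (average plausible values):")
    for (nm in names(mi$imm)) add("  %-18s %8.4f", nm, mi$imm[[nm]])
    if (!is.null(mi$boot_ci)) {
      add("")
      add("Bias-corrected bootstrap 95%% CIs (B = %d):",
          nrow(attr(mi$boot_ci, "boot")))
      for (i in seq_len(nrow(mi$boot_ci))) {
        add("  %-28s %8.4f  [%8.4f, %8.4f]", rownames(mi$boot_ci)[i],
            mi$boot_ci[i, "estimate"], mi$boot_ci[i, "lower"],
            mi$boot_ci[i, "upper"])
      }
    }
  } else partial <- TRUE
  if (partial) {
    warning("render_report: some stage outputs are missing; partial report")
  }
  ln
}
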