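#' Validate a study configuration
#'
#' Schema and cross-field checks for the configuration consumed by
#' [run_study()]; never mutates state. A configuration must supply exactly
#' one of `synth` (synthetic-study parameters, see [synth_config()]) or
#' `events`/`actors` (paths to a real event log and actor table), plus a
#' `model` block (`effects`, `rates`, optionally `rate_outdegree`) and
#' optionally `estimation` (`n1`, `n2`, `n3`, `gof_nsim`) and `seed`.
#'
#' @param config A named list, or the path of a YAML file.
#' @return Character vector of problems (length 0 if the configuration is
#'   valid).
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  errs <- character()
  has_synth <- !is.null(config$synth)
  has_real <- !is.null(config$events) || !is.null(config$actors)
  if (has_synth && has_real)
    errs <- c(errs, "supply either 'synth' or 'events'+'actors', not both")
  if (!has_synth && !has_real)
    errs <- c(errs, "one of 'synth' or 'events'+'actors' is required")
  if (has_real && (is.null(config$events) || is.null(config$actors)))
    errs <- c(errs, "real-data input needs both 'events' and 'actors' paths")
  if (has_real && is.null(config$study_start))
    errs <- c(errs, "real-data input needs 'study_start'")
  if (is.null(config$model)) {
    errs <- c(errs, "missing field: model")
  } else {
    if (is.null(config$model$effects))
      errs <- c(errs, "missing field: model$effects")
    if (is.null(config$model$rates))
      errs <- c(errs, "missing field: model$rates")
  }
  errs
}

parse_model_block <- function(model, covariates) {
  effects <- lapply(model$effects, function(e) {
    if (is.character(e)) saom_effect(e) else
      saom_effect(e$name, covariate = e$covariate,
                  param = e$param %||% 0)
  })
  model_spec(effects, rates = as.numeric(model$rates),
             covariates = covariates,
             rate_outdegree = model$rate_outdegree)
}

#' Run the full study workflow
#'
#' Orchestrates the pipeline: synthesize (or ingest) the behavioural data,
#' build the weekly wave panel, compute descriptive summaries and tie
#' dynamics, derive weekly dominance ranks and their stability, fit the
#' actor-oriented model, and run convergence diagnostics, collinearity
#' screen, goodness of fit and the time-heterogeneity test. Artifacts are
#' written to `out_dir`: `summary.csv`, `changes.csv`, `ranks.csv`,
#' `fit.json`, `gof.json` and `run.log`.
#'
#' Available model covariates: `age` (constant), `sr` (constant mean weekly
#' dominance index), `entry` (changing; 1 in the week an animal entered),
#' `oestrus` (changing weekly indicator).
#'
#' @param config Configuration list or YAML path (see [validate_config()]).
#' @param out_dir Output directory.
#' @return The report bundle, invisibly: panel, summaries, ranks, fit, gof,
#'   heterogeneity test and artifact paths.
#' @export
run_study <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  errs <- validate_config(config)
  if (length(errs)) stop("invalid configuration:\n  ",
                         paste(errs, collapse = "\n  "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  logf <- file.path(out_dir, "run.log")
  say <- function(...) cat(sprintf(...), "\n", file = logf, append = TRUE,
                           sep = "")
  cat(sprintf("groomnet %s | seed %d | %s\n",
              as.character(utils::packageVersion("groomnet")), seed,
              format(Sys.time(), "%Y-%m-%d %H:%M:%S")), file = logf)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # ---- data ----------------------------------------------------------------
  if (!is.null(config$synth)) {
    study <- stage("synthesize", {
      sc <- do.call(synth_config, c(config$synth, list(seed = seed)))
      synthesize_study(sc)
    })
    actors <- study$actors
    groom <- study$grooming
    hb <- study$headbutts
    n_waves <- study$config$n_waves
    study_start <- study$study_start
    say("synthesized study: %d cows, %d waves", nrow(actors), n_waves)
  } else {
    study <- NULL
    study_start <- as.Date(config$study_start)
    actors <- stage("ingest", {
      df <- read.csv(config$actors, stringsAsFactors = FALSE)
      actor_table(df, config$n_waves %||%
                    max(as.integer(sub("oestrus_w", "",
                                       grep("^oestrus_w", names(df),
                                            value = TRUE))), 1))
    })
    n_waves <- attr(actors, "n_waves")
    log_all <- stage("ingest", read_event_log(config$events, study_start))
    groom <- log_all[log_all$behavior == "groom", , drop = FALSE]
    hb <- log_all[log_all$behavior == "headbutt", , drop = FALSE]
    say("ingested %d grooming and %d headbutt events",
        nrow(groom), nrow(hb))
  }

  # ---- networks & descriptives --------------------------------------------
  panel <- stage("networks", build_panel(groom, actors, n_waves))
  summ <- stage("descriptives", summarize_panel(panel, digits = 2))
  write.csv(summ$waves, file.path(out_dir, "summary.csv"), row.names = FALSE)
  if (!is.null(summ$changes))
    write.csv(summ$changes, file.path(out_dir, "changes.csv"),
              row.names = FALSE)
  say("panel: nodes %s; densities %s",
      paste(summ$waves$n_nodes, collapse = " "),
      paste(summ$waves$density, collapse = " "))

  # ---- dominance ranks -----------------------------------------------------
  ranks <- stage("ranks", rank_table(hb, actors, n_waves))
  write.csv(ranks, file.path(out_dir, "ranks.csv"), row.names = FALSE)
  stability <- tryCatch(di_stability(ranks), error = function(e) NULL)
  if (!is.null(stability))
    say("DI stability ICC(A,k) = %.3f (p = %.2g)", stability$icc,
        stability$p)

  # ---- model ---------------------------------------------------------------
  covs <- stage("covariates", {
    pm <- presence_matrix(actors)
    entry <- matrix(0, nrow(actors), n_waves,
                    dimnames = list(actors$actor_id, NULL))
    entry[cbind(seq_len(nrow(actors)), actors$entry_week)] <- 1
    oe <- as.matrix(actors[, paste0("oestrus_w", seq_len(n_waves))])
    rownames(oe) <- actors$actor_id
    sr <- tryCatch(social_rank_covariate(ranks), error = function(e) NULL)
    c(list(age = stats::setNames(actors$age, actors$actor_id),
           entry = entry, oestrus = oe),
      if (!is.null(sr)) list(sr = sr))
  })
  spec <- stage("model", parse_model_block(config$model, covs))
  est <- config$estimation %||% list()
  fit <- stage("fit", estimate_mom(
    panel, spec,
    n1 = est$n1 %||% 80,
    n2 = est$n2 %||% c(100, 200, 400, 800),
    n3 = est$n3 %||% 1000,
    seed = seed + 1L))
  say("fit %s: max|t| = %.3f, max convergence ratio = %.3f",
      if (fit$converged) "converged" else "NOT converged",
      max(abs(fit$t_ratios), na.rm = TRUE), fit$max_convergence_ratio)
  coll <- collinearity_check(fit)
  gof_res <- stage("gof", gof(fit, n_sim = est$gof_nsim %||% 200,
                              seed = seed + 2L))
  het <- if (n_waves >= 3)
    stage("heterogeneity", time_heterogeneity_test(fit)) else NULL

  fit_json <- list(
    estimates = as.list(fit$theta), se = as.list(fit$se),
    t_ratios = as.list(fit$t_ratios),
    max_convergence_ratio = fit$max_convergence_ratio,
    converged = fit$converged,
    collinearity_flags = coll$flags,
    heterogeneity = if (!is.null(het))
      het[c("chi2", "df", "p")],
    di_stability_icc = if (!is.null(stability))
      stability[c("icc", "p")],
    seed = seed, log = fit$log)
  jsonlite::write_json(fit_json, file.path(out_dir, "fit.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(
    list(p_values = as.list(gof_res$p_values),
         observed = lapply(gof_res$observed, as.list)),
    file.path(out_dir, "gof.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  say("artifacts written to %s", normalizePath(out_dir))

  invisible(list(panel = panel, summary = summ, ranks = ranks,
                 stability = stability, fit = fit, gof = gof_res,
                 heterogeneity = het, collinearity = coll,
                 study = study,
                 paths = file.path(out_dir, c("summary.csv", "changes.csv",
                                              "ranks.csv", "fit.json",
                                              "gof.json", "run.log"))))
}
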