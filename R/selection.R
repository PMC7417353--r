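#' Forward selection of model effects
#'
#' Starting from a fitted base specification, candidate effects are added
#' one at a time. A candidate is retained only if the enlarged model (i)
#' converges at the usual thresholds (all |t-ratios| < `t_max`, maximum
#' convergence ratio < `mcr_max`), (ii) the candidate is significant
#' (|estimate / SE| >= `z_min`), and (iii) no auxiliary goodness-of-fit
#' p-value falls below `gof_min`. Every decision is recorded in a ledger.
#'
#' @param panel A [wave_panel()].
#' @param base_spec A [model_spec()] that fits on its own.
#' @param candidates List of [saom_effect()] objects to try, in order.
#' @param t_max,mcr_max Convergence thresholds.
#' @param z_min Significance threshold on |estimate/SE|.
#' @param gof_min Minimum acceptable auxiliary GOF p-value (`NA` skips the
#'   GOF screen).
#' @param gof_nsim Simulations per GOF evaluation.
#' @param seed Integer seed.
#' @param ... Passed to [estimate_mom()] (e.g. `n3`).
#' @return List with the selected `spec`, the final `fit`, and a `ledger`
#'   data frame recording every candidate decision.
#' @export
forward_selection <- function(panel, base_spec, candidates,
                              t_max = 0.1, mcr_max = 0.25, z_min = 1.96,
                              gof_min = 0.05, gof_nsim = 200, seed = NULL,
                              ...) {
  if (!is.null(seed)) set.seed(seed)
  spec <- base_spec
  fit <- estimate_mom(panel, spec,
                      seed = sample.int(.Machine$integer.max, 1), ...)
  ledger <- data.frame(effect = character(), covariate = character(),
                       decision = character(), reason = character(),
                       estimate = numeric(), se = numeric())
  for (cand in candidates) {
    label <- paste0(cand$name,
                    if (is.null(cand$covariate)) "" else
                      paste0(".", cand$covariate))
    row <- data.frame(effect = cand$name,
                      covariate = cand$covariate %||% "",
                      decision = "rejected", reason = "",
                      estimate = NA_real_, se = NA_real_)
    trial_spec <- try(model_spec(c(spec$effects, list(cand)),
                                 rates = spec$rates,
                                 covariates = spec$covariates,
                                 rate_outdegree = spec$rate_outdegree),
                      silent = TRUE)
    if (inherits(trial_spec, "try-error")) {
      row$reason <- "invalid specification (duplicate or missing covariate)"
      ledger <- rbind(ledger, row)
      next
    }
    trial_fit <- try(estimate_mom(panel, trial_spec,
                                  seed = sample.int(.Machine$integer.max, 1),
                                  ...),
                     silent = TRUE)
    if (inherits(trial_fit, "try-error")) {
      row$reason <- paste("estimation failed:",
                          trimws(attr(trial_fit, "condition")$message))
      ledger <- rbind(ledger, row)
      next
    }
    row$estimate <- unname(trial_fit$theta[length(trial_fit$theta)])
    row$se <- unname(trial_fit$se[length(trial_fit$se)])
    if (!trial_fit$converged) {
      row$reason <- sprintf("convergence missed (max|t| %.3f, mcr %.3f)",
                            max(abs(trial_fit$t_ratios), na.rm = TRUE),
                            trial_fit$max_convergence_ratio)
      ledger <- rbind(ledger, row)
      next
    }
    z <- abs(row$estimate / row$se)
    if (!is.finite(z) || z < z_min) {
      row$reason <- sprintf("not significant (|z| = %.2f)", z)
      ledger <- rbind(ledger, row)
      next
    }
    if (!is.na(gof_min)) {
      g <- gof(trial_fit, n_sim = gof_nsim,
               seed = sample.int(.Machine$integer.max, 1))
      if (any(g$p_values < gof_min)) {
        row$reason <- sprintf("GOF impaired (min p = %.3f)",
                              min(g$p_values))
        ledger <- rbind(ledger, row)
        next
      }
    }
    row$decision <- "retained"
    row$reason <- sprintf("converged, |z| = %.2f", z)
    ledger <- rbind(ledger, row)
    spec <- trial_spec
    fit <- trial_fit
  }
  list(spec = spec, fit = fit, ledger = ledger)
}
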