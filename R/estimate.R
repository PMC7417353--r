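#' Fit a stochastic actor-oriented model by Method of Moments
#'
#' Robbins-Monro stochastic-approximation estimation in the classical three
#' phases. Phase 1 simulates `n1` panels at the initial parameters to
#' estimate the derivative matrix D of expected statistics by forward finite
#' differences with common random numbers. Phase 2 runs four subphases of
#' diminishing gain (halved each subphase, Polyak-averaged within each),
#' updating `theta <- theta - a * solve(D, S_sim - S_obs)`; every period is
#' simulated forward from the observed previous wave. Phase 3 re-estimates D
#' at the final estimate and simulates `n3` panels for the convergence
#' t-ratios, the overall maximum convergence ratio, and the standard errors
#' `cov(theta) = D^-1 Sigma D^-T`.
#'
#' Rate parameters are initialised from the observed per-period Hamming
#' distances, evaluation parameters at zero except the outdegree parameter,
#' which starts at the logit of the mean observed density. Estimation is
#' unconditional: the per-period rates are estimated alongside the
#' evaluation parameters.
#'
#' @param panel A [wave_panel()] with at least 2 waves.
#' @param spec A [model_spec()]; effect `param` values are ignored as
#'   starting values unless `use_spec_start = TRUE`.
#' @param n1 Phase-1 simulations for the derivative matrix.
#' @param n2 Iterations per phase-2 subphase (length 4).
#' @param gain Initial Robbins-Monro gain.
#' @param n3 Phase-3 simulations (set 4000 for the full-length diagnostic
#'   run; 1000 is the package default).
#' @param n_deriv Simulations for the phase-3 derivative re-estimate.
#' @param delta Finite-difference step.
#' @param seed Integer seed; the fit is fully reproducible given it.
#' @param max_restarts Extra polish passes attempted when the convergence
#'   thresholds (|t| < 0.1, maximum convergence ratio < 0.25) are missed:
#'   each takes one deterministic Newton step on the estimated moment
#'   equation and re-runs phase 3; the best pass (smallest diagnostics) is
#'   kept.
#' @param use_spec_start Start from the parameters in `spec` instead of the
#'   data-driven initial values.
#' @return An object of class `saom_fit`: estimates, standard errors,
#'   t-ratios, maximum convergence ratio, derivative matrix `D`, statistic
#'   covariance `Sigma`, parameter covariance, the phase-3 statistic archive
#'   and per-period statistic archive, and an iteration log.
#' @export
estimate_mom <- function(panel, spec, n1 = 80, n2 = c(100, 200, 400, 800),
                         gain = 0.2, n3 = 1000, n_deriv = 150, delta = 0.15,
                         seed = NULL, max_restarts = 6,
                         use_spec_start = FALSE) {
  W <- panel$n_waves
  if (W < 2) stop("estimation requires at least 2 waves")
  if (!is.null(seed)) set.seed(seed)
  layout <- param_layout(spec, W - 1)
  check_identifiable(spec)
  ctxs <- lapply(seq_len(W - 1), function(m) period_context(panel, spec, m))
  s_obs <- target_statistics(panel, spec)
  theta <- if (use_spec_start) spec_params(spec, W - 1) else
    initial_theta(panel, spec, layout, s_obs)
  log_lines <- sprintf("start: %s",
                       paste(sprintf("%s=%.3f", layout$names, theta),
                             collapse = " "))

  sim_at <- function(theta, seed1) {
    set.seed(seed1)
    simulate_statistics(ctxs, spec, theta, layout)
  }
  estimate_D <- function(theta, n_it) {
    p <- layout$p
    D <- matrix(0, p, p, dimnames = list(layout$names, layout$names))
    for (t in seq_len(n_it)) {
      sd1 <- sample.int(.Machine$integer.max, 1)
      s0 <- sim_at(theta, sd1)
      for (l in seq_len(p)) {
        th <- theta
        th[l] <- th[l] + delta
        D[, l] <- D[, l] + (sim_at(th, sd1) - s0) / delta
      }
    }
    D / n_it
  }

  run_phase2 <- function(theta, D) {
    Dinv <- safe_solve(D, layout$names)
    for (sub in seq_along(n2)) {
      a <- gain / 2^(sub - 1)
      iter <- matrix(NA_real_, n2[sub], layout$p)
      for (it in seq_len(n2[sub])) {
        s <- sim_at(theta, sample.int(.Machine$integer.max, 1))
        step <- a * as.numeric(Dinv %*% (s - s_obs))
        step <- pmin(pmax(step, -1), 1) # guard against runaway updates
        theta <- theta - step
        theta[seq_len(layout$n_rate)] <-
          pmax(theta[seq_len(layout$n_rate)], 0.01)
        iter[it, ] <- theta
      }
      theta <- colMeans(iter)
      log_lines <<- c(log_lines, sprintf(
        "subphase %d (gain %.3g): %s", sub, a,
        paste(sprintf("%s=%.3f", layout$names, theta), collapse = " ")))
    }
    theta
  }

  run_phase3 <- function(theta) {
    D <- estimate_D(theta, n_deriv)
    arch <- matrix(NA_real_, n3, layout$p,
                   dimnames = list(NULL, layout$names))
    pe <- array(NA_real_, c(n3, layout$n_eval, W - 1))
    ph <- matrix(NA_real_, n3, W - 1)
    for (r in seq_len(n3)) {
      set.seed(sample.int(.Machine$integer.max, 1))
      sim <- simulate_statistics(ctxs, spec, theta, layout,
                                 per_period = TRUE)
      arch[r, ] <- sim$stats
      pe[r, , ] <- sim$period_eval
      ph[r, ] <- sim$period_ham
    }
    dev <- colMeans(arch) - s_obs
    sds <- apply(arch, 2, sd)
    tr <- dev / ifelse(sds > 0, sds, NA)
    Sigma <- cov(arch)
    mcr <- max_conv_ratio(dev, Sigma)
    list(theta = theta, D = D, archive = arch, period_eval = pe,
         period_ham = ph, t_ratios = tr, Sigma = Sigma, mcr = mcr,
         maxt = max(abs(tr), na.rm = TRUE),
         converged = all(abs(tr) < 0.1, na.rm = TRUE) && mcr < 0.25)
  }

  D <- estimate_D(theta, n1)
  restarts <- 0
  last <- NULL
  best <- NULL
  repeat {
    pass <- tryCatch({
      if (is.null(best)) {
        theta <- run_phase2(theta, D)
      } else {
        # damped diagonal Newton polish on the estimated moment equation,
        # iterating from the latest pass; the diagonal of D avoids the
        # amplification a full solve suffers when a near-saturated rate
        # makes D ill-conditioned, and deviations within the Monte-Carlo
        # noise of the t-ratio estimate are left alone so the polish does
        # not chase noise (a gated pass with no correction re-diagnoses at
        # fresh random numbers)
        dev <- colMeans(last$archive) - s_obs
        dev[abs(last$t_ratios) < 1.5 / sqrt(nrow(last$archive))] <- 0
        step <- 0.7 * dev / pmax(diag(last$D), 1e-6)
        theta <- last$theta - pmin(pmax(step, -0.3), 0.3)
        theta[seq_len(layout$n_rate)] <-
          pmax(theta[seq_len(layout$n_rate)], 0.01)
      }
      run_phase3(theta)
    }, error = function(e) e)
    if (inherits(pass, "error")) {
      if (is.null(best)) stop(pass)
      log_lines <- c(log_lines, paste("restart pass failed:",
                                      conditionMessage(pass)))
      break
    }
    log_lines <- c(log_lines, sprintf(
      "phase 3: max|t| = %.3f, max convergence ratio = %.3f%s",
      pass$maxt, pass$mcr, if (pass$converged) "" else
        " (thresholds missed)"))
    last <- pass
    # keep the best pass (converged beats non-converged, then smallest
    # diagnostics): restarts must never degrade a near-converged fit
    better <- is.null(best) ||
      (pass$converged && !best$converged) ||
      (pass$converged == best$converged &&
         max(pass$maxt, pass$mcr) < max(best$maxt, best$mcr))
    if (better) best <- pass
    if (best$converged || restarts >= max_restarts) break
    restarts <- restarts + 1
  }
  Dinv <- safe_solve(best$D, layout$names)
  covtheta <- Dinv %*% best$Sigma %*% t(Dinv)
  se <- sqrt(pmax(diag(covtheta), 0))
  structure(list(
    theta = stats::setNames(best$theta, layout$names),
    se = stats::setNames(se, layout$names),
    t_ratios = best$t_ratios, max_convergence_ratio = best$mcr,
    converged = best$converged,
    D = best$D, Sigma = best$Sigma, cov_theta = covtheta,
    archive = best$archive, period_eval_archive = best$period_eval,
    period_ham_archive = best$period_ham,
    s_obs = s_obs, layout = layout, spec = spec_with_params(
      spec, best$theta, layout),
    panel = panel, n3 = n3, restarts = restarts, log = log_lines),
    class = "saom_fit")
}

#' @export
print.saom_fit <- function(x, ...) {
  cat("<saom_fit>", if (x$converged) "converged" else "NOT converged", "\n")
  est <- data.frame(estimate = round(x$theta, 4), se = round(x$se, 4),
                    t_conv = round(x$t_ratios, 4))
  print(est)
  cat(sprintf("max convergence ratio: %.4f (phase-3 n = %d)\n",
              x$max_convergence_ratio, x$n3))
  invisible(x)
}

initial_theta <- function(panel, spec, layout, s_obs) {
  W <- panel$n_waves
  rates <- numeric(W - 1)
  for (m in seq_len(W - 1)) {
    joint <- sum(panel$active[, m] & panel$active[, m + 1])
    ham <- s_obs[m]
    rates[m] <- max(0.5, 1.5 * ham / max(joint, 1))
  }
  dens <- vapply(2:W, function(w) {
    act <- panel$actors[panel$active[, w]]
    suppressWarnings(net_density(panel$binary[[w]][act, act]))
  }, 0)
  dbar <- min(max(mean(dens, na.rm = TRUE), 0.01), 0.99)
  betas <- numeric(layout$n_eval)
  nm <- vapply(spec$effects, `[[`, "", "name")
  betas[nm == "outdegree"] <- log(dbar / (1 - dbar))
  c(rates, if (layout$has_alpha) 0, betas)
}

check_identifiable <- function(spec) {
  key <- vapply(spec$effects, function(e)
    paste(e$name, e$covariate %||% "", sep = ":"), "")
  if (anyDuplicated(key))
    stop("duplicated effect makes the model unidentifiable: ",
         key[duplicated(key)][1])
}

safe_solve <- function(D, names) {
  z <- try(solve(D), silent = TRUE)
  if (inherits(z, "try-error") || any(!is.finite(z))) {
    ev <- svd(D)$d
    bad <- which(ev < max(ev) * 1e-10)
    if (length(bad))
      stop("derivative matrix is singular; near-collinear effects: ",
           paste(names[bad], collapse = ", "))
    z <- MASS::ginv(D)
    dimnames(z) <- dimnames(D)
  }
  z
}

max_conv_ratio <- function(dev, Sigma) {
  Si <- try(solve(Sigma), silent = TRUE)
  if (inherits(Si, "try-error") || any(!is.finite(Si))) {
    warning("singular statistic covariance; using pseudo-inverse")
    Si <- MASS::ginv(Sigma)
  }
  sqrt(max(0, as.numeric(t(dev) %*% Si %*% dev)))
}

#' Convergence diagnostics of a fitted model
#'
#' Per-parameter convergence t-ratios (mean simulated minus observed
#' statistic, over the simulation standard deviation) and the overall
#' maximum convergence ratio, the largest t-ratio over all linear
#' combinations of statistics: `sqrt(dev' Sigma^-1 dev)`.
#'
#' @param fit A [estimate_mom()] result.
#' @return List with `t_ratios` and `max_convergence_ratio`.
#' @export
convergence_diagnostics <- function(fit) {
  dev <- colMeans(fit$archive) - fit$s_obs
  sds <- apply(fit$archive, 2, sd)
  list(t_ratios = dev / ifelse(sds > 0, sds, NA),
       max_convergence_ratio = max_conv_ratio(dev, cov(fit$archive)))
}

#' Parameter collinearity screen
#'
#' Correlation matrix of the parameter estimates (from the Method-of-Moments
#' covariance) with flags for |r| > 0.9.
#'
#' @param fit A [estimate_mom()] result.
#' @param threshold Absolute correlation above which a pair is flagged.
#' @return List with `correlations` and a data frame of `flags`.
#' @export
collinearity_check <- function(fit, threshold = 0.9) {
  v <- fit$cov_theta
  d <- sqrt(diag(v))
  r <- v / outer(d, d)
  diag(r) <- 1
  dimnames(r) <- list(names(fit$theta), names(fit$theta))
  idx <- which(abs(r) > threshold & upper.tri(r), arr.ind = TRUE)
  flags <- data.frame(param1 = rownames(r)[idx[, 1]],
                      param2 = colnames(r)[idx[, 2]],
                      r = r[idx])
  list(correlations = r, flags = flags)
}
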