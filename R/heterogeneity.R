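#' Time-heterogeneity score test
#'
#' Tests whether the evaluation parameters are stable across periods. Under
#' the pooled fit the summed per-effect statistics are matched exactly, but
#' their distribution over periods is free; the test compares the observed
#' per-period effect statistics with their phase-3 simulated distribution on
#' the contrast space orthogonal to the pooled sums (per effect, deviations
#' of periods 2..W-1 from period 1). The standardized quadratic form is
#' referred to a chi-square with `(# tested effects) * (W - 2)` degrees of
#' freedom.
#'
#' @param fit A [estimate_mom()] result on a panel with >= 3 waves.
#' @param effects Indices (or names) of the evaluation effects to test;
#'   default all of them.
#' @return List with `chi2`, `df`, `p` and the per-period deviation matrix.
#' @export
time_heterogeneity_test <- function(fit, effects = NULL) {
  panel <- fit$panel
  W <- panel$n_waves
  if (W < 3) stop("time-heterogeneity test requires at least 3 waves")
  spec <- fit$spec
  layout <- fit$layout
  K <- layout$n_eval
  nm <- vapply(spec$effects, `[[`, "", "name")
  if (is.null(effects)) effects <- seq_len(K)
  if (is.character(effects)) effects <- match(effects, nm)
  stopifnot(all(effects %in% seq_len(K)))
  n_per <- W - 1

  # observed per-period eval statistics
  obs <- sapply(seq_len(n_per), function(m) {
    ctx <- period_context(panel, spec, m)
    period_statistics(ctx, ctx$x_end_obs, spec$effects,
                      layout$has_alpha)$eval
  })
  obs <- matrix(obs, nrow = K) # K x n_per

  # phase-3 archive: n3 x K x n_per
  pe <- fit$period_eval_archive
  n3 <- dim(pe)[1]
  flat <- function(m) as.numeric(t(m[effects, , drop = FALSE]))
  o <- flat(obs)
  sims <- t(vapply(seq_len(n3), function(r)
    flat(matrix(pe[r, , ], nrow = K)), numeric(length(effects) * n_per)))

  # within-effect contrasts across periods: period m minus period 1
  Ke <- length(effects)
  C1 <- cbind(-1, diag(n_per - 1)) # (n_per-1) x n_per
  C <- kronecker(diag(Ke), C1)
  d <- as.numeric(C %*% (o - colMeans(sims)))
  V <- C %*% cov(sims) %*% t(C)
  Vi <- tryCatch(solve(V), error = function(e) {
    warning("singular contrast covariance; using pseudo-inverse")
    MASS::ginv(V)
  })
  chi2 <- as.numeric(t(d) %*% Vi %*% d)
  df <- Ke * (W - 2)
  list(chi2 = chi2, df = df, p = pchisq(chi2, df, lower.tail = FALSE),
       deviations = matrix(d, nrow = Ke, byrow = TRUE,
                           dimnames = list(nm[effects], NULL)))
}
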