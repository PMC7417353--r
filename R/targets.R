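# ---- Method-of-Moments target statistics ----------------------------------

# Parameter vector layout used throughout estimation:
#   [rates (one per period)] [rate_outdegree alpha, if present] [eval betas]
param_layout <- function(spec, n_per) {
  nms <- c(paste0("rate_", seq_len(n_per)),
           if (!is.null(spec$rate_outdegree)) "rate_outdegree",
           vapply(spec$effects, function(e)
             paste0(e$name, if (is.null(e$covariate)) "" else
               paste0(".", e$covariate)), ""))
  list(names = nms,
       n_rate = n_per,
       has_alpha = !is.null(spec$rate_outdegree),
       n_eval = length(spec$effects),
       p = n_per + as.integer(!is.null(spec$rate_outdegree)) +
         length(spec$effects))
}

spec_with_params <- function(spec, theta, layout) {
  spec$rates <- pmax(theta[seq_len(layout$n_rate)], 1e-8)
  idx <- layout$n_rate
  if (layout$has_alpha) {
    idx <- idx + 1
    spec$rate_outdegree <- theta[idx]
  }
  for (k in seq_len(layout$n_eval))
    spec$effects[[k]]$param <- theta[idx + k]
  spec
}

spec_params <- function(spec, n_per) {
  c(rep(spec$rates, length.out = n_per),
    if (!is.null(spec$rate_outdegree)) spec$rate_outdegree,
    vapply(spec$effects, `[[`, 0, "param"))
}

# statistics of one period given the end network (observed or simulated),
# restricted to the jointly active actors
period_statistics <- function(ctx, x_end, eval_eff, has_alpha) {
  joint <- ctx$joint
  xj <- x_end[joint, joint, drop = FALSE]
  x0j <- ctx$x0[joint, joint, drop = FALSE]
  ham <- sum(abs(xj - x0j))
  alpha_stat <- if (has_alpha)
    sum(rowSums(x0j) * rowSums(abs(xj - x0j))) else NULL
  # per-effect totals over jointly active actors, using the sim-context
  # covariate resolution (subset rows/cols to joint actors)
  jidx <- match(joint, ctx$sim_actors)
  ev <- vapply(seq_along(eval_eff), function(k) {
    code <- ctx$eff$codes[k]
    dy <- ctx$eff$dyads[[k]]
    stat_total(code, xj, ctx$eff$attr[jidx, k],
               if (is.null(dy)) NULL else dy[jidx, jidx, drop = FALSE])
  }, 0)
  list(ham = ham, alpha = alpha_stat, eval = ev)
}

# total (summed over actors) of one effect statistic on binary matrix x
stat_total <- function(code, x, v, dyad) {
  outdeg <- rowSums(x)
  indeg <- colSums(x)
  xx <- NULL
  switch(code,
    sum(x),                                   # outdegree
    sum(x * t(x)),                            # reciprocity
    sum((x %*% x) * x),                       # transitive triplets
    sum((x %*% x) * x * t(x)),                # transitive recip triplets
    sum((x %*% x) * t(x)),                    # three-cycles
    sum(x %*% indeg),                         # indegree popularity
    sum(x %*% sqrt(outdeg)),                  # outdegree popularity (sqrt)
    sum(outdeg^1.5),                          # outdegree activity (sqrt)
    sum(sqrt(outdeg) * (x %*% sqrt(outdeg))), # out-out assortativity
    sum(v * outdeg),                          # cov ego (v centred)
    sum(x %*% v),                             # cov alter (v centred)
    sum(x * dyad),                            # cov same (equality matrix)
    sum(x * dyad),                            # cov similarity (centred)
    sum(x * t(x) * dyad)                      # same cov x reciprocity
  )
}

assemble_stats <- function(per_period, layout) {
  hams <- vapply(per_period, `[[`, 0, "ham")
  alpha <- if (layout$has_alpha)
    sum(vapply(per_period, `[[`, 0, "alpha")) else NULL
  ev <- Reduce(`+`, lapply(per_period, `[[`, "eval"))
  stats::setNames(c(hams, alpha, ev), layout$names)
}

#' Method-of-Moments target statistics of a panel
#'
#' For each evaluation effect, the sum over periods and actors of the effect
#' statistic evaluated on the observed end-of-period wave; for each period's
#' basic rate, the Hamming distance between its two waves; for the
#' rate-outdegree effect, the outdegree-weighted row Hamming distance. All
#' statistics are restricted to dyads jointly active in both waves of the
#' period.
#'
#' @param panel A [wave_panel()].
#' @param spec A [model_spec()].
#' @return Named numeric vector, one entry per free parameter.
#' @export
target_statistics <- function(panel, spec) {
  W <- panel$n_waves
  if (W < 2) stop("target statistics require at least 2 waves")
  layout <- param_layout(spec, W - 1)
  pp <- lapply(seq_len(W - 1), function(m) {
    ctx <- period_context(panel, spec, m)
    period_statistics(ctx, ctx$x_end_obs, spec$effects, layout$has_alpha)
  })
  assemble_stats(pp, layout)
}

# simulate the whole panel once at theta and return the statistic vector
# (and optionally per-period eval stats for the heterogeneity test)
simulate_statistics <- function(ctxs, spec, theta, layout,
                                per_period = FALSE) {
  sp <- spec_with_params(spec, theta, layout)
  pp <- vector("list", length(ctxs))
  for (m in seq_along(ctxs)) {
    ctx <- ctxs[[m]]
    eff <- ctx$eff
    eff$betas <- vapply(sp$effects, `[[`, 0, "param")
    rho <- sp$rates[m]
    alpha <- if (is.null(sp$rate_outdegree)) 0 else sp$rate_outdegree
    out <- cpp_sim_period(ctx$x0, eff$codes, eff$betas, eff$attr, eff$dyads,
                          rho, alpha, as.numeric(ctx$presence), FALSE,
                          1000000L)
    dimnames(out$x) <- dimnames(ctx$x0)
    ctx2 <- ctx
    ctx2$eff$betas <- eff$betas
    pp[[m]] <- period_statistics(ctx2, out$x, sp$effects, layout$has_alpha)
  }
  s <- assemble_stats(pp, layout)
  if (!per_period) return(s)
  list(stats = s,
       period_eval = do.call(cbind, lapply(pp, `[[`, "eval")),
       period_ham = vapply(pp, `[[`, 0, "ham"))
}
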