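# ---- auxiliary statistics --------------------------------------------------

# cumulative degree counts: number of active actors with degree <= v,
# v = 0..max_val, pooled (summed) over the supplied waves
aux_degree <- function(waves, direction = c("out", "in"), max_val = 8) {
  direction <- match.arg(direction)
  tot <- numeric(max_val + 1)
  for (x in waves) {
    deg <- if (direction == "out") rowSums(x) else colSums(x)
    tot <- tot + vapply(0:max_val, function(v) sum(deg <= v), 0)
  }
  stats::setNames(tot, paste0("deg<=", 0:max_val))
}

# full 16-class directed triad census, pooled over waves
aux_triads <- function(waves) {
  cls <- c("003", "012", "102", "021D", "021U", "021C", "111D", "111U",
           "030T", "030C", "201", "120D", "120U", "120C", "210", "300")
  tot <- numeric(16)
  for (x in waves) {
    g <- igraph::graph_from_adjacency_matrix(x, mode = "directed")
    tot <- tot + igraph::triad_census(g)
  }
  stats::setNames(tot, cls)
}

# counts of ordered pairs at geodesic distance 1..max_d, pooled over waves
aux_geodesic <- function(waves, max_d = 5) {
  tot <- numeric(max_d)
  for (x in waves) {
    g <- igraph::graph_from_adjacency_matrix(x, mode = "directed")
    d <- igraph::distances(g, mode = "out")
    d <- d[row(d) != col(d)]
    tot <- tot + vapply(seq_len(max_d), function(v) sum(d == v), 0)
  }
  stats::setNames(tot, paste0("dist", seq_len(max_d)))
}

#' Auxiliary statistics of a set of wave networks
#'
#' The pooled auxiliary statistic vector used by [gof()]: cumulative degree
#' counts at 0..8, the 16-class directed triad census, or geodesic pair
#' counts at distances 1..5, summed over the supplied waves.
#'
#' @param waves List of binary adjacency matrices (each restricted to the
#'   actors active in that wave).
#' @param auxiliary One of `"outdegree"`, `"indegree"`, `"triad_census"`,
#'   `"geodesic"`.
#' @return Named numeric vector.
#' @export
aux_statistics <- function(waves, auxiliary = c("outdegree", "indegree",
                                                "triad_census",
                                                "geodesic")) {
  auxiliary <- match.arg(auxiliary)
  aux_fun(auxiliary)(waves)
}

aux_fun <- function(name) {
  switch(name,
         outdegree = function(w) aux_degree(w, "out"),
         indegree = function(w) aux_degree(w, "in"),
         triad_census = aux_triads,
         geodesic = aux_geodesic,
         stop("unknown auxiliary statistic: ", name))
}

# waves 2..W of a panel (observed), each restricted to its active actors
observed_aux_waves <- function(panel) {
  lapply(2:panel$n_waves, function(w) {
    act <- panel$actors[panel$active[, w]]
    panel$binary[[w]][act, act, drop = FALSE]
  })
}

#' Monte-Carlo Mahalanobis p-value for auxiliary statistics
#'
#' Mahalanobis distance of each statistic vector from the simulated mean,
#' using the (pseudo-inverted, variance-pooled) simulated covariance;
#' components with zero simulated variance are dropped. The p-value is the
#' proportion of simulated distances at least as large as the observed one.
#'
#' @param obs Observed auxiliary statistic vector.
#' @param sims Matrix of simulated auxiliary statistics (one row per
#'   simulated panel).
#' @return List with `p`, `obs_distance`, `sim_distances`, `kept`.
#' @export
mahalanobis_gof_p <- function(obs, sims) {
  keep <- apply(sims, 2, sd) > 0
  if (!any(keep)) stop("all auxiliary components are degenerate")
  if (any(!keep))
    warning("dropping degenerate auxiliary components: ",
            paste(colnames(sims)[!keep], collapse = ", "))
  s <- sims[, keep, drop = FALSE]
  o <- obs[keep]
  mu <- colMeans(s)
  Vi <- MASS::ginv(cov(s))
  dist1 <- function(z) as.numeric(t(z - mu) %*% Vi %*% (z - mu))
  d_obs <- dist1(o)
  d_sim <- apply(s, 1, dist1)
  list(p = mean(d_sim >= d_obs), obs_distance = d_obs,
       sim_distances = d_sim, kept = colnames(sims)[keep])
}

#' Goodness of fit of a fitted actor-oriented model
#'
#' Simulates `n_sim` panels at the estimated parameters (each period forward
#' from the observed previous wave) and compares the observed auxiliary
#' statistics -- cumulative outdegree and indegree counts at 0..8, the
#' 16-class directed triad census, and geodesic pair counts at distances
#' 1..5, pooled over waves 2..W -- with their simulated distributions by a
#' Monte-Carlo Mahalanobis p-value. p-values above 0.05 indicate the
#' simulated networks are close to the observed ones.
#'
#' @param fit A [estimate_mom()] result.
#' @param auxiliary Character vector among `"outdegree"`, `"indegree"`,
#'   `"triad_census"`, `"geodesic"`.
#' @param n_sim Number of simulated panels.
#' @param seed Integer seed.
#' @return An object of class `saom_gof`: per-auxiliary observed vectors,
#'   simulated matrices and p-values.
#' @export
gof <- function(fit, auxiliary = c("outdegree", "indegree", "triad_census",
                                   "geodesic"),
                n_sim = 500, seed = NULL) {
  auxiliary <- match.arg(auxiliary, several.ok = TRUE)
  if (!is.null(seed)) set.seed(seed)
  panel <- fit$panel
  obs_waves <- observed_aux_waves(panel)
  obs <- lapply(auxiliary, function(a) aux_fun(a)(obs_waves))
  names(obs) <- auxiliary
  sims <- lapply(auxiliary, function(a)
    matrix(NA_real_, n_sim, length(obs[[a]]),
           dimnames = list(NULL, names(obs[[a]]))))
  names(sims) <- auxiliary
  for (r in seq_len(n_sim)) {
    waves <- simulate_panel(panel, fit$spec)
    for (a in auxiliary) sims[[a]][r, ] <- aux_fun(a)(waves)
  }
  res <- lapply(auxiliary, function(a)
    suppressWarnings(mahalanobis_gof_p(obs[[a]], sims[[a]])))
  names(res) <- auxiliary
  structure(list(auxiliary = auxiliary, observed = obs, simulated = sims,
                 tests = res,
                 p_values = vapply(res, `[[`, 0, "p")),
            class = "saom_gof")
}

#' @export
print.saom_gof <- function(x, ...) {
  cat("<saom_gof> Monte-Carlo Mahalanobis p-values\n")
  for (a in x$auxiliary)
    cat(sprintf("  %-14s p = %.3f\n", a, x$tests[[a]]$p))
  invisible(x)
}
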