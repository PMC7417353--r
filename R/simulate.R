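# ---- period context --------------------------------------------------------

# Everything needed to simulate period m (waves m -> m+1) of a panel:
# the actors simulated over (those present at wave m+1), the observed start
# network restricted to them (joiners start with empty tie profiles), the
# jointly active actors used for target statistics, presence fractions and
# the resolved effect inputs (covariates of week m+1).
period_context <- function(panel, spec, m) {
  ids <- panel$actors
  sim_act <- ids[panel$active[, m + 1]]
  joint <- ids[panel$active[, m] & panel$active[, m + 1]]
  x0 <- panel$binary[[m]][sim_act, sim_act, drop = FALSE]
  storage.mode(x0) <- "integer"
  joiners <- setdiff(sim_act, ids[panel$active[, m]])
  x0[joiners, ] <- 0L
  x0[, joiners] <- 0L
  pres <- panel$presence[sim_act, m + 1]
  eff <- resolve_effects(spec, sim_act, spec$covariates, m + 1)
  list(m = m, sim_actors = sim_act, joint = joint, x0 = x0,
       presence = pres, eff = eff,
       x_end_obs = panel$binary[[m + 1]][sim_act, sim_act, drop = FALSE])
}

period_rho <- function(spec, m) {
  r <- spec$rates
  r[min(m, length(r))]
}

#' Simulate one period of network evolution
#'
#' Runs the continuous-time micro-step chain for one unit of model time:
#' actors receive change opportunities with exponential holding times at
#' total intensity sum(lambda_i), and at each opportunity toggle at most one
#' outgoing tie by multinomial-logit choice over their evaluation function.
#' Joiners of the period start with empty tie profiles; absent actors are
#' outside the choice set.
#'
#' @param x_start Binary adjacency matrix at the period start (actors =
#'   those present at the period's end wave).
#' @param spec A [model_spec()]; effect `param` values are the simulation
#'   parameters.
#' @param m Period index (selects the basic rate and changing covariates).
#' @param presence Per-actor fraction-of-week presence (default all 1).
#' @param record Keep the micro-step log (`$steps`: acting actor and toggled
#'   target, 0 = kept the network).
#' @param max_steps Safety cap on the number of micro-steps.
#' @return List with `x` (end network), `n_steps`, and optionally `steps`.
#' @export
simulate_period <- function(x_start, spec, m = 1, presence = NULL,
                            record = FALSE, max_steps = 1e6) {
  ids <- rownames(x_start)
  if (is.null(ids)) {
    ids <- as.character(seq_len(nrow(x_start)))
    dimnames(x_start) <- list(ids, ids)
  }
  if (is.null(presence)) presence <- rep(1, nrow(x_start))
  eff <- resolve_effects(spec, ids, spec$covariates, m + 1)
  rho <- period_rho(spec, m)
  if (rho < 0) stop("negative basic rate")
  alpha <- if (is.null(spec$rate_outdegree)) 0 else spec$rate_outdegree
  storage.mode(x_start) <- "integer"
  out <- cpp_sim_period(x_start, eff$codes, eff$betas, eff$attr, eff$dyads,
                        rho, alpha, as.numeric(presence), record,
                        as.integer(max_steps))
  dimnames(out$x) <- list(ids, ids)
  out
}

#' One micro-step of the actor-oriented chain
#'
#' Draws the acting actor with probability proportional to its change rate,
#' then one option from {toggle one outgoing tie, keep the network} by
#' multinomial logit on the evaluation function. Reference R implementation;
#' the period simulator runs the same chain in compiled code.
#'
#' @inheritParams simulate_period
#' @param x Binary adjacency matrix.
#' @return List with `x` (possibly one tie different), `actor`, `target`
#'   (`NA` if the actor kept the network) and `probs` (the actor's choice
#'   probabilities; position = alter toggled, own position = no change).
#'   If all rates are zero, returns `x` unchanged with `actor = NA`.
#' @export
micro_step <- function(x, spec, m = 1, presence = NULL) {
  n <- nrow(x)
  if (is.null(presence)) presence <- rep(1, n)
  lambda <- vapply(seq_len(n), function(i)
    rate_fn(i, x, m, spec, presence), 0)
  if (sum(lambda) <= 0)
    return(list(x = x, actor = NA_integer_, target = NA_integer_,
                probs = NULL))
  i <- sample.int(n, 1, prob = lambda)
  probs <- micro_step_probs(i, x, spec, m, presence)
  choice <- sample.int(n, 1, prob = probs)
  target <- NA_integer_
  if (choice != i) {
    x[i, choice] <- 1L - x[i, choice]
    target <- choice
  }
  list(x = x, actor = i, target = target, probs = probs)
}

#' @rdname micro_step
#' @param i Acting actor index.
#' @export
micro_step_probs <- function(i, x, spec, m = 1, presence = NULL) {
  n <- nrow(x)
  if (is.null(presence)) presence <- rep(1, n)
  covs <- lapply(stats::setNames(nm = names(spec$covariates)), function(nm)
    resolve_covariate(spec$covariates[[nm]],
                      rownames(x) %||% as.character(seq_len(n)), m + 1))
  f <- numeric(n)
  f[i] <- evaluation_fn(i, x, spec, covs)
  for (j in seq_len(n)) {
    if (j == i) next
    if (presence[j] <= 0) {
      f[j] <- -Inf
      next
    }
    xc <- x
    xc[i, j] <- 1L - xc[i, j]
    f[j] <- evaluation_fn(i, xc, spec, covs)
  }
  p <- exp(f - max(f))
  p / sum(p)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a full panel forward from observed waves
#'
#' For each period, simulates from the OBSERVED network at the period start
#' (the conditioning used by Method-of-Moments estimation), honouring
#' joiners, leavers and fractional presence.
#'
#' @param panel A [wave_panel()] supplying wave 1 and the composition.
#' @param spec A [model_spec()].
#' @param chain If `TRUE`, simulate each period from the previously
#'   simulated wave instead (a free-running trajectory from wave 1).
#' @return List of simulated end-of-period networks (waves 2..W), each over
#'   the actors present at that wave.
#' @export
simulate_panel <- function(panel, spec, chain = FALSE) {
  W <- panel$n_waves
  sims <- vector("list", W - 1)
  prev <- NULL
  for (m in seq_len(W - 1)) {
    ctx <- period_context(panel, spec, m)
    x0 <- ctx$x0
    if (chain && !is.null(prev)) {
      common <- intersect(rownames(prev), rownames(x0))
      x0[] <- 0L
      x0[common, common] <- prev[common, common]
    }
    rho <- period_rho(spec, m)
    alpha <- if (is.null(spec$rate_outdegree)) 0 else spec$rate_outdegree
    out <- cpp_sim_period(x0, ctx$eff$codes, ctx$eff$betas, ctx$eff$attr,
                          ctx$eff$dyads, rho, alpha,
                          as.numeric(ctx$presence), FALSE, 1000000L)
    dimnames(out$x) <- dimnames(x0)
    sims[[m]] <- out$x
    prev <- out$x
  }
  sims
}
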