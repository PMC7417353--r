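#' SAOM effect catalogue
#'
#' Names of the network evaluation effects understood by the model machinery,
#' in their canonical order. Covariate effects (`cov_*`, `same_cov_*`) require
#' a covariate name when used in a [model_spec()].
#'
#' @return Character vector of effect names.
#' @export
saom_effect_names <- function() {
  c("outdegree", "reciprocity", "transitive_triplets",
    "transitive_recip_triplets", "three_cycles", "indegree_popularity",
    "outdegree_popularity_sqrt", "outdegree_activity_sqrt",
    "out_out_assortativity", "cov_ego", "cov_alter", "cov_same",
    "cov_similarity", "same_cov_x_reciprocity")
}

# integer codes shared with the C++ simulator core
effect_code <- function(name) {
  code <- match(name, saom_effect_names())
  if (anyNA(code)) stop("unknown effect name: ",
                        paste(name[is.na(code)], collapse = ", "))
  code
}

effect_needs_covariate <- function(name) {
  name %in% c("cov_ego", "cov_alter", "cov_same", "cov_similarity",
              "same_cov_x_reciprocity")
}

#' Define a single model effect
#'
#' @param name Effect name, one of [saom_effect_names()], or `"rate_outdegree"`
#'   for the outdegree effect on the change rate.
#' @param covariate Name of the actor covariate the effect refers to (for
#'   `cov_*` and `same_cov_*` effects only).
#' @param param Parameter value (used as ground truth when simulating, or as
#'   an initial value when estimating).
#' @return An object of class `saom_effect`.
#' @export
saom_effect <- function(name, covariate = NULL, param = 0) {
  if (name != "rate_outdegree" && !(name %in% saom_effect_names()))
    stop("unknown effect name: ", name)
  if (name != "rate_outdegree" && effect_needs_covariate(name) &&
      is.null(covariate))
    stop("effect '", name, "' requires a covariate name")
  if (!effect_needs_covariate(name)) covariate <- NULL
  structure(list(name = name, covariate = covariate, param = param),
            class = "saom_effect")
}

#' @export
print.saom_effect <- function(x, ...) {
  cat(sprintf("<saom_effect> %s%s (param %.4g)\n", x$name,
              if (is.null(x$covariate)) "" else paste0(":", x$covariate),
              x$param))
  invisible(x)
}

#' Specify a stochastic actor-oriented model
#'
#' A model specification couples a list of evaluation effects with per-period
#' basic change rates, an optional outdegree effect on the rate function, and
#' a registry of actor covariates. Covariates are centred at the mean over all
#' actors ever present before entering any statistic; attribute similarity is
#' additionally centred by the grand mean similarity.
#'
#' @param effects List of [saom_effect()] objects (or a character vector of
#'   structural effect names). Must contain the `outdegree` effect.
#' @param rates Per-period basic rate parameters (positive); recycled to the
#'   number of periods at fit/simulation time.
#' @param covariates Named list. A constant covariate is a numeric vector
#'   named by actor id; a changing (week-varying) covariate is a matrix with
#'   one row per actor (rownames = actor ids) and one column per week.
#' @param rate_outdegree Either `NULL` (no rate effect) or a number, the
#'   parameter of the multiplicative `exp(alpha * outdegree)` term in the
#'   rate function.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(effects, rates = 3, covariates = list(),
                       rate_outdegree = NULL) {
  if (is.character(effects)) effects <- lapply(effects, saom_effect)
  if (inherits(effects, "saom_effect")) effects <- list(effects)
  stopifnot(length(effects) >= 1, all(vapply(effects, inherits, TRUE,
                                             "saom_effect")))
  nm <- vapply(effects, `[[`, "", "name")
  if (any(nm == "rate_outdegree"))
    stop("give the rate effect through the 'rate_outdegree' argument")
  if (!("outdegree" %in% nm))
    stop("the model must contain the outdegree effect")
  key <- paste(nm, vapply(effects, function(e)
    if (is.null(e$covariate)) "" else e$covariate, ""), sep = ":")
  if (anyDuplicated(key))
    stop("duplicated effect: ", key[duplicated(key)][1])
  if (any(rates <= 0)) stop("all rate parameters must be positive")
  bad <- vapply(effects, function(e)
    !is.null(e$covariate) && !(e$covariate %in% names(covariates)), TRUE)
  if (any(bad))
    stop("covariate effect without registered covariate: ",
         paste(unique(vapply(effects[bad], `[[`, "", "covariate")),
               collapse = ", "))
  structure(list(effects = effects, rates = rates, covariates = covariates,
                 rate_outdegree = rate_outdegree),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec>\n  evaluation effects:\n")
  for (e in x$effects)
    cat(sprintf("    %-28s%-10s param %.4g\n", e$name,
                if (is.null(e$covariate)) "" else e$covariate, e$param))
  cat("  rates:", paste(signif(x$rates, 4), collapse = " "), "\n")
  if (!is.null(x$rate_outdegree))
    cat("  rate outdegree effect:", signif(x$rate_outdegree, 4), "\n")
  if (length(x$covariates))
    cat("  covariates:", paste(names(x$covariates), collapse = ", "), "\n")
  invisible(x)
}

n_eval_effects <- function(spec) length(spec$effects)

#' Per-actor effect statistic
#'
#' Computes the contribution s_ik(x) of actor `i` to evaluation effect `name`
#' on the binary directed network `x`. These statistics define both the
#' evaluation function that an actor myopically maximises in a micro-step and
#' the Method-of-Moments target statistics.
#'
#' Covariate effects interpret `v` as follows: `cov_ego`/`cov_alter` use the
#' centred attribute; `cov_same` and `same_cov_x_reciprocity` use exact value
#' matching; `cov_similarity` uses `1 - |v_i - v_j| / range(v)`, centred by
#' the mean similarity over distinct ordered pairs (overridable through
#' `sim_center` and `v_range` so that period-level statistics can share one
#' global centring).
#'
#' @param name Effect name (see [saom_effect_names()]).
#' @param i Actor index (row of `x`).
#' @param x Square binary adjacency matrix, zero diagonal.
#' @param v Actor covariate vector (for covariate effects).
#' @param v_range Range used by `cov_similarity`; default `diff(range(v))`.
#' @param sim_center Centring constant for `cov_similarity`; default the mean
#'   similarity over distinct ordered pairs of `v`.
#' @return A single number.
#' @export
effect_statistic <- function(name, i, x, v = NULL, v_range = NULL,
                             sim_center = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (effect_needs_covariate(name)) {
    if (is.null(v)) stop("effect '", name, "' requires covariate values")
    stopifnot(length(v) == n)
  }
  outdeg <- unname(rowSums(x))
  indeg <- unname(colSums(x))
  xi <- unname(x[i, ])
  v <- unname(v)
  unname(switch(name,
    outdegree = sum(xi),
    reciprocity = sum(xi * x[, i]),
    transitive_triplets = sum(xi * (xi %*% x)),
    transitive_recip_triplets = sum(xi * x[, i] * (xi %*% x)),
    three_cycles = sum(xi * (x %*% x[, i])),
    indegree_popularity = sum(xi * indeg),
    outdegree_popularity_sqrt = sum(xi * sqrt(outdeg)),
    outdegree_activity_sqrt = outdeg[i]^1.5,
    out_out_assortativity = sqrt(outdeg[i]) * sum(xi * sqrt(outdeg)),
    cov_ego = v[i] * outdeg[i],
    cov_alter = sum(xi * v),
    cov_same = sum(xi * (v == v[i])),
    cov_similarity = {
      if (is.null(v_range)) v_range <- diff(range(v))
      if (v_range == 0) {
        sim <- rep(1, n)
        if (is.null(sim_center)) sim_center <- 1
      } else {
        sim <- 1 - abs(v - v[i]) / v_range
        if (is.null(sim_center)) {
          sm <- 1 - abs(outer(v, v, "-")) / v_range
          sim_center <- mean(sm[row(sm) != col(sm)])
        }
      }
      sum(xi * (sim - sim_center))
    },
    same_cov_x_reciprocity = sum(xi * x[, i] * (v == v[i])),
    stop("unknown effect name: ", name)
  ))
}

#' Actor evaluation function
#'
#' The linear combination f_i(x) = sum_k beta_k s_ik(x) over the evaluation
#' effects of a model specification, using the effects' `param` values as
#' coefficients.
#'
#' @param i Actor index.
#' @param x Binary adjacency matrix.
#' @param spec A [model_spec()].
#' @param covariates Named list of resolved covariate vectors (one value per
#'   actor, for the period at hand). Defaults to the constant covariates
#'   registered in `spec`.
#' @return A single number.
#' @export
evaluation_fn <- function(i, x, spec, covariates = NULL) {
  if (is.null(covariates)) covariates <- spec$covariates
  f <- 0
  for (e in spec$effects) {
    v <- NULL
    if (!is.null(e$covariate)) {
      v <- covariates[[e$covariate]]
      if (is.null(v)) stop("covariate not supplied: ", e$covariate)
      if (e$name %in% c("cov_ego", "cov_alter")) v <- v - mean(v)
    }
    f <- f + e$param * effect_statistic(e$name, i, x, v)
  }
  f
}

#' Actor change-rate function
#'
#' Rate at which actor `i` receives micro-step opportunities in period `m`:
#' `rho_m * exp(alpha * outdegree_i) * presence_i`, and 0 for absent actors.
#'
#' @param i Actor index.
#' @param x Binary adjacency matrix.
#' @param m Period index (into `spec$rates`).
#' @param spec A [model_spec()].
#' @param presence Per-actor fraction of the week present (0 = absent).
#' @return A non-negative number.
#' @export
rate_fn <- function(i, x, m, spec, presence = NULL) {
  rho <- spec$rates[min(m, length(spec$rates))]
  if (rho <= 0) stop("nonpositive basic rate for period ", m)
  pres <- if (is.null(presence)) 1 else presence[i]
  if (pres <= 0) return(0)
  alpha <- if (is.null(spec$rate_outdegree)) 0 else spec$rate_outdegree
  rho * exp(alpha * sum(x[i, ])) * pres
}

# ---- internal: resolve a spec against a panel into simulator inputs --------

# Centre constant covariates over actors ever present; resolve changing
# covariates for period m to their week-(m+1) column. Returns, per effect,
# the node attribute vector (centred where applicable) and the dyadic matrix
# (equality or centred similarity) the C++ core consumes.
resolve_effects <- function(spec, actors, covariates, week) {
  n <- length(actors)
  K <- length(spec$effects)
  attr_mat <- matrix(0, n, K)
  dyads <- vector("list", K)
  for (k in seq_len(K)) {
    e <- spec$effects[[k]]
    if (is.null(e$covariate)) next
    cv <- covariates[[e$covariate]]
    v <- resolve_covariate(cv, actors, week)
    if (e$name %in% c("cov_ego", "cov_alter")) {
      attr_mat[, k] <- v - mean(v)
    } else if (e$name %in% c("cov_same", "same_cov_x_reciprocity")) {
      dyads[[k]] <- outer(v, v, "==") * 1
    } else if (e$name == "cov_similarity") {
      rng <- diff(range(v))
      sm <- if (rng == 0) matrix(1, n, n) else 1 - abs(outer(v, v, "-")) / rng
      ctr <- mean(sm[row(sm) != col(sm)])
      dyads[[k]] <- sm - ctr
    }
  }
  list(codes = effect_code(vapply(spec$effects, `[[`, "", "name")),
       betas = vapply(spec$effects, `[[`, 0, "param"),
       attr = attr_mat, dyads = dyads)
}

resolve_covariate <- function(cv, actors, week) {
  if (is.matrix(cv)) {
    if (is.null(rownames(cv))) stop("changing covariate needs actor rownames")
    wk <- min(week, ncol(cv))
    v <- cv[actors, wk]
  } else {
    if (is.null(names(cv))) stop("covariate needs actor names")
    v <- cv[actors]
  }
  if (anyNA(v)) stop("covariate missing for some actors")
  unname(v)
}
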