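#' Directed network density
#'
#' Ratio of the number of directed ties to the number of possible ordered
#' dyads among active actors.
#'
#' @param x Binary adjacency matrix (restricted to active actors, or use
#'   `active` to subset).
#' @param active Optional actor ids / logical mask selecting active actors.
#' @return Density in [0, 1]; `NA` (with a warning) for fewer than 2 actors.
#' @export
net_density <- function(x, active = NULL) {
  x <- subset_active(x, active)
  n <- nrow(x)
  if (n < 2) {
    warning("density undefined for fewer than 2 active actors")
    return(NA_real_)
  }
  sum(x) / (n * (n - 1))
}

#' Tie reciprocity
#'
#' Proportion of ties i -> j whose reverse tie j -> i is also present.
#'
#' @inheritParams net_density
#' @return Proportion in [0, 1]; `NA` (with a warning) if there are no ties.
#' @export
reciprocity <- function(x, active = NULL) {
  x <- subset_active(x, active)
  nt <- sum(x)
  if (nt == 0) {
    warning("reciprocity undefined on a network without ties")
    return(NA_real_)
  }
  sum(x * t(x)) / nt
}

#' Geodesic summary of a directed network
#'
#' Diameter (longest finite shortest path) and average path length over all
#' reachable ordered pairs; unreachable pairs are excluded from the average.
#'
#' @inheritParams net_density
#' @return List with `diameter` and `average_path_length` (`NA` with a
#'   warning if no pair is reachable).
#' @export
shortest_path_stats <- function(x, active = NULL) {
  x <- subset_active(x, active)
  if (nrow(x) < 2) {
    warning("path statistics undefined for fewer than 2 active actors")
    return(list(diameter = NA_real_, average_path_length = NA_real_))
  }
  g <- igraph::graph_from_adjacency_matrix(x, mode = "directed")
  d <- igraph::distances(g, mode = "out")
  d <- d[row(d) != col(d)]
  d <- d[is.finite(d)]
  if (!length(d)) {
    warning("no finite directed paths")
    return(list(diameter = NA_real_, average_path_length = NA_real_))
  }
  list(diameter = max(d), average_path_length = mean(d))
}

#' Tie changes between two consecutive waves
#'
#' Counts created (0 -> 1), dissolved (1 -> 0) and stable (1 -> 1) ties over
#' the ordered dyads both of whose actors are active in BOTH waves, and the
#' Jaccard stability index `stable / (created + dissolved + stable)`.
#'
#' @param xa,xb Adjacency matrices of the earlier and later wave (shared
#'   global actor index).
#' @param active_a,active_b Actor ids (or logical masks) active in each wave;
#'   default: all actors of the matrices.
#' @return List with `created`, `dissolved`, `stable`, `jaccard`.
#' @export
tie_changes <- function(xa, xb, active_a = NULL, active_b = NULL) {
  ids <- rownames(xa)
  aa <- resolve_ids(active_a, ids)
  ab <- resolve_ids(active_b, rownames(xb))
  joint <- intersect(aa, ab)
  if (length(joint) < 2) {
    warning("tie changes undefined: fewer than 2 jointly active actors")
    return(list(created = NA_integer_, dissolved = NA_integer_,
                stable = NA_integer_, jaccard = NA_real_))
  }
  a <- xa[joint, joint]
  b <- xb[joint, joint]
  created <- sum(a == 0 & b == 1)
  dissolved <- sum(a == 1 & b == 0)
  stable <- sum(a == 1 & b == 1)
  denom <- created + dissolved + stable
  list(created = created, dissolved = dissolved, stable = stable,
       jaccard = if (denom > 0) stable / denom else NA_real_)
}

#' Summarize a wave panel
#'
#' Per-wave structural metrics (nodes, ties, density, diameter, average path
#' length, reciprocity) and between-wave tie dynamics (created / dissolved /
#' stable counts and Jaccard index).
#'
#' @param panel A [wave_panel()].
#' @param digits Rounding (half-up) applied to the report columns; `NULL`
#'   for full precision.
#' @return List of two data frames, `waves` and `changes`.
#' @export
summarize_panel <- function(panel, digits = NULL) {
  W <- panel$n_waves
  waves <- do.call(rbind, lapply(seq_len(W), function(w) {
    act <- panel$actors[panel$active[, w]]
    x <- panel$binary[[w]][act, act, drop = FALSE]
    sp <- suppressWarnings(shortest_path_stats(x))
    data.frame(week = w, n_nodes = length(act), n_ties = sum(x),
               density = suppressWarnings(net_density(x)),
               diameter = sp$diameter,
               average_path_length = sp$average_path_length,
               reciprocity = suppressWarnings(reciprocity(x)))
  }))
  changes <- NULL
  if (W >= 2) {
    changes <- do.call(rbind, lapply(seq_len(W - 1), function(w) {
      tc <- suppressWarnings(tie_changes(
        panel$binary[[w]], panel$binary[[w + 1]],
        panel$active[, w], panel$active[, w + 1]))
      data.frame(from_week = w, to_week = w + 1,
                 entering = sum(!panel$active[, w] & panel$active[, w + 1]),
                 leaving = sum(panel$active[, w] & !panel$active[, w + 1]),
                 created = tc$created, dissolved = tc$dissolved,
                 stable = tc$stable, jaccard = tc$jaccard)
    }))
  }
  if (!is.null(digits)) {
    num <- c("density", "average_path_length", "reciprocity")
    waves[num] <- lapply(waves[num], round_half_up, digits)
    if (!is.null(changes))
      changes$jaccard <- round_half_up(changes$jaccard, digits)
  }
  list(waves = waves, changes = changes)
}

subset_active <- function(x, active) {
  x <- as.matrix(x)
  if (is.null(active)) return(x)
  if (is.logical(active)) active <- rownames(x)[active]
  x[active, active, drop = FALSE]
}

resolve_ids <- function(active, ids) {
  if (is.null(active)) return(ids)
  if (is.logical(active)) ids[active] else intersect(active, ids)
}
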