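#' Actor attribute table
#'
#' Validates and classes a data frame of per-cow attributes: `actor_id`,
#' `age` (years), `entry_week`, optional `leave_week` (first week absent,
#' `NA` = present to the end), and weekly oestrus indicator columns
#' `oestrus_w1 .. oestrus_wW` (0/1).
#'
#' @param df Data frame with the columns above.
#' @param n_waves Number of observation weeks covered by the table.
#' @return The validated data frame with class `actor_table`.
#' @export
actor_table <- function(df, n_waves) {
  need <- c("actor_id", "age", "entry_week")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("actor table missing columns: ",
                         paste(miss, collapse = ", "))
  df$actor_id <- as.character(df$actor_id)
  if (anyDuplicated(df$actor_id)) stop("duplicated actor ids")
  if (is.null(df$leave_week)) df$leave_week <- NA_integer_
  if (any(df$entry_week < 1 | df$entry_week > n_waves))
    stop("entry_week outside 1..n_waves")
  ok <- is.na(df$leave_week) | df$leave_week > df$entry_week
  if (!all(ok)) stop("leave_week must exceed entry_week")
  attr(df, "n_waves") <- n_waves
  class(df) <- c("actor_table", "data.frame")
  df
}

#' Per-actor presence mask
#'
#' @param actors An [actor_table()].
#' @return Logical matrix actors x weeks; `TRUE` where the actor is present.
#' @export
presence_matrix <- function(actors) {
  W <- attr(actors, "n_waves")
  out <- sapply(seq_len(W), function(w)
    actors$entry_week <= w & (is.na(actors$leave_week) | actors$leave_week > w))
  out <- matrix(out, nrow = nrow(actors), dimnames =
                  list(actors$actor_id, paste0("w", seq_len(W))))
  out
}

#' Construct a wave panel
#'
#' Bundles an ordered sequence of weekly weighted grooming-count matrices,
#' their binarized versions, and the group composition into one object. All
#' waves share a single global actor index; ties never involve actors absent
#' that week.
#'
#' @param weighted List of square non-negative integer matrices (one per
#'   week) with identical actor dimnames.
#' @param active Logical matrix actors x weeks.
#' @param presence Optional numeric matrix actors x weeks with the fraction
#'   of the week each actor was present (defaults to `active * 1`).
#' @return An object of class `wave_panel`.
#' @export
wave_panel <- function(weighted, active, presence = NULL) {
  W <- length(weighted)
  stopifnot(W >= 1)
  actors <- rownames(weighted[[1]])
  if (is.null(actors)) stop("wave matrices need actor dimnames")
  n <- length(actors)
  for (w in seq_len(W)) {
    m <- weighted[[w]]
    if (!all(dim(m) == n) || !identical(rownames(m), actors))
      stop("wave ", w, ": actor index differs from wave 1")
    if (any(m < 0)) stop("wave ", w, ": negative weight")
    if (any(diag(m) != 0)) stop("wave ", w, ": self-ties on the diagonal")
    inact <- !active[, w]
    if (any(m[inact, ] != 0) || any(m[, inact] != 0))
      stop("wave ", w, ": ties involving inactive actors")
  }
  if (is.null(presence)) presence <- active * 1
  binary <- lapply(weighted, function(m) binarize(m))
  structure(list(actors = actors, n_waves = W,
                 weighted = weighted, binary = binary,
                 active = active, presence = presence),
            class = "wave_panel")
}

#' @export
print.wave_panel <- function(x, ...) {
  cat(sprintf("<wave_panel> %d actors, %d waves\n", length(x$actors),
              x$n_waves))
  nn <- colSums(x$active)
  nt <- vapply(seq_len(x$n_waves), function(w) sum(x$binary[[w]]), 0)
  cat("  active: ", paste(nn, collapse = " "), "\n")
  cat("  ties:   ", paste(nt, collapse = " "), "\n")
  invisible(x)
}

n_periods <- function(panel) panel$n_waves - 1L

#' Binarize a weighted contact matrix
#'
#' A directed tie is present in a week if one cow groomed the other at any
#' point in that week: entries with weight >= 1 become 1, all others 0.
#'
#' @param weighted Non-negative numeric matrix.
#' @return Integer 0/1 matrix of the same shape and dimnames.
#' @export
binarize <- function(weighted) {
  if (any(weighted < 0)) stop("negative weight in contact matrix")
  out <- (weighted >= 1) * 1L
  dimnames(out) <- dimnames(weighted)
  out
}

#' Weekly weighted contact matrix from an event log
#'
#' @param log An [event_log()] (grooming events are selected internally).
#' @param week Week number.
#' @param active Character vector of actor ids active that week.
#' @param on_inactive `"error"` (default) to fail when an event involves an
#'   actor not active that week, or `"drop"` to discard such events with a
#'   warning.
#' @return Integer matrix `active x active`; entry (i, j) counts i -> j
#'   grooming events in the week.
#' @export
build_weighted_wave <- function(log, week, active,
                                on_inactive = c("error", "drop")) {
  on_inactive <- match.arg(on_inactive)
  ev <- log[log$behavior == "groom" & event_week(log) == week, , drop = FALSE]
  m <- matrix(0L, length(active), length(active),
              dimnames = list(active, active))
  if (nrow(ev)) {
    bad <- !(ev$actor %in% active) | !(ev$recipient %in% active)
    if (any(bad)) {
      if (on_inactive == "error")
        stop("week ", week, ": ", sum(bad),
             " grooming event(s) involve inactive actors")
      warning("week ", week, ": dropping ", sum(bad),
              " event(s) involving inactive actors")
      ev <- ev[!bad, , drop = FALSE]
    }
    if (nrow(ev)) {
      tab <- table(factor(ev$actor, levels = active),
                   factor(ev$recipient, levels = active))
      m <- m + unclass(tab)
      dimnames(m) <- list(active, active)
    }
  }
  m
}

#' Normalized weighted degrees
#'
#' Weighted out- and in-strength of each active actor, normalized to [0, 1]
#' by the maximum attainable value in the wave: `(n_active - 1)` times the
#' maximum observed dyadic weight (`mode = "weighted"`), or plain
#' `(n_active - 1)` for binary degrees (`mode = "binary"`).
#'
#' @param weighted Weighted contact matrix for one wave.
#' @param active Character vector (or logical mask) of active actors.
#' @param mode `"weighted"` or `"binary"`.
#' @return Data frame with `actor_id`, `outdegree`, `indegree` in [0, 1].
#' @export
normalized_weighted_degrees <- function(weighted, active = rownames(weighted),
                                        mode = c("weighted", "binary")) {
  mode <- match.arg(mode)
  if (is.logical(active)) active <- rownames(weighted)[active]
  m <- weighted[active, active, drop = FALSE]
  n <- length(active)
  if (n < 2) stop("normalized degrees undefined for fewer than 2 active actors")
  if (mode == "binary") m <- binarize(m)
  mx <- max(m)
  denom <- if (mode == "weighted") (n - 1) * max(mx, 1) else n - 1
  data.frame(actor_id = active,
             outdegree = rowSums(m) / denom,
             indegree = colSums(m) / denom,
             row.names = NULL)
}

#' Build a wave panel from an event log
#'
#' One weighted and one binary directed network per week, with composition
#' (join/leave weeks, fraction-of-week presence) taken from the actor table.
#'
#' @param log An [event_log()] of validated events.
#' @param actors An [actor_table()].
#' @param n_waves Number of weekly waves to build.
#' @param presence Optional actors x weeks numeric matrix of fractional
#'   presence (defaults to full weeks).
#' @inheritParams build_weighted_wave
#' @return A [wave_panel()].
#' @export
build_panel <- function(log, actors, n_waves, presence = NULL,
                        on_inactive = c("error", "drop")) {
  act <- presence_matrix(actors)
  ids <- actors$actor_id
  weighted <- lapply(seq_len(n_waves), function(w) {
    m <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
    aw <- ids[act[, w]]
    if (length(aw) >= 2)
      m[aw, aw] <- build_weighted_wave(log, w, aw, on_inactive)
    m
  })
  if (!is.null(presence)) presence <- presence * act
  wave_panel(weighted, act[, seq_len(n_waves), drop = FALSE], presence)
}

# ---- serialization ---------------------------------------------------------

#' Write / read a wave panel as plain-text matrices
#'
#' Each wave's weighted matrix is written as a dense CSV next to a YAML
#' manifest carrying the composition; `read_panel()` restores the object
#' losslessly.
#'
#' @param panel A [wave_panel()].
#' @param dir Output directory (created if needed).
#' @return `write_panel()` the manifest path, invisibly; `read_panel()` a
#'   [wave_panel()].
#' @export
write_panel <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("wave_%02d.csv", seq_len(panel$n_waves))
  for (w in seq_len(panel$n_waves))
    write.csv(panel$weighted[[w]], file.path(dir, files[w]))
  manifest <- list(actors = panel$actors, n_waves = panel$n_waves,
                   waves = files,
                   active = apply(panel$active, 2, as.integer,
                                  simplify = FALSE),
                   presence = apply(panel$presence, 2, as.numeric,
                                    simplify = FALSE))
  path <- file.path(dir, "panel.yaml")
  yaml::write_yaml(manifest, path)
  invisible(path)
}

#' @rdname write_panel
#' @param manifest Path to a `panel.yaml` written by `write_panel()`.
#' @export
read_panel <- function(manifest) {
  mf <- yaml::read_yaml(manifest)
  dir <- dirname(manifest)
  weighted <- lapply(mf$waves, function(f) {
    m <- as.matrix(read.csv(file.path(dir, f), row.names = 1,
                            check.names = FALSE))
    storage.mode(m) <- "integer"
    m
  })
  n <- length(mf$actors)
  active <- matrix(unlist(mf$active) == 1, nrow = n,
                   dimnames = list(mf$actors, names(mf$active)))
  presence <- matrix(as.numeric(unlist(mf$presence)), nrow = n,
                     dimnames = list(mf$actors, names(mf$presence)))
  wave_panel(weighted, active, presence)
}

#' Export panel waves as GraphML
#'
#' @param panel A [wave_panel()].
#' @param dir Output directory.
#' @return Paths of the written files, invisibly.
#' @export
export_graphml <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(panel$n_waves)
  for (w in seq_len(panel$n_waves)) {
    act <- panel$actors[panel$active[, w]]
    g <- igraph::graph_from_adjacency_matrix(
      panel$weighted[[w]][act, act, drop = FALSE],
      mode = "directed", weighted = TRUE)
    paths[w] <- file.path(dir, sprintf("wave_%02d.graphml", w))
    igraph::write_graph(g, paths[w], format = "graphml")
  }
  invisible(paths)
}
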