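#' Weekly headbutt count matrix
#'
#' @param log An [event_log()].
#' @param week Week number.
#' @param active Character vector of actor ids active that week.
#' @return Integer matrix; entry (i, j) counts headbutts i -> j.
#' @export
headbutt_matrix <- function(log, week, active) {
  ev <- log[log$behavior == "headbutt" & event_week(log) == week, ,
            drop = FALSE]
  ev <- ev[ev$actor %in% active & ev$recipient %in% active, , drop = FALSE]
  m <- matrix(0L, length(active), length(active),
              dimnames = list(active, active))
  if (nrow(ev)) {
    tab <- table(factor(ev$actor, levels = active),
                 factor(ev$recipient, levels = active))
    m <- m + unclass(tab)
    dimnames(m) <- list(active, active)
  }
  m
}

#' Dyadic dominance labels
#'
#' For every unordered pair with at least one agonistic interaction, the
#' dominant animal is the one with the higher directed headbutt count; equal
#' counts give a tied dyad.
#'
#' @param dm Headbutt count matrix (e.g. from [headbutt_matrix()]).
#' @return Data frame with columns `a`, `b`, `n_ab`, `n_ba`, `dominant`
#'   (`NA` for tied dyads).
#' @export
dyadic_dominance <- function(dm) {
  ids <- rownames(dm)
  n <- length(ids)
  out <- list()
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    nab <- dm[i, j]; nba <- dm[j, i]
    if (nab + nba == 0) next
    out[[length(out) + 1]] <- data.frame(
      a = ids[i], b = ids[j], n_ab = nab, n_ba = nba,
      dominant = if (nab > nba) ids[i] else if (nba > nab) ids[j]
        else NA_character_)
  }
  if (!length(out))
    return(data.frame(a = character(), b = character(), n_ab = integer(),
                      n_ba = integer(), dominant = character()))
  do.call(rbind, out)
}

#' Lamprecht dominance index and rank class
#'
#' DI = number of subordinates / number of interaction partners, with rank
#' classes low (DI < 0.40), medium (0.40 <= DI < 0.60) and high (DI >= 0.60).
#' By default a tied dyad counts toward an animal's partners but not its
#' subordinates; `tie_credit = "half"` awards half a subordinate instead.
#'
#' @param labels Dyadic labels from [dyadic_dominance()].
#' @param actors Actor ids to report (default: all appearing in `labels`).
#' @param week Week number recorded in the output.
#' @param tie_credit `"none"` (default) or `"half"`.
#' @return Data frame with `actor_id`, `week`, `n_subordinates`,
#'   `n_partners`, `di`, `rank_class` (`NA` where no partners).
#' @export
dominance_index <- function(labels, actors = NULL, week = NA_integer_,
                            tie_credit = c("none", "half")) {
  tie_credit <- match.arg(tie_credit)
  if (is.null(actors)) actors <- sort(unique(c(labels$a, labels$b)))
  res <- lapply(actors, function(id) {
    mine <- labels[labels$a == id | labels$b == id, , drop = FALSE]
    partners <- nrow(mine)
    subs <- sum(!is.na(mine$dominant) & mine$dominant == id)
    if (tie_credit == "half") subs <- subs + sum(is.na(mine$dominant)) / 2
    di <- if (partners > 0) subs / partners else NA_real_
    data.frame(actor_id = id, week = week, n_subordinates = subs,
               n_partners = partners, di = di,
               rank_class = rank_class(di))
  })
  do.call(rbind, res)
}

#' @rdname dominance_index
#' @param di Dominance index value(s).
#' @export
rank_class <- function(di) {
  ifelse(is.na(di), NA_character_,
         ifelse(di < 0.40, "low", ifelse(di < 0.60, "medium", "high")))
}

#' Weekly rank records for a study
#'
#' Computes [dyadic_dominance()] and [dominance_index()] per week over the
#' actors active that week.
#'
#' @param log An [event_log()] containing headbutt events.
#' @param actors An [actor_table()].
#' @param n_waves Number of weeks.
#' @inheritParams dominance_index
#' @return Data frame of weekly rank records (one row per actor-week).
#' @export
rank_table <- function(log, actors, n_waves, tie_credit = c("none", "half")) {
  tie_credit <- match.arg(tie_credit)
  act <- presence_matrix(actors)
  out <- lapply(seq_len(n_waves), function(w) {
    ids <- actors$actor_id[act[, w]]
    dm <- headbutt_matrix(log, w, ids)
    dominance_index(dyadic_dominance(dm), actors = ids, week = w,
                    tie_credit = tie_credit)
  })
  do.call(rbind, out)
}

#' Across-week stability of the dominance index
#'
#' ICC(A,k) of the actors x weeks DI matrix (complete cases only).
#'
#' @param ranks Weekly rank records from [rank_table()].
#' @return The result of [icc_absolute_agreement()] plus the DI matrix used.
#' @export
di_stability <- function(ranks) {
  wk <- sort(unique(ranks$week))
  ids <- sort(unique(ranks$actor_id))
  m <- matrix(NA_real_, length(ids), length(wk), dimnames = list(ids, wk))
  m[cbind(match(ranks$actor_id, ids), match(ranks$week, wk))] <- ranks$di
  m <- m[complete.cases(m), , drop = FALSE]
  if (nrow(m) < 2)
    stop("DI stability undefined: fewer than 2 complete-case actors")
  res <- icc_absolute_agreement(m)
  res$di_matrix <- m
  res
}

#' Summarise per-actor social rank for use as a model covariate
#'
#' @param ranks Weekly rank records from [rank_table()].
#' @param type `"di"` for the mean weekly dominance index (continuous), or
#'   `"class"` for the modal rank class coded low = 1, medium = 2, high = 3.
#' @return Named numeric vector by actor id.
#' @export
social_rank_covariate <- function(ranks, type = c("di", "class")) {
  type <- match.arg(type)
  sp <- split(ranks, ranks$actor_id)
  vapply(sp, function(d) {
    di <- mean(d$di, na.rm = TRUE)
    if (type == "di") di else
      as.numeric(c(low = 1, medium = 2, high = 3)[rank_class(di)])
  }, 0)
}
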