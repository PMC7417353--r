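#' Configuration for the synthetic herd generator
#'
#' Defaults emulate the observed study group: 38 Holstein cows aged
#' 2.5-10.2 years (mean 4.5, SD 1.9) entering a postpartum paddock on a
#' staggered weekly schedule (25, then 7, 1, 5, 0, 0), observed over 6
#' weekly waves of directed grooming networks, with weekly headbutt logs
#' inducing a stable age-related hierarchy. The default evaluation
#' parameters carry the signs and magnitudes of the fitted herd model
#' (outdegree -1.965, reciprocity 1.118, and so on).
#'
#' @param n_actors Herd size.
#' @param n_waves Number of weekly waves.
#' @param entry_schedule Per-wave counts of cows joining (must sum to
#'   `n_actors`).
#' @param age_law `c(mean, sd, min, max)` in years of the truncated-normal
#'   age distribution.
#' @param beta_true Named list/vector of true evaluation parameters (names
#'   from [saom_effect_names()]; `cov_*` names take the form
#'   `"cov_ego.age"`).
#' @param rate_true Per-period basic change rates.
#' @param rate_outdegree_alpha Outdegree effect on the rate function.
#' @param bout_mean Mean number of extra grooming bouts per realized
#'   tie-week (each tie yields `1 + Poisson(bout_mean)` events).
#' @param headbutt_mean Mean headbutts per co-present dyad-week.
#' @param hierarchy_steepness Steepness kappa of the logistic initiator
#'   probability in agonistic encounters.
#' @param rank_noise_sd SD of the Gaussian noise on standardized age in the
#'   latent rank.
#' @param oestrus_prob Weekly probability an actor is in oestrus.
#' @param density_target Tie probability of the wave-1 seed network.
#' @param seed Integer seed; all generation is deterministic given it.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_actors = 38, n_waves = 6,
                         entry_schedule = c(25, 7, 1, 5, 0, 0),
                         age_law = c(mean = 4.5, sd = 1.9,
                                     min = 2.5, max = 10.2),
                         beta_true = c(outdegree = -1.965,
                                       reciprocity = 1.118,
                                       transitive_triplets = 0.133,
                                       outdegree_popularity_sqrt = -0.162,
                                       outdegree_activity_sqrt = 0.233,
                                       cov_ego.age = 0.101,
                                       cov_alter.age = 0.046,
                                       cov_similarity.age = 1.044),
                         rate_true = rep(6, 5),
                         rate_outdegree_alpha = 0,
                         bout_mean = 0.2, headbutt_mean = 0.5,
                         hierarchy_steepness = 3, rank_noise_sd = 0.5,
                         oestrus_prob = 0.15, density_target = 0.25,
                         seed = 1L) {
  if (length(entry_schedule) != n_waves)
    stop("entry_schedule must have one entry per wave")
  if (sum(entry_schedule) != n_actors)
    stop("entry_schedule must sum to n_actors")
  if (any(rate_true <= 0)) stop("all rates must be positive")
  if (length(rate_true) != n_waves - 1)
    rate_true <- rep(rate_true, length.out = n_waves - 1)
  stopifnot(age_law["min"] < age_law["max"], age_law["sd"] > 0,
            bout_mean >= 0, headbutt_mean >= 0, hierarchy_steepness >= 0,
            oestrus_prob >= 0, oestrus_prob <= 1,
            density_target >= 0, density_target <= 1)
  structure(list(n_actors = n_actors, n_waves = n_waves,
                 entry_schedule = entry_schedule, age_law = age_law,
                 beta_true = beta_true, rate_true = rate_true,
                 rate_outdegree_alpha = rate_outdegree_alpha,
                 bout_mean = bout_mean, headbutt_mean = headbutt_mean,
                 hierarchy_steepness = hierarchy_steepness,
                 rank_noise_sd = rank_noise_sd,
                 oestrus_prob = oestrus_prob,
                 density_target = density_target,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# translate a beta_true vector like c(outdegree = -2, cov_ego.age = 0.1)
# into a model_spec over the given covariates
spec_from_beta <- function(config, covariates = list()) {
  nm <- names(config$beta_true)
  effects <- lapply(seq_along(nm), function(k) {
    parts <- strsplit(nm[k], ".", fixed = TRUE)[[1]]
    saom_effect(parts[1], covariate = if (length(parts) > 1) parts[2],
                param = as.numeric(config$beta_true[k]))
  })
  model_spec(effects, rates = config$rate_true, covariates = covariates,
             rate_outdegree = if (config$rate_outdegree_alpha != 0)
               config$rate_outdegree_alpha)
}

#' Generate a synthetic cohort
#'
#' Ages are drawn from a truncated normal with the configured moments and
#' bounds (inverse-CDF sampling, so every age respects the bounds exactly);
#' entry weeks follow the entry schedule; the weekly oestrus indicator is an
#' independent Bernoulli per actor-week.
#'
#' @param config A [synth_config()].
#' @return An [actor_table()] with oestrus indicator columns.
#' @export
gen_cohort <- function(config) {
  set.seed(config$seed)
  n <- config$n_actors
  W <- config$n_waves
  al <- config$age_law
  # location chosen so the TRUNCATED distribution has the target mean
  # (truncating an asymmetric window shifts the mean upward otherwise)
  trunc_mean <- function(mu) {
    a <- (al["min"] - mu) / al["sd"]
    b <- (al["max"] - mu) / al["sd"]
    mu + al["sd"] * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
  }
  mu <- stats::uniroot(function(m) trunc_mean(m) - al["mean"],
                       interval = al["mean"] + c(-3, 1) * al["sd"])$root
  plo <- pnorm(al["min"], mu, al["sd"])
  phi <- pnorm(al["max"], mu, al["sd"])
  ages <- qnorm(runif(n, plo, phi), mu, al["sd"])
  entry <- rep(seq_len(W), times = config$entry_schedule)
  df <- data.frame(actor_id = sprintf("cow%02d", seq_len(n)),
                   age = as.numeric(ages), entry_week = entry)
  oe <- matrix(rbinom(n * W, 1, config$oestrus_prob), n, W)
  colnames(oe) <- paste0("oestrus_w", seq_len(W))
  df <- cbind(df, oe)
  tab <- actor_table(df, W)
  # oestrus only meaningful while present
  pm <- presence_matrix(tab)
  for (w in seq_len(W)) tab[[paste0("oestrus_w", w)]][!pm[, w]] <- 0L
  tab
}

#' Latent dominance rank of a synthetic cohort
#'
#' Standardized age plus Gaussian noise: older cows tend to rank higher, as
#' hierarchies in closed dairy herds are strongly age-related.
#'
#' @param actors An [actor_table()].
#' @param config A [synth_config()].
#' @return Named numeric vector of latent ranks.
#' @export
gen_latent_rank <- function(actors, config) {
  set.seed(config$seed + 1L)
  z <- as.numeric(scale(actors$age))
  stats::setNames(z + rnorm(nrow(actors), 0, config$rank_noise_sd),
                  actors$actor_id)
}

#' Generate a synthetic headbutt log
#'
#' Each co-present dyad-week receives a Poisson(`headbutt_mean`) number of
#' headbutts; each event is initiated by the higher-ranked animal with
#' probability `plogis(kappa * (rank_i - rank_j))`. Timestamps fall inside
#' the daily observation blocks of the week.
#'
#' @param actors An [actor_table()].
#' @param latent_rank Named rank vector (see [gen_latent_rank()]).
#' @param config A [synth_config()].
#' @param study_start Date of the week-1 Monday.
#' @return An [event_log()] of headbutt events.
#' @export
gen_headbutt_log <- function(actors, latent_rank, config,
                             study_start = as.Date("2026-02-02")) {
  set.seed(config$seed + 2L)
  W <- config$n_waves
  pm <- presence_matrix(actors)
  ids <- actors$actor_id
  rows <- list()
  for (w in seq_len(W)) {
    present <- ids[pm[, w]]
    if (length(present) < 2) next
    for (i in seq_len(length(present) - 1))
      for (j in seq(i + 1, length(present))) {
        a <- present[i]; b <- present[j]
        ne <- rpois(1, config$headbutt_mean)
        if (ne == 0) next
        p_a <- plogis(config$hierarchy_steepness *
                        (latent_rank[a] - latent_rank[b]))
        init_a <- rbinom(ne, 1, p_a) == 1
        rows[[length(rows) + 1]] <- data.frame(
          actor = ifelse(init_a, a, b),
          recipient = ifelse(init_a, b, a),
          behavior = "headbutt",
          timestamp = observation_times(ne, w, study_start),
          session = sprintf("w%d", w))
      }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(actor = character(), recipient = character(),
               behavior = character(), timestamp = as.POSIXct(character()),
               session = character())
  df <- df[order(df$timestamp), , drop = FALSE]
  event_log(df, study_start)
}

# uniform timestamps inside the observation schedule of week w: 5 days,
# two daily blocks (09:00-12:00, 18:00-21:00), each four 30-min periods
# separated by 20-min breaks
observation_times <- function(n, week, study_start) {
  day <- sample.int(5, n, replace = TRUE)
  block <- sample(c(9, 18), n, replace = TRUE) # block start hour
  per <- sample.int(4, n, replace = TRUE)      # 30-min period within block
  within <- runif(n, 0, 30 * 60)
  date <- study_start + (week - 1) * 7 + (day - 1)
  as.POSIXct(paste(date, "00:00:00"), tz = "UTC") +
    block * 3600 + (per - 1) * 50 * 60 + within
}

#' Generate a seed network
#'
#' Each ordered non-self pair of active actors is tied independently with
#' probability `density_target`.
#'
#' @param active Character vector of actor ids.
#' @param density_target Tie probability.
#' @param seed Integer seed.
#' @return Binary adjacency matrix over `active`.
#' @export
gen_initial_network <- function(active, density_target, seed = 1L) {
  stopifnot(density_target >= 0, density_target <= 1)
  set.seed(seed)
  n <- length(active)
  m <- matrix(rbinom(n * n, 1, density_target), n, n,
              dimnames = list(active, active))
  diag(m) <- 0L
  storage.mode(m) <- "integer"
  m
}

#' Generate a synthetic wave panel from ground truth
#'
#' Wave 1 is a seed network over the initially present cows; waves 2..W are
#' produced by the actor-oriented micro-step simulator under the true
#' parameters. Joiners enter with no ties at their entry wave.
#'
#' @param actors An [actor_table()].
#' @param config A [synth_config()].
#' @param covariates Named list of covariates referenced by
#'   `config$beta_true` (default: `age` from the actor table).
#' @param x1 Optional wave-1 binary matrix over the initially present cows
#'   (generated at `density_target` if omitted).
#' @return A list with `panel` (a [wave_panel()]) and `spec` (the
#'   ground-truth [model_spec()]).
#' @export
gen_wave_panel <- function(actors, config, covariates = NULL, x1 = NULL) {
  set.seed(config$seed + 3L)
  W <- config$n_waves
  ids <- actors$actor_id
  pm <- presence_matrix(actors)
  if (is.null(covariates))
    covariates <- list(age = stats::setNames(actors$age, ids))
  spec <- spec_from_beta(config, covariates)
  first <- ids[pm[, 1]]
  if (is.null(x1))
    x1 <- gen_initial_network(first, config$density_target,
                              seed = config$seed + 4L)
  waves <- vector("list", W)
  full <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  waves[[1]] <- full
  waves[[1]][first, first] <- x1
  for (m in seq_len(W - 1)) {
    act <- ids[pm[, m + 1]]
    x0 <- waves[[m]][act, act, drop = FALSE]
    joiners <- setdiff(act, ids[pm[, m]])
    x0[joiners, ] <- 0L
    x0[, joiners] <- 0L
    sp <- spec
    sp$rates <- config$rate_true[m]
    out <- simulate_period(x0, sp, m = m)
    waves[[m + 1]] <- full
    waves[[m + 1]][act, act] <- out$x
  }
  panel <- wave_panel(waves, pm)
  list(panel = panel, spec = spec)
}

#' Generate a synthetic grooming event log from a panel
#'
#' Every tie i -> j present in week w yields `1 + Poisson(bout_mean)`
#' grooming events (so binarization is invertible); non-ties yield none.
#' Timestamps are uniform over the week's observation schedule.
#'
#' @param panel A [wave_panel()].
#' @param config A [synth_config()].
#' @param study_start Date of the week-1 Monday.
#' @return An [event_log()] of grooming events; rebuilding a panel from it
#'   reproduces `panel`'s binary waves exactly.
#' @export
gen_grooming_log <- function(panel, config,
                             study_start = as.Date("2026-02-02")) {
  set.seed(config$seed + 5L)
  rows <- list()
  for (w in seq_len(panel$n_waves)) {
    x <- panel$binary[[w]]
    idx <- which(x == 1, arr.ind = TRUE)
    if (!nrow(idx)) next
    for (r in seq_len(nrow(idx))) {
      ne <- 1 + rpois(1, config$bout_mean)
      rows[[length(rows) + 1]] <- data.frame(
        actor = panel$actors[idx[r, 1]],
        recipient = panel$actors[idx[r, 2]],
        behavior = "groom",
        timestamp = observation_times(ne, w, study_start),
        session = sprintf("w%d", w))
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(actor = character(), recipient = character(),
               behavior = character(), timestamp = as.POSIXct(character()),
               session = character())
  df <- df[order(df$timestamp), , drop = FALSE]
  event_log(df, study_start)
}

#' Generate a complete synthetic study
#'
#' Cohort, latent hierarchy, ground-truth wave panel, grooming log and
#' headbutt log in one call.
#'
#' @param config A [synth_config()].
#' @param study_start Date of the week-1 Monday.
#' @return List with `actors`, `latent_rank`, `panel`, `spec` (ground-truth
#'   parameters), `grooming`, `headbutts`, `config`, `study_start`.
#' @export
synthesize_study <- function(config = synth_config(),
                             study_start = as.Date("2026-02-02")) {
  actors <- gen_cohort(config)
  rank <- gen_latent_rank(actors, config)
  gp <- gen_wave_panel(actors, config)
  groom <- gen_grooming_log(gp$panel, config, study_start)
  hb <- gen_headbutt_log(actors, rank, config, study_start)
  list(actors = actors, latent_rank = rank, panel = gp$panel,
       spec = gp$spec, grooming = groom, headbutts = hb,
       config = config, study_start = study_start)
}

#' Write the synthetic study inputs as CSV
#'
#' @param study Result of [synthesize_study()].
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(as.data.frame(study$actors),
            file.path(dir, "actors.csv"), row.names = FALSE)
  write_event_log(study$grooming, file.path(dir, "grooming.csv"))
  write_event_log(study$headbutts, file.path(dir, "headbutts.csv"))
  invisible(dir)
}
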