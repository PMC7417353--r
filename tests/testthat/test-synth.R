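test_that("cohorts respect the entry schedule and age law", {
  cfg <- synth_config(seed = 2)
  tab <- gen_cohort(cfg)
  expect_equal(nrow(tab), 38)
  expect_equal(as.vector(table(factor(tab$entry_week, levels = 1:6))),
               c(25, 7, 1, 5, 0, 0))
  expect_true(all(tab$age >= 2.5 & tab$age <= 10.2))
  expect_identical(gen_cohort(cfg), tab) # deterministic under the seed

  one <- synth_config(n_actors = 1, n_waves = 1, entry_schedule = 1,
                      rate_true = 1, seed = 2)
  t1 <- gen_cohort(one)
  expect_equal(nrow(t1), 1)
  expect_equal(t1$entry_week, 1)
  expect_error(synth_config(n_actors = 10, entry_schedule = c(5, 5)),
               "one entry per wave")
  expect_error(synth_config(n_actors = 10, n_waves = 2,
                            entry_schedule = c(5, 4), rate_true = 3),
               "sum to n_actors")
  # truncated-normal moments: large cohort mean near 4.5
  big <- synth_config(n_actors = 2000, n_waves = 1, entry_schedule = 2000,
                      rate_true = 1, seed = 8)
  ages <- gen_cohort(big)$age
  expect_lt(abs(mean(ages) - 4.5), 0.25)
})

test_that("headbutt logs follow the logistic initiator model", {
  cfg <- synth_config(n_actors = 2, n_waves = 1, entry_schedule = 2,
                      rate_true = 1, headbutt_mean = 30,
                      hierarchy_steepness = 50, seed = 5)
  actors <- gen_cohort(cfg)
  rank <- stats::setNames(c(2, -2), actors$actor_id)
  hb <- gen_headbutt_log(actors, rank, cfg)
  # near-infinite steepness: the higher-ranked cow initiates everything
  expect_true(all(hb$actor == actors$actor_id[1]))

  # kappa = 0: initiator is a fair coin
  cfg0 <- synth_config(n_actors = 2, n_waves = 1, entry_schedule = 2,
                       rate_true = 1, headbutt_mean = 400,
                       hierarchy_steepness = 0, seed = 6)
  hb0 <- gen_headbutt_log(actors, rank, cfg0)
  n <- nrow(hb0)
  share <- mean(hb0$actor == actors$actor_id[1])
  expect_lt(abs(share - 0.5), 3 * sqrt(0.25 / n))

  cfg_none <- synth_config(n_actors = 2, n_waves = 1, entry_schedule = 2,
                           rate_true = 1, headbutt_mean = 0, seed = 7)
  expect_equal(nrow(gen_headbutt_log(actors, rank, cfg_none)), 0)
})

test_that("seed networks hit their density targets", {
  acts <- sprintf("a%02d", 1:25)
  expect_equal(sum(gen_initial_network(acts, 0, seed = 1)), 0)
  full <- gen_initial_network(acts, 1, seed = 1)
  expect_equal(sum(full), 25 * 24)
  expect_equal(net_density(full), 1)
  # binomial mean: 200 seeds at p = 0.25 average 150 ties within 3 SE
  ties <- vapply(1:200, function(s)
    sum(gen_initial_network(acts, 0.25, seed = s)), 0)
  se <- sqrt(600 * 0.25 * 0.75 / 200)
  expect_lt(abs(mean(ties) - 150), 3 * se)
})

test_that("wave panels degenerate correctly at extreme parameters", {
  herd <- closed_herd(10, 3)
  # negligible change rates: every wave equals wave 1
  cfg <- synth_config(n_actors = 10, n_waves = 3,
                      entry_schedule = c(10, 0, 0),
                      beta_true = c(outdegree = -1), rate_true = rep(1e-9, 2),
                      seed = 9)
  gp <- gen_wave_panel(herd, cfg)
  expect_identical(gp$panel$binary[[2]], gp$panel$binary[[1]])
  expect_identical(gp$panel$binary[[3]], gp$panel$binary[[1]])

  # strongly negative outdegree: densities decay toward zero in expectation
  dens <- replicate(60, {
    s <- sample.int(1e6, 1)
    cfgd <- synth_config(n_actors = 10, n_waves = 3,
                         entry_schedule = c(10, 0, 0),
                         beta_true = c(outdegree = -10),
                         rate_true = rep(4, 2), density_target = 0.5,
                         seed = s)
    p <- gen_wave_panel(herd, cfgd)$panel
    vapply(p$binary, function(x) net_density(x), 0)
  })
  means <- rowMeans(dens)
  expect_true(all(diff(means) < 0))
  expect_lt(means[3], 0.1)
})

test_that("joiners enter with no ties at their entry wave", {
  cfg <- synth_config(n_actors = 12, n_waves = 4,
                      entry_schedule = c(8, 0, 4, 0),
                      beta_true = c(outdegree = -1.5, reciprocity = 0.8),
                      rate_true = rep(3, 3), seed = 10)
  st <- synthesize_study(cfg)
  joiners <- st$actors$actor_id[st$actors$entry_week == 3]
  for (w in 1:2) {
    expect_equal(sum(st$panel$binary[[w]][joiners, ]), 0)
    expect_equal(sum(st$panel$binary[[w]][, joiners]), 0)
  }
})

test_that("grooming logs invert binarization exactly", {
  cfg <- synth_config(n_actors = 15, n_waves = 4,
                      entry_schedule = c(10, 3, 2, 0),
                      beta_true = c(outdegree = -1.8, reciprocity = 1),
                      rate_true = rep(4, 3), bout_mean = 0.4, seed = 12)
  st <- synthesize_study(cfg)
  rebuilt <- build_panel(st$grooming, st$actors, cfg$n_waves)
  expect_identical(lapply(rebuilt$binary, unname),
                   lapply(st$panel$binary, unname))
  # bout_mean = 0: exactly one event per tie-week, weights equal the binary
  cfg0 <- synth_config(n_actors = 15, n_waves = 4,
                       entry_schedule = c(10, 3, 2, 0),
                       beta_true = c(outdegree = -1.8, reciprocity = 1),
                       rate_true = rep(4, 3), bout_mean = 0, seed = 12)
  st0 <- synthesize_study(cfg0)
  rebuilt0 <- build_panel(st0$grooming, st0$actors, cfg0$n_waves)
  expect_identical(lapply(rebuilt0$weighted, function(m) unname(binarize(m))),
                   lapply(rebuilt0$weighted, unname))
  expect_equal(nrow(st0$grooming),
               sum(vapply(st0$panel$binary, sum, 0)))
  # an empty panel yields an empty log
  acts <- c("A", "B")
  active <- matrix(TRUE, 2, 1, dimnames = list(acts, "w1"))
  blank <- wave_panel(list(matrix(0L, 2, 2, dimnames = list(acts, acts))),
                      active)
  expect_equal(nrow(gen_grooming_log(blank, cfg0)), 0)
})

test_that("paper-shaped panels keep densities inside the sanity envelope", {
  # the envelope is a property of the generating process: per-wave expected
  # densities (seed-averaged) stay in [0.10, 0.35]; single realized waves
  # scatter around them and must stay clear of degeneration
  D <- sapply(1:8, function(s)
    summarize_panel(synthesize_study(synth_config(seed = 20 + s))$panel)$
      waves$density)
  expect_true(all(rowMeans(D) >= 0.10 & rowMeans(D) <= 0.35),
              label = paste("mean densities",
                            paste(round(rowMeans(D), 3), collapse = " ")))
  expect_true(all(D > 0.05 & D < 0.40))
})

test_that("event timestamps respect the observation schedule", {
  cfg <- synth_config(seed = 33)
  st <- synthesize_study(cfg)
  for (log in list(st$grooming, st$headbutts)) {
    lt <- as.POSIXlt(log$timestamp)
    expect_true(all(lt$wday %in% 1:5)) # five observation days per week
    hrs <- lt$hour + lt$min / 60
    in_morning <- hrs >= 9 & hrs < 12
    in_evening <- hrs >= 18 & hrs < 21
    expect_true(all(in_morning | in_evening))
  }
})
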