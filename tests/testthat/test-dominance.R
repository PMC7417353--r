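test_that("dyadic dominance assigns the higher headbutt count as dominant", {
  acts <- c("A", "B", "C")
  dm <- matrix(0L, 3, 3, dimnames = list(acts, acts))
  dm["A", "B"] <- 3; dm["B", "A"] <- 1
  dm["B", "C"] <- 2; dm["C", "B"] <- 2
  lab <- dyadic_dominance(dm)
  expect_equal(nrow(lab), 2)
  expect_equal(lab$dominant[lab$a == "A" & lab$b == "B"], "A")
  expect_true(is.na(lab$dominant[lab$a == "B" & lab$b == "C"]))
  expect_equal(nrow(dyadic_dominance(dm * 0L)), 0)
})

test_that("dominance index and rank classes follow the boundary table", {
  # 3 subordinates of 4 partners -> 0.75 -> high
  acts <- paste0("c", 1:5)
  dm <- matrix(0L, 5, 5, dimnames = list(acts, acts))
  dm["c1", c("c2", "c3", "c4")] <- 2 # c1 dominates three
  dm["c5", "c1"] <- 1                # and is dominated by c5
  di <- dominance_index(dyadic_dominance(dm))
  r1 <- di[di$actor_id == "c1", ]
  expect_equal(r1$n_partners, 4)
  expect_equal(r1$n_subordinates, 3)
  expect_equal(r1$di, 0.75)
  expect_equal(r1$rank_class, "high")
  # 0 subordinates of 5 -> 0 -> low
  dm2 <- matrix(0L, 6, 6, dimnames = list(paste0("c", 1:6), paste0("c", 1:6)))
  dm2[paste0("c", 2:6), "c1"] <- 1
  di2 <- dominance_index(dyadic_dominance(dm2))
  expect_equal(di2$di[di2$actor_id == "c1"], 0)
  expect_equal(di2$rank_class[di2$actor_id == "c1"], "low")
  # exact boundaries
  expect_equal(rank_class(0.399), "low")
  expect_equal(rank_class(0.40), "medium")
  expect_equal(rank_class(0.599), "medium")
  expect_equal(rank_class(0.60), "high")
})

test_that("tied dyads count as partners but not subordinates by default", {
  acts <- c("A", "B", "C")
  dm <- matrix(0L, 3, 3, dimnames = list(acts, acts))
  dm["A", "B"] <- 2; dm["B", "A"] <- 2 # tied
  dm["A", "C"] <- 1                    # A dominates C
  di <- dominance_index(dyadic_dominance(dm))
  a <- di[di$actor_id == "A", ]
  expect_equal(a$n_partners, 2)
  expect_equal(a$n_subordinates, 1)
  expect_equal(a$di, 0.5)
  half <- dominance_index(dyadic_dominance(dm), tie_credit = "half")
  expect_equal(half$di[half$actor_id == "A"], 0.75)
  # an actor with no interactions has undefined DI
  di_all <- dominance_index(dyadic_dominance(dm), actors = acts)
  expect_true(all(!is.na(di_all$di)))
  dm0 <- dm * 0L
  di0 <- dominance_index(dyadic_dominance(dm0), actors = acts)
  expect_true(all(is.na(di0$di)))
})

test_that("ICC(A,k) matches a direct two-way ANOVA oracle", {
  set.seed(21)
  m <- matrix(rnorm(18, rep(c(10, 12, 14, 16, 18, 20), 3)), 6, 3)
  res <- icc_absolute_agreement(m)
  # oracle: mean squares straight from aov()
  df <- data.frame(y = as.vector(m),
                   subj = factor(rep(1:6, 3)),
                   rater = factor(rep(1:3, each = 6)))
  av <- summary(stats::aov(y ~ subj + rater, data = df))[[1]]
  MSR <- av["subj", "Mean Sq"]; MSC <- av["rater", "Mean Sq"]
  MSE <- av["Residuals", "Mean Sq"]
  icc_oracle <- (MSR - MSE) / (MSR + (MSC - MSE) / 6)
  expect_equal(res$icc, icc_oracle, tolerance = 1e-10)
  expect_equal(unname(res$ms["MSR"]), MSR, tolerance = 1e-10)
  expect_equal(res$F, MSR / MSE, tolerance = 1e-10)
  expect_true(res$ci95[1] <= res$icc && res$icc <= res$ci95[2])
})

test_that("ICC degenerate and invariance cases behave", {
  # identical raters, varying subjects: exactly 1
  m <- matrix(rep(c(1, 5, 9, 13), 3), 4, 3)
  expect_identical(icc_absolute_agreement(m)$icc, 1)
  # adding a constant changes nothing
  set.seed(4)
  m2 <- matrix(rnorm(20, rep(1:5, 4)), 5, 4)
  expect_equal(icc_absolute_agreement(m2)$icc,
               icc_absolute_agreement(m2 + 100)$icc, tolerance = 1e-12)
  # no between-subject variance: undefined, flagged
  flat <- matrix(2, 3, 3)
  expect_warning(res <- icc_absolute_agreement(flat), "undefined")
  expect_true(is.na(res$icc))
  # pure-noise raters: ICC near zero in expectation (the single-rating
  # form averages stably; the mean-rating form is checked by its median
  # because its small-sample distribution is heavy-tailed below zero)
  set.seed(9)
  res <- replicate(500, {
    r <- icc_absolute_agreement(matrix(rnorm(60), 20, 3))
    c(r$icc_single, r$icc)
  })
  expect_lt(abs(mean(res[1, ])), 0.05)
  expect_lt(abs(median(res[2, ])), 0.1)
})

test_that("DI stability ICC separates stable from shuffled hierarchies", {
  set.seed(31)
  di <- matrix(rep(seq(0.1, 0.9, length.out = 10), 4), 10, 4)
  stable <- di_stability(data.frame(actor_id = rep(paste0("c", 1:10), 4),
                                    week = rep(1:4, each = 10),
                                    di = as.vector(di)))
  expect_equal(stable$icc, 1)
  shuffled <- di
  for (w in 2:4) shuffled[, w] <- sample(shuffled[, w])
  sh <- di_stability(data.frame(actor_id = rep(paste0("c", 1:10), 4),
                                week = rep(1:4, each = 10),
                                di = as.vector(shuffled)))
  expect_lt(sh$icc, 0.5)
})

test_that("synthetic hierarchies yield rank-correlated, stable DI", {
  # steep hierarchies: DI tracks latent rank and is stable across weeks
  rhos <- iccs <- numeric(5)
  for (s in 1:5) {
    cfg <- synth_config(n_actors = 20, n_waves = 4,
                        entry_schedule = c(20, 0, 0, 0),
                        rate_true = rep(4, 3),
                        beta_true = c(outdegree = -2, reciprocity = 1),
                        hierarchy_steepness = 5, headbutt_mean = 1,
                        seed = 40 + s)
    actors <- gen_cohort(cfg)
    rank <- gen_latent_rank(actors, cfg)
    hb <- gen_headbutt_log(actors, rank, cfg)
    ranks <- rank_table(hb, actors, cfg$n_waves)
    sr <- social_rank_covariate(ranks)
    rhos[s] <- cor(sr[names(rank)], rank, method = "spearman",
                   use = "complete.obs")
    iccs[s] <- di_stability(ranks)$icc
  }
  expect_gt(mean(rhos), 0.5)
  expect_gt(mean(iccs), 0.7)
})
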