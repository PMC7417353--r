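test_that("effect statistics match hand enumerations", {
  acts <- c("A", "B", "C")
  x <- adj(list(c("A", "B"), c("B", "A"), c("A", "C")), acts)
  expect_equal(effect_statistic("reciprocity", 1, x), 1)
  expect_equal(effect_statistic("outdegree", 1, x), 2)

  x2 <- adj(list(c("A", "B"), c("B", "C"), c("A", "C")), acts)
  expect_equal(effect_statistic("transitive_triplets", 1, x2), 1)
  expect_equal(effect_statistic("transitive_triplets", 2, x2), 0)

  empty <- x * 0L
  for (nm in setdiff(saom_effect_names(),
                     c("cov_ego", "cov_alter", "cov_same", "cov_similarity",
                       "same_cov_x_reciprocity")))
    expect_equal(effect_statistic(nm, 2, empty), 0)
  v <- c(1, 2, 3)
  for (nm in c("cov_alter", "cov_same", "cov_similarity",
               "same_cov_x_reciprocity"))
    expect_equal(effect_statistic(nm, 2, empty, v = v), 0)
})

test_that("every statistic matches the brute-force oracle on random graphs", {
  set.seed(77)
  cov_effects <- c("cov_ego", "cov_alter", "cov_same", "cov_similarity",
                   "same_cov_x_reciprocity")
  for (rep in 1:40) {
    n <- sample(3:7, 1)
    x <- random_digraph(n, runif(1, 0.2, 0.6))
    v <- sample(1:3, n, replace = TRUE)
    vc <- v - mean(v)
    for (nm in saom_effect_names()) {
      vv <- if (nm %in% c("cov_ego", "cov_alter")) vc else v
      for (i in seq_len(n)) {
        got <- effect_statistic(nm, i, x,
                                v = if (nm %in% cov_effects) vv)
        want <- brute_effect_statistic(nm, i, x,
                                       v = if (nm %in% cov_effects) vv)
        expect_equal(got, want, tolerance = 1e-12,
                     label = sprintf("%s actor %d", nm, i))
      }
    }
  }
})

test_that("statistics are permutation-equivariant", {
  set.seed(13)
  for (rep in 1:10) {
    n <- 6
    x <- random_digraph(n, 0.4)
    v <- runif(n)
    perm <- sample(n)
    xp <- x[perm, perm]
    vp <- v[perm]
    for (nm in c("reciprocity", "transitive_triplets", "three_cycles",
                 "indegree_popularity", "out_out_assortativity",
                 "cov_similarity")) {
      for (i in seq_len(n)) {
        a <- effect_statistic(nm, perm[i], x, v = v)
        b <- effect_statistic(nm, i, xp, v = vp)
        expect_equal(a, b, tolerance = 1e-12)
      }
    }
  }
})

test_that("similarity totals are invariant to affine covariate transforms", {
  set.seed(19)
  x <- random_digraph(8, 0.4)
  v <- runif(8, 2, 10)
  tot <- function(vv) sum(vapply(1:8, function(i)
    effect_statistic("cov_similarity", i, x, v = vv), 0))
  expect_equal(tot(v), tot(2.5 * v - 7), tolerance = 1e-10)
})

test_that("evaluation and rate functions combine statistics linearly", {
  acts <- c("A", "B", "C")
  x <- adj(list(c("A", "B"), c("B", "A"), c("A", "C")), acts)
  spec <- model_spec(list(saom_effect("outdegree", param = -2),
                          saom_effect("reciprocity", param = 1)),
                     rates = 2)
  # actor A: outdeg 2, one reciprocated tie -> f = -4 + 1 = -3
  expect_equal(evaluation_fn(1, x, spec), -3)
  zero <- model_spec(list(saom_effect("outdegree", param = 0),
                          saom_effect("reciprocity", param = 0)), rates = 2)
  expect_equal(evaluation_fn(1, x, zero), 0)

  expect_equal(rate_fn(1, x, 1, spec), 2)
  spec_a <- model_spec(list(saom_effect("outdegree", param = 0)),
                       rates = 2, rate_outdegree = 0.1)
  expect_equal(rate_fn(1, x, 1, spec_a) / rate_fn(3, x, 1, spec_a),
               exp(0.1 * 2)) # outdeg 2 vs 0
  expect_equal(rate_fn(1, x, 1, spec, presence = c(0, 1, 1)), 0)
  # fractional presence scales the rate proportionally
  expect_equal(rate_fn(1, x, 1, spec, presence = c(0.4, 1, 1)), 2 * 0.4)
})

test_that("model_spec validates its invariants", {
  expect_error(model_spec(list(saom_effect("reciprocity"))), "outdegree")
  expect_error(model_spec(list(saom_effect("outdegree"),
                               saom_effect("outdegree"))), "duplicated")
  expect_error(model_spec(list(saom_effect("outdegree")), rates = 0),
               "positive")
  expect_error(model_spec(list(saom_effect("outdegree"),
                               saom_effect("cov_ego", "age"))),
               "registered covariate")
  expect_error(saom_effect("cov_alter"), "requires a covariate")
  expect_error(saom_effect("no_such_effect"), "unknown")
})

test_that("target statistics sum effect statistics over end-of-period waves", {
  # identical consecutive waves: all rate targets zero
  acts <- sprintf("a%d", 1:4)
  x <- adj(list(c("a1", "a2"), c("a2", "a3")), acts)
  active <- matrix(TRUE, 4, 3, dimnames = list(acts, paste0("w", 1:3)))
  panel <- wave_panel(list(x, x, x), active)
  spec <- model_spec("outdegree", rates = 1)
  tg <- target_statistics(panel, spec)
  expect_equal(length(tg), 3) # 2 rates + 1 effect
  expect_equal(unname(tg[1:2]), c(0, 0))
  expect_equal(unname(tg[3]), 4) # 2 ties per end wave, 2 periods

  # a panel whose waves 2..6 have prescribed tie counts gives their sum
  set.seed(23)
  n <- 38
  ids <- sprintf("n%02d", 1:n)
  counts <- c(148, 187, 180, 218, 252, 344)
  waves <- lapply(counts, function(k) {
    m <- matrix(0L, n, n, dimnames = list(ids, ids))
    m[sample(which(row(m) != col(m)), k)] <- 1L
    m
  })
  act6 <- matrix(TRUE, n, 6, dimnames = list(ids, paste0("w", 1:6)))
  p6 <- wave_panel(waves, act6)
  tg6 <- target_statistics(p6, spec)
  expect_equal(unname(tg6["outdegree"]), sum(counts[-1]))
  expect_equal(unname(tg6["outdegree"]), 1181)
  expect_equal(length(tg6), 5 + 1)
})
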