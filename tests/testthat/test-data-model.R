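test_that("read_event_log accepts well-formed files and flags bad rows", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("actor,recipient,behavior,timestamp,session",
               "c1,c2,groom,2026-02-02 09:10:00,s1",
               "c2,c1,groom,2026-02-02 09:15:00,s1",
               "c3,c1,headbutt,2026-02-03 18:30:00,s2"), path)
  log <- read_event_log(path, study_start = as.Date("2026-02-02"))
  expect_s3_class(log, "event_log")
  expect_equal(nrow(log), 3)
  expect_equal(event_week(log), c(1L, 1L, 1L))

  writeLines(c("actor,recipient,behavior,timestamp,session",
               "c1,c1,groom,2026-02-02 09:10:00,s1",
               "c1,c2,shove,2026-02-02 09:11:00,s1",
               "c1,c2,groom,not-a-time,s1"), path)
  err <- tryCatch(read_event_log(path, as.Date("2026-02-02")),
                  error = conditionMessage)
  expect_match(err, "row 1: actor equals recipient")
  expect_match(err, "row 2: unknown behavior")
  expect_match(err, "row 3: unparseable timestamp")

  writeLines("actor,recipient,behavior,timestamp,session", path)
  empty <- read_event_log(path, as.Date("2026-02-02"))
  expect_equal(nrow(empty), 0)
})

test_that("bout rule merges within-gap episodes and splits interrupted ones", {
  mk <- function(actor, recipient, behavior, start, stop)
    data.frame(actor = actor, recipient = recipient, behavior = behavior,
               start = as.POSIXct(start, tz = "UTC"),
               stop = as.POSIXct(stop, tz = "UTC"), session = "s1")
  base <- "2026-02-02 "
  # 15 s pause: one event
  obs <- rbind(mk("A", "B", "groom", paste0(base, "09:00:00"),
                  paste0(base, "09:01:00")),
               mk("A", "B", "groom", paste0(base, "09:01:15"),
                  paste0(base, "09:02:00")))
  expect_equal(nrow(merge_split_bouts(obs, study_start = "2026-02-02")), 1)
  # 25 s pause: two events
  obs2 <- rbind(mk("A", "B", "groom", paste0(base, "09:00:00"),
                   paste0(base, "09:01:00")),
                mk("A", "B", "groom", paste0(base, "09:01:25"),
                   paste0(base, "09:02:00")))
  expect_equal(nrow(merge_split_bouts(obs2, study_start = "2026-02-02")), 2)
  # interruption by a headbutt at C: two grooming events despite 10 s gap
  obs3 <- rbind(mk("A", "B", "groom", paste0(base, "09:00:00"),
                   paste0(base, "09:01:00")),
                mk("A", "C", "headbutt", paste0(base, "09:01:02"),
                   paste0(base, "09:01:05")),
                mk("A", "B", "groom", paste0(base, "09:01:10"),
                   paste0(base, "09:02:00")))
  out <- merge_split_bouts(obs3, study_start = "2026-02-02")
  expect_equal(sum(out$behavior == "groom"), 2)
  # chained within-gap episodes collapse into a single bout
  obs4 <- rbind(mk("A", "B", "groom", paste0(base, "09:00:00"),
                   paste0(base, "09:01:00")),
                mk("A", "B", "groom", paste0(base, "09:01:10"),
                   paste0(base, "09:02:00")),
                mk("A", "B", "groom", paste0(base, "09:02:15"),
                   paste0(base, "09:03:00")))
  expect_equal(nrow(merge_split_bouts(obs4, study_start = "2026-02-02")), 1)
  # overlapping episodes by one actor are invalid
  obs5 <- rbind(mk("A", "B", "groom", paste0(base, "09:00:00"),
                   paste0(base, "09:01:00")),
                mk("A", "C", "groom", paste0(base, "09:00:30"),
                   paste0(base, "09:01:30")))
  expect_error(merge_split_bouts(obs5, study_start = "2026-02-02"),
               "overlapping")
})

test_that("weighted waves count directed events and binarize correctly", {
  ev <- data.frame(
    actor = c("A", "A", "A", "B"),
    recipient = c("B", "B", "B", "A"),
    behavior = "groom",
    timestamp = as.POSIXct("2026-02-03 09:30:00", tz = "UTC"),
    session = "s1")
  log <- event_log(ev, study_start = as.Date("2026-02-02"))
  w <- build_weighted_wave(log, week = 1, active = c("A", "B", "C"))
  expect_equal(w["A", "B"], 3)
  expect_equal(w["B", "A"], 1)
  expect_equal(sum(w), 4)

  b <- binarize(w)
  expect_equal(b["A", "B"], 1L)
  expect_equal(b["B", "A"], 1L)
  expect_equal(sum(b), 2)
  expect_identical(binarize(b), b) # idempotent
  expect_error(binarize(matrix(-1, 1, 1)), "negative")

  # events by actors not active that week are rejected by default
  expect_error(build_weighted_wave(log, week = 1, active = c("A", "C")),
               "inactive")
  expect_warning(
    w2 <- build_weighted_wave(log, 1, c("A", "C"), on_inactive = "drop"),
    "dropping")
  expect_equal(sum(w2), 0)
})

test_that("normalized weighted degrees live in [0,1] with closed forms", {
  acts <- c("A", "B")
  w <- matrix(c(0, 1, 0, 0), 2, 2, byrow = TRUE,
              dimnames = list(acts, acts))
  d <- normalized_weighted_degrees(w)
  expect_equal(d$outdegree[d$actor_id == "A"], 1)
  expect_equal(d$indegree[d$actor_id == "A"], 0)

  # all dyads at the same maximal weight: everyone at exactly 1
  acts <- c("A", "B", "C")
  w <- matrix(5, 3, 3, dimnames = list(acts, acts)); diag(w) <- 0
  d <- normalized_weighted_degrees(w)
  expect_equal(d$outdegree, rep(1, 3))
  expect_equal(d$indegree, rep(1, 3))

  # empty network: all zero
  d0 <- normalized_weighted_degrees(w * 0)
  expect_equal(d0$outdegree, rep(0, 3))
  expect_error(normalized_weighted_degrees(w[1, 1, drop = FALSE]),
               "fewer than 2")
})

test_that("build_panel reproduces the staggered-entry node counts", {
  cfg <- synth_config(seed = 3)
  study <- synthesize_study(cfg)
  expect_equal(colSums(study$panel$active), c(25, 32, 33, 38, 38, 38),
               ignore_attr = TRUE)
  rebuilt <- build_panel(study$grooming, study$actors, cfg$n_waves)
  expect_identical(lapply(rebuilt$binary, unname),
                   lapply(study$panel$binary, unname))
})

test_that("panel serialization round-trips losslessly", {
  cfg <- synth_config(n_actors = 8, n_waves = 3,
                      entry_schedule = c(6, 2, 0), rate_true = rep(4, 2),
                      beta_true = c(outdegree = -1.5, reciprocity = 1),
                      seed = 5)
  panel <- synthesize_study(cfg)$panel
  dir <- withr::local_tempdir()
  mf <- write_panel(panel, dir)
  back <- read_panel(mf)
  expect_identical(back$weighted, panel$weighted)
  expect_equal(back$active, panel$active)
  expect_equal(back$presence, panel$presence)
})

test_that("wave panels reject ties on the diagonal or to inactive actors", {
  acts <- c("A", "B")
  w <- matrix(0L, 2, 2, dimnames = list(acts, acts))
  active <- matrix(TRUE, 2, 1, dimnames = list(acts, "w1"))
  diag_bad <- w; diag_bad["A", "A"] <- 1L
  expect_error(wave_panel(list(diag_bad), active), "self-ties")
  inact <- active; inact["B", 1] <- FALSE
  tie_bad <- w; tie_bad["A", "B"] <- 1L
  expect_error(wave_panel(list(tie_bad), inact), "inactive")
})
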