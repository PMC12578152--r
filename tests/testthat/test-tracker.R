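make_dets <- function(frame, cx, cy, w = 40, h = 80, conf = 0.95,
                      behavior = "stand") {
  data.frame(frame = frame, cx = cx, cy = cy, w = w, h = h, conf = conf,
             behavior = behavior, stringsAsFactors = FALSE)
}

unit_vec <- function(i, d = 8) { v <- numeric(d); v[i] <- 1; v }

test_that("population estimate is the half-up rounded mean of recent counts", {
  expect_equal(population_estimate(c(16, 15, 17)), 16L)
  expect_equal(population_estimate(16), 16L)
  expect_equal(population_estimate(c(15, 16)), 16L)
  expect_equal(population_estimate(c(14, 15)), 15L)  # 14.5 rounds half-up
  expect_equal(population_estimate(integer(0)), 0L)
})

test_that("first frame creates one tentative track per detection with sequential ids", {
  trk <- pig_tracker(tracker_config())
  dets <- make_dets(1, cx = seq(100, 1600, by = 100), cy = 500)
  tracker_step(trk, dets)
  states <- vapply(trk$tracks, `[[`, character(1), "state")
  ids <- vapply(trk$tracks, `[[`, integer(1), "id")
  expect_equal(length(trk$tracks), 16L)
  expect_true(all(states == "tentative"))
  expect_equal(ids, 1:16)
})

test_that("the population cap admits exactly n minus alive new tracks", {
  trk <- pig_tracker(tracker_config())
  trk$n_frames_seen <- 5L
  trk$tracks <- list(
    pentrack:::new_track(1L, c(100, 100, 40, 80), 0.9, "stand", NULL, trk$cfg),
    pentrack:::new_track(2L, c(300, 100, 40, 80), 0.9, "stand", NULL, trk$cfg))
  trk$next_id <- 3L
  dets <- make_dets(6, cx = c(500, 700), cy = 100)

  # n = alive = 2: nothing created
  created <- pentrack:::create_or_drop(trk, 1L, dets, NULL, n = 2L, FALSE)
  expect_equal(created, 0L)
  expect_equal(trk$n_dropped, 1L)

  # n = 3, alive = 2, two unmatched detections: exactly one admitted
  created <- pentrack:::create_or_drop(trk, 1:2, dets, NULL, n = 3L, FALSE)
  expect_equal(created, 1L)
  expect_equal(length(trk$tracks), 3L)

  # cap disabled (baseline): always create
  trk$cfg <- tracker_config(mode = "baseline")
  created <- pentrack:::create_or_drop(trk, 2L, dets, NULL, n = 0L, FALSE)
  expect_equal(created, 1L)
})

test_that("pruning respects the strict max-age boundary and confirmation rule", {
  cfg <- tracker_config(max_age = 30L, n_init = 3L)
  trk <- pig_tracker(cfg)
  t1 <- pentrack:::new_track(1L, c(1, 1, 2, 2), 0.9, "lie", NULL, cfg)
  t1$state <- "confirmed"; t1$time_since_update <- 31L
  t2 <- t1; t2$id <- 2L; t2$time_since_update <- 30L
  t3 <- pentrack:::new_track(3L, c(9, 9, 2, 2), 0.9, "eat", NULL, cfg)
  t3$hits <- 3L; t3$time_since_update <- 0L    # tentative, just matched
  t4 <- pentrack:::new_track(4L, c(5, 5, 2, 2), 0.9, "eat", NULL, cfg)
  t4$time_since_update <- 1L                   # tentative, missed its frame
  trk$tracks <- list(t1, t2, t3, t4)
  pentrack:::prune_tracks(trk)
  states <- vapply(trk$tracks, `[[`, character(1), "state")
  expect_equal(states, c("deleted", "confirmed", "confirmed", "deleted"))
})

test_that("a stationary noiseless stream yields one confirmed stable track", {
  dets <- make_dets(1:50, cx = 500, cy = 500)
  res <- track_sequence(dets, tracker_config())
  expect_equal(attr(res, "max_id"), 1L)
  expect_true(all(res$id == 1L))
  # confirmed from frame n_init onward
  expect_equal(res$frame, 3:50)
  gt <- data.frame(frame = 1:50, id = 1, cx = 500, cy = 500, w = 40, h = 80)
  expect_equal(clear_mot(gt, res)$ids, 0L)
})

test_that("out-of-order frames are rejected", {
  trk <- pig_tracker()
  tracker_step(trk, make_dets(5, 100, 100))
  expect_error(tracker_step(trk, make_dets(5, 100, 100)), "increasing order")
  expect_error(tracker_step(trk, make_dets(3, 100, 100)), "increasing order")
})

test_that("cascade matching favors the most recently updated track at equal cost", {
  cfg <- tracker_config()
  trk <- pig_tracker(cfg)
  e <- unit_vec(1)
  emb1 <- matrix(rep(e, 2), nrow = 2, byrow = TRUE)
  # two targets confirmed over frames 1..4 with identical embeddings
  for (f in 1:4) {
    tracker_step(trk, make_dets(f, cx = c(100, 140), cy = 100, w = 200, h = 200),
                 emb1)
  }
  # frame 5: only target A is detected; B becomes stale
  tracker_step(trk, make_dets(5, cx = 100, cy = 100, w = 200, h = 200),
               matrix(e, 1))
  # frame 6: one detection between both predicted positions, equal appearance
  out <- tracker_step(trk, make_dets(6, cx = 120, cy = 100, w = 200, h = 200),
                      matrix(e, 1))
  expect_equal(nrow(out), 1L)
  expect_equal(out$id, 1L)  # the fresher track (updated frame 5) wins
  tsu <- vapply(trk$tracks, `[[`, integer(1), "time_since_update")
  expect_equal(tsu[2], 2L)
})

test_that("the second IoU round recovers a stale track the cascade rejected", {
  run_mode <- function(mode) {
    cfg <- tracker_config(mode = mode)
    trk <- pig_tracker(cfg)
    eA <- unit_vec(1); eB <- unit_vec(2); eX <- unit_vec(3)
    both <- rbind(eA, eB)
    for (f in 1:4) {
      tracker_step(trk, make_dets(f, cx = c(100, 400), cy = 100), both)
    }
    # frame 5: B missed entirely
    tracker_step(trk, make_dets(5, cx = 100, cy = 100), matrix(eA, 1))
    # frame 6: B reappears at its old position but with an unfamiliar
    # embedding (occlusion-corrupted), so the appearance cascade rejects it
    # and round 1 never sees the stale track
    out <- tracker_step(trk, make_dets(6, cx = c(100, 400), cy = 100),
                        rbind(eA, eX))
    list(out = out, trk = trk)
  }
  improved <- run_mode("improved")
  expect_setequal(improved$out$id, c(1L, 2L))    # stale track recovered
  expect_equal(improved$trk$next_id - 1L, 2L)
  baseline <- run_mode("baseline")
  # without the second round the reappearance spawns a new identity
  expect_equal(baseline$trk$next_id - 1L, 3L)
})

test_that("two crossing targets with reliable counts never exceed two identities", {
  frames <- 1:60
  xa <- 100 + 10 * frames
  xb <- 700 - 10 * frames
  dets <- rbind(make_dets(frames, cx = xa, cy = 300),
                make_dets(frames, cx = xb, cy = 310))
  dets <- dets[order(dets$frame), ]
  res <- track_sequence(dets, tracker_config())
  expect_lte(attr(res, "max_id"), 2L)
})

test_that("tracking output is deterministic for fixed input", {
  scene <- simulate_pen(pen_preset("sparse_day", n_frames = 40, seed = 12))
  r1 <- track_sequence(scene$detections, tracker_config(), scene$embeddings)
  r2 <- track_sequence(scene$detections, tracker_config(), scene$embeddings)
  expect_identical(r1, r2)
  f1 <- tempfile(); f2 <- tempfile()
  on.exit(unlink(c(f1, f2)))
  write_mot(r1, f1, "result"); write_mot(r2, f2, "result")
  expect_identical(readLines(f1), readLines(f2))
})

test_that("track behavior is the majority label of recent assignments", {
  expect_equal(pentrack:::majority_behavior(c("stand", "eat", "eat"), 3), "eat")
  expect_equal(pentrack:::majority_behavior(c("lie", "stand"), 3), "stand")  # tie -> most recent
  expect_equal(pentrack:::majority_behavior(c("attack", "attack", "lie", "lie", "lie"), 3), "lie")
  dets <- make_dets(1:10, cx = 500, cy = 500,
                    behavior = c(rep("stand", 6), rep("eat", 4)))
  res <- track_sequence(dets, tracker_config())
  expect_equal(res$behavior[res$frame == 6], "stand")
  expect_equal(res$behavior[res$frame == 10], "eat")
})

test_that("missing embeddings fall back to IoU-based cascade with a log line", {
  dets <- make_dets(1:6, cx = 500, cy = 500)
  expect_message(track_sequence(dets, tracker_config()), "falls back to IoU")
})
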