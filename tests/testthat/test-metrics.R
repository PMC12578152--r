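straight_track <- function(id, frames, x0, y = 100, step = 5, w = 40, h = 80) {
  data.frame(frame = frames, id = id, cx = x0 + step * (frames - frames[1]),
             cy = y, w = w, h = h)
}

test_that("a perfect hypothesis scores 100 everywhere with zero switches", {
  gt <- rbind(straight_track(1, 1:10, 100), straight_track(2, 1:10, 400))
  hyp <- gt
  hyp$id <- hyp$id + 10
  rep <- clear_mot(gt, hyp)
  expect_equal(rep$mota, 100)
  expect_equal(rep$motp, 100)
  expect_equal(rep$idf1, 100)
  expect_equal(rep$ids, 0L)
  expect_equal(rep$rcll, 100)
  expect_equal(rep$prcn, 100)
})

test_that("one missed detection in 2 objects x 3 frames gives MOTA 100*(1 - 1/6)", {
  gt <- rbind(straight_track(1, 1:3, 100), straight_track(2, 1:3, 400))
  hyp <- gt[!(gt$id == 2 & gt$frame == 2), ]
  rep <- clear_mot(gt, hyp)
  expect_equal(rep$fn, 1L)
  expect_equal(rep$fp, 0L)
  expect_equal(rep$ids, 0L)
  expect_equal(rep$mota, 100 * (1 - 1 / 6))
})

test_that("an empty hypothesis degenerates to MOTA 0 with a warning", {
  gt <- straight_track(1, 1:5, 100)
  hyp <- data.frame(frame = 1, id = 1, cx = 5000, cy = 5000, w = 10, h = 10)[0, ]
  expect_warning(rep <- clear_mot(gt, hyp), "MOTP")
  expect_equal(rep$mota, 0)
  expect_equal(rep$fn, 5L)
  expect_error(clear_mot(gt[0, ], gt), "empty ground truth")
})

test_that("previous-frame pairs persist even when a new hypothesis is closer", {
  gt <- data.frame(frame = 1:2, id = 1, cx = 100, cy = 100, w = 40, h = 80)
  hyp <- rbind(
    data.frame(frame = 1, id = 7, cx = 100, cy = 100, w = 40, h = 80),
    # frame 2: id 7 drifts (IoU ~0.6) while a new id 8 sits dead on
    data.frame(frame = 2, id = 7, cx = 110, cy = 100, w = 40, h = 80),
    data.frame(frame = 2, id = 8, cx = 100, cy = 100, w = 40, h = 80))
  rep <- clear_mot(gt, hyp)
  expect_equal(rep$ids, 0L)       # persistence kept gt1 - hyp7
  expect_equal(rep$fp, 1L)        # the interloper is a false positive
})

test_that("id switches are counted when a trajectory changes hypothesis id", {
  gt <- straight_track(1, 1:10, 100)
  hyp <- gt
  hyp$id <- ifelse(hyp$frame <= 5, 7, 8)
  rep <- clear_mot(gt, hyp)
  expect_equal(rep$ids, 1L)
  expect_equal(rep$mota, 100 * (1 - 1 / 10))
})

test_that("IDF1 toy cases match the exhaustive id-assignment oracle", {
  # split: one gt trajectory covered half by id A, half by id B
  gt <- straight_track(1, 1:10, 100)
  hyp <- gt
  hyp$id <- ifelse(hyp$frame <= 5, 7, 8)
  expect_equal(idf1(gt, hyp), idf1_oracle(gt, hyp))
  expect_equal(idf1(gt, hyp), 50)
  # swap: two perfectly tracked objects exchange ids at the midpoint
  gt2 <- rbind(straight_track(1, 1:10, 100), straight_track(2, 1:10, 400))
  hyp2 <- gt2
  hyp2$id <- ifelse(hyp2$frame <= 5, hyp2$id, 3 - hyp2$id)
  expect_equal(idf1(gt2, hyp2), idf1_oracle(gt2, hyp2))
  expect_equal(idf1(gt2, hyp2), 50)
  # fragmentation into unequal pieces
  hyp3 <- gt
  hyp3$id <- c(rep(7, 7), rep(8, 3))
  expect_equal(idf1(gt, hyp3), idf1_oracle(gt, hyp3))
  expect_equal(idf1(gt, hyp3), 70)
})

test_that("MOTA decomposition identity holds exactly on integer counts", {
  set.seed(91)
  for (i in 1:5) {
    scene <- simulate_pen(pen_preset("sparse_day", n_frames = 30, seed = i))
    res <- track_sequence(scene$detections, tracker_config(), scene$embeddings)
    rep <- clear_mot(scene$gt, res)
    expect_equal(rep$mota,
                 100 * (1 - (rep$fn + rep$fp + rep$ids) / rep$num_gt))
    expect_equal(rep$rcll, 100 * (rep$num_gt - rep$fn) / rep$num_gt)
    expect_lte(rep$rcll, 100); expect_lte(rep$prcn, 100)
  }
})

test_that("removing a hypothesis row never increases FP; duplicate gt rows are rejected", {
  scene <- simulate_pen(pen_preset("sparse_day", n_frames = 25, seed = 4))
  res <- track_sequence(scene$detections, tracker_config(), scene$embeddings)
  full <- clear_mot(scene$gt, res)
  thinned <- clear_mot(scene$gt, res[-sample(nrow(res), 5), ])
  expect_lte(thinned$fp, full$fp)
  dup <- rbind(scene$gt, scene$gt[1, ])
  expect_error(clear_mot(dup, res), "duplicated")
})

test_that("compare_runs reports paired metrics and reproducible deltas", {
  scene <- simulate_pen(pen_preset("dense_day", n_frames = 40, seed = 8))
  base <- track_sequence(scene$detections, tracker_config(mode = "baseline"),
                         scene$embeddings)
  impr <- track_sequence(scene$detections, tracker_config(mode = "improved"),
                         scene$embeddings)
  same <- compare_runs(scene$gt, base, base)
  expect_true(all(same$delta == 0))
  cmpr1 <- compare_runs(scene$gt, base, impr)
  cmpr2 <- compare_runs(scene$gt, base, impr)
  expect_identical(cmpr1$delta, cmpr2$delta)
  expect_equal(cmpr1$delta[["ids"]],
               cmpr1$improved$ids - cmpr1$baseline$ids)
})

test_that("metrics agree with the independent Python reference on seeded scenes", {
  py_ok <- !is.null(python_mot_reference(
    straight_track(1, 1:3, 100), straight_track(1, 1:3, 100)))
  expect_true(py_ok)
  n_checked <- 0
  for (seed in 1:20) {
    preset <- if (seed %% 2 == 0) "dense_day" else "sparse_day"
    scene <- simulate_pen(pen_preset(preset, n_frames = 40, seed = seed))
    res <- track_sequence(scene$detections, tracker_config(), scene$embeddings)
    if (nrow(res) == 0) next
    mine <- clear_mot(scene$gt, res)
    ref <- python_mot_reference(scene$gt, res)
    expect_false(is.null(ref))
    expect_equal(mine$mota, ref$mota, tolerance = 1e-4)
    expect_equal(mine$motp, ref$motp, tolerance = 1e-4)
    expect_equal(mine$idf1, ref$idf1, tolerance = 1e-4)
    expect_equal(mine$ids, ref$ids)
    expect_equal(mine$rcll, ref$rcll, tolerance = 1e-4)
    expect_equal(mine$prcn, ref$prcn, tolerance = 1e-4)
    n_checked <- n_checked + 1
  }
  expect_equal(n_checked, 20)
})
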