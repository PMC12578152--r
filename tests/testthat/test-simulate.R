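noise_free <- function(...) {
  args <- utils::modifyList(
    list(miss_p = 0, fp_rate = 0, jitter_sigma = 0, occlusion_drop_p = 0,
         class_confusion = diag(4)),
    list(...))
  do.call(pen_config, args)
}

test_that("scenes are reproducible from their seed and conserve gt rows", {
  cfg <- pen_preset("sparse_day", n_frames = 30, seed = 99)
  a <- simulate_pen(cfg)
  b <- simulate_pen(cfg)
  expect_identical(a$gt, b$gt)
  expect_identical(a$detections, b$detections)
  expect_identical(a$embeddings, b$embeddings)
  expect_equal(nrow(a$gt), cfg$n_pigs * cfg$n_frames)
  # every non-FP detection maps to exactly one gt row of its frame
  real <- a$detections[!is.na(a$detections$gt_id), ]
  expect_false(anyDuplicated(real[, c("frame", "gt_id")]) > 0)
  expect_true(all(real$gt_id %in% seq_len(cfg$n_pigs)))
})

test_that("with all noise off the detections equal the ground truth boxes", {
  cfg <- noise_free(n_pigs = 16L, n_frames = 100L, seed = 5)
  sc <- simulate_pen(cfg)
  expect_equal(nrow(sc$gt), 1600L)
  expect_equal(nrow(sc$detections), 1600L)
  expect_equal(sc$detections$cx, sc$gt$cx)
  expect_equal(sc$detections$cy, sc$gt$cy)
  expect_equal(sc$detections$w, sc$gt$w)
  expect_equal(sc$detections$behavior, sc$gt$behavior)
})

test_that("boxes stay inside the arena with positive dimensions", {
  sc <- simulate_pen(pen_preset("dense_night", n_frames = 50, seed = 21))
  g <- sc$gt
  expect_true(all(g$w > 0 & g$h > 0))
  expect_true(all(g$cx - g$w / 2 >= -1e-9))
  expect_true(all(g$cx + g$w / 2 <= sc$config$arena_w + 1e-9))
  expect_true(all(g$cy - g$h / 2 >= -1e-9))
  expect_true(all(g$cy + g$h / 2 <= sc$config$arena_h + 1e-9))
  expect_true(all(sc$detections$w > 0 & sc$detections$h > 0))
})

test_that("miss counts follow their binomial expectation across seeds", {
  # 16 pigs x 100 frames, miss_p = 0.1: detections ~ Binomial(1600, 0.9)
  rows <- vapply(1:10, function(s) {
    nrow(simulate_pen(noise_free(n_pigs = 16L, n_frames = 100L,
                                 miss_p = 0.1, seed = s))$detections)
  }, numeric(1))
  expected <- 1600 * 0.9
  sigma <- sqrt(1600 * 0.9 * 0.1)
  expect_lt(abs(mean(rows) - expected), 3 * sigma / sqrt(10))
})

test_that("false positives follow their Poisson expectation", {
  cfg <- noise_free(n_pigs = 4L, n_frames = 500L, fp_rate = 2, seed = 31)
  sc <- simulate_pen(cfg)
  n_fp <- sum(is.na(sc$detections$gt_id))
  expect_lt(abs(n_fp - 1000), 3 * sqrt(1000))
})

test_that("behavior chain respects its transition matrix", {
  # identity matrix: the state never changes
  set.seed(1)
  s <- "eat"
  for (i in 1:50) s <- behavior_step(s, diag(4))
  expect_equal(s, "eat")
  # uniform rows: empirical occupancy approaches 1/4 each
  set.seed(2)
  u <- matrix(0.25, 4, 4)
  states <- character(10000)
  s <- "stand"
  for (i in 1:10000) { s <- behavior_step(s, u); states[i] <- s }
  occ <- table(factor(states, levels = c("stand", "lie", "eat", "attack"))) / 10000
  sigma <- sqrt(0.25 * 0.75 / 10000)
  expect_true(all(abs(occ - 0.25) < 3 * sigma * 4))  # loose LLN band
  expect_error(behavior_step("stand", matrix(0.3, 4, 4)), "stochastic")
})

test_that("lying pigs do not move and attacks pair pigs rushing together", {
  cfg <- noise_free(n_pigs = 6L, n_frames = 80L, seed = 13,
                    behavior_transition = matrix(rep(c(0, 1, 0, 0), 4), 4, 4,
                                                 byrow = TRUE),
                    attack_pairing = 0)
  sc <- simulate_pen(cfg)
  # all pigs lie from frame 2 on: positions frozen
  late <- sc$gt[sc$gt$frame >= 3, ]
  for (id in 1:6) {
    xs <- late$cx[late$id == id]
    expect_true(all(abs(diff(xs)) < 1e-9))
  }
  # attack-heavy preset produces paired attack states that close distance
  cfg2 <- noise_free(n_pigs = 8L, n_frames = 120L, seed = 17,
                     attack_pairing = 0.5)
  sc2 <- simulate_pen(cfg2)
  atk <- sc2$gt[sc2$gt$behavior == "attack", ]
  expect_gt(nrow(atk), 0)
  per_frame <- table(atk$frame)
  expect_true(all(per_frame %% 2 == 0))  # attacks always come in pairs
})

test_that("dense night scenes lose more boxes to occlusion than sparse day scenes", {
  drop_rate <- function(preset) {
    lost <- vapply(1:5, function(s) {
      sc <- simulate_pen(pen_preset(preset, n_frames = 60, seed = s,
                                    fp_rate = 0))
      1 - nrow(sc$detections) / nrow(sc$gt)
    }, numeric(1))
    mean(lost)
  }
  expect_gt(drop_rate("dense_night"), drop_rate("sparse_day"))
})

test_that("identity embeddings are unit norm and separate identities", {
  cfg <- pen_config(n_pigs = 16L, n_frames = 4L, embed_dim = 64L,
                    embed_noise = 0.05, seed = 3)
  sc <- simulate_pen(cfg)
  norms <- sqrt(rowSums(sc$embeddings^2))
  expect_true(all(abs(norms - 1) < 1e-9))
  # zero noise reproduces the identity vector exactly
  v <- sc$identity_embeddings[1, ]
  expect_equal(embed_identity(v, 0), v)
  # same-identity cosine distance well below cross-identity distance
  set.seed(7)
  same <- numeric(500); cross <- numeric(500)
  for (k in 1:500) {
    i <- sample(16, 1); j <- sample(setdiff(1:16, i), 1)
    a <- embed_identity(sc$identity_embeddings[i, ], 0.05)
    b <- embed_identity(sc$identity_embeddings[i, ], 0.05)
    c2 <- embed_identity(sc$identity_embeddings[j, ], 0.05)
    same[k] <- 1 - sum(a * b)
    cross[k] <- 1 - sum(a * c2)
  }
  expect_lt(mean(same), mean(cross) / 5)
})

test_that("forced occlusion drops exactly one of a fully stacked pair", {
  gt_f <- data.frame(frame = 1, id = 1:2, cx = 500, cy = c(300, 301),
                     w = 200, h = 100, behavior = "stand")
  cfg <- noise_free(occlusion_drop_p = 1, occlusion_iou = 0.3)
  set.seed(11)
  d <- degrade_frame(gt_f, cfg)
  expect_equal(nrow(d), 1L)
  expect_equal(d$gt_id, 2L)  # the lower-cy (rear) box is the one dropped
})
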