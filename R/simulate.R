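#' Pen simulation configuration
#'
#' Describes a synthetic pen of group-housed pigs viewed by a fixed overhead
#' camera: arena size (defaults to a 2688 x 1520 px frame at 25 fps), pig
#' count, per-behavior movement speeds, a Markov chain over the four behavior
#' states (stand, lie, eat, attack), paired attack bursts, and a detector
#' degradation model (occlusion dropouts, misses, localization jitter, false
#' positives, class confusion, a night-time miss multiplier) plus unit-norm
#' identity embeddings standing in for re-identification CNN features.
#'
#' @param n_pigs Number of pigs in the pen.
#' @param n_frames Number of frames to simulate.
#' @param arena_w,arena_h Arena (image) size in pixels.
#' @param fps Frame rate, frames per second.
#' @param behavior_transition 4x4 row-stochastic matrix over
#'   stand/lie/eat/attack governing per-frame behavior switching for pigs not
#'   currently in an attack episode.
#' @param speed_px Named per-behavior mean step length in px/frame
#'   (`lie` must be 0).
#' @param attack_pairing Per-frame probability that an idle pair starts a
#'   paired attack burst (two pigs rushing toward each other).
#' @param attack_continue Per-frame probability an attack burst continues
#'   (geometric episode length).
#' @param body_w,body_h Mean body box dimensions in px.
#' @param body_jitter Relative per-pig size variation (lognormal sd).
#' @param occlusion_iou Pairwise IoU above which the rear pig of an
#'   overlapping pair may be dropped by the detector.
#' @param occlusion_drop_p Probability of dropping the rear box of an
#'   occluded pair.
#' @param miss_p Baseline per-detection miss probability.
#' @param night Logical; night scenes multiply `miss_p`.
#' @param night_miss_multiplier Factor (>= 1) applied to `miss_p` at night.
#' @param fp_rate Expected false positives per frame (Poisson).
#' @param jitter_sigma Localization noise sd in px, applied per coordinate.
#' @param class_confusion 4x4 row-stochastic confusion matrix over the
#'   behavior classes.
#' @param embed_dim Embedding dimension.
#' @param embed_noise Gaussian noise sd added to the identity embedding
#'   before renormalization.
#' @param seed Integer RNG seed; one shared stream drives the whole scene.
#' @return A list of class `pen_config`.
#' @export
pen_config <- function(n_pigs = 16L, n_frames = 250L,
                       arena_w = 2688, arena_h = 1520, fps = 25,
                       behavior_transition = default_behavior_transition(),
                       speed_px = c(stand = 8, lie = 0, eat = 2, attack = 20),
                       attack_pairing = 0.01, attack_continue = 0.92,
                       body_w = 300, body_h = 160, body_jitter = 0.08,
                       occlusion_iou = 0.3, occlusion_drop_p = 0.5,
                       miss_p = 0.02, night = FALSE, night_miss_multiplier = 3,
                       fp_rate = 0.2, jitter_sigma = 2,
                       class_confusion = default_class_confusion(),
                       embed_dim = 32L, embed_noise = 0.05, seed = 1L) {
  check_stochastic(behavior_transition, "behavior_transition")
  check_stochastic(class_confusion, "class_confusion")
  stopifnot(n_pigs >= 1L, n_frames >= 1L, arena_w > 0, arena_h > 0,
            all(speed_px >= 0), speed_px[["lie"]] == 0,
            attack_pairing >= 0, attack_pairing <= 1,
            attack_continue >= 0, attack_continue < 1,
            occlusion_drop_p >= 0, occlusion_drop_p <= 1,
            miss_p >= 0, miss_p <= 1, night_miss_multiplier >= 1,
            fp_rate >= 0, jitter_sigma >= 0, embed_dim >= 2L,
            embed_noise >= 0)
  structure(as.list(environment()), class = "pen_config")
}

BEHAVIORS <- c("stand", "lie", "eat", "attack")

#' Default behavior transition matrix
#'
#' A sticky chain: pigs mostly keep doing what they are doing, with
#' occasional switches between standing, lying and eating. Transitions
#' *into* attack go through the paired-burst process, not this matrix, so
#' the attack column is zero for the other states; the attack row describes
#' what a pig does if placed in the attack state outside a burst.
#'
#' @return 4x4 row-stochastic matrix with dimnames over the behavior states.
#' @export
default_behavior_transition <- function() {
  m <- rbind(stand = c(0.950, 0.030, 0.020, 0),
             lie   = c(0.040, 0.950, 0.010, 0),
             eat   = c(0.060, 0.010, 0.930, 0),
             attack = c(0.700, 0.050, 0.050, 0.2))
  colnames(m) <- BEHAVIORS
  m
}

#' Default behavior confusion matrix of the emulated detector
#' @return 4x4 row-stochastic matrix.
#' @export
default_class_confusion <- function() {
  m <- matrix(0.02, 4, 4, dimnames = list(BEHAVIORS, BEHAVIORS))
  diag(m) <- 0.94
  m
}

check_stochastic <- function(m, what) {
  if (!is.matrix(m) || !all(dim(m) == c(4L, 4L))) {
    stop(what, " must be a 4x4 matrix", call. = FALSE)
  }
  if (any(m < 0) || any(abs(rowSums(m) - 1) > 1e-9)) {
    stop(what, " must be row-stochastic (rows summing to 1)", call. = FALSE)
  }
  invisible(m)
}

#' Scene presets mirroring sparse/dense and day/night pens
#'
#' `sparse_day`: 7 pigs, daytime detector noise. `dense_day`: 16 pigs.
#' `dense_night`: 16 pigs, night-time miss inflation and a high paired
#' attack rate (an occlusion-heavy regime).
#'
#' @param name Preset name.
#' @param ... Overrides passed on to [pen_config()].
#' @return A [pen_config()].
#' @export
pen_preset <- function(name = c("sparse_day", "dense_day", "dense_night"), ...) {
  name <- match.arg(name)
  args <- switch(name,
    sparse_day = list(n_pigs = 7L, night = FALSE),
    dense_day = list(n_pigs = 16L, night = FALSE),
    dense_night = list(n_pigs = 16L, night = TRUE, attack_pairing = 0.05,
                       occlusion_drop_p = 0.6))
  do.call(pen_config, utils::modifyList(args, list(...)))
}

#' One behavior-chain step
#'
#' Samples the next behavior state from the row of the transition matrix for
#' the current state, consuming one uniform draw from the active RNG stream.
#'
#' @param state Current behavior label.
#' @param transition 4x4 row-stochastic matrix (rows/cols in stand, lie,
#'   eat, attack order).
#' @return Next behavior label.
#' @export
behavior_step <- function(state, transition) {
  check_stochastic(transition, "transition")
  i <- match(state, BEHAVIORS)
  if (is.na(i)) stop("unknown behavior state: ", state, call. = FALSE)
  BEHAVIORS[findInterval(stats::runif(1L), cumsum(transition[i, ]),
                         left.open = TRUE) + 1L]
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Simulate a pen scene
#'
#' Generates ground-truth trajectories (bounded random walk with
#' per-behavior speeds and paired attack bursts in which two pigs rush
#' toward each other), then degrades them into a detection stream with
#' occlusion dropouts, misses, jitter, false positives and class confusion,
#' and attaches noisy identity embeddings. One RNG stream seeded from the
#' config drives everything, consumed in a fixed order (motion and behavior
#' first, then per-frame degradation and embeddings), so a scene is fully
#' reproducible from its seed.
#'
#' @param cfg A [pen_config()].
#' @return A list of class `pen_scene` with elements `gt` (trajectory data
#'   frame `frame, id, cx, cy, w, h, behavior`), `detections` (data frame
#'   `frame, cx, cy, w, h, conf, behavior, gt_id` with `gt_id = NA` for
#'   false positives), `embeddings` (matrix aligned with detection rows),
#'   `identity_embeddings` (`n_pigs x embed_dim`) and `config`.
#' @export
simulate_pen <- function(cfg = pen_config()) {
  stopifnot(inherits(cfg, "pen_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)
  n <- cfg$n_pigs

  # fixed per-pig geometry and identity
  bw <- cfg$body_w * exp(stats::rnorm(n, 0, cfg$body_jitter))
  bh <- cfg$body_h * exp(stats::rnorm(n, 0, cfg$body_jitter))
  ident <- matrix(stats::rnorm(n * cfg$embed_dim), n, cfg$embed_dim)
  ident <- ident / sqrt(rowSums(ident^2))

  x <- stats::runif(n, bw / 2, cfg$arena_w - bw / 2)
  y <- stats::runif(n, bh / 2, cfg$arena_h - bh / 2)
  heading <- stats::runif(n, 0, 2 * pi)
  behavior <- sample(c("stand", "lie", "eat"), n, replace = TRUE,
                     prob = c(0.5, 0.4, 0.1))
  attack_partner <- rep(NA_integer_, n)

  gt <- vector("list", cfg$n_frames)
  for (f in seq_len(cfg$n_frames)) {
    # behavior updates for pigs not in an attack episode
    for (i in seq_len(n)) {
      if (is.na(attack_partner[i])) {
        behavior[i] <- behavior_step(behavior[i], cfg$behavior_transition)
        if (behavior[i] == "attack") behavior[i] <- "stand"  # bursts only
      }
    }
    # attack episode termination (decided once per active pair)
    active <- which(!is.na(attack_partner) & seq_len(n) < attack_partner)
    for (i in active) {
      if (stats::runif(1L) > cfg$attack_continue) {
        j <- attack_partner[i]
        attack_partner[c(i, j)] <- NA_integer_
        behavior[c(i, j)] <- "stand"
      }
    }
    # attack episode initiation: one candidate pair per frame
    idle <- which(is.na(attack_partner) & behavior != "lie")
    if (length(idle) >= 2L && stats::runif(1L) < cfg$attack_pairing) {
      pair <- sample(idle, 2L)
      attack_partner[pair] <- rev(pair)
      behavior[pair] <- "attack"
    }
    # motion
    for (i in seq_len(n)) {
      sp <- cfg$speed_px[[behavior[i]]]
      step <- sp * stats::rgamma(1L, shape = 2, rate = 2)
      if (!is.na(attack_partner[i])) {
        j <- attack_partner[i]
        heading[i] <- atan2(y[j] - y[i], x[j] - x[i])
      } else {
        heading[i] <- heading[i] + stats::rnorm(1L, 0, 0.3)
      }
      x[i] <- clamp(x[i] + step * cos(heading[i]), bw[i] / 2, cfg$arena_w - bw[i] / 2)
      y[i] <- clamp(y[i] + step * sin(heading[i]), bh[i] / 2, cfg$arena_h - bh[i] / 2)
    }
    gt[[f]] <- data.frame(frame = f, id = seq_len(n), cx = x, cy = y,
                          w = bw, h = bh, behavior = behavior,
                          stringsAsFactors = FALSE)
  }
  gt <- do.call(rbind, gt)

  det <- vector("list", cfg$n_frames)
  emb <- vector("list", cfg$n_frames)
  for (f in seq_len(cfg$n_frames)) {
    gt_f <- gt[gt$frame == f, , drop = FALSE]
    d <- degrade_frame(gt_f, cfg)
    e <- matrix(0, nrow(d), cfg$embed_dim)
    for (k in seq_len(nrow(d))) {
      e[k, ] <- if (is.na(d$gt_id[k])) {
        v <- stats::rnorm(cfg$embed_dim); v / sqrt(sum(v^2))
      } else {
        embed_identity(ident[d$gt_id[k], ], cfg$embed_noise)
      }
    }
    det[[f]] <- d
    emb[[f]] <- e
  }
  det <- do.call(rbind, det)
  rownames(det) <- NULL
  structure(list(gt = gt, detections = det,
                 embeddings = do.call(rbind, emb),
                 identity_embeddings = ident, config = cfg),
            class = "pen_scene")
}

#' @export
print.pen_scene <- function(x, ...) {
  cat(sprintf("pen_scene: %d pigs, %d frames, %d gt rows, %d detections (%d FP)\n",
              x$config$n_pigs, x$config$n_frames, nrow(x$gt),
              nrow(x$detections), sum(is.na(x$detections$gt_id))))
  invisible(x)
}

#' Degrade one frame of ground truth into detections
#'
#' Applies, in order: occlusion dropouts (for each pair with IoU above the
#' occlusion threshold, the rear box -- the one with the smaller cy, the
#' farther-from-camera proxy under an overhead view -- is dropped with the
#' configured probability), independent misses (multiplied at night),
#' Gaussian localization jitter per coordinate, Poisson false positives,
#' and class confusion. Consumes the active RNG stream.
#'
#' @param gt_f One frame of ground-truth rows.
#' @param cfg A [pen_config()].
#' @return Detection data frame
#'   (`frame, cx, cy, w, h, conf, behavior, gt_id`).
#' @export
degrade_frame <- function(gt_f, cfg) {
  n <- nrow(gt_f)
  keep <- rep(TRUE, n)
  if (n >= 2L) {
    iou <- box_iou_matrix(gt_f, gt_f)
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (iou[i, j] > cfg$occlusion_iou) {
          rear <- if (gt_f$cy[i] < gt_f$cy[j]) i else j
          if (keep[rear] && stats::runif(1L) < cfg$occlusion_drop_p) {
            keep[rear] <- FALSE
          }
        }
      }
    }
  }
  p_miss <- min(1, cfg$miss_p * if (cfg$night) cfg$night_miss_multiplier else 1)
  if (p_miss > 0) {
    keep <- keep & (stats::runif(n) >= p_miss)
  }
  d <- gt_f[keep, , drop = FALSE]
  out <- data.frame(frame = d$frame, cx = d$cx, cy = d$cy, w = d$w, h = d$h,
                    conf = stats::runif(nrow(d), 0.85, 0.99),
                    behavior = d$behavior, gt_id = d$id,
                    stringsAsFactors = FALSE)
  if (cfg$jitter_sigma > 0 && nrow(out) > 0L) {
    out$cx <- out$cx + stats::rnorm(nrow(out), 0, cfg$jitter_sigma)
    out$cy <- out$cy + stats::rnorm(nrow(out), 0, cfg$jitter_sigma)
    out$w <- pmax(out$w + stats::rnorm(nrow(out), 0, cfg$jitter_sigma), 1)
    out$h <- pmax(out$h + stats::rnorm(nrow(out), 0, cfg$jitter_sigma), 1)
  }
  # class confusion
  if (nrow(out) > 0L) {
    for (k in seq_len(nrow(out))) {
      i <- match(out$behavior[k], BEHAVIORS)
      out$behavior[k] <- BEHAVIORS[
        findInterval(stats::runif(1L), cumsum(cfg$class_confusion[i, ]),
                     left.open = TRUE) + 1L]
    }
  }
  n_fp <- stats::rpois(1L, cfg$fp_rate)
  if (n_fp > 0L) {
    fw <- cfg$body_w * stats::runif(n_fp, 0.5, 1.2)
    fh <- cfg$body_h * stats::runif(n_fp, 0.5, 1.2)
    fp <- data.frame(
      frame = gt_f$frame[1L],
      cx = stats::runif(n_fp, fw / 2, cfg$arena_w - fw / 2),
      cy = stats::runif(n_fp, fh / 2, cfg$arena_h - fh / 2),
      w = fw, h = fh,
      conf = stats::runif(n_fp, 0.3, 0.6),
      behavior = sample(BEHAVIORS, n_fp, replace = TRUE),
      gt_id = NA_integer_, stringsAsFactors = FALSE)
    out <- rbind(out, fp)
  }
  rownames(out) <- NULL
  out
}

#' Noisy identity embedding
#'
#' Adds isotropic Gaussian noise to a unit identity vector and renormalizes,
#' emulating the frame-to-frame variation of a re-identification feature.
#'
#' @param identity Unit-norm identity vector.
#' @param noise Noise standard deviation.
#' @return Unit-norm numeric vector.
#' @export
embed_identity <- function(identity, noise = 0.05) {
  v <- identity + stats::rnorm(length(identity), 0, noise)
  v / sqrt(sum(v^2))
}
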