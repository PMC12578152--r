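#' Tracker configuration
#'
#' Parameters of the improved DeepSORT tracker. The improvements over the
#' stock tracker are (a) a second round of IoU matching between leftover
#' unmatched tracks and detections and (b) a cap on new-track creation: after
#' the first frame, new tracks are created only while the estimated pen
#' population `n` (rounded 3-frame average of raw detection counts) exceeds
#' the number of alive (non-deleted) tracks. `mode = "baseline"` disables
#' both, reproducing stock DeepSORT track management.
#'
#' @param max_age Frames a confirmed track may remain unmatched before
#'   deletion (deleted strictly when `time_since_update > max_age`;
#'   default 30).
#' @param n_init Consecutive hits needed to confirm a tentative track
#'   (default 3).
#' @param min_confidence Detections below this confidence are discarded
#'   before association (default 0.8, the stock DeepSORT pipeline value).
#' @param max_cosine_distance Appearance gate for cascade matching
#'   (default 0.2).
#' @param iou_threshold_round1,iou_threshold_round2 Cost caps on `1 - IoU`
#'   for the two IoU matching rounds (default 0.7 each).
#' @param gating_chi2 Mahalanobis gating threshold, 0.95 chi-square quantile
#'   with 4 degrees of freedom (default `qchisq(0.95, 4)` = 9.4877).
#' @param cap_window Number of recent frames averaged for the population
#'   estimate (default 3).
#' @param cap_enabled Enable the population cap on track creation.
#' @param second_round_enabled Enable the second IoU matching round.
#' @param gallery_size Appearance gallery budget per track (FIFO, default 100).
#' @param mode Convenience switch: `"improved"` (default) or `"baseline"`.
#' @return A list of class `tracker_config`.
#' @export
tracker_config <- function(max_age = 30L, n_init = 3L,
                           min_confidence = 0.8,
                           max_cosine_distance = 0.2,
                           iou_threshold_round1 = 0.7,
                           iou_threshold_round2 = 0.7,
                           gating_chi2 = chi2_gate_95(),
                           cap_window = 3L,
                           cap_enabled = TRUE,
                           second_round_enabled = TRUE,
                           gallery_size = 100L,
                           mode = c("improved", "baseline")) {
  mode <- match.arg(mode)
  if (mode == "baseline") {
    cap_enabled <- FALSE
    second_round_enabled <- FALSE
  }
  stopifnot(max_age >= 1L, n_init >= 1L, max_cosine_distance > 0,
            min_confidence >= 0, min_confidence <= 1,
            iou_threshold_round1 > 0, iou_threshold_round2 > 0,
            gating_chi2 > 0, cap_window >= 1L, gallery_size >= 1L)
  structure(list(max_age = as.integer(max_age), n_init = as.integer(n_init),
                 min_confidence = min_confidence,
                 max_cosine_distance = max_cosine_distance,
                 iou_threshold_round1 = iou_threshold_round1,
                 iou_threshold_round2 = iou_threshold_round2,
                 gating_chi2 = gating_chi2,
                 cap_window = as.integer(cap_window),
                 cap_enabled = isTRUE(cap_enabled),
                 second_round_enabled = isTRUE(second_round_enabled),
                 gallery_size = as.integer(gallery_size),
                 mode = mode),
            class = "tracker_config")
}

#' Create a tracker
#'
#' Returns a mutable tracker object (an environment) that consumes one frame
#' of detections at a time through [tracker_step()].
#'
#' @param cfg A [tracker_config()].
#' @return An environment of class `pig_tracker`.
#' @export
pig_tracker <- function(cfg = tracker_config()) {
  stopifnot(inherits(cfg, "tracker_config"))
  trk <- new.env(parent = emptyenv())
  trk$cfg <- cfg
  trk$tracks <- list()
  trk$next_id <- 1L
  trk$n_frames_seen <- 0L
  trk$last_frame <- 0L
  trk$count_history <- integer(0)
  trk$n_dropped <- 0L
  trk$fallback_logged <- FALSE
  class(trk) <- "pig_tracker"
  trk
}

#' @export
print.pig_tracker <- function(x, ...) {
  states <- vapply(x$tracks, function(t) t$state, character(1L))
  cat(sprintf("pig_tracker (%s): frame %d, %d confirmed / %d tentative / %d deleted\n",
              x$cfg$mode, x$last_frame,
              sum(states == "confirmed"), sum(states == "tentative"),
              sum(states == "deleted")))
  invisible(x)
}

new_track <- function(id, b, conf, behavior, embedding, cfg) {
  list(id = id, state = "tentative", kf = kf_initiate(b),
       hits = 1L, age = 0L, time_since_update = 0L,
       gallery = if (is.null(embedding)) list() else list(embedding),
       behaviors = as.character(behavior), conf = conf)
}

alive_states <- c("tentative", "confirmed")

track_states <- function(trk) vapply(trk$tracks, `[[`, character(1L), "state")

#' Rounded mean of recent detection counts
#'
#' The pen-population estimate `n`: the arithmetic mean of the per-frame raw
#' detection counts over the most recent frames (up to the cap window, fewer
#' at sequence start), rounded half-up to the nearest integer. An empty
#' history gives 0.
#'
#' @param counts Integer vector of recent per-frame detection counts.
#' @return Non-negative integer `n`.
#' @examples
#' population_estimate(c(16, 15, 17))  # 16
#' population_estimate(c(15, 16))     # 16 (15.5 rounds half-up)
#' @export
population_estimate <- function(counts) {
  if (length(counts) == 0L) return(0L)
  as.integer(floor(mean(counts) + 0.5))
}

cosine_distance_to_gallery <- function(gallery, emb) {
  # min over the gallery of 1 - <g, e> for unit vectors
  if (length(gallery) == 0L) return(1)
  1 - max(vapply(gallery, function(g) sum(g * emb), numeric(1L)))
}

appearance_cost_matrix <- function(trk, track_idx, det_boxes, det_emb) {
  cfg <- trk$cfg
  nt <- length(track_idx); nd <- nrow(det_boxes)
  cost <- matrix(0, nt, nd)
  for (k in seq_len(nt)) {
    t <- trk$tracks[[track_idx[k]]]
    for (j in seq_len(nd)) {
      cost[k, j] <- cosine_distance_to_gallery(t$gallery, det_emb[j, ])
    }
    gate <- kf_gating_distance(t$kf, det_boxes)
    cost[k, gate > cfg$gating_chi2] <- Inf
  }
  cost
}

iou_cost_matrix <- function(trk, track_idx, det_boxes, gate = FALSE) {
  pred <- do.call(rbind, lapply(track_idx, function(i) {
    unclass(kf_box(trk$tracks[[i]]$kf))
  }))
  cost <- 1 - box_iou_matrix(pred, det_boxes)
  if (gate) {
    for (k in seq_along(track_idx)) {
      gd <- kf_gating_distance(trk$tracks[[track_idx[k]]]$kf, det_boxes)
      cost[k, gd > trk$cfg$gating_chi2] <- Inf
    }
  }
  cost
}

# Cascade matching: confirmed tracks grouped by staleness, freshest first,
# each group solved by thresholded Hungarian assignment on appearance cost
# (Mahalanobis-gated). Without embeddings, falls back to gated IoU cost.
cascade_match <- function(trk, confirmed_idx, det_boxes, det_emb) {
  cfg <- trk$cfg
  matches <- matrix(integer(0), 0L, 2L)
  unmatched_det <- seq_len(nrow(det_boxes))
  remaining <- confirmed_idx
  use_appearance <- !is.null(det_emb)
  if (!use_appearance && length(confirmed_idx) > 0L && !trk$fallback_logged) {
    message("pentrack: no embeddings supplied; cascade matching falls back to IoU cost")
    trk$fallback_logged <- TRUE
  }
  for (level in seq_len(cfg$max_age)) {
    if (length(unmatched_det) == 0L || length(remaining) == 0L) break
    level_idx <- remaining[vapply(trk$tracks[remaining],
                                  function(t) t$time_since_update == level,
                                  logical(1L))]
    if (length(level_idx) == 0L) next
    boxes <- det_boxes[unmatched_det, , drop = FALSE]
    if (use_appearance) {
      cost <- appearance_cost_matrix(trk, level_idx, boxes,
                                     det_emb[unmatched_det, , drop = FALSE])
      cap <- cfg$max_cosine_distance
    } else {
      cost <- iou_cost_matrix(trk, level_idx, boxes, gate = TRUE)
      cap <- cfg$iou_threshold_round1
    }
    res <- hungarian_assign(cost, max_cost = cap)
    if (nrow(res$matches) > 0L) {
      matches <- rbind(matches,
                       cbind(level_idx[res$matches[, "row"]],
                             unmatched_det[res$matches[, "col"]]))
      unmatched_det <- unmatched_det[-res$matches[, "col"]]
      remaining <- setdiff(remaining, level_idx[res$matches[, "row"]])
    }
  }
  list(matches = matches, unmatched_tracks = remaining,
       unmatched_dets = unmatched_det)
}

# One Hungarian round on 1 - IoU cost with cap `threshold`.
iou_match_round <- function(trk, track_idx, det_idx, det_boxes, threshold) {
  if (length(track_idx) == 0L || length(det_idx) == 0L) {
    return(list(matches = matrix(integer(0), 0L, 2L),
                unmatched_tracks = track_idx, unmatched_dets = det_idx))
  }
  cost <- iou_cost_matrix(trk, track_idx, det_boxes[det_idx, , drop = FALSE])
  res <- hungarian_assign(cost, max_cost = threshold)
  matches <- cbind(track_idx[res$matches[, "row"]],
                   det_idx[res$matches[, "col"]])
  list(matches = matches,
       unmatched_tracks = track_idx[res$unmatched_rows],
       unmatched_dets = det_idx[res$unmatched_cols])
}

# New-track creation under the population cap. First frame: one tentative
# track per unmatched detection. Later frames with the cap enabled: create
# while n > alive count, drop the rest; cap disabled: always create.
create_or_drop <- function(trk, det_idx, dets, det_emb, n, is_first_frame) {
  cfg <- trk$cfg
  created <- 0L
  for (j in det_idx) {
    alive <- sum(track_states(trk) %in% alive_states)
    create <- is_first_frame || !cfg$cap_enabled || n > alive
    if (create) {
      if (cfg$cap_enabled && !is_first_frame) {
        # cap safety: creation must never happen at or above the estimate
        stopifnot(alive < n)
      }
      emb <- if (is.null(det_emb)) NULL else det_emb[j, ]
      trk$tracks[[length(trk$tracks) + 1L]] <-
        new_track(trk$next_id, c(dets$cx[j], dets$cy[j], dets$w[j], dets$h[j]),
                  dets$conf[j], dets$behavior[j], emb, cfg)
      trk$next_id <- trk$next_id + 1L
      created <- created + 1L
    } else {
      trk$n_dropped <- trk$n_dropped + 1L
    }
  }
  created
}

# Track lifecycle maintenance, once per frame after matching:
# tentative tracks unmatched this frame die; tentative tracks reaching
# n_init hits confirm; confirmed tracks stale beyond max_age die.
prune_tracks <- function(trk) {
  cfg <- trk$cfg
  for (i in seq_along(trk$tracks)) {
    t <- trk$tracks[[i]]
    if (t$state == "deleted") next
    if (t$state == "tentative") {
      if (t$time_since_update > 0L) {
        t$state <- "deleted"
      } else if (t$hits >= cfg$n_init) {
        t$state <- "confirmed"
      }
    } else if (t$state == "confirmed" && t$time_since_update > cfg$max_age) {
      t$state <- "deleted"
    }
    trk$tracks[[i]] <- t
  }
  invisible(trk)
}

apply_match <- function(trk, i, j, dets, det_emb) {
  t <- trk$tracks[[i]]
  t$kf <- kf_update(t$kf, c(dets$cx[j], dets$cy[j], dets$w[j], dets$h[j]))
  t$hits <- t$hits + 1L
  t$time_since_update <- 0L
  t$conf <- dets$conf[j]
  t$behaviors <- c(t$behaviors, as.character(dets$behavior[j]))
  if (!is.null(det_emb)) {
    t$gallery <- c(t$gallery, list(det_emb[j, ]))
    if (length(t$gallery) > trk$cfg$gallery_size) {
      t$gallery <- t$gallery[(length(t$gallery) - trk$cfg$gallery_size + 1L):
                               length(t$gallery)]
    }
  }
  trk$tracks[[i]] <- t
}

majority_behavior <- function(behaviors, window) {
  b <- utils::tail(behaviors, window)
  if (length(b) == 0L) return(NA_character_)
  tab <- table(b)
  top <- names(tab)[tab == max(tab)]
  if (length(top) == 1L) return(top)
  # tie: most recently observed among the tied labels
  b[max(which(b %in% top))]
}

#' Advance the tracker by one frame
#'
#' Executes the full per-frame pipeline: Kalman prediction for every alive
#' track; cascade (appearance) matching of confirmed tracks; a first IoU
#' matching round over tentative tracks and just-missed confirmed tracks; an
#' optional second IoU round over all remaining unmatched tracks; the
#' population estimate from raw detection counts; population-capped track
#' creation; and lifecycle pruning.
#'
#' @param trk A [pig_tracker()].
#' @param dets Data frame of this frame's detections with columns
#'   `frame, cx, cy, w, h, conf, behavior` (may have zero rows). All rows
#'   must share one frame index, strictly greater than the previous call's.
#' @param embeddings Optional matrix of unit-norm appearance embeddings,
#'   one row per detection row.
#' @return Data frame of confirmed tracks updated this frame:
#'   `frame, id, cx, cy, w, h, conf, behavior` (behavior is the majority
#'   label of the track's recent assigned detections).
#' @export
tracker_step <- function(trk, dets, embeddings = NULL) {
  stopifnot(inherits(trk, "pig_tracker"))
  cfg <- trk$cfg
  frame <- if (nrow(dets) > 0L) unique(dets$frame) else trk$last_frame + 1L
  if (length(frame) != 1L) stop("detections must all belong to one frame", call. = FALSE)
  if (frame <= trk$last_frame) {
    stop("frames must be presented in strictly increasing order (got ",
         frame, " after ", trk$last_frame, ")", call. = FALSE)
  }
  if (!is.null(embeddings)) {
    embeddings <- as.matrix(embeddings)
    stopifnot(nrow(embeddings) == nrow(dets))
  }
  # confidence filter ahead of any association or counting
  keep <- if (nrow(dets) > 0L) dets$conf >= cfg$min_confidence else logical(0)
  dets <- dets[keep, , drop = FALSE]
  if (!is.null(embeddings)) embeddings <- embeddings[keep, , drop = FALSE]
  trk$last_frame <- frame
  trk$n_frames_seen <- trk$n_frames_seen + 1L
  is_first <- trk$n_frames_seen == 1L

  # predict + ageing
  for (i in seq_along(trk$tracks)) {
    t <- trk$tracks[[i]]
    if (t$state == "deleted") next
    t$kf <- kf_predict(t$kf)
    t$age <- t$age + 1L
    t$time_since_update <- t$time_since_update + 1L
    trk$tracks[[i]] <- t
  }

  det_boxes <- if (nrow(dets) > 0L) {
    cbind(cx = dets$cx, cy = dets$cy, w = dets$w, h = dets$h)
  } else matrix(0, 0L, 4L, dimnames = list(NULL, c("cx", "cy", "w", "h")))

  states <- track_states(trk)
  confirmed_idx <- which(states == "confirmed")
  tentative_idx <- which(states == "tentative")

  all_matches <- matrix(integer(0), 0L, 2L)

  # (1) cascade matching on confirmed tracks
  cm <- cascade_match(trk, confirmed_idx, det_boxes, embeddings)
  all_matches <- rbind(all_matches, cm$matches)

  # (2) IoU round 1: tentative tracks + confirmed tracks unmatched in the
  # cascade that were updated last frame
  r1_tracks <- c(tentative_idx,
                 cm$unmatched_tracks[vapply(trk$tracks[cm$unmatched_tracks],
                                            function(t) t$time_since_update == 1L,
                                            logical(1L))])
  r1_tracks <- sort(r1_tracks)
  r1 <- iou_match_round(trk, r1_tracks, cm$unmatched_dets, det_boxes,
                        cfg$iou_threshold_round1)
  all_matches <- rbind(all_matches, r1$matches)

  # (2b) IoU round 2 over everything still unmatched (any staleness)
  leftover_tracks <- sort(c(r1$unmatched_tracks,
                            setdiff(cm$unmatched_tracks, r1_tracks)))
  unmatched_dets <- r1$unmatched_dets
  if (cfg$second_round_enabled) {
    r2 <- iou_match_round(trk, leftover_tracks, unmatched_dets, det_boxes,
                          cfg$iou_threshold_round2)
    all_matches <- rbind(all_matches, r2$matches)
    unmatched_dets <- r2$unmatched_dets
  }

  # KF correction for all matched tracks
  if (nrow(all_matches) > 0L) {
    for (k in seq_len(nrow(all_matches))) {
      apply_match(trk, all_matches[k, 1L], all_matches[k, 2L], dets, embeddings)
    }
  }

  # (3) population estimate from raw per-frame detection counts, then capped
  # creation for detections unmatched after both IoU rounds
  trk$count_history <- utils::tail(c(trk$count_history, nrow(dets)),
                                   cfg$cap_window)
  n <- population_estimate(trk$count_history)
  create_or_drop(trk, unmatched_dets, dets, embeddings, n, is_first)

  prune_tracks(trk)

  # emit confirmed tracks updated this frame
  out_idx <- which(vapply(trk$tracks, function(t) {
    t$state == "confirmed" && t$time_since_update == 0L
  }, logical(1L)))
  if (length(out_idx) == 0L) {
    return(data.frame(frame = integer(0), id = integer(0), cx = numeric(0),
                      cy = numeric(0), w = numeric(0), h = numeric(0),
                      conf = numeric(0), behavior = character(0),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(trk$tracks[out_idx], function(t) {
    b <- kf_box(t$kf)
    data.frame(frame = frame, id = t$id, cx = b[["cx"]], cy = b[["cy"]],
               w = b[["w"]], h = b[["h"]], conf = t$conf,
               behavior = majority_behavior(t$behaviors, cfg$cap_window),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Track a full detection sequence
#'
#' Runs [tracker_step()] over every frame from the first to the last frame
#' index present in `dets` (frames with no detections are stepped with an
#' empty set, so tracks age through detector dropouts).
#'
#' @param dets Detection data frame (`frame, cx, cy, w, h, conf, behavior`).
#' @param cfg A [tracker_config()].
#' @param embeddings Optional embedding matrix aligned with `dets` rows.
#' @return Result trajectory data frame
#'   (`frame, id, cx, cy, w, h, conf, behavior`) with attributes `max_id`
#'   (largest id ever assigned, 0 if none) and `n_dropped` (detections
#'   discarded by the population cap).
#' @export
track_sequence <- function(dets, cfg = tracker_config(), embeddings = NULL) {
  stopifnot(is.data.frame(dets), nrow(dets) > 0L)
  trk <- pig_tracker(cfg)
  out <- vector("list", max(dets$frame))
  for (f in seq(min(dets$frame), max(dets$frame))) {
    rows <- which(dets$frame == f)
    emb <- if (is.null(embeddings)) NULL else embeddings[rows, , drop = FALSE]
    out[[f]] <- tracker_step(trk, dets[rows, , drop = FALSE], emb)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(frame = integer(0), id = integer(0), cx = numeric(0),
                      cy = numeric(0), w = numeric(0), h = numeric(0),
                      conf = numeric(0), behavior = character(0))
  }
  rownames(res) <- NULL
  attr(res, "max_id") <- trk$next_id - 1L
  attr(res, "n_dropped") <- trk$n_dropped
  res
}
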