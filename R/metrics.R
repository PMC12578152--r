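#' Trajectory file checks
#'
#' A trajectory table has one row per (frame, id) with a center-form box.
#' Frames need not be contiguous but (frame, id) pairs must be unique.
#'
#' @param x Data frame with columns `frame, id, cx, cy, w, h`.
#' @param what Label used in error messages.
#' @return `x`, invisibly.
#' @keywords internal
check_trajectory <- function(x, what = "trajectory") {
  need <- c("frame", "id", "cx", "cy", "w", "h")
  if (!all(need %in% names(x))) {
    stop(what, " must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(x[, c("frame", "id")])) {
    stop(what, " has duplicated (frame, id) pairs", call. = FALSE)
  }
  if (nrow(x) > 0L && (any(x$w <= 0) || any(x$h <= 0))) {
    stop(what, " contains non-positive box dimensions", call. = FALSE)
  }
  invisible(x)
}

# Per-frame gt/hyp correspondence under the CLEAR-MOT protocol: pairs matched
# in the previous frame persist while they still overlap >= iou_thr; the
# remainder is matched by Hungarian assignment on 1 - IoU.
frame_correspondence <- function(gt_f, hyp_f, prev_pairs, iou_thr = 0.5) {
  ng <- nrow(gt_f); nh <- nrow(hyp_f)
  pairs <- matrix(numeric(0), 0L, 3L,
                  dimnames = list(NULL, c("gt", "hyp", "iou")))
  if (ng == 0L || nh == 0L) return(pairs)
  iou <- box_iou_matrix(gt_f, hyp_f)
  g_free <- rep(TRUE, ng); h_free <- rep(TRUE, nh)
  # persistence: keep previous pairings that still hold
  if (length(prev_pairs) > 0L) {
    for (gid in names(prev_pairs)) {
      gi <- match(as.numeric(gid), gt_f$id)
      hi <- match(prev_pairs[[gid]], hyp_f$id)
      if (!is.na(gi) && !is.na(hi) && g_free[gi] && h_free[hi] &&
          iou[gi, hi] >= iou_thr) {
        pairs <- rbind(pairs, c(gt_f$id[gi], hyp_f$id[hi], iou[gi, hi]))
        g_free[gi] <- FALSE; h_free[hi] <- FALSE
      }
    }
  }
  gi_rest <- which(g_free); hi_rest <- which(h_free)
  if (length(gi_rest) > 0L && length(hi_rest) > 0L) {
    cost <- 1 - iou[gi_rest, hi_rest, drop = FALSE]
    res <- hungarian_assign(cost, max_cost = 1 - iou_thr)
    if (nrow(res$matches) > 0L) {
      for (k in seq_len(nrow(res$matches))) {
        gi <- gi_rest[res$matches[k, "row"]]
        hi <- hi_rest[res$matches[k, "col"]]
        pairs <- rbind(pairs, c(gt_f$id[gi], hyp_f$id[hi], iou[gi, hi]))
      }
    }
  }
  pairs
}

#' CLEAR-MOT evaluation
#'
#' Computes MOTA, MOTP, recall, precision and identity switches by the
#' CLEAR-MOT protocol: per frame, ground-truth/hypothesis pairs matched in
#' the previous frame persist while their IoU stays at or above `iou_thr`,
#' the rest are matched by minimum-cost assignment on `1 - IoU`, and an
#' identity switch is counted whenever a ground-truth object's matched
#' hypothesis id differs from the hypothesis id it was last matched to.
#' MOTP is reported as the mean IoU of matched pairs, in percent.
#'
#' @param gt Ground-truth trajectory data frame (`frame, id, cx, cy, w, h`).
#' @param hyp Hypothesis trajectory data frame (same columns).
#' @param iou_thr Overlap threshold for a valid correspondence (default 0.5).
#' @return A list of class `mot_report`: `mota, motp, idf1, ids, rcll, prcn`
#'   (percent except `ids`), plus raw counts `fp, fn, num_gt, num_matches`.
#'   The identity `mota = 100 (1 - (fn + fp + ids)/num_gt)` holds exactly.
#' @export
clear_mot <- function(gt, hyp, iou_thr = 0.5) {
  check_trajectory(gt, "ground truth")
  check_trajectory(hyp, "hypothesis")
  if (nrow(gt) == 0L) stop("empty ground truth", call. = FALSE)
  frames <- sort(unique(gt$frame))
  frames <- sort(union(frames, unique(hyp$frame)))
  prev_pairs <- list()       # persistent pairing for correspondence
  last_hyp_for_gt <- list()  # last matched hyp id ever, for ID switches
  fp <- 0L; fn <- 0L; ids <- 0L; matches <- 0L; iou_sum <- 0
  for (f in frames) {
    gt_f <- gt[gt$frame == f, , drop = FALSE]
    hyp_f <- hyp[hyp$frame == f, , drop = FALSE]
    pairs <- frame_correspondence(gt_f, hyp_f, prev_pairs, iou_thr)
    fn <- fn + nrow(gt_f) - nrow(pairs)
    fp <- fp + nrow(hyp_f) - nrow(pairs)
    matches <- matches + nrow(pairs)
    prev_pairs <- list()
    if (nrow(pairs) > 0L) {
      iou_sum <- iou_sum + sum(pairs[, "iou"])
      for (k in seq_len(nrow(pairs))) {
        gid <- as.character(pairs[k, "gt"]); hid <- pairs[k, "hyp"]
        old <- last_hyp_for_gt[[gid]]
        if (!is.null(old) && old != hid) ids <- ids + 1L
        last_hyp_for_gt[[gid]] <- hid
        prev_pairs[[gid]] <- hid
      }
    }
  }
  num_gt <- nrow(gt)
  motp <- if (matches > 0L) 100 * iou_sum / matches else {
    warning("no matched pairs; MOTP reported as 0")
    0
  }
  structure(list(
    mota = 100 * (1 - (fn + fp + ids) / num_gt),
    motp = motp,
    idf1 = idf1(gt, hyp, iou_thr),
    ids = ids,
    rcll = 100 * (num_gt - fn) / num_gt,
    prcn = if (matches + fp > 0L) 100 * matches / (matches + fp) else 0,
    fp = fp, fn = fn, num_gt = num_gt, num_matches = matches),
    class = "mot_report")
}

#' @export
print.mot_report <- function(x, ...) {
  cat(sprintf("MOTA %.2f  MOTP %.2f  IDF1 %.2f  IDs %d  Rcll %.2f  Prcn %.2f\n",
              x$mota, x$motp, x$idf1, x$ids, x$rcll, x$prcn))
  cat(sprintf("  (FP %d, FN %d, matches %d, gt rows %d)\n",
              x$fp, x$fn, x$num_matches, x$num_gt))
  invisible(x)
}

#' Identity F1 score
#'
#' IDF1 under the global one-to-one assignment of hypothesis ids to
#' ground-truth ids that maximizes identity true positives (frames where the
#' assigned pair co-occurs with IoU at or above `iou_thr`):
#' `IDF1 = 100 * 2 IDTP / (2 IDTP + IDFP + IDFN)`.
#'
#' @inheritParams clear_mot
#' @return IDF1 in percent.
#' @export
idf1 <- function(gt, hyp, iou_thr = 0.5) {
  check_trajectory(gt, "ground truth")
  check_trajectory(hyp, "hypothesis")
  if (nrow(gt) == 0L) stop("empty ground truth", call. = FALSE)
  g_ids <- sort(unique(gt$id)); h_ids <- sort(unique(hyp$id))
  total_gt <- nrow(gt); total_hyp <- nrow(hyp)
  if (length(h_ids) == 0L) return(0)
  overlap <- matrix(0, length(g_ids), length(h_ids))
  for (f in sort(unique(gt$frame))) {
    gt_f <- gt[gt$frame == f, , drop = FALSE]
    hyp_f <- hyp[hyp$frame == f, , drop = FALSE]
    if (nrow(hyp_f) == 0L) next
    iou <- box_iou_matrix(gt_f, hyp_f)
    hit <- which(iou >= iou_thr, arr.ind = TRUE)
    if (nrow(hit) > 0L) {
      gi <- match(gt_f$id[hit[, 1L]], g_ids)
      hi <- match(hyp_f$id[hit[, 2L]], h_ids)
      for (k in seq_along(gi)) overlap[gi[k], hi[k]] <- overlap[gi[k], hi[k]] + 1
    }
  }
  # maximize total IDTP over one-to-one id assignments (pad to square; a
  # zero-overlap pairing contributes nothing, same as leaving ids unmatched)
  res <- hungarian_assign(-overlap, max_cost = 0)
  idtp <- if (nrow(res$matches) > 0L) {
    sum(overlap[res$matches[, , drop = FALSE]])
  } else 0
  100 * 2 * idtp / (total_gt + total_hyp)
}

#' Compare a baseline and an improved tracking run
#'
#' Evaluates both hypothesis files against the same ground truth and reports
#' the per-metric deltas (improved minus baseline).
#'
#' @param gt Ground-truth trajectory data frame.
#' @param hyp_baseline,hyp_improved Hypothesis trajectory data frames.
#' @param iou_thr Correspondence threshold (default 0.5).
#' @return List of class `mot_comparison` with elements `baseline`,
#'   `improved` (both `mot_report`) and `delta` (named numeric vector over
#'   mota, motp, idf1, ids, rcll, prcn).
#' @export
compare_runs <- function(gt, hyp_baseline, hyp_improved, iou_thr = 0.5) {
  base <- clear_mot(gt, hyp_baseline, iou_thr)
  impr <- clear_mot(gt, hyp_improved, iou_thr)
  keys <- c("mota", "motp", "idf1", "ids", "rcll", "prcn")
  delta <- vapply(keys, function(k) impr[[k]] - base[[k]], numeric(1L))
  structure(list(baseline = base, improved = impr, delta = delta),
            class = "mot_comparison")
}

#' @export
print.mot_comparison <- function(x, ...) {
  keys <- c("mota", "motp", "idf1", "ids", "rcll", "prcn")
  tab <- rbind(baseline = vapply(keys, function(k) x$baseline[[k]], numeric(1L)),
               improved = vapply(keys, function(k) x$improved[[k]], numeric(1L)),
               delta = x$delta)
  colnames(tab) <- toupper(keys)
  print(round(tab, 2))
  invisible(x)
}

#' Flatten a mot_report to a one-row data frame
#' @param x A `mot_report`.
#' @return One-row data frame of its numeric fields.
#' @export
as.data.frame.mot_report <- function(x, ...) {
  data.frame(mota = x$mota, motp = x$motp, idf1 = x$idf1, ids = x$ids,
             rcll = x$rcll, prcn = x$prcn, fp = x$fp, fn = x$fn,
             num_gt = x$num_gt, num_matches = x$num_matches)
}
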