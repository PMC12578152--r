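# Independent oracles used across the suite. These deliberately share no
# code with the package implementation: plain direct arithmetic, exhaustive
# enumeration, and (for the metric protocol) an external Python reference.

# All permutations of 1..n (n <= 7), in lexicographic order.
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, 0L, n)
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub), n - 1L)))
  }
  out
}

# Brute-force thresholded assignment: minimum total cost over all injective
# maps of the smaller dimension, on the sentinel-substituted matrix (same
# preprocessing the solver applies), then threshold-filtered.
brute_force_assign <- function(cost, max_cost = Inf) {
  nr <- nrow(cost); nc <- ncol(cost)
  work <- cost
  sentinel <- max(max(work[is.finite(work)], -Inf), max_cost, 1) + 1e6
  work[!is.finite(work) | work > max_cost] <- sentinel
  if (nr <= nc) {
    perms <- all_perms(nc)
    best <- Inf; best_cols <- NULL
    for (p in seq_len(nrow(perms))) {
      cols <- perms[p, seq_len(nr)]
      tot <- sum(work[cbind(seq_len(nr), cols)])
      if (tot < best) { best <- tot; best_cols <- cols }
    }
    pairs <- cbind(seq_len(nr), best_cols)
  } else {
    perms <- all_perms(nr)
    best <- Inf; best_rows <- NULL
    for (p in seq_len(nrow(perms))) {
      rows <- perms[p, seq_len(nc)]
      tot <- sum(work[cbind(rows, seq_len(nc))])
      if (tot < best) { best <- tot; best_rows <- rows }
    }
    pairs <- cbind(best_rows, seq_len(nc))
  }
  keep <- cost[pairs] <= max_cost & is.finite(cost[pairs])
  list(pairs = pairs[keep, , drop = FALSE], total = best)
}

# Direct-arithmetic Shape-IoU oracle: the loss written out in one flat
# expression from corner coordinates, no shared helpers.
shape_iou_oracle <- function(pred, gt, scale = 0, theta = 4) {
  px1 <- pred[1] - pred[3] / 2; px2 <- pred[1] + pred[3] / 2
  py1 <- pred[2] - pred[4] / 2; py2 <- pred[2] + pred[4] / 2
  gx1 <- gt[1] - gt[3] / 2; gx2 <- gt[1] + gt[3] / 2
  gy1 <- gt[2] - gt[4] / 2; gy2 <- gt[2] + gt[4] / 2
  iw <- max(0, min(px2, gx2) - max(px1, gx1))
  ih <- max(0, min(py2, gy2) - max(py1, gy1))
  inter <- iw * ih
  iou <- inter / (pred[3] * pred[4] + gt[3] * gt[4] - inter)
  ww <- 2 * gt[3]^scale / (gt[3]^scale + gt[4]^scale)
  hh <- 2 * gt[4]^scale / (gt[3]^scale + gt[4]^scale)
  c2 <- (max(px2, gx2) - min(px1, gx1))^2 + (max(py2, gy2) - min(py1, gy1))^2
  dist <- hh * (pred[1] - gt[1])^2 / c2 + ww * (pred[2] - gt[2])^2 / c2
  ow <- hh * abs(pred[3] - gt[3]) / max(pred[3], gt[3])
  oh <- ww * abs(pred[4] - gt[4]) / max(pred[4], gt[4])
  omega <- (1 - exp(-ow))^theta + (1 - exp(-oh))^theta
  1 - iou + dist + omega / 2
}

# Exhaustive IDF1 oracle: enumerate every one-to-one map of hypothesis ids
# to ground-truth ids (small cases only) and take the best.
idf1_oracle <- function(gt, hyp, iou_thr = 0.5) {
  g_ids <- sort(unique(gt$id)); h_ids <- sort(unique(hyp$id))
  m <- matrix(0, length(g_ids), length(h_ids),
              dimnames = list(g_ids, h_ids))
  for (f in sort(unique(c(gt$frame, hyp$frame)))) {
    gf <- gt[gt$frame == f, , drop = FALSE]
    hf <- hyp[hyp$frame == f, , drop = FALSE]
    for (a in seq_len(nrow(gf))) for (b in seq_len(nrow(hf))) {
      iw <- max(0, min(gf$cx[a] + gf$w[a]/2, hf$cx[b] + hf$w[b]/2) -
                   max(gf$cx[a] - gf$w[a]/2, hf$cx[b] - hf$w[b]/2))
      ih <- max(0, min(gf$cy[a] + gf$h[a]/2, hf$cy[b] + hf$h[b]/2) -
                   max(gf$cy[a] - gf$h[a]/2, hf$cy[b] - hf$h[b]/2))
      ov <- iw * ih / (gf$w[a]*gf$h[a] + hf$w[b]*hf$h[b] - iw * ih)
      if (ov >= iou_thr) {
        m[as.character(gf$id[a]), as.character(hf$id[b])] <-
          m[as.character(gf$id[a]), as.character(hf$id[b])] + 1
      }
    }
  }
  ng <- length(g_ids); nh <- length(h_ids)
  k <- max(ng, nh)
  best <- 0
  perms <- all_perms(k)
  for (p in seq_len(nrow(perms))) {
    tot <- 0
    for (gi in seq_len(ng)) {
      hi <- perms[p, gi]
      if (hi <= nh) tot <- tot + m[gi, hi]
    }
    best <- max(best, tot)
  }
  100 * 2 * best / (nrow(gt) + nrow(hyp))
}

# Random valid box as a plain numeric vector (cx, cy, w, h).
random_box <- function(span = 100) {
  c(runif(1, -span, span), runif(1, -span, span),
    runif(1, 0.5, span / 2), runif(1, 0.5, span / 2))
}

# Run the external Python reference implementation of the CLEAR-MOT/IDF1
# protocol (scipy-based, shares no code with the package).
python_mot_reference <- function(gt, hyp, iou_thr = 0.5) {
  py <- Sys.which("python")
  if (!nzchar(py)) return(NULL)
  gt_file <- tempfile(fileext = ".csv")
  hyp_file <- tempfile(fileext = ".csv")
  out_file <- tempfile(fileext = ".json")
  on.exit(unlink(c(gt_file, hyp_file, out_file)))
  utils::write.csv(gt[, c("frame", "id", "cx", "cy", "w", "h")], gt_file,
                   row.names = FALSE)
  utils::write.csv(hyp[, c("frame", "id", "cx", "cy", "w", "h")], hyp_file,
                   row.names = FALSE)
  status <- system2(py, c(test_path("ref_mot.py"), gt_file, hyp_file,
                          as.character(iou_thr), out_file),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0L || !file.exists(out_file)) return(NULL)
  jsonlite::read_json(out_file, simplifyVector = TRUE)
}
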