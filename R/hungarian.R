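#' Minimum-cost linear assignment (Hungarian algorithm)
#'
#' Shortest-augmenting-path implementation with dual potentials (O(n^3)),
#' written for the small association problems of multi-object tracking
#' (tens of rows and columns). Rows are processed in index order and path
#' extension breaks ties on the lowest column index, so the solution is
#' deterministic.
#'
#' @param cost Square numeric matrix of finite costs.
#' @return Integer vector `a` with `a[i]` the column assigned to row `i`.
#' @keywords internal
solve_lap <- function(cost) {
  n <- nrow(cost)
  if (n == 0L) return(integer(0))
  stopifnot(ncol(cost) == n, all(is.finite(cost)))
  u <- numeric(n)          # row potentials
  v <- numeric(n + 1L)     # column potentials, slot 1 = virtual column 0
  p <- integer(n + 1L)     # p[j+1]: row matched to column j (0 = none)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (used[j + 1L]) next
        cur <- cost[i0, j] - u[i0] - v[j + 1L]
        if (cur < minv[j + 1L]) {
          minv[j + 1L] <- cur
          way[j + 1L] <- j0
        }
        if (minv[j + 1L] < delta) {
          delta <- minv[j + 1L]
          j1 <- j
        }
      }
      for (j in 0:n) {
        if (used[j + 1L]) {
          u[p[j + 1L]] <- u[p[j + 1L]] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(n)) assignment[p[j + 1L]] <- j
  assignment
}

#' Thresholded Hungarian assignment
#'
#' Solves the rectangular min-cost assignment after replacing entries above
#' `max_cost` (and non-finite entries) with a large sentinel, then discards
#' any produced match whose original cost exceeds `max_cost`. The smaller
#' dimension is padded with a constant, which leaves the optimal assignment
#' of real entries unchanged.
#'
#' @param cost Numeric matrix (rows: tracks, columns: detections).
#' @param max_cost Matches with cost above this are rejected.
#' @return List with `matches` (2-column integer matrix of row/col pairs),
#'   `unmatched_rows` and `unmatched_cols`.
#' @examples
#' hungarian_assign(matrix(c(0.1, 0.9, 0.8, 0.2), 2, 2), max_cost = 0.5)
#' @export
hungarian_assign <- function(cost, max_cost = Inf) {
  if (is.null(dim(cost))) cost <- matrix(cost, nrow = 1L)
  nr <- nrow(cost); nc <- ncol(cost)
  if (nr == 0L || nc == 0L) {
    return(list(matches = matrix(integer(0), 0L, 2L,
                                 dimnames = list(NULL, c("row", "col"))),
                unmatched_rows = seq_len(nr), unmatched_cols = seq_len(nc)))
  }
  work <- cost
  finite_max <- suppressWarnings(max(work[is.finite(work)], -Inf))
  sentinel <- max(finite_max, max_cost, 1) + 1e6
  work[!is.finite(work) | work > max_cost] <- sentinel
  n <- max(nr, nc)
  sq <- matrix(0, n, n)
  sq[seq_len(nr), seq_len(nc)] <- work
  a <- solve_lap(sq)
  rows <- seq_len(nr)
  cols <- a[seq_len(nr)]
  keep <- cols <= nc & cost[cbind(rows, pmin(cols, nc))] <= max_cost &
    is.finite(cost[cbind(rows, pmin(cols, nc))])
  matches <- cbind(row = rows[keep], col = cols[keep])
  list(matches = matches,
       unmatched_rows = setdiff(rows, matches[, "row"]),
       unmatched_cols = setdiff(seq_len(nc), matches[, "col"]))
}
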