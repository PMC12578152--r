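#' Read a MOTChallenge-style CSV file
#'
#' Dialects: `det` ("frame,id,bb_left,bb_top,w,h,conf,class,vis"), `gt`
#' ("frame,id,bb_left,bb_top,w,h,flag,class,vis") and `result`
#' ("frame,id,bb_left,bb_top,w,h,conf,-1,-1,-1"). Files carry top-left +
#' width/height boxes with 1-based frames; boxes are converted to center
#' form internally. Behavior classes 1..4 map to stand, lie, eat, attack.
#'
#' @param path File path.
#' @param dialect One of `"det"`, `"gt"`, `"result"`.
#' @return For `det`: a detection data frame
#'   (`frame, cx, cy, w, h, conf, behavior`). For `gt`/`result`: a
#'   trajectory data frame (`frame, id, cx, cy, w, h`, plus `behavior` for
#'   gt rows carrying a class and `conf` for results).
#' @export
read_mot <- function(path, dialect = c("det", "gt", "result")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty file: ", path, call. = FALSE)
  parts <- strsplit(lines, ",", fixed = TRUE)
  nfield <- lengths(parts)
  bad <- which(nfield < 6L)
  if (length(bad) > 0L) {
    stop("malformed row at line ", bad[1L], " of ", path,
         " (expected at least 6 comma-separated fields)", call. = FALSE)
  }
  num <- suppressWarnings(
    t(vapply(parts, function(p) as.numeric(p[1:6]), numeric(6L))))
  badnum <- which(apply(num, 1L, function(r) any(is.na(r))))
  if (length(badnum) > 0L) {
    stop("non-numeric field at line ", badnum[1L], " of ", path, call. = FALSE)
  }
  badwh <- which(num[, 5L] <= 0 | num[, 6L] <= 0)
  if (length(badwh) > 0L) {
    stop("non-positive box dimensions at line ", badwh[1L], " of ", path,
         call. = FALSE)
  }
  cx <- num[, 3L] + num[, 5L] / 2
  cy <- num[, 4L] + num[, 6L] / 2
  extra7 <- vapply(parts, function(p) {
    if (length(p) >= 7L) suppressWarnings(as.numeric(p[7L])) else NA_real_
  }, numeric(1L))
  extra8 <- vapply(parts, function(p) {
    if (length(p) >= 8L) suppressWarnings(as.numeric(p[8L])) else NA_real_
  }, numeric(1L))
  if (dialect == "det") {
    data.frame(frame = as.integer(num[, 1L]), cx = cx, cy = cy,
               w = num[, 5L], h = num[, 6L],
               conf = ifelse(is.na(extra7), 1, extra7),
               behavior = class_to_behavior(extra8),
               stringsAsFactors = FALSE)
  } else if (dialect == "gt") {
    data.frame(frame = as.integer(num[, 1L]), id = as.integer(num[, 2L]),
               cx = cx, cy = cy, w = num[, 5L], h = num[, 6L],
               behavior = class_to_behavior(extra8),
               stringsAsFactors = FALSE)
  } else {
    data.frame(frame = as.integer(num[, 1L]), id = as.integer(num[, 2L]),
               cx = cx, cy = cy, w = num[, 5L], h = num[, 6L],
               conf = ifelse(is.na(extra7), 1, extra7),
               stringsAsFactors = FALSE)
  }
}

class_to_behavior <- function(cls) {
  out <- rep(NA_character_, length(cls))
  ok <- !is.na(cls) & cls >= 1 & cls <= 4
  out[ok] <- BEHAVIORS[cls[ok]]
  out[!ok] <- "stand"
  out
}

behavior_to_class <- function(b) {
  i <- match(b, BEHAVIORS)
  i[is.na(i)] <- 1L
  i
}

#' Write a MOTChallenge-style CSV file
#'
#' Inverse of [read_mot()]; center-form boxes are written back as top-left +
#' width/height. Numbers use up to 6 decimal places with trailing zeros
#' trimmed, so write-then-read round-trips canonical files.
#'
#' @param x Detection or trajectory data frame (center-form boxes).
#' @param path Output path.
#' @param dialect One of `"det"`, `"gt"`, `"result"`.
#' @return `path`, invisibly.
#' @export
write_mot <- function(x, path, dialect = c("det", "gt", "result")) {
  dialect <- match.arg(dialect)
  if (nrow(x) > 0 && (any(x$w <= 0) || any(x$h <= 0))) {
    stop("refusing to write non-positive box dimensions", call. = FALSE)
  }
  left <- x$cx - x$w / 2
  top <- x$cy - x$h / 2
  fmt <- function(v) sub("\\.?0+$", "", sprintf("%.6f", v))
  lines <- switch(dialect,
    det = sprintf("%d,-1,%s,%s,%s,%s,%s,%d,1",
                  x$frame, fmt(left), fmt(top), fmt(x$w), fmt(x$h),
                  fmt(x$conf), behavior_to_class(x$behavior)),
    gt = sprintf("%d,%d,%s,%s,%s,%s,1,%d,1",
                 x$frame, x$id, fmt(left), fmt(top), fmt(x$w), fmt(x$h),
                 if (is.null(x$behavior)) rep(1L, nrow(x)) else
                   behavior_to_class(x$behavior)),
    result = sprintf("%d,%d,%s,%s,%s,%s,%s,-1,-1,-1",
                     x$frame, x$id, fmt(left), fmt(top), fmt(x$w), fmt(x$h),
                     fmt(if (is.null(x$conf)) rep(1, nrow(x)) else x$conf)))
  writeLines(lines, path)
  invisible(path)
}

#' Read / write YOLO label text
#'
#' One line per object: `class cx cy w h`, whitespace-separated, with
#' coordinates normalized to `[0, 1]`. Pixel conversion needs the image
#' dimensions.
#'
#' @param path File path.
#' @param img_w,img_h Image size in pixels.
#' @return Data frame `class, cx, cy, w, h` in pixel center form.
#' @export
read_yolo <- function(path, img_w, img_h) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(seq_along(lines), function(i) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1L]]))
    if (length(v) != 5L || any(is.na(v))) {
      stop("malformed YOLO label at line ", i, " of ", path, call. = FALSE)
    }
    b <- convert_box(v[2:5], "yolo", "center", img_w = img_w, img_h = img_h)
    data.frame(class = as.integer(v[1L]), cx = b[["cx"]], cy = b[["cy"]],
               w = b[["w"]], h = b[["h"]])
  })
  do.call(rbind, rows)
}

#' @rdname read_yolo
#' @param x Data frame `class, cx, cy, w, h` (pixel center form).
#' @export
write_yolo <- function(x, path, img_w, img_h) {
  lines <- vapply(seq_len(nrow(x)), function(i) {
    b <- convert_box(c(x$cx[i], x$cy[i], x$w[i], x$h[i]), "center", "yolo",
                     img_w = img_w, img_h = img_h)
    sprintf("%d %.9g %.9g %.9g %.9g", x$class[i], b[1L], b[2L], b[3L], b[4L])
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Plain-text named-matrix archive
#'
#' A portable flat archive of named numeric matrices (used for embeddings
#' and CBAM weights): each section starts with `# name nrow ncol` followed
#' by one whitespace-separated row per line.
#'
#' @param mats Named list of numeric matrices (vectors are stored as
#'   one-column matrices).
#' @param path File path.
#' @return `path` invisibly (writer); named list of matrices (reader).
#' @export
write_named_matrices <- function(mats, path) {
  stopifnot(is.list(mats), !is.null(names(mats)), all(nzchar(names(mats))))
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(mats)) {
    m <- mats[[nm]]
    if (is.null(dim(m))) m <- matrix(m, ncol = 1L)
    writeLines(sprintf("# %s %d %d", nm, nrow(m), ncol(m)), con)
    utils::write.table(format(m, digits = 17, scientific = TRUE, trim = TRUE),
                       con, row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_named_matrices
#' @export
read_named_matrices <- function(path) {
  lines <- readLines(path)
  headers <- grep("^# ", lines)
  if (length(headers) == 0L) stop("no sections in ", path, call. = FALSE)
  out <- list()
  for (k in seq_along(headers)) {
    h <- strsplit(sub("^# ", "", lines[headers[k]]), "\\s+")[[1L]]
    nm <- h[1L]; nr <- as.integer(h[2L]); nc <- as.integer(h[3L])
    body <- lines[(headers[k] + 1L):(headers[k] + nr)]
    vals <- as.numeric(unlist(strsplit(trimws(body), "\\s+")))
    out[[nm]] <- matrix(vals, nr, nc, byrow = TRUE)
  }
  out
}

#' Serialize / load CBAM weights as a named-matrix archive
#' @param w A [cbam_weights()] object.
#' @param path File path.
#' @return `path` invisibly (writer); a `cbam_weights` object (reader).
#' @export
write_cbam_weights <- function(w, path) {
  stopifnot(inherits(w, "cbam_weights"))
  write_named_matrices(list(
    mlp_hidden = w$mlp_hidden,
    mlp_out = w$mlp_out,
    reduction = matrix(w$reduction),
    spatial_kernel = matrix(w$spatial_kernel, nrow = 7L),  # 7 x 14 flat
    spatial_bias = matrix(w$spatial_bias)), path)
}

#' @rdname write_cbam_weights
#' @export
read_cbam_weights <- function(path) {
  m <- read_named_matrices(path)
  cbam_weights(mlp_hidden = m$mlp_hidden, mlp_out = m$mlp_out,
               reduction = as.integer(m$reduction[1L]),
               spatial_kernel = array(m$spatial_kernel, dim = c(7L, 7L, 2L)),
               spatial_bias = m$spatial_bias[1L])
}

#' Load a run configuration from YAML
#'
#' Recognized keys are the arguments of [pen_config()] and
#' [tracker_config()] plus `iou_thr`, `seed` and `preset`; unknown keys are
#' rejected so typos fail loudly instead of silently using defaults.
#'
#' @param path YAML file path.
#' @return Named list of validated configuration values.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  known <- unique(c(names(formals(pen_config)), names(formals(tracker_config)),
                    "iou_thr", "preset"))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0L) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg
}

#' Write a provenance sidecar
#'
#' Every artifact written by the CLI gets `<artifact>.meta.json` recording
#' the package version, the seed, and an MD5 hash of the effective
#' configuration, so runs can be traced and reproduced.
#'
#' @param artifact_path Path of the artifact the sidecar describes.
#' @param seed Integer seed used for the run.
#' @param config Configuration list the run used.
#' @return Sidecar path, invisibly.
#' @export
write_sidecar <- function(artifact_path, seed, config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  meta <- list(
    package = "pentrack",
    version = as.character(utils::packageVersion("pentrack")),
    seed = seed,
    config_hash = unname(tools::md5sum(tmp)))
  side <- paste0(artifact_path, ".meta.json")
  jsonlite::write_json(meta, side, auto_unbox = TRUE)
  invisible(side)
}
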