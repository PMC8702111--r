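#' Structure labels
#'
#' The three anatomical structures annotated in lateral-view VFSS frames:
#' the thyroid cartilage and vocal fold complex (`"tvc"`), the C1 spinous
#' process used as the static reference (`"c1_spinous"`), and the anterior
#' hyoid margin together with the airway column (`"hyoid_airway"`).
#'
#' @return Character vector of the three canonical label strings.
#' @export
structure_labels <- function() c("tvc", "c1_spinous", "hyoid_airway")

assert_label <- function(label) {
  if (!(is.character(label) && length(label) == 1L && label %in% structure_labels()))
    stop("unknown structure label: ", deparse(label),
         " (expected one of ", paste(structure_labels(), collapse = ", "), ")",
         call. = FALSE)
  label
}

#' Video metadata
#'
#' Frame geometry and timing of a VFSS clip. Defaults match the common
#' acquisition format of 640 x 480 pixels at 30 frames per second.
#'
#' @param width,height Frame size in pixels.
#' @param fps Frame rate in frames per second.
#' @param n_frames Number of frames in the clip.
#' @return A `video_meta` object.
#' @export
video_meta <- function(width = 640L, height = 480L, fps = 30, n_frames = 1L) {
  width <- as.integer(width); height <- as.integer(height)
  n_frames <- as.integer(n_frames)
  if (width <= 0L || height <= 0L) stop("width and height must be positive", call. = FALSE)
  if (fps <= 0) stop("fps must be positive", call. = FALSE)
  if (n_frames < 1L) stop("n_frames must be >= 1", call. = FALSE)
  structure(list(width = width, height = height, fps = fps, n_frames = n_frames),
            class = "video_meta")
}

#' @export
print.video_meta <- function(x, ...) {
  cat(sprintf("<video_meta> %d x %d px, %g fps, %d frames\n",
              x$width, x$height, x$fps, x$n_frames))
  invisible(x)
}

#' One segmented structure in one frame
#'
#' Holds a single structure annotation as a polygon contour (pixel
#' coordinates, x = column rightward, y = row downward), a binary raster
#' mask, or both. Predictions may carry a confidence score.
#'
#' @param label One of [structure_labels()].
#' @param polygon Numeric matrix with columns x, y and at least 3 rows, or `NULL`.
#' @param raster Logical matrix (rows = image rows, columns = image columns)
#'   with at least one `TRUE` pixel, or `NULL`.
#' @param score Optional confidence in `[0, 1]`.
#' @return A `structure_mask` object.
#' @export
structure_mask <- function(label, polygon = NULL, raster = NULL, score = NULL) {
  assert_label(label)
  if (is.null(polygon) && is.null(raster))
    stop("structure_mask needs a polygon or a raster", call. = FALSE)
  if (!is.null(polygon)) {
    polygon <- as.matrix(polygon)
    storage.mode(polygon) <- "double"
    if (ncol(polygon) != 2L || nrow(polygon) < 3L)
      stop("invalid annotation: polygon must have >= 3 (x, y) vertices", call. = FALSE)
    colnames(polygon) <- c("x", "y")
  }
  if (!is.null(raster)) {
    raster <- as.matrix(raster)
    if (!is.logical(raster)) raster <- raster != 0
    if (!any(raster)) stop("raster mask has no set pixels", call. = FALSE)
  }
  if (!is.null(score)) {
    score <- as.numeric(score)
    if (length(score) != 1L || is.na(score) || score < 0 || score > 1)
      stop("score must be a single value in [0, 1]", call. = FALSE)
  }
  structure(list(label = label, polygon = polygon, raster = raster, score = score),
            class = "structure_mask")
}

#' Rasterize a polygon contour to a binary mask
#'
#' Scan-converts a closed polygon to pixel membership by the even-odd rule
#' tested against pixel centers: pixel (row r, col c), 0-based, is set iff
#' its center (c + 0.5, r + 0.5) lies inside the polygon. Centers that fall
#' exactly on the boundary count as inside. Vertices outside the canvas are
#' clipped to `[0, width] x [0, height]`.
#'
#' @param polygon Numeric matrix of (x, y) vertices, >= 3 rows.
#' @param meta A [video_meta()] giving the canvas size.
#' @return Logical matrix of dimension `height x width`.
#' @export
rasterize_polygon <- function(polygon, meta) {
  polygon <- as.matrix(polygon)
  if (ncol(polygon) != 2L || nrow(polygon) < 3L)
    stop("invalid annotation: polygon must have >= 3 (x, y) vertices", call. = FALSE)
  px <- pmin(pmax(polygon[, 1], 0), meta$width)
  py <- pmin(pmax(polygon[, 2], 0), meta$height)
  out <- matrix(FALSE, nrow = meta$height, ncol = meta$width)

  # restrict to the polygon's bounding box of pixel centers
  c0 <- max(0L, floor(min(px) - 0.5)); c1 <- min(meta$width - 1L, ceiling(max(px)))
  r0 <- max(0L, floor(min(py) - 0.5)); r1 <- min(meta$height - 1L, ceiling(max(py)))
  if (c1 < c0 || r1 < r0) return(out)
  cols <- c0:c1; rows <- r0:r1
  cx <- cols + 0.5; cy <- rows + 0.5
  gx <- rep(cx, times = length(cy))     # grid in column-major over (col, row)
  gy <- rep(cy, each = length(cx))

  n <- length(px)
  xj <- px; yj <- py
  xk <- px[c(n, seq_len(n - 1L))]       # previous vertex (closes the ring)
  yk <- py[c(n, seq_len(n - 1L))]

  inside <- rep(FALSE, length(gx))
  onedge <- rep(FALSE, length(gx))
  for (e in seq_len(n)) {
    x1 <- xj[e]; y1 <- yj[e]; x2 <- xk[e]; y2 <- yk[e]
    # even-odd crossing of the upward ray from each center
    crosses <- ((y1 > gy) != (y2 > gy))
    if (any(crosses)) {
      xint <- x1 + (gy[crosses] - y1) * (x2 - x1) / (y2 - y1)
      hit <- gx[crosses] < xint
      inside[crosses][hit] <- !inside[crosses][hit]
    }
    # boundary test: center lies on the segment
    dx <- x2 - x1; dy <- y2 - y1
    segl2 <- dx * dx + dy * dy
    if (segl2 > 0) {
      t <- ((gx - x1) * dx + (gy - y1) * dy) / segl2
      t <- pmin(pmax(t, 0), 1)
      d2 <- (x1 + t * dx - gx)^2 + (y1 + t * dy - gy)^2
      onedge <- onedge | d2 < 1e-18
    }
  }
  member <- matrix(inside | onedge, nrow = length(cx), ncol = length(cy)) # [col, row]
  out[rows + 1L, cols + 1L] <- t(member)
  out
}

#' Realize the raster mask of a structure
#'
#' Returns the stored raster if present, otherwise rasterizes the polygon
#' on demand against the supplied canvas.
#'
#' @param mask A [structure_mask()].
#' @param meta A [video_meta()].
#' @return Logical `height x width` matrix.
#' @export
mask_raster <- function(mask, meta) {
  if (!is.null(mask$raster)) {
    r <- mask$raster
    if (nrow(r) != meta$height || ncol(r) != meta$width)
      stop("raster dimensions do not match video metadata", call. = FALSE)
    return(r)
  }
  rasterize_polygon(mask$polygon, meta)
}

#' Pixel area of a structure mask
#' @param mask A [structure_mask()].
#' @param meta A [video_meta()].
#' @return Number of set pixels.
#' @export
mask_area <- function(mask, meta) sum(mask_raster(mask, meta))

#' Annotations of one video frame
#'
#' @param frame_index 0-based frame number.
#' @param structures List of [structure_mask()] objects.
#' @return A `frame_annotation` object.
#' @export
frame_annotation <- function(frame_index, structures = list()) {
  frame_index <- as.integer(frame_index)
  if (is.na(frame_index) || frame_index < 0L)
    stop("frame_index must be a non-negative integer", call. = FALSE)
  if (!all(vapply(structures, inherits, logical(1), "structure_mask")))
    stop("structures must be structure_mask objects", call. = FALSE)
  structure(list(frame_index = frame_index, structures = structures),
            class = "frame_annotation")
}

#' Per-video annotation set
#'
#' Container for all frame annotations of one clip, either ground truth
#' (at most one instance per label per frame) or predictions (multiple
#' instances per label allowed; resolved later by [match_detections()]).
#'
#' @param meta A [video_meta()].
#' @param frames List of [frame_annotation()] objects; sorted by frame index.
#' @param kind `"ground_truth"` or `"prediction"`.
#' @return An `annotation_set` object.
#' @export
annotation_set <- function(meta, frames = list(), kind = c("ground_truth", "prediction")) {
  kind <- match.arg(kind)
  stopifnot(inherits(meta, "video_meta"))
  idx <- vapply(frames, function(f) f$frame_index, integer(1))
  frames <- frames[order(idx)]
  idx <- sort(idx)
  if (anyDuplicated(idx))
    stop("duplicate frame_index in annotation set", call. = FALSE)
  if (kind == "ground_truth") {
    for (f in frames) {
      labs <- vapply(f$structures, function(s) s$label, character(1))
      if (anyDuplicated(labs))
        stop(sprintf("frame %d: ground truth has multiple instances of label '%s'",
                     f$frame_index, labs[duplicated(labs)][1]), call. = FALSE)
    }
  }
  # canonical within-frame order: label, then descending score (stable)
  frames <- lapply(frames, function(f) {
    ord <- order(vapply(f$structures, function(s) match(s$label, structure_labels()),
                        integer(1)),
                 -vapply(f$structures, function(s) if (is.null(s$score)) -1 else s$score,
                         numeric(1)))
    f$structures <- f$structures[ord]
    f
  })
  for (f in frames) for (s in f$structures) {
    if (!is.null(s$raster) &&
        (nrow(s$raster) != meta$height || ncol(s$raster) != meta$width))
      stop(sprintf("frame %d: raster shape does not match video metadata",
                   f$frame_index), call. = FALSE)
  }
  structure(list(meta = meta, frames = frames, kind = kind), class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> %s, %d annotated frames, %d x %d px\n",
              x$kind, length(x$frames), x$meta$width, x$meta$height))
  invisible(x)
}

# look up a frame_annotation by 0-based index; NULL if absent
frame_by_index <- function(set, frame_index) {
  for (f in set$frames) if (f$frame_index == frame_index) return(f)
  NULL
}
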