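#' Read per-frame structure annotations from JSON
#'
#' Parses the package's COCO-flavoured annotation dialect: one JSON file per
#' video with `meta` (width, height, fps, n_frames), `categories` (the three
#' fixed labels), `images` (one per annotated frame, carrying `frame_index`)
#' and `annotations` (polygon `segmentation` as a flat
#' `[x1, y1, x2, y2, ...]` list, optional `score`).
#'
#' @param path Path to the JSON file.
#' @param kind `"ground_truth"` or `"prediction"`.
#' @return An [annotation_set()].
#' @export
read_annotations <- function(path, kind = c("ground_truth", "prediction")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("annotation file not found: ", path, call. = FALSE)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (field in c("meta", "images", "annotations"))
    if (is.null(doc[[field]]))
      stop("parse error: missing top-level field '", field, "' in ", path, call. = FALSE)
  m <- doc$meta
  meta <- video_meta(m$width, m$height, m$fps, m$n_frames)

  img_frame <- list()  # image id -> frame_index
  for (im in doc$images) {
    if (is.null(im$id) || is.null(im$frame_index))
      stop("parse error: image entry missing id or frame_index", call. = FALSE)
    img_frame[[as.character(im$id)]] <- as.integer(im$frame_index)
  }
  cat_label <- list() # category id -> label string
  for (ct in doc$categories) cat_label[[as.character(ct$id)]] <- ct$name

  per_frame <- list()
  for (an in doc$annotations) {
    img_id <- as.character(an$image_id)
    fidx <- img_frame[[img_id]]
    if (is.null(fidx))
      stop("parse error: annotation references unknown image id ", img_id, call. = FALSE)
    label <- cat_label[[as.character(an$category_id)]]
    if (is.null(label)) label <- an$category_id
    if (!is.character(label) || !(label %in% structure_labels()))
      stop(sprintf("parse error: frame %d: unknown label %s", fidx, deparse(label)),
           call. = FALSE)
    seg <- unlist(an$segmentation)
    if (is.null(seg) || length(seg) < 6L || length(seg) %% 2L != 0L)
      stop(sprintf("parse error: frame %d, label %s: malformed polygon segmentation",
                   fidx, label), call. = FALSE)
    poly <- matrix(as.numeric(seg), ncol = 2L, byrow = TRUE)
    sm <- structure_mask(label, polygon = poly,
                         score = if (!is.null(an$score)) as.numeric(an$score) else NULL)
    key <- as.character(fidx)
    per_frame[[key]] <- c(per_frame[[key]], list(sm))
  }
  for (im in doc$images) {
    key <- as.character(img_frame[[as.character(im$id)]])
    if (is.null(per_frame[[key]])) per_frame[[key]] <- list()
  }
  frames <- lapply(names(per_frame), function(k)
    frame_annotation(as.integer(k), per_frame[[k]]))
  annotation_set(meta, frames, kind)
}

#' Write an annotation set to JSON
#'
#' Serialization is deterministic: frames sorted by index, structures sorted
#' by label (then score), so writing the same set twice yields identical
#' bytes.
#'
#' @param set An [annotation_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(set, path) {
  stopifnot(inherits(set, "annotation_set"))
  labs <- structure_labels()
  categories <- lapply(seq_along(labs), function(i) list(id = i, name = labs[i]))
  images <- list(); annotations <- list(); ann_id <- 1L
  for (i in seq_along(set$frames)) {
    f <- set$frames[[i]]
    images[[i]] <- list(id = i, frame_index = f$frame_index)
    ord <- order(vapply(f$structures, function(s) match(s$label, labs), integer(1)),
                 -vapply(f$structures, function(s) if (is.null(s$score)) -1 else s$score,
                         numeric(1)))
    for (s in f$structures[ord]) {
      if (is.null(s$polygon))
        stop(sprintf("frame %d: raster-only masks cannot be serialized to polygon JSON; ",
                     f$frame_index), call. = FALSE)
      entry <- list(id = ann_id, image_id = i,
                    category_id = match(s$label, labs),
                    segmentation = as.numeric(t(s$polygon)))
      if (!is.null(s$score)) entry$score <- s$score
      annotations[[ann_id]] <- entry
      ann_id <- ann_id + 1L
    }
  }
  doc <- list(meta = list(width = set$meta$width, height = set$meta$height,
                          fps = set$meta$fps, n_frames = set$meta$n_frames),
              kind = set$kind, categories = categories,
              images = images, annotations = annotations)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  invisible(path)
}

#' Read per-frame PNG label maps as an annotation set
#'
#' Alternative raster input: grayscale PNGs named `frame_%06d.png` whose
#' pixel values are 0 (background), 1 (TVC), 2 (C1 spinous process) or
#' 3 (hyoid/airway), stored as value/255 in the PNG.
#'
#' @param dir Directory holding the label maps.
#' @param meta A [video_meta()]; `NULL` derives size from the first map.
#' @param kind Annotation kind.
#' @param fps Frame rate used when `meta` is derived.
#' @return An [annotation_set()].
#' @export
read_label_maps <- function(dir, meta = NULL, kind = c("ground_truth", "prediction"),
                            fps = 30) {
  kind <- match.arg(kind)
  files <- sort(list.files(dir, pattern = "^frame_[0-9]{6}\\.png$", full.names = TRUE))
  if (!length(files)) stop("no frame_%06d.png label maps in ", dir, call. = FALSE)
  frames <- vector("list", length(files))
  for (i in seq_along(files)) {
    fidx <- as.integer(sub("^frame_([0-9]{6})\\.png$", "\\1", basename(files[i])))
    img <- png::readPNG(files[i])
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    lab <- round(img * 255)
    if (is.null(meta))
      meta <- video_meta(ncol(lab), nrow(lab), fps, length(files))
    structs <- list()
    for (v in 1:3) if (any(lab == v))
      structs <- c(structs, list(structure_mask(structure_labels()[v],
                                                raster = lab == v)))
    frames[[i]] <- frame_annotation(fidx, structs)
  }
  annotation_set(meta, frames, kind)
}

#' Write an annotation set as PNG label maps
#'
#' @param set An [annotation_set()] whose masks are (or rasterize to)
#'   non-overlapping regions; later labels overwrite earlier ones on overlap.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_label_maps <- function(set, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (f in set$frames) {
    lab <- matrix(0L, set$meta$height, set$meta$width)
    for (s in f$structures)
      lab[mask_raster(s, set$meta)] <- match(s$label, structure_labels())
    png::writePNG(lab / 255, file.path(dir, sprintf("frame_%06d.png", f$frame_index)))
  }
  invisible(dir)
}

#' Write a midpoint track / relative trajectory to CSV
#'
#' One row per frame with the fixed header
#' `frame,tvc_x,tvc_y,c1_x,c1_y,rel_x,rel_y,valid`; missing midpoints are
#' serialized as empty fields.
#'
#' @param track A `midpoint_track` from [build_track()] (the relative
#'   trajectory is derived automatically).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(track, path) {
  stopifnot(inherits(track, "midpoint_track"))
  traj <- relative_trajectory(track)
  df <- data.frame(frame = track$frame,
                   tvc_x = track$tvc_x, tvc_y = track$tvc_y,
                   c1_x = track$c1_x, c1_y = track$c1_y,
                   rel_x = traj$rel_x, rel_y = traj$rel_y,
                   valid = tolower(as.character(track$valid)))
  num <- function(v) ifelse(is.na(v), "", format(v, digits = 17, trim = TRUE,
                                                 scientific = FALSE))
  lines <- c("frame,tvc_x,tvc_y,c1_x,c1_y,rel_x,rel_y,valid",
             sprintf("%d,%s,%s,%s,%s,%s,%s,%s", df$frame,
                     num(df$tvc_x), num(df$tvc_y), num(df$c1_x), num(df$c1_y),
                     num(df$rel_x), num(df$rel_y), df$valid))
  writeLines(lines, path)
  invisible(path)
}

#' Read a trajectory CSV written by [write_trajectory_csv()]
#'
#' @param path CSV path.
#' @return A `midpoint_track` data frame.
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = c(frame = "integer", valid = "character"))
  expected <- c("frame", "tvc_x", "tvc_y", "c1_x", "c1_y", "rel_x", "rel_y", "valid")
  if (!identical(names(df), expected))
    stop("unexpected trajectory CSV header in ", path, call. = FALSE)
  out <- df[c("frame", "tvc_x", "tvc_y", "c1_x", "c1_y")]
  out$valid <- df$valid == "true"
  class(out) <- c("midpoint_track", "data.frame")
  out
}
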