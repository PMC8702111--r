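# internal helpers shared by the phantom and pipeline modules

# evaluate `code` under a temporary RNG state seeded with `seed`;
# seed = NULL uses (and advances) the caller's RNG
local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# 3x3 homogeneous transforms, pixel-center coordinates (x right, y down)
tr_translate <- function(tx, ty) matrix(c(1, 0, 0, 0, 1, 0, tx, ty, 1), 3, 3)
tr_scale <- function(sx, sy = sx) diag(c(sx, sy, 1))
tr_rotate <- function(theta_deg) {
  th <- theta_deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}

# forward transform for the augmentation chain flip -> rotate -> scale -> shift,
# flip/rotation/scaling about the image center
augment_transform <- function(width, height, flip, theta_deg, scale, tx, ty) {
  cx <- width / 2; cy <- height / 2
  M <- tr_translate(cx, cy)
  M <- M %*% tr_scale(scale)
  M <- M %*% tr_rotate(theta_deg)
  if (flip) M <- M %*% tr_scale(-1, 1)
  M <- M %*% tr_translate(-cx, -cy)
  tr_translate(tx, ty) %*% M
}

# inverse-mapped affine warp of an H x W matrix; pixel centers at
# (col - 0.5, row - 0.5) in 1-based indices. "nearest" preserves binarity and
# makes integer shifts and flips exact set operations; "bilinear" for images.
affine_warp <- function(img, M, interpolation = c("bilinear", "nearest"), fill = 0) {
  interpolation <- match.arg(interpolation)
  H <- nrow(img); W <- ncol(img)
  Minv <- solve(M)
  x <- rep(seq_len(W) - 0.5, each = H)
  y <- rep(seq_len(H) - 0.5, times = W)
  sx <- Minv[1, 1] * x + Minv[1, 2] * y + Minv[1, 3]
  sy <- Minv[2, 1] * x + Minv[2, 2] * y + Minv[2, 3]
  out <- matrix(fill, H, W)
  if (interpolation == "nearest") {
    c0 <- floor(sx); r0 <- floor(sy)
    ok <- c0 >= 0 & c0 < W & r0 >= 0 & r0 < H
    out[ok] <- img[cbind(r0[ok] + 1L, c0[ok] + 1L)]
  } else {
    u <- sx - 0.5; v <- sy - 0.5          # continuous 0-based pixel indices
    ok <- u > -0.5 & u < W - 0.5 & v > -0.5 & v < H - 0.5
    uc <- pmin(pmax(u[ok], 0), W - 1); vc <- pmin(pmax(v[ok], 0), H - 1)
    c0 <- floor(uc); r0 <- floor(vc)
    fc <- uc - c0; fr <- vc - r0
    c1 <- pmin(c0 + 1, W - 1); r1 <- pmin(r0 + 1, H - 1)
    out[ok] <-
      img[cbind(r0 + 1L, c0 + 1L)] * (1 - fr) * (1 - fc) +
      img[cbind(r0 + 1L, c1 + 1L)] * (1 - fr) * fc +
      img[cbind(r1 + 1L, c0 + 1L)] * fr * (1 - fc) +
      img[cbind(r1 + 1L, c1 + 1L)] * fr * fc
  }
  out
}

# Gaussian blur of an intensity matrix; sigma <= 0 is the identity
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  EBImage::gblur(img, sigma = sigma, boundary = "replicate")
}

# 8-connected component labelling via a pixel-adjacency graph
label_components <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  idx <- which(mask)
  n <- length(idx)
  if (!n) return(lab)
  id <- matrix(0L, H, W)
  id[idx] <- seq_len(n)
  r <- ((idx - 1L) %% H) + 1L
  cc <- ((idx - 1L) %/% H) + 1L
  edges <- list()
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- r + off[1]; c2 <- cc + off[2]
    ok <- r2 >= 1L & r2 <= H & c2 >= 1L & c2 <= W
    if (!any(ok)) next
    nb <- id[cbind(r2[ok], c2[ok])]
    has <- nb > 0L
    if (any(has))
      edges[[length(edges) + 1L]] <- cbind(id[idx[ok]][has], nb[has])
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(edges))
    g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  lab[idx] <- as.integer(igraph::components(g)$membership)
  lab
}

# centroid (x, y) of a labelled region in pixel-center coordinates
region_centroid <- function(lab, value) {
  idx <- which(lab == value, arr.ind = TRUE)
  c(x = mean(idx[, 2]) - 0.5, y = mean(idx[, 1]) - 0.5)
}
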