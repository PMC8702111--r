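# Independent brute-force oracles. These deliberately share no code with the
# package: scalar loops and naive formulas only.

# even-odd point-in-polygon test for a single point, with boundary = inside
oracle_point_in_polygon <- function(qx, qy, poly) {
  n <- nrow(poly)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    # on-segment check
    dx <- xj - xi; dy <- yj - yi
    len2 <- dx^2 + dy^2
    if (len2 > 0) {
      t <- ((qx - xi) * dx + (qy - yi) * dy) / len2
      t <- min(max(t, 0), 1)
      if ((xi + t * dx - qx)^2 + (yi + t * dy - qy)^2 < 1e-18) return(TRUE)
    }
    if ((yi > qy) != (yj > qy)) {
      xint <- xi + (qy - yi) * (xj - xi) / (yj - yi)
      if (qx < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# exhaustive rasterization over every pixel center of the canvas
oracle_rasterize <- function(poly, width, height) {
  out <- matrix(FALSE, height, width)
  px <- pmin(pmax(poly[, 1], 0), width)
  py <- pmin(pmax(poly[, 2], 0), height)
  poly <- cbind(px, py)
  for (r in seq_len(height)) for (c in seq_len(width))
    out[r, c] <- oracle_point_in_polygon(c - 0.5, r - 0.5, poly)
  out
}

# IoU by explicit per-pixel counting
oracle_iou <- function(a, b) {
  inter <- 0L; uni <- 0L
  for (k in seq_along(a)) {
    if (a[k] && b[k]) inter <- inter + 1L
    if (a[k] || b[k]) uni <- uni + 1L
  }
  inter / uni
}

# exhaustive O(n^2) swallow-event selection over all valid index pairs,
# ties broken by smallest i then smallest j; NULL when no upward excursion
oracle_select_event <- function(frame, rel_y, valid) {
  best <- NULL; best_exc <- 0
  n <- length(rel_y)
  for (i in seq_len(n - 1)) {
    if (!valid[i] || is.na(rel_y[i])) next
    for (j in (i + 1):n) {
      if (!valid[j] || is.na(rel_y[j])) next
      exc <- rel_y[i] - rel_y[j]
      if (exc > best_exc) {
        best_exc <- exc
        best <- c(frame[i], frame[j])
      }
    }
  }
  best
}

# random convex polygon (angularly sorted points on a jittered circle)
random_convex_polygon <- function(n = 6, cx = 10, cy = 10, rmax = 8) {
  th <- sort(stats::runif(n, 0, 2 * pi))
  rr <- stats::runif(n, rmax / 3, rmax)
  cbind(x = cx + rr * cos(th), y = cy + rr * sin(th))
}

random_mask <- function(height, width, p = 0.4) {
  matrix(stats::runif(height * width) < p, height, width)
}

square_mask <- function(height, width, r0, c0, side) {
  m <- matrix(FALSE, height, width)
  m[r0:(r0 + side - 1), c0:(c0 + side - 1)] <- TRUE
  m
}
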