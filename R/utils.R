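# Internal geometry helpers shared across modules. All take plain numeric
# vectors; coordinates are in cm unless noted.

logistic <- function(x) 1 / (1 + exp(-x))

# Signed area of a polygon given vertex coordinates (shoelace). Positive for
# counterclockwise orientation.
polygon_signed_area <- function(x, y) {
  n <- length(x)
  if (n < 3L) return(0)
  j <- c(2:n, 1L)
  sum(x * y[j] - x[j] * y) / 2
}

# Orientation of the triplet (a, b, c): +1 counterclockwise, -1 clockwise,
# 0 collinear (within a relative tolerance).
orient <- function(ax, ay, bx, by, cx, cy, eps = 1e-12) {
  v <- (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
  scale <- pmax(abs(bx - ax) + abs(by - ay), abs(cx - ax) + abs(cy - ay), 1)
  ifelse(abs(v) <= eps * scale * scale, 0, sign(v))
}

# TRUE where segment p1-p2 intersects segment p3-p4 anywhere other than at a
# shared endpoint coordinate. Vectorised over segment pairs.
segments_cross <- function(x1, y1, x2, y2, x3, y3, x4, y4) {
  d1 <- orient(x3, y3, x4, y4, x1, y1)
  d2 <- orient(x3, y3, x4, y4, x2, y2)
  d3 <- orient(x1, y1, x2, y2, x3, y3)
  d4 <- orient(x1, y1, x2, y2, x4, y4)
  proper <- (d1 * d2 < 0) & (d3 * d4 < 0)
  on_seg <- function(px, py, ax, ay, bx, by, d) {
    # point strictly inside segment ab (collinear already established by d==0)
    d == 0 &
      px >= pmin(ax, bx) - 1e-12 & px <= pmax(ax, bx) + 1e-12 &
      py >= pmin(ay, by) - 1e-12 & py <= pmax(ay, by) + 1e-12 &
      !(px == ax & py == ay) & !(px == bx & py == by)
  }
  touch <- on_seg(x1, y1, x3, y3, x4, y4, d1) |
    on_seg(x2, y2, x3, y3, x4, y4, d2) |
    on_seg(x3, y3, x1, y1, x2, y2, d3) |
    on_seg(x4, y4, x1, y1, x2, y2, d4)
  proper | touch
}

# Distance from points (px, py) to segment a-b; vectorised over points.
point_segment_distance <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax
  dy <- by - ay
  len2 <- dx * dx + dy * dy
  if (len2 == 0) return(sqrt((px - ax)^2 + (py - ay)^2))
  t <- ((px - ax) * dx + (py - ay) * dy) / len2
  t <- pmin(pmax(t, 0), 1)
  sqrt((px - (ax + t * dx))^2 + (py - (ay + t * dy))^2)
}

# Ray-casting point-in-polygon; boundary points count as inside.
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if (((vy[i] > py) != (vy[j] > py)) &&
        (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])) {
      inside <- !inside
    }
    j <- i
  }
  inside
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
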