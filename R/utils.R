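## Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream. All generators route randomness through this, so they are pure
# functions of (parameters, seed).
withSeed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Round half away from zero (half-up for the non-negative intensities used
# here); base round() rounds half to even, which would bias discretization.
roundHalfUp <- function(x) floor(x + 0.5)

# Clip to the 8-bit working range, preserving dim attributes.
clip255 <- function(x) {
  x[x < 0] <- 0
  x[x > 255] <- 255
  x
}

## Polygon geometry ----------------------------------------------------------

# Cross-product orientation of (p -> q -> r); sign only.
.orient <- function(px, py, qx, qy, rx, ry) {
  sign((qx - px) * (ry - py) - (qy - py) * (rx - px))
}

# Proper or improper intersection of segments (a1,a2) and (b1,b2).
.segmentsIntersect <- function(a1, a2, b1, b2) {
  d1 <- .orient(b1[1], b1[2], b2[1], b2[2], a1[1], a1[2])
  d2 <- .orient(b1[1], b1[2], b2[1], b2[2], a2[1], a2[2])
  d3 <- .orient(a1[1], a1[2], a2[1], a2[2], b1[1], b1[2])
  d4 <- .orient(a1[1], a1[2], a2[1], a2[2], b2[1], b2[2])
  if (d1 != d2 && d3 != d4) return(TRUE)
  onSeg <- function(p, q, r) {
    # r collinear with p-q: is r within the bounding box?
    min(p[1], q[1]) <= r[1] && r[1] <= max(p[1], q[1]) &&
      min(p[2], q[2]) <= r[2] && r[2] <= max(p[2], q[2])
  }
  (d1 == 0 && onSeg(b1, b2, a1)) || (d2 == 0 && onSeg(b1, b2, a2)) ||
    (d3 == 0 && onSeg(a1, a2, b1)) || (d4 == 0 && onSeg(a1, a2, b2))
}

# TRUE iff the closed polygon given by vertex matrix v (n x 2) is simple:
# no two non-adjacent edges intersect.
.isSimplePolygon <- function(v) {
  n <- nrow(v)
  nxt <- c(seq_len(n)[-1], 1L)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      # skip adjacent edges (sharing a vertex), including the wrap-around pair
      if (j == i || j == i %% n + 1L || i == j %% n + 1L) next
      if (.segmentsIntersect(v[i, ], v[nxt[i], ], v[j, ], v[nxt[j], ]))
        return(FALSE)
    }
  }
  TRUE
}

# Even-odd point-in-polygon test, vectorized over query points (px, py).
# Points exactly on an edge resolve deterministically via the half-open
# crossing rule; pixel centers at half-integers rarely hit edges anyway.
.pointInPolygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    yi <- vy[i]; yj <- vy[j]
    xi <- vx[i]; xj <- vx[j]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}
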