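# Small internal helpers shared across modules.

# Evaluate expr with a locally seeded RNG, restoring the caller's RNG state.
# seed = NULL leaves the current RNG stream untouched.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}

# Derive k child seeds from one parent seed (kept below 2^31).
childSeeds <- function(seed, k) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, k))
}

# Round half away from zero at `digits` decimals (base round() is half-to-even).
roundHalfAway <- function(x, digits = 0L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Bilinear interpolation of matrix m (values at pixel centres
# ((i - 0.5) dx, (j - 0.5) dy)) at physical points (px, py).
# Points outside the centre lattice clamp to the border value.
bilinearAt <- function(m, dx, dy, px, py) {
  nx <- nrow(m); ny <- ncol(m)
  u <- px / dx + 0.5
  v <- py / dy + 0.5
  u <- pmin(pmax(u, 1), nx)
  v <- pmin(pmax(v, 1), ny)
  i0 <- pmin(floor(u), nx - 1L); j0 <- pmin(floor(v), ny - 1L)
  if (nx == 1L) i0 <- rep(1, length(u))
  if (ny == 1L) j0 <- rep(1, length(v))
  fu <- u - i0; fv <- v - j0
  i1 <- pmin(i0 + 1, nx); j1 <- pmin(j0 + 1, ny)
  idx <- function(i, j) (j - 1) * nx + i
  m <- as.numeric(m)
  m[idx(i0, j0)] * (1 - fu) * (1 - fv) +
    m[idx(i1, j0)] * fu * (1 - fv) +
    m[idx(i0, j1)] * (1 - fu) * fv +
    m[idx(i1, j1)] * fu * fv
}

# 2D rotation matrix.
rot2 <- function(a) matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2L, 2L)

# Rotation about the z axis (3D), angle in radians.
rotZ <- function(a) {
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3L, 3L)
}

# Rotation about the y axis (3D).
rotY <- function(a) {
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3L, 3L)
}

identityPose <- function(center = c(0, 0, 0)) {
  list(rotation = diag(3), translation = as.numeric(center))
}

# Proper (transversal) segment-segment crossing test, vectorized over pairs.
# p1..q2 are n x 2 matrices; returns logical n. Tangential touches (any
# collinear endpoint) count FALSE: sign changes must be strict.
segmentsCross <- function(p1, p2, q1, q2) {
  cross <- function(ax, ay, bx, by) ax * by - ay * bx
  d1 <- cross(q2[, 1] - q1[, 1], q2[, 2] - q1[, 2], p1[, 1] - q1[, 1], p1[, 2] - q1[, 2])
  d2 <- cross(q2[, 1] - q1[, 1], q2[, 2] - q1[, 2], p2[, 1] - q1[, 1], p2[, 2] - q1[, 2])
  d3 <- cross(p2[, 1] - p1[, 1], p2[, 2] - p1[, 2], q1[, 1] - p1[, 1], q1[, 2] - p1[, 2])
  d4 <- cross(p2[, 1] - p1[, 1], p2[, 2] - p1[, 2], q2[, 1] - p1[, 1], q2[, 2] - p1[, 2])
  (d1 * d2 < 0) & (d3 * d4 < 0)
}

# Intersection points for segment pairs known to cross.
segmentIntersection <- function(p1, p2, q1, q2) {
  rx <- p2[, 1] - p1[, 1]; ry <- p2[, 2] - p1[, 2]
  sx <- q2[, 1] - q1[, 1]; sy <- q2[, 2] - q1[, 2]
  denom <- rx * sy - ry * sx
  t <- ((q1[, 1] - p1[, 1]) * sy - (q1[, 2] - p1[, 2]) * sx) / denom
  cbind(p1[, 1] + t * rx, p1[, 2] + t * ry)
}

# Connected components (26-connectivity) of a voxel set given by integer
# coordinates (n x 3, 1-based) inside a grid of dimension dims. Returns an
# integer component id per voxel. Pure R, vectorized wave BFS over encoded
# codes; intended for small structures (pores), not whole stacks.
voxelComponents <- function(coords, dims) {
  n <- nrow(coords)
  if (n == 0L) return(integer(0))
  nx <- dims[1]; ny <- dims[2]
  code <- (coords[, 1] - 1) + nx * ((coords[, 2] - 1) + ny * (coords[, 3] - 1))
  ord <- order(code)
  sorted <- code[ord]
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  comp <- integer(n)
  nextComp <- 0L
  for (start in seq_len(n)) {
    if (comp[start] != 0L) next
    nextComp <- nextComp + 1L
    comp[start] <- nextComp
    frontier <- start
    while (length(frontier)) {
      fc <- coords[frontier, , drop = FALSE]
      nb <- do.call(rbind, lapply(seq_len(nrow(off)), function(k)
        sweep(fc, 2, off[k, ], "+")))
      ok <- nb[, 1] >= 1 & nb[, 1] <= nx & nb[, 2] >= 1 & nb[, 2] <= ny &
            nb[, 3] >= 1 & nb[, 3] <= dims[3]
      nb <- nb[ok, , drop = FALSE]
      nbcode <- (nb[, 1] - 1) + nx * ((nb[, 2] - 1) + ny * (nb[, 3] - 1))
      pos <- findInterval(nbcode, sorted)
      hit <- pos > 0 & sorted[pmax(pos, 1)] == nbcode
      idx <- unique(ord[pos[hit]])
      idx <- idx[comp[idx] == 0L]
      comp[idx] <- nextComp
      frontier <- idx
    }
  }
  comp
}
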