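# Shared fixtures and independent oracles, built in code at test time.

# Disc-mask section: integer mask with a filled disc, physical spacing dx.
discSection <- function(n = 300L, dx = 0.01, rho = 1, cx = NULL, cy = NULL,
                        label = 1L) {
  if (is.null(cx)) cx <- n * dx / 2
  if (is.null(cy)) cy <- n * dx / 2
  xs <- (seq_len(n) - 0.5) * dx
  m <- outer(xs, xs, function(x, y)
    ifelse((x - cx)^2 + (y - cy)^2 <= rho^2, label, 0L))
  storage.mode(m) <- "integer"
  sectionPlane(m, c(dx, dx))
}

# Brute-force crossing oracle: walk each arc at `samples` points uniformly
# in arc length and count strict sign changes of the (smoothed, bilinear)
# inside indicator. Independent of the polygon-intersection route.
bruteCrossings <- function(grid, section, targetLabel, samples = 1e4,
                           smooth = 2L) {
  mask <- matrix(section@image %in% targetLabel,
                 nrow(section@image), ncol(section@image))
  field <- cycloidSV:::boxSmooth(mask + 0, smooth)
  dx <- section@spacing[[1]]; dy <- section@spacing[[2]]
  total <- 0L
  for (a in grid@arcs) {
    seglen <- sqrt(rowSums(diff(a)^2))
    s <- c(0, cumsum(seglen))
    ss <- seq(0, s[length(s)], length.out = samples)
    px <- approx(s, a[, 1], xout = ss)$y
    py <- approx(s, a[, 2], xout = ss)$y
    inside <- cycloidSV:::bilinearAt(field, dx, dy, px, py) > 0.5
    total <- total + sum(inside[-1] != inside[-length(inside)])
  }
  as.integer(total)
}

# Numeric surface/volume of the tube-with-bulb union by dense profile
# revolution (independent of the closed forms): radius profile rho(x) =
# max(shaft, bulb) on a fine x grid; S = int 2 pi rho ds, V = int pi rho^2 dx.
tubeProfileOracle <- function(rShaft, L, RBulb, n = 2e6) {
  x <- seq(-rShaft, L + RBulb, length.out = n)
  shaft <- ifelse(x < 0, sqrt(pmax(rShaft^2 - x^2, 0)),
                  ifelse(x <= L, rShaft, 0))
  bulb <- sqrt(pmax(RBulb^2 - (x - L)^2, 0))
  rho <- pmax(shaft, bulb)
  dxs <- diff(x)
  dr <- diff(rho)
  ds <- sqrt(dxs^2 + dr^2)
  rmid <- (rho[-1] + rho[-n]) / 2
  list(S = sum(2 * pi * rmid * ds), V = sum(pi * rmid^2 * dxs))
}

# A single-arc "grid" with a straight test line, for first-principles
# crossing tests (Jordan curve: a line through a disc crosses twice).
lineGrid <- function(x0, y0, x1, y1, n = 50L, point = c(x0, y0)) {
  a <- cbind(seq(x0, x1, length.out = n), seq(y0, y1, length.out = n))
  methods::new("CycloidGrid", lp = 1, arcScale = 1 / 8, orientation = 0,
               phase = c(0, 0), tile = c(2 * pi / 8, 4 / 8),
               arcs = list(a), points = matrix(point, 1L, 2L))
}

# Tiny stack with explicit labels, spacing and legend.
tinyStack <- function(arr, spacing = c(0.01, 0.01, 0.1), legend) {
  storage.mode(arr) <- "integer"
  cycloidSV:::newLabelStack(arr, spacing, legend)
}
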