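#' @include AllClasses.R utils.R
NULL

# One full cycloid arch sampled at n vertices uniformly in arc length.
# Canonical arch: x = rc (theta - sin theta), y = rc (1 - cos theta),
# theta in [0, 2*pi]; spans 2*pi*rc along x (major axis) and 2*rc along y
# (minor axis); total length 8*rc. Arc-length midpoint is theta = pi.
cycloidArch <- function(rc, n = 97L) {
  s <- seq(0, 8 * rc, length.out = n)
  theta <- 2 * acos(pmin(pmax(1 - s / (4 * rc), -1), 1))
  cbind(rc * (theta - sin(theta)), rc * (1 - cos(theta)))
}

#' Build a cycloid test grid over an image extent
#'
#' Tiles the plane with full cycloid arcs (one test point at each arc's
#' arc-length midpoint, so l/p = 8 r_c = \code{lp}) and returns the arcs
#' and points that intersect the requested extent. The repeating tile is
#' 2*pi*r_c wide (major axis) by 4*r_c tall and holds two arcs in
#' point-symmetric arrangement, so the tiled pattern maps onto itself under
#' rotation by pi. The arcs' minor axis is parallel to the grid's vertical
#' axis, whose direction in the image is given by \code{orientation}; in
#' vertical-section stereology the vertical axis is aligned with the basal
#' lamina per the sampling protocol (see \code{\link{laminaOrientation}}).
#'
#' @param lp Test-line length per test point, um; > 0.
#' @param orientation Angle of the grid's vertical axis, radians from the
#'   image x axis.
#' @param phase Numeric length 2: translation within one tile, grid-frame um
#'   (u along the major axis, v along the vertical axis).
#' @param extent Numeric length 4: \code{c(xmin, xmax, ymin, ymax)} um.
#' @param nSegments Vertices per arc polyline (default 97 keeps the
#'   polyline length within 0.1 percent of 8 r_c).
#' @return A \linkS4class{CycloidGrid}.
#' @examples
#' g <- buildGrid(lp = 1, orientation = 0, phase = c(0.1, 0.2),
#'                extent = c(0, 5, 0, 5))
#' length(g@arcs)
#' @export
buildGrid <- function(lp, orientation = 0, phase = c(0, 0), extent,
                      nSegments = 97L) {
  if (!is.numeric(lp) || length(lp) != 1L || !is.finite(lp) || lp <= 0)
    stop("invalid parameter: lp must be positive")
  if (length(extent) != 4L || extent[2] <= extent[1] || extent[4] <= extent[3])
    stop("invalid parameter: extent must be a nonempty box")
  rc <- lp / 8
  W <- 2 * pi * rc
  H <- 4 * rc
  arc1 <- cycloidArch(rc, nSegments)
  # second arc: vertical flip + half-tile shift; congruent to arc1 rotated
  # by pi (the arch is mirror-symmetric about its own midline), giving the
  # tiled pattern two-fold rotational symmetry
  arc2 <- cbind(arc1[, 1] + W / 2, 4 * rc - arc1[, 2])
  pt1 <- c(pi * rc, 2 * rc)         # arc-length midpoint of arc1
  pt2 <- c(pi * rc + W / 2, 2 * rc) # midpoint of arc2
  # grid frame -> image frame: vertical axis (grid +v) maps to
  # (cos orientation, sin orientation)
  Rm <- rot2(orientation - pi / 2)
  phase <- as.numeric(phase)
  # tile index range covering the extent (conservative: map extent corners
  # into the grid frame and pad by one tile)
  corners <- rbind(c(extent[1], extent[3]), c(extent[2], extent[3]),
                   c(extent[1], extent[4]), c(extent[2], extent[4]))
  gc <- corners %*% Rm   # R^T via right-multiplication
  iRange <- floor((min(gc[, 1]) - phase[1]) / W - 1):ceiling((max(gc[, 1]) - phase[1]) / W + 1)
  jRange <- floor((min(gc[, 2]) - phase[2]) / H - 1):ceiling((max(gc[, 2]) - phase[2]) / H + 1)
  arcs <- list(); pts <- NULL
  keep <- function(m) {
    any(m[, 1] >= extent[1] & m[, 1] <= extent[2] &
        m[, 2] >= extent[3] & m[, 2] <= extent[4])
  }
  toImage <- function(m) {
    m2 <- sweep(m, 2, phase, "+")
    m2 %*% t(Rm)
  }
  for (i in iRange) for (j in jRange) {
    off <- c(i * W, j * H)
    for (base in list(list(a = arc1, p = pt1), list(a = arc2, p = pt2))) {
      a <- toImage(sweep(base$a, 2, off, "+"))
      if (keep(a)) {
        arcs[[length(arcs) + 1L]] <- a
        pts <- rbind(pts, toImage(matrix(base$p + off, 1L, 2L)))
      }
    }
  }
  if (is.null(pts)) pts <- matrix(numeric(), 0L, 2L)
  methods::new("CycloidGrid", lp = lp, arcScale = rc,
               orientation = orientation, phase = phase, tile = c(W, H),
               arcs = arcs, points = pts)
}

setMethod("show", "CycloidGrid", function(object) {
  cat(sprintf(paste0("CycloidGrid: lp %.4g um (r_c %.4g), %d arcs, ",
                     "vertical axis %.1f deg, tile %.3g x %.3g um\n"),
              object@lp, object@arcScale, length(object@arcs),
              object@orientation * 180 / pi, object@tile[1], object@tile[2]))
})

#' Orientation of the basal lamina in a section
#'
#' Fits the total-least-squares line (first principal direction) through
#' the lamina trace points and returns its angle in [0, pi). The grid's
#' vertical axis is oriented parallel to this direction when casting, so
#' the test system follows the anisotropy of the tissue as the sampling
#' protocol requires.
#'
#' @param section A \linkS4class{SectionPlane} with a nonempty lamina trace.
#' @return Angle in radians, in [0, pi).
#' @export
laminaOrientation <- function(section) {
  tr <- section@laminaTrace
  if (nrow(tr) < 2L) stop("lamina trace needs at least 2 points")
  ctr <- sweep(tr, 2, colMeans(tr))
  cv <- crossprod(ctr) / nrow(tr)
  if (max(abs(cv)) < .Machine$double.eps * 100)
    stop("degenerate geometry: lamina trace points coincide")
  v <- eigen(cv, symmetric = TRUE)$vectors[, 1]
  ang <- atan2(v[2], v[1]) %% pi
  if (abs(ang - pi) < 1e-12) ang <- 0
  ang
}

#' Restriction line across a basal-lamina pore
#'
#' The chord joining the two pore endpoints of a section. Counts are
#' restricted to the stromal side of this line, defined as the half-plane
#' not containing the centroid of the epithelium label.
#'
#' @param section A \linkS4class{SectionPlane} with pore endpoints.
#' @return List with \code{a}, \code{b} (endpoints), \code{normal} (unit
#'   normal pointing to the stromal side).
#' @export
restrictionLine <- function(section) {
  pe <- section@poreEndpoints
  if (nrow(pe) != 2L)
    stop("no pore: this section has no pore endpoints")
  a <- pe[1, ]; b <- pe[2, ]
  d <- b - a
  n <- c(-d[2], d[1])
  n <- n / sqrt(sum(n^2))
  ec <- section@epiCentroid
  if (any(is.na(ec)))
    stop("restriction requires an epithelium centroid to orient the stromal side")
  if (sum((ec - a) * n) > 0) n <- -n  # flip so the normal points stromally
  list(a = a, b = b, normal = n)
}

# Signed stromal-side coordinate of points (n x 2): > 0 means stromal.
stromalSide <- function(rline, pts) {
  (pts[, 1] - rline$a[1]) * rline$normal[1] +
    (pts[, 2] - rline$a[2]) * rline$normal[2]
}
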