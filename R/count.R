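#' @include AllClasses.R grid.R utils.R
NULL

#' Construct a section plane
#'
#' Low-level constructor used by tests and by \code{\link{sectionFromStack}}.
#'
#' @param image Integer label matrix \code{[x, y]}.
#' @param spacing Numeric length 2 (\code{dx}, \code{dy}), um.
#' @param laminaTrace Optional two-column matrix of lamina points (um).
#' @param poreEndpoints Optional 2 x 2 matrix of pore endpoints (um).
#' @param epiCentroid Optional numeric length 2 (um).
#' @param legend Named character label legend.
#' @return A \linkS4class{SectionPlane}.
#' @export
sectionPlane <- function(image, spacing, laminaTrace = NULL,
                         poreEndpoints = NULL, epiCentroid = c(NA_real_, NA_real_),
                         legend = character()) {
  storage.mode(image) <- "integer"
  methods::new("SectionPlane", image = image,
               spacing = stats::setNames(as.numeric(spacing), c("dx", "dy")),
               laminaTrace = if (is.null(laminaTrace))
                 matrix(numeric(), 0L, 2L) else laminaTrace,
               poreEndpoints = if (is.null(poreEndpoints))
                 matrix(numeric(), 0L, 2L) else poreEndpoints,
               epiCentroid = as.numeric(epiCentroid),
               legend = legend)
}

setMethod("show", "SectionPlane", function(object) {
  cat(sprintf("SectionPlane: %d x %d px, spacing %.4g x %.4g um; lamina trace: %d pts%s\n",
              nrow(object@image), ncol(object@image), object@spacing[1],
              object@spacing[2], nrow(object@laminaTrace),
              if (nrow(object@poreEndpoints)) "; pore present" else ""))
})

# Resolve a target given as integer label(s) or role string(s) to labels.
resolveLabels <- function(target, legend) {
  if (is.character(target)) {
    labs <- as.integer(names(legend)[legend %in% target])
    if (!length(labs))
      stop("label role(s) ", paste(target, collapse = ", "),
           " absent from legend")
    labs
  } else as.integer(target)
}

# Boxcar smoothing with replicate padding, via an integral image. Applied
# to the 0/1 mask before contouring: the raw marching-squares contour of a
# binary image is a 45-degree staircase whose length (and hence crossing
# count) overshoots the true boundary by several percent; a small local
# average restores a sub-pixel boundary. k is the half-width in pixels.
boxSmooth <- function(m, k = 2L) {
  if (k <= 0L) return(m + 0)
  nx <- nrow(m); ny <- ncol(m)
  p <- m[c(rep(1L, k), seq_len(nx), rep(nx, k)),
         c(rep(1L, k), seq_len(ny), rep(ny, k))]
  cs <- apply(p, 2, cumsum)
  cs <- t(apply(cs, 1, cumsum))
  Z <- matrix(0, nx + 2L * k + 1L, ny + 2L * k + 1L)
  Z[-1L, -1L] <- cs
  ri <- seq_len(nx); ci <- seq_len(ny)
  (Z[ri + 2L * k + 1L, ci + 2L * k + 1L, drop = FALSE] -
     Z[ri, ci + 2L * k + 1L, drop = FALSE] -
     Z[ri + 2L * k + 1L, ci, drop = FALSE] +
     Z[ri, ci, drop = FALSE]) / (2 * k + 1)^2
}

# Iso-contour at level 0.5 of a (smoothed) indicator field, as segments.
# Returns list(p = n x 2 starts, q = n x 2 ends).
fieldBoundarySegments <- function(field, dx, dy) {
  nx <- nrow(field); ny <- ncol(field)
  xs <- (seq_len(nx) - 0.5) * dx
  ys <- (seq_len(ny) - 0.5) * dy
  cl <- grDevices::contourLines(xs, ys, field, levels = 0.5)
  if (!length(cl)) return(list(p = matrix(numeric(), 0, 2),
                               q = matrix(numeric(), 0, 2)))
  p <- NULL; q <- NULL
  for (cc in cl) {
    m <- cbind(cc$x, cc$y)
    if (nrow(m) < 2L) next
    p <- rbind(p, m[-nrow(m), , drop = FALSE])
    q <- rbind(q, m[-1L, , drop = FALSE])
  }
  list(p = p, q = q)
}

# Count proper crossings between grid segments (gp -> gq) and boundary
# segments (bp -> bq) using a uniform spatial hash to prune pairs. Returns
# list(n = total, pts = crossing coordinates, arc = arc id per crossing).
crossingsBinned <- function(gp, gq, arcId, bp, bq) {
  if (!nrow(gp) || !nrow(bp))
    return(list(n = 0L, pts = matrix(numeric(), 0, 2), arc = integer()))
  seglen <- function(p, q) sqrt((q[, 1] - p[, 1])^2 + (q[, 2] - p[, 2])^2)
  h <- max(0.05, 2 * max(seglen(gp, gq)), 2 * max(seglen(bp, bq)))
  x0 <- min(gp[, 1], bp[, 1]); y0 <- min(gp[, 2], bp[, 2])
  cellOf <- function(p, q) {
    mx <- (p[, 1] + q[, 1]) / 2; my <- (p[, 2] + q[, 2]) / 2
    cbind(floor((mx - x0) / h), floor((my - y0) / h))
  }
  gc <- cellOf(gp, gq)
  bc <- cellOf(bp, bq)
  ncellx <- max(gc[, 1], bc[, 1]) + 2L
  gkey <- gc[, 1] + 1L + ncellx * gc[, 2]
  bkey <- bc[, 1] + 1L + ncellx * bc[, 2]
  ordG <- order(gkey)
  gkeyS <- gkey[ordG]
  pi_ <- integer(); qi_ <- integer()
  neigh <- as.matrix(expand.grid(-1:1, -1:1))
  ub <- sort(unique(bkey))
  bByKey <- split(seq_len(nrow(bp)), match(bkey, ub))
  for (kk in seq_along(ub)) {
    key <- ub[kk]
    bi <- bByKey[[kk]]
    cx <- (key - 1L) %% ncellx
    cy <- (key - 1L) %/% ncellx
    nkeys <- (cx + neigh[, 1]) + 1L + ncellx * (cy + neigh[, 2])
    gi <- integer()
    for (nk in nkeys) {
      lo <- findInterval(nk - 1L, gkeyS) + 1L
      hi2 <- findInterval(nk, gkeyS)
      if (hi2 >= lo) gi <- c(gi, ordG[lo:hi2])
    }
    if (!length(gi)) next
    np <- length(gi) * length(bi)
    gij <- rep(gi, times = length(bi))
    bij <- rep(bi, each = length(gi))
    hit <- segmentsCross(gp[gij, , drop = FALSE], gq[gij, , drop = FALSE],
                         bp[bij, , drop = FALSE], bq[bij, , drop = FALSE])
    if (any(hit)) { pi_ <- c(pi_, gij[hit]); qi_ <- c(qi_, bij[hit]) }
  }
  if (!length(pi_))
    return(list(n = 0L, pts = matrix(numeric(), 0, 2), arc = integer()))
  pts <- segmentIntersection(gp[pi_, , drop = FALSE], gq[pi_, , drop = FALSE],
                             bp[qi_, , drop = FALSE], bq[qi_, , drop = FALSE])
  list(n = length(pi_), pts = pts, arc = arcId[pi_])
}

#' Count grid intersections and points on a section
#'
#' Casts a cycloid grid on a section and tallies I, the transversal
#' crossings between the grid arcs and the sub-pixel boundary of the target
#' mask (polygonized at iso-level 0.5), and P, the test points falling
#' inside the mask (bilinear indicator > 0.5). Tangential touches are not
#' counted: a crossing requires a strict sign change. With
#' \code{restricted = TRUE} only crossings and points on the stromal side
#' of the restriction line (see \code{\link{restrictionLine}}) contribute,
#' reproducing the rule that profiles on the epithelial side of the
#' basal-lamina pore are excluded.
#'
#' @param grid A \linkS4class{CycloidGrid}.
#' @param section A \linkS4class{SectionPlane}.
#' @param targetLabel Integer label(s) or role string(s) (resolved via the
#'   section legend) defining the target mask.
#' @param restricted Logical; apply the restriction line.
#' @param smooth Half-width (pixels) of the boxcar pre-smoothing applied to
#'   the mask indicator before polygonizing its boundary; the same smoothed
#'   field defines point membership, so I and P refer to one region. The
#'   default 2 (a 5 x 5 window) suppresses the raster staircase; set 0 for
#'   the raw binary boundary.
#' @return A \linkS4class{CountTally}.
#' @examples
#' img <- matrix(0L, 60, 60)
#' img[20:40, 20:40] <- 1L
#' sp <- sectionPlane(img, c(0.1, 0.1))
#' g <- buildGrid(1, 0, c(0.3, 0.2), extent = c(0, 6, 0, 6))
#' countGrid(g, sp, 1L)
#' @export
countGrid <- function(grid, section, targetLabel, restricted = FALSE,
                      smooth = 2L) {
  labs <- if (is.character(targetLabel))
    resolveLabels(targetLabel, section@legend) else as.integer(targetLabel)
  mask <- matrix(section@image %in% labs,
                 nrow(section@image), ncol(section@image))
  nA <- length(grid@arcs)
  rline <- if (restricted) restrictionLine(section) else NULL
  if (!any(mask)) {
    warning("target label absent from section; returning I = P = 0")
    return(methods::new("CountTally", I = 0L, P = 0L, nArcs = as.integer(nA),
                        restricted = restricted,
                        perArc = data.frame(arc = seq_len(nA),
                                            I = integer(nA), P = integer(nA))))
  }
  dx <- section@spacing[[1]]; dy <- section@spacing[[2]]
  # smoothed indicator: sub-pixel boundary without the raster staircase;
  # structures narrower than about (smooth + 1) px fall below resolution
  field <- boxSmooth(mask + 0, smooth)
  bnd <- fieldBoundarySegments(field, dx, dy)
  gp <- NULL; gq <- NULL; arcId <- integer()
  for (i in seq_len(nA)) {
    a <- grid@arcs[[i]]
    gp <- rbind(gp, a[-nrow(a), , drop = FALSE])
    gq <- rbind(gq, a[-1L, , drop = FALSE])
    arcId <- c(arcId, rep.int(i, nrow(a) - 1L))
  }
  cr <- crossingsBinned(gp, gq, arcId, bnd$p, bnd$q)
  crossArc <- cr$arc
  if (restricted && cr$n > 0L) {
    keep <- stromalSide(rline, cr$pts) > 0
    crossArc <- crossArc[keep]
  }
  Iarc <- tabulate(crossArc, nbins = nA)
  pin <- if (nrow(grid@points))
    bilinearAt(field, dx, dy, grid@points[, 1], grid@points[, 2]) > 0.5
  else logical()
  # points must lie within the section extent to count
  if (length(pin)) {
    inExt <- grid@points[, 1] >= 0 & grid@points[, 1] <= nrow(mask) * dx &
             grid@points[, 2] >= 0 & grid@points[, 2] <= ncol(mask) * dy
    pin <- pin & inExt
    if (restricted)
      pin <- pin & stromalSide(rline, grid@points) > 0
  }
  Parc <- as.integer(pin)
  methods::new("CountTally", I = as.integer(sum(Iarc)),
               P = as.integer(sum(Parc)), nArcs = as.integer(nA),
               restricted = restricted,
               perArc = data.frame(arc = seq_len(nA), I = Iarc, P = Parc))
}

setMethod("show", "CountTally", function(object) {
  cat(sprintf("CountTally: I = %d, P = %d over %d arcs%s\n", object@I,
              object@P, object@nArcs,
              if (object@restricted) " (restricted)" else ""))
})

#' Cast a randomly translated grid on a section
#'
#' Convenience wrapper: draws a uniform random phase within one tile,
#' orients the grid's vertical axis parallel to the basal lamina (when a
#' trace is available; otherwise uses \code{orientation}), builds the grid
#' over the section extent and counts.
#'
#' @inheritParams countGrid
#' @param lp Test-line length per point, um.
#' @param orientation Fallback vertical-axis angle (radians) when the
#'   section has no lamina trace.
#' @param seed Optional seed for the phase draw.
#' @return A \linkS4class{CountTally}.
#' @export
castGrid <- function(section, targetLabel, lp, restricted = FALSE,
                     orientation = 0, seed = NULL) {
  o <- if (nrow(section@laminaTrace) >= 2L) laminaOrientation(section)
       else orientation
  rc <- lp / 8
  ph <- withSeed(seed, stats::runif(2) * c(2 * pi * rc, 4 * rc))
  ext <- c(0, nrow(section@image) * section@spacing[[1]],
           0, ncol(section@image) * section@spacing[[2]])
  g <- buildGrid(lp, o, ph, ext)
  countGrid(g, section, targetLabel, restricted = restricted)
}
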