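#' @include AllClasses.R AllGenerics.R
NULL

newPhantom <- function(kind, params, S, V, pose = identityPose()) {
  methods::new("Phantom", shapeKind = kind, params = params, pose = pose,
               analyticSurface = S, analyticVolume = V)
}

#' Create a spherical phantom
#'
#' @param r Radius in um; must be > 0.
#' @param center Optional centre in scene coordinates (um).
#' @return A \linkS4class{Phantom} with surface \eqn{4\pi r^2} and volume
#'   \eqn{(4/3)\pi r^3}, so S/V = 3/r.
#' @examples
#' svRatio(makeSphere(1))      # 3
#' analyticVolume(makeSphere(2))  # 33.51
#' @export
makeSphere <- function(r, center = c(0, 0, 0)) {
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r <= 0)
    stop("invalid parameter: sphere radius must be a positive number")
  newPhantom("sphere", c(r = r), 4 * pi * r^2, (4 / 3) * pi * r^3,
             identityPose(center))
}

#' Create a capsule phantom (cylinder with hemispherical caps)
#'
#' The model of a thin penetrating nerve-bundle segment. In the canonical
#' frame the cylinder axis runs along x from 0 to L, with hemispherical
#' caps beyond both ends.
#'
#' @param r Radius in um; must be > 0.
#' @param L Cylinder length between the caps, um; L >= 0 (L = 0 is a sphere).
#' @param pose Optional rigid pose (list with \code{rotation}, \code{translation}).
#' @return A \linkS4class{Phantom} with surface \eqn{2\pi r L + 4\pi r^2}
#'   and volume \eqn{\pi r^2 L + (4/3)\pi r^3}. For long capsules S/V
#'   approaches the infinite-cylinder limit 2/r.
#' @export
makeCapsule <- function(r, L, pose = identityPose()) {
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r <= 0)
    stop("invalid parameter: capsule radius must be a positive number")
  if (!is.numeric(L) || length(L) != 1L || !is.finite(L) || L < 0)
    stop("invalid parameter: capsule length must be non-negative")
  S <- 2 * pi * r * L + 4 * pi * r^2
  V <- pi * r^2 * L + (4 / 3) * pi * r^3
  newPhantom("capsule", c(r = r, L = L), S, V, pose)
}

#' Create a finite (uncapped) cylinder phantom
#'
#' @param r Radius, um.
#' @param L Length, um; must be > 0.
#' @param pose Optional rigid pose.
#' @return A \linkS4class{Phantom} with surface \eqn{2\pi r L + 2\pi r^2}
#'   and volume \eqn{\pi r^2 L}.
#' @export
makeFiniteCylinder <- function(r, L, pose = identityPose()) {
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r <= 0)
    stop("invalid parameter: cylinder radius must be a positive number")
  if (!is.numeric(L) || length(L) != 1L || !is.finite(L) || L <= 0)
    stop("invalid parameter: cylinder length must be positive")
  S <- 2 * pi * r * L + 2 * pi * r^2
  V <- pi * r^2 * L
  newPhantom("finite_cylinder", c(r = r, L = L), S, V, pose)
}

#' Create a tube-with-bulb phantom (thin shaft ending in a large sphere)
#'
#' The model of a swollen fusing nerve bundle: a shaft of radius
#' \code{rShaft} (hemispherical cap at the start, canonical x = 0) running
#' to x = L, where a bulb sphere of radius \code{RBulb} is centred. Surface
#' and volume are the exact solid-union values (the sphere cap swallowed by
#' the shaft and the shaft portion inside the bulb are subtracted).
#'
#' Two regimes are supported: the tube regime, where the bulb sits at the
#' end of an exposed shaft (requires \eqn{\sqrt{R^2 - r^2} \le L} and
#' \eqn{R \le L}), and the sphere regime where the bulb swallows the shaft
#' entirely (\eqn{R \ge L + r}). Intermediate partial-overlap geometries
#' are rejected.
#'
#' @param rShaft Shaft radius, um; 0 < rShaft <= RBulb.
#' @param L Shaft axis length, um.
#' @param RBulb Bulb radius, um.
#' @param pose Optional rigid pose.
#' @return A \linkS4class{Phantom}. With \code{RBulb == rShaft} it equals
#'   \code{makeCapsule(rShaft, L)}.
#' @export
makeTubeWithBulb <- function(rShaft, L, RBulb, pose = identityPose()) {
  if (!is.numeric(rShaft) || length(rShaft) != 1L || rShaft <= 0)
    stop("invalid parameter: shaft radius must be a positive number")
  if (!is.numeric(L) || length(L) != 1L || L < 0)
    stop("invalid parameter: shaft length must be non-negative")
  if (!is.numeric(RBulb) || length(RBulb) != 1L || RBulb < rShaft)
    stop("invalid parameter: bulb radius must satisfy RBulb >= rShaft")
  r <- rShaft; R <- RBulb
  if (R >= L + r) {
    # bulb swallows the whole shaft
    S <- 4 * pi * R^2
    V <- (4 / 3) * pi * R^3
  } else {
    cjun <- sqrt(R^2 - r^2)
    if (cjun > L || R > L)
      stop("unsupported geometry: bulb partially engulfs the shaft ",
           "(need sqrt(RBulb^2 - rShaft^2) <= L and RBulb <= L, ",
           "or RBulb >= L + rShaft)")
    h <- R - cjun  # height of the sphere cap hidden inside the shaft
    S <- 2 * pi * r^2 +                  # start hemisphere
         2 * pi * r * (L - cjun) +       # exposed lateral shaft
         4 * pi * R^2 - 2 * pi * R * h   # bulb minus hidden cap
    V <- (2 / 3) * pi * r^3 + pi * r^2 * L + (4 / 3) * pi * R^3 -
         pi * r^2 * cjun -               # shaft slab inside the bulb
         (pi / 3) * h^2 * (3 * R - h)    # sphere cap inside the shaft
  }
  newPhantom("tube_with_bulb", c(r = r, L = L, R_bulb = R), S, V, pose)
}

#' @rdname analyticSurface
#' @export
setMethod("analyticSurface", "Phantom", function(object) object@analyticSurface)

#' @rdname analyticVolume
#' @export
setMethod("analyticVolume", "Phantom", function(object) object@analyticVolume)

#' @rdname svRatio
#' @export
setMethod("svRatio", "Phantom", function(object)
  object@analyticSurface / object@analyticVolume)

setMethod("show", "Phantom", function(object) {
  cat(sprintf("Phantom <%s>  params: %s\n", object@shapeKind,
              paste(sprintf("%s=%.4g", names(object@params), object@params),
                    collapse = ", ")))
  cat(sprintf("  surface %.4f um^2, volume %.4f um^3, S/V %.4f um^-1\n",
              object@analyticSurface, object@analyticVolume, svRatio(object)))
})

# Rebuild the same shape family with a different free radius.
rebuildShape <- function(kind, radius, fixed, pose = identityPose()) {
  switch(kind,
    sphere = makeSphere(radius),
    capsule = makeCapsule(radius, fixed$L, pose),
    finite_cylinder = makeFiniteCylinder(radius, fixed$L, pose),
    tube_with_bulb = makeTubeWithBulb(fixed$rShaft, fixed$L, radius, pose),
    stop("unknown shape kind: ", kind))
}

#' Calibrate the free radius of a shape family to a target S/V
#'
#' Solves, by bisection on the closed-form surface-to-volume ratio, for the
#' radius at which the shape family attains a prescribed S/V. The free
#' radius is \code{r} for spheres, capsules and cylinders, and the bulb
#' radius \code{R_bulb} for tube-with-bulb (with \code{rShaft} and \code{L}
#' fixed); S/V is monotone decreasing in the free radius in each family.
#' Used to build phantom cohorts whose ground-truth S/V equals the group
#' means reported for penetrating (3.32 um^-1) and fusing (1.39 um^-1)
#' corneal nerve bundles.
#'
#' @param targetSV Target surface-to-volume ratio, um^-1; > 0.
#' @param shapeKind One of \code{"sphere"}, \code{"capsule"},
#'   \code{"finite_cylinder"}, \code{"tube_with_bulb"}.
#' @param fixedParams List of the fixed parameters: \code{L} for capsule /
#'   cylinder, \code{rShaft} and \code{L} for tube_with_bulb.
#' @param tol Relative tolerance on the achieved S/V (default 1e-8).
#' @return The calibrated radius (um).
#' @examples
#' calibrateRadiusForSV(3, "sphere")              # 1
#' r <- calibrateRadiusForSV(3.32, "capsule", list(L = 10))
#' svRatio(makeCapsule(r, 10))                    # 3.32
#' @export
calibrateRadiusForSV <- function(targetSV, shapeKind,
                                 fixedParams = list(), tol = 1e-8) {
  if (!is.numeric(targetSV) || length(targetSV) != 1L || targetSV <= 0)
    stop("invalid parameter: targetSV must be positive")
  f <- function(radius) svRatio(rebuildShape(shapeKind, radius, fixedParams))
  # bracket: S/V decreases in the free radius
  if (shapeKind == "tube_with_bulb") {
    lo <- fixedParams$rShaft
    hi <- fixedParams$L  # upper edge of the supported tube regime
    if (hi <= lo) stop("no solution: fixed geometry leaves no bulb range")
    if (targetSV > f(lo) + tol || targetSV < f(hi) - tol)
      stop(sprintf(paste0("no solution: target S/V %.4g outside the reachable",
                          " range [%.4g, %.4g] for this family"),
                   targetSV, f(hi), f(lo)))
    lo <- lo * (1 + 1e-12)
  } else {
    lo <- 1e-9; hi <- 1
    while (f(hi) > targetSV && hi < 1e9) hi <- hi * 2
    while (f(lo) < targetSV && lo > 1e-12) lo <- lo / 2
    if (f(hi) > targetSV || f(lo) < targetSV)
      stop("no solution: target S/V unreachable within the family")
  }
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > targetSV) lo <- mid else hi <- mid
    if (abs(f(mid) - targetSV) <= tol * targetSV) return(mid)
  }
  (lo + hi) / 2
}

# Map scene-frame points (n x 3) into a phantom's canonical frame.
toCanonical <- function(phantom, pts) {
  Rm <- phantom@pose$rotation
  tr <- phantom@pose$translation
  sweep(pts, 2, tr) %*% Rm   # q = R^T (p - t), as rows: (p - t) %*% R
}

# Inside test in the canonical frame; q is n x 3.
insideCanonical <- function(kind, params, q) {
  r <- params[["r"]]
  switch(kind,
    sphere = q[, 1]^2 + q[, 2]^2 + q[, 3]^2 <= r^2,
    capsule = {
      L <- params[["L"]]
      s <- pmin(pmax(q[, 1], 0), L)
      (q[, 1] - s)^2 + q[, 2]^2 + q[, 3]^2 <= r^2
    },
    finite_cylinder = {
      L <- params[["L"]]
      q[, 1] >= 0 & q[, 1] <= L & q[, 2]^2 + q[, 3]^2 <= r^2
    },
    tube_with_bulb = {
      L <- params[["L"]]; R <- params[["R_bulb"]]
      s <- pmin(pmax(q[, 1], 0), L)
      shaft <- (q[, 1] - s)^2 + q[, 2]^2 + q[, 3]^2 <= r^2
      bulb <- (q[, 1] - L)^2 + q[, 2]^2 + q[, 3]^2 <= R^2
      shaft | bulb
    },
    stop("unknown shape kind: ", kind))
}

# Scene-frame membership test for arbitrary points.
insideSolid <- function(phantom, pts) {
  insideCanonical(phantom@shapeKind, phantom@params, toCanonical(phantom, pts))
}

# Canonical-frame axis-aligned bounding box, conservative after rotation.
phantomBounds <- function(phantom) {
  p <- phantom@params
  bb <- switch(phantom@shapeKind,
    sphere = rbind(c(-p[["r"]], p[["r"]]), c(-p[["r"]], p[["r"]]),
                   c(-p[["r"]], p[["r"]])),
    capsule = rbind(c(-p[["r"]], p[["L"]] + p[["r"]]),
                    c(-p[["r"]], p[["r"]]), c(-p[["r"]], p[["r"]])),
    finite_cylinder = rbind(c(0, p[["L"]]),
                            c(-p[["r"]], p[["r"]]), c(-p[["r"]], p[["r"]])),
    tube_with_bulb = {
      R <- p[["R_bulb"]]
      rbind(c(-p[["r"]], p[["L"]] + R), c(-R, R), c(-R, R))
    })
  corners <- as.matrix(expand.grid(bb[1, ], bb[2, ], bb[3, ]))
  world <- corners %*% t(phantom@pose$rotation)
  world <- sweep(world, 2, phantom@pose$translation, "+")
  c(min(world[, 1]), max(world[, 1]), min(world[, 2]), max(world[, 2]),
    min(world[, 3]), max(world[, 3]))
}
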