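#' Phantom: a parametric solid with closed-form surface area and volume
#'
#' A \code{Phantom} describes one rigid solid in the scene: a sphere, a
#' capsule (cylinder with hemispherical caps), a finite cylinder, or a
#' tube-with-bulb (thin shaft ending in a large sphere, the model of a
#' swollen fusing nerve bundle). The canonical frame places the symmetry
#' axis along x; \code{pose} carries a rotation matrix and translation that
#' move the solid into scene coordinates. All lengths are micrometres.
#'
#' @slot shapeKind One of \code{"sphere"}, \code{"capsule"},
#'   \code{"finite_cylinder"}, \code{"tube_with_bulb"}.
#' @slot params Named numeric vector of shape parameters (um): \code{r} and,
#'   depending on the shape, \code{L} and \code{R_bulb}.
#' @slot pose List with elements \code{rotation} (3 x 3 orthonormal matrix)
#'   and \code{translation} (numeric length 3, um).
#' @slot analyticSurface Closed-form surface area, um^2.
#' @slot analyticVolume Closed-form volume, um^3.
#' @seealso \code{\link{makeSphere}}, \code{\link{makeCapsule}},
#'   \code{\link{makeTubeWithBulb}}, \code{\link{calibrateRadiusForSV}}
#' @export
setClass("Phantom", representation(
  shapeKind = "character",
  params = "numeric",
  pose = "list",
  analyticSurface = "numeric",
  analyticVolume = "numeric"
))

setValidity("Phantom", function(object) {
  msg <- character()
  kinds <- c("sphere", "capsule", "finite_cylinder", "tube_with_bulb")
  if (length(object@shapeKind) != 1L || !object@shapeKind %in% kinds)
    msg <- c(msg, sprintf("shapeKind must be one of: %s", paste(kinds, collapse = ", ")))
  if (any(!is.finite(object@params)) || any(object@params < 0))
    msg <- c(msg, "shape parameters must be finite and non-negative")
  if (!is.null(object@params["r"]) && !is.na(object@params["r"]) &&
      object@params[["r"]] <= 0)
    msg <- c(msg, "radius must be strictly positive")
  if (length(object@analyticSurface) != 1L || object@analyticSurface <= 0)
    msg <- c(msg, "analyticSurface must be a positive scalar")
  if (length(object@analyticVolume) != 1L || object@analyticVolume <= 0)
    msg <- c(msg, "analyticVolume must be a positive scalar")
  R <- object@pose$rotation
  if (is.null(R) || !is.matrix(R) || !all(dim(R) == c(3L, 3L)) ||
      max(abs(crossprod(R) - diag(3))) > 1e-8)
    msg <- c(msg, "pose$rotation must be a 3 x 3 orthonormal matrix")
  if (length(object@pose$translation) != 3L)
    msg <- c(msg, "pose$translation must have length 3")
  if (length(msg)) msg else TRUE
})

#' SceneSpec: the geometric description of one synthetic stack
#'
#' Collects the phantoms (nerve-bundle compartments), the basal-lamina slab,
#' its elliptical pores, and an epithelium slab, together with the bounding
#' box and the seed the scene was generated from. The coordinate convention
#' is: x to the right in each section, y pointing from stroma toward the
#' epithelium, z the section (stacking) axis; all geometry in um. The
#' lamina is a slab normal to y, so each xy section shows it as a band whose
#' trace is parallel to x.
#'
#' @slot phantoms List of \linkS4class{Phantom} objects, in label-priority
#'   order (earlier phantoms win voxel ties).
#' @slot phantomLabels Integer labels (> 0), one per phantom.
#' @slot lamina List with \code{y0} (lower face, um), \code{thickness} (um)
#'   and \code{label}, or empty list for no lamina.
#' @slot pores data.frame with columns \code{cx}, \code{cz} (ellipse centre
#'   in the lamina plane, um), \code{a}, \code{b} (semi-axes, a >= b, a
#'   along x), \code{label}.
#' @slot epithelium List with \code{label}; the epithelium occupies
#'   y > lamina y0 + thickness. Empty list for none.
#' @slot bounds Numeric length 6: xmin, xmax, ymin, ymax, zmin, zmax (um).
#' @slot seed Integer seed the scene derives from (bookkeeping).
#' @seealso \code{\link{sceneSpec}}, \code{\link{voxelize}}
#' @export
setClass("SceneSpec", representation(
  phantoms = "list",
  phantomLabels = "integer",
  lamina = "list",
  pores = "data.frame",
  epithelium = "list",
  bounds = "numeric",
  seed = "integer"
))

setValidity("SceneSpec", function(object) {
  msg <- character()
  if (length(object@phantoms) != length(object@phantomLabels))
    msg <- c(msg, "one label per phantom required")
  if (length(object@bounds) != 6L ||
      any(object@bounds[c(2, 4, 6)] <= object@bounds[c(1, 3, 5)]))
    msg <- c(msg, "bounds must be c(xmin, xmax, ymin, ymax, zmin, zmax) with positive extent")
  labs <- c(object@phantomLabels,
            if (length(object@lamina)) object@lamina$label,
            if (nrow(object@pores)) object@pores$label,
            if (length(object@epithelium)) object@epithelium$label)
  if (length(labs) && (anyDuplicated(labs) || any(labs <= 0)))
    msg <- c(msg, "label ids must be unique and > 0 (0 is background)")
  if (nrow(object@pores) && !length(object@lamina))
    msg <- c(msg, "pores require a lamina")
  if (nrow(object@pores)) {
    if (any(object@pores$a < object@pores$b))
      msg <- c(msg, "pore semi-axes must satisfy a >= b")
    inx <- object@pores$cx - object@pores$a >= object@bounds[1] &
           object@pores$cx + object@pores$a <= object@bounds[2]
    inz <- object@pores$cz - object@pores$b >= object@bounds[5] &
           object@pores$cz + object@pores$b <= object@bounds[6]
    if (!all(inx & inz))
      msg <- c(msg, "pores must lie within the lamina plane inside bounds")
  }
  if (length(msg)) msg else TRUE
})

#' LabelStack: serial 2D label images with anisotropic voxel spacing
#'
#' The universal segmentation container: an ordered set of 2D integer label
#' images (sections), stored as a 3D integer array indexed \code{[x, y, z]}
#' with z the section number, plus the physical voxel spacing and a legend
#' mapping label values to roles. Default spacing is 0.01 x 0.01 x 0.1 um,
#' i.e. 10 nm pixels and 100 nm section steps, typical SBF-SEM acquisition
#' geometry.
#'
#' @slot data 3D integer array \code{[x, y, z]} of label values (0 = background).
#' @slot spacing Named numeric: \code{dx}, \code{dy}, \code{dz} in um.
#' @slot legend Named character: names are label values as strings, values
#'   are role strings.
#' @slot meta List of provenance fields (seed, notes, ...).
#' @seealso \code{\link{voxelize}}, \code{\link{readStack}},
#'   \code{\link{writeStack}}
#' @export
setClass("LabelStack", representation(
  data = "array",
  spacing = "numeric",
  legend = "character",
  meta = "list"
))

setValidity("LabelStack", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "data must be a 3D array [x, y, z]")
  if (!is.integer(object@data))
    msg <- c(msg, "data must be an integer array")
  if (length(object@spacing) != 3L || any(object@spacing <= 0) ||
      any(!is.finite(object@spacing)))
    msg <- c(msg, "spacing must be three positive numbers (dx, dy, dz)")
  present <- unique(as.vector(object@data))
  present <- present[present != 0L]
  if (length(present) && !all(as.character(present) %in% names(object@legend)))
    msg <- c(msg, "legend must cover all nonzero labels present in the data")
  if (length(msg)) msg else TRUE
})

#' CycloidGrid: a tiled system of cycloid test arcs with test points
#'
#' A cycloid test grid for vertical-section stereology. Each full cycloid
#' arc (parameter theta in [0, 2*pi]) has length 8 * arcScale and carries
#' one test point at its arc-length midpoint, so the test-line length per
#' point is l/p = 8 * arcScale. The arcs' minor axis is parallel to the
#' grid's vertical axis; the repeating tile holds two arcs in
#' point-symmetric arrangement, making the pattern invariant under rotation
#' by pi.
#'
#' @slot lp Test-line length per test point (um); \code{lp = 8 * arcScale}.
#' @slot arcScale Cycloid parameter r_c (um).
#' @slot orientation Angle (radians from the image x axis) of the grid's
#'   vertical axis.
#' @slot phase Numeric length 2: translation within one tile, grid-frame um.
#' @slot tile Numeric length 2: repeating-cell width and height, grid-frame um.
#' @slot arcs List of two-column matrices (x, y image coordinates, um), one
#'   polyline per arc.
#' @slot points Matrix (n x 2) of test-point image coordinates (um), row i
#'   belonging to arc i.
#' @seealso \code{\link{buildGrid}}, \code{\link{countGrid}}
#' @export
setClass("CycloidGrid", representation(
  lp = "numeric",
  arcScale = "numeric",
  orientation = "numeric",
  phase = "numeric",
  tile = "numeric",
  arcs = "list",
  points = "matrix"
))

setValidity("CycloidGrid", function(object) {
  msg <- character()
  if (length(object@lp) != 1L || object@lp <= 0)
    msg <- c(msg, "lp must be a positive scalar")
  if (length(object@phase) != 2L || length(object@tile) != 2L)
    msg <- c(msg, "phase and tile must have length 2")
  if (length(object@arcs) != nrow(object@points))
    msg <- c(msg, "one test point per arc required")
  if (length(msg)) msg else TRUE
})

#' SectionPlane: one section prepared for grid casting
#'
#' A single 2D label image together with its pixel spacing and the
#' section-level annotations grid casting needs: the basal-lamina trace
#' (for grid orientation), the pore endpoints (for the restriction line)
#' and the epithelium centroid (to orient the stromal side). Coordinates
#' are physical um with pixel (i, j) centred at ((i - 0.5) dx, (j - 0.5) dy).
#'
#' @slot image Integer matrix \code{[x, y]} of labels.
#' @slot spacing Named numeric: \code{dx}, \code{dy} in um.
#' @slot laminaTrace Two-column matrix of lamina points (um); may have 0 rows.
#' @slot poreEndpoints 2 x 2 matrix (rows = the two endpoints, um) or 0-row
#'   matrix when no pore crosses this section.
#' @slot epiCentroid Numeric length 2 (um) or \code{c(NA, NA)}.
#' @slot legend Named character label legend (as in \linkS4class{LabelStack}).
#' @seealso \code{\link{sectionFromStack}}, \code{\link{laminaOrientation}},
#'   \code{\link{restrictionLine}}
#' @export
setClass("SectionPlane", representation(
  image = "matrix",
  spacing = "numeric",
  laminaTrace = "matrix",
  poreEndpoints = "matrix",
  epiCentroid = "numeric",
  legend = "character"
))

setValidity("SectionPlane", function(object) {
  msg <- character()
  if (!is.integer(object@image))
    msg <- c(msg, "image must be an integer matrix")
  if (length(object@spacing) != 2L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be two positive numbers (dx, dy)")
  if (ncol(object@laminaTrace) != 2L)
    msg <- c(msg, "laminaTrace must be a two-column matrix")
  if (nrow(object@poreEndpoints) && !all(dim(object@poreEndpoints) == c(2L, 2L)))
    msg <- c(msg, "poreEndpoints must be a 2 x 2 matrix (or have 0 rows)")
  if (length(msg)) msg else TRUE
})

#' CountTally: intersection and point counts for one grid cast
#'
#' Bookkeeping for a single cast of a cycloid grid on a section: I is the
#' number of transversal crossings between the grid arcs and the target
#' mask boundary, P the number of test points falling inside the mask. When
#' the cast was restricted, only crossings and points on the stromal side
#' of the restriction line were counted.
#'
#' @slot I Integer intersection count.
#' @slot P Integer point count.
#' @slot nArcs Number of arcs cast.
#' @slot restricted Logical flag.
#' @slot perArc data.frame with one row per arc (columns \code{arc},
#'   \code{I}, \code{P}) for audit.
#' @seealso \code{\link{countGrid}}, \code{\link{estimateSV}}
#' @export
setClass("CountTally", representation(
  I = "integer",
  P = "integer",
  nArcs = "integer",
  restricted = "logical",
  perArc = "data.frame"
))

setValidity("CountTally", function(object) {
  msg <- character()
  if (object@I < 0L || object@P < 0L)
    msg <- c(msg, "I and P must be non-negative")
  if (length(msg)) msg else TRUE
})

#' GroupComparison: a two-group statistical comparison report
#'
#' Holds the summary (n, mean, SEM per group), the statistic used
#' (pooled two-tailed Student's t or Mann-Whitney U), its value and the
#' two-sided p value.
#'
#' @slot groups Character length 2, group names.
#' @slot n Integer length 2, group sizes.
#' @slot means Numeric length 2.
#' @slot sems Numeric length 2, standard errors of the mean.
#' @slot statistic One of \code{"student_t_two_tailed"},
#'   \code{"mann_whitney_u"}.
#' @slot statValue Numeric: t (with df attribute) or U of group 1.
#' @slot pValue Two-sided p value.
#' @slot alpha Significance level (default 0.05).
#' @slot details List of method details (df, exact flag, ...).
#' @seealso \code{\link{compareSV}}, \code{\link{comparePores}}
#' @export
setClass("GroupComparison", representation(
  groups = "character",
  n = "integer",
  means = "numeric",
  sems = "numeric",
  statistic = "character",
  statValue = "numeric",
  pValue = "numeric",
  alpha = "numeric",
  details = "list"
))

setValidity("GroupComparison", function(object) {
  msg <- character()
  if (any(object@n < 2L))
    msg <- c(msg, "each group needs n >= 2")
  if (object@pValue < 0 || object@pValue > 1)
    msg <- c(msg, "pValue must lie in [0, 1]")
  if (any(object@sems < 0))
    msg <- c(msg, "sems must be non-negative")
  if (length(msg)) msg else TRUE
})
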