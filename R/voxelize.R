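#' @include AllClasses.R AllGenerics.R scene.R
NULL

newLabelStack <- function(data, spacing, legend, meta = list()) {
  methods::new("LabelStack", data = data,
               spacing = stats::setNames(as.numeric(spacing), c("dx", "dy", "dz")),
               legend = legend, meta = meta)
}

#' @rdname spacing
#' @export
setMethod("spacing", "LabelStack", function(object) object@spacing)

#' @rdname labelLegend
#' @export
setMethod("labelLegend", "LabelStack", function(object) object@legend)

#' @rdname spacing
#' @export
setMethod("spacing", "SectionPlane", function(object) object@spacing)

#' @rdname labelLegend
#' @export
setMethod("labelLegend", "SectionPlane", function(object) object@legend)

#' Number of sections in a stack
#' @param stack A \linkS4class{LabelStack}.
#' @return Integer.
#' @export
nSections <- function(stack) dim(stack@data)[3]

#' Extract one section image
#' @param stack A \linkS4class{LabelStack}.
#' @param index Section number (1-based).
#' @return Integer matrix \code{[x, y]}.
#' @export
sectionImage <- function(stack, index) {
  if (index < 1L || index > nSections(stack)) stop("section index out of range")
  stack@data[, , index]
}

#' Raw label array of a stack
#' @param stack A \linkS4class{LabelStack}.
#' @return The 3D integer array \code{[x, y, z]}.
#' @export
stackData <- function(stack) stack@data

setMethod("show", "LabelStack", function(object) {
  d <- dim(object@data)
  cat(sprintf("LabelStack: %d x %d px, %d sections; spacing %.4g x %.4g x %.4g um\n",
              d[1], d[2], d[3], object@spacing[1], object@spacing[2],
              object@spacing[3]))
  if (length(object@legend)) {
    cat("  legend:",
        paste(sprintf("%s=%s", names(object@legend), object@legend),
              collapse = ", "), "\n")
  } else cat("  legend: (empty)\n")
})

#' @describeIn voxelize Rasterize a \linkS4class{SceneSpec} on a regular
#'   anisotropic voxel grid. Each voxel is labeled by the highest-priority
#'   structure containing its centre: pore > basal lamina > phantoms (in
#'   list order) > epithelium > background. Deterministic given scene and
#'   spacing. Voxel centres sit at \code{bounds_min + (i - 0.5) * spacing}.
#' @param roles Optional character vector of role strings for the phantoms
#'   (defaults to \code{"phantom_<i>"}).
#' @export
setMethod("voxelize", "SceneSpec", function(scene,
                                            spacing = c(0.01, 0.01, 0.1),
                                            roles = NULL, ...) {
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0) || any(!is.finite(spacing)))
    stop("spacing must be three positive numbers (dx, dy, dz)")
  b <- scene@bounds
  nx <- max(1L, as.integer(ceiling((b[2] - b[1]) / spacing[1] - 1e-9)))
  ny <- max(1L, as.integer(ceiling((b[4] - b[3]) / spacing[2] - 1e-9)))
  nz <- max(1L, as.integer(ceiling((b[6] - b[5]) / spacing[3] - 1e-9)))
  minR <- suppressWarnings(min(vapply(scene@phantoms,
                                      function(p) p@params[["r"]], numeric(1))))
  if (length(scene@phantoms) && max(spacing) > minR)
    warning("voxel spacing exceeds the smallest phantom radius; ",
            "the stack undersamples the geometry")
  xs <- b[1] + (seq_len(nx) - 0.5) * spacing[1]
  ys <- b[3] + (seq_len(ny) - 0.5) * spacing[2]
  zs <- b[5] + (seq_len(nz) - 0.5) * spacing[3]
  arr <- array(0L, dim = c(nx, ny, nz))

  lam <- scene@lamina
  lamRows <- if (length(lam))
    which(ys >= lam$y0 & ys <= lam$y0 + lam$thickness) else integer()
  epiRows <- if (length(scene@epithelium) && length(lam))
    which(ys > lam$y0 + lam$thickness) else integer()

  for (k in seq_len(nz)) {
    sec <- matrix(0L, nx, ny)
    if (length(epiRows)) sec[, epiRows] <- as.integer(scene@epithelium$label)
    # phantoms: later in the list = lower priority, so paint in reverse;
    # evaluate only inside each phantom's xy bounding box
    for (i in rev(seq_along(scene@phantoms))) {
      ph <- scene@phantoms[[i]]
      bb <- phantomBounds(ph)
      if (zs[k] < bb[5] - 1e-12 || zs[k] > bb[6] + 1e-12) next
      ix <- which(xs >= bb[1] - spacing[1] & xs <= bb[2] + spacing[1])
      iy <- which(ys >= bb[3] - spacing[2] & ys <= bb[4] + spacing[2])
      if (!length(ix) || !length(iy)) next
      pts <- cbind(rep(xs[ix], times = length(iy)),
                   rep(ys[iy], each = length(ix)), zs[k])
      sub <- matrix(insideSolid(ph, pts), length(ix), length(iy))
      block <- sec[ix, iy, drop = FALSE]
      block[sub] <- scene@phantomLabels[i]
      sec[ix, iy] <- block
    }
    if (length(lamRows)) sec[, lamRows] <- as.integer(lam$label)
    if (length(lamRows) && nrow(scene@pores)) {
      for (pidx in seq_len(nrow(scene@pores))) {
        po <- scene@pores[pidx, ]
        if (abs(zs[k] - po$cz) > po$b) next
        halfw <- po$a * sqrt(1 - ((zs[k] - po$cz) / po$b)^2)
        cols <- which(abs(xs - po$cx) <= halfw)
        if (length(cols)) sec[cols, lamRows] <- as.integer(po$label)
      }
    }
    arr[, , k] <- sec
  }
  legend <- sceneLegend(scene, roles)
  present <- unique(as.vector(arr)); present <- present[present != 0L]
  legend <- legend[names(legend) %in% as.character(present)]
  newLabelStack(arr, spacing, legend,
                meta = list(seed = scene@seed, bounds = b))
})
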