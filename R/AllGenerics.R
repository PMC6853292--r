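#' @include AllClasses.R
NULL

#' Analytic surface area of a phantom
#'
#' Closed-form surface area, in square micrometres, of the solid a
#' \linkS4class{Phantom} describes.
#'
#' @param object A \linkS4class{Phantom}.
#' @return Numeric scalar, um^2.
#' @export
setGeneric("analyticSurface", function(object) standardGeneric("analyticSurface"))

#' Analytic volume of a phantom
#'
#' Closed-form volume, in cubic micrometres, of the solid a
#' \linkS4class{Phantom} describes.
#'
#' @param object A \linkS4class{Phantom}.
#' @return Numeric scalar, um^3.
#' @export
setGeneric("analyticVolume", function(object) standardGeneric("analyticVolume"))

#' Analytic surface-to-volume ratio
#'
#' Ratio of \code{\link{analyticSurface}} to \code{\link{analyticVolume}},
#' the ground-truth quantity the cycloid-grid estimator targets.
#'
#' @param object A \linkS4class{Phantom}.
#' @return Numeric scalar, um^-1.
#' @export
setGeneric("svRatio", function(object) standardGeneric("svRatio"))

#' Voxel spacing of an image container
#'
#' @param object A \linkS4class{LabelStack} or \linkS4class{SectionPlane}.
#' @return Named numeric vector of physical voxel/pixel spacings in um
#'   (\code{dx}, \code{dy} and, for stacks, \code{dz}).
#' @export
setGeneric("spacing", function(object) standardGeneric("spacing"))

#' Label legend of an image container
#'
#' Maps integer label values to role strings such as
#' \code{"axon_penetrating"}, \code{"axon_fusing"}, \code{"basal_lamina"},
#' \code{"pore"} and \code{"epithelium"}.
#'
#' @param object A \linkS4class{LabelStack} or \linkS4class{SectionPlane}.
#' @return Named character vector; names are label integers as strings.
#' @export
setGeneric("labelLegend", function(object) standardGeneric("labelLegend"))

#' Rasterize a scene into a label stack
#'
#' @param scene A \linkS4class{SceneSpec}.
#' @param spacing Numeric length-3, voxel spacing \code{c(dx, dy, dz)} in um.
#' @param ... Further arguments passed to methods.
#' @return A \linkS4class{LabelStack}.
#' @export
setGeneric("voxelize", function(scene, spacing, ...) standardGeneric("voxelize"))
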