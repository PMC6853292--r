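#' @include AllClasses.R voxelize.R
NULL

SIDE_CAR_KEYS <- c("spacing", "legend", "schema_version")

#' Write a label stack to multi-page TIFF with a JSON sidecar
#'
#' Sections are written as 16-bit pages (x/y transposed to the usual
#' row-major image layout); spacing, legend, seed and schema version go to
#' \code{<path>.json}. Label semantics live in the sidecar, never in the
#' pixel values.
#'
#' @param stack A \linkS4class{LabelStack} (labels must fit in 16 bits).
#' @param path Output TIFF path; the sidecar is written next to it.
#' @return \code{path}, invisibly.
#' @export
writeStack <- function(stack, path) {
  mx <- max(stack@data)
  if (mx > 65535L) stop("labels exceed the uint16 range")
  pages <- lapply(seq_len(nSections(stack)), function(k)
    t(stack@data[, , k]) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  sidecar <- list(schema_version = 1L,
                  spacing = as.list(stack@spacing),
                  legend = as.list(stack@legend),
                  seed = stack@meta$seed)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' Read a label stack from multi-page TIFF + JSON sidecar
#'
#' @param path TIFF path; \code{<path>.json} must exist and provide
#'   \code{spacing} (dx, dy, dz) and \code{legend}.
#' @return A \linkS4class{LabelStack}; page order is section order.
#' @export
readStack <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(side))
    stop("missing sidecar ", side, "; required keys: ",
         paste(SIDE_CAR_KEYS, collapse = ", "))
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (is.null(meta$spacing) || length(unlist(meta$spacing)) != 3L)
    stop("sidecar lacks 'spacing' (dx, dy, dz)")
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (!length(pages) || any(!vapply(pages, is.matrix, logical(1))))
    stop("TIFF contains no readable sections")
  if (!all(vapply(pages, function(p) is.integer(p) || all(p == round(p)),
                  logical(1))))
    stop("non-integer pixel type: label stacks must be integer TIFFs")
  d1 <- dim(pages[[1]])
  if (any(vapply(pages, function(p) any(dim(p) != d1), logical(1))))
    stop("all sections must share dimensions")
  arr <- array(0L, dim = c(d1[2], d1[1], length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- as.integer(t(pages[[k]]))
  legend <- unlist(meta$legend)
  if (is.null(legend)) legend <- stats::setNames(character(), character())
  newLabelStack(arr, unlist(meta$spacing)[1:3], legend,
                meta = list(seed = meta$seed))
}

#' Read a pipeline run configuration (YAML or JSON)
#'
#' Fills defaults for any key not given; see \code{\link{runPipeline}} for
#' the key list.
#'
#' @param path Config file (.yaml/.yml or .json), or \code{NULL} for all
#'   defaults.
#' @return Named list of configuration values.
#' @export
readRunConfig <- function(path = NULL) {
  defaults <- list(
    n_pen = 23L, n_fus = 20L, sv_pen = 3.32, sv_fus = 1.39, cv = 0.1,
    l_pen = 10, shaft_radius = 0.3, shaft_length = 5,
    pore_mean_diameter = 2, pore_cv = 0.15,
    spacing = c(0.01, 0.01, 0.1), lp = 1, casts = 1L, restricted = FALSE,
    seed = 1L, alpha = 0.05, write_stacks = FALSE, schema_version = 1L)
  if (is.null(path)) return(defaults)
  user <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path) else jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  utils::modifyList(defaults, user)
}
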