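#' @include AllClasses.R phantom-shapes.R
NULL

#' Standard label roles
#'
#' Role strings used in label legends throughout the package.
#' @format Character vector.
#' @export
LABEL_ROLES <- c("axon_penetrating", "axon_fusing", "basal_lamina",
                 "pore", "epithelium")

#' Assemble a scene specification
#'
#' @param phantoms List of \linkS4class{Phantom} objects in label-priority
#'   order (earlier phantoms win voxel ties among phantoms).
#' @param phantomLabels Integer labels > 0, one per phantom.
#' @param bounds Numeric length 6: \code{c(xmin, xmax, ymin, ymax, zmin, zmax)} um.
#' @param lamina \code{NULL}, or list with \code{y0} (lower face, um),
#'   \code{thickness} (um) and \code{label}.
#' @param pores \code{NULL}, or data.frame with columns \code{cx}, \code{cz},
#'   \code{a}, \code{b}, \code{label} (ellipse holes in the lamina plane;
#'   semi-axis a along x, b along z, a >= b).
#' @param epithelium \code{NULL}, or list with \code{label}; fills
#'   y > lamina top.
#' @param seed Integer bookkeeping seed recorded in the scene.
#' @return A validated \linkS4class{SceneSpec}.
#' @seealso \code{\link{voxelize}}, \code{\link{writeScene}}
#' @export
sceneSpec <- function(phantoms, phantomLabels, bounds, lamina = NULL,
                      pores = NULL, epithelium = NULL, seed = NA_integer_) {
  if (inherits(phantoms, "Phantom")) phantoms <- list(phantoms)
  if (is.null(pores))
    pores <- data.frame(cx = numeric(), cz = numeric(), a = numeric(),
                        b = numeric(), label = integer())
  for (ph in phantoms) {
    bb <- phantomBounds(ph)
    if (any(bb[c(1, 3, 5)] > bounds[c(2, 4, 6)]) ||
        any(bb[c(2, 4, 6)] < bounds[c(1, 3, 5)]))
      warning("phantom lies entirely outside the scene bounds; ",
              "it will not appear in the rasterized stack")
    else if (any(bb[c(1, 3, 5)] < bounds[c(1, 3, 5)] - 1e-9) ||
             any(bb[c(2, 4, 6)] > bounds[c(2, 4, 6)] + 1e-9))
      warning("phantom extends beyond the scene bounds and will be clipped")
  }
  methods::new("SceneSpec",
    phantoms = phantoms,
    phantomLabels = as.integer(phantomLabels),
    lamina = if (is.null(lamina)) list() else lamina,
    pores = pores,
    epithelium = if (is.null(epithelium)) list() else epithelium,
    bounds = as.numeric(bounds),
    seed = as.integer(seed))
}

setMethod("show", "SceneSpec", function(object) {
  cat(sprintf("SceneSpec: %d phantom(s), bounds [%.2f,%.2f]x[%.2f,%.2f]x[%.2f,%.2f] um\n",
              length(object@phantoms), object@bounds[1], object@bounds[2],
              object@bounds[3], object@bounds[4], object@bounds[5],
              object@bounds[6]))
  if (length(object@lamina))
    cat(sprintf("  lamina at y in [%.3f, %.3f], %d pore(s)\n",
                object@lamina$y0, object@lamina$y0 + object@lamina$thickness,
                nrow(object@pores)))
})

sceneLegend <- function(scene, roles) {
  labs <- integer(); nms <- character()
  add <- function(label, role) {
    labs <<- c(labs, label); nms <<- c(nms, role)
  }
  for (i in seq_along(scene@phantoms))
    add(scene@phantomLabels[i],
        if (!is.null(roles) && length(roles) >= i) roles[i] else
          paste0("phantom_", i))
  if (length(scene@lamina)) add(scene@lamina$label, "basal_lamina")
  if (nrow(scene@pores)) for (lb in unique(scene@pores$label)) add(lb, "pore")
  if (length(scene@epithelium)) add(scene@epithelium$label, "epithelium")
  stats::setNames(as.character(nms), as.character(labs))
}

# ---- scene (de)serialization: schema-versioned YAML / JSON ----------------

sceneToList <- function(scene, roles = NULL) {
  list(
    schema_version = 1L,
    seed = scene@seed,
    bounds = scene@bounds,
    phantoms = lapply(seq_along(scene@phantoms), function(i) {
      ph <- scene@phantoms[[i]]
      list(kind = ph@shapeKind, params = as.list(ph@params),
           rotation = as.numeric(ph@pose$rotation),
           translation = ph@pose$translation,
           label = scene@phantomLabels[i],
           role = if (!is.null(roles)) roles[i] else NULL)
    }),
    lamina = if (length(scene@lamina)) scene@lamina else NULL,
    pores = if (nrow(scene@pores)) as.list(scene@pores) else NULL,
    epithelium = if (length(scene@epithelium)) scene@epithelium else NULL)
}

listToScene <- function(x) {
  if (is.null(x$schema_version) || x$schema_version != 1L)
    stop("unsupported scene schema version")
  phantoms <- lapply(x$phantoms, function(p) {
    pose <- list(rotation = matrix(as.numeric(p$rotation), 3L, 3L),
                 translation = as.numeric(p$translation))
    pr <- p$params
    switch(p$kind,
      sphere = makeSphere(pr$r, pose$translation),
      capsule = makeCapsule(pr$r, pr$L, pose),
      finite_cylinder = makeFiniteCylinder(pr$r, pr$L, pose),
      tube_with_bulb = makeTubeWithBulb(pr$r, pr$L, pr$R_bulb, pose))
  })
  pores <- if (!is.null(x$pores)) as.data.frame(x$pores) else NULL
  sceneSpec(phantoms,
            vapply(x$phantoms, function(p) as.integer(p$label), integer(1)),
            as.numeric(x$bounds), lamina = x$lamina, pores = pores,
            epithelium = x$epithelium,
            seed = if (is.null(x$seed)) NA_integer_ else x$seed)
}

#' Write / read a scene specification (YAML or JSON)
#'
#' Serializes a \linkS4class{SceneSpec} to a schema-versioned document; the
#' format is chosen from the file extension (\code{.yaml}/\code{.yml} or
#' \code{.json}).
#'
#' @param scene A \linkS4class{SceneSpec}.
#' @param path Output file path.
#' @param roles Optional character vector of phantom roles stored alongside.
#' @return \code{writeScene} returns \code{path} invisibly;
#'   \code{readScene} returns a \linkS4class{SceneSpec}.
#' @export
writeScene <- function(scene, path, roles = NULL) {
  x <- sceneToList(scene, roles)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(x, path, precision = 15L)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null")
  }
  invisible(path)
}

#' @rdname writeScene
#' @export
readScene <- function(path) {
  x <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE,
                        simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  }
  # yaml returns data frames as named column lists; normalize
  if (!is.null(x$pores) && !is.data.frame(x$pores))
    x$pores <- as.data.frame(x$pores)
  listToScene(x)
}
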