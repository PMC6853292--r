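#' @include AllClasses.R count.R voxelize.R utils.R
NULL

#' Surface-to-volume ratio from cycloid-grid tallies
#'
#' The classical vertical-section stereology estimator
#' \deqn{\hat S_V = \frac{2 \sum_i I_i}{(l/p) \sum_i P_i}}
#' where I is the number of intersections between the test lines and the
#' target boundary, P the number of test points inside the target, and l/p
#' the test-line length per grid point. Aggregation across casts is
#' ratio-of-sums (sum first, then divide), the standard low-variance choice,
#' not a mean of per-cast ratios.
#'
#' @param tallies A \linkS4class{CountTally} or list of them.
#' @param lp Test-line length per point, um (must match the grid used).
#' @return Estimated surface-to-volume ratio, um^-1.
#' @examples
#' t1 <- new("CountTally", I = 10L, P = 5L, nArcs = 1L, restricted = FALSE,
#'           perArc = data.frame(arc = 1L, I = 10L, P = 5L))
#' estimateSV(t1, lp = 2)  # 2
#' @export
estimateSV <- function(tallies, lp) {
  if (methods::is(tallies, "CountTally")) tallies <- list(tallies)
  if (!is.numeric(lp) || length(lp) != 1L || lp <= 0)
    stop("invalid parameter: lp must be positive")
  sumI <- sum(vapply(tallies, function(t) t@I, integer(1)))
  sumP <- sum(vapply(tallies, function(t) t@P, integer(1)))
  if (sumP == 0L)
    stop("undefined estimate: no test point fell inside the target ",
         "(sum(P) = 0)")
  2 * sumI / (lp * sumP)
}

#' Select a random section containing a label
#'
#' Uniform draw over the sections in which the target label is visible,
#' mirroring the sampling protocol in which one serial image per nerve is
#' chosen at random for grid casting.
#'
#' @param stack A \linkS4class{LabelStack}.
#' @param targetLabel Integer label(s) or role string(s).
#' @param seed Optional seed; a fixed seed gives a reproducible draw.
#' @return Section index (1-based).
#' @export
selectSection <- function(stack, targetLabel, seed = NULL) {
  labs <- if (is.character(targetLabel))
    resolveLabels(targetLabel, stack@legend) else as.integer(targetLabel)
  vis <- visibleSections(stack, labs)
  if (!length(vis))
    stop("not found: label absent from every section")
  if (length(vis) == 1L) return(vis)
  withSeed(seed, vis[sample.int(length(vis), 1L)])
}

# Sections in which any of the labels appears.
visibleSections <- function(stack, labs) {
  d <- dim(stack@data)
  hit <- logical(d[3])
  for (k in seq_len(d[3])) {
    s <- stack@data[, , k]
    hit[k] <- any(vapply(labs, function(l) any(s == l), logical(1)))
  }
  which(hit)
}

#' Volume of a label from voxel counts
#'
#' Cavalieri-style volume extraction: number of voxels carrying the label
#' times the voxel volume dx * dy * dz.
#'
#' @param stack A \linkS4class{LabelStack}.
#' @param targetLabel Integer label(s) or role string(s).
#' @return Volume in um^3 (0 with a warning if the label is absent).
#' @export
volumeFromLabels <- function(stack, targetLabel) {
  labs <- if (is.character(targetLabel))
    resolveLabels(targetLabel, stack@legend) else as.integer(targetLabel)
  n <- sum(stack@data %in% labs)
  if (n == 0L) warning("label absent from stack; volume 0")
  n * prod(stack@spacing)
}

# Max pairwise distance among points (n x 2), via convex hull.
maxFeret <- function(pts) {
  if (nrow(pts) == 1L) return(0)
  hull <- pts[grDevices::chull(pts), , drop = FALSE]
  d <- stats::dist(hull)
  max(as.numeric(d))
}

#' Basal-lamina pore diameter (maximum dimension)
#'
#' The maximum dimension of a lamina discontinuity: for each section the
#' maximum Feret (caliper) diameter of the pore region, in physical units,
#' then the maximum over all sections of the stack.
#'
#' @param stack A \linkS4class{LabelStack}.
#' @param poreLabel Integer label(s) or role string (default \code{"pore"}).
#' @return Pore diameter in um.
#' @export
poreDiameter <- function(stack, poreLabel = "pore") {
  labs <- if (is.character(poreLabel))
    resolveLabels(poreLabel, stack@legend) else as.integer(poreLabel)
  dx <- stack@spacing[[1]]; dy <- stack@spacing[[2]]
  best <- -Inf
  found <- FALSE
  for (k in seq_len(nSections(stack))) {
    idx <- which(matrix(stack@data[, , k] %in% labs,
                        dim(stack@data)[1], dim(stack@data)[2]),
                 arr.ind = TRUE)
    if (!nrow(idx)) next
    found <- TRUE
    pts <- cbind((idx[, 1] - 0.5) * dx, (idx[, 2] - 0.5) * dy)
    best <- max(best, maxFeret(pts))
  }
  if (!found) stop("not found: pore label absent from stack")
  best
}

# Neighbor codes adjacent (26-connectivity) to a voxel coordinate set.
adjacentLabels <- function(stack, coords) {
  d <- dim(stack@data)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  out <- integer()
  for (k in seq_len(nrow(off))) {
    nb <- sweep(coords, 2, off[k, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
          nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    nb <- nb[ok, , drop = FALSE]
    out <- c(out, stack@data[cbind(nb[, 1], nb[, 2], nb[, 3])])
  }
  unique(out)
}

#' Classify a nerve bundle as penetrating or fusing-mixed
#'
#' A bundle is \code{fusing_mixed} when fusing-axon voxels communicate with
#' the epithelium through a basal-lamina pore: concretely, when some
#' 26-connected component of the pore label touches (26-adjacency) both a
#' fusing-axon voxel and an epithelium voxel. A fusing label separated from
#' the epithelium by intact lamina, or a stack containing only penetrating
#' axons, classifies as \code{penetrating}.
#'
#' @param stack A \linkS4class{LabelStack} whose legend distinguishes
#'   \code{"axon_fusing"} and/or \code{"axon_penetrating"} roles.
#' @return \code{"fusing_mixed"} or \code{"penetrating"}.
#' @export
classifyBundle <- function(stack) {
  lg <- stack@legend
  fusLabs <- as.integer(names(lg)[lg == "axon_fusing"])
  penLabs <- as.integer(names(lg)[lg == "axon_penetrating"])
  if (!length(fusLabs) && !length(penLabs))
    stop("not found: no nerve labels in legend")
  if (!length(fusLabs)) return("penetrating")
  poreLabs <- as.integer(names(lg)[lg == "pore"])
  epiLabs <- as.integer(names(lg)[lg == "epithelium"])
  if (!length(poreLabs) || !length(epiLabs)) return("penetrating")
  pidx <- which(array(stack@data %in% poreLabs, dim(stack@data)),
                arr.ind = TRUE)
  if (!nrow(pidx)) return("penetrating")
  comp <- voxelComponents(pidx, dim(stack@data))
  for (cid in unique(comp)) {
    cc <- pidx[comp == cid, , drop = FALSE]
    nb <- adjacentLabels(stack, cc)
    if (any(nb %in% fusLabs) && any(nb %in% epiLabs))
      return("fusing_mixed")
  }
  "penetrating"
}

#' Build a SectionPlane from one stack section
#'
#' Extracts a section image and derives the cast annotations: the lamina
#' trace (all basal-lamina pixel centres), the pore endpoints (extreme
#' projections of in-section pore pixels onto the lamina direction) and the
#' epithelium centroid.
#'
#' @param stack A \linkS4class{LabelStack}.
#' @param index Section number (1-based).
#' @return A \linkS4class{SectionPlane}.
#' @export
sectionFromStack <- function(stack, index) {
  img <- sectionImage(stack, index)
  dx <- stack@spacing[[1]]; dy <- stack@spacing[[2]]
  lg <- stack@legend
  pixCoords <- function(roles) {
    labs <- as.integer(names(lg)[lg %in% roles])
    if (!length(labs)) return(matrix(numeric(), 0L, 2L))
    idx <- which(matrix(img %in% labs, nrow(img), ncol(img)), arr.ind = TRUE)
    cbind((idx[, 1] - 0.5) * dx, (idx[, 2] - 0.5) * dy)
  }
  lamPts <- pixCoords("basal_lamina")
  # thin the trace for the orientation fit (it only needs the direction)
  if (nrow(lamPts) > 4000L)
    lamPts <- lamPts[seq(1L, nrow(lamPts), length.out = 4000L), , drop = FALSE]
  porePts <- pixCoords("pore")
  epiPts <- pixCoords("epithelium")
  poreEnds <- NULL
  if (nrow(porePts) >= 2L && nrow(lamPts) >= 2L) {
    ang <- laminaOrientationOfPoints(lamPts)
    u <- c(cos(ang), sin(ang))
    proj <- porePts %*% u
    poreEnds <- rbind(porePts[which.min(proj), ], porePts[which.max(proj), ])
  }
  epiC <- if (nrow(epiPts)) colMeans(epiPts) else c(NA_real_, NA_real_)
  sectionPlane(img, c(dx, dy), laminaTrace = lamPts,
               poreEndpoints = poreEnds, epiCentroid = epiC, legend = lg)
}

# TLS direction of a point set (shared by laminaOrientation and
# sectionFromStack).
laminaOrientationOfPoints <- function(pts) {
  ctr <- sweep(pts, 2, colMeans(pts))
  cv <- crossprod(ctr) / nrow(pts)
  v <- eigen(cv, symmetric = TRUE)$vectors[, 1]
  atan2(v[2], v[1]) %% pi
}

#' Full morphometry of one bundle stack
#'
#' Runs the per-nerve protocol end to end on a labeled stack: select
#' random section(s), cast cycloid grids oriented to the lamina, pool the
#' tallies (ratio-of-sums) into a surface-to-volume estimate, extract
#' per-label volumes, measure the pore diameter and classify the phenotype.
#' The default \code{casts = 1} matches the original protocol (one random
#' section per nerve); with \code{casts > 1} each cast independently redraws
#' the section and the grid phase.
#'
#' @param stack A \linkS4class{LabelStack} with role legend.
#' @param targetLabel Label(s) or role(s) defining the bundle (default: all
#'   axon roles present).
#' @param lp Test-line length per point, um.
#' @param casts Number of independent (section, phase) casts to pool.
#' @param restricted Logical; restrict counts to the stromal side.
#' @param seed Optional seed driving section and phase draws.
#' @param bundleId Identifier copied into the result row.
#' @return One-row data.frame: \code{bundle_id}, \code{phenotype},
#'   \code{sv_hat} (um^-1), \code{section_index_used} (last cast),
#'   \code{volume_bundle} (um^3), \code{pore_diameter} (um, NA if absent),
#'   \code{casts}, \code{lp}, \code{seed}.
#' @export
bundleMorphometry <- function(stack, targetLabel = NULL, lp = 1, casts = 1L,
                              restricted = FALSE, seed = NULL,
                              bundleId = NA_character_) {
  lg <- stack@legend
  if (is.null(targetLabel)) {
    targetLabel <- intersect(c("axon_penetrating", "axon_fusing"), lg)
    if (!length(targetLabel)) stop("not found: no nerve labels in legend")
  }
  seeds <- childSeeds(seed, 2L * casts)
  tallies <- vector("list", casts)
  lastIdx <- NA_integer_
  labs <- if (is.character(targetLabel))
    resolveLabels(targetLabel, stack@legend) else as.integer(targetLabel)
  vis <- visibleSections(stack, labs)  # scanned once, drawn per cast
  if (!length(vis)) stop("not found: label absent from every section")
  for (i in seq_len(casts)) {
    lastIdx <- if (length(vis) == 1L) vis else
      withSeed(seeds[2L * i - 1L], vis[sample.int(length(vis), 1L)])
    sp <- sectionFromStack(stack, lastIdx)
    tallies[[i]] <- castGrid(sp, targetLabel, lp, restricted = restricted,
                             seed = seeds[2L * i])
  }
  sv <- estimateSV(tallies, lp)
  vol <- volumeFromLabels(stack, targetLabel)
  pd <- if ("pore" %in% lg) poreDiameter(stack) else NA_real_
  phen <- classifyBundle(stack)
  data.frame(bundle_id = as.character(bundleId), phenotype = phen,
             sv_hat = sv,
             sum_I = sum(vapply(tallies, function(t) t@I, integer(1))),
             sum_P = sum(vapply(tallies, function(t) t@P, integer(1))),
             section_index_used = lastIdx,
             volume_bundle = vol, pore_diameter = pd,
             casts = as.integer(casts), lp = lp,
             seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
             stringsAsFactors = FALSE)
}
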