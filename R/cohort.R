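#' @include AllClasses.R phantom-shapes.R scene.R voxelize.R estimators.R
NULL

# Standard label assignment used by generated scenes.
COHORT_LABELS <- c(axon = 1L, lamina = 2L, pore = 3L, epithelium = 4L)

# Build the scene for one penetrating bundle: a thin capsule running
# parallel to (and below) the basal lamina, with a pore in the lamina above
# its midpoint. Margins in um.
penetratingScene <- function(r, L, poreD, seed, laminaThickness = 0.08,
                             gap = 0.15, epiHeight = 0.4, margin = 0.25,
                             origin = c(0, 0, 0)) {
  a <- poreD / 2; b <- 0.8 * a
  t1x <- margin + r + origin[1]
  y0 <- margin + r + origin[2]     # capsule axis height
  z0 <- max(r, b) + margin + origin[3]
  lamY0 <- y0 + r + gap
  bounds <- c(0, L + 2 * r + 2 * margin + origin[1],
              0, lamY0 + laminaThickness + epiHeight,
              0, 2 * max(r, b) + 2 * margin + origin[3])
  caps <- makeCapsule(r, L, list(rotation = diag(3),
                                 translation = c(t1x, y0, z0)))
  sceneSpec(list(caps), COHORT_LABELS[["axon"]], bounds,
            lamina = list(y0 = lamY0, thickness = laminaThickness,
                          label = COHORT_LABELS[["lamina"]]),
            pores = data.frame(cx = t1x + L / 2, cz = z0, a = a, b = b,
                               label = COHORT_LABELS[["pore"]]),
            epithelium = list(label = COHORT_LABELS[["epithelium"]]),
            seed = seed)
}

# Scene for one fusing bundle: a thin shaft ending in a swollen bulb whose
# top is tangent to the basal-lamina pore (half-voxel contact), so the
# fusing axon communicates with the epithelium through the pore.
fusingScene <- function(rShaft, L, RBulb, poreD, seed, dy = 0.01,
                        laminaThickness = 0.08, epiHeight = 0.4,
                        margin = 0.25, origin = c(0, 0, 0)) {
  a <- poreD / 2; b <- 0.8 * a
  t1x <- margin + rShaft + origin[1]
  yB <- margin + RBulb + origin[2]  # bulb centre height
  z0 <- max(RBulb, b) + margin + origin[3]
  lamY0 <- yB + RBulb - dy / 2 # bulb pokes half a voxel into the lamina
  bounds <- c(0, t1x + L + RBulb + margin,
              0, lamY0 + laminaThickness + epiHeight,
              0, 2 * max(RBulb, b) + 2 * margin + origin[3])
  tube <- makeTubeWithBulb(rShaft, L, RBulb,
                           list(rotation = diag(3),
                                translation = c(t1x, yB, z0)))
  sceneSpec(list(tube), COHORT_LABELS[["axon"]], bounds,
            lamina = list(y0 = lamY0, thickness = laminaThickness,
                          label = COHORT_LABELS[["lamina"]]),
            pores = data.frame(cx = t1x + L, cz = z0, a = a, b = b,
                               label = COHORT_LABELS[["pore"]]),
            epithelium = list(label = COHORT_LABELS[["epithelium"]]),
            seed = seed)
}

#' Generate a two-phenotype cohort of synthetic nerve-bundle scenes
#'
#' Builds \code{nPen} penetrating bundles (thin capsules) and \code{nFus}
#' fusing bundles (tube-with-bulb), each calibrated so the analytic
#' surface-to-volume ratio of the cohort's base shape equals the group
#' target (defaults 3.32 and 1.39 um^-1, the reported penetrating and
#' fusing group means). Between-bundle biological variation is modeled as a
#' mean-one lognormal factor with coefficient of variation \code{cv}
#' applied to the calibrated free radius. Both phenotypes draw their
#' basal-lamina pore diameter from one common lognormal distribution,
#' reflecting the observation that pore size does not differ between
#' groups. Bundles run parallel to the basal lamina (the grid's vertical
#' axis direction), and every geometric quantity is reproducible from
#' \code{seed}.
#'
#' @param nPen,nFus Number of penetrating / fusing bundles (>= 0).
#' @param svPen,svFus Target analytic S/V per group, um^-1.
#' @param cv Coefficient of variation of the lognormal radius factor
#'   (0 = every bundle exactly at target).
#' @param seed Integer seed; drives all draws.
#' @param lPen Capsule shaft length of penetrating bundles, um.
#' @param shaftRadius,shaftLength Fusing-bundle shaft radius and length, um.
#' @param poreMeanDiameter Mean pore diameter, um (both groups).
#' @param poreCV CV of the pore-diameter lognormal.
#' @param spacing Voxel spacing for rasterization, um.
#' @param rasterize Logical; also voxelize every scene into a
#'   \linkS4class{LabelStack} (memory-heavy for large cohorts; the
#'   measurement helpers voxelize scene-by-scene instead).
#' @return List with \code{scenes} (list of \linkS4class{SceneSpec}),
#'   \code{roles} (phantom role per scene), \code{truth} (data.frame of
#'   analytic ground truth per bundle), \code{spacing}, and \code{stacks}
#'   (list of \linkS4class{LabelStack} or NULL).
#' @examples
#' coh <- generateCohort(nPen = 2, nFus = 1, cv = 0, seed = 7)
#' coh$truth$sv_true
#' @export
generateCohort <- function(nPen, nFus, svPen = 3.32, svFus = 1.39, cv = 0,
                           seed = NULL, lPen = 10, shaftRadius = 0.3,
                           shaftLength = 5, poreMeanDiameter = 2,
                           poreCV = 0.15, spacing = c(0.01, 0.01, 0.1),
                           rasterize = FALSE) {
  if (nPen < 0 || nFus < 0 || nPen + nFus < 1)
    stop("invalid parameter: need at least one bundle")
  if (cv < 0) stop("invalid parameter: cv must be >= 0")
  n <- nPen + nFus
  seeds <- childSeeds(seed, n)
  rPen0 <- if (nPen) calibrateRadiusForSV(svPen, "capsule", list(L = lPen))
  rFus0 <- if (nFus) calibrateRadiusForSV(svFus, "tube_with_bulb",
                                          list(rShaft = shaftRadius,
                                               L = shaftLength))
  sig <- sqrt(log(1 + cv^2))
  sigP <- sqrt(log(1 + poreCV^2))
  scenes <- vector("list", n)
  roles <- character(n)
  truth <- vector("list", n)
  phen <- c(rep("penetrating", nPen), rep("fusing_mixed", nFus))
  for (i in seq_len(n)) {
    draws <- withSeed(seeds[i], list(
      f = if (cv > 0) stats::rlnorm(1, -sig^2 / 2, sig) else 1,
      D = stats::rlnorm(1, log(poreMeanDiameter) - sigP^2 / 2, sigP),
      # uniform random sub-lattice offset: a uniform random sampling
      # start relative to the voxel/section lattice, which makes pooled
      # section sampling an unbiased (Cavalieri-type) design
      jit = stats::runif(3) * spacing))
    D <- max(draws$D, 0.6)
    if (phen[i] == "penetrating") {
      r <- rPen0 * draws$f
      scenes[[i]] <- penetratingScene(r, lPen, D, seeds[i],
                                      origin = draws$jit)
      ph <- scenes[[i]]@phantoms[[1]]
      roles[i] <- "axon_penetrating"
      radius <- r
    } else {
      R <- rFus0 * draws$f
      scenes[[i]] <- fusingScene(shaftRadius, shaftLength, R, D, seeds[i],
                                 dy = spacing[2], origin = draws$jit)
      ph <- scenes[[i]]@phantoms[[1]]
      roles[i] <- "axon_fusing"
      radius <- R
    }
    truth[[i]] <- data.frame(
      bundle_id = sprintf("%s_%02d", substr(phen[i], 1, 3), i),
      phenotype = phen[i], shape_kind = ph@shapeKind, radius = radius,
      sv_true = svRatio(ph), surface_true = analyticSurface(ph),
      volume_true = analyticVolume(ph), pore_diameter_true = D,
      seed = seeds[i], stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  stacks <- NULL
  if (rasterize)
    stacks <- lapply(seq_len(n), function(i)
      voxelize(scenes[[i]], spacing, roles = roles[i]))
  list(scenes = scenes, roles = roles, truth = truth, spacing = spacing,
       stacks = stacks)
}

#' Measure a generated cohort with the cycloid-grid protocol
#'
#' Voxelizes each scene (one at a time, to bound memory), runs
#' \code{\link{bundleMorphometry}} on the resulting stack, and binds the
#' measurements to the analytic ground truth.
#'
#' @param cohort Output of \code{\link{generateCohort}}.
#' @param lp Test-line length per point, um.
#' @param casts Independent (section, phase) casts per bundle.
#' @param restricted Logical; apply the restriction line during counting.
#' @param seed Seed driving section selection and grid phases.
#' @return data.frame: ground-truth columns plus \code{sv_hat},
#'   \code{volume_bundle}, \code{pore_diameter}, \code{phenotype_called}.
#' @export
measureCohort <- function(cohort, lp = 1, casts = 1L, restricted = FALSE,
                          seed = NULL) {
  n <- length(cohort$scenes)
  seeds <- childSeeds(seed, n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    stack <- if (!is.null(cohort$stacks)) cohort$stacks[[i]]
             else voxelize(cohort$scenes[[i]], cohort$spacing,
                           roles = cohort$roles[i])
    m <- bundleMorphometry(stack, targetLabel = cohort$roles[i], lp = lp,
                           casts = casts, restricted = restricted,
                           seed = seeds[i],
                           bundleId = cohort$truth$bundle_id[i])
    rows[[i]] <- cbind(cohort$truth[i, setdiff(names(cohort$truth),
                                               c("bundle_id", "phenotype"))],
                       bundle_id = m$bundle_id,
                       phenotype = cohort$truth$phenotype[i],
                       phenotype_called = m$phenotype,
                       sv_hat = m$sv_hat, sum_I = m$sum_I, sum_P = m$sum_P,
                       lp = m$lp,
                       volume_bundle = m$volume_bundle,
                       pore_diameter = m$pore_diameter,
                       section_index_used = m$section_index_used,
                       row.names = NULL)
  }
  do.call(rbind, rows)
}

#' Group-level surface-to-volume estimate by pooled tallies
#'
#' The design-based group estimator: intersections and points are summed
#' over every cast of every bundle in a group before dividing,
#' \eqn{\hat S_V = 2 \sum I / ((l/p) \sum P)}. Pooling at the group level
#' extends the estimator's own ratio-of-sums aggregation rule across
#' bundles; unlike a mean of per-bundle ratios it is not inflated by casts
#' that land on thin near-tangential sections (small-P denominators), which
#' is why it is the group summary the recovery checks use. Per-bundle
#' \code{sv_hat} values remain the inputs to the group t test.
#'
#' @param results data.frame from \code{\link{measureCohort}} (needs
#'   \code{sum_I}, \code{sum_P}, \code{lp} and \code{phenotype} columns).
#' @param by Grouping column (default \code{"phenotype"}).
#' @return data.frame with one row per group: \code{group}, \code{n},
#'   \code{sum_I}, \code{sum_P}, \code{sv_pooled}, \code{sv_mean} (mean of
#'   per-bundle estimates, for comparison).
#' @export
groupEstimateSV <- function(results, by = "phenotype") {
  lp <- unique(results$lp)
  if (length(lp) != 1L) stop("mixed lp values; pool per lp")
  grp <- split(results, results[[by]])
  out <- lapply(names(grp), function(g) {
    r <- grp[[g]]
    data.frame(group = g, n = nrow(r), sum_I = sum(r$sum_I),
               sum_P = sum(r$sum_P),
               sv_pooled = 2 * sum(r$sum_I) / (lp * sum(r$sum_P)),
               sv_mean = mean(r$sv_hat), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
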