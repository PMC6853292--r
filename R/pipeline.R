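#' @include cohort.R stats.R io.R
NULL

configHash <- function(config) {
  s <- paste(vapply(config[order(names(config))], function(v)
    paste(format(v, digits = 15), collapse = ","), character(1)),
    collapse = ";")
  # small stable rolling hash; provenance only, not cryptographic
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Run the full simulate - count - estimate - compare pipeline
#'
#' Generates a two-phenotype cohort, measures every bundle with the
#' cycloid-grid protocol, compares the groups (pooled t test on S/V,
#' Mann-Whitney on pore diameter) and writes all outputs to \code{outDir}:
#' \code{morphometry.csv} (one row per bundle), \code{comparisons.json},
#' \code{config.json}, a \code{MANIFEST} marking stage completeness, and
#' optionally the voxelized stacks. Every output embeds the config hash;
#' two runs with the same config and seed produce byte-identical CSVs.
#'
#' @param config Named list (see \code{\link{readRunConfig}}) or a path to
#'   a YAML/JSON config.
#' @param outDir Output directory (created if needed).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with \code{results} (data.frame),
#'   \code{comparisons} (list of \linkS4class{GroupComparison} or NULL),
#'   \code{summary} (list), \code{configHash}.
#' @export
runPipeline <- function(config = readRunConfig(), outDir = "cycloidSV-run",
                        quiet = FALSE) {
  if (is.character(config)) config <- readRunConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  hash <- configHash(config)
  say <- function(...) if (!quiet) message("[cycloidSV] ", sprintf(...))
  manifest <- c()
  writeManifest <- function() writeLines(manifest, file.path(outDir, "MANIFEST"))
  jsonlite::write_json(c(config, list(config_hash = hash)),
                       file.path(outDir, "config.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  manifest <- c(manifest, "config: complete"); writeManifest()

  say("simulate: generating %d penetrating + %d fusing bundles (seed %s)",
      config$n_pen, config$n_fus, config$seed)
  cohort <- generateCohort(config$n_pen, config$n_fus,
                           svPen = config$sv_pen, svFus = config$sv_fus,
                           cv = config$cv, seed = config$seed,
                           lPen = config$l_pen,
                           shaftRadius = config$shaft_radius,
                           shaftLength = config$shaft_length,
                           poreMeanDiameter = config$pore_mean_diameter,
                           poreCV = config$pore_cv,
                           spacing = config$spacing)
  manifest <- c(manifest, "simulate: complete"); writeManifest()

  say("count/estimate: lp = %g um, %d cast(s) per bundle%s", config$lp,
      config$casts, if (config$restricted) ", restricted" else "")
  results <- measureCohort(cohort, lp = config$lp, casts = config$casts,
                           restricted = config$restricted,
                           seed = config$seed + 1L)
  results$config_hash <- hash
  utils::write.csv(results, file.path(outDir, "morphometry.csv"),
                   row.names = FALSE)
  manifest <- c(manifest, "estimate: complete"); writeManifest()

  if (config$write_stacks) {
    stackDir <- file.path(outDir, "stacks")
    dir.create(stackDir, showWarnings = FALSE)
    for (i in seq_along(cohort$scenes)) {
      st <- voxelize(cohort$scenes[[i]], cohort$spacing,
                     roles = cohort$roles[i])
      writeStack(st, file.path(stackDir,
                               paste0(cohort$truth$bundle_id[i], ".tif")))
    }
    manifest <- c(manifest, "stacks: complete"); writeManifest()
  }

  comparisons <- NULL
  summaryList <- list(config_hash = hash, seed = config$seed)
  pen <- results$sv_hat[results$phenotype == "penetrating"]
  fus <- results$sv_hat[results$phenotype == "fusing_mixed"]
  if (length(pen) >= 2L && length(fus) >= 2L) {
    say("compare: pooled t on S/V, Mann-Whitney on pore diameter")
    cmpSV <- compareSV(pen, fus, alpha = config$alpha)
    penP <- results$pore_diameter[results$phenotype == "penetrating"]
    fusP <- results$pore_diameter[results$phenotype == "fusing_mixed"]
    cmpPore <- comparePores(penP, fusP, alpha = config$alpha)
    comparisons <- list(sv = cmpSV, pore = cmpPore)
    summaryList <- c(summaryList, list(
      sv = list(mean_penetrating = cmpSV@means[1],
                mean_fusing = cmpSV@means[2],
                sem_penetrating = cmpSV@sems[1], sem_fusing = cmpSV@sems[2],
                t = cmpSV@statValue, df = cmpSV@details$df,
                p = cmpSV@pValue),
      pore = list(mean_penetrating = cmpPore@means[1],
                  mean_fusing = cmpPore@means[2],
                  U = cmpPore@statValue, p = cmpPore@pValue,
                  exact = cmpPore@details$exact),
      fusion_frequency_pct = fusionFrequency(results$phenotype_called)))
    manifest <- c(manifest, "compare: complete")
  } else {
    say("compare: skipped (need n >= 2 per group; got %d penetrating, %d fusing)",
        length(pen), length(fus))
    manifest <- c(manifest, "compare: skipped (degenerate cohort)")
  }
  jsonlite::write_json(summaryList, file.path(outDir, "comparisons.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  writeManifest()
  say("done: outputs in %s", outDir)
  invisible(list(results = results, comparisons = comparisons,
                 summary = summaryList, configHash = hash))
}

#' Plot a grid cast over a section (audit overlay)
#'
#' Draws the section labels, the cycloid arcs, the test points (filled when
#' they score P) and the counted boundary crossings, mirroring the manual
#' counting overlay used with printed cycloid grid cards.
#'
#' @param section A \linkS4class{SectionPlane}.
#' @param grid A \linkS4class{CycloidGrid}.
#' @param targetLabel Label(s) or role(s) of the counted structure.
#' @param restricted Draw and apply the restriction line.
#' @return Invisibly, the \linkS4class{CountTally} of the displayed cast.
#' @export
plotGridCast <- function(section, grid, targetLabel, restricted = FALSE) {
  img <- section@image
  dx <- section@spacing[[1]]; dy <- section@spacing[[2]]
  xs <- (seq_len(nrow(img)) - 0.5) * dx
  ys <- (seq_len(ncol(img)) - 0.5) * dy
  graphics::image(xs, ys, img, col = grDevices::hcl.colors(
    max(img) + 1L, "Grays", rev = TRUE), useRaster = TRUE, asp = 1,
    xlab = "x (um)", ylab = "y (um)")
  for (a in grid@arcs) graphics::lines(a, col = "orange", lwd = 0.8)
  tally <- countGrid(grid, section, targetLabel, restricted = restricted)
  labs <- if (is.character(targetLabel))
    resolveLabels(targetLabel, section@legend) else as.integer(targetLabel)
  mask <- matrix(img %in% labs, nrow(img), ncol(img))
  pin <- bilinearAt(mask, dx, dy, grid@points[, 1], grid@points[, 2]) > 0.5
  graphics::points(grid@points, pch = ifelse(pin, 16, 1),
                   col = ifelse(pin, "darkgreen", "grey40"), cex = 0.8)
  if (restricted) {
    rl <- restrictionLine(section)
    graphics::segments(rl$a[1], rl$a[2], rl$b[1], rl$b[2],
                       col = "red", lwd = 2)
  }
  graphics::title(sub = sprintf("I = %d, P = %d", tally@I, tally@P))
  invisible(tally)
}
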