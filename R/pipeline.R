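# End-to-end chronosequence pipeline: preprocess -> segment -> architecture
# -> porosity -> DIC/strain, all days referenced to Day 0.

#' SpecimenRecord: one specimen's chronosequence and metadata
#'
#' @slot specimenId character id.
#' @slot dayPaths named character vector of grey-volume paths; names are
#'   day indices ("0", "1", ...), Day 0 required.
#' @slot sandMass_g dry sand mass poured into the cell.
#' @slot grainDensity_g_cm3 grain density (default 2.65).
#' @slot waterVolume_ml poured water volume.
#' @slot d50_um median grain diameter.
#' @slot seedPosition numeric (x, y, z) voxel position of the seed.
#' @slot surfaceZ sand surface slice (voxel index).
#' @export
setClass("SpecimenRecord", representation(
  specimenId = "character", dayPaths = "character", sandMass_g = "numeric",
  grainDensity_g_cm3 = "numeric", waterVolume_ml = "numeric",
  d50_um = "numeric", seedPosition = "numeric", surfaceZ = "integer"))

setValidity("SpecimenRecord", function(object) {
  dn <- names(object@dayPaths)
  if (is.null(dn) || anyDuplicated(dn)) return("day indices must be unique names")
  if (!"0" %in% dn) return("Day 0 is required (calibration and DIC reference)")
  if (any(is.na(suppressWarnings(as.integer(dn))))) return("day names must be integers")
  TRUE
})

#' @rdname SpecimenRecord-class
#' @param specimenId,dayPaths,sandMass_g,grainDensity_g_cm3,waterVolume_ml
#'   see slots.
#' @param d50_um,seedPosition,surfaceZ see slots.
#' @export
specimenRecord <- function(specimenId, dayPaths, sandMass_g,
                           grainDensity_g_cm3 = 2.65, waterVolume_ml = 0,
                           d50_um = 338, seedPosition, surfaceZ = 0L) {
  new("SpecimenRecord", specimenId = specimenId, dayPaths = dayPaths,
      sandMass_g = sandMass_g, grainDensity_g_cm3 = grainDensity_g_cm3,
      waterVolume_ml = waterVolume_ml, d50_um = d50_um,
      seedPosition = as.numeric(seedPosition), surfaceZ = as.integer(surfaceZ))
}

#' Default pipeline configuration
#'
#' Defaults follow the study conditions for fine sand: variance radius 4
#' (2 for coarse), factor-2 downscale, 1.3 mm DIC windows, 1\% engaged
#' threshold, shells of D50/2 up to 16 mm.
#'
#' @param rv variance-filter half-width (voxels).
#' @param downscaleFactor integer binning factor.
#' @param windowSide_mm DIC window side.
#' @param engagedThreshold deviatoric strain threshold.
#' @param maxShellDistance_mm outermost porosity shell.
#' @param nPeaks histogram peaks used for the contrast stretch.
#' @param bilateralSigmaSpatial spatial sd (voxels); NULL skips denoising.
#' @param background TRUE if air above the sand surface is in the field of
#'   view.
#' @return Named list of parameters for \code{\link{runPipeline}}.
#' @export
pipelineConfig <- function(rv = 4L, downscaleFactor = 2L, windowSide_mm = 1.3,
                           engagedThreshold = 0.01, maxShellDistance_mm = 16,
                           nPeaks = 2L, bilateralSigmaSpatial = 2,
                           background = TRUE) {
  list(rv = rv, downscaleFactor = downscaleFactor,
       windowSide_mm = windowSide_mm, engagedThreshold = engagedThreshold,
       maxShellDistance_mm = maxShellDistance_mm, nPeaks = nPeaks,
       bilateralSigmaSpatial = bilateralSigmaSpatial, background = background)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the full analysis chain on a chronosequence
#'
#' For every day: contrast stretch onto the Day-0 peaks, downscale,
#' optional bilateral denoising, four-phase segmentation (thresholds
#' calibrated once on Day 0 and reused), root architecture, porosity
#' profiles, and — for days after Day 0 — DIC against Day 0 with strain
#' invariants. Results and a provenance manifest are written to
#' \code{outDir}; a failing stage halts the pipeline with a
#' stage-attributed error, keeping the files already written.
#'
#' @param record a \linkS4class{SpecimenRecord}.
#' @param config from \code{\link{pipelineConfig}}.
#' @param outDir output directory (created if needed).
#' @return Invisibly, a list of per-day results plus the manifest.
#' @export
runPipeline <- function(record, config = pipelineConfig(), outDir) {
  stopifnot(is(record, "SpecimenRecord"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  days <- sort(as.integer(names(record@dayPaths)))
  if (days[1] != 0L) stop("[stage load] Day 0 missing")
  results <- list()
  ref <- NULL
  calib <- list()
  day0 <- NULL
  for (day in days) {
    tag <- as.character(day)
    vol <- .stage("load", readGreyVolume(record@dayPaths[[tag]]))
    peaks <- .stage("preprocess", findHistogramPeaks(vol, config$nPeaks,
                                                     reference = day == 0L))
    if (day == 0L) ref <- peaks
    vol <- .stage("preprocess", {
      v <- contrastStretch(vol, peaks, ref)
      v <- downscale(v, config$downscaleFactor)
      if (!is.null(config$bilateralSigmaSpatial))
        v <- denoiseBilateral(v, config$bilateralSigmaSpatial, peaks = ref)
      v
    })
    f <- config$downscaleFactor
    surfZ <- record@surfaceZ %/% f
    seedPos <- record@seedPosition / f
    seg <- .stage("segment", {
      if (day == 0L) {
        sandTarget <- sandVolumeFromMass(record@sandMass_g,
                                         record@grainDensity_g_cm3)
        calib$sand <- calibrateThresholdByVolume(vol, sandTarget,
                                                  side = "above")$threshold
      }
      sand <- segmentSand(vol, calib$sand)
      rootSeg <- segmentRoot(vol, varianceSegParams(config$rv), sand,
                             background = config$background)
      wa <- if (day == 0L) {
        w <- segmentWaterAir(vol, sand, rootSeg$mask,
                             waterVolume_mm3 = record@waterVolume_ml * 1000)
        calib$water <- w$threshold
        w
      } else segmentWaterAir(vol, sand, rootSeg$mask,
                             threshold = calib$water)
      phases <- assembleFourPhase(sand, rootSeg$mask, wa$water, wa$air,
                                  vol@voxelSize)
      list(phases = phases, root = rootSeg)
    })
    arch <- .stage("architecture", {
      g <- skeletonGraph(seg$root$mask, vol@voxelSize)
      g <- labelHierarchy(g, seedPos)
      d <- dim(vol@data)
      soil_mm3 <- prod(d[1:2]) * (d[3] - surfZ) * (vol@voxelSize * 1e-3)^3
      prior <- vapply(results, function(r) r$metrics$primary_length_mm, 0)
      list(graph = g, metrics = architectureMetrics(g, soil_mm3, surfZ, prior))
    })
    poro <- .stage("porosity", {
      vp <- verticalPorosityProfile(seg$phases, surfaceZ = surfZ,
                                    excludeAboveZ = round(seedPos[3]),
                                    dayIndex = day)
      sp <- shellPorosityProfile(seg$phases, seg$root$mask,
                                 shellSpec(record@d50_um / 2,
                                           config$maxShellDistance_mm),
                                 surfaceZ = surfZ, dayIndex = day)
      list(vertical = vp, shell = sp)
    })
    kin <- if (day > 0L) .stage("kinematics", {
      fld <- localDIC(day0$volume, vol, config$windowSide_mm)
      if (sum(fld@status == "converged") >= 5L) {
        st <- strainGeers(fld)
        eng <- engagedVolumeMask(st, config$engagedThreshold)
        rd <- rootDistanceByWindow(seg$root$mask, vol@voxelSize,
                                   config$windowSide_mm, st@points)
        clouds <- strainClouds(st, rd,
                               engagedThreshold = config$engagedThreshold)
        list(field = fld, strain = st, engaged = eng, clouds = clouds)
      } else list(field = fld, strain = NULL, engaged = NULL, clouds = NULL)
    }) else NULL
    res <- list(day = day, volume = vol, phases = seg$phases,
                components = seg$root$components, graph = arch$graph,
                metrics = arch$metrics, porosity = poro, kinematics = kin)
    if (day == 0L) day0 <- res
    results[[tag]] <- res
  }
  manifest <- list(
    specimen = record@specimenId,
    inputs = as.list(record@dayPaths),
    input_md5 = as.list(tools::md5sum(unname(record@dayPaths))),
    config = config,
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("rhizoCT")),
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeReport(results, outDir)
  invisible(list(days = results, manifest = manifest))
}

#' Write summary tables and figures for pipeline results
#'
#' Emits per-day architecture metrics (CSV + JSON), porosity profile
#' tables, displacement/strain point tables, a porosity-profile figure and
#' an eps_v-versus-eps_q scatter with the binned centroid line. Days
#' without a strain field simply omit the scatter (noted in the metrics
#' JSON).
#'
#' @param results per-day result list (as built by \code{\link{runPipeline}}).
#' @param outDir output directory.
#' @return Invisibly, the vector of files written.
#' @export
writeReport <- function(results, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  met <- do.call(rbind, lapply(results, function(r)
    data.frame(day = r$day, rld_m_per_m3 = r$metrics$rld_m_per_m3,
               tip_depth_mm = r$metrics$tip_depth_mm,
               n_laterals = r$metrics$n_laterals,
               primary_length_mm = r$metrics$primary_length_mm,
               total_length_mm = r$metrics$total_length_mm,
               has_strain = !is.null(r$kinematics$strain))))
  p <- file.path(outDir, "architecture_metrics.csv")
  write.csv(met, p, row.names = FALSE)
  files <- c(files, p)
  jsonlite::write_json(met, file.path(outDir, "architecture_metrics.json"),
                       digits = NA)
  for (r in results) {
    tag <- sprintf("day%d", r$day)
    p <- file.path(outDir, paste0("porosity_shell_", tag, ".csv"))
    write.csv(r$porosity$shell@table, p, row.names = FALSE)
    files <- c(files, p)
    p <- file.path(outDir, paste0("porosity_vertical_", tag, ".csv"))
    write.csv(r$porosity$vertical@table, p, row.names = FALSE)
    files <- c(files, p)
    grDevices::png(file.path(outDir, paste0("porosity_profile_", tag, ".png")),
                   width = 640, height = 480)
    tb <- r$porosity$shell@table
    graphics::plot(tb$mid_mm, tb$porosity, type = "b", pch = 16,
                   xlab = "distance from root surface [mm]",
                   ylab = "porosity [-]",
                   main = sprintf("Shell porosity, day %d", r$day))
    grDevices::dev.off()
    if (!is.null(r$kinematics$strain)) {
      st <- r$kinematics$strain
      ok <- st@valid
      p <- file.path(outDir, paste0("strain_", tag, ".csv"))
      write.csv(data.frame(x_mm = st@points[ok, 1], y_mm = st@points[ok, 2],
                           z_mm = st@points[ok, 3], eps_v = st@epsV[ok],
                           eps_q = st@epsQ[ok]), p, row.names = FALSE)
      files <- c(files, p)
      grDevices::png(file.path(outDir, paste0("strain_cloud_", tag, ".png")),
                     width = 640, height = 480)
      graphics::plot(st@epsQ[ok], st@epsV[ok], pch = ".", col = "grey40",
                     xlab = "deviatoric strain eps_q [-]",
                     ylab = "volumetric strain eps_v [-]",
                     main = sprintf("Strain invariants, day %d", r$day))
      cl <- r$kinematics$clouds
      if (!is.null(cl) && nrow(cl$centroids)) {
        cc <- cl$centroids[order(cl$centroids$q_mid), ]
        for (z in unique(cc$zone))
          graphics::lines(cc$q_mid[cc$zone == z], cc$mean_eps_v[cc$zone == z],
                          col = if (z == "near") "blue" else "red", lwd = 2)
      }
      graphics::abline(h = 0, lty = 2)
      grDevices::dev.off()
    }
  }
  invisible(files)
}
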