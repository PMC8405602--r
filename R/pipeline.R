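## End-to-end orchestration: ingest -> clean -> partition -> dBBMM ->
## isopleths -> zones -> occupancy -> cohort statistics.

#' Pipeline run configuration
#'
#' A flat key-value configuration for [runPipeline()]. `input`/`meta` may
#' be `NULL`, in which case a synthetic study is generated from
#' `simulation` (a [simConfig()]) -- the bundled way to exercise the full
#' pipeline.
#'
#' @param input path to a fix CSV (see [readFixes()]), or `NULL`.
#' @param meta path to a bird metadata CSV, or `NULL`.
#' @param simulation a [simConfig()] used when `input` is `NULL`.
#' @param crs working projection ([laeaCRS()]).
#' @param region [StudyRegion-class] clip polygon; `NULL` to skip
#'   clipping; defaults to [balkanRegion()] for file input.
#' @param window,utcOffset diurnal analysis window (local clock hours)
#'   and fixed UTC offset.
#' @param maxSpeed outlier speed threshold, km/h.
#' @param acclimatisationDays post-release exclusion period, days.
#' @param minTrackingDays minimum tracked days per bird.
#' @param minSeasonDays season-completeness threshold, days.
#' @param w,margin,locError dBBMM estimation parameters.
#' @param cellSize raster cell size, metres.
#' @param maxGap maximum bridgeable gap, seconds.
#' @param levels isopleth levels, descending; the first is the home
#'   range used for zone inference, the last the core area.
#' @param zoneThreshold movement-day fraction for zone linkage.
#' @param zoneMinPatchKm2 minimum candidate-patch area (km^2), see
#'   [spatialComponents()]; the pipeline additionally keeps only patches
#'   containing core-isopleth cells.
#' @param occupancyThreshold inside-fraction for day classification.
#' @param seasonal also compute per-bird-season ranges and their
#'   summary/ANOVA (slower).
#' @param outDir output directory, or `NULL` to skip writing files.
#' @param seed RNG seed (used by the simulation input).
#' @return list with class `"pipelineConfig"`.
#' @export
pipelineConfig <- function(input = NULL, meta = NULL,
                           simulation = simConfig(),
                           crs = laeaCRS(), region = NULL,
                           window = c(6, 18), utcOffset = 2,
                           maxSpeed = 120, acclimatisationDays = 50,
                           minTrackingDays = 50, minSeasonDays = 45,
                           w = 31, margin = 11, locError = 20,
                           cellSize = 500, maxGap = 12 * 3600,
                           levels = c(0.95, 0.5), zoneThreshold = 0.05,
                           zoneMinPatchKm2 = 0,
                           occupancyThreshold = 0.95, seasonal = FALSE,
                           outDir = NULL, seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "pipelineConfig"
  cfg
}

#' Validate a pipeline configuration
#'
#' @param cfg a [pipelineConfig()].
#' @return character vector of problems; empty iff the config is usable.
#' @export
validateConfig <- function(cfg) {
  p <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) p <<- c(p, msg)
  chk(inherits(cfg, "pipelineConfig"), "not a pipelineConfig")
  if (!is.null(cfg$input)) chk(file.exists(cfg$input),
                               paste("input file not found:", cfg$input))
  if (!is.null(cfg$meta)) chk(file.exists(cfg$meta),
                              paste("metadata file not found:", cfg$meta))
  chk(is.numeric(cfg$window) && length(cfg$window) == 2 &&
        cfg$window[1] < cfg$window[2],
      "day window start must be before end")
  chk(cfg$maxSpeed > 0, "maxSpeed must be positive")
  chk(all(cfg$levels > 0 & cfg$levels <= 1),
      "isopleth levels must be in (0, 1]")
  chk(!is.unsorted(rev(cfg$levels)), "levels must be sorted descending")
  chk(cfg$zoneThreshold > 0 && cfg$zoneThreshold < 1,
      "zoneThreshold must be in (0, 1)")
  chk(cfg$occupancyThreshold > 0 && cfg$occupancyThreshold < 1,
      "occupancyThreshold must be in (0, 1)")
  chk(cfg$cellSize > 0, "cellSize must be positive")
  chk(cfg$w %% 2 == 1 && cfg$w >= 5, "w must be an odd integer >= 5")
  chk(cfg$margin >= 3 && 2 * cfg$margin < cfg$w,
      "margin must be >= 3 with 2*margin < w")
  p
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage [", name, "]: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes ingest, cleaning (deduplication, speed filter,
#' acclimatisation exclusion, region clip), diurnal partitioning and the
#' minimum-tracking filter, per-bird dBBMM utilization distributions and
#' isopleths, zone inference, daily occupancy classification, roost
#' detection and cohort statistics, optionally writing all tabular and
#' vector outputs beneath `cfg$outDir`.
#'
#' @param cfg a [pipelineConfig()].
#' @param quiet suppress per-stage progress messages.
#' @return list with elements `tracks` (cleaned, projected), `ranges`
#'   (per-bird isopleths per level), `totalRange` / `totalCore` (merged
#'   across birds), `zones`, `zoneTable`, `classifications`, `occupancy`,
#'   `roosts`, `stats` (per-group summary + ANOVA when computable),
#'   `seasonal` (when enabled) and `report` (per-stage counts and
#'   parameters).
#' @export
runPipeline <- function(cfg = pipelineConfig(), quiet = FALSE) {
  probs <- validateConfig(cfg)
  if (length(probs))
    stop("invalid configuration:\n  - ", paste(probs, collapse = "\n  - "))
  say <- function(...) if (!quiet) message("[", format(Sys.time(), "%H:%M:%S"),
                                           "] ", ...)
  report <- list(seed = cfg$seed,
                 parameters = cfg[c("window", "utcOffset", "maxSpeed",
                                    "acclimatisationDays", "minTrackingDays",
                                    "minSeasonDays", "w", "margin",
                                    "locError", "cellSize", "maxGap",
                                    "levels", "zoneThreshold",
                                    "occupancyThreshold")])
  ## 1. ingest ------------------------------------------------------------
  tracks <- .stage("ingest", {
    if (!is.null(cfg$input)) {
      fixes <- readFixes(cfg$input)
      meta <- if (!is.null(cfg$meta)) readBirdMeta(cfg$meta) else NULL
      makeTracks(fixes, meta)
    } else {
      sim <- simulateTracks(cfg$simulation)
      report$simulationTruth <- sim$truth
      sim$tracks
    }
  })
  report$nBirdsIn <- length(tracks)
  report$nFixesIn <- sum(vapply(tracks, nFixes, integer(1)))
  say("ingest: ", report$nBirdsIn, " birds, ", report$nFixesIn, " fixes")
  ## 2. clean -------------------------------------------------------------
  region <- cfg$region
  if (is.null(region) && !is.null(cfg$input)) region <- balkanRegion()
  tracks <- .stage("clean", lapply(tracks, function(tr) {
    tr <- deduplicate(tr)
    tr <- acclimatisationFilter(tr, cfg$acclimatisationDays)
    tr <- projectTrack(tr, cfg$crs)
    tr <- removeOutliers(tr, cfg$maxSpeed)
    if (!is.null(region)) tr <- clipToRegion(tr, region)
    tr
  }))
  report$nFixesClean <- sum(vapply(tracks, nFixes, integer(1)))
  say("clean: ", report$nFixesClean, " fixes retained")
  ## 3. tracking filter ---------------------------------------------------
  keep <- vapply(tracks, minTrackingFilter, logical(1),
                 minDays = cfg$minTrackingDays, window = cfg$window,
                 utcOffset = cfg$utcOffset)
  report$excludedBirds <- names(tracks)[!keep]
  tracks <- tracks[keep]
  if (!length(tracks))
    stop("pipeline stage [tracking-filter]: no bird passes the ",
         cfg$minTrackingDays, "-day filter")
  say("tracking filter: ", length(tracks), " birds retained")
  ## 4. dBBMM + isopleths -------------------------------------------------
  diurnalTracks <- lapply(tracks, function(tr) {
    d <- splitDayNight(tr, cfg$window, cfg$utcOffset)$diurnal
    tr@fixes <- d[, c("timestamp", "lon", "lat", "x", "y")]
    tr
  })
  uds <- .stage("dbbmm", lapply(diurnalTracks, function(tr) {
    mvs <- if (nFixes(tr) >= cfg$w)
      estimateMotionVariance(tr, cfg$w, cfg$margin, cfg$locError)
    else estimateMotionVariance(tr, cfg$w, cfg$margin, cfg$locError,
                                static = TRUE)
    computeUD(tr, mvs, cellSize = cfg$cellSize, maxGap = cfg$maxGap)
  }))
  ranges <- .stage("isopleths", lapply(cfg$levels, function(lv)
    lapply(names(uds), function(b)
      isopleth(uds[[b]], lv, birdId = b))))
  names(ranges) <- paste0("level", round(cfg$levels * 100))
  totalRange <- unionRanges(ranges[[1]])
  totalCore <- unionRanges(ranges[[length(ranges)]])
  say("dBBMM: total ", round(areaKm2(totalRange), 1), " km^2 at level ",
      cfg$levels[1])
  ## 5. zones -------------------------------------------------------------
  zones <- .stage("zones", buildZones(ranges[[1]], diurnalTracks,
                                      cfg$zoneThreshold,
                                      cores = ranges[[length(ranges)]],
                                      minPatchKm2 = cfg$zoneMinPatchKm2,
                                      window = cfg$window,
                                      utcOffset = cfg$utcOffset))
  say("zones: ", length(zones@zoneIds), " zone(s)")
  ## 6. occupancy + roosts ------------------------------------------------
  classifications <- .stage("occupancy",
                            classifyDays(tracks, zones,
                                         cfg$occupancyThreshold,
                                         cfg$window, cfg$utcOffset))
  occupancy <- occupancySummary(classifications)
  roosts <- .stage("roosts", detectRoosts(tracks, window = cfg$window,
                                          utcOffset = cfg$utcOffset))
  ## 7. cohort stats ------------------------------------------------------
  hr <- vapply(ranges[[1]], areaKm2, numeric(1))
  core <- vapply(ranges[[length(ranges)]], areaKm2, numeric(1))
  grp <- vapply(tracks, function(tr) tr@captureGroup, character(1))
  stats <- list(perBird = data.frame(bird_id = names(uds),
                                     capture_group = unname(grp),
                                     homerange_km2 = unname(hr),
                                     core_km2 = unname(core)),
                summary = rangeStats(hr, grp))
  if (length(unique(grp[!is.na(grp)])) >= 2 && length(hr) > 2)
    stats$anova <- tryCatch(rangeAnova(hr, grp), error = function(e) NULL)
  ## 8. seasonal (optional) -----------------------------------------------
  seasonal <- NULL
  if (isTRUE(cfg$seasonal))
    seasonal <- .stage("seasonal",
                       .seasonalRanges(diurnalTracks, cfg))
  res <- list(tracks = tracks, uds = uds, ranges = ranges,
              totalRange = totalRange, totalCore = totalCore,
              zones = zones,
              zoneTable = zoneReport(zones, diurnalTracks,
                                     levels = rev(cfg$levels),
                                     cellSize = cfg$cellSize,
                                     window = cfg$window,
                                     utcOffset = cfg$utcOffset),
              classifications = classifications, occupancy = occupancy,
              roosts = roosts, stats = stats, seasonal = seasonal,
              report = report)
  if (!is.null(cfg$outDir)) .writeOutputs(res, cfg)
  res
}

.seasonalRanges <- function(diurnalTracks, cfg) {
  rows <- NULL
  for (tr in diurnalTracks) {
    cov <- seasonCoverage(tr, window = cfg$window,
                          utcOffset = cfg$utcOffset,
                          minDays = cfg$minSeasonDays)
    for (i in which(cov$include)) {
      d <- splitDayNight(tr, cfg$window, cfg$utcOffset)$diurnal
      sel <- d$local_date >= cov$start[i] & d$local_date <= cov$end[i]
      sub <- d[sel, , drop = FALSE]
      if (nrow(sub) < 2) next
      trs <- tr
      trs@fixes <- sub[, c("timestamp", "lon", "lat", "x", "y")]
      mvs <- if (nFixes(trs) >= cfg$w)
        estimateMotionVariance(trs, cfg$w, cfg$margin, cfg$locError)
      else estimateMotionVariance(trs, cfg$w, cfg$margin, cfg$locError,
                                  static = TRUE)
      ud <- computeUD(trs, mvs, cellSize = cfg$cellSize,
                      maxGap = cfg$maxGap)
      rows <- rbind(rows, data.frame(
        bird_id = tr@birdId, season = cov$season[i],
        season_year = cov$season_year[i],
        days_with_data = cov$days_with_data[i],
        core50_km2 = areaKm2(isopleth(ud, min(cfg$levels))),
        homerange95_km2 = areaKm2(isopleth(ud, max(cfg$levels)))))
    }
  }
  if (is.null(rows)) return(NULL)
  out <- list(perBirdSeason = rows,
              summary = seasonalRangeStats(rows))
  if (length(unique(rows$season)) >= 2)
    out$anova <- tryCatch(rangeAnova(rows$homerange95_km2, rows$season),
                          error = function(e) NULL)
  out
}

.writeOutputs <- function(res, cfg) {
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$outDir, f)
  writeFixesCSV(res$tracks, out("fixes_clean.csv"))
  write.csv(res$stats$perBird, out("per_bird_ranges.csv"),
            row.names = FALSE)
  write.csv(res$zoneTable, out("zone_report.csv"), row.names = FALSE)
  write.csv(res$zones@linkage, out("zone_linkage.csv"), row.names = FALSE)
  write.csv(res$classifications, out("day_classifications.csv"),
            row.names = FALSE)
  write.csv(res$occupancy, out("occupancy_summary.csv"), row.names = FALSE)
  writeRegionGeoJSON(res$zones@regions, out("zones.geojson"),
                     crs = cfg$crs)
  if (nrow(res$roosts))
    writeRoostsGeoJSON(res$roosts, out("roosts.geojson"), crs = cfg$crs)
  for (b in names(res$uds))
    writeAsciiGrid(res$uds[[b]], out(paste0("ud_", b, ".asc")))
  if (!is.null(res$seasonal)) {
    write.csv(res$seasonal$perBirdSeason, out("seasonal_ranges.csv"),
              row.names = FALSE)
    write.csv(res$seasonal$summary, out("seasonal_summary.csv"),
              row.names = FALSE)
  }
  ## resolved configuration, for reproducibility
  cfgOut <- cfg
  cfgOut$simulation <- NULL; cfgOut$region <- NULL; cfgOut$crs <- NULL
  writeLines(jsonlite::toJSON(unclass(cfgOut), auto_unbox = TRUE,
                              null = "null", force = TRUE),
             out("run_config.json"))
  invisible(NULL)
}
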