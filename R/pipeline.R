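# End-to-end pipeline: (simulate | load) -> decorrelation -> vessel
# segmentation -> VISTA fit -> ROI quantification -> rendering, driven by a
# YAML configuration.  Every run writes a machine-readable log (package
# version, seed, full parameter set) so outputs are reproducible.

configError <- function(msg) {
  stop(structure(class = c("octavista_config_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

dataError <- function(msg) {
  stop(structure(class = c("octavista_data_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

pipelineConfigDefaults <- function() {
  list(
    seed = 1L,
    out_dir = "octavista-out",
    pixel_size_um = 5,
    shape = c(96L, 128L),
    phantom = list(vessels = list(
      list(diameter_um = 12, tau_ms = 1.0, D = 1, from_mm = c(0.05, 0.10),
           to_mm = c(0.60, 0.10)),
      list(diameter_um = 30, tau_ms = 0.7, D = 1, from_mm = c(0.05, 0.24),
           to_mm = c(0.60, 0.24)),
      list(diameter_um = 48, tau_ms = 0.4, D = 1, from_mm = c(0.05, 0.38),
           to_mm = c(0.60, 0.38)))),
    simulate = list(mode = "frames", repeats = 5L, a_scan_rate_hz = 4e5,
                    alines_per_circle = 512L, noise_sd = 0.02),
    decorr = list(kernel = c(3L, 3L)),
    vessels = list(radii_um = seq(4, 40, by = 2), global_q = 0.80,
                   local_window_um = 200, local_offset = 0.5,
                   min_area_px = 5, psf_fwhm_um = 0),
    vista = list(tau_range_ms = c(0.05, 100), noise_floor = 0.05),
    roi = list(diameter_mm = NULL, center_mm = NULL),
    render = list(flow_range = c(0, 2.5))
  )
}

mergeConfig <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults))
      configError(paste0("unknown configuration key: ", full))
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]])) &&
        key != "phantom" && is.list(user[[key]]))
      defaults[[key]] <- mergeConfig(defaults[[key]], user[[key]], full)
    else defaults[[key]] <- user[[key]]
  }
  defaults
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML file, checks every key against the schema (unknown keys are
#' an error naming the key) and fills unset values with defaults.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return validated configuration list.
#' @export
loadPipelineConfig <- function(path = NULL) {
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  cfg <- mergeConfig(pipelineConfigDefaults(), user)
  if (!cfg$simulate$mode %in% c("frames", "stack"))
    configError("simulate.mode must be 'frames' or 'stack'")
  cfg$shape <- as.integer(cfg$shape)
  cfg
}

phantomFromConfig <- function(cfg) {
  specs <- lapply(cfg$phantom$vessels, function(v)
    vesselSpec(rbind(as.numeric(v$from_mm), as.numeric(v$to_mm)),
               diameter = v$diameter_um, tau = v$tau_ms,
               D = if (is.null(v$D)) 1 else v$D))
  buildPhantom(specs, pixelSize = cfg$pixel_size_um, shape = cfg$shape)
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or load) -> decorrelation -> vessel segmentation ->
#' VISTA fit -> ROI quantification -> rendering as configured, writing all
#' artifacts plus `run_log.json` into the output directory.
#'
#' @param config a YAML path, a configuration list from
#'   [loadPipelineConfig()], or `NULL` for defaults.
#' @param outDir overrides the configured output directory.
#' @param seed overrides the configured seed.
#' @return (invisibly) a list with the in-memory stage results and the
#'   output directory.
#' @export
runPipeline <- function(config = NULL, outDir = NULL, seed = NULL) {
  cfg <- if (is.character(config)) loadPipelineConfig(config)
         else if (is.null(config)) loadPipelineConfig(NULL)
         else config
  if (!is.null(outDir)) cfg$out_dir <- outDir
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)

  phantom <- phantomFromConfig(cfg)
  if (cfg$simulate$mode == "frames") {
    plan <- scanPlan(aScanRate = cfg$simulate$a_scan_rate_hz,
                     alinesPerCircle = cfg$simulate$alines_per_circle,
                     repeats = cfg$simulate$repeats)
    frames <- simulateComplexFrames(phantom, plan, seed = cfg$seed)
    stack <- decorrelationMultilag(frames, kernel = cfg$decorr$kernel)
  } else {
    plan <- scanPlan(aScanRate = cfg$simulate$a_scan_rate_hz,
                     alinesPerCircle = cfg$simulate$alines_per_circle,
                     repeats = cfg$simulate$repeats)
    stack <- simulateDecorrelationStack(phantom, lags = lagTimes(plan),
                                        noiseSd = cfg$simulate$noise_sd,
                                        seed = cfg$seed)
  }
  writeDecorrelationStack(stack, file.path(cfg$out_dir, "decorr_stack.tif"))

  # mean decorrelation over lags stands in for the en-face OCTA image
  octa <- Reduce(`+`, stack@images) / length(stack@images)
  vcfg <- cfg$vessels
  oof <- oofMultiscale(octa, oofScaleSet(vcfg$radii_um, cfg$pixel_size_um))
  mask <- segmentVessels(oof$response, cfg$pixel_size_um,
                         globalQ = vcfg$global_q,
                         localWindow = vcfg$local_window_um,
                         localOffset = vcfg$local_offset,
                         minArea = vcfg$min_area_px)
  dm <- diameterFromOOF(oof, mask, psfFwhm = vcfg$psf_fwhm_um)
  writeMaskPNG(mask, file.path(cfg$out_dir, "vessel_mask.png"))

  fit <- fitVistaMap(stack, mask, tauRange = cfg$vista$tau_range_ms,
                     noiseFloor = cfg$vista$noise_floor)
  flowPages <- list(flow = fit@flowMap, tau = fit@tauMap, D = fit@DMap)
  flowPages <- lapply(flowPages, function(p) { p[is.na(p)] <- 0; p })
  writeImageStack(flowPages, file.path(cfg$out_dir, "vista_maps.tif"))
  writeMaskPNG(fit@validMask, file.path(cfg$out_dir, "vista_valid.png"))

  pxMm <- cfg$pixel_size_um / 1e3
  roi <- if (!is.null(cfg$roi$diameter_mm)) {
    ctr <- if (is.null(cfg$roi$center_mm))
      c(ncol(octa), nrow(octa)) * pxMm / 2 else as.numeric(cfg$roi$center_mm)
    circularROI(ctr, cfg$roi$diameter_mm, dim(octa), cfg$pixel_size_um)
  } else ROIMask(matrix(TRUE, nrow(octa), ncol(octa)), cfg$pixel_size_um,
                 "full-field")
  rec <- quantifyROI(mask, dm$classMap, fit, roi)
  writeQuantRecords(rec, file.path(cfg$out_dir, "quant.csv"))
  prof <- diameterFlowProfile(dm$diameterMap, fit, roi)
  write.csv(prof, file.path(cfg$out_dir, "diameter_flow_profile.csv"),
            row.names = FALSE, quote = FALSE)

  writeRenderPNG(renderDiameterMap(dm$classMap, octa),
                 file.path(cfg$out_dir, "diameter_map.png"))
  vimg <- renderVista(fit, octa,
                      renderSpec(flowRange = cfg$render$flow_range))
  writeRenderPNG(vimg, file.path(cfg$out_dir, "vista.png"))
  writeRenderPNG(attr(vimg, "colorbar"),
                 file.path(cfg$out_dir, "vista_colorbar.png"))

  jsonlite::write_json(list(package = "octavista",
                            version = as.character(packageVersion("octavista")),
                            r_version = R.version.string,
                            seed = cfg$seed, config = cfg),
                       file.path(cfg$out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(list(phantom = phantom, stack = stack, mask = mask,
                 diameterMap = dm$diameterMap, classMap = dm$classMap,
                 fit = fit, roi = roi, record = rec, profile = prof,
                 outDir = cfg$out_dir))
}
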