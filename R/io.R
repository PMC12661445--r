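## Stack I/O (multi-frame TIFF with JSON sidecars), reagent-panel
## serialization, and manifest-driven end-to-end runs.

.sidecarPath <- function(path) paste0(path, ".json")

#' Write an image stack as a multi-frame TIFF with a JSON sidecar
#'
#' 16-bit stacks are written losslessly (values rounded to integers in
#' [0, 65535]); float stacks are range-encoded to 32-bit samples with the
#' affine range recorded in the sidecar, giving ~1e-7 relative round-trip
#' fidelity. The sidecar carries pixel size, frame interval, channel, clock
#' origin and the encoding.
#'
#' @param stack an \linkS4class{ImageStack} with at least one frame.
#' @param path output file path (".tif").
#' @param bits 16 (integer) or 32 (float).
#' @return \code{path}, invisibly.
#' @export
writeStack <- function(stack, path, bits = 16L) {
  stopifnot(is(stack, "ImageStack"))
  n <- nFrames(stack)
  if (n < 1L || any(dim(stack@frames)[1:2] < 1L)) stop("empty stack")
  if (!bits %in% c(16L, 32L)) stop("bits must be 16 or 32")
  meta <- list(pixel_size_um = stack@pixelSize,
               frame_interval_s = stack@frameInterval,
               channel = stack@channel, clock_origin_s = stack@clockOrigin,
               bits = bits, package = "uncage",
               version = as.character(packageVersion("uncage")))
  if (bits == 16L) {
    v <- round(stack@frames)
    if (any(v < 0 | v > 65535)) stop("16-bit output needs values in [0, 65535]")
    frames <- lapply(seq_len(n), function(k) v[, , k] / 65535)
    meta$encoding <- list(lo = 0, hi = 65535)
  } else {
    lo <- min(stack@frames); hi <- max(stack@frames)
    if (hi <= lo) hi <- lo + 1
    frames <- lapply(seq_len(n), function(k) (stack@frames[, , k] - lo) / (hi - lo))
    meta$encoding <- list(lo = lo, hi = hi)
  }
  tiff::writeTIFF(frames, path, bits.per.sample = bits)
  jsonlite::write_json(meta, .sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multi-frame TIFF stack
#'
#' Grayscale multi-frame TIFFs only; RGB/multi-channel files are rejected.
#' Metadata come from the JSON sidecar written by \code{\link{writeStack}}
#' when present; explicit arguments override the sidecar, and pixel size and
#' frame interval must be available from one of the two sources.
#'
#' @param path TIFF path.
#' @param pixelSize,frameInterval,channel,clockOrigin metadata overrides.
#' @return an \linkS4class{ImageStack}.
#' @export
readStack <- function(path, pixelSize = NA_real_, frameInterval = NA_real_,
                      channel = NA_character_, clockOrigin = NA_real_) {
  if (!file.exists(path)) stop("cannot read '", path, "'")
  frames <- tiff::readTIFF(path, all = TRUE, info = FALSE)
  if (!is.list(frames)) frames <- list(frames)
  if (any(vapply(frames, function(f) length(dim(f)) > 2, logical(1))))
    stop("RGB/multi-channel TIFF not supported; expected grayscale frames")
  shp <- dim(frames[[1]])
  if (!all(vapply(frames, function(f) identical(dim(f), shp), logical(1))))
    stop("inconsistent frame shapes in '", path, "'")
  meta <- list()
  if (file.exists(.sidecarPath(path)))
    meta <- jsonlite::read_json(.sidecarPath(path), simplifyVector = TRUE)
  dec <- function(m) m
  if (!is.null(meta$encoding))
    dec <- function(m) meta$encoding$lo +
      m * (meta$encoding$hi - meta$encoding$lo)
  if (!is.null(meta$bits) && meta$bits == 16L)
    dec <- function(m) round(m * 65535)
  arr <- array(0, c(shp, length(frames)))
  for (k in seq_along(frames)) arr[, , k] <- dec(frames[[k]])
  pick <- function(override, key) {
    if (!is.na(override)) override
    else if (!is.null(meta[[key]])) meta[[key]]
    else NA
  }
  ps <- pick(pixelSize, "pixel_size_um")
  fi <- pick(frameInterval, "frame_interval_s")
  if (is.na(ps) || is.na(fi))
    stop("pixel size and frame interval must come from the sidecar or overrides")
  ch <- pick(channel, "channel"); if (is.na(ch)) ch <- "unknown"
  co <- pick(clockOrigin, "clock_origin_s"); if (is.na(co)) co <- 0
  ImageStack(arr, ps, fi, ch, co)
}

#' Serialize a reagent panel to YAML
#'
#' @param panel a \linkS4class{ReagentPanel}.
#' @param path output path; NULL returns the YAML string.
#' @return the path (or YAML string), invisibly.
#' @export
writeReagentPanelYaml <- function(panel, path = NULL) {
  obj <- list(total_calcium_uM = panel@totalCalcium,
              species = lapply(panel@species, function(s)
                list(name = s@name, total_uM = s@total, kd_uM = s@kd,
                     D_um2_per_s = s@D, mobile = s@mobile)))
  txt <- yaml::as.yaml(obj)
  if (is.null(path)) return(invisible(txt))
  writeLines(txt, path)
  invisible(path)
}

#' Read a reagent panel from YAML
#'
#' @param path YAML file as written by \code{\link{writeReagentPanelYaml}}.
#' @return a \linkS4class{ReagentPanel}.
#' @export
readReagentPanelYaml <- function(path) {
  obj <- yaml::read_yaml(path)
  sp <- lapply(obj$species, function(s)
    BindingSpecies(s$name, s$total_uM, s$kd_uM, s$D_um2_per_s,
                   if (is.null(s$mobile)) s$D_um2_per_s > 0 else s$mobile))
  ReagentPanel(sp, obj$total_calcium_uM)
}

#' Save / load a calibration fit as JSON
#'
#' @param fit a \linkS4class{CalibrationFit}.
#' @param path JSON path.
#' @return \code{path} (writer) or the \linkS4class{CalibrationFit} (reader).
#' @export
writeCalibrationJson <- function(fit, path) {
  jsonlite::write_json(list(a = fit@curve@a, b = fit@curve@b,
                            residual_rms = fit@residualRms,
                            linear_range_max_uM = fit@linearRangeMax,
                            n_points = fit@nPoints),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeCalibrationJson
#' @export
readCalibrationJson <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("CalibrationFit", curve = SaturationCurve(o$a, o$b),
      residualRms = o$residual_rms, linearRangeMax = o$linear_range_max_uM,
      nPoints = as.integer(o$n_points))
}

## canonical md5 of a manifest-like list
.configHash <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = 12, pretty = FALSE)
  unname(tools::md5sum(tmp))
}

#' Run the full dual-channel experiment described by a manifest
#'
#' Orchestrates the end-to-end workflow: read the reference, experimental
#' and brightfield stacks and the saturated bleach reference; bleach-correct
#' both fluorescence stacks; form the intensity difference and the
#' bound-protein map; track the network boundary; extract the maximum and
#' boundary bound-protein traces and the outcome; write the result bundle
#' (CSV/JSON, stamped with the manifest hash, seed and package version).
#' Re-running the same manifest reproduces the same bundle.
#'
#' @param manifest path to a YAML manifest or an equivalent named list with
#'   fields \code{protocol} (center, diameter_um, duration_s, intensity_pct,
#'   start_s), \code{ref_stack}, \code{exp_stack}, \code{brightfield_stack},
#'   \code{bleach_reference_stack}, \code{calibration} (JSON path),
#'   \code{camera_offset}, optional \code{panel} (YAML path), \code{mode},
#'   \code{detection} (blur_radius_px, threshold_k, min_area_px2),
#'   \code{seed}, and \code{out_dir}.
#' @return invisibly, a list with the traces, outcome, Hill-ready
#'   observations, and the bundle hash.
#' @export
runExperiment <- function(manifest) {
  mf <- if (is.character(manifest)) yaml::read_yaml(manifest) else manifest
  need <- c("protocol", "ref_stack", "exp_stack", "brightfield_stack",
            "bleach_reference_stack", "calibration", "out_dir")
  miss <- setdiff(need, names(mf))
  if (length(miss))
    stop("manifest is missing required field(s): ", paste(miss, collapse = ", "))
  for (f in c("ref_stack", "exp_stack", "brightfield_stack",
              "bleach_reference_stack", "calibration"))
    if (!file.exists(mf[[f]]))
      stop("manifest field '", f, "' points to a missing file: ", mf[[f]])
  pr <- mf$protocol
  protocol <- PulseProtocol(center = unlist(pr$center),
                            diameter = pr$diameter_um,
                            duration = pr$duration_s,
                            intensity = pr$intensity_pct,
                            start = pr$start_s)
  offset <- if (is.null(mf$camera_offset)) 0 else mf$camera_offset
  mode <- if (is.null(mf$mode)) "inversion-difference" else mf$mode
  seed <- if (is.null(mf$seed)) 1L else as.integer(mf$seed)
  set.seed(seed)

  fit <- readCalibrationJson(mf$calibration)
  ref <- readStack(mf$ref_stack)
  exp_ <- readStack(mf$exp_stack)
  bf <- readStack(mf$brightfield_stack)
  sat <- readStack(mf$bleach_reference_stack)
  bref <- buildBleachReference(sat, offset = offset)
  refC <- applyBleachCorrection(ref, bref)
  expC <- applyBleachCorrection(exp_, bref)
  delta <- deltaIntensity(refC, expC)
  panel <- if (!is.null(mf$panel)) readReagentPanelYaml(mf$panel) else NULL
  bstack <- boundTcb2FromDelta(delta, fit, mode = mode, refStack = refC,
                               panel = panel, offset = offset)
  dpl <- mf$detection
  dp <- DetectionParams(
    blurRadius = if (is.null(dpl$blur_radius_px)) 5 else dpl$blur_radius_px,
    thresholdK = if (is.null(dpl$threshold_k)) 6 else dpl$threshold_k,
    minArea = if (is.null(dpl$min_area_px2)) 20 else dpl$min_area_px2)
  pre <- which(frameTimes(bf) < protocol@start)
  if (!length(pre)) pre <- 1L
  trace <- trackRadius(bf, protocol@center, dp, prePulseFrames = pre)
  postWindow <- max(0.5, max(trace@times) - (protocol@start + protocol@duration) - 1e-9)
  outcome <- classifyOutcome(trace, protocol, postWindow = postWindow)
  maxTrace <- maxBoundTrace(bstack, protocol@center, protocol@diameter / 2)
  bcTrace <- if (any(trace@detected))
    boundaryConcentration(bstack, trace) else NULL
  obs <- collectAssemblyObservations(bstack, bf, protocol, dp,
                                     prePulseFrames = pre)

  dir.create(mf$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- .configHash(mf[setdiff(names(mf), "out_dir")])
  traceDf <- data.frame(t_s = trace@times, radius_um = trace@radii,
                        detected = trace@detected)
  write.csv(traceDf, file.path(mf$out_dir, "boundary_trace.csv"),
            row.names = FALSE)
  write.csv(maxTrace, file.path(mf$out_dir, "max_bound_trace.csv"),
            row.names = FALSE)
  if (!is.null(bcTrace))
    write.csv(bcTrace, file.path(mf$out_dir, "boundary_concentration.csv"),
              row.names = FALSE)
  write.csv(obs, file.path(mf$out_dir, "assembly_observations.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    list(outcome = outcome@label, delay_s = outcome@delay,
         max_radius_um = outcome@maxRadius,
         initial_growth_rate_um_per_s = outcome@initialGrowthRate,
         floored_fraction = bstack@flooredFraction,
         config_hash = hash, seed = seed,
         package_version = as.character(packageVersion("uncage"))),
    file.path(mf$out_dir, "outcome.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(trace = trace, outcome = outcome, maxBound = maxTrace,
                 boundary = bcTrace, observations = obs, hash = hash,
                 boundStack = bstack))
}
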