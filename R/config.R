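#' @include recon.R
NULL

#' Assemble a full run configuration
#'
#' Bundles the phantom, acquisition, reconstruction and repeatability-design
#' settings for an end-to-end run. `scale` is the desk-scale factor: it
#' uniformly shrinks the rasterization/reconstruction grids and the spoke
#' count (and coarsens the nominal resolution accordingly) while preserving
#' the field of view, so that a `scale = 0.25` experiment runs in minutes on
#' one CPU. `scale = 1` is the full 3 T protocol.
#'
#' @param scale desk-scale factor in (0, 1].
#' @param phantom a `"PhantomConfig"`; defaults to [phantomConfig()] at
#'   `scale`.
#' @param acq an `"AcqParams"`; defaults to [acqParams()] at `scale`.
#' @param recon a `"ReconParams"`; defaults to [reconParams()] at `scale`.
#' @param noiseSigma per-channel k-space noise SD; `NULL` means "calibrate
#'   to `targetSnr` before running sessions".
#' @param targetSnr target image SNR for noise calibration (the protocol's
#'   FA-30 regime is around 79).
#' @param days,scansPerDay repeatability design (defaults 3 x 3).
#' @param driftRange per-day intensity drift half-width.
#' @param seed default base seed.
#' @return Named list with class `"RunConfig"`.
#' @seealso [loadConfig()], [configHash()]
#' @export
runConfig <- function(scale = 1,
                      phantom = phantomConfig(scale = scale),
                      acq = acqParams(scale = scale),
                      recon = reconParams(scale = scale),
                      noiseSigma = NULL,
                      targetSnr = 79,
                      days = 3, scansPerDay = 3, driftRange = 0.02,
                      seed = 1L) {
  cfg <- structure(list(scale = scale, phantom = phantom, acq = acq,
                        recon = recon, noiseSigma = noiseSigma,
                        targetSnr = targetSnr, days = days,
                        scansPerDay = scansPerDay, driftRange = driftRange,
                        seed = as.integer(seed)),
                   class = "RunConfig")
  .validateRunConfig(cfg)
  cfg
}

.validateRunConfig <- function(cfg) {
  .validateAcqParams(cfg$acq)
  if (!isTRUE(all.equal(cfg$acq$fov, cfg$recon$fov)))
    stop("validation error at key 'recon.fov': must equal acq.fov")
  if (!is.null(cfg$noiseSigma) && cfg$noiseSigma < 0)
    stop("validation error at key 'noiseSigma': must be >= 0")
  if (cfg$days < 1 || cfg$scansPerDay < 1)
    stop("validation error at key 'days'/'scansPerDay': must be >= 1")
  invisible(TRUE)
}

.mergeConfigLevel <- function(defaults, overrides, path = "") {
  for (key in names(overrides)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults))
      stop(sprintf("unknown configuration key '%s'", full))
    if (is.list(defaults[[key]]) && is.list(overrides[[key]]) &&
        !is.null(names(defaults[[key]])))
      defaults[[key]] <- .mergeConfigLevel(defaults[[key]], overrides[[key]], full)
    else
      defaults[key] <- list(overrides[[key]])  # keeps explicit NULLs in place
  }
  defaults
}

#' Load and validate a run configuration file
#'
#' Reads a YAML (`.yaml`/`.yml`) or JSON (`.json`) document, fills every
#' unspecified setting with the protocol defaults (an empty file yields the
#' full default configuration: FOV 38.4 cm, 15,460 spokes, TR 5 ms, TE
#' 0.5 ms, FA 30 degrees, 12 averages), rejects unknown keys by name, and
#' validates the result (e.g. TE < TR). Top-level `scale` is applied first
#' so that scale-dependent defaults are consistent.
#'
#' Recognized top-level keys are those of [runConfig()]; `phantom`, `acq`
#' and `recon` accept the argument names of [phantomConfig()], [acqParams()]
#' and [reconParams()].
#'
#' @param path configuration file path.
#' @return A validated `"RunConfig"` list.
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop(sprintf("configuration file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else if (ext == "json") jsonlite::fromJSON(path, simplifyVector = TRUE)
         else stop(sprintf("unsupported configuration format '.%s' (use YAML or JSON)", ext))
  if (is.null(raw)) raw <- list()
  scale <- if (!is.null(raw$scale)) raw$scale else 1
  defaults <- runConfig(scale = scale)
  # explicit file values are taken literally (scale only shapes the
  # defaults); derived reconstruction quantities are recomputed afterwards
  cfg <- .mergeConfigLevel(defaults, raw)
  cfg$recon <- .refreshReconDerived(cfg$recon)
  class(cfg) <- "RunConfig"
  .validateRunConfig(cfg)
  cfg
}

.refreshReconDerived <- function(rp) {
  n <- as.integer(round(rp$fov / rp$reconResolution))
  g <- as.integer(2 * ceiling(n * rp$gridOversampling / 2))
  osEff <- g / n
  rp$gridShape <- n
  rp$oversampledShape <- g
  rp$beta <- pi * sqrt(rp$kernelWidth^2 / osEff^2 * (osEff - 0.5)^2 - 0.8)
  rp
}

#' Save a run configuration
#'
#' Writes the configuration as YAML or JSON (by extension). A saved and
#' re-loaded configuration hashes identically.
#'
#' @param config a `"RunConfig"`.
#' @param path output path (`.yaml`, `.yml` or `.json`).
#' @return `path`, invisibly.
#' @export
saveConfig <- function(config, path) {
  ext <- tolower(tools::file_ext(path))
  strip <- function(x) {
    if (is.list(x) && !is.data.frame(x)) lapply(unclass(x), strip) else unclass(x)
  }
  plain <- strip(config)
  if (ext %in% c("yaml", "yml")) yaml::write_yaml(plain, path)
  else if (ext == "json")
    writeLines(jsonlite::toJSON(plain, auto_unbox = TRUE, digits = NA, null = "null"), path)
  else stop(sprintf("unsupported configuration format '.%s'", ext))
  invisible(path)
}

#' Stable hash of a configuration
#'
#' Deterministic content hash recorded in every output artifact so runs can
#' be replayed exactly.
#'
#' @param config a `"RunConfig"` (or any R object).
#' @return Character hash.
#' @export
configHash <- function(config) {
  # canonicalize numeric storage mode so a config re-read from a format that
  # narrows whole doubles to integers (JSON) hashes identically
  canon <- function(x) {
    if (is.list(x)) lapply(x, canon)
    else if (is.integer(x)) as.double(x)
    else x
  }
  rlang::hash(canon(as.list(config)))
}
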