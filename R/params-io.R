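# Human-readable parameter file (YAML) bundling the intensity model and
# the learned DRF weights, so segmentation needs exactly one artifact.

paramFileVersion <- 1L

#' Write DRF parameters to a YAML parameter file
#'
#' Field names are versioned; [readDrfParams()] refuses files whose
#' version it does not know.
#'
#' @param params a [DrfParams-class].
#' @param path output path.
#' @param provenance optional named list stored verbatim (e.g. a training
#'   manifest hash).
#' @return Invisibly, `path`.
#' @export
writeDrfParams <- function(params, path, provenance = list()) {
  stopifnot(is(params, "DrfParams"))
  obj <- list(
    format = "noduleDRF-params",
    version = paramFileVersion,
    association_weights = as.numeric(params@w),
    interaction_weight = as.numeric(params@v),
    beta = as.numeric(params@beta),
    delta_scale_hu = as.numeric(params@deltaScale),
    intensity_model = list(
      mu_int = params@model@muInt, sigma_int = params@model@sigmaInt,
      t_min = params@model@tMin, t_max = params@model@tMax))
  if (length(provenance)) obj$provenance <- provenance
  yaml::write_yaml(obj, path, precision = 15L)
  invisible(path)
}

#' Read DRF parameters from a YAML parameter file
#'
#' @param path file written by [writeDrfParams()].
#' @return A [DrfParams-class].
#' @export
readDrfParams <- function(path) {
  if (!file.exists(path)) stopfmt("parameter file not found: %s", path)
  obj <- yaml::read_yaml(path)
  if (!identical(obj$format, "noduleDRF-params"))
    stopfmt("%s is not a noduleDRF parameter file", path)
  if (!identical(as.integer(obj$version), paramFileVersion))
    stopfmt("unsupported parameter file version %s", obj$version)
  im <- obj$intensity_model
  drfParams(w = as.numeric(obj$association_weights),
            v = as.numeric(obj$interaction_weight),
            beta = as.numeric(obj$beta),
            deltaScale = as.numeric(obj$delta_scale_hu),
            model = intensityModel(im$mu_int, im$sigma_int, im$t_min,
                                   im$t_max))
}
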