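#' Pipeline configuration
#'
#' Nested list of all tunable parameters with the pipeline defaults:
#' structuring-element diameter 11 px, CLAHE tile 16 px with clip factor 2,
#' diffusion (K = 15, lambda = 1, 5 iterations), gradient smoothing sigma
#' 1 px, merge-threshold ladder 10..70 in steps of 10 processed in
#' descending order, relative quality threshold 0.97, and a 21-point sweep
#' grid 0.900..1.000. Unknown keys are rejected.
#'
#' @param overrides named nested list of overrides (partial).
#' @return an `msm_config` list.
#' @export
msm_config <- function(overrides = list()) {
  defaults <- list(
    preprocess = list(
      tophat_diameter = 11L,
      clahe_tile = 16L,
      clahe_clip = 2.0,
      diffusion = list(K = 15, lambda = 1.0, iterations = 5L)
    ),
    oversegmentation = list(
      gaussian_sigma = 1.0,
      mean_source = "diffused"   # or "raw"
    ),
    merging = list(
      thresholds = 10 * (1:7),
      order = "desc",            # or "asc"
      stability_aggregate = "mean",  # or "median"
      combine = "segment-clip"       # or "segment-reject"
    ),
    semantics = list(
      tqual = 0.97,
      boundary_mode = "segment-mean",  # or "raw-pixel"
      perimeter = "crofton"            # or "pixel-count"
    ),
    evaluation = list(
      sweep_grid = seq(0.900, 1.000, by = 0.005),
      min_overlap = 1L,
      min_dc = 0.75
    )
  )
  structure(merge_config(defaults, overrides, path = ""),
            class = "msm_config")
}

merge_config <- function(base, over, path) {
  if (!length(over)) return(base)
  if (is.null(names(over)) || any(!nzchar(names(over))))
    stop("config overrides must be named")
  for (k in names(over)) {
    if (!k %in% names(base))
      stop(sprintf("unknown config key: %s%s", path, k))
    if (is.list(base[[k]]) && !is.null(names(base[[k]]))) {
      base[[k]] <- merge_config(base[[k]], as.list(over[[k]]),
                                paste0(path, k, "."))
    } else {
      base[[k]] <- over[[k]]
    }
  }
  base
}

#' Read / write a configuration as JSON
#'
#' @param path JSON file path.
#' @return [msm_config()] list.
#' @export
read_config <- function(path) {
  msm_config(jsonlite::fromJSON(path, simplifyVector = TRUE))
}

#' @rdname read_config
#' @param config configuration to serialize.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
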