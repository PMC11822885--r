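#' Pipeline configuration with all analysis constants
#'
#' Aggregates every tunable of the pipeline with its default: frequency
#' bands, FIR transition bandwidth, 100 ms feature windows, class anchors
#' (silence 1.5 s / 0.5 s auditory after voice offset; delay probe ending
#' 1 s after stimulus offset), the -1.5..0.7 s offset sweep, decoder grids,
#' 500 shuffles at alpha 0.05, Savitzky-Golay and Gaussian smoothing
#' parameters and the 2..10 k-means range. Values round-trip bit-exactly
#' through a YAML file; unknown keys are rejected on read.
#'
#' @param ... Name-value overrides of top-level keys (partial lists are
#'   merged).
#' @param seed Integer seed.
#' @return A nested list of class `si_config`.
#' @export
pipeline_config <- function(..., seed = 1) {
  cfg <- list(
    bands = list(high_gamma = c(70, 200), alpha = c(8, 12), beta = c(13, 30)),
    transition_bandwidth_hz = 10,
    feature = list(window_width_s = 0.1, n_windows = 4,
                   silence_anchor_visual_s = 1.5, silence_anchor_auditory_s = 0.5,
                   delay_probe_end_s = 1.0),
    sweep = list(silence_offsets_s = c(-1.5, 0.7, 0.1),
                 delay_offsets_s = c(-0.2, -0.1, 0)),
    decoder = list(outer_split = 0.8, inner_folds = 5, n_iterations = 20,
                   penalty_grid = c(0.1, 1, 10, 100),
                   kernel_width_grid = c(0.01, 0.1, NA, 1, 10),
                   n_shuffles = 500, alpha = 0.05),
    dpca = list(sg_order = 4, sg_length_s = 0.201,
                speech_window_s = c(-0.5, 0), silence_window_s = c(1.0, 1.5)),
    clustering = list(window_s = c(-1, 0.5), gaussian_sd_s = 0.025,
                      k_range = c(2, 10), n_restarts = 20),
    seed = as.integer(seed)
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) .stopf("unknown configuration key(s): %s", paste(bad, collapse = ", "))
  for (nm in names(over)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(over[[nm]]))
      utils::modifyList(cfg[[nm]], over[[nm]]) else over[[nm]]
  }
  structure(cfg, class = "si_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' @param cfg An `si_config`.
#' @param path YAML file path.
#' @return `path` (write) or the validated `si_config` (read). Unknown keys
#'   in the file cause an error.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  ref <- pipeline_config()
  bad <- setdiff(names(raw), names(ref))
  if (length(bad)) .stopf("unknown configuration key(s) in %s: %s",
                          path, paste(bad, collapse = ", "))
  for (nm in names(raw)) {
    if (is.list(ref[[nm]])) {
      badsub <- setdiff(names(raw[[nm]]), names(ref[[nm]]))
      if (length(badsub)) .stopf("unknown configuration key(s) in %s: %s.%s",
                                 path, nm, paste(badsub, collapse = ", "))
    }
  }
  cfg <- do.call(pipeline_config, c(raw[names(raw) != "seed"],
                                    list(seed = if (is.null(raw$seed)) 1 else raw$seed)))
  cfg
}
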