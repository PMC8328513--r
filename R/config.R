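#' Run configuration
#'
#' A flat configuration bundling the model parameters with the standard
#' stimulus conventions, serializable to YAML or JSON. Defaults reproduce
#' the standard parameterization: 4 Hz unit-amplitude oscillation with
#' automatic phase alignment, base inhibition -0.2, threshold 1, 125 ms
#' ramps, 250 ms SOA, feedback delay 0.9 cycle / hold 0.5 cycle / decay
#' 0.01 / gain 1.5, and 1 ms integration step.
#'
#' @param ... overrides for any default field (unknown fields are rejected).
#' @return A named list of class `"stimcon_config"`.
#' @examples
#' cfg <- stimcon_config(omega = 6.25)
#' cfg$soa_ms
#' @export
stimcon_config <- function(...) {
  defaults <- list(
    am = 1, omega = 4, phi = NULL,
    base_inhib = -0.2, excit_ms = 20, recov_ms = 100, threshold = 1,
    fb_delay_cycles = 0.9, fb_hold_cycles = 0.5, fb_decay = 0.01,
    fb_gain = 1.5, dt = 1,
    soa_ms = 250, ramp_ms = 125, gauss_sd = 42, shape = "ramp",
    seed = 1L)
  over <- list(...)
  if (length(over) == 1 && is.list(over[[1]]) && is.null(names(over)[1]))
    over <- over[[1]]
  bad <- setdiff(names(over), names(defaults))
  if (length(bad)) stop("unknown configuration field(s): ",
                        paste(bad, collapse = ", "))
  cfg <- modifyList(defaults, over, keep.null = TRUE)
  validate_config(cfg)
  structure(cfg, class = "stimcon_config")
}

validate_config <- function(cfg) {
  # delegate numeric constraints to the parameter constructor
  as_params(cfg)
  if (cfg$soa_ms <= 0 || cfg$ramp_ms <= 0 || cfg$gauss_sd <= 0)
    stop("soa_ms, ramp_ms and gauss_sd must be positive")
  if (!cfg$shape %in% c("ramp", "gaussian"))
    stop("shape must be 'ramp' or 'gaussian'")
  invisible(cfg)
}

#' Convert a configuration to simulator parameters
#'
#' @param cfg a [stimcon_config()].
#' @return A [stimcon_params()].
#' @export
as_params <- function(cfg) {
  stimcon_params(am = cfg$am, omega = cfg$omega, phi = cfg$phi,
                 base_inhib = cfg$base_inhib, excit_ms = cfg$excit_ms,
                 recov_ms = cfg$recov_ms, threshold = cfg$threshold,
                 fb_delay_cycles = cfg$fb_delay_cycles,
                 fb_hold_cycles = cfg$fb_hold_cycles,
                 fb_decay = cfg$fb_decay, fb_gain = cfg$fb_gain,
                 dt = cfg$dt)
}

#' Read / write a run configuration
#'
#' Configurations are stored as flat YAML (or JSON — YAML is a superset);
#' missing fields are filled with defaults, unknown fields rejected, and an
#' empty file yields the all-defaults configuration.
#'
#' @param path file path.
#' @param cfg a [stimcon_config()].
#' @return `load_config()` returns a validated [stimcon_config()];
#'   `save_config()` returns `path` invisibly.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- yaml::read_yaml(path)
  if (is.null(x)) x <- list()
  stimcon_config(x)
}

#' @rdname load_config
#' @export
save_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "stimcon_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @export
print.stimcon_config <- function(x, ...) {
  cat("STiMCON run configuration\n")
  for (f in names(x))
    cat(sprintf("  %-16s %s\n", f,
                if (is.null(x[[f]])) "auto" else format(x[[f]])))
  invisible(x)
}
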