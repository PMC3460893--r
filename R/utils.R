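#' Round half away from zero
#'
#' Report tables round percentages with halves going away from zero (so 0.05
#' renders as 0.1), matching the convention of most GIS summary tools rather
#' than R's banker's rounding.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places.
#' @return numeric vector.
#' @export
#' @examples
#' round_half_up(c(0.25, -0.25, 2.5), 1)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

.stop_config <- function(msg, ...) {
  abort(msg, class = "prioralign_config_error", ...)
}

.stop_data <- function(msg, ...) {
  abort(msg, class = "prioralign_data_error", ...)
}

.stop_geometry <- function(msg, ...) {
  abort(msg, class = "prioralign_geometry_error", ...)
}

.stop_metric <- function(msg, ...) {
  abort(msg, class = "prioralign_metric_error", ...)
}

# deterministic per-stage RNG sub-stream so adding parcels does not perturb
# state/priority geometry
.set_substream <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  set.seed(as.integer((as.numeric(seed) + 1000003 * stage) %% 2147483647L))
}
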