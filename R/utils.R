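#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif rexp rbinom qnorm dnorm pnorm optim mad
#'   median setNames spline splinefun integrate quantile coef lm approx sd
#' @importFrom utils head tail modifyList write.csv read.csv
NULL

abort_param <- function(msg) {
  stop(errorCondition(msg, class = c("telospt_parameter_error", "error")))
}

abort_insufficient <- function(msg) {
  stop(errorCondition(msg, class = c("telospt_insufficient_data", "error")))
}

abort_degenerate <- function(msg) {
  stop(errorCondition(msg, class = c("telospt_degenerate_correction", "error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    abort_param(sprintf("`%s` must be a probability in [0, 1], got %s",
                        name, format(x)))
  invisible(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0)
    abort_param(sprintf("`%s` must be a non-negative number, got %s",
                        name, format(x)))
  invisible(x)
}

check_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    abort_param(sprintf("`%s` must be a positive number, got %s",
                        name, format(x)))
  invisible(x)
}

check_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 ||
      x != round(x))
    abort_param(sprintf("`%s` must be a non-negative integer, got %s",
                        name, format(x)))
  invisible(as.integer(x))
}

#' Fold a free Brownian coordinate into a reflecting interval
#'
#' Billiard (triangle-wave) map of an unconstrained coordinate into
#' `[lo, hi]`; the image of an unreflected Brownian path under this map is a
#' reflected Brownian path on the interval.
#' @noRd
reflect_interval <- function(x, lo, hi) {
  w <- hi - lo
  y <- (x - lo) %% (2 * w)
  y <- ifelse(y > w, 2 * w - y, y)
  y + lo
}

# Uniform point(s) in a disk of radius R centred at the origin.
runif_disk <- function(n, radius) {
  r <- radius * sqrt(runif(n))
  th <- runif(n, 0, 2 * pi)
  cbind(x = r * cos(th), y = r * sin(th))
}

#' Stable hash of an R object (configuration stamping)
#' @noRd
config_hash <- function(x) rlang::hash(x)
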