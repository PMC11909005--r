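#' Empirical survival curve of binding durations
#'
#' The survival function `S(t) = #(durations >= t) / n`, evaluated over the
#' sorted unique durations — the "1 - CDF" representation of track-length
#' distributions. It starts at 1 at the minimum observed duration and is
#' non-increasing.
#'
#' @param durations Positive durations in seconds (track durations:
#'   `(frames observed - 1) * frame_interval`).
#' @return A tibble of class `survival_curve` with columns `time`,
#'   `survival`, `n_at_risk`; attributes `n_tracks` and `durations`.
#' @export
survival_curve <- function(durations) {
  if (length(durations) == 0) abort_param("no durations supplied")
  if (any(!is.finite(durations)) || any(durations <= 0))
    abort_param("durations must be positive and finite")
  tt <- sort(unique(durations))
  n <- length(durations)
  n_at_risk <- vapply(tt, function(t) sum(durations >= t), numeric(1))
  out <- tibble::tibble(time = tt, survival = n_at_risk / n,
                        n_at_risk = n_at_risk)
  class(out) <- c("survival_curve", class(out))
  attr(out, "n_tracks") <- n
  attr(out, "durations") <- durations
  out
}

#' Fit exponential photobleaching to an intensity trace
#'
#' Least-squares fit of `amplitude * exp(-k_bleach * t) + baseline` to a
#' per-frame integrated channel intensity.
#'
#' @param intensity_trace Numeric vector of per-frame integrated intensity
#'   (length >= 10, finite).
#' @param frame_interval Frame spacing in seconds.
#' @return A list of class `bleach_model`: `k_bleach` (1/s), `amplitude`,
#'   `baseline`, `residual`.
#' @export
fit_bleach <- function(intensity_trace, frame_interval = 1) {
  y <- as.numeric(intensity_trace)
  if (length(y) < 10) abort_param("intensity trace must have >= 10 frames")
  if (any(!is.finite(y))) abort_param("intensity trace contains non-finite values")
  check_pos(frame_interval, "frame_interval")
  t <- (seq_along(y) - 1) * frame_interval
  if (stats::sd(y) == 0 || all(diff(y) >= 0)) {
    return(structure(list(k_bleach = 0, amplitude = 0, baseline = mean(y),
                          residual = sqrt(sum((y - mean(y))^2))),
                     class = "bleach_model"))
  }
  c0 <- min(y); a0 <- max(y) - c0
  pos <- which(y - c0 > a0 * 1e-3)
  k0 <- tryCatch({
    sl <- stats::coef(lm(log(y[pos] - c0 + a0 * 1e-6) ~ t[pos]))[2]
    max(1e-6, -sl)
  }, error = function(e) 1 / max(t[length(t)], 1))
  fit <- minpack.lm::nls.lm(
    par = c(A = a0, k = as.numeric(k0), C = c0),
    fn = function(p) y - (p[1] * exp(-p[2] * t) + p[3]),
    lower = c(0, 0, -Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  p <- fit$par
  structure(list(k_bleach = p[[2]], amplitude = p[[1]], baseline = p[[3]],
                 residual = sqrt(sum(fit$fvec^2))),
            class = "bleach_model")
}

# weighted LS exponential fits to a survival curve ----------------------

fit_surv_one_exp <- function(tt, ss, wt) {
  t0 <- tt[1]
  keep <- ss > 0
  x <- tt[keep] - t0; yl <- log(ss[keep]); w <- wt[keep]
  if (sum(keep) < 2 || all(x == 0)) return(list(k = NA_real_, rss = NA_real_, npar = 1))
  k <- -sum(w * x * yl) / sum(w * x^2)   # weighted regression through origin
  k <- max(k, 1e-9)
  pred <- exp(-k * (tt - t0))
  list(k = k, rss = sum(wt * (ss - pred)^2), npar = 1)
}

fit_surv_two_exp <- function(tt, ss, wt, k_init) {
  t0 <- tt[1]
  fit <- tryCatch(minpack.lm::nls.lm(
    par = c(w = 0.5, k1 = k_init / 3, k2 = k_init * 3),
    fn = function(p) sqrt(wt) * (ss - (p[1] * exp(-p[2] * (tt - t0)) +
                                         (1 - p[1]) * exp(-p[3] * (tt - t0)))),
    lower = c(0, 1e-9, 1e-9), upper = c(1, Inf, Inf),
    control = minpack.lm::nls.lm.control(maxiter = 300)),
    error = function(e) NULL)
  if (is.null(fit)) return(list(k = NA_real_, rss = NA_real_, npar = 3))
  p <- fit$par
  ks <- sort(c(p[[2]], p[[3]]))
  wslow <- if (p[[2]] <= p[[3]]) p[[1]] else 1 - p[[1]]
  list(k = ks[1], k2 = ks[2], w = wslow, rss = sum(fit$fvec^2), npar = 3)
}

#' Fit residence kinetics to a survival curve with bleaching correction
#'
#' Fits the survival curve with a one- or two-exponential decay (weighted
#' by the number of tracks at risk), subtracts the photobleaching rate
#' from the observed decay rate (`k_off = k_obs - k_bleach`; unbinding and
#' bleaching are independent competing exponential risks), and converts to
#' a half-life `t_half = ln 2 / k_off`. For the two-exponential model the
#' reported rate is the slow component's. Confidence intervals come from a
#' seeded bootstrap over tracks.
#'
#' @param curve A [survival_curve()].
#' @param bleach A `bleach_model` from [fit_bleach()], or `NULL` for no
#'   correction.
#' @param model `"one_exp"`, `"two_exp"` or `"auto"` (BIC selection).
#' @param n_boot Bootstrap resamples (default 500).
#' @param seed Bootstrap seed.
#' @param min_tracks Minimum number of tracks required (default 50).
#' @return A list of class `residence_fit`: `model`, `k_obs` (1/s),
#'   (`k_obs2`, `weight` for two_exp), `k_bleach`, `k_off`, `t_half` (s),
#'   `t_half_uncorrected`, `ci` (95% percentile CI of `t_half`),
#'   `boot_t_half` (draws), `n_tracks`.
#' @export
fit_residence <- function(curve, bleach = NULL,
                          model = c("one_exp", "two_exp", "auto"),
                          n_boot = 500, seed = 7, min_tracks = 50) {
  model <- match.arg(model)
  stopifnot(inherits(curve, "survival_curve"))
  n <- attr(curve, "n_tracks")
  if (n < min_tracks)
    abort_insufficient(sprintf("%d tracks, but at least %d are required",
                               n, min_tracks))
  k_bleach <- if (is.null(bleach)) 0 else bleach$k_bleach
  durations <- attr(curve, "durations")

  point <- fit_surv_point(curve$time, curve$survival, curve$n_at_risk, model)
  k_obs <- point$k
  if (!is.finite(k_obs)) stop("residence fit failed")
  if (k_bleach >= k_obs)
    abort_degenerate(sprintf(
      "photobleaching rate (%.4g/s) is at least the observed decay rate (%.4g/s); residence time not resolvable",
      k_bleach, k_obs))
  k_off <- k_obs - k_bleach

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  boot <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    d <- sample(durations, n, replace = TRUE)
    sc <- survival_curve(d)
    pb <- tryCatch(fit_surv_point(sc$time, sc$survival, sc$n_at_risk,
                                  point$model_used),
                   error = function(e) NULL)
    if (is.null(pb) || !is.finite(pb$k) || pb$k <= k_bleach) next
    boot[b] <- log(2) / (pb$k - k_bleach)
  }
  ci <- stats::quantile(boot, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  structure(list(model = point$model_used, k_obs = k_obs,
                 k_obs2 = point$k2 %||% NA_real_,
                 weight = point$w %||% NA_real_,
                 k_bleach = k_bleach, k_off = k_off,
                 t_half = log(2) / k_off,
                 t_half_uncorrected = log(2) / k_obs,
                 ci = ci, boot_t_half = boot, n_tracks = n),
            class = "residence_fit")
}

fit_surv_point <- function(tt, ss, n_at_risk, model) {
  wt <- n_at_risk / sum(n_at_risk)
  one <- fit_surv_one_exp(tt, ss, wt)
  if (model == "one_exp") return(c(one, model_used = "one_exp"))
  two <- fit_surv_two_exp(tt, ss, wt, one$k)
  if (model == "two_exp") return(c(two, model_used = "two_exp"))
  # BIC on the weighted least-squares criterion
  m <- length(tt)
  bic1 <- m * log(one$rss / m) + one$npar * log(m)
  bic2 <- if (is.finite(two$rss)) m * log(two$rss / m) + two$npar * log(m) else Inf
  if (bic2 < bic1) c(two, model_used = "two_exp") else c(one, model_used = "one_exp")
}

#' @export
print.residence_fit <- function(x, ...) {
  cat(sprintf(paste0("<residence_fit> %s: k_obs = %.3f/s, k_bleach = %.3f/s",
                     " -> k_off = %.3f/s, t_half = %.2f s [%.2f, %.2f]\n"),
              x$model, x$k_obs, x$k_bleach, x$k_off, x$t_half,
              x$ci[1], x$ci[2]))
  invisible(x)
}

#' Compare residence half-lives of two groups
#'
#' Point ratio `t_half_a / t_half_b` with a percentile confidence interval
#' from the paired bootstrap draws stored in the fits.
#'
#' @param fit_a,fit_b `residence_fit`s.
#' @return List with `ratio`, `ci` (95%), `n_pairs`.
#' @export
compare_groups <- function(fit_a, fit_b) {
  if (!is.finite(fit_a$t_half) || !is.finite(fit_b$t_half) ||
      fit_a$t_half <= 0 || fit_b$t_half <= 0)
    abort_param("both fits must have positive finite half-lives")
  ratio <- fit_a$t_half / fit_b$t_half
  m <- min(length(fit_a$boot_t_half), length(fit_b$boot_t_half))
  rr <- fit_a$boot_t_half[seq_len(m)] / fit_b$boot_t_half[seq_len(m)]
  rr <- rr[is.finite(rr) & rr > 0]
  ci <- if (length(rr) >= 10)
    stats::quantile(rr, c(0.025, 0.975), names = FALSE) else c(NA_real_, NA_real_)
  list(ratio = ratio, ci = ci, n_pairs = length(rr))
}

#' Track durations for residence analysis
#'
#' Duration of each track as `(frames observed - 1) * frame_interval`;
#' tracks with fewer than two localizations carry no duration and are
#' dropped. Bridged gap frames count toward the elapsed time.
#'
#' @param tracks A `track_table`.
#' @return Numeric vector of durations (s).
#' @export
track_durations <- function(tracks) {
  if (nrow(tracks) == 0) return(numeric(0))
  dt <- attr(tracks, "frame_interval")
  span <- tapply(tracks$frame, tracks$track_id, function(f) max(f) - min(f))
  as.numeric(span[span > 0]) * dt
}
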