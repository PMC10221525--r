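#' Simulate Poisson partitioning of template into droplets
#'
#' Emulates a droplet digital assay (e.g. digital LAMP): a sample at
#' concentration `c_input` is partitioned into `n_droplets` monodisperse
#' droplets of volume `v_droplet`, so the number of template copies per
#' droplet is independent Poisson with mean `lambda = c_input * v_droplet`.
#' Each droplet is an independent yes/no amplification reactor: under the
#' default readout a droplet is positive iff it received at least one copy.
#'
#' @param c_input input template concentration, copies per microlitre (>= 0).
#' @param v_droplet droplet volume in microlitres. Default `5e-4` uL (0.5 nL):
#'   a 10 uL reaction mix split into 2e4 droplets.
#' @param n_droplets number of droplets (>= 1). Default `2e4`.
#' @param seed integer seed; the assay is deterministic given the seed.
#' @param false_negative_rate probability that a template-bearing droplet
#'   fails to amplify (sensitivity-analysis knob; default 0, i.e. perfect
#'   amplification).
#' @return An object of class `"partition_assay"`: a list with fields
#'   `c_input`, `v_droplet`, `n_droplets`, `copies` (integer vector),
#'   `n_positive`, `lambda` (the Poisson mean used), `seed`.
#' @examples
#' a <- simulate_partition_assay(2e3, v_droplet = 5e-4, n_droplets = 1e4, seed = 1)
#' a$n_positive / a$n_droplets      # close to 1 - exp(-1)
#' @export
simulate_partition_assay <- function(c_input, v_droplet = 5e-4, n_droplets = 2e4,
                                     seed = 1L, false_negative_rate = 0) {
  if (!is.numeric(c_input) || length(c_input) != 1L || is.na(c_input) || c_input < 0)
    stop("`c_input` must be a single non-negative number (copies/uL)")
  if (!is.numeric(v_droplet) || v_droplet <= 0)
    stop("`v_droplet` must be positive (uL)")
  if (n_droplets < 1) stop("`n_droplets` must be >= 1")
  if (false_negative_rate < 0 || false_negative_rate > 1)
    stop("`false_negative_rate` must be in [0, 1]")
  n_droplets <- as.integer(n_droplets)
  lambda <- c_input * v_droplet
  set.seed(as.integer(seed))
  copies <- stats::rpois(n_droplets, lambda)
  amplified <- copies >= 1L
  if (false_negative_rate > 0) {
    drop <- stats::runif(n_droplets) < false_negative_rate
    amplified <- amplified & !drop
  }
  out <- structure(list(
    c_input = c_input, v_droplet = v_droplet, n_droplets = n_droplets,
    copies = copies, amplified = amplified,
    n_positive = sum(amplified),
    lambda = lambda, seed = as.integer(seed),
    false_negative_rate = false_negative_rate
  ), class = "partition_assay")
  out
}

#' @export
print.partition_assay <- function(x, ...) {
  cat(sprintf(
    "Partition assay: %d droplets of %.3g uL, input %.4g copies/uL (lambda = %.4g)\n",
    x$n_droplets, x$v_droplet, x$c_input, x$lambda))
  cat(sprintf("  positives: %d / %d (fraction %.4f)\n",
              x$n_positive, x$n_droplets, x$n_positive / x$n_droplets))
  invisible(x)
}

#' Count positive droplets at a copy-number detection threshold
#'
#' A droplet is scored positive when it holds at least `detection_threshold`
#' template copies (and, if the assay was simulated with a false-negative
#' rate, was not dropped by amplification failure; the default threshold 1
#' reproduces the assay's own `n_positive`).
#'
#' @param assay a [simulate_partition_assay()] result.
#' @param detection_threshold minimum copies for a positive call (default 1).
#' @return integer count of positive droplets.
#' @export
classify_positives <- function(assay, detection_threshold = 1L) {
  stopifnot(inherits(assay, "partition_assay"))
  if (detection_threshold < 1) stop("`detection_threshold` must be >= 1")
  pos <- assay$copies >= detection_threshold
  if (detection_threshold == 1L) pos <- pos & assay$amplified
  sum(pos)
}

#' Estimate concentration from a digital readout (Poisson inversion)
#'
#' Inverts the Poisson partition model: with positive fraction
#' `p = n_positive / n_droplets`, the per-droplet mean is
#' `lambda_hat = -log(1 - p)` and the concentration estimate is
#' `lambda_hat / v_droplet`. A delta-method 95% interval is formed on
#' `log(lambda_hat)` (`se(lambda_hat) = sqrt(p / (n (1 - p)))`).
#'
#' @param n_positive number of positive droplets (0 <= n_positive < n_droplets;
#'   an all-positive assay is saturated and has no finite estimate).
#' @param n_droplets total droplets.
#' @param v_droplet droplet volume, uL.
#' @param conf_level confidence level for the interval (default 0.95).
#' @return list with `c_hat` (copies/uL), `lambda_hat`, `ci` (length-2
#'   concentration interval), `n_positive`, `n_droplets`.
#' @export
estimate_concentration <- function(n_positive, n_droplets, v_droplet = 5e-4,
                                   conf_level = 0.95) {
  if (n_positive < 0 || n_droplets < 1) stop("invalid counts")
  if (n_positive >= n_droplets)
    stop("saturated assay: all droplets positive; concentration above dynamic range")
  p <- n_positive / n_droplets
  lambda_hat <- -log1p(-p)
  c_hat <- lambda_hat / v_droplet
  if (n_positive == 0L) {
    ci <- c(0, -log1p(-stats::qbeta(conf_level, 1, n_droplets)) / v_droplet)
    return(list(c_hat = 0, lambda_hat = 0, ci = ci,
                n_positive = n_positive, n_droplets = n_droplets))
  }
  se_lambda <- sqrt(p / (n_droplets * (1 - p)))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci_lambda <- lambda_hat * exp(c(-1, 1) * z * se_lambda / lambda_hat)
  list(c_hat = c_hat, lambda_hat = lambda_hat,
       ci = ci_lambda / v_droplet,
       n_positive = n_positive, n_droplets = n_droplets)
}

#' Fit a serial-dilution calibration line
#'
#' Ordinary least squares of detected on input concentration, both on the
#' log10 scale (digital dilution series span several decades, so the fit is
#' done in log space). The slope of an ideal assay is 1 and the intercept 0.
#'
#' @param c_input input concentrations, copies/uL (all > 0).
#' @param c_detected detected concentrations, copies/uL (all > 0).
#' @return An object of class `"calibration_fit"` wrapping the `lm` fit, with
#'   `slope`, `intercept`, `r_squared`, `points` (data frame) and `scale`
#'   (`"log10"`).
#' @examples
#' f <- fit_calibration(c(10, 100, 1000), c(10, 100, 1000))
#' coef(f)   # slope 1, intercept 0
#' @export
fit_calibration <- function(c_input, c_detected) {
  if (length(c_input) != length(c_detected))
    stop("`c_input` and `c_detected` must have equal length")
  if (length(c_input) < 3) stop("need at least 3 calibration points")
  if (any(c_input <= 0) || any(c_detected <= 0))
    stop("concentrations must be positive for a log10-scale fit")
  pts <- data.frame(log10_input = log10(c_input),
                    log10_detected = log10(c_detected))
  fit <- stats::lm(log10_detected ~ log10_input, data = pts)
  # summary.lm warns on exact fits (zero residual variance); R^2 is still 1
  s <- suppressWarnings(summary(fit))
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = s$r.squared,
    scale = "log10",
    points = data.frame(c_input = c_input, c_detected = c_detected, pts),
    lm = fit
  ), class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("Dilution-series calibration (log10 scale, %d points)\n",
              nrow(x$points)))
  cat(sprintf("  Y = %.4f X %+.4f   (R^2 = %.5f)\n",
              x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' @export
coef.calibration_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
summary.calibration_fit <- function(object, ...) summary(object$lm, ...)

#' Predict detected concentration for new input concentrations
#' @param object a [fit_calibration()] result.
#' @param newdata numeric vector of input concentrations (copies/uL), or
#'   omitted for the fitted points.
#' @param ... unused.
#' @return predicted detected concentrations on the linear scale (copies/uL).
#' @export
predict.calibration_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(unname(10^stats::fitted(object$lm)))
  stopifnot(is.numeric(newdata), all(newdata > 0))
  unname(10^stats::predict(object$lm,
                           newdata = data.frame(log10_input = log10(newdata))))
}

#' @export
residuals.calibration_fit <- function(object, ...) stats::residuals(object$lm)

#' Run a simulated dilution-series calibration end to end
#'
#' For each input concentration, simulates a partition assay, estimates the
#' detected concentration by Poisson inversion, and fits the log10-log10
#' calibration line.
#'
#' @param concentrations input series, copies/uL; default the five-point
#'   series 10, 1e2, 1e3, 2e3, 1e4.
#' @param v_droplet,n_droplets as in [simulate_partition_assay()].
#' @param seed integer seed (one stream drives all points).
#' @return list with `table` (per-point data frame: c_input, n_positive,
#'   c_detected) and `fit` (a `calibration_fit`).
#' @export
run_dilution_series <- function(concentrations = c(10, 1e2, 1e3, 2e3, 1e4),
                                v_droplet = 5e-4, n_droplets = 2e4, seed = 1L) {
  stopifnot(all(concentrations > 0))
  rows <- lapply(seq_along(concentrations), function(i) {
    a <- simulate_partition_assay(concentrations[i], v_droplet, n_droplets,
                                  seed = as.integer(seed) + i - 1L)
    est <- estimate_concentration(a$n_positive, a$n_droplets, v_droplet)
    data.frame(c_input = concentrations[i], n_positive = a$n_positive,
               c_detected = est$c_hat)
  })
  tab <- do.call(rbind, rows)
  list(table = tab, fit = fit_calibration(tab$c_input, tab$c_detected))
}

#' Detection-probability curve and limit of detection
#'
#' For each concentration in `c_grid`, simulates `n_replicates` assays and
#' scores a replicate as "detected" when it yields at least `k_min` positive
#' droplets (the minimal count that distinguishes a sample from the
#' no-template control). Reports the per-concentration detection probability
#' and the smallest grid concentration detected with probability >= `prob`.
#'
#' @param c_grid concentrations to probe, copies/uL (may include 0 for NTC).
#' @param v_droplet,n_droplets as in [simulate_partition_assay()].
#' @param n_replicates replicates per concentration (default 20).
#' @param k_min positive-droplet count needed to call detection (default 3).
#' @param prob required detection probability for the LOD (default 0.95).
#' @param seed integer seed.
#' @return list with `curve` (data frame: c_input, detect_prob) and `lod`
#'   (smallest concentration with detect_prob >= `prob`, or `NA` if none).
#' @export
assess_lod <- function(c_grid, v_droplet = 5e-4, n_droplets = 2e4,
                       n_replicates = 20L, k_min = 3L, prob = 0.95,
                       seed = 1L) {
  stopifnot(all(c_grid >= 0), k_min >= 1, n_replicates >= 1)
  c_grid <- sort(unique(c_grid))
  seed <- as.integer(seed)
  detect <- vapply(seq_along(c_grid), function(i) {
    hits <- vapply(seq_len(n_replicates), function(r) {
      a <- simulate_partition_assay(c_grid[i], v_droplet, n_droplets,
                                    seed = seed + 1000L * i + r)
      a$n_positive >= k_min
    }, logical(1))
    mean(hits)
  }, numeric(1))
  curve <- data.frame(c_input = c_grid, detect_prob = detect)
  ok <- curve$c_input[curve$detect_prob >= prob & curve$c_input > 0]
  list(curve = curve, lod = if (length(ok)) min(ok) else NA_real_,
       k_min = as.integer(k_min), prob = prob)
}
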