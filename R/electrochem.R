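# Amperometric sensor model and sealed-chamber depletion kinetics.
#
# The platinum tip held at a small bias (0.85 V) oxidizes ROS/RNS; current
# is linear in concentration (calibration), and once the probe is inside a
# cell the cell behaves as a sealed chamber: V dC/dt = -A C, so the current
# decays as i(t) = baseline + i0 exp(-t/tau) with tau = V/A.

#' Uniformly sampled amperometric current trace
#'
#' @param current numeric vector of currents in pA.
#' @param sample_rate sampling rate in Hz (default 1000).
#' @param position optional synchronized probe-position channel in um
#'   (same length as `current`).
#' @param annotations data.frame with columns `time` (s) and `label`.
#' @return an object of class `nt_trace`.
#' @export
nt_trace <- function(current, sample_rate = 1000,
                     position = NULL, annotations = NULL) {
  stopifnot_scalar(sample_rate, "sample_rate", positive = TRUE)
  current <- as.numeric(current)
  if (!is.null(position) && length(position) != length(current))
    stop("position channel must match current length", call. = FALSE)
  if (is.null(annotations))
    annotations <- data.frame(time = numeric(), label = character())
  structure(list(current = current, sample_rate = sample_rate,
                 position = position, annotations = annotations),
            class = "nt_trace")
}

#' @rdname nt_trace
#' @param x an `nt_trace`.
#' @return `trace_time()`: the time axis in s (first sample at t = 0).
#' @export
trace_time <- function(x) (seq_along(x$current) - 1) / x$sample_rate

#' Linear sensor calibration with selectivity weights
#'
#' @param slope sensitivity in pA per mM of the primary analyte (H2O2).
#' @param intercept background current in pA.
#' @param bias_voltage electrode bias in V (default 0.85).
#' @param selectivity_weights named numeric vector of relative responses;
#'   the primary analyte `h2o2` must have weight 1.
#' @return an object of class `nt_cal`.
#' @export
sensor_calibration <- function(slope = 25, intercept = 0,
                               bias_voltage = 0.85,
                               selectivity_weights = c(h2o2 = 1,
                                                       k = 0.005,
                                                       na = 0.005,
                                                       ascorbate = 0.03,
                                                       glucose = 0.01)) {
  stopifnot_scalar(slope, "slope", positive = TRUE)
  if (is.null(names(selectivity_weights)) ||
      !"h2o2" %in% names(selectivity_weights) ||
      selectivity_weights[["h2o2"]] != 1)
    stop("selectivity_weights must be named and have h2o2 = 1", call. = FALSE)
  structure(list(slope = slope, intercept = intercept,
                 bias_voltage = bias_voltage,
                 selectivity_weights = selectivity_weights),
            class = "nt_cal")
}

#' Sensor current for a concentration or analyte mixture
#'
#' `current = slope * sum(w_s * C_s) + intercept`; a bare numeric
#' concentration is the primary analyte, a named vector is a mixture
#' weighted by the calibration's selectivity weights.
#'
#' @param cal an [sensor_calibration()].
#' @param concentration mM; numeric scalar/vector (primary analyte) or a
#'   named vector of analyte concentrations.
#' @return current in pA.
#' @export
calibration_current <- function(cal, concentration) {
  stopifnot(inherits(cal, "nt_cal"))
  if (any(concentration < 0))
    stop("concentration must be >= 0", call. = FALSE)
  if (!is.null(names(concentration)) && all(nzchar(names(concentration)))) {
    w <- cal$selectivity_weights[names(concentration)]
    if (any(is.na(w)))
      stop("unknown analyte(s): ",
           paste(names(concentration)[is.na(w)], collapse = ", "),
           call. = FALSE)
    cal$slope * sum(w * concentration) + cal$intercept
  } else {
    cal$slope * concentration + cal$intercept
  }
}

#' Simulate a sealed-chamber depletion trace
#'
#' `i(t) = baseline + i0 exp(-t/tau) + N(0, noise_sd)`, the solution of
#' the sealed-chamber model `V dC/dt = -A C` with `i - baseline`
#' proportional to `A C` and `tau = V/A`.
#'
#' @param i0 initial depletion amplitude in pA.
#' @param tau time constant in s (default 12 s, the average cell value).
#' @param baseline baseline current in pA.
#' @param window trace duration in s.
#' @param noise_sd Gaussian noise SD in pA.
#' @param seed integer seed (NULL: use current RNG state).
#' @param sample_rate Hz.
#' @return an [nt_trace()].
#' @export
simulate_depletion_trace <- function(i0 = 20, tau = 12, baseline = 0,
                                     window = 60, noise_sd = 0,
                                     seed = NULL, sample_rate = 1000) {
  stopifnot_scalar(window, "window", positive = TRUE)
  stopifnot_scalar(tau, "tau", positive = TRUE)
  n <- round(window * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  i <- baseline + i0 * exp(-t / tau)
  if (noise_sd > 0)
    i <- i + with_seed(seed, stats::rnorm(n, sd = noise_sd))
  nt_trace(i, sample_rate)
}

#' Fit the exponential depletion model to a trace
#'
#' Nonlinear least squares of `baseline + i0 exp(-t/tau)` over the first
#' `window` seconds.  Start values come from a tail-estimated baseline and
#' a log-linear regression; `nls` refines them (port algorithm), with a
#' Nelder-Mead fallback on the residual sum of squares.
#'
#' @param trace an [nt_trace()].
#' @param window fit window in s (default: whole trace); must contain at
#'   least 100 samples.
#' @param sensitivity electrochemical sensitivity A (arbitrary units) used
#'   for `volume_estimate = A * tau`.
#' @param cal optional [sensor_calibration()] to convert `i0` to an initial
#'   concentration `c0 = i0 / slope`.
#' @return an object of class `nt_depfit`: list with `i0`, `tau`,
#'   `baseline`, `c0`, `volume_estimate`, `rss`.
#' @export
fit_depletion <- function(trace, window = NULL, sensitivity = 1, cal = NULL) {
  stopifnot(inherits(trace, "nt_trace"))
  t <- trace_time(trace)
  i <- trace$current
  if (!is.null(window) && is.finite(window)) {
    keep <- t <= window
    t <- t[keep]; i <- i[keep]
  }
  if (length(i) < 100)
    stop("fit window must contain at least 100 samples", call. = FALSE)
  # normalize the current scale so the fit is exactly scale-equivariant
  # (tau-hat depends only on the shape of the trace)
  cscale <- max(abs(i))
  if (cscale == 0) cscale <- 1
  i <- i / cscale
  # start values
  b0 <- stats::median(i[t >= max(t) * 0.9])
  amp <- i[1] - b0
  if (amp <= 0) amp <- max(i) - b0
  pos <- which(i - b0 > 0.05 * amp & t < max(t) * 0.8)
  tau0 <- if (length(pos) > 10) {
    lf <- stats::lm(log(i[pos] - b0) ~ t[pos])
    max(-1 / stats::coef(lf)[2], max(t) / 100)
  } else max(t) / 5
  if (!is.finite(tau0) || tau0 <= 0) tau0 <- max(t) / 5
  dat <- data.frame(t = t, i = i)
  fit <- tryCatch(
    stats::nls(i ~ b + a * exp(-t / tau), data = dat,
               start = list(b = b0, a = amp, tau = tau0),
               control = stats::nls.control(maxiter = 200, warnOnly = FALSE),
               algorithm = "port", lower = c(-Inf, 1e-12, 1e-6)),
    error = function(e) NULL)
  if (is.null(fit)) {
    rssf <- function(p) sum((i - (p[1] + exp(p[2]) * exp(-t / exp(p[3]))))^2)
    op <- stats::optim(c(b0, log(max(amp, 1e-6)), log(tau0)), rssf,
                       control = list(maxit = 5000, reltol = 1e-14))
    if (!op$convergence %in% c(0L))
      stop("depletion fit failed to converge", call. = FALSE)
    est <- c(b = op$par[1], a = exp(op$par[2]), tau = exp(op$par[3]))
    rss <- op$value
  } else {
    est <- stats::coef(fit)
    rss <- sum(stats::resid(fit)^2)
  }
  if (est[["tau"]] <= 0)
    stop("rejected fit: nonpositive time constant", call. = FALSE)
  structure(list(i0 = unname(est[["a"]]) * cscale,
                 tau = unname(est[["tau"]]),
                 baseline = unname(est[["b"]]) * cscale,
                 c0 = if (!is.null(cal))
                        unname(est[["a"]]) * cscale / cal$slope
                      else NA_real_,
                 volume_estimate = sensitivity * unname(est[["tau"]]),
                 rss = rss * cscale^2),
            class = "nt_depfit")
}

# -- zero-phase low-pass -----------------------------------------------------

# 2nd-order Butterworth low-pass biquad coefficients (bilinear transform)
butter2 <- function(cutoff, sample_rate) {
  K <- tan(pi * cutoff / sample_rate)
  norm <- 1 / (1 + sqrt(2) * K + K^2)
  list(b = c(K^2, 2 * K^2, K^2) * norm,
       a = c(2 * (K^2 - 1), (1 - sqrt(2) * K + K^2)) * norm)
}

biquad_filter <- function(x, co) {
  v <- stats::filter(c(x[1], x[1], x), co$b, sides = 1)[-(1:2)]
  as.numeric(stats::filter(v, -co$a, method = "recursive",
                           init = c(x[1], x[1])))
}

#' Zero-phase low-pass filter
#'
#' Forward-backward 2nd-order Butterworth: squared magnitude response,
#' zero phase shift, exact unit DC gain.  Edges are reflection-padded.
#'
#' @param trace an [nt_trace()].
#' @param cutoff -3 dB cutoff in Hz (per pass); must lie in
#'   `(0, sample_rate/2)`.  Default 50 Hz.
#' @return the filtered `nt_trace`.
#' @export
filter_trace <- function(trace, cutoff = 50) {
  stopifnot(inherits(trace, "nt_trace"))
  fs <- trace$sample_rate
  if (!(cutoff > 0 && cutoff < fs / 2))
    stop("cutoff must be in (0, sample_rate/2)", call. = FALSE)
  x <- trace$current
  n <- length(x)
  np <- min(n - 1, ceiling(3 * fs / cutoff))
  pad_l <- 2 * x[1] - x[seq(np + 1, 2)]
  pad_r <- 2 * x[n] - x[seq(n - 1, n - np)]
  xx <- c(pad_l, x, pad_r)
  co <- butter2(cutoff, fs)
  y <- biquad_filter(xx, co)
  y <- rev(biquad_filter(rev(y), co))
  trace$current <- y[(np + 1):(np + n)]
  trace
}

# -- detectors ---------------------------------------------------------------

#' Detect membrane penetration from the current spike
#'
#' The median-filtered current derivative is compared against
#' `k * MAD(derivative)`; a sustained positive excursion marks insertion
#' ("a sudden increase in current").  With a synchronized position channel
#' and a `contact` annotation, the insertion deformation is the probe
#' displacement between contact and penetration; the withdrawal
#' deformation is the displacement from the start of withdrawal (a
#' `withdraw` annotation) until the current returns to within
#' `2 * noise SD` of the pre-insertion baseline.
#'
#' @param trace an [nt_trace()].
#' @param k MAD multiplier for the derivative threshold (default 6).
#' @param median_window odd samples for the median pre-filter (default 11).
#' @return an object of class `nt_penetration`: list with `detected`,
#'   `t_insert`, `t_withdraw`, `insertion_deformation`,
#'   `withdrawal_deformation` (um; NA without position/annotations).
#' @export
detect_penetration <- function(trace, k = 6, median_window = 11) {
  stopifnot(inherits(trace, "nt_trace"))
  t <- trace_time(trace)
  x <- stats::runmed(trace$current, median_window)
  d <- diff(x) * trace$sample_rate
  # noise scale from the raw derivative: the median pre-filter suppresses
  # noise in d, so thresholding against mad(d) would fire on residual
  # noise; the raw-derivative MAD is the honest per-sample noise scale
  draw <- diff(trace$current) * trace$sample_rate
  s <- stats::mad(draw)
  if (s == 0) s <- stats::sd(draw)
  res <- list(detected = FALSE, t_insert = NA_real_, t_withdraw = NA_real_,
              insertion_deformation = NA_real_,
              withdrawal_deformation = NA_real_)
  class(res) <- "nt_penetration"
  if (is.na(s) || s == 0) return(res)         # flat noiseless trace
  up <- which(d > k * s)
  if (length(up) == 0) return(res)
  res$detected <- TRUE
  i_ins <- up[1]
  res$t_insert <- t[i_ins + 1]
  ann <- trace$annotations
  t_contact <- ann$time[ann$label == "contact"][1]
  t_wstart <- ann$time[ann$label == "withdraw"][1]
  pos <- trace$position
  if (!is.null(pos) && length(t_contact) == 1 && !is.na(t_contact)) {
    ic <- max(1, round(t_contact * trace$sample_rate) + 1)
    res$insertion_deformation <- abs(pos[i_ins + 1] - pos[ic])
  }
  if (!is.na(t_wstart)) {
    iw <- min(length(x), round(t_wstart * trace$sample_rate) + 1)
    pre <- trace$current[seq_len(max(i_ins - round(0.05 * trace$sample_rate), 2))]
    base <- stats::median(pre)
    nsd <- stats::mad(diff(pre)) / sqrt(2)
    if (!is.finite(nsd) || nsd == 0) nsd <- 1e-9
    after <- seq(iw, length(x))
    back <- after[x[after] <= base + 2 * nsd]
    if (length(back) > 0) {
      res$t_withdraw <- t[back[1]]
      if (!is.null(pos))
        res$withdrawal_deformation <- abs(pos[back[1]] - pos[iw])
    }
  }
  res
}

#' Threshold detector for mitochondrial proximity
#'
#' TRUE when the (baseline-corrected, low-pass-filtered) current stays
#' above `threshold` for at least `debounce` seconds; `t_detect` is the
#' first sample of the sustained crossing.
#'
#' @param trace an [nt_trace()] (already baseline-corrected).
#' @param threshold detection threshold in pA (default 8).
#' @param debounce required hold time in s (default 0.05).
#' @param cutoff low-pass cutoff in Hz applied before thresholding
#'   (NULL: no filtering).
#' @return list `(detected, t_detect)`.
#' @export
detect_mitochondrion <- function(trace, threshold = 8, debounce = 0.05,
                                 cutoff = 50) {
  stopifnot(inherits(trace, "nt_trace"))
  x <- if (is.null(cutoff)) trace$current
       else filter_trace(trace, cutoff)$current
  need <- max(1L, ceiling(debounce * trace$sample_rate))
  above <- x > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hit <- which(r$values & r$lengths >= need)
  if (length(hit) == 0) return(list(detected = FALSE, t_detect = NA_real_))
  list(detected = TRUE,
       t_detect = (starts[hit[1]] - 1) / trace$sample_rate)
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' @param pairs two-column matrix/data.frame (current pA, fluorescence
#'   a.u.) or a list of length-2 pairs.
#' @param conf_level confidence level (default 0.95).
#' @return list with `r`, `ci` (length 2), `n`.
#' @export
correlate_current_fluorescence <- function(pairs, conf_level = 0.95) {
  if (is.list(pairs) && !is.data.frame(pairs))
    pairs <- do.call(rbind, lapply(pairs, unlist))
  pairs <- as.matrix(pairs)
  if (nrow(pairs) < 3) stop("need at least 3 pairs", call. = FALSE)
  x <- pairs[, 1]; y <- pairs[, 2]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined", call. = FALSE)
  n <- length(x)
  r <- stats::cor(x, y)
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  q <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(r = r, ci = tanh(c(z - q * se, z + q * se)), n = n)
}
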