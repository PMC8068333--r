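## Morlet-Gabor continuous wavelet transform, spectrograms, instantaneous
## frequencies, and artifact (jump) filtering.
##
## The mother wavelet is psi(t) = pi^(-1/4) exp(i w0 t) exp(-t^2 / (2 sigma^2)).
## Its wavelength at scale s is lambda = s * 4 pi / (w0 + sqrt(2 + w0^2)), so
## frequency and scale are related by nu = factor / s with
## factor = (w0 + sqrt(2 + w0^2)) / (4 pi); at w0 = 2 pi the factor is 1.01.

#' Morlet-Gabor wavelet parameters
#'
#' @param omega0 main plane-wave angular frequency (default `2*pi`)
#' @param sigma Gaussian window width parameter (default 8)
#' @return object of class `wavelet_params`
#' @export
wavelet_params <- function(omega0 = 2 * pi, sigma = 8) {
  if (omega0 <= 0 || sigma <= 0) .stopf("omega0 and sigma must be > 0")
  structure(list(omega0 = omega0, sigma = sigma), class = "wavelet_params")
}

#' Morlet-Gabor mother wavelet
#'
#' @param t dimensionless time (already scaled by `(t - tau)/s`)
#' @param params a [wavelet_params()]
#' @return complex value(s)
#' @export
morlet_gabor <- function(t, params = wavelet_params()) {
  pi^(-0.25) * exp(1i * params$omega0 * t - t^2 / (2 * params$sigma^2))
}

#' Frequency-scale conversion factor
#'
#' The product `nu * s` relating a scale to its effective frequency. Two
#' conventions coexist in the literature and differ by about 1% at
#' `omega0 = 2*pi`:
#'
#' * `"wavelength"`: from the Fourier-wavelength relation
#'   `lambda = s * 4 pi / (omega0 + sqrt(2 + omega0^2))`, giving
#'   `nu * s = 1.01` at `omega0 = 2*pi` (the quoted effective frequency
#'   `nu = 1.01/s`).
#' * `"ridge"`: the scale maximizing the wavelet modulus of a pure cosine
#'   satisfies `s * omega = omega0` (up to O(1/(sigma^2 omega0^2))), so the
#'   frequency read off a modulus ridge is `nu = (omega0 / 2 pi) / s` --
#'   exactly `1/s` at `omega0 = 2*pi`. Instantaneous frequencies use this
#'   convention; it is what makes single-tone inputs come back at their
#'   Fourier frequency.
#'
#' @param params a [wavelet_params()]
#' @param convention `"wavelength"` or `"ridge"`
#' @return dimensionless factor
#' @export
wavelet_frequency_factor <- function(params = wavelet_params(),
                                     convention = c("wavelength", "ridge")) {
  convention <- match.arg(convention)
  w0 <- params$omega0
  switch(convention,
         wavelength = (w0 + sqrt(2 + w0^2)) / (4 * pi),
         ridge = w0 / (2 * pi))
}

#' Convert a wavelet scale (fs) to a wavenumber (cm^-1), and back
#'
#' @param s scale in fs
#' @param params a [wavelet_params()]
#' @param convention see [wavelet_frequency_factor()]; ridge extraction uses
#'   `"ridge"`, the nominal wavelength relation is `"wavelength"`
#' @return wavenumber in cm^-1
#' @export
scale_to_frequency <- function(s, params = wavelet_params(),
                               convention = c("wavelength", "ridge")) {
  if (any(s <= 0)) .stopf("scale must be > 0")
  wavelet_frequency_factor(params, convention) / (s * .c_cm_fs)
}

#' @rdname scale_to_frequency
#' @param nu_cm wavenumber in cm^-1
#' @export
frequency_to_scale <- function(nu_cm, params = wavelet_params(),
                               convention = c("wavelength", "ridge")) {
  if (any(nu_cm <= 0)) .stopf("frequency must be > 0")
  wavelet_frequency_factor(params, convention) / (nu_cm * .c_cm_fs)
}

#' Logarithmic scale grid covering a wavenumber band
#'
#' 512 log-spaced scales over 1000-2200 cm^-1 by default, giving about 0.15%
#' frequency spacing around the amide I band.
#'
#' @param band length-2 cm^-1 interval
#' @param n number of scales
#' @param params a [wavelet_params()]
#' @return increasing vector of scales in fs
#' @export
default_scale_grid <- function(band = c(1000, 2200), n = 512,
                               params = wavelet_params()) {
  s <- frequency_to_scale(sort(band, decreasing = TRUE), params, "ridge")
  exp(seq(log(s[1]), log(s[2]), length.out = n))
}

## one scale row of the discrete transform:
## W(n) = s^(-1/2) * sum_m f(n + m) psi*(m dt / s), via FFT cross-correlation.
## Kernel support truncated at |m dt / s| <= 7 sigma (envelope < 3e-11),
## or the full signal span if shorter.
.cwt_row <- function(fpad, np, n, dt, s, params) {
  half <- min(n - 1L, ceiling(7 * params$sigma * s / dt))
  m <- (-half):half
  g <- morlet_gabor(m * dt / s, params)    # unconjugated; conjugation in FFT
  gc <- complex(length.out = np)
  gc[1 + (m %% np)] <- g
  w <- stats::fft(fpad * Conj(stats::fft(gc)), inverse = TRUE) / np
  w[seq_len(n)] / sqrt(s)
}

#' Continuous wavelet transform (Morlet-Gabor)
#'
#' Discrete transform `W(n, s) = sum_n' f(n' dt) psi*((n' - n) dt / s)` with
#' `1/sqrt(|s|)` normalization, evaluated over a scale grid. The signal is
#' mean-centered first. Frames within one envelope half-width
#' (`sigma * s / dt` samples) of either edge lie inside the cone of
#' influence and are flagged, not discarded.
#'
#' @param signal numeric vector (e.g. a C=O bond-length series)
#' @param dt timestep in fs
#' @param scales increasing scale grid in fs (default [default_scale_grid()])
#' @param params a [wavelet_params()]
#' @return object of class `spectrogram`: `times` (fs), `scales` (fs),
#'   `frequency` (cm^-1 per scale), complex `W` (scales x time), `power`
#'   = |W|^2, and the per-scale cone-of-influence half-width `coi` (frames)
#' @export
cwt <- function(signal, dt, scales = default_scale_grid(params = params),
                params = wavelet_params()) {
  n <- length(signal)
  if (n < 4) .stopf("signal too short")
  nyq <- 1 / (2 * dt * .c_cm_fs)
  if (any(scale_to_frequency(scales, params, "ridge") > nyq))
    .stopf("scale grid extends beyond the Nyquist wavenumber (%.0f cm^-1)", nyq)
  f <- signal - mean(signal)
  np <- 2^ceiling(log2(n + 2 * min(n - 1L, ceiling(7 * params$sigma * max(scales) / dt)) + 1))
  fpad <- stats::fft(c(f, rep(0, np - n)))
  W <- matrix(0i, nrow = length(scales), ncol = n)
  for (j in seq_along(scales))
    W[j, ] <- .cwt_row(fpad, np, n, dt, scales[j], params)
  structure(list(times = (seq_len(n) - 1) * dt, scales = scales,
                 frequency = scale_to_frequency(scales, params, "ridge"),
                 W = W, power = Mod(W)^2, dt = dt, params = params,
                 coi = ceiling(params$sigma * scales / dt)),
            class = "spectrogram")
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("<spectrogram> %d scales x %d frames, %.0f-%.0f cm^-1\n",
              length(x$scales), length(x$times),
              min(x$frequency), max(x$frequency)))
  invisible(x)
}

.instfreq_series <- function(frequency, valid, edge, times, band) {
  structure(list(frequency = frequency, valid = valid, edge = edge,
                 times = times, band = band),
            class = "instfreq_series")
}

#' @export
print.instfreq_series <- function(x, ...) {
  cat(sprintf("<instfreq_series> %d frames, %d valid, band %.0f-%.0f cm^-1\n",
              length(x$frequency), sum(x$valid), x$band[1], x$band[2]))
  invisible(x)
}

## parabolic refinement of the ridge in log-scale space
.refine_ridge <- function(i_best, p_lo, p_best, p_hi, scales, params) {
  nsc <- length(scales)
  delta <- numeric(length(i_best))
  ok <- i_best > 1 & i_best < nsc & is.finite(p_lo) & is.finite(p_hi)
  den <- p_lo - 2 * p_best + p_hi
  ok <- ok & den < 0
  delta[ok] <- 0.5 * (p_lo[ok] - p_hi[ok]) / den[ok]
  delta <- pmax(pmin(delta, 0.5), -0.5)
  ratio <- log(scales[2] / scales[1])      # uniform in log space
  s_star <- scales[i_best] * exp(delta * ratio)
  scale_to_frequency(s_star, params, "ridge")
}

#' Instantaneous frequency from a spectrogram
#'
#' Per time step, the frequency of the scale maximizing the wavelet modulus
#' `|W(n, s)|^2`, refined by parabolic interpolation across log-spaced scales.
#' Frames inside the cone of influence of the ridge scale are marked
#' `edge = TRUE` (lower confidence) but remain valid.
#'
#' @param sg a `spectrogram` from [cwt()]
#' @return an `instfreq_series`: `frequency` (cm^-1), `valid`, `edge`, `times`
#' @export
instantaneous_frequency <- function(sg) {
  n <- length(sg$times); nsc <- length(sg$scales)
  i_best <- apply(sg$power, 2, which.max)
  p_best <- sg$power[cbind(i_best, seq_len(n))]
  p_lo <- ifelse(i_best > 1, sg$power[cbind(pmax(i_best - 1, 1), seq_len(n))], NA)
  p_hi <- ifelse(i_best < nsc, sg$power[cbind(pmin(i_best + 1, nsc), seq_len(n))], NA)
  freq <- .refine_ridge(i_best, p_lo, p_best, p_hi, sg$scales, sg$params)
  coi <- sg$coi[i_best]
  fr <- seq_len(n)
  edge <- fr <= coi | fr > n - coi
  band <- range(sg$frequency)
  .instfreq_series(freq, valid = rep(TRUE, n), edge = edge,
                   times = sg$times, band = band)
}

#' Instantaneous frequency directly from a signal (streaming ridge)
#'
#' Equivalent to `instantaneous_frequency(cwt(...))` but never materializes
#' the full scale-time grid, so it handles long trajectories in bounded
#' memory. Used by the pipeline.
#'
#' @inheritParams cwt
#' @return an `instfreq_series`
#' @export
wavelet_ridge <- function(signal, dt, scales = default_scale_grid(params = params),
                          params = wavelet_params()) {
  n <- length(signal)
  if (n < 4) .stopf("signal too short")
  nyq <- 1 / (2 * dt * .c_cm_fs)
  if (any(scale_to_frequency(scales, params, "ridge") > nyq))
    .stopf("scale grid extends beyond the Nyquist wavenumber (%.0f cm^-1)", nyq)
  f <- signal - mean(signal)
  np <- 2^ceiling(log2(n + 2 * min(n - 1L, ceiling(7 * params$sigma * max(scales) / dt)) + 1))
  fpad <- stats::fft(c(f, rep(0, np - n)))
  nsc <- length(scales)
  i_best <- rep(1L, n); p_best <- rep(-Inf, n)
  p_lo <- rep(NA_real_, n); p_hi <- rep(NA_real_, n)
  p_prev <- rep(NA_real_, n)
  for (j in seq_len(nsc)) {
    p <- Mod(.cwt_row(fpad, np, n, dt, scales[j], params))^2
    hit <- p > p_best
    p_hi[i_best == j - 1L & !hit] <- p[i_best == j - 1L & !hit]
    i_best[hit] <- j
    p_best[hit] <- p[hit]
    p_lo[hit] <- p_prev[hit]
    p_hi[hit] <- NA_real_
    p_prev <- p
  }
  freq <- .refine_ridge(i_best, p_lo, p_best, p_hi, scales, params)
  coi <- ceiling(params$sigma * scales / dt)[i_best]
  fr <- seq_len(n)
  edge <- fr <= coi | fr > n - coi
  .instfreq_series(freq, valid = rep(TRUE, n), edge = edge,
                   times = (seq_len(n) - 1) * dt,
                   band = range(scale_to_frequency(scales, params, "ridge")))
}

#' Filter artifact jumps out of an instantaneous-frequency series
#'
#' Wavelet ridges over C=O bond-length signals occasionally jump to very low
#' values when the local water structure rearranges; entries below `floor`
#' are treated as artifacts: they are invalidated, linearly interpolated
#' over, and the result is smoothed with a rolling median.
#'
#' @param series an `instfreq_series`
#' @param floor lowest physical frequency, cm^-1 (default 1500)
#' @param smooth rolling-median window in frames (odd; 1 = no smoothing)
#' @return the filtered `instfreq_series`
#' @export
filter_jumps <- function(series, floor = 1500, smooth = 25) {
  f <- series$frequency
  bad <- !is.finite(f) | f < floor
  if (all(bad)) .stopf("all %d entries fall below the %g cm^-1 floor", length(f), floor)
  f[bad] <- NA_real_
  if (any(bad))
    f <- stats::approx(seq_along(f), f, xout = seq_along(f), rule = 2)$y
  if (smooth > 1) {
    k <- if (smooth %% 2 == 1) smooth else smooth + 1
    k <- min(k, if (length(f) %% 2 == 1) length(f) else length(f) - 1)
    if (k >= 3) f <- as.numeric(stats::runmed(f, k, endrule = "median"))
  }
  out <- series
  out$frequency <- f
  out$valid <- series$valid & !bad
  out$filtered <- bad
  out
}

#' Windowed mean of an instantaneous-frequency series
#'
#' @param series an `instfreq_series`
#' @param window length-2 time interval in fs (start inclusive, end exclusive)
#' @return mean frequency over valid frames in the window, cm^-1
#' @export
instfreq_window_mean <- function(series, window) {
  sel <- series$times >= window[1] & series$times < window[2] & series$valid
  if (!any(sel)) .stopf("no valid frames in window [%g, %g) fs", window[1], window[2])
  mean(series$frequency[sel])
}
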