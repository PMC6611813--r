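# Time-domain trajectories -> spectra -> peak tables.

#' Fourier-transform a trajectory into a spectrum
#'
#' Applies optional exponential apodization and zero filling, then a discrete
#' Fourier transform. Real signals yield a one-sided spectrum (0..Nyquist) by
#' default; complex FIDs a two-sided one (centered on zero offset). The
#' frequency resolution before zero filling is 1/(N*dwell) and the transform
#' is linear in the input signal.
#'
#' @param traj An `nmr_trajectory` (see [propagate()]) or a list with
#'   elements `signal` and `dwell_s`.
#' @param apodization_s Exponential apodization rate lambda in s^-1 (the
#'   signal is multiplied by exp(-lambda t); this adds lambda/pi Hz to every
#'   Lorentzian FWHH). Default: 1/T_acq, matched to the acquisition length.
#'   Use 0 to disable.
#' @param zero_fill Integer zero-filling factor (1 = none).
#' @param two_sided Force a two-sided (fft-shifted) axis; defaults to TRUE
#'   for complex signals and FALSE for real ones.
#' @return Object of class `nmr_spectrum` with `freq_Hz`, complex
#'   `amplitude`, and processing metadata.
#' @export
fft_spectrum <- function(traj, apodization_s = NULL, zero_fill = 1L,
                         two_sided = NULL) {
  s <- traj$signal
  if (is.null(s) || length(s) == 0)
    stop("trajectory has no signal", call. = FALSE)
  dt <- traj$dwell_s
  N <- length(s)
  if (is.null(apodization_s)) apodization_s <- 1 / (N * dt)
  t <- dt * (seq_len(N) - 1)
  s <- s * exp(-apodization_s * t)
  zero_fill <- max(1L, as.integer(zero_fill))
  Np <- N * zero_fill
  if (Np > N) s <- c(s, rep(0 + 0i, Np - N))
  S <- stats::fft(s)
  k <- seq_len(Np) - 1
  was_complex <- is.complex(traj$signal) &&
    max(abs(Im(traj$signal))) > 1e-12 * max(abs(traj$signal), 1e-300)
  if (is.null(two_sided)) two_sided <- was_complex
  if (two_sided) {
    k[k >= ceiling(Np / 2)] <- k[k >= ceiling(Np / 2)] - Np
    freq <- k / (Np * dt)
    ord <- order(freq)
    freq <- freq[ord]
    S <- S[ord]
  } else {
    keep <- seq_len(floor(Np / 2) + 1)
    freq <- k[keep] / (Np * dt)
    S <- S[keep]
  }
  structure(
    list(freq_Hz = freq, amplitude = S, apodization_s = apodization_s,
         zero_fill = zero_fill, dwell_s = dt, n_time = N,
         two_sided = two_sided),
    class = "nmr_spectrum"
  )
}

#' @export
print.nmr_spectrum <- function(x, ...) {
  cat(sprintf(
    "<nmr_spectrum> %d points, %.4g Hz resolution, %s, apodization %.3g s^-1\n",
    length(x$freq_Hz), 1 / (x$n_time * x$dwell_s),
    if (x$two_sided) "two-sided" else "one-sided", x$apodization_s))
  invisible(x)
}

#' Locate and characterize spectral peaks
#'
#' Finds local maxima of the chosen spectrum representation above a relative
#' threshold, excluding a window around zero frequency (where the static
#' magnetization of the sample produces a non-oscillating component). Peak
#' positions are refined by three-point parabolic interpolation, FWHH by
#' linear interpolation at half height, and the integral by the trapezoid
#' rule over the peak's support (down to 1% of the apex or the nearest local
#' minimum).
#'
#' @param spectrum An `nmr_spectrum` from [fft_spectrum()].
#' @param min_rel_amplitude Threshold relative to the tallest in-window
#'   point (default 0.05).
#' @param exclude_hz Half-width of the zero-frequency exclusion window in Hz
#'   (default 2; set 0 to keep everything, e.g. for high-field spectra
#'   centered on the offset).
#' @param mode `"magnitude"` (default; robust to protocol-dependent phase) or
#'   `"real"` (absorption part, for phased spectra).
#' @return Data frame with columns `position_Hz`, `amplitude`, `fwhh_Hz`,
#'   `integral`, sorted by position. Zero rows if nothing exceeds the
#'   threshold.
#' @export
find_peaks <- function(spectrum, min_rel_amplitude = 0.05, exclude_hz = 2,
                       mode = c("magnitude", "real")) {
  mode <- match.arg(mode)
  y <- if (mode == "magnitude") Mod(spectrum$amplitude) else
    Re(spectrum$amplitude)
  f <- spectrum$freq_Hz
  df <- f[2] - f[1]
  inwin <- abs(f) >= exclude_hz
  if (!any(inwin)) return(.empty_peaks())
  thr <- min_rel_amplitude * max(y[inwin])
  n <- length(y)
  cand <- which(inwin &
                  seq_len(n) > 1 & seq_len(n) < n &
                  y > thr &
                  y >= c(Inf, y[-n]) & y > c(y[-1], Inf))
  if (!length(cand)) return(.empty_peaks())
  rows <- lapply(cand, function(i) {
    ym <- y[i - 1]; y0 <- y[i]; yp <- y[i + 1]
    denom <- ym - 2 * y0 + yp
    delta <- if (denom != 0) 0.5 * (ym - yp) / denom else 0
    delta <- max(-0.5, min(0.5, delta))
    pos <- f[i] + delta * df
    apex <- y0 - 0.25 * (ym - yp) * delta
    half <- apex / 2
    xl <- .half_crossing(y, f, i, half, -1L)
    xr <- .half_crossing(y, f, i, half, +1L)
    fw <- if (is.na(xl) || is.na(xr)) NA_real_ else xr - xl
    il <- .support_edge(y, i, apex, -1L)
    ir <- .support_edge(y, i, apex, +1L)
    integ <- sum((y[il:(ir - 1)] + y[(il + 1):ir]) / 2) * df
    data.frame(position_Hz = pos, amplitude = apex, fwhh_Hz = fw,
               integral = integ)
  })
  out <- do.call(rbind, rows)
  out[order(out$position_Hz), , drop = FALSE]
}

.empty_peaks <- function() {
  data.frame(position_Hz = numeric(0), amplitude = numeric(0),
             fwhh_Hz = numeric(0), integral = numeric(0))
}

.half_crossing <- function(y, f, i, half, dir) {
  j <- i
  n <- length(y)
  while (j + dir >= 1 && j + dir <= n && y[j + dir] >= half) {
    j <- j + dir
    if (y[j] > y[i]) return(NA_real_)  # merged with a taller neighbor
  }
  jn <- j + dir
  if (jn < 1 || jn > n) return(NA_real_)
  # linear interpolation between j (>= half) and jn (< half)
  frac <- (y[j] - half) / (y[j] - y[jn])
  f[j] + dir * frac * (f[2] - f[1])
}

.support_edge <- function(y, i, apex, dir) {
  j <- i
  n <- length(y)
  repeat {
    jn <- j + dir
    if (jn < 1 || jn > n) break
    if (y[jn] >= y[j] || y[jn] < 0.01 * apex) break
    j <- jn
  }
  j
}

#' Pairwise peak position and amplitude ratios
#'
#' Supports multiplet diagnostics such as the 1:4:6:4:1 quintet
#' (center/outer amplitude ratio 6) and the 2J/J zero-field line pair
#' (position ratio 2).
#'
#' @param peaks A peak table from [find_peaks()] with at least two rows.
#' @return Data frame with one row per unordered pair (peaks sorted by
#'   position): indices `i`, `j` (i < j), `position_ratio` (pos_j / pos_i)
#'   and `amplitude_ratio` (amp_j / amp_i).
#' @export
peak_ratio_report <- function(peaks) {
  if (nrow(peaks) < 2)
    stop("need at least two peaks for a ratio report", call. = FALSE)
  peaks <- peaks[order(peaks$position_Hz), , drop = FALSE]
  pr <- utils::combn(nrow(peaks), 2)
  data.frame(
    i = pr[1, ], j = pr[2, ],
    position_ratio = peaks$position_Hz[pr[2, ]] / peaks$position_Hz[pr[1, ]],
    amplitude_ratio = peaks$amplitude[pr[2, ]] / peaks$amplitude[pr[1, ]]
  )
}

#' Write a spectrum as two-column delimited text
#'
#' Columns: frequency_Hz, amplitude (magnitude). Metadata (protocol, software
#' version, arbitrary key-value pairs) goes into `#`-prefixed header lines.
#'
#' @param spectrum An `nmr_spectrum`.
#' @param path Output file path.
#' @param metadata Optional named list echoed into the header.
#' @return The path, invisibly.
#' @export
write_spectrum <- function(spectrum, path, metadata = NULL) {
  hdr <- c(
    paste0("# zulfspin spectrum, version ",
           as.character(utils::packageVersion("zulfspin"))),
    sprintf("# apodization_s: %.10g", spectrum$apodization_s),
    sprintf("# zero_fill: %d", spectrum$zero_fill),
    sprintf("# dwell_s: %.10g", spectrum$dwell_s),
    vapply(names(metadata %||% list()),
           function(k) sprintf("# %s: %s", k, format(metadata[[k]])), "")
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines("frequency_Hz\tamplitude", con)
  utils::write.table(
    data.frame(f = sprintf("%.10g", spectrum$freq_Hz),
               a = sprintf("%.10g", Mod(spectrum$amplitude))),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a spectrum written by [write_spectrum()]
#'
#' @param path File path.
#' @return An `nmr_spectrum`-like object (magnitude only).
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  dat <- utils::read.table(text = body, header = TRUE, sep = "\t")
  structure(
    list(freq_Hz = dat$frequency_Hz, amplitude = dat$amplitude + 0i,
         apodization_s = NA_real_, zero_fill = NA_integer_,
         dwell_s = NA_real_, n_time = NA_integer_,
         two_sided = any(dat$frequency_Hz < 0)),
    class = "nmr_spectrum"
  )
}

#' Write a peak table as delimited text
#'
#' @param peaks Peak table from [find_peaks()].
#' @param path Output file path.
#' @param metadata Optional named list echoed into `#` header lines.
#' @return The path, invisibly.
#' @export
write_peaks <- function(peaks, path, metadata = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# zulfspin peaks, version ",
           as.character(utils::packageVersion("zulfspin"))),
    vapply(names(metadata %||% list()),
           function(k) sprintf("# %s: %s", k, format(metadata[[k]])), "")
  ), con)
  utils::write.table(format(peaks, digits = 10), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
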