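#' Preprocessing and array I/O
#'
#' Minimal preprocessing mirroring the analysis pipeline: band-limited
#' downsampling (Fourier method, which low-passes at the new Nyquist) and a
#' first-order IIR high-pass to remove slow drift. Recordings are exchanged
#' as a plain tab-separated value matrix plus a JSON sidecar, rather than
#' any proprietary MEG format.
#'
#' @name signal_io
NULL

#' Resample a recording (band-limited, Fourier method)
#'
#' Downsamples each channel by truncating its discrete Fourier spectrum at
#' the new Nyquist frequency, which combines anti-alias filtering and
#' interpolation in one step (exact for signals that are band-limited and
#' periodic over the record). Only downsampling (or the identity) is
#' supported.
#'
#' @param rec a `sensor_recording`.
#' @param target_rate new sampling rate in Hz (must be `<= rec$rate`).
#' @return the resampled `sensor_recording`; duration is preserved to within
#'   one sample.
#' @export
resample_recording <- function(rec, target_rate) {
  stopifnot(inherits(rec, "sensor_recording"))
  stop_if_not_scalar_number(target_rate, "target_rate", lower = 1e-9)
  if (target_rate > rec$rate)
    stop("upsampling not supported (target_rate > rec$rate)")
  n <- ncol(rec$data)
  m <- round(n * target_rate / rec$rate)
  if (m == n) return(new_recording(rec$data, target_rate))
  keep <- ceiling(m / 2) - 1L  # bins strictly below the new Nyquist
  out <- t(apply(rec$data, 1L, function(x) {
    X <- stats::fft(x)
    Y <- complex(length.out = m)
    Y[1L] <- X[1L]
    if (keep >= 1L) {
      Y[2:(keep + 1L)] <- X[2:(keep + 1L)]
      Y[(m - keep + 1L):m] <- X[(n - keep + 1L):n]
    }
    Re(stats::fft(Y, inverse = TRUE)) / n
  }))
  new_recording(out, target_rate)
}

#' First-order IIR high-pass filter
#'
#' Discretizes a one-pole analog high-pass at `cutoff_hz` via the bilinear
#' transform and applies it causally per channel (forward pass only by
#' default; `zero_phase = TRUE` runs a forward-backward pass, squaring the
#' magnitude response and cancelling phase). The -3 dB point of the causal
#' filter sits at the cutoff.
#'
#' @param rec a `sensor_recording`.
#' @param cutoff_hz cutoff frequency, `0 < cutoff_hz < rate / 2`.
#' @param zero_phase apply forward-backward instead of causal filtering.
#' @return the filtered `sensor_recording`.
#' @export
highpass_recording <- function(rec, cutoff_hz = 0.5, zero_phase = FALSE) {
  stopifnot(inherits(rec, "sensor_recording"))
  if (!is.numeric(cutoff_hz) || cutoff_hz <= 0 || cutoff_hz >= rec$rate / 2)
    stop("cutoff_hz must lie strictly between 0 and rate/2")
  wc <- tan(pi * cutoff_hz / rec$rate)
  b0 <- 1 / (1 + wc); b1 <- -b0
  a1 <- (wc - 1) / (wc + 1)
  filt1 <- function(x) {
    u <- b0 * x + b1 * c(x[1L], x[-length(x)])  # first sample: assume held input
    as.numeric(stats::filter(u, -a1, method = "recursive"))
  }
  run <- function(x) {
    y <- filt1(x)
    if (zero_phase) y <- rev(filt1(rev(y)))
    y
  }
  new_recording(t(apply(rec$data, 1L, run)), rec$rate)
}

#' Write / read a recording as TSV + JSON sidecar
#'
#' The data matrix (channels in rows) is stored as headerless
#' tab-separated text at `<stem>.tsv`; sampling rate, dimensions, and
#' optional metadata go in `<stem>.json`.
#'
#' @param rec a `sensor_recording`.
#' @param stem path stem (without extension).
#' @param meta optional named list merged into the sidecar.
#' @return `write_recording`: `stem`, invisibly. `read_recording`: the
#'   restored `sensor_recording` (with sidecar metadata in `attr(, "meta")`).
#' @export
write_recording <- function(rec, stem, meta = list()) {
  stopifnot(inherits(rec, "sensor_recording"))
  utils::write.table(rec$data, paste0(stem, ".tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  side <- c(list(rate = rec$rate, n_channels = nrow(rec$data),
                 n_samples = ncol(rec$data)), meta)
  writeLines(jsonlite::toJSON(side, auto_unbox = TRUE, digits = NA),
             paste0(stem, ".json"))
  invisible(stem)
}

#' @rdname write_recording
#' @export
read_recording <- function(stem) {
  side <- jsonlite::fromJSON(paste0(stem, ".json"))
  data <- as.matrix(utils::read.table(paste0(stem, ".tsv"), sep = "\t"))
  dimnames(data) <- NULL
  stopifnot(nrow(data) == side$n_channels, ncol(data) == side$n_samples)
  rec <- new_recording(data, side$rate)
  attr(rec, "meta") <- side
  rec
}

#' Write / read a reactivation matrix as TSV + JSON sidecar
#'
#' @param Y a `reactivation_matrix`.
#' @param stem path stem (without extension).
#' @return `write_reactivations`: `stem`, invisibly; `read_reactivations`:
#'   the restored `reactivation_matrix`.
#' @export
write_reactivations <- function(Y, stem) {
  stopifnot(inherits(Y, "reactivation_matrix"))
  utils::write.table(Y$values, paste0(stem, ".tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  writeLines(jsonlite::toJSON(list(rate = Y$rate, n_states = ncol(Y$values),
                                   n_samples = nrow(Y$values)),
                              auto_unbox = TRUE, digits = NA),
             paste0(stem, ".json"))
  invisible(stem)
}

#' @rdname write_reactivations
#' @export
read_reactivations <- function(stem) {
  side <- jsonlite::fromJSON(paste0(stem, ".json"))
  vals <- as.matrix(utils::read.table(paste0(stem, ".tsv"), sep = "\t"))
  dimnames(vals) <- NULL
  new_reactivation_matrix(vals, side$rate)
}
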