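new_protocol <- function(fn, kind, t_total, meta) {
  structure(list(fn = fn, kind = kind, t_total = t_total, meta = meta),
            class = "nvc_protocol")
}

#' Stimulus protocols
#'
#' Constructors for the external excitatory drive `nu_ext(t)` applied to the
#' neuronal population. `stim_event()` is a single rectangular pulse (the
#' event-related protocol; the standard reference stimulus is 2 s at 4 Hz),
#' `stim_block()` a train of `n_stim` pulses separated by `isi`, and
#' `stim_sinusoid()` a sinusoid about a positive mean, clipped at zero.
#' `stim_custom()` wraps an arbitrary vectorized function of time. All
#' protocols may ride on a constant `baseline` drive (used e.g. when
#' studying post-stimulus effects of neuronal adaptation, which need a
#' nonzero pre-stimulus firing rate to dip below).
#'
#' @param amplitude Pulse amplitude above baseline (Hz, `>= 0`).
#' @param duration Pulse duration (s).
#' @param onset Stimulus onset time from simulation start (s).
#' @param t_total Total simulated time (s); must cover the stimulus and is
#'   typically at least 30 s beyond it to capture the undershoot tail.
#' @param baseline Constant background drive (Hz, default 0).
#' @return An `nvc_protocol` object: a vectorized `nu_ext(t)` plus metadata.
#' @export
stim_event <- function(amplitude, duration = 2, onset = 10,
                       t_total = onset + duration + 40, baseline = 0) {
  stopifnot(amplitude >= 0, duration > 0, onset >= 0, baseline >= 0)
  if (onset + duration > t_total) {
    stop("stimulus extends past t_total", call. = FALSE)
  }
  fn <- function(t) baseline + ifelse(t >= onset & t < onset + duration, amplitude, 0)
  new_protocol(fn, "event", t_total,
               list(onset = onset, duration = duration, amplitude = amplitude,
                    baseline = baseline, offset = onset + duration))
}

#' @param stim_dur Duration of each pulse in a block (s).
#' @param isi Inter-stimulus interval within the block (s).
#' @param n_stim Number of pulses (`>= 1`).
#' @rdname stim_event
#' @export
stim_block <- function(amplitude, stim_dur = 2, isi = 1, n_stim = 10,
                       onset = 10, t_total = NULL, baseline = 0) {
  stopifnot(amplitude >= 0, stim_dur > 0, isi >= 0, n_stim >= 1)
  span <- n_stim * stim_dur + (n_stim - 1) * isi
  if (is.null(t_total)) t_total <- onset + span + 40
  if (onset + span > t_total) {
    stop("block extends past t_total", call. = FALSE)
  }
  starts <- onset + (seq_len(n_stim) - 1) * (stim_dur + isi)
  fn <- function(t) {
    on <- rep(FALSE, length(t))
    for (s in starts) on <- on | (t >= s & t < s + stim_dur)
    baseline + ifelse(on, amplitude, 0)
  }
  new_protocol(fn, "block", t_total,
               list(onset = onset, duration = span, amplitude = amplitude,
                    stim_dur = stim_dur, isi = isi, n_stim = n_stim,
                    baseline = baseline, offset = onset + span))
}

#' @param center Mean drive of the sinusoid (Hz); must be `>= amplitude` so
#'   the drive stays non-negative.
#' @param period Oscillation period (s).
#' @rdname stim_event
#' @export
stim_sinusoid <- function(center, amplitude, period, onset = 10,
                          duration = 4 * period,
                          t_total = onset + duration + 40) {
  if (center < 0) stop("center must be >= 0", call. = FALSE)
  if (center < amplitude) {
    stop("center must be >= amplitude to keep nu_ext non-negative", call. = FALSE)
  }
  stopifnot(period > 0)
  fn <- function(t) {
    on <- t >= onset & t < onset + duration
    pmax(0, ifelse(on, center + amplitude * sin(2 * pi * (t - onset) / period), 0))
  }
  new_protocol(fn, "sinusoid", t_total,
               list(onset = onset, duration = duration, amplitude = amplitude,
                    center = center, period = period, baseline = 0,
                    offset = onset + duration))
}

#' @param fn Vectorized function of time (s) returning `nu_ext` (Hz).
#' @param meta Optional metadata list (`onset`, `offset`, ... as available).
#' @rdname stim_event
#' @export
stim_custom <- function(fn, t_total, meta = list()) {
  stopifnot(is.function(fn), t_total > 0)
  new_protocol(fn, "custom", t_total, meta)
}

#' Sample a protocol on a time grid
#'
#' @param protocol An `nvc_protocol`.
#' @param times Numeric vector of times (s).
#' @return Tibble with `time` and `nu_ext`.
#' @export
protocol_trace <- function(protocol, times) {
  stopifnot(inherits(protocol, "nvc_protocol"))
  v <- protocol$fn(times)
  if (any(v < 0)) stop("protocol produced negative nu_ext", call. = FALSE)
  tibble::tibble(time = times, nu_ext = v)
}

#' @export
print.nvc_protocol <- function(x, ...) {
  cat("<nvc_protocol: ", x$kind, ">, t_total = ", x$t_total, " s\n", sep = "")
  meta <- x$meta[vapply(x$meta, is.numeric, logical(1))]
  if (length(meta)) {
    cat("  ", paste0(names(meta), " = ", signif(unlist(meta), 4),
                     collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
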