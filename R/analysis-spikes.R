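#' Detect astrocytic calcium spikes
#'
#' Peak detection with hysteresis: a spike begins when the calcium trace
#' crosses `basal + frac * (max(Ca) - basal)` upward and ends when it falls
#' back below `basal + lower_frac * (max(Ca) - basal)`; the spike time and
#' amplitude are the maximum inside that excursion. Traces whose total
#' excursion above basal stays below `min_amp` contain no spikes. The mean
#' spike frequency is `(n - 1) / (t_last - t_first)` when at least two
#' spikes are present, otherwise `n / window`.
#'
#' @param x An `nvc_sim` tibble (column `Ca` is used) or a data frame with
#'   columns `time` and `Ca`.
#' @param basal Basal calcium level (uM). Defaults to the first sample of
#'   the trace (the resting value for simulations started at rest).
#' @param window Optional numeric `c(t0, t1)` restricting detection to a
#'   time window (s).
#' @param frac,lower_frac Upper/lower hysteresis thresholds as fractions of
#'   the peak excursion above basal.
#' @param min_amp Minimum excursion (uM) for the trace to count as spiking.
#' @return A tibble of class `nvc_spikes` with one row per spike (`time`,
#'   `amplitude`), and attributes `f_ca` (Hz), `a_ca` (mean amplitude, uM),
#'   `basal` and `window`.
#' @export
detect_ca_spikes <- function(x, basal = NULL, window = NULL,
                             frac = 0.5, lower_frac = 0.25, min_amp = 0.15) {
  df <- as.data.frame(x)
  if (!all(c("time", "Ca") %in% names(df))) {
    stop("x must contain 'time' and 'Ca' columns", call. = FALSE)
  }
  if (nrow(df) == 0) stop("empty trace", call. = FALSE)
  t <- df$time; ca <- df$Ca
  if (!is.null(window)) {
    keep <- t >= window[1] & t <= window[2]
    t <- t[keep]; ca <- ca[keep]
    if (length(t) == 0) stop("window excludes the whole trace", call. = FALSE)
  } else {
    window <- range(t)
  }
  if (is.null(basal)) basal <- ca[1]
  exc <- max(ca) - basal
  times <- numeric(0); amps <- numeric(0)
  if (exc >= min_amp) {
    hi <- basal + frac * exc
    lo <- basal + lower_frac * exc
    in_spike <- FALSE; pk_v <- -Inf; pk_t <- NA_real_
    for (i in seq_along(ca)) {
      if (!in_spike && ca[i] >= hi) {
        in_spike <- TRUE; pk_v <- ca[i]; pk_t <- t[i]
      } else if (in_spike) {
        if (ca[i] > pk_v) { pk_v <- ca[i]; pk_t <- t[i] }
        if (ca[i] < lo) {
          times <- c(times, pk_t); amps <- c(amps, pk_v)
          in_spike <- FALSE
        }
      }
    }
    if (in_spike) { times <- c(times, pk_t); amps <- c(amps, pk_v) }
  }
  n <- length(times)
  f_ca <- if (n >= 2) (n - 1) / (times[n] - times[1]) else n / diff(window)
  out <- tibble::tibble(time = times, amplitude = amps)
  attr(out, "f_ca") <- f_ca
  attr(out, "a_ca") <- if (n) mean(amps) else NA_real_
  attr(out, "basal") <- basal
  attr(out, "window") <- window
  class(out) <- c("nvc_spikes", class(out))
  out
}

#' Summarise a detected spike train
#'
#' @param x An `nvc_spikes` object.
#' @param ... Unused.
#' @return One-row tibble with `n_spikes`, `f_ca` (Hz), `a_ca` (uM),
#'   `first_spike` (s) and `basal` (uM).
#' @export
glance.nvc_spikes <- function(x, ...) {
  tibble::tibble(
    n_spikes = nrow(x),
    f_ca = attr(x, "f_ca"),
    a_ca = attr(x, "a_ca"),
    first_spike = if (nrow(x)) x$time[1] else NA_real_,
    basal = attr(x, "basal")
  )
}

#' @export
print.nvc_spikes <- function(x, ...) {
  cat("<nvc_spikes> ", nrow(x), " spikes, f_ca = ",
      signif(attr(x, "f_ca"), 3), " Hz, A_ca = ",
      signif(attr(x, "a_ca"), 3), " uM\n", sep = "")
  NextMethod()
}
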