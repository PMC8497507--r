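#' Mossy-fiber stimulation protocol
#'
#' Describes a train of brief mossy-fiber (MF) stimuli: one or more bursts of
#' \code{n_pulses} pulses at \code{pulse_rate}. All response times in the
#' package are measured from the offset of the (first) burst, i.e. t = 0 at
#' the last pulse of the burst; the burst therefore occupies
#' \code{[-(n_pulses-1)/pulse_rate, 0]}.
#'
#' @param n_pulses number of pulses per burst (default 20, the reference
#'   protocol: 20 stimuli at 100 Hz).
#' @param pulse_rate pulse rate within a burst, Hz.
#' @param n_bursts number of bursts (default 1).
#' @param burst_interval seconds between burst onsets when \code{n_bursts > 1}.
#' @return an object of class \code{stimulus_protocol}.
#' @examples
#' stimulus_protocol()                      # 20 x 100 Hz
#' stimulus_protocol(10, 100, n_bursts = 10, burst_interval = 2)
#' @export
stimulus_protocol <- function(n_pulses = 20, pulse_rate = 100,
                              n_bursts = 1, burst_interval = NULL) {
  stopifnot(n_pulses >= 1, pulse_rate > 0, n_bursts >= 1)
  if (n_bursts > 1 && (is.null(burst_interval) || burst_interval <= 0))
    stop("burst_interval must be positive when n_bursts > 1")
  obj <- list(n_pulses = as.integer(n_pulses), pulse_rate = pulse_rate,
              n_bursts = as.integer(n_bursts),
              burst_interval = if (n_bursts > 1) burst_interval else NA_real_)
  class(obj) <- "stimulus_protocol"
  obj
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat(sprintf("MF stimulus protocol: %d x %g Hz", x$n_pulses, x$pulse_rate))
  if (x$n_bursts > 1)
    cat(sprintf(", %d bursts every %g s", x$n_bursts, x$burst_interval))
  cat(sprintf(" (burst duration %.3f s, t = 0 at offset)\n",
              burst_duration(x)))
  invisible(x)
}

#' Burst duration of a protocol
#'
#' Time from the first to the last pulse of one burst; the stimulus offset is
#' \code{burst_duration} after onset.
#' @param protocol a \code{stimulus_protocol}.
#' @return seconds.
#' @export
burst_duration <- function(protocol) {
  (protocol$n_pulses - 1) / protocol$pulse_rate
}

#' Pulse times of a protocol
#'
#' Offset-referenced pulse times. For a single burst the pulses run from
#' \code{-burst_duration(protocol)} to 0; later bursts (if any) start at
#' multiples of \code{burst_interval} after the first burst's onset.
#' @param protocol a \code{stimulus_protocol}.
#' @return numeric vector of pulse times, seconds.
#' @export
pulse_times <- function(protocol) {
  one <- seq(-burst_duration(protocol), 0, length.out = protocol$n_pulses)
  if (protocol$n_bursts == 1) return(one)
  starts <- (seq_len(protocol$n_bursts) - 1) * protocol$burst_interval
  as.vector(outer(one, starts, `+`))
}
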