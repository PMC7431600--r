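#' Stimulation protocol
#'
#' Describes the timing of a recording (baseline, stimulation and recovery
#' phases), the diameter sampling interval, and the spacing of measurement
#' positions along the vessel. The default protocol is 30 s of each phase,
#' diameters sampled every 10 s, and positions every 50 um upstream of the
#' stimulation site.
#'
#' @param baseline_duration Baseline phase duration in seconds.
#' @param stimulation_duration Stimulation phase duration in seconds.
#' @param recovery_duration Recovery phase duration in seconds.
#' @param sampling_interval Diameter sampling interval in seconds; every
#'   phase duration must be a positive integer multiple of it.
#' @param position_spacing Spacing of measurement positions in um.
#'
#' @return An object of class `"stim_protocol"`.
#' @examples
#' default_protocol()
#' stim_protocol(baseline_duration = 60)
#' @export
stim_protocol <- function(baseline_duration = 30,
                          stimulation_duration = 30,
                          recovery_duration = 30,
                          sampling_interval = 10,
                          position_spacing = 50) {
  durs <- c(baseline = baseline_duration, stimulation = stimulation_duration,
            recovery = recovery_duration)
  if (!all(is.finite(durs)) || !is.finite(sampling_interval) ||
      !is.finite(position_spacing))
    stop("protocol fields must be finite numbers", call. = FALSE)
  if (any(durs <= 0))
    stop("all phase durations must be > 0", call. = FALSE)
  if (sampling_interval <= 0)
    stop("sampling_interval must be > 0", call. = FALSE)
  if (position_spacing <= 0)
    stop("position_spacing must be > 0", call. = FALSE)
  mult <- durs / sampling_interval
  if (any(abs(mult - round(mult)) > 1e-9))
    stop("phase durations must be integer multiples of sampling_interval",
         call. = FALSE)
  structure(list(baseline_duration = baseline_duration,
                 stimulation_duration = stimulation_duration,
                 recovery_duration = recovery_duration,
                 sampling_interval = sampling_interval,
                 position_spacing = position_spacing),
            class = "stim_protocol")
}

#' @rdname stim_protocol
#' @export
default_protocol <- function() stim_protocol()

#' @export
print.stim_protocol <- function(x, ...) {
  cat("Stimulation protocol\n")
  cat(sprintf("  phases (s): baseline %g / stimulation %g / recovery %g\n",
              x$baseline_duration, x$stimulation_duration, x$recovery_duration))
  cat(sprintf("  sampling every %g s, positions every %g um\n",
              x$sampling_interval, x$position_spacing))
  invisible(x)
}

# Sample times: first sample one interval into the recording, so the
# stimulation phase contains samples at 10, 20 and 30 s after onset under
# the default protocol.
protocol_times <- function(protocol) {
  total <- protocol$baseline_duration + protocol$stimulation_duration +
    protocol$recovery_duration
  seq(protocol$sampling_interval, total, by = protocol$sampling_interval)
}

protocol_phases <- function(protocol, times = protocol_times(protocol)) {
  b <- protocol$baseline_duration
  s <- b + protocol$stimulation_duration
  ifelse(times <= b, "baseline", ifelse(times <= s, "stimulation", "recovery"))
}
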