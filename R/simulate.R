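#' Generate a synthetic vessel recording
#'
#' Simulates one vessel's diameter time series on the position x time grid
#' defined by the protocol. The noiseless diameter at position `x` and time
#' `t` is
#' \deqn{D(x, t) = D_0 \,\{1 - c(x)\, g(t)\}}
#' with spatial profile `c(x) = a * exp(-x / lambda)` (local constriction
#' `a`, length constant `lambda`) and temporal gate `g(t)` rising
#' mono-exponentially from 0 toward 1 during stimulation (time constant
#' `constriction_onset_tau`) and relaxing toward 0 during recovery
#' (`recovery_tau`). Two noise terms are added: a vessel-wide AR(1)
#' vasomotion series (correlation 0.5 per sample, stationary SD
#' `vasomotion_sd`) and independent measurement noise
#' (`measurement_noise_sd`).
#'
#' The vessel's traceable length is drawn uniformly from the multiples of
#' `position_spacing` in `[traceable_length_min, traceable_length_max]`;
#' positions beyond it are absent (`NA` for every time point). The same
#' `(params, protocol, seed)` always reproduces the identical recording.
#'
#' @param params A [group_params()] object.
#' @param protocol A [stim_protocol()] object.
#' @param seed Integer seed for this vessel's draws.
#' @param vessel_id Identifier attached to the recording.
#'
#' @return An object of class `"vessel_recording"`: a list with elements
#'   `vessel_id`, `group_label`, `positions` (um), `times` (s), `phases`,
#'   and `diameters` (positions x times matrix, um; `NA` beyond the
#'   traceable length), plus the drawn `baseline_diameter` and
#'   `traceable_length`.
#' @examples
#' rec <- generate_vessel(default_group_params("Cx45 WT"), default_protocol(),
#'                        seed = 1)
#' rec$positions
#' rec$diameters[1, ]
#' @export
generate_vessel <- function(params, protocol, seed, vessel_id = "v1") {
  stopifnot(inherits(params, "group_params"),
            inherits(protocol, "stim_protocol"))
  if (!is.finite(seed)) stop("seed must be a finite integer", call. = FALSE)
  dx <- protocol$position_spacing
  kmin <- params$traceable_length_min / dx
  kmax <- params$traceable_length_max / dx
  if (abs(kmin - round(kmin)) > 1e-9 || abs(kmax - round(kmax)) > 1e-9)
    stop("traceable length bounds must be multiples of position_spacing",
         call. = FALSE)

  times <- protocol_times(protocol)
  phases <- protocol_phases(protocol, times)

  set.seed(as.integer(seed))
  # draw order is fixed: baseline diameter, traceable length, vasomotion,
  # measurement noise -- so the stream is reproducible by construction
  d0 <- rnorm(1, params$baseline_diameter_mean, params$baseline_diameter_sd)
  while (d0 < 5) # truncated-normal draw; lumen floor 5 um
    d0 <- rnorm(1, params$baseline_diameter_mean, params$baseline_diameter_sd)
  length_choices <- seq(round(kmin), round(kmax)) * dx
  traceable <- if (length(length_choices) == 1L) length_choices else
    length_choices[sample.int(length(length_choices), 1L)]
  positions <- seq(0, traceable, by = dx)

  nt <- length(times)
  np <- length(positions)
  rho <- 0.5
  vaso <- numeric(nt)
  vaso[1] <- rnorm(1, 0, params$vasomotion_sd)
  innov <- rnorm(nt - 1, 0, params$vasomotion_sd * sqrt(1 - rho^2))
  for (i in seq_len(nt - 1L)) vaso[i + 1L] <- rho * vaso[i] + innov[i]
  eps <- matrix(rnorm(np * nt, 0, params$measurement_noise_sd), np, nt)

  g <- .temporal_gate(times, phases, protocol,
                      params$constriction_onset_tau, params$recovery_tau)
  cx <- params$true_local_constriction *
    exp(-positions / params$true_length_constant)
  d <- d0 * (1 - outer(cx, g)) + matrix(vaso, np, nt, byrow = TRUE) + eps
  d <- pmax(d, 0.1) # diameters stay positive even under extreme noise
  dimnames(d) <- list(position = positions, time = times)

  structure(list(vessel_id = vessel_id,
                 group_label = params$group_label,
                 positions = positions,
                 times = times,
                 phases = phases,
                 diameters = d,
                 baseline_diameter = d0,
                 traceable_length = traceable),
            class = "vessel_recording")
}

# g(t): 0 at baseline; 1 - exp(-elapsed/tau_on) during stimulation;
# exponential relaxation from the end-of-stimulation value during recovery.
.temporal_gate <- function(times, phases, protocol, tau_on, tau_off) {
  b <- protocol$baseline_duration
  s <- b + protocol$stimulation_duration
  g <- numeric(length(times))
  stim <- phases == "stimulation"
  g[stim] <- if (tau_on <= 0) 1 else 1 - exp(-(times[stim] - b) / tau_on)
  g_end <- if (tau_on <= 0) 1 else 1 - exp(-protocol$stimulation_duration / tau_on)
  rec <- phases == "recovery"
  g[rec] <- if (tau_off <= 0) 0 else g_end * exp(-(times[rec] - s) / tau_off)
  g
}

#' Generate a multi-group synthetic cohort
#'
#' Generates `n_vessels` recordings for each group. Per-vessel seeds are
#' derived from the master seed by a counter scheme,
#' `(seed + 100000 * group_index + vessel_index) mod (2^31 - 1)`, so the
#' draws of one group do not depend on how many vessels other groups have,
#' and appending a group leaves earlier groups' recordings unchanged.
#'
#' @param groups A list of [group_params()] objects with distinct labels
#'   (a single `group_params` object is accepted).
#' @param protocol A [stim_protocol()] object.
#' @param seed Master integer seed.
#'
#' @return An object of class `"vessel_cohort"`: a list of
#'   [generate_vessel()] recordings.
#' @examples
#' coh <- generate_cohort(list(default_group_params("Cx40 WT"),
#'                             default_group_params("Cx40 KO")),
#'                        default_protocol(), seed = 42)
#' length(coh)
#' @export
generate_cohort <- function(groups, protocol = default_protocol(), seed = 1) {
  if (inherits(groups, "group_params")) groups <- list(groups)
  stopifnot(length(groups) >= 1)
  labels <- vapply(groups, function(g) g$group_label, character(1))
  if (anyDuplicated(labels))
    stop("group labels must be distinct", call. = FALSE)
  recs <- list()
  for (gi in seq_along(groups)) {
    gp <- groups[[gi]]
    for (vi in seq_len(gp$n_vessels)) {
      vseed <- (as.numeric(seed) + 100000 * gi + vi) %% (2^31 - 1)
      id <- sprintf("%s_%02d", gsub("[^A-Za-z0-9]+", "", gp$group_label), vi)
      recs[[length(recs) + 1L]] <-
        generate_vessel(gp, protocol, seed = vseed, vessel_id = id)
    }
  }
  structure(recs, class = "vessel_cohort")
}

#' @export
print.vessel_recording <- function(x, ...) {
  cat(sprintf("Vessel recording '%s' (group %s)\n", x$vessel_id, x$group_label))
  cat(sprintf("  %d positions (0-%g um), %d samples, baseline diameter %.1f um\n",
              length(x$positions), max(x$positions), length(x$times),
              x$baseline_diameter))
  invisible(x)
}

#' @export
print.vessel_cohort <- function(x, ...) {
  labs <- vapply(x, function(r) r$group_label, character(1))
  cat(sprintf("Vessel cohort: %d recordings\n", length(x)))
  print(table(group = labs))
  invisible(x)
}

#' @describeIn generate_vessel Flatten a recording to a tidy data frame with
#'   columns `vessel_id`, `group`, `position_um`, `time_s`, `phase`,
#'   `diameter_um` (one row per position x time cell, `NA` beyond the
#'   traceable length).
#' @param x A `vessel_recording`.
#' @param row.names,optional,... Passed for S3 compatibility; ignored.
#' @export
as.data.frame.vessel_recording <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
  np <- length(x$positions); nt <- length(x$times)
  data.frame(vessel_id = rep(x$vessel_id, np * nt),
             group = rep(x$group_label, np * nt),
             position_um = rep(x$positions, times = nt),
             time_s = rep(x$times, each = np),
             phase = rep(x$phases, each = np),
             diameter_um = as.vector(x$diameters),
             stringsAsFactors = FALSE)
}

#' @export
as.data.frame.vessel_cohort <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  do.call(rbind, lapply(unclass(x), as.data.frame))
}
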