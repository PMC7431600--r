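#' Resting and stimulation diameters at one position
#'
#' `resting_diameter()` is the arithmetic mean of all baseline-phase
#' diameter samples at a position. `stimulation_diameter()` is the mean of
#' the three consecutive measurements taken 10, 20 and 30 s after
#' stimulation onset (more generally: at one, two and three sampling
#' intervals into the stimulation phase), which is the steady-state window
#' the constriction is read from.
#'
#' @param recording A `vessel_recording`.
#' @param position Measurement position in um; must be present in the
#'   recording.
#' @return Diameter in um.
#' @examples
#' rec <- generate_vessel(default_group_params("Cx45 WT"), default_protocol(),
#'                        seed = 1)
#' resting_diameter(rec, 0)
#' stimulation_diameter(rec, 0)
#' @export
resting_diameter <- function(recording, position) {
  d <- .position_series(recording, position)
  base <- d[recording$phases == "baseline"]
  base <- base[!is.na(base)]
  if (!length(base))
    stop("no baseline-phase samples at position ", position, call. = FALSE)
  mean(base)
}

#' @rdname resting_diameter
#' @export
stimulation_diameter <- function(recording, position) {
  d <- .position_series(recording, position)
  stim_idx <- which(recording$phases == "stimulation")
  if (!length(stim_idx))
    stop("recording has no stimulation phase", call. = FALSE)
  onset <- min(recording$times[stim_idx]) -
    diff(recording$times[1:2]) # phase starts one interval before first sample
  dt <- diff(recording$times[1:2])
  want <- onset + dt * (1:3)
  idx <- match(want, recording$times)
  vals <- d[idx]
  missing <- want[is.na(idx) | is.na(vals)]
  if (length(missing))
    stop("missing stimulation sample(s) at t = ",
         paste(missing, collapse = ", "), " s", call. = FALSE)
  mean(vals)
}

.position_series <- function(recording, position) {
  i <- match(position, recording$positions)
  if (is.na(i))
    stop("position ", position, " um not present in recording ",
         recording$vessel_id, call. = FALSE)
  recording$diameters[i, ]
}

#' Relative constriction
#'
#' The fractional diameter reduction `(d_rest - d_stim) / d_rest`: positive
#' values are narrowing, negative values dilation.
#'
#' @param d_rest Resting diameter (um), must be positive.
#' @param d_stim Stimulated diameter (um), non-negative.
#' @return Dimensionless fraction.
#' @examples
#' relative_constriction(20, 16) # 0.20
#' @export
relative_constriction <- function(d_rest, d_stim) {
  if (any(!is.finite(d_rest)) || any(d_rest <= 0))
    stop("d_rest must be positive", call. = FALSE)
  if (any(d_stim < 0)) stop("d_stim must be >= 0", call. = FALSE)
  (d_rest - d_stim) / d_rest
}

#' Zero-truncate a constriction profile
#'
#' From the first distance at which the conducted constriction reaches 0 or
#' a negative value, the constriction is set to exactly 0 for that and all
#' remaining distances. Values before that point are unchanged; the
#' operation is idempotent.
#'
#' @param values Constriction fractions ordered by increasing distance.
#' @return The truncated vector, with attribute `"truncated_from"` giving
#'   the first truncated index (or `NA` if nothing was truncated).
#' @examples
#' truncate_profile(c(0.20, 0.10, -0.02, 0.05)) # 0.20 0.10 0.00 0.00
#' @export
truncate_profile <- function(values) {
  idx <- which(values <= 0)
  from <- if (length(idx)) idx[1] else NA_integer_
  if (!is.na(from)) values[from:length(values)] <- 0
  attr(values, "truncated_from") <- from
  values
}

#' Build a per-vessel constriction profile
#'
#' Reduces a recording to one relative-constriction value per distance:
#' diameters during stimulation (mean of the 10/20/30-s samples) are
#' normalised to the mean resting diameter at the same distance, then the
#' zero-truncation rule is applied along the vessel.
#'
#' @param recording A `vessel_recording`.
#' @return An object of class `"constriction_profile"`: list with
#'   `vessel_id`, `group_label`, `distances` (um), `constriction`
#'   (truncated), `raw_constriction` (pre-truncation), `truncated_from`
#'   (index or `NA`) and `resting_diameters` (um).
#' @examples
#' rec <- generate_vessel(default_group_params("Cx40 WT"), default_protocol(),
#'                        seed = 2)
#' build_profile(rec)
#' @export
build_profile <- function(recording) {
  stopifnot(inherits(recording, "vessel_recording"))
  distances <- recording$positions
  d_rest <- vapply(distances, function(p) resting_diameter(recording, p),
                   numeric(1))
  d_stim <- vapply(distances, function(p) stimulation_diameter(recording, p),
                   numeric(1))
  raw <- relative_constriction(d_rest, d_stim)
  trunc <- truncate_profile(raw)
  structure(list(vessel_id = recording$vessel_id,
                 group_label = recording$group_label,
                 distances = distances,
                 constriction = as.numeric(trunc),
                 raw_constriction = raw,
                 truncated_from = attr(trunc, "truncated_from"),
                 resting_diameters = d_rest),
            class = "constriction_profile")
}

#' @export
print.constriction_profile <- function(x, digits = 3, ...) {
  cat(sprintf("Constriction profile '%s' (group %s)\n", x$vessel_id,
              x$group_label))
  print(data.frame(distance_um = x$distances,
                   constriction = round(x$constriction, digits)))
  invisible(x)
}

#' @export
as.data.frame.constriction_profile <- function(x, row.names = NULL,
                                               optional = FALSE, ...) {
  data.frame(vessel_id = x$vessel_id, group = x$group_label,
             distance_um = x$distances, constriction = x$constriction,
             stringsAsFactors = FALSE)
}

#' Apply the study's inclusion criteria to a vessel
#'
#' A vessel is included when all three criteria hold: (1) the local
#' response is at least 5% constriction at the stimulation site; (2) after
#' stimulation the vessel recovers to at least 50% of its baseline diameter
#' (mean recovery-phase diameter at the stimulation site relative to the
#' resting diameter there); (3) diameters are measurable at a minimum of
#' three positions, counting the stimulation site.
#'
#' @param profile The vessel's [build_profile()] result.
#' @param recording The `vessel_recording` the profile was built from.
#' @param min_local Minimum local constriction (default 0.05).
#' @param min_recovery Minimum recovery fraction of baseline (default 0.50).
#' @param min_positions Minimum number of measurable positions (default 3).
#' @return An object of class `"inclusion_decision"`: list with
#'   `vessel_id`, `included`, and `failed_criteria` (named list of measured
#'   values for each failed criterion, empty when included).
#' @examples
#' rec <- generate_vessel(default_group_params("Cx45 KO"), default_protocol(),
#'                        seed = 7)
#' apply_inclusion_criteria(build_profile(rec), rec)
#' @export
apply_inclusion_criteria <- function(profile, recording,
                                     min_local = 0.05,
                                     min_recovery = 0.50,
                                     min_positions = 3) {
  stopifnot(inherits(profile, "constriction_profile"),
            inherits(recording, "vessel_recording"))
  failed <- list()

  local_c <- profile$raw_constriction[match(0, profile$distances)]
  if (is.na(local_c) || local_c < min_local)
    failed$local_constriction_min <- local_c

  d_rest0 <- resting_diameter(recording, 0)
  rec_d <- recording$diameters[match(0, recording$positions),
                               recording$phases == "recovery"]
  rec_frac <- mean(rec_d, na.rm = TRUE) / d_rest0
  if (!is.finite(rec_frac) || rec_frac < min_recovery)
    failed$recovery_min <- rec_frac

  n_pos <- length(profile$distances)
  if (n_pos < min_positions)
    failed$position_min <- n_pos

  structure(list(vessel_id = profile$vessel_id,
                 included = length(failed) == 0L,
                 failed_criteria = failed),
            class = "inclusion_decision")
}

#' @export
print.inclusion_decision <- function(x, ...) {
  if (x$included) {
    cat(sprintf("Vessel '%s': included\n", x$vessel_id))
  } else {
    cat(sprintf("Vessel '%s': excluded (%s)\n", x$vessel_id,
                paste(names(x$failed_criteria), collapse = ", ")))
  }
  invisible(x)
}

#' Pool constriction profiles of one group
#'
#' Collects every (distance, constriction) measurement of the group's
#' included vessels into one flat point set -- the data the decay curve is
#' fitted to, in which shorter distances carry more points because every
#' vessel contributes there -- and computes per-distance summaries (mean,
#' SEM with the n-1 standard deviation, and the number of contributing
#' vessels).
#'
#' @param profiles List of `constriction_profile` objects from included
#'   vessels of a single group.
#' @param label Group label; defaults to the profiles' common label.
#' @return An object of class `"pooled_group"`: list with `group_label`,
#'   `points` (data frame `distance`, `constriction`, `vessel_id`) and
#'   `per_distance` (data frame `distance`, `mean`, `sem`, `n`; `sem` is
#'   `NA` where `n < 2`).
#' @examples
#' coh <- generate_cohort(default_group_params("Cx45 WT"), seed = 5)
#' profs <- lapply(coh, build_profile)
#' pool_group(profs)
#' @export
pool_group <- function(profiles, label = NULL) {
  if (inherits(profiles, "constriction_profile")) profiles <- list(profiles)
  if (!length(profiles)) stop("no profiles to pool", call. = FALSE)
  labs <- unique(vapply(profiles, function(p) p$group_label, character(1)))
  if (is.null(label)) {
    if (length(labs) != 1L)
      stop("profiles span several groups (", paste(labs, collapse = ", "),
           "); pass `label` or pool one group at a time", call. = FALSE)
    label <- labs
  }
  points <- do.call(rbind, lapply(profiles, function(p)
    data.frame(distance = p$distances, constriction = p$constriction,
               vessel_id = p$vessel_id, stringsAsFactors = FALSE)))
  agg <- lapply(split(points$constriction, points$distance), function(v)
    c(mean = mean(v), sd = stats::sd(v), n = length(v)))
  agg <- do.call(rbind, agg)
  per_distance <- data.frame(distance = as.numeric(rownames(agg)),
                             mean = agg[, "mean"],
                             sem = ifelse(agg[, "n"] >= 2,
                                          agg[, "sd"] / sqrt(agg[, "n"]),
                                          NA_real_),
                             n = as.integer(agg[, "n"]),
                             row.names = NULL)
  per_distance <- per_distance[order(per_distance$distance), ]
  structure(list(group_label = label, points = points,
                 per_distance = per_distance),
            class = "pooled_group")
}

#' @export
print.pooled_group <- function(x, digits = 3, ...) {
  cat(sprintf("Pooled group '%s': %d points from %d vessels\n",
              x$group_label, nrow(x$points),
              length(unique(x$points$vessel_id))))
  pd <- x$per_distance
  pd$mean <- round(pd$mean, digits); pd$sem <- round(pd$sem, digits)
  print(pd, row.names = FALSE)
  invisible(x)
}
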