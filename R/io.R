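#' Read and write vessel recordings as tidy CSV
#'
#' The on-disk dialect is a UTF-8 CSV with header row and columns
#' `vessel_id, group, position_um, time_s, phase, diameter_um`; "."
#' decimal separator; missing diameters (positions beyond a vessel's
#' traceable length) written as empty fields. `write_recordings()` drops
#' rows for wholly-absent positions on request; by default the full grid is
#' written so the file round-trips exactly.
#'
#' @param cohort A `vessel_cohort` or single `vessel_recording`.
#' @param path File path.
#' @return `read_recordings()` returns a `vessel_cohort`;
#'   `write_recordings()` returns `path` invisibly.
#' @examples
#' coh <- generate_cohort(default_group_params("Cx40 KO"), seed = 3)
#' f <- tempfile(fileext = ".csv")
#' write_recordings(coh, f)
#' coh2 <- read_recordings(f)
#' @export
write_recordings <- function(cohort, path) {
  if (inherits(cohort, "vessel_recording"))
    cohort <- structure(list(cohort), class = "vessel_cohort")
  df <- as.data.frame(cohort)
  utils::write.csv(df, path, row.names = FALSE, na = "", quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_recordings
#' @export
read_recordings <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                        fileEncoding = "UTF-8")
  required <- c("vessel_id", "group", "position_um", "time_s", "phase",
                "diameter_um")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("malformed recordings CSV: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  for (col in c("position_um", "time_s", "diameter_um")) {
    if (!is.numeric(df[[col]])) {
      bad <- which(!is.na(df[[col]]) & is.na(suppressWarnings(
        as.numeric(df[[col]]))))[1]
      stop(sprintf("malformed recordings CSV: non-numeric %s at data row %d",
                   col, bad), call. = FALSE)
    }
  }
  bad <- which(!is.na(df$diameter_um) & df$diameter_um <= 0)
  if (length(bad))
    stop(sprintf("malformed recordings CSV: non-positive diameter at data row %d",
                 bad[1]), call. = FALSE)
  bad <- which(!df$phase %in% c("baseline", "stimulation", "recovery"))
  if (length(bad))
    stop(sprintf("malformed recordings CSV: unknown phase at data row %d",
                 bad[1]), call. = FALSE)

  recs <- lapply(split(df, df$vessel_id), function(d) {
    positions <- sort(unique(d$position_um))
    times <- sort(unique(d$time_s))
    m <- matrix(NA_real_, length(positions), length(times),
                dimnames = list(position = positions, time = times))
    m[cbind(match(d$position_um, positions), match(d$time_s, times))] <-
      d$diameter_um
    # drop positions with no data at all (beyond traceable length)
    keep <- rowSums(!is.na(m)) > 0
    ph <- d$phase[match(times, d$time_s)]
    structure(list(vessel_id = d$vessel_id[1],
                   group_label = d$group[1],
                   positions = positions[keep],
                   times = times,
                   phases = ph,
                   diameters = m[keep, , drop = FALSE],
                   baseline_diameter = NA_real_,
                   traceable_length = max(positions[keep])),
              class = "vessel_recording")
  })
  # preserve file order of first appearance
  ord <- match(unique(df$vessel_id), names(recs))
  structure(unname(recs[ord]), class = "vessel_cohort")
}
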