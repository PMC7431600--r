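#' Per-distance one-sample t-tests against zero
#'
#' At each distance, the per-vessel constriction values of the pooled group
#' are tested against 0 with a two-sided one-sample t-test. Distances with
#' fewer than two values, or with zero sample variance, are reported as not
#' testable rather than raising an error.
#'
#' @param pooled A [pool_group()] result.
#' @param alpha Significance level (default 0.05).
#' @return A data frame with one row per distance: `distance`, `n`, `mean`,
#'   `t_statistic`, `df`, `p_value`, `significant` (at `alpha`) and
#'   `testable`.
#' @examples
#' coh <- generate_cohort(default_group_params("Cx45 WT"), seed = 11)
#' pooled <- pool_group(lapply(coh, build_profile))
#' per_distance_tests(pooled)
#' @export
per_distance_tests <- function(pooled, alpha = 0.05) {
  stopifnot(inherits(pooled, "pooled_group"))
  by_d <- split(pooled$points$constriction, pooled$points$distance)
  rows <- lapply(names(by_d), function(dn) {
    v <- by_d[[dn]]
    n <- length(v)
    testable <- n >= 2 && stats::sd(v) > 0
    if (testable) {
      tt <- stats::t.test(v, mu = 0)
      data.frame(distance = as.numeric(dn), n = n, mean = mean(v),
                 t_statistic = unname(tt$statistic),
                 df = unname(tt$parameter),
                 p_value = tt$p.value,
                 significant = tt$p.value <= alpha,
                 testable = TRUE)
    } else {
      data.frame(distance = as.numeric(dn), n = n, mean = mean(v),
                 t_statistic = NA_real_, df = NA_real_, p_value = NA_real_,
                 significant = NA, testable = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out[order(out$distance), ]
}

#' Compare local constriction between groups by one-way ANOVA
#'
#' Tests whether the relative constriction at the stimulation site differs
#' between groups. With exactly two groups the ANOVA F statistic equals the
#' square of the pooled-variance two-sample t statistic.
#'
#' @param groupA_locals,groupB_locals Numeric vectors of per-vessel local
#'   constriction values (at distance 0), one per group; each needs at
#'   least 2 values.
#' @return The `htest` object from [stats::oneway.test()] (equal-variance
#'   form): `statistic` is F, `p.value` the ANOVA p-value.
#' @examples
#' compare_local(c(0.1, 0.2, 0.3), c(0.4, 0.5, 0.6))
#' @export
compare_local <- function(groupA_locals, groupB_locals) {
  if (length(groupA_locals) < 2 || length(groupB_locals) < 2)
    stop("each group needs at least 2 local constriction values",
         call. = FALSE)
  df <- data.frame(
    value = c(groupA_locals, groupB_locals),
    group = factor(rep(c("A", "B"),
                       c(length(groupA_locals), length(groupB_locals)))))
  stats::oneway.test(value ~ group, data = df, var.equal = TRUE)
}

#' Extent of significant conducted constriction
#'
#' The largest distance up to which constriction is statistically
#' significant: the last distance in the initial run of significant
#' testable distances (an isolated significant distance beyond a
#' non-significant one does not extend the range).
#'
#' @param tests A [per_distance_tests()] data frame.
#' @return Distance in um, or `NA` if not even the stimulation site is
#'   significant.
#' @export
significance_extent <- function(tests) {
  tests <- tests[order(tests$distance), ]
  tests <- tests[tests$testable, ]
  if (!nrow(tests)) return(NA_real_)
  extent <- NA_real_
  for (i in seq_len(nrow(tests))) {
    if (isTRUE(tests$significant[i])) extent <- tests$distance[i] else break
  }
  extent
}
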