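#' Pipeline configuration
#'
#' Describes one end-to-end run: where the recordings come from (simulated
#' from group parameters, or read from a tidy recordings CSV), the
#' stimulation protocol, bootstrap size, master seed, significance level
#' and output directory.
#'
#' @param input_mode `"simulate"` or `"csv"`.
#' @param group_params List of [group_params()] objects (simulate mode).
#' @param input_path Path to a recordings CSV (csv mode).
#' @param protocol A [stim_protocol()].
#' @param n_bootstrap Bootstrap replicates per group (default 1000).
#' @param master_seed Master integer seed; all stage seeds derive from it.
#' @param alpha Significance level (default 0.05).
#' @param output_dir Directory for report CSVs and the run log; `NULL`
#'   skips writing.
#' @return An object of class `"pipeline_config"`.
#' @seealso [run_pipeline()], [read_pipeline_config()]
#' @export
pipeline_config <- function(input_mode = c("simulate", "csv"),
                            group_params = NULL,
                            input_path = NULL,
                            protocol = default_protocol(),
                            n_bootstrap = 1000,
                            master_seed = 1,
                            alpha = 0.05,
                            output_dir = NULL) {
  input_mode <- match.arg(input_mode)
  if (input_mode == "simulate") {
    if (is.null(group_params) || !is.null(input_path))
      stop("simulate mode requires group_params and no input_path",
           call. = FALSE)
    if (inherits(group_params, "group_params"))
      group_params <- list(group_params)
    ok <- vapply(group_params, inherits, logical(1), "group_params")
    if (!all(ok)) stop("group_params must be group_params objects",
                       call. = FALSE)
  } else {
    if (is.null(input_path) || !is.null(group_params))
      stop("csv mode requires input_path and no group_params", call. = FALSE)
  }
  if (n_bootstrap < 1) stop("n_bootstrap must be >= 1", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  structure(list(input_mode = input_mode, group_params = group_params,
                 input_path = input_path, protocol = protocol,
                 n_bootstrap = n_bootstrap, master_seed = master_seed,
                 alpha = alpha, output_dir = output_dir),
            class = "pipeline_config")
}

#' Read or write a pipeline configuration as YAML
#'
#' The YAML mirrors the configuration one-to-one: top-level keys
#' `input_mode`, `input_path`, `n_bootstrap`, `master_seed`, `alpha`,
#' `output_dir`, a `protocol` mapping with the [stim_protocol()] fields,
#' and a `groups` sequence of mappings with the [group_params()] fields.
#'
#' @param path YAML file path.
#' @param config A `pipeline_config` (for writing).
#' @return `read_pipeline_config()` returns a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  protocol <- if (is.null(y$protocol)) default_protocol() else
    do.call(stim_protocol, y$protocol)
  groups <- NULL
  if (!is.null(y$groups))
    groups <- lapply(y$groups, function(g) do.call(group_params, g))
  pipeline_config(input_mode = y$input_mode %||% "simulate",
                  group_params = groups,
                  input_path = y$input_path,
                  protocol = protocol,
                  n_bootstrap = y$n_bootstrap %||% 1000,
                  master_seed = y$master_seed %||% 1,
                  alpha = y$alpha %||% 0.05,
                  output_dir = y$output_dir)
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  y <- list(input_mode = config$input_mode,
            input_path = config$input_path,
            protocol = unclass(config$protocol),
            groups = lapply(config$group_params, unclass),
            n_bootstrap = config$n_bootstrap,
            master_seed = config$master_seed,
            alpha = config$alpha,
            output_dir = config$output_dir)
  yaml::write_yaml(y[!vapply(y, is.null, logical(1))], path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summarise a cohort after inclusion decisions
#'
#' Per-group counts and, over included vessels only, mean +/- SEM resting
#' diameter at the stimulation site and mean +/- SEM traceable length.
#'
#' @param recordings A `vessel_cohort` (or list of `vessel_recording`s).
#' @param decisions List of [apply_inclusion_criteria()] decisions, one per
#'   recording and in the same order.
#' @return Data frame with columns `group`, `n_input`, `n_included`,
#'   `diameter_mean`, `diameter_sem`, `length_mean`, `length_sem` (SEMs
#'   `NA` when a single vessel remains).
#' @export
summarize_cohort <- function(recordings, decisions) {
  if (length(recordings) != length(decisions))
    stop("decisions must cover all recordings", call. = FALSE)
  groups <- vapply(recordings, function(r) r$group_label, character(1))
  inc <- vapply(decisions, function(d) d$included, logical(1))
  d0 <- vapply(recordings, function(r) resting_diameter(r, 0), numeric(1))
  len <- vapply(recordings, function(r) max(r$positions), numeric(1))
  sem <- function(v) if (length(v) >= 2) stats::sd(v) / sqrt(length(v)) else NA_real_
  rows <- lapply(unique(groups), function(g) {
    sel <- groups == g & inc
    data.frame(group = g,
               n_input = sum(groups == g),
               n_included = sum(sel),
               diameter_mean = if (any(sel)) mean(d0[sel]) else NA_real_,
               diameter_sem = sem(d0[sel]),
               length_mean = if (any(sel)) mean(len[sel]) else NA_real_,
               length_sem = sem(len[sel]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# match "X WT" with "X KO" labels into comparison pairs
.pair_groups <- function(labels) {
  wt <- labels[grepl("\\bWT\\b", labels)]
  pairs <- list()
  for (w in wt) {
    k <- sub("\\bWT\\b", "KO", w)
    if (k %in% labels) pairs[[length(pairs) + 1L]] <- c(w, k)
  }
  pairs
}

#' Run the full conducted-vasoconstriction analysis
#'
#' Orchestrates the pipeline: simulate (or read) recordings, build
#' per-vessel constriction profiles, apply the inclusion criteria, pool
#' included vessels per group, fit the exponential decay per group, run
#' per-distance one-sample t-tests, bootstrap the fits, and compare WT
#' vs KO pairs (local constriction by one-way ANOVA, decay rates by the
#' bootstrap t-test). If `config$output_dir` is set, writes report CSVs
#' (`cohort_summary.csv`, `inclusion.csv`, `fits.csv`,
#' `profile_summary.csv`, `bootstrap_summary.csv`, `comparisons.csv`) and
#' a `run_log.txt`; numbers are written at full precision.
#'
#' Stage seeds derive from the master seed: the simulation uses it
#' directly, and each group's bootstrap uses
#' `master_seed + 1000 + group_index`.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `"analysis_report"`: list with `groups`
#'   (per group: `pooled`, `fit`, `tests`, `boot`, `sig_extent`,
#'   `decisions`), `summary` (the [summarize_cohort()] table), `fits_table`,
#'   `comparisons`, `config`.
#' @examples
#' \donttest{
#' cfg <- pipeline_config(group_params = list(default_group_params("Cx45 WT"),
#'                                            default_group_params("Cx45 KO")),
#'                        n_bootstrap = 100, master_seed = 1)
#' rep <- run_pipeline(cfg)
#' rep$fits_table
#' }
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))

  cohort <- if (config$input_mode == "simulate") {
    generate_cohort(config$group_params, config$protocol,
                    seed = config$master_seed)
  } else {
    read_recordings(config$input_path)
  }

  profiles <- lapply(cohort, build_profile)
  decisions <- Map(apply_inclusion_criteria, profiles, unclass(cohort))
  included <- vapply(decisions, function(d) d$included, logical(1))
  groups <- vapply(cohort, function(r) r$group_label, character(1))
  labels <- unique(groups)

  group_results <- list()
  for (gi in seq_along(labels)) {
    g <- labels[gi]
    sel <- groups == g & included
    if (!any(sel))
      stop("group '", g, "' has no included vessels", call. = FALSE)
    pooled <- pool_group(profiles[sel], label = g)
    fit <- decay_fit(pooled)
    tests <- per_distance_tests(pooled, alpha = config$alpha)
    boot <- bootstrap_fit(pooled, n_reps = config$n_bootstrap,
                          seed = config$master_seed + 1000 + gi)
    group_results[[g]] <- list(
      label = g, pooled = pooled, fit = fit, tests = tests, boot = boot,
      sig_extent = significance_extent(tests),
      decisions = decisions[groups == g],
      locals = vapply(profiles[sel], function(p)
        p$raw_constriction[match(0, p$distances)], numeric(1)))
  }

  comparisons <- list()
  for (pair in .pair_groups(labels)) {
    A <- group_results[[pair[1]]]; B <- group_results[[pair[2]]]
    an <- compare_local(A$locals, B$locals)
    dc <- compare_decay_rates(A$boot, B$boot)
    comparisons[[paste(pair, collapse = " vs ")]] <-
      list(pair = pair, local_anova = an, decay = dc)
  }

  fits_table <- do.call(rbind, lapply(group_results, function(gr) {
    cf <- coef(gr$fit)
    data.frame(group = gr$label, a = cf[["a"]], b = cf[["b"]],
               length_constant_um = gr$fit$length_constant,
               n_points = gr$fit$n_points,
               converged = gr$fit$converged,
               stringsAsFactors = FALSE)
  }))
  rownames(fits_table) <- NULL

  report <- structure(list(groups = group_results,
                           summary = summarize_cohort(cohort, decisions),
                           fits_table = fits_table,
                           comparisons = comparisons,
                           config = config),
                      class = "analysis_report")
  if (!is.null(config$output_dir)) .write_report(report, config)
  report
}

.write_report <- function(report, config) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(config$output_dir, name)
  w <- function(df, name) utils::write.csv(df, out(name), row.names = FALSE,
                                           na = "")
  w(report$summary, "cohort_summary.csv")

  inc <- do.call(rbind, lapply(report$groups, function(gr) {
    do.call(rbind, lapply(gr$decisions, function(d)
      data.frame(group = gr$label, vessel_id = d$vessel_id,
                 included = d$included,
                 failed_criteria = paste(names(d$failed_criteria),
                                         collapse = ";"),
                 stringsAsFactors = FALSE)))
  }))
  w(inc, "inclusion.csv")
  w(report$fits_table, "fits.csv")

  prof <- do.call(rbind, lapply(report$groups, function(gr) {
    pd <- gr$pooled$per_distance
    tst <- gr$tests
    data.frame(group = gr$label, distance_um = pd$distance, mean = pd$mean,
               sem = pd$sem, n = pd$n,
               p_value = tst$p_value[match(pd$distance, tst$distance)],
               fitted_value = predict(gr$fit, pd$distance),
               stringsAsFactors = FALSE)
  }))
  w(prof, "profile_summary.csv")

  bs <- do.call(rbind, lapply(report$groups, function(gr) {
    b <- gr$boot
    data.frame(group = gr$label, n_reps = b$n_reps, n_failed = b$n_failed,
               a_median = stats::median(b$a_samples),
               a_ci_low = b$ci_a[1], a_ci_high = b$ci_a[2],
               b_median = stats::median(b$b_samples),
               b_ci_low = b$ci_b[1], b_ci_high = b$ci_b[2],
               seed = b$seed, stringsAsFactors = FALSE)
  }))
  w(bs, "bootstrap_summary.csv")

  cmp <- do.call(rbind, lapply(report$comparisons, function(cp)
    data.frame(group_pair = paste(cp$pair, collapse = " vs "),
               anova_F = unname(cp$local_anova$statistic),
               anova_p = cp$local_anova$p.value,
               decay_t = cp$decay$statistic,
               decay_p = cp$decay$p.value,
               stringsAsFactors = FALSE)))
  if (!is.null(cmp)) w(cmp, "comparisons.csv") else
    w(data.frame(group_pair = character(), anova_F = numeric(),
                 anova_p = numeric(), decay_t = numeric(),
                 decay_p = numeric()), "comparisons.csv")

  log <- c(sprintf("condvaso %s", as.character(utils::packageVersion("condvaso"))),
           sprintf("R %s", getRversion()),
           sprintf("input_mode: %s", config$input_mode),
           sprintf("master_seed: %s", format(config$master_seed)),
           sprintf("n_bootstrap: %d", config$n_bootstrap),
           sprintf("alpha: %g", config$alpha),
           sprintf("bootstrap stage seeds: %s",
                   paste(config$master_seed + 1000 +
                           seq_along(report$groups), collapse = ", ")),
           "exclusions:",
           sprintf("  %s: excluded %d of %d", report$summary$group,
                   report$summary$n_input - report$summary$n_included,
                   report$summary$n_input))
  writeLines(log, out("run_log.txt"))
  invisible(NULL)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Conducted-vasoconstriction analysis report\n\n")
  cat("Cohort summary (included vessels):\n")
  s <- x$summary
  s$diameter_mean <- round(s$diameter_mean, 1)
  s$diameter_sem <- round(s$diameter_sem, 1)
  s$length_mean <- round(s$length_mean, 1)
  s$length_sem <- round(s$length_sem, 1)
  print(s, row.names = FALSE)
  cat("\nDecay fits (length constants to the nearest um):\n")
  f <- x$fits_table
  f$a <- round(f$a, 2)
  f$b <- signif(f$b, 2)
  f$length_constant_um <- round(f$length_constant_um)
  print(f, row.names = FALSE)
  ext <- vapply(x$groups, function(g) g$sig_extent, numeric(1))
  cat("\nSignificant constriction measurable up to (um):\n")
  print(ext)
  if (length(x$comparisons)) {
    cat("\nWT vs KO comparisons:\n")
    for (nm in names(x$comparisons)) {
      cp <- x$comparisons[[nm]]
      cat(sprintf("  %s: local ANOVA p = %.3g; decay-rate bootstrap t-test p = %.3g\n",
                  nm, cp$local_anova$p.value, cp$decay$p.value))
    }
  }
  invisible(x)
}
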