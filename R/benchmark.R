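#' False-discovery benchmark for the differential-splicing caller
#'
#' Simulates replicate two-group cohorts with a planted differential
#' fraction, runs the full caller (PSI computation, t-tests, BH
#' correction, significance thresholds) on each, and scores the calls
#' against the generator's truth table. The false-discovery proportion of
#' a replicate is the fraction of significant calls that are planted-null
#' events; replicates with zero calls contribute 0. Under BH at level
#' `padj_max` the mean FDP is expected at or below `padj_max`.
#'
#' @param seed Master seed; replicate r uses `seed + 101 * r`.
#' @param n_reps Number of replicate cohorts.
#' @param n_events,frac_differential,effect_dpsi,n_per_group,coverage_mean
#'   Cohort parameters forwarded to [sim_config()].
#' @param padj_max,dpsi_min Significance thresholds of the caller.
#' @param min_total PSI coverage floor.
#' @return A tibble of class `fdr_benchmark`, one row per replicate:
#'   `rep`, `seed`, `n_called`, `n_false`, `fdp`, `tpr` (fraction of
#'   planted events recovered).
#' @examples
#' \donttest{
#' bench <- benchmark_fdr(seed = 1, n_reps = 3, n_events = 500)
#' mean(bench$fdp)
#' }
#' @export
benchmark_fdr <- function(seed = 1L, n_reps = 50, n_events = 2000,
                          frac_differential = 0.1, effect_dpsi = 20,
                          n_per_group = 6, coverage_mean = 100,
                          padj_max = 0.25, dpsi_min = 10, min_total = 10) {
  reps <- purrr::map_dfr(seq_len(n_reps), function(r) {
    cfg <- sim_config(
      seed = as.integer(seed) + 101L * r,
      n_events = n_events,
      n_samples_per_group = c(ref = n_per_group, test = n_per_group),
      frac_differential = frac_differential,
      effect_dpsi = effect_dpsi,
      coverage_mean = coverage_mean
    )
    sim <- simulate_splicing_cohort(cfg)
    psi <- compute_psi(sim$counts, min_total = min_total)
    res <- compare_groups(psi, sim$samples, "ref", "test",
                          padj_max = padj_max, dpsi_min = dpsi_min)
    calls <- res$event_id[res$significant]
    is_diff <- sim$truth$is_differential[match(calls, sim$truth$event_id)]
    n_false <- sum(!is_diff)
    n_planted <- sum(sim$truth$is_differential)
    tibble(
      rep = r, seed = cfg$seed,
      n_called = length(calls), n_false = n_false,
      fdp = if (length(calls) == 0) 0 else n_false / length(calls),
      tpr = if (n_planted == 0) NA_real_ else sum(is_diff) / n_planted
    )
  })
  structure(reps, class = c("fdr_benchmark", class(reps)))
}

#' @export
glance.fdr_benchmark <- function(x, ...) {
  tibble(
    n_reps = nrow(x),
    mean_fdp = mean(x$fdp),
    mean_tpr = mean(x$tpr, na.rm = TRUE),
    mean_calls = mean(x$n_called)
  )
}
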