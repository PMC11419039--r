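#' End-to-end demonstration pipeline on generated data
#'
#' Simulates a two-genotype splicing cohort, a burden cohort, expression
#' results with planted gene sets, and allele pileups; runs every analysis
#' stage (PSI, event filters, differential splicing, non-redundant
#' selection, event-type distributions, outlier burden, ranked lists,
#' preranked enrichment, allele-ratio classification and co-occurrence);
#' and writes all tables under `out_dir` together with the configuration
#' (YAML) and a checksummed manifest. All randomness flows from `seed`, so
#' the same seed reproduces byte-identical outputs.
#'
#' @param seed Integer seed for the whole run.
#' @param out_dir Output directory (created if needed).
#' @param n_events Events per simulated cohort (kept modest so the demo
#'   runs in well under a minute).
#' @param n_perm Permutations for the enrichment stage.
#' @param quiet Suppress progress messages.
#' @return Invisibly, the manifest tibble (`stage`, `file`, `md5`), with
#'   the output directory in attribute `dir`.
#' @examples
#' \donttest{
#' manifest <- run_demo(seed = 1, out_dir = tempfile("demo"))
#' }
#' @export
run_demo <- function(seed = 1L, out_dir = tempfile("psitools_demo_"),
                     n_events = 400, n_perm = 200, quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  say <- function(...) if (!quiet) inform(sprintf(...))
  emit <- function(df, stage, name) {
    path <- file.path(out_dir, name)
    readr::write_tsv(df, path, na = "NA", progress = FALSE)
    files[[length(files) + 1]] <<- path
    names(files)[length(files)] <<- stage
    path
  }
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      abort(sprintf("demo stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  cfg <- sim_config(seed = as.integer(seed), n_events = n_events)
  yaml::write_yaml(
    c(cfg[setdiff(names(cfg), "n_samples_per_group")],
      list(n_samples_per_group = as.list(cfg$n_samples_per_group))),
    file.path(out_dir, "config.yaml")
  )
  files[["config"]] <- file.path(out_dir, "config.yaml")

  say("simulating splicing cohort (%d events)", n_events)
  splice <- stage("simulate_splicing", {
    sim <- simulate_splicing_cohort(cfg)
    write_juncbase_table(sim$counts, file.path(out_dir, "counts.tsv"))
    files[["counts"]] <- file.path(out_dir, "counts.tsv")
    emit(sim$samples, "samples", "samples.tsv")
    emit(sim$truth, "truth_splicing", "truth_splicing.tsv")
    sim
  })

  say("differential splicing")
  ds <- stage("diff_splicing", {
    psi <- compute_psi(splice$counts)
    psi <- filter_events(psi, diff_splicing_rules())
    res <- compare_groups(psi, splice$samples, "ref", "test")
    res_nr <- make_nonredundant(res)
    emit(tidy(res), "diff_splicing", "diff_splicing.tsv")
    emit(dplyr::as_tibble(res_nr), "diff_splicing_nonredundant",
         "diff_splicing_nonredundant.tsv")
    dist <- event_type_distribution(res_nr, label = "test vs ref")
    emit(dist, "event_type_distribution", "event_type_distribution.tsv")
    list(res = res, res_nr = res_nr, dist = dist)
  })

  say("event-type distribution comparison against a second cohort")
  stage("compare_distributions", {
    cfg2 <- sim_config(
      seed = as.integer(seed) + 7L, n_events = n_events,
      event_type_proportions = c(
        cassette = 0.5, mutually_exclusive = 0.02, coordinate_cassette = 0.03,
        alt_5ss = 0.05, alt_3ss = 0.05, alt_first_exon = 0.25,
        alt_last_exon = 0.02, intron_retention = 0.08
      )
    )
    sim2 <- simulate_splicing_cohort(cfg2)
    psi2 <- filter_events(compute_psi(sim2$counts), diff_splicing_rules())
    res2 <- make_nonredundant(compare_groups(psi2, sim2$samples, "ref", "test"))
    cmp <- compare_distributions(
      ds$dist, event_type_distribution(res2, label = "cohort 2"),
      seed = as.integer(seed)
    )
    emit(dplyr::mutate(tidy(cmp), overall_p = cmp$overall_p),
         "event_type_comparison", "event_type_comparison.tsv")
  })

  say("splicing-alteration burden")
  stage("burden", {
    bcfg <- sim_config(
      seed = as.integer(seed) + 11L, n_events = n_events,
      n_samples_per_group = c(unexposed = 10L, exposed = 10L)
    )
    bsim <- simulate_burden_cohort(bcfg)
    psi_b <- filter_events(bsim$psi, burden_rules())
    rs <- event_robust_stats(psi_b)
    flags <- flag_alterations(psi_b, rs)
    burden <- sample_burden(flags)
    cmp <- compare_burden(burden, bsim$samples, "unexposed", "exposed")
    emit(rs, "event_robust_stats", "event_robust_stats.tsv")
    emit(flags, "alteration_flags", "alteration_flags.tsv")
    emit(burden, "burden", "burden.tsv")
    emit(cmp, "burden_comparison", "burden_comparison.tsv")
  })

  say("expression simulation and preranked enrichment")
  stage("enrichment", {
    universe <- sprintf("G%05d", seq_len(1000))
    sets <- list(
      planted_up = universe[1:30],
      decoy_a = universe[301:340],
      decoy_b = universe[501:560]
    )
    esim <- simulate_expression_results(cfg, n_genes = 1000,
                                        planted_sets = sets["planted_up"])
    emit(esim$de, "expression", "expression_de.tsv")
    rnk <- build_rank_from_expression(esim$de)
    write_rnk(rnk, file.path(out_dir, "expression.rnk"))
    files[["rnk"]] <- file.path(out_dir, "expression.rnk")
    write_gmt(sets, file.path(out_dir, "sets.gmt"))
    files[["gmt"]] <- file.path(out_dir, "sets.gmt")
    gsea <- gsea_preranked(rnk, sets, n_perm = n_perm,
                           seed = as.integer(seed))
    emit(tidy(gsea), "gsea", "gsea.tsv")
    emit(filter_enrichment(gsea), "nes_matrix", "nes_matrix.tsv")

    spl_rnk <- build_rank_from_splicing(tidy(ds$res))
    if (nrow(spl_rnk) > 0) {
      write_rnk(spl_rnk, file.path(out_dir, "splicing.rnk"))
      files[["splicing_rnk"]] <- file.path(out_dir, "splicing.rnk")
    }
  })

  say("allele fractions and classification")
  stage("allele_ratio", {
    fractions <- setNames(
      c(rep(0.30, 6), rep(0.50, 6)),
      c(sprintf("double_mut_%02d", 1:6), sprintf("s34f_only_%02d", 1:6))
    )
    pile <- simulate_pileup(cfg, fractions = fractions, depth = 2000)
    emit(pile, "pileup", "pileup.tsv")
    frac <- allele_fraction(pile)
    cls <- classify_ratio(frac)
    cls$group <- rep(c("double_mut", "s34f_only"), each = 6)
    emit(cls, "ratio_classes", "ratio_classes.tsv")
    cmp <- compare_fractions(cls, "double_mut", "s34f_only")
    emit(cmp, "fraction_comparison", "fraction_comparison.tsv")
    cls$driver <- cls$group == "double_mut"
    co <- cooccurrence_table(cls)
    emit(glance(co), "cooccurrence", "cooccurrence.tsv")
  })

  manifest <- tibble(
    stage = names(files),
    file = basename(unlist(files)),
    md5 = unname(tools::md5sum(unlist(files)))
  )
  readr::write_tsv(manifest, file.path(out_dir, "manifest.tsv"),
                   progress = FALSE)
  say("demo complete: %d files in %s", nrow(manifest), out_dir)
  invisible(structure(manifest, dir = out_dir))
}
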