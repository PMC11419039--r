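#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators into one validated
#' object. The defaults describe the cohort structure the analyses assume: a
#' two-group design with a handful of replicates per genotype, junction
#' counts drawn beta-binomially around a true PSI with mild overdispersion,
#' a small rate of coverage dropout, and a minority of events planted with a
#' real group difference.
#'
#' @param seed Integer master seed. Every table derives its own sub-stream
#'   from it, so identical configurations regenerate identical output.
#' @param n_events Number of base splicing events to simulate.
#' @param n_samples_per_group Named integer vector, samples per group. The
#'   first name is the reference group; planted differential shifts and
#'   outlier-sample enrichment apply to the last group.
#' @param event_type_proportions Named numeric vector over the eight
#'   categories in [EVENT_TYPES], summing to 1. Zeros are allowed.
#' @param frac_differential Fraction of events planted with a group shift.
#' @param effect_dpsi Planted mean PSI shift, in PSI percentage points.
#'   Shifts that would leave [0, 100] are clamped and the clamped value is
#'   recorded in the truth table.
#' @param baseline_psi_shape Two beta shape parameters; baseline PSI is
#'   drawn as `rbeta(shape1, shape2) * 100`.
#' @param coverage_mean Expected total (inclusion + exclusion) count per
#'   event and sample; totals are Poisson.
#' @param dispersion Beta-binomial overdispersion rho in (0, 1).
#' @param missing_rate Fraction of cells blanked (both counts set missing)
#'   to mimic coverage dropout.
#' @param frac_redundant Fraction of events duplicated into two-member
#'   redundancy groups with jittered counts.
#' @param frac_jcn_only Fraction of alternative 5'/3' splice-site events
#'   flagged junction-only.
#' @param frac_novel_ir Fraction of intron-retention events flagged novel.
#' @param outlier_sample_rate,outlier_event_rate Burden cohorts: fraction of
#'   samples designated outliers, and fraction of events displaced within
#'   each outlier sample.
#' @param outlier_deviation Magnitude of the planted PSI displacement for
#'   outlier cells, in PSI points; must exceed 0.
#' @param outlier_group_ratio Relative odds that an outlier sample falls in
#'   the last (exposed) group rather than the first.
#' @param psi_noise_sd Gaussian noise (PSI points) around the shared event
#'   baseline in burden cohorts.
#' @param true_allele_fraction Default per-sample mutant-allele fraction for
#'   pileup simulation.
#' @param depth Default sequencing depth at the mutation locus.
#'
#' @return An object of class `sim_config` (a named list).
#' @examples
#' cfg <- sim_config(seed = 1, n_events = 200)
#' sim <- simulate_splicing_cohort(cfg)
#' head(sim$counts)
#' @export
sim_config <- function(seed = 1L,
                       n_events = 1000L,
                       n_samples_per_group = c(ref = 6L, test = 6L),
                       event_type_proportions = NULL,
                       frac_differential = 0.1,
                       effect_dpsi = 20,
                       baseline_psi_shape = c(2, 2),
                       coverage_mean = 100,
                       dispersion = 0.01,
                       missing_rate = 0.02,
                       frac_redundant = 0.05,
                       frac_jcn_only = 0.1,
                       frac_novel_ir = 0.3,
                       outlier_sample_rate = 0.1,
                       outlier_event_rate = 0.1,
                       outlier_deviation = 30,
                       outlier_group_ratio = 3,
                       psi_noise_sd = 2,
                       true_allele_fraction = 0.3,
                       depth = 1000L) {
  if (is.null(event_type_proportions)) {
    event_type_proportions <- c(
      cassette = 0.35, mutually_exclusive = 0.05, coordinate_cassette = 0.05,
      alt_5ss = 0.10, alt_3ss = 0.10, alt_first_exon = 0.10,
      alt_last_exon = 0.05, intron_retention = 0.20
    )
  }
  if (!is_scalar_number(seed)) abort("`seed` must be a single integer")
  if (!is_scalar_number(n_events) || n_events < 1) {
    abort("`n_events` must be a positive count")
  }
  if (is.null(names(n_samples_per_group)) ||
      anyDuplicated(names(n_samples_per_group)) ||
      any(n_samples_per_group < 2)) {
    abort("`n_samples_per_group` must be uniquely named with >= 2 samples per group")
  }
  if (!setequal(names(event_type_proportions), EVENT_TYPES)) {
    abort("`event_type_proportions` must be named by the 8 categories in EVENT_TYPES")
  }
  if (any(event_type_proportions < 0) ||
      abs(sum(event_type_proportions) - 1) > 1e-9) {
    abort("`event_type_proportions` must be non-negative and sum to 1")
  }
  for (nm in c("frac_differential", "missing_rate", "frac_redundant",
               "frac_jcn_only", "frac_novel_ir", "outlier_sample_rate",
               "outlier_event_rate", "true_allele_fraction")) {
    assert_fraction(get(nm), nm)
  }
  if (!is_scalar_number(coverage_mean) || coverage_mean <= 0) {
    abort("`coverage_mean` must be positive")
  }
  if (!is_scalar_number(dispersion) || dispersion <= 0 || dispersion >= 1) {
    abort("`dispersion` must lie strictly inside (0, 1)")
  }
  if (!is_scalar_number(outlier_deviation) || outlier_deviation <= 0) {
    abort("`outlier_deviation` must be positive")
  }
  if (!is_scalar_number(effect_dpsi) || effect_dpsi < 0) {
    abort("`effect_dpsi` must be non-negative")
  }
  if (!is_scalar_number(psi_noise_sd) || psi_noise_sd < 0) {
    abort("`psi_noise_sd` must be non-negative")
  }
  if (!is_scalar_number(depth) || depth < 1) abort("`depth` must be positive")
  if (length(baseline_psi_shape) != 2 || any(baseline_psi_shape <= 0)) {
    abort("`baseline_psi_shape` must be two positive beta shapes")
  }
  structure(
    list(
      seed = as.integer(seed), n_events = as.integer(n_events),
      n_samples_per_group = setNames(as.integer(n_samples_per_group),
                                     names(n_samples_per_group)),
      event_type_proportions = event_type_proportions[EVENT_TYPES],
      frac_differential = frac_differential, effect_dpsi = effect_dpsi,
      baseline_psi_shape = baseline_psi_shape,
      coverage_mean = coverage_mean, dispersion = dispersion,
      missing_rate = missing_rate, frac_redundant = frac_redundant,
      frac_jcn_only = frac_jcn_only, frac_novel_ir = frac_novel_ir,
      outlier_sample_rate = outlier_sample_rate,
      outlier_event_rate = outlier_event_rate,
      outlier_deviation = outlier_deviation,
      outlier_group_ratio = outlier_group_ratio,
      psi_noise_sd = psi_noise_sd,
      true_allele_fraction = true_allele_fraction,
      depth = as.integer(depth)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  seed:", x$seed, " events:", x$n_events, "\n")
  cat("  samples:", paste(sprintf("%s=%d", names(x$n_samples_per_group),
                                  x$n_samples_per_group), collapse = ", "), "\n")
  cat(sprintf("  differential: %.0f%% at dPSI %.1f; coverage %g; rho %g\n",
              100 * x$frac_differential, x$effect_dpsi,
              x$coverage_mean, x$dispersion))
  invisible(x)
}

# overdispersed inclusion counts: inclusion ~ BetaBin(size, mu, rho)
rbetabinom <- function(n, size, mu, rho) {
  shape1 <- mu * (1 - rho) / rho
  shape2 <- (1 - mu) * (1 - rho) / rho
  p <- rep(0, n)
  ok <- mu > 0 & mu < 1
  p[ok] <- rbeta(sum(ok), shape1[ok], shape2[ok])
  p[mu >= 1] <- 1
  rbinom(n, size, p)
}

sim_event_annotations <- function(config) {
  n <- config$n_events
  event_type <- sample(EVENT_TYPES, n, replace = TRUE,
                       prob = config$event_type_proportions)
  gene <- sprintf("G%05d", sample.int(max(2L, ceiling(n / 2)), n, replace = TRUE))
  novelty <- ifelse(
    event_type == "intron_retention" & runif(n) < config$frac_novel_ir,
    "novel", "known"
  )
  junction_only <- event_type %in% c("alt_5ss", "alt_3ss") &
    runif(n) < config$frac_jcn_only
  chr <- sample(1:22, n, replace = TRUE)
  start <- sample.int(2e8, n, replace = TRUE)
  width <- sample.int(5e4, n, replace = TRUE)
  tibble(
    event_id = sprintf("chr%d:%d-%d;%s;e%05d", chr, start, start + width,
                       event_type, seq_len(n)),
    gene = gene, event_type = event_type, novelty = novelty,
    junction_only = junction_only, redundancy_group = NA_character_
  )
}

sim_sample_sheet <- function(config) {
  npg <- config$n_samples_per_group
  groups <- names(npg)
  sample_id <- unlist(lapply(groups, function(g) {
    sprintf("%s_%02d", g, seq_len(npg[[g]]))
  }))
  tibble(
    sample_id = sample_id,
    group = rep(groups, times = npg),
    batch = sprintf("clone%d", rep_len(1:2, length(sample_id)))
  )
}

counts_to_long <- function(events, sample_ids, incl, excl) {
  n <- nrow(events)
  out <- tibble(
    event_id = rep(events$event_id, times = length(sample_ids)),
    sample_id = rep(sample_ids, each = n),
    inclusion = as.vector(incl),
    exclusion = as.vector(excl)
  )
  dplyr::left_join(out, events, by = "event_id") |>
    dplyr::relocate("event_id", "gene", "event_type", "novelty",
                    "junction_only", "redundancy_group")
}

#' Simulate a two-group splicing cohort with planted differential events
#'
#' Draws a baseline PSI per event, shifts the test group's true PSI by
#' `effect_dpsi` (random sign, clamped to \[0, 100\]) for a planted fraction
#' of events, then generates length-normalized inclusion/exclusion counts:
#' totals are Poisson with mean `coverage_mean` and inclusion counts are
#' beta-binomial around the true PSI with overdispersion `dispersion`.
#' A fraction of events is duplicated into redundancy groups with jittered
#' counts, and cells are blanked at `missing_rate`.
#'
#' @param config A [sim_config()] with exactly two groups.
#' @return A list of class `splicing_sim`:
#' \describe{
#'   \item{counts}{long tibble: event annotations, `sample_id`,
#'     `inclusion`, `exclusion` (NA = missing cell).}
#'   \item{samples}{sample metadata (`sample_id`, `group`, `batch`).}
#'   \item{truth}{per event: `baseline_psi`, `is_differential`,
#'     `planted_dpsi` (signed, after clamping; 0 for null events).}
#'   \item{config}{the input configuration.}
#' }
#' @examples
#' sim <- simulate_splicing_cohort(sim_config(seed = 42, n_events = 100))
#' sum(sim$truth$is_differential)
#' @export
simulate_splicing_cohort <- function(config) {
  if (!inherits(config, "sim_config")) abort("`config` must be a sim_config")
  npg <- config$n_samples_per_group
  if (length(npg) != 2) {
    abort("splicing cohort simulation requires exactly two groups")
  }
  with_sub_seed(config$seed, 101L, {
    events <- sim_event_annotations(config)
    samples <- sim_sample_sheet(config)
    n <- config$n_events
    n_s <- nrow(samples)
    test_cols <- samples$group == names(npg)[2]

    baseline <- rbeta(n, config$baseline_psi_shape[1],
                      config$baseline_psi_shape[2]) * 100
    n_diff <- round(config$frac_differential * n)
    diff_idx <- if (n_diff > 0) sort(sample.int(n, n_diff)) else integer(0)
    direction <- integer(n)
    if (n_diff > 0) direction[diff_idx] <- sample(c(-1L, 1L), n_diff, replace = TRUE)
    test_psi <- clamp_psi(baseline + direction * config$effect_dpsi)
    planted_dpsi <- test_psi - baseline # clamped truth; 0 for null events

    true_psi <- matrix(baseline, n, n_s)
    true_psi[, test_cols] <- test_psi
    total <- matrix(rpois(n * n_s, config$coverage_mean), n, n_s)
    incl <- matrix(
      rbetabinom(n * n_s, as.vector(total), as.vector(true_psi) / 100,
                 config$dispersion),
      n, n_s
    )
    excl <- total - incl

    truth <- tibble(
      event_id = events$event_id,
      event_type = events$event_type,
      baseline_psi = baseline,
      is_differential = direction != 0L,
      planted_dpsi = planted_dpsi
    )

    # redundancy groups: duplicate events with jittered ids and counts
    n_dup <- round(config$frac_redundant * n)
    if (n_dup > 0) {
      dup_idx <- sort(sample.int(n, n_dup))
      rg <- sprintf("rg%05d", dup_idx)
      events$redundancy_group[dup_idx] <- rg
      dup_events <- events[dup_idx, ]
      dup_events$event_id <- sub(";e", ";r", dup_events$event_id, fixed = TRUE)
      incl_dup <- pmax(incl[dup_idx, , drop = FALSE] +
                         matrix(round(rnorm(n_dup * n_s, 0, 2)), n_dup, n_s), 0)
      excl_dup <- pmax(excl[dup_idx, , drop = FALSE] +
                         matrix(round(rnorm(n_dup * n_s, 0, 2)), n_dup, n_s), 0)
      events <- dplyr::bind_rows(events, dup_events)
      incl <- rbind(incl, incl_dup)
      excl <- rbind(excl, excl_dup)
      truth_dup <- truth[dup_idx, ]
      truth_dup$event_id <- dup_events$event_id
      truth <- dplyr::bind_rows(truth, truth_dup)
    }

    if (config$missing_rate > 0) {
      drop <- matrix(runif(nrow(events) * n_s) < config$missing_rate,
                     nrow(events), n_s)
      incl[drop] <- NA_real_
      excl[drop] <- NA_real_
    }

    structure(
      list(
        counts = counts_to_long(events, samples$sample_id, incl, excl),
        samples = samples, truth = truth, config = config
      ),
      class = "splicing_sim"
    )
  })
}

#' Simulate a PSI cohort with planted outlier-burden samples
#'
#' Every sample shares an event-level baseline PSI plus Gaussian noise
#' (`psi_noise_sd`). A subset of samples, drawn at `outlier_sample_rate` and
#' enriched in the second (exposed) group by `outlier_group_ratio`, has a
#' fraction `outlier_event_rate` of its events displaced by
#' `outlier_deviation` PSI points (sign chosen to stay inside \[0, 100\]).
#'
#' @param config A [sim_config()] with two groups, e.g.
#'   `n_samples_per_group = c(unexposed = 10, exposed = 10)`.
#' @return A list of class `burden_sim` with elements `psi` (long tibble of
#'   event annotations, `sample_id`, `psi`), `samples`, `truth` (one row per
#'   displaced sample x event cell), `outlier_samples`, and `config`.
#' @examples
#' sim <- simulate_burden_cohort(
#'   sim_config(seed = 3, n_events = 200,
#'              n_samples_per_group = c(unexposed = 10, exposed = 10))
#' )
#' sim$outlier_samples
#' @export
simulate_burden_cohort <- function(config) {
  if (!inherits(config, "sim_config")) abort("`config` must be a sim_config")
  npg <- config$n_samples_per_group
  if (length(npg) != 2) {
    abort("burden cohort simulation requires exactly two groups")
  }
  with_sub_seed(config$seed, 202L, {
    events <- sim_event_annotations(config)
    samples <- sim_sample_sheet(config)
    n <- config$n_events
    n_s <- nrow(samples)
    baseline <- rbeta(n, config$baseline_psi_shape[1],
                      config$baseline_psi_shape[2]) * 100
    psi <- clamp_psi(baseline + matrix(rnorm(n * n_s, 0, config$psi_noise_sd),
                                       n, n_s))

    k_out <- round(config$outlier_sample_rate * n_s)
    outlier_samples <- character(0)
    truth <- tibble(sample_id = character(0), event_id = character(0),
                    deviation = numeric(0))
    if (k_out > 0) {
      w <- ifelse(samples$group == names(npg)[2], config$outlier_group_ratio, 1)
      outlier_samples <- sample(samples$sample_id, k_out, prob = w)
      m_ev <- round(config$outlier_event_rate * n)
      dev <- config$outlier_deviation
      cells <- lapply(outlier_samples, function(s) {
        j <- match(s, samples$sample_id)
        ev <- sort(sample.int(n, m_ev))
        dir <- ifelse(
          baseline[ev] + dev > 100, -1,
          ifelse(baseline[ev] - dev < 0, 1,
                 sample(c(-1, 1), length(ev), replace = TRUE))
        )
        psi[ev, j] <<- clamp_psi(baseline[ev] + dir * dev +
                                   rnorm(length(ev), 0, config$psi_noise_sd))
        tibble(sample_id = s, event_id = events$event_id[ev],
               deviation = dir * dev)
      })
      truth <- dplyr::bind_rows(cells)
    }

    if (config$missing_rate > 0) {
      psi[matrix(runif(n * n_s) < config$missing_rate, n, n_s)] <- NA_real_
    }

    psi_long <- tibble(
      event_id = rep(events$event_id, times = n_s),
      sample_id = rep(samples$sample_id, each = n),
      psi = as.vector(psi)
    ) |>
      dplyr::left_join(events, by = "event_id") |>
      dplyr::relocate("event_id", "gene", "event_type", "novelty",
                      "junction_only", "redundancy_group")

    structure(
      list(psi = psi_long, samples = samples, truth = truth,
           outlier_samples = sort(outlier_samples), config = config),
      class = "burden_sim"
    )
  })
}

#' Simulate a differential-expression summary table
#'
#' Emulates the (gene, log2 fold change, adjusted p) summary that a
#' count-based differential-expression fit produces, with member genes of
#' planted gene sets shifted in log2FC and guaranteed small adjusted
#' p-values so they survive the ranked-list filter.
#'
#' @param config A [sim_config()]; only its seed is used.
#' @param n_genes Gene universe size.
#' @param planted_sets Named list of gene vectors; each must be a subset of
#'   the universe `G00001 ... G<n_genes>`.
#' @param effect_log2fc Mean log2FC shift added to member genes.
#' @param sig_fraction Fraction of non-member genes with padj below 0.05.
#' @param member_padj_max Upper bound of the member genes' padj draw.
#' @return A list of class `expression_sim` with `de` (tibble of `gene`,
#'   `log2fc`, `padj`), `truth` (gene membership), `sets`, `config`.
#' @examples
#' cfg <- sim_config(seed = 5)
#' sets <- list(setA = sprintf("G%05d", 1:25))
#' sim <- simulate_expression_results(cfg, n_genes = 500, planted_sets = sets)
#' @export
simulate_expression_results <- function(config, n_genes = 1000,
                                        planted_sets = list(),
                                        effect_log2fc = 2,
                                        sig_fraction = 0.3,
                                        member_padj_max = 0.04) {
  if (!inherits(config, "sim_config")) abort("`config` must be a sim_config")
  genes <- sprintf("G%05d", seq_len(n_genes))
  members <- unique(unlist(planted_sets))
  if (!all(members %in% genes)) {
    abort("every planted set must be a subset of the gene universe")
  }
  with_sub_seed(config$seed, 303L, {
    log2fc <- rnorm(n_genes, 0, 1)
    is_member <- genes %in% members
    log2fc[is_member] <- log2fc[is_member] + effect_log2fc
    padj <- ifelse(runif(n_genes) < sig_fraction,
                   runif(n_genes, 0, 0.05), runif(n_genes, 0.05, 1))
    padj[is_member] <- runif(sum(is_member), 0, member_padj_max)
    structure(
      list(
        de = tibble(gene = genes, log2fc = log2fc, padj = padj),
        truth = tibble(gene = genes, is_member = is_member),
        sets = planted_sets, config = config
      ),
      class = "expression_sim"
    )
  })
}

#' Simulate per-sample base counts at a mutation locus
#'
#' Mutant-base reads are binomial in the sequencing depth and the true
#' mutant-allele fraction; the remaining reads carry the reference base.
#'
#' @param config A [sim_config()]; supplies the seed and the defaults for
#'   `fractions` and `depth`.
#' @param fractions Per-sample true mutant fractions in \[0, 1\] (recycled
#'   names become sample ids when unnamed).
#' @param depth Locus depth per sample (recycled).
#' @param mutant_base,ref_base Single bases among A/C/G/T.
#' @return A tibble of class `allele_counts`: `sample_id`, `A`, `C`, `G`,
#'   `T`.
#' @examples
#' simulate_pileup(sim_config(seed = 9), fractions = c(0.3, 0.5), depth = 100)
#' @export
simulate_pileup <- function(config, fractions = NULL, depth = NULL,
                            mutant_base = "A", ref_base = "G") {
  if (!inherits(config, "sim_config")) abort("`config` must be a sim_config")
  fractions <- fractions %||% rep(config$true_allele_fraction, 6)
  depth <- depth %||% config$depth
  if (any(fractions < 0 | fractions > 1)) {
    abort("`fractions` must lie in [0, 1]")
  }
  if (any(depth <= 0)) abort("`depth` must be positive")
  bases <- c("A", "C", "G", "T")
  if (!mutant_base %in% bases || !ref_base %in% bases ||
      mutant_base == ref_base) {
    abort("`mutant_base` and `ref_base` must be distinct bases in A/C/G/T")
  }
  n <- length(fractions)
  depth <- rep_len(as.integer(depth), n)
  ids <- names(fractions) %||% sprintf("sample_%02d", seq_len(n))
  with_sub_seed(config$seed, 404L, {
    mutant <- rbinom(n, depth, fractions)
    out <- tibble(sample_id = ids, A = 0L, C = 0L, G = 0L, T = 0L)
    out[[mutant_base]] <- mutant
    out[[ref_base]] <- depth - mutant
    class(out) <- c("allele_counts", class(out))
    out
  })
}
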