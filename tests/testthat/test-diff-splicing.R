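make_psi <- function(values) {
  # values: named list event_id -> named numeric vector (names = samples)
  purrr::map_dfr(names(values), function(ev) {
    tibble::tibble(event_id = ev, sample_id = names(values[[ev]]),
                   psi = unname(values[[ev]]))
  })
}

two_group_meta <- function(n_ref = 3, n_test = 3) {
  tibble::tibble(
    sample_id = c(sprintf("r%d", seq_len(n_ref)),
                  sprintf("t%d", seq_len(n_test))),
    group = rep(c("ref", "test"), c(n_ref, n_test))
  )
}

test_that("group means, dPSI and degenerate ties behave as specified", {
  meta <- two_group_meta()
  psi <- make_psi(list(
    flat = c(r1 = 50, r2 = 50, r3 = 50, t1 = 50, t2 = 50, t3 = 50),
    up = c(r1 = 10, r2 = 12, r3 = 11, t1 = 40, t2 = 42, t3 = 41),
    const_diff = c(r1 = 20, r2 = 20, r3 = 20, t1 = 80, t2 = 80, t3 = 80)
  ))
  res <- compare_groups(psi, meta, "ref", "test")
  flat <- res[res$event_id == "flat", ]
  expect_equal(flat$delta_psi, 0)
  expect_equal(flat$p_raw, 1) # both groups constant and equal
  expect_false(flat$significant)
  up <- res[res$event_id == "up", ]
  expect_equal(up$delta_psi, 30)
  cd <- res[res$event_id == "const_diff", ]
  expect_equal(cd$p_raw, .Machine$double.xmin) # constant but different
  # invariant: delta equals difference of reported means
  expect_equal(res$delta_psi, res$mean_psi_test - res$mean_psi_ref,
               tolerance = 1e-9)
  expect_error(compare_groups(psi, meta, "ref", "nonexistent"), "unknown group")
})

test_that("per-event p-values match t.test for both flavors", {
  withr::with_seed(42, {
    n_ev <- 40
    meta <- two_group_meta(5, 6)
    psi <- purrr::map_dfr(seq_len(n_ev), function(i) {
      v <- runif(11, 10, 90)
      v[sample(11, sample(0:2, 1))] <- NA # some missing cells
      tibble::tibble(event_id = sprintf("e%02d", i),
                     sample_id = meta$sample_id, psi = v)
    })
  })
  for (flavor in c("pooled", "welch")) {
    res <- compare_groups(psi, meta, "ref", "test", test_flavor = flavor)
    oracle <- vapply(res$event_id, function(ev) {
      v <- psi$psi[psi$event_id == ev]
      x <- v[1:5]
      y <- v[6:11]
      if (sum(!is.na(x)) < 2 || sum(!is.na(y)) < 2) return(NA_real_)
      stats::t.test(y, x, var.equal = (flavor == "pooled"))$p.value
    }, numeric(1))
    expect_equal(res$p_raw, unname(oracle), tolerance = 1e-12,
                 info = flavor)
  }
})

test_that("BH adjustment equals the step-up definition and spec example", {
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.04), "BH"),
               c(0.03, 0.03, 0.04))
  meta <- two_group_meta(4, 4)
  withr::with_seed(9, {
    psi <- purrr::map_dfr(1:60, function(i) {
      tibble::tibble(event_id = sprintf("e%02d", i),
                     sample_id = meta$sample_id,
                     psi = runif(8, 20, 80) + c(0, 0, 0, 0, rep(i %% 3, 4)))
    })
  })
  res <- compare_groups(psi, meta, "ref", "test")
  expect_equal(res$p_adj[res$tested],
               bh_stepup_oracle(res$p_raw[res$tested]), tolerance = 1e-12)
  expect_true(all(res$p_adj >= res$p_raw, na.rm = TRUE))
})

test_that("untested events are excluded from the correction family", {
  meta <- two_group_meta()
  psi <- make_psi(list(
    ok = c(r1 = 10, r2 = 20, r3 = 30, t1 = 50, t2 = 60, t3 = 70),
    thin = c(r1 = 10, r2 = NA, r3 = NA, t1 = 50, t2 = 60, t3 = 70)
  ))
  res <- compare_groups(psi, meta, "ref", "test")
  thin <- res[res$event_id == "thin", ]
  expect_false(thin$tested)
  expect_true(is.na(thin$p_adj))
  ok <- res[res$event_id == "ok", ]
  expect_equal(ok$p_adj, ok$p_raw) # family of size 1
})

test_that("swapping reference and test negates dPSI and keeps p", {
  sim <- simulate_splicing_cohort(sim_config(seed = 14, n_events = 120))
  psi <- compute_psi(sim$counts)
  ab <- compare_groups(psi, sim$samples, "ref", "test")
  ba <- compare_groups(psi, sim$samples, "test", "ref")
  expect_equal(ab$delta_psi, -ba$delta_psi, tolerance = 1e-9)
  expect_equal(ab$p_raw, ba$p_raw, tolerance = 1e-12)
})

test_that("non-redundant selection keeps the best event per group", {
  res <- tibble::tibble(
    event_id = c("a1", "a2", "b1", "b2", "b3", "c1", "lone"),
    delta_psi = c(12, 15, 15, 25, 25, 11, 30),
    p_adj = c(0.01, 0.20, 0.05, 0.05, 0.05, 0.9, 0.02),
    redundancy_group = c("A", "A", "B", "B", "B", "C", NA)
  )
  nr <- make_nonredundant(res)
  expect_identical(sort(nr$event_id), sort(c("a1", "b2", "c1", "lone")))
  # a1: smallest p_adj; b2: p tie, |dPSI| tie broken by event id; 3 groups in,
  # 3 group representatives + 1 ungrouped out
  expect_identical(nrow(nr), 4L)
  # tie on p, different |dPSI|: larger wins
  res2 <- tibble::tibble(
    event_id = c("x1", "x2"), delta_psi = c(15, 25),
    p_adj = c(0.05, 0.05), redundancy_group = "X"
  )
  expect_identical(make_nonredundant(res2)$event_id, "x2")
})

test_that("redundancy-group assignment links events sharing coordinates", {
  ev <- tibble::tibble(
    event_id = c("chr1:1000-2000;x", "chr1:2000-3000;y", "chr1:7000-8000;z",
                 "chr2:1000-2000;w"),
    gene = c("GA", "GA", "GA", "GA"),
    event_type = c("cassette", "cassette", "cassette", "alt_5ss")
  )
  out <- assign_redundancy_groups(ev)
  # first two share the token 2000 within the same gene/type
  expect_identical(out$redundancy_group[1], out$redundancy_group[2])
  expect_true(is.na(out$redundancy_group[3]))
  expect_true(is.na(out$redundancy_group[4])) # different event type
})

test_that("event-type distributions count significant events per category", {
  res <- tibble::tibble(
    event_type = c(rep("cassette", 5), rep("intron_retention", 3)),
    significant = TRUE
  )
  d <- event_type_distribution(res)
  expect_identical(d$n[d$event_type == "cassette"], 5L)
  expect_identical(d$n[d$event_type == "intron_retention"], 3L)
  expect_identical(sum(d$n), 8L)
  empty <- event_type_distribution(res[0, ])
  expect_identical(sum(empty$n), 0L)
  expect_identical(nrow(empty), 8L)
})

test_that("planted category proportions are recovered in significant calls", {
  props <- c(cassette = 0.5, mutually_exclusive = 0, coordinate_cassette = 0,
             alt_5ss = 0, alt_3ss = 0, alt_first_exon = 0.5,
             alt_last_exon = 0, intron_retention = 0)
  cfg <- sim_config(seed = 19, n_events = 1000, frac_differential = 0.3,
                    effect_dpsi = 30, event_type_proportions = props)
  sim <- simulate_splicing_cohort(cfg)
  psi <- filter_events(compute_psi(sim$counts), diff_splicing_rules())
  res <- make_nonredundant(compare_groups(psi, sim$samples, "ref", "test"))
  d <- event_type_distribution(res)
  obs <- d$n / sum(d$n)
  expect_lt(abs(obs[d$event_type == "cassette"] - 0.5), 0.1)
  expect_lt(abs(obs[d$event_type == "alt_first_exon"] - 0.5), 0.1)
})

test_that("distribution comparison: identical inputs give p near 1", {
  d <- structure(
    tibble::tibble(
      event_type = factor(EVENT_TYPES, levels = EVENT_TYPES),
      n = c(10L, 5L, 3L, 2L, 2L, 4L, 1L, 8L)
    ),
    class = c("event_type_distribution", "tbl_df", "tbl", "data.frame")
  )
  cmp <- compare_distributions(d, d)
  expect_gte(cmp$overall_p, 0.999)
  expect_equal(cmp$per_category$p, rep(1, 8), tolerance = 1e-9)
  expect_equal(cmp$per_category$p_adj, rep(1, 8), tolerance = 1e-9)
})

test_that("per-category Fisher tests match hypergeometric enumeration", {
  tabs <- list(
    matrix(c(3, 5, 1, 4), nrow = 2),
    matrix(c(10, 0, 0, 10), nrow = 2),
    matrix(c(2, 7, 8, 2), nrow = 2),
    matrix(c(0, 4, 0, 9), nrow = 2)
  )
  for (tab in tabs) {
    got <- psitools:::fisher_exact_2x2(tab)$p_value
    expect_equal(got, fisher_2x2_oracle(tab), tolerance = 1e-9)
  }
  # the diagonal table's p from first principles
  expect_equal(psitools:::fisher_exact_2x2(tabs[[2]])$p_value,
               2 / choose(20, 10), tolerance = 1e-9)
  # invariance to transposition and to swapping both rows and columns
  tab <- tabs[[3]]
  p0 <- psitools:::fisher_exact_2x2(tab)$p_value
  expect_equal(psitools:::fisher_exact_2x2(t(tab))$p_value, p0)
  expect_equal(psitools:::fisher_exact_2x2(tab[2:1, 2:1])$p_value, p0)
})

test_that("power rises with effect size and coverage", {
  recovery <- function(effect, coverage) {
    cfg <- sim_config(seed = 23, n_events = 1000, frac_differential = 0.2,
                      effect_dpsi = effect, coverage_mean = coverage)
    sim <- simulate_splicing_cohort(cfg)
    psi <- compute_psi(sim$counts)
    res <- compare_groups(psi, sim$samples, "ref", "test")
    called <- res$event_id[res$significant]
    hits <- sum(sim$truth$is_differential[match(called, sim$truth$event_id)])
    n_planted <- sum(sim$truth$is_differential)
    c(rate = hits / n_planted, se = sqrt(0.25 / n_planted))
  }
  by_effect <- vapply(c(5, 15, 25), recovery, numeric(2), coverage = 100)
  expect_true(all(diff(by_effect["rate", ]) >= -max(by_effect["se", ])))
  by_cov <- vapply(c(30, 100, 300), function(cv) recovery(15, cv),
                   numeric(2))
  expect_true(all(diff(by_cov["rate", ]) >= -max(by_cov["se", ])))
})
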