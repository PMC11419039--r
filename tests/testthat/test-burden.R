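psi_of <- function(values, event = "e1") {
  tibble::tibble(event_id = event,
                 sample_id = sprintf("s%02d", seq_along(values)),
                 psi = values)
}

test_that("robust statistics use interpolated quartiles", {
  got <- event_robust_stats(psi_of(c(rep(50, 8), 90)))
  expect_equal(got$median, 50)
  expect_equal(got$iqr, 0)
  got2 <- event_robust_stats(psi_of(c(10, 20, 30, 40)))
  expect_equal(got2$median, 25)
  expect_equal(got2$iqr, 32.5 - 17.5) # type-7 interpolated quartiles
  got3 <- event_robust_stats(psi_of(rep(42, 6)))
  expect_equal(got3$iqr, 0)
  # events with fewer than 4 usable values are excluded with a warning
  psi <- dplyr::bind_rows(psi_of(c(1, 2, 3), event = "thin"),
                          psi_of(c(1, 2, 3, 4), event = "ok"))
  expect_warning(out <- event_robust_stats(psi), "fewer than 4")
  expect_identical(out$event_id, "ok")
})

test_that("the alteration rule requires both the IQR and absolute margins", {
  stats <- tibble::tibble(event_id = c("wide", "tight", "null"),
                          median = c(50, 50, 50), iqr = c(0, 4, 4))
  psi <- tibble::tibble(
    event_id = c("wide", "tight", "null"),
    sample_id = "s1",
    psi = c(90, 58, 50)
  )
  flags <- flag_alterations(psi, stats)
  expect_identical(flags$altered[flags$event_id == "wide"], TRUE)   # 40 > 0, > 10
  expect_identical(flags$altered[flags$event_id == "tight"], FALSE) # 8 > 6 but not > 10
  expect_identical(flags$altered[flags$event_id == "null"], FALSE)  # at the median
  # missing cells are never flagged
  psi$psi <- NA_real_
  expect_false(any(flag_alterations(psi, stats)$altered))
  # mismatched event sets are rejected
  expect_error(
    flag_alterations(psi[psi$event_id != "wide", ], stats),
    "absent"
  )
})

test_that("with zero IQR the rule reduces to the absolute deviation", {
  withr::with_seed(5, {
    psi <- psi_of(round(runif(30, 0, 100), 1))
  })
  stats <- tibble::tibble(event_id = "e1", median = 50, iqr = 0)
  flags <- flag_alterations(psi, stats, k = 1.5, min_dev = 10)
  expect_identical(flags$altered, abs(psi$psi - 50) > 10)
})

test_that("burden is monotone in both thresholds", {
  sim <- simulate_burden_cohort(
    sim_config(seed = 17, n_events = 300,
               n_samples_per_group = c(unexposed = 10L, exposed = 10L))
  )
  stats <- event_robust_stats(sim$psi)
  base <- sample_burden(flag_alterations(sim$psi, stats, k = 1.5, min_dev = 10))
  for (pars in list(c(2.5, 10), c(1.5, 20))) {
    harder <- sample_burden(
      flag_alterations(sim$psi, stats, k = pars[1], min_dev = pars[2])
    )
    merged <- dplyr::inner_join(base, harder, by = "sample_id")
    expect_true(all(merged$burden.y <= merged$burden.x))
  }
})

test_that("burden ignores sample order and median-constant events", {
  sim <- simulate_burden_cohort(
    sim_config(seed = 27, n_events = 100,
               n_samples_per_group = c(unexposed = 5L, exposed = 5L))
  )
  stats <- event_robust_stats(sim$psi)
  base <- sample_burden(flag_alterations(sim$psi, stats))
  shuffled <- withr::with_seed(1, sim$psi[sample(nrow(sim$psi)), ])
  again <- sample_burden(flag_alterations(shuffled, stats))
  expect_equal(dplyr::arrange(base, sample_id),
               dplyr::arrange(again, sample_id))
  # an event sitting exactly at its median everywhere adds nothing
  flat <- tibble::tibble(event_id = "flat",
                         sample_id = unique(sim$psi$sample_id), psi = 60)
  psi2 <- dplyr::bind_rows(sim$psi[c("event_id", "sample_id", "psi")], flat)
  stats2 <- event_robust_stats(psi2)
  with_flat <- sample_burden(flag_alterations(psi2, stats2))
  merged <- dplyr::inner_join(base, with_flat, by = "sample_id")
  expect_true(all(merged$burden.x == merged$burden.y))
})

test_that("planted outlier samples carry the largest burdens", {
  cfg <- sim_config(seed = 33, n_events = 500,
                    n_samples_per_group = c(unexposed = 10L, exposed = 10L),
                    outlier_sample_rate = 0.1, outlier_event_rate = 0.1,
                    outlier_deviation = 30, psi_noise_sd = 2)
  sim <- simulate_burden_cohort(cfg)
  k <- length(sim$outlier_samples)
  expect_identical(k, 2L)
  psi <- filter_events(sim$psi, burden_rules())
  burden <- sample_burden(flag_alterations(psi, event_robust_stats(psi)))
  top <- burden$sample_id[order(-burden$burden)][seq_len(k)]
  expect_setequal(top, sim$outlier_samples)
})

test_that("burden comparison follows the exact Mann-Whitney distribution", {
  prof <- function(values) {
    structure(tibble::tibble(
      sample_id = sprintf("s%02d", seq_along(values)),
      burden = values, n_events_evaluated = 100L
    ), class = c("burden_profile", "tbl_df", "tbl", "data.frame"))
  }
  meta6 <- tibble::tibble(sample_id = sprintf("s%02d", 1:6),
                          group = rep(c("a", "b"), each = 3))
  # identical samples: degenerate, p = 1
  same <- compare_burden(prof(c(1, 2, 3, 1, 2, 3)), meta6, "a", "b")
  expect_equal(same$p_value, 1, tolerance = 1e-6)
  # full separation of 3 vs 3: p = 2 / C(6,3)
  sep <- compare_burden(prof(c(1, 2, 3, 10, 11, 12)), meta6, "a", "b")
  expect_equal(sep$p_value, 0.1, tolerance = 1e-12)
  expect_identical(sep$method, "exact")
  expect_error(compare_burden(prof(c(1, 2, 1, 2, 3, 4)),
                              meta6[c(1, 2, 4, 5, 6), ], "a", "b"),
               "at least 3")
})

test_that("exact Mann-Whitney p equals full rank-split enumeration", {
  withr::with_seed(71, {
    for (i in 1:6) {
      n1 <- sample(3:8, 1)
      n2 <- sample(3:8, 1)
      x <- round(rnorm(n1, 0, 10), 4)
      y <- round(rnorm(n2, 1, 10), 4)
      got <- psitools:::mann_whitney(x, y)
      expect_identical(got$method, "exact")
      expect_equal(got$p_value, mw_exact_oracle(x, y), tolerance = 1e-9)
    }
  })
})

test_that("Mann-Whitney holds its size under a null burden model", {
  reject <- withr::with_seed(55, {
    vapply(seq_len(1000), function(i) {
      x <- rpois(15, 20)
      y <- rpois(15, 20)
      psitools:::mann_whitney(x, y)$p_value < 0.05
    }, logical(1))
  })
  expect_lt(abs(mean(reject) - 0.05), 0.02)
})
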