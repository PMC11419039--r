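test_that("expression ranked lists filter, deduplicate and sort", {
  de <- tibble::tibble(
    gene = c("gA", "gB"), log2fc = c(2, -1), padj = c(0.01, 0.2)
  )
  rl <- build_rank_from_expression(de)
  expect_identical(rl$gene, "gA")
  expect_equal(rl$score, 2)
  # duplicates keep the entry with the largest |log2FC| (sign preserved)
  dup <- tibble::tibble(
    gene = c("gA", "gA", "gZ"), log2fc = c(2, -3, 1),
    padj = c(0.01, 0.02, 0.01)
  )
  rl2 <- build_rank_from_expression(dup)
  expect_equal(rl2$score[rl2$gene == "gA"], -3)
  # sorted descending with gene-symbol tie-break
  expect_identical(rl2$gene, c("gZ", "gA"))
  expect_warning(
    empty <- build_rank_from_expression(de[de$padj > 0.5, ]),
    "no gene"
  )
  expect_identical(nrow(empty), 0L)
})

test_that("splicing ranked lists use |dPSI| with per-gene maxima", {
  ds <- tibble::tibble(
    gene = c("gA", "gA", "gB", "", "gC"),
    delta_psi = c(15, -20, 12, 50, 11),
    p_adj = c(0.1, 0.2, 0.01, 0.01, 0.3)
  )
  expect_message(rl <- build_rank_from_splicing(ds), "without gene symbol")
  expect_equal(rl$score[rl$gene == "gA"], 20) # highest |dPSI| kept
  expect_false("gC" %in% rl$gene) # padj 0.3 >= 0.25
  expect_true(all(rl$score >= 0))
})

test_that("enrichment score walks match the hand-derived examples", {
  rl <- as_ranked_list(tibble::tibble(
    gene = c("g1", "g2", "g3", "g4"), score = c(3, 2, 1, 0.5)
  ))
  expect_equal(enrichment_score(rl, "g1")$es, 1)
  expect_equal(enrichment_score(rl, "g4")$es, -1)
  whole <- enrichment_score(rl, rl$gene)
  expect_equal(whole$es,
               es_bruteforce_oracle(rl$gene, rl$score, rl$gene))
  expect_equal(whole$es, 1) # monotone walk with no misses
  none <- enrichment_score(rl, "absent")
  expect_false(none$evaluable)
})

test_that("streaming and hit-boundary scores equal brute force", {
  withr::with_seed(77, {
    for (i in 1:12) {
      n <- sample(5:50, 1)
      rl <- random_ranked_list(n, seed = 1000 + i)
      set <- sample(rl$gene, sample.int(n, 1))
      w <- sample(c(0, 1), 1)
      oracle <- es_bruteforce_oracle(rl$gene, rl$score, set, weight = w)
      expect_equal(enrichment_score(rl, set, weight = w)$es, oracle,
                   tolerance = 1e-12)
      a <- abs(rl$score)^w
      expect_equal(
        psitools:::es_from_hits(a, which(rl$gene %in% set), n),
        oracle, tolerance = 1e-12
      )
    }
  })
})

test_that("ES is scale-invariant and reversal-antisymmetric", {
  rl <- random_ranked_list(30, seed = 81)
  set <- rl$gene[c(2, 9, 15, 28)]
  base <- enrichment_score(rl, set)$es
  scaled <- rl
  scaled$score <- scaled$score * 13.7
  expect_equal(enrichment_score(scaled, set)$es, base, tolerance = 1e-12)
  # negating all scores reverses the ranked order; for weight 0 (and for
  # single-gene sets at weight 1) the ES negates
  reversed <- as_ranked_list(tibble::tibble(gene = rl$gene,
                                            score = -rl$score))
  expect_equal(enrichment_score(reversed, set, weight = 0)$es,
               -enrichment_score(rl, set, weight = 0)$es, tolerance = 1e-12)
  single <- rl$gene[7]
  expect_equal(enrichment_score(reversed, single)$es,
               -enrichment_score(rl, single)$es, tolerance = 1e-12)
})

test_that("the ES walk agrees with an independent implementation", {
  skip_if_not_installed("fgsea")
  rl <- random_ranked_list(60, seed = 91)
  stats <- setNames(rl$score, rl$gene)
  for (size in c(3, 10, 25)) {
    set <- withr::with_seed(size, sample(rl$gene, size))
    ours <- enrichment_score(rl, set)$es
    theirs <- fgsea::calcGseaStat(stats, which(rl$gene %in% set),
                                  gseaParam = 1)
    expect_equal(ours, theirs, tolerance = 1e-9)
  }
})

test_that("preranked enrichment is deterministic and order-invariant", {
  rl <- random_ranked_list(300, seed = 101)
  sets <- list(
    a = rl$gene[1:20], b = withr::with_seed(2, sample(rl$gene, 35)),
    c = withr::with_seed(3, sample(rl$gene, 12))
  )
  r1 <- gsea_preranked(rl, sets, n_perm = 200, seed = 5)
  r2 <- gsea_preranked(rl, sets, n_perm = 200, seed = 5)
  expect_identical(tidy(r1), tidy(r2))
  r3 <- gsea_preranked(rl, sets[c(3, 1, 2)], n_perm = 200, seed = 5)
  expect_equal(
    dplyr::arrange(tidy(r1), set), dplyr::arrange(tidy(r3), set)
  )
  expect_true(all(r1$p_nominal >= 1 / 201, na.rm = TRUE))
  expect_true(all(sign(r1$nes) == sign(r1$es) | r1$es == 0, na.rm = TRUE))
  expect_error(gsea_preranked(rl, sets, n_perm = 50), "at least 100")
  expect_error(
    gsea_preranked(rl, list(huge = c(rl$gene, "zzz", sprintf("x%d", 1:300)))),
    "larger than"
  )
})

test_that("a planted top-ranked set is called enriched", {
  withr::with_seed(111, {
    rl <- as_ranked_list(tibble::tibble(
      gene = sprintf("G%04d", 1:1000),
      score = sort(rnorm(1000, 0, 1), decreasing = TRUE)
    ))
  })
  sets <- list(planted = rl$gene[1:20],
               decoy = withr::with_seed(4, sample(rl$gene, 40)))
  res <- gsea_preranked(rl, sets, n_perm = 500, seed = 9)
  planted <- res[res$set == "planted", ]
  expect_gt(planted$nes, 0)
  expect_lt(planted$fdr_q, 0.25)
  expect_lt(planted$p_nominal, 0.05)
})

test_that("the reporting filter zeroes non-passing cells", {
  res <- tibble::tibble(
    comparison = c("c1", "c1", "c2", "c2"),
    set = c("s1", "s2", "s1", "s2"),
    nes = c(2.1, 1.5, -1.8, 0.4),
    p_nominal = c(0.001, 0.01, 0.002, 0.5),
    fdr_q = c(0.01, 0.30, 0.10, 0.9)
  )
  m <- filter_enrichment(res)
  expect_equal(m$s1, c(2.1, -1.8))
  expect_equal(m$s2, c(0, 0)) # q 0.30 and p 0.5 both fail
  empty <- filter_enrichment(res[0, ])
  expect_identical(nrow(empty), 0L)
})

test_that("gene-set restriction is an order-preserving intersection", {
  expect_message(
    expect_identical(restrict_gene_set(c("a", "b", "c"), c("c", "b", "d")),
                     c("b", "c")),
    "2 of 3"
  )
  expect_warning(
    expect_message(out <- restrict_gene_set(c("a", "b"), c("x", "y"))),
    "empty"
  )
  expect_length(out, 0)
  expect_message(
    expect_identical(restrict_gene_set(c("a", "b"), c("a", "b")),
                     c("a", "b"))
  )
  expect_error(restrict_gene_set(character(0), "a"), "non-empty")
})

test_that("RNK and GMT files round-trip", {
  rl <- random_ranked_list(25, seed = 121)
  path <- withr::local_tempfile(fileext = ".rnk")
  write_rnk(rl, path)
  back <- read_rnk(path)
  expect_equal(as.data.frame(back), as.data.frame(rl), tolerance = 1e-9)
  sets <- list(one = c("a", "b", "c"), two = c("d", "e"))
  gmt <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, gmt)
  expect_identical(read_gmt(gmt), sets)
})
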