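# Independent oracles used to validate the package's statistics. Each is a
# direct transcription of the defining formula (enumeration or brute force),
# deliberately sharing no code with the implementation it checks.

# Benjamini-Hochberg step-up by definition: sort ascending, q_(i) =
# min_{j >= i} m * p_(j) / j, capped at 1, mapped back to input order.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- (m * p[o]) / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Two-sided Fisher exact p for a 2x2 table by hypergeometric enumeration
# over all tables with the observed margins; tables whose probability ties
# the observed one (within relative 1e-7) are included.
fisher_2x2_oracle <- function(tab) {
  r1 <- sum(tab[1, ])
  c1 <- sum(tab[, 1])
  n <- sum(tab)
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- stats::dhyper(tab[1, 1], c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exact two-sided Mann-Whitney p by full enumeration of the C(n1+n2, n1)
# assignments of the pooled observations to group one (no ties assumed).
# Matches the conventional two-sided definition 2 * min(P(W <= w), P(W >= w)).
mw_exact_oracle <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  splits <- utils::combn(length(pooled), n1)
  w_all <- apply(splits, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  p_lo <- mean(w_all <= w_obs)
  p_hi <- mean(w_all >= w_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# Brute-force running-sum enrichment score: build the full step vector,
# cumulate, take the signed maximum deviation (positive wins magnitude
# ties).
es_bruteforce_oracle <- function(genes, scores, set, weight = 1) {
  n <- length(genes)
  hit <- genes %in% set
  m <- sum(hit)
  a <- abs(scores)^weight
  s <- sum(a[hit])
  step <- numeric(n)
  step[hit] <- if (s > 0) a[hit] / s else 1 / m
  if (m < n) step[!hit] <- -1 / (n - m)
  run <- cumsum(step)
  mx <- max(run, 0)
  mn <- min(run, 0)
  if (mx >= -mn) mx else mn
}

# small deterministic ranked list for enrichment tests
random_ranked_list <- function(n, seed) {
  withr::with_seed(seed, {
    as_ranked_list(tibble::tibble(
      gene = sprintf("g%03d", sample.int(n)),
      score = round(rnorm(n), 6)
    ))
  })
}
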