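test_that("interquartile mean matches hand-derived slices", {
  expect_equal(iqr_mean_coverage(rep(7, 10)), 7)
  expect_equal(iqr_mean_coverage(c(1, 1, 2, 2, 3, 3, 100, 100)), 2.5)
  expect_equal(iqr_mean_coverage(0:99), 49.5)
  expect_error(iqr_mean_coverage(c(1, 2, 3)), "fewer than 4")
})

test_that("interquartile mean agrees with the sort-and-slice oracle", {
  set.seed(41)
  for (i in 1:200) {
    L <- sample(4:500, 1)
    v <- switch(sample(3, 1),
                rpois(L, sample(1:50, 1)),
                round(runif(L, 0, 1000)),
                rep(sample(0:5, 1), L))
    expect_equal(iqr_mean_coverage(v), oracle_iqr_mean(v))
  }
})

test_that("run-length encoded input matches the expanded vector", {
  set.seed(42)
  for (i in 1:100) {
    n_runs <- sample(2:30, 1)
    vals <- rpois(n_runs, 20)
    lens <- sample(1:40, n_runs, replace = TRUE)
    if (sum(lens) < 4) next
    expect_equal(iqr_mean_coverage(vals, lens),
                 oracle_iqr_mean(rep(vals, lens)))
  }
})

# Analytic expectation of the middle-half mean when a spike of the given
# fraction occupies the top ranks: the background's truncated mean between
# quantiles 1/4/(1-f) and (3/4-f)/(1-f), computed from the Poisson pmf.
truncated_poisson_mean <- function(lambda, spike_fraction) {
  stopifnot(spike_fraction < 0.25) # slice must stay below the spike block
  p_lo <- (1 / 4) / (1 - spike_fraction)
  p_hi <- (3 / 4) / (1 - spike_fraction)
  k <- 0:max(50, ceiling(lambda + 12 * sqrt(lambda)))
  Fk <- ppois(k, lambda)
  Fk_prev <- c(0, Fk[-length(Fk)])
  mass <- pmax(0, pmin(Fk, p_hi) - pmax(Fk_prev, p_lo))
  sum(k * mass) / (p_hi - p_lo)
}

test_that("the middle-quartile mean shrugs off a conserved-gene spike", {
  set.seed(7)
  v <- generate_spiked_coverage(20000, base_lambda = 10, spike_fraction = 0.2,
                                spike_multiplier = 50)
  expect_gt(mean(v), 5 * 10) # arithmetic mean inflated ~10x
  # the slice mean lands on its analytic expectation: the spike displaces
  # the band slightly upward but the 50x inflation never reaches it
  expect_lt(abs(iqr_mean_coverage(v) / truncated_poisson_mean(10, 0.2) - 1),
            0.03)
  expect_lt(iqr_mean_coverage(v), 0.12 * mean(v))
  # unspiked control: both statistics near the base rate
  u <- generate_spiked_coverage(10000, base_lambda = 10)
  expect_lt(abs(mean(u) / 10 - 1), 0.1)
  expect_lt(abs(iqr_mean_coverage(u) / 10 - 1), 0.1)
})

test_that("coverage summaries reduce RLE tables exactly", {
  cov <- data.frame(
    contig_id = c("a", "a", "a", "b"),
    sample_id = c("s1", "s1", "s2", "s1"),
    run_start = c(1L, 5L, 1L, 1L),
    run_length = c(4L, 4L, 8L, 10L),
    depth = c(2, 6, 3, 0)
  )
  s <- coverage_summaries(cov)
  a_s1 <- s[s$contig_id == "a" & s$sample_id == "s1", ]
  expect_equal(a_s1$nucleotides_mapped, 4 * 2 + 4 * 6)
  expect_equal(a_s1$iqr_mean, oracle_iqr_mean(rep(c(2, 6), c(4, 4))))
  expect_equal(s$nucleotides_mapped[s$contig_id == "b"], 0)
  m <- summary_matrix(s, "nucleotides_mapped")
  expect_equal(m["a", "s2"], 24)
  expect_equal(m["b", "s2"], 0) # absent pair fills with zero
})

test_that("relative abundance normalizes within samples", {
  expect_equal(unname(relative_abundance(c(a = 30000, b = 10000))),
               c(0.75, 0.25))
  expect_equal(unname(relative_abundance(c(x = 5))), 1)
  expect_error(relative_abundance(c(a = 0, b = 0)), "undefined")
  m <- matrix(c(3, 1, 0, 0, 2, 2), 2,
              dimnames = list(c("a", "b"), c("s1", "s2", "s3")))
  expect_warning(ab <- relative_abundance_matrix(m), "zero total")
  expect_equal(colnames(ab), c("s1", "s3"))
  expect_equal(unname(colSums(ab)), c(1, 1))
})

test_that("mean-normalized variance behaves as an index of dispersion", {
  expect_equal(mean_normalized_variance(rep(0.3, 12)), 0)
  expect_equal(mean_normalized_variance(c(0, 2)), 1)
  s <- c(0.1, 0.4, 0.2, 0.05)
  # scaling the series by c scales the statistic by c (variance c^2, mean c)
  expect_equal(mean_normalized_variance(5 * s), 5 * mean_normalized_variance(s))
  expect_warning(out <- mean_normalized_variance(c(0, 0, 0)), "zero")
  expect_true(is.na(out))
  # Poisson-like series: dispersion approaches a scale-free constant
  set.seed(11)
  d1 <- mean_normalized_variance(rpois(5000, 4) / 4) * 4
  expect_lt(abs(d1 - 1), 0.1)
})

test_that("top-k ranking is deterministic under ties", {
  samples <- data.frame(sample_id = c("s1", "s2", "s3", "s4"),
                        depth_m = c(25, 25, 1000, 1000),
                        date = as.Date("2010-08-15") + c(0, 45, 0, 45))
  ab <- rbind(zeta = c(0.5, 0.5, 0.1, 0.1), alpha = c(0.5, 0.5, 0.2, 0.2),
              mid = c(0, 0, 0.7, 0.7))
  colnames(ab) <- samples$sample_id
  top <- top_k_per_depth(ab, samples, k = 2)
  expect_equal(top[["25"]], c("alpha", "zeta")) # tie broken by id
  expect_equal(top[["1000"]][1], "mid")
  expect_warning(all3 <- top_k_per_depth(ab, samples, k = 13), "exceeds")
  expect_equal(length(all3[["25"]]), 3)
})

test_that("depth-group assignment follows the peak-depth and dispersion rules", {
  samples <- data.frame(
    sample_id = paste0("s", 1:8),
    depth_m = rep(c(25, 1000), each = 4),
    date = rep(as.Date("2010-08-15") + 45 * (0:3), 2)
  )
  iqr <- rbind(surf = c(20, 22, 18, 21, 0, 0, 0, 0),
               deep = c(0, 0, 0, 0, 10, 11, 9, 10),
               burst = c(0, 0, 0, 0, 0, 40, 0, 0))
  colnames(iqr) <- samples$sample_id
  nuc <- iqr * 1000
  ab <- relative_abundance_matrix(nuc)
  g <- assign_depth_groups(iqr, ab, samples, sporadic_threshold = 0.5)
  expect_equal(g$group[g$contig_id == "surf"], "surface")
  expect_equal(g$group[g$contig_id == "deep"], "mesopelagic")
  expect_equal(g$group[g$contig_id == "burst"], "sporadic")
  # manual override wins
  g2 <- assign_depth_groups(iqr, ab, samples, sporadic_threshold = 0.5,
                            overrides = c(burst = "mesopelagic"))
  expect_equal(g2$group[g2$contig_id == "burst"], "mesopelagic")
  # a contig absent everywhere is an error
  iqr0 <- rbind(iqr, gone = 0)
  expect_error(assign_depth_groups(iqr0, ab, samples), "absent")
})
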