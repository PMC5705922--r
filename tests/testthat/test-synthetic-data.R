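test_that("config validation rejects malformed designs", {
  expect_error(sim_config(depths_m = c(75, 25, 125)), "increasing")
  expect_error(sim_config(n_contigs = 0), ">= 1")
  expect_error(sim_config(lysogeny_fold = 0), "lysogeny_fold")
  expect_error(sim_config(spike_fraction = 1), "spike_fraction")
})

test_that("the same seed reproduces byte-identical fixture files", {
  cfg <- small_config(seed = 4)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_fixture(generate_fixture(cfg), d1)
  write_fixture(generate_fixture(cfg), d2)
  files <- list.files(d1)
  expect_true(length(files) >= 9)
  for (f in files) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))),
                 info = f)
  }
  # a different seed changes the data
  write_fixture(generate_fixture(small_config(seed = 5)), d2)
  expect_false(unname(tools::md5sum(file.path(d1, "coverage.tsv"))) ==
                 unname(tools::md5sum(file.path(d2, "coverage.tsv"))))
})

test_that("the sampling frame is the 7x12 design with one missed cast", {
  fx <- generate_fixture(small_config(seed = 2), sequences = FALSE)
  expect_equal(nrow(fx$samples), 83)
  expect_equal(sort(unique(fx$samples$depth_m)),
               c(25, 75, 125, 200, 500, 770, 1000))
  expect_equal(length(unique(fx$samples$date)), 12)
  expect_false(any(duplicated(fx$samples[, c("depth_m", "date")])))
})

test_that("planted contaminants carry ribosomal markers; truth records them", {
  fx <- generate_fixture(sim_config(seed = 8, n_contigs = 12,
                                    contaminant_count = 3,
                                    coverage_window = 2000),
                         sequences = FALSE)
  expect_length(fx$truth$contaminant_ids, 3)
  ribo <- default_marker_set()
  ribo <- ribo$family[ribo$ribosomal]
  ribo_hits <- fx$domain_hits[fx$domain_hits$family %in% ribo &
                                fx$domain_hits$bit_score > 50, ]
  host <- fx$genes$contig_id[match(ribo_hits$gene_id, fx$genes$gene_id)]
  expect_setequal(unique(host), fx$truth$contaminant_ids)
  # and the cascade removes exactly those
  out <- run_cascade(fx$contigs, fx$genes, fx$domain_hits)
  expect_length(intersect(out$retained$contig_id, fx$truth$contaminant_ids), 0)
})

test_that("referential integrity holds across all fixture tables", {
  fx <- generate_fixture(small_config(seed = 6), sequences = FALSE)
  expect_true(all(fx$genes$contig_id %in% fx$contigs$contig_id))
  expect_true(all(fx$coverage$contig_id %in% fx$contigs$contig_id))
  expect_true(all(fx$coverage$sample_id %in% fx$samples$sample_id))
  expect_true(all(fx$gene_coverage$sample_id %in% fx$samples$sample_id))
  expect_true(all(fx$gene_coverage$gene_id %in% fx$gene_catalog$gene_id))
  # gene coordinates stay inside their contig
  len <- fx$contigs$length[match(fx$genes$contig_id, fx$contigs$contig_id)]
  expect_true(all(fx$genes$start >= 0 & fx$genes$end <= len))
  # pipeline inputs never include the truth file
  expect_false("truth.json" %in% phagedepth:::pipeline_input_files())
})

test_that("spiked coverage has the planted mean structure", {
  set.seed(61)
  reps <- t(replicate(300, {
    v <- generate_spiked_coverage(1000, 10, 0.2, 50)
    c(mean(v), iqr_mean_coverage(v))
  }))
  expect_lt(abs(mean(reps[, 1]) / 108 - 1), 0.03) # 0.8*10 + 0.2*500
  # middle half stays near the base rate (vs the 10.8x-inflated mean); the
  # residual upward shift is the analytic truncated-mean displacement
  expect_lt(abs(mean(reps[, 2]) / 10 - 1), 0.15)
  expect_gt(mean(reps[, 1]) / mean(reps[, 2]), 5)
  # multiplier 1 is indistinguishable from plain Poisson in its mean
  flat <- replicate(200, mean(generate_spiked_coverage(1000, 10, 0.2, 1)))
  expect_lt(abs(mean(flat) / 10 - 1), 0.02)
  # spike_fraction 0 ignores the multiplier
  v0 <- generate_spiked_coverage(500, 5, 0, 100, seed = 3)
  v1 <- generate_spiked_coverage(500, 5, 0, 1, seed = 3)
  expect_identical(v0, v1)
  expect_error(generate_spiked_coverage(100, 5, 0.5, 2), "quartiles")
  expect_error(generate_spiked_coverage(0, 5), "length")
})

test_that("surface-group contigs peak shallow under the naive depth-mean", {
  hits <- 0L
  trials <- 0L
  for (seed in 1:10) {
    fx <- generate_fixture(sim_config(seed = seed, n_contigs = 20,
                                      coverage_window = 2000),
                           sequences = FALSE)
    surf <- fx$truth$contigs$contig_id[fx$truth$contigs$group == "surface"]
    if (length(surf) == 0) next
    summ <- coverage_summaries(fx$coverage)
    m <- summary_matrix(summ, "iqr_mean", contig_ids = surf,
                        sample_ids = fx$samples$sample_id)
    depth_mean <- sapply(c(25, 75, 125, 200, 500, 770, 1000), function(d) {
      cols <- fx$samples$sample_id[fx$samples$depth_m == d]
      rowMeans(m[, cols, drop = FALSE])
    })
    peak <- c(25, 75, 125, 200, 500, 770, 1000)[max.col(depth_mean)]
    hits <- hits + sum(peak <= 75)
    trials <- trials + length(surf)
  }
  expect_gte(hits / trials, 0.95)
})
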