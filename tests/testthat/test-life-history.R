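dh <- function(gene, family, bit) {
  data.frame(gene_id = gene, family = family, bit_score = bit,
             stringsAsFactors = FALSE)
}

test_that("marker detection is strict at bit 50 and takes the best family", {
  hits <- rbind(dh("g1", "integrase", 50), # not > 50
                dh("g2", "integrase", 80), dh("g2", "excisionase", 60),
                dh("g3", "capsid", 51),
                dh("g4", "CI_repressor", 70), dh("g4", "excisionase", 70))
  asn <- detect_markers(hits)
  expect_false("g1" %in% asn$gene_id)
  expect_equal(asn$family[asn$gene_id == "g2"], "integrase")
  expect_equal(asn$family[asn$gene_id == "g3"], "capsid")
  # tie at equal score: lexicographic family
  expect_equal(asn$family[asn$gene_id == "g4"], "CI_repressor")
})

test_that("lysogeny index is the prophage:capsid coverage ratio", {
  asn <- data.frame(gene_id = c("p1", "p2", "c1", "c2"),
                    family = c("integrase", "excisionase", "capsid", "capsid"))
  gcov <- data.frame(
    gene_id = rep(c("p1", "p2", "c1", "c2"), 2),
    sample_id = rep(c("s1", "s2"), each = 4),
    coverage = c(4, 6, 5, 5, 0, 0, 3, 1)
  )
  idx <- lysogeny_index(asn, gcov)
  expect_equal(idx$index[idx$sample_id == "s1"], 1.0)
  expect_equal(idx$index[idx$sample_id == "s2"], 0.0)
  # per-family decomposition sums to the joint index
  expect_equal(idx$index_integrase + idx$index_CI_repressor +
                 idx$index_excisionase, idx$index)
  # uniform rescaling of a sample's coverages cancels
  gcov2 <- gcov
  gcov2$coverage <- gcov2$coverage * 7
  expect_equal(lysogeny_index(asn, gcov2)$index, idx$index)
  # zero capsid coverage leaves the index undefined, with a warning
  gcov3 <- gcov[gcov$gene_id %in% c("p1", "p2"), ]
  expect_warning(idx3 <- lysogeny_index(asn, gcov3), "zero capsid")
  expect_true(all(is.na(idx3$index)))
})

test_that("fold-vs-surface is 1 at the surface and errors without a reference", {
  samples <- data.frame(sample_id = paste0("s", 1:6),
                        depth_m = c(25, 75, 200, 500, 770, 1000))
  idx <- data.frame(sample_id = samples$sample_id, index = rep(0.4, 6))
  prof <- fold_vs_surface(idx, samples)
  expect_equal(prof$fold_vs_surface, rep(1, 6))
  idx2 <- data.frame(sample_id = samples$sample_id,
                     index = c(0.2, 0.2, 0.5, 1.0, 1.0, 1.0))
  prof2 <- fold_vs_surface(idx2, samples)
  expect_equal(prof2$fold_vs_surface[prof2$depth_m >= 500], rep(5, 3))
  expect_error(fold_vs_surface(idx2[3:6, ], samples), "surface")
})

test_that("copy numbers normalize by the mean single-copy coverage", {
  asn <- data.frame(gene_id = c("m1", "m2"),
                    family = c("capsid", "integrase"))
  gcov <- data.frame(gene_id = c("m1", "m2"), sample_id = "s1",
                     coverage = c(20, 5))
  sc <- data.frame(family = sprintf("sc%02d", 1:10), sample_id = "s1",
                   coverage = rep(20, 10))
  cn <- copy_number_per_genome(asn, gcov, sc)
  expect_equal(cn$copy_number[cn$family == "capsid"], 1.0)
  expect_equal(cn$copy_number[cn$family == "integrase"], 0.25)
  expect_equal(cn$copy_number[cn$family == "terminase"], 0.0) # absent marker
  sc_bad <- sc[-1, ]
  expect_error(copy_number_per_genome(asn, gcov, sc_bad,
                                      expected_families = sc$family),
               "missing")
  # geometric mean option
  sc2 <- sc
  sc2$coverage <- c(rep(10, 5), rep(40, 5))
  cn2 <- copy_number_per_genome(asn, gcov, sc2, mean_type = "geometric")
  expect_equal(cn2$copy_number[cn2$family == "capsid"], 20 / 20)
})

test_that("prophage contig flag uses the looser bit-30 rule with Cro", {
  genes <- data.frame(gene_id = paste0("c", 1:4, "_g1"),
                      contig_id = paste0("c", 1:4))
  hits <- rbind(dh("c1_g1", "Cro", 31),
                dh("c2_g1", "integrase", 30),   # not > 30
                dh("c3_g1", "capsid", 300),     # lytic markers never flag
                dh("c4_g1", "excisionase", 45))
  fl <- flag_prophage_contigs(paste0("c", 1:4), genes, hits)
  expect_equal(unname(fl), c(TRUE, FALSE, FALSE, TRUE))
})

test_that("boosted integrase inflates only the integrase-specific index", {
  cfg_base <- small_config(seed = 9)
  cfg_boost <- small_config(seed = 9, integrase_boost = 4)
  fx_b <- generate_fixture(cfg_base, sequences = FALSE)
  fx_i <- generate_fixture(cfg_boost, sequences = FALSE)
  mean_idx <- function(fx, col) {
    asn <- detect_markers(fx$domain_hits)
    idx <- lysogeny_index(asn, fx$gene_coverage)
    mean(idx[[col]], na.rm = TRUE)
  }
  # the integrase-specific index rises roughly by the boost factor ...
  expect_gt(mean_idx(fx_i, "index_integrase") /
              mean_idx(fx_b, "index_integrase"), 3)
  # ... while the excisionase- and CI-specific indices stay put
  expect_lt(abs(mean_idx(fx_i, "index_excisionase") /
                  mean_idx(fx_b, "index_excisionase") - 1), 0.15)
  expect_lt(abs(mean_idx(fx_i, "index_CI_repressor") /
                  mean_idx(fx_b, "index_CI_repressor") - 1), 0.15)
})
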