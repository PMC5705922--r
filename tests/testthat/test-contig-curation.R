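mk_contigs <- function(lengths, ids = sprintf("c%02d", seq_along(lengths))) {
  data.frame(contig_id = ids, length = lengths,
             virsorter_category = rep(1L, length(lengths)),
             stringsAsFactors = FALSE)
}
one_gene_each <- function(contigs) {
  data.frame(gene_id = paste0(contigs$contig_id, "_g1"),
             contig_id = contigs$contig_id, start = 0L, end = 900L,
             strand = "+", stringsAsFactors = FALSE)
}

test_that("length filter is inclusive at 20 kbp and preserves order", {
  contigs <- mk_contigs(c(19999, 20000, 108000))
  out <- filter_by_length(contigs)
  expect_equal(out$retained$length, c(20000, 108000))
  expect_equal(out$report$removed, "c01")
  expect_warning(empty <- filter_by_length(mk_contigs(numeric(0))), "empty")
  expect_equal(nrow(empty$retained), 0)
  all_short <- filter_by_length(mk_contigs(c(1700, 5000)))
  expect_equal(all_short$report$n_retained, 0)
})

test_that("structural-gene requirement is strict at bit 10 and synonym-aware", {
  contigs <- mk_contigs(rep(30000, 4))
  genes <- one_gene_each(contigs)
  hits <- data.frame(
    gene_id = c("c01_g1", "c02_g1", "c03_g1", "c04_g1"),
    family = c("capsid", "portal", "major head protein", "hypothetical"),
    bit_score = c(10.5, 10.0, 25, 300)
  )
  keep <- require_structural_gene(contigs$contig_id, genes, hits)
  expect_equal(unname(keep), c(TRUE, FALSE, TRUE, FALSE))
})

test_that("contamination screen removes ribosomal hits but tolerates recA", {
  contigs <- mk_contigs(rep(30000, 3))
  genes <- one_gene_each(contigs)
  hits <- data.frame(
    gene_id = c("c01_g1", "c02_g1", "c03_g1"),
    family = c("ribosomal protein L2", "recA", "ribosomal protein L2"),
    bit_score = c(60, 90, 50) # the bit-50 ribosomal hit is not > 50
  )
  out <- contamination_screen(contigs, genes, hits)
  expect_equal(out$retained$contig_id, c("c02", "c03"))
  expect_equal(out$report$n_marker_hits, 2)
  expect_equal(out$report$n_ambiguous_hits, 1)
  # completeness proxy counts distinct non-ambiguous families only
  expect_equal(out$report$completeness_proxy,
               1 / sum(!default_marker_set()$phage_ambiguous))
  clean <- contamination_screen(contigs, genes, hits[0, , drop = FALSE])
  expect_equal(clean$report$completeness_proxy, 0)
  expect_equal(nrow(clean$retained), 3)
  expect_error(contamination_screen(contigs, genes, hits,
                                    marker_set = default_marker_set()[0, ]),
               "empty")
})

test_that("cascade equals three independent predicates and ignores input order", {
  set.seed(5)
  for (rep_i in 1:20) {
    n <- sample(10:50, 1)
    contigs <- mk_contigs(round(runif(n, 1700, 108000)))
    genes <- one_gene_each(contigs)
    fams <- c(structural_families(), "hypothetical", "ribosomal protein L2",
              "recA")
    hits <- data.frame(
      gene_id = sample(genes$gene_id, n * 2, replace = TRUE),
      family = sample(fams, n * 2, replace = TRUE),
      bit_score = round(runif(n * 2, 0, 120), 1)
    )
    out <- run_cascade(contigs, genes, hits)
    # oracle: evaluate the three predicates independently per contig
    th <- default_thresholds()
    expected <- vapply(seq_len(n), function(i) {
      cid <- contigs$contig_id[i]
      gh <- hits[hits$gene_id %in% genes$gene_id[genes$contig_id == cid], ,
                 drop = FALSE]
      pass_len <- contigs$length[i] >= th$min_contig_len
      pass_str <- any(vapply(seq_len(nrow(gh)), function(k) {
        phagedepth:::is_structural_family(gh$family[k]) &&
          gh$bit_score[k] > th$structural_bit
      }, logical(1)))
      ribo <- default_marker_set()
      ribo <- ribo$family[ribo$ribosomal]
      pass_cont <- !any(gh$family %in% ribo & gh$bit_score > th$marker_bit)
      pass_len && pass_str && pass_cont
    }, logical(1))
    expect_setequal(out$retained$contig_id, contigs$contig_id[expected])
    # permutation invariance
    perm <- sample.int(n)
    out2 <- run_cascade(contigs[perm, ], genes, hits)
    expect_setequal(out2$retained$contig_id, out$retained$contig_id)
    # stage counts are monotone and consistent
    counts <- vapply(out$report$stages, `[[`, 0, "n_retained")
    expect_true(all(diff(counts) <= 0))
    expect_equal(counts[3], nrow(out$retained))
  }
})

test_that("permissive thresholds make the cascade an identity transform", {
  contigs <- mk_contigs(c(1700, 30000))
  genes <- one_gene_each(contigs)
  hits <- data.frame(gene_id = "c01_g1", family = "hypothetical",
                     bit_score = 5)
  th <- default_thresholds(min_contig_len = 1e-9, structural_bit = -Inf)
  out <- run_cascade(contigs, genes, hits, thresholds = th)
  expect_equal(out$retained$contig_id, contigs$contig_id)
})

test_that("an out-of-range viral-detection category is rejected", {
  contigs <- mk_contigs(c(30000, 30000))
  contigs$virsorter_category <- c(3L, 9L)
  expect_error(run_cascade(contigs, one_gene_each(contigs),
                           data.frame(gene_id = character(),
                                      family = character(),
                                      bit_score = numeric())),
               "virsorter_category")
})
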