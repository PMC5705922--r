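hit_row <- function(gene, ref, db, aai, bit) {
  data.frame(gene_id = gene, reference_id = ref, database = db,
             aai_percent = aai, bit_score = bit, stringsAsFactors = FALSE)
}

test_that("best hit per gene takes max bit, then max AAI, then smallest id", {
  hits <- rbind(hit_row("g1", "r1", "GOV", 70, 50),
                hit_row("g1", "r2", "GOV", 40, 60),
                hit_row("g2", "rA", "EV", 70, 80),
                hit_row("g2", "rB", "EV", 65, 80),
                hit_row("g3", "rZ", "EV", 50, 90),
                hit_row("g3", "rA", "EV", 50, 90))
  b <- best_hit_per_gene(hits)
  expect_equal(b$reference_id[b$gene_id == "g1"], "r2")
  expect_equal(b$reference_id[b$gene_id == "g2"], "rA")
  expect_equal(b$reference_id[b$gene_id == "g3"], "rA")
  expect_equal(nrow(best_hit_per_gene(hits[0, ])), 0)
  # duplicate hit rows change nothing
  expect_equal(best_hit_per_gene(rbind(hits, hits)), b)
})

test_that("majority-AAI rule is strict at both boundaries", {
  genes <- sprintf("g%02d", 1:10)
  # 6/10 genes at mean AAI 63.5: classified
  hits6 <- do.call(rbind, lapply(1:6, function(i) {
    hit_row(genes[i], "refA", "GOV", 60 + i, 100)
  }))
  out <- classify_contig(genes, best_hit_per_gene(hits6))
  expect_equal(out$category, "virome:GOV")
  expect_equal(out$gene_fraction_hit, 0.6)
  expect_equal(out$mean_aai, 63.5)
  # exactly 5/10 genes even at AAI 90: 0.5 is not > 0.5, stays novel
  hits5 <- do.call(rbind, lapply(1:5, function(i) {
    hit_row(genes[i], "refA", "GOV", 90, 100)
  }))
  expect_equal(classify_contig(genes, best_hit_per_gene(hits5))$category,
               "novel")
  # 6/10 genes at AAI exactly 60: novel
  hits60 <- do.call(rbind, lapply(1:6, function(i) {
    hit_row(genes[i], "refA", "GOV", 60, 100)
  }))
  expect_equal(classify_contig(genes, best_hit_per_gene(hits60))$category,
               "novel")
  expect_error(classify_contig(character(0), best_hit_per_gene(hits6)),
               "0 genes")
})

test_that("RefSeq precedence beats a better-covered virome reference", {
  genes <- sprintf("g%02d", 1:10)
  hits <- rbind(
    do.call(rbind, lapply(1:6, function(i) {
      hit_row(genes[i], "rs1", "refseq75", 80, 200)
    })),
    do.call(rbind, lapply(7:10, function(i) {
      hit_row(genes[i], "gov1", "GOV", 95, 100)
    })),
    # gov1 also hits the first 6 genes, but at lower bit: not their best hit
    do.call(rbind, lapply(1:4, function(i) {
      hit_row(genes[i], "gov1", "GOV", 95, 50)
    }))
  )
  out <- classify_contig(genes, best_hit_per_gene(hits))
  expect_equal(out$category, "refseq_phage")
  expect_equal(out$best_reference_id, "rs1")
})

test_that("classification matches the exhaustive oracle on random cases", {
  set.seed(19)
  for (i in 1:120) {
    case <- random_classification_case(sample(1:8, 1), sample(1:4, 1),
                                       force_boundary = i %% 10 == 0)
    got <- classify_contig(case$gene_ids, best_hit_per_gene(case$hits))
    want <- oracle_classify(case$gene_ids, case$hits)
    expect_equal(got$category, want$category, info = paste("case", i))
    if (want$category != "novel") {
      expect_equal(got$best_reference_id, want$ref, info = paste("case", i))
    }
  }
})

test_that("tightening thresholds never rescues a novel contig", {
  set.seed(23)
  for (i in 1:40) {
    case <- random_classification_case(sample(2:8, 1), sample(1:4, 1))
    bh <- best_hit_per_gene(case$hits)
    base <- classify_contig(case$gene_ids, bh)
    tight <- classify_contig(case$gene_ids, bh,
                             thresholds = default_thresholds(
                               aai_classify = 75, gene_fraction = 0.7))
    if (base$category == "novel") expect_equal(tight$category, "novel")
  }
})

test_that("category proportions sum to one per sample and average per depth", {
  cls <- data.frame(contig_id = c("a", "b", "c"),
                    category = c("refseq_phage", "novel", "novel"))
  nuc <- rbind(a = c(100, 50, 0), b = c(100, 50, 0), c = c(200, 100, 0))
  colnames(nuc) <- c("s1", "s2", "s3")
  samples <- data.frame(sample_id = c("s1", "s2", "s3"),
                        depth_m = c(25, 25, 1000))
  expect_warning(out <- category_proportions(cls, nuc, samples), "zero total")
  expect_equal(unname(rowSums(out$per_sample)), c(1, 1))
  expect_equal(unname(out$per_sample[, "novel"]), c(0.75, 0.75))
  d25 <- out$per_depth[out$per_depth$depth_m == 25, ]
  expect_equal(d25$mean_proportion[d25$category == "refseq_phage"], 0.25)
  expect_equal(d25$se, c(0, 0))
  # equal split across two categories
  nuc2 <- rbind(a = 1000, b = 1000, c = 0)
  colnames(nuc2) <- "s1"
  out2 <- category_proportions(cls, nuc2, samples[1, ])
  expect_equal(unname(out2$per_sample[1, ]), c(0.5, 0.5))
})

test_that("planted 10/40/79 labels are recovered exactly", {
  fx <- fixture_classification_counts(seed = 7)
  got <- classify_contigs(fx$genes, fx$ref_hits)
  expect_equal(got$category[match(fx$truth$contig_id, got$contig_id)],
               fx$truth$category)
  expect_equal(as.integer(table(got$category)[c("refseq_phage", "novel")]),
               c(10L, 79L))
  expect_equal(sum(startsWith(got$category, "virome:")), 40)
})
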