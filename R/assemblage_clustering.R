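#' Partition the gene catalog into phage-specific and cellular sets
#'
#' Phage genes are those whose best viral-database hit exceeds 90% amino-acid
#' identity, minus photosystem genes (domain bit score > 30): phage-carried
#' photosystem copies cannot be reliably distinguished from bacterium-encoded
#' ones, so they are excluded from the phage side entirely. Every other gene
#' is cell-associated; the two sets are a disjoint cover of the catalog.
#'
#' @param catalog Data frame with columns `gene_id`, `viral_best_aai`
#'   (percent, `NA` when no viral hit) and `photosystem_bit` (`NA` when no
#'   photosystem hit).
#' @param thresholds A [default_thresholds()] list (`aai_viral_gene`,
#'   `photosystem_bit`).
#' @return List with character vectors `phage_genes` and `cell_genes`.
#' @export
partition_gene_catalog <- function(catalog, thresholds = default_thresholds()) {
  aai <- catalog$viral_best_aai
  psb <- catalog$photosystem_bit
  viral <- !is.na(aai) & aai > thresholds$aai_viral_gene
  photo <- !is.na(psb) & psb > thresholds$photosystem_bit
  phage <- viral & !photo
  list(phage_genes = catalog$gene_id[phage],
       cell_genes = catalog$gene_id[!phage])
}

#' Gene relative-abundance matrix
#'
#' Converts a long per-gene per-sample coverage table into a genes x samples
#' matrix of relative abundances, each sample's coverages divided by the total
#' coverage of all genes in that sample (so library size cancels).
#'
#' @param gene_coverage Data frame `gene_id`, `sample_id`, `coverage`.
#' @return Genes x samples matrix; columns sum to 1.
#' @export
gene_abundance_matrix <- function(gene_coverage) {
  genes <- sort(unique(gene_coverage$gene_id))
  samps <- sort(unique(gene_coverage$sample_id))
  m <- matrix(0, length(genes), length(samps), dimnames = list(genes, samps))
  m[cbind(gene_coverage$gene_id, gene_coverage$sample_id)] <-
    gene_coverage$coverage
  relative_abundance_matrix(m)
}

#' Bray-Curtis distance matrix between samples
#'
#' `d(i, j) = sum_g |x_gi - x_gj| / sum_g (x_gi + x_gj)` over the genes of one
#' catalog partition, computed on relative abundances.
#'
#' @param abundance Genes x samples nonnegative matrix (>= 2 samples).
#' @return A symmetric samples x samples matrix with zero diagonal, values in
#'   \[0, 1\].
#' @export
bray_curtis_matrix <- function(abundance) {
  if (ncol(abundance) < 2) stop("need at least 2 samples")
  if (any(abundance < 0)) stop("abundances must be nonnegative")
  zero <- colSums(abundance) == 0
  if (any(zero)) {
    stop("sample(s) with all-zero abundance: ",
         paste(colnames(abundance)[zero], collapse = ", "))
  }
  as.matrix(vegan::vegdist(t(abundance), method = "bray"))
}

#' Average-linkage (UPGMA) clustering of samples
#'
#' @param dist_matrix Symmetric distance matrix (e.g. from
#'   [bray_curtis_matrix()]).
#' @return An [stats::hclust] tree.
#' @export
average_linkage <- function(dist_matrix) {
  if (!all(is.finite(dist_matrix))) stop("distances must be finite")
  stats::hclust(stats::as.dist(dist_matrix), method = "average")
}

#' Compare two sample dendrograms
#'
#' Numeric summaries of the tanglegram-style comparison between the trees
#' built from phage-specific and cellular genes: the Pearson correlation of
#' cophenetic distances, and the fraction of sample pairs co-clustered
#' identically when both trees are cut into `k` groups (default 7, one per
#' sampling depth).
#'
#' @param tree_a,tree_b [stats::hclust] trees over the same samples.
#' @param k Number of groups for the cut-based agreement.
#' @return List with `cophenetic_correlation` and `pair_agreement`.
#' @export
compare_dendrograms <- function(tree_a, tree_b, k = 7) {
  if (!setequal(tree_a$labels, tree_b$labels)) {
    stop("trees must share the same leaf set")
  }
  ca <- stats::cophenetic(tree_a)
  cb <- stats::cophenetic(tree_b)
  labs <- tree_a$labels
  ca <- as.matrix(ca)[labs, labs]
  cb <- as.matrix(cb)[labs, labs]
  upper <- upper.tri(ca)
  cut_a <- stats::cutree(tree_a, k = k)[labs]
  cut_b <- stats::cutree(tree_b, k = k)[labs]
  same_a <- outer(cut_a, cut_a, "==")[upper]
  same_b <- outer(cut_b, cut_b, "==")[upper]
  list(
    cophenetic_correlation = stats::cor(ca[upper], cb[upper]),
    pair_agreement = mean(same_a == same_b)
  )
}

#' Relative abundance of labeled taxon groups per sample
#'
#' Generic summary behind bubble-plot style panels: for genes carrying a taxon
#' label (e.g. four groups of well-characterized phages, or their bacterial
#' hosts), the summed relative abundance per label per sample.
#'
#' @param catalog Gene catalog with a `taxon_label` column (`NA` = unlabeled).
#' @param abundance Genes x samples relative-abundance matrix.
#' @return Labels x samples matrix of summed relative abundances.
#' @export
taxon_group_abundance <- function(catalog, abundance) {
  lab <- catalog$taxon_label[match(rownames(abundance), catalog$gene_id)]
  keep <- !is.na(lab)
  if (!any(keep)) stop("no labeled genes in the abundance matrix")
  rowsum(abundance[keep, , drop = FALSE], lab[keep])
}
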