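#' Best reference hit per gene
#'
#' Reduces a gene-to-reference-protein hit table to one hit per gene: the hit
#' with maximal bit score, ties broken by higher amino-acid identity, then by
#' lexicographic reference id, so the reduction is deterministic.
#'
#' @param ref_hits Data frame with columns `gene_id`, `reference_id`,
#'   `database`, `aai_percent`, `bit_score`.
#' @return Data frame with one row per gene that has any hit.
#' @export
best_hit_per_gene <- function(ref_hits) {
  if (nrow(ref_hits) == 0) {
    return(ref_hits[0, c("gene_id", "reference_id", "database", "aai_percent"),
                    drop = FALSE])
  }
  ord <- order(ref_hits$gene_id, -ref_hits$bit_score, -ref_hits$aai_percent,
               ref_hits$reference_id)
  h <- ref_hits[ord, , drop = FALSE]
  h <- h[!duplicated(h$gene_id),
         c("gene_id", "reference_id", "database", "aai_percent"), drop = FALSE]
  rownames(h) <- NULL
  h
}

# Category label for a database tag.
database_category <- function(database) {
  ifelse(database == "refseq75", "refseq_phage", paste0("virome:", database))
}

#' Classify one contig by the majority-gene AAI rule
#'
#' For each reference genome `r`, let `f(r)` be the fraction of the contig's
#' genes whose best hit is to `r` (all genes on the contig count in the
#' denominator, hit or not) and `a(r)` the unweighted mean amino-acid identity
#' of those genes. A reference qualifies iff `f(r) > gene_fraction` and
#' `a(r) > aai_classify` (both strict). Among qualifiers, RefSeq genomes take
#' precedence over virome references, then higher `f`, then higher `a`, then
#' lexicographic reference id. A contig with no qualifier is novel.
#'
#' @param gene_ids Character vector: all genes on the contig.
#' @param best_hits Output of [best_hit_per_gene()].
#' @param thresholds A [default_thresholds()] list.
#' @param denominator `"all_genes"` (default) counts every gene on the contig
#'   in `f(r)`; `"hit_genes"` counts only genes with some best hit.
#' @return One-row data frame: `category`, `best_reference_id`,
#'   `gene_fraction_hit`, `mean_aai` (the latter two `NA` for novel contigs).
#' @export
classify_contig <- function(gene_ids, best_hits,
                            thresholds = default_thresholds(),
                            denominator = c("all_genes", "hit_genes")) {
  denominator <- match.arg(denominator)
  if (length(gene_ids) == 0) stop("cannot classify a contig with 0 genes")
  h <- best_hits[best_hits$gene_id %in% gene_ids, , drop = FALSE]
  denom <- if (denominator == "all_genes") length(gene_ids) else nrow(h)
  novel <- data.frame(category = "novel", best_reference_id = NA_character_,
                      gene_fraction_hit = NA_real_, mean_aai = NA_real_,
                      stringsAsFactors = FALSE)
  if (nrow(h) == 0 || denom == 0) return(novel)
  f <- tapply(h$gene_id, h$reference_id, length) / denom
  a <- tapply(h$aai_percent, h$reference_id, mean)
  db <- h$database[match(names(f), h$reference_id)]
  qualifies <- f > thresholds$gene_fraction & a > thresholds$aai_classify
  if (!any(qualifies)) return(novel)
  refs <- names(f)[qualifies]
  is_refseq <- db[qualifies] == "refseq75"
  ord <- order(!is_refseq, -f[refs], -a[refs], refs)
  best <- refs[ord[1]]
  data.frame(
    category = database_category(db[match(best, names(f))]),
    best_reference_id = best,
    gene_fraction_hit = unname(f[best]),
    mean_aai = unname(a[best]),
    stringsAsFactors = FALSE
  )
}

#' Classify a set of curated contigs
#'
#' @param genes Gene table (`gene_id`, `contig_id`).
#' @param ref_hits Reference hit table; see [best_hit_per_gene()].
#' @param contig_ids Contigs to classify (default: all in `genes`).
#' @inheritParams classify_contig
#' @return Data frame with one row per contig: `contig_id`, `category`,
#'   `best_reference_id`, `gene_fraction_hit`, `mean_aai`.
#' @export
classify_contigs <- function(genes, ref_hits, contig_ids = NULL,
                             thresholds = default_thresholds(),
                             denominator = "all_genes") {
  if (is.null(contig_ids)) contig_ids <- unique(genes$contig_id)
  bh <- best_hit_per_gene(ref_hits)
  rows <- lapply(contig_ids, function(cid) {
    res <- classify_contig(genes$gene_id[genes$contig_id == cid], bh,
                           thresholds, denominator)
    cbind(data.frame(contig_id = cid, stringsAsFactors = FALSE), res)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Category proportions of mapped nucleotides, per sample and depth bin
#'
#' Within each sample, the proportion of nucleotides mapped to contigs of each
#' homology category, normalized by total nucleotides mapped to all curated
#' contigs in that sample. Per depth bin the proportions are averaged across
#' samples and a standard error (`sd/sqrt(n)`) is attached. Samples with zero
#' total mapping are excluded with a warning.
#'
#' @param classifications Output of [classify_contigs()].
#' @param nucleotide_matrix Contigs x samples matrix of nucleotides mapped.
#' @param samples Sample frame (`sample_id`, `depth_m`).
#' @return List with `per_sample` (samples x categories proportion matrix) and
#'   `per_depth` (data frame: depth, category, mean_proportion, se, n).
#' @export
category_proportions <- function(classifications, nucleotide_matrix, samples) {
  cat_of <- classifications$category[
    match(rownames(nucleotide_matrix), classifications$contig_id)]
  if (anyNA(cat_of)) stop("nucleotide matrix contains unclassified contigs")
  tot <- colSums(nucleotide_matrix)
  bad <- tot <= 0
  if (any(bad)) {
    warning("excluding ", sum(bad), " sample(s) with zero total mapping")
  }
  m <- nucleotide_matrix[, !bad, drop = FALSE]
  by_cat <- rowsum(m, cat_of)                      # categories x samples
  prop <- t(sweep(by_cat, 2, colSums(by_cat), "/")) # samples x categories
  samples <- samples[match(rownames(prop), samples$sample_id), , drop = FALSE]
  per_depth <- do.call(rbind, lapply(sort(unique(samples$depth_m)), function(d) {
    rows <- prop[samples$depth_m == d, , drop = FALSE]
    data.frame(
      depth_m = d,
      category = colnames(rows),
      mean_proportion = colMeans(rows),
      se = apply(rows, 2, stats::sd) / sqrt(nrow(rows)),
      n = nrow(rows),
      stringsAsFactors = FALSE
    )
  }))
  rownames(per_depth) <- NULL
  list(per_sample = prop, per_depth = per_depth)
}
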