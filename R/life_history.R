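#' Marker catalog for viral life-history profiling
#'
#' Prophage markers (integrase, CI repressor, excisionase) diagnose the
#' lambda-style lysogenic module; phage markers (DNA polymerase, terminase,
#' capsid, tail fiber) diagnose general phage content, with capsid serving as
#' the normalizer of the lysogeny index. Cro is used only for per-contig
#' prophage flagging, never in the index.
#'
#' @return List with character vectors `prophage`, `phage`, `flag_only`.
#' @export
marker_catalog <- function() {
  list(
    prophage = c("CI_repressor", "excisionase", "integrase"),
    phage = c("DNA_polymerase", "capsid", "tail_fiber", "terminase"),
    flag_only = "Cro"
  )
}

#' Assign catalog genes to marker families
#'
#' A gene is assigned to a marker family iff its curated-HMM domain bit score
#' for that family strictly exceeds `marker_bit` (default 50, over the whole
#' sequence). A gene clearing the threshold for several families takes the
#' highest-scoring one; ties break lexicographically by family name.
#'
#' @param domain_hits Data frame `gene_id`, `family`, `bit_score`.
#' @param catalog A [marker_catalog()] list.
#' @param thresholds A [default_thresholds()] list.
#' @return Data frame `gene_id`, `family` (one row per assigned gene).
#' @export
detect_markers <- function(domain_hits, catalog = marker_catalog(),
                           thresholds = default_thresholds()) {
  fams <- c(catalog$prophage, catalog$phage)
  h <- domain_hits[domain_hits$family %in% fams &
                     domain_hits$bit_score > thresholds$marker_bit, ,
                   drop = FALSE]
  if (nrow(h) == 0) {
    return(data.frame(gene_id = character(), family = character(),
                      stringsAsFactors = FALSE))
  }
  ord <- order(h$gene_id, -h$bit_score, h$family)
  h <- h[ord, , drop = FALSE]
  h <- h[!duplicated(h$gene_id), c("gene_id", "family"), drop = FALSE]
  rownames(h) <- NULL
  h
}

# Summed coverage of the genes of one family set, per sample.
summed_family_coverage <- function(assignments, gene_coverage, families) {
  genes <- assignments$gene_id[assignments$family %in% families]
  cov <- gene_coverage[gene_coverage$gene_id %in% genes, , drop = FALSE]
  samps <- sort(unique(gene_coverage$sample_id))
  out <- rep(0, length(samps))
  names(out) <- samps
  if (nrow(cov) > 0) {
    s <- tapply(cov$coverage, cov$sample_id, sum)
    out[names(s)] <- s
  }
  out
}

#' Per-sample lysogeny index
#'
#' The summed coverage of prophage markers (integrase, CI repressor,
#' excisionase) divided by the summed coverage of capsids — a proxy for the
#' proportion of phages with the genetic potential for lysogeny. Being a
#' ratio, the index is invariant to uniform rescaling of a sample's coverages
#' (sequencing depth cancels). Per-family indices are also returned so that a
#' family behaving anomalously (integrase counts can be inflated by
#' non-prophage integrases) can be inspected on its own.
#'
#' @param assignments Output of [detect_markers()].
#' @param gene_coverage Data frame `gene_id`, `sample_id`, `coverage`.
#' @param catalog A [marker_catalog()] list.
#' @return Data frame with one row per sample: `sample_id`, `prophage_sum`,
#'   `capsid_sum`, `index`, plus `index_<family>` per prophage family.
#'   Samples with zero capsid coverage get `NA` indices with a warning.
#' @export
lysogeny_index <- function(assignments, gene_coverage,
                           catalog = marker_catalog()) {
  capsid <- summed_family_coverage(assignments, gene_coverage, "capsid")
  pro <- summed_family_coverage(assignments, gene_coverage, catalog$prophage)
  if (any(capsid == 0)) {
    warning(sum(capsid == 0),
            " sample(s) have zero capsid coverage; index undefined there")
  }
  idx <- ifelse(capsid > 0, pro / capsid, NA_real_)
  out <- data.frame(sample_id = names(capsid), prophage_sum = unname(pro),
                    capsid_sum = unname(capsid), index = unname(idx),
                    stringsAsFactors = FALSE)
  for (fam in catalog$prophage) {
    fs <- summed_family_coverage(assignments, gene_coverage, fam)
    out[[paste0("index_", fam)]] <-
      ifelse(capsid > 0, unname(fs) / unname(capsid), NA_real_)
  }
  rownames(out) <- NULL
  out
}

#' Fold change of a per-sample index relative to the surface mean
#'
#' Averages the index within each depth, then divides by the mean index over
#' surface samples (25 and 75 m by default). The surface bin folds average to
#' 1 by construction.
#'
#' @param indices Data frame `sample_id`, `index` (e.g. from
#'   [lysogeny_index()]; `NA` indices are dropped).
#' @param samples Sample frame (`sample_id`, `depth_m`).
#' @param surface_depths Depths (m) defining the surface reference.
#' @param index_col Which column of `indices` to profile.
#' @return Data frame `depth_m`, `mean_index`, `fold_vs_surface`.
#' @export
fold_vs_surface <- function(indices, samples, surface_depths = c(25, 75),
                            index_col = "index") {
  x <- indices[[index_col]]
  depth <- samples$depth_m[match(indices$sample_id, samples$sample_id)]
  ok <- !is.na(x) & !is.na(depth)
  x <- x[ok]
  depth <- depth[ok]
  if (!any(depth %in% surface_depths)) stop("no valid surface samples")
  surf_mean <- mean(x[depth %in% surface_depths])
  if (surf_mean == 0) stop("surface mean index is zero; fold undefined")
  depths <- sort(unique(samples$depth_m))
  mu <- vapply(depths, function(d) mean(x[depth == d]), numeric(1))
  data.frame(depth_m = depths, mean_index = mu,
             fold_vs_surface = mu / surf_mean)
}

#' Marker copy number per cellular genome
#'
#' For every sample and marker family, the family's summed coverage divided by
#' the average coverage of 10 universal single-copy bacterial marker genes
#' (mOTU-style normalization), estimating marker copies per cellular genome.
#' Prophages are predominantly nonreplicative, so prophage-marker copy numbers
#' approximate prophages per genome; phage-marker copy numbers approximate
#' total phage genomes captured inside cells.
#'
#' @inheritParams lysogeny_index
#' @param single_copy_coverage Data frame `family`, `sample_id`, `coverage`
#'   with all 10 universal single-copy families present and positive in every
#'   sample.
#' @param mean_type `"arithmetic"` (default; "average coverage") or
#'   `"geometric"`.
#' @param expected_families The single-copy families that must be present and
#'   positive in every sample; defaults to all families seen in
#'   `single_copy_coverage`.
#' @return Data frame `sample_id`, `family`, `copy_number` covering every
#'   prophage and phage marker family.
#' @export
copy_number_per_genome <- function(assignments, gene_coverage,
                                   single_copy_coverage,
                                   catalog = marker_catalog(),
                                   mean_type = c("arithmetic", "geometric"),
                                   expected_families = NULL) {
  mean_type <- match.arg(mean_type)
  samps <- sort(unique(gene_coverage$sample_id))
  fams <- c(catalog$prophage, catalog$phage)
  sc_fams <- if (is.null(expected_families)) {
    unique(single_copy_coverage$family)
  } else {
    expected_families
  }
  out <- list()
  for (s in samps) {
    sc <- single_copy_coverage[single_copy_coverage$sample_id == s, ,
                               drop = FALSE]
    missing <- setdiff(sc_fams, sc$family[sc$coverage > 0])
    if (length(missing) > 0) {
      stop("sample ", s, " missing positive coverage for single-copy ",
           "families: ", paste(missing, collapse = ", "))
    }
    sc_cov <- tapply(sc$coverage, sc$family, sum)
    denom <- if (mean_type == "arithmetic") mean(sc_cov) else exp(mean(log(sc_cov)))
    for (fam in fams) {
      num <- summed_family_coverage(assignments, gene_coverage, fam)[s]
      out[[length(out) + 1]] <- data.frame(
        sample_id = s, family = fam, copy_number = unname(num) / denom,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Flag contigs containing prophage markers
#'
#' TRUE for contigs where any gene scores strictly above `prophage_flag_bit`
#' (default 30) against integrase, CI repressor, Cro, or excisionase. This is
#' the looser, PFAM-style per-contig flag (asterisks in abundance panels); it
#' is deliberately distinct from the stricter bit > 50 curated-HMM rule used
#' for the gene-catalog marker profile, and the two are never conflated.
#'
#' @param contig_ids Contigs to flag.
#' @param genes Gene table (`gene_id`, `contig_id`).
#' @param domain_hits Data frame `gene_id`, `family`, `bit_score`.
#' @param thresholds A [default_thresholds()] list.
#' @return Named logical vector over `contig_ids`.
#' @export
flag_prophage_contigs <- function(contig_ids, genes, domain_hits,
                                  thresholds = default_thresholds()) {
  fams <- c(marker_catalog()$prophage, marker_catalog()$flag_only)
  h <- domain_hits[domain_hits$family %in% fams &
                     domain_hits$bit_score > thresholds$prophage_flag_bit, ,
                   drop = FALSE]
  flagged <- unique(genes$contig_id[genes$gene_id %in% h$gene_id])
  out <- contig_ids %in% flagged
  names(out) <- contig_ids
  out
}
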