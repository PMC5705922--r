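#' Single-copy prokaryotic marker families used in the contamination screen
#'
#' A curated list of gene families expected exactly once per prokaryotic
#' genome. Ribosomal families trigger outright removal of a contig when hit;
#' recA and DNA helicase are flagged phage-ambiguous because phages carry
#' their own recombination and replication homologs, so hits to them are
#' tallied but do not remove contigs.
#'
#' @return Data frame with columns `family`, `ribosomal`, `phage_ambiguous`.
#' @export
default_marker_set <- function() {
  ribosomal <- c(
    "ribosomal protein S2", "ribosomal protein S7", "ribosomal protein S11",
    "ribosomal protein S17", "ribosomal protein L1", "ribosomal protein L2",
    "ribosomal protein L5", "ribosomal protein L6", "ribosomal protein L14",
    "ribosomal protein L16", "ribosomal protein L22"
  )
  ambiguous <- c("recA", "DNA helicase")
  other <- c("rpoB", "gyrA", "dnaG", "pyrG", "tsf", "frr", "infC", "nusA",
             "smpB")
  data.frame(
    family = c(ribosomal, ambiguous, other),
    ribosomal = c(rep(TRUE, length(ribosomal)),
                  rep(FALSE, length(ambiguous) + length(other))),
    phage_ambiguous = c(rep(FALSE, length(ribosomal)),
                        rep(TRUE, length(ambiguous)),
                        rep(FALSE, length(other))),
    stringsAsFactors = FALSE
  )
}

#' Length filter for candidate viral contigs
#'
#' Retains contigs at least `min_contig_len` bp long (inclusive); 20 kbp is
#' the lower end of genome size in marine dsDNA phages, so the default focuses
#' the analysis on near-complete genomes or large fragments. Input order is
#' preserved.
#'
#' @param contigs Data frame with at least `contig_id` and `length` columns.
#' @param thresholds A [default_thresholds()] list.
#' @return List with `retained` (subset of `contigs`) and `report` (stage
#'   entry: counts and removed ids).
#' @export
filter_by_length <- function(contigs, thresholds = default_thresholds()) {
  if (nrow(contigs) == 0) warning("empty contig set passed to length filter")
  keep <- contigs$length >= thresholds$min_contig_len
  list(
    retained = contigs[keep, , drop = FALSE],
    report = list(stage = "length", n_in = nrow(contigs),
                  n_retained = sum(keep),
                  removed = contigs$contig_id[!keep],
                  reason = sprintf("length < %s bp",
                                   format(thresholds$min_contig_len)))
  )
}

# Best structural-family bit score per contig (-Inf when none).
best_structural_bit <- function(contig_ids, genes, domain_hits) {
  hits <- domain_hits[is_structural_family(domain_hits$family), , drop = FALSE]
  hits$contig_id <- genes$contig_id[match(hits$gene_id, genes$gene_id)]
  hits <- hits[!is.na(hits$contig_id), , drop = FALSE]
  best <- tapply(hits$bit_score, hits$contig_id, max)
  out <- rep(-Inf, length(contig_ids))
  names(out) <- contig_ids
  best <- best[names(best) %in% contig_ids]
  out[names(best)] <- best
  out
}

#' Does a contig carry a recognizable phage structural gene?
#'
#' TRUE iff at least one gene on the contig hits any of the eight structural
#' families (terminase, portal, capsid, tail, base plate, spike, neck, head)
#' with a domain bit score strictly greater than `structural_bit`. Contigs
#' failing this are dropped as unverifiable: even distant homology to a
#' structural protein is required for a high-confidence viral call.
#'
#' @param contig_ids Character vector of contig ids to test.
#' @param genes Gene table (`gene_id`, `contig_id`, ...).
#' @param domain_hits Domain score table (`gene_id`, `family`, `bit_score`).
#' @param thresholds A [default_thresholds()] list.
#' @return Named logical vector over `contig_ids`.
#' @export
require_structural_gene <- function(contig_ids, genes, domain_hits,
                                    thresholds = default_thresholds()) {
  if (is.infinite(thresholds$structural_bit) && thresholds$structural_bit < 0) {
    # a -Inf cutoff disables the stage entirely, even for hit-less contigs
    return(stats::setNames(rep(TRUE, length(contig_ids)), contig_ids))
  }
  best_structural_bit(contig_ids, genes, domain_hits) > thresholds$structural_bit
}

#' Screen curated contigs for cellular contamination
#'
#' Maps every gene against a set of single-copy prokaryotic marker families.
#' A contig carrying a ribosomal marker hit above `marker_bit` is removed.
#' Hits to recA / DNA helicase are counted separately as phage-ambiguous
#' (phages encode their own recombination/replication homologs) and never
#' remove a contig. The report carries a completeness proxy: the fraction of
#' distinct non-ambiguous marker families observed, an order-of-magnitude
#' stand-in for lineage-aware genome completeness estimation.
#'
#' @inheritParams require_structural_gene
#' @param contigs Contig table.
#' @param marker_set Data frame as returned by [default_marker_set()].
#' @return List with `retained` and `report` (stage counts, marker tallies,
#'   `completeness_proxy`).
#' @export
contamination_screen <- function(contigs, genes, domain_hits,
                                 marker_set = default_marker_set(),
                                 thresholds = default_thresholds()) {
  if (nrow(marker_set) == 0) stop("marker_set must not be empty")
  on_contigs <- genes$gene_id[genes$contig_id %in% contigs$contig_id]
  hits <- domain_hits[domain_hits$gene_id %in% on_contigs &
                        domain_hits$family %in% marker_set$family &
                        domain_hits$bit_score > thresholds$marker_bit, ,
                      drop = FALSE]
  fam <- marker_set[match(hits$family, marker_set$family), ]
  n_marker_genes <- length(unique(hits$gene_id))
  n_ambiguous <- length(unique(hits$gene_id[fam$phage_ambiguous]))
  nonambig <- unique(hits$family[!fam$phage_ambiguous])
  completeness <- length(nonambig) / sum(!marker_set$phage_ambiguous)

  ribo_genes <- hits$gene_id[fam$ribosomal]
  bad_contigs <- unique(genes$contig_id[genes$gene_id %in% ribo_genes])
  keep <- !(contigs$contig_id %in% bad_contigs)
  list(
    retained = contigs[keep, , drop = FALSE],
    report = list(
      stage = "contamination", n_in = nrow(contigs), n_retained = sum(keep),
      removed = contigs$contig_id[!keep],
      reason = "ribosomal single-copy marker hit",
      n_marker_hits = n_marker_genes,
      n_ambiguous_hits = n_ambiguous,
      n_total_genes = length(on_contigs),
      completeness_proxy = completeness
    )
  )
}

#' The full contig quality-control cascade
#'
#' Applies, in order: the 20 kbp length filter, the structural-gene
#' requirement, and the cellular-contamination screen. The returned report
#' records counts and removed ids for every stage; retained counts are
#' monotonically nonincreasing by construction.
#'
#' @inheritParams contamination_screen
#' @return List with `retained` (final contig table) and `report` (class
#'   `"curation_report"`).
#' @export
run_cascade <- function(contigs, genes, domain_hits,
                        marker_set = default_marker_set(),
                        thresholds = default_thresholds()) {
  # the viral-detection category is consumed as input, only validated here
  vc <- contigs$virsorter_category
  if (!is.null(vc) && any(!is.na(vc) & !(vc %in% 1:6))) {
    stop("virsorter_category must be in 1..6 (or NA) for: ",
         paste(contigs$contig_id[!is.na(vc) & !(vc %in% 1:6)],
               collapse = ", "))
  }
  st1 <- filter_by_length(contigs, thresholds)
  ok <- require_structural_gene(st1$retained$contig_id, genes, domain_hits,
                                thresholds)
  st2 <- list(
    retained = st1$retained[ok, , drop = FALSE],
    report = list(stage = "structural", n_in = nrow(st1$retained),
                  n_retained = sum(ok),
                  removed = st1$retained$contig_id[!ok],
                  reason = sprintf("no structural-family hit > %g bits",
                                   thresholds$structural_bit))
  )
  st3 <- contamination_screen(st2$retained, genes, domain_hits, marker_set,
                              thresholds)
  report <- structure(
    list(stages = list(st1$report, st2$report, st3$report)),
    class = "curation_report"
  )
  list(retained = st3$retained, report = report)
}

#' @export
print.curation_report <- function(x, ...) {
  cat("contig curation cascade:\n")
  for (s in x$stages) {
    cat(sprintf("  %-13s %5d -> %5d retained (%d removed: %s)\n",
                s$stage, s$n_in, s$n_retained, s$n_in - s$n_retained,
                s$reason))
  }
  last <- x$stages[[length(x$stages)]]
  cat(sprintf("  marker-hit genes: %d (%d phage-ambiguous) of %d genes;",
              last$n_marker_hits, last$n_ambiguous_hits, last$n_total_genes),
      sprintf("completeness proxy %.3f\n", last$completeness_proxy))
  invisible(x)
}

# Flatten a curation report into a plain list for JSON serialization.
curation_report_as_list <- function(report) {
  lapply(report$stages, function(s) s)
}
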