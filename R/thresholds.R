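#' Analysis thresholds
#'
#' Single home for every cutoff used by the pipeline. All bit-score and
#' amino-acid-identity comparisons in this package are strict (`>`); the
#' contig length filter is inclusive (`>=`).
#'
#' @param min_contig_len Minimum contig length retained, in bp (inclusive).
#' @param structural_bit Domain bit score a structural-family hit must exceed
#'   for a contig to count as carrying a phage structural gene.
#' @param amg_bit Domain bit score a functional hit must exceed to nominate a
#'   candidate novel gene / auxiliary metabolic gene (AMG).
#' @param marker_bit Domain bit score a curated-HMM marker hit must exceed in
#'   the gene-catalog marker profile, and the single-copy prokaryotic marker
#'   screen during curation.
#' @param prophage_flag_bit Domain bit score above which a per-contig prophage
#'   flag is raised (integrase, CI repressor, Cro, excisionase).
#' @param photosystem_bit Domain bit score above which a gene counts as a
#'   photosystem gene and is removed from the phage gene set.
#' @param aai_classify Average amino-acid identity (percent) a reference must
#'   exceed for contig classification.
#' @param aai_viral_gene Amino-acid identity (percent) above which a catalog
#'   gene is called viral.
#' @param gene_fraction Fraction of a contig's genes that must best-hit one
#'   reference (strictly exceeded) for classification.
#' @param top_k How many most-abundant contigs to rank per depth bin.
#'
#' @return A named list of class `"phage_thresholds"`.
#' @examples
#' th <- default_thresholds()
#' th$min_contig_len
#' @export
default_thresholds <- function(min_contig_len = 20000,
                               structural_bit = 10,
                               amg_bit = 30,
                               marker_bit = 50,
                               prophage_flag_bit = 30,
                               photosystem_bit = 30,
                               aai_classify = 60,
                               aai_viral_gene = 90,
                               gene_fraction = 0.5,
                               top_k = 13) {
  th <- list(
    min_contig_len = min_contig_len,
    structural_bit = structural_bit,
    amg_bit = amg_bit,
    marker_bit = marker_bit,
    prophage_flag_bit = prophage_flag_bit,
    photosystem_bit = photosystem_bit,
    aai_classify = aai_classify,
    aai_viral_gene = aai_viral_gene,
    gene_fraction = gene_fraction,
    top_k = top_k
  )
  num <- vapply(th, function(x) is.numeric(x) && length(x) == 1 && !is.na(x),
                logical(1))
  if (!all(num)) {
    stop("all thresholds must be numeric scalars: ",
         paste(names(th)[!num], collapse = ", "))
  }
  if (any(unlist(th[c("min_contig_len", "gene_fraction", "top_k")]) <= 0)) {
    stop("min_contig_len, gene_fraction and top_k must be strictly positive")
  }
  structure(th, class = "phage_thresholds")
}

#' @export
print.phage_thresholds <- function(x, ...) {
  cat("phage analysis thresholds:\n")
  for (nm in names(x)) cat(sprintf("  %-18s %g\n", nm, x[[nm]]))
  invisible(x)
}

# The eight structural protein families whose presence (bit > structural_bit)
# qualifies a contig as carrying a phage structural gene. Synonyms are matched
# case-insensitively after squashing separators.
structural_families <- function() {
  c("terminase", "portal", "capsid", "tail", "base plate", "spike",
    "neck", "head")
}

# Maps free-text family labels onto the canonical structural set; returns the
# canonical name or NA. "major head protein" -> "head", "baseplate" ->
# "base plate", "tail_fiber" -> "tail", etc.
normalize_structural_family <- function(family) {
  canon <- structural_families()
  key <- gsub("[^a-z0-9]+", " ", tolower(family))
  key <- trimws(key)
  syn <- c(
    "baseplate" = "base plate", "base plate protein" = "base plate",
    "major head protein" = "head", "head protein" = "head",
    "major capsid protein" = "capsid", "capsid protein" = "capsid",
    "portal protein" = "portal", "portal vertex" = "portal",
    "terminase large subunit" = "terminase",
    "terminase small subunit" = "terminase",
    "tail fiber" = "tail", "tail fibre" = "tail", "tail sheath" = "tail",
    "tail tube" = "tail", "neck protein" = "neck", "tail spike" = "spike",
    "tailspike" = "spike"
  )
  out <- ifelse(key %in% canon, key,
                ifelse(key %in% names(syn), unname(syn[key]), NA_character_))
  # "phage tail fiber protein" and friends: fall back to word match
  miss <- is.na(out)
  if (any(miss)) {
    for (fam in canon) {
      hit <- miss & grepl(paste0("\\b", fam, "\\b"), key)
      out[hit] <- fam
      miss <- is.na(out)
    }
  }
  out
}

is_structural_family <- function(family) {
  !is.na(normalize_structural_family(family))
}
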