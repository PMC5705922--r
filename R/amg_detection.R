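#' Known marine phage AMG / function labels
#'
#' Functional labels already reported in prior marine virome surveys. A
#' candidate "novel" gene must carry a label outside this list. The list ships
#' as editable plain text in `inst/extdata/known_amgs.txt`; pass your own file
#' to extend it.
#'
#' @param path Optional path to a one-label-per-line text file.
#' @return Character vector of labels (lower-cased).
#' @export
known_amg_functions <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "known_amgs.txt", package = "phagedepth")
  }
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  tolower(x[nzchar(x) & !startsWith(x, "#")])
}

# Families that can never nominate a "novel function": phage structural
# families and the life-history / single-copy marker families.
non_functional_families <- function() {
  cat <- marker_catalog()
  c(cat$prophage, cat$phage, cat$flag_only, default_marker_set()$family)
}

#' Find candidate novel phage genes / AMGs by colocalization
#'
#' A gene qualifies iff (a) it carries a functional domain hit with bit score
#' strictly > `amg_bit` whose label is neither in the known-function list nor
#' a structural or marker family, and (b) its contig carries at least one
#' structural-family hit with bit score strictly > `structural_bit` — the
#' colocalization requirement that anchors the call to a phage genome.
#'
#' @param genes Gene table (`gene_id`, `contig_id`).
#' @param domain_hits Data frame `gene_id`, `family`, `bit_score`.
#' @param known_functions Character vector of known AMG/function labels
#'   (matched case-insensitively); [known_amg_functions()] by default. An
#'   empty vector treats every functional label as novel, with a warning.
#' @param thresholds A [default_thresholds()] list.
#' @return Data frame, one row per candidate gene: `gene_id`, `contig_id`,
#'   `function_label`, `pfam_bit`, `structural_family`, `structural_bit`.
#' @export
find_candidates <- function(genes, domain_hits,
                            known_functions = known_amg_functions(),
                            thresholds = default_thresholds()) {
  if (length(known_functions) == 0) {
    warning("empty known-function list: every functional label is novel")
  }
  known <- tolower(known_functions)
  excluded <- domain_hits$family %in% non_functional_families() |
    is_structural_family(domain_hits$family)
  func <- domain_hits[!excluded &
                        !(tolower(domain_hits$family) %in% known) &
                        domain_hits$bit_score > thresholds$amg_bit, ,
                      drop = FALSE]
  if (nrow(func) == 0) {
    return(data.frame(gene_id = character(), contig_id = character(),
                      function_label = character(), pfam_bit = numeric(),
                      structural_family = character(),
                      structural_bit = numeric(), stringsAsFactors = FALSE))
  }
  # best novel-function hit per gene
  ord <- order(func$gene_id, -func$bit_score, func$family)
  func <- func[ord, , drop = FALSE]
  func <- func[!duplicated(func$gene_id), , drop = FALSE]
  func$contig_id <- genes$contig_id[match(func$gene_id, genes$gene_id)]
  func <- func[!is.na(func$contig_id), , drop = FALSE]

  # best structural support per contig
  str_hits <- domain_hits[is_structural_family(domain_hits$family) &
                            domain_hits$bit_score > thresholds$structural_bit, ,
                          drop = FALSE]
  str_hits$contig_id <- genes$contig_id[match(str_hits$gene_id, genes$gene_id)]
  str_hits <- str_hits[!is.na(str_hits$contig_id), , drop = FALSE]
  sord <- order(str_hits$contig_id, -str_hits$bit_score, str_hits$family)
  str_best <- str_hits[sord, , drop = FALSE]
  str_best <- str_best[!duplicated(str_best$contig_id), , drop = FALSE]

  m <- match(func$contig_id, str_best$contig_id)
  keep <- !is.na(m)
  out <- data.frame(
    gene_id = func$gene_id[keep],
    contig_id = func$contig_id[keep],
    function_label = func$family[keep],
    pfam_bit = func$bit_score[keep],
    structural_family = str_best$family[m[keep]],
    structural_bit = str_best$bit_score[m[keep]],
    stringsAsFactors = FALSE
  )
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Re-validate AMG candidates with an independent pass
#'
#' Walks gene-by-gene over the raw hit tables and confirms both predicates
#' (novel functional hit > `amg_bit`; structural support on the contig >
#' `structural_bit`) for every reported candidate.
#'
#' @param candidates Output of [find_candidates()].
#' @inheritParams find_candidates
#' @return TRUE invisibly; stops at the first violation.
#' @export
validate_candidates <- function(candidates, genes, domain_hits,
                                known_functions = known_amg_functions(),
                                thresholds = default_thresholds()) {
  known <- tolower(known_functions)
  for (i in seq_len(nrow(candidates))) {
    g <- candidates$gene_id[i]
    cid <- candidates$contig_id[i]
    gh <- domain_hits[domain_hits$gene_id == g, , drop = FALSE]
    ok_fun <- any(gh$bit_score > thresholds$amg_bit &
                    !(tolower(gh$family) %in% known) &
                    !(gh$family %in% non_functional_families()) &
                    !is_structural_family(gh$family))
    contig_genes <- genes$gene_id[genes$contig_id == cid]
    ch <- domain_hits[domain_hits$gene_id %in% contig_genes, , drop = FALSE]
    ok_str <- any(ch$bit_score > thresholds$structural_bit &
                    is_structural_family(ch$family))
    if (!ok_fun || !ok_str) {
      stop("candidate ", g, " fails revalidation (functional: ", ok_fun,
           ", structural: ", ok_str, ")")
    }
  }
  invisible(TRUE)
}

#' Depth specificity of an AMG candidate's host contig
#'
#' Labels the depth bins where the host contig is present — mean relative
#' abundance above `floor` in at least `min_samples` samples of the bin — and
#' flags the candidate depth-specific when exactly one bin qualifies, or two
#' adjacent bins (matching "25 and 75 m"-style reporting).
#'
#' @param contig_id Host contig.
#' @param abundance Contigs x samples relative-abundance matrix.
#' @param samples Sample frame.
#' @param floor Presence floor on relative abundance (default 0.001).
#' @param min_samples Minimum qualifying samples per bin (default 2).
#' @return List with `depth_labels` (numeric depths) and `specific` (logical).
#' @export
depth_specificity <- function(contig_id, abundance, samples, floor = 0.001,
                              min_samples = 2) {
  if (!contig_id %in% rownames(abundance)) {
    stop("contig ", contig_id, " not in abundance matrix")
  }
  samples <- samples[samples$sample_id %in% colnames(abundance), , drop = FALSE]
  depths <- sort(unique(samples$depth_m))
  present <- vapply(depths, function(d) {
    cols <- samples$sample_id[samples$depth_m == d]
    sum(abundance[contig_id, cols] > floor) >= min_samples
  }, logical(1))
  if (!any(present)) stop("contig ", contig_id, " absent from every depth bin")
  labs <- depths[present]
  idx <- which(present)
  specific <- length(labs) == 1 ||
    (length(labs) == 2 && diff(idx) == 1)
  list(depth_labels = labs, specific = specific)
}
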