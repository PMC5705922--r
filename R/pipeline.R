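# Readers for the plain-text interchange formats. All TSVs carry one header
# line, UTF-8, LF endings; genes.gff is GFF3-style with 1-based inclusive
# coordinates (internal gene coordinates are 0-based half-open).

read_tsv_strict <- function(path, required) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(x))
  if (length(miss) > 0) {
    stop(basename(path), " is missing column(s): ", paste(miss, collapse = ", "))
  }
  x
}

#' Read pipeline input files
#'
#' @param path File path.
#' @return A data frame in the column layout the pipeline operations expect.
#' @name readers
NULL

#' @rdname readers
#' @export
read_samples <- function(path) {
  x <- read_tsv_strict(path, c("sample_id", "depth_m", "date"))
  x$date <- as.Date(x$date)
  x
}

#' @rdname readers
#' @export
read_coverage <- function(path) {
  read_tsv_strict(path, c("contig_id", "sample_id", "run_start",
                          "run_length", "depth"))
}

#' @rdname readers
#' @export
read_ref_hits <- function(path) {
  read_tsv_strict(path, c("gene_id", "reference_id", "database",
                          "aai_percent", "bit_score"))
}

#' @rdname readers
#' @export
read_domain_hits <- function(path) {
  read_tsv_strict(path, c("gene_id", "family", "bit_score"))
}

#' @rdname readers
#' @export
read_gene_catalog <- function(path) {
  read_tsv_strict(path, c("gene_id", "viral_best_aai", "photosystem_bit"))
}

#' @rdname readers
#' @export
read_gene_coverage <- function(path) {
  read_tsv_strict(path, c("gene_id", "sample_id", "coverage"))
}

#' @rdname readers
#' @export
read_single_copy <- function(path) {
  read_tsv_strict(path, c("family", "sample_id", "coverage"))
}

#' @rdname readers
#' @export
read_genes_gff <- function(path) {
  x <- utils::read.delim(path, header = FALSE, comment.char = "#",
                         stringsAsFactors = FALSE)
  if (ncol(x) < 9) stop(basename(path), " is not 9-column GFF")
  ids <- sub("^.*ID=([^;]+).*$", "\\1", x[[9]])
  data.frame(gene_id = ids, contig_id = x[[1]], start = x[[4]] - 1L,
             end = x[[5]], strand = x[[7]], stringsAsFactors = FALSE)
}

#' @rdname readers
#' @export
read_contigs_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  hdr <- names(seqs)
  id <- sub("\\s.*$", "", hdr)
  cat_m <- regmatches(hdr, regexpr("virsorter_category=[0-9]+", hdr))
  vcat <- rep(NA_integer_, length(hdr))
  has <- grepl("virsorter_category=", hdr)
  vcat[has] <- as.integer(sub("virsorter_category=", "", cat_m))
  data.frame(contig_id = id, length = Biostrings::width(seqs),
             virsorter_category = vcat, stringsAsFactors = FALSE)
}

write_tsv <- function(df, path, rownames_as = NULL) {
  if (!is.null(rownames_as)) {
    df <- cbind(stats::setNames(data.frame(rownames(df),
                                           stringsAsFactors = FALSE),
                                rownames_as),
                as.data.frame(df))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  path
}

#' Write a fixture directory plus a README describing the planted truth
#'
#' @param config A [sim_config()].
#' @param dir Output directory.
#' @param sequences Simulate and write `contigs.fasta`.
#' @return `dir`, invisibly.
#' @export
make_fixture <- function(config = sim_config(), dir, sequences = TRUE) {
  fix <- generate_fixture(config, sequences = sequences)
  write_fixture(fix, dir)
  n_groups <- table(fix$truth$contigs$group)
  writeLines(c(
    "Synthetic fixture emulating a 7-depth x 12-timepoint water-column design.",
    sprintf("Seed %d; %d contigs (%s).", config$seed, nrow(fix$contigs),
            paste(sprintf("%s: %d", names(n_groups), n_groups),
                  collapse = ", ")),
    sprintf("Planted lysogeny fold (mesopelagic vs surface): %g.",
            config$lysogeny_fold),
    sprintf("Planted AMG genes: %d; contaminant contigs: %d.",
            length(fix$truth$amg_gene_ids),
            length(fix$truth$contaminant_ids)),
    "truth.json holds the planted ground truth; no pipeline stage reads it."
  ), file.path(dir, "README.txt"))
  invisible(dir)
}

pipeline_input_files <- function() {
  c("genes.gff", "ref_hits.tsv", "domain_hits.tsv", "coverage.tsv",
    "samples.tsv", "gene_catalog.tsv", "gene_coverage.tsv", "single_copy.tsv")
}

#' Run the whole analysis pipeline over a fixture directory
#'
#' Executes, in order: contig curation, homology classification, coverage
#' statistics and depth grouping, assemblage clustering, life-history
#' profiling, and AMG detection. Every stage writes its tables under
#' `out_dir`; a `manifest.json` records the thresholds, per-stage row counts
#' and wall time. All input files are checked before any stage runs; a stage
#' failure aborts with the stage named and leaves a `FAILED` marker.
#'
#' @param input_dir Directory of pipeline inputs (see [write_fixture()]).
#' @param out_dir Output directory (created).
#' @param thresholds A [default_thresholds()] list.
#' @param cut_k Tree-cut group count for the dendrogram comparison.
#' @return The manifest, invisibly.
#' @export
run_all <- function(input_dir, out_dir, thresholds = default_thresholds(),
                    cut_k = 7) {
  t0 <- Sys.time()
  missing <- pipeline_input_files()[
    !file.exists(file.path(input_dir, pipeline_input_files()))]
  if (length(missing) > 0) {
    stop("missing input file(s): ", paste(missing, collapse = ", "))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  counts <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste("failed at stage:", name, "-", conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
      stop("pipeline failed at stage '", name, "': ", conditionMessage(e),
           call. = FALSE)
    })
  }

  genes <- read_genes_gff(file.path(input_dir, "genes.gff"))
  domain_hits <- read_domain_hits(file.path(input_dir, "domain_hits.tsv"))
  samples <- read_samples(file.path(input_dir, "samples.tsv"))
  fasta <- file.path(input_dir, "contigs.fasta")
  coverage <- read_coverage(file.path(input_dir, "coverage.tsv"))
  contigs <- stage("curate", {
    if (file.exists(fasta)) {
      read_contigs_fasta(fasta)
    } else {
      # fall back to gene + coverage extents when no FASTA is shipped
      ext <- tapply(genes$end, genes$contig_id, max)
      data.frame(contig_id = names(ext), length = as.integer(ext),
                 virsorter_category = NA_integer_, stringsAsFactors = FALSE)
    }
  })

  cur <- stage("curate", run_cascade(contigs, genes, domain_hits,
                                     thresholds = thresholds))
  writeLines(cur$retained$contig_id, file.path(out_dir, "retained_contigs.txt"))
  jsonlite::write_json(curation_report_as_list(cur$report),
                       file.path(out_dir, "curation_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  counts$curated <- nrow(cur$retained)

  cls <- stage("classify", {
    ref_hits <- read_ref_hits(file.path(input_dir, "ref_hits.tsv"))
    classify_contigs(genes, ref_hits, cur$retained$contig_id, thresholds)
  })
  write_tsv(cls, file.path(out_dir, "classifications.tsv"))
  counts$classified <- nrow(cls)

  cov_out <- stage("abundance", {
    cv <- coverage[coverage$contig_id %in% cur$retained$contig_id, ,
                   drop = FALSE]
    summ <- coverage_summaries(cv)
    iqr <- summary_matrix(summ, "iqr_mean",
                          contig_ids = cur$retained$contig_id,
                          sample_ids = samples$sample_id)
    nuc <- summary_matrix(summ, "nucleotides_mapped",
                          contig_ids = cur$retained$contig_id,
                          sample_ids = samples$sample_id)
    ab <- relative_abundance_matrix(nuc)
    groups <- assign_depth_groups(iqr[, colnames(ab), drop = FALSE], ab,
                                  samples)
    disp <- dispersion_by_depth(ab, samples)
    props <- category_proportions(cls, nuc, samples)
    list(iqr = iqr, nuc = nuc, ab = ab, groups = groups, disp = disp,
         props = props)
  })
  write_tsv(as.data.frame(cov_out$ab), file.path(out_dir, "abundance_matrix.tsv"),
            rownames_as = "contig_id")
  write_tsv(as.data.frame(cov_out$disp), file.path(out_dir, "dispersion.tsv"),
            rownames_as = "contig_id")
  write_tsv(cov_out$groups, file.path(out_dir, "depth_groups.tsv"))
  write_tsv(cov_out$props$per_depth, file.path(out_dir, "proportions.tsv"))
  counts$grouped <- nrow(cov_out$groups)

  asm <- stage("assemblage", {
    catalog <- read_gene_catalog(file.path(input_dir, "gene_catalog.tsv"))
    gcov <- read_gene_coverage(file.path(input_dir, "gene_coverage.tsv"))
    ab <- gene_abundance_matrix(gcov)
    part <- partition_gene_catalog(catalog, thresholds)
    d_ph <- bray_curtis_matrix(ab[rownames(ab) %in% part$phage_genes, ,
                                  drop = FALSE])
    d_ce <- bray_curtis_matrix(ab[rownames(ab) %in% part$cell_genes, ,
                                  drop = FALSE])
    t_ph <- average_linkage(d_ph)
    t_ce <- average_linkage(d_ce)
    list(part = part, d_ph = d_ph, d_ce = d_ce, t_ph = t_ph, t_ce = t_ce,
         cmp = compare_dendrograms(t_ph, t_ce, k = cut_k))
  })
  write_tsv(as.data.frame(asm$d_ph), file.path(out_dir, "phage_dist.tsv"),
            rownames_as = "sample_id")
  write_tsv(as.data.frame(asm$d_ce), file.path(out_dir, "cell_dist.tsv"),
            rownames_as = "sample_id")
  ape::write.tree(ape::as.phylo(asm$t_ph), file.path(out_dir, "phage_tree.nwk"))
  ape::write.tree(ape::as.phylo(asm$t_ce), file.path(out_dir, "cell_tree.nwk"))
  jsonlite::write_json(asm$cmp, file.path(out_dir, "tree_comparison.json"),
                       auto_unbox = TRUE, digits = NA)
  counts$phage_genes <- length(asm$part$phage_genes)

  lh <- stage("lifehistory", {
    gcov <- read_gene_coverage(file.path(input_dir, "gene_coverage.tsv"))
    sc <- read_single_copy(file.path(input_dir, "single_copy.tsv"))
    asn <- detect_markers(domain_hits, thresholds = thresholds)
    idx <- lysogeny_index(asn, gcov)
    prof <- fold_vs_surface(idx, samples)
    cnum <- copy_number_per_genome(asn, gcov, sc)
    flags <- flag_prophage_contigs(cur$retained$contig_id, genes, domain_hits,
                                   thresholds)
    list(idx = idx, prof = prof, cnum = cnum, flags = flags)
  })
  write_tsv(merge(lh$idx, samples[, c("sample_id", "depth_m")]),
            file.path(out_dir, "lysogeny_profile.tsv"))
  write_tsv(lh$prof, file.path(out_dir, "lysogeny_fold_profile.tsv"))
  write_tsv(lh$cnum, file.path(out_dir, "copy_numbers.tsv"))
  write_tsv(data.frame(contig_id = names(lh$flags),
                       prophage_flagged = unname(lh$flags)),
            file.path(out_dir, "prophage_flags.tsv"))
  counts$marker_samples <- nrow(lh$idx)

  amg <- stage("amg", {
    cand <- find_candidates(genes, domain_hits, thresholds = thresholds)
    validate_candidates(cand, genes, domain_hits, thresholds = thresholds)
    cand
  })
  write_tsv(amg, file.path(out_dir, "amg_candidates.tsv"))
  counts$amg_candidates <- nrow(amg)

  manifest <- list(
    package_version = as.character(utils::packageVersion("phagedepth")),
    input_dir = normalizePath(input_dir),
    thresholds = unclass(thresholds),
    stage_counts = counts,
    wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
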