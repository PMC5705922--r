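# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

# sort-and-slice interquartile mean
oracle_iqr_mean <- function(v) {
  L <- length(v)
  s <- sort(v)
  lo <- ceiling(L / 4)
  hi <- floor(3 * L / 4)
  mean(s[(lo + 1):hi])
}

# exhaustive UPGMA: average of original leaf-pair distances, min merged first
oracle_upgma_heights <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    best_h <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1)) {
        h <- mean(d[clusters[[i]], clusters[[j]]])
        if (h < best_h) {
          best_h <- h
          best <- c(j, i)
        }
      }
    }
    heights <- c(heights, best_h)
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
  }
  heights
}

# exhaustive majority-AAI classifier over every reference in the hit table
oracle_classify <- function(gene_ids, ref_hits, gene_fraction = 0.5,
                            aai_classify = 60) {
  h <- ref_hits[ref_hits$gene_id %in% gene_ids, , drop = FALSE]
  # best hit per gene: max bit, then max aai, then smallest reference id
  best <- do.call(rbind, lapply(split(h, h$gene_id), function(g) {
    g <- g[g$bit_score == max(g$bit_score), , drop = FALSE]
    g <- g[g$aai_percent == max(g$aai_percent), , drop = FALSE]
    g[which.min(rank(g$reference_id, ties.method = "first")), , drop = FALSE]
  }))
  refs <- unique(best$reference_id)
  qual <- list()
  for (r in refs) {
    sub <- best[best$reference_id == r, , drop = FALSE]
    f <- nrow(sub) / length(gene_ids)
    a <- mean(sub$aai_percent)
    if (f > gene_fraction && a > aai_classify) {
      qual[[r]] <- list(ref = r, db = sub$database[1], f = f, a = a)
    }
  }
  if (length(qual) == 0) return(list(category = "novel", ref = NA))
  is_rs <- vapply(qual, function(q) q$db == "refseq75", logical(1))
  fs <- vapply(qual, function(q) q$f, numeric(1))
  as_ <- vapply(qual, function(q) q$a, numeric(1))
  ids <- vapply(qual, function(q) q$ref, character(1))
  pick <- order(!is_rs, -fs, -as_, ids)[1]
  q <- qual[[pick]]
  list(category = if (q$db == "refseq75") "refseq_phage"
                  else paste0("virome:", q$db),
       ref = q$ref)
}

# double-loop AMG candidate enumeration
oracle_amg <- function(genes, domain_hits, known, amg_bit = 30,
                       structural_bit = 10) {
  structural <- c("terminase", "portal", "capsid", "tail", "base plate",
                  "spike", "neck", "head")
  is_struct <- function(fam) {
    fam <- gsub("[^a-z0-9]+", " ", tolower(fam))
    any(vapply(structural, function(s) grepl(paste0("\\b", s, "\\b"), fam),
               logical(1)))
  }
  marker_like <- c("integrase", "CI_repressor", "excisionase", "Cro",
                   "DNA_polymerase", "tail_fiber",
                   phagedepth::default_marker_set()$family)
  out <- character(0)
  for (i in seq_len(nrow(genes))) {
    g <- genes$gene_id[i]
    gh <- domain_hits[domain_hits$gene_id == g, , drop = FALSE]
    ok_fun <- FALSE
    for (k in seq_len(nrow(gh))) {
      if (gh$bit_score[k] > amg_bit && !is_struct(gh$family[k]) &&
          !(tolower(gh$family[k]) %in% tolower(known)) &&
          !(gh$family[k] %in% marker_like)) {
        ok_fun <- TRUE
      }
    }
    if (!ok_fun) next
    mates <- genes$gene_id[genes$contig_id == genes$contig_id[i]]
    ch <- domain_hits[domain_hits$gene_id %in% mates, , drop = FALSE]
    ok_str <- FALSE
    for (k in seq_len(nrow(ch))) {
      if (ch$bit_score[k] > structural_bit && is_struct(ch$family[k])) {
        ok_str <- TRUE
      }
    }
    if (ok_str) out <- c(out, g)
  }
  sort(out)
}

# random hit-table generator for the classification oracle tests
random_classification_case <- function(n_genes, n_refs, force_boundary = FALSE) {
  gene_ids <- sprintf("g%02d", seq_len(n_genes))
  dbs <- sample(c("refseq75", "uvMED", "GOV", "EV", "uvDeep"), n_refs,
                replace = TRUE)
  refs <- sprintf("ref%02d", seq_len(n_refs))
  rows <- list()
  for (g in gene_ids) {
    n_hit <- sample(0:n_refs, 1)
    if (n_hit == 0) next
    pick <- sample.int(n_refs, n_hit)
    rows[[g]] <- data.frame(
      gene_id = g, reference_id = refs[pick], database = dbs[pick],
      aai_percent = round(runif(n_hit, 30, 100), 1),
      bit_score = round(runif(n_hit, 20, 200), 1),
      stringsAsFactors = FALSE
    )
  }
  hits <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(), reference_id = character(),
               database = character(), aai_percent = numeric(),
               bit_score = numeric(), stringsAsFactors = FALSE)
  if (force_boundary && n_genes %% 2 == 0 && n_genes > 0) {
    # exactly half the genes best-hit one reference at AAI exactly 60:
    # must stay novel under the strict > rules
    hits <- hits[!(hits$gene_id %in% gene_ids[seq_len(n_genes / 2)]), ,
                 drop = FALSE]
    hits <- rbind(hits, data.frame(
      gene_id = gene_ids[seq_len(n_genes / 2)], reference_id = "ref_bound",
      database = "refseq75", aai_percent = 60, bit_score = 500,
      stringsAsFactors = FALSE
    ))
  }
  list(gene_ids = gene_ids, hits = hits)
}

# adjusted Rand index (via mclust when present)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# small default-noise fixture reused across recovery tests
small_config <- function(seed, ...) {
  phagedepth::sim_config(seed = seed, n_contigs = 10, coverage_window = 2000,
                         ...)
}
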