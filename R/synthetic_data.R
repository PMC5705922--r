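#' Configuration for the synthetic fixture generator
#'
#' Describes a depth-stratified, time-resolved sampling design: by default 7
#' depths (25, 75, 125, 200, 500, 770, 1,000 m) sampled on 12 occasions, with
#' one depth/date combination missing so the full design holds 83 samples.
#' Contigs are assigned to five depth-distribution groups (surface, DCM,
#' 200 m, mesopelagic, sporadic); persistent groups keep their home-depth
#' population above the detection floor at every timepoint, sporadic contigs
#' bloom in a random minority of timepoints only. A lysogeny gradient is
#' planted below the deep chlorophyll maximum: the prophage:capsid coverage
#' ratio at 500-1,000 m is `lysogeny_fold` times the surface ratio in
#' expectation.
#'
#' Noise model: per-base read depth is Poisson around a per-contig, per-sample
#' rate; the rate varies across samples as a mean-preserving lognormal whose
#' log-sd is group-specific (`sigma_log`), giving boom-and-bust style
#' overdispersion at the sample level. A rate below `detection_floor` is
#' treated as absence.
#'
#' @param seed Integer seed; all draws flow from it.
#' @param depths_m Strictly increasing sampling depths (m).
#' @param n_timepoints Number of sampling occasions.
#' @param n_contigs Number of viral contigs (contaminants are extra).
#' @param group_weights Named sampling weights over the five depth groups.
#' @param lysogeny_fold Planted mesopelagic:surface prophage-to-capsid ratio
#'   fold (> 0).
#' @param surface_ratio Prophage:capsid coverage ratio at the surface.
#' @param copy_numbers Phage-marker copies per cellular genome: families x
#'   depths matrix (see [default_copy_numbers()]).
#' @param sigma_log Named per-group lognormal log-sd of the coverage rate
#'   across samples.
#' @param sigma_log_marker Lognormal log-sd of catalog marker-gene coverage.
#' @param spike_fraction Fraction of a contig's positions carrying a
#'   conserved-gene coverage spike (in `[0, 1)`, < 0.5 in practice).
#' @param spike_multiplier Depth multiplier inside the spike block (>= 1).
#' @param contaminant_count Cellular contigs carrying ribosomal single-copy
#'   marker hits.
#' @param n_amg Planted novel-function (AMG candidate) genes.
#' @param integrase_boost Extra multiplier on integrase coverage only, to
#'   emulate anomalous non-prophage integrase signal (default 1 = off).
#' @param detection_floor Coverage rate below which a contig is absent.
#' @param coverage_window Resolution (bp) of the simulated per-base depth:
#'   depth is piecewise constant over windows of this size, one Poisson draw
#'   per window, stored run-length encoded.
#' @param contig_len_range Contig length range (bp), uniform.
#' @param gene_length Gene length (bp); genes tile each contig.
#' @param class_weights Named weights over homology categories
#'   (refseq/virome/novel) for planted reference hits.
#' @param n_cell_genes,n_phage_genes Depth-indicator genes on the cellular and
#'   phage sides of the gene catalog.
#' @param n_photosystem_genes Viral-identified photosystem genes (removed by
#'   the catalog partition).
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1,
                       depths_m = c(25, 75, 125, 200, 500, 770, 1000),
                       n_timepoints = 12,
                       n_contigs = 60,
                       group_weights = c(surface = 0.30, DCM = 0.15,
                                         two_hundred = 0.15,
                                         mesopelagic = 0.30, sporadic = 0.10),
                       lysogeny_fold = 5,
                       surface_ratio = 0.2,
                       copy_numbers = default_copy_numbers(depths_m),
                       sigma_log = c(surface = 0.3, DCM = 0.35,
                                     two_hundred = 0.4, mesopelagic = 0.7,
                                     sporadic = 0.6),
                       sigma_log_marker = 0.4,
                       spike_fraction = 0.05,
                       spike_multiplier = 20,
                       contaminant_count = 2,
                       n_amg = 5,
                       integrase_boost = 1,
                       detection_floor = 0.05,
                       coverage_window = 500,
                       contig_len_range = c(20000, 108000),
                       gene_length = 900,
                       class_weights = c(refseq = 0.08, virome = 0.31,
                                         novel = 0.61),
                       n_cell_genes = 140,
                       n_phage_genes = 70,
                       n_photosystem_genes = 6) {
  if (is.unsorted(depths_m, strictly = TRUE)) {
    stop("depths_m must be strictly increasing")
  }
  counts <- c(n_timepoints = n_timepoints, n_contigs = n_contigs,
              n_depths = length(depths_m))
  if (any(counts < 1)) stop("all counts must be >= 1")
  if (lysogeny_fold <= 0) stop("lysogeny_fold must be > 0")
  if (spike_fraction < 0 || spike_fraction >= 1) {
    stop("spike_fraction must lie in [0, 1)")
  }
  if (contaminant_count < 0 || n_amg < 0) stop("counts must be nonnegative")
  structure(list(
    seed = seed, depths_m = depths_m, n_timepoints = n_timepoints,
    n_contigs = n_contigs, group_weights = group_weights,
    lysogeny_fold = lysogeny_fold, surface_ratio = surface_ratio,
    copy_numbers = copy_numbers, sigma_log = sigma_log,
    sigma_log_marker = sigma_log_marker, spike_fraction = spike_fraction,
    spike_multiplier = spike_multiplier,
    contaminant_count = contaminant_count, n_amg = n_amg,
    integrase_boost = integrase_boost, detection_floor = detection_floor,
    coverage_window = coverage_window, contig_len_range = contig_len_range,
    gene_length = gene_length, class_weights = class_weights,
    n_cell_genes = n_cell_genes, n_phage_genes = n_phage_genes,
    n_photosystem_genes = n_photosystem_genes
  ), class = "sim_config")
}

#' Default planted marker copy numbers per cellular genome
#'
#' Phage markers decline with depth (fewer active infections per cell in the
#' aphotic ocean); values interpolate log-linearly between a surface and a
#' bottom anchor per family.
#'
#' @param depths_m Sampling depths.
#' @return Families x depths matrix.
#' @export
default_copy_numbers <- function(depths_m = c(25, 75, 125, 200, 500, 770,
                                              1000)) {
  anchors <- rbind(
    capsid = c(3.0, 0.5),
    DNA_polymerase = c(2.0, 0.4),
    terminase = c(1.0, 0.3),
    tail_fiber = c(0.8, 0.2)
  )
  frac <- (log(depths_m) - log(min(depths_m))) /
    (log(max(depths_m)) - log(min(depths_m)))
  out <- t(vapply(seq_len(nrow(anchors)), function(i) {
    exp(log(anchors[i, 1]) + frac * (log(anchors[i, 2]) - log(anchors[i, 1])))
  }, numeric(length(depths_m))))
  dimnames(out) <- list(rownames(anchors), as.character(depths_m))
  out
}

# Planted prophage:capsid ratio per depth: flat at the surface and DCM, a
# half-way ramp at 200 m, and fold x surface from 500 m down.
planted_ratio_profile <- function(config) {
  d <- config$depths_m
  r0 <- config$surface_ratio
  fold <- config$lysogeny_fold
  r <- ifelse(d <= 125, r0, ifelse(d <= 200, r0 * (1 + fold) / 2, r0 * fold))
  names(r) <- as.character(d)
  r
}

# Mean single-copy (cellular) coverage per depth; declines with depth like
# cell abundance.
single_copy_profile <- function(depths_m) {
  s <- 50 * (depths_m / min(depths_m))^-0.25
  names(s) <- as.character(depths_m)
  s
}

# mean-preserving lognormal multipliers
rlnorm_mean1 <- function(n, sigma) {
  exp(stats::rnorm(n, -sigma^2 / 2, sigma))
}

#' Simulated per-base depth vector with a conserved-gene coverage spike
#'
#' Draws per-base depths as independent Poisson(`base_lambda`) and overlays a
#' contiguous block of `floor(spike_fraction * length)` positions whose mean
#' depth is `spike_multiplier * base_lambda` — the signature of a conserved
#' gene attracting reads from related phages. The spike must stay below half
#' the contig so that the middle quartiles remain spike-free.
#'
#' @param length Contig length (bp, >= 1).
#' @param base_lambda Background per-base depth rate.
#' @param spike_fraction Fraction of positions inside the spike (< 0.5).
#' @param spike_multiplier Depth multiplier inside the spike (>= 1).
#' @param seed Optional seed; the caller's RNG state is restored afterwards.
#' @return Integer vector of per-base depths.
#' @export
generate_spiked_coverage <- function(length, base_lambda, spike_fraction = 0,
                                     spike_multiplier = 1, seed = NULL) {
  if (length < 1) stop("length must be >= 1")
  if (spike_multiplier < 1) stop("spike_multiplier must be >= 1")
  if (spike_fraction < 0) stop("spike_fraction must be nonnegative")
  if (spike_fraction >= 0.5) {
    stop("spike_fraction >= 0.5 would contaminate the middle quartiles")
  }
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  depths <- stats::rpois(length, base_lambda)
  n_spike <- floor(spike_fraction * length)
  if (n_spike > 0) {
    start <- sample.int(length - n_spike + 1, 1)
    depths[start:(start + n_spike - 1)] <-
      stats::rpois(n_spike, spike_multiplier * base_lambda)
  }
  depths
}

# --- internal builders -------------------------------------------------------

sim_samples <- function(config) {
  dates <- seq(as.Date("2010-08-15"), by = 45, length.out = config$n_timepoints)
  grid <- expand.grid(depth_m = config$depths_m, date = dates,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$depth_m, grid$date), ]
  # one depth/date combination missed at sea: 770 m, final occasion
  if (length(config$depths_m) == 7 && config$n_timepoints == 12) {
    grid <- grid[!(grid$depth_m == 770 & grid$date == max(dates)), ]
  }
  data.frame(
    sample_id = sprintf("S%04dm_t%02d", grid$depth_m,
                        match(grid$date, dates)),
    depth_m = grid$depth_m,
    date = grid$date,
    stringsAsFactors = FALSE
  )
}

sim_contigs <- function(config) {
  n <- config$n_contigs
  groups <- sample(names(config$group_weights), n, replace = TRUE,
                   prob = config$group_weights)
  d <- config$depths_m
  idx_of <- function(g) switch(g,
    surface = sample(which(d <= 75), 1),
    DCM = which(d == 125),
    two_hundred = which(d == 200),
    mesopelagic = sample(which(d >= 500), 1),
    sporadic = sample(which(d >= 500), 1))
  home_idx <- vapply(groups, idx_of, integer(1))
  data.frame(
    contig_id = sprintf("AV_%03d", seq_len(n)),
    length = round(stats::runif(n, config$contig_len_range[1],
                                config$contig_len_range[2])),
    virsorter_category = sample(1:6, n, replace = TRUE),
    group = groups,
    home_depth_m = d[home_idx],
    peak_lambda = stats::runif(n, 10, 30),
    stringsAsFactors = FALSE
  )
}

sim_genes <- function(contigs, config) {
  pitch <- config$gene_length + 60
  rows <- lapply(seq_len(nrow(contigs)), function(i) {
    n_g <- max(1L, (contigs$length[i] - 60) %/% pitch)
    start <- (seq_len(n_g) - 1L) * pitch
    data.frame(
      gene_id = sprintf("%s_g%03d", contigs$contig_id[i], seq_len(n_g)),
      contig_id = contigs$contig_id[i],
      start = start,
      end = start + config$gene_length,
      strand = sample(c("+", "-"), n_g, replace = TRUE),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

# Expected coverage rate of each contig at each depth (before temporal noise).
contig_depth_lambda <- function(contigs, config) {
  d <- config$depths_m
  lam <- matrix(0, nrow(contigs), length(d),
                dimnames = list(contigs$contig_id, as.character(d)))
  for (i in seq_len(nrow(contigs))) {
    di <- match(contigs$home_depth_m[i], d)
    prof <- contigs$peak_lambda[i] * exp(-((seq_along(d) - di) / 0.75)^2)
    prof[prof < config$detection_floor] <- 0
    lam[i, ] <- prof
  }
  lam
}

sim_coverage <- function(contigs, samples, config) {
  lam_depth <- contig_depth_lambda(contigs, config)
  w <- config$coverage_window
  acc <- vector("list", nrow(contigs) * nrow(samples))
  k <- 0
  sporadic_active <- lapply(seq_len(nrow(contigs)), function(i) {
    if (contigs$group[i] == "sporadic") {
      sort(sample.int(config$n_timepoints, sample(2:4, 1)))
    } else NULL
  })
  tp_of <- as.integer(sub(".*_t", "", samples$sample_id))
  for (i in seq_len(nrow(contigs))) {
    sig <- config$sigma_log[[contigs$group[i]]]
    for (j in seq_len(nrow(samples))) {
      base <- lam_depth[i, as.character(samples$depth_m[j])]
      if (contigs$group[i] == "sporadic") {
        base <- if (samples$depth_m[j] == contigs$home_depth_m[i] &&
                    tp_of[j] %in% sporadic_active[[i]]) {
          2 * contigs$peak_lambda[i]
        } else 0
      }
      lam <- base * rlnorm_mean1(1, sig)
      if (lam < config$detection_floor) next
      len <- contigs$length[i]
      n_win <- ceiling(len / w)
      depth <- stats::rpois(n_win, lam)
      n_spike <- floor(config$spike_fraction * n_win)
      if (n_spike > 0) {
        s0 <- sample.int(n_win - n_spike + 1, 1)
        depth[s0:(s0 + n_spike - 1)] <-
          stats::rpois(n_spike, lam * config$spike_multiplier)
      }
      run_length <- rep.int(w, n_win)
      run_length[n_win] <- len - (n_win - 1L) * w
      k <- k + 1
      acc[[k]] <- list(contig_id = contigs$contig_id[i],
                       sample_id = samples$sample_id[j],
                       run_start = c(0L, cumsum(run_length[-n_win])) + 1L,
                       run_length = run_length, depth = depth)
    }
  }
  acc <- acc[seq_len(k)]
  data.frame(
    contig_id = rep(vapply(acc, `[[`, "", "contig_id"),
                    vapply(acc, function(x) length(x$depth), 0L)),
    sample_id = rep(vapply(acc, `[[`, "", "sample_id"),
                    vapply(acc, function(x) length(x$depth), 0L)),
    run_start = unlist(lapply(acc, `[[`, "run_start")),
    run_length = unlist(lapply(acc, `[[`, "run_length")),
    depth = unlist(lapply(acc, `[[`, "depth")),
    stringsAsFactors = FALSE
  )
}

sim_contaminants <- function(config, samples) {
  n <- config$contaminant_count
  if (n == 0) {
    return(list(contigs = NULL, genes = NULL, domain_hits = NULL))
  }
  contigs <- data.frame(
    contig_id = sprintf("CELL_%02d", seq_len(n)),
    length = round(stats::runif(n, 25000, 60000)),
    virsorter_category = sample(3:6, n, replace = TRUE),
    group = "contaminant", home_depth_m = NA_real_, peak_lambda = 2,
    stringsAsFactors = FALSE
  )
  genes <- data.frame(
    gene_id = sprintf("%s_g%03d", rep(contigs$contig_id, each = 3), 1:3),
    contig_id = rep(contigs$contig_id, each = 3),
    start = rep(c(0L, 1000L, 2000L), n),
    end = rep(c(900L, 1900L, 2900L), n),
    strand = "+", stringsAsFactors = FALSE
  )
  ribo <- default_marker_set()
  ribo <- ribo$family[ribo$ribosomal]
  first_gene <- genes$gene_id[seq(1, by = 3, length.out = n)]
  second_gene <- genes$gene_id[seq(2, by = 3, length.out = n)]
  domain_hits <- rbind(
    # a weak, spurious structural call keeps them past the structural stage,
    # so removal is up to the contamination screen
    data.frame(gene_id = second_gene, family = "tail",
               bit_score = stats::runif(n, 10.5, 14), stringsAsFactors = FALSE),
    data.frame(gene_id = first_gene,
               family = sample(ribo, n, replace = TRUE),
               bit_score = stats::runif(n, 60, 120), stringsAsFactors = FALSE)
  )
  list(contigs = contigs, genes = genes, domain_hits = domain_hits)
}

sim_viral_domain_hits <- function(contigs, genes, config) {
  acc <- list()
  for (i in seq_len(nrow(contigs))) {
    g <- genes$gene_id[genes$contig_id == contigs$contig_id[i]]
    n_str <- min(length(g), sample(1:3, 1))
    pick <- sample(g, n_str)
    acc[[length(acc) + 1]] <- data.frame(
      gene_id = pick,
      family = sample(structural_families(), n_str, replace = TRUE),
      bit_score = stats::runif(n_str, 15, 120), stringsAsFactors = FALSE
    )
  }
  do.call(rbind, acc)
}

sim_prophage_flags <- function(contigs, genes, config) {
  flag_prob <- c(surface = 0.1, DCM = 0.2, two_hundred = 0.3,
                 mesopelagic = 0.6, sporadic = 0.4)
  flagged <- stats::runif(nrow(contigs)) < flag_prob[contigs$group]
  fams <- c(marker_catalog()$prophage, marker_catalog()$flag_only)
  acc <- list()
  for (i in which(flagged)) {
    g <- genes$gene_id[genes$contig_id == contigs$contig_id[i]]
    acc[[length(acc) + 1]] <- data.frame(
      gene_id = sample(g, 1), family = sample(fams, 1),
      bit_score = stats::runif(1, 31, 90), stringsAsFactors = FALSE
    )
  }
  list(hits = if (length(acc)) do.call(rbind, acc) else NULL,
       flagged = contigs$contig_id[flagged])
}

sim_ref_hits <- function(contigs, genes, config) {
  cats <- sample(names(config$class_weights), nrow(contigs), replace = TRUE,
                 prob = config$class_weights)
  viromes <- c("uvMED", "uvDeep", "GOV", "EV")
  acc <- list()
  truth_cat <- character(nrow(contigs))
  for (i in seq_len(nrow(contigs))) {
    g <- genes$gene_id[genes$contig_id == contigs$contig_id[i]]
    n_g <- length(g)
    if (cats[i] == "refseq") {
      ref <- sprintf("RS_%03d", sample.int(200, 1)); db <- "refseq75"
      truth_cat[i] <- "refseq_phage"
    } else if (cats[i] == "virome") {
      db <- sample(viromes, 1)
      ref <- sprintf("VR_%s_%03d", db, sample.int(200, 1))
      truth_cat[i] <- paste0("virome:", db)
    } else {
      truth_cat[i] <- "novel"
    }
    if (cats[i] != "novel") {
      n_hit <- max(ceiling(0.6 * n_g),
                   round(stats::runif(1, 0.6, 0.85) * n_g))
      pick <- sample(g, min(n_hit, n_g))
      acc[[length(acc) + 1]] <- data.frame(
        gene_id = pick, reference_id = ref, database = db,
        aai_percent = stats::runif(length(pick), 65, 95),
        bit_score = stats::runif(length(pick), 60, 200),
        stringsAsFactors = FALSE
      )
    } else if (stats::runif(1) < 0.5 && n_g >= 2) {
      # sub-threshold homology: fails either the AAI or the fraction rule
      db <- sample(viromes, 1)
      ref <- sprintf("VR_%s_%03d", db, sample.int(200, 1))
      if (stats::runif(1) < 0.5) {
        pick <- sample(g, max(2, ceiling(0.6 * n_g)))
        aai <- stats::runif(length(pick), 30, 55)
      } else {
        pick <- sample(g, max(1, floor(0.3 * n_g)))
        aai <- stats::runif(length(pick), 65, 95)
      }
      acc[[length(acc) + 1]] <- data.frame(
        gene_id = pick, reference_id = ref, database = db,
        aai_percent = aai, bit_score = stats::runif(length(pick), 40, 120),
        stringsAsFactors = FALSE
      )
    }
  }
  list(hits = do.call(rbind, acc), category = truth_cat)
}

sim_amg <- function(contigs, genes, config) {
  n <- config$n_amg
  if (n == 0) return(list(hits = NULL, gene_ids = character()))
  hosts <- sample(contigs$contig_id, min(n, nrow(contigs)), replace = n > nrow(contigs))
  picked <- vapply(seq_len(n), function(k) {
    g <- genes$gene_id[genes$contig_id == hosts[((k - 1) %% length(hosts)) + 1]]
    sample(g, 1)
  }, character(1))
  picked <- unique(picked)
  hits <- data.frame(
    gene_id = picked,
    family = sprintf("simulated novel function %02d", seq_along(picked)),
    bit_score = stats::runif(length(picked), 35, 90),
    stringsAsFactors = FALSE
  )
  # decoys: known label, sub-threshold novel, and a novel hit on a
  # catalog-only gene (no host contig, so no structural colocalization)
  some_genes <- sample(genes$gene_id, 3)
  decoys <- data.frame(
    gene_id = c(some_genes, "cat_orphan_001"),
    family = c("transaldolase", "glycosyltransferase",
               "simulated novel decoy 01", "simulated novel decoy 02"),
    bit_score = c(80, 60, 22, 75),
    stringsAsFactors = FALSE
  )
  list(hits = rbind(hits, decoys), gene_ids = picked)
}

sim_gene_catalog <- function(config, samples) {
  d <- config$depths_m
  n_d <- length(d)
  sc_prof <- single_copy_profile(d)
  ratio <- planted_ratio_profile(config)
  cn <- config$copy_numbers
  cat_def <- marker_catalog()
  marker_counts <- c(integrase = 4, CI_repressor = 5, excisionase = 8,
                     DNA_polymerase = 12, terminase = 6, capsid = 10,
                     tail_fiber = 5)
  # per-depth family coverage totals
  capsid_total <- cn["capsid", ] * sc_prof
  fam_total <- matrix(0, length(marker_counts), n_d,
                      dimnames = list(names(marker_counts), as.character(d)))
  for (fam in cat_def$phage) fam_total[fam, ] <- cn[fam, ] * sc_prof
  pro_share <- c(integrase = 0.3, CI_repressor = 0.3, excisionase = 0.4)
  for (fam in cat_def$prophage) {
    fam_total[fam, ] <- pro_share[[fam]] * ratio * capsid_total
  }
  fam_total["integrase", ] <- fam_total["integrase", ] * config$integrase_boost

  genes <- list(); coverage <- list(); dh <- list()
  for (fam in names(marker_counts)) {
    n_g <- marker_counts[[fam]]
    ids <- sprintf("cat_%s_%02d", fam, seq_len(n_g))
    genes[[fam]] <- data.frame(
      gene_id = ids, viral_best_aai = stats::runif(n_g, 91, 99),
      photosystem_bit = NA_real_, taxon_label = NA_character_,
      role = paste0("marker:", fam), stringsAsFactors = FALSE
    )
    dh[[fam]] <- data.frame(gene_id = ids, family = fam,
                            bit_score = stats::runif(n_g, 60, 150),
                            stringsAsFactors = FALSE)
    per_gene <- fam_total[fam, as.character(samples$depth_m)] / n_g
    cov <- as.vector(outer(rep(1, n_g), per_gene)) *
      rlnorm_mean1(n_g * nrow(samples), config$sigma_log_marker)
    coverage[[fam]] <- data.frame(
      gene_id = rep(ids, times = nrow(samples)),
      sample_id = rep(samples$sample_id, each = n_g),
      coverage = cov, stringsAsFactors = FALSE
    )
  }
  # sub-threshold marker decoys, never detected
  decoy <- data.frame(gene_id = c("cat_decoy_01", "cat_decoy_02"),
                      family = c("integrase", "capsid"),
                      bit_score = c(45, 49.5), stringsAsFactors = FALSE)
  dh[["decoy"]] <- decoy

  # 10 universal single-copy bacterial marker genes
  sc_fams <- sprintf("single_copy_%02d", 1:10)
  sc_cov <- do.call(rbind, lapply(sc_fams, function(f) {
    data.frame(
      family = f, sample_id = samples$sample_id,
      coverage = sc_prof[as.character(samples$depth_m)] *
        rlnorm_mean1(nrow(samples), 0.25),
      stringsAsFactors = FALSE
    )
  }))

  # depth-indicator bulk genes: cellular and phage sides mirror the same
  # depth structure, so sample trees from either partition agree
  mk_bulk <- function(prefix, n, viral, taxa) {
    home <- rep_len(seq_len(n_d), n)
    ids <- sprintf("cat_%s_%03d", prefix, seq_len(n))
    prof <- 20 * exp(-((matrix(seq_len(n_d), n, n_d, byrow = TRUE) - home) /
                         0.75)^2) + 0.2
    cov <- prof[, match(samples$depth_m, d), drop = FALSE] *
      matrix(rlnorm_mean1(n * nrow(samples), 0.3), n)
    list(
      catalog = data.frame(
        gene_id = ids,
        viral_best_aai = if (viral) stats::runif(n, 91, 99)
                         else stats::runif(n, 20, 60),
        photosystem_bit = NA_real_,
        taxon_label = taxa[((home - 1) %% length(taxa)) + 1],
        role = if (viral) "bulk:phage" else "bulk:cell",
        stringsAsFactors = FALSE
      ),
      coverage = data.frame(
        gene_id = rep(ids, times = nrow(samples)),
        sample_id = rep(samples$sample_id, each = n),
        coverage = as.vector(cov), stringsAsFactors = FALSE
      )
    )
  }
  cellb <- mk_bulk("cell", config$n_cell_genes, FALSE,
                   c("Prochlorococcus", "SAR11", "SAR324", "Thaumarchaeota",
                     "Vibrio", NA, NA))
  phageb <- mk_bulk("phage", config$n_phage_genes, TRUE,
                    c("cyanophage", "pelagiphage", "vibriophage",
                      "deep_phage", NA, NA, NA))
  # viral-identified photosystem genes (shallow; excluded from the phage set)
  n_ps <- config$n_photosystem_genes
  ps <- NULL; ps_cov <- NULL
  if (n_ps > 0) {
    ids <- sprintf("cat_photo_%02d", seq_len(n_ps))
    ps <- data.frame(gene_id = ids,
                     viral_best_aai = stats::runif(n_ps, 91, 99),
                     photosystem_bit = stats::runif(n_ps, 35, 80),
                     taxon_label = NA_character_, role = "photosystem",
                     stringsAsFactors = FALSE)
    shallow <- 15 * exp(-(match(samples$depth_m, d) - 1))
    ps_cov <- data.frame(
      gene_id = rep(ids, times = nrow(samples)),
      sample_id = rep(samples$sample_id, each = n_ps),
      coverage = as.vector(outer(rep(1, n_ps), shallow)) *
        rlnorm_mean1(n_ps * nrow(samples), 0.3),
      stringsAsFactors = FALSE
    )
  }
  catalog <- rbind(do.call(rbind, genes), cellb$catalog, phageb$catalog, ps)
  gene_coverage <- rbind(do.call(rbind, coverage), cellb$coverage,
                         phageb$coverage, ps_cov)
  rownames(catalog) <- rownames(gene_coverage) <- NULL
  # implied per-depth copy numbers for every marker family (phage families
  # are planted directly; prophage families follow from the ratio profile)
  cn_truth <- fam_total / matrix(sc_prof, nrow(fam_total), n_d, byrow = TRUE)
  list(catalog = catalog, gene_coverage = gene_coverage,
       single_copy_coverage = sc_cov, domain_hits = do.call(rbind, dh),
       copy_number_truth = cn_truth, ratio_truth = ratio)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a complete synthetic fixture set
#'
#' Builds, deterministically from `config$seed`: the sample frame, viral and
#' contaminant contigs with tiled gene calls, planted reference and domain hit
#' tables, run-length-encoded per-base coverage, the gene-centric catalog with
#' marker and single-copy coverage, and a planted-truth record kept separate
#' from everything the pipeline reads.
#'
#' @param config A [sim_config()].
#' @param sequences Also simulate contig nucleotide sequences (for FASTA
#'   output); skip for speed in purely tabular work.
#' @return A list of class `"fixture_set"`; see the fields written by
#'   [write_fixture()].
#' @export
generate_fixture <- function(config = sim_config(), sequences = TRUE) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(config$seed)

  samples <- sim_samples(config)
  contigs <- sim_contigs(config)
  genes <- sim_genes(contigs, config)
  str_hits <- sim_viral_domain_hits(contigs, genes, config)
  flags <- sim_prophage_flags(contigs, genes, config)
  refs <- sim_ref_hits(contigs, genes, config)
  amg <- sim_amg(contigs, genes, config)
  contam <- sim_contaminants(config, samples)
  cat_part <- sim_gene_catalog(config, samples)

  all_contigs <- rbind(contigs, contam$contigs)
  all_genes <- rbind(genes, contam$genes)
  coverage <- sim_coverage(contigs, samples, config)
  domain_hits <- rbind(str_hits, flags$hits, contam$domain_hits, amg$hits,
                       cat_part$domain_hits)
  rownames(domain_hits) <- NULL

  seqs <- NULL
  if (sequences) {
    seqs <- vapply(all_contigs$length, random_dna, character(1))
    names(seqs) <- all_contigs$contig_id
  }
  truth <- list(
    contigs = data.frame(
      contig_id = all_contigs$contig_id,
      group = all_contigs$group,
      home_depth_m = all_contigs$home_depth_m,
      category = c(refs$category, rep(NA_character_,
                                      nrow(all_contigs) - nrow(contigs))),
      prophage_flagged = all_contigs$contig_id %in% flags$flagged,
      stringsAsFactors = FALSE
    ),
    ratio_by_depth = as.list(cat_part$ratio_truth),
    lysogeny_fold = config$lysogeny_fold,
    copy_numbers = apply(cat_part$copy_number_truth, 1, as.list,
                         simplify = FALSE),
    amg_gene_ids = amg$gene_ids,
    contaminant_ids = if (is.null(contam$contigs)) character()
                      else contam$contigs$contig_id,
    seed = config$seed
  )
  structure(list(
    contigs = all_contigs[, c("contig_id", "length", "virsorter_category")],
    genes = all_genes,
    ref_hits = refs$hits,
    domain_hits = domain_hits,
    coverage = coverage,
    samples = samples,
    gene_catalog = cat_part$catalog[, c("gene_id", "viral_best_aai",
                                        "photosystem_bit", "taxon_label")],
    gene_coverage = cat_part$gene_coverage,
    single_copy_coverage = cat_part$single_copy_coverage,
    sequences = seqs,
    truth = truth,
    config = config
  ), class = "fixture_set")
}

#' @export
print.fixture_set <- function(x, ...) {
  cat("synthetic fixture set:\n")
  cat(sprintf("  %d contigs (%d contaminant), %d genes, %d samples\n",
              nrow(x$contigs), length(x$truth$contaminant_ids),
              nrow(x$genes), nrow(x$samples)))
  cat(sprintf("  %d coverage runs, %d catalog genes, lysogeny fold %g\n",
              nrow(x$coverage), nrow(x$gene_catalog),
              x$truth$lysogeny_fold))
  invisible(x)
}

#' Write a fixture set to disk
#'
#' Emits the files the pipeline consumes — `contigs.fasta`, `genes.gff`
#' (1-based inclusive coordinates), `ref_hits.tsv`, `domain_hits.tsv`,
#' `coverage.tsv` (run-length encoded), `samples.tsv`, `gene_catalog.tsv`,
#' `gene_coverage.tsv`, `single_copy.tsv` — plus `truth.json`, which holds the
#' planted ground truth and is never read by any pipeline stage.
#'
#' @param fixture A [generate_fixture()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE, eol = "\n")
  }
  if (!is.null(fixture$sequences)) {
    seqs <- Biostrings::DNAStringSet(fixture$sequences)
    names(seqs) <- paste0(fixture$contigs$contig_id, " virsorter_category=",
                          fixture$contigs$virsorter_category)
    Biostrings::writeXStringSet(seqs, file.path(dir, "contigs.fasta"))
  }
  g <- fixture$genes
  gff <- data.frame(seqid = g$contig_id, source = "phagedepth_sim",
                    type = "CDS", start = g$start + 1L, end = g$end,
                    score = ".", strand = g$strand, frame = "0",
                    attributes = paste0("ID=", g$gene_id))
  utils::write.table(gff, file.path(dir, "genes.gff"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE,
                     eol = "\n")
  tsv(fixture$ref_hits, "ref_hits.tsv")
  tsv(fixture$domain_hits, "domain_hits.tsv")
  tsv(fixture$coverage, "coverage.tsv")
  s <- fixture$samples
  s$date <- format(s$date, "%Y-%m-%d")
  tsv(s, "samples.tsv")
  tsv(fixture$gene_catalog, "gene_catalog.tsv")
  tsv(fixture$gene_coverage, "gene_coverage.tsv")
  tsv(fixture$single_copy_coverage, "single_copy.tsv")
  jsonlite::write_json(fixture$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(dir)
}

# --- worked-example fixture builders ----------------------------------------
# These rebuild, at full printed size, the filter inputs whose counts the
# curation, partition and AMG worked examples quote; they are deliberately
# tabular-only and fast.

#' Curation worked-example fixture
#'
#' Candidate contigs sized so that `n_ge_20kb` pass the length filter, of
#' which `n_no_structural` carry only sub-threshold or non-structural hits,
#' and `n_ribosomal` short contigs carry a ribosomal marker.
#'
#' @param n_total,n_ge_20kb,n_no_structural,n_ribosomal Planted counts.
#' @param seed Seed.
#' @return List `contigs`, `genes`, `domain_hits`, `truth`.
#' @export
fixture_curation_counts <- function(n_total = 917, n_ge_20kb = 142,
                                    n_no_structural = 13, n_ribosomal = 1,
                                    seed = 1) {
  stopifnot(n_ge_20kb <= n_total, n_no_structural <= n_ge_20kb,
            n_ribosomal <= n_total - n_ge_20kb)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  n_short <- n_total - n_ge_20kb
  contigs <- data.frame(
    contig_id = sprintf("C_%04d", seq_len(n_total)),
    length = round(c(stats::runif(n_ge_20kb, 20000, 108000),
                     stats::runif(n_short, 1700, 19999))),
    virsorter_category = sample(1:6, n_total, replace = TRUE),
    stringsAsFactors = FALSE
  )
  contigs$length[1] <- 20000 # keep the boundary on-grid
  contigs <- contigs[sample.int(n_total), , drop = FALSE]
  genes <- data.frame(
    gene_id = paste0(contigs$contig_id, "_g01"),
    contig_id = contigs$contig_id,
    start = 0L, end = 900L, strand = "+", stringsAsFactors = FALSE
  )
  long_ids <- contigs$contig_id[contigs$length >= 20000]
  no_struct <- sample(long_ids, n_no_structural)
  with_struct <- setdiff(contigs$contig_id, no_struct)
  ribo_host <- sample(setdiff(contigs$contig_id, long_ids), n_ribosomal)
  ribo_fams <- default_marker_set()
  ribo_fams <- ribo_fams$family[ribo_fams$ribosomal]
  domain_hits <- rbind(
    data.frame(gene_id = paste0(with_struct, "_g01"),
               family = sample(structural_families(), length(with_struct),
                               replace = TRUE),
               bit_score = stats::runif(length(with_struct), 10.5, 120),
               stringsAsFactors = FALSE),
    data.frame(gene_id = paste0(no_struct, "_g01"),
               family = sample(c(structural_families(), "hypothetical"),
                               length(no_struct), replace = TRUE),
               bit_score = stats::runif(length(no_struct), 1, 10),
               stringsAsFactors = FALSE),
    data.frame(gene_id = paste0(ribo_host, "_g01"),
               family = sample(ribo_fams, n_ribosomal, replace = TRUE),
               bit_score = stats::runif(n_ribosomal, 60, 120),
               stringsAsFactors = FALSE)
  )
  list(contigs = contigs, genes = genes, domain_hits = domain_hits,
       truth = list(n_pass_length = n_ge_20kb,
                    n_fail_structural = n_no_structural,
                    expected_final = n_ge_20kb - n_no_structural))
}

#' Gene-catalog partition worked-example fixture
#'
#' A catalog in which exactly `n_viral` genes carry viral best-hit identity
#' > 90%, `n_photosystem` of those additionally carry a photosystem hit > 30
#' bits, and `n_cell` genes sit below the viral identity cutoff.
#'
#' @param n_viral,n_photosystem,n_cell Planted counts.
#' @param seed Seed.
#' @return A gene catalog data frame.
#' @export
fixture_catalog_counts <- function(n_viral = 177713, n_photosystem = 5328,
                                   n_cell = 25000, seed = 1) {
  stopifnot(n_photosystem <= n_viral)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  n <- n_viral + n_cell
  catalog <- data.frame(
    gene_id = sprintf("g%07d", seq_len(n)),
    viral_best_aai = c(stats::runif(n_viral, 90.01, 100),
                       stats::runif(n_cell, 10, 90)),
    photosystem_bit = NA_real_,
    stringsAsFactors = FALSE
  )
  ps <- sample.int(n_viral, n_photosystem)
  catalog$photosystem_bit[ps] <- stats::runif(n_photosystem, 30.5, 200)
  # photosystem hits below the bit cutoff must NOT remove genes
  sub <- sample(setdiff(seq_len(n_viral), ps), min(500, n_viral))
  catalog$photosystem_bit[sub] <- stats::runif(length(sub), 1, 30)
  catalog[sample.int(n), , drop = FALSE]
}

#' AMG colocalization worked-example fixture
#'
#' `n_contigs` contigs of which `n_structural` carry a structural hit > 10
#' bits; exactly `n_candidates` genes on structural contigs carry
#' novel-function hits > 30 bits. Decoys include novel-function hits on
#' non-structural contigs, known-function hits, and sub-threshold hits.
#'
#' @param n_contigs,n_structural,n_candidates Planted counts.
#' @param seed Seed.
#' @return List `genes`, `domain_hits`, `truth`.
#' @export
fixture_amg_counts <- function(n_contigs = 917, n_structural = 625,
                               n_candidates = 37, seed = 1) {
  stopifnot(n_structural <= n_contigs, n_candidates <= n_structural)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  contig_ids <- sprintf("V_%04d", seq_len(n_contigs))
  struct_ids <- sample(contig_ids, n_structural)
  plain_ids <- setdiff(contig_ids, struct_ids)
  # two genes per contig: one structural slot, one functional slot
  genes <- data.frame(
    gene_id = c(paste0(contig_ids, "_gA"), paste0(contig_ids, "_gB")),
    contig_id = rep(contig_ids, 2),
    start = rep(c(0L, 1000L), each = n_contigs),
    end = rep(c(900L, 1900L), each = n_contigs),
    strand = "+", stringsAsFactors = FALSE
  )
  cand_host <- sample(struct_ids, n_candidates)
  n_decoy <- min(20, length(plain_ids))
  decoy_host <- sample(plain_ids, n_decoy)
  known_host <- sample(setdiff(struct_ids, cand_host), 15)
  sub_host <- sample(setdiff(struct_ids, c(cand_host, known_host)), 20)
  domain_hits <- rbind(
    data.frame(gene_id = paste0(struct_ids, "_gA"),
               family = sample(structural_families(), n_structural,
                               replace = TRUE),
               bit_score = stats::runif(n_structural, 10.5, 120),
               stringsAsFactors = FALSE),
    # non-structural contigs still get sub-threshold structural noise
    data.frame(gene_id = paste0(plain_ids, "_gA"),
               family = sample(structural_families(), length(plain_ids),
                               replace = TRUE),
               bit_score = stats::runif(length(plain_ids), 1, 10),
               stringsAsFactors = FALSE),
    data.frame(gene_id = paste0(cand_host, "_gB"),
               family = sprintf("simulated novel function %03d",
                                seq_len(n_candidates)),
               bit_score = stats::runif(n_candidates, 30.5, 120),
               stringsAsFactors = FALSE),
    data.frame(gene_id = paste0(decoy_host, "_gB"),
               family = sprintf("simulated novel offsite %03d",
                                seq_len(n_decoy)),
               bit_score = stats::runif(n_decoy, 30.5, 120),
               stringsAsFactors = FALSE),
    data.frame(gene_id = paste0(known_host, "_gB"),
               family = sample(known_amg_functions(), 15),
               bit_score = stats::runif(15, 40, 150),
               stringsAsFactors = FALSE),
    data.frame(gene_id = paste0(sub_host, "_gB"),
               family = sprintf("simulated novel weak %03d", 1:20),
               bit_score = stats::runif(20, 5, 30),
               stringsAsFactors = FALSE)
  )
  list(genes = genes, domain_hits = domain_hits,
       truth = list(candidate_gene_ids = sort(paste0(cand_host, "_gB")),
                    n_candidates = n_candidates))
}

#' Classification worked-example fixture
#'
#' Plants reference hit tables so that exactly `n_refseq`, `n_virome` and
#' `n_novel` contigs carry the corresponding homology labels, with margins
#' comfortably past the >50% gene-fraction and >60% AAI rules, so a correct
#' classifier must recover the planted labels exactly.
#'
#' @param n_refseq,n_virome,n_novel Planted counts per category.
#' @param genes_per_contig Genes per contig.
#' @param seed Seed.
#' @return List `genes`, `ref_hits`, `truth` (planted label per contig).
#' @export
fixture_classification_counts <- function(n_refseq = 10, n_virome = 40,
                                          n_novel = 79, genes_per_contig = 10,
                                          seed = 1) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  n <- n_refseq + n_virome + n_novel
  contig_ids <- sprintf("K_%03d", seq_len(n))
  genes <- data.frame(
    gene_id = sprintf("%s_g%02d", rep(contig_ids, each = genes_per_contig),
                      seq_len(genes_per_contig)),
    contig_id = rep(contig_ids, each = genes_per_contig),
    stringsAsFactors = FALSE
  )
  viromes <- c("uvMED", "uvDeep", "GOV", "EV")
  label <- c(rep("refseq_phage", n_refseq),
             paste0("virome:", sample(viromes, n_virome, replace = TRUE)),
             rep("novel", n_novel))
  acc <- list()
  for (i in seq_len(n)) {
    g <- genes$gene_id[genes$contig_id == contig_ids[i]]
    if (label[i] == "novel") next
    db <- if (label[i] == "refseq_phage") "refseq75" else sub("virome:", "", label[i])
    ref <- sprintf("%s_ref_%03d", db, i)
    n_hit <- ceiling(0.7 * length(g))
    acc[[length(acc) + 1]] <- data.frame(
      gene_id = sample(g, n_hit), reference_id = ref, database = db,
      aai_percent = stats::runif(n_hit, 70, 95),
      bit_score = stats::runif(n_hit, 80, 200), stringsAsFactors = FALSE
    )
  }
  list(genes = genes, ref_hits = do.call(rbind, acc),
       truth = data.frame(contig_id = contig_ids, category = label,
                          stringsAsFactors = FALSE))
}
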