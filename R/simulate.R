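#' Configuration for the synthetic around-the-clock ChIP-seq world
#'
#' Describes a toy genome with planted rhythmic binding sites, matched
#' input libraries, motif embeddings and a clustered rhythmic expression
#' matrix. All randomness derives from `seed`; the same config yields
#' byte-identical fixtures.
#'
#' Defaults state a desk-scale world mirroring the assumed data: a 2-Mb
#' genome (one chromosome pure background), 50 sites, 7 libraries at 4-h
#' spacing (ZT02..ZT26), fragment 190 nt / read 80 nt, ~5e5 background
#' tags per library. Site enrichment folds are log-uniform on
#' `fold_range` (strong sites, as expected above a four-fold calling
#' floor), relative amplitudes uniform on `amp_range`, binding phases
#' wrapped-normal around ZT16 (binding maximal at ZT14-18).
#'
#' @param seed master RNG seed
#' @param chrom_lengths named vector of chromosome lengths (nt)
#' @param background_chroms chromosomes that receive no sites
#' @param n_sites planted binding sites
#' @param time_points library ZT times (hours)
#' @param fragment_size,read_length library metadata (nt)
#' @param depth expected background tags per library
#' @param fold_range log-uniform enrichment-fold range over local background
#' @param amp_range relative-amplitude range, in [0, 1]
#' @param phase_mean,phase_sd binding-phase distribution (hours)
#' @param multimap_frac fraction of background reads mapped at 2 positions
#' @param jitter_sd tag-placement jitter sd (nt); default fragment_size/4
#'   produces refined peaks of roughly 200 nt
#' @param nb_size negative-binomial size for overdispersed tag counts;
#'   NULL (default) = Poisson
#' @param n_genes gene/TSS count
#' @param gene_near_site_prob probability a site gets a TSS within 500 nt
#' @param expr_clusters data.frame name/phase/amplitude/prop describing
#'   expression clusters (NA phase = arrhythmic)
#' @param expr_b0_mean,expr_b0_sd baseline expression level
#' @param expr_noise_sd Gaussian expression noise
#' @param expr_phase_jitter per-gene phase jitter sd (hours)
#' @param batch_offsets additive offsets for batches 1, 2 (default none)
#' @param ko_phase_shift binding phase shift of the KO genotype (hours)
#' @param motif consensus embedded under sites
#' @param motif_fraction fraction of sites with an embedded motif
#' @param bg_motif_rate fraction of background TSS windows with the motif
#' @return object of class `sim_config`
#' @export
sim_config <- function(seed = 1L,
                       chrom_lengths = c(chr1 = 5e5, chr2 = 5e5,
                                         chr3 = 5e5, chrBg = 5e5),
                       background_chroms = "chrBg",
                       n_sites = 50L,
                       time_points = c(2, 6, 10, 14, 18, 22, 26),
                       fragment_size = 190L, read_length = 80L,
                       depth = 5e5,
                       fold_range = c(6, 32), amp_range = c(0.3, 0.8),
                       phase_mean = 16, phase_sd = 2,
                       multimap_frac = 0.02,
                       jitter_sd = NULL, nb_size = NULL,
                       n_genes = 300L, gene_near_site_prob = 0.7,
                       expr_clusters = data.frame(
                         name = c("A1", "A2", "A3", "flat"),
                         phase = c(16, 20, 0, NA),
                         amplitude = c(1, 1, 1, 0.05),
                         prop = c(0.3, 0.25, 0.25, 0.2)),
                       expr_b0_mean = 8, expr_b0_sd = 1,
                       expr_noise_sd = 0.2, expr_phase_jitter = 0.5,
                       batch_offsets = c(0, 0),
                       ko_phase_shift = 4,
                       motif = "ATCACCCCAC", motif_fraction = 0.6,
                       bg_motif_rate = 0.05) {
  stopifnot(all(chrom_lengths > 0), n_sites >= 0, depth >= 0,
            all(amp_range >= 0), all(amp_range <= 1),
            abs(sum(expr_clusters$prop) - 1) < 1e-9)
  cfg <- list(seed = as.integer(seed), chrom_lengths = chrom_lengths,
              background_chroms = background_chroms, n_sites = as.integer(n_sites),
              time_points = time_points, fragment_size = as.integer(fragment_size),
              read_length = as.integer(read_length), depth = depth,
              fold_range = fold_range, amp_range = amp_range,
              phase_mean = phase_mean, phase_sd = phase_sd,
              multimap_frac = multimap_frac,
              jitter_sd = jitter_sd %||% (fragment_size / 4),
              nb_size = nb_size, n_genes = as.integer(n_genes),
              gene_near_site_prob = gene_near_site_prob,
              expr_clusters = expr_clusters,
              expr_b0_mean = expr_b0_mean, expr_b0_sd = expr_b0_sd,
              expr_noise_sd = expr_noise_sd,
              expr_phase_jitter = expr_phase_jitter,
              batch_offsets = batch_offsets,
              ko_phase_shift = ko_phase_shift,
              motif = motif, motif_fraction = motif_fraction,
              bg_motif_rate = bg_motif_rate)
  structure(cfg, class = "sim_config")
}

#' Ground truth of the synthetic world
#'
#' Deterministically derives (from the config seed alone) the planted
#' site table (center, fold, amplitude, phase, motif flag), the gene/TSS
#' table with expression-cluster assignments, and the motif-embedding
#' positions.
#'
#' @param cfg a `sim_config`
#' @param genotype "WT" or "KO"; KO shifts binding phases by
#'   `ko_phase_shift` hours
#' @return list of class `sim_truth`: sites, genes, embeddings
#' @export
simulate_truth <- function(cfg, genotype = c("WT", "KO")) {
  genotype <- match.arg(genotype)
  set.seed(child_seed(cfg$seed, 1L))
  site_chroms <- setdiff(names(cfg$chrom_lengths), cfg$background_chroms)
  cand <- rbindlist(c(list(data.table(chrom = character(), center = integer())),
                      lapply(site_chroms, function(ch)
    data.table(chrom = ch,
               center = as.integer(seq(5000L, cfg$chrom_lengths[[ch]] - 5000L,
                                       by = 4000L))))))
  stopifnot(nrow(cand) >= cfg$n_sites)
  sites <- cand[sample(.N, cfg$n_sites)]
  if (nrow(sites))
    sites[, center := center + sample(-1000:1000, .N, replace = TRUE)]
  sites[, fold := exp(runif(.N, log(cfg$fold_range[1]), log(cfg$fold_range[2])))]
  sites[, rel_amplitude := runif(.N, cfg$amp_range[1], cfg$amp_range[2])]
  sites[, phase_hours := wrap24(rnorm(.N, cfg$phase_mean, cfg$phase_sd))]
  if (genotype == "KO")
    sites[, phase_hours := wrap24(phase_hours + cfg$ko_phase_shift)]
  sites[, motif_flag := FALSE]
  sites[sample(.N, floor(cfg$motif_fraction * .N)), motif_flag := TRUE]
  sites[, site_id := sprintf("site_%03d", .I)]
  setorder(sites, chrom, center)
  # genes: most sites get a nearby TSS; the rest are background genes
  near <- sites[runif(.N) < cfg$gene_near_site_prob,
                .(chrom, tss = center + sample(-500:500, .N, replace = TRUE))]
  n_bg_genes <- cfg$n_genes - nrow(near)
  probs <- cfg$chrom_lengths / sum(cfg$chrom_lengths)
  bg_ch <- sample(names(cfg$chrom_lengths), n_bg_genes, replace = TRUE,
                  prob = probs)
  bg <- data.table(chrom = bg_ch,
                   tss = vapply(bg_ch, function(ch)
                     sample(2000L:(as.integer(cfg$chrom_lengths[[ch]]) - 2000L), 1L),
                     integer(1)))
  genes <- rbind(near, bg)
  genes[, strand := sample(c("+", "-"), .N, replace = TRUE)]
  genes[, gene := sprintf("gene_%04d", seq_len(.N))]
  cl <- cfg$expr_clusters
  genes[, cluster := sample(cl$name, .N, replace = TRUE, prob = cl$prop)]
  genes[, tss := pmax(0L, pmin(as.integer(tss),
                               as.integer(cfg$chrom_lengths[chrom]) - 1L))]
  # motif embeddings: under flagged sites plus a share of TSS windows
  emb_site <- sites[motif_flag == TRUE,
                    .(chrom, pos = center - 5L + sample(-30:30, .N, replace = TRUE))]
  emb_bg <- genes[runif(.N) < cfg$bg_motif_rate,
                  .(chrom, pos = tss + sample(-200:200, .N, replace = TRUE))]
  embeddings <- rbind(emb_site, emb_bg)
  embeddings[, pos := pmax(0L, pmin(as.integer(pos),
                                    as.integer(cfg$chrom_lengths[chrom]) -
                                      nchar(cfg$motif)))]
  structure(list(sites = sites[], genes = genes[], embeddings = embeddings[],
                 genotype = genotype), class = "sim_truth")
}

#' Random genome sequence with embedded motif instances
#'
#' @param cfg a `sim_config`
#' @param truth output of [simulate_truth()] (recomputed if NULL)
#' @return `Biostrings::DNAStringSet`, one sequence per chromosome
#' @export
simulate_genome <- function(cfg, truth = NULL) {
  truth <- truth %||% simulate_truth(cfg)
  set.seed(child_seed(cfg$seed, 2L))
  motif_chars <- strsplit(cfg$motif, "")[[1]]
  seqs <- lapply(names(cfg$chrom_lengths), function(ch) {
    len <- as.integer(cfg$chrom_lengths[[ch]])
    v <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    emb <- truth$embeddings[chrom == ch]
    for (p in emb$pos) v[(p + 1):(p + length(motif_chars))] <- motif_chars
    paste(v, collapse = "")
  })
  g <- Biostrings::DNAStringSet(unlist(seqs))
  names(g) <- names(cfg$chrom_lengths)
  g
}

site_mu <- function(cfg, truth, t) {
  # expected site tag count: local-background-equivalent rate x fold x cosine
  base <- cfg$depth * 500 / sum(cfg$chrom_lengths)
  base * truth$sites$fold *
    (1 + truth$sites$rel_amplitude *
       cos(2 * pi * (t - truth$sites$phase_hours) / 24))
}

draw_counts <- function(n, lambda, nb_size) {
  if (is.null(nb_size)) rpois(n, lambda)
  else stats::rnbinom(n, size = nb_size, mu = lambda)
}

sim_background_tags <- function(cfg) {
  tot <- sum(cfg$chrom_lengths)
  rbindlist(lapply(names(cfg$chrom_lengths), function(ch) {
    len <- as.numeric(cfg$chrom_lengths[[ch]])
    n <- draw_counts(1L, cfg$depth * len / tot, cfg$nb_size)
    data.table(chrom = ch, pos = as.integer(floor(runif(n, 0, len))),
               strand = sample(c("+", "-"), n, replace = TRUE))
  }))
}

#' Simulate one ChIP library
#'
#' Background tags are uniform; per planted site the expected tag count
#' follows baseline x fold x (1 + rel_amplitude cos(2 pi (t - phase)/24))
#' and is drawn Poisson (or negative binomial). Plus-strand tags sit at
#' center - fragment/2 + jitter, minus-strand tags (leftmost coordinate)
#' at center + fragment/2 - read_length + jitter. A `multimap_frac`
#' share of background reads carries n_hits = 2 with a second alignment
#' at a random position.
#'
#' @param cfg a `sim_config`
#' @param t library time (hours ZT)
#' @param truth ground truth (recomputed if NULL)
#' @return `tag_library` (not deduplicated; see [prepare_library()])
#' @export
simulate_chip_library <- function(cfg, t, truth = NULL) {
  truth <- truth %||% simulate_truth(cfg)
  set.seed(child_seed(cfg$seed, 10L + as.integer(round(t)) +
                        1000L * (truth$genotype == "KO")))
  bg <- sim_background_tags(cfg)
  mu <- site_mu(cfg, truth, t)
  ns <- draw_counts(length(mu), pmax(mu, 0), cfg$nb_size)
  st <- rbindlist(lapply(which(ns > 0), function(i) {
    n <- ns[i]
    strand <- sample(c("+", "-"), n, replace = TRUE)
    jit <- as.integer(round(rnorm(n, 0, cfg$jitter_sd)))
    pos <- ifelse(strand == "+",
                  truth$sites$center[i] - cfg$fragment_size %/% 2L,
                  truth$sites$center[i] + cfg$fragment_size %/% 2L -
                    cfg$read_length) + jit
    data.table(chrom = truth$sites$chrom[i], pos = pos, strand = strand)
  }))
  tags <- if (nrow(st)) rbind(bg, st) else bg
  tags[, pos := pmax(0L, pmin(as.integer(pos),
                              as.integer(cfg$chrom_lengths[chrom]) - 1L))]
  tags[, n_hits := 1L]
  if (cfg$multimap_frac > 0 && nrow(bg) > 0) {
    nm <- rbinom(1L, nrow(bg), cfg$multimap_frac)
    if (nm > 0) {
      idx <- sample(nrow(bg), nm)
      tags[idx, n_hits := 2L]
      extra <- sim_background_tags(cfg)[sample(.N, min(nm, .N))]
      extra[, n_hits := 2L]
      tags <- rbind(tags, extra)
    }
  }
  tags[, weight := 1 / n_hits]
  setorder(tags, chrom, pos, strand)
  tag_library(tags, label = t, avg_fragment_size = cfg$fragment_size,
              read_length = cfg$read_length, dedup = FALSE)
}

#' Simulate one input (control) library
#'
#' Uniform background at matched depth; no site signal.
#'
#' @inheritParams simulate_chip_library
#' @return `tag_library`
#' @export
simulate_input_library <- function(cfg, t, truth = NULL) {
  truth <- truth %||% simulate_truth(cfg)
  set.seed(child_seed(cfg$seed, 40L + as.integer(round(t)) +
                        1000L * (truth$genotype == "KO")))
  tags <- sim_background_tags(cfg)
  tags[, `:=`(n_hits = 1L, weight = 1)]
  setorder(tags, chrom, pos, strand)
  tag_library(tags, label = t, avg_fragment_size = cfg$fragment_size,
              read_length = cfg$read_length, dedup = FALSE)
}

#' Deduplicate and strand-shift a library
#'
#' Applies the standard preprocessing: redundant-tag removal, then the
#' fragment-size shift from the library's own metadata.
#'
#' @param lib a `tag_library`
#' @param shift override the computed shift (optional)
#' @return `tag_library` with shifted, deduplicated tags and updated
#'   `total_nonredundant`
#' @export
prepare_library <- function(lib, shift = NULL) {
  tags <- deduplicate_tags(lib$tags)
  total <- nrow(tags)
  s <- shift %||% compute_shift(lib$avg_fragment_size, lib$read_length)
  tags <- shift_tags(tags, s)
  out <- tag_library(tags, lib$label, lib$avg_fragment_size,
                     lib$read_length, dedup = FALSE)
  out$total_nonredundant <- total
  out
}

#' Simulate a rhythmic expression matrix
#'
#' x_g(t) = b0_g + amp_cluster * cos(2 pi (t - phase_g)/24) +
#' batch_offset + N(0, noise_sd). Batches alternate over columns. In KO
#' mode the rhythmic clusters' phases collapse to the binding phase
#' (`phase_mean`).
#'
#' @param cfg a `sim_config`
#' @param genotype "WT" or "KO"
#' @param truth ground truth (recomputed if NULL; gene table reused)
#' @return list: mat (genes x time), genes (with cluster, phase, b0),
#'   batch (per-column batch index), time_points
#' @export
simulate_expression <- function(cfg, genotype = c("WT", "KO"), truth = NULL) {
  genotype <- match.arg(genotype)
  truth <- truth %||% simulate_truth(cfg)
  set.seed(child_seed(cfg$seed, 70L + (genotype == "KO")))
  genes <- copy(truth$genes)
  cl <- cfg$expr_clusters
  genes[, amp := cl$amplitude[match(cluster, cl$name)]]
  genes[, phase := cl$phase[match(cluster, cl$name)]]
  if (genotype == "KO") genes[!is.na(phase), phase := cfg$phase_mean]
  genes[, phase := wrap24(ifelse(is.na(phase),
                                 runif(.N, 0, 24),
                                 phase + rnorm(.N, 0, cfg$expr_phase_jitter)))]
  genes[, b0 := rnorm(.N, cfg$expr_b0_mean, cfg$expr_b0_sd)]
  tp <- cfg$time_points
  batch <- rep_len(c(1L, 2L), length(tp))
  mat <- sapply(seq_along(tp), function(j)
    genes$b0 + genes$amp * cos(2 * pi * (tp[j] - genes$phase) / 24) +
      cfg$batch_offsets[batch[j]] +
      rnorm(nrow(genes), 0, cfg$expr_noise_sd))
  rownames(mat) <- genes$gene
  colnames(mat) <- sprintf("ZT%02g", tp)
  list(mat = mat, genes = genes[], batch = batch, time_points = tp)
}

#' Simulate the complete in-memory fixture
#'
#' @param cfg a `sim_config`
#' @param genotype "WT" or "KO"
#' @return list: cfg, truth, genome, chip (list of `tag_library`),
#'   input (list), expression
#' @export
simulate_fixture <- function(cfg, genotype = "WT") {
  truth <- simulate_truth(cfg, genotype)
  list(cfg = cfg, truth = truth,
       genome = simulate_genome(cfg, truth),
       chip = lapply(cfg$time_points, simulate_chip_library, cfg = cfg,
                     truth = truth),
       input = lapply(cfg$time_points, simulate_input_library, cfg = cfg,
                      truth = truth),
       expression = simulate_expression(cfg, genotype, truth))
}

#' Write a complete fixture to disk
#'
#' Emits genome.fa, per-library chip_ZT*.bed / input_ZT*.bed tag files,
#' tss.bed, expression.tsv, truth.json and config.json: a self-contained
#' input set for every pipeline stage, byte-identical under the same
#' config.
#'
#' @param cfg a `sim_config`
#' @param outdir output directory (created)
#' @param genotype "WT" or "KO"
#' @return invisibly, the fixture list with a `files` element
#' @export
write_fixture <- function(cfg, outdir, genotype = "WT") {
  fx <- simulate_fixture(cfg, genotype)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- list(genome = file.path(outdir, "genome.fa"),
                tss = file.path(outdir, "tss.bed"),
                expression = file.path(outdir, "expression.tsv"),
                truth = file.path(outdir, "truth.json"),
                config = file.path(outdir, "config.json"))
  Biostrings::writeXStringSet(fx$genome, files$genome)
  g <- fx$truth$genes
  fwrite(g[, .(chrom, start = tss, end = tss + 1L, name = gene, score = 0L,
               strand)], files$tss, sep = "\t", col.names = FALSE)
  em <- data.table(gene = rownames(fx$expression$mat), fx$expression$mat)
  fwrite(em, files$expression, sep = "\t")
  files$chip <- character(); files$input <- character()
  for (i in seq_along(cfg$time_points)) {
    zt <- sprintf("ZT%02g", cfg$time_points[i])
    fc <- file.path(outdir, paste0("chip_", zt, ".bed"))
    fi <- file.path(outdir, paste0("input_", zt, ".bed"))
    write_tags_bed(fx$chip[[i]]$tags, fc)
    write_tags_bed(fx$input[[i]]$tags, fi)
    files$chip <- c(files$chip, fc); files$input <- c(files$input, fi)
  }
  jsonlite::write_json(
    list(sites = fx$truth$sites, genes = fx$truth$genes,
         genotype = genotype,
         batch = fx$expression$batch,
         library_metadata = list(fragment_size = cfg$fragment_size,
                                 read_length = cfg$read_length,
                                 time_points = cfg$time_points)),
    files$truth, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  cfg_out <- unclass(cfg)
  cfg_out$chrom_lengths <- as.list(cfg$chrom_lengths)
  jsonlite::write_json(cfg_out, files$config, auto_unbox = TRUE, digits = NA)
  fx$files <- files
  invisible(fx)
}
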