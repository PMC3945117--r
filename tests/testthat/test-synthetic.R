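test_that("site occupancy follows the cosine program", {
  cfg <- sim_config(seed = 5, chrom_lengths = c(chr1 = 1e5), background_chroms = character(),
                    n_sites = 1L, depth = 2e4, n_genes = 10L,
                    amp_range = c(0, 0), multimap_frac = 0)
  truth <- simulate_truth(cfg)
  site_counts <- sapply(cfg$time_points, function(t) {
    lib <- simulate_chip_library(cfg, t, truth)
    ctr <- truth$sites$center[1]
    nrow(lib$tags[pos > ctr - 400 & pos < ctr + 400]) -
      800 * cfg$depth / 1e5   # subtract expected background
  })
  # rel_amplitude 0: counts flat across time within Poisson fluctuation
  expect_lt(max(abs(site_counts - mean(site_counts))),
            5 * sqrt(mean(site_counts)))
})

test_that("strand modes are separated pre-shift and coincide post-shift", {
  cfg <- sim_config(seed = 6, chrom_lengths = c(chr1 = 1e5), background_chroms = character(),
                    n_sites = 1L, depth = 1e3, fold_range = c(400, 400),
                    n_genes = 5L, multimap_frac = 0)
  truth <- simulate_truth(cfg)
  lib <- simulate_chip_library(cfg, 14, truth)  # near peak time
  ctr <- truth$sites$center[1]
  site <- lib$tags[pos > ctr - 500 & pos < ctr + 500]
  sep <- median(site[strand == "-", pos]) - median(site[strand == "+", pos])
  expect_lt(abs(sep - 110), 12)   # fragment - read_length = 110 nt
  shifted <- shift_tags(site, compute_shift(cfg$fragment_size, cfg$read_length))
  sep2 <- median(shifted[strand == "-", pos]) - median(shifted[strand == "+", pos])
  expect_lt(abs(sep2), 12)
})

test_that("doubling depth doubles mean counts", {
  base <- sim_config(seed = 7, chrom_lengths = c(chr1 = 1e5),
                     background_chroms = "chr1", n_sites = 0L,
                     depth = 2e4, n_genes = 5L, multimap_frac = 0)
  dbl <- sim_config(seed = 7, chrom_lengths = c(chr1 = 1e5),
                    background_chroms = "chr1", n_sites = 0L,
                    depth = 4e4, n_genes = 5L, multimap_frac = 0)
  n1 <- nrow(simulate_chip_library(base, 2)$tags)
  n2 <- nrow(simulate_chip_library(dbl, 2)$tags)
  expect_lt(abs(n2 / n1 - 2), 0.1)
})

test_that("input libraries are flat, reproducible, and empty at depth 0", {
  cfg <- small_cfg()
  inp <- simulate_input_library(cfg, 2)
  tl <- tile_counts(list(inp$tags), 500L, 0L)
  expect_lt(max(tl$n1) / median(tl$n1), 3)
  inp2 <- simulate_input_library(cfg, 2)
  expect_identical(inp$tags, inp2$tags)
  cfg0 <- sim_config(seed = 1, chrom_lengths = c(chr1 = 1e4), depth = 0,
                     n_sites = 0L, background_chroms = "chr1", n_genes = 2L)
  expect_equal(nrow(simulate_input_library(cfg0, 2)$tags), 0)
})

test_that("multi-mapper weights keep per-read contribution at 1", {
  cfg <- sim_config(seed = 8, chrom_lengths = c(chr1 = 1e5),
                    background_chroms = "chr1", n_sites = 0L, depth = 5e3,
                    n_genes = 5L, multimap_frac = 0.2)
  tags <- simulate_chip_library(cfg, 2)$tags
  expect_true(all(tags$weight == 1 / tags$n_hits))
  # total weight ~ number of reads (each read sums to 1)
  n_reads <- sum(tags$weight)
  expect_lt(abs(n_reads / 5e3 - 1), 0.1)
})

test_that("noiseless expression recovers cluster phases exactly", {
  cfg <- sim_config(seed = 10, chrom_lengths = c(chr1 = 1e5),
                    background_chroms = character(), n_sites = 5L,
                    depth = 1e3, n_genes = 40L, expr_noise_sd = 0,
                    expr_phase_jitter = 0)
  ex <- simulate_expression(cfg)
  g <- ex$genes[cluster == "A1"][1]
  f <- fit_cosine(ex$time_points, ex$mat[g$gene, ])
  expect_equal(f$phase_hours, 16, tolerance = 1e-6)
  # 8-h separated clusters are resolved at sigma = 0.2
  cfg2 <- sim_config(seed = 10, chrom_lengths = c(chr1 = 1e5),
                     background_chroms = character(), n_sites = 5L,
                     depth = 1e3, n_genes = 200L, expr_noise_sd = 0.2,
                     expr_phase_jitter = 0)
  ex2 <- simulate_expression(cfg2)
  ph <- function(cl) {
    ids <- ex2$genes[cluster == cl, gene]
    v <- sapply(ids, function(g)
      fit_cosine(ex2$time_points, ex2$mat[g, ])$phase_hours) * 2 * pi / 24
    wrap24(atan2(mean(sin(v)), mean(cos(v))) * 24 / (2 * pi))  # circular mean
  }
  expect_lt(abs(wrap24(ph("A3") - ph("A1"), centered = TRUE) - 8), 1)
})

test_that("KO mode collapses expression phases and shifts binding phases", {
  cfg <- sim_config(seed = 12, expr_noise_sd = 0, expr_phase_jitter = 0)
  ko <- simulate_expression(cfg, "KO")
  phs <- ko$genes[cluster %in% c("A1", "A2", "A3"), unique(phase)]
  expect_true(all(abs(phs - cfg$phase_mean) < 1e-9))
  wt_truth <- simulate_truth(cfg, "WT")
  ko_truth <- simulate_truth(cfg, "KO")
  d <- wrap24(ko_truth$sites$phase_hours - wt_truth$sites$phase_hours,
              centered = TRUE)
  expect_true(all(abs(d - cfg$ko_phase_shift) < 1e-9))
})

test_that("batch offsets enter the stated columns", {
  cfg <- sim_config(seed = 13, chrom_lengths = c(chr1 = 1e5),
                    background_chroms = character(), n_sites = 5L,
                    n_genes = 30L, expr_noise_sd = 0, expr_phase_jitter = 0,
                    batch_offsets = c(0, 1))
  ex <- simulate_expression(cfg)
  g <- ex$genes[cluster == "flat"][1]
  x <- ex$mat[g$gene, ]
  b2 <- ex$batch == 2
  # flat gene: batch-2 columns sit ~1 above batch-1 columns
  expect_equal(mean(x[b2]) - mean(x[!b2]), 1, tolerance = 0.15)
})

test_that("fixtures round-trip through disk byte-identically", {
  cfg <- sim_config(seed = 14, chrom_lengths = c(chr1 = 3e4, chrBg = 2e4),
                    n_sites = 4L, depth = 3e3, n_genes = 20L,
                    time_points = c(2, 14))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  fx1 <- write_fixture(cfg, d1)
  fx2 <- write_fixture(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  # motif embedded under exactly the flagged fraction of sites
  expect_equal(sum(fx1$truth$sites$motif_flag), floor(0.6 * 4))
  genome <- Biostrings::readDNAStringSet(file.path(d1, "genome.fa"))
  m <- motif_model("SRE", consensus = cfg$motif)
  flagged <- fx1$truth$sites[motif_flag == TRUE]
  win <- data.table(chrom = flagged$chrom, start = flagged$center - 100L,
                    end = flagged$center + 100L)
  expect_true(all(region_has_motif(win, scan_motif(genome, m))))
  # tag files round-trip to the in-memory libraries
  back <- read_tags(file.path(d1, "chip_ZT02.bed"))
  orig <- copy(fx1$chip[[1]]$tags)
  setorder(orig, chrom, pos, strand, n_hits)
  expect_equal(back[, .(chrom, pos, strand, weight)],
               orig[, .(chrom, pos, strand, weight)])
})
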