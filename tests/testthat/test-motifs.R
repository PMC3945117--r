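sre <- motif_model("SRE", consensus = "ATCACCCCAC")

test_that("consensus scanning finds exact and reverse-complement matches", {
  hits <- scan_motif(c(a = "ATCACCCCAC"), sre)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 1)
  expect_equal(hits$strand, "+")

  rc <- scan_motif(c(b = paste0("TTTT", "GTGGGGTGAT", "AAAA")), sre)
  expect_equal(rc$strand, "-")
  expect_equal(rc$start, 5)

  expect_equal(nrow(scan_motif(c(n = strrep("N", 40)), sre)), 0)
  expect_error(motif_model("x", consensus = ""), "empty")
})

test_that("degenerate IUPAC letters match their base sets only", {
  m <- motif_model("deg", consensus = "ATCRCCCCAC")
  expect_equal(nrow(scan_motif(c(x = "ATCGCCCCAC"), m)), 1)
  expect_equal(nrow(scan_motif(c(x = "ATCACCCCAC"), m)), 1)
  expect_equal(nrow(scan_motif(c(x = "ATCTCCCCAC"), m)), 0)
})

test_that("scan counts are strand-symmetric", {
  set.seed(19)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
               collapse = "")
    fwd <- nrow(scan_motif(c(x = s), sre))
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    expect_equal(nrow(scan_motif(c(x = rc), sre)), fwd)
  }
})

test_that("PWM scanning calls high-scoring windows on both strands", {
  p <- matrix(0.05, 4, 10, dimnames = list(c("A", "C", "G", "T"), NULL))
  cons <- strsplit("ATCACCCCAC", "")[[1]]
  for (j in 1:10) p[cons[j], j] <- 0.85
  m <- motif_model("pwm", pwm = p, threshold = 0.7)
  hits <- scan_motif(c(x = paste0("GGGG", "ATCACCCCAC", "GGGG")), m)
  expect_equal(hits$start, 5)
  # one mismatching base still above the 70% score fraction
  hits2 <- scan_motif(c(x = paste0("GGGG", "TTCACCCCAC", "GGGG")), m)
  expect_equal(nrow(hits2), 1)
  # reverse complement found on the minus strand
  hits3 <- scan_motif(c(x = paste0("AAAA", "GTGGGGTGAT", "AAAA")), m)
  expect_equal(hits3$strand, "-")
  # N inside the window kills the match
  expect_equal(nrow(scan_motif(c(x = "ATCACNCCAC"), m)), 0)
})

test_that("motif files round-trip consensus and PWM blocks", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("SRE\tATCACCCCAC",
               ">pwm1\t0.9",
               paste(c("A", 0.7, 0.1), collapse = "\t"),
               paste(c("C", 0.1, 0.7), collapse = "\t"),
               paste(c("G", 0.1, 0.1), collapse = "\t"),
               paste(c("T", 0.1, 0.1), collapse = "\t")), f)
  ms <- read_motifs(f)
  expect_named(ms, c("SRE", "pwm1"))
  expect_equal(ms$SRE$consensus, "ATCACCCCAC")
  expect_equal(ms$pwm1$threshold, 0.9)
  expect_equal(ncol(ms$pwm1$pwm), 2)
})

test_that("matched region groups copy peak geometry deterministically", {
  tss <- data.table(gene = sprintf("g%02d", 1:40), chrom = "chr1",
                    tss = seq(10000L, 205000L, by = 5000L),
                    strand = rep(c("+", "-"), 20))
  expr <- setNames(seq_len(40), tss$gene)   # upper half eligible
  peaks <- data.table(chrom = "chr1",
                      start = tss$tss[1:10] - 100L,
                      end = tss$tss[1:10] + 100L)
  g1 <- sample_matched_regions(peaks, tss, expr, n_groups = 5, seed = 42)
  g2 <- sample_matched_regions(peaks, tss, expr, n_groups = 5, seed = 42)
  expect_identical(g1, g2)
  expect_equal(nrow(g1), 50)   # group cardinality = peak count
  # peaks are all length 200 at distance 0: every region is a 200-nt
  # window centered on an eligible (above-median-expression) TSS
  expect_true(all(g1$end - g1$start == 200))
  mids <- (g1$start + g1$end) %/% 2
  eligible <- tss$tss[21:40]
  expect_true(all(mids %in% eligible))
  # sampled lengths follow the peak length distribution
  set.seed(1)
  pk2 <- data.table(chrom = "chr1", start = tss$tss - 100L,
                    end = tss$tss - 100L + sample(c(150L, 300L, 600L), 40,
                                                  replace = TRUE))
  gg <- sample_matched_regions(pk2, tss, expr, n_groups = 50, seed = 7)
  drawn <- gg$end - gg$start
  expect_gt(suppressWarnings(
    ks.test(drawn + runif(length(drawn), -0.4, 0.4),
            (pk2$end - pk2$start) + runif(40, -0.4, 0.4))$p.value), 0.05)
  expect_error(sample_matched_regions(peaks, tss,
                                      setNames(rep(1, 40), tss$gene)),
               "eligible")
})

test_that("empirical p follows the rank rule and is never zero", {
  r <- empirical_enrichment_p(150, rep(100, 1000))
  expect_equal(r$empirical_p, 1 / 1000)
  expect_equal(r$report_string, "<0.001")
  r2 <- empirical_enrichment_p(5, rep(5, 100))
  expect_equal(r2$empirical_p, 1)
  # monotone non-increasing in the observed count
  nulls <- c(1, 5, 9, 3, 7)
  ps <- sapply(0:10, function(o) empirical_enrichment_p(o, nulls)$empirical_p)
  expect_true(all(diff(ps) <= 0))
  expect_true(all(ps > 0))
})

test_that("empirical p is uniform under a continuous null generator", {
  set.seed(55)
  ps <- replicate(400, {
    empirical_enrichment_p(rnorm(1), rnorm(100))$empirical_p
  })
  # chi-square over deciles
  cnt <- table(cut(ps, seq(0, 1, 0.1), include.lowest = TRUE))
  expect_gt(suppressWarnings(chisq.test(cnt)$p.value), 0.01)
})

test_that("motif frequency Fisher test matches the hypergeometric oracle", {
  r <- motif_frequency_test(rep(c("A", "B"), each = 10),
                            c(rep(TRUE, 8), rep(FALSE, 2),
                              rep(TRUE, 2), rep(FALSE, 8)), "A")
  expect_equal(r$p_value, 0.023, tolerance = 0.002)
  expect_equal(r$p_value, oracle_fisher_p(r$table), tolerance = 1e-10)

  same <- motif_frequency_test(rep(c("A", "B"), each = 10),
                               rep(c(TRUE, FALSE), 10), "A")
  expect_equal(same$p_value, 1)

  set.seed(23)
  for (i in 1:200) {
    n1 <- sample(2:30, 1); n2 <- sample(2:30, 1)
    fl <- c(runif(n1) < runif(1), runif(n2) < runif(1))
    lab <- rep(c("A", "B"), c(n1, n2))
    got <- suppressWarnings(motif_frequency_test(lab, fl, "A"))
    if (is.na(got$odds_ratio)) next  # degenerate margin
    expect_equal(got$p_value, oracle_fisher_p(got$table), tolerance = 1e-9)
  }
  expect_warning(
    d <- motif_frequency_test(rep(c("A", "B"), 5), rep(TRUE, 10), "A"),
    "degenerate")
  expect_equal(d$p_value, 1)
  # Haldane correction gives a finite odds ratio with a zero cell
  hz <- motif_frequency_test(rep(c("A", "B"), each = 5),
                             c(rep(TRUE, 5), rep(FALSE, 4), TRUE), "A")
  expect_true(is.finite(hz$odds_ratio))
})

test_that("planted cluster enrichment is detected with good power", {
  set.seed(67)
  hits <- replicate(100, {
    lab <- rep(c("A", "B"), c(20, 40))
    fl <- c(runif(20) < 0.6, runif(40) < 0.2)   # 3x enrichment in A
    motif_frequency_test(lab, fl, "A")$p_value < 0.05
  })
  expect_gte(mean(hits), 0.8)
})
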