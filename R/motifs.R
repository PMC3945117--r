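#' Construct a motif model
#'
#' Either an IUPAC consensus string (degenerate letters allowed) or a
#' position probability matrix with rows A, C, G, T whose columns sum
#' to 1. PWM matches are called where the log-odds score against a
#' uniform background reaches `threshold` times the maximal score.
#'
#' @param name motif name
#' @param consensus IUPAC string, e.g. "ATCACCCCAC"
#' @param pwm 4 x L numeric matrix (rownames A, C, G, T), probabilities
#' @param threshold PWM score fraction in (0, 1] (default 0.8)
#' @return object of class `motif_model`
#' @export
motif_model <- function(name, consensus = NULL, pwm = NULL, threshold = 0.8) {
  if (is.null(consensus) == is.null(pwm))
    stop("give exactly one of consensus or pwm", call. = FALSE)
  if (!is.null(consensus)) {
    consensus <- toupper(consensus)
    if (nchar(consensus) == 0) stop("empty motif", call. = FALSE)
    ok <- strsplit(consensus, "")[[1]] %in% names(Biostrings::IUPAC_CODE_MAP)
    if (!all(ok)) stop("invalid IUPAC letter in consensus", call. = FALSE)
  } else {
    pwm <- as.matrix(pwm)
    if (nrow(pwm) != 4 || ncol(pwm) == 0) stop("pwm must be 4 x L", call. = FALSE)
    rownames(pwm) <- c("A", "C", "G", "T")
    if (any(abs(colSums(pwm) - 1) > 1e-9))
      stop("pwm columns must sum to 1", call. = FALSE)
    if (threshold <= 0 || threshold > 1)
      stop("threshold must be in (0, 1]", call. = FALSE)
  }
  structure(list(name = name, consensus = consensus, pwm = pwm,
                 threshold = threshold), class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  if (!is.null(x$consensus))
    cat(sprintf("motif %s: consensus %s\n", x$name, x$consensus))
  else
    cat(sprintf("motif %s: PWM, %d positions, threshold %.2f\n",
                x$name, ncol(x$pwm), x$threshold))
  invisible(x)
}

#' Read motifs from a simple tab file
#'
#' Two formats per motif: a line `name<TAB>IUPAC` for consensus motifs,
#' or a block starting `>name[<TAB>threshold]` followed by four lines
#' `A/C/G/T<TAB>p1<TAB>p2...` for PWMs.
#'
#' @param path motif file
#' @return list of `motif_model`
#' @export
read_motifs <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list(); i <- 1L
  while (i <= length(lines)) {
    if (startsWith(lines[i], ">")) {
      hdr <- strsplit(sub("^>", "", lines[i]), "\t")[[1]]
      thr <- if (length(hdr) > 1) as.numeric(hdr[2]) else 0.8
      rows <- lapply(lines[i + 1:4], function(l) {
        f <- strsplit(l, "\t")[[1]]
        as.numeric(f[-1])
      })
      pwm <- do.call(rbind, rows)
      out[[length(out) + 1L]] <- motif_model(hdr[1], pwm = pwm, threshold = thr)
      i <- i + 5L
    } else {
      f <- strsplit(lines[i], "\t")[[1]]
      out[[length(out) + 1L]] <- motif_model(f[1], consensus = f[2])
      i <- i + 1L
    }
  }
  names(out) <- vapply(out, `[[`, "", "name")
  out
}

pwm_scan_one <- function(codes, lo, min_score) {
  # codes: integer 1..4 (A,C,G,T), NA for N; lo: 4 x L log-odds
  L <- ncol(lo); n <- length(codes)
  if (n < L) return(integer())
  score <- rep(0, n - L + 1L)
  bad <- rep(FALSE, n - L + 1L)
  for (j in seq_len(L)) {
    v <- codes[j:(n - L + j)]
    bad <- bad | is.na(v)
    vv <- v; vv[is.na(vv)] <- 1L
    score <- score + lo[cbind(vv, j)]
  }
  which(!bad & score >= min_score)
}

#' Scan sequences for a motif on both strands
#'
#' IUPAC mode does exact degenerate matching (an N in the sequence never
#' matches); PWM mode calls windows whose log-odds score against a
#' uniform background is at least threshold x maximal score. Both the
#' motif and its reverse complement are searched.
#'
#' @param seqs `Biostrings::DNAStringSet` or named character vector
#' @param motif a `motif_model`
#' @return data.table of matches: seq (name), start, end (1-based,
#'   inclusive, in sequence coordinates), strand
#' @export
scan_motif <- function(seqs, motif) {
  if (!inherits(seqs, "DNAStringSet"))
    seqs <- Biostrings::DNAStringSet(seqs)
  if (is.null(names(seqs))) names(seqs) <- as.character(seq_along(seqs))
  res <- list()
  if (!is.null(motif$consensus)) {
    pat <- Biostrings::DNAString(motif$consensus)
    for (pp in list(list(p = pat, s = "+"),
                    list(p = Biostrings::reverseComplement(pat), s = "-"))) {
      mm <- Biostrings::vmatchPattern(pp$p, seqs,
                                      fixed = c(pattern = FALSE, subject = TRUE))
      for (i in seq_along(mm)) {
        r <- mm[[i]]
        if (length(r))
          res[[length(res) + 1L]] <- data.table(
            seq = names(seqs)[i], start = IRanges::start(r),
            end = IRanges::end(r), strand = pp$s)
      }
    }
  } else {
    lo <- log2(pmax(motif$pwm, 1e-4) / 0.25)
    min_score <- motif$threshold * sum(apply(lo, 2, max))
    L <- ncol(lo)
    lo_rc <- lo[4:1, L:1, drop = FALSE]
    for (i in seq_along(seqs)) {
      codes <- match(strsplit(as.character(seqs[[i]]), "")[[1]],
                     c("A", "C", "G", "T"))
      for (pp in list(list(m = lo, s = "+"), list(m = lo_rc, s = "-"))) {
        hits <- pwm_scan_one(codes, pp$m, min_score)
        if (length(hits))
          res[[length(res) + 1L]] <- data.table(
            seq = names(seqs)[i], start = hits, end = hits + L - 1L,
            strand = pp$s)
      }
    }
  }
  if (!length(res))
    return(data.table(seq = character(), start = integer(),
                      end = integer(), strand = character()))
  out <- rbindlist(res)
  setorder(out, seq, start, strand)
  out[]
}

#' Flag regions containing at least one motif match
#'
#' Matches are taken from a genome-wide scan and a region is flagged when
#' a match lies fully inside it.
#'
#' @param regions data.table chrom, start, end (0-based half-open)
#' @param matches genome-scan output of [scan_motif()] (seq = chromosome,
#'   1-based inclusive coordinates)
#' @return logical vector, one per region
#' @export
region_has_motif <- function(regions, matches) {
  regions <- as.data.table(regions)
  flags <- rep(FALSE, nrow(regions))
  if (!nrow(matches)) return(flags)
  for (ch in unique(regions$chrom)) {
    rid <- which(regions$chrom == ch)
    mm <- matches[seq == ch]
    if (!nrow(mm)) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(mm$start, mm$end),
      IRanges::IRanges(regions$start[rid] + 1L, regions$end[rid]),
      type = "within")
    flags[rid[unique(S4Vectors::subjectHits(ov))]] <- TRUE
  }
  flags
}

#' Sample random region groups matched to a peak set
#'
#' Each group has the peak set's cardinality; every sampled region copies
#' the (length, signed TSS distance) of one peak, both drawn jointly with
#' replacement, and is anchored at a random TSS of an expressed gene
#' (expression above the `expressed_quantile` of all genes). Regions are
#' clipped to chromosome bounds. Fully reproducible from `seed`.
#'
#' @param peaks data.table chrom, start, end
#' @param tss gene annotation: data.table gene, chrom, tss, strand
#' @param expression named numeric vector of per-gene expression levels
#'   (names matching `tss$gene`); genes without a value are ineligible
#' @param n_groups number of groups (default 1000)
#' @param expressed_quantile eligibility quantile (default 0.5, i.e.
#'   above the median; the discovery stage of the source analysis used
#'   the top decile - set 0.9 for that reading)
#' @param seed RNG seed
#' @param chrom_lengths named vector for clipping (optional)
#' @return data.table: group, chrom, start, end
#' @export
sample_matched_regions <- function(peaks, tss, expression, n_groups = 1000L,
                                   expressed_quantile = 0.5, seed = 1L,
                                   chrom_lengths = NULL) {
  peaks <- as.data.table(peaks)
  tss <- as.data.table(tss)
  stop_if_not_cols(tss, c("gene", "chrom", "tss", "strand"), "tss annotation")
  expr <- expression[tss$gene]
  cut <- quantile(expression, expressed_quantile, na.rm = TRUE)
  elig <- tss[which(!is.na(expr) & expr > cut)]
  if (!nrow(elig)) stop("no eligible TSS above the expression quantile", call. = FALSE)
  pk <- nearest_tss(peaks, tss)
  lens <- peaks$end - peaks$start
  dists <- pk$distance
  usable <- which(!is.na(dists))
  if (!length(usable)) stop("no peak has an assignable TSS distance", call. = FALSE)
  m <- nrow(peaks)
  set.seed(seed)
  total <- n_groups * m
  pick <- sample(usable, total, replace = TRUE)
  anch <- sample(nrow(elig), total, replace = TRUE)
  sgn <- ifelse(elig$strand[anch] == "+", 1L, -1L)
  mid <- elig$tss[anch] + sgn * dists[pick]
  len <- lens[pick]
  start <- as.integer(round(mid - len / 2))
  end <- start + len
  out <- data.table(group = rep(seq_len(n_groups), each = m),
                    chrom = elig$chrom[anch], start = start, end = end)
  out[, start := pmax(0L, start)]
  if (!is.null(chrom_lengths))
    out[, end := pmin(as.integer(chrom_lengths[chrom]), end)]
  out[, end := pmax(end, start + 1L)]
  out[]
}

#' Empirical enrichment p-value against matched-group null counts
#'
#' p = #(null >= observed) / n_groups; when no null group reaches the
#' observed count the result is reported as "< 1/n_groups" and the bound
#' 1/n_groups is stored (the p-value is never zero).
#'
#' @param observed observed count of motif-bearing regions
#' @param null_counts numeric vector of per-group null counts
#' @return object of class `motif_enrichment`: observed, null_counts,
#'   n_groups, empirical_p, report_string
#' @export
empirical_enrichment_p <- function(observed, null_counts) {
  n <- length(null_counts)
  stopifnot(n >= 1)
  k <- sum(null_counts >= observed)
  if (k == 0) {
    p <- 1 / n
    rep_str <- paste0("<", format(1 / n, scientific = FALSE, trim = TRUE))
  } else {
    p <- k / n
    rep_str <- format(p, scientific = FALSE, trim = TRUE)
  }
  structure(list(observed = observed, null_counts = null_counts,
                 n_groups = n, empirical_p = p, report_string = rep_str),
            class = "motif_enrichment")
}

#' @export
print.motif_enrichment <- function(x, ...) {
  cat(sprintf("motif enrichment: observed %g vs %d matched groups (null max %g), empirical p %s\n",
              x$observed, x$n_groups, max(x$null_counts), x$report_string))
  invisible(x)
}

#' Motif enrichment of a peak set against matched random regions
#'
#' Scans the genome once for the motif, counts peaks bearing at least one
#' match, samples `n_groups` matched random region groups and computes
#' the empirical enrichment p-value.
#'
#' @param genome `DNAStringSet` (names = chromosomes)
#' @param peaks data.table chrom, start, end
#' @param tss gene annotation (gene, chrom, tss, strand)
#' @param expression named per-gene expression vector
#' @param motif `motif_model`
#' @inheritParams sample_matched_regions
#' @return `motif_enrichment` object, with the per-peak flags in
#'   `$peak_flags` and the genome matches in `$matches`
#' @export
motif_enrichment <- function(genome, peaks, tss, expression, motif,
                             n_groups = 1000L, expressed_quantile = 0.5,
                             seed = 1L) {
  matches <- scan_motif(genome, motif)
  flags <- region_has_motif(peaks, matches)
  groups <- sample_matched_regions(
    peaks, tss, expression, n_groups = n_groups,
    expressed_quantile = expressed_quantile, seed = seed,
    chrom_lengths = setNames(Biostrings::width(genome), names(genome)))
  gflags <- region_has_motif(groups, matches)
  null_counts <- as.numeric(tapply(gflags, groups$group, sum))
  res <- empirical_enrichment_p(sum(flags), null_counts)
  res$peak_flags <- flags
  res$matches <- matches
  res
}

#' Fisher test of motif frequency in one profile cluster vs the rest
#'
#' Builds the 2x2 table (focal cluster vs others) x (motif vs no motif)
#' and returns the two-sided Fisher exact p (hypergeometric sum) with a
#' Haldane-corrected odds ratio when a cell is empty.
#'
#' @param cluster_labels vector of cluster labels, one per region
#' @param match_flags logical motif flags, one per region
#' @param focal_cluster label of the cluster tested for enrichment
#' @return list: table (2x2), odds_ratio, p_value
#' @export
motif_frequency_test <- function(cluster_labels, match_flags, focal_cluster) {
  stopifnot(length(cluster_labels) == length(match_flags))
  if (length(unique(cluster_labels)) < 2)
    stop("need at least 2 clusters", call. = FALSE)
  focal <- cluster_labels == focal_cluster
  tab <- matrix(c(sum(focal & match_flags), sum(focal & !match_flags),
                  sum(!focal & match_flags), sum(!focal & !match_flags)),
                2, 2, byrow = TRUE,
                dimnames = list(c("focal", "rest"), c("motif", "no_motif")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("degenerate 2x2 table (empty margin); p = 1")
    return(list(table = tab, odds_ratio = NA_real_, p_value = 1))
  }
  p <- fisher.test(tab)$p.value
  h <- if (any(tab == 0)) 0.5 else 0
  or <- ((tab[1, 1] + h) * (tab[2, 2] + h)) /
    ((tab[1, 2] + h) * (tab[2, 1] + h))
  list(table = tab, odds_ratio = or, p_value = p)
}
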