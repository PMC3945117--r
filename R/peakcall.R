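#' Tile shifted tags into fixed-size blocks
#'
#' The genome is fragmented per chromosome into `block_size`-nt blocks
#' starting at `offset`; each tag is assigned to exactly one block by its
#' (shifted) position and weighted counts are accumulated per time point.
#'
#' @param tags_by_time list of tag tables (or `tag_library` objects), one
#'   per time point, already strand-shifted
#' @param block_size block length in nt (default 500)
#' @param offset tiling origin, normally 0 or block_size/2
#' @return data.table with chrom, start, end and one count column
#'   `n1..nT` per time point; blocks with no tags are absent (count 0)
#' @export
tile_counts <- function(tags_by_time, block_size = 500L, offset = 0L) {
  block_size <- as.integer(block_size); offset <- as.integer(offset)
  stopifnot(block_size > 0)
  tabs <- lapply(tags_by_time, function(x) if (inherits(x, "tag_library")) x$tags else as.data.table(x))
  out <- NULL
  for (i in seq_along(tabs)) {
    dt <- tabs[[i]]
    agg <- dt[, .(cnt = sum(weight)),
              by = .(chrom, start = offset + ((pos - offset) %/% block_size) * block_size)]
    setnames(agg, "cnt", paste0("n", i))
    out <- if (is.null(out)) agg else
      merge(out, agg, by = c("chrom", "start"), all = TRUE)
  }
  for (j in grep("^n[0-9]+$", names(out), value = TRUE))
    set(out, which(is.na(out[[j]])), j, 0)
  out[, end := start + block_size]
  setcolorder(out, c("chrom", "start", "end"))
  setorder(out, chrom, start)
  out[]
}

#' Select ChIP-enriched blocks against input
#'
#' Blocks passing a raw-count floor in at least one ChIP time point are
#' log2(x + pseudo) transformed, quantile normalized, and kept when the
#' normalized ChIP minus input difference exceeds `log2_threshold` at one
#' or more time points (i.e. at least a four-fold enrichment when the
#' threshold is 2).
#'
#' @param chip_tiles,input_tiles outputs of [tile_counts()] on the same
#'   tiling for the ChIP and input libraries (same number of time points)
#' @param min_signal raw weighted-count floor applied to ChIP before any
#'   transform (default 40)
#' @param pseudo pseudo-count added before the log (default 1)
#' @param log2_threshold minimum normalized log2 ChIP - input difference
#'   (default 2)
#' @param qn_group `"experiment"` quantile-normalizes the ChIP columns as
#'   one group and the input columns as another, preserving the
#'   ChIP/input scale so the threshold keeps its fold-change meaning;
#'   `"joint"` normalizes all columns together.
#' @return data.table of passing blocks (chrom, start, end) with the
#'   per-time normalized differences as columns `d1..dT`
#' @export
select_blocks <- function(chip_tiles, input_tiles, min_signal = 40,
                          pseudo = 1, log2_threshold = 2,
                          qn_group = c("experiment", "joint")) {
  qn_group <- match.arg(qn_group)
  cn <- grep("^n[0-9]+$", names(chip_tiles), value = TRUE)
  stopifnot(length(cn) >= 1,
            identical(cn, grep("^n[0-9]+$", names(input_tiles), value = TRUE)))
  m <- merge(chip_tiles, input_tiles, by = c("chrom", "start", "end"),
             all = TRUE, suffixes = c(".chip", ".input"))
  for (j in setdiff(names(m), c("chrom", "start", "end")))
    set(m, which(is.na(m[[j]])), j, 0)
  chip <- as.matrix(m[, paste0(cn, ".chip"), with = FALSE])
  keep <- apply(chip, 1, max) >= min_signal
  if (sum(keep) < 2) {
    warning("fewer than 2 blocks pass the raw-count floor; no blocks selected")
    return(m[0, .(chrom, start, end)])
  }
  m <- m[keep]
  chip <- log2(chip[keep, , drop = FALSE] + pseudo)
  inp <- log2(as.matrix(m[, paste0(cn, ".input"), with = FALSE]) + pseudo)
  if (qn_group == "joint") {
    q <- limma::normalizeQuantiles(cbind(chip, inp), ties = TRUE)
    chip <- q[, seq_along(cn), drop = FALSE]
    inp <- q[, length(cn) + seq_along(cn), drop = FALSE]
  } else {
    chip <- limma::normalizeQuantiles(chip, ties = TRUE)
    inp <- limma::normalizeQuantiles(inp, ties = TRUE)
  }
  d <- chip - inp
  pass <- apply(d, 1, max) > log2_threshold
  out <- m[pass, .(chrom, start, end)]
  dmat <- as.data.table(d[pass, , drop = FALSE])
  setnames(dmat, paste0("d", seq_along(cn)))
  cbind(out, dmat)
}

#' Merge passing blocks from the two half-offset tilings
#'
#' Overlapping or book-ended passing blocks from both tilings are merged
#' into maximal regions.
#'
#' @param pass0,pass_half passing-block tables (need chrom, start, end)
#' @return data.table of merged regions (chrom, start, end)
#' @export
merge_offset_tilings <- function(pass0, pass_half) {
  both <- rbind(as.data.table(pass0)[, .(chrom, start, end)],
                as.data.table(pass_half)[, .(chrom, start, end)])
  if (nrow(both) == 0) return(both)
  out <- both[, {
    r <- IRanges::reduce(IRanges::IRanges(start + 1L, end))
    .(start = IRanges::start(r) - 1L, end = IRanges::end(r))
  }, by = chrom]
  setorder(out, chrom, start)
  out[]
}

#' Refine a peak region by iterative border trimming
#'
#' Starting from border width `init_border`, the weighted read counts in
#' the left and right border windows of the current interval are compared;
#' the border with fewer counts is discarded if the remaining interval
#' still accounts for at least `retain` of the region's total counts
#' (retention is cumulative, against the original total, so the refined
#' peak always keeps most of the reads). On failure the border width is
#' halved (integer division), stopping below `min_border`.
#'
#' @param start,end region interval, 0-based half-open
#' @param density nonnegative numeric of length end - start: per-base
#'   weighted tag counts pooled over all time points
#' @param init_border starting border width in nt (default 50)
#' @param retain minimum fraction of counts that must survive a trim
#'   (default 0.75)
#' @param min_border smallest border width attempted (default 10)
#' @return list with `start`, `end` (refined interval) and `steps`, a
#'   data.table logging each accepted trim (width, side, retained fraction)
#' @export
refine_peak <- function(start, end, density, init_border = 50L,
                        retain = 0.75, min_border = 10L) {
  stopifnot(length(density) == end - start, all(density >= 0))
  total <- sum(density)
  if (total == 0) {
    warning("region has zero counts; returned unrefined")
    return(list(start = start, end = end,
                steps = data.table(width = integer(), side = character(),
                                   retained = numeric())))
  }
  cs <- cumsum(density)
  lo <- 1L; hi <- length(density)   # current interval in 1-based density idx
  steps <- list()
  w <- as.integer(init_border)
  range_sum <- function(a, b) cs[b] - if (a > 1) cs[a - 1] else 0
  while (w >= min_border) {
    len <- hi - lo + 1L
    if (len <= w) { w <- w %/% 2L; next }
    cur_total <- range_sum(lo, hi)
    left <- range_sum(lo, lo + w - 1L)
    right <- range_sum(hi - w + 1L, hi)
    side <- if (left <= right) "left" else "right"
    cand <- min(left, right)
    if ((cur_total - cand) / total >= retain) {
      if (side == "left") lo <- lo + w else hi <- hi - w
      steps[[length(steps) + 1L]] <-
        data.table(width = w, side = side,
                   retained = (cur_total - cand) / total)
    } else {
      w <- w %/% 2L
    }
  }
  list(start = start + lo - 1L, end = start + hi,
       steps = if (length(steps)) rbindlist(steps) else
         data.table(width = integer(), side = character(), retained = numeric()))
}

#' Per-base pooled tag density over a region
#'
#' @param tags_pooled tag table pooled over time points (shifted)
#' @param chrom,start,end region
#' @return numeric vector of length end - start of weighted counts
#' @export
region_density <- function(tags_pooled, chrom, start, end) {
  dt <- as.data.table(tags_pooled)
  .ch <- chrom; .s <- start; .e <- end
  sel <- dt[chrom == .ch & pos >= .s & pos < .e]
  dens <- numeric(end - start)
  if (nrow(sel)) {
    agg <- sel[, .(w = sum(weight)), by = pos]
    dens[agg$pos - start + 1L] <- agg$w
  }
  dens
}

#' Quantify regions across time points with depth normalization
#'
#' Entry (r, t) is the weighted tag count of region r in library t scaled
#' by reference_total / total_t, where reference_total is the mean of the
#' library totals (non-redundant mapped reads).
#'
#' @param tags_by_time list of shifted tag tables or `tag_library` objects
#' @param regions data.table with chrom, start, end (0-based half-open)
#' @param totals_by_time numeric vector of per-library non-redundant
#'   totals; defaults to the `total_nonredundant` of `tag_library` inputs
#' @return numeric matrix regions x time points
#' @export
quantify_regions <- function(tags_by_time, regions, totals_by_time = NULL) {
  regions <- as.data.table(regions)
  if (is.null(totals_by_time))
    totals_by_time <- vapply(tags_by_time, function(x) {
      if (inherits(x, "tag_library")) x$total_nonredundant else nrow(as.data.table(x))
    }, numeric(1))
  if (any(totals_by_time <= 0)) stop("library totals must be positive", call. = FALSE)
  ref <- mean(totals_by_time)
  out <- matrix(0, nrow(regions), length(tags_by_time))
  for (t in seq_along(tags_by_time)) {
    x <- tags_by_time[[t]]
    dt <- if (inherits(x, "tag_library")) x$tags else as.data.table(x)
    for (ch in unique(regions$chrom)) {
      rid <- which(regions$chrom == ch)
      sub <- dt[dt$chrom == ch]
      if (!nrow(sub)) next
      hits <- IRanges::findOverlaps(
        IRanges::IRanges(sub$pos + 1L, width = 1L),
        IRanges::IRanges(regions$start[rid] + 1L, regions$end[rid]))
      if (length(hits)) {
        w <- tapply(sub$weight[S4Vectors::queryHits(hits)],
                    S4Vectors::subjectHits(hits), sum)
        out[rid[as.integer(names(w))], t] <- as.numeric(w)
      }
    }
    out[, t] <- out[, t] * ref / totals_by_time[t]
  }
  rownames(out) <- regions$id %||% paste0("peak_", seq_len(nrow(regions)))
  out
}

#' Full block-based peak calling
#'
#' Runs the two half-offset tilings, selects enriched blocks in each,
#' merges them, refines every merged region's borders on the pooled
#' density, and quantifies the refined peaks.
#'
#' @param chip_libs,input_libs lists of `tag_library` objects (one per
#'   time point, shifted), ChIP and matched input
#' @param block_size,min_signal,pseudo,log2_threshold,qn_group see
#'   [select_blocks()]
#' @param init_border,retain,min_border see [refine_peak()]
#' @return list with `peaks` (data.table: id, chrom, start, end,
#'   raw_start, raw_end), `signal` (refined-peak x time normalized
#'   matrix), and `refinement` (list of step logs)
#' @export
call_peaks <- function(chip_libs, input_libs, block_size = 500L,
                       min_signal = 40, pseudo = 1, log2_threshold = 2,
                       qn_group = "experiment", init_border = 50L,
                       retain = 0.75, min_border = 10L) {
  stopifnot(length(chip_libs) == length(input_libs))
  chip_tabs <- lapply(chip_libs, function(x) if (inherits(x, "tag_library")) x$tags else as.data.table(x))
  input_tabs <- lapply(input_libs, function(x) if (inherits(x, "tag_library")) x$tags else as.data.table(x))
  half <- as.integer(block_size) %/% 2L
  pass <- lapply(c(0L, half), function(off) {
    select_blocks(tile_counts(chip_tabs, block_size, off),
                  tile_counts(input_tabs, block_size, off),
                  min_signal = min_signal, pseudo = pseudo,
                  log2_threshold = log2_threshold, qn_group = qn_group)
  })
  regions <- merge_offset_tilings(pass[[1]], pass[[2]])
  if (nrow(regions) == 0) {
    return(list(peaks = data.table(id = character(), chrom = character(),
                                   start = integer(), end = integer(),
                                   raw_start = integer(), raw_end = integer()),
                signal = matrix(0, 0, length(chip_libs)), refinement = list()))
  }
  pooled <- rbindlist(chip_tabs)
  peaks <- vector("list", nrow(regions))
  steps <- vector("list", nrow(regions))
  for (i in seq_len(nrow(regions))) {
    dens <- region_density(pooled, regions$chrom[i], regions$start[i],
                           regions$end[i])
    r <- refine_peak(regions$start[i], regions$end[i], dens,
                     init_border = init_border, retain = retain,
                     min_border = min_border)
    peaks[[i]] <- data.table(chrom = regions$chrom[i], start = r$start,
                             end = r$end, raw_start = regions$start[i],
                             raw_end = regions$end[i])
    steps[[i]] <- r$steps
  }
  peaks <- rbindlist(peaks)
  peaks[, id := sprintf("peak_%04d", .I)]
  setcolorder(peaks, "id")
  totals <- vapply(chip_libs, function(x) {
    if (inherits(x, "tag_library")) x$total_nonredundant else nrow(as.data.table(x))
  }, numeric(1))
  sig <- quantify_regions(chip_tabs, peaks, totals)
  rownames(sig) <- peaks$id
  names(steps) <- peaks$id
  list(peaks = peaks, signal = sig, refinement = steps)
}

#' Write peaks as BED
#' @param peaks peak table from [call_peaks()]
#' @param signal optional peak x time matrix; max per peak becomes the score
#' @param path output file
#' @export
write_peaks_bed <- function(peaks, path, signal = NULL) {
  dt <- as.data.table(peaks)
  score <- if (!is.null(signal)) as.integer(round(apply(signal, 1, max)))
    else 0L
  out <- dt[, .(chrom, start, end, name = id, score = score, strand = ".")]
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
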