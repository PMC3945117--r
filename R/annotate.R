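#' Read a TSS annotation from BED
#'
#' BED6 with the gene id in the name column; the TSS is the interval
#' start for + strand genes and end - 1 for - strand genes.
#'
#' @param path BED file
#' @return data.table: gene, chrom, tss, strand
#' @export
read_tss_bed <- function(path) {
  dt <- fread(path, header = FALSE)
  setnames(dt, seq_len(min(6, ncol(dt))),
           c("chrom", "start", "end", "gene", "score", "strand")[seq_len(min(6, ncol(dt)))])
  dt[, .(gene, chrom, tss = ifelse(strand == "+", start, end - 1L), strand)]
}

#' Read transcript TSSs from GFF3
#'
#' Keeps `type` features (default mRNA/transcript/gene fallback) and
#' derives the TSS from the strand. GFF coordinates are 1-based; the
#' returned `tss` is 0-based to match the rest of the package.
#'
#' @param path GFF3 file
#' @param types feature types to use, in order of preference
#' @return data.table: gene, chrom, tss, strand
#' @export
read_tss_gff <- function(path, types = c("mRNA", "transcript", "gene")) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  dt <- fread(text = lines, header = FALSE, sep = "\t",
              col.names = c("chrom", "source", "type", "start", "end",
                            "score", "strand", "frame", "attr"))
  use <- NULL
  for (ty in types) {
    use <- dt[type == ty]
    if (nrow(use)) break
  }
  if (!nrow(use)) stop("no usable features in GFF", call. = FALSE)
  id <- sub('.*?(?:ID|gene_id)[=\\s]"?([^";]+)"?.*', "\\1", use$attr,
            perl = TRUE)
  use[, .(gene = id, chrom,
          tss = as.integer(ifelse(strand == "+", start - 1L, end - 1L)),
          strand)]
}

#' Nearest TSS for each peak
#'
#' Distance is measured from the peak midpoint to the TSS and signed
#' relative to gene orientation (negative = upstream of the gene). The
#' search is per chromosome; peaks on chromosomes absent from the
#' annotation get NA. Ties go to the TSS at the smaller coordinate.
#'
#' @param peaks data.table chrom, start, end
#' @param annotation data.table gene, chrom, tss, strand
#' @return data.table: one row per peak with gene, tss, strand, distance
#' @export
nearest_tss <- function(peaks, annotation) {
  peaks <- as.data.table(peaks)
  ann <- as.data.table(annotation)
  if (!nrow(ann)) stop("empty annotation", call. = FALSE)
  stop_if_not_cols(ann, c("gene", "chrom", "tss", "strand"), "annotation")
  mid <- (peaks$start + peaks$end) %/% 2L
  out <- data.table(gene = rep(NA_character_, nrow(peaks)),
                    tss = NA_integer_, strand = NA_character_,
                    distance = NA_integer_)
  for (ch in unique(peaks$chrom)) {
    rid <- which(peaks$chrom == ch)
    a <- ann[chrom == ch]
    if (!nrow(a)) next
    setorder(a, tss, gene)
    idx <- findInterval(mid[rid], a$tss)
    for (j in seq_along(rid)) {
      i <- idx[j]
      cand <- unique(pmin(pmax(c(i, i + 1L), 1L), nrow(a)))
      dd <- abs(a$tss[cand] - mid[rid[j]])
      best <- cand[order(dd, a$tss[cand])][1]
      sgn <- if (a$strand[best] == "+") 1L else -1L
      set(out, rid[j], names(out),
          list(a$gene[best], a$tss[best], a$strand[best],
               as.integer(sgn * (mid[rid[j]] - a$tss[best]))))
    }
  }
  out
}

#' Per-peak descriptive features
#'
#' Length, fitted oscillation amplitude and signed distance to the
#' nearest TSS, joined by peak id.
#'
#' @param peaks data.table id, chrom, start, end
#' @param fits output of [fit_cosine_matrix()] on the peak signal matrix
#' @param annotation optional TSS annotation for the distance column
#' @return data.table: id, length, amplitude, phase_hours, amplitude_p,
#'   gene, distance
#' @export
peak_features <- function(peaks, fits, annotation = NULL) {
  peaks <- as.data.table(peaks)
  out <- peaks[, .(id, length = end - start)]
  f <- as.data.table(fits)[, .(id, amplitude = b1, phase_hours, amplitude_p)]
  out <- merge(out, f, by = "id", all.x = TRUE, sort = FALSE)
  if (!is.null(annotation)) {
    nt <- nearest_tss(peaks, annotation)
    out[, `:=`(gene = nt$gene, distance = nt$distance)]
  }
  out[]
}

#' Count peaks overlapping another region set
#'
#' `overlapping`: a peak counts if it intersects any other region by at
#' least 1 nt. `near_promoter`: a peak counts if any other region lies
#' within `window` nt of the peak's assigned gene TSS (requires `tss`).
#'
#' @param peaks,others data.tables with chrom, start, end
#' @param mode "overlapping" or "near_promoter"
#' @param tss annotation for near_promoter mode
#' @param window promoter window in nt (default 1000)
#' @return list: n (peaks counted), total, fraction, flags
#' @export
overlap_count <- function(peaks, others, mode = c("overlapping", "near_promoter"),
                          tss = NULL, window = 1000L) {
  mode <- match.arg(mode)
  peaks <- as.data.table(peaks)
  others <- as.data.table(others)
  flags <- rep(FALSE, nrow(peaks))
  if (mode == "overlapping") {
    for (ch in unique(peaks$chrom)) {
      rid <- which(peaks$chrom == ch)
      o <- others[chrom == ch]
      if (!nrow(o)) next
      cnt <- IRanges::countOverlaps(
        IRanges::IRanges(peaks$start[rid] + 1L, peaks$end[rid]),
        IRanges::IRanges(o$start + 1L, o$end))
      flags[rid] <- cnt > 0
    }
  } else {
    if (is.null(tss)) stop("near_promoter mode needs a tss annotation", call. = FALSE)
    nt <- nearest_tss(peaks, tss)
    for (ch in unique(peaks$chrom)) {
      rid <- which(peaks$chrom == ch & !is.na(nt$tss))
      o <- others[chrom == ch]
      if (!nrow(o) || !length(rid)) next
      cnt <- IRanges::countOverlaps(
        IRanges::IRanges(nt$tss[rid] + 1L - window, nt$tss[rid] + 1L + window),
        IRanges::IRanges(o$start + 1L, o$end))
      flags[rid] <- cnt > 0
    }
  }
  list(n = sum(flags), total = nrow(peaks),
       fraction = if (nrow(peaks)) sum(flags) / nrow(peaks) else NA_real_,
       flags = flags)
}
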