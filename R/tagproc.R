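#' Build a weighted tag table from alignment records
#'
#' Each aligned read contributes one tag per reported alignment, weighted
#' 1/n_hits so that the read's total contribution to genomic densities is
#' exactly one. Reads with more than `max_hits` alignments are discarded
#' entirely.
#'
#' @param records data.frame with columns `chrom`, `pos` (0-based leftmost
#'   coordinate), `strand` ("+"/"-") and optionally `n_hits` (defaults 1).
#' @param max_hits alignments allowed per read; reads above this are dropped.
#' @param chroms optional character vector of known chromosome names; records
#'   on other chromosomes are rejected with their row index.
#' @return a `data.table` with columns chrom, pos, strand, n_hits, weight,
#'   sorted by (chrom, pos, strand).
#' @export
load_mapped_tags <- function(records, max_hits = 5L, chroms = NULL) {
  dt <- as.data.table(records)
  if (!"n_hits" %in% names(dt)) dt[, n_hits := 1L]
  stop_if_not_cols(dt, c("chrom", "pos", "strand"), "alignment records")
  bad <- which(is.na(dt$chrom) | is.na(dt$pos) | !(dt$strand %in% c("+", "-")) |
                 dt$pos < 0 | is.na(dt$n_hits) | dt$n_hits < 1)
  if (length(bad))
    stop(sprintf("malformed alignment record(s) at row(s): %s",
                 paste(head(bad, 10), collapse = ", ")), call. = FALSE)
  if (!is.null(chroms)) {
    bad <- which(!dt$chrom %in% chroms)
    if (length(bad))
      stop(sprintf("unknown chromosome in record(s) at row(s): %s",
                   paste(head(bad, 10), collapse = ", ")), call. = FALSE)
  }
  dt <- dt[n_hits <= max_hits]
  dt <- dt[, .(chrom = as.character(chrom), pos = as.integer(pos),
               strand = as.character(strand), n_hits = as.integer(n_hits))]
  dt[, weight := 1 / n_hits]
  setorder(dt, chrom, pos, strand, n_hits)
  dt[]
}

#' Remove redundant tags
#'
#' Tags mapped at the same position and on the same strand are collapsed to
#' a single survivor (the first in sorted order); its weight is kept
#' unchanged. Idempotent.
#'
#' @param tags tag table from [load_mapped_tags()]
#' @return deduplicated tag table
#' @export
deduplicate_tags <- function(tags) {
  dt <- as.data.table(tags)
  setorder(dt, chrom, pos, strand, n_hits)
  unique(dt, by = c("chrom", "pos", "strand"))
}

#' Strand shift from fragment size and read length
#'
#' shift = round(fragment/2 - read_length/2), rounding half away from zero,
#' so that reads moved by `shift` toward the fragment center have their
#' midpoints over the binding site.
#'
#' @param avg_fragment_size mean sequenced-fragment length (nt), positive
#' @param read_length read length (nt), positive
#' @return integer shift in nucleotides
#' @export
compute_shift <- function(avg_fragment_size, read_length) {
  if (any(avg_fragment_size <= 0) || any(read_length <= 0))
    stop("avg_fragment_size and read_length must be positive", call. = FALSE)
  as.integer(round_half_away(avg_fragment_size / 2 - read_length / 2))
}

#' Shift tags toward fragment centers
#'
#' Plus-strand tags move +shift, minus-strand tags move -shift; positions
#' are clipped at zero. Weights are untouched.
#'
#' @param tags tag table
#' @param shift nonnegative integer from [compute_shift()]
#' @return shifted tag table
#' @export
shift_tags <- function(tags, shift) {
  stopifnot(shift >= 0)
  dt <- copy(as.data.table(tags))
  dt[, pos := pmax(0L, pos + ifelse(strand == "+", 1L, -1L) * as.integer(shift))]
  dt[]
}

#' A ZT-labelled tag library
#'
#' Bundles a (deduplicated) tag table with its metadata: ZT label, average
#' fragment size, read length, and the total non-redundant tag count used
#' for depth normalization.
#'
#' @param tags tag table (deduplicated with [deduplicate_tags()] if
#'   `dedup = TRUE`, the default)
#' @param label ZT time in hours
#' @param avg_fragment_size,read_length library metadata (nt)
#' @param dedup deduplicate on construction
#' @return object of class `tag_library`
#' @export
tag_library <- function(tags, label, avg_fragment_size, read_length = 80,
                        dedup = TRUE) {
  if (avg_fragment_size <= 0 || read_length <= 0)
    stop("fragment size and read length must be positive", call. = FALSE)
  tags <- as.data.table(tags)
  if (dedup) tags <- deduplicate_tags(tags)
  structure(list(label = label, tags = tags,
                 avg_fragment_size = avg_fragment_size,
                 read_length = read_length,
                 total_nonredundant = nrow(tags)),
            class = "tag_library")
}

#' @export
print.tag_library <- function(x, ...) {
  cat(sprintf("tag_library ZT%02g: %d non-redundant tags, fragment %d nt, read %d nt\n",
              x$label, x$total_nonredundant,
              as.integer(x$avg_fragment_size), as.integer(x$read_length)))
  invisible(x)
}

#' Read mapped tags from disk
#'
#' Accepts 4-column tab text (chrom, pos, strand, n_hits), 6-column BED as
#' written by [write_tags_bed()] (score = weight x 1000), or BAM (needs
#' Rsamtools; the NH tag is used as n_hits when present). SAM positions are
#' 1-based and converted; tab/BED input is taken as 0-based.
#'
#' @param path input file
#' @param format one of "auto", "tab", "bed", "bam"
#' @param max_hits passed to [load_mapped_tags()]
#' @return tag table
#' @export
read_tags <- function(path, format = c("auto", "tab", "bed", "bam"),
                      max_hits = 5L) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bam$", path, ignore.case = TRUE)) "bam"
      else if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE)) "bed"
      else "tab"
  }
  if (format == "bam") {
    if (!requireNamespace("Rsamtools", quietly = TRUE))
      stop("BAM input requires the Rsamtools package", call. = FALSE)
    p <- Rsamtools::ScanBamParam(what = c("rname", "pos", "strand"),
                                 tag = "NH")
    b <- Rsamtools::scanBam(path, param = p)[[1]]
    nh <- b$tag$NH %||% rep(1L, length(b$pos))
    nh[is.na(nh)] <- 1L
    rec <- data.table(chrom = as.character(b$rname), pos = b$pos - 1L,
                      strand = as.character(b$strand), n_hits = nh)
    rec <- rec[strand %in% c("+", "-")]
    return(load_mapped_tags(rec, max_hits = max_hits))
  }
  dt <- fread(path, header = FALSE)
  if (format == "bed" || ncol(dt) >= 6) {
    setnames(dt, 1:6, c("chrom", "start", "end", "name", "score", "strand"))
    rec <- dt[, .(chrom, pos = start, strand,
                  n_hits = as.integer(round(1000 / pmax(score, 1e-9))))]
  } else {
    if (ncol(dt) < 3) stop("need at least chrom, pos, strand columns")
    if (ncol(dt) == 3) dt[, V4 := 1L]
    setnames(dt, 1:4, c("chrom", "pos", "strand", "n_hits"))
    rec <- dt
  }
  load_mapped_tags(rec, max_hits = max_hits)
}

#' Write tags as 6-column BED
#'
#' One interval per tag (width 1 at the tag position); score carries the
#' multi-hit weight scaled by 1000 so it round-trips through BED.
#'
#' @param tags tag table
#' @param path output file
#' @export
write_tags_bed <- function(tags, path) {
  dt <- as.data.table(tags)
  out <- dt[, .(chrom, start = pos, end = pos + 1L, name = "tag",
                score = as.integer(round(weight * 1000)), strand)]
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
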