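#' Default pipeline configuration
#'
#' All thresholds of the workflow in one validated list: block size 500,
#' 40-tag floor, pseudo-count 1, log2 threshold 2, border 50 / retain
#' 0.75, period 24 h, rhythmicity cutoffs P<0.1 (binding) and P<0.05
#' (expression), 1000 matched groups.
#'
#' @param ... overrides of the defaults
#' @return named list of class `run_config`
#' @export
run_config <- function(...) {
  cfg <- list(block_size = 500L, min_signal = 40, pseudo = 1,
              log2_threshold = 2, qn_group = "experiment",
              init_border = 50L, retain = 0.75, min_border = 10L,
              period = 24, k_clusters = 4L,
              pcut_binding = 0.1, pcut_expression = 0.05,
              n_groups = 1000L, expressed_quantile = 0.5,
              max_hits = 5L, seed = 1L, outdir = NULL)
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown))
    stop(sprintf("unknown config field(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  cfg[names(ov)] <- ov
  stopifnot(cfg$block_size > 0, cfg$retain > 0, cfg$retain <= 1,
            cfg$period > 0, cfg$n_groups >= 1)
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration from JSON or YAML
#' @param path config file (.json, or .yaml/.yml with the yaml package)
#' @return `run_config`
#' @export
read_run_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML config needs the yaml package; use JSON", call. = FALSE)
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, vals)
}

#' Run the full around-the-clock workflow on in-memory libraries
#'
#' Stages, in order: library preparation (dedup + strand shift), block
#' peak calling with border refinement, peak quantification, cosinor
#' fitting, profile clustering, TSS annotation, and (when a genome,
#' annotation, expression and motifs are given) motif enrichment. When
#' `outdir` is set in the config, each product is written alongside a
#' JSON provenance record (config hash, seed, package version).
#'
#' @param chip_libs,input_libs lists of raw `tag_library` objects
#' @param config a [run_config()]
#' @param genome optional `DNAStringSet` for motif work
#' @param tss optional annotation (gene, chrom, tss, strand)
#' @param expression optional named per-gene expression vector
#' @param motifs optional list of `motif_model`
#' @return list: peaks, signal, fits, clusters, features, motif_results
#' @export
run_pipeline <- function(chip_libs, input_libs, config = run_config(),
                         genome = NULL, tss = NULL, expression = NULL,
                         motifs = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  chip <- stage("tags", lapply(chip_libs, prepare_library))
  input <- stage("tags", lapply(input_libs, prepare_library))
  called <- stage("callpeaks", call_peaks(
    chip, input, block_size = config$block_size,
    min_signal = config$min_signal, pseudo = config$pseudo,
    log2_threshold = config$log2_threshold, qn_group = config$qn_group,
    init_border = config$init_border, retain = config$retain,
    min_border = config$min_border))
  tp <- vapply(chip_libs, `[[`, numeric(1), "label")
  fits <- stage("rhythm", fit_cosine_matrix(called$signal, tp,
                                            period = config$period))
  clusters <- NULL
  if (nrow(called$peaks) >= config$k_clusters)
    clusters <- stage("cluster",
                      cluster_profiles(called$signal, config$k_clusters))
  features <- NULL
  if (!is.null(tss) && nrow(called$peaks))
    features <- stage("annotate", peak_features(called$peaks, fits, tss))
  motif_results <- NULL
  if (!is.null(genome) && !is.null(tss) && !is.null(expression) &&
      !is.null(motifs) && nrow(called$peaks))
    motif_results <- stage("motifs", lapply(motifs, function(m)
      motif_enrichment(genome, called$peaks, tss, expression, m,
                       n_groups = config$n_groups,
                       expressed_quantile = config$expressed_quantile,
                       seed = config$seed)))
  out <- list(peaks = called$peaks, signal = called$signal,
              refinement = called$refinement, fits = fits,
              clusters = clusters, features = features,
              motif_results = motif_results, config = config)
  if (!is.null(config$outdir)) write_results(out, config$outdir)
  out
}

#' Write pipeline results with provenance
#' @param results output of [run_pipeline()]
#' @param outdir directory (created)
#' @return invisible vector of written paths
#' @export
write_results <- function(results, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(outdir, "run_config.json")
  cfg <- unclass(results$config)
  cfg$outdir <- NULL   # a location, not an analysis parameter; keeps the hash portable
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE,
                       null = "null", digits = NA)
  paths <- cfg_path
  if (nrow(results$peaks)) {
    p <- file.path(outdir, "peaks.bed")
    write_peaks_bed(results$peaks, p, results$signal)
    sig <- data.table(id = rownames(results$signal), results$signal)
    fwrite(sig, file.path(outdir, "signal.tsv"), sep = "\t")
    fwrite(results$fits, file.path(outdir, "fits.tsv"), sep = "\t")
    paths <- c(paths, p)
    if (!is.null(results$clusters))
      fwrite(data.table(id = names(results$clusters),
                        cluster = results$clusters),
             file.path(outdir, "clusters.tsv"), sep = "\t")
    if (!is.null(results$features))
      fwrite(results$features, file.path(outdir, "features.tsv"), sep = "\t")
  }
  if (!is.null(results$motif_results)) {
    mr <- rbindlist(lapply(names(results$motif_results), function(nm) {
      r <- results$motif_results[[nm]]
      data.table(motif = nm, observed = r$observed, n_groups = r$n_groups,
                 null_max = max(r$null_counts), empirical_p = r$empirical_p,
                 report = r$report_string)
    }))
    fwrite(mr, file.path(outdir, "motif_enrichment.tsv"), sep = "\t")
  }
  prov <- list(config_md5 = unname(tools::md5sum(cfg_path)),
               seed = results$config$seed,
               package = "rhythmochip",
               version = as.character(packageVersion("rhythmochip")),
               r_version = as.character(getRversion()),
               written = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(prov, file.path(outdir, "provenance.json"),
                       auto_unbox = TRUE)
  invisible(paths)
}
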