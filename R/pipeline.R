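#' Pipeline configuration
#'
#' A single nested key-value configuration covering every stage: windowing,
#' LOESS span, classification thresholds, k-mer purging and the simulation
#' block. Defaults are the stage defaults; a config written with
#' [write_pipeline_config()] and read back with [read_pipeline_config()]
#' round-trips identically.
#'
#' @param window_size Window width in bp.
#' @param span LOESS span for GC correction.
#' @param thresholds A [linkage_thresholds()] object or a list of its
#'   fields.
#' @param kmer_k,kmer_t K-mer size and pairing threshold for purging.
#' @param min_windows Minimum usable windows per contig.
#' @param baseline Copy-number baseline rule (`"mean"` or `"median"`).
#' @param simulation A [sim_config()] object or a list of its fields.
#' @param seed Integer seed recorded in the config (the simulation block
#'   carries its own, kept in sync here).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(window_size = 1e5, span = 0.3,
                            thresholds = linkage_thresholds(),
                            kmer_k = 21, kmer_t = 0.6,
                            min_windows = 3,
                            baseline = "mean",
                            simulation = sim_config(),
                            seed = 1) {
  if (!inherits(thresholds, "linkage_thresholds")) {
    thresholds <- do.call(linkage_thresholds, thresholds)
  }
  if (!inherits(simulation, "sim_config")) {
    # the recorded bias form is an output field, not a constructor argument
    simulation$gc_bias_form <- NULL
    simulation <- do.call(sim_config, simulation)
  }
  simulation$seed <- as.integer(seed)
  simulation$window_size <- window_size
  structure(list(window_size = window_size, span = span,
                 thresholds = unclass(thresholds),
                 kmer_k = kmer_k, kmer_t = kmer_t,
                 min_windows = min_windows, baseline = baseline,
                 simulation = unclass(simulation),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @param config A `pipeline_config` (for writing).
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim <- raw$simulation
  sim$gc_bias_form <- NULL
  pipeline_config(
    window_size = raw$window_size, span = raw$span,
    thresholds = raw$thresholds, kmer_k = raw$kmer_k, kmer_t = raw$kmer_t,
    min_windows = raw$min_windows, baseline = raw$baseline,
    simulation = sim, seed = raw$seed
  )
}

#' Simulate a study to disk
#'
#' Writes the synthetic genome FASTA, one bedgraph per sample, the truth
#' TSV and the simulation config (including the recorded GC-bias form).
#' Deterministic given the config seed.
#'
#' @param config A `pipeline_config` (its `simulation` block drives the
#'   generator).
#' @param out_dir Output directory (created if needed).
#' @return Named list of output paths, invisibly.
#' @export
run_simulate <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- do.call(sim_config, config$simulation[setdiff(
    names(config$simulation), "gc_bias_form")])
  genome <- generate_genome(sim)
  tracks <- simulate_study(genome)
  paths <- list(
    fasta = file.path(out_dir, "genome.fasta"),
    truth = file.path(out_dir, "truth.tsv"),
    config = file.path(out_dir, "config.yaml")
  )
  write_fasta(genome$assembly, paths$fasta)
  write_truth(genome, paths$truth)
  write_pipeline_config(config, paths$config)
  paths$tracks <- file.path(out_dir, paste0(names(tracks), ".bedgraph"))
  purrr::walk2(tracks, paths$tracks, write_bedgraph)
  invisible(paths)
}

#' Classify an assembly from depth-track files
#'
#' Reads the assembly and the male/female bedgraph tracks, runs the full
#' profile > GC-fit > correct > copy-number > combine > classify chain, and
#' writes `calls.tsv` and `summary.tsv` (plus per-sex window tables when
#' `keep_intermediates = TRUE`).
#'
#' @param assembly_path FASTA path.
#' @param male_paths,female_paths Character vectors of bedgraph paths
#'   (at least one each).
#' @param out_dir Output directory.
#' @param config A `pipeline_config`.
#' @param keep_intermediates Write per-sex combined window tables too.
#' @return The `linkage_result`, invisibly.
#' @export
run_classify <- function(assembly_path, male_paths, female_paths, out_dir,
                         config = pipeline_config(),
                         keep_intermediates = FALSE) {
  if (length(male_paths) == 0 || length(female_paths) == 0) {
    stop("both sexes required: supply at least one male and one female ",
         "depth track", call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  assembly <- read_fasta(assembly_path)
  male <- purrr::map(male_paths, read_bedgraph, assembly = assembly)
  female <- purrr::map(female_paths, read_bedgraph, assembly = assembly)
  thr <- do.call(linkage_thresholds, config$thresholds)
  result <- classify_sex_linkage(assembly, male, female,
                                 window_size = config$window_size,
                                 span = config$span, thr = thr,
                                 min_windows = config$min_windows,
                                 baseline = config$baseline)
  write_linkage(result, file.path(out_dir, "calls.tsv"),
                file.path(out_dir, "summary.tsv"))
  if (keep_intermediates) {
    write_window_table(result$profiles$male,
                       file.path(out_dir, "windows_male.tsv"))
    write_window_table(result$profiles$female,
                       file.path(out_dir, "windows_female.tsv"))
  }
  invisible(result)
}

#' Purge allelic contigs from an assembly file
#'
#' @param assembly_path FASTA path.
#' @param out_dir Output directory (`primary.fasta`, `purged.fasta`,
#'   `pairs.tsv`).
#' @param config A `pipeline_config` (supplies `kmer_k`, `kmer_t`).
#' @return The purge result list, invisibly.
#' @export
run_purge <- function(assembly_path, out_dir, config = pipeline_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  assembly <- read_fasta(assembly_path)
  res <- purge_assembly(assembly, k = config$kmer_k, t = config$kmer_t)
  write_fasta(res$primary, file.path(out_dir, "primary.fasta"))
  if (nrow(res$purged) > 0) {
    write_fasta(res$purged, file.path(out_dir, "purged.fasta"))
  } else {
    file.create(file.path(out_dir, "purged.fasta"))
  }
  readr::write_tsv(res$pairs, file.path(out_dir, "pairs.tsv"))
  invisible(res)
}

#' Summarise an assembly file
#'
#' @param assembly_path FASTA path.
#' @param out_path Optional TSV output path.
#' @return The statistics tibble.
#' @export
run_stats <- function(assembly_path, out_path = NULL) {
  stats <- summarize_assembly(read_fasta(assembly_path))
  if (!is.null(out_path)) readr::write_tsv(stats, out_path)
  stats
}
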