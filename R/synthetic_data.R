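#' Simulation configuration for synthetic genomes and depth tracks
#'
#' Defines the study conditions the simulator emulates: a diploid genome
#' with autosomes, an X present in two copies in females and one in males,
#' a male-only Y, window-scale GC heterogeneity, a multiplicative GC
#' depth bias, and Poisson (or mildly over-dispersed negative-binomial)
#' count noise. Defaults mirror a triplicate male / triplicate female
#' whole-genome sequencing design at 30x diploid depth.
#'
#' @param n_autosomes,n_x_contigs,n_y_contigs Number of contigs of each
#'   class (at least one contig in total).
#' @param contig_length_range Min/max contig length in bp; lengths are
#'   drawn uniformly.
#' @param window_size Window width in bp used when simulating depth.
#' @param mean_depth Expected per-base depth of an ordinary diploid locus.
#' @param gc_bias_strength Strength `s >= 0` of the multiplicative GC bias
#'   `b(gc) = exp(-s * (2 * (gc - 0.5))^2)`: unimodal with `b(0.5) = 1`,
#'   monotone on each side of `gc = 0.5`. `s = 0` disables the bias.
#' @param noise Noise law for observed window depths: `"poisson"`,
#'   `"nbinom"` (negative binomial with dispersion `nb_dispersion`), or
#'   `"none"` (expected depth reported exactly).
#' @param nb_dispersion Negative-binomial dispersion (variance =
#'   `mu + dispersion * mu^2`); used only when `noise = "nbinom"`.
#' @param n_male_samples,n_female_samples Replicate tracks per sex.
#' @param gc_range Range the per-segment target GC fraction is drawn from.
#' @param gc_segment_length Length of the constant-GC segments contigs are
#'   built from (the scale of GC heterogeneity).
#' @param allelic_fraction Fraction of contigs that receive an allelic
#'   duplicate (haplotig) copy, for redundancy-purge testing.
#' @param allelic_length_fraction Duplicate length as a fraction of its
#'   source contig.
#' @param allelic_substitution_rate Per-base substitution rate applied to
#'   duplicates.
#' @param seed Integer master seed; every random draw in the simulator is
#'   derived from it through named substreams, so e.g. adding a replicate
#'   does not perturb the genome or the other tracks.
#' @return A `sim_config` object (a validated list).
#' @export
sim_config <- function(n_autosomes = 20,
                       n_x_contigs = 5,
                       n_y_contigs = 5,
                       contig_length_range = c(3e5, 6e5),
                       window_size = 1e5,
                       mean_depth = 30,
                       gc_bias_strength = 0.5,
                       noise = c("poisson", "nbinom", "none"),
                       nb_dispersion = 0.05,
                       n_male_samples = 3,
                       n_female_samples = 3,
                       gc_range = c(0.25, 0.65),
                       gc_segment_length = 1e5,
                       allelic_fraction = 0,
                       allelic_length_fraction = 0.9,
                       allelic_substitution_rate = 0.01,
                       seed = 1) {
  noise <- match.arg(noise)
  cfg <- list(
    n_autosomes = as.integer(n_autosomes),
    n_x_contigs = as.integer(n_x_contigs),
    n_y_contigs = as.integer(n_y_contigs),
    contig_length_range = as.numeric(contig_length_range),
    window_size = as.numeric(window_size),
    mean_depth = as.numeric(mean_depth),
    gc_bias_strength = as.numeric(gc_bias_strength),
    gc_bias_form = "b(gc) = exp(-strength * (2*(gc - 0.5))^2)",
    noise = noise,
    nb_dispersion = as.numeric(nb_dispersion),
    n_male_samples = as.integer(n_male_samples),
    n_female_samples = as.integer(n_female_samples),
    gc_range = as.numeric(gc_range),
    gc_segment_length = as.numeric(gc_segment_length),
    allelic_fraction = as.numeric(allelic_fraction),
    allelic_length_fraction = as.numeric(allelic_length_fraction),
    allelic_substitution_rate = as.numeric(allelic_substitution_rate),
    seed = as.integer(seed)
  )
  with(cfg, {
    if (n_autosomes < 0 || n_x_contigs < 0 || n_y_contigs < 0)
      stop("contig counts must be >= 0", call. = FALSE)
    if (n_autosomes + n_x_contigs + n_y_contigs < 1)
      stop("at least one contig is required", call. = FALSE)
    if (mean_depth <= 0) stop("mean_depth must be > 0", call. = FALSE)
    if (gc_bias_strength < 0) stop("gc_bias_strength must be >= 0", call. = FALSE)
    if (any(contig_length_range < 1) ||
        contig_length_range[1] > contig_length_range[2])
      stop("invalid contig_length_range", call. = FALSE)
    if (allelic_fraction < 0 || allelic_fraction > 1)
      stop("allelic_fraction must be in [0, 1]", call. = FALSE)
  })
  structure(cfg, class = "sim_config")
}

#' Copy count of a chromosome class in a given sex
#'
#' The diploid XY model: females carry two copies of autosomes and X and
#' no Y; males carry two autosomal copies and one copy each of X and Y.
#' Copy counts are always derived from (class, sex), never stored.
#'
#' @param class Character vector of classes (`"AUTOSOME"`, `"X"`, `"Y"`).
#' @param sex `"male"` or `"female"`.
#' @return Integer copy counts, same length as `class`.
#' @examples
#' copy_count(c("AUTOSOME", "X", "Y"), "male")
#' @export
copy_count <- function(class, sex) {
  tab <- list(
    male = c(AUTOSOME = 2, X = 1, Y = 1),
    female = c(AUTOSOME = 2, X = 2, Y = 0)
  )
  sex <- match.arg(sex, c("male", "female"))
  unname(tab[[sex]][class])
}

#' Multiplicative GC bias curve used by the simulator
#'
#' `b(gc) = exp(-strength * (2 * (gc - 0.5))^2)`: equal to 1 at GC = 0.5,
#' strictly decreasing away from 0.5 on either side (monotone-unimodal).
#' Undefined GC (all-N windows) gets `b = 1`.
#'
#' @param gc GC fraction(s) in \[0, 1\] (NA allowed).
#' @param strength Bias strength `s >= 0`.
#' @return Numeric vector of multiplicative bias factors.
#' @export
gc_bias_curve <- function(gc, strength) {
  b <- exp(-strength * (2 * (gc - 0.5))^2)
  b[is.na(gc)] <- 1
  b
}

# Deterministic substream seeds: hash (seed, stream tokens) into [1, 2^31-2].
substream_seed <- function(seed, ...) {
  tokens <- c(seed, vapply(list(...), function(t) {
    if (is.character(t)) sum(utf8ToInt(t) * seq_len(nchar(t))) else as.numeric(t)
  }, numeric(1)))
  s <- 0
  for (t in tokens) s <- (s * 1103 + t * 12289 + 1) %% 2147483647
  as.integer(s %% 2147483646 + 1)
}

random_sequence <- function(length, gc) {
  codes <- sample(c(65L, 67L, 71L, 84L), length, replace = TRUE,
                  prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  intToUtf8(codes)
}

reverse_complement <- function(x) {
  chartr("ACGTN", "TGCAN", intToUtf8(rev(utf8ToInt(x))))
}

mutate_sequence <- function(sequence, rate) {
  codes <- utf8ToInt(sequence)
  hit <- which(stats::runif(length(codes)) < rate)
  if (length(hit) > 0) {
    bases <- c(65L, 67L, 71L, 84L)
    idx <- match(codes[hit], bases)
    idx <- ((idx - 1 + sample(1:3, length(hit), replace = TRUE)) %% 4) + 1
    codes[hit] <- bases[idx]
  }
  intToUtf8(codes)
}

#' Generate a synthetic genome with known chromosome classes
#'
#' Builds contigs from constant-GC segments (target GC drawn uniformly from
#' `gc_range` per segment) and labels each contig AUTOSOME, X or Y. Copy
#' counts follow the diploid model: females carry two copies of autosomes
#' and X and no Y; males carry two autosomal copies and one copy each of X
#' and Y. Optionally appends allelic duplicates (truncated, lightly mutated
#' copies of source contigs) for testing redundancy purging; duplicates
#' inherit their source's class. Deterministic given `config$seed`.
#'
#' @param config A [sim_config()] object.
#' @return A `genome_model` list with elements `assembly` (tibble: `contig`,
#'   `sequence`, `length`), `truth` (tibble: `contig`, `class`, `copy_male`,
#'   `copy_female`, `is_duplicate`), `allelic_pairs` (tibble: `primary`,
#'   `duplicate`) and `config`.
#' @export
generate_genome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  classes <- rep(c("AUTOSOME", "X", "Y"),
                 times = c(config$n_autosomes, config$n_x_contigs,
                           config$n_y_contigs))
  n <- length(classes)
  ids <- sprintf("%s_%02d", c(AUTOSOME = "ctgA", X = "ctgX", Y = "ctgY")[classes],
                 stats::ave(seq_len(n), classes, FUN = seq_along))
  set.seed(substream_seed(config$seed, "genome"))
  lengths <- round(stats::runif(n, config$contig_length_range[1],
                                config$contig_length_range[2]))
  seqs <- vapply(lengths, function(len) {
    n_seg <- ceiling(len / config$gc_segment_length)
    seg_len <- c(rep(config$gc_segment_length, n_seg - 1),
                 len - (n_seg - 1) * config$gc_segment_length)
    seg_gc <- stats::runif(n_seg, config$gc_range[1], config$gc_range[2])
    paste0(vapply(seq_len(n_seg),
                  function(i) random_sequence(seg_len[i], seg_gc[i]),
                  character(1)), collapse = "")
  }, character(1))
  assembly <- tibble::tibble(contig = ids, sequence = seqs,
                             length = nchar(seqs))
  truth <- tibble::tibble(
    contig = ids, class = classes,
    copy_male = copy_count(classes, "male"),
    copy_female = copy_count(classes, "female"),
    is_duplicate = FALSE
  )
  pairs <- tibble::tibble(primary = character(), duplicate = character())

  n_dup <- round(config$allelic_fraction * n)
  if (n_dup > 0) {
    set.seed(substream_seed(config$seed, "duplicates"))
    src <- sample(seq_len(n), n_dup)
    dup_rows <- purrr::map_dfr(src, function(i) {
      dup_len <- round(config$allelic_length_fraction * assembly$length[i])
      seq <- mutate_sequence(substring(assembly$sequence[i], 1, dup_len),
                             config$allelic_substitution_rate)
      tibble::tibble(contig = paste0(ids[i], "_alt"), sequence = seq,
                     length = nchar(seq), class = classes[i])
    })
    assembly <- dplyr::bind_rows(assembly,
                                 dplyr::select(dup_rows, -"class"))
    truth <- dplyr::bind_rows(truth, tibble::tibble(
      contig = dup_rows$contig, class = dup_rows$class,
      copy_male = copy_count(dup_rows$class, "male"),
      copy_female = copy_count(dup_rows$class, "female"),
      is_duplicate = TRUE
    ))
    pairs <- tibble::tibble(primary = ids[src], duplicate = dup_rows$contig)
  }
  structure(list(assembly = assembly, truth = truth, allelic_pairs = pairs,
                 config = config),
            class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  cat("<genome_model> ", nrow(x$assembly), " contigs, ",
      format(sum(x$assembly$length), big.mark = ","), " bp (",
      paste(names(table(x$truth$class)), table(x$truth$class),
            sep = ": ", collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Simulate one whole-genome depth track
#'
#' Emits a window-resolution bedgraph-style track for one sample of the
#' given sex. The expected per-base depth of a window is
#' `mean_depth * copy/2 * b(gc)` where `copy` is the copy count of the
#' contig's class in that sex and `b` is [gc_bias_curve()]; observed depth
#' is drawn from the configured noise law. Y-contig windows in females have
#' expected depth 0 (no reads can originate from an absent sequence), so
#' their observed depth is identically 0 under any noise law.
#' Deterministic given `(config$seed, sex, replicate)`.
#'
#' @param genome A `genome_model` from [generate_genome()]. Allelic
#'   duplicate contigs, if present, are simulated like their source class.
#' @param sex `"male"` or `"female"`.
#' @param replicate Replicate index (distinct replicates get independent
#'   noise substreams).
#' @param config Simulation config; defaults to the genome's own.
#' @return A depth-track tibble (`contig`, `start`, `end`, `depth`).
#' @export
simulate_depth <- function(genome, sex, replicate = 1,
                           config = genome$config) {
  stopifnot(inherits(genome, "genome_model"))
  sex <- match.arg(sex, c("male", "female"))
  windows <- tile_assembly(genome$assembly, config$window_size)
  gc <- assembly_window_gc(genome$assembly, windows)
  cls <- stats::setNames(genome$truth$class, genome$truth$contig)
  copies <- copy_count(unname(cls[windows$contig]), sex)
  mu <- config$mean_depth * copies / 2 *
    gc_bias_curve(gc, config$gc_bias_strength)
  set.seed(substream_seed(config$seed, "depth", sex, replicate))
  depth <- switch(config$noise,
    none = mu,
    poisson = stats::rpois(length(mu), mu),
    nbinom = ifelse(mu == 0, 0,
                    stats::rnbinom(length(mu), mu = mu,
                                   size = 1 / config$nb_dispersion))
  )
  tibble::tibble(contig = windows$contig, start = windows$start,
                 end = windows$end, depth = as.numeric(depth))
}

#' Simulate the full male/female replicate study
#'
#' @param genome A `genome_model`.
#' @param config Simulation config; defaults to the genome's own.
#' @return A named list of depth tracks (`male_1`, ..., `female_1`, ...).
#' @export
simulate_study <- function(genome, config = genome$config) {
  tracks <- c(
    purrr::map(seq_len(config$n_male_samples),
               ~ simulate_depth(genome, "male", .x, config)),
    purrr::map(seq_len(config$n_female_samples),
               ~ simulate_depth(genome, "female", .x, config))
  )
  names(tracks) <- c(paste0("male_", seq_len(config$n_male_samples)),
                     paste0("female_", seq_len(config$n_female_samples)))
  tracks
}

#' Write the truth table of a synthetic genome
#'
#' @param genome A `genome_model`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(genome, path) {
  readr::write_tsv(genome$truth, path)
  invisible(path)
}
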