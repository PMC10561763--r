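# Shared fixture builders; everything is generated in code at test time.

random_assembly <- function(n = 3, len_range = c(200, 800), gc = 0.5,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lens <- sample(len_range[1]:len_range[2], n, replace = TRUE)
  tibble::tibble(
    contig = sprintf("c%02d", seq_len(n)),
    sequence = vapply(lens, function(l) {
      paste(sample(c("A", "C", "G", "T"), l, replace = TRUE,
                   prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
            collapse = "")
    }, character(1))
  ) |>
    dplyr::mutate(length = nchar(sequence))
}

# One full-length record per contig at the given constant depth.
uniform_track <- function(assembly, depth) {
  tibble::tibble(contig = assembly$contig, start = 0,
                 end = assembly$length, depth = depth)
}

# Window table built directly (no sequences needed) for GC-correction and
# copy-number tests: one pseudo-contig, unit-width windows.
synthetic_window_table <- function(gc, raw_depth, sex = "male",
                                   width = 1000, excluded = FALSE) {
  n <- length(gc)
  tibble::tibble(
    sample_id = "s1", sex = sex,
    contig = "w", start = (seq_len(n) - 1) * width,
    end = seq_len(n) * width,
    gc = gc, raw_depth = raw_depth,
    excluded = rep_len(excluded, n)
  )
}

# A small fast study scenario used by several end-to-end tests.
small_sim_config <- function(seed = 1, noise = "none", ...) {
  args <- list(n_autosomes = 5, n_x_contigs = 2, n_y_contigs = 2,
               contig_length_range = c(15e4, 25e4), window_size = 5e4,
               seed = seed, noise = noise)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

run_recovery <- function(seed, noise = "poisson", config = NULL) {
  cfg <- if (is.null(config)) sim_config(seed = seed, noise = noise) else config
  g <- generate_genome(cfg)
  tracks <- simulate_study(g)
  res <- classify_sex_linkage(
    g$assembly,
    tracks[startsWith(names(tracks), "male")],
    tracks[startsWith(names(tracks), "female")],
    window_size = cfg$window_size
  )
  m <- dplyr::inner_join(res$calls, g$truth, by = "contig")
  m$expected_call <- c(AUTOSOME = "AUTOSOMAL", X = "X_LINKED",
                       Y = "Y_LINKED")[m$class]
  m
}
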