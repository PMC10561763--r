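test_that("genome generation is deterministic given the seed", {
  cfg <- small_sim_config(seed = 5)
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(g1$assembly, g2$assembly)
  expect_identical(g1$truth, g2$truth)

  f1 <- withr::local_tempfile(fileext = ".fa")
  f2 <- withr::local_tempfile(fileext = ".fa")
  write_fasta(g1$assembly, f1)
  write_fasta(g2$assembly, f2)
  expect_identical(readLines(f1), readLines(f2))

  g3 <- generate_genome(small_sim_config(seed = 6))
  expect_false(identical(g1$assembly$sequence, g3$assembly$sequence))
})

test_that("truth labels and copy counts follow the diploid XY model", {
  g <- generate_genome(small_sim_config(seed = 2))
  expect_equal(nrow(g$truth), 9)
  expect_equal(as.vector(table(g$truth$class)[c("AUTOSOME", "X", "Y")]),
               c(5L, 2L, 2L))
  with(g$truth, {
    expect_true(all(copy_male[class == "AUTOSOME"] == 2 &
                      copy_female[class == "AUTOSOME"] == 2))
    expect_true(all(copy_male[class == "X"] == 1 &
                      copy_female[class == "X"] == 2))
    expect_true(all(copy_male[class == "Y"] == 1 &
                      copy_female[class == "Y"] == 0))
  })
  g0 <- generate_genome(small_sim_config(seed = 2, n_y_contigs = 0))
  expect_false(any(g0$truth$class == "Y"))
})

test_that("allelic duplicates have the configured length fraction", {
  cfg <- small_sim_config(seed = 3, allelic_fraction = 0.25)
  g <- generate_genome(cfg)
  expect_equal(nrow(g$allelic_pairs), 2)  # 25% of 9 contigs, rounded
  for (i in seq_len(nrow(g$allelic_pairs))) {
    src_len <- g$assembly$length[g$assembly$contig == g$allelic_pairs$primary[i]]
    dup_len <- g$assembly$length[g$assembly$contig == g$allelic_pairs$duplicate[i]]
    expect_equal(dup_len, round(0.9 * src_len))
  }
  expect_true(all(g$truth$is_duplicate[g$truth$contig %in%
                                         g$allelic_pairs$duplicate]))
})

test_that("noise-free, bias-free depth equals mean_depth * copy / 2 exactly", {
  cfg <- small_sim_config(seed = 4, noise = "none", gc_bias_strength = 0)
  g <- generate_genome(cfg)
  cls <- stats::setNames(g$truth$class, g$truth$contig)
  for (sex in c("male", "female")) {
    trk <- simulate_depth(g, sex)
    expected <- 30 * copy_count(unname(cls[trk$contig]), sex) / 2
    expect_equal(trk$depth, expected)
  }
})

test_that("female Y-contig depth is identically zero under any noise law", {
  for (noise in c("poisson", "nbinom")) {
    cfg <- small_sim_config(seed = 8, noise = noise)
    g <- generate_genome(cfg)
    trk <- simulate_depth(g, "female")
    y <- g$truth$contig[g$truth$class == "Y"]
    expect_true(all(trk$depth[trk$contig %in% y] == 0))
    expect_true(any(trk$depth[!trk$contig %in% y] > 0))
  }
})

test_that("Poisson window depths average to the configured mean", {
  # law of large numbers: ~1000 windows of an all-autosome genome
  cfg <- sim_config(n_autosomes = 2, n_x_contigs = 0, n_y_contigs = 0,
                    contig_length_range = c(5e5, 5e5), window_size = 1e3,
                    gc_bias_strength = 0, noise = "poisson", seed = 7)
  g <- generate_genome(cfg)
  trk <- simulate_depth(g, "male")
  n <- nrow(trk)
  se <- sqrt(30 / n)
  expect_lt(abs(mean(trk$depth) - 30), 3 * se)
  # and the variance is Poisson-like, not degenerate
  expect_gt(stats::var(trk$depth), 30 * 0.7)
  expect_lt(stats::var(trk$depth), 30 * 1.3)
})

test_that("negative-binomial noise is over-dispersed relative to Poisson", {
  cfg <- sim_config(n_autosomes = 2, n_x_contigs = 0, n_y_contigs = 0,
                    contig_length_range = c(5e5, 5e5), window_size = 1e3,
                    gc_bias_strength = 0, noise = "nbinom",
                    nb_dispersion = 0.05, seed = 7)
  g <- generate_genome(cfg)
  trk <- simulate_depth(g, "male")
  # var = mu + 0.05 * mu^2 = 30 + 45 = 75
  expect_gt(stats::var(trk$depth), 55)
  expect_lt(stats::var(trk$depth), 100)
})

test_that("simulated tracks round-trip through bedgraph files", {
  cfg <- small_sim_config(seed = 9, noise = "poisson")
  g <- generate_genome(cfg)
  trk <- simulate_depth(g, "male")
  bg <- withr::local_tempfile(fileext = ".bedgraph")
  write_bedgraph(trk, bg)
  back <- read_bedgraph(bg, g$assembly)
  expect_equal(back$depth, trk$depth, tolerance = 1e-8)
  expect_equal(back[, c("contig", "start", "end")],
               trk[, c("contig", "start", "end")])
})

test_that("invalid simulation requests are rejected", {
  expect_error(sim_config(n_autosomes = 0, n_x_contigs = 0, n_y_contigs = 0),
               "at least one contig")
  expect_error(sim_config(mean_depth = 0), "mean_depth")
  g <- generate_genome(small_sim_config(seed = 1))
  expect_error(simulate_depth(g, "unknown"), "arg")
})
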