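test_that("canonical k-mer counting matches strand enumeration", {
  set.seed(31)
  for (i in 1:30) {
    n <- sample(15:100, 1)
    chars <- sample(c("A", "C", "G", "T", "N"), n, replace = TRUE,
                    prob = c(0.24, 0.24, 0.24, 0.24, 0.04))
    s <- paste(chars, collapse = "")
    k <- sample(c(11, 13), 1)
    expect_equal(sort(contig_kmers(s, k)),
                 sort(oracle_canonical_kmers(s, k)),
                 info = paste("seq", i))
  }
  # too-short sequences yield no k-mers
  expect_length(contig_kmers("ACGTACGT", 21), 0)
})

test_that("the index classifies k-mers by assembly-wide count", {
  set.seed(32)
  a <- random_assembly(n = 1, len_range = c(60, 60))$sequence
  asm <- tibble::tibble(contig = c("c1", "c2", "c3"),
                        sequence = c(a, a, strrep("A", 40)),
                        length = c(60, 60, 40))
  idx <- build_kmer_index(asm, k = 11)
  # twin contigs: every k-mer from them occurs exactly twice
  twins <- idx$kmers$kmer %in% contig_kmers(a, 11)
  expect_true(all(idx$kmers$class[twins] == "duo"))
  # poly-A: one k-mer occurring 30 times
  polya <- idx$kmers[idx$kmers$kmer == strrep("A", 11), ]
  expect_equal(polya$count, 30)
  expect_equal(polya$class, "repeat")
  expect_error(build_kmer_index(asm, k = 12), "odd")
  expect_error(build_kmer_index(asm, k = 9), "\\[11, 31\\]")
})

test_that("k-mer classification does not depend on contig order", {
  asm <- random_assembly(n = 4, len_range = c(100, 200), seed = 33)
  idx1 <- build_kmer_index(asm, k = 11)
  idx2 <- build_kmer_index(asm[c(3, 1, 4, 2), ], k = 11)
  expect_equal(dplyr::arrange(idx1$kmers, kmer),
               dplyr::arrange(idx2$kmers, kmer))
})

test_that("identical twins pair with similarity 1, unrelated contigs do not", {
  set.seed(34)
  a <- random_assembly(n = 1, len_range = c(5000, 5000))$sequence
  b <- random_assembly(n = 1, len_range = c(5000, 5000))$sequence
  asm <- tibble::tibble(contig = c("t1", "t2", "r1"),
                        sequence = c(a, a, b),
                        length = nchar(c(a, a, b)))
  graph <- find_allelic_pairs(build_kmer_index(asm, 21), asm)
  pair <- graph$pairs[graph$pairs$a == "t1" & graph$pairs$b == "t2", ]
  expect_equal(pair$s, 1)
  expect_true(pair$edge)
  others <- graph$pairs[!(graph$pairs$a == "t1" & graph$pairs$b == "t2"), ]
  expect_true(all(others$s < 0.05) || nrow(others) == 0)
})

test_that("a 1% diverged haplotig at 90% length still pairs at default t", {
  set.seed(35)
  src <- random_assembly(n = 1, len_range = c(20000, 20000))$sequence
  dup <- sexlinkr:::mutate_sequence(substr(src, 1, 18000), 0.01)
  asm <- tibble::tibble(contig = c("p", "h"), sequence = c(src, dup),
                        length = nchar(c(src, dup)))
  graph <- find_allelic_pairs(build_kmer_index(asm, 21), asm)
  expect_gte(graph$pairs$s[1], 0.6)
  expect_true(graph$pairs$edge[1])
})

test_that("primary selection keeps the longest contig of each pair/chain", {
  mk_graph <- function(edges, lengths) {
    structure(list(
      pairs = dplyr::mutate(edges, shared = 1, s = 1, edge = TRUE),
      t = 0.6,
      lengths = tibble::tibble(contig = names(lengths),
                               length = unname(lengths))
    ), class = "allelic_graph")
  }
  sel <- select_primary(mk_graph(tibble::tibble(a = "p", b = "h"),
                                 c(p = 100000, h = 90000)))
  expect_equal(sel$primary, "p")
  expect_equal(sel$purged, "h")

  # chain a-b-c with lengths 90, 100, 95: keep b, purge both neighbours
  sel2 <- select_primary(mk_graph(
    tibble::tibble(a = c("a", "b"), b = c("b", "c")),
    c(a = 90, b = 100, c = 95)
  ))
  expect_equal(sel2$primary, "b")
  expect_equal(sort(sel2$purged), c("a", "c"))

  # no edges: everything is primary
  sel3 <- select_primary(mk_graph(
    tibble::tibble(a = character(), b = character()), c(x = 10, y = 20)))
  expect_equal(sort(sel3$primary), c("x", "y"))
})

test_that("primary selection matches the recursive oracle on small graphs", {
  check_graph <- function(adj, lengths, ids) {
    edges <- which(upper.tri(adj) & adj, arr.ind = TRUE)
    g <- structure(list(
      pairs = tibble::tibble(a = ids[edges[, 1]], b = ids[edges[, 2]],
                             shared = 1, s = 1, edge = TRUE),
      t = 0.6,
      lengths = tibble::tibble(contig = ids, length = lengths)
    ), class = "allelic_graph")
    sel <- select_primary(g)
    expect_equal(sort(sel$primary), oracle_select_primary(adj, lengths, ids))
    expect_true(oracle_is_maximal_independent(
      adj, ids %in% sel$primary))
    expect_setequal(c(sel$primary, sel$purged), ids)
  }
  # exhaustive over all graphs on 4 nodes (two length profiles, with ties)
  ids4 <- c("a", "b", "c", "d")
  pairs4 <- t(utils::combn(4, 2))
  for (lengths in list(c(40, 30, 20, 10), c(30, 30, 20, 20))) {
    for (mask in 0:(2^nrow(pairs4) - 1)) {
      adj <- matrix(FALSE, 4, 4)
      on <- which(bitwAnd(mask, 2^(seq_len(nrow(pairs4)) - 1)) > 0)
      for (e in on) {
        adj[pairs4[e, 1], pairs4[e, 2]] <- TRUE
        adj[pairs4[e, 2], pairs4[e, 1]] <- TRUE
      }
      check_graph(adj, lengths, ids4)
    }
  }
  # random graphs on 6-8 nodes
  set.seed(36)
  for (i in 1:60) {
    n <- sample(6:8, 1)
    ids <- letters[seq_len(n)]
    adj <- matrix(stats::runif(n * n) < 0.35, n, n)
    adj[lower.tri(adj, diag = TRUE)] <- FALSE
    adj <- adj | t(adj)
    lengths <- sample(10:60, n, replace = TRUE)
    check_graph(adj, lengths, ids)
  }
})

test_that("purging removes simulated haplotigs and is idempotent", {
  cfg <- sim_config(n_autosomes = 16, n_x_contigs = 2, n_y_contigs = 2,
                    contig_length_range = c(3e4, 6e4),
                    allelic_fraction = 0.1, seed = 37)
  g <- generate_genome(cfg)
  res <- purge_assembly(g$assembly)
  expect_setequal(res$purged$contig, g$allelic_pairs$duplicate)
  expect_setequal(res$primary$contig, g$truth$contig[!g$truth$is_duplicate])
  truth_bp <- sum(g$assembly$length[!g$truth$is_duplicate])
  expect_lt(abs(sum(res$primary$length) / truth_bp - 1), 0.02)
  expect_lte(sum(res$primary$length), sum(g$assembly$length))
  # second pass purges nothing
  res2 <- purge_assembly(res$primary)
  expect_equal(nrow(res2$purged), 0)
})
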