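#' Canonical k-mers of a single sequence
#'
#' Every length-k substring over A/C/G/T is reported in canonical form (the
#' lexicographic minimum of the k-mer and its reverse complement); k-mers
#' containing N are skipped. One element per occurrence.
#'
#' @param sequence Uppercase sequence string.
#' @param k Odd k-mer size.
#' @return Character vector of canonical k-mers (possibly empty).
#' @export
contig_kmers <- function(sequence, k) {
  n <- nchar(sequence)
  if (n < k) return(character(0))
  fwd <- substring(sequence, 1:(n - k + 1), k:n)
  rcseq <- reverse_complement(sequence)
  # reverse complement of the k-mer at (1-based) i..i+k-1 sits at
  # n-i-k+2 .. n-i+1 in the reverse-complemented sequence
  i <- 1:(n - k + 1)
  rc <- substring(rcseq, n - i - k + 2, n - i + 1)
  keep <- !grepl("N", fwd, fixed = TRUE)
  pmin(fwd[keep], rc[keep])
}

#' Build a canonical k-mer index over an assembly
#'
#' Counts every canonical k-mer occurrence across all contigs and classes
#' each distinct k-mer by its assembly-wide occurrence count: `unique`
#' (count 1), `duo` (count 2) or `repeat` (count >= 3). Only non-repeat
#' (unique + duo) k-mers carry haplotype information; duo k-mers are the
#' currency of allelic-pair detection. `k` must be odd so no k-mer can be
#' its own reverse complement.
#'
#' @param assembly Contig table (`contig`, `sequence`).
#' @param k Odd k-mer size in \[11, 31\] (default 21).
#' @return A `kmer_index` with `occurrences` (tibble: `contig`, `kmer`,
#'   `n` occurrences of that k-mer in that contig), `kmers` (tibble:
#'   `kmer`, `count`, `class`) and `k`.
#' @export
build_kmer_index <- function(assembly, k = 21) {
  if (k %% 2 == 0) {
    stop("k must be odd (even k allows reverse-complement palindromes)",
         call. = FALSE)
  }
  if (k < 11 || k > 31) stop("k must be in [11, 31]", call. = FALSE)
  occ <- purrr::map2_dfr(assembly$contig, assembly$sequence, function(id, s) {
    km <- contig_kmers(s, k)
    if (length(km) == 0) {
      return(tibble::tibble(contig = character(), kmer = character(),
                            n = integer()))
    }
    dplyr::count(tibble::tibble(contig = id, kmer = km),
                 .data$contig, .data$kmer, name = "n")
  })
  kmers <- occ |>
    dplyr::group_by(.data$kmer) |>
    dplyr::summarise(count = sum(.data$n), .groups = "drop") |>
    dplyr::mutate(class = dplyr::case_when(
      .data$count == 1 ~ "unique",
      .data$count == 2 ~ "duo",
      TRUE ~ "repeat"
    ))
  structure(list(occurrences = occ, kmers = kmers, k = k),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat("<kmer_index> k = ", x$k, ", ", nrow(x$kmers), " distinct k-mers (",
      paste(names(table(x$kmers$class)), table(x$kmers$class),
            sep = ": ", collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Detect allelic contig pairs by shared duo k-mers
#'
#' Scores every contig pair that shares duo k-mers (k-mers occurring
#' exactly twice assembly-wide; repeat k-mers are ignored, the "non-repeat"
#' qualifier) with `s(a, b) = shared duo k-mers / duo k-mers of the shorter
#' contig`, so a short haplotig fully contained in its primary scores near
#' 1. Pairs with `s >= t` become edges of the allelic graph, provided they
#' share at least `min_shared` duo k-mers: a contig without an allelic
#' partner has almost no duo k-mers at all, so its ratio denominator is
#' tiny and a single chance collision would otherwise score `s = 1`.
#'
#' @param index A `kmer_index` built on these contigs.
#' @param assembly Contig table (`contig`, `length`).
#' @param t Pairing threshold on `s` (default 0.6).
#' @param min_shared Minimum shared duo k-mers for an edge (default 50;
#'   genuine haplotig pairs share duo k-mers across most of the shorter
#'   contig).
#' @return An `allelic_graph` with `pairs` (tibble: `a`, `b`, `shared`,
#'   `s`, `edge`), `t` and the contig `lengths`.
#' @export
find_allelic_pairs <- function(index, assembly, t = 0.6, min_shared = 50) {
  stopifnot(inherits(index, "kmer_index"))
  duo <- dplyr::filter(index$kmers, .data$class == "duo")$kmer
  occ <- dplyr::filter(index$occurrences, .data$kmer %in% duo)
  if (nrow(occ) == 0) {
    return(structure(list(
      pairs = tibble::tibble(a = character(), b = character(),
                             shared = integer(), s = numeric(),
                             edge = logical()),
      t = t,
      lengths = tibble::tibble(contig = assembly$contig,
                               length = assembly$length)
    ), class = "allelic_graph"))
  }
  duo_per_contig <- occ |>
    dplyr::distinct(.data$contig, .data$kmer) |>
    dplyr::count(.data$contig, name = "n_duo")
  # a duo k-mer seen once in each of two distinct contigs links them
  cross <- occ |>
    dplyr::group_by(.data$kmer) |>
    dplyr::filter(dplyr::n() == 2) |>
    dplyr::summarise(a = min(.data$contig), b = max(.data$contig),
                     .groups = "drop")
  pairs <- cross |>
    dplyr::count(.data$a, .data$b, name = "shared")
  len <- stats::setNames(assembly$length, assembly$contig)
  nd <- stats::setNames(duo_per_contig$n_duo, duo_per_contig$contig)
  pairs <- pairs |>
    dplyr::mutate(
      shorter = ifelse(len[.data$a] <= len[.data$b], .data$a, .data$b),
      s = unname(.data$shared / pmax(nd[.data$shorter], 1)),
      edge = .data$s >= t & .data$shared >= min_shared
    ) |>
    dplyr::select("a", "b", "shared", "s", "edge")
  structure(list(pairs = pairs, t = t,
                 lengths = tibble::tibble(contig = assembly$contig,
                                          length = assembly$length)),
            class = "allelic_graph")
}

#' @export
print.allelic_graph <- function(x, ...) {
  cat("<allelic_graph> ", nrow(x$lengths), " contigs, ",
      sum(x$pairs$edge), " allelic edge(s) at t = ", x$t, "\n", sep = "")
  invisible(x)
}

#' Select primary contigs from the allelic graph
#'
#' Within each connected component of the allelic graph the longest contig
#' is kept and its neighbours purged, recursing on the remainder (ties
#' broken by lexicographic id). Unconnected contigs are always primary.
#' The primary and purged sets partition the contig set, and re-running
#' the selection on the primary set purges nothing further.
#'
#' @param graph An `allelic_graph` from [find_allelic_pairs()].
#' @return A list with character vectors `primary` and `purged`.
#' @export
select_primary <- function(graph) {
  stopifnot(inherits(graph, "allelic_graph"))
  ids <- graph$lengths$contig
  edges <- dplyr::filter(graph$pairs, .data$edge)
  if (nrow(edges) == 0) {
    return(list(primary = ids, purged = character(0)))
  }
  g <- igraph::graph_from_data_frame(edges[, c("a", "b")], directed = FALSE,
                                     vertices = ids)
  # priority order: longest first, lexicographic id on ties; a contig is
  # kept iff none of its higher-priority neighbours was kept
  ord <- order(-graph$lengths$length, graph$lengths$contig)
  keep <- logical(length(ids))
  names(keep) <- ids
  adj <- igraph::adjacent_vertices(g, ids)
  names(adj) <- ids
  for (i in ord) {
    id <- ids[i]
    nb <- names(adj[[id]])
    keep[id] <- !any(keep[nb])
  }
  list(primary = ids[keep[ids]], purged = ids[!keep[ids]])
}

#' Purge allelic (haplotig) contigs from an assembly
#'
#' Convenience wrapper: builds the k-mer index, detects allelic pairs and
#' selects primaries by length.
#'
#' @param assembly Contig table (`contig`, `sequence`, `length`).
#' @param k Odd k-mer size (default 21).
#' @param t Pairing threshold (default 0.6).
#' @param min_shared Minimum shared duo k-mers for a pairing (see
#'   [find_allelic_pairs()]).
#' @return A list with `primary` and `purged` contig tables (subsets of
#'   `assembly`) and the `pairs` tibble.
#' @export
purge_assembly <- function(assembly, k = 21, t = 0.6, min_shared = 50) {
  index <- build_kmer_index(assembly, k)
  graph <- find_allelic_pairs(index, assembly, t, min_shared)
  sel <- select_primary(graph)
  list(
    primary = dplyr::filter(assembly, .data$contig %in% sel$primary),
    purged = dplyr::filter(assembly, .data$contig %in% sel$purged),
    pairs = dplyr::mutate(graph$pairs,
                          decision = ifelse(.data$edge, "purge_shorter",
                                            "keep_both"))
  )
}
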