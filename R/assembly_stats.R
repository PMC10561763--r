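#' Nx / Lx of a set of sequence lengths
#'
#' With lengths sorted in decreasing order, Nx is the length of the
#' sequence at which the cumulative sum first reaches at least x% of the
#' total (the `>=` convention), and Lx is the number of sequences in that
#' cumulative set.
#'
#' @param lengths Non-empty numeric vector of sequence lengths (bp).
#' @param x Percentage in (0, 100\] (default 50).
#' @return A list with elements `nx` (bp) and `lx` (count).
#' @examples
#' nx(c(80, 70, 50, 40, 30, 20, 10))  # N50 = 70, L50 = 2
#' @export
nx <- function(lengths, x = 50) {
  if (length(lengths) == 0) stop("empty length list", call. = FALSE)
  if (x <= 0 || x > 100) stop("x must be in (0, 100]", call. = FALSE)
  sorted <- sort(lengths, decreasing = TRUE)
  cum <- cumsum(sorted)
  lx <- which(cum >= x / 100 * sum(sorted))[1]
  list(nx = sorted[lx], lx = lx)
}

#' Rounded fold ratio between two sizes
#'
#' `round(size_a / size_b, decimals)` with R's round-half-to-even rule;
#' both sizes must share units.
#'
#' @param size_a,size_b Sizes in the same unit; `size_b > 0`.
#' @param decimals Decimal places to round to (default 1).
#' @return The rounded ratio.
#' @examples
#' fold_ratio(116.4, 69.3)  # 1.7
#' @export
fold_ratio <- function(size_a, size_b, decimals = 1) {
  if (any(size_b <= 0)) stop("size_b must be > 0", call. = FALSE)
  round(size_a / size_b, decimals)
}

# GC% over non-N bases of one sequence (counts, not fraction).
count_bases <- function(sequence) {
  r <- charToRaw(sequence)
  c(gc = sum(r == as.raw(71L) | r == as.raw(67L)),
    acgt = sum(r == as.raw(65L) | r == as.raw(67L) |
                 r == as.raw(71L) | r == as.raw(84L)))
}

#' Summary statistics of an assembly
#'
#' Sequence count, total size, N50/L50, longest sequence and GC% (G+C over
#' non-N bases, the standard convention).
#'
#' @param assembly Contig table (`contig`, `sequence`, `length`).
#' @return A one-row tibble: `n_seqs`, `total_bp`, `n50`, `l50`, `longest`,
#'   `gc_percent`.
#' @export
summarize_assembly <- function(assembly) {
  if (nrow(assembly) == 0) stop("empty assembly", call. = FALSE)
  half <- nx(assembly$length, 50)
  counts <- rowSums(vapply(assembly$sequence, count_bases, numeric(2)))
  tibble::tibble(
    n_seqs = nrow(assembly),
    total_bp = sum(assembly$length),
    n50 = half$nx,
    l50 = half$lx,
    longest = max(assembly$length),
    gc_percent = unname(100 * counts["gc"] / counts["acgt"])
  )
}

#' Per-class size breakdown of an assembly
#'
#' @param assembly Contig table (`contig`, `length`).
#' @param class_map Tibble mapping `contig` to `class` (contigs missing
#'   from the map are reported as `unannotated`).
#' @return A tibble: `class`, `n_contigs`, `bp`, `fraction_percent` (of
#'   total assembly bp; fractions sum to 100 including `unannotated`).
#' @export
class_summary <- function(assembly, class_map) {
  total <- sum(assembly$length)
  assembly |>
    dplyr::left_join(dplyr::select(class_map, "contig", "class"),
                     by = "contig") |>
    dplyr::mutate(class = dplyr::coalesce(.data$class, "unannotated")) |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(n_contigs = dplyr::n(), bp = sum(.data$length),
                     .groups = "drop") |>
    dplyr::mutate(fraction_percent = 100 * .data$bp / total)
}

#' Write assembly statistics as an aligned text table and/or TSV
#'
#' @param stats A one-row tibble from [summarize_assembly()].
#' @param path Output path for the TSV (`NULL` to skip).
#' @return The formatted text lines, invisibly.
#' @export
write_assembly_stats <- function(stats, path = NULL) {
  labels <- c(n_seqs = "Number of sequences",
              total_bp = "Total size (bp)",
              n50 = "N50 (bp)",
              l50 = "L50",
              longest = "Longest sequence (bp)",
              gc_percent = "G+C contents (%)")
  vals <- unlist(stats[1, names(labels)])
  text <- sprintf("%-24s %s", labels,
                  ifelse(names(labels) == "gc_percent",
                         sprintf("%.1f", vals),
                         format(vals, big.mark = ",", trim = TRUE)))
  if (!is.null(path)) readr::write_tsv(stats, path)
  invisible(text)
}
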