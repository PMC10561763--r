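#' Read an assembly FASTA into a contig table
#'
#' Reads a (possibly multi-line) FASTA file and returns one row per record.
#' Sequences are uppercased and validated against the strict assembly
#' alphabet `{A, C, G, T, N}`; IUPAC ambiguity codes other than `N` are
#' rejected rather than coerced so that downstream GC computation stays
#' well defined. Record order is preserved and the contig id is the FASTA
#' header truncated at the first whitespace.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `contig` (character), `sequence`
#'   (character, uppercase) and `length` (integer bp).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">c1 description", "acgt", "NN"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  if (file.size(path) == 0) {
    stop("no records in FASTA file: ", path, call. = FALSE)
  }
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0) {
    stop("no records in FASTA file: ", path, call. = FALSE)
  }
  ids <- sub("\\s.*$", "", names(recs))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    stop("duplicate contig id(s) in FASTA: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  seqs <- unname(toupper(as.character(recs)))
  bad <- regexpr("[^ACGTN]", seqs)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop("invalid character '", substring(seqs[i], bad[i], bad[i]),
         "' in contig '", ids[i], "' at position ", bad[i],
         " (only A, C, G, T, N are accepted)", call. = FALSE)
  }
  if (any(nchar(seqs) == 0)) {
    stop("empty sequence for contig '", ids[which(nchar(seqs) == 0)[1]], "'",
         call. = FALSE)
  }
  tibble::tibble(
    contig = unname(ids),
    sequence = seqs,
    length = nchar(seqs)
  )
}

#' Write a contig table to FASTA
#'
#' @param assembly A tibble with columns `contig` and `sequence`
#'   (as returned by [read_fasta()] or [generate_genome()]).
#' @param path Output file path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(assembly, path, width = 70L) {
  stopifnot(all(c("contig", "sequence") %in% names(assembly)))
  x <- Biostrings::DNAStringSet(stats::setNames(assembly$sequence,
                                                assembly$contig))
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Tile a contig with fixed-size windows
#'
#' Produces consecutive half-open `[start, end)` intervals (0-based) of
#' width `window_size`; the final window is truncated at the contig end so
#' the windows partition `[0, contig_length)` exactly. An optional
#' `step < window_size` yields overlapping (sliding) windows; the pipeline
#' default is the tiling partition (step = width) because overlapping
#' windows would double-count depth in contig-level medians.
#'
#' @param contig_length Contig length in bp (>= 1).
#' @param window_size Window width in bp (>= 1; default 100 kb).
#' @param step Distance between successive window starts (default
#'   `window_size`, i.e. non-overlapping tiling).
#' @return A tibble with columns `start`, `end`.
#' @examples
#' make_windows(250000, 100000)
#' @export
make_windows <- function(contig_length, window_size = 1e5, step = window_size) {
  if (length(contig_length) != 1 || is.na(contig_length) || contig_length < 1) {
    stop("contig_length must be a positive integer", call. = FALSE)
  }
  if (length(window_size) != 1 || is.na(window_size) || window_size < 1) {
    stop("window_size must be a positive integer", call. = FALSE)
  }
  if (length(step) != 1 || is.na(step) || step < 1 || step > window_size) {
    stop("step must be in [1, window_size]", call. = FALSE)
  }
  starts <- seq(0, contig_length - 1, by = step)
  tibble::tibble(
    start = starts,
    end = pmin(starts + window_size, contig_length)
  )
}

#' Tile every contig of an assembly
#'
#' @param assembly Contig table with columns `contig`, `length`.
#' @inheritParams make_windows
#' @return A tibble with columns `contig`, `start`, `end`.
#' @export
tile_assembly <- function(assembly, window_size = 1e5, step = window_size) {
  purrr::map2_dfr(assembly$contig, assembly$length, function(id, len) {
    dplyr::mutate(make_windows(len, window_size, step), contig = id,
                  .before = 1)
  })
}

#' Read a 4-column bedgraph depth track
#'
#' Parses whitespace- or tab-delimited records `(contig, start, end, depth)`
#' with 0-based half-open coordinates and validates them against the
#' assembly: unknown contigs, intervals extending past the contig end,
#' overlapping records and negative depths are errors. Positions not
#' covered by any record have depth 0.
#'
#' @param path Path to a bedgraph file (may be empty: a zero-coverage track).
#' @param assembly Contig table the track refers to (columns `contig`,
#'   `length`).
#' @return A depth-track tibble with columns `contig`, `start`, `end`,
#'   `depth`, sorted by contig then start.
#' @export
read_bedgraph <- function(path, assembly) {
  if (!file.exists(path)) {
    stop("bedgraph file not found: ", path, call. = FALSE)
  }
  if (file.size(path) == 0) {
    return(tibble::tibble(contig = character(), start = numeric(),
                          end = numeric(), depth = numeric()))
  }
  raw <- utils::read.table(path, header = FALSE, comment.char = "#",
                           colClasses = c("character", "numeric", "numeric",
                                          "numeric"))
  names(raw) <- c("contig", "start", "end", "depth")
  track <- tibble::as_tibble(raw)
  validate_track(track, assembly)
  dplyr::arrange(track, .data$contig, .data$start)
}

validate_track <- function(track, assembly) {
  unknown <- setdiff(unique(track$contig), assembly$contig)
  if (length(unknown) > 0) {
    stop("depth track references unknown contig(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (any(track$start < 0) || any(track$end <= track$start)) {
    stop("malformed interval: need 0 <= start < end", call. = FALSE)
  }
  if (any(track$depth < 0)) {
    stop("negative depth in track", call. = FALSE)
  }
  len <- stats::setNames(assembly$length, assembly$contig)
  over <- track$end > len[track$contig]
  if (any(over)) {
    i <- which(over)[1]
    stop("record on '", track$contig[i], "' ends at ", track$end[i],
         " beyond contig length ", len[track$contig[i]], call. = FALSE)
  }
  ov <- track |>
    dplyr::arrange(.data$contig, .data$start) |>
    dplyr::group_by(.data$contig) |>
    dplyr::filter(dplyr::row_number() > 1 &
                    .data$start < dplyr::lag(.data$end)) |>
    dplyr::ungroup()
  if (nrow(ov) > 0) {
    stop("overlapping depth records on contig '", ov$contig[1], "' near ",
         ov$start[1], call. = FALSE)
  }
  invisible(track)
}

#' Write a depth track (or window table) as bedgraph
#'
#' Emits tab-delimited `(contig, start, end, depth)` records with depths
#' serialized to 4 decimal places; a written track read back with
#' [read_bedgraph()] yields identical per-window mean depths at that
#' precision.
#'
#' @param track Tibble with columns `contig`, `start`, `end` and either
#'   `depth` or `raw_depth`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  depth <- if ("depth" %in% names(track)) track$depth else track$raw_depth
  lines <- sprintf("%s\t%d\t%d\t%.4f", track$contig,
                   as.integer(track$start), as.integer(track$end), depth)
  writeLines(lines, path)
  invisible(path)
}

#' Mean per-base depth of windows under a depth track
#'
#' Computes, for each query window, the coverage-weighted mean depth of the
#' track records overlapping it (uncovered positions count as depth 0).
#'
#' @param windows Tibble with columns `contig`, `start`, `end`.
#' @param track Depth-track tibble from [read_bedgraph()] (or simulated).
#' @return Numeric vector of mean depths, one per window row.
#' @export
window_mean_depth <- function(windows, track) {
  depth <- numeric(nrow(windows))
  if (nrow(windows) == 0 || nrow(track) == 0) {
    return(depth)
  }
  for (ctg in unique(windows$contig)) {
    wi <- which(windows$contig == ctg)
    ri <- which(track$contig == ctg)
    if (length(ri) == 0) next
    w_ir <- IRanges::IRanges(start = windows$start[wi] + 1, end = windows$end[wi])
    r_ir <- IRanges::IRanges(start = track$start[ri] + 1, end = track$end[ri])
    ov <- IRanges::findOverlaps(w_ir, r_ir)
    if (length(ov) == 0) next
    q <- S4Vectors::queryHits(ov)
    s <- S4Vectors::subjectHits(ov)
    inter <- IRanges::pintersect(w_ir[q], r_ir[s])
    contrib <- IRanges::width(inter) * track$depth[ri][s]
    sums <- rowsum(contrib, q)
    idx <- as.integer(rownames(sums))
    depth[wi[idx]] <- sums[, 1] / (windows$end[wi[idx]] - windows$start[wi[idx]])
  }
  depth
}
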