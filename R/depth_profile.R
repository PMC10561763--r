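#' GC fraction of one window of a contig
#'
#' GC is `(#G + #C) / (#A + #C + #G + #T)` over the window; `N` bases are
#' excluded from the denominator, and the value is undefined (`NA`) for an
#' all-N window.
#'
#' @param sequence Contig sequence (uppercase A/C/G/T/N).
#' @param start,end Half-open 0-based window coordinates within the contig.
#' @return GC fraction in \[0, 1\], or `NA` for an all-N window.
#' @examples
#' window_gc("ATGCNN", 0, 6)  # 0.5
#' @export
window_gc <- function(sequence, start, end) {
  n <- nchar(sequence)
  if (start < 0 || end <= start || end > n) {
    stop("window [", start, ", ", end, ") out of bounds for contig of length ",
         n, call. = FALSE)
  }
  assembly_window_gc(
    tibble::tibble(contig = "x", sequence = sequence),
    tibble::tibble(contig = "x", start = start, end = end)
  )
}

# Vectorized per-window GC over an assembly, via cumulative base counts.
# Returns NA where the window contains no A/C/G/T.
assembly_window_gc <- function(assembly, windows) {
  gc <- rep(NA_real_, nrow(windows))
  for (i in seq_len(nrow(assembly))) {
    wi <- which(windows$contig == assembly$contig[i])
    if (length(wi) == 0) next
    r <- charToRaw(assembly$sequence[i])
    is_gc <- r == as.raw(71L) | r == as.raw(67L)
    is_base <- is_gc | r == as.raw(65L) | r == as.raw(84L)
    cg <- c(0, cumsum(is_gc))
    cb <- c(0, cumsum(is_base))
    s <- windows$start[wi]
    e <- windows$end[wi]
    gcn <- cg[e + 1] - cg[s + 1]
    bn <- cb[e + 1] - cb[s + 1]
    gc[wi] <- ifelse(bn > 0, gcn / bn, NA_real_)
  }
  gc
}

# Fraction of N bases per window (used for the exclusion flag).
assembly_window_nfrac <- function(assembly, windows) {
  nfrac <- rep(NA_real_, nrow(windows))
  for (i in seq_len(nrow(assembly))) {
    wi <- which(windows$contig == assembly$contig[i])
    if (length(wi) == 0) next
    r <- charToRaw(assembly$sequence[i])
    cn <- c(0, cumsum(r == as.raw(78L)))
    s <- windows$start[wi]
    e <- windows$end[wi]
    nfrac[wi] <- (cn[e + 1] - cn[s + 1]) / (e - s)
  }
  nfrac
}

#' Build the per-window GC/depth table for one sample
#'
#' Tiles every contig of the assembly with fixed-size windows and attaches
#' the window GC fraction and the mean raw depth under the sample's depth
#' track. Windows with more than `max_n_fraction` N bases (or undefined GC)
#' are flagged `excluded`: they are left out of GC-model fitting and of the
#' global depth baseline, but still receive a corrected depth later so
#' gappy contigs are never silently dropped.
#'
#' @param assembly Contig table (`contig`, `sequence`, `length`).
#' @param track Depth-track tibble (see [read_bedgraph()]).
#' @param window_size Window width in bp (default 100 kb).
#' @param sample_id Sample identifier carried through the pipeline.
#' @param sex `"male"` or `"female"`.
#' @param max_n_fraction Windows with a larger N fraction are flagged
#'   excluded (default 0.5).
#' @return A window-table tibble: `sample_id`, `sex`, `contig`, `start`,
#'   `end`, `gc`, `raw_depth`, `excluded`.
#' @export
profile_sample <- function(assembly, track, window_size = 1e5,
                           sample_id = "sample",
                           sex = c("male", "female"),
                           max_n_fraction = 0.5) {
  sex <- match.arg(sex)
  validate_track(track, assembly)
  windows <- tile_assembly(assembly, window_size)
  gc <- assembly_window_gc(assembly, windows)
  nfrac <- assembly_window_nfrac(assembly, windows)
  tibble::tibble(
    sample_id = sample_id,
    sex = sex,
    contig = windows$contig,
    start = windows$start,
    end = windows$end,
    gc = gc,
    raw_depth = window_mean_depth(windows, track),
    excluded = nfrac > max_n_fraction | is.na(gc)
  )
}

#' Global depth baseline of a window table
#'
#' The length-weighted mean depth over non-excluded windows; the level all
#' copy-number estimates of the sample are referred to.
#'
#' @param table A window table from [profile_sample()] (or one extended
#'   with `corrected_depth`).
#' @param column Which depth column to average (default `raw_depth`).
#' @return A single number.
#' @export
global_raw_mean <- function(table, column = "raw_depth") {
  keep <- !table$excluded
  if (!any(keep)) stop("no non-excluded windows in table", call. = FALSE)
  stats::weighted.mean(table[[column]][keep],
                       (table$end - table$start)[keep])
}

#' Write a window table as TSV
#'
#' @param table A window table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_window_table <- function(table, path) {
  readr::write_tsv(table, path)
  invisible(path)
}
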