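#' Window copy number from corrected depth
#'
#' `cn = 2 * corrected_depth / baseline_depth`, so that an ordinary diploid
#' window has cn ~ 2, a locus present as a single copy has cn ~ 1 and an
#' absent locus has cn 0. The diploid x2 scaling makes "single copy" and
#' "twofold" read literally off the cn values.
#'
#' @param corrected_depth Corrected depth value(s), >= 0.
#' @param baseline_depth The sample's depth baseline (> 0), normally its
#'   global length-weighted mean depth.
#' @return Copy-number estimate(s).
#' @examples
#' window_cn(15, 30)  # 1: single copy
#' @export
window_cn <- function(corrected_depth, baseline_depth) {
  if (length(baseline_depth) != 1 || is.na(baseline_depth) ||
      baseline_depth <= 0) {
    stop("baseline_depth must be a single positive number", call. = FALSE)
  }
  2 * corrected_depth / baseline_depth
}

#' Add per-window copy numbers to a corrected window table
#'
#' @param table A corrected window table (see [correct_depth()]).
#' @param baseline Either a positive number, or the statistic of the
#'   sample's raw window depths to use as the overall sequencing depth:
#'   `"mean"` (default; the length-weighted mean over non-excluded
#'   windows) or `"median"` (length-weighted median, robust to extreme
#'   high-copy windows). The GC model anchors corrected depth to the
#'   diploid component of the sample, so dividing corrected depth by the
#'   raw overall depth puts ordinary diploid windows at cn 2 even when a
#'   large fraction of the assembly is sex-linked.
#' @param column Depth column to convert (default `corrected_depth`).
#' @return The table with a `cn` column appended.
#' @export
add_copy_number <- function(table, baseline = c("mean", "median"),
                            column = "corrected_depth") {
  if (is.numeric(baseline)) {
    b <- baseline
  } else {
    baseline <- match.arg(baseline)
    keep <- !table$excluded
    b <- switch(baseline,
      mean = global_raw_mean(table),
      median = weighted_median(table$raw_depth[keep],
                               (table$end - table$start)[keep])
    )
  }
  dplyr::mutate(table, cn = window_cn(.data[[column]], b))
}

weighted_median <- function(x, w) {
  weighted_quantile(x, w, 0.5)
}

weighted_quantile <- function(x, w, q) {
  o <- order(x)
  cw <- cumsum(w[o]) / sum(w)
  x[o][which(cw >= q)[1]]
}

#' Summarise copy number per contig
#'
#' Aggregates window copy numbers to one estimate per contig using the
#' median over non-excluded windows (the median resists collapsed-repeat
#' windows and mapping pileups; an even window count averages the central
#' pair). Contigs with fewer than `min_windows` usable windows are flagged
#' `low_evidence`; contigs with none are unclassifiable (`median_cn` NA).
#'
#' @param table A window table with a `cn` column (see [add_copy_number()]).
#' @param min_windows Minimum usable windows for a confident call
#'   (default 3).
#' @return A tibble: `contig`, `median_cn`, `n_windows`, `mad_cn`
#'   (unscaled median absolute deviation), `low_evidence`.
#' @export
contig_cn <- function(table, min_windows = 3) {
  table |>
    dplyr::group_by(.data$contig) |>
    dplyr::summarise(
      median_cn = if (any(!.data$excluded))
        stats::median(.data$cn[!.data$excluded]) else NA_real_,
      n_windows = sum(!.data$excluded),
      mad_cn = if (any(!.data$excluded))
        stats::mad(.data$cn[!.data$excluded], constant = 1) else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::mutate(low_evidence = .data$n_windows < min_windows)
}

#' Combine replicate copy-number profiles of one sex
#'
#' Averages per-window copy numbers across samples sharing an identical
#' window grid (same contigs, starts and ends); a window is excluded in
#' the consensus only if it is excluded in every replicate.
#'
#' @param profiles A list of window tables with `cn` columns, all from the
#'   same sex and windowing.
#' @return A consensus window table (`sample_id` concatenates the inputs).
#' @export
combine_replicates <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  base <- profiles[[1]]
  for (p in profiles[-1]) {
    if (nrow(p) != nrow(base) ||
        !all(p$contig == base$contig & p$start == base$start &
               p$end == base$end)) {
      stop("window grids differ between replicate profiles", call. = FALSE)
    }
    if (!all(p$sex == base$sex)) {
      stop("replicate profiles must share one sex", call. = FALSE)
    }
  }
  cn_mat <- vapply(profiles, function(p) p$cn, numeric(nrow(base)))
  cn_mat <- matrix(cn_mat, nrow = nrow(base))
  excl_mat <- matrix(vapply(profiles, function(p) p$excluded,
                            logical(nrow(base))), nrow = nrow(base))
  dplyr::mutate(base,
    sample_id = paste(vapply(profiles, function(p) p$sample_id[1],
                             character(1)), collapse = "+"),
    cn = rowMeans(cn_mat),
    excluded = apply(excl_mat, 1, all)
  )
}
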