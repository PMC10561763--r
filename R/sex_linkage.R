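#' Thresholds for the sex-linkage classification rules
#'
#' The classification rules themselves are fixed (Y: single copy in males,
#' absent in females; X: twofold female:male copy number with at most a
#' single male copy; autosomal: balanced diploid); these tolerances define
#' how far an estimate may stray from the ideal values. The constructor
#' checks that the default-style rule regions are pairwise disjoint, so at
#' most one rule can fire for any `(cn_male, cn_female)` pair.
#'
#' @param delta_single Tolerance around cn = 1 for the male single-copy
#'   condition (default 0.35).
#' @param absent_max Maximum female cn that still counts as "absent"
#'   (default 0.2).
#' @param ratio_x Acceptable female:male cn ratio interval for an X call
#'   (default `c(1.6, 2.4)`, i.e. twofold +/- 20%).
#' @param delta_autosome Tolerance around ratio 1 for the autosomal call;
#'   both cn must also lie within `2 +/- delta_autosome` (default 0.35,
#'   i.e. a balanced contig must sit near the diploid level to be called
#'   autosomal; a balanced pair at e.g. 1.5/1.5 stays ambiguous).
#' @return A `linkage_thresholds` object.
#' @export
linkage_thresholds <- function(delta_single = 0.35, absent_max = 0.2,
                               ratio_x = c(1.6, 2.4),
                               delta_autosome = 0.35) {
  thr <- structure(list(delta_single = delta_single, absent_max = absent_max,
                        ratio_x = ratio_x, delta_autosome = delta_autosome),
                   class = "linkage_thresholds")
  if (absent_max <= 0 || absent_max >= 1) {
    stop("absent_max must be in (0, 1)", call. = FALSE)
  }
  if (delta_single <= 0 || delta_single >= 1 ||
      delta_autosome <= 0 || delta_autosome >= 1) {
    stop("tolerances must be in (0, 1)", call. = FALSE)
  }
  if (length(ratio_x) != 2 || ratio_x[1] >= ratio_x[2] || ratio_x[1] <= 1) {
    stop("ratio_x must be an increasing interval above 1", call. = FALSE)
  }
  # Pairwise disjointness of the rule regions:
  #  Y vs X: split by the absent_max boundary on cn_female (by construction).
  #  Y vs A: the autosomal region needs cn_female >= 2 - delta_autosome.
  if (absent_max >= 2 - delta_autosome) {
    stop("rules overlap: absent_max must be < 2 - delta_autosome",
         call. = FALSE)
  }
  #  X vs A: the ratio intervals must not intersect.
  if (ratio_x[1] <= 1 + delta_autosome) {
    stop("rules overlap: ratio_x lower bound must exceed 1 + delta_autosome",
         call. = FALSE)
  }
  thr
}

#' Which classification rules fire for given copy numbers
#'
#' Evaluates the three rules independently (no precedence), mainly for
#' diagnostics and for checking rule exclusivity over a cn grid.
#'
#' @param cn_male,cn_female Copy-number estimates (>= 0), recycled.
#' @param thr A [linkage_thresholds()] object.
#' @return A tibble of logicals `y_linked`, `x_linked`, `autosomal`.
#' @export
rule_fires <- function(cn_male, cn_female, thr = linkage_thresholds()) {
  n <- max(length(cn_male), length(cn_female))
  m <- rep_len(cn_male, n)
  f <- rep_len(cn_female, n)
  ratio <- ifelse(m > 0, f / m, NA_real_)
  lo <- 2 - thr$delta_autosome
  hi <- 2 + thr$delta_autosome
  tibble::tibble(
    y_linked = abs(m - 1) <= thr$delta_single & f <= thr$absent_max,
    x_linked = m <= 1 + thr$delta_single & f > thr$absent_max &
      !is.na(ratio) & ratio >= thr$ratio_x[1] & ratio <= thr$ratio_x[2],
    autosomal = !is.na(ratio) & abs(ratio - 1) <= thr$delta_autosome &
      m >= lo & m <= hi & f >= lo & f <= hi
  )
}

#' Classify contigs from male and female copy numbers
#'
#' Applies the rule cascade in a fixed order -- Y-linked, then X-linked,
#' then autosomal, else ambiguous. Y comes first because its signature
#' (presence in males, absence in females) is the most specific; with the
#' default thresholds the rule regions are disjoint so the order only
#' resolves degenerate configurations. A contig absent in both sexes
#' (`cn_male = 0`) is ambiguous, not Y-linked: a Y call requires male
#' presence. Undefined copy numbers (`NA`) give `UNCLASSIFIABLE`.
#'
#' @param data A tibble with columns `cn_male` and `cn_female` (e.g. joined
#'   contig summaries), one row per contig.
#' @param thr A [linkage_thresholds()] object.
#' @return `data` with `fm_ratio` (female:male cn ratio, `NA` when
#'   `cn_male = 0`) and `call` (factor: `AUTOSOMAL`, `X_LINKED`,
#'   `Y_LINKED`, `AMBIGUOUS`, `UNCLASSIFIABLE`) appended.
#' @examples
#' classify_contigs(tibble::tibble(cn_male = c(1, 1, 2), cn_female = c(0, 2, 2)))
#' @export
classify_contigs <- function(data, thr = linkage_thresholds()) {
  m <- data$cn_male
  f <- data$cn_female
  if (any(stats::na.omit(c(m, f)) < 0)) {
    stop("copy numbers must be >= 0", call. = FALSE)
  }
  rules <- rule_fires(ifelse(is.na(m), 0, m), ifelse(is.na(f), 0, f), thr)
  call <- dplyr::case_when(
    is.na(m) | is.na(f) ~ "UNCLASSIFIABLE",
    rules$y_linked ~ "Y_LINKED",
    rules$x_linked ~ "X_LINKED",
    rules$autosomal ~ "AUTOSOMAL",
    TRUE ~ "AMBIGUOUS"
  )
  dplyr::mutate(data,
    fm_ratio = ifelse(!is.na(m) & m > 0, f / m, NA_real_),
    call = factor(call, levels = c("AUTOSOMAL", "X_LINKED", "Y_LINKED",
                                   "AMBIGUOUS", "UNCLASSIFIABLE"))
  )
}

#' Classify a whole assembly from per-sex contig copy-number summaries
#'
#' Joins the male and female contig summaries (which must cover identical
#' contig sets), classifies every contig, and tallies contig counts and
#' summed bp per class.
#'
#' @param male_summary,female_summary Contig summaries from [contig_cn()]
#'   for the combined male and female profiles.
#' @param assembly Contig table supplying lengths (`contig`, `length`).
#' @param thr A [linkage_thresholds()] object.
#' @return A `linkage_result` with `calls` (tibble: `contig`, `call`,
#'   `cn_male`, `cn_female`, `fm_ratio`, `n_windows`, `low_evidence`,
#'   `length`), `summary` (tibble: `call`, `n_contigs`, `bp`) and
#'   `thresholds`.
#' @export
classify_assembly <- function(male_summary, female_summary, assembly,
                              thr = linkage_thresholds()) {
  extra_m <- setdiff(male_summary$contig, female_summary$contig)
  extra_f <- setdiff(female_summary$contig, male_summary$contig)
  if (length(extra_m) > 0 || length(extra_f) > 0) {
    stop("contig sets differ between sexes; male-only: {",
         paste(extra_m, collapse = ", "), "}, female-only: {",
         paste(extra_f, collapse = ", "), "}", call. = FALSE)
  }
  calls <- male_summary |>
    dplyr::select("contig", cn_male = "median_cn",
                  n_windows_male = "n_windows",
                  low_evidence_male = "low_evidence") |>
    dplyr::inner_join(
      dplyr::select(female_summary, "contig", cn_female = "median_cn",
                    n_windows_female = "n_windows",
                    low_evidence_female = "low_evidence"),
      by = "contig") |>
    classify_contigs(thr) |>
    dplyr::mutate(
      n_windows = pmin(.data$n_windows_male, .data$n_windows_female),
      low_evidence = .data$low_evidence_male | .data$low_evidence_female
    ) |>
    dplyr::left_join(dplyr::select(assembly, "contig", "length"),
                     by = "contig") |>
    dplyr::select("contig", "call", "cn_male", "cn_female", "fm_ratio",
                  "n_windows", "low_evidence", "length")
  summary <- calls |>
    dplyr::group_by(call = .data$call, .drop = FALSE) |>
    dplyr::summarise(n_contigs = dplyr::n(),
                     bp = sum(.data$length, na.rm = TRUE),
                     .groups = "drop")
  structure(list(calls = calls, summary = summary, thresholds = thr),
            class = "linkage_result")
}

#' @export
print.linkage_result <- function(x, ...) {
  cat("<linkage_result> ", nrow(x$calls), " contigs\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' @export
tidy.linkage_result <- function(x, ...) x$calls

#' @export
glance.linkage_result <- function(x, ...) {
  wide <- tidyr::pivot_wider(
    x$summary, names_from = "call",
    values_from = c("n_contigs", "bp"), names_sep = "_"
  )
  names(wide) <- tolower(names(wide))
  dplyr::mutate(wide, n_contigs = nrow(x$calls),
                total_bp = sum(x$calls$length, na.rm = TRUE))
}

#' Plot classified contigs in copy-number space
#'
#' Scatter of female vs male contig copy number, coloured by call, with
#' guides at the ideal autosomal (2, 2), X (1, 2) and Y (1, 0) points.
#'
#' @param object A `linkage_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.linkage_result <- function(object, ...) {
  ideal <- tibble::tibble(cn_male = c(2, 1, 1), cn_female = c(2, 2, 0),
                          label = c("autosomal", "X", "Y"))
  ggplot2::ggplot(object$calls,
                  ggplot2::aes(x = .data$cn_male, y = .data$cn_female)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$call,
                                     size = .data$length), alpha = 0.8) +
    ggplot2::geom_point(data = ideal, shape = 3, size = 3) +
    ggplot2::geom_text(data = ideal, ggplot2::aes(label = .data$label),
                       nudge_x = 0.12, hjust = 0) +
    ggplot2::scale_size_area(max_size = 4, guide = "none") +
    ggplot2::labs(x = "male copy number", y = "female copy number",
                  colour = "call")
}

#' Write linkage calls and class summary as TSV
#'
#' @param result A `linkage_result`.
#' @param calls_path,summary_path Output paths (`NULL` to skip one).
#' @return `result`, invisibly.
#' @export
write_linkage <- function(result, calls_path = NULL, summary_path = NULL) {
  if (!is.null(calls_path)) readr::write_tsv(result$calls, calls_path)
  if (!is.null(summary_path)) readr::write_tsv(result$summary, summary_path)
  invisible(result)
}

#' Run the full depth-to-linkage pipeline
#'
#' Fixed stage order per sample: window profile, GC-model fit, depth
#' correction, copy number; then replicate combination per sex, contig
#' summaries, and classification. Both sexes are required: the method rests
#' on comparing male and female copy number.
#'
#' @param assembly Contig table (`contig`, `sequence`, `length`).
#' @param male_tracks,female_tracks Lists of depth-track tibbles (each as
#'   returned by [read_bedgraph()] or [simulate_depth()]).
#' @param window_size Window width in bp (default 100 kb).
#' @param span LOESS span for GC correction.
#' @param thr A [linkage_thresholds()] object.
#' @param min_windows Minimum usable windows per contig before the call is
#'   flagged low-evidence.
#' @param baseline Copy-number baseline rule, `"mean"` (default) or `"median"`
#'   (see [add_copy_number()]).
#' @return A `linkage_result` (see [classify_assembly()]); the per-sex
#'   combined window profiles are attached as `$profiles` for inspection.
#' @export
classify_sex_linkage <- function(assembly, male_tracks, female_tracks,
                                 window_size = 1e5, span = 0.3,
                                 thr = linkage_thresholds(),
                                 min_windows = 3,
                                 baseline = c("mean", "median")) {
  baseline <- match.arg(baseline)
  if (length(male_tracks) == 0 || length(female_tracks) == 0) {
    stop("both sexes required: the classification compares male and ",
         "female copy number", call. = FALSE)
  }
  if (nrow(assembly) == 0) {
    empty <- tibble::tibble(contig = character(), median_cn = numeric(),
                            n_windows = integer(), mad_cn = numeric(),
                            low_evidence = logical())
    return(classify_assembly(empty, empty, assembly, thr))
  }
  one_sex <- function(tracks, sex) {
    profiles <- purrr::imap(tracks, function(trk, i) {
      prof <- profile_sample(assembly, trk, window_size,
                             sample_id = paste0(sex, "_", i), sex = sex)
      model <- fit_gc_model(prof, span = span)
      prof |>
        correct_depth(model) |>
        add_copy_number(baseline = baseline)
    })
    combine_replicates(unname(profiles))
  }
  male <- one_sex(male_tracks, "male")
  female <- one_sex(female_tracks, "female")
  result <- classify_assembly(contig_cn(male, min_windows),
                              contig_cn(female, min_windows),
                              assembly, thr)
  result$profiles <- list(male = male, female = female)
  result
}
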