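#' Fit the expected-depth-vs-GC model (LOESS)
#'
#' Models the systematic dependence of window depth on GC content with a
#' locally weighted regression (LOESS: tricube weights, local fit over the
#' span-nearest neighbours) of raw depth on window GC, evaluated on a fixed
#' GC grid. Corrections later interpolate linearly on that grid, which
#' makes the correction deterministic and cheap. Fitted expected depths are
#' floored at a small positive epsilon (`1e-3 * reference_depth`) so the
#' correction ratio can never blow up; evaluation outside the observed GC
#' range clamps to the nearest grid endpoint.
#'
#' Sex-linked windows sit at other copy-number levels than the diploid
#' bulk (half depth in the hemizygous sex, zero for absent sequence) and
#' would distort a fit through all windows wherever they cluster in GC. By
#' default the fit therefore treats window depth as a constrained mixture
#' `level * b(gc)`, `level` in {diploid, half, zero}: each window is
#' assigned to the copy level nearest its depth ratio against the current
#' diploid curve (starting from the flat global 0.7-quantile of depth, an
#' upper quantile that starts on the diploid level regardless of how
#' windows cluster along GC), the LOESS is refitted on diploid-assigned
#' windows, and the assignment/refit is iterated (3 rounds). This recovers
#' the diploid bias curve without knowing contig classes in advance;
#' `refit_diploid = FALSE` gives the plain single-pass fit over all
#' windows. Each sample is fitted with its own model since libraries
#' differ in bias.
#'
#' @param table A window table from [profile_sample()].
#' @param span LOESS span: fraction of points in each local neighbourhood,
#'   in (0, 1] (default 0.3).
#' @param degree Local polynomial degree, 0 or 1 (default 1, the standard
#'   local-linear LOESS).
#' @param grid_n Number of GC grid points the fit is evaluated on.
#' @param refit_diploid Iteratively refit on windows whose provisional
#'   copy level is diploid (default TRUE; skipped when fewer than 20
#'   windows qualify).
#' @return A `gc_model` object with elements `grid` (tibble: `gc`,
#'   `expected_depth`), `span`, `degree`, `reference_depth` (the sample's
#'   global raw mean, the level corrections normalise to), `gc_range` and
#'   `constant`.
#' @export
fit_gc_model <- function(table, span = 0.3, degree = 1, grid_n = 101,
                         refit_diploid = TRUE) {
  if (span <= 0 || span > 1) stop("span must be in (0, 1]", call. = FALSE)
  if (!degree %in% c(0, 1)) stop("degree must be 0 or 1", call. = FALSE)
  use <- !table$excluded & !is.na(table$gc)
  if (sum(use) < 20) {
    stop("only ", sum(use), " usable windows (>= 20 required); ",
         "consider a smaller window size", call. = FALSE)
  }
  ref <- global_raw_mean(table)
  gc <- table$gc[use]
  depth <- table$raw_depth[use]
  rng <- range(gc)
  if (diff(rng) < 1e-9) {
    return(new_gc_model(tibble::tibble(gc = rng[1], expected_depth = ref),
                        span, degree, ref, rng, constant = TRUE))
  }
  if (refit_diploid) {
    # Window depths follow a constrained mixture: level * b(gc) with level
    # in {diploid, half, zero}. Alternate (a) assigning each window to the
    # copy level nearest its depth ratio against the current diploid curve
    # with (b) refitting the curve on diploid-assigned windows. The start
    # is the flat global 0.7-quantile: sub-diploid windows occupy the low
    # end of the depth distribution, so an upper quantile starts on the
    # diploid level no matter how windows cluster along GC.
    w <- (table$end - table$start)[use]
    e_prov <- rep(weighted_quantile(depth, w, 0.7), length(gc))
    refit <- NULL
    for (iter in 1:3) {
      r <- depth / pmax(e_prov, 1e-3 * ref)
      diploid <- r >= 0.75 & r <= 1.25  # nearest level is 1, not 1/2 or 3/2
      if (sum(diploid) < 20) break
      m <- loess_on_grid(gc[diploid], depth[diploid], span, degree,
                         grid_n, ref, range(gc[diploid]))
      e_prov <- predict(m, gc)
      refit <- m
    }
    # a collapsed curve signals a degenerate refit; fall back to one pass
    if (!is.null(refit) && min(refit$grid$expected_depth) > 0.05 * ref) {
      return(refit)
    }
  }
  loess_on_grid(gc, depth, span, degree, grid_n, ref, rng)
}


loess_on_grid <- function(gc, depth, span, degree, grid_n, ref, rng) {
  # keep at least ~25 windows in every local fit: with few windows a small
  # span hugs noise and swings in GC gaps (the bias curve is smooth, so a
  # wide span is the right bias/variance trade-off at small n)
  span <- max(span, min(1, 25 / length(gc)))
  # robust (bisquare-reweighted) fit: windows at other copy-number levels
  # act as level outliers and must not drag the curve
  fit <- stats::loess(depth ~ gc, span = span, degree = degree,
                      family = "symmetric",
                      control = stats::loess.control(surface = "direct",
                                                     iterations = 6))
  grid <- seq(rng[1], rng[2], length.out = grid_n)
  e <- as.numeric(stats::predict(fit, data.frame(gc = grid)))
  e <- pmax(e, 1e-3 * ref)
  new_gc_model(tibble::tibble(gc = grid, expected_depth = e),
               span, degree, ref, rng, constant = FALSE)
}

new_gc_model <- function(grid, span, degree, reference_depth, gc_range,
                         constant) {
  structure(list(grid = grid, span = span, degree = degree,
                 reference_depth = reference_depth, gc_range = gc_range,
                 constant = constant),
            class = "gc_model")
}

#' @export
print.gc_model <- function(x, ...) {
  cat("<gc_model> span ", x$span, ", degree ", x$degree,
      ", reference depth ", signif(x$reference_depth, 5),
      ", GC range [", signif(x$gc_range[1], 3), ", ",
      signif(x$gc_range[2], 3), "]",
      if (x$constant) " (constant)", "\n", sep = "")
  invisible(x)
}

#' Expected depth at given GC values
#'
#' Linear interpolation on the fitted grid; GC outside the fitted range is
#' clamped to the nearest endpoint, and undefined GC (`NA`, all-N windows)
#' falls back to the reference depth (correction factor 1).
#'
#' @param object A `gc_model`.
#' @param gc Numeric vector of GC fractions (NA allowed).
#' @param ... Unused.
#' @return Expected depths, same length as `gc`.
#' @export
predict.gc_model <- function(object, gc, ...) {
  out <- rep(object$reference_depth, length(gc))
  ok <- !is.na(gc)
  if (any(ok) && !object$constant) {
    clamped <- pmin(pmax(gc[ok], object$gc_range[1]), object$gc_range[2])
    out[ok] <- stats::approx(object$grid$gc, object$grid$expected_depth,
                             xout = clamped, rule = 2)$y
  }
  out
}

#' GC-correct the window depths of a sample
#'
#' Divides each window's raw depth by its expected depth given GC and
#' rescales to the model's reference level:
#' `corrected = raw * reference_depth / e(gc)`. Excluded windows are
#' corrected with the clamped nearest-GC expectation (factor 1 when GC is
#' undefined), so every window keeps a corrected depth. On a predominantly
#' diploid fitting sample the length-weighted mean corrected depth stays
#' within ~2% of the reference depth; when a large fraction of the sample
#' is sex-linked the corrected level is anchored to the diploid component
#' instead (see [fit_gc_model()]), which is what copy-number estimation
#' needs.
#'
#' @param table A window table from [profile_sample()].
#' @param model A `gc_model` fitted on a compatible sample.
#' @return The window table with a `corrected_depth` column appended.
#' @export
correct_depth <- function(table, model) {
  stopifnot(inherits(model, "gc_model"))
  if (model$constant) {
    observed <- range(table$gc, na.rm = TRUE)
    if (diff(observed) > 1e-9) {
      warning("GC model is constant but table GC varies; ",
              "applying constant correction", call. = FALSE)
    }
  }
  e <- predict(model, table$gc)
  dplyr::mutate(table,
                corrected_depth = .data$raw_depth * model$reference_depth / e)
}

#' @export
tidy.gc_model <- function(x, ...) x$grid

#' @export
glance.gc_model <- function(x, ...) {
  tibble::tibble(span = x$span, degree = x$degree,
                 reference_depth = x$reference_depth,
                 gc_min = x$gc_range[1], gc_max = x$gc_range[2],
                 constant = x$constant)
}

#' Plot a fitted GC model
#'
#' Shows the fitted expected-depth-vs-GC curve, optionally over the window
#' scatter it was fitted to.
#'
#' @param object A `gc_model`.
#' @param table Optional window table to draw as points.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gc_model <- function(object, table = NULL, ...) {
  p <- ggplot2::ggplot()
  if (!is.null(table)) {
    p <- p + ggplot2::geom_point(
      data = dplyr::filter(table, !.data$excluded),
      ggplot2::aes(x = .data$gc, y = .data$raw_depth),
      alpha = 0.3, size = 0.8
    )
  }
  p +
    ggplot2::geom_line(data = object$grid,
                       ggplot2::aes(x = .data$gc, y = .data$expected_depth),
                       colour = "firebrick", linewidth = 1) +
    ggplot2::labs(x = "window GC fraction", y = "depth",
                  title = "Expected depth vs GC (LOESS)")
}

#' Dump a GC model as TSV
#'
#' Header comment lines record the span, degree and reference depth; the
#' body is the `(gc, expected_depth)` grid.
#'
#' @param model A `gc_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gc_model <- function(model, path) {
  hdr <- c(sprintf("# span\t%g", model$span),
           sprintf("# degree\t%d", model$degree),
           sprintf("# reference_depth\t%.6f", model$reference_depth))
  writeLines(c(hdr, "gc\texpected_depth",
               sprintf("%.6f\t%.6f", model$grid$gc,
                       model$grid$expected_depth)), path)
  invisible(path)
}
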