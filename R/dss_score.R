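#' DSS configuration
#'
#' @param t activity threshold in percent inhibition (default 10; drug
#'   activity below this never contributes to the score).
#' @param grid_n number of points of the fixed log10-concentration trapezoid
#'   grid (>= 256; default 1024).
#' @return object of class `dss_config`.
#' @export
dss_config <- function(t = 10, grid_n = 1024) {
  stopifnot(t >= 0, t < 100, grid_n >= 256)
  structure(list(t = t, grid_n = grid_n), class = "dss_config")
}

#' Drug sensitivity score (modified DSS type 1)
#'
#' Normalized area between the inhibition curve and the activity threshold
#' `t`, integrated on the log10-concentration axis over the tested range.
#' With `x = log10(conc)` and clamped inhibition
#' `Ihat(x) = clamp(I(x), 0, 100)`, the activity onset `x_t` is the smallest
#' `x` with `Ihat(x) >= t` (`x_max` if never reached), and
#'
#' `DSS = 100 * A / ((100 - t) * (x_max - x_min))`,
#' `A = integral from x_t to x_max of (Ihat(x) - t) dx`.
#'
#' There is no logarithm-of-upper-limit divisor (the DSS type 1 variant used
#' here drops that term). The score lies in `[0, 100]`: 0 for a drug never
#' exceeding the threshold, 100 for complete kill across the whole range.
#' Integration uses a fixed trapezoid grid, branch-agnostic across the
#' LL4/L4 models.
#'
#' @param curve a [dose_response_curve()].
#' @param range concentration range `(c_min, c_max)` in nM (defaults to the
#'   curve's tested range).
#' @param config a [dss_config()].
#' @return DSS value in `[0, 100]`.
#' @export
dss <- function(curve, range = curve$conc_range, config = dss_config()) {
  if (!(range[1] > 0 && range[1] < range[2])) {
    stop("degenerate concentration range", call. = FALSE)
  }
  x <- seq(log10(range[1]), log10(range[2]), length.out = config$grid_n)
  inh <- clamp(predict_inhibition(curve, 10^x), 0, 100)
  t <- config$t
  i0 <- which(inh >= t)[1]
  if (is.na(i0) || i0 == length(x)) return(0)
  xs <- x[i0:length(x)]
  ys <- inh[i0:length(x)] - t
  a <- sum((ys[-1] + ys[-length(ys)]) / 2 * diff(xs))
  100 * a / ((100 - t) * (x[length(x)] - x[1]))
}

#' Efficacy band classification of DSS values
#'
#' Bands: low for DSS in `[0, 10]`, intermediate in `(10, 40]`, high in
#' `(40, 100]`.
#'
#' @param dss numeric DSS value(s).
#' @return character vector of `"low"`, `"intermediate"`, `"high"`.
#' @export
classify_dss <- function(dss) {
  stopifnot(all(dss >= 0 & dss <= 100))
  out <- rep("low", length(dss))
  out[dss > 10] <- "intermediate"
  out[dss > 40] <- "high"
  out
}

#' Combination DSS for the IC20-primed double design
#'
#' One DSS is computed for the combination titration (partner doses with the
#' primer fixed) and compared with the partner's single-agent DSS over the
#' identical concentration range (the combination range, 0.1-1000 nM in the
#' screening design).
#'
#' @param combo_curve curve fitted to combination wells over the partner
#'   titration.
#' @param single_curve the partner's single-agent curve.
#' @param range concentration range used for both scores; defaults to the
#'   combination curve's tested range.
#' @param config a [dss_config()].
#' @param override allow a `range` outside the single-agent tested span
#'   (extended one decade each side).
#' @return list with `dss_combo`, `dss_single`, `delta` (combo minus
#'   single).
#' @export
combo_dss_double <- function(combo_curve, single_curve,
                             range = combo_curve$conc_range,
                             config = dss_config(), override = FALSE) {
  covered <- range[1] >= single_curve$conc_range[1] / 10 &&
    range[2] <= single_curve$conc_range[2] * 10
  if (!covered && !override) {
    stop("combination range not covered by the single-agent curve; ",
         "pass override = TRUE to score anyway", call. = FALSE)
  }
  d_combo <- dss(combo_curve, range, config)
  d_single <- dss(single_curve, range, config)
  list(dss_combo = d_combo, dss_single = d_single,
       delta = d_combo - d_single)
}

#' Combination DSS for the 4x4 triple design
#'
#' A concentration-response curve is fitted to each line of the matrix (by
#' default each level of drug A, with drug B varying over its four doses,
#' all in the presence of the fixed background drug), its DSS computed over
#' the varying drug's range, and the per-line scores averaged.
#'
#' @param cells tibble with columns `conc_a`, `conc_b` (nM) and `inhibition`
#'   (fraction in `[0, 1]`, measured with the background present); replicate
#'   rows per cell are averaged. All grid cells must be present.
#' @param config a [dss_config()].
#' @param orientation `"rows"` fits along drug B within each drug A level;
#'   `"cols"` the transpose.
#' @return list with `dss` (the averaged score) and `per_curve` (tibble of
#'   the per-line fixed dose, DSS and fit model).
#' @export
combo_dss_triple <- function(cells, config = dss_config(),
                             orientation = c("rows", "cols")) {
  orientation <- match.arg(orientation)
  stopifnot(all(c("conc_a", "conc_b", "inhibition") %in% names(cells)))
  if (orientation == "cols") {
    cells <- dplyr::rename(cells, conc_a = "conc_b", conc_b = "conc_a")
  }
  agg <- stats::aggregate(inhibition ~ conc_a + conc_b, data = cells, FUN = mean)
  ca <- sort(unique(agg$conc_a)); cb <- sort(unique(agg$conc_b))
  if (nrow(agg) != length(ca) * length(cb)) {
    stop("incomplete concentration matrix", call. = FALSE)
  }
  per <- lapply(ca, function(a) {
    sub <- agg[agg$conc_a == a, ]
    sub <- sub[order(sub$conc_b), ]
    fit <- fit_curve(sub$conc_b, 100 * (1 - sub$inhibition))
    tibble(fixed_conc = a, dss = dss(fit, range(cb), config),
           model = fit$model)
  })
  per <- dplyr::bind_rows(per)
  list(dss = mean(per$dss), per_curve = per)
}

#' Build a DSS record table
#'
#' @param sample_id,treatment_label identifiers.
#' @param dss DSS values.
#' @param source `"single"`, `"combo_double"` or `"combo_triple"`.
#' @param range concentration range the scores were computed on.
#' @param t activity threshold used.
#' @return tibble with the canonical DSS-record columns including the
#'   efficacy `band`.
#' @export
dss_record <- function(sample_id, treatment_label, dss, source = "single",
                       range = c(0.1, 10000), t = 10) {
  tibble(sample_id = sample_id, treatment_label = treatment_label,
         dss = dss, band = classify_dss(dss), source = source,
         range_min_nM = range[1], range_max_nM = range[2], t = t)
}

#' Wide samples-by-treatments DSS matrix
#'
#' Heatmap-ready export: one row per sample, one column per treatment.
#'
#' @param records tibble of DSS records ([dss_record()] schema).
#' @return numeric matrix with sample ids as row names.
#' @export
dss_wide <- function(records) {
  wide <- tidyr::pivot_wider(records[, c("sample_id", "treatment_label", "dss")],
                             names_from = "treatment_label",
                             values_from = "dss")
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$sample_id
  m
}
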