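#' Bliss-independence expected inhibition
#'
#' For two non-interacting drugs with single-agent inhibition fractions `fA`
#' and `fB`, the expected combined inhibition is `fA + fB - fA * fB`
#' (independent kill probabilities).
#'
#' @param fA,fB inhibition fractions in `[0, 1]` (vectorized).
#' @return expected combined inhibition fraction.
#' @export
bliss_expected <- function(fA, fB) {
  if (any(fA < 0 | fA > 1 | fB < 0 | fB > 1)) {
    stop("inhibition fractions must lie in [0, 1]", call. = FALSE)
  }
  fA + fB - fA * fB
}

new_synergy_result <- function(grid, design) {
  ms <- mean(grid$excess)
  structure(list(
    grid = grid, design = design,
    mean_synergy = ms,
    synergy_sum = sum(grid$excess),
    n_cells = nrow(grid),
    synergistic = ms > 0
  ), class = "synergy_result")
}

#' @export
print.synergy_result <- function(x, ...) {
  cat(sprintf("<synergy_result: %s> %d cells, mean %.2f, sum %.2f, %s\n",
              x$design, x$n_cells, x$mean_synergy, x$synergy_sum,
              if (x$synergistic) "synergistic" else "not synergistic"))
  invisible(x)
}

#' Bliss excess over a dose matrix
#'
#' Per non-zero dose pair, `excess = 100 * (f_obs - bliss_expected(fA, fB))`
#' in percentage points; positive excess marks synergy, negative antagonism.
#' The summary is the mean over the grid and the synergy sum (mean times the
#' number of non-zero dose pairs — over the 4x4 matrix of the triple design
#' this is the synergy-sum statistic). A combination is classified
#' synergistic when the mean score is strictly greater than 0.
#'
#' When the matrix was measured on top of a fixed background drug, `fA`,
#' `fB` and `f_obs` must all be measured with the background present
#' (conditional two-way Bliss): the background is constant across cells, so
#' it is absorbed into the baseline rather than attributed three-way.
#'
#' @param observed matrix of observed combined inhibition fractions, rows
#'   indexed by `concsA`, columns by `concsB`.
#' @param fA,fB monotherapy inhibition fractions at `concsA` / `concsB`.
#' @param concsA,concsB dose grids in nM (non-zero doses only).
#' @param design label recorded in the result.
#' @return object of class `synergy_result` with a long-format `grid`
#'   (`conc_a`, `conc_b`, `f_obs`, `f_expected`, `excess`), `mean_synergy`,
#'   `synergy_sum`, `n_cells` and the `synergistic` classification.
#' @export
excess_matrix <- function(observed, fA, fB, concsA, concsB,
                          design = "triple_matrix") {
  observed <- as.matrix(observed)
  if (nrow(observed) != length(concsA) || ncol(observed) != length(concsB)) {
    stop("observed matrix shape does not match the dose grids", call. = FALSE)
  }
  if (length(fA) != length(concsA) || length(fB) != length(concsB)) {
    stop("missing monotherapy inhibition for some grid dose", call. = FALSE)
  }
  if (any(!is.finite(observed)) || any(observed < 0 | observed > 1)) {
    stop("observed inhibition must be finite fractions in [0, 1]", call. = FALSE)
  }
  expected <- outer(fA, fB, bliss_expected)
  grid <- tibble(
    conc_a = rep(concsA, times = length(concsB)),
    conc_b = rep(concsB, each = length(concsA)),
    f_obs = as.vector(observed),
    f_expected = as.vector(expected),
    excess = 100 * (as.vector(observed) - as.vector(expected))
  )
  new_synergy_result(grid, design)
}

#' Bliss synergy along an IC20-primed titration
#'
#' Scores the primed double design as a 1x5 dose grid: the primer's
#' monotherapy inhibition at its fixed concentration is evaluated from its
#' single-agent curve, the partner's at each titrated dose, and the per-dose
#' Bliss excess of the observed combination inhibition is returned together
#' with the mean score and classification (the screen reports synergy per
#' concentration across samples).
#'
#' @param combo_inhibition observed combination inhibition fractions at the
#'   partner doses (replicate-mean, clamped to `[0, 1]`).
#' @param partner_concs partner doses in nM.
#' @param primer_curve single-agent [dose_response_curve()] of the primer.
#' @param primer_conc fixed priming concentration in nM.
#' @param partner_curve single-agent curve of the partner, used for its
#'   monotherapy fractions when `partner_inhibition` is not given.
#' @param partner_inhibition optional measured partner monotherapy fractions
#'   at `partner_concs` (takes precedence over `partner_curve`).
#' @return a `synergy_result` (see [excess_matrix()]) with design
#'   `"double_primed"`.
#' @export
primed_double_synergy <- function(combo_inhibition, partner_concs,
                                  primer_curve, primer_conc,
                                  partner_curve = NULL,
                                  partner_inhibition = NULL) {
  span <- log10(primer_curve$conc_range) + c(-1, 1)
  if (log10(primer_conc) < span[1] || log10(primer_conc) > span[2]) {
    stop("primer concentration outside the primer curve's evaluable span",
         call. = FALSE)
  }
  f_primer <- clamp(predict_inhibition(primer_curve, primer_conc) / 100, 0, 1)
  if (is.null(partner_inhibition)) {
    if (is.null(partner_curve)) {
      stop("supply partner_inhibition or partner_curve", call. = FALSE)
    }
    partner_inhibition <- clamp(
      predict_inhibition(partner_curve, partner_concs) / 100, 0, 1)
  }
  excess_matrix(matrix(combo_inhibition, nrow = 1),
                fA = f_primer, fB = partner_inhibition,
                concsA = primer_conc, concsB = partner_concs,
                design = "double_primed")
}

#' Long-format synergy landscape export
#'
#' The per-cell grid of a `synergy_result` as a `(conc_a, conc_b, excess)`
#' table suitable for 2D contour plotting (negative excess = antagonism).
#'
#' @param result a `synergy_result`.
#' @return tibble with columns `conc_a`, `conc_b`, `excess`.
#' @export
landscape_export <- function(result) {
  stopifnot(inherits(result, "synergy_result"))
  result$grid[, c("conc_a", "conc_b", "excess")]
}

#' Synergy scoring of a simulated/measured triple-matrix plate
#'
#' Extracts the 4x4 combination cells and the zero-dose margins (each drug
#' alone in the presence of the fixed background) from a normalized triple
#' design plate and runs [excess_matrix()] under conditional two-way Bliss:
#' the background drug is constant across all cells, so it is absorbed into
#' the baseline by conditioning every fraction on the background-alone
#' survival `S_bg` (from the background-alone wells),
#' `f|bg = clamp(1 - (1 - f) / S_bg, 0, 1)`. Monotherapy fractions come from
#' the margin wells (`zero_dose_cells`); when margins are absent, supply
#' single-agent curves already conditional on the background via
#' `curveA`/`curveB` (`external_curves`). Without background-alone wells the
#' baseline is taken as 1 (no background).
#'
#' @param norm_wells normalized wells of one triple-design plate
#'   ([normalize_viability()] output); flagged wells are dropped.
#' @param drugA,drugB names of the two titrated drugs.
#' @param background name of the fixed third drug.
#' @param curveA,curveB optional external single-agent curves.
#' @return a `synergy_result`.
#' @export
matrix_synergy_from_plate <- function(norm_wells, drugA, drugB, background,
                                      curveA = NULL, curveB = NULL) {
  w <- norm_wells[!norm_wells$qc_outlier & !norm_wells$qc_excluded, ]
  w <- w[w$role == "treated", ]
  has <- function(d) (!is.na(w$drug1) & w$drug1 == d) |
    (!is.na(w$drug2) & w$drug2 == d) | (!is.na(w$drug3) & w$drug3 == d)
  conc_of <- function(i, d) {
    for (k in 1:3) {
      if (!is.na(w[[paste0("drug", k)]][i]) && w[[paste0("drug", k)]][i] == d) {
        return(w[[paste0("conc", k, "_nM")]][i])
      }
    }
    NA_real_
  }
  in_a <- has(drugA); in_b <- has(drugB); in_bg <- has(background)
  combo <- which(in_a & in_b & in_bg)
  if (length(combo) == 0) stop("no combination wells found", call. = FALSE)

  # fractions are built from unclamped viability, averaged over replicates,
  # conditioned on the background baseline, and clamped once at the end:
  # clamping per well would truncate the noise asymmetrically near 0/1 and
  # bias the excess
  u <- (100 - w$viability_pct) / 100
  bg_alone <- which(in_bg & !in_a & !in_b)
  s_bg <- if (length(bg_alone) > 0) max(1 - mean(u[bg_alone]), 1e-6) else 1
  conditional <- function(f) clamp(1 - (1 - f) / s_bg, 0, 1)

  cells <- tibble(
    conc_a = vapply(combo, conc_of, numeric(1), d = drugA),
    conc_b = vapply(combo, conc_of, numeric(1), d = drugB),
    inhibition = u[combo]
  )
  agg <- stats::aggregate(inhibition ~ conc_a + conc_b, data = cells, FUN = mean)
  ca <- sort(unique(agg$conc_a)); cb <- sort(unique(agg$conc_b))
  obs <- matrix(NA_real_, length(ca), length(cb))
  obs[cbind(match(agg$conc_a, ca), match(agg$conc_b, cb))] <-
    conditional(agg$inhibition)
  if (any(is.na(obs))) stop("incomplete combination matrix", call. = FALSE)

  mono <- function(drug, concs, curve) {
    # margin wells: the drug plus background, without the other varying drug
    idx <- which(has(drug) & in_bg & !(in_a & in_b))
    if (length(idx) > 0) {
      cc <- vapply(idx, conc_of, numeric(1), d = drug)
      m <- stats::aggregate(inh ~ cc,
                            data = data.frame(cc = cc, inh = u[idx]),
                            FUN = mean)
      f <- m$inh[match(concs, m$cc)]
      if (!any(is.na(f))) return(conditional(f))
    }
    if (is.null(curve)) {
      stop("missing monotherapy wells for ", drug,
           " and no external curve supplied", call. = FALSE)
    }
    clamp(predict_inhibition(curve, concs) / 100, 0, 1)
  }
  fA <- mono(drugA, ca, curveA)
  fB <- mono(drugB, cb, curveB)
  excess_matrix(obs, fA, fB, ca, cb, design = "triple_matrix")
}
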