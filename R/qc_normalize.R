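#' Z-prime factor plate QC
#'
#' `Z' = 1 - 3 * (sd_pos + sd_neg) / |mu_neg - mu_pos|` from the plate's
#' control wells (mean and sample SD, the standard Z'-factor estimators).
#' `Z' = 1` only when both control SDs are zero; a plate is usable when
#' `Z' >= floor` and the controls are not inverted (`mu_neg > mu_pos`).
#' Wells already flagged (`qc_outlier`/`qc_excluded`) are ignored.
#'
#' @param plate well table for one plate.
#' @param floor usability floor on Z' (default 0.4).
#' @return one-row tibble: `plate_id`, `zprime`, `mu_neg`, `sd_neg`,
#'   `mu_pos`, `sd_pos`, `n_outliers_flagged`, `usable`, `note`.
#' @export
zprime <- function(plate, floor = 0.4) {
  stopifnot(length(unique(plate$plate_id)) == 1)
  keep <- !plate$qc_outlier & !plate$qc_excluded
  neg <- plate$signal[keep & plate$role == "negative_control"]
  pos <- plate$signal[keep & plate$role == "positive_control"]
  if (length(neg) < 2 || length(pos) < 2) {
    stop("plate ", plate$plate_id[1],
         ": need >= 2 wells of each control role for Z'", call. = FALSE)
  }
  mu_neg <- mean(neg); sd_neg <- stats::sd(neg)
  mu_pos <- mean(pos); sd_pos <- stats::sd(pos)
  note <- NA_character_
  if (mu_neg == mu_pos) {
    zp <- -Inf
    usable <- FALSE
    note <- "degenerate controls: mu_neg == mu_pos"
  } else {
    zp <- 1 - 3 * (sd_pos + sd_neg) / abs(mu_neg - mu_pos)
    usable <- zp >= floor && mu_neg > mu_pos
    if (mu_neg <= mu_pos) note <- "inverted controls: mu_neg <= mu_pos"
  }
  tibble(plate_id = plate$plate_id[1], zprime = zp,
         mu_neg = mu_neg, sd_neg = sd_neg, mu_pos = mu_pos, sd_pos = sd_pos,
         n_outliers_flagged = sum(plate$qc_outlier), usable = usable,
         note = note)
}

#' QC report over all plates in a well table
#'
#' @param wells well table (possibly many plates).
#' @param floor usability floor on Z'.
#' @return tibble with one [zprime()] row per plate.
#' @export
qc_report <- function(wells, floor = 0.4) {
  dplyr::bind_rows(lapply(split_plates(wells), zprime, floor = floor))
}

#' Control-based viability normalization
#'
#' Per plate, `viability_pct = 100 * (signal - mu_pos) / (mu_neg - mu_pos)`,
#' with control means taken over unflagged control wells of the same plate.
#' Viability is left unclamped (values slightly outside [0, 100] carry
#' information for curve fitting); `inhibition_frac = clamp((100 -
#' viability_pct) / 100, 0, 1)` is clamped because Bliss scoring needs
#' probabilities. Control wells are normalized too (negatives average 100,
#' positives 0, by construction).
#'
#' @param wells well table (one or more plates).
#' @param floor usability floor passed to [zprime()].
#' @param override normalize even plates that fail QC (logged in the result's
#'   `qc_override` column).
#' @return the well table with `viability_pct`, `inhibition_frac` and
#'   `qc_override` columns added.
#' @export
normalize_viability <- function(wells, floor = 0.4, override = FALSE) {
  out <- lapply(split_plates(wells), function(plate) {
    qc <- zprime(plate, floor = floor)
    if (!qc$usable && !override) {
      stop("plate ", qc$plate_id, " failed QC (Z' = ",
           formatC(qc$zprime, digits = 3, format = "fg"),
           "); pass override = TRUE to normalize anyway", call. = FALSE)
    }
    denom <- qc$mu_neg - qc$mu_pos
    plate$viability_pct <- 100 * (plate$signal - qc$mu_pos) / denom
    plate$inhibition_frac <- clamp((100 - plate$viability_pct) / 100, 0, 1)
    plate$qc_override <- !qc$usable
    plate
  })
  dplyr::bind_rows(out)
}

# Robust standardized residuals of points against a fitted curve. The
# residual scale is proportional to max(predicted viability, 5) because the
# measurement noise is multiplicative (a 5-percentage-point floor keeps the
# near-zero-viability tail from blowing up); s_rel is estimated by MAD over
# the points in `ref` only.
std_residuals <- function(fit, conc, viability, ref = NULL) {
  pred <- predict_viability(fit, conc)
  res <- viability - pred
  scale_base <- pmax(pred, 5)
  if (is.null(ref)) ref <- seq_along(conc)
  s_rel <- stats::mad((res / scale_base)[ref], center = 0)
  s_rel <- max(s_rel, 0.005)  # never standardize by a near-zero scale
  abs(res) / pmax(s_rel * scale_base, 2)
}

#' Automated outlier screen
#'
#' Replacement for manual curation of screening plates, applied to
#' normalized wells and scored on simulations with labeled outliers. Rules,
#' in order:
#'
#' 1. Replicate rule: within a group of wells sharing an identical treatment
#'    (same plate, sample and drug-concentration set, controls included),
#'    flag wells with `|viability - median| > max(3 * mad(viability), 15)`
#'    (scaled MAD; 15-percentage-point absolute floor). Needs >= 3 wells —
#'    a pair cannot be adjudicated by MAD.
#' 2. Control log-signal rule: the large control groups (>= 8 wells) are
#'    additionally screened on the log raw-signal scale, where the
#'    multiplicative noise is homoskedastic: flag
#'    `|log s - median(log s)| > max(3 * mad(log s), log(1.5))`. This
#'    catches gross positive-control outliers whose viability deviation
#'    sits below the 15-point floor.
#' 3. Residual rule on single-agent titrations (>= 5 points at >= 4 doses):
#'    duplicate dose groups whose within-pair spread is discordant with the
#'    series' robust pair-noise estimate are set aside, a preliminary curve
#'    is fitted to the concordant points (so a gross outlier cannot mask
#'    itself by dragging the fit), and every point with robust standardized
#'    residual > 3 against that fit is flagged; one refit pass then catches
#'    stragglers. Residuals are standardized by a robust relative scale
#'    times `max(predicted viability, 5)` with a 2-point absolute floor.
#'
#' Flagged wells get `qc_outlier = TRUE`; they are excluded from final fits
#' but never deleted from the table.
#'
#' @param norm_wells output of [normalize_viability()].
#' @param mad_k,abs_floor replicate-rule multiplier and floor (percentage
#'   points).
#' @param resid_k residual-rule multiplier.
#' @return the well table with updated `qc_outlier`.
#' @export
flag_outliers <- function(norm_wells, mad_k = 3, abs_floor = 15, resid_k = 3) {
  stopifnot("viability_pct" %in% names(norm_wells))
  w <- norm_wells
  w$.tlab <- paste(w$plate_id, w$sample_id, treatment_label(w))

  # stage 1: replicate rule
  for (g in split(seq_len(nrow(w)), w$.tlab)) {
    if (length(g) < 3) next
    v <- w$viability_pct[g]
    thr <- max(mad_k * stats::mad(v), abs_floor)
    w$qc_outlier[g] <- w$qc_outlier[g] | abs(v - stats::median(v)) > thr
  }

  # stage 2: control groups on the log-signal scale
  ctrl <- w$role %in% c("negative_control", "positive_control")
  for (g in split(which(ctrl), w$.tlab[ctrl])) {
    g <- g[w$signal[g] > 0]
    if (length(g) < 8) next
    ls <- log(w$signal[g])
    thr <- max(mad_k * stats::mad(ls), log(1.5))
    w$qc_outlier[g] <- w$qc_outlier[g] | abs(ls - stats::median(ls)) > thr
  }

  # stage 3: residual rule on single-agent titrations
  single <- w$role == "treated" &
    !is.na(w$drug1) & is.na(w$drug2) & is.na(w$drug3)
  w$.series <- paste(w$plate_id, w$sample_id, w$drug1)
  for (g in split(which(single), w$.series[single])) {
    keep <- g[!w$qc_outlier[g]]
    if (length(keep) < 5 || length(unique(w$conc1_nM[keep])) < 4) next
    conc <- w$conc1_nM[keep]
    v <- w$viability_pct[keep]

    # pair concordance: relative within-dose spread vs the series' robust
    # pair noise, with a 4.5-sigma multiplier and a 0.2 relative floor
    grp <- match(conc, unique(conc))
    rel_spread <- vapply(seq_along(unique(conc)), function(j) {
      vv <- v[grp == j]
      if (length(vv) < 2) return(NA_real_)
      (max(vv) - min(vv)) / max(abs(mean(vv)), 5)
    }, numeric(1))
    s_pair <- 1.4826 * stats::median(rel_spread, na.rm = TRUE)
    discordant <- !is.na(rel_spread) &
      rel_spread > max(4.5 * s_pair, 0.2, na.rm = TRUE)
    concordant_pts <- which(!(grp %in% which(discordant)))

    flag <- rep(FALSE, length(keep))
    base <- if (length(unique(conc[concordant_pts])) >= 4) concordant_pts
            else seq_along(keep)
    fit <- try(fit_curve(conc[base], v[base]), silent = TRUE)
    if (!inherits(fit, "try-error")) {
      flag <- std_residuals(fit, conc, v, ref = base) > resid_k
      if (any(flag) && length(unique(conc[!flag])) >= 4) {
        refit <- try(fit_curve(conc[!flag], v[!flag]), silent = TRUE)
        if (!inherits(refit, "try-error")) {
          flag <- flag | std_residuals(refit, conc, v, ref = which(!flag)) > resid_k
        }
      }
    }
    w$qc_outlier[keep] <- flag
  }
  w$.tlab <- NULL
  w$.series <- NULL
  w
}

#' Squared Pearson correlation between replicate plates
#'
#' Treatments are matched across the two plates by their canonical label;
#' per-treatment mean viabilities are correlated.
#'
#' @param plate_a,plate_b normalized well tables of two replicate runs of the
#'   same design.
#' @return R-squared (scalar).
#' @export
replicate_correlation <- function(plate_a, plate_b) {
  mean_by_treatment <- function(p) {
    p$.tlab <- treatment_label(p)
    out <- stats::aggregate(viability_pct ~ .tlab, data = p, FUN = mean)
    stats::setNames(out$viability_pct, out$.tlab)
  }
  a <- mean_by_treatment(plate_a)
  b <- mean_by_treatment(plate_b)
  common <- intersect(names(a), names(b))
  if (length(common) < 3) {
    stop("fewer than 3 matched treatments between replicates", call. = FALSE)
  }
  x <- a[common]; y <- b[common]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: a replicate has zero variance", call. = FALSE)
  }
  stats::cor(x, y)^2
}
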