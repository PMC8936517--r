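#' Measurement-noise model for simulated plates
#'
#' Noise is multiplicative lognormal on the raw luminescence signal
#' (luminescence scales with cell number, and a multiplicative model keeps
#' signals non-negative), parameterized by its coefficient of variation so
#' that the noise factor has mean exactly 1. Occasional outlier wells
#' multiply the signal by `outlier_scale`; their ground-truth labels are kept
#' so outlier-screening rules can be scored.
#'
#' @param cv coefficient of variation of the multiplicative noise (>= 0).
#' @param outlier_rate per-well probability of an outlier in `[0, 0.1]`.
#' @param outlier_scale multiplicative factor applied to outlier wells.
#' @param neg_ctrl_signal expected raw signal of a DMSO (negative-control)
#'   well, in luminescence counts.
#' @param pos_ctrl_fraction expected positive-control (BzCl, full-kill) signal
#'   as a fraction of `neg_ctrl_signal`, in `[0, 0.2]`.
#' @param seed optional integer seed; identical seed and parameters give
#'   bit-identical plates. `NULL` leaves the RNG stream untouched.
#' @return object of class `noise_model`.
#' @export
noise_model <- function(cv = 0.05, outlier_rate = 0, outlier_scale = 3,
                        neg_ctrl_signal = 10000, pos_ctrl_fraction = 0.02,
                        seed = NULL) {
  stopifnot(cv >= 0, outlier_rate >= 0, outlier_rate <= 0.1,
            outlier_scale > 0, neg_ctrl_signal > 0,
            pos_ctrl_fraction >= 0, pos_ctrl_fraction <= 0.2)
  structure(list(cv = cv, outlier_rate = outlier_rate,
                 outlier_scale = outlier_scale,
                 neg_ctrl_signal = neg_ctrl_signal,
                 pos_ctrl_fraction = pos_ctrl_fraction, seed = seed),
            class = "noise_model")
}

#' Ground-truth drug-response profile
#'
#' The simulator's true concentration-response curve for one drug (same
#' log-logistic family the fitting stage estimates; see [hill_viability()]).
#'
#' @param drug drug name.
#' @param ic50 midpoint concentration in nM (> 0).
#' @param slope Hill slope (> 0).
#' @param top,bottom asymptotic viabilities in percent, `0 <= bottom < top`.
#' @return one-row tibble (profiles can be row-bound into a panel).
#' @export
gt_profile <- function(drug, ic50, slope = 1, top = 100, bottom = 0) {
  stopifnot(ic50 > 0, slope > 0, bottom >= 0, bottom < top)
  tibble(drug = drug, ic50 = ic50, slope = slope, top = top, bottom = bottom)
}

#' Interaction model for combination wells
#'
#' `bliss_independent`: combined survival is the product of the single-agent
#' survivals. `bliss_shifted`: the product minus a fixed synergy excess
#' `delta` whenever both interacting drugs are present, i.e.
#' `S_AB = clamp(S_A * S_B - delta, 0, 1)`; `delta = 0` reproduces exact
#' Bliss independence and positive `delta` injects a known synergy for
#' recovery tests.
#'
#' @param kind `"bliss_independent"` or `"bliss_shifted"`.
#' @param delta synergy excess fraction in `[-1, 1]` (0 for independence).
#' @return object of class `interaction_model`.
#' @export
interaction_model <- function(kind = c("bliss_independent", "bliss_shifted"),
                              delta = 0) {
  kind <- match.arg(kind)
  stopifnot(delta >= -1, delta <= 1)
  if (kind == "bliss_independent" && delta != 0) {
    stop("bliss_independent requires delta = 0", call. = FALSE)
  }
  structure(list(kind = kind, delta = delta), class = "interaction_model")
}

# Mean-1 lognormal noise factors with CV = cv, plus outlier multipliers.
# Returns list(factor, is_outlier); draws nothing when cv = 0 and
# outlier_rate = 0 would still consume RNG, so guard both.
sim_noise_factors <- function(n, noise) {
  if (noise$cv > 0) {
    sdlog <- sqrt(log(1 + noise$cv^2))
    f <- stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  } else {
    f <- rep(1, n)
  }
  if (noise$outlier_rate > 0) {
    is_out <- stats::runif(n) < noise$outlier_rate
  } else {
    is_out <- rep(FALSE, n)
  }
  f[is_out] <- f[is_out] * noise$outlier_scale
  list(factor = f, is_outlier = is_out)
}

# Assemble a full plate table from a treated-well design plus controls.
# design: tibble with drug1..3, conc1..3_nM and true viability (percent).
sim_build_plate <- function(design, n_ctrl_wells, noise, plate_id, sample_id) {
  if (!is.null(noise$seed)) set.seed(noise$seed)
  ctrl <- tibble(
    drug1 = NA_character_, conc1_nM = NA_real_,
    drug2 = NA_character_, conc2_nM = NA_real_,
    drug3 = NA_character_, conc3_nM = NA_real_,
    role = rep(c("negative_control", "positive_control"), each = n_ctrl_wells),
    true_viability = rep(c(100, 0), each = n_ctrl_wells)
  )
  design$role <- "treated"
  wells <- dplyr::bind_rows(ctrl, design)
  n <- nrow(wells)
  if (n > 384) stop("design exceeds 384 wells (", n, ")", call. = FALSE)
  idx <- seq_len(n) - 1L
  wells$row <- LETTERS[idx %/% 24L + 1L]
  wells$col <- idx %% 24L + 1L
  wells$well <- well_label(wells$row, wells$col)
  wells$plate_id <- plate_id
  wells$sample_id <- sample_id

  nf <- sim_noise_factors(n, noise)
  # every well shares the same luminescence background (pos_ctrl_fraction of
  # the negative-control signal), which is exactly what control-based
  # normalization subtracts; with cv = 0 normalization inverts this mapping
  # exactly for any background fraction
  f0 <- noise$pos_ctrl_fraction
  expected <- noise$neg_ctrl_signal *
    (f0 + (1 - f0) * wells$true_viability / 100)
  wells$signal <- pmax(expected * nf$factor, 0)
  wells$true_outlier <- nf$is_outlier
  wells$qc_outlier <- FALSE
  wells$qc_excluded <- FALSE
  wells <- wells[, c(plate_table_cols, "row", "col",
                     "qc_outlier", "qc_excluded",
                     "true_viability", "true_outlier")]
  validate_plate_table(wells)
  wells
}

#' Simulate a single-agent titration plate
#'
#' Each drug in `profiles` is titrated over `concentrations` with
#' `n_replicates` wells per dose; the plate also carries `n_ctrl_wells` DMSO
#' negative and BzCl positive controls. Treated signal is
#' `neg_ctrl_signal * viability(conc) / 100` times a mean-1 lognormal noise
#' factor, floored at zero.
#'
#' @param profiles tibble of ground-truth profiles ([gt_profile()] rows).
#' @param concentrations strictly increasing dose grid in nM; default the
#'   6-point screening grid 0.1-10000 nM.
#' @param n_replicates wells per (drug, dose).
#' @param n_ctrl_wells wells per control role.
#' @param noise a [noise_model()].
#' @param plate_id,sample_id identifiers written into the table.
#' @return list with `wells` (canonical plate table plus `row`, `col`,
#'   QC-flag and ground-truth columns `true_viability`, `true_outlier`) and
#'   `truth` (the profile table).
#' @export
simulate_single_agent <- function(profiles,
                                  concentrations = c(0.1, 1, 10, 100, 1000, 10000),
                                  n_replicates = 2, n_ctrl_wells = 16,
                                  noise = noise_model(),
                                  plate_id = "P1", sample_id = "S1") {
  stopifnot(is.data.frame(profiles), nrow(profiles) >= 1)
  if (any(diff(concentrations) <= 0) || any(concentrations <= 0)) {
    stop("concentrations must be strictly increasing and positive", call. = FALSE)
  }
  design <- tidyr::expand_grid(
    drug1 = profiles$drug, conc1_nM = concentrations,
    rep = seq_len(n_replicates)
  )
  design <- dplyr::left_join(design, profiles, by = c(drug1 = "drug"))
  design$true_viability <- hill_viability(design$conc1_nM, design$ic50,
                                          design$slope, design$top, design$bottom)
  design <- tibble(
    drug1 = design$drug1, conc1_nM = design$conc1_nM,
    drug2 = NA_character_, conc2_nM = NA_real_,
    drug3 = NA_character_, conc3_nM = NA_real_,
    true_viability = design$true_viability
  )
  wells <- sim_build_plate(design, n_ctrl_wells, noise, plate_id, sample_id)
  list(wells = wells, truth = profiles)
}

# survival fractions in [0,1] from a profile
sim_survival <- function(profile, conc) {
  hill_viability(conc, profile$ic50, profile$slope, profile$top, profile$bottom) / 100
}

#' Simulate an IC20-primed double-combination plate
#'
#' The priming drug is held at a fixed concentration (its cohort IC20 in the
#' screening design) while the partner is titrated over 5 doses; the plate
#' also carries partner-alone wells at the same doses and primer-alone wells
#' at the fixed dose. Combination survival follows the
#' [interaction_model()]: `clamp(S_primer * S_partner - delta, 0, 1)`.
#'
#' @param primer ground-truth profile of the priming drug.
#' @param primer_conc fixed priming concentration in nM (> 0).
#' @param partner ground-truth profile of the titrated partner.
#' @param partner_concs exactly 5 doses in nM, strictly increasing; default
#'   0.1-1000 nM.
#' @param interaction an [interaction_model()].
#' @inheritParams simulate_single_agent
#' @return list with `wells` and `truth` (primer/partner profiles plus the
#'   injected `delta`).
#' @export
simulate_double_primed <- function(primer, primer_conc, partner,
                                   partner_concs = c(0.1, 1, 10, 100, 1000),
                                   interaction = interaction_model(),
                                   n_replicates = 2, n_ctrl_wells = 16,
                                   noise = noise_model(),
                                   plate_id = "P1", sample_id = "S1") {
  if (primer_conc <= 0) stop("primer_conc must be positive", call. = FALSE)
  if (length(partner_concs) != 5) {
    stop("the primed double design uses exactly 5 partner concentrations",
         call. = FALSE)
  }
  if (any(diff(partner_concs) <= 0) || any(partner_concs <= 0)) {
    stop("partner_concs must be strictly increasing and positive", call. = FALSE)
  }
  s_primer <- sim_survival(primer, primer_conc)
  s_partner <- sim_survival(partner, partner_concs)
  s_combo <- clamp(s_primer * s_partner - interaction$delta, 0, 1)

  rep_rows <- function(df) df[rep(seq_len(nrow(df)), each = n_replicates), ]
  combo <- rep_rows(tibble(
    drug1 = primer$drug, conc1_nM = primer_conc,
    drug2 = partner$drug, conc2_nM = partner_concs,
    drug3 = NA_character_, conc3_nM = NA_real_,
    true_viability = 100 * s_combo
  ))
  partner_alone <- rep_rows(tibble(
    drug1 = partner$drug, conc1_nM = partner_concs,
    drug2 = NA_character_, conc2_nM = NA_real_,
    drug3 = NA_character_, conc3_nM = NA_real_,
    true_viability = 100 * s_partner
  ))
  primer_alone <- rep_rows(tibble(
    drug1 = primer$drug, conc1_nM = primer_conc,
    drug2 = NA_character_, conc2_nM = NA_real_,
    drug3 = NA_character_, conc3_nM = NA_real_,
    true_viability = 100 * s_primer
  ))
  design <- dplyr::bind_rows(combo, partner_alone, primer_alone)
  wells <- sim_build_plate(design, n_ctrl_wells, noise, plate_id, sample_id)
  truth <- dplyr::bind_rows(primer, partner)
  truth$delta <- interaction$delta
  list(wells = wells, truth = truth)
}

#' Simulate a 4x4 triple-combination matrix plate
#'
#' Two drugs are crossed factorially over 4 doses each while a third
#' (background) drug is fixed at one concentration in every treated well (the
#' background's IC20 in the screening design). The plate includes the
#' matrix's zero-dose margins: A-alone + background, B-alone + background,
#' and background-alone wells. Survival composes multiplicatively with the
#' background; the synergy `delta` of the [interaction_model()] applies to
#' the (A, B) pair only.
#'
#' @param drugA,drugB ground-truth profiles of the two titrated drugs.
#' @param concsA,concsB dose grids of exactly 4 nM values each; default
#'   0.1-100 nM.
#' @param background ground-truth profile of the fixed third drug.
#' @param background_conc its fixed concentration in nM.
#' @param interaction an [interaction_model()] for the (A, B) pair.
#' @inheritParams simulate_single_agent
#' @return list with `wells` and `truth`.
#' @export
simulate_triple_matrix <- function(drugA, drugB,
                                   concsA = c(0.1, 1, 10, 100),
                                   concsB = c(0.1, 1, 10, 100),
                                   background, background_conc,
                                   interaction = interaction_model(),
                                   n_replicates = 2, n_ctrl_wells = 16,
                                   noise = noise_model(),
                                   plate_id = "P1", sample_id = "S1") {
  if (length(concsA) != 4 || length(concsB) != 4) {
    stop("the triple design uses a 4x4 concentration matrix", call. = FALSE)
  }
  if (background_conc <= 0) stop("background_conc must be positive", call. = FALSE)
  s_bg <- sim_survival(background, background_conc)
  rep_rows <- function(df) df[rep(seq_len(nrow(df)), each = n_replicates), ]

  grid <- tidyr::expand_grid(conc_a = concsA, conc_b = concsB)
  s_ab <- clamp(sim_survival(drugA, grid$conc_a) * sim_survival(drugB, grid$conc_b) -
                  interaction$delta, 0, 1)
  matrix_wells <- rep_rows(tibble(
    drug1 = drugA$drug, conc1_nM = grid$conc_a,
    drug2 = drugB$drug, conc2_nM = grid$conc_b,
    drug3 = background$drug, conc3_nM = background_conc,
    true_viability = 100 * clamp(s_ab * s_bg, 0, 1)
  ))
  a_margin <- rep_rows(tibble(
    drug1 = drugA$drug, conc1_nM = concsA,
    drug2 = NA_character_, conc2_nM = NA_real_,
    drug3 = background$drug, conc3_nM = background_conc,
    true_viability = 100 * sim_survival(drugA, concsA) * s_bg
  ))
  b_margin <- rep_rows(tibble(
    drug1 = NA_character_, conc1_nM = NA_real_,
    drug2 = drugB$drug, conc2_nM = concsB,
    drug3 = background$drug, conc3_nM = background_conc,
    true_viability = 100 * sim_survival(drugB, concsB) * s_bg
  ))
  bg_alone <- rep_rows(tibble(
    drug1 = NA_character_, conc1_nM = NA_real_,
    drug2 = NA_character_, conc2_nM = NA_real_,
    drug3 = background$drug, conc3_nM = background_conc,
    true_viability = 100 * s_bg
  ))
  design <- dplyr::bind_rows(matrix_wells, a_margin, b_margin, bg_alone)
  wells <- sim_build_plate(design, n_ctrl_wells, noise, plate_id, sample_id)
  truth <- dplyr::bind_rows(drugA, drugB, background)
  truth$delta <- interaction$delta
  list(wells = wells, truth = truth)
}

#' Random drug panel for cohort simulations
#'
#' Draws a realistic screening library from the current RNG stream: IC50
#' log-uniform over `ic50_range`, Hill slope lognormal around 1 (sdlog 0.25),
#' top fixed at 100% and bottom uniform over `bottom_range` (ATP-viability
#' screens of primary cells typically plateau above complete kill).
#'
#' @param n_drugs number of drugs.
#' @param ic50_range IC50 range in nM (log-uniform draw).
#' @param bottom_range lower-asymptote range in percent viability.
#' @return tibble of ground-truth profiles.
#' @export
random_drug_panel <- function(n_drugs, ic50_range = c(1, 1000),
                              bottom_range = c(0, 20)) {
  tibble(
    drug = sprintf("drug%02d", seq_len(n_drugs)),
    ic50 = 10^stats::runif(n_drugs, log10(ic50_range[1]), log10(ic50_range[2])),
    slope = stats::rlnorm(n_drugs, 0, 0.25),
    top = 100,
    bottom = stats::runif(n_drugs, bottom_range[1], bottom_range[2])
  )
}

#' Simulate a screening cohort with per-sample heterogeneity
#'
#' One single-agent plate per sample. Each sample's IC50 for each drug is the
#' panel median times a lognormal factor with spread `heterogeneity` (sdlog).
#' In two-group mode, half the samples (rounded down) form a "resistant"
#' group whose IC50s are multiplied by `fold_shift` on a stated subset of the
#' drugs, giving ground-truth labels for clustering recovery tests. The
#' ground-truth DSS of every (sample, drug) pair is computed analytically
#' from the sample's true curve.
#'
#' @param n_samples number of samples (>= 2); sample `i` is `"S<i>"` on plate
#'   `"P<i>"`.
#' @param drugs panel of ground-truth profiles (e.g. [random_drug_panel()]).
#' @param concentrations dose grid in nM.
#' @param heterogeneity lognormal sdlog of the per-sample IC50 spread (>= 0);
#'   0 makes all samples identical.
#' @param n_replicates wells per (drug, dose); the 30-drug cohort design uses
#'   1 so a sample fits on one plate (180 treated wells + controls).
#' @param noise a [noise_model()]; its `seed` seeds the whole cohort.
#' @param two_group if `TRUE`, inject a sensitive/resistant group structure.
#' @param fold_shift IC50 multiplier for the resistant group.
#' @param prop_shifted_drugs fraction of drugs (first drugs in panel order)
#'   carrying the shift.
#' @param dss_t activity threshold used for the analytic ground-truth DSS.
#' @return list with `wells` (all plates row-bound), `truth` (sample_id,
#'   drug, ic50, slope, top, bottom, true_dss, group_label) and `profiles`
#'   (the drug panel).
#' @export
simulate_cohort <- function(n_samples, drugs,
                            concentrations = c(0.1, 1, 10, 100, 1000, 10000),
                            heterogeneity = 0.5, n_replicates = 1,
                            noise = noise_model(),
                            two_group = FALSE, fold_shift = 100,
                            prop_shifted_drugs = 0.5, dss_t = 10) {
  stopifnot(n_samples >= 2, heterogeneity >= 0)
  if (!is.null(noise$seed)) set.seed(noise$seed)
  nm <- noise
  nm$seed <- NULL

  n_shift <- floor(nrow(drugs) * prop_shifted_drugs)
  shifted <- drugs$drug[seq_len(n_shift)]
  group <- rep("sensitive", n_samples)
  if (two_group) group[seq_len(n_samples %/% 2)] <- "resistant"

  all_wells <- vector("list", n_samples)
  all_truth <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    prof <- drugs
    prof$ic50 <- prof$ic50 * stats::rlnorm(nrow(prof), 0, heterogeneity)
    if (two_group && group[i] == "resistant") {
      sel <- prof$drug %in% shifted
      prof$ic50[sel] <- prof$ic50[sel] * fold_shift
    }
    sid <- sprintf("S%02d", i)
    sim <- simulate_single_agent(prof, concentrations, n_replicates,
                                 noise = nm,
                                 plate_id = sprintf("P%02d", i),
                                 sample_id = sid)
    all_wells[[i]] <- sim$wells
    tr <- prof
    tr$sample_id <- sid
    tr$group_label <- group[i]
    tr$true_dss <- vapply(seq_len(nrow(prof)), function(j) {
      cur <- dose_response_curve("LL4", b = prof$slope[j], c = prof$bottom[j],
                                 d = prof$top[j], e = prof$ic50[j],
                                 conc_range = range(concentrations))
      dss(cur, config = dss_config(t = dss_t))
    }, numeric(1))
    all_truth[[i]] <- tr
  }
  list(wells = dplyr::bind_rows(all_wells),
       truth = dplyr::bind_rows(all_truth)[, c("sample_id", "drug", "ic50",
                                               "slope", "top", "bottom",
                                               "true_dss", "group_label")],
       profiles = drugs)
}
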