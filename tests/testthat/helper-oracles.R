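# Independent oracles used by the tests. These never call the package's own
# integrators/statistics for the quantity they check.

# Brute-force DSS oracle: dense trapezoid over the clamped inhibition of an
# explicit LL4/L4 parameter set (formulas written out here, independent of
# predict_viability()).
dss_oracle <- function(b, c, d, e, range, t = 10, model = "LL4", n = 1e5) {
  x <- seq(log10(range[1]), log10(range[2]), length.out = n)
  v <- if (model == "LL4") {
    c + (d - c) / (1 + exp(b * (log(10^x) - log(e))))
  } else {
    c + (d - c) / (1 + exp(b * (x - e)))
  }
  inh <- pmin(pmax(100 - v, 0), 100)
  i0 <- which(inh >= t)[1]
  if (is.na(i0) || i0 == n) return(0)
  xs <- x[i0:n]; ys <- inh[i0:n] - t
  a <- sum((ys[-1] + ys[-length(ys)]) / 2 * diff(xs))
  100 * a / ((100 - t) * (x[n] - x[1]))
}

# Exact two-sided Mann-Whitney p by enumeration of all group assignments.
mw_enum_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled); m <- length(x)
  u_of <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  u_obs <- u_of(x, y)
  combos <- utils::combn(n, m)
  us <- apply(combos, 2, function(idx) u_of(pooled[idx], pooled[-idx]))
  mu <- m * (n - m) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# Random plausible fitted curves for property tests.
random_curve <- function() {
  e <- 10^runif(1, -0.5, 3.5)
  dose_response_curve("LL4",
                      b = runif(1, 0.3, 3),
                      c = runif(1, 0, 40),
                      d = runif(1, 80, 110),
                      e = e,
                      conc_range = c(0.1, 10000))
}

# Minimal normalized-well table builder for QC-rule unit tests.
make_norm_wells <- function(viability, drug = "drugX", conc = 10,
                            role = "treated", plate_id = "P1",
                            sample_id = "S1") {
  n <- length(viability)
  tibble::tibble(
    plate_id = plate_id,
    well = sprintf("%s%02d", rep(LETTERS[1:16], length.out = n),
                   ((seq_len(n) - 1) %% 24) + 1),
    sample_id = sample_id,
    drug1 = if (role == "treated") drug else NA_character_,
    conc1_nM = if (role == "treated") conc else NA_real_,
    drug2 = NA_character_, conc2_nM = NA_real_,
    drug3 = NA_character_, conc3_nM = NA_real_,
    role = role, signal = NA_real_,
    qc_outlier = FALSE, qc_excluded = FALSE,
    viability_pct = viability,
    inhibition_frac = pmin(pmax((100 - viability) / 100, 0), 1)
  )
}

# Long DSS records from a named samples-by-treatments matrix.
records_from_matrix <- function(m) {
  df <- expand.grid(sample_id = rownames(m), treatment_label = colnames(m),
                    stringsAsFactors = FALSE)
  df$dss <- m[cbind(df$sample_id, df$treatment_label)]
  tibble::as_tibble(df[!is.na(df$dss), ])
}

# Control wells engineered to exact mean/SD: two wells at mu +/- sd/sqrt(2)
# have sample mean mu and sample SD sd.
make_control_plate <- function(mu_neg, sd_neg, mu_pos, sd_pos,
                               plate_id = "P1") {
  sig <- c(mu_neg - sd_neg / sqrt(2), mu_neg + sd_neg / sqrt(2),
           mu_pos - sd_pos / sqrt(2), mu_pos + sd_pos / sqrt(2))
  tibble::tibble(
    plate_id = plate_id,
    well = c("A01", "A02", "A03", "A04"),
    sample_id = "S1",
    drug1 = NA_character_, conc1_nM = NA_real_,
    drug2 = NA_character_, conc2_nM = NA_real_,
    drug3 = NA_character_, conc3_nM = NA_real_,
    role = rep(c("negative_control", "positive_control"), each = 2),
    signal = sig,
    qc_outlier = FALSE, qc_excluded = FALSE
  )
}
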