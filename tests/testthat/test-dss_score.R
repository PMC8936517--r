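full_range <- c(0.1, 10000)

const_curve <- function(viability) {
  dose_response_curve("LL4", b = 0, c = viability, d = viability, e = 10,
                      conc_range = full_range)
}

test_that("DSS analytic battery: saturated, sub-threshold and constant curves", {
  expect_equal(dss(const_curve(0)), 100)            # 100% inhibition everywhere
  expect_equal(dss(const_curve(95)), 0)             # inhibition 5 < t
  expect_equal(dss(const_curve(45)), 50)            # inhibition 55, t = 10
  expect_equal(dss(const_curve(90)), 0)             # inhibition == t exactly
  expect_error(dss(const_curve(45), range = c(10, 10)), "degenerate")
})

test_that("DSS is monotone non-increasing in the activity threshold", {
  set.seed(21)
  for (i in 1:10) {
    cur <- random_curve()
    vals <- vapply(c(0, 5, 10, 20, 40), function(t) {
      dss(cur, config = dss_config(t = t))
    }, numeric(1))
    expect_true(all(diff(vals) <= 1e-9))
    expect_true(all(vals >= 0 & vals <= 100))
  }
})

test_that("DSS is invariant to concentration-unit reparameterization", {
  cur_nM <- dose_response_curve("LL4", 1.2, 5, 100, 30, conc_range = full_range)
  cur_uM <- dose_response_curve("LL4", 1.2, 5, 100, 30 / 1000,
                                conc_range = full_range / 1000)
  expect_equal(dss(cur_nM), dss(cur_uM), tolerance = 1e-12)
})

test_that("widening the range on the inactive side can only decrease DSS", {
  cur <- dose_response_curve("LL4", 1, 0, 100, 100, conc_range = c(1, 10000))
  base <- dss(cur, range = c(1, 10000))
  widened <- dss(cur, range = c(0.001, 10000))
  expect_lt(widened, base)
})

test_that("production integrator agrees with the brute-force quadrature oracle", {
  set.seed(22)
  for (i in 1:30) {
    b <- runif(1, 0.3, 3); c <- runif(1, -10, 40); d <- runif(1, 60, 120)
    e <- 10^runif(1, -1, 4)
    cur <- dose_response_curve("LL4", b, c, d, e, conc_range = full_range)
    expect_equal(dss(cur),
                 dss_oracle(b, c, d, e, full_range),
                 tolerance = 1e-3)
  }
  # the L4 branch integrates through the same grid
  cur4 <- dose_response_curve("L4", 2.5, 0, 100, 1.5, conc_range = full_range)
  expect_equal(dss(cur4), dss_oracle(2.5, 0, 100, 1.5, full_range, model = "L4"),
               tolerance = 1e-3)
})

test_that("efficacy bands follow the 0-10 / 10-40 / 40-100 convention", {
  expect_equal(classify_dss(c(64.5, 10, 10.5, 0, 40, 40.5, 100)),
               c("high", "low", "intermediate", "low", "intermediate",
                 "high", "high"))
  expect_error(classify_dss(101))
})

test_that("double-combination DSS compares combo and single on one range", {
  combo_range <- c(0.1, 1000)
  cur <- dose_response_curve("LL4", 1, 0, 100, 50, conc_range = combo_range)
  same <- combo_dss_double(cur, cur)
  expect_equal(same$delta, 0)

  sat <- const_curve(0); sat$conc_range <- combo_range
  dud <- const_curve(95)
  ext <- combo_dss_double(sat, dud, range = combo_range)
  expect_equal(ext$dss_combo, 100)
  expect_equal(ext$delta, 100)

  narrow <- dose_response_curve("LL4", 1, 0, 100, 5, conc_range = c(0.1, 10))
  expect_error(combo_dss_double(sat, narrow, range = c(0.1, 1000)),
               "not covered")
  expect_silent(combo_dss_double(sat, narrow, range = c(0.1, 1000),
                                 override = TRUE))
})

test_that("combo DSS delta is positive under injected synergy with a potent primer", {
  set.seed(23)
  hits <- 0
  for (i in 1:40) {
    primer <- gt_profile("p", ic50 = 8)
    partner <- gt_profile("q", ic50 = 500)
    sim <- simulate_double_primed(primer, 2, partner,
                                  interaction = interaction_model("bliss_shifted", 0.1),
                                  noise = noise_model(cv = 0.05, seed = 9000 + i))
    nv <- normalize_viability(sim$wells)
    combo <- nv[!is.na(nv$drug1) & !is.na(nv$drug2), ]
    alone <- nv[!is.na(nv$drug1) & is.na(nv$drug2) & nv$drug1 == "q", ]
    fit_c <- fit_curve(combo$conc2_nM, combo$viability_pct)
    fit_s <- fit_curve(alone$conc1_nM, alone$viability_pct)
    res <- combo_dss_double(fit_c, fit_s, range = c(0.1, 1000))
    hits <- hits + (res$delta > 0)
  }
  expect_gte(hits / 40, 0.95)
})

test_that("triple-matrix DSS averages the per-line scores", {
  concs <- c(0.1, 1, 10, 100)
  grid <- expand.grid(conc_a = concs, conc_b = concs)

  sat <- grid; sat$inhibition <- 1
  expect_equal(combo_dss_triple(sat)$dss, 100)

  dead <- grid; dead$inhibition <- 0.05
  expect_equal(combo_dss_triple(dead)$dss, 0)

  expect_error(combo_dss_triple(grid[-1, ] |> transform(inhibition = 0.5)),
               "incomplete")

  # rows generated from known curves: average of analytic row DSS values
  row_e <- c(2, 8, 30, 120)  # per-row midpoints in nM
  cells <- do.call(rbind, lapply(seq_along(concs), function(i) {
    data.frame(conc_a = concs[i], conc_b = concs,
               inhibition = 1 - hill_viability(concs, row_e[i]) / 100)
  }))
  got <- combo_dss_triple(cells)
  want <- mean(vapply(row_e, function(e) {
    dss_oracle(1, 0, 100, e, range(concs))
  }, numeric(1)))
  expect_equal(got$dss, want, tolerance = 1e-2)

  # column-wise orientation transposes the matrix
  got_cols <- combo_dss_triple(cells, orientation = "cols")
  expect_false(isTRUE(all.equal(got$dss, got_cols$dss, tolerance = 1e-6)))
})
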