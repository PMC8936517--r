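test_that("bliss_expected follows the independence formula and its limits", {
  expect_equal(bliss_expected(0.5, 0.5), 0.75)
  expect_equal(bliss_expected(0.3, 0.4), 0.58)
  expect_equal(bliss_expected(0, 0.37), 0.37)
  expect_equal(bliss_expected(1, 0.37), 1)
  expect_error(bliss_expected(-0.1, 0.5), "\\[0, 1\\]")
  expect_error(bliss_expected(0.5, 1.2), "\\[0, 1\\]")
})

test_that("excess matrix is zero for exact Bliss surfaces and additive shifts are recovered", {
  fA <- c(0.1, 0.3, 0.5, 0.7)
  fB <- c(0.05, 0.2, 0.4, 0.8)
  obs <- outer(fA, fB, function(a, b) a + b - a * b)
  res <- excess_matrix(obs, fA, fB, 1:4, 1:4)
  expect_equal(res$grid$excess, rep(0, 16))
  expect_equal(res$synergy_sum, 0)
  expect_false(res$synergistic)  # strict > 0

  # uniform +5-point injected excess: sum 80, mean 5
  res5 <- excess_matrix(pmin(obs + 0.05, 1), fA, fB, 1:4, 1:4)
  expect_equal(res5$mean_synergy, 5, tolerance = 1e-9)
  expect_equal(res5$synergy_sum, 80, tolerance = 1e-9)
  expect_true(res5$synergistic)
})

test_that("synergy_sum equals mean times cell count for any grid shape", {
  set.seed(31)
  for (shape in list(c(1, 5), c(4, 4), c(3, 7))) {
    fA <- runif(shape[1]); fB <- runif(shape[2])
    obs <- matrix(runif(prod(shape)), shape[1], shape[2])
    res <- excess_matrix(obs, fA, fB, seq_len(shape[1]), seq_len(shape[2]))
    expect_equal(res$synergy_sum, res$mean_synergy * res$n_cells,
                 tolerance = 1e-12)
    expect_equal(res$n_cells, prod(shape))
  }
})

test_that("excess is antisymmetric and shift-monotone", {
  set.seed(32)
  fA <- runif(4); fB <- runif(4)
  obs <- matrix(runif(16), 4, 4)
  exp_m <- outer(fA, fB, bliss_expected)
  res <- excess_matrix(obs, fA, fB, 1:4, 1:4)
  # zero iff observed equals expected
  expect_equal(excess_matrix(exp_m, fA, fB, 1:4, 1:4)$grid$excess, rep(0, 16))
  # adding a positive shift (clamped away from 1) never decreases the mean
  shifted <- pmin(obs + 0.03, 1)
  expect_gte(excess_matrix(shifted, fA, fB, 1:4, 1:4)$mean_synergy,
             res$mean_synergy)
})

test_that("shape errors name the offending input", {
  expect_error(excess_matrix(matrix(0.5, 3, 4), runif(3), runif(3), 1:3, 1:4),
               "monotherapy")
  expect_error(excess_matrix(matrix(0.5, 3, 4), runif(4), runif(4), 1:4, 1:4),
               "shape")
  expect_error(excess_matrix(matrix(1.5, 4, 4), runif(4), runif(4), 1:4, 1:4),
               "fractions")
})

test_that("primed-double synergy scores the titration cell-wise", {
  primer_curve <- dose_response_curve("LL4", 1, 0, 100, 8,
                                      conc_range = c(0.1, 10000))
  partner_curve <- dose_response_curve("LL4", 1, 0, 100, 300,
                                       conc_range = c(0.1, 10000))
  concs <- c(0.1, 1, 10, 100, 1000)
  f_primer <- 1 - 1 / (1 + 2 / 8)          # 0.2 at the fixed 2 nM
  f_partner <- 1 - 1 / (1 + concs / 300)

  # observed exactly at the Bliss prediction -> all-zero scores
  obs <- bliss_expected(f_primer, f_partner)
  res0 <- primed_double_synergy(obs, concs, primer_curve, 2,
                                partner_curve = partner_curve)
  expect_equal(res0$grid$excess, rep(0, 5), tolerance = 1e-9)
  expect_false(res0$synergistic)
  expect_equal(res0$design, "double_primed")

  # worked cell: primer 0.2, partner 0.5, observed 0.75 -> +15 points
  res1 <- primed_double_synergy(0.75, 300, primer_curve, 2,
                                partner_inhibition = 0.5)
  expect_equal(res1$grid$excess, 15, tolerance = 1e-9)

  expect_error(primed_double_synergy(obs, concs, primer_curve, 1e9),
               "evaluable span")
})

test_that("simulated synergy injection is recovered by the scoring", {
  primer <- gt_profile("A", ic50 = 8)
  partner <- gt_profile("B", ic50 = 500)
  means <- vapply(1:25, function(i) {
    sim <- simulate_double_primed(primer, 2, partner,
                                  interaction = interaction_model("bliss_shifted", 0.1),
                                  noise = noise_model(cv = 0.05, seed = 700 + i))
    nv <- normalize_viability(sim$wells)
    combo <- nv[!is.na(nv$drug1) & !is.na(nv$drug2), ]
    obs <- tapply(combo$inhibition_frac, combo$conc2_nM, mean)
    alone_b <- nv[is.na(nv$drug2) & !is.na(nv$drug1) & nv$drug1 == "B", ]
    f_b <- tapply(alone_b$inhibition_frac, alone_b$conc1_nM, mean)
    alone_a <- nv[is.na(nv$drug2) & !is.na(nv$drug1) & nv$drug1 == "A", ]
    res <- excess_matrix(matrix(obs, nrow = 1), mean(alone_a$inhibition_frac),
                         f_b, 2, sort(unique(combo$conc2_nM)),
                         design = "double_primed")
    res$mean_synergy
  }, numeric(1))
  expect_equal(mean(means), 10, tolerance = 0.2)
})

test_that("landscape export preserves shape and sign", {
  fA <- c(0.2, 0.4, 0.6, 0.8); fB <- fA
  obs <- outer(fA, fB, function(a, b) pmin(pmax(a + b - a * b - 0.05, 0), 1))
  res <- excess_matrix(obs, fA, fB, c(0.1, 1, 10, 100), c(0.1, 1, 10, 100))
  tbl <- landscape_export(res)
  expect_equal(nrow(tbl), 16)
  expect_named(tbl, c("conc_a", "conc_b", "excess"))
  expect_true(all(tbl$excess < 0))  # antagonism keeps its sign

  path <- withr::local_tempfile(fileext = ".csv")
  write_results(tbl, path)
  back <- read_results(path)
  expect_equal(as.data.frame(back), as.data.frame(tbl), tolerance = 1e-12)
})
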