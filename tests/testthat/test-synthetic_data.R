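test_that("noiseless single-agent signals sit exactly on the true curve", {
  prof <- gt_profile("d1", ic50 = 10, slope = 1, top = 100, bottom = 0)
  nm0 <- noise_model(cv = 0, pos_ctrl_fraction = 0, seed = 1)
  sim <- simulate_single_agent(prof, noise = nm0)
  w <- sim$wells
  half <- w$signal[!is.na(w$drug1) & w$conc1_nM == 10]
  expect_equal(half, rep(0.5 * nm0$neg_ctrl_signal, length(half)))

  # with a luminescence background the half-max well sits halfway between
  # the control means
  nm <- noise_model(cv = 0, seed = 1)
  w2 <- simulate_single_agent(prof, noise = nm)$wells
  mu_neg <- mean(w2$signal[w2$role == "negative_control"])
  mu_pos <- mean(w2$signal[w2$role == "positive_control"])
  half2 <- w2$signal[!is.na(w2$drug1) & w2$conc1_nM == 10]
  expect_equal(half2 - mu_pos, rep(0.5 * (mu_neg - mu_pos), length(half2)))
})

test_that("identical seeds reproduce plates bit for bit; cv = 0 is deterministic", {
  prof <- random_drug_panel(2)
  a <- simulate_single_agent(prof, noise = noise_model(cv = 0.1, seed = 42))
  b <- simulate_single_agent(prof, noise = noise_model(cv = 0.1, seed = 42))
  expect_identical(a$wells, b$wells)

  z1 <- simulate_single_agent(prof, noise = noise_model(cv = 0, seed = 1))
  z2 <- simulate_single_agent(prof, noise = noise_model(cv = 0, seed = 99))
  expect_identical(z1$wells$signal, z2$wells$signal)
})

test_that("empirical CV of replicate wells matches the lognormal noise model", {
  prof <- gt_profile("d1", ic50 = 1e6)  # essentially untreated wells
  sim <- simulate_single_agent(prof, concentrations = 1, n_replicates = 100,
                               noise = noise_model(cv = 0.05, seed = 7))
  s <- sim$wells$signal[!is.na(sim$wells$drug1)]
  expect_length(s, 100)
  expect_gt(sd(s) / mean(s), 0.03)
  expect_lt(sd(s) / mean(s), 0.07)
})

test_that("design violations are rejected", {
  prof <- gt_profile("d1", 10)
  expect_error(simulate_single_agent(prof, concentrations = c(10, 1)),
               "strictly increasing")
  expect_error(noise_model(cv = -0.1))
  expect_error(simulate_double_primed(prof, 0, gt_profile("d2", 100)),
               "positive")
  expect_error(
    simulate_double_primed(prof, 2, gt_profile("d2", 100),
                           partner_concs = c(0.1, 1, 10, 100)),
    "exactly 5")
  expect_error(
    simulate_triple_matrix(prof, gt_profile("d2", 100),
                           concsA = c(0.1, 1, 10),
                           background = gt_profile("d3", 5),
                           background_conc = 1),
    "4x4")
  expect_error(interaction_model("bliss_independent", delta = 0.1))
})

test_that("primed-double wells follow the interaction model exactly at cv = 0", {
  primer <- gt_profile("primer", ic50 = 8, slope = 1)
  partner <- gt_profile("partner", ic50 = 300, slope = 1)
  pc <- 2  # primer survival 0.8
  concs <- c(0.1, 1, 10, 100, 1000)
  s_primer <- 1 / (1 + pc / 8)
  s_partner <- 1 / (1 + concs / 300)

  ind <- simulate_double_primed(primer, pc, partner, concs,
                                interaction_model("bliss_independent"),
                                noise = noise_model(cv = 0, seed = 1))
  combo <- ind$wells[!is.na(ind$wells$drug1) & !is.na(ind$wells$drug2), ]
  combo <- combo[order(combo$conc2_nM), ]
  expect_equal(combo$true_viability,
               rep(100 * s_primer * s_partner, each = 2))

  shift <- simulate_double_primed(primer, pc, partner, concs,
                                  interaction_model("bliss_shifted", 0.1),
                                  noise = noise_model(cv = 0, seed = 1))
  combo2 <- shift$wells[!is.na(shift$wells$drug1) & !is.na(shift$wells$drug2), ]
  combo2 <- combo2[order(combo2$conc2_nM), ]
  # inhibition exceeds the Bliss expectation by exactly 10 points
  excess <- (100 - combo2$true_viability) -
    rep(100 * (1 - s_primer * s_partner), each = 2)
  expect_equal(excess, rep(10, length(excess)))
})

test_that("triple-matrix survival composes multiplicatively with the background", {
  # background survival 0.8 at 1 nM (ic50 = 4), drug A survival 0.5 at 10 nM
  a <- gt_profile("A", ic50 = 10, slope = 1)
  b <- gt_profile("B", ic50 = 50, slope = 1)
  bg <- gt_profile("C", ic50 = 4, slope = 1)
  sim <- simulate_triple_matrix(a, b, background = bg, background_conc = 1,
                                noise = noise_model(cv = 0, seed = 1))
  w <- sim$wells
  a_margin <- w[!is.na(w$drug1) & is.na(w$drug2) & !is.na(w$drug3) &
                  w$conc1_nM == 10, ]
  expect_equal(a_margin$true_viability, rep(40, nrow(a_margin)))

  # delta = 0: every 4x4 cell matches conditional Bliss from the margins
  nw <- normalize_viability(w)
  syn <- matrix_synergy_from_plate(nw, "A", "B", "C")
  expect_equal(syn$grid$excess, rep(0, 16), tolerance = 1e-9)
  expect_equal(syn$synergy_sum, 0, tolerance = 1e-7)
})

test_that("cohort simulation has the stated shape and heterogeneity behavior", {
  panel <- local({set.seed(3); random_drug_panel(30)})
  sim <- simulate_cohort(4, panel, heterogeneity = 0,
                         noise = noise_model(cv = 0, seed = 5))
  expect_length(unique(sim$wells$plate_id), 4)
  per_plate <- table(sim$wells$plate_id[!is.na(sim$wells$drug1)])
  expect_true(all(per_plate == 180))  # 30 drugs x 6 concentrations x 1 rep
  # zero spread: every sample carries identical true parameters and DSS
  by_drug <- split(sim$truth, sim$truth$drug)
  expect_true(all(vapply(by_drug, function(d) {
    length(unique(d$ic50)) == 1 && length(unique(d$true_dss)) == 1
  }, logical(1))))

  two <- simulate_cohort(6, panel[1:4, ], heterogeneity = 0.2,
                         noise = noise_model(cv = 0, seed = 5),
                         two_group = TRUE, fold_shift = 100)
  expect_setequal(unique(two$truth$group_label), c("sensitive", "resistant"))
  expect_equal(sum(tapply(two$truth$group_label, two$truth$sample_id,
                          function(g) g[1]) == "resistant"), 3)
})
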