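test_that("cohort assembly pivots records with explicit missingness", {
  m <- matrix(c(10, 20, 30, 40, 50, NA), nrow = 3,
              dimnames = list(c("S1", "S2", "S3"), c("d1", "d2")))
  cm <- assemble_cohort(records_from_matrix(m))
  expect_s3_class(cm, "cohort_matrix")
  expect_equal(dim(cm$dss), c(3, 2))
  expect_equal(cm$n_missing, 1)
  expect_equal(unname(cm$missing_by_treatment["d2"]), 1)

  dup <- rbind(records_from_matrix(m),
               tibble::tibble(sample_id = "S1", treatment_label = "d1", dss = 5))
  expect_error(assemble_cohort(dup), "duplicate.*S1 / d1")
  expect_error(assemble_cohort(records_from_matrix(m)[1:2, ]), ">= 2")
  bad <- records_from_matrix(m); bad$dss[1] <- 101
  expect_error(assemble_cohort(bad), "\\[0, 100\\]")
})

test_that("annotations align to samples with explicit NA", {
  m <- matrix(1:4, 2, dimnames = list(c("S1", "S2"), c("d1", "d2")))
  ann <- tibble::tibble(sample_id = "S2", stage = "RMM")
  cm <- assemble_cohort(records_from_matrix(m), annotations = ann)
  expect_equal(cm$annotations$stage, c(NA, "RMM"))
})

test_that("identical samples merge first at height zero; hand-computed Ward order holds", {
  m <- matrix(c(10, 10, 50, 20, 20, 80), nrow = 3,
              dimnames = list(c("S1", "S2", "S3"), c("d1", "d2")))
  hc <- cluster_cohort(assemble_cohort(records_from_matrix(m)))$samples$hclust
  expect_equal(hc$height[1], 0)
  expect_equal(sort(hc$merge[1, ]), c(-2, -1))

  # points (0,0), (0,1), (10,10): Ward joins the close pair first
  m2 <- matrix(c(0, 0, 10, 0, 1, 10), nrow = 3,
               dimnames = list(c("A", "B", "C"), c("d1", "d2")))
  hc2 <- cluster_cohort(assemble_cohort(records_from_matrix(m2)))$samples$hclust
  expect_equal(sort(hc2$merge[1, ]), c(-2, -1))
  expect_equal(hc2$height[1], 1)  # Euclidean distance of the first pair
})

test_that("merge heights are monotone and the partition ignores sample order", {
  set.seed(41)
  m <- matrix(runif(60, 0, 100), nrow = 10,
              dimnames = list(sprintf("S%02d", 1:10), sprintf("d%d", 1:6)))
  cl <- cluster_cohort(assemble_cohort(records_from_matrix(m)), k = 3)
  expect_true(all(diff(cl$samples$hclust$height) >= -1e-9))

  perm <- sample(nrow(m))
  cl2 <- cluster_cohort(assemble_cohort(records_from_matrix(m[perm, ])), k = 3)
  l1 <- cl$samples$labels
  l2 <- cl2$samples$labels[names(l1)]
  expect_equal(mclust::adjustedRandIndex(l1, l2), 1)
})

test_that("missing cells are median-imputed before clustering", {
  m <- matrix(c(10, 20, 30, 40, 50, NA), nrow = 3,
              dimnames = list(c("S1", "S2", "S3"), c("d1", "d2")))
  cl <- cluster_cohort(assemble_cohort(records_from_matrix(m)), k = 2)
  expect_equal(cl$n_imputed, 1)
  expect_length(cl$samples$labels, 3)
})

test_that("a two-group cohort with a 100x IC50 shift is recovered by Ward clustering", {
  aris <- vapply(1:5, function(s) {
    panel <- local({set.seed(100 + s); random_drug_panel(10)})
    sim <- simulate_cohort(16, panel, heterogeneity = 0.5,
                           noise = noise_model(cv = 0.05, seed = 100 + s),
                           two_group = TRUE, fold_shift = 100)
    res <- run_pipeline(sim$wells, pipeline_config(cluster_k = 2))
    labels <- res$clusters$samples$labels
    truth <- tapply(sim$truth$group_label, sim$truth$sample_id, `[`, 1)
    mclust::adjustedRandIndex(labels, truth[names(labels)])
  }, numeric(1))
  expect_gte(mean(aris), 0.9)
})

test_that("newick export writes a tree over all samples", {
  m <- matrix(runif(40, 0, 100), nrow = 8,
              dimnames = list(sprintf("S%d", 1:8), sprintf("d%d", 1:5)))
  cl <- cluster_cohort(assemble_cohort(records_from_matrix(m)))
  path <- withr::local_tempfile(fileext = ".nwk")
  export_newick(cl$samples$hclust, path)
  tree <- ape::read.tree(path)
  expect_setequal(tree$tip.label, rownames(m))
})

test_that("group_compare matches exact enumeration on small samples", {
  res <- group_compare(c(1, 2, 3, 4), c("a", "a", "b", "b"))
  expect_equal(res$U, 0)
  expect_equal(res$p, mw_enum_p(c(1, 2), c(3, 4)), tolerance = 1e-12)
  expect_equal(res$p, 1 / 3, tolerance = 1e-12)
  expect_equal(res$method, "exact")

  bal <- group_compare(c(1, 4, 2, 3), c("a", "a", "b", "b"))
  expect_equal(bal$p, mw_enum_p(c(1, 4), c(2, 3)), tolerance = 1e-12)

  set.seed(42)
  x <- runif(6, 0, 100); y <- runif(5, 0, 100)
  expect_equal(group_compare(c(x, y), rep(c("a", "b"), c(6, 5)))$p,
               mw_enum_p(x, y), tolerance = 1e-12)

  expect_error(group_compare(1:3, c("a", "a", "a")), "two groups")
})

test_that("group_compare is invariant under monotone transforms and approximates well at cohort size", {
  set.seed(43)
  x <- rnorm(23, 30, 12); y <- rnorm(20, 22, 12)
  v <- c(x, y); g <- rep(c("refractory", "nonrefractory"), c(23, 20))
  r1 <- group_compare(v, g)
  r2 <- group_compare(exp(v / 20), g)   # strictly monotone transform
  expect_equal(r1$U, r2$U)
  expect_equal(r1$p, r2$p, tolerance = 1e-12)
  expect_equal(r1$method, "normal_approx_tie_corrected")

  # permutation oracle for the normal approximation
  u_of <- function(a, b) sum(outer(a, b, ">"))
  u_obs <- u_of(x, y)
  mu <- length(x) * length(y) / 2
  set.seed(44)
  perm <- replicate(4000, {
    idx <- sample(length(v), length(x))
    abs(u_of(v[idx], v[-idx]) - mu)
  })
  p_perm <- mean(perm >= abs(u_obs - mu) - 1e-12)
  expect_lt(abs(r1$p - p_perm), 0.01)
})
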