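#' Assemble the samples-by-treatments cohort matrix
#'
#' Pivots DSS records into a wide matrix with explicit `NA` for absent
#' cells, carries per-sample annotations (disease stage, refractory status,
#' cytogenetic flags, ...) and reports missingness.
#'
#' @param records DSS record table ([dss_record()] schema) with >= 2 samples
#'   and >= 2 treatments.
#' @param annotations optional tibble with a `sample_id` column plus
#'   annotation columns; missing samples get explicit `NA`.
#' @return object of class `cohort_matrix`: list with `dss` (numeric
#'   matrix, samples in rows), `annotations`, `n_missing`,
#'   `missing_by_treatment`.
#' @export
assemble_cohort <- function(records, annotations = NULL) {
  stopifnot(all(c("sample_id", "treatment_label", "dss") %in% names(records)))
  if (any(!is.na(records$dss) & (records$dss < 0 | records$dss > 100))) {
    stop("DSS values must lie in [0, 100]", call. = FALSE)
  }
  key <- paste(records$sample_id, records$treatment_label, sep = " / ")
  if (anyDuplicated(key)) {
    stop("duplicate (sample, treatment) pair(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  }
  samples <- unique(records$sample_id)
  treatments <- unique(records$treatment_label)
  if (length(samples) < 2 || length(treatments) < 2) {
    stop("need >= 2 samples and >= 2 treatments", call. = FALSE)
  }
  m <- matrix(NA_real_, length(samples), length(treatments),
              dimnames = list(samples, treatments))
  m[cbind(match(records$sample_id, samples),
          match(records$treatment_label, treatments))] <- records$dss
  ann <- NULL
  if (!is.null(annotations)) {
    stopifnot("sample_id" %in% names(annotations))
    ann <- dplyr::left_join(tibble(sample_id = samples), annotations,
                            by = "sample_id")
  }
  structure(list(dss = m, annotations = ann,
                 n_missing = sum(is.na(m)),
                 missing_by_treatment = colSums(is.na(m))),
            class = "cohort_matrix")
}

#' Hierarchical clustering of the cohort matrix
#'
#' Agglomerative clustering with Euclidean distance and Ward linkage (the
#' squared-Euclidean `ward.D2` criterion, whose merge heights are
#' non-decreasing). DSS values share the 0-100 scale, so rows are clustered
#' unscaled by default; `scale = TRUE` z-scores the non-clustered axis
#' variables first. Missing cells are imputed with the treatment-wise median
#' before clustering (reported in the result).
#'
#' @param cohort a [assemble_cohort()] result.
#' @param axis cluster `"samples"` (rows), `"treatments"` (columns) or
#'   `"both"`.
#' @param k optional number of flat clusters to cut at.
#' @param scale z-score variables before clustering.
#' @return list with, per clustered axis, the `hclust` tree and (when `k`
#'   given) integer `labels`; plus `n_imputed`.
#' @export
cluster_cohort <- function(cohort, axis = c("samples", "treatments", "both"),
                           k = NULL, scale = FALSE) {
  axis <- match.arg(axis)
  stopifnot(inherits(cohort, "cohort_matrix"))
  m <- cohort$dss
  n_imputed <- sum(is.na(m))
  if (n_imputed > 0) {
    for (j in seq_len(ncol(m))) {
      med <- stats::median(m[, j], na.rm = TRUE)
      m[is.na(m[, j]), j] <- med
    }
  }
  if (any(!is.finite(m))) {
    stop("non-finite values remain after imputation", call. = FALSE)
  }
  one_axis <- function(mat) {
    if (scale) {
      sds <- apply(mat, 2, stats::sd)
      mat <- base::scale(mat, center = TRUE, scale = ifelse(sds > 0, sds, 1))
    }
    hc <- stats::hclust(stats::dist(mat, method = "euclidean"),
                        method = "ward.D2")
    labels <- if (!is.null(k)) stats::cutree(hc, k = k) else NULL
    list(hclust = hc, labels = labels)
  }
  out <- list(n_imputed = n_imputed)
  if (axis %in% c("samples", "both")) out$samples <- one_axis(m)
  if (axis %in% c("treatments", "both")) out$treatments <- one_axis(t(m))
  out
}

#' Export a dendrogram in Newick format
#'
#' Leaf names are the clustered ids, branch lengths derive from the merge
#' heights; readable by external tree viewers.
#'
#' @param hc an `hclust` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
export_newick <- function(hc, path) {
  phy <- ape::as.phylo(hc)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Two-group DSS comparison (Mann-Whitney U)
#'
#' Wilcoxon rank-sum / Mann-Whitney U test of DSS values between two groups:
#' exact enumeration of the rank distribution when the combined sample size
#' is at most 12 and there are no ties, the normal approximation with tie
#' correction otherwise.
#'
#' @param values numeric DSS values.
#' @param groups vector with exactly two distinct levels, aligned with
#'   `values`.
#' @return list with `U` (the U statistic of the first group level), `p`
#'   (two-sided) and `method`.
#' @export
group_compare <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("need exactly two groups", call. = FALSE)
  x <- values[groups == levels(groups)[1]]
  y <- values[groups == levels(groups)[2]]
  if (length(x) == 0 || length(y) == 0) {
    stop("a group is empty", call. = FALSE)
  }
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y)) <= 12 && !ties
  wt <- stats::wilcox.test(x, y, exact = exact, correct = !exact)
  list(U = unname(wt$statistic), p = wt$p.value,
       method = if (exact) "exact" else "normal_approx_tie_corrected")
}
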