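#' Pipeline configuration
#'
#' Defaults mirror the screening design: DSS activity threshold 10%
#' inhibition, Z' usability floor 0.4, outlier screening on.
#'
#' @param dss_t DSS activity threshold (% inhibition).
#' @param dss_grid_n DSS trapezoid grid size.
#' @param zprime_floor plate usability floor on Z'.
#' @param screen_outliers run the automated outlier screen.
#' @param override_qc normalize plates that fail QC instead of excluding
#'   them.
#' @param cluster_k optional flat cluster count for the cohort dendrogram.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(dss_t = 10, dss_grid_n = 1024, zprime_floor = 0.4,
                            screen_outliers = TRUE, override_qc = FALSE,
                            cluster_k = NULL) {
  structure(list(dss_t = dss_t, dss_grid_n = dss_grid_n,
                 zprime_floor = zprime_floor,
                 screen_outliers = screen_outliers,
                 override_qc = override_qc, cluster_k = cluster_k),
            class = "pipeline_config")
}

# Split treated wells by how many drugs they carry.
well_arity <- function(wells) {
  n <- (!is.na(wells$drug1)) + (!is.na(wells$drug2)) + (!is.na(wells$drug3))
  n[wells$role != "treated"] <- 0L
  n
}

#' Run the full screening analysis pipeline
#'
#' Stages, in order: provisional control normalization -> automated outlier
#' screen -> plate QC (Z' on the curated control wells, since curation is
#' what takes out the control outliers that deflate Z'; the raw Z' is
#' reported alongside) -> exclusion of plates still failing QC -> final
#' normalization excluding flagged controls -> per-(sample, drug) curve
#' fitting with IC20/IC50 -> single-agent DSS -> combination analysis
#' (combo DSS and Bliss synergy for IC20-primed double and 4x4 triple
#' designs, when such wells are present) -> cohort matrix assembly and Ward
#' clustering (when >= 2 samples and >= 2 single-agent treatments). Plates
#' failing QC are reported and excluded downstream unless `override_qc`.
#' The pipeline is deterministic: it draws no random numbers.
#'
#' @param wells canonical well table (e.g. [read_plate_table()] or a
#'   simulator's `wells`).
#' @param config a [pipeline_config()].
#' @param annotations optional per-sample annotation table for the cohort
#'   matrix.
#' @return list with `qc`, `wells` (normalized + flagged), `curves`,
#'   `dss`, `synergy`, `synergy_landscapes`, `cohort`, `clusters`.
#' @export
run_pipeline <- function(wells, config = pipeline_config(),
                         annotations = NULL) {
  qc_raw <- qc_report(wells, floor = config$zprime_floor)
  if (config$screen_outliers) {
    prov <- normalize_viability(wells, floor = config$zprime_floor,
                                override = TRUE)
    wells <- flag_outliers(prov)[, setdiff(names(prov),
                                           c("viability_pct",
                                             "inhibition_frac",
                                             "qc_override"))]
  }
  qc <- qc_report(wells, floor = config$zprime_floor)
  qc$zprime_raw <- qc_raw$zprime[match(qc$plate_id, qc_raw$plate_id)]
  usable <- qc$plate_id[qc$usable]
  if (!config$override_qc) {
    dropped <- setdiff(unique(wells$plate_id), usable)
    if (length(dropped) > 0) {
      wells <- wells[wells$plate_id %in% usable, ]
      if (nrow(wells) == 0) stop("no usable plates", call. = FALSE)
    }
  }
  norm <- normalize_viability(wells, floor = config$zprime_floor,
                              override = config$override_qc)
  dcfg <- dss_config(t = config$dss_t, grid_n = config$dss_grid_n)
  arity <- well_arity(norm)

  # ---- single agents -------------------------------------------------
  singles <- norm[arity == 1L & !is.na(norm$drug1), ]
  curves <- list(); curve_rows <- list(); dss_rows <- list()
  if (nrow(singles) > 0) {
    for (g in split(singles, paste(singles$sample_id, singles$drug1, sep = "\r"))) {
      if (length(unique(g$conc1_nM[!g$qc_outlier])) < 3) next
      fit <- fit_curve(g$conc1_nM, g$viability_pct,
                       flagged = g$qc_outlier | g$qc_excluded)
      key <- paste(g$sample_id[1], g$drug1[1], sep = "\r")
      curves[[key]] <- fit
      ic20 <- ic_value(fit, 20); ic50 <- ic_value(fit, 50)
      curve_rows[[key]] <- tibble(
        sample_id = g$sample_id[1], treatment_label = g$drug1[1],
        model = fit$model, top = fit$d, bottom = fit$c, slope = fit$b,
        midpoint_nM = if (fit$model == "LL4") fit$e else 10^fit$e,
        rss = fit$rss, converged = fit$converged,
        ic20_nM = ic20, ic50_nM = ic50
      )
      rng <- range(g$conc1_nM)
      dss_rows[[key]] <- dss_record(g$sample_id[1], g$drug1[1],
                                    dss(fit, rng, dcfg), "single", rng,
                                    config$dss_t)
    }
  }

  # ---- combinations --------------------------------------------------
  synergy_rows <- list(); landscapes <- list()
  doubles <- norm[arity == 2L & is.na(norm$drug3) & !is.na(norm$drug1) &
                    !is.na(norm$drug2), ]
  if (nrow(doubles) > 0) {
    for (g in split(doubles, paste(doubles$sample_id, doubles$drug1,
                                   doubles$drug2, sep = "\r"))) {
      n1 <- length(unique(g$conc1_nM)); n2 <- length(unique(g$conc2_nM))
      if (n1 == 1 && n2 >= 3) {
        primer <- g$drug1[1]; primer_conc <- g$conc1_nM[1]
        partner <- g$drug2[1]; pconc <- g$conc2_nM; pwell <- g
      } else if (n2 == 1 && n1 >= 3) {
        primer <- g$drug2[1]; primer_conc <- g$conc2_nM[1]
        partner <- g$drug1[1]; pconc <- g$conc1_nM; pwell <- g
      } else next
      sid <- g$sample_id[1]
      keep <- !pwell$qc_outlier & !pwell$qc_excluded
      combo_fit <- fit_curve(pconc[keep], pwell$viability_pct[keep])
      label <- paste0(primer, "@", format(primer_conc, trim = TRUE,
                                          scientific = FALSE), "+", partner)

      # monotherapy from companion single-agent wells
      mono_mean <- function(drug, concs) {
        s <- singles[singles$sample_id == sid & singles$drug1 == drug &
                       !singles$qc_outlier & !singles$qc_excluded, ]
        if (nrow(s) == 0) return(NULL)
        m <- stats::aggregate(inhibition_frac ~ conc1_nM, data = s, FUN = mean)
        f <- m$inhibition_frac[match(concs, m$conc1_nM)]
        if (any(is.na(f))) NULL else f
      }
      agg <- stats::aggregate(inhibition_frac ~ conc2,
                              data = data.frame(conc2 = pconc[keep],
                                                inhibition_frac = pwell$inhibition_frac[keep]),
                              FUN = mean)
      agg <- agg[order(agg$conc2), ]
      f_primer <- mono_mean(primer, primer_conc)
      f_partner <- mono_mean(partner, agg$conc2)
      if (!is.null(f_primer) && !is.null(f_partner)) {
        syn <- excess_matrix(matrix(agg$inhibition_frac, nrow = 1),
                             fA = f_primer, fB = f_partner,
                             concsA = primer_conc, concsB = agg$conc2,
                             design = "double_primed")
        synergy_rows[[paste(sid, label)]] <- tibble(
          sample_id = sid, combination_label = label,
          design = "double_primed", mean_synergy = syn$mean_synergy,
          synergy_sum = syn$synergy_sum, synergistic = syn$synergistic)
        landscapes[[paste(sid, label)]] <- dplyr::mutate(landscape_export(syn),
                                             sample_id = sid,
                                             combination_label = label)
      }
      skey <- paste(sid, partner, sep = "\r")
      if (!is.null(curves[[skey]])) {
        cd <- combo_dss_double(combo_fit, curves[[skey]],
                               range = range(pconc), config = dcfg,
                               override = TRUE)
        dss_rows[[paste0("d\r", sid, label)]] <- dss_record(
          sid, label, cd$dss_combo, "combo_double", range(pconc),
          config$dss_t)
      }
    }
  }

  triples <- norm[arity == 3L, ]
  triple_bg <- norm[arity %in% c(1L, 2L), ]
  if (nrow(triples) > 0) {
    for (g in split(triples, paste(triples$sample_id, triples$drug1,
                                   triples$drug2, triples$drug3, sep = "\r"))) {
      sid <- g$sample_id[1]
      drugA <- g$drug1[1]; drugB <- g$drug2[1]; bg <- g$drug3[1]
      label <- paste0(drugA, "+", drugB, "+", bg, "@",
                      format(g$conc3_nM[1], trim = TRUE, scientific = FALSE))
      plate <- norm[norm$plate_id %in% unique(g$plate_id) &
                      norm$sample_id == sid, ]
      syn <- try(matrix_synergy_from_plate(plate, drugA, drugB, bg),
                 silent = TRUE)
      if (!inherits(syn, "try-error")) {
        synergy_rows[[paste(sid, label)]] <- tibble(
          sample_id = sid, combination_label = label,
          design = "triple_matrix", mean_synergy = syn$mean_synergy,
          synergy_sum = syn$synergy_sum, synergistic = syn$synergistic)
        landscapes[[paste(sid, label)]] <- dplyr::mutate(landscape_export(syn),
                                             sample_id = sid,
                                             combination_label = label)
      }
      keep <- !g$qc_outlier & !g$qc_excluded
      cells <- tibble(conc_a = g$conc1_nM[keep], conc_b = g$conc2_nM[keep],
                      inhibition = g$inhibition_frac[keep])
      ct <- try(combo_dss_triple(cells, dcfg), silent = TRUE)
      if (!inherits(ct, "try-error")) {
        dss_rows[[paste0("t\r", sid, label)]] <- dss_record(
          sid, label, ct$dss, "combo_triple",
          range(g$conc2_nM), config$dss_t)
      }
    }
  }

  curve_tbl <- dplyr::bind_rows(curve_rows)
  dss_tbl <- dplyr::bind_rows(dss_rows)
  synergy_tbl <- dplyr::bind_rows(synergy_rows)
  landscape_tbl <- dplyr::bind_rows(landscapes)

  # ---- cohort --------------------------------------------------------
  cohort <- NULL; clusters <- NULL
  single_dss <- dss_tbl[dss_tbl$source == "single", , drop = FALSE]
  if (nrow(single_dss) > 0 &&
      length(unique(single_dss$sample_id)) >= 2 &&
      length(unique(single_dss$treatment_label)) >= 2) {
    cohort <- assemble_cohort(single_dss, annotations)
    clusters <- cluster_cohort(cohort, axis = "both", k = config$cluster_k)
  }

  list(qc = qc, wells = norm, curves = curve_tbl, curve_fits = curves,
       dss = dss_tbl, synergy = synergy_tbl,
       synergy_landscapes = landscape_tbl,
       cohort = cohort, clusters = clusters, config = config)
}

#' Write the pipeline's result tables
#'
#' One CSV per stage under `dir` (created if needed): `qc.csv`,
#' `normalized_wells.csv`, `curves.csv`, `dss.csv`, `dss_matrix.csv`,
#' `synergy.csv`, `synergy_landscapes.csv`, plus `sample_clusters.csv` and a
#' Newick dendrogram when clustering ran. Outputs are deterministic for
#' identical inputs.
#'
#' @param res a [run_pipeline()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_pipeline_results <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_results(res$qc, p("qc.csv"))
  keep <- c(plate_table_cols, "viability_pct", "inhibition_frac",
            "qc_outlier", "qc_excluded")
  write_results(res$wells[, intersect(keep, names(res$wells))],
                p("normalized_wells.csv"))
  write_results(res$curves, p("curves.csv"))
  write_results(res$dss, p("dss.csv"))
  if (nrow(res$dss) > 0) {
    wide <- dss_wide(res$dss[res$dss$source == "single", ])
    write_results(tibble::rownames_to_column(as.data.frame(wide), "sample_id"),
                  p("dss_matrix.csv"))
  }
  write_results(res$synergy, p("synergy.csv"))
  write_results(res$synergy_landscapes, p("synergy_landscapes.csv"))
  if (!is.null(res$clusters) && !is.null(res$clusters$samples)) {
    if (!is.null(res$clusters$samples$labels)) {
      write_results(tibble(sample_id = names(res$clusters$samples$labels),
                           cluster = unname(res$clusters$samples$labels)),
                    p("sample_clusters.csv"))
    }
    export_newick(res$clusters$samples$hclust, p("sample_dendrogram.nwk"))
  }
  invisible(dir)
}
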