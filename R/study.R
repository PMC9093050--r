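#' Study configuration
#'
#' Defaults mirror the pipeline's standard parameters: 2-s Welch windows,
#' four microstate classes with 30 ms smoothing, edge alpha 0.05 with a
#' 2000-permutation budget, and the default SVM/SVR grids.
#'
#' @param fs sampling rate for matrix-text inputs (Hz).
#' @param conn_bands connectivity band names to analyze.
#' @param microstate_k number of microstate classes.
#' @param min_dur_ms microstate smoothing floor (ms).
#' @param alpha significance level / NBS edge threshold.
#' @param n_perm permutation budget.
#' @param seed master seed; every stage seed is derived from it.
#' @param montage optional [eeg_montage()]; when supplied, connectivity is
#'   computed on surface-Laplacian signals and symmetry indices are reported.
#' @param preprocess logical: run [preprocess_recording()] on each input.
#' @export
study_config <- function(fs = 250, conn_bands = c("delta", "theta", "alpha"),
                         microstate_k = 4, min_dur_ms = 30,
                         alpha = 0.05, n_perm = 2000, seed = 1,
                         montage = NULL, preprocess = FALSE) {
  list(fs = fs, conn_bands = conn_bands, microstate_k = microstate_k,
       min_dur_ms = min_dur_ms, alpha = alpha, n_perm = n_perm, seed = seed,
       montage = montage, preprocess = preprocess)
}

#' Run the full paired-study pipeline
#'
#' Orchestrates preprocessing (optional), spectral and microstate features,
#' band-limited PLV connectivity with NBS inference (T1 vs T0, within
#' subjects), FCSCC summaries over the smallest-p component, sign-flip
#' permutation tests on every scalar feature, an SVM separating the two
#' conditions on the smallest-p features, and (when outcomes are given) an
#' SVR predicting them from the best-correlated FCSCC feature. Every subject
#' must appear in both conditions.
#'
#' @param recordings tibble with columns `subject`, `condition` ("T0"/"T1")
#'   and either a `recording` list-column of [eeg_recording()]s or a `path`
#'   column of matrix-text files.
#' @param outcomes optional tibble (`subject`, `outcome`) of follow-up scores.
#' @param config a [study_config()].
#' @param out_dir optional directory: feature CSVs and a JSON stats report are
#'   written there.
#' @return A `study_report` list: `features`, `stats`, `nbs`, `fcscc`,
#'   `svm`, `svr`, `manifest`.
#' @export
run_study <- function(recordings, outcomes = NULL, config = study_config(),
                      out_dir = NULL) {
  recs <- tibble::as_tibble(recordings)
  stopifnot(all(c("subject", "condition") %in% names(recs)))
  subjects <- unique(recs$subject)
  for (s in subjects) {
    have <- recs$condition[recs$subject == s]
    if (!all(c("T0", "T1") %in% have))
      stop("subject ", s, " lacks a ", setdiff(c("T0", "T1"), have)[1], " recording")
  }
  if (!"recording" %in% names(recs)) {
    if (!"path" %in% names(recs)) stop("need a `recording` or `path` column")
    recs$recording <- lapply(recs$path, read_recording, format = "auto",
                             fs = config$fs)
  }
  if (config$preprocess) {
    recs$recording <- lapply(recs$recording, preprocess_recording,
                             montage = config$montage)
  } else {
    recs$recording <- lapply(recs$recording, function(r) {
      if (r$reference == "original") rereference_average(r) else r
    })
  }
  n_rec <- nrow(recs)

  # ---- spectral features ----
  psds <- lapply(recs$recording, welch_psd)
  spectral <- purrr::map2_dfr(seq_len(n_rec), psds, function(i, p) {
    rp <- relative_power(p)
    dplyr::mutate(rp$global, subject = recs$subject[i],
                  condition = recs$condition[i],
                  feature = paste0("relpow_", .data$band)) |>
      dplyr::select("subject", "condition", "feature", value = "relative_power")
  })

  # ---- microstates ----
  per_templates <- lapply(seq_len(n_rec), function(i)
    recording_templates(recs$recording[[i]], K = config$microstate_k,
                        seed = config$seed + i))
  grp <- group_templates(per_templates, seed = config$seed,
                         montage = config$montage)
  micro <- purrr::map_dfr(seq_len(n_rec), function(i) {
    f <- microstate_analysis(recs$recording[[i]], grp,
                             min_dur_ms = config$min_dur_ms)
    f$per_class |>
      tidyr::pivot_longer(-"class", names_to = "what") |>
      dplyr::mutate(subject = recs$subject[i], condition = recs$condition[i],
                    feature = paste0("ms_", .data$what, "_", .data$class)) |>
      dplyr::select("subject", "condition", "feature", "value")
  })

  # ---- connectivity + NBS + FCSCC ----
  conn_input <- lapply(recs$recording, function(r) {
    if (!is.null(config$montage)) surface_laplacian(r, config$montage) else r
  })
  nbs_results <- list(); fcscc <- NULL
  for (bd in config$conn_bands) {
    conns <- lapply(conn_input, band_plv, band = bd)
    i1 <- which(recs$condition == "T1")[match(subjects, recs$subject[recs$condition == "T1"])]
    i0 <- which(recs$condition == "T0")[match(subjects, recs$subject[recs$condition == "T0"])]
    nbs_results[[bd]] <- nbs_test(conns[i1], conns[i0], design = "within",
                                  edge_alpha = config$alpha,
                                  n_perm = config$n_perm, seed = config$seed)
    comp <- nbs_results[[bd]]$components
    if (nrow(comp)) {
      edges <- as.matrix(comp$edges[[1]])
      vals <- purrr::map_dbl(conns, mean_fcscc, component = edges)
      fcscc <- dplyr::bind_rows(fcscc, tibble::tibble(
        subject = recs$subject, condition = recs$condition,
        feature = paste0("fcscc_", bd), value = vals))
    }
  }

  features <- dplyr::bind_rows(spectral, micro, fcscc)

  # ---- within-subject permutation tests on every scalar feature ----
  stats_tbl <- features |>
    tidyr::pivot_wider(names_from = "condition", values_from = "value") |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(result = list(
      if (any(is.na(.data$T1)) || any(is.na(.data$T0))) NULL
      else perm_test_scalar(.data$T1, .data$T0, design = "within",
                            seed = config$seed)), .groups = "drop") |>
    dplyr::mutate(
      statistic = purrr::map_dbl(.data$result, ~ if (is.null(.x)) NA_real_ else .x$statistic),
      p = purrr::map_dbl(.data$result, ~ if (is.null(.x)) NA_real_ else .x$p)) |>
    dplyr::select(-"result")

  # ---- SVM on smallest-p features ----
  svm_eval <- NULL
  pv <- stats::setNames(stats_tbl$p, stats_tbl$feature)
  pv <- pv[!is.na(pv)]
  if (length(pv)) {
    sel <- select_features(pv)
    wide <- features |>
      dplyr::filter(.data$feature %in% sel) |>
      tidyr::pivot_wider(names_from = "feature", values_from = "value")
    svm_eval <- tryCatch(
      nested_loocv_svm(wide, features = sel,
                       n_components = min(2, length(sel)),
                       seed = config$seed),
      error = function(e) NULL)
  }

  # ---- SVR on the outcome, FCSCC features at T0 ----
  svr_eval <- NULL
  if (!is.null(outcomes) && !is.null(fcscc)) {
    t0_feats <- fcscc |>
      dplyr::filter(.data$condition == "T0") |>
      tidyr::pivot_wider(names_from = "feature", values_from = "value") |>
      dplyr::select(-"condition") |>
      dplyr::left_join(tibble::as_tibble(outcomes), by = "subject")
    cand <- setdiff(names(t0_feats), c("subject", "outcome"))
    pc <- vapply(cand, function(f)
      perm_corr(t0_feats[[f]], t0_feats$outcome, seed = config$seed)$p,
      numeric(1))
    sel_r <- select_features(pc)
    svr_eval <- tryCatch(
      nested_loocv_svr(t0_feats, features = sel_r, n_components = 1,
                       seed = config$seed),
      error = function(e) NULL)
  }

  report <- structure(list(
    features = features, stats = stats_tbl, nbs = nbs_results,
    fcscc = fcscc, svm = svm_eval, svr = svr_eval,
    templates = grp,
    manifest = list(subjects = subjects, seed = config$seed,
                    conn_bands = config$conn_bands,
                    package_version = as.character(utils::packageVersion("zolpiscope")))),
    class = "study_report")

  if (!is.null(out_dir)) write_study_report(report, out_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d subjects, %d features\n",
              length(x$manifest$subjects), length(unique(x$features$feature))))
  top <- dplyr::arrange(x$stats, .data$p)
  print(utils::head(top, 5))
  invisible(x)
}

write_study_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(report$features, file.path(out_dir, "features.csv"))
  readr::write_csv(report$stats, file.path(out_dir, "feature_stats.csv"))
  nbs_json <- lapply(report$nbs, function(r) {
    comps <- r$components
    lapply(seq_len(nrow(comps)), function(i) list(
      sign = comps$sign[i], size = comps$size[i], p = comps$p[i],
      edges = comps$edges[[i]]))
  })
  metrics <- list(
    manifest = report$manifest,
    nbs = nbs_json,
    svm_auc = if (!is.null(report$svm)) report$svm$auc else NULL,
    svr = if (!is.null(report$svr))
      list(rmse = report$svr$rmse, cor = report$svr$cor) else NULL)
  jsonlite::write_json(metrics, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
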