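#' Run the full independence analysis on a cohort
#'
#' The core workflow applied to a cohort of labeled image sequences:
#' \enumerate{
#'   \item texture features for every (case, frame, ROI);
#'   \item intra-case JS divergence samples pooled over every time shift,
#'     and seeded inter-case samples within each group;
#'   \item divergence-versus-shift curves per case, pooled per group, with a
#'     period estimate per group;
#'   \item the per-group one-sided equivalence test (margin
#'     `delta_frac * M1`) deciding which groups' frames behave as
#'     independent samples;
#'   \item leave-one-out classification: two-class logistic regression for
#'     every label pair and against the pooled rest, plus one-vs-rest
#'     random-forest AUCs when 3+ groups are present.
#' }
#'
#' @param cohort a `phantom_cohort` or any list with parallel named lists
#'   `sequences` ([image_sequence()]) and `rois` ([roi_set()]).
#' @param pseudocount histogram smoothing (see [gray_histogram()]).
#' @param max_inter_pairs inter-case pairs drawn per group.
#' @param delta_frac,alpha equivalence-test margin fraction and level.
#' @param seed master seed for inter-pair sampling and the forest.
#' @param classify run the classification stage (slowest stage).
#' @param rl_levels run-length quantization for the features.
#' @return a `frameindep_analysis` list: `features`, `samples`
#'   (divergence samples with a `group` column), `shift_curves` (per group),
#'   `periods` (named vector), `equivalence` (per-group report) and
#'   `classification` (list of [roc_auc()] reports or `NULL`).
#' @export
analyze_cohort <- function(cohort, pseudocount = 1e-6, max_inter_pairs = 2000L,
                           delta_frac = 0.05, alpha = 0.05, seed = 1L,
                           classify = TRUE, rl_levels = 16L) {
  seqs <- cohort$sequences
  rois <- cohort$rois
  if (length(seqs) == 0L) stop("empty cohort: nothing to analyze")
  groups <- vapply(seqs, function(s) s$group, character(1))

  features <- do.call(rbind, lapply(names(seqs), function(id)
    extract_features(seqs[[id]], rois[[id]], rl_levels = rl_levels)))

  samples <- list(); curves_by_group <- list(); periods <- c()
  for (g in unique(groups)) {
    ids <- names(seqs)[groups == g]
    intra_by_case <- lapply(ids, function(id)
      intra_pairs_all_shifts(seqs[[id]], rois[[id]], pseudocount))
    intra <- do.call(rbind, intra_by_case)
    if (length(ids) >= 2L) {
      inter <- inter_pairs(seqs[ids], rois[ids],
                           seed = as.integer(seed) + match(g, unique(groups)),
                           max_pairs = max_inter_pairs,
                           pseudocount = pseudocount)
    } else inter <- NULL
    s <- rbind(intra, inter)
    s$group <- g
    samples[[g]] <- s
    case_curves <- lapply(intra_by_case, shift_curve_from_samples)
    curves_by_group[[g]] <- pool_shift_curves(case_curves)
    periods[g] <- if (nrow(curves_by_group[[g]]) >= 8L)
      estimate_period(curves_by_group[[g]]) else NA_integer_
  }
  samples <- do.call(rbind, samples)
  rownames(samples) <- NULL

  equivalence <- group_independence_report(samples, delta_frac = delta_frac,
                                           alpha = alpha)

  classification <- NULL
  if (classify && length(unique(groups)) >= 2L) {
    classification <- classify_features(features, seed = seed)
  }

  structure(list(features = features, samples = samples,
                 shift_curves = curves_by_group, periods = periods,
                 equivalence = equivalence, classification = classification),
            class = "frameindep_analysis")
}

feature_columns_for_ml <- c("echo_intensity", "internal_heterogeneity",
                            "heterogeneity", "glnu", "rlnu", "entropy")

#' Classification stage on a feature table
#'
#' Per-ROI rows are used as instances, as is common practice for sequential
#' imaging data — precisely the practice whose validity the divergence test
#' interrogates. Produces a disease-vs-normal logistic report when a
#' `"normal"` group exists, logistic reports for every label pair, and
#' one-vs-rest random-forest reports when 3+ classes are present.
#'
#' @param features feature table from [extract_features()] (with `group`).
#' @param seed forest seed.
#' @param n_trees forest size.
#' @return named list of [roc_auc()] reports.
#' @export
classify_features <- function(features, seed = 1L, n_trees = 100L) {
  X <- features[feature_columns_for_ml]
  g <- as.character(features$group)
  out <- list()
  lv <- sort(unique(g))
  if ("normal" %in% lv && length(lv) >= 2L) {
    y <- factor(ifelse(g == "normal", "normal", "disease"),
                levels = c("normal", "disease"))
    sc <- loo_cv_scores(X, y, "logistic")
    out[["disease_vs_normal"]] <- roc_auc(sc, y, positive = "disease")
  }
  for (pair in utils::combn(lv, 2, simplify = FALSE)) {
    sel <- g %in% pair
    y <- factor(g[sel], levels = pair)
    sc <- loo_cv_scores(X[sel, ], y, "logistic")
    out[[paste(pair[2], "vs", pair[1], sep = "_")]] <-
      roc_auc(sc, y, positive = pair[2])
  }
  if (length(lv) >= 3L) {
    ovr <- multicategory_eval(X, g, seed = seed, n_trees = n_trees)
    names(ovr) <- paste0(names(ovr), "_vs_rest")
    out <- c(out, ovr)
  }
  out
}

#' @export
print.frameindep_analysis <- function(x, ...) {
  cat("<frameindep_analysis>\n")
  cat(sprintf("  %d feature rows, %d divergence samples\n",
              nrow(x$features), nrow(x$samples)))
  cat("  independence decisions:\n")
  for (i in seq_len(nrow(x$equivalence))) {
    r <- x$equivalence[i, ]
    cat(sprintf("    %-12s intra %.4f +/- %.4f  inter %.4f +/- %.4f  p = %.3g  %s\n",
                r$group, r$mean_intra, r$sd_intra, r$mean_inter, r$sd_inter,
                r$p, if (r$independent) "INDEPENDENT" else "not independent"))
  }
  if (!is.null(x$classification)) {
    cat("  classification (LOO):\n")
    for (nm in names(x$classification))
      cat(sprintf("    %-24s AUC = %.3f\n", nm, x$classification[[nm]]$auc))
  }
  invisible(x)
}

#' Write every analysis artifact under an output directory
#'
#' Emits `features.csv`, `divergence_samples.csv`, `shift_curve_<group>.csv`,
#' `equivalence_report.csv`, `classification_report.csv` (+ per-task ROC
#' point lists) and a machine-readable `manifest.json` with seeds, stage row
#' counts and parameters.
#'
#' @param analysis a `frameindep_analysis`.
#' @param out_dir output directory (created).
#' @param params list of run parameters recorded in the manifest.
#' @return `out_dir`, invisibly.
#' @export
write_analysis <- function(analysis, out_dir, params = list()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_feature_table(analysis$features, file.path(out_dir, "features.csv"))
  write_divergence_csv(analysis$samples, file.path(out_dir, "divergence_samples.csv"))
  for (g in names(analysis$shift_curves))
    write_divergence_csv(analysis$shift_curves[[g]],
                         file.path(out_dir, paste0("shift_curve_", g, ".csv")))
  utils::write.csv(analysis$equivalence,
                   file.path(out_dir, "equivalence_report.csv"), row.names = FALSE)
  cls <- NULL
  if (!is.null(analysis$classification)) {
    cls <- do.call(rbind, lapply(names(analysis$classification), function(nm) {
      r <- analysis$classification[[nm]]
      utils::write.csv(r$roc, file.path(out_dir, paste0("roc_", nm, ".csv")),
                       row.names = FALSE)
      data.frame(task = nm, auc = r$auc, sensitivity = r$sensitivity,
                 specificity = r$specificity, n = r$n)
    }))
    utils::write.csv(cls, file.path(out_dir, "classification_report.csv"),
                     row.names = FALSE)
  }
  manifest <- list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    package_version = as.character(utils::packageVersion("frameindep")),
    params = params,
    stages = list(
      features = list(rows = nrow(analysis$features)),
      divergence = list(rows = nrow(analysis$samples),
                        intra = sum(analysis$samples$kind == "intra"),
                        inter = sum(analysis$samples$kind == "inter")),
      equivalence = list(rows = nrow(analysis$equivalence)),
      classification = if (is.null(cls)) NULL else list(rows = nrow(cls))
    ),
    periods = as.list(analysis$periods)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
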