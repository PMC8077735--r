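#' Experiment configuration
#'
#' Bundles the tunable parameters of the train/cross-validate/predict
#' workflow.
#'
#' @param residue Candidate residue type, one of K, P, R, T.
#' @param half_width Window half-width (default 10; 21-residue
#'   interior windows).
#' @param d_max_grid Encoding distances to scan (default 1:3).
#' @param K_grid Feature-subset counts to scan (default 300 to 400 in
#'   steps of 10).
#' @param L Subclassifiers per Rotation Forest (default 5).
#' @param folds Cross-validation folds (default 10).
#' @param threshold Decision threshold (default 0.5).
#' @param seed Integer seed for fold assignment, resampling and model
#'   fitting.
#' @param resample_mode `"per_fold"` (default) balances each training
#'   fold separately so held-out folds never contain synthetic rows;
#'   `"global"` balances the full dataset before splitting, which
#'   leaks synthetic neighbors of test points and triggers a warning.
#' @param k_neighbors,n_clusters SMOTE / KSU parameters.
#' @param bootstrap_fraction,svm_params,pca_tolerance Rotation Forest
#'   parameters (see [rotation_forest()]).
#' @return A list of class `"experiment_config"`.
#' @export
experiment_config <- function(residue = "K", half_width = 10,
                              d_max_grid = 1:3,
                              K_grid = seq(300, 400, by = 10), L = 5,
                              folds = 10, threshold = 0.5, seed = 1,
                              resample_mode = c("per_fold", "global"),
                              k_neighbors = 5, n_clusters = 6,
                              bootstrap_fraction = 0.75,
                              svm_params = list(), pca_tolerance = 1e-8) {
  residue <- match.arg(residue, CANDIDATE_RESIDUES)
  resample_mode <- match.arg(resample_mode)
  stopifnot(is_count(folds, min = 2), length(d_max_grid) >= 1L,
            length(K_grid) >= 1L, all(d_max_grid %in% 1:3),
            is_count(L, min = 1), threshold > 0, threshold < 1)
  structure(
    list(residue = residue, half_width = half_width,
         d_max_grid = as.integer(d_max_grid), K_grid = as.integer(K_grid),
         L = as.integer(L), folds = as.integer(folds),
         threshold = threshold, seed = as.integer(seed),
         resample_mode = resample_mode, k_neighbors = k_neighbors,
         n_clusters = n_clusters, bootstrap_fraction = bootstrap_fraction,
         svm_params = svm_params, pca_tolerance = pca_tolerance),
    class = "experiment_config"
  )
}

# Seeded stratified fold assignment: within each class, shuffled
# indices get fold ids 1..folds round-robin, so per-class fold sizes
# differ by at most one.
stratified_folds <- function(labels, folds, seed = NULL) {
  counts <- table(factor(labels, levels = c(0L, 1L)))
  if (any(counts < folds)) {
    stop("smallest class has ", min(counts), " members; use at most that ",
         "many folds")
  }
  with_seed_or_current(seed, {
    fold <- integer(length(labels))
    for (cl in c(0L, 1L)) {
      idx <- which(labels == cl)
      fold[sample(idx)] <- rep_len(seq_len(folds), length(idx))
    }
    fold
  })
}

#' Cross-validated grid selection over encoding distance and subset count
#'
#' For every `(d_max, K)` grid cell: encode the windows at `d_max`,
#' split into seeded stratified folds, balance the training side with
#' SMOTE-KSU (per fold by default), fit a Rotation Forest with `(K, L)`
#' and evaluate on the untouched held-out fold. Fold reports are
#' averaged per cell; the selected cell maximizes mean MCC, with ties
#' broken by higher AUC, then smaller K, then smaller d_max. Grid
#' cells whose K exceeds the encoding's feature count are skipped with
#' a message.
#'
#' @param windows Labeled window data.frame from [extract_windows()].
#' @param config An [experiment_config()].
#' @return An object of class `"cv_result"`: `grid` (one row per
#'   evaluated cell with mean metrics), `selected` (list with `d_max`,
#'   `K`), `fold_reports` (nested list of per-fold
#'   [metrics_report()]s), `folds` and `config`.
#' @export
cross_validate <- function(windows, config) {
  stopifnot(is.data.frame(windows), inherits(config, "experiment_config"))
  labels <- windows$label
  if (any(is.na(labels))) stop("cross-validation requires labeled windows")
  withr::with_seed(config$seed, {
    rows <- list()
    fold_reports <- list()
    fold_assign <- NULL
    for (d_max in config$d_max_grid) {
      fs <- encode_dataset(windows, d_max)
      if (config$resample_mode == "global") {
        warning("global resampling balances before the fold split; ",
                "held-out folds can contain synthetic neighbors of ",
                "training points", call. = FALSE)
        fs <- smote_ksu(fs, k_neighbors = config$k_neighbors,
                        n_clusters = config$n_clusters,
                        skip_if_balanced = TRUE)
      }
      folds <- stratified_folds(fs$labels, config$folds)
      if (is.null(fold_assign)) fold_assign <- folds
      for (K in config$K_grid) {
        if (K > ncol(fs$x)) {
          message("skipping grid cell d_max = ", d_max, ", K = ", K,
                  ": K exceeds feature dimension ", ncol(fs$x))
          next
        }
        reports <- lapply(seq_len(config$folds), function(f) {
          train <- folds != f
          fs_train <- feature_set(fs$x[train, , drop = FALSE],
                                  fs$labels[train], d_max = fs$d_max)
          if (config$resample_mode == "per_fold") {
            fs_train <- smote_ksu(fs_train,
                                  k_neighbors = config$k_neighbors,
                                  n_clusters = config$n_clusters,
                                  skip_if_balanced = TRUE)
          }
          model <- rotation_forest(
            fs_train$x, fs_train$labels, K = K, L = config$L,
            bootstrap_fraction = config$bootstrap_fraction,
            svm_params = config$svm_params,
            pca_tolerance = config$pca_tolerance)
          mu <- predict_scores(model, fs$x[!train, , drop = FALSE])
          metrics_report(fs$labels[!train], mu[, "mu_pos"],
                         threshold = config$threshold)
        })
        mean_rep <- average_reports(reports)
        cell <- sprintf("d%d_K%d", d_max, K)
        fold_reports[[cell]] <- reports
        rows[[cell]] <- cbind(data.frame(d_max = d_max, K = K),
                              as.data.frame(mean_rep))
      }
    }
    if (length(rows) == 0L) stop("every grid cell was skipped")
    grid <- do.call(rbind, rows)
    rownames(grid) <- NULL
    mcc_key <- ifelse(is.nan(grid$MCC), -Inf, grid$MCC)
    best <- order(-mcc_key, -grid$AUC, grid$K, grid$d_max)[1L]
    structure(
      list(grid = grid,
           selected = list(d_max = grid$d_max[best], K = grid$K[best]),
           fold_reports = fold_reports, folds = fold_assign,
           config = config),
      class = "cv_result"
    )
  })
}

#' @export
print.cv_result <- function(x, digits = 4, ...) {
  cat(sprintf("<cv_result> %d grid cell(s), %d-fold CV\n",
              nrow(x$grid), x$config$folds))
  g <- x$grid
  g[, -(1:2)] <- round(g[, -(1:2)], digits)
  print(g)
  cat(sprintf("selected: d_max = %d, K = %d\n",
              x$selected$d_max, x$selected$K))
  invisible(x)
}

#' Export a cross-validation grid as TSV
#'
#' One row per `(d_max, K)` cell with the mean Sn, Sp, Acc, MCC, AUC
#' and G-mean.
#'
#' @param cv A [cross_validate()] result.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_cv_grid <- function(cv, path) {
  stopifnot(inherits(cv, "cv_result"))
  utils::write.table(cv$grid, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Train the final model at a selected grid cell
#'
#' Balances the full training windows with SMOTE-KSU and fits one
#' Rotation Forest at the selected `(d_max, K)`, bundling the encoder
#' settings needed at prediction time.
#'
#' @param windows Labeled window data.frame.
#' @param config An [experiment_config()].
#' @param selected List with `d_max` and `K`; defaults to the single
#'   grid cell when both grids have length one.
#' @return An object of class `"carbonyl_model"`: the fitted
#'   `rotation_forest` plus `d_max`, `half_width`, `residue` and
#'   `threshold`.
#' @export
train_final <- function(windows, config, selected = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  if (is.null(selected)) {
    if (length(config$d_max_grid) == 1L && length(config$K_grid) == 1L) {
      selected <- list(d_max = config$d_max_grid, K = config$K_grid)
    } else {
      stop("supply `selected` (e.g. cross_validate(...)$selected) when ",
           "the grids have more than one cell")
    }
  }
  stopifnot(selected$d_max %in% config$d_max_grid,
            selected$K %in% config$K_grid)
  withr::with_seed(config$seed, {
    fs <- encode_dataset(windows, selected$d_max)
    balanced <- smote_ksu(fs, k_neighbors = config$k_neighbors,
                          n_clusters = config$n_clusters,
                          skip_if_balanced = TRUE)
    model <- rotation_forest(
      balanced$x, balanced$labels, K = selected$K, L = config$L,
      bootstrap_fraction = config$bootstrap_fraction,
      svm_params = config$svm_params,
      pca_tolerance = config$pca_tolerance)
    structure(
      list(model = model, d_max = selected$d_max,
           half_width = attr(windows, "half_width") %||% config$half_width,
           residue = config$residue, threshold = config$threshold,
           plan = attr(balanced, "plan")),
      class = "carbonyl_model"
    )
  })
}

#' @export
print.carbonyl_model <- function(x, ...) {
  cat(sprintf(
    "<carbonyl_model> residue %s, d_max = %d, half_width = %d, threshold = %.2f\n",
    x$residue, x$d_max, x$half_width, x$threshold))
  print(x$model)
  invisible(x)
}

#' Score every candidate residue in a set of proteins
#'
#' Scans each protein for the model's residue type, extracts windows,
#' encodes them at the model's `d_max` and scores them with the
#' Rotation Forest. Proteins without candidate residues contribute no
#' rows (with a message).
#'
#' @param bundle A [train_final()] model bundle (or one restored with
#'   [load_model()]).
#' @param proteins Named character vector of sequences, or the path to
#'   a FASTA file.
#' @param threshold Decision threshold; defaults to the bundle's.
#' @return Data.frame `protein_id`, `position`, `residue`, `score`,
#'   `call`, sorted by protein then position.
#' @export
predict_proteins <- function(bundle, proteins, threshold = NULL) {
  stopifnot(inherits(bundle, "carbonyl_model"))
  if (is.character(proteins) && length(proteins) == 1L &&
      is.null(names(proteins))) {
    proteins <- read_fasta(proteins)
  }
  threshold <- threshold %||% bundle$threshold
  candidates <- scan_candidate_sites(proteins, bundle$residue)
  empty <- setdiff(names(proteins), candidates$protein_id)
  for (id in empty) {
    message("protein '", id, "' has no ", bundle$residue,
            " residues; no predictions")
  }
  if (nrow(candidates) == 0L) {
    return(data.frame(protein_id = character(), position = integer(),
                      residue = character(), score = numeric(),
                      call = integer(), stringsAsFactors = FALSE))
  }
  windows <- extract_windows(proteins, candidates, bundle$half_width)
  fs <- encode_dataset(windows, bundle$d_max)
  mu <- predict_scores(bundle$model, fs$x)
  out <- data.frame(protein_id = windows$protein_id,
                    position = windows$position,
                    residue = windows$residue,
                    score = mu[, "mu_pos"],
                    call = as.integer(mu[, "mu_pos"] >= threshold),
                    stringsAsFactors = FALSE)
  out[order(out$protein_id, out$position), , drop = FALSE]
}
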