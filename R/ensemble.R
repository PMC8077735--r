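#' Randomly partition feature indices into K subsets
#'
#' A seeded random permutation of the feature indices is split into K
#' contiguous chunks; when K does not divide the feature count the
#' first `n %% K` subsets receive one extra index. Subsets are disjoint
#' and cover every index.
#'
#' @param n_features Total number of features.
#' @param K Number of subsets (`1 <= K <= n_features`).
#' @param seed Optional integer seed.
#' @return List of K integer vectors.
#' @export
partition_features <- function(n_features, K, seed = NULL) {
  stopifnot(is_count(n_features, min = 1), is_count(K, min = 1))
  if (K > n_features) stop("K (", K, ") exceeds n_features (", n_features, ")")
  with_seed_or_current(seed, {
    perm <- sample.int(n_features)
    sizes <- rep(n_features %/% K, K)
    extra <- n_features %% K
    if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    unname(split(perm, rep(seq_len(K), times = sizes)))
  })
}

#' PCA coefficient matrix for one feature subset
#'
#' Draws a bootstrap sample (`ceiling(bootstrap_fraction * n)` rows,
#' with replacement), runs PCA on the drawn rows restricted to the
#' subset columns, and returns the loading vectors whose eigenvalue
#' exceeds `pca_tolerance`. If every eigenvalue is at or below the
#' tolerance (a constant bootstrap draw), an identity matrix on the
#' subset is used instead, with a message.
#'
#' @param x Full training matrix.
#' @param subset_cols Column indices of this subset.
#' @param bootstrap_fraction Fraction of rows drawn (default 0.75).
#' @param pca_tolerance Eigenvalue cutoff for discarding null
#'   components.
#' @param seed Optional integer seed.
#' @return Loading matrix with `length(subset_cols)` rows and at most
#'   that many orthonormal columns.
#' @export
fit_rotation <- function(x, subset_cols, bootstrap_fraction = 0.75,
                         pca_tolerance = 1e-8, seed = NULL) {
  stopifnot(is.matrix(x), length(subset_cols) >= 1L,
            bootstrap_fraction > 0, bootstrap_fraction <= 1)
  n <- nrow(x)
  if (n < 2L) stop("need at least 2 rows for a bootstrap draw")
  with_seed_or_current(seed, {
    rows <- sample.int(n, ceiling(bootstrap_fraction * n), replace = TRUE)
    sub <- x[rows, subset_cols, drop = FALSE]
    pc <- stats::prcomp(sub, center = TRUE, scale. = FALSE)
    keep <- pc$sdev^2 > pca_tolerance
    if (!any(keep)) {
      message("constant feature subset in bootstrap draw; identity fallback")
      return(diag(length(subset_cols)))
    }
    pc$rotation[, keep, drop = FALSE]
  })
}

#' Assemble the reordered rotation matrix
#'
#' Places each subset's coefficient matrix as a block of a sparse
#' rotation matrix whose rows are indexed by the original feature
#' order (the block-diagonal layout over the permuted order, with rows
#' permuted back). Entry (f, c) is nonzero only if feature f belongs to
#' the subset owning component c.
#'
#' @param partition List of feature-index subsets
#'   (see [partition_features()]).
#' @param coefficient_matrices List of loading matrices, one per
#'   subset, with `nrow` equal to the subset size.
#' @param n_features Total feature count.
#' @return Matrix of dimension `n_features x total retained
#'   components`.
#' @export
build_rotation_matrix <- function(partition, coefficient_matrices, n_features) {
  stopifnot(length(partition) == length(coefficient_matrices))
  sizes <- unname(vapply(coefficient_matrices, nrow, integer(1)))
  if (!identical(sizes, lengths(partition, use.names = FALSE))) {
    stop("coefficient matrix rows must match subset sizes")
  }
  ncomp <- vapply(coefficient_matrices, ncol, integer(1))
  R <- matrix(0, nrow = n_features, ncol = sum(ncomp))
  offset <- 0L
  for (j in seq_along(partition)) {
    cols <- offset + seq_len(ncomp[j])
    R[partition[[j]], cols] <- coefficient_matrices[[j]]
    offset <- offset + ncomp[j]
  }
  R
}

#' Fit a Rotation Forest of SVM subclassifiers
#'
#' Each of the L subclassifiers gets a fresh random partition of the
#' features into K subsets, a per-subset bootstrap-PCA coefficient
#' matrix ([fit_rotation()]), the assembled rotation matrix
#' ([build_rotation_matrix()]), and an RBF SVM trained on the rotated
#' data `X %*% R` against the full label vector. Probability outputs
#' use deterministic Platt scaling of the decision values.
#'
#' @param x Numeric training matrix (at least 10 rows).
#' @param y Integer 0/1 labels; both classes must be present.
#' @param K Number of feature subsets per subclassifier.
#' @param L Number of subclassifiers (default 5).
#' @param bootstrap_fraction Row fraction for each PCA bootstrap
#'   (default 0.75).
#' @param svm_params List with elements `kernel` (default
#'   `"radial"`), `cost` (default 1) and `gamma` (default
#'   `1 / (n_features * mean feature variance)`).
#' @param pca_tolerance Eigenvalue cutoff (default 1e-8).
#' @param seed Optional integer seed; fitting twice with the same seed
#'   yields identical models.
#' @return An object of class `"rotation_forest"`.
#' @export
rotation_forest <- function(x, y, K, L = 5, bootstrap_fraction = 0.75,
                            svm_params = list(), pca_tolerance = 1e-8,
                            seed = NULL) {
  stopifnot(is.matrix(x), nrow(x) == length(y))
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("both classes must be present in y")
  if (nrow(x) < 10L) stop("need at least 10 training rows")
  stopifnot(is_count(L, min = 1))
  with_seed_or_current(seed, {
    members <- lapply(seq_len(L), function(i) {
      partition <- partition_features(ncol(x), K)
      coefs <- lapply(partition, function(cols) {
        fit_rotation(x, cols, bootstrap_fraction = bootstrap_fraction,
                     pca_tolerance = pca_tolerance)
      })
      R <- build_rotation_matrix(partition, coefs, ncol(x))
      clf <- fit_svm_prob(x %*% R, y, svm_params)
      list(partition = partition, rotation = R, classifier = clf)
    })
    structure(
      list(members = members, n_features = ncol(x),
           config = list(K = K, L = L,
                         bootstrap_fraction = bootstrap_fraction,
                         svm_params = svm_params,
                         pca_tolerance = pca_tolerance, seed = seed)),
      class = "rotation_forest"
    )
  })
}

#' @export
print.rotation_forest <- function(x, ...) {
  cat(sprintf("<rotation_forest> L = %d subclassifiers, K = %d subsets, %d features\n",
              x$config$L, x$config$K, x$n_features))
  invisible(x)
}

#' Ensemble credibility scores
#'
#' Each sample is rotated by each subclassifier's own rotation matrix
#' before scoring; the positive-class credibility is the mean
#' positive-class probability over the L subclassifiers (and the
#' negative-class credibility its complement).
#'
#' @param model A fitted [rotation_forest()].
#' @param x_new Matrix with the training feature dimension.
#' @return Matrix with columns `mu_pos`, `mu_neg`, one row per sample.
#' @export
predict_scores <- function(model, x_new) {
  stopifnot(inherits(model, "rotation_forest"), is.matrix(x_new))
  if (ncol(x_new) != model$n_features) {
    stop("feature dimension mismatch: model expects ", model$n_features,
         ", got ", ncol(x_new))
  }
  probs <- vapply(model$members, function(m) {
    predict_svm_prob(m$classifier, x_new %*% m$rotation)
  }, numeric(nrow(x_new)))
  mu_pos <- if (nrow(x_new) == 1L) mean(probs) else rowMeans(probs)
  cbind(mu_pos = mu_pos, mu_neg = 1 - mu_pos)
}

#' Threshold credibilities into binary calls
#'
#' A sample is called positive when its positive-class credibility is
#' greater than or equal to the threshold (the boundary goes to the
#' positive class).
#'
#' @param model A fitted [rotation_forest()].
#' @param x_new Matrix with the training feature dimension.
#' @param threshold Decision threshold in (0, 1), default 0.5.
#' @return Integer 0/1 vector.
#' @export
predict_labels <- function(model, x_new, threshold = 0.5) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L)
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  mu <- predict_scores(model, x_new)
  as.integer(mu[, "mu_pos"] >= threshold)
}

#' Predict method for rotation forests
#'
#' @param object A fitted [rotation_forest()].
#' @param newdata Feature matrix or [feature_set()].
#' @param type `"prob"` for credibility scores, `"class"` for binary
#'   calls.
#' @param threshold Decision threshold used for `type = "class"`.
#' @param ... Ignored.
#' @return See [predict_scores()] / [predict_labels()].
#' @export
predict.rotation_forest <- function(object, newdata,
                                    type = c("prob", "class"),
                                    threshold = 0.5, ...) {
  type <- match.arg(type)
  if (inherits(newdata, "feature_set")) newdata <- newdata$x
  if (type == "prob") predict_scores(object, newdata)
  else predict_labels(object, newdata, threshold)
}

#' Save a fitted model bundle
#'
#' Writes a versioned container; [load_model()] rejects files that are
#' not such a container or carry an unknown version.
#'
#' @param model A [rotation_forest()] or [train_final()] bundle.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, c("rotation_forest", "carbonyl_model")))
  saveRDS(list(container = "carbonylr_model", version = 1L, model = model),
          path)
  invisible(path)
}

#' Load a model bundle written by [save_model()]
#'
#' @param path Path to the saved container.
#' @return The stored model object.
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$container, "carbonylr_model")) {
    stop("not a carbonylr model container: ", path)
  }
  if (!identical(obj$version, 1L)) {
    stop("unsupported model container version: ", obj$version)
  }
  obj$model
}
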