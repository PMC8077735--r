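#' Compute the class-balancing plan
#'
#' The number of samples N moved during resampling is
#' `N = round(k1 * n0 - k0 * n1)` with rounding half away from zero.
#' Both classes are brought to the common size `M = n1 + N`: the
#' positive class gains `N` synthetic samples (SMOTE) and the negative
#' class loses `n0 - M` samples (KSU undersampling).
#'
#' @param n1 Positive (minority) class count.
#' @param n0 Negative (majority) class count; must exceed `n1`.
#' @param k0,k1 Weights on the two class counts (default 0.5 each).
#' @return An object of class `"resample_plan"` with fields `n1`, `n0`,
#'   `k0`, `k1`, `N`, `M`, `additions`, `removals`.
#' @examples
#' compute_plan(618, 26995)   # N = 13189, M = 13807
#' compute_plan(204, 22849)   # N = 11323 (half-integer rounds away from zero)
#' @export
compute_plan <- function(n1, n0, k0 = 0.5, k1 = 0.5) {
  stopifnot(is_count(n1, min = 1), is_count(n0, min = 1),
            is.numeric(k0), is.numeric(k1))
  if (n1 >= n0) stop("classes already balanced or inverted (n1 >= n0)")
  N <- as.integer(round_half_away(k1 * n0 - k0 * n1))
  M <- as.integer(n1 + N)
  structure(
    list(n1 = as.integer(n1), n0 = as.integer(n0), k0 = k0, k1 = k1,
         N = N, M = M, additions = N, removals = as.integer(n0 - M)),
    class = "resample_plan"
  )
}

#' @export
print.resample_plan <- function(x, ...) {
  cat(sprintf(
    "<resample_plan> n1 = %d, n0 = %d -> N = %d, target M = %d per class\n",
    x$n1, x$n0, x$N, x$M))
  cat(sprintf("  SMOTE additions: %d; KSU removals: %d\n",
              x$additions, x$removals))
  invisible(x)
}

#' SMOTE: synthetic minority oversampling
#'
#' Each synthetic sample is `X + u * (Y - X)` where `X` is a minority
#' row, `Y` one of its `k_neighbors` nearest minority neighbors
#' (Euclidean distance, excluding `X` itself) chosen uniformly, and
#' `u ~ Uniform(0, 1)`. Base rows are cycled round-robin over a
#' shuffled ordering of the minority set until the quota is met, so any
#' quota (including quotas exceeding the minority size) yields exactly
#' `additions` rows.
#'
#' @param minority_matrix Numeric matrix of minority-class rows.
#' @param additions Number of synthetic rows to create.
#' @param k_neighbors Neighborhood size (default 5).
#' @param seed Optional integer seed; `NULL` uses the current RNG
#'   stream.
#' @return Numeric matrix with `additions` rows.
#' @export
smote <- function(minority_matrix, additions, k_neighbors = 5, seed = NULL) {
  stopifnot(is.matrix(minority_matrix), is_count(additions),
            is_count(k_neighbors, min = 1))
  n <- nrow(minority_matrix)
  p <- ncol(minority_matrix)
  if (additions == 0L) {
    return(matrix(numeric(0), nrow = 0L, ncol = p,
                  dimnames = list(NULL, colnames(minority_matrix))))
  }
  if (n <= k_neighbors) {
    stop("minority class has ", n, " rows; need more than k_neighbors = ",
         k_neighbors)
  }
  d <- as.matrix(stats::dist(minority_matrix))
  diag(d) <- Inf
  # n x k matrix of nearest-neighbor row indices
  nn <- do.call(rbind, lapply(seq_len(n), function(i) {
    order(d[i, ])[seq_len(k_neighbors)]
  }))
  with_seed_or_current(seed, {
    bases <- rep(sample.int(n), length.out = additions)
    pick <- sample.int(k_neighbors, additions, replace = TRUE)
    neighbors <- nn[cbind(bases, pick)]
    u <- stats::runif(additions)
    xb <- minority_matrix[bases, , drop = FALSE]
    xn <- minority_matrix[neighbors, , drop = FALSE]
    xb + u * (xn - xb)
  })
}

#' KSU dissimilarity of samples within one cluster
#'
#' Columns are first normalized by their column maximum (columns whose
#' maximum is 0 become all-zero); the dissimilarity between rows p and
#' q is then the squared Euclidean distance of the normalized rows
#' scaled by `1/n`, n being the number of rows in the cluster. Only the
#' strict upper triangle is materialized.
#'
#' @param cluster_matrix Numeric matrix of the rows in one cluster.
#' @return A data.frame with columns `p`, `q` (row indices, `p < q`)
#'   and `d` (dissimilarity), ordered by pair index; zero rows if the
#'   cluster has fewer than two members.
#' @export
ksu_dissimilarity <- function(cluster_matrix) {
  stopifnot(is.matrix(cluster_matrix))
  n <- nrow(cluster_matrix)
  if (n < 2L) {
    return(data.frame(p = integer(), q = integer(), d = numeric()))
  }
  cmax <- apply(cluster_matrix, 2L, max)
  scale <- ifelse(cmax == 0, 0, 1 / cmax)
  pi_mat <- sweep(cluster_matrix, 2L, scale, `*`)
  d2 <- as.vector(stats::dist(pi_mat))^2 / n
  # stats::dist stores pairs (p, q) ordered p = 1..n-1, q = p+1..n
  p <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  q <- sequence((n - 1L):1L, from = 2:n)
  data.frame(p = p, q = q, d = d2)
}

# k-means++ center seeding: first center uniform, subsequent centers
# drawn with probability proportional to squared distance from the
# nearest chosen center.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1L] <- sample.int(n, 1L)
  closest <- rowSums(sweep(x, 2L, x[centers[1L], ], `-`)^2)
  for (j in seq_len(k - 1L)) {
    prob <- closest
    if (all(prob == 0)) prob <- rep(1, n)
    centers[j + 1L] <- sample.int(n, 1L, prob = prob)
    d_new <- rowSums(sweep(x, 2L, x[centers[j + 1L], ], `-`)^2)
    closest <- pmin(closest, d_new)
  }
  centers
}

# Seeded k-means with k-means++ initialization and multiple restarts.
ksu_kmeans <- function(x, k, restarts = 10, max_iter = 100) {
  best <- NULL
  for (r in seq_len(restarts)) {
    ctr <- x[kmeanspp_centers(x, k), , drop = FALSE]
    ctr <- ctr + 1e-9 * matrix(stats::runif(length(ctr)), nrow(ctr))
    fit <- suppressWarnings(
      stats::kmeans(x, centers = ctr, iter.max = max_iter)
    )
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  best
}

#' KSU: K-means similarity-based undersampling
#'
#' Majority rows are partitioned into `n_clusters` k-means clusters
#' (k-means++ initialization, multiple restarts). Within each cluster
#' all pairwise dissimilarities ([ksu_dissimilarity()]) are computed;
#' pairs from all clusters are merged and sorted by increasing
#' dissimilarity (ties broken by cluster then pair index for
#' determinism). Walking this list, whenever both members of a pair
#' still survive one member is eliminated uniformly at random, until
#' exactly `removals` rows are gone. If the pair list is exhausted
#' first, the remaining quota is removed uniformly at random from the
#' survivors with a warning.
#'
#' @param majority_matrix Numeric matrix of majority-class rows.
#' @param removals Number of rows to eliminate (must be less than the
#'   row count).
#' @param n_clusters Number of k-means clusters (default 6).
#' @param seed Optional integer seed.
#' @param kmeans_restarts,kmeans_max_iter K-means control parameters.
#' @return The surviving rows, in original order. Attributes:
#'   `keep_idx` (original indices kept) and `removed_per_cluster`
#'   (integer tally).
#' @export
ksu_undersample <- function(majority_matrix, removals, n_clusters = 6,
                            seed = NULL, kmeans_restarts = 10,
                            kmeans_max_iter = 100) {
  stopifnot(is.matrix(majority_matrix), is_count(removals),
            is_count(n_clusters, min = 1))
  n <- nrow(majority_matrix)
  if (removals >= n) stop("removals (", removals, ") must be < row count (", n, ")")
  if (n_clusters > n) stop("n_clusters exceeds the number of majority rows")
  if (removals == 0L) {
    out <- majority_matrix
    attr(out, "keep_idx") <- seq_len(n)
    attr(out, "removed_per_cluster") <- integer(n_clusters)
    return(out)
  }
  with_seed_or_current(seed, {
    km <- ksu_kmeans(majority_matrix, n_clusters,
                     restarts = kmeans_restarts, max_iter = kmeans_max_iter)
    assign <- km$cluster
    pair_tabs <- lapply(seq_len(n_clusters), function(cl) {
      members <- which(assign == cl)
      if (length(members) < 2L) {
        message("KSU: cluster ", cl, " has fewer than 2 members; no pairs")
        return(NULL)
      }
      tab <- ksu_dissimilarity(majority_matrix[members, , drop = FALSE])
      data.frame(p = members[tab$p], q = members[tab$q], d = tab$d,
                 cluster = cl, pair_idx = seq_len(nrow(tab)))
    })
    pairs <- do.call(rbind, pair_tabs)
    ord <- order(pairs$d, pairs$cluster, pairs$pair_idx)
    alive <- rep(TRUE, n)
    tally <- integer(n_clusters)
    eliminated <- 0L
    for (r in ord) {
      if (eliminated >= removals) break
      p <- pairs$p[r]; q <- pairs$q[r]
      if (alive[p] && alive[q]) {
        victim <- if (stats::runif(1) < 0.5) p else q
        alive[victim] <- FALSE
        tally[pairs$cluster[r]] <- tally[pairs$cluster[r]] + 1L
        eliminated <- eliminated + 1L
      }
    }
    if (eliminated < removals) {
      warning("KSU: pair list exhausted after ", eliminated,
              " eliminations; removing remaining ", removals - eliminated,
              " rows uniformly at random", call. = FALSE)
      extra <- sample(which(alive), removals - eliminated)
      alive[extra] <- FALSE
    }
    out <- majority_matrix[alive, , drop = FALSE]
    attr(out, "keep_idx") <- which(alive)
    attr(out, "removed_per_cluster") <- tally
    out
  })
}

#' Balance a labeled feature set with SMOTE + KSU
#'
#' Brings both classes to the common size `M` from [compute_plan()]:
#' the positive class is augmented with SMOTE synthetics and the
#' negative class reduced by KSU undersampling. Row provenance is
#' recorded so synthetic rows remain identifiable.
#'
#' @param fs A labeled [feature_set()].
#' @param plan Optional [compute_plan()] result; defaults to the plan
#'   computed from the feature set's own class counts (and must match
#'   them if supplied).
#' @param k_neighbors SMOTE neighborhood size (default 5).
#' @param n_clusters KSU cluster count (default 6).
#' @param seed Optional integer seed governing both resamplers.
#' @param ... Passed to [ksu_undersample()].
#' @param skip_if_balanced Return the input unchanged (with a message)
#'   when the positive class is not the minority, instead of erroring;
#'   used by the cross-validation driver so already-balanced folds run
#'   end to end.
#' @return A balanced [feature_set()]; `$meta$source` is one of
#'   `"original_pos"`, `"synthetic"`, `"original_neg"`. The plan and
#'   per-cluster removal tally are attached as attributes.
#' @export
smote_ksu <- function(fs, plan = NULL, k_neighbors = 5, n_clusters = 6,
                      seed = NULL, skip_if_balanced = FALSE, ...) {
  stopifnot(inherits(fs, "feature_set"))
  n1 <- sum(fs$labels == 1L)
  n0 <- sum(fs$labels == 0L)
  if (skip_if_balanced && n1 >= n0) {
    message("classes already balanced (", n1, " vs ", n0,
            "); resampling skipped")
    return(fs)
  }
  if (is.null(plan)) plan <- compute_plan(n1, n0)
  if (plan$n1 != n1 || plan$n0 != n0) {
    stop("plan was computed for counts (", plan$n1, ", ", plan$n0,
         ") but the feature set has (", n1, ", ", n0, ")")
  }
  pos <- fs$x[fs$labels == 1L, , drop = FALSE]
  neg <- fs$x[fs$labels == 0L, , drop = FALSE]
  with_seed_or_current(seed, {
    synth <- smote(pos, plan$additions, k_neighbors = k_neighbors)
    kept <- ksu_undersample(neg, plan$removals, n_clusters = n_clusters, ...)
    x <- rbind(pos, synth, kept)
    labels <- c(rep(1L, nrow(pos) + nrow(synth)), rep(0L, nrow(kept)))
    meta <- data.frame(source = c(rep("original_pos", nrow(pos)),
                                  rep("synthetic", nrow(synth)),
                                  rep("original_neg", nrow(kept))),
                       stringsAsFactors = FALSE)
    out <- feature_set(x, labels, d_max = fs$d_max, meta = meta)
    attr(out, "plan") <- plan
    attr(out, "removed_per_cluster") <- attr(kept, "removed_per_cluster")
    out
  })
}
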