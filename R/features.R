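#' Distance-based residue (DR) encoding of a peptide window
#'
#' A window of length L is encoded as a count vector of dimension
#' `20 + 400 * d_max`. Block 0 holds the occurrence count of each of
#' the 20 standard residues (order A, C, D, E, F, G, H, I, K, L, M, N,
#' P, Q, R, S, T, V, W, Y). Block d (1 <= d <= d_max) holds, for each
#' ordered residue pair (i, j) in row-major order, the number of
#' positions t with residue i at t and residue j at t + d, i.e. pairs
#' at exact distance d. The unknown symbol `"X"` occupies a position
#' but contributes to no count bin.
#'
#' For an X-free window the counts conserve length: block 0 sums to L
#' and block d sums to `max(L - d, 0)`.
#'
#' @param window_sequence Character scalar, the peptide window.
#' @param d_max Maximum pair distance; one of 1, 2, 3.
#' @return Named integer vector of length `20 + 400 * d_max`; pair
#'   features are named like `"AC@1"`.
#' @examples
#' v <- dr_encode("AAC", 1)
#' v[c("A", "C", "AA@1", "AC@1")]
#' @export
dr_encode <- function(window_sequence, d_max) {
  stopifnot(is.character(window_sequence), length(window_sequence) == 1L)
  if (!is_count(d_max, min = 1) || !d_max %in% 1:3) {
    stop("d_max must be 1, 2 or 3")
  }
  if (is.na(window_sequence) || nchar(window_sequence) == 0L) {
    stop("empty window sequence")
  }
  idx <- match(strsplit(window_sequence, "", fixed = TRUE)[[1]], AA20)
  len <- length(idx)
  blocks <- vector("list", d_max + 1L)
  blocks[[1L]] <- tabulate(idx[!is.na(idx)], nbins = 20L)
  for (d in seq_len(d_max)) {
    if (len > d) {
      i <- idx[seq_len(len - d)]
      j <- idx[seq_len(len - d) + d]
      ok <- !is.na(i) & !is.na(j)
      blocks[[d + 1L]] <- tabulate((i[ok] - 1L) * 20L + j[ok], nbins = 400L)
    } else {
      blocks[[d + 1L]] <- integer(400L)
    }
  }
  out <- unlist(blocks, use.names = FALSE)
  names(out) <- dr_feature_names(d_max)
  out
}

#' Feature names for a DR encoding
#'
#' @param d_max Maximum pair distance.
#' @return Character vector: the 20 residues, then `"AA@d"`-style pair
#'   names in row-major order for each distance block.
#' @export
dr_feature_names <- function(d_max) {
  pair <- paste0(rep(AA20, each = 20L), rep(AA20, times = 20L))
  c(AA20, unlist(lapply(seq_len(d_max), function(d) paste0(pair, "@", d))))
}

#' Construct a labeled feature set
#'
#' Lightweight container pairing a numeric feature matrix with labels
#' and encoding metadata; used throughout resampling, model fitting and
#' evaluation.
#'
#' @param x Numeric matrix, one row per sample.
#' @param labels Integer vector of 0/1 labels aligned with rows (may be
#'   `NA` for prediction-mode samples).
#' @param d_max The encoding distance the columns correspond to, or
#'   `NULL` for feature matrices that are not DR encodings.
#' @param meta Optional data.frame of per-row provenance.
#' @return An object of class `"feature_set"`.
#' @export
feature_set <- function(x, labels, d_max = NULL, meta = NULL) {
  stopifnot(is.matrix(x), nrow(x) == length(labels))
  if (!is.null(meta)) stopifnot(nrow(meta) == nrow(x))
  structure(
    list(x = x, labels = as.integer(labels), d_max = d_max, meta = meta),
    class = "feature_set"
  )
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %d samples x %d features", nrow(x$x), ncol(x$x)))
  if (!is.null(x$d_max)) cat(sprintf(" (DR, d_max = %d)", x$d_max))
  tab <- table(factor(x$labels, levels = c(0, 1)))
  cat(sprintf("\n  labels: %d positive / %d negative\n", tab[["1"]], tab[["0"]]))
  invisible(x)
}

#' Encode a set of site windows as a DR feature matrix
#'
#' @param windows Data.frame of windows from [extract_windows()].
#' @param d_max Maximum pair distance (1, 2 or 3).
#' @return A [feature_set()] whose rows follow the input order; labels
#'   and site provenance are carried through.
#' @export
encode_dataset <- function(windows, d_max) {
  stopifnot(is.data.frame(windows), "window" %in% names(windows))
  if (nrow(windows) == 0L) stop("no windows to encode")
  bad <- which(is.na(windows$window) | nchar(windows$window) == 0L)
  if (length(bad) > 0L) {
    stop("empty window(s) at row(s): ", paste(bad, collapse = ", "))
  }
  nm <- dr_feature_names(d_max)
  x <- t(vapply(windows$window, dr_encode, numeric(20L + 400L * d_max),
                d_max = d_max, USE.NAMES = FALSE))
  colnames(x) <- nm
  meta_cols <- intersect(c("protein_id", "position", "residue"), names(windows))
  feature_set(x, labels = windows$label %||% rep(NA_integer_, nrow(x)),
              d_max = d_max, meta = windows[, meta_cols, drop = FALSE])
}

#' Write a feature set to TSV
#'
#' One row per sample: the feature columns (bit-exact integers for DR
#' encodings) plus a final `label` column.
#'
#' @param fs A [feature_set()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_features <- function(fs, path) {
  stopifnot(inherits(fs, "feature_set"))
  df <- as.data.frame(fs$x, check.names = FALSE)
  df$label <- fs$labels
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature set from TSV
#'
#' @param path TSV written by [write_features()].
#' @param d_max Encoding distance to record, or `NULL` to infer from
#'   the column count when possible.
#' @return A [feature_set()].
#' @export
read_features <- function(path, d_max = NULL) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE)
  if (!"label" %in% names(df)) stop("feature table lacks a 'label' column")
  labels <- df$label
  x <- as.matrix(df[, setdiff(names(df), "label"), drop = FALSE])
  if (is.null(d_max) && (ncol(x) - 20L) %% 400L == 0L) {
    d <- (ncol(x) - 20L) %/% 400L
    if (d %in% 1:3) d_max <- d
  }
  feature_set(x, labels, d_max = d_max)
}
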