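# Positions (relative to the site) and letters enriched in positive
# windows, per candidate residue. K sites show upstream K enrichment at
# -6..-1, R sites upstream R at -5..-1, T sites upstream T at -3..-2;
# P sites carry no positional motif, so the P default enrichment
# strength is zero.
MOTIF_POSITIONS <- list(
  K = -6:-1,
  R = -5:-1,
  T = c(-3L, -2L),
  P = integer(0)
)

DEFAULT_THETA <- c(K = 0.8, R = 0.8, T = 0.5, P = 0)

#' Configuration for the synthetic sequence generator
#'
#' @param n_pos,n_neg Numbers of positive / negative sites to plant.
#' @param residue Candidate residue type, one of K, P, R, T.
#' @param theta Enrichment strength in `[0, 1]`: the probability that
#'   each motif position upstream of a positive site is overwritten
#'   with the enriched letter. `NULL` uses a per-residue default
#'   (0.8 for K and R, 0.5 for T, 0 for P, mirroring the relative
#'   strength of the observed sequence logos).
#' @param sites_per_protein Sites planted per synthetic protein
#'   (default 20); site centers are spaced 21 residues apart so
#'   neighbouring windows never overlap a foreign motif.
#' @param background Residue sampling frequencies over the 20 standard
#'   amino acids (default uniform). `uniprot_background()` gives a
#'   natural-abundance alternative.
#' @param seed Integer seed; generation is byte-reproducible.
#' @return A list of class `"synth_config"`.
#' @export
synth_config <- function(n_pos, n_neg, residue = "K", theta = NULL,
                         sites_per_protein = 20,
                         background = rep(1 / 20, 20), seed = 1) {
  residue <- match.arg(residue, CANDIDATE_RESIDUES)
  if (is.null(theta)) theta <- DEFAULT_THETA[[residue]]
  stopifnot(is_count(n_pos, min = 1), is_count(n_neg, min = 1),
            theta >= 0, theta <= 1, is_count(sites_per_protein, min = 1),
            length(background) == 20L,
            abs(sum(background) - 1) < 1e-8)
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 residue = residue, theta = theta,
                 sites_per_protein = as.integer(sites_per_protein),
                 background = background, seed = as.integer(seed)),
            class = "synth_config")
}

#' Approximate natural amino-acid background frequencies
#'
#' Frequencies in the order A, C, D, E, F, G, H, I, K, L, M, N, P, Q,
#' R, S, T, V, W, Y, normalized to sum to one.
#' @return Numeric vector of length 20.
#' @export
uniprot_background <- function() {
  f <- c(8.25, 1.38, 5.46, 6.72, 3.86, 7.07, 2.27, 5.91, 5.80, 9.65,
         2.41, 4.06, 4.74, 3.93, 5.53, 6.63, 5.35, 6.86, 1.10, 2.92)
  f / sum(f)
}

#' Generate synthetic proteins with planted carbonylation sites
#'
#' Proteins are drawn residue-wise from the background frequencies.
#' Candidate sites of the chosen residue are planted on a regular
#' 21-residue grid (center position 11, 32, 53, ...), labels are
#' assigned by a seeded shuffle, and for each positive site every
#' motif position upstream of the center is overwritten with the
#' enriched letter with probability `theta`. With `theta = 0` the
#' positive and negative windows are distributionally identical; with
#' `theta = 1` every positive window carries the full motif.
#'
#' @param config A [synth_config()].
#' @return List with `proteins` (named character vector) and `sites`
#'   (data.frame with `protein_id`, `position`, `residue`, `label`),
#'   both round-trippable through [write_fasta()] / [write_sites()]
#'   and [read_fasta()] / [read_sites()].
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  total <- config$n_pos + config$n_neg
  spp <- config$sites_per_protein
  n_proteins <- ceiling(total / spp)
  spacing <- 21L
  margin <- 10L
  motif <- MOTIF_POSITIONS[[config$residue]]
  withr::with_seed(config$seed, {
    labels <- sample(rep(c(1L, 0L), c(config$n_pos, config$n_neg)))
    ids <- sprintf("synth%04d", seq_len(n_proteins))
    proteins <- character(n_proteins)
    sites <- vector("list", n_proteins)
    planted <- 0L
    for (pr in seq_len(n_proteins)) {
      k <- min(spp, total - planted)
      len <- margin + spacing * k
      chars <- sample(AA20, len, replace = TRUE, prob = config$background)
      centers <- margin + 1L + spacing * (seq_len(k) - 1L)
      chars[centers] <- config$residue
      lab <- labels[planted + seq_len(k)]
      for (s in which(lab == 1L)) {
        if (length(motif) > 0L && config$theta > 0) {
          hit <- stats::runif(length(motif)) < config$theta
          chars[centers[s] + motif[hit]] <- config$residue
        }
      }
      proteins[pr] <- paste(chars, collapse = "")
      sites[[pr]] <- data.frame(protein_id = ids[pr], position = centers,
                                residue = config$residue, label = lab,
                                stringsAsFactors = FALSE)
      planted <- planted + k
    }
    names(proteins) <- ids
    list(proteins = proteins, sites = do.call(rbind, sites))
  })
}

#' Two-class Gaussian feature blobs
#'
#' A sequence-free fixture for exercising the resampler and the
#' ensemble: standard normal noise in every coordinate, with the
#' class-1 mean shifted by `separation` on 5 informative coordinates
#' (the first five). `separation = 0` gives a null dataset with
#' Bayes-optimal AUC 0.5; large separations are linearly separable.
#'
#' @param n_per_class Rows per class.
#' @param dim Feature dimension (at least 5).
#' @param separation Mean shift applied to the informative
#'   coordinates.
#' @param seed Optional integer seed.
#' @return A [feature_set()] with `2 * n_per_class` rows (class 1
#'   first) and `d_max = NULL`.
#' @export
generate_feature_blobs <- function(n_per_class, dim = 420, separation = 5,
                                   seed = NULL) {
  stopifnot(is_count(n_per_class, min = 1), is_count(dim, min = 5),
            is.numeric(separation), separation >= 0)
  with_seed_or_current(seed, {
    n <- 2L * n_per_class
    x <- matrix(stats::rnorm(n * dim), n, dim)
    x[seq_len(n_per_class), seq_len(5L)] <-
      x[seq_len(n_per_class), seq_len(5L)] + separation
    colnames(x) <- paste0("V", seq_len(dim))
    feature_set(x, labels = rep(c(1L, 0L), each = n_per_class))
  })
}
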