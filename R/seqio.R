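#' Read protein sequences from a FASTA file
#'
#' Sequences are uppercased and any character outside the 20 standard
#' amino-acid letters is replaced by the unknown symbol `"X"` (with a
#' warning naming the record). `"X"` positions are retained in windows
#' but contribute to no feature count bin.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of sequences; names are the FASTA
#'   identifiers (first whitespace-delimited token of each header).
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1", "MKTACDK"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  normalize_sequences(seqs)
}

# Replace non-standard residue letters (B, J, O, U, Z, *, ...) by 'X',
# warning once per affected record.
normalize_sequences <- function(seqs) {
  pattern <- paste0("[^", paste(AA20, collapse = ""), "]")
  n_bad <- vapply(seqs, function(s) {
    lengths(regmatches(s, gregexpr(pattern, s)))
  }, integer(1))
  for (i in which(n_bad > 0L)) {
    warning(sprintf("sequence '%s': %d non-standard residue(s) replaced by 'X'",
                    names(seqs)[i], n_bad[i]), call. = FALSE)
  }
  seqs[n_bad > 0L] <- gsub(pattern, "X", seqs[n_bad > 0L])
  seqs
}

#' Read and validate a site-annotation table
#'
#' The table is tab-separated with header columns `protein_id`,
#' `position` (1-based), `residue` (one of K, P, R, T) and `label`
#' (1 = carbonylated, 0 = non-carbonylated). Every row is validated
#' against its protein: the position must be in range and the sequence
#' character at that position must equal `residue`.
#'
#' @param path Path to the site TSV.
#' @param proteins Named character vector of sequences, as returned by
#'   [read_fasta()].
#' @return A data.frame with columns `protein_id`, `position`,
#'   `residue`, `label`.
#' @export
read_sites <- function(path, proteins) {
  if (!file.exists(path)) stop("site table not found: ", path)
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE)
  required <- c("protein_id", "position", "residue", "label")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0L) {
    stop("site table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(tab) == 0L) stop("site table is empty: ", path)
  sites <- data.frame(
    protein_id = tab$protein_id,
    position   = suppressWarnings(as.integer(tab$position)),
    residue    = toupper(tab$residue),
    label      = suppressWarnings(as.integer(tab$label)),
    stringsAsFactors = FALSE
  )
  validate_sites(sites, proteins)
}

validate_sites <- function(sites, proteins) {
  for (i in seq_len(nrow(sites))) {
    row <- sites[i, ]
    where <- sprintf("site table row %d (%s:%s)", i, row$protein_id, row$position)
    if (!row$protein_id %in% names(proteins)) {
      stop(where, ": unknown protein_id")
    }
    if (is.na(row$position)) stop(where, ": position is not an integer")
    seq <- proteins[[row$protein_id]]
    if (row$position < 1L || row$position > nchar(seq)) {
      stop(where, ": position out of range (sequence length ", nchar(seq), ")")
    }
    if (!row$residue %in% CANDIDATE_RESIDUES) {
      stop(where, ": residue must be one of K, P, R, T; got '", row$residue, "'")
    }
    found <- substr(seq, row$position, row$position)
    if (found != row$residue) {
      stop(where, ": residue mismatch: found ", found)
    }
    if (!is.na(row$label) && !row$label %in% c(0L, 1L)) {
      stop(where, ": label must be 0 or 1")
    }
  }
  sites
}

#' Extract peptide windows centered on annotated sites
#'
#' Each window spans `half_width` residues on either side of the
#' annotated position. Windows that would extend past a sequence
#' terminus are truncated, never padded: the distance-based residue
#' encoding is defined for any window length, so variable-length
#' windows are valid downstream inputs.
#'
#' @param proteins Named character vector of sequences.
#' @param sites Validated site data.frame (see [read_sites()]); the
#'   `label` column may be `NA` for prediction-mode candidates.
#' @param half_width Number of flanking residues on each side
#'   (default 10, giving 21-residue interior windows).
#' @return A data.frame with the site columns plus `window`; the
#'   half-width is recorded in attribute `"half_width"`.
#' @examples
#' p <- c(p1 = "ACDKACD")
#' s <- data.frame(protein_id = "p1", position = 4L, residue = "K", label = 1L)
#' extract_windows(p, s, half_width = 2)$window  # "CDKAC"
#' @export
extract_windows <- function(proteins, sites, half_width = 10) {
  stopifnot(is_count(half_width, min = 1))
  seqs <- proteins[sites$protein_id]
  start <- pmax(1L, sites$position - half_width)
  end <- pmin(nchar(seqs), sites$position + half_width)
  out <- sites
  out$window <- substr(seqs, start, end)
  attr(out, "half_width") <- as.integer(half_width)
  out
}

#' Enumerate candidate sites of a residue type
#'
#' Prediction mode treats every occurrence of the chosen residue as a
#' candidate site. Returns unlabeled annotations (label `NA`).
#'
#' @param proteins Named character vector of sequences.
#' @param residue One of `"K"`, `"P"`, `"R"`, `"T"`.
#' @return A data.frame with columns `protein_id`, `position`,
#'   `residue`, `label` (all `NA`), positions 1-based ascending within
#'   each protein.
#' @export
scan_candidate_sites <- function(proteins, residue) {
  residue <- match.arg(residue, CANDIDATE_RESIDUES)
  hits <- lapply(names(proteins), function(id) {
    pos <- gregexpr(residue, proteins[[id]], fixed = TRUE)[[1]]
    if (pos[1] == -1L) return(NULL)
    data.frame(protein_id = id, position = as.integer(pos),
               residue = residue, label = NA_integer_,
               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits)) {
    hits <- data.frame(protein_id = character(), position = integer(),
                       residue = character(), label = integer(),
                       stringsAsFactors = FALSE)
  }
  hits
}

#' Write a prediction table
#'
#' @param predictions Data.frame with columns `protein_id`, `position`,
#'   `residue`, `score`, `call` (see [predict_proteins()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  required <- c("protein_id", "position", "residue", "score", "call")
  stopifnot(all(required %in% names(predictions)))
  utils::write.table(predictions[, required], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write sequences to a FASTA file
#'
#' @param proteins Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  set <- Biostrings::AAStringSet(proteins)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write a site-annotation table
#'
#' @param sites Data.frame with columns `protein_id`, `position`,
#'   `residue`, `label`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_sites <- function(sites, path) {
  required <- c("protein_id", "position", "residue", "label")
  stopifnot(all(required %in% names(sites)))
  utils::write.table(sites[, required], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
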