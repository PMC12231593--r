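#' @import methods
NULL

DNA_BASES4 <- c("A", "C", "G", "T")

#' Validate promoter sequences
#'
#' Checks that every sequence is a non-empty string over the alphabet
#' \{A,C,G,T\}. Lowercase input is accepted and uppercased; ambiguity codes
#' (including N) are rejected because the design space is
#' substitution-mutagenised ACGT only.
#'
#' @param seqs Character vector of sequences (names, if any, are kept as ids).
#' @param sameLength If `TRUE`, additionally require all sequences to share
#'   one length.
#' @return The validated (uppercased) character vector, invisibly usable.
#' @examples
#' checkDNA(c(p1 = "acgt"))
#' @export
checkDNA <- function(seqs, sameLength = FALSE) {
  if (!is.character(seqs) || length(seqs) == 0L)
    stop("'seqs' must be a non-empty character vector")
  seqs <- toupper(seqs)
  bad <- regexpr("[^ACGT]", seqs)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("invalid base '%s' at position %d of sequence %d",
                 substr(seqs[i], bad[i], bad[i]), bad[i], i))
  }
  if (any(nchar(seqs) == 0L)) stop("empty sequence not allowed")
  if (sameLength && length(unique(nchar(seqs))) != 1L)
    stop("sequences must all have the same length")
  seqs
}

#' One-hot encode a DNA sequence
#'
#' Returns the L x 4 indicator matrix of a sequence, with the fixed column
#' order A, C, G, T. Hard encodings have exactly one 1 per row; relaxed
#' real-valued matrices of the same shape are used as the optimisation
#' variable in gradient-based design.
#'
#' @param seq A single sequence (character scalar).
#' @return Numeric matrix of dimension `nchar(seq)` x 4 with
#'   `colnames` A,C,G,T.
#' @seealso [decodeArgmax()]
#' @examples
#' encodeOneHot("ACGT")
#' @export
encodeOneHot <- function(seq) {
  seq <- checkDNA(seq)
  if (length(seq) != 1L) stop("'seq' must be a single sequence")
  idx <- match(strsplit(seq, "", fixed = TRUE)[[1L]], DNA_BASES4)
  L <- length(idx)
  m <- matrix(0, L, 4L, dimnames = list(NULL, DNA_BASES4))
  m[cbind(seq_len(L), idx)] <- 1
  m
}

# batch version: returns array [n, L, 4] for equal-length sequences
encodeOneHotBatch <- function(seqs) {
  seqs <- checkDNA(seqs, sameLength = TRUE)
  n <- length(seqs)
  L <- nchar(seqs[1L])
  idx <- match(strsplit(paste(seqs, collapse = ""), "", fixed = TRUE)[[1L]],
               DNA_BASES4)
  x <- array(0, dim = c(n, L, 4L))
  # idx runs position-fastest within sequence
  pos <- rep(seq_len(L), times = n)
  sq <- rep(seq_len(n), each = L)
  x[cbind(sq, pos, idx)] <- 1
  x
}

#' Decode a (relaxed) one-hot matrix to a sequence by per-position argmax
#'
#' Each row is mapped to the base with the maximal value; ties are broken
#' deterministically towards the lowest column index (A < C < G < T).
#'
#' @param enc Numeric matrix with 4 columns (column order A,C,G,T).
#' @return A character scalar sequence.
#' @examples
#' decodeArgmax(diag(4))  # "ACGT"
#' @export
decodeArgmax <- function(enc) {
  if (!is.matrix(enc) || ncol(enc) != 4L || nrow(enc) == 0L)
    stop("'enc' must be a non-empty matrix with 4 columns")
  paste(DNA_BASES4[max.col(enc, ties.method = "first")], collapse = "")
}

#' Hamming distance between two equal-length sequences
#'
#' Number of mismatching positions. For equal-length substitution-only
#' mutants this coincides with edit distance (the bounded-mutation pools
#' used in semi-rational design contain only substitutions).
#'
#' @param a,b Character scalars of equal length.
#' @return Non-negative integer.
#' @export
hammingDist <- function(a, b) {
  a <- checkDNA(a); b <- checkDNA(b)
  if (nchar(a) != nchar(b)) stop("sequences must have equal length")
  sum(utf8ToInt(a) != utf8ToInt(b))
}

# rows of an integer code matrix, one row per sequence
.seqCodeMatrix <- function(seqs) {
  n <- length(seqs)
  L <- nchar(seqs[1L])
  matrix(utf8ToInt(paste(seqs, collapse = "")), nrow = n, ncol = L,
         byrow = TRUE)
}

#' Minimum pairwise Hamming distance of a sequence set
#'
#' @param seqs Character vector of at least two equal-length sequences.
#' @return The minimum Hamming distance over all unordered pairs.
#' @export
minPairwiseHamming <- function(seqs) {
  seqs <- checkDNA(seqs, sameLength = TRUE)
  if (length(seqs) < 2L) stop("need at least 2 sequences")
  m <- .seqCodeMatrix(seqs)
  best <- nchar(seqs[1L])
  for (i in seq_len(nrow(m) - 1L)) {
    d <- rowSums(m[(i + 1L):nrow(m), , drop = FALSE] !=
                   matrix(m[i, ], nrow(m) - i, ncol(m), byrow = TRUE))
    best <- min(best, d)
    if (best == 0L) return(0L)
  }
  as.integer(best)
}

# all pairwise hamming distances from one sequence to a set
hammingToAll <- function(seq, seqs) {
  m <- .seqCodeMatrix(c(seq, seqs))
  rowSums(m[-1L, , drop = FALSE] !=
            matrix(m[1L, ], length(seqs), ncol(m), byrow = TRUE))
}

#' Read promoter sequences from a FASTA file
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] that uppercases and
#' validates the alphabet.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
readFastaSeqs <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  checkDNA(seqs)
}

#' Write promoter sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
writeFastaSeqs <- function(seqs, path) {
  seqs <- checkDNA(seqs)
  if (is.null(names(seqs)))
    names(seqs) <- sprintf("seq%d", seq_along(seqs))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

ACTIVITY_FIXED_COLS <- c("id", "sequence", "induced", "uninduced", "purified")

#' Read an activity table
#'
#' Activity tables are tab-separated with a header row and columns
#' `id`, `sequence`, `induced`, `uninduced`, `purified` plus optional
#' replicate columns `rep<i>_induced` / `rep<i>_uninduced`. `purified` may be
#' `NA` before purification. All activities are in arbitrary fluorescence
#' units and must be non-negative.
#'
#' @param path Path to a TSV file.
#' @return A `data.frame`, one row per promoter.
#' @export
readActivityTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(c("id", "sequence", "induced", "uninduced"), names(df))
  if (length(missing))
    stop("activity table lacks column(s): ", paste(missing, collapse = ", "))
  if (!"purified" %in% names(df)) df$purified <- NA_real_
  df$sequence <- checkDNA(df$sequence)
  num <- setdiff(names(df), c("id", "sequence"))
  for (cn in num) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- which(is.na(v) & !is.na(df[[cn]]) & df[[cn]] != "NA")
    if (length(bad))
      stop(sprintf("non-numeric value in column '%s' at line %d",
                   cn, bad[1L] + 1L))
    df[[cn]] <- v
  }
  if (any(unlist(df[num]) < 0, na.rm = TRUE))
    stop("activities must be non-negative")
  df
}

#' Write an activity table
#'
#' @param records A `data.frame` as returned by [readActivityTable()] or
#'   [buildTrainingDataset()].
#' @param path Output path; tab-separated with header.
#' @export
writeActivityTable <- function(records, path) {
  stopifnot(is.data.frame(records),
            all(c("id", "sequence") %in% names(records)))
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Average replicate measurements into the induced/uninduced columns
#'
#' @param records Activity `data.frame` with `rep<i>_induced` /
#'   `rep<i>_uninduced` columns.
#' @return The same `data.frame` with `induced` and `uninduced` set to the
#'   replicate means.
#' @export
averageReplicates <- function(records) {
  ri <- grep("^rep[0-9]+_induced$", names(records), value = TRUE)
  ru <- grep("^rep[0-9]+_uninduced$", names(records), value = TRUE)
  if (length(ri)) records$induced <- rowMeans(records[ri])
  if (length(ru)) records$uninduced <- rowMeans(records[ru])
  records
}
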