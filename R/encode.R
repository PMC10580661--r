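#' Sliding-window k-merisation of a strand
#'
#' Traverses the sequence with a window of size `k1` in steps of `stride`
#' (the 2Lk configuration uses stride 1), returning
#' `floor((L - k1) / stride) + 1` words left to right.
#'
#' @param strand a single sequence (character scalar, or an element of a
#'   [Biostrings::DNAStringSet]).
#' @param k1 window size in nucleotides.
#' @param stride window step (default 1).
#' @param id optional strand id used in error messages.
#' @return character vector of k1-mers.
#' @examples
#' kmerize("ATGCGA", 3)  # "ATG" "TGC" "GCG" "CGA"
#' @export
kmerize <- function(strand, k1, stride = 1L, id = NULL) {
  seq <- as.character(strand)
  L <- nchar(seq)
  if (L < k1)
    stop(sprintf("strand %s of length %d is shorter than k1 = %d",
                 if (is.null(id)) "<unnamed>" else id, L, k1))
  starts <- seq.int(1L, L - k1 + 1L, by = stride)
  substring(seq, starts, starts + k1 - 1L)
}

#' Precompute the k-mer encoding lookup table
#'
#' FCGR vectors for all `5^k1` words over \{A,C,G,T,N\} — 125 entries for
#' k1 = 3 — computed once, independent of the number of training samples.
#' Encoding a dataset is then pure table lookup.
#'
#' @param k1 outer window size.
#' @param k2 FCGR resolution, `1 <= k2 <= k1`.
#' @return a [LookupTable-class].
#' @export
buildLookup <- function(k1, k2) {
  k1 <- as.integer(k1); k2 <- as.integer(k2)
  if (k2 > k1) stop("k2 must not exceed k1")
  if (k2 < 1L || k1 < 1L) stop("k1 and k2 must be positive")
  alpha <- c(BASES, "N")
  grid <- do.call(expand.grid,
                  c(rep(list(alpha), k1), stringsAsFactors = FALSE))
  # vary last character fastest so words come out in lexicographic order
  words <- do.call(paste0, rev(grid))
  words <- sort(words)
  entries <- t(vapply(words, function(w) .fcgrVec(w, k2),
                      numeric(4^k2)))
  rownames(entries) <- words
  new("LookupTable", k1 = k1, k2 = k2, entries = entries)
}

#' Encode one strand with the two-level k-mer (2Lk) scheme
#'
#' Row `i` of the result is the flat FCGR vector (resolution `k2`) of the
#' `i`-th sliding k1-mer, giving an `(L - k1 + 1) x 4^k2` matrix. Every
#' N-free row sums to `k1 - k2 + 1`.
#'
#' @param strand a single sequence.
#' @param k1 outer sliding-window size.
#' @param k2 FCGR resolution.
#' @param lookup optional [LookupTable-class] from [buildLookup()]; computed
#'   on the fly when absent.
#' @param id optional strand id for error messages.
#' @return numeric matrix `(L - k1 + 1) x 4^k2`.
#' @examples
#' dim(encode2Lk(strrep("A", 375), 3, 2))  # 373 x 16
#' @export
encode2Lk <- function(strand, k1, k2, lookup = NULL, id = NULL) {
  if (is.null(lookup)) lookup <- buildLookup(k1, k2)
  stopifnot(lookup@k1 == k1, lookup@k2 == k2)
  words <- kmerize(strand, k1, 1L, id = id)
  m <- lookup@entries[words, , drop = FALSE]
  dimnames(m) <- NULL
  m
}

#' One-hot encode a strand
#'
#' `L x 4` matrix with columns in A,C,G,T order; N positions give an
#' all-zero row (DeepBind-style convention).
#'
#' @param strand a single sequence.
#' @return numeric `L x 4` matrix of 0/1.
#' @export
encodeOneHot <- function(strand) {
  seq <- normalizeStrand(as.character(strand))
  d <- .digits(seq)
  m <- matrix(0, length(d), 4L)
  ok <- !is.na(d)
  m[cbind(which(ok), d[ok] + 1L)] <- 1
  m
}

#' Encode a dataset into a padded 3-axis tensor
#'
#' Each strand is encoded ([encode2Lk()] or [encodeOneHot()]); shorter
#' strands are right-padded with all-zero rows to the batch maximum and a
#' logical validity mask records the real rows. Labels travel with the
#' batch when the input is a [LabeledStrands-class].
#'
#' @param x a [LabeledStrands-class], [Biostrings::DNAStringSet], or named
#'   character vector of sequences.
#' @param scheme `"2lk"` (default) or `"onehot"`.
#' @param k1,k2 2Lk parameters (ignored for one-hot).
#' @return an [EncodedBatch-class].
#' @export
encodeBatch <- function(x, scheme = c("2lk", "onehot"), k1 = 3L, k2 = 2L) {
  scheme <- match.arg(scheme)
  labels <- matrix(numeric(0), 0L, 0L)
  if (is(x, "LabeledStrands")) {
    labels <- x@labels
    x <- x@strands
  }
  if (is.character(x)) x <- Biostrings::DNAStringSet(normalizeStrand(x))
  n <- length(x)
  if (!n) stop("cannot encode an empty dataset")
  ids <- if (is.null(names(x))) paste0("s", seq_len(n)) else names(x)
  seqs <- as.character(x)
  if (scheme == "2lk") {
    lookup <- buildLookup(k1, k2)
    mats <- lapply(seq_len(n), function(i)
      encode2Lk(seqs[i], k1, k2, lookup = lookup, id = ids[i]))
    cols <- 4L^as.integer(k2)
  } else {
    mats <- lapply(seqs, encodeOneHot)
    cols <- 4L
    k1 <- 1L; k2 <- 1L
  }
  rows <- vapply(mats, nrow, integer(1))
  maxR <- max(rows)
  tensor <- array(0, c(n, maxR, cols))
  mask <- matrix(FALSE, n, maxR)
  for (i in seq_len(n)) {
    tensor[i, seq_len(rows[i]), ] <- mats[[i]]
    mask[i, seq_len(rows[i])] <- TRUE
  }
  if (nrow(labels)) labels <- labels[ids, , drop = FALSE]
  new("EncodedBatch", tensor = tensor, mask = mask, ids = ids,
      scheme = scheme, k1 = as.integer(k1), k2 = as.integer(k2),
      labels = labels)
}

#' Memory-footprint report for an encoding scheme
#'
#' Shape arithmetic behind the encoded-dataset size comparison: a 375-nt
#' strand occupies 373 x 16 values under 2Lk(3,2), 375 x 4 under one-hot,
#' and 373 x 64 under 2Lk(3,3).
#'
#' @param L strand length in nucleotides.
#' @param nStrands number of strands.
#' @param scheme `"2lk"` or `"onehot"`.
#' @param k1,k2 2Lk parameters (ignored for one-hot).
#' @return list with `rows`, `cols`, `totalValues`.
#' @export
footprintReport <- function(L, nStrands, scheme = c("2lk", "onehot"),
                            k1 = 3L, k2 = 2L) {
  scheme <- match.arg(scheme)
  stopifnot(L >= 1, nStrands >= 0)
  if (scheme == "2lk") {
    if (L < k1) stop("L must be >= k1")
    rows <- L - k1 + 1L
    cols <- 4L^as.integer(k2)
  } else {
    rows <- as.integer(L)
    cols <- 4L
  }
  list(rows = as.integer(rows), cols = cols,
       totalValues = as.numeric(nStrands) * rows * cols)
}
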