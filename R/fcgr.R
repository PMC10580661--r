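BASES <- c("A", "C", "G", "T")

# base -> digit (A=0, C=1, G=2, T=3); NA for N
.digits <- function(word) {
  m <- match(strsplit(word, "", fixed = TRUE)[[1L]], BASES)
  m - 1L
}

#' Cell index of a k-mer in the FCGR grid
#'
#' Bijection between the `4^k2` possible N-free words of length `k2` and
#' flat cell indices `0 .. 4^k2 - 1`, using the lexicographic digit
#' encoding A=0, C=1, G=2, T=3:
#' `index = sum_i digit(word[i]) * 4^(k2 - 1 - i)`. Any fixed bijection
#' carries the same information; this one makes indices auditable.
#'
#' @param word string over \{A,C,G,T\} of length `k2`.
#' @param k2 expected word length (defaults to `nchar(word)`).
#' @return integer in `[0, 4^k2)`.
#' @examples
#' kmerCellIndex("AA")  # 0
#' kmerCellIndex("TT")  # 15
#' @export
kmerCellIndex <- function(word, k2 = nchar(word)) {
  if (nchar(word) != k2)
    stop(sprintf("word '%s' does not have length k2 = %d", word, k2))
  d <- .digits(word)
  if (anyNA(d)) stop("word must contain only A/C/G/T: ", word)
  as.integer(sum(d * 4^((k2 - 1):0)))
}

# flat FCGR vector; N windows distribute 1/4^m over compatible cells
.fcgrVec <- function(word, k2) {
  W <- nchar(word)
  d <- .digits(word)
  pow <- 4^((k2 - 1):0)
  v <- numeric(4^k2)
  for (i in seq_len(W - k2 + 1L)) {
    win <- d[i:(i + k2 - 1L)]
    nas <- which(is.na(win))
    if (!length(nas)) {
      idx <- sum(win * pow) + 1
      v[idx] <- v[idx] + 1
    } else {
      base <- sum(win[-nas] * pow[-nas])
      offs <- 0
      for (j in nas) offs <- as.vector(outer(offs, (0:3) * pow[j], `+`))
      v[base + offs + 1] <- v[base + offs + 1] + 1 / 4^length(nas)
    }
  }
  v
}

#' Flat FCGR k-mer count vector of a word
#'
#' Slides a window of size `k2` (step 1) over `word`; each N-free window
#' adds 1 to its cell ([kmerCellIndex()] order). A window containing
#' `m >= 1` N characters adds `1/4^m` to every cell compatible with
#' substituting the Ns, so the vector always sums to `W - k2 + 1`
#' (count conservation).
#'
#' @param word string over \{A,C,G,T,N\} with `nchar(word) >= k2`.
#' @param k2 FCGR resolution.
#' @return numeric vector of length `4^k2`.
#' @examples
#' fcgrVector("ATG", 2)  # 1 at cells 3 (AT) and 14 (TG)
#' @export
fcgrVector <- function(word, k2) {
  stopifnot(k2 >= 1L)
  if (nchar(word) < k2)
    stop(sprintf("word of length %d is shorter than k2 = %d", nchar(word), k2))
  if (grepl("[^ACGTN]", word)) word <- normalizeStrand(word)
  .fcgrVec(word, as.integer(k2))
}

#' FCGR grid of a word
#'
#' Row-major reshape of [fcgrVector()] into the `2^k2 x 2^k2` grid:
#' cell index `i` sits at row `i %/% 2^k2 + 1`, column `i %% 2^k2 + 1`.
#'
#' @inheritParams fcgrVector
#' @return a [FcgrGrid-class].
#' @export
fcgrGrid <- function(word, k2) {
  v <- fcgrVector(word, k2)
  side <- 2L^as.integer(k2)
  new("FcgrGrid", k2 = as.integer(k2),
      counts = matrix(v, side, side, byrow = TRUE))
}
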