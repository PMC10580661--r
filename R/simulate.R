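#' Default synthetic test motif
#'
#' A high-information 8-wide PWM (consensus TGACGTCA, 0.85 on the
#' consensus base, the rest uniform) — strong enough that a small model
#' recovers it, yet stochastic enough that implanted instances vary.
#'
#' @param width motif width; the consensus cycles through TGACGTCA.
#' @param maxProb probability of the consensus base per column.
#' @return numeric 4 x width column-stochastic matrix (rows A,C,G,T).
#' @export
defaultMotifPwm <- function(width = 8L, maxProb = 0.85) {
  stopifnot(width >= 1L, maxProb > 0.25, maxProb < 1)
  consensus <- rep(strsplit("TGACGTCA", "")[[1L]], length.out = width)
  pwm <- matrix((1 - maxProb) / 3, 4L, width, dimnames = list(BASES, NULL))
  pwm[cbind(match(consensus, BASES), seq_len(width))] <- maxProb
  pwm
}

#' Sample an i.i.d. background sequence
#'
#' Order-0 background with `P(G) = P(C) = gc/2` and
#' `P(A) = P(T) = (1 - gc)/2`.
#'
#' @param length sequence length in nucleotides.
#' @param gc GC content in (0, 1).
#' @return a single character string.
#' @export
sampleBackground <- function(length, gc = 0.5) {
  stopifnot(gc > 0, gc < 1, length >= 1)
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(BASES, length, replace = TRUE, prob = probs), collapse = "")
}

#' Implant a PWM-sampled motif instance into a sequence
#'
#' Samples one base per motif column from the PWM and overwrites the
#' chosen window. `positionPolicy = "uniform"` places the instance
#' anywhere it fits; `"center"` jitters it by up to half a motif width
#' around the centred placement (for a 101-nt strand and an 8-wide motif,
#' 1-based starts 44..51).
#'
#' @param sequence a single character string.
#' @param motifPwm 4 x W column-stochastic matrix (rows A,C,G,T).
#' @param positionPolicy `"uniform"` or `"center"`.
#' @return list with `sequence` (motif-bearing) and `start` (1-based).
#' @export
implantMotif <- function(sequence, motifPwm,
                         positionPolicy = c("uniform", "center")) {
  positionPolicy <- match.arg(positionPolicy)
  L <- nchar(sequence)
  W <- ncol(motifPwm)
  if (W > L) stop(sprintf("motif width %d exceeds sequence length %d", W, L))
  instance <- paste(vapply(seq_len(W), function(j)
    sample(BASES, 1L, prob = motifPwm[, j]), character(1)), collapse = "")
  if (positionPolicy == "uniform") {
    start <- sample.int(L - W + 1L, 1L)
  } else {
    mid <- (L - W) / 2 + 1          # centred 1-based start (possibly .5)
    lo <- max(1L, as.integer(ceiling(mid - W / 2)))
    hi <- min(L - W + 1L, as.integer(floor(mid + W / 2)))
    start <- sample(lo:hi, 1L)
  }
  out <- paste0(substr(sequence, 1L, start - 1L), instance,
                substr(sequence, start + W, L))
  list(sequence = out, start = start)
}

#' Generate a synthetic motif-implantation dataset
#'
#' `nPos` positives each carry one PWM-sampled motif instance implanted in
#' an i.i.d. background strand; `nNeg` negatives are pure background.
#' Strands are shuffled; ground-truth implant positions are retained for
#' motif-recovery and attention-localisation experiments. Fully
#' reproducible under `seed`.
#'
#' @param nPos,nNeg numbers of positive / negative strands.
#' @param length strand length in nucleotides — a scalar, or `c(min, max)`
#'   for uniformly drawn variable lengths.
#' @param gc background GC content.
#' @param motifPwm 4 x W generating PWM (default [defaultMotifPwm()]).
#' @param implantPosition `"center"` (default) or `"uniform"`.
#' @param seed integer seed.
#' @return a [SyntheticDataset-class].
#' @export
makeDataset <- function(nPos = 1000L, nNeg = 1000L, length = 101L,
                        gc = 0.5, motifPwm = defaultMotifPwm(),
                        implantPosition = c("center", "uniform"),
                        seed = 1L) {
  implantPosition <- match.arg(implantPosition)
  stopifnot(nPos >= 0L, nNeg >= 0L)
  if (base::length(length) == 1L) length <- c(length, length)
  stopifnot(ncol(motifPwm) <= length[1L])
  .withSeed(seed, {
    n <- nPos + nNeg
    if (n < 1L) stop("dataset must contain at least one strand")
    lens <- if (length[1L] == length[2L]) rep(length[1L], n)
            else sample(seq.int(length[1L], length[2L]), n, replace = TRUE)
    label <- c(rep(1, nPos), rep(0, nNeg))
    seqs <- character(n); start <- rep(NA_integer_, n)
    for (i in seq_len(n)) {
      s <- sampleBackground(lens[i], gc)
      if (label[i] == 1) {
        imp <- implantMotif(s, motifPwm, implantPosition)
        s <- imp$sequence
        start[i] <- imp$start
      }
      seqs[i] <- s
    }
    ord <- sample.int(n)
    seqs <- seqs[ord]; label <- label[ord]; start <- start[ord]
    ids <- sprintf("s%04d", seq_len(n))
    names(seqs) <- ids
    ls <- LabeledStrands(seqs, matrix(label, ncol = 1L,
                                      dimnames = list(ids, "target1")))
    new("SyntheticDataset", ls,
        truth = data.frame(id = ids, label = label, implantStart = start,
                           stringsAsFactors = FALSE),
        motifPwm = motifPwm)
  })
}
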