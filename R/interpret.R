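#' Scan one convolution filter along an encoded strand
#'
#' A filter of width `F` rows scans an `S`-row encoded strand at
#' `P = S - F + 1` sites; the activation at site `p` is the inner product
#' of the filter with rows `p .. p + F - 1`. Ties in the maximum go to the
#' leftmost site.
#'
#' @param filter numeric `F x C` matrix.
#' @param encoded numeric `S x C` encoded strand (`C` matching the filter).
#' @return list with `activations` (length `P`) and `site` (argmax, 1-based).
#' @export
scanActivations <- function(filter, encoded) {
  filter <- as.matrix(filter); encoded <- as.matrix(encoded)
  Fw <- nrow(filter); S <- nrow(encoded)
  if (ncol(filter) != ncol(encoded))
    stop("filter and encoded strand must have the same number of columns")
  if (Fw > S)
    stop(sprintf("filter width %d exceeds strand rows %d", Fw, S))
  P <- S - Fw + 1L
  acts <- vapply(seq_len(P), function(p)
    sum(filter * encoded[p:(p + Fw - 1L), , drop = FALSE]), numeric(1))
  list(activations = acts, site = which.max(acts))
}

# activation tensor (n x P x K) of all first-layer filters, inner products
# only (no bias), restricted to valid (unpadded) sites
.convActivations <- function(model, batch) {
  cfg <- model@config
  X <- batch@tensor
  n <- dim(X)[1]; S <- dim(X)[2]
  Fw <- cfg@filterWidth
  if (S < Fw) stop("strands too short for the model's filter width")
  P <- S - Fw + 1L
  Xcol <- .im2col(X, Fw)
  acts <- array(Xcol %*% model@params$convW, c(n, P, cfg@nFilters))
  nSites <- pmax(rowSums(batch@mask) - Fw + 1L, 0L)
  list(acts = acts, nSites = nSites, P = P)
}

#' Harvest maximal-activation substrings per filter
#'
#' For every first-layer filter and every strand, the site with the
#' highest activation is located; the site is kept ("valid") when its
#' activation reaches `activationFraction` of that filter's maximum over
#' the whole strand set (and is positive), with `activationFraction = 0`
#' meaning keep-all. A kept site `p` decodes to the nucleotide substring
#' covering positions `p .. p + F + k1 - 2` of the original strand — a
#' filter spanning `F` consecutive k1-mers covers `W = F + k1 - 1` bases.
#'
#' @param model a [KDeepModel-class].
#' @param strands the original sequences ([Biostrings::DNAStringSet],
#'   [LabeledStrands-class], or character vector).
#' @param activationFraction fraction of the per-filter global maximum an
#'   activation must reach (default 0.5).
#' @return list of length `nFilters` of character vectors of substrings,
#'   each of width `F + k1 - 1`.
#' @export
harvestSubstrings <- function(model, strands, activationFraction = 0.5) {
  cfg <- model@config
  if (is(strands, "LabeledStrands")) strands <- strands@strands
  if (is.character(strands))
    strands <- Biostrings::DNAStringSet(normalizeStrand(strands))
  if (!length(strands)) stop("strand set must be non-empty")
  seqs <- as.character(strands)
  batch <- encodeBatch(strands, scheme = cfg@scheme, k1 = cfg@k1, k2 = cfg@k2)
  sc <- .convActivations(model, batch)
  n <- length(seqs)
  W <- cfg@filterWidth + cfg@k1 - 1L
  lapply(seq_len(cfg@nFilters), function(k) {
    am <- matrix(sc$acts[, , k], n)
    best <- integer(n); bestAct <- numeric(n)
    for (i in seq_len(n)) {
      v <- am[i, seq_len(sc$nSites[i])]
      best[i] <- which.max(v)
      bestAct[i] <- v[best[i]]
    }
    gmax <- max(bestAct)
    keep <- if (activationFraction <= 0) rep(TRUE, n)
            else bestAct > 0 & bestAct >= activationFraction * gmax
    substring(seqs[keep], best[keep], best[keep] + W - 1L)
  })
}

#' Tally aligned substrings into a position frequency matrix
#'
#' `counts[b, j]` is the number of substrings carrying base `b` at position
#' `j` (rows A,C,G,T). Substrings may contain N, which contributes to no
#' base, so column totals can fall below the substring count.
#'
#' @param substrings character vector, all of width `W`.
#' @param W motif width (defaults to the common substring width).
#' @return a [PfmMotif-class].
#' @export
pfmFromSubstrings <- function(substrings, W = NULL) {
  if (length(substrings)) {
    widths <- nchar(substrings)
    if (is.null(W)) W <- widths[1L]
    if (any(widths != W))
      stop("all substrings must have width ", W)
  } else if (is.null(W)) stop("W is required for an empty substring set")
  counts <- matrix(0, 4L, W, dimnames = list(BASES, NULL))
  for (j in seq_len(W)) {
    tab <- table(factor(substr(substrings, j, j), levels = BASES))
    counts[, j] <- as.numeric(tab)
  }
  new("PfmMotif", counts = counts, nSites = length(substrings))
}

#' Convert a PFM to a pseudocounted PWM
#'
#' `probs[b, j] = (counts[b, j] + pseudocount) /
#' (columnTotal_j + 4 * pseudocount)`; every column sums to 1 and all
#' entries stay positive, as MEME consumers require. A zero-count column
#' becomes uniform.
#'
#' @param pfm a [PfmMotif-class].
#' @param pseudocount positive pseudocount per cell (default 0.25).
#' @param filterIndex optional provenance index.
#' @return a [PwmMotif-class].
#' @export
pwmFromPfm <- function(pfm, pseudocount = 0.25, filterIndex = NA_integer_) {
  stopifnot(pseudocount > 0)
  counts <- pfm@counts
  tot <- colSums(counts)
  probs <- sweep(counts + pseudocount, 2, tot + 4 * pseudocount, `/`)
  new("PwmMotif", probs = probs, filterIndex = as.integer(filterIndex),
      nSites = pfm@nSites)
}

#' Extract one motif per first-layer convolution filter
#'
#' The filter-to-motif pipeline: scan, harvest maximal-activation
#' substrings ([harvestSubstrings()]), align them into a PFM and normalise
#' to a PWM. Always emits exactly `nFilters` PWMs of width `F + k1 - 1`;
#' a filter with no valid substrings yields the uniform (pseudocount-only)
#' motif with `nSites = 0`.
#'
#' @inheritParams harvestSubstrings
#' @param pseudocount passed to [pwmFromPfm()].
#' @return list of [PwmMotif-class], one per filter.
#' @export
extractMotifs <- function(model, strands, activationFraction = 0.5,
                          pseudocount = 0.25) {
  subs <- harvestSubstrings(model, strands, activationFraction)
  W <- model@config@filterWidth + model@config@k1 - 1L
  lapply(seq_along(subs), function(k)
    pwmFromPfm(pfmFromSubstrings(subs[[k]], W), pseudocount,
               filterIndex = k))
}

#' Write motifs in MEME minimal format
#'
#' Emits the MEME minimal motif format consumed by the TOMTOM comparison
#' tool: version line, alphabet, uniform background, and one MOTIF block
#' with a letter-probability matrix per PWM. `alphabet = "RNA"` writes
#' ACGU (the T row is reported as U).
#'
#' @param pwms list of [PwmMotif-class] (or a single one).
#' @param path output file.
#' @param alphabet `"DNA"` (default) or `"RNA"`.
#' @return `path`, invisibly.
#' @export
writeMeme <- function(pwms, path, alphabet = c("DNA", "RNA")) {
  alphabet <- match.arg(alphabet)
  if (is(pwms, "PwmMotif")) pwms <- list(pwms)
  letters <- if (alphabet == "RNA") c("A", "C", "G", "U") else BASES
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "",
               paste0("ALPHABET= ", paste(letters, collapse = "")), "",
               "Background letter frequencies",
               paste(rbind(letters, "0.25"), collapse = " "), ""), con)
  for (k in seq_along(pwms)) {
    pwm <- pwms[[k]]
    name <- if (is.na(pwm@filterIndex)) paste0("motif_", k)
            else paste0("filter_", pwm@filterIndex)
    writeLines(c(paste("MOTIF", name),
                 sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                         ncol(pwm@probs), max(pwm@nSites, 1L))), con)
    writeLines(apply(pwm@probs, 2, function(col)
      paste(sprintf("%.6f", col), collapse = " ")), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read motifs from a MEME minimal format file
#'
#' Parses the letter-probability matrices back into [PwmMotif-class]
#' objects (columns renormalised against rounding); the inverse of
#' [writeMeme()] up to the printed precision.
#'
#' @param path a MEME minimal motif file.
#' @return list of [PwmMotif-class].
#' @export
readMeme <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^MOTIF\\b", lines)
  lapply(starts, function(s) {
    hdr <- grep("letter-probability matrix", lines[s:length(lines)])[1L] + s - 1L
    w <- as.integer(sub(".*w= *([0-9]+).*", "\\1", lines[hdr]))
    ns <- as.integer(sub(".*nsites= *([0-9]+).*", "\\1", lines[hdr]))
    rows <- lines[(hdr + 1L):(hdr + w)]
    probs <- t(vapply(strsplit(trimws(rows), "\\s+"),
                      function(x) as.numeric(x), numeric(4)))
    probs <- t(probs)  # 4 x W
    probs <- sweep(probs, 2, colSums(probs), `/`)
    rownames(probs) <- BASES
    fi <- if (grepl("^MOTIF filter_", lines[s]))
      as.integer(sub("^MOTIF filter_", "", lines[s])) else NA_integer_
    new("PwmMotif", probs = probs, filterIndex = fi, nSites = ns)
  })
}

#' Mean per-column Pearson correlation between two PWMs
#'
#' Slides the narrower matrix over the wider one and returns the best mean
#' per-column Pearson correlation of the 4-vectors (a column with zero
#' variance scores 0). The package's stand-in for a TOMTOM match score in
#' motif-recovery experiments.
#'
#' @param pwm a [PwmMotif-class] or 4-row matrix.
#' @param reference a [PwmMotif-class] or 4-row matrix.
#' @return list with `score` (best mean column correlation) and `offset`
#'   (0-based shift of the narrower motif within the wider).
#' @export
pwmSimilarity <- function(pwm, reference) {
  a <- if (is(pwm, "PwmMotif")) pwm@probs else as.matrix(pwm)
  b <- if (is(reference, "PwmMotif")) reference@probs else as.matrix(reference)
  if (ncol(a) < ncol(b)) { tmp <- a; a <- b; b <- tmp }
  wA <- ncol(a); wB <- ncol(b)
  colCor <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
    stats::cor(x, y)
  }
  best <- -Inf; bestOff <- 0L
  for (off in 0:(wA - wB)) {
    sc <- mean(vapply(seq_len(wB), function(j)
      colCor(a[, off + j], b[, j]), numeric(1)))
    if (sc > best) { best <- sc; bestOff <- off }
  }
  list(score = best, offset = bestOff)
}

#' Best motif-recovery match in a set of extracted PWMs
#'
#' @param pwms list of [PwmMotif-class].
#' @param reference the implanted/known 4 x W PWM.
#' @return list with `score`, `filter` (index of the best-matching PWM)
#'   and `offset`.
#' @export
bestMotifMatch <- function(pwms, reference) {
  scores <- lapply(pwms, pwmSimilarity, reference = reference)
  i <- which.max(vapply(scores, `[[`, numeric(1), "score"))
  list(score = scores[[i]]$score, filter = i, offset = scores[[i]]$offset)
}

#' Attention heatmap export
#'
#' Computes the per-strand attention weights of a KDeep+ model
#' ([attentionScores()]), writes them as a tab-separated matrix
#' (`<path>.tsv`, strands x pooled positions) and renders a heatmap image
#' (`<path>.png`). Each row sums to 1; the bright band marks the input
#' fragments driving the prediction.
#'
#' @param model a KDeep+ [KDeepModel-class] (`useAttention = TRUE`).
#' @param strands sequences or an [EncodedBatch-class].
#' @param path output path prefix (extensions are appended).
#' @return the score matrix, invisibly.
#' @export
attentionHeatmap <- function(model, strands, path) {
  scores <- attentionScores(model, strands)
  tsv <- paste0(path, ".tsv")
  utils::write.table(scores, tsv, sep = "\t", quote = FALSE,
                     col.names = NA)
  img <- paste0(path, ".png")
  grDevices::png(img, width = 720, height = 480)
  on.exit(grDevices::dev.off())
  graphics::image(x = seq_len(ncol(scores)), y = seq_len(nrow(scores)),
                  z = t(scores), col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = "pooled position", ylab = "strand",
                  main = "attention scores")
  invisible(scores)
}
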