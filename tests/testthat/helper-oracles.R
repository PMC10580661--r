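# Independent brute-force oracles used to freeze expected values.

# count occurrences of every k2-mer (lexicographic order) by string scanning
oracleKmerCounts <- function(word, k2) {
  alpha <- c("A", "C", "G", "T")
  kmers <- sort(do.call(paste0, expand.grid(
    rep(list(alpha), k2), stringsAsFactors = FALSE)[, k2:1, drop = FALSE]))
  # expand.grid varies first column fastest; sort gives lexicographic order
  windows <- substring(word, seq_len(nchar(word) - k2 + 1),
                       seq_len(nchar(word) - k2 + 1) + k2 - 1)
  vapply(kmers, function(k) sum(windows == k), numeric(1))
}

# pairwise-counting auROC: wins + half-ties over all pos x neg pairs
oracleAuroc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# average precision by explicit threshold enumeration over distinct scores
oracleAp <- function(scores, labels) {
  thr <- sort(unique(scores), decreasing = TRUE)
  nPos <- sum(labels == 1)
  ap <- 0; prevRec <- 0
  for (t in thr) {
    sel <- scores >= t
    prec <- sum(labels[sel] == 1) / sum(sel)
    rec <- sum(labels[sel] == 1) / nPos
    ap <- ap + (rec - prevRec) * prec
    prevRec <- rec
  }
  ap
}

randomStrand <- function(L, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, L, replace = TRUE), collapse = "")
}

# small model configuration for fast unit tests (encoded rows 59 = 61-nt
# strands under 2Lk(3,2))
tinyConfig <- function(...) {
  args <- list(inputCols = 16, inputRows = 59, nOutputs = 1,
               strandType = "RNA", nFilters = 8, filterWidth = 16,
               poolSize = 13, lstmUnits = 8, denseUnits = 16,
               attnUnits = 8)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(kdeepConfig, args)
}

tinyDataset <- function(n = 150, seed = 5, length = 61)
  makeDataset(n / 2, n / 2, length = length, seed = seed)
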