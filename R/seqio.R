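IUPAC_OK <- c("A", "C", "G", "T", "U", "N",
              "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

#' Normalise a raw nucleotide string to the \{A,C,G,T,N\} alphabet
#'
#' Upper-cases, maps U to T (so one encoder serves DNA and RNA strands),
#' and collapses every IUPAC ambiguity code other than A/C/G/T to N.
#' Idempotent. A character outside the IUPAC nucleotide codes raises an
#' error naming the character and its position.
#'
#' @param raw character vector of raw sequences.
#' @return character vector over \{A,C,G,T,N\}.
#' @examples
#' normalizeStrand("augcga")  # "ATGCGA"
#' normalizeStrand("ACRGT")   # "ACNGT"
#' @export
normalizeStrand <- function(raw) {
  if (!is.character(raw) || any(!nzchar(raw)))
    stop("sequences must be non-empty strings")
  up <- toupper(raw)
  bad <- regexpr(sprintf("[^%s]", paste(IUPAC_OK, collapse = "")), up)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("invalid nucleotide character '%s' at position %d of sequence %d",
                 substr(up[i], bad[i], bad[i]), bad[i], i))
  }
  chartr("URYSWKMBDHV", "TNNNNNNNNNN", up)
}

#' Read nucleotide strands from a FASTA file
#'
#' Parses FASTA (any line wrapping), normalises every sequence with
#' [normalizeStrand()], and returns a named [Biostrings::DNAStringSet] in
#' file order. Ids are the header up to the first whitespace. An empty file
#' yields an empty set; a sequence line before any header is a parse error
#' naming the offending line.
#'
#' @param path path to a FASTA file.
#' @return a [Biostrings::DNAStringSet].
#' @export
readStrands <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  content <- which(nzchar(trimws(lines)))
  if (!length(content)) return(Biostrings::DNAStringSet())
  if (!startsWith(trimws(lines[content[1L]]), ">"))
    stop(sprintf("malformed FASTA: sequence line before any header at line %d",
                 content[1L]))
  raw <- Biostrings::readBStringSet(path)
  seqs <- normalizeStrand(as.character(raw))
  ids <- vapply(strsplit(names(raw), "\\s+"), `[`, character(1), 1L)
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  out
}

#' Write strands to FASTA
#'
#' Sequences are wrapped at 80 columns; `readStrands(writeStrands(x))`
#' round-trips ids and sequences exactly.
#'
#' @param strands a named [Biostrings::DNAStringSet] (or character vector).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeStrands <- function(strands, path) {
  if (is.character(strands)) strands <- Biostrings::DNAStringSet(strands)
  Biostrings::writeXStringSet(strands, path, width = 80L)
  invisible(path)
}

#' Read a tab-separated binary label sidecar
#'
#' Format: `id<TAB>l1[<TAB>l2...]`, no header, one row per strand. Values
#' must be 0 or 1. When `ids` is supplied the matrix is aligned to that
#' order; missing or extra ids are reported explicitly.
#'
#' @param path path to the label file.
#' @param nTargets expected number of label columns.
#' @param ids optional character vector (e.g. FASTA order) to align to.
#' @return numeric matrix of 0/1 with rownames set to the ids.
#' @export
readLabels <- function(path, nTargets, ids = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, header = FALSE, sep = "\t",
                           colClasses = "character")
  if (ncol(tab) != nTargets + 1L)
    stop(sprintf("expected %d label column(s) after the id, found %d",
                 nTargets, ncol(tab) - 1L))
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  if (any(is.na(num)) || !all(num %in% c(0, 1)))
    stop("labels must be 0 or 1; offending value(s): ",
         paste(unique(vals[is.na(num) | !(num %in% c(0, 1))]), collapse = ", "))
  rownames(num) <- tab[[1L]]
  colnames(num) <- paste0("target", seq_len(ncol(num)))
  if (!is.null(ids)) {
    missing <- setdiff(ids, rownames(num))
    extra <- setdiff(rownames(num), ids)
    if (length(missing) || length(extra))
      stop("label/FASTA id mismatch",
           if (length(missing)) paste0("; missing: ", paste(missing, collapse = ", ")),
           if (length(extra)) paste0("; extra: ", paste(extra, collapse = ", ")))
    num <- num[ids, , drop = FALSE]
  }
  num
}

#' Construct a LabeledStrands container
#'
#' @param strands named [Biostrings::DNAStringSet] or character vector of
#'   sequences (normalised on the way in).
#' @param labels 0/1 matrix (or vector for a single target), one row per
#'   strand.
#' @return a [LabeledStrands-class].
#' @export
LabeledStrands <- function(strands, labels) {
  if (is.character(strands)) {
    ids <- names(strands)
    strands <- Biostrings::DNAStringSet(normalizeStrand(strands))
    names(strands) <- if (is.null(ids)) paste0("s", seq_along(strands)) else ids
  }
  if (is.null(dim(labels))) labels <- matrix(labels, ncol = 1L)
  labels <- as.matrix(labels)
  if (nrow(labels) == length(strands)) rownames(labels) <- names(strands)
  new("LabeledStrands", strands = strands, labels = labels)
}
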