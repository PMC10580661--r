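#' Accessors for kdeep containers
#'
#' Small accessor generics so slot layout stays private to the package.
#'
#' @param x an object from this package.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("strands", function(x) standardGeneric("strands"))

#' @rdname accessors
#' @export
setGeneric("labelMatrix", function(x) standardGeneric("labelMatrix"))

#' @rdname accessors
#' @export
setGeneric("fcgrCounts", function(x) standardGeneric("fcgrCounts"))

#' @rdname accessors
#' @export
setGeneric("encodedTensor", function(x) standardGeneric("encodedTensor"))

#' @rdname accessors
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))

#' @rdname accessors
#' @export
setGeneric("strandIds", function(x) standardGeneric("strandIds"))

#' @rdname accessors
#' @export
setGeneric("modelConfig", function(x) standardGeneric("modelConfig"))

#' @rdname accessors
#' @export
setGeneric("trainingLog", function(x) standardGeneric("trainingLog"))

#' @rdname accessors
#' @export
setGeneric("firstLayerFilters", function(x) standardGeneric("firstLayerFilters"))

#' @rdname accessors
#' @export
setGeneric("pwmMatrix", function(x) standardGeneric("pwmMatrix"))

#' @rdname accessors
#' @export
setGeneric("pfmCounts", function(x) standardGeneric("pfmCounts"))

#' @rdname accessors
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' @rdname accessors
#' @export
setGeneric("motifTruth", function(x) standardGeneric("motifTruth"))

setMethod("strands", "LabeledStrands", function(x) x@strands)
setMethod("labelMatrix", "LabeledStrands", function(x) x@labels)
setMethod("labelMatrix", "EncodedBatch", function(x) x@labels)
setMethod("fcgrCounts", "FcgrGrid", function(x) x@counts)
setMethod("encodedTensor", "EncodedBatch", function(x) x@tensor)
setMethod("validMask", "EncodedBatch", function(x) x@mask)
setMethod("strandIds", "EncodedBatch", function(x) x@ids)
setMethod("strandIds", "LabeledStrands", function(x) names(x@strands))
setMethod("modelConfig", "KDeepModel", function(x) x@config)
setMethod("trainingLog", "KDeepModel", function(x) x@log)
setMethod("pwmMatrix", "PwmMotif", function(x) x@probs)
setMethod("pfmCounts", "PfmMotif", function(x) x@counts)
setMethod("nSites", "PwmMotif", function(x) x@nSites)
setMethod("nSites", "PfmMotif", function(x) x@nSites)
setMethod("motifTruth", "SyntheticDataset", function(x) x@truth)

setMethod("firstLayerFilters", "KDeepModel", function(x) {
  cfg <- x@config
  lapply(seq_len(cfg@nFilters), function(k)
    matrix(x@params$convW[, k], cfg@filterWidth, cfg@inputCols, byrow = TRUE))
})

setMethod("show", "LabeledStrands", function(object) {
  cat(sprintf("LabeledStrands: %d strands, %d target(s)\n",
              length(object@strands), ncol(object@labels)))
  if (length(object@strands)) {
    w <- Biostrings::width(object@strands)
    cat(sprintf("  lengths: %d..%d nt\n", min(w), max(w)))
  }
})

setMethod("show", "FcgrGrid", function(object) {
  cat(sprintf("FcgrGrid: k2 = %d (%d cells), total count %.4g\n",
              object@k2, 4L^object@k2, sum(object@counts)))
})

setMethod("show", "EncodedBatch", function(object) {
  d <- dim(object@tensor)
  cat(sprintf("EncodedBatch [%s]: %d strands x %d rows x %d cols (k1=%d, k2=%d)\n",
              object@scheme, d[1], d[2], d[3], object@k1, object@k2))
})

setMethod("show", "KDeepConfig", function(object) {
  cat(sprintf("KDeepConfig: %s, %d filters x %d rows, pool %d, BiLSTM %d/dir, dense %d -> %d output(s)\n",
              if (object@useAttention) "KDeep+ (attention)" else "KDeep",
              object@nFilters, object@filterWidth, object@poolSize,
              object@lstmUnits, object@denseUnits, object@nOutputs))
})

setMethod("show", "KDeepModel", function(object) {
  show(object@config)
  cat(sprintf("  %s, %d trainable parameters\n",
              if (object@trained) "trained" else "initialised (untrained)",
              countTrainableParameters(object)))
})

setMethod("show", "PwmMotif", function(object) {
  cat(sprintf("PwmMotif: width %d, filter %s, %d supporting site(s)\n",
              ncol(object@probs),
              ifelse(is.na(object@filterIndex), "NA", object@filterIndex),
              object@nSites))
})

setMethod("show", "SyntheticDataset", function(object) {
  callNextMethod()
  cat(sprintf("  synthetic: motif width %d, %d implanted positives\n",
              ncol(object@motifPwm), sum(!is.na(object@truth$implantStart))))
})

#' Subset an encoded batch by strand
#'
#' @param x an [EncodedBatch-class].
#' @param i strand indices (integer, logical, or ids).
#' @param j,...,drop ignored.
#' @export
setMethod("[", "EncodedBatch", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@ids)
  new("EncodedBatch",
      tensor = x@tensor[i, , , drop = FALSE],
      mask = x@mask[i, , drop = FALSE],
      ids = x@ids[i], scheme = x@scheme, k1 = x@k1, k2 = x@k2,
      labels = if (nrow(x@labels)) x@labels[i, , drop = FALSE] else x@labels)
})
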