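#' @import methods
#' @importFrom Biostrings DNAStringSet readBStringSet writeXStringSet width
NULL

#' Labelled nucleotide strands
#'
#' Container pairing an ordered set of nucleotide strands (DNA alphabet;
#' RNA is normalised by U -> T at ingest) with a binary label matrix of one
#' row per strand and one column per prediction target.
#'
#' @slot strands a [Biostrings::DNAStringSet] whose names are strand ids.
#' @slot labels numeric matrix of 0/1 values, `length(strands)` rows,
#'   `n_targets >= 1` columns; rownames are the strand ids.
#'
#' @seealso [LabeledStrands()], [readStrands()], [readLabels()]
#' @export
setClass("LabeledStrands",
  representation(strands = "DNAStringSet", labels = "matrix"))

setValidity("LabeledStrands", function(object) {
  msg <- character(0)
  if (nrow(object@labels) != length(object@strands))
    msg <- c(msg, sprintf("label rows (%d) != strand count (%d)",
                          nrow(object@labels), length(object@strands)))
  if (ncol(object@labels) < 1L)
    msg <- c(msg, "label matrix needs at least one target column")
  if (length(object@labels) && !all(object@labels %in% c(0, 1)))
    msg <- c(msg, "labels must be 0 or 1")
  if (length(msg)) msg else TRUE
})

#' Frequency chaos game representation grid
#'
#' A `2^k2 x 2^k2` grid of non-negative k-mer counts. Cells are in bijection
#' with the `4^k2` possible k2-mers via the lexicographic digit encoding
#' A=0, C=1, G=2, T=3 (see [kmerCellIndex()]); the grid is the row-major
#' reshape of the flat count vector. For an N-free word of length W the
#' grid total is exactly `W - k2 + 1`.
#'
#' @slot k2 integer, FCGR resolution.
#' @slot counts numeric `2^k2 x 2^k2` matrix, entries >= 0.
#' @export
setClass("FcgrGrid", representation(k2 = "integer", counts = "matrix"))

setValidity("FcgrGrid", function(object) {
  side <- as.integer(2^object@k2)
  if (!identical(dim(object@counts), c(side, side)))
    return(sprintf("counts must be %d x %d for k2 = %d", side, side, object@k2))
  if (any(object@counts < 0)) return("counts must be non-negative")
  TRUE
})

#' Batch of encoded strands
#'
#' A 3-axis tensor of encoded strands, right-padded with all-zero rows to
#' the batch maximum, plus a row-validity mask. `scheme` is `"2lk"`
#' (rows are `L - k1 + 1` sliding k1-mers, columns the `4^k2` FCGR cells)
#' or `"onehot"` (`L` rows, 4 columns in A,C,G,T order).
#'
#' @slot tensor numeric array `n x maxRows x cols`.
#' @slot mask logical matrix `n x maxRows`; `TRUE` marks real (unpadded) rows.
#' @slot ids character vector of strand ids.
#' @slot scheme `"2lk"` or `"onehot"`.
#' @slot k1,k2 integer encoding parameters (1 for one-hot).
#' @slot labels numeric label matrix (possibly 0 columns when unlabelled).
#' @export
setClass("EncodedBatch",
  representation(tensor = "array", mask = "matrix", ids = "character",
                 scheme = "character", k1 = "integer", k2 = "integer",
                 labels = "matrix"))

setValidity("EncodedBatch", function(object) {
  d <- dim(object@tensor)
  msg <- character(0)
  if (length(d) != 3L) msg <- c(msg, "tensor must have 3 axes")
  if (!identical(dim(object@mask), d[1:2]))
    msg <- c(msg, "mask dimensions must match tensor rows")
  if (length(object@ids) != d[1]) msg <- c(msg, "one id per strand required")
  if (!object@scheme %in% c("2lk", "onehot"))
    msg <- c(msg, "scheme must be '2lk' or 'onehot'")
  if (length(msg)) msg else TRUE
})

#' Precomputed k-mer encoding lookup table
#'
#' FCGR profile of every length-`k1` word over \{A,C,G,T,N\} — `5^k1`
#' entries (125 for k1 = 3), independent of the number of training samples.
#'
#' @slot k1,k2 integer encoding parameters.
#' @slot entries numeric `5^k1 x 4^k2` matrix; rownames are the words.
#' @export
setClass("LookupTable",
  representation(k1 = "integer", k2 = "integer", entries = "matrix"))

setValidity("LookupTable", function(object) {
  if (nrow(object@entries) != 5^object@k1)
    return(sprintf("expected %d entries, found %d",
                   5^object@k1, nrow(object@entries)))
  if (ncol(object@entries) != 4^object@k2)
    return("entry width must be 4^k2")
  TRUE
})

#' KDeep model configuration
#'
#' Hyperparameter record for the KDeep (CNN-BiLSTM) and KDeep+
#' (CNN-attention-BiLSTM) predictors. Construct with [kdeepConfig()].
#'
#' @slot nFilters first-layer convolution kernels.
#' @slot filterWidth rows of encoded input each kernel spans (F).
#' @slot poolSize non-overlapping max-pool window.
#' @slot dropoutCnn,dropoutLstm dropout rates after pooling / after BiLSTM.
#' @slot lstmUnits BiLSTM units per direction.
#' @slot attnUnits hidden width of the additive attention scorer.
#' @slot denseUnits units in the penultimate dense layer.
#' @slot nOutputs prediction targets (independent sigmoids).
#' @slot useAttention logical, KDeep+ when `TRUE`.
#' @slot inputCols encoded columns (`4^k2`, or 4 for one-hot).
#' @slot inputRows encoded rows the model expects (`L - k1 + 1`); shorter
#'   batches are zero-padded up to this, as with any fixed-input network.
#' @slot k1,k2 encoding parameters the model was built for.
#' @slot scheme `"2lk"` or `"onehot"`.
#' @slot seed integer used for parameter initialisation and training RNG.
#' @export
setClass("KDeepConfig",
  representation(nFilters = "integer", filterWidth = "integer",
                 poolSize = "integer", dropoutCnn = "numeric",
                 lstmUnits = "integer", dropoutLstm = "numeric",
                 attnUnits = "integer", denseUnits = "integer",
                 nOutputs = "integer", useAttention = "logical",
                 inputCols = "integer", inputRows = "integer",
                 k1 = "integer", k2 = "integer",
                 scheme = "character", seed = "integer"))

setValidity("KDeepConfig", function(object) {
  msg <- character(0)
  pos <- c(nFilters = object@nFilters, filterWidth = object@filterWidth,
           poolSize = object@poolSize, lstmUnits = object@lstmUnits,
           attnUnits = object@attnUnits, denseUnits = object@denseUnits,
           nOutputs = object@nOutputs, inputCols = object@inputCols,
           inputRows = object@inputRows)
  bad <- names(pos)[pos < 1L]
  if (length(bad)) msg <- c(msg, paste("must be >= 1:", paste(bad, collapse = ", ")))
  if (object@filterWidth > object@inputRows)
    msg <- c(msg, "filterWidth must not exceed inputRows")
  for (r in c(object@dropoutCnn, object@dropoutLstm))
    if (r < 0 || r >= 1) msg <- c(msg, "dropout rates must lie in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' Fitted (or initialised) KDeep predictor
#'
#' Parameters are plain numeric matrices/vectors in `params`; first-layer
#' convolution filters stay inspectable via [firstLayerFilters()], which the
#' motif-extraction pipeline relies on.
#'
#' @slot config a [KDeepConfig-class].
#' @slot params named list of parameter arrays.
#' @slot trained logical.
#' @slot log per-epoch data.frame of training/validation loss.
#' @export
setClass("KDeepModel",
  representation(config = "KDeepConfig", params = "list",
                 trained = "logical", log = "data.frame"))

#' Position weight matrix with provenance
#'
#' Column-stochastic 4 x W matrix (rows A,C,G,T) derived from the aligned
#' maximal-activation substrings of one convolution filter.
#'
#' @slot probs numeric 4 x W matrix, every column summing to 1.
#' @slot filterIndex integer index of the originating filter (NA if none).
#' @slot nSites integer count of supporting substrings.
#' @export
setClass("PwmMotif",
  representation(probs = "matrix", filterIndex = "integer",
                 nSites = "integer"))

setValidity("PwmMotif", function(object) {
  if (nrow(object@probs) != 4L) return("probs must have 4 rows (A,C,G,T)")
  if (any(abs(colSums(object@probs) - 1) > 1e-9))
    return("every column must sum to 1")
  if (any(object@probs <= 0)) return("entries must be > 0 (pseudocounted)")
  TRUE
})

#' Position frequency matrix
#'
#' Raw per-position base counts from aligned substrings. Substrings may
#' contain N, which contributes to no base; per-column totals are therefore
#' tracked separately from the substring count.
#'
#' @slot counts numeric 4 x W matrix (rows A,C,G,T) of non-negative counts.
#' @slot nSites integer number of contributing substrings.
#' @export
setClass("PfmMotif",
  representation(counts = "matrix", nSites = "integer"))

#' Synthetic motif-implantation dataset
#'
#' A [LabeledStrands-class] whose positives carry a PWM-sampled motif
#' instance, plus the generating ground truth (implant position per strand)
#' for motif-recovery and attention-localisation experiments.
#'
#' @slot truth data.frame with columns `id`, `label`, `implantStart`
#'   (1-based; NA for negatives).
#' @slot motifPwm the generating 4 x W PWM.
#' @export
setClass("SyntheticDataset", contains = "LabeledStrands",
  representation(truth = "data.frame", motifPwm = "matrix"))
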