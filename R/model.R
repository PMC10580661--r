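#' Configure a KDeep / KDeep+ predictor
#'
#' Defaults follow the DanQ-family conventions the architecture belongs to:
#' filter width 16 encoded rows, non-overlapping max-pool 13, dropout
#' 0.2 after pooling and 0.5 after the BiLSTM, dense 128, and — for the
#' DNA-scale configuration — 320 first-layer kernels with 320 BiLSTM units
#' per direction (`strandType = "RNA"` scales the recurrent part down to
#' 32 units). Every value is overridable.
#'
#' @param inputCols encoded columns per row (`4^k2` for 2Lk; 4 for one-hot).
#' @param inputRows encoded rows the model expects (`L - k1 + 1` for 2Lk on
#'   length-L strands; default 99 suits fixed 101-nt strands). Shorter
#'   inputs are zero-padded up to this at prediction time; the BiLSTM's
#'   per-position outputs are flattened into the dense classifier, so the
#'   network can exploit where along the strand a feature occurred.
#' @param nOutputs number of prediction targets (independent sigmoids).
#' @param strandType `"DNA"` or `"RNA"`; sets the scale defaults above.
#' @param nFilters,filterWidth,poolSize,dropoutCnn,lstmUnits,dropoutLstm,attnUnits,denseUnits
#'   architecture hyperparameters, see slots of [KDeepConfig-class].
#' @param useAttention build the KDeep+ variant (additive attention over
#'   pooled positions) when `TRUE`.
#' @param k1,k2,scheme the encoding the model expects; used when decoding
#'   filters back to nucleotide motifs.
#' @param seed integer seed for parameter initialisation and training.
#' @return a [KDeepConfig-class].
#' @examples
#' kdeepConfig(16, strandType = "DNA")@nFilters  # 320
#' @export
kdeepConfig <- function(inputCols = 16L, inputRows = 99L, nOutputs = 1L,
                        strandType = c("DNA", "RNA"),
                        nFilters = 320L, filterWidth = 16L, poolSize = 13L,
                        dropoutCnn = 0.2,
                        lstmUnits = if (match.arg(strandType) == "DNA") 320L else 32L,
                        dropoutLstm = 0.5, attnUnits = 16L,
                        denseUnits = 128L, useAttention = FALSE,
                        k1 = 3L, k2 = 2L, scheme = "2lk", seed = 1L) {
  new("KDeepConfig",
      nFilters = as.integer(nFilters), filterWidth = as.integer(filterWidth),
      poolSize = as.integer(poolSize), dropoutCnn = dropoutCnn,
      lstmUnits = as.integer(lstmUnits), dropoutLstm = dropoutLstm,
      attnUnits = as.integer(attnUnits), denseUnits = as.integer(denseUnits),
      nOutputs = as.integer(nOutputs), useAttention = isTRUE(useAttention),
      inputCols = as.integer(inputCols), inputRows = as.integer(inputRows),
      k1 = as.integer(k1),
      k2 = as.integer(k2), scheme = scheme, seed = as.integer(seed))
}

# run expr with a private RNG stream, restoring the caller's state
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Build an (untrained) KDeep model
#'
#' Layer sequence: conv(nFilters, filterWidth, valid padding) -> ReLU ->
#' maxpool(poolSize) -> dropout -> \[attention if KDeep+\] ->
#' BiLSTM(lstmUnits per direction) -> dropout -> dense(denseUnits, ReLU) ->
#' dense(nOutputs, sigmoid). Valid (no) padding keeps the filter-scan
#' arithmetic `P = S - F + 1` exact. Parameters are Glorot-uniform
#' initialised from `config@seed`, so two builds with the same seed are
#' bitwise identical.
#'
#' @param config a [KDeepConfig-class].
#' @return a [KDeepModel-class] (untrained).
#' @export
buildModel <- function(config) {
  validObject(config)
  params <- .withSeed(config@seed, .nnInitParams(config))
  new("KDeepModel", config = config, params = params, trained = FALSE,
      log = data.frame())
}

#' Count trainable parameters
#'
#' @param model a [KDeepModel-class].
#' @param byLayer return a named per-parameter-tensor breakdown instead of
#'   the total.
#' @return integer count (or named integer vector).
#' @export
countTrainableParameters <- function(model, byLayer = FALSE) {
  n <- vapply(model@params, length, integer(1))
  if (byLayer) n else sum(n)
}

#' Additive attention over a sequence of feature vectors
#'
#' Location-free additive attention: each position's feature vector is
#' scored by `v' tanh(W h + b)`, scores are softmax-normalised over
#' positions (non-negative, summing to 1), and features are rescaled by
#' their score. With the default weights the score reduces to
#' `sum(tanh(h))`, so uniform features always receive uniform weights.
#'
#' @param features numeric `P x K` matrix (positions x feature channels).
#' @param W,b,v scorer parameters (`K x A`, length-A, `A x 1`); defaults
#'   are the identity map, zero bias and an all-ones readout.
#' @return list with `features` (reweighted `P x K`) and `scores`
#'   (length-P, sums to 1).
#' @export
attentionBlock <- function(features, W = diag(ncol(features)),
                           b = numeric(ncol(W)),
                           v = matrix(1, ncol(W), 1L)) {
  features <- as.matrix(features)
  if (!nrow(features)) stop("feature sequence must be non-empty")
  e <- as.vector(tanh(sweep(features %*% W, 2, b, `+`)) %*% v)
  a <- exp(e - max(e))
  a <- a / sum(a)
  list(features = features * a, scores = a)
}

# coerce assorted inputs to an EncodedBatch matching the model's encoding,
# zero-padding rows up to the model's fixed input size
.asBatch <- function(x, cfg) {
  if (!is(x, "EncodedBatch"))
    x <- encodeBatch(x, scheme = cfg@scheme, k1 = cfg@k1, k2 = cfg@k2)
  if (x@scheme != cfg@scheme || (cfg@scheme == "2lk" &&
      (x@k1 != cfg@k1 || x@k2 != cfg@k2)))
    stop("batch encoding does not match the model configuration")
  d <- dim(x@tensor)
  if (d[3] != cfg@inputCols)
    stop(sprintf("model expects %d encoded columns, batch has %d",
                 cfg@inputCols, d[3]))
  if (d[2] > cfg@inputRows)
    stop(sprintf("batch has %d encoded rows but the model was built for %d",
                 d[2], cfg@inputRows))
  if (d[2] < cfg@inputRows) {
    tensor <- array(0, c(d[1], cfg@inputRows, d[3]))
    tensor[, seq_len(d[2]), ] <- x@tensor
    mask <- matrix(FALSE, d[1], cfg@inputRows)
    mask[, seq_len(d[2])] <- x@mask
    x <- new("EncodedBatch", tensor = tensor, mask = mask, ids = x@ids,
             scheme = x@scheme, k1 = x@k1, k2 = x@k2, labels = x@labels)
  }
  x
}

#' Train a KDeep model
#'
#' Minimises mean binary cross-entropy (over targets for multi-label) with
#' Adam, holding out `validationFraction` of the strands for per-epoch
#' validation; the parameters with the best validation loss are retained,
#' and training stops early after `patience` epochs without improvement.
#' All randomness (split, shuffling, dropout) flows from `config@seed`, so
#' identical data + config reproduce the training log exactly.
#'
#' @param model a [KDeepModel-class] from [buildModel()].
#' @param data an [EncodedBatch-class] (or anything [encodeBatch()] accepts).
#' @param labels 0/1 matrix, one row per strand; taken from `data` when the
#'   batch carries labels.
#' @param epochs maximum training epochs.
#' @param batchSize minibatch size.
#' @param learningRate Adam step size.
#' @param validationFraction fraction of strands held out for validation
#'   (0 disables early stopping and checkpointing).
#' @param patience early-stopping patience in epochs.
#' @param verbose print per-epoch losses.
#' @return the trained [KDeepModel-class] with a populated training log.
#' @export
trainModel <- function(model, data, labels = NULL, epochs = 10L,
                       batchSize = 64L, learningRate = 1e-3,
                       validationFraction = 0.2, patience = 5L,
                       verbose = FALSE) {
  cfg <- model@config
  batch <- .asBatch(data, cfg)
  X <- batch@tensor; mask <- batch@mask
  if (is.null(labels)) labels <- batch@labels
  if (is.null(dim(labels))) labels <- matrix(labels, ncol = 1L)
  Y <- as.matrix(labels)
  n <- dim(X)[1]
  if (nrow(Y) != n) stop("label rows must match strand count")
  if (ncol(Y) != cfg@nOutputs)
    stop(sprintf("model expects %d target(s), labels have %d columns",
                 cfg@nOutputs, ncol(Y)))
  if (!all(Y %in% c(0, 1))) stop("labels must be binary")
  p <- model@params
  .withSeed(cfg@seed + 1L, {
    nVal <- floor(validationFraction * n)
    valIdx <- if (nVal > 0) sample.int(n, nVal) else integer(0)
    trIdx <- setdiff(seq_len(n), valIdx)
    st <- .adamInit(p)
    bestLoss <- Inf; bestP <- p; wait <- 0L
    log <- data.frame(epoch = integer(0), trainLoss = numeric(0),
                      valLoss = numeric(0))
    for (ep in seq_len(epochs)) {
      ord <- sample(trIdx)
      bl <- numeric(0)
      for (s in seq(1L, length(ord), by = batchSize)) {
        bi <- ord[s:min(s + batchSize - 1L, length(ord))]
        Xb <- X[bi, , , drop = FALSE]; Yb <- Y[bi, , drop = FALSE]
        S <- dim(Xb)[2]
        Qb <- max((S - cfg@filterWidth + 1L) %/% cfg@poolSize, 1L)
        dm <- .sampleDropMasks(cfg, length(bi), Qb)
        fw <- .nnForward(p, cfg, Xb, mask[bi, , drop = FALSE], dropMasks = dm)
        loss <- .bceLoss(fw$logits, Yb)
        if (!is.finite(loss))
          stop(sprintf("non-finite loss at epoch %d; lower the learning rate", ep))
        g <- .nnBackward(p, cfg, fw, Yb)
        upd <- .adamStep(p, g, st, learningRate)
        p <- upd$p; st <- upd$st
        bl <- c(bl, loss)
      }
      valLoss <- if (length(valIdx)) {
        fv <- .nnForward(p, cfg, X[valIdx, , , drop = FALSE],
                         mask[valIdx, , drop = FALSE])
        .bceLoss(fv$logits, Y[valIdx, , drop = FALSE])
      } else NA_real_
      log <- rbind(log, data.frame(epoch = ep, trainLoss = mean(bl),
                                   valLoss = valLoss))
      if (verbose)
        message(sprintf("epoch %d: train %.4f  val %.4f", ep, mean(bl), valLoss))
      if (length(valIdx)) {
        if (valLoss < bestLoss - 1e-6) {
          bestLoss <- valLoss; bestP <- p; wait <- 0L
        } else {
          wait <- wait + 1L
          if (wait >= patience) break
        }
      } else bestP <- p
    }
    model@params <- bestP
    model@trained <- TRUE
    model@log <- log
  })
  model
}

#' Predict binding scores
#'
#' Deterministic inference (dropout disabled); scores lie in (0, 1), one
#' column per target, and each row is independent of the rest of the batch.
#'
#' @param model a [KDeepModel-class].
#' @param data an [EncodedBatch-class] or anything [encodeBatch()] accepts.
#' @return numeric `n x nOutputs` matrix with strand ids as rownames.
#' @export
predictScores <- function(model, data) {
  batch <- .asBatch(data, model@config)
  fw <- .nnForward(model@params, model@config, batch@tensor, batch@mask)
  out <- fw$yhat
  rownames(out) <- batch@ids
  out
}

#' @describeIn predictScores `predict` method for fitted KDeep models.
#' @param object a [KDeepModel-class].
#' @param ... passed on; first argument is the data.
#' @export
setMethod("predict", "KDeepModel",
          function(object, ...) predictScores(object, ...))

#' Per-strand attention scores
#'
#' Forward pass of a KDeep+ model capturing the attention weights over
#' pooled positions; each row is non-negative and sums to 1.
#'
#' @param model a [KDeepModel-class] built with `useAttention = TRUE`.
#' @param data an [EncodedBatch-class] or anything [encodeBatch()] accepts.
#' @return numeric `n x P_pooled` matrix of attention weights.
#' @export
attentionScores <- function(model, data) {
  if (!model@config@useAttention)
    stop("model was built without an attention block")
  batch <- .asBatch(data, model@config)
  fw <- .nnForward(model@params, model@config, batch@tensor, batch@mask)
  a <- fw$cache$attn$alpha
  rownames(a) <- batch@ids
  a
}

#' Save / load a KDeep model
#'
#' Serialises configuration, parameters and training log;
#' `loadModel(saveModel(m, f))` predicts bitwise identically to `m`.
#'
#' @param model a [KDeepModel-class].
#' @param path file path.
#' @return `saveModel`: `path` invisibly; `loadModel`: the model.
#' @export
saveModel <- function(model, path) {
  cfg <- model@config
  cfgList <- sapply(slotNames(cfg), function(s) slot(cfg, s),
                    simplify = FALSE)
  saveRDS(list(format = "kdeep-model", version = 1L, config = cfgList,
               params = model@params, trained = model@trained,
               log = model@log), path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  if (!file.exists(path)) stop("no such model file: ", path)
  obj <- tryCatch(readRDS(path), error = function(e)
    stop("not a readable model file: ", path, " (", conditionMessage(e), ")"))
  if (!is.list(obj) || !identical(obj$format, "kdeep-model"))
    stop("file is not a saved kdeep model: ", path)
  cfg <- do.call(kdeepConfig, obj$config)
  new("KDeepModel", config = cfg, params = obj$params,
      trained = obj$trained, log = obj$log)
}
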