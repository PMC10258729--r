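#' Log-normalize reflectance vectors
#'
#' Applies the per-channel standardization used by the inverse model:
#' x -> (ln x - mean_c) / sd_c. When `stats` is `NULL` the statistics are
#' fitted on the given matrix (so the fitting set maps to per-channel mean
#' 0 and SD 1) and attached to the result as attribute `"stats"`;
#' otherwise the supplied statistics are applied. A constant channel is
#' guarded by an SD floor of `1e-8`.
#'
#' @param x Samples x channels matrix of strictly positive Rd values.
#' @param stats Optional list with `mean` and `sd` per channel.
#' @return Normalized matrix; when fitted, with attribute `"stats"`.
#' @export
logNormalize <- function(x, stats = NULL) {
  x <- as.matrix(x)
  if (any(x <= 0))
    stop("reflectance must be strictly positive for log-normalization")
  lx <- log(x)
  fitted <- is.null(stats)
  if (fitted) {
    m <- colMeans(lx)
    s <- pmax(apply(lx, 2, sd), 1e-8)
    stats <- list(mean = m, sd = s)
  }
  out <- sweep(sweep(lx, 2, stats$mean, "-"), 2, stats$sd, "/")
  if (fitted) attr(out, "stats") <- stats
  out
}

.mlpInit <- function(widths, seed) {
  .withSeed(seed, {
    lapply(seq_len(length(widths) - 1L), function(l) {
      fanin <- widths[l]
      lim <- 1 / sqrt(fanin)
      list(W = matrix(runif(fanin * widths[l + 1L], -lim, lim),
        nrow = fanin), b = numeric(widths[l + 1L]))
    })
  })
}

.mlpForward <- function(weights, X) {
  acts <- vector("list", length(weights) + 1L)
  acts[[1L]] <- X
  nl <- length(weights)
  for (l in seq_len(nl)) {
    Z <- acts[[l]] %*% weights[[l]]$W
    Z <- Z + rep(weights[[l]]$b, each = nrow(Z))
    acts[[l + 1L]] <- if (l < nl) pmax(Z, 0) else Z
  }
  acts
}

#' Train the neural-network inverse model
#'
#' Fits a fully connected network (default three hidden layers of 20
#' rectified-linear nodes, linear two-node output) that maps log-normalized
#' reflectance vectors to water and lipid volume fractions. Training uses
#' the Adam optimizer (learning rate 0.001) on the mean squared error of
#' the fraction-scaled (0-1) labels, in shuffled mini-batches. With
#' `earlyStop = TRUE`, training halts once the mean loss over the previous
#' 200 epochs is no longer decreasing (compared with the 200 epochs before
#' those).
#'
#' Labels are trained in fraction units so the converged loss magnitudes
#' are comparable across runs; predictions are reported in percent.
#'
#' @param trainSet A [ReflectanceSet-class].
#' @param hidden Hidden-layer widths.
#' @param epochs Maximum epochs (>= 1).
#' @param batchSize Mini-batch size.
#' @param lr Adam learning rate.
#' @param earlyStop Apply the 200-epoch moving-average stopping rule.
#' @param window Width of the moving-average window (epochs).
#' @param seed Seed for weight initialization and batch shuffling.
#' @param assay Which assay to train on: `"reflectance"` (noise-added) or
#'   `"noiseless"`.
#' @param labels Composition columns used as outputs (percent).
#' @return An [InverseModel-class]; its `training` slot holds the
#'   [TrainingReport][InverseModel-class] (per-epoch loss trace in
#'   fraction^2 units, epochs run, stopping reason, seed).
#' @seealso [predictFractions()], [evaluateRecovery()]
#' @export
trainInverseModel <- function(trainSet, hidden = c(20, 20, 20),
    epochs = 2000, batchSize = 256, lr = 1e-3, earlyStop = TRUE,
    window = 200, seed = 1, assay = "reflectance",
    labels = c("water", "lipid")) {
  stopifnot(is(trainSet, "ReflectanceSet"), epochs >= 1)
  X <- reflectanceMatrix(trainSet, assay)
  Xn <- logNormalize(X)
  stats <- attr(Xn, "stats")
  attr(Xn, "stats") <- NULL
  Y <- as.matrix(compositions(trainSet)[, labels, drop = FALSE]) / 100
  n <- nrow(Xn)
  widths <- c(ncol(Xn), hidden, ncol(Y))
  weights <- .mlpInit(widths, seed)
  nl <- length(weights)
  mW <- lapply(weights, function(w) w$W * 0)
  vW <- mW
  mB <- lapply(weights, function(w) w$b * 0)
  vB <- mB
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  lossTrace <- numeric(epochs)
  step <- 0L
  reason <- "max_epochs"
  .withSeed(seed + 1L, {
    for (epoch in seq_len(epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = batchSize)
      epochLoss <- 0
      for (s in starts) {
        idx <- ord[s:min(s + batchSize - 1L, n)]
        Xb <- Xn[idx, , drop = FALSE]
        Yb <- Y[idx, , drop = FALSE]
        nb <- length(idx)
        acts <- .mlpForward(weights, Xb)
        pred <- acts[[nl + 1L]]
        resid <- pred - Yb
        epochLoss <- epochLoss + sum(resid^2)
        delta <- resid / (nb * ncol(Y))
        step <- step + 1L
        c1 <- 1 - beta1^step
        c2 <- 1 - beta2^step
        for (l in rev(seq_len(nl))) {
          gW <- crossprod(acts[[l]], delta)
          gB <- colSums(delta)
          if (l > 1L)
            delta <- (delta %*% t(weights[[l]]$W)) * (acts[[l]] > 0)
          mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
          vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
          weights[[l]]$W <- weights[[l]]$W -
            lr * (mW[[l]] / c1) / (sqrt(vW[[l]] / c2) + eps)
          mB[[l]] <- beta1 * mB[[l]] + (1 - beta1) * gB
          vB[[l]] <- beta2 * vB[[l]] + (1 - beta2) * gB^2
          weights[[l]]$b <- weights[[l]]$b -
            lr * (mB[[l]] / c1) / (sqrt(vB[[l]] / c2) + eps)
        }
      }
      lossTrace[epoch] <- epochLoss / (n * ncol(Y))
      if (!is.finite(lossTrace[epoch]))
        stop("training diverged: non-finite loss at epoch ", epoch,
          " (lr = ", lr, ", batchSize = ", batchSize, ")")
      if (earlyStop && epoch >= 2L * window) {
        recent <- mean(lossTrace[(epoch - window + 1L):epoch])
        previous <- mean(lossTrace[(epoch - 2L * window + 1L):
          (epoch - window)])
        if (recent >= previous) {
          reason <- "early_stop"
          lossTrace <- lossTrace[seq_len(epoch)]
          break
        }
      }
      if (epoch == epochs) lossTrace <- lossTrace[seq_len(epochs)]
    }
  })
  new("InverseModel", weights = weights, normStats = stats,
    channels = channels(trainSet),
    training = list(loss = lossTrace, epochs = length(lossTrace),
      reason = reason, seed = seed, lr = lr, batchSize = batchSize,
      hidden = hidden, labels = labels, assay = assay))
}

setMethod("show", "InverseModel", function(object) {
  widths <- c(nrow(object@weights[[1L]]$W),
    vapply(object@weights, function(w) ncol(w$W), integer(1L)))
  tr <- object@training
  cat("InverseModel:", paste(widths, collapse = "-"),
    "(ReLU hidden, linear output)\n")
  cat(sprintf("  trained %d epochs (%s), final loss %.3g (fraction^2)\n",
    tr$epochs, tr$reason, tr$loss[length(tr$loss)]))
})

#' Predict water and lipid fractions
#'
#' Applies the stored log-normalization and network weights to reflectance
#' vectors. Predictions are deterministic, reported in percent, and not
#' clamped: out-of-[0, 100] estimates are returned as-is. A
#' [ReflectanceSet-class] input must carry the same channel ordering the
#' model was trained on; a matrix input must have the model's input width.
#'
#' @param model An [InverseModel-class].
#' @param x Samples x channels matrix of raw (not yet log-normalized) Rd
#'   values, or a [ReflectanceSet-class].
#' @param ... For the `ReflectanceSet` method, `assay` selects the assay
#'   (default `"reflectance"`).
#' @return Samples x outputs matrix in percent (columns named after the
#'   training labels).
#' @export
setMethod("predictFractions", signature(model = "InverseModel", x = "matrix"),
  function(model, x, ...) {
    if (ncol(x) != nrow(model@channels))
      stop("input width ", ncol(x), " does not match the model's ",
        nrow(model@channels), " channels")
    Xn <- logNormalize(x, model@normStats)
    pred <- .mlpForward(model@weights, Xn)[[length(model@weights) + 1L]]
    colnames(pred) <- model@training$labels
    pred * 100
  })

#' @rdname predictFractions
#' @export
setMethod("predictFractions",
  signature(model = "InverseModel", x = "ReflectanceSet"),
  function(model, x, ..., assay = "reflectance") {
    chs <- channels(x)
    if (!isTRUE(all.equal(chs[c("wavelength_nm", "separation_mm")],
        model@channels[c("wavelength_nm", "separation_mm")],
        check.attributes = FALSE)))
      stop("channel ordering of the dataset differs from the model's ",
        "training channels; refusing to predict")
    predictFractions(model, reflectanceMatrix(x, assay))
  })

#' Recovery-error statistics on a labeled test set
#'
#' Predicts every sample of a labeled [ReflectanceSet-class] and summarizes
#' the recovery error, defined as estimated minus true, in percent.
#'
#' @param model An [InverseModel-class].
#' @param testSet A [ReflectanceSet-class].
#' @param assay Assay to evaluate on (default the noise-added
#'   `"reflectance"`).
#' @return A `RecoveryReport`: list with `errors` (per-sample data.frame of
#'   estimated - true, percent), `stats` (per-quantity mean and SD), and
#'   `n`.
#' @export
evaluateRecovery <- function(model, testSet, assay = "reflectance") {
  pred <- predictFractions(model, testSet, assay = assay)
  labs <- model@training$labels
  truth <- as.matrix(compositions(testSet)[, labs, drop = FALSE])
  err <- as.data.frame(pred - truth)
  stats <- data.frame(quantity = labs,
    mean = vapply(err, mean, numeric(1L)),
    sd = vapply(err, sd, numeric(1L)), row.names = NULL)
  structure(list(errors = err, stats = stats, n = nrow(err)),
    class = "RecoveryReport")
}

#' @export
print.RecoveryReport <- function(x, ...) {
  cat("RecoveryReport over", x$n, "samples (estimated - true, %):\n")
  for (i in seq_len(nrow(x$stats)))
    cat(sprintf("  %-6s %+6.2f %% +/- %5.2f %%\n", x$stats$quantity[i],
      x$stats$mean[i], x$stats$sd[i]))
  invisible(x)
}

#' Save or load an inverse model
#'
#' Stores architecture, weights, normalization statistics, channel
#' ordering and training metadata in one file; the round trip preserves
#' predictions bit-exactly.
#'
#' @param model An [InverseModel-class].
#' @param file Path to write to or read from.
#' @return `readInverseModel()` returns the model; `saveInverseModel()`
#'   returns `file` invisibly.
#' @export
saveInverseModel <- function(model, file) {
  stopifnot(is(model, "InverseModel"))
  saveRDS(model, file)
  invisible(file)
}

#' @rdname saveInverseModel
#' @export
readInverseModel <- function(file) {
  m <- readRDS(file)
  if (!is(m, "InverseModel")) stop("file does not contain an InverseModel")
  validObject(m)
  m
}
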