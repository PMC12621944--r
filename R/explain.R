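#' @include AllClasses.R cnn.R
NULL

#' Grad-CAM attribution map
#'
#' Gradient-weighted class activation mapping: the gradient of the target
#' class's pre-softmax score with respect to the last convolutional
#' layer's activations is spatially averaged into per-channel weights; the
#' weighted activation sum is rectified, bilinearly upsampled to the input
#' resolution and min-max normalised to \[0, 1\]. The model is a pure
#' observer here - its weights and predictions are untouched.
#'
#' @param model a trained [CNNClassifier-class].
#' @param image a [MelImage-class] (or side x side x channels array).
#' @param targetClass `"HC"`, `"ScZ"`, or `NULL` (default) for the
#'   predicted class.
#' @param pixelScale divide pixels by 255 as during training.
#' @return list with `map` (side x side numeric matrix in \[0, 1\]),
#'   `targetClass`, `probs`, and `method = "gradcam"`. A map that is
#'   all-zero (zero gradient everywhere) is returned as such with a
#'   warning.
#' @export
gradCAM <- function(model, image, targetClass = NULL, pixelScale = TRUE) {
  stopifnot(is(model, "CNNClassifier"))
  arr <- .imageArray(image, model@config,
                     scale = if (pixelScale) 1 / 255 else 1)
  if (dim(arr)[4] != 1L) stop("gradCAM explains one image at a time")
  probs <- .cnn_predict(model@weights, as.numeric(arr),
                        model@config$inputSize,
                        model@config$inputChannels, 1L)[1, ]
  names(probs) <- model@classes
  if (is.null(targetClass))
    targetClass <- model@classes[which.max(probs)]
  cls <- match(targetClass, model@classes)
  if (is.na(cls)) stop(sprintf("unknown target class '%s'", targetClass))
  res <- .cnn_gradcam(model@weights, as.numeric(arr),
                      model@config$inputSize, model@config$inputChannels,
                      cls - 1L)
  cam <- res$cam
  side <- model@config$inputSize
  up <- EBImage::imageData(EBImage::resize(EBImage::Image(cam), w = side,
                                           h = side, filter = "bilinear"))
  rng <- range(up)
  if (rng[2] <= rng[1]) {
    if (rng[2] == 0)
      warning("Grad-CAM gradient is zero everywhere; returning an all-zero map")
    map <- matrix(0, side, side)
  } else {
    map <- (up - rng[1]) / (rng[2] - rng[1])
  }
  list(map = map, targetClass = targetClass, probs = probs,
       method = "gradcam")
}

# Fixed grid superpixelisation: side x side label matrix, labels 1..n^2 in
# row-major blocks.
.gridSuperpixels <- function(side, nPerAxis) {
  cell <- side / nPerAxis
  row <- pmin(nPerAxis, floor((seq_len(side) - 1) / cell) + 1)
  outer(row, row, function(r, c) (r - 1) * nPerAxis + c)
}

#' LIME-style superpixel explanation
#'
#' Approximates the classifier locally with an interpretable linear model:
#' the image is partitioned into superpixels (a fixed grid by default);
#' random on/off masks are sampled; masked-off superpixels are replaced by
#' the image's per-channel mean; the model's ScZ/HC probabilities for the
#' perturbed images are fit by ridge regression weighted with an
#' exponential kernel on the cosine distance between each mask and the
#' unperturbed mask. Positive-weight superpixels (P1, P2, ...) push the
#' prediction towards the target class, negative ones (N1, N2, ...) away
#' from it.
#'
#' @param model a trained [CNNClassifier-class], or a function mapping a
#'   side x side x channels x n array (0--255 scale) to a numeric vector
#'   or 2-column matrix of target-class probabilities (useful for
#'   surrogate ground-truth checks).
#' @param image a [MelImage-class] or pixel array.
#' @param nSuperpixels number of superpixels; must be a perfect square for
#'   the grid segmentation. Default 64 (an 8 x 8 grid).
#' @param nPerturbations number of sampled masks (>= nSuperpixels).
#'   Default 1000.
#' @param targetClass class being explained; default the model's
#'   prediction on the unperturbed image.
#' @param kernelWidth width of the exponential proximity kernel. Default
#'   0.25.
#' @param ridgeLambda ridge penalty. Default 0.01.
#' @param seed mask-sampling seed; fixed seed, fixed explanation.
#' @param config image geometry when `model` is a plain function;
#'   ignored otherwise.
#' @return list with `labelMap` (side x side superpixel labels),
#'   `weights` (one per superpixel), `positive` and `negative` (superpixel
#'   indices ranked by |weight|), `targetClass`, `r2` (weighted fit
#'   quality of the surrogate), and `method = "lime"`.
#' @export
limeExplain <- function(model, image, nSuperpixels = 64L,
                        nPerturbations = 1000L, targetClass = NULL,
                        kernelWidth = 0.25, ridgeLambda = 0.01,
                        seed = 42L, config = NULL) {
  if (is(model, "CNNClassifier")) {
    config <- model@config
    predictFun <- function(arr) predictProba(model, arr)[, , drop = FALSE]
  } else if (is.function(model)) {
    if (is.null(config)) stop("'config' is required when 'model' is a function")
    predictFun <- function(arr) model(arr)
  } else stop("'model' must be a CNNClassifier or a prediction function")
  nPerAxis <- round(sqrt(nSuperpixels))
  if (nPerAxis^2 != nSuperpixels || nSuperpixels < 2)
    stop("'nSuperpixels' must be a perfect square >= 4 for grid segmentation")
  if (nPerturbations < nSuperpixels)
    stop("'nPerturbations' must be >= 'nSuperpixels'")
  side <- config$inputSize
  px <- if (is(image, "MelImage")) imagePixels(image) else image
  stopifnot(all(dim(px)[1:2] == side))
  labelMap <- .gridSuperpixels(side, nPerAxis)
  nC <- config$inputChannels
  chanMean <- vapply(seq_len(nC), function(k) mean(px[, , k]), 0)

  probsOf <- function(arr) {
    p <- predictFun(arr)
    if (is.matrix(p)) p else matrix(p, ncol = 1)
  }
  base <- probsOf(array(px, dim = c(side, side, nC, 1)))
  if (is.null(targetClass)) {
    targetClass <- if (ncol(base) >= 2)
      .CLASS_LABELS[which.max(base[1, ])] else "ScZ"
  }
  targetCol <- if (ncol(base) >= 2) match(targetClass, .CLASS_LABELS) else 1L

  .withSeed(seed, {
    masks <- matrix(stats::runif(nPerturbations * nSuperpixels) < 0.5,
                    nrow = nPerturbations)
    masks[1, ] <- TRUE  # include the unperturbed instance
    batch <- array(0, dim = c(side, side, nC, nPerturbations))
    for (i in seq_len(nPerturbations)) {
      im <- px
      off <- which(!masks[i, ])
      if (length(off)) {
        hit <- labelMap %in% off
        for (k in seq_len(nC)) {
          ch <- im[, , k]
          ch[hit] <- chanMean[k]
          im[, , k] <- ch
        }
      }
      batch[, , , i] <- im
    }
    y <- probsOf(batch)[, targetCol]
    # exponential kernel on cosine distance to the all-on mask
    on <- rowSums(masks)
    cosSim <- on / sqrt(nSuperpixels * pmax(on, 1))
    w <- exp(-(1 - cosSim)^2 / kernelWidth^2)
    X <- cbind(1, masks * 1)
    XtW <- t(X * w)
    A <- XtW %*% X + diag(c(0, rep(ridgeLambda, nSuperpixels)))
    beta <- tryCatch(solve(A, XtW %*% y), error = function(e) NULL)
    if (is.null(beta) || stats::var(y) < 1e-12) {
      if (!is.null(beta) && stats::var(y) < 1e-12)
        warning("model output is constant under perturbation; all weights ~ 0")
      weights <- rep(0, nSuperpixels)
      fitted <- rep(mean(y), length(y))
    } else {
      weights <- as.numeric(beta[-1])
      fitted <- as.numeric(X %*% beta)
    }
    ybar <- sum(w * y) / sum(w)
    ssTot <- sum(w * (y - ybar)^2)
    r2 <- if (ssTot > 0) 1 - sum(w * (y - fitted)^2) / ssTot else NA_real_
    pos <- which(weights > 0)
    neg <- which(weights < 0)
    list(labelMap = labelMap,
         weights = weights,
         positive = pos[order(-abs(weights[pos]))],
         negative = neg[order(-abs(weights[neg]))],
         targetClass = targetClass,
         r2 = r2,
         method = "lime")
  })
}

#' Blend an attribution map over its image
#'
#' Utility for inspection: alpha-blends a \[0, 1\] attribution map (as
#' red intensity) over the grayscale version of the image.
#'
#' @param image a [MelImage-class].
#' @param map side x side matrix in \[0, 1\] (e.g. from [gradCAM()]).
#' @param alpha blend weight of the heatmap. Default 0.5.
#' @return side x side x 3 numeric array in \[0, 1\].
#' @export
overlayMap <- function(image, map, alpha = 0.5) {
  px <- imagePixels(image) / 255
  gray <- (px[, , 1] + px[, , 2] + px[, , 3]) / 3
  out <- array(0, dim = dim(px))
  out[, , 1] <- (1 - alpha) * gray + alpha * map
  out[, , 2] <- (1 - alpha) * gray
  out[, , 3] <- (1 - alpha) * gray
  out
}
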