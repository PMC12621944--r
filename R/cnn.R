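#' @include AllClasses.R
NULL

#' Convolutional network configuration
#'
#' Describes the classifier architecture: four convolutional blocks, each
#' with 32 3x3 filters (stride 1, 'same' padding, ReLU) followed by 2x2
#' max pooling with stride 2; dropout 0.25 after blocks 2 and 4; a
#' 256-unit dense ReLU layer with dropout 0.5; and a 2-class softmax
#' output. At the default 224x224x3 input the four poolings shrink the
#' feature maps 224 -> 112 -> 56 -> 28 -> 14 and the network has
#' 1,635,042 trainable parameters. The input side must be divisible by 16
#' so every pooling halves an even size.
#'
#' @param inputSize input image side in pixels (divisible by 16).
#' @param inputChannels image channels. Default 3 (RGB).
#' @param nFilters filters per convolutional layer. Default 32.
#' @param denseUnits units of the dense layer. Default 256.
#' @param nClasses output classes. Default 2.
#' @return named list describing the architecture.
#' @seealso [deskConfig()] for the reduced profile, [buildModel()],
#'   [countParams()]
#' @export
cnnConfig <- function(inputSize = 224L, inputChannels = 3L, nFilters = 32L,
                      denseUnits = 256L, nClasses = 2L) {
  inputSize <- as.integer(inputSize)
  if (inputSize %% 16L != 0L || inputSize < 16L)
    stop("'inputSize' must be a positive multiple of 16")
  list(inputSize = inputSize, inputChannels = as.integer(inputChannels),
       nConvBlocks = 4L, nFilters = as.integer(nFilters),
       kernel = 3L, poolSize = 2L,
       dropoutConv = 0.25, dropoutDense = 0.5,
       denseUnits = as.integer(denseUnits), nClasses = as.integer(nClasses))
}

#' Reduced "desk" configuration
#'
#' The same architecture on 64x64 inputs; the dense layer size is derived
#' from the resulting flatten length. Intended for quick experiments and
#' continuous testing where the full 224x224 profile would be wasteful.
#'
#' @param inputSize input side. Default 64.
#' @param ... forwarded to [cnnConfig()].
#' @return a configuration list.
#' @export
deskConfig <- function(inputSize = 64L, ...) {
  cnnConfig(inputSize = inputSize, ...)
}

#' Trainable parameter count of a configuration
#'
#' Computed analytically from the layer stack: each conv layer has
#' `filters * (9 * inChannels + 1)` parameters, the dense layer
#' `(flatten + 1) * units`, the output `(units + 1) * classes`.
#'
#' @param config a [cnnConfig()] list or a [CNNClassifier-class].
#' @return integer parameter count (1,635,042 at the defaults).
#' @examples
#' countParams(cnnConfig())
#' @export
countParams <- function(config) {
  if (is(config, "CNNClassifier")) config <- config@config
  fm <- config$inputSize %/% 2L^config$nConvBlocks
  flat <- fm * fm * config$nFilters
  convIn <- c(config$inputChannels,
              rep(config$nFilters, config$nConvBlocks - 1L))
  conv <- sum(config$nFilters * (9L * convIn + 1L))
  dense <- (flat + 1L) * config$denseUnits
  out <- (config$denseUnits + 1L) * config$nClasses
  as.integer(conv + dense + out)
}

#' Layer output shapes of a configuration
#'
#' @param config a [cnnConfig()] list.
#' @return data frame of layer names and output height/width/depth.
#' @examples
#' layerShapes(cnnConfig())  # feature map after block 4: 14 x 14 x 32
#' @export
layerShapes <- function(config) {
  s <- config$inputSize
  rows <- list(data.frame(layer = "input", height = s, width = s,
                          depth = config$inputChannels))
  for (b in seq_len(config$nConvBlocks)) {
    rows <- c(rows, list(data.frame(layer = sprintf("conv%d", b), height = s,
                                    width = s, depth = config$nFilters)))
    s <- s %/% 2L
    rows <- c(rows, list(data.frame(layer = sprintf("pool%d", b), height = s,
                                    width = s, depth = config$nFilters)))
  }
  flat <- s * s * config$nFilters
  rows <- c(rows,
            list(data.frame(layer = "flatten", height = 1L, width = 1L,
                            depth = flat),
                 data.frame(layer = "dense", height = 1L, width = 1L,
                            depth = config$denseUnits),
                 data.frame(layer = "output", height = 1L, width = 1L,
                            depth = config$nClasses)))
  do.call(rbind, rows)
}

#' Build an (untrained) classifier
#'
#' Instantiates the network with Glorot-uniform weights and zero biases
#' from a seeded generator. The softmax class order is `c("HC", "ScZ")`.
#'
#' @param config a [cnnConfig()] list.
#' @param seed weight-initialisation seed. Default 42.
#' @return an untrained [CNNClassifier-class].
#' @examples
#' model <- buildModel(deskConfig(inputSize = 16), seed = 1)
#' model
#' @export
buildModel <- function(config = cnnConfig(), seed = 42L) {
  weights <- .cnn_init(config$inputSize, config$inputChannels,
                       config$nFilters, config$denseUnits, config$nClasses,
                       as.integer(seed))
  new("CNNClassifier", config = config, weights = weights,
      classes = .CLASS_LABELS,
      history = data.frame(epoch = integer(), loss = numeric(),
                           accuracy = numeric()),
      trained = FALSE)
}

# Stack MelImage objects (or raw arrays) into a side x side x C x N double
# array scaled by `scale`.
.imageArray <- function(images, config, scale = 1 / 255) {
  if (is(images, "MelImage")) images <- list(images)
  if (is.array(images) && length(dim(images)) == 3L)
    images <- list(images)
  if (is.array(images) && length(dim(images)) == 4L) {
    arr <- images
  } else {
    stopifnot(is.list(images), length(images) >= 1L)
    s <- config$inputSize
    arr <- array(0, dim = c(s, s, config$inputChannels, length(images)))
    for (i in seq_along(images)) {
      px <- if (is(images[[i]], "MelImage")) imagePixels(images[[i]])
            else images[[i]]
      if (!all(dim(px) == c(s, s, config$inputChannels)))
        stop(sprintf("image %d has shape %s, expected %dx%dx%d", i,
                     paste(dim(px), collapse = "x"), s, s,
                     config$inputChannels))
      arr[, , , i] <- px
    }
  }
  arr * scale
}

.labelIndex <- function(labels) {
  labels <- as.character(labels)
  if (!all(labels %in% .CLASS_LABELS))
    stop(sprintf("unknown label(s): %s",
                 paste(setdiff(labels, .CLASS_LABELS), collapse = ", ")))
  match(labels, .CLASS_LABELS) - 1L
}

#' Train the classifier
#'
#' Adam on categorical cross-entropy with one-hot targets in class order
#' (HC, ScZ). Pixel values are scaled by 1/255 before fitting (disable
#' with `pixelScale = FALSE` when images are pre-scaled). Training is
#' deterministic given the seed: initialisation, shuffling and dropout all
#' derive from it.
#'
#' @param model a [CNNClassifier-class] from [buildModel()].
#' @param images list of [MelImage-class] (or a side x side x C x N array).
#' @param labels character vector of `"HC"`/`"ScZ"`, one per image.
#' @param epochs training epochs. Default 100.
#' @param batchSize minibatch size. Default 32.
#' @param lr,beta1,beta2,adamEps Adam hyperparameters (library defaults
#'   0.001, 0.9, 0.999, 1e-7).
#' @param seed training seed (shuffling and dropout). Default 42.
#' @param pixelScale divide pixel values by 255 before fitting.
#' @return the fitted [CNNClassifier-class] with its per-epoch history.
#' @export
trainModel <- function(model, images, labels, epochs = 100L,
                       batchSize = 32L, lr = 1e-3, beta1 = 0.9,
                       beta2 = 0.999, adamEps = 1e-7, seed = 42L,
                       pixelScale = TRUE) {
  stopifnot(is(model, "CNNClassifier"))
  if (epochs < 1L || batchSize < 1L)
    stop("'epochs' and 'batchSize' must be >= 1")
  y <- .labelIndex(labels)
  if (length(unique(y)) < 2L)
    stop("training data must contain both classes; the loss is degenerate otherwise")
  arr <- .imageArray(images, model@config,
                     scale = if (pixelScale) 1 / 255 else 1)
  if (dim(arr)[4] != length(y))
    stop("number of images and labels differ")
  fit <- .cnn_train(model@weights, as.numeric(arr), y,
                    model@config$inputSize, model@config$inputChannels,
                    as.integer(epochs), as.integer(batchSize), lr, beta1,
                    beta2, adamEps, as.integer(seed))
  model@weights <- fit$weights
  model@history <- data.frame(epoch = seq_len(epochs), loss = fit$loss,
                              accuracy = fit$accuracy)
  model@trained <- TRUE
  model
}

#' Class probabilities for images
#'
#' Softmax probabilities in class order (HC, ScZ); rows sum to 1. The
#' predicted label is the argmax; an exact 0.5/0.5 tie resolves to ScZ
#' (the positive class).
#'
#' @param model a trained [CNNClassifier-class].
#' @param images list of [MelImage-class] or a 4-d array.
#' @param pixelScale divide pixel values by 255 (as during training).
#' @return numeric matrix, one row per image, columns `HC` and `ScZ`, with
#'   attribute `"predicted"` holding the label vector.
#' @export
predictProba <- function(model, images, pixelScale = TRUE) {
  stopifnot(is(model, "CNNClassifier"))
  arr <- .imageArray(images, model@config,
                     scale = if (pixelScale) 1 / 255 else 1)
  n <- dim(arr)[4]
  p <- .cnn_predict(model@weights, as.numeric(arr),
                    model@config$inputSize, model@config$inputChannels, n)
  colnames(p) <- model@classes
  pred <- ifelse(p[, "ScZ"] >= p[, "HC"], "ScZ", "HC")
  attr(p, "predicted") <- pred
  p
}

#' Predicted class labels
#'
#' @inheritParams predictProba
#' @return character vector of `"HC"`/`"ScZ"`.
#' @export
predictLabel <- function(model, images, pixelScale = TRUE) {
  attr(predictProba(model, images, pixelScale), "predicted")
}
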