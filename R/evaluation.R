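#' @include AllClasses.R cnn.R melspec.R montage.R preprocess.R
NULL

#' Cross-validation fold assignment
#'
#' Partitions items into `k` test folds. With `stratified = TRUE` the
#' class ratio of every test fold matches the overall ratio to within one
#' item. With `unit = "subject"` whole subjects are assigned to folds, so
#' no subject contributes segments to both the training and test side of
#' any fold (the split that supports honest generalisation claims);
#' `unit = "segment"` splits at the item level.
#'
#' @param labels character class labels, one per item.
#' @param k number of folds. Default 10.
#' @param stratified preserve class ratio per fold. Default TRUE.
#' @param unit `"segment"` (default) or `"subject"`.
#' @param subjectIds required when `unit = "subject"`.
#' @param seed shuffling seed. Default 42.
#' @return list of `k` elements, each `list(train =, test =)` integer
#'   index vectors; the test sets partition `seq_along(labels)`.
#' @examples
#' f <- makeFolds(rep(c("HC", "ScZ"), each = 50), k = 10, seed = 1)
#' lengths(lapply(f, `[[`, "test"))
#' @export
makeFolds <- function(labels, k = 10L, stratified = TRUE,
                      unit = c("segment", "subject"), subjectIds = NULL,
                      seed = 42L) {
  unit <- match.arg(unit)
  labels <- as.character(labels)
  n <- length(labels)
  if (k < 2L) stop("'k' must be >= 2")
  .withSeed(seed, {
    if (unit == "subject") {
      if (is.null(subjectIds) || length(subjectIds) != n)
        stop("'subjectIds' (one per item) is required for unit = \"subject\"")
      subj <- unique(subjectIds)
      subjLabel <- labels[match(subj, subjectIds)]
      foldOfSubj <- .assignFolds(subjLabel, k, stratified)
      foldOf <- unname(foldOfSubj[match(subjectIds, subj)])
    } else {
      foldOf <- .assignFolds(labels, k, stratified)
    }
    lapply(seq_len(k), function(f)
      list(train = which(foldOf != f), test = which(foldOf == f)))
  })
}

# Round-robin fold assignment of shuffled items, per class when stratified.
.assignFolds <- function(labels, k, stratified) {
  n <- length(labels)
  foldOf <- integer(n)
  groups <- if (stratified) split(seq_len(n), labels) else list(seq_len(n))
  for (g in groups) {
    if (length(g) < k)
      stop(sprintf("a class has only %d unit(s) but k = %d folds were requested",
                   length(g), k))
    g <- sample(g)
    foldOf[g] <- rep_len(seq_len(k), length(g))
  }
  foldOf
}

#' Confusion-matrix metrics (percent)
#'
#' With ScZ as the positive class: sensitivity TP/(TP+FN), specificity
#' TN/(TN+FP), precision TP/(TP+FP), accuracy (TP+TN)/n, F1 the harmonic
#' mean of precision and sensitivity, and false positive rate FP/(FP+TN),
#' all on the 0--100 percent scale. A zero denominator yields `NaN` with a
#' warning, never a silent 0. Note the identity FPR = 100 - specificity.
#'
#' @param yTrue,yPred character vectors of `"HC"`/`"ScZ"`, equal length.
#' @return named numeric: sensitivity, specificity, precision, accuracy,
#'   f1, fpr; with attribute `"counts"` (TP, FP, TN, FN).
#' @examples
#' truth <- rep(c("ScZ", "HC"), c(50, 50))
#' pred <- c(rep("ScZ", 50), rep("HC", 40), rep("ScZ", 10))
#' confusionMetrics(truth, pred)
#' @export
confusionMetrics <- function(yTrue, yPred) {
  yTrue <- as.character(yTrue); yPred <- as.character(yPred)
  if (length(yTrue) != length(yPred))
    stop("'yTrue' and 'yPred' must have equal length")
  bad <- setdiff(unique(c(yTrue, yPred)), .CLASS_LABELS)
  if (length(bad))
    stop(sprintf("unknown label(s): %s", paste(bad, collapse = ", ")))
  tp <- sum(yTrue == "ScZ" & yPred == "ScZ")
  fn <- sum(yTrue == "ScZ" & yPred == "HC")
  tn <- sum(yTrue == "HC" & yPred == "HC")
  fp <- sum(yTrue == "HC" & yPred == "ScZ")
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s is undefined (zero denominator)", what))
      return(NaN)
    }
    100 * num / den
  }
  sen <- ratio(tp, tp + fn, "sensitivity")
  spe <- ratio(tn, tn + fp, "specificity")
  pre <- ratio(tp, tp + fp, "precision")
  acc <- ratio(tp + tn, tp + fn + tn + fp, "accuracy")
  f1 <- if (is.finite(pre) && is.finite(sen) && pre + sen > 0)
    2 * pre * sen / (pre + sen) else NaN
  fpr <- ratio(fp, fp + tn, "false positive rate")
  out <- c(sensitivity = sen, specificity = spe, precision = pre,
           accuracy = acc, f1 = f1, fpr = fpr)
  attr(out, "counts") <- c(TP = tp, FP = fp, TN = tn, FN = fn)
  out
}

#' ROC curve and AUC
#'
#' Sweeps the decision threshold over the unique scores (probability of
#' ScZ); an item is called positive when its score is >= the threshold.
#' The returned curve runs from (0, 0) to (1, 1) and the AUC is computed
#' by the trapezoid rule.
#'
#' @param yTrue character labels (`"HC"`/`"ScZ"`), both classes present.
#' @param scores numeric ScZ probabilities/scores, one per item.
#' @return data frame with columns `threshold`, `fpr`, `tpr`, carrying the
#'   AUC in attribute `"auc"`.
#' @examples
#' r <- rocPoints(c("HC", "HC", "ScZ", "ScZ"), c(.1, .4, .35, .8))
#' attr(r, "auc")
#' @export
rocPoints <- function(yTrue, scores) {
  yTrue <- as.character(yTrue)
  if (length(yTrue) != length(scores))
    stop("'yTrue' and 'scores' must have equal length")
  pos <- yTrue == "ScZ"
  nP <- sum(pos); nN <- sum(!pos)
  if (nP == 0L || nN == 0L)
    stop("ROC needs both classes present in 'yTrue'")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & pos) / nP, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & !pos) / nN, 0)
  out <- data.frame(threshold = c(Inf, thr, -Inf),
                    fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
  auc <- sum(diff(out$fpr) * (head(out$tpr, -1) + out$tpr[-1]) / 2)
  attr(out, "auc") <- auc
  out
}

.foldReport <- function(foldIndex, yTrue, yPred, scores) {
  m <- confusionMetrics(yTrue, yPred)
  roc <- rocPoints(yTrue, scores)
  new("FoldReport", foldIndex = as.integer(foldIndex),
      counts = attr(m, "counts"), metrics = c(m),
      roc = roc, auc = attr(roc, "auc"))
}

#' Aggregate fold reports into a region result
#'
#' Mean and sample standard deviation (ddof = 1, the convention for
#' k-fold summaries) of every metric over folds, plus a pooled ROC from
#' the concatenated out-of-fold scores when provided.
#'
#' @param reports list of [FoldReport-class] (k >= 2).
#' @param region region name to store.
#' @param oofLabels,oofScores optional concatenated out-of-fold labels and
#'   ScZ scores for the pooled ROC.
#' @return a [RegionResult-class].
#' @export
aggregateFolds <- function(reports, region = "region", oofLabels = NULL,
                           oofScores = NULL) {
  stopifnot(length(reports) >= 2L)
  metricNames <- names(reports[[1]]@metrics)
  mat <- t(vapply(reports, function(r) r@metrics, numeric(length(metricNames))))
  summary <- data.frame(metric = metricNames,
                        mean = colMeans(mat),
                        sd = apply(mat, 2, sd),
                        row.names = NULL)
  if (!is.null(oofLabels)) {
    roc <- rocPoints(oofLabels, oofScores)
    auc <- attr(roc, "auc")
  } else {
    roc <- data.frame(threshold = numeric(), fpr = numeric(),
                      tpr = numeric())
    auc <- NA_real_
  }
  new("RegionResult", region = as.character(region), folds = reports,
      summary = summary, pooledRoc = roc, pooledAuc = auc)
}

#' k-fold cross-validated training and evaluation
#'
#' Trains one classifier per fold on the training images and evaluates it
#' on the held-out fold; every image is scored exactly once out of fold.
#' Per-fold seeds are derived from `seed` so the whole run is reproducible.
#'
#' @param images list of [MelImage-class].
#' @param labels character labels, one per image.
#' @param config a [cnnConfig()] list sized to the images.
#' @param k folds. Default 10.
#' @param unit,stratified,subjectIds fold assignment, see [makeFolds()].
#' @param epochs,batchSize,lr training settings, see [trainModel()].
#' @param seed master seed for folds, initialisation and training.
#' @param region region name stored in the result.
#' @return a [RegionResult-class].
#' @export
crossValidate <- function(images, labels, config = cnnConfig(), k = 10L,
                          unit = "segment", stratified = TRUE,
                          subjectIds = NULL, epochs = 100L, batchSize = 32L,
                          lr = 1e-3, seed = 42L, region = "region") {
  labels <- as.character(labels)
  if (is.null(subjectIds) && length(images) &&
      is(images[[1]], "MelImage"))
    subjectIds <- vapply(images, function(im) im@subjectId, "")
  folds <- makeFolds(labels, k = k, stratified = stratified, unit = unit,
                     subjectIds = subjectIds, seed = seed)
  arr <- .imageArray(images, config)  # scale once, reuse across folds
  reports <- vector("list", k)
  oofScore <- numeric(length(labels))
  for (f in seq_len(k)) {
    tr <- folds[[f]]$train; te <- folds[[f]]$test
    model <- buildModel(config, seed = seed + 1000L * f)
    model <- trainModel(model, arr[, , , tr, drop = FALSE], labels[tr],
                        epochs = epochs, batchSize = batchSize, lr = lr,
                        seed = seed + 1000L * f + 1L, pixelScale = FALSE)
    p <- predictProba(model, arr[, , , te, drop = FALSE],
                      pixelScale = FALSE)
    oofScore[te] <- p[, "ScZ"]
    reports[[f]] <- .foldReport(f, labels[te], attr(p, "predicted"),
                                p[, "ScZ"])
  }
  aggregateFolds(reports, region = region, oofLabels = labels,
                 oofScores = oofScore)
}

#' Lobe-ablation experiment
#'
#' The full pipeline, run once per montage region: preprocess every
#' recording (band-pass, resample, segment), restrict to the region's
#' channels, render mel-spectrogram images, and evaluate the classifier
#' under k-fold cross-validation. Regions are then ranked by mean
#' accuracy, mirroring the lobe-ablation design in which the same
#' classification protocol is repeated on each lobe's channels and on the
#' full montage.
#'
#' @param cohort list of [EEGRecording-class] (e.g. [generateCohort()]).
#' @param regions regions to evaluate; any of the table's lobes and
#'   `"full"`.
#' @param table a [LobeTable-class] matching the cohort's channels.
#' @param config classifier configuration sized to `imageSize`.
#' @param k,unit,epochs,batchSize training/evaluation settings.
#' @param lowHz,highHz,order,targetHz,lengthS preprocessing settings.
#' @param stft,mel imaging settings ([stftParams()], [melParams()]).
#' @param seed master seed.
#' @param verbose print progress lines.
#' @return list with elements `results` (named list of
#'   [RegionResult-class]) and `ranking` (data frame of regions sorted by
#'   decreasing mean accuracy).
#' @export
runLobeExperiment <- function(cohort,
                              regions = c("full", "frontal", "central",
                                          "temporal", "parietal",
                                          "occipital"),
                              table = lobeTable("repod19"),
                              config = deskConfig(), k = 5L,
                              unit = "segment", epochs = 10L,
                              batchSize = 32L, lowHz = 0.5, highHz = 45,
                              order = 2L, targetHz = 256, lengthS = 3,
                              stft = stftParams(), mel = melParams(),
                              seed = 42L, verbose = FALSE) {
  stopifnot(length(cohort) >= 2L)
  pre <- lapply(cohort, function(rec) {
    rec <- bandpassFilter(rec, lowHz, highHz, order)
    resampleRecording(rec, targetHz)
  })
  results <- list()
  for (region in regions) {
    segs <- unlist(lapply(pre, function(rec)
      segmentRecording(applyMontage(rec, table, region), lengthS)),
      recursive = FALSE)
    imgs <- lapply(segs, segmentToImage, stft = stft, mel = mel,
                   size = config$inputSize, region = region)
    labels <- vapply(imgs, function(im) im@label, "")
    subj <- vapply(imgs, function(im) im@subjectId, "")
    res <- tryCatch(
      crossValidate(imgs, labels, config = config, k = k, unit = unit,
                    subjectIds = subj, epochs = epochs,
                    batchSize = batchSize, seed = seed, region = region),
      error = function(e)
        stop(sprintf("region '%s': %s", region, conditionMessage(e)),
             call. = FALSE))
    results[[region]] <- res
    if (verbose) {
      acc <- res@summary$mean[res@summary$metric == "accuracy"]
      message(sprintf("region %-9s: accuracy %.2f%%", region, acc))
    }
  }
  acc <- vapply(results, function(r)
    r@summary$mean[r@summary$metric == "accuracy"], 0)
  ranking <- data.frame(region = names(results), meanAccuracy = unname(acc))
  ranking <- ranking[order(-ranking$meanAccuracy), ]
  rownames(ranking) <- NULL
  list(results = results, ranking = ranking)
}

#' Write experiment reports to disk
#'
#' Writes a region x metric CSV of mean +/- sd values, per-region ROC
#' point CSVs, a JSON file with per-fold detail, and a plain-text ranking
#' summary.
#'
#' @param experiment result of [runLobeExperiment()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeRegionReport <- function(experiment, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  tab <- do.call(rbind, lapply(names(experiment$results), function(rg) {
    s <- experiment$results[[rg]]@summary
    data.frame(region = rg, metric = s$metric,
               mean = round(s$mean, 2), sd = round(s$sd, 2))
  }))
  p <- file.path(dir, "metrics.csv")
  write.csv(tab, p, row.names = FALSE); paths <- c(paths, p)
  for (rg in names(experiment$results)) {
    p <- file.path(dir, sprintf("roc_%s.csv", rg))
    write.csv(experiment$results[[rg]]@pooledRoc, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  detail <- lapply(experiment$results, function(r)
    list(region = r@region, pooledAuc = r@pooledAuc,
         folds = lapply(r@folds, function(fd)
           list(fold = fd@foldIndex, counts = as.list(fd@counts),
                metrics = as.list(round(fd@metrics, 4)), auc = fd@auc))))
  p <- file.path(dir, "report.json")
  jsonlite::write_json(detail, p, auto_unbox = TRUE, pretty = TRUE)
  paths <- c(paths, p)
  p <- file.path(dir, "ranking.txt")
  writeLines(sprintf("%-10s %6.2f", experiment$ranking$region,
                     experiment$ranking$meanAccuracy), p)
  paths <- c(paths, p)
  invisible(paths)
}
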