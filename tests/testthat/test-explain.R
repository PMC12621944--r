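test_that("Grad-CAM maps are normalized and leave the model untouched", {
  toy <- toyClassifier()
  img <- toy$images[[1]]
  before <- predictProba(toy$model, list(img))
  g <- gradCAM(toy$model, img)
  expect_identical(dim(g$map), c(32L, 32L))
  expect_equal(min(g$map), 0)
  expect_equal(max(g$map), 1)
  expect_true(all(is.finite(g$map)))
  after <- predictProba(toy$model, list(img))
  expect_identical(before, after)
})

test_that("Grad-CAM highlights the discriminative half of toy images", {
  toy <- toyClassifier()
  # all class information lives in the top half; the top-decile heatmap
  # mass should concentrate there for the predicted class
  fracInHalf <- vapply(seq_along(toy$images), function(i) {
    g <- gradCAM(toy$model, toy$images[[i]],
                 targetClass = toy$labels[i])
    thr <- stats::quantile(g$map, 0.9)
    hot <- g$map >= thr
    sum(hot[1:16, ]) / max(sum(hot), 1)
  }, 0)
  expect_gte(mean(fracInHalf), 0.7)
})

test_that("a zero-gradient target yields an all-zero map with a warning", {
  toy <- toyClassifier()
  dead <- toy$model
  dead@weights$Wo[, 2] <- 0   # ScZ logit no longer depends on features
  expect_warning(g <- gradCAM(dead, toy$images[[1]], targetClass = "ScZ"),
                 "zero")
  expect_true(all(g$map == 0))
})

test_that("LIME returns zero weights for a constant model", {
  constModel <- function(arr) rep(0.7, dim(arr)[4])
  img <- array(100L, dim = c(32, 32, 3))
  expect_warning(
    ex <- limeExplain(constModel, img, nSuperpixels = 16,
                      nPerturbations = 64, targetClass = "ScZ", seed = 1,
                      config = cnnConfig(32)),
    "constant")
  expect_true(all(abs(ex$weights) < 1e-6))
})

test_that("LIME recovers the signs of a known linear surrogate", {
  side <- 32; nSup <- 16
  labelMap <- lobemel:::.gridSuperpixels(side, 4)
  set.seed(17)
  coefs <- c(stats::runif(8, 0.5, 1), -stats::runif(8, 0.5, 1))[sample(16)]
  linModel <- function(arr) {
    vapply(seq_len(dim(arr)[4]), function(i) {
      means <- vapply(seq_len(nSup), function(s)
        mean(arr[, , 1, i][labelMap == s]), 0)
      stats::plogis(sum(coefs * (means / 255 - 0.5)))
    }, 0)
  }
  # alternating bright/dark superpixels so that mean-fill perturbs them;
  # masking superpixel s moves its mean from vals[s] to the image mean,
  # so the true local coefficient of mask bit s is coefs[s]*(vals[s]-mean)
  vals <- rep(c(255, 0), length.out = nSup)
  img <- array(0L, dim = c(side, side, 3))
  for (k in 1:3) { ch <- img[, , k]; ch[] <- vals[labelMap]; img[, , k] <- ch }
  ex <- limeExplain(linModel, img, nSuperpixels = nSup,
                    nPerturbations = 400, targetClass = "ScZ", seed = 2,
                    config = cnnConfig(side))
  trueLocal <- coefs * (vals - mean(vals))
  expect_identical(sign(ex$weights), sign(trueLocal))
  expect_gt(ex$r2, 0.9)
})

test_that("LIME is seed-deterministic with disjoint, sorted rankings", {
  # a lightly trained model, so perturbed probabilities actually vary
  toy <- toyImageSet(8, 32, seed = 12)
  model <- trainModel(buildModel(cnnConfig(32), seed = 12), toy$images,
                      toy$labels, epochs = 3, batchSize = 4, seed = 12)
  img <- toy$images[[1]]
  e1 <- limeExplain(model, img, nSuperpixels = 16,
                    nPerturbations = 80, seed = 5)
  e2 <- limeExplain(model, img, nSuperpixels = 16,
                    nPerturbations = 80, seed = 5)
  expect_identical(e1$weights, e2$weights)
  expect_identical(e1$positive, e2$positive)
  expect_length(intersect(e1$positive, e1$negative), 0)
  # rankings sorted by decreasing |weight| within sign groups
  expect_true(!is.unsorted(rev(abs(e1$weights[e1$positive]))))
  expect_true(!is.unsorted(rev(abs(e1$weights[e1$negative]))))
  # argument validation
  expect_error(limeExplain(model, img, nSuperpixels = 10), "square")
  expect_error(limeExplain(model, img, nSuperpixels = 16,
                           nPerturbations = 4), "nPerturbations")
})
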