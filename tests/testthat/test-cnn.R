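test_that("the default architecture matches the hand-derived arithmetic", {
  cfg <- cnnConfig()
  # 896 + 3 x 9248 + 1,605,888 + 514
  expect_identical(countParams(cfg), 1635042L)
  shapes <- layerShapes(cfg)
  pool4 <- shapes[shapes$layer == "pool4", ]
  expect_identical(c(pool4$height, pool4$width, pool4$depth), c(14L, 14L, 32L))
  expect_identical(shapes$depth[shapes$layer == "flatten"], 6272L)
  # spatial sizes halve through the four pools: 224 -> 112 -> 56 -> 28 -> 14
  expect_identical(shapes$height[grep("pool", shapes$layer)],
                   c(112L, 56L, 28L, 14L))
  # model weights agree with the analytic count
  model <- buildModel(cnnConfig(inputSize = 32), seed = 1)
  nW <- sum(vapply(model@weights, length, 0L))
  expect_identical(nW, countParams(cnnConfig(inputSize = 32)))
  expect_error(cnnConfig(inputSize = 100), "multiple of 16")
})

test_that("forward passes produce valid, repeatable probabilities", {
  model <- buildModel(cnnConfig(inputSize = 32), seed = 2)
  set.seed(5)
  imgs <- lapply(1:4, function(i)
    array(sample(0:255, 32 * 32 * 3, TRUE), dim = c(32, 32, 3)))
  p <- predictProba(model, imgs)
  expect_equal(rowSums(p), rep(1, 4), tolerance = 1e-6)
  expect_true(all(p >= 0))
  # duplicated image -> identical rows
  p2 <- predictProba(model, list(imgs[[1]], imgs[[1]]))
  expect_identical(p2[1, ], p2[2, ])
})

test_that("the network overfits a trivially separable toy set", {
  toy <- toyClassifier()
  hist <- toy$model@history
  expect_equal(tail(hist$accuracy, 1), 1.0)
  # inference reproduces the training labels
  p <- predictProba(toy$model, toy$images)
  expect_identical(unname(attr(p, "predicted")), toy$labels)
  # training loss trends down: upticks beyond dropout noise are rare
  floorNoise <- 0.05 * max(hist$loss)
  upticks <- diff(hist$loss) > pmax(0.05 * head(hist$loss, -1), floorNoise)
  expect_lte(mean(upticks), 0.05)
  expect_lt(tail(hist$loss, 1), head(hist$loss, 1))
})

test_that("shuffled labels train worse than separable ones", {
  toy <- toyImageSet(16, 32, seed = 2)
  set.seed(10)
  shuffled <- sample(toy$labels)
  mSep <- trainModel(buildModel(cnnConfig(32), seed = 3), toy$images,
                     toy$labels, epochs = 2, batchSize = 8, seed = 3)
  mShuf <- trainModel(buildModel(cnnConfig(32), seed = 3), toy$images,
                      shuffled, epochs = 2, batchSize = 8, seed = 3)
  expect_gte(tail(mShuf@history$loss, 1), tail(mSep@history$loss, 1))
})

test_that("constant images carry no signal", {
  imgs <- lapply(1:12, function(i) array(100L, dim = c(16, 16, 3)))
  labs <- rep(c("HC", "ScZ"), 6)
  m <- trainModel(buildModel(cnnConfig(16), seed = 4), imgs[1:8], labs[1:8],
                  epochs = 5, batchSize = 4, seed = 4)
  p <- predictProba(m, imgs[9:12])
  acc <- mean(attr(p, "predicted") == labs[9:12])
  expect_gte(acc, 0.35)
  expect_lte(acc, 0.65)
})

test_that("training is deterministic and single-class input errors", {
  toy <- toyImageSet(8, 16, seed = 3)
  imgs <- lapply(toy$images, function(a) a[1:16, 1:16, , drop = FALSE])
  m1 <- trainModel(buildModel(cnnConfig(16), seed = 7), imgs, toy$labels,
                   epochs = 3, batchSize = 4, seed = 7)
  m2 <- trainModel(buildModel(cnnConfig(16), seed = 7), imgs, toy$labels,
                   epochs = 3, batchSize = 4, seed = 7)
  expect_identical(m1@weights, m2@weights)
  expect_error(trainModel(buildModel(cnnConfig(16)), imgs,
                          rep("HC", length(imgs)), epochs = 1),
               "both classes")
})

test_that("pre-scaled inputs with scaling disabled train identically", {
  toy <- toyImageSet(8, 16, seed = 6)
  imgs <- lapply(toy$images, function(a) a[1:16, 1:16, , drop = FALSE])
  arr <- array(0, dim = c(16, 16, 3, 8))
  for (i in 1:8) arr[, , , i] <- imgs[[i]] / 255
  m1 <- trainModel(buildModel(cnnConfig(16), seed = 8), imgs, toy$labels,
                   epochs = 2, batchSize = 4, seed = 8, pixelScale = TRUE)
  m2 <- trainModel(buildModel(cnnConfig(16), seed = 8), arr, toy$labels,
                   epochs = 2, batchSize = 4, seed = 8, pixelScale = FALSE)
  expect_identical(m1@history$loss, m2@history$loss)
  expect_identical(m1@weights, m2@weights)
})
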