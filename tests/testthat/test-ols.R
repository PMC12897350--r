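toy_model <- function(n = 30, p = 5, idx = c(2L, 4L), seed = 31,
                      beta = c(2, -1), intercept = 0.5, noise = 0.1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p, 1, 0.5), n, p)
  sc <- fitAutoscale(X)
  Xs <- applyAutoscale(X, sc)
  y <- intercept + Xs[, idx, drop = FALSE] %*% beta + rnorm(n, sd = noise)
  list(X = X, Xs = Xs, y = as.numeric(y), sc = sc, idx = idx,
       grid = nirGrid(1100, 2, p))
}

test_that("an exact line is recovered exactly", {
  set.seed(32)
  x <- rnorm(20)
  X <- cbind(x, rnorm(20))
  sc <- fitAutoscale(X)
  Xs <- applyAutoscale(X, sc)
  y <- 2 * Xs[, 1] + 1
  m <- fitOls(Xs, y, 1L, sc, grid = nirGrid(1100, 2, 2))
  expect_equal(m@coefficients, 2)
  expect_equal(m@intercept, 1)
})

test_that("a constant response gives zero coefficients and the constant intercept", {
  t <- toy_model()
  m <- fitOls(t$Xs, rep(4.2, 30), t$idx, t$sc, grid = t$grid)
  expect_equal(m@coefficients, c(0, 0), tolerance = 1e-10)
  expect_equal(m@intercept, 4.2)
})

test_that("coefficients match the normal-equations oracle", {
  t <- toy_model(n = 30, p = 5, idx = 1:5, beta = rnorm(5), seed = 33)
  m <- fitOls(t$Xs, t$y, 1:5, t$sc, grid = t$grid)
  expect_equal(c(m@intercept, m@coefficients), oracle_ols(t$Xs, t$y),
               tolerance = 1e-8)
})

test_that("rank deficiency is reported with the offending channels", {
  set.seed(34)
  X <- matrix(rnorm(60), 20, 3)
  X[, 3] <- X[, 1]
  sc <- fitAutoscale(X)
  Xs <- applyAutoscale(X, sc)
  expect_error(fitOls(Xs, rnorm(20), c(1L, 3L), sc, grid = nirGrid(1100, 2, 3)),
               "channel\\(s\\) 3 \\(1104 nm\\)")
  expect_error(fitOls(Xs[1:3, ], rnorm(3), c(1L, 3L), sc,
                      grid = nirGrid(1100, 2, 3)), "rows")
})

test_that("prediction reproduces fitted values and ignores unselected channels", {
  t <- toy_model(seed = 35)
  m <- fitOls(t$Xs, t$y, t$idx, t$sc, grid = t$grid)
  expect_equal(predict(m, t$X),
               as.numeric(t$Xs[, t$idx] %*% m@coefficients + m@intercept),
               tolerance = 1e-8)
  # a raw spectrum equal to the training column means predicts the intercept
  expect_equal(predict(m, matrix(t$sc@means, 1)), m@intercept)
  # perturbing unselected channels leaves predictions unchanged
  Xp <- t$X
  Xp[, setdiff(1:5, t$idx)] <- Xp[, setdiff(1:5, t$idx)] + 100
  expect_equal(predict(m, Xp), predict(m, t$X))
})

test_that("training residuals are orthogonal to selected channels and sum to zero", {
  t <- toy_model(seed = 36)
  m <- fitOls(t$Xs, t$y, t$idx, t$sc, grid = t$grid)
  res <- t$y - predict(m, t$X)
  expect_lt(abs(sum(res)), 1e-8)
  expect_lt(max(abs(crossprod(t$Xs[, t$idx], res))), 1e-8)
})

test_that("raw-space coefficients reproduce scaled-space predictions", {
  t <- toy_model(seed = 37)
  m <- fitOls(t$Xs, t$y, t$idx, t$sc, grid = t$grid)
  raw <- coefficientsRaw(m)
  pred_raw <- as.numeric(t$X[, t$idx, drop = FALSE] %*% raw$coefficients +
                           raw$intercept)
  expect_equal(pred_raw, predict(m, t$X), tolerance = 1e-8)
  # identity scaling leaves coefficients unchanged; halving an sd doubles one
  id_sc <- new("ScalingParams", means = rep(0, 5), sds = rep(1, 5),
               flagged = rep(FALSE, 5), n_fit = 30L)
  m_id <- new("OlsModel", trace = m@trace, coefficients = m@coefficients,
              intercept = m@intercept, scaling = id_sc, response_name = "y")
  expect_equal(as.numeric(coefficientsRaw(m_id)$coefficients), m@coefficients)
  half <- id_sc; half@sds[t$idx[1]] <- 0.5
  m_h <- m_id; m_h@scaling <- half
  expect_equal(as.numeric(coefficientsRaw(m_h)$coefficients[1]),
               2 * m@coefficients[1])
})

test_that("predictions stay stable under tiny perturbation of collinear channels", {
  set.seed(38)
  n <- 40
  base <- rnorm(n)
  X <- cbind(base, base + 1e-3 * rnorm(n), rnorm(n))
  sc <- fitAutoscale(X)
  Xs <- applyAutoscale(X, sc)
  y <- base + 0.05 * rnorm(n)
  m1 <- fitOls(Xs, y, c(1L, 2L), sc, grid = nirGrid(1100, 2, 3))
  X2 <- X
  X2[, 2] <- X2[, 2] + 1e-6 * rnorm(n)
  sc2 <- fitAutoscale(X2)
  m2 <- fitOls(applyAutoscale(X2, sc2), y, c(1L, 2L), sc2,
               grid = nirGrid(1100, 2, 3))
  # coefficients can swing wildly; predictions must not
  expect_lt(max(abs(predict(m2, X2) - predict(m1, X))), 1e-2)
})

test_that("a model report has the published two-panel structure and round-trips", {
  t <- toy_model(seed = 39)
  m <- fitOls(t$Xs, t$y, t$idx, t$sc, grid = t$grid)
  s <- looStats(t$X, t$y, t$idx)
  rep1 <- modelReport(m, s)
  expect_equal(sum(grepl("^\\d+\t", rep1)), 2)         # one row per channel
  expect_equal(sum(grepl("^Intercept\t", rep1)), 1)
  expect_equal(length(rep1) - which(rep1 == "(B) Statistical Characteristics"), 7)
  parsed <- parseModelReport(rep1)
  expect_equal(parsed$panelA$predictor_index, t$idx)
  expect_equal(parsed$panelA$coefficient, m@coefficients)
  expect_equal(unname(parsed$panelB), unname(statsTable(s)))
  # re-rendering the parsed report is byte-identical
  m2 <- m; m2@coefficients <- parsed$panelA$coefficient
  expect_identical(modelReport(m, s), rep1)
})

test_that("model JSON artifacts round-trip", {
  t <- toy_model(seed = 40)
  m <- fitOls(t$Xs, t$y, t$idx, t$sc, response_name = "pv", grid = t$grid)
  path <- withr::local_tempfile(fileext = ".json")
  writeOlsModel(m, path)
  m2 <- readOlsModel(path)
  expect_equal(m2@coefficients, m@coefficients)
  expect_equal(m2@intercept, m@intercept)
  expect_identical(m2@trace@predictor_index, m@trace@predictor_index)
  expect_equal(predict(m2, t$X), predict(m, t$X))
  expect_identical(m2@response_name, "pv")
})
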