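test_that("OLS zone models recover exact and orthogonal-design truths", {
  set.seed(21)
  X <- data.frame(a = runif(20, 0, 5), b = runif(20, -2, 2))
  y <- 2 + 1 * X$a - 3 * X$b
  m <- fit_mlr(X, y)
  expect_equal(m$intercept, 2, tolerance = 1e-10)
  expect_equal(unname(m$coefficients), c(1, -3), tolerance = 1e-10)
  expect_equal(m$r_squared, 1)

  # orthogonal centred design: slopes equal per-column cov/var ratios
  a <- rep(c(-1, 1), each = 8)
  b <- rep(c(-1, 1), times = 8)
  Xo <- data.frame(a = a, b = b)
  yo <- 5 + 0.7 * a - 0.2 * b + rep(c(0.1, -0.1), 8)
  mo <- fit_mlr(Xo, yo)
  expect_equal(unname(mo$coefficients["a"]),
               sum((a - mean(a)) * (yo - mean(yo))) / sum((a - mean(a))^2),
               tolerance = 1e-10)
  expect_equal(unname(mo$coefficients["b"]),
               sum((b - mean(b)) * (yo - mean(yo))) / sum((b - mean(b))^2),
               tolerance = 1e-10)

  expect_error(fit_mlr(data.frame(a = a, b = a), yo), "collinear")
  expect_error(fit_mlr(X[1:3, ], y[1:3]), "more rows")
})

test_that("composed nonlinear fit identifies planted families and saturates", {
  # variance shares are balanced so each predictor's univariate signal is
  # resolvable at the R-squared comparison precision
  set.seed(22)
  hits <- 0
  for (i in 1:40) {
    X <- data.frame(a = runif(1500, -3, 3), b = runif(1500, 0.2, 8))
    y <- 1 + 0.22 * X$a^2 - 8 / (0.8 + X$b) + rnorm(1500, 0, 0.05)
    fams <- fit_mnlr(X, y)$selected_families
    if (fams[["a"]] == "quadratic" && fams[["b"]] == "shifted_inverse") {
      hits <- hits + 1
    }
  }
  expect_gte(hits, 36)

  X0 <- data.frame(a = runif(60, -3, 3), b = runif(60, 0.2, 8))
  y0 <- 1 + 0.22 * X0$a^2 - 8 / (0.8 + X0$b)
  m0 <- fit_mnlr(X0, y0)
  expect_equal(m0$r_squared, 1, tolerance = 1e-9)
})

test_that("over-parameterised compositions are demoted to stay identifiable", {
  cfg <- small_analogue()
  study <- generate_study(cfg, 23)
  mt <- modelling_table(study, cfg)
  X <- mt$fit[, unname(model_indicators())]
  m <- fit_mnlr(X, mt$fit$zone)
  expect_lte(length(m$structure$coefficients), nrow(X) - 1)
  expect_true(is.character(m$demoted))
})

test_that("PCA retains eigenvalues above one with unit-variance scores", {
  # two perfectly correlated indicators collapse to one component
  v <- c(1, 3, 4, 7, 9.5)
  p2 <- fit_pca(data.frame(a = v, b = 2 * v + 1))
  expect_length(p2$retained, 1)
  expect_equal(p2$contribution[1], 100, tolerance = 1e-9)

  set.seed(24)
  X <- as.data.frame(matrix(rnorm(9 * 30), 30, 9))
  names(X) <- paste0("v", 1:9)
  p <- fit_pca(X)
  expect_equal(sum(p$contribution), 100, tolerance = 1e-9)
  expect_true(all(p$eigenvalues[p$retained] > 1))

  s <- pc_scores(p, X, components = seq_along(p$eigenvalues))
  expect_equal(colMeans(s), setNames(rep(0, 9), colnames(s)),
               tolerance = 1e-10)
  expect_equal(unname(apply(s, 2, sd)), rep(1, 9), tolerance = 1e-9)
  cors <- cor(s)
  expect_lt(max(abs(cors[upper.tri(cors)])), 1e-8)

  # a row at the training mean maps to the origin
  mu <- as.data.frame(as.list(p$means))
  expect_equal(unname(drop(pc_scores(p, mu))), rep(0, length(p$retained)),
               tolerance = 1e-10)

  # with all PCs, inverse-transforming the scores reproduces standardised X
  Z <- scale(as.matrix(X))
  back <- s %*% (t(p$loadings))
  expect_equal(unname(back), matrix(as.numeric(Z), nrow(Z)),
               tolerance = 1e-8)

  expect_error(fit_pca(data.frame(a = v, b = 5)), "constant")
})

test_that("PC-score regressions mirror their raw-indicator counterparts", {
  set.seed(25)
  X <- as.data.frame(matrix(rnorm(5 * 40), 40, 5))
  names(X) <- paste0("v", 1:5)
  p <- fit_pca(X)
  s <- pc_scores(p, X)
  y <- drop(2 + s %*% seq_len(ncol(s)) + rnorm(40, 0, 0.01))
  pm <- fit_pca_mlr(s, y)
  expect_gt(pm$r_squared, 0.999)

  # cubic response in PC1 is picked up by the nonlinear variant
  y2 <- 1 + 0.5 * s[, 1]^3 + rnorm(40, 0, 0.05)
  pn <- fit_pca_mnlr(s, y2)
  expect_equal(unname(pn$selected_families[1]), "cubic")
  expect_gt(pn$r_squared, pm2 <- fit_pca_mlr(s, y2)$r_squared)
})

test_that("nested indicator sets cannot raise training R2 when reduced", {
  cfg <- small_analogue()
  study <- generate_study(cfg, 26)
  mt <- modelling_table(study, cfg)
  full_ids <- unname(model_indicators())
  e_ids <- unname(model_indicators()[c(1:4, 6:8, 10:13)])
  m_full <- fit_mlr(mt$fit[, full_ids], mt$fit$zone)
  m_e <- fit_mlr(mt$fit[, e_ids], mt$fit$zone, indicator_set = "E")
  expect_gte(m_full$r_squared, m_e$r_squared)
})

test_that("prediction, rounding and training-row reproduction behave", {
  expect_identical(round_zone(c(1.681, 13.4, -2, 6.5)), c(2L, 12L, 1L, 7L))

  set.seed(27)
  X <- data.frame(a = runif(15, 0, 4), b = runif(15, 0, 4))
  y <- 1 + X$a + 2 * X$b + rnorm(15, 0, 0.1)
  m <- fit_mlr(X, y)
  pred <- predict_zone(m, X)
  refit <- m$intercept + as.matrix(X) %*% m$coefficients
  expect_equal(pred, drop(refit), tolerance = 1e-12)
})

test_that("published equations evaluate to their printed constants at zero", {
  zero_of <- function(m) setNames(rep(0, length(m$variables)), m$variables)
  anchors <- c("MLR" = 1.681, "PCA-MLR" = 5.335, "PCA-MNLR" = -6.309,
               "MLR-E" = -1.549, "PCA-MLR-E" = 5.814, "PCA-MNLR-E" = 19.856)
  for (nm in names(anchors)) {
    m <- published_model(nm)
    expect_equal(predict_zone(m, zero_of(m)), unname(anchors[[nm]]),
                 tolerance = 1e-12, info = nm)
  }
  expect_error(published_model("MNLR-E"), "figure")
  expect_error(published_model("nope"), "PCA-MNLR-E")
})

test_that("published equations accept panel indicator names and evaluate terms", {
  m <- published_model("MLR")
  v <- setNames(rep(0, 13), unname(model_indicators()))
  v[["leaf_length"]] <- 10  # x2
  expect_equal(predict_zone(m, v), 1.681 - 0.010 * 10, tolerance = 1e-12)

  # full nonlinear equation at the zero vector keeps its hyperbolic terms
  mn <- published_model("MNLR")
  at0 <- predict_zone(mn, setNames(rep(0, 13), paste0("x", 1:13)))
  expect_equal(at0, 259.063 - 187.388 / 1.594 - 4.833 / 0.036,
               tolerance = 1e-9)

  # hand-computed oracle at a non-zero point
  v2 <- setNames(rep(0, 13), paste0("x", 1:13))
  v2[["x6"]] <- 2
  want <- 259.063 - 187.388 / 1.594 - 4.833 / 0.036 +
    (-9.959 * 8 + 40.43 * 4 - 48.269 * 2)
  expect_equal(predict_zone(mn, v2), want, tolerance = 1e-9)

  # published score matrices map x-symbols onto scores
  pca <- published_model("PCA")
  xv <- as.data.frame(as.list(setNames(rep(1, 13), paste0("x", 1:13))))
  sc <- pc_scores(pca, xv)
  expect_equal(unname(sc[1, "y1"]), sum(pca$score_coef[, "y1"]),
               tolerance = 1e-12)
})

test_that("zone models survive a JSON round trip", {
  set.seed(28)
  X <- data.frame(a = runif(20, 1, 5), b = runif(20, 1, 5))
  y <- 2 + X$a - 0.5 * X$b^2 + rnorm(20, 0, 0.05)
  probe <- data.frame(a = c(1.5, 4.2), b = c(2, 3.3))

  for (m in list(fit_mlr(X, y), fit_mnlr(X, y), published_model("MNLR"))) {
    path <- withr::local_tempfile(fileext = ".json")
    write_zone_model(m, path)
    back <- read_zone_model(path)
    newdata <- if (m$kind == "equation") {
      as.data.frame(as.list(setNames(runif(13, 0, 0.5), paste0("x", 1:13))))
    } else probe
    expect_equal(predict_zone(back, newdata), predict_zone(m, newdata),
                 tolerance = 1e-10, info = m$family)
  }
})
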