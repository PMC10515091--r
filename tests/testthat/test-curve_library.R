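test_that("curve families recover noiseless parameters", {
  x <- 1:10
  lin <- fit_curve(x, 3 + 2 * x, "linear")
  expect_equal(unname(lin$params), c(3, 2), tolerance = 1e-10)
  expect_equal(lin$r_squared, 1)

  quad <- fit_curve(-2:2, (-2:2)^2, "quadratic")
  expect_equal(unname(quad$params), c(0, 0, 1), tolerance = 1e-10)

  # power is fitted in closed form through the log transform
  pow <- fit_curve(1:10, 2 * (1:10)^1.5, "power")
  expect_equal(unname(pow$params), c(2, 1.5), tolerance = 1e-10)
  expect_equal(pow$r_squared, 1, tolerance = 1e-12)

  sinv <- fit_curve(x, 5 - 12 / (0.8 + x), "shifted_inverse")
  expect_equal(unname(sinv$params), c(5, -12, 0.8), tolerance = 1e-4)
})

test_that("infeasible domains mark families rather than erroring", {
  x <- c(-1, 0, 1, 2, 3)
  y <- c(1, 2, 3, 4, 5)
  expect_false(fit_curve(x, y, "logarithmic")$feasible)
  expect_false(fit_curve(x, y, "power")$feasible)
  expect_false(fit_curve(x, -y, "exponential")$feasible)
  expect_true(fit_curve(x, y, "linear")$feasible)
})

test_that("family selection maximises rounded R2 with parsimony ties", {
  x <- 1:12
  # exactly linear data: quadratic and cubic also reach R2 = 1, but the
  # tie goes to the family with fewest parameters
  bf <- best_family(x, 4 + 0.5 * x)
  expect_equal(bf$family, "linear")

  # data with non-positive x exclude the log/power families
  bf2 <- best_family(c(-2:5), 1 + (-2:5)^2)
  cand <- vapply(attr(bf2, "candidates"), `[[`, "", "family")
  expect_false(any(c("logarithmic", "power") %in% cand))

  expect_error(best_family(c(0, 1), c(1, 2)), "no feasible")
})

test_that("a pronounced cubic is identified under 1% range noise", {
  set.seed(500)
  g <- function(z) 1500 + 140 * z + 7.5 * (z - 6.5)^3
  zr <- rep(1:12, length.out = 29)
  rng <- diff(range(g(1:12)))
  hits <- 0
  for (i in 1:100) {
    z <- sample(zr)
    y <- g(z) + rnorm(29, 0, 0.01 * rng)
    if (best_family(z, y)$family == "cubic") hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("selected family never undercuts the linear fit", {
  set.seed(321)
  for (i in 1:30) {
    x <- runif(20, 0.5, 10)
    y <- rnorm(20, 2 + 0.3 * x + 0.05 * x^2, 0.5)
    bf <- best_family(x, y)
    lin <- fit_curve(x, y, "linear")
    expect_gte(round(bf$r_squared, 2), round(lin$r_squared, 2))
  }
})

test_that("additive composition collapses constants into one intercept", {
  x1 <- 1:8
  x2 <- seq(0.5, 4, by = 0.5)
  sel <- list(
    a = fit_curve(x1, 2 + 0.5 * x1 + 0.25 * x1^2, "quadratic"),
    b = fit_curve(x2, 3 + 1.5 / x2, "inverse")
  )
  comp <- compose_additive(sel)
  # 1 intercept + 2 quadratic slopes + 1 inverse slope
  expect_length(leafzone:::.flatten_params(comp), 4)
  expect_equal(comp$intercept, 5, tolerance = 1e-10)

  expect_error(compose_additive(list()), "empty")

  # at all-zero predictors only the intercept and shifted-inverse constants
  # survive: b0 + b1/b2
  sel2 <- list(
    a = fit_curve(x1, 1 + 2 * x1, "linear"),
    b = fit_curve(x1, 4 - 6 / (1.5 + x1), "shifted_inverse")
  )
  comp2 <- compose_additive(sel2)
  at0 <- predict_composed(comp2, data.frame(a = 0, b = 0))
  expect_equal(at0, 1 + 4 + (-6) / 1.5, tolerance = 1e-3)
})

test_that("joint refit recovers a noiseless planted structure", {
  set.seed(11)
  X <- data.frame(a = runif(40, 1, 9), b = runif(40, 0, 5))
  y <- 2 + 0.8 * X$a + 0.12 * X$a^2 - 5 / (0.7 + X$b)
  sel <- list(a = fit_curve(X$a, y, "quadratic"),
              b = fit_curve(X$b, y, "shifted_inverse"))
  comp <- compose_additive(sel)
  fit <- joint_nls_fit(comp, X, y)
  expect_true(fit$converged)
  expect_equal(unname(fit$coefficients["(Intercept)"]), 2, tolerance = 1e-5)
  expect_equal(unname(fit$coefficients["a.b1"]), 0.8, tolerance = 1e-5)
  expect_equal(unname(fit$coefficients["a.b2"]), 0.12, tolerance = 1e-5)
  expect_equal(unname(fit$coefficients["b.b1"]), -5, tolerance = 1e-4)
  expect_equal(unname(fit$coefficients["b.b2"]), 0.7, tolerance = 1e-4)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)

  # initialising at the optimum stays there
  fit2 <- joint_nls_fit(comp, X, y, init = fit$coefficients)
  expect_equal(fit2$coefficients, fit$coefficients, tolerance = 1e-8)
})

test_that("joint refit never worsens the initial SSE", {
  set.seed(12)
  for (i in 1:10) {
    X <- data.frame(a = runif(30, 1, 9), b = runif(30, 1, 6))
    y <- 1 + 0.5 * X$a - 0.3 * X$b^2 + rnorm(30, 0, 2)
    sel <- list(a = best_family(X$a, y), b = best_family(X$b, y))
    comp <- compose_additive(sel)
    sse0 <- sum((y - predict_composed(comp, X))^2)
    fit <- joint_nls_fit(comp, X, y)
    expect_lte(fit$sse, sse0 + 1e-8)
    expect_true(fit$r_squared >= 0 && fit$r_squared <= 1)
  }
})

test_that("underdetermined joint fits are refused", {
  X <- data.frame(a = 1:3)
  y <- c(1, 2, 3)
  sel <- list(a = fit_curve(1:10, (1:10)^3, "cubic"))
  comp <- compose_additive(sel)
  expect_error(joint_nls_fit(comp, X, y), "fewer rows")
})

test_that("noisy planted coefficients are recovered within Monte Carlo bounds", {
  # coefficient RMSE under noise stays within 5x the noiseless RMSE floor
  set.seed(13)
  truth <- c(1, 0.4, 0.02, -2)  # intercept, linear a, cubic a, linear b
  rmse <- function(noise_sd) {
    errs <- replicate(25, {
      X <- data.frame(a = runif(100, 1, 9), b = runif(100, 0, 5))
      y <- truth[1] + truth[2] * X$a + truth[3] * X$a^3 + truth[4] * X$b +
        rnorm(100, 0, noise_sd)
      sel <- list(a = fit_curve(X$a, y, "cubic"),
                  b = fit_curve(X$b, y, "linear"))
      fit <- joint_nls_fit(compose_additive(sel), X, y)
      cf <- fit$coefficients
      got <- c(cf[["(Intercept)"]], cf[["a.b1"]], cf[["a.b3"]], cf[["b.b1"]])
      sqrt(mean((got - truth)^2))
    })
    mean(errs)
  }
  expect_lt(rmse(0.1), 0.1)      # small against coefficient scale
  expect_lt(rmse(0), 1e-6)       # numerically exact in the noiseless limit
})
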