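# Univariate curve-family catalogue, per-predictor family selection by R2,
# and additive composition into a joint multivariate nonlinear model.

.family_defs <- local({
  lm_fit <- function(formula_rhs, transform = identity, back = identity,
                     param_names, y_log = FALSE) {
    # returns a closure fitting y (optionally log y) on transformed x terms
    function(x, y) {
      yy <- if (y_log) log(y) else y
      X <- do.call(cbind, lapply(formula_rhs, function(f) f(x)))
      fit <- stats::lm.fit(cbind(1, X), yy)
      stats::setNames(as.numeric(fit$coefficients), param_names)
    }
  }

  list(
    linear = list(
      n_params = 2, constant = "b0", params = c("b0", "b1"),
      feasible = function(x, y) TRUE,
      fit = lm_fit(list(function(x) x), param_names = c("b0", "b1")),
      predict = function(p, x) p[["b0"]] + p[["b1"]] * x,
      label = function(p) sprintf("%+g*x", p[["b1"]])
    ),
    quadratic = list(
      n_params = 3, constant = "b0", params = c("b0", "b1", "b2"),
      feasible = function(x, y) TRUE,
      fit = lm_fit(list(function(x) x, function(x) x^2),
                   param_names = c("b0", "b1", "b2")),
      predict = function(p, x) p[["b0"]] + p[["b1"]] * x + p[["b2"]] * x^2,
      label = function(p) sprintf("%+g*x %+g*x^2", p[["b1"]], p[["b2"]])
    ),
    cubic = list(
      n_params = 4, constant = "b0", params = c("b0", "b1", "b2", "b3"),
      feasible = function(x, y) TRUE,
      fit = lm_fit(list(function(x) x, function(x) x^2, function(x) x^3),
                   param_names = c("b0", "b1", "b2", "b3")),
      predict = function(p, x) p[["b0"]] + p[["b1"]] * x + p[["b2"]] * x^2 +
        p[["b3"]] * x^3,
      label = function(p) sprintf("%+g*x %+g*x^2 %+g*x^3",
                                  p[["b1"]], p[["b2"]], p[["b3"]])
    ),
    logarithmic = list(
      n_params = 2, constant = "b0", params = c("b0", "b1"),
      feasible = function(x, y) if (all(x > 0)) TRUE else "requires x > 0",
      fit = lm_fit(list(log), param_names = c("b0", "b1")),
      predict = function(p, x) p[["b0"]] + p[["b1"]] * log(x),
      label = function(p) sprintf("%+g*ln(x)", p[["b1"]])
    ),
    inverse = list(
      n_params = 2, constant = "b0", params = c("b0", "b1"),
      feasible = function(x, y) if (all(x != 0)) TRUE else "requires x != 0",
      fit = lm_fit(list(function(x) 1 / x), param_names = c("b0", "b1")),
      predict = function(p, x) p[["b0"]] + p[["b1"]] / x,
      label = function(p) sprintf("%+g/x", p[["b1"]])
    ),
    shifted_inverse = list(
      n_params = 3, constant = "b0", params = c("b0", "b1", "b2"),
      feasible = function(x, y) TRUE,
      fit = function(x, y) {
        # profile the shift: for a fixed shift s the model is linear in
        # (b0, b1); s is constrained so that s + x stays positive
        lo <- -min(x)
        span <- max(diff(range(x)), abs(min(x)), 1)
        eps <- 1e-6 * span
        sse_of <- function(s) {
          f <- stats::lm.fit(cbind(1, 1 / (s + x)), y)
          sum(f$residuals^2)
        }
        opt <- stats::optimize(sse_of, interval = c(lo + eps, lo + 20 * span))
        s <- opt$minimum
        f <- stats::lm.fit(cbind(1, 1 / (s + x)), y)
        c(b0 = as.numeric(f$coefficients[1]),
          b1 = as.numeric(f$coefficients[2]), b2 = s)
      },
      predict = function(p, x) p[["b0"]] + p[["b1"]] / (p[["b2"]] + x),
      label = function(p) sprintf("%+g/(%g + x)", p[["b1"]], p[["b2"]])
    ),
    power = list(
      n_params = 2, constant = NULL, params = c("b0", "b1"),
      feasible = function(x, y) {
        if (!all(x > 0)) return("requires x > 0")
        if (!all(y > 0)) return("requires y > 0")
        TRUE
      },
      fit = function(x, y) {
        f <- stats::lm.fit(cbind(1, log(x)), log(y))
        c(b0 = exp(as.numeric(f$coefficients[1])),
          b1 = as.numeric(f$coefficients[2]))
      },
      predict = function(p, x) p[["b0"]] * x^p[["b1"]],
      label = function(p) sprintf("%g*x^%g", p[["b0"]], p[["b1"]])
    ),
    exponential = list(
      n_params = 2, constant = NULL, params = c("b0", "b1"),
      feasible = function(x, y) if (all(y > 0)) TRUE else "requires y > 0",
      fit = function(x, y) {
        f <- stats::lm.fit(cbind(1, x), log(y))
        c(b0 = exp(as.numeric(f$coefficients[1])),
          b1 = as.numeric(f$coefficients[2]))
      },
      predict = function(p, x) p[["b0"]] * exp(p[["b1"]] * x),
      label = function(p) sprintf("%g*exp(%g*x)", p[["b0"]], p[["b1"]])
    ),
    growth = list(
      n_params = 2, constant = NULL, params = c("b0", "b1"),
      feasible = function(x, y) if (all(y > 0)) TRUE else "requires y > 0",
      fit = function(x, y) {
        f <- stats::lm.fit(cbind(1, x), log(y))
        c(b0 = as.numeric(f$coefficients[1]),
          b1 = as.numeric(f$coefficients[2]))
      },
      predict = function(p, x) exp(p[["b0"]] + p[["b1"]] * x),
      label = function(p) sprintf("exp(%g %+g*x)", p[["b0"]], p[["b1"]])
    ),
    s_curve = list(
      n_params = 2, constant = NULL, params = c("b0", "b1"),
      feasible = function(x, y) {
        if (!all(x != 0)) return("requires x != 0")
        if (!all(y > 0)) return("requires y > 0")
        TRUE
      },
      fit = function(x, y) {
        f <- stats::lm.fit(cbind(1, 1 / x), log(y))
        c(b0 = as.numeric(f$coefficients[1]),
          b1 = as.numeric(f$coefficients[2]))
      },
      predict = function(p, x) exp(p[["b0"]] + p[["b1"]] / x),
      label = function(p) sprintf("exp(%g %+g/x)", p[["b0"]], p[["b1"]])
    ),
    logistic = list(
      n_params = 3, constant = NULL, params = c("asym", "xmid", "scal"),
      feasible = function(x, y) {
        if (!all(y > 0)) return("requires y > 0")
        if (length(unique(x)) < 4) return("requires >= 4 distinct x")
        TRUE
      },
      fit = function(x, y) {
        fit <- stats::nls(y ~ SSlogis(x, asym, xmid, scal),
                          data = data.frame(x = x, y = y))
        stats::setNames(as.numeric(stats::coef(fit)),
                        c("asym", "xmid", "scal"))
      },
      predict = function(p, x) p[["asym"]] / (1 + exp((p[["xmid"]] - x) / p[["scal"]])),
      label = function(p) sprintf("%g/(1+exp((%g-x)/%g))",
                                  p[["asym"]], p[["xmid"]], p[["scal"]])
    )
  )
})

#' The univariate curve-family catalogue
#'
#' Families mirror a standard curve-estimation set: `linear`, `quadratic`,
#' `cubic`, `logarithmic` (`y = b0 + b1 ln x`), `inverse` (`y = b0 + b1/x`),
#' `shifted_inverse` (`y = b0 + b1/(b2 + x)`), `power` (`y = b0 x^b1`),
#' `exponential` (`y = b0 e^(b1 x)`), `growth` (`y = e^(b0 + b1 x)`),
#' `s_curve` (`y = e^(b0 + b1/x)`) and a three-parameter `logistic`.
#' `shifted_inverse` extends the standard set because hyperbolic terms with
#' an estimated offset arise in the published composed equations.
#'
#' @param names Optional character vector restricting the catalogue; order
#'   is preserved and defines the tie-break order of [best_family()].
#' @return Named list of family definitions.
#' @export
curve_catalogue <- function(names = NULL) {
  if (is.null(names)) return(.family_defs)
  unknown <- setdiff(names, base::names(.family_defs))
  if (length(unknown) > 0) {
    stop("unknown curve families: ", paste(unknown, collapse = ", "))
  }
  .family_defs[names]
}

#' Fit one curve family to paired data
#'
#' Least-squares fit of `y` on `x` under the given family. Families that can
#' be linearised (logarithmic, power, exponential, growth, s-curve) are
#' fitted in closed form on the transformed scale; R-squared is always
#' recomputed from the back-transformed predictions on the original `y`
#' scale so families are comparable.
#'
#' A family whose domain constraints the data violate is not an error: the
#' returned object carries `feasible = FALSE` and the reason, so callers can
#' skip it.
#'
#' @param x,y Numeric vectors of equal length.
#' @param family A family name or an entry of [curve_catalogue()].
#' @return Object of class `curve_fit`: `family`, `params`, `r_squared`,
#'   `feasible`, `reason`, `n`.
#' @export
#' @examples
#' fit_curve(1:10, 3 + 2 * (1:10), "linear")$params
fit_curve <- function(x, y, family) {
  if (is.character(family)) {
    fam_name <- family
    family <- curve_catalogue(family)[[1]]
  } else {
    fam_name <- family$name %||% names(which(vapply(
      .family_defs, identical, logical(1), family)))[1]
  }
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  infeasible <- function(reason) {
    structure(list(family = fam_name, params = NULL, r_squared = NA_real_,
                   feasible = FALSE, reason = reason, n = length(x)),
              class = "curve_fit")
  }
  if (length(x) <= family$n_params) {
    return(infeasible("fewer points than parameters"))
  }
  feas <- family$feasible(x, y)
  if (!isTRUE(feas)) return(infeasible(feas))
  params <- tryCatch(family$fit(x, y), error = function(e) e)
  if (inherits(params, "error") || anyNA(params) ||
      any(!is.finite(params))) {
    return(infeasible(if (inherits(params, "error"))
      conditionMessage(params) else "non-finite parameters"))
  }
  pred <- family$predict(params, x)
  if (any(!is.finite(pred))) return(infeasible("non-finite predictions"))
  sst <- sum((y - mean(y))^2)
  if (sst == 0) return(infeasible("constant response"))
  r2 <- 1 - sum((y - pred)^2) / sst
  structure(list(family = fam_name, params = params, r_squared = r2,
                 feasible = TRUE, reason = NULL, n = length(x)),
            class = "curve_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Select the best curve family by R-squared
#'
#' Fits every feasible family in the catalogue and returns the one with the
#' highest R-squared, compared at `r2_digits` decimal places. Ties at that
#' precision are broken by fewest parameters, then catalogue order. The
#' rounded comparison is essential with nested polynomial families: compared
#' at machine precision, a cubic would never lose to the quadratic or linear
#' family it nests.
#'
#' @inheritParams fit_curve
#' @param catalogue Catalogue from [curve_catalogue()].
#' @param r2_digits Decimal places at which R-squared values are compared.
#' @return The winning `curve_fit`, with attribute `"candidates"` holding
#'   all feasible fits.
#' @export
best_family <- function(x, y, catalogue = curve_catalogue(), r2_digits = 2) {
  fits <- lapply(names(catalogue), function(nm) fit_curve(x, y, nm))
  feasible <- Filter(function(f) isTRUE(f$feasible), fits)
  if (length(feasible) == 0) {
    reasons <- vapply(fits, function(f) paste0(f$family, ": ", f$reason), "")
    stop("no feasible curve family; ", paste(reasons, collapse = "; "))
  }
  r2 <- round(vapply(feasible, function(f) f$r_squared, numeric(1)), r2_digits)
  np <- vapply(feasible, function(f) catalogue[[f$family]]$n_params, numeric(1))
  ord <- order(-r2, np, seq_along(feasible))
  best <- feasible[[ord[1]]]
  attr(best, "candidates") <- feasible
  best
}

# ---------------------------------------------------------------------------
# Additive composition and joint refit
# ---------------------------------------------------------------------------

#' Compose per-predictor curve fits into one additive structure
#'
#' Builds a multivariate model `y = intercept + sum_j f_j(x_j)` from one
#' fitted univariate family per predictor. Additive constants of the
#' individual fits are collapsed into a single global intercept; families
#' without an additive constant (power, exponential, growth, s-curve,
#' logistic) contribute all their parameters to their term.
#'
#' @param selections Named list of `curve_fit` objects (names are predictor
#'   identifiers), e.g. from [best_family()] per column.
#' @return Object of class `composed_structure` with fields `intercept` and
#'   `terms` (per predictor: family name and non-constant parameters).
#' @export
compose_additive <- function(selections) {
  if (length(selections) == 0) stop("empty selection: nothing to compose")
  if (is.null(names(selections)) || any(names(selections) == "")) {
    stop("selections must be a named list (names = predictor ids)")
  }
  intercept <- 0
  terms <- list()
  for (var in names(selections)) {
    fit <- selections[[var]]
    stopifnot(inherits(fit, "curve_fit"), isTRUE(fit$feasible))
    fam <- .family_defs[[fit$family]]
    p <- fit$params
    if (!is.null(fam$constant)) {
      intercept <- intercept + p[[fam$constant]]
      p <- p[setdiff(names(p), fam$constant)]
    }
    terms[[var]] <- list(var = var, family = fit$family, params = p)
  }
  structure(list(intercept = intercept, terms = terms),
            class = "composed_structure")
}

# evaluate the non-constant part of one term at predictor values
.term_value <- function(term, x) {
  fam <- .family_defs[[term$family]]
  p <- term$params
  if (!is.null(fam$constant)) p[[fam$constant]] <- 0
  fam$predict(p, x)
}

#' Evaluate a composed structure on a data frame of predictors
#'
#' @param structure A `composed_structure` (or jointly refitted
#'   `composed_fit`).
#' @param X Data frame or matrix containing the structure's predictor
#'   columns.
#' @return Numeric vector of predictions.
#' @export
predict_composed <- function(structure, X) {
  stopifnot(inherits(structure, "composed_structure") ||
              inherits(structure, "composed_fit"))
  X <- as.data.frame(X)
  missing_cols <- setdiff(names(structure$terms), names(X))
  if (length(missing_cols) > 0) {
    stop("missing predictor column(s): ", paste(missing_cols, collapse = ", "))
  }
  pred <- rep(structure$intercept, nrow(X))
  for (term in structure$terms) {
    pred <- pred + .term_value(term, X[[term$var]])
  }
  pred
}

.flatten_params <- function(structure) {
  out <- c("(Intercept)" = structure$intercept)
  for (term in structure$terms) {
    p <- term$params
    names(p) <- paste(term$var, names(p), sep = ".")
    out <- c(out, p)
  }
  out
}

.unflatten_params <- function(structure, par) {
  structure$intercept <- par[["(Intercept)"]]
  i <- 1L
  for (nm in names(structure$terms)) {
    k <- length(structure$terms[[nm]]$params)
    structure$terms[[nm]]$params[] <- par[i + seq_len(k)]
    i <- i + k
  }
  structure
}

#' Jointly refit a composed structure by nonlinear least squares
#'
#' Refits all coefficients of an additively composed model simultaneously
#' with Levenberg-Marquardt least squares, initialised at the univariate
#' parameters. Because the refit starts from that initialisation, its SSE
#' never exceeds the SSE of the composed structure evaluated without refit.
#'
#' @param structure A `composed_structure`.
#' @param X Data frame of predictor columns.
#' @param y Response vector.
#' @param init Optional named parameter vector overriding the structure's
#'   initial values (same layout as the fitted coefficients).
#' @param control List with `maxiter` (default 500) and `ftol` (default
#'   1e-8, relative SSE change).
#' @return Object of class `composed_fit` (also a `composed_structure`):
#'   the refitted structure plus `coefficients`, `sse`, `r_squared`,
#'   `converged`, `iterations`, `message`. Non-convergence is reported in
#'   those fields, not raised.
#' @export
joint_nls_fit <- function(structure, X, y, init = NULL,
                          control = list(maxiter = 500, ftol = 1e-8)) {
  stopifnot(inherits(structure, "composed_structure"))
  X <- as.data.frame(X)
  stopifnot(length(y) == nrow(X))
  par0 <- .flatten_params(structure)
  if (!is.null(init)) {
    stopifnot(all(names(par0) %in% names(init)))
    par0[] <- init[names(par0)]
  }
  if (nrow(X) < length(par0)) {
    stop("fewer rows (", nrow(X), ") than parameters (", length(par0), ")")
  }
  resid_fn <- function(par) {
    names(par) <- names(par0)
    s <- .unflatten_params(structure, par)
    r <- y - predict_composed(s, X)
    r[!is.finite(r)] <- 1e10  # keep LM inside the feasible region
    r
  }
  lm_out <- suppressWarnings(minpack.lm::nls.lm(
    par = par0, fn = resid_fn,
    control = minpack.lm::nls.lm.control(
      maxiter = control$maxiter %||% 500,
      ftol = control$ftol %||% 1e-8,
      maxfev = control$maxfev %||% (1000L * (length(par0) + 1L))
    )
  ))
  par <- stats::setNames(as.numeric(lm_out$par), names(par0))
  if (any(!is.finite(par))) {
    stop("joint fit diverged to non-finite parameters; info = ", lm_out$info)
  }
  fitted_structure <- .unflatten_params(structure, par)
  pred <- predict_composed(fitted_structure, X)
  sse <- sum((y - pred)^2)
  sst <- sum((y - mean(y))^2)
  out <- fitted_structure
  out$coefficients <- par
  out$sse <- sse
  out$r_squared <- if (sst > 0) 1 - sse / sst else NA_real_
  out$converged <- lm_out$info %in% 1:4
  out$iterations <- lm_out$niter
  out$message <- lm_out$message
  class(out) <- c("composed_fit", "composed_structure")
  out
}

#' @export
print.composed_structure <- function(x, ...) {
  cat("Additive composed model:", length(x$terms), "term(s)\n")
  cat(sprintf("  intercept: %g\n", x$intercept))
  for (term in x$terms) {
    fam <- .family_defs[[term$family]]
    p <- term$params
    if (!is.null(fam$constant)) p[[fam$constant]] <- 0
    cat(sprintf("  %s [%s]: %s\n", term$var, term$family,
                fam$label(p)))
  }
  if (inherits(x, "composed_fit")) {
    cat(sprintf("  SSE %.6g, R^2 %.4f, converged: %s (%d iterations)\n",
                x$sse, x$r_squared, x$converged, x$iterations))
  }
  invisible(x)
}
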