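# Zone-predictor model families: MLR, MNLR, PCA-MLR, PCA-MNLR and their
# reduced "-E" variants, plus prediction and serialisation.

.new_zone_model <- function(family, kind, indicator_set = "full",
                            provenance = "fitted", ...) {
  structure(c(list(family = family, kind = kind,
                   indicator_set = indicator_set, provenance = provenance),
              list(...)),
            class = "zone_model")
}

#' Fit a multiple linear regression zone model
#'
#' Ordinary least squares of zone on the indicator columns.
#'
#' @param X Data frame (or matrix) of indicator values, species in rows.
#' @param y Zone vector, one per row of `X`.
#' @param indicator_set Label stored on the model (`"full"`, `"E"`, ...).
#' @param family Family tag stored on the model.
#' @return A `zone_model` with `intercept`, `coefficients`, `r_squared`.
#' @export
fit_mlr <- function(X, y, indicator_set = "full", family = "MLR") {
  X <- as.data.frame(X)
  stopifnot(nrow(X) == length(y))
  if (anyNA(X) || anyNA(y)) stop("missing values in the design or response")
  if (nrow(X) <= ncol(X) + 1) {
    stop("need more rows (", nrow(X), ") than indicators + 1 (",
         ncol(X) + 1, ")")
  }
  mm <- cbind(`(Intercept)` = 1, as.matrix(X))
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    bad <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  coefs <- qr.coef(qr_mm, y)
  pred <- drop(mm %*% coefs)
  sst <- sum((y - mean(y))^2)
  .new_zone_model(
    family, kind = "ols", indicator_set = indicator_set,
    variables = colnames(X),
    intercept = unname(coefs[1]),
    coefficients = coefs[-1],
    r_squared = 1 - sum((y - pred)^2) / sst,
    n = nrow(X)
  )
}

#' Fit a composed multivariate nonlinear regression zone model
#'
#' For each indicator the best univariate curve family is selected by
#' R-squared ([best_family()]); the per-indicator fits are composed
#' additively ([compose_additive()]) and all coefficients refitted jointly
#' ([joint_nls_fit()]).
#'
#' When the composed parameter count would reach the number of rows, the
#' least informative predictors (lowest univariate R-squared) are demoted to
#' the linear family until the joint fit is identifiable; demotions are
#' recorded in the model's `demoted` field.
#'
#' @inheritParams fit_mlr
#' @param catalogue Curve catalogue, see [curve_catalogue()].
#' @param r2_digits Precision of the family comparison, see [best_family()].
#' @param max_params Cap on total parameters (default `nrow(X) - 1`).
#' @param control Convergence control passed to [joint_nls_fit()].
#' @return A `zone_model` wrapping the jointly fitted structure, with
#'   `selected_families` and training `r_squared`; a non-converged joint fit
#'   is reported via the `converged` field, not an error.
#' @export
fit_mnlr <- function(X, y, catalogue = curve_catalogue(), r2_digits = 2,
                     max_params = NULL, indicator_set = "full",
                     family = "MNLR",
                     control = list(maxiter = 500, ftol = 1e-8)) {
  X <- as.data.frame(X)
  stopifnot(nrow(X) == length(y))
  if (anyNA(X) || anyNA(y)) stop("missing values in the design or response")
  if (is.null(max_params)) max_params <- nrow(X) - 1

  fits <- lapply(X, function(col) best_family(col, y, catalogue, r2_digits))
  names(fits) <- names(X)

  n_term_params <- function(f) {
    fam <- .family_defs[[f$family]]
    fam$n_params - if (is.null(fam$constant)) 0 else 1
  }
  total <- 1 + sum(vapply(fits, n_term_params, numeric(1)))
  demoted <- character(0)
  if (total > max_params) {
    r2 <- vapply(fits, function(f) f$r_squared, numeric(1))
    for (var in names(sort(r2))) {
      if (total <= max_params) break
      if (fits[[var]]$family == "linear") next
      before <- n_term_params(fits[[var]])
      fits[[var]] <- fit_curve(X[[var]], y, "linear")
      demoted <- c(demoted, var)
      total <- total - before + 1
    }
    if (total > max_params) {
      stop("cannot reduce composed model to ", max_params, " parameters")
    }
  }

  struct <- compose_additive(fits)
  fit <- joint_nls_fit(struct, X, y, control = control)
  .new_zone_model(
    family, kind = "composed", indicator_set = indicator_set,
    variables = names(X),
    structure = fit,
    selected_families = vapply(fits, function(f) f$family, character(1)),
    univariate_r2 = vapply(fits, function(f) f$r_squared, numeric(1)),
    demoted = demoted,
    r_squared = fit$r_squared,
    converged = fit$converged,
    n = nrow(X)
  )
}

# ---------------------------------------------------------------------------
# PCA
# ---------------------------------------------------------------------------

#' Principal component analysis of an indicator table
#'
#' Standardises the columns, eigendecomposes the correlation matrix and
#' retains components with eigenvalue > 1 (strictly). Component score
#' coefficients follow the regression method, loading / eigenvalue (i.e.
#' eigenvector / sqrt(eigenvalue)), so training scores have unit variance.
#' Contribution rates are 100 * eigenvalue / number of variables.
#'
#' @param X Data frame or matrix of indicator values (>= 2 columns, >= 3
#'   rows, no constant column).
#' @return Object of class `pca_model`: `means`, `sds`, `eigenvalues`,
#'   `loadings`, `score_coef` (variables x components), `retained`,
#'   `contribution`, `cumulative`, `variables`.
#' @export
fit_pca <- function(X) {
  X <- as.data.frame(X)
  if (ncol(X) < 2 || nrow(X) < 3) stop("need >= 2 indicators and >= 3 rows")
  if (anyNA(X)) stop("missing values in the indicator table")
  sds <- vapply(X, stats::sd, numeric(1))
  if (any(sds == 0)) {
    stop("constant column(s): ",
         paste(names(X)[sds == 0], collapse = ", "))
  }
  means <- vapply(X, mean, numeric(1))
  Z <- scale(as.matrix(X), center = means, scale = sds)
  eig <- eigen(stats::cor(as.matrix(X)), symmetric = TRUE)
  lambda <- pmax(eig$values, 0)
  vecs <- eig$vectors
  # fix sign: largest-magnitude loading positive, for reproducibility
  for (j in seq_len(ncol(vecs))) {
    k <- which.max(abs(vecs[, j]))
    if (vecs[k, j] < 0) vecs[, j] <- -vecs[, j]
  }
  loadings <- sweep(vecs, 2, sqrt(lambda), `*`)
  score_coef <- sweep(loadings, 2, ifelse(lambda > 0, lambda, 1), `/`)
  dimnames(loadings) <- dimnames(score_coef) <-
    list(names(X), paste0("y", seq_along(lambda)))
  retained <- which(lambda > 1)
  if (length(retained) == 0) retained <- 1L
  structure(list(
    variables = names(X), means = means, sds = sds,
    eigenvalues = lambda, loadings = loadings, score_coef = score_coef,
    retained = retained,
    contribution = 100 * lambda / length(lambda),
    cumulative = cumsum(100 * lambda / length(lambda)),
    standardize = TRUE, provenance = "fitted"
  ), class = "pca_model")
}

#' Principal-component scores for new data
#'
#' @param model A `pca_model` (fitted or published).
#' @param X Data frame containing the model's variables (for published
#'   models, either the x-symbols or the mapped indicator identifiers).
#' @param standardize Standardise `X` with the model's means/SDs before
#'   applying the score coefficients. Defaults to the model's own mode;
#'   published score matrices carry no means/SDs and are applied to raw
#'   values unless means/SDs are supplied.
#' @param components Which components to return (default: retained set).
#' @return Matrix of scores, one column per component (`y1`, `y2`, ...).
#' @export
pc_scores <- function(model, X, standardize = NULL, components = NULL) {
  stopifnot(inherits(model, "pca_model"))
  X <- as.data.frame(X)
  cols <- .resolve_columns(model$variables, X,
                           attr(model, "indicator_map") %||% model$indicator_map)
  M <- as.matrix(X[, cols, drop = FALSE])
  if (is.null(standardize)) standardize <- isTRUE(model$standardize)
  if (standardize) {
    if (is.null(model$means)) {
      stop("model carries no standardisation means/SDs")
    }
    M <- scale(M, center = model$means, scale = model$sds)
  }
  comp <- components %||% model$retained
  scores <- M %*% model$score_coef[, comp, drop = FALSE]
  colnames(scores) <- colnames(model$score_coef)[comp]
  scores
}

# Find each model variable in the data, falling back to a mapped alias
# (x-symbol -> panel indicator id).
.resolve_columns <- function(vars, X, map = NULL) {
  cols <- character(length(vars))
  for (i in seq_along(vars)) {
    v <- vars[i]
    if (v %in% names(X)) {
      cols[i] <- v
    } else if (!is.null(map) && !is.na(map[v]) && map[[v]] %in% names(X)) {
      cols[i] <- map[[v]]
    } else {
      stop("missing column: ", v)
    }
  }
  cols
}

#' Fit linear or nonlinear regression on principal-component scores
#'
#' `fit_pca_mlr()` regresses zone on the retained PC scores by OLS;
#' `fit_pca_mnlr()` selects the best curve family per score and refits the
#' additive composition jointly, as [fit_mnlr()] does for raw indicators.
#'
#' @param scores Matrix or data frame of PC scores (e.g. [pc_scores()]).
#' @param y Zone vector.
#' @param pca Optional `pca_model`. When supplied it is stored on the zone
#'   model, and [predict_zone()] accepts raw indicator columns, projecting
#'   them onto the scores first.
#' @inheritParams fit_mnlr
#' @return A `zone_model`.
#' @export
fit_pca_mlr <- function(scores, y, indicator_set = "full", pca = NULL) {
  m <- fit_mlr(as.data.frame(scores), y, indicator_set = indicator_set,
               family = if (indicator_set == "E") "PCA-MLR-E" else "PCA-MLR")
  m$pca <- pca
  m
}

#' @rdname fit_pca_mlr
#' @export
fit_pca_mnlr <- function(scores, y, catalogue = curve_catalogue(),
                         r2_digits = 2, indicator_set = "full", pca = NULL) {
  m <- fit_mnlr(as.data.frame(scores), y, catalogue = catalogue,
                r2_digits = r2_digits, indicator_set = indicator_set,
                family = if (indicator_set == "E") "PCA-MNLR-E" else "PCA-MNLR")
  m$pca <- pca
  m
}

# ---------------------------------------------------------------------------
# Prediction
# ---------------------------------------------------------------------------

#' Predict continuous distribution zones
#'
#' Evaluates a zone model on new indicator (or PC-score) data. Published
#' models accept either their x/y symbols or the mapped panel indicator
#' identifiers as column names.
#'
#' @param model A `zone_model`.
#' @param newdata Data frame, or a named vector for a single species.
#' @return Numeric vector of continuous zone predictions.
#' @seealso [round_zone()] to map predictions to integer zones.
#' @export
predict_zone <- function(model, newdata) {
  stopifnot(inherits(model, "zone_model"))
  if (is.numeric(newdata) && !is.null(names(newdata))) {
    newdata <- as.data.frame(as.list(newdata))
  }
  newdata <- as.data.frame(newdata)
  if (!is.null(model$pca) &&
      !all(model$variables %in% names(newdata))) {
    newdata <- as.data.frame(pc_scores(model$pca, newdata))
  }
  switch(model$kind,
    ols = {
      cols <- .resolve_columns(model$variables, newdata, model$indicator_map)
      M <- as.matrix(newdata[, cols, drop = FALSE])
      drop(model$intercept + M %*% model$coefficients)
    },
    composed = {
      cols <- .resolve_columns(model$variables, newdata, model$indicator_map)
      sub <- newdata[, cols, drop = FALSE]
      names(sub) <- model$variables
      predict_composed(model$structure, sub)
    },
    equation = {
      cols <- .resolve_columns(model$variables, newdata, model$indicator_map)
      sub <- newdata[, cols, drop = FALSE]
      names(sub) <- model$variables
      .eval_equation(model, sub)
    },
    stop("unknown model kind: ", model$kind)
  )
}

#' @export
predict.zone_model <- function(object, newdata, ...) {
  predict_zone(object, newdata)
}

# Evaluate an equation-kind model: intercept + polynomial and
# shifted-inverse terms.
.eval_equation <- function(model, X) {
  pred <- rep(model$intercept, nrow(X))
  for (term in model$terms) {
    x <- X[[term$var]]
    type <- term$type %||% "poly"
    if (type == "poly") {
      for (i in seq_along(term$powers)) {
        pred <- pred + term$coefs[i] * x^term$powers[i]
      }
    } else if (type == "shifted_inverse") {
      pred <- pred + term$coef / (term$shift + x)
    } else {
      stop("unknown term type: ", type)
    }
  }
  pred
}

#' Round a continuous zone prediction to an integer zone
#'
#' Nearest integer, half away from zero, clipped to the zone range 1-12.
#'
#' @param value Numeric vector of continuous predictions.
#' @param range Integer zone range (default `c(1, 12)`).
#' @return Integer vector of zones.
#' @export
#' @examples
#' round_zone(c(1.681, 13.4, -2))
round_zone <- function(value, range = c(1, 12)) {
  as.integer(pmin(pmax(floor(value + 0.5), range[1]), range[2]))
}

#' @export
print.zone_model <- function(x, ...) {
  cat(sprintf("Zone model %s (%s indicators, %s)\n",
              x$family, x$indicator_set, x$provenance))
  if (!is.null(x$r_squared) && !is.na(x$r_squared %||% NA)) {
    cat(sprintf("  training R^2: %.4f\n", x$r_squared))
  }
  if (x$kind == "ols") {
    cat(sprintf("  intercept %g + %d linear term(s)\n",
                x$intercept, length(x$coefficients)))
  } else if (x$kind == "composed") {
    cat("  families:", paste(x$selected_families, collapse = ", "), "\n")
  } else {
    cat(sprintf("  intercept %g + %d equation term(s)\n",
                x$intercept, length(x$terms)))
  }
  invisible(x)
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("PCA model (%s): %d variables, %d retained component(s)\n",
              x$provenance, length(x$variables), length(x$retained)))
  if (!is.null(x$eigenvalues)) {
    cat("  eigenvalues:",
        paste(sprintf("%.3f", x$eigenvalues[x$retained]), collapse = ", "),
        "\n  cumulative contribution:",
        sprintf("%.3f%%", x$cumulative[max(x$retained)]), "\n")
  }
  invisible(x)
}

# ---------------------------------------------------------------------------
# Serialisation: one human-readable format shared by fitted and published
# models
# ---------------------------------------------------------------------------

#' Write or read a zone model as JSON
#'
#' Fitted and published models share one human-readable file format so that
#' models can be exchanged, versioned and re-evaluated without refitting.
#'
#' @param model A `zone_model`.
#' @param path File path.
#' @return `write_zone_model()` returns `path` invisibly;
#'   `read_zone_model()` returns the `zone_model`.
#' @export
write_zone_model <- function(model, path) {
  stopifnot(inherits(model, "zone_model"))
  payload <- unclass(model)
  payload$format_version <- 1L
  if (model$kind == "composed") {
    s <- payload$structure
    payload$structure <- list(
      intercept = s$intercept,
      terms = lapply(unname(s$terms), function(t) {
        list(var = t$var, family = t$family, params = as.list(t$params))
      }),
      r_squared = s$r_squared, sse = s$sse,
      converged = s$converged, iterations = s$iterations
    )
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_zone_model
#' @export
read_zone_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  payload$format_version <- NULL
  if (identical(payload$kind, "composed")) {
    s <- payload$structure
    terms <- lapply(s$terms, function(t) {
      list(var = t$var, family = t$family, params = unlist(t$params))
    })
    names(terms) <- vapply(terms, function(t) t$var, character(1))
    struct <- structure(list(intercept = s$intercept, terms = terms),
                        class = c("composed_fit", "composed_structure"))
    struct$r_squared <- s$r_squared
    struct$sse <- s$sse
    struct$converged <- s$converged
    struct$iterations <- s$iterations
    payload$structure <- struct
  }
  if (identical(payload$kind, "equation")) {
    payload$terms <- lapply(payload$terms, function(t) {
      t$powers <- unlist(t$powers); t$coefs <- unlist(t$coefs); t
    })
  }
  if (!is.null(payload$coefficients)) {
    payload$coefficients <- unlist(payload$coefficients)
  }
  if (!is.null(payload$indicator_map)) {
    payload$indicator_map <- unlist(payload$indicator_map)
  }
  structure(payload, class = "zone_model")
}
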