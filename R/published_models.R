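# The published fitted equations, encoded verbatim (including suspected
# typographical oddities) so they can be evaluated as reference predictors
# without refitting. Indicator symbols: x1 vein density ... x13 total
# cuticle thickness/leaf area (see model_indicators()); y1..y4 are PC
# scores.

.poly_term <- function(var, coefs) {
  # coefs named by power, e.g. c(`1` = 0.147, `3` = -7.1e-07)
  list(var = var, type = "poly",
       powers = as.numeric(names(coefs)), coefs = unname(coefs))
}

.sinv_term <- function(var, coef, shift) {
  list(var = var, type = "shifted_inverse", coef = coef, shift = shift)
}

.published_equation <- function(family, indicator_set, intercept, terms,
                                variables, map = NULL) {
  .new_zone_model(family, kind = "equation", indicator_set = indicator_set,
                  provenance = "published", intercept = intercept,
                  terms = terms, variables = variables, indicator_map = map)
}

.x_map <- function(vars) model_indicators()[vars]

.published_store <- function() {
  x_full <- paste0("x", 1:13)
  x_e <- paste0("x", c(1:4, 6:8, 10:13))

  lin_terms <- function(vars, coefs) {
    mapply(function(v, cf) .poly_term(v, stats::setNames(cf, "1")),
           vars, coefs, SIMPLIFY = FALSE, USE.NAMES = FALSE)
  }

  mlr <- .published_equation(
    "MLR", "full", intercept = 1.681,
    terms = lin_terms(x_full, c(-0.008, -0.010, 0.149, -0.331, 0.289,
                                2.638, -9.189, 179.648, -121.779,
                                44.883, 200.331, 1004.379, -922.690)),
    variables = x_full, map = .x_map(x_full)
  )

  mnlr <- .published_equation(
    "MNLR", "full", intercept = 259.063,
    terms = list(
      .poly_term("x1", c(`1` = -0.018)),
      .poly_term("x2", c(`3` = -0.0000007137, `1` = 0.147)),
      .poly_term("x3", c(`2` = -0.031, `1` = 266.417)),
      .poly_term("x4", c(`3` = 0.099, `2` = -3.5741, `1` = 35.065)),
      .poly_term("x5", c(`3` = -0.063, `2` = 3.764, `1` = -69.234)),
      .poly_term("x6", c(`3` = -9.959, `2` = 40.43, `1` = -48.269)),
      .poly_term("x7", c(`3` = 1061.43, `2` = -534.01, `1` = 82.578)),
      .poly_term("x8", c(`3` = 7112.004, `2` = -5283.989, `1` = 2023.526)),
      .poly_term("x9", c(`2` = 1701.552, `1` = -1301.342)),
      .sinv_term("x10", coef = -187.388, shift = 1.594),
      .sinv_term("x11", coef = -4.833, shift = 0.036),
      .poly_term("x12", c(`3` = 17117685.84, `2` = -508496.037,
                          `1` = 1917.935)),
      .poly_term("x13", c(`1` = 0.03))
    ),
    variables = x_full, map = .x_map(x_full)
  )

  # Component score coefficient matrices (rows = x-symbols, cols = PCs),
  # encoded from the printed PC score equations.
  pca_coef <- cbind(
    y1 = c(0.094, -0.129, -0.12, -0.339, 0.039, -0.115, -0.119,
           0.064, 0.067, 0.128, 0.123, 0.12, 0.119),
    y2 = c(0.023, 0.07, 0.046, 0.344, 0.325, 0.002, 0.003,
           0.277, 0.227, -0.1, -0.097, -0.089, -0.088),
    y3 = c(0.086, -0.016, -0.121, -0.264, -0.323, 0.348, 0.149,
           0.363, 0.446, 0.116, -0.027, -0.044, -0.029),
    # the x8 coefficient of y4 is printed "0067"; encoded as 0.067
    y4 = c(-0.403, 0.186, 0.328, 0.078, 0.09, 0.146, 0.336,
           0.067, 0.06, 0.097, 0.314, 0.38, 0.391)
  )
  rownames(pca_coef) <- x_full
  pca <- structure(list(
    variables = x_full, means = NULL, sds = NULL,
    eigenvalues = NULL, loadings = NULL, score_coef = pca_coef,
    retained = 1:4, contribution = NULL,
    cumulative = c(NA, NA, NA, 94.964),
    standardize = FALSE, provenance = "published",
    indicator_map = .x_map(x_full)
  ), class = "pca_model")

  pca_mlr <- .published_equation(
    "PCA-MLR", "full", intercept = 5.335,
    terms = lin_terms(paste0("y", 1:4), c(-0.07, 0.098, -0.062, -0.044)),
    variables = paste0("y", 1:4)
  )

  pca_mnlr <- .published_equation(
    "PCA-MNLR", "full", intercept = -6.309,
    terms = list(
      .poly_term("y1", c(`2` = -0.019, `1` = -0.218)),
      .poly_term("y2", c(`2` = -0.039, `1` = 1.253)),
      .poly_term("y3", c(`3` = -0.005, `2` = -0.104, `1` = -0.606)),
      # printed with two cubic y4 terms; kept verbatim
      .poly_term("y4", c(`3` = -0.00006113)),
      .poly_term("y4", c(`3` = 0.005, `1` = -0.33))
    ),
    variables = paste0("y", 1:4)
  )

  mlr_e <- .published_equation(
    "MLR-E", "E", intercept = -1.549,
    terms = lin_terms(x_e, c(-0.002, -0.013, 0.206, 0.228, 2.942,
                             -16.321, 5.208, 38.243, 222.019,
                             472.326, -620.374)),
    variables = x_e, map = .x_map(x_e)
  )

  pca_e_coef <- cbind(
    y1 = c(0.097, -0.135, -0.125, 0.03, -0.121, -0.124, 0.054,
           0.135, 0.13, 0.127, 0.126),
    y2 = c(0.187, 0.02, -0.042, 0.537, -0.077, -0.115, 0.445,
           -0.131, -0.17, -0.178, -0.177),
    y3 = c(-0.341, 0.209, 0.34, 0.326, 0.124, 0.317, 0.282,
           0.055, 0.28, 0.347, 0.361)
  )
  rownames(pca_e_coef) <- x_e
  pca_e <- structure(list(
    variables = x_e, means = NULL, sds = NULL,
    eigenvalues = NULL, loadings = NULL, score_coef = pca_e_coef,
    retained = 1:3, contribution = NULL,
    cumulative = c(NA, NA, 87.083),
    standardize = FALSE, provenance = "published",
    indicator_map = .x_map(x_e)
  ), class = "pca_model")

  pca_mlr_e <- .published_equation(
    "PCA-MLR-E", "E", intercept = 5.814,
    terms = lin_terms(paste0("y", 1:3), c(0.156, 0.131, 0.119)),
    variables = paste0("y", 1:3)
  )

  pca_mnlr_e <- .published_equation(
    "PCA-MNLR-E", "E", intercept = 19.856,
    terms = list(
      .poly_term("y1", c(`2` = 0.008, `1` = 0.499)),
      .poly_term("y2", c(`2` = 0.032, `1` = -1.155)),
      .poly_term("y3", c(`3` = 0.00001637, `2` = -0.004, `1` = 0.287))
    ),
    variables = paste0("y", 1:3)
  )

  list(
    "MLR" = mlr, "MNLR" = mnlr, "PCA" = pca,
    "PCA-MLR" = pca_mlr, "PCA-MNLR" = pca_mnlr,
    "MLR-E" = mlr_e, "PCA-E" = pca_e,
    "PCA-MLR-E" = pca_mlr_e, "PCA-MNLR-E" = pca_mnlr_e
  )
}

#' Published zone-prediction equations
#'
#' Returns the published fitted models for this system, encoded verbatim
#' from the printed equations (suspected typographical slips are preserved
#' where the equation is still evaluable, and noted in the source). The
#' available names are `MLR`, `MNLR`, `PCA`, `PCA-MLR`, `PCA-MNLR`,
#' `MLR-E`, `PCA-E`, `PCA-MLR-E` and `PCA-MNLR-E`. The `PCA` and `PCA-E`
#' entries are `pca_model` objects holding the printed component score
#' coefficient matrices; the rest are `zone_model` equations evaluable with
#' [predict_zone()].
#'
#' The reduced nonlinear equation (`MNLR-E`) was published only as a figure
#' and its coefficients are not recoverable from the text, so requesting it
#' is an error.
#'
#' The indicator-side equations take x-symbol columns (`x1`..`x13`) or the
#' mapped panel identifiers ([model_indicators()]); the PC-side equations
#' take score columns `y1`..`y4`. The printed score matrices carry no
#' standardisation constants and are applied to the supplied values as-is
#' (see [pc_scores()]).
#'
#' @param name One of the published model names.
#' @return A `zone_model` or `pca_model`.
#' @export
#' @examples
#' m <- published_model("MLR")
#' predict_zone(m, setNames(rep(0, 13), paste0("x", 1:13)))  # 1.681
published_model <- function(name) {
  store <- .published_store()
  if (identical(name, "MNLR-E")) {
    stop("the MNLR-E equation was published only as a figure; ",
         "its coefficients are not available. Valid names: ",
         paste(names(store), collapse = ", "))
  }
  if (!name %in% names(store)) {
    stop("unknown published model '", name, "'; valid names: ",
         paste(c(names(store), "MNLR-E"), collapse = ", "))
  }
  store[[name]]
}

#' @rdname published_model
#' @export
published_model_names <- function() names(.published_store())
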