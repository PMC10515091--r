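# Goodness of fit, fit-set / holdout verification, and model ranking.

#' Coefficient of determination
#'
#' Two conventions are supported: `one_minus_sse` (the default),
#' `1 - SSE/SST`, and `regression_ss`, the ratio of the regression sum of
#' squares to the total sum of squares, `sum((pred - mean(actual))^2) /
#' sum((actual - mean(actual))^2)`. The two coincide for least-squares
#' linear fits with an intercept but can diverge for nonlinear or external
#' predictions.
#'
#' @param actual Observed values (n >= 2, non-zero variance).
#' @param predicted Predicted values, same length.
#' @param method `"one_minus_sse"` or `"regression_ss"`.
#' @return R-squared under the requested convention.
#' @export
#' @examples
#' r_squared(c(1, 2, 3), c(1, 2, 4))  # 0.5
r_squared <- function(actual, predicted,
                      method = c("one_minus_sse", "regression_ss")) {
  method <- match.arg(method)
  ok <- !is.na(actual) & !is.na(predicted)
  actual <- actual[ok]; predicted <- predicted[ok]
  if (length(actual) < 2) stop("need at least 2 paired values")
  sst <- sum((actual - mean(actual))^2)
  if (sst == 0) stop("zero total sum of squares: actual values are constant")
  if (method == "one_minus_sse") {
    1 - sum((actual - predicted)^2) / sst
  } else {
    sum((predicted - mean(actual))^2) / sst
  }
}

#' Verify zone models on fit and holdout species
#'
#' Predicts every species in the fit and holdout tables with every model,
#' and summarises training R-squared, rounded-zone agreement and ranking.
#' Models are ranked by fit-set R-squared; ties are broken by holdout
#' exact-match count. Following the convention for very small holdout sets,
#' holdout performance is reported as prediction error and exact-match
#' counts rather than R-squared when the holdout has fewer than 5 species.
#'
#' @param models Named list of `zone_model` objects.
#' @param fit_table Data frame with `species_id`, a `zone` column, and the
#'   indicator (or score) columns each model needs.
#' @param holdout_table As `fit_table`, for species not used in fitting;
#'   may be `NULL`. Holdout species must be disjoint from fit species.
#' @param r2_method Passed to [r_squared()].
#' @return Object of class `verification_report`: `summary` (one row per
#'   model) and `predictions` (one row per model x species).
#' @export
verify_models <- function(models, fit_table, holdout_table = NULL,
                          r2_method = "one_minus_sse") {
  stopifnot(is.list(models), length(models) > 0, !is.null(names(models)))
  stopifnot(all(c("species_id", "zone") %in% names(fit_table)))
  if (!is.null(holdout_table)) {
    overlap <- intersect(fit_table$species_id, holdout_table$species_id)
    if (length(overlap) > 0) {
      stop("holdout species overlap the fit set: ",
           paste(overlap, collapse = ", "))
    }
  }

  predict_set <- function(model, tab, set) {
    if (is.null(tab) || nrow(tab) == 0) return(NULL)
    complete <- stats::complete.cases(tab[, setdiff(names(tab), "zone")])
    if (any(!complete)) {
      message("excluding ", sum(!complete),
              " species with missing indicators from the ", set, " set")
      tab <- tab[complete, , drop = FALSE]
    }
    pred <- predict_zone(model, tab)
    data.frame(set = set, species_id = tab$species_id,
               actual = tab$zone, predicted = pred,
               rounded = round_zone(pred), stringsAsFactors = FALSE)
  }

  all_pred <- list()
  rows <- lapply(names(models), function(nm) {
    m <- models[[nm]]
    pf <- predict_set(m, fit_table, "fit")
    ph <- predict_set(m, holdout_table, "holdout")
    both <- rbind(pf, ph)
    both$model <- nm
    all_pred[[nm]] <<- both
    holdout_n <- if (is.null(ph)) 0L else nrow(ph)
    r2_main <- r_squared(pf$actual, pf$predicted, r2_method)
    r2_other <- r_squared(pf$actual, pf$predicted,
                          setdiff(c("one_minus_sse", "regression_ss"),
                                  r2_method))
    data.frame(
      model = nm,
      fit_r2 = r2_main,
      fit_r2_alt = r2_other,
      r2_divergent = abs(r2_main - r2_other) > 0.01,
      fit_match = sum(pf$rounded == pf$actual),
      fit_n = nrow(pf),
      holdout_match = if (holdout_n > 0) sum(ph$rounded == ph$actual) else NA_integer_,
      holdout_n = holdout_n,
      holdout_mae = if (holdout_n > 0) mean(abs(ph$predicted - ph$actual)) else NA_real_,
      holdout_r2 = if (holdout_n >= 5)
        r_squared(ph$actual, ph$predicted, r2_method) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  summary <- do.call(rbind, rows)
  hm <- ifelse(is.na(summary$holdout_match), -Inf, summary$holdout_match)
  ord <- order(-summary$fit_r2, -hm, summary$model)
  summary <- summary[ord, , drop = FALSE]
  summary$rank <- seq_len(nrow(summary))
  rownames(summary) <- NULL
  structure(list(summary = summary,
                 predictions = do.call(rbind, all_pred)),
            class = "verification_report")
}

#' Render a verification report as an ordered summary table
#'
#' @param report A `verification_report` from [verify_models()].
#' @param path Optional CSV output path.
#' @return The summary data frame (invisibly if written to `path`).
#' @export
ranking_report <- function(report, path = NULL) {
  stopifnot(inherits(report, "verification_report"))
  out <- report$summary
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' @export
print.verification_report <- function(x, ...) {
  cat("Model verification (", nrow(x$summary), " model(s))\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
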