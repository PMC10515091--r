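# Stability (CV) and correlation screening of leaf indicators.

#' Coefficient of variation, in percent
#'
#' 100 * sample standard deviation / mean. The sample SD (n - 1 denominator)
#' is used throughout the package.
#'
#' @param values Numeric sample, n >= 2, with non-zero mean.
#' @return CV in percent.
#' @export
#' @examples
#' coefficient_of_variation(c(8, 12))  # 28.28
coefficient_of_variation <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stop("need at least 2 values for a CV")
  m <- mean(values)
  if (m == 0) stop("CV undefined for zero mean")
  100 * stats::sd(values) / m
}

#' Classify a CV into variation levels
#'
#' Weak variation for CV in \[0, 15), middle for \[15, 35), strong for
#' \[35, Inf). Bins are left-closed.
#'
#' @param cv CV in percent (>= 0); vectorised.
#' @return Factor with levels `weak`, `middle`, `strong`.
#' @export
classify_variation <- function(cv) {
  if (any(cv < 0, na.rm = TRUE)) stop("CV must be non-negative")
  cut(cv, breaks = c(0, 15, 35, Inf), labels = c("weak", "middle", "strong"),
      right = FALSE, include.lowest = TRUE)
}

#' Classify a correlation coefficient by magnitude
#'
#' High correlation for |r| >= 0.8, moderate for 0.5 <= |r| < 0.8, weak for
#' 0.3 <= |r| < 0.5, extremely weak for |r| < 0.3.
#'
#' @param r Correlation coefficient(s) in \[-1, 1\].
#' @return Factor with levels `extremely_weak`, `weak`, `moderate`, `high`.
#' @export
classify_correlation <- function(r) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) stop("|r| cannot exceed 1")
  cut(pmin(abs(r), 1), breaks = c(0, 0.3, 0.5, 0.8, Inf),
      labels = c("extremely_weak", "weak", "moderate", "high"),
      right = FALSE, include.lowest = TRUE)
}

# Shared engine for seasonal/regional stability: per species-indicator CV
# across stratum means, then the per-indicator summary is the arithmetic
# mean of species CVs.
.stability <- function(table, stratum_col, species = NULL, label = "stratum") {
  stopifnot(is.data.frame(table), all(c("species_id", "indicator", "mean",
                                        stratum_col) %in% names(table)))
  if (!is.null(species)) {
    table <- table[table$species_id %in% species, , drop = FALSE]
  }
  if (nrow(table) == 0) stop("no rows for the requested species subset")

  # stratum-level mean per species x indicator x stratum (averages away any
  # other stratifier present in the table)
  f <- stats::aggregate(
    mean ~ species_id + indicator + table[[stratum_col]],
    data = data.frame(table, check.names = FALSE), FUN = mean
  )
  names(f)[3] <- stratum_col

  counts <- table(unique(f[, c("species_id", stratum_col)])$species_id)
  single <- names(counts)[counts < 2]
  if (length(single) > 0) {
    message("skipping species with a single ", label, ": ",
            paste(single, collapse = ", "))
    f <- f[!f$species_id %in% single, , drop = FALSE]
  }
  if (nrow(f) == 0) stop("no species observed in more than one ", label)

  per_species <- stats::aggregate(
    mean ~ species_id + indicator, data = f,
    FUN = function(v) if (length(v) < 2) NA_real_ else coefficient_of_variation(v)
  )
  names(per_species)[3] <- "cv"
  per_species <- per_species[!is.na(per_species$cv), , drop = FALSE]

  summary <- stats::aggregate(cv ~ indicator, data = per_species, FUN = mean)
  n_species <- stats::aggregate(species_id ~ indicator, data = per_species,
                                FUN = function(s) length(unique(s)))
  out <- merge(summary, n_species, by = "indicator")
  names(out)[3] <- "n_species"
  out$class <- classify_variation(out$cv)
  out <- out[order(match(out$indicator, .indicator_report_order())), ]
  rownames(out) <- NULL
  attr(out, "per_species") <- per_species
  out
}

#' Seasonal stability of indicators
#'
#' For each species observed in at least two seasons, the CV of its
#' season-level indicator means is computed; the per-indicator summary is
#' the arithmetic mean of species CVs, classified with
#' [classify_variation()]. Species seen in a single season are skipped with
#' a message.
#'
#' @param table A `species_indicator_table` stratified by season.
#' @param species Optional species subset.
#' @return Data frame with `indicator`, `cv`, `n_species`, `class`; the
#'   per-species CVs are attached as attribute `"per_species"` for audit.
#' @export
seasonal_stability <- function(table, species = NULL) {
  .stability(table, "season", species, label = "season")
}

#' Regional stability of indicators
#'
#' As [seasonal_stability()], across region-level means.
#'
#' @inheritParams seasonal_stability
#' @return Data frame with `indicator`, `cv`, `n_species`, `class`.
#' @export
regional_stability <- function(table, species = NULL) {
  .stability(table, "region_id", species, label = "region")
}

#' Correlate species indicator means with distribution zones
#'
#' Product-moment correlation of species-level indicator means against the
#' species' northernmost distribution zones, with a two-sided p value from
#' the t distribution on n - 2 degrees of freedom. Missing values are
#' removed pairwise. Zero-variance indicators are excluded with a message
#' (their r is undefined).
#'
#' @param table A `species_indicator_table`.
#' @param zones Named numeric vector of zones keyed by `species_id`.
#' @param season,region Optional stratum filters; correlation screening is
#'   conventionally restricted to a single season and region so that
#'   environmental variation does not dilute the zone signal.
#' @return Data frame with `indicator`, `r`, `p`, `n`, `r_class`.
#' @export
correlate_with_zone <- function(table, zones, season = NULL, region = NULL) {
  wide <- species_means_wide(table, season = season, region = region)
  zone <- zones[wide$species_id]
  keep <- !is.na(zone)
  wide <- wide[keep, , drop = FALSE]
  zone <- zone[keep]
  if (length(zone) < 3) stop("need at least 3 species with zones")

  ids <- setdiff(names(wide), "species_id")
  rows <- lapply(ids, function(id) {
    x <- wide[[id]]
    ok <- !is.na(x)
    n <- sum(ok)
    if (n < 3) return(NULL)
    if (stats::sd(x[ok]) == 0 || stats::sd(zone[ok]) == 0) {
      message("indicator '", id, "' has zero variance; correlation undefined")
      return(NULL)
    }
    r <- stats::cor(x[ok], zone[ok])
    tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
    data.frame(indicator = id, r = r, p = p, n = n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0) stop("no indicator had a defined correlation")
  out$r_class <- classify_correlation(out$r)
  out <- out[order(match(out$indicator, .indicator_report_order())), ]
  rownames(out) <- NULL
  out
}

#' Assemble a screening report
#'
#' Combines seasonal and regional CV screening with zone-correlation
#' screening into one per-indicator report, and flags the selected model
#' indicator sets (see [select_model_indicators()]).
#'
#' @param seasonal Output of [seasonal_stability()], or `NULL` if seasonal
#'   data are unavailable.
#' @param regional Output of [regional_stability()], or `NULL`.
#' @param correlation Output of [correlate_with_zone()].
#' @param alpha Significance threshold for the zone correlation.
#' @param cv_cutoff CV (percent) at and above which an indicator counts as
#'   strong-variation and is rejected.
#' @return Data frame of class `screening_report` with one row per
#'   indicator: `seasonal_cv`, `seasonal_class`, `regional_cv`,
#'   `regional_class`, `r`, `p`, `n`, `r_class`, `selected_full`,
#'   `selected_E`.
#' @export
screen_indicators <- function(seasonal = NULL, regional = NULL, correlation,
                              alpha = 0.05, cv_cutoff = 35) {
  stopifnot(is.data.frame(correlation))
  report <- data.frame(indicator = correlation$indicator,
                       r = correlation$r, p = correlation$p,
                       n = correlation$n, r_class = correlation$r_class,
                       stringsAsFactors = FALSE)
  .merge_cv <- function(report, cv_tab, prefix) {
    if (is.null(cv_tab)) {
      report[[paste0(prefix, "_cv")]] <- NA_real_
      report[[paste0(prefix, "_class")]] <- NA_character_
    } else {
      idx <- match(report$indicator, cv_tab$indicator)
      report[[paste0(prefix, "_cv")]] <- cv_tab$cv[idx]
      report[[paste0(prefix, "_class")]] <- as.character(cv_tab$class)[idx]
    }
    report
  }
  report <- .merge_cv(report, seasonal, "seasonal")
  report <- .merge_cv(report, regional, "regional")

  sel <- select_model_indicators(report, alpha = alpha, cv_cutoff = cv_cutoff)
  report$selected_full <- report$indicator %in% sel$full_set
  report$selected_E <- report$indicator %in% sel$e_set
  report <- report[order(match(report$indicator, .indicator_report_order())), ]
  rownames(report) <- NULL
  class(report) <- c("screening_report", "data.frame")
  report
}

#' Select model indicator sets from a screening report
#'
#' The full set keeps indicators significantly correlated with zone
#' (p < `alpha`) whose seasonal and regional variation is below the strong
#' level (CV < `cv_cutoff`); an unknown (NA) CV does not exclude an
#' indicator. The reduced "E" set additionally drops indicators with
#' extremely weak correlation (|r| < 0.3). Both sets are returned in
#' canonical order (x1..x13 first, then panel order), so the selection is
#' idempotent and `e_set` is always a subset of `full_set`.
#'
#' @param report Data frame with columns `indicator`, `p`, `r_class` and
#'   (optionally) `seasonal_class`, `regional_class` — e.g. a
#'   `screening_report` or the bare correlation/CV columns.
#' @param alpha Significance threshold (default 0.05, uncorrected; pass
#'   p.adjusted values for a Benjamini-Hochberg variant).
#' @param cv_cutoff Strong-variation CV threshold in percent.
#' @return List with character vectors `full_set` and `e_set`.
#' @export
select_model_indicators <- function(report, alpha = 0.05, cv_cutoff = 35) {
  stopifnot(is.data.frame(report),
            all(c("indicator", "p", "r_class") %in% names(report)))
  strong_of <- function(col) {
    if (!col %in% names(report)) return(rep(FALSE, nrow(report)))
    cls <- as.character(report[[col]])
    cv_col <- sub("_class$", "_cv", col)
    if (cv_col %in% names(report)) {
      cv <- report[[cv_col]]
      ifelse(!is.na(cv), cv >= cv_cutoff,
             !is.na(cls) & cls == "strong")
    } else {
      !is.na(cls) & cls == "strong"
    }
  }
  significant <- !is.na(report$p) & report$p < alpha
  strong <- strong_of("seasonal_class") | strong_of("regional_class")
  full <- report$indicator[significant & !strong]
  if (length(full) == 0) {
    stop("no indicator passed screening; review alpha (", alpha,
         ") and cv_cutoff (", cv_cutoff, ")")
  }
  ew <- as.character(report$r_class)[match(full, report$indicator)]
  e_set <- full[is.na(ew) | ew != "extremely_weak"]
  ord <- .indicator_report_order()
  # unknown indicators (e.g. PC scores) keep their incoming order after the
  # canonical panel
  rank_of <- function(x) {
    m <- match(x, ord)
    m[is.na(m)] <- length(ord) + seq_len(sum(is.na(m)))
    m
  }
  list(full_set = full[order(rank_of(full))],
       e_set = e_set[order(rank_of(e_set))])
}
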