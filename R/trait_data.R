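#' leafzone: leaf-trait screening and distribution-zone prediction
#'
#' Predicts the northernmost hardiness zone (an integer 1-12, zone 1 coldest)
#' that a bamboo species can occupy, from morphological and anatomical leaf
#' indicators. The workflow is: derive a 33-indicator panel from per-leaf
#' measurements ([compute_indicator_panel()]), aggregate to species means
#' ([aggregate_species_table()]), screen indicators for seasonal/regional
#' stability and zone correlation ([screen_indicators()]), and fit zone
#' predictors ([fit_mlr()], [fit_mnlr()], [fit_pca_mlr()], [fit_pca_mnlr()]).
#' The fitted equations published for this system are available via
#' [published_model()]; [generate_study()] produces synthetic datasets with
#' known ground truth for benchmarking.
#'
#' @keywords internal
"_PACKAGE"

# ---------------------------------------------------------------------------
# Indicator vocabulary
# ---------------------------------------------------------------------------

# Raw measurement columns of a leaf record. Thickness columns are kept on the
# printed micrometre-magnitude scale of the source tables and never converted;
# all derived ratios are therefore on the same numeric scale as the published
# fitted equations.
.measurement_columns <- c(
  "leaf_length", "leaf_width", "leaf_area",
  "vein_count", "vein_span_width",
  "stomata_count", "stomata_field_area",
  "leaf_thickness",
  "adaxial_cuticle_thickness", "abaxial_cuticle_thickness",
  "adaxial_epidermis_thickness", "abaxial_epidermis_thickness",
  "mesophyll_thickness"
)

.key_columns <- c("species_id", "season", "region_id")

# vein_span_width has a documented fallback (leaf_width mm -> cm), so it is
# the only optional measurement column.
.mandatory_columns <- setdiff(c(.key_columns, .measurement_columns),
                              "vein_span_width")

#' Identifiers of the full leaf-indicator panel
#'
#' Returns the 33 indicator identifiers in canonical order: raw morphology
#' and anatomy first, then ratios to leaf thickness, then ratios to leaf
#' area. Thickness-derived indicators are expressed on the printed scale of
#' the source anatomy tables (micrometre magnitude), lengths and widths in
#' mm, areas in mm^2; ratio indicators inherit those scales.
#'
#' @return Character vector of length 33.
#' @seealso [model_indicators()] for the 13-indicator modelling subset.
#' @export
#' @examples
#' indicator_panel_ids()
indicator_panel_ids <- function() {
  c(
    "vein_density", "stomatal_density",
    "leaf_length", "leaf_width", "leaf_area", "length_width_ratio",
    "leaf_thickness",
    "adaxial_cuticle", "abaxial_cuticle", "total_cuticle",
    "adaxial_epidermis", "abaxial_epidermis", "total_epidermis",
    "mesophyll",
    "length_per_thickness", "width_per_thickness",
    "adaxial_cuticle_per_thickness", "abaxial_cuticle_per_thickness",
    "total_cuticle_per_thickness",
    "adaxial_epidermis_per_thickness", "abaxial_epidermis_per_thickness",
    "total_epidermis_per_thickness",
    "mesophyll_per_thickness",
    "length_per_area", "width_per_area", "thickness_per_area",
    "adaxial_cuticle_per_area", "abaxial_cuticle_per_area",
    "total_cuticle_per_area",
    "adaxial_epidermis_per_area", "abaxial_epidermis_per_area",
    "total_epidermis_per_area",
    "mesophyll_per_area"
  )
}

#' The 13 modelling indicators and their x-symbols
#'
#' The regression models use a fixed subset of the panel, conventionally
#' written x1..x13: x1 vein density, x2 leaf length, x3 leaf width, x4
#' adaxial epidermis thickness, x5 total epidermis thickness, x6 leaf
#' length/leaf thickness, x7 leaf width/leaf thickness, x8 adaxial epidermis
#' thickness/leaf thickness, x9 total epidermis thickness/leaf thickness,
#' x10 leaf length/leaf area, x11 leaf width/leaf area, x12 adaxial
#' cuticle/leaf area, x13 total cuticle thickness/leaf area.
#'
#' @return Named character vector; names are `x1`..`x13`, values are panel
#'   indicator identifiers.
#' @export
#' @examples
#' model_indicators()[["x6"]]
model_indicators <- function() {
  c(
    x1 = "vein_density",
    x2 = "leaf_length",
    x3 = "leaf_width",
    x4 = "adaxial_epidermis",
    x5 = "total_epidermis",
    x6 = "length_per_thickness",
    x7 = "width_per_thickness",
    x8 = "adaxial_epidermis_per_thickness",
    x9 = "total_epidermis_per_thickness",
    x10 = "length_per_area",
    x11 = "width_per_area",
    x12 = "adaxial_cuticle_per_area",
    x13 = "total_cuticle_per_area"
  )
}

# Canonical ordering used for reporting selected sets: x1..x13 first, then
# the remaining panel indicators in panel order.
.indicator_report_order <- function() {
  mod <- unname(model_indicators())
  c(mod, setdiff(indicator_panel_ids(), mod))
}

# ---------------------------------------------------------------------------
# Derived densities
# ---------------------------------------------------------------------------

#' Vein density of a leaf
#'
#' Number of veins counted across a transverse span of the blade, divided by
#' that span in cm.
#'
#' @param vein_count Number of veins counted (>= 0).
#' @param vein_span_width Width of the counting span in cm (> 0).
#' @return Vein density, veins per cm.
#' @export
#' @examples
#' derive_vein_density(20, 2.5)
derive_vein_density <- function(vein_count, vein_span_width) {
  stopifnot(is.numeric(vein_count), is.numeric(vein_span_width))
  if (any(vein_count < 0, na.rm = TRUE)) {
    stop("vein_count must be non-negative")
  }
  if (any(vein_span_width <= 0, na.rm = TRUE)) {
    stop("vein_span_width must be positive")
  }
  vein_count / vein_span_width
}

#' Stomatal density of a leaf
#'
#' Number of stomata in a microscope field divided by the field area in mm^2.
#'
#' @param stomata_count Number of stomata counted (>= 0).
#' @param field_area Field area in mm^2 (> 0).
#' @return Stomatal density, stomata per mm^2.
#' @export
#' @examples
#' derive_stomatal_density(100, 0.25)
derive_stomatal_density <- function(stomata_count, field_area) {
  stopifnot(is.numeric(stomata_count), is.numeric(field_area))
  if (any(stomata_count < 0, na.rm = TRUE)) {
    stop("stomata_count must be non-negative")
  }
  if (any(field_area <= 0, na.rm = TRUE)) {
    stop("field_area must be positive")
  }
  stomata_count / field_area
}

# ---------------------------------------------------------------------------
# Indicator panel
# ---------------------------------------------------------------------------

#' Compute the full indicator panel from leaf records
#'
#' Derives all 33 panel indicators for each leaf. Composite thicknesses are
#' sums of their parts (total cuticle = adaxial + abaxial cuticle; total
#' epidermis = adaxial + abaxial epidermis). Ratios are taken on the raw
#' numeric scales of the measurements, so e.g. `length_per_thickness` for a
#' 150 mm blade of thickness 130 (printed units) is 150/130.
#'
#' If `vein_span_width` is absent or NA, the span falls back to
#' `leaf_width`/10 (mm to cm) with a message. Missing measurements propagate
#' to NA indicator values; they are never imputed.
#'
#' @param records Data frame of leaf records with the columns of
#'   [read_trait_csv()].
#' @return Data frame with `species_id`, `season`, `region_id` and one column
#'   per panel indicator, one row per leaf.
#' @export
#' @examples
#' rec <- data.frame(
#'   species_id = "sp1", season = "winter", region_id = "KM",
#'   leaf_length = 150, leaf_width = 17, leaf_area = 2000,
#'   vein_count = 120, vein_span_width = 1.7,
#'   stomata_count = 60, stomata_field_area = 0.15,
#'   leaf_thickness = 130, adaxial_cuticle_thickness = 4,
#'   abaxial_cuticle_thickness = 3, adaxial_epidermis_thickness = 11,
#'   abaxial_epidermis_thickness = 7, mesophyll_thickness = 100
#' )
#' compute_indicator_panel(rec)$length_per_thickness
compute_indicator_panel <- function(records) {
  records <- .validate_leaf_records(records)
  if (any(records$leaf_thickness <= 0, na.rm = TRUE)) {
    stop("leaf_thickness must be positive")
  }
  if (any(records$leaf_area <= 0, na.rm = TRUE)) {
    stop("leaf_area must be positive")
  }

  span <- records$vein_span_width
  if (anyNA(span)) {
    message(sum(is.na(span)),
            " leaf record(s) lack vein_span_width; using leaf_width/10 (cm)")
    span[is.na(span)] <- records$leaf_width[is.na(span)] / 10
  }

  thick <- records$leaf_thickness
  area <- records$leaf_area
  cut_ad <- records$adaxial_cuticle_thickness
  cut_ab <- records$abaxial_cuticle_thickness
  epi_ad <- records$adaxial_epidermis_thickness
  epi_ab <- records$abaxial_epidermis_thickness

  out <- data.frame(
    species_id = records$species_id,
    season = records$season,
    region_id = records$region_id,
    vein_density = derive_vein_density(records$vein_count, span),
    stomatal_density = derive_stomatal_density(records$stomata_count,
                                               records$stomata_field_area),
    leaf_length = records$leaf_length,
    leaf_width = records$leaf_width,
    leaf_area = area,
    length_width_ratio = records$leaf_length / records$leaf_width,
    leaf_thickness = thick,
    adaxial_cuticle = cut_ad,
    abaxial_cuticle = cut_ab,
    total_cuticle = cut_ad + cut_ab,
    adaxial_epidermis = epi_ad,
    abaxial_epidermis = epi_ab,
    total_epidermis = epi_ad + epi_ab,
    mesophyll = records$mesophyll_thickness,
    stringsAsFactors = FALSE
  )

  per_thickness <- c(
    length_per_thickness = "leaf_length",
    width_per_thickness = "leaf_width",
    adaxial_cuticle_per_thickness = "adaxial_cuticle",
    abaxial_cuticle_per_thickness = "abaxial_cuticle",
    total_cuticle_per_thickness = "total_cuticle",
    adaxial_epidermis_per_thickness = "adaxial_epidermis",
    abaxial_epidermis_per_thickness = "abaxial_epidermis",
    total_epidermis_per_thickness = "total_epidermis",
    mesophyll_per_thickness = "mesophyll"
  )
  for (nm in names(per_thickness)) {
    out[[nm]] <- out[[per_thickness[[nm]]]] / thick
  }

  per_area <- c(
    length_per_area = "leaf_length",
    width_per_area = "leaf_width",
    thickness_per_area = "leaf_thickness",
    adaxial_cuticle_per_area = "adaxial_cuticle",
    abaxial_cuticle_per_area = "abaxial_cuticle",
    total_cuticle_per_area = "total_cuticle",
    adaxial_epidermis_per_area = "adaxial_epidermis",
    abaxial_epidermis_per_area = "abaxial_epidermis",
    total_epidermis_per_area = "total_epidermis",
    mesophyll_per_area = "mesophyll"
  )
  for (nm in names(per_area)) {
    out[[nm]] <- out[[per_area[[nm]]]] / area
  }

  out[, c(.key_columns, indicator_panel_ids())]
}

.validate_leaf_records <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    stop("records must be a non-empty data frame of leaf measurements")
  }
  missing_cols <- setdiff(.mandatory_columns, names(records))
  if (length(missing_cols) > 0) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!"vein_span_width" %in% names(records)) {
    records$vein_span_width <- NA_real_
  }
  num_cols <- intersect(.measurement_columns, names(records))
  for (cl in num_cols) {
    records[[cl]] <- as.numeric(records[[cl]])
  }
  records
}

# ---------------------------------------------------------------------------
# Species-level aggregation
# ---------------------------------------------------------------------------

#' Aggregate per-leaf indicators to species means
#'
#' Collapses a per-leaf indicator table to group means, sample standard
#' deviations (n - 1 denominator) and counts, grouped by species and
#' optionally season and/or region.
#'
#' @param panel Per-leaf indicator table from [compute_indicator_panel()],
#'   or raw leaf records (which are converted first).
#' @param group_by Character subset of `c("season", "region")` giving the
#'   stratification kept alongside species.
#' @return A long-format data frame of class `species_indicator_table` with
#'   columns `species_id`, `season`, `region_id`, `indicator`, `mean`, `sd`,
#'   `n`. Groups collapsed over a stratifier carry `"all"` in its column.
#' @export
aggregate_species_table <- function(panel, group_by = c("season", "region")) {
  if (!is.data.frame(panel) || nrow(panel) == 0) {
    stop("panel must be a non-empty data frame")
  }
  if (!all(indicator_panel_ids() %in% names(panel))) {
    panel <- compute_indicator_panel(panel)
  }
  stopifnot(all(group_by %in% c("season", "region")))

  season <- if ("season" %in% group_by) as.character(panel$season) else "all"
  region <- if ("region" %in% group_by) as.character(panel$region_id) else "all"
  key <- interaction(panel$species_id, season, region, drop = TRUE)

  ids <- indicator_panel_ids()
  groups <- split(seq_len(nrow(panel)), key)
  rows <- lapply(groups, function(idx) {
    sub <- panel[idx, , drop = FALSE]
    means <- vapply(ids, function(i) mean(sub[[i]], na.rm = TRUE), numeric(1))
    ns <- vapply(ids, function(i) sum(!is.na(sub[[i]])), numeric(1))
    sds <- vapply(ids, function(i) {
      v <- sub[[i]][!is.na(sub[[i]])]
      if (length(v) <= 1) 0 else stats::sd(v)
    }, numeric(1))
    data.frame(
      species_id = sub$species_id[1],
      season = if ("season" %in% group_by) as.character(sub$season[1]) else "all",
      region_id = if ("region" %in% group_by) as.character(sub$region_id[1]) else "all",
      indicator = ids,
      mean = unname(means),
      sd = unname(sds),
      n = unname(ns),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("species_indicator_table", "data.frame")
  out
}

#' Reshape a species indicator table to wide species-by-indicator means
#'
#' @param table A `species_indicator_table`.
#' @param season,region Optional stratum filters; `NULL` keeps all rows
#'   (means are then averaged over strata per species).
#' @param indicators Indicator identifiers to keep (default: full panel).
#' @return Data frame with `species_id` and one mean column per indicator.
#' @export
species_means_wide <- function(table, season = NULL, region = NULL,
                               indicators = indicator_panel_ids()) {
  stopifnot(inherits(table, "species_indicator_table") || is.data.frame(table))
  tab <- table
  if (!is.null(season)) tab <- tab[tab$season %in% season, , drop = FALSE]
  if (!is.null(region)) tab <- tab[tab$region_id %in% region, , drop = FALSE]
  tab <- tab[tab$indicator %in% indicators, , drop = FALSE]
  if (nrow(tab) == 0) stop("no rows left after filtering")
  agg <- stats::aggregate(mean ~ species_id + indicator, data = tab, FUN = mean)
  wide <- stats::reshape(agg, idvar = "species_id", timevar = "indicator",
                         direction = "wide")
  names(wide) <- sub("^mean\\.", "", names(wide))
  keep <- c("species_id", intersect(indicators, names(wide)))
  wide <- wide[, keep, drop = FALSE]
  rownames(wide) <- NULL
  wide
}

# ---------------------------------------------------------------------------
# CSV I/O
# ---------------------------------------------------------------------------

#' Read a per-leaf trait table from CSV
#'
#' The file must contain one row per leaf with the documented header:
#' `species_id`, `season`, `region_id`, `leaf_length` (mm), `leaf_width`
#' (mm), `leaf_area` (mm^2), `vein_count`, `vein_span_width` (cm, optional),
#' `stomata_count`, `stomata_field_area` (mm^2), `leaf_thickness`,
#' `adaxial_cuticle_thickness`, `abaxial_cuticle_thickness`,
#' `adaxial_epidermis_thickness`, `abaxial_epidermis_thickness`,
#' `mesophyll_thickness` (printed anatomy-table units). Unknown extra
#' columns are preserved.
#'
#' @param path Path to a CSV file.
#' @return Data frame of leaf records.
#' @export
read_trait_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  records <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(records) == 0) stop("empty trait table: ", path)
  .validate_leaf_records(records)
}

#' Write a trait or indicator table to CSV
#'
#' Round-trips losslessly with [read_trait_csv()] for the declared columns.
#'
#' @param table Data frame to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(table, path) {
  stopifnot(is.data.frame(table))
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Read a species-to-zone table from CSV
#'
#' @param path CSV with columns `species_id` and `zone` (integer 1-12).
#' @return Named numeric vector of zones keyed by species.
#' @export
read_zone_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("species_id", "zone"), names(tab))
  if (length(missing_cols) > 0) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  zone <- as.numeric(tab$zone)
  if (any(zone < 1 | zone > 12, na.rm = TRUE)) {
    stop("zones must lie in [1, 12]")
  }
  stats::setNames(zone, tab$species_id)
}
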