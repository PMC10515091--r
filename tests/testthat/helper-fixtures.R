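# Shared fixtures, built in code.

# one fully specified leaf record, with overridable fields
make_leaf <- function(...) {
  rec <- data.frame(
    species_id = "sp1", season = "winter", region_id = "KM",
    leaf_length = 150, leaf_width = 17, leaf_area = 2000,
    vein_count = 120, vein_span_width = 1.7,
    stomata_count = 60, stomata_field_area = 0.15,
    leaf_thickness = 130,
    adaxial_cuticle_thickness = 4, abaxial_cuticle_thickness = 3,
    adaxial_epidermis_thickness = 11, abaxial_epidermis_thickness = 7,
    mesophyll_thickness = 100,
    stringsAsFactors = FALSE
  )
  dots <- list(...)
  for (nm in names(dots)) rec[[nm]] <- dots[[nm]]
  rec
}

# a small multi-species, multi-stratum leaf table with per-trait values
# supplied as a function(species index, season, region) -> multiplier
make_leaf_set <- function(species = c("a", "b", "c"),
                          seasons = "winter", regions = "KM",
                          n_per_group = 1, value_fn = NULL) {
  rows <- list()
  for (sp in seq_along(species)) {
    for (se in seasons) {
      for (re in regions) {
        for (k in seq_len(n_per_group)) {
          f <- if (is.null(value_fn)) 1 else value_fn(sp, se, re)
          rows[[length(rows) + 1]] <- make_leaf(
            species_id = species[sp], season = se, region_id = re,
            leaf_length = 150 * f, leaf_width = 17 * f, leaf_area = 2000 * f,
            leaf_thickness = 130 * f,
            adaxial_cuticle_thickness = 4 * f,
            abaxial_cuticle_thickness = 3 * f,
            adaxial_epidermis_thickness = 11 * f,
            abaxial_epidermis_thickness = 7 * f,
            mesophyll_thickness = 100 * f,
            vein_count = 120 * f, stomata_count = 60 * f
          )
        }
      }
    }
  }
  do.call(rbind, rows)
}

# tiny fast analogue config for pipeline tests
small_analogue <- function(leaf_cv = 0.1, species_cv = 0.08,
                           leaves = 8) {
  cfg <- paper_analogue_config(leaf_cv = leaf_cv, species_cv = species_cv)
  cfg$leaves_per_species <- leaves
  cfg
}

# brute-force sample CV oracle, independent of the package's helper
oracle_cv <- function(v) {
  m <- sum(v) / length(v)
  s <- sqrt(sum((v - m)^2) / (length(v) - 1))
  100 * s / m
}
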