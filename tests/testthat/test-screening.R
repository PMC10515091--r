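test_that("coefficient of variation uses sample SD over mean, in percent", {
  expect_equal(coefficient_of_variation(c(5, 5, 5)), 0)
  expect_equal(coefficient_of_variation(c(8, 12)), oracle_cv(c(8, 12)))
  expect_equal(coefficient_of_variation(c(1, 2, 3)), 50)
  expect_error(coefficient_of_variation(7), "at least 2")
  expect_error(coefficient_of_variation(c(-1, 1)), "zero mean")
})

test_that("CV is scale invariant", {
  set.seed(42)
  for (i in 1:25) {
    v <- rlnorm(sample(3:30, 1), 2, 0.4)
    c <- runif(1, 0.01, 100)
    expect_equal(coefficient_of_variation(c * v), coefficient_of_variation(v))
  }
})

test_that("variation classes use left-closed bins at 15 and 35", {
  expect_equal(as.character(classify_variation(c(10, 20, 40))),
               c("weak", "middle", "strong"))
  expect_equal(as.character(classify_variation(c(0, 15, 35, 34.999))),
               c("weak", "middle", "strong", "middle"))
  expect_error(classify_variation(-1), "non-negative")
})

test_that("classification pipeline agrees with a brute-force oracle", {
  set.seed(77)
  for (i in 1:100) {
    v <- rlnorm(sample(5:40, 1), meanlog = 3, sdlog = runif(1, 0.01, 0.8))
    cv <- oracle_cv(v)
    want <- if (cv < 15) "weak" else if (cv < 35) "middle" else "strong"
    expect_equal(
      as.character(classify_variation(coefficient_of_variation(v))), want)
  }
})

test_that("correlation classes follow the |r| bins", {
  expect_equal(as.character(classify_correlation(c(0.85, 0.25, 0.3, -0.5, 0.8))),
               c("high", "extremely_weak", "weak", "moderate", "high"))
  expect_error(classify_correlation(1.2), "exceed")
})

test_that("seasonal stability averages per-species two-point CVs", {
  # identical season means -> zero CV, weak
  flat <- make_leaf_set(seasons = c("winter", "summer"))
  tabf <- aggregate_species_table(flat)
  sf <- seasonal_stability(tabf)
  expect_true(all(sf$cv == 0))
  expect_true(all(sf$class == "weak"))

  # planted 1.30x winter->summer multiplier on every trait
  lifted <- make_leaf_set(seasons = c("winter", "summer"),
                          value_fn = function(sp, se, re)
                            if (se == "summer") 1.3 else 1)
  sl <- seasonal_stability(aggregate_species_table(lifted))
  expect_equal(sl$cv[sl$indicator == "leaf_length"], oracle_cv(c(1, 1.3)),
               tolerance = 1e-10)

  # summary equals the hand-averaged species CVs for 3 species with
  # different seasonal shifts
  mult <- c(a = 1.1, b = 1.25, c = 1.4)
  mixed <- make_leaf_set(seasons = c("winter", "summer"),
                         value_fn = function(sp, se, re)
                           if (se == "summer") mult[[sp]] else 1)
  sm <- seasonal_stability(aggregate_species_table(mixed))
  want <- mean(vapply(mult, function(m) oracle_cv(c(1, m)), numeric(1)))
  expect_equal(sm$cv[sm$indicator == "leaf_length"], want, tolerance = 1e-10)

  # single-season species are skipped with a message
  partial <- rbind(mixed, make_leaf(species_id = "d"))
  expect_message(seasonal_stability(aggregate_species_table(partial)),
                 "single season")
})

test_that("regional stability matches the multi-point CV oracle", {
  regions <- c("r1", "r2", "r3", "r4", "r5")
  mult <- c(r1 = 0.7, r2 = 0.85, r3 = 1.0, r4 = 1.15, r5 = 1.3)
  leaves <- make_leaf_set(regions = regions,
                          value_fn = function(sp, se, re) mult[[re]])
  rs <- regional_stability(aggregate_species_table(leaves))
  expect_equal(rs$cv[rs$indicator == "leaf_width"], oracle_cv(mult),
               tolerance = 1e-10)
  expect_equal(as.character(rs$class[rs$indicator == "leaf_width"]), "middle")

  same <- make_leaf_set(regions = regions)
  rs0 <- regional_stability(aggregate_species_table(same))
  expect_true(all(rs0$cv == 0))
})

test_that("an indicator with planted >35% regional dispersion is strong", {
  cfg <- small_analogue(leaf_cv = 0, species_cv = 0)
  study <- generate_study(cfg, 31)
  tab <- aggregate_species_table(compute_indicator_panel(study$leaves))
  rs <- suppressMessages(
    regional_stability(tab[tab$season == "winter", , drop = FALSE]))
  expect_equal(as.character(rs$class[rs$indicator == "leaf_area"]), "strong")
  expect_gt(rs$cv[rs$indicator == "leaf_area"], 35)
})

test_that("zone correlation has exact endpoints and calibrated null", {
  leaves <- do.call(rbind, lapply(1:8, function(i)
    make_leaf(species_id = paste0("s", i), leaf_length = 2 * i,
              mesophyll_thickness = 9 - i)))
  tab <- aggregate_species_table(leaves)
  zones <- setNames(1:8, paste0("s", 1:8))
  corr <- suppressMessages(correlate_with_zone(tab, zones))
  expect_equal(corr$r[corr$indicator == "leaf_length"], 1)
  expect_lt(corr$p[corr$indicator == "leaf_length"], 1e-6)
  expect_equal(corr$r[corr$indicator == "mesophyll"], -1)

  # under a zone-independent indicator the |r| > 0.367 rate is ~5% at n=29
  set.seed(1234)
  crit <- 0.3673  # t-critical at alpha = .05, df = 27, mapped to r
  hits <- mean(replicate(1000, {
    abs(cor(rnorm(29), sample(rep_len(1:12, 29)))) > crit
  }))
  expect_gt(hits, 0.025)
  expect_lt(hits, 0.085)

  # zero-variance indicators are excluded with a message
  expect_message(correlate_with_zone(tab, zones), "zero variance")
})

test_that("model indicator selection reproduces the screening arithmetic", {
  # the printed screening outcome: 14 zone-correlated indicators, of which
  # leaf area carries strong regional variation; abaxial cuticle/area and
  # mesophyll/area are strong too but were never significant
  correlated <- c(unname(model_indicators()), "leaf_area")
  strong <- c("leaf_area", "abaxial_cuticle_per_area", "mesophyll_per_area")
  report <- data.frame(
    indicator = indicator_panel_ids(),
    p = ifelse(indicator_panel_ids() %in% correlated, 0.01, 0.5),
    r = ifelse(indicator_panel_ids() %in% correlated, 0.6, 0.1),
    seasonal_cv = 10,
    seasonal_class = "weak",
    regional_cv = ifelse(indicator_panel_ids() %in% strong, 45, 20),
    regional_class = ifelse(indicator_panel_ids() %in% strong,
                            "strong", "middle"),
    stringsAsFactors = FALSE
  )
  # x5 and x9 carry extremely weak correlations in the reduced model
  report$r[report$indicator %in% model_indicators()[c("x5", "x9")]] <- 0.25
  report$r_class <- as.character(classify_correlation(report$r))

  sel <- select_model_indicators(report)
  expect_length(sel$full_set, 13)
  expect_identical(sel$full_set, unname(model_indicators()))
  expect_length(sel$e_set, 11)
  expect_identical(sel$e_set,
                   unname(model_indicators()[c(1:4, 6:8, 10:13)]))

  # idempotent, and e_set is always nested in full_set
  set.seed(9)
  for (i in 1:20) {
    rnd <- report
    rnd$p <- runif(nrow(rnd))
    rnd$r <- runif(nrow(rnd), -1, 1)
    rnd$r_class <- as.character(classify_correlation(rnd$r))
    rnd$regional_cv <- runif(nrow(rnd), 0, 60)
    rnd$regional_class <- as.character(classify_variation(rnd$regional_cv))
    s <- tryCatch(select_model_indicators(rnd), error = function(e) NULL)
    if (is.null(s)) next
    expect_true(all(s$e_set %in% s$full_set))
    again <- rnd[rnd$indicator %in% s$full_set, , drop = FALSE]
    s2 <- select_model_indicators(again)
    expect_identical(s2$full_set, s$full_set)
  }

  # everything strong-variation -> advisory error
  allstrong <- report
  allstrong$regional_cv <- 50
  allstrong$regional_class <- "strong"
  expect_error(select_model_indicators(allstrong), "review")
})
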