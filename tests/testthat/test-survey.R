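toy_species <- data.frame(
  taxon_id = c("PARR", "WRAS", "CHRO", "GROU", "SHRK"),
  lw_a = c(0.0137, 0.012, 0.02, 0.01, 0.005),
  lw_b = c(3.05, 3.0, 2.9, 3.1, 3.2),
  trophic_group = c("primary", "secondary", "planktivore", "piscivore",
                    "piscivore"),
  shark_or_jack = c(FALSE, FALSE, FALSE, FALSE, TRUE),
  stringsAsFactors = FALSE
)

test_that("fish_mass is the allometric power law", {
  expect_equal(fish_mass(0.01, 3, 10), 10)
  expect_equal(fish_mass(0.0137, 3.05, 23), 0.0137 * 23^3.05)
  expect_lt(fish_mass(0.01, 3, 1e-6), 1e-15)  # mass -> 0 as L -> 0
  expect_error(fish_mass(-1, 3, 10), "lw_a")
  expect_error(fish_mass(0.01, 3, 0), "length_cm")
})

test_that("exclusions drop sharks/jacks and strict-MPA sites with bookkeeping", {
  rec <- data.frame(site_id = rep(c("a", "b"), each = 5),
                    cylinder_id = 1,
                    taxon_id = c(rep("PARR", 4), "SHRK", "SHRK", "SHRK",
                                 "WRAS", "GROU", "CHRO"),
                    count = 1, length_cm = 20)
  sites <- data.frame(site_id = c("a", "b"), mpa_strict = c(FALSE, FALSE))
  out <- apply_exclusions(rec, toy_species, sites)
  expect_equal(nrow(out$records), 7)  # 3 shark rows of 10 removed
  expect_equal(out$exclusion_log$records_removed,
               c(3, 0))

  clean <- rec[rec$taxon_id != "SHRK", ]
  out2 <- apply_exclusions(clean, toy_species, sites)
  expect_identical(out2$records, clean)
  expect_identical(out2$sites, sites)

  sites$mpa_strict <- c(TRUE, FALSE)
  out3 <- apply_exclusions(clean, toy_species, sites)
  expect_false(any(out3$records$site_id == "a"))
  expect_equal(out3$exclusion_log$sites_removed, c(0, 1))

  bad <- rec; bad$taxon_id[1] <- "NOPE"
  expect_error(apply_exclusions(bad, toy_species, sites), "NOPE")
})

test_that("generator MPA flags drive exclusion counts", {
  cfg <- sim_config(n_islands = 4, sites_per_island = 10,
                    mpa_fraction = 0.3, seed = 21)
  sp <- simulate_species_table(cfg)
  w <- simulate_islands(cfg)
  sv <- simulate_surveys(w$islands, w$truth, sp, cfg)
  out <- apply_exclusions(sv$records, sp, sv$sites)
  expect_equal(out$exclusion_log$sites_removed[2], sum(sv$sites$mpa_strict))
  expect_false(any(out$records$site_id %in%
                     sv$sites$site_id[sv$sites$mpa_strict]))
})

test_that("site biomass pools cylinder densities", {
  # one fish whose mass equals the cylinder area: 1 g m^-2 in its cylinder,
  # empty partner cylinder represented by a zero-count record -> 0.5 overall
  area <- pi * 7.5^2
  L <- (area / 0.01)^(1 / 3)  # mass = 0.01 * L^3 = area grams
  rec <- data.frame(site_id = "s1", cylinder_id = c(1, 2),
                    taxon_id = "FISH", count = c(1, 0),
                    length_cm = c(L, 10))
  sp1 <- data.frame(taxon_id = "FISH", lw_a = 0.01, lw_b = 3,
                    trophic_group = "primary", shark_or_jack = FALSE)
  sb <- site_biomass(rec, sp1)
  expect_equal(sb$total, 0.5, tolerance = 1e-12)
  expect_equal(sb$primary, 0.5, tolerance = 1e-12)

  # identical cylinders: site value equals the cylinder value
  rec2 <- data.frame(site_id = "s1", cylinder_id = c(1, 2),
                     taxon_id = "FISH", count = 3, length_cm = 20)
  sb2 <- site_biomass(rec2, sp1)
  expect_equal(sb2$total, 3 * 0.01 * 20^3 / area)
})

test_that("site biomass equals the brute-force per-record oracle", {
  set.seed(14)
  rec <- data.frame(
    site_id = sample(c("s1", "s2"), 12, replace = TRUE),
    cylinder_id = sample(1:2, 12, replace = TRUE),
    taxon_id = sample(c("PARR", "WRAS", "CHRO", "GROU"), 12, replace = TRUE),
    count = sample(0:6, 12, replace = TRUE),
    length_cm = runif(12, 5, 40)
  )
  sb <- suppressWarnings(site_biomass(rec, toy_species))
  orc <- oracle_site_biomass(rec, toy_species)
  for (sid in sb$site_id) {
    expect_equal(unname(unlist(sb[sb$site_id == sid, TROPHIC_GROUPS])),
                 unname(orc[[sid]]), tolerance = 1e-12)
  }
  # additivity to machine precision
  expect_equal(sb$total, rowSums(sb[, TROPHIC_GROUPS]))
  # doubling every count doubles every density
  rec2 <- rec; rec2$count <- rec2$count * 2L
  sb2 <- suppressWarnings(site_biomass(rec2, toy_species))
  expect_equal(sb2[, c(TROPHIC_GROUPS, "total")],
               sb[, c(TROPHIC_GROUPS, "total")] * 2)
  # removing a zero-count record changes nothing (cylinder ids preserved)
  zc <- which(rec$count == 0)
  if (length(zc) > 0) {
    keep_cyl <- unique(rec[, c("site_id", "cylinder_id")])
    drop1 <- rec[-zc[1], ]
    still <- nrow(unique(drop1[, c("site_id", "cylinder_id")])) ==
      nrow(keep_cyl)
    if (still) {
      expect_equal(suppressWarnings(site_biomass(drop1, toy_species)), sb)
    }
  }
})

test_that("single-cylinder sites warn by default and drop in strict mode", {
  rec <- data.frame(site_id = c("s1", "s1", "s2"), cylinder_id = c(1, 2, 1),
                    taxon_id = "PARR", count = 1, length_cm = 20)
  expect_warning(sb <- site_biomass(rec, toy_species), "single")
  expect_equal(nrow(sb), 2)
  expect_warning(sb2 <- site_biomass(rec, toy_species, strict = TRUE),
                 "dropped")
  expect_equal(sb2$site_id, "s1")
})

test_that("complexity calibration converts categorical sites and passes heights", {
  p <- simulate_calibration_pairs(n = 15, slope = 0.2, intercept = 0,
                                  noise_sd = 0, seed = 2)
  cal <- calibrate_complexity(p)
  expect_equal(cal$convert(3, "categorical"), 0.6, tolerance = 1e-12)
  expect_equal(cal$convert(0.92, "height"), 0.92)
  expect_equal(cal$r_squared, 1)

  # noisy pairs with known truth: recovered slope within 2 SE
  pn <- simulate_calibration_pairs(n = 15, slope = 0.2, intercept = 0.05,
                                   noise_sd = 0.06, seed = 3)
  caln <- calibrate_complexity(pn)
  se <- summary(lm(height_m ~ category, pn))$coefficients["category", 2]
  expect_lt(abs(caln$slope - 0.2), 2 * se)

  expect_error(calibrate_complexity(p[1:2, ]), "3 calibration")
  expect_error(
    calibrate_complexity(data.frame(category = c(2, 2, 2),
                                    height_m = c(0.4, 0.5, 0.6))),
    "degenerate")
})
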