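#' Simulation configuration
#'
#' Assembles and validates the configuration of the synthetic survey
#' generator. Defaults describe a plausible Pacific-island survey campaign:
#' 40 reef areas, 30 forereef sites each split over three depth strata with
#' area fractions (0.25, 0.50, 0.25), covariates spanning the ranges of the
#' packaged reef-area table, a saturating-exponential human effect
#' (multiplier exp(-lambda * sqrt(density)) with lambda set so 40 people per
#' hectare depletes ~75\% of biomass) and a log-linear oceanic-productivity
#' effect (x2.2 from lowest to highest CHL).
#'
#' @param n_islands number of reef areas.
#' @param sites_per_island sites per island (single count, or length-2 range
#'   sampled uniformly).
#' @param strata_spec data.frame with \code{stratum}, \code{area_frac},
#'   \code{alloc_frac}; fractions must each sum to 1.
#' @param covariate_ranges named list of c(min, max) for CHL, WV, SSTL, HC,
#'   CX.
#' @param effects named list of log-scale effect functions of the island
#'   covariate (names among CHL, WV, SSTL, HC, CX, AT, HUM, HDIST); see
#'   \code{\link{default_effects}}.
#' @param baseline_gm2 expected total biomass (g m^-2) at the effect
#'   reference point (min CHL, no humans), default 45.
#' @param group_mix trophic-group proportions of total biomass (sums to 1).
#' @param dispersion gamma shape of site-level noise on totals (> 0);
#'   default 4 gives a site-level CV of 50\%, i.e. island-mean CVs near 10\%
#'   at 30 sites, comparable to real campaigns.
#' @param species_pool_size number of species (>= 4, all groups covered).
#' @param mpa_fraction fraction of sites flagged as strictly protected.
#' @param shark_encounter per-site probability of an (excluded) shark/jack
#'   record.
#' @param inhabited_fraction fraction of islands with residents.
#' @param max_density maximum local human density (people per forereef
#'   hectare), default 40.
#' @param max_distant_density maximum distant-population density.
#' @param seed integer seed; all generator draws derive from it.
#' @return validated list of class \code{sim_config}.
#' @export
sim_config <- function(n_islands = 40,
                       sites_per_island = 30,
                       strata_spec = default_strata(),
                       covariate_ranges = default_covariate_ranges(),
                       effects = default_effects(),
                       baseline_gm2 = 45,
                       group_mix = c(primary = 0.42, secondary = 0.17,
                                     planktivore = 0.21, piscivore = 0.20),
                       dispersion = 4,
                       species_pool_size = 24,
                       mpa_fraction = 0.05,
                       shark_encounter = 0.10,
                       inhabited_fraction = 0.55,
                       max_density = 40,
                       max_distant_density = 200,
                       seed = 1L) {
  if (dispersion <= 0) stop_reefbl("dispersion must be > 0")
  if (abs(sum(strata_spec$area_frac) - 1) > 1e-8 ||
      abs(sum(strata_spec$alloc_frac) - 1) > 1e-8) {
    stop_reefbl("strata area and allocation fractions must each sum to 1")
  }
  for (nm in names(covariate_ranges)) {
    r <- covariate_ranges[[nm]]
    if (length(r) != 2 || r[1] >= r[2]) {
      stop_reefbl("covariate range for ", nm, " must satisfy min < max")
    }
  }
  if (species_pool_size < 4) {
    stop_reefbl("species_pool_size must be >= 4 to cover all trophic groups")
  }
  if (!all(names(group_mix) == TROPHIC_GROUPS) ||
      abs(sum(group_mix) - 1) > 1e-8) {
    stop_reefbl("group_mix must be named over the trophic groups and sum to 1")
  }
  structure(as.list(environment()), class = "sim_config")
}

#' @rdname sim_config
#' @export
default_strata <- function() {
  data.frame(stratum = c("shallow", "mid", "deep"),
             area_frac = c(0.25, 0.50, 0.25),
             alloc_frac = c(0.25, 0.50, 0.25),
             stringsAsFactors = FALSE)
}

#' @rdname sim_config
#' @export
default_covariate_ranges <- function() {
  # spans of the packaged 37-reef-area table
  list(CHL = c(0.03, 0.21), WV = c(15.5, 46.1), SSTL = c(19.0, 27.9),
       HC = c(3, 38), CX = c(0.29, 0.92))
}

#' Default true covariate effects (log scale)
#'
#' CHL: log-linear increase, exp(amplitude) = 2.2-fold from the low to the
#' high end of the CHL range. HUM/HDIST: linear decline in the square-root
#' density covariate, i.e. a saturating-exponential multiplier
#' exp(-lambda*sqrt(density)) — steepest decline near zero density. The
#' default hum_lambda = log(4)/sqrt(40) makes 40 people per hectare deplete
#' 75\% of biomass. Set all amplitudes 0 for a null world.
#'
#' @param chl_amplitude log fold-change over the CHL range (default
#'   log(2.2)).
#' @param hum_lambda decline rate per unit HUM = sqrt(density).
#' @param hdist_lambda decline rate per unit HDIST.
#' @return named list of functions, with the human terms recorded in
#'   attribute \code{"human"}.
#' @export
default_effects <- function(chl_amplitude = log(2.2),
                            hum_lambda = log(4) / sqrt(40),
                            hdist_lambda = 0.03) {
  rng <- default_covariate_ranges()$CHL
  eff <- list(
    CHL = function(x) chl_amplitude * (x - rng[1]) / (rng[2] - rng[1]),
    HUM = function(x) -hum_lambda * x,
    HDIST = function(x) -hdist_lambda * x
  )
  attr(eff, "human") <- c("HUM", "HDIST")
  eff
}

effect_column <- c(CHL = "CHL", WV = "WV", SSTL = "SSTL", HC = "hc_true",
                   CX = "cx_true", AT = "AT", HUM = "HUM", HDIST = "HDIST")

eval_effects <- function(islands, effects, which = names(effects)) {
  total <- numeric(nrow(islands))
  for (nm in intersect(which, names(effects))) {
    col <- effect_column[[nm]]
    total <- total + effects[[nm]](islands[[col]])
  }
  total
}

#' Simulate the species trait table
#'
#' Species get FishBase-style length-weight parameters, a mean length used
#' for record generation, a trophic group (round-robin so all four groups
#' are always covered) and a shark/jack flag (a small number of piscivores
#' in larger pools; flagged species never contribute to the biomass target,
#' mirroring their exclusion from the analysis).
#'
#' @param config a \code{\link{sim_config}}.
#' @return data.frame: \code{taxon_id, lw_a, lw_b, trophic_group,
#'   shark_or_jack, mean_length_cm}.
#' @export
simulate_species_table <- function(config) {
  set.seed(config$seed + 1L)
  n <- config$species_pool_size
  grp <- rep(TROPHIC_GROUPS, length.out = n)
  sp <- data.frame(
    taxon_id = sprintf("SP%03d", seq_len(n)),
    lw_a = exp(stats::runif(n, log(0.008), log(0.03))),
    lw_b = stats::runif(n, 2.8, 3.2),
    trophic_group = grp,
    shark_or_jack = FALSE,
    mean_length_cm = stats::runif(n, 8, 35),
    stringsAsFactors = FALSE
  )
  n_shark <- min(floor(n / 8), sum(grp == "piscivore") - 1)
  if (n_shark > 0) {
    pisc <- which(grp == "piscivore")
    sp$shark_or_jack[utils::head(rev(pisc), n_shark)] <- TRUE
  }
  sp
}

#' Simulate island covariates and ground truth
#'
#' Draws island covariates (uniform within configured ranges; human
#' densities zero for uninhabited islands and right-skewed up to
#' \code{max_density} otherwise) and computes each island's true expected
#' biomass surface: log E[biomass] = log(baseline) + sum of effect
#' functions. Ground truth also stores the no-human expectation (human
#' effect terms zeroed) and the implied true depletion fraction.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{islands} (covariate table in the packaged
#'   reef-area layout plus \code{hc_true}, \code{cx_true} and the derived
#'   HUM/HDIST/AT/CHL/WV/SSTL columns) and \code{truth} (island x trophic
#'   group expected biomass, no-human expectation, true depletion).
#' @export
simulate_islands <- function(config) {
  set.seed(config$seed + 2L)
  n <- config$n_islands
  rng <- config$covariate_ranges
  area <- round(exp(stats::runif(n, log(300), log(20000))))
  inhabited <- stats::rbinom(n, 1, config$inhabited_fraction)
  density <- inhabited * config$max_density * stats::runif(n)^2
  has_dist <- stats::rbinom(n, 1, 0.5)
  ddensity <- has_dist * config$max_distant_density * stats::runif(n)^2
  islands <- data.frame(
    island_id = sprintf("ISL%02d", seq_len(n)),
    island = sprintf("ISL%02d", seq_len(n)),
    region = "SIM",
    atoll = stats::rbinom(n, 1, 0.27),
    forereef_ha = area,
    pop = round(density * area),
    distant_pop = round(ddensity * area),
    chl = stats::runif(n, rng$CHL[1], rng$CHL[2]),
    wv = stats::runif(n, rng$WV[1], rng$WV[2]),
    sstl = stats::runif(n, rng$SSTL[1], rng$SSTL[2]),
    hc_true = stats::runif(n, rng$HC[1], rng$HC[2]),
    cx_true = stats::runif(n, rng$CX[1], rng$CX[2]),
    stringsAsFactors = FALSE
  )
  islands <- build_covariates(islands)

  human <- attr(config$effects, "human") %||% c("HUM", "HDIST")
  log_nohuman <- log(config$baseline_gm2) +
    eval_effects(islands, config$effects, setdiff(names(config$effects), human))
  log_human_mult <- eval_effects(islands, config$effects,
                                 intersect(names(config$effects), human))
  mu_nohuman <- exp(log_nohuman)
  mu <- mu_nohuman * exp(log_human_mult)

  mix <- config$group_mix
  truth <- do.call(rbind, lapply(c(TROPHIC_GROUPS, "total"), function(g) {
    p <- if (g == "total") 1 else mix[[g]]
    data.frame(island_id = islands$island_id, group = g,
               expected_gm2 = mu * p,
               expected_nohuman_gm2 = mu_nohuman * p,
               true_depletion = 1 - exp(log_human_mult),
               stringsAsFactors = FALSE)
  }))
  rownames(truth) <- NULL
  list(islands = islands, truth = truth)
}

#' Simulate the survey hierarchy: strata, sites, paired-cylinder records
#'
#' Allocates sites to depth strata, draws site-level biomass around each
#' island's true expectation (per-group gamma draws whose shapes sum to the
#' configured total dispersion, so site totals are exactly gamma with that
#' shape), splits each site draw over two cylinders, and emits fish records
#' (taxon, count, length) whose implied mass reproduces each cylinder's
#' group biomass to machine precision (the last record per
#' cylinder-by-group cell has its length solved from the mass remainder).
#' Flagged shark/jack records and strict-MPA site flags are added on top and
#' never count toward the target.
#'
#' @param islands,truth output of \code{\link{simulate_islands}}.
#' @param species output of \code{\link{simulate_species_table}}.
#' @param config the \code{\link{sim_config}} used throughout.
#' @return list with \code{records}, \code{sites}, \code{strata}
#'   data.frames ready for \code{\link{site_biomass}} and
#'   \code{\link{build_island_table}}.
#' @export
simulate_surveys <- function(islands, truth, species, config) {
  set.seed(config$seed + 3L)
  if (!all(islands$island_id %in% truth$island_id)) {
    stop_reefbl("ground truth missing islands")
  }
  ss <- config$strata_spec
  strata <- do.call(rbind, lapply(seq_len(nrow(islands)), function(i) {
    data.frame(island_id = islands$island_id[i], stratum = ss$stratum,
               area_ha = ss$area_frac * islands$forereef_ha[i],
               stringsAsFactors = FALSE)
  }))

  spi <- config$sites_per_island
  n_sites_isl <- if (length(spi) == 2) {
    sample(seq(spi[1], spi[2]), nrow(islands), replace = TRUE)
  } else rep(spi, nrow(islands))

  mu_total <- truth$expected_gm2[truth$group == "total"][
    match(islands$island_id, truth$island_id[truth$group == "total"])]

  sites_list <- lapply(seq_len(nrow(islands)), function(i) {
    ns <- n_sites_isl[i]
    # deterministic proportional allocation with remainder to largest strata
    alloc <- floor(ss$alloc_frac * ns)
    rem <- ns - sum(alloc)
    if (rem > 0) {
      o <- order(ss$alloc_frac * ns - alloc, decreasing = TRUE)
      alloc[o[seq_len(rem)]] <- alloc[o[seq_len(rem)]] + 1L
    }
    data.frame(
      site_id = sprintf("%s_S%03d", islands$island_id[i], seq_len(ns)),
      island_id = islands$island_id[i],
      stratum = rep(ss$stratum, alloc),
      stringsAsFactors = FALSE
    )
  })
  sites <- do.call(rbind, sites_list)
  ns_tot <- nrow(sites)
  ii <- match(sites$island_id, islands$island_id)
  sites$depth_bin <- sites$stratum
  sites$mpa_strict <- stats::rbinom(ns_tot, 1, config$mpa_fraction) == 1
  sites$hard_coral_pct <- pmin(100, pmax(0,
    stats::rnorm(ns_tot, islands$hc_true[ii], 6)))
  sites$complexity_m <- pmax(0.05,
    stats::rnorm(ns_tot, islands$cx_true[ii], 0.10))
  sites$cx_protocol <- "height"

  # site x group biomass: gamma shapes proportional to the group mix sum to
  # the configured total shape, all on a common scale, so totals are
  # Gamma(dispersion, mean = island expectation)
  mix <- config$group_mix
  disp <- config$dispersion
  scale_site <- mu_total[ii] / disp
  dens <- sapply(TROPHIC_GROUPS, function(g) {
    stats::rgamma(ns_tot, shape = disp * mix[[g]], scale = scale_site)
  })

  # split each site over two cylinders; mean of the two equals the site draw
  u <- stats::runif(ns_tot, 0.35, 0.65)
  area_cyl <- pi * 7.5^2
  cell <- expand.grid(site = seq_len(ns_tot), cyl = 1:2,
                      grp = TROPHIC_GROUPS, stringsAsFactors = FALSE)
  cell$dens <- dens[cbind(cell$site, match(cell$grp, TROPHIC_GROUPS))] *
    ifelse(cell$cyl == 1, 2 * u[cell$site], 2 * (1 - u[cell$site]))
  cell$target_g <- cell$dens * area_cyl

  usable <- !species$shark_or_jack
  pick_species <- function(grp_vec) {
    out <- integer(length(grp_vec))
    for (g in unique(grp_vec)) {
      idx <- grp_vec == g
      cand <- which(usable & species$trophic_group == g)
      if (length(cand) == 0) stop_reefbl("no usable species for group ", g)
      out[idx] <- cand[sample.int(length(cand), sum(idx), replace = TRUE)]
    }
    out
  }
  make_draw <- function(rem, grp_vec, f_lo, f_hi) {
    sp <- pick_species(grp_vec)
    len <- stats::rlnorm(length(sp), log(species$mean_length_cm[sp]), 0.25)
    m <- fish_mass(species$lw_a[sp], species$lw_b[sp], len)
    cnt <- pmin(2000, floor(rem * stats::runif(length(sp), f_lo, f_hi) / m))
    list(sp = sp, len = len, mass = m, count = cnt)
  }

  rem <- cell$target_g
  d1 <- make_draw(rem, cell$grp, 0.3, 0.6)
  rem1 <- rem - d1$count * d1$mass
  d2 <- make_draw(rem1, cell$grp, 0.5, 0.9)
  rem2 <- rem1 - d2$count * d2$mass
  # closing record: one fish whose length is solved from the remainder
  sp3 <- pick_species(cell$grp)
  len3 <- (rem2 / species$lw_a[sp3])^(1 / species$lw_b[sp3])

  rec <- function(sp, cnt, len) data.frame(
    site_id = sites$site_id[cell$site],
    cylinder_id = cell$cyl,
    taxon_id = species$taxon_id[sp],
    count = as.integer(cnt),
    length_cm = len,
    stringsAsFactors = FALSE
  )
  records <- rbind(rec(d1$sp, d1$count, d1$len)[d1$count > 0, ],
                   rec(d2$sp, d2$count, d2$len)[d2$count > 0, ],
                   rec(sp3, 1L, len3))

  shark_sp <- which(species$shark_or_jack)
  if (length(shark_sp) > 0 && config$shark_encounter > 0) {
    hit <- which(stats::runif(ns_tot) < config$shark_encounter)
    if (length(hit) > 0) {
      sharks <- data.frame(
        site_id = sites$site_id[hit],
        cylinder_id = sample(1:2, length(hit), replace = TRUE),
        taxon_id = species$taxon_id[
          shark_sp[sample.int(length(shark_sp), length(hit), replace = TRUE)]],
        count = sample(1:3, length(hit), replace = TRUE),
        length_cm = stats::runif(length(hit), 60, 120),
        stringsAsFactors = FALSE
      )
      records <- rbind(records, sharks)
    }
  }
  records <- records[order(records$site_id, records$cylinder_id,
                           records$taxon_id, records$length_cm), ]
  rownames(records) <- NULL
  list(records = records, sites = sites, strata = strata)
}

#' Simulate complexity calibration pairs
#'
#' Paired categorical (1-5) and measured vertical-height observations at
#' sites scored under both complexity protocols: height = intercept +
#' slope * category + Gaussian noise, clipped at zero.
#'
#' @param n number of paired sites (default 15, >= 3).
#' @param slope,intercept true linear map from category to height (m).
#' @param noise_sd Gaussian noise SD (>= 0).
#' @param seed integer seed.
#' @return data.frame with \code{category}, \code{height_m}.
#' @export
simulate_calibration_pairs <- function(n = 15, slope = 0.2, intercept = 0,
                                       noise_sd = 0.05, seed = 1L) {
  if (n < 3) stop_reefbl("need n >= 3 calibration pairs")
  if (noise_sd < 0) stop_reefbl("noise_sd must be >= 0")
  set.seed(seed)
  category <- rep(1:5, length.out = n)
  data.frame(
    category = category,
    height_m = pmax(0, intercept + slope * category +
                      stats::rnorm(n, 0, noise_sd))
  )
}
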