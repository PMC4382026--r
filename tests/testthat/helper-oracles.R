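TROPHIC_GROUPS <- c("primary", "secondary", "planktivore", "piscivore")

# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: plain-loop formula evaluation only.

oracle_aicc <- function(ll, k, n) {
  -2 * ll + 2 * k + (2 * k * (k + 1)) / (n - k - 1)
}

oracle_weights <- function(aicc_vec) {
  d <- aicc_vec - min(aicc_vec)
  e <- exp(-d / 2)
  e / sum(e)
}

oracle_importance <- function(specs, weights, predictor) {
  tot <- 0
  for (i in seq_along(specs)) {
    if (predictor %in% specs[[i]]) tot <- tot + weights[i]
  }
  tot
}

oracle_stratified <- function(values, strata, areas) {
  labs <- unique(strata)
  w <- areas[labs] / sum(areas[labs])
  m <- 0; v <- 0
  for (i in seq_along(labs)) {
    y <- values[strata == labs[i]]
    m <- m + w[i] * mean(y)
    s2 <- if (length(y) > 1) var(y) else 0
    v <- v + w[i]^2 * s2 / length(y)
  }
  list(mean = unname(m), var = unname(v))
}

oracle_vif <- function(tab, predictors) {
  sapply(predictors, function(p) {
    others <- setdiff(predictors, p)
    X <- cbind(1, as.matrix(tab[, others, drop = FALSE]))
    y <- tab[[p]]
    b <- solve(crossprod(X), crossprod(X, y))
    res <- y - X %*% b
    r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
    1 / (1 - r2)
  })
}

# per-record summation oracle for site biomass (density mean over cylinders)
oracle_site_biomass <- function(records, species, diameter = 15) {
  area <- pi * (diameter / 2)^2
  groups <- c("primary", "secondary", "planktivore", "piscivore")
  out <- list()
  for (sid in unique(records$site_id)) {
    rs <- records[records$site_id == sid, ]
    cyls <- unique(rs$cylinder_id)
    dens <- setNames(numeric(4), groups)
    for (g in groups) {
      tot <- 0
      for (cy in cyls) {
        m <- 0
        rr <- rs[rs$cylinder_id == cy, ]
        for (i in seq_len(nrow(rr))) {
          sp <- species[species$taxon_id == rr$taxon_id[i], ]
          if (sp$trophic_group == g) {
            m <- m + rr$count[i] * sp$lw_a * rr$length_cm[i]^sp$lw_b
          }
        }
        tot <- tot + m / area
      }
      dens[g] <- tot / length(cyls)
    }
    out[[sid]] <- dens
  }
  out
}

# brute-force enumeration of admissible subsets
oracle_enumerate_count <- function(predictors, constraints) {
  n <- length(predictors)
  count <- 0L
  for (mask in 0:(2^n - 1)) {
    s <- predictors[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
    ok <- TRUE
    for (p in constraints) if (all(p %in% s)) ok <- FALSE
    if (ok) count <- count + 1L
  }
  count
}

# a small fitted world shared by several tests (built once per test run)
tiny_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sc <- sim_config(n_islands = 18, sites_per_island = 12,
                       mpa_fraction = 0, seed = 42)
      sp <- simulate_species_table(sc)
      w <- simulate_islands(sc)
      sv <- simulate_surveys(w$islands, w$truth, sp, sc)
      sb <- site_biomass(sv$records[!sp$shark_or_jack[
        match(sv$records$taxon_id, sp$taxon_id)], ], sp)
      it <- suppressWarnings(build_island_table(
        sb, sv$sites, sv$strata, w$islands, min_sites = 0, max_cv = Inf))
      it$total <- it$total_mean
      cache <<- list(config = sc, species = sp, islands = w$islands,
                     truth = w$truth, surveys = sv, site_bio = sb,
                     island_table = it)
    }
    cache
  }
})
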