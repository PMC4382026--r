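#' Area-weighted stratified mean and variance
#'
#' Classical stratified estimator over depth strata: the island mean is
#' sum_h w_h * ybar_h with w_h proportional to stratum hardbottom area, and
#' the variance of the mean is sum_h w_h^2 * s_h^2 / n_h. Strata containing a
#' single site contribute zero variance (with a warning); no finite
#' population correction is applied.
#'
#' @param values numeric site values (e.g. total biomass, g m^-2).
#' @param strata stratum label per site.
#' @param areas named numeric vector of stratum areas (same labels).
#' @return list with \code{mean}, \code{var} (variance of the mean),
#'   \code{se}, \code{n} and a per-stratum summary data.frame.
#' @examples
#' stratified_island_mean(c(10, 12, 20, 22), c("S", "S", "D", "D"),
#'                        c(S = 1, D = 1))$mean  # 16
#' @export
stratified_island_mean <- function(values, strata, areas) {
  if (length(values) == 0) stop_reefbl("no sites")
  if (length(values) != length(strata)) stop_reefbl("values/strata mismatch")
  strata <- as.character(strata)
  present <- unique(strata)
  if (is.null(names(areas)) || !all(present %in% names(areas))) {
    stop_reefbl("areas must be named and cover every sampled stratum")
  }
  a <- areas[present]
  if (any(!is.finite(a)) || any(a <= 0)) {
    stop_reefbl("every sampled stratum needs a positive area")
  }
  unsampled <- setdiff(names(areas), present)
  if (length(unsampled) > 0) {
    warning("stratum/strata with no sites ignored, weights renormalised: ",
            paste(unsampled, collapse = ", "))
  }
  w <- a / sum(a)
  ybar <- tapply(values, factor(strata, levels = present), mean)
  s2 <- tapply(values, factor(strata, levels = present), stats::var)
  n_h <- tapply(values, factor(strata, levels = present), length)
  if (any(n_h == 1)) {
    warning("stratum with a single site contributes zero variance")
    s2[n_h == 1] <- 0
  }
  est_var <- sum(w^2 * s2 / n_h)
  list(
    mean = sum(w * ybar),
    var = est_var,
    se = sqrt(est_var),
    n = length(values),
    strata = data.frame(stratum = present, n_sites = as.integer(n_h),
                        mean = as.numeric(ybar), variance = as.numeric(s2),
                        area_weight = as.numeric(w))
  )
}

#' Filter islands on sample size and precision
#'
#' Drops reef areas surveyed at too few sites or whose island-scale total
#' biomass is too imprecise (coefficient of variation = SE/mean). The
#' defaults (>= 12 sites, CV <= 0.40) retain every island with at least 12
#' sites and CV up to 35% while excluding 8-site islands and CVs of 47-87%.
#'
#' @param island_table data.frame with \code{island_id}, \code{n_sites},
#'   \code{total_mean}, \code{total_se}.
#' @param min_sites minimum site count, default 12.
#' @param max_cv maximum CV of total biomass, default 0.40.
#' @return list with \code{retained} table and \code{exclusion_log}.
#' @export
filter_islands <- function(island_table, min_sites = 12, max_cv = 0.40) {
  cv <- island_table$total_se / island_table$total_mean
  fail_n <- island_table$n_sites < min_sites
  fail_cv <- cv > max_cv
  drop <- fail_n | fail_cv
  if (all(drop)) stop_reefbl("island filters removed every island")
  log <- data.frame(
    island_id = island_table$island_id[drop],
    n_sites = island_table$n_sites[drop],
    cv = cv[drop],
    reason = paste0(ifelse(fail_n[drop], "n_sites", ""),
                    ifelse(fail_n[drop] & fail_cv[drop], "+", ""),
                    ifelse(fail_cv[drop], "cv", ""))
  )
  list(retained = island_table[!drop, , drop = FALSE], exclusion_log = log)
}

#' Pool small adjacent reef areas into single reporting units
#'
#' Survey data of pooled members are concatenated before stratified
#' estimation (use \code{relabel} on the site table and the summed strata
#' areas); covariate rows are combined with oceanographic covariates
#' (\code{chl, wv, sstl}, and lat/lon) as unweighted member means, while
#' populations and forereef area are summed so that people-per-hectare stays
#' well defined, and \code{atoll} is 1 if any member is an atoll.
#'
#' @param islands covariate table in \code{\link{pacific_reef_areas}} layout.
#' @param pooling named list: pooled-unit name -> character vector of member
#'   island names. Empty list is the identity.
#' @return list with pooled \code{islands} table and \code{relabel(ids)}, a
#'   function mapping member island ids to their pooled unit name.
#' @export
pool_reef_areas <- function(islands, pooling = list()) {
  relabel <- function(ids) {
    ids <- as.character(ids)
    for (unit in names(pooling)) ids[ids %in% pooling[[unit]]] <- unit
    ids
  }
  if (length(pooling) == 0) {
    return(list(islands = islands, relabel = relabel))
  }
  mean_cols <- intersect(c("lat", "lon", "chl", "wv", "sstl"), names(islands))
  sum_cols <- intersect(c("forereef_ha", "pop", "distant_pop"), names(islands))
  out <- islands
  for (unit in names(pooling)) {
    members <- pooling[[unit]]
    ii <- which(out$island %in% members)
    if (length(ii) != length(members)) {
      stop_reefbl("pooling unit '", unit, "' has missing member(s): ",
                  paste(setdiff(members, out$island), collapse = ", "))
    }
    row <- out[ii[1], , drop = FALSE]
    row$island <- unit
    if ("island_id" %in% names(out)) row$island_id <- unit
    for (cc in mean_cols) row[[cc]] <- mean(out[[cc]][ii])
    for (cc in sum_cols) row[[cc]] <- sum(out[[cc]][ii])
    if ("atoll" %in% names(out)) row$atoll <- as.integer(any(out$atoll[ii] > 0))
    out <- rbind(out[-ii, , drop = FALSE], row)
  }
  rownames(out) <- NULL
  list(islands = out, relabel = relabel)
}

#' Build human-density and atoll covariates
#'
#' HUM and HDIST are square-root transformed people per hectare of forereef
#' hardbottom: HUM = sqrt(resident population / forereef area), HDIST the
#' same for the population living within 200 km but not on the island.
#' Missing populations count as zero; AT recodes the atoll flag as 0/1.
#'
#' @param meta covariate table with \code{forereef_ha}, \code{pop},
#'   \code{distant_pop}, \code{atoll}, and (upper- or lower-case) columns
#'   \code{chl, wv, sstl}.
#' @return the table with numeric columns \code{HUM}, \code{HDIST},
#'   \code{AT}, \code{CHL}, \code{WV}, \code{SSTL} appended/normalised.
#' @examples
#' m <- data.frame(island = "Oahu", forereef_ha = 25119, pop = 953207,
#'                 distant_pop = 199685, atoll = 0,
#'                 chl = 0.08, wv = 28.56, sstl = 23.87)
#' round(build_covariates(m)$HUM, 2)  # 6.16
#' @export
build_covariates <- function(meta) {
  if (any(!is.finite(meta$forereef_ha)) || any(meta$forereef_ha <= 0)) {
    stop_reefbl("forereef_ha must be positive for every reef area")
  }
  pop <- ifelse(is.na(meta$pop), 0, meta$pop)
  dpop <- ifelse(is.na(meta$distant_pop), 0, meta$distant_pop)
  if (any(pop < 0) || any(dpop < 0)) stop_reefbl("populations must be >= 0")
  meta$HUM <- sqrt(pop / meta$forereef_ha)
  meta$HDIST <- sqrt(dpop / meta$forereef_ha)
  meta$AT <- as.numeric(meta$atoll > 0)
  for (cc in c("chl", "wv", "sstl")) {
    uc <- toupper(cc)
    if (!uc %in% names(meta) && cc %in% names(meta)) meta[[uc]] <- meta[[cc]]
  }
  meta
}

#' Assemble the island-scale response and covariate table
#'
#' Joins site biomass to site metadata, applies optional reef-area pooling,
#' computes area-weighted stratified means and SEs of every trophic group
#' (plus total, hard coral and complexity), builds the human-density
#' covariates and applies the island quality filters.
#'
#' @param site_bio output of \code{\link{site_biomass}}.
#' @param sites site table (\code{site_id, island_id, stratum}, optionally
#'   \code{hard_coral_pct}, \code{complexity_m}).
#' @param strata stratum area table (\code{island_id, stratum, area_ha}).
#' @param islands covariate table (\code{\link{pacific_reef_areas}} layout,
#'   keyed by \code{island} or \code{island_id}).
#' @param pooling pooling map passed to \code{\link{pool_reef_areas}}.
#' @param min_sites,max_cv island filters (see \code{\link{filter_islands}});
#'   set \code{min_sites = 0, max_cv = Inf} to keep everything.
#' @return data.frame, one row per retained reef area: \code{island_id},
#'   \code{n_sites}, \code{<group>_mean}/\code{<group>_se} for the four
#'   trophic groups and total, \code{HC}, \code{CX}, and the model
#'   covariates \code{HUM, HDIST, AT, CHL, WV, SSTL}. The exclusion log is
#'   attached as attribute \code{"exclusion_log"}.
#' @export
build_island_table <- function(site_bio, sites, strata, islands,
                               pooling = list(), min_sites = 12,
                               max_cv = 0.40) {
  pooled <- pool_reef_areas(islands, pooling)
  key <- if ("island_id" %in% names(pooled$islands)) "island_id" else "island"
  meta <- build_covariates(pooled$islands)

  df <- merge(site_bio, sites, by = "site_id")
  df$island_id <- pooled$relabel(df$island_id)
  strata$island_id <- pooled$relabel(strata$island_id)
  # summed member areas per stratum for pooled units
  strata <- stats::aggregate(area_ha ~ island_id + stratum, data = strata, FUN = sum)

  resp_cols <- c(TROPHIC_GROUPS, "total")
  rows <- lapply(split(df, df$island_id), function(d) {
    isl <- d$island_id[1]
    ar <- strata[strata$island_id == isl, ]
    if (nrow(ar) == 0) stop_reefbl("no strata areas for island ", isl)
    areas <- setNames(ar$area_ha, ar$stratum)
    out <- list(island_id = isl, n_sites = nrow(d))
    for (cc in resp_cols) {
      est <- stratified_island_mean(d[[cc]], d$stratum, areas)
      out[[paste0(cc, "_mean")]] <- est$mean
      out[[paste0(cc, "_se")]] <- est$se
    }
    out$HC <- if ("hard_coral_pct" %in% names(d))
      stratified_island_mean(d$hard_coral_pct, d$stratum, areas)$mean else NA_real_
    out$CX <- if ("complexity_m" %in% names(d))
      stratified_island_mean(d$complexity_m, d$stratum, areas)$mean else NA_real_
    as.data.frame(out, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL

  mi <- match(tab$island_id, meta[[key]])
  if (anyNA(mi)) {
    stop_reefbl("islands missing from covariate table: ",
                paste(tab$island_id[is.na(mi)], collapse = ", "))
  }
  for (cc in c("HUM", "HDIST", "AT", "CHL", "WV", "SSTL")) {
    tab[[cc]] <- meta[[cc]][mi]
  }
  if ("region" %in% names(meta)) tab$region <- meta$region[mi]

  filt <- filter_islands(tab, min_sites = min_sites, max_cv = max_cv)
  out <- filt$retained
  attr(out, "exclusion_log") <- filt$exclusion_log
  out
}
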