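#' Fish mass from length-weight allometry
#'
#' Converts total length to body mass with the standard FishBase power law
#' W = a * L^b, L in centimetres and W in grams.
#'
#' @param lw_a allometric coefficient, > 0.
#' @param lw_b allometric exponent, > 0 (typically near 3).
#' @param length_cm total length in cm, > 0.
#' @return mass in grams; vectorised over all three arguments.
#' @examples
#' fish_mass(0.01, 3, 10)   # 10 g
#' @export
fish_mass <- function(lw_a, lw_b, length_cm) {
  check_positive(lw_a, "lw_a")
  check_positive(lw_b, "lw_b")
  check_positive(length_cm, "length_cm")
  lw_a * length_cm^lw_b
}

#' Apply shark/jack and strict-MPA exclusions
#'
#' Drops every record of a taxon flagged \code{shark_or_jack} (their response
#' to divers biases density estimates between locations) and every site
#' inside a strictly enforced no-fishing MPA (protection confounds the
#' human-density gradient). Records at dropped sites are dropped too.
#'
#' @param records data.frame with \code{site_id, cylinder_id, taxon_id,
#'   count, length_cm}.
#' @param species data.frame with \code{taxon_id, shark_or_jack} (one row per
#'   taxon).
#' @param sites data.frame with \code{site_id, mpa_strict}; optional — when
#'   NULL only the taxon rule is applied.
#' @return list with filtered \code{records}, \code{sites}, and an
#'   \code{exclusion_log} data.frame (rule, records_removed, sites_removed).
#' @export
apply_exclusions <- function(records, species, sites = NULL) {
  if (anyDuplicated(species$taxon_id)) {
    stop_reefbl("species table must have exactly one row per taxon")
  }
  unknown <- setdiff(unique(records$taxon_id), species$taxon_id)
  if (length(unknown) > 0) {
    stop_reefbl("records reference taxa absent from the species table: ",
                paste(unknown, collapse = ", "))
  }
  flag <- species$shark_or_jack[match(records$taxon_id, species$taxon_id)]
  flag <- as.logical(flag)
  n_shark <- sum(flag)
  records <- records[!flag, , drop = FALSE]

  n_mpa_sites <- 0L
  n_mpa_records <- 0L
  if (!is.null(sites)) {
    drop_sites <- sites$site_id[as.logical(sites$mpa_strict)]
    n_mpa_sites <- length(drop_sites)
    keep <- !(records$site_id %in% drop_sites)
    n_mpa_records <- sum(!keep)
    records <- records[keep, , drop = FALSE]
    sites <- sites[!as.logical(sites$mpa_strict), , drop = FALSE]
  }
  log <- data.frame(
    rule = c("shark_or_jack", "strict_mpa"),
    records_removed = c(n_shark, n_mpa_records),
    sites_removed = c(0L, n_mpa_sites)
  )
  list(records = records, sites = sites, exclusion_log = log)
}

#' Site biomass density by trophic group
#'
#' For each survey cylinder, biomass density per trophic group is
#' sum(count * mass) / cylinder area; the site value is the mean of its two
#' cylinder densities (for equal-area cylinders this equals pooling masses
#' over the combined area). An empty cylinder is represented by at least one
#' zero-count record naming its \code{cylinder_id}.
#'
#' @param records fish records (\code{site_id, cylinder_id, taxon_id, count,
#'   length_cm}); counts may be zero.
#' @param species traits table (\code{taxon_id, lw_a, lw_b, trophic_group}).
#' @param cylinder_diameter_m cylinder diameter, default 15 m.
#' @param strict if TRUE, sites with a single observed cylinder are dropped
#'   (with a message in the attribute \code{"dropped"}); the default keeps
#'   them with a warning.
#' @return data.frame with one row per site: \code{site_id}, one column per
#'   trophic group (g m^-2) and \code{total}.
#' @examples
#' sp <- data.frame(taxon_id = "t1", lw_a = 0.01, lw_b = 3,
#'                  trophic_group = "primary", shark_or_jack = FALSE)
#' rec <- data.frame(site_id = "s1", cylinder_id = c(1, 2), taxon_id = "t1",
#'                   count = c(1, 0), length_cm = c(26.07, 10))
#' site_biomass(rec, sp)  # one ~176.7 g fish over 176.7 m^2, halved: ~0.5
#' @export
site_biomass <- function(records, species, cylinder_diameter_m = 15,
                         strict = FALSE) {
  if (nrow(records) == 0) stop_reefbl("no records supplied")
  if (any(records$count < 0)) stop_reefbl("negative counts")
  unknown <- setdiff(unique(records$taxon_id), species$taxon_id)
  if (length(unknown) > 0) {
    stop_reefbl("unresolvable taxa: ", paste(unknown, collapse = ", "))
  }
  area <- pi * (cylinder_diameter_m / 2)^2
  idx <- match(records$taxon_id, species$taxon_id)
  grp <- as.character(species$trophic_group[idx])
  bad_grp <- setdiff(unique(grp), TROPHIC_GROUPS)
  if (length(bad_grp) > 0) {
    stop_reefbl("unknown trophic group(s): ", paste(bad_grp, collapse = ", "))
  }
  mass <- records$count *
    fish_mass(species$lw_a[idx], species$lw_b[idx], records$length_cm)

  cyl_key <- interaction(records$site_id, records$cylinder_id, drop = TRUE)
  # per cylinder x group mass, then density
  out_site <- character(0)
  sites <- split(seq_len(nrow(records)), records$site_id)
  res <- lapply(names(sites), function(sid) {
    ii <- sites[[sid]]
    cyls <- unique(records$cylinder_id[ii])
    dens <- sapply(TROPHIC_GROUPS, function(g) {
      per_cyl <- vapply(cyls, function(cy) {
        jj <- ii[records$cylinder_id[ii] == cy & grp[ii] == g]
        sum(mass[jj]) / area
      }, numeric(1))
      mean(per_cyl)
    })
    c(n_cyl = length(cyls), dens)
  })
  res <- as.data.frame(do.call(rbind, res))
  res$site_id <- names(sites)
  single <- res$n_cyl == 1
  if (any(single)) {
    if (strict) {
      dropped <- res$site_id[single]
      res <- res[!single, , drop = FALSE]
      if (nrow(res) == 0) stop_reefbl("all sites dropped in strict mode")
      warning(length(dropped), " single-cylinder site(s) dropped (strict)")
      attr(res, "dropped") <- dropped
    } else {
      warning(sum(single), " site(s) have a single usable cylinder; kept")
    }
  }
  res$total <- rowSums(res[, TROPHIC_GROUPS, drop = FALSE])
  rownames(res) <- NULL
  res[, c("site_id", TROPHIC_GROUPS, "total")]
}

#' Calibrate the categorical complexity protocol against measured height
#'
#' Early surveys scored structural complexity on a 1-5 categorical scale;
#' later surveys measured mean vertical substrate height (m). Ordinary least
#' squares of height on category at sites scored under both protocols yields
#' a conversion, so all sites can be expressed as (measured or calibrated)
#' substrate height.
#'
#' @param pairs data.frame with \code{category} (1-5) and \code{height_m}.
#' @return object of class \code{cx_calibration}: list with \code{slope},
#'   \code{intercept}, \code{r_squared}, \code{n} and \code{convert(x,
#'   protocol)} mapping categorical scores to predicted height; measured
#'   heights pass through unchanged.
#' @export
calibrate_complexity <- function(pairs) {
  if (nrow(pairs) < 3) stop_reefbl("need at least 3 calibration pairs")
  if (length(unique(pairs$category)) < 2) {
    stop_reefbl("degenerate calibration design: a single category value")
  }
  fit <- stats::lm(height_m ~ category, data = pairs)
  cf <- stats::coef(fit)
  out <- list(
    intercept = unname(cf[1]),
    slope = unname(cf[2]),
    r_squared = summary(fit)$r.squared,
    n = nrow(pairs)
  )
  out$convert <- function(x, protocol = c("categorical", "height")) {
    protocol <- match.arg(protocol)
    if (protocol == "height") return(x)
    out$intercept + out$slope * x
  }
  class(out) <- "cx_calibration"
  out
}

#' @export
print.cx_calibration <- function(x, ...) {
  cat(sprintf(
    "Complexity calibration: height = %.4f + %.4f * category (R^2 = %.3f, n = %d)\n",
    x$intercept, x$slope, x$r_squared, x$n))
  invisible(x)
}
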