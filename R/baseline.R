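#' Counterfactual predictions with human covariates zeroed
#'
#' Model-averaged prediction for every island with the human-density
#' covariates (HUM, HDIST by default) set to zero — the estimated biomass
#' each reef area would hold in the absence of humans, given its
#' oceanographic and habitat setting.
#'
#' @param ensemble a \code{\link{fit_ensemble}} result.
#' @param island_table covariate rows (defaults to the table the ensemble
#'   was fitted on).
#' @param human_terms covariates to zero, default \code{c("HUM", "HDIST")}.
#' @return data.frame with \code{island_id} (if present), \code{mean},
#'   \code{se} of the no-human prediction.
#' @export
predict_no_humans <- function(ensemble, island_table = NULL,
                              human_terms = c("HUM", "HDIST")) {
  if (is.null(island_table)) island_table <- ensemble$data
  missing <- setdiff(ensemble$predictors, names(island_table))
  if (length(missing) > 0) {
    stop_reefbl("island table missing covariates: ",
                paste(missing, collapse = ", "))
  }
  nd <- island_table
  for (h in intersect(human_terms, names(nd))) nd[[h]] <- 0
  pr <- model_average_predict(ensemble, nd)
  if ("island_id" %in% names(island_table)) {
    pr <- cbind(island_id = island_table$island_id, pr)
  }
  pr
}

#' Depletion relative to a no-human baseline
#'
#' depletion = 1 - observed / predicted. The 95\% CI comes from first-order
#' (delta-method) propagation of independent observed and predicted SEs on
#' the ratio: Var(obs/pred) ~ (obs/pred)^2 [(se_o/obs)^2 + (se_p/pred)^2].
#'
#' @param observed observed island biomass (g m^-2).
#' @param predicted predicted no-human biomass, > 0.
#' @param observed_se,predicted_se standard errors (default 0: point
#'   estimate only).
#' @return data.frame with \code{depletion}, \code{se}, \code{lo}, \code{hi}
#'   (95\% normal CI, truncated above at 1).
#' @examples
#' depletion(8.3, 37.7)$depletion  # ~0.78
#' @export
depletion <- function(observed, predicted, observed_se = 0,
                      predicted_se = 0) {
  if (any(predicted <= 0)) stop_reefbl("predicted baseline must be > 0")
  ratio <- observed / predicted
  se <- ratio * sqrt((observed_se / observed)^2 +
                       (predicted_se / predicted)^2)
  se[observed_se == 0 & predicted_se == 0] <- 0
  z <- stats::qnorm(0.975)
  data.frame(
    depletion = 1 - ratio,
    se = se,
    lo = 1 - ratio - z * se,
    hi = pmin(1, 1 - ratio + z * se)
  )
}

#' Island reference-point report
#'
#' Combines observed biomass and no-human baselines into per-island
#' reference points, split into two panels: remote-uninhabited reef areas
#' (zero resident population, plus configured no-harvest islands with small
#' resident staff) sorted from high to low CHL, and human-populated islands
#' sorted from low to high human density. Depletion is reported only for the
#' populated panel.
#'
#' @param island_table retained island table (needs \code{island_id},
#'   \code{total_mean}, \code{total_se}, \code{HUM}, \code{CHL}).
#' @param baseline output of \code{\link{predict_no_humans}} aligned with
#'   \code{island_table} rows.
#' @param no_harvest island ids treated as remote-uninhabited despite a
#'   (small) nonzero population; default \code{c("Midway", "Palmyra")}.
#' @return object of class \code{reference_report}: list with
#'   \code{estimates} (full table with observed/predicted CIs, depletion,
#'   status), \code{remote} and \code{populated} panels in display order.
#' @export
reference_report <- function(island_table, baseline,
                             no_harvest = c("Midway", "Palmyra")) {
  if (nrow(island_table) == 0) stop_reefbl("no islands")
  if (nrow(baseline) != nrow(island_table)) {
    stop_reefbl("baseline rows must align with island table rows")
  }
  z <- stats::qnorm(0.975)
  remote <- island_table$HUM == 0 | island_table$island_id %in% no_harvest
  dep <- depletion(island_table$total_mean, baseline$mean,
                   island_table$total_se, baseline$se)
  est <- data.frame(
    island_id = island_table$island_id,
    status = ifelse(remote, "remote-uninhabited", "populated"),
    observed = island_table$total_mean,
    observed_lo = island_table$total_mean - z * island_table$total_se,
    observed_hi = island_table$total_mean + z * island_table$total_se,
    predicted = baseline$mean,
    predicted_lo = baseline$mean - z * baseline$se,
    predicted_hi = baseline$mean + z * baseline$se,
    depletion = ifelse(remote, NA_real_, dep$depletion),
    depletion_lo = ifelse(remote, NA_real_, dep$lo),
    depletion_hi = ifelse(remote, NA_real_, dep$hi),
    CHL = island_table$CHL,
    HUM = island_table$HUM
  )
  remote_panel <- est[est$status == "remote-uninhabited", , drop = FALSE]
  remote_panel <- remote_panel[order(-remote_panel$CHL), , drop = FALSE]
  pop_panel <- est[est$status == "populated", , drop = FALSE]
  pop_panel <- pop_panel[order(pop_panel$HUM), , drop = FALSE]
  structure(list(estimates = est, remote = remote_panel,
                 populated = pop_panel), class = "reference_report")
}

#' @export
print.reference_report <- function(x, ...) {
  cat("Reef fish reference points\n")
  cat(sprintf("  %d remote-uninhabited reef areas (sorted high->low CHL)\n",
              nrow(x$remote)))
  cat(sprintf("  %d populated islands (sorted low->high human density)\n",
              nrow(x$populated)))
  if (nrow(x$populated) > 0) {
    rng <- range(x$populated$depletion)
    cat(sprintf("  depletion at populated islands: %.0f%% to %.0f%%\n",
                100 * rng[1], 100 * rng[2]))
  }
  invisible(x)
}
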