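#' Pipeline configuration
#'
#' @param out_dir output directory for all CSV/JSON artifacts.
#' @param seed integer seed for the synthetic stage and any other
#'   randomness.
#' @param simulate if TRUE (default) the synthetic generator provides the
#'   survey inputs; otherwise \code{records}, \code{species}, \code{sites},
#'   \code{strata}, \code{islands} must point to CSV files.
#' @param sim named list of overrides passed to \code{\link{sim_config}}.
#' @param responses response columns to model; default all five.
#' @param predictors candidate predictors.
#' @param r_threshold collinearity exclusion threshold.
#' @param weight_cutoff retained-model Akaike weight cutoff in (0, 1).
#' @param min_sites,max_cv island quality filters.
#' @param k smooth basis dimension.
#' @param records,species,sites,strata,islands input CSV paths (ignored when
#'   \code{simulate} is TRUE).
#' @param verbose print stage progress.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(out_dir = tempfile("reefbl_"),
                            seed = 1L,
                            simulate = TRUE,
                            sim = list(),
                            responses = c("total", TROPHIC_GROUPS),
                            predictors = c("AT", "CHL", "CX", "HC",
                                           "HDIST", "HUM", "SSTL", "WV"),
                            r_threshold = 0.8,
                            weight_cutoff = 0.05,
                            min_sites = 12, max_cv = 0.40,
                            k = 5,
                            records = NULL, species = NULL, sites = NULL,
                            strata = NULL, islands = NULL,
                            verbose = FALSE) {
  if (weight_cutoff <= 0 || weight_cutoff >= 1) {
    stop_reefbl("weight_cutoff must be in (0, 1)")
  }
  structure(as.list(environment()), class = "pipeline_config")
}

#' Load a pipeline configuration from a JSON file
#'
#' @param path JSON file whose fields match \code{\link{pipeline_config}}
#'   arguments (the \code{sim} field maps to \code{\link{sim_config}}
#'   overrides).
#' @return a \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$sim <- as.list(cfg$sim)
  do.call(pipeline_config, cfg)
}

#' Validate pipeline input tables
#'
#' Schema and invariant checks with row-level diagnostics: required columns,
#' positive areas and length-weight coefficients, non-negative counts,
#' trophic-group coverage, taxa resolvable against the species table.
#'
#' @param records,species,sites,strata,islands input data.frames (any may be
#'   NULL to skip its checks).
#' @return character vector of violations (empty when clean), invisibly;
#'   also returned as a \code{validation} attribute-free vector.
#' @export
validate_inputs <- function(records = NULL, species = NULL, sites = NULL,
                            strata = NULL, islands = NULL) {
  v <- character(0)
  need <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss) > 0) {
      v <<- c(v, paste0(what, ": missing column(s) ",
                        paste(miss, collapse = ", ")))
      FALSE
    } else TRUE
  }
  if (!is.null(species) &&
      need(species, c("taxon_id", "lw_a", "lw_b", "trophic_group"), "species")) {
    bad <- which(species$lw_a <= 0 | species$lw_b <= 0)
    if (length(bad) > 0) {
      v <- c(v, paste0("species: nonpositive length-weight parameters at row(s) ",
                       paste(bad, collapse = ",")))
    }
    if (!all(TROPHIC_GROUPS %in% species$trophic_group)) {
      v <- c(v, "species: not all four trophic groups represented")
    }
  }
  if (!is.null(records) &&
      need(records, c("site_id", "cylinder_id", "taxon_id", "count",
                      "length_cm"), "records")) {
    bad <- which(records$count < 0 | records$length_cm <= 0)
    if (length(bad) > 0) {
      v <- c(v, paste0("records: invalid count/length at row(s) ",
                       paste(utils::head(bad, 10), collapse = ",")))
    }
    if (!is.null(species)) {
      unknown <- setdiff(unique(records$taxon_id), species$taxon_id)
      if (length(unknown) > 0) {
        v <- c(v, paste0("records: unresolvable taxa ",
                         paste(unknown, collapse = ",")))
      }
    }
  }
  if (!is.null(sites)) need(sites, c("site_id", "island_id", "stratum"), "sites")
  if (!is.null(strata) &&
      need(strata, c("island_id", "stratum", "area_ha"), "strata")) {
    bad <- which(strata$area_ha <= 0)
    if (length(bad) > 0) {
      v <- c(v, paste0("strata: nonpositive area at row(s) ",
                       paste(bad, collapse = ",")))
    }
  }
  if (!is.null(islands) &&
      need(islands, c("forereef_ha", "pop", "distant_pop"), "islands")) {
    bad <- which(islands$forereef_ha <= 0)
    if (length(bad) > 0) {
      v <- c(v, paste0("islands: nonpositive forereef area at row(s) ",
                       paste(bad, collapse = ",")))
    }
  }
  invisible(v)
}

write_stage_csv <- function(df, out_dir, name) {
  path <- file.path(out_dir, name)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes, in order: (1) simulate (or load) survey inputs; (2) exclusions
#' and site biomass; (3) island aggregation; (4) collinearity screen; (5)
#' ensemble fits per response; (6) no-human baseline prediction; (7)
#' reference report. All tabular outputs are written as CSV under
#' \code{config$out_dir}; the run manifest (seed, stage row counts, input
#' hashes, package version) is written as \code{manifest.json}.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return list with the manifest, the island table, the per-response
#'   ensembles and the reference report (for the \code{total} response).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (isTRUE(config$verbose)) message(...)
  manifest <- list(package = "reefbl",
                   version = as.character(utils::packageVersion("reefbl")),
                   seed = config$seed, stages = list())
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      stop_reefbl("pipeline stage '", name, "' failed: ", conditionMessage(e))
    })
    say("stage ", name, " done")
    res
  }

  inputs <- stage("simulate", {
    if (isTRUE(config$simulate)) {
      sc <- do.call(sim_config, c(list(seed = config$seed), config$sim))
      species <- simulate_species_table(sc)
      world <- simulate_islands(sc)
      surv <- simulate_surveys(world$islands, world$truth, species, sc)
      write_stage_csv(world$truth, config$out_dir, "truth.csv")
      list(records = surv$records, species = species, sites = surv$sites,
           strata = surv$strata, islands = world$islands,
           truth = world$truth)
    } else {
      list(records = utils::read.csv(config$records),
           species = utils::read.csv(config$species),
           sites = utils::read.csv(config$sites),
           strata = utils::read.csv(config$strata),
           islands = utils::read.csv(config$islands),
           truth = NULL)
    }
  })
  viol <- validate_inputs(inputs$records, inputs$species, inputs$sites,
                          inputs$strata, inputs$islands)
  if (length(viol) > 0) {
    stop_reefbl("pipeline stage 'validate' failed:\n  ",
                paste(viol, collapse = "\n  "))
  }
  manifest$stages$simulate <- list(records = nrow(inputs$records),
                                   sites = nrow(inputs$sites),
                                   islands = nrow(inputs$islands))
  for (nm in c("records", "species", "sites", "strata", "islands")) {
    write_stage_csv(inputs[[nm]], config$out_dir, paste0(nm, ".csv"))
  }

  bio <- stage("biomass", {
    ex <- apply_exclusions(inputs$records, inputs$species, inputs$sites)
    sb <- site_biomass(ex$records, inputs$species)
    list(site_bio = sb, sites = ex$sites, log = ex$exclusion_log)
  })
  write_stage_csv(bio$site_bio, config$out_dir, "site_biomass.csv")
  manifest$stages$biomass <- list(sites = nrow(bio$site_bio),
                                  excluded_records = sum(bio$log$records_removed),
                                  excluded_sites = sum(bio$log$sites_removed))

  island_table <- stage("aggregate", {
    build_island_table(bio$site_bio, bio$sites, inputs$strata,
                       inputs$islands, min_sites = config$min_sites,
                       max_cv = config$max_cv)
  })
  write_stage_csv(island_table, config$out_dir, "island_table.csv")
  manifest$stages$aggregate <- list(islands = nrow(island_table))

  screen <- stage("screen", {
    collinearity_screen(island_table, config$predictors,
                        r_threshold = config$r_threshold)
  })
  jsonlite::write_json(
    list(pearson = screen$pearson, exclusion_pairs = screen$exclusion_pairs,
         max_vif = screen$max_vif, r_threshold = screen$r_threshold),
    file.path(config$out_dir, "screen_report.json"),
    auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  manifest$stages$screen <- list(
    n_exclusion_pairs = length(screen$exclusion_pairs),
    max_vif = screen$max_vif)

  ensembles <- stage("fit", {
    out <- list()
    for (resp in config$responses) {
      col <- if (resp == "total") "total_mean" else paste0(resp, "_mean")
      dat <- island_table
      dat[[resp]] <- dat[[col]]
      ens <- fit_ensemble(dat, resp, config$predictors,
                          constraints = screen$exclusion_pairs,
                          k = config$k, cutoff = config$weight_cutoff)
      write_stage_csv(ens$table, config$out_dir,
                      paste0("ensemble_", resp, ".csv"))
      out[[resp]] <- ens
    }
    out
  })
  manifest$stages$fit <- lapply(ensembles, function(e)
    list(models = nrow(e$table), retained = length(e$retained)))

  baseline <- stage("predict", {
    predict_no_humans(ensembles[["total"]])
  })
  write_stage_csv(baseline, config$out_dir, "baseline_total.csv")
  manifest$stages$predict <- list(islands = nrow(baseline))

  report <- stage("report", {
    reference_report(island_table, baseline)
  })
  write_stage_csv(report$estimates, config$out_dir, "baselines.csv")
  manifest$stages$report <- list(
    remote = nrow(report$remote), populated = nrow(report$populated))

  manifest$input_hashes <- vapply(
    c("records.csv", "species.csv", "sites.csv", "strata.csv", "islands.csv"),
    function(f) unname(tools::md5sum(file.path(config$out_dir, f))),
    character(1))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(manifest = manifest, island_table = island_table,
                 ensembles = ensembles, baseline = baseline,
                 report = report, truth = inputs$truth))
}

#' Command-line entry point
#'
#' Thin argument parser so the package can be driven as
#' \code{Rscript -e 'reefbl::reefbl_main()' run --out-dir DIR --seed 7}.
#' Subcommands: \code{run} (full pipeline), \code{simulate} (generator
#' only). \code{--config FILE} loads a JSON \code{\link{pipeline_config}}.
#'
#' @param args character vector, default \code{commandArgs(trailingOnly =
#'   TRUE)}.
#' @return exit status 0 invisibly.
#' @export
reefbl_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    cat("usage: reefbl <run|simulate> [--config FILE] [--seed INT] [--out-dir DIR]\n")
    return(invisible(1L))
  }
  cmd <- args[1]
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) == 1 && i < length(args)) args[i + 1] else default
  }
  cfg <- if (!is.null(opt("--config"))) {
    read_pipeline_config(opt("--config"))
  } else {
    pipeline_config()
  }
  if (!is.null(opt("--seed"))) cfg$seed <- as.integer(opt("--seed"))
  if (!is.null(opt("--out-dir"))) cfg$out_dir <- opt("--out-dir")
  cfg$verbose <- TRUE

  if (cmd == "run") {
    run_pipeline(cfg)
  } else if (cmd == "simulate") {
    sc <- do.call(sim_config, c(list(seed = cfg$seed), cfg$sim))
    species <- simulate_species_table(sc)
    world <- simulate_islands(sc)
    surv <- simulate_surveys(world$islands, world$truth, species, sc)
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_stage_csv(surv$records, cfg$out_dir, "fish_records.csv")
    write_stage_csv(surv$sites, cfg$out_dir, "sites.csv")
    write_stage_csv(surv$strata, cfg$out_dir, "strata.csv")
    write_stage_csv(world$islands, cfg$out_dir, "islands.csv")
    write_stage_csv(world$truth, cfg$out_dir, "truth.csv")
    write_stage_csv(species, cfg$out_dir, "species.csv")
  } else {
    stop_reefbl("unknown subcommand '", cmd, "'")
  }
  invisible(0L)
}
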