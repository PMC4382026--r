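#' Pearson correlation matrix of island predictors
#'
#' Pairwise Pearson correlations over the island table; the binary atoll
#' indicator enters as 0/1 (point-biserial correlation).
#'
#' @param tab island table with the predictor columns.
#' @param predictors character vector of column names.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
pearson_matrix <- function(tab, predictors) {
  if (nrow(tab) < 3) stop_reefbl("need at least 3 islands")
  x <- as.matrix(tab[, predictors, drop = FALSE])
  if (anyNA(x)) stop_reefbl("missing predictor values")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop_reefbl("constant predictor column(s): ",
                paste(predictors[sds == 0], collapse = ", "))
  }
  stats::cor(x)
}

#' Variance inflation factors
#'
#' VIF_j = 1 / (1 - R^2_j), with R^2_j from the ordinary least squares
#' regression of predictor j on the other predictors in the subset.
#' Perfectly collinear predictors are reported as \code{Inf}, not dropped.
#'
#' @param tab island table.
#' @param predictors predictor subset (length >= 2).
#' @return named numeric vector of VIFs (all >= 1).
#' @export
vif <- function(tab, predictors) {
  if (length(predictors) < 2) stop_reefbl("VIF needs at least 2 predictors")
  if (nrow(tab) <= length(predictors)) {
    stop_reefbl("need more islands than predictors")
  }
  x <- as.data.frame(tab[, predictors, drop = FALSE])
  out <- vapply(predictors, function(p) {
    f <- stats::as.formula(paste0("`", p, "` ~ ",
                                  paste0("`", setdiff(predictors, p), "`",
                                         collapse = " + ")))
    r2 <- summary(stats::lm(f, data = x))$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  out
}

#' Mutual-exclusion constraints for model enumeration
#'
#' Pairs of predictors whose absolute Pearson correlation reaches the
#' threshold are barred from co-occurring in a single candidate model; extra
#' pairs may be declared a priori.
#'
#' @param mat correlation matrix from \code{\link{pearson_matrix}}.
#' @param r_threshold absolute-correlation threshold in (0, 1], default 0.8.
#' @param declared list of length-2 character vectors to always exclude.
#' @return list of sorted length-2 character vectors (deduplicated).
#' @export
exclusion_pairs <- function(mat, r_threshold = 0.8, declared = list()) {
  if (r_threshold <= 0 || r_threshold > 1) {
    stop_reefbl("r_threshold must be in (0, 1]")
  }
  pairs <- list()
  nm <- colnames(mat)
  for (i in seq_len(ncol(mat) - 1)) {
    for (j in seq(i + 1, ncol(mat))) {
      if (abs(mat[i, j]) >= r_threshold) {
        pairs[[length(pairs) + 1L]] <- sort(c(nm[i], nm[j]))
      }
    }
  }
  for (p in declared) pairs[[length(pairs) + 1L]] <- sort(p)
  unique(pairs)
}

#' Collinearity screen report
#'
#' Runs the full screening step: Pearson matrix over all predictors,
#' derivation of mutual-exclusion pairs, and VIFs within each maximal
#' admissible subset (for each exclusion pair, the subsets omitting one
#' member; with no pairs, the full set).
#'
#' @inheritParams pearson_matrix
#' @inheritParams exclusion_pairs
#' @return object of class \code{screen_report}: list with \code{pearson},
#'   \code{exclusion_pairs}, \code{vif} (named list per subset),
#'   \code{max_vif} and the thresholds used.
#' @export
collinearity_screen <- function(tab, predictors = ALL_PREDICTORS,
                                r_threshold = 0.8, declared = list()) {
  mat <- pearson_matrix(tab, predictors)
  pairs <- exclusion_pairs(mat, r_threshold, declared)
  subsets <- if (length(pairs) == 0) {
    list(all = predictors)
  } else {
    # omit one member of each constrained pair in every combination
    choices <- expand.grid(lapply(pairs, function(p) p),
                           stringsAsFactors = FALSE)
    ss <- lapply(seq_len(nrow(choices)), function(i) {
      setdiff(predictors, unlist(choices[i, ]))
    })
    names(ss) <- vapply(seq_len(nrow(choices)), function(i) {
      paste0("minus_", paste(unlist(choices[i, ]), collapse = "_"))
    }, character(1))
    ss
  }
  vifs <- lapply(subsets, function(s) vif(tab, s))
  structure(list(
    pearson = mat,
    exclusion_pairs = pairs,
    vif = vifs,
    max_vif = max(unlist(vifs)),
    r_threshold = r_threshold
  ), class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat("Collinearity screen over", ncol(x$pearson), "predictors\n")
  cat("Exclusion pairs (|r| >=", x$r_threshold, "or declared):",
      if (length(x$exclusion_pairs) == 0) "none" else
        paste(vapply(x$exclusion_pairs, paste, character(1), collapse = "-"),
              collapse = ", "), "\n")
  cat("Max VIF over admissible subsets:", round(x$max_vif, 2), "\n")
  invisible(x)
}
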