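#' Enumerate admissible additive model specifications
#'
#' All subsets of the predictor set (including the intercept-only null
#' model) that contain no mutually excluded pair, in deterministic order:
#' by number of terms, then lexicographically.
#'
#' @param predictors character vector of predictor names.
#' @param constraints list of length-2 character vectors that may not
#'   co-occur in one model.
#' @return list of character vectors (each sorted); the first element is
#'   \code{character(0)}, the null model.
#' @examples
#' length(enumerate_models(c("A", "B"), list()))                 # 4
#' # 8 predictors, one exclusion pair: 2^8 - 2^6 = 192 models
#' @export
enumerate_models <- function(predictors, constraints = list()) {
  predictors <- sort(unique(predictors))
  bad <- vapply(constraints, function(p) !all(p %in% predictors), logical(1))
  if (any(bad)) stop_reefbl("constraint names outside the predictor set")
  specs <- list(character(0))
  for (m in seq_along(predictors)) {
    cm <- utils::combn(predictors, m, simplify = FALSE)
    specs <- c(specs, cm)
  }
  ok <- vapply(specs, function(s) {
    !any(vapply(constraints, function(p) all(p %in% s), logical(1)))
  }, logical(1))
  specs <- specs[ok]
  # order: size, then lexicographic on the comma-joined term string
  key <- vapply(specs, paste, character(1), collapse = ",")
  specs[order(lengths(specs), key)]
}

#' Small-sample corrected Akaike information criterion
#'
#' AICc = -2*logLik + 2k + 2k(k+1)/(n-k-1), with k the (possibly fractional)
#' effective number of parameters including the dispersion parameter.
#'
#' @param log_likelihood maximised log-likelihood.
#' @param k effective number of parameters (> 0, may be fractional for
#'   penalized smooths).
#' @param n number of observations; requires n - k - 1 > 0.
#' @return AICc value.
#' @examples
#' aicc(-100, 5, 37)  # 210 + 60/31
#' @export
aicc <- function(log_likelihood, k, n) {
  if (n - k - 1 <= 0) stop_reefbl("AICc undefined: need n - k - 1 > 0")
  -2 * log_likelihood + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike deltas and weights
#'
#' delta_i = AICc_i - min(AICc); weight_i = exp(-delta_i/2) normalised over
#' the whole model set. Non-finite AICc values receive weight 0.
#'
#' @param aicc_values numeric vector of AICc values.
#' @return data.frame with \code{aicc}, \code{delta}, \code{weight}.
#' @export
akaike_weights <- function(aicc_values) {
  fin <- is.finite(aicc_values)
  if (!any(fin)) stop_reefbl("no finite AICc values")
  delta <- aicc_values - min(aicc_values[fin])
  raw <- ifelse(fin, exp(-delta / 2), 0)
  data.frame(aicc = aicc_values, delta = delta, weight = raw / sum(raw))
}

gam_formula <- function(response, terms, k, parametric = "AT") {
  if (length(terms) == 0) {
    return(stats::as.formula(paste(response, "~ 1")))
  }
  rhs <- vapply(terms, function(t) {
    if (t %in% parametric) t else sprintf("s(%s, k = %d)", t, k)
  }, character(1))
  stats::as.formula(paste(response, "~", paste(rhs, collapse = " + ")))
}

#' Fit one candidate gamma log-link additive model
#'
#' Penalized-spline GAM (mgcv) with gamma family and log link; every
#' continuous term gets a thin-plate smooth with basis dimension
#' \code{k} (5 by default, guarding against overfitting with few islands),
#' binary terms (AT) enter as linear 0/1 parametric terms.
#'
#' @param data island table (strictly positive response).
#' @param response response column name.
#' @param terms character vector of predictor names (may be empty: null
#'   model).
#' @param k smooth basis dimension, default 5.
#' @param method mgcv smoothness selection: \code{"GCV.Cp"} (default) or
#'   \code{"REML"}.
#' @param parametric names treated as parametric (default \code{"AT"}).
#' @param ... further arguments passed to \code{mgcv::gam} (e.g. fixed
#'   smoothing parameters \code{sp}).
#' @return object of class \code{reef_fit}: list with \code{terms},
#'   \code{gam} (the mgcv fit), \code{loglik}, \code{df} (total effective
#'   degrees of freedom incl. intercept and scale), \code{aicc},
#'   \code{adj_r2}, \code{fitted}, \code{se_fit} (response scale) and
#'   \code{converged}.
#' @export
fit_gam <- function(data, response, terms, k = 5, method = "GCV.Cp",
                    parametric = "AT", ...) {
  y <- data[[response]]
  if (is.null(y)) stop_reefbl("response column '", response, "' not found")
  if (any(!is.finite(y)) || any(y <= 0)) {
    stop_reefbl("gamma log-link response must be strictly positive")
  }
  f <- gam_formula(response, terms, k, parametric)
  fit <- mgcv::gam(f, family = stats::Gamma(link = "log"), data = data,
                   method = method, ...)
  ll <- stats::logLik(fit)
  kdf <- attr(ll, "df")  # total edf + 1 for the gamma scale parameter
  pr <- stats::predict(fit, type = "response", se.fit = TRUE)
  structure(list(
    terms = terms,
    gam = fit,
    loglik = as.numeric(ll),
    df = kdf,
    aicc = aicc(as.numeric(ll), kdf, nrow(data)),
    adj_r2 = summary(fit)$r.sq,
    fitted = as.numeric(pr$fit),
    se_fit = as.numeric(pr$se.fit),
    converged = isTRUE(fit$converged)
  ), class = "reef_fit")
}

#' @export
print.reef_fit <- function(x, ...) {
  cat(sprintf("Gamma log-link GAM [%s] df = %.1f, adj-R2 = %.3f, AICc = %.2f\n",
              if (length(x$terms) == 0) "null" else
                paste(x$terms, collapse = " + "),
              x$df, x$adj_r2, x$aicc))
  invisible(x)
}

#' Fit the exhaustive constrained model ensemble
#'
#' Enumerates every admissible term subset, fits each as a gamma log-link
#' GAM, computes AICc, and derives Akaike weights and per-predictor variable
#' importance over the \emph{full} model space. Models with Akaike weight
#' above \code{cutoff} form the retained set used for model-averaged
#' prediction. Models that fail or do not converge are dropped with a
#' warning and carry zero weight.
#'
#' @inheritParams fit_gam
#' @param predictors candidate predictor names.
#' @param constraints mutual-exclusion pairs (see
#'   \code{\link{enumerate_models}}), e.g. from
#'   \code{\link{collinearity_screen}}.
#' @param cutoff retention threshold on Akaike weight, default 0.05.
#' @return object of class \code{reef_ensemble}: list with \code{fits},
#'   \code{table} (one row per fitted model: term flags, d.f., adj-R2,
#'   AICc, delta, weight), \code{retained} (indices), \code{importance},
#'   \code{response}, \code{predictors}, \code{data}.
#' @export
fit_ensemble <- function(data, response, predictors,
                         constraints = list(), k = 5, cutoff = 0.05,
                         method = "GCV.Cp") {
  specs <- enumerate_models(predictors, constraints)
  fits <- vector("list", length(specs))
  failed <- logical(length(specs))
  for (i in seq_along(specs)) {
    fits[[i]] <- tryCatch(
      fit_gam(data, response, specs[[i]], k = k, method = method),
      error = function(e) e
    )
    failed[i] <- inherits(fits[[i]], "error") ||
      !isTRUE(fits[[i]]$converged)
  }
  if (any(failed)) {
    warning(sum(failed), " model(s) failed or did not converge; ",
            "dropped from the ensemble")
  }
  if (all(failed)) stop_reefbl("every candidate model failed")
  specs <- specs[!failed]
  fits <- fits[!failed]
  av <- akaike_weights(vapply(fits, `[[`, numeric(1), "aicc"))
  ord <- order(av$aicc)
  specs <- specs[ord]; fits <- fits[ord]; av <- av[ord, ]

  flag <- sapply(predictors, function(p)
    vapply(specs, function(s) p %in% s, logical(1)))
  flag <- matrix(flag, nrow = length(specs),
                 dimnames = list(NULL, predictors))
  tab <- data.frame(flag * 1L, check.names = FALSE)
  tab$df <- vapply(fits, `[[`, numeric(1), "df")
  tab$adj_r2 <- vapply(fits, `[[`, numeric(1), "adj_r2")
  tab$aicc <- av$aicc
  tab$delta <- av$delta
  tab$weight <- av$weight

  importance <- vapply(predictors, function(p)
    sum(tab$weight[flag[, p]]), numeric(1))
  structure(list(
    fits = fits,
    specs = specs,
    table = tab,
    retained = which(tab$weight > cutoff),
    cutoff = cutoff,
    importance = importance,
    response = response,
    predictors = predictors,
    constraints = constraints,
    data = data
  ), class = "reef_ensemble")
}

#' Variable importance
#'
#' Sum of the Akaike weights of every model containing each predictor,
#' computed over the full enumerated model space (weights sum to 1, so
#' importance lies in [0, 1]).
#'
#' @param ensemble a \code{reef_ensemble}.
#' @return named numeric vector.
#' @export
variable_importance <- function(ensemble) {
  ensemble$importance
}

#' Model-averaged prediction with unconditional standard errors
#'
#' Averages predictions of the retained models (weights renormalised over
#' the retained set) on the response scale. The unconditional variance adds
#' the between-model spread to the within-model variance:
#' SE^2 = sum_i w_i (se_i^2 + (yhat_i - ybar)^2).
#'
#' @param ensemble a \code{reef_ensemble}.
#' @param newdata covariate rows carrying every predictor column.
#' @param scale \code{"response"} (default) or \code{"link"}: scale on which
#'   predictions are averaged.
#' @return data.frame with \code{mean} and \code{se} per row of
#'   \code{newdata}.
#' @export
model_average_predict <- function(ensemble, newdata,
                                  scale = c("response", "link")) {
  scale <- match.arg(scale)
  ri <- ensemble$retained
  if (length(ri) == 0) stop_reefbl("retained model set is empty")
  w <- ensemble$table$weight[ri]
  w <- w / sum(w)
  preds <- lapply(ensemble$fits[ri], function(f) {
    stats::predict(f$gam, newdata = newdata, type = scale, se.fit = TRUE)
  })
  yhat <- sapply(preds, function(p) as.numeric(p$fit))
  sehat <- sapply(preds, function(p) as.numeric(p$se.fit))
  yhat <- matrix(yhat, nrow = nrow(newdata))
  sehat <- matrix(sehat, nrow = nrow(newdata))
  mu <- as.numeric(yhat %*% w)
  v <- sapply(seq_len(nrow(newdata)), function(i) {
    sum(w * (sehat[i, ]^2 + (yhat[i, ] - mu[i])^2))
  })
  out <- data.frame(mean = mu, se = sqrt(v))
  if (scale == "link") {
    out$mean_response <- exp(out$mean)
  }
  out
}

#' Partial smoother profile of one predictor
#'
#' Predicts the response over a grid of equally spaced values of one
#' predictor, holding all other predictors at their observed means (AT at
#' its mean, i.e. the atoll fraction), and rescales the curve as a
#' proportion of its value at a reference point: predictor = 0 for the
#' human-density terms (HUM, HDIST), the observed minimum otherwise.
#'
#' @param ensemble a \code{reef_ensemble}.
#' @param predictor predictor to profile; must occur in at least one
#'   retained model.
#' @param n_grid grid resolution, default 100.
#' @param model \code{"top"} (default; the AICc-best retained model, as used
#'   for smoother visualisation) or \code{"average"} (retained-set model
#'   average).
#' @param reference reference predictor value for scaling; default as
#'   described above.
#' @return data.frame with \code{value} (predictor), \code{response}
#'   (predicted biomass), \code{se}, and \code{scaled} (proportion of the
#'   reference prediction, = 1 at the reference point by construction).
#' @export
smoother_profile <- function(ensemble, predictor, n_grid = 100,
                             model = c("top", "average"), reference = NULL) {
  model <- match.arg(model)
  ri <- ensemble$retained
  in_retained <- vapply(ensemble$specs[ri], function(s) predictor %in% s,
                        logical(1))
  if (!any(in_retained)) {
    stop_reefbl("predictor '", predictor, "' absent from all retained models")
  }
  dat <- ensemble$data
  rng <- range(dat[[predictor]])
  grid <- seq(rng[1], rng[2], length.out = n_grid)
  if (is.null(reference)) {
    reference <- if (predictor %in% c("HUM", "HDIST")) 0 else rng[1]
  }
  nd <- as.data.frame(lapply(dat[, ensemble$predictors, drop = FALSE], mean))
  nd <- nd[rep(1, n_grid + 1), , drop = FALSE]
  nd[[predictor]] <- c(grid, reference)

  if (model == "top") {
    top <- ri[in_retained][1]
    pr <- stats::predict(ensemble$fits[[top]]$gam, newdata = nd,
                         type = "response", se.fit = TRUE)
    resp <- as.numeric(pr$fit); se <- as.numeric(pr$se.fit)
  } else {
    pr <- model_average_predict(ensemble, nd)
    resp <- pr$mean; se <- pr$se
  }
  ref_val <- resp[n_grid + 1]
  data.frame(value = grid,
             response = resp[seq_len(n_grid)],
             se = se[seq_len(n_grid)],
             scaled = resp[seq_len(n_grid)] / ref_val)
}

#' @export
print.reef_ensemble <- function(x, digits = 3, ...) {
  cat(sprintf("Gamma log-link GAM ensemble for '%s': %d models, %d retained (weight > %.2f)\n",
              x$response, nrow(x$table), length(x$retained), x$cutoff))
  tt <- x$table[x$retained, , drop = FALSE]
  for (p in x$predictors) tt[[p]] <- ifelse(tt[[p]] == 1, "X", "")
  tt$df <- round(tt$df, 1)
  tt$adj_r2 <- round(tt$adj_r2, 3)
  tt$aicc <- round(tt$aicc, 2)
  tt$delta <- round(tt$delta, 2)
  tt$weight <- round(tt$weight, 3)
  print(tt, row.names = FALSE)
  cat("Variable importance (all models):\n")
  print(round(x$importance, digits))
  invisible(x)
}
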