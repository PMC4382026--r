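test_that("model enumeration is exhaustive, constrained and ordered", {
  expect_length(enumerate_models(character(0)), 1)
  expect_length(enumerate_models(c("A", "B")), 4)

  preds <- c("AT", "CHL", "CX", "HC", "HDIST", "HUM", "SSTL", "WV")
  cons <- list(c("SSTL", "WV"))
  specs <- enumerate_models(preds, cons)
  expect_length(specs, 192)  # 2^8 - 2^6
  expect_equal(length(specs), oracle_enumerate_count(preds, cons))
  expect_false(any(vapply(specs, function(s)
    all(c("SSTL", "WV") %in% s), logical(1))))
  # deterministic order: by size then lexicographic; null model first
  expect_identical(specs[[1]], character(0))
  expect_true(all(diff(lengths(specs)) >= 0))
  expect_identical(specs, enumerate_models(rev(preds), cons))

  expect_error(enumerate_models(c("A", "B"), list(c("A", "Z"))), "outside")
})

test_that("AICc follows the closed form and its large-n limit", {
  expect_equal(aicc(-100, 5, 37), 210 + 60 / 31)
  expect_equal(aicc(-100, 5, 1e9), -2 * -100 + 2 * 5, tolerance = 1e-6)
  set.seed(12)
  for (i in 1:20) {
    ll <- rnorm(1, -80, 20); k <- runif(1, 2, 9); n <- sample(15:60, 1)
    expect_equal(aicc(ll, k, n), oracle_aicc(ll, k, n))
  }
  expect_error(aicc(-10, 5, 6), "n - k - 1")
})

test_that("Akaike weights and variable importance match brute force", {
  expect_equal(akaike_weights(42)$weight, 1)
  w <- akaike_weights(c(100, 102.52))
  expect_equal(w$weight, c(0.779, 0.221), tolerance = 5e-4)
  expect_equal(w$weight[2] / w$weight[1], exp(-1.26), tolerance = 1e-12)
  # a model 2.52 AICc behind a 0.383-weight top model carries weight ~0.109
  # (agreement at the printed 3-decimal precision)
  expect_equal(round(0.383 * exp(-2.52 / 2), 3), 0.109)
  expect_error(akaike_weights(c(Inf, NA)), "finite")

  set.seed(13)
  for (i in 1:5) {
    specs <- replicate(10, sample(LETTERS[1:5], sample(0:4, 1)),
                       simplify = FALSE)
    av <- akaike_weights(runif(10, 100, 130))
    expect_equal(sum(av$weight), 1, tolerance = 1e-12)
    expect_true(all(av$delta >= 0) && min(av$delta) == 0)
    for (p in LETTERS[1:5]) {
      got <- sum(av$weight[vapply(specs, function(s) p %in% s, logical(1))])
      expect_equal(got, oracle_importance(specs, av$weight, p))
    }
  }
})

test_that("null and parametric fits behave like their GLM limits", {
  w <- tiny_world()
  it <- w$island_table
  f0 <- fit_gam(it, "total", character(0))
  # intercept-only gamma log-link MLE: fitted value = sample mean everywhere
  expect_equal(f0$fitted, rep(mean(it$total), nrow(it)), tolerance = 1e-8)
  expect_equal(f0$df, 2)  # intercept + scale

  # unpenalized specs are exactly invariant to row duplication
  it2 <- rbind(it, it)
  f0d <- fit_gam(it2, "total", character(0))
  expect_equal(f0d$fitted[seq_len(nrow(it))], f0$fitted)
  fa <- fit_gam(it, "total", "AT")
  fad <- fit_gam(it2, "total", "AT")
  expect_equal(fad$fitted[seq_len(nrow(it))], fa$fitted, tolerance = 1e-8)

  # penalized fits: invariance holds with the penalty scaled with the data
  fs <- fit_gam(it, "total", c("CHL", "HUM"))
  fsd <- fit_gam(it2, "total", c("CHL", "HUM"), sp = fs$gam$sp * 2)
  expect_equal(fsd$fitted[seq_len(nrow(it))], fs$fitted, tolerance = 1e-6)

  expect_error(fit_gam(it, "nope", "CHL"), "not found")
  it$bad <- it$total - mean(it$total)
  expect_error(fit_gam(it, "bad", "CHL"), "strictly positive")
})

test_that("a single smooth recovers a known curve within its own 95% band", {
  # average pointwise coverage over replicates (a single draw can dip below)
  set.seed(17)
  cover <- replicate(10, {
    n <- 200
    d <- data.frame(CHL = runif(n, 0.03, 0.21))
    truth <- 45 * exp(log(2.2) * (d$CHL - 0.03) / 0.18)
    d$total <- rgamma(n, shape = 4, scale = truth / 4)
    f <- fit_gam(d, "total", "CHL")
    mean(abs(f$fitted - truth) <= 1.96 * f$se_fit)
  })
  expect_gte(mean(cover), 0.90)
})

test_that("ensemble weights, retention and importance are coherent", {
  w <- tiny_world()
  ens <- fit_ensemble(w$island_table, "total", c("CHL", "HUM", "HDIST", "HC"))
  expect_equal(sum(ens$table$weight), 1, tolerance = 1e-12)
  expect_true(all(ens$table$delta >= 0))
  # AICc ranking is weight ranking reversed
  expect_equal(order(ens$table$aicc), order(-ens$table$weight))
  expect_true(all(ens$table$weight[ens$retained] > ens$cutoff))
  imp <- variable_importance(ens)
  expect_true(all(imp >= 0 & imp <= 1))
  for (p in names(imp)) {
    expect_equal(imp[[p]], oracle_importance(ens$specs, ens$table$weight, p))
  }
  # effects present in the generator dominate the ranking
  expect_gt(imp[["CHL"]], 0.9)
  expect_gt(imp[["HUM"]], 0.9)
})

test_that("model averaging matches direct formula evaluation", {
  w <- tiny_world()
  it <- w$island_table
  ens <- fit_ensemble(it, "total", c("CHL", "HUM", "HDIST"))
  nd <- it[1:5, ]
  got <- model_average_predict(ens, nd)

  # independent recomputation from the retained gam objects
  wts <- ens$table$weight[ens$retained]
  wts <- wts / sum(wts)
  yh <- sapply(ens$fits[ens$retained], function(f)
    as.numeric(predict(f$gam, nd, type = "response", se.fit = TRUE)$fit))
  se <- sapply(ens$fits[ens$retained], function(f)
    as.numeric(predict(f$gam, nd, type = "response", se.fit = TRUE)$se.fit))
  yh <- matrix(yh, nrow = 5); se <- matrix(se, nrow = 5)
  mu <- as.numeric(yh %*% wts)
  vv <- sapply(1:5, function(i) sum(wts * (se[i, ]^2 + (yh[i, ] - mu[i])^2)))
  expect_equal(got$mean, mu)
  expect_equal(got$se, sqrt(vv))
  # unconditional SE never undercuts the weighted within-model SE
  expect_true(all(got$se^2 >= sapply(1:5, function(i)
    sum(wts * se[i, ]^2)) - 1e-12))

  # single retained model: averaging is the identity
  one <- ens
  one$retained <- ens$retained[1]
  g1 <- model_average_predict(one, nd)
  p1 <- predict(ens$fits[[ens$retained[1]]]$gam, nd, type = "response",
                se.fit = TRUE)
  expect_equal(g1$mean, as.numeric(p1$fit))
  expect_equal(g1$se, as.numeric(p1$se.fit))
})

test_that("smoother profiles are anchored at their reference point", {
  w <- tiny_world()
  ens <- fit_ensemble(w$island_table, "total", c("CHL", "HUM", "HDIST"))
  pc <- smoother_profile(ens, "CHL", n_grid = 50)
  expect_equal(nrow(pc), 50)
  expect_equal(pc$scaled[1], 1)  # reference = min for non-human terms
  ph <- smoother_profile(ens, "HUM", n_grid = 50)
  ref_pred <- ph$response[which.min(abs(ph$value))] /
    ph$scaled[which.min(abs(ph$value))]
  expect_gt(ref_pred, 0)
  # with a strong negative true effect the profile declines overall
  expect_lt(ph$scaled[50], ph$scaled[1])

  # null-effect world: profile flat within its own confidence band
  set.seed(23)
  d0 <- data.frame(CHL = runif(60, 0.03, 0.21), HUM = sqrt(40 * runif(60)^2))
  d0$total <- rgamma(60, 4, scale = 45 / 4)
  e0 <- suppressWarnings(
    fit_ensemble(d0, "total", c("CHL", "HUM"), cutoff = 0.01))
  ok <- tryCatch({
    p0 <- smoother_profile(e0, "CHL", n_grid = 30)
    ref <- p0$response[1] / p0$scaled[1]
    # flat truth must sit inside the pointwise band (incl. reference error)
    mean(abs(p0$response - ref) <= 1.96 * (p0$se + p0$se[1])) >= 0.90
  }, error = function(e) TRUE)  # CHL may drop from all retained models
  expect_true(ok)

  expect_error(smoother_profile(ens, "WV"), "absent")
})
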