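test_that("K = 1 reduces exactly to OLS", {
  set.seed(2)
  x <- runif(300, 1e3, 5e4)
  y <- 500 + 0.3 * x + rnorm(300, 0, 800)
  fit <- em_fit_mixture(x, y, K = 1)
  ols <- stats::lm(y ~ x)
  expect_equal(fit$beta1, unname(coef(ols)[1]), tolerance = 1e-10)
  expect_equal(fit$beta2, unname(coef(ols)[2]), tolerance = 1e-10)
  expect_equal(fit$sigma, sqrt(sum(resid(ols)^2) / 300), tolerance = 1e-10)
  expect_equal(fit$loglik, as.numeric(logLik(ols)), tolerance = 1e-8)
})

test_that("EM log-likelihood is non-decreasing and nests lower K", {
  d <- gen_mixture_data(1500, seed = 21)
  fits <- lapply(1:4, function(K)
    em_fit_mixture(d$x, d$y, K, seed = 31, n_restarts = 4))
  for (f in fits) {
    expect_true(all(diff(f$loglik_trace) >= -1e-6 * abs(f$loglik)))
  }
  ll <- vapply(fits, function(f) f$loglik, numeric(1))
  expect_true(all(diff(ll) >= -1e-6))
})

test_that("EM recovers ground-truth mixture parameters", {
  d <- gen_mixture_data(5000, seed = 77)
  fit <- em_fit_mixture(d$x, d$y, K = 4, seed = 78, n_restarts = 5)
  gt <- d$truth
  ord <- order(gt$beta2)
  expect_true(all(abs(fit$beta2 - gt$beta2[ord]) / gt$beta2[ord] < 0.05))
  expect_true(all(abs(fit$weights - gt$weights[ord]) < 0.03))
  expect_equal(sum(fit$weights), 1, tolerance = 1e-9)
  # slope-sorted components, positive weights, sigma above floor
  expect_true(all(diff(fit$beta2) >= 0))
  expect_true(all(fit$weights > 0) && all(fit$sigma > 0))
})

test_that("component labelling is invariant to initialisation", {
  d <- gen_mixture_data(2500, seed = 41)
  f1 <- em_fit_mixture(d$x, d$y, 4, seed = 1, n_restarts = 4)
  f2 <- em_fit_mixture(d$x, d$y, 4, seed = 999, n_restarts = 4)
  expect_equal(f1$beta2, f2$beta2, tolerance = 1e-4)
  expect_equal(f1$weights, f2$weights, tolerance = 1e-4)
})

test_that("degenerate fits error after exhausting restarts", {
  set.seed(6)
  x <- runif(80, 0, 100)
  y <- 2 + 3 * x  # exactly linear: extra components must degenerate
  expect_error(em_fit_mixture(x, y, K = 5, seed = 7, n_restarts = 3),
               "degenerat")
})

test_that("information criteria match their closed forms", {
  ic <- information_criteria(0, K = 2, n = exp(2))
  expect_equal(unname(ic["k"]), 7)
  expect_equal(unname(ic["AIC"]), 14)
  expect_equal(unname(ic["AIC3"]), 21)
  expect_equal(unname(ic["BIC"]), 14)
  expect_equal(unname(ic["MDL"]), 7)
  # AIC3 - AIC = k for any fit; MDL = BIC / 2
  ic2 <- information_criteria(-1234.5, K = 4, n = 5000)
  expect_equal(unname(ic2["AIC3"] - ic2["AIC"]), unname(ic2["k"]))
  expect_equal(unname(ic2["MDL"]), unname(ic2["BIC"]) / 2)
  expect_error(information_criteria(0, 2, 1), "exceed")
})

test_that("selection tabulates criteria over the K range", {
  d <- gen_mixture_data(2000, seed = 55)
  sel <- select_mixture_components(d$x, d$y, K_range = 1:4, seed = 56,
                                   n_restarts = 3)
  expect_equal(sel$table$K, 1:4)
  expect_true(all(is.finite(sel$table$BIC)))
  for (cr in c("AIC", "AIC3", "MDL", "BIC")) {
    expect_equal(sel$table$K[which.min(sel$table[[cr]])],
                 unname(sel$chosen[cr]))
  }
})

test_that("expected prediction matches the mixture mean and variance law", {
  m <- ballastr:::new_mixture(2, c(0.5, 0.5), c(0, 0), c(1, 3), c(1, 1),
                              0, 100, 0, 1L)
  p <- predict_discharge(m, capacity = 10)
  expect_equal(p$expected_m3, 20)
  # between-component variance (10-20)^2/2 + (30-20)^2/2 = 100, plus 1
  expect_equal(p$variance_m6, 101)
  expect_gte(p$variance_m6, 100)
})

test_that("sampled predictions average to the expected prediction", {
  d <- gen_mixture_data(3000, seed = 61)
  fit <- em_fit_mixture(d$x, d$y, 4, seed = 62, n_restarts = 3)
  xcap <- 30000
  ex <- predict_discharge(fit, xcap)
  set.seed(63)
  draws <- replicate(4000, predict_discharge(fit, xcap, mode = "sample"))
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - ex$expected_m3), 3 * se)
})

test_that("predictions are truncated to the feasible range", {
  m <- ballastr:::new_mixture(1, 1, -500, 0.1, 10, 0, 50, 0, 1L)
  expect_equal(predict_discharge(m, 0)$expected_m3, 0)
  # cap at 120% of implied DWT = 1.2 * capacity / 0.30 = 4 * capacity
  big <- ballastr:::new_mixture(1, 1, 0, 10, 1, 0, 50, 0, 1L)
  expect_equal(predict_discharge(big, 100)$expected_m3, 400)
})

test_that("unseen purpose levels fall back to the marginal offset", {
  d <- gen_tanker_data(400, seed = 13)
  fit <- fit_linear_discharge(d)
  expect_warning(
    p <- predict_discharge(fit, 2e4, purpose = "moon_base"),
    "unseen")
  ft <- fit$factor_terms$purpose
  manual <- fit$intercept + fit$capacity_slope * 2e4 +
    sum(ft$offset * ft$freq)
  expect_equal(p$expected_m3, manual)
})

test_that("cross-validation is deterministic given a seed and exact on noiseless data", {
  set.seed(4)
  x <- runif(400, 1e3, 5e4)
  v <- tibble::tibble(discharge_m3 = 100 + 0.5 * x, capacity_m3 = x)
  cv <- cross_validate(discharge_spec("linear", "capacity"), v,
                       n_repeats = 3, seed = 10)
  expect_equal(cv$summary$mean_r_squared, 1, tolerance = 1e-9)
  expect_equal(cv$summary$mean_abs_total_error_m3, 0, tolerance = 1e-6)
  cv2 <- cross_validate(discharge_spec("linear", "capacity"), v,
                        n_repeats = 3, seed = 10)
  expect_identical(cv$repeats, cv2$repeats)
})

test_that("mixture cross-validation matches the linear model when the mixture mean is linear", {
  # with capacity-independent weights the mixture predictive mean is an
  # affine function of capacity, so held-out accuracy must match OLS
  d <- gen_mixture_data(2500, seed = 71)
  v <- tibble::tibble(discharge_m3 = d$y, capacity_m3 = d$x)
  cv_mix <- cross_validate(discharge_spec("mixture", K = 4, n_restarts = 2),
                           v, n_repeats = 5, seed = 72)
  cv_lin <- cross_validate(discharge_spec("linear", "capacity"),
                           v, n_repeats = 5, seed = 72)
  expect_gt(cv_mix$summary$mean_r_squared,
            cv_lin$summary$mean_r_squared - 0.02)
  expect_lt(abs(cv_mix$summary$mean_total_error_m3 -
                  cv_lin$summary$mean_total_error_m3),
            0.05 * sum(v$discharge_m3))
})

test_that("fitted models survive a JSON round trip", {
  d <- gen_mixture_data(1200, seed = 81)
  fit <- em_fit_mixture(d$x, d$y, 3, seed = 82, n_restarts = 2)
  f <- tempfile(fileext = ".json")
  model_to_json(fit, f)
  back <- model_from_json(f)
  expect_equal(back$beta2, fit$beta2)
  expect_equal(predict_discharge(back, 2e4)$expected_m3,
               predict_discharge(fit, 2e4)$expected_m3)
  lin <- fit_linear_discharge(gen_tanker_data(300, seed = 83))
  model_to_json(lin, f)
  lin2 <- model_from_json(f)
  expect_equal(predict_discharge(lin2, 2e4, purpose = "coal"),
               predict_discharge(lin, 2e4, purpose = "coal"))
})
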