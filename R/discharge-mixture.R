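#' Fit a K-component mixture of linear regressions by EM
#'
#' Models bulker ballast discharge y as drawn from component j with
#' probability p_j, where under component j
#' \eqn{y_i \sim \beta_{1j} + \beta_{2j} x_i + N(0, \sigma_j^2)} and x is
#' the calculated ballast capacity. A single linear model is unrealistic
#' for bulkers, which may discharge a typical, much smaller or much larger
#' volume depending on ballast condition; the mixture captures these
#' regimes.
#'
#' The EM alternates a responsibility E-step with per-component weighted
#' least squares; the observed-data log-likelihood is non-decreasing
#' across iterations (asserted internally). The best of `n_restarts`
#' random-responsibility initialisations is kept. Component variances are
#' floored at `(sigma_floor_factor * sd(y))^2`; a restart is declared
#' degenerate when any weight falls below 1/n or a variance sits at the
#' floor for 10 consecutive iterations. K = 1 reduces exactly to OLS.
#' Components are returned sorted by slope for identifiability.
#'
#' @param x Calculated ballast capacity (m3), numeric vector.
#' @param y Per-voyage total discharge (m3), same length.
#' @param K Number of components, 1-5.
#' @param seed Optional integer seed for the restarts.
#' @param n_restarts Random initialisations (best final log-likelihood
#'   wins).
#' @param tol Relative log-likelihood change declaring convergence.
#' @param max_iter Maximum EM iterations per restart.
#' @param sigma_floor_factor Variance floor, as a fraction of sd(y).
#' @return Object of class `mixture_discharge`: `K`, `weights`, `beta1`,
#'   `beta2`, `sigma`, `loglik`, `n`, `criteria` (AIC/AIC3/MDL/BIC),
#'   `loglik_trace` of the winning run, `n_iter`.
#' @export
em_fit_mixture <- function(x, y, K, seed = NULL, n_restarts = 10,
                           tol = 1e-8, max_iter = 1000,
                           sigma_floor_factor = 1e-6) {
  stopifnot(length(x) == length(y), K >= 1, K <= 5)
  n <- length(y)
  if (n <= 5 * (3 * K - 1)) {
    stop("too few observations for K = ", K, " components", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  sig_floor <- sigma_floor_factor * stats::sd(y)

  if (K == 1) {
    fit <- stats::lm.fit(cbind(1, x), y)
    b <- unname(fit$coefficients)
    r <- fit$residuals
    s <- sqrt(sum(r^2) / n)
    ll <- sum(stats::dnorm(y, b[1] + b[2] * x, s, log = TRUE))
    return(new_mixture(1, 1, b[1], b[2], s, ll, n, ll, 1L))
  }

  best <- NULL
  n_degenerate <- 0L
  for (rs in seq_len(n_restarts)) {
    run <- em_single_run(x, y, K, tol, max_iter, sig_floor)
    if (is.null(run)) {
      n_degenerate <- n_degenerate + 1L
      next
    }
    if (is.null(best) || run$loglik > best$loglik) best <- run
  }
  if (is.null(best)) {
    stop("all ", n_restarts, " EM restarts degenerated for K = ", K,
         call. = FALSE)
  }
  ord <- order(best$beta2)
  new_mixture(K, best$p[ord], best$beta1[ord], best$beta2[ord],
              best$sigma[ord], best$loglik, n, best$trace, best$n_iter)
}

em_single_run <- function(x, y, K, tol, max_iter, sig_floor) {
  n <- length(y)
  W <- matrix(stats::runif(n * K), n, K)
  W <- W / rowSums(W)
  res <- em_run_cpp(x, y, K, tol, max_iter, sig_floor, W)
  if (res$status == 2) {
    stop("EM log-likelihood decreased; numerical failure", call. = FALSE)
  }
  if (res$status == 1 || res$n_iter == 0) return(NULL)
  list(p = res$p, beta1 = res$beta1, beta2 = res$beta2, sigma = res$sigma,
       loglik = res$loglik, trace = res$trace, n_iter = res$n_iter)
}

new_mixture <- function(K, p, b1, b2, s, ll, n, trace, n_iter) {
  structure(list(K = K, weights = p, beta1 = b1, beta2 = b2, sigma = s,
                 loglik = ll, n = n,
                 criteria = information_criteria(ll, K, n),
                 loglik_trace = trace, n_iter = n_iter),
            class = "mixture_discharge")
}

#' @export
print.mixture_discharge <- function(x, ...) {
  cat(sprintf("<mixture_discharge> K = %d, n = %d, logLik = %.1f\n",
              x$K, x$n, x$loglik))
  print(tidy.mixture_discharge(x))
  invisible(x)
}

#' @rdname em_fit_mixture
#' @param object,x A `mixture_discharge` object.
#' @param ... Unused.
#' @export
tidy.mixture_discharge <- function(x, ...) {
  tibble::tibble(component = seq_len(x$K), weight = x$weights,
                 intercept = x$beta1, slope = x$beta2, sigma = x$sigma)
}

#' @rdname em_fit_mixture
#' @export
glance.mixture_discharge <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(K = x$K, n = x$n, logLik = x$loglik,
                                  n_iter = x$n_iter),
                   tibble::as_tibble(as.list(x$criteria)))
}

#' Information criteria for a fitted mixture
#'
#' Computes AIC, AIC3, BIC and MDL from the maximised log-likelihood of a
#' K-component regression mixture. Free parameters per component are
#' intercept, slope and sigma, plus K - 1 mixing weights: k = 4K - 1.
#' AIC = -2l + 2k; AIC3 = -2l + 3k; BIC = -2l + k ln n;
#' MDL = -l + (k/2) ln n (half of BIC), the usual mixtures form.
#'
#' @param loglik Maximised log-likelihood.
#' @param K Number of components.
#' @param n Sample size, > 1.
#' @return Named numeric vector `c(k, AIC, AIC3, BIC, MDL)`.
#' @export
information_criteria <- function(loglik, K, n) {
  if (n <= 1) stop("n must exceed 1", call. = FALSE)
  k <- 4 * K - 1
  c(k = k,
    AIC = -2 * loglik + 2 * k,
    AIC3 = -2 * loglik + 3 * k,
    BIC = -2 * loglik + k * log(n),
    MDL = -loglik + (k / 2) * log(n))
}

#' Choose the number of mixture components
#'
#' Fits the regression mixture for each K in `K_range` (default 1-5) and
#' tabulates AIC, AIC3, MDL and BIC; each criterion's chosen K is its
#' minimiser. A K whose every restart degenerates is recorded as
#' non-competing.
#'
#' @inheritParams em_fit_mixture
#' @param K_range Candidate component counts.
#' @return List of class `mixture_selection`: `table` (per-K criteria),
#'   `chosen` (named integer vector per criterion), `fits` (list of
#'   `mixture_discharge` objects indexed by K).
#' @export
select_mixture_components <- function(x, y, K_range = 1:5, seed = NULL,
                                      n_restarts = 10, tol = 1e-8,
                                      max_iter = 1000) {
  if (!is.null(seed)) set.seed(seed)
  fits <- purrr::map(K_range, function(K) {
    tryCatch(em_fit_mixture(x, y, K, seed = NULL, n_restarts = n_restarts,
                            tol = tol, max_iter = max_iter),
             error = function(e) conditionMessage(e))
  })
  names(fits) <- as.character(K_range)
  tab <- purrr::map2_dfr(K_range, fits, function(K, f) {
    if (inherits(f, "mixture_discharge")) {
      dplyr::bind_cols(tibble::tibble(K = K, logLik = f$loglik),
                       tibble::as_tibble(as.list(f$criteria)))
    } else {
      tibble::tibble(K = K, logLik = NA_real_, k = NA_real_, AIC = NA_real_,
                     AIC3 = NA_real_, BIC = NA_real_, MDL = NA_real_)
    }
  })
  chosen <- vapply(c("AIC", "AIC3", "MDL", "BIC"), function(cr) {
    v <- tab[[cr]]
    if (all(is.na(v))) NA_integer_ else tab$K[which.min(v)]
  }, integer(1))
  structure(list(table = tab, chosen = chosen, fits = fits),
            class = "mixture_selection")
}

#' @export
print.mixture_selection <- function(x, ...) {
  print(x$table)
  cat("chosen K:",
      paste(names(x$chosen), x$chosen, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Predict ballast discharge from a fitted model
#'
#' For a mixture, the expected prediction is the mixture mean
#' \eqn{\sum_j p_j (\beta_{1j} + \beta_{2j} x)} with predictive variance
#' from the law of total variance; `mode = "sample"` draws a component and
#' then Gaussian noise. For a linear model the expectation is the linear
#' predictor (unseen factor levels fall back to the frequency-weighted
#' marginal offset, with a warning). All predictions are truncated below
#' at 0 and capped at the feasibility bound, 120% of the DWT implied by
#' the capacity.
#'
#' @param object A `mixture_discharge` or `linear_discharge` fit.
#' @param capacity Calculated ballast capacity (m3), vectorised.
#' @param purpose,src_port,dst_port,src_ecoregion,dst_ecoregion Factor
#'   values for linear-model predictors, recycled as needed.
#' @param mode `"expected"` (returns a tibble with `expected_m3` and
#'   `variance_m6`) or `"sample"` (returns a numeric draw per row).
#' @param coeffs [design_coefficients()] fixing the capacity/DWT ratio for
#'   the feasibility cap.
#' @param max_discharge_fraction_of_dwt Cap, as a fraction of implied DWT.
#' @return Tibble (`expected`) or numeric vector (`sample`).
#' @export
predict_discharge <- function(object, capacity, purpose = NULL,
                              src_port = NULL, dst_port = NULL,
                              src_ecoregion = NULL, dst_ecoregion = NULL,
                              mode = c("expected", "sample"),
                              coeffs = design_coefficients(),
                              max_discharge_fraction_of_dwt = 1.20) {
  mode <- match.arg(mode)
  stopifnot(all(capacity >= 0))
  UseMethod("predict_discharge")
}

#' @export
predict_discharge.mixture_discharge <- function(object, capacity, ...,
                                                mode = c("expected", "sample"),
                                                coeffs = design_coefficients(),
                                                max_discharge_fraction_of_dwt = 1.20) {
  mode <- match.arg(mode)
  cap <- max_discharge_fraction_of_dwt * capacity / coeffs$ballast_fraction
  M <- outer(capacity, object$beta2) +
    matrix(object$beta1, length(capacity), object$K, byrow = TRUE)
  if (mode == "expected") {
    mu <- drop(M %*% object$weights)
    ex2 <- drop((M^2 + matrix(object$sigma^2, length(capacity), object$K,
                              byrow = TRUE)) %*% object$weights)
    tibble::tibble(expected_m3 = pmin(pmax(mu, 0), cap),
                   variance_m6 = ex2 - mu^2)
  } else {
    j <- sample.int(object$K, length(capacity), replace = TRUE,
                    prob = object$weights)
    draw <- M[cbind(seq_along(capacity), j)] +
      stats::rnorm(length(capacity), 0, object$sigma[j])
    pmin(pmax(draw, 0), cap)
  }
}

#' @export
predict_discharge.linear_discharge <- function(object, capacity,
                                               purpose = NULL,
                                               src_port = NULL,
                                               dst_port = NULL,
                                               src_ecoregion = NULL,
                                               dst_ecoregion = NULL,
                                               mode = c("expected", "sample"),
                                               coeffs = design_coefficients(),
                                               max_discharge_fraction_of_dwt = 1.20) {
  mode <- match.arg(mode)
  cap <- max_discharge_fraction_of_dwt * capacity / coeffs$ballast_fraction
  mu <- object$intercept + object$capacity_slope * capacity
  vals <- list(purpose = purpose, src_port = src_port, dst_port = dst_port,
               src_ecoregion = src_ecoregion, dst_ecoregion = dst_ecoregion)
  for (f in names(object$factor_terms)) {
    if (is.null(vals[[f]])) {
      stop("model requires `", f, "` for prediction", call. = FALSE)
    }
    mu <- mu + factor_offset(object$factor_terms[[f]], vals[[f]])
  }
  if (mode == "expected") {
    tibble::tibble(expected_m3 = pmin(pmax(mu, 0), cap),
                   variance_m6 = rep(object$sigma^2, length(mu)))
  } else {
    pmin(pmax(mu + stats::rnorm(length(mu), 0, object$sigma), 0), cap)
  }
}

#' Model specification for cross-validation
#'
#' A lightweight description of a discharge model to be refitted inside
#' each cross-validation repeat: either a linear model over a predictor
#' set, or a K-component capacity mixture.
#'
#' @param type `"linear"` or `"mixture"`.
#' @param predictors Predictor set for linear models.
#' @param K Components for mixtures.
#' @param n_restarts,tol,max_iter EM controls for mixtures.
#' @return A `discharge_spec` object.
#' @export
discharge_spec <- function(type = c("linear", "mixture"),
                           predictors = c("capacity", "purpose"), K = 4,
                           n_restarts = 5, tol = 1e-8, max_iter = 1000) {
  type <- match.arg(type)
  structure(list(type = type, predictors = predictors, K = K,
                 n_restarts = n_restarts, tol = tol, max_iter = max_iter),
            class = "discharge_spec")
}

fit_spec <- function(spec, voyages) {
  if (spec$type == "linear") {
    fit_linear_discharge(voyages, spec$predictors)
  } else {
    em_fit_mixture(voyages$capacity_m3, voyages$discharge_m3, spec$K,
                   n_restarts = spec$n_restarts, tol = spec$tol,
                   max_iter = spec$max_iter)
  }
}

predict_spec <- function(model, voyages) {
  args <- list(model, capacity = voyages$capacity_m3, mode = "expected")
  if (inherits(model, "linear_discharge")) {
    for (f in names(model$factor_terms)) args[[f]] <- voyages[[f]]
  }
  do.call(predict_discharge, args)$expected_m3
}

#' Repeated random-sampling cross-validation
#'
#' Splits the voyages into train/test at `train_fraction`, refits the
#' model on the training split and evaluates on the held-out split,
#' repeated `n_repeats` times. Reports held-out R-squared and the total
#' ballast-discharge prediction error (predicted minus true held-out
#' total) per repeat, with mean and s.d. summaries. Mixture predictions
#' use the predictive mean.
#'
#' @param model_spec A [discharge_spec()].
#' @param voyages Curated voyage table (see [fit_linear_discharge()]).
#' @param train_fraction Proportion used for training, in (0, 1).
#' @param n_repeats Number of random splits.
#' @param seed Integer seed making splits reproducible.
#' @return Object of class `cv_result`: `repeats` tibble
#'   (`repeat`, `r_squared`, `total_error_m3`) and `summary` tibble.
#' @export
cross_validate <- function(model_spec, voyages, train_fraction = 0.8,
                           n_repeats = 20, seed = NULL) {
  stopifnot(inherits(model_spec, "discharge_spec"),
            train_fraction > 0, train_fraction < 1)
  v <- tibble::as_tibble(voyages)
  n <- nrow(v)
  n_train <- floor(train_fraction * n)
  if (n_train >= n || n_train < 1) {
    stop("empty train or test split at this train_fraction", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  reps <- purrr::map_dfr(seq_len(n_repeats), function(i) {
    idx <- sample.int(n, n_train)
    fit <- fit_spec(model_spec, v[idx, ])
    test <- v[-idx, ]
    pred <- predict_spec(fit, test)
    ss_res <- sum((test$discharge_m3 - pred)^2)
    ss_tot <- sum((test$discharge_m3 - mean(test$discharge_m3))^2)
    tibble::tibble(rep = i,
                   r_squared = 1 - ss_res / ss_tot,
                   total_error_m3 = sum(pred) - sum(test$discharge_m3))
  })
  structure(list(
    repeats = reps,
    summary = tibble::tibble(
      mean_r_squared = mean(reps$r_squared),
      sd_r_squared = stats::sd(reps$r_squared),
      mean_total_error_m3 = mean(reps$total_error_m3),
      sd_total_error_m3 = stats::sd(reps$total_error_m3),
      mean_abs_total_error_m3 = mean(abs(reps$total_error_m3)))),
    class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d repeats\n", nrow(x$repeats)))
  print(x$summary)
  invisible(x)
}
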