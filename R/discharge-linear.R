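#' Fit a linear ballast-discharge model
#'
#' Ordinary least-squares regression of per-voyage total ballast discharge
#' on a chosen predictor set. Used for tankers, container vessels and
#' "other" vessels, where a single linear model is adequate. Factor
#' predictors enter as fixed-effect offsets with the alphabetically first
#' level as reference. The Gaussian log-likelihood uses the ML residual
#' variance, and BIC counts one free parameter per coefficient plus one
#' for sigma.
#'
#' @param voyages Data frame with one row per curated voyage, containing
#'   `discharge_m3` and the predictor columns: `capacity_m3` (calculated
#'   ballast capacity) and/or factors `purpose`, `src_port`, `dst_port`,
#'   `src_ecoregion`, `dst_ecoregion`.
#' @param predictors Character subset of
#'   `c("capacity", "purpose", "src_port", "dst_port", "src_ecoregion",
#'   "dst_ecoregion")`. An empty set fits the intercept-only model.
#' @return An object of class `linear_discharge` with the coefficient
#'   decomposition, `sigma` (ML residual s.d., m3), `loglik`, `bic`, `n`.
#' @export
fit_linear_discharge <- function(voyages, predictors = c("capacity", "purpose")) {
  v <- tibble::as_tibble(voyages)
  stopifnot("discharge_m3" %in% names(v))
  allowed <- c("capacity", "purpose", "src_port", "dst_port",
               "src_ecoregion", "dst_ecoregion")
  if (!all(predictors %in% allowed)) {
    stop("unknown predictor(s): ",
         paste(setdiff(predictors, allowed), collapse = ", "), call. = FALSE)
  }
  terms <- ifelse(predictors == "capacity", "capacity_m3", predictors)
  missing_cols <- setdiff(terms, names(v))
  if (length(missing_cols)) {
    stop("voyages lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (f in setdiff(terms, "capacity_m3")) {
    v[[f]] <- factor(as.character(v[[f]]))  # levels sorted alphabetically
    if (nlevels(v[[f]]) < 2) {
      stop("rank-deficient design; collinear term(s): ", f, call. = FALSE)
    }
  }
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  fml <- stats::as.formula(paste("discharge_m3 ~", rhs))
  fit <- stats::lm(fml, data = v)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stop("rank-deficient design; collinear term(s): ",
         paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
  }
  n <- nrow(v)
  k <- length(cf) + 1  # + sigma
  ll <- as.numeric(stats::logLik(fit))
  sigma_ml <- sqrt(sum(stats::residuals(fit)^2) / n)

  # decompose coefficients by model term for serialisable prediction
  asgn <- attr(stats::model.matrix(fit), "assign")
  term_labels <- attr(stats::terms(fit), "term.labels")
  factor_terms <- list()
  for (f in setdiff(terms, "capacity_m3")) {
    j <- which(term_labels == f)
    idx <- which(asgn == j)
    levs <- levels(v[[f]])
    offs <- c(0, unname(cf[idx]))
    freq <- as.numeric(table(v[[f]])[levs]) / n
    factor_terms[[f]] <- tibble::tibble(level = levs, offset = offs,
                                        freq = freq)
  }
  structure(list(
    predictors = predictors,
    intercept = unname(cf["(Intercept)"]),
    capacity_slope = if ("capacity_m3" %in% terms)
      unname(cf["capacity_m3"]) else 0,
    factor_terms = factor_terms,
    sigma = sigma_ml,
    loglik = ll,
    n = n,
    k = k,
    bic = -2 * ll + k * log(n),
    fitted_mean = mean(v$discharge_m3)
  ), class = "linear_discharge")
}

#' @export
print.linear_discharge <- function(x, ...) {
  cat(sprintf("<linear_discharge> {%s}; n = %d, sigma = %.1f m3, BIC = %.1f\n",
              paste(x$predictors, collapse = ", "), x$n, x$sigma, x$bic))
  invisible(x)
}

#' @rdname fit_linear_discharge
#' @param x A `linear_discharge` object.
#' @param ... Unused.
#' @export
tidy.linear_discharge <- function(x, ...) {
  rows <- tibble::tibble(term = "(Intercept)", estimate = x$intercept)
  if ("capacity" %in% x$predictors) {
    rows <- dplyr::bind_rows(rows, tibble::tibble(term = "capacity_m3",
                                                  estimate = x$capacity_slope))
  }
  for (f in names(x$factor_terms)) {
    ft <- x$factor_terms[[f]]
    rows <- dplyr::bind_rows(rows,
      tibble::tibble(term = paste0(f, ft$level), estimate = ft$offset))
  }
  rows
}

#' @rdname fit_linear_discharge
#' @export
glance.linear_discharge <- function(x, ...) {
  tibble::tibble(n = x$n, sigma = x$sigma, logLik = x$loglik,
                 df = x$k, BIC = x$bic)
}

factor_offset <- function(ft, level) {
  # marginal (frequency-weighted) offset for unseen levels
  i <- match(as.character(level), ft$level)
  marg <- sum(ft$offset * ft$freq)
  out <- ft$offset[i]
  unseen <- is.na(i)
  if (any(unseen)) {
    warning("unseen factor level(s): ",
            paste(unique(level[unseen]), collapse = ", "),
            "; using the frequency-weighted marginal offset", call. = FALSE)
    out[unseen] <- marg
  }
  out
}

#' Rank candidate predictor sets by BIC
#'
#' Fits every candidate predictor set by OLS and ranks by BIC ascending;
#' ties are broken in favour of fewer free parameters. Candidates whose
#' fit fails (e.g. a rank-deficient design) are recorded as non-competing
#' with the error message.
#'
#' @param voyages As for [fit_linear_discharge()].
#' @param candidate_sets List of character predictor sets (at least two
#'   for a meaningful comparison; a single candidate is returned as best
#'   trivially).
#' @return List with `best` (the winning `linear_discharge`) and `table`
#'   (a tibble of candidates ranked by BIC, failed fits last).
#' @export
select_linear_by_bic <- function(voyages, candidate_sets) {
  stopifnot(length(candidate_sets) >= 1)
  fits <- purrr::map(candidate_sets, function(p) {
    tryCatch(fit_linear_discharge(voyages, p),
             error = function(e) conditionMessage(e))
  })
  tab <- purrr::map2_dfr(candidate_sets, fits, function(p, f) {
    if (inherits(f, "linear_discharge")) {
      tibble::tibble(predictors = paste(sort(p), collapse = "+"),
                     k = f$k, logLik = f$loglik, BIC = f$bic,
                     error = NA_character_)
    } else {
      tibble::tibble(predictors = paste(sort(p), collapse = "+"),
                     k = NA_integer_, logLik = NA_real_, BIC = NA_real_,
                     error = f)
    }
  })
  ord <- order(is.na(tab$BIC), tab$BIC, tab$k)
  tab <- tab[ord, ]
  tab$rank <- seq_len(nrow(tab))
  best <- fits[ord][[1]]
  if (!inherits(best, "linear_discharge")) {
    stop("no candidate model could be fitted", call. = FALSE)
  }
  list(best = best, table = tibble::as_tibble(tab))
}
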