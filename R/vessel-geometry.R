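#' Ship design coefficients
#'
#' Coefficients of the cube-root ship-design relation linking vessel length
#' to deadweight tonnage (DWT), plus the fraction of DWT taken as ballast
#' capacity. Defaults follow standard design-guideline values for the cargo
#' fleet: deadweight coefficient 0.8, block coefficient 0.75,
#' length/breadth 6.5, breadth/draft 2.2, saltwater density 1.025, and
#' ballast capacity 30% of DWT.
#'
#' @param C_D Deadweight coefficient (deadweight/displacement), dimensionless.
#' @param C_B Block coefficient (hull volume / L*B*H box), dimensionless.
#' @param L_over_B Length-to-breadth ratio.
#' @param B_over_H Breadth-to-draft ratio.
#' @param rho Saltwater density coefficient (t/m3).
#' @param ballast_fraction Ballast capacity as a proportion of DWT.
#' @return An object of class `design_coefficients` (a named list).
#' @examples
#' coeffs <- design_coefficients()
#' calc_dwt(200, coeffs)
#' @export
design_coefficients <- function(C_D = 0.8, C_B = 0.75, L_over_B = 6.5,
                                B_over_H = 2.2, rho = 1.025,
                                ballast_fraction = 0.30) {
  vals <- c(C_D = C_D, C_B = C_B, L_over_B = L_over_B, B_over_H = B_over_H,
            rho = rho, ballast_fraction = ballast_fraction)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all design coefficients must be finite and strictly positive",
         call. = FALSE)
  }
  structure(as.list(vals), class = "design_coefficients")
}

#' Deadweight tonnage from vessel length
#'
#' Inverts the cube-root design relation
#' \eqn{L = [DWT (L/B)^2 (B/H) / (\rho C_B C_D)]^{1/3}} to give
#' \eqn{DWT = L^3 \rho C_B C_D / ((L/B)^2 (B/H))}: DWT is a linear
#' function of length cubed.
#'
#' @param length_m Vessel length overall in metres (vectorised).
#' @param coeffs A [design_coefficients()] object.
#' @return Deadweight tonnage in tonnes.
#' @examples
#' calc_dwt(c(100, 200, 300))
#' @export
calc_dwt <- function(length_m, coeffs = design_coefficients()) {
  stopifnot(inherits(coeffs, "design_coefficients"))
  if (any(length_m < 0, na.rm = TRUE)) {
    stop("vessel length must be non-negative", call. = FALSE)
  }
  length_m^3 * coeffs$rho * coeffs$C_B * coeffs$C_D /
    (coeffs$L_over_B^2 * coeffs$B_over_H)
}

#' Block coefficient from speed and length
#'
#' The design-guideline relation \eqn{C_B = a - b V / \sqrt{L}} with
#' a = 1.23 and b = 0.395. Provided for completeness; the discharge
#' pipeline fixes C_B at its default value.
#'
#' @param speed_knots Service speed in knots.
#' @param length_m Vessel length in metres, strictly positive.
#' @param a,b Relation constants.
#' @return Dimensionless block coefficient.
#' @export
calc_block_coefficient <- function(speed_knots, length_m, a = 1.23, b = 0.395) {
  if (any(length_m <= 0, na.rm = TRUE)) {
    stop("vessel length must be strictly positive", call. = FALSE)
  }
  a - b * speed_knots / sqrt(length_m)
}

#' Ballast capacity from deadweight tonnage
#'
#' Ballast capacity estimated as a fixed fraction (default 30%) of
#' calculated DWT. Tonnes are reported numerically as cubic metres; with
#' `convert_to_m3 = TRUE` the value is divided by the saltwater density
#' (a difference of at most 2.5%).
#'
#' @param dwt_tonnes Deadweight tonnage (vectorised), non-negative.
#' @param coeffs A [design_coefficients()] object.
#' @param convert_to_m3 Divide by seawater density to convert tonnes to m3.
#' @return Calculated ballast capacity in m3.
#' @export
calc_ballast_capacity <- function(dwt_tonnes, coeffs = design_coefficients(),
                                  convert_to_m3 = FALSE) {
  stopifnot(inherits(coeffs, "design_coefficients"))
  if (any(dwt_tonnes < 0, na.rm = TRUE)) {
    stop("DWT must be non-negative", call. = FALSE)
  }
  out <- coeffs$ballast_fraction * dwt_tonnes
  if (convert_to_m3) out <- out / coeffs$rho
  out
}

#' Data-curation rules for ballast records
#'
#' Records are removed when vessel length is zero or negative, exceeds the
#' maximum plausible length (no vessel above 345 m occurs in the study
#' fleet), or when reported discharge exceeds 120% of calculated DWT
#' (physically infeasible).
#'
#' @param max_length_m Maximum admissible vessel length (m).
#' @param max_discharge_fraction_of_dwt Maximum discharge as a fraction of
#'   calculated DWT.
#' @return An object of class `curation_rules`.
#' @export
curation_rules <- function(max_length_m = 345,
                           max_discharge_fraction_of_dwt = 1.20) {
  stopifnot(max_length_m > 0, max_discharge_fraction_of_dwt > 0)
  structure(list(max_length_m = max_length_m,
                 max_discharge_fraction_of_dwt = max_discharge_fraction_of_dwt),
            class = "curation_rules")
}

#' Curate ballast voyage records
#'
#' Applies the curation filters to per-voyage ballast records. Length rules
#' are applied first, then the discharge-feasibility rule; records with
#' missing length or discharge are rejected with reason `"missing"` and
#' counted separately from rule-based rejections. Curation is idempotent.
#'
#' @param ballast_voyages A data frame with at least `length_m` and
#'   `discharge_m3` columns (one row per voyage).
#' @param rules A [curation_rules()] object.
#' @param coeffs A [design_coefficients()] object used to compute DWT for
#'   the feasibility rule.
#' @return An object of class `curation` with elements `curated` (the
#'   retained rows, as a tibble), `rejected` (dropped rows with a `reason`
#'   column) and `report` (per-rule counts and the overall rejected
#'   fraction).
#' @examples
#' x <- tibble::tibble(length_m = c(200, 350, 0, 200),
#'                     discharge_m3 = c(1e4, 1e4, 1e4, 1e7))
#' curate_ballast(x)$report
#' @export
curate_ballast <- function(ballast_voyages, rules = curation_rules(),
                           coeffs = design_coefficients()) {
  stopifnot(inherits(rules, "curation_rules"))
  x <- tibble::as_tibble(ballast_voyages)
  if (!all(c("length_m", "discharge_m3") %in% names(x))) {
    stop("ballast_voyages must have columns `length_m` and `discharge_m3`",
         call. = FALSE)
  }
  n <- nrow(x)
  reason <- rep(NA_character_, n)
  miss <- is.na(x$length_m) | is.na(x$discharge_m3)
  reason[miss] <- "missing"
  # length rules first, then the feasibility rule
  bad_zero <- !miss & x$length_m <= 0
  reason[bad_zero & is.na(reason)] <- "zero_length"
  bad_long <- !miss & x$length_m > rules$max_length_m
  reason[bad_long & is.na(reason)] <- "max_length"
  ok_len <- is.na(reason)
  dwt <- rep(NA_real_, n)
  dwt[ok_len] <- calc_dwt(x$length_m[ok_len], coeffs)
  infeasible <- ok_len &
    x$discharge_m3 > rules$max_discharge_fraction_of_dwt * dwt
  reason[infeasible] <- "infeasible_discharge"

  kept <- is.na(reason)
  report <- tibble::tibble(
    rule = c("missing", "zero_length", "max_length", "infeasible_discharge"),
    n_rejected = c(sum(reason == "missing", na.rm = TRUE),
                   sum(reason == "zero_length", na.rm = TRUE),
                   sum(reason == "max_length", na.rm = TRUE),
                   sum(reason == "infeasible_discharge", na.rm = TRUE))
  )
  structure(
    list(curated = x[kept, , drop = FALSE],
         rejected = dplyr::mutate(x[!kept, , drop = FALSE],
                                  reason = reason[!kept]),
         report = report,
         n_input = n,
         rejected_fraction = if (n > 0) sum(!kept) / n else 0),
    class = "curation")
}

#' @export
print.curation <- function(x, ...) {
  cat(sprintf("<curation> %d records in, %d retained (%.1f%% rejected)\n",
              x$n_input, nrow(x$curated), 100 * x$rejected_fraction))
  print(x$report)
  invisible(x)
}

#' @rdname curate_ballast
#' @param x A `curation` object.
#' @param ... Unused.
#' @export
tidy.curation <- function(x, ...) {
  dplyr::mutate(x$report,
                fraction = .data$n_rejected / max(x$n_input, 1L))
}
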