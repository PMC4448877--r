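test_that("organism density decays exponentially from D(0)", {
  expect_equal(density_at(0), 2113.489)
  expect_equal(density_at(10), 2113.489 * exp(-1.61), tolerance = 1e-12)
  expect_equal(round(density_at(10), 2), 422.46)
  expect_equal(density_at(5, decay_params(lam = 0)), rep(2113.489, 1))
  t <- seq(0, 30, by = 0.5)
  expect_true(all(diff(density_at(t)) < 0))
  expect_error(density_at(-1), "non-negative")
})

test_that("composite decay rate is the duration-weighted mean", {
  expect_equal(composite_lambda(0.161, 0.161, 0.3), 0.161)
  expect_equal(composite_lambda(0.1, 0.3, 1), 0.1)
  expect_equal(composite_lambda(0.1, 0.3, 0), 0.3)
  expect_equal(composite_lambda(0.1, 0.3, 0.5), 0.2)
  expect_error(composite_lambda(0.1, 0.3, 1.2), "0, 1")
})

test_that("BWE density factorisation equals the composite-lambda form", {
  expect_equal(bwe_density(7), density_at(7))  # r = 1, mu1 = mu2
  expect_equal(bwe_density(3, decay_params(r = 0)), 0)
  set.seed(8)
  for (i in 1:200) {
    p <- decay_params(D0 = runif(1, 1, 5000), mu1 = runif(1, 0, 0.8),
                      mu2 = runif(1, 0, 0.8), p_exchange = runif(1),
                      r = runif(1))
    T <- runif(1, 0, 40)
    lam <- composite_lambda(p$mu1, p$mu2, p$p_exchange)
    expect_equal(bwe_density(T, p), p$D0 * p$r * exp(-lam * T),
                 tolerance = 1e-12)
  }
})

# minimal hindcast-record table builder
risk_records <- function(vol, src, dst = "A1") {
  tibble::tibble(src_port = src, dst_port = dst,
                 src_ecoregion = paste0("e_", src),
                 dst_ecoregion = paste0("e_", dst),
                 expected_discharge_m3 = vol)
}

test_that("propagule pressure is volume times surviving density", {
  d0 <- tibble::tibble(src_port = "S", dst_port = "A1", distance_nm = 0)
  rr <- propagule_pressure(risk_records(1000, "S"), d0)
  expect_equal(rr$routes$propagules, 1000 * 2113.489)
  # linearity: doubling volumes doubles every total
  dists <- tibble::tibble(src_port = c("S1", "S2"), dst_port = "A1",
                          distance_nm = c(1800, 5400))
  h <- risk_records(c(500, 800), c("S1", "S2"))
  r1 <- propagule_pressure(h, dists)
  h2 <- dplyr::mutate(h, expected_discharge_m3 = 2 * expected_discharge_m3)
  r2 <- propagule_pressure(h2, dists)
  expect_equal(r2$routes$propagules, 2 * r1$routes$propagules)
  expect_equal(r2$sources$propagules, 2 * r1$sources$propagules)
})

test_that("nearer of two equal-volume sources gets the expected share", {
  # durations 5 and 15 days at 15 knots
  dists <- tibble::tibble(src_port = c("near", "far"), dst_port = "A1",
                          distance_nm = c(5 * 360, 15 * 360))
  rr <- propagule_pressure(risk_records(c(1000, 1000), c("near", "far")),
                           dists)
  share <- with(rr$sources,
                propagules[ecoregion == "e_near"] / sum(propagules))
  expect_equal(share, exp(-0.805) / (exp(-0.805) + exp(-2.415)),
               tolerance = 1e-12)
  expect_equal(round(share, 3), 0.833)
})

test_that("voyages on routes without a distance are excluded and counted", {
  dists <- tibble::tibble(src_port = "S1", dst_port = "A1",
                          distance_nm = 1000)
  rr <- propagule_pressure(risk_records(c(10, 20), c("S1", "ghost")), dists)
  expect_equal(rr$n_missing_distance, 1)
  expect_equal(nrow(rr$routes), 1)
})

test_that("rankings are invariant to the D0 and r scale factors", {
  dists <- tibble::tibble(src_port = c("S1", "S2", "S3"), dst_port = "A1",
                          distance_nm = c(500, 2500, 7000))
  h <- risk_records(c(300, 900, 1500), c("S1", "S2", "S3"))
  base <- propagule_pressure(h, dists)
  scaled <- propagule_pressure(h, dists,
                               decay_params(D0 = 10, r = 0.25))
  expect_identical(base$sources$ecoregion, scaled$sources$ecoregion)
  expect_identical(base$routes$src_port, scaled$routes$src_port)
})

test_that("no-decay sensitivity ranking equals the volume ranking", {
  dists <- tibble::tibble(src_port = c("S1", "S2", "S3"), dst_port = "A1",
                          distance_nm = c(7000, 500, 2500))
  h <- risk_records(c(1500, 300, 900), c("S1", "S2", "S3"))
  sg <- sensitivity_rank(h, dists, lambda_grid = c(0, 0.1, 0.3))
  by_vol <- h$src_port[order(-h$expected_discharge_m3)]
  r0 <- dplyr::filter(sg$trajectories, lambda == 0, side == "source")
  expect_identical(sub("e_", "", r0$ecoregion[order(r0$rank)]), by_vol)
  # rankings are permutations at every lambda
  for (l in unique(sg$trajectories$lambda)) {
    r <- dplyr::filter(sg$trajectories, lambda == l, side == "source")
    expect_setequal(r$rank, 1:3)
  }
})

test_that("nearer equal-volume source never loses rank as lambda grows", {
  dists <- tibble::tibble(src_port = c("near", "far"), dst_port = "A1",
                          distance_nm = c(2 * 360, 20 * 360))
  # far source has much more volume: dominant at small lambda
  h <- risk_records(c(1000, 8000), c("near", "far"))
  sg <- sensitivity_rank(h, dists,
                         lambda_grid = seq(0.01, 0.5, length.out = 50))
  near <- dplyr::filter(sg$trajectories, side == "source",
                        ecoregion == "e_near") |>
    dplyr::arrange(lambda)
  expect_true(all(diff(near$rank) <= 0))
  shares <- dplyr::filter(sg$trajectories, side == "source") |>
    dplyr::group_by(lambda) |>
    dplyr::mutate(share = propagules / sum(propagules)) |>
    dplyr::filter(ecoregion == "e_near") |>
    dplyr::arrange(lambda)
  expect_true(all(diff(shares$share) > 0))
})

test_that("single-source world is rank 1 at every lambda", {
  dists <- tibble::tibble(src_port = "S", dst_port = "A1",
                          distance_nm = 3000)
  sg <- sensitivity_rank(risk_records(100, "S"), dists)
  src <- dplyr::filter(sg$trajectories, side == "source")
  expect_true(all(src$rank == 1))
  expect_equal(nrow(src), 50)
})

test_that("top routes report the covered share of the grand total", {
  routes <- tibble::tibble(
    src_port = c("a", "b", "c"), dst_port = "z",
    src_ecoregion = "e1", dst_ecoregion = "e2",
    distance_nm = 1, duration_days = 1,
    n_voyages = c(5, 3, 2), total_discharge_m3 = c(50, 30, 20),
    propagules = c(50, 30, 20))
  t2 <- top_routes(routes, "volume", 2)
  expect_equal(attr(t2, "share"), 0.8)
  expect_equal(nrow(t2), 2)
  tall <- top_routes(routes, "voyages", 10)
  expect_equal(attr(tall, "share"), 1.0)
  # lambda = 0 propagules ordering equals volume ordering
  expect_identical(top_routes(routes, "propagules", 3)$src_port,
                   top_routes(routes, "volume", 3)$src_port)
  expect_error(top_routes(routes, "banana"), "arg")
})
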