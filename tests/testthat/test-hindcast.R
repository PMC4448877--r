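test_that("a single voyage under a K = 1 model hindcasts the linear predictor", {
  m1 <- ballastr:::new_mixture(1, 1, 1000, 0.5, 100, 0, 50, 0, 1L)
  vessels <- tibble::tibble(vessel_id = "V1", type = "bulker",
                            length_m = 200)
  ports <- tibble::tibble(port_id = c("S", "A"),
                          ecoregion_id = c("e1", "e2"),
                          purpose = c("unknown", "coal"))
  voyages <- tibble::tibble(voyage_id = "J1", vessel_id = "V1",
                            year = 2000L, src_port = "S", dst_port = "A")
  hc <- hindcast_voyages(voyages, vessels, ports, list(bulker = m1))
  cap <- calc_ballast_capacity(calc_dwt(200))
  expect_equal(hc$expected_discharge_m3, 1000 + 0.5 * cap)
  expect_equal(hc$variance_m6, 100^2)
})

test_that("duplicating the voyage table exactly doubles totals", {
  st <- gen_small_study(seed = 33, truth = ground_truth(corruption_rate = 0))
  models <- make_truth_models()
  hc1 <- hindcast_voyages(st$voyages, st$fleet, st$world$ports, models)
  hc2 <- hindcast_voyages(dplyr::bind_rows(st$voyages, st$voyages),
                          st$fleet, st$world$ports, models)
  a1 <- aggregate_discharge(hc1, "year")
  a2 <- aggregate_discharge(hc2, "year")
  expect_equal(a2$total_discharge_m3, 2 * a1$total_discharge_m3)
  expect_equal(a2$n_voyages, 2L * a1$n_voyages)
})

test_that("aggregates conserve the grand total over every partition", {
  st <- gen_small_study(seed = 37)
  hc <- hindcast_voyages(st$voyages, st$fleet, st$world$ports,
                         make_truth_models())
  grand <- sum(hc$expected_discharge_m3)
  for (by in c("year", "port", "ecoregion", "route", "source_port",
               "source_ecoregion")) {
    agg <- aggregate_discharge(hc, by)
    expect_equal(sum(agg$total_discharge_m3), grand, tolerance = 1e-12)
    expect_equal(sum(agg$n_voyages), nrow(hc))
  }
  expect_equal(sum(aggregate_discharge(hc, "year")$total_variance_m6),
               sum(hc$variance_m6), tolerance = 1e-12)
  expect_error(aggregate_discharge(hc, "by_moon_phase"), "arg")
})

test_that("missing vessel-type models are reported by name", {
  st <- gen_small_study(seed = 39)
  models <- make_truth_models()
  models$tanker <- NULL
  expect_error(
    hindcast_voyages(st$voyages, st$fleet, st$world$ports, models),
    "tanker")
})

test_that("invalid-geometry vessels are excluded and counted", {
  st <- gen_small_study(seed = 43)
  fleet <- st$fleet
  fleet$length_m[1:3] <- c(0, 400, NA)
  bad_ids <- fleet$vessel_id[1:3]
  hc <- hindcast_voyages(st$voyages, fleet, st$world$ports,
                         make_truth_models())
  expect_equal(attr(hc, "n_excluded"),
               sum(st$voyages$vessel_id %in% bad_ids))
  expect_true(all(hc$expected_discharge_m3 >= 0))
})

test_that("hindcast is self-consistent with the generating models", {
  # bulker-only traffic so zero-truncation of the generator is negligible
  world <- gen_world(world_config(n_ecoregions = 4, ports_per_ecoregion = 2,
                                  n_islands = 0, seed = 51))
  fleet <- gen_fleet(fleet_config(n_vessels = 400,
                                  type_mix = c(bulker = 1, tanker = 0,
                                               container = 0, other = 0)),
                     seed = 52)
  voyages <- gen_voyages(world, fleet,
                         traffic_config(years = 1999:2003,
                                        base_intensity = 40), seed = 53)
  truth <- ground_truth(corruption_rate = 0, provenance_mismatch_rate = 0)
  events <- gen_ballast_census(voyages, world, fleet, truth, seed = 54)
  generated_total <- sum(events$volume_m3)
  hc <- hindcast_voyages(voyages, fleet, world$ports, make_truth_models())
  hindcast_total <- sum(hc$expected_discharge_m3)
  mc_sd <- sqrt(sum(hc$variance_m6))
  expect_lt(abs(hindcast_total - generated_total), 2 * mc_sd)
})

test_that("volume-weighted provenance consistency is computed by hand", {
  ev <- tibble::tibble(
    uptake_port = c("S1", "S1", "S2"),
    discharge_port = c("A", "A", "A"),
    src_port = c("S1", "S1", "S1"),
    dst_port = c("A", "A", "A"),
    volume_m3 = c(10, 20, 70))
  ports <- tibble::tibble(port_id = c("S1", "S2", "A"),
                          ecoregion_id = c("e1", "e2", "e3"))
  expect_equal(as.numeric(provenance_consistency(ev, ports, "port")), 0.30)
  expect_equal(as.numeric(provenance_consistency(ev, ports, "port",
                                                 "arrival")), 1.0)
  # grouping e1 and e2 merges the mismatch away
  expect_equal(
    as.numeric(provenance_consistency(
      ev, ports, "grouped", groups = list(g1 = c("e1", "e2")))), 1.0)
})

test_that("coarsening the resolution never lowers consistency", {
  for (seed in c(61, 67, 71)) {
    st <- gen_small_study(seed = seed)
    p <- as.numeric(provenance_consistency(st$events, st$world$ports,
                                           "port"))
    e <- as.numeric(provenance_consistency(st$events, st$world$ports,
                                           "ecoregion"))
    g <- as.numeric(provenance_consistency(
      st$events, st$world$ports, "grouped",
      groups = list(g1 = st$world$ecoregions$ecoregion_id)))
    expect_lte(p, e)
    expect_lte(e, g)
    expect_equal(g, 1.0)  # one super-group of everything
  }
})

test_that("events at unknown ports are excluded from ecoregion consistency", {
  ev <- tibble::tibble(uptake_port = c("S1", "atlantis"),
                       discharge_port = "A", src_port = "S1",
                       dst_port = "A", volume_m3 = c(30, 50))
  ports <- tibble::tibble(port_id = c("S1", "A"),
                          ecoregion_id = c("e1", "e2"))
  pc <- provenance_consistency(ev, ports, "ecoregion")
  expect_equal(as.numeric(pc), 1.0)
  expect_equal(attr(pc, "n_excluded"), 1L)
})
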