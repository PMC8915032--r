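test_that("scenario transformations act field-by-field and never mutate", {
  net <- besos_network()
  before <- net

  s1 <- apply_scenario(net, scenario_spec("S1", cod_multiplier = 10))
  expect_equal(s1$sources$cod_mg_l[s1$sources$id == "W1"], 199000)
  expect_equal(s1$sources$cod_mg_l, net$sources$cod_mg_l * 10)
  expect_equal(s1$distances, net$distances)

  s2a <- apply_scenario(net, scenario_spec("S2a", distance_mode = "linear",
                                           distance_factor = 10))
  expect_equal(s2a$distances, net$distances * 10)

  s2b <- apply_scenario(net, scenario_spec("S2b", distance_mode = "sqrt"))
  expect_equal(s2b$distances["W1", "R1"], sqrt(5.3))
  expect_equal(s2b$distances, sqrt(net$distances))

  s3 <- apply_scenario(net, scenario_spec("S3", volume_multiplier = 3))
  expect_equal(s3$sources$volume_l_per_day,
               net$sources$volume_l_per_day * 3)

  ident <- apply_scenario(net, scenario_spec("id"))
  expect_equal(ident, net)
  # composing identities is a no-op too
  expect_equal(apply_scenario(ident, scenario_spec("id2")), net)
  # the input network is untouched
  expect_equal(net, before)
})

test_that("C/N override resamples the named sources reproducibly", {
  net <- besos_network()
  spec <- scenario_spec("S4", cn_override = list(
    sources = paste0("W", 1:12), range = c(50, 60), seed = 99))
  s4a <- apply_scenario(net, spec)
  s4b <- apply_scenario(net, spec)
  expect_equal(s4a, s4b)
  i <- match(paste0("W", 1:12), s4a$sources$id)
  expect_true(all(s4a$sources$cn_ratio[i] >= 50 &
                  s4a$sources$cn_ratio[i] <= 60))
  expect_equal(s4a$sources$cn_ratio[-i], net$sources$cn_ratio[-i])
  bad <- scenario_spec("S4", cn_override = list(
    sources = "W99", range = c(50, 60), seed = 1))
  expect_error(apply_scenario(net, bad), "unknown source")
})

test_that("tenfold COD multiplies biogas exactly for a fixed allocation", {
  net <- besos_network()
  s1 <- apply_scenario(net, scenario_spec("S1", cod_multiplier = 10))
  set.seed(14)
  for (i in 1:5) {
    a <- random_allocation(net)
    g0 <- biogas_estimate(lapply(1:3, blend_profile, a = a, net = net))
    a1 <- allocation(s1); a1[] <- a
    g1 <- biogas_estimate(lapply(1:3, blend_profile, a = a1, net = s1))
    expect_equal(g1, 10 * g0)
  }
})

test_that("volume tripling preserves scaled option sets", {
  net <- besos_network()
  s3 <- apply_scenario(net, scenario_spec("S3", volume_multiplier = 3))
  for (w in seq_len(nrow(net$sources))) {
    base <- volume_options(net$sources$volume_l_per_day[w], 1000)
    scaled <- volume_options(s3$sources$volume_l_per_day[w], 1000)
    expect_true(all((base * 3) %in% scaled))
  }
})

test_that("the bundled scenario battery matches the study set", {
  sc <- standard_scenarios()
  expect_named(sc, c("baseline", "S1", "S2a", "S2b", "S3", "S4"))
  expect_equal(sc$S1$cod_multiplier, 10)
  expect_equal(sc$S2a$distance_factor, 10)
  expect_equal(sc$S2b$distance_mode, "sqrt")
  expect_equal(sc$S3$volume_multiplier, 3)
  expect_equal(sc$S4$cn_override$range, c(50, 60))
  expect_equal(sc$S4$cn_override$sources, paste0("W", 1:12))
})

test_that("scenario configs parse from DCF blocks", {
  f <- withr::local_tempfile(fileext = ".dcf")
  writeLines(c("id: double_cod",
               "cod_multiplier: 2",
               "",
               "id: far",
               "distance_mode: linear",
               "distance_factor: 5",
               "",
               "id: rich_cn",
               "cn_sources: W1, W2",
               "cn_lo: 50",
               "cn_hi: 55",
               "cn_seed: 3"), f)
  sc <- read_scenario_config(f)
  expect_named(sc, c("double_cod", "far", "rich_cn"))
  expect_equal(sc$double_cod$cod_multiplier, 2)
  expect_equal(sc$far$distance_factor, 5)
  expect_equal(sc$rich_cn$cn_override$sources, c("W1", "W2"))
  expect_equal(sc$rich_cn$cn_override$range, c(50, 55))
})

test_that("benchmark emits one metric row per scenario-algorithm pair", {
  net <- small_instance(2)
  cfg <- solver_config("ga", population = 30, iterations = 40,
                       repetitions = 2, seed = 1)
  scen <- list(scenario_spec("base"),
               scenario_spec("S2b", distance_mode = "sqrt"))
  tbl <- run_benchmark(net, scen, algorithms = c("ga", "pso"), cfg = cfg)
  expect_equal(nrow(tbl), 4)
  expect_setequal(tbl$scenario, c("base", "S2b"))
  # feasible rows re-verify independently against the transformed nets
  for (i in which(tbl$feasible)) {
    a <- attr(tbl, "allocations")[[paste(tbl$scenario[i],
                                         tbl$algorithm[i], sep = ".")]]
    snet <- apply_scenario(net, scen[[match(tbl$scenario[i],
                                            c("base", "S2b"))]])
    expect_true(check_feasibility(a, snet)$feasible)
  }
  # empty scenario list -> empty table
  empty <- run_benchmark(net, list(), algorithms = "ga", cfg = cfg)
  expect_equal(nrow(empty), 0)
})

test_that("blending profiles list per-receptor fractions summing to one", {
  net <- besos_network()
  a <- allocation(net); a["W1", "R1"] <- 27600
  pr <- blending_profile_report(a, net)
  expect_equal(nrow(pr), 1)
  expect_equal(pr$fraction, 1)
  expect_equal(pr$source, "W1")

  expect_equal(nrow(blending_profile_report(allocation(net), net)), 0)

  set.seed(8)
  for (i in 1:10) {
    a <- random_allocation(net)
    pr <- blending_profile_report(a, net)
    for (r in unique(pr$receptor))
      expect_equal(sum(pr$fraction[pr$receptor == r]), 1,
                   tolerance = 1e-9)
  }
})

test_that("truck schedules apply ceiling arithmetic over the HRT cycle", {
  net <- besos_network()
  a <- allocation(net); a["W1", "R1"] <- 2000
  sch <- logistics_schedule(a, net)  # 20 t trucks, 20-day cycle
  expect_equal(nrow(sch), 1)
  expect_equal(sch$cycle_mass_kg, 40000)
  expect_equal(sch$loads_per_cycle, 2)
  expect_true(attr(sch, "feasible_within_hrt"))

  # zero-volume edges are pruned
  expect_equal(nrow(logistics_schedule(allocation(net), net)), 0)

  # doubling density doubles mass and never reduces loads
  set.seed(15)
  a <- random_allocation(net)
  s1 <- logistics_schedule(a, net, density_kg_l = 1)
  s2 <- logistics_schedule(a, net, density_kg_l = 2)
  expect_equal(s2$cycle_mass_kg, 2 * s1$cycle_mass_kg)
  expect_true(all(s2$loads_per_cycle >= s1$loads_per_cycle))
})

test_that("parameter sweeps run one campaign per grid point", {
  net <- small_instance(2)
  cfg <- solver_config("ga", population = 30, iterations = 30,
                       repetitions = 1, seed = 4)
  tbl <- parameter_sweep(net, "ga",
                         list(ga_crossover_fraction = c(0.2, 0.5, 0.8)),
                         cfg = cfg)
  expect_equal(nrow(tbl), 3)
  expect_equal(sum(tbl$is_best), 1)
  expect_equal(tbl$best_b[tbl$is_best], max(tbl$best_b))
  # single-point grid: one row, marked best
  one <- parameter_sweep(net, "ga", list(population = 20), cfg = cfg)
  expect_equal(nrow(one), 1)
  expect_true(one$is_best)
  # deterministic under a fixed seed
  tbl2 <- parameter_sweep(net, "ga",
                          list(ga_crossover_fraction = c(0.2, 0.5, 0.8)),
                          cfg = cfg)
  expect_equal(tbl$best_b, tbl2$best_b)
  expect_error(parameter_sweep(net, "ga", list(nope = 1), cfg = cfg),
               "unknown solver_config parameter")
})
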