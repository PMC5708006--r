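# Scenario orchestration: conservation, determinism, saturation behaviour,
# scenario comparison and the choropleth export.

small_region <- function(seed = 51, pop = 3000) {
  generate_region(region_spec(nx = 3, ny = 3, total_population = pop,
                              n_hospitals = 2, seed = seed))
}

test_that("zero inpatient rates yield zero demand and fully vacant beds", {
  region <- small_region()
  region$rates$inpatient_rate[] <- 0
  sc <- scenario("null", n_samples = 1, seed = 2)
  run <- run_scenario(region, sc, n_steps = 1)
  expect_true(all(run$totals$patients_mean == 0))
  expect_true(all(run$totals$overdemand_mean == 0))
  expect_true(all(run$totals$oversupply_mean == run$capacity_total))
  expect_equal(run$first_overdemand_year, Inf)
})

test_that("identical seeds reproduce identical aggregates", {
  region <- small_region()
  sc <- scenario("s", n_samples = 3, seed = 42)
  a <- run_scenario(region, sc, n_steps = 2)
  b <- run_scenario(region, sc, n_steps = 2)
  expect_identical(a$totals, b$totals)
  expect_identical(a$mesh_overdemand, b$mesh_overdemand)
  expect_identical(a$hospital_vacancy, b$hospital_vacancy)
  d <- run_scenario(region, scenario("s", n_samples = 3, seed = 43),
                    n_steps = 2)
  expect_false(identical(a$totals, d$totals))
})

test_that("per-sample conservation holds in the aggregates", {
  region <- small_region()
  sc <- scenario("s", n_samples = 5, seed = 7)
  run <- run_scenario(region, sc, n_steps = 2)
  # patients = allocated + unallocated and beds = allocated + vacant,
  # so the means obey both identities too
  expect_equal(run$totals$allocated_mean + run$totals$overdemand_mean,
               run$totals$patients_mean)
  expect_equal(run$totals$allocated_mean + run$totals$oversupply_mean,
               rep(run$capacity_total, nrow(run$totals)))
  # per-mesh and per-hospital means aggregate to the totals
  expect_equal(unname(rowSums(run$mesh_overdemand)),
               run$totals$overdemand_mean)
  expect_equal(unname(rowSums(run$hospital_vacancy)),
               run$totals$oversupply_mean)
})

test_that("when capacity is far below demand, over-demand saturates", {
  region <- small_region(seed = 60, pop = 8000)
  # shrink hospitals to a handful of beds so every sampling saturates
  region$hospitals$total_beds <- c(5L, 5L)
  region$hospitals$size_class <-
    classify_hospital_size(region$hospitals$total_beds)
  sc <- scenario("tight", n_samples = 50, seed = 3)
  run <- run_scenario(region, sc, n_steps = 0)
  mu <- sum(expected_inpatients(region$meshes, region$rates))
  se <- run$totals$patients_sd[1] / sqrt(sc$n_samples)
  expect_lt(abs(run$totals$overdemand_mean[1] -
                  (mu - run$capacity_total)), 3 * se)
})

test_that("scenario comparison aligns years and ranks improvements", {
  region <- small_region(seed = 61, pop = 6000)
  # make supply tight enough that the baseline sees over-demand
  region$hospitals$total_beds <- c(20L, 15L)
  region$hospitals$size_class <-
    classify_hospital_size(region$hospitals$total_beds)
  suite <- default_scenarios(seed = 9, n_samples = 30)
  cmp <- compare_scenarios(region, suite, n_steps = 2)
  od <- cmp$table[, grep("^overdemand\\.", names(cmp$table))]
  expect_true(all(od[[1]] >= od[[2]] - 1e-9))
  expect_true(all(od[[2]] >= od[[3]] - 1e-9))
  expect_gte(cmp$first_overdemand[[3]], cmp$first_overdemand[[1]])
  expect_error(compare_scenarios(region, suite[1]), "at least two")
})

test_that("identical scenarios give identical comparison columns", {
  region <- small_region(seed = 62)
  s1 <- scenario("a", n_samples = 2, seed = 5)
  s2 <- scenario("b", n_samples = 2, seed = 5)
  cmp <- compare_scenarios(region, list(s1, s2), n_steps = 1)
  expect_equal(cmp$table$overdemand.a, cmp$table$overdemand.b)
  expect_error(compare_scenarios(region, list(s1, s1)), "unique")
})

test_that("a lower utilization rate brings over-demand onset weakly earlier", {
  region <- small_region(seed = 63, pop = 6000)
  region$hospitals$total_beds <- c(30L, 25L)
  region$hospitals$size_class <-
    classify_hospital_size(region$hospitals$total_beds)
  hi <- run_scenario(region, scenario("hi", utilization_rate = 1.0,
                                      n_samples = 20, seed = 4),
                     n_steps = 3)
  lo <- run_scenario(region, scenario("lo", utilization_rate = 0.5,
                                      n_samples = 20, seed = 4),
                     n_steps = 3)
  expect_lte(lo$first_overdemand_year, hi$first_overdemand_year)
})

test_that("the over-demand map export round-trips per-mesh means", {
  region <- small_region(seed = 64)
  sc <- scenario("s", n_samples = 2, seed = 11)
  run <- run_scenario(region, sc, n_steps = 1)
  path <- withr::local_tempfile(fileext = ".geojson")
  export_overdemand_map(run, region$meshes, path)
  props <- read_meshes_geojson(path)
  expect_equal(nrow(props), nrow(region$meshes))
  want <- run$mesh_overdemand[nrow(run$mesh_overdemand), ]
  expect_equal(props$overdemand[match(names(want), props$mesh_id)],
               unname(want))
  expect_error(export_overdemand_map(run, region$meshes, path, year = 1999),
               "year grid")
})
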