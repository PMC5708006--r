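# Cohort-component projection: aging identity, expected-mode arithmetic,
# and convergence of the stochastic sampler to the expected-mode oracle.

test_that("survival 1, no migration, no fertility is the pure aging shift", {
  rates <- simple_rates()
  cfg_e <- projection_config(mode = "expected")
  cfg_s <- projection_config(mode = "stochastic")
  set.seed(31)
  p <- population(0)
  p[] <- sample.int(500, 36)
  for (cfg in list(cfg_e, cfg_s)) {
    cur <- p
    for (step in 1:4) {
      nxt <- project_step(cur, rates, cfg)
      expect_equal(sum(nxt), sum(cur))           # total conserved
      expect_equal(nxt[, 2:17], cur[, 1:16],
                   ignore_attr = TRUE)           # cohorts one band older
      expect_equal(nxt[, 18], cur[, 17] + cur[, 18],
                   ignore_attr = TRUE)           # 85+ absorbs
      expect_equal(unname(nxt[, 1]), c(0, 0))    # no births
      cur <- nxt
    }
  }
})

test_that("aging alone drains everyone into the top band, which persists", {
  rates <- simple_rates()
  meshes <- mesh_table("m1", 0, 0, list(population(10)))
  series <- project_series(meshes, rates,
                           projection_config(n_steps = 20, mode = "expected"))
  final <- mesh_population(series[[21]], "m1")
  expect_equal(unname(final[, 18]), c(180, 180))  # 10 per band x 18 bands
  expect_equal(sum(final[, 1:17]), 0)
  expect_equal(final, mesh_population(series[[19]], "m1"))  # absorbed state
})

test_that("expected mode reproduces hand arithmetic for one cohort", {
  # 1000 people, survival 0.9, net migration -0.1: 1000*0.9*0.9 = 810
  rates <- simple_rates(survival = 0.9, migration = -0.1)
  p <- population(0)
  p["female", "30-34"] <- 1000
  nxt <- project_step(p, rates, projection_config(mode = "expected"))
  expect_equal(nxt["female", "35-39"], 810)
  expect_equal(sum(nxt), 810)
})

test_that("expected-mode births follow fertility, sex ratio and newborn survival", {
  rates <- rate_tables(fertility = c(0, 0.5, 0, 0, 0, 0, 0),
                       sex_ratio_at_birth = 1.05,
                       survival = 1, net_migration = 0, inpatient_rate = 0)
  p <- population(0)
  p["female", "15-19"] <- 1000  # shifts into 20-24 before births
  nxt <- project_step(p, rates, projection_config(mode = "expected"))
  expect_equal(nxt["male", "0-4"], 500 * 1.05 / 2.05)
  expect_equal(nxt["female", "0-4"], 500 / 2.05)

  # newborn thinning by band-0 survival
  rates2 <- rate_tables(fertility = c(0, 0.5, 0, 0, 0, 0, 0),
                        sex_ratio_at_birth = 1.05,
                        survival = 0.9, net_migration = 0,
                        inpatient_rate = 0)
  nxt2 <- project_step(p, rates2, projection_config(mode = "expected"))
  expect_equal(nxt2["female", "0-4"], 0.9 * 1000 * 0.9 * 0.5 / 2.05)
  nxt3 <- project_step(p, rates2,
                       projection_config(mode = "expected",
                                         newborn_survival = FALSE))
  expect_equal(nxt3["female", "0-4"], 1000 * 0.9 * 0.5 / 2.05)
})

test_that("expected mode is linear in the starting population", {
  rates <- default_rate_tables()
  cfg <- projection_config(mode = "expected")
  set.seed(5)
  p1 <- population(0); p1[] <- runif(36, 0, 100)
  p2 <- population(0); p2[] <- runif(36, 0, 100)
  lhs <- project_step(p1 + 2 * p2, rates, cfg)
  rhs <- project_step(p1, rates, cfg) + 2 * project_step(p2, rates, cfg)
  expect_equal(lhs, rhs)
})

test_that("stochastic means converge to the expected-mode oracle", {
  rates <- default_rate_tables()
  p <- population(200)
  cfg_s <- projection_config(mode = "stochastic")
  expected <- project_step(p, rates, projection_config(mode = "expected"))
  n <- 500
  draws <- array(0, c(2, 18, n))
  set.seed(99)
  for (i in seq_len(n)) draws[, , i] <- project_step(p, rates, cfg_s)
  mean_draw <- apply(draws, c(1, 2), mean)
  se <- apply(draws, c(1, 2), sd) / sqrt(n)
  expect_true(all(abs(mean_draw - expected) <= 3 * se + 1e-9))
  # stochastic counts stay non-negative integers
  expect_true(all(draws >= 0))
  expect_true(all(draws == round(draws)))
})

test_that("zero steps return the input; substreams make meshes independent", {
  region <- generate_region(region_spec(nx = 2, ny = 2,
                                        total_population = 2000,
                                        n_hospitals = 1, seed = 3))
  meshes <- region$meshes
  rates <- region$rates
  cfg0 <- projection_config(n_steps = 0, mode = "stochastic", seed = 1)
  expect_identical(project_series(meshes, rates, cfg0)[[1]], meshes)

  cfg <- projection_config(n_steps = 2, mode = "stochastic", seed = 8)
  joint <- project_series(meshes, rates, cfg, sample_index = 4L)
  for (id in meshes$mesh_id) {
    solo <- project_series(meshes[meshes$mesh_id == id, ], rates, cfg,
                           sample_index = 4L)
    expect_equal(mesh_population(solo[[3]], id),
                 mesh_population(joint[[3]], id))
  }
})

test_that("the long-format export indexes mesh, year, sex and band correctly", {
  meshes <- mesh_table(c("a", "b"), c(0, 500), 0)
  p <- population(0); p["male", "85+"] <- 7
  meshes <- paam:::set_mesh_populations(meshes, list(p, population(1)))
  series <- project_series(meshes, simple_rates(),
                           projection_config(n_steps = 1, mode = "expected"))
  long <- population_long(series, start_year = 2010, sample_index = 3L)
  expect_equal(nrow(long), 2 * 2 * 2 * 18)
  expect_equal(long$count[long$mesh_id == "a" & long$year == 2010 &
                            long$sex == "male" & long$age_band == "85+"], 7)
  expect_equal(long$count[long$mesh_id == "a" & long$year == 2015 &
                            long$sex == "male" & long$age_band == "85+"], 7)
  expect_equal(sum(long$count[long$mesh_id == "b" & long$year == 2010]), 36)
  expect_true(all(long$sample_index == 3L))
})
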