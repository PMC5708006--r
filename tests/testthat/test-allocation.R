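# Patient allocation: conservation, capacity limits, PAA containment,
# priority ordering, and the max-flow lower-bound oracle.

test_that("patients fill available beds and the rest are over-demand", {
  w <- toy_world(minutes = 10, beds = 7)
  caps <- setNames(5L, "h1")
  set.seed(1)
  res <- allocate(c(m1 = 7L), w$paa, w$hospitals, w$tm, capacities = caps)
  expect_equal(unname(res$allocated), 5L)
  expect_equal(unname(res$unallocated), 2L)
  expect_equal(unname(res$remaining), 0L)
  expect_equal(res$allocated + res$remaining, res$available)
  expect_equal(sum(res$allocated) + sum(res$unallocated), 7)
})

test_that("a mesh with an empty PAA loses every patient to over-demand", {
  w <- toy_world(minutes = Inf, beds = 100)
  paa <- compute_paa(w$tm, 60)
  expect_equal(lengths(paa$by_mesh), c(m1 = 0L))
  set.seed(2)
  res <- allocate(c(m1 = 9L), paa, w$hospitals, w$tm,
                  scenario = scenario("s"))
  expect_equal(unname(res$unallocated), 9L)
  expect_equal(sum(res$allocated), 0)
})

test_that("size class outranks travel time by default, and vice versa", {
  # nearer small hospital (10 min) vs farther large hospital (50 min)
  w <- toy_world(minutes = c(10, 50), beds = c(30, 500))
  sc <- scenario("s", utilization_rate = 0.8)
  set.seed(3)
  res <- allocate(c(m1 = 1L), w$paa, w$hospitals, w$tm, sc)
  expect_equal(unname(res$allocated), c(0L, 1L))  # large wins
  set.seed(3)
  res_t <- allocate(c(m1 = 1L), w$paa, w$hospitals, w$tm, sc,
                    strategy = "time_first")
  expect_equal(unname(res_t$allocated), c(1L, 0L))  # nearest wins
})

test_that("equal size and time fall back to the lowest hospital id", {
  w <- toy_world(minutes = c(10, 10), beds = c(50, 50))
  set.seed(4)
  res <- allocate(c(m1 = 1L), w$paa, w$hospitals, w$tm, scenario("s"))
  expect_equal(unname(res$allocated), c(1L, 0L))
})

test_that("patients never land outside their PAA and capacity never overflows", {
  for (seed in 1:25) {
    region <- generate_region(random_small_spec(seed + 500))
    tm <- build_travel_matrix(region$meshes, region$hospitals,
                              region$network)
    threshold <- sample(c(5, 15, 60), 1)
    paa <- compute_paa(tm, threshold)
    sc <- scenario("s", n_samples = 1, seed = seed)
    set.seed(seed)
    patients <- sample_inpatients(region$meshes, region$rates)
    patients <- patients + 2L  # force some pressure
    res <- allocate(patients, paa, region$hospitals, tm, sc)
    expect_true(all(res$allocated <= res$available))
    expect_equal(res$allocated + res$remaining, res$available)
    expect_equal(sum(res$allocated) + sum(res$unallocated), sum(patients))
    # hospitals reachable from no patient-bearing mesh must stay empty
    reachable <- unique(unlist(paa$by_mesh[names(patients)[patients > 0]]))
    empty <- setdiff(region$hospitals$hospital_id, reachable)
    expect_true(all(res$allocated[empty] == 0))
    # meshes with an empty PAA keep all their patients unallocated
    for (m in names(patients))
      if (!length(paa$by_mesh[[m]]))
        expect_equal(unname(res$unallocated[m]), unname(patients[m]))
  }
})

test_that("greedy over-demand is bounded below by the max-flow optimum", {
  set.seed(61)
  for (k in 1:30) {
    n_mesh <- sample(2:5, 1)
    n_hosp <- sample(1:5, 1)
    mesh_ids <- paste0("m", seq_len(n_mesh))
    hosp_ids <- paste0("h", seq_len(n_hosp))
    tm <- matrix(sample(c(10, 30, 120), n_mesh * n_hosp, replace = TRUE),
                 n_mesh, n_hosp, dimnames = list(mesh_ids, hosp_ids))
    paa <- compute_paa(tm, 60)
    patients <- setNames(sample(0:12, n_mesh, replace = TRUE), mesh_ids)
    caps <- setNames(sample(0:10, n_hosp, replace = TRUE), hosp_ids)
    hospitals <- hospital_table(hosp_ids, seq_len(n_hosp), 0,
                                sample(c(30, 200, 450), n_hosp,
                                       replace = TRUE))
    res <- allocate(patients, paa, hospitals, tm, capacities = caps)
    expect_gte(sum(res$unallocated), flow_min_overdemand(patients, paa, caps))
  }
})

test_that("greedy matches the flow optimum when every mesh sees every hospital", {
  set.seed(62)
  for (k in 1:20) {
    n_mesh <- sample(2:5, 1)
    n_hosp <- sample(1:5, 1)
    mesh_ids <- paste0("m", seq_len(n_mesh))
    hosp_ids <- paste0("h", seq_len(n_hosp))
    tm <- matrix(sample(5:50, n_mesh * n_hosp, replace = TRUE),
                 n_mesh, n_hosp, dimnames = list(mesh_ids, hosp_ids))
    paa <- compute_paa(tm, 60)  # all within threshold
    patients <- setNames(sample(0:12, n_mesh, replace = TRUE), mesh_ids)
    caps <- setNames(sample(0:10, n_hosp, replace = TRUE), hosp_ids)
    hospitals <- hospital_table(hosp_ids, seq_len(n_hosp), 0,
                                rep(100, n_hosp))
    res <- allocate(patients, paa, hospitals, tm, capacities = caps)
    expect_equal(sum(res$unallocated),
                 flow_min_overdemand(patients, paa, caps))
    expect_equal(sum(res$unallocated),
                 max(0, sum(patients) - sum(caps)))
  }
})

test_that("the gravity-model strategy conserves patients and respects the PAA", {
  w <- toy_world(minutes = c(5, 40), beds = c(100, 100))
  sc <- scenario("s")
  set.seed(9)
  res <- allocate(c(m1 = 50L), w$paa, w$hospitals, w$tm, sc,
                  strategy = "huff")
  expect_equal(sum(res$allocated) + sum(res$unallocated), 50)
  expect_equal(res$allocated + res$remaining, res$available)
  # beta = 2 distance decay: the 5-min hospital should dominate 64:1
  expect_gt(res$allocated[["h1"]], res$allocated[["h2"]])
})

test_that("allocation demands a PAA entry for every mesh with patients", {
  w <- toy_world(minutes = 10, beds = 10)
  expect_error(allocate(c(ghost = 1L), w$paa, w$hospitals, w$tm,
                        scenario("s")),
               "absent from the PAA")
  expect_error(allocate(c(m1 = -1L), w$paa, w$hospitals, w$tm,
                        scenario("s")),
               "non-negative")
})

test_that("raising the utilization rate never raises mean over-demand", {
  region <- generate_region(region_spec(nx = 3, ny = 3,
                                        total_population = 4000,
                                        n_hospitals = 2, seed = 88))
  tm <- build_travel_matrix(region$meshes, region$hospitals, region$network)
  paa <- compute_paa(tm, 60)
  run_mean <- function(util, n = 200) {
    sc <- scenario("s", utilization_rate = util)
    od <- numeric(n)
    for (i in seq_len(n)) {
      set.seed(derive_seed(1000, i))
      patients <- sample_inpatients(region$meshes, region$rates)
      set.seed(derive_seed(2000, i))
      od[i] <- sum(allocate(patients, paa, region$hospitals, tm,
                            sc)$unallocated)
    }
    c(mean = mean(od), se = sd(od) / sqrt(n))
  }
  lo <- run_mean(0.4)
  hi <- run_mean(0.8)
  expect_lte(hi[["mean"]], lo[["mean"]] + 2 * (lo[["se"]] + hi[["se"]]))
})
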