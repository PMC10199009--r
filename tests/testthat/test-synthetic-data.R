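test_that("grid geographies have exact rook contiguity", {
  g1 <- generate_geography(1, 1, c(100, 100))
  expect_length(g1$area_ids, 1)
  expect_equal(nrow(g1$edges), 0)

  g2 <- generate_geography(2, 2, c(50, 80), seed = 1)
  expect_equal(nrow(g2$edges), 4)
  expect_equal(unname(rowSums(geography_adjacency(g2))), rep(2, 4))
  expect_true(all(g2$populations >= 50 & g2$populations <= 80))

  # 3x3: corners 2 neighbours, edge midpoints 3, centre 4 (hand-enumerated)
  g3 <- generate_geography(3, 3, c(10, 10))
  deg <- unname(rowSums(geography_adjacency(g3)))
  expect_equal(deg, c(2, 3, 2, 3, 4, 3, 2, 3, 2))

  expect_error(generate_geography(0, 3), "positive")
})

test_that("generator is seed-reproducible and seed-sensitive", {
  g_a <- generate_geography(3, 3, c(100, 200), seed = 7)
  g_b <- generate_geography(3, 3, c(100, 200), seed = 7)
  expect_identical(g_a, g_b)
  s_a <- generate_participants(g_a, c(20, 30), seed = 8)
  s_b <- generate_participants(g_a, c(20, 30), seed = 8)
  expect_identical(s_a, s_b)
  s_c <- generate_participants(g_a, c(20, 30), seed = 9)
  expect_false(identical(s_a$trips, s_c$trips))
})

test_that("generated diaries classify back to their generating categories", {
  g <- small_geography(3, 3)
  sv <- generate_participants(g, c(60, 60), seed = 21)
  cl <- suppressWarnings(classify_travel(sv$trips, sv$persons))
  truth <- toupper(sv$persons$true_category[match(cl$person_id,
                                                  sv$persons$person_id)])
  expect_equal(as.character(cl$duration_category), truth)

  # degenerate mixture: everyone is a high-level active traveller
  prof <- behaviour_profile(category_probs = c(no_travel = 0, low_at = 0,
                                               high_at = 1, mt = 0, st = 0))
  sv2 <- generate_participants(g, c(25, 25), profile = prof, seed = 22)
  cl2 <- classify_travel(sv2$trips, sv2$persons)
  expect_true(all(cl2$duration_category == "HIGH_AT"))
  expect_true(all(cl2$walkcycle_min >= 30))

  expect_error(behaviour_profile(category_probs = c(
    no_travel = 0.5, low_at = 0.2, high_at = 0.2, mt = 0.2, st = 0.2)),
    "sum to 1")
})

test_that("default behaviour profile reproduces the target category mix", {
  g <- small_geography(4, 4)
  sv <- generate_participants(g, c(150, 150), seed = 23)
  cl <- suppressWarnings(classify_travel(sv$trips, sv$persons))
  share <- 100 * table(cl$duration_category) / nrow(cl)
  target <- c(NO_TRAVEL = 20.8, LOW_AT = 2.6, HIGH_AT = 5.5, MT = 11.9,
              ST = 59.2)
  # 2400 participants: binomial Monte-Carlo error ~1 point on the largest
  expect_true(all(abs(share[names(target)] - target) < 2.5))
  grp <- table(cl$mode_group[cl$mode_group %in%
                               c("WALK_CYCLE_ONLY", "CAR_USER", "PT_USER")])
  grp <- 100 * grp / sum(grp)
  expect_true(abs(grp[["CAR_USER"]] - 86.4) < 4)
  expect_true(abs(grp[["PT_USER"]] - 8.6) < 3)
})

test_that("outcome generation follows the CAR generative model", {
  g <- small_geography(3, 3)
  sv <- generate_participants(g, c(40, 40), seed = 31)
  cl <- suppressWarnings(classify_travel(sv$trips, sv$persons))
  prof <- aggregate_areas(cl)

  # noise-free limit: y equals the linear predictor exactly
  tr0 <- ground_truth(62, c(pct_high_at = -0.2), rho = 0.5, tau2 = 0,
                      nu2 = 0)
  y0 <- generate_outcomes(prof, g, tr0, seed = 32)
  expect_equal(as.vector(y0), 62 - 0.2 * prof$pct_high_at[
    match(g$area_ids, prof$area_id)], ignore_attr = TRUE)

  # law of large numbers: beta = 0 gives mean outcome near the intercept
  tr_flat <- ground_truth(62, c(pct_high_at = 0), rho = 0.5, tau2 = 1,
                          nu2 = 1)
  ys <- sapply(1:100, function(r)
    mean(generate_outcomes(prof, g, tr_flat, seed = 100 + r)))
  expect_lt(abs(mean(ys) - 62), 0.2)  # MC error ~0.05 over 100 replicates

  # independence at rho = 0: Moran's I of the spatial draw stays near its
  # null expectation -1/(n-1)
  W <- geography_adjacency(g)
  tr_ind <- ground_truth(62, c(pct_high_at = 0), rho = 0, tau2 = 2, nu2 = 0)
  mi <- sapply(1:200, function(r)
    morans_i(attr(generate_outcomes(prof, g, tr_ind, seed = 300 + r),
                  "phi"), W))
  expect_lt(abs(mean(mi) - (-1 / 8)), 0.03)

  # and at rho near 1 the draws are positively autocorrelated
  tr_sp <- ground_truth(62, c(pct_high_at = 0), rho = 0.99, tau2 = 2,
                        nu2 = 0)
  mi_sp <- sapply(1:100, function(r)
    morans_i(attr(generate_outcomes(prof, g, tr_sp, seed = 600 + r),
                  "phi"), W))
  expect_gt(mean(mi_sp), 0.1)
})

test_that("residual variance converges to nu2 plus the marginal CAR variance", {
  g <- small_geography(3, 3)
  sv <- generate_participants(g, c(40, 40), seed = 41)
  prof <- aggregate_areas(suppressWarnings(
    classify_travel(sv$trips, sv$persons)))
  W <- geography_adjacency(g)
  rho <- 0.6; tau2 <- 3; nu2 <- 0.5
  Q <- rho * (diag(rowSums(W)) - W) + (1 - rho) * diag(9)
  expected <- nu2 + tau2 * mean(diag(solve(Q)))
  tr <- ground_truth(60, c(pct_st = 0.05), rho = rho, tau2 = tau2,
                     nu2 = nu2)
  resid2 <- unlist(lapply(1:300, function(r) {
    y <- generate_outcomes(prof, g, tr, seed = 700 + r)
    (unname(y) - attr(y, "linear_predictor"))^2
  }))
  expect_equal(mean(resid2), expected, tolerance = 0.1)
})

test_that("degenerate CAR precision is reported", {
  ids <- c("A", "B")
  g <- structure(list(area_ids = ids,
                      edges = data.frame(area_a = character(0),
                                         area_b = character(0)),
                      populations = setNames(c(10, 10), ids),
                      rows = 1L, cols = 2L),
                 class = "area_geography")
  prof <- data.frame(area_id = ids, pct_high_at = c(5, 10))
  tr <- ground_truth(62, c(pct_high_at = 0), rho = 1, tau2 = 2, nu2 = 0)
  expect_error(generate_outcomes(prof, g, tr, seed = 1), "singular")
})

test_that("survey files round-trip through the delimited writers", {
  g <- generate_geography(2, 2, c(30, 30), seed = 51)
  sv <- generate_participants(g, c(15, 15), seed = 52)
  dir <- tempfile("survey")
  write_survey_files(sv, g, dir)
  back <- read_survey_files(dir)
  expect_equal(nrow(back$trips), nrow(sv$trips))
  expect_equal(back$persons$person_id, sv$persons$person_id)
  first_line <- readLines(file.path(dir, "trips.tsv"), n = 1)
  expect_match(first_line, "seed: 52")
  cl_disk <- suppressWarnings(classify_travel(back$trips, back$persons))
  cl_mem <- suppressWarnings(classify_travel(sv$trips, sv$persons))
  expect_equal(as.character(cl_disk$duration_category),
               as.character(cl_mem$duration_category))
})
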