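# shared synthetic study data for the model battery tests
study_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    g <- generate_geography(6, 6, c(100, 100), seed = 201)
    sv <- generate_participants(g, c(120, 160), seed = 202)
    cl <- suppressWarnings(classify_travel(sv$trips, sv$persons))
    set.seed(203)
    irsd <- data.frame(area_id = g$area_ids,
                       irsd = rnorm(36, 1020, 65))
    prof <- aggregate_areas(cl, irsd = irsd)
    cache <<- list(geo = g, prof = prof, W = geography_adjacency(g))
    cache
  }
})

test_that("model specs pin down the battery's exposure rosters", {
  m3 <- model_spec("M3")
  expect_setequal(m3$exposures, c("pct_low_at", "pct_high_at", "pct_mt",
                                  "pct_no_travel"))
  expect_false("pct_st" %in% m3$exposures)
  expect_false("pct_pst" %in% m3$exposures)
  expect_length(model_spec("M1", "pct_st")$covariates, 0)
  expect_length(model_spec("M2", "pct_st")$covariates, 6)
  expect_equal(model_spec("DIVERSITY_M1")$exposures, "diversity")
  expect_error(model_spec("M1"), "exactly one")
  expect_error(model_spec("M1", "pct_bogus"), "unknown exposure")
})

test_that("unadjusted models recover a strong negative exposure effect", {
  fx <- study_fixture()
  prof <- fx$prof
  tr <- ground_truth(70, c(pct_high_at = -0.6), rho = 0.5, tau2 = 0.5,
                     nu2 = 0.3)
  prof$outcome_rate <- generate_outcomes(prof, fx$geo, tr, seed = 204)
  res <- run_model(model_spec("M1", "pct_high_at"), prof, fx$W,
                   config = quick_mcmc(2000, 500, 1, seed = 205))
  b <- res$summary[res$summary$parameter == "pct_high_at", ]
  expect_true(b$significant)
  expect_lt(b$median, 0)
  # reported per 5-point increment: about 5 times the generative slope
  expect_equal(b$median, 5 * -0.6, tolerance = 0.25)
})

test_that("adjusted and unadjusted models agree when covariates are independent", {
  fx <- study_fixture()
  prof <- fx$prof
  tr <- ground_truth(70, c(pct_high_at = -0.5), rho = 0.4, tau2 = 0.5,
                     nu2 = 0.5)
  prof$outcome_rate <- generate_outcomes(prof, fx$geo, tr, seed = 206)
  m1 <- run_model(model_spec("M1", "pct_high_at"), prof, fx$W,
                  config = quick_mcmc(2000, 500, 1, seed = 207))
  m2 <- run_model(model_spec("M2", "pct_high_at"), prof, fx$W,
                  config = quick_mcmc(2000, 500, 1, seed = 208))
  b1 <- m1$summary$median[m1$summary$parameter == "pct_high_at"]
  b2 <- m2$summary$median[m2$summary$parameter == "pct_high_at"]
  expect_lt(abs(b1 - b2), 0.6)  # both on the 5-point scale
  expect_equal(nrow(m2$summary), nrow(m1$summary) + 6)
})

test_that("substitution contrasts are invariant to the omitted category", {
  fx <- study_fixture()
  prof <- fx$prof
  tr <- ground_truth(70, c(pct_high_at = -0.5), rho = 0.3, tau2 = 0.3,
                     nu2 = 0.3)
  prof$outcome_rate <- generate_outcomes(prof, fx$geo, tr, seed = 209)
  cfg <- quick_mcmc(4000, 1000, 1, seed = 210)
  # omit ST: coefficients are direct ST-replacement contrasts
  f_st <- fit_car_leroux(
    outcome_rate ~ pct_low_at + pct_high_at + pct_mt + pct_no_travel,
    prof, fx$W, cfg)
  # omit no-travel instead: ST contrast for c is beta_c - beta_st
  f_nt <- fit_car_leroux(
    outcome_rate ~ pct_low_at + pct_high_at + pct_mt + pct_st,
    prof, fx$W, mcmc_config(4000, 1000, 1, seed = 211))
  for (v in c("pct_low_at", "pct_high_at", "pct_mt")) {
    c_st <- median(f_st$draws$beta[, v])
    c_nt <- median(f_nt$draws$beta[, v] - f_nt$draws$beta[, "pct_st"])
    expect_lt(abs(c_st - c_nt), 0.12)
  }
  c_nt_row <- median(f_st$draws$beta[, "pct_no_travel"])
  c_nt_alt <- median(-f_nt$draws$beta[, "pct_st"])
  expect_lt(abs(c_nt_row - c_nt_alt), 0.12)
})

test_that("the substitution table renders contrasts with the omitted target", {
  fx <- study_fixture()
  prof <- fx$prof
  # pure composition: the outcome is driven by the high-AT vs ST trade-off
  set.seed(212)
  prof$outcome_rate <- 75 - 0.6 * prof$pct_high_at + rnorm(36, 0, 0.4)
  m3 <- run_model(model_spec("M3"), prof, fx$W,
                  config = quick_mcmc(3000, 1000, 1, seed = 213))
  tab <- substitution_table(m3)
  expect_equal(nrow(tab), 5)
  expect_equal(tab$parameter,
               c("pct_low_at", "pct_high_at", "pct_mt", "pct_no_travel",
                 "pct_st"))
  st_row <- tab[tab$parameter == "pct_st", ]
  expect_true(is.na(st_row$median))
  expect_equal(st_row$note, "(substitution target)")
  high <- tab[tab$parameter == "pct_high_at", ]
  expect_lt(high$median, 0)  # replacing ST with high AT lowers the rate
  expect_true(high$significant)
})

test_that("run_model validates its inputs", {
  fx <- study_fixture()
  prof <- fx$prof
  prof$outcome_rate <- 62
  expect_error(run_model(model_spec("M2", "pct_high_at"), prof[1:5, ],
                         fx$W[1:5, 1:5], config = quick_mcmc()),
               "insufficient areas")
  expect_error(run_model(model_spec("M1", "pct_high_at"),
                         prof[, c("area_id", "pct_st")], fx$W,
                         config = quick_mcmc()),
               "outcome_rate")
})

test_that("diversity models drop missing-diversity areas and rebuild W", {
  fx <- study_fixture()
  prof <- fx$prof
  tr <- ground_truth(70, c(diversity = -8), rho = 0.4, tau2 = 0.3,
                     nu2 = 0.3)
  prof$outcome_rate <- generate_outcomes(prof, fx$geo, tr, seed = 214)
  prof$diversity[1:4] <- NA
  res <- run_model(model_spec("DIVERSITY_M1"), prof, fx$W,
                   config = quick_mcmc(1500, 500, 1, seed = 215))
  expect_equal(res$n_areas, 32)
  expect_equal(nrow(res$fit$W), 32)
  b <- res$summary[res$summary$parameter == "diversity", ]
  expect_lt(b$median, 0)
})

test_that("the full simulated study runs end-to-end and is deterministic", {
  cfg <- list(seed = 42,
              simulate = list(rows = 5, cols = 5,
                              n_per_area = c(60, 90),
                              truth = list(intercept = 62,
                                           beta = c(pct_high_at = -0.4),
                                           rho = 0.5, tau2 = 1, nu2 = 0.5)),
              mcmc = list(n_iter = 700, burn_in = 200, thin = 2),
              models = c("M1", "M3"),
              m1_m2_metrics = c("pct_high_at", "pct_st"))
  r1 <- run_full_study(cfg)
  r2 <- run_full_study(cfg)
  expect_identical(r1$included, r2$included)
  expect_identical(lapply(r1$models, `[[`, "summary"),
                   lapply(r2$models, `[[`, "summary"))
  expect_identical(r1$substitution, r2$substitution)

  # one model result per requested spec, one summary row per exposure
  expect_named(r1$models, c("M1.pct_high_at", "M1.pct_st", "M3"),
               ignore.order = TRUE)
  m3s <- r1$models$M3$summary
  expect_true(all(c("pct_low_at", "pct_high_at", "pct_mt",
                    "pct_no_travel") %in% m3s$parameter))
  expect_equal(nrow(r1$profiles), 25)
  expect_s3_class(r1$correlations, NA)
  expect_true(is.matrix(r1$correlations))
  expect_output(print(r1), "Simulated area-level")

  # raising the minimum sample above every area size fails cleanly
  cfg_bad <- cfg
  cfg_bad$min_n <- 1000
  expect_error(run_full_study(cfg_bad), "insufficient areas")
})

test_that("study configs load from YAML and JSON files", {
  cfg <- list(seed = 7,
              simulate = list(rows = 4, cols = 4, n_per_area = c(50, 70),
                              truth = list(intercept = 62,
                                           beta = list(pct_high_at = -0.3),
                                           rho = 0.5, tau2 = 1, nu2 = 0.5)),
              mcmc = list(n_iter = 400, burn_in = 100, thin = 2),
              models = "M1", m1_m2_metrics = "pct_high_at")
  yml <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, yml)
  r_yaml <- run_full_study(yml)
  r_list <- run_full_study(cfg)
  expect_identical(r_yaml$models$M1.pct_high_at$summary,
                   r_list$models$M1.pct_high_at$summary)
  jsn <- tempfile(fileext = ".json")
  jsonlite::write_json(cfg, jsn, auto_unbox = TRUE, digits = NA)
  r_json <- run_full_study(jsn)
  expect_identical(r_json$models$M1.pct_high_at$summary,
                   r_list$models$M1.pct_high_at$summary)
})

test_that("participant accounting applies the exclusion cascade", {
  acc <- participant_accounting(c(a = 1000, b = 500), incomplete_diary = 40,
                                missing_location = 10, small_area = 50)
  expect_equal(acc$total_adults, 1500)
  expect_equal(acc$analysed, 1450)
  expect_equal(acc$final, 1400)
})
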