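two_parcel_fixture <- function() {
  list(
    states = rect_layer(0, 0, 20, 10, id = "S1", state_name = "S1"),
    priorities = rect_layer(0, 0, 5, 5),
    lands = square_layer(c(1, 12), c(1, 1), c(1, 1),
                         acquisition_date = as.Date(c("2001-06-01", NA)),
                         tenure = c("fee", "easement"))
  )
}

test_that("a half-aligned two-parcel portfolio scores P_TNC = 0.5", {
  fx <- two_parcel_fixture()
  rep <- suppressWarnings(run_assessment(fx$lands, fx$priorities, fx$states))
  all_row <- rep$by_stratum[rep$by_stratum$stratum == "all", ]
  expect_equal(all_row$p_tnc, 0.5, tolerance = 1e-9)
  expect_equal(all_row$a_tnc, 2, tolerance = 1e-9)
  expect_equal(all_row$p_s, 25 / 200, tolerance = 1e-9)
  expect_equal(all_row$score,
               science_influence_score(0.5, 0.125), tolerance = 1e-9)
  # stratum membership: the dated fee parcel, the undated easement parcel
  expect_equal(rep$by_stratum$a_tnc[rep$by_stratum$stratum == "2000-2005"], 1)
  expect_equal(rep$by_stratum$a_tnc[rep$by_stratum$stratum == "easement"], 1)
  expect_equal(rep$by_stratum$a_tnc[rep$by_stratum$stratum == "fee"], 1)
})

test_that("parcels wholly inside priorities give P_TNC = 1 in every stratum", {
  states <- rect_layer(0, 0, 10, 10, state_name = "S1")
  priorities <- rect_layer(0, 0, 10, 6)
  lands <- square_layer(c(1, 3, 5), c(1, 1, 1), c(1, 1, 1),
                        acquisition_date = as.Date(c("1995-01-01", "2003-01-01", NA)),
                        tenure = c("fee", "easement", "fee"))
  rep <- suppressWarnings(run_assessment(lands, priorities, states))
  filled <- rep$by_stratum[!is.na(rep$by_stratum$p_tnc), ]
  expect_true(all(abs(filled$p_tnc - 1) < 1e-9))
  expect_true(all(abs(filled$score - 1) < 1e-9))
})

test_that("a parcel straddling two states splits its area between them", {
  states <- rect_layer(c(0, 10), c(0, 0), c(10, 20), c(10, 10),
                       id = c("A", "B"), state_name = c("A", "B"))
  priorities <- rect_layer(0, 0, 20, 5) # southern half of both states
  lands <- rect_layer(9.5, 4, 10.5, 5) # 1x1 parcel, half in each state
  rep <- suppressWarnings(run_assessment(lands, priorities, states))
  expect_equal(sort(rep$by_state$a_tnc), c(0.5, 0.5), tolerance = 1e-9)
  expect_equal(sum(rep$by_state$a_tnc),
               rep$by_stratum$a_tnc[rep$by_stratum$stratum == "all"],
               tolerance = 1e-9)
})

test_that("per-state summaries are consistent with the national overlay", {
  cfg <- simulation_config(n_states = 4, state_size = 300, coverage = 0.3,
                           n_parcels = 1500, influence = 0.5, seed = 17)
  ls <- simulate_landscape(cfg)
  rep <- run_assessment(ls$lands, ls$priorities, ls$states, strata = "all")
  nat <- rep$by_stratum[rep$by_stratum$stratum == "all", ]
  expect_equal(sum(rep$by_state$a_o) / nat$a_o, 1, tolerance = 1e-6)
  expect_equal(sum(rep$by_state$a_tnc) / nat$a_tnc, 1, tolerance = 1e-6)
  expect_equal(sum(rep$by_state$a_p) / nat$a_p, 1, tolerance = 1e-6)
  # clipping to states never increases any area
  expect_lte(nat$a_tnc, sum(feature_areas(ls$lands)) + 1e-9)
})

test_that("single-state summaries equal the national summary", {
  fx <- two_parcel_fixture()
  rep <- suppressWarnings(run_assessment(fx$lands, fx$priorities, fx$states))
  nat <- rep$by_stratum[rep$by_stratum$stratum == "all", ]
  st <- rep$by_state
  expect_equal(st$a_o, nat$a_o, tolerance = 1e-9)
  expect_equal(st$p_tnc, nat$p_tnc, tolerance = 1e-9)
  expect_equal(st$score, nat$score, tolerance = 1e-9)
})

test_that("states without priorities or without land are handled explicitly", {
  states <- rect_layer(c(0, 10), c(0, 0), c(10, 20), c(10, 10),
                       id = c("A", "B"), state_name = c("A", "B"))
  priorities <- rect_layer(1, 1, 5, 5) # only in state A
  lands <- square_layer(1.5, 1.5, 1)   # only in state A
  rep <- suppressWarnings(run_assessment(lands, priorities, states))
  a <- rep$by_state[rep$by_state$region == "A", ]
  b <- rep$by_state[rep$by_state$region == "B", ]
  # state with no priority area: P_S = 0 so score equals P_TNC
  expect_equal(a$score, a$p_tnc, tolerance = 1e-12)
  # state with no land: alignment missing, not zero
  expect_true(is.na(b$p_tnc) && is.na(b$score))
  expect_equal(b$p_s, 0)
})

test_that("empty inputs are flagged or rejected", {
  fx <- two_parcel_fixture()
  empty <- vector_layer(fx$lands[0, ])
  expect_warning(rep <- run_assessment(empty, fx$priorities, fx$states), "no land")
  expect_true(rep$meta$empty_lands)
  expect_equal(rep$by_stratum$a_tnc[rep$by_stratum$stratum == "all"], 0)
  expect_null(rep$centroid_test)

  no_pri <- vector_layer(fx$priorities[0, ])
  expect_error(run_assessment(fx$lands, no_pri, fx$states),
               class = "prioralign_data_error")
})

test_that("the pipeline is deterministic for identical inputs", {
  cfg <- simulation_config(n_states = 2, state_size = 200, n_parcels = 400, seed = 31)
  ls <- simulate_landscape(cfg)
  r1 <- run_assessment(ls$lands, ls$priorities, ls$states)
  r2 <- run_assessment(ls$lands, ls$priorities, ls$states)
  expect_identical(r1$by_stratum, r2$by_stratum)
  expect_identical(r1$by_state, r2$by_state)
  expect_identical(glance(r1$centroid_test), glance(r2$centroid_test))
})

test_that("tenure-specific influence is recovered as a score contrast", {
  reps <- lapply(1:4, function(seed) {
    cfg <- simulation_config(n_states = 1, state_size = 700, coverage = 0.364,
                             n_parcels = 20000, influence = 0.6,
                             s_easement = 0.44, s_fee = 0.78, seed = seed)
    ls <- simulate_landscape(cfg)
    rep <- run_assessment(ls$lands, ls$priorities, ls$states, strata = "tenure",
                          centroid_test = FALSE, per_state = FALSE)
    rep$by_stratum
  })
  ease <- mean(vapply(reps, function(r) r$score[r$stratum == "easement"], 0))
  fee <- mean(vapply(reps, function(r) r$score[r$stratum == "fee"], 0))
  expect_lt(abs(ease - 0.44), 0.02)
  expect_lt(abs(fee - 0.78), 0.02)
  expect_lt(abs((fee - ease) - 0.34), 0.02)
})

test_that("the centroid test has power against influence and holds its size", {
  # power: moderate influence at realistic coverage rejects decisively
  rejections <- vapply(1:10, function(seed) {
    cfg <- simulation_config(n_states = 1, state_size = 700, coverage = 0.364,
                             n_parcels = 2000, influence = 0.6, seed = seed)
    ls <- simulate_landscape(cfg)
    counts <- count_centroids_in_priorities(ls$lands, ls$priorities)
    ct <- centroid_chi_square(counts$n_in, counts$n_in + counts$n_out, 0.364)
    ct$p_value < 1e-4
  }, TRUE)
  expect_true(all(rejections))

  # size: under the null (s = 0) the rejection rate at alpha = 0.05 is ~5%
  pvals <- vapply(1:150, function(seed) {
    cfg <- simulation_config(n_states = 1, state_size = 700, coverage = 0.35,
                             n_parcels = 500, influence = 0, seed = 1000 + seed)
    ls <- simulate_landscape(cfg)
    counts <- count_centroids_in_priorities(ls$lands, ls$priorities)
    centroid_chi_square(counts$n_in, counts$n_in + counts$n_out, 0.35)$p_value
  }, 0)
  rate <- mean(pvals < 0.05)
  expect_gte(rate, 0.01)
  expect_lte(rate, 0.11)
})

test_that("report accessors expose tidy tables", {
  fx <- two_parcel_fixture()
  rep <- suppressWarnings(run_assessment(fx$lands, fx$priorities, fx$states))
  expect_s3_class(tidy(rep), "tbl_df")
  expect_s3_class(tidy(rep, table = "state"), "tbl_df")
  gl <- glance(rep)
  expect_equal(gl$p_tnc, 0.5, tolerance = 1e-9)
  expect_true("chi2" %in% names(gl))
})
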