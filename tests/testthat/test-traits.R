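test_that("280-day milk standardization sums, extrapolates or drops", {
  expect_equal(cumulative_milk_280(rep(20, 300)), 5600)
  expect_equal(cumulative_milk_280(rep(20, 280)), 5600)
  # spline extrapolation of constant data is (nearly) constant
  expect_equal(cumulative_milk_280(rep(20, 240)), 5600, tolerance = 1 / 5600)
  expect_true(is.na(cumulative_milk_280(rep(20, 200))))
  expect_error(cumulative_milk_280(c(rep(20, 230), -1)),
               class = "lactgain_contract_error")
  # declining lactation: extrapolation stays between naive bounds
  y <- 25 * exp(-seq_len(240) / 300)
  v <- cumulative_milk_280(y)
  expect_gt(v, sum(y))
  expect_lt(v, sum(y) + 40 * y[240])
})

test_that("derived phenotypes gate third-lactation traits on parity", {
  sim <- tiny_sim_hs()
  ph <- derive_phenotypes(sim)
  early <- sim$summary$final_parity < 3
  expect_true(all(is.na(ph$milk_280[early])))
  expect_true(all(is.na(ph$dmi_mean[early])))
  expect_true(all(is.na(ph$lact_eff[early])))
  expect_true(all(is.na(ph$ifc[early])))
  expect_true(all(!is.na(ph$bw_calv1[sim$summary$final_parity >= 1])))
  expect_true(all(!is.na(ph$life_eff)))
  late <- !early
  expect_true(all(ph$lact_eff[late] > 0 & ph$lact_eff[late] < 100))
  expect_true(all(ph$life_eff > 0 & ph$life_eff < 100))
  expect_true(all(ph$ifc >= 0, na.rm = TRUE))
  # interval is a whole number of oestrus cycles
  expect_true(all(ph$ifc %% 21 == 0, na.rm = TRUE))
})

test_that("a cow conceiving at first third-lactation service has ifc 0", {
  sim <- tiny_sim_hs()
  ph <- derive_phenotypes(sim)
  ins <- sim$inseminations
  first_service <- ins[ins$parity == 3 & ins$success, ]
  one_shot <- vapply(unique(first_service$animal_id), function(a) {
    sub <- ins[ins$animal_id == a & ins$parity == 3, ]
    nrow(sub) == 1
  }, logical(1))
  skip_if(!any(one_shot), "no first-service conception in fixture")
  a <- unique(first_service$animal_id)[one_shot][1]
  expect_equal(ph$ifc[ph$animal_id == a], 0)
})

test_that("mean trajectories reduce to the individual records for one cow", {
  clone <- mean_cow()
  sim1 <- simulate_herd(clone, cal_hs(), seed = 44)
  tr1 <- mean_trajectories(sim1)
  skip_if(nrow(tr1) == 0, "cow did not reach third lactation")
  i <- which(!is.na(sim1$p3$milk[1, ]))
  expect_equal(tr1$milk_ecm, sim1$p3$milk[1, i], ignore_attr = TRUE)
  # mean of two identical cows equals either one
  sim2 <- simulate_herd(clone[rep(1, 2), ], cal_hs(), seed = 44)
  tr2 <- mean_trajectories(sim2)
  if (nrow(tr2) == nrow(tr1)) {
    expect_equal(tr2$milk_ecm, tr1$milk_ecm, tolerance = 1e-6)
  }
  expect_error(mean_trajectories(sim1, parity = 2),
               class = "lactgain_config_error")
})

test_that("lifetime summary covers all cows including early culls", {
  sim <- tiny_sim_ms()
  ph <- derive_phenotypes(sim)
  ls <- lifetime_summary(sim)
  expect_equal(ls$n_cows, nrow(sim$summary))
  expect_equal(ls$mean_lactations, mean(ph$lactations_completed))
  # survivor-only summaries differ from all-cow summaries (selection bias)
  survivors <- ph[!is.na(ph$milk_280), ]
  expect_lt(nrow(survivors), nrow(ph))
})
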