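fake_scheme <- function(resp = c(BasAcq = 0.28, LactAcq = 0.19,
                                 f_prio_GS = 0.08, LactAll = 0.16),
                        alpha = c(BasAcq = 0.93, LactAcq = 0.93,
                                  f_prio_GS = 0.93, LactAll = 0.93)) {
  structure(list(goal = "Base",
                 mean_gains = tibble::tibble(trait = names(resp),
                                             annual_gain_sd = unname(resp)),
                 alpha = tibble::tibble(trait = names(alpha),
                                        alpha = unname(alpha))),
            class = "scheme_result")
}

test_that("selection updates accumulate responses on the trait scale", {
  upd <- build_update(fake_scheme(), horizon = 10)
  # basal acquisition: 0.28 SD/yr, sigma_g = 7.00 * 0.10 * sqrt(0.35)
  sg <- 7.00 * 0.10 * sqrt(0.35)
  row <- upd[upd$trait == "bas_acq", ]
  expect_equal(row$sigma_g, sg, tolerance = 1e-12)
  expect_equal(row$delta_mean, 0.28 * sg * 10, tolerance = 1e-12)
  expect_equal(row$delta_mean, 1.16, tolerance = 0.01)
  expect_equal(row$new_mean, 7.00 + 0.28 * sg * 10)
  expect_equal(row$h2_prime, bulmer_update(0.35, 0.93))
  expect_equal(row$h2_prime, 0.3337, tolerance = 1e-4)
  # residual variance unchanged, genetic variance scaled by alpha
  expect_equal(row$var_e, 0.65 * (0.7)^2, tolerance = 1e-12)
  expect_equal(row$var_g, 0.93 * sg^2, tolerance = 1e-12)
  expect_error(build_update(fake_scheme(), horizon = 0),
               class = "lactgain_config_error")
})

test_that("the identity update leaves the baseline configuration unchanged", {
  upd <- identity_update()
  expect_equal(upd$new_mean, unname(aa_means()))
  expect_true(all(upd$delta_mean == 0))
  expect_equal(upd$h2_prime, rep(0.35, 4))
})

test_that("an identity update produces exactly zero mechanistic response", {
  upd <- identity_update()
  r <- predict_mm_response(upd, "HS", n_cows = 60, seed = 5,
                           daughters_per_sire = 10)
  expect_true(all(r$annual_response[!is.na(r$annual_response)] == 0))
})

test_that("method comparison flags differences and rank inversions", {
  mm <- tidyr::crossing(goal = c("A", "B"), trait = c("Milk", "IFC"))
  mm$annual_response_sd <- c(0.3, 0.1, 0.2, 0.2)
  conv <- mm
  names(conv)[3] <- "annual_gain_sd"
  cmp <- compare_methods(mm, conv)
  expect_true(all(cmp$differences$difference == 0))
  expect_true(all(!cmp$rankings$inverted))
  # swap one pair: exactly one trait shows inversions
  conv2 <- conv
  conv2$annual_gain_sd[conv2$trait == "Milk"] <-
    rev(conv2$annual_gain_sd[conv2$trait == "Milk"])
  cmp2 <- compare_methods(mm, conv2)
  inv <- cmp2$rankings[cmp2$rankings$inverted, ]
  expect_equal(sort(unique(inv$trait)), "Milk")
  expect_equal(nrow(inv), 2)
  expect_error(compare_methods(mm[mm$goal == "A", ], conv),
               class = "lactgain_config_error")
})

test_that("positive acquisition updates move intake less under restriction", {
  upd <- build_update(fake_scheme(), horizon = 15)
  rh <- predict_mm_response(upd, "HS", n_cows = 150, seed = 9,
                            daughters_per_sire = 15)
  rm <- predict_mm_response(upd, "MS", n_cows = 150, seed = 9,
                            daughters_per_sire = 15)
  dmi_h <- rh$annual_response[rh$trait == "DMI"]
  dmi_m <- rm$annual_response[rm$trait == "DMI"]
  expect_gt(dmi_h, 0)
  expect_lt(dmi_m, dmi_h)
})
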