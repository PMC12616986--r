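trio_ped <- tibble::tibble(animal_id = 1:3, sire_id = c(0, 0, 1),
                           dam_id = c(0, 0, 2))

test_that("A-inverse matches the closed form for a parent-offspring trio", {
  Ai <- as.matrix(a_inverse(trio_ped))
  expect_equal(Ai, matrix(c(1.5, 0.5, -1, 0.5, 1.5, -1, -1, -1, 2), 3),
               ignore_attr = TRUE)
  # inverse of the tabular relationship matrix
  A <- matrix(c(1, 0, 0.5, 0, 1, 0.5, 0.5, 0.5, 1), 3)
  expect_equal(as.matrix(Ai %*% A), diag(3), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_error(a_inverse(tibble::tibble(animal_id = 1:2, sire_id = c(2, 0),
                                        dam_id = c(0, 0))),
               class = "lactgain_config_error")
})

test_that("inbreeding coefficients match hand-computed pedigrees", {
  # full-sib mating: offspring of two full sibs has F = 0.25
  ped <- tibble::tibble(animal_id = 1:5,
                        sire_id = c(0, 0, 1, 1, 3),
                        dam_id = c(0, 0, 2, 2, 4))
  f <- inbreeding_coefficients(ped)
  expect_equal(f$inbreeding, c(0, 0, 0, 0, 0.25))
  # half-sib mating: F = 0.125
  ped2 <- tibble::tibble(animal_id = 1:6,
                         sire_id = c(0, 0, 0, 1, 1, 4),
                         dam_id = c(0, 0, 0, 2, 3, 5))
  f2 <- inbreeding_coefficients(ped2, subset = 6)
  expect_equal(f2$inbreeding, 0.125)
  # parent-offspring mating: F = 0.25
  ped3 <- tibble::tibble(animal_id = 1:3, sire_id = c(0, 1, 1),
                         dam_id = c(0, 0, 2))
  expect_equal(inbreeding_coefficients(ped3, subset = 3)$inbreeding, 0.25)
})

test_that("single-trait BLUP equals the dense GLS oracle on a 5-animal pedigree", {
  ped <- tibble::tibble(animal_id = 1:5,
                        sire_id = c(0, 0, 1, 1, 3),
                        dam_id = c(0, 0, 2, 2, 4))
  y <- c(2.1, -0.7, 1.4, 0.3, 2.8)
  anim <- c(1, 2, 3, 4, 5)
  h2 <- 0.4
  G <- matrix(1, 1, 1, dimnames = list("T", "T"))
  res <- blup_evaluate(ped, tibble::tibble(animal_id = anim, trait = "T",
                                           value = y),
                       G, c(T = (1 - h2) / h2))
  u <- dense_blup_oracle(ped, anim, y, var_g = 1, var_e = (1 - h2) / h2)
  expect_equal(res$ebv_T, u, tolerance = 1e-8)
})

test_that("records shrink toward the mean and propagate to relatives", {
  ped <- tibble::tibble(animal_id = 1:12,
                        sire_id = c(0, 0, rep(1, 10)),
                        dam_id = c(0, 0, rep(2, 10)))
  y <- c(rep(2, 5), rep(-1, 5)) # records on the 10 offspring
  res <- blup_evaluate(ped, tibble::tibble(animal_id = 3:12, trait = "T",
                                           value = y),
                       matrix(1, 1, 1, dimnames = list("T", "T")),
                       c(T = 1.5))
  # unrecorded parents get nonzero EBVs through their progeny
  expect_gt(res$ebv_T[1], 0 - 1e-9)
  ranked <- order(res$ebv_T[3:12], decreasing = TRUE)
  expect_true(all(ranked[1:5] %in% 1:5))
})

test_that("parent EBV from progeny means strengthens with progeny count", {
  # 50 unrelated animals with null records anchor the population mean, so
  # the progeny group's deviation is not absorbed by the fixed effect
  ebv_parent <- vapply(c(1, 10, 100), function(np) {
    n_anchor <- 50
    ped <- tibble::tibble(
      animal_id = seq_len(n_anchor + 2 + np),
      sire_id = c(rep(0, n_anchor + 2), rep(n_anchor + 1, np)),
      dam_id = c(rep(0, n_anchor + 2), rep(n_anchor + 2, np)))
    recs <- tibble::tibble(
      animal_id = c(seq_len(n_anchor), n_anchor + 2 + seq_len(np)),
      trait = "T", value = c(rep(0, n_anchor), rep(1, np)))
    res <- blup_evaluate(ped, recs, matrix(1, 1, 1,
                                           dimnames = list("T", "T")),
                         c(T = 2))
    res$ebv_T[n_anchor + 1]
  }, numeric(1))
  expect_true(all(diff(ebv_parent) > 0))
})

test_that("multi-trait evaluation transfers information across traits", {
  ped <- tibble::tibble(animal_id = 1:4, sire_id = c(0, 0, 1, 1),
                        dam_id = c(0, 0, 2, 2))
  G <- matrix(c(1, 0.8, 0.8, 1), 2, dimnames = list(c("A", "B"), c("A", "B")))
  recs <- tibble::tibble(animal_id = c(3, 4), trait = "A", value = c(2, 1.6))
  res <- blup_evaluate(ped, recs, G, c(A = 1, B = 1))
  # trait B has no records; EBVs come entirely through the correlation
  expect_equal(res$ebv_B, 0.8 * res$ebv_A, tolerance = 1e-8)
  expect_error(blup_evaluate(ped, tibble::tibble(animal_id = 1, trait = "C",
                                                 value = 1), G, c(C = 1)),
               class = "lactgain_config_error")
})
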