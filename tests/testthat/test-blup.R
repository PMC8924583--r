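make_balanced_pheno <- function(n = 60, su = 6, se = 4, years = c(2019L, 2020L),
                                year_eff = c(0, 8), mu = 50, seed = 1) {
  withr::with_seed(seed, {
    u <- rnorm(n, 0, su)
    tibble::tibble(
      id = rep(sprintf("S%03d", 1:n), each = length(years)),
      trait = "firmness",
      year = rep(years, n),
      value = mu + rep(year_eff, n) + rep(u, each = length(years)) +
        rnorm(n * length(years), 0, se)
    )
  })
}

test_that("balanced-design BLUPs equal the closed-form shrinkage estimator", {
  pheno <- make_balanced_pheno(seed = 5)
  fit <- fit_multiyear_blup(pheno, "firmness")
  wide <- tidyr::pivot_wider(pheno, id_cols = id, names_from = year,
                             values_from = value)
  vw <- as.matrix(wide[-1])
  rownames(vw) <- wide$id
  oracle <- balanced_blup_oracle(vw, fit$sigma_u2, fit$sigma_e2)
  got <- tidy(fit)
  expect_equal(got$deviation, unname(oracle[got$id]), tolerance = 1e-6)
  expect_true(all(got$n_years == 2))
  # deviations centre on zero for a balanced design
  expect_lt(abs(mean(got$deviation)), 1e-6)
})

test_that("BLUP deviations shrink toward zero and vanish without residual noise", {
  pheno <- make_balanced_pheno(seed = 6)
  fit <- fit_multiyear_blup(pheno, "firmness")
  wide <- tidyr::pivot_wider(pheno, id_cols = id, names_from = year,
                             values_from = value)
  raw_dev <- rowMeans(as.matrix(wide[-1])) - mean(rowMeans(as.matrix(wide[-1])))
  got <- tidy(fit)
  expect_true(all(abs(got$deviation) <= abs(raw_dev[match(got$id, wide$id)]) + 1e-8))

  # zero residual variance: no shrinkage, deviation = centred individual mean
  pheno0 <- make_balanced_pheno(se = 0, seed = 7)
  # near-zero residual variance trips lmer's convergence checks; the
  # deviations themselves are what is under test
  fit0 <- suppressWarnings(suppressMessages(fit_multiyear_blup(pheno0, "firmness")))
  wide0 <- tidyr::pivot_wider(pheno0, id_cols = id, names_from = year,
                              values_from = value)
  raw0 <- rowMeans(as.matrix(wide0[-1])) - mean(rowMeans(as.matrix(wide0[-1])))
  got0 <- tidy(fit0)
  dev0 <- got0$deviation - mean(got0$deviation)
  expect_equal(dev0, unname(raw0[match(got0$id, wide0$id)]), tolerance = 1e-3)
})

test_that("REML recovers known variance components and ignores constant shifts", {
  pheno <- make_balanced_pheno(n = 500, su = 6, se = 4, seed = 8)
  fit <- fit_multiyear_blup(pheno, "firmness")
  expect_lt(abs(fit$sigma_u2 - 36) / 36, 0.2)
  expect_lt(abs(fit$sigma_e2 - 16) / 16, 0.2)

  shifted <- dplyr::mutate(pheno, value = value + 1000)
  fit2 <- fit_multiyear_blup(shifted, "firmness")
  expect_equal(tidy(fit2)$deviation, tidy(fit)$deviation, tolerance = 1e-6)
  expect_equal(fit2$intercept, fit$intercept + 1000, tolerance = 1e-6)
  g <- glance(fit)
  expect_identical(g$n_individuals, 500L)
})

test_that("zero-variance phenotypes warn and return zero deviations", {
  flat <- tibble::tibble(id = c("a", "a", "b", "b"), trait = "firmness",
                         year = rep(c(2019L, 2020L), 2), value = 300)
  expect_warning(fit <- fit_multiyear_blup(flat, "firmness"), "zero variance")
  expect_true(all(tidy(fit)$deviation == 0))
  expect_identical(fit$sigma_u2, 0)
})

test_that("between-year correlation handles exact, reversed and simulated data", {
  base <- tibble::tibble(id = sprintf("S%02d", 1:10), trait = "cracking",
                         year = 2019L, value = seq(2, 20, 2))
  same <- dplyr::bind_rows(base, dplyr::mutate(base, year = 2020L))
  expect_equal(between_year_correlation(same, "cracking", c(2019, 2020))$estimate, 1)
  anti <- dplyr::bind_rows(base, dplyr::mutate(base, year = 2020L,
                                               value = 100 - value))
  expect_equal(between_year_correlation(anti, "cracking", c(2019, 2020))$estimate, -1)
  few <- same[c(1, 2, 11, 12), ]
  expect_error(between_year_correlation(few, "cracking", c(2019, 2020)),
               "at least 3")

  # true between-year correlation 0.6 at n = 250: estimate within 3 SE
  # (Fisher z SE = 1/sqrt(n - 3))
  withr::with_seed(9, {
    n <- 250
    g <- rnorm(n, 0, sqrt(0.6))
    y1 <- pmin(pmax(50 + 20 * (g + rnorm(n, 0, sqrt(0.4))), 0), 100)
    y2 <- pmin(pmax(50 + 20 * (g + rnorm(n, 0, sqrt(0.4))), 0), 100)
  })
  sim <- tibble::tibble(id = rep(sprintf("S%03d", 1:n), 2), trait = "cracking",
                        year = rep(c(2019L, 2020L), each = n), value = c(y1, y2))
  r <- between_year_correlation(sim, "cracking", c(2019, 2020))$estimate
  expect_lt(abs(atanh(r) - atanh(0.6)), 3 / sqrt(n - 3))
})

test_that("subpopulation comparison picks the right test and controls type I", {
  subpops <- tibble::tibble(id = sprintf("S%03d", 1:60),
                            subpop = rep(c("A", "B"), each = 30))
  withr::with_seed(10, {
    hits <- vapply(1:2000, function(i) {
      ph <- tibble::tibble(id = subpops$id, trait = "firmness", year = 2020L,
                          value = rnorm(60, 300, 40))
      compare_subpopulations(ph, subpops, "firmness", 2020)$p_value <= 0.05
    }, logical(1))
  })
  expect_lte(mean(hits), 0.06)

  # power: +49 g/mm shift, SD 40, n = 120 / 140 -> essentially always detected
  subpops2 <- tibble::tibble(id = sprintf("S%03d", 1:260),
                             subpop = rep(c("A", "B"), c(120, 140)))
  withr::with_seed(11, {
    found <- vapply(1:200, function(i) {
      ph <- tibble::tibble(
        id = subpops2$id, trait = "firmness", year = 2020L,
        value = rnorm(260, 281, 40) + ifelse(subpops2$subpop == "B", 49, 0))
      compare_subpopulations(ph, subpops2, "firmness", 2020)$p_value <= 0.05
    }, logical(1))
  })
  expect_gte(mean(found), 0.99)

  # method conventions and the constant-groups convention
  ph <- tibble::tibble(id = subpops$id, trait = "cracking", year = 2019L,
                       value = rep(c(40, 60), 30))
  expect_identical(compare_subpopulations(ph, subpops, "cracking", 2019)$method,
                   "wilcoxon")
  flat <- dplyr::mutate(ph, value = 50)
  expect_identical(compare_subpopulations(flat, subpops, "cracking", 2019)$p_value, 1)
})

test_that("simulated germplasm shows the expected between-year correlations", {
  sim <- sim_germplasm(seed = 1, config = sim_config(seed = 1))
  rc <- between_year_correlation(sim$phenotypes, "cracking", c(2019, 2020))
  expect_gt(rc$estimate, 0.4)
  expect_lt(rc$estimate, 0.78)
  rf <- between_year_correlation(sim$phenotypes, "firmness", c(2019, 2020))
  expect_gt(rf$estimate, 0.4)
})
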