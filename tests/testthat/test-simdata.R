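test_that("build_pedigree counts founders, IBPs, seedlings and accepts self-crosses", {
  cfg <- small_config()
  ped <- build_pedigree(cfg)
  expect_identical(sum(ped$role == "founder"), 4L)
  expect_identical(sum(ped$role == "IBP"), 6L)
  expect_identical(sum(ped$role == "seedling"), 48L)
  both_known <- sum(!is.na(ped$mother) & !is.na(ped$father))
  expect_identical(both_known, 48L + 2L)  # seedlings + the two derived IBPs
  # self-cross offspring have mother == father
  selfed <- ped[ped$mother %in% "P05" & ped$father %in% "P05", ]
  expect_identical(nrow(selfed), 8L)

  bad <- cfg
  bad$cross_design$mother[1] <- "P99"
  expect_error(build_pedigree(bad), "undeclared")
})

test_that("default configuration matches the emulated germplasm scale", {
  cfg <- sim_config()
  ped <- build_pedigree(cfg)
  expect_identical(sum(ped$role == "seedling"), 259L)
  expect_identical(sum(ped$role == "IBP"), 22L)
  expect_identical(sum(ped$subpop %in% "A"), 119L)
  expect_identical(sum(ped$subpop %in% "B"), 140L)
  map <- make_marker_map(cfg)
  expect_identical(nrow(map), 1617L)
  expect_identical(dplyr::n_distinct(map$linkage_group), 8L)
})

test_that("founder simulation respects allele frequencies", {
  cfg <- small_config()
  ped <- build_pedigree(cfg)
  map <- make_marker_map(cfg)
  f0 <- simulate_founders(ped, map, founder_freq = 0, seed = 1)
  expect_true(all(f0$h1 == "A") && all(f0$h2 == "A"))

  # 500 founders -> 1000 haplotypes per SNP; binomial 3.2-sigma band
  big_ped <- tibble::tibble(id = sprintf("F%03d", 1:500),
                            mother = NA_character_, father = NA_character_)
  small_map <- map[1:20, ]
  fb <- simulate_founders(validate_pedigree(big_ped), small_map,
                          founder_freq = 0.5, seed = 42)
  freq <- (colSums(fb$h1 == "B") + colSums(fb$h2 == "B")) / 1000
  expect_true(all(freq >= 0.45 & freq <= 0.55))

  expect_error(simulate_founders(ped, map[0, ], seed = 1), "empty")
})

test_that("a zero-length map transmits parental haplotypes intact", {
  cfg <- small_config()
  ped <- build_pedigree(cfg)
  map <- make_marker_map(cfg)
  map$genetic_pos <- 0
  f <- simulate_founders(ped, map, seed = 2)
  drop <- drop_gametes(ped, f, map, seed = 3)
  expect_true(all(drop$transmissions$n_crossovers == 0))
  kid <- ped$id[ped$role == "seedling"][1]
  mo <- ped$mother[ped$id == kid]
  for (lg in unique(map$linkage_group)) {
    idx <- map$linkage_group == lg
    expect_true(identical(drop$phased$h1[kid, idx], drop$phased$h1[mo, idx]) ||
                  identical(drop$phased$h1[kid, idx], drop$phased$h2[mo, idx]))
  }
})

test_that("recombinant gamete fraction follows Haldane's map function", {
  # two SNPs 50 cM apart: expected recombinant fraction (1 - exp(-1))/2
  ped <- validate_pedigree(tibble::tibble(
    id = c("P1", "P2", sprintf("S%04d", 1:5000)),
    mother = c(NA, NA, rep("P1", 5000)),
    father = c(NA, NA, rep("P2", 5000)),
    role = c("founder", "founder", rep("seedling", 5000))
  ))
  map <- tibble::tibble(snp_id = c("m1", "m2"), linkage_group = 1L,
                        genetic_pos = c(0, 50), physical_pos = c(0, 16.5))
  f <- simulate_founders(ped, map, seed = 7)
  drop <- drop_gametes(ped, f, map, seed = 8)
  kids <- sprintf("S%04d", 1:5000)
  rec <- mean(c(drop$phased$org1[kids, 1] != drop$phased$org1[kids, 2],
                drop$phased$org2[kids, 1] != drop$phased$org2[kids, 2]))
  expected <- (1 - exp(-1)) / 2
  se <- sqrt(expected * (1 - expected) / 10000)
  expect_lt(abs(rec - expected), 3 * se)
})

test_that("every simulated trio is Mendelian-consistent at every SNP", {
  sim <- sim_germplasm(config = small_config(seed = 9))
  ped <- sim$pedigree
  ph <- sim$phased
  kids <- ped[!is.na(ped$mother), ]
  ok <- vapply(seq_len(nrow(kids)), function(i) {
    id <- kids$id[i]; mo <- kids$mother[i]; fa <- kids$father[i]
    all(ph$h1[id, ] == ph$h1[mo, ] | ph$h1[id, ] == ph$h2[mo, ]) &&
      all(ph$h2[id, ] == ph$h1[fa, ] | ph$h2[id, ] == ph$h2[fa, ])
  }, logical(1))
  expect_true(all(ok))
})

test_that("phenotypes honour granularity, bounds and degenerate settings", {
  sim <- sim_germplasm(config = small_config(seed = 4))
  crack <- sim$phenotypes$value[sim$phenotypes$trait == "cracking"]
  expect_true(all(crack >= 0 & crack <= 100))
  expect_true(all(abs(crack / 2 - round(crack / 2)) < 1e-9))  # 2% steps
  expect_identical(
    nrow(dplyr::count(sim$phenotypes, id, trait) |> dplyr::filter(n != 2)), 0L)

  cfg0 <- small_config(seed = 6)
  cfg0$qtl_specs$effect <- 0
  cfg0$polygenic_sd[] <- 0
  cfg0$residual_sd <- 0
  cfg0$trait_means[["firmness"]] <- 300
  cfg0$year_effects$firmness[] <- 0
  cfg0$subpop_effects$firmness[] <- 0
  sim0 <- sim_germplasm(config = cfg0)
  firm <- sim0$phenotypes$value[sim0$phenotypes$trait == "firmness"]
  expect_true(all(firm == 300))
})

test_that("a planted firmness haplotype effect is recovered from carrier means", {
  cfg <- small_config(seed = 13, n_off = 90)  # 540 seedlings
  sim <- sim_germplasm(config = cfg)
  q <- sim$truth$qtl[sim$truth$qtl$trait == "firmness", ]
  dose <- (sim$phased$h1[, q$ps_snp] == "B") + (sim$phased$h2[, q$ps_snp] == "B")
  firm <- sim$phenotypes |>
    dplyr::filter(trait == "firmness") |>
    dplyr::group_by(id) |>
    dplyr::summarise(value = mean(value))
  d <- dose[firm$id]
  fit <- coef(lm(firm$value ~ d))[2]
  # regression on dosage recovers the planted additive effect (30 g/mm)
  se <- sqrt(sum(residuals(lm(firm$value ~ d))^2) /
               (length(d) - 2) / sum((d - mean(d))^2))
  expect_lt(abs(fit - 30), 3 * se + 3)
})

test_that("degrade unphases faithfully and hits the missing rate", {
  sim <- sim_germplasm(config = small_config(seed = 21))
  g0 <- degrade(sim$phased, 0)
  expect_identical(unname(g0),
                   unname((sim$phased$h1 == "B") + (sim$phased$h2 == "B")))
  # single phased pair (A,B) -> dosage 1
  expect_identical(unname(g0[which(sim$phased$h1 == "A" &
                                     sim$phased$h2 == "B")[1]]), 1L)
  big <- sim_germplasm(config = small_config(seed = 22, n_off = 200))
  g <- degrade(big$phased, 0.05, seed = 1)
  frac <- mean(is.na(g))
  expect_gt(length(g), 1e5)
  expect_true(frac >= 0.045 && frac <= 0.055)
  expect_error(degrade(sim$phased, 1), "missing_rate")
})

test_that("identical seeds give bit-identical germplasm", {
  a <- sim_germplasm(config = small_config(seed = 33))
  b <- sim_germplasm(config = small_config(seed = 33))
  expect_identical(a$phased, b$phased)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$genotypes, b$genotypes)
})
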