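# the recurring worked example: a 7-SNP haploblock, primary SNP at
# within-block position 3, parental haplotypes H1/H2
worked_catalog <- function() {
  haplotype_catalog(c("AABAAAA", "ABABBAB"), ps_index = 3)
}

test_that("the haplotype catalog numbers distinct strings by frequency", {
  cat <- haplotype_catalog(c("AABAAAA", "ABABBAB", "AABAAAA", "BBBBBBB"),
                           ps_index = 3)
  expect_identical(cat$label, c("H1", "H2", "H3"))
  expect_identical(cat$string[1], "AABAAAA")  # most frequent first
  expect_identical(cat$ps_allele, c("B", "A", "B"))
  expect_identical(nrow(haplotype_catalog(c("AA-AAAA"), 3)), 0L)  # missing excluded
})

test_that("recombinant seedling haplotypes classify by the primary-SNP allele", {
  cat <- worked_catalog()
  # recombinant mixing both parental strings: the PS B allele decides H1
  expect_identical(classify_haplotype("AABABAB", cat, 3), "H1")
  # exact matches take their own label
  expect_identical(classify_haplotype("ABABBAB", cat, 3), "H2")
  expect_identical(classify_haplotype("AABAAAA", cat, 3), "H1")
  # missing PS allele and no exact match: unassigned
  expect_identical(classify_haplotype("AA-ABAB", cat, 3), NA_character_)
  # both parental haplotypes share the PS allele: ambiguous
  cat2 <- haplotype_catalog(c("AABAAAA", "ABBBBAB"), ps_index = 3)
  expect_identical(classify_haplotype("AABABAB", cat2, 3), NA_character_)
  expect_error(classify_haplotype("AAB", cat, 3), "length")
})

test_that("classification is idempotent and never contradicts the PS allele", {
  cat <- worked_catalog()
  haps <- apply(expand.grid(rep(list(c("A", "B")), 7)), 1, paste, collapse = "")
  for (h in haps) {
    lab <- classify_haplotype(h, cat, 3)
    if (!is.na(lab)) {
      expect_identical(substr(h, 3, 3), cat$ps_allele[cat$label == lab])
    }
  }
})

test_that("primary SNPs require significance, proximity and maximal PVE", {
  map <- tibble::tibble(
    snp_id = sprintf("s%02d", 1:12), linkage_group = 1L,
    genetic_pos = seq(2, 46, by = 4), physical_pos = seq(2, 46, by = 4) / 3)
  blocks <- validate_haploblocks(tibble::tibble(
    block_id = c("B1", "B2", "B3"), linkage_group = 1L,
    snp_ids = list(sprintf("s%02d", 1:4), sprintf("s%02d", 5:8),
                   sprintf("s%02d", 9:12))), map)
  scan <- tibble::tibble(
    snp_id = map$snp_id, p_value = 1, minus_log10_p = 0, maf = 0.3,
    pve_adj_r2 = 0, bonferroni_significant = FALSE, cofactor = FALSE)
  scan$bonferroni_significant[c(2, 6)] <- TRUE
  scan$pve_adj_r2[c(2, 6)] <- c(0.12, 0.15)
  qtl <- list(name = "qCrack-LG1.1m", linkage_group = 1L, peak_cm = 20)
  ps <- designate_primary_snp(scan, qtl, blocks, map)
  expect_identical(ps$snp_id, "s06")            # larger PVE wins
  expect_identical(ps$block_id, "B2")
  expect_identical(ps$ps_index, 2L)

  # PVE tie: the lower genetic position wins
  scan$pve_adj_r2[c(2, 6)] <- 0.15
  expect_identical(designate_primary_snp(scan, qtl, blocks, map)$snp_id, "s02")

  # only significant SNP 25 cM from the peak: no primary SNP
  far <- list(name = "q", linkage_group = 1L, peak_cm = 70)
  scan2 <- dplyr::mutate(scan, bonferroni_significant = snp_id == "s11")
  scan2$pve_adj_r2[11] <- 0.2
  blocks2 <- blocks
  expect_identical(nrow(designate_primary_snp(scan2, far, blocks2, map)), 0L)
})

test_that("parent-guided phasing keeps only uniquely consistent gamete pairs", {
  # homozygous seedling: trivially phased
  r <- parent_guided_phasing(c(2L, 0L, 2L), c("BAB", "AAB"), c("BAB", "BAA"))
  expect_identical(r$status, "phased")
  expect_identical(r$hap1, "BAB")

  # AA/BB x AA/BB, all-heterozygous seedling: unique unordered string pair
  r2 <- parent_guided_phasing(c(1L, 1L), c("AA", "BB"), c("AA", "BB"))
  expect_identical(r2$status, "phased")
  expect_setequal(c(r2$hap1, r2$hap2), c("AA", "BB"))

  # several distinct consistent pairs: unassigned
  r3 <- parent_guided_phasing(c(1L, 1L), c("AA", "AB"), c("BB", "BA"))
  expect_identical(r3$status, "unassigned")

  # Mendelian-inconsistent genotype: flagged
  r4 <- parent_guided_phasing(c(2L, 2L), c("AA", "AA"), c("AA", "AA"))
  expect_identical(r4$status, "inconsistent")

  # exhaustive check against brute-force enumeration on 3-SNP blocks
  combos <- expand.grid(rep(list(c("A", "B")), 3))
  strings <- apply(combos, 1, paste, collapse = "")
  withr::with_seed(3, {
    for (i in 1:60) {
      mo <- sample(strings, 2); fa <- sample(strings, 2)
      mh <- sample(1:2, 1); fh <- sample(1:2, 1)
      dose <- vapply(1:3, function(j) {
        (substr(mo[mh], j, j) == "B") + (substr(fa[fh], j, j) == "B")
      }, numeric(1))
      got <- parent_guided_phasing(as.integer(dose), mo, fa)
      pairs <- unique(apply(expand.grid(m = 1:2, f = 1:2), 1, function(k) {
        cand <- c(mo[k[1]], fa[k[2]])
        ok <- all(vapply(1:3, function(j) {
          (substr(cand[1], j, j) == "B") + (substr(cand[2], j, j) == "B") == dose[j]
        }, logical(1)))
        if (ok) paste(sort(cand), collapse = "/") else NA_character_
      }))
      n_ok <- sum(!is.na(pairs))
      expect_identical(got$status == "phased", n_ok == 1)
    }
  })
})

test_that("only haplotypes seen at least five times enter the analysis", {
  labels <- tibble::tibble(
    id = sprintf("S%02d", 1:20),
    label = c(rep("H1", 5), rep("H2", 4), rep("H3", 10), NA))
  common <- common_haplotypes(labels)
  expect_setequal(common$label, c("H1", "H3"))
  expect_identical(common$n[common$label == "H1"], 5L)
})

test_that("haplotype effects are carrier means minus the population mean", {
  # single shared haplotype: zero effect
  one <- tibble::tibble(id = sprintf("S%02d", 1:10), label = "H1")
  vals <- tibble::tibble(id = one$id, value = rnorm(10, 300, 10))
  eff <- estimate_effects(one, vals, min_n = 5)
  expect_equal(eff$effect, 0)

  # the published arithmetic: carriers at 341 vs population 270 -> +71
  ids <- sprintf("S%02d", 1:20)
  noncarrier <- (270 * 20 - 341 * 7) / 13   # population mean pinned at 270
  vals2 <- tibble::tibble(id = ids, value = c(rep(341, 7), rep(noncarrier, 13)))
  expect_equal(mean(vals2$value), 270, tolerance = 1e-10)
  labels2 <- tibble::tibble(id = ids[1:7], label = "H1")
  eff2 <- estimate_effects(labels2, vals2, min_n = 5)
  expect_equal(eff2$effect, 71, tolerance = 1e-10)
  expect_identical(eff2$n_carriers, 7L)
})

test_that("instance-weighted effects of all labels sum to zero", {
  # all-heterozygous population: every seedling carries two distinct labels
  withr::with_seed(4, {
    ids <- sprintf("S%03d", 1:60)
    l1 <- sample(c("H1", "H2", "H3"), 60, replace = TRUE)
    l2 <- paste0(l1, "x")  # guaranteed distinct second strand
    labels <- tibble::tibble(id = rep(ids, 2), label = c(l1, l2))
    vals <- tibble::tibble(id = ids, value = rnorm(60, 50, 8))
  })
  eff <- estimate_effects(labels, vals, min_n = 1)
  expect_lt(abs(sum(eff$n * eff$effect)), 1e-8)
})

test_that("pairwise contrasts control the family-wise error and find real gaps", {
  # identical groups: no edges
  flat <- tibble::tibble(label = rep(c("H1", "H2"), each = 10), value = rep(1:10, 2))
  expect_identical(nrow(pairwise_tests(flat, "tukey_hsd")), 0L)

  # null: 6 groups, family-wise any-edge rate at alpha = 0.05
  withr::with_seed(5, {
    hits <- vapply(1:2000, function(i) {
      d <- tibble::tibble(label = rep(sprintf("H%d", 1:6), each = 10),
                          value = rnorm(60))
      nrow(pairwise_tests(d, "tukey_hsd")) > 0
    }, logical(1))
  })
  expect_lte(mean(hits), 0.07)

  # two groups 5 pooled SD apart: detected essentially always, right direction
  withr::with_seed(6, {
    found <- vapply(1:200, function(i) {
      d <- tibble::tibble(label = rep(c("HI", "LO"), each = 12),
                          value = c(rnorm(12, 5, 1), rnorm(12, 0, 1)))
      e <- pairwise_tests(d, "pairwise_wilcoxon")
      nrow(e) == 1 && e$higher == "HI"
    }, logical(1))
  })
  expect_gte(mean(found), 0.99)

  # undersized groups are excluded with a warning
  d <- tibble::tibble(label = c("H1", rep(c("H2", "H3"), each = 5)),
                      value = c(1, rnorm(10)))
  expect_warning(pairwise_tests(d, "tukey_hsd"), "H1")
})

test_that("functional classes follow the relational rule on the worked example", {
  edges <- tibble::tibble(
    higher = c("H1", "H1", "H1", "H5", "H3"),
    lower = c("H2", "H3", "H4", "H2", "H6"))
  labs <- paste0("H", 1:6)
  cls <- assign_functional_classes(edges, labs)
  got <- setNames(cls$class, cls$label)
  expect_identical(got[["H1"]], "high")
  expect_identical(got[["H5"]], "moderate")
  expect_identical(got[["H3"]], "moderate")
  expect_identical(got[["H2"]], "low")   # most incoming among pure-low labels
  # never both high and low, only the four classes
  expect_true(all(cls$class %in% c("high", "moderate", "low", "none")))

  empty <- assign_functional_classes(tibble::tibble(higher = character(),
                                                    lower = character()), labs)
  expect_true(all(empty$class == "none"))
})

test_that("diplotype compilation counts desirable haplotypes per seedling", {
  assignments <- tibble::tibble(
    id = rep(c("S1", "S2"), each = 2),
    block_id = rep(c("B1", "B2"), 2),
    label1 = c("H2", "H2", NA, NA),
    label2 = c("H2", "H2", NA, NA))
  classes <- tibble::tibble(block_id = rep(c("B1", "B2"), each = 2),
                            label = rep(c("H1", "H2"), 2),
                            class = rep(c("high", "low"), 2))
  out <- compile_diplotypes(assignments, classes, desirable = "low")
  expect_identical(out$counts$n_desirable[out$counts$id == "S1"], 4L)
  expect_identical(out$counts$n_desirable[out$counts$id == "S2"], 0L)
  expect_true(all(out$diplotypes$diplotype[out$diplotypes$id == "S2"] == "?/?"))
})
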