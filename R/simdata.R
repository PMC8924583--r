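# Gene-dropping simulator: founder haplotypes dropped through a multi-parental
# breeding pedigree under Haldane (no-interference) recombination, with
# two-year cracking/firmness phenotypes carrying planted haplotype effects.

# run code under a temporary RNG state so simulation calls are reproducible
# and never disturb the caller's stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulation configuration for a synthetic breeding germplasm
#'
#' Bundles every knob of the synthetic germplasm: the pedigree design
#' (ancestor founders, important breeding parents, cross list), the genetic
#' map (8 linkage groups, 1,617 SNPs by default), the planted QTLs
#' (haplotype-level additive effects keyed by the B allele of a focal SNP
#' inside a haploblock), and the phenotype model. Defaults emulate a
#' 259-seedling sweet cherry program: two subpopulations (A, n = 119;
#' B, n = 140) descending from 22 important breeding parents, cracking
#' incidence scored as percent of 50 soaked fruit in 2019 and 2020
#' (bounded, non-normal, between-year r about 0.6), and firmness in g/mm
#' (normal; subpopulation A measured 2012 + 2020, B 2019 + 2020, everyone
#' together in 2020, B about 49 g/mm firmer).
#'
#' @param seed Integer seed applied by the generator functions.
#' @param n_ancestors Count of unnamed generation-0 founders.
#' @param n_ibps Count of important breeding parents (default 22).
#' @param n_founder_ibps How many IBPs are themselves founders.
#' @param cross_design Tibble `mother, father, n_offspring, subpop`
#'   (self-crosses allowed). `NULL` uses the default 22-cross design
#'   producing 119 A and 140 B seedlings.
#' @param map_spec Tibble `linkage_group, length_cm, n_snps`.
#' @param block_size SNPs per haploblock (default 7, the worked-example
#'   block length).
#' @param qtl_specs Tibble `trait, linkage_group, pos_cm, ps_index, effect`:
#'   the planted QTLs. `effect` is the additive effect per B allele at the
#'   focal SNP, in trait units (g/mm for firmness, logit-liability units
#'   for cracking).
#' @param founder_freq B-allele frequency among founder gametes (scalar or
#'   per-SNP vector).
#' @param trait_means Named vector: `firmness` intercept in g/mm and
#'   `cracking` latent intercept on the logit scale.
#' @param year_effects List of named vectors of per-year shifts
#'   (trait units; logit units for cracking).
#' @param subpop_effects List of named vectors of per-subpopulation shifts.
#' @param polygenic_sd Named vector: SD of the individual polygenic value
#'   not attributable to the planted QTLs (drives between-year correlation).
#' @param residual_sd Within-individual, between-year residual SD for
#'   firmness (g/mm).
#' @param tree_liability_sd Tree-by-year SD on the logit liability scale for
#'   cracking.
#' @param fruits_per_tree Fruits scored per tree and year (default 50, so
#'   incidence has 2 percentage-point granularity).
#' @param missing_rate Fraction of dosage calls masked by [degrade()].
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_ancestors = 10L,
                       n_ibps = 22L,
                       n_founder_ibps = 8L,
                       cross_design = NULL,
                       map_spec = default_map_spec(),
                       block_size = 7L,
                       qtl_specs = default_qtl_specs(),
                       founder_freq = 0.5,
                       trait_means = c(firmness = 309, cracking = 0),
                       year_effects = list(
                         firmness = c("2012" = -20, "2019" = -10, "2020" = 0),
                         cracking = c("2019" = -0.12, "2020" = 0.45)
                       ),
                       subpop_effects = list(
                         firmness = c(A = -28, B = 21),
                         cracking = c(A = 0, B = 0)
                       ),
                       polygenic_sd = c(firmness = 44, cracking = 0.9),
                       residual_sd = 40,
                       tree_liability_sd = 0.7,
                       fruits_per_tree = 50L,
                       missing_rate = 0) {
  cfg <- list(
    seed = as.integer(seed),
    n_ancestors = as.integer(n_ancestors),
    n_ibps = as.integer(n_ibps),
    n_founder_ibps = as.integer(n_founder_ibps),
    cross_design = cross_design,
    map_spec = as_tibble(map_spec),
    block_size = as.integer(block_size),
    qtl_specs = as_tibble(qtl_specs),
    founder_freq = founder_freq,
    trait_means = trait_means,
    year_effects = year_effects,
    subpop_effects = subpop_effects,
    polygenic_sd = polygenic_sd,
    residual_sd = residual_sd,
    tree_liability_sd = tree_liability_sd,
    fruits_per_tree = as.integer(fruits_per_tree),
    missing_rate = missing_rate
  )
  if (cfg$n_ancestors < 1 || cfg$n_ibps < 1 || cfg$n_founder_ibps < 0 ||
      cfg$n_founder_ibps > cfg$n_ibps) {
    stop_bad_input("pedigree counts must be positive and consistent")
  }
  if (cfg$fruits_per_tree < 1) stop_bad_input("fruits_per_tree must be >= 1")
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    stop_bad_input("missing_rate must lie in [0, 1)")
  }
  if (cfg$residual_sd < 0 || cfg$tree_liability_sd < 0 ||
      any(cfg$polygenic_sd < 0)) {
    stop_bad_input("variance parameters must be non-negative")
  }
  if (is.null(cfg$cross_design)) cfg$cross_design <- default_cross_design(cfg)
  cfg$cross_design <- as_tibble(cfg$cross_design)
  structure(cfg, class = "sim_config")
}

#' @rdname sim_config
#' @export
default_map_spec <- function() {
  tibble(
    linkage_group = 1:8,
    length_cm = c(115, 80, 66, 55, 75, 60, 74, 62),
    n_snps = c(320L, 230L, 185L, 155L, 210L, 170L, 200L, 147L)
  )
}

#' @rdname sim_config
#' @export
default_qtl_specs <- function() {
  tibble(
    trait = c("cracking", "cracking", "firmness", "firmness"),
    linkage_group = c(1L, 5L, 1L, 3L),
    pos_cm = c(45, 47, 45, 50),
    ps_index = 4L,
    effect = c(0.45, -0.40, 30, 18)
  )
}

# 22 crosses among the IBPs (one Sweetheart-x-Sweetheart-style self),
# 119 subpopulation-A and 140 subpopulation-B seedlings
default_cross_design <- function(cfg) {
  p <- sprintf("P%02d", seq_len(cfg$n_ibps))
  a <- tibble(
    mother = p[c(1, 3, 5, 7, 9, 11, 1, 3, 5, 7)],
    father = p[c(2, 4, 6, 8, 10, 12, 9, 11, 10, 12)],
    n_offspring = c(rep(12L, 9), 11L),
    subpop = "A"
  )
  b <- tibble(
    mother = p[c(13, 15, 17, 18, 20, 22, 14, 15, 19, 20, 17, 13)],
    father = p[c(14, 16, 17, 19, 21, 13, 16, 18, 21, 22, 19, 16)],
    n_offspring = c(rep(12L, 11), 8L),
    subpop = "B"
  )
  bind_rows(a, b)
}

#' Build the synthetic pedigree
#'
#' Assembles ancestor founders, important breeding parents (IBPs; some are
#' founders, the rest offspring of the ancestors) and the seedlings of the
#' cross design, then validates the whole pedigree (acyclicity, parent
#' resolvability). Self-crosses (mother = father) are legitimate.
#'
#' @param config A [sim_config()].
#' @return A validated pedigree tibble (`id, mother, father, role, subpop`).
#' @export
build_pedigree <- function(config) {
  founders <- tibble(
    id = sprintf("F%02d", seq_len(config$n_ancestors)),
    mother = NA_character_, father = NA_character_,
    role = "founder", subpop = NA_character_
  )
  ibp_ids <- sprintf("P%02d", seq_len(config$n_ibps))
  n_derived <- config$n_ibps - config$n_founder_ibps
  # deterministic ancestor pairings for the non-founder IBPs
  anc <- founders$id
  pair_idx <- cbind(
    ((seq_len(n_derived) - 1L) %% length(anc)) + 1L,
    ((seq_len(n_derived) * 3L) %% length(anc)) + 1L
  )
  pair_idx[pair_idx[, 1] == pair_idx[, 2], 2] <-
    (pair_idx[pair_idx[, 1] == pair_idx[, 2], 2] %% length(anc)) + 1L
  ibps <- tibble(
    id = ibp_ids,
    mother = c(rep(NA_character_, config$n_founder_ibps), anc[pair_idx[, 1]]),
    father = c(rep(NA_character_, config$n_founder_ibps), anc[pair_idx[, 2]]),
    role = "IBP", subpop = NA_character_
  )
  cd <- config$cross_design
  declared <- c(founders$id, ibps$id)
  undeclared <- setdiff(c(cd$mother, cd$father), declared)
  if (length(undeclared)) {
    stop_bad_input(paste0("cross design references undeclared parent(s): ",
                          paste(head(undeclared, 5), collapse = ", ")))
  }
  if (any(cd$n_offspring < 1)) stop_bad_input("n_offspring must be positive")
  seedlings <- tibble(
    id = sprintf("S%03d", seq_len(sum(cd$n_offspring))),
    mother = rep(cd$mother, cd$n_offspring),
    father = rep(cd$father, cd$n_offspring),
    role = "seedling",
    subpop = rep(cd$subpop, cd$n_offspring)
  )
  validate_pedigree(bind_rows(founders, ibps, seedlings))
}

#' Build the synthetic genetic map and haploblocks
#'
#' SNPs are evenly spaced per linkage group; physical positions follow a
#' fixed 0.33 Mbp/cM scaling. Haploblocks are consecutive runs of
#' `block_size` adjacent SNPs.
#'
#' @param config A [sim_config()].
#' @return `make_marker_map()`: a marker-map tibble;
#'   `make_haploblocks()`: a haploblock tibble with cM spans.
#' @export
make_marker_map <- function(config) {
  ms <- config$map_spec
  rows <- pmap(ms, function(linkage_group, length_cm, n_snps) {
    pos <- seq(0, length_cm, length.out = n_snps)
    tibble(
      snp_id = sprintf("ss%d_%04d", linkage_group, seq_len(n_snps)),
      linkage_group = as.integer(linkage_group),
      genetic_pos = round(pos, 4),
      physical_pos = round(pos * 0.33, 4)
    )
  })
  validate_marker_map(list_rbind(rows))
}

#' @rdname make_marker_map
#' @param map Marker map from [make_marker_map()].
#' @export
make_haploblocks <- function(map, config) {
  bs <- config$block_size
  rows <- map |>
    group_by(.data$linkage_group) |>
    group_map(function(d, key) {
      lg <- key$linkage_group
      chunk <- ceiling(seq_len(nrow(d)) / bs)
      tibble(
        block_id = sprintf("HB%d_%03d", lg, unique(chunk)),
        linkage_group = lg,
        snp_ids = unname(split(d$snp_id, chunk))
      )
    })
  validate_haploblocks(list_rbind(rows), map)
}

#' Simulate phased founder genomes
#'
#' Each founder (pedigree individual with both parents unknown) receives
#' two gametes drawn SNP-wise Bernoulli with the configured B-allele
#' frequency, independent across loci (no founder linkage disequilibrium).
#' Every founder gamete gets a unique integer strand id, the ground-truth
#' currency for descent tracking.
#'
#' @param pedigree Validated pedigree.
#' @param map Marker map.
#' @param founder_freq Scalar or per-SNP B-allele frequency.
#' @param seed Integer seed.
#' @return A `phased_snps` object: matrices `h1`, `h2` (alleles `"A"/"B"`),
#'   `org1`, `org2` (founder strand ids), and `strand_owner` mapping strand
#'   id to founder id.
#' @export
simulate_founders <- function(pedigree, map, founder_freq = 0.5, seed = 1L) {
  if (nrow(map) == 0) stop_bad_input("marker map is empty")
  founders <- pedigree$id[is.na(pedigree$mother) & is.na(pedigree$father)]
  if (length(founders) == 0) stop_bad_input("pedigree has no founders")
  n <- length(founders); m <- nrow(map)
  freq <- rep(founder_freq, length.out = m)
  if (any(freq < 0 | freq > 1)) stop_bad_input("founder_freq must lie in [0, 1]")
  with_seed(seed, {
    draw <- function() {
      x <- matrix(rbinom(n * m, 1L, rep(freq, each = n)), nrow = n)
      matrix(c("A", "B")[x + 1L], nrow = n,
             dimnames = list(founders, map$snp_id))
    }
    h1 <- draw(); h2 <- draw()
  })
  org1 <- matrix(rep(2L * seq_len(n) - 1L, m), nrow = n,
                 dimnames = list(founders, map$snp_id))
  org2 <- org1 + 1L
  structure(
    list(h1 = h1, h2 = h2, org1 = org1, org2 = org2,
         strand_owner = setNames(rep(founders, each = 2),
                                 as.character(seq_len(2L * n)))),
    class = "phased_snps"
  )
}

# one gamete from a phased parent row; Haldane model: crossover count
# Poisson(length/100) per linkage group, positions uniform on the cM scale
make_gamete <- function(h1, h2, o1, o2, lg_split) {
  g_h <- character(length(h1)); g_o <- integer(length(o1))
  trans <- vector("list", length(lg_split))
  for (k in seq_along(lg_split)) {
    idx <- lg_split[[k]]$idx
    pos <- lg_split[[k]]$pos
    len <- lg_split[[k]]$len
    n_cross <- rpois(1L, len / 100)
    start <- sample.int(2L, 1L)
    if (n_cross == 0) {
      strand <- rep(start, length(idx))
      breaks <- numeric(0)
    } else {
      breaks <- sort(runif(n_cross, 0, len))
      strand <- ((start - 1L + findInterval(pos, breaks)) %% 2L) + 1L
    }
    pick1 <- strand == 1L
    g_h[idx] <- ifelse(pick1, h1[idx], h2[idx])
    g_o[idx] <- ifelse(pick1, o1[idx], o2[idx])
    trans[[k]] <- list(start = start, breaks = breaks)
  }
  list(h = g_h, o = g_o, trans = trans)
}

#' Drop founder gametes through the pedigree
#'
#' Processes non-founders parents-first; each inherits one recombinant
#' gamete per parent under the Haldane no-interference model (crossovers a
#' Poisson process on the cM scale, so the recombinant fraction between two
#' loci d cM apart is (1 - exp(-2d/100))/2). `h1`/`org1` hold the maternal
#' gamete, `h2`/`org2` the paternal one. Every transmission (crossover
#' count, breakpoints, starting strand) is recorded as ground truth.
#'
#' @param pedigree Validated pedigree.
#' @param founders `phased_snps` from [simulate_founders()].
#' @param map Marker map.
#' @param seed Integer seed.
#' @return List with `phased` (a `phased_snps` over all individuals) and
#'   `transmissions` (tibble `id, side, linkage_group, n_crossovers,
#'   breakpoints, start_strand`).
#' @export
drop_gametes <- function(pedigree, founders, map, seed = 1L) {
  ord <- attr(validate_pedigree(pedigree), "topo_order")
  n <- nrow(pedigree); m <- nrow(map)
  ids <- pedigree$id
  h1 <- matrix(NA_character_, n, m, dimnames = list(ids, map$snp_id))
  h2 <- h1
  org1 <- matrix(NA_integer_, n, m, dimnames = list(ids, map$snp_id))
  org2 <- org1
  fnd <- rownames(founders$h1)
  h1[fnd, ] <- founders$h1; h2[fnd, ] <- founders$h2
  org1[fnd, ] <- founders$org1; org2[fnd, ] <- founders$org2
  lgs <- sort(unique(map$linkage_group))
  lg_split <- map(lgs, function(g) {
    idx <- which(map$linkage_group == g)
    list(idx = idx, pos = map$genetic_pos[idx], len = max(map$genetic_pos[idx]))
  })
  parent_of <- setNames(seq_len(n), ids)
  mothers <- setNames(pedigree$mother, ids)
  fathers <- setNames(pedigree$father, ids)
  trans_rows <- list()
  with_seed(seed, {
    for (id in ord) {
      mo <- mothers[[id]]; fa <- fathers[[id]]
      if (is.na(mo) && is.na(fa)) next
      if (is.na(mo) != is.na(fa)) {
        stop_bad_input(paste0("individual ", id, " has exactly one known parent; ",
                              "declare both or neither"))
      }
      for (side in c("mother", "father")) {
        p <- if (side == "mother") mo else fa
        if (anyNA(h1[p, ])) {
          abort(paste0("parent ", p, " is not phased before offspring ", id),
                class = "cherryhap_input_error")
        }
        gam <- make_gamete(h1[p, ], h2[p, ], org1[p, ], org2[p, ], lg_split)
        if (side == "mother") {
          h1[id, ] <- gam$h; org1[id, ] <- gam$o
        } else {
          h2[id, ] <- gam$h; org2[id, ] <- gam$o
        }
        trans_rows[[length(trans_rows) + 1L]] <- tibble(
          id = id, side = side, linkage_group = lgs,
          n_crossovers = map_int(gam$trans, function(t) length(t$breaks)),
          breakpoints = map(gam$trans, "breaks"),
          start_strand = map_int(gam$trans, "start")
        )
      }
    }
  })
  phased <- structure(
    list(h1 = h1, h2 = h2, org1 = org1, org2 = org2,
         strand_owner = founders$strand_owner),
    class = "phased_snps"
  )
  list(phased = phased, transmissions = list_rbind(trans_rows))
}

# resolve planted QTL specs against the realized map/haploblocks:
# each spec picks the haploblock on its LG whose span contains pos_cm
# (nearest otherwise) and the member SNP at ps_index
resolve_qtl_specs <- function(qtl_specs, map, blocks) {
  pos <- setNames(map$genetic_pos, map$snp_id)
  rows <- pmap(qtl_specs, function(trait, linkage_group, pos_cm, ps_index, effect) {
    cand <- blocks[blocks$linkage_group == linkage_group, ]
    if (nrow(cand) == 0) {
      stop_bad_input(paste0("no haploblock on linkage group ", linkage_group))
    }
    inside <- cand$start_cm <= pos_cm & cand$end_cm >= pos_cm
    pick <- if (any(inside)) which(inside)[1] else {
      which.min(pmin(abs(cand$start_cm - pos_cm), abs(cand$end_cm - pos_cm)))
    }
    snps <- cand$snp_ids[[pick]]
    idx <- min(ps_index, length(snps))
    tibble(trait = trait, linkage_group = linkage_group,
           block_id = cand$block_id[pick], ps_snp = snps[idx],
           ps_index = idx, pos_cm = unname(pos[snps[idx]]), effect = effect)
  })
  list_rbind(rows)
}

#' Simulate two-year cracking and firmness phenotypes
#'
#' Firmness (g/mm): intercept + year + subpopulation + planted QTL effects
#' + polygenic value + N(0, residual_sd), per seedling and year (A measured
#' 2012 + 2020, B 2019 + 2020). Cracking: a logit-scale liability
#' (intercept + year + QTL + polygenic + tree-by-year N(0,
#' tree_liability_sd)) converted to a probability, then scored as
#' 100 x Binomial(fruits_per_tree, p)/fruits_per_tree in 2019 and 2020, so
#' values are multiples of 100/fruits_per_tree in \[0, 100\].
#'
#' @param phased `phased_snps` over all individuals.
#' @param pedigree Validated pedigree (phenotypes are generated for
#'   seedlings).
#' @param map,blocks Map and haploblocks matching `phased`.
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return List: `phenotypes` (long tibble), `truth` with `qtl` (resolved
#'   planted QTLs) and `genetic_values` (per individual x trait planted-QTL
#'   plus polygenic values, trait/latent units).
#' @export
simulate_phenotypes <- function(phased, pedigree, map, blocks, config, seed = 1L) {
  qtl <- resolve_qtl_specs(config$qtl_specs, map, blocks)
  ids <- rownames(phased$h1)
  n_b <- function(snp) {
    (phased$h1[, snp] == "B") + (phased$h2[, snp] == "B")
  }
  gv <- sapply(c("firmness", "cracking"), function(tr) {
    q <- qtl[qtl$trait == tr, ]
    if (nrow(q) == 0) return(rep(0, length(ids)))
    Reduce(`+`, pmap(q, function(ps_snp, effect, ...) effect * n_b(ps_snp)))
  })
  rownames(gv) <- ids
  seedlings <- pedigree[pedigree$role %in% "seedling", ]
  with_seed(seed, {
    poly <- sapply(c("firmness", "cracking"), function(tr) {
      rnorm(length(ids), 0, config$polygenic_sd[[tr]])
    })
    rownames(poly) <- ids
    total_gv <- gv + poly
    rows <- list()
    for (i in seq_len(nrow(seedlings))) {
      id <- seedlings$id[i]; sp <- seedlings$subpop[i]
      firm_years <- if (identical(sp, "A")) c(2012L, 2020L) else c(2019L, 2020L)
      for (y in firm_years) {
        mu <- config$trait_means[["firmness"]] +
          config$year_effects$firmness[[as.character(y)]] +
          config$subpop_effects$firmness[[sp]] +
          total_gv[id, "firmness"]
        rows[[length(rows) + 1L]] <- tibble(
          id = id, trait = "firmness", year = y,
          value = max(round(rnorm(1, mu, config$residual_sd), 2), 1)
        )
      }
      for (y in c(2019L, 2020L)) {
        lat <- config$trait_means[["cracking"]] +
          config$year_effects$cracking[[as.character(y)]] +
          config$subpop_effects$cracking[[sp]] +
          total_gv[id, "cracking"] +
          rnorm(1, 0, config$tree_liability_sd)
        k <- rbinom(1, config$fruits_per_tree, plogis(lat))
        rows[[length(rows) + 1L]] <- tibble(
          id = id, trait = "cracking", year = y,
          value = 100 * k / config$fruits_per_tree
        )
      }
    }
  })
  gv_long <- bind_rows(
    tibble(id = ids, trait = "firmness", value = unname(total_gv[, "firmness"])),
    tibble(id = ids, trait = "cracking", value = unname(total_gv[, "cracking"]))
  )
  list(phenotypes = validate_phenotypes(list_rbind(rows)),
       truth = list(qtl = qtl, genetic_values = gv_long))
}

#' Unphase a simulated genome into a dosage matrix with missingness
#'
#' @param phased `phased_snps`.
#' @param missing_rate Fraction of calls masked, in \[0, 1).
#' @param seed Integer seed.
#' @return Integer dosage matrix (individuals x SNPs, `NA` missing).
#' @export
degrade <- function(phased, missing_rate = 0, seed = 1L) {
  if (missing_rate < 0 || missing_rate >= 1) {
    stop_bad_input("missing_rate must lie in [0, 1)")
  }
  geno <- (phased$h1 == "B") + (phased$h2 == "B")
  storage.mode(geno) <- "integer"
  if (missing_rate > 0) {
    with_seed(seed, {
      mask <- matrix(runif(length(geno)) < missing_rate, nrow = nrow(geno))
    })
    geno[mask] <- NA_integer_
  }
  geno
}

#' @rdname degrade
#' @description `degrade_phased()` masks individual alleles of the phased
#'   strings (to `"-"`) instead, exercising the parent-guided phasing and
#'   imputed-origin pathways downstream.
#' @export
degrade_phased <- function(phased, missing_rate = 0, seed = 1L) {
  if (missing_rate < 0 || missing_rate >= 1) {
    stop_bad_input("missing_rate must lie in [0, 1)")
  }
  if (missing_rate > 0) {
    with_seed(seed, {
      for (h in c("h1", "h2")) {
        mask <- matrix(runif(length(phased[[h]])) < missing_rate,
                       nrow = nrow(phased[[h]]))
        phased[[h]][mask] <- "-"
      }
    })
  }
  phased
}

#' Collapse SNP-level phase to per-haploblock allele strings
#'
#' @param phased `phased_snps`.
#' @param blocks Haploblock tibble.
#' @param ids Optional subset of individuals.
#' @return Tibble `id, block_id, hap1, hap2, origin1, origin2` with hap1
#'   the maternal string for non-founders.
#' @export
phased_to_blocks <- function(phased, blocks, ids = NULL) {
  if (is.null(ids)) ids <- rownames(phased$h1)
  rows <- map(seq_len(nrow(blocks)), function(i) {
    snps <- blocks$snp_ids[[i]]
    tibble(
      id = ids,
      block_id = blocks$block_id[i],
      hap1 = apply(phased$h1[ids, snps, drop = FALSE], 1, paste, collapse = ""),
      hap2 = apply(phased$h2[ids, snps, drop = FALSE], 1, paste, collapse = ""),
      origin1 = "maternal", origin2 = "paternal"
    )
  })
  validate_phased(list_rbind(rows))
}

#' Generate a complete synthetic germplasm
#'
#' One-call orchestrator: pedigree, map, haploblocks, founder genomes,
#' gene-dropped phase, dosage matrix, two-year phenotypes and the full
#' ground truth. Identical seeds give bit-identical output.
#'
#' @param seed Integer seed (also used for the sub-stage seeds).
#' @param config A [sim_config()]; defaults to `sim_config(seed)`.
#' @return List: `config`, `pedigree`, `map`, `blocks`, `phased`,
#'   `genotypes`, `phenotypes`, `truth` (`transmissions`, `qtl`,
#'   `genetic_values`, `strand_owner`).
#' @export
sim_germplasm <- function(seed = 1L, config = NULL) {
  if (is.null(config)) config <- sim_config(seed = seed)
  pedigree <- build_pedigree(config)
  map <- make_marker_map(config)
  blocks <- make_haploblocks(map, config)
  founders <- simulate_founders(pedigree, map, config$founder_freq,
                                seed = config$seed)
  drop <- drop_gametes(pedigree, founders, map, seed = config$seed + 1L)
  phe <- simulate_phenotypes(drop$phased, pedigree, map, blocks, config,
                             seed = config$seed + 2L)
  geno <- degrade(drop$phased, config$missing_rate, seed = config$seed + 3L)
  list(
    config = config, pedigree = pedigree, map = map, blocks = blocks,
    phased = drop$phased, genotypes = geno, phenotypes = phe$phenotypes,
    truth = list(transmissions = drop$transmissions, qtl = phe$truth$qtl,
                 genetic_values = phe$truth$genetic_values,
                 strand_owner = drop$phased$strand_owner)
  )
}

#' Write a simulated germplasm to interchange files
#'
#' Emits pedigree CSV, genotype CSV, minimal VCF (phased GT), map TSV,
#' haploblock TSV, phenotype CSV and phased-haplotype TSV under `dir`.
#'
#' @param sim Result of [sim_germplasm()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_germplasm <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    pedigree = file.path(dir, "pedigree.csv"),
    genotypes = file.path(dir, "genotypes.csv"),
    vcf = file.path(dir, "genotypes.vcf"),
    map = file.path(dir, "map.tsv"),
    blocks = file.path(dir, "haploblocks.tsv"),
    phenotypes = file.path(dir, "phenotypes.csv"),
    phased = file.path(dir, "phased.tsv")
  )
  write_pedigree(sim$pedigree, paths[["pedigree"]])
  write_genotypes(sim$genotypes, paths[["genotypes"]])
  gt <- matrix(paste0(ifelse(sim$phased$h1 == "B", "1", "0"), "|",
                      ifelse(sim$phased$h2 == "B", "1", "0")),
               nrow = nrow(sim$phased$h1), dimnames = dimnames(sim$phased$h1))
  gt[is.na(sim$genotypes)] <- "./."
  write_vcf(sim$genotypes, sim$map, paths[["vcf"]], gt = gt)
  write_marker_map(sim$map, paths[["map"]])
  write_haploblocks(sim$blocks, paths[["blocks"]])
  write_phenotypes(sim$phenotypes, paths[["phenotypes"]])
  write_phased(phased_to_blocks(sim$phased, sim$blocks), paths[["phased"]])
  invisible(paths)
}
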