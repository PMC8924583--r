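#' Read and validate a pedigree table
#'
#' The pedigree CSV has columns `id, mother, father, role, subpop`, one row
#' per individual. Unknown parents are written `NA` and are preserved as
#' unknown (never dropped); explicit placeholder ancestors (e.g.
#' `Unknown_Parent_of_X` rows with both parents `NA`) are ordinary nodes.
#' `role` is one of `founder`, `IBP`, `seedling`; `subpop` labels the
#' subpopulation (e.g. `A`/`B`) and may be `NA` for ancestors.
#'
#' @param path Path to a pedigree CSV with header.
#' @return A tibble with columns `id`, `mother`, `father`, `role`, `subpop`,
#'   validated (unique ids, parents resolvable or unknown, acyclic).
#' @export
read_pedigree <- function(path) {
  ped <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  validate_pedigree(as_tibble(ped))
}

#' Write a pedigree table
#'
#' @param pedigree A pedigree tibble as returned by [read_pedigree()] or
#'   [build_pedigree()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(pedigree, path) {
  pedigree <- validate_pedigree(pedigree)
  readr::write_csv(pedigree, path, na = "NA")
  invisible(path)
}

#' Validate a pedigree tibble
#'
#' Checks id uniqueness, parent resolvability and acyclicity, and returns
#' the table with a topological-order attribute (`"topo_order"`, parents
#' before offspring).
#'
#' @param pedigree Tibble with columns `id`, `mother`, `father` and
#'   optionally `role`, `subpop`.
#' @return The validated tibble.
#' @export
validate_pedigree <- function(pedigree) {
  need <- c("id", "mother", "father")
  if (!all(need %in% names(pedigree))) {
    stop_bad_input("pedigree must have columns id, mother, father")
  }
  if (!"role" %in% names(pedigree)) pedigree$role <- NA_character_
  if (!"subpop" %in% names(pedigree)) pedigree$subpop <- NA_character_
  pedigree <- select(pedigree, "id", "mother", "father", "role", "subpop")
  if (anyNA(pedigree$id)) stop_bad_input("pedigree ids must be non-missing")
  if (anyDuplicated(pedigree$id)) {
    stop_bad_input(paste0("duplicate pedigree id: ",
                          pedigree$id[duplicated(pedigree$id)][1]))
  }
  for (side in c("mother", "father")) {
    p <- pedigree[[side]]
    bad <- !is.na(p) & !(p %in% pedigree$id)
    if (any(bad)) {
      stop_bad_input(paste0(side, " '", p[bad][1], "' of '",
                            pedigree$id[bad][1], "' is not a pedigree individual"))
    }
  }
  attr(pedigree, "topo_order") <- pedigree_topo_order(pedigree)
  pedigree
}

# Kahn's algorithm; errors on cycles (an individual cannot be its own ancestor)
pedigree_topo_order <- function(pedigree) {
  ids <- pedigree$id
  parents <- map2(pedigree$mother, pedigree$father, function(m, f) {
    stats::na.omit(unique(c(m, f)))
  })
  names(parents) <- ids
  placed <- character(0)
  remaining <- ids
  while (length(remaining) > 0) {
    ready <- remaining[map_int(parents[remaining], function(p) {
      sum(!(p %in% placed))
    }) == 0]
    if (length(ready) == 0) {
      stop_bad_input(paste0("pedigree cycle detected involving: ",
                            paste(head(remaining, 5), collapse = ", ")))
    }
    placed <- c(placed, ready)
    remaining <- setdiff(remaining, ready)
  }
  placed
}

#' Read a genetic marker map
#'
#' Tab-separated with columns `snp_id, linkage_group, genetic_pos,
#' physical_pos` (cM and Mbp respectively).
#'
#' @param path Path to the map TSV.
#' @return A tibble sorted by linkage group and genetic position.
#' @export
read_marker_map <- function(path) {
  m <- readr::read_tsv(path, col_types = readr::cols(
    snp_id = readr::col_character(),
    linkage_group = readr::col_integer(),
    genetic_pos = readr::col_double(),
    physical_pos = readr::col_double()
  ))
  validate_marker_map(as_tibble(m))
}

#' @rdname read_marker_map
#' @param map A marker-map tibble.
#' @export
write_marker_map <- function(map, path) {
  map <- validate_marker_map(map)
  readr::write_tsv(map, path, na = "NA")
  invisible(path)
}

#' @rdname read_marker_map
#' @export
validate_marker_map <- function(map) {
  need <- c("snp_id", "linkage_group", "genetic_pos", "physical_pos")
  if (!all(need %in% names(map))) {
    stop_bad_input("marker map needs columns snp_id, linkage_group, genetic_pos, physical_pos")
  }
  if (anyDuplicated(map$snp_id)) stop_bad_input("duplicate snp_id in marker map")
  if (any(!is.finite(map$genetic_pos)) || any(!is.finite(map$physical_pos)) ||
      any(map$genetic_pos < 0) || any(map$physical_pos < 0)) {
    stop_bad_input("map coordinates must be finite and non-negative")
  }
  arrange(as_tibble(map[need]), .data$linkage_group, .data$genetic_pos)
}

#' Read haploblock definitions
#'
#' Tab-separated with columns `block_id, linkage_group, snp_ids`, the last a
#' comma-separated ordered list of member SNPs. Haploblocks are sets of
#' adjacent SNPs with no known historic recombination, treated as multi-SNP
#' alleles.
#'
#' @param path Path to the haploblock TSV.
#' @param map Optional marker map; when given, membership and ordering are
#'   validated against it and the cM span is attached.
#' @return Tibble with columns `block_id`, `linkage_group`, `snp_ids`
#'   (list-column) and, when `map` is given, `start_cm`, `end_cm`.
#' @export
read_haploblocks <- function(path, map = NULL) {
  b <- readr::read_tsv(path, col_types = readr::cols(
    block_id = readr::col_character(),
    linkage_group = readr::col_integer(),
    snp_ids = readr::col_character()
  ))
  b <- as_tibble(b)
  b$snp_ids <- stringr::str_split(b$snp_ids, stringr::fixed(","))
  validate_haploblocks(b, map)
}

#' @rdname read_haploblocks
#' @param blocks A haploblock tibble (list-column `snp_ids`).
#' @export
write_haploblocks <- function(blocks, path) {
  out <- tibble(
    block_id = blocks$block_id,
    linkage_group = blocks$linkage_group,
    snp_ids = map_chr(blocks$snp_ids, paste, collapse = ",")
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname read_haploblocks
#' @export
validate_haploblocks <- function(blocks, map = NULL) {
  if (anyDuplicated(blocks$block_id)) stop_bad_input("duplicate block_id")
  if (any(lengths(blocks$snp_ids) == 0)) stop_bad_input("empty haploblock")
  if (anyDuplicated(unlist(blocks$snp_ids))) {
    stop_bad_input("a SNP belongs to more than one haploblock")
  }
  if (!is.null(map)) {
    pos <- setNames(map$genetic_pos, map$snp_id)
    lg <- setNames(map$linkage_group, map$snp_id)
    for (i in seq_len(nrow(blocks))) {
      ids <- blocks$snp_ids[[i]]
      if (!all(ids %in% map$snp_id)) {
        stop_bad_input(paste0("haploblock ", blocks$block_id[i],
                              " references SNPs absent from the map"))
      }
      if (!all(lg[ids] == blocks$linkage_group[i])) {
        stop_bad_input(paste0("haploblock ", blocks$block_id[i],
                              " mixes linkage groups"))
      }
      if (is.unsorted(pos[ids])) {
        stop_bad_input(paste0("haploblock ", blocks$block_id[i],
                              " SNPs are not ordered by genetic position"))
      }
    }
    blocks$start_cm <- map_dbl(blocks$snp_ids, function(ids) min(pos[ids]))
    blocks$end_cm <- map_dbl(blocks$snp_ids, function(ids) max(pos[ids]))
  }
  as_tibble(blocks)
}

#' Read a genotype dosage matrix
#'
#' Dosages count copies of the B allele (0, 1, 2; `NA` missing). The CSV
#' layout is one row per individual: an `id` column followed by one column
#' per SNP. VCF input (4.2 minimal subset: CHROM, POS, ID, REF, ALT, GT) is
#' parsed with \pkg{vcfR}; `./.` becomes missing and phase separators are
#' retained in the `"gt"` attribute for downstream phasing seeds.
#'
#' @param path Input file.
#' @param format `"csv"` or `"vcf"`.
#' @param map Marker map; SNPs absent from the map are dropped with a
#'   message, never silently.
#' @return Integer matrix individuals x SNPs with `dimnames`; VCF input also
#'   carries attribute `"gt"` (raw GT strings).
#' @export
read_genotypes <- function(path, format = c("csv", "vcf"), map = NULL) {
  format <- match.arg(format)
  if (format == "csv") {
    g <- readr::read_csv(path, col_types = readr::cols(
      id = readr::col_character(), .default = readr::col_integer()
    ))
    geno <- as.matrix(g[setdiff(names(g), "id")])
    storage.mode(geno) <- "integer"
    rownames(geno) <- g$id
  } else {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")  # SNPs x individuals
    gt <- t(gt)
    alleles <- gsub("[|/]", "", gt)
    dose <- stringr::str_count(alleles, "1")
    dose[!grepl("^[01][|/][01]$", gt)] <- NA_integer_
    geno <- matrix(as.integer(dose), nrow = nrow(gt), dimnames = dimnames(gt))
    attr(geno, "gt") <- gt
  }
  validate_genotypes(geno, map)
}

#' @rdname read_genotypes
#' @param geno Dosage matrix (individuals x SNPs).
#' @export
write_genotypes <- function(geno, path) {
  out <- as_tibble(as.data.frame(geno, check.names = FALSE))
  out <- bind_cols(tibble(id = rownames(geno)), out)
  readr::write_csv(out, path, na = "NA")
  invisible(path)
}

#' @rdname read_genotypes
#' @export
validate_genotypes <- function(geno, map = NULL) {
  if (is.null(rownames(geno)) || is.null(colnames(geno))) {
    stop_bad_input("genotype matrix needs individual rownames and SNP colnames")
  }
  if (anyDuplicated(rownames(geno))) stop_bad_input("duplicate individual in genotypes")
  if (anyDuplicated(colnames(geno))) stop_bad_input("duplicate SNP in genotypes")
  vals <- geno[!is.na(geno)]
  if (length(vals) && !all(vals %in% 0:2)) {
    stop_bad_input("dosages must be 0, 1, 2 or missing")
  }
  if (!is.null(map)) {
    keep <- colnames(geno) %in% map$snp_id
    if (!all(keep)) {
      inform(paste0("dropping ", sum(!keep), " SNP(s) absent from the marker map"))
      gt <- attr(geno, "gt")
      geno <- geno[, keep, drop = FALSE]
      if (!is.null(gt)) attr(geno, "gt") <- gt[, keep, drop = FALSE]
    }
  }
  geno
}

#' Write a minimal VCF for a dosage matrix
#'
#' Emits the VCF 4.2 subset used throughout (CHROM = linkage group,
#' POS = physical position in bp, REF = A, ALT = B, GT only). When `gt` is
#' supplied (a character matrix of GT strings, individuals x SNPs) it is
#' written verbatim, preserving phase (`0|1`); otherwise unphased GT is
#' derived from dosages (`./.` for missing).
#'
#' @inheritParams write_genotypes
#' @param map Marker map covering the matrix columns.
#' @param gt Optional GT string matrix.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(geno, map, path, gt = NULL) {
  map <- validate_marker_map(map)
  map <- map[match(colnames(geno), map$snp_id), ]
  if (anyNA(map$snp_id)) stop_bad_input("all genotype SNPs must be on the map")
  if (is.null(gt)) {
    gt <- matrix(c("0/0", "0/1", "1/1")[geno + 1L], nrow = nrow(geno),
                 dimnames = dimnames(geno))
    gt[is.na(geno)] <- "./."
  }
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(geno)), collapse = "\t")
  )
  body <- vapply(seq_len(ncol(geno)), function(j) {
    paste(c(map$linkage_group[j],
            format(round(map$physical_pos[j] * 1e6), scientific = FALSE),
            map$snp_id[j], "A", "B", ".", "PASS", ".", "GT", gt[, j]),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read and write long-format phenotype tables
#'
#' Columns `id, trait, year, value`; traits are `cracking` (% incidence in
#' \[0, 100\]) and `firmness` (g/mm, positive). At most one record per
#' (individual, trait, year).
#'
#' @param path CSV path.
#' @return A validated tibble.
#' @export
read_phenotypes <- function(path) {
  p <- readr::read_csv(path, col_types = readr::cols(
    id = readr::col_character(),
    trait = readr::col_character(),
    year = readr::col_integer(),
    value = readr::col_double()
  ))
  validate_phenotypes(as_tibble(p))
}

#' @rdname read_phenotypes
#' @param pheno Phenotype tibble.
#' @export
write_phenotypes <- function(pheno, path) {
  pheno <- validate_phenotypes(pheno)
  readr::write_csv(pheno, path, na = "NA")
  invisible(path)
}

#' @rdname read_phenotypes
#' @export
validate_phenotypes <- function(pheno) {
  need <- c("id", "trait", "year", "value")
  if (!all(need %in% names(pheno))) {
    stop_bad_input("phenotypes need columns id, trait, year, value")
  }
  pheno <- as_tibble(pheno[need])
  if (anyDuplicated(pheno[c("id", "trait", "year")])) {
    stop_bad_input("duplicate (id, trait, year) phenotype record")
  }
  crack <- pheno$value[pheno$trait == "cracking"]
  if (any(!is.na(crack) & (crack < 0 | crack > 100))) {
    stop_bad_input("cracking incidence must lie in [0, 100]")
  }
  firm <- pheno$value[pheno$trait == "firmness"]
  if (any(!is.na(firm) & firm <= 0)) {
    stop_bad_input("firmness must be positive")
  }
  pheno
}

#' Read and write phased haploblock genotypes
#'
#' Tab-separated with columns `id, block_id, hap1, hap2` and optional
#' `origin1, origin2` (maternal/paternal/unknown). Haplotypes are allele
#' strings over `A`, `B`, `-` (missing), one character per member SNP.
#'
#' @param path TSV path.
#' @return A validated tibble.
#' @export
read_phased <- function(path) {
  p <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  validate_phased(as_tibble(p))
}

#' @rdname read_phased
#' @param phased Phased tibble.
#' @export
write_phased <- function(phased, path) {
  phased <- validate_phased(phased)
  readr::write_tsv(phased, path, na = "NA")
  invisible(path)
}

#' @rdname read_phased
#' @export
validate_phased <- function(phased) {
  need <- c("id", "block_id", "hap1", "hap2")
  if (!all(need %in% names(phased))) {
    stop_bad_input("phased table needs columns id, block_id, hap1, hap2")
  }
  for (h in c("hap1", "hap2")) {
    bad <- grepl("[^AB-]", phased[[h]])
    if (any(bad)) stop_bad_input("haplotype strings may only contain A, B, -")
  }
  if (any(nchar(phased$hap1) != nchar(phased$hap2))) {
    stop_bad_input("hap1 and hap2 must have equal length within a record")
  }
  if (!"origin1" %in% names(phased)) phased$origin1 <- NA_character_
  if (!"origin2" %in% names(phased)) phased$origin2 <- NA_character_
  as_tibble(phased[c(need, "origin1", "origin2")])
}

#' QTL detections for cracking and firmness in a sweet cherry breeding
#' population
#'
#' A transcription of the QTL detection table for fruit cracking incidence
#' and fruit firmness in a 259-seedling sweet cherry breeding germplasm:
#' one row per (dataset, method, linkage-group) detection, where `method`
#' is `pba` (pedigree-based Bayesian analysis: cM interval, peak, PVE
#' weighted by QTL probability) or `blink` (iterative fixed-effects GWAS:
#' peak SNP, its position, adjusted-r2 PVE). `dataset` is `2019`, `2020`
#' or `multiyear` (two-year BLUP). PVE is in percent. Entries printed as
#' "<0.1" are stored as 0.1.
#'
#' @return A tibble with columns `trait`, `dataset`, `method`,
#'   `linkage_group`, `interval_start`, `interval_end`, `peak_cm`,
#'   `snp_id`, `snp_cm`, `snp_mbp`, `pve`.
#' @export
cherry_qtl_detections <- function() {
  path <- system.file("extdata", "cherry_qtl_detections.tsv",
                      package = "cherryhap", mustWork = TRUE)
  readr::read_tsv(path, col_types = readr::cols(
    trait = readr::col_character(),
    dataset = readr::col_character(),
    method = readr::col_character(),
    linkage_group = readr::col_integer(),
    interval_start = readr::col_double(),
    interval_end = readr::col_double(),
    peak_cm = readr::col_double(),
    snp_id = readr::col_character(),
    snp_cm = readr::col_double(),
    snp_mbp = readr::col_double(),
    pve = readr::col_double()
  ))
}
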