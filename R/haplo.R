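# Primary-SNP-guided haplotype analysis at QTL haploblocks: PS designation,
# recombinant classification by the PS allele, parent-guided phasing,
# haplotype effect estimation and relational functional-class assignment.

#' Designate the primary SNP of a QTL
#'
#' The primary SNP (PS) is chosen among scan SNPs that are (1) Bonferroni
#' significant, (2) housed in a haploblock on the QTL's linkage group whose
#' start or end lies less than `max_dist_cm` from the QTL peak, and (3) of
#' maximal single-SNP PVE among qualifiers. Ties break to the smallest
#' genetic position.
#'
#' @param scan A `cherry_scan` tibble (from [blink_scan()]).
#' @param qtl One QTL record: a list/one-row tibble with `name`,
#'   `linkage_group` and `peak_cm`.
#' @param blocks Haploblock tibble with cM spans (see [read_haploblocks()]).
#' @param map Marker map.
#' @param max_dist_cm Haploblock-to-peak distance bound (default 10 cM).
#' @return One-row tibble `qtl_name, snp_id, block_id, ps_index, pve,
#'   distance_cm`; zero rows when no SNP qualifies (the QTL is skipped from
#'   haplotype analysis).
#' @export
designate_primary_snp <- function(scan, qtl, blocks, map, max_dist_cm = 10) {
  if (is.null(qtl$peak_cm) || is.na(qtl$peak_cm)) {
    stop_bad_input("QTL record must carry a PBA peak position")
  }
  sig <- filter(as_tibble(scan), .data$bonferroni_significant)
  sig <- inner_join(sig, map, by = "snp_id") |>
    filter(.data$linkage_group == qtl$linkage_group)
  if (nrow(sig) == 0) return(designate_empty())
  blk <- filter(blocks, .data$linkage_group == qtl$linkage_group)
  snp2block <- tibble(
    snp_id = unlist(blk$snp_ids),
    block_id = rep(blk$block_id, lengths(blk$snp_ids)),
    ps_index = unlist(map(blk$snp_ids, seq_along))
  ) |>
    left_join(select(blk, "block_id", "start_cm", "end_cm"), by = "block_id")
  cand <- inner_join(sig, snp2block, by = "snp_id") |>
    mutate(distance_cm = pmin(abs(.data$start_cm - qtl$peak_cm),
                              abs(.data$end_cm - qtl$peak_cm))) |>
    filter(.data$distance_cm < max_dist_cm)
  if (nrow(cand) == 0) return(designate_empty())
  best <- cand |>
    arrange(desc(.data$pve_adj_r2), .data$genetic_pos) |>
    slice(1)
  tibble(qtl_name = qtl$name %||% NA_character_, snp_id = best$snp_id,
         block_id = best$block_id, ps_index = best$ps_index,
         pve = best$pve_adj_r2, distance_cm = best$distance_cm)
}

designate_empty <- function() {
  tibble(qtl_name = character(), snp_id = character(), block_id = character(),
         ps_index = integer(), pve = double(), distance_cm = double())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build the haplotype catalog of a haploblock
#'
#' Labels `H1..Hk` are the distinct non-recombinant allele strings observed
#' among the given parents, numbered by descending frequency (ties
#' lexicographic). Strings containing missing alleles are not catalogued.
#'
#' @param parent_haps Character vector of parental haplotype strings
#'   (both strands of each parent).
#' @param ps_index 1-based position of the primary SNP within the block.
#' @return Tibble `label, string, ps_allele, n_parental`.
#' @export
haplotype_catalog <- function(parent_haps, ps_index) {
  parent_haps <- parent_haps[!is.na(parent_haps) &
                               !grepl("-", parent_haps, fixed = TRUE)]
  if (length(parent_haps) == 0) {
    return(tibble(label = character(), string = character(),
                  ps_allele = character(), n_parental = integer()))
  }
  tab <- table(parent_haps)
  ord <- order(-as.integer(tab), names(tab))
  tibble(
    label = paste0("H", seq_along(tab)),
    string = names(tab)[ord],
    ps_allele = substr(names(tab)[ord], ps_index, ps_index),
    n_parental = as.integer(tab)[ord]
  )
}

#' Classify a seedling haplotype against a parental catalog
#'
#' An exact match to a catalog string takes that label. A recombinant
#' string (no exact match) takes the label of the transmitting parent's
#' haplotype sharing its primary-SNP allele; when the PS allele is missing,
#' or both parental haplotypes carry the same PS allele while differing
#' elsewhere, the haplotype is left unassigned (`NA`).
#'
#' @param hap Seedling haplotype string (alleles `A`, `B`, `-`).
#' @param catalog Catalog tibble for the transmitting parent (usually its
#'   two strings), from [haplotype_catalog()].
#' @param ps_index 1-based primary-SNP position within the block.
#' @return The matched label, or `NA_character_`.
#' @export
classify_haplotype <- function(hap, catalog, ps_index) {
  if (nrow(catalog) == 0) return(NA_character_)
  if (any(nchar(catalog$string) != nchar(hap))) {
    stop_bad_input("haplotype and catalog strings must share the block length")
  }
  exact <- which(catalog$string == hap)
  if (length(exact) == 1) return(catalog$label[exact])
  ps <- substr(hap, ps_index, ps_index)
  if (ps == "-" || !ps %in% c("A", "B")) return(NA_character_)
  ps_match <- which(catalog$ps_allele == ps)
  if (length(ps_match) == 1) return(catalog$label[ps_match])
  # several catalog haplotypes share the PS allele: ambiguous
  NA_character_
}

#' Phase a haploblock genotype using parental diplotypes
#'
#' Enumerates the (up to four) maternal-gamete x paternal-gamete pairs and
#' keeps those consistent with the observed per-SNP dosages (missing
#' dosages and missing parental alleles constrain nothing). Exactly one
#' distinct string pair consistent: phased. None: Mendelian-inconsistent.
#' Several: unassigned.
#'
#' @param dosage Integer vector of B-allele dosages over the block SNPs
#'   (`NA` missing).
#' @param mother_pair,father_pair Character vectors of length 2: each
#'   parent's two haplotype strings (may contain `-`).
#' @return List `status` (`"phased"`, `"unassigned"`, `"inconsistent"`),
#'   `hap1` (maternal), `hap2` (paternal); haplotypes `NA` unless phased.
#' @export
parent_guided_phasing <- function(dosage, mother_pair, father_pair) {
  L <- length(dosage)
  split1 <- function(s) strsplit(s, "", fixed = TRUE)[[1]]
  combos <- expand.grid(m = 1:2, f = 1:2)
  consistent <- list()
  for (i in seq_len(nrow(combos))) {
    mh <- split1(mother_pair[combos$m[i]])
    fh <- split1(father_pair[combos$f[i]])
    if (length(mh) != L || length(fh) != L) {
      stop_bad_input("parental haplotypes must match the block length")
    }
    ok <- TRUE
    for (j in seq_len(L)) {
      if (is.na(dosage[j]) || mh[j] == "-" || fh[j] == "-") next
      if ((mh[j] == "B") + (fh[j] == "B") != dosage[j]) { ok <- FALSE; break }
    }
    if (ok) {
      consistent[[length(consistent) + 1L]] <-
        c(paste(mh, collapse = ""), paste(fh, collapse = ""))
    }
  }
  if (length(consistent) == 0) {
    return(list(status = "inconsistent", hap1 = NA_character_, hap2 = NA_character_))
  }
  uniq <- unique(map_chr(consistent, function(p) paste(sort(p), collapse = "/")))
  if (length(uniq) == 1) {
    list(status = "phased", hap1 = consistent[[1]][1], hap2 = consistent[[1]][2])
  } else {
    list(status = "unassigned", hap1 = NA_character_, hap2 = NA_character_)
  }
}

#' Restrict to haplotypes common among the seedlings
#'
#' Only haplotypes represented at least `min_n` times among the seedlings
#' (counting both strands) enter comparative analyses.
#'
#' @param labels Tibble `id, label` with one row per seedling haplotype
#'   instance (`NA` labels are ignored).
#' @param min_n Minimum instance count (default 5).
#' @return Tibble `label, n` of retained haplotypes, by descending count.
#' @export
common_haplotypes <- function(labels, min_n = 5) {
  labels |>
    filter(!is.na(.data$label)) |>
    count(.data$label, name = "n") |>
    filter(.data$n >= min_n) |>
    arrange(desc(.data$n), .data$label)
}

#' Estimate haplotype effects on a trait
#'
#' The effect of a haplotype is the mean trait value of its carrier
#' seedlings minus the mean over all phenotyped seedlings, so a positive
#' effect means carriers sit above the population average, in trait units.
#' `n` counts haplotype instances (a homozygote carries two).
#'
#' @param labels Tibble `id, label`, one row per haplotype instance.
#' @param values Tibble `id, value`: one trait value per phenotyped
#'   seedling (yearly value or multi-year BLUP deviation).
#' @param min_n Common-haplotype threshold passed to [common_haplotypes()].
#' @return Tibble `label, n, n_carriers, carrier_mean, effect`.
#' @export
estimate_effects <- function(labels, values, min_n = 5) {
  common <- common_haplotypes(labels, min_n)
  pop_mean <- mean(values$value, na.rm = TRUE)
  rows <- map(common$label, function(lab) {
    carriers <- unique(labels$id[!is.na(labels$label) & labels$label == lab])
    v <- values$value[values$id %in% carriers & !is.na(values$value)]
    if (length(v) == 0) {
      warn(paste0("haplotype ", lab, " has no phenotyped carriers; dropped"))
      return(NULL)
    }
    tibble(label = lab, n = common$n[common$label == lab],
           n_carriers = length(v), carrier_mean = mean(v),
           effect = mean(v) - pop_mean)
  })
  list_rbind(rows)
}

#' Pairwise haplotype contrasts
#'
#' Carrier trait values are compared between haplotypes with Tukey's HSD
#' (firmness convention: effectively normal) or pairwise Wilcoxon rank-sum
#' tests with Bonferroni correction over all unordered pairs (cracking
#' convention), at a family-wise error rate of `alpha`. A directed edge
#' `higher -> lower` is emitted for each significant pair, directed by the
#' carrier group means.
#'
#' @param groups Tibble `label, value`: one row per carrier seedling and
#'   haplotype (a seedling contributes to each haplotype it carries).
#' @param method `"tukey_hsd"` or `"pairwise_wilcoxon"`.
#' @param alpha Family-wise error rate (default 0.05).
#' @return Tibble `higher, lower, p_adj`, one row per significant ordered
#'   contrast. Groups with fewer than 2 observations are excluded with a
#'   warning.
#' @export
pairwise_tests <- function(groups, method = c("tukey_hsd", "pairwise_wilcoxon"),
                           alpha = 0.05) {
  method <- match.arg(method)
  groups <- filter(groups, !is.na(.data$label), !is.na(.data$value))
  sizes <- count(groups, .data$label)
  small <- sizes$label[sizes$n < 2]
  if (length(small)) {
    warn(paste0("excluding haplotype(s) with < 2 observations: ",
                paste(small, collapse = ", ")))
    groups <- filter(groups, !.data$label %in% small)
  }
  labs <- sort(unique(groups$label))
  if (length(labs) < 2) stop_bad_input("need at least 2 haplotype groups")
  means <- groups |> group_by(.data$label) |>
    summarise(m = mean(.data$value), .groups = "drop")
  mean_of <- setNames(means$m, means$label)
  groups$label_f <- factor(groups$label, levels = labs)
  if (method == "tukey_hsd") {
    if (var(groups$value) == 0) return(tibble(higher = character(),
                                              lower = character(),
                                              p_adj = double()))
    tk <- TukeyHSD(aov(value ~ label_f, data = groups))$label_f
    pair <- rownames(tk)
    p_adj <- tk[, "p adj"]
    ab <- stringr::str_split_fixed(pair, stringr::fixed("-"), 2)
  } else {
    pw <- suppressWarnings(
      pairwise.wilcox.test(groups$value, groups$label_f,
                           p.adjust.method = "bonferroni", exact = FALSE)
    )$p.value
    idx <- which(!is.na(pw), arr.ind = TRUE)
    ab <- cbind(rownames(pw)[idx[, 1]], colnames(pw)[idx[, 2]])
    p_adj <- pw[idx]
  }
  sig <- which(p_adj < alpha)
  if (length(sig) == 0) return(tibble(higher = character(),
                                      lower = character(), p_adj = double()))
  a <- ab[sig, 1]; b <- ab[sig, 2]; p <- unname(p_adj[sig])
  hi <- ifelse(mean_of[a] >= mean_of[b], a, b)
  lo <- ifelse(mean_of[a] >= mean_of[b], b, a)
  tibble(higher = unname(hi), lower = unname(lo), p_adj = p) |>
    arrange(.data$higher, .data$lower)
}

#' Assign relational functional classes to haplotypes
#'
#' The significance digraph (edges point from the significantly higher
#' haplotype to the lower) is turned into classes: a haplotype with no
#' significant contrast is unclassified (`none`); one that is both above
#' and below others is `moderate`; among haplotypes that are only above
#' (respectively only below) others, those with the greatest number of
#' significant contrasts are `high` (respectively `low`) and the rest
#' `moderate`. `high` and `low` are never assigned to the same haplotype.
#'
#' @param edges Digraph tibble `higher, lower` from [pairwise_tests()].
#' @param labels All haplotype labels under comparison (so isolated ones
#'   get `none`).
#' @return Tibble `label, class, out_degree, in_degree` with `class` in
#'   `high, moderate, low, none`.
#' @export
assign_functional_classes <- function(edges, labels) {
  out_deg <- setNames(integer(length(labels)), labels)
  in_deg <- out_deg
  if (nrow(edges)) {
    to <- table(factor(edges$higher, levels = labels))
    ti <- table(factor(edges$lower, levels = labels))
    out_deg[names(to)] <- as.integer(to)
    in_deg[names(ti)] <- as.integer(ti)
  }
  pure_high <- out_deg > 0 & in_deg == 0
  pure_low <- in_deg > 0 & out_deg == 0
  cls <- rep("none", length(labels))
  cls[out_deg > 0 & in_deg > 0] <- "moderate"
  if (any(pure_high)) {
    cls[pure_high] <- ifelse(out_deg[pure_high] == max(out_deg[pure_high]),
                             "high", "moderate")
  }
  if (any(pure_low)) {
    cls[pure_low] <- ifelse(in_deg[pure_low] == max(in_deg[pure_low]),
                            "low", "moderate")
  }
  tibble(label = labels, class = cls,
         out_degree = unname(out_deg), in_degree = unname(in_deg))
}

#' Compile diplotypes and count desirable haplotypes per seedling
#'
#' @param assignments Tibble `id, block_id, label1, label2` (labels may be
#'   `NA` for unassigned strands).
#' @param classes Tibble `block_id, label, class` from
#'   [assign_functional_classes()] per block.
#' @param desirable Which class counts as desirable (e.g. `"low"` for
#'   cracking, `"high"` for firmness).
#' @return List: `diplotypes` (per individual x block, label pair string)
#'   and `counts` (tibble `id, n_desirable`, maximum 2 x number of
#'   blocks).
#' @export
compile_diplotypes <- function(assignments, classes, desirable = "high") {
  cls <- setNames(classes$class, paste(classes$block_id, classes$label))
  get_cls <- function(block, lab) {
    out <- unname(cls[paste(block, lab)])
    out[is.na(lab) | is.na(out)] <- "none"
    out
  }
  dip <- assignments |>
    mutate(
      diplotype = paste0(ifelse(is.na(.data$label1), "?", .data$label1), "/",
                         ifelse(is.na(.data$label2), "?", .data$label2)),
      n_desirable = (get_cls(.data$block_id, .data$label1) == desirable) +
        (get_cls(.data$block_id, .data$label2) == desirable)
    )
  counts <- dip |>
    group_by(.data$id) |>
    summarise(n_desirable = sum(.data$n_desirable), .groups = "drop")
  list(diplotypes = select(dip, "id", "block_id", "diplotype", "n_desirable"),
       counts = counts)
}
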