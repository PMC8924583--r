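# QTL-level accounting: heritability and PVE from Bayesian variance
# components, Bayes-factor evidence classes, cross-method stability
# consensus and naming, and additive-variance attribution.

#' Narrow-sense heritability from QTL variance components
#'
#' `vqtl / (vqtl + verr)`, where `vqtl` is the QTL additive genetic
#' variance of the additive-only model and `verr` the residual. Vectors are
#' averaged ratio-wise (the convention for reporting two MCMC runs).
#'
#' @param vqtl,verr Variance components (trait units squared), scalars or
#'   equal-length vectors of per-run values.
#' @return A fraction in \[0, 1\].
#' @export
h2_from_components <- function(vqtl, verr) {
  if (any(vqtl < 0) || any(verr < 0)) stop_bad_input("variance components must be >= 0")
  tot <- vqtl + verr
  if (any(tot == 0)) stop_bad_input("vqtl + verr must be positive")
  mean(vqtl / tot)
}

#' QTL PVE from probability-weighted variance components
#'
#' `wavt / sigma_p2`, the QTL-probability-weighted variance explained over
#' the total phenotypic variance; per-run vectors are averaged ratio-wise.
#'
#' @param wavt Weighted QTL variance(s), trait units squared.
#' @param sigma_p2 Total phenotypic variance(s).
#' @return A fraction in \[0, 1\].
#' @export
pve_from_components <- function(wavt, sigma_p2) {
  if (any(wavt < 0)) stop_bad_input("weighted QTL variance must be >= 0")
  if (any(sigma_p2 <= 0)) stop_bad_input("total phenotypic variance must be positive")
  if (any(wavt > sigma_p2)) {
    stop_bad_input("weighted QTL variance cannot exceed the phenotypic variance")
  }
  mean(wavt / sigma_p2)
}

#' Classify Bayes-factor evidence for a QTL
#'
#' BF below 2 is non-significant; 2-5 positive, 5-10 strong, 10 and above
#' decisive evidence.
#'
#' @param bf Numeric vector of Bayes factors (`NA` allowed).
#' @return Factor with levels `none, positive, strong, decisive`.
#' @export
classify_bayes_factor <- function(bf) {
  cut(bf, breaks = c(-Inf, 2, 5, 10, Inf),
      labels = c("none", "positive", "strong", "decisive"), right = FALSE)
}

#' Total PVE over a set of QTL records
#'
#' Arithmetic sum of the chosen method's per-QTL PVE; records must share a
#' single trait.
#'
#' @param records Tibble with columns `trait`, `method`, `pve`.
#' @param method Method tag to sum over (e.g. `"pba"` or `"blink"`).
#' @return The summed PVE (same scale as the input, e.g. percent).
#' @export
total_pve <- function(records, method) {
  r <- filter(records, .data$method == !!method)
  if (nrow(r) == 0) return(0)
  if (length(unique(r$trait)) > 1) {
    stop_bad_input("total_pve must not mix traits")
  }
  sum(r$pve)
}

#' Fraction of the additive genetic variance captured by detected QTLs
#'
#' `100 * total_pve / h2`, rounded to the nearest integer percent. A value
#' above 100 (over-attribution) is returned with a warning.
#'
#' @param total_pve Summed QTL PVE as a fraction of phenotypic variance.
#' @param h2 Narrow-sense heritability (fraction, > 0).
#' @return Integer percent.
#' @export
additive_fraction <- function(total_pve, h2) {
  if (h2 <= 0) stop_bad_input("h2 must be positive")
  out <- round(100 * total_pve / h2)
  if (out > 100) warn("QTLs attributed more than 100% of the additive variance")
  out
}

#' Consolidate QTL detections across datasets and methods
#'
#' Detections on the same trait and linkage group are merged into one QTL
#' when their evidence co-locates: two interval (PBA) detections whose cM
#' intervals overlap, a GWAS peak SNP lying inside (or within `snp_slack`
#' cM of) a PBA interval, or two GWAS detections of the identical peak SNP.
#' Each merged QTL is named `q<Trait>-LG<lg>.<k>` with QTLs ordered by
#' position within the linkage group, suffixed `m` when supported by
#' distinct evidence from at least two datasets (repeated identical
#' intervals or identical peak SNPs count once). A QTL is flagged stable
#' when it was detected in every PBA dataset available for the trait and in
#' at least two GWAS datasets.
#'
#' @param detections Tibble with columns `trait, dataset, method`
#'   (`"pba"`/`"blink"`), `linkage_group`, and per method
#'   `interval_start, interval_end, peak_cm` (PBA) or `snp_id, snp_cm`
#'   (GWAS); see [cherry_qtl_detections()] for the layout.
#' @param snp_slack cM tolerance for a peak SNP just outside a PBA
#'   interval (default 2).
#' @return Tibble of consolidated QTL records: `trait, linkage_group, name,
#'   stable, multi_year, interval_start, interval_end, position_cm,
#'   n_detections, datasets_pba, datasets_blink`, plus `detections`, a
#'   list-column of the member rows.
#' @export
consolidate_stability <- function(detections, snp_slack = 2) {
  need <- c("trait", "dataset", "method", "linkage_group")
  if (!all(need %in% names(detections))) {
    stop_bad_input("detections need columns trait, dataset, method, linkage_group")
  }
  groups <- detections |>
    group_by(.data$trait, .data$linkage_group) |>
    group_split()
  pba_datasets <- detections |>
    filter(.data$method == "pba") |>
    group_by(.data$trait) |>
    summarise(all_pba = list(unique(.data$dataset)), .groups = "drop")
  out <- map(groups, function(d) {
    k <- nrow(d)
    # union-find over the detections of this trait x LG
    parent <- seq_len(k)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    union_ <- function(i, j) { parent[find(i)] <<- find(j) }
    for (i in seq_len(k)) for (j in seq_len(k)) {
      if (j <= i) next
      mi <- d$method[i]; mj <- d$method[j]
      linked <- FALSE
      if (mi == "pba" && mj == "pba") {
        linked <- d$interval_start[i] <= d$interval_end[j] &&
          d$interval_start[j] <= d$interval_end[i]
      } else if (mi != mj) {
        pb <- if (mi == "pba") i else j
        bl <- if (mi == "pba") j else i
        linked <- !is.na(d$snp_cm[bl]) &&
          d$snp_cm[bl] >= d$interval_start[pb] - snp_slack &&
          d$snp_cm[bl] <= d$interval_end[pb] + snp_slack
      } else {
        linked <- !is.na(d$snp_id[i]) && identical(d$snp_id[i], d$snp_id[j])
      }
      if (linked) union_(i, j)
    }
    comp <- vapply(seq_len(k), find, integer(1))
    all_pba <- pba_datasets$all_pba[match(d$trait[1], pba_datasets$trait)][[1]]
    recs <- map(unique(comp), function(cid) {
      dd <- d[comp == cid, ]
      pos <- mean(c(dd$peak_cm, dd$snp_cm), na.rm = TRUE)
      # distinct-evidence count: identical intervals / identical SNPs collapse
      ev <- distinct(tibble(
        method = dd$method,
        key = ifelse(dd$method == "pba",
                     paste0("i:", dd$interval_start, "-", dd$interval_end),
                     paste0("s:", dd$snp_id))
      ))
      distinct_datasets <- dd |>
        mutate(key = ifelse(.data$method == "pba",
                            paste0("i:", .data$interval_start, "-", .data$interval_end),
                            paste0("s:", .data$snp_id))) |>
        distinct(.data$key, .keep_all = TRUE) |>
        pull(.data$dataset) |>
        unique()
      multi_year <- nrow(ev) >= 2 && length(distinct_datasets) >= 2
      ds_pba <- unique(dd$dataset[dd$method == "pba"])
      ds_blink <- unique(dd$dataset[dd$method == "blink"])
      stable <- length(all_pba) > 0 && setequal(intersect(all_pba, ds_pba), all_pba) &&
        length(ds_blink) >= 2
      tibble(
        trait = dd$trait[1], linkage_group = dd$linkage_group[1],
        position_cm = pos,
        interval_start = suppressWarnings(min(dd$interval_start, na.rm = TRUE)),
        interval_end = suppressWarnings(max(dd$interval_end, na.rm = TRUE)),
        multi_year = multi_year, stable = stable,
        n_detections = nrow(dd),
        datasets_pba = list(ds_pba), datasets_blink = list(ds_blink),
        detections = list(dd)
      )
    })
    recs <- list_rbind(recs) |> arrange(.data$position_cm)
    short <- c(cracking = "Crack", firmness = "Firm")
    tr_tag <- ifelse(recs$trait %in% names(short), short[recs$trait],
                     paste0(toupper(substr(recs$trait, 1, 1)),
                            substr(recs$trait, 2, 5)))
    recs$name <- sprintf("q%s-LG%d.%d%s", tr_tag,
                         recs$linkage_group, seq_len(nrow(recs)),
                         ifelse(recs$multi_year, "m", ""))
    recs
  })
  list_rbind(out) |>
    mutate(interval_start = ifelse(is.finite(.data$interval_start),
                                   .data$interval_start, NA_real_),
           interval_end = ifelse(is.finite(.data$interval_end),
                                 .data$interval_end, NA_real_)) |>
    relocate("trait", "linkage_group", "name", "stable", "multi_year")
}
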