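# shared fixtures and independent oracles, all built in code

# a down-scaled germplasm: 3 linkage groups, 90 SNPs, ~48 seedlings
small_config <- function(seed = 1L, n_off = 8L, missing_rate = 0) {
  sim_config(
    seed = seed,
    n_ancestors = 4L, n_ibps = 6L, n_founder_ibps = 4L,
    cross_design = tibble::tibble(
      mother = c("P01", "P03", "P05", "P01", "P02", "P05"),
      father = c("P02", "P04", "P06", "P03", "P04", "P05"),  # one self-cross
      n_offspring = n_off,
      subpop = c("A", "A", "A", "B", "B", "B")
    ),
    map_spec = tibble::tibble(
      linkage_group = 1:3, length_cm = c(60, 50, 40),
      n_snps = c(35L, 30L, 25L)
    ),
    qtl_specs = tibble::tibble(
      trait = c("cracking", "firmness"),
      linkage_group = c(1L, 2L), pos_cm = c(30, 25),
      ps_index = 4L, effect = c(0.5, 30)
    ),
    missing_rate = missing_rate
  )
}

# closed-form BLUP for a balanced two-year design:
# dev_i = (2 su2 / (2 su2 + se2)) * (indiv mean - grand mean)
balanced_blup_oracle <- function(values_wide, su2, se2) {
  im <- rowMeans(values_wide)
  shrink <- 2 * su2 / (2 * su2 + se2)
  shrink * (im - mean(im))
}

# independently coded restatement of the relational functional-class rule
oracle_classes <- function(edges, labels) {
  above <- function(l) unique(edges$lower[edges$higher == l])
  below <- function(l) unique(edges$higher[edges$lower == l])
  res <- stats::setNames(rep("none", length(labels)), labels)
  only_high <- labels[vapply(labels, function(l) {
    length(above(l)) > 0 && length(below(l)) == 0
  }, logical(1))]
  only_low <- labels[vapply(labels, function(l) {
    length(below(l)) > 0 && length(above(l)) == 0
  }, logical(1))]
  max_out <- if (length(only_high)) {
    max(vapply(only_high, function(l) length(above(l)), integer(1)))
  } else 0L
  max_in <- if (length(only_low)) {
    max(vapply(only_low, function(l) length(below(l)), integer(1)))
  } else 0L
  for (l in labels) {
    na <- length(above(l)); nb <- length(below(l))
    if (na == 0 && nb == 0) next
    if (na > 0 && nb > 0) res[l] <- "moderate"
    else if (na > 0) res[l] <- if (na == max_out) "high" else "moderate"
    else res[l] <- if (nb == max_in) "low" else "moderate"
  }
  res
}

# all digraphs over the given labels: each unordered pair is absent,
# forward, or backward (a pair cannot be significant in both directions)
enumerate_digraphs <- function(labels) {
  pairs <- utils::combn(labels, 2)
  n_pairs <- ncol(pairs)
  lapply(seq_len(3^n_pairs) - 1L, function(code) {
    hi <- character(0); lo <- character(0)
    for (k in seq_len(n_pairs)) {
      state <- (code %/% 3^(k - 1)) %% 3
      if (state == 1) { hi <- c(hi, pairs[1, k]); lo <- c(lo, pairs[2, k]) }
      if (state == 2) { hi <- c(hi, pairs[2, k]); lo <- c(lo, pairs[1, k]) }
    }
    tibble::tibble(higher = hi, lower = lo)
  })
}

# founders whose strands carry globally unique strings at one block, so
# descent has a unique string-level ground truth
unique_string_founders <- function(founders, block_snps) {
  n_strand <- 2L * nrow(founders$h1)
  stopifnot(2^length(block_snps) >= n_strand)
  enc <- function(k) {
    bits <- as.integer(intToBits(k))[seq_along(block_snps)]
    c("A", "B")[bits + 1L]
  }
  for (i in seq_len(nrow(founders$h1))) {
    founders$h1[i, block_snps] <- enc(2L * i - 2L)
    founders$h2[i, block_snps] <- enc(2L * i - 1L)
  }
  founders
}
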