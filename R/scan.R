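# Iterative fixed-effects genome scan in the BLINK style: one model picks
# cofactor SNPs by BIC under an LD-exclusion rule (|Pearson r| > 0.7), the
# other tests every SNP with the accumulated cofactors as covariates; the
# two alternate until the cofactor set is stable.

#' Filter SNPs by minor allele frequency
#'
#' MAF is computed on non-missing calls; only SNPs with MAF strictly above
#' `threshold` are retained (a SNP at exactly the threshold is removed).
#'
#' @param geno Dosage matrix (individuals x SNPs, B-allele count, `NA`
#'   missing).
#' @param threshold MAF threshold (default 0.01).
#' @return The filtered matrix, with attribute `"removed"` naming the
#'   dropped SNPs.
#' @export
maf_filter <- function(geno, threshold = 0.01) {
  geno <- validate_genotypes(geno)
  p <- colMeans(geno, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0  # all-missing column
  keep <- maf > threshold
  if (!any(keep)) stop_bad_input("MAF filter removed every SNP")
  if (any(!keep)) {
    inform(paste0("MAF filter removed ", sum(!keep), " of ", length(keep), " SNPs"))
  }
  out <- geno[, keep, drop = FALSE]
  attr(out, "removed") <- colnames(geno)[!keep]
  out
}

# per-SNP mean imputation, the convention for association testing
impute_mean <- function(geno) {
  if (!anyNA(geno)) return(geno + 0)
  mu <- colMeans(geno, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  idx <- which(is.na(geno))
  geno <- geno + 0
  geno[idx] <- mu[(idx - 1L) %/% nrow(geno) + 1L]
  geno
}

# p-values for adding each column of G to the fixed model X0 (already
# including the intercept), via residual projection; exact single-SNP
# F(1, df) = t^2 tests
scan_pass <- function(G, y, X0) {
  qr0 <- qr(X0)
  ry <- qr.resid(qr0, y)
  RG <- qr.resid(qr0, G)
  ss_g <- colSums(RG^2)
  df <- length(y) - ncol(X0) - 1L
  ok <- ss_g > 1e-10
  b <- rep(0, ncol(G))
  b[ok] <- as.vector(crossprod(RG[, ok, drop = FALSE], ry)) / ss_g[ok]
  rss <- pmax(sum(ry^2) - b^2 * ss_g, 0)
  tt <- rep(0, ncol(G))
  tt[ok] <- b[ok] / sqrt(rss[ok] / df / ss_g[ok])
  p <- 2 * pt(-abs(tt), df)
  p[!ok] <- 1
  pmax(p, .Machine$double.xmin)
}

bic_lm <- function(y, X) {
  n <- length(y)
  rss <- sum(qr.resid(qr(X), y)^2)
  n * log(rss / n) + log(n) * (ncol(X) + 1)  # +1 for the error variance
}

#' Iterative fixed-effects genome scan with BIC cofactor selection
#'
#' Alternates two fixed-effects models until the cofactor set stabilizes:
#' (a) every SNP is tested in a simple linear model with the current
#' cofactor SNPs (and any `covariates`) as fixed covariates; (b) the
#' Bonferroni-significant SNPs, in ascending p order, are greedily admitted
#' as cofactors when they lower the BIC of the joint model and are not in
#' high linkage disequilibrium (|Pearson r| > 0.7) with an already-admitted
#' cofactor. Reported p-values come from the final testing pass; cofactor
#' SNPs are tested with themselves excluded from the covariate set.
#'
#' @param geno Dosage matrix (missing calls mean-imputed for testing).
#' @param y Phenotype vector aligned to `geno` rows (typically multi-year
#'   BLUP deviations).
#' @param alpha Family-wise error rate for the Bonferroni threshold.
#' @param max_iter Maximum model alternations.
#' @param covariates Optional numeric matrix of fixed covariates (e.g.
#'   principal components or cross indicators).
#' @param ld_max LD exclusion threshold on |r| (strictly above excludes).
#' @return A `cherry_scan` tibble: `snp_id, p_value, minus_log10_p, maf,
#'   pve_adj_r2, bonferroni_significant, cofactor`, with the Bonferroni
#'   threshold and iteration count as attributes.
#' @export
blink_scan <- function(geno, y, alpha = 0.05, max_iter = 10,
                       covariates = NULL, ld_max = 0.7) {
  geno <- validate_genotypes(geno)
  if (nrow(geno) != length(y)) stop_bad_input("phenotype length must match genotype rows")
  keep <- !is.na(y)
  geno <- geno[keep, , drop = FALSE]; y <- y[keep]
  if (var(y) == 0) stop_bad_input("phenotype has zero variance")
  G <- impute_mean(geno)
  m <- ncol(G); n <- nrow(G)
  base <- cbind(`(Intercept)` = rep(1, n), covariates)
  thr <- alpha / m
  cof <- integer(0)
  p <- rep(1, m)
  for (iter in seq_len(max_iter)) {
    if (n <= length(cof) + 2) stop_bad_input("too many cofactors for the sample size")
    X0 <- cbind(base, G[, cof, drop = FALSE])
    p <- scan_pass(G, y, X0)
    for (j in cof) {  # a cofactor is tested without itself as covariate
      Xj <- cbind(base, G[, setdiff(cof, j), drop = FALSE])
      p[j] <- scan_pass(G[, j, drop = FALSE], y, Xj)
    }
    cand <- which(p <= thr)
    cand <- cand[order(p[cand])]
    sel <- integer(0)
    X <- base
    for (j in cand) {
      if (length(sel) &&
          any(abs(suppressWarnings(cor(G[, j], G[, sel, drop = FALSE]))) > ld_max,
              na.rm = TRUE)) next
      Xj <- cbind(X, G[, j])
      if (qr(Xj)$rank < ncol(Xj)) next
      if (bic_lm(y, Xj) < bic_lm(y, X)) {
        sel <- c(sel, j)
        X <- Xj
      }
    }
    if (length(sel) == length(cof) && setequal(sel, cof)) break
    cof <- sel
  }
  if (length(cof) > 1) {  # invariant: admitted cofactors are mutually below the LD bound
    cc <- abs(suppressWarnings(cor(G[, cof, drop = FALSE])))
    diag(cc) <- 0
    stopifnot(all(cc <= ld_max + 1e-12, na.rm = TRUE))
  }
  pve <- vapply(seq_len(m), function(j) {
    suppressWarnings(snp_pve(geno[, j], y))
  }, numeric(1))
  pvals <- colMeans(geno, na.rm = TRUE) / 2
  out <- tibble(
    snp_id = colnames(geno),
    p_value = p,
    minus_log10_p = -log10(p),
    maf = pmin(pvals, 1 - pvals),
    pve_adj_r2 = pve,
    bonferroni_significant = p <= thr,
    cofactor = seq_len(m) %in% cof
  )
  attr(out, "bonferroni_threshold") <- thr
  attr(out, "n") <- n
  class(out) <- c("cherry_scan", class(out))
  out
}

#' Phenotypic variance explained by a single SNP
#'
#' The adjusted r-squared of the simple linear regression of the phenotype
#' on the SNP dosage: `1 - (1 - r2) * (n - 1) / (n - 2)`, clipped at 0.
#'
#' @param dosage Dosage vector (missing allowed).
#' @param y Phenotype vector.
#' @return A fraction in \[0, 1\].
#' @export
snp_pve <- function(dosage, y) {
  keep <- !is.na(dosage) & !is.na(y)
  n <- sum(keep)
  if (n < 4) stop_bad_input("need at least 4 complete (dosage, phenotype) pairs")
  if (var(dosage[keep]) == 0) {
    warn("constant dosage; PVE is 0")
    return(0)
  }
  r2 <- cor(dosage[keep], y[keep])^2
  max(1 - (1 - r2) * (n - 1) / (n - 2), 0)
}

#' Genomic narrow-sense heritability from a dosage matrix
#'
#' Builds a VanRaden-style genomic relationship matrix from centered
#' dosages (normalized to unit mean diagonal) and partitions the phenotypic
#' variance into additive and residual components by single-component REML
#' on the eigenbasis of the GRM; h2 = additive / (additive + residual).
#' Falls back to Haseman-Elston regression with a warning when the REML
#' optimization fails.
#'
#' @param geno Dosage matrix.
#' @param y Phenotype vector.
#' @return Tibble `h2, v_additive, v_residual, method` (variances in trait
#'   units squared).
#' @export
estimate_h2_additive <- function(geno, y) {
  geno <- validate_genotypes(geno)
  if (nrow(geno) != length(y)) stop_bad_input("phenotype length must match genotype rows")
  keep <- !is.na(y)
  geno <- geno[keep, , drop = FALSE]; y <- y[keep]
  n <- nrow(geno)
  if (n < 50 || ncol(geno) < 100) {
    warn("fewer than 50 individuals or 100 SNPs; heritability estimate will be noisy")
  }
  W <- scale(impute_mean(geno), center = TRUE, scale = FALSE)
  G <- tcrossprod(W) / ncol(W)
  G <- G / mean(diag(G))
  eg <- eigen(G, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  yt <- crossprod(eg$vectors, y)
  xt <- crossprod(eg$vectors, rep(1, n))
  reml_nll <- function(log_lambda) {
    w <- exp(log_lambda) * d + 1
    xwx <- sum(xt^2 / w)
    beta <- sum(xt * yt / w) / xwx
    rss <- sum((yt - xt * beta)^2 / w)
    s2 <- rss / (n - 1)
    0.5 * ((n - 1) * log(s2) + sum(log(w)) + log(xwx))
  }
  fit <- try(optimize(reml_nll, c(-12, 12)), silent = TRUE)
  if (!inherits(fit, "try-error") && is.finite(fit$objective)) {
    lambda <- exp(fit$minimum)
    w <- lambda * d + 1
    beta <- sum(xt * yt / w) / sum(xt^2 / w)
    se2 <- sum((yt - xt * beta)^2 / w) / (n - 1)
    sg2 <- lambda * se2
    return(tibble(h2 = sg2 / (sg2 + se2), v_additive = sg2,
                  v_residual = se2, method = "reml_grm"))
  }
  warn("REML optimization failed; falling back to Haseman-Elston regression")
  yc <- y - mean(y)
  off <- upper.tri(G)
  sg2 <- max(coef(lm(tcrossprod(yc)[off] ~ G[off]))[2], 0)
  se2 <- max(var(y) - sg2, 0)
  tibble(h2 = sg2 / max(sg2 + se2, .Machine$double.eps),
         v_additive = sg2, v_residual = se2, method = "haseman_elston")
}

#' Principal-component structure check of a genotype matrix
#'
#' Eigen-decomposes the covariance of the mean-imputed, centered dosage
#' matrix and reports the fraction of variance on each component.
#'
#' @param geno Dosage matrix (at least 3 individuals).
#' @param k Number of leading components to report (default all).
#' @return Tibble `component, variance_fraction` (fractions sum to 1 over
#'   all components).
#' @export
pca_structure <- function(geno, k = NULL) {
  geno <- validate_genotypes(geno)
  if (nrow(geno) < 3) stop_bad_input("need at least 3 individuals for PCA")
  pc <- prcomp(impute_mean(geno), center = TRUE, scale. = FALSE)
  frac <- pc$sdev^2 / sum(pc$sdev^2)
  if (is.null(k)) k <- length(frac)
  tibble(component = seq_len(min(k, length(frac))),
         variance_fraction = frac[seq_len(min(k, length(frac)))])
}
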