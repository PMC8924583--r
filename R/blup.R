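# Multi-year BLUPs: year as fixed effect, individual as random intercept,
# fitted by REML with lme4. Deviations are the predicted random effects,
# i.e. "deviations from the intercept", reported in trait units.

#' Fit a multi-year BLUP model for one trait
#'
#' Fits `value ~ year + (1 | id)` by REML (year a fixed factor, individual a
#' random intercept) and returns each individual's predicted random effect
#' as its multi-year deviation, in trait units. With a single year of data
#' the year term is dropped. A zero-variance phenotype short-circuits to
#' zero deviations with a warning.
#'
#' @param pheno Phenotype tibble (`id, trait, year, value`).
#' @param trait Trait to fit (`"cracking"` or `"firmness"`).
#' @return An object of class `multiyear_blup`: deviations, intercept,
#'   variance components and the underlying \pkg{lme4} fit. Use [tidy()] for
#'   the per-individual table and [glance()] for the model summary.
#' @export
fit_multiyear_blup <- function(pheno, trait) {
  d <- filter(validate_phenotypes(pheno), .data$trait == !!trait, !is.na(.data$value))
  if (length(unique(d$id)) < 2) {
    stop_bad_input("need phenotype records for at least 2 individuals")
  }
  res <- list(trait = trait)
  n_years <- tibble(id = d$id) |> count(.data$id, name = "n_years")
  if (var(d$value) == 0) {
    warn("phenotype has zero variance; returning zero deviations")
    res$blups <- tibble(id = sort(unique(d$id)), trait = trait, deviation = 0) |>
      left_join(n_years, by = "id")
    res$intercept <- d$value[1]
    res$sigma_u2 <- 0
    res$sigma_e2 <- 0
    res$model <- NULL
    return(structure(res, class = "multiyear_blup"))
  }
  d$year_f <- factor(d$year)
  fml <- if (nlevels(d$year_f) > 1) value ~ year_f + (1 | id) else value ~ (1 | id)
  fit <- lme4::lmer(fml, data = d, REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  vc <- as.data.frame(lme4::VarCorr(fit))
  re <- lme4::ranef(fit)$id
  res$blups <- tibble(id = rownames(re), trait = trait,
                      deviation = re[["(Intercept)"]]) |>
    left_join(n_years, by = "id") |>
    arrange(.data$id)
  res$intercept <- unname(lme4::fixef(fit)[["(Intercept)"]])
  res$sigma_u2 <- vc$vcov[vc$grp == "id"]
  res$sigma_e2 <- vc$vcov[vc$grp == "Residual"]
  res$model <- fit
  structure(res, class = "multiyear_blup")
}

#' @export
print.multiyear_blup <- function(x, ...) {
  cat("Multi-year BLUP fit --", x$trait, "\n")
  cat(sprintf("  individuals: %d   intercept: %.3f\n", nrow(x$blups), x$intercept))
  cat(sprintf("  sigma_u^2: %.4f   sigma_e^2: %.4f   repeatability: %.3f\n",
              x$sigma_u2, x$sigma_e2,
              x$sigma_u2 / max(x$sigma_u2 + x$sigma_e2, .Machine$double.eps)))
  invisible(x)
}

#' Tidy a multi-year BLUP fit
#'
#' @param x A `multiyear_blup` object.
#' @param ... Unused.
#' @return `tidy()`: tibble `id, trait, deviation, n_years` (deviation in
#'   trait units, relative to the model intercept). `glance()`: one-row
#'   tibble with the intercept, variance components and record counts.
#' @importFrom generics tidy
#' @export
tidy.multiyear_blup <- function(x, ...) {
  x$blups
}

#' @rdname tidy.multiyear_blup
#' @importFrom generics glance
#' @export
glance.multiyear_blup <- function(x, ...) {
  tibble(
    trait = x$trait,
    intercept = x$intercept,
    sigma_u2 = x$sigma_u2,
    sigma_e2 = x$sigma_e2,
    repeatability = x$sigma_u2 / max(x$sigma_u2 + x$sigma_e2, .Machine$double.eps),
    n_individuals = nrow(x$blups)
  )
}

#' Between-year Pearson correlation for a trait
#'
#' Computed on individuals with both years observed.
#'
#' @param pheno Phenotype tibble.
#' @param trait Trait name.
#' @param years Length-2 vector of years to pair.
#' @return Tibble `year1, year2, estimate, p_value, n`.
#' @export
between_year_correlation <- function(pheno, trait, years) {
  stopifnot(length(years) == 2)
  d <- filter(validate_phenotypes(pheno), .data$trait == !!trait,
              .data$year %in% years) |>
    tidyr::pivot_wider(id_cols = "id", names_from = "year",
                       values_from = "value")
  y1 <- as.character(years[1]); y2 <- as.character(years[2])
  if (!all(c(y1, y2) %in% names(d))) {
    stop_bad_input("both years must have phenotype records")
  }
  keep <- complete.cases(d[c(y1, y2)])
  if (sum(keep) < 3) stop_bad_input("need at least 3 complete year pairs")
  ct <- cor.test(d[[y1]][keep], d[[y2]][keep], method = "pearson")
  tibble(year1 = years[1], year2 = years[2],
         estimate = unname(ct$estimate), p_value = ct$p.value, n = sum(keep))
}

#' Compare trait levels between subpopulations
#'
#' Firmness (effectively normal) uses Welch's two-sample t test on means;
#' cracking incidence (bounded, non-normal) uses the Wilcoxon rank-sum
#' test. `method` can override the convention. Two identical constant
#' groups return p = 1 by convention.
#'
#' @param pheno Phenotype tibble.
#' @param subpops Tibble `id, subpop` (e.g. the seedling rows of a
#'   pedigree).
#' @param trait Trait name.
#' @param year Year to compare.
#' @param method `"auto"`, `"welch"` or `"wilcoxon"`.
#' @return Tibble `trait, year, method, statistic, p_value, n_a, n_b,
#'   mean_a, mean_b` (group order = sorted subpopulation labels).
#' @export
compare_subpopulations <- function(pheno, subpops, trait, year,
                                   method = c("auto", "welch", "wilcoxon")) {
  method <- match.arg(method)
  if (method == "auto") method <- if (trait == "cracking") "wilcoxon" else "welch"
  d <- filter(validate_phenotypes(pheno), .data$trait == !!trait,
              .data$year == !!year) |>
    inner_join(distinct(subpops, .data$id, .data$subpop), by = "id") |>
    filter(!is.na(.data$subpop))
  labs <- sort(unique(d$subpop))
  if (length(labs) != 2) stop_bad_input("need exactly two subpopulations with data")
  xa <- d$value[d$subpop == labs[1]]
  xb <- d$value[d$subpop == labs[2]]
  if (length(xa) < 2 || length(xb) < 2) {
    stop_bad_input("each subpopulation needs at least 2 observations")
  }
  if (var(c(xa, xb)) == 0) {
    stat <- 0; p <- 1
  } else if (method == "welch") {
    tt <- t.test(xa, xb, var.equal = FALSE)
    stat <- unname(tt$statistic); p <- tt$p.value
  } else {
    wt <- suppressWarnings(wilcox.test(xa, xb, exact = FALSE))
    stat <- unname(wt$statistic); p <- wt$p.value
  }
  tibble(trait = trait, year = year, method = method, statistic = stat,
         p_value = p, n_a = length(xa), n_b = length(xb),
         mean_a = mean(xa), mean_b = mean(xb))
}
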