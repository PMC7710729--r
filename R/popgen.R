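#' Derived allele frequency from genotype fractions
#'
#' Given the fractions of ancestral homozygotes, heterozygotes and derived
#' homozygotes in a population, the derived allele frequency is the derived
#' homozygote fraction plus half the heterozygote fraction.
#'
#' @param g numeric length-3 vector `(ancestral hom, het, derived hom)`,
#'   summing to 1 within `tol`.
#' @param tol tolerance on the sum (default 1e-9).
#' @return derived allele frequency.
#' @export
allele_frequency_from_genotypes <- function(g, tol = 1e-9) {
  g <- as.numeric(g)
  if (length(g) != 3 || any(g < -tol) || any(g > 1 + tol))
    stop("genotype fractions must be three values in [0, 1]")
  if (abs(sum(g) - 1) > tol)
    stop("genotype fractions must sum to 1 (got ", sum(g), ")")
  g[3] + g[2] / 2
}

#' Two-locus haplotype frequencies by direct counting
#'
#' Counts the four phased two-locus haplotype classes (derived-derived,
#' derived-ancestral, ancestral-derived, ancestral-ancestral) among the
#' haplotypes of one population. Haplotypes missing either allele drop out
#' of the denominator.
#'
#' @param panel a [haplotype_panel()].
#' @param locus_i,locus_j site indices of the two loci.
#' @param population population label, or `NULL` for the whole panel.
#' @return named numeric vector of class `haplotype_freqs`:
#'   `p11, p10, p01, p00` (1 = derived), plus attributes `n` (haplotypes
#'   counted) and `dropped`.
#' @export
haplotype_frequencies <- function(panel, locus_i, locus_j,
                                  population = NULL) {
  if (!is.null(population)) panel <- subset_population(panel, population)
  a <- panel$haps[, locus_i]
  b <- panel$haps[, locus_j]
  ok <- !is.na(a) & !is.na(b)
  n <- sum(ok)
  if (n == 0) stop("no haplotype with complete data at both loci")
  cls <- paste0(a[ok], b[ok])
  cnt <- c(`11` = sum(cls == "11"), `10` = sum(cls == "10"),
           `01` = sum(cls == "01"), `00` = sum(cls == "00"))
  structure(setNames(as.numeric(cnt) / n, c("p11", "p10", "p01", "p00")),
            n = n, dropped = sum(!ok), class = "haplotype_freqs")
}

#' Two-locus linkage disequilibrium from haplotype frequencies
#'
#' Computes `D = p11 - pA pB` (with `pA`, `pB` the marginal derived
#' frequencies), the normalized `D' = |D| / Dmax`, and
#' `r^2 = D^2 / (pA (1-pA) pB (1-pB))`. `Dmax` is
#' `min(pA (1-pB), (1-pA) pB)` for positive `D` and
#' `min(pA pB, (1-pA)(1-pB))` for negative `D`. `D'` is reported unsigned.
#'
#' @param t haplotype frequency vector `(p11, p10, p01, p00)` summing to 1
#'   (e.g. from [haplotype_frequencies()]).
#' @param tol tolerance on the sum.
#' @return list of class `ld_pair`: `D`, `Dprime`, `r2`, `pA`, `pB`; if a
#'   locus is monomorphic the LD fields are `NA` and `reason`
#'   `"monomorphic"`.
#' @export
ld_from_haplotype_freqs <- function(t, tol = 1e-9) {
  t <- as.numeric(t)
  if (length(t) != 4 || any(t < -tol))
    stop("need four non-negative haplotype frequencies")
  if (abs(sum(t) - 1) > tol) stop("haplotype frequencies must sum to 1")
  p11 <- t[1]; p10 <- t[2]; p01 <- t[3]
  pA <- p11 + p10
  pB <- p11 + p01
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1)
    return(structure(list(D = NA_real_, Dprime = NA_real_, r2 = NA_real_,
                          pA = pA, pB = pB, reason = "monomorphic"),
                     class = "ld_pair"))
  D <- p11 - pA * pB
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  structure(list(D = D,
                 Dprime = if (dmax > 0) abs(D) / dmax else 0,
                 r2 = D^2 / (pA * (1 - pA) * pB * (1 - pB)),
                 pA = pA, pB = pB, reason = NA_character_),
            class = "ld_pair")
}

#' @export
print.ld_pair <- function(x, ...) {
  if (!is.na(x$reason))
    cat("LD undefined:", x$reason, "\n")
  else
    cat(sprintf("D = %.4f, D' = %.4f, r2 = %.4f (pA = %.3f, pB = %.3f)\n",
                x$D, x$Dprime, x$r2, x$pA, x$pB))
  invisible(x)
}

#' Per-site Fst between two populations
#'
#' Hudson-style estimator with sample-size correction (default):
#' numerator `(p1-p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)`, denominator
#' `p1(1-p2) + p2(1-p1)`. The uncorrected plug-in estimator
#' `(p1-p2)^2 / (p1(1-p2) + p2(1-p1))` is available for analytic work, as is
#' the Weir-Cockerham estimator. Negative corrected values are reported as
#' computed, not clamped.
#'
#' @param p1,p2 derived allele frequencies in the two populations.
#' @param n1,n2 haplotype sample sizes (must be >= 2 for corrected
#'   estimators).
#' @param estimator `"hudson"` (default), `"plugin"` or `"wc"`.
#' @param position optional position annotation.
#' @return list of class `fst_record`: `fst`, `estimator`, `position`,
#'   `n1`, `n2`; `fst` is `NA` with `reason = "undefined"` when the
#'   denominator vanishes (both populations monomorphic for the same
#'   allele).
#' @export
fst_per_site <- function(p1, n1, p2, n2,
                         estimator = c("hudson", "plugin", "wc"),
                         position = NA) {
  estimator <- match.arg(estimator)
  if (estimator != "plugin" && (n1 < 2 || n2 < 2))
    stop("corrected estimators need sample sizes >= 2")
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  fst <- reason <- NA
  if (estimator %in% c("hudson", "plugin")) {
    num <- (p1 - p2)^2
    if (estimator == "hudson")
      num <- num - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
    if (den <= 0) reason <- "undefined" else fst <- num / den
  } else {
    # Weir & Cockerham (1984) single-site theta-hat, two demes
    n <- c(n1, n2); p <- c(p1, p2)
    r <- 2
    nbar <- mean(n)
    nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
    pbar <- sum(n * p) / sum(n)
    s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n * 2 * p * (1 - p) * n / (n - 1)) / sum(n)
    a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 -
                              hbar / 4) / (nbar - 1))
    b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    if (a + b + cc == 0) reason <- "undefined" else fst <- a / (a + b + cc)
  }
  structure(list(fst = fst, estimator = estimator, position = position,
                 n1 = n1, n2 = n2, reason = reason),
            class = "fst_record")
}

#' @export
print.fst_record <- function(x, ...) {
  if (!is.na(x$reason)) cat("Fst undefined (", x$reason, ")\n", sep = "")
  else cat(sprintf("Fst = %.4f (%s estimator, n1 = %d, n2 = %d)\n", x$fst,
                   x$estimator, x$n1, x$n2))
  invisible(x)
}

#' Per-site Fst track between two populations of a panel
#'
#' @param panel a [haplotype_panel()].
#' @param pop1,pop2 population labels.
#' @param estimator see [fst_per_site()].
#' @return data.frame: `position`, `p1`, `p2`, `fst`, `estimator`.
#' @export
fst_scan <- function(panel, pop1, pop2, estimator = "hudson") {
  s1 <- subset_population(panel, pop1)
  s2 <- subset_population(panel, pop2)
  f1 <- derived_freq(s1); f2 <- derived_freq(s2)
  n1 <- nrow(s1$haps); n2 <- nrow(s2$haps)
  fst <- vapply(seq_along(f1), function(j) {
    r <- fst_per_site(f1[j], n1, f2[j], n2, estimator)
    if (is.na(r$reason)) r$fst else NA_real_
  }, numeric(1))
  data.frame(position = panel$positions, p1 = f1, p2 = f2, fst = fst,
             estimator = estimator)
}
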