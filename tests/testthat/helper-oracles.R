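# Independent brute-force oracles, kept deliberately naive: pair enumeration
# for EHH, literal trapezoid sums for integration, direct counting for
# frequencies. They share no code with the implementation under test.

# EHH at every offset by enumerating all C(n,2) carrier pairs and comparing
# the haplotype slices between core and offset.
oracle_ehh <- function(haps, positions, core, allele) {
  car <- which(!is.na(haps[, core]) & haps[, core] == allele)
  S <- ncol(haps)
  ehh_at <- function(j) {
    lo <- min(core, j); hi <- max(core, j)
    seg <- haps[car, lo:hi, drop = FALSE]
    ok <- car[rowSums(is.na(seg)) == 0]
    if (length(ok) < 2) return(0)
    pairs <- combn(length(ok), 2)
    same <- 0
    for (k in seq_len(ncol(pairs))) {
      a <- haps[ok[pairs[1, k]], lo:hi]
      b <- haps[ok[pairs[2, k]], lo:hi]
      if (all(a == b)) same <- same + 1
    }
    same / ncol(pairs)
  }
  list(n_carriers = length(car),
       left = if (core > 1) vapply(rev(seq_len(core - 1)), ehh_at,
                                   numeric(1)) else numeric(0),
       right = if (core < S) vapply((core + 1):S, ehh_at,
                                    numeric(1)) else numeric(0))
}

# iHH with truncation at the cutoff, the gap rule and border exclusion,
# written as a literal walk (no vectorization shared with the package).
oracle_ihh_side <- function(ehh_vals, pos_vals, core_pos, cutoff, gap_limit) {
  total <- 0; prev_e <- 1; prev_p <- core_pos
  for (k in seq_along(ehh_vals)) {
    gap <- abs(pos_vals[k] - prev_p)
    if (gap > gap_limit) return(list(ihh = NA, why = "gap"))
    total <- total + gap * (prev_e + ehh_vals[k]) / 2
    if (ehh_vals[k] < cutoff) return(list(ihh = total, why = NA))
    prev_e <- ehh_vals[k]; prev_p <- pos_vals[k]
  }
  list(ihh = NA, why = "border")
}

# Full per-variant iHS pipeline on a small panel; returns NA and a reason
# whenever the variant would be excluded. Mirrors the documented semantics,
# not the implementation.
oracle_ihs_site <- function(haps, positions, core, maf_min = 0.05,
                            cutoff = 0.05, gap_limit = 20000) {
  f <- mean(haps[, core], na.rm = TRUE)
  if (!(min(f, 1 - f) > maf_min)) return(list(uihs = NA, reason = "maf"))
  calls <- haps[, core][!is.na(haps[, core])]
  if (sum(calls == 0) < 2 || sum(calls == 1) < 2)
    return(list(uihs = NA, reason = "few_carriers"))
  out <- list()
  for (allele in c(0, 1)) {
    o <- oracle_ehh(haps, positions, core, allele)
    lpos <- rev(positions[seq_len(core - 1)])
    rpos <- positions[seq(core + 1, length.out = ncol(haps) - core)]
    l <- oracle_ihh_side(o$left, lpos, positions[core], cutoff, gap_limit)
    if (!is.na(l$why)) return(list(uihs = NA, reason = l$why))
    r <- oracle_ihh_side(o$right, rpos, positions[core], cutoff, gap_limit)
    if (!is.na(r$why)) return(list(uihs = NA, reason = r$why))
    out[[allele + 1]] <- l$ihh + r$ihh
  }
  if (out[[1]] <= 0 || out[[2]] <= 0) return(list(uihs = NA,
                                                  reason = "zero_ihh"))
  list(uihs = log(out[[1]] / out[[2]]), ihh_a = out[[1]], ihh_d = out[[2]],
       reason = NA)
}

# literal trapezoid rule
oracle_trapz <- function(x, y) {
  s <- 0
  for (k in 2:length(x)) s <- s + (x[k] - x[k - 1]) * (y[k] + y[k - 1]) / 2
  s
}

# random small phased panel (no missing data unless asked)
random_panel <- function(n_dip, n_sites, seed, miss_prob = 0,
                         span = 100000) {
  set.seed(seed)
  h <- matrix(rbinom(2 * n_dip * n_sites, 1, runif(n_sites, 0.1, 0.9)),
              nrow = 2 * n_dip, ncol = n_sites, byrow = TRUE)
  if (miss_prob > 0)
    h[matrix(runif(length(h)) < miss_prob, nrow(h))] <- NA
  pos <- sort(sample(span, n_sites))
  haplotype_panel(h, pos, paste0("s", seq_len(n_dip)), rep("P", n_dip))
}

# tiny two-population demography for fast simulator tests
tiny_demography <- function(N = 40, n_gen = 10 * N, mu = 2e-6, rec = 2e-6,
                            L = 50000, sample_n = 10) {
  demography_config(
    pops = data.frame(id = "A", origin = NA, split_gen = 0),
    epochs = data.frame(id = "A", gen = 0, size = N),
    mu = mu, recomb = rec, length_bp = L, n_generations = n_gen,
    samples = c(A = sample_n))
}
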