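as_cpp_args <- function(demography) {
  d <- demography
  ids <- d$pops$id
  origin <- match(d$pops$origin, ids)
  origin[is.na(origin)] <- 0L
  list(n_pops = nrow(d$pops),
       origin = as.integer(origin),
       split_gen = as.integer(d$pops$split_gen),
       epoch_pop = as.integer(match(d$epochs$id, ids)),
       epoch_gen = as.integer(d$epochs$gen),
       epoch_size = as.integer(d$epochs$size),
       migration = d$migration,
       mu = d$mu, rec = d$recomb, L = d$length_bp,
       n_gen = as.integer(d$n_generations),
       sample_sizes = as.integer(ifelse(ids %in% names(d$samples),
                                        d$samples[ids], 0L)))
}

panel_from_cpp <- function(res, demography, chrom) {
  ids <- demography$pops$id
  pops <- ids[res$pop]
  sidx <- seq_len(length(pops) / 2)
  samples <- paste0(pops[2 * sidx - 1], "_", ave(sidx, pops[2 * sidx - 1],
                                                 FUN = seq_along))
  haplotype_panel(res$haps, res$positions, samples, pops[2 * sidx - 1],
                  chrom = chrom)
}

#' Simulate a neutral phased haplotype panel
#'
#' Forward-in-time Wright-Fisher simulation under the given demography:
#' discrete non-overlapping generations, Poisson infinite-sites mutation,
#' Poisson crossovers at uniform positions, multinomial resampling, splits
#' and migration. At the final generation the configured number of diploids
#' is sampled per population; only sites segregating within the combined
#' sample are returned, polarized 0 = ancestral / 1 = derived.
#'
#' The same `(demography, seed)` pair always yields an identical panel.
#'
#' @param demography a [demography_config()].
#' @param seed integer seed for the simulator's own RNG.
#' @param chrom chromosome label for the output panel.
#' @return a [haplotype_panel()].
#' @export
simulate_panel <- function(demography, seed, chrom = "sim1") {
  a <- as_cpp_args(demography)
  res <- wf_simulate_cpp(a$n_pops, a$origin, a$split_gen, a$epoch_pop,
                         a$epoch_gen, a$epoch_size, a$migration, a$mu, a$rec,
                         a$L, a$n_gen, a$sample_sizes,
                         sweep = FALSE, sweep_pos = 0, sel_s = 0, sel_h = 0.5,
                         f0 = 0.5, sweep_pop = 1L, sweep_start = 0L,
                         stop_freq = 0, stop_at_absorption = FALSE,
                         seed = as.integer(seed))
  panel_from_cpp(res, demography, chrom)
}

#' Simulate a panel carrying a selective sweep from standing variation
#'
#' Identical to [simulate_panel()] up to `sweep$start_gen`, when a selected
#' allele is planted at frequency `f0` in the target population; from then on
#' parents in that population are drawn with fitnesses 1, 1 + hs, 1 + s. The
#' allele's full frequency trajectory is returned with the panel. If the
#' allele is lost before sampling the outcome is labelled `"sweep_lost"`
#' (not an error) and the panel reflects the post-loss population.
#'
#' @param demography a [demography_config()].
#' @param sweep a [sweep_config()]; its position must lie inside the
#'   simulated sequence.
#' @param seed integer seed.
#' @param stop_at_absorption stop (and sample) as soon as the allele fixes or
#'   is lost; used by drift-validation harnesses.
#' @param chrom chromosome label.
#' @return a list of class `sweep_panel`: `panel`, `trajectory` (derived
#'   frequency per generation from planting), `outcome` (`"sweep_reached"`,
#'   `"sweep_fixed"`, `"sweep_lost"` or `"sweep_segregating"`),
#'   `final_freq`, `sweep_site` (column index of the selected site in the
#'   panel, `NA` if monomorphic in the sample), `position_bp`, `end_gen`.
#' @export
simulate_sweep_panel <- function(demography, sweep, seed,
                                 stop_at_absorption = FALSE, chrom = "sim1") {
  if (sweep$position_bp <= 0 || sweep$position_bp > demography$length_bp)
    stop("sweep position lies outside the simulated sequence")
  if (!sweep$population %in% demography$pops$id)
    stop("unknown sweep population: ", sweep$population)
  a <- as_cpp_args(demography)
  res <- wf_simulate_cpp(a$n_pops, a$origin, a$split_gen, a$epoch_pop,
                         a$epoch_gen, a$epoch_size, a$migration, a$mu, a$rec,
                         a$L, a$n_gen, a$sample_sizes,
                         sweep = TRUE, sweep_pos = sweep$position_bp - 0.5,
                         sel_s = sweep$s, sel_h = sweep$h, f0 = sweep$f0,
                         sweep_pop = match(sweep$population,
                                           demography$pops$id),
                         sweep_start = as.integer(sweep$start_gen),
                         stop_freq = sweep$stop_freq,
                         stop_at_absorption = stop_at_absorption,
                         seed = as.integer(seed))
  structure(list(panel = panel_from_cpp(res, demography, chrom),
                 trajectory = res$trajectory, outcome = res$outcome,
                 final_freq = res$final_freq, sweep_site = res$sweep_site,
                 position_bp = sweep$position_bp, end_gen = res$end_gen),
            class = "sweep_panel")
}

#' @export
print.sweep_panel <- function(x, ...) {
  cat(sprintf("Sweep simulation: outcome %s, final frequency %.3f (gen %d)\n",
              x$outcome, x$final_freq, x$end_gen))
  print(x$panel)
  invisible(x)
}

#' Mean pairwise nucleotide diversity of a panel
#'
#' Average number of pairwise differences over all haplotype pairs; with a
#' single constant-size population at equilibrium its expectation is
#' theta = 4 N mu L.
#'
#' @param panel a [haplotype_panel()].
#' @return numeric scalar.
#' @export
pairwise_diversity <- function(panel) {
  h <- panel$haps
  n <- nrow(h)
  if (n < 2) return(0)
  f <- colMeans(h, na.rm = TRUE)
  # per-site pairwise difference probability n/(n-1)*2f(1-f), summed
  sum(2 * f * (1 - f) * n / (n - 1))
}
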