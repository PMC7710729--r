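#' Demographic model for the forward simulator
#'
#' Describes a multi-population Wright-Fisher demography: per-population
#' diploid sizes (piecewise constant through `epochs`), population splits,
#' symmetric or asymmetric per-generation migration, and per-bp mutation and
#' recombination rates. Generations count forward from 0 (founding) to
#' `n_generations` (sampling).
#'
#' @param pops data.frame with columns `id` (population label), `origin`
#'   (parent population label, `NA` for founders) and `split_gen` (generation
#'   the population appears; 0 for founders).
#' @param epochs data.frame with columns `id`, `gen`, `size` (diploid size
#'   taking effect at generation `gen`; every population needs an epoch at
#'   its founding generation).
#' @param migration square numeric matrix of per-generation backward
#'   migration rates, dimnames = population ids (`migration[d, s]` is the
#'   probability a parent of a `d` individual comes from `s`). Default: no
#'   migration.
#' @param mu per-bp per-generation mutation rate (infinite-sites).
#' @param recomb per-bp per-generation recombination rate.
#' @param length_bp simulated sequence length in bp.
#' @param n_generations total generations simulated.
#' @param samples named integer vector: diploids sampled per population at
#'   the final generation.
#' @return An object of class `demography_config`.
#' @export
demography_config <- function(pops, epochs, migration = NULL, mu, recomb,
                              length_bp, n_generations, samples) {
  pops <- as.data.frame(pops); epochs <- as.data.frame(epochs)
  stopifnot(all(c("id", "origin", "split_gen") %in% names(pops)),
            all(c("id", "gen", "size") %in% names(epochs)))
  if (length_bp <= 0) stop("sequence length must be > 0")
  if (mu < 0 || recomb < 0) stop("rates must be >= 0")
  if (any(epochs$size < 2)) stop("population sizes must be >= 2")
  if (!all(epochs$id %in% pops$id)) stop("epoch for unknown population")
  if (!all(names(samples) %in% pops$id)) stop("sample for unknown population")
  founders <- is.na(pops$origin)
  if (!any(founders)) stop("at least one founder population required")
  if (any(pops$split_gen[founders] != 0))
    stop("founder populations must have split_gen = 0")
  ch <- pops[!founders, , drop = FALSE]
  if (nrow(ch)) {
    if (any(ch$split_gen <= 0) || any(ch$split_gen > n_generations))
      stop("split generations must lie in (0, n_generations]")
    if (anyDuplicated(ch$split_gen))
      stop("split generations must be strictly ordered (no ties)")
    # a child must split from a population that already exists
    pg <- pops$split_gen[match(ch$origin, pops$id)]
    if (anyNA(pg) || any(pg >= ch$split_gen))
      stop("unreachable split order: parent must exist before the child splits")
  }
  for (i in seq_len(nrow(pops)))
    if (!any(epochs$id == pops$id[i] & epochs$gen == pops$split_gen[i]))
      stop("population ", pops$id[i], " lacks an epoch at its founding generation")
  if (is.null(migration)) {
    migration <- matrix(0, nrow(pops), nrow(pops),
                        dimnames = list(pops$id, pops$id))
  } else {
    migration <- as.matrix(migration)
    if (any(migration < 0)) stop("migration rates must be >= 0")
    if (is.null(dimnames(migration)))
      dimnames(migration) <- list(pops$id, pops$id)
    migration <- migration[pops$id, pops$id, drop = FALSE]
  }
  structure(list(pops = pops, epochs = epochs, migration = migration,
                 mu = mu, recomb = recomb, length_bp = length_bp,
                 n_generations = n_generations,
                 samples = samples),
            class = "demography_config")
}

#' @export
print.demography_config <- function(x, ...) {
  cat("Wright-Fisher demography\n")
  cat(sprintf("  %d population(s), %d generations, L = %s bp\n",
              nrow(x$pops), x$n_generations,
              format(x$length_bp, big.mark = ",")))
  cat(sprintf("  mu = %g /bp/gen, r = %g /bp/gen\n", x$mu, x$recomb))
  for (i in seq_len(nrow(x$pops))) {
    p <- x$pops[i, ]
    sz <- x$epochs$size[x$epochs$id == p$id][1]
    cat(sprintf("  %s: N = %d%s, sampled %d\n", p$id, sz,
                if (is.na(p$origin)) "" else
                  sprintf(", splits from %s at gen %d", p$origin, p$split_gen),
                if (p$id %in% names(x$samples)) x$samples[[p$id]] else 0L))
  }
  invisible(x)
}

#' Selective sweep from standing variation
#'
#' Parameters of a selected allele planted at frequency `f0` in one
#' population: diploid fitnesses 1, 1 + hs, 1 + s for ancestral homozygote,
#' heterozygote and derived homozygote.
#'
#' @param position_bp selected site position (must fall inside the simulated
#'   sequence).
#' @param s selection coefficient (>= 0).
#' @param h dominance coefficient.
#' @param f0 initial derived frequency in (0, 1) (standing variation).
#' @param population target population id.
#' @param start_gen generation at which the allele becomes selected (and is
#'   planted).
#' @param stop_freq if > 0, stop the simulation and sample as soon as the
#'   derived frequency first reaches this value ("sampled near fixation").
#' @return An object of class `sweep_config`.
#' @export
sweep_config <- function(position_bp, s, h = 0.5, f0, population,
                         start_gen, stop_freq = 0) {
  if (f0 <= 0 || f0 >= 1) stop("f0 must lie in (0, 1)")
  if (s < 0) stop("selection coefficient must be >= 0")
  structure(list(position_bp = position_bp, s = s, h = h, f0 = f0,
                 population = population, start_gen = start_gen,
                 stop_freq = stop_freq),
            class = "sweep_config")
}

#' Bundled example demography
#'
#' A deliberately small three-population demography (African-like founder
#' with European-like and Asian-like daughter populations) whose per-bp
#' scaled diversity (theta = 4 N mu) and recombination (rho = 4 N r) match
#' human-like values of about 5e-4 at a reduced population size, so that
#' neutral replicates are cheap while haplotype structure stays realistic.
#' Shipped as `inst/extdata/demography_three_pop.yaml`; this helper reads it
#' (or any config with the same layout).
#'
#' @param file YAML file to read; defaults to the bundled example.
#' @return a [demography_config()].
#' @export
read_demography_yaml <- function(file = system.file("extdata",
                                                    "demography_three_pop.yaml",
                                                    package = "sweepfunc")) {
  y <- yaml::read_yaml(file)
  pops <- do.call(rbind, lapply(y$populations, function(p)
    data.frame(id = p$id,
               origin = if (is.null(p$origin)) NA_character_ else p$origin,
               split_gen = if (is.null(p$split_gen)) 0L else as.integer(p$split_gen))))
  epochs <- do.call(rbind, lapply(y$populations, function(p)
    do.call(rbind, lapply(p$epochs, function(e)
      data.frame(id = p$id, gen = as.integer(e$gen),
                 size = as.integer(e$size))))))
  mig <- NULL
  if (!is.null(y$migration)) {
    ids <- pops$id
    mig <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    for (m in y$migration) mig[m$dest, m$src] <- m$rate
  }
  samples <- setNames(vapply(y$populations, function(p)
    as.integer(if (is.null(p$sample)) 0L else p$sample), integer(1)), pops$id)
  demography_config(pops, epochs, mig, mu = y$mu, recomb = y$recomb,
                    length_bp = as.numeric(y$length_bp),
                    n_generations = as.integer(y$n_generations),
                    samples = samples[samples > 0])
}
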