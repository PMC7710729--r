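#' Remove low-frequency sites
#'
#' Keeps only sites whose minor allele frequency is strictly greater than
#' `maf_min` (sites at exactly `maf_min` are removed). Site order is
#' preserved.
#'
#' @param panel a [haplotype_panel()].
#' @param maf_min minor-allele-frequency threshold (default 0.05).
#' @return the filtered [haplotype_panel()]; warns if no site survives.
#' @export
filter_sites <- function(panel, maf_min = 0.05) {
  f <- derived_freq(panel)
  maf <- pmin(f, 1 - f)
  keep <- !is.na(maf) & maf > maf_min
  if (!any(keep)) warning("no site passes the MAF filter")
  haplotype_panel(panel$haps[, keep, drop = FALSE], panel$positions[keep],
                  panel$samples, panel$populations, panel$chrom)
}

#' Extended haplotype homozygosity curve around a core site
#'
#' For carriers of the chosen core allele, EHH at an offset site is the
#' fraction of carrier pairs whose haplotypes are identical over the whole
#' interval between the core and that site, computed separately leftward and
#' rightward. Haplotypes with a missing call inside the interval drop out of
#' the pair count from that offset outward. EHH is 1 at the core by
#' definition and non-increasing outward.
#'
#' @param panel a [haplotype_panel()].
#' @param core site index (column) of the core SNP.
#' @param allele `"ancestral"` (0) or `"derived"` (1) core allele class.
#' @param stop_below stop extending the curve once EHH drops below this
#'   value (0 = full curve to the panel edge).
#' @return An object of class `ehh_curve` with fields `core`, `core_pos`,
#'   `allele`, `n_carriers`, `offset_bp` (signed offsets, 0 included),
#'   `position` and `ehh`; or, with fewer than two carriers, the same object
#'   with `defined = FALSE`.
#' @export
compute_ehh <- function(panel, core, allele = c("derived", "ancestral"),
                        stop_below = 0) {
  allele <- match.arg(allele)
  a <- if (allele == "derived") 1L else 0L
  res <- ehh_curve_cpp(panel$haps, panel$positions, as.integer(core), a,
                       stop_below)
  defined <- res$n_carriers >= 2
  pos <- c(rev(res$left_pos), res$core_pos, res$right_pos)
  ehh <- c(rev(res$left_ehh), 1, res$right_ehh)
  structure(list(core = core, core_pos = res$core_pos, allele = allele,
                 n_carriers = res$n_carriers, defined = defined,
                 offset_bp = pos - res$core_pos, position = pos,
                 ehh = ehh,
                 hit_edge = c(left = res$left_edge, right = res$right_edge)),
            class = "ehh_curve")
}

#' @export
print.ehh_curve <- function(x, ...) {
  cat(sprintf("EHH curve: core site %d (%s allele, %d carriers)%s\n",
              x$core, x$allele, x$n_carriers,
              if (x$defined) "" else " -- undefined (<2 carriers)"))
  if (x$defined)
    cat(sprintf("  span %d bp left, %d bp right\n",
                -min(x$offset_bp), max(x$offset_bp)))
  invisible(x)
}

#' @export
plot.ehh_curve <- function(x, ...) {
  plot(x$offset_bp, x$ehh, type = "l", xlab = "offset from core (bp)",
       ylab = "EHH", ylim = c(0, 1), ...)
  abline(v = 0, lty = 3)
  invisible(x)
}

#' Integrated haplotype homozygosity (iHH) of an EHH curve
#'
#' Trapezoidal integral of EHH over physical distance, each side truncated
#' at the first offset where EHH drops below `ehh_cutoff` (the trapezoid
#' reaching that offset is included). If, before truncation, two adjacent
#' curve sites are more than `gap_limit_bp` apart, the variant is excluded
#' (a typed outcome, not an error).
#'
#' If a side reaches the panel border while EHH is still at or above the
#' cutoff, the integral is undefined there and the variant is excluded
#' (`"border"`), the convention of the standard EHH software.
#'
#' @param curve an [compute_ehh()] result (computed with
#'   `stop_below <= ehh_cutoff`, e.g. the default full curve).
#' @param ehh_cutoff EHH truncation level (default 0.05).
#' @param gap_limit_bp maximum tolerated gap between adjacent informative
#'   sites (default 20000, i.e. the 20 kb rule).
#' @param border `"exclude"` (default): a side reaching the panel border
#'   with EHH at or above the cutoff invalidates the variant;
#'   `"truncate"`: the integral over the observable span is used instead.
#'   Truncation is appropriate for short simulated panels, where the
#'   exclusion rule would remove a large share of variants (see the
#'   methods vignette); on genome-scale data the two differ only at
#'   chromosome ends.
#' @return list with `ihh` (bp), `excluded` (logical) and `reason`
#'   (`NA`, `"few_carriers"`, `"gap"` or `"border"`).
#' @export
compute_ihh <- function(curve, ehh_cutoff = 0.05, gap_limit_bp = 20000,
                        border = c("exclude", "truncate")) {
  border <- match.arg(border)
  if (!curve$defined)
    return(list(ihh = NA_real_, excluded = TRUE, reason = "few_carriers"))
  side <- function(sel, dir, edge) {
    ord <- order(dir * curve$position[sel])
    pos <- curve$position[sel][ord]
    ehh <- curve$ehh[sel][ord]
    if (!length(pos))
      return(if (edge && border == "exclude")
               list(ihh = NA_real_, why = "border")
             else list(ihh = 0, why = NA))
    gaps <- abs(diff(c(curve$core_pos, pos)))
    trap <- gaps * (c(1, ehh[-length(ehh)]) + ehh) / 2
    below <- which(ehh < ehh_cutoff)
    if (!length(below) && edge && border == "exclude")
      return(list(ihh = NA_real_, why = "border"))
    k0 <- if (length(below)) below[1] else length(ehh)
    if (any(gaps[seq_len(k0)] > gap_limit_bp))
      return(list(ihh = NA_real_, why = "gap"))
    list(ihh = sum(trap[seq_len(k0)]), why = NA)
  }
  l <- side(curve$offset_bp < 0, -1, curve$hit_edge[["left"]])
  if (!is.na(l$why))
    return(list(ihh = NA_real_, excluded = TRUE, reason = l$why))
  r <- side(curve$offset_bp > 0, +1, curve$hit_edge[["right"]])
  if (!is.na(r$why))
    return(list(ihh = NA_real_, excluded = TRUE, reason = r$why))
  list(ihh = l$ihh + r$ihh, excluded = FALSE, reason = NA_character_)
}

#' Unstandardized iHS
#'
#' Log-ratio of the ancestral to the derived integrated haplotype
#' homozygosity, `ln(iHH_A / iHH_D)`. Positive values indicate extended
#' homozygosity around the ancestral allele; sweeps on the derived allele
#' push the score negative.
#'
#' @param ihh_a,ihh_d integrated EHH for ancestral and derived carriers.
#' @return numeric; `NA` if either integral is not strictly positive.
#' @export
unstandardized_ihs <- function(ihh_a, ihh_d) {
  out <- ifelse(is.na(ihh_a) | is.na(ihh_d) | ihh_a <= 0 | ihh_d <= 0,
                NA_real_, log(ihh_a / ihh_d))
  out
}

#' Per-SNP iHS scan of a panel
#'
#' Runs the full per-variant computation: MAF filter (strictly greater than
#' `maf_min`), EHH curves for both core allele classes, iHH integration with
#' the gap rule, and the unstandardized score. Standardization is a separate
#' step ([standardize_ihs()]) so that a common reference can be reused
#' across panels.
#'
#' @param panel a [haplotype_panel()] (typically one population,
#'   [subset_population()]).
#' @param maf_min minor-allele-frequency cutoff (sites at or below are
#'   flagged, not scored).
#' @param ehh_cutoff EHH truncation level for the integration.
#' @param gap_limit_bp adjacent-site gap beyond which a variant is excluded.
#' @param border panel-border handling, `"exclude"` or `"truncate"`; see
#'   [compute_ihh()].
#' @return data.frame of class `ihs_scan` with one row per site: `position`,
#'   `freq` (derived), `ihh_a`, `ihh_d`, `uihs`, `excluded`, `reason`.
#' @export
ihs_scan <- function(panel, maf_min = 0.05, ehh_cutoff = 0.05,
                     gap_limit_bp = 20000,
                     border = c("exclude", "truncate")) {
  border <- match.arg(border)
  res <- ihs_scan_cpp(panel$haps, panel$positions, maf_min, ehh_cutoff,
                      gap_limit_bp, border == "exclude")
  out <- data.frame(position = panel$positions, freq = res$freq,
                    ihh_a = res$ihh_a, ihh_d = res$ihh_d, uihs = res$uihs,
                    excluded = res$code != 0,
                    reason = c(NA, "maf", "few_carriers", "gap",
                               "zero_ihh", "border")[res$code + 1])
  class(out) <- c("ihs_scan", "data.frame")
  attr(out, "chrom") <- panel$chrom
  attr(out, "params") <- list(maf_min = maf_min, ehh_cutoff = ehh_cutoff,
                              gap_limit_bp = gap_limit_bp, border = border)
  out
}

#' Standardize iHS within derived-allele-frequency bins
#'
#' Within each frequency bin, `iHS = (uiHS - bin mean) / bin sd`, removing
#' the systematic dependence of the raw log-ratio on allele frequency. Bins
#' with fewer than two scored records or zero spread cannot be standardized;
#' their records are flagged excluded rather than merged into neighbours.
#'
#' A `reference` (the `bin_stats` of another standardization, typically from
#' neutral simulations) can be supplied so that a candidate panel is scored
#' against the neutral background instead of against itself; records whose
#' bin is absent from the reference use the nearest reference bin.
#'
#' @param records an [ihs_scan()] result (or data.frame with `freq`,
#'   `uihs`, `excluded`).
#' @param bin_width derived-frequency bin width (default 0.05).
#' @param reference optional `bin_stats` data.frame (`bin`, `mean`, `sd`).
#' @return the records with columns `bin`, `ihs` added (class
#'   `ihs_scores`); attribute `bin_stats` holds the per-bin mean/sd used.
#' @export
standardize_ihs <- function(records, bin_width = 0.05, reference = NULL) {
  records$bin <- pmin(floor(records$freq / bin_width),
                      ceiling(1 / bin_width) - 1)
  records$ihs <- NA_real_
  ok <- !records$excluded & !is.na(records$uihs)
  if (is.null(reference)) {
    stats <- do.call(rbind, lapply(split(records$uihs[ok], records$bin[ok]),
                                   function(v) data.frame(n = length(v),
                                                          mean = mean(v),
                                                          sd = sd(v))))
    if (is.null(stats))
      stats <- data.frame(n = integer(), mean = numeric(), sd = numeric())
    stats$bin <- as.integer(rownames(stats))
    usable <- stats$n >= 2 & !is.na(stats$sd) & stats$sd > 0
    stats <- stats[, c("bin", "n", "mean", "sd")]
    ref <- stats[usable, , drop = FALSE]
  } else {
    stats <- ref <- reference
  }
  if (nrow(ref)) {
    idx <- vapply(records$bin, function(b)
      which.min(abs(ref$bin - b)), integer(1))
    exact_needed <- is.null(reference)   # self-standardization: bin must match
    match_ok <- if (exact_needed) ref$bin[idx] == records$bin else TRUE
    z <- (records$uihs - ref$mean[idx]) / ref$sd[idx]
    records$ihs[ok & match_ok] <- z[ok & match_ok]
  }
  flag <- ok & is.na(records$ihs)
  records$excluded[flag] <- TRUE
  records$reason[flag] <- "bin"
  class(records) <- c("ihs_scores", class(records))
  attr(records, "bin_stats") <- stats
  attr(records, "bin_width") <- bin_width
  records
}

#' Aggregate standardized iHS into non-overlapping 30 kb windows
#'
#' Windows tile the chromosome from coordinate 0 in half-open intervals
#' `[k w, (k+1) w)`; a 1-based position `p` falls in window
#' `floor((p - 1)/w)`. Windows without any scored SNP are omitted. Both the
#' absolute value of the mean iHS and the mean of absolute iHS are computed;
#' `score` selects which one is reported as the window score.
#'
#' @param records an [standardize_ihs()] result.
#' @param window_bp window width (default 30000).
#' @param score `"abs-of-mean"` (default; |mean iHS|) or `"mean-of-abs"`.
#' @param min_snps minimum scored SNPs for a window to be emitted.
#' @return data.frame of class `window_scores`: `chrom`, `start` (0-based),
#'   `end`, `n_snps`, `mean_ihs`, `abs_mean`, `mean_abs`, `score`.
#' @export
window_scan <- function(records, window_bp = 30000,
                        score = c("abs-of-mean", "mean-of-abs"),
                        min_snps = 1) {
  score <- match.arg(score)
  ok <- !records$excluded & !is.na(records$ihs)
  r <- records[ok, , drop = FALSE]
  win <- floor((r$position - 1) / window_bp)
  agg <- lapply(split(seq_len(nrow(r)), win), function(i) {
    data.frame(n_snps = length(i), mean_ihs = mean(r$ihs[i]),
               mean_abs = mean(abs(r$ihs[i])))
  })
  out <- do.call(rbind, agg)
  if (is.null(out)) out <- data.frame(n_snps = integer(), mean_ihs = numeric(),
                                      mean_abs = numeric())
  w <- as.numeric(names(agg))
  out <- data.frame(chrom = rep(attr(records, "chrom") %||% "1", nrow(out)),
                    start = w * window_bp, end = (w + 1) * window_bp,
                    out, row.names = NULL)
  out$abs_mean <- abs(out$mean_ihs)
  out$score <- if (score == "abs-of-mean") out$abs_mean else out$mean_abs
  out <- out[out$n_snps >= min_snps, , drop = FALSE]
  attr(out, "score_type") <- score
  class(out) <- c("window_scores", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Empirical critical value from a neutral window-score distribution
#'
#' Linear-interpolation empirical percentile (quantile type 7) of the
#' neutral window scores; the conventional choice is the 99.99th percentile.
#'
#' @param scores numeric vector of neutral window scores.
#' @param percentile percentile in (0, 100].
#' @return list of class `null_threshold`: `critical`, `percentile`, `n`.
#' @export
null_threshold <- function(scores, percentile = 99.99) {
  scores <- scores[!is.na(scores)]
  if (!length(scores)) stop("no window scores supplied")
  if (length(scores) < 1e4 && percentile >= 99.99)
    warning("fewer than 10^4 window scores: the ", percentile,
            "th percentile is poorly resolved")
  structure(list(critical = unname(quantile(scores, percentile / 100,
                                            type = 7)),
                 percentile = percentile, n = length(scores)),
            class = "null_threshold")
}

#' @export
print.null_threshold <- function(x, ...) {
  cat(sprintf("Neutral critical value: %.4f (%.2fth percentile of %d windows)\n",
              x$critical, x$percentile, x$n))
  invisible(x)
}

#' Call candidate windows above a neutral critical value
#'
#' @param windows a [window_scan()] result.
#' @param threshold a [null_threshold()] object or numeric critical value.
#' @return the windows data.frame with logical `called` and the `threshold`
#'   used; rows with `score > threshold` are candidates.
#' @export
call_candidates <- function(windows, threshold) {
  crit <- if (inherits(threshold, "null_threshold")) threshold$critical
          else as.numeric(threshold)
  windows$threshold <- crit
  windows$called <- windows$score > crit
  windows
}

#' Build the neutral null distribution of window scores
#'
#' Simulates `reps` neutral replicates of `demography`, scans the target
#' population of each, pools the unstandardized scores across replicates,
#' standardizes them jointly within frequency bins (the genome-wide
#' standardization that a single long chromosome would give), aggregates
#' into windows per replicate and records the empirical critical value.
#'
#' @param demography a [demography_config()].
#' @param reps number of neutral replicates.
#' @param seed base seed; replicate `i` uses `seed + i`.
#' @param scan_pop population to scan (default: first configured sample).
#' @param percentile critical percentile (default 99.99).
#' @param maf_min,ehh_cutoff,gap_limit_bp,bin_width,window_bp,score,min_snps
#'   scan parameters, see [ihs_scan()], [standardize_ihs()],
#'   [window_scan()].
#' @return list of class `ihs_null`: `window_scores` (numeric), `threshold`
#'   (a [null_threshold()]), `bin_stats` (reference for standardizing other
#'   panels), `windows` (full per-window table), `reps`, `seed`, `params`.
#' @export
neutral_null <- function(demography, reps, seed, scan_pop = NULL,
                         percentile = 99.99, maf_min = 0.05,
                         ehh_cutoff = 0.05, gap_limit_bp = 20000,
                         bin_width = 0.05, window_bp = 30000,
                         score = "abs-of-mean", min_snps = 1,
                         border = "exclude") {
  if (is.null(scan_pop)) scan_pop <- names(demography$samples)[1]
  scans <- vector("list", reps)
  for (i in seq_len(reps)) {
    panel <- simulate_panel(demography, seed = seed + i)
    sub <- subset_population(panel, scan_pop, drop_monomorphic = TRUE)
    sc <- ihs_scan(sub, maf_min = maf_min, ehh_cutoff = ehh_cutoff,
                   gap_limit_bp = gap_limit_bp, border = border)
    sc$rep <- i
    scans[[i]] <- sc
  }
  pooled <- do.call(rbind, scans)
  attr(pooled, "chrom") <- "null"
  std <- standardize_ihs(pooled, bin_width = bin_width)
  winlist <- lapply(split(std, std$rep), function(r) {
    attr(r, "chrom") <- paste0("rep", r$rep[1])
    attr(r, "bin_stats") <- attr(std, "bin_stats")
    window_scan(r, window_bp = window_bp, score = score, min_snps = min_snps)
  })
  windows <- do.call(rbind, winlist)
  thr <- null_threshold(windows$score, percentile)
  thr_both <- suppressWarnings(list(
    `abs-of-mean` = null_threshold(windows$abs_mean, percentile),
    `mean-of-abs` = null_threshold(windows$mean_abs, percentile)))
  bs <- attr(std, "bin_stats")
  bs <- bs[bs$n >= 2 & !is.na(bs$sd) & bs$sd > 0, , drop = FALSE]
  structure(list(window_scores = windows$score, threshold = thr,
                 thresholds = thr_both,
                 bin_stats = bs, windows = windows, reps = reps, seed = seed,
                 scan_pop = scan_pop,
                 params = list(percentile = percentile, maf_min = maf_min,
                               ehh_cutoff = ehh_cutoff,
                               gap_limit_bp = gap_limit_bp,
                               bin_width = bin_width, window_bp = window_bp,
                               score = score, min_snps = min_snps,
                               border = border)),
            class = "ihs_null")
}

#' @export
print.ihs_null <- function(x, ...) {
  cat(sprintf("Neutral iHS null: %d replicates, %d windows\n", x$reps,
              length(x$window_scores)))
  print(x$threshold)
  invisible(x)
}

#' Detection power for planted sweeps
#'
#' Repeatedly simulates a sweep panel conditioned on the selected allele
#' surviving (replicates where it is lost are labelled `sweep_lost` and
#' redrawn with a fresh sub-seed, up to `max_attempts` each), scans the
#' target population, standardizes against the neutral `null`'s bin
#' statistics, and asks whether the window overlapping the selected site is
#' called above the null critical value.
#'
#' @param demography a [demography_config()].
#' @param sweep a [sweep_config()].
#' @param null an [neutral_null()] result (threshold + reference bins).
#' @param reps number of conditioned sweep replicates.
#' @param seed base seed.
#' @param max_attempts resampling attempts per replicate before giving up.
#' @return list of class `sweep_power`: `power`, `detected` (logical per
#'   replicate), `final_freq`, `attempts`, `neutral_call_rate` (fraction of
#'   null windows above the threshold, approximately
#'   `1 - percentile/100` by construction).
#' @export
sweep_power <- function(demography, sweep, null, reps, seed,
                        max_attempts = 60) {
  p <- null$params
  detected <- logical(reps)
  ffreq <- numeric(reps)
  attempts <- integer(reps)
  for (i in seq_len(reps)) {
    sp <- NULL
    for (a in seq_len(max_attempts)) {
      cand <- simulate_sweep_panel(demography, sweep,
                                   seed = seed + i * 1000L + a)
      attempts[i] <- a
      if (cand$outcome != "sweep_lost") { sp <- cand; break }
    }
    if (is.null(sp)) stop("sweep lost in every attempt of replicate ", i)
    sub <- subset_population(sp$panel, sweep$population,
                             drop_monomorphic = TRUE)
    sc <- ihs_scan(sub, maf_min = p$maf_min, ehh_cutoff = p$ehh_cutoff,
                   gap_limit_bp = p$gap_limit_bp, border = p$border)
    std <- standardize_ihs(sc, bin_width = p$bin_width,
                           reference = null$bin_stats)
    win <- window_scan(std, window_bp = p$window_bp, score = p$score,
                       min_snps = p$min_snps)
    win <- call_candidates(win, null$threshold)
    hit <- win$called & win$start < sweep$position_bp &
      win$end >= sweep$position_bp
    detected[i] <- any(hit)
    ffreq[i] <- sp$final_freq
  }
  structure(list(power = mean(detected), detected = detected,
                 final_freq = ffreq, attempts = attempts,
                 neutral_call_rate = mean(null$window_scores >
                                            null$threshold$critical)),
            class = "sweep_power")
}

#' @export
print.sweep_power <- function(x, ...) {
  cat(sprintf("Sweep detection power: %.2f (%d replicates)\n", x$power,
              length(x$detected)))
  cat(sprintf("  neutral windows called at rate %.2g\n",
              x$neutral_call_rate))
  invisible(x)
}
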