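make_panel <- function(h, pos = NULL) {
  h <- as.matrix(h)
  if (is.null(pos)) pos <- seq_len(ncol(h)) * 1000
  haplotype_panel(h, pos, paste0("s", seq_len(nrow(h) / 2)),
                  rep("P", nrow(h) / 2))
}

test_that("the MAF filter is strict: sites at exactly the cutoff are removed", {
  h <- cbind(rep(0, 20),                       # monomorphic
             c(rep(1, 1), rep(0, 19)),         # maf 0.05 -> removed
             c(rep(1, 2), rep(0, 18)),         # maf 0.10 -> kept
             c(rep(1, 10), rep(0, 10)))        # maf 0.50 -> kept
  pan <- make_panel(h)
  flt <- filter_sites(pan, maf_min = 0.05)
  expect_equal(flt$positions, c(3000, 4000))
  expect_warning(filter_sites(make_panel(cbind(rep(0, 20)))), "MAF")
})

test_that("MAF filtering equals a direct per-site count oracle", {
  for (seed in 1:5) {
    pan <- random_panel(15, 30, seed)
    flt <- filter_sites(pan, 0.05)
    f <- colMeans(pan$haps)
    keep <- pmin(f, 1 - f) > 0.05
    expect_equal(flt$positions, pan$positions[keep])
    expect_equal(flt$haps, pan$haps[, keep, drop = FALSE])
  }
})

test_that("EHH is 1 along identical carrier haplotypes and drops to 0 on a difference", {
  # all derived carriers share one extended haplotype
  h <- rbind(matrix(c(1, 1, 0, 1, 0), 4, 5, byrow = TRUE),
             matrix(c(0, 0, 1, 0, 1), 4, 5, byrow = TRUE))
  cv <- compute_ehh(make_panel(h), 1, "derived")
  expect_true(all(cv$ehh == 1))

  # two carriers differing at the adjacent site: EHH 0 from there outward
  h2 <- rbind(c(1, 0, 0, 0), c(1, 1, 0, 0), c(0, 0, 0, 0), c(0, 0, 0, 0))
  cv2 <- compute_ehh(make_panel(h2), 1, "derived")
  expect_equal(cv2$ehh[cv2$offset_bp > 0], c(0, 0, 0))
  expect_equal(cv2$ehh[cv2$offset_bp == 0], 1)
})

test_that("EHH curves equal brute-force pair enumeration on small panels", {
  for (seed in c(3, 8, 21)) {
    pan <- random_panel(4, 12, seed, miss_prob = 0.1)   # 8 haplotypes
    for (core in c(2, 6, 11)) {
      for (al in c("ancestral", "derived")) {
        a <- if (al == "derived") 1 else 0
        o <- oracle_ehh(pan$haps, pan$positions, core, a)
        if (o$n_carriers < 2) {
          expect_false(compute_ehh(pan, core, al)$defined)
          next
        }
        # the walker stops once fewer than two carriers remain alive; the
        # oracle keeps recording zeros (EHH cannot recover outward), so
        # compare the shared range and require the oracle tail to be zero
        cv <- compute_ehh(pan, core, al)
        left <- rev(cv$ehh[cv$offset_bp < 0])
        right <- cv$ehh[cv$offset_bp > 0]
        expect_equal(left, o$left[seq_along(left)], tolerance = 1e-12)
        expect_equal(right, o$right[seq_along(right)], tolerance = 1e-12)
        expect_true(all(o$left[-seq_along(left)] == 0))
        expect_true(all(o$right[-seq_along(right)] == 0))
      }
    }
  }
})

test_that("EHH curves are bounded in [0,1] and non-increasing outward", {
  for (seed in 1:5) {
    pan <- random_panel(10, 25, seed)
    for (core in c(5, 13, 20)) {
      cv <- compute_ehh(pan, core, "derived")
      if (!cv$defined) next
      expect_true(all(cv$ehh >= 0 & cv$ehh <= 1))
      right <- cv$ehh[cv$offset_bp >= 0]
      left <- rev(cv$ehh[cv$offset_bp <= 0])
      expect_true(all(diff(right) <= 1e-12))
      expect_true(all(diff(left) <= 1e-12))
    }
  }
})

test_that("iHH of a symmetric tent curve is the exact trapezoid area", {
  h3 <- cbind(c(1, 0, 0, 0), rep(c(1, 0), 2), c(1, 1, 0, 0),
              rep(c(1, 0), 2), c(1, 0, 0, 0))
  pan3 <- make_panel(rbind(h3, h3),
                     c(5000, 10000, 20000, 30000, 35000))
  cv3 <- compute_ehh(pan3, 3, "derived")
  ih3 <- compute_ihh(cv3, ehh_cutoff = 0.5, gap_limit_bp = 2e4)
  expect_false(ih3$excluded)
  # EHH 1 at core; 0.333 at +-10 kb (below cutoff 0.5): trapezoid each side
  expect_equal(ih3$ihh, 2 * 10000 * (1 + 1 / 3) / 2, tolerance = 1e-9)
})

test_that("a gap over 20 kb between informative sites excludes the variant", {
  h <- cbind(c(1, 0, 0, 0, 0, 0),   # left neighbour splits the carriers
             c(1, 1, 0, 0, 0, 0),   # core: carriers are haplotypes 1, 2
             c(1, 1, 0, 0, 0, 0),   # 26 kb away: crossed before truncation
             c(1, 0, 0, 1, 1, 0))   # splits the carriers: truncation point
  pan <- make_panel(h, c(1000, 5000, 31000, 40000))
  cv <- compute_ehh(pan, 2, "derived")
  ih <- compute_ihh(cv, ehh_cutoff = 0.05, gap_limit_bp = 20000)
  expect_true(ih$excluded)
  expect_equal(ih$reason, "gap")
  # widening the allowed gap clears the exclusion
  ih2 <- compute_ihh(cv, ehh_cutoff = 0.05, gap_limit_bp = 30000)
  expect_false(ih2$excluded)
})

test_that("iHH equals a dense-grid trapezoid of the piecewise-linear curve", {
  for (seed in c(2, 9)) {
    pan <- random_panel(8, 20, seed)
    for (core in c(8, 12)) {
      cv <- compute_ehh(pan, core, "ancestral")
      if (!cv$defined) next
      ih <- compute_ihh(cv, ehh_cutoff = 0.05, gap_limit_bp = 1e9)
      if (ih$excluded) next
      # oracle: piecewise-linear interpolation on a ~1 bp grid
      dense_side <- function(sel, dir) {
        ord <- order(dir * cv$position[sel])
        p <- c(cv$core_pos, cv$position[sel][ord])
        e <- c(1, cv$ehh[sel][ord])
        below <- which(e < 0.05)
        k <- if (length(below)) below[1] else length(e)
        p <- p[1:k]; e <- e[1:k]
        if (length(p) < 2) return(0)
        grid <- seq(min(p), max(p), length.out = 20001)
        vals <- approx(p, e, xout = grid)$y
        oracle_trapz(grid, vals)
      }
      dense <- dense_side(cv$offset_bp < 0, -1) +
        dense_side(cv$offset_bp > 0, 1)
      expect_equal(ih$ihh, dense, tolerance = 1e-6)
    }
  }
})

test_that("the unstandardized score is the log ratio of the two integrals", {
  expect_equal(unstandardized_ihs(5, 5), 0)
  expect_equal(unstandardized_ihs(exp(1) * 3, 3), 1)
  expect_true(is.na(unstandardized_ihs(0, 3)))
  set.seed(4)
  a <- runif(20, 1, 100); d <- runif(20, 1, 100)
  expect_equal(unstandardized_ihs(a, d), log(a) - log(d), tolerance = 1e-12)
})

test_that("the full per-site scan matches the independent brute-force pipeline", {
  for (seed in c(1, 5, 12)) {
    pan <- random_panel(8, 20, seed)          # 16 haplotypes, 20 sites
    sc <- ihs_scan(pan, maf_min = 0.05, ehh_cutoff = 0.05,
                   gap_limit_bp = 20000)
    for (j in seq_len(20)) {
      o <- oracle_ihs_site(pan$haps, pan$positions, j)
      if (is.na(o$uihs)) {
        expect_true(sc$excluded[j])
        expect_equal(sc$reason[j], o$reason)
      } else {
        expect_false(sc$excluded[j])
        expect_equal(sc$uihs[j], o$uihs, tolerance = 1e-9)
        expect_equal(sc$ihh_a[j], o$ihh_a, tolerance = 1e-9)
        expect_equal(sc$ihh_d[j], o$ihh_d, tolerance = 1e-9)
      }
    }
  }
})

test_that("the scan is invariant under haplotype row permutation", {
  pan <- random_panel(10, 25, 33)
  sc1 <- ihs_scan(pan)
  set.seed(1)
  perm <- sample(nrow(pan$haps))
  pan2 <- haplotype_panel(pan$haps[perm, ], pan$positions,
                          pan$samples, pan$populations)
  sc2 <- ihs_scan(pan2)
  expect_equal(sc1$uihs, sc2$uihs)
  expect_equal(sc1$ihh_a, sc2$ihh_a)
})

test_that("standardization centers and scales each occupied frequency bin", {
  set.seed(6)
  rec <- data.frame(position = (1:200) * 500,
                    freq = runif(200, 0.06, 0.94),
                    uihs = rnorm(200), excluded = FALSE, reason = NA)
  std <- standardize_ihs(rec, bin_width = 0.05)
  for (b in unique(std$bin[!std$excluded])) {
    z <- std$ihs[std$bin == b & !std$excluded]
    if (length(z) < 2) next
    expect_equal(mean(z), 0, tolerance = 1e-12)
    expect_equal(sd(z), 1, tolerance = 1e-12)
  }
})

test_that("bins with a single record are flagged, not scored", {
  rec <- data.frame(position = c(1000, 2000, 3000),
                    freq = c(0.32, 0.33, 0.61),
                    uihs = c(0.5, -0.2, 1.1), excluded = FALSE, reason = NA)
  std <- standardize_ihs(rec, bin_width = 0.05)
  expect_true(std$excluded[3])
  expect_equal(std$reason[3], "bin")
  expect_true(all(!std$excluded[1:2]))
})

test_that("two-bin toy standardization reproduces hand-computed z-scores", {
  rec <- data.frame(position = (1:4) * 1000,
                    freq = c(0.12, 0.13, 0.62, 0.63),
                    uihs = c(1, 3, -2, 4), excluded = FALSE, reason = NA)
  std <- standardize_ihs(rec, bin_width = 0.05)
  expect_equal(std$ihs[1:2], c((1 - 2) / sd(c(1, 3)), (3 - 2) / sd(c(1, 3))))
  expect_equal(std$ihs[3:4], c((-2 - 1) / sd(c(-2, 4)), (4 - 1) / sd(c(-2, 4))))
})

test_that("a reference standardization reuses the null bins", {
  ref <- data.frame(bin = c(2, 12), n = c(50, 50), mean = c(1, -1),
                    sd = c(2, 0.5))
  rec <- data.frame(position = c(1000, 2000), freq = c(0.13, 0.64),
                    uihs = c(3, 0), excluded = FALSE, reason = NA)
  std <- standardize_ihs(rec, bin_width = 0.05, reference = ref)
  expect_equal(std$ihs, c((3 - 1) / 2, (0 + 1) / 0.5))
})

test_that("window aggregation tiles from zero and reports both score variants", {
  rec <- data.frame(position = c(10, 29999, 30001, 59000),
                    freq = 0.5, uihs = 0, excluded = FALSE, reason = NA,
                    ihs = c(2, 3, -2, 2), bin = 9)
  class(rec) <- c("ihs_scores", "data.frame")
  w <- window_scan(rec, window_bp = 30000)
  expect_equal(w$start, c(0, 30000))
  expect_equal(w$mean_ihs, c(2.5, 0))
  expect_equal(w$score, c(2.5, 0))          # |mean| default
  expect_equal(w$mean_abs, c(2.5, 2))       # the alternative is reported too
  w2 <- window_scan(rec, window_bp = 30000, score = "mean-of-abs")
  expect_equal(w2$score, c(2.5, 2))
})

test_that("window grouping matches a brute-force per-window oracle", {
  set.seed(14)
  rec <- data.frame(position = sort(sample(1:150000, 120)),
                    freq = 0.5, uihs = 0, excluded = FALSE, reason = NA,
                    ihs = rnorm(120), bin = 9)
  rec$excluded[sample(120, 10)] <- TRUE
  class(rec) <- c("ihs_scores", "data.frame")
  w <- window_scan(rec, window_bp = 30000)
  for (i in seq_len(nrow(w))) {
    sel <- !rec$excluded & rec$position > w$start[i] &
      rec$position <= w$end[i]     # 1-based positions in [start+1, end]
    expect_equal(w$n_snps[i], sum(sel))
    expect_equal(w$mean_ihs[i], mean(rec$ihs[sel]))
  }
})

test_that("the empirical threshold interpolates order statistics", {
  thr <- suppressWarnings(null_threshold(1:10000, 50))
  expect_equal(thr$critical, 5000.5)
  expect_equal(suppressWarnings(null_threshold(1:10000, 100))$critical,
               10000)
  expect_error(null_threshold(numeric(0)), "no window scores")
  expect_warning(null_threshold(1:100, 99.99), "10\\^4")
  # monotone in the percentile
  set.seed(2)
  x <- rnorm(5000)
  crits <- vapply(c(90, 99, 99.9, 99.99), function(p)
    suppressWarnings(null_threshold(x, p))$critical, numeric(1))
  expect_true(all(diff(crits) > 0))
})

test_that("candidate calling is a strict threshold on the window score", {
  w <- data.frame(start = c(0, 30000), end = c(30000, 60000),
                  score = c(1.2, 3.1), n_snps = c(5, 8))
  cc <- call_candidates(w, 5)
  expect_false(any(cc$called))
  cc2 <- call_candidates(w, 2)
  expect_equal(cc2$called, c(FALSE, TRUE))
  expect_equal(cc2$threshold, c(2, 2))
})
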