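spec_452 <- parse_pair_spec("A:390:OD1,OD2-A:452:NZ")
spec_455 <- parse_pair_spec("A:390:OD1,OD2-A:455:NZ")

test_that("pair spec strings parse into atoms and a reduction rule", {
  expect_equal(spec_452$side_a$atom, c("OD1", "OD2"))
  expect_equal(spec_452$side_b$resno, 452)
  expect_equal(spec_452$reduce, "min")
  expect_error(parse_pair_spec("A:390:OD1"), "two sides")
})

test_that("toy ensembles round-trip distances through PDB files", {
  dir <- withr::local_tempdir()
  spec <- ensemble_spec(20, list(D390_K452 = list(mean = 6, sd = 1.5),
                                 D390_K455 = list(mean = 9, sd = 2)),
                        seed = 3)
  gen <- generate_toy_ensemble(spec, dir)
  ens <- load_ensemble(dir)
  expect_length(ens$models, 20)
  d452 <- vapply(ens$models, pair_distance, numeric(1), spec = spec_452)
  d455 <- vapply(ens$models, pair_distance, numeric(1), spec = spec_455)
  expect_equal(d452, gen$truth$D390_K452, tolerance = 1e-3)
  expect_equal(d455, gen$truth$D390_K455, tolerance = 1e-3)
  # manifest records the same truth
  man <- jsonlite::read_json(gen$manifest, simplifyVector = TRUE)
  expect_equal(man$truth$D390_K452, gen$truth$D390_K452)
})

test_that("impossible target distances are rejected", {
  dir <- withr::local_tempdir()
  spec <- ensemble_spec(5, list(D390_K452 = list(mean = 0.1, sd = 0)),
                        seed = 1)
  expect_error(generate_toy_ensemble(spec, dir), "impossible geometry")
  expect_error(ensemble_spec(0, list()), ">= 1")
  expect_error(ensemble_spec(5, list(D390_K452 = list(bond_prob = 1.5))),
               "bond probability")
})

test_that("pair distance takes the minimum over cross atom pairs", {
  model <- data.frame(chain = "A", resno = c(390, 390, 452),
                      resid = c("ASP", "ASP", "LYS"),
                      atom = c("OD1", "OD2", "NZ"),
                      x = c(0, 0, 3), y = c(0, 6, 0), z = 0)
  expect_equal(pair_distance(model, spec_452), 3)
  model2 <- model; model2$x[3] <- 0
  expect_equal(pair_distance(model2, spec_452), 0)
})

test_that("missing atoms flag the model instead of failing", {
  model <- data.frame(chain = "A", resno = 390, resid = "ASP",
                      atom = "OD1", x = 0, y = 0, z = 0)
  d <- pair_distance(model, spec_452)
  expect_true(is.na(d))
  expect_true(any(grepl("452", attr(d, "missing"))))
})

test_that("pair distance is symmetric and rigid-motion invariant", {
  set.seed(19)
  for (i in 1:10) {
    model <- data.frame(chain = "A", resno = c(390, 390, 452, 455),
                        resid = c("ASP", "ASP", "LYS", "LYS"),
                        atom = c("OD1", "OD2", "NZ", "NZ"),
                        x = rnorm(4), y = rnorm(4), z = rnorm(4))
    swapped <- pair_spec(spec_452$side_b, spec_452$side_a)
    expect_equal(pair_distance(model, spec_452),
                 pair_distance(model, swapped), tolerance = 1e-12)
    # random rotation (QR of a random matrix) + translation
    q <- qr.Q(qr(matrix(rnorm(9), 3)))
    xyz <- as.matrix(model[, c("x", "y", "z")]) %*% q
    model2 <- model
    model2[, c("x", "y", "z")] <- sweep(xyz, 2, c(1, -2, 3), "+")
    expect_equal(pair_distance(model, spec_452),
                 pair_distance(model2, spec_452), tolerance = 1e-9)
    # oracle: direct elementwise distance computation
    d_oracle <- min(
      sqrt(sum((model[1, c("x", "y", "z")] - model[3, c("x", "y", "z")])^2)),
      sqrt(sum((model[2, c("x", "y", "z")] - model[3, c("x", "y", "z")])^2)))
    expect_equal(pair_distance(model, spec_452), d_oracle,
                 tolerance = 1e-12)
  }
})

test_that("distance classification honours the cutoff and the margin", {
  pol <- hbond_policy(3.5, 0.5)
  expect_equal(as.character(classify_hbond(3.2, pol)), "bonded")
  expect_equal(as.character(classify_hbond(3.8, pol)), "marginal")
  expect_equal(as.character(classify_hbond(8.7, pol)), "non_bonded")
  expect_equal(as.character(classify_hbond(3.5, pol)), "bonded")
  expect_equal(as.character(classify_hbond(4.0, pol)), "marginal")
  expect_error(classify_hbond(-1, pol), ">= 0")
})

test_that("bonded fraction is monotone in cutoff and margin", {
  set.seed(8)
  d <- runif(500, 2, 10)
  fr <- function(cut, mar)
    mean(classify_hbond(d, hbond_policy(cut, mar)) != "non_bonded")
  expect_true(all(diff(vapply(seq(2.5, 6, 0.5), fr, numeric(1),
                              mar = 0.5)) >= 0))
  expect_true(all(diff(vapply(seq(0, 2, 0.25), function(m) fr(3.5, m),
                              numeric(1))) >= 0))
})

test_that("an all-bonded ensemble has fraction 1 and no non-bonded sample", {
  dir <- withr::local_tempdir()
  gen <- generate_toy_ensemble(
    ensemble_spec(10, list(D390_K452 = list(mean = 3, sd = 0)), seed = 2),
    dir)
  ens <- load_ensemble(dir)
  s <- hbond_summary(ens, spec_452)
  expect_equal(s$fraction_bonded, 1)
  expect_length(s$nonbonded, 0)
})

test_that("hbond summaries combine across concatenated ensembles by counts", {
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  g1 <- generate_toy_ensemble(
    ensemble_spec(30, list(D390_K452 = list(mean = 3.2, sd = 0.3)),
                  seed = 4), dir1)
  g2 <- generate_toy_ensemble(
    ensemble_spec(50, list(D390_K452 = list(mean = 8, sd = 1)), seed = 5),
    dir2)
  e1 <- load_ensemble(dir1); e2 <- load_ensemble(dir2)
  both <- load_ensemble(c(e1$files, e2$files))
  s1 <- hbond_summary(e1, spec_452); s2 <- hbond_summary(e2, spec_452)
  sb <- hbond_summary(both, spec_452)
  expect_equal(sb$n_models, 80)
  expect_equal(sb$fraction_bonded,
               (30 * s1$fraction_bonded + 50 * s2$fraction_bonded) / 80,
               tolerance = 1e-12)
  expect_equal(sort(sb$nonbonded), sort(c(s1$nonbonded, s2$nonbonded)),
               tolerance = 1e-9)
})

test_that("models missing required atoms are excluded but counted", {
  dir <- withr::local_tempdir()
  gen <- generate_toy_ensemble(
    ensemble_spec(5, list(D390_K452 = list(mean = 5, sd = 0.5)), seed = 6),
    dir)
  # strip the K452 NZ atom from one model
  f <- gen$files[3]
  writeLines(grep("LYS A 452", readLines(f), value = TRUE,
                  invert = TRUE), f)
  ens <- load_ensemble(dir)
  s <- hbond_summary(ens, spec_452)
  expect_equal(s$n_models, 5)
  expect_equal(s$n_usable, 4)
  expect_equal(s$n_missing, 1)
})

test_that("unparseable ensemble files raise a typed error naming the file", {
  dir <- withr::local_tempdir()
  bad <- file.path(dir, "broken.pdb")
  writeLines("this is not a pdb", bad)
  expect_error(load_ensemble(dir), "broken.pdb")
})

test_that("identical samples give U = n^2/2 and p = 1", {
  r <- mann_whitney_u(c(1, 3, 5), c(1, 3, 5))
  expect_equal(r$u, 4.5)
  expect_equal(r$p_value, 1)
})

test_that("exact enumeration reproduces the small worked example", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r$u, 0)
  expect_equal(r$method, "exact")
  expect_equal(r$p_value, 1 / 3)
})

test_that("exact p-values agree with the reference implementation on tie-free samples", {
  set.seed(23)
  for (i in 1:10) {
    x <- sample(1:1000, 7); y <- sample(1001:2000 + 0.5, 9)
    y <- y - 1000.25   # interleave while keeping ties impossible
    ours <- mann_whitney_u(x, y, mode = "exact")
    ref <- wilcox.test(x, y, exact = TRUE)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(ours$u, unname(ref$statistic))
  }
})

test_that("exact and approximate p-values agree within 10% at n = 10 vs 10", {
  set.seed(77)
  for (i in 1:5) {
    x <- rnorm(10); y <- rnorm(10, 0.5)
    ex <- mann_whitney_u(x, y, mode = "exact")
    ap <- mann_whitney_u(x, y, mode = "approx")
    expect_lt(abs(ex$p_value - ap$p_value) / ex$p_value, 0.10)
  }
})

test_that("the tie-corrected approximation matches a permutation estimate", {
  set.seed(99)
  x <- rnorm(400, 8.7, 1.9)
  y <- rnorm(400, 8.7, 2.3)
  r <- mann_whitney_u(x, y)
  expect_match(r$method, "approximation")
  pooled <- rank(c(x, y))
  obs <- sum(pooled[1:400]) - 400 * 401 / 2
  perm <- vapply(1:4000, function(i)
    sum(pooled[sample(800, 400)]) - 400 * 401 / 2, numeric(1))
  p_perm <- mean(abs(perm - mean(perm)) >= abs(obs - mean(perm)))
  se <- sqrt(p_perm * (1 - p_perm) / 4000)
  expect_lt(abs(r$p_value - p_perm), 4 * se + 0.01)
})
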