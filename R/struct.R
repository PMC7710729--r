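#' Residue-pair atom specification
#'
#' Names the atoms on each side of an inter-residue contact and how the
#' per-model distance is reduced over the cross pairs (minimum by default:
#' the two carboxyl oxygens of an aspartate are chemically equivalent, so
#' the shortest oxygen-to-amine distance is the relevant one).
#'
#' Compact string form: `"A:390:OD1,OD2-A:452:NZ"`
#' (chain, residue number and comma-separated atom names for each side,
#' joined by `-`).
#'
#' @param side_a,side_b data.frames with columns `chain`, `resno`, `atom`
#'   (>= 1 atom each side).
#' @param reduce `"min"` (default) or `"mean"` over the cross pairs.
#' @return An object of class `pair_spec`.
#' @export
pair_spec <- function(side_a, side_b, reduce = c("min", "mean")) {
  reduce <- match.arg(reduce)
  chk <- function(s) {
    s <- as.data.frame(s)
    stopifnot(all(c("chain", "resno", "atom") %in% names(s)), nrow(s) >= 1)
    s
  }
  structure(list(side_a = chk(side_a), side_b = chk(side_b),
                 reduce = reduce),
            class = "pair_spec")
}

#' @rdname pair_spec
#' @param string compact pair string, e.g. `"A:390:OD1,OD2-A:452:NZ"`.
#' @export
parse_pair_spec <- function(string, reduce = "min") {
  sides <- strsplit(string, "-", fixed = TRUE)[[1]]
  if (length(sides) != 2) stop("pair spec must have two sides joined by '-'")
  parse_side <- function(s) {
    f <- strsplit(s, ":", fixed = TRUE)[[1]]
    if (length(f) != 3) stop("each side must be chain:resno:atoms")
    atoms <- strsplit(f[3], ",", fixed = TRUE)[[1]]
    data.frame(chain = f[1], resno = as.integer(f[2]), atom = atoms)
  }
  pair_spec(parse_side(sides[1]), parse_side(sides[2]), reduce = reduce)
}

#' Specification of a toy conformational ensemble
#'
#' Describes how many models to generate and, per named residue pair,
#' either a normal target-distance distribution (mean/sd in Angstrom) or a
#' bond probability (in which case distances are drawn near the bonded or
#' the non-bonded regime according to that probability).
#'
#' @param n_models number of models (>= 1).
#' @param pairs named list; each element is either
#'   `list(mean = , sd = )` or
#'   `list(bond_prob = , bonded_mean = 3.0, bonded_sd = 0.2,
#'   unbonded_mean = 8.7, unbonded_sd = 1.9)`.
#'   Recognized pair names: `"D390_K452"`, `"D390_K455"`.
#' @param seed integer seed.
#' @return An object of class `ensemble_spec`.
#' @export
ensemble_spec <- function(n_models, pairs, seed = 1) {
  if (n_models < 1) stop("number of models must be >= 1")
  for (p in pairs) {
    if (!is.null(p$sd) && p$sd < 0) stop("sd must be >= 0")
    if (!is.null(p$bond_prob) && (p$bond_prob < 0 || p$bond_prob > 1))
      stop("bond probability must lie in [0, 1]")
  }
  structure(list(n_models = n_models, pairs = pairs, seed = seed),
            class = "ensemble_spec")
}

format_pdb_atom <- function(serial, atom, resid, chain, resno, xyz,
                            element) {
  # PDB v3.3 ATOM record; atom names of <4 characters start in column 14
  name <- if (nchar(atom) < 4) sprintf(" %-3s", atom) else atom
  sprintf("ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, resid, chain, resno, xyz[1], xyz[2], xyz[3],
          1, 0, element)
}

#' Generate a toy PDB ensemble with controlled pair distances
#'
#' Writes one minimal PDB file per model containing the atoms of the
#' D390/K452/K455 contact analysis (Asp390 OD1 and OD2, Lys452 NZ, Lys455
#' NZ on chain A), placed so that the minimum distance of each named pair
#' equals its sampled target: OD1 sits at the origin with OD2 offset 0.5 A
#' along x, K452 NZ on the negative x axis at the `D390_K452` target and
#' K455 NZ on the y axis at the `D390_K455` target (only pairwise distances
#' of the named pairs are meaningful). A `manifest.json` listing the files
#' and the sampled truth distances is written alongside.
#'
#' @param spec an [ensemble_spec()].
#' @param dir output directory (created if needed).
#' @return invisibly, a list with `files`, `truth` (data.frame of sampled
#'   distances per model and pair) and `manifest` path.
#' @export
generate_toy_ensemble <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed)
  known <- c("D390_K452", "D390_K455")
  draw <- function(p, n) {
    d <- if (!is.null(p$bond_prob)) {
      bonded <- runif(n) < p$bond_prob
      ifelse(bonded,
             rnorm(n, p$bonded_mean %||% 3.0, p$bonded_sd %||% 0.2),
             rnorm(n, p$unbonded_mean %||% 8.7, p$unbonded_sd %||% 1.9))
    } else rnorm(n, p$mean, p$sd)
    if (any(d <= 0.5))
      stop("impossible geometry: sampled a non-positive target distance")
    d
  }
  truth <- as.data.frame(lapply(spec$pairs, draw, n = spec$n_models))
  names(truth) <- names(spec$pairs)
  if (!all(names(truth) %in% known))
    stop("recognized pairs are: ", paste(known, collapse = ", "))
  files <- character(spec$n_models)
  for (m in seq_len(spec$n_models)) {
    d452 <- if ("D390_K452" %in% names(truth)) truth$D390_K452[m] else 10
    d455 <- if ("D390_K455" %in% names(truth)) truth$D390_K455[m] else 10
    lines <- c(
      sprintf("REMARK   1 TOY ENSEMBLE MODEL %d", m),
      format_pdb_atom(1, "OD1", "ASP", "A", 390, c(0, 0, 0), "O"),
      format_pdb_atom(2, "OD2", "ASP", "A", 390, c(0.5, 0, 0), "O"),
      format_pdb_atom(3, "NZ", "LYS", "A", 452, c(-d452, 0, 0), "N"),
      format_pdb_atom(4, "NZ", "LYS", "A", 455, c(0, d455, 0), "N"),
      "END")
    files[m] <- file.path(dir, sprintf("model_%04d.pdb", m))
    writeLines(lines, files[m])
  }
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(n_models = spec$n_models, seed = spec$seed,
                            files = basename(files), truth = truth),
                       manifest, digits = NA, auto_unbox = TRUE)
  invisible(list(files = files, truth = truth, manifest = manifest))
}

#' Load a conformational ensemble from PDB files
#'
#' Reads each file's ATOM records (via bio3d) into a per-model coordinate
#' table keyed by (chain, residue number, residue name, atom name). Models
#' stay in input order. Files that cannot be parsed raise a typed error
#' naming the file; missing atoms are only detected (and reported) when a
#' pair specification is evaluated.
#'
#' @param paths character vector of PDB files, a directory, or a glob
#'   pattern.
#' @return An object of class `ensemble`: list with `models` (list of
#'   data.frames: `chain`, `resno`, `resid`, `atom`, `x`, `y`, `z`) and
#'   `files`.
#' @export
load_ensemble <- function(paths) {
  if (length(paths) == 1 && dir.exists(paths))
    paths <- list.files(paths, pattern = "\\.pdb$", full.names = TRUE)
  else if (length(paths) == 1 && grepl("[*?]", paths))
    paths <- Sys.glob(paths)
  if (!length(paths)) stop("no PDB files found")
  models <- lapply(paths, function(f) {
    pdb <- tryCatch(bio3d::read.pdb(f, verbose = FALSE),
                    error = function(e)
                      stop("unparseable PDB file '", f, "': ",
                           conditionMessage(e), call. = FALSE))
    a <- pdb$atom
    if (is.null(a) || nrow(a) == 0)
      stop("unparseable PDB file '", f, "': no ATOM records", call. = FALSE)
    df <- data.frame(chain = a$chain, resno = a$resno, resid = a$resid,
                     atom = a$elety, x = a$x, y = a$y, z = a$z)
    if (any(!is.finite(as.matrix(df[, c("x", "y", "z")]))))
      stop("non-finite coordinates in '", f, "'")
    df
  })
  structure(list(models = models, files = paths), class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("Conformational ensemble: %d models\n", length(x$models)))
  invisible(x)
}

#' Reduced inter-residue distance in one model
#'
#' Euclidean distances between every atom of side A and every atom of side
#' B, reduced with the rule carried by the [pair_spec()] (minimum by
#' default).
#'
#' @param model one element of an [load_ensemble()] `$models` list.
#' @param spec a [pair_spec()].
#' @return distance in Angstrom, or `NA` (with attribute `missing`) if a
#'   required atom is absent from the model.
#' @export
pair_distance <- function(model, spec) {
  find_atoms <- function(side) {
    idx <- lapply(seq_len(nrow(side)), function(i)
      which(model$chain == side$chain[i] & model$resno == side$resno[i] &
              model$atom == side$atom[i]))
    miss <- vapply(idx, length, integer(1)) == 0
    list(missing = paste(side$chain[miss], side$resno[miss],
                         side$atom[miss], sep = ":"),
         rows = unlist(idx))
  }
  A <- find_atoms(spec$side_a); B <- find_atoms(spec$side_b)
  if (length(A$missing) || length(B$missing))
    return(structure(NA_real_, missing = c(A$missing, B$missing)))
  Am <- as.matrix(model[A$rows, c("x", "y", "z"), drop = FALSE])
  Bm <- as.matrix(model[B$rows, c("x", "y", "z"), drop = FALSE])
  d2 <- outer(rowSums(Am^2), rowSums(Bm^2), "+") - 2 * Am %*% t(Bm)
  d <- sqrt(pmax(d2, 0))
  if (spec$reduce == "min") min(d) else mean(d)
}

#' Hydrogen-bond distance policy
#'
#' Distance-only criterion: bonded at or below `cutoff` (3.5 A), marginal
#' within an extra acceptance `margin` (0.5 A, i.e. up to 4.0 A), otherwise
#' non-bonded. The accepted (bond-forming) class is bonded plus marginal.
#'
#' @param cutoff maximum bonded distance in Angstrom (> 0).
#' @param margin extra acceptance margin in Angstrom (>= 0).
#' @return An object of class `hbond_policy`.
#' @export
hbond_policy <- function(cutoff = 3.5, margin = 0.5) {
  if (cutoff <= 0 || margin < 0) stop("cutoff > 0 and margin >= 0 required")
  structure(list(cutoff = cutoff, margin = margin), class = "hbond_policy")
}

#' Classify a donor-acceptor distance
#'
#' @param distance heavy-atom distance(s) in Angstrom (>= 0).
#' @param policy an [hbond_policy()].
#' @return factor with levels `bonded`, `marginal`, `non_bonded`.
#' @export
classify_hbond <- function(distance, policy = hbond_policy()) {
  if (any(distance < 0, na.rm = TRUE)) stop("distances must be >= 0")
  cls <- ifelse(distance <= policy$cutoff, "bonded",
                ifelse(distance <= policy$cutoff + policy$margin,
                       "marginal", "non_bonded"))
  factor(cls, levels = c("bonded", "marginal", "non_bonded"))
}

#' Hydrogen-bond summary of an ensemble for one residue pair
#'
#' Per-model reduced distances, the fraction of usable models accepted as
#' hydrogen-bonded (bonded or marginal under the policy), and the mean/sd
#' of the distances over the strictly non-bonded models (those beyond the
#' 3.5 A cutoff; the margin only affects the accepted fraction).
#'
#' @param ensemble an [load_ensemble()] result.
#' @param spec a [pair_spec()].
#' @param policy an [hbond_policy()].
#' @return An object of class `hbond_summary`: `distances`, `class`,
#'   `fraction_bonded`, `nonbonded` (vector), `nonbonded_mean`,
#'   `nonbonded_sd`, `n_models`, `n_usable`, `n_missing`, `policy`.
#' @export
hbond_summary <- function(ensemble, spec, policy = hbond_policy()) {
  d <- vapply(ensemble$models, pair_distance, numeric(1), spec = spec)
  usable <- !is.na(d)
  if (!any(usable)) stop("no usable model: required atoms missing everywhere")
  cls <- classify_hbond(d[usable], policy)
  nb <- d[usable][d[usable] > policy$cutoff]
  structure(list(distances = d, class = cls,
                 fraction_bonded = mean(cls != "non_bonded"),
                 nonbonded = nb,
                 nonbonded_mean = if (length(nb)) mean(nb) else NA_real_,
                 nonbonded_sd = if (length(nb) > 1) sd(nb) else NA_real_,
                 n_models = length(d), n_usable = sum(usable),
                 n_missing = sum(!usable), policy = policy),
            class = "hbond_summary")
}

#' @export
print.hbond_summary <- function(x, ...) {
  cat(sprintf("H-bond summary over %d models (%d usable):\n", x$n_models,
              x$n_usable))
  cat(sprintf("  accepted bonded fraction: %.3f (cutoff %.1f A + margin %.1f A)\n",
              x$fraction_bonded, x$policy$cutoff, x$policy$margin))
  if (length(x$nonbonded))
    cat(sprintf("  non-bonded distances (> %.1f A): mean %.2f A, sd %.2f A (n = %d)\n",
                x$policy$cutoff, x$nonbonded_mean, x$nonbonded_sd,
                length(x$nonbonded)))
  invisible(x)
}

#' Mann-Whitney U test (exact by enumeration or normal approximation)
#'
#' `U` counts, over all cross pairs, the times a sample-1 value exceeds a
#' sample-2 value (ties count 1/2). With both samples of size at most 10
#' and no ties the two-sided p-value is exact, by enumerating every
#' assignment of the pooled ranks; otherwise the normal approximation with
#' tie correction and continuity correction is used. The method actually
#' applied is reported.
#'
#' @param x,y numeric samples (non-empty).
#' @param mode `"auto"` (default), `"exact"` or `"approx"`.
#' @param exact_max largest per-sample size for the exact enumeration.
#' @return An object of class `mwu_result`: `u`, `p_value`, `method`,
#'   `n1`, `n2`.
#' @export
mann_whitney_u <- function(x, y, mode = c("auto", "exact", "approx"),
                           exact_max = 10) {
  mode <- match.arg(mode)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (!n1 || !n2) stop("both samples must be non-empty")
  pooled <- c(x, y)
  ties <- anyDuplicated(pooled) > 0
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2     # 'greater than' count
  use_exact <- mode == "exact" ||
    (mode == "auto" && n1 <= exact_max && n2 <= exact_max && !ties)
  if (use_exact && ties)
    stop("exact enumeration requires tie-free samples")
  if (use_exact) {
    # all C(n1+n2, n1) assignments of the pooled ranks to sample 1
    sel <- combn(n1 + n2, n1)
    uall <- colSums(matrix(seq_len(n1 + n2)[sel], nrow = n1)) -
      n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    p <- mean(abs(uall - mu) >= abs(u - mu) - 1e-9)
    method <- "exact"
  } else {
    n <- n1 + n2
    mu <- n1 * n2 / 2
    tie_tab <- table(pooled)
    tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) return(structure(list(u = u, p_value = 1,
                                           method = "degenerate",
                                           n1 = n1, n2 = n2),
                                      class = "mwu_result"))
    z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
    p <- if (z <= 0) 1 else min(1, 2 * pnorm(z, lower.tail = FALSE))
    method <- if (ties) "normal approximation, tie-corrected"
              else "normal approximation"
  }
  structure(list(u = u, p_value = p, method = method, n1 = n1, n2 = n2),
            class = "mwu_result")
}

#' @export
print.mwu_result <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g, two-sided p = %.4g (%s; n = %d vs %d)\n",
              x$u, x$p_value, x$method, x$n1, x$n2))
  invisible(x)
}

#' Compare the same residue pair across two ensembles
#'
#' Summarizes both ensembles under one policy and tests their strictly
#' non-bonded distance distributions with [mann_whitney_u()].
#'
#' @param ens1,ens2 [load_ensemble()] results.
#' @param spec a [pair_spec()].
#' @param policy an [hbond_policy()].
#' @return list: `summary1`, `summary2`, `mwu`.
#' @export
compare_ensembles <- function(ens1, ens2, spec, policy = hbond_policy()) {
  s1 <- hbond_summary(ens1, spec, policy)
  s2 <- hbond_summary(ens2, spec, policy)
  list(summary1 = s1, summary2 = s2,
       mwu = mann_whitney_u(s1$nonbonded, s2$nonbonded))
}
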