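#' Derive a per-stage seed from the run seed
#'
#' Every stochastic stage draws its seed deterministically from the single
#' top-level run seed and the stage name, so stages can be rerun
#' independently yet reproducibly.
#'
#' @param seed top-level integer seed.
#' @param stage stage name.
#' @return integer seed below 2^31.
#' @export
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_len(nchar(stage)))
  as.integer((as.numeric(seed) * 10007 + h) %% .Machine$integer.max)
}

#' Run the multi-stage analysis pipeline
#'
#' Executes the requested stages in dependency order
#' (`simulate` -> `scan`/`null` -> `popstats`; `ephys` and `struct` are
#' independent), writing each stage's outputs under
#' `outdir/<stage>/` and a run report (`report.json`) listing every emitted
#' file with its checksum. A failing stage is recorded with its cause and
#' does not destroy outputs of completed stages.
#'
#' The configuration is a named list (or YAML file) with optional blocks:
#' \describe{
#' \item{simulate}{`demography` (YAML path; default the bundled example),
#'   optional `sweep` block (`position_bp`, `s`, `h`, `f0`, `population`,
#'   `start_gen`, `stop_freq`).}
#' \item{scan}{`vcf`, `popmap`, `pop` (or `use_simulated: true`), `maf`,
#'   `ehh_cutoff`, `gap_kb`, `window_kb`, `score`, optional `null` (JSON
#'   from a `null` stage) for threshold calls.}
#' \item{null}{`demography`, `reps`, `percentile`.}
#' \item{popstats}{`genotype_table` and/or `haplotype_table` (TSV paths).}
#' \item{ephys}{`g_max_ns`, `cm_pf`, `tau_deact_ms`, `gating` block
#'   (`n_channels`, `po`, `g_ps`, `v_mv`, `duration_s`).}
#' \item{struct}{`models` (dir/glob), `pair`, `cutoff`, `margin`, optional
#'   `compare` (second dir).}
#' }
#'
#' @param config named list or path to a YAML file.
#' @param outdir output directory.
#' @param seed top-level seed (overrides `config$seed`).
#' @return An object of class `run_report`; its `status` field is
#'   `"ok"` or `"failed"`.
#' @export
run_pipeline <- function(config, outdir, seed = NULL) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  seed <- as.integer(seed %||% config$seed %||% 1L)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  t_start <- Sys.time()
  stages <- intersect(c("simulate", "null", "scan", "popstats", "ephys",
                        "struct"), names(config))
  manifest <- list()
  failures <- list()
  state <- new.env(parent = emptyenv())

  run_stage <- function(name, fun) {
    sdir <- file.path(outdir, name)
    dir.create(sdir, showWarnings = FALSE)
    res <- tryCatch(list(ok = TRUE, files = fun(sdir)),
                    error = function(e) list(ok = FALSE,
                                             cause = conditionMessage(e)))
    if (res$ok) {
      manifest[[name]] <<- res$files
    } else {
      failures[[name]] <<- res$cause
    }
  }

  for (st in stages) {
    cfg <- config[[st]]
    if (st == "simulate") run_stage(st, function(sdir)
      pipeline_simulate(cfg, sdir, stage_seed(seed, st), state))
    if (st == "null") run_stage(st, function(sdir)
      pipeline_null(cfg, sdir, stage_seed(seed, st), state))
    if (st == "scan") run_stage(st, function(sdir)
      pipeline_scan(cfg, sdir, state))
    if (st == "popstats") run_stage(st, function(sdir)
      pipeline_popstats(cfg, sdir))
    if (st == "ephys") run_stage(st, function(sdir)
      pipeline_ephys(cfg, sdir, stage_seed(seed, st)))
    if (st == "struct") run_stage(st, function(sdir)
      pipeline_struct(cfg, sdir))
  }

  files <- unlist(manifest, use.names = FALSE)
  if (is.null(files)) files <- character(0)
  report <- structure(list(
    status = if (length(failures)) "failed" else "ok",
    stages_run = stages, failures = failures,
    files = data.frame(file = files,
                       md5 = unname(tools::md5sum(files)),
                       row.names = NULL),
    seed = seed, version = as.character(utils::packageVersion("sweepfunc")),
    wall_time_s = as.numeric(difftime(Sys.time(), t_start, units = "secs"))),
    class = "run_report")
  jsonlite::write_json(
    list(status = report$status, stages_run = stages,
         failures = failures, files = report$files, seed = seed,
         version = report$version, wall_time_s = report$wall_time_s),
    file.path(outdir, "report.json"), auto_unbox = TRUE, digits = NA)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("Pipeline run: %s (seed %d, %.1f s)\n", x$status, x$seed,
              x$wall_time_s))
  cat("  stages:", paste(x$stages_run, collapse = ", "), "\n")
  for (nm in names(x$failures))
    cat(sprintf("  FAILED %s: %s\n", nm, x$failures[[nm]]))
  cat(sprintf("  %d file(s) written\n", nrow(x$files)))
  invisible(x)
}

pipeline_simulate <- function(cfg, sdir, seed, state) {
  dem <- read_demography_yaml(cfg$demography %||%
                                system.file("extdata",
                                            "demography_three_pop.yaml",
                                            package = "sweepfunc"))
  vcf <- file.path(sdir, "panel.vcf.gz")
  pm <- file.path(sdir, "popmap.tsv")
  if (!is.null(cfg$sweep)) {
    sw <- sweep_config(cfg$sweep$position_bp, cfg$sweep$s,
                       cfg$sweep$h %||% 0.5, cfg$sweep$f0,
                       cfg$sweep$population,
                       cfg$sweep$start_gen,
                       cfg$sweep$stop_freq %||% 0)
    sp <- simulate_sweep_panel(dem, sw, seed)
    panel <- sp$panel
    jsonlite::write_json(list(outcome = sp$outcome,
                              final_freq = sp$final_freq,
                              trajectory = sp$trajectory),
                         file.path(sdir, "sweep.json"), auto_unbox = TRUE,
                         digits = NA)
  } else panel <- simulate_panel(dem, seed)
  write_panel_vcf(panel, vcf, pm)
  state$vcf <- vcf; state$popmap <- pm
  state$scan_pop <- names(dem$samples)[1]
  list.files(sdir, full.names = TRUE)
}

pipeline_null <- function(cfg, sdir, seed, state) {
  dem <- read_demography_yaml(cfg$demography %||%
                                system.file("extdata",
                                            "demography_three_pop.yaml",
                                            package = "sweepfunc"))
  nl <- neutral_null(dem, reps = cfg$reps %||% 100, seed = seed,
                     percentile = cfg$percentile %||% 99.99)
  out <- file.path(sdir, "null.json")
  jsonlite::write_json(list(critical = nl$threshold$critical,
                            percentile = nl$threshold$percentile,
                            n_windows = nl$threshold$n, reps = nl$reps,
                            seed = seed, bin_stats = nl$bin_stats,
                            scores = nl$window_scores),
                       out, auto_unbox = TRUE, digits = NA)
  state$null <- nl
  out
}

pipeline_scan <- function(cfg, sdir, state) {
  vcf <- if (isTRUE(cfg$use_simulated)) state$vcf else cfg$vcf
  popmap <- if (isTRUE(cfg$use_simulated)) state$popmap else cfg$popmap
  pop <- cfg$pop %||% state$scan_pop
  if (is.null(vcf) || !file.exists(vcf))
    stop("scan input VCF not found: ", vcf %||% "<missing>")
  panel <- read_panel_vcf(vcf, popmap)
  sub <- subset_population(panel, pop, drop_monomorphic = TRUE)
  sc <- ihs_scan(sub, maf_min = cfg$maf %||% 0.05,
                 ehh_cutoff = cfg$ehh_cutoff %||% 0.05,
                 gap_limit_bp = (cfg$gap_kb %||% 20) * 1000)
  ref <- if (!is.null(state$null)) state$null$bin_stats else NULL
  std <- standardize_ihs(sc, reference = ref)
  win <- window_scan(std, window_bp = (cfg$window_kb %||% 30) * 1000,
                     score = cfg$score %||% "abs-of-mean")
  if (!is.null(state$null))
    win <- call_candidates(win, state$null$threshold)
  snp_file <- file.path(sdir, "ihs_per_snp.tsv")
  write.table(as.data.frame(std)[, c("position", "freq", "ihh_a", "ihh_d",
                                     "uihs", "ihs", "excluded", "reason")],
              snp_file, sep = "\t", quote = FALSE, row.names = FALSE)
  win_file <- file.path(sdir, "windows.tsv")
  write.table(as.data.frame(win), win_file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  c(snp_file, win_file)
}

pipeline_popstats <- function(cfg, sdir) {
  files <- character()
  if (!is.null(cfg$genotype_table)) {
    gt <- read.table(cfg$genotype_table, sep = "\t", header = TRUE)
    gt$derived_freq <- apply(gt[, c("hom_ancestral", "het", "hom_derived")],
                             1, allele_frequency_from_genotypes)
    f <- file.path(sdir, "allele_frequencies.tsv")
    write.table(gt, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
  }
  if (!is.null(cfg$haplotype_table)) {
    ht <- read.table(cfg$haplotype_table, sep = "\t", header = TRUE)
    ld <- lapply(seq_len(nrow(ht)), function(i) {
      p <- as.numeric(ht[i, c("p11", "p10", "p01", "p00")])
      p <- p / sum(p)   # printed tables carry rounding error
      r <- ld_from_haplotype_freqs(p)
      data.frame(population = ht$population[i], D = r$D, Dprime = r$Dprime,
                 r2 = r$r2, reason = r$reason)
    })
    f <- file.path(sdir, "ld.tsv")
    write.table(do.call(rbind, ld), f, sep = "\t", quote = FALSE,
                row.names = FALSE)
    files <- c(files, f)
  }
  if (!length(files)) stop("popstats stage needs a genotype or haplotype table")
  files
}

pipeline_ephys <- function(cfg, sdir, seed) {
  proto <- step_protocol()
  traces <- simulate_iv_recording(cfg$g_max_ns %||% 0.5, proto, seed = seed,
                                  tau_deact_ms = cfg$tau_deact_ms %||% 20,
                                  cm_pf = cfg$cm_pf %||% 15)
  iv <- extract_step_responses(traces, proto)
  auc_ss <- iv_auc(iv, "steady")
  auc_tail <- iv_auc(iv, "tail")
  tau <- fit_deactivation(tail_segment(traces[[length(traces)]], proto))
  g <- cfg$gating %||% list()
  po <- g$po %||% 0.2
  gc <- gating_config(n_channels = g$n_channels %||% 3,
                      k_open = 10 * po / (1 - po), k_close = 10,
                      g_ps = g$g_ps %||% 150, v_mv = g$v_mv %||% -80,
                      duration_s = g$duration_s %||% 40, seed = seed)
  tr <- simulate_gating_trace(gc)
  # the closed level plus the first n-1 open levels carry almost all weight
  # at low Po; the all-open level is too rare to fit as its own component
  fitg <- fit_amplitude_histogram(tr, components = max(2, gc$n_channels))
  npo <- compute_npo(tr, fitg$amplitude_pa, fitg$baseline_pa)
  iv_file <- file.path(sdir, "iv.tsv")
  write.table(as.data.frame(iv), iv_file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  out <- file.path(sdir, "ephys.json")
  jsonlite::write_json(list(auc_steady = auc_ss, auc_tail = auc_tail,
                            tau_deact_ms = tau$tau_ms, npo = npo$npo,
                            unitary_amplitude_pa = fitg$amplitude_pa,
                            seed = seed),
                       out, auto_unbox = TRUE, digits = NA)
  c(iv_file, out)
}

pipeline_struct <- function(cfg, sdir) {
  spec <- parse_pair_spec(cfg$pair %||% "A:390:OD1,OD2-A:452:NZ")
  policy <- hbond_policy(cfg$cutoff %||% 3.5, cfg$margin %||% 0.5)
  ens <- load_ensemble(cfg$models)
  s1 <- hbond_summary(ens, spec, policy)
  res <- list(fraction_bonded = s1$fraction_bonded,
              nonbonded_mean = s1$nonbonded_mean,
              nonbonded_sd = s1$nonbonded_sd, n_models = s1$n_models)
  if (!is.null(cfg$compare)) {
    cmp <- compare_ensembles(ens, load_ensemble(cfg$compare), spec, policy)
    res$compare <- list(fraction_bonded = cmp$summary2$fraction_bonded,
                        nonbonded_mean = cmp$summary2$nonbonded_mean,
                        nonbonded_sd = cmp$summary2$nonbonded_sd,
                        mwu_u = cmp$mwu$u, mwu_p = cmp$mwu$p_value,
                        mwu_method = cmp$mwu$method)
  }
  dist_file <- file.path(sdir, "distances.tsv")
  write.table(data.frame(model = seq_along(s1$distances),
                         distance_A = s1$distances),
              dist_file, sep = "\t", quote = FALSE, row.names = FALSE)
  out <- file.path(sdir, "hbond.json")
  jsonlite::write_json(res, out, auto_unbox = TRUE, digits = NA)
  c(dist_file, out)
}

#' Human-readable summary tables from pipeline outputs
#'
#' Rebuilds summary tables purely from the files a [run_pipeline()] run
#' left on disk (no in-memory state): candidate windows with threshold
#' flags, allele/haplotype frequency and LD tables, the ephys summary and
#' the H-bond comparison. Sections whose outputs are absent are listed as
#' absent, not fatal.
#'
#' @param outdir a pipeline output directory.
#' @param file optional path for a Markdown rendering of the tables.
#' @return list of data.frames (class `pipeline_summary`), one per
#'   available section; `absent` names the missing ones.
#' @export
make_report <- function(outdir, file = NULL) {
  sections <- list()
  absent <- character()
  grab_tsv <- function(path) if (file.exists(path))
    read.table(path, sep = "\t", header = TRUE) else NULL
  grab_json <- function(path) if (file.exists(path))
    jsonlite::read_json(path, simplifyVector = TRUE) else NULL

  w <- grab_tsv(file.path(outdir, "scan", "windows.tsv"))
  if (is.null(w)) absent <- c(absent, "windows") else sections$windows <- w
  f <- grab_tsv(file.path(outdir, "popstats", "allele_frequencies.tsv"))
  if (is.null(f)) absent <- c(absent, "frequencies") else
    sections$frequencies <- f
  ld <- grab_tsv(file.path(outdir, "popstats", "ld.tsv"))
  if (is.null(ld)) absent <- c(absent, "ld") else sections$ld <- ld
  e <- grab_json(file.path(outdir, "ephys", "ephys.json"))
  if (is.null(e)) absent <- c(absent, "ephys") else
    sections$ephys <- as.data.frame(e)
  h <- grab_json(file.path(outdir, "struct", "hbond.json"))
  if (is.null(h)) absent <- c(absent, "hbond") else
    sections$hbond <- as.data.frame(h[setdiff(names(h), "compare")])
  sections$absent <- absent
  if (!is.null(file)) {
    con <- file(file, "w"); on.exit(close(con))
    writeLines("# Pipeline summary", con)
    for (nm in setdiff(names(sections), "absent")) {
      writeLines(c("", paste("##", nm), ""), con)
      df <- sections[[nm]]
      writeLines(paste(names(df), collapse = " | "), con)
      writeLines(paste(rep("---", ncol(df)), collapse = " | "), con)
      for (i in seq_len(min(nrow(df), 50)))
        writeLines(paste(unlist(format(df[i, ])), collapse = " | "), con)
    }
    if (length(absent))
      writeLines(c("", paste("Absent sections:",
                             paste(absent, collapse = ", "))), con)
  }
  class(sections) <- c("pipeline_summary", class(sections))
  sections
}
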