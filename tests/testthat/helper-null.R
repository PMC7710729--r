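# The two reduced neutral-null runs (>= 1e4 windows each) are expensive and
# shared between the threshold-stability and sweep-power checks, so they are
# computed lazily and cached for the duration of the test run.

.null_cache <- new.env(parent = emptyenv())

shared_null <- function(seed, reps = 1000) {
  key <- paste0("null_", seed, "_", reps)
  if (!exists(key, envir = .null_cache)) {
    dem <- read_demography_yaml()
    assign(key,
           neutral_null(dem, reps = reps, seed = seed,
                        score = "mean-of-abs", border = "truncate"),
           envir = .null_cache)
  }
  get(key, envir = .null_cache)
}

# bootstrap standard error of an upper percentile of a score vector
bootstrap_percentile_se <- function(scores, percentile, B = 200,
                                    seed = 1) {
  set.seed(seed)
  n <- length(scores)
  reps <- vapply(seq_len(B), function(b)
    quantile(sample(scores, n, replace = TRUE), percentile / 100,
             type = 7, names = FALSE), numeric(1))
  sd(reps)
}
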