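# Seed plumbing: one master seed, fixed per-stage offsets so stages are
# reproducible in isolation.  Offsets are small primes; all derived seeds are
# kept inside the 32-bit integer range.
stage_seed <- function(master, stage, k = 0L) {
  offsets <- c(
    gene_trees = 101L, sequences = 211L, dropout = 307L,
    bootstrap = 401L, quartet = 503L, pipeline = 601L
  )
  off <- offsets[[stage]]
  as.integer((as.numeric(master) * 31 + off + as.numeric(k) * 7) %% 2147483647)
}

with_seed_ <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

assert_that_ <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg)
  invisible(TRUE)
}

# nearest-key suggestion for config errors
nearest_key <- function(key, valid) {
  d <- adist(key, valid, ignore.case = TRUE)
  valid[which.min(d)]
}
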