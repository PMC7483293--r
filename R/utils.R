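# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed when one is supplied, leaving the
# caller's RNG state untouched; otherwise use the ambient RNG stream.
with_seed_if <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}

# Derive a stream of child seeds from one parent seed (kept < 2^31).
child_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  with_seed_if(seed, as.list(sample.int(.Machine$integer.max - 1L, n)))
}

assert_cols <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")),
          class = "ppiscale_schema_error")
  }
  invisible(df)
}

# Sample standard deviation (n - 1 denominator), the convention used for
# every spread/standard-error computation in the package.
sample_sd <- function(x) stats::sd(x)

# Add-one permutation/bootstrap p-value: (1 + #{null >= observed}) / (1 + B).
perm_pvalue <- function(null_stats, observed) {
  (1 + sum(null_stats >= observed)) / (1 + length(null_stats))
}

is_baseline_condition <- function(prepulse_db) prepulse_db == 0

condition_label <- function(prepulse_db, delay_ms) {
  ifelse(is_baseline_condition(prepulse_db), "baseline",
         sprintf("pp%gdB_%gms", prepulse_db, delay_ms))
}
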