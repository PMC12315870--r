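# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so library code never clobbers user-level seeds.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}

# Deterministic order by primary key then index (used for distance ties).
order_ties_by_index <- function(x) order(x, seq_along(x))

# Cheap content fingerprint for a count matrix, used to warn when reports
# from different datasets are compared. Not cryptographic.
counts_fingerprint <- function(counts) {
  v <- counts$values
  sprintf("%dx%d-%.0f-%.6g", nrow(v), ncol(v), sum(v), sum(v * seq_len(nrow(v)) %% 97))
}
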