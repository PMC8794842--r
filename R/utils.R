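# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate expr with a temporary RNG state seeded by `seed`, restoring the
# caller's RNG state afterwards so seeded draws do not perturb outer streams
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# deterministic sub-seed derived from a base seed and a character tag;
# kept in [0, 2^31 - 1) so it is a valid R integer seed
derive_seed <- function(seed, ...) {
  tag <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(tag)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

softmax_rows <- function(m) {
  m <- m - apply(m, 1, max)
  e <- exp(m)
  e / rowSums(e)
}

# numerically stable log-sum-exp over rows
logsumexp_rows <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

zeros_cube <- function(b, n, t) array(0, dim = c(b, n, t))
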