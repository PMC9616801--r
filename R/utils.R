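# Internal helpers shared across modules.

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards. `seed = NULL` leaves the RNG alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream of child seeds from one seed, so that independent stages of
# a pipeline can be reseeded without coupling their random streams.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Cosine of the angle between two vectors, on the common support of finite
# entries; NA when fewer than 2 entries are shared or a vector has zero norm.
pairwise_cosine <- function(u, v) {
  keep <- is.finite(u) & is.finite(v)
  if (sum(keep) < 2L) {
    return(NA_real_)
  }
  u <- u[keep]
  v <- v[keep]
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    return(NA_real_)
  }
  sum(u * v) / (nu * nv)
}

unit_vector <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) {
    stop("cannot normalize a zero vector", call. = FALSE)
  }
  v / n
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# per-lag means of a square similarity matrix (lag 0 = diagonal)
lag_means <- function(M) {
  n <- nrow(M)
  d <- row(M) - col(M)
  vapply(0:(n - 1), function(l) {
    v <- M[abs(d) == l]
    mean(v, na.rm = TRUE)
  }, numeric(1))
}
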