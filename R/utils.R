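# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a fixed RNG seed, restoring caller state
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Shift a 3D array by integer offset `o`; result[x] = a[x - o], `fill` outside.
shift_array <- function(a, o, fill) {
  d <- dim(a)
  out <- array(fill, d)
  idx_dst <- vector("list", 3L)
  idx_src <- vector("list", 3L)
  for (ax in 1:3) {
    n <- d[ax] - abs(o[ax])
    if (n <= 0L) return(out)
    if (o[ax] >= 0L) {
      idx_dst[[ax]] <- seq_len(n) + o[ax]
      idx_src[[ax]] <- seq_len(n)
    } else {
      idx_dst[[ax]] <- seq_len(n)
      idx_src[[ax]] <- seq_len(n) - o[ax]
    }
  }
  out[idx_dst[[1L]], idx_dst[[2L]], idx_dst[[3L]]] <-
    a[idx_src[[1L]], idx_src[[2L]], idx_src[[3L]]]
  out
}

# The 13 unique 3D lattice directions at Chebyshev distance 1 (first nonzero
# component positive); their negatives complete the 26-neighborhood.
directions_13 <- function() {
  matrix(c(
    1, 0, 0,
    0, 1, 0,
    0, 0, 1,
    1, 1, 0,
    1, -1, 0,
    1, 0, 1,
    1, 0, -1,
    0, 1, 1,
    0, 1, -1,
    1, 1, 1,
    1, 1, -1,
    1, -1, 1,
    1, -1, -1), ncol = 3L, byrow = TRUE)
}

is_binary01 <- function(x) {
  u <- unique(as.vector(x))
  u <- u[!is.na(u)]
  all(u %in% c(0, 1))
}

# Population moments
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
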