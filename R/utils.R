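# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_that <- function(ok, fmt, ...) if (!isTRUE(ok)) stopf(fmt, ...)

#' Run code with a private, restorable RNG state
#'
#' All stochastic operations in the package take an explicit `seed` and leave
#' the global RNG stream untouched, so pipelines are reproducible regardless
#' of call order.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
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

# derive a child seed below 2^31 from a base seed and a stream index
child_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 1103L + as.numeric(index) * 7919L) %% 2147483629)
}

# harmonic mean, NA-safe
harmonic_mean <- function(x) {
  x <- x[!is.na(x) & x > 0]
  if (!length(x)) return(NA_real_)
  length(x) / sum(1 / x)
}

# all permutations of 1..k as a matrix (k! rows); k is small (<= 7 clusters)
all_permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(k - 1L)
  out <- matrix(0L, nrow(sub) * k, k)
  r <- 0L
  for (i in seq_len(nrow(sub))) {
    for (pos in seq_len(k)) {
      r <- r + 1L
      out[r, ] <- append(sub[i, ], k, after = pos - 1L)
    }
  }
  out
}
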