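#' Derive independent child seeds from one master seed
#'
#' Stages of a simulation or pipeline each receive their own RNG seed so
#' they can be re-run independently yet reproducibly. Child seeds are drawn
#' deterministically from the master seed and kept below 2^31.
#'
#' @param seed Integer master seed.
#' @param n Number of child seeds.
#' @return Integer vector of length `n`.
#' @export
split_seed <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.numeric(n), n >= 1L)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, as.integer(n))
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# log(sum(exp(x))) along rows of a matrix, guarding -Inf rows
.logsumexp_rows <- function(x) {
  m <- x[, 1L]
  for (j in seq_len(ncol(x))[-1L]) m <- pmax(m, x[, j])
  m[!is.finite(m)] <- 0
  m + log(rowSums(exp(x - m)))
}

.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

.stop_if <- function(cond, ...) if (cond) stop(..., call. = FALSE)
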