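# Internal helpers shared across modules.

#' Derive a child seed from a master seed and a key path
#'
#' Deterministic integer hashing used to split one master seed into
#' independent child seeds (per replicate, per algorithm arm, per operator
#' category). The scheme is a multiplicative congruential mix over the
#' master seed and each key component, reduced modulo 2^31 - 1 so the
#' result is always a valid R integer seed.
#'
#' @param master Integer master seed.
#' @param ... Additional integer or character key components; characters are
#'   folded to integers by summing scaled character codes.
#' @return A single integer in `[1, 2^31 - 2]`.
#' @examples
#' derive_seed(42, "replicate", 3)
#' @export
derive_seed <- function(master, ...) {
  m <- 2147483647 # 2^31 - 1 (prime)
  fold <- function(x) {
    if (is.character(x)) {
      sum(as.double(utf8ToInt(x)) * seq_along(utf8ToInt(x)) * 131) %% m
    } else {
      as.double(x) %% m
    }
  }
  h <- fold(master)
  for (k in list(...)) {
    # 48271 and 69621 are classic MINSTD-family multipliers; doubles hold
    # intermediates exactly because each factor is < 2^31 and we reduce by
    # splitting the product (a*b mod m with a,b < m can exceed 2^53, so
    # reduce the high part first).
    h <- .mulmod(h + 1, 48271, m)
    h <- (h + .mulmod(fold(k) + 1, 69621, m)) %% m
    h <- .mulmod(h + 1, 16807, m)
  }
  as.integer(if (h < 1) 1 else h)
}

# (a * b) mod m without overflowing double precision, for a, b < m < 2^31.
.mulmod <- function(a, b, m) {
  a <- a %% m
  b <- b %% m
  hi <- floor(a / 65536)
  lo <- a - hi * 65536
  (((hi * b) %% m) * 65536 + lo * b) %% m
}

# Run an expression under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
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
  set.seed(seed)
  expr
}

.stop_invalid <- function(...) {
  stop(..., call. = FALSE)
}

# Validate a genotype (vector) or population (matrix) of 0/1 alleles.
.check_binary <- function(x, n = NULL, what = "genotype") {
  if (!is.numeric(x) && !is.integer(x) && !is.logical(x)) {
    .stop_invalid("invalid ", what, ": alleles must be numeric 0/1")
  }
  if (any(x != 0L & x != 1L)) {
    .stop_invalid("invalid ", what, ": alleles must all be 0 or 1")
  }
  len <- if (is.matrix(x)) ncol(x) else length(x)
  if (!is.null(n) && len != n) {
    .stop_invalid(
      "invalid ", what, ": length ", len,
      " does not match landscape N = ", n
    )
  }
  invisible(TRUE)
}

# Standard error of the mean: stdev/sqrt(n).
.stderr <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}
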