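# Internal helpers shared across modules.

logit <- function(p) log(p / (1 - p))
expit <- function(x) 1 / (1 + exp(-x))

#' @noRd
#' Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
#' global RNG state is untouched (generators are pure functions of their
#' arguments and seed).
with_local_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("seed must be a single finite number")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
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
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a distinct child seed from a parent seed, staying inside 32-bit range.
child_seed <- function(seed, k) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(k) * 7919L
}

stopifnot_aligned <- function(a, b, what = "matrices") {
  if (!identical(dim(a), dim(b)) ||
      !identical(rownames(a), rownames(b)) ||
      !identical(colnames(a), colnames(b))) {
    stop(sprintf("%s must share dimensions and dimnames (axis mismatch)", what))
  }
  invisible(TRUE)
}

# Significant-digit rounding with halves away from zero (so 0.003125 -> 0.00313
# at three digits, matching conventional reporting rather than half-to-even).
signif_half_up <- function(x, digits = 3) {
  if (x == 0) return(0)
  e <- floor(log10(abs(x)))
  scale <- 10^(e - digits + 1)
  m <- abs(x) / scale
  r <- floor(m + 0.5)
  sign(x) * r * scale
}

# Dirichlet draws via gamma representation; rows are samples.
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  g / rowSums(g)
}
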