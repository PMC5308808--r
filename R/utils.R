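# Internal helpers shared across modules.

#' Population standard deviation
#'
#' City- and segment-level GVI spread is reported as the population standard
#' deviation (divide by n, not n - 1); `sample = TRUE` switches to the sample
#' estimator for users who prefer it.
#'
#' @param x Numeric vector.
#' @param sample Use the n - 1 denominator instead of n.
#' @return A single number; 0 for a length-one input.
#' @export
pop_sd <- function(x, sample = FALSE) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0L) return(NA_real_)
  if (n == 1L) return(0)
  if (sample) return(sd(x))
  sqrt(sum((x - mean(x))^2) / n)
}

# Deterministic 31-bit hash of a string (polynomial rolling hash). Used to
# derive per-(pano, heading) RNG streams; not cryptographic.
hash31 <- function(s) {
  codes <- utf8ToInt(as.character(s))
  h <- 0
  for (k in codes) h <- (h * 131 + k) %% 2147483647
  as.integer(h)
}

# Derive a child seed below 2^31 from a parent seed and a label.
child_seed <- function(seed, label) {
  as.integer((as.numeric(seed) %% 2147483647 + hash31(label)) %% 2147483647)
}

stopifnot_scalar_num <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi) {
    abort(sprintf("`%s` must be a single number in [%s, %s].", name,
                  format(lo), format(hi)))
  }
  invisible(x)
}

# Condition constructors so callers can distinguish provider failures.
gv_error <- function(class, message, ...) {
  abort(message, class = c(class, "gv_error"), ...)
}
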