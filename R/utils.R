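## Internal helpers shared across the package.

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the RNG seed, evaluates `expr`, then restores the caller's RNG state,
#' so seeded package functions do not perturb the global random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
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

#' Derive reproducible child seeds from a master seed
#'
#' Splitting rule: seed the RNG with `master` and draw `n` integers uniformly
#' from 1..(2^31 - 1). Child streams are therefore mutually independent in
#' the usual Monte-Carlo sense but fully determined by the master seed.
#'
#' @param master integer master seed.
#' @param n number of child seeds.
#' @return integer vector of length `n`, all in [1, 2^31 - 1].
#' @export
#' @examples
#' derive_seeds(1, 3)
derive_seeds <- function(master, n) {
  stopifnot(n >= 0)
  if (n == 0) return(integer(0))
  with_seed(master, sample.int(.Machine$integer.max, n, replace = TRUE))
}

## scalar checks ------------------------------------------------------------

is_number <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)

check_nonneg <- function(x, name) {
  if (!is_number(x) || x < 0) {
    stop(sprintf("`%s` must be a single nonnegative number", name),
         call. = FALSE)
  }
  invisible(x)
}

check_pos <- function(x, name) {
  if (!is_number(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive number", name),
         call. = FALSE)
  }
  invisible(x)
}

check_unit <- function(x, name) {
  if (!is_number(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single number in [0, 1]", name),
         call. = FALSE)
  }
  invisible(x)
}

## moment-matched nonnegative draws -----------------------------------------

# Gamma draws with given mean and sd (shape = (m/s)^2, scale = s^2/m).
# sd = 0 gives a point mass at the mean; mean = 0 gives zeros.
rgamma_ms <- function(n, mean, sd) {
  if (mean <= 0) return(numeric(n) + 0)
  if (sd <= 0) return(rep(mean, n))
  shape <- (mean / sd)^2
  stats::rgamma(n, shape = shape, scale = sd^2 / mean)
}

# Lognormal draws with mean 1 and given coefficient of variation.
rlnorm_unit <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}
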