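#' Model specification for the gBLUP design problem
#'
#' Fixes the ingredients of the linear mixed model `y = X beta + Z gamma + e`
#' with `Z = I` on the phenotyped units, `gamma ~ N(0, sigma_g^2 G)` and
#' `e ~ N(0, sigma_e^2 I)`. Only the variance ratio `lambda = sigma_e^2 /
#' sigma_g^2` enters any design quantity, so the individual variance
#' components are never stored. All covariances are handled on the
#' proportional (sigma-free) scale.
#'
#' @param N number of candidate individuals (rows of the full fixed-effects
#'   matrix).
#' @param lambda positive variance ratio `sigma_e^2 / sigma_g^2`.
#' @param X optional `N x p` fixed-effects matrix over all candidates.
#'   Default: a single intercept column of ones.
#' @return An object of class `"model_spec"` with elements `X_full`,
#'   `lambda`, `p` and `N`.
#' @examples
#' spec <- model_spec(N = 10, lambda = 1)
#' spec$p
#' @export
model_spec <- function(N, lambda = 1, X = NULL) {
  N <- as.integer(N)
  if (N < 2) stop("'N' must be at least 2", call. = FALSE)
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda <= 0) {
    stop("'lambda' must be a single positive number", call. = FALSE)
  }
  if (is.null(X)) X <- matrix(1, N, 1)
  X <- as.matrix(X)
  if (nrow(X) != N) stop("'X' must have N rows", call. = FALSE)
  structure(
    list(X_full = X, lambda = as.numeric(lambda), p = ncol(X), N = N),
    class = "model_spec"
  )
}

#' Exact design: a support set and its complement
#'
#' An exact design of size `n` is an ordered subset of `n` distinct
#' candidate indices (the support set, the individuals to be phenotyped);
#' the remaining `N - n` candidates form the complement. Indices are 1-based.
#'
#' @param support integer vector of distinct candidate indices in `1..N`.
#'   A design occupying all of `1..N` (empty complement) is admissible for
#'   the model machinery; the exchange searches additionally require a
#'   nonempty candidate set.
#' @param N total number of candidates.
#' @return An object of class `"design"` with elements `support`,
#'   `candidates`, `n` and `N`.
#' @examples
#' d <- design(c(2, 5), N = 6)
#' d$candidates
#' @export
design <- function(support, N) {
  support <- as.integer(support)
  N <- as.integer(N)
  n <- length(support)
  if (n < 1 || n > N) stop("design size must satisfy 1 <= n <= N", call. = FALSE)
  if (anyDuplicated(support)) stop("support indices must be distinct (no replicates)", call. = FALSE)
  if (any(support < 1L | support > N)) stop("support indices must lie in 1..N", call. = FALSE)
  new_design(support, N)
}

# internal fast constructor: no validation, used inside search loops
new_design <- function(support, N) {
  structure(
    list(
      support = support,
      candidates = setdiff(seq_len(N), support),
      n = length(support),
      N = N
    ),
    class = "design"
  )
}

#' @export
print.design <- function(x, ...) {
  cat(sprintf(
    "Design: n = %d of N = %d; support = {%s}\n",
    x$n, x$N, paste(sort(x$support), collapse = ", ")
  ))
  invisible(x)
}

#' Draw a uniform-random design of size n
#'
#' @param N number of candidates.
#' @param n design size.
#' @return A `"design"` object. Uses the current RNG state; seed it for
#'   reproducibility.
#' @export
random_design <- function(N, n) {
  design(sample.int(N, n), N)
}

# check design/spec/grm consistency; called at user-facing entry points
check_design <- function(grm_obj, spec, des) {
  stopifnot(inherits(grm_obj, "grm"), inherits(spec, "model_spec"), inherits(des, "design"))
  if (des$N != grm_obj$N || spec$N != grm_obj$N) {
    stop("design, model spec and GRM disagree on the number of candidates", call. = FALSE)
  }
  if (des$n < spec$p) {
    stop(sprintf(
      "design size n = %d is below the number of fixed effects p = %d (rank deficiency)",
      des$n, spec$p
    ), call. = FALSE)
  }
  invisible(TRUE)
}
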