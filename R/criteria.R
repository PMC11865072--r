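#' Design criterion specification
#'
#' Bundles a criterion name with its options behind a uniform contract.
#' Supported criteria (all maximized):
#' \describe{
#'   \item{`"D"`}{`-ln |H22(xi)|`, the D-criterion on the random-effect
#'     (PEV) block: minimizes the generalized prediction variance.}
#'   \item{`"CDMin"`}{the minimum coefficient of determination over the
#'     target set: guards the worst-predicted individual.}
#'   \item{`"CDMean"`}{the mean CD over the target set.}
#' }
#'
#' @param name one of `"D"`, `"CDMin"`, `"CDMean"`.
#' @param target_set indices over which CD criteria are evaluated; `NULL`
#'   (default) means all `N` candidates, support and non-support alike.
#' @return An object of class `"criterion_spec"`.
#' @export
criterion_spec <- function(name = c("D", "CDMin", "CDMean"), target_set = NULL) {
  name <- match.arg(name)
  if (!is.null(target_set)) {
    target_set <- as.integer(target_set)
    if (length(target_set) == 0) {
      stop("'target_set' must be nonempty for CD criteria", call. = FALSE)
    }
  }
  structure(list(name = name, target_set = target_set), class = "criterion_spec")
}

#' D-criterion on the random-effect block
#'
#' Returns `-ln |H22(xi)|`, computed as the log-determinant of
#' `H22^{-1} = I_n + lambda G(xi)^{-1} - X(X'X)^{-1}X'` (Schur form), so no
#' full MME inverse is formed. Larger is better; invariant under support
#' permutation.
#'
#' @inheritParams build_mme
#' @return finite scalar.
#' @export
d_criterion <- function(grm_obj, spec, des) {
  sup <- des$support
  n <- des$n
  R <- chol_support(grm_obj, sup)
  K <- diag(n) + spec$lambda * chol2inv(R)
  if (spec$p > 0) {
    Xs <- spec$X_full[sup, , drop = FALSE]
    K <- K - Xs %*% solve(crossprod(Xs), t(Xs))
  }
  ld <- determinant(K, logarithm = TRUE)
  if (ld$sign <= 0) {
    stop(sprintf(
      "PEV block is not positive definite on support {%s}",
      paste(sort(sup), collapse = ", ")
    ), call. = FALSE)
  }
  as.numeric(ld$modulus)
}

#' Minimum-CD criterion
#'
#' The smallest coefficient of determination over the target set: the
#' design is scored by its worst-predicted individual. In `[0, 1]`, larger
#' is better.
#'
#' @inheritParams cd_matrix
#' @param target_set target indices; default all `N` individuals.
#' @return scalar in `[0, 1]`.
#' @export
cdmin_criterion <- function(grm_obj, spec, des, target_set = seq_len(grm_obj$N)) {
  min(cd_matrix(grm_obj, spec, des, targets = target_set))
}

#' Mean-CD criterion
#'
#' The average coefficient of determination over the target set.
#'
#' @inheritParams cdmin_criterion
#' @return scalar in `[0, 1]`.
#' @export
cdmean_criterion <- function(grm_obj, spec, des, target_set = seq_len(grm_obj$N)) {
  mean(cd_matrix(grm_obj, spec, des, targets = target_set))
}

#' Criterion-evaluation counter
#'
#' A mutable counter passed through the search algorithms; every call to
#' [evaluate_criterion()] increments it by one. Evaluation counts are the
#' hardware-independent cost metric used to compare algorithms.
#'
#' @return an environment with field `n` (count so far).
#' @export
eval_counter <- function() {
  e <- new.env(parent = emptyenv())
  e$n <- 0L
  e
}

#' Evaluate a design criterion
#'
#' Uniform dispatch over the named criteria, with optional cost accounting.
#' Pure in its inputs: two calls on the same design return the same value.
#'
#' @param criterion a [criterion_spec()].
#' @inheritParams build_mme
#' @param counter optional [eval_counter()]; incremented by exactly 1.
#' @return the scalar criterion value (maximization convention).
#' @export
evaluate_criterion <- function(criterion, grm_obj, spec, des, counter = NULL) {
  stopifnot(inherits(criterion, "criterion_spec"))
  if (!is.null(counter)) counter$n <- counter$n + 1L
  targets <- criterion$target_set
  if (is.null(targets)) targets <- seq_len(grm_obj$N)
  switch(criterion$name,
    D = d_criterion(grm_obj, spec, des),
    CDMin = cdmin_criterion(grm_obj, spec, des, target_set = targets),
    CDMean = cdmean_criterion(grm_obj, spec, des, target_set = targets),
    stop(sprintf("unknown criterion '%s'", criterion$name), call. = FALSE)
  )
}
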