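#' @title Mixed-model-equation machinery for a given design
#' @description
#' For a design with support set `xi` of size `n`, the (proportional)
#' information matrix of the gBLUP mixed model equations is
#' `M(xi) = D'D + lambda * B` with `D = [X_xi  I_n]` and
#' `B = blockdiag(0_pxp, G(xi)^{-1})`. Its inverse carries the
#' (proportional) covariance of the fixed-effect estimators and random-effect
#' predictors; the `n x n` lower-right block `H22` is the prediction error
#' variance (PEV) matrix of the random effects and is the object every
#' design criterion is built on.
#' @name mme
NULL

# Cholesky of the support-restricted GRM; error names offending indices
chol_support <- function(grm_obj, support) {
  Gs <- grm_obj$G[support, support, drop = FALSE]
  dimnames(Gs) <- NULL
  R <- tryCatch(chol(Gs), error = function(e) NULL)
  if (is.null(R)) {
    stop(sprintf(
      "support-restricted GRM G(xi) is singular for support indices {%s}",
      paste(sort(support), collapse = ", ")
    ), call. = FALSE)
  }
  R
}

#' Build the information matrix and its covariance blocks
#'
#' @param grm_obj a [grm()] object.
#' @param spec a [model_spec()].
#' @param des a [design()].
#' @return An object of class `"mme_blocks"`: list with the `q x q`
#'   information matrix `M` (`q = n + p`), its inverse `M_inv`, and the four
#'   covariance blocks `H11` (`p x p`, fixed effects), `H12`, `H21` and
#'   `H22` (`n x n`, random effects / PEV).
#' @examples
#' g <- grm(diag(2))
#' b <- build_mme(g, model_spec(2), design(1:2, 2))
#' b$H22
#' @export
build_mme <- function(grm_obj, spec, des) {
  check_design(grm_obj, spec, des)
  sup <- des$support
  n <- des$n
  p <- spec$p
  R <- chol_support(grm_obj, sup)
  Ginv <- chol2inv(R)
  Xs <- unname(spec$X_full[sup, , drop = FALSE])
  D <- cbind(Xs, diag(n))
  B <- matrix(0, n + p, n + p)
  B[(p + 1):(p + n), (p + 1):(p + n)] <- Ginv
  M <- crossprod(D) + spec$lambda * B
  M <- (M + t(M)) / 2
  M_inv <- tryCatch(solve(M), error = function(e) {
    stop(sprintf(
      "information matrix is singular for support {%s}: %s",
      paste(sort(sup), collapse = ", "), conditionMessage(e)
    ), call. = FALSE)
  })
  fi <- seq_len(p)
  ri <- (p + 1):(p + n)
  structure(
    list(
      M = M, M_inv = M_inv,
      H11 = M_inv[fi, fi, drop = FALSE],
      H12 = M_inv[fi, ri, drop = FALSE],
      H21 = M_inv[ri, fi, drop = FALSE],
      H22 = M_inv[ri, ri, drop = FALSE],
      support = sup, n = n, p = p, lambda = spec$lambda
    ),
    class = "mme_blocks"
  )
}

#' PEV block via the Schur complement
#'
#' Computes the random-effect covariance block `H22` without forming the
#' full information matrix, through
#' `H22 = (I_n + lambda * G(xi)^{-1} - X(X'X)^{-1}X')^{-1}` (the Schur
#' complement of the fixed-effect block). Serves as an algebraically
#' independent route to the same quantity as [build_mme()].
#'
#' @inheritParams build_mme
#' @return `n x n` matrix equal to the `H22` block of [build_mme()].
#' @export
h22_via_schur <- function(grm_obj, spec, des) {
  check_design(grm_obj, spec, des)
  sup <- des$support
  n <- des$n
  R <- chol_support(grm_obj, sup)
  K <- diag(n) + spec$lambda * chol2inv(R)
  if (spec$p > 0) {
    Xs <- spec$X_full[sup, , drop = FALSE]
    XtX <- crossprod(Xs)
    K <- K - Xs %*% solve(XtX, t(Xs))
  }
  solve((K + t(K)) / 2)
}

# Schur route without fixed effects is used by p = 0 internal paths; the
# exported surface always carries at least the intercept.

#' Prediction variance of the observed (support) units
#'
#' Proportional variance of the fitted values on the support set,
#' `diag(D M^{-1} D')`.
#'
#' @param blocks result of [build_mme()].
#' @param spec the [model_spec()] used to build `blocks`.
#' @param des the [design()] used to build `blocks`.
#' @return numeric vector of length `n`, strictly positive, aligned with
#'   `des$support`.
#' @export
prediction_variance_observed <- function(blocks, spec, des) {
  stopifnot(inherits(blocks, "mme_blocks"))
  Xs <- spec$X_full[des$support, , drop = FALSE]
  D <- cbind(Xs, diag(des$n))
  rowSums((D %*% blocks$M_inv) * D)
}

#' Prediction variance of an unobserved individual
#'
#' For a candidate `x0` outside the support, the proportional prediction
#' variance of its genomic estimated breeding value is `d0 M^{-1} d0'` with
#' `d0 = [x0  z0]` and `z0 = G(x0, xi) G(xi)^{-1}`: the unobserved random
#' effect is carried onto the trained units through the relationship matrix.
#'
#' @inheritParams prediction_variance_observed
#' @param grm_obj the [grm()] object.
#' @param unit index of a candidate outside the support.
#' @return positive scalar.
#' @export
prediction_variance_unobserved <- function(grm_obj, spec, des, blocks, unit) {
  stopifnot(inherits(blocks, "mme_blocks"))
  unit <- as.integer(unit)
  if (unit %in% des$support) {
    stop(sprintf("unit %d is in the support set; use prediction_variance_observed()", unit),
      call. = FALSE
    )
  }
  sup <- des$support
  R <- chol_support(grm_obj, sup)
  z0 <- backsolve(R, forwardsolve(t(R), unname(grm_obj$G[sup, unit])))
  d0 <- unname(c(spec$X_full[unit, ], z0))
  as.numeric(d0 %*% blocks$M_inv %*% d0)
}

# vectorized candidate variances (one solve for all candidates); internal,
# used by unit_scores in the exchange algorithms
prediction_variance_candidates <- function(grm_obj, spec, des, blocks) {
  sup <- des$support
  cand <- des$candidates
  R <- chol_support(grm_obj, sup)
  Z0 <- t(backsolve(R, forwardsolve(t(R), unname(grm_obj$G[sup, cand, drop = FALSE]))))
  D0 <- cbind(unname(spec$X_full[cand, , drop = FALSE]), Z0)
  rowSums((D0 %*% blocks$M_inv) * D0)
}

#' Fixed-effect annihilating projection on the support set
#'
#' On the proportional scale `V = G(xi) + lambda * I_n`, returns
#' `P = V^{-1} - V^{-1} X (X' V^{-1} X)^{-1} X' V^{-1}`, the projection that
#' annihilates the fixed-effects columns (`P X_xi = 0`). All coefficient-of-
#' determination quantities are quadratic forms in `P`.
#'
#' @inheritParams build_mme
#' @return symmetric `n x n` matrix.
#' @export
projection_matrix <- function(grm_obj, spec, des) {
  check_design(grm_obj, spec, des)
  sup <- des$support
  V <- unname(grm_obj$G[sup, sup, drop = FALSE]) + spec$lambda * diag(des$n)
  Vi <- chol2inv(chol(V))
  if (spec$p == 0) return((Vi + t(Vi)) / 2)
  Xs <- spec$X_full[sup, , drop = FALSE]
  ViX <- Vi %*% Xs
  XtViX <- crossprod(Xs, ViX)
  ok <- tryCatch({
    middle <- solve(XtViX, t(ViX))
    TRUE
  }, error = function(e) FALSE)
  if (!ok) {
    stop("X' V^{-1} X is singular: fixed-effects matrix is rank-deficient on this support",
      call. = FALSE
    )
  }
  P <- Vi - ViX %*% middle
  (P + t(P)) / 2
}

# clamp CD values into [0,1]; warn only on material excursions
clamp_cd <- function(cd, tol = 1e-8) {
  excess <- pmax(cd - 1, -cd, 0)
  if (any(excess > tol)) {
    warning(sprintf(
      "CD value outside [0,1] by up to %.3e before clamping", max(excess)
    ), call. = FALSE)
  }
  pmin(pmax(cd, 0), 1)
}

#' Coefficient of determination of target individuals
#'
#' The generalized coefficient of determination (CD) of individual `i` given
#' a training design is the proportion of its random-effect variance
#' explained by the prediction -- equivalently the squared correlation
#' between the predicted and realized effect. It is computed as the
#' quadratic form `CD_i = G(i, xi) P G(xi, i) / G(i, i)` with `P` from
#' [projection_matrix()], and lies in `[0, 1]` (clamped against floating-
#' point excursions). Targets may be inside or outside the support.
#'
#' @inheritParams build_mme
#' @param targets integer vector of target individuals in `1..N`.
#' @return numeric vector of CD values aligned with `targets`.
#' @examples
#' g <- grm(diag(2))
#' cd_matrix(g, model_spec(2), design(1:2, 2), targets = 1:2)
#' @export
cd_matrix <- function(grm_obj, spec, des, targets = seq_len(grm_obj$N)) {
  targets <- as.integer(targets)
  if (length(targets) == 0) stop("'targets' must be nonempty", call. = FALSE)
  if (any(targets < 1L | targets > grm_obj$N)) {
    stop("targets must lie in 1..N", call. = FALSE)
  }
  P <- projection_matrix(grm_obj, spec, des)
  A <- unname(grm_obj$G[targets, des$support, drop = FALSE])
  num <- rowSums((A %*% P) * A)
  clamp_cd(num / unname(diag(grm_obj$G)[targets]))
}

#' Coefficient of determination of contrasts
#'
#' Extends the per-individual CD to linear contrasts between target
#' individuals: for a contrast column `c` with zero sum, the value is
#' `(c' G(T, xi) P G(xi, T) c) / (c' G(T, T) c)` where `T` is the target
#' set. Useful when the quantity of interest is a difference of breeding
#' values rather than a single one.
#'
#' @inheritParams cd_matrix
#' @param contrasts numeric matrix with `length(targets)` rows; every column
#'   must sum to zero (tolerance `1e-10`).
#' @return numeric vector with one CD value per contrast column.
#' @export
cd_contrasts <- function(grm_obj, spec, des, contrasts,
                         targets = seq_len(grm_obj$N)) {
  contrasts <- as.matrix(contrasts)
  targets <- as.integer(targets)
  if (nrow(contrasts) != length(targets)) {
    stop("'contrasts' must have one row per target", call. = FALSE)
  }
  csums <- colSums(contrasts)
  if (any(abs(csums) > 1e-10)) {
    stop(sprintf(
      "contrast column(s) %s do not sum to zero",
      paste(which(abs(csums) > 1e-10), collapse = ", ")
    ), call. = FALSE)
  }
  P <- projection_matrix(grm_obj, spec, des)
  A <- unname(grm_obj$G[targets, des$support, drop = FALSE])
  Gt <- unname(grm_obj$G[targets, targets, drop = FALSE])
  B <- crossprod(contrasts, A)          # k x n, rows are c' G(T, xi)
  num <- rowSums((B %*% P) * B)
  den <- colSums(contrasts * (Gt %*% contrasts))
  clamp_cd(num / den)
}
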