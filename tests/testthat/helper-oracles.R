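# Naive, formula-transcription oracles kept deliberately independent of the
# package's internal routes (full inverses everywhere, no Cholesky, no Schur
# shortcuts). Tests compare the package against these.

# random correlation-like SPD relationship matrix
rand_spd_grm <- function(N, seed) {
  set.seed(seed)
  A <- matrix(stats::rnorm(N * (N + 5)), N)
  G <- tcrossprod(A) / (N + 5)
  s <- sqrt(diag(G))
  grm(G / tcrossprod(s))
}

# full MME route: D = [X_sup I], B = blockdiag(0, solve(G_sup)),
# M = D'D + lambda B, everything by explicit solve()
naive_mme <- function(G, X, lambda, sup) {
  G <- unname(G); X <- unname(X)
  n <- length(sup)
  p <- ncol(X)
  Xs <- X[sup, , drop = FALSE]
  D <- cbind(Xs, diag(n))
  B <- matrix(0, n + p, n + p)
  B[(p + 1):(p + n), (p + 1):(p + n)] <- solve(G[sup, sup])
  M <- t(D) %*% D + lambda * B
  Minv <- solve(M)
  list(
    M = M, Minv = Minv, D = D,
    H11 = Minv[seq_len(p), seq_len(p), drop = FALSE],
    H22 = Minv[(p + 1):(p + n), (p + 1):(p + n), drop = FALSE]
  )
}

naive_d_criterion <- function(G, X, lambda, sup) {
  -log(det(naive_mme(G, X, lambda, sup)$H22))
}

naive_projection <- function(G, X, lambda, sup) {
  G <- unname(G); X <- unname(X)
  V <- G[sup, sup] + lambda * diag(length(sup))
  Vi <- solve(V)
  Xs <- X[sup, , drop = FALSE]
  Vi - Vi %*% Xs %*% solve(t(Xs) %*% Vi %*% Xs) %*% t(Xs) %*% Vi
}

naive_cd <- function(G, X, lambda, sup, targets) {
  P <- naive_projection(G, X, lambda, sup)
  unname(sapply(targets, function(t0) {
    a <- unname(G[t0, sup])
    as.numeric(t(a) %*% P %*% a) / G[t0, t0]
  }))
}

naive_cdmin <- function(G, X, lambda, sup) {
  min(naive_cd(G, X, lambda, sup, seq_len(nrow(G))))
}

naive_pred_var_observed <- function(G, X, lambda, sup) {
  nm <- naive_mme(G, X, lambda, sup)
  unname(diag(nm$D %*% nm$Minv %*% t(nm$D)))
}

naive_pred_var_unobserved <- function(G, X, lambda, sup, unit) {
  nm <- naive_mme(G, X, lambda, sup)
  z0 <- G[unit, sup] %*% solve(G[sup, sup])
  d0 <- c(X[unit, ], z0)
  as.numeric(t(d0) %*% nm$Minv %*% d0)
}

# exchangeable two-unit micro population: G = I2, intercept, lambda = 1
micro_fixture <- function() {
  list(grm = grm(diag(2)), spec = model_spec(2, lambda = 1), des = design(1:2, 2))
}

# independent full-neighborhood rescan of swap-local optimality
rescan_local_optimum <- function(grm_obj, spec, cspec, des, tol = 1e-12) {
  cur <- evaluate_criterion(cspec, grm_obj, spec, des)
  for (si in seq_len(des$n)) {
    for (cand in des$candidates) {
      sup2 <- des$support
      sup2[si] <- cand
      val <- evaluate_criterion(cspec, grm_obj, spec, design(sup2, des$N))
      if (val > cur + tol) return(FALSE)
    }
  }
  TRUE
}
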