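# Exchangeable micro population (G = I2, intercept, lambda = 1): every block
# below was computed by direct inversion of the 3x3 information matrix
# before the implementation existed.

test_that("information matrix and covariance blocks match the hand oracle", {
  fx <- micro_fixture()
  b <- build_mme(fx$grm, fx$spec, fx$des)

  expect_equal(unname(b$M), rbind(c(2, 1, 1), c(1, 2, 0), c(1, 0, 2)), tolerance = 1e-12)
  expect_equal(unname(b$H22), rbind(c(0.75, 0.25), c(0.25, 0.75)), tolerance = 1e-12)
  expect_lt(max(abs(b$M %*% b$M_inv - diag(3))), 1e-8)
  expect_equal(dim(b$H11), c(1, 1))
  expect_equal(dim(b$H12), c(1, 2))

  # Schur route: H22^{-1} = I + G^{-1} - J/2 = 2I - J/2 at lambda = 1
  expect_equal(unname(h22_via_schur(fx$grm, fx$spec, fx$des)),
    solve(2 * diag(2) - 0.5 * matrix(1, 2, 2)),
    tolerance = 1e-12
  )
})

test_that("Schur and full-inverse H22 routes agree on random fixtures", {
  for (lam in c(0.1, 1, 10)) {
    for (seed in 1:4) {
      g <- rand_spd_grm(20, seed = seed)
      spec <- model_spec(20, lambda = lam)
      des <- design(c(2, 5, 7, 11, 13, 17, 19, 20), 20)
      b <- build_mme(g, spec, des)
      h <- h22_via_schur(g, spec, des)
      expect_lt(max(abs(h - b$H22)) / max(abs(b$H22)), 1e-8)
      # and both agree with the naive transcription oracle
      expect_equal(unname(b$H22), naive_mme(g$G, spec$X_full, lam, des$support)$H22,
        tolerance = 1e-8
      )
    }
  }
})

test_that("intercept-free Schur route reduces to (I + lambda G^-1)^-1", {
  g <- rand_spd_grm(8, seed = 3)
  spec0 <- model_spec(8, lambda = 1.7, X = matrix(numeric(0), 8, 0))
  des <- design(c(1, 4, 6), 8)
  expect_equal(
    h22_via_schur(g, spec0, des),
    unname(solve(diag(3) + 1.7 * solve(g$G[des$support, des$support]))),
    tolerance = 1e-10
  )
})

test_that("singular restricted GRM and rank errors are explicit", {
  # duplicated individuals make the support-restricted GRM exactly singular;
  # bypass the constructor guard to exercise the downstream error path
  G <- diag(4)
  G[1, 2] <- G[2, 1] <- 1
  g <- structure(list(ids = paste0("id", 1:4), G = G, N = 4L), class = "grm")
  spec <- model_spec(4)
  expect_error(build_mme(g, spec, design(c(1, 2), 4)), "singular.*1, 2")
  expect_error(
    build_mme(grm(diag(3)), model_spec(3, X = cbind(1, c(1, 2, 3))), design(1, 3)),
    "below the number of fixed effects"
  )
})

test_that("prediction variances match the naive oracle and permute with the support", {
  g <- rand_spd_grm(20, seed = 9)
  spec <- model_spec(20, lambda = 1.3)
  sup <- c(3, 8, 1, 15, 12)
  des <- design(sup, 20)
  b <- build_mme(g, spec, des)

  pv <- prediction_variance_observed(b, spec, des)
  expect_true(all(pv > 0))
  expect_equal(pv, naive_pred_var_observed(g$G, spec$X_full, 1.3, sup), tolerance = 1e-9)

  # permutation equivariance
  perm <- c(4, 1, 5, 2, 3)
  des_p <- design(sup[perm], 20)
  b_p <- build_mme(g, spec, des_p)
  expect_equal(prediction_variance_observed(b_p, spec, des_p), pv[perm], tolerance = 1e-10)
  expect_equal(unname(b_p$H22), unname(b$H22[perm, perm]), tolerance = 1e-10)

  for (unit in c(2, 20)) {
    expect_equal(
      prediction_variance_unobserved(g, spec, des, b, unit),
      naive_pred_var_unobserved(g$G, spec$X_full, 1.3, sup, unit),
      tolerance = 1e-9
    )
  }
  expect_error(prediction_variance_unobserved(g, spec, des, b, 3), "support")
})

test_that("a candidate unrelated to the support reduces to the H11 quadratic form", {
  # unit 3 unrelated to support {1, 2}
  g <- grm(diag(3))
  spec <- model_spec(3)
  des <- design(1:2, 3)
  b <- build_mme(g, spec, des)
  expect_equal(
    prediction_variance_unobserved(g, spec, des, b, 3),
    as.numeric(b$H11),
    tolerance = 1e-12
  )
})

test_that("projection annihilates the fixed effects and matches the naive formula", {
  for (seed in 1:3) {
    g <- rand_spd_grm(12, seed = seed + 100)
    spec <- model_spec(12, lambda = 0.8)
    des <- design(c(1, 3, 6, 9, 12), 12)
    P <- projection_matrix(g, spec, des)
    Xs <- spec$X_full[des$support, , drop = FALSE]
    expect_lt(max(abs(P %*% Xs)), 1e-8)
    expect_lt(max(abs(P - t(P))), 1e-12)
    expect_equal(P, naive_projection(g$G, spec$X_full, 0.8, des$support), tolerance = 1e-10)
  }
  # p = 0: projection is plain V^{-1}
  g <- rand_spd_grm(6, seed = 5)
  spec0 <- model_spec(6, lambda = 2, X = matrix(numeric(0), 6, 0))
  des <- design(c(2, 4), 6)
  expect_equal(projection_matrix(g, spec0, des),
    unname(solve(g$G[c(2, 4), c(2, 4)] + 2 * diag(2))),
    tolerance = 1e-10
  )
})

test_that("CD values match the PEV identity, stay in [0,1], and vanish for unrelated targets", {
  fx <- micro_fixture()
  expect_equal(cd_matrix(fx$grm, fx$spec, fx$des, targets = 1:2), c(0.25, 0.25),
    tolerance = 1e-12
  )

  # PEV identity CD_i = 1 - lambda * H22_ii / G_ii on random fixtures
  for (lam in c(0.1, 1, 10)) {
    g <- rand_spd_grm(20, seed = 77)
    spec <- model_spec(20, lambda = lam)
    des <- design(seq(1, 20, by = 3), 20)
    b <- build_mme(g, spec, des)
    cd_sup <- cd_matrix(g, spec, des, targets = des$support)
    ident <- 1 - lam * diag(b$H22) / diag(g$G)[des$support]
    expect_equal(cd_sup, unname(ident), tolerance = 1e-8)
  }

  # bounds on all N targets
  g <- rand_spd_grm(20, seed = 78)
  spec <- model_spec(20)
  des <- design(1:8, 20)
  cd <- cd_matrix(g, spec, des)
  expect_true(all(cd >= 0 & cd <= 1))
  expect_equal(cd, naive_cd(g$G, spec$X_full, 1, des$support, 1:20), tolerance = 1e-9)

  # unrelated target has CD exactly 0
  g0 <- grm(diag(3))
  expect_equal(cd_matrix(g0, model_spec(3), design(1:2, 3), targets = 3), 0)

  # no genetic signal limit
  spec_big <- model_spec(20, lambda = 1e6)
  expect_lte(max(cd_matrix(g, spec_big, des)), 1e-3)

  expect_error(cd_matrix(g, spec, des, targets = integer(0)), "nonempty")
})

test_that("contrast CDs are sign-invariant, vanish for unrelated pairs, and match the oracle", {
  fx <- micro_fixture()
  c1 <- matrix(c(1, -1), 2, 1)
  v <- cd_contrasts(fx$grm, fx$spec, fx$des, c1, targets = 1:2)
  expect_true(v >= 0 && v <= 1)
  expect_equal(v, cd_contrasts(fx$grm, fx$spec, fx$des, -c1, targets = 1:2))

  # difference of two unrelated non-support units
  g0 <- grm(diag(4))
  c2 <- matrix(c(1, -1), 2, 1)
  expect_equal(
    cd_contrasts(g0, model_spec(4), design(1:2, 4), c2, targets = 3:4), 0
  )

  # random contrasts vs naive per-column quadratic forms
  g <- rand_spd_grm(20, seed = 11)
  spec <- model_spec(20)
  des <- design(c(2, 4, 9, 14, 18), 20)
  set.seed(1)
  C <- matrix(rnorm(20 * 3), 20, 3)
  C <- sweep(C, 2, colMeans(C)) # zero-sum columns
  got <- cd_contrasts(g, spec, des, C)
  P <- naive_projection(g$G, spec$X_full, 1, des$support)
  A <- g$G[, des$support]
  want <- sapply(1:3, function(k) {
    b <- as.numeric(t(C[, k]) %*% A)
    as.numeric(t(b) %*% P %*% b) / as.numeric(t(C[, k]) %*% g$G %*% C[, k])
  })
  expect_equal(got, want, tolerance = 1e-9)

  expect_error(cd_contrasts(g, spec, des, matrix(1, 20, 1)), "sum to zero")
})
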