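# Robust density fitting: complete-fitting identities, oracle comparisons,
# variational second-order error behaviour, and the fitted coupling.

# one-centre system whose AO product space is spanned exactly by s fitting
# functions with the summed exponents
.span_ao <- function() list(shell_block(0, c(0, 0, 0), 1.3, 1),
                            shell_block(0, c(0, 0, 0), 0.4, 1))
.span_fit <- function() list(shell_block(0, c(0, 0, 0), 2.6, 1),
                             shell_block(0, c(0, 0, 0), 1.7, 1),
                             shell_block(0, c(0, 0, 0), 0.8, 1))

test_that("complete fitting reproduces exact J and K", {
  M <- four_index(.span_ao())
  B3 <- three_index(.span_ao(), .span_fit())
  J2 <- coulomb_metric(.span_fit())
  D <- matrix(c(0.9, 0.3, 0.3, 0.5), 2)
  jk <- neoscf:::jk_exact(M, D)
  expect_lt(max(abs(build_J_df(D, B3, J2) - jk$J)), 1e-10)
  # exchange for an idempotent single-orbital density
  S <- one_particle(.span_ao())$S
  X <- neoscf:::lowdin_x(S)
  C1 <- X[, 1, drop = FALSE] / sqrt(sum((S %*% X[, 1]) * X[, 1]))
  Didem <- 2 * tcrossprod(C1)
  jki <- neoscf:::jk_exact(M, Didem)
  expect_lt(max(abs(build_K_df(C1, B3, J2, occ = 2) - jki$K)), 1e-10)
})

test_that("zero density and empty occupied set give zero builds", {
  B3 <- three_index(.span_ao(), .span_fit())
  J2 <- coulomb_metric(.span_fit())
  expect_equal(build_J_df(matrix(0, 2, 2), B3, J2), matrix(0, 2, 2))
  expect_equal(build_K_df(NULL, B3, J2), matrix(0, 2, 2))
  d <- fit_coefficients(matrix(0, 2, 2), B3, J2)
  expect_equal(as.numeric(d), rep(0, 3))
})

test_that("fit coefficients solve the metric equation", {
  B3 <- three_index(.span_ao(), .span_fit())
  J2 <- coulomb_metric(.span_fit())
  D <- matrix(c(1.1, -0.2, -0.2, 0.7), 2)
  d <- fit_coefficients(D, B3, J2)
  rhs <- attr(d, "rhs")
  expect_lt(sqrt(sum((J2 %*% d - rhs)^2)) / sqrt(sum(rhs^2)), 1e-10)
})

test_that("H2 with a saturated fitting basis approaches exact J/K", {
  sys <- generate_fixture("h2")
  bas <- make_basis(sys, "sto-3g")
  # dense even-tempered ladder on both atoms plus a bond-midpoint centre for
  # the off-centre s x s products
  mid <- colMeans(sys$coords)
  fit <- c(build_even_tempered(sys$coords[1, ], 14, 2, 40, 1.6),
           build_even_tempered(sys$coords[2, ], 14, 2, 40, 1.6),
           build_even_tempered(mid, 14, 2, 40, 1.6))
  M <- four_index(bas)
  rhf <- neoscf:::rhf_in_basis(sys, bas)
  jk <- neoscf:::jk_exact(M, rhf$D)
  B3 <- three_index(bas, fit)
  J2 <- suppressWarnings(coulomb_metric(fit))
  Jdf <- build_J_df(rhf$D, B3, J2)
  Kdf <- build_K_df(rhf$C[, 1, drop = FALSE], B3, J2)
  expect_lt(max(abs(Jdf - jk$J)), 1e-6)
  expect_lt(max(abs(Kdf - jk$K)), 1e-6)
})

test_that("fitted Coulomb self-energy error is variational and shrinks with the basis", {
  ao <- list(shell_block(0, c(0, 0, 0), c(5, 1.2, 0.3), c(0.4, 0.5, 0.3)),
             shell_block(0, c(0, 0, 0), 0.7, 1))
  D <- matrix(c(1.4, 0.2, 0.2, 0.6), 2)
  fit_full <- build_even_tempered(c(0, 0, 0), 12, 0, 12, 1.5)
  fit_half <- fit_full[seq(1, 12, by = 2)]
  M <- four_index(ao)
  Eex <- 0.5 * sum(D * neoscf:::jk_exact(M, D)$J)
  efit <- function(fit) {
    B3 <- three_index(ao, fit)
    J2 <- suppressWarnings(coulomb_metric(fit))
    Eex - 0.5 * sum(D * build_J_df(D, B3, J2))
  }
  e_full <- efit(fit_full)
  e_half <- efit(fit_half)
  # error equals the Coulomb norm of the fitting residual: positive, and
  # growing fast as the ladder is thinned
  expect_gte(e_full, -1e-12)
  expect_gt(e_half, e_full)
  expect_gt(e_half / max(e_full, 1e-15), 3)
})

test_that("exchange build is invariant under occupied rotations", {
  sys <- generate_fixture("water")
  bas <- make_basis(sys, "sto-3g")
  rhf <- neoscf:::rhf_in_basis(sys, bas)
  Cocc <- rhf$C[, seq_len(rhf$nocc)]
  fb <- make_basis(sys, "tz-synth-jkfit")
  B3 <- three_index(bas, fb)
  fac <- df_metric_factor(coulomb_metric(fb))
  K1 <- build_K_df(Cocc, B3, fac)
  set.seed(3)
  Q <- qr.Q(qr(matrix(stats::rnorm(rhf$nocc^2), rhf$nocc)))
  K2 <- build_K_df(Cocc %*% Q, B3, fac)
  expect_lt(max(abs(K1 - K2)), 1e-10)
})

test_that("fitted coupling has the right sign, symmetry and exact limit", {
  # proton basis whose pair products are spanned exactly by the fit
  sys <- generate_fixture("h2", quantum = 2L)
  p <- 2L
  eb <- list(shell_block(0, sys$coords[1, ], 0.9, 1),
             shell_block(0, sys$coords[2, ], 0.9, 1))
  nb <- list(shell_block(0, sys$coords[p, ], 16, 1),
             shell_block(0, sys$coords[p, ], 4, 1))
  fit <- list(shell_block(0, sys$coords[p, ], 32, 1),
              shell_block(0, sys$coords[p, ], 20, 1),
              shell_block(0, sys$coords[p, ], 8, 1))
  X3 <- three_index(nb, fit)     # proton pairs x fit
  B3e <- three_index(eb, fit)    # electron pairs x fit
  J2 <- coulomb_metric(fit)
  Dn <- matrix(c(0.6, 0.2, 0.2, 0.3), 2)
  De <- matrix(c(0.8, 0.1, 0.1, 0.9), 2)
  # zero density -> zero coupling
  V0 <- build_coupling_J(matrix(0, 2, 2), X3, J2, B3e, -1, +1)
  expect_equal(max(abs(V0)), 0)
  # charge product flips the sign only
  Vep <- build_coupling_J(Dn, X3, J2, B3e, -1, +1)
  Vpp <- build_coupling_J(Dn, X3, J2, B3e, +1, +1)
  expect_equal(Vpp, -Vep, tolerance = 1e-14, ignore_attr = TRUE)
  # exact-span limit: fitted potential equals the exact cross contraction
  Vex <- -coulomb_contract(eb, nb, Dn, thresh = 1e-16)
  expect_lt(abs(sum(De * Vep) - sum(De * Vex)), 1e-8)
  # identical fitted intermediate on both sides: energies agree to 1e-10
  Vne <- build_coupling_J(De, B3e, J2, X3, +1, -1)
  expect_lt(abs(sum(De * Vep) - sum(Dn * Vne)), 1e-10)
})
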