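# Integral engine versus closed forms, the quadrature oracle, and the
# symmetry/scaling properties every tensor must satisfy.

test_that("one-particle integrals match closed forms and scale with mass", {
  sh <- list(shell_block(0, c(0, 0, 0), 1, 1))
  op <- one_particle(sh, mass = 1, charge = -1)
  expect_equal(op$S[1, 1], 1, tolerance = 1e-12)
  # kinetic energy of a normalised s Gaussian: 3 alpha / (2 m)
  expect_equal(op$T[1, 1], 1.5, tolerance = 1e-12)
  opm <- one_particle(sh, mass = PROTON_MASS)
  expect_equal(opm$T[1, 1], 1.5 / PROTON_MASS, tolerance = 1e-15)
  expect_identical(op$S, opm$S)
  # attraction at the centre: 2 sqrt(2 alpha / pi), signed by charge
  pc <- list(q = 1, pos = matrix(0, 1, 3))
  Ve <- one_particle(sh, charge = -1, point_charges = pc)$V
  Vp <- one_particle(sh, charge = +1, point_charges = pc)$V
  expect_equal(Ve[1, 1], -2 * sqrt(2 / pi), tolerance = 1e-12)
  expect_equal(Vp, -Ve, tolerance = 1e-14)
})

test_that("grid quadrature oracle confirms overlap and kinetic blocks", {
  shells <- list(shell_block(0, c(0, 0, 0), c(1.4, 0.35), c(0.5, 0.6)),
                 shell_block(1, c(0, 0, 1.1), 0.7, 1),
                 shell_block(0, c(0.4, -0.3, 0.2), 0.9, 1))
  eng <- one_particle(shells)
  orc <- oracle_one_particle(shells, spacing = 0.1, extent = 7)
  expect_lt(max(abs(eng$S - orc$S)), 5e-6)
  expect_lt(max(abs(eng$T - orc$T)), 5e-5)
})

test_that("Coulomb tensors match the radial quadrature oracle", {
  # metric diagonal: normalised s function against itself
  sh <- list(shell_block(0, c(0, 0, 0), 1, 1))
  J2 <- coulomb_metric(sh)
  N <- (2 / pi)^0.75
  expect_equal(J2[1, 1], oracle_coulomb_spherical(N, 1, N, 1, 0),
               tolerance = 1e-6)
  # off-centre metric entry
  shf <- list(shell_block(0, c(0, 0, 0), 1, 1),
              shell_block(0, c(0, 0, 1.7), 0.6, 1))
  J2b <- coulomb_metric(shf)
  Nb <- (2 * 0.6 / pi)^0.75
  expect_equal(J2b[1, 2], oracle_coulomb_spherical(N, 1, Nb, 0.6, 1.7),
               tolerance = 1e-6)
  expect_identical(J2b, t(J2b))
  # three-index entry via the Gaussian product of the bra pair
  B3 <- three_index(sh, list(shell_block(0, c(0, 0, 1.7), 0.6, 1)))
  expect_equal(B3[1, 1], oracle_coulomb_spherical(N^2, 2, Nb, 0.6, 1.7),
               tolerance = 1e-6)
  # four-index (gg|gg)
  M <- four_index(sh)
  expect_equal(M[1, 1], oracle_coulomb_spherical(N^2, 2, N^2, 2, 0),
               tolerance = 1e-6)
})

test_that("identical fitting functions give identical metric entries", {
  sh <- list(shell_block(0, c(0, 0, 0), 0.8, 1),
             shell_block(0, c(0, 0, 0), 0.8, 1))
  # duplicate functions make the metric singular by construction; the
  # regularised factorisation warning is expected here
  J2 <- suppressWarnings(coulomb_metric(sh))
  expect_equal(J2[1, 1], J2[2, 2], tolerance = 1e-13)
  expect_equal(J2[1, 1], J2[1, 2], tolerance = 1e-13)
})

test_that("four-index tensor has exact permutational symmetry and obeys Schwarz", {
  sys <- generate_fixture("hehplus")
  bas <- make_basis(sys, "sv-synth")
  M <- four_index(bas)
  n <- bas$nao
  set.seed(7)
  for (rep in 1:40) {
    id <- sample(n, 4, replace = TRUE)
    v <- eri4_elem(M, id[1], id[2], id[3], id[4])
    for (perm in list(c(2, 1, 3, 4), c(1, 2, 4, 3), c(3, 4, 1, 2),
                      c(4, 3, 2, 1))) {
      expect_identical(v, eri4_elem(M, id[perm[1]], id[perm[2]],
                                    id[perm[3]], id[perm[4]]))
    }
    # Cauchy-Schwarz for the positive-definite Coulomb kernel
    lhs <- eri4_elem(M, id[1], id[2], id[1], id[2]) *
      eri4_elem(M, id[3], id[4], id[3], id[4])
    expect_gte(lhs + 1e-14, v^2)
  }
})

test_that("all tensors are translation invariant", {
  shift <- c(0.73, -1.2, 0.41)
  mk <- function(s) {
    list(shell_block(0, c(0, 0, 0) + s, c(1.3, 0.4), c(0.7, 0.4)),
         shell_block(1, c(0, 0, 1.2) + s, 0.8, 1),
         shell_block(2, c(0.5, 0.3, 0) + s, 1.1, 1))
  }
  pc0 <- list(q = c(1, 8), pos = rbind(c(0, 0, 1.2), c(0, 0, 0)))
  pcs <- list(q = pc0$q, pos = sweep(pc0$pos, 2, -shift))
  a <- one_particle(mk(c(0, 0, 0)), charge = -1, point_charges = pc0)
  b <- one_particle(mk(shift), charge = -1, point_charges = pcs)
  expect_lt(max(abs(a$S - b$S)), 1e-10)
  expect_lt(max(abs(a$T - b$T)), 1e-10)
  expect_lt(max(abs(a$V - b$V)), 1e-10)
  expect_lt(max(abs(coulomb_metric(mk(c(0, 0, 0))) -
                    coulomb_metric(mk(shift)))), 1e-10)
  expect_lt(max(abs(unclass(four_index(mk(c(0, 0, 0)))) -
                    unclass(four_index(mk(shift))))), 1e-10)
})

test_that("three-index tensor is bra-symmetric and cross-class capable", {
  ao <- list(shell_block(0, c(0, 0, 0), c(1.2, 0.3), c(0.6, 0.5)),
             shell_block(1, c(0, 0, 1.4), 0.9, 1))
  fit <- build_even_tempered(c(0, 0, 0.7), 3, 1, 8, 2.5)
  B3 <- three_index(ao, fit)
  n <- basis_nfun(ao)
  A3 <- array(B3, c(n, n, basis_nfun(fit)))
  expect_lt(max(abs(A3 - aperm(A3, c(2, 1, 3)))), 1e-14)
})

test_that("direct screened contraction equals the dense contraction", {
  sys <- generate_fixture("water")
  bas <- make_basis(sys, "sto-3g")
  M <- four_index(bas)
  n <- bas$nao
  set.seed(11)
  D <- crossprod(matrix(stats::rnorm(n * n), n)) / n
  jk <- neoscf:::jk_exact(M, D)
  Jdir <- coulomb_contract(bas, bas, D, thresh = 1e-14)
  expect_lt(max(abs(Jdir - jk$J)), 1e-9)
})

test_that("electron and proton charges give sign-mirrored potentials", {
  sh <- build_even_tempered(c(0, 0, 0), 4, 1, 16, 3)
  pc <- list(q = 8, pos = matrix(c(0, 0, 1.5), 1, 3))
  Ve <- one_particle(sh, mass = 1, charge = -1, point_charges = pc)$V
  Vp <- one_particle(sh, mass = PROTON_MASS, charge = +1, point_charges = pc)$V
  expect_equal(Vp, -Ve, tolerance = 1e-13)
})
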