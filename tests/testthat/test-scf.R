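# SCF machinery: guesses, DIIS convergence, Roothaan stationarity, the
# block-diagonal nuclear guess, and single-particle exactness.

test_that("conventional RHF reproduces literature energies", {
  # H2/STO-3G at 0.74 A and water/STO-3G at the standard geometry are
  # textbook anchors
  h2 <- rhf_h2_sto3g()
  sys <- generate_fixture("h2")
  expect_equal(h2$energy + neoscf:::classical_repulsion(sys), -1.1167,
               tolerance = 2e-4)
  wat <- rhf_water_sto3g()
  s <- generate_fixture("water")
  expect_equal(wat$energy + neoscf:::classical_repulsion(s), -74.9659,
               tolerance = 5e-3)
})

test_that("convergence requires all three criteria and satisfies Roothaan", {
  st <- rhf_water_sto3g()
  expect_true(all(st$flags))
  expect_lte(st$trace$dE[st$iterations], 1e-8)
  expect_lte(st$trace$grad[st$iterations], 1e-8)
  expect_lte(st$iterations, 50)
  s <- generate_fixture("water")
  bas <- make_basis(s, "sto-3g")
  op <- one_particle(bas, charge = -1,
                     point_charges = neoscf:::classical_charges_all(s))
  S <- op$S
  # Roothaan stationarity and density invariants at convergence
  expect_lt(max(abs(st$F %*% st$D %*% S - S %*% st$D %*% st$F)), 1e-6)
  expect_equal(sum(st$D * S), 10, tolerance = 1e-8)
  expect_lt(max(abs(st$D %*% S %*% st$D - 2 * st$D)), 1e-6)
})

test_that("a converged start exits after one iteration", {
  sys <- generate_fixture("h2")
  bas <- make_basis(sys, "sto-3g")
  st <- rhf_h2_sto3g()
  M <- four_index(bas)
  op <- one_particle(bas, charge = -1,
                     point_charges = neoscf:::classical_charges_all(sys))
  st2 <- scf_iterate(
    op$T + op$V, op$S,
    fock_builder = function(D, orbs) {
      jk <- neoscf:::jk_exact(M, D)
      op$T + op$V + jk$J - 0.5 * jk$K
    },
    energy_fn = function(D, F, h) 0.5 * sum(D * (h + F)),
    D0 = st$D, nocc = 1, occ = 2)
  expect_equal(st2$iterations, 1)
  expect_lte(st2$trace$dE[1], 1e-8)
})

test_that("electronic guesses integrate to the electron count", {
  sys <- generate_fixture("water")
  bas <- make_basis(sys, "sv-synth")
  S <- one_particle(bas)$S
  for (mode in c("atomic_density", "minimal_projection")) {
    D <- electronic_guess(sys, bas, mode = mode)
    expect_equal(sum(D * S), 10, tolerance = 1e-6)
  }
  # one H atom, any mode -> one electron
  h <- neo_system("H", matrix(0, 1, 3), charge = 0)
  bh <- make_basis(h, "sv-synth")
  Sh <- one_particle(bh)$S
  Dh <- electronic_guess(h, bh, mode = "atomic_density")
  expect_equal(sum(Dh * Sh), 1, tolerance = 1e-6)
  expect_error(electronic_guess(sys, bas, mode = "supplied",
                                supplied = matrix(0, 2, 2)),
               "wrong dimension")
})

test_that("the projected minimal guess converges no slower than atomic densities", {
  sys <- generate_fixture("water")
  bas <- make_basis(sys, "sv-synth")
  cc <- neoscf:::classical_charges_all(sys)
  op <- one_particle(bas, charge = -1, point_charges = cc)
  M <- four_index(bas, max_pairs = 1e6)
  run_from <- function(D0) {
    scf_iterate(
      op$T + op$V, op$S,
      fock_builder = function(D, orbs) {
        jk <- neoscf:::jk_exact(M, D)
        op$T + op$V + jk$J - 0.5 * jk$K
      },
      energy_fn = function(D, F, h) 0.5 * sum(D * (h + F)),
      D0 = D0, nocc = 5, occ = 2, max_iter = 80)$iterations
  }
  it_atomic <- run_from(electronic_guess(sys, bas, "atomic_density"))
  it_proj <- run_from(electronic_guess(sys, bas, "minimal_projection"))
  expect_lte(it_proj, it_atomic)
})

test_that("block-diagonal guess occupies every centre; full diagonalisation does not", {
  sys <- generate_fixture("h5o2+", quantum = "all-H")
  cfg <- tiny_cfg(mode = "direct")
  ba <- basis_assignment(sys, cfg)
  ints <- neoscf:::build_neo_integrals(sys, ba, cfg)
  D_e <- electronic_guess(sys, ba$e, "atomic_density")
  keys <- names(ba$n_ao)
  sizes <- vapply(keys, function(k) ints$n[[k]]$nao, integer(1))
  off <- cumsum(c(0L, sizes[-length(sizes)]))
  blocks <- lapply(seq_along(keys), function(i) off[i] + seq_len(sizes[i]))
  ush <- unlist(lapply(ba$n_ao, function(b) b$shells), recursive = FALSE)
  cc <- neoscf:::classical_charges(sys)
  opu <- one_particle(ush, mass = PROTON_MASS, charge = +1,
                      point_charges = list(q = cc$q, pos = cc$pos))
  h_eff <- opu$T + opu$V - coulomb_contract(ush, ba$e, D_e)
  Db <- block_diag_guess(h_eff, opu$S, blocks)
  tr_b <- vapply(blocks, function(b)
    sum(Db[b, b] * opu$S[b, b]), numeric(1))
  expect_equal(tr_b, rep(1, 5), tolerance = 1e-10)
  # exact block structure
  Off <- Db
  for (b in blocks) Off[b, b] <- 0
  expect_equal(max(abs(Off)), 0)
  # full diagonalisation piles protons onto few centres
  Df <- neoscf:::full_diag_guess(h_eff, opu$S, 5)
  SD <- opu$S %*% Df %*% opu$S
  tr_f <- vapply(blocks, function(b)
    sum(Df[b, b] * opu$S[b, b]), numeric(1))
  expect_gt(max(tr_f), 1)
  # one block equals full diagonalisation for a single centre
  b1 <- blocks[[1]]
  D1b <- block_diag_guess(h_eff[b1, b1], opu$S[b1, b1], list(seq_along(b1)))
  D1f <- neoscf:::full_diag_guess(h_eff[b1, b1], opu$S[b1, b1], 1)
  expect_lt(max(abs(D1b - D1f)), 1e-10)
  expect_error(block_diag_guess(h_eff, opu$S, blocks[1:4]), "partition")
})

test_that("a lone quantum proton matches dense diagonalisation exactly", {
  # H2^{2+} with one quantum proton: no electrons, one classical charge
  sys <- neo_system(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 1.9)),
                    charge = 2L, quantum = 2L)
  expect_equal(n_electrons(sys), 0)
  cfg <- tiny_cfg(mode = "direct")
  res <- run_neo(sys, cfg)
  # the same one-particle Hamiltonian, diagonalised densely
  nb <- build_even_tempered(sys$coords[2, ], tiny_nb$n_per_l, tiny_nb$l_max,
                            tiny_nb$alpha_max, tiny_nb$ratio)
  op <- one_particle(nb, mass = PROTON_MASS, charge = +1,
                     point_charges = list(q = 1, pos = sys$coords[1, , drop = FALSE]))
  h <- op$T + op$V
  ev <- eigen(solve(op$S, h))$values
  e0 <- min(Re(ev[abs(Im(ev)) < 1e-10]))
  expect_equal(res$E_total - res$components$classical, e0, tolerance = 1e-12)
})

test_that("deuteration lowers the nuclear kinetic expectation", {
  sys <- generate_fixture("water", quantum = "all-H")
  cfg <- tiny_cfg(mode = "df", e_basis = "sto-3g")
  rh <- cached("neo_water_tiny_df", run_neo(sys, cfg))
  rd <- run_neo(set_deuterium(sys), cfg)
  kin <- function(res, sys) {
    ba <- basis_assignment(sys, res$config)
    ints <- neoscf:::build_neo_integrals(sys, ba, tiny_cfg(mode = "direct"))
    sum(vapply(names(res$Dn), function(k)
      sum(res$Dn[[k]] * ints$n[[k]]$T), numeric(1)))
  }
  expect_lt(kin(rd, set_deuterium(sys)), kin(rh, sys))
})
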