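# Intrinsic bond orbitals, domain construction and the local exchange build.

.dimer_rhf <- function() {
  cached("rhf_wdimer_svs", {
    sys <- generate_fixture("water_dimer")
    bas <- make_basis(sys, "sv-synth")
    fb <- make_basis(sys, "tz-synth-jkfit")
    op <- one_particle(bas, charge = -1,
                       point_charges = neoscf:::classical_charges_all(sys))
    B3 <- three_index(bas, fb)
    J2 <- coulomb_metric(fb)
    fac <- df_metric_factor(J2)
    st <- scf_iterate(
      op$T + op$V, op$S,
      fock_builder = function(D, orbs) {
        op$T + op$V + build_J_df(D, B3, fac) -
          0.5 * build_K_df(orbs$C, B3, fac, occ_num = orbs$n)
      },
      energy_fn = function(D, F, h) 0.5 * sum(D * (h + F)),
      D0 = electronic_guess(sys, bas, "atomic_density"),
      nocc = 10, occ = 2, max_iter = 80)
    list(sys = sys, bas = bas, fb = fb, S = op$S, st = st, B3 = B3, J2 = J2,
         fac = fac)
  })
}

test_that("a single occupied orbital localises to itself up to sign", {
  h <- neo_system(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 1.4)), charge = 0)
  bas <- make_basis(h, "sto-3g")
  rhf <- neoscf:::rhf_in_basis(h, bas)
  C1 <- rhf$C[, 1, drop = FALSE]
  S <- one_particle(bas)$S
  loc <- localize_ibo(C1, S, bas, h)
  expect_lt(min(max(abs(loc$L - C1)), max(abs(loc$L + C1))), 1e-10)
  expect_equal(sum(loc$charges), 1, tolerance = 1e-6)
})

test_that("localisation metric ascends and charges are normalised", {
  d <- .dimer_rhf()
  Cocc <- d$st$C[, 1:10]
  loc <- localize_ibo(Cocc, d$S, d$bas, d$sys)
  expect_true(all(diff(loc$metric_trace) > -1e-10))
  # per-orbital charges sum to unity (occupation-normalised)
  expect_equal(rowSums(loc$charges), rep(1, 10), tolerance = 1e-6)
  # LMOs stay orthonormal and span the occupied space
  SL <- crossprod(loc$L, d$S %*% loc$L)
  expect_lt(max(abs(SL - diag(10))), 1e-8)
  P1 <- tcrossprod(Cocc)
  P2 <- tcrossprod(loc$L)
  expect_lt(max(abs(P1 - P2)), 1e-8)
  # water-dimer bonds/lone pairs live on at most two atoms
  for (i in 1:10) {
    expect_gte(sum(sort(loc$charges[i, ], decreasing = TRUE)[1:2]), 0.95)
  }
})

test_that("domains shrink monotonically with the threshold and cover at 0", {
  d <- .dimer_rhf()
  loc <- localize_ibo(d$st$C[, 1:10], d$S, d$bas, d$sys)
  l0 <- build_domains(loc, d$bas, d$fb, d$sys, charge_threshold = 0)
  expect_true(all(vapply(l0$domains_ao, length, integer(1)) == d$bas$nao))
  l1 <- build_domains(loc, d$bas, d$fb, d$sys, charge_threshold = 0.05,
                      fit_extension = 0)
  l2 <- build_domains(loc, d$bas, d$fb, d$sys, charge_threshold = 0.2,
                      fit_extension = 0)
  for (i in 1:10) {
    expect_true(all(l2$domains_ao[[i]] %in% l1$domains_ao[[i]]))
  }
  expect_error(build_domains(loc, d$bas, d$fb, d$sys, charge_threshold = 1.2),
               "0, 1")
})

test_that("full domains reproduce the conventional fitted exchange", {
  d <- .dimer_rhf()
  loc <- localize_ibo(d$st$C[, 1:10], d$S, d$bas, d$sys)
  loc <- build_domains(loc, d$bas, d$fb, d$sys, charge_threshold = 0)
  K_ldf <- build_K_ldf(loc, d$B3, d$J2)
  K_df <- build_K_df(d$st$C[, 1:10], d$B3, d$fac)
  expect_lt(max(abs(K_ldf - K_df)), 1e-10)
})

test_that("local exchange is accurate at default domains on the dimer", {
  d <- .dimer_rhf()
  loc <- localize_ibo(d$st$C[, 1:10], d$S, d$bas, d$sys)
  loc <- build_domains(loc, d$bas, d$fb, d$sys)
  K_ldf <- build_K_ldf(loc, d$B3, d$J2)
  K_df <- build_K_df(d$st$C[, 1:10], d$B3, d$fac)
  dE <- -0.25 * sum(d$st$D * (K_ldf - K_df))
  expect_lt(abs(dE) * HARTREE_TO_KCALMOL, 0.01)
  rep <- domain_report(loc, d$sys)
  expect_equal(rep$n_orbitals, 10)
  expect_true(all(vapply(rep$orbitals, function(o) o$n_ao, numeric(1)) > 0))
})

test_that("repeated-monomer chains develop constant-size domains", {
  sizes <- function(n) {
    sys <- generate_fixture(sprintf("chain%d", n))
    bas <- make_basis(sys, "sto-3g")
    fb <- make_basis(sys, "tz-synth-jkfit")
    rhf <- neoscf:::rhf_in_basis(sys, bas)
    loc <- localize_ibo(rhf$C[, seq_len(rhf$nocc)], one_particle(bas)$S,
                        bas, sys)
    loc <- build_domains(loc, bas, fb, sys)
    mean(vapply(loc$domains_ao, length, integer(1)))
  }
  # long enough that the distance-extended domains no longer cover the
  # whole chain: the mean domain size saturates
  s5 <- sizes(5)
  s7 <- sizes(7)
  expect_lt(abs(s7 - s5) / s5, 0.10)
})
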