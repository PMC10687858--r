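# Shared test machinery: reduced-size nuclear bases for fast unit tests, a
# cache so expensive converged runs are shared between test files, and an
# independent brute-force alternating-diagonalisation NEO oracle.

.test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.test_cache[[key]])) .test_cache[[key]] <- force(expr)
  .test_cache[[key]]
}

# lean nuclear bases: enough structure for physics, cheap enough for tests
tiny_nb <- list(n_per_l = 4, l_max = 1, alpha_max = 24, ratio = 2.6)
tiny_nf <- list(n_per_l = 6, l_max = 2, alpha_max = 48, ratio = 2.4)

tiny_cfg <- function(mode = "direct", e_basis = "sto-3g", ...) {
  neo_config(mode = mode, e_basis = e_basis, n_basis = tiny_nb,
             n_fit = tiny_nf, ...)
}

# shared expensive artefacts, constructed on first use from any test file
rhf_water_sto3g <- function() {
  cached("rhf_water_sto3g", {
    s <- generate_fixture("water")
    neoscf:::rhf_in_basis(s, make_basis(s, "sto-3g"))
  })
}

rhf_h2_sto3g <- function() {
  cached("rhf_h2_sto3g", {
    s <- generate_fixture("h2")
    neoscf:::rhf_in_basis(s, make_basis(s, "sto-3g"))
  })
}

neo_water_df <- function() {
  cached("neo_water_sto3g_df", {
    run_neo(generate_fixture("water", quantum = "all-H"),
            tiny_cfg(mode = "df", e_basis = "sto-3g", keep_integrals = TRUE))
  })
}

nqe_h2_runs <- function() {
  cached("nqe_h2", {
    cfg <- neo_config(mode = "direct", e_basis = "sto-3g",
                      n_basis = list(n_per_l = 4, l_max = 1, alpha_max = 24,
                                     ratio = 2.6))
    nqe_delta(generate_fixture("h2", quantum = "all-H"), cfg)
  })
}

# run_neo versus the brute-force alternating dense-diagonalisation oracle
neo_h2_oracle_pair <- function() {
  cached("neo_h2_oracle", {
    sys <- generate_fixture("h2", quantum = 2L)
    nb <- list(n_per_l = 3, l_max = 0, alpha_max = 24, ratio = 3)
    list(oracle = brute_force_neo(sys, "sto-3g", nb),
         neo = run_neo(sys, neo_config(mode = "direct", e_basis = "sto-3g",
                                       n_basis = nb, n_fit = tiny_nf)))
  })
}

# Independent oracle: alternating dense-diagonalisation NEO for one quantum
# proton, no DIIS, no density fitting, fixed-point iteration on exact
# tensors.  Deliberately avoids scf_iterate()/run_neo() internals.
brute_force_neo <- function(system, e_basis, n_basis_spec,
                            max_outer = 400, tol = 1e-12) {
  stopifnot(length(system$quantum) == 1)
  p <- system$quantum
  eb <- make_basis(system, e_basis)
  nb_shells <- build_even_tempered(system$coords[p, ], n_basis_spec$n_per_l,
                                   n_basis_spec$l_max, n_basis_spec$alpha_max,
                                   n_basis_spec$ratio)
  cc_idx <- setdiff(seq_along(system$elements), p)
  pc <- list(q = system$z[cc_idx], pos = system$coords[cc_idx, , drop = FALSE])
  ope <- one_particle(eb, mass = 1, charge = -1, point_charges = pc)
  he <- ope$T + ope$V
  opn <- one_particle(nb_shells, mass = system$qmass[[as.character(p)]],
                      charge = +1, point_charges = pc)
  hn <- opn$T + opn$V
  Me <- four_index(eb, max_pairs = 1e6)
  ne <- n_electrons(system)
  nocc <- ne / 2
  nao_e <- eb$nao
  nao_n <- basis_nfun(nb_shells)
  solve_lowest <- function(F, S, n) {
    # generalized symmetric eigenproblem via Cholesky, own code path
    L <- t(chol(S))
    Ft <- solve(L, t(solve(L, t(F))))
    e <- eigen((Ft + t(Ft)) / 2, symmetric = TRUE)
    ord <- order(e$values)
    list(C = solve(t(L), e$vectors[, ord[seq_len(n)], drop = FALSE]),
         eps = e$values[ord[seq_len(n)]])
  }
  De <- matrix(0, nao_e, nao_e)
  Dn <- matrix(0, nao_n, nao_n)
  E <- Inf
  for (outer in seq_len(max_outer)) {
    # nuclear step with frozen electrons
    Vne <- -coulomb_contract(nb_shells, eb, De)
    cn <- solve_lowest(hn + Vne, opn$S, 1)
    Dn <- tcrossprod(cn$C)
    # electronic step with frozen proton
    Ven <- -coulomb_contract(eb, nb_shells, Dn)
    for (inner in 1:200) {
      jk <- neoscf:::jk_exact(Me, De)
      Fe <- he + Ven + jk$J - 0.5 * jk$K
      ce <- solve_lowest(Fe, ope$S, nocc)
      Den <- 2 * tcrossprod(ce$C)
      if (max(abs(Den - De)) < 1e-11) { De <- Den; break }
      De <- 0.6 * Den + 0.4 * De
    }
    jk <- neoscf:::jk_exact(Me, De)
    E_e <- sum(De * he) + 0.5 * sum(De * (jk$J - 0.5 * jk$K))
    E_n <- sum(Dn * hn)
    E_c <- sum(De * (-coulomb_contract(eb, nb_shells, Dn)))
    E_cl <- if (length(cc_idx) > 1) {
      s <- 0
      for (i in 1:(length(cc_idx) - 1)) for (j in (i + 1):length(cc_idx)) {
        s <- s + pc$q[i] * pc$q[j] /
          sqrt(sum((pc$pos[i, ] - pc$pos[j, ])^2))
      }
      s
    } else 0
    En <- E_e + E_n + E_c + E_cl
    if (abs(En - E) < tol && outer > 3) { E <- En; break }
    E <- En
  }
  E
}
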