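# The NEO driver: stepwise macro-iteration between the nuclear and
# electronic SCF, energy assembly without double counting of the coupling,
# the composite nuclear-quantum-effect correction, and cube export of
# proton densities.

#' Run configuration for NEO calculations
#'
#' @param mode `"df"` (density-fitted, default), `"ldf"` (local exchange
#'   fitting) or `"direct"` (exact four-index reference).
#' @param e_basis electronic basis name/path/template.
#' @param jkfit electronic JK fitting basis name/path/template.
#' @param n_basis nuclear AO basis: a list
#'   `list(n_per_l=, l_max=, alpha_max=, ratio=)` for an even-tempered set
#'   (default 8s8p8d, alpha_max 32, ratio 2) or a Gaussian94 file path with
#'   an `H` entry (e.g. a PB4-F2 file).
#' @param n_fit nuclear fitting basis, same conventions.  The default
#'   (18 per l up to f, alpha_max 64, ratio 1.42) spans the same exponent
#'   window as the classic 10-per-l ratio-2 ladder but at roughly double
#'   radial density; the coupling fit needs that density because its error
#'   is the product of the proton-density residual with the large residual
#'   of the electronic density in proton-site functions.
#' @param profile `"tight"` (1e-8 au micro / 1e-7 macro, the water-cluster
#'   settings) or `"loose"` (1e-7 / 1e-6, for larger systems).
#' @param guess electronic guess source (see [electronic_guess()]).
#' @param nuclear_mode `"distinguishable"` (default: one Fock per proton) or
#'   `"combined"` (single Fock over the union basis).
#' @param nuclear_guess `"block"` (per-centre block diagonalisation,
#'   default) or `"full"` (full core-Hamiltonian diagonalisation; only
#'   meaningful in combined mode).
#' @param charge_threshold,fit_extension,domain_radius local-fitting domain
#'   controls (see [build_domains()]).
#' @param max_scf,max_macro iteration caps.
#' @param screen integral-direct prescreening threshold.
#' @param eri_cap four-index pair-product cap for direct mode.
#' @param level_shift electronic level shift in Hartree (0 = off).
#' @param keep_integrals retain the integral bundle in the result (tests).
#' @param seed recorded in the config for reproducibility of perturbed
#'   fixtures; the SCF itself is deterministic.
#' @export
neo_config <- function(mode = c("df", "ldf", "direct"),
                       e_basis = "tz-synth", jkfit = "tz-synth-jkfit",
                       n_basis = list(n_per_l = 8, l_max = 2, alpha_max = 32,
                                      ratio = 2),
                       n_fit = list(n_per_l = 18, l_max = 3, alpha_max = 64,
                                    ratio = 1.42),
                       profile = c("tight", "loose"),
                       guess = "atomic_density",
                       nuclear_mode = c("distinguishable", "combined"),
                       nuclear_guess = c("block", "full"),
                       charge_threshold = 0.05, fit_extension = 1,
                       domain_radius = 8,
                       max_scf = 60, max_macro = 50,
                       screen = 1e-10, eri_cap = 40000,
                       level_shift = 0, keep_integrals = FALSE, seed = 0L) {
  mode <- match.arg(mode)
  profile <- match.arg(profile)
  th <- if (profile == "tight") {
    list(scf = c(e = 1e-8, d = 1e-8, g = 1e-8), macro = 1e-7)
  } else {
    list(scf = c(e = 1e-7, d = 1e-7, g = 1e-7), macro = 1e-6)
  }
  structure(list(
    mode = mode, e_basis = e_basis, jkfit = jkfit, n_basis = n_basis,
    n_fit = n_fit, profile = profile, scf_thresh = th$scf,
    macro_thresh = th$macro, guess = guess,
    nuclear_mode = match.arg(nuclear_mode),
    nuclear_guess = match.arg(nuclear_guess),
    charge_threshold = charge_threshold, fit_extension = fit_extension,
    domain_radius = domain_radius,
    max_scf = max_scf, max_macro = max_macro, screen = screen,
    eri_cap = eri_cap, level_shift = level_shift,
    keep_integrals = keep_integrals, seed = as.integer(seed)
  ), class = "neo_config")
}

#' @export
print.neo_config <- function(x, ...) {
  cat(sprintf("<neo_config: mode=%s, profile=%s, nuclear=%s/%s guess>\n",
              x$mode, x$profile, x$nuclear_mode, x$nuclear_guess))
  invisible(x)
}

# ---------------------------------------------------------- basis assignment

.nuclear_shells <- function(spec, center) {
  if (is.character(spec)) {
    tmpl <- get_basis_template(spec)
    if (is.null(tmpl$H)) stop("nuclear basis file lacks an H entry")
    lapply(tmpl$H, function(t) shell_block(t$l, center, t$exps, t$coefs))
  } else {
    build_even_tempered(center, spec$n_per_l, spec$l_max, spec$alpha_max,
                        spec$ratio)
  }
}

.as_nbasis <- function(shells, atom_idx) {
  structure(list(shells = shells, atom = rep(atom_idx, length(shells)),
                 ao_atom = rep(atom_idx, basis_nfun(shells)),
                 nao = basis_nfun(shells)), class = "ao_basis")
}

#' Assign all four basis classes to a system
#'
#' Electronic AO and JK-fitting bases on every atom; per-quantum-nucleus AO
#' and fitting bases centred at the classical positions.
#'
#' @param system a `neo_system`.
#' @param config a `neo_config`.
#' @return a `basis_assignment` list: `e`, `e_fit`, `n_ao` (per quantum
#'   index), `n_fit` (per quantum index), `n_fit_union`.
#' @export
basis_assignment <- function(system, config = neo_config()) {
  ba <- list(
    e = make_basis(system, config$e_basis),
    e_fit = if (config$mode %in% c("df", "ldf"))
      make_basis(system, config$jkfit) else NULL,
    n_ao = list(), n_fit = list()
  )
  # In a multicomponent run the electronic JK fitting basis must also expand
  # the quantum-proton densities (the electronic-side coupling fit).  Proton
  # AO products are far tighter than electronic ones, so the fitting ladders
  # on quantum sites are extended up to twice the largest nuclear exponent.
  if (!is.null(ba$e_fit) && length(system$quantum) > 0 &&
      isTRUE(config$augment_jkfit %||% TRUE)) {
    amax_n <- if (is.character(config$n_basis)) {
      max(unlist(lapply(get_basis_template(config$n_basis)$H,
                        function(t) t$exps)))
    } else config$n_basis$alpha_max
    extra <- list(); exatom <- integer(0)
    for (p in system$quantum) {
      ctr <- system$coords[p, ]
      have <- ba$e_fit$shells[ba$e_fit$atom == p]
      for (L in 0:3) {
        tops <- vapply(have, function(s) if (s$l == L) max(s$exps) else 0,
                       numeric(1))
        lo <- if (any(tops > 0)) max(tops) * 2.0 else 1.0
        hi <- 2 * amax_n / c(1, 1.5, 2, 3)[L + 1]
        a <- hi
        while (a > lo) {
          extra[[length(extra) + 1L]] <- shell_block(L, ctr, a, 1)
          exatom <- c(exatom, p)
          a <- a / 2.0
        }
      }
    }
    if (length(extra) > 0) {
      sh <- c(ba$e_fit$shells, extra)
      at <- c(ba$e_fit$atom, exatom)
      ba$e_fit <- structure(
        list(shells = sh, atom = at,
             ao_atom = rep(at, vapply(sh, shell_nfun, integer(1))),
             nao = basis_nfun(sh)), class = "ao_basis")
    }
  }
  for (p in system$quantum) {
    key <- as.character(p)
    ctr <- system$coords[p, ]
    ba$n_ao[[key]] <- .as_nbasis(.nuclear_shells(config$n_basis, ctr), p)
    ba$n_fit[[key]] <- .as_nbasis(.nuclear_shells(config$n_fit, ctr), p)
  }
  if (length(system$quantum) > 0) {
    ush <- unlist(lapply(ba$n_fit, function(b) b$shells), recursive = FALSE)
    uat <- unlist(lapply(ba$n_fit, function(b) b$atom))
    ba$n_fit_union <- structure(
      list(shells = ush, atom = uat,
           ao_atom = rep(uat, vapply(ush, shell_nfun, integer(1))),
           nao = basis_nfun(ush)), class = "ao_basis")
  }
  class(ba) <- "basis_assignment"
  ba
}

# --------------------------------------------------------- integral assembly

build_neo_integrals <- function(system, ba, config) {
  cc <- classical_charges(system)
  pc <- list(q = cc$q, pos = cc$pos)
  ints <- list(E_cl = classical_repulsion(system), nq = length(system$quantum))
  ope <- one_particle(ba$e, mass = 1, charge = -1, point_charges = pc)
  ints$e <- list(S = ope$S, h = ope$T + ope$V, nao = ba$e$nao)
  if (config$mode == "direct") {
    # stored stripped of attributes: attribute changes on a 100s-of-MB
    # matrix would force R to duplicate it at every Fock build
    ints$e$M <- unclass(four_index(ba$e, max_pairs = config$eri_cap))
  } else {
    ints$e$B3 <- three_index(ba$e, ba$e_fit)
    ints$e$J2 <- coulomb_metric(ba$e_fit)
    ints$e$fac <- df_metric_factor(ints$e$J2)
  }
  if (ints$nq > 0) {
    ints$n <- list()
    for (key in names(ba$n_ao)) {
      p <- as.integer(key)
      m <- system$qmass[[key]]
      opn <- one_particle(ba$n_ao[[key]], mass = m, charge = +1,
                          point_charges = pc)
      ints$n[[key]] <- list(S = opn$S, h = opn$T + opn$V,
                            T = opn$T, mass = m, nao = ba$n_ao[[key]]$nao)
    }
    if (config$mode == "direct") {
      # cache cross four-index tensors when they fit in memory: each is
      # reused several times per macro-iteration in the couplings and the
      # energy assembly
      npe <- ints$e$nao * (ints$e$nao + 1) / 2
      npn <- vapply(ints$n, function(x) x$nao * (x$nao + 1) / 2, numeric(1))
      bytes <- 8 * (npe * sum(npn) + sum(outer(npn, npn)[upper.tri(diag(length(npn)))]))
      if (bytes / 2^20 <= 2600) {
        keys <- names(ba$n_ao)
        ints$xen <- list()
        for (key in keys) {
          ints$xen[[key]] <- cpp_eri_cross_packed(
            .shell_list(ba$e), .shell_list(ba$n_ao[[key]]))
        }
        ints$xnn <- list()
        if (length(keys) > 1) {
          for (i in 1:(length(keys) - 1)) for (j in (i + 1):length(keys)) {
            ints$xnn[[paste(keys[i], keys[j])]] <- cpp_eri_cross_packed(
              .shell_list(ba$n_ao[[keys[i]]]), .shell_list(ba$n_ao[[keys[j]]]))
          }
        }
      }
    }
    if (config$mode != "direct") {
      ints$J2n <- coulomb_metric(ba$n_fit_union)
      ints$facn <- df_metric_factor(ints$J2n)
      ints$X3_en <- three_index(ba$e, ba$n_fit_union) # e pairs x nuclear fit
      for (key in names(ba$n_ao)) {
        ints$n[[key]]$B3 <- three_index(ba$n_ao[[key]], ba$n_fit_union)
        ints$n[[key]]$X3e <- three_index(ba$n_ao[[key]], ba$e_fit)
      }
    }
  }
  ints
}

# ------------------------------------------------------------- coupling terms

# nuclear-side coupling potentials (electron density frozen); sign -1
nuclear_coupling <- function(D_e, ba, ints, config) {
  out <- list()
  if (config$mode == "direct") {
    for (key in names(ba$n_ao)) {
      out[[key]] <- if (!is.null(ints$xen[[key]])) {
        -cross_J_ket(ints$xen[[key]], D_e, ints$n[[key]]$nao)
      } else {
        -coulomb_contract(ba$n_ao[[key]], ba$e, D_e, thresh = config$screen)
      }
    }
  } else {
    g <- crossprod(ints$X3_en, as.numeric(D_e))
    d <- ints$facn$solve(g)
    for (key in names(ba$n_ao)) {
      n <- ints$n[[key]]$nao
      V <- matrix(ints$n[[key]]$B3 %*% d, n, n)
      out[[key]] <- -(V + t(V)) / 2
    }
  }
  out
}

# electronic-side coupling potential (nuclear densities frozen); sign -1
electronic_coupling <- function(Dn_list, ba, ints, config) {
  nao <- ints$e$nao
  if (length(Dn_list) == 0) return(matrix(0, nao, nao))
  if (config$mode == "direct") {
    V <- matrix(0, nao, nao)
    for (key in names(Dn_list)) {
      V <- V - (if (!is.null(ints$xen[[key]])) {
        cross_J_bra(ints$xen[[key]], Dn_list[[key]], nao)
      } else {
        coulomb_contract(ba$e, ba$n_ao[[key]], Dn_list[[key]],
                         thresh = config$screen)
      })
    }
    V
  } else {
    g <- 0
    for (key in names(Dn_list)) {
      g <- g + crossprod(ints$n[[key]]$X3e, as.numeric(Dn_list[[key]]))
    }
    d <- ints$e$fac$solve(g)
    V <- matrix(ints$e$B3 %*% d, nao, nao)
    -(V + t(V)) / 2
  }
}

# frozen inter-proton Coulomb potentials for each proton
proton_proton_potentials <- function(Dn_list, ba, ints, config) {
  keys <- names(ba$n_ao)
  out <- list()
  if (config$mode == "direct") {
    for (key in keys) {
      n <- ints$n[[key]]$nao
      V <- matrix(0, n, n)
      for (other in setdiff(keys, key)) {
        if (is.null(Dn_list[[other]])) next
        V <- V + pp_potential(key, other, Dn_list[[other]], ba, ints, config)
      }
      out[[key]] <- V
    }
  } else {
    dsum <- list()
    for (key in keys) {
      dsum[[key]] <- if (is.null(Dn_list[[key]])) NULL else
        ints$facn$solve(crossprod(ints$n[[key]]$B3, as.numeric(Dn_list[[key]])))
    }
    for (key in keys) {
      n <- ints$n[[key]]$nao
      dtot <- 0
      for (other in setdiff(keys, key)) {
        if (!is.null(dsum[[other]])) dtot <- dtot + dsum[[other]]
      }
      if (identical(dtot, 0)) { out[[key]] <- matrix(0, n, n); next }
      V <- matrix(ints$n[[key]]$B3 %*% dtot, n, n)
      out[[key]] <- (V + t(V)) / 2
    }
  }
  out
}

# exact Coulomb potential of proton `other`'s density in proton `key`'s AO
# basis, through the cached cross tensor when available
pp_potential <- function(key, other, D_other, ba, ints, config) {
  n <- ints$n[[key]]$nao
  nm1 <- paste(key, other)
  nm2 <- paste(other, key)
  if (!is.null(ints$xnn[[nm1]])) {
    cross_J_bra(ints$xnn[[nm1]], D_other, n)
  } else if (!is.null(ints$xnn[[nm2]])) {
    cross_J_ket(ints$xnn[[nm2]], D_other, n)
  } else {
    coulomb_contract(ba$n_ao[[key]], ba$n_ao[[other]], D_other,
                     thresh = config$screen)
  }
}

# ---------------------------------------------------------------- subsystems

# electronic Fock two-particle part G(D) for the configured mode
make_electronic_G <- function(ints, ba, system, config, state_env) {
  nocc <- n_electrons(system) / 2
  if (config$mode == "direct") {
    function(D, orbs) {
      J <- cpp_j_packed(ints$e$M, D)
      K <- cpp_k_occ_packed(ints$e$M, orbs$C, orbs$n)
      J - 0.5 * K
    }
  } else if (config$mode == "df") {
    function(D, orbs) {
      J <- build_J_df(D, ints$e$B3, ints$e$fac)
      K <- build_K_df(orbs$C, ints$e$B3, ints$e$fac, occ_num = orbs$n)
      J - 0.5 * K
    }
  } else { # ldf
    mc <- state_env$metric_cache
    function(D, orbs) {
      J <- build_J_df(D, ints$e$B3, ints$e$fac)
      idempotent <- length(orbs$n) == nocc && all(abs(orbs$n - 2) < 1e-6)
      K <- if (idempotent) {
        loc <- localize_ibo(orbs$C, ints$e$S, ba$e, system)
        loc <- build_domains(loc, ba$e, ba$e_fit, system,
                             charge_threshold = config$charge_threshold,
                             fit_extension = config$fit_extension,
                             domain_radius = config$domain_radius)
        state_env$last_loc <- loc
        build_K_ldf(loc, ints$e$B3, ints$e$J2, metric_cache = mc)
      } else {
        build_K_df(orbs$C, ints$e$B3, ints$e$fac, occ_num = orbs$n)
      }
      J - 0.5 * K
    }
  }
}

run_electronic_scf <- function(D_e, Ven, ints, ba, system, config, state_env) {
  nocc <- n_electrons(system) / 2
  if (nocc != round(nocc)) stop("odd electron count: closed-shell RHF only")
  G <- make_electronic_G(ints, ba, system, config, state_env)
  h_eff <- ints$e$h + Ven
  scf_iterate(
    h_eff, ints$e$S,
    fock_builder = function(D, orbs) h_eff + G(D, orbs),
    energy_fn = function(D, F, h) 0.5 * sum(D * (h + F)),
    D0 = D_e, nocc = nocc, occ = 2, thresholds = config$scf_thresh,
    max_iter = config$max_scf, level_shift = config$level_shift)
}

#' Nuclear SCF micro-iterations
#'
#' Distinguishable mode (default): each quantum proton gets its own Fock
#' matrix over its own centre's basis, containing the mass-scaled kinetic
#' term, the classical-nucleus repulsion, the Coulomb potential of the other
#' protons' frozen densities and the frozen electronic coupling; no
#' nuclear-nuclear exchange.  Other protons' densities are frozen within a
#' micro-cycle and refreshed each macro-cycle.  Combined mode builds one
#' Fock over the union basis and occupies one orbital per proton.
#'
#' @param system,ba,ints,config internal bundles (see [run_neo()]).
#' @param D_e frozen electronic density.
#' @param prev per-proton previous densities (list, may be NULL entries).
#' @return list of `subsystem_state` per proton (distinguishable) or a list
#'   with the shared `state` and per-proton densities (combined).
#' @export
nuclear_scf <- function(system, ba, ints, config, D_e, prev = list()) {
  Vne <- nuclear_coupling(D_e, ba, ints, config)
  if (config$nuclear_mode == "distinguishable") {
    Vpp <- proton_proton_potentials(prev, ba, ints, config)
    out <- list()
    for (key in names(ba$n_ao)) {
      ni <- ints$n[[key]]
      Fstat <- ni$h + Vne[[key]] + Vpp[[key]]
      D0 <- if (!is.null(prev[[key]])) prev[[key]] else
        matrix(0, ni$nao, ni$nao)
      out[[key]] <- scf_iterate(
        Fstat, ni$S,
        fock_builder = function(D, orbs) Fstat,
        energy_fn = function(D, F, h) sum(D * F),
        D0 = D0, nocc = 1, occ = 1, thresholds = config$scf_thresh,
        max_iter = config$max_scf)
    }
    out
  } else {
    combined_nuclear_scf(system, ba, ints, config, D_e, prev)
  }
}

# union-basis ("combined") nuclear SCF; exercised by the starting-guess
# comparison.  The Fock holds the mean field of the total nuclear density.
combined_nuclear_scf <- function(system, ba, ints, config, D_e, prev = list()) {
  keys <- names(ba$n_ao)
  masses <- vapply(keys, function(k) ints$n[[k]]$mass, numeric(1))
  if (length(unique(masses)) > 1) {
    stop("combined nuclear mode requires equal quantum-nucleus masses")
  }
  ush <- unlist(lapply(ba$n_ao, function(b) b$shells), recursive = FALSE)
  union_b <- .as_nbasis(ush, 0L)
  sizes <- vapply(keys, function(k) ints$n[[k]]$nao, integer(1))
  off <- cumsum(c(0L, sizes[-length(sizes)]))
  blocks <- lapply(seq_along(keys), function(i) off[i] + seq_len(sizes[i]))
  cc <- classical_charges(system)
  opu <- one_particle(union_b, mass = masses[1], charge = +1,
                      point_charges = list(q = cc$q, pos = cc$pos))
  h_u <- opu$T + opu$V
  Vne_u <- -coulomb_contract(union_b, ba$e, D_e, thresh = config$screen)
  h_eff <- h_u + Vne_u
  nq <- length(keys)
  # Single-Fock treatment of all protons: one high-spin determinant, so
  # F = h + J(D) - K(D) with unit occupations.  The exchange term cancels
  # each proton's Coulomb self-interaction exactly (without it the compact
  # proton densities feel a ~2 Hartree spurious self-repulsion and the SCF
  # is qualitatively wrong); the genuine inter-proton exchange it adds is
  # negligible at these overlaps.
  nu <- sum(sizes)
  if (nu * (nu + 1) / 2 > config$eri_cap) {
    stop("combined nuclear mode needs the union four-index tensor; ",
         "reduce the nuclear basis or raise eri_cap")
  }
  M_u <- unclass(four_index(ush, max_pairs = config$eri_cap))
  D0 <- if (length(prev) == nq && !any(vapply(prev, is.null, logical(1)))) {
    Dm <- matrix(0, sum(sizes), sum(sizes))
    for (i in seq_along(keys)) Dm[blocks[[i]], blocks[[i]]] <- prev[[keys[i]]]
    Dm
  } else if (config$nuclear_guess == "block") {
    block_diag_guess(h_eff, opu$S, blocks)
  } else {
    full_diag_guess(h_eff, opu$S, nq)
  }
  st <- scf_iterate(
    h_eff, opu$S,
    fock_builder = function(D, orbs) {
      h_eff + cpp_j_packed(M_u, D) -
        cpp_k_occ_packed(M_u, orbs$C, orbs$n)
    },
    energy_fn = function(D, F, h) sum(D * h) + 0.5 * sum(D * (F - h)),
    D0 = D0, nocc = nq, occ = 1, thresholds = config$scf_thresh,
    # the single-Fock map is close to marginally stable for compact
    # unit-charge densities (occ->virt response gain approaches 1), so the
    # union-basis SCF may legitimately need hundreds of iterations
    max_iter = max(config$max_scf, 400), level_shift = config$level_shift)
  # per-proton densities from the diagonal blocks (for coupling/assembly)
  dens <- list()
  for (i in seq_along(keys)) {
    dens[[keys[i]]] <- st$D[blocks[[i]], blocks[[i]]]
    tr <- sum(dens[[keys[i]]] * ints$n[[keys[i]]]$S)
    if (tr > 1e-8) dens[[keys[i]]] <- dens[[keys[i]]] / tr
  }
  list(state = st, densities = dens, blocks = blocks, union = union_b,
       h_eff = h_eff, S = opu$S)
}

# ------------------------------------------------------------ energy assembly

#' Assemble the total NEO energy from converged subsystem densities
#'
#' `E = E_elec[D_e] + sum_n E_nuc[D_n] + E_pp + E_coupling + E_classical`,
#' with subsystem internal energies excluding coupling and the
#' electron-proton Coulomb coupling counted exactly once.  The coupling is
#' recomputed from the final densities through one designated fitting basis
#' (or exactly in direct mode), so the value is identical whichever
#' subsystem's bookkeeping is used.
#'
#' @param D_e electronic density.
#' @param Dn_list per-proton densities.
#' @param ints,ba,config internal bundles.
#' @param G_e two-particle electronic matrix `J - K/2` evaluated at `D_e`
#'   (passed in to avoid a rebuild).
#' @param coupling_scale test hook: scales the coupling term (default 1).
#' @param Ven optional precomputed electronic-side coupling potential for
#'   the current nuclear densities (recomputed when absent).
#' @return list of components and `E_total`.
#' @export
assemble_energy <- function(D_e, Dn_list, ints, ba, config, G_e,
                            coupling_scale = 1, Ven = NULL) {
  E_e_int <- sum(D_e * ints$e$h) + 0.5 * sum(D_e * G_e)
  E_n_int <- vapply(names(Dn_list), function(key)
    sum(Dn_list[[key]] * ints$n[[key]]$h), numeric(1))
  # electron-proton coupling, one designated route
  E_coup <- 0
  if (length(Dn_list) > 0) {
    if (is.null(Ven)) Ven <- electronic_coupling(Dn_list, ba, ints, config)
    E_coup <- sum(D_e * Ven)
  }
  # proton-proton Coulomb counted once per pair
  E_pp <- 0
  keys <- names(Dn_list)
  if (length(keys) > 1) {
    if (config$mode == "direct") {
      for (i in 1:(length(keys) - 1)) for (j in (i + 1):length(keys)) {
        Vij <- pp_potential(keys[i], keys[j], Dn_list[[keys[j]]], ba, ints,
                            config)
        E_pp <- E_pp + sum(Dn_list[[keys[i]]] * Vij)
      }
    } else {
      gs <- lapply(keys, function(k)
        crossprod(ints$n[[k]]$B3, as.numeric(Dn_list[[k]])))
      for (i in 1:(length(keys) - 1)) for (j in (i + 1):length(keys)) {
        E_pp <- E_pp + fitted_pair_energy(gs[[i]], gs[[j]], ints$facn)
      }
    }
  }
  comps <- list(electronic = E_e_int, nuclear = E_n_int,
                nuclear_pair = E_pp, coupling = E_coup,
                classical = ints$E_cl)
  list(components = comps,
       E_total = E_e_int + sum(E_n_int) + E_pp +
         coupling_scale * E_coup + ints$E_cl)
}

# ---------------------------------------------------------------- the driver

#' Run a (L)DF-NEO-RHF or integral-direct NEO-RHF calculation
#'
#' Macro loop: nuclear SCF with the electronic density frozen, then
#' electronic SCF with the nuclear densities frozen, repeated until the
#' total energy changes by less than the macro threshold (default 1e-7
#' Hartree).  With zero quantum nuclei this reduces to a conventional
#' (L)DF-RHF / RHF calculation on the same code path.
#'
#' @param system a `neo_system`.
#' @param config a `neo_config`.
#' @param ba optional pre-built [basis_assignment()].
#' @param D_e0 optional electronic starting density (overrides the guess).
#' @param Dn0 optional per-proton starting densities (named list), e.g. the
#'   converged densities of a cheaper run used to warm-start a reference.
#' @return a `neo_result`.
#' @export
run_neo <- function(system, config = neo_config(), ba = NULL, D_e0 = NULL,
                    Dn0 = NULL) {
  t0 <- proc.time()[["elapsed"]]
  if (is.null(ba)) ba <- basis_assignment(system, config)
  ints <- build_neo_integrals(system, ba, config)
  state_env <- new.env(parent = emptyenv())
  state_env$metric_cache <- new.env(parent = emptyenv())
  D_e <- if (!is.null(D_e0)) D_e0 else
    electronic_guess(system, ba$e, mode = config$guess)
  nq <- ints$nq
  Dn <- if (!is.null(Dn0)) Dn0 else list()
  nuclear_states <- NULL
  combined <- NULL
  E_prev <- NA_real_
  macro_trace <- data.frame()
  converged <- FALSE
  est <- NULL
  for (macro in seq_len(config$max_macro)) {
    if (nq > 0) {
      ns <- nuclear_scf(system, ba, ints, config, D_e, prev = Dn)
      if (config$nuclear_mode == "distinguishable") {
        nuclear_states <- ns
        Dn <- lapply(ns, function(s) s$D)
      } else {
        combined <- ns
        nuclear_states <- list(combined = ns$state)
        Dn <- ns$densities
      }
    }
    Ven <- electronic_coupling(Dn, ba, ints, config)
    if (n_electrons(system) > 0) {
      est <- run_electronic_scf(D_e, Ven, ints, ba, system, config, state_env)
      D_e <- est$D
    } else { # bare quantum nuclei in a classical point-charge field
      est <- structure(list(D = D_e, F = ints$e$h + Ven, energy = 0,
                            iterations = 0L, converged = TRUE,
                            trace = data.frame()),
                       class = "subsystem_state")
    }
    G_e <- est$F - ints$e$h - Ven # two-particle part at the converged D_e
    asm <- assemble_energy(D_e, Dn, ints, ba, config, G_e, Ven = Ven)
    dE <- asm$E_total - E_prev
    macro_trace <- rbind(macro_trace, data.frame(
      macro = macro, E_total = asm$E_total, dE = dE,
      e_iters = est$iterations,
      n_iters = if (nq > 0) sum(vapply(nuclear_states, function(s)
        s$iterations, numeric(1))) else 0))
    if (nq == 0) { converged <- TRUE; E_prev <- asm$E_total; break }
    if (!is.na(dE) && abs(dE) <= config$macro_thresh) {
      converged <- TRUE; E_prev <- asm$E_total; break
    }
    E_prev <- asm$E_total
    if (nrow(macro_trace) >= 6) {
      s <- sign(macro_trace$dE[(nrow(macro_trace) - 4):nrow(macro_trace)])
      if (all(s[-1] * s[-length(s)] < 0)) {
        warning("macro-iteration energy oscillates; consider tighter ",
                "micro-iteration thresholds")
      }
    }
  }
  if (!converged) {
    err <- simpleError(sprintf(
      "NEO macro-iterations did not converge in %d cycles (last dE = %.3e)",
      config$max_macro, macro_trace$dE[nrow(macro_trace)]))
    err$trace <- macro_trace
    stop(err)
  }
  res <- structure(list(
    E_total = asm$E_total, components = asm$components,
    macro_trace = macro_trace, converged = converged,
    electronic = est, nuclear = nuclear_states, Dn = Dn,
    combined = combined,
    system = system, config = config,
    basis_hash = basis_hashes(ba),
    nao = list(e = ints$e$nao,
               n = if (nq > 0) vapply(ints$n, function(x) x$nao, integer(1))
                   else integer(0)),
    seconds = proc.time()[["elapsed"]] - t0
  ), class = "neo_result")
  if (config$keep_integrals) { res$ints <- ints; res$ba <- ba }
  res
}

#' @export
print.neo_result <- function(x, ...) {
  cat(sprintf("NEO-RHF result (%s mode)\n", x$config$mode))
  cat(sprintf("  E_total      = %18.12f Eh\n", x$E_total))
  cat(sprintf("  electronic   = %18.12f\n", x$components$electronic))
  if (length(x$components$nuclear) > 0) {
    cat(sprintf("  nuclear      = %18.12f (sum over %d protons)\n",
                sum(x$components$nuclear), length(x$components$nuclear)))
    cat(sprintf("  proton-proton= %18.12f\n", x$components$nuclear_pair))
    cat(sprintf("  coupling     = %18.12f\n", x$components$coupling))
  }
  cat(sprintf("  classical    = %18.12f\n", x$components$classical))
  cat(sprintf("  macro cycles = %d, converged = %s, %.1f s\n",
              nrow(x$macro_trace), x$converged, x$seconds))
  invisible(x)
}

#' Integral-direct NEO-RHF reference
#'
#' Identical driver logic with exact four-index Coulomb/exchange and exact
#' cross-subsystem Coulomb coupling; the oracle for DF/LDF error
#' measurements.
#'
#' @inheritParams run_neo
#' @export
run_reference_direct <- function(system, config = neo_config(), ba = NULL) {
  config$mode <- "direct"
  run_neo(system, config, ba = ba)
}

#' Compare nuclear starting guesses in combined mode
#'
#' Runs the first macro-cycle nuclear SCF over the union basis twice with
#' identical DIIS settings and thresholds: once seeded from a full
#' diagonalisation of the effective nuclear core Hamiltonian and once from
#' the per-centre block diagonalisation, and reports the iteration counts.
#' Without inter-proton repulsion in the core Hamiltonian the full
#' diagonalisation piles several protons onto one centre, which the SCF then
#' has to undo.
#'
#' @param system a `neo_system` with > 1 quantum nuclei of equal mass.
#' @param config a `neo_config`; `nuclear_mode` is forced to `"combined"`.
#' @return list with `iterations_full`, `iterations_block`, `ratio` and a
#'   flag `full_converged` (the full-diagonalisation start may hit the
#'   iteration cap).
#' @export
block_guess_experiment <- function(system, config = neo_config()) {
  config$nuclear_mode <- "combined"
  ba <- basis_assignment(system, config)
  # the experiment needs only the union one-particle pieces and the
  # electronic guess density, not the fitted nuclear tensors
  cc <- classical_charges(system)
  pc <- list(q = cc$q, pos = cc$pos)
  ints <- list(nq = length(system$quantum), n = list())
  for (key in names(ba$n_ao)) {
    m <- system$qmass[[key]]
    opn <- one_particle(ba$n_ao[[key]], mass = m, charge = +1,
                        point_charges = pc)
    ints$n[[key]] <- list(S = opn$S, mass = m, nao = ba$n_ao[[key]]$nao)
  }
  D_e <- electronic_guess(system, ba$e, mode = config$guess)
  run_guess <- function(gu) {
    cfg <- config
    cfg$nuclear_guess <- gu
    tryCatch(
      list(it = combined_nuclear_scf(system, ba, ints, cfg, D_e)$state$iterations,
           conv = TRUE),
      error = function(e) {
        if (is.null(e$trace)) stop(e)
        list(it = nrow(e$trace), conv = FALSE)
      })
  }
  full <- run_guess("full")
  block <- run_guess("block")
  list(iterations_full = full$it, iterations_block = block$it,
       ratio = full$it / block$it,
       full_converged = full$conv, block_converged = block$conv)
}

# -------------------------------------------------------------- NQE correction

#' Composite nuclear-quantum-effect correction
#'
#' Corrects a higher-level electronic energy `E_X` by the difference between
#' a multicomponent and a conventional Hartree-Fock calculation:
#' `E = E_X + (E_NEOHF - E_HF)`.
#'
#' @param E_X electronic single-point energy (Hartree).
#' @param E_NEOHF multicomponent NEO-HF total energy (Hartree).
#' @param E_HF conventional HF energy on the same geometry/basis (Hartree).
#' @export
nqe_correction <- function(E_X, E_NEOHF, E_HF) {
  if (any(abs(E_NEOHF - E_HF) > 1)) {
    warning("|E_NEOHF - E_HF| exceeds 1 Hartree; inputs may be mismatched")
  }
  E_X + (E_NEOHF - E_HF)
}

#' Nuclear-quantum-effect energy of a system
#'
#' Runs the NEO calculation and the conventional calculation (zero quantum
#' nuclei) with identical settings, so fitting errors cancel in the
#' difference `delta = E_NEOHF - E_HF`.
#'
#' @param system a `neo_system` with at least one quantum nucleus.
#' @param config a `neo_config`.
#' @return list with `E_neo`, `E_hf`, `delta` (Hartree) and both results.
#' @export
nqe_delta <- function(system, config = neo_config()) {
  if (length(system$quantum) == 0) stop("system has no quantum nuclei")
  res_neo <- run_neo(system, config)
  sys_cl <- system
  sys_cl$quantum <- integer(0)
  sys_cl$classical <- seq_along(system$elements)
  sys_cl$qmass <- numeric(0)
  res_hf <- run_neo(sys_cl, config)
  list(E_neo = res_neo$E_total, E_hf = res_hf$E_total,
       delta = res_neo$E_total - res_hf$E_total,
       neo = res_neo, hf = res_hf)
}

# ----------------------------------------------------------------- densities

#' Evaluate a proton density on a regular grid
#'
#' @param result a `neo_result` from a run with quantum nuclei.
#' @param proton quantum atom index (as in the system).
#' @param spacing grid spacing in bohr (default 0.05).
#' @param margin box half-width around the proton site in bohr (default 2).
#' @return a `density_grid`: origin, axes, counts, values (bohr^-3).
#' @export
proton_density_grid <- function(result, proton, spacing = 0.05, margin = 2) {
  key <- as.character(proton)
  if (is.null(result$Dn[[key]])) stop("no quantum nucleus with index ", proton)
  sys <- result$system
  cfg <- result$config
  nb <- .as_nbasis(.nuclear_shells(cfg$n_basis, sys$coords[proton, ]), proton)
  ctr <- sys$coords[proton, ]
  ax <- lapply(1:3, function(d) seq(ctr[d] - margin, ctr[d] + margin,
                                    by = spacing))
  counts <- vapply(ax, length, integer(1))
  pts <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  V <- eval_basis(nb, pts)
  rho <- rowSums((V %*% result$Dn[[key]]) * V)
  rho[rho < 0] <- 0
  structure(list(origin = vapply(ax, min, numeric(1)), spacing = spacing,
                 counts = counts, values = rho,
                 integral = sum(rho) * spacing^3,
                 center = ctr,
                 second_moment = sum(rho * rowSums(sweep(pts, 2, ctr)^2)) *
                   spacing^3),
            class = "density_grid")
}

#' Export a proton density as a Gaussian cube file
#'
#' One file per proton; quantum nuclei are listed as ordinary atoms in the
#' header and the scalar field is the proton's normalised density in
#' bohr^-3 (numerical integral within [0.99, 1.01] for a converged state).
#'
#' @param result a `neo_result`.
#' @param proton quantum atom index.
#' @param path output file path.
#' @param spacing,margin grid controls (see [proton_density_grid()]).
#' @export
export_cube <- function(result, proton, path, spacing = 0.05, margin = 2) {
  g <- proton_density_grid(result, proton, spacing, margin)
  sys <- result$system
  nat <- length(sys$elements)
  con <- tryCatch(suppressWarnings(file(path, "w")), error = function(e)
    stop("cannot open cube output path: ", path))
  on.exit(close(con))
  writeLines(c("neoscf proton density",
               sprintf("proton index %d; integral %.6f", proton, g$integral)),
             con)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f", nat,
                     g$origin[1], g$origin[2], g$origin[3]), con)
  for (d in 1:3) {
    ax <- c(0, 0, 0); ax[d] <- g$spacing
    writeLines(sprintf("%5d %11.6f %11.6f %11.6f", g$counts[d],
                       ax[1], ax[2], ax[3]), con)
  }
  for (ia in seq_len(nat)) {
    writeLines(sprintf("%5d %11.6f %11.6f %11.6f %11.6f",
                       sys$z[ia], as.numeric(sys$z[ia]),
                       sys$coords[ia, 1], sys$coords[ia, 2],
                       sys$coords[ia, 3]), con)
  }
  # values with x slowest, z fastest
  arr <- array(g$values, dim = g$counts)
  for (ix in seq_len(g$counts[1])) for (iy in seq_len(g$counts[2])) {
    vals <- arr[ix, iy, ]
    for (k in seq(1, length(vals), by = 6)) {
      writeLines(paste(sprintf("%13.5E", vals[k:min(k + 5, length(vals))]),
                       collapse = " "), con)
    }
  }
  invisible(path)
}

# stable content hash of the basis assignment (logged for reproducibility)
basis_hashes <- function(ba) {
  hash1 <- function(b) {
    if (is.null(b)) return(NA_character_)
    v <- unlist(lapply(b$shells, function(s) c(s$l, s$center, s$exps, s$coefs)))
    h <- sum((abs(v) * 1e6) %% 97777) %% 2147483647
    sprintf("%08x", as.integer(h))
  }
  list(e = hash1(ba$e), e_fit = hash1(ba$e_fit),
       n = lapply(ba$n_ao, hash1), n_fit = lapply(ba$n_fit, hash1))
}
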