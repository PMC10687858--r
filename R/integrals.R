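# R-level interface to the McMurchie-Davidson engine: one-particle matrices
# for arbitrary particle mass and charge, the 2-index Coulomb metric, 3-index
# tensors (including cross-subsystem ones), the exact four-index tensor used
# by the integral-direct reference, and direct screened Coulomb contractions.

.shell_list <- function(basis) {
  shells <- if (inherits(basis, "ao_basis")) basis$shells else basis
  lapply(shells, function(s) list(l = s$l, pure = s$pure, center = s$center,
                                  exps = s$exps, coefs = s$coefs))
}

#' One-particle matrices S, T, V for an arbitrary particle class
#'
#' `T` is the kinetic matrix scaled by `1/mass`; `V` is the interaction with
#' the given point charges, signed by the particle charge, i.e.
#' `V = charge * sum_c q_c (mu|1/|r-R_c||nu)` -- negative (attractive) for an
#' electron near a nucleus, positive (repulsive) for like charges.
#'
#' @param basis an `ao_basis` or list of `shell_block`s.
#' @param mass particle mass in electron masses (> 0).
#' @param charge particle charge (signed integer; electron = -1, proton = +1).
#' @param point_charges list with `q` (charges) and `pos` (n x 3, bohr); may
#'   be empty.
#' @return list with matrices `S`, `T`, `V`.
#' @export
one_particle <- function(basis, mass = 1, charge = -1,
                         point_charges = list(q = numeric(0),
                                              pos = matrix(0, 0, 3))) {
  if (mass <= 0) stop("particle mass must be positive")
  sl <- .shell_list(basis)
  st <- cpp_overlap_kinetic(sl)
  V <- charge * cpp_attraction(sl, as.numeric(point_charges$q),
                               matrix(as.numeric(point_charges$pos), ncol = 3))
  list(S = st$S, T = st$T / mass, V = V)
}

#' 2-index Coulomb metric over a fitting basis
#'
#' Returns the symmetric positive-definite matrix `(A|B)` of two-centre
#' Coulomb integrals among fitting functions.  A condition-number estimate is
#' attached as attribute `cond`; values above 1e14 indicate near-singularity
#' (downstream solves use a pivoted eigen factorisation with a floor).
#'
#' @param fit_basis an `ao_basis` or list of `shell_block`s.
#' @export
coulomb_metric <- function(fit_basis) {
  J2 <- cpp_metric2(.shell_list(fit_basis))
  ev <- eigen(J2, symmetric = TRUE, only.values = TRUE)$values
  cond <- max(ev) / max(min(ev), .Machine$double.xmin)
  if (!is.finite(cond) || cond > 1e14) {
    warning("fitting-basis Coulomb metric is near-singular (cond ~ ",
            format(cond, digits = 3), "); solves use the regularised factorisation")
  }
  attr(J2, "cond") <- cond
  J2
}

#' 3-index Coulomb integrals (mu nu | A)
#'
#' The AO and fitting bases may belong to different particle classes; calling
#' this with a nuclear AO basis and an electronic fitting basis (or vice
#' versa) yields the cross-subsystem tensors used in the coupling build.
#'
#' @param ao_basis AO basis (bra pair side).
#' @param fit_basis fitting basis.
#' @param max_mb allocation guard in megabytes (default 2000).
#' @return matrix of dimension (nao*nao) x nfit; entry `[mu + (nu-1)*nao, A]`
#'   is `(mu nu|A)`, symmetric in mu <-> nu.
#' @export
three_index <- function(ao_basis, fit_basis, max_mb = 2000) {
  sl <- .shell_list(ao_basis)
  fl <- .shell_list(fit_basis)
  nao <- basis_nfun(if (inherits(ao_basis, "ao_basis")) ao_basis$shells else ao_basis)
  nfit <- basis_nfun(if (inherits(fit_basis, "ao_basis")) fit_basis$shells else fit_basis)
  mb <- nao^2 * nfit * 8 / 2^20
  if (mb > max_mb) {
    stop(sprintf("3-index tensor would need %.0f MB (> %.0f MB guard)", mb, max_mb))
  }
  cpp_eri3(sl, fl)
}

#' Exact four-index integrals over packed AO pairs
#'
#' Oracle / integral-direct mode.  Stores the full chemists'-notation tensor
#' `(mu nu|lam sig)` over packed pairs (mu >= nu); eight-fold permutational
#' symmetry is exact by construction.
#'
#' @param ao_basis AO basis.
#' @param max_pairs guard on the number of AO pair products (default 40000);
#'   exceeding it raises an error instructing use of the DF mode.
#' @return an `eri4` object (packed matrix with `nao` attribute).
#' @export
four_index <- function(ao_basis, max_pairs = 40000) {
  nao <- basis_nfun(if (inherits(ao_basis, "ao_basis")) ao_basis$shells else ao_basis)
  npair <- nao * (nao + 1) / 2
  if (npair > max_pairs) {
    stop(sprintf(paste0("four-index storage guard: %d AO pairs exceed the cap ",
                        "of %d; use the density-fitted mode"), npair, max_pairs))
  }
  M <- cpp_eri4_packed(.shell_list(ao_basis))
  attr(M, "nao") <- nao
  class(M) <- c("eri4", class(M))
  M
}

#' Extract a single element (mu nu|lam sig) from a packed four-index tensor
#' @param M an `eri4` object.
#' @param mu,nu,lam,sig 1-based AO indices.
#' @export
eri4_elem <- function(M, mu, nu, lam, sig) {
  pk <- function(i, j) { a <- max(i, j) - 1L; b <- min(i, j) - 1L; a * (a + 1L) / 2L + b + 1L }
  M[pk(mu, nu), pk(lam, sig)]
}

# exact J/K from the packed tensor
jk_exact <- function(M, D) cpp_jk_packed(unclass(M), D)

#' Direct screened Coulomb contraction between two particle classes
#'
#' Computes `J[mu nu] = sum_{lam sig} (mu nu|lam sig) D_other[lam sig]`
#' integral-directly with combined Schwarz and density-element prescreening,
#' without storing the cross four-index tensor.  This is the default engine
#' for the nuclear iterations and the exact-coupling reference.
#'
#' @param bra_basis basis in which the potential matrix is returned.
#' @param ket_basis basis of the contracted density.
#' @param D_other symmetric density matrix over `ket_basis`.
#' @param thresh prescreening threshold (default 1e-10).
#' @export
coulomb_contract <- function(bra_basis, ket_basis, D_other, thresh = 1e-10) {
  cpp_coulomb_cross(.shell_list(bra_basis), .shell_list(ket_basis),
                    D_other, thresh)
}

# packed symmetric-pair helpers matching the C++ pair ordering (upper
# triangle, column-major)
pack_weights <- function(D) {
  W2 <- matrix(2, nrow(D), ncol(D))
  diag(W2) <- 1
  (D * W2)[upper.tri(D, diag = TRUE)]
}

unpack_sym <- function(v, n) {
  M <- matrix(0, n, n)
  M[upper.tri(M, diag = TRUE)] <- v
  M + t(M) - diag(diag(M), n)
}

# Coulomb potentials from a cached packed cross tensor
cross_J_bra <- function(Mx, Dket, nbra) unpack_sym(Mx %*% pack_weights(Dket), nbra)
cross_J_ket <- function(Mx, Dbra, nket) unpack_sym(crossprod(Mx, pack_weights(Dbra)), nket)

#' Evaluate basis functions on points
#' @param basis an `ao_basis` or shell list.
#' @param points n x 3 matrix (bohr).
#' @return n x nao matrix.
#' @export
eval_basis <- function(basis, points) {
  cpp_eval_basis(.shell_list(basis), matrix(as.numeric(points), ncol = 3))
}
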