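# Robust density-fitted Coulomb and exchange builds, and the fitted Coulomb
# coupling between the electronic and nuclear subsystems.
#
# Expansion coefficients minimise the Coulomb-metric least-squares functional
# (the electric-field-weighted robust fit); with a single shared fitting
# basis the robust corrections collapse onto the plain resolution-of-the-
# identity expressions, so the fitted Coulomb energy error is second order
# in the fitting residual.

#' Factorise a fitting-basis Coulomb metric
#'
#' Pivoted symmetric eigen-factorisation with an eigenvalue floor: directions
#' with eigenvalues below `floor_rel * max(eigenvalue)` are discarded, which
#' keeps near-singular even-tempered fitting ladders usable.
#'
#' @param J2 Coulomb metric matrix.
#' @param floor_rel relative eigenvalue floor (default 1e-10).
#' @return a `df_metric` object with solve and inverse-square-root operators.
#' @export
df_metric_factor <- function(J2, floor_rel = 1e-10) {
  e <- eigen((J2 + t(J2)) / 2, symmetric = TRUE)
  keep <- e$values > floor_rel * max(e$values)
  V <- e$vectors[, keep, drop = FALSE]
  ev <- e$values[keep]
  structure(list(
    V = V, ev = ev, n = ncol(J2),
    cond = max(e$values) / max(min(e$values), .Machine$double.xmin),
    dropped = sum(!keep),
    solve = function(b) V %*% ((crossprod(V, b)) / ev),
    half = function(B) B %*% V %*% diag(1 / sqrt(ev), length(ev))
  ), class = "df_metric")
}

#' @export
print.df_metric <- function(x, ...) {
  cat(sprintf("<df_metric: %d functions, %d directions floored, cond ~ %.2e>\n",
              x$n, x$dropped, x$cond))
  invisible(x)
}

.as_fac <- function(J2) if (inherits(J2, "df_metric")) J2 else df_metric_factor(J2)

#' Fitted total-density coefficients d_A
#'
#' Solves `J2 d = B` with `B_A = sum_{mu nu} D_{mu nu} (mu nu|A)`.
#'
#' @param D symmetric density matrix.
#' @param B3 3-index tensor, (nao*nao) x nfit layout.
#' @param J2 Coulomb metric or its `df_metric` factorisation.
#' @return coefficient vector with attribute `rhs` (the contraction B).
#' @export
fit_coefficients <- function(D, B3, J2) {
  fac <- .as_fac(J2)
  B <- crossprod(B3, as.numeric(D))
  d <- as.numeric(fac$solve(B))
  attr(d, "rhs") <- as.numeric(B)
  d
}

#' Density-fitted Coulomb matrix
#'
#' `J_{mu nu} = sum_A (mu nu|A) d_A` with the fitted coefficients of the
#' total density.
#'
#' @inheritParams fit_coefficients
#' @export
build_J_df <- function(D, B3, J2) {
  n <- as.integer(sqrt(nrow(B3)))
  if (n * n != nrow(B3) || any(dim(D) != n)) stop("density/3-index dimension mismatch")
  d <- fit_coefficients(D, B3, J2)
  J <- matrix(B3 %*% d, n, n)
  (J + t(J)) / 2
}

#' Density-fitted exchange matrix from half-transformed integrals
#'
#' Assembles `K` from occupied-orbital half-transformed 3-index integrals
#' `(i nu|A)` and their metric-solved coefficients; with `occ = 2` (closed
#' shell) the result equals the exact-integral `K(D)` for `D = 2 C C^T` in
#' the complete-fitting limit.
#'
#' @param C_occ AO x nocc occupied coefficients (columns may carry fractional
#'   occupations via `occ_num`).
#' @param B3 3-index tensor.
#' @param J2 metric or factorisation.
#' @param occ uniform occupation per orbital (default 2, closed-shell).
#' @param occ_num optional per-orbital occupation vector overriding `occ`.
#' @export
build_K_df <- function(C_occ, B3, J2, occ = 2, occ_num = NULL) {
  n <- as.integer(sqrt(nrow(B3)))
  K <- matrix(0, n, n)
  if (is.null(C_occ) || NCOL(C_occ) == 0) return(K)
  C_occ <- as.matrix(C_occ)
  if (nrow(C_occ) != n) stop("orbital/3-index dimension mismatch")
  fac <- .as_fac(J2)
  nfit <- ncol(B3)
  if (is.null(occ_num)) occ_num <- rep(occ, ncol(C_occ))
  # (i nu | A) for all occupied orbitals at once
  T1 <- crossprod(C_occ, matrix(B3, n, n * nfit)) # nocc x (nao*nfit)
  for (i in seq_len(ncol(C_occ))) {
    Bi <- matrix(T1[i, ], n, nfit)
    Bt <- fac$half(Bi)
    K <- K + occ_num[i] * tcrossprod(Bt)
  }
  (K + t(K)) / 2
}

#' Fitted Coulomb coupling potential between subsystems
#'
#' Expands the (frozen) density of the complementary subsystem in the
#' designated fitting basis and evaluates its electrostatic potential in this
#' subsystem's AO basis:
#' `V = q_self q_other * B3_self %*% solve(J2, t(X3) %*% vec(D_other))`.
#' The fitted intermediate `d_A` is returned as an attribute so the coupling
#' energy can be computed identically from either subsystem.
#'
#' @param D_other density matrix of the complementary subsystem.
#' @param X3 cross 3-index tensor: (n_other^2) x nfit, other-subsystem AO
#'   pairs against the shared fitting basis.
#' @param J2_fit metric (or factorisation) of the shared fitting basis.
#' @param B3_self 3-index tensor of this subsystem's AO pairs against the
#'   same fitting basis.
#' @param q_self,q_other particle charges (electron -1, proton +1).
#' @export
build_coupling_J <- function(D_other, X3, J2_fit, B3_self, q_self, q_other) {
  if (nrow(X3) != length(D_other)) stop("cross-tensor/density dimension mismatch")
  d <- fit_coefficients(D_other, X3, J2_fit)
  n <- as.integer(sqrt(nrow(B3_self)))
  V <- matrix(B3_self %*% as.numeric(d), n, n)
  V <- q_self * q_other * (V + t(V)) / 2
  attr(V, "d") <- as.numeric(d)
  V
}

# Coulomb interaction energy of two fitted densities sharing one metric:
# (rho_a | tilde rho_b) = g_a^T J2^{-1} g_b
fitted_pair_energy <- function(g_a, g_b, fac) {
  as.numeric(crossprod(g_a, fac$solve(g_b)))
}
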