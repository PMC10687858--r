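# Slow, independent quadrature oracles for s/p Gaussian integrals.
#
# These deliberately avoid the McMurchie-Davidson machinery: overlaps and
# kinetic matrices come from dense midpoint grids with finite-difference
# Laplacians; Coulomb interactions between spherical distributions come from
# the shell theorem (1-D radial quadrature of the electrostatic potential)
# plus Legendre quadrature over the relative angle.  They validate the
# compiled engine on small cases in the test suite.

# evaluate an s or p shell's normalised functions on points (own code path)
oracle_eval <- function(shell, pts) {
  if (shell$l > 1) stop("quadrature oracle covers s and p shells only")
  d <- sweep(pts, 2, shell$center)
  r2 <- rowSums(d^2)
  rad <- rep(0, nrow(pts))
  for (k in seq_along(shell$exps)) {
    a <- shell$exps[k]
    pn <- (2 * a / pi)^0.75 * if (shell$l == 1) 2 * sqrt(a) else 1
    rad <- rad + shell$coefs[k] * pn * exp(-a * r2)
  }
  if (shell$l == 0) matrix(rad, ncol = 1) else d * rad
}

#' Grid-quadrature overlap and kinetic oracle (s/p shells)
#'
#' @param shells list of `shell_block`s with l <= 1.
#' @param spacing grid spacing in bohr.
#' @param extent box half-width beyond the outermost centre in bohr.
#' @param mass particle mass for the kinetic scaling.
#' @return list with `S` and `T` for grid-normalised functions.
#' @export
oracle_one_particle <- function(shells, spacing = 0.12, extent = 6, mass = 1) {
  ctr <- do.call(rbind, lapply(shells, function(s) s$center))
  lo <- apply(ctr, 2, min) - extent
  hi <- apply(ctr, 2, max) + extent
  gx <- lapply(1:3, function(d) seq(lo[d] + spacing / 2, hi[d], by = spacing))
  pts <- as.matrix(expand.grid(gx[[1]], gx[[2]], gx[[3]]))
  h3 <- spacing^3
  V <- do.call(cbind, lapply(shells, oracle_eval, pts = pts))
  nrm <- sqrt(colSums(V^2) * h3)
  V <- sweep(V, 2, nrm, "/")
  S <- crossprod(V) * h3
  # finite-difference Laplacian
  fd <- 1e-3
  L <- matrix(0, nrow(pts), ncol(V))
  for (d in 1:3) {
    for (sgn in c(-1, 1)) {
      sh_pts <- pts
      sh_pts[, d] <- sh_pts[, d] + sgn * fd
      Vs <- do.call(cbind, lapply(shells, oracle_eval, pts = sh_pts))
      Vs <- sweep(Vs, 2, nrm, "/")
      L <- L + Vs
    }
  }
  L <- (L - 6 * V) / fd^2
  T <- -0.5 * crossprod(V, L) * h3 / mass
  list(S = S, T = (T + t(T)) / 2)
}

# electrostatic potential of the spherical distribution c*exp(-a r^2) at
# radius R, via the shell theorem (no closed form used)
oracle_point_potential <- function(c0, a, R) {
  qin <- function(s) {
    stats::integrate(function(r) 4 * pi * r^2 * c0 * exp(-a * r^2), 0, s,
                     rel.tol = 1e-11)$value
  }
  qout <- stats::integrate(function(r) 4 * pi * r * c0 * exp(-a * r^2),
                           max(R, 1e-12), Inf, rel.tol = 1e-11)$value
  if (R < 1e-12) {
    return(stats::integrate(function(r) 4 * pi * r * c0 * exp(-a * r^2),
                            0, Inf, rel.tol = 1e-11)$value)
  }
  qin(R) / R + qout
}

#' Coulomb interaction of two spherical Gaussian distributions (oracle)
#'
#' Energy `\int\int rho1(r1) rho2(r2) / |r1-r2|` for
#' `rho_i = c_i exp(-a_i r^2)` centred a distance `R` apart, by radial
#' quadrature of the shell-theorem potential and Gauss-Legendre angular
#' quadrature.
#'
#' @param c1,a1 prefactor and exponent of the first distribution.
#' @param c2,a2 prefactor and exponent of the second distribution.
#' @param R centre separation in bohr.
#' @param nleg number of angular quadrature nodes.
#' @export
oracle_coulomb_spherical <- function(c1, a1, c2, a2, R, nleg = 48) {
  # Gauss-Legendre nodes on [-1, 1]
  gl <- .gauss_legendre(nleg)
  pot_at <- function(s) {
    vapply(s, function(si) oracle_point_potential(c2, a2, si), numeric(1))
  }
  integrand <- function(r) {
    vapply(r, function(ri) {
      s <- sqrt(pmax(ri^2 + R^2 - 2 * ri * R * gl$x, 0))
      avg <- sum(gl$w * pot_at(s)) / 2
      4 * pi * ri^2 * c1 * exp(-a1 * ri^2) * avg
    }, numeric(1))
  }
  stats::integrate(integrand, 0, Inf, rel.tol = 1e-9)$value
}

# Golub-Welsch Gauss-Legendre rule
.gauss_legendre <- function(n) {
  k <- seq_len(n - 1)
  b <- k / sqrt(4 * k^2 - 1)
  Jm <- matrix(0, n, n)
  Jm[cbind(k, k + 1)] <- b
  Jm[cbind(k + 1, k)] <- b
  e <- eigen(Jm, symmetric = TRUE)
  list(x = e$values, w = 2 * e$vectors[1, ]^2)
}
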