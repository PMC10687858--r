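# Self-consistent field machinery shared by the electronic and nuclear
# subsystems: Roothaan iterations with DIIS (error vector FDS - SDF in the
# orthonormalised AO basis, history depth 10, extrapolation starting after
# the first iteration), convergence on energy difference, density difference
# and gradient simultaneously, plus the starting-guess constructions.

# canonical orthogonalisation; near-dependent directions are pruned
lowdin_x <- function(S, thresh = 1e-9) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  keep <- e$values > thresh * max(e$values)
  if (!all(keep)) {
    if (sum(keep) == 0) stop("overlap matrix is singular; prune the basis")
  }
  e$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(e$values[keep]), sum(keep))
}

# natural orbitals of a (possibly non-idempotent) density in the S metric:
# D = sum_p n_p C_p C_p^T
density_orbitals <- function(D, S, X = lowdin_x(S), tol = 1e-10) {
  Dp <- crossprod(X, S %*% D %*% S %*% X)
  e <- eigen((Dp + t(Dp)) / 2, symmetric = TRUE)
  keep <- e$values > tol
  list(C = X %*% e$vectors[, keep, drop = FALSE], n = e$values[keep])
}

.diis_extrapolate <- function(flist, elist) {
  m <- length(flist)
  if (m == 1) return(flist[[1]])
  B <- matrix(0, m + 1, m + 1)
  for (i in 1:m) for (j in 1:m) B[i, j] <- sum(elist[[i]] * elist[[j]])
  # normalise the error-overlap block: near convergence its entries are
  # ~||err||^2 << 1 and an unscaled solve against the constraint row is
  # declared singular, silently degrading DIIS to plain Roothaan steps
  s <- max(diag(B)[1:m], .Machine$double.xmin)
  B[1:m, 1:m] <- B[1:m, 1:m] / s
  B[m + 1, 1:m] <- B[1:m, m + 1] <- -1
  rhs <- c(rep(0, m), -1)
  # minimal-norm pseudo-solve: with near-parallel stored error vectors the
  # system is rank-deficient and a plain solve() would reject it
  sv <- svd(B)
  keep <- sv$d > 1e-12 * max(sv$d)
  cf <- (sv$v[, keep, drop = FALSE] %*%
           (crossprod(sv$u[, keep, drop = FALSE], rhs) / sv$d[keep]))[1:m]
  if (any(!is.finite(cf)) || abs(sum(cf) - 1) > 1e-6) return(flist[[m]])
  F <- matrix(0, nrow(flist[[1]]), ncol(flist[[1]]))
  for (i in 1:m) F <- F + cf[i] * flist[[i]]
  F
}

#' Run one subsystem's SCF micro-iterations
#'
#' Generic Roothaan/DIIS driver.  The Fock builder closes over the frozen
#' complementary-subsystem coupling potential; convergence requires the
#' energy difference, the density difference and the orbital gradient
#' `||FDS - SDF||` to fall below their thresholds simultaneously.
#'
#' @param h core Hamiltonian (kinetic + external potential) of the subsystem.
#' @param S overlap matrix.
#' @param fock_builder function(D, orbs) returning the full Fock matrix;
#'   `orbs` is a list with occupied `C` and occupations `n`.
#' @param energy_fn function(D, F, h) returning the subsystem energy
#'   (including its share of the frozen coupling).
#' @param D0 starting density.
#' @param nocc number of occupied orbitals.
#' @param occ occupation per orbital (2 closed-shell electrons, 1 nucleus).
#' @param thresholds named vector `c(e=, d=, g=)`.
#' @param max_iter iteration cap; exceeding it raises an error carrying the
#'   trace.
#' @param diis_size history depth (default 10).
#' @param level_shift virtual-orbital shift in Hartree (0 = off;
#'   auto-disabled once the gradient falls below 1e-4).
#' @return a `subsystem_state`: list with `D`, `C`, `eps`, `F`, `energy`,
#'   `iterations`, `converged`, per-criterion `flags` and a `trace`
#'   data.frame.
#' @export
scf_iterate <- function(h, S, fock_builder, energy_fn, D0, nocc, occ = 2,
                        thresholds = c(e = 1e-8, d = 1e-8, g = 1e-8),
                        max_iter = 50, diis_size = 10, level_shift = 0) {
  X <- lowdin_x(S)
  D <- D0
  orbs <- density_orbitals(D, S, X)
  # clip to the physical occupation pattern for exchange-type builders
  F <- fock_builder(D, orbs)
  E <- energy_fn(D, F, h)
  flist <- list(); elist <- list()
  trace <- data.frame()
  C <- NULL; eps <- NULL
  conv <- c(e = FALSE, d = FALSE, g = FALSE)
  for (it in seq_len(max_iter)) {
    err <- crossprod(X, (F %*% D %*% S - S %*% D %*% F) %*% X)
    gnorm <- max(abs(err))
    # DIIS: store and extrapolate from the second iteration onward
    flist <- c(flist, list(F)); elist <- c(elist, list(err))
    if (length(flist) > diis_size) { flist <- flist[-1]; elist <- elist[-1] }
    Fd <- if (it >= 2) .diis_extrapolate(flist, elist) else F
    Fo <- crossprod(X, Fd %*% X)
    if (level_shift > 0 && !is.null(C)) {
      # shift the previous iterate's virtual space upward; the converged
      # density is unchanged (occupied-virtual Fock blocks vanish there)
      Cv <- crossprod(X, S %*% C[, -seq_len(nocc), drop = FALSE])
      Fo <- Fo + level_shift * tcrossprod(Cv)
    }
    ee <- eigen((Fo + t(Fo)) / 2, symmetric = TRUE)
    ord <- order(ee$values)
    C <- X %*% ee$vectors[, ord, drop = FALSE]
    eps <- ee$values[ord]
    C_occ <- C[, seq_len(nocc), drop = FALSE]
    Dn <- occ * tcrossprod(C_occ)
    dnorm <- max(abs(Dn - D))
    D <- Dn
    orbs <- list(C = C_occ, n = rep(occ, nocc))
    F <- fock_builder(D, orbs)
    En <- energy_fn(D, F, h)
    de <- abs(En - E)
    E <- En
    trace <- rbind(trace, data.frame(iter = it, energy = En, dE = de,
                                     dD = dnorm, grad = gnorm,
                                     diis_dim = length(flist)))
    conv <- c(e = de <= thresholds[["e"]], d = dnorm <= thresholds[["d"]],
              g = gnorm <= thresholds[["g"]])
    if (all(conv)) break
  }
  if (!all(conv)) {
    err <- simpleError(sprintf(
      "SCF did not converge in %d iterations (dE=%.3e, dD=%.3e, grad=%.3e)",
      max_iter, trace$dE[nrow(trace)], trace$dD[nrow(trace)],
      trace$grad[nrow(trace)]))
    err$trace <- trace
    stop(err)
  }
  structure(list(D = D, C = C, eps = eps, F = F, energy = E,
                 nocc = nocc, occ = occ, iterations = nrow(trace),
                 converged = TRUE, flags = conv, trace = trace),
            class = "subsystem_state")
}

#' @export
print.subsystem_state <- function(x, ...) {
  cat(sprintf("<subsystem_state: E = %.10f Eh, %d iterations, converged = %s>\n",
              x$energy, x$iterations, x$converged))
  invisible(x)
}

# -------------------------------------------------------------------- guesses

# spherically averaged atomic RHF occupations (spatial orbitals)
atomic_occupations <- function(z) {
  shells <- c(2, 2, 6, 2, 6) # 1s 2s 2p 3s 3p capacities (electrons)
  per <- c(1, 1, 3, 1, 3)    # spatial orbitals per subshell
  occ <- numeric(0)
  left <- z
  for (k in seq_along(shells)) {
    take <- min(left, shells[k])
    if (take > 0) occ <- c(occ, rep(take / per[k], per[k]))
    left <- left - take
    if (left <= 0) break
  }
  occ
}

# spherically averaged atomic RHF density for one atom in its own shells
atomic_density <- function(element, shells_tmpl, center, pure = TRUE) {
  shells <- lapply(shells_tmpl, function(t)
    shell_block(t$l, center, t$exps, t$coefs, pure = pure))
  z <- element_charge(element)
  op <- one_particle(shells, charge = -1,
                     point_charges = list(q = z, pos = matrix(center, 1, 3)))
  h <- op$T + op$V
  M <- four_index(shells, max_pairs = 1e6)
  X <- lowdin_x(op$S)
  occ <- atomic_occupations(z)
  no <- length(occ)
  D <- matrix(0, nrow(h), ncol(h))
  for (it in 1:80) {
    jk <- jk_exact(M, D)
    F <- h + jk$J - 0.5 * jk$K
    ee <- eigen(crossprod(X, F %*% X), symmetric = TRUE)
    ord <- order(ee$values)
    C <- X %*% ee$vectors[, ord[seq_len(no)], drop = FALSE]
    Dn <- C %*% diag(occ, no) %*% t(C)
    if (max(abs(Dn - D)) < 1e-8 && it > 3) { D <- Dn; break }
    D <- 0.7 * Dn + 0.3 * D # damped
  }
  D
}

#' Electronic starting density
#'
#' Three sources: `atomic_density` superposes spherically averaged atomic
#' RHF densities (no molecular calculation needed); `minimal_projection`
#' solves RHF in the bundled minimal basis and projects onto the target
#' basis; `supplied` validates and passes through a given density.  The
#' returned density satisfies `Tr(D S) = N_e` after trace purification.
#'
#' @param system a `neo_system`.
#' @param basis electronic `ao_basis`.
#' @param mode guess source.
#' @param supplied density matrix for `mode = "supplied"`.
#' @export
electronic_guess <- function(system, basis,
                             mode = c("atomic_density", "minimal_projection",
                                      "supplied"),
                             supplied = NULL) {
  mode <- match.arg(mode)
  ne <- n_electrons(system)
  S <- one_particle(basis)$S
  if (mode == "supplied") {
    if (is.null(supplied) || !all(dim(supplied) == basis$nao)) {
      stop("supplied density has wrong dimension")
    }
    D <- supplied
  } else if (mode == "atomic_density") {
    D <- matrix(0, basis$nao, basis$nao)
    # atomic densities are built in the *molecular* basis functions of each
    # atom so the superposition lives directly in the target basis
    for (ia in seq_along(system$elements)) {
      idx_sh <- which(basis$atom == ia)
      at_shells <- lapply(basis$shells[idx_sh], function(s)
        list(l = s$l, exps = s$exps, coefs = s$coefs))
      Da <- atomic_density(system$elements[ia], at_shells, system$coords[ia, ])
      idx_ao <- which(basis$ao_atom == ia)
      D[idx_ao, idx_ao] <- D[idx_ao, idx_ao] + Da
    }
  } else { # minimal_projection
    minb <- make_basis(system, "sto-3g")
    res <- rhf_in_basis(system, minb)
    # mixed overlap between target and minimal basis
    both <- c(basis$shells, minb$shells)
    Sfull <- cpp_overlap_kinetic(.shell_list(both))$S
    n1 <- basis$nao
    S12 <- Sfull[seq_len(n1), n1 + seq_len(minb$nao), drop = FALSE]
    Cmin <- res$C[, seq_len(res$nocc), drop = FALSE]
    Cp <- solve(Sfull[seq_len(n1), seq_len(n1)], S12 %*% Cmin)
    # S-orthonormalise the projected occupied set
    M <- crossprod(Cp, S %*% Cp)
    e <- eigen((M + t(M)) / 2, symmetric = TRUE)
    Cp <- Cp %*% e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-12)),
                                    ncol(Cp)) %*% t(e$vectors)
    D <- 2 * tcrossprod(Cp)
  }
  # trace purification
  tr <- sum(D * S)
  if (tr > 1e-8) D <- D * (ne / tr)
  D
}

# plain RHF in a given basis with exact integrals (used by the projection
# guess and as an internal reference)
rhf_in_basis <- function(system, basis, thresholds = c(e = 1e-8, d = 1e-8, g = 1e-8),
                         max_iter = 60) {
  cc <- classical_charges_all(system)
  op <- one_particle(basis, charge = -1, point_charges = cc)
  h <- op$T + op$V
  M <- four_index(basis, max_pairs = 1e6)
  ne <- n_electrons(system)
  nocc <- ne / 2
  if (nocc != round(nocc)) stop("odd electron count: closed-shell RHF only")
  D0 <- electronic_guess_simple(op$S, h, ne)
  st <- scf_iterate(
    h, op$S,
    fock_builder = function(D, orbs) {
      jk <- jk_exact(M, D)
      h + jk$J - 0.5 * jk$K
    },
    energy_fn = function(D, F, h) 0.5 * sum(D * (h + F)),
    D0 = D0, nocc = nocc, occ = 2, thresholds = thresholds,
    max_iter = max_iter)
  st$nocc <- nocc
  st
}

# core-Hamiltonian guess (internal)
electronic_guess_simple <- function(S, h, ne) {
  X <- lowdin_x(S)
  ee <- eigen(crossprod(X, h %*% X), symmetric = TRUE)
  ord <- order(ee$values)
  C <- X %*% ee$vectors[, ord[seq_len(ne / 2)], drop = FALSE]
  2 * tcrossprod(C)
}

# all nuclei as point charges (for conventional RHF, where no nucleus is
# quantum); contrast with classical_charges() which excludes quantum nuclei
classical_charges_all <- function(system) {
  list(q = system$z, pos = system$coords)
}

#' Block-diagonal nuclear starting guess
#'
#' Diagonalises each nuclear centre's diagonal block of the effective
#' nuclear core Hamiltonian independently and occupies the lowest orbital of
#' every block, so each proton site starts occupied.  The alternative (full
#' diagonalisation) tends to pile all protons onto a single centre because
#' the core Hamiltonian has no density-density repulsion between them.
#'
#' @param H_core_n nuclear core Hamiltonian over the union basis (kinetic +
#'   classical attraction + frozen electronic coupling).
#' @param S_n union-basis overlap.
#' @param center_blocks list of integer index vectors, one per nuclear
#'   centre, partitioning the basis.
#' @return density matrix with exact block structure; each block has
#'   S-weighted trace 1.
#' @export
block_diag_guess <- function(H_core_n, S_n, center_blocks) {
  n <- nrow(H_core_n)
  cover <- sort(unlist(center_blocks))
  if (!identical(cover, seq_len(n))) stop("centre blocks must partition the basis")
  D <- matrix(0, n, n)
  for (blk in center_blocks) {
    if (length(blk) == 0) stop("a nuclear centre has zero basis functions")
    Xb <- lowdin_x(S_n[blk, blk, drop = FALSE])
    ee <- eigen(crossprod(Xb, H_core_n[blk, blk, drop = FALSE] %*% Xb),
                symmetric = TRUE)
    cb <- Xb %*% ee$vectors[, which.min(ee$values), drop = FALSE]
    D[blk, blk] <- tcrossprod(cb)
  }
  D
}

# full-diagonalisation nuclear guess over the union basis (the problematic
# alternative exercised by the block-guess comparison)
full_diag_guess <- function(H_core_n, S_n, n_particles) {
  X <- lowdin_x(S_n)
  ee <- eigen(crossprod(X, H_core_n %*% X), symmetric = TRUE)
  ord <- order(ee$values)
  C <- X %*% ee$vectors[, ord[seq_len(n_particles)], drop = FALSE]
  tcrossprod(C)
}
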