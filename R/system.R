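# Molecular systems: classical atoms plus a selection of quantum nuclei
# (protons by default), XYZ input/output, and deterministic test fixtures.

#' Define a molecular system with quantum-nucleus selection
#'
#' @param elements character vector of element symbols.
#' @param coords n x 3 matrix of positions in bohr.
#' @param charge total charge (integer).
#' @param quantum integer indices (1-based) of nuclei treated quantum
#'   mechanically, or `"all-H"`, or `"none"`.
#' @param masses optional named override of quantum-nucleus masses in
#'   electron masses; by default protons get [PROTON_MASS].
#' @param protons_only error if a quantum index refers to a non-hydrogen atom
#'   (default TRUE; only proton/deuteron quantisation is supported).
#' @return object of class `neo_system`.
#' @export
neo_system <- function(elements, coords, charge = 0L, quantum = "none",
                       masses = NULL, protons_only = TRUE) {
  coords <- matrix(as.numeric(coords), ncol = 3)
  n <- length(elements)
  if (nrow(coords) != n) stop("coordinate/element length mismatch")
  if (any(!is.finite(coords))) stop("non-finite coordinates")
  z <- element_charge(elements)
  if (n > 1) {
    dd <- as.matrix(stats::dist(coords))
    diag(dd) <- Inf
    if (min(dd) < 1e-6) stop("two atoms coincide")
  }
  qidx <- resolve_quantum_selector(quantum, elements, protons_only)
  qmass <- rep(PROTON_MASS, length(qidx))
  names(qmass) <- as.character(qidx)
  if (!is.null(masses)) {
    if (is.null(names(masses))) stop("mass overrides must be named by atom index")
    for (nm in names(masses)) {
      if (!nm %in% names(qmass)) stop("mass override for non-quantum atom ", nm)
      if (masses[[nm]] <= 0) stop("quantum nucleus mass must be positive")
      qmass[nm] <- masses[[nm]]
    }
  }
  structure(
    list(elements = elements, coords = coords, z = z,
         charge = as.integer(charge), quantum = qidx,
         classical = setdiff(seq_len(n), qidx), qmass = qmass),
    class = "neo_system"
  )
}

resolve_quantum_selector <- function(quantum, elements, protons_only = TRUE) {
  if (is.character(quantum)) {
    if (length(quantum) != 1) stop("character selector must be a single string")
    if (quantum == "none") return(integer(0))
    if (tolower(quantum) == "all-h") return(which(elements == "H"))
    stop("unknown quantum selector '", quantum, "'")
  }
  qidx <- as.integer(quantum)
  if (any(qidx < 1 | qidx > length(elements))) {
    stop("quantum selector index out of range")
  }
  if (anyDuplicated(qidx)) stop("duplicate quantum indices")
  if (protons_only && any(elements[qidx] != "H")) {
    stop("quantum selection names a non-hydrogen atom (only protons/deuterons ",
         "can be quantised); offending index: ",
         paste(qidx[elements[qidx] != "H"], collapse = ", "))
  }
  sort(qidx)
}

#' Number of electrons of a system
#' @param system a `neo_system`.
#' @export
n_electrons <- function(system) sum(system$z) - system$charge

#' Switch quantum protons to deuterons
#'
#' @param system a `neo_system`.
#' @param indices quantum atom indices to switch (default: all).
#' @export
set_deuterium <- function(system, indices = system$quantum) {
  for (i in indices) {
    if (!i %in% system$quantum) stop("atom ", i, " is not a quantum nucleus")
    system$qmass[as.character(i)] <- DEUTERON_MASS
  }
  system
}

#' @export
print.neo_system <- function(x, ...) {
  cat(sprintf("<neo_system: %d atoms (%s), charge %+d, %d quantum nuclei>\n",
              length(x$elements), paste(unique(x$elements), collapse = ","),
              x$charge, length(x$quantum)))
  invisible(x)
}

# ---------------------------------------------------------------------- XYZ

#' Read an XYZ file (Angstrom) into a `neo_system`
#'
#' @param path XYZ file path.
#' @param charge total charge.
#' @param quantum quantum-nucleus selector (see [neo_system()]).
#' @param protons_only restrict quantisation to hydrogens.
#' @export
read_xyz <- function(path, charge = 0L, quantum = "none", protons_only = TRUE) {
  if (!file.exists(path)) stop("XYZ file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2) stop("XYZ parse error at line 1: missing header")
  nat <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(nat) || nat < 1) stop("XYZ parse error at line 1: bad atom count")
  if (length(lines) < nat + 2) stop("XYZ parse error: fewer atom lines than declared")
  elements <- character(nat)
  coords <- matrix(NA_real_, nat, 3)
  for (k in seq_len(nat)) {
    ln <- k + 2L
    tok <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    xyz <- suppressWarnings(as.numeric(tok[2:4]))
    if (length(tok) < 4 || any(is.na(xyz))) {
      stop("XYZ parse error at line ", ln, ": '", lines[ln], "'")
    }
    elements[k] <- tok[1]
    coords[k, ] <- xyz
  }
  neo_system(elements, coords * BOHR_PER_ANGSTROM, charge = charge,
             quantum = quantum, protons_only = protons_only)
}

#' Write a system to an XYZ file (Angstrom)
#'
#' @param system a `neo_system`.
#' @param path output file.
#' @param comment second header line.
#' @export
write_xyz <- function(system, path, comment = "written by neoscf") {
  ang <- system$coords / BOHR_PER_ANGSTROM
  lines <- c(
    as.character(length(system$elements)), comment,
    sprintf("%-3s %18.10f %18.10f %18.10f", system$elements,
            ang[, 1], ang[, 2], ang[, 3])
  )
  writeLines(lines, path)
  invisible(path)
}

# ------------------------------------------------------------------ fixtures

.fixture_coords <- function(name) {
  A <- function(...) matrix(c(...), ncol = 3, byrow = TRUE) # Angstrom
  switch(name,
    h2 = list(el = c("H", "H"), xyz = A(0, 0, 0, 0, 0, 0.74), charge = 0L),
    hehplus = list(el = c("He", "H"), xyz = A(0, 0, 0, 0, 0, 0.772), charge = 1L),
    water = list(el = c("O", "H", "H"),
                 xyz = A(0, 0, 0.1173, 0, 0.7572, -0.4692, 0, -0.7572, -0.4692),
                 charge = 0L),
    water_dimer = list(
      el = c("O", "H", "H", "O", "H", "H"),
      xyz = A(-1.551007, -0.114520, 0.0,
              -1.934259,  0.762503, 0.0,
              -0.599677,  0.040712, 0.0,
               1.350625,  0.111469, 0.0,
               1.680398, -0.373741, -0.758561,
               1.680398, -0.373741,  0.758561),
      charge = 0L),
    `h5o2+` = list(
      el = c("O", "O", "H", "H", "H", "H", "H"),
      xyz = A(-1.197, 0, 0,
               1.197, 0, 0,
               0.000, 0, 0,
              -1.560,  0.790,  0.450,
              -1.560, -0.790, -0.450,
               1.560,  0.790, -0.450,
               1.560, -0.790,  0.450),
      charge = 1L),
    `h9o4+` = .eigen_cation(),
    gc_pair_toy = list(
      # doubly hydrogen-bonded carboxylic dimer: a desk-scale stand-in for a
      # base pair with two transferable protons (synthetic geometry)
      el = c("C", "O", "O", "H", "H", "C", "O", "O", "H", "H"),
      xyz = A(-1.950,  0.113, 0,
              -1.265,  1.152, 0,
              -1.416, -1.093, 0,
              -0.447, -1.068, 0,
              -3.035,  0.139, 0,
               1.950, -0.113, 0,
               1.265, -1.152, 0,
               1.416,  1.093, 0,
               0.447,  1.068, 0,
               3.035, -0.139, 0),
      charge = 0L),
    {
      m <- regmatches(name, regexec("^chain([0-9]+)$", name))[[1]]
      if (length(m) == 2) .hf_chain(as.integer(m[2])) else
        stop("unknown fixture '", name, "'")
    }
  )
}

# hydrogen-bonded (HF)_n zigzag chain; the scalable monomer-chain fixture
.hf_chain <- function(n) {
  stopifnot(n >= 1)
  el <- character(0)
  xyz <- NULL
  for (i in seq_len(n) - 1L) {
    fx <- c(i * 2.30, (i %% 2) * 0.85, 0)
    nxt <- c((i + 1) * 2.30, ((i + 1) %% 2) * 0.85, 0)
    u <- (nxt - fx) / sqrt(sum((nxt - fx)^2))
    hx <- fx + 0.93 * u
    el <- c(el, "F", "H")
    xyz <- rbind(xyz, fx, hx)
  }
  list(el = el, xyz = xyz, charge = 0L)
}

# Eigen cation H9O4+: pyramidal hydronium core, three water ligands
.eigen_cation <- function() {
  el <- c("O", "H", "H", "H")
  oh <- 1.00; oo <- 2.55
  core_h <- t(vapply(0:2, function(k) {
    th <- 2 * pi * k / 3
    c(oh * cos(th) * sin(1.9), oh * sin(th) * sin(1.9), oh * cos(1.9))
  }, numeric(3)))
  xyz <- rbind(c(0, 0, 0), core_h)
  for (k in 1:3) {
    u <- core_h[k, ] / sqrt(sum(core_h[k, ]^2))
    ow <- u * oo
    # two water hydrogens, roughly tetrahedral about the acceptor O
    v1 <- c(-u[2], u[1], 0); v1 <- v1 / sqrt(sum(v1^2))
    v2 <- c(u[2] * v1[3] - u[3] * v1[2], u[3] * v1[1] - u[1] * v1[3],
            u[1] * v1[2] - u[2] * v1[1])
    h1 <- ow + 0.96 * (0.50 * u + 0.76 * v1)
    h2 <- ow + 0.96 * (0.50 * u - 0.38 * v1 + 0.66 * v2)
    el <- c(el, "O", "H", "H")
    xyz <- rbind(xyz, ow, h1, h2)
  }
  list(el = el, xyz = xyz, charge = 1L)
}

#' Deterministic fixture geometries
#'
#' Built-in small systems used by tests and examples: `h2`, `hehplus`,
#' `water`, `water_dimer`, `h5o2+` (Zundel cation), `h9o4+` (Eigen cation),
#' `gc_pair_toy` (doubly hydrogen-bonded dimer with two transferable
#' protons) and `chainN` (hydrogen-bonded (HF)_N monomer chain, e.g.
#' `"chain6"`).  With `seed != 0` a deterministic random perturbation of at
#' most 0.01 bohr per coordinate is applied.
#'
#' @param name fixture identifier.
#' @param seed integer; 0 = unperturbed.
#' @param quantum quantum selector applied to the fixture (default "none").
#' @export
generate_fixture <- function(name, seed = 0L, quantum = "none") {
  fx <- .fixture_coords(name)
  coords <- fx$xyz * BOHR_PER_ANGSTROM
  if (seed != 0) {
    rs <- .Random.seed_protect()
    on.exit(rs(), add = TRUE)
    set.seed(as.integer(seed))
    coords <- coords + matrix(stats::runif(length(coords), -0.01, 0.01),
                              nrow = nrow(coords))
  }
  neo_system(fx$el, coords, charge = fx$charge, quantum = quantum)
}

# save/restore the global RNG state so fixture perturbation does not disturb
# user-level reproducibility
.Random.seed_protect <- function() {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  function() {
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }
}

# classical point-charge table seen by a given particle class: the quantum
# nuclei are removed from the classical list (they interact through their
# densities instead)
classical_charges <- function(system) {
  idx <- system$classical
  list(q = system$z[idx], pos = system$coords[idx, , drop = FALSE], idx = idx)
}

# Coulomb repulsion among classical nuclei only
classical_repulsion <- function(system) {
  cc <- classical_charges(system)
  n <- length(cc$q)
  if (n < 2) return(0)
  e <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    e <- e + cc$q[i] * cc$q[j] / sqrt(sum((cc$pos[i, ] - cc$pos[j, ])^2))
  }
  e
}
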