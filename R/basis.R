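# Gaussian basis sets: shell blocks, even-tempered generation, the
# Gaussian94 text-format reader, and the bundled/synthetic basis library.
#
# A shell block is a contracted set of primitives sharing one centre and one
# angular momentum.  Coefficients stored here are the "raw" published ones
# (per-primitive-normalised convention); the integral engine folds primitive
# and contraction normalisation in at evaluation time so that every AO has
# unit self-overlap.

#' Create a contracted Gaussian shell block
#'
#' @param l integer angular momentum (0 = s ... 3 = f).
#' @param center numeric length-3 position in bohr.
#' @param exps primitive exponents in bohr^-2 (sorted descending internally).
#' @param coefs contraction coefficients (normalised-primitive convention).
#' @param pure use real solid-harmonic components for l >= 2 (default TRUE).
#' @return an object of class `shell_block`.
#' @export
shell_block <- function(l, center, exps, coefs, pure = TRUE) {
  stopifnot(length(l) == 1, l >= 0, l <= 4, length(center) == 3)
  if (length(exps) != length(coefs) || length(exps) == 0) {
    stop("exponents and coefficients must be non-empty and of equal length")
  }
  if (any(exps <= 0)) stop("shell exponents must be strictly positive")
  o <- order(exps, decreasing = TRUE)
  exps <- exps[o]
  coefs <- coefs[o]
  if (any(diff(exps) == 0)) stop("duplicate exponents within a shell")
  structure(
    list(l = as.integer(l), center = as.numeric(center),
         exps = as.numeric(exps), coefs = as.numeric(coefs),
         pure = isTRUE(pure) || l < 2),
    class = "shell_block"
  )
}

#' @export
print.shell_block <- function(x, ...) {
  cat(sprintf("<shell l=%d (%s) nprim=%d at [%.3f %.3f %.3f] bohr>\n",
              x$l, if (x$pure) "pure" else "cart", length(x$exps),
              x$center[1], x$center[2], x$center[3]))
  invisible(x)
}

shell_nfun <- function(sh) if (sh$pure) 2L * sh$l + 1L else (sh$l + 1L) * (sh$l + 2L) / 2L

basis_nfun <- function(shells) sum(vapply(shells, shell_nfun, integer(1)))

#' Even-tempered shell ladder
#'
#' Emits, for each angular momentum 0..`l_max`, `n_per_l` single-primitive
#' shells with exponents `alpha_max / ratio^k`, k = 0..n_per_l-1 -- a strictly
#' decreasing geometric sequence.
#'
#' @param center position in bohr.
#' @param n_per_l number of exponents per angular momentum (>= 1).
#' @param l_max highest angular momentum (0..3).
#' @param alpha_max largest exponent in bohr^-2 (> 0).
#' @param ratio geometric ratio (> 1).
#' @param pure solid-harmonic components for l >= 2.
#' @return list of `shell_block`s.
#' @export
build_even_tempered <- function(center, n_per_l, l_max, alpha_max, ratio,
                                pure = TRUE) {
  if (n_per_l < 1) stop("n_per_l must be >= 1")
  if (ratio <= 1) stop("even-tempered ratio must exceed 1 (degenerate ladder)")
  if (alpha_max <= 0) stop("alpha_max must be positive")
  shells <- list()
  for (l in 0:l_max) {
    for (k in seq_len(n_per_l) - 1L) {
      shells[[length(shells) + 1L]] <-
        shell_block(l, center, alpha_max / ratio^k, 1.0, pure = pure)
    }
  }
  shells
}

# ------------------------------------------------------------------ G94 I/O

#' Read a basis set in Gaussian94 text format
#'
#' Parses the plain-text "Gaussian94" dialect used by basis-set repositories:
#' blocks separated by `****`, each starting with `<Element> 0`, followed by
#' shell headers `<L> <nprim> <scale>` and primitive lines.  `SP` shells are
#' split into an S and a P block.
#'
#' @param path file path.
#' @return named list: element symbol -> list of shell templates
#'   (`l`, `exps`, `coefs`; no centre).
#' @export
read_basis_g94 <- function(path) {
  if (!file.exists(path)) stop("basis file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("!.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  lmap <- c(S = 0L, P = 1L, D = 2L, F = 3L)
  out <- list()
  i <- 1L
  nline <- length(lines)
  skip_seps <- function(i) { while (i <= nline && grepl("^\\*\\*\\*\\*", lines[i])) i <- i + 1L; i }
  i <- skip_seps(i)
  while (i <= nline) {
    hdr <- strsplit(lines[i], "\\s+")[[1]]
    elem <- hdr[1]
    if (is.na(.element_z[elem])) stop("line ", i, ": unknown element '", elem, "'")
    i <- i + 1L
    shells <- list()
    while (i <= nline && !grepl("^\\*\\*\\*\\*", lines[i])) {
      sh <- strsplit(lines[i], "\\s+")[[1]]
      ang <- toupper(sh[1])
      nprim <- suppressWarnings(as.integer(sh[2]))
      if (is.na(nprim)) stop("line ", i, ": malformed shell header '", lines[i], "'")
      scale <- if (length(sh) >= 3) as.numeric(sh[3]) else 1.0
      prim <- matrix(NA_real_, nprim, if (ang == "SP") 3L else 2L)
      for (k in seq_len(nprim)) {
        v <- suppressWarnings(as.numeric(
          strsplit(gsub("[dD]([+-])", "e\\1", lines[i + k]), "\\s+")[[1]]))
        if (length(v) != ncol(prim) || any(is.na(v))) {
          stop("line ", i + k, ": malformed primitive line '", lines[i + k], "'")
        }
        prim[k, ] <- v
      }
      ex <- prim[, 1] * scale^2
      if (ang == "SP") {
        shells[[length(shells) + 1L]] <- list(l = 0L, exps = ex, coefs = prim[, 2])
        shells[[length(shells) + 1L]] <- list(l = 1L, exps = ex, coefs = prim[, 3])
      } else {
        if (is.na(lmap[ang])) stop("line ", i, ": unsupported shell type '", ang, "'")
        shells[[length(shells) + 1L]] <- list(l = lmap[[ang]], exps = ex, coefs = prim[, 2])
      }
      i <- i + nprim + 1L
    }
    out[[elem]] <- shells
    i <- skip_seps(i)
  }
  out
}

# ------------------------------------------------- bundled / synthetic sets

# split-valence + polarisation synthetic set ("sv-synth").  Values are of
# def2-SVP quality but are a package-internal synthetic set, not a copy of a
# published basis.
.sv_synth <- function() {
  list(
    H = list(
      list(l = 0L, exps = c(13.0107, 1.96226, 0.444538),
           coefs = c(0.0196855, 0.1379770, 0.4783193)),
      list(l = 0L, exps = 0.121950, coefs = 1),
      list(l = 1L, exps = 0.8, coefs = 1)
    ),
    He = list(
      list(l = 0L, exps = c(38.3549, 5.76890, 1.23994),
           coefs = c(0.0238100, 0.1549100, 0.4699800)),
      list(l = 0L, exps = 0.297578, coefs = 1),
      list(l = 1L, exps = 1.0, coefs = 1)
    ),
    C = list(
      list(l = 0L, exps = c(1238.40, 186.290, 42.2511, 11.6768, 3.59305),
           coefs = c(0.005457, 0.040638, 0.180256, 0.463151, 0.440872)),
      list(l = 0L, exps = 0.402451, coefs = 1),
      list(l = 0L, exps = 0.130902, coefs = 1),
      list(l = 1L, exps = c(9.46809, 2.01033, 0.547855),
           coefs = c(0.038388, 0.211170, 0.513282)),
      list(l = 1L, exps = 0.152686, coefs = 1),
      list(l = 2L, exps = 0.8, coefs = 1)
    ),
    N = list(
      list(l = 0L, exps = c(1712.84, 257.648, 58.4583, 16.1984, 5.00526),
           coefs = c(0.005393, 0.040222, 0.179311, 0.463763, 0.441714)),
      list(l = 0L, exps = 0.587186, coefs = 1),
      list(l = 0L, exps = 0.187642, coefs = 1),
      list(l = 1L, exps = c(13.5715, 2.92573, 0.799277),
           coefs = c(0.040072, 0.218070, 0.512944)),
      list(l = 1L, exps = 0.219543, coefs = 1),
      list(l = 2L, exps = 1.0, coefs = 1)
    ),
    O = list(
      list(l = 0L, exps = c(2266.18, 340.870, 77.3631, 21.4796, 6.65894),
           coefs = c(0.005343, 0.039890, 0.178539, 0.464277, 0.443097)),
      list(l = 0L, exps = 0.809760, coefs = 1),
      list(l = 0L, exps = 0.255308, coefs = 1),
      list(l = 1L, exps = c(17.7215, 3.86355, 1.04809),
           coefs = c(0.043394, 0.230941, 0.513753)),
      list(l = 1L, exps = 0.276415, coefs = 1),
      list(l = 2L, exps = 1.2, coefs = 1)
    ),
    F = list(
      list(l = 0L, exps = c(2894.83, 435.419, 98.8433, 27.4852, 8.54043),
           coefs = c(0.005341, 0.039990, 0.179165, 0.467447, 0.446465)),
      list(l = 0L, exps = 1.03954, coefs = 1),
      list(l = 0L, exps = 0.332247, coefs = 1),
      list(l = 1L, exps = c(22.6966, 4.98723, 1.34916),
           coefs = c(0.044879, 0.235718, 0.508521)),
      list(l = 1L, exps = 0.348299, coefs = 1),
      list(l = 2L, exps = 1.4, coefs = 1)
    )
  )
}

# triple-zeta-quality synthetic set: sv-synth plus one outer s and p shell
# (ratio 2.75 below the most diffuse existing shell) and, for H, a 2nd p and
# a d polarisation shell
.tz_synth <- function() {
  base <- .sv_synth()
  for (el in names(base)) {
    sh <- base[[el]]
    smin <- min(unlist(lapply(sh, function(s) if (s$l == 0L) min(s$exps))))
    pmin <- min(unlist(lapply(sh, function(s) if (s$l == 1L) min(s$exps))))
    sh[[length(sh) + 1L]] <- list(l = 0L, exps = smin / 2.75, coefs = 1)
    sh[[length(sh) + 1L]] <- list(l = 1L, exps = pmin / 2.75, coefs = 1)
    if (el %in% c("H", "He")) {
      sh[[length(sh) + 1L]] <- list(l = 2L, exps = 1.0, coefs = 1)
    } else {
      dmin <- min(unlist(lapply(sh, function(s) if (s$l == 2L) min(s$exps))))
      sh[[length(sh) + 1L]] <- list(l = 2L, exps = dmin * 3.0, coefs = 1)
    }
    base[[el]] <- sh
  }
  base
}

# JK-fitting synthetic sets: even-tempered ladders sized per angular
# momentum from the orbital product space they must span (an AutoAux-style
# rule).  A fitting function of momentum L serves AO pair products with
# |la - lb| <= L <= la + lb; its exponent ladder covers the range of product
# exponents (alpha_a + alpha_b) of those pairs.  The quality knob is the
# geometric ratio `beta`.
.jkfit_synth <- function(ao_template, beta, lmax_cap = 4L, n_cap = 25L) {
  out <- list()
  for (el in names(ao_template)) {
    sh <- ao_template[[el]]
    ls <- vapply(sh, function(s) as.integer(s$l), integer(1))
    lmax <- min(2L * max(ls), lmax_cap)
    tmpl <- list()
    for (L in 0:lmax) {
      sums <- c()
      for (i in seq_along(sh)) for (j in seq_along(sh)) {
        la <- ls[i]; lb <- ls[j]
        if (L > la + lb || L < abs(la - lb)) next
        sums <- c(sums, outer(sh[[i]]$exps, sh[[j]]$exps, "+"))
      }
      if (length(sums) == 0) next
      ahi <- max(sums); alo <- min(sums)
      n <- min(n_cap, ceiling(log(ahi / alo) / log(beta)) + 1L)
      for (k in seq_len(n) - 1L) {
        tmpl[[length(tmpl) + 1L]] <- list(l = L, exps = ahi / beta^k, coefs = 1)
      }
    }
    out[[el]] <- tmpl
  }
  out
}

#' Retrieve a basis-set template by name or file
#'
#' Bundled plain-text sets: `"sto-3g"` (minimal; also the intrinsic-atomic-
#' orbital reference under the alias `"minao"`) and `"6-31g"` (split
#' valence).  Synthetic in-code sets: `"sv-synth"` (split-valence +
#' polarisation quality), `"tz-synth"` (triple-zeta quality), and the JK
#' fitting ladders `"tz-synth-jkfit"` / `"qz-synth-jkfit"`.  Any other value
#' is treated as a path to a Gaussian94 file.
#'
#' @param name basis name or file path.
#' @return named list of per-element shell templates.
#' @export
get_basis_template <- function(name) {
  lname <- tolower(name)
  if (lname %in% c("sto-3g", "minao")) {
    return(read_basis_g94(system.file("extdata/basis/sto-3g.g94", package = "neoscf")))
  }
  if (lname == "6-31g") {
    return(read_basis_g94(system.file("extdata/basis/6-31g.g94", package = "neoscf")))
  }
  if (lname == "sv-synth") return(.sv_synth())
  if (lname == "tz-synth") return(.tz_synth())
  if (lname == "tz-synth-jkfit") return(.jkfit_synth(.tz_synth(), beta = 2.2))
  if (lname == "qz-synth-jkfit") return(.jkfit_synth(.tz_synth(), beta = 1.7))
  read_basis_g94(name)
}

#' Instantiate a basis on a set of centres
#'
#' @param system a `neo_system`.
#' @param template basis name/path (see [get_basis_template()]) or a template
#'   list as returned by it.
#' @param atoms integer atom indices to place shells on (default all).
#' @param pure solid-harmonic components for l >= 2.
#' @return an `ao_basis`: list with `shells`, per-shell `atom` index,
#'   per-function `ao_atom` index and `nao`.
#' @export
make_basis <- function(system, template, atoms = seq_along(system$elements),
                       pure = TRUE) {
  if (is.character(template)) template <- get_basis_template(template)
  shells <- list()
  atom_of_shell <- integer(0)
  for (ia in atoms) {
    el <- system$elements[ia]
    tmpl <- template[[el]]
    if (is.null(tmpl)) stop("basis template has no entry for element ", el)
    for (t in tmpl) {
      shells[[length(shells) + 1L]] <-
        shell_block(t$l, system$coords[ia, ], t$exps, t$coefs, pure = pure)
      atom_of_shell <- c(atom_of_shell, ia)
    }
  }
  ao_atom <- rep(atom_of_shell, vapply(shells, shell_nfun, integer(1)))
  structure(list(shells = shells, atom = atom_of_shell, ao_atom = ao_atom,
                 nao = basis_nfun(shells)),
            class = "ao_basis")
}

#' @export
print.ao_basis <- function(x, ...) {
  cat(sprintf("<ao_basis: %d shells, %d functions on %d centres>\n",
              length(x$shells), x$nao, length(unique(x$atom))))
  invisible(x)
}

# even-tempered basis placed on one quantum nucleus; the package defaults
# (nuclear AO 8s8p8d alpha_max 32, nuclear fit 10s10p10d10f alpha_max 64,
# ratio 2) are set where these are called
nuclear_basis_even <- function(center, n_per_l = 8L, l_max = 2L,
                               alpha_max = 32, ratio = 2) {
  build_even_tempered(center, n_per_l, l_max, alpha_max, ratio)
}
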