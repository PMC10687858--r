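# The macro-iteration driver: reductions, oracle equivalence, energy
# assembly, physical properties of the quantum protons, and cube export.

test_that("zero quantum nuclei reduces to the plain SCF on the same path", {
  sys <- generate_fixture("water")
  res <- run_neo(sys, tiny_cfg(mode = "direct", e_basis = "sto-3g"))
  rhf <- rhf_water_sto3g()
  expect_equal(res$E_total,
               rhf$energy + neoscf:::classical_repulsion(sys),
               tolerance = 1e-10)
  expect_equal(res$components$coupling, 0)
  expect_equal(nrow(res$macro_trace), 1)
})

test_that("run_neo matches the brute-force alternating dense oracle", {
  pair <- neo_h2_oracle_pair()
  expect_equal(pair$neo$E_total, pair$oracle, tolerance = 1e-8)
})

test_that("energy assembly is linear in the coupling and self-consistent", {
  sys <- generate_fixture("water", quantum = "all-H")
  cfg <- tiny_cfg(mode = "df", e_basis = "sto-3g", keep_integrals = TRUE)
  res <- neo_water_df()
  # components re-add to the total
  comp <- res$components
  expect_equal(comp$electronic + sum(comp$nuclear) + comp$nuclear_pair +
                 comp$coupling + comp$classical,
               res$E_total, tolerance = 1e-12)
  # recomputation from the final densities reproduces the stored assembly
  G_e <- res$electronic$F - res$ints$e$h -
    neoscf:::electronic_coupling(res$Dn, res$ba, res$ints, res$config)
  asm <- assemble_energy(res$electronic$D, res$Dn, res$ints, res$ba,
                         res$config, G_e)
  expect_equal(asm$E_total, res$E_total, tolerance = 1e-9)
  # doubling the coupling moves the total by exactly the coupling term
  asm2 <- assemble_energy(res$electronic$D, res$Dn, res$ints, res$ba,
                          res$config, G_e, coupling_scale = 2)
  expect_equal(asm2$E_total - asm$E_total, asm$components$coupling,
               tolerance = 1e-12)
})

test_that("subsystem invariants hold at convergence", {
  res <- neo_water_df()
  sys <- generate_fixture("water", quantum = "all-H")
  # nuclear densities are normalised and idempotent
  for (key in names(res$Dn)) {
    Sn <- res$ints$n[[key]]$S
    expect_equal(sum(res$Dn[[key]] * Sn), 1, tolerance = 1e-8)
    DSD <- res$Dn[[key]] %*% Sn %*% res$Dn[[key]]
    expect_lt(max(abs(DSD - res$Dn[[key]])), 1e-6)
  }
  # electronic trace
  expect_equal(sum(res$electronic$D * res$ints$e$S), 10, tolerance = 1e-8)
  # macro energies settle monotonically in magnitude at the end
  dE <- stats::na.omit(res$macro_trace$dE)
  expect_lte(abs(dE[length(dE)]), res$config$macro_thresh)
})

test_that("quantum protons raise the energy and deuteration lowers the NQE", {
  sys <- generate_fixture("h2", quantum = "all-H")
  nq_h <- nqe_h2_runs()
  cfg <- nq_h$neo$config
  expect_gt(nq_h$delta, 0)
  nq_d <- nqe_delta(set_deuterium(sys), cfg)
  expect_gt(nq_d$delta, 0)
  expect_lt(nq_d$delta, nq_h$delta)
})

test_that("the composite correction is plain arithmetic with a sanity check", {
  expect_equal(nqe_correction(-100.0, -99.5, -100.0), -99.5)
  expect_equal(nqe_correction(-76.3, -75.9, -75.9), -76.3)
  expect_warning(nqe_correction(-100, -90, -100), "mismatched")
  # corrected barrier = uncorrected barrier + difference of NQE deltas
  E_X <- c(a = -100.00, b = -99.98)
  E_neo <- c(a = -99.10, b = -99.05)
  E_hf <- c(a = -99.15, b = -99.12)
  corr <- nqe_correction(E_X, E_neo, E_hf)
  barrier_raw <- E_X["b"] - E_X["a"]
  dd_nqe <- (E_neo["b"] - E_hf["b"]) - (E_neo["a"] - E_hf["a"])
  expect_equal(unname(corr["b"] - corr["a"]),
               unname(barrier_raw + dd_nqe), tolerance = 1e-12)
})

test_that("results are deterministic and invariant to atom relabelling", {
  sys <- generate_fixture("water", quantum = "all-H")
  cfg <- tiny_cfg(mode = "df", e_basis = "sto-3g")
  r1 <- cached("neo_water_sto3g_df2", run_neo(sys, cfg))
  r2 <- run_neo(sys, cfg)
  expect_equal(r1$E_total, r2$E_total, tolerance = 1e-12)
  # swap the two protons in the atom list
  perm <- c(1, 3, 2)
  sys2 <- neo_system(sys$elements[perm], sys$coords[perm, ], charge = 0,
                     quantum = "all-H")
  r3 <- run_neo(sys2, cfg)
  expect_equal(r3$E_total, r1$E_total, tolerance = 1e-9)
})

test_that("energies are translation invariant", {
  sys <- generate_fixture("water", quantum = "all-H")
  cfg <- tiny_cfg(mode = "df", e_basis = "sto-3g")
  r1 <- cached("neo_water_sto3g_df2", stop("populated above"))
  sys2 <- neo_system(sys$elements, sweep(sys$coords, 2, c(-1.1, 0.6, 2.3)),
                     charge = 0, quantum = "all-H")
  r2 <- run_neo(sys2, cfg)
  expect_equal(r2$E_total, r1$E_total, tolerance = 1e-8)
})

test_that("proton densities export as normalised cube files", {
  res <- neo_water_df()
  g <- proton_density_grid(res, res$system$quantum[1], spacing = 0.08,
                           margin = 2.4)
  expect_gte(g$integral, 0.99)
  expect_lte(g$integral, 1.01)
  f <- tempfile(fileext = ".cube")
  export_cube(res, res$system$quantum[1], f, spacing = 0.12, margin = 2)
  lines <- readLines(f)
  expect_match(lines[1], "proton density")
  expect_equal(as.integer(strsplit(trimws(lines[3]), "\\s+")[[1]][1]), 3)
  expect_gt(length(lines), 50)
  expect_error(export_cube(res, res$system$quantum[1],
                           file.path(tempdir(), "no/such/dir/x.cube")),
               "cube output")
})

test_that("a tight single-s proton density peaks at its basis centre", {
  sys <- neo_system(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 1.9)),
                    charge = 2L, quantum = 2L)
  cfg <- neo_config(mode = "direct", e_basis = "sto-3g",
                    n_basis = list(n_per_l = 1, l_max = 0, alpha_max = 12,
                                   ratio = 2))
  res <- run_neo(sys, cfg)
  g <- proton_density_grid(res, 2, spacing = 0.1, margin = 1.5)
  ax <- lapply(1:3, function(d) seq(g$origin[d], by = g$spacing,
                                    length.out = g$counts[d]))
  pts <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  peak <- pts[which.max(g$values), ]
  expect_lt(max(abs(peak - sys$coords[2, ])), g$spacing)
})

test_that("a shared proton is more delocalised than a covalent one", {
  cfg <- tiny_cfg(mode = "df", e_basis = "sto-3g")
  # central (shared) proton of the Zundel cation
  shared <- run_neo(generate_fixture("h5o2+", quantum = 3L), cfg)
  g_shared <- proton_density_grid(shared, 3, spacing = 0.08, margin = 2.4)
  covalent <- neo_water_df()
  g_cov <- proton_density_grid(covalent, covalent$system$quantum[1],
                               spacing = 0.08, margin = 2.4)
  expect_gt(g_shared$second_moment, g_cov$second_moment)
})

test_that("macro non-convergence raises an error carrying the trace", {
  sys <- generate_fixture("water", quantum = "all-H")
  cfg <- tiny_cfg(mode = "df", e_basis = "sto-3g", max_macro = 1)
  err <- tryCatch(run_neo(sys, cfg), error = function(e) e)
  expect_s3_class(err, "simpleError")
  expect_match(conditionMessage(err), "did not converge")
  expect_true(is.data.frame(err$trace))
})
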