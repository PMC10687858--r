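# Molecular systems, XYZ I/O, quantum-nucleus selection and fixtures.

test_that("XYZ files round-trip to 1e-6 Angstrom", {
  sys <- generate_fixture("water_dimer")
  f <- tempfile(fileext = ".xyz")
  write_xyz(sys, f)
  sys2 <- read_xyz(f)
  expect_equal(sys2$elements, sys$elements)
  expect_lt(max(abs(sys2$coords - sys$coords)) / BOHR_PER_ANGSTROM, 1e-6)
})

test_that("quantum selectors resolve and validate", {
  f <- tempfile(fileext = ".xyz")
  write_xyz(generate_fixture("h5o2+"), f)
  s0 <- read_xyz(f, charge = 1, quantum = "none")
  expect_length(s0$quantum, 0)
  expect_length(s0$classical, 7)
  sh <- read_xyz(f, charge = 1, quantum = "all-H")
  expect_length(sh$quantum, 5)
  expect_equal(sort(sh$elements[sh$quantum]), rep("H", 5))
  expect_equal(length(sh$classical), 2)
  # atom 1 is an oxygen: proton-only quantisation must refuse it
  expect_error(read_xyz(f, charge = 1, quantum = 1), "non-hydrogen")
  expect_error(read_xyz(f, charge = 1, quantum = 99), "out of range")
})

test_that("malformed XYZ input reports the offending line", {
  f <- tempfile(fileext = ".xyz")
  writeLines(c("2", "broken", "H 0 0 0", "H 0 0 bad"), f)
  expect_error(read_xyz(f), "line 4")
})

test_that("even-tempered ladders follow the geometric rule", {
  sh <- build_even_tempered(c(0, 0, 0), 3, 0, 8, 2)
  expect_equal(vapply(sh, function(s) s$exps, numeric(1)), c(8, 4, 2))
  sh2 <- build_even_tempered(c(0, 0, 0), 10, 3, 64, 2)
  expect_length(sh2, 40)
  expect_equal(sum(vapply(sh2, function(s) s$l, integer(1)) == 3), 10)
  expect_equal(max(unlist(lapply(sh2, function(s) s$exps))), 64)
  # strictly decreasing within each l and bit-identical on regeneration
  for (l in 0:3) {
    ex <- unlist(lapply(sh2[vapply(sh2, function(s) s$l, integer(1)) == l],
                        function(s) s$exps))
    expect_true(all(diff(ex) < 0))
  }
  expect_identical(sh2, build_even_tempered(c(0, 0, 0), 10, 3, 64, 2))
  expect_error(build_even_tempered(c(0, 0, 0), 3, 0, 8, 1), "ratio")
})

test_that("fixtures are deterministic with bounded perturbation", {
  a <- generate_fixture("h5o2+")
  expect_equal(length(a$elements), 7)
  expect_equal(a$charge, 1L)
  expect_equal(sum(a$elements == "H"), 5)
  expect_identical(generate_fixture("h2")$coords, generate_fixture("h2")$coords)
  p1 <- generate_fixture("h5o2+", seed = 1)
  p2 <- generate_fixture("h5o2+", seed = 2)
  expect_false(identical(p1$coords, p2$coords))
  expect_lte(max(abs(p1$coords - a$coords)), 0.01)
  expect_lte(max(abs(p2$coords - a$coords)), 0.01)
  expect_error(generate_fixture("nonesuch"), "unknown fixture")
  # chain fixtures scale
  ch <- generate_fixture("chain4")
  expect_equal(sum(ch$elements == "F"), 4)
})

test_that("contracted shells are normalised and parser reads bundled sets", {
  tmpl <- get_basis_template("sto-3g")
  expect_true(all(c("H", "C", "N", "O", "F") %in% names(tmpl)))
  sys <- generate_fixture("water")
  for (bn in c("sto-3g", "6-31g", "sv-synth")) {
    S <- one_particle(make_basis(sys, bn))$S
    expect_lt(max(abs(diag(S) - 1)), 1e-10)
  }
  # malformed basis file names the line
  f <- tempfile()
  writeLines(c("****", "H 0", "S 2 1.00", "  1.0 0.5", "  oops"), f)
  expect_error(read_basis_g94(f), "line 5")
})

test_that("deuterium switch changes only the masses", {
  sys <- generate_fixture("h2", quantum = "all-H")
  sysd <- set_deuterium(sys)
  expect_equal(unname(sysd$qmass), rep(DEUTERON_MASS, 2))
  expect_identical(sysd$coords, sys$coords)
  expect_error(set_deuterium(generate_fixture("water"), 2),
               "not a quantum nucleus")
})
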