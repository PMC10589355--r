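test_that("formula parsing handles Hill strings, multipliers and errors", {
  expect_equal(unclass(parse_formula("H")), c(H = 1L))
  f <- parse_formula("C27H23BrN2O5S")
  expect_equal(unclass(f),
               c(C = 27L, H = 23L, Br = 1L, N = 2L, O = 5L, S = 1L))
  expect_identical(render_formula(f), "C27H23BrN2O5S")
  # round trip on canonical strings
  for (s in c("C2H6O", "H2O", "C6H6", "BrClN2", "C27H23BrN2O5S"))
    expect_identical(render_formula(parse_formula(s)), s)
  expect_error(parse_formula("Xx9"), "unknown element")
  expect_error(parse_formula(""), "non-empty")
  expect_error(parse_formula("C0H4"), "multiplier")
  expect_error(parse_formula("C2 H6"), "characters")
})

test_that("monoisotopic mass matches hand-computed sums and is additive", {
  expect_equal(monoisotopic_mass("H2O"), 2 * 1.007825032 + 15.994914620,
               tolerance = 1e-9)
  expect_equal(round(monoisotopic_mass("H2O"), 4), 18.0106)
  # empty formula (obtained by subtraction) has zero mass
  empty <- formula_arith(parse_formula("H2O"), parse_formula("H2O"), "-")
  expect_length(empty, 0)
  expect_equal(monoisotopic_mass(empty), 0)
  # additivity over formula concatenation
  set.seed(42)
  els <- c("C", "H", "N", "O", "S", "Cl", "Br")
  for (k in 1:25) {
    a <- stats::setNames(sample(1:30, 3), sample(els, 3))
    b <- stats::setNames(sample(1:30, 3), sample(els, 3))
    expect_equal(monoisotopic_mass(formula_arith(a, b, "+")),
                 monoisotopic_mass(dualscreen:::as_formula(a)) +
                   monoisotopic_mass(dualscreen:::as_formula(b)),
                 tolerance = 1e-9)
  }
  # adducts are explicit, never implicit
  expect_equal(monoisotopic_mass("H2O", adduct = "M+H") -
                 monoisotopic_mass("H2O"), 1.007276467, tolerance = 1e-9)
  expect_error(monoisotopic_mass(c(Uue = 1L)), "no isotope mass")
})

test_that("property calculation gives expected descriptor values", {
  skip_if_not_installed("ChemmineOB")
  benzene <- molecule_from_smiles("c1ccccc1", "benzene")
  expect_equal(compute_properties(benzene)$tpsa, 0)
  ethanol <- molecule_from_smiles("CCO", "ethanol")
  pe <- compute_properties(ethanol)
  expect_equal(pe$hbd, 1)
  expect_equal(pe$hba, 1)
  water <- molecule_from_smiles("O", "water")
  expect_equal(compute_properties(water)$mw, 18.02, tolerance = 0.001)
})

test_that("properties are invariant to atom reordering", {
  # ethanol written with two different atom orders
  m1 <- molecule("etoh", data.frame(element = c("C", "C", "O")),
                 data.frame(i = c(1, 2), j = c(2, 3), order = c(1, 1)))
  m2 <- molecule("etoh", data.frame(element = c("O", "C", "C")),
                 data.frame(i = c(1, 2), j = c(2, 3), order = c(1, 1)))
  expect_identical(render_formula(molecular_formula(m1)),
                   render_formula(molecular_formula(m2)))
  skip_if_not_installed("ChemmineOB")
  p1 <- compute_properties(m1); p2 <- compute_properties(m2)
  expect_equal(p1[, -1], p2[, -1], tolerance = 1e-9)
})

test_that("implicit hydrogen completion follows valence and charge", {
  m <- molecule("mix", data.frame(element = c("C", "N", "O", "S", "Cl")),
                data.frame(i = c(1, 1, 1), j = c(2, 3, 4),
                           order = c(1, 2, 1)))
  # C: 4 - 4 bonds = 0H; N: single bond -> 2H; O: double bond -> 0H;
  # S: single bond -> 1H; isolated Cl -> 1H equivalent (treated as HCl)
  expect_equal(m$atoms$hcount, c(0L, 2L, 0L, 1L, 1L))
  anion <- molecule("acetate", data.frame(element = c("C", "C", "O", "O"),
                                          charge = c(0L, 0L, 0L, -1L)),
                    data.frame(i = c(1, 2, 2), j = c(2, 3, 4),
                               order = c(1, 2, 1)))
  expect_equal(anion$atoms$hcount, c(3L, 0L, 0L, 0L))
})

test_that("SDF writer and reader round-trip molecules including charges", {
  anion <- molecule("acetate", data.frame(element = c("C", "C", "O", "O"),
                                          charge = c(0L, 0L, 0L, -1L),
                                          x = c(0, 1.5, 2.1, 2.1),
                                          y = c(0, 0, 1.1, -1.1),
                                          z = c(0, 0, 0, 0)),
                    data.frame(i = c(1L, 2L, 2L), j = c(2L, 3L, 4L),
                               order = c(1L, 2L, 1L)))
  path <- withr::local_tempfile(fileext = ".sdf")
  write_sdf(anion, path)
  back <- read_sdf(path)[[1]]
  expect_identical(back$id, "acetate")
  expect_identical(back$atoms$element, anion$atoms$element)
  expect_identical(back$atoms$charge, anion$atoms$charge)
  expect_identical(back$atoms$hcount, anion$atoms$hcount)
  expect_equal(back$atoms$x, anion$atoms$x, tolerance = 1e-4)
  expect_identical(back$bonds$order, anion$bonds$order)
  expect_error(read_sdf(character(0)), "empty")
})

test_that("amide enumeration conserves formula mass balance", {
  skip_if_not_installed("ChemmineOB")
  acid <- ref_ligand("G1-PABA")
  nucs <- list(ref_ligand("4-methylbenzenesulfonamide"),
               ref_ligand("4-chlorobenzenesulfonamide"))
  prods <- enumerate_amide_products(acid, nucs)
  expect_length(prods, 2)
  expect_identical(render_formula(molecular_formula(prods[[1]])),
                   "C27H23BrN2O5S")
  expect_identical(render_formula(molecular_formula(prods[[2]])),
                   "C26H20BrClN2O5S")
  # product formula = acid + nucleophile - H2O, exactly
  h2o <- parse_formula("H2O")
  for (k in 1:2) {
    lhs <- molecular_formula(prods[[k]])
    rhs <- formula_arith(formula_arith(molecular_formula(acid),
                                       molecular_formula(nucs[[k]]), "+"),
                         h2o, "-")
    expect_identical(render_formula(lhs), render_formula(rhs))
  }
  # also holds for simple aliphatic partners
  acetic <- molecule_from_smiles("CC(=O)O", "acetic")
  benzyl <- molecule_from_smiles("NCc1ccccc1", "benzylamine")
  p <- enumerate_amide_products(acetic, benzyl)[[1]]
  expect_identical(render_formula(molecular_formula(p)), "C9H11NO")
})

test_that("amide enumeration validates reactive groups", {
  skip_if_not_installed("ChemmineOB")
  benzene <- molecule_from_smiles("c1ccccc1", "benzene")
  amine <- molecule_from_smiles("CN", "methylamine")
  expect_error(enumerate_amide_products(benzene, amine),
               "no carboxylic-acid group")
  acetic <- molecule_from_smiles("CC(=O)O", "acetic")
  ether <- molecule_from_smiles("COC", "ether")
  expect_warning(out <- enumerate_amide_products(acetic, ether),
                 "no reactive N-H")
  expect_length(out, 0)
})
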