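# Formula/SMILES parsing, standardization, exclusion and the
# constitutional descriptors.

test_that("formula parser expands literal formulas, groups and charges", {
  cases <- list(
    list("C8H9NO2", c(C = 8, H = 9, N = 1, O = 2), 0L),
    list("Ca(OH)2", c(Ca = 1, O = 2, H = 2), 0L),
    list("C24H27NO5S", c(C = 24, H = 27, N = 1, O = 5, S = 1), 0L),
    list("Fe2(SO4)3", c(Fe = 2, S = 3, O = 12), 0L),
    list("CH3COO-", c(C = 2, H = 3, O = 2), -1L),
    list("NH4+", c(N = 1, H = 4), 1L),
    list("SO4-2", c(S = 1, O = 4), -2L),
    list("Fe+3", c(Fe = 1), 3L)
  )
  for (cs in cases) {
    got <- parse_formula(cs[[1]])
    want <- composition(cs[[2]], cs[[3]])
    expect_true(got == want, label = cs[[1]])
  }
})

test_that("formula parser fails loudly on bad input", {
  expect_error(parse_formula(""), "empty")
  expect_error(parse_formula("C8Xx2"), "Xx")
  expect_error(parse_formula("Ca(OH"), "parenthesis")
  expect_error(parse_formula("C)O("), "parenthesis|unexpected")
})

test_that("descriptors match the independently computed 20-formula fixture", {
  fix <- read.csv(extdata("formula_oracle.csv"))
  for (i in seq_len(nrow(fix))) {
    cmp <- parse_formula(fix$formula[i])
    expect_equal(molecular_weight(cmp), fix$mw[i], tolerance = 1e-9,
                 label = fix$formula[i])
    expect_equal(amw(cmp), fix$amw[i], tolerance = 1e-9,
                 label = fix$formula[i])
    expect_equal(h_percent(cmp), fix$h_percent[i], tolerance = 1e-9,
                 label = fix$formula[i])
  }
})

test_that("descriptor spot values and error contracts hold", {
  expect_equal(molecular_weight(parse_formula("H2O")), 18.015,
               tolerance = 0.001)
  expect_equal(amw(parse_formula("CH4")), 3.209, tolerance = 0.001)
  expect_gt(amw(parse_formula("C8H9NO2")), 7.4)   # acetaminophen flagged
  expect_equal(amw(composition(c(H = 2))), atomic_masses()[["H"]])
  expect_equal(h_percent(parse_formula("C6H6")), 50)
  expect_equal(h_percent(parse_formula("C2F6")), 0)
  expect_error(molecular_weight(parse_formula("CH4"),
                                masses = c(H = 1.008)), "C")
  expect_error(composition(numeric(0)), "at least one")
})

test_that("SMILES parser resolves implicit hydrogens by default valence", {
  cases <- c(
    "CC(=O)Nc1ccc(O)cc1" = "C8H9NO2",     # acetaminophen (hand count)
    "C" = "CH4",
    "c1ccccc1" = "C6H6",
    "c1ccc2ccccc2c1" = "C10H8",           # fused aromatics
    "Cn1cnc2c1c(=O)n(C)c(=O)n2C" = "C8H10N4O2",  # N-methylated aromatics
    "Fc1c[nH]c(=O)[nH]c1=O" = "C4H3FN2O2",
    "CS(=O)(=O)O" = "CH4O3S",             # hypervalent S
    "OP(=O)(O)O" = "H3O4P",               # hypervalent P
    "N#Cc1ccccc1" = "C7H5N",
    "C1CC1" = "C3H6",
    "c1ccsc1" = "C4H4S",
    "C/C=C/C" = "C4H8"                    # stereo bonds read as single/double
  )
  for (smi in names(cases)) {
    expect_identical(hill_formula(graph_composition(parse_smiles(smi))),
                     unname(cases[smi]), label = smi)
  }
})

test_that("SMILES bracket atoms carry explicit charge and hydrogen", {
  g <- parse_smiles("[Na+].[O-]C(=O)C")
  comps <- split_components(g)
  expect_length(comps, 2L)
  charges <- vapply(comps, function(x) graph_composition(x)$charge, 0L)
  expect_setequal(charges, c(1L, -1L))
  expect_identical(hill_formula(graph_composition(parse_smiles("[13CH4]"))),
                   "CH4")   # isotope label parsed, mass table per element
  expect_equal(graph_composition(parse_smiles("[NH4+]"))$counts[["H"]], 4)
})

test_that("SMILES parser rejects malformed or unsupported input", {
  expect_error(parse_smiles("C1CC"), "ring")
  expect_error(parse_smiles("C(C"), "\\(")
  expect_error(parse_smiles("C*C"), "unsupported")
  expect_error(parse_smiles("NaCl"), "unsupported")  # Na needs brackets
  expect_error(parse_smiles("C=:C"), "bond")
  expect_error(parse_smiles(""), "non-empty")
})

test_that("standardization desalts, neutralizes and is idempotent", {
  # hydrochloride removal
  std <- standardize_structure("CNC1CCC(c2ccc(Cl)c(Cl)c2)c2ccccc21.Cl")
  expect_identical(hill_formula(graph_composition(std$graph)), "C17H17Cl2N")
  expect_match(std$log, "counterion", all = FALSE)
  # sodium carboxylate -> carboxylic acid
  std <- standardize_structure("[O-]C(=O)C.[Na+]")
  expect_identical(hill_formula(graph_composition(std$graph)), "C2H4O2")
  expect_equal(graph_composition(std$graph)$charge, 0L)
  # single neutral component unchanged, empty log
  std <- standardize_structure("CC(=O)Nc1ccc(O)cc1")
  expect_identical(hill_formula(graph_composition(std$graph)), "C8H9NO2")
  expect_length(std$log, 0L)
  # protonated amine neutralized
  std <- standardize_structure("C[NH3+].[Cl-]")
  expect_identical(hill_formula(graph_composition(std$graph)), "CH5N")
  # idempotence over assorted inputs
  for (smi in c("CC(=O)Nc1ccc(O)cc1", "[O-]C(=O)C.[Na+]",
                "C[NH3+].[Cl-]", "CCCC(CCC)C(=O)[O-].[Na+]")) {
    once <- standardize_structure(smi)
    twice <- standardize_structure(once$graph)
    expect_identical(hill_formula(graph_composition(twice$graph)),
                     hill_formula(graph_composition(once$graph)),
                     label = smi)
    expect_length(twice$log, 0L)
  }
})

test_that("standardization keeps the largest non-salt component and errors
          when nothing remains", {
  std <- standardize_structure("CCO.c1ccccc1O")
  expect_identical(hill_formula(graph_composition(std$graph)), "C6H6O")
  expect_match(std$log, "kept largest", all = FALSE)
  expect_error(standardize_structure("[Na+].[Cl-]"), "no parent structure")
})

test_that("exclusion rules follow the metal/annotation contract", {
  pt <- parse_smiles("N.N.Cl[Pt]Cl")
  res <- exclusion_check(pt)
  expect_true(res$excluded)
  expect_match(res$reason, "metal")
  ok <- exclusion_check(parse_smiles("CC(=O)Nc1ccc(O)cc1"))
  expect_false(ok$excluded)
  expect_true(exclusion_check(NULL, peptide = TRUE)$excluded)
  expect_match(exclusion_check(NULL, nucleic_acid = TRUE)$reason, "nucleic")
})

test_that("AMW is intensive and responds to atom mass as expected", {
  m <- atomic_masses()
  base <- c(C = 8, H = 9, N = 1, O = 2)
  a0 <- amw(composition(base))
  # permutation invariance
  expect_equal(amw(composition(base[c(3, 1, 4, 2)])), a0)
  # intensivity: k-fold multiplication leaves AMW unchanged
  for (k in c(2, 5)) expect_equal(amw(composition(base * k)), a0)
  # adding H (lighter than current AMW) strictly decreases
  plus_h <- base; plus_h["H"] <- plus_h["H"] + 1
  expect_lt(amw(composition(plus_h)), a0)
  heavier <- base; heavier["Cl"] <- 1
  expect_gt(amw(composition(heavier)), a0)
  # H% partition
  set.seed(4)
  for (i in 1:20) {
    cnt <- c(C = sample(1:10, 1), H = sample(0:20, 1), O = sample(0:5, 1))
    cnt <- cnt[cnt > 0]
    if (!length(cnt)) next
    cmp <- composition(cnt)
    non_h <- 100 * sum(cmp$counts[names(cmp$counts) != "H"]) / n_atoms(cmp)
    expect_equal(h_percent(cmp) + non_h, 100)
  }
})

test_that("SMILES-derived AMW equals formula-derived AMW exactly", {
  smis <- c("CC(=O)Nc1ccc(O)cc1", "CC(=O)Oc1ccccc1C(=O)O",
            "Cn1cnc2c1c(=O)n(C)c(=O)n2C", "FC(F)(F)C(Cl)Br",
            "CS(=O)(=O)O", "c1ccc2ccccc2c1")
  for (smi in smis) {
    cmp_g <- graph_composition(parse_smiles(smi))
    cmp_f <- parse_formula(hill_formula(cmp_g))
    expect_identical(amw(cmp_g), amw(cmp_f), label = smi)
  }
})

test_that("descriptor pipeline runs end to end on the example table", {
  df <- read_drug_table(extdata("example_drugs.csv"))
  desc <- compute_descriptors(df)
  expect_equal(desc$AMW[desc$id == "D001"], 7.55825, tolerance = 1e-6)
  expect_true(desc$excluded[desc$id == "D008"])   # platinum complex
  expect_match(desc$exclusion_reason[desc$id == "D009"], "peptide")
  # formula-only record computed without structure standardization
  expect_false(desc$excluded[desc$id == "D009"] == FALSE)
  audit <- attr(desc, "audit")
  expect_length(audit, nrow(df))
  expect_match(audit[df$id == "D007"], "counterion")
  # labels derive deterministically from class
  expect_identical(df$dili_label, as.integer(df$dili_class %in% c("Most", "Less")))
})
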