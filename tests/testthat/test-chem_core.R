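test_that("SDF reading: ethane fixture gives HAC 2 and intact topology", {
  f <- withr::local_tempfile(fileext = ".sdf")
  writeLines(ethane_sdf_text, f)
  mols <- read_sdf(f)
  expect_length(mols, 1)
  m <- mols[[1]]
  expect_equal(nrow(m$atoms), 8)
  expect_equal(hac(m), 2)
  expect_equal(nrow(m$bonds), 7)
  expect_equal(m$name, "ethane")
})

test_that("SDF write/read round-trips atoms, bonds, charges and properties", {
  lig <- scaffold_template()
  lig$properties <- list(pIC50 = "5.11", LogP = "-0.78")
  f1 <- withr::local_tempfile(fileext = ".sdf")
  f2 <- withr::local_tempfile(fileext = ".sdf")
  write_sdf(lig, f1)
  back <- read_sdf(f1)[[1]]
  write_sdf(back, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(coords(back), coords(lig), tolerance = 1e-4)
  expect_identical(back$atoms$formal_charge, lig$atoms$formal_charge)
  expect_identical(back$properties$pIC50, "5.11")
  expect_identical(back$bonds$order, lig$bonds$order)
})

test_that("SDF conformers group by repeated molecule name", {
  lig <- scaffold_template("mol1")
  f <- withr::local_tempfile(fileext = ".sdf")
  write_sdf(list(lig, lig, lig), f)
  grp <- group_conformers(read_sdf(f))
  expect_length(grp, 1)
  expect_length(grp$mol1, 3)
})

test_that("malformed SDF counts line errors with the record index", {
  f <- withr::local_tempfile(fileext = ".sdf")
  writeLines(c("bad", "", "", "not a counts line", "M  END", "$$$$"), f)
  expect_error(read_sdf(f), "record 1.*counts")
})

test_that("PDB single model: residues, labels, attached ligand", {
  tp <- toy_pocket()
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(tp$protein, f, ligand = tp$ligand)
  p <- read_pdb(f)
  expect_s3_class(p, "ProteinStructure")
  expect_setequal(residue_ids(p), residue_ids(tp$protein))
  expect_false(is.null(attr(p, "ligand")))
  expect_equal(hac(attr(p, "ligand")), hac(tp$ligand))
})

test_that("residue 252 PHE renders as F252", {
  at <- data.frame(record = "ATOM", atom_name = "CA", resname = "PHE",
                   chain = "A", resno = 252L, icode = "", x = 0, y = 0, z = 0,
                   element = "C")
  expect_equal(residue_ids(protein_structure(at)), "F252")
})

test_that("multi-model PDB yields frames timed at the 2 ps default", {
  tp <- toy_pocket()
  frames <- replicate(10, trajectory_frame(0, tp$protein, tp$ligand),
                      simplify = FALSE)
  f <- withr::local_tempfile(fileext = ".pdb")
  # strip the REMARK TIME annotation to exercise the default
  write_pdb(frames, f)
  raw <- readLines(f)
  writeLines(raw[!startsWith(raw, "REMARK")], f)
  fr <- read_pdb(f)
  expect_length(fr, 10)
  expect_equal(vapply(fr, `[[`, 0, "time"), seq(0, 18, by = 2))
  expect_s3_class(fr[[4]]$protein, "ProteinStructure")
})

test_that("model JSON round-trips and validates", {
  m <- pocket_model()
  f <- withr::local_tempfile(fileext = ".json")
  write_model_json(m, f)
  back <- read_model_json(f)
  expect_equal(length(back$features), length(m$features))
  expect_equal(feature_positions(back), feature_positions(m))
  expect_equal(feature_kinds(back), feature_kinds(m))
  expect_equal(back$exclusion_volumes$radius, m$exclusion_volumes$radius)
  expect_identical(lapply(back$features, `[[`, "ligand_atoms"),
                   lapply(m$features, `[[`, "ligand_atoms"))
})

test_that("model JSON rejects unknown keys and bad kinds; empty models error", {
  f <- withr::local_tempfile(fileext = ".json")
  writeLines('{"name":"x","features":[],"bogus":1}', f)
  expect_error(read_model_json(f), "unknown key")
  writeLines(paste0('{"name":"x","features":[{"kind":"ZZ",',
                    '"position":[0,0,0],"radius":1,"ligand_atoms":[1]}]}'), f)
  expect_error(read_model_json(f), "unknown feature kind")
  expect_error(phore_model("x", list()), "at least one feature")
  expect_error(phore_feature("HBD", c(0, 0, 0), radius = 1,
                             ligand_atoms = integer()), "non-empty")
  expect_error(phore_feature("HBD", c(0, 0, 0), direction = c(1, 1, 0),
                             ligand_atoms = 1), "unit-norm")
})

test_that("HAC equals the non-hydrogen atom count on random molecules", {
  withr::local_seed(42)
  for (i in 1:25) {
    nh <- sample(1:12, 1); nH <- sample(0:10, 1)
    expect_identical(hac(random_molecule(nh, nH)), nh)
  }
})

test_that("hydrophobic typing follows the element/neighbour rule", {
  # chlorobenzene-ish: aromatic C6 + Cl, all hydrophobic; add an O to one
  # carbon and that carbon turns polar
  ang <- seq(30, 330, 60) * pi / 180
  at <- data.frame(element = c(rep("C", 6), "Cl", "O"),
                   x = c(1.4 * cos(ang), 2.8, -2.8),
                   y = c(1.4 * sin(ang), 0, 0), z = 0)
  bonds <- data.frame(a1 = c(1:6, 1, 4), a2 = c(2:6, 1, 7, 8),
                      order = c(rep(4L, 6), 1L, 1L))
  mol <- molecule("m", at, bonds)
  hyd <- hydrophobic_atoms(mol)
  expect_true(all(hyd[c(1:3, 5:7)]))
  expect_false(hyd[4])      # carbon bonded to O
  expect_false(hyd[8])      # O itself
})

test_that("atom roles: donors, acceptors, halogen carriers", {
  tmpl <- scaffold_template()
  roles <- atom_roles(tmpl)
  expect_true(roles$donor[11])            # protonated amine (no explicit H)
  expect_false(roles$acceptor[11])
  expect_true(all(roles$acceptor[13:14])) # carboxylate oxygens
  expect_false(any(roles$halogen))
  # explicit hydrogens switch the donor rule to H-based
  eth <- local({
    f <- withr::local_tempfile(fileext = ".sdf")
    writeLines(ethane_sdf_text, f)
    read_sdf(f)[[1]]
  })
  expect_false(any(atom_roles(eth)$donor))
})

test_that("scaffold_map validation", {
  tmpl <- scaffold_template()
  expect_error(ligand_pose("l", "p", tmpl, c(1, 1, 2)), "duplicate")
  expect_error(ligand_pose("l", "p", tmpl, c(1, 99)), "out of range")
  expect_s3_class(ligand_pose("l", "p", tmpl, 1:14), "LigandPose")
})
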