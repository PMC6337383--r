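test_that("hydrogen-bond geometry rule", {
  # D...A = 2.8, angle 165 deg -> bond
  D <- c(0, 0, 0); A <- c(2.8, 0, 0)
  H <- c(1.0, -0.13, 0)                      # D-H...A approximately 165 deg
  r <- detect_hbond(D, A, H)
  expect_true(r$hbond); expect_gt(r$angle, 160)
  # distance beyond 3.5 fails regardless of angle
  expect_false(detect_hbond(D, c(3.6, 0, 0))$hbond)
  # 3.0 A but bent (100 deg) fails
  H2 <- c(0.17, 0.98, 0)                     # angle D-H2-A about 100 deg
  r2 <- detect_hbond(D, c(3.0, 0, 0), H2)
  expect_false(r2$hbond); expect_lt(r2$angle, 120)
  # distance-only rule when no hydrogen is given
  expect_true(detect_hbond(D, c(3.0, 0, 0))$hbond)
})

test_that("halogen-bond geometry rule, including a meta-Cl backbone contact", {
  C <- c(-1.7, 0, 0); X <- c(0, 0, 0)
  expect_true(detect_halogen_bond(C, X, c(3.2, 0.3, 0))$xbond)   # ~175 deg
  bent <- c(3.2 * cos(pi / 3), 3.2 * sin(pi / 3), 0)             # 120 deg
  expect_false(detect_halogen_bond(C, X, bent)$xbond)
  # aryl chlorine contacting a backbone carbonyl oxygen at 3.1 A / 168 deg
  ang <- (180 - 168) * pi / 180
  O <- c(3.1 * cos(ang), 3.1 * sin(ang), 0)
  r <- detect_halogen_bond(C, X, O)
  expect_true(r$xbond)
  expect_equal(r$distance, 3.1)
  expect_equal(r$angle, 168, tolerance = 1e-6)
})

test_that("residues_near applies the 5 A inclusion rule", {
  mk_res <- function(resno, x) data.frame(
    record = "ATOM", atom_name = "CA", resname = "GLY", chain = "A",
    resno = resno, icode = "", x = x, y = 0, z = 0, element = "C")
  prot <- protein_structure(do.call(rbind, list(
    mk_res(1, 4.9), mk_res(2, 5.1), mk_res(3, 2.0), mk_res(4, 4.99),
    mk_res(5, 30))))
  lig <- molecule("l", data.frame(element = "C", x = 0, y = 0, z = 0))
  expect_setequal(residues_near(lig, prot), c("G1", "G3", "G4"))
})

test_that("SIFt: full involvement, absent residues, planted 75 percent", {
  tp <- toy_pocket()
  pose <- ligand_pose("lig", "p1", tp$ligand, 1:14)
  prof <- sift_profile(list(pose), tp$protein)
  expect_s3_class(prof, "InteractionProfile")
  expect_true(all(prof$any_contact >= 0 & prof$any_contact <= 100))
  expect_equal(prof$hbond[prof$residue == "G101"], 100)
  expect_false("E136" %in% prof$residue)   # remote pair never within 5 A
  # planted fraction: shift the ligand out of the pocket in 25 of 100 poses
  far <- tp$ligand
  far$atoms[, c("x", "y", "z")] <- far$atoms[, c("x", "y", "z")] + 50
  poses <- c(replicate(75, pose, simplify = FALSE),
             replicate(25, ligand_pose("lig", "pf", far, 1:14),
                       simplify = FALSE))
  prof2 <- sift_profile(poses, tp$protein)
  expect_equal(prof2$hbond[prof2$residue == "G101"], 75)
  expect_equal(attr(prof2, "n_observations"), 100)
  expect_error(sift_profile(list(), tp$protein), "empty")
})

test_that("single-pose SIFt equals single-frame DIFt", {
  tp <- toy_pocket()
  prof_s <- sift_profile(list(ligand_pose("l", "p", tp$ligand, 1:14)),
                         tp$protein)
  prof_d <- dift_profile(list(tp$frame))
  ord <- function(p) p[order(p$residue), ]
  expect_equal(ord(as.data.frame(prof_s)), ord(as.data.frame(prof_d)),
               ignore_attr = TRUE)
})

test_that("DIFt recovers planted toggle occupancy within 3 sigma", {
  n <- 1500; p <- 0.8
  tr <- gen_trajectory(toy_pocket(), n_frames = n,
                       toggle_probs = c(HBA1 = p), seed = 33)
  prof <- dift_profile(tr$frames)
  got <- prof$hbond[prof$residue == "G104"]
  sigma <- 100 * sqrt(p * (1 - p) / n)
  expect_lt(abs(got - 100 * mean(tr$truth[, "HBA1"])), 1e-9)  # exact vs truth
  expect_lt(abs(got - 100 * p), 3 * sigma)                    # planted prob
})

test_that("hydrophobic channel is empty for an all-polar ligand", {
  tp <- toy_pocket()
  lig <- molecule("polar", data.frame(element = c("O", "O"),
                                      x = c(0, 1.3), y = 0, z = 0),
                  data.frame(a1 = 1, a2 = 2, order = 1L))
  prof <- sift_profile(list(ligand_pose("l", "p", lig, 1:2)), tp$protein)
  expect_true(all(prof$hydrophobic == 0))
})

test_that("pair_hbond_occupancy: trivial and planted probabilities", {
  tp <- toy_pocket()
  expect_equal(pair_hbond_occupancy(list(tp$frame), "N258", "E136"), 100)
  expect_equal(pair_hbond_occupancy(list(tp$frame), "N258", "G101"), 0)
  expect_error(pair_hbond_occupancy(list(tp$frame), "Z999", "E136"),
               "unknown residue")
  n <- 1500; p <- 0.92
  tr <- gen_trajectory(tp, n_frames = n, toggle_probs = c(pair = p),
                       seed = 44)
  occ <- pair_hbond_occupancy(tr$frames, "N258", "E136")
  expect_equal(occ, 100 * mean(tr$truth[, "pair"]))
  expect_lt(abs(occ - 100 * p), 3 * 100 * sqrt(p * (1 - p) / n))
})

test_that("Coulomb and Lennard-Jones closed forms", {
  mk <- function(x, el = "C") {
    lig <- molecule("l", data.frame(element = el, x = 0, y = 0, z = 0))
    prot <- protein_structure(data.frame(
      record = "ATOM", atom_name = "CA", resname = "GLY", chain = "A",
      resno = 1L, icode = "", x = x, y = 0, z = 0, element = el))
    list(lig = lig, prot = prot)
  }
  par1 <- function(q1, q2, sig = 0, eps = 0) list(
    ligand = data.frame(charge = q1, sigma = sig, epsilon = eps),
    protein = data.frame(charge = q2, sigma = sig, epsilon = eps))
  # +1/-1 at r = 3.320636 A -> exactly -100 kcal/mol
  s <- mk(3.320636)
  e <- residue_energies(s$lig, s$prot, par1(1, -1), center = c(0, 0, 0))
  expect_equal(e$electrostatic, -100)
  expect_equal(e$total, e$electrostatic + e$vdw)
  # LJ: zero at r = sigma; -eps at the 2^(1/6) sigma minimum
  s2 <- mk(3.4)
  e2 <- residue_energies(s2$lig, s2$prot, par1(0, 0, sig = 3.4, eps = 0.25),
                         center = c(0, 0, 0))
  expect_equal(e2$vdw, 0, tolerance = 1e-12)
  s3 <- mk(2^(1 / 6) * 3.4)
  e3 <- residue_energies(s3$lig, s3$prot, par1(0, 0, sig = 3.4, eps = 0.25),
                         center = c(0, 0, 0))
  expect_equal(e3$vdw, -0.25)
})

test_that("energy decomposition conserves the restricted pairwise sum", {
  tp <- toy_pocket()
  np <- nrow(tp$protein$atoms); nl <- nrow(tp$ligand$atoms)
  withr::local_seed(9)
  params <- list(
    ligand = data.frame(charge = runif(nl, -0.5, 0.5),
                        sigma = runif(nl, 3, 3.6), epsilon = runif(nl, 0.1, 0.3)),
    protein = data.frame(charge = runif(np, -0.5, 0.5),
                         sigma = runif(np, 3, 3.6), epsilon = runif(np, 0.1, 0.3)))
  ctr <- colMeans(coords(tp$ligand))
  dec <- residue_energies(tp$ligand, tp$protein, params, center = ctr,
                          radius = 12)
  # independent total: direct double sum over ligand x included-residue atoms
  keys <- residue_key(tp$protein)
  inc <- keys %in% dec$residue
  P <- protein_coords(tp$protein)[inc, , drop = FALSE]
  L <- coords(tp$ligand)
  R <- dynophoreR:::cross_dist(L, P)
  qq <- outer(params$ligand$charge, params$protein$charge[inc])
  elec <- 332.0636 * sum(qq / R)
  sij <- outer(params$ligand$sigma, params$protein$sigma[inc], function(a, b) (a + b) / 2)
  eij <- sqrt(outer(params$ligand$epsilon, params$protein$epsilon[inc]))
  vdw <- sum(4 * eij * ((sij / R)^12 - (sij / R)^6))
  expect_equal(sum(dec$electrostatic), elec, tolerance = 1e-9)
  expect_equal(sum(dec$vdw), vdw, tolerance = 1e-9)
  expect_equal(dec$total, dec$electrostatic + dec$vdw, tolerance = 1e-9)
  # 12 A inclusion is center-based: remote pair residues excluded
  expect_false("E136" %in% dec$residue)
  expect_error(residue_energies(tp$ligand, tp$protein,
                                list(ligand = params$ligand[1:3, ],
                                     protein = params$protein),
                                center = ctr), "one row per ligand atom")
})
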