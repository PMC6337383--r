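test_that("kabsch: identity, planted rotation recovery, chirality, errors", {
  withr::local_seed(3)
  P <- matrix(rnorm(15), 5, 3)
  k0 <- kabsch(P, P)
  expect_equal(k0$rmsd, 0, tolerance = 1e-12)
  expect_equal(k0$rotation, diag(3), tolerance = 1e-9)
  # 90 degrees about z plus translation
  R90 <- rotation_matrix(c(0, 0, 1), pi / 2)
  Q <- P %*% t(R90) + matrix(c(1, -2, 3), 5, 3, byrow = TRUE)
  k <- kabsch(P, Q)
  expect_equal(k$rmsd, 0, tolerance = 1e-9)
  expect_equal(k$rotation, R90, tolerance = 1e-9)
  expect_equal(det(k$rotation), 1, tolerance = 1e-9)
  # a chiral (non-planar) point set cannot be superposed on its mirror image
  # by any proper rotation; planar sets can, so a tetrahedron is used
  tet <- rbind(c(0, 0, 0), c(2, 0, 0), c(0.5, 1.7, 0), c(0.7, 0.6, 1.5))
  mir <- tet %*% diag(c(-1, 1, 1))
  expect_gt(kabsch(tet, mir)$rmsd, 0.1)
  tri <- tet[1:3, ]
  # collinear sets are degenerate
  line <- cbind(0:3, 0, 0)
  expect_error(kabsch(line, line), "collinear")
  expect_error(kabsch(tri[1:2, ], tri[1:2, ]), "at least 3")
})

test_that("fit_score formula and monotonicity in matched count", {
  expect_equal(fit_score(6, 0, 1.5), 69)
  expect_equal(fit_score(5, 0, 1.5), 59)
  expect_gte(fit_score(6, 10, 1.5), 60)       # geometric term clamps at 0
  expect_equal(fit_score(4, 2, 1.5), 40)      # rmsd >= mean radius
  expect_lt(fit_score(5, 0, 1.5), fit_score(6, 1.49, 1.5))
})

test_that("self-match: a perceived model retrieves its source ligand", {
  tp <- toy_pocket(); m <- pocket_model()
  res <- match_conformer(tp$ligand, m, max_omit = 1)
  expect_equal(res$n_matched, length(m$features))
  expect_length(res$omitted, 0)
  expect_equal(res$feature_rmsd, 0, tolerance = 1e-9)
  expect_true(res$passed_exclusion)
  # same after an arbitrary rigid motion of the conformer
  lig2 <- tp$ligand
  R <- rotation_matrix(c(2, 1, -1), 2.1)
  lig2$atoms[, c("x", "y", "z")] <-
    coords(tp$ligand) %*% t(R) + matrix(c(-8, 5, 11), 14, 3, byrow = TRUE)
  res2 <- match_conformer(lig2, m)
  expect_equal(res2$n_matched, length(m$features))
  expect_equal(res2$feature_rmsd, 0, tolerance = 1e-6)
})

test_that("n-1 matching and the too-few-features rejection", {
  tp <- toy_pocket(); m <- pocket_model()    # 5 features
  # remove the carboxylate oxygen generating one HBA -> 4 of 5 ligand-side
  # features survive, matched with one omission
  lig <- tp$ligand
  lig$atoms$element[14] <- "C"               # acceptor turns into carbon
  res <- match_conformer(lig, m, max_omit = 1)
  expect_equal(res$n_matched, 4)
  expect_length(res$omitted, 1)
  # with max_omit = 0 the same conformer is no hit
  expect_null(match_conformer(lig, m, max_omit = 0))
  # degrade a second polar feature -> 3 of 5 < n - 1, no hit
  lig2 <- lig
  lig2$atoms$element[13] <- "C"
  lig2$atoms$formal_charge[13] <- 0L
  expect_null(match_conformer(lig2, m, max_omit = 1))
})

test_that("exclusion volumes: boundary behaviour and anti-monotonicity", {
  m <- pocket_model()
  expect_true(check_exclusion(matrix(c(0, 0, 0), 1), phore_model(
    "x", m$features, data.frame(x = 1.1, y = 0, z = 0, radius = 1))))
  expect_false(check_exclusion(matrix(c(0, 0, 0), 1), phore_model(
    "x", m$features, data.frame(x = 0.9, y = 0, z = 0, radius = 1))))
  # adding a sphere on top of the planted ligand kills its own hit
  tp <- toy_pocket()
  hit0 <- match_conformer(tp$ligand, m)
  expect_false(is.null(hit0))
  blocked <- m
  blocked$exclusion_volumes <- rbind(
    m$exclusion_volumes,
    data.frame(x = coords(tp$ligand)[1, 1], y = coords(tp$ligand)[1, 2],
               z = coords(tp$ligand)[1, 3], radius = 1))
  expect_null(match_conformer(tp$ligand, blocked))
})

test_that("relaxing max_omit never shrinks the hit list", {
  tp <- toy_pocket(); m <- pocket_model()
  lig_degraded <- tp$ligand
  lig_degraded$atoms$element[14] <- "C"
  lib <- list(tp$ligand, lig_degraded)
  lib[[2]]$name <- "degraded"
  h0 <- screen_library(lib, m, max_omit = 0)
  h1 <- screen_library(lib, m, max_omit = 1)
  expect_true(all(h0$molecule_id %in% h1$molecule_id))
  expect_gt(nrow(h1), nrow(h0))
})

test_that("planted 1-in-101 retrieval with zero false positives", {
  tp <- toy_pocket(); m <- pocket_model()
  lib <- c(gen_decoy_library(100, seed = 13), list(tp$ligand))
  hits <- screen_library(lib, m, max_omit = 1)
  expect_equal(hits$molecule_id, "planted")
  expect_equal(hits$n_matched, 5)
  # all-decoy library: empty hit list
  hits0 <- screen_library(gen_decoy_library(30, seed = 14), m)
  expect_equal(nrow(hits0), 0)
  expect_error(screen_library(list(), m), "empty")
})

test_that("screening is invariant under rigid motion of model or library", {
  tp <- toy_pocket(); m <- pocket_model()
  lib <- c(gen_decoy_library(10, seed = 15), list(tp$ligand))
  base <- screen_library(lib, m)
  R <- rotation_matrix(c(0.3, 1, 2), 0.77); tvec <- c(12, -7, 3)
  m_mov <- transform_model(m, R, tvec)
  moved_lib <- lapply(lib, function(mol) {
    mol$atoms[, c("x", "y", "z")] <-
      coords(mol) %*% t(R) + matrix(tvec, nrow(mol$atoms), 3, byrow = TRUE)
    mol
  })
  a <- screen_library(lib, m_mov)
  b <- screen_library(moved_lib, m)
  for (h in list(a, b)) {
    expect_equal(h$molecule_id, base$molecule_id)
    expect_equal(h$n_matched, base$n_matched)
    expect_equal(h$fit_score, base$fit_score, tolerance = 1e-6)
  }
})

test_that("match_conformer agrees with unpruned exhaustive enumeration", {
  # oracle: enumerate every injective kind-compatible correspondence without
  # distance pruning, align, apply the same acceptance and scoring
  oracle_match <- function(mol, model, max_omit = 1, rules = perception_rules()) {
    cf <- ligand_features(mol, rules)
    atoms <- coords(mol)[mol$atoms$element != "H", , drop = FALSE]
    n <- length(model$features)
    mkinds <- feature_kinds(model); mpos <- feature_positions(model)
    mrad <- feature_radii(model)
    ckinds <- vapply(cf, `[[`, "", "kind")
    cpos <- do.call(rbind, lapply(cf, `[[`, "position"))
    best <- NULL
    for (k in seq.int(n, max(1, n - max_omit))) {
      for (msel in utils::combn(n, k, simplify = FALSE)) {
        for (asg in dynophoreR:::enumerate_assignments(
          msel, mpos, mrad, mkinds, cpos, ckinds, prune = FALSE)) {
          al <- dynophoreR:::align_points(cpos[asg, , drop = FALSE],
                                          mpos[msel, , drop = FALSE])
          moved <- cpos[asg, , drop = FALSE] %*% t(al$rotation) +
            matrix(al$translation, k, 3, byrow = TRUE)
          dev <- sqrt(rowSums((moved - mpos[msel, , drop = FALSE])^2))
          if (any(dev > mrad[msel])) next
          alat <- atoms %*% t(al$rotation) +
            matrix(al$translation, nrow(atoms), 3, byrow = TRUE)
          if (!check_exclusion(alat, model)) next
          sc <- fit_score(k, sqrt(mean(dev^2)), mean(mrad[msel]))
          if (is.null(best) || sc > best$fit_score)
            best <- list(n_matched = k, fit_score = sc)
        }
      }
    }
    best
  }
  tp <- toy_pocket(); m <- pocket_model()
  cases <- list(tp$ligand)
  lig_d <- tp$ligand; lig_d$atoms$element[14] <- "C"
  cases <- c(cases, list(lig_d), gen_decoy_library(5, seed = 31)[1:5])
  small_model <- phore_model("small", m$features[1:4], m$exclusion_volumes)
  for (mol in cases) for (mod in list(m, small_model)) {
    got <- match_conformer(mol, mod, max_omit = 1)
    want <- oracle_match(mol, mod, max_omit = 1)
    if (is.null(want)) expect_null(got) else {
      expect_equal(got$n_matched, want$n_matched)
      expect_equal(got$fit_score, want$fit_score, tolerance = 1e-9)
    }
  }
})

test_that("cha_screen ranks by model-hit count then mean fit", {
  tp <- toy_pocket(); m <- pocket_model()
  m_sub <- phore_model("sub", m$features[c(1, 2, 4)], m$exclusion_volumes)
  lig_full <- tp$ligand
  lig_deg <- tp$ligand; lig_deg$atoms$element[14] <- "C"
  lig_deg$name <- "partial"
  ranked <- cha_screen(list(lig_full, lig_deg), list(m, m_sub), max_omit = 0)
  expect_equal(ranked$molecule_id[1], "planted")
  expect_equal(ranked$n_models_hit[ranked$molecule_id == "planted"], 2)
  # molecule hitting no model is excluded
  dec <- gen_decoy_library(1, seed = 9)[[1]]
  ranked2 <- cha_screen(list(lig_full, dec), list(m, m_sub))
  expect_false(dec$name %in% ranked2$molecule_id)
  expect_error(cha_screen(list(lig_full), list(m)), "at least 2")
})
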