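test_that("perception on the planted pocket emits the designed feature set", {
  m <- pocket_model()
  sigs <- model_signatures(m)
  expect_setequal(sigs, c("HBD:11", "HBA:13", "HBA:14",
                          "H:1,2,3,4,5,6,7,9,10", "AR:1,2,3,4,5,6"))
  hbd <- m$features[[which(sigs == "HBD:11")]]
  expect_setequal(hbd$partner_residues, c("G101", "G102", "G103"))
  expect_equal(vnorm(hbd$direction), 1, tolerance = 1e-9)
  h <- m$features[[which(startsWith(sigs, "H:"))]]
  expect_equal(h$partner_residues, "I106")
  expect_gt(nrow(m$exclusion_volumes), 0)
  expect_true(all(m$exclusion_volumes$radius == 1.0))
})

test_that("feature partners are never exclusion spheres", {
  tp <- toy_pocket()
  m <- pocket_model()
  # every exclusion sphere center is a protein heavy atom, and none of the
  # H-bond partner oxygens/nitrogens appears among them
  P <- protein_coords(tp$protein)
  keys <- residue_key(tp$protein)
  partner_res <- unique(unlist(lapply(m$features, `[[`, "partner_residues")))
  partner_oxy <- P[keys %in% c("G101", "G102", "G103") &
                     tp$protein$atoms$atom_name == "O", , drop = FALSE]
  ev <- as.matrix(m$exclusion_volumes[, c("x", "y", "z")])
  expect_gt(min(dynophoreR:::cross_dist(ev, partner_oxy)), 0.5)
})

test_that("isolated ligand perceives no features and errors", {
  tp <- toy_pocket()
  lig <- tp$ligand
  lig$atoms[, c("x", "y", "z")] <- lig$atoms[, c("x", "y", "z")] + 40
  fr <- trajectory_frame(0, tp$protein, lig)
  expect_error(perceive_features(fr), "no perceivable")
  expect_null(perceive_frames(list(fr))[[1]])
})

test_that("occupancy profile: trivial percentages and major/minor split", {
  m <- pocket_model()
  prof <- occupancy_profile(list(m, m, m))
  expect_true(all(prof$percent == 100))
  expect_true(all(prof$class == "major"))
  # drop one feature from one frame
  m2 <- m; m2$features <- m$features[-1]
  prof2 <- occupancy_profile(c(replicate(4, m2, simplify = FALSE), list(m)),
                             major_threshold = 70)
  dropped <- feature_signature(m$features[[1]])
  expect_equal(prof2$percent[prof2$signature == dropped], 20)
  expect_equal(prof2$class[prof2$signature == dropped], "minor")
  expect_equal(attr(prof2, "n_frames"), 5)
})

test_that("occupancy is order-independent and exact against planted truth", {
  tr <- gen_trajectory(toy_pocket(), n_frames = 400,
                       toggle_probs = c(HBD = 0.9, HBA1 = 0.5, H = 0.75),
                       seed = 5)
  models <- perceive_frames(tr$frames)
  prof <- occupancy_profile(models)
  get <- function(sig) prof$percent[prof$signature == sig]
  expect_equal(get("HBD:11"), 100 * mean(tr$truth[, "HBD"]))
  expect_equal(get("HBA:13"), 100 * mean(tr$truth[, "HBA1"]))
  expect_equal(get("H:1,2,3,4,5,6,7,9,10"), 100 * mean(tr$truth[, "H"]))
  withr::local_seed(1)
  shuffled <- occupancy_profile(sample(models))
  expect_equal(shuffled[order(shuffled$signature), ],
               prof[order(prof$signature), ], ignore_attr = TRUE)
})

test_that("evs_stats: constant, alternating and empty cases", {
  m <- pocket_model()
  mk_ev <- function(n) {
    mm <- m
    mm$exclusion_volumes <- data.frame(x = as.numeric(seq_len(n)),
                                       y = rep(0, n), z = rep(0, n),
                                       radius = rep(1, n))
    mm
  }
  expect_equal(evs_stats(replicate(5, mk_ev(17), simplify = FALSE))$mean, 17)
  alt <- rep(list(mk_ev(10), mk_ev(20)), 3)
  s <- evs_stats(alt)
  expect_equal(s$mean, 15)
  expect_equal(s$per_frame, rep(c(10L, 20L), 3))
  expect_equal(evs_stats(list(mk_ev(0), mk_ev(0)))$mean, 0)
})

test_that("rdf_code: rigid invariance, localized peak, scale sensitivity", {
  m <- pocket_model()
  code <- rdf_code(m)
  expect_equal(length(code), 840)
  R <- rotation_matrix(c(1, -2, 0.5), 1.234)
  expect_equal(rdf_code(transform_model(m, R, c(7, -4, 2))), code,
               tolerance = 1e-12)
  # feature re-ordering leaves the code unchanged
  m_perm <- m; m_perm$features <- rev(m$features)
  expect_equal(rdf_code(m_perm), code)
  # two H features 5 A apart: a single block peaked at the 5 A bin
  two <- phore_model("two", list(
    phore_feature("H", c(0, 0, 0), ligand_atoms = 1),
    phore_feature("H", c(5, 0, 0), ligand_atoms = 2)))
  c2 <- rdf_code(two)
  blk <- matrix(c2, nrow = 21, byrow = TRUE)
  expect_equal(sum(rowSums(blk) > 0), 1)        # only the H|H block
  centers <- (1:40 - 0.5) * 0.5
  expect_equal(centers[which.max(blk[1, ])], 4.75)  # bin nearest 5 A
  # doubling coordinates changes the code
  doubled <- two
  doubled$features[[2]]$position <- c(10, 0, 0)
  expect_gt(max(abs(rdf_code(doubled) - c2)), 0.1)
  # single-feature model: zero vector with a warning
  single <- phore_model("one", list(phore_feature("H", c(0, 0, 0),
                                                  ligand_atoms = 1)))
  expect_warning(z <- rdf_code(single), "single feature")
  expect_equal(z, numeric(840))
})

test_that("cluster_models: identical models collapse; planted families split", {
  m <- pocket_model()
  same <- replicate(6, m, simplify = FALSE)
  mc <- cluster_models(same)
  expect_length(mc$clusters, 1)
  expect_equal(mc$rpm, 1L)              # lowest frame index on ties
  # two geometric families: original pocket model vs a stretched variant
  stretched <- m
  for (i in seq_along(stretched$features))
    stretched$features[[i]]$position <- 3 * stretched$features[[i]]$position
  models <- c(replicate(4, m, simplify = FALSE),
              replicate(3, stretched, simplify = FALSE))
  mc2 <- cluster_models(models)
  expect_length(mc2$clusters, 2)
  expect_setequal(mc2$clusters[[1]], 1:4)     # ordered by population
  expect_setequal(mc2$clusters[[2]], 5:7)
  # top clamp: asking for 10 of 2 returns 2
  expect_length(cluster_models(models, top = 10)$clusters, 2)
})

test_that("RPM medoids are optimal versus brute force on small clusters", {
  tr <- gen_trajectory(toy_pocket(), n_frames = 8, jitter_sd = 0.25,
                       toggle_probs = c(HBA2 = 0.5), seed = 21)
  models <- perceive_frames(tr$frames)
  models <- models[!vapply(models, is.null, TRUE)]
  mc <- cluster_models(models)
  D <- mc$distance
  for (k in seq_along(mc$clusters)) {
    mem <- mc$clusters[[k]]
    means <- if (length(mem) == 1) 0 else rowSums(D[mem, mem]) / (length(mem) - 1)
    expect_equal(min(means),
                 if (length(mem) == 1) 0 else
                   sum(D[mc$rpm[k], mem]) / (length(mem) - 1),
                 tolerance = 1e-12)
  }
})

test_that("distinct_rpms deduplicates by signature set", {
  m <- pocket_model()
  m2 <- m; m2$features <- m$features[-1]
  sets <- list(replicate(3, m, simplify = FALSE),
               c(replicate(2, m, simplify = FALSE), list(m2)))
  rpms <- distinct_rpms(sets)
  keys <- vapply(rpms, function(x) paste(sort(model_signatures(x)),
                                         collapse = ";"), "")
  expect_equal(anyDuplicated(keys), 0L)
})
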