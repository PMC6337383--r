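# Shared fixtures, built in code. The pocket and its perceived model are
# deterministic, so they are memoized per test run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env))
    assign(key, expr, envir = .fixture_env)
  get(key, envir = .fixture_env)
}

toy_pocket <- function() memo("pocket", gen_toy_pocket())

pocket_model <- function() memo("model", perceive_features(toy_pocket()$frame))

# ethane with explicit hydrogens (8 atoms, HAC 2)
ethane_sdf_text <- c(
  "ethane", "  fixture", "",
  "  8  7  0  0  0  0  0  0  0  0999 V2000",
  "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
  "    1.5400    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
  "   -0.4000    1.0000    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0",
  "   -0.4000   -0.5000    0.8700 H   0  0  0  0  0  0  0  0  0  0  0  0",
  "   -0.4000   -0.5000   -0.8700 H   0  0  0  0  0  0  0  0  0  0  0  0",
  "    1.9400    1.0000    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0",
  "    1.9400   -0.5000    0.8700 H   0  0  0  0  0  0  0  0  0  0  0  0",
  "    1.9400   -0.5000   -0.8700 H   0  0  0  0  0  0  0  0  0  0  0  0",
  "  1  2  1  0  0  0  0",
  "  1  3  1  0  0  0  0",
  "  1  4  1  0  0  0  0",
  "  1  5  1  0  0  0  0",
  "  2  6  1  0  0  0  0",
  "  2  7  1  0  0  0  0",
  "  2  8  1  0  0  0  0",
  "M  END",
  "$$$$")

# random small molecule for property tests: chain of heavy atoms + hydrogens
random_molecule <- function(n_heavy, n_h, name = "rnd") {
  el <- c(sample(c("C", "N", "O"), n_heavy, replace = TRUE),
          rep("H", n_h))
  n <- n_heavy + n_h
  xyz <- matrix(cumsum(rnorm(3 * n, sd = 0.8)), n, 3)
  bonds <- if (n > 1)
    data.frame(a1 = 1:(n - 1), a2 = 2:n, order = 1L) else NULL
  molecule(name, data.frame(element = el, x = xyz[, 1], y = xyz[, 2],
                            z = xyz[, 3]), bonds)
}

# bare poses from coordinate matrices (single-element scaffolds for
# clustering arithmetic tests)
pose_from_coords <- function(id, xyz, ligand_id = "L") {
  xyz <- matrix(xyz, ncol = 3)
  mol <- molecule(id, data.frame(element = "C", x = xyz[, 1], y = xyz[, 2],
                                 z = xyz[, 3]))
  ligand_pose(ligand_id, id, mol, seq_len(nrow(xyz)))
}

# random symmetric zero-diagonal distance matrix
random_dmat <- function(n, scale = 3) {
  pts <- matrix(runif(n * 2) * scale, n, 2)
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(as.character(1:n), as.character(1:n))
  d
}

# independent complete-linkage oracle: stats::hclust + cutree just below the
# cutoff (tie-free matrices make the strict-< semantics equivalent)
hclust_partition <- function(dmat, h) {
  hc <- stats::hclust(stats::as.dist(dmat), method = "complete")
  grp <- stats::cutree(hc, h = h - 1e-9)
  unname(split(seq_along(grp), grp))
}

same_partition <- function(a, b) {
  norm <- function(p) {
    p <- lapply(p, sort)
    p[order(vapply(p, min, 0L))]
  }
  identical(norm(a), norm(b))
}
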