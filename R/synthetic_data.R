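#' Seeded synthetic generators
#'
#' Deterministic stand-ins for the black-box engines upstream of the pipeline
#' (docking, MD, decoy generation). Each generator consumes an explicit seed,
#' restores the caller's RNG state, and emits a machine-readable truth table
#' alongside its artifact so planted structure can be asserted exactly.
#'
#' @name synthetic_data
NULL

#' Rigid 14-heavy-atom scaffold template
#'
#' A fused bicyclic (naphthalene-like) core carrying a protonated amine and a
#' carboxylate on the saturated ring: the heavy-atom skeleton of a
#' conformationally restricted amino-acid analog (HAC 14). One ring is
#' aromatic; atoms 11 (N+), 13/14 (carboxylate O) carry the polar head.
#'
#' @param name molecule name.
#' @return a `Molecule`.
#' @export
scaffold_template <- function(name = "scaffold") {
  ang <- (c(30, 90, 150, 210, 270, 330)) * pi / 180
  r1 <- cbind(1.4 * cos(ang), 1.4 * sin(ang), 0)
  cx <- 2 * 1.4 * cos(pi / 6)
  r2 <- cbind(cx + 1.4 * cos(ang), 1.4 * sin(ang), 0)
  # ring2 unique vertices: drop the two shared with ring1
  r2u <- r2[c(2, 1, 6, 5), , drop = FALSE]   # (cx,1.4), (cx+1.21,.7), (cx+1.21,-.7), (cx,-1.4)
  ca <- r2u[2, ]                               # quaternary carbon
  nN <- ca + 1.47 * unit(c(0.5, 0.6, 1.0))
  cC <- ca + 1.52 * unit(c(0.9, -0.4, -1.0))
  o1 <- cC + 1.25 * unit(c(1.0, -0.1, -0.6))
  o2 <- cC + 1.25 * unit(c(-0.2, -1.0, -0.6))
  xyz <- rbind(r1, r2u, nN, cC, o1, o2)
  atoms <- data.frame(element = c(rep("C", 10), "N", "C", "O", "O"),
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      formal_charge = c(rep(0L, 10), 1L, 0L, -1L, 0L),
                      aromatic = c(rep(TRUE, 6), rep(FALSE, 8)))
  bonds <- data.frame(
    a1    = c(1, 2, 3, 4, 5, 6, 1, 7, 8, 9, 10,  8,  8, 12, 12),
    a2    = c(2, 3, 4, 5, 6, 1, 7, 8, 9, 10, 6, 11, 12, 13, 14),
    order = c(4, 4, 4, 4, 4, 4, 1, 1, 1, 1,  1,  1,  1,  1,  2))
  molecule(name, atoms, bonds)
}

gly_chain <- function(resno, anchor, dir, head = c("O", "N"), chain = "A") {
  # minimal glycine backbone extended from `anchor` along `dir`;
  # head = "O": carbonyl O sits at `anchor` (H-bond acceptor toward ligand);
  # head = "N": amide N sits at `anchor` (donor toward ligand).
  head <- match.arg(head)
  d <- unit(dir)
  side <- orthogonal_to(d)
  if (head == "O") {
    o <- anchor
    c1 <- o + 1.23 * d
    ca <- c1 + 1.52 * unit(d + 0.6 * side)
    n <- ca + 1.47 * unit(d - 0.4 * side)
    nm <- c("O", "C", "CA", "N"); xyz <- rbind(o, c1, ca, n)
  } else {
    n <- anchor
    ca <- n + 1.47 * d
    c1 <- ca + 1.52 * unit(d + 0.6 * side)
    o <- c1 + 1.23 * unit(d - 0.4 * side)
    nm <- c("N", "CA", "C", "O"); xyz <- rbind(n, ca, c1, o)
  }
  data.frame(record = "ATOM", atom_name = nm, resname = "GLY", chain = chain,
             resno = resno, icode = "", x = xyz[, 1], y = xyz[, 2],
             z = xyz[, 3], element = substr(nm, 1, 1), formal_charge = 0L)
}

#' Toy binding pocket with a planted amino-acid-like ligand
#'
#' Builds the scaffold-template ligand at the origin and places a handful of
#' residues realizing a configured interaction set: three backbone carbonyls
#' accepting from the ligand ammonium (the polar head site), two backbone
#' amides donating to the carboxylate oxygens, an aliphatic cluster and an
#' aromatic ring forming the hydrophobic sub-pocket, and (optionally) a
#' remote glutamate/asparagine pair used for residue-residue hydrogen-bond
#' occupancy studies. The planted frame therefore perceives a 5-feature model
#' (1 H, 1 AR, 1 HBD, 2 HBA) and exactly five ligand-protein hydrogen bonds.
#'
#' @param include_aromatic place the aromatic sub-pocket residue (default TRUE).
#' @param include_remote_pair place the remote residue pair (default TRUE).
#' @return list with `protein` (`ProteinStructure`), `ligand` (`Molecule`),
#'   `frame` (`TrajectoryFrame`), and `toggle_groups` (named list of protein
#'   atom-row sets with their displacement directions, used by
#'   [gen_trajectory()]).
#' @export
gen_toy_pocket <- function(include_aromatic = TRUE, include_remote_pair = TRUE) {
  lig <- scaffold_template("planted")
  xyz <- coords(lig)
  pN <- xyz[11, ]; pO1 <- xyz[13, ]; pO2 <- xyz[14, ]
  hyd <- hydrophobic_atoms(lig)
  frag <- hydrophobic_fragments(lig)[[1]]
  pH <- colMeans(xyz[frag, , drop = FALSE])
  pAr <- colMeans(xyz[1:6, , drop = FALSE])
  res <- list()
  # three carbonyl acceptors around the ammonium, fanned into open space
  dirs_o <- list(unit(c(0.2, 0.6, 1.0)), unit(c(1.0, 0.6, 0.3)),
                 unit(c(-0.4, 1.0, 0.6)))
  for (k in 1:3)
    res[[k]] <- gly_chain(100 + k, pN + 2.9 * dirs_o[[k]], dirs_o[[k]], "O")
  # two amide donors for the carboxylate oxygens
  dirs_n <- list(unit(c(1.0, -0.2, -0.9)), unit(c(-0.3, -1.0, -0.7)))
  res[[4]] <- gly_chain(104, pO1 + 2.9 * dirs_n[[1]], dirs_n[[1]], "N")
  res[[5]] <- gly_chain(105, pO2 + 2.9 * dirs_n[[2]], dirs_n[[2]], "N")
  # aliphatic sub-pocket: four isolated side-chain carbons 4 A below the
  # hydrophobic fragment centroid
  off <- rbind(c(0, 0, -4.0), c(1.9, 0.6, -3.6), c(-1.9, 0.6, -3.6),
               c(0, -1.9, -3.7))
  ile <- data.frame(record = "ATOM",
                    atom_name = c("CB", "CG1", "CG2", "CD1"),
                    resname = "ILE", chain = "A", resno = 106, icode = "",
                    x = pH[1] + off[, 1], y = pH[2] + off[, 2],
                    z = pH[3] + off[, 3], element = "C", formal_charge = 0L)
  res[[6]] <- ile
  if (include_aromatic) {
    # 5.3 A above the ligand ring: inside the 5.5 A aromatic cutoff but with
    # every ring carbon > 5.0 A from the hydrophobic fragment centroid, so the
    # AR and H channels toggle independently in synthetic trajectories
    ctr <- pAr + c(0, 0, 5.3)
    aang <- (seq(0, 300, 60)) * pi / 180
    ring <- cbind(ctr[1] + 1.39 * cos(aang), ctr[2] + 1.39 * sin(aang),
                  ctr[3])
    phe <- data.frame(record = "ATOM",
                      atom_name = c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"),
                      resname = "PHE", chain = "A", resno = 107, icode = "",
                      x = ring[, 1], y = ring[, 2], z = ring[, 3],
                      element = "C", formal_charge = 0L)
    res[[length(res) + 1L]] <- phe
  }
  if (include_remote_pair) {
    base <- c(-12, 8, 2)
    glu <- data.frame(record = "ATOM", atom_name = c("CD", "OE1", "OE2"),
                      resname = "GLU", chain = "A", resno = 136, icode = "",
                      x = base[1] + c(0, 1.25, -0.6),
                      y = base[2] + c(0, 0.2, 1.1),
                      z = base[3] + c(0, 0, 0),
                      element = c("C", "O", "O"), formal_charge = 0L)
    # ND2 donates to OE1 at 2.9 A along +x
    asn <- data.frame(record = "ATOM", atom_name = c("CG", "OD1", "ND2"),
                      resname = "ASN", chain = "A", resno = 258, icode = "",
                      x = base[1] + c(5.4, 6.0, 1.25 + 2.9),
                      y = base[2] + c(0.2, 1.2, 0.2),
                      z = base[3] + c(0, 0, 0),
                      element = c("C", "O", "N"), formal_charge = 0L)
    res[[length(res) + 1L]] <- glu
    res[[length(res) + 1L]] <- asn
  }
  atoms <- do.call(rbind, res)
  protein <- protein_structure(atoms)
  find_rows <- function(resno, names) which(atoms$resno == resno &
                                              atoms$atom_name %in% names)
  ligand_centroid <- colMeans(xyz)
  away <- function(rows) unit(colMeans(as.matrix(atoms[rows, c("x", "y", "z")])) -
                                ligand_centroid)
  tg <- list(
    HBD = list(atoms = which(atoms$resno %in% 101:103)),
    HBA1 = list(atoms = which(atoms$resno == 104)),
    HBA2 = list(atoms = which(atoms$resno == 105)),
    H = list(atoms = which(atoms$resno == 106)))
  if (include_aromatic)
    tg$AR <- list(atoms = which(atoms$resno == 107))
  if (include_remote_pair)
    tg$pair <- list(atoms = find_rows(258, c("ND2")))
  tg <- lapply(tg, function(g) { g$direction <- away(g$atoms); g })
  # the remote pair toggles along the donor-acceptor axis, not the pocket exit
  if (include_remote_pair) tg$pair$direction <- c(1, 0, 0)
  list(protein = protein, ligand = lig,
       frame = trajectory_frame(0, protein, lig),
       toggle_groups = tg)
}

#' Synthetic trajectory with per-feature toggle probabilities
#'
#' Each frame jitters all coordinates isotropically and independently decides,
#' per toggleable feature group, whether its geometric condition holds
#' (probability `p`): "off" displaces the group's protein partner atoms 3 A
#' outward along their pocket-exit direction, breaking the distance criterion
#' while leaving the rest of the frame intact. 10,000 frames at 2 ps spacing
#' emulate a 20 ns production run.
#'
#' @param base pocket description from [gen_toy_pocket()].
#' @param n_frames number of frames (default 10000).
#' @param toggle_probs named per-feature on-probabilities; names must be a
#'   subset of `names(base$toggle_groups)`. Defaults cover one clearly major,
#'   one borderline and one minor feature plus a 0.92-occupancy residue pair.
#' @param jitter_sd isotropic positional jitter, A (default 0.05).
#' @param seed integer seed.
#' @return list with `frames` (list of `TrajectoryFrame`) and `truth`
#'   (logical matrix `n_frames` x features).
#' @export
gen_trajectory <- function(base = gen_toy_pocket(), n_frames = 10000,
                           toggle_probs = c(HBD = 0.95, HBA1 = 0.85,
                                            HBA2 = 0.40, H = 0.90,
                                            AR = 0.75, pair = 0.92),
                           jitter_sd = 0.05, seed = 1) {
  toggle_probs <- toggle_probs[names(toggle_probs) %in% names(base$toggle_groups)]
  prot0 <- base$protein
  lig0 <- base$ligand
  P0 <- protein_coords(prot0)
  L0 <- coords(lig0)
  with_seed(seed, {
    truth <- matrix(stats::runif(n_frames * length(toggle_probs)) <
                      rep(toggle_probs, each = n_frames),
                    n_frames, length(toggle_probs),
                    dimnames = list(NULL, names(toggle_probs)))
    frames <- vector("list", n_frames)
    for (f in seq_len(n_frames)) {
      P <- P0 + matrix(stats::rnorm(length(P0), 0, jitter_sd), nrow(P0), 3)
      L <- L0 + matrix(stats::rnorm(length(L0), 0, jitter_sd), nrow(L0), 3)
      for (g in names(toggle_probs)) {
        if (!truth[f, g]) {
          grp <- base$toggle_groups[[g]]
          P[grp$atoms, ] <- P[grp$atoms, ] +
            matrix(3.0 * grp$direction, length(grp$atoms), 3, byrow = TRUE)
        }
      }
      prot <- prot0; prot$atoms[, c("x", "y", "z")] <- P
      lig <- lig0; lig$atoms[, c("x", "y", "z")] <- L
      frames[[f]] <- trajectory_frame((f - 1) * 2, prot, lig)
    }
    list(frames = frames, truth = truth)
  })
}

#' Synthetic docked-pose ensemble with planted cluster structure
#'
#' Each cluster is a rigid placement (random rotation + grid translation at
#' `separation` spacing) of the common scaffold; poses are cluster placements
#' plus isotropic Gaussian jitter. The first `n_csc` clusters receive poses
#' from every ligand (planted common scaffold clusters); the remaining
#' clusters are restricted to at most `min_distinct - 1` ligands and land in
#' the residual set. Ligand decorations beyond the scaffold are randomized
#' per ligand. Defaults mirror the docking campaign's shape: 5 ligands x 100
#' poses, 30 clusters of which 12 are common.
#'
#' @param n_ligands,poses_per_ligand ensemble shape (default 5 x 100).
#' @param n_clusters planted cluster count (default 30).
#' @param n_csc planted common clusters (default 12).
#' @param separation inter-centroid spacing, A (default 6; must comfortably
#'   exceed both the jitter scale and the clustering height).
#' @param jitter_sd isotropic pose jitter, A (default 0.3).
#' @param min_distinct CSC rule used to restrict residual clusters (default 4).
#' @param seed integer seed.
#' @return list with `poses` (list of `LigandPose`), `truth` (data.frame
#'   `pose_id`, `ligand_id`, `cluster`), `scaffold_map`.
#' @export
gen_pose_ensemble <- function(n_ligands = 5, poses_per_ligand = 100,
                              n_clusters = 30, n_csc = 12, separation = 6,
                              jitter_sd = 0.3, min_distinct = 4, seed = 1) {
  if (separation < 2 * jitter_sd)
    warning("separation < 2 * jitter_sd: planted clusters may overlap")
  template <- scaffold_template()
  X0 <- coords(template)
  ctr <- colMeans(X0)
  with_seed(seed, {
    # rigid cluster placements on a grid
    grid <- as.matrix(expand.grid(0:3, 0:3, 0:3)) * separation
    placements <- lapply(seq_len(n_clusters), function(k) {
      list(R = if (k == 1) diag(3) else random_rotation(),
           t = grid[k, ])
    })
    # per-ligand decorations: 0-3 extra atoms on the saturated ring
    decorations <- lapply(seq_len(n_ligands), function(i) {
      nd <- (i - 1) %% 4
      if (nd == 0) return(NULL)
      el <- sample(c("C", "Cl"), nd, replace = TRUE)
      anchor <- sample(c(9L, 10L), nd, replace = TRUE)
      dir <- matrix(stats::rnorm(3 * nd), nd, 3)
      list(element = el, anchor = anchor, dir = dir)
    })
    # residual clusters: allowed ligand subsets of size < min_distinct
    allowed <- vector("list", n_clusters)
    for (k in seq_len(n_clusters))
      allowed[[k]] <- if (k <= n_csc) seq_len(n_ligands) else
        sort(sample(seq_len(n_ligands), sample(seq_len(min_distinct - 1), 1)))
    poses <- list(); truth <- list()
    for (i in seq_len(n_ligands)) {
      lig_id <- sprintf("lig%d", i)
      open_clusters <- which(vapply(allowed, function(a) i %in% a, TRUE))
      # guarantee every planted CSC holds a pose of every ligand, and every
      # residual cluster is populated by its first allowed ligand
      forced <- seq_len(n_csc)
      for (k in setdiff(seq_len(n_clusters), forced))
        if (allowed[[k]][1] == i) forced <- c(forced, k)
      n_free <- poses_per_ligand - length(forced)
      assignment <- c(forced, sample(open_clusters, n_free, replace = TRUE))
      for (p in seq_len(poses_per_ligand)) {
        k <- assignment[p]
        pl <- placements[[k]]
        X <- sweep(sweep(X0, 2, ctr) %*% t(pl$R), 2, ctr + pl$t, "+")
        mol <- template
        dec <- decorations[[i]]
        if (!is.null(dec)) {
          extra <- t(vapply(seq_along(dec$element), function(q)
            X[dec$anchor[q], ] + 1.7 * unit(dec$dir[q, ]), numeric(3)))
          mol$atoms <- rbind(mol$atoms,
                             data.frame(element = dec$element,
                                        x = extra[, 1], y = extra[, 2],
                                        z = extra[, 3], formal_charge = 0L,
                                        aromatic = FALSE))
          mol$bonds <- rbind(mol$bonds,
                             data.frame(a1 = dec$anchor,
                                        a2 = 14L + seq_along(dec$element),
                                        order = 1L, aromatic = FALSE))
          X <- rbind(X, extra)
        }
        X <- X + matrix(stats::rnorm(length(X), 0, jitter_sd), nrow(X), 3)
        mol$atoms[, c("x", "y", "z")] <- X
        mol$name <- lig_id
        pose_id <- sprintf("%s_p%03d", lig_id, p)
        poses[[length(poses) + 1L]] <-
          ligand_pose(lig_id, pose_id, mol, scaffold_map = 1:14,
                      scores = c(GlideScore = stats::rnorm(1, -8, 1)))
        truth[[length(truth) + 1L]] <-
          data.frame(pose_id = pose_id, ligand_id = lig_id, cluster = k)
      }
    }
    list(poses = poses, truth = do.call(rbind, truth), scaffold_map = 1:14)
  })
}

#' Synthetic active/decoy score populations
#'
#' Actives ~ Normal(`delta`, 1), decoys ~ Normal(0, 1): the expected ROC AUC
#' is the closed form `pnorm(delta / sqrt(2))`. Default counts mirror a
#' 97-active / 5300-decoy retrospective validation set.
#'
#' @param n_actives,n_decoys population sizes.
#' @param delta mean score separation.
#' @param seed integer seed.
#' @return data.frame with `molecule_id`, `class` ("active"/"decoy"), `score`.
#' @export
gen_screening_population <- function(n_actives = 97, n_decoys = 5300,
                                     delta = 1, seed = 1) {
  with_seed(seed, {
    data.frame(
      molecule_id = c(sprintf("act%04d", seq_len(n_actives)),
                      sprintf("dec%04d", seq_len(n_decoys))),
      class = rep(c("active", "decoy"), c(n_actives, n_decoys)),
      score = c(stats::rnorm(n_actives, delta, 1), stats::rnorm(n_decoys, 0, 1)))
  })
}

#' Decoy molecule library for screening tests
#'
#' Pure-carbon chain molecules (3-8 atoms, 2 conformers each): they expose at
#' most hydrophobic features and cannot satisfy a polar multi-feature query,
#' giving a guaranteed-negative background for planted-retrieval tests.
#'
#' @param n number of decoy molecules.
#' @param seed integer seed.
#' @return list of `Molecule` (conformers share molecule names).
#' @export
gen_decoy_library <- function(n = 100, seed = 1) {
  with_seed(seed, {
    out <- list()
    for (i in seq_len(n)) {
      na <- sample(3:8, 1)
      for (conf in 1:2) {
        xyz <- matrix(0, na, 3)
        for (a in 2:na)
          xyz[a, ] <- xyz[a - 1, ] + 1.5 * unit(stats::rnorm(3))
        bonds <- data.frame(a1 = seq_len(na - 1), a2 = 2:na, order = 1L)
        out[[length(out) + 1L]] <-
          molecule(sprintf("dec%03d", i),
                   data.frame(element = "C", x = xyz[, 1], y = xyz[, 2],
                              z = xyz[, 3]), bonds)
      }
    }
    out
  })
}
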