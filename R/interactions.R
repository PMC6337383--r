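#' Geometric interaction rules
#'
#' Every geometric threshold used by interaction detection and pharmacophore
#' perception, in one overridable object. The source campaign names the
#' interaction types but not the criteria (they are tool-internal), so common
#' practice values are fixed here and logged with every run.
#'
#' @param hbond_dist donor-acceptor heavy-atom distance cutoff, A.
#' @param hbond_angle minimum D-H...A angle, degrees (applied when an explicit
#'   hydrogen is present; otherwise the distance-only rule is used).
#' @param xbond_dist halogen-bond X...A distance cutoff, A.
#' @param xbond_angle minimum C-X...A angle, degrees.
#' @param contact_dist proximity cutoff defining "close to the ligand", A.
#' @param hydrophobic_dist hydrophobic heavy-atom contact cutoff, A.
#' @param h_feature_dist pocket radius around a hydrophobic fragment centroid, A.
#' @param min_hydrophobic_partners pocket atoms required to emit an H feature.
#' @param aromatic_dist ring-centroid distance cutoff for AR features, A.
#' @param ionic_dist charged-group to partner distance cutoff, A.
#' @param exclusion_radius radius of excluded-volume spheres, A.
#' @param feature_radius named tolerance radii per feature kind, A.
#' @return named list of class `PerceptionRules`.
#' @export
perception_rules <- function(hbond_dist = 3.5, hbond_angle = 120,
                             xbond_dist = 3.8, xbond_angle = 140,
                             contact_dist = 5.0, hydrophobic_dist = 4.5,
                             h_feature_dist = 5.0, min_hydrophobic_partners = 3L,
                             aromatic_dist = 5.5, ionic_dist = 5.0,
                             exclusion_radius = 1.0,
                             feature_radius = c(H = 1.5, HBD = 1.5, HBA = 1.5,
                                                AR = 1.5, PI = 1.5, NI = 1.5)) {
  structure(as.list(environment()), class = "PerceptionRules")
}

#' Hydrogen-bond geometry test
#'
#' True when the donor-acceptor heavy-atom distance is at most
#' `rules$hbond_dist` and, when a hydrogen position is supplied, the D-H...A
#' angle is at least `rules$hbond_angle`. Without a hydrogen the distance-only
#' rule applies (the usual situation for PDB inputs without protons).
#'
#' @param donor,acceptor length-3 coordinates of the heavy atoms, A.
#' @param h optional coordinate of the donated hydrogen.
#' @param rules a [perception_rules()] object.
#' @return list with `hbond` (logical), `distance` (A), `angle` (degrees or NA).
#' @export
detect_hbond <- function(donor, acceptor, h = NULL, rules = perception_rules()) {
  d <- vnorm(donor - acceptor)
  ang <- NA_real_
  ok <- d <= rules$hbond_dist
  if (ok && !is.null(h)) {
    ang <- angle_deg(donor, h, acceptor)
    ok <- ang >= rules$hbond_angle
  }
  list(hbond = ok, distance = d, angle = ang)
}

#' Halogen-bond geometry test
#'
#' @param c_atom coordinate of the carbon bound to the halogen.
#' @param x_atom coordinate of the halogen (Cl/Br/I).
#' @param acceptor coordinate of the acceptor atom.
#' @param rules a [perception_rules()] object.
#' @return list with `xbond` (logical), `distance`, `angle`.
#' @export
detect_halogen_bond <- function(c_atom, x_atom, acceptor,
                                rules = perception_rules()) {
  d <- vnorm(x_atom - acceptor)
  ang <- angle_deg(c_atom, x_atom, acceptor)
  list(xbond = d <= rules$xbond_dist && ang >= rules$xbond_angle,
       distance = d, angle = ang)
}

#' Residues with any heavy atom near the ligand
#'
#' @param pose `LigandPose` (or `Molecule`) in the protein frame.
#' @param protein `ProteinStructure`.
#' @param cutoff distance cutoff in Angstrom (default 5.0).
#' @return character vector of residue labels.
#' @export
residues_near <- function(pose, protein, cutoff = 5.0) {
  mol <- if (inherits(pose, "LigandPose")) pose$molecule else pose
  L <- coords(mol)[heavy_idx(mol), , drop = FALSE]
  ph <- protein_heavy(protein)
  D <- cross_dist(protein_coords(protein)[ph, , drop = FALSE], L)
  keys <- residue_key(protein)[ph]
  near <- apply(D, 1, min) <= cutoff
  unique(keys[near])
}

# All ligand-protein hydrogen bonds of one snapshot.
# Returns data.frame(residue, ligand_atom, protein_atom, distance, direction)
hbond_pairs <- function(mol, protein, rules = perception_rules()) {
  roles_l <- atom_roles(mol)
  roles_p <- protein_roles(protein)
  keys <- residue_key(protein)
  Lxyz <- coords(mol)
  Pxyz <- protein_coords(protein)
  adj <- adjacency(mol)
  el <- mol$atoms$element
  out <- list()
  add <- function(res, la, pa, d, dir)
    out[[length(out) + 1L]] <<- data.frame(residue = res, ligand_atom = la,
                                           protein_atom = pa, distance = d,
                                           direction = dir)
  don_l <- which(roles_l$donor)
  acc_p <- which(roles_p$acceptor)
  if (length(don_l) && length(acc_p)) {
    D <- cross_dist(Lxyz[don_l, , drop = FALSE], Pxyz[acc_p, , drop = FALSE])
    hits <- which(D <= rules$hbond_dist, arr.ind = TRUE)
    for (k in seq_len(nrow(hits))) {
      la <- don_l[hits[k, 1]]; pa <- acc_p[hits[k, 2]]
      hs <- adj[[la]][el[adj[[la]]] == "H"]
      ok <- if (length(hs)) {
        any(vapply(hs, function(h)
          angle_deg(Lxyz[la, ], Lxyz[h, ], Pxyz[pa, ]) >= rules$hbond_angle, TRUE))
      } else TRUE
      if (ok) add(keys[pa], la, pa, D[hits[k, 1], hits[k, 2]], "donated")
    }
  }
  acc_l <- which(roles_l$acceptor)
  don_p <- which(roles_p$donor)
  if (length(acc_l) && length(don_p)) {
    D <- cross_dist(Lxyz[acc_l, , drop = FALSE], Pxyz[don_p, , drop = FALSE])
    hits <- which(D <= rules$hbond_dist, arr.ind = TRUE)
    for (k in seq_len(nrow(hits))) {
      la <- acc_l[hits[k, 1]]; pa <- don_p[hits[k, 2]]
      add(keys[pa], la, pa, D[hits[k, 1], hits[k, 2]], "accepted")
    }
  }
  if (!length(out))
    return(data.frame(residue = character(), ligand_atom = integer(),
                      protein_atom = integer(), distance = numeric(),
                      direction = character()))
  do.call(rbind, out)
}

# halogen bonds of one snapshot: data.frame(residue, ligand_atom, protein_atom)
xbond_pairs <- function(mol, protein, rules = perception_rules()) {
  roles_l <- atom_roles(mol)
  keys <- residue_key(protein)
  Lxyz <- coords(mol)
  Pxyz <- protein_coords(protein)
  adj <- adjacency(mol)
  el <- mol$atoms$element
  acc_p <- which(protein_roles(protein)$acceptor)
  out <- list()
  for (xi in which(roles_l$halogen)) {
    cs <- adj[[xi]][el[adj[[xi]]] == "C"]
    if (!length(cs) || !length(acc_p)) next
    d <- cross_dist(Lxyz[xi, , drop = FALSE], Pxyz[acc_p, , drop = FALSE])[1, ]
    for (k in which(d <= rules$xbond_dist)) {
      pa <- acc_p[k]
      ang <- angle_deg(Lxyz[cs[1], ], Lxyz[xi, ], Pxyz[pa, ])
      if (ang >= rules$xbond_angle)
        out[[length(out) + 1L]] <- data.frame(residue = keys[pa],
                                              ligand_atom = xi,
                                              protein_atom = pa)
    }
  }
  if (!length(out))
    return(data.frame(residue = character(), ligand_atom = integer(),
                      protein_atom = integer()))
  do.call(rbind, out)
}

# per-residue logical channels for one snapshot
pose_channels <- function(pose, protein, rules = perception_rules()) {
  mol <- if (inherits(pose, "LigandPose")) pose$molecule else pose
  keys <- residue_key(protein)
  ph <- protein_heavy(protein)
  L <- coords(mol)[heavy_idx(mol), , drop = FALSE]
  D <- cross_dist(protein_coords(protein)[ph, , drop = FALSE], L)
  contact_atoms <- apply(D, 1, min) <= rules$contact_dist
  res_all <- unique(keys[ph][contact_atoms])
  hyd_l <- which(hydrophobic_atoms(mol) & mol$atoms$element != "H")
  hyd_p <- intersect(ph, which(protein_hydrophobic(protein)))
  hyd_res <- character()
  if (length(hyd_l) && length(hyd_p)) {
    Dh <- cross_dist(protein_coords(protein)[hyd_p, , drop = FALSE],
                     coords(mol)[hyd_l, , drop = FALSE])
    hyd_res <- unique(keys[hyd_p][apply(Dh, 1, min) <= rules$hydrophobic_dist])
  }
  hb <- hbond_pairs(mol, protein, rules)
  xb <- xbond_pairs(mol, protein, rules)
  residues <- unique(c(res_all, hyd_res, hb$residue, xb$residue))
  data.frame(residue = residues,
             any_contact = residues %in% res_all,
             hbond = residues %in% hb$residue,
             hydrophobic = residues %in% hyd_res,
             halogen = residues %in% xb$residue)
}

CHANNELS <- c("any_contact", "hbond", "hydrophobic", "halogen")

aggregate_channels <- function(per_obs, n_obs) {
  residues <- unique(unlist(lapply(per_obs, `[[`, "residue")))
  counts <- matrix(0, length(residues), length(CHANNELS),
                   dimnames = list(residues, CHANNELS))
  fav <- setNames(numeric(length(residues)), residues)
  for (ch in per_obs) {
    m <- match(ch$residue, residues)
    for (col in CHANNELS) counts[m, col] <- counts[m, col] + ch[[col]]
    fav[m] <- fav[m] + ch$hbond + ch$hydrophobic
  }
  prof <- data.frame(residue = residues, 100 * counts / n_obs,
                     favorable_contacts = as.numeric(fav),
                     row.names = NULL, check.names = FALSE)
  attr(prof, "n_observations") <- n_obs
  class(prof) <- c("InteractionProfile", "data.frame")
  prof
}

#' Structural interaction fingerprint (SIFt) over a pose ensemble
#'
#' Per-residue involvement percentages per interaction channel (any contact
#' within 5 A, hydrogen bond, hydrophobic, halogen) over all poses, plus the
#' total favorable-contact count (hydrogen bond + hydrophobic observations)
#' used to compare CSC against residual poses.
#'
#' @param poses non-empty list of `LigandPose`.
#' @param protein `ProteinStructure` shared by all poses.
#' @param rules a [perception_rules()] object.
#' @return `InteractionProfile` data.frame (percent columns per channel,
#'   attribute `n_observations`).
#' @export
sift_profile <- function(poses, protein, rules = perception_rules()) {
  if (!length(poses)) stopf("sift_profile: empty pose list")
  per <- lapply(poses, pose_channels, protein = protein, rules = rules)
  aggregate_channels(per, length(poses))
}

#' Dynamic interaction fingerprint (DIFt) over a trajectory
#'
#' Same channels as [sift_profile()], with occupancy computed over frames.
#'
#' @param frames non-empty list of `TrajectoryFrame`.
#' @param rules a [perception_rules()] object.
#' @return `InteractionProfile`.
#' @export
dift_profile <- function(frames, rules = perception_rules()) {
  if (!length(frames)) stopf("dift_profile: empty frame list")
  per <- lapply(frames, function(fr)
    pose_channels(fr$ligand, fr$protein, rules))
  aggregate_channels(per, length(frames))
}

#' Occupancy of hydrogen bonding between two protein residues
#'
#' Percentage of frames with at least one donor-acceptor pair within
#' `rules$hbond_dist` between the atoms of the two residues (distance-only
#' rule; protein hydrogens are typically absent).
#'
#' @param frames list of `TrajectoryFrame`.
#' @param residue_a,residue_b residue labels as produced by [residue_key()].
#' @param rules a [perception_rules()] object.
#' @return percent in `[0, 100]`.
#' @export
pair_hbond_occupancy <- function(frames, residue_a, residue_b,
                                 rules = perception_rules()) {
  if (!length(frames)) stopf("empty frame list")
  keys0 <- residue_key(frames[[1]]$protein)
  for (r in c(residue_a, residue_b))
    if (!r %in% keys0) stopf("unknown residue id '%s'", r)
  hit <- vapply(frames, function(fr) {
    at <- fr$protein$atoms
    keys <- residue_key(fr$protein)
    roles <- protein_roles(fr$protein)
    ia <- which(keys == residue_a); ib <- which(keys == residue_b)
    xyz <- protein_coords(fr$protein)
    pairs_ok <- function(don, acc) {
      if (!length(don) || !length(acc)) return(FALSE)
      any(cross_dist(xyz[don, , drop = FALSE],
                     xyz[acc, , drop = FALSE]) <= rules$hbond_dist)
    }
    pairs_ok(ia[roles$donor[ia]], ib[roles$acceptor[ib]]) ||
      pairs_ok(ib[roles$donor[ib]], ia[roles$acceptor[ia]])
  }, TRUE)
  100 * mean(hit)
}

#' Per-residue interaction-energy decomposition
#'
#' For every residue with at least one atom within `radius` of `center`, the
#' ligand-residue electrostatic energy (Coulomb, vacuum dielectric,
#' 332.0636 kcal A / (mol e^2)) and Lennard-Jones energy
#' (4 eps ((sig/r)^12 - (sig/r)^6), Lorentz-Berthelot combining) are summed
#' over ligand x residue atom pairs. Values target rank agreement with
#' docking-internal energies, not their absolute scale.
#'
#' @param pose `LigandPose` (or `Molecule`).
#' @param protein `ProteinStructure`.
#' @param params list with data.frames `ligand` and `protein`, each holding
#'   columns `charge` (e), `sigma` (A), `epsilon` (kcal/mol) with one row per
#'   atom of the respective structure.
#' @param center grid center, length-3 numeric (A).
#' @param radius inclusion radius around `center` (default 12 A).
#' @return `EnergyDecomposition` data.frame with columns `residue`,
#'   `electrostatic`, `vdw`, `total` (kcal/mol).
#' @export
residue_energies <- function(pose, protein, params, center, radius = 12.0) {
  mol <- if (inherits(pose, "LigandPose")) pose$molecule else pose
  pl <- params$ligand; pp <- params$protein
  if (is.null(pl) || nrow(pl) != nrow(mol$atoms))
    stopf("params$ligand must have one row per ligand atom")
  if (is.null(pp) || nrow(pp) != nrow(protein$atoms))
    stopf("params$protein must have one row per protein atom")
  for (tab in list(ligand = pl, protein = pp)) {
    bad <- which(!stats::complete.cases(tab[, c("charge", "sigma", "epsilon")]))
    if (length(bad))
      stopf("missing force-field parameters for atom(s): %s",
            paste(utils::head(bad, 10), collapse = ", "))
  }
  keys <- residue_key(protein)
  Pxyz <- protein_coords(protein)
  Lxyz <- coords(mol)
  dc <- cross_dist(Pxyz, matrix(center, 1))[, 1]
  keep_res <- unique(keys[dc <= radius])
  rows <- lapply(keep_res, function(res) {
    ia <- which(keys == res)
    R <- cross_dist(Lxyz, Pxyz[ia, , drop = FALSE])
    R[R < 1e-6] <- 1e-6
    qq <- outer(pl$charge, pp$charge[ia])
    elec <- 332.0636 * sum(qq / R)
    sij <- outer(pl$sigma, pp$sigma[ia], function(a, b) (a + b) / 2)
    eij <- sqrt(outer(pl$epsilon, pp$epsilon[ia]))
    sr6 <- (sij / R)^6
    vdw <- sum(4 * eij * (sr6^2 - sr6))
    data.frame(residue = res, electrostatic = elec, vdw = vdw,
               total = elec + vdw)
  })
  out <- do.call(rbind, rows)
  attr(out, "center") <- center
  attr(out, "radius") <- radius
  class(out) <- c("EnergyDecomposition", "data.frame")
  out
}
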