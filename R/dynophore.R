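#' Dynamic pharmacophores
#'
#' A structure-based pharmacophore model is perceived independently for every
#' saved trajectory frame; a feature is identified across frames by its
#' signature (kind + generating ligand atom set), and its occupancy is the
#' percentage of frames in which it appears. Features above the major
#' threshold (70%) are the stable recognition elements; model geometries are
#' clustered by RDF-code similarity and each cluster is represented by its
#' medoid (the representative pharmacophore model, RPM).
#'
#' @name dynophore
NULL

PROTEIN_RING_ATOMS <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2"))

PROTEIN_ANION_ATOMS <- c("OD1", "OD2", "OE1", "OE2", "OXT")
PROTEIN_CATION_ATOMS <- c("NZ", "NH1", "NH2", "NE", "ND1", "NE2")

# contiguous hydrophobic heavy-atom fragments; halogens are singleton fragments
hydrophobic_fragments <- function(mol) {
  hyd <- hydrophobic_atoms(mol) & mol$atoms$element != "H"
  halo <- mol$atoms$element %in% HALOGENS
  core <- which(hyd & !halo)
  adj <- adjacency(mol)
  seen <- logical(nrow(mol$atoms))
  frags <- list()
  for (s in core) {
    if (seen[s]) next
    comp <- integer(); queue <- s; seen[s] <- TRUE
    while (length(queue)) {
      a <- queue[1]; queue <- queue[-1]
      comp <- c(comp, a)
      nb <- setdiff(intersect(adj[[a]], core), which(seen))
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    frags[[length(frags) + 1L]] <- sort(comp)
  }
  for (x in which(hyd & halo)) frags[[length(frags) + 1L]] <- x
  frags
}

# connected components of the aromatic subgraph
aromatic_rings <- function(mol) {
  ar <- which(mol$atoms$aromatic)
  if (!length(ar)) return(list())
  adj <- adjacency(mol)
  seen <- logical(nrow(mol$atoms))
  comps <- list()
  for (s in ar) {
    if (seen[s]) next
    comp <- integer(); queue <- s; seen[s] <- TRUE
    while (length(queue)) {
      a <- queue[1]; queue <- queue[-1]
      comp <- c(comp, a)
      nb <- setdiff(intersect(adj[[a]], ar), which(seen))
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    if (length(comp) >= 5L) comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}

# ligand charged groups: list(kind = "PI"/"NI", atoms, position)
charged_groups <- function(mol) {
  fc <- mol$atoms$formal_charge
  el <- mol$atoms$element
  adj <- adjacency(mol)
  xyz <- coords(mol)
  out <- list()
  for (i in which(fc > 0 & el == "N"))
    out[[length(out) + 1L]] <- list(kind = "PI", atoms = i, position = xyz[i, ])
  seen <- logical(nrow(mol$atoms))
  for (i in which(fc < 0 & el == "O")) {
    if (seen[i]) next
    cs <- adj[[i]][el[adj[[i]]] == "C"]
    atoms <- if (length(cs)) {
      os <- adj[[cs[1]]][el[adj[[cs[1]]]] == "O"]
      sort(unique(c(i, os)))
    } else i
    seen[atoms] <- TRUE
    pos <- colMeans(xyz[atoms, , drop = FALSE])
    out[[length(out) + 1L]] <- list(kind = "NI", atoms = atoms, position = pos)
  }
  out
}

protein_ring_centroids <- function(protein) {
  at <- protein$atoms
  keys <- residue_key(protein)
  out <- list()
  rk <- paste(at$chain, at$resno, at$icode)
  for (res in split(seq_len(nrow(at)), rk)) {
    rn <- at$resname[res[1]]
    ring <- PROTEIN_RING_ATOMS[[rn]]
    if (is.null(ring)) next
    ix <- res[at$atom_name[res] %in% ring]
    if (length(ix) < 5L) next
    out[[length(out) + 1L]] <-
      list(residue = keys[res[1]], atoms = ix,
           centroid = colMeans(as.matrix(at[ix, c("x", "y", "z")])))
  }
  out
}

#' Perceive a structure-based pharmacophore model from one frame
#'
#' Emits: an HBD feature at every ligand donor heavy atom hydrogen-bonded to a
#' protein acceptor (direction pointing at the acceptor); an HBA feature at
#' every ligand acceptor bonded to a protein donor; an H feature at the
#' centroid of each contiguous hydrophobic ligand fragment (halogens are their
#' own fragments) with at least `rules$min_hydrophobic_partners` hydrophobic
#' pocket heavy atoms within `rules$h_feature_dist`; an AR feature at each
#' aromatic-ring centroid with a protein ring centroid within
#' `rules$aromatic_dist`; PI/NI features at charged-group centroids with a
#' complementary protein partner within `rules$ionic_dist`. Exclusion spheres
#' (radius `rules$exclusion_radius`) are placed at protein heavy atoms within
#' `rules$contact_dist` of the ligand that are not partners of any feature.
#'
#' @param frame a `TrajectoryFrame` (ligand + pocket snapshot).
#' @param rules a [perception_rules()] object.
#' @return a `PharmacophoreModel`; an error when no feature is perceivable.
#' @export
perceive_features <- function(frame, rules = perception_rules()) {
  mol <- frame$ligand$molecule
  protein <- frame$protein
  keys <- residue_key(protein)
  Pxyz <- protein_coords(protein)
  Lxyz <- coords(mol)
  feats <- list()
  partner_atoms <- integer()
  rad <- rules$feature_radius
  emit <- function(kind, pos, atoms, p_atoms, dir = NULL) {
    feats[[length(feats) + 1L]] <<- phore_feature(
      kind, pos, radius = unname(rad[[kind]]), direction = dir,
      ligand_atoms = atoms, partner_residues = unique(keys[p_atoms]))
    partner_atoms <<- c(partner_atoms, p_atoms)
  }
  hb <- hbond_pairs(mol, protein, rules)
  for (d in split(hb[hb$direction == "donated", ], hb$ligand_atom[hb$direction == "donated"])) {
    if (!nrow(d)) next
    la <- d$ligand_atom[1]
    nearest <- d$protein_atom[which.min(d$distance)]
    emit("HBD", Lxyz[la, ], la, d$protein_atom,
         dir = unit(Pxyz[nearest, ] - Lxyz[la, ]))
  }
  for (d in split(hb[hb$direction == "accepted", ], hb$ligand_atom[hb$direction == "accepted"])) {
    if (!nrow(d)) next
    la <- d$ligand_atom[1]
    nearest <- d$protein_atom[which.min(d$distance)]
    emit("HBA", Lxyz[la, ], la, d$protein_atom,
         dir = unit(Pxyz[nearest, ] - Lxyz[la, ]))
  }
  hyd_p <- intersect(protein_heavy(protein), which(protein_hydrophobic(protein)))
  for (fr in hydrophobic_fragments(mol)) {
    ctr <- colMeans(Lxyz[fr, , drop = FALSE])
    if (!length(hyd_p)) next
    d <- cross_dist(matrix(ctr, 1), Pxyz[hyd_p, , drop = FALSE])[1, ]
    near <- hyd_p[d <= rules$h_feature_dist]
    if (length(near) >= rules$min_hydrophobic_partners)
      emit("H", ctr, fr, near)
  }
  prings <- protein_ring_centroids(protein)
  for (ring in aromatic_rings(mol)) {
    ctr <- colMeans(Lxyz[ring, , drop = FALSE])
    for (pr in prings) {
      if (vnorm(ctr - pr$centroid) <= rules$aromatic_dist) {
        emit("AR", ctr, ring, pr$atoms, dir = unit(pr$centroid - ctr))
        break
      }
    }
  }
  at <- protein$atoms
  anion <- which(at$atom_name %in% PROTEIN_ANION_ATOMS | at$formal_charge < 0)
  cation <- which(at$atom_name %in% PROTEIN_CATION_ATOMS | at$formal_charge > 0)
  for (grp in charged_groups(mol)) {
    partners <- if (grp$kind == "PI") anion else cation
    if (!length(partners)) next
    d <- cross_dist(matrix(grp$position, 1), Pxyz[partners, , drop = FALSE])[1, ]
    near <- partners[d <= rules$ionic_dist]
    if (length(near)) emit(grp$kind, grp$position, grp$atoms, near)
  }
  if (!length(feats))
    stopf("no perceivable pharmacophore features in frame at t=%s ps", frame$time)
  ph <- protein_heavy(protein)
  lig_heavy <- Lxyz[heavy_idx(mol), , drop = FALSE]
  Dc <- cross_dist(Pxyz[ph, , drop = FALSE], lig_heavy)
  close_atoms <- ph[apply(Dc, 1, min) <= rules$contact_dist]
  ev_atoms <- setdiff(close_atoms, unique(partner_atoms))
  ev <- if (length(ev_atoms))
    data.frame(x = Pxyz[ev_atoms, 1], y = Pxyz[ev_atoms, 2],
               z = Pxyz[ev_atoms, 3], radius = rules$exclusion_radius)
  else NULL
  phore_model(name = sprintf("%s@%sps", mol$name, format(frame$time)),
              features = feats, exclusion_volumes = ev,
              provenance = sprintf("frame t=%s ps", format(frame$time)))
}

#' Feature-signature occupancy profile over per-frame models
#'
#' @param models frame-ordered list of `PharmacophoreModel`.
#' @param major_threshold percent occupancy separating major from minor
#'   features (default 70).
#' @return `OccupancyProfile` data.frame with columns `signature`, `kind`,
#'   `ligand_atoms`, `count`, `percent`, `class`; attribute `n_frames`.
#' @export
occupancy_profile <- function(models, major_threshold = 70) {
  if (!length(models)) stopf("occupancy_profile: no models")
  # NULL entries mark frames without a perceivable model; they count in the
  # denominator but contribute no signatures
  sigs <- lapply(models, function(m) if (is.null(m)) character() else
    model_signatures(m))
  tab <- table(unlist(sigs))
  n <- length(models)
  sig <- names(tab)
  kind <- sub(":.*", "", sig)
  atoms <- sub("^[A-Z]+:", "", sig)
  pct <- 100 * as.numeric(tab) / n
  out <- data.frame(signature = sig, kind = kind, ligand_atoms = atoms,
                    count = as.integer(tab), percent = pct,
                    class = ifelse(pct >= major_threshold, "major", "minor"))
  out <- out[order(-out$percent, out$signature), ]
  rownames(out) <- NULL
  attr(out, "n_frames") <- n
  attr(out, "major_threshold") <- major_threshold
  class(out) <- c("OccupancyProfile", "data.frame")
  out
}

#' Excluded-volume sphere statistics over per-frame models
#'
#' @param models list of `PharmacophoreModel`.
#' @return list with `per_frame` (integer counts) and `mean`.
#' @export
evs_stats <- function(models) {
  if (!length(models)) stopf("evs_stats: no models")
  counts <- vapply(models, function(m) nrow(m$exclusion_volumes), 0L)
  list(per_frame = counts, mean = mean(counts))
}

#' Radial-distribution-function code of a pharmacophore model
#'
#' For every unordered pair of feature kinds, the inter-feature distances are
#' accumulated into a Gaussian-smeared histogram (0 to `r_max`, bin width and
#' smearing sigma 0.5 A); blocks are concatenated in fixed kind-pair order and
#' L2-normalized individually. The code is invariant under rigid motion and
#' feature reordering but sensitive to geometry.
#'
#' @param model a `PharmacophoreModel`.
#' @param r_max histogram range, A.
#' @param bin_width bin width, A.
#' @param sigma Gaussian smearing width, A.
#' @return numeric descriptor vector (21 blocks x `r_max/bin_width` bins).
#' @export
rdf_code <- function(model, r_max = 20, bin_width = 0.5, sigma = 0.5) {
  kinds <- feature_kinds(model)
  nb <- as.integer(round(r_max / bin_width))
  centers <- (seq_len(nb) - 0.5) * bin_width
  pair_names <- apply(cbind(rep(FEATURE_KINDS, times = seq(6, 1)),
                            unlist(lapply(seq_along(FEATURE_KINDS), function(i)
                              FEATURE_KINDS[i:6]))), 1, paste, collapse = "|")
  blocks <- matrix(0, length(pair_names), nb,
                   dimnames = list(pair_names, NULL))
  n <- length(kinds)
  if (n < 2L) {
    warning("rdf_code: model has a single feature; returning a zero vector")
    return(as.numeric(blocks))
  }
  pos <- feature_positions(model)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d <- vnorm(pos[i, ] - pos[j, ])
    ks <- sort(factor(c(kinds[i], kinds[j]), levels = FEATURE_KINDS))
    key <- paste(ks, collapse = "|")
    blocks[key, ] <- blocks[key, ] + exp(-(centers - d)^2 / (2 * sigma^2))
  }
  for (r in seq_len(nrow(blocks))) {
    nrm <- sqrt(sum(blocks[r, ]^2))
    if (nrm > 0) blocks[r, ] <- blocks[r, ] / nrm
  }
  as.numeric(t(blocks))
}

cosine_similarity_matrix <- function(codes) {
  nrm <- sqrt(rowSums(codes^2))
  S <- tcrossprod(codes / ifelse(nrm > 0, nrm, 1))
  S[nrm == 0, ] <- 0; S[, nrm == 0] <- 0
  diag(S) <- 1
  pmin(pmax(S, -1), 1)
}

medoid_index <- function(D, members) {
  if (length(members) == 1L) return(members[1])
  sub <- D[members, members, drop = FALSE]
  members[which.min(rowSums(sub) / (length(members) - 1L))]
}

#' Cluster per-frame pharmacophore models; pick representative models
#'
#' Model similarity is the cosine of RDF codes; models are clustered by
#' average linkage on distance 1 - similarity, cut at distance
#' `1 - similarity_cutoff`. Clusters are ordered by population (ties by
#' lowest frame index) and each is represented by its medoid (RPM).
#'
#' @param models list of `PharmacophoreModel`.
#' @param similarity_cutoff cosine similarity threshold (default 0.5).
#' @param top optionally keep only the `top` most populated clusters
#'   (clamped to the number found).
#' @return object of class `ModelClustering`: `clusters` (list of model index
#'   vectors), `rpm` (medoid model index per cluster), `rpm_models` (the
#'   medoid models), `distance` (model distance matrix).
#' @export
cluster_models <- function(models, similarity_cutoff = 0.5, top = NULL) {
  if (!length(models)) stopf("cluster_models: no models")
  codes <- t(vapply(models, rdf_code, numeric(840)))
  D <- 1 - cosine_similarity_matrix(codes)
  diag(D) <- 0
  D <- (D + t(D)) / 2
  res <- agglomerate_cut(D, height = 1 - similarity_cutoff, linkage = "average")
  clusters <- order_clusters(res$clusters)
  rpm <- vapply(clusters, function(m) medoid_index(D, m), 0L)
  if (!is.null(top)) {
    k <- min(top, length(clusters))
    clusters <- clusters[seq_len(k)]
    rpm <- rpm[seq_len(k)]
  }
  structure(list(clusters = clusters, rpm = rpm,
                 rpm_models = models[rpm], distance = D),
            class = "ModelClustering")
}

#' @export
print.ModelClustering <- function(x, ...) {
  cat(sprintf("<ModelClustering: %d clusters, populations %s>\n",
              length(x$clusters),
              paste(utils::head(lengths(x$clusters), 10), collapse = ",")))
  invisible(x)
}

#' Deduplicated representative models across several trajectories
#'
#' Takes the medoids of all clusters across per-ligand model streams and
#' removes duplicates with identical feature-signature sets, yielding the
#' distinct dynamic models used for common-hits screening.
#'
#' @param model_sets list of lists of `PharmacophoreModel` (one per ligand).
#' @param similarity_cutoff passed to [cluster_models()].
#' @return list of `PharmacophoreModel`.
#' @export
distinct_rpms <- function(model_sets, similarity_cutoff = 0.5) {
  rpms <- list()
  for (ms in model_sets) {
    cl <- cluster_models(ms, similarity_cutoff)
    rpms <- c(rpms, cl$rpm_models)
  }
  keys <- vapply(rpms, function(m)
    paste(sort(model_signatures(m)), collapse = ";"), "")
  rpms[!duplicated(keys)]
}
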