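#' Common-scaffold clustering of docking poses
#'
#' The common-binding-mode workflow: all poses of a congeneric ligand series
#' are compared by the RMSD of their shared core scaffold (no superposition --
#' poses live in the common receptor frame), clustered by complete linkage at
#' a fixed height, and clusters holding poses of at least `min_distinct`
#' different ligands are kept as common scaffold clusters (CSCs). The medoid
#' of a CSC is its representative pose.
#'
#' @name scaffold_cluster
NULL

#' Scaffold RMSD between two poses
#'
#' Root-mean-square deviation over corresponding scaffold heavy atoms, without
#' superposition. If `automorphisms` is supplied (a list of permutations of
#' the scaffold positions encoding graph symmetries of the core), the minimum
#' over all of them is returned.
#'
#' @param pose_a,pose_b `LigandPose` objects with equal scaffold lengths.
#' @param automorphisms optional list of integer permutations.
#' @return RMSD in Angstrom.
#' @export
scaffold_rmsd <- function(pose_a, pose_b, automorphisms = NULL) {
  A <- scaffold_coords(pose_a)
  B <- scaffold_coords(pose_b)
  if (nrow(A) != nrow(B))
    stopf("scaffold length mismatch: %d vs %d", nrow(A), nrow(B))
  best <- sqrt(mean(rowSums((A - B)^2)))
  for (p in automorphisms) {
    best <- min(best, sqrt(mean(rowSums((A - B[p, , drop = FALSE])^2))))
  }
  best
}

#' Pairwise scaffold-RMSD matrix of a pose ensemble
#'
#' @param poses list of `LigandPose`.
#' @param automorphisms optional scaffold symmetry permutations.
#' @return symmetric matrix with pose ids as dimnames.
#' @export
scaffold_rmsd_matrix <- function(poses, automorphisms = NULL) {
  n <- length(poses)
  ids <- vapply(poses, `[[`, "", "pose_id")
  if (anyDuplicated(ids)) stopf("duplicate pose ids in ensemble")
  lens <- vapply(poses, function(p) length(p$scaffold_map), 0L)
  if (length(unique(lens)) != 1L)
    stopf("all poses in one ensemble must share the scaffold length")
  m <- lens[1]
  # stack scaffold coordinates: n x (3m); plain Euclidean distance over the
  # stacked rows equals sqrt(m) * scaffold RMSD
  S <- t(vapply(poses, function(p) as.numeric(scaffold_coords(p)), numeric(3 * m)))
  D <- cross_dist(S, S) / sqrt(m)
  D <- (D + t(D)) / 2
  if (!is.null(automorphisms)) {
    for (p in automorphisms) {
      perm <- as.integer(p)
      Sp <- t(vapply(poses, function(ps) {
        as.numeric(scaffold_coords(ps)[perm, , drop = FALSE])
      }, numeric(3 * m)))
      D <- pmin(D, cross_dist(S, Sp) / sqrt(m))
    }
    D <- pmin(D, t(D))
  }
  diag(D) <- 0
  dimnames(D) <- list(ids, ids)
  D
}

# Agglomerative clustering with deterministic tie-breaking. Returns the
# partition after applying every merge with inter-cluster distance strictly
# below `height`, plus the full merge-height sequence. Ties in the minimum
# are broken by the lexicographically lowest (smallest-member, smallest-member)
# cluster pair, which makes the dendrogram reproducible.
agglomerate_cut <- function(dmat, height, linkage = c("complete", "average")) {
  linkage <- match.arg(linkage)
  n <- nrow(dmat)
  if (any(is.na(dmat))) stopf("distance matrix contains NA/NaN")
  if (max(abs(dmat - t(dmat))) > 1e-9) stopf("distance matrix must be symmetric")
  if (any(abs(diag(dmat)) > 1e-12)) stopf("distance matrix must have zero diagonal")
  D <- (dmat + t(dmat)) / 2   # make float-level symmetry exact

  diag(D) <- Inf
  members <- as.list(seq_len(n))
  sizes <- rep(1L, n)
  active <- rep(TRUE, n)
  rep_member <- seq_len(n)           # smallest original index per cluster
  heights <- numeric(0)
  while (sum(active) > 1L) {
    sub <- D[active, active, drop = FALSE]
    mval <- min(sub)
    if (!is.finite(mval)) break
    if (mval >= height) break
    act_idx <- which(active)
    cand <- which(sub == mval, arr.ind = TRUE)   # exact ties
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pr <- cbind(rep_member[act_idx[cand[, 1]]], rep_member[act_idx[cand[, 2]]])
    pr <- cbind(pmin(pr[, 1], pr[, 2]), pmax(pr[, 1], pr[, 2]))
    pick <- order(pr[, 1], pr[, 2])[1]
    i <- act_idx[cand[pick, 1]]; j <- act_idx[cand[pick, 2]]
    heights <- c(heights, mval)
    # merge j into i
    di <- D[i, ]; dj <- D[j, ]
    newd <- if (linkage == "complete") pmax(di, dj)
    else (sizes[i] * di + sizes[j] * dj) / (sizes[i] + sizes[j])
    D[i, ] <- newd; D[, i] <- newd
    D[i, i] <- Inf
    D[j, ] <- Inf; D[, j] <- Inf
    members[[i]] <- c(members[[i]], members[[j]])
    sizes[i] <- sizes[i] + sizes[j]
    rep_member[i] <- min(rep_member[i], rep_member[j])
    active[j] <- FALSE
  }
  clusters <- members[active]
  list(clusters = clusters, merge_heights = heights)
}

order_clusters <- function(clusters) {
  sz <- lengths(clusters)
  lo <- vapply(clusters, min, 0L)
  clusters[order(-sz, lo)]
}

#' Complete-linkage clustering of a pose RMSD matrix
#'
#' Agglomerative complete linkage cut at `height`: merges with inter-cluster
#' distance strictly below the cutoff are applied, so every output cluster has
#' diameter (max pairwise distance) < `height` <= the diameter bound. Cluster
#' ids are assigned by size descending, ties by lowest member index.
#'
#' @param dmat symmetric distance matrix (zero diagonal), Angstrom.
#' @param height clustering height in Angstrom (default 2.0).
#' @return object of class `PoseClustering`: list with `clusters` (list of
#'   pose-id character vectors), `assignment` (named integer vector),
#'   `merge_heights`, `height_cutoff`.
#' @export
complete_linkage <- function(dmat, height = 2.0) {
  dmat <- as.matrix(dmat)
  ids <- rownames(dmat) %||% as.character(seq_len(nrow(dmat)))
  res <- agglomerate_cut(dmat, height, "complete")
  clusters <- order_clusters(res$clusters)
  cl_ids <- lapply(clusters, function(ix) ids[sort(ix)])
  assignment <- integer(length(ids)); names(assignment) <- ids
  for (k in seq_along(clusters)) assignment[clusters[[k]]] <- k
  structure(list(clusters = cl_ids, assignment = assignment,
                 merge_heights = res$merge_heights, height_cutoff = height),
            class = "PoseClustering")
}

#' @export
print.PoseClustering <- function(x, ...) {
  cat(sprintf("<PoseClustering: %d poses in %d clusters (cut %.2f A)>\n",
              length(x$assignment), length(x$clusters), x$height_cutoff))
  invisible(x)
}

#' Partition clusters into common scaffold clusters (CSCs) and residual
#'
#' A cluster is a CSC when it contains poses of at least `min_distinct`
#' distinct ligands (4 of the 5 docked ligands in the original campaign).
#'
#' @param clustering a `PoseClustering`.
#' @param ligand_of named character vector mapping pose id to ligand id.
#' @param min_distinct minimum number of distinct ligands (default 4).
#' @return list with `csc` and `residual` (each a list of pose-id vectors),
#'   and `is_csc` (logical per cluster of `clustering`).
#' @export
partition_csc <- function(clustering, ligand_of, min_distinct = 4L) {
  miss <- setdiff(unlist(clustering$clusters), names(ligand_of))
  if (length(miss)) stopf("poses without ligand mapping: %s",
                          paste(utils::head(miss, 3), collapse = ", "))
  is_csc <- vapply(clustering$clusters, function(cl)
    length(unique(ligand_of[cl])) >= min_distinct, TRUE)
  list(csc = clustering$clusters[is_csc],
       residual = clustering$clusters[!is_csc],
       is_csc = is_csc)
}

#' Representative (medoid) pose of a cluster
#'
#' The pose minimizing the mean scaffold RMSD to all other cluster members;
#' ties are broken by the lowest pose position in `dmat`'s ordering. This is
#' the well-defined stand-in for "the pose closest to the cluster centroid".
#'
#' @param cluster character vector of pose ids (or integer indices into `dmat`).
#' @param dmat the ensemble distance matrix.
#' @return the medoid pose id.
#' @export
representative_pose <- function(cluster, dmat) {
  if (!length(cluster)) stopf("empty cluster")
  sub <- dmat[cluster, cluster, drop = FALSE]
  if (length(cluster) == 1L) return(cluster[[1]])
  meand <- rowSums(sub) / (length(cluster) - 1L)
  cluster[which.min(meand)]   # which.min takes the first = lowest index on ties
}
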