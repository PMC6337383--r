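#' Pharmacophore screening
#'
#' Conformers are screened against a model by enumerating kind-compatible
#' feature correspondences of size n or n-1 (one omitted feature allowed),
#' pruned by pairwise distance compatibility, rigidly aligned by Kabsch
#' superposition, checked against the model tolerance radii and exclusion
#' volumes, and scored by a fit score that strictly increases with the number
#' of matched features.
#'
#' @name screen
NULL

#' Kabsch superposition
#'
#' Proper rotation (det = +1) and translation minimizing the RMSD of `P`
#' mapped onto `Q`. Reflections are forbidden; point sets must contain at
#' least 3 non-collinear points.
#'
#' @param P,Q n x 3 matrices of corresponding points.
#' @return list with `rotation` (3x3), `translation` (length 3), `rmsd`;
#'   transformed points are `P %*% t(rotation) + translation` (row-wise).
#' @export
kabsch <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (nrow(P) != nrow(Q) || ncol(P) != 3 || ncol(Q) != 3)
    stopf("kabsch: point sets must be equal-size n x 3 matrices")
  if (nrow(P) < 3) stopf("kabsch: need at least 3 points")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  sv <- svd(crossprod(Pc, Qc))
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1))
    stopf("kabsch: degenerate (collinear) point set")
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  Rm <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  moved <- Pc %*% t(Rm)
  list(rotation = Rm, translation = as.numeric(cq - Rm %*% cp),
       rmsd = sqrt(mean(rowSums((moved - Qc)^2))))
}

# Permissive aligner used during matching: handles 1 point (translation),
# 2 points or collinear sets (segment alignment, roll angle unconstrained but
# deterministic), and falls back to kabsch otherwise.
align_points <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  n <- nrow(P)
  if (n == 1L)
    return(list(rotation = diag(3), translation = as.numeric(Q[1, ] - P[1, ]),
                rmsd = 0))
  collinear <- function(M) {
    Mc <- sweep(M, 2, colMeans(M))
    s <- svd(Mc)$d
    s[2] < 1e-9 * max(s[1], 1)
  }
  if (n >= 3L && !collinear(P) && !collinear(Q)) return(kabsch(P, Q))
  # principal-axis alignment for (near-)collinear sets
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  u <- svd(Pc)$v[, 1]; v <- svd(Qc)$v[, 1]
  if (sum((Pc %*% u) * (Qc %*% v)) < 0) v <- -v
  ax <- pracma_cross(u, v)
  Rm <- if (vnorm(ax) < 1e-9) {
    if (sum(u * v) > 0) diag(3) else rotation_matrix(orthogonal_to(u), pi)
  } else rotation_matrix(unit(ax), acos(min(1, max(-1, sum(u * v)))))
  moved <- Pc %*% t(Rm)
  list(rotation = Rm, translation = as.numeric(cq - Rm %*% cp),
       rmsd = sqrt(mean(rowSums((moved - Qc)^2))))
}

pracma_cross <- function(a, b)
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])

orthogonal_to <- function(u) {
  v <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  unit(pracma_cross(u, v))
}

#' Ligand-side feature perception (all potential features)
#'
#' Emits every candidate feature of a conformer irrespective of any protein:
#' an HBD per donor atom, an HBA per acceptor atom, an H per hydrophobic
#' fragment and per halogen, an AR per aromatic ring, PI/NI per charged
#' group. Used to build the conformer side of pharmacophore matching.
#'
#' @param mol a `Molecule` (one conformation).
#' @param rules a [perception_rules()] object (for tolerance radii).
#' @return list of `PharmacophoreFeature`.
#' @export
ligand_features <- function(mol, rules = perception_rules()) {
  xyz <- coords(mol)
  roles <- atom_roles(mol)
  rad <- rules$feature_radius
  feats <- list()
  emit <- function(kind, pos, atoms)
    feats[[length(feats) + 1L]] <<- phore_feature(kind, pos,
                                                  radius = unname(rad[[kind]]),
                                                  ligand_atoms = atoms)
  for (i in which(roles$donor)) emit("HBD", xyz[i, ], i)
  for (i in which(roles$acceptor)) emit("HBA", xyz[i, ], i)
  for (fr in hydrophobic_fragments(mol))
    emit("H", colMeans(xyz[fr, , drop = FALSE]), fr)
  for (ring in aromatic_rings(mol))
    emit("AR", colMeans(xyz[ring, , drop = FALSE]), ring)
  for (grp in charged_groups(mol)) emit(grp$kind, grp$position, grp$atoms)
  feats
}

#' Pharmacophore fit score
#'
#' `10 * N_matched + 9 * max(0, 1 - feature_rmsd / mean matched radius)`:
#' dominated by the matched-feature count (as the n / n-1 hit rule implies),
#' with a geometric bonus for tight fits.
#'
#' @param n_matched number of matched feature pairs.
#' @param feature_rmsd RMSD of aligned matched feature positions, A.
#' @param mean_radius mean tolerance radius of the matched model features, A.
#' @return numeric score.
#' @export
fit_score <- function(n_matched, feature_rmsd, mean_radius) {
  10 * n_matched + 9 * max(0, 1 - feature_rmsd / mean_radius)
}

#' Exclusion-volume check
#'
#' Fails when any aligned conformer heavy atom lies strictly inside any
#' exclusion sphere of the model.
#'
#' @param aligned_atoms n x 3 matrix of aligned heavy-atom coordinates.
#' @param model a `PharmacophoreModel`.
#' @return logical flag (TRUE = passed).
#' @export
check_exclusion <- function(aligned_atoms, model) {
  ev <- model$exclusion_volumes
  if (!nrow(ev)) return(TRUE)
  D <- cross_dist(as.matrix(aligned_atoms),
                  as.matrix(ev[, c("x", "y", "z")]))
  !any(sweep(D, 2, ev$radius, "<"))
}

# enumerate injective kind-compatible assignments of model-feature subset
# `msel` onto conformer features, with pairwise distance-compatibility
# pruning |d_model - d_conf| <= r_i + r_j.
enumerate_assignments <- function(msel, mpos, mrad, mkinds, cpos, ckinds,
                                  prune = TRUE) {
  k <- length(msel)
  cand <- lapply(msel, function(i) which(ckinds == mkinds[i]))
  if (any(!lengths(cand))) return(list())
  Dm <- cross_dist(mpos[msel, , drop = FALSE], mpos[msel, , drop = FALSE])
  Dc <- cross_dist(cpos, cpos)
  out <- list()
  assign_next <- function(depth, chosen) {
    if (depth > k) { out[[length(out) + 1L]] <<- chosen; return(invisible()) }
    for (cj in cand[[depth]]) {
      if (cj %in% chosen) next
      ok <- TRUE
      if (prune && depth > 1L) {
        for (q in seq_len(depth - 1L)) {
          tol <- mrad[msel[depth]] + mrad[msel[q]]
          if (abs(Dm[depth, q] - Dc[cj, chosen[q]]) > tol) { ok <- FALSE; break }
        }
      }
      if (ok) assign_next(depth + 1L, c(chosen, cj))
    }
  }
  assign_next(1L, integer())
  out
}

#' Match one conformer against a pharmacophore model
#'
#' Enumerates kind-compatible correspondences of at least `n - max_omit`
#' model features (distance-compatibility pruned), aligns matched conformer
#' features onto the model by rigid superposition, accepts an alignment when
#' every matched conformer feature lies within its model feature's tolerance
#' radius and no conformer heavy atom violates the exclusion volumes, and
#' returns the acceptance with the highest fit score (ties: more matched
#' features, then lower feature RMSD).
#'
#' @param conformer a `Molecule` or a pre-perceived list of
#'   `PharmacophoreFeature` (then `atoms` must be supplied for the exclusion
#'   check).
#' @param model a `PharmacophoreModel`.
#' @param max_omit maximum number of omitted model features (default 1).
#' @param rules a [perception_rules()] object.
#' @param atoms optional heavy-atom coordinate matrix when `conformer` is a
#'   feature list.
#' @return a `MatchResult` list (fields `n_matched`, `pairs`, `omitted`,
#'   `rotation`, `translation`, `feature_rmsd`, `fit_score`,
#'   `passed_exclusion`) or `NULL` when the conformer is not a hit.
#' @export
match_conformer <- function(conformer, model, max_omit = 1L,
                            rules = perception_rules(), atoms = NULL) {
  if (inherits(conformer, "Molecule")) {
    cf <- ligand_features(conformer, rules)
    atoms <- coords(conformer)[heavy_idx(conformer), , drop = FALSE]
  } else cf <- conformer
  if (!length(cf)) return(NULL)
  n <- length(model$features)
  mkinds <- feature_kinds(model)
  mpos <- feature_positions(model)
  mrad <- feature_radii(model)
  ckinds <- vapply(cf, `[[`, "", "kind")
  cpos <- do.call(rbind, lapply(cf, `[[`, "position"))
  best <- NULL
  better <- function(a, b) {
    if (is.null(b)) return(TRUE)
    if (a$fit_score != b$fit_score) return(a$fit_score > b$fit_score)
    if (a$n_matched != b$n_matched) return(a$n_matched > b$n_matched)
    a$feature_rmsd < b$feature_rmsd
  }
  sizes <- seq.int(n, max(1L, n - max_omit))
  for (k in sizes) {
    subsets <- utils::combn(n, k, simplify = FALSE)
    for (msel in subsets) {
      for (asg in enumerate_assignments(msel, mpos, mrad, mkinds, cpos, ckinds)) {
        P <- cpos[asg, , drop = FALSE]
        Q <- mpos[msel, , drop = FALSE]
        al <- align_points(P, Q)
        moved <- P %*% t(al$rotation) +
          matrix(al$translation, nrow(P), 3, byrow = TRUE)
        dev <- sqrt(rowSums((moved - Q)^2))
        if (any(dev > mrad[msel])) next
        frmsd <- sqrt(mean(dev^2))
        passed <- TRUE
        if (!is.null(atoms)) {
          alat <- as.matrix(atoms) %*% t(al$rotation) +
            matrix(al$translation, nrow(atoms), 3, byrow = TRUE)
          passed <- check_exclusion(alat, model)
        }
        if (!passed) next
        res <- list(n_matched = k, pairs = cbind(model = msel, conformer = asg),
                    omitted = setdiff(seq_len(n), msel),
                    rotation = al$rotation, translation = al$translation,
                    feature_rmsd = frmsd,
                    fit_score = fit_score(k, frmsd, mean(mrad[msel])),
                    passed_exclusion = TRUE)
        if (better(res, best)) best <- res
      }
    }
  }
  best
}

#' Screen a multi-conformer library against one model
#'
#' @param library list of `Molecule` (conformers of one molecule share a
#'   name) or a named list of conformer lists from [group_conformers()].
#' @param model a `PharmacophoreModel`.
#' @param max_omit maximum omitted model features (default 1).
#' @param rules a [perception_rules()] object.
#' @return data.frame of hits (one row per hit molecule: `molecule_id`,
#'   `conformer_id`, `n_matched`, `omitted`, `feature_rmsd`, `fit_score`)
#'   sorted by fit score descending; attribute `matches` holds the raw
#'   `MatchResult` objects.
#' @export
screen_library <- function(library, model, max_omit = 1L,
                           rules = perception_rules()) {
  if (!length(library)) stopf("screen_library: empty library")
  if (inherits(library[[1]], "Molecule")) library <- group_conformers(library)
  rows <- list(); matches <- list()
  for (mol_id in names(library)) {
    confs <- library[[mol_id]]
    best <- NULL; best_conf <- NA_integer_
    for (ci in seq_along(confs)) {
      m <- match_conformer(confs[[ci]], model, max_omit, rules)
      if (!is.null(m) && (is.null(best) || m$fit_score > best$fit_score)) {
        best <- m; best_conf <- ci
      }
    }
    if (!is.null(best)) {
      rows[[length(rows) + 1L]] <- data.frame(
        molecule_id = mol_id, conformer_id = best_conf,
        n_matched = best$n_matched, omitted = length(best$omitted),
        feature_rmsd = best$feature_rmsd, fit_score = best$fit_score)
      matches[[mol_id]] <- best
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(molecule_id = character(), conformer_id = integer(),
               n_matched = integer(), omitted = integer(),
               feature_rmsd = numeric(), fit_score = numeric())
  out <- out[order(-out$fit_score, out$molecule_id), ]
  rownames(out) <- NULL
  attr(out, "matches") <- matches
  out
}

#' Common-hits-approach screening over a model ensemble
#'
#' Each molecule is screened against every model; molecules are ranked by the
#' number of models retrieving them (descending), ties broken by the mean fit
#' score over the hitting models. Molecules hitting no model are excluded.
#'
#' @param library as in [screen_library()].
#' @param models list of `PharmacophoreModel` (at least 2).
#' @param max_omit,rules passed to [screen_library()].
#' @return data.frame with `molecule_id`, `n_models_hit`, `mean_fit`,
#'   ranked best first.
#' @export
cha_screen <- function(library, models, max_omit = 1L,
                       rules = perception_rules()) {
  if (length(models) < 2L) stopf("cha_screen: need at least 2 models")
  if (length(library) && inherits(library[[1]], "Molecule"))
    library <- group_conformers(library)
  tallies <- list()
  for (mi in seq_along(models)) {
    hits <- screen_library(library, models[[mi]], max_omit, rules)
    for (r in seq_len(nrow(hits))) {
      id <- hits$molecule_id[r]
      t0 <- tallies[[id]] %||% list(n = 0L, fits = numeric())
      tallies[[id]] <- list(n = t0$n + 1L, fits = c(t0$fits, hits$fit_score[r]))
    }
  }
  if (!length(tallies))
    return(data.frame(molecule_id = character(), n_models_hit = integer(),
                      mean_fit = numeric()))
  out <- data.frame(molecule_id = names(tallies),
                    n_models_hit = vapply(tallies, `[[`, 0L, "n"),
                    mean_fit = vapply(tallies, function(t) mean(t$fits), 0))
  out <- out[order(-out$n_models_hit, -out$mean_fit, out$molecule_id), ]
  rownames(out) <- NULL
  out
}
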