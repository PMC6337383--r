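#' Pharmacophore features and models
#'
#' A feature is a typed sphere in space: kind (H hydrophobic, HBD donor,
#' HBA acceptor, AR aromatic, PI positive ionizable, NI negative ionizable),
#' position, tolerance radius, optional unit direction (HBD/HBA/AR), the
#' ligand atom set that generated it and the partner residues (provenance).
#' A model is a named list of features plus exclusion-volume spheres marking
#' positions sterically claimed by the protein.
#'
#' @param kind one of `"H"`, `"HBD"`, `"HBA"`, `"AR"`, `"PI"`, `"NI"`.
#' @param position numeric length-3, Angstrom.
#' @param radius tolerance radius, Angstrom (> 0).
#' @param direction optional unit 3-vector (projection direction for vector
#'   features).
#' @param ligand_atoms 1-based ligand atom indices generating the feature.
#' @param partner_residues residue labels on the protein side (provenance).
#' @return `phore_feature()` an object of class `PharmacophoreFeature`.
#' @export
phore_feature <- function(kind, position, radius = 1.5, direction = NULL,
                          ligand_atoms = integer(), partner_residues = character()) {
  if (!kind %in% FEATURE_KINDS)
    stopf("unknown feature kind '%s'", kind)
  if (radius <= 0) stopf("feature radius must be > 0")
  if (!length(ligand_atoms)) stopf("feature needs a non-empty ligand atom set")
  if (!is.null(direction)) {
    if (abs(vnorm(direction) - 1) > 1e-6)
      stopf("feature direction must be unit-norm")
  }
  structure(list(kind = kind, position = as.numeric(position),
                 radius = radius, direction = direction,
                 ligand_atoms = sort(as.integer(ligand_atoms)),
                 partner_residues = partner_residues),
            class = "PharmacophoreFeature")
}

#' @param name model name.
#' @param features list of `PharmacophoreFeature` (at least one).
#' @param exclusion_volumes data.frame with columns `x`, `y`, `z`, `radius`
#'   (may have zero rows).
#' @param provenance free-text source annotation (e.g. frame time).
#' @return `phore_model()` an object of class `PharmacophoreModel`.
#' @rdname phore_feature
#' @export
phore_model <- function(name, features, exclusion_volumes = NULL,
                        provenance = "") {
  if (!length(features)) stopf("a pharmacophore model needs at least one feature")
  if (is.null(exclusion_volumes))
    exclusion_volumes <- data.frame(x = numeric(), y = numeric(),
                                    z = numeric(), radius = numeric())
  structure(list(name = name, features = features,
                 exclusion_volumes = as.data.frame(exclusion_volumes),
                 provenance = provenance),
            class = "PharmacophoreModel")
}

#' @export
print.PharmacophoreModel <- function(x, ...) {
  kinds <- table(feature_kinds(x))
  cat(sprintf("<PharmacophoreModel %s: %s; %d exclusion spheres>\n", x$name,
              paste(sprintf("%d %s", kinds, names(kinds)), collapse = ", "),
              nrow(x$exclusion_volumes)))
  invisible(x)
}

#' Accessors for model feature kinds, positions and radii
#' @param model a `PharmacophoreModel`.
#' @return kinds: character; positions: n x 3 matrix; radii: numeric.
#' @export
feature_kinds <- function(model) vapply(model$features, `[[`, "", "kind")

#' @rdname feature_kinds
#' @export
feature_positions <- function(model)
  do.call(rbind, lapply(model$features, `[[`, "position"))

#' @rdname feature_kinds
#' @export
feature_radii <- function(model) vapply(model$features, `[[`, 0, "radius")

#' Feature signature: kind plus sorted ligand atom set
#'
#' Two features are the same dynamic-pharmacophore entity iff their kind and
#' generating ligand atoms are identical; positions may drift frame to frame.
#' @param feature a `PharmacophoreFeature`.
#' @return character scalar, e.g. `"HBA:4,5"`.
#' @export
feature_signature <- function(feature)
  paste0(feature$kind, ":", paste(feature$ligand_atoms, collapse = ","))

#' @rdname feature_signature
#' @param model a `PharmacophoreModel`.
#' @export
model_signatures <- function(model)
  vapply(model$features, feature_signature, "")

# ---- JSON serialization ---------------------------------------------------

MODEL_KEYS <- c("name", "features", "exclusion_volumes", "provenance")
FEATURE_KEYS <- c("kind", "position", "radius", "direction", "ligand_atoms",
                  "partner_residues")

#' Read / write pharmacophore models as JSON
#'
#' Schema: `{"name": str, "features": [{"kind": "H|HBD|HBA|AR|PI|NI",
#' "position": [x,y,z], "radius": r, "direction": [x,y,z]|null,
#' "ligand_atoms": [i,...], "partner_residues": [s,...]}],
#' "exclusion_volumes": [{"center": [x,y,z], "radius": r}],
#' "provenance": str}`. Atom indices are 1-based. Unknown keys are rejected.
#'
#' @param path JSON file path.
#' @return `read_model_json()`: a `PharmacophoreModel`.
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  extra <- setdiff(names(obj), MODEL_KEYS)
  if (length(extra)) stopf("model JSON: unknown key(s) %s",
                           paste(extra, collapse = ", "))
  feats <- lapply(obj$features, function(f) {
    fx <- setdiff(names(f), FEATURE_KEYS)
    if (length(fx)) stopf("model JSON feature: unknown key(s) %s",
                          paste(fx, collapse = ", "))
    phore_feature(kind = f$kind,
                  position = unlist(f$position),
                  radius = f$radius,
                  direction = if (!is.null(f$direction)) unlist(f$direction),
                  ligand_atoms = unlist(f$ligand_atoms),
                  partner_residues = as.character(unlist(f$partner_residues %||% list())))
  })
  ev <- obj$exclusion_volumes %||% list()
  evdf <- if (length(ev)) {
    centers <- do.call(rbind, lapply(ev, function(e) unlist(e$center)))
    data.frame(x = centers[, 1], y = centers[, 2], z = centers[, 3],
               radius = vapply(ev, `[[`, 0, "radius"))
  } else NULL
  phore_model(obj$name, feats, evdf, obj$provenance %||% "")
}

#' @param model a `PharmacophoreModel`.
#' @rdname read_model_json
#' @return `write_model_json()`: `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  feats <- lapply(model$features, function(f) {
    list(kind = f$kind, position = f$position, radius = f$radius,
         direction = f$direction, ligand_atoms = as.integer(f$ligand_atoms),
         partner_residues = as.character(f$partner_residues))
  })
  ev <- model$exclusion_volumes
  evl <- lapply(seq_len(nrow(ev)), function(i)
    list(center = as.numeric(ev[i, c("x", "y", "z")]), radius = ev$radius[i]))
  obj <- list(name = model$name, features = feats, exclusion_volumes = evl,
              provenance = model$provenance)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Apply a rigid motion to a pharmacophore model
#'
#' @param model a `PharmacophoreModel`.
#' @param rotation 3x3 proper rotation matrix.
#' @param translation length-3 numeric.
#' @return transformed model.
#' @export
transform_model <- function(model, rotation = diag(3), translation = c(0, 0, 0)) {
  model$features <- lapply(model$features, function(f) {
    f$position <- as.numeric(rotation %*% f$position + translation)
    if (!is.null(f$direction)) f$direction <- as.numeric(rotation %*% f$direction)
    f
  })
  if (nrow(model$exclusion_volumes)) {
    ctr <- t(rotation %*% t(as.matrix(model$exclusion_volumes[, c("x", "y", "z")])) +
               translation)
    model$exclusion_volumes[, c("x", "y", "z")] <- ctr
  }
  model
}
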