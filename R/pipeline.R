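#' End-to-end campaign orchestration
#'
#' Runs the full desk-scale analogue of the discovery workflow from a single
#' config: pose clustering -> CSC partition -> SIFt -> per-frame pharmacophore
#' perception -> occupancy -> model clustering / RPM selection -> screening ->
#' consensus scoring -> enrichment validation. Every threshold used is
#' materialized into a JSON-lines run log, and identical config + seed
#' reproduce identical outputs.
#'
#' @name cli_pipeline
NULL

default_config <- function() {
  list(
    seed = 1L,
    out_dir = "pipeline_out",
    poses = list(file = NULL, n_ligands = 5L, poses_per_ligand = 100L,
                 n_clusters = 30L, n_csc = 12L, separation = 6,
                 jitter_sd = 0.3),
    clustering = list(height = 2.0, min_distinct = 4L),
    trajectory = list(file = NULL, n_frames = 200L, jitter_sd = 0.05),
    dynophore = list(major_threshold = 70, similarity_cutoff = 0.5,
                     top_models = 10L),
    screening = list(library_file = NULL, n_decoys = 25L, max_omit = 1L),
    consensus = list(scores_file = NULL),
    validation = list(n_actives = 97L, n_decoys = 5300L, delta = 1,
                      alpha = 20))
}

merge_config <- function(user, defaults = default_config(), path = "config") {
  extra <- setdiff(names(user), names(defaults))
  if (length(extra))
    stopf("%s: unknown key(s) %s", path, paste(extra, collapse = ", "))
  for (k in names(user)) {
    defaults[[k]] <- if (is.list(defaults[[k]]) && is.list(user[[k]]))
      merge_config(user[[k]], defaults[[k]], paste(path, k, sep = "$"))
    else user[[k]]
  }
  defaults
}

#' Load a pipeline config from JSON or YAML
#'
#' Unknown keys are rejected; missing keys take the documented defaults
#' (clustering height 2.0 A, CSC rule 4 distinct ligands, 5 A proximity,
#' 1 omitted feature, model-similarity 0.5, RIE alpha 20).
#'
#' @param path config file (`.json`, `.yaml`/`.yml`) or a named list.
#' @return complete config list.
#' @export
load_config <- function(path) {
  user <- if (is.list(path)) path
  else if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stopf("YAML configs require the 'yaml' package; use JSON instead")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  merge_config(user)
}

# CSV score tables: header molecule_id,conformer_id,score_name,value
read_score_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("molecule_id", "conformer_id", "score_name", "value")
  if (!all(need %in% names(tab)))
    stopf("score table must have columns %s", paste(need, collapse = ","))
  tab
}

#' Run the full pipeline
#'
#' @param config path to a JSON/YAML config or a named list (see
#'   [load_config()]); absent sections run on synthetic defaults.
#' @return invisibly, the run report (also written to `report.json`).
#' @export
run_pipeline <- function(config = list()) {
  cfg <- load_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$out_dir, "run_log.jsonl")
  unlink(log_path)
  log_event <- function(stage, ...) {
    rec <- list(stage = stage, ...)
    cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
        file = log_path, append = TRUE, sep = "")
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  report <- list()
  log_event("config", config = cfg)

  ## 1. poses -----------------------------------------------------------
  ens <- stage("poses", {
    if (!is.null(cfg$poses$file)) {
      mols <- read_sdf(cfg$poses$file)
      poses <- lapply(seq_along(mols), function(i)
        ligand_pose(mols[[i]]$name, sprintf("%s_p%03d", mols[[i]]$name, i),
                    mols[[i]], scaffold_map = seq_len(min(14, hac(mols[[i]])))))
      list(poses = poses, truth = NULL)
    } else do.call(gen_pose_ensemble,
                   c(cfg$poses[names(cfg$poses) != "file"],
                     list(seed = sub_seed(cfg$seed, "poses"))))
  })
  report$n_poses <- length(ens$poses)
  log_event("poses", n_poses = report$n_poses)

  ## 2. scaffold clustering ---------------------------------------------
  cl <- stage("cluster-poses", {
    dmat <- scaffold_rmsd_matrix(ens$poses)
    clustering <- complete_linkage(dmat, height = cfg$clustering$height)
    ligand_of <- stats::setNames(vapply(ens$poses, `[[`, "", "ligand_id"),
                                 vapply(ens$poses, `[[`, "", "pose_id"))
    part <- partition_csc(clustering, ligand_of,
                          min_distinct = cfg$clustering$min_distinct)
    medoids <- vapply(clustering$clusters, representative_pose, "",
                      dmat = dmat)
    tab <- data.frame(
      pose_id = unlist(clustering$clusters),
      cluster_id = rep(seq_along(clustering$clusters),
                       lengths(clustering$clusters)))
    tab$ligand_id <- ligand_of[tab$pose_id]
    tab$is_csc <- rep(part$is_csc, lengths(clustering$clusters))
    tab$is_medoid <- tab$pose_id %in% medoids
    utils::write.csv(tab, file.path(cfg$out_dir, "clusters.csv"),
                     row.names = FALSE)
    list(clustering = clustering, part = part, dmat = dmat, table = tab)
  })
  report$n_clusters <- length(cl$clustering$clusters)
  report$n_csc <- sum(cl$part$is_csc)
  report$n_csc_poses <- length(unlist(cl$part$csc))
  report$n_residual_poses <- length(unlist(cl$part$residual))
  log_event("cluster-poses", height = cfg$clustering$height,
            min_distinct = cfg$clustering$min_distinct,
            n_clusters = report$n_clusters, n_csc = report$n_csc)

  ## 3. SIFt over the in-pocket cluster ---------------------------------
  pocket <- gen_toy_pocket()
  sift <- stage("sift", {
    in_pocket <- cl$clustering$clusters[[
      which.max(vapply(cl$clustering$clusters, length, 0L))]]
    sel <- ens$poses[vapply(ens$poses, `[[`, "", "pose_id") %in% in_pocket]
    prof <- sift_profile(sel, pocket$protein)
    utils::write.csv(prof, file.path(cfg$out_dir, "sift.csv"),
                     row.names = FALSE)
    prof
  })
  log_event("sift", proximity_cutoff = perception_rules()$contact_dist,
            n_residues = nrow(sift))

  ## 4. dynamic pharmacophores ------------------------------------------
  dyn <- stage("dynophore", {
    frames <- if (!is.null(cfg$trajectory$file))
      read_pdb(cfg$trajectory$file)
    else gen_trajectory(pocket, n_frames = cfg$trajectory$n_frames,
                        jitter_sd = cfg$trajectory$jitter_sd,
                        seed = sub_seed(cfg$seed, "traj"))$frames
    models <- perceive_frames(frames)
    prof <- occupancy_profile(models,
                              major_threshold = cfg$dynophore$major_threshold)
    utils::write.csv(prof, file.path(cfg$out_dir, "occupancy.csv"),
                     row.names = FALSE)
    list(models = models, profile = prof,
         evs = evs_stats(models[!vapply(models, is.null, TRUE)]))
  })
  report$n_frames <- length(dyn$models)
  report$n_major_features <- sum(dyn$profile$class == "major")
  report$mean_evs <- dyn$evs$mean
  log_event("dynophore", n_frames = report$n_frames,
            major_threshold = cfg$dynophore$major_threshold,
            mean_evs = report$mean_evs)

  ## 5. model clustering / RPMs -----------------------------------------
  rpms <- stage("cluster-models", {
    keep <- dyn$models[!vapply(dyn$models, is.null, TRUE)]
    mc <- cluster_models(keep,
                         similarity_cutoff = cfg$dynophore$similarity_cutoff,
                         top = cfg$dynophore$top_models)
    rpm_dir <- file.path(cfg$out_dir, "rpm")
    dir.create(rpm_dir, showWarnings = FALSE)
    for (i in seq_along(mc$rpm_models))
      write_model_json(mc$rpm_models[[i]],
                       file.path(rpm_dir, sprintf("rpm%02d.json", i)))
    mc
  })
  report$n_model_clusters <- length(rpms$clusters)
  log_event("cluster-models",
            similarity_cutoff = cfg$dynophore$similarity_cutoff,
            n_clusters = report$n_model_clusters)

  ## 6. screening against the top RPM ------------------------------------
  hits <- stage("screen", {
    library <- if (!is.null(cfg$screening$library_file))
      read_sdf(cfg$screening$library_file)
    else c(gen_decoy_library(cfg$screening$n_decoys,
                             seed = sub_seed(cfg$seed, "lib")),
           list(pocket$ligand))
    model <- rpms$rpm_models[[1]]
    h <- screen_library(library, model, max_omit = cfg$screening$max_omit)
    utils::write.csv(h, file.path(cfg$out_dir, "hits.csv"), row.names = FALSE)
    h
  })
  report$n_hits <- nrow(hits)
  log_event("screen", max_omit = cfg$screening$max_omit,
            n_hits = report$n_hits)

  ## 7. consensus ranking -------------------------------------------------
  ranked <- stage("consensus", {
    if (nrow(hits)) {
      recs <- data.frame(molecule_id = hits$molecule_id, fit = hits$fit_score)
      if (!is.null(cfg$consensus$scores_file)) {
        tab <- read_score_table(cfg$consensus$scores_file)
        wide <- stats::reshape(tab[, c("molecule_id", "score_name", "value")],
                               idvar = "molecule_id",
                               timevar = "score_name", direction = "wide")
        names(wide) <- sub("^value\\.", "", names(wide))
        recs <- merge(recs, wide, by = "molecule_id", all.x = TRUE)
      } else {
        # engine scores unavailable: draw surrogate docking scores so the
        # stage exercises Eq.-style min-max consensus end to end
        recs <- with_seed(sub_seed(cfg$seed, "dock"), {
          recs$chemplp <- stats::rnorm(nrow(recs), 60, 8)
          recs$goldscore <- stats::rnorm(nrow(recs), 40, 6)
          recs
        })
      }
      recs <- consensus_score(recs)
      recs <- recs[order(-recs$consensus), ]
    } else recs <- data.frame()
    utils::write.csv(recs, file.path(cfg$out_dir, "ranked.csv"),
                     row.names = FALSE)
    recs
  })
  report$top_ranked <- if (nrow(ranked)) ranked$molecule_id[1] else NA

  ## 8. enrichment validation --------------------------------------------
  val <- stage("validate", {
    pop <- gen_screening_population(cfg$validation$n_actives,
                                    cfg$validation$n_decoys,
                                    delta = cfg$validation$delta,
                                    seed = sub_seed(cfg$seed, "enrich"))
    a <- pop$score[pop$class == "active"]
    d <- pop$score[pop$class == "decoy"]
    lab <- pop$class[order(-pop$score)] == "active"
    list(auc = roc_auc(a, d), rie = rie(lab, alpha = cfg$validation$alpha))
  })
  report$auc <- val$auc
  report$rie <- val$rie
  log_event("validate", alpha = cfg$validation$alpha, auc = val$auc,
            rie = val$rie)

  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(report)
}

#' Perceive pharmacophore models for every frame
#'
#' @param frames list of `TrajectoryFrame`.
#' @param rules a [perception_rules()] object.
#' @param on_empty `"null"` records frames with no perceivable feature as
#'   `NULL` (they still count toward occupancy denominators); `"error"`
#'   propagates the perception error.
#' @return list of `PharmacophoreModel` (or `NULL`), frame-ordered.
#' @export
perceive_frames <- function(frames, rules = perception_rules(),
                            on_empty = c("null", "error")) {
  on_empty <- match.arg(on_empty)
  lapply(frames, function(fr) {
    tryCatch(perceive_features(fr, rules), error = function(e) {
      if (on_empty == "error") stop(e)
      NULL
    })
  })
}
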