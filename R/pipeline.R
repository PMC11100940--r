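## End-to-end orchestration: confirm -> cluster -> refine -> propose ->
## features -> predict -> statistics, plus cohort-level evaluation against
## synthetic ground truth.

fnv1a_hash <- function(s) {
  # small stable content hash (multiplicative, modulo a Mersenne prime)
  bytes <- utf8ToInt(s)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Pipeline configuration
#'
#' All tunable constants of the pipeline in one place, with the defaults
#' used throughout the package (distances in um). The configuration hash is
#' stamped into every pipeline result for provenance.
#'
#' @param ... Overrides for any of the defaults (see the function body for
#'   names and values).
#' @return A named list of class `pipeline_config` with a `hash` attribute.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    min_area_um2 = 100,          # smallest component kept as a candidate
    tolerance_um = 20,           # bile-duct co-occurrence dilation
    eps_um = 25,                 # DBSCAN radius (mean cell size)
    min_pts = 3,                 # DBSCAN minimum neighbourhood
    band_um = 50,                # lymphocyte search band around the portal
    touch_um = 7,                # cluster-portal contact tolerance
    max_edge_um = 20,            # Delaunay edge cutoff (min hepatocyte size)
    window_um = 50,              # chord-test window (2x hepatocyte diameter)
    depth_min_um = 3,            # chord incursion depth threshold
    guard_px = 2,                # chord endpoint guard
    min_nonprotruding_um = 10,   # minimum quiet-run span
    enclosure_band_um = 25,      # hepatocyte band for the enclosure test
    dilate_um = 25,              # cell dilation for neighbour lymphocytes
    marker_sep_um = 10,          # watershed marker separation
    proj_dist_um = 10,           # projection gate for f3 / f13
    footprint_um = 7,            # lymphocyte footprint on the boundary (f3)
    curvature_step_um = 5,       # Menger triplet spacing (f5)
    glcm_levels = 32,
    glcm_dists_um = c(3, 5),
    glcm_min_px = 50,
    quantization = 0.05,         # mode bin width for ratio statistics
    w = 3,                       # WCE positive class weight
    mlp_hidden = c(16L, 8L),
    mlp_lr = 1e-3,
    mlp_epochs = 500L,
    mlp_seed = 1L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config entries: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  attr(cfg, "hash") <- fnv1a_hash(jsonlite::toJSON(cfg, auto_unbox = TRUE,
                                                   digits = 10))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the detection pipeline on one scene
#'
#' Executes portal confirmation, lymphocyte clustering, boundary
#' refinement, protruding-region proposal, feature extraction, and (when a
#' trained model is supplied) region classification and ratio statistics.
#'
#' @param scene A [scene_masks()] object.
#' @param model Optional trained [train_mlp()] model.
#' @param config A [pipeline_config()].
#' @return An object of class `periportal_result` with elements `portals`
#'   (refined, confirmed only), `proposals`, `cells`, `features`,
#'   `predictions`, `ratios`, `statistics`, `log`, `config_hash`.
#' @export
run_scene_pipeline <- function(scene, model = NULL, config = pipeline_config()) {
  stopifnot(inherits(scene, "scene_masks"))
  scale <- scene$scale
  cand <- portal_regions(scene$portal, scale, config$min_area_um2)
  cand <- confirm_portals(cand, scene$bile_duct, scale, config$tolerance_um)
  confirmed <- Filter(function(p) isTRUE(p$confirmed), cand)
  lymph <- mask_centroids(scene$lymphocyte)
  portals <- list(); proposals <- list(); cells_list <- list()
  feats <- list()
  for (i in seq_along(confirmed)) {
    p <- confirmed[[i]]
    p$id <- i
    cl <- cluster_periportal_lymphocytes(lymph, p, scale, config$eps_um,
                                         config$min_pts, config$band_um,
                                         config$touch_um)
    p <- refine_portal_boundary(p, cl, scale, config$max_edge_um)
    prop <- propose_regions(p, scale, config$window_um, config$depth_min_um,
                            config$guard_px, config$min_nonprotruding_um)
    cells <- find_enclosed_hepatocytes(scene, p, scale, lymph,
                                       config$enclosure_band_um,
                                       config$dilate_um,
                                       config$marker_sep_um)
    ft <- region_features(prop, p, scene, cells, scale)
    portals[[i]] <- p
    proposals[[i]] <- prop
    cells_list[[i]] <- cells
    feats[[i]] <- ft
  }
  features <- if (length(feats)) do.call(rbind, feats) else data.frame()
  res <- structure(list(
    portals = portals, proposals = proposals, cells = cells_list,
    features = features, predictions = NULL, ratios = NULL,
    statistics = NULL, scale = scale,
    config_hash = attr(config, "hash"),
    log = list(n_candidates = length(cand), n_confirmed = length(confirmed),
               n_lymphocytes = nrow(lymph),
               n_regions = sum(features$kind == "protruding"),
               n_segments = sum(features$kind == "non_protruding"))
  ), class = "periportal_result")
  if (!is.null(model) && nrow(features)) {
    res <- classify_result(res, model)
  }
  res
}

#' Attach predictions and ratio statistics to a pipeline result
#'
#' @param result A `periportal_result` (from [run_scene_pipeline()]).
#' @param model A trained `wce_mlp`.
#' @param quantization Mode bin width for [scene_statistics()].
#' @return The result with `predictions`, `ratios` and `statistics` filled.
#' @export
classify_result <- function(result, model, quantization = 0.05) {
  if (!nrow(result$features)) return(result)
  result$predictions <- predict_regions(model, result$features)
  ratios <- lapply(result$portals, function(p) {
    portal_ratio(result$predictions[result$predictions$portal_id == p$id, ,
                                    drop = FALSE], p)
  })
  result$ratios <- do.call(rbind, lapply(ratios, as.data.frame))
  result$statistics <- if (nrow(result$ratios))
    scene_statistics(result$ratios, quantization) else NULL
  result
}

#' @export
print.periportal_result <- function(x, ...) {
  cat("<periportal_result>\n")
  cat(sprintf("  portals: %d confirmed of %d candidates; %d protruding regions, %d quiet segments\n",
              x$log$n_confirmed, x$log$n_candidates, x$log$n_regions,
              x$log$n_segments))
  if (!is.null(x$statistics)) {
    s <- x$statistics
    cat(sprintf("  ratios: S_avg %.3f, S_mdt %.3f, S_avg25 %.3f, median %.3f, mode %.2f\n",
                s$S_avg, s$S_mdt, s$S_avg25, s$median, s$mode))
  }
  invisible(x)
}

#' Write pipeline outputs to disk
#'
#' Writes `features.csv`, `predictions.csv` (when present), `stats.json`
#' and a GeoJSON of the proposed regions with their labels. Outputs are
#' byte-stable for a fixed scene, model and config.
#'
#' @param result A `periportal_result`.
#' @param dir Output directory.
#' @return Invisibly, the written paths.
#' @export
write_result <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(features = file.path(dir, "features.csv"))
  utils::write.csv(result$features, paths["features"], row.names = FALSE)
  if (!is.null(result$predictions)) {
    paths["predictions"] <- file.path(dir, "predictions.csv")
    utils::write.csv(result$predictions, paths["predictions"], row.names = FALSE)
    paths["stats"] <- file.path(dir, "stats.json")
    jsonlite::write_json(
      c(result$statistics, list(config_hash = result$config_hash)),
      paths["stats"], auto_unbox = TRUE, digits = 10)
  }
  polys <- list(); props <- list()
  for (i in seq_along(result$proposals)) {
    for (r in result$proposals[[i]]$regions) {
      polys[[length(polys) + 1L]] <- r$polygon
      props[[length(props) + 1L]] <- data.frame(
        portal_id = r$portal_id, region_id = r$region_id, kind = "protruding",
        contour_length_um = r$contour_length_um, area_um2 = r$area_um2)
    }
  }
  if (length(polys)) {
    paths["geojson"] <- file.path(dir, "regions.geojson")
    geojson_polygons(polys, do.call(rbind, props), paths["geojson"])
  }
  invisible(paths)
}

## --- truth matching and cohort evaluation ---------------------------------

match_portal_to_truth <- function(portal, truth) {
  idx <- which(portal$mask != 0)
  cr <- mean(((idx - 1L) %% nrow(portal$mask)) + 1L)
  cc <- mean(((idx - 1L) %/% nrow(portal$mask)) + 1L)
  cent <- vapply(truth$portals, function(tp) tp$center, numeric(2))
  which.min((cent[1, ] - cr)^2 + (cent[2, ] - cc)^2)
}

region_truth_label <- function(arc_points, tp, scale_um) {
  # TRUE when the arc covers at least half of some planted infiltrated
  # bump's boundary span: detection is judged per bump, so the quiet
  # flanks a region absorbs around a bump do not dilute its label
  spans <- tp$bumps[tp$bumps$infiltrated, , drop = FALSE]
  if (!nrow(spans)) return(FALSE)
  th <- atan2(-(arc_points[, 1] - tp$center[1]), arc_points[, 2] - tp$center[2])
  seg <- sqrt(rowSums(diff(arc_points)^2)) * scale_um
  step <- c(seg, 0) / 2 + c(0, seg) / 2       # arc length carried per point
  for (s in seq_len(nrow(spans))) {
    inb <- wrap_angle(th - spans$theta_lo[s]) >= 0 &
           wrap_angle(th - spans$theta_hi[s]) <= 0
    if (spans$arc_um[s] > 0 && sum(step[inb]) >= 0.5 * spans$arc_um[s]) {
      return(TRUE)
    }
  }
  FALSE
}

#' Assign ground-truth labels to proposed regions
#'
#' A proposed region (or quiet segment) is truth-infiltrated when its arc
#' covers at least half of the boundary span of some planted infiltrated
#' bump of the matching truth portal — i.e. labels are detection-level,
#' per bump, unaffected by how much quiet boundary the partition attaches
#' around the bump.
#'
#' @param result A `periportal_result` from a synthetic scene.
#' @param truth The matching `truth` record from [generate_scene()].
#' @return The result's feature table with a logical `truth_infiltrated`
#'   column.
#' @export
label_regions_by_truth <- function(result, truth) {
  ft <- result$features
  if (!nrow(ft)) return(ft)
  um <- result$scale$microns_per_pixel
  ft$truth_infiltrated <- FALSE
  for (i in seq_along(result$portals)) {
    tp <- truth$portals[[match_portal_to_truth(result$portals[[i]], truth)]]
    prop <- result$proposals[[i]]
    for (r in prop$regions) {
      sel <- ft$portal_id == i & ft$kind == "protruding" &
             ft$region_id == r$region_id
      ft$truth_infiltrated[sel] <- region_truth_label(r$arc_points, tp, um)
    }
    for (s in prop$segments) {
      sel <- ft$portal_id == i & ft$kind == "non_protruding" &
             ft$region_id == s$segment_id
      ft$truth_infiltrated[sel] <- region_truth_label(s$arc_points, tp, um)
    }
  }
  ft
}

f1_score <- function(truth, pred) {
  tp <- sum(truth & pred); fp <- sum(!truth & pred); fn <- sum(truth & !pred)
  if (tp == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

#' Evaluate the full pipeline on a synthetic cohort
#'
#' Runs proposal and feature extraction on every scene, assigns truth
#' labels, trains the WCE MLP with two-fold cross-prediction over scenes
#' (so every region is scored by a model that never saw its scene), and
#' reports the region-level F1 of the protruding-region classifier plus
#' the Spearman correlation between the planted grade and the per-scene
#' S_avg statistic computed from the predictions.
#'
#' @param cohort A cohort from [generate_cohort()].
#' @param config A [pipeline_config()].
#' @param w Class weight for training, default `config$w`.
#' @param seed Seed for MLP initialisation.
#' @return `list(f1, spearman, p_value, per_scene, features, models)`.
#' @export
evaluate_cohort <- function(cohort, config = pipeline_config(), w = config$w,
                            seed = 1L) {
  n <- length(cohort)
  results <- vector("list", n)
  tables <- vector("list", n)
  for (i in seq_len(n)) {
    res <- run_scene_pipeline(cohort[[i]]$scene, model = NULL, config = config)
    ft <- label_regions_by_truth(res, cohort[[i]]$truth)
    if (nrow(ft)) ft$scene <- i
    results[[i]] <- res
    tables[[i]] <- ft
  }
  all_ft <- do.call(rbind, tables[vapply(tables, nrow, integer(1)) > 0])
  folds <- list(which(seq_len(n) %% 2L == 1L), which(seq_len(n) %% 2L == 0L))
  models <- list()
  pred_rows <- vector("list", n)
  per_scene <- data.frame(scene = seq_len(n),
                          grade = vapply(cohort, function(s) s$truth$grade, numeric(1)),
                          S_avg = NA_real_, S_mdt = NA_real_,
                          S_avg25 = NA_real_, median = NA_real_,
                          true_ratio = vapply(cohort, function(s)
                            s$truth$statistics$S_avg, numeric(1)))
  for (f in 1:2) {
    train_scenes <- folds[[3L - f]]
    test_scenes <- folds[[f]]
    tr <- all_ft[all_ft$scene %in% train_scenes & all_ft$kind == "protruding", ]
    models[[f]] <- train_mlp(tr, as.integer(tr$truth_infiltrated), w = w,
                             seed = seed, hidden = config$mlp_hidden,
                             lr = config$mlp_lr, epochs = config$mlp_epochs)
    for (i in test_scenes) {
      if (is.null(tables[[i]]) || !nrow(tables[[i]])) next
      res <- classify_result(results[[i]], models[[f]], config$quantization)
      pr <- res$predictions
      pr$scene <- i
      pr$truth_infiltrated <- tables[[i]]$truth_infiltrated
      pred_rows[[i]] <- pr
      if (!is.null(res$statistics)) {
        per_scene[i, c("S_avg", "S_mdt", "S_avg25", "median")] <-
          unlist(res$statistics[c("S_avg", "S_mdt", "S_avg25", "median")])
      }
    }
  }
  preds <- do.call(rbind, pred_rows[!vapply(pred_rows, is.null, logical(1))])
  prot <- preds[preds$kind == "protruding" & !is.na(preds$label), ]
  f1 <- f1_score(prot$truth_infiltrated, prot$label == "infiltrated")
  ct <- correlate_statistic(per_scene$S_avg, per_scene$grade, "numerical")
  list(f1 = f1, spearman = ct$estimate, p_value = ct$p_value,
       per_scene = per_scene, features = all_ft, predictions = preds,
       models = models)
}
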