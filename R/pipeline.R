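#' Default pipeline configuration
#'
#' Nested list of every tunable parameter with its default. Unknown keys
#' in a user configuration are rejected by [load_config()] /
#' [run_pipeline()].
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(
    input = list(mask_dir = NULL, metadata_csv = NULL,
                 annotations_json = NULL),
    segmentation = list(binarize_threshold = 127, min_area = 60,
                        connectivity = 8, border_policy = "keep"),
    morphometry = list(opening_radius = 6, sholl_step = 10,
                       diagonal_weight = FALSE),
    rfe = list(target = "group", n_keep = NULL, seed = 1, ntree = 100),
    umap = list(n_neighbors = 10, min_dist = 0.1, n_components = 2,
                seed = 1, scale = TRUE),
    hdbscan = list(min_cluster_size = 20, min_samples = 10),
    spatial = list(bin_start = 0.48, bin_width = 0.24),
    stats = list(residuals = "pearson", p_adjust = "none"),
    output = list(dir = "gliaclust_run", gallery = FALSE)
  )
}

merge_config <- function(user, defaults, path = character()) {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    config_error("unknown config key(s): ",
                 paste(paste(c(path, ""), collapse = "."), unknown,
                       sep = "", collapse = ", "))
  }
  for (k in names(user)) {
    defaults[[k]] <- if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      merge_config(user[[k]], defaults[[k]], c(path, k))
    } else {
      user[[k]]
    }
  }
  defaults
}

#' Load and validate a YAML pipeline configuration
#'
#' Reads a YAML file, checks every key against [default_config()]
#' (unknown keys are an error) and fills in defaults.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @param overrides Optional named list merged on top of the file.
#' @return Validated configuration list.
#' @export
load_config <- function(path = NULL, overrides = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) config_error("config file not found: ", path)
    user <- yaml::read_yaml(path)
    cfg <- merge_config(user, cfg)
  }
  if (!is.null(overrides)) cfg <- merge_config(overrides, cfg)
  cfg
}

log_line <- function(log_path, ...) {
  msg <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ...)
  cat(msg, "\n", sep = "", file = log_path, append = TRUE)
  message(msg)
}

run_stage <- function(name, log_path, expr) {
  tryCatch(expr, error = function(e) {
    log_line(log_path, "stage ", name, " FAILED: ", conditionMessage(e))
    stop(errorCondition(
      paste0("stage '", name, "' failed: ", conditionMessage(e)),
      class = c(class(e)[1], "gliaclust_stage_error", "error")))
  })
}

#' Run the five-stage pipeline
#'
#' Orchestrates morphometry, feature selection, UMAP embedding, HDBSCAN
#' clustering, and spatial mapping/statistics over a directory of binary
#' mask images. Every stage writes its artifact into the run directory
#' (`features.csv`, `selection.csv`, `embedding.csv`, `clusters.csv`,
#' `painted/*.png`, `spatial_*.csv`, `chisq.json`, heatmap CSVs) together
#' with the resolved `config.yaml` and a `run.log` recording versions,
#' seeds, and per-stage cell counts. With `resume = TRUE` a stage whose
#' output file already exists is skipped and its CSV is read back, so a
#' run can be restarted from any stage.
#'
#' @param config Configuration list (see [default_config()]) or a path to
#'   a YAML file.
#' @param resume Reuse existing stage outputs (default FALSE).
#' @return Invisibly, a list with the run directory and the main in-memory
#'   artifacts (`features`, `selection`, `embedding`, `clusters`,
#'   `contingency`, `chisq`).
#' @export
run_pipeline <- function(config = default_config(), resume = FALSE) {
  if (is.character(config)) config <- load_config(config)
  config <- merge_config(config, default_config())
  if (is.null(config$input$mask_dir)) config_error("input$mask_dir is required")
  out_dir <- config$output$dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  yaml::write_yaml(config, file.path(out_dir, "config.yaml"))
  log_line(log_path, "gliaclust ", as.character(utils::packageVersion("gliaclust")),
           " | R ", paste(R.version$major, R.version$minor, sep = "."))
  log_line(log_path, "seeds: rfe=", config$rfe$seed, " umap=", config$umap$seed)

  masks <- sort(list.files(config$input$mask_dir, "\\.(tiff?|png)$",
                           full.names = TRUE, ignore.case = TRUE))
  if (!length(masks)) data_error("no mask images in ", config$input$mask_dir)
  md <- NULL
  if (!is.null(config$input$metadata_csv)) {
    md <- read_image_metadata(config$input$metadata_csv)
  }

  feat_path <- file.path(out_dir, "features.csv")
  cells_all <- NULL
  if (resume && file.exists(feat_path)) {
    features <- utils::read.csv(feat_path, stringsAsFactors = FALSE)
    log_line(log_path, "stage features: resumed from ", feat_path,
             " (", nrow(features), " cells)")
  } else {
    features <- run_stage("features", log_path, {
      tabs <- list()
      cells_all <- list()
      for (f in masks) {
        id <- tools::file_path_sans_ext(basename(f))
        grp <- NA_character_; lat <- NA_real_
        if (!is.null(md) && id %in% md$image_id) {
          row <- md[md$image_id == id, ][1, ]
          grp <- row$group; lat <- row$lateral_mm
        }
        img <- load_mask(f, binarize_threshold = config$segmentation$binarize_threshold,
                         group = grp, lateral_mm = lat)
        cells <- segment_cells(img, min_area = config$segmentation$min_area,
                               connectivity = config$segmentation$connectivity,
                               border_policy = config$segmentation$border_policy)
        log_line(log_path, "  image ", id, ": ", length(cells), " cells")
        if (isTRUE(config$output$gallery)) {
          write_cell_gallery(cells, file.path(out_dir, "gallery", id))
        }
        cells_all[[id]] <- cells
        tabs[[id]] <- extract_feature_table(
          cells, morpho_config(opening_radius = config$morphometry$opening_radius,
                               sholl_step = config$morphometry$sholl_step,
                               diagonal_weight = config$morphometry$diagonal_weight))
      }
      ft <- do.call(rbind, tabs)
      rownames(ft) <- NULL
      utils::write.csv(ft, feat_path, row.names = FALSE)
      log_line(log_path, "stage features: ", nrow(ft), " cells x ",
               length(feature_columns(ft)), " features")
      ft
    })
  }

  sel_path <- file.path(out_dir, "selection.csv")
  sel <- run_stage("selection", log_path, {
    s <- select_features(features, target = config$rfe$target,
                         n_keep = config$rfe$n_keep, seed = config$rfe$seed,
                         ntree = config$rfe$ntree)
    utils::write.csv(selection_report(s, feature_columns(features)), sel_path,
                     row.names = FALSE)
    log_line(log_path, "stage selection: kept ", s$n_keep, " of ",
             length(feature_columns(features)), " features")
    s
  })

  emb_path <- file.path(out_dir, "embedding.csv")
  if (resume && file.exists(emb_path)) {
    emb_df <- utils::read.csv(emb_path, stringsAsFactors = FALSE)
    coords <- as.matrix(emb_df[, grep("^umap", names(emb_df)), drop = FALSE])
    emb <- structure(list(coords = coords, params = config$umap),
                     class = "glia_embedding")
    log_line(log_path, "stage embedding: resumed from ", emb_path)
  } else {
    emb <- run_stage("embedding", log_path, {
      e <- embed_features(features, features = sel$selected_features,
                          n_neighbors = config$umap$n_neighbors,
                          min_dist = config$umap$min_dist,
                          n_components = config$umap$n_components,
                          seed = config$umap$seed, scale = config$umap$scale)
      utils::write.csv(cbind(data.frame(cell_id = features$cell_id),
                             as.data.frame(e$coords)),
                       emb_path, row.names = FALSE)
      log_line(log_path, "stage embedding: ", nrow(e$coords), " cells -> ",
               ncol(e$coords), "D")
      e
    })
  }

  clu_path <- file.path(out_dir, "clusters.csv")
  clusters <- run_stage("clustering", log_path, {
    cl <- cluster_cells(emb, min_cluster_size = config$hdbscan$min_cluster_size,
                        min_samples = config$hdbscan$min_samples)
    utils::write.csv(data.frame(cell_id = features$cell_id,
                                cluster = cl$labels),
                     clu_path, row.names = FALSE)
    log_line(log_path, "stage clustering: ", length(cl$cluster_sizes),
             " clusters, ", sum(cl$labels == -1L), " noise of ",
             length(cl$labels), " cells")
    cl
  })
  labels <- stats::setNames(clusters$labels, features$cell_id)

  run_stage("spatial", log_path, {
    if (!is.null(cells_all)) {
      pdir <- file.path(out_dir, "painted")
      dir.create(pdir, showWarnings = FALSE)
      for (id in names(cells_all)) {
        cells <- cells_all[[id]]
        if (!length(cells)) next
        shape <- cells[[1]]$image_shape
        canvas <- paint_clusters(shape, cells, labels)
        png::writePNG(canvas, file.path(pdir, paste0(id, ".png")))
      }
      ann <- NULL
      if (!is.null(config$input$annotations_json)) {
        ann <- read_layer_annotations(config$input$annotations_json)
        lc <- list()
        for (id in intersect(names(cells_all), names(ann))) {
          if (!length(cells_all[[id]])) next
          lc[[id]] <- count_by_layer(cells_all[[id]], labels, ann[[id]])
        }
        if (length(lc)) {
          layer_counts <- do.call(rbind, lc)
          utils::write.csv(layer_counts,
                           file.path(out_dir, "spatial_layers.csv"),
                           row.names = FALSE)
          grps <- unique(layer_counts$group)
          if (length(grps) >= 2) {
            rt <- layer_rank_tests(layer_counts, grps[1], grps[2],
                                   p_adjust = config$stats$p_adjust)
            utils::write.csv(rt, file.path(out_dir, "rank_tests.csv"),
                             row.names = FALSE)
          }
        }
      }
      flat <- unlist(cells_all, recursive = FALSE)
      if (any(!is.na(vapply(flat, function(x) x$lateral_mm, 0)))) {
        bins <- count_by_lateral_bin(flat, labels,
                                     bin_start = config$spatial$bin_start,
                                     bin_width = config$spatial$bin_width)
        utils::write.csv(bins, file.path(out_dir, "spatial_bins.csv"),
                         row.names = FALSE)
      }
      log_line(log_path, "stage spatial: painted ", length(cells_all), " images")
    } else {
      log_line(log_path, "stage spatial: skipped (resumed without cell rasters)")
    }
    NULL
  })

  stats_out <- run_stage("stats", log_path, {
    res <- list(contingency = NULL, chisq = NULL)
    grps <- unique(features$group[!is.na(features$group)])
    kcl <- length(unique(labels[labels >= 0]))
    if (length(grps) >= 2 && kcl >= 2) {
      ct <- contingency(labels, features$group)
      cs <- chi_square(ct, residuals = config$stats$residuals)
      jsonlite::write_json(
        list(statistic = cs$statistic, df = cs$df, p_value = cs$p_value),
        file.path(out_dir, "chisq.json"), auto_unbox = TRUE, digits = NA)
      utils::write.csv(as.data.frame(as.table(cs$pearson_residuals)),
                       file.path(out_dir, "chisq_residuals.csv"),
                       row.names = FALSE)
      res <- list(contingency = ct, chisq = cs)
      log_line(log_path, "stage stats: chi-square ",
               format(cs$statistic, digits = 6), " (df=", cs$df, ")")
    } else {
      log_line(log_path, "stage stats: skipped chi-square (needs >= 2 groups and clusters)")
    }
    hm_cl <- cluster_heatmap(features[labels >= 0, , drop = FALSE],
                             labels[labels >= 0])
    utils::write.csv(hm_cl$matrix, file.path(out_dir, "heatmap_clusters.csv"))
    if (length(grps) >= 2) {
      hm_gr <- cluster_heatmap(features, features$group)
      utils::write.csv(hm_gr$matrix, file.path(out_dir, "heatmap_groups.csv"))
    }
    res
  })

  log_line(log_path, "run complete: ", out_dir)
  invisible(list(dir = out_dir, features = features, selection = sel,
                 embedding = emb, clusters = clusters,
                 contingency = stats_out$contingency, chisq = stats_out$chisq))
}
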