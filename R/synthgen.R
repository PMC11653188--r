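#' Define a morphology archetype
#'
#' Parametric description of a synthetic microglia-like silhouette: a disk
#' soma with branching random-walk processes. Means and standard
#' deviations are per-cell draws; lengths are in pixels at a nominal 40x
#' scale.
#'
#' @param name Archetype name.
#' @param soma_radius `c(mean, sd)` of the soma radius in px.
#' @param n_processes `c(mean, sd)` of the number of primary processes.
#' @param process_length `c(mean, sd)` of the process length in steps.
#' @param branch_prob Per-step probability that a process splits.
#' @param tortuosity Angular noise per step, radians (sd).
#' @param process_width Process thickness in px (dilation diameter).
#' @return List of class `glia_archetype`.
#' @export
archetype <- function(name, soma_radius, n_processes, process_length,
                      branch_prob = 0.1, tortuosity = 0.3,
                      process_width = 1) {
  stopifnot(length(soma_radius) == 2, soma_radius[1] > 0,
            length(n_processes) == 2, n_processes[1] >= 0,
            length(process_length) == 2, process_length[1] >= 0,
            branch_prob >= 0, branch_prob <= 1, tortuosity >= 0,
            process_width >= 1)
  structure(list(name = name, soma_radius = soma_radius,
                 n_processes = n_processes, process_length = process_length,
                 branch_prob = branch_prob, tortuosity = tortuosity,
                 process_width = process_width),
            class = "glia_archetype")
}

#' Shipped archetype presets
#'
#' Three points along the microglial morphology spectrum, for testing and
#' simulation (they echo the qualitative amoeboid / reactive / ramified
#' phenotypes without claiming biological fidelity):
#' * `amoeboid`: large compact soma, at most stubby protrusions;
#' * `reactive`: medium soma, a few short thick processes;
#' * `ramified`: small soma, many long thin branching processes.
#'
#' @return Named list of [archetype()] objects.
#' @export
archetype_presets <- function() {
  list(
    amoeboid = archetype("amoeboid", soma_radius = c(13, 1.5),
                         n_processes = c(0.3, 0.6), process_length = c(8, 3),
                         branch_prob = 0.02, tortuosity = 0.4,
                         process_width = 3),
    reactive = archetype("reactive", soma_radius = c(10, 1),
                         n_processes = c(3, 1), process_length = c(30, 8),
                         branch_prob = 0.1, tortuosity = 0.35,
                         process_width = 2),
    ramified = archetype("ramified", soma_radius = c(7, 1),
                         n_processes = c(6, 1), process_length = c(65, 12),
                         branch_prob = 0.25, tortuosity = 0.25,
                         process_width = 1)
  )
}

#' Generate one synthetic cell mask
#'
#' Draws a disk soma at the canvas centre and grows processes from the
#' soma rim as pixel random walks: unit steps with Gaussian angular noise
#' (`tortuosity`), splitting with probability `branch_prob` per step
#' (depth-limited), finally dilated to `process_width`. Deterministic for
#' a given seed.
#'
#' @param spec A [archetype()].
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param canvas Canvas side in px, or `NULL` to size it from the spec.
#' @return List: `mask` (binary matrix), `soma` (binary matrix),
#'   `archetype` (name), `n_processes` (ground truth).
#' @export
make_cell <- function(spec, seed = NULL, canvas = NULL) {
  stopifnot(inherits(spec, "glia_archetype"))
  if (!is.null(seed)) set.seed(seed)
  r <- max(3, round(rnorm(1, spec$soma_radius[1], spec$soma_radius[2])))
  npr <- max(0, round(rnorm(1, spec$n_processes[1], spec$n_processes[2])))
  reach <- spec$process_length[1] + 2.5 * spec$process_length[2]
  side <- canvas %||% (2 * ceiling(r + reach + spec$process_width + 4) + 1)
  if (side < 2 * r + 3) {
    config_error("make_cell: canvas side ", side, " too small for soma radius ", r)
  }
  ctr <- (side + 1) / 2
  d2 <- outer((1:side - ctr)^2, (1:side - ctr)^2, `+`)
  soma <- matrix(as.integer(d2 <= r^2), side, side)
  proc <- matrix(0L, side, side)
  if (npr > 0) {
    base_angles <- seq(0, 2 * pi, length.out = npr + 1)[-(npr + 1)] +
      runif(1, 0, 2 * pi)
    # queue of walks: start position, angle, remaining steps, depth
    queue <- lapply(seq_len(npr), function(i) {
      a <- base_angles[i] + runif(1, -0.3, 0.3)
      len <- max(0, round(rnorm(1, spec$process_length[1],
                                spec$process_length[2])))
      list(row = ctr + (r - 0.5) * sin(a), col = ctr + (r - 0.5) * cos(a),
           angle = a, steps = len, depth = 1L)
    })
    total <- npr
    while (length(queue)) {
      wk <- queue[[1]]; queue <- queue[-1]
      row <- wk$row; col <- wk$col; a <- wk$angle
      steps <- wk$steps
      while (steps > 0) {
        row <- row + sin(a); col <- col + cos(a)
        if (row < 2 || row > side - 1 || col < 2 || col > side - 1) break
        proc[round(row), round(col)] <- 1L
        a <- a + rnorm(1, 0, spec$tortuosity)
        steps <- steps - 1
        if (steps > 0 && wk$depth < 3L && total < 24L &&
            runif(1) < spec$branch_prob) {
          total <- total + 1L
          queue[[length(queue) + 1L]] <- list(
            row = row, col = col,
            angle = a + sample(c(-1, 1), 1) * runif(1, 0.5, 1.1),
            steps = round(steps * runif(1, 0.5, 0.9)), depth = wk$depth + 1L)
        }
      }
    }
    if (spec$process_width > 1 && any(proc == 1L)) {
      kern <- EBImage::makeBrush(odd_brush(spec$process_width), shape = "disc")
      proc <- as_binary_matrix(EBImage::dilate(proc, kern))
    }
  }
  mask <- matrix(pmax(soma, proc), side, side)
  list(mask = mask, soma = soma, archetype = spec$name, n_processes = npr)
}

#' Scene specification for the synthetic generator
#'
#' @param canvas `c(height, width)` in px.
#' @param n_cells Named integer vector: cells per archetype.
#' @param min_separation Minimum centroid distance between cells, px.
#' @param seed Master seed; all cell draws and placements derive from it.
#' @param group Study-group label attached to the scene.
#' @param lateral_mm Lateral slice coordinate.
#' @param image_id Image identifier.
#' @return List of class `glia_scene_spec`.
#' @export
scene_spec <- function(canvas = c(512, 512), n_cells = c(ramified = 8),
                       min_separation = 30, seed = 1, group = "A",
                       lateral_mm = NA_real_, image_id = "scene") {
  stopifnot(length(canvas) == 2, all(canvas > 0), !is.null(names(n_cells)))
  structure(list(canvas = as.integer(canvas), n_cells = n_cells,
                 min_separation = min_separation, seed = as.integer(seed),
                 group = group, lateral_mm = lateral_mm,
                 image_id = image_id),
            class = "glia_scene_spec")
}

#' Compose a synthetic mask image from archetype cells
#'
#' Places cells by rejection sampling: a candidate position is accepted
#' when the cell fits the canvas, its centroid is at least
#' `min_separation` from all placed centroids, and its 1-px-dilated mask
#' does not touch existing foreground (so connected-component
#' segmentation recovers exactly the generated cells). Up to 1000
#' placement attempts per cell.
#'
#' @param spec A [scene_spec()].
#' @param archetypes Named list of [archetype()]s covering
#'   `names(spec$n_cells)` (default [archetype_presets()]).
#' @return List: `image` (a `glia_mask`), `truth` (data.frame with
#'   `archetype`, `centroid_row`, `centroid_col`, `n_processes` per
#'   placed cell).
#' @export
make_scene <- function(spec, archetypes = archetype_presets()) {
  stopifnot(inherits(spec, "glia_scene_spec"))
  missing_arch <- setdiff(names(spec$n_cells), names(archetypes))
  if (length(missing_arch)) {
    config_error("make_scene: unknown archetype(s): ",
                 paste(missing_arch, collapse = ", "))
  }
  h <- spec$canvas[1]; w <- spec$canvas[2]
  total <- sum(spec$n_cells)
  seeds <- derive_seeds(spec$seed, 2L * total)
  canvas <- matrix(0L, h, w)
  truth <- list()
  centroids <- matrix(numeric(0), 0, 2)
  idx <- 0L
  set.seed(seeds[1])
  for (arch_name in names(spec$n_cells)) {
    for (j in seq_len(spec$n_cells[[arch_name]])) {
      idx <- idx + 1L
      cellgen <- make_cell(archetypes[[arch_name]], seed = seeds[total + idx])
      cm <- cellgen$mask
      bb <- mask_bbox(cm)
      crop <- cm[(bb[["row0"]] + 1L):bb[["row1"]],
                 (bb[["col0"]] + 1L):bb[["col1"]], drop = FALSE]
      ch <- nrow(crop); cw <- ncol(crop)
      if (ch > h || cw > w) {
        data_error("make_scene: cell larger than canvas; enlarge canvas")
      }
      # 1-px halo around the crop so adjacency across bbox borders is
      # also detected (otherwise two touching cells would merge)
      pc <- matrix(0L, ch + 2L, cw + 2L)
      pc[2:(ch + 1L), 2:(cw + 1L)] <- crop
      dil <- as_binary_matrix(EBImage::dilate(pc, EBImage::makeBrush(3, "box")))
      set.seed(seeds[idx])
      placed <- FALSE
      for (try in seq_len(1000L)) {
        r0 <- sample.int(h - ch + 1L, 1L) - 1L
        c0 <- sample.int(w - cw + 1L, 1L) - 1L
        ctr <- mask_centroid(crop) + c(r0, c0)
        if (nrow(centroids) &&
            min(sqrt((centroids[, 1] - ctr[1])^2 +
                     (centroids[, 2] - ctr[2])^2)) < spec$min_separation) next
        sel_r <- max(1L, r0):min(h, r0 + ch + 1L)
        sel_c <- max(1L, c0):min(w, c0 + cw + 1L)
        if (any(canvas[sel_r, sel_c, drop = FALSE] &
                dil[sel_r - r0 + 1L, sel_c - c0 + 1L, drop = FALSE])) next
        win <- canvas[(r0 + 1L):(r0 + ch), (c0 + 1L):(c0 + cw), drop = FALSE]
        canvas[(r0 + 1L):(r0 + ch), (c0 + 1L):(c0 + cw)] <-
          pmax(win, crop)
        centroids <- rbind(centroids, ctr)
        truth[[idx]] <- data.frame(archetype = cellgen$archetype,
                                   centroid_row = ctr[1], centroid_col = ctr[2],
                                   n_processes = cellgen$n_processes,
                                   stringsAsFactors = FALSE)
        placed <- TRUE
        break
      }
      if (!placed) {
        data_error("make_scene: failed to place cell ", idx,
                   " after 1000 tries; use fewer/smaller cells or a larger canvas")
      }
    }
  }
  list(image = new_glia_mask(canvas, image_id = spec$image_id,
                             group = spec$group, lateral_mm = spec$lateral_mm),
       truth = do.call(rbind, truth))
}

#' Match segmented cells to generator ground truth
#'
#' Pairs each segmented cell with the nearest ground-truth centroid.
#'
#' @param cells List of `glia_cell` records from [segment_cells()].
#' @param truth Truth table from [make_scene()].
#' @return Character vector of archetype names, one per cell.
#' @export
match_truth <- function(cells, truth) {
  vapply(cells, function(cl) {
    d <- sqrt((truth$centroid_row - cl$centroid[["row"]])^2 +
              (truth$centroid_col - cl$centroid[["col"]])^2)
    truth$archetype[which.min(d)]
  }, "")
}

#' Generate a synthetic multi-group dataset on disk
#'
#' Writes one PNG mask per scene plus `metadata.csv`
#' (`image_id,group,lateral_mm`) and `truth.csv` (per-cell archetypes),
#' ready to be consumed by [run_pipeline()]. Group identity shifts the
#' archetype mixture so that supervised feature selection has signal.
#'
#' @param out_dir Output directory.
#' @param mixtures Named list: per group, a named vector of cells per
#'   archetype per scene.
#' @param scenes_per_group Scenes (images) per group.
#' @param canvas Scene canvas `c(h, w)`.
#' @param seed Master seed.
#' @param lateral_range Range of lateral coordinates sampled per scene.
#' @return Paths list: `mask_dir`, `metadata`, `truth`, invisibly.
#' @export
generate_dataset <- function(out_dir,
                             mixtures = list(
                               SS = c(ramified = 7, reactive = 2, amoeboid = 1),
                               SCOP = c(ramified = 2, reactive = 4, amoeboid = 4)),
                             scenes_per_group = 4, canvas = c(600, 600),
                             seed = 1, lateral_range = c(0.48, 1.90)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  md <- list(); tr <- list()
  seeds <- derive_seeds(seed, length(mixtures) * scenes_per_group + 1L)
  set.seed(seeds[length(seeds)])
  lat_all <- round(runif(length(mixtures) * scenes_per_group,
                         lateral_range[1], lateral_range[2]), 2)
  i <- 0L
  for (grp in names(mixtures)) {
    for (s in seq_len(scenes_per_group)) {
      i <- i + 1L
      id <- sprintf("%s_img%02d", grp, s)
      sc <- make_scene(scene_spec(canvas = canvas, n_cells = mixtures[[grp]],
                                  seed = seeds[i], group = grp,
                                  lateral_mm = lat_all[i], image_id = id))
      png::writePNG(sc$image$pixels + 0.0,
                    file.path(out_dir, paste0(id, ".png")))
      md[[i]] <- data.frame(image_id = id, group = grp,
                            lateral_mm = lat_all[i])
      tt <- sc$truth
      tt$image_id <- id
      tr[[i]] <- tt
    }
  }
  mdp <- file.path(out_dir, "metadata.csv")
  trp <- file.path(out_dir, "truth.csv")
  utils::write.csv(do.call(rbind, md), mdp, row.names = FALSE)
  utils::write.csv(do.call(rbind, tr), trp, row.names = FALSE)
  invisible(list(mask_dir = out_dir, metadata = mdp, truth = trp))
}
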