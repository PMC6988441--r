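# Synthetic racecourse fence scenes.
#
# A flat (fronto-parallel) mock-up of the photographic protocol: sky and
# distant vegetation in the upper half, the birch fence body with its
# midrail and optional colour-board patch row, the painted takeoff board
# at the fence base, turf foreground, and the two PTFE reflectance
# standards placed in the foreground. Every region carries a named
# registry material; the ground-truth layer computes each region's cone
# catches and pairwise JNDs purely spectrally, never through the camera.

#' Region layout of the default synthetic scene
#'
#' @param nrow,ncol image size in pixels.
#' @param patches character vector of patch materials for the
#'   colour-board row mounted on the fence body, or `NULL` for none.
#' @return A named list of logical masks plus `region_table`, a data
#'   frame of region name, material slot and fence-mounted flag.
#' @keywords internal
.scene_layout <- function(nrow = 96, ncol = 128, patches = NULL) {
  blank <- function() matrix(FALSE, nrow, ncol)
  rows <- function(m, r, c = seq_len(ncol)) { m[r, c] <- TRUE; m }
  masks <- list(
    background     = rows(blank(), 1:40),
    fence_top_edge = rows(blank(), 41:46),
    fence_body     = rows(blank(), 47:70),
    midrail        = rows(blank(), 58:63),
    takeoff_board  = rows(blank(), 71:76),
    foreground     = rows(blank(), 77:96),
    standard_white = rows(blank(), 80:93, 9:24),
    standard_black = rows(blank(), 80:93, 33:48)
  )
  if (!is.null(patches)) {
    np <- length(patches)
    w <- ncol %/% np
    for (i in seq_len(np)) {
      m <- blank()
      c0 <- (i - 1) * w + 3
      m[48:56, c0:(c0 + w - 5)] <- TRUE
      masks[[paste0("patch_", patches[i])]] <- m
    }
  }
  # measurement masks must not overlap: carve mounted strips/patches out of
  # the fence body and the standards out of the foreground
  for (rg in names(masks)) {
    if (rg %in% c("midrail") || grepl("^patch_", rg))
      masks$fence_body <- masks$fence_body & !masks[[rg]]
  }
  masks$foreground <- masks$foreground &
    !(masks$standard_white | masks$standard_black)
  masks
}

#' Specify a synthetic fence scene
#'
#' @param condition one of the eight light/weather class labels.
#' @param materials named list assigning registry materials to the slots
#'   `background`, `fence_body`, `fence_top_edge`, `midrail`,
#'   `takeoff_board`, `foreground` (defaults: sky, birch, birch,
#'   orange_paint, orange_paint, turf).
#' @param patches materials for an optional colour-board patch row on the
#'   fence body (default none).
#' @param camera a [camera_model()] (default [default_camera()]).
#' @param system a [visual_system()] (default [horse_visual_system()]).
#' @param noise_sd camera read noise in counts (overrides the camera's).
#' @param seed integer seed for the render.
#' @param nrow,ncol image size.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(condition,
                       materials = list(),
                       patches = NULL,
                       camera = default_camera(),
                       system = horse_visual_system(),
                       noise_sd = NULL, seed = 1,
                       nrow = 96, ncol = 128) {
  .condition_row(condition)  # validates the label
  mat <- utils::modifyList(
    list(background = "sky", fence_body = "birch", fence_top_edge = "birch",
         midrail = "orange_paint", takeoff_board = "orange_paint",
         foreground = "turf",
         standard_white = "ptfe_white", standard_black = "ptfe_black"),
    materials)
  for (m in c(unlist(mat), patches)) {
    if (!m %in% material_names())
      stop("unknown material '", m, "'; registry: ",
           paste(material_names(), collapse = ", "))
  }
  if (!is.null(noise_sd)) camera$noise_sd <- noise_sd
  structure(list(condition = condition, materials = mat, patches = patches,
                 camera = camera, system = system, seed = seed,
                 nrow = nrow, ncol = ncol),
            class = "scene_spec")
}

# Regions mounted on the fence, hence subject to the class's shading
# factor; standards and ground/sky regions stay in ambient light.
.fence_mounted <- function(region) {
  grepl("^patch_", region) |
    region %in% c("fence_body", "fence_top_edge", "midrail", "takeoff_board")
}

# Internal: effective radiance-factor curve for a material under I
# (fluorescence for the fluorescent card, gloss handled by name suffix).
.effective_reflectance <- function(material, illuminant, grid) {
  base <- material_spectrum(material, grid)
  if (material == "fluoro_yellow_matt")
    fluorescent_radiance_factor(base, illuminant, grid)
  else base
}

#' Render a synthetic scene through the simulated camera
#'
#' For each region the linear camera signal is the channel-integrated
#' radiance of its material under the scene illuminant (times the fence
#' shading factor for fence-mounted regions), scaled by a global exposure
#' that puts the white standard at ~85 % of full scale. The camera
#' response (power law, seeded Gaussian noise, quantization) produces the
#' stored-count image. Deterministic given `spec$seed`.
#'
#' @param spec a [scene_spec()].
#' @param grid wavelength grid.
#' @return A list of class `rendered_scene`: `counts` (integer array
#'   `[r, c, 3]`), `masks` (named logical masks), `label` (integer label
#'   matrix, 0 = unlabelled, with `region_levels` attribute), `meta`
#'   (condition, camera, exposure, seed), and `truth` (see
#'   [scene_truth()]).
#' @export
render_scene <- function(spec, grid = default_grid()) {
  stopifnot(inherits(spec, "scene_spec"))
  cond <- .condition_row(spec$condition)
  I <- make_illuminant(spec$condition, grid)
  masks <- .scene_layout(spec$nrow, spec$ncol, spec$patches)
  cam <- spec$camera
  Iv <- I$value
  dl <- 1
  ch_int <- vapply(cam$channel_sensitivities,
                   function(cs) sum(Iv * .on_grid(cs, grid) * dl), numeric(1))
  exposure <- 0.85 / (0.931 * max(ch_int))
  lin <- array(0, c(spec$nrow, spec$ncol, length(ch_int)),
               dimnames = list(NULL, NULL, names(ch_int)))
  region_materials <- .region_materials(spec)
  for (rg in names(masks)) {
    Reff <- .effective_reflectance(region_materials[[rg]], I, grid)$value
    shade <- if (.fence_mounted(rg)) cond$fence_shade else 1
    sig <- exposure * shade *
      vapply(cam$channel_sensitivities,
             function(cs) sum(Reff * Iv * .on_grid(cs, grid) * dl), numeric(1))
    for (k in seq_along(sig)) {
      plane <- lin[, , k]
      plane[masks[[rg]]] <- sig[k]
      lin[, , k] <- plane
    }
  }
  counts <- camera_response(lin, cam, seed = spec$seed)
  label <- matrix(0L, spec$nrow, spec$ncol)
  for (i in seq_along(masks)) label[masks[[i]]] <- i
  attr(label, "region_levels") <- names(masks)
  structure(list(counts = counts, masks = masks, label = label,
                 meta = list(condition = spec$condition,
                             gamma = cam$gamma, noise_sd = cam$noise_sd,
                             bit_depth = cam$bit_depth, exposure = exposure,
                             seed = spec$seed,
                             white_reflectance = 0.931,
                             black_reflectance = 0.0449),
                 truth = scene_truth(spec, grid = grid)),
            class = "rendered_scene")
}

# Internal: region -> material name map (patch regions included).
.region_materials <- function(spec) {
  rm <- spec$materials
  for (p in spec$patches) rm[[paste0("patch_", p)]] <- p
  rm
}

#' Spectral ground truth for a scene
#'
#' Adapted cone catches per region and true JNDs for the three fence
#' comparisons, computed purely spectrally (never through the camera
#' path). Fence-mounted regions have their catches multiplied by the
#' class's shading factor; adaptation is to the ambient illuminant via
#' the perfect-reflector catch, matching equalization to unshaded
#' standards.
#'
#' @param spec a [scene_spec()].
#' @param grid wavelength grid.
#' @return A list: `catches` (matrix regions x receptors), `jnd` (data
#'   frame of comparison, colour_jnd, luminance_jnd).
#' @export
scene_truth <- function(spec, grid = default_grid()) {
  cond <- .condition_row(spec$condition)
  I <- make_illuminant(spec$condition, grid)
  region_materials <- .region_materials(spec)
  qs <- t(vapply(names(region_materials), function(rg) {
    Reff <- .effective_reflectance(region_materials[[rg]], I, grid)
    shade <- if (.fence_mounted(rg)) cond$fence_shade else 1
    shade * unclass(cone_catch(Reff, I, spec$system, adapt = TRUE, grid = grid))
  }, numeric(length(spec$system$receptors))))
  pairs <- .comparison_pairs(rownames(qs))
  jnd <- do.call(rbind, lapply(names(pairs), function(cmp) {
    p <- pairs[[cmp]]
    data.frame(comparison = cmp, target = p[1], against = p[2],
               colour_jnd = colour_jnd(qs[p[1], ], qs[p[2], ], spec$system),
               luminance_jnd = luminance_jnd(qs[p[1], ], qs[p[2], ], spec$system))
  }))
  list(catches = qs, jnd = jnd)
}

# The three fence-edge comparisons plus one comparison per colour-board
# patch against the fence body and against the foreground turf.
.comparison_pairs <- function(regions) {
  pairs <- list(
    board_vs_foreground = c("takeoff_board", "foreground"),
    midrail_vs_fence    = c("midrail", "fence_body"),
    top_vs_background   = c("fence_top_edge", "background"))
  for (rg in grep("^patch_", regions, value = TRUE)) {
    nm <- sub("^patch_", "", rg)
    pairs[[paste0("patch_vs_fence:", nm)]] <- c(rg, "fence_body")
    pairs[[paste0("patch_vs_foreground:", nm)]] <- c(rg, "foreground")
  }
  pairs
}

#' Render one scene per light/weather class
#'
#' The panel used throughout the tests and the analysis scripts: eight
#' scenes sharing geometry, camera and materials, one per light class,
#' each with a colour-board patch row (orange, white, fluorescent
#' yellow, light blue, dark blue, black by default).
#'
#' @param seed integer seed (each scene uses `seed + class index`).
#' @param patches patch materials for the colour-board row.
#' @param noise_sd camera read noise in counts (default 50, a typical
#'   RAW sensor read noise expressed at 16 bit; use 0 for noise-free
#'   oracle checks).
#' @param ... further arguments passed to [scene_spec()].
#' @return Named list of `rendered_scene`s, one per class label.
#' @export
generate_condition_panel <- function(seed = 1,
                                     patches = c("orange_paint", "white_eva",
                                                 "fluoro_yellow_matt",
                                                 "light_blue", "dark_blue",
                                                 "black_eva"),
                                     noise_sd = 50, ...) {
  labels <- light_conditions()$label
  scenes <- lapply(seq_along(labels), function(i) {
    render_scene(scene_spec(labels[i], patches = patches,
                            noise_sd = noise_sd, seed = seed + i, ...))
  })
  names(scenes) <- labels
  scenes
}

#' Write a rendered scene to disk
#'
#' Stored counts as 16-bit TIFF, the label mask as 8-bit PNG, metadata
#' as JSON, and the spectral truth JNDs as CSV.
#'
#' @param scene a `rendered_scene`.
#' @param dir output directory (created if needed).
#' @param stem file stem (default the light condition).
#' @return Invisibly, the written paths.
#' @export
write_scene <- function(scene, dir, stem = scene$meta$condition) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  maxc <- 2^scene$meta$bit_depth - 1
  p_tif <- file.path(dir, paste0(stem, ".tif"))
  tiff::writeTIFF(scene$counts / maxc, p_tif, bits.per.sample = 16L)
  p_png <- file.path(dir, paste0(stem, "_labels.png"))
  png::writePNG(scene$label / 255, p_png)
  p_json <- file.path(dir, paste0(stem, ".json"))
  meta <- scene$meta
  meta$region_levels <- attr(scene$label, "region_levels")
  jsonlite::write_json(meta, p_json, auto_unbox = TRUE, digits = NA)
  p_csv <- file.path(dir, paste0(stem, "_truth.csv"))
  utils::write.csv(scene$truth$jnd, p_csv, row.names = FALSE)
  invisible(c(p_tif, p_png, p_json, p_csv))
}

#' Read a rendered scene's counts back from TIFF
#'
#' @param path TIFF written by [write_scene()].
#' @param bit_depth camera bit depth used at write time.
#' @return Integer count array `[r, c, ch]`.
#' @export
read_scene_tiff <- function(path, bit_depth = 16) {
  img <- tiff::readTIFF(path)
  round(img * (2^bit_depth - 1))
}
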