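# Fence-component comparisons and Table-style summaries.

#' Compare two scene components in a cone-catch image
#'
#' Computes the mean cone catch of each region and returns colour and
#' luminance JNDs with contrast bands. The three named fence-edge
#' comparisons are `board_vs_foreground` (takeoff board against the turf
#' in front of the obstacle), `midrail_vs_fence` (midrail against the
#' surrounding fence material) and `top_vs_background` (top edge of the
#' fence against the visual background); `patch_vs_fence:<m>` and
#' `patch_vs_foreground:<m>` compare a colour-board patch with the fence
#' body or the foreground.
#'
#' @param cone_image array `[r, c, receptors]` from [apply_mapping()] (or
#'   a truth-rendered equivalent).
#' @param masks named list of logical region masks.
#' @param which comparison name (see above), or a pair
#'   `c(target_region, against_region)`.
#' @param system a [visual_system()].
#' @param condition light-condition label carried into the result.
#' @param course_id,fence_id identifiers carried into the result.
#' @return A one-row data frame of class `comparison_result`.
#' @export
compare_components <- function(cone_image, masks, which, system,
                               condition = NA_character_,
                               course_id = NA_character_,
                               fence_id = NA_character_) {
  if (length(which) == 1) {
    pairs <- .comparison_pairs(names(masks))
    if (!which %in% names(pairs))
      stop("unknown comparison '", which, "'; available: ",
           paste(names(pairs), collapse = ", "))
    pair <- pairs[[which]]
    cmp_name <- which
  } else {
    pair <- which
    cmp_name <- paste(which, collapse = "_vs_")
  }
  for (rg in pair) {
    if (is.null(masks[[rg]]))
      stop("region '", rg, "' is missing from the masks")
    if (!any(masks[[rg]])) stop("region '", rg, "' is empty")
  }
  mean_catch <- function(rg) {
    q <- .region_channel_means(cone_image, masks[[rg]])
    names(q) <- dimnames(cone_image)[[3]]
    q
  }
  qa <- mean_catch(pair[1]); qb <- mean_catch(pair[2])
  res <- jnd_result(qa, qb, system)
  out <- data.frame(
    course_id = course_id, fence_id = fence_id, light_condition = condition,
    comparison = cmp_name,
    target_name = sub("^patch_", "", pair[1]), against_name = pair[2],
    colour_jnd = res$colour_jnd, luminance_jnd = res$luminance_jnd,
    band_colour = res$band_colour, band_luminance = res$band_luminance,
    n_pixels_a = sum(masks[[pair[1]]]), n_pixels_b = sum(masks[[pair[2]]]),
    stringsAsFactors = FALSE)
  class(out) <- c("comparison_result", class(out))
  out
}

#' Run all comparisons for a rendered scene through the full pipeline
#'
#' Calibrate (linearize + equalize to the in-frame standards), map to
#' cone catches, and compare every defined component pair. One-stop
#' driver mirroring the photograph-processing workflow.
#'
#' @param scene a `rendered_scene` from [render_scene()].
#' @param camera the camera the scene was rendered with.
#' @param mapping a `cone_mapping` fitted for the scene's light class.
#' @param system a [visual_system()].
#' @param course_id,fence_id identifiers carried into the results.
#' @return Data frame, one row per comparison.
#' @export
analyze_scene <- function(scene, camera, mapping,
                          system = horse_visual_system(),
                          course_id = NA_character_,
                          fence_id = NA_character_) {
  lin <- linearize(scene$counts, camera)
  standards <- standard_set(scene$masks$standard_white,
                            scene$masks$standard_black,
                            scene$meta$white_reflectance,
                            scene$meta$black_reflectance)
  cal <- equalize_to_standards(lin, standards,
                               provenance = list(light_condition = scene$meta$condition))
  cone <- apply_mapping(cal, mapping)
  pairs <- .comparison_pairs(names(scene$masks))
  do.call(rbind, lapply(names(pairs), function(cmp)
    compare_components(cone, scene$masks, cmp, system,
                       condition = scene$meta$condition,
                       course_id = course_id, fence_id = fence_id)))
}

#' Summarize comparison results
#'
#' Per-group sample size, mean and standard error (sd / sqrt(N)) of the
#' colour and luminance JNDs -- the shape of the published visibility
#' tables. The SE of a single observation is reported as `NA`; grouped
#' counts always total the number of input rows.
#'
#' @param results data frame of rows from [compare_components()].
#' @param group_by columns to group over (default comparison target and
#'   light condition).
#' @return Data frame with `n`, `mean_colour_jnd`, `se_colour_jnd`,
#'   `mean_luminance_jnd`, `se_luminance_jnd` per group.
#' @export
summarize_comparisons <- function(results,
                                  group_by = c("comparison", "target_name",
                                               "light_condition")) {
  if (!nrow(results)) stop("no results to summarize")
  key <- interaction(results[group_by], drop = TRUE, sep = "|")
  se <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
  agg <- lapply(split(results, key), function(d) {
    cbind(d[1, group_by, drop = FALSE],
          data.frame(n = nrow(d),
                     mean_colour_jnd = mean(d$colour_jnd),
                     se_colour_jnd = se(d$colour_jnd),
                     mean_luminance_jnd = mean(d$luminance_jnd),
                     se_luminance_jnd = se(d$luminance_jnd)))
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}
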