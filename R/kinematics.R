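# Jump-kinematics parameters from annotated video still frames.
#
# Points are 2-D pixel coordinates c(x, y) with y increasing downwards
# (image convention). The camera is assumed level and perpendicular to
# the fence, so "parallel to the ground" is the image horizontal; a
# custom ground line can be supplied where that assumption fails.

#' Scale calibration from fence-bar reference points
#'
#' The first bars of the fence, with known physical spacing, establish
#' the mm-per-pixel scale: `scale = spacing / mean adjacent inter-point
#' pixel distance`. Bar points must be roughly collinear (residual of a
#' total-least-squares line fit below 5 px).
#'
#' @param bar_points matrix/list of >= 2 points (rows of `x, y`), in
#'   bar order.
#' @param bar_spacing_mm known physical spacing between adjacent bars
#'   (> 0); there is no default, it must be supplied.
#' @return Scale in mm per pixel.
#' @export
calibrate_scale <- function(bar_points, bar_spacing_mm) {
  p <- .as_points(bar_points)
  if (nrow(p) < 2) stop("need at least two bar points")
  if (!is.numeric(bar_spacing_mm) || bar_spacing_mm <= 0)
    stop("bar_spacing_mm must be > 0")
  d <- sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2))
  if (any(d == 0)) stop("coincident bar points")
  if (nrow(p) >= 3) {
    ctr <- sweep(p, 2, colMeans(p))
    resid <- sqrt(min(eigen(crossprod(ctr) / nrow(p), symmetric = TRUE)$values))
    if (resid > 5)
      warning(sprintf("bar points deviate from a line by %.1f px", resid))
  }
  bar_spacing_mm / mean(d)
}

.as_points <- function(x) {
  if (is.list(x) && !is.data.frame(x)) x <- do.call(rbind, x)
  x <- as.matrix(x)
  if (ncol(x) != 2) stop("points must have two columns (x, y)")
  storage.mode(x) <- "double"
  x
}

#' Distance between a hoof contact point and the fence base
#'
#' Euclidean pixel distance times the mm-per-pixel scale. Takeoff
#' distances use the anterior fence base, landing distances the
#' posterior base.
#'
#' @param hoof_point,fence_base_point points `c(x, y)` in the same frame
#'   coordinate system.
#' @param scale mm per pixel from [calibrate_scale()].
#' @return Distance in mm.
#' @export
limb_distance <- function(hoof_point, fence_base_point, scale) {
  if (is.null(hoof_point) || is.null(fence_base_point) ||
      any(is.na(hoof_point)) || any(is.na(fence_base_point)))
    stop("missing point for limb distance")
  sqrt(sum((as.numeric(hoof_point) - as.numeric(fence_base_point))^2)) * scale
}

#' Angle of takeoff
#'
#' Two lines emanate from the hindquarters (the point between the sacral
#' vertebra and the croup): one towards the forelimbs parallel to the
#' ground, one along the dorsum towards the withers. The takeoff angle is
#' the unsigned angle between them, in degrees. A horizontal dorsum gives
#' 0 degrees. The result is invariant to horizontal translation and to
#' uniform scaling of the coordinates.
#'
#' @param croup,sacral points defining the hindquarters; the line origin
#'   is their midpoint.
#' @param withers point towards which the dorsum line runs.
#' @param ground_direction optional unit-direction `c(dx, dy)` of the
#'   ground line; default the image horizontal towards the withers.
#' @return Angle in degrees, in [0, 180).
#' @export
takeoff_angle <- function(croup, sacral, withers, ground_direction = NULL) {
  o <- (as.numeric(croup) + as.numeric(sacral)) / 2
  v <- as.numeric(withers) - o
  if (all(v == 0)) stop("withers coincides with the hindquarters origin")
  if (is.null(ground_direction)) {
    if (v[1] == 0) return(90)
    ground_direction <- c(sign(v[1]), 0)
  }
  g <- as.numeric(ground_direction)
  if (all(g == 0)) stop("degenerate ground direction")
  cosang <- sum(v * g) / (sqrt(sum(v^2)) * sqrt(sum(g^2)))
  acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
}

#' Angle of bascule
#'
#' The interior angle at the withers vertex between the line to the
#' hindquarters and the line to the ears (the lower of the two angles the
#' lines form), representing body rounding at the jump mid-point.
#' Collinear points give 180 degrees.
#'
#' @param hindquarters,withers,ears points `c(x, y)`.
#' @return Angle in degrees, in [0, 180].
#' @export
bascule_angle <- function(hindquarters, withers, ears) {
  u <- as.numeric(hindquarters) - as.numeric(withers)
  v <- as.numeric(ears) - as.numeric(withers)
  if (all(u == 0) || all(v == 0))
    stop("coincident points defining the bascule angle")
  cosang <- sum(u * v) / (sqrt(sum(u^2)) * sqrt(sum(v^2)))
  acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
}

#' Height of the withers over the fence
#'
#' Vertical distance (mm) between the withers at the jump apex and the
#' top of the obstacle.
#'
#' @param withers,fence_top points `c(x, y)`.
#' @param scale mm per pixel.
#' @return Height in mm (>= 0).
#' @export
wither_height <- function(withers, fence_top, scale) {
  abs(as.numeric(fence_top)[2] - as.numeric(withers)[2]) * scale
}

#' Total jump distance
#'
#' Distance between the hind leading limb contact at takeoff and the
#' front trailing limb contact at landing.
#'
#' @param hind_leading_takeoff,front_trailing_landing points `c(x, y)`.
#' @param scale mm per pixel.
#' @return Distance in mm.
#' @export
total_jump_distance <- function(hind_leading_takeoff, front_trailing_landing,
                                scale) {
  limb_distance(hind_leading_takeoff, front_trailing_landing, scale)
}

.hoof_labels <- c("front_leading", "front_trailing",
                  "hind_leading", "hind_trailing")

#' Compute the eleven jump parameters from an annotation
#'
#' The annotation is a list with:
#' \describe{
#'   \item{scale_ref}{`bar_points` (>= 2 points) and `bar_spacing_mm`.}
#'   \item{takeoff}{the four hoof points (`front_leading`,
#'     `front_trailing`, `hind_leading`, `hind_trailing`),
#'     `fence_base_anterior`, `croup`, `sacral`, `withers`.}
#'   \item{apex}{`hindquarters`, `withers`, `ears`, `fence_top`.}
#'   \item{landing}{the four hoof points and `fence_base_posterior`.}
#' }
#' All frames share one (fixed-camera) coordinate system.
#'
#' @param annotation annotation list (see Details), e.g. from
#'   [read_jump_annotation()] or [synthetic_jump()].
#' @return One-row data frame: four takeoff distances, four landing
#'   distances, total jump distance, takeoff angle, bascule angle, and
#'   wither height (distances mm, angles degrees).
#' @export
jump_parameters <- function(annotation) {
  need <- function(frame, label) {
    p <- annotation[[frame]][[label]]
    if (is.null(p)) stop("annotation is missing ", frame, "$", label)
    as.numeric(p)
  }
  scale <- calibrate_scale(annotation$scale_ref$bar_points,
                           annotation$scale_ref$bar_spacing_mm)
  ba <- need("takeoff", "fence_base_anterior")
  bp <- need("landing", "fence_base_posterior")
  td <- vapply(.hoof_labels, function(l)
    limb_distance(need("takeoff", l), ba, scale), numeric(1))
  ld <- vapply(.hoof_labels, function(l)
    limb_distance(need("landing", l), bp, scale), numeric(1))
  out <- data.frame(
    takeoff_distance_1 = td[["front_leading"]],
    takeoff_distance_2 = td[["front_trailing"]],
    takeoff_distance_3 = td[["hind_leading"]],
    takeoff_distance_4 = td[["hind_trailing"]],
    landing_distance_1 = ld[["front_leading"]],
    landing_distance_2 = ld[["front_trailing"]],
    landing_distance_3 = ld[["hind_leading"]],
    landing_distance_4 = ld[["hind_trailing"]],
    total_jump_distance = total_jump_distance(need("takeoff", "hind_leading"),
                                              need("landing", "front_trailing"),
                                              scale),
    takeoff_angle = takeoff_angle(need("takeoff", "croup"),
                                  need("takeoff", "sacral"),
                                  need("takeoff", "withers")),
    bascule_angle = bascule_angle(need("apex", "hindquarters"),
                                  need("apex", "withers"),
                                  need("apex", "ears")),
    wither_height = wither_height(need("apex", "withers"),
                                  need("apex", "fence_top"), scale))
  for (m in c("horse_id", "fence_colour", "fence_sequence", "jump_number")) {
    out[[m]] <- if (is.null(annotation[[m]])) NA else annotation[[m]]
  }
  out
}

#' Generate a synthetic jump with known geometry
#'
#' Parametric limb placement and a parabolic trajectory produce an
#' annotation plus its exact parameter values, for round-trip testing of
#' the geometry. Optionally adds Gaussian annotation noise to every
#' point.
#'
#' @param scale_mm_per_px true scale (default 2.5).
#' @param takeoff_distances,landing_distances four distances (mm) for
#'   front leading/trailing and hind leading/trailing limbs.
#' @param takeoff_angle_deg,bascule_angle_deg,wither_height_mm remaining
#'   true parameters.
#' @param fence_gap_mm anterior-to-posterior fence base separation (mm).
#' @param bar_spacing_mm physical bar spacing for the scale reference.
#' @param noise_px s.d. of annotation noise in pixels (default 0).
#' @param seed seed for the noise draw.
#' @return List with `annotation` and `truth` (one-row data frame of the
#'   eleven parameters).
#' @export
synthetic_jump <- function(scale_mm_per_px = 2.5,
                           takeoff_distances = c(2200, 1900, 2600, 2350),
                           landing_distances = c(1500, 1800, 2100, 2400),
                           takeoff_angle_deg = 22,
                           bascule_angle_deg = 150,
                           wither_height_mm = 600,
                           fence_gap_mm = 500,
                           bar_spacing_mm = 250,
                           noise_px = 0, seed = 1) {
  s <- scale_mm_per_px
  ground_y <- 600
  fence_x <- 800
  ba <- c(fence_x, ground_y)                       # anterior base
  bp <- c(fence_x + fence_gap_mm / s, ground_y)    # posterior base
  fence_top <- c(fence_x + fence_gap_mm / s / 2, ground_y - 1300 / s)
  hoof_t <- lapply(takeoff_distances, function(d) c(fence_x - d / s, ground_y))
  names(hoof_t) <- .hoof_labels
  hoof_l <- lapply(landing_distances, function(d) c(bp[1] + d / s, ground_y))
  names(hoof_l) <- .hoof_labels
  # hindquarters origin behind the fence, dorsum line rising at the
  # takeoff angle towards the withers (y axis points down)
  o <- c(fence_x - 1800 / s, ground_y - 1200 / s)
  croup <- o + c(0, -40); sacral <- o + c(0, 40)
  alpha <- takeoff_angle_deg * pi / 180
  withers_t <- o + 300 * c(cos(alpha), -sin(alpha))
  # apex: withers above the fence at the true height; hindquarters and
  # ears placed symmetrically so the interior angle is the bascule angle
  withers_a <- c(fence_top[1], fence_top[2] - wither_height_mm / s)
  half <- bascule_angle_deg / 2 * pi / 180
  arm <- 320
  hind_a <- withers_a + arm * c(-sin(half), cos(half))
  ears_a <- withers_a + arm * c(sin(half), cos(half))
  bar1 <- c(fence_x, ground_y - 40)
  bars <- list(bar1, bar1 - c(0, bar_spacing_mm / s),
               bar1 - c(0, 2 * bar_spacing_mm / s))
  ann <- list(
    scale_ref = list(bar_points = bars, bar_spacing_mm = bar_spacing_mm),
    takeoff = c(hoof_t, list(fence_base_anterior = ba, croup = croup,
                             sacral = sacral, withers = withers_t)),
    apex = list(hindquarters = hind_a, withers = withers_a, ears = ears_a,
                fence_top = fence_top),
    landing = c(hoof_l, list(fence_base_posterior = bp)))
  if (noise_px > 0) {
    set.seed(seed)
    jitter_pt <- function(p) p + stats::rnorm(2, 0, noise_px)
    ann$scale_ref$bar_points <- lapply(ann$scale_ref$bar_points, jitter_pt)
    for (f in c("takeoff", "apex", "landing"))
      ann[[f]] <- lapply(ann[[f]], jitter_pt)
  }
  truth <- data.frame(
    takeoff_distance_1 = takeoff_distances[1],
    takeoff_distance_2 = takeoff_distances[2],
    takeoff_distance_3 = takeoff_distances[3],
    takeoff_distance_4 = takeoff_distances[4],
    landing_distance_1 = landing_distances[1],
    landing_distance_2 = landing_distances[2],
    landing_distance_3 = landing_distances[3],
    landing_distance_4 = landing_distances[4],
    total_jump_distance = (takeoff_distances[3] + fence_gap_mm +
                             landing_distances[2]),
    takeoff_angle = takeoff_angle_deg,
    bascule_angle = bascule_angle_deg,
    wither_height = wither_height_mm)
  list(annotation = ann, truth = truth)
}

#' Read a jump annotation from JSON
#'
#' @param path JSON file with the structure described in
#'   [jump_parameters()] (points as two-element arrays).
#' @return Annotation list.
#' @export
read_jump_annotation <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write a jump annotation to JSON
#' @param annotation annotation list.
#' @param path output file.
#' @export
write_jump_annotation <- function(annotation, path) {
  jsonlite::write_json(annotation, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
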