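#' Build the scene geometry of the simulated gaze interface
#'
#' The interface displays `n_objects` selectable objects on an invisible
#' circle around the fixation cross. Each object owns a wedge-shaped target
#' area extending from the fixation cross out to `area_outer_radius` and
#' `180/n_objects` arc degrees to either side of the object, so the target
#' areas tile the disk without gaps. A constant clockwise rotation
#' (`distortion`, arc deg) is applied to every primary-saccade endpoint
#' before decoding; it is fixed for the lifetime of the scene object.
#'
#' Defaults give the eight-object scene: objects at clock angles 0, 45, ...,
#' 315 (star at 12 o'clock, triangle at 3 o'clock, ...) on a 7-deg circle,
#' 9-deg outer radius, 22.5 arc-deg half-width, +45 arc-deg clockwise
#' distortion and a 1-deg feedback dot.
#'
#' @param n_objects number of objects (>= 2).
#' @param object_radius radius of the circle carrying the objects, deg > 0.
#' @param area_outer_radius outer radius of the target areas, deg > 0.
#' @param distortion clockwise rotation added to saccade endpoints, arc deg.
#' @param feedback_dot_diameter diameter of the motor-feedback dot, deg.
#' @param object_names optional character vector of length `n_objects`.
#'
#' @return An object of class `scene_geometry`: a list with the fields above
#'   plus `object_clock_angle` (arc deg, clockwise from 12 o'clock) and
#'   `area_half_width` (= `180/n_objects` arc deg).
#' @examples
#' sc <- build_scene()
#' sc$object_clock_angle[sc$object_names == "triangle"]  # 90 (3 o'clock)
#' @export
build_scene <- function(n_objects = 8,
                        object_radius = 7,
                        area_outer_radius = 9,
                        distortion = 45,
                        feedback_dot_diameter = 1,
                        object_names = NULL) {
  if (!is.numeric(n_objects) || length(n_objects) != 1L || n_objects < 2 ||
      n_objects != round(n_objects)) {
    stop("`n_objects` must be a single integer >= 2", call. = FALSE)
  }
  if (object_radius <= 0 || area_outer_radius <= 0) {
    stop("radii must be positive", call. = FALSE)
  }
  if (object_radius >= area_outer_radius) {
    stop("`object_radius` must be smaller than `area_outer_radius`",
         call. = FALSE)
  }
  n_objects <- as.integer(n_objects)
  if (is.null(object_names)) {
    object_names <- if (n_objects == 8L) {
      c("star", "octagon", "triangle", "rhombus", "square", "hexagon",
        "circle", "parallelogram")
    } else {
      paste0("object", seq_len(n_objects))
    }
  }
  if (length(object_names) != n_objects) {
    stop("`object_names` must have length `n_objects`", call. = FALSE)
  }
  scene <- list(
    n_objects = n_objects,
    object_names = object_names,
    object_clock_angle = (seq_len(n_objects) - 1L) * 360 / n_objects,
    object_radius = object_radius,
    area_outer_radius = area_outer_radius,
    area_half_width = 180 / n_objects,
    distortion = distortion,
    feedback_dot_diameter = feedback_dot_diameter
  )
  class(scene) <- "scene_geometry"
  scene
}

#' @export
print.scene_geometry <- function(x, ...) {
  cat("Scene geometry:", x$n_objects, "objects on a", x$object_radius,
      "deg circle\n")
  cat("  target areas: outer radius", x$area_outer_radius, "deg, half-width",
      x$area_half_width, "arc deg\n")
  cat("  endpoint distortion:", x$distortion, "arc deg clockwise\n")
  cat("  objects:", paste0(x$object_names, " (", x$object_clock_angle, ")",
                           collapse = ", "), "\n")
  invisible(x)
}

#' Apply the interface's endpoint distortion
#'
#' Rotates screen points clockwise about the fixation cross by the scene's
#' `distortion` (arc deg). The radius of each point is preserved.
#'
#' @param x,y screen coordinates, deg of visual angle (vectorised).
#' @param scene a [build_scene()] object.
#' @return A list with rotated components `x` and `y`.
#' @examples
#' sc <- build_scene()
#' p <- clock_to_xy(90, 7)                 # triangle position
#' apply_distortion(p$x, p$y, sc)          # lands at clock 135 (rhombus)
#' @export
apply_distortion <- function(x, y, scene) {
  stopifnot(inherits(scene, "scene_geometry"))
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("endpoint coordinates must be finite", call. = FALSE)
  }
  a <- -scene$distortion * pi / 180 # clockwise rotation in y-up coordinates
  list(x = cos(a) * x - sin(a) * y,
       y = sin(a) * x + cos(a) * y)
}

#' Decode the intended object from a (distorted) saccade endpoint
#'
#' Returns, for each point, the index of the object in whose target area the
#' point falls, or `NA` when the point lies beyond the outer radius of all
#' target areas ("eye too far from any possible target"). A point belongs to
#' object i when its radius is at most `area_outer_radius` and the clockwise
#' angular distance from the object's clock angle lies in
#' `[-half_width, +half_width)`; the half-open boundary guarantees that the
#' target areas partition the disk.
#'
#' @inheritParams apply_distortion
#' @return Integer vector of object indices (1-based), `NA` = none/too far.
#' @examples
#' sc <- build_scene()
#' p <- clock_to_xy(135, 7)
#' sc$object_names[decode_object(p$x, p$y, sc)]   # "rhombus"
#' @export
decode_object <- function(x, y, scene) {
  stopifnot(inherits(scene, "scene_geometry"))
  r <- sqrt(x^2 + y^2)
  theta <- clock_angle(x, y)
  hw <- scene$area_half_width
  # objects are equally spaced, so the wedge index is a closed form; the
  # floor realises the half-open [-hw, +hw) membership rule
  idx <- (floor((theta + hw) / (2 * hw)) %% scene$n_objects) + 1L
  idx[r > scene$area_outer_radius] <- NA_integer_
  as.integer(idx)
}

#' Compare decoded and intended objects
#'
#' @param decoded integer vector of decoded object indices (`NA` = none).
#' @param intended integer vector (or scalar) of intended object indices.
#' @param x,y optional coordinates of the distorted endpoint, stored in the
#'   result for feedback rendering.
#' @return A data frame of class `decoding_outcome` with columns
#'   `decoded_object`, `intended_object`, `too_far`, `decoding_error`
#'   (`NA` when no object was decoded) and the endpoint coordinates.
#' @examples
#' evaluate_trial(4L, 3L)   # rhombus decoded, triangle intended -> error
#' @export
evaluate_trial <- function(decoded, intended, x = NA_real_, y = NA_real_) {
  if (any(is.na(intended))) {
    stop("`intended` must be a valid object index", call. = FALSE)
  }
  n <- max(length(decoded), length(intended))
  decoded <- rep_len(as.integer(decoded), n)
  intended <- rep_len(as.integer(intended), n)
  too_far <- is.na(decoded)
  out <- data.frame(
    decoded_object = decoded,
    intended_object = intended,
    too_far = too_far,
    decoding_error = ifelse(too_far, NA, decoded != intended),
    x = rep_len(x, n),
    y = rep_len(y, n)
  )
  class(out) <- c("decoding_outcome", "data.frame")
  out
}

#' Render the post-saccadic feedback for a decoding outcome
#'
#' Exactly one feedback element is produced per trial: under motor feedback a
#' dot at the distorted saccade endpoint; under action feedback the decoded
#' object is coloured; when no object was decoded a "too far" message is
#' shown instead (in either condition).
#'
#' @param outcome a `decoding_outcome` from [evaluate_trial()] (the stored
#'   `x`,`y` must be the distorted endpoint for motor feedback).
#' @param condition `"motor"` or `"action"`.
#' @param scene a [build_scene()] object (supplies the dot diameter).
#' @return A data frame with columns `feedback_kind` (`"dot"`, `"color"` or
#'   `"message"`), `feedback_x`, `feedback_y`, `dot_diameter`,
#'   `colored_object` and `too_far`, one row per trial.
#' @export
render_feedback <- function(outcome, condition, scene) {
  stopifnot(inherits(outcome, "decoding_outcome"),
            inherits(scene, "scene_geometry"))
  if (length(condition) != 1L || !condition %in% c("motor", "action")) {
    stop("`condition` must be \"motor\" or \"action\"", call. = FALSE)
  }
  n <- nrow(outcome)
  kind <- rep(if (condition == "motor") "dot" else "color", n)
  kind[outcome$too_far] <- "message"
  fb <- data.frame(
    feedback_kind = kind,
    feedback_x = ifelse(kind == "dot", outcome$x, NA_real_),
    feedback_y = ifelse(kind == "dot", outcome$y, NA_real_),
    dot_diameter = ifelse(kind == "dot", scene$feedback_dot_diameter,
                          NA_real_),
    colored_object = ifelse(kind == "color", outcome$decoded_object,
                            NA_integer_),
    too_far = outcome$too_far
  )
  fb
}
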