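#' Angular helpers for the clock-position coordinate convention
#'
#' Positions on screen are measured in Cartesian degrees of visual angle with
#' the origin at the fixation cross and y increasing upward. Angular positions
#' along the object circle ("clock angles") are measured in arc degrees,
#' clockwise from 12 o'clock, so that 12 o'clock is 0, 3 o'clock is 90, and
#' so on. `wrap_angle()` wraps a signed angular difference into `(-180, 180]`
#' (clockwise positive); `clock_angle()` returns the clock angle of a screen
#' point in `[0, 360)`; `clock_to_xy()` is its inverse at a given radius.
#'
#' @param angle numeric vector of angles in arc degrees.
#' @param x,y screen coordinates in degrees of visual angle.
#' @param clock clock angle(s) in arc degrees (clockwise from 12 o'clock).
#' @param radius radial distance(s) from the fixation cross, deg.
#'
#' @return `wrap_angle()`: angles in `(-180, 180]`. `clock_angle()`: angles in
#'   `[0, 360)`. `clock_to_xy()`: a list with components `x` and `y`.
#' @examples
#' wrap_angle(350)        # -10
#' clock_angle(7, 0)      # 90: 3 o'clock
#' clock_to_xy(90, 7)     # list(x = 7, y = 0)
#' @export
wrap_angle <- function(angle) 180 - ((180 - angle) %% 360)

#' @rdname wrap_angle
#' @export
clock_angle <- function(x, y) (atan2(x, y) * 180 / pi) %% 360

#' @rdname wrap_angle
#' @export
clock_to_xy <- function(clock, radius) {
  rad <- clock * pi / 180
  list(x = radius * sin(rad), y = radius * cos(rad))
}

# wrap into [-180, 180): used for the half-open target-area membership rule
wrap_angle_cw <- function(angle) ((angle + 180) %% 360) - 180
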