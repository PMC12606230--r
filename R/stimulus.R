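#' Equidistant CIELAB color wheel
#'
#' Places `n_colors` points on a circle in the (a*, b*) plane, centred on the
#' grey point (a* = 0, b* = 0) at fixed lightness `L`, such that the chord
#' between adjacent points equals `adjacent_distance` CIELAB units. The circle
#' radius is therefore `adjacent_distance / (2 * sin(pi / n_colors))`, so
#' adjacent colors are equally different from each other and all colors are
#' equally different from grey.
#'
#' With the defaults used in the partial-report design (`L = 70`,
#' `adjacent_distance = 149.2975`, `phase = 0`) the four-color wheel starts at
#' (70, 105.5692, 0) and the five-color wheel at (70, 127, 0).
#'
#' @param n_colors Number of colors (>= 2); the experimental design uses 4 or 5.
#' @param adjacent_distance Chord length between adjacent points, CIELAB units.
#' @param L Fixed lightness (CIELAB L*).
#' @param phase Angle (radians) of the first point on the (a*, b*) plane.
#'
#' @return A tibble with columns `index`, `L`, `a`, `b` and one row per color.
#'   Values are kept at full floating precision; round only for display.
#' @examples
#' color_wheel(4, 149.2975)
#' color_wheel(5, 149.2975)
#' @export
color_wheel <- function(n_colors, adjacent_distance, L = 70, phase = 0) {
  if (length(n_colors) != 1L || is.na(n_colors) || n_colors < 2 ||
      n_colors != round(n_colors)) {
    abort("`n_colors` must be a single integer >= 2.")
  }
  if (!is.finite(adjacent_distance) || adjacent_distance <= 0) {
    abort("`adjacent_distance` must be a positive finite number.")
  }
  radius <- adjacent_distance / (2 * sin(pi / n_colors))
  ang <- phase + 2 * pi * (seq_len(n_colors) - 1L) / n_colors
  tibble::tibble(
    index = seq_len(as.integer(n_colors)),
    L = L,
    a = radius * cos(ang),
    b = radius * sin(ang)
  )
}

#' Four-decimal display convention for CIELAB coordinates
#'
#' Wheel coordinates are kept at full floating precision; the published
#' four-color stimulus table lists them truncated toward zero at four
#' decimals (105.5692 is the truncation of 149.2975 / (2 sin(pi/4)) =
#' 105.56930; plain rounding would print 105.5693). This helper applies
#' that truncating serialization convention. The published five-color
#' values correspond to ordinary rounding instead, so the convention is
#' ambiguous at one unit in the fourth decimal; full precision is always
#' available in the wheel tibble itself.
#'
#' @param x Numeric vector.
#' @param digits Decimals to keep (4).
#' @return `x` truncated toward zero at `digits` decimals.
#' @export
format_lab <- function(x, digits = 4) {
  trunc(x * 10^digits) / 10^digits
}

#' Equispaced circular array positions
#'
#' Computes the `n_items` item positions of the circular letter array:
#' equispaced angles (gap `2 * pi / n_items`) offset by a global `rotation`,
#' all at `radius_deg` degrees of visual angle from the centre. The
#' experimental design rotates the array randomly on every trial, which is
#' emulated by drawing `rotation` uniformly.
#'
#' @param n_items Number of array positions (>= 1).
#' @param radius_deg Array radius in degrees of visual angle (design: 8.81).
#' @param rotation Global rotation of the array, radians.
#'
#' @return A tibble with columns `index`, `angle_rad`, `x_deg`, `y_deg`.
#' @examples
#' array_positions(4, 8.81)
#' @export
array_positions <- function(n_items, radius_deg = 8.81, rotation = 0) {
  if (length(n_items) != 1L || is.na(n_items) || n_items < 1 ||
      n_items != round(n_items)) {
    abort("`n_items` must be a single integer >= 1.")
  }
  ang <- rotation + 2 * pi * (seq_len(n_items) - 1L) / n_items
  tibble::tibble(
    index = seq_len(as.integer(n_items)),
    angle_rad = ang %% (2 * pi),
    x_deg = radius_deg * cos(ang),
    y_deg = radius_deg * sin(ang)
  )
}

#' Number of wheel colors for a given set size
#'
#' The design rule: five colors when 5, 9 or 13 items are displayed (set sizes
#' congruent to 1 mod 4, where a four-color cyclic assignment would place the
#' same color on the first and last, adjacent, positions), four otherwise.
#'
#' @param n_items Number of items in the array.
#' @return 4 or 5.
#' @export
n_wheel_colors <- function(n_items) {
  ifelse(n_items > 1 & n_items %% 4 == 1, 5L, 4L)
}

#' Cyclic color assignment with distinct neighbours
#'
#' Assigns wheel colors to array positions cyclically (position `i` gets color
#' `(i - 1) mod k + 1` for a `k`-color wheel) and verifies that no two
#' neighbouring positions -- including the wrap-around pair -- share a color.
#'
#' @param layout An `array_positions()` tibble (or an integer set size).
#' @param wheel A `color_wheel()` tibble with 4 or 5 rows.
#'
#' @return An integer vector of color indices (into `wheel`), one per position.
#' @examples
#' assign_colors(array_positions(9), color_wheel(5, 149.2975))
#' @export
assign_colors <- function(layout, wheel) {
  n_items <- if (is.data.frame(layout)) nrow(layout) else as.integer(layout)
  k <- if (is.data.frame(wheel)) nrow(wheel) else as.integer(wheel)
  if (!k %in% c(4L, 5L)) {
    abort("`wheel` must contain 4 or 5 colors.")
  }
  if (n_items < 1) abort("layout must contain at least one position.")
  idx <- ((seq_len(n_items) - 1L) %% k) + 1L
  if (n_items > 1L) {
    nxt <- c(idx[-1L], idx[1L])
    if (any(idx == nxt)) {
      abort(
        sprintf(
          "cyclic %d-color assignment violates the adjacency constraint for %d items",
          k, n_items
        ),
        class = "memmeta_constraint_violation"
      )
    }
  }
  idx
}
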