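#' The six directed behaviours, in intensity rank order
#'
#' The calibration protocol observes six directed behaviours spanning the
#' intensity spectrum of a 3-year-old's day, from watching cartoons
#' (essentially motionless) to a competitive sprinting game. Activity counts
#' are expected to rank the behaviours in a fixed order, which is the ordering
#' all One-vs-Rest and One-vs-One binarisations rely on.
#'
#' @return Character vector of the six canonical behaviour names, ordered from
#'   lowest (rank 1) to highest (rank 6) movement intensity.
#' @examples
#' behaviour_levels()
#' @export
behaviour_levels <- function() {
  c(
    "sedentary_screen_time", # watching cartoons, motionless alert
    "recumbent_listening",   # story listening, lying down
    "sedentary_crafts",      # seated drawing / sticker play
    "play_on_floor",         # light: floor play with toys
    "floorball_walk",        # moderate: brisk walk / floorball
    "sprinting"              # vigorous: sprinting game
  )
}

#' @rdname behaviour_levels
#' @param x Character vector of behaviour names.
#' @return `behaviour_factor()` returns `x` as a factor with the six canonical
#'   levels in rank order; unknown names raise an error.
#' @export
behaviour_factor <- function(x) {
  lev <- behaviour_levels()
  bad <- setdiff(unique(as.character(x)), lev)
  if (length(bad) > 0) {
    abort(paste0(
      "Unknown behaviour name(s): ", paste(bad, collapse = ", "),
      ". Expected one of: ", paste(lev, collapse = ", ")
    ))
  }
  factor(as.character(x), levels = lev)
}

#' @rdname behaviour_levels
#' @return `behaviour_rank()` returns the integer intensity rank (1 = most
#'   stationary, 6 = most vigorous) for each element of `x`.
#' @export
behaviour_rank <- function(x) {
  as.integer(behaviour_factor(x))
}

# Devices and wear positions recognised throughout the package.
device_levels <- function() c("MW8", "GT3X")
position_levels <- function() c("wrist", "hip")

assert_device <- function(device) {
  if (!is.character(device) || length(device) != 1 ||
      !device %in% device_levels()) {
    abort("`device` must be one of: MW8, GT3X")
  }
  device
}

assert_position <- function(position) {
  if (!is.character(position) || length(position) != 1 ||
      !position %in% position_levels()) {
    abort("`position` must be one of: wrist, hip")
  }
  position
}
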