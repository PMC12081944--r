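#' Speaker elevation angle relative to the listener's ears
#'
#' Computes the elevation of a loudspeaker as seen from the listener's ear
#' position, `atan((speaker_height - ear_height) / distance)` in degrees.
#' Negative values mean the speaker sits below ear level.
#'
#' @param ear_height Listener ear height in metres.
#' @param speaker_height Speaker (acoustic centre) height in metres.
#' @param distance Horizontal distance from listener to speaker in metres;
#'   must be positive.
#' @return Elevation angle in degrees.
#' @examples
#' speaker_elevation(1.8, 1.14, 2)  # near speaker, about -18.2 degrees
#' @export
speaker_elevation <- function(ear_height, speaker_height, distance) {
  stopifnot(is.numeric(ear_height), is.numeric(speaker_height),
            is.numeric(distance))
  if (any(distance <= 0)) {
    stop("`distance` must be positive", call. = FALSE)
  }
  atan2(speaker_height - ear_height, distance) * 180 / pi
}

#' Schroeder frequency of a room
#'
#' Crossover frequency below which discrete room modes dominate the sound
#' field: `2000 * sqrt(T60 / V)`.
#'
#' @param t60 Broadband reverberation time in seconds (positive).
#' @param volume Room volume in cubic metres (positive).
#' @return Schroeder frequency in Hz.
#' @export
schroeder_frequency <- function(t60, volume) {
  if (any(t60 <= 0) || any(volume <= 0)) {
    stop("`t60` and `volume` must be positive", call. = FALSE)
  }
  2000 * sqrt(t60 / volume)
}

#' Floor area and volume of a rectangular room
#'
#' @param width,length,height Room dimensions in metres (all positive).
#' @return A list with elements `floor_area` (m^2) and `volume` (m^3).
#' @export
room_metrics <- function(width, length, height) {
  if (any(c(width, length, height) <= 0)) {
    stop("room dimensions must be positive", call. = FALSE)
  }
  area <- width * length
  list(floor_area = area, volume = area * height)
}

#' Room specification
#'
#' Bundles the physical constants of the experimental room. The critical
#' distance is a recorded constant (its derivation depends on source
#' directivity, which is not modelled); the Schroeder frequency, floor area
#' and volume are derived.
#'
#' @param width,length,height Room dimensions in metres.
#' @param t60 Broadband reverberation time in seconds.
#' @param critical_distance Critical distance in metres (recorded, not
#'   derived).
#' @return An object of class `room_spec`.
#' @export
room_spec <- function(width = 7.22, length = 12, height = 3.4,
                      t60 = 0.8, critical_distance = 3.5) {
  m <- room_metrics(width, length, height)
  if (t60 <= 0) stop("`t60` must be positive", call. = FALSE)
  structure(list(
    width = width, length = length, height = height,
    t60 = t60, critical_distance = critical_distance,
    floor_area = m$floor_area, volume = m$volume,
    schroeder_frequency = schroeder_frequency(t60, m$volume)
  ), class = "room_spec")
}

#' @export
print.room_spec <- function(x, ...) {
  cat(sprintf("Room %.2f x %.2f x %.2f m (area %.1f m^2, volume %.1f m^3)\n",
              x$width, x$length, x$height, x$floor_area, x$volume))
  cat(sprintf("T60 %.2f s, critical distance %.1f m, Schroeder frequency %.1f Hz\n",
              x$t60, x$critical_distance, x$schroeder_frequency))
  invisible(x)
}

#' Loudspeaker layout of the spatial oddball setup
#'
#' Five speakers: standard at centre (4 m), targets near (2 m), far (8 m) on
#' the median plane and left/right at +/-24 degrees azimuth (4 m radial).
#' Elevations are derived from speaker and ear heights.
#'
#' @param ear_height Listener ear height in metres.
#' @param speaker_height Speaker height in metres.
#' @return An object of class `speaker_layout`: a data frame with columns
#'   `label`, `distance`, `azimuth`, `elevation`.
#' @export
speaker_layout <- function(ear_height = 1.8, speaker_height = 1.14) {
  pos <- data.frame(
    label = c("center", "near", "far", "left", "right"),
    distance = c(4, 2, 8, 4, 4),
    azimuth = c(0, 0, 0, -24, 24),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(pos$label)) stop("speaker labels must be unique")
  pos$elevation <- speaker_elevation(ear_height, speaker_height, pos$distance)
  structure(pos, class = c("speaker_layout", "data.frame"),
            ear_height = ear_height, speaker_height = speaker_height)
}
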