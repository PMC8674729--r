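#' The 61-point lateral foot landmark scheme
#'
#' The scheme outlines the bones relevant to foot collapse (calcaneus, talus,
#' cuboid, first and fifth metatarsals, navicular, medial cuneiform, distal
#' tibia) and carries the index runs that drive the three measurements:
#'
#' \itemize{
#'   \item calcaneal tilt: angle at point 10 between the rays to points 11 and 12;
#'   \item cuboid height: distance from the spline through points
#'     37-38-39-14-40-41-42 to the line through points 13 and 15;
#'   \item Meary's angle: angle between the metatarsal axis (centre line of the
#'     splines through points 20-24 and 25-28) and the talar axis (through the
#'     midpoint of points 4-5 and the midpoint of point 9 with the most
#'     superior point of the spline through points 8-16-17-7-18-19-6).
#' }
#'
#' Bone-group outlines beyond the measurement indices are fixed here as the
#' package's canonical anatomy (the measurement code is purely index-driven,
#' so group membership only affects the point-to-curve error and rendering).
#'
#' @return A \linkS4class{LandmarkScheme}.
#' @export
footScheme <- function() {
  new("LandmarkScheme",
    nPoints = 61L,
    splineDefs = list(
      cuboid_inferior = c(37L, 38L, 39L, 14L, 40L, 41L, 42L),
      talus_superior  = c(8L, 16L, 17L, 7L, 18L, 19L, 6L),
      metatarsal_a    = 20:24,
      metatarsal_b    = 25:28
    ),
    lineDefs = list(
      ct_base    = c(10L, 11L),
      ct_ramp    = c(10L, 12L),
      ch_base    = c(13L, 15L),
      talus_neck = c(4L, 5L)
    ),
    boneGroups = list(
      calcaneus   = c(33L, 32L, 31L, 30L, 10L, 13L, 11L, 29L, 12L),
      talus       = c(9L, 8L, 16L, 17L, 7L, 18L, 19L, 6L, 4L, 5L, 3L, 2L, 1L),
      cuboid      = c(35L, 34L, 37L, 38L, 39L, 14L, 40L, 41L, 42L, 36L),
      met1_sup    = c(20L, 21L, 22L, 23L, 24L, 55L),
      met1_inf    = c(25L, 26L, 27L, 28L, 54L),
      met5        = c(15L, 50L, 51L, 52L, 53L),
      navicular   = c(43L, 44L, 45L, 46L),
      cuneiform   = c(47L, 48L, 49L),
      tibia       = c(56L, 57L, 58L, 59L)
    ),
    blocks = list(
      calcaneus_ramp = c(12L, 29L, 30L, 31L, 32L, 33L),
      cuboid         = c(14L, 34L, 35L, 36L, 37L, 38L, 39L, 40L, 41L, 42L),
      metatarsal     = c(20:28, 54L, 55L)
    )
  )
}
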