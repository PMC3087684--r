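# Body and egg volumes from linear measurements. Both shapes are ellipsoids
# built from measured diameters, so volume = (pi/6) x product of diameters
# ((4/3) pi times the three semi-axes).

#' Body volume from three linear measurements
#'
#' The body is approximated as a general ellipsoid with total length as the
#' polar diameter and the two breadth measurements as the equatorial
#' diameters: V = (pi/6) L B1 B2.
#'
#' @param totalLength total body length, um.
#' @param maxBreadth maximum breadth, um.
#' @param anteriorBreadth breadth at the anterior end, um.
#' @return body volume in um^3 (vectorized).
#' @export
#' @examples
#' bodyVolume(2, 2, 2)           # sphere of diameter 2: 4.18879
#' bodyVolume(200, 150, 100)
bodyVolume <- function(totalLength, maxBreadth, anteriorBreadth) {
  stopIfNot(all(totalLength > 0) && all(maxBreadth > 0) &&
              all(anteriorBreadth > 0),
            "all body dimensions must be positive")
  pi / 6 * totalLength * maxBreadth * anteriorBreadth
}

#' Egg volume from length and breadth
#'
#' The egg is approximated as an ellipsoid of revolution about its long
#' axis: V = (pi/6) L B^2.
#'
#' @param length egg length, um.
#' @param breadth egg breadth, um.
#' @return egg volume in um^3 (vectorized).
#' @export
#' @examples
#' eggVolume(100, 50)   # 130899.7
eggVolume <- function(length, breadth) {
  stopIfNot(all(length > 0) && all(breadth > 0),
            "all egg dimensions must be positive")
  pi / 6 * length * breadth^2
}
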