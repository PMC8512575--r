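#' MIMO antenna array around a hemispherical examination mold
#'
#' Default fixture geometry: a hemispherical mold (breast phantom container,
#' radius 7 cm, flat face up at z = 0, origin at the mold center) with 8
#' transmitting antennas on one ring and 16 receiving antennas on a second
#' ring of the mold surface, giving 128 ordered (tx, rx) channels. The exact
#' antenna coordinates of the physical array are not published; a regular
#' two-ring layout is used as the fixture default.
#'
#' @param n_tx,n_rx Number of transmitters / receivers.
#' @param mold_radius Mold radius (m).
#' @param mold_center Mold center (m), length-3.
#' @param tx_ring_z,rx_ring_z z coordinate of each antenna ring (m, negative:
#'   below the array plane).
#' @param rx_az_offset Azimuthal offset of the receiver ring (rad); the
#'   default interleaves the two rings.
#' @return An object of class `array_geometry` with matrices `tx` (n_tx x 3)
#'   and `rx` (n_rx x 3), the mold description, and the ordered channel table.
#' @examples
#' g <- array_geometry()
#' nrow(g$channels)  # 128
#' @export
array_geometry <- function(n_tx = 8, n_rx = 16, mold_radius = 0.07,
                           mold_center = c(0, 0, 0),
                           tx_ring_z = -0.015, rx_ring_z = -0.05,
                           rx_az_offset = pi / 16) {
  stopifnot(n_tx >= 1, n_rx >= 1, mold_radius > 0,
            abs(tx_ring_z) <= mold_radius, abs(rx_ring_z) <= mold_radius)
  ring <- function(n, z, off) {
    az <- 2 * pi * (seq_len(n) - 1) / n + off
    rho <- sqrt(mold_radius^2 - z^2)
    cbind(x = mold_center[1] + rho * cos(az),
          y = mold_center[2] + rho * sin(az),
          z = mold_center[3] + z)
  }
  channels <- expand.grid(rx = seq_len(n_rx), tx = seq_len(n_tx))[, c("tx", "rx")]
  structure(list(tx = ring(n_tx, tx_ring_z, 0),
                 rx = ring(n_rx, rx_ring_z, rx_az_offset),
                 mold = list(center = mold_center, radius = mold_radius),
                 channels = channels),
            class = "array_geometry")
}

#' @export
print.array_geometry <- function(x, ...) {
  cat(sprintf("MIMO array: %d Tx x %d Rx = %d channels, mold radius %.3g m\n",
              nrow(x$tx), nrow(x$rx), nrow(x$channels), x$mold$radius))
  invisible(x)
}

#' Is a point inside the examination mold?
#'
#' The mold is the lower hemisphere: within `mold_radius` of the center and at
#' or below the array plane.
#'
#' @param pos Numeric length-3 position or n x 3 matrix (m).
#' @param geometry An [array_geometry()].
#' @return Logical vector.
#' @export
in_mold <- function(pos, geometry) {
  pos <- matrix(pos, ncol = 3)
  ctr <- geometry$mold$center
  d <- sqrt((pos[, 1] - ctr[1])^2 + (pos[, 2] - ctr[2])^2 + (pos[, 3] - ctr[3])^2)
  d <= geometry$mold$radius & pos[, 3] <= ctr[3] + 1e-12
}

#' Select imaging channels by tx-rx angular separation
#'
#' Keeps channels whose transmitter and receiver subtend an angle (seen from
#' the mold center) no larger than `max_angle_deg`. Wide-angle (transmission)
#' channels carry little backscatter information and degrade delay-and-sum
#' image quality; with the default fixture geometry the 60 degree cut keeps 48
#' of the 128 channels.
#'
#' @param geometry An [array_geometry()].
#' @param max_angle_deg Maximum tx-rx angular separation in degrees.
#' @return An object of class `channel_selection`: a data.frame of `(tx, rx)`
#'   pairs with the separation angle, plus the rule parameter as an attribute.
#' @examples
#' nrow(select_channels(array_geometry()))        # 48
#' nrow(select_channels(array_geometry(), 180))   # 128
#' @export
select_channels <- function(geometry, max_angle_deg = 60) {
  stopifnot(inherits(geometry, "array_geometry"))
  ctr <- geometry$mold$center
  ang <- function(a, b) {
    ua <- (a - ctr) / sqrt(sum((a - ctr)^2))
    ub <- (b - ctr) / sqrt(sum((b - ctr)^2))
    acos(min(1, max(-1, sum(ua * ub)))) * 180 / pi
  }
  ch <- geometry$channels
  ch$angle_deg <- mapply(function(i, j) ang(geometry$tx[i, ], geometry$rx[j, ]),
                         ch$tx, ch$rx)
  sel <- ch[ch$angle_deg <= max_angle_deg, , drop = FALSE]
  if (nrow(sel) == 0)
    stop("channel selection is empty: increase max_angle_deg")
  rownames(sel) <- NULL
  structure(sel, class = c("channel_selection", "data.frame"),
            max_angle_deg = max_angle_deg)
}
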