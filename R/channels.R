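#' IMU channel names
#'
#' The fixed order of the ten IMU channels used throughout the package:
#' triaxial acceleration, pitch and roll for each of the two units. Every
#' module refers to this single constant; no other code re-declares the
#' channel order.
#'
#' @return Character vector of length 10.
#' @export
#' @examples
#' imu_channels()
imu_channels <- function() {
  c("imu1_ax", "imu1_ay", "imu1_az", "imu1_pitch", "imu1_roll",
    "imu2_ax", "imu2_ay", "imu2_az", "imu2_pitch", "imu2_roll")
}

#' Euler-angle channel names
#'
#' The four pitch/roll channels that are subject to random pulses from the
#' orientation filter and therefore pass through the limiting filter.
#'
#' @return Character vector of length 4.
#' @export
euler_channels <- function() {
  c("imu1_pitch", "imu1_roll", "imu2_pitch", "imu2_roll")
}

# Column order of the on-disk CSV dialect (label column optional).
recording_columns <- function(with_label = FALSE) {
  cols <- c("t_ms", imu_channels(), "pressure")
  if (with_label) cols <- c(cols, "label")
  cols
}
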