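#' Default 59-channel extended 10-20 montage
#'
#' Channel labels used when a simulated recording does not supply its own.
#' The list corresponds to a 61-electrode extended 10-20 cap with the two
#' mastoid electrodes (TP9/TP10) removed, as these are consumed by offline
#' re-referencing and leave 59 scalp channels for analysis.
#'
#' @return Character vector of 59 unique channel labels.
#' @export
#' @examples
#' length(default_montage())
default_montage <- function() {
  c("Fp1", "Fp2",
    "AF7", "AF3", "AF4", "AF8",
    "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
    "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8",
    "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
    "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8",
    "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
    "PO7", "PO3", "POz", "PO4", "PO8",
    "O1", "Oz", "O2")
}

#' Canonical EEG frequency bands
#'
#' The four analysis bands: theta 4-8 Hz, alpha 8-13 Hz, beta 13-30 Hz and
#' gamma 30-45 Hz.
#'
#' @return Named list of [band_definition] objects.
#' @export
#' @examples
#' default_bands()$theta
default_bands <- function() {
  list(theta = band_definition("theta", 4, 8),
       alpha = band_definition("alpha", 8, 13),
       beta  = band_definition("beta", 13, 30),
       gamma = band_definition("gamma", 30, 45))
}
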