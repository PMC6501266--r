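#' Default 32-channel dry-electrode montage
#'
#' Channel labels of a standard 32-electrode 10-20 montage as used by
#' portable dry-electrode systems. The occipital/parietal channels
#' (O1, O2, Oz, PO3, PO4, P7, P8) and the frontal pair Fp1/Fp2 that the
#' decoding analyses single out are all present.
#'
#' @return Character vector of 32 channel labels.
#' @export
#' @examples
#' default_montage()
default_montage <- function() {
  c("P7", "P4", "Cz", "Pz", "P3", "P8", "O1", "O2",
    "T8", "F8", "C4", "F4", "Fp2", "Fz", "C3", "F3",
    "Fp1", "T7", "F7", "Oz", "PO4", "FC6", "FC2", "AF4",
    "CP6", "CP2", "CP1", "CP5", "AF3", "FC1", "FC5", "PO3")
}

# Scalp region of each montage label, used by the simulator to weight
# evoked components (posterior-dominant visual response).
.channel_region <- function(channels) {
  posterior <- c("O1", "O2", "Oz", "PO3", "PO4", "P3", "P4", "P7", "P8", "Pz")
  frontal   <- c("Fp1", "Fp2", "AF3", "AF4", "F3", "F4", "F7", "F8", "Fz")
  out <- rep("central", length(channels))
  out[channels %in% posterior] <- "posterior"
  out[channels %in% frontal] <- "frontal"
  out
}
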