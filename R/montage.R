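# Synthetic spherical electrode layout. The coordinates are a regularised
# 10-10-style grid built in code (not measured cap positions): labels sit on
# a schematic anterior-posterior x lateral grid that is mapped onto a sphere
# by azimuthal-equidistant projection. Simulation, leakage topographies,
# channel distances and spherical-spline interpolation all use the same
# layout, so internal consistency is what matters, not anatomical fidelity.

MONTAGE_ROWS <- list(
  Fp = list(y = 4,  labels = c("Fp1", "Fpz", "Fp2"),       xs = c(-1, 0, 1)),
  AF = list(y = 3,  labels = c("AF7", "AF3", "AFz", "AF4", "AF8"),
            xs = c(-3, -1.5, 0, 1.5, 3)),
  F  = list(y = 2,  labels = c("F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8"),
            xs = -4:4),
  FC = list(y = 1,  labels = c("FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8"),
            xs = -4:4),
  C  = list(y = 0,  labels = c("T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8"),
            xs = -4:4),
  CP = list(y = -1, labels = c("TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8"),
            xs = -4:4),
  P  = list(y = -2, labels = c("P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8"),
            xs = -4:4),
  PO = list(y = -3, labels = c("PO7", "PO5", "PO3", "POz", "PO4", "PO6", "PO8"),
            xs = c(-3, -2, -1, 0, 1, 2, 3)),
  O  = list(y = -4, labels = c("O1", "Oz", "O2"),          xs = c(-1, 0, 1)),
  I  = list(y = -4.5, labels = "Iz",                        xs = 0))

EOG_CHANNELS <- c("HEOG_L", "HEOG_R", "VEOG_U", "VEOG_D")

#' Synthetic EEG montage (64 scalp channels + 4 EOG)
#'
#' Builds the package's synthetic extended 10-20-style layout: 64 scalp
#' electrodes (including FCz and Pz) on a sphere of radius `head_radius_cm`
#' plus four periocular EOG channels. Scalp positions are schematic, built
#' in code; they are used consistently by the simulator (theta topography,
#' ocular leakage decay) and the preprocessing (distances, spherical-spline
#' interpolation).
#'
#' @param subset `"full"` (64 EEG) or `"small"` (16 EEG, still including
#'   FCz, Fpz and Pz) for fast simulations.
#' @param head_radius_cm Sphere radius used for physical distances.
#' @return A data.frame with `channel`, `type` (`"eeg"`/`"eog"`), unit-sphere
#'   coordinates `nx`, `ny`, `nz`, and head coordinates `x_cm`, `y_cm`,
#'   `z_cm` (EOG rows get frontal extra-scalp positions).
#' @export
standard_montage <- function(subset = c("full", "small"), head_radius_cm = 9) {
  subset <- match.arg(subset)
  rows <- do.call(rbind, lapply(MONTAGE_ROWS, function(r)
    data.frame(channel = r$labels, gx = r$xs, gy = r$y)))
  # azimuthal-equidistant: grid radius 4 -> 90 deg inclination from vertex
  rr <- sqrt(rows$gx^2 + rows$gy^2)
  incl <- pmin(rr / 4 * 90, 100) * pi / 180
  azim <- atan2(rows$gx, rows$gy)  # 0 = front, positive to the right
  out <- data.frame(channel = rows$channel, type = "eeg",
                    nx = sin(incl) * sin(azim),
                    ny = sin(incl) * cos(azim),
                    nz = cos(incl), stringsAsFactors = FALSE)
  if (subset == "small") {
    keep <- c("Fp1", "Fpz", "Fp2", "F3", "Fz", "F4", "FC1", "FCz", "FC2",
              "C3", "Cz", "C4", "P3", "Pz", "P4", "Oz")
    out <- out[out$channel %in% keep, , drop = FALSE]
  }
  eog <- data.frame(channel = EOG_CHANNELS, type = "eog",
                    nx = c(-0.9, 0.9, -0.3, -0.3),
                    ny = c(0.9, 0.9, 1.05, 1.05),
                    nz = c(-0.1, -0.1, 0.05, -0.15),
                    stringsAsFactors = FALSE)
  out <- rbind(out, eog)
  out$x_cm <- out$nx * head_radius_cm
  out$y_cm <- out$ny * head_radius_cm
  out$z_cm <- out$nz * head_radius_cm
  rownames(out) <- NULL
  out
}

# great-circle-ish 3D chord distance between two channels (cm)
channel_distance <- function(montage, a, b) {
  ia <- match(a, montage$channel); ib <- match(b, montage$channel)
  sqrt(sum((montage[ia, c("x_cm", "y_cm", "z_cm")] -
            montage[ib, c("x_cm", "y_cm", "z_cm")])^2))
}
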