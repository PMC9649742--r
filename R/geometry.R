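#' Tether/bead geometry
#'
#' Geometry of a surface-tethered bead: bead radius, end-to-end tether
#' extension under the current force, and (optionally) the in-plane
#' displacement of the bead center from the tether anchor. When both the
#' extension and the displacement are given they must satisfy the small-tilt
#' relation `(l + r)^2 = d^2 + r^2` (negligible vertical bead displacement).
#'
#' @param bead_radius_nm Bead radius r in nm.
#' @param extension_nm Tether end-to-end length l in nm (>= 0).
#' @param displacement_nm Optional in-plane displacement d of the bead center
#'   in nm; if supplied without `extension_nm`, the extension is derived via
#'   [tether_extension_from_displacement()].
#'
#' @return An object of class `tether_geometry`.
#' @examples
#' tether_geometry(bead_radius_nm = 1100, displacement_nm = 2600)
#' @export
tether_geometry <- function(bead_radius_nm, extension_nm = NULL,
                            displacement_nm = NULL) {
  stopifnot(is.numeric(bead_radius_nm), length(bead_radius_nm) == 1L,
            bead_radius_nm > 0)
  if (is.null(extension_nm)) {
    if (is.null(displacement_nm)) {
      stop("supply `extension_nm` or `displacement_nm`", call. = FALSE)
    }
    extension_nm <- tether_extension_from_displacement(displacement_nm,
                                                       bead_radius_nm)
  } else if (!is.null(displacement_nm)) {
    lhs <- (extension_nm + bead_radius_nm)^2
    rhs <- displacement_nm^2 + bead_radius_nm^2
    if (abs(lhs - rhs) > 1e-6 * lhs) {
      stop("inconsistent geometry: (l + r)^2 must equal d^2 + r^2",
           call. = FALSE)
    }
  }
  stopifnot(extension_nm >= 0)
  structure(
    list(bead_radius_nm = bead_radius_nm, extension_nm = extension_nm,
         displacement_nm = displacement_nm),
    class = "tether_geometry"
  )
}

#' Tether extension from in-plane bead displacement
#'
#' Inverts the tethered-bead geometry under the assumption of negligible
#' vertical displacement: `(l + r)^2 = d^2 + r^2`, so
#' `l = sqrt(d^2 + r^2) - r`.
#'
#' @param d In-plane displacement of the bead center in nm (>= 0); vectorized.
#' @param r Bead radius in nm.
#'
#' @return Tether end-to-end extension l in nm.
#' @examples
#' tether_extension_from_displacement(d = 2600, r = 1100)
#' @export
tether_extension_from_displacement <- function(d, r) {
  stopifnot(is.numeric(d), all(d >= 0), is.numeric(r), length(r) == 1L, r > 0)
  sqrt(d^2 + r^2) - r
}

#' In-plane displacement from tether extension (inverse of the above)
#'
#' @param l Tether extension in nm (>= 0); vectorized.
#' @param r Bead radius in nm.
#' @return In-plane displacement d in nm.
#' @export
displacement_from_tether_extension <- function(l, r) {
  stopifnot(is.numeric(l), all(l >= 0), is.numeric(r), length(r) == 1L, r > 0)
  sqrt((l + r)^2 - r^2)
}

#' Microfluidic channel geometry
#'
#' @param width_um Channel width in micrometers.
#' @param height_um Channel height in micrometers.
#' @param index Position of the channel along the serial chain (1-based).
#' @return An object of class `channel_geometry`.
#' @export
channel_geometry <- function(width_um, height_um, index = 1L) {
  stopifnot(width_um > 0, height_um > 0)
  structure(list(width_um = width_um, height_um = height_um,
                 index = as.integer(index)),
            class = "channel_geometry")
}

#' Serially connected multi-width chip layout
#'
#' An ordered set of serially connected channels of common height and varying
#' width. Serial connection means one volumetric flow rate traverses every
#' channel, so the mean flow velocity -- and with it the drag force and the
#' loading rate on tethered beads -- scales inversely with channel width.
#'
#' @param widths_um Channel widths in micrometers, in serial order.
#' @param height_um Shared channel height in micrometers.
#'
#' @return An object of class `chip_layout`; `$channels` is a tibble with
#'   columns `index` and `width_um`.
#' @examples
#' chip_layout(widths_um = c(500, 1000, 1500, 2000, 2500), height_um = 120)
#' @export
chip_layout <- function(widths_um, height_um) {
  stopifnot(is.numeric(widths_um), length(widths_um) >= 1L, all(widths_um > 0),
            is.numeric(height_um), length(height_um) == 1L, height_um > 0)
  structure(
    list(channels = tibble::tibble(index = seq_along(widths_um),
                                   width_um = as.numeric(widths_um)),
         height_um = height_um),
    class = "chip_layout"
  )
}

#' @export
print.chip_layout <- function(x, ...) {
  cat(sprintf("<chip_layout> %d serial channels, height %.0f um, widths (um): %s\n",
              nrow(x$channels), x$height_um,
              paste(x$channels$width_um, collapse = ", ")))
  invisible(x)
}

#' Relative force scale of a channel within a multi-width chip
#'
#' At a shared volumetric flow rate, the force on a tethered bead in channel
#' `i` relative to the narrowest channel is `narrowest_width / width_i`
#' (wider channel, proportionally slower flow, proportionally lower force and
#' loading rate).
#'
#' @param chip A [chip_layout()].
#' @param channel_index Channel index (1-based, vectorized). Default: all.
#' @return Dimensionless force scale factor(s) relative to the narrowest
#'   channel.
#' @examples
#' chip <- chip_layout(c(500, 1000, 1500, 2000, 2500), 120)
#' channel_force_scale(chip)  # 1, 1/2, 1/3, 1/4, 1/5
#' @export
channel_force_scale <- function(chip, channel_index = NULL) {
  stopifnot(inherits(chip, "chip_layout"))
  w <- chip$channels$width_um
  if (is.null(channel_index)) channel_index <- chip$channels$index
  if (any(channel_index < 1L | channel_index > length(w))) {
    stop("`channel_index` out of range for this chip", call. = FALSE)
  }
  min(w) / w[channel_index]
}

#' Mean flow velocity in a rectangular channel
#'
#' Cross-section-averaged velocity `V = Q / (w h)` for a volumetric flow
#' rate `Q`.
#'
#' @param q_mm3_s Volumetric flow rate in mm^3/s (vectorized, >= 0).
#' @param channel A [channel_geometry()] or a [chip_layout()] plus
#'   `channel_index`.
#' @param channel_index Channel to use when `channel` is a chip layout.
#' @return Mean velocity in mm/s.
#' @examples
#' mean_velocity(1, channel_geometry(width_um = 1000, height_um = 120))
#' @export
mean_velocity <- function(q_mm3_s, channel, channel_index = 1L) {
  stopifnot(is.numeric(q_mm3_s), all(q_mm3_s >= 0))
  dims <- channel_dims_mm(channel, channel_index)
  area <- dims$width_mm * dims$height_mm
  if (area <= 0) stop("channel cross-section area must be positive", call. = FALSE)
  q_mm3_s / area
}

channel_dims_mm <- function(channel, channel_index = 1L) {
  if (inherits(channel, "chip_layout")) {
    w <- channel$channels$width_um[channel_index]
    h <- channel$height_um
  } else if (inherits(channel, "channel_geometry")) {
    w <- channel$width_um
    h <- channel$height_um
  } else {
    stop("`channel` must be a channel_geometry or chip_layout", call. = FALSE)
  }
  list(width_mm = w / 1000, height_mm = h / 1000)
}

#' Convert a flow rate from uL/min to mm^3/s
#'
#' Syringe pumps are commonly programmed in uL/min; all internal flow-rate
#' computations here use mm^3/s (1 uL/min = 1/60 mm^3/s).
#'
#' @param q_ul_min Flow rate in uL/min; vectorized.
#' @return Flow rate in mm^3/s.
#' @export
ul_min_to_mm3_s <- function(q_ul_min) q_ul_min / 60

#' Linear flow-ramp loading protocol
#'
#' Volumetric flow rate versus time, `Q(t) = Q0 + beta t`, driving a linearly
#' increasing drag force on tethered beads. The ramp slope `beta` together
#' with a calibration slope and a channel cross-section fixes the force
#' loading rate.
#'
#' @param q0_mm3_s Initial flow rate in mm^3/s (>= 0).
#' @param ramp_mm3_s2 Ramp slope beta = dQ/dt in mm^3/s^2 (>= 0).
#' @param duration_s Protocol duration in s (> 0).
#'
#' @return An object of class `loading_protocol` with a `$flow_rate(t)`
#'   function.
#' @examples
#' prot <- loading_protocol(ramp_mm3_s2 = 0.01, duration_s = 120)
#' prot$flow_rate(c(0, 60, 120))
#' @export
loading_protocol <- function(q0_mm3_s = 0, ramp_mm3_s2, duration_s) {
  stopifnot(q0_mm3_s >= 0, ramp_mm3_s2 >= 0, duration_s > 0)
  structure(
    list(q0_mm3_s = q0_mm3_s, ramp_mm3_s2 = ramp_mm3_s2,
         duration_s = duration_s,
         flow_rate = function(t) q0_mm3_s + ramp_mm3_s2 * t),
    class = "loading_protocol"
  )
}

#' Contour length of double-stranded DNA
#'
#' @param n_bp Number of base pairs.
#' @param rise_per_bp_nm Helical rise per base pair in nm (default 0.34 for
#'   B-form DNA).
#' @return Contour length in nm.
#' @examples
#' dna_contour_length(5745)  # ~1953 nm, i.e. ~1.95 um
#' @export
dna_contour_length <- function(n_bp, rise_per_bp_nm = 0.34) {
  stopifnot(n_bp > 0, rise_per_bp_nm > 0)
  n_bp * rise_per_bp_nm
}
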