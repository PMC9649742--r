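#' Detect beads in a single frame
#'
#' Thresholds the frame (fixed level or Otsu), labels connected components
#' and returns per-component centroids and pixel areas. Components whose
#' area exceeds 1.5x the median are flagged as likely merged beads.
#'
#' @param frame Numeric matrix (rows = y, columns = x), values in [0, 1].
#' @param min_area_px Minimum component area in pixels (default 4).
#' @param threshold Intensity threshold, or `"otsu"` for automatic selection.
#'
#' @return A tibble with columns `bead_id`, `y_px`, `x_px`, `area_px`,
#'   `merged`. Empty (zero rows) for a blank frame.
#' @export
detect_beads <- function(frame, min_area_px = 4, threshold = "otsu") {
  stopifnot(is.matrix(frame), is.numeric(frame))
  empty <- tibble::tibble(bead_id = integer(0), y_px = numeric(0),
                          x_px = numeric(0), area_px = integer(0),
                          merged = logical(0))
  if (all(frame <= 0) || max(frame) == min(frame)) return(empty)
  thr <- if (identical(threshold, "otsu")) {
    EBImage::otsu(EBImage::Image(t(frame)), range = c(0, 1))
  } else {
    stopifnot(is.numeric(threshold), length(threshold) == 1L)
    threshold
  }
  mask <- frame > thr
  if (!any(mask)) return(empty)
  labels <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(mask))))
  labels <- t(labels)  # back to rows = y
  idx <- which(labels > 0)
  lab <- labels[idx]
  yy <- ((idx - 1) %% nrow(frame)) + 1
  xx <- ((idx - 1) %/% nrow(frame)) + 1
  area <- as.integer(table(lab))
  out <- tibble::tibble(
    bead_id = sort(unique(lab)),
    y_px = as.numeric(tapply(yy, lab, mean)),
    x_px = as.numeric(tapply(xx, lab, mean)),
    area_px = area
  )
  out <- out[out$area_px >= min_area_px, , drop = FALSE]
  out$bead_id <- seq_len(nrow(out))
  out$merged <- out$area_px > 1.5 * stats::median(out$area_px)
  out
}

fft_freq_idx <- function(n) c(0:(ceiling(n / 2) - 1), seq.int(-floor(n / 2), -1))

# Matrix-multiply DFT of a localized patch of the upsampled cross-correlation
# (evaluates `nor x noc` output points at 1/usfac pixel spacing, offset by
# (roff, coff) upsampled pixels), avoiding the full zero-padded inverse FFT.
dft_upsampled_patch <- function(fprod, nor, noc, usfac, roff, coff) {
  nr <- nrow(fprod); nc <- ncol(fprod)
  kernc <- exp((-2i * pi / (nc * usfac)) *
                 outer(fft_freq_idx(nc), (0:(noc - 1)) - coff))
  kernr <- exp((-2i * pi / (nr * usfac)) *
                 outer((0:(nor - 1)) - roff, fft_freq_idx(nr)))
  kernr %*% fprod %*% kernc
}

#' Sub-pixel displacement between two image windows
#'
#' Registers `window` against `reference_window` by Fourier cross-
#' correlation: the integer-pixel peak of the inverse-transformed
#' cross-correlation is refined on an upsampled grid evaluated -- via a
#' matrix-multiply discrete Fourier transform -- only in a small
#' neighbourhood of the coarse peak, which gives the same answer as
#' upsampling the full correlation plane at a fraction of the cost. The
#' attainable resolution is about one pixel divided by the upsampling
#' factor; choose `upsample_factor >= pixel_size / desired_resolution`
#' (e.g. 65 nm pixels and a 10 nm target need a factor of 7 or more).
#'
#' @param window,reference_window Same-size numeric matrices.
#' @param upsample_factor Integer >= 1; 1 gives whole-pixel registration.
#'
#' @return Named numeric vector `c(dx, dy)`: the displacement of `window`
#'   relative to `reference_window`, in pixels (x = column, y = row,
#'   origin top-left).
#' @examples
#' ref <- outer(dnorm(1:32, 16, 2), dnorm(1:32, 16, 2))
#' win <- outer(dnorm(1:32, 15, 2), dnorm(1:32, 18, 2))
#' subpixel_displacement(win, ref, upsample_factor = 50)
#' @export
subpixel_displacement <- function(window, reference_window,
                                  upsample_factor = 10L) {
  stopifnot(is.matrix(window), is.matrix(reference_window),
            all(dim(window) == dim(reference_window)),
            upsample_factor >= 1)
  if (stats::sd(window) == 0 || stats::sd(reference_window) == 0) {
    stop("flat (zero-variance) window: correlation peak undefined",
         call. = FALSE)
  }
  nr <- nrow(reference_window); nc <- ncol(reference_window)
  fprod <- stats::fft(reference_window) * Conj(stats::fft(window))
  cc <- Re(stats::fft(fprod, inverse = TRUE))
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  rs <- pk[[1]] - 1; cs <- pk[[2]] - 1
  if (rs > nr / 2) rs <- rs - nr
  if (cs > nc / 2) cs <- cs - nc
  usfac <- as.integer(upsample_factor)
  if (usfac > 1L) {
    rs0 <- round(rs * usfac) / usfac
    cs0 <- round(cs * usfac) / usfac
    nloc <- ceiling(usfac * 1.5)
    dftshift <- floor(nloc / 2)
    cc_up <- Conj(dft_upsampled_patch(Conj(fprod), nloc, nloc, usfac,
                                      dftshift - rs0 * usfac,
                                      dftshift - cs0 * usfac))
    m <- Re(cc_up)
    pk <- which(m == max(m), arr.ind = TRUE)[1, ]
    rs <- rs0 + (pk[[1]] - 1 - dftshift) / usfac
    cs <- cs0 + (pk[[2]] - 1 - dftshift) / usfac
  }
  # cross-correlation peak sits at minus the displacement of `window`
  c(dx = -cs, dy = -rs)
}

#' Track beads through a movie
#'
#' Detects beads in the first frame, then for each bead registers a fixed
#' window around its initial position against the frame-zero window of the
#' same bead (sub-pixel, Fourier cross-correlation) and records the pixel
#' area above threshold inside the window. A bead whose in-window area falls
#' below `min_area_px` is recorded as absent (`area_px = 0`, positions `NA`).
#'
#' @param movie Array `ny x nx x n_frames` (values in [0, 1]).
#' @param pixel_size_nm Physical pixel size in nm.
#' @param frame_times_s Frame acquisition times in s (default `0, 1, 2, ...`).
#' @param window_half_px Half-width of the square tracking window; default
#'   4x the median bead "radius" estimated from the first-frame areas.
#' @param threshold Detection threshold (see [detect_beads()]).
#' @param min_area_px Minimum in-window area to call the bead present.
#' @param upsample_factor Upsampling factor for [subpixel_displacement()];
#'   default targets ~10 nm resolution, `ceiling(pixel_size_nm / 10)`.
#'
#' @return A tibble with columns `bead_id`, `frame`, `time_s`, `y_px`,
#'   `x_px`, `y_um`, `x_um`, `area_px`.
#' @export
track_beads <- function(movie, pixel_size_nm, frame_times_s = NULL,
                        window_half_px = NULL, threshold = "otsu",
                        min_area_px = 4,
                        upsample_factor = ceiling(pixel_size_nm / 10)) {
  stopifnot(is.array(movie), length(dim(movie)) == 3L, pixel_size_nm > 0)
  nfr <- dim(movie)[3]
  if (is.null(frame_times_s)) frame_times_s <- seq_len(nfr) - 1
  stopifnot(length(frame_times_s) == nfr)
  first <- movie[, , 1]
  det <- detect_beads(first, min_area_px = min_area_px, threshold = threshold)
  if (nrow(det) == 0) stop("no beads detected in the first frame", call. = FALSE)
  thr <- if (identical(threshold, "otsu")) {
    EBImage::otsu(EBImage::Image(t(first)), range = c(0, 1))
  } else threshold
  if (is.null(window_half_px)) {
    r_est <- sqrt(stats::median(det$area_px) / pi)
    window_half_px <- max(6L, ceiling(2 * r_est))  # window width = 4 r
  }
  ny <- dim(movie)[1]; nx <- dim(movie)[2]
  out <- vector("list", nrow(det))
  for (b in seq_len(nrow(det))) {
    yc <- round(det$y_px[b]); xc <- round(det$x_px[b])
    rows <- max(1, yc - window_half_px):min(ny, yc + window_half_px)
    cols <- max(1, xc - window_half_px):min(nx, xc + window_half_px)
    ref <- movie[rows, cols, 1]
    y <- x <- rep(NA_real_, nfr)
    area <- integer(nfr)
    for (k in seq_len(nfr)) {
      win <- movie[rows, cols, k]
      area[k] <- sum(win > thr)
      if (area[k] >= min_area_px) {
        d <- subpixel_displacement(win, ref, upsample_factor)
        y[k] <- det$y_px[b] + d[["dy"]]
        x[k] <- det$x_px[b] + d[["dx"]]
      } else {
        area[k] <- 0L
      }
    }
    out[[b]] <- tibble::tibble(
      bead_id = det$bead_id[b], frame = seq_len(nfr), time_s = frame_times_s,
      y_px = y, x_px = x,
      y_um = y * pixel_size_nm / 1000, x_um = x * pixel_size_nm / 1000,
      area_px = area
    )
  }
  res <- dplyr::bind_rows(out)
  attr(res, "pixel_size_nm") <- pixel_size_nm
  res
}

#' Select tethered beads from bidirectional-flow tracks
#'
#' A bead anchored by a single tether swings by roughly the tether length
#' plus bead radius when the flow direction reverses; stuck beads barely
#' move and free beads wash away. This selects beads whose flow-parallel
#' center excursion exceeds the threshold under *both* flow directions
#' (strict inequality). Beads present in only one direction's tracks are
#' rejected as free-floating (set `on_orphan = "error"` to treat them as a
#' validation failure instead).
#'
#' @param tracks_forward,tracks_backward Track tables from [track_beads()]
#'   (need `bead_id`, `x_um`, `y_um`).
#' @param displacement_threshold_um Threshold in micrometers (default 2.0).
#' @param flow_axis `"x"` (default) or `"y"`: the flow-parallel coordinate.
#' @param on_orphan `"reject"` (default) or `"error"` for bead ids present in
#'   only one direction.
#'
#' @return Character/integer vector of selected `bead_id`s, with attribute
#'   `"rejected"` (a tibble of per-bead excursions and reasons).
#' @export
select_tethered_beads <- function(tracks_forward, tracks_backward,
                                  displacement_threshold_um = 2.0,
                                  flow_axis = c("x", "y"),
                                  on_orphan = c("reject", "error")) {
  flow_axis <- match.arg(flow_axis)
  on_orphan <- match.arg(on_orphan)
  col <- paste0(flow_axis, "_um")
  excursion <- function(tracks) {
    stopifnot(is.data.frame(tracks), all(c("bead_id", col) %in% names(tracks)))
    tracks |>
      dplyr::group_by(.data$bead_id) |>
      dplyr::summarise(excursion_um = {
        v <- .data[[col]][!is.na(.data[[col]])]
        if (length(v) < 2) 0 else max(abs(v - v[1]))
      }, .groups = "drop")
  }
  fwd <- excursion(tracks_forward)
  bwd <- excursion(tracks_backward)
  orphans <- union(setdiff(fwd$bead_id, bwd$bead_id),
                   setdiff(bwd$bead_id, fwd$bead_id))
  if (length(orphans) > 0 && on_orphan == "error") {
    stop("bead ids present in only one flow direction: ",
         paste(orphans, collapse = ", "), call. = FALSE)
  }
  both <- dplyr::inner_join(fwd, bwd, by = "bead_id",
                            suffix = c("_fwd", "_bwd"))
  sel <- both$excursion_um_fwd > displacement_threshold_um &
    both$excursion_um_bwd > displacement_threshold_um
  rejected <- dplyr::bind_rows(
    both[!sel, , drop = FALSE] |> dplyr::mutate(reason = "sub-threshold"),
    tibble::tibble(bead_id = orphans, excursion_um_fwd = NA_real_,
                   excursion_um_bwd = NA_real_, reason = "orphan")
  )
  out <- both$bead_id[sel]
  attr(out, "rejected") <- rejected
  out
}

#' Rupture flow rate of one bead from area dropout
#'
#' Scans a bead's area series for the first frame at which the in-window
#' pixel area falls below `area_floor_fraction` times the bead's initial
#' area (median of its first frames); the ramp flow rate at that frame's
#' time is the rupture flow rate. A bead that never drops out is censored
#' at the final flow rate.
#'
#' @param track One bead's rows from [track_beads()] (columns `time_s`,
#'   `area_px`; a `bead_id` column is carried through if present).
#' @param protocol The [loading_protocol()] aligned to `time_s`.
#' @param area_floor_fraction Dropout threshold as a fraction of the initial
#'   area (default 0.5).
#' @param n_baseline_frames Frames used for the initial-area median
#'   (default 5).
#'
#' @return One-row tibble: `bead_id`, `rupture_time_s`,
#'   `rupture_flow_rate_mm3_s`, `censored`.
#' @export
detect_rupture <- function(track, protocol, area_floor_fraction = 0.5,
                           n_baseline_frames = 5L) {
  stopifnot(is.data.frame(track),
            all(c("time_s", "area_px") %in% names(track)),
            inherits(protocol, "loading_protocol"),
            area_floor_fraction > 0, area_floor_fraction <= 1)
  track <- track[order(track$time_s), , drop = FALSE]
  if (all(track$area_px == 0)) {
    stop("bead never detected: area series is all zero", call. = FALSE)
  }
  id <- if ("bead_id" %in% names(track)) track$bead_id[1] else NA
  base <- stats::median(utils::head(track$area_px,
                                    min(n_baseline_frames, nrow(track))))
  dropped <- track$area_px < area_floor_fraction * base
  if (any(dropped)) {
    t_rupt <- track$time_s[which(dropped)[1]]
    censored <- FALSE
  } else {
    t_rupt <- track$time_s[nrow(track)]
    censored <- TRUE
  }
  tibble::tibble(bead_id = id, rupture_time_s = t_rupt,
                 rupture_flow_rate_mm3_s = protocol$flow_rate(t_rupt),
                 censored = censored)
}

#' Rupture flow rates for all beads in a track table
#'
#' @param tracks Track table from [track_beads()].
#' @inheritParams detect_rupture
#' @return Tibble with one row per bead (see [detect_rupture()]).
#' @export
detect_ruptures <- function(tracks, protocol, area_floor_fraction = 0.5,
                            n_baseline_frames = 5L) {
  tracks |>
    dplyr::group_by(.data$bead_id) |>
    dplyr::group_map(~ detect_rupture(dplyr::mutate(.x, bead_id = .y$bead_id),
                                      protocol, area_floor_fraction,
                                      n_baseline_frames)) |>
    dplyr::bind_rows()
}
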