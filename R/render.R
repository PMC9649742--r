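#' Render a synthetic multi-frame bead movie
#'
#' Draws each bead at its sub-pixel center in every frame, as either a
#' soft-edged disk (a disk of the given radius whose edge is blurred by a
#' 1-px Gaussian, mimicking a bright bead blob in transmitted-light imaging)
#' or a Gaussian spot, plus optional additive Gaussian noise. A bead whose
#' row has `present = FALSE` renders nothing in that frame (area dropout at
#' rupture).
#'
#' @param tracks A data frame with columns `bead_id`, `frame` (1-based),
#'   `y_px`, `x_px` and optionally `present` (logical, default `TRUE`).
#' @param field_dim Field size `c(n_rows, n_cols)` in pixels.
#' @param bead_radius_px Bead radius in pixels (disk profile) or `2 sigma`
#'   (Gaussian profile).
#' @param bead_profile `"disk"` (default) or `"gaussian"`.
#' @param amplitude Peak bead intensity (image values are clipped to [0, 1]).
#' @param noise_sd Additive Gaussian noise SD in intensity units.
#' @param seed Optional integer seed (noise only).
#'
#' @return A numeric array `field_dim[1] x field_dim[2] x n_frames` with
#'   values in [0, 1]. Row index is y (origin top-left), column index is x.
#' @examples
#' tr <- tibble::tibble(bead_id = 1, frame = 1:3, y_px = 16, x_px = 16)
#' mov <- render_bead_movie(tr, field_dim = c(32, 32), bead_radius_px = 3)
#' @export
render_bead_movie <- function(tracks, field_dim, bead_radius_px = 4,
                              bead_profile = c("disk", "gaussian"),
                              amplitude = 0.8, noise_sd = 0, seed = NULL) {
  bead_profile <- match.arg(bead_profile)
  stopifnot(is.data.frame(tracks),
            all(c("bead_id", "frame", "y_px", "x_px") %in% names(tracks)),
            length(field_dim) == 2L, all(field_dim >= 4), bead_radius_px > 0,
            noise_sd >= 0)
  if (!"present" %in% names(tracks)) tracks$present <- TRUE
  visible <- tracks[tracks$present & is.finite(tracks$x_px) &
                      is.finite(tracks$y_px), , drop = FALSE]
  if (nrow(visible) > 0 &&
      (any(visible$x_px < 1) || any(visible$x_px > field_dim[2]) ||
       any(visible$y_px < 1) || any(visible$y_px > field_dim[1]))) {
    stop("bead positions must lie inside the field", call. = FALSE)
  }
  f1 <- visible[visible$frame == min(tracks$frame), , drop = FALSE]
  if (nrow(f1) > 1) {
    dmin <- min(stats::dist(cbind(f1$y_px, f1$x_px)))
    if (dmin < 2 * bead_radius_px) {
      warning("beads closer than twice the profile radius: tracking windows ",
              "would collide", call. = FALSE)
    }
  }
  frames <- sort(unique(tracks$frame))
  nfr <- length(frames)
  if (!is.null(seed)) set.seed(seed)
  movie <- array(0, dim = c(field_dim[1], field_dim[2], nfr))
  half <- ceiling(bead_radius_px + 4)
  for (k in seq_len(nfr)) {
    fr <- visible[visible$frame == frames[k], , drop = FALSE]
    img <- matrix(0, field_dim[1], field_dim[2])
    for (b in seq_len(nrow(fr))) {
      y0 <- fr$y_px[b]; x0 <- fr$x_px[b]
      rows <- max(1, floor(y0) - half):min(field_dim[1], ceiling(y0) + half)
      cols <- max(1, floor(x0) - half):min(field_dim[2], ceiling(x0) + half)
      dy <- rows - y0
      dx <- cols - x0
      dist <- sqrt(outer(dy^2, dx^2, `+`))
      patch <- if (bead_profile == "disk") {
        amplitude * stats::pnorm(bead_radius_px - dist)  # 1-px Gaussian edge
      } else {
        amplitude * exp(-dist^2 / (2 * (bead_radius_px / 2)^2))
      }
      img[rows, cols] <- img[rows, cols] + patch
    }
    if (noise_sd > 0) {
      img <- img + matrix(stats::rnorm(length(img), sd = noise_sd),
                          nrow(img), ncol(img))
    }
    movie[, , k] <- pmin(pmax(img, 0), 1)
  }
  attr(movie, "frames") <- frames
  movie
}

#' Simulate a trackable movie of a flow-ramp rupture experiment
#'
#' Couples [simulate_rupture_experiment()] to [render_bead_movie()]: beads
#' are laid out on a jittered grid (one field per chip, channels side by
#' side is not modelled -- each channel gets its own movie), imaged at a
#' fixed frame rate during the ramp, and disappear from the first frame at
#' which the ramp flow rate exceeds their sampled rupture flow rate.
#'
#' @param experiment One channel's rows from [simulate_rupture_experiment()].
#' @param protocol The [loading_protocol()] used for the experiment.
#' @param frame_interval_s Time between frames in s.
#' @param field_dim Field size `c(n_rows, n_cols)` in pixels.
#' @param bead_radius_px Rendered bead radius in pixels.
#' @param noise_sd Additive Gaussian image noise SD.
#' @param seed Optional integer seed (layout + noise).
#'
#' @return A list with `movie` (array), `tracks_truth` (tibble of rendered
#'   positions with `present`), `frame_times_s`, and `experiment` (the input
#'   with a `rupture_frame` column; `NA` when censored).
#' @export
simulate_rupture_movie <- function(experiment, protocol, frame_interval_s,
                                   field_dim = c(128, 128), bead_radius_px = 3,
                                   noise_sd = 0, seed = NULL) {
  stopifnot(is.data.frame(experiment), inherits(protocol, "loading_protocol"),
            frame_interval_s > 0)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(experiment)
  frame_times <- seq(0, protocol$duration_s, by = frame_interval_s)
  nfr <- length(frame_times)
  # jittered grid layout with margins for the tracking windows
  margin <- 4 * bead_radius_px
  ncol_grid <- ceiling(sqrt(n * field_dim[2] / field_dim[1]))
  nrow_grid <- ceiling(n / ncol_grid)
  if (nrow_grid * 8 * bead_radius_px > field_dim[1] ||
      ncol_grid * 8 * bead_radius_px > field_dim[2]) {
    stop("field too small for this many beads without window collisions",
         call. = FALSE)
  }
  gx <- seq(margin, field_dim[2] - margin, length.out = ncol_grid)
  gy <- seq(margin, field_dim[1] - margin, length.out = nrow_grid)
  pos <- expand.grid(y_px = gy, x_px = gx)[seq_len(n), ]
  pos$y_px <- pos$y_px + stats::runif(n, -1, 1)
  pos$x_px <- pos$x_px + stats::runif(n, -1, 1)
  q_at_frame <- protocol$flow_rate(frame_times)
  rupture_frame <- vapply(seq_len(n), function(b) {
    if (experiment$censored[b]) return(NA_integer_)
    idx <- which(q_at_frame >= experiment$rupture_flow_rate_mm3_s[b])
    if (length(idx) == 0) NA_integer_ else idx[1]
  }, integer(1))
  tracks <- tidyr::crossing(bead = seq_len(n), frame = seq_len(nfr))
  tracks$bead_id <- experiment$bead_id[tracks$bead]
  tracks$y_px <- pos$y_px[tracks$bead]
  tracks$x_px <- pos$x_px[tracks$bead]
  rf <- rupture_frame[tracks$bead]
  tracks$present <- is.na(rf) | tracks$frame < rf
  tracks <- tracks[, c("bead_id", "frame", "y_px", "x_px", "present")]
  movie <- render_bead_movie(tracks, field_dim = field_dim,
                             bead_radius_px = bead_radius_px,
                             noise_sd = noise_sd)
  experiment$rupture_frame <- rupture_frame
  list(movie = movie, tracks_truth = tracks, frame_times_s = frame_times,
       experiment = experiment)
}

#' Write a movie array as a multi-page 16-bit TIFF
#'
#' @param movie Array `ny x nx x n_frames`, values in [0, 1].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_movie_tiff <- function(movie, path) {
  stopifnot(is.array(movie), length(dim(movie)) == 3L)
  pages <- lapply(seq_len(dim(movie)[3]), function(k) movie[, , k])
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read a multi-page TIFF movie into an array
#'
#' @param path TIFF file path.
#' @return Array `ny x nx x n_frames`, values in [0, 1].
#' @export
read_movie_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  array(unlist(pages), dim = c(dim(pages[[1]])[1:2], length(pages)))
}
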