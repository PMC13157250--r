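# Rigid, translation-only motion correction. Shifts are estimated per frame
# by phase correlation against a median template, refined to subpixel
# precision with a local matrix-multiply DFT upsampling (the standard
# efficient subpixel image-registration scheme), and applied by bilinear
# interpolation. Sign convention: applying the returned shift to a frame
# aligns it to the template.

#' Build a registration template from a frame range
#'
#' @param movie a [gevi_movie()].
#' @param frame_range integer frame indices (1-based), non-empty, within
#'   `[1, T]`; defaults to the first 100 frames. The template is the
#'   pixelwise median, which is robust to spikes and noise.
#' @return numeric `H x W` matrix.
#' @export
make_template <- function(movie, frame_range = seq_len(min(100L, n_frames(movie)))) {
  check_that(inherits(movie, "gevi_movie"), "movie must be a gevi_movie")
  frame_range <- as.integer(frame_range)
  check_that(length(frame_range) >= 1, "frame_range must be non-empty")
  check_that(all(frame_range >= 1 & frame_range <= n_frames(movie)),
             "frame_range must lie within [1, %d]", n_frames(movie))
  sub <- movie$frames[, , frame_range, drop = FALSE]
  if (length(frame_range) == 1L) return(sub[, , 1])
  apply(sub, c(1, 2), stats::median)
}

# Upsampled cross-correlation in a (1.5 x 1.5) px neighbourhood of an
# integer peak, via matrix-multiply DFT (no full zero-padded FFT needed).
refine_subpixel <- function(cross_spec, peak_dy, peak_dx, upsample) {
  d <- dim(cross_spec); h <- d[1]; w <- d[2]
  usfac <- upsample
  nb <- ceiling(usfac * 1.5)                 # samples across the window
  # sample offsets around the integer peak, spacing 1/usfac px
  off <- (seq_len(nb) - 1 - floor(nb / 2)) / usfac
  fy <- c(0:(floor(h / 2)), -(ceiling(h / 2) - 1):-1) / h  # fft freqs
  fx <- c(0:(floor(w / 2)), -(ceiling(w / 2) - 1):-1) / w
  ky <- exp(2i * pi * outer(peak_dy + off, fy))    # nb x h
  kx <- exp(2i * pi * outer(fx, peak_dx + off))    # w x nb
  cc <- Re(ky %*% cross_spec %*% kx)
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  c(peak_dy + off[pk[1]], peak_dx + off[pk[2]])
}

#' Estimate per-frame rigid shifts by phase correlation
#'
#' For each frame the mean-subtracted cross-correlation against the template
#' is computed via FFT; the correlation peak within `+/- max_shift` gives the
#' integer displacement, refined to `1 / upsample` px by local DFT
#' upsampling of the cross spectrum. The
#' returned shift, applied to the frame with [apply_shifts()], aligns it to
#' the template.
#'
#' @param movie a [gevi_movie()].
#' @param template `H x W` matrix from [make_template()]; must not be
#'   all-zero (the correlation would be undefined).
#' @param max_shift maximum absolute shift searched, in pixels (>= 1).
#' @param upsample integer subpixel refinement factor (>= 1; 1 = integer).
#' @return an object of class `shift_series`: a `T x 2` matrix with columns
#'   `dy`, `dx` and attributes `template_range` and `upsample`.
#' @export
estimate_shifts <- function(movie, template, max_shift = 10, upsample = 10L) {
  check_that(inherits(movie, "gevi_movie"), "movie must be a gevi_movie")
  d <- dim(movie$frames)
  check_that(all(dim(template) == d[1:2]), "template size must match frames")
  check_that(any(template != 0), "template is all-zero; correlation undefined")
  check_that(max_shift >= 1, "max_shift must be >= 1")
  upsample <- as.integer(upsample)
  check_that(upsample >= 1, "upsample must be >= 1")
  h <- d[1]; w <- d[2]; n_t <- d[3]
  # mean-subtracted cross-correlation (no spectral whitening): robust to
  # shot noise on band-limited fluorescence images
  ft_t <- stats::fft(template - mean(template))
  # wrap-around displacement values for each fft bin
  dy_of <- c(0:(floor(h / 2)), -(ceiling(h / 2) - 1):-1)
  dx_of <- c(0:(floor(w / 2)), -(ceiling(w / 2) - 1):-1)
  ok_y <- abs(dy_of) <= max_shift
  ok_x <- abs(dx_of) <= max_shift
  shifts <- matrix(0, n_t, 2, dimnames = list(NULL, c("dy", "dx")))
  for (t in seq_len(n_t)) {
    fr <- movie$frames[, , t]
    cs <- stats::fft(fr - mean(fr)) * Conj(ft_t)
    cc <- Re(stats::fft(cs, inverse = TRUE))
    cc_w <- cc[ok_y, ok_x, drop = FALSE]
    pk <- which(cc_w == max(cc_w), arr.ind = TRUE)[1, ]
    dy <- dy_of[ok_y][pk[1]]; dx <- dx_of[ok_x][pk[2]]
    if (upsample > 1L) {
      s <- refine_subpixel(cs, dy, dx, upsample)
      dy <- s[1]; dx <- s[2]
    }
    # cc peaks at the displacement of the frame relative to the template;
    # the aligning correction is its negative
    shifts[t, ] <- c(-dy, -dx)
  }
  structure(shifts, class = c("shift_series", "matrix"),
            template_range = attr(template, "frame_range"),
            upsample = upsample)
}

#' Apply per-frame shifts to a movie
#'
#' Each frame is translated by its `(dy, dx)` with bilinear interpolation;
#' pixels sampled from outside the field are filled with that frame's median
#' and intensities are clamped at zero.
#'
#' @param movie a [gevi_movie()].
#' @param shifts a [estimate_shifts()] result or a `T x 2` numeric matrix.
#' @return a corrected [gevi_movie()].
#' @export
apply_shifts <- function(movie, shifts) {
  check_that(inherits(movie, "gevi_movie"), "movie must be a gevi_movie")
  shifts <- unclass(shifts)
  check_that(is.matrix(shifts) && ncol(shifts) == 2 &&
               nrow(shifts) == n_frames(movie),
             "shifts must be a T x 2 matrix matching the movie")
  out <- movie$frames
  for (t in seq_len(n_frames(movie))) {
    if (shifts[t, 1] != 0 || shifts[t, 2] != 0) {
      out[, , t] <- pmax(0, translate_bilinear(movie$frames[, , t],
                                               shifts[t, 1], shifts[t, 2]))
    }
  }
  gevi_movie(out, movie$meta)
}

#' Motion-correct a movie in one call
#'
#' Convenience wrapper: template from the first `template_frames` frames,
#' shift estimation, then shift application.
#'
#' @inheritParams estimate_shifts
#' @param template_frames number of leading frames for the median template.
#' @return list with `movie` (corrected) and `shifts` (the `shift_series`).
#' @export
motion_correct <- function(movie, max_shift = 10, upsample = 10L,
                           template_frames = 100L) {
  template <- make_template(movie,
                            seq_len(min(template_frames, n_frames(movie))))
  shifts <- estimate_shifts(movie, template, max_shift, upsample)
  list(movie = apply_shifts(movie, shifts), shifts = shifts)
}

#' Write / read a shift series as CSV (frame, dy, dx)
#'
#' @param shifts a `shift_series` or `T x 2` matrix.
#' @param path CSV path.
#' @return the path (write) or a `T x 2` matrix (read).
#' @export
write_shifts <- function(shifts, path) {
  df <- data.frame(frame = seq_len(nrow(shifts)) - 1L,
                   dy = shifts[, 1], dx = shifts[, 2])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_shifts
#' @export
read_shifts <- function(path) {
  df <- utils::read.csv(path)
  as.matrix(df[, c("dy", "dx")])
}
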