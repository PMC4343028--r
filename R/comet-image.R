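#' Render a synthetic comet micrograph
#'
#' Minimal physical model of one stained comet on a greyscale grid, built to
#' test the premise that integrated staining signal tracks DNA content
#' whether the cell is damaged or not. The head is an isotropic 2-D Gaussian
#' integrating to `(1 - f) * D`; the tail is a one-sided exponential profile
#' along the +x electrophoresis direction from the head center (Gaussian
#' cross-section in y) integrating to `f * D`. Both profiles are integrated
#' analytically over each pixel and renormalized on the grid, so without
#' noise or saturation the background-subtracted pixel sum equals `D` to
#' machine precision. A constant background, optional Poisson shot noise and
#' an optional saturation ceiling (pixel clipping — the distortion one must
#' avoid for quantitative DNA-content work) can be added.
#'
#' @param D total DNA signal (> 0, arbitrary units).
#' @param f damage fraction in \[0, 1\]: share of signal in the tail.
#' @param head_sd head Gaussian SD in pixels (default 1.6; compact relative
#'   to the tail decay length so the head peak dominates the column profile
#'   even at high damage fractions).
#' @param tail_decay tail exponential decay length in pixels (default 80).
#' @param grid `c(ny, nx)` image size in pixels (default `c(96, 384)`).
#' @param head_center `c(x, y)` head center in pixels (default `c(40, 48)`).
#' @param background constant background level per pixel (default 0).
#' @param noise `"none"` or `"poisson"`.
#' @param saturation optional ceiling; pixels are clipped to it.
#' @param seed integer seed (Poisson noise only).
#' @return A `comet_image`: list with `pixels` (ny x nx matrix), `pixel_size`
#'   and a `ground_truth` list (`D`, `f`, `head_center`, `background`,
#'   `saturation`). Quantification must not look at `ground_truth`.
#' @export
render_comet <- function(D, f, head_sd = 1.6, tail_decay = 80,
                         grid = c(96, 384), head_center = c(40, 48),
                         background = 0, noise = c("none", "poisson"),
                         saturation = NULL, seed = 1L) {
  noise <- match.arg(noise)
  stopifnot_number(D, "D", positive = TRUE)
  stopifnot_number(f, "f", nonneg = TRUE)
  if (f > 1) abort_cometcal("`f` must be in [0, 1]", "cometcal_parameter_error")
  stopifnot_number(head_sd, "head_sd", positive = TRUE)
  stopifnot_number(tail_decay, "tail_decay", positive = TRUE)
  stopifnot_number(background, "background", nonneg = TRUE)
  ny <- grid[1]; nx <- grid[2]
  cx <- head_center[1]; cy <- head_center[2]
  fits <- cx - 4 * head_sd >= 1 && cx + 4 * head_sd <= nx &&
    cy - 4 * head_sd >= 1 && cy + 4 * head_sd <= ny &&
    (nx - cx) >= 3 * tail_decay
  if (!fits) {
    abort_cometcal(
      "comet geometry does not fit the grid (need 4 head SDs around the center and 3 tail decay lengths of +x room)",
      "cometcal_render_error")
  }
  # per-pixel analytic integrals, renormalized on the grid
  gauss_profile <- function(n, center) {
    p <- stats::pnorm(seq_len(n) + 0.5, center, head_sd) -
      stats::pnorm(seq_len(n) - 0.5, center, head_sd)
    p / sum(p)
  }
  hx <- gauss_profile(nx, cx)
  hy <- gauss_profile(ny, cy)
  tail_cdf <- function(x) ifelse(x <= cx, 0, 1 - exp(-(x - cx) / tail_decay))
  tx <- tail_cdf(seq_len(nx) + 0.5) - tail_cdf(seq_len(nx) - 0.5)
  tx <- tx / sum(tx)
  pixels <- (1 - f) * D * outer(hy, hx) + f * D * outer(hy, tx) + background
  if (noise == "poisson") {
    set.seed(as.integer(seed))
    pixels <- matrix(stats::rpois(length(pixels), pixels), nrow = ny)
  }
  if (!is.null(saturation)) {
    stopifnot_number(saturation, "saturation", positive = TRUE)
    pixels <- pmin(pixels, saturation)
  }
  structure(list(pixels = pixels, pixel_size = 1,
                 ground_truth = list(D = D, f = f,
                                     head_center = c(x = cx, y = cy),
                                     background = background,
                                     saturation = saturation)),
            class = "comet_image")
}

#' Quantify a comet image
#'
#' Re-implements, at toy scale, what comet scoring systems report per cell:
#' total fluorescence intensity, Tail %DNA and Tail Moment. Works from
#' pixels alone — when given a `comet_image` it strips the object down to
#' its pixel matrix first and never reads the ground truth.
#'
#' Steps: background = median of the outermost 2-pixel border; object mask =
#' pixels above background + 3 robust SDs (MAD) of the border; TFI = sum of
#' background-subtracted masked pixels; head center = peak of the masked
#' column profile (leftmost on ties); head SD estimated from the profile's
#' left flank (mirrored); head/tail split at head center + 2 estimated SDs;
#' Tail %DNA = 100 x masked signal right of the split over total; Tail
#' Moment = tail fraction x (tail intensity centroid - head center) in
#' pixels. The fixed 3-SD rule and the simple split are documented
#' conventions of this toy scorer, not a claim of equivalence to any
#' commercial algorithm.
#'
#' @param image a `comet_image` or a plain numeric matrix of pixels.
#' @return List with `tfi`, `tail_dna_pct`, `tail_moment`, and the
#'   `background` and `head_x` estimates.
#' @export
quantify_comet <- function(image) {
  pixels <- if (inherits(image, "comet_image")) image$pixels else image
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    abort_cometcal("`image` must be a comet_image or numeric matrix",
                   "cometcal_parameter_error")
  }
  ny <- nrow(pixels); nx <- ncol(pixels)
  border <- c(pixels[c(1, 2, ny - 1, ny), ], pixels[3:(ny - 2), c(1, 2, nx - 1, nx)])
  bg <- stats::median(border)
  rsd <- stats::mad(border)
  mask <- pixels > bg + 3 * rsd
  if (!any(mask)) {
    abort_cometcal("no pixels above the detection threshold; empty image",
                   "cometcal_empty_image_error")
  }
  sig <- (pixels - bg) * mask
  sig[sig < 0] <- 0
  tfi <- sum(sig)
  prof <- colSums(sig)
  head_x <- which.max(prof)  # leftmost maximum by which.max convention
  # head SD from the tail-free left flank: interpolate the abscissa where the
  # cumulative profile reaches the one-sigma fraction (15.87% / 50%) of the
  # left-flank mass, a quantile estimate unbiased by pixel discretization
  cum <- cumsum(prof)
  left_mass <- cum[head_x] - prof[head_x] / 2
  head_sd_est <- 0.5
  if (left_mass > 0) {
    target <- (stats::pnorm(-1) / 0.5) * left_mass
    j <- which(cum >= target)[1L]
    if (!is.na(j) && j <= head_x && prof[j] > 0) {
      below <- if (j > 1L) cum[j - 1L] else 0
      x_sigma <- (j - 0.5) + (target - below) / prof[j]
      head_sd_est <- max(0.5, head_x - x_sigma)
    }
  }
  split <- head_x + 2 * head_sd_est
  tail_cols <- which(seq_len(nx) > split)
  tail_mass <- sum(prof[tail_cols])
  td <- 100 * tail_mass / sum(prof)
  tm <- if (tail_mass > 0) {
    (td / 100) * (sum(tail_cols * prof[tail_cols]) / tail_mass - head_x)
  } else 0
  list(tfi = tfi, tail_dna_pct = td, tail_moment = tm,
       background = bg, head_x = head_x)
}

#' Write / read a comet image as 16-bit greyscale TIFF
#'
#' Intensities are stored linearly scaled to the 16-bit range by
#' `full_scale` (default: the image maximum). `read_comet_image` undoes the
#' scaling given the same `full_scale`, so values round-trip to within one
#' part in 65 535.
#'
#' @param image a `comet_image` or numeric matrix.
#' @param path output `.tif` path.
#' @param full_scale intensity mapped to white (default `max(pixels)`).
#' @return `write_comet_image`: `full_scale`, invisibly;
#'   `read_comet_image`: numeric matrix of intensities.
#' @export
write_comet_image <- function(image, path, full_scale = NULL) {
  pixels <- if (inherits(image, "comet_image")) image$pixels else image
  full_scale <- full_scale %||% max(pixels)
  m <- pmin(pmax(pixels / full_scale, 0), 1)
  tiff::writeTIFF(m, path, bits.per.sample = 16L)
  invisible(full_scale)
}

#' @rdname write_comet_image
#' @export
read_comet_image <- function(path, full_scale = 1) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  m * full_scale
}
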