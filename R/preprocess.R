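# Standardization chain: frame-quality filtering, min-max normalization,
# length standardization to a fixed frame count, Gaussian smoothing, and the
# three augmentation / interference operators.

#' Gray-variance frame-quality filter
#'
#' Flags blurry video frames by pixel-intensity variance: frames whose
#' variance falls below the threshold (default 50) are considered blurred and
#' dropped. Applies to optional grayscale video input only; the main pipeline
#' consumes pose sequences directly.
#'
#' @param frames List of 2-D numeric intensity matrices.
#' @param threshold Variance threshold; frames with variance `>= threshold`
#'   are kept.
#' @return Integer indices of kept frames, order preserved.
#' @export
gray_variance_filter <- function(frames, threshold = 50) {
  if (length(frames) == 0L) return(integer(0))
  ok <- vapply(frames, function(f) {
    stop_if(!(is.matrix(f) && is.numeric(f)), "frames must be 2-D intensity matrices")
    v <- mean((f - mean(f))^2)  # population variance of the pixel intensities
    v >= threshold
  }, logical(1))
  which(ok)
}

#' Per-axis min-max normalization statistics
#'
#' Corpus minima and maxima per joint and axis, used to map coordinates to
#' `[0, 1]` and so remove dancer height (1.55-1.85 m) and body-type
#' differences.
#'
#' @param sequences List of [pose_sequence()] objects (typically the training
#'   split).
#' @return A list of class `normalization_stats` with 25 x 3 matrices `x_min`
#'   and `x_max`.
#' @export
pose_stats <- function(sequences) {
  x_min <- matrix(Inf, 25L, 3L)
  x_max <- matrix(-Inf, 25L, 3L)
  for (s in sequences) {
    coords <- as_coords(s)
    x_min <- pmin(x_min, apply(coords, c(2, 3), min))
    x_max <- pmax(x_max, apply(coords, c(2, 3), max))
  }
  structure(list(x_min = x_min, x_max = x_max), class = "normalization_stats")
}

#' Min-max normalize a pose sequence
#'
#' Maps every coordinate by `(x - x_min) / (x_max - x_min)`. A degenerate axis
#' (`x_max == x_min`, e.g. a static joint) maps to 0 rather than erroring.
#'
#' @param seq A [pose_sequence()].
#' @param stats A `normalization_stats` from [pose_stats()].
#' @return The normalized sequence; coordinates lie in `[0, 1]` whenever the
#'   input lies within the stats range.
#' @export
minmax_normalize <- function(seq, stats) {
  stop_if(!all(is.finite(stats$x_min)) || !all(is.finite(stats$x_max)),
          "normalization stats must be finite")
  stop_if(any(stats$x_max < stats$x_min), "x_max must be >= x_min elementwise")
  coords <- as_coords(seq)
  rng <- stats$x_max - stats$x_min
  out <- coords
  for (j in 1:25) {
    for (d in 1:3) {
      out[, j, d] <- if (rng[j, d] == 0) 0 else
        (coords[, j, d] - stats$x_min[j, d]) / rng[j, d]
    }
  }
  replace_coords(seq, out)
}

#' Standardize sequence length to a fixed frame count
#'
#' Short sequences (fewer than `target` frames) are completed by linear
#' interpolation along time. Long sequences are segmented at the music-beat
#' frames nearest each multiple of `target` (uniform cuts when no beats are
#' recorded), and every segment is then linearly resampled to exactly
#' `target` frames.
#'
#' @param seq A [pose_sequence()] with at least 2 frames.
#' @param target Target frame count (default 100).
#' @return A list of [pose_sequence()] objects, each with exactly `target`
#'   frames.
#' @export
standardize_length <- function(seq, target = 100) {
  coords <- as_coords(seq)
  n <- dim(coords)[1]
  stop_if(n < 2L, "standardize_length needs at least 2 frames")
  if (n == target) return(list(seq))
  if (n < target) return(list(resample_sequence(seq, target)))

  n_seg <- ceiling(n / target)
  beats <- seq$beat_frames + 1L  # to 1-based
  cuts <- integer(0)
  for (m in seq_len(n_seg - 1L)) {
    want <- m * target + 1L
    cut <- if (length(beats) > 1L) beats[which.min(abs(beats - want))] else want
    cuts <- c(cuts, cut)
  }
  cuts <- unique(pmin(pmax(cuts, 2L), n))  # keep every segment non-empty
  bounds <- c(1L, cuts, n + 1L)
  out <- vector("list", length(bounds) - 1L)
  for (s in seq_along(out)) {
    idx <- bounds[s]:(bounds[s + 1L] - 1L)
    piece <- replace_coords(seq, coords[idx, , , drop = FALSE])
    piece$beat_frames <- integer(0)
    out[[s]] <- if (length(idx) == target) piece else resample_sequence(piece, target)
  }
  out
}

# Linear time-resampling of a sequence to `target` frames.
resample_sequence <- function(seq, target) {
  coords <- as_coords(seq)
  n <- dim(coords)[1]
  if (n == 1L) {
    out <- array(coords[rep(1L, target), , ], c(target, 25L, 3L))
  } else {
    grid <- seq(1, n, length.out = target)
    out <- array(0, c(target, 25L, 3L))
    for (j in 1:25) {
      for (d in 1:3) {
        out[, j, d] <- approx(seq_len(n), coords[, j, d], xout = grid)$y
      }
    }
  }
  res <- replace_coords(seq, out)
  if (inherits(res, "pose_sequence")) {
    res$beat_frames <- sort(unique(as.integer(round(seq$beat_frames * (target - 1) /
                                                      max(n - 1, 1)))))
  }
  res
}

#' Gaussian temporal smoothing
#'
#' Convolves every coordinate channel with a length-`window` Gaussian kernel
#' (normalized to sum 1) to suppress capture noise; edges are handled by
#' reflection so boundary frames are not attenuated.
#'
#' @param seq A [pose_sequence()] or T x 25 x 3 array.
#' @param window Odd window length in frames (default 5).
#' @param sigma Kernel standard deviation in frames (default 0.8).
#' @return The smoothed sequence.
#' @export
gaussian_smooth <- function(seq, window = 5, sigma = 0.8) {
  stop_if(window %% 2 == 0, "window must be odd")
  stop_if(sigma <= 0, "sigma must be positive")
  kern <- gaussian_kernel(window, sigma)
  coords <- as_coords(seq)
  n <- dim(coords)[1]
  half <- (window - 1L) / 2L
  pad_idx <- c(rev(seq_len(half) + 1L), seq_len(n), n - seq_len(half))  # reflect
  out <- coords
  for (j in 1:25) {
    for (d in 1:3) {
      padded <- coords[pad_idx, j, d]
      out[, j, d] <- vapply(seq_len(n), function(t)
        sum(kern * padded[t:(t + window - 1L)]), numeric(1))
    }
  }
  replace_coords(seq, out)
}

#' Discrete Gaussian kernel weights
#'
#' @param window Odd kernel length.
#' @param sigma Standard deviation in samples.
#' @return Numeric vector of length `window`, summing to 1.
#' @export
gaussian_kernel <- function(window, sigma) {
  half <- (window - 1) / 2
  w <- exp(-((-half):half)^2 / (2 * sigma^2))
  w / sum(w)
}

#' Augmentation / interference specification
#'
#' The three perturbation operators used both as training augmentation and as
#' robustness interference scenarios: temporal scaling (frame-rate factor
#' within +-`temporal_scale_pct`%), spatial noise (additive coordinate
#' perturbation bounded by `spatial_noise_pct`% of each axis range) and
#' feature disturbance (per-frame joint-angle jitter up to
#' `angle_jitter_deg` degrees, applied in the parent-bone local frame).
#' Setting a magnitude to 0 switches that operator off.
#'
#' @param temporal_scale_pct Temporal scaling bound in percent (default 10).
#' @param spatial_noise_pct Spatial noise bound in percent of axis range
#'   (default 5).
#' @param angle_jitter_deg Per-frame joint-angle jitter bound in degrees
#'   (default 3).
#' @param seed Integer seed for the perturbation draws.
#' @return A list of class `augment_spec`.
#' @export
augment_spec <- function(temporal_scale_pct = 10, spatial_noise_pct = 5,
                         angle_jitter_deg = 3, seed = 1) {
  stop_if(temporal_scale_pct < 0 || spatial_noise_pct < 0 || angle_jitter_deg < 0,
          "augmentation magnitudes must be non-negative")
  structure(list(temporal_scale_pct = temporal_scale_pct,
                 spatial_noise_pct = spatial_noise_pct,
                 angle_jitter_deg = angle_jitter_deg,
                 seed = as.integer(seed)),
            class = "augment_spec")
}

#' Apply the augmentation operators to a sequence
#'
#' Under the seeded random state: (a) temporal resampling by a factor drawn
#' uniformly from `[1 - s, 1 + s]` with `s = temporal_scale_pct/100`,
#' re-interpolated back to the input length; (b) additive coordinate noise
#' drawn uniformly within `spatial_noise_pct`% of each axis' observed range;
#' (c) per-joint per-frame rotation of the parent-relative bone vector about
#' a random axis by an angle within `angle_jitter_deg` degrees, with child
#' positions rebuilt down the tree. The drawn temporal factor is attached as
#' attribute `"temporal_factor"`.
#'
#' @param seq A [pose_sequence()] (typically standardized to 100 frames).
#' @param spec An [augment_spec()].
#' @param topo Skeleton topology used for the angle jitter.
#' @return The augmented [pose_sequence()].
#' @export
augment <- function(seq, spec, topo = default_skeleton()) {
  coords <- as_coords(seq)
  n <- dim(coords)[1]
  with_seed(spec$seed, {
    factor <- 1
    # (a) temporal scaling
    if (spec$temporal_scale_pct > 0) {
      s <- spec$temporal_scale_pct / 100
      factor <- runif(1, 1 - s, 1 + s)
      m <- max(2L, as.integer(round(n * factor)))
      warped <- resample_sequence(replace_coords(seq, coords), m)
      coords <- as_coords(resample_sequence(warped, n))
    }
    # (b) spatial noise, bounded by a fraction of each axis' range
    if (spec$spatial_noise_pct > 0) {
      frac <- spec$spatial_noise_pct / 100
      for (d in 1:3) {
        rng <- diff(range(coords[, , d]))
        if (rng > 0) {
          coords[, , d] <- coords[, , d] +
            array(runif(n * 25L, -frac * rng, frac * rng), c(n, 25L))
        }
      }
    }
    # (c) joint-angle jitter in the parent-bone local frame
    if (spec$angle_jitter_deg > 0) {
      max_rad <- spec$angle_jitter_deg * pi / 180
      ord <- skeleton_order(topo)
      for (t in seq_len(n)) {
        frame <- coords[t, , ]
        new <- frame
        for (j in ord) {
          p <- topo$parent[j]
          if (is.na(p)) next
          bone <- frame[j, ] - frame[p, ]
          axis <- rnorm(3)
          axis <- axis / sqrt(sum(axis^2))
          ang <- runif(1, -max_rad, max_rad)
          new[j, ] <- new[p, ] + rotate_about_axis(bone, axis, ang)
        }
        coords[t, , ] <- new
      }
    }
    out <- replace_coords(seq, coords)
    attr(out, "temporal_factor") <- factor
    out
  })
}

# Rodrigues rotation of vector v about unit axis k by angle theta.
rotate_about_axis <- function(v, k, theta) {
  v * cos(theta) + crossprod3(k, v) * sin(theta) + k * sum(k * v) * (1 - cos(theta))
}

crossprod3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Swap the coordinate payload of a sequence, keeping its metadata.
replace_coords <- function(seq, coords) {
  if (inherits(seq, "pose_sequence")) {
    seq$coords <- coords
    seq
  } else {
    coords
  }
}
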