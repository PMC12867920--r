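# Objective cognitive-load label construction: coordination entropy, the
# weighted composite, corpus scaling to [0,100], and an ICC reliability check.

#' Coordination entropy of a pose sequence
#'
#' Shannon entropy (bits) of the per-joint share of total motion. Each joint's
#' probability mass is its trajectory path length divided by the total path
#' length of all 25 joints, so a sequence in which many joints move comparable
#' distances (high multi-joint coordination demand) scores close to the
#' maximum log2(25) ~ 4.64 bits, while motion concentrated in a single joint
#' scores 0. A sequence with zero total motion carries no coordination demand
#' and is assigned 0 bits.
#'
#' @param seq A [pose_sequence()] or T x 25 x 3 coordinate array (T >= 2).
#' @return Entropy in bits, within `[0, log2(25)]`.
#' @export
#' @examples
#' s <- generate_sequence(gen_config(n_sequences = 1), difficulty = 3, seed = 1)
#' coordination_entropy(s)
coordination_entropy <- function(seq) {
  coords <- as_coords(seq)
  stop_if(dim(coords)[1] < 2L, "coordination entropy needs at least 2 frames")
  steps <- coords[-1, , , drop = FALSE] - coords[-dim(coords)[1], , , drop = FALSE]
  # per-joint path length: sum over time of Euclidean step norms
  len <- apply(steps, 2, function(m) sum(sqrt(rowSums(m^2))))
  total <- sum(len)
  if (total <= 0) return(0)
  p <- len / total
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Composite raw cognitive-load score
#'
#' Weighted sum of the four objective load factors: choreographic difficulty
#' level `D` (1-5), coordination entropy `E` (bits), the sympathetic-activation
#' proxy LF/HF (heart-rate-variability band ratio) and the attention proxy
#' `delta_alpha` (EEG alpha-power change rate). The weights (0.4, 0.3, 0.2,
#' 0.1) are fixed analytic-hierarchy-process weights taken as given.
#'
#' @param D Difficulty level, integer in `[1, 5]` (vectorized).
#' @param E Coordination entropy in bits.
#' @param lfhf LF/HF ratio.
#' @param delta_alpha Alpha-power change rate.
#' @param standardize If `TRUE`, z-score each component across the supplied
#'   vectors before weighting (off by default: the composite is applied
#'   literally on the raw scales).
#' @return The raw composite score `0.4*D + 0.3*E + 0.2*lfhf + 0.1*delta_alpha`.
#' @export
composite_load <- function(D, E, lfhf, delta_alpha, standardize = FALSE) {
  stop_if(any(D < 1 | D > 5), "difficulty D must lie in [1, 5]")
  if (standardize) {
    z <- function(x) if (length(x) > 1L && sd(x) > 0) (x - mean(x)) / sd(x) else x * 0
    D <- z(D); E <- z(E); lfhf <- z(lfhf); delta_alpha <- z(delta_alpha)
  }
  0.4 * D + 0.3 * E + 0.2 * lfhf + 0.1 * delta_alpha
}

#' Scale raw composite scores to the [0, 100] label range
#'
#' Min-max scaling over the corpus: the corpus minimum maps to 0, the maximum
#' to 100, affinely in between. A degenerate corpus (all values equal) maps to
#' 0, mirroring the degenerate-range rule of coordinate normalization.
#'
#' @param y_raw Numeric vector of raw composite scores.
#' @return Vector of labels in `[0, 100]`.
#' @export
scale_labels <- function(y_raw) {
  stop_if(length(y_raw) < 1L || any(!is.finite(y_raw)), "y_raw must be finite")
  rng <- range(y_raw)
  if (diff(rng) == 0) return(rep(0, length(y_raw)))
  (y_raw - rng[1]) / diff(rng) * 100
}

#' Intraclass correlation coefficient ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-rater ICC, the standard
#' agreement statistic for "k raters each score the same n items". Computed
#' from the two-way ANOVA mean squares:
#' \deqn{ICC(2,1) = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' where \eqn{MS_R}, \eqn{MS_C}, \eqn{MS_E} are the item, rater and residual
#' mean squares. Absolute agreement penalizes systematic rater bias, unlike
#' consistency-type ICCs.
#'
#' @param ratings Numeric matrix, items in rows, raters in columns, no missing
#'   cells; at least 2 items and 2 raters.
#' @return ICC(2,1) in `[-1, 1]`.
#' @export
icc_reliability <- function(ratings) {
  ratings <- as.matrix(ratings)
  stop_if(anyNA(ratings), "ratings must have no missing cells")
  n <- nrow(ratings); k <- ncol(ratings)
  stop_if(n < 2L || k < 2L, "need at least 2 items and 2 raters")
  grand <- mean(ratings)
  row_m <- rowMeans(ratings)
  col_m <- colMeans(ratings)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((ratings - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (denom == 0) return(1)  # all cells identical: perfect agreement
  (msr - mse) / denom
}

#' Build the label table for a corpus of sequences
#'
#' Computes coordination entropy per sequence, the weighted composite from the
#' sequence metadata, and the corpus-scaled `[0, 100]` label.
#'
#' @param sequences List of [pose_sequence()] objects.
#' @param standardize Passed to [composite_load()].
#' @return A data.frame with columns `sequence_id`, `D`, `E`, `lfhf`,
#'   `delta_alpha`, `y_raw`, `y`.
#' @export
build_labels <- function(sequences, standardize = FALSE) {
  stop_if(length(sequences) < 1L, "no sequences supplied")
  E <- vapply(sequences, coordination_entropy, numeric(1))
  D <- vapply(sequences, function(s) s$difficulty, numeric(1))
  lfhf <- vapply(sequences, function(s) s$lfhf, numeric(1))
  da <- vapply(sequences, function(s) s$delta_alpha, numeric(1))
  y_raw <- composite_load(D, E, lfhf, da, standardize = standardize)
  data.frame(sequence_id = seq_along(sequences), D = D, E = E, lfhf = lfhf,
             delta_alpha = da, y_raw = y_raw, y = scale_labels(y_raw))
}
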