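# Whale optimization: population search over a joint space of continuous /
# integer hyperparameters and a relaxed [0,1] block of feature-mask logits
# (decoded as the top-`n_select` slots), scored by
# fitness = alpha * MAE + (1 - alpha) * FRC.

#' Feature redundancy coefficient (FRC)
#'
#' `(1 / M^2) * sum_{j<k} |corr(f_j, f_k)|` over the selected feature
#' columns. Absolute Pearson correlations are used by default so that
#' positively and negatively redundant pairs both count as redundancy
#' (signed correlations would cancel); the raw signed sum is available with
#' `method = "signed"`. Constant columns contribute 0.
#'
#' @param features n x M numeric matrix (n >= 2 rows).
#' @param method `"absolute"` (default) or `"signed"`.
#' @return The redundancy coefficient (0 when `M = 1`).
#' @export
frc <- function(features, method = c("absolute", "signed")) {
  method <- match.arg(method)
  features <- as.matrix(features)
  stop_if(nrow(features) < 2L, "FRC needs at least 2 rows")
  M <- ncol(features)
  if (M < 2L) return(0)
  C <- suppressWarnings(cor(features))
  C[!is.finite(C)] <- 0  # constant columns
  if (method == "absolute") C <- abs(C)
  sum(C[upper.tri(C)]) / M^2
}

#' WOA fitness
#'
#' `alpha * mae + (1 - alpha) * frc_value`, weighting assessment accuracy
#' against feature redundancy (default `alpha = 0.7`).
#'
#' @param mae Mean absolute error of the candidate's predictions.
#' @param frc_value Redundancy of the candidate's feature subset.
#' @param alpha MAE weight in `(0, 1)`.
#' @return The scalar fitness (lower is better).
#' @export
woa_fitness <- function(mae, frc_value, alpha = 0.7) {
  stop_if(!(alpha > 0 && alpha < 1), "alpha must lie in (0, 1)")
  alpha * mae + (1 - alpha) * frc_value
}

#' WOA configuration
#'
#' @param population Whales per iteration (default 30).
#' @param max_iter Iteration cap (default 50).
#' @param b Spiral shape constant (default 1).
#' @param explore_prob Minimum exploration floor: with this probability a
#'   whale is forced into the random-search branch regardless of its `|A|`
#'   value (default 0.10).
#' @param alpha MAE weight of the fitness (default 0.7).
#' @param taboo_capacity Maximum entries in the FIFO taboo list.
#' @param taboo_expire Iterations after which a taboo entry expires and its
#'   region becomes admissible again (the desirability relaxation).
#' @param taboo_tol Position quantization step used to match candidates
#'   against taboo entries.
#' @param seed Integer seed for the whole search.
#' @return A list of class `woa_config`.
#' @export
woa_config <- function(population = 30, max_iter = 50, b = 1,
                       explore_prob = 0.1, alpha = 0.7,
                       taboo_capacity = 50, taboo_expire = 10,
                       taboo_tol = 0.05, seed = 1) {
  stop_if(population < 2, "population must be >= 2")
  stop_if(!(alpha > 0 && alpha < 1), "alpha must lie in (0, 1)")
  structure(list(population = as.integer(population),
                 max_iter = as.integer(max_iter), b = b,
                 explore_prob = explore_prob, alpha = alpha,
                 taboo_capacity = as.integer(taboo_capacity),
                 taboo_expire = as.integer(taboo_expire),
                 taboo_tol = taboo_tol, seed = as.integer(seed)),
            class = "woa_config")
}

#' Encircling coefficient schedule
#'
#' The control scalar `a(t) = 2 * (1 - t / max_iter)`: exactly linear from 2
#' at `t = 0` to 0 at `t = max_iter`. Since `A = 2 a r - a` with
#' `r ~ U(0, 1)`, the random-search branch (`|A| >= 1`) becomes unreachable
#' as `a` falls below 1, shifting the population from exploration to
#' exploitation.
#'
#' @param t Iteration index (0..max_iter).
#' @param max_iter Iteration cap.
#' @return The value of `a` at iteration `t`.
#' @export
woa_a_schedule <- function(t, max_iter) 2 * (1 - t / max_iter)

#' Declare a WOA search space
#'
#' A continuous block of hyperparameters (each with bounds, optional log10
#' scaling, optional rounding to integers) followed by `n_mask` relaxed
#' `[0, 1]` feature-mask logits decoded as the `n_select` largest entries.
#'
#' @param lower,upper Named numeric vectors of hyperparameter bounds (on the
#'   log10 scale for dimensions flagged in `log10`). May be empty.
#' @param integer Logical vector: round this hyperparameter to an integer
#'   (half-up) at decode time.
#' @param log10 Logical vector: decode this hyperparameter as `10^x`.
#' @param n_mask Number of feature-mask logits (0 for a purely continuous
#'   search).
#' @param n_select Number of features decoded from the mask (default 300).
#' @return A list of class `woa_space`.
#' @export
woa_space <- function(lower = numeric(0), upper = numeric(0),
                      integer = rep(FALSE, length(lower)),
                      log10 = rep(FALSE, length(lower)),
                      n_mask = 0, n_select = min(300L, n_mask)) {
  stop_if(length(lower) != length(upper), "lower/upper length mismatch")
  stop_if(any(upper < lower), "upper must be >= lower")
  stop_if(n_mask > 0 && n_select > n_mask, "n_select cannot exceed n_mask")
  structure(list(lower = lower, upper = upper,
                 integer = integer, log10 = log10,
                 n_hyper = length(lower), n_mask = as.integer(n_mask),
                 n_select = as.integer(n_select),
                 bounds_lo = c(lower, rep(0, n_mask)),
                 bounds_hi = c(upper, rep(1, n_mask))),
            class = "woa_space")
}

#' Decode a whale position
#'
#' Continuous hyperparameter coordinates are clipped into their declared
#' bounds, exponentiated for log10-scale dimensions and rounded half-up for
#' integer dimensions. The feature subset is the set of `n_select` largest
#' mask logits, ties broken toward the lowest index; exactly `n_select`
#' indices are always returned.
#'
#' @param position Numeric position vector of length `n_hyper + n_mask`.
#' @param space A [woa_space()].
#' @return A list with `hyper` (named numeric vector) and `features`
#'   (sorted 1-based indices, length `n_select`).
#' @export
decode_position <- function(position, space) {
  stop_if(any(!is.finite(position)), "position must be finite")
  hyper <- numeric(0)
  if (space$n_hyper > 0) {
    x <- pmin(pmax(position[seq_len(space$n_hyper)], space$lower), space$upper)
    x <- ifelse(space$log10, 10^x, x)
    # round half-up, then clip back into the decoded bounds
    lo <- ifelse(space$log10, 10^space$lower, space$lower)
    hi <- ifelse(space$log10, 10^space$upper, space$upper)
    x <- ifelse(space$integer,
                pmin(pmax(floor(x + 0.5), ceiling(lo)), floor(hi)), x)
    hyper <- stats::setNames(x, names(space$lower))
  }
  features <- integer(0)
  if (space$n_mask > 0) {
    logits <- position[space$n_hyper + seq_len(space$n_mask)]
    ord <- order(-logits, seq_along(logits))  # ties: lowest index wins
    features <- sort(ord[seq_len(space$n_select)])
  }
  list(hyper = hyper, features = features)
}

#' One WOA position update
#'
#' Updates every whale from the current best: with probability 0.5 the
#' logarithmic-spiral (bubble-net) move toward the best; otherwise draw
#' `A = 2 a r - a`, `C = 2 r'` and apply the encircling move when `|A| < 1`
#' or the random-search move (toward a random peer) when `|A| >= 1`. An
#' exploration floor forces the random-search branch with probability
#' `explore_prob` regardless of `|A|`. Positions are clipped to the space
#' bounds. Draws come from the current RNG state (the optimizer seeds it).
#'
#' @param positions Population matrix (whales in rows).
#' @param best Position vector of the current best whale.
#' @param t Current iteration (1-based).
#' @param cfg A [woa_config()].
#' @param space A [woa_space()] supplying the bounds.
#' @return Updated population matrix; the branch taken per whale is attached
#'   as attribute `"branch"` (`"spiral"`, `"encircle"` or `"search"`).
#' @export
whale_step <- function(positions, best, t, cfg, space) {
  stop_if(nrow(positions) == 0L, "empty population")
  a <- woa_a_schedule(t, cfg$max_iter)
  n <- nrow(positions)
  out <- positions
  branch <- character(n)
  for (i in seq_len(n)) {
    X <- positions[i, ]
    force_search <- runif(1) < cfg$explore_prob
    if (!force_search && runif(1) < 0.5) {
      l <- runif(1, -1, 1)
      out[i, ] <- abs(best - X) * exp(cfg$b * l) * cos(2 * pi * l) + best
      branch[i] <- "spiral"
    } else {
      A <- 2 * a * runif(1) - a
      C <- 2 * runif(1)
      if (force_search || abs(A) >= 1) {
        peer <- positions[sample.int(n, 1L), ]
        out[i, ] <- peer - A * abs(C * peer - X)
        branch[i] <- "search"
      } else {
        out[i, ] <- best - A * abs(C * best - X)
        branch[i] <- "encircle"
      }
    }
  }
  out <- clip_positions(out, space)
  attr(out, "branch") <- branch
  out
}

clip_positions <- function(positions, space) {
  for (d in seq_len(ncol(positions))) {
    positions[, d] <- pmin(pmax(positions[, d], space$bounds_lo[d]),
                           space$bounds_hi[d])
  }
  positions
}

#' Run the whale optimization
#'
#' Seeded population initialization within bounds, then `max_iter` rounds of
#' [whale_step()] with elitist bookkeeping: the best-so-far candidate never
#' worsens. Candidates matching an active taboo entry (quantized position
#' within `taboo_tol`) are re-sampled uniformly; a candidate whose evaluation
#' errors is assigned `+Inf` fitness and its region recorded in the FIFO
#' taboo list, from which entries expire after `taboo_expire` iterations.
#'
#' @param evaluate `function(decoded, position)` returning a list or vector
#'   with elements `mae` and `frc`; must be deterministic given the RNG
#'   state.
#' @param space A [woa_space()].
#' @param cfg A [woa_config()].
#' @return A list of class `woa_result`: `best` (list with `position`,
#'   `fitness`, `decoded`), `trace` (data.frame `iter`, `iter_best`,
#'   `best_so_far`), `n_evaluations`.
#' @export
woa_optimize <- function(evaluate, space, cfg = woa_config()) {
  with_seed(cfg$seed, {
    D <- space$n_hyper + space$n_mask
    stop_if(D == 0L, "empty search space")
    pop <- matrix(runif(cfg$population * D), cfg$population, D)
    pop <- t(t(pop) * (space$bounds_hi - space$bounds_lo) + space$bounds_lo)

    taboo <- list()  # entries: list(key, iter)
    n_eval <- 0L

    score_one <- function(position) {
      n_eval <<- n_eval + 1L
      res <- tryCatch(evaluate(decode_position(position, space), position),
                      error = function(e) NULL)
      if (is.null(res)) return(NA_real_)  # caller records the taboo entry
      mae <- as.numeric(res[["mae"]])
      fr <- as.numeric(res[["frc"]])
      if (!is.finite(mae) || !is.finite(fr)) return(NA_real_)
      woa_fitness(mae, fr, cfg$alpha)
    }

    taboo_key <- function(position) {
      paste(round(position / cfg$taboo_tol), collapse = ",")
    }
    taboo_active <- function(key, iter) {
      any(vapply(taboo, function(e)
        e$key == key && (iter - e$iter) < cfg$taboo_expire, logical(1)))
    }
    taboo_add <- function(key, iter) {
      taboo[[length(taboo) + 1L]] <<- list(key = key, iter = iter)
      if (length(taboo) > cfg$taboo_capacity) {
        taboo <<- taboo[-1L]  # FIFO
      }
    }

    fitness <- numeric(cfg$population)
    for (i in seq_len(cfg$population)) {
      f <- score_one(pop[i, ])
      if (is.na(f)) {
        taboo_add(taboo_key(pop[i, ]), 0L)
        f <- Inf
      }
      fitness[i] <- f
    }
    best_i <- which.min(fitness)
    best <- list(position = pop[best_i, ], fitness = fitness[best_i])

    trace <- data.frame(iter = integer(0), iter_best = numeric(0),
                        best_so_far = numeric(0))
    for (t in seq_len(cfg$max_iter)) {
      pop <- whale_step(pop, best$position, t, cfg, space)
      for (i in seq_len(cfg$population)) {
        if (taboo_active(taboo_key(pop[i, ]), t)) {
          pop[i, ] <- runif(D) * (space$bounds_hi - space$bounds_lo) +
            space$bounds_lo
        }
        f <- score_one(pop[i, ])
        if (is.na(f)) {
          taboo_add(taboo_key(pop[i, ]), t)
          f <- Inf
        }
        fitness[i] <- f
      }
      it_best <- min(fitness)
      if (it_best < best$fitness) {
        bi <- which.min(fitness)
        best <- list(position = pop[bi, ], fitness = fitness[bi])
      }
      trace <- rbind(trace, data.frame(iter = t, iter_best = it_best,
                                       best_so_far = best$fitness))
    }
    best$decoded <- decode_position(best$position, space)
    structure(list(best = best, trace = trace, n_evaluations = n_eval,
                   cfg = cfg, space = space),
              class = "woa_result")
  })
}

#' Dual search for a low-redundancy, low-error feature subset
#'
#' Convenience wrapper running [woa_optimize()] over the 512 global feature
#' slots (plus any declared hyperparameter block): each candidate's 300-slot
#' subset is scored by the validation MAE of a closed-form ridge proxy
#' regression on the selected columns together with the subset's redundancy
#' coefficient. The ridge proxy stands in for a short training run of the
#' full model, which is what keeps the search affordable; Gram matrices are
#' precomputed once so each candidate costs one `solve()` on the selected
#' block.
#'
#' @param features n x M feature-slot matrix (e.g. the synthetic 512-slot
#'   matrix of a [generate_dataset()]).
#' @param y Labels on the `[0, 100]` scale.
#' @param cfg A [woa_config()].
#' @param n_select Subset size (default 300).
#' @param lambda Ridge penalty of the proxy (default 10).
#' @param val_frac Fraction of rows held out for the proxy validation MAE.
#' @param space Optional [woa_space()] adding hyperparameter dimensions in
#'   front of the mask block; defaults to a mask-only space.
#' @return A `woa_result`; `$best$decoded$features` holds the selected slots.
#' @export
woa_select_features <- function(features, y, cfg = woa_config(),
                                n_select = 300, lambda = 10,
                                val_frac = 0.3, space = NULL) {
  features <- as.matrix(features)
  n <- nrow(features); M <- ncol(features)
  stop_if(n < 10L, "need at least 10 samples")
  space <- space %||% woa_space(n_mask = M, n_select = n_select)
  stop_if(space$n_mask != M, "space mask size must match feature count")

  setup <- with_seed(cfg$seed + 1L, {
    val <- sort(sample.int(n, max(2L, round(val_frac * n))))
    tr <- setdiff(seq_len(n), val)
    Xtr <- scale(features[tr, , drop = FALSE], center = TRUE, scale = FALSE)
    mu <- attr(Xtr, "scaled:center")
    Xva <- sweep(features[val, , drop = FALSE], 2, mu)
    ytr <- y[tr]
    Cabs <- abs(suppressWarnings(cor(features[tr, , drop = FALSE])))
    Cabs[!is.finite(Cabs)] <- 0
    list(G = crossprod(Xtr), Xty = crossprod(Xtr, ytr - mean(ytr)),
         Xva = Xva, yva = y[val], ybar = mean(ytr), Cabs = Cabs)
  })

  evaluate <- function(decoded, position) {
    idx <- decoded$features
    A <- setup$G[idx, idx]
    diag(A) <- diag(A) + lambda
    beta <- solve(A, setup$Xty[idx])
    pred <- setup$Xva[, idx, drop = FALSE] %*% beta + setup$ybar
    m <- length(idx)
    list(mae = mean(abs(pred - setup$yva)),
         frc = sum(setup$Cabs[idx, idx][upper.tri(diag(m))]) / m^2)
  }
  woa_optimize(evaluate, space, cfg)
}
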