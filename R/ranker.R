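# The CIF ranking model.
#
# Fibrosis severity is a continuum, not a set of discrete grades, so the
# model is trained with ordinal supervision only: for pairs of tiles whose
# teacher labels differ by at least a gap delta, it learns to score the
# more fibrotic tile higher. The scorer is a compact feed-forward ranking
# network: tiles are downscaled by block averaging, standardised, and
# passed through one tanh hidden layer to a scalar. Both pair branches
# share weights (a Siamese arrangement) and the pairwise logistic
# (RankNet) loss — optionally a margin hinge — is minimised with Adam.
# Raw scores are mapped to the CIF scale [0, 1] by a min-max calibration
# frozen on the training scores.

#' Configuration for ranking-model training
#'
#' @param input_px Side length of the pooled-descriptor grid tiles are
#'   reduced to before scoring (each cell contributes its mean and
#'   standard deviation per channel; default 4, i.e. 96 features). Coarse
#'   pooling is deliberate: fibre density, the learnable severity signal,
#'   is a low-frequency statistic, and a small feature space keeps the
#'   desk-scale model from memorising tile noise.
#' @param hidden Hidden units in the scoring network (default 16).
#' @param loss `"logistic"` (RankNet, default) or `"hinge"`.
#' @param margin Margin for the hinge loss.
#' @param lr Adam learning rate.
#' @param batch_pairs Pairs per minibatch.
#' @param epochs Training epochs (>= 1).
#' @param delta Minimum teacher-label gap for a training pair (> 0,
#'   default 0.1).
#' @param equalize Apply [equalize_channels()] to tiles before feature
#'   extraction (default TRUE, matching the pipeline's preprocessing).
#' @param seed RNG seed for pair sampling, initialisation and shuffling.
#' @return A `ranking_config` list.
#' @export
ranking_config <- function(input_px = 4L, hidden = 16L,
                           loss = c("logistic", "hinge"), margin = 1,
                           lr = 0.01, batch_pairs = 64L, epochs = 60L,
                           delta = 0.1, equalize = TRUE, seed = 1L) {
  loss <- match.arg(loss)
  if (delta <= 0) abort("`delta` must be > 0")
  if (epochs < 1) abort("`epochs` must be >= 1")
  structure(list(input_px = as.integer(input_px), hidden = as.integer(hidden),
                 loss = loss, margin = margin, lr = lr,
                 batch_pairs = as.integer(batch_pairs),
                 epochs = as.integer(epochs), delta = delta,
                 equalize = equalize, seed = as.integer(seed)),
            class = "ranking_config")
}

# Downscale an RGB tile to a p x p grid of pooled descriptors (handles
# sides not divisible by p via pixel->block assignment) and flatten to a
# feature row. Each block contributes its mean and its standard deviation:
# the dispersion channel keeps local fibre texture visible even after
# histogram equalisation has normalised global intensity.
tile_features <- function(tile, p, equalize = TRUE) {
  if (equalize) tile <- equalize_channels(tile)
  h <- dim(tile)[1]; w <- dim(tile)[2]
  by <- pmin(floor((0:(h - 1)) * p / h) + 1L, p)
  bx <- pmin(floor((0:(w - 1)) * p / w) + 1L, p)
  pp <- p * p
  feats <- numeric(6L * pp)
  # block sums via two rowsum passes
  cnt <- tabulate(by, p) %o% tabulate(bx, p)
  for (c in 1:3) {
    ch <- tile[, , c]
    m <- t(rowsum(t(rowsum(ch, by)), bx)) / cnt          # p x p block means
    m2 <- t(rowsum(t(rowsum(ch * ch, by)), bx)) / cnt    # block mean squares
    feats[((c - 1) * pp + 1):(c * pp)] <- as.vector(m) / 255
    feats[((c + 2) * pp + 1):((c + 3) * pp)] <- sqrt(pmax(m2 - m * m, 0)) / 255
  }
  feats
}

#' Sample ordered training pairs from teacher-labelled tiles
#'
#' Returns index pairs `(hi, lo)` with `label[hi] - label[lo] >= delta`,
#' orientation recorded by column position. With `n_pairs = NULL` all
#' qualifying ordered pairs are enumerated; otherwise `n_pairs` are drawn
#' uniformly with replacement (deterministic per seed).
#'
#' @param labels Numeric teacher labels in \[0, 1\], one per tile.
#' @param delta Minimum label gap (> 0).
#' @param n_pairs Number of pairs to sample, or NULL for exhaustive.
#' @param seed RNG seed (used only when sampling).
#' @return Tibble with columns `hi`, `lo` (1-based tile indices) and `gap`.
#' @export
make_training_pairs <- function(labels, delta = 0.1, n_pairs = NULL, seed = 1L) {
  if (length(labels) < 2) abort("need at least two labelled tiles")
  if (delta <= 0) abort("`delta` must be > 0")
  d <- outer(labels, labels, "-")
  qual <- which(d >= delta, arr.ind = TRUE)
  if (nrow(qual) == 0)
    abort(sprintf("no tile pair has a label gap >= %g; lower `delta`", delta))
  pairs <- tibble(hi = unname(qual[, 1]), lo = unname(qual[, 2]),
                  gap = labels[qual[, 1]] - labels[qual[, 2]])
  if (is.null(n_pairs)) return(arrange(pairs, .data$hi, .data$lo))
  with_seed(seed, pairs[sample.int(nrow(pairs), n_pairs, replace = TRUE), ])
}

# Forward pass: X is n x d (rows = tiles). Returns list(score, hidden).
rank_forward <- function(par, X) {
  z <- sweep(X %*% par$W1, 2, par$b1, "+")
  hdn <- tanh(z)
  list(score = drop(hdn %*% par$w2) + par$b2, hidden = hdn)
}

#' Train the CIF ranking model
#'
#' @param tiles List of RGB tile arrays (or a tibble with a `tile` list
#'   column and a `label` column).
#' @param labels Teacher labels aligned with `tiles` (ignored when `tiles`
#'   is a tibble carrying them).
#' @param config A [ranking_config()].
#' @param pairs Optional precomputed pair tibble from
#'   [make_training_pairs()]; by default `4 * n` pairs are sampled with the
#'   config's `delta` and seed.
#' @return A `cif_ranker` object with the fitted weights, feature
#'   standardisation, min-max calibration over training scores, and the
#'   per-epoch training history.
#' @export
train_ranking_model <- function(tiles, labels = NULL, config = ranking_config(),
                                pairs = NULL) {
  if (is.data.frame(tiles)) {
    labels <- tiles$label
    tiles <- tiles$tile
  }
  if (length(tiles) == 0) abort("no training tiles")
  if (is.null(labels) || length(labels) != length(tiles))
    abort("`labels` must align with `tiles`")
  n <- length(tiles)
  X <- do.call(rbind, lapply(tiles, tile_features, p = config$input_px,
                             equalize = config$equalize))
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd); sdv[sdv < 1e-8] <- 1
  X <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  if (is.null(pairs))
    pairs <- make_training_pairs(labels, config$delta, n_pairs = 4L * n,
                                 seed = config$seed)
  d <- ncol(X); H <- config$hidden
  with_seed(config$seed + 1L, {
    par <- list(W1 = matrix(rnorm(d * H, 0, 1 / sqrt(d)), d, H),
                b1 = numeric(H), w2 = rnorm(H, 0, 1 / sqrt(H)), b2 = 0)
    mstate <- lapply(par, function(p) p * 0)
    vstate <- lapply(par, function(p) p * 0)
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; step <- 0
    history <- numeric(config$epochs)
    np <- nrow(pairs)
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(np)
      ep_loss <- 0
      for (b0 in seq(1, np, by = config$batch_pairs)) {
        bidx <- ord[b0:min(b0 + config$batch_pairs - 1, np)]
        hi <- pairs$hi[bidx]; lo <- pairs$lo[bidx]
        fh <- rank_forward(par, X[hi, , drop = FALSE])
        fl <- rank_forward(par, X[lo, , drop = FALSE])
        s <- fh$score - fl$score
        if (config$loss == "logistic") {
          ep_loss <- ep_loss + sum(log1p(exp(-s)))
          dl <- -1 / (1 + exp(s))          # dLoss/ds
        } else {
          viol <- s < config$margin
          ep_loss <- ep_loss + sum(pmax(0, config$margin - s))
          dl <- ifelse(viol, -1, 0)
        }
        if (any(!is.finite(s))) abort("ranking loss diverged (non-finite scores)")
        grad <- pair_gradient(par, X, hi, lo, fh, fl, dl)
        step <- step + 1
        lr_t <- config$lr * sqrt(1 - beta2^step) / (1 - beta1^step)
        for (nm in names(par)) {
          mstate[[nm]] <- beta1 * mstate[[nm]] + (1 - beta1) * grad[[nm]]
          vstate[[nm]] <- beta2 * vstate[[nm]] + (1 - beta2) * grad[[nm]]^2
          par[[nm]] <- par[[nm]] - lr_t * mstate[[nm]] / (sqrt(vstate[[nm]]) + eps)
        }
      }
      history[epoch] <- ep_loss / np
    }
  })
  raw <- rank_forward(par, X)$score
  model <- structure(list(par = par, feat_mean = mu, feat_sd = sdv,
                          config = config,
                          calibration = c(lo = min(raw), hi = max(raw)),
                          history = tibble(epoch = seq_len(config$epochs),
                                           loss = history),
                          n_tiles = n, n_pairs = nrow(pairs)),
                     class = "cif_ranker")
  model
}

# Gradient of sum(dl * (f(hi) - f(lo))) wrt the shared parameters.
pair_gradient <- function(par, X, hi, lo, fh, fl, dl) {
  gb2 <- 0                          # shared bias cancels across branches
  gw2 <- colSums(dl * fh$hidden) - colSums(dl * fl$hidden)
  dz_h <- (dl * (1 - fh$hidden^2)) * rep(par$w2, each = length(dl))
  dz_l <- (dl * (1 - fl$hidden^2)) * rep(par$w2, each = length(dl))
  gW1 <- t(X[hi, , drop = FALSE]) %*% dz_h - t(X[lo, , drop = FALSE]) %*% dz_l
  gb1 <- colSums(dz_h) - colSums(dz_l)
  m <- length(dl)
  list(W1 = gW1 / m, b1 = gb1 / m, w2 = gw2 / m, b2 = gb2 / m)
}

#' @export
print.cif_ranker <- function(x, ...) {
  cat(sprintf("<cif_ranker> %d features -> %d hidden -> score; %s loss\n",
              length(x$feat_mean), x$config$hidden, x$config$loss))
  cat(sprintf("trained on %d tiles / %d pairs, %d epochs; final loss %.4f\n",
              x$n_tiles, x$n_pairs, x$config$epochs,
              tail(x$history$loss, 1)))
  invisible(x)
}

#' @describeIn train_ranking_model per-epoch training history (`epoch`,
#'   `loss`).
#' @param x A `cif_ranker`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.cif_ranker <- function(x, ...) x$history

#' @describeIn train_ranking_model one-row model summary.
#' @exportS3Method generics::glance
glance.cif_ranker <- function(x, ...) {
  tibble(n_tiles = x$n_tiles, n_pairs = x$n_pairs,
         epochs = x$config$epochs, final_loss = tail(x$history$loss, 1),
         calibration_lo = unname(x$calibration["lo"]),
         calibration_hi = unname(x$calibration["hi"]))
}

# Raw (uncalibrated) scores for a list of tiles.
ranker_raw_scores <- function(model, tiles) {
  X <- do.call(rbind, lapply(tiles, tile_features, p = model$config$input_px,
                             equalize = model$config$equalize))
  X <- sweep(sweep(X, 2, model$feat_mean), 2, model$feat_sd, "/")
  rank_forward(model$par, X)$score
}

#' Predict CIF scores for tiles
#'
#' Raw network scores are mapped to \[0, 1\] by the min-max calibration
#' frozen on the training set (clipped), giving the CIF scale: the
#' training tile with the lowest raw score maps to 0, the highest to 1.
#'
#' @param model A fitted `cif_ranker`.
#' @param tiles List of RGB tile arrays, or a tibble with a `tile` list
#'   column (whose remaining columns are carried into the result).
#' @param tile_table Optional `tile_table` providing `index`/`x0`/`y0`
#'   geometry for the scored tiles (row-aligned with `tiles`).
#' @return A `cif_map` tibble with columns `index`, `x0`, `y0`,
#'   `tile_size` (when known) and `cif`.
#' @export
predict_cif <- function(model, tiles, tile_table = NULL) {
  stopifnot(inherits(model, "cif_ranker"))
  if (is.null(model$calibration) || any(!is.finite(model$calibration)))
    abort("model has no fitted calibration")
  geom <- NULL
  if (is.data.frame(tiles)) {
    geom <- select(tiles, -dplyr::any_of("tile"))
    tiles <- tiles$tile
  }
  raw <- ranker_raw_scores(model, tiles)
  lo <- model$calibration["lo"]; hi <- model$calibration["hi"]
  cif <- if (hi > lo) clamp((raw - lo) / (hi - lo), 0, 1) else rep(0.5, length(raw))
  base <- if (!is.null(tile_table)) as_tibble(tile_table)
          else if (!is.null(geom) && ncol(geom) > 0) geom
          else tibble(index = seq_along(tiles) - 1L)
  out <- mutate(base, cif = unname(cif))
  new_cif_map(out)
}
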