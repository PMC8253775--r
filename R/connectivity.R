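# Directed effective connectivity from binarized spike trains via a plug-in
# generalized transfer entropy (GTE) at Markov order k with an optional
# instant-feedback (same-bin) source term, thresholded against the pooled
# distribution of all pair scores, plus degree-distribution comparisons.

#' Binarize a spike raster
#'
#' Cell `(i, b)` is 1 iff neuron `i` has at least one onset in
#' `[b * bin, (b + 1) * bin)`.
#'
#' @param raster A [spike_raster()].
#' @param bin Bin width in seconds (default one frame at 20 Hz).
#' @return A `binarized_raster`: integer matrix neurons x bins with
#'   attribute `bin`.
#' @export
binarize <- function(raster, bin = 0.05) {
  stopifnot(inherits(raster, "spike_raster"), bin > 0)
  n_bins <- max(1L, ceiling(raster$duration / bin - 1e-9))
  m <- matrix(0L, raster$n_neurons, n_bins)
  if (nrow(raster$events) > 0) {
    # epsilon guards against times sitting exactly on a bin boundary in
    # floating point (half-open [b*bin, (b+1)*bin) convention)
    b <- pmin(floor(raster$events$time / bin + 1e-9), n_bins - 1L) + 1L
    m[cbind(raster$events$neuron_id, b)] <- 1L
  }
  structure(m, bin = bin, class = c("binarized_raster", class(m)))
}

#' Pairwise generalized transfer entropy
#'
#' Plug-in estimate (in bits) of
#' `TE(X -> Y) = sum p(y_{t+1}, Y_t, X_t) log2 [ p(y_{t+1} | Y_t, X_t) /
#' p(y_{t+1} | Y_t) ]` on binary series, with `Y_t = (y_t, ..., y_{t-k+1})`
#' and the source window `X_t = (x_{t+1}, ..., x_{t-k+2})` when
#' `instant_feedback` is on (shifted one bin forward so that same-bin
#' interactions are visible), else `(x_t, ..., x_{t-k+1})`. Probabilities are
#' raw state-histogram frequencies pooled over all valid `t`; the estimate is
#' non-negative by construction.
#'
#' @param x,y Binary (0/1) vectors of equal length `>= k + 2`.
#' @param k Markov order.
#' @param instant_feedback Include the same-bin source term.
#' @return Transfer entropy in bits.
#' @export
gte_pair <- function(x, y, k = 2, instant_feedback = TRUE) {
  x <- as.integer(x); y <- as.integer(y)
  n <- length(x)
  if (length(y) != n) abort("`x` and `y` must have equal length")
  if (n < k + 2) abort("series too short for the requested Markov order")
  # valid prediction times: t = k, ..., n - 1 (1-based; predict y[t + 1])
  t_idx <- k:(n - 1L)
  y_next <- y[t_idx + 1L]
  y_hist <- hist_code(y, t_idx, k, shift = 0L)
  x_hist <- hist_code(x, t_idx, k, shift = if (instant_feedback) 1L else 0L)
  te_from_states(y_next, y_hist, x_hist, k, instant_feedback)
}

# k-bin history code at times t, optionally shifted one bin forward:
# sum_{i=0}^{k-1} s[t + shift - i] * 2^i.
hist_code <- function(s, t_idx, k, shift = 0L) {
  code <- integer(length(t_idx))
  for (i in seq_len(k) - 1L) {
    code <- code + s[t_idx + shift - i] * 2L^i
  }
  code
}

# Plug-in conditional-entropy difference from coded states.
te_from_states <- function(y_next, y_hist, x_hist, k, instant_feedback) {
  n <- length(y_next)
  xs <- 2L^k
  joint <- y_next + 2L * y_hist + (2L * 2L^k) * x_hist
  cnt <- tabulate(joint + 1L, nbins = 2L * 2L^k * xs)
  p_joint <- cnt / n
  # marginals by aggregation
  idx <- which(cnt > 0)
  states <- idx - 1L
  yn <- states %% 2L
  yh <- (states %/% 2L) %% 2L^k
  xh <- states %/% (2L * 2L^k)
  p <- p_joint[idx]
  p_yx <- tapply(p, interaction(yh, xh, drop = TRUE), sum)
  p_yhx <- setNames(as.vector(p_yx), names(p_yx))
  p_y <- tapply(p, factor(yh), sum)
  p_yny <- tapply(p, interaction(yn, yh, drop = TRUE), sum)
  key_yx <- interaction(yh, xh, drop = TRUE)
  key_y <- factor(yh)
  key_yny <- interaction(yn, yh, drop = TRUE)
  cond_full <- p / p_yhx[as.character(key_yx)]
  cond_red <- as.vector(p_yny[as.character(key_yny)]) /
    as.vector(p_y[as.character(key_y)])
  sum(p * log2(cond_full / cond_red))
}

#' Effective connectivity matrix via GTE
#'
#' Scores every ordered pair of a random subsample of active neurons. A
#' recording qualifies only if its burst catalog shows at least `min_bursts`
#' network bursts (connectivity is meant to capture interactions during
#' bursting episodes); recordings failing the filter are refused. If fewer
#' active neurons than `subsample` exist, all are used with a warning.
#'
#' @param raster A [spike_raster()].
#' @param catalog Optional `burst_catalog`; computed internally (1-s window
#'   GNA at `rate`, mean + 2 SD background removal) if omitted.
#' @param bin Binarization bin width, seconds.
#' @param k Markov order.
#' @param instant_feedback Include the same-bin source term.
#' @param subsample Number of neurons scored.
#' @param min_bursts Minimum burst count required.
#' @param rate Frame rate used when computing the internal catalog.
#' @param seed Seed for the subsample draw.
#' @return An `effective_network`: GTE `scores` matrix (bits, rows = source),
#'   `ids` (raster neuron ids of the rows), settings, and empty adjacency
#'   until [threshold_network()] is applied.
#' @export
gte_matrix <- function(raster, catalog = NULL, bin = 0.05, k = 2,
                       instant_feedback = TRUE, subsample = 340,
                       min_bursts = 10, rate = 20, seed = 1L) {
  stopifnot(inherits(raster, "spike_raster"))
  if (is.null(catalog)) {
    catalog <- detect_bursts(compute_gna(raster, window = 1, rate = rate))
  }
  if (nrow(catalog) < min_bursts)
    abort(sprintf(
      "connectivity refused: %d network bursts found but %d required",
      nrow(catalog), min_bursts))
  act <- active_neurons(raster)
  if (length(act) < 2) abort("need at least 2 active neurons")
  ids <- if (length(act) > subsample) {
    with_seed(seed, sort(sample(act, subsample)))
  } else {
    if (length(act) < subsample)
      warn(sprintf("only %d active neurons; using all (subsample = %d)",
                   length(act), subsample))
    act
  }
  bins <- binarize(raster, bin)
  scores <- gte_matrix_cpp(bins[ids, , drop = FALSE], as.integer(k),
                           isTRUE(instant_feedback))
  dimnames(scores) <- list(ids, ids)
  structure(list(scores = scores, adjacency = NULL, ids = ids,
                 threshold_sd = NA_real_, threshold_value = NA_real_,
                 markov_order = k, instant_feedback = instant_feedback,
                 bin = bin),
            class = "effective_network")
}

#' Threshold GTE scores into a binary adjacency
#'
#' The null is the pooled distribution of all off-diagonal pair scores of the
#' same network; an edge `i -> j` is kept iff its score exceeds
#' `mean + n_sd * SD` of that pool. `n_sd = 1` is the analysis threshold;
#' `n_sd = 2.5` is the sparser display variant.
#'
#' @param network An `effective_network` from [gte_matrix()], or a bare
#'   square score matrix.
#' @param n_sd SD multiplier over the pooled score distribution.
#' @return For an `effective_network`, the network with `adjacency`,
#'   `threshold_sd` and `threshold_value` filled; for a matrix, the binary
#'   adjacency matrix.
#' @export
threshold_network <- function(network, n_sd = 1) {
  scores <- if (inherits(network, "effective_network")) network$scores
            else as.matrix(network)
  if (nrow(scores) != ncol(scores)) abort("score matrix must be square")
  off <- scores[row(scores) != col(scores)]
  thr <- mean(off) + n_sd * sd(off)
  if (is.na(thr)) thr <- Inf
  adj <- (scores > thr) * 1L
  diag(adj) <- 0L
  if (inherits(network, "effective_network")) {
    network$adjacency <- adj
    network$threshold_sd <- n_sd
    network$threshold_value <- thr
    network
  } else {
    adj
  }
}

#' Per-neuron degree counts
#'
#' @param adjacency Square binary matrix (row = source).
#' @param direction `"total"` (in + out), `"in"` or `"out"`.
#' @return Integer vector of per-neuron connection counts.
#' @export
degrees <- function(adjacency, direction = c("total", "in", "out")) {
  direction <- match.arg(direction)
  adjacency <- as.matrix(adjacency)
  if (nrow(adjacency) != ncol(adjacency)) abort("adjacency must be square")
  diag(adjacency) <- 0
  switch(direction,
         total = rowSums(adjacency) + colSums(adjacency),
         out = rowSums(adjacency),
         "in" = colSums(adjacency))
}

#' Degree distribution and CDF
#'
#' Normalized histogram `p(k)` of per-neuron connection counts and its
#' cumulative form `CDF(k)`, the probability that a neuron has at most `k`
#' connections. With `percent = TRUE` the degree axis is expressed as a
#' percentage of the network (per-direction degree divided by `n - 1`,
#' summed over the two directions for `"total"`).
#'
#' @inheritParams degrees
#' @param percent Express degrees as % of network instead of counts.
#' @return A `degree_distribution` tibble (`k`, `p`, `cdf`) with attributes
#'   `direction` and `degrees` (the raw per-neuron sample).
#' @export
degree_cdf <- function(adjacency, direction = c("total", "in", "out"),
                       percent = FALSE) {
  direction <- match.arg(direction)
  deg <- degrees(adjacency, direction)
  n <- length(deg)
  if (percent && n > 1) {
    denom <- (n - 1) * if (direction == "total") 2 else 1
    deg <- 100 * deg / denom
  }
  ks <- sort(unique(deg))
  p <- as.vector(table(factor(deg, levels = ks))) / n
  out <- tibble(k = ks, p = p, cdf = cumsum(p))
  structure(out, direction = direction, degrees = deg, percent = percent,
            class = c("degree_distribution", class(out)))
}

#' Kullback-Leibler divergence between two discrete distributions
#'
#' `D_KL(P || S) = sum_i P(i) ln(P(i) / S(i))` in nats. Terms with
#' `P(i) = 0` contribute 0; `S(i) = 0` where `P(i) > 0` is an error. Two
#' `degree_distribution` objects are first aligned on the union of their
#' supports.
#'
#' @param p,s Probability vectors on a common support, or two
#'   `degree_distribution` objects.
#' @return Divergence in nats (non-negative).
#' @export
kl_divergence <- function(p, s) {
  if (inherits(p, "degree_distribution") && inherits(s, "degree_distribution")) {
    support <- sort(union(p$k, s$k))
    pv <- p$p[match(support, p$k)]; pv[is.na(pv)] <- 0
    sv <- s$p[match(support, s$k)]; sv[is.na(sv)] <- 0
    p <- pv; s <- sv
  }
  p <- as.numeric(p); s <- as.numeric(s)
  if (length(p) != length(s)) abort("`p` and `s` must share a support")
  if (any(p < 0) || any(s < 0)) abort("probabilities must be non-negative")
  p <- p / sum(p); s <- s / sum(s)
  bad <- p > 0 & s == 0
  if (any(bad))
    abort("D_KL undefined: S has zero mass where P is positive")
  pos <- p > 0
  sum(p[pos] * log(p[pos] / s[pos]))
}

#' Two-sample Kolmogorov-Smirnov comparison of degree samples
#'
#' @param sample_a,sample_b Numeric degree samples, or `degree_distribution`
#'   objects (their raw per-neuron samples are used).
#' @return A one-row tibble (`statistic`, `p_value`).
#' @export
compare_distributions_ks <- function(sample_a, sample_b) {
  as_sample <- function(x) {
    if (inherits(x, "degree_distribution")) attr(x, "degrees") else
      as.numeric(x)
  }
  a <- as_sample(sample_a); b <- as_sample(sample_b)
  if (length(a) == 0 || length(b) == 0) abort("samples must be nonempty")
  res <- suppressWarnings(stats::ks.test(a, b))
  tibble(statistic = unname(res$statistic), p_value = unname(res$p.value))
}

#' @export
print.effective_network <- function(x, ...) {
  cat(sprintf("<effective_network> %d neurons, k = %d, instant feedback %s\n",
              nrow(x$scores), x$markov_order,
              if (x$instant_feedback) "on" else "off"))
  if (!is.null(x$adjacency)) {
    cat(sprintf("  threshold: mean + %g SD (%.4g bits), %d edges\n",
                x$threshold_sd, x$threshold_value, sum(x$adjacency)))
  } else {
    cat("  unthresholded (run threshold_network())\n")
  }
  invisible(x)
}

#' @export
tidy.effective_network <- function(x, ...) {
  n <- nrow(x$scores)
  out <- tibble(
    source = rep(x$ids, times = n),
    target = rep(x$ids, each = n),
    score = as.vector(x$scores)
  )
  out <- out[out$source != out$target, ]
  if (!is.null(x$adjacency))
    out$edge <- as.vector(x$adjacency)[as.vector(row(x$scores) != col(x$scores))]
  out
}

#' @export
glance.effective_network <- function(x, ...) {
  n <- nrow(x$scores)
  tibble(
    n_neurons = n,
    markov_order = x$markov_order,
    threshold_sd = x$threshold_sd,
    n_edges = if (is.null(x$adjacency)) NA_integer_ else sum(x$adjacency),
    density = if (is.null(x$adjacency)) NA_real_ else
      sum(x$adjacency) / (n * (n - 1))
  )
}
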