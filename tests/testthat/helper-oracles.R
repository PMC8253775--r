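# Independent brute-force oracles used to validate the package's estimators.
# These deliberately share no code with the implementation: state histograms
# are keyed by strings, modularity is evaluated from the definition,
# components by flood fill, ECDF gaps by direct evaluation.

# Plug-in transfer entropy by explicit enumeration of (y_next, y-history,
# x-window) states collected with string keys.
te_bruteforce <- function(x, y, k = 2, instant = TRUE) {
  n <- length(x)
  shift <- if (instant) 1L else 0L
  rows_full <- character(0)
  rows_yx <- character(0)
  rows_yny <- character(0)
  rows_yh <- character(0)
  for (t in k:(n - 1L)) {
    yh <- paste(y[t:(t - k + 1L)], collapse = "")
    xs <- paste(x[(t + shift):(t - k + 1L + shift)], collapse = "")
    yn <- y[t + 1L]
    rows_full <- c(rows_full, paste(yn, yh, xs, sep = "|"))
    rows_yx <- c(rows_yx, paste(yh, xs, sep = "|"))
    rows_yny <- c(rows_yny, paste(yn, yh, sep = "|"))
    rows_yh <- c(rows_yh, yh)
  }
  nn <- length(rows_full)
  cnt_full <- table(rows_full)
  cnt_yx <- table(rows_yx)
  cnt_yny <- table(rows_yny)
  cnt_yh <- table(rows_yh)
  te <- 0
  for (state in names(cnt_full)) {
    parts <- strsplit(state, "|", fixed = TRUE)[[1]]
    c_full <- cnt_full[[state]]
    c_yx <- cnt_yx[[paste(parts[2], parts[3], sep = "|")]]
    c_yny <- cnt_yny[[paste(parts[1], parts[2], sep = "|")]]
    c_yh <- cnt_yh[[parts[2]]]
    p_cond_full <- c_full / c_yx
    p_cond_red <- c_yny / c_yh
    te <- te + (c_full / nn) * log2(p_cond_full / p_cond_red)
  }
  te
}

# Newman modularity straight from the definition on the symmetrized graph.
modularity_bruteforce <- function(adj, membership) {
  sym <- 1 * ((adj + t(adj)) > 0)
  diag(sym) <- 0
  two_m <- sum(sym)
  total <- 0
  for (cc in unique(membership)) {
    nodes <- which(membership == cc)
    e_cc <- sum(sym[nodes, nodes]) / two_m
    a_c <- sum(sym[nodes, ] ) / two_m
    total <- total + e_cc - a_c^2
  }
  total
}

# All partitions of n items as restricted-growth strings.
all_partitions <- function(n) {
  out <- list()
  recurse <- function(labels, next_max) {
    i <- length(labels) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- labels
      return(invisible())
    }
    for (lab in seq_len(next_max + 1L)) {
      recurse(c(labels, lab), max(next_max, lab))
    }
  }
  recurse(integer(0), 0L)
  out
}

# Best-modularity partition by exhaustive search (n <= 10).
best_partition_bruteforce <- function(adj) {
  parts <- all_partitions(nrow(adj))
  qs <- vapply(parts, function(m) modularity_bruteforce(adj, m), numeric(1))
  parts[[which.max(qs)]]
}

# Weakly connected components by flood fill on the symmetrized graph.
components_bruteforce <- function(adj) {
  sym <- (adj + t(adj)) > 0
  n <- nrow(adj)
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      nb <- which(sym[v, ] & is.na(comp))
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  comp
}

# Two-sample KS statistic as the maximum ECDF gap over the pooled support.
ks_bruteforce <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  max(abs(vapply(grid, function(g) mean(a <= g) - mean(b <= g), numeric(1))))
}

# Degree histogram by direct counting.
degree_hist_bruteforce <- function(adj, direction = "total") {
  diag(adj) <- 0
  deg <- switch(direction,
                total = rowSums(adj) + colSums(adj),
                out = rowSums(adj),
                "in" = colSums(adj))
  ks <- sort(unique(deg))
  counts <- vapply(ks, function(k) sum(deg == k), numeric(1))
  list(k = ks, p = counts / length(deg))
}

# Random directed adjacency matrix fixture.
random_adjacency <- function(n, p = 0.2, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rbinom(n * n, 1, p), n, n)
    diag(m) <- 0
    m
  })
}
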