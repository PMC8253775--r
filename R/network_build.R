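# Spatially-embedded structural networks. Each neuron owns an axon polyline
# (fixed-length segments, Gaussian angular increments, Rayleigh total
# length, clipped at the field walls) and a circular dendritic tree
# (truncated-Gaussian radius). A directed edge source -> target is created
# with probability alpha whenever the source's axon crosses the target's
# dendritic disk. The arc length of the first crossing and the minimal
# axon-to-soma distance are stored per edge so that axon shortening and
# dendrite shrinkage can be calibrated exactly against a target connection
# loss.

#' Build a spatially-embedded structural network
#'
#' @param n Number of neurons.
#' @param field Field dimensions c(width, height) in micrometres.
#' @param seed RNG seed (placement, growth, wiring).
#' @param positions Optional ROI table supplying neuron positions; `n`
#'   neurons are subsampled from it (error if it has fewer than `n` rows).
#' @param populations Fractions of excitatory/DA/inhibitory neurons (sum 1);
#'   converted to counts by largest-remainder rounding and assigned at
#'   random.
#' @param axon_segment Axon segment length, micrometres.
#' @param axon_angle_sd SD of the Gaussian angular increment per segment,
#'   radians.
#' @param axon_mean_length Mean of the Rayleigh-distributed total axon
#'   length, micrometres.
#' @param dendrite_mean,dendrite_sd,dendrite_min Gaussian dendritic radius
#'   (micrometres), truncated below at `dendrite_min`.
#' @param alpha Connection probability per axon-dendrite crossing.
#' @return A `spatial_network`: `neurons` tibble (`id`, `x`, `y`, `type`,
#'   `axon_length`, `dendrite_radius`), `edges` tibble (`source`, `target`,
#'   `s_len`, `dist`), `axons` list of polylines, `field`, and `pruning`
#'   (`NULL` until [prune()]).
#' @export
build_network <- function(n = 300, field = c(2800, 2100), seed = 1L,
                          positions = NULL,
                          populations = c(excitatory = 0.55, da = 0.25,
                                          inhibitory = 0.20),
                          axon_segment = 10, axon_angle_sd = 0.1,
                          axon_mean_length = 1100,
                          dendrite_mean = 150, dendrite_sd = 20,
                          dendrite_min = 10, alpha = 0.5) {
  stopifnot(n >= 10, length(field) == 2, all(field > 0))
  if (abs(sum(populations) - 1) > 1e-8 || length(populations) != 3)
    abort("`populations` must be 3 fractions summing to 1")
  with_seed(seed, {
    if (!is.null(positions)) {
      positions <- validate_roi(positions)
      if (nrow(positions) < n)
        abort(sprintf("supplied positions (%d) fewer than n = %d",
                      nrow(positions), n))
      pick <- sort(sample.int(nrow(positions), n))
      xy <- cbind(positions$x[pick], positions$y[pick])
    } else {
      xy <- cbind(runif(n, 0, field[1]), runif(n, 0, field[2]))
    }
    types <- assign_types(n, populations)
    radius <- pmax(dendrite_min, rnorm(n, dendrite_mean, dendrite_sd))
    # Rayleigh total length with the requested mean
    sigma <- axon_mean_length / sqrt(pi / 2)
    lengths <- sigma * sqrt(-2 * log(runif(n)))
    axons <- vector("list", n)
    for (i in seq_len(n)) {
      axons[[i]] <- grow_axon(xy[i, ], lengths[i], axon_segment,
                              axon_angle_sd, field)
    }
    edge_list <- vector("list", n)
    for (i in seq_len(n)) {
      hits <- axon_disk_crossings(axons[[i]], xy, radius, exclude = i)
      if (nrow(hits) == 0) next
      accept <- runif(nrow(hits)) < alpha
      hits <- hits[accept, , drop = FALSE]
      if (nrow(hits) == 0) next
      edge_list[[i]] <- tibble(source = i, target = hits$target,
                               s_len = hits$s_len, dist = hits$dist)
    }
    edges <- dplyr::bind_rows(edge_list)
    if (nrow(edges) == 0)
      edges <- tibble(source = integer(), target = integer(),
                      s_len = double(), dist = double())
    neurons <- tibble(id = seq_len(n), x = xy[, 1], y = xy[, 2],
                      type = types,
                      axon_length = vapply(axons, polyline_length, numeric(1)),
                      dendrite_radius = radius)
    structure(list(neurons = neurons, edges = edges, axons = axons,
                   field = field, pruning = NULL),
              class = "spatial_network")
  })
}

# Largest-remainder rounding of population fractions, randomized assignment.
assign_types <- function(n, populations) {
  labels <- c("excitatory", "da", "inhibitory")
  frac <- as.numeric(populations)
  base <- floor(n * frac)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(n * frac - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  sample(rep(labels, times = base))
}

# Axon polyline: fixed-length segments with Gaussian angular increments from
# a uniform initial heading, terminated where it first leaves the field.
grow_axon <- function(origin, total_length, segment, angle_sd, field) {
  n_seg <- round(total_length / segment)
  if (n_seg < 1) return(matrix(origin, nrow = 1))
  ang <- cumsum(c(runif(1, 0, 2 * pi), rnorm(n_seg - 1, 0, angle_sd)))
  dx <- segment * cos(ang)
  dy <- segment * sin(ang)
  pts <- cbind(origin[1] + cumsum(c(0, dx))[-1],
               origin[2] + cumsum(c(0, dy))[-1])
  pts <- rbind(origin, pts)
  outside <- pts[, 1] < 0 | pts[, 1] > field[1] |
    pts[, 2] < 0 | pts[, 2] > field[2]
  first_out <- which(outside)[1]
  if (!is.na(first_out)) {
    a <- pts[first_out - 1L, ]
    b <- pts[first_out, ]
    t_exit <- boundary_exit_param(a, b, field)
    pts <- rbind(pts[seq_len(first_out - 1L), , drop = FALSE],
                 a + t_exit * (b - a))
  }
  pts
}

# Smallest t in (0, 1] at which segment a + t (b - a) leaves [0,w]x[0,h].
boundary_exit_param <- function(a, b, field) {
  d <- b - a
  ts <- c(
    if (d[1] != 0) c((0 - a[1]) / d[1], (field[1] - a[1]) / d[1]),
    if (d[2] != 0) c((0 - a[2]) / d[2], (field[2] - a[2]) / d[2])
  )
  ts <- ts[ts > 1e-12 & ts <= 1]
  if (length(ts) == 0) 1 else min(ts)
}

polyline_length <- function(pts) {
  if (nrow(pts) < 2) return(0)
  sum(sqrt(rowSums(diff(pts)^2)))
}

# All disks crossed by a polyline: for each target, whether the minimum
# point-to-segment distance is within the disk radius, the arc length of the
# first entry point, and the minimal distance (the smallest dendritic radius
# that would still be crossed).
axon_disk_crossings <- function(pts, centers, radii, exclude = NULL) {
  m <- nrow(pts) - 1L
  n <- nrow(centers)
  if (m < 1)
    return(tibble(target = integer(), s_len = double(), dist = double()))
  A <- pts[seq_len(m), , drop = FALSE]
  D <- pts[seq_len(m) + 1L, , drop = FALSE] - A
  len <- sqrt(rowSums(D^2))
  len2 <- pmax(len^2, 1e-300)
  cum <- c(0, cumsum(len))
  # t[s, j]: projection parameter of center j on segment s, clamped to [0,1]
  tx <- (outer(D[, 1], centers[, 1]) - D[, 1] * A[, 1] +
           outer(D[, 2], centers[, 2]) - D[, 2] * A[, 2]) / len2
  tx[tx < 0] <- 0; tx[tx > 1] <- 1
  px <- A[, 1] + tx * D[, 1] - rep(centers[, 1], each = m)
  py <- A[, 2] + tx * D[, 2] - rep(centers[, 2], each = m)
  dist2 <- matrix(px^2 + py^2, nrow = m)
  mind <- sqrt(apply(dist2, 2, min))
  hit <- mind <= radii
  if (!is.null(exclude)) hit[exclude] <- FALSE
  targets <- which(hit)
  if (length(targets) == 0)
    return(tibble(target = integer(), s_len = double(), dist = double()))
  s_len <- vapply(targets, function(j) {
    s0 <- which(dist2[, j] <= radii[j]^2)[1]
    a <- A[s0, ]; d <- D[s0, ]; cvec <- a - centers[j, ]
    # |a + t d - c|^2 = r^2
    qa <- sum(d^2); qb <- 2 * sum(d * cvec)
    qc <- sum(cvec^2) - radii[j]^2
    disc <- qb^2 - 4 * qa * qc
    t_entry <- if (qc <= 0) 0 else if (disc < 0 || qa == 0) 0 else
      max(0, min(1, (-qb - sqrt(disc)) / (2 * qa)))
    cum[s0] + t_entry * len[s0]
  }, numeric(1))
  tibble(target = targets, s_len = s_len, dist = mind[targets])
}

#' Structural adjacency matrix of a spatial network
#'
#' @param network A `spatial_network`.
#' @return Binary matrix, row = source (axon owner), column = target
#'   (dendrite owner).
#' @export
adjacency_matrix <- function(network) {
  stopifnot(inherits(network, "spatial_network"))
  n <- nrow(network$neurons)
  m <- matrix(0L, n, n)
  if (nrow(network$edges) > 0)
    m[cbind(network$edges$source, network$edges$target)] <- 1L
  m
}

#' Prune DA neurites
#'
#' Selects `ceiling(fraction * n_DA)` DA neurons uniformly and removes the
#' target fraction of each one's structural connections:
#' * `"axon_shorten"` truncates the axon so that the surviving out-edges
#'   (those whose first dendritic crossing lies before the cut) match the
#'   target loss as closely as the discrete edge geometry allows;
#' * `"dendrite_shrink"` shrinks the dendritic radius analogously, acting on
#'   the neuron's in-edges;
#' * `"random_edge"` deletes `round(target * m)` of the neuron's out-edges
#'   uniformly at random.
#' Non-DA neurons are untouched; pruning the same network twice is an error.
#'
#' @param network A `spatial_network` from [build_network()].
#' @param fraction Fraction of DA neurons to prune, in `[0, 1]`.
#' @param mode `"axon_shorten"`, `"dendrite_shrink"` or `"random_edge"`.
#' @param target_loss Target fraction of connections removed per pruned
#'   neuron, in `(0, 1]`.
#' @param seed RNG seed (neuron selection, random-edge draws).
#' @return The pruned network; `$pruning` records per-neuron realized losses.
#' @export
prune <- function(network, fraction, mode = c("axon_shorten",
                                              "dendrite_shrink",
                                              "random_edge"),
                  target_loss = 0.8, seed = 1L) {
  stopifnot(inherits(network, "spatial_network"))
  mode <- match.arg(mode)
  if (fraction < 0 || fraction > 1) abort("`fraction` must lie in [0, 1]")
  if (target_loss <= 0 || target_loss > 1)
    abort("`target_loss` must lie in (0, 1]")
  if (!is.null(network$pruning))
    abort("network already pruned; rebuild before pruning again")
  da <- network$neurons$id[network$neurons$type == "da"]
  n_sel <- ceiling(fraction * length(da))
  if (n_sel == 0) {
    network$pruning <- tibble(neuron = integer(), mode = character(),
                              n_edges = integer(), n_removed = integer(),
                              realized_loss = double())
    return(network)
  }
  with_seed(seed, {
    selected <- sort(sample(da, n_sel))
    edges <- network$edges
    drop_idx <- integer(0)
    rec <- vector("list", n_sel)
    for (s in seq_along(selected)) {
      v <- selected[s]
      if (mode == "random_edge" || mode == "axon_shorten") {
        idx <- which(edges$source == v)
        key <- edges$s_len[idx]
      } else {
        idx <- which(edges$target == v)
        key <- edges$dist[idx]
      }
      m <- length(idx)
      if (m == 0) {
        rec[[s]] <- tibble(neuron = v, mode = mode, n_edges = 0L,
                           n_removed = 0L, realized_loss = NA_real_)
        next
      }
      if (mode == "random_edge") {
        n_rm <- round(target_loss * m)
        rm_local <- sample.int(m, n_rm)
      } else {
        # keep the k nearest crossings; k chosen so the realized loss is as
        # close as possible to the target (ties -> more conservative cut)
        ord <- order(key)
        losses <- (m - 0:m) / m
        k_keep <- (0:m)[which.min(abs(losses - target_loss))]
        rm_local <- if (k_keep == m) integer(0) else ord[(k_keep + 1):m]
        n_rm <- length(rm_local)
        if (mode == "axon_shorten") {
          cut <- if (k_keep == 0) 0 else if (k_keep == m)
            network$neurons$axon_length[v] else
              (key[ord[k_keep]] + key[ord[k_keep + 1]]) / 2
          network$neurons$axon_length[v] <- min(
            network$neurons$axon_length[v], cut)
        } else {
          newr <- if (k_keep == 0) 0 else if (k_keep == m)
            network$neurons$dendrite_radius[v] else
              (key[ord[k_keep]] + key[ord[k_keep + 1]]) / 2
          network$neurons$dendrite_radius[v] <- min(
            network$neurons$dendrite_radius[v], newr)
        }
      }
      drop_idx <- c(drop_idx, idx[rm_local])
      rec[[s]] <- tibble(neuron = v, mode = mode, n_edges = m,
                         n_removed = as.integer(n_rm),
                         realized_loss = n_rm / m)
    }
    if (length(drop_idx) > 0)
      network$edges <- edges[-drop_idx, , drop = FALSE]
    network$pruning <- dplyr::bind_rows(rec)
    network
  })
}

#' @export
print.spatial_network <- function(x, ...) {
  tab <- table(x$neurons$type)
  cat(sprintf("<spatial_network> %d neurons (%s), %d edges, field %g x %g um\n",
              nrow(x$neurons),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
              nrow(x$edges), x$field[1], x$field[2]))
  if (!is.null(x$pruning) && nrow(x$pruning) > 0)
    cat(sprintf("  pruned: %d neurons (%s), mean realized loss %.1f%%\n",
                nrow(x$pruning), x$pruning$mode[1],
                100 * mean(x$pruning$realized_loss, na.rm = TRUE)))
  invisible(x)
}

#' @export
tidy.spatial_network <- function(x, ...) x$edges

#' @export
glance.spatial_network <- function(x, ...) {
  tab <- table(factor(x$neurons$type,
                      levels = c("excitatory", "da", "inhibitory")))
  tibble(n_neurons = nrow(x$neurons),
         n_excitatory = as.integer(tab[["excitatory"]]),
         n_da = as.integer(tab[["da"]]),
         n_inhibitory = as.integer(tab[["inhibitory"]]),
         n_edges = nrow(x$edges),
         pruned = !is.null(x$pruning) && nrow(x$pruning) > 0)
}
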