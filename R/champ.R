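#' Affine-in-gamma decomposition of a partition's modularity
#'
#' For a single resolution parameter shared across layers, the multilayer
#' modularity of a fixed partition is affine in gamma:
#' Q(gamma) = (a_p - gamma * b_p) / C_norm, where a_p collects the
#' within-community intralayer correlations (diagonal included) plus the
#' interlayer couplings, and b_p is the within-community null sum.
#'
#' @param partition label vector over the supra nodes (layer-major order:
#'   all genes of layer 1, then layer 2, ...).
#' @param mlc a `multilayer_correlation`.
#' @param nulls list of `null_layer` objects, one per layer.
#' @return list of class `partition_line`: `a`, `b`, `c_norm`, `partition`.
#' @export
partition_line <- function(partition, mlc, nulls) {
  L <- length(mlc$layer_names)
  N <- length(mlc$gene_ids)
  if (length(partition) != N * L)
    stop_mlcoex("partition must cover all ", N * L, " nodes")
  lab <- canonical_labels(partition)
  a <- 0
  b <- 0
  for (al in seq_len(L)) {
    idx <- (al - 1L) * N + seq_len(N)
    labl <- lab[idx]
    nr <- if (inherits(nulls[[al]], "null_layer")) nulls[[al]]$null_rho
          else as.matrix(nulls[[al]])
    for (c in unique(labl)) {
      members <- which(labl == c)
      a <- a + sum(mlc$rho[[al]][members, members])
      b <- b + sum(nr[members, members])
    }
  }
  if (L >= 2L) for (al in seq_len(L - 1L)) for (be in (al + 1L):L) {
    same <- lab[(al - 1L) * N + seq_len(N)] == lab[(be - 1L) * N + seq_len(N)]
    a <- a + 2 * sum(mlc$omega[same, al, be])
  }
  c_norm <- sum(vapply(mlc$rho, sum, 0)) + sum(mlc$omega)
  structure(list(a = a, b = b, c_norm = c_norm, partition = lab),
            class = "partition_line")
}

#' Evaluate a partition line at given resolutions
#'
#' @param line a `partition_line`.
#' @param gamma numeric vector of resolution values.
#' @return modularity values Q(gamma).
#' @export
evaluate_line <- function(line, gamma) {
  (line$a - gamma * line$b) / line$c_norm
}

#' One-dimensional convex hull of admissible partitions
#'
#' Computes the upper envelope of the partition lines over a gamma interval:
#' the tiling of `[gamma_min, gamma_max]` into sub-intervals on which one
#' input partition attains the largest modularity. Dominated lines are
#' discarded; coincident lines are merged keeping the first partition id.
#' Wide intervals indicate resolutions at which the optimal partition is
#' robust.
#'
#' @param lines list of `partition_line` objects (or a list of lists with
#'   fields `a` and `b`).
#' @param gamma_min,gamma_max interval bounds (default 1 and 4).
#' @return object of class `gamma_domains`: data.frame `intervals` with
#'   columns `gamma_low`, `gamma_high`, `partition_id`, `width`, and logical
#'   `at_boundary` marking intervals truncated by the sweep range (the
#'   envelope is only reported inside the range).
#' @export
champ_1d <- function(lines, gamma_min = 1, gamma_max = 4) {
  if (length(lines) == 0L) stop_mlcoex("no partition lines supplied")
  if (gamma_max <= gamma_min) stop_mlcoex("gamma bounds must be ordered")
  a <- vapply(lines, function(l) l$a, 0)
  b <- vapply(lines, function(l) l$b, 0)
  eps <- 1e-12 * max(1, max(abs(a)), max(abs(b)))
  ints <- list()
  g <- gamma_min
  # current leader: max value at g; ties resolved toward the shallower line
  # (smaller b), which dominates immediately to the right
  pick <- function(g) {
    v <- a - g * b
    cand <- which(v >= max(v) - eps)
    cand[which.min(b[cand])]
  }
  cur <- pick(gamma_min)
  guard <- 0L
  while (g < gamma_max && (guard <- guard + 1L) <= length(lines) + 2L) {
    # earliest gamma > g at which a shallower line overtakes the leader
    steeper <- which(b < b[cur] - eps)
    g_next <- gamma_max
    nxt <- NA_integer_
    if (length(steeper)) {
      cross <- (a[cur] - a[steeper]) / (b[cur] - b[steeper])
      ok <- which(cross > g + eps & cross < g_next - eps)
      if (length(ok)) {
        j <- ok[which.min(cross[ok])]
        g_next <- cross[j]
        nxt <- steeper[j]
      }
    }
    ints[[length(ints) + 1L]] <- data.frame(gamma_low = g, gamma_high = g_next,
                                            partition_id = cur)
    if (is.na(nxt)) break
    g <- g_next
    cur <- nxt
  }
  intervals <- do.call(rbind, ints)
  intervals$width <- intervals$gamma_high - intervals$gamma_low
  intervals <- intervals[intervals$width > eps, , drop = FALSE]
  rownames(intervals) <- NULL
  intervals$at_boundary <- intervals$gamma_low <= gamma_min + eps |
    intervals$gamma_high >= gamma_max - eps
  structure(list(intervals = intervals, gamma_min = gamma_min,
                 gamma_max = gamma_max),
            class = "gamma_domains")
}

#' @export
print.gamma_domains <- function(x, ...) {
  cat(sprintf("<gamma_domains> %d interval(s) on [%g, %g]\n",
              nrow(x$intervals), x$gamma_min, x$gamma_max))
  print(x$intervals)
  invisible(x)
}

#' Sweep the resolution parameter
#'
#' Runs one iterated generalized Louvain partition per grid value. The
#' default grid is 15 evenly spaced values on `[1, 4]`.
#'
#' @param mlc a `multilayer_correlation`.
#' @param nulls list of fitted `null_layer` objects.
#' @param grid gamma grid.
#' @param seed integer seed (one RNG stream drives the whole sweep).
#' @return list with one element per grid value: `gamma`, `partition`, `Q`.
#' @export
gamma_sweep <- function(mlc, nulls, grid = seq(1, 4, length.out = 15),
                        seed = NULL) {
  if (length(grid) == 0L) stop_mlcoex("empty gamma grid")
  if (!is.null(seed)) set.seed(seed)
  lapply(grid, function(g) {
    supra <- build_supra_modularity(mlc, nulls, gamma = g)
    p <- iterated_genlouvain(supra)
    list(gamma = g, partition = p, Q = modularity_score(p, supra))
  })
}

#' Pick representative resolutions from the widest domains
#'
#' Selects the `n_domains` widest envelope intervals (ties broken toward
#' smaller gamma) and returns the midpoint of each, unless `pin` supplies an
#' explicit value falling inside a chosen interval, in which case that value
#' is used for it.
#'
#' @param domains a `gamma_domains` from [champ_1d()].
#' @param n_domains how many intervals to represent (default 2).
#' @param pin optional numeric vector of preferred gamma values.
#' @return data.frame with `gamma`, `gamma_low`, `gamma_high`,
#'   `partition_id`, ordered by decreasing interval width.
#' @export
select_gamma <- function(domains, n_domains = 2L, pin = NULL) {
  ints <- domains$intervals
  if (nrow(ints) == 0L) stop_mlcoex("no intervals in domains")
  ord <- order(-ints$width, ints$gamma_low)
  chosen <- ints[ord[seq_len(min(n_domains, nrow(ints)))], , drop = FALSE]
  chosen$gamma <- (chosen$gamma_low + chosen$gamma_high) / 2
  if (!is.null(pin)) {
    for (v in pin) {
      hit <- which(chosen$gamma_low <= v & v <= chosen$gamma_high)
      if (length(hit)) chosen$gamma[hit[1L]] <- v
    }
  }
  rownames(chosen) <- NULL
  chosen[, c("gamma", "gamma_low", "gamma_high", "partition_id")]
}
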