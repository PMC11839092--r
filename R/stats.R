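## Cluster-based spatiotemporal permutation tests, Bonferroni channel
## tests, exact-binomial empirical chance level, paired behavioural tests.

#' Channel adjacency graph from sensor positions
#'
#' Distance-threshold neighbourhood on the 2-D montage; symmetric, no
#' self-neighbours.
#'
#' @param montage data.frame with columns `channel`, `x`, `y`
#'   (default [default_montage()]).
#' @param threshold Euclidean distance below which channels are
#'   neighbours (default 0.35 in unit-head coordinates; gives a median of
#'   ~5 neighbours on the shipped montage).
#' @return Object of class `adjacency_graph`: list with `channels`,
#'   `matrix` (logical adjacency) and `neighbors` (named list).
#' @export
adjacency_graph <- function(montage = default_montage(), threshold = 0.35) {
  stopifnot(all(c("channel", "x", "y") %in% names(montage)))
  check_number(threshold, "threshold", positive = TRUE)
  d <- as.matrix(stats::dist(montage[, c("x", "y")]))
  A <- d < threshold
  diag(A) <- FALSE
  dimnames(A) <- list(montage$channel, montage$channel)
  structure(list(channels = montage$channel, matrix = A,
                 neighbors = apply(A, 1L, function(r)
                   montage$channel[r], simplify = FALSE)),
            class = "adjacency_graph")
}

#' Permutation-test configuration
#'
#' @param n_permutations random within-subject condition swaps (>= 100;
#'   default 1000).
#' @param sample_alpha two-sided sample-level alpha for cluster formation
#'   (default 0.05).
#' @param min_neighbors spatially adjacent suprathreshold channels required
#'   for a sample to enter a cluster: 3 for grand-average analyses, 1 for
#'   channel-group analyses.
#' @param cluster_alpha one-sided cluster-level alpha (default 0.05: a
#'   cluster is significant when its mass exceeds the 95th percentile of
#'   the permutation null).
#' @param seed integer seed for the permutation draws.
#' @return Object of class `permutation_config`.
#' @export
permutation_config <- function(n_permutations = 1000L, sample_alpha = 0.05,
                               min_neighbors = 3L, cluster_alpha = 0.05,
                               seed = 1L) {
  check_number(n_permutations, "n_permutations", positive = TRUE,
               integerish = TRUE)
  if (n_permutations < 100) stop_invalid("`n_permutations` must be >= 100")
  check_number(sample_alpha, "sample_alpha", positive = TRUE)
  check_number(cluster_alpha, "cluster_alpha", positive = TRUE)
  if (sample_alpha >= 1 || cluster_alpha >= 1)
    stop_invalid("alphas must lie in (0, 1)")
  check_number(min_neighbors, "min_neighbors", nonneg = TRUE,
               integerish = TRUE)
  structure(list(n_permutations = as.integer(n_permutations),
                 sample_alpha = sample_alpha,
                 min_neighbors = as.integer(min_neighbors),
                 cluster_alpha = cluster_alpha, seed = as.integer(seed)),
            class = "permutation_config")
}

#' Dependent-samples t map
#'
#' Paired t statistic per (lag, channel) cell, n - 1 degrees of freedom.
#' Cells with a zero-variance, nonzero-mean difference return a signed
#' `Inf` sentinel; identically zero differences return 0.
#'
#' @param condA,condB numeric arrays, subjects x lags x channels
#'   (or subjects x cells matrices), paired by subject.
#' @return Matrix (lags x channels) or vector of t values.
#' @export
dependent_t_map <- function(condA, condB) {
  if (!all(dim(condA) == dim(condB)))
    stop_invalid("`condA` and `condB` must have identical shape")
  dims <- dim(condA)
  n <- dims[1]
  if (n < 2) stop_invalid("need >= 2 paired subjects")
  D <- condA - condB
  Dm <- matrix(D, nrow = n)
  m <- colMeans(Dm)
  s <- sqrt(pmax(colSums(Dm^2) - n * m^2, 0) / (n - 1))
  t <- ifelse(s == 0, ifelse(m == 0, 0, sign(m) * Inf),
              m / (s / sqrt(n)))
  if (length(dims) == 3L) matrix(t, dims[2], dims[3]) else t
}

## union-find over suprathreshold cells
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

## Connected components of same-sign suprathreshold cells on the
## (lag x channel) grid: edges link time-adjacent samples on a channel and
## channel-adjacent samples at a lag.  Cells must additionally have at
## least `min_neighbors` suprathreshold adjacent channels at their lag.
form_clusters <- function(tmat, t_crit, adj, min_neighbors) {
  L <- nrow(tmat); C <- ncol(tmat)
  out <- list()
  for (sgn in c(1, -1)) {
    supra <- if (sgn > 0) tmat > t_crit else tmat < -t_crit
    if (!any(supra)) next
    if (min_neighbors > 0) {
      nbcount <- (supra + 0) %*% adj
      supra <- supra & (nbcount >= min_neighbors)
      if (!any(supra)) next
    }
    cells <- which(supra)              # column-major cell ids
    pos <- match(seq_len(L * C), cells)  # cell id -> local index
    parent <- seq_along(cells)
    for (ii in seq_along(cells)) {
      cell <- cells[ii]
      lag <- (cell - 1L) %% L + 1L
      ch <- (cell - 1L) %/% L + 1L
      if (lag < L) {                   # next time sample, same channel
        jj <- pos[cell + 1L]
        if (!is.na(jj)) {
          ri <- uf_find(parent, ii); rj <- uf_find(parent, jj)
          if (ri != rj) parent[rj] <- ri
        }
      }
      for (ch2 in which(adj[ch, ])) {  # adjacent channels, same lag
        if (ch2 <= ch) next
        jj <- pos[lag + (ch2 - 1L) * L]
        if (!is.na(jj)) {
          ri <- uf_find(parent, ii); rj <- uf_find(parent, jj)
          if (ri != rj) parent[rj] <- ri
        }
      }
    }
    roots <- vapply(seq_along(cells), function(i) uf_find(parent, i),
                    integer(1))
    for (r in unique(roots)) {
      members <- cells[roots == r]
      out[[length(out) + 1L]] <- list(
        cells = members,
        lags = (members - 1L) %% L + 1L,
        channels = (members - 1L) %/% L + 1L,
        mass = sum(tmat[members]),
        sign = sgn)
    }
  }
  out
}

#' Cluster-based permutation test for paired TRF arrays
#'
#' Forms spatiotemporal clusters of suprathreshold paired-t samples
#' (two-sided sample alpha, spatial `min_neighbors` gate) and compares each
#' cluster's t-mass against the permutation null of the maximum absolute
#' cluster mass under random within-subject condition swaps (sign flips of
#' the paired differences).  A cluster is significant when its absolute
#' mass exceeds the `1 - cluster_alpha` quantile of the null.
#'
#' @param condA,condB subjects x lags x channels arrays, paired by subject.
#' @param adjacency an [adjacency_graph()] covering all channels; channel
#'   order of the arrays must match `channels`.
#' @param config a [permutation_config()].
#' @param lags_s optional lag axis in seconds (for reporting intervals).
#' @param channels optional channel labels (default from adjacency).
#' @return Object of class `cluster_test_result`: `clusters` (list with
#'   member lags/channels, `mass`, `p_value`, `significant`),
#'   `null_max_mass`, `threshold_mass`, `t_map`, `significant_intervals`
#'   (data.frame start_s/end_s, union over significant clusters).
#' @export
cluster_permutation_test <- function(condA, condB, adjacency,
                                     config = permutation_config(),
                                     lags_s = NULL, channels = NULL) {
  if (!all(dim(condA) == dim(condB)))
    stop_invalid("`condA` and `condB` must have identical shape")
  n <- dim(condA)[1]; L <- dim(condA)[2]; C <- dim(condA)[3]
  if (is.null(channels)) channels <- adjacency$channels[seq_len(C)]
  if (C > length(adjacency$channels))
    stop_invalid("adjacency must cover all channels")
  adj <- adjacency$matrix[channels, channels, drop = FALSE]
  if (is.null(lags_s)) lags_s <- seq_len(L)

  D <- matrix(condA - condB, nrow = n)       # subjects x (L*C)
  SS <- colSums(D^2)                          # invariant under sign flips
  t_crit <- stats::qt(1 - config$sample_alpha / 2, df = n - 1)

  t_from_signs <- function(sgn) {             # sgn: perms x subjects
    M <- (sgn %*% D) / n
    V <- sweep(-n * M^2, 2L, SS, "+") / (n - 1)
    Tm <- M / sqrt(pmax(V, 0) / n)
    Tm[!is.finite(Tm)] <- 0
    Tm
  }

  t_obs <- matrix(t_from_signs(matrix(1, 1, n)), L, C)
  obs_clusters <- form_clusters(t_obs, t_crit, adj, config$min_neighbors)

  n_patterns <- 2^n
  exact <- FALSE
  if (n_patterns <= config$n_permutations) {
    warning("few distinct sign patterns (2^n <= n_permutations): ",
            "using exact enumeration of all ", n_patterns, " patterns")
    signs <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
    exact <- TRUE
  } else {
    signs <- with_seed(config$seed,
                       matrix(sample(c(1, -1), config$n_permutations * n,
                                     replace = TRUE),
                              ncol = n))
  }
  Tperm <- t_from_signs(signs)
  null_max <- vapply(seq_len(nrow(signs)), function(i) {
    cl <- form_clusters(matrix(Tperm[i, ], L, C), t_crit, adj,
                        config$min_neighbors)
    if (!length(cl)) 0 else max(abs(vapply(cl, `[[`, numeric(1), "mass")))
  }, numeric(1))
  thr <- stats::quantile(null_max, 1 - config$cluster_alpha, names = FALSE,
                         type = 1)

  clusters <- lapply(obs_clusters, function(cl) {
    cl$p_value <- mean(null_max >= abs(cl$mass))
    cl$significant <- abs(cl$mass) > thr
    cl$start_s <- lags_s[min(cl$lags)]
    cl$end_s <- lags_s[max(cl$lags)]
    cl$channel_labels <- unique(channels[cl$channels])
    cl
  })
  sig <- Filter(function(cl) cl$significant, clusters)
  intervals <- if (length(sig)) {
    iv <- unique(do.call(rbind, lapply(sig, function(cl)
      data.frame(start_s = cl$start_s, end_s = cl$end_s))))
    iv[order(iv$start_s), , drop = FALSE]
  } else data.frame(start_s = numeric(0), end_s = numeric(0))
  structure(list(clusters = clusters, null_max_mass = null_max,
                 threshold_mass = thr, t_map = t_obs,
                 significant_intervals = intervals,
                 exact_enumeration = exact,
                 channels = channels, lags_s = lags_s),
            class = "cluster_test_result")
}

#' @export
print.cluster_test_result <- function(x, ...) {
  nsig <- sum(vapply(x$clusters, `[[`, logical(1), "significant"))
  cat(sprintf("<cluster_test_result> %d cluster(s), %d significant (mass > %.3f)\n",
              length(x$clusters), nsig, x$threshold_mass))
  invisible(x)
}

#' Bonferroni-corrected paired channel tests
#'
#' Paired t-test per channel between two per-subject channel maps; each raw
#' p-value is multiplied by the channel count N (clipped at 1).
#'
#' @param mapA,mapB subjects x channels matrices, paired by subject.
#' @param N total number of channels used for the correction (default
#'   `ncol(mapA)`).
#' @param alpha significance level (default 0.05).
#' @return data.frame with columns `channel`, `t`, `p_raw`, `p_corrected`,
#'   `significant`.
#' @export
bonferroni_channel_tests <- function(mapA, mapB, N = ncol(mapA),
                                     alpha = 0.05) {
  if (!all(dim(mapA) == dim(mapB)))
    stop_invalid("`mapA` and `mapB` must have identical shape")
  check_number(N, "N", positive = TRUE, integerish = TRUE)
  n <- nrow(mapA)
  if (n < 2) stop_invalid("need >= 2 paired subjects")
  t <- dependent_t_map(mapA, mapB)
  p_raw <- ifelse(is.infinite(t), 0, 2 * stats::pt(-abs(t), df = n - 1))
  p_corr <- pmin(1, p_raw * N)
  data.frame(channel = colnames(mapA) %||% seq_len(ncol(mapA)),
             t = as.numeric(t), p_raw = as.numeric(p_raw),
             p_corrected = as.numeric(p_corr),
             significant = as.numeric(p_corr) < alpha)
}

#' Empirical chance level of a c-alternative forced-choice task
#'
#' The smallest integer k with `P(Binomial(n, 1/c) <= k) >= 1 - alpha`,
#' expressed as the percentage `100 k / n`: the lowest accuracy that
#' exceeds chance with confidence `1 - alpha` under an exact binomial
#' model.  Implemented by direct CDF enumeration (`cumsum(dbinom)`), which
#' tests cross-check against `qbinom`.
#'
#' @param n number of subjects (>= 1).
#' @param c number of alternatives (>= 2; default 2).
#' @param alpha significance level in (0, 1) (default 0.05).
#' @return Chance threshold in percent.
#' @examples
#' empirical_chance_level(30, 2, 0.05)  # 63.33...
#' @export
empirical_chance_level <- function(n, c = 2, alpha = 0.05) {
  check_number(n, "n", positive = TRUE, integerish = TRUE)
  check_number(c, "c", positive = TRUE, integerish = TRUE)
  if (c < 2) stop_invalid("`c` must be >= 2")
  check_number(alpha, "alpha", positive = TRUE)
  if (alpha >= 1) stop_invalid("`alpha` must lie in (0, 1)")
  cdf <- cumsum(stats::dbinom(0:n, n, 1 / c))
  k <- which(cdf >= 1 - alpha)[1] - 1L
  100 * k / n
}

#' Paired behavioural t-test
#'
#' Two-tailed paired t-test on per-subject percent-correct scores.
#' Zero-variance differences return the degenerate sentinel: t = 0, p = 1
#' when all differences are zero; signed `Inf`, p = 0 otherwise.
#'
#' @param accA,accB numeric vectors of per-subject accuracies, paired.
#' @return List with `t`, `df`, `p_value`, `mean_difference`.
#' @export
paired_behavioral_test <- function(accA, accB) {
  if (length(accA) != length(accB))
    stop_invalid("`accA` and `accB` must be paired (equal length)")
  n <- length(accA)
  if (n < 2) stop_invalid("need >= 2 paired subjects")
  d <- accA - accB
  m <- mean(d); s <- stats::sd(d)
  if (s == 0) {
    t <- if (m == 0) 0 else sign(m) * Inf
    p <- if (m == 0) 1 else 0
  } else {
    t <- m / (s / sqrt(n))
    p <- 2 * stats::pt(-abs(t), df = n - 1)
  }
  list(t = t, df = n - 1, p_value = p, mean_difference = m)
}
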