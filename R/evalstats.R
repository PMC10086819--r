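#' K-means clustering of t_RC estimate vectors
#'
#' Best of `n_init` seeded Lloyd runs by within-cluster sum of squares;
#' deterministic given `seed`. Points are rows of `x` (scalars allowed).
#'
#' @param x numeric vector or matrix (rows = genes).
#' @param k number of clusters.
#' @param seed integer seed.
#' @param n_init random restarts.
#' @return object of class `cluster_assignment`: list with `cluster`
#'   (integer vector), `sizes`, `cost` (total within-cluster SS) and `k`.
#' @export
kmeans_lloyd <- function(x, k = 2L, seed = 1L, n_init = 50L) {
  x <- as.matrix(x)
  if (nrow(x) < k) stop("fewer points than clusters")
  set.seed(seed)
  if (nrow(unique(x)) < k) {
    warning("fewer distinct points than clusters; degenerate partition")
    cl <- rep(1L, nrow(x))
    return(structure(list(cluster = cl, sizes = tabulate(cl, k), cost = 0,
                          k = k), class = "cluster_assignment"))
  }
  km <- stats::kmeans(x, centers = k, nstart = n_init, iter.max = 100L,
                      algorithm = "Lloyd")
  structure(list(cluster = unname(km$cluster), sizes = unname(km$size),
                 cost = km$tot.withinss, k = k),
            class = "cluster_assignment")
}

#' K-medoids (PAM) clustering of a distance matrix
#'
#' Partitioning around medoids (build + swap) on a precomputed distance
#' matrix, the clustering used for posterior-distribution estimates where
#' only pairwise (Wasserstein) distances are defined. PAM is deterministic;
#' `seed` is accepted for interface symmetry.
#'
#' @param d square symmetric non-negative matrix with zero diagonal.
#' @param k number of clusters.
#' @param seed unused (PAM is deterministic).
#' @return a `cluster_assignment`; `cost` is the total distance to medoids.
#' @export
kmedoids <- function(d, k = 2L, seed = 1L) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("need a square matrix")
  if (max(abs(d - t(d))) > 1e-8) stop("matrix is not symmetric")
  if (any(diag(d) != 0)) stop("diagonal must be zero")
  if (any(d < 0)) stop("negative distances")
  if (nrow(d) < k) stop("fewer points than clusters")
  if (nrow(d) == k) {  # every point its own cluster (PAM requires k < n)
    cl <- seq_len(k)
    return(structure(list(cluster = cl, sizes = rep(1L, k), cost = 0,
                          k = k, medoids = cl),
                     class = "cluster_assignment"))
  }
  pm <- cluster::pam(stats::as.dist(d), k = k, diss = TRUE)
  cl <- unname(pm$clustering)
  med <- pm$id.med
  cost <- sum(d[cbind(seq_len(nrow(d)), med[cl])])
  structure(list(cluster = cl, sizes = unname(tabulate(cl, k)), cost = cost,
                 k = k, medoids = med),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("k =", x$k, "clusters, sizes", paste(x$sizes, collapse = "/"),
      ", cost", format(x$cost, digits = 5), "\n")
  invisible(x)
}

#' Second-order (quadratic) Wasserstein distance between 1-D samples
#'
#' For empirical measures, `W2^2 = integral (Qa(u) - Qb(u))^2 du` over the
#' unit interval, with `Q` the sample quantile functions; for equal sizes
#' this reduces to the root mean squared difference of order statistics.
#' Handles unequal sample sizes exactly via the merged quantile grid.
#'
#' @param a,b non-empty numeric samples (equal weights).
#' @return the W2 distance (scalar).
#' @export
wasserstein2_1d <- function(a, b) {
  if (!length(a) || !length(b)) stop("empty sample")
  n <- length(a); m <- length(b)
  sa <- sort(a); sb <- sort(b)
  u <- sort(unique(c(seq_len(n) / n, seq_len(m) / m, 0)))
  w2 <- 0
  for (i in seq_len(length(u) - 1L)) {
    du <- u[i + 1L] - u[i]
    qa <- sa[floor(u[i] * n + 1e-12) + 1L]
    qb <- sb[floor(u[i] * m + 1e-12) + 1L]
    w2 <- w2 + du * (qa - qb)^2
  }
  sqrt(w2)
}

# pairwise W2 matrix over a list of samples
wasserstein2_matrix <- function(samples) {
  n <- length(samples)
  d <- matrix(0, n, n, dimnames = list(names(samples), names(samples)))
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    d[i, j] <- d[j, i] <- wasserstein2_1d(samples[[i]], samples[[j]])
  }
  d
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Pearson correlation of mid-ranks (ties averaged); the p-value uses the
#' t approximation. A constant input vector leaves the correlation
#' undefined (`NA` with `defined = FALSE`).
#'
#' @param x,y equal-length numeric vectors (n >= 3).
#' @return list with `rho`, `p`, `n`, `defined`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3L) stop("need n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = length(x), defined = FALSE))
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x),
       defined = TRUE)
}

#' Kruskal-Wallis + pairwise Wilcoxon signed-rank battery
#'
#' The comparison battery for per-gene measures across conditions: one
#' Kruskal-Wallis test over all groups (tie-corrected H), then pairwise
#' paired Wilcoxon signed-rank tests (exact null for n <= 25 without
#' ties/zeros, normal approximation otherwise), Bonferroni-adjusted over
#' the pairwise family.
#'
#' @param groups named list of equal-length numeric vectors (same genes in
#'   the same order; pairing is by position).
#' @return data frame with columns `test`, `groups`, `statistic`, `p`,
#'   `p_adjusted`, `note`.
#' @export
nonparam_battery <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  kw <- stats::kruskal.test(groups)
  rows <- data.frame(test = "kruskal-wallis",
                     groups = paste(names(groups), collapse = ","),
                     statistic = unname(kw$statistic), p = kw$p.value,
                     p_adjusted = NA_real_, note = "")
  pairs <- utils::combn(names(groups), 2L, simplify = FALSE)
  pr <- lapply(pairs, function(pp) {
    x <- groups[[pp[1]]]; y <- groups[[pp[2]]]
    if (length(x) != length(y)) stop("paired groups differ in length")
    dif <- x - y
    if (all(dif == 0))
      return(data.frame(test = "wilcoxon-signed-rank",
                        groups = paste(pp, collapse = ","),
                        statistic = NA_real_, p = NA_real_,
                        p_adjusted = NA_real_,
                        note = "all paired differences zero"))
    wt <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                              exact = length(x) <= 25L))
    data.frame(test = "wilcoxon-signed-rank",
               groups = paste(pp, collapse = ","),
               statistic = unname(wt$statistic), p = wt$p.value,
               p_adjusted = NA_real_, note = "")
  })
  pr <- do.call(rbind, pr)
  ok <- !is.na(pr$p)
  pr$p_adjusted[ok] <- pmin(1, pr$p[ok] * sum(ok))  # Bonferroni
  rbind(rows, pr)
}

#' Compare HPD widths across outgroup levels
#'
#' Builds the long per-gene table of 95% HPD widths by outgroup count,
#' per-level medians, and the nonparametric battery over levels.
#'
#' @param widths named list: level -> numeric vector of per-gene widths
#'   (same genes, same order, across levels).
#' @return list with `long` (level x gene rows), `summary` (per-level
#'   median width) and `tests` (from [nonparam_battery]).
#' @export
compare_hpd_widths <- function(widths) {
  stopifnot(is.list(widths), length(widths) >= 2L)
  ns <- lengths(widths)
  if (length(unique(ns)) != 1L) stop("gene sets differ across levels")
  gn <- lapply(widths, names)
  if (!is.null(gn[[1]]) &&
      !all(vapply(gn, identical, TRUE, y = gn[[1]])))
    stop("gene sets differ across levels")
  long <- do.call(rbind, lapply(names(widths), function(lv)
    data.frame(level = lv,
               gene_id = if (is.null(names(widths[[lv]])))
                 paste0("g", seq_along(widths[[lv]])) else names(widths[[lv]]),
               hpd_width = unname(widths[[lv]]))))
  summary <- data.frame(level = names(widths),
                        median_width = vapply(widths, stats::median, 0))
  list(long = long, summary = summary, tests = nonparam_battery(widths))
}

#' Cluster t_RC estimates the way each approach represents them
#'
#' Dispatcher mirroring the per-approach feature representations: scalar
#' estimates (dS) and small vectors (ML_CT lo/hi ranges, ELW weight
#' vectors) are clustered by K-means in Euclidean space; posterior samples
#' (dating) by PAM on the pairwise second-order Wasserstein matrix.
#'
#' @param x numeric vector, matrix (rows = genes), or list of posterior
#'   sample vectors.
#' @param k clusters.
#' @param seed integer seed.
#' @return a `cluster_assignment`.
#' @export
cluster_estimates <- function(x, k = 2L, seed = 1L) {
  if (is.list(x) && !is.data.frame(x))
    kmedoids(wasserstein2_matrix(x), k = k, seed = seed)
  else kmeans_lloyd(as.matrix(x), k = k, seed = seed)
}

#' Adjusted Rand index between two partitions
#'
#' @param a,b equal-length cluster label vectors.
#' @return the adjusted Rand index (1 = identical partitions).
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch")
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sij <- sum(ch2(tab))
  si <- sum(ch2(rowSums(tab)))
  sj <- sum(ch2(colSums(tab)))
  n2 <- ch2(length(a))
  exp_ <- si * sj / n2
  den <- (si + sj) / 2 - exp_
  if (den == 0) return(1)
  (sij - exp_) / den
}
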