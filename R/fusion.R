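#' Pairwise distance matrix between perturbagen profiles
#'
#' `"sq_euclidean"` follows the dist2 convention (squared Euclidean
#' distances); `"pearson_distance"` is (1 - r)/2, mapping r = 1 to 0 and
#' r = -1 to 1.
#'
#' @param profile A `profile_matrix` or a plain numeric matrix (rows =
#'   perturbagens).
#' @param metric `"sq_euclidean"` or `"pearson_distance"`.
#' @return A `distance_matrix`: list with `d` (symmetric matrix, zero
#'   diagonal), `metric`, `ids`.
#' @export
pairwise_distance <- function(profile, metric = c("sq_euclidean", "pearson_distance")) {
  metric <- match.arg(metric)
  x <- if (inherits(profile, "profile_matrix")) profile$z else as.matrix(profile)
  if (nrow(x) < 3L) stop("need at least 3 perturbagens")
  if (metric == "sq_euclidean") {
    d <- as.matrix(stats::dist(x))^2
  } else {
    v <- apply(x, 1L, stats::sd)
    if (any(v == 0))
      stop("zero-variance row(s) under pearson_distance: ",
           paste(utils::head(rownames(x)[v == 0], 5L), collapse = ", "))
    d <- (1 - stats::cor(t(x))) / 2
  }
  diag(d) <- 0
  d <- (d + t(d)) / 2
  structure(list(d = d, metric = metric, ids = rownames(x)),
            class = "distance_matrix")
}

#' Scaled-exponential affinity kernel
#'
#' `W(i,j) = exp(-D(i,j) / (mu * eps(i,j)))` with the locally adaptive scale
#' `eps(i,j) = (mean_k(i) + mean_k(j) + D(i,j)) / 3`, where `mean_k(i)` is the
#' mean distance from i to its k nearest neighbours (self excluded). The
#' kernel is scale invariant: multiplying all distances by c > 0 leaves W
#' unchanged.
#'
#' @param D A `distance_matrix` or square symmetric matrix.
#' @param k Number of nearest neighbours for the local scale, 1 <= k < n.
#' @param mu Kernel bandwidth multiplier in (0, 1], default 0.5.
#' @return An `affinity_matrix`: list with `w` (symmetric, unit diagonal,
#'   entries in (0, 1]), `ids`, `k_used`, `source`.
#' @export
affinity_kernel <- function(D, k, mu = 0.5, source = "dataset") {
  d <- if (inherits(D, "distance_matrix")) D$d else as.matrix(D)
  ids <- if (inherits(D, "distance_matrix")) D$ids else rownames(d)
  n <- nrow(d)
  if (k < 1L || k >= n) stop("k must satisfy 1 <= k < n")
  if (mu <= 0) stop("mu must be > 0")
  knn_mean <- knn_mean_dist(d)[, k]
  w <- kernel_from_means(d, knn_mean, mu)
  structure(list(w = w, ids = ids, k_used = as.integer(k), source = source),
            class = "affinity_matrix")
}

# mean distance to the j nearest neighbours (self excluded), all j at once:
# row i, column k gives mean of the k smallest off-diagonal distances of i
knn_mean_dist <- function(d) {
  n <- nrow(d)
  out <- matrix(0, n, n - 1L)
  for (i in seq_len(n)) {
    s <- sort(d[i, -i])
    out[i, ] <- cumsum(s) / seq_len(n - 1L)
  }
  out
}

kernel_from_means <- function(d, knn_mean, mu) {
  eps <- (outer(knn_mean, knn_mean, "+") + d) / 3
  zero <- eps <= 0
  if (any(zero[upper.tri(zero)])) {
    warning("coincident points with zero kernel scale; flooring eps")
    eps[zero] <- .Machine$double.eps
  }
  w <- exp(-d / (mu * eps))
  diag(w) <- 1
  (w + t(w)) / 2
}

# full-kernel transition matrix: off-diagonal row sums 1/2, diagonal 1/2
p_normalize <- function(w) {
  rs <- rowSums(w) - diag(w)
  p <- w / (2 * rs)
  diag(p) <- 0.5
  p
}

# sparse kNN kernel: keep the k nearest neighbours of each row (self
# excluded), rows normalized to sum 1
s_kernel <- function(w, k) {
  n <- nrow(w)
  s <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- order(w[i, -i], decreasing = TRUE)[seq_len(k)]
    nb <- seq_len(n)[-i][nb]
    s[i, nb] <- w[i, nb]
  }
  s / rowSums(s)
}

#' Fuse affinity networks by cross-network diffusion
#'
#' The standard similarity-network-fusion update: each dataset's full-kernel
#' transition matrix P is repeatedly replaced by `S %*% mean(other P) %*% t(S)`
#' (S = the dataset's sparse kNN kernel), symmetrized and renormalized, for
#' `t` rounds; the fused network is the mean of the final P matrices,
#' symmetrized.
#'
#' @param affinities List of >= 2 `affinity_matrix` objects over identical ids
#'   (same order), all built with the same k.
#' @param t Number of diffusion rounds (default 20).
#' @return Symmetric positive matrix with ids as dimnames.
#' @export
snf_fuse <- function(affinities, t = 20L) {
  if (length(affinities) < 2L) stop("need >= 2 affinity matrices")
  if (t < 1L) stop("t must be >= 1")
  ids <- affinities[[1L]]$ids
  for (a in affinities)
    if (!identical(a$ids, ids)) stop("affinity matrices have mismatched ids")
  k <- affinities[[1L]]$k_used
  P <- lapply(affinities, function(a) p_normalize(a$w))
  S <- lapply(affinities, function(a) s_kernel(a$w, k))
  m <- length(P)
  for (iter in seq_len(t)) {
    Pnew <- vector("list", m)
    for (v in seq_len(m)) {
      others <- Reduce(`+`, P[-v]) / (m - 1L)
      q <- S[[v]] %*% others %*% t(S[[v]])
      q <- (q + t(q)) / 2
      Pnew[[v]] <- p_normalize(q)
    }
    P <- Pnew
  }
  w <- Reduce(`+`, P) / m
  w <- (w + t(w)) / 2
  dimnames(w) <- list(ids, ids)
  w
}

# diffusion of a single dataset against itself (the m = 2 update with both
# inputs equal collapses to this recursion); used for per-dataset attribution
self_diffuse <- function(w, k, t = 20L) {
  P <- p_normalize(w)
  S <- s_kernel(w, k)
  for (iter in seq_len(t)) {
    q <- S %*% P %*% t(S)
    q <- (q + t(q)) / 2
    P <- p_normalize(q)
  }
  (P + t(P)) / 2
}

#' Kernel and sweep parameters for fused-network construction
#'
#' @param mu Kernel bandwidth multiplier (default 0.5).
#' @param t Diffusion rounds (default 20).
#' @param k_range Integer vector of kNN values to sweep; default
#'   `2:floor(n/2)`, resolved when the network is built.
#' @return List of class `kernel_params`.
#' @export
kernel_params <- function(mu = 0.5, t = 20L, k_range = NULL) {
  if (mu <= 0) stop("mu must be > 0")
  if (t < 1L) stop("t must be >= 1")
  structure(list(mu = mu, t = as.integer(t), k_range = k_range),
            class = "kernel_params")
}

#' Build the k-swept, aggregated fused similarity network
#'
#' For every k in the sweep (default k = 2 .. floor(n/2)) the two datasets'
#' affinity kernels are fused by cross-network diffusion; each fused matrix is
#' range-normalized by its maximum off-diagonal value; the aggregate network
#' is the element-wise mean over all k (so the sweep over an even n produces
#' n/2 - 1 fused matrices before averaging). Per-dataset attribution matrices
#' are computed the same way but diffusing each dataset alone.
#'
#' @param profiles_a,profiles_b `profile_matrix` objects for the two
#'   platforms; ids are intersected (with a warning if any are dropped).
#' @param metric Distance metric passed to [pairwise_distance()].
#' @param params A [kernel_params()] object.
#' @param per_dataset Also compute per-dataset (self-diffusion) aggregate
#'   matrices for edge attribution (default `TRUE`).
#' @return A `fused_network`: list with `w_agg` (symmetric, off-diagonal in
#'   (0, 1], unit diagonal), `ids`, `params` (with resolved `k_range`),
#'   `per_dataset_agg` (named list of matrices, or `NULL`), `metric`,
#'   `platforms`.
#' @export
ksweep_aggregate <- function(profiles_a, profiles_b,
                             metric = c("sq_euclidean", "pearson_distance"),
                             params = kernel_params(), per_dataset = TRUE) {
  metric <- match.arg(metric)
  ids <- intersect(rownames(profiles_a$z), rownames(profiles_b$z))
  n_union <- length(union(rownames(profiles_a$z), rownames(profiles_b$z)))
  if (length(ids) < n_union)
    warning(n_union - length(ids),
            " perturbagen(s) present in only one platform were dropped")
  n <- length(ids)
  if (n < 4L) stop("need n >= 4 shared perturbagens (k sweep would be empty)")
  k_range <- params$k_range
  if (is.null(k_range)) k_range <- 2:floor(n / 2)
  if (any(k_range < 1L | k_range >= n)) stop("k_range values must satisfy 1 <= k < n")

  xa <- profiles_a$z[ids, , drop = FALSE]
  xb <- profiles_b$z[ids, , drop = FALSE]
  da <- pairwise_distance(xa, metric)$d
  db <- pairwise_distance(xb, metric)$d
  ma <- knn_mean_dist(da)
  mb <- knn_mean_dist(db)
  tags <- c(profiles_a$platform, profiles_b$platform)
  if (anyDuplicated(tags)) tags <- c("A", "B")

  acc <- matrix(0, n, n)
  acc_self <- if (per_dataset) list(matrix(0, n, n), matrix(0, n, n)) else NULL
  for (k in k_range) {
    wa <- kernel_from_means(da, ma[, k], params$mu)
    wb <- kernel_from_means(db, mb[, k], params$mu)
    aff <- list(structure(list(w = wa, ids = ids, k_used = k, source = tags[1L]),
                          class = "affinity_matrix"),
                structure(list(w = wb, ids = ids, k_used = k, source = tags[2L]),
                          class = "affinity_matrix"))
    fk <- snf_fuse(aff, t = params$t)
    acc <- acc + range_normalize(fk)
    if (per_dataset) {
      acc_self[[1L]] <- acc_self[[1L]] + range_normalize(self_diffuse(wa, k, params$t))
      acc_self[[2L]] <- acc_self[[2L]] + range_normalize(self_diffuse(wb, k, params$t))
    }
  }
  nk <- length(k_range)
  w_agg <- acc / nk
  diag(w_agg) <- 1
  dimnames(w_agg) <- list(ids, ids)
  pda <- NULL
  if (per_dataset) {
    pda <- lapply(acc_self, function(m) {
      m <- m / nk
      diag(m) <- 1
      dimnames(m) <- list(ids, ids)
      m
    })
    names(pda) <- tags
  }
  params$k_range <- k_range
  structure(list(w_agg = w_agg, ids = ids, params = params,
                 per_dataset_agg = pda, metric = metric, platforms = tags),
            class = "fused_network")
}

# divide by the maximum off-diagonal entry so the off-diagonal max is 1
range_normalize <- function(w) {
  d <- diag(w)
  diag(w) <- -Inf
  mx <- max(w)
  diag(w) <- d
  w / mx
}

#' @export
print.fused_network <- function(x, ...) {
  off <- x$w_agg[upper.tri(x$w_agg)]
  cat(sprintf("<fused_network> %d perturbagens, metric %s, k swept %d..%d (%d matrices)\n",
              length(x$ids), x$metric, min(x$params$k_range),
              max(x$params$k_range), length(x$params$k_range)))
  cat(sprintf("  off-diagonal similarity: min %.3g, median %.3g, max %.3g\n",
              min(off), stats::median(off), max(off)))
  invisible(x)
}

#' @export
summary.fused_network <- function(object, ...) {
  off <- object$w_agg[upper.tri(object$w_agg)]
  out <- list(n = length(object$ids), metric = object$metric,
              k_range = object$params$k_range,
              quantiles = stats::quantile(off, c(0, .25, .5, .75, .95, 1)))
  class(out) <- "summary.fused_network"
  out
}

#' @export
print.summary.fused_network <- function(x, ...) {
  cat(sprintf("Fused similarity network: n = %d, metric = %s, %d k values\n",
              x$n, x$metric, length(x$k_range)))
  print(signif(x$quantiles, 3))
  invisible(x)
}

#' Heatmap of the fused similarity matrix
#'
#' @param x A `fused_network`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.fused_network <- function(x, ...) {
  n <- length(x$ids)
  graphics::image(seq_len(n), seq_len(n), x$w_agg[, n:1],
                  xlab = "perturbagen", ylab = "perturbagen",
                  main = "Aggregate fused similarity", ...)
  invisible(x)
}

#' Log10-transform a fused network's aggregate matrix
#'
#' Entries below `floor` are clipped up to it before taking log10.
#'
#' @param net A `fused_network` or positive matrix.
#' @param floor Underflow guard (default 1e-12).
#' @return Matrix of log10 similarities.
#' @export
log_transform <- function(net, floor = 1e-12) {
  w <- if (inherits(net, "fused_network")) net$w_agg else as.matrix(net)
  w[w < floor] <- floor
  if (any(w <= 0)) stop("nonpositive entries remain after flooring")
  log10(w)
}

#' Row-wise distance or correlation between perturbagens of a network matrix
#'
#' Applied to the (log-transformed) fused matrix: each perturbagen's row is
#' its similarity profile, and rows are compared by Euclidean distance or
#' Pearson correlation.
#'
#' @param m Square symmetric matrix (e.g. from [log_transform()]).
#' @param metric `"euclidean"` (returns a `distance_matrix`) or `"pearson"`
#'   (returns a correlation matrix with unit diagonal).
#' @export
network_distance <- function(m, metric = c("euclidean", "pearson")) {
  metric <- match.arg(metric)
  m <- as.matrix(m)
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-8)
    stop("input must be square and symmetric")
  if (metric == "euclidean") {
    d <- as.matrix(stats::dist(m))
    structure(list(d = d, metric = "euclidean", ids = rownames(m)),
              class = "distance_matrix")
  } else {
    v <- apply(m, 1L, stats::sd)
    if (any(v == 0))
      stop("constant row(s) under pearson: ",
           paste(utils::head(which(v == 0), 5L), collapse = ", "))
    r <- stats::cor(t(m))
    diag(r) <- 1
    r
  }
}

#' Write a fused network to a directory of delimited text files
#'
#' Writes `w_agg.csv`, per-dataset aggregate matrices (if present), and a
#' JSON sidecar `params.json`.
#'
#' @param net A `fused_network`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fused_network <- function(net, dir) {
  stopifnot(inherits(net, "fused_network"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix_csv(net$w_agg, file.path(dir, "w_agg.csv"))
  for (nm in names(net$per_dataset_agg))
    write_matrix_csv(net$per_dataset_agg[[nm]],
                     file.path(dir, paste0("agg_", nm, ".csv")))
  jsonlite::write_json(list(mu = net$params$mu, t = net$params$t,
                            k_range = net$params$k_range, metric = net$metric,
                            platforms = net$platforms),
                       file.path(dir, "params.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a fused network written by [write_fused_network()]
#'
#' @param dir Directory containing `w_agg.csv` and `params.json`.
#' @return A `fused_network`.
#' @export
read_fused_network <- function(dir) {
  p <- jsonlite::read_json(file.path(dir, "params.json"), simplifyVector = TRUE)
  w <- read_matrix_csv(file.path(dir, "w_agg.csv"))
  pda <- NULL
  files <- list.files(dir, pattern = "^agg_.*\\.csv$")
  if (length(files) > 0L) {
    pda <- lapply(files, function(f) read_matrix_csv(file.path(dir, f)))
    names(pda) <- sub("^agg_(.*)\\.csv$", "\\1", files)
    pda <- pda[p$platforms[p$platforms %in% names(pda)]]
  }
  structure(list(w_agg = w, ids = rownames(w),
                 params = kernel_params(p$mu, p$t, p$k_range),
                 per_dataset_agg = pda, metric = p$metric,
                 platforms = p$platforms),
            class = "fused_network")
}

write_matrix_csv <- function(m, path) {
  df <- data.frame(id = rownames(m),
                   apply(m, 2L, function(col) formatC(col, digits = 17, format = "g")),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("id", colnames(m))
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_matrix_csv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = ",", check.names = FALSE,
                           stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- tab[[1L]]
  m
}
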