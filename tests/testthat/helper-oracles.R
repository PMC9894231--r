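# Independent oracles used across the suite. Each is deliberately written
# from first principles (enumeration / direct summation / an external
# reference implementation) so it never shares code with the package path it
# checks.

# exhaustive one-sided two-sample KS p-value: proportion of all C(m+n, m)
# group assignments of the pooled values whose directional statistic reaches
# the observed one
ks_enum_oracle <- function(x, y, orientation = "smaller-is-closer") {
  dstat <- function(a, b) {
    v <- sort(unique(c(a, b)))
    d <- stats::ecdf(a)(v) - stats::ecdf(b)(v)
    if (orientation == "smaller-is-closer") max(d) else max(-d)
  }
  pool <- c(x, y)
  m <- length(x)
  obs <- dstat(x, y)
  idx <- utils::combn(length(pool), m)
  hits <- 0L
  for (j in seq_len(ncol(idx))) {
    a <- pool[idx[, j]]
    if (dstat(a, pool[-idx[, j]]) >= obs - 1e-12) hits <- hits + 1L
  }
  list(D = obs, p = hits / ncol(idx))
}

# upper-tail hypergeometric P(X >= x) by direct summation of the pmf written
# out in factorials (via lchoose for stability)
hyper_sum_oracle <- function(x, K, N, n) {
  hi <- min(K, n)
  if (x > hi) return(0)
  kk <- x:hi
  sum(exp(lchoose(K, kk) + lchoose(N - K, n - kk) - lchoose(N, n)))
}

# reference affinity propagation (scikit-learn) run on a batch of instances;
# returns list of list(exemplars=, labels=) with 1-based indices
run_reference_ap <- function(instances) {
  script <- test_path("ap_oracle.py")
  json <- jsonlite::toJSON(instances, auto_unbox = TRUE, digits = NA)
  out <- system2("python", shQuote(script), input = json, stdout = TRUE)
  jsonlite::fromJSON(paste(out, collapse = ""), simplifyVector = FALSE)
}

# canonical exemplar per cluster: the member maximizing total within-cluster
# similarity (diagonal set to the preference), ties to the lowest index --
# identical rule on both implementations, since exemplar identity is
# non-identifiable when totals tie exactly (every 2-member cluster ties)
canonical_exemplars <- function(s, labels, preference) {
  d <- as.matrix(s)
  diag(d) <- preference
  sort(vapply(sort(unique(labels)), function(k) {
    memb <- which(labels == k)
    memb[which.max(colSums(d[memb, memb, drop = FALSE]))]
  }, integer(1L)))
}

# brute-force SNF basket score: double loop over distinct fraction pairs
snf_score_brute <- function(samples, w) {
  samples <- intersect(samples, rownames(w))
  if (length(samples) < 2L) return(0)
  tot <- 0; cnt <- 0L
  for (i in seq_along(samples)) {
    for (j in seq_along(samples)) {
      if (j > i) {
        tot <- tot + w[samples[i], samples[j]]
        cnt <- cnt + 1L
      }
    }
  }
  tot / cnt
}

# direct (un-swept) diffusion of one dataset, written independently of the
# package internals, for the self-fusion fixed-point check
reference_self_diffusion <- function(w, k, t) {
  n <- nrow(w)
  pnorm_ref <- function(m) {
    out <- m
    for (i in seq_len(n)) {
      rs <- sum(m[i, -i])
      out[i, -i] <- m[i, -i] / (2 * rs)
      out[i, i] <- 0.5
    }
    out
  }
  sk <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- setdiff(order(w[i, ], decreasing = TRUE), i)[seq_len(k)]
    sk[i, nb] <- w[i, nb] / sum(w[i, nb])
  }
  p <- pnorm_ref(w)
  for (it in seq_len(t)) {
    q <- sk %*% p %*% t(sk)
    q <- (q + t(q)) / 2
    p <- pnorm_ref(q)
  }
  (p + t(p)) / 2
}

# small labelled Gaussian point clouds for clustering fixtures
make_pairs_geometry <- function(centers, spread = 0.05, per = 2L, seed = 1L) {
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
    matrix(rep(centers[i, ], each = per), per) +
      matrix(rnorm(per * ncol(centers), sd = spread), per)))
  rownames(x) <- paste0("p", seq_len(nrow(x)))
  x
}

# tiny two-platform screen used by several module tests
small_screen <- function(seed = 7L, ...) {
  cfg <- screen_config(n_classes = 4L, members_per_class = 5L,
                       n_noise_perturbagens = 10L, n_fractions = 12L,
                       n_bioactive_classes = 2L, fractions_per_bioactive = 3L,
                       seed = seed, ...)
  simulate_screen(cfg)
}
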