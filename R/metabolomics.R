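#' Matching tolerances for feature consensus and basketing
#'
#' @param mz_tol m/z tolerance in Thomson (default 0.01).
#' @param rt_tol Retention-time tolerance in minutes (default 0.2).
#' @param ccs_tol Collision-cross-section tolerance in percent (default 5).
#' @param min_replicates Replicates a feature must appear in to enter the
#'   consensus list (default 2, of 3).
#' @return List of class `tolerance_spec`.
#' @export
tolerance_spec <- function(mz_tol = 0.01, rt_tol = 0.2, ccs_tol = 5,
                           min_replicates = 2L) {
  if (mz_tol <= 0 || rt_tol <= 0 || ccs_tol <= 0 || min_replicates < 1L)
    stop("all tolerances must be positive")
  structure(list(mz_tol = mz_tol, rt_tol = rt_tol, ccs_tol = ccs_tol,
                 min_replicates = as.integer(min_replicates)),
            class = "tolerance_spec")
}

#' Read replicate-level mass-spectrometry feature observations
#'
#' @param path CSV with columns `sample`, `replicate`, `mz`, `rt`, optional
#'   `ccs`, `intensity`.
#' @param sep Field delimiter.
#' @return Data frame of feature observations (`ccs` filled with `NA` when
#'   absent).
#' @export
read_feature_observations <- function(path, sep = ",") {
  if (!file.exists(path)) stop("feature table not found: ", path)
  obs <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c("sample", "replicate", "mz", "rt", "intensity")
  if (!all(need %in% names(obs)))
    stop("feature table needs columns: ", paste(need, collapse = ", "))
  if (!"ccs" %in% names(obs)) obs$ccs <- NA_real_
  if (any(obs$mz <= 0) || any(obs$rt < 0))
    stop("mz must be > 0 and rt >= 0")
  obs[, c("sample", "replicate", "mz", "rt", "ccs", "intensity")]
}

ccs_match <- function(a, b, ccs_tol) {
  ifelse(is.na(a) | is.na(b), TRUE, abs(a - b) <= ccs_tol / 100 * pmax(a, b))
}

#' Collapse replicate observations of one sample into consensus features
#'
#' Observations are processed in ascending m/z and greedily grouped: an
#' observation joins the nearest-m/z open group that lies within all
#' tolerances of the group consensus and does not already contain an
#' observation from the same replicate (one match consumed per feature per
#' replicate); otherwise it opens a new group. Groups seen in at least
#' `min_replicates` distinct replicates are kept, with consensus = mean
#' m/z, RT, CCS and the maximum intensity.
#'
#' @param obs Feature observations for a single sample (see
#'   [read_feature_observations()]).
#' @param tol A [tolerance_spec()].
#' @return Data frame: `sample`, `mz`, `rt`, `ccs`, `intensity`,
#'   `n_replicates`, sorted by m/z.
#' @export
replicate_consensus <- function(obs, tol = tolerance_spec()) {
  if (nrow(obs) == 0L)
    return(data.frame(sample = character(), mz = numeric(), rt = numeric(),
                      ccs = numeric(), intensity = numeric(),
                      n_replicates = integer()))
  if (length(unique(obs$sample)) != 1L)
    stop("replicate_consensus expects observations from a single sample")
  obs <- obs[order(obs$mz), , drop = FALSE]
  g_mz <- numeric(0); g_rt <- numeric(0); g_ccs <- numeric(0)
  g_int <- numeric(0); g_n <- integer(0)
  g_reps <- list()
  for (i in seq_len(nrow(obs))) {
    mz <- obs$mz[i]; rt <- obs$rt[i]; ccs <- obs$ccs[i]
    cand <- which(abs(g_mz - mz) <= tol$mz_tol &
                  abs(g_rt - rt) <= tol$rt_tol &
                  ccs_match(g_ccs, ccs, tol$ccs_tol))
    cand <- cand[vapply(cand, function(g) !(obs$replicate[i] %in% g_reps[[g]]),
                        logical(1L))]
    if (length(cand) == 0L) {
      g_mz <- c(g_mz, mz); g_rt <- c(g_rt, rt); g_ccs <- c(g_ccs, ccs)
      g_int <- c(g_int, obs$intensity[i]); g_n <- c(g_n, 1L)
      g_reps[[length(g_mz)]] <- obs$replicate[i]
    } else {
      g <- cand[which.min(abs(g_mz[cand] - mz))]
      n <- g_n[g]
      g_mz[g] <- (g_mz[g] * n + mz) / (n + 1L)
      g_rt[g] <- (g_rt[g] * n + rt) / (n + 1L)
      g_ccs[g] <- if (is.na(g_ccs[g])) ccs else
        if (is.na(ccs)) g_ccs[g] else (g_ccs[g] * n + ccs) / (n + 1L)
      g_int[g] <- max(g_int[g], obs$intensity[i])
      g_n[g] <- n + 1L
      g_reps[[g]] <- c(g_reps[[g]], obs$replicate[i])
    }
  }
  nrep <- vapply(g_reps, function(r) length(unique(r)), integer(1L))
  keep <- nrep >= tol$min_replicates
  out <- data.frame(sample = obs$sample[1L], mz = g_mz[keep], rt = g_rt[keep],
                    ccs = g_ccs[keep], intensity = g_int[keep],
                    n_replicates = nrep[keep], stringsAsFactors = FALSE)
  out[order(out$mz), , drop = FALSE]
}

#' Basket consensus features across the full sample set
#'
#' Single-linkage grouping: features are processed in ascending m/z, and a
#' feature joins a basket if it lies within tolerance of any basket member
#' (chains a-b-c merge even when a and c are not mutually within tolerance);
#' baskets bridged by one feature are merged. Deterministic given the input.
#'
#' @param per_sample Either a list of per-sample consensus data frames from
#'   [replicate_consensus()] or one combined data frame.
#' @param tol A [tolerance_spec()].
#' @return A `basket_set`: data.frame with `basket`, consensus `mz`, `rt`,
#'   `ccs`, `n_samples`, `n_members`, `max_intensity`, and a `samples`
#'   list-column of fraction ids, sorted by m/z.
#' @export
basket_features <- function(per_sample, tol = tolerance_spec()) {
  feats <- if (is.data.frame(per_sample)) per_sample else
    do.call(rbind, per_sample)
  if (is.null(feats) || nrow(feats) == 0L) {
    out <- data.frame(basket = integer(), mz = numeric(), rt = numeric(),
                      ccs = numeric(), n_samples = integer(),
                      n_members = integer(), max_intensity = numeric())
    out$samples <- list()
    class(out) <- c("basket_set", "data.frame")
    return(out)
  }
  feats <- feats[order(feats$mz, feats$rt, feats$sample), , drop = FALSE]
  n <- nrow(feats)
  assign <- integer(n)            # basket id per feature, 0 = unassigned
  parent <- integer(0)            # union-find over basket ids
  find <- function(b) { while (parent[b] != b) b <- parent[b]; b }
  b_members <- list()
  lo <- 1L
  for (i in seq_len(n)) {
    mz <- feats$mz[i]
    while (lo < i && feats$mz[lo] < mz - tol$mz_tol) lo <- lo + 1L
    j <- if (lo < i) lo:(i - 1L) else integer(0)
    hit <- j[abs(feats$mz[j] - mz) <= tol$mz_tol &
             abs(feats$rt[j] - feats$rt[i]) <= tol$rt_tol &
             ccs_match(feats$ccs[j], feats$ccs[i], tol$ccs_tol)]
    if (length(hit) == 0L) {
      parent <- c(parent, length(parent) + 1L)
      assign[i] <- length(parent)
    } else {
      roots <- unique(vapply(assign[hit], find, integer(1L)))
      root <- min(roots)
      parent[roots] <- root
      assign[i] <- root
    }
  }
  root_of <- vapply(assign, find, integer(1L))
  groups <- split(seq_len(n), root_of)
  ord <- order(vapply(groups, function(g) min(feats$mz[g]), numeric(1L)))
  groups <- groups[ord]
  out <- do.call(rbind, lapply(seq_along(groups), function(b) {
    g <- groups[[b]]
    data.frame(basket = b, mz = mean(feats$mz[g]), rt = mean(feats$rt[g]),
               ccs = if (all(is.na(feats$ccs[g]))) NA_real_ else
                 mean(feats$ccs[g], na.rm = TRUE),
               n_samples = length(unique(feats$sample[g])),
               n_members = length(g),
               max_intensity = max(feats$intensity[g]),
               stringsAsFactors = FALSE)
  }))
  out$samples <- unname(lapply(groups, function(g) sort(unique(feats$sample[g]))))
  rownames(out) <- NULL
  class(out) <- c("basket_set", "data.frame")
  out
}

#' @export
print.basket_set <- function(x, ...) {
  cat(sprintf("<basket_set> %d baskets over %d samples (%d singletons)\n",
              nrow(x), length(unique(unlist(x$samples))),
              sum(x$n_samples == 1L)))
  invisible(x)
}

#' SNF score of a basket
#'
#' Mean of the off-diagonal fused-similarity entries among the natural-product
#' fractions containing the basket. Baskets present in fewer than two
#' fractions of the network score 0 by convention.
#'
#' @param samples Character vector of fraction ids (a basket's sample set);
#'   ids absent from the network are dropped with a warning.
#' @param net A `fused_network`, or a symmetric similarity matrix.
#' @return A single score in `[0, 1]`.
#' @export
snf_score <- function(samples, net) {
  w <- if (inherits(net, "fused_network")) net$w_agg else as.matrix(net)
  present <- intersect(samples, rownames(w))
  if (length(present) < length(samples))
    warning(length(samples) - length(present),
            " basket sample(s) missing from the network were dropped")
  if (length(present) < 2L) return(0)
  sub <- w[present, present]
  mean(sub[upper.tri(sub)])
}

#' Five activity descriptors for every basket
#'
#' Attaches the Compound-Activity-Mapping descriptors to each basket:
#' per-platform Cluster Scores (mean off-diagonal Pearson correlation of the
#' containing fractions' Z-profiles), per-platform Activity Scores (Euclidean
#' norm of the element-wise mean Z-fingerprint of those fractions, divided by
#' the square root of the feature count, so a fingerprint of all +/-1 scores
#' 1), the SNF Cluster Score ([snf_score()]), and the percentile of the SNF
#' score among all baskets.
#'
#' @param baskets A `basket_set`.
#' @param net A `fused_network`.
#' @param profile_a,profile_b `profile_matrix` objects for the two platforms.
#' @return The `basket_set` with columns `a_cluster_score`,
#'   `a_activity_score`, `b_cluster_score`, `b_activity_score`,
#'   `snf_cluster_score`, `snf_percentile` added (column prefixes follow the
#'   platform labels when available).
#' @export
score_baskets <- function(baskets, net, profile_a = NULL, profile_b = NULL) {
  stopifnot(inherits(baskets, "basket_set"))
  w <- if (inherits(net, "fused_network")) net$w_agg else as.matrix(net)
  snf <- vapply(baskets$samples, function(s) {
    suppressWarnings(snf_score(s, w))
  }, numeric(1L))
  baskets$snf_cluster_score <- snf
  baskets$snf_percentile <- 100 * vapply(snf, function(s) mean(snf <= s),
                                         numeric(1L))
  for (side in c("a", "b")) {
    prof <- if (side == "a") profile_a else profile_b
    if (is.null(prof)) next
    tag <- if (inherits(prof, "profile_matrix") &&
               prof$platform %in% c("unknown", "")) side else
      tolower(if (inherits(prof, "profile_matrix")) prof$platform else side)
    z <- if (inherits(prof, "profile_matrix")) prof$z else as.matrix(prof)
    sim <- stats::cor(t(z))
    cs <- vapply(baskets$samples, function(s) {
      pres <- intersect(s, rownames(z))
      if (length(pres) < 2L) return(0)
      sub <- sim[pres, pres]
      mean(sub[upper.tri(sub)])
    }, numeric(1L))
    as_ <- vapply(baskets$samples, function(s) {
      pres <- intersect(s, rownames(z))
      if (length(pres) == 0L) return(0)
      f <- colMeans(z[pres, , drop = FALSE])
      sqrt(sum(f^2)) / sqrt(length(f))
    }, numeric(1L))
    baskets[[paste0(tag, "_cluster_score")]] <- cs
    baskets[[paste0(tag, "_activity_score")]] <- as_
  }
  baskets
}

#' Select bioactive baskets by score percentile or absolute threshold
#'
#' With `percentile`, the nearest-rank percentile of all basket scores marks
#' the cutoff and baskets strictly above it are retained, except that ties
#' spanning the retained boundary are kept (so 100 distinct scores at the
#' 95th percentile keep exactly 5, while an all-tied score vector keeps
#' everything). With `threshold`, baskets scoring strictly above the
#' threshold are retained (the map-building convention).
#'
#' @param baskets A scored `basket_set` (see [score_baskets()]).
#' @param percentile Percentile cutoff in `[0, 100]` (default 95); ignored
#'   when `threshold` is given.
#' @param threshold Absolute score threshold (strictly greater).
#' @param score_col Column holding the score (default `"snf_cluster_score"`).
#' @return The retained subset of `baskets`.
#' @export
select_active <- function(baskets, percentile = 95, threshold = NULL,
                          score_col = "snf_cluster_score") {
  if (nrow(baskets) == 0L) return(baskets)
  s <- baskets[[score_col]]
  if (is.null(s)) stop("baskets have no '", score_col, "' column; run score_baskets()")
  if (!is.null(threshold)) {
    if (threshold < 0) stop("threshold must be >= 0")
    keep <- s > threshold
  } else {
    if (percentile < 0 || percentile > 100) stop("percentile must be in [0, 100]")
    rank_idx <- max(1L, ceiling(percentile / 100 * length(s)))
    cutoff <- sort(s)[min(rank_idx + 1L, length(s))]
    keep <- s >= cutoff
  }
  baskets[keep, , drop = FALSE]
}

#' Write a (scored) basket table to CSV
#'
#' The `samples` list-column is serialized as a `;`-separated string; numeric
#' columns are written at full precision.
#'
#' @param baskets A `basket_set`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_baskets <- function(baskets, path) {
  df <- as.data.frame(baskets)
  df$samples <- vapply(df$samples, paste, character(1L), collapse = ";")
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], function(col) formatC(col, digits = 17, format = "g"))
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a basket table written by [write_baskets()]
#'
#' @param path CSV path.
#' @return A `basket_set`.
#' @export
read_baskets <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = ",",
                          stringsAsFactors = FALSE)
  df$samples <- strsplit(df$samples, ";", fixed = TRUE)
  class(df) <- c("basket_set", "data.frame")
  df
}
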