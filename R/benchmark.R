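#' In-class vs out-of-class Kolmogorov-Smirnov tests per target class
#'
#' For every target class, the in-class sample is the set of pairwise values
#' (distances or correlations) among class members, and the out-of-class
#' sample is the set of pairwise values between class members and members of
#' other classes. A one-sided two-sample KS test asks whether in-class values
#' are stochastically smaller (`"smaller-is-closer"`, for distances) or
#' larger (`"larger-is-closer"`, for correlations) than out-of-class values.
#' Exact p-values (the permutation/Smirnov null) are used when sample sizes
#' permit, otherwise the asymptotic one-sided approximation.
#'
#' @param dist_or_sim A `distance_matrix`, or a square symmetric matrix of
#'   similarities/correlations.
#' @param classes Result of [class_membership()], or a named list of member
#'   id vectors.
#' @param orientation `"smaller-is-closer"` (default for `distance_matrix`
#'   input) or `"larger-is-closer"` (default for similarity input).
#' @param exact Passed to [stats::ks.test()] (`NULL` = exact when feasible).
#' @return Data frame with one row per class: `class`, `n_members`, `n_in`,
#'   `n_out`, `D`, `p`. Classes with fewer than 2 members present in the
#'   matrix are skipped with a warning.
#' @export
ks_inclass <- function(dist_or_sim, classes,
                       orientation = NULL, exact = NULL) {
  if (inherits(dist_or_sim, "distance_matrix")) {
    m <- dist_or_sim$d
    if (is.null(orientation)) orientation <- "smaller-is-closer"
  } else {
    m <- as.matrix(dist_or_sim)
    if (is.null(orientation)) orientation <- "larger-is-closer"
  }
  orientation <- match.arg(orientation,
                           c("smaller-is-closer", "larger-is-closer"))
  alt <- if (orientation == "smaller-is-closer") "greater" else "less"
  cls <- if (is.list(classes) && !is.null(classes$classes)) classes$classes
         else classes
  ids <- rownames(m)
  all_members <- unique(unlist(cls))
  rows <- list()
  for (nm in names(cls)) {
    memb <- intersect(cls[[nm]], ids)
    if (length(memb) < 2L) {
      warning("class '", nm, "' has <2 members in the matrix; skipped")
      next
    }
    other <- intersect(setdiff(all_members, cls[[nm]]), ids)
    if (length(other) == 0L) {
      warning("class '", nm, "' has no out-of-class partners; skipped")
      next
    }
    sub_in <- m[memb, memb, drop = FALSE]
    v_in <- sub_in[upper.tri(sub_in)]
    v_out <- as.vector(m[memb, other, drop = FALSE])
    kt <- suppressWarnings(
      stats::ks.test(v_in, v_out, alternative = alt, exact = exact))
    rows[[nm]] <- data.frame(class = nm, n_members = length(memb),
                             n_in = length(v_in), n_out = length(v_out),
                             D = unname(kt$statistic), p = kt$p.value,
                             stringsAsFactors = FALSE)
  }
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(class = character(), n_members = integer(), n_in = integer(),
               n_out = integer(), D = numeric(), p = numeric())
  rownames(out) <- NULL
  out
}

#' Hypergeometric enrichment of target classes within clusters
#'
#' Upper-tail hypergeometric test `P(X >= x)` for the overlap `x` between
#' each cluster (size n) and each class (size K) in a population of N
#' clustered perturbagens. Unannotated perturbagens count in N but belong to
#' no class. Significance is Bonferroni-corrected for the number of classes
#' tested.
#'
#' @param labels Named vector mapping perturbagen id -> cluster (e.g.
#'   `apc_result$labels` or `kmeans$cluster`).
#' @param classes Result of [class_membership()] or named list of member ids.
#' @param base_alpha Family-wise significance level before correction
#'   (default 0.05).
#' @return List with `table` (data.frame: `cluster`, `class`, `N`, `K`, `n`,
#'   `x`, `p`, `significant`), `alpha_corrected`, `n_classes_tested`,
#'   `n_significant_classes` (classes significant in at least one cluster).
#' @export
hypergeom_enrichment <- function(labels, classes, base_alpha = 0.05) {
  cls <- if (is.list(classes) && !is.null(classes$classes)) classes$classes
         else classes
  pop <- names(labels)
  if (is.null(pop)) stop("labels must be a named vector")
  N <- length(pop)
  cls <- lapply(cls, intersect, pop)
  cls <- cls[vapply(cls, length, integer(1L)) > 0L]
  if (length(cls) == 0L) stop("no class has members in the clustered population")
  alpha <- base_alpha / length(cls)
  rows <- list()
  for (cl in sort(unique(labels))) {
    memb <- pop[labels == cl]
    n <- length(memb)
    for (nm in names(cls)) {
      K <- length(cls[[nm]])
      x <- length(intersect(memb, cls[[nm]]))
      p <- stats::phyper(x - 1L, K, N - K, n, lower.tail = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = cl, class = nm, N = N, K = K, n = n, x = x, p = p,
        significant = p < alpha, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(table = tab, alpha_corrected = alpha,
       n_classes_tested = length(cls),
       n_significant_classes = length(unique(tab$class[tab$significant])))
}

#' k-means clustering of both platforms restricted to the largest classes
#'
#' Reproduces the per-platform concordance analysis: profiles from the top
#' `k` largest target classes are clustered by k-means (k clusters, fixed
#' seed, 25 restarts, Euclidean on Z-scores) independently in each platform,
#' each clustering is scored for class enrichment, and a cross-platform
#' membership-flow table (alluvial-ready) is returned.
#'
#' @param profile_a,profile_b `profile_matrix` objects.
#' @param annotations An `annotation_table`.
#' @param k Number of classes selected and of k-means clusters (default 30).
#' @param seed RNG seed for the k-means restarts.
#' @param nstart k-means restarts (default 25).
#' @param base_alpha Enrichment significance level before Bonferroni
#'   correction (default 0.05).
#' @return List with `labels_a`, `labels_b` (named cluster vectors),
#'   `enrichment_a`, `enrichment_b` (see [hypergeom_enrichment()]), `flow`
#'   (data.frame `id`, `class`, `cluster_a`, `cluster_b`), `classes_used`.
#' @export
kmeans_class_comparison <- function(profile_a, profile_b, annotations,
                                    k = 30L, seed = 1L, nstart = 25L,
                                    base_alpha = 0.05) {
  cm <- class_membership(annotations, min_size = 1L)
  sizes <- sort(cm$sizes, decreasing = TRUE)
  top <- names(sizes)[seq_len(min(k, length(sizes)))]
  cls <- cm$classes[top]
  members <- unlist(cls, use.names = FALSE)
  ids <- Reduce(intersect, list(members, rownames(profile_a$z),
                                rownames(profile_b$z)))
  if (k > length(ids))
    stop("k = ", k, " exceeds the ", length(ids), " available perturbagens")
  cls <- lapply(cls, intersect, ids)
  run_km <- function(z) {
    set.seed(seed)
    stats::kmeans(z[ids, , drop = FALSE], centers = k, nstart = nstart,
                  iter.max = 100L)$cluster
  }
  la <- run_km(profile_a$z)
  lb <- run_km(profile_b$z)
  ann <- annotations[match(ids, annotations$id), ]
  flow <- data.frame(id = ids, class = ann$target_class,
                     cluster_a = unname(la), cluster_b = unname(lb),
                     stringsAsFactors = FALSE)
  list(labels_a = la, labels_b = lb,
       enrichment_a = hypergeom_enrichment(la, cls, base_alpha),
       enrichment_b = hypergeom_enrichment(lb, cls, base_alpha),
       flow = flow, classes_used = top)
}

#' Cross-platform concordance of pairwise correlations
#'
#' For every (fraction, other-perturbagen) pair, the Pearson correlation of
#' their Z-profiles is computed in each platform; the concordance summary is
#' the Pearson correlation between the two vectors of pairwise r values.
#'
#' @param profile_a,profile_b `profile_matrix` objects sharing ids.
#' @param fractions Optional character vector of fraction ids; defaults to
#'   perturbagens with `type == "fraction"` in `profile_a`'s metadata.
#' @return List with `pairs` (data.frame `fraction`, `other`, `r_a`, `r_b`)
#'   and `concordance` (single Pearson r).
#' @export
platform_concordance <- function(profile_a, profile_b, fractions = NULL) {
  ids <- intersect(rownames(profile_a$z), rownames(profile_b$z))
  if (is.null(fractions)) {
    meta <- profile_a$perturbagen_meta
    fractions <- meta$id[meta$type == "fraction"]
  }
  fractions <- intersect(fractions, ids)
  if (length(fractions) == 0L) stop("no fractions shared between platforms")
  ok_a <- apply(profile_a$z[ids, , drop = FALSE], 1L, stats::sd) > 0
  ok_b <- apply(profile_b$z[ids, , drop = FALSE], 1L, stats::sd) > 0
  ok <- ids[ok_a & ok_b]
  if (length(ok) < length(ids))
    warning(length(ids) - length(ok), " perturbagen(s) with constant profiles skipped")
  ra <- stats::cor(t(profile_a$z[ok, , drop = FALSE]))
  rb <- stats::cor(t(profile_b$z[ok, , drop = FALSE]))
  fr <- intersect(fractions, ok)
  rows <- do.call(rbind, lapply(fr, function(f) {
    others <- setdiff(ok, f)
    data.frame(fraction = f, other = others,
               r_a = ra[f, others], r_b = rb[f, others],
               stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  list(pairs = rows, concordance = stats::cor(rows$r_a, rows$r_b))
}
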