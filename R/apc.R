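#' Deterministic affinity propagation clustering
#'
#' Message-passing exemplar clustering of a square similarity matrix (larger
#' values = more similar; use negative Euclidean distances or Pearson
#' correlations). The implementation is fully deterministic: no jitter is
#' added to the similarities and ties are broken by lowest index, so repeated
#' runs on the same input are bit-identical.
#'
#' @param similarity Square symmetric numeric matrix.
#' @param preference Diagonal self-similarity controlling the number of
#'   clusters; a single number, a vector, or `"median"` (default: median of
#'   the off-diagonal similarities).
#' @param damping Message damping factor in `[0.5, 1)` (default 0.9).
#' @param max_iter Maximum message-passing iterations (default 2000).
#' @param stable_iter Iterations the exemplar set must stay unchanged to
#'   declare convergence (default 200).
#'
#' @return An `apc_result`: list with `labels` (named integer vector,
#'   clusters numbered by first-member index), `exemplars` (named character
#'   vector cluster -> exemplar id), `exemplar_idx`, `preference`, `damping`,
#'   `converged`, `iterations_run`.
#' @export
apc <- function(similarity, preference = "median", damping = 0.9,
                max_iter = 2000L, stable_iter = 200L) {
  s <- as.matrix(similarity)
  n <- nrow(s)
  if (n != ncol(s)) stop("similarity matrix must be square")
  if (max(abs(s - t(s))) > 1e-8) stop("similarity matrix must be symmetric")
  if (damping < 0.5 || damping >= 1) stop("damping must be in [0.5, 1)")
  ids <- rownames(s)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (n == 1L) {
    return(structure(list(labels = stats::setNames(1L, ids),
                          exemplars = stats::setNames(ids, "1"),
                          exemplar_idx = 1L, preference = NA_real_,
                          damping = damping, converged = TRUE,
                          iterations_run = 0L),
                     class = "apc_result"))
  }
  if (identical(preference, "median"))
    preference <- stats::median(s[row(s) != col(s)])
  diag(s) <- preference
  dimnames(s) <- NULL

  R <- matrix(0, n, n)
  A <- matrix(0, n, n)
  ind <- seq_len(n)
  e_hist <- matrix(FALSE, n, stable_iter)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    # responsibilities
    M <- A + s
    mx1_idx <- max.col(M, ties.method = "first")
    mx1 <- M[cbind(ind, mx1_idx)]
    M[cbind(ind, mx1_idx)] <- -Inf
    mx2 <- M[cbind(ind, max.col(M, ties.method = "first"))]
    Rnew <- s - mx1
    Rnew[cbind(ind, mx1_idx)] <- s[cbind(ind, mx1_idx)] - mx2
    R <- damping * R + (1 - damping) * Rnew

    # availabilities
    Rp <- pmax(R, 0)
    diag(Rp) <- diag(R)
    cs <- colSums(Rp)
    Anew <- matrix(cs, n, n, byrow = TRUE) - Rp
    dA <- diag(Anew)
    Anew <- pmin(Anew, 0)
    diag(Anew) <- dA
    A <- damping * A + (1 - damping) * Anew

    e <- (diag(A) + diag(R)) > 0
    slot <- ((it - 1L) %% stable_iter) + 1L
    e_hist[, slot] <- e
    if (it >= stable_iter) {
      se <- rowSums(e_hist)
      if (all(se == 0L | se == stable_iter) && sum(e) > 0L) {
        converged <- TRUE
        break
      }
    }
  }

  ex <- which((diag(A) + diag(R)) > 0)
  if (length(ex) == 0L) ex <- which.max(diag(A) + diag(R))
  # assign, then refine exemplars to maximize within-cluster similarity
  cl <- max.col(s[, ex, drop = FALSE], ties.method = "first")
  cl[ex] <- seq_along(ex)
  for (k in seq_along(ex)) {
    memb <- which(cl == k)
    tot <- colSums(s[memb, memb, drop = FALSE])
    ex[k] <- memb[which.max(tot)]
  }
  ex <- sort(ex)
  cl <- max.col(s[, ex, drop = FALSE], ties.method = "first")
  cl[ex] <- seq_along(ex)

  # renumber clusters by first-member index
  first <- vapply(seq_along(ex), function(k) min(which(cl == k)), integer(1L))
  ord <- order(first)
  remap <- integer(length(ex))
  remap[ord] <- seq_along(ex)
  cl <- remap[cl]
  ex <- ex[ord]

  structure(list(labels = stats::setNames(as.integer(cl), ids),
                 exemplars = stats::setNames(ids[ex], seq_along(ex)),
                 exemplar_idx = unname(ex),
                 preference = preference[1L], damping = damping,
                 converged = converged, iterations_run = it),
            class = "apc_result")
}

#' @export
print.apc_result <- function(x, ...) {
  cat(sprintf("<apc_result> %d points -> %d clusters (%sconverged, %d iterations)\n",
              length(x$labels), length(x$exemplars),
              if (x$converged) "" else "NOT ", x$iterations_run))
  invisible(x)
}

#' Hierarchical affinity propagation
#'
#' Clusters the points, then recursively clusters the exemplars (using the
#' similarity sub-matrix restricted to exemplar rows/columns) until the
#' cluster count stops decreasing or reaches 1.
#'
#' @inheritParams apc
#' @param preference As in [apc()]; may also be a vector giving one
#'   preference per hierarchy level (the last entry is reused for deeper
#'   levels). The default `"median"` is recomputed on each level's
#'   sub-matrix.
#' @return An `apc_hierarchy`: list with `levels` (list of `apc_result`;
#'   level 1 clusters all points, level L clusters level L-1 exemplars) and
#'   `edges` (data.frame with columns `member`, `exemplar`, `level`; self
#'   edges omitted).
#' @export
hierarchical_apc <- function(similarity, preference = "median", damping = 0.9,
                             max_iter = 2000L, stable_iter = 200L) {
  s <- as.matrix(similarity)
  if (is.null(rownames(s)))
    dimnames(s) <- list(as.character(seq_len(nrow(s))),
                        as.character(seq_len(nrow(s))))
  levels <- list()
  edges <- list()
  cur <- rownames(s)
  prev_k <- length(cur) + 1L
  pref_at <- function(lev) {
    if (identical(preference, "median")) "median"
    else preference[min(lev, length(preference))]
  }
  repeat {
    res <- apc(s[cur, cur, drop = FALSE],
               preference = pref_at(length(levels) + 1L),
               damping = damping, max_iter = max_iter,
               stable_iter = stable_iter)
    k <- length(res$exemplars)
    if (k >= prev_k) break
    levels[[length(levels) + 1L]] <- res
    lev <- length(levels)
    exn <- unname(res$exemplars[as.character(res$labels)])
    keep <- names(res$labels) != exn
    edges[[lev]] <- data.frame(member = names(res$labels)[keep],
                               exemplar = exn[keep],
                               level = rep(lev, sum(keep)),
                               stringsAsFactors = FALSE)
    if (k <= 1L) break
    cur <- unname(res$exemplars)
    prev_k <- k
  }
  edges <- if (length(edges) > 0L) do.call(rbind, edges) else
    data.frame(member = character(), exemplar = character(),
               level = integer(), stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  structure(list(levels = levels, edges = edges),
            class = "apc_hierarchy")
}

#' @export
print.apc_hierarchy <- function(x, ...) {
  ks <- vapply(x$levels, function(l) length(l$exemplars), integer(1L))
  cat(sprintf("<apc_hierarchy> depth %d; clusters per level: %s; %d edges\n",
              length(x$levels), paste(ks, collapse = " -> "), nrow(x$edges)))
  invisible(x)
}

#' Annotate hierarchy edges with per-dataset support
#'
#' For each member-exemplar edge the log10 ratio of the two platforms'
#' aggregate (self-diffused) affinities is computed,
#' `r = log10(Aff_A(i,j) / Aff_B(i,j))` with platform A the first platform of
#' the fused network (conventionally the gene-signature platform).
#' Edges with `r <= -0.5` are flagged as supported by platform A, `r >= 0.5`
#' by platform B, and everything else by `"both"` — the attribution rule as
#' printed in the source analysis. `swap = TRUE` inverts the A/B labels for
#' users who prefer the opposite orientation.
#'
#' @param hierarchy An `apc_hierarchy`.
#' @param net A `fused_network` built with `per_dataset = TRUE`.
#' @param cutoff Absolute log10-ratio threshold (default 0.5).
#' @param swap Swap the two platform labels in the attribution (default
#'   `FALSE`).
#' @return List with `edges` (the hierarchy edge table plus columns `r` and
#'   `support`) and `cluster_summary` (per level-1 cluster, percentage of
#'   edges supported by each platform or both).
#' @export
annotate_edges <- function(hierarchy, net, cutoff = 0.5, swap = FALSE) {
  stopifnot(inherits(hierarchy, "apc_hierarchy"), inherits(net, "fused_network"))
  if (is.null(net$per_dataset_agg) || length(net$per_dataset_agg) != 2L)
    stop("fused network lacks per-dataset aggregate matrices; rebuild with per_dataset = TRUE")
  ed <- hierarchy$edges
  if (nrow(ed) == 0L) stop("hierarchy has no edges to annotate")
  tag_a <- names(net$per_dataset_agg)[1L]
  tag_b <- names(net$per_dataset_agg)[2L]
  aff_a <- net$per_dataset_agg[[tag_a]]
  aff_b <- net$per_dataset_agg[[tag_b]]
  # the ratio is always platform-A : platform-B; `swap` inverts only which
  # label each tail of the ratio is attributed to
  if (swap) { tmp <- tag_a; tag_a <- tag_b; tag_b <- tmp }
  ij <- cbind(match(ed$member, net$ids), match(ed$exemplar, net$ids))
  if (anyNA(ij)) stop("edge ids not present in fused network")
  num <- aff_a[ij]
  den <- aff_b[ij]
  r <- ifelse(den == 0, Inf, log10(num / den))
  if (any(den == 0)) warning("zero denominator affinity; r set to +Inf")
  support <- ifelse(r <= -cutoff, tag_a, ifelse(r >= cutoff, tag_b, "both"))
  ed$r <- r
  ed$support <- support

  lab1 <- hierarchy$levels[[1L]]$labels
  e1 <- ed[ed$level == 1L, , drop = FALSE]
  cl <- lab1[e1$member]
  summ <- do.call(rbind, lapply(sort(unique(cl)), function(k) {
    sup <- e1$support[cl == k]
    data.frame(cluster = k, n_edges = length(sup),
               pct_a = 100 * mean(sup == tag_a),
               pct_b = 100 * mean(sup == tag_b),
               pct_both = 100 * mean(sup == "both"))
  }))
  names(summ)[3:4] <- paste0("pct_", c(tag_a, tag_b))
  list(edges = ed, cluster_summary = summ,
       platforms = c(tag_a, tag_b))
}

#' Export a clustered network for external viewers
#'
#' @param hierarchy An `apc_hierarchy`.
#' @param path Output file.
#' @param annotations Optional result of [annotate_edges()]; adds `r` and
#'   `support` edge attributes.
#' @param node_meta Optional data.frame with columns `id` and `type`
#'   (`"reference"`/`"fraction"`).
#' @param format `"graphml"` or `"edge-table"` (CSV).
#' @return `path`, invisibly.
#' @export
export_network <- function(hierarchy, path, annotations = NULL,
                           node_meta = NULL,
                           format = c("graphml", "edge-table")) {
  stopifnot(inherits(hierarchy, "apc_hierarchy"))
  format <- match.arg(format)
  if (length(hierarchy$levels) == 0L) stop("empty hierarchy")
  ed <- if (!is.null(annotations)) annotations$edges else hierarchy$edges
  ed <- ed[order(ed$level, ed$member), , drop = FALSE]
  lab1 <- hierarchy$levels[[1L]]$labels
  nodes <- data.frame(id = names(lab1), cluster = unname(lab1),
                      stringsAsFactors = FALSE)
  nodes$type <- "reference"
  if (!is.null(node_meta)) {
    m <- match(nodes$id, node_meta$id)
    nodes$type[!is.na(m)] <- node_meta$type[m[!is.na(m)]]
  }
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  if (format == "edge-table") {
    ed$cluster <- unname(lab1[ed$member])
    utils::write.table(ed, path, sep = ",", row.names = FALSE, quote = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(
      ed[, c("member", "exemplar",
             setdiff(names(ed), c("member", "exemplar"))), drop = FALSE],
      directed = FALSE, vertices = nodes)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}
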