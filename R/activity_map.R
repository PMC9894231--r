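#' Build a bipartite Compound Activity Map
#'
#' Links extract (fraction) nodes to the baskets they contain, keeping only
#' baskets whose SNF score is strictly greater than the threshold; extracts
#' left with no incident basket are excluded. Extract nodes carry the mean
#' score of their incident baskets and, when a clustering is supplied, their
#' APC cluster.
#'
#' @param baskets A scored `basket_set` (see [score_baskets()]).
#' @param threshold Minimum SNF score, strict (default 0.06).
#' @param clusters Optional named vector mapping extract id -> cluster (e.g.
#'   level-1 `apc_result$labels`).
#' @param score_col Score column used for thresholding.
#' @return A `compound_activity_map`: list with `extracts` (data.frame `id`,
#'   `cluster`, `mean_score`, `n_baskets`), `baskets` (data.frame `basket`,
#'   `mz`, `rt`, `score`), `edges` (data.frame `extract`, `basket`), and
#'   `threshold`.
#' @export
build_map <- function(baskets, threshold = 0.06, clusters = NULL,
                      score_col = "snf_cluster_score") {
  stopifnot(inherits(baskets, "basket_set"))
  if (threshold < 0) stop("threshold must be >= 0")
  s <- baskets[[score_col]]
  if (is.null(s)) stop("baskets are not scored; run score_baskets()")
  keep <- baskets[s > threshold, , drop = FALSE]
  edges <- if (nrow(keep) > 0L)
    do.call(rbind, lapply(seq_len(nrow(keep)), function(i)
      data.frame(extract = keep$samples[[i]], basket = keep$basket[i],
                 stringsAsFactors = FALSE)))
  else data.frame(extract = character(), basket = integer())
  edges <- edges[order(edges$extract, edges$basket), , drop = FALSE]
  rownames(edges) <- NULL
  bn <- data.frame(basket = keep$basket, mz = keep$mz, rt = keep$rt,
                   score = keep[[score_col]], stringsAsFactors = FALSE)
  bn <- bn[order(bn$basket), , drop = FALSE]
  ex_ids <- sort(unique(edges$extract))
  ex <- do.call(rbind, lapply(ex_ids, function(e) {
    inc <- edges$basket[edges$extract == e]
    data.frame(id = e,
               cluster = if (!is.null(clusters) && e %in% names(clusters))
                 unname(clusters[e]) else NA_integer_,
               mean_score = mean(bn$score[match(inc, bn$basket)]),
               n_baskets = length(inc), stringsAsFactors = FALSE)
  }))
  if (is.null(ex))
    ex <- data.frame(id = character(), cluster = integer(),
                     mean_score = numeric(), n_baskets = integer())
  structure(list(extracts = ex, baskets = bn, edges = edges,
                 threshold = threshold),
            class = "compound_activity_map")
}

#' @export
print.compound_activity_map <- function(x, ...) {
  cat(sprintf("<compound_activity_map> %d extracts, %d baskets (score > %g), %d edges\n",
              nrow(x$extracts), nrow(x$baskets), x$threshold, nrow(x$edges)))
  invisible(x)
}

#' Plot a Compound Activity Map
#'
#' Bipartite layout via igraph; extract nodes large, basket nodes small and
#' shaded by score.
#'
#' @param x A `compound_activity_map`.
#' @param ... Passed to [igraph::plot.igraph()].
#' @export
plot.compound_activity_map <- function(x, ...) {
  g <- cam_igraph(x)
  shade <- grDevices::gray(1 - pmin(1, igraph::V(g)$score))
  is_ex <- igraph::V(g)$kind == "extract"
  igraph::plot.igraph(g, vertex.size = ifelse(is_ex, 9, 4),
                      vertex.color = ifelse(is_ex, "steelblue", shade),
                      vertex.label = ifelse(is_ex, igraph::V(g)$name, NA),
                      vertex.label.cex = 0.6, ...)
  invisible(x)
}

cam_igraph <- function(map) {
  bn <- paste0("basket_", map$baskets$basket)
  nodes <- rbind(
    data.frame(name = map$extracts$id, kind = "extract",
               score = map$extracts$mean_score, mz = NA_real_, rt = NA_real_,
               cluster = map$extracts$cluster, stringsAsFactors = FALSE),
    data.frame(name = bn, kind = "basket", score = map$baskets$score,
               mz = map$baskets$mz, rt = map$baskets$rt,
               cluster = NA_integer_, stringsAsFactors = FALSE))
  ed <- data.frame(from = map$edges$extract,
                   to = paste0("basket_", map$edges$basket),
                   stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(ed, directed = FALSE, vertices = nodes)
}

#' Export a Compound Activity Map
#'
#' `"graphml"` writes the bipartite graph with node kind/score attributes;
#' `"edge-table"` writes the extract-basket edge list as CSV;
#' `"retention-plot-table"` writes one row per basket node (`rt`, `mz`,
#' `score`, `samples`), the static stand-in for an interactive
#' retention-time/mass viewer, optionally filtered to baskets whose sample
#' set intersects `extracts`.
#'
#' @param map A `compound_activity_map`.
#' @param path Output file.
#' @param format One of `"graphml"`, `"edge-table"`,
#'   `"retention-plot-table"`.
#' @param extracts Optional extract ids to filter the retention table.
#' @return `path`, invisibly.
#' @export
export_map <- function(map, path,
                       format = c("graphml", "edge-table",
                                  "retention-plot-table"),
                       extracts = NULL) {
  stopifnot(inherits(map, "compound_activity_map"))
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(cam_igraph(map), path, format = "graphml")
  } else if (format == "edge-table") {
    utils::write.table(map$edges, path, sep = ",", row.names = FALSE,
                       quote = FALSE)
  } else {
    samp <- lapply(map$baskets$basket, function(b)
      sort(unique(map$edges$extract[map$edges$basket == b])))
    tab <- data.frame(basket = map$baskets$basket, rt = map$baskets$rt,
                      mz = map$baskets$mz, score = map$baskets$score,
                      samples = vapply(samp, paste, character(1L),
                                       collapse = ";"),
                      stringsAsFactors = FALSE)
    if (!is.null(extracts)) {
      keep <- vapply(samp, function(s) any(s %in% extracts), logical(1L))
      tab <- tab[keep, , drop = FALSE]
    }
    tab <- tab[order(tab$rt, tab$mz), , drop = FALSE]
    utils::write.table(tab, path, sep = ",", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
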