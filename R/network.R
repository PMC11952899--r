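# PPI network analysis of the predicted granule proteome: STRING-style
# edge-list ingestion, seven centrality metrics with percentile ranks,
# probability-binned trends, Louvain clustering, overlap accounting, and a
# 2D embedding for plotting.

#' Load a STRING-style edge list into an undirected graph
#'
#' Reads a whitespace- or tab-separated file with columns `protein1`,
#' `protein2`, `combined_score`, keeps edges with score at or above the
#' threshold, drops self-loops, and collapses duplicate/reciprocal pairs.
#' Identifiers pass through unmodified.
#'
#' @param path Path to the edge file (header required).
#' @param score_threshold Minimum combined score (default 400, STRING
#'   "medium confidence").
#' @return An undirected simple `igraph` graph with edge attribute
#'   `weight` (the combined score) and graph attribute `score_threshold`.
#' @export
load_string_edges <- function(path, score_threshold = 400) {
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("protein1", "protein2", "combined_score")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L)
    stop("missing column(s): ", paste(missing, collapse = ", "))
  score <- suppressWarnings(as.numeric(df$combined_score))
  if (anyNA(score))
    stop("nonnumeric combined_score at line(s): ",
         paste(utils::head(which(is.na(score)) + 1L, 5L), collapse = ", "))
  df$combined_score <- score
  graph_from_edges(df, score_threshold)
}

#' Build a PPI graph from an in-memory edge table
#'
#' Same semantics as [load_string_edges()] but starting from a data frame
#' (e.g. the output of [generate_ppi()]). Vertices without any surviving
#' edge can be retained by naming them in `vertices`.
#'
#' @param edges Data frame with `protein1`, `protein2`, `combined_score`.
#' @param score_threshold Minimum combined score.
#' @param vertices Optional character vector of node names to keep even if
#'   isolated.
#' @return An undirected simple `igraph` graph.
#' @export
ppi_graph <- function(edges, score_threshold = 400, vertices = NULL) {
  g <- graph_from_edges(edges, score_threshold)
  if (!is.null(vertices)) {
    missing <- setdiff(vertices, igraph::V(g)$name)
    if (length(missing) > 0L) g <- igraph::add_vertices(g, length(missing),
                                                        name = missing)
  }
  g
}

# Shared constructor: filter, dedupe, and build the simple graph.
graph_from_edges <- function(df, score_threshold) {
  df <- df[df$combined_score >= score_threshold & df$protein1 != df$protein2, ,
           drop = FALSE]
  if (nrow(df) == 0L) {
    warning("no edges at or above score ", score_threshold)
    g <- igraph::make_empty_graph(0, directed = FALSE)
  } else {
    a <- pmin(df$protein1, df$protein2)
    b <- pmax(df$protein1, df$protein2)
    key <- paste(a, b, sep = "\r")
    keep <- !duplicated(key)
    g <- igraph::graph_from_data_frame(
      data.frame(from = a[keep], to = b[keep],
                 weight = df$combined_score[keep]),
      directed = FALSE)
  }
  g <- igraph::set_graph_attr(g, "score_threshold", score_threshold)
  g
}

#' Induce the predicted-proteome subgraph
#'
#' Node-induced subgraph on accessions whose predicted propensity reaches
#' `min_p`; isolated nodes among those are retained. With `min_p <= 0` the
#' graph is returned unchanged.
#'
#' @param graph An `igraph` graph over accessions.
#' @param propensity Data frame with columns `accession` and `p` (e.g.
#'   from [predict.granule_model()]).
#' @param min_p Propensity cutoff.
#' @return The induced `igraph` subgraph.
#' @export
induce_predicted_subgraph <- function(graph, propensity, min_p = 0.5) {
  if (nrow(propensity) == 0L) stop("empty propensity table")
  if (min_p <= 0) return(graph)
  keep_acc <- propensity$accession[propensity$p >= min_p]
  nodes <- intersect(igraph::V(graph)$name, keep_acc)
  if (length(nodes) == 0L)
    stop("no graph node reaches propensity ", min_p)
  igraph::induced_subgraph(graph, nodes)
}

#' Seven node-centrality metrics with percentile ranks
#'
#' Computes, per node: raw degree; betweenness centrality (normalized,
#' unweighted shortest paths); eigenvector centrality (computed per
#' connected component, each component scaled to max 1; components without
#' edges score 0); PageRank (damping 0.85, uniform teleport; sums to 1);
#' closeness with the Wasserman-Faust correction for disconnected graphs;
#' local clustering coefficient (0 for degree < 2); and degree centrality
#' (degree / (n - 1)). Each metric is accompanied by its percentile rank,
#' the mid-rank fraction in \[0, 1\] (ties averaged).
#'
#' @param graph An undirected `igraph` graph.
#' @return Data frame with `accession`, the 7 metrics, and 7 `pct_*`
#'   percentile columns.
#' @export
compute_centralities <- function(graph) {
  n <- igraph::vcount(graph)
  if (n == 0L) stop("empty graph")
  if (n == 1L) warning("single-node graph; centralities are degenerate")
  deg <- igraph::degree(graph)
  btw <- if (n > 2L)
    igraph::betweenness(graph, weights = NA, normalized = TRUE)
  else rep(0, n)

  eig <- numeric(n)
  comp <- igraph::components(graph)
  for (ci in seq_len(comp$no)) {
    members <- which(comp$membership == ci)
    sub <- igraph::induced_subgraph(graph, members)
    if (igraph::ecount(sub) == 0L) next
    ev <- igraph::eigen_centrality(sub, weights = NA,
                                   options = list(maxiter = 10000))$vector
    eig[members] <- ev / max(ev)
  }

  pr <- igraph::page_rank(graph, damping = 0.85, weights = NA)$vector

  clo <- numeric(n)
  if (n > 1L) {
    raw <- suppressWarnings(igraph::closeness(graph, weights = NA,
                                              normalized = TRUE))
    comp_size <- comp$csize[comp$membership]
    wf <- raw * (comp_size - 1) / (n - 1)
    wf[comp_size == 1L | !is.finite(wf)] <- 0
    clo <- wf
  }

  cc <- igraph::transitivity(graph, type = "local", isolates = "zero",
                             weights = NA)
  cc[!is.finite(cc)] <- 0

  dc <- if (n > 1L) deg / (n - 1) else rep(0, n)

  metrics <- data.frame(
    accession = igraph::V(graph)$name %||% as.character(seq_len(n)),
    degree = as.numeric(deg),
    betweenness = as.numeric(btw),
    eigenvector = eig,
    pagerank = as.numeric(pr),
    closeness = as.numeric(clo),
    clustering_coefficient = as.numeric(cc),
    degree_centrality = as.numeric(dc),
    stringsAsFactors = FALSE)
  for (m in centrality_metric_names())
    metrics[[paste0("pct_", m)]] <- percentile_rank(metrics[[m]])
  rownames(metrics) <- NULL
  metrics
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Names of the seven centrality metrics
#' @return Character vector of length 7.
#' @export
centrality_metric_names <- function() {
  c("degree", "betweenness", "eigenvector", "pagerank", "closeness",
    "clustering_coefficient", "degree_centrality")
}

#' Percentile rank (mid-rank fraction)
#'
#' @param x Numeric vector.
#' @return Ranks with ties averaged, divided by `length(x)`; the unique
#'   maximum gets 1.0.
#' @export
percentile_rank <- function(x) rank(x, ties.method = "average") / length(x)

#' Probability-binned centrality trends with adjacent-bin ANOVA
#'
#' Nodes are binned by predicted propensity into \[0.5,0.6), \[0.6,0.7),
#' \[0.7,0.8), \[0.8,0.9), \[0.9,1.0\]; for each requested metric the
#' per-bin mean, SD and n are reported, together with one-way ANOVA
#' p-values comparing each bin with its predecessor. Pairs in which either
#' bin has fewer than 2 nodes are flagged and skipped (p = NA).
#'
#' @param centralities Output of [compute_centralities()].
#' @param propensity Data frame (`accession`, `p`); every node of the
#'   centrality table must have p >= 0.5.
#' @param metric_list Metrics to summarize (default all seven).
#' @return List with `summary` (bin x metric long data frame) and `anova`
#'   (metric, bin pair, F, p, flag).
#' @export
bin_by_probability <- function(centralities, propensity,
                               metric_list = centrality_metric_names()) {
  p <- propensity$p[match(centralities$accession, propensity$accession)]
  if (anyNA(p)) stop("propensity missing for some nodes")
  if (any(p < 0.5)) stop("all nodes must have propensity >= 0.5")
  bin <- pmin(floor((p - 0.5) / 0.1) + 1L, 5L)
  bin_labels <- c("[0.5,0.6)", "[0.6,0.7)", "[0.7,0.8)", "[0.8,0.9)", "[0.9,1.0]")
  summary_rows <- list(); anova_rows <- list()
  for (m in metric_list) {
    x <- centralities[[m]]
    if (is.null(x)) stop("unknown metric: ", m)
    for (b in 1:5) {
      v <- x[bin == b]
      summary_rows[[length(summary_rows) + 1L]] <- data.frame(
        metric = m, bin = bin_labels[b], n = length(v),
        mean = if (length(v)) mean(v) else NA_real_,
        sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
        stringsAsFactors = FALSE)
    }
    for (b in 2:5) {
      v0 <- x[bin == b - 1L]; v1 <- x[bin == b]
      if (length(v0) < 2L || length(v1) < 2L) {
        anova_rows[[length(anova_rows) + 1L]] <- data.frame(
          metric = m, comparison = paste(bin_labels[b], "vs", bin_labels[b - 1L]),
          F = NA_real_, p = NA_real_, flag = "n<2", stringsAsFactors = FALSE)
      } else {
        av <- oneway_anova(v0, v1)
        anova_rows[[length(anova_rows) + 1L]] <- data.frame(
          metric = m, comparison = paste(bin_labels[b], "vs", bin_labels[b - 1L]),
          F = av["F"], p = av["p"], flag = "", stringsAsFactors = FALSE)
      }
    }
  }
  list(summary = do.call(rbind, summary_rows),
       anova = do.call(rbind, anova_rows))
}

# Two-group one-way ANOVA; F = 0 (p = 1) when there is no between-group
# variation, including the all-identical degenerate case.
oneway_anova <- function(a, b) {
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  gm <- mean(c(a, b))
  ssb <- n1 * (mean(a) - gm)^2 + n2 * (mean(b) - gm)^2
  ssw <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
  if (ssb <= .Machine$double.eps * max(1, ssw)) return(c(F = 0, p = 1))
  if (ssw == 0) return(c(F = Inf, p = 0))
  f <- (ssb / 1) / (ssw / (n - 2))
  c(F = f, p = stats::pf(f, 1, n - 2, lower.tail = FALSE))
}

#' Louvain community detection
#'
#' Seeded Louvain modularity optimization on the unweighted graph (edge
#' weights are used only for thresholding upstream). Clusters are
#' relabeled by decreasing size so that "cluster 1" is always the largest;
#' an edgeless graph yields one cluster per node with a warning.
#'
#' @param graph An undirected `igraph` graph.
#' @param resolution Louvain resolution parameter.
#' @param seed RNG seed; identical seeds give identical partitions.
#' @return Object of class `community_partition`: named `membership`
#'   vector, cluster `sizes`, `modularity`, `resolution`, `seed`.
#' @export
louvain_partition <- function(graph, resolution = 1.0, seed = 1L) {
  nm <- igraph::V(graph)$name %||% as.character(seq_len(igraph::vcount(graph)))
  if (igraph::ecount(graph) == 0L) {
    warning("edgeless graph; every node is its own cluster")
    membership <- stats::setNames(seq_along(nm), nm)
    return(structure(list(membership = membership,
                          sizes = table(membership),
                          modularity = NA_real_,
                          resolution = resolution, seed = seed),
                     class = "community_partition"))
  }
  comm <- with_seed(seed,
    igraph::cluster_louvain(graph, weights = NA, resolution = resolution))
  mem <- igraph::membership(comm)
  sizes <- sort(table(mem), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes), names(sizes))
  membership <- stats::setNames(as.integer(relabel[as.character(mem)]), nm)
  structure(list(membership = membership,
                 sizes = table(membership),
                 modularity = igraph::modularity(graph, mem),
                 resolution = resolution, seed = seed),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat("Louvain partition: ", length(x$sizes), " clusters, modularity ",
      sprintf("%.3f", x$modularity), " (resolution ", x$resolution,
      ", seed ", x$seed, ")\n", sep = "")
  cat("  sizes:", paste(utils::head(as.integer(x$sizes), 10L), collapse = ", "),
      if (length(x$sizes) > 10L) "..." else "", "\n")
  invisible(x)
}

#' Summarize clusters by their high-confidence membership
#'
#' For each cluster: the members whose predicted propensity exceeds
#' `min_p`, the size of that high-confidence set, its mean propensity, and
#' its mean PageRank percentile rank. The `top_k` clusters by
#' high-confidence size are returned first; clusters with no
#' high-confidence member report NA means.
#'
#' @param partition A `community_partition`.
#' @param propensity Data frame (`accession`, `p`).
#' @param centralities Output of [compute_centralities()] on the same
#'   graph.
#' @param min_p High-confidence cutoff (default 0.7).
#' @param top_k Number of leading clusters to return in `top`.
#' @return List with `summary` (all clusters, ordered by high-confidence
#'   size), `top` (first `top_k` rows), and `members` (named list of
#'   high-confidence accessions per cluster).
#' @export
summarize_clusters <- function(partition, propensity, centralities,
                               min_p = 0.7, top_k = 3L) {
  stopifnot(inherits(partition, "community_partition"))
  acc <- names(partition$membership)
  p <- propensity$p[match(acc, propensity$accession)]
  pct_pr <- centralities$pct_pagerank[match(acc, centralities$accession)]
  clusters <- sort(unique(partition$membership))
  rows <- lapply(clusters, function(cl) {
    in_cl <- partition$membership == cl
    hc <- in_cl & !is.na(p) & p > min_p
    data.frame(cluster = cl, size = sum(in_cl), hc_size = sum(hc),
               mean_p = if (any(hc)) mean(p[hc]) else NA_real_,
               mean_pagerank_pct = if (any(hc)) mean(pct_pr[hc]) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$hc_size, out$cluster), ]
  rownames(out) <- NULL
  members <- lapply(stats::setNames(out$cluster, paste0("cluster_", out$cluster)),
                    function(cl) acc[partition$membership == cl & !is.na(p) & p > min_p])
  list(summary = out, top = utils::head(out, top_k), members = members)
}

#' Multi-list overlap (Venn) accounting
#'
#' Deduplicates each list, then counts every Venn region (membership
#' pattern across the lists), the union, and the intersection of all
#' lists.
#'
#' @param lists Named list of 2-8 accession character vectors.
#' @return List with `union_size`, `regions` (named counts over membership
#'   patterns such as `"A&B"`), `all_shared` (accessions present in every
#'   list) and `all_shared_size`.
#' @export
overlap_analysis <- function(lists) {
  if (is.null(names(lists)) || any(names(lists) == ""))
    stop("lists must be named")
  if (length(lists) < 2L || length(lists) > 8L)
    stop("need between 2 and 8 lists")
  empty <- names(lists)[vapply(lists, length, integer(1L)) == 0L]
  if (length(empty) > 0L)
    stop("empty list(s): ", paste(empty, collapse = ", "))
  lists <- lapply(lists, unique)
  universe <- unique(unlist(lists, use.names = FALSE))
  membership <- vapply(lists, function(l) universe %in% l,
                       logical(length(universe)))
  if (is.null(dim(membership)))
    membership <- matrix(membership, nrow = 1L, dimnames = list(NULL, names(lists)))
  pattern <- apply(membership, 1L, function(row)
    paste(names(lists)[row], collapse = "&"))
  all_shared <- universe[rowSums(membership) == length(lists)]
  list(union_size = length(universe),
       regions = c(table(pattern)),
       all_shared = all_shared,
       all_shared_size = length(all_shared))
}

#' Seeded 2D embedding of a graph for plotting
#'
#' Seeded force-directed (Fruchterman-Reingold) layout of the graph,
#' returned as one (component 1, component 2) pair per node. Intended for
#' visualization only; no geometric accuracy is implied.
#'
#' @param graph An `igraph` graph with at least 3 nodes.
#' @param seed RNG seed; identical seeds give identical coordinates.
#' @return Data frame (`accession`, `c1`, `c2`).
#' @export
embed_2d <- function(graph, seed = 1L) {
  n <- igraph::vcount(graph)
  if (n < 3L) stop("need at least 3 nodes to embed")
  coords <- with_seed(seed, igraph::layout_with_fr(graph))
  data.frame(accession = igraph::V(graph)$name %||% as.character(seq_len(n)),
             c1 = coords[, 1L], c2 = coords[, 2L],
             stringsAsFactors = FALSE)
}
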