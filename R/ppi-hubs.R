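#' Build an interaction graph from a scored edge list
#'
#' STRING-dialect scores larger than 1 are divided by 1000.
#'
#' @param edges data.frame with columns `node_a`, `node_b`, `score`.
#' @param nodes optional full node set (isolated nodes kept).
#' @return undirected simple `igraph` with edge attribute `score`.
#' @export
ppi_graph <- function(edges, nodes = NULL) {
  score <- edges$score
  if (any(score > 1)) score <- score / 1000
  if (any(score < 0 | score > 1)) stop("edge scores must lie in [0, 1] (or STRING's 0-1000)")
  ed <- data.frame(from = as.character(edges$node_a),
                   to = as.character(edges$node_b), score = score,
                   stringsAsFactors = FALSE)
  if (is.null(nodes)) nodes <- sort(unique(c(ed$from, ed$to)))
  g <- igraph::graph_from_data_frame(ed, directed = FALSE,
                                     vertices = sort(unique(c(nodes, ed$from, ed$to))))
  igraph::simplify(g, edge.attr.comb = list(score = "max"))
}

#' Confidence filter on interaction edges
#'
#' Removes edges with confidence below `min_score` (the "score < 0.7
#' removed" rule); all nodes are preserved.
#'
#' @param g igraph with edge attribute `score`.
#' @param min_score minimum retained confidence (default 0.7).
#' @return filtered igraph.
#' @export
filter_edges <- function(g, min_score = 0.7) {
  igraph::delete_edges(g, igraph::E(g)[igraph::E(g)$score < min_score])
}

#' Largest connected component
#'
#' Largest by node count; ties broken by more edges, then by the
#' lexicographically smallest sorted node-name set.
#'
#' @param g igraph.
#' @return induced subgraph on the main component.
#' @export
main_component <- function(g) {
  comp <- igraph::components(g)
  if (comp$no <= 1) return(g)
  members <- split(igraph::V(g)$name, comp$membership)
  sizes <- lengths(members)
  cand <- which(sizes == max(sizes))
  if (length(cand) > 1) {
    ecount <- vapply(cand, function(i) {
      igraph::ecount(igraph::induced_subgraph(g, members[[i]]))
    }, numeric(1))
    cand <- cand[ecount == max(ecount)]
    if (length(cand) > 1) {
      keys <- vapply(cand, function(i) paste(sort(members[[i]]), collapse = "|"),
                     character(1))
      cand <- cand[order(keys)][1]
    }
  }
  igraph::induced_subgraph(g, members[[cand[1]]])
}

#' Degree-and-betweenness core
#'
#' Induced subgraph on nodes whose degree and (raw, unnormalized)
#' betweenness both strictly exceed the respective means over the input
#' graph. The means are recorded as attributes `mean_degree` and
#' `mean_betweenness`.
#'
#' @param g connected igraph.
#' @return induced subgraph with the two means attached as graph attributes.
#' @export
degree_betweenness_core <- function(g) {
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  keep <- deg > mean(deg) & btw > mean(btw)
  if (!any(keep)) {
    stop("empty core: no node exceeds both the mean degree and mean betweenness; relax the thresholds")
  }
  sub <- igraph::induced_subgraph(g, igraph::V(g)[keep])
  sub <- igraph::set_graph_attr(sub, "mean_degree", mean(deg))
  igraph::set_graph_attr(sub, "mean_betweenness", mean(btw))
}

# Shortest-path counts sigma[s, v] from one source (BFS), plus distances.
.bfs_sigma <- function(adj, s, n) {
  dist <- rep(Inf, n); sigma <- rep(0, n)
  dist[s] <- 0; sigma[s] <- 1
  frontier <- s
  while (length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) {
      for (w in adj[[v]]) {
        if (is.infinite(dist[w])) {
          dist[w] <- dist[v] + 1
          nxt <- c(nxt, w)
        }
        if (dist[w] == dist[v] + 1) sigma[w] <- sigma[w] + sigma[v]
      }
    }
    frontier <- unique(nxt)
  }
  list(dist = dist, sigma = sigma)
}

.adj_list <- function(g) {
  lapply(igraph::as_adj_list(g, mode = "all"), as.integer)
}

#' The twelve topological centralities
#'
#' Computes, for every node of a connected graph, the centralities used for
#' hub voting: Degree, EPC (edge percolated component; mean size of the
#' node's component over `epc_rep` random half-retentions of the edges,
#' seeded), MNC (size of the largest connected component of the open
#' neighborhood), DMNC (edges of that component divided by its node count to
#' the power 1.7), MCC (sum over maximal cliques through the node of
#' `(|C| - 1)!`), BottleNeck (one shortest-path tree per source, each node's
#' tree parent being its smallest-index neighbor one BFS level closer to the
#' source; a node scores a point when its subtree holds more than n/4 nodes,
#' the root not being credited for its own tree), EcCentricity
#' (1/eccentricity), Closeness (`(n-1)/sum d`), Radiality
#' (`sum(diam + 1 - d) / (n-1)`), Betweenness (Brandes, fraction-weighted
#' path counts), ClusteringCoefficient (local transitivity, 0 below degree
#' 2), and Stress (raw count of shortest paths through the node).
#'
#' @param g connected igraph with at least 3 nodes.
#' @param epc_rep EPC resample count (default 1000).
#' @param epc_seed RNG seed for the EPC resamples.
#' @return data.frame, one row per node, one column per centrality.
#' @export
centralities <- function(g, epc_rep = 1000L, epc_seed = 1L) {
  if (!igraph::is_connected(g)) stop("centralities require a connected graph (distances undefined otherwise)")
  n <- igraph::vcount(g)
  if (n < 3) stop("centralities require at least 3 nodes")
  name <- igraph::V(g)$name
  adj <- .adj_list(g)
  D <- igraph::distances(g)
  deg <- igraph::degree(g)

  # neighborhood components: MNC / DMNC
  mnc <- dmnc <- numeric(n)
  for (v in seq_len(n)) {
    nb <- adj[[v]]
    if (length(nb) == 0) { mnc[v] <- 0; next }
    sub <- igraph::induced_subgraph(g, nb)
    comp <- igraph::components(sub)
    big <- which.max(comp$csize)
    mnc[v] <- max(comp$csize)
    cc <- igraph::induced_subgraph(sub, which(comp$membership == big))
    dmnc[v] <- igraph::ecount(cc) / igraph::vcount(cc)^1.7
  }

  # MCC over maximal cliques of size >= 2
  mcc <- numeric(n)
  for (cl in igraph::max_cliques(g, min = 2)) {
    contrib <- factorial(length(cl) - 1)
    mcc[as.integer(cl)] <- mcc[as.integer(cl)] + contrib
  }

  # EPC: seeded edge half-retention resamples
  el <- igraph::as_edgelist(g, names = FALSE)
  m <- nrow(el)
  epc <- numeric(n)
  .with_stream(epc_seed, 17L, {
    for (r in seq_len(epc_rep)) {
      keep <- stats::runif(m) < 0.5
      gs <- igraph::subgraph_from_edges(g, which(keep), delete.vertices = FALSE)
      memb <- igraph::components(gs)$membership
      epc <- epc + tabulate(memb)[memb]
    }
  })
  epc <- epc / epc_rep

  # Stress: raw shortest-path counts through each node
  sig <- vector("list", n)
  for (s in seq_len(n)) sig[[s]] <- .bfs_sigma(adj, s, n)$sigma
  stress <- numeric(n)
  for (v in seq_len(n)) {
    acc <- 0
    for (s in seq_len(n - 1)) {
      if (s == v) next
      for (t in seq(s + 1, n)) {
        if (t == v || t == s) next
        if (D[s, v] + D[v, t] == D[s, t]) {
          acc <- acc + sig[[s]][v] * sig[[t]][v]
        }
      }
    }
    stress[v] <- acc
  }

  # BottleNeck: one shortest-path tree per source (parent of w = the
  # smallest-index neighbor one BFS level closer to the source); a node is
  # credited when its subtree holds more than n/4 nodes, roots excluded
  bn <- numeric(n)
  for (s in seq_len(n)) {
    dist <- D[s, ]
    parent <- rep(NA_integer_, n)
    for (w in seq_len(n)) {
      if (w == s) next
      up <- adj[[w]][dist[adj[[w]]] == dist[w] - 1]
      parent[w] <- min(up)
    }
    subtree <- rep(1, n)
    for (v in order(dist, decreasing = TRUE)) {
      if (!is.na(parent[v])) subtree[parent[v]] <- subtree[parent[v]] + subtree[v]
    }
    credit <- subtree > n / 4
    credit[s] <- FALSE
    bn <- bn + credit
  }

  diam <- max(D)
  tab <- data.frame(
    node = name,
    Degree = as.numeric(deg),
    EPC = epc,
    MNC = mnc,
    DMNC = dmnc,
    MCC = mcc,
    BottleNeck = bn,
    EcCentricity = 1 / apply(D, 1, max),
    Closeness = (n - 1) / rowSums(D),
    Radiality = rowSums(diam + 1 - D) / (n - 1) - (diam + 1) / (n - 1),
    Betweenness = as.numeric(igraph::betweenness(g, directed = FALSE)),
    ClusteringCoefficient = {
      tr <- igraph::transitivity(g, type = "local", isolates = "zero")
      ifelse(deg < 2, 0, tr)
    },
    Stress = stress,
    row.names = NULL, stringsAsFactors = FALSE
  )
  tab
}

#' Consensus hub voting over the centrality table
#'
#' Takes, per algorithm, the nodes at or above the `top_k`-th score (ties at
#' the boundary all included), counts per-node list memberships, and flags
#' hubs at `count >= min_count`.
#'
#' @param table a [centralities()] data.frame.
#' @param top_k list depth per algorithm (default 20).
#' @param min_count minimum number of lists (default 2).
#' @return data.frame `gene`, `count`, `hub`, sorted by count descending.
#' @export
consensus_hubs <- function(table, top_k = 20L, min_count = 2L) {
  algos <- setdiff(names(table), "node")
  counts <- stats::setNames(integer(nrow(table)), table$node)
  for (a in algos) {
    sc <- table[[a]]
    cutoff <- if (length(sc) > top_k) sort(sc, decreasing = TRUE)[top_k] else min(sc)
    counts[table$node[sc >= cutoff]] <- counts[table$node[sc >= cutoff]] + 1L
  }
  out <- data.frame(gene = names(counts), count = as.integer(counts),
                    hub = counts >= min_count, row.names = NULL,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$gene), ]
  rownames(out) <- NULL
  out
}
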