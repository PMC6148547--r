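#' Jaccard and overlap coefficients between gene sets
#'
#' `jaccard = |A ∩ B| / |A ∪ B|`; `overlap_coef = |A ∩ B| / min(|A|, |B|)`
#' (Szymkiewicz-Simpson). Both symmetric; both error on empty sets.
#'
#' @param A,B character vectors of genes, non-empty.
#' @return scalar in `[0, 1]`.
#' @export
jaccard <- function(A, B) {
  if (length(A) == 0 || length(B) == 0) stop("undefined-coefficient error: empty gene set")
  A <- unique(A); B <- unique(B)
  length(intersect(A, B)) / length(union(A, B))
}

#' @rdname jaccard
#' @export
overlap_coef <- function(A, B) {
  if (length(A) == 0 || length(B) == 0) stop("undefined-coefficient error: empty gene set")
  A <- unique(A); B <- unique(B)
  length(intersect(A, B)) / min(length(A), length(B))
}

#' Pathway-crosstalk network
#'
#' Nodes are pathways with at least `min_genes` genes; edges join pairs
#' sharing at least `min_shared` genes and carry `jc`, `oc`, and
#' `weight = (jc + oc) / 2`.
#'
#' @param pathways named list of gene sets (e.g. the enrichment-significant
#'   pathways).
#' @param min_genes minimum pathway size (default 3).
#' @param min_shared minimum shared genes per edge (default 2).
#' @return object of class `crosstalk_network`: list with `nodes` (named
#'   list of retained sets), `edges` (data.frame `pathway_a`, `pathway_b`,
#'   `shared`, `jc`, `oc`, `weight`), and counts `n_input`, `n_retained`.
#'   Warns when fewer than two nodes survive.
#' @export
build_crosstalk <- function(pathways, min_genes = 3L, min_shared = 2L) {
  keep <- lengths(lapply(pathways, unique)) >= min_genes
  nodes <- pathways[keep]
  edges <- data.frame(pathway_a = character(0), pathway_b = character(0),
                      shared = integer(0), jc = numeric(0), oc = numeric(0),
                      weight = numeric(0), stringsAsFactors = FALSE)
  if (length(nodes) < 2) {
    warning("fewer than two pathways survive the size filter: empty crosstalk network")
  } else {
    ids <- names(nodes)
    rows <- list()
    for (i in seq_len(length(ids) - 1)) {
      for (j in seq(i + 1, length(ids))) {
        shared <- length(intersect(nodes[[i]], nodes[[j]]))
        if (shared < min_shared) next
        jc <- jaccard(nodes[[i]], nodes[[j]])
        oc <- overlap_coef(nodes[[i]], nodes[[j]])
        rows[[length(rows) + 1]] <- data.frame(
          pathway_a = ids[i], pathway_b = ids[j], shared = shared,
          jc = jc, oc = oc, weight = (jc + oc) / 2, stringsAsFactors = FALSE)
      }
    }
    if (length(rows)) edges <- do.call(rbind, rows)
  }
  structure(list(nodes = nodes, edges = edges,
                 n_input = length(pathways), n_retained = length(nodes)),
            class = "crosstalk_network")
}

# igraph view of the crosstalk topology (unweighted; weights as attributes).
.crosstalk_graph <- function(net) {
  igraph::graph_from_data_frame(
    net$edges[, c("pathway_a", "pathway_b", "weight")],
    directed = FALSE, vertices = names(net$nodes))
}

#' MCODE clustering of the crosstalk network
#'
#' Bader-Hogue molecular-complex detection on the unweighted topology:
#' vertex weighting by the highest k-core of the closed neighborhood
#' (weight = core number x density of that core), seed-and-grow complex
#' prediction admitting neighbors whose weight is within `vwp` of the seed
#' weight, optional haircut (iterative removal of degree-1 members).
#' Cluster score is density x node count; clusters are retained when the
#' score strictly exceeds `min_score`.
#'
#' @param net a `crosstalk_network` or an undirected igraph.
#' @param vwp vertex weight percentage (default 0.2).
#' @param haircut drop singly-connected cluster members (default TRUE).
#' @param min_score retention threshold (default 4).
#' @return data.frame of clusters (`cluster`, `n_nodes`, `n_edges`,
#'   `density`, `score`, `retained`, `members`), sorted by score descending,
#'   with the member sets in attribute `member_sets`.
#' @export
mcode <- function(net, vwp = 0.2, haircut = TRUE, min_score = 4) {
  g <- if (inherits(net, "crosstalk_network")) .crosstalk_graph(net) else net
  n <- igraph::vcount(g)
  if (n < 3) stop("MCODE needs a network with at least 3 nodes")
  adj <- .adj_list(g)
  name <- igraph::V(g)$name

  # vertex weighting on the closed neighborhood's highest k-core
  wt <- numeric(n)
  for (v in seq_len(n)) {
    nb <- c(v, adj[[v]])
    if (length(nb) < 2) next
    sub <- igraph::induced_subgraph(g, nb)
    core <- igraph::coreness(sub)
    kmax <- max(core)
    members <- which(core == kmax)
    core_sub <- igraph::induced_subgraph(sub, members)
    dens <- igraph::edge_density(core_sub)
    if (is.nan(dens)) dens <- 0
    wt[v] <- kmax * dens
  }

  # seed-and-grow
  visited <- rep(FALSE, n)
  complexes <- list()
  for (seed in order(-wt)) {
    if (visited[seed]) next
    thr <- wt[seed] * (1 - vwp)
    members <- seed
    visited[seed] <- TRUE
    frontier <- seed
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) {
        for (w in adj[[v]]) {
          if (!visited[w] && wt[w] >= thr) {
            visited[w] <- TRUE
            members <- c(members, w)
            nxt <- c(nxt, w)
          }
        }
      }
      frontier <- nxt
    }
    if (length(members) >= 2) complexes[[length(complexes) + 1]] <- members
  }

  rows <- list()
  member_sets <- list()
  for (members in complexes) {
    sub <- igraph::induced_subgraph(g, members)
    if (haircut) {
      repeat {
        dg <- igraph::degree(sub)
        if (igraph::vcount(sub) <= 2 || all(dg > 1)) break
        sub <- igraph::induced_subgraph(sub, which(dg > 1))
      }
    }
    nv <- igraph::vcount(sub)
    if (nv < 3) next
    ne <- igraph::ecount(sub)
    dens <- 2 * ne / (nv * (nv - 1))
    rows[[length(rows) + 1]] <- data.frame(
      n_nodes = nv, n_edges = ne, density = dens, score = dens * nv,
      members = paste(sort(igraph::V(sub)$name), collapse = ";"),
      stringsAsFactors = FALSE)
    member_sets[[length(member_sets) + 1]] <- sort(igraph::V(sub)$name)
  }
  if (!length(rows)) {
    out <- data.frame(cluster = integer(0), n_nodes = integer(0),
                      n_edges = integer(0), density = numeric(0),
                      score = numeric(0), retained = logical(0),
                      members = character(0))
    attr(out, "member_sets") <- list()
    return(out)
  }
  out <- do.call(rbind, rows)
  ord <- order(-out$score)
  out <- out[ord, ]
  member_sets <- member_sets[ord]
  out <- cbind(cluster = seq_len(nrow(out)), out)
  out$retained <- out$score > min_score
  rownames(out) <- NULL
  attr(out, "member_sets") <- member_sets
  out
}

#' Score of a cluster with given size and edge count
#'
#' MCODE cluster score: graph density times node count,
#' `2E / (V (V - 1)) * V`.
#'
#' @param n_nodes,n_edges cluster size and edge count, or an igraph as
#'   `n_nodes` (then `n_edges` is ignored).
#' @return numeric score.
#' @export
mcode_score <- function(n_nodes, n_edges = NULL) {
  if (inherits(n_nodes, "igraph")) {
    g <- n_nodes
    n_edges <- igraph::ecount(g)
    n_nodes <- igraph::vcount(g)
  }
  if (n_nodes < 2) return(0)
  2 * n_edges / (n_nodes * (n_nodes - 1)) * n_nodes
}

#' Bipartite gene-pathway network
#'
#' One edge per (gene, pathway) membership pair over the retained cluster
#' pathways; genes belonging to no pathway are dropped.
#'
#' @param genes character vector (e.g. the consensus hub genes).
#' @param pathways named list of gene sets (the retained cluster pathways).
#' @return list `edges` (data.frame `gene`, `pathway`), `gene_degree`,
#'   `pathway_degree`, `n_genes`, `n_pathways`.
#' @export
map_gene_pathway <- function(genes, pathways) {
  rows <- list()
  for (p in names(pathways)) {
    hit <- intersect(genes, pathways[[p]])
    if (length(hit)) {
      rows[[p]] <- data.frame(gene = hit, pathway = p, stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(0), pathway = character(0))
  rownames(edges) <- NULL
  gd <- table(factor(edges$gene))
  pd <- table(factor(edges$pathway))
  list(edges = edges,
       gene_degree = stats::setNames(as.integer(gd), names(gd)),
       pathway_degree = stats::setNames(as.integer(pd), names(pd)),
       n_genes = length(gd), n_pathways = length(pd))
}

#' Degree-above-average core of the bipartite network
#'
#' Keeps the nodes whose degree strictly exceeds the mean degree pooled over
#' both sides of the bipartite network, returning genes and pathways
#' separately.
#'
#' @param net a [map_gene_pathway()] result.
#' @return list `genes`, `pathways`, `mean_degree`.
#' @export
select_core <- function(net) {
  degs <- c(net$gene_degree, net$pathway_degree)
  if (length(degs) == 0) stop("select_core needs a non-empty network")
  mu <- mean(degs)
  list(genes = sort(names(net$gene_degree)[net$gene_degree > mu]),
       pathways = sort(names(net$pathway_degree)[net$pathway_degree > mu]),
       mean_degree = mu)
}
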