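# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths (and igraph where the implementation
# uses igraph): distances by Floyd-Warshall, path counts by exhaustive
# simple-path enumeration, cliques by subset enumeration.

# adjacency matrix of a small igraph (undirected, simple)
adj_matrix <- function(g) {
  as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
}

# Floyd-Warshall all-pairs distances on an adjacency matrix
fw_distances <- function(A) {
  n <- nrow(A)
  D <- ifelse(A > 0, 1, Inf)
  diag(D) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      D[i, ] <- pmin(D[i, ], D[i, k] + D[k, ])
    }
  }
  D
}

# enumerate every shortest path between every ordered pair by DFS
all_shortest_paths_brute <- function(A) {
  n <- nrow(A)
  D <- fw_distances(A)
  paths <- vector("list", n * n)
  dim(paths) <- c(n, n)
  dfs <- function(path, target, maxlen) {
    v <- path[length(path)]
    if (v == target) return(list(path))
    if (length(path) > maxlen) return(list())
    out <- list()
    for (w in which(A[v, ] > 0)) {
      if (!(w %in% path) && D[w, target] == maxlen - length(path) - 1) {
        out <- c(out, dfs(c(path, w), target, maxlen))
      }
    }
    out
  }
  for (s in seq_len(n)) {
    for (t in seq_len(n)) {
      if (s == t || is.infinite(D[s, t])) { paths[[s, t]] <- list(); next }
      paths[[s, t]] <- dfs(s, t, D[s, t] + 1)
    }
  }
  paths
}

# brute-force versions of the distance-based centralities; A must be the
# adjacency matrix of a connected graph
brute_centralities <- function(A) {
  n <- nrow(A)
  D <- fw_distances(A)
  paths <- all_shortest_paths_brute(A)
  btw <- stress <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in seq(s + 1, n)) {
      pl <- paths[[s, t]]
      if (length(pl) == 0) next
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        through <- sum(vapply(pl, function(p) v %in% p, logical(1)))
        stress[v] <- stress[v] + through
        btw[v] <- btw[v] + through / length(pl)
      }
    }
  }
  diam <- max(D)
  list(
    Degree = rowSums(A),
    Betweenness = btw,
    Stress = stress,
    Closeness = (n - 1) / rowSums(D),
    EcCentricity = 1 / apply(D, 1, max),
    Radiality = (rowSums(diam + 1 - D) - (diam + 1)) / (n - 1),
    ClusteringCoefficient = vapply(seq_len(n), function(v) {
      nb <- which(A[v, ] > 0)
      k <- length(nb)
      if (k < 2) return(0)
      sum(A[nb, nb]) / 2 / (k * (k - 1) / 2)
    }, numeric(1))
  )
}

# brute-force maximal-clique MCC by subset enumeration (n <= 12)
brute_mcc <- function(A) {
  n <- nrow(A)
  score <- numeric(n)
  is_clique <- function(S) all(A[S, S][upper.tri(matrix(0, length(S), length(S)))] == 1)
  subsets <- lapply(seq_len(2^n - 1), function(mask) which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0))
  for (S in subsets) {
    if (length(S) < 2 || !is_clique(S)) next
    maximal <- all(vapply(setdiff(seq_len(n), S), function(w) {
      !all(A[w, S] == 1)
    }, logical(1)))
    if (maximal) score[S] <- score[S] + factorial(length(S) - 1)
  }
  score
}

# brute-force MNC / DMNC via neighborhood component search without igraph
brute_mnc_dmnc <- function(A) {
  n <- nrow(A)
  mnc <- dmnc <- numeric(n)
  comp_split <- function(S) {
    out <- list()
    left <- S
    while (length(left)) {
      grp <- left[1]
      repeat {
        grow <- setdiff(left[colSums(A[grp, left, drop = FALSE]) > 0], grp)
        if (!length(grow)) break
        grp <- c(grp, grow)
      }
      out[[length(out) + 1]] <- grp
      left <- setdiff(left, grp)
    }
    out
  }
  for (v in seq_len(n)) {
    nb <- which(A[v, ] > 0)
    if (!length(nb)) next
    comps <- comp_split(nb)
    sizes <- lengths(comps)
    big <- comps[[which.max(sizes)]]
    mnc[v] <- max(sizes)
    dmnc[v] <- sum(A[big, big]) / 2 / length(big)^1.7
  }
  list(MNC = mnc, DMNC = dmnc)
}

# brute-force BottleNeck with the declared smallest-index-parent rule
brute_bottleneck <- function(A) {
  n <- nrow(A)
  D <- fw_distances(A)
  bn <- numeric(n)
  for (s in seq_len(n)) {
    parent <- rep(NA_integer_, n)
    for (w in seq_len(n)) {
      if (w == s) next
      parent[w] <- min(which(A[w, ] > 0 & D[s, ] == D[s, w] - 1))
    }
    size <- vapply(seq_len(n), function(v) {
      inside <- function(w) {
        while (!is.na(parent[w])) {
          if (w == v) return(TRUE)
          w <- parent[w]
        }
        w == v
      }
      sum(vapply(seq_len(n), inside, logical(1)))
    }, numeric(1))
    credit <- size > n / 4
    credit[s] <- FALSE
    bn <- bn + credit
  }
  bn
}

# every connected labeled graph on n nodes (n <= 5), as igraphs
all_connected_graphs <- function(n) {
  pairs <- t(utils::combn(n, 2))
  m <- nrow(pairs)
  out <- list()
  for (mask in seq_len(2^m - 1)) {
    sel <- bitwAnd(mask, 2^(seq_len(m) - 1)) > 0
    g <- igraph::graph_from_edgelist(pairs[sel, , drop = FALSE], directed = FALSE)
    g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
    if (igraph::is_connected(g) && igraph::vcount(g) == n) {
      igraph::V(g)$name <- paste0("v", seq_len(n))
      out[[length(out) + 1]] <- g
    }
  }
  out
}

# seeded random connected graph on n nodes
random_connected_graph <- function(n, p = 0.4) {
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::is_connected(g)) {
      igraph::V(g)$name <- paste0("v", seq_len(n))
      return(g)
    }
  }
}

# brute-force upper hypergeometric tail P(X >= k) by pmf summation
brute_hyper_tail <- function(k, K, N, n) {
  if (k <= 0) return(1)
  total <- 0
  for (x in k:min(K, n)) {
    total <- total + choose(K, x) * choose(N - K, n - x) / choose(N, n)
  }
  total
}

# brute-force median-rank tail: exact P(median of k iid uniform{1..m} <= s)
brute_median_rank_tail <- function(s, m, k) {
  grids <- as.matrix(expand.grid(rep(list(seq_len(m)), k)))
  mean(apply(grids, 1, stats::median) <= s)
}

# brute-force seed-site scan by explicit window comparison
brute_seed_scan <- function(utr, site) {
  w <- nchar(site)
  hits <- integer(0)
  if (nchar(utr) < w) return(hits)
  for (i in 0:(nchar(utr) - w)) {
    if (substr(utr, i + 1, i + w) == site) hits <- c(hits, i)
  }
  hits
}
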