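# Independent brute-force oracles used to cross-check the implementation.

# random undirected scored graph as an edge data.frame
random_graph_edges <- function(n_nodes, p_edge, seed) {
  set.seed(seed)
  ids <- sprintf("N%02d", seq_len(n_nodes))
  pairs <- t(combn(ids, 2L))
  take <- runif(nrow(pairs)) < p_edge
  data.frame(protein_a = pairs[take, 1L], protein_b = pairs[take, 2L],
             combined_score = round(runif(sum(take), 0.5, 1), 3),
             stringsAsFactors = FALSE)
}

# BFS-layer enumeration of the network density score, written against the
# defining equation with explicit layer sets and no shared code with the
# package implementation
nds_oracle <- function(edges, node, max_depth = 3L) {
  nodes <- unique(c(edges$protein_a, edges$protein_b, node))
  adj <- setNames(lapply(nodes, function(v) {
    c(edges$protein_b[edges$protein_a == v],
      edges$protein_a[edges$protein_b == v])
  }), nodes)
  score_of <- function(u, v) {
    hit <- (edges$protein_a == u & edges$protein_b == v) |
      (edges$protein_a == v & edges$protein_b == u)
    edges$combined_score[hit][1L]
  }
  deg <- vapply(adj, length, 0L)
  visited <- node
  layer <- node
  total <- deg[[node]]
  for (s in seq_len(max_depth)) {
    next_layer <- sort(setdiff(unique(unlist(adj[layer])), visited))
    for (b in next_layer) {
      parents <- sort(intersect(adj[[b]], layer))
      total <- total + (1 / 2^s) * deg[[b]] * score_of(b, parents[1L])
    }
    visited <- c(visited, next_layer)
    layer <- next_layer
    if (!length(layer)) break
  }
  unname(total)
}

# all-pairs shortest path by repeated relaxation (hop counts)
bfs_dist_oracle <- function(edges, from, to) {
  nodes <- unique(c(edges$protein_a, edges$protein_b, from, to))
  d <- matrix(Inf, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  diag(d) <- 0
  for (i in seq_len(nrow(edges))) {
    d[edges$protein_a[i], edges$protein_b[i]] <- 1
    d[edges$protein_b[i], edges$protein_a[i]] <- 1
  }
  for (k in nodes) for (i in nodes) for (j in nodes)
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d[from, to, drop = FALSE]
}

# exact hypergeometric upper tail by enumeration over overlap counts
hyper_oracle <- function(k, term_size, universe_size, draws) {
  ks <- k:min(term_size, draws)
  sum(choose(term_size, ks) * choose(universe_size - term_size, draws - ks)) /
    choose(universe_size, draws)
}

# exact two-sided rank-sum p-value by permutation enumeration
ranksum_perm_oracle <- function(x, y) {
  all_v <- c(x, y)
  n <- length(x)
  combs <- combn(length(all_v), n)
  w_obs <- sum(rank(all_v)[seq_len(n)]) - n * (n + 1) / 2
  w_all <- apply(combs, 2L, function(idx)
    sum(rank(all_v)[idx]) - n * (n + 1) / 2)
  mu <- length(x) * length(y) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# tiny two-gene expression matrix used across tests
toy_matrix <- function() {
  tpm <- matrix(c(10, 4, 8, 2,
                  3, 2, 1, 5), nrow = 4,
                dimnames = list(c("T1", "T2", "T3", "T4"),
                                c("S1", "S2")))
  expression_matrix(tpm,
                    c(T1 = "G1", T2 = "G1", T3 = "G2", T4 = "G2"),
                    c(T1 = "P1", T2 = "P2", T3 = "P3", T4 = "P4"))
}
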