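#' Build an igraph object from a scored edge table
#'
#' @param edges data.frame with columns `protein_a`, `protein_b`,
#'   `combined_score` ([read_interaction_edges()]); scores must lie in
#'   [0, 1].
#' @param vertices optional character vector of additional (possibly
#'   isolated) vertex ids to include.
#' @return undirected [igraph::igraph] with edge attribute `score`.
#' @export
ppi_graph <- function(edges, vertices = NULL) {
  if (nrow(edges) && (any(edges$combined_score < 0) ||
                      any(edges$combined_score > 1)))
    stop("edge scores must lie in [0, 1]")
  vs <- sort(unique(c(edges$protein_a, edges$protein_b, vertices)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$protein_a, to = edges$protein_b,
               score = edges$combined_score),
    directed = FALSE, vertices = vs)
  g
}

#' Attribute interaction disruptions to cMDT calls
#'
#' Joins cMDT calls to the isoform-specific network: every physical
#' interaction of the gene's canonical protein whose status is `lost` for
#' the called isoform becomes one disruption record in that sample. The
#' per-call summary reports the percentage of interactions lost and flags
#' genes without any network edge as having no PPI data.
#'
#' @param calls cMDT call table ([call_cmdt()]).
#' @param network an `IsoformInteractionNetwork`
#'   ([build_isoform_network()]).
#' @param transcript_to_protein named character vector mapping transcript
#'   ids to isoform protein ids.
#' @return list with `records` (data.frame: `sample_id`, `transcript_id`,
#'   `gene_id`, `partner_protein`, `combined_score`) and `summary`
#'   (data.frame per call: `sample_id`, `transcript_id`, `gene_id`,
#'   `n_lost`, `n_persist`, `percent_lost`, `has_ppi_data`).
#' @export
map_disruptions <- function(calls, network, transcript_to_protein) {
  st <- network$statuses
  records <- list(); summ <- list()
  for (i in seq_len(nrow(calls))) {
    iso <- transcript_to_protein[[calls$transcript_id[i]]]
    rows <- if (is.null(iso) || is.na(iso))
      st[0, , drop = FALSE] else st[st$isoform_id == iso, , drop = FALSE]
    n_lost <- sum(rows$status == "lost")
    n_persist <- sum(rows$status == "persists")
    summ[[i]] <- data.frame(
      sample_id = calls$sample_id[i], transcript_id = calls$transcript_id[i],
      gene_id = calls$gene_id[i], n_lost = n_lost, n_persist = n_persist,
      percent_lost = if (n_lost + n_persist > 0)
        100 * n_lost / (n_lost + n_persist) else NA_real_,
      has_ppi_data = n_lost + n_persist > 0, stringsAsFactors = FALSE)
    if (n_lost > 0L) {
      lost <- rows[rows$status == "lost", , drop = FALSE]
      records[[length(records) + 1L]] <- data.frame(
        sample_id = calls$sample_id[i],
        transcript_id = calls$transcript_id[i], gene_id = calls$gene_id[i],
        protein_id = unname(network$canonical_of[calls$gene_id[i]]),
        partner_protein = lost$partner_protein,
        combined_score = lost$combined_score, stringsAsFactors = FALSE)
    }
  }
  records <- if (length(records)) do.call(rbind, records) else
    data.frame(sample_id = character(), transcript_id = character(),
               gene_id = character(), protein_id = character(),
               partner_protein = character(), combined_score = numeric())
  summary <- if (length(summ)) do.call(rbind, summ) else
    data.frame(sample_id = character(), transcript_id = character(),
               gene_id = character(), n_lost = integer(),
               n_persist = integer(), percent_lost = numeric(),
               has_ppi_data = logical())
  rownames(records) <- rownames(summary) <- NULL
  list(records = records, summary = summary)
}

#' Network density score (NDS) of a protein
#'
#' Measures how densely populated a protein's network neighbourhood is: the
#' protein's own degree plus, for every node first reached at breadth-first
#' depth s (1 to `max_depth`), a contribution of that node's degree, scaled
#' by the confidence score of the edge to its BFS parent and decayed by
#' 1 / 2^s. Each node contributes once, at its shortest depth; when several
#' parents are possible, the lexicographically smallest parent id is used,
#' which makes the score deterministic.
#'
#' @param graph a [ppi_graph()].
#' @param protein_id the protein of interest; must be a graph vertex.
#' @param max_depth neighbourhood radius in hops (default 3).
#' @return non-negative numeric; 0 for an isolated protein.
#' @export
network_density_score <- function(graph, protein_id, max_depth = 3L) {
  vs <- igraph::V(graph)$name
  if (!protein_id %in% vs) stop("protein absent from graph: ", protein_id)
  deg <- igraph::degree(graph)
  # adjacency as named list of neighbor names, edges carry scores
  d <- suppressWarnings(igraph::distances(graph, v = protein_id,
                                          weights = NA))[1L, ]
  total <- deg[[protein_id]]
  for (s in seq_len(max_depth)) {
    layer <- names(d)[is.finite(d) & d == s]
    for (b in layer) {
      nb <- igraph::neighbors(graph, b)$name
      parents <- sort(nb[d[nb] == s - 1L])
      parent <- parents[1L]
      eid <- igraph::get_edge_ids(graph, c(b, parent))
      sc <- igraph::E(graph)$score[eid]
      total <- total + (1 / 2^s) * deg[[b]] * sc
    }
  }
  unname(total)
}

#' NDS for many proteins
#'
#' @inheritParams network_density_score
#' @param protein_ids vertices to score; default all.
#' @return named numeric vector of NDS values.
#' @export
network_density_scores <- function(graph, protein_ids = igraph::V(graph)$name,
                                   max_depth = 3L) {
  vapply(protein_ids, network_density_score, 0, graph = graph,
         max_depth = max_depth)
}

#' Relative rank of NDS values
#'
#' Orders proteins by ascending NDS and assigns each a relative rank position
#' on [0, 1]: (ordinal position - 1) / (N - 1), with ties sharing the mean of
#' their positions.
#'
#' @param nds named numeric vector of NDS values (>= 2 proteins).
#' @return data.frame with `protein_id`, `nds`, `relative_rank`, sorted by
#'   ascending NDS.
#' @export
rank_nds <- function(nds) {
  if (length(nds) < 2L) stop("need at least 2 proteins to rank")
  r <- (rank(nds, ties.method = "average") - 1) / (length(nds) - 1)
  out <- data.frame(protein_id = names(nds), nds = as.numeric(nds),
                    relative_rank = as.numeric(r), stringsAsFactors = FALSE)
  out <- out[order(out$nds, out$protein_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Shortest-path proximity to cancer census genes
#'
#' Multi-source breadth-first search from the census proteins present in the
#' graph; each query's distance is the hop count to the nearest census
#' protein (0 when the query itself is in the census, `Inf` when
#' unreachable).
#'
#' @param graph a [ppi_graph()].
#' @param queries character vector of query protein ids (graph vertices).
#' @param census character vector of census protein ids.
#' @return data.frame with `protein_id`, `distance`,
#'   `nearest_census_gene` (NA when unreachable).
#' @export
census_proximity <- function(graph, queries, census) {
  if (!length(census)) stop("empty census set")
  vs <- igraph::V(graph)$name
  missing <- setdiff(queries, vs)
  if (length(missing))
    stop("query protein(s) absent from graph: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  sources <- intersect(census, vs)
  if (!length(sources)) {
    return(data.frame(protein_id = queries, distance = Inf,
                      nearest_census_gene = NA_character_,
                      stringsAsFactors = FALSE))
  }
  uq <- unique(queries)
  dmat <- igraph::distances(graph, v = sources, to = uq, weights = NA)
  dist <- apply(dmat, 2L, min)
  nearest <- apply(dmat, 2L, function(col) {
    if (!any(is.finite(col))) NA_character_
    else sort(sources[col == min(col)])[1L]
  })
  idx <- match(queries, uq)
  data.frame(protein_id = queries, distance = as.numeric(dist)[idx],
             nearest_census_gene = nearest[idx], stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Random-control comparison of census proximity
#'
#' Compares the census-distance distribution of a query set (typically cMDT
#' proteins) with distances of randomly drawn eligible proteins. Eligible
#' controls are proteins that are expressed (>= `min_tpm` in at least one
#' cohort sample) and whose gene has at least two annotated isoforms, drawn
#' uniformly with replacement under the given seed. Distributions are
#' compared with a two-sided Wilcoxon rank-sum test.
#'
#' @param mat [expression_matrix()] of the cancer cohort.
#' @param graph a [ppi_graph()].
#' @param census character vector of census protein ids.
#' @param queries character vector of query protein ids.
#' @param n_draws number of random control draws (> 0).
#' @param seed integer seed for the draws.
#' @param min_tpm expression floor for eligibility (default 2 TPM).
#' @return list with `query_distances`, `control_distances` (numeric,
#'   unreachable queries dropped) and `p_value`.
#' @export
proximity_control <- function(mat, graph, census, queries, n_draws, seed,
                              min_tpm = 2) {
  if (n_draws <= 0L) stop("n_draws must be positive")
  gene <- mat$transcript_to_gene
  iso_count <- table(gene)
  multi_iso <- names(iso_count)[iso_count >= 2L]
  expressed <- rownames(mat$tpm)[apply(mat$tpm >= min_tpm, 1L, any)]
  elig_tx <- expressed[gene[expressed] %in% multi_iso]
  elig <- unique(stats::na.omit(mat$transcript_to_protein[elig_tx]))
  elig <- intersect(elig, igraph::V(graph)$name)
  if (!length(elig)) stop("no eligible control proteins")
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  draws <- sample(elig, n_draws, replace = TRUE)
  qd <- census_proximity(graph, queries, census)$distance
  cd <- census_proximity(graph, draws, census)$distance
  qd <- qd[is.finite(qd)]; cd <- cd[is.finite(cd)]
  p <- if (length(qd) && length(cd))
    suppressWarnings(stats::wilcox.test(qd, cd)$p.value) else NA_real_
  list(query_distances = qd, control_distances = cd, p_value = p)
}

# hypergeometric upper tail: P(overlap >= k) drawing `draws` from a universe
# with `term_size` successes
.hyper_upper <- function(k, term_size, universe_size, draws) {
  stats::phyper(k - 1L, term_size, universe_size - term_size, draws,
                lower.tail = FALSE)
}

#' Enrichment of disrupted subnetworks in gene sets
#'
#' The disrupted interactions of one sample form a graph whose connected
#' components are the disrupted subnetworks. Each component is tested for
#' enrichment of every gene set by a hypergeometric upper-tail test against
#' the proteins of the isoform-specific network as the universe; p-values
#' are BH-adjusted across the terms of a component and only the most
#' significant term is retained per component (ties broken by the
#' lexicographically smallest term id). Components with no protein in the
#' universe are skipped.
#'
#' @param records disruption records of one sample
#'   ([map_disruptions()]`$records`).
#' @param gene_sets named list of protein-id sets ([read_gmt()]).
#' @param universe character vector of background protein ids (all proteins
#'   of the isoform-specific network).
#' @return data.frame with one row per component: `sample_id`,
#'   `component_id`, `term_id`, `overlap`, `component_size`, `term_size`,
#'   `universe_size`, `p_value`, `q_value`.
#' @export
enrich_components <- function(records, gene_sets, universe) {
  if (nrow(records) == 0L) stop("no disruption records")
  universe <- unique(universe)
  sets <- lapply(gene_sets, intersect, y = universe)
  # the disrupted gene enters the subnetwork through its canonical protein
  g <- igraph::graph_from_data_frame(
    data.frame(from = records$protein_id, to = records$partner_protein),
    directed = FALSE)
  comp <- igraph::components(g)
  out <- list()
  for (ci in seq_len(comp$no)) {
    members <- names(comp$membership)[comp$membership == ci]
    in_univ <- intersect(members, universe)
    if (!length(in_univ)) {
      message("component ", ci, " has no protein in universe; skipped")
      next
    }
    k <- vapply(sets, function(s) length(intersect(s, in_univ)), 0L)
    m <- vapply(sets, length, 0L)
    p <- mapply(.hyper_upper, k, m,
                MoreArgs = list(universe_size = length(universe),
                                draws = length(in_univ)))
    q <- stats::p.adjust(p, method = "BH")
    ord <- order(q, p, names(sets))
    best <- ord[1L]
    out[[length(out) + 1L]] <- data.frame(
      sample_id = records$sample_id[1L], component_id = ci,
      term_id = names(sets)[best], overlap = k[[best]],
      component_size = length(in_univ), term_size = m[[best]],
      universe_size = length(universe), p_value = p[[best]],
      q_value = q[[best]], stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(sample_id = character(), component_id = integer(),
               term_id = character(), overlap = integer(),
               component_size = integer(), term_size = integer(),
               universe_size = integer(), p_value = numeric(),
               q_value = numeric())
  rownames(res) <- NULL
  res
}
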