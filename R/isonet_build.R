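#' Retain proteins whose sequences agree between two sources
#'
#' Cross-checks the protein sequences backing the interaction network against
#' an independent annotation source: a protein is retained only when it is
#' present in both sources with a byte-identical sequence. Mismatching or
#' network-only proteins are discarded (their count is reported).
#'
#' @param network_seqs named character vector of sequences used by the
#'   interaction network.
#' @param annotation_seqs named character vector from the annotation source.
#' @return character vector of retained protein ids.
#' @export
verify_sequence_identity <- function(network_seqs, annotation_seqs) {
  shared <- intersect(names(network_seqs), names(annotation_seqs))
  retained <- shared[network_seqs[shared] == annotation_seqs[shared]]
  n_drop <- length(network_seqs) - length(retained)
  if (n_drop > 0L)
    message("discarded ", n_drop,
            " protein(s) absent or non-identical in annotation source")
  retained
}

#' Flag physical edges by interacting domain pairs
#'
#' A functional edge is considered physical when its two proteins carry
#' domain instances whose family pair is a known physical domain-domain
#' interaction. All supporting instance pairs are recorded per edge, in both
#' family orientations.
#'
#' @param edges data.frame from [read_interaction_edges()].
#' @param domains data.frame from [read_domain_table()].
#' @param ddi data.frame of unordered domain family pairs
#'   ([read_ddi_table()]).
#' @return `edges` with added columns `physical` (logical) and
#'   `domain_pairs` (list column; each element a data.frame with columns
#'   `instance_a`, `instance_b` of domain-instance ids on protein_a /
#'   protein_b).
#' @export
annotate_physical_edges <- function(edges, domains, ddi) {
  ddi_key <- unique(paste(pmin(ddi$domain_a, ddi$domain_b),
                          pmax(ddi$domain_a, ddi$domain_b), sep = "\r"))
  by_protein <- split(domains, domains$protein_id)
  pairs <- vector("list", nrow(edges))
  for (i in seq_len(nrow(edges))) {
    da <- by_protein[[edges$protein_a[i]]]
    db <- by_protein[[edges$protein_b[i]]]
    if (is.null(da) || is.null(db)) {
      pairs[[i]] <- data.frame(instance_a = character(),
                               instance_b = character())
      next
    }
    grid <- expand.grid(ia = seq_len(nrow(da)), ib = seq_len(nrow(db)))
    key <- paste(pmin(da$domain_id[grid$ia], db$domain_id[grid$ib]),
                 pmax(da$domain_id[grid$ia], db$domain_id[grid$ib]),
                 sep = "\r")
    hit <- key %in% ddi_key
    pairs[[i]] <- data.frame(instance_a = da$instance_id[grid$ia[hit]],
                             instance_b = db$instance_id[grid$ib[hit]],
                             stringsAsFactors = FALSE)
  }
  edges$physical <- vapply(pairs, nrow, 0L) > 0L
  edges$domain_pairs <- pairs
  edges
}

#' Assess whether one isoform keeps one physical interaction
#'
#' The canonical isoform interacts through specific domain instances; the
#' interaction is assumed to persist in an alternative isoform when the exact
#' amino-acid sequence of at least one supporting instance (on the isoform's
#' side of the edge) occurs verbatim in the isoform sequence, and to be lost
#' otherwise. Matching is exact substring presence, no alignment.
#'
#' @param isoform_sequence amino-acid string of the alternative isoform.
#' @param edge a single-row slice of an annotated edge table
#'   ([annotate_physical_edges()]).
#' @param side `"a"` or `"b"`: which endpoint the isoform's gene occupies.
#' @param domains domain table ([read_domain_table()]), used to look up
#'   instance sequences.
#' @return list with `status` (`"persists"` or `"lost"`),
#'   `supporting_domains`, `matched_domains` (character vectors of instance
#'   ids).
#' @export
assess_isoform_interaction <- function(isoform_sequence, edge, side,
                                       domains) {
  dp <- edge$domain_pairs[[1L]]
  if (is.null(dp) || nrow(dp) == 0L) stop("no domain evidence")
  side <- match.arg(side, c("a", "b"))
  supporting <- unique(if (side == "a") dp$instance_a else dp$instance_b)
  seqs <- domains$sequence[match(supporting, domains$instance_id)]
  matched <- supporting[vapply(seqs, grepl, TRUE, x = isoform_sequence,
                               fixed = TRUE)]
  list(status = if (length(matched)) "persists" else "lost",
       supporting_domains = supporting, matched_domains = matched)
}

#' Build the isoform-specific interaction network
#'
#' For every alternative isoform of every gene with a retained canonical
#' protein, decides which of the canonical protein's physical interactions
#' persist in that isoform and which are lost. Canonical isoforms persist by
#' definition for all their edges.
#'
#' @param retained character vector of retained protein ids
#'   ([verify_sequence_identity()]).
#' @param edges annotated edge table ([annotate_physical_edges()]).
#' @param domains domain table ([read_domain_table()]).
#' @param isoforms named character vector of protein sequences for all
#'   isoforms (canonical and alternative).
#' @param protein_to_gene named character vector mapping every isoform
#'   protein id to its gene id.
#' @param canonical_of named character vector mapping gene id to canonical
#'   protein id.
#' @return object of class `IsoformInteractionNetwork`: list with `edges`
#'   (the annotated edge table), `statuses` (data.frame: `isoform_id`,
#'   `gene_id`, `partner_protein`, `status`, `supporting_domains`,
#'   `matched_domains`; instance ids `;`-joined), `canonical_of`, and
#'   `skipped_genes` (genes whose canonical protein was not retained).
#' @export
build_isoform_network <- function(retained, edges, domains, isoforms,
                                  protein_to_gene, canonical_of) {
  stopifnot(is.character(isoforms), !is.null(names(isoforms)))
  phys <- edges[edges$physical, , drop = FALSE]
  skipped <- names(canonical_of)[!(canonical_of %in% retained)]
  if (length(skipped))
    message("skipping ", length(skipped),
            " gene(s) without a retained canonical protein")

  rows <- list()
  for (g in setdiff(names(canonical_of), skipped)) {
    canon <- canonical_of[[g]]
    on_a <- which(phys$protein_a == canon)
    on_b <- which(phys$protein_b == canon)
    if (!length(on_a) && !length(on_b)) next
    members <- names(protein_to_gene)[protein_to_gene == g]
    for (iso in members) {
      is_canon <- identical(iso, canon)
      for (i in c(on_a, on_b)) {
        side <- if (i %in% on_a) "a" else "b"
        partner <- if (side == "a") phys$protein_b[i] else phys$protein_a[i]
        st <- assess_isoform_interaction(isoforms[[iso]], phys[i, ], side,
                                         domains)
        if (is_canon && st$status != "persists")
          stop("canonical isoform ", iso, " fails its own domain sequences")
        rows[[length(rows) + 1L]] <- data.frame(
          isoform_id = iso, gene_id = g, partner_protein = partner,
          status = st$status, combined_score = phys$combined_score[i],
          supporting_domains = paste(st$supporting_domains, collapse = ";"),
          matched_domains = paste(st$matched_domains, collapse = ";"),
          stringsAsFactors = FALSE)
      }
    }
  }
  statuses <- if (length(rows)) do.call(rbind, rows) else
    data.frame(isoform_id = character(), gene_id = character(),
               partner_protein = character(), status = character(),
               combined_score = numeric(), supporting_domains = character(),
               matched_domains = character())
  statuses <- statuses[order(statuses$isoform_id,
                             statuses$partner_protein), , drop = FALSE]
  rownames(statuses) <- NULL
  structure(list(edges = edges, statuses = statuses,
                 canonical_of = canonical_of, skipped_genes = skipped),
            class = "IsoformInteractionNetwork")
}

#' @export
print.IsoformInteractionNetwork <- function(x, ...) {
  cat(sprintf(paste0("IsoformInteractionNetwork: %d edges (%d physical), ",
                     "%d isoform-interaction statuses (%d lost)\n"),
              nrow(x$edges), sum(x$edges$physical), nrow(x$statuses),
              sum(x$statuses$status == "lost")))
  invisible(x)
}

#' Export the isoform interaction status table as TSV
#'
#' @param network an `IsoformInteractionNetwork`.
#' @param path output TSV path.
#' @export
write_isoform_network <- function(network, path) {
  utils::write.table(network$statuses, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
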