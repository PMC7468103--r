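AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Configuration of the synthetic toy world
#'
#' Collects every tunable of the generator in one validated object. The
#' defaults describe the standard toy study: 50 genes with 2-3 isoforms
#' each, a 10-sample tumor cohort against a 20-sample matched normal cohort,
#' a fifth of the genes carrying a planted cancer-specific dominance switch
#' with a relative-expression gap of 0.6 between cohorts, and moderate
#' lognormal abundance noise.
#'
#' @param n_genes number of genes.
#' @param isoforms_per_gene integer vector of possible isoform counts per
#'   gene (sampled uniformly).
#' @param n_tumor,n_normal cohort sizes.
#' @param switch_fraction fraction of genes with a planted switch.
#' @param rel_expr_gap separation between the switch transcript's relative
#'   expression in tumors and in normals; must exceed 1/3 so that the
#'   planted transcript clears the two-fold dominance rule in expectation.
#' @param noise_sd standard deviation of the lognormal TPM noise (log
#'   scale).
#' @param edge_density probability that an unordered pair of canonical
#'   proteins is connected by a physical interaction.
#' @param domain_length integer length-2 vector, range of domain lengths in
#'   residues.
#' @param n_assoc_genes number of genes with a planted cis-mutation
#'   expression association.
#' @param assoc_fold expression fold change planted in mutated samples.
#' @param seed integer seed fixing every draw.
#' @return list of class `SyntheticConfig`.
#' @export
synthetic_config <- function(n_genes = 50L, isoforms_per_gene = 2:3,
                             n_tumor = 10L, n_normal = 20L,
                             switch_fraction = 0.2, rel_expr_gap = 0.6,
                             noise_sd = 0.25, edge_density = 0.04,
                             domain_length = c(8L, 15L),
                             n_assoc_genes = 3L, assoc_fold = 10,
                             seed = 42L) {
  stopifnot(n_genes >= 2L, n_tumor >= 1L, n_normal >= 1L,
            switch_fraction >= 0, switch_fraction <= 1,
            rel_expr_gap >= 0, rel_expr_gap < 1, noise_sd >= 0,
            edge_density >= 0, edge_density <= 1,
            length(domain_length) == 2L, all(isoforms_per_gene >= 1L))
  if (switch_fraction > 0 && rel_expr_gap <= 1 / 3)
    stop("infeasible config: rel_expr_gap must exceed 1/3 for planted ",
         "switches to clear the two-fold dominance rule")
  if (switch_fraction > 0 && noise_sd > rel_expr_gap)
    stop("infeasible config: noise_sd exceeds rel_expr_gap; planted ",
         "switches would not be recoverable")
  structure(list(n_genes = as.integer(n_genes),
                 isoforms_per_gene = as.integer(isoforms_per_gene),
                 n_tumor = as.integer(n_tumor),
                 n_normal = as.integer(n_normal),
                 switch_fraction = switch_fraction,
                 rel_expr_gap = rel_expr_gap, noise_sd = noise_sd,
                 edge_density = edge_density,
                 domain_length = as.integer(domain_length),
                 n_assoc_genes = as.integer(n_assoc_genes),
                 assoc_fold = assoc_fold, seed = as.integer(seed)),
            class = "SyntheticConfig")
}

.rand_aa <- function(n) paste(sample(AA_ALPHABET, n, replace = TRUE),
                              collapse = "")

#' Generate a self-contained synthetic world with known ground truth
#'
#' Emits a toy proteome (canonical and alternative isoform sequences),
#' domain annotations, physical domain-pair table, scored interaction edge
#' list, tumor and normal TPM cohorts with planted cancer-specific
#' dominance switches, a mutation table with functional regions, a census
#' list and pathway gene sets, plus truth tables for every planted signal.
#' Alternative isoforms are canonical sequences with whole-domain (or
#' inert-linker) deletions, so interaction persistence outcomes are known
#' exactly; planted switch genes have the alternative transcript dominant in
#' tumors and the canonical transcript dominant in normals.
#'
#' @param config a [synthetic_config()].
#' @param dir output directory for the standard-format files (created if
#'   needed); `NULL` generates the world in memory only.
#' @return (invisibly when writing) list with the in-memory world: `config`,
#'   `genes`, `canonical_of`, `transcript_to_gene`, `transcript_to_protein`,
#'   `sequences` (all isoform proteins), `network_sequences`, `domains`,
#'   `ddi`, `edges` (score on 0-1, high-confidence only), `tumor`, `normal`
#'   ([expression_matrix()]s), `cohort` ([cohort_pair()]), `mutations`
#'   (variant-level table), `census` (protein ids), `gene_sets`, `truth`
#'   (list of data.frames: `switches`, `cmdt`, `lost_edges`,
#'   `associations`), and `paths` when files were written.
#' @export
generate_world <- function(config = synthetic_config(), dir = NULL) {
  stopifnot(inherits(config, "SyntheticConfig"))
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(config$seed)

  ng <- config$n_genes
  genes <- sprintf("G%03d", seq_len(ng))
  n_iso <- sample(config$isoforms_per_gene, ng, replace = TRUE)
  n_switch <- round(config$switch_fraction * ng)
  switch_genes <- if (n_switch > 0) sort(sample(genes, n_switch)) else
    character()
  # switch genes need an alternative isoform
  n_iso[genes %in% switch_genes] <- pmax(n_iso[genes %in% switch_genes], 2L)

  tx_gene <- rep(genes, n_iso)
  tx_idx <- unlist(lapply(n_iso, seq_len))
  transcripts <- sprintf("T%s.%d", sub("^G", "", tx_gene), tx_idx)
  proteins <- sprintf("P%s.%d", sub("^G", "", tx_gene), tx_idx)
  t2g <- stats::setNames(tx_gene, transcripts)
  t2p <- stats::setNames(proteins, transcripts)
  canonical_of <- stats::setNames(
    proteins[tx_idx == 1L][match(genes, tx_gene[tx_idx == 1L])], genes)

  ## --- physical edge skeleton between canonical proteins ----------------
  pairs <- utils::combn(genes, 2L)
  take <- stats::runif(ncol(pairs)) < config$edge_density
  edge_genes <- pairs[, take, drop = FALSE]
  # guarantee every switch gene at least one physical edge
  covered <- unique(c(edge_genes[1L, ], edge_genes[2L, ]))
  for (g in switch_genes) {
    if (g %in% covered) next
    partner <- sample(setdiff(genes, g), 1L)
    edge_genes <- cbind(edge_genes, c(g, partner))
    covered <- unique(c(covered, g, partner))
  }
  n_edge <- ncol(edge_genes)

  ## --- domains: one fresh interacting family pair per physical edge -----
  dom_len <- function() sample(seq(config$domain_length[1L],
                                   config$domain_length[2L]), 1L)
  dom_rows <- list(); ddi_rows <- list()
  dom_seqs <- character()
  new_domain_seq <- function() {
    repeat {
      s <- .rand_aa(dom_len())
      if (!s %in% dom_seqs) return(s)
    }
  }
  for (e in seq_len(n_edge)) {
    fam_a <- sprintf("DOM%04dA", e); fam_b <- sprintf("DOM%04dB", e)
    sa <- new_domain_seq(); sb <- new_domain_seq()
    dom_seqs <- c(dom_seqs, sa, sb)
    dom_rows[[length(dom_rows) + 1L]] <-
      data.frame(gene = edge_genes[1L, e], domain_id = fam_a, sequence = sa,
                 stringsAsFactors = FALSE)
    dom_rows[[length(dom_rows) + 1L]] <-
      data.frame(gene = edge_genes[2L, e], domain_id = fam_b, sequence = sb,
                 stringsAsFactors = FALSE)
    ddi_rows[[length(ddi_rows) + 1L]] <-
      data.frame(domain_a = fam_a, domain_b = fam_b,
                 stringsAsFactors = FALSE)
  }
  # one inert (non-interacting) domain on every gene, deletable without
  # edge loss
  for (g in genes) {
    s <- new_domain_seq(); dom_seqs <- c(dom_seqs, s)
    dom_rows[[length(dom_rows) + 1L]] <-
      data.frame(gene = g, domain_id = sprintf("INERT%s", sub("^G", "", g)),
                 sequence = s, stringsAsFactors = FALSE)
  }
  dom_df <- do.call(rbind, dom_rows)

  ## --- canonical sequences: linkers interleaved with domain instances ---
  canon_seq <- character(0)
  dom_pos <- list()   # per gene: data.frame(domain_id, start, end, sequence)
  for (g in genes) {
    dg <- dom_df[dom_df$gene == g, , drop = FALSE]
    dg <- dg[sample(nrow(dg)), , drop = FALSE]
    seqv <- .rand_aa(sample(20:40, 1L))
    rows <- list()
    for (j in seq_len(nrow(dg))) {
      start <- nchar(seqv) + 1L
      seqv <- paste0(seqv, dg$sequence[j])
      rows[[j]] <- data.frame(domain_id = dg$domain_id[j], start = start,
                              end = nchar(seqv), sequence = dg$sequence[j],
                              stringsAsFactors = FALSE)
      seqv <- paste0(seqv, .rand_aa(sample(15:30, 1L)))
    }
    canon_seq[canonical_of[[g]]] <- seqv
    dom_pos[[g]] <- do.call(rbind, rows)
  }

  ## --- alternative isoforms: whole-domain or linker deletions -----------
  # edge-supporting family on each gene's side, by edge index
  side_fam <- function(g) {
    fams <- character()
    for (e in seq_len(n_edge)) {
      if (edge_genes[1L, e] == g) fams <- c(fams, sprintf("DOM%04dA", e))
      if (edge_genes[2L, e] == g) fams <- c(fams, sprintf("DOM%04dB", e))
    }
    fams
  }
  sequences <- canon_seq
  deleted_fams <- stats::setNames(vector("list", length(proteins)), proteins)
  for (k in seq_along(transcripts)) {
    if (tx_idx[k] == 1L) next
    g <- tx_gene[k]
    pos <- dom_pos[[g]]
    interacting <- side_fam(g)
    is_switch_iso <- g %in% switch_genes && tx_idx[k] == 2L
    cand <- if (is_switch_iso) intersect(pos$domain_id, interacting)
    else setdiff(pos$domain_id, interacting)
    if (is_switch_iso) {
      n_del <- sample(seq_along(cand), 1L)
      del <- sample(cand, n_del)
    } else if (length(cand)) {
      del <- sample(cand, 1L)
    } else del <- character()
    keep <- pos[!pos$domain_id %in% del, , drop = FALSE]
    if (length(del)) {
      spans <- pos[pos$domain_id %in% del, , drop = FALSE]
      spans <- spans[order(spans$start), , drop = FALSE]
      full <- canon_seq[[canonical_of[[g]]]]
      keep_mask <- rep(TRUE, nchar(full))
      for (j in seq_len(nrow(spans)))
        keep_mask[spans$start[j]:spans$end[j]] <- FALSE
      iso_seq <- paste(strsplit(full, "")[[1L]][keep_mask], collapse = "")
    } else {
      iso_seq <- canon_seq[[canonical_of[[g]]]]
    }
    # deleted domain sequences must be genuinely absent from the isoform
    for (ds in pos$sequence[pos$domain_id %in% del])
      if (grepl(ds, iso_seq, fixed = TRUE))
        stop("domain sequence collision in generator; use another seed")
    sequences[proteins[k]] <- iso_seq
    deleted_fams[[proteins[k]]] <- del
  }

  ## --- edge table with scores (0-999 dialect) and truth lost edges ------
  hi_score <- sample(900:999, n_edge, replace = TRUE)
  edges_out <- data.frame(protein_a = canonical_of[edge_genes[1L, ]],
                          protein_b = canonical_of[edge_genes[2L, ]],
                          combined_score = hi_score,
                          stringsAsFactors = FALSE)
  # low-confidence decoy rows, excluded by the score filter at load
  n_low <- max(2L, round(n_edge / 4))
  low_pairs <- pairs[, sample(ncol(pairs), n_low), drop = FALSE]
  edges_out <- rbind(edges_out, data.frame(
    protein_a = canonical_of[low_pairs[1L, ]],
    protein_b = canonical_of[low_pairs[2L, ]],
    combined_score = sample(100:899, n_low, replace = TRUE),
    stringsAsFactors = FALSE))
  rownames(edges_out) <- NULL

  lost_rows <- list()
  for (k in seq_along(transcripts)) {
    if (tx_idx[k] == 1L) next
    del <- deleted_fams[[proteins[k]]]
    if (!length(del)) next
    g <- tx_gene[k]
    for (e in seq_len(n_edge)) {
      fam <- if (edge_genes[1L, e] == g) sprintf("DOM%04dA", e)
      else if (edge_genes[2L, e] == g) sprintf("DOM%04dB", e)
      else next
      if (fam %in% del) {
        partner_gene <- setdiff(edge_genes[, e], g)
        lost_rows[[length(lost_rows) + 1L]] <- data.frame(
          isoform_id = proteins[k], gene_id = g,
          partner_protein = canonical_of[[partner_gene]],
          stringsAsFactors = FALSE)
      }
    }
  }
  truth_lost <- if (length(lost_rows)) do.call(rbind, lost_rows) else
    data.frame(isoform_id = character(), gene_id = character(),
               partner_protein = character())
  truth_lost <- truth_lost[order(truth_lost$isoform_id,
                                 truth_lost$partner_protein), , drop = FALSE]
  rownames(truth_lost) <- NULL

  ## --- expression cohorts ----------------------------------------------
  tumor_samples <- sprintf("Tumor%02d", seq_len(config$n_tumor))
  normal_samples <- sprintf("Normal%02d", seq_len(config$n_normal))
  gap <- config$rel_expr_gap
  rel_lo <- (1 - gap) / 2   # switch transcript share in normals
  rel_hi <- (1 + gap) / 2   # switch transcript share in tumors

  # isoform proportions for one gene: the dominant isoform takes
  # `dominant_share`; when the canonical (index 1) is not dominant it takes
  # 90% of the remaining mass, minor isoforms split what is left
  base_props <- function(k, dominant_idx, dominant_share) {
    p <- numeric(k)
    p[dominant_idx] <- dominant_share
    rest <- setdiff(seq_len(k), dominant_idx)
    rem <- 1 - dominant_share
    if (length(rest)) {
      if (1L %in% rest) {
        others <- setdiff(rest, 1L)
        p[1L] <- if (length(others)) rem * 0.9 else rem
        if (length(others)) p[others] <- rem * 0.1 / length(others)
      } else {
        p[rest] <- rem / length(rest)
      }
    }
    p
  }

  gene_level <- stats::setNames(stats::rlnorm(ng, log(100), 0.5), genes)
  make_matrix <- function(samples, tumor) {
    m <- matrix(0, nrow = length(transcripts), ncol = length(samples),
                dimnames = list(transcripts, samples))
    for (gi in seq_len(ng)) {
      g <- genes[gi]; k <- n_iso[gi]
      rows <- which(tx_gene == g)
      is_sw <- g %in% switch_genes
      props <- if (is_sw && tumor) base_props(k, 2L, rel_hi)
      else if (is_sw) base_props(k, 2L, rel_lo)
      else base_props(k, 1L, 0.8)
      noise <- matrix(stats::rlnorm(k * length(samples), 0,
                                    config$noise_sd), nrow = k)
      m[rows, ] <- gene_level[[g]] * props * noise
    }
    m
  }
  to_tpm <- function(m) sweep(m, 2L, colSums(m), "/") * 1e6
  tumor_tpm <- make_matrix(tumor_samples, TRUE)
  normal_tpm <- to_tpm(make_matrix(normal_samples, FALSE))

  ## --- planted cis-mutation associations and variant table --------------
  non_switch <- setdiff(genes, switch_genes)
  assoc_genes <- if (config$n_assoc_genes > 0 && length(non_switch))
    sort(sample(non_switch, min(config$n_assoc_genes,
                                length(non_switch)))) else character()
  n_mut <- max(6L, floor(config$n_tumor / 2))
  n_mut <- min(n_mut, config$n_tumor)
  assoc_rows <- list(); var_rows <- list()
  locus_start <- stats::setNames((seq_len(ng) - 1L) * 1000L, genes)
  region_layout <- data.frame(
    off_start = c(0L, 100L, 300L, 400L, 700L, 720L),
    off_end = c(100L, 300L, 400L, 700L, 720L, 900L),
    region_class = c("promoter_core", "promoter_domain", "utr5", "cds",
                     "splice_site", "utr3"), stringsAsFactors = FALSE)
  for (g in assoc_genes) {
    mut_samples <- sort(sample(tumor_samples, n_mut))
    rows <- which(tx_gene == g)
    tumor_tpm[rows, mut_samples] <- tumor_tpm[rows, mut_samples] *
      config$assoc_fold
    for (s in mut_samples) {
      # one cds SNV per mutated sample
      pos <- locus_start[[g]] + sample(401:700, 1L)
      var_rows[[length(var_rows) + 1L]] <- data.frame(
        sample_id = s, chrom = "chr1", pos = pos,
        ref = sample(c("A", "C", "G", "T"), 1L),
        alt = sample(c("A", "C", "G", "T"), 1L), stringsAsFactors = FALSE)
    }
    assoc_rows[[length(assoc_rows) + 1L]] <- data.frame(
      gene_id = g, transcript_id = transcripts[rows],
      n_mutated = n_mut, fold = config$assoc_fold,
      mutated_samples = paste(mut_samples, collapse = ";"),
      stringsAsFactors = FALSE)
  }
  # background variants: some in functional regions of random genes, some
  # intergenic (discarded at load), one adjacent SNV pair (merged to MNV)
  n_bg <- 3L * config$n_tumor
  for (i in seq_len(n_bg)) {
    g <- sample(genes, 1L)
    var_rows[[length(var_rows) + 1L]] <- data.frame(
      sample_id = sample(tumor_samples, 1L), chrom = "chr1",
      pos = locus_start[[g]] + sample(1:1000, 1L),
      ref = sample(c("A", "C", "G", "T"), 1L),
      alt = sample(c("A", "C", "G", "T"), 1L), stringsAsFactors = FALSE)
  }
  mnv_gene <- genes[1L]
  var_rows[[length(var_rows) + 1L]] <- data.frame(
    sample_id = tumor_samples[1L], chrom = "chr1",
    pos = locus_start[[mnv_gene]] + 450L, ref = "A", alt = "G",
    stringsAsFactors = FALSE)
  var_rows[[length(var_rows) + 1L]] <- data.frame(
    sample_id = tumor_samples[1L], chrom = "chr1",
    pos = locus_start[[mnv_gene]] + 451L, ref = "C", alt = "T",
    stringsAsFactors = FALSE)
  variants <- do.call(rbind, var_rows)
  variants <- variants[order(variants$sample_id, variants$pos), ,
                       drop = FALSE]
  rownames(variants) <- NULL
  # planted fold changes are applied before TPM renormalization so column
  # sums keep TPM semantics
  tumor_tpm <- to_tpm(tumor_tpm)

  regions <- do.call(rbind, lapply(genes, function(g) {
    data.frame(chrom = "chr1",
               start = locus_start[[g]] + region_layout$off_start,
               end = locus_start[[g]] + region_layout$off_end,
               gene_id = g, region_class = region_layout$region_class,
               stringsAsFactors = FALSE)
  }))

  ## --- census and gene sets ---------------------------------------------
  switch_partners <- unique(unlist(lapply(switch_genes, function(g) {
    hits <- edge_genes[1L, ] == g | edge_genes[2L, ] == g
    setdiff(as.vector(edge_genes[, hits, drop = FALSE]), g)
  })))
  n_census <- max(3L, round(0.1 * ng))
  census_genes <- unique(c(utils::head(switch_partners, n_census),
                           sample(genes, n_census)))
  census <- unname(canonical_of[census_genes])
  n_terms <- 5L
  term_of <- sample(seq_len(n_terms), ng, replace = TRUE)
  gene_sets <- lapply(seq_len(n_terms), function(ti)
    unname(canonical_of[genes[term_of == ti]]))
  names(gene_sets) <- sprintf("TERM%02d", seq_len(n_terms))
  gene_sets <- gene_sets[vapply(gene_sets, length, 0L) > 0L]

  ## --- assemble ----------------------------------------------------------
  tumor_mat <- expression_matrix(tumor_tpm, t2g, t2p)
  normal_mat <- expression_matrix(normal_tpm, t2g, t2p)
  cohort <- cohort_pair("ToyCancer", tumor_samples, "ToyTissue",
                        normal_samples)
  domains_tab <- do.call(rbind, lapply(genes, function(g) {
    pos <- dom_pos[[g]]
    data.frame(protein_id = canonical_of[[g]], domain_id = pos$domain_id,
               start = pos$start, end = pos$end, stringsAsFactors = FALSE)
  }))
  ddi <- unique(do.call(rbind, ddi_rows))
  switch_tx <- transcripts[tx_gene %in% switch_genes & tx_idx == 2L]
  truth_switches <- data.frame(
    gene_id = tx_gene[match(switch_tx, transcripts)],
    transcript_id = switch_tx,
    canonical_transcript = transcripts[match(
      tx_gene[match(switch_tx, transcripts)], tx_gene)],
    stringsAsFactors = FALSE)
  truth_cmdt <- if (length(switch_tx))
    data.frame(sample_id = rep(tumor_samples, each = length(switch_tx)),
               gene_id = rep(truth_switches$gene_id, config$n_tumor),
               transcript_id = rep(switch_tx, config$n_tumor),
               stringsAsFactors = FALSE)
  else data.frame(sample_id = character(), gene_id = character(),
                  transcript_id = character())
  truth_assoc <- if (length(assoc_rows)) do.call(rbind, assoc_rows) else
    data.frame(gene_id = character(), transcript_id = character(),
               n_mutated = integer(), fold = numeric(),
               mutated_samples = character())

  world <- list(config = config, genes = genes, canonical_of = canonical_of,
                transcript_to_gene = t2g, transcript_to_protein = t2p,
                sequences = sequences, network_sequences = canon_seq,
                domains = domains_tab, ddi = ddi, edges_raw = edges_out,
                tumor = tumor_mat, normal = normal_mat, cohort = cohort,
                variants = variants, regions = regions, census = census,
                gene_sets = gene_sets,
                truth = list(switches = truth_switches, cmdt = truth_cmdt,
                             lost_edges = truth_lost,
                             associations = truth_assoc))

  if (is.null(dir)) return(world)

  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  tsv <- function(df, path) utils::write.table(df, path, sep = "\t",
                                               quote = FALSE,
                                               row.names = FALSE)
  # annotation FASTA: every isoform; network FASTA: canonical sequences
  # plus one decoy that disagrees, exercising the identity filter
  write_protein_fasta(sequences, p("proteome.fasta"))
  decoy <- c(canon_seq, DECOY0 = .rand_aa(60L))
  write_protein_fasta(decoy, p("network_proteins.fasta"))
  tsv(domains_tab, p("domains.tsv"))
  tsv(ddi, p("ddi.tsv"))
  tsv(edges_out, p("edges.tsv"))
  write_expression_matrix(tumor_mat, p("expression_tumor.tsv"))
  write_expression_matrix(normal_mat, p("expression_normal.tsv"))
  id_maps <- data.frame(transcript_id = transcripts, gene_id = tx_gene,
                        protein_id = proteins, stringsAsFactors = FALSE)
  tsv(id_maps, p("id_maps.tsv"))
  tsv(variants, p("variants.tsv"))
  tsv(regions, p("regions.bed"))
  write_gmt(list(cancer_census = census), p("census.gmt"))
  write_gmt(gene_sets, p("gene_sets.gmt"))
  tsv(truth_switches, p("truth", "switches.tsv"))
  tsv(truth_cmdt, p("truth", "cmdt.tsv"))
  tsv(truth_lost, p("truth", "lost_edges.tsv"))
  tsv(truth_assoc, p("truth", "associations.tsv"))
  config_yaml <- list(
    paths = list(proteome_fasta = "proteome.fasta",
                 network_fasta = "network_proteins.fasta",
                 domains = "domains.tsv", ddi = "ddi.tsv",
                 edges = "edges.tsv",
                 expression_tumor = "expression_tumor.tsv",
                 expression_normal = "expression_normal.tsv",
                 id_maps = "id_maps.tsv", variants = "variants.tsv",
                 regions = "regions.bed", census = "census.gmt",
                 gene_sets = "gene_sets.gmt"),
    cohort = list(cancer_type = cohort$cancer_type,
                  tumor_samples = tumor_samples,
                  normal_tissue = cohort$normal_tissue,
                  normal_samples = normal_samples),
    thresholds = list(min_score = 0.9, min_tpm_tumor = 2.0,
                      min_tpm_normal = 0.2, dominance_fold = 2.0,
                      q_cmdt = 0.01, q_assoc = 0.01, min_mutated = 5L,
                      nds_depth = 3L),
    seed = config$seed)
  yaml::write_yaml(config_yaml, p("config.yaml"))
  world$paths <- list(dir = dir, config = p("config.yaml"))
  invisible(world)
}
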