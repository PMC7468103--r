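#' Read and validate a pipeline configuration
#'
#' YAML with three blocks: `paths` (all input files, relative to the config
#' file's directory unless absolute), `cohort` (cancer type, tumor and
#' normal sample ids, normal tissue), `thresholds` (`min_score`,
#' `min_tpm_tumor`, `min_tpm_normal`, `dominance_fold`, `q_cmdt`,
#' `q_assoc`, `min_mutated`, `nds_depth`) and `seed`.
#'
#' @param path YAML config file.
#' @return list of class `PipelineConfig` with absolute paths.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  cfg$paths <- lapply(cfg$paths, function(p)
    if (startsWith(p, "/")) p else file.path(base, p))
  missing <- names(cfg$paths)[!vapply(cfg$paths, file.exists, TRUE)]
  if (length(missing))
    stop("missing input file(s): ",
         paste(unlist(cfg$paths[missing]), collapse = ", "))
  th <- cfg$thresholds
  if (any(unlist(th) <= 0)) stop("thresholds must be positive")
  structure(cfg, class = "PipelineConfig")
}

#' Run the full pipeline from a configuration
#'
#' Executes, in order: sequence-identity verification and isoform network
#' construction; per-sample MDT calling in both cohorts; cMDT calling;
#' disruption mapping; network density scores and census proximity with a
#' random control; per-sample subnetwork enrichment; and cis-mutation
#' association. All result tables are written as TSV to `out_dir` and a
#' cohort summary is produced (cMDT counts per sample, total and mean
#' disrupted interactions, recurrence table). All randomness derives from
#' the config seed, so a rerun writes identical output.
#'
#' @param config a `PipelineConfig` ([read_pipeline_config()]) or the path
#'   to one.
#' @param out_dir output directory (created if needed).
#' @return invisible list of the result tables.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  th <- config$thresholds
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name) utils::write.table(
    df, file.path(out_dir, name), sep = "\t", quote = FALSE,
    row.names = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ## network construction
  nb <- stage("build-network", {
    annot <- read_protein_fasta(config$paths$proteome_fasta)
    netseq <- read_protein_fasta(config$paths$network_fasta)
    retained <- verify_sequence_identity(netseq, annot)
    edges <- read_interaction_edges(config$paths$edges, th$min_score)
    t2g <- utils::read.delim(config$paths$id_maps,
                             colClasses = "character")
    canonical_of <- stats::setNames(
      t2g$protein_id[!duplicated(t2g$gene_id)],
      t2g$gene_id[!duplicated(t2g$gene_id)])
    domains <- read_domain_table(config$paths$domains, netseq)
    ddi <- read_ddi_table(config$paths$ddi)
    edges <- annotate_physical_edges(edges, domains, ddi)
    p2g <- stats::setNames(t2g$gene_id, t2g$protein_id)
    network <- build_isoform_network(retained, edges, domains, annot,
                                     p2g, canonical_of)
    list(network = network, edges = edges, canonical_of = canonical_of,
         id_maps = t2g)
  })
  write_isoform_network(nb$network, file.path(out_dir, "isoform_network.tsv"))

  ## expression and dominance
  dm <- stage("call-mdt", {
    tumor <- read_expression_matrix(config$paths$expression_tumor,
                                    config$paths$id_maps)
    normal <- read_expression_matrix(config$paths$expression_normal,
                                     config$paths$id_maps)
    cohort <- cohort_pair(config$cohort$cancer_type,
                          unlist(config$cohort$tumor_samples),
                          config$cohort$normal_tissue,
                          unlist(config$cohort$normal_samples))
    tm <- identify_mdt_all(tumor, "tumor", fold = th$dominance_fold,
                           min_tpm = th$min_tpm_tumor)
    nm <- identify_mdt_all(normal, "normal", fold = th$dominance_fold,
                           min_tpm = th$min_tpm_normal)
    list(tumor = tumor, normal = normal, cohort = cohort,
         tumor_mdt = tm, normal_mdt = nm)
  })
  tsv(dm$tumor_mdt, "mdt_tumor.tsv")
  tsv(dm$normal_mdt, "mdt_normal.tsv")

  calls <- stage("call-cmdt",
                 call_cmdt(dm$tumor_mdt, dm$normal_mdt, dm$tumor,
                           dm$normal, dm$cohort, q_threshold = th$q_cmdt))
  tsv(calls, "cmdt.tsv")
  recurrence <- recurrent_cmdt(calls, dm$cohort)
  tsv(recurrence, "cmdt_recurrence.tsv")

  ## impact
  imp <- stage("impact", {
    t2p <- stats::setNames(nb$id_maps$protein_id, nb$id_maps$transcript_id)
    dis <- map_disruptions(calls, nb$network, t2p)
    graph <- ppi_graph(nb$network$edges[, c("protein_a", "protein_b",
                                            "combined_score")],
                       vertices = unname(nb$canonical_of))
    nds <- rank_nds(network_density_scores(graph,
                                           max_depth = th$nds_depth))
    census <- unique(unlist(read_gmt(config$paths$census)))
    cmdt_prot <- unique(unname(nb$canonical_of[calls$gene_id]))
    cmdt_prot <- intersect(cmdt_prot, igraph::V(graph)$name)
    prox <- if (length(cmdt_prot))
      census_proximity(graph, cmdt_prot, census)
    else data.frame(protein_id = character(), distance = numeric(),
                    nearest_census_gene = character())
    ctrl <- if (length(cmdt_prot))
      proximity_control(dm$tumor, graph, census, cmdt_prot,
                        n_draws = 100L, seed = config$seed)
    else NULL
    list(dis = dis, graph = graph, nds = nds, prox = prox, ctrl = ctrl,
         census = census, t2p = t2p)
  })
  tsv(imp$dis$records, "disruptions.tsv")
  tsv(imp$dis$summary, "disruption_summary.tsv")
  tsv(imp$nds, "nds.tsv")
  tsv(imp$prox, "census_proximity.tsv")

  enr <- stage("enrich", {
    gene_sets <- read_gmt(config$paths$gene_sets)
    universe <- unique(c(nb$network$edges$protein_a,
                         nb$network$edges$protein_b))
    res <- lapply(split(imp$dis$records, imp$dis$records$sample_id),
                  enrich_components, gene_sets = gene_sets,
                  universe = universe)
    if (length(res)) do.call(rbind, res) else
      data.frame(sample_id = character(), component_id = integer(),
                 term_id = character(), overlap = integer(),
                 component_size = integer(), term_size = integer(),
                 universe_size = integer(), p_value = numeric(),
                 q_value = numeric())
  })
  rownames(enr) <- NULL
  tsv(enr, "enrichment.tsv")

  ## mutation association
  ma <- stage("mut-assoc", {
    muts <- read_mutation_table(config$paths$variants,
                                config$paths$regions)
    groups <- assign_groups(dm$tumor, muts, dm$cohort$tumor_samples)
    assoc <- test_association(dm$tumor, groups, dm$cohort$tumor_samples,
                              min_mutated = th$min_mutated,
                              q_threshold = th$q_assoc)
    cmdt_load <- table(factor(calls$sample_id,
                              levels = dm$cohort$tumor_samples))
    var_load <- table(factor(muts$sample_id[!duplicated(
      paste(muts$sample_id, muts$chrom, muts$pos))],
      levels = dm$cohort$tumor_samples))
    # a constant load vector has no rank correlation; report NA then
    rho <- tryCatch(suppressWarnings(load_correlation(
      stats::setNames(as.numeric(cmdt_load), names(cmdt_load)),
      stats::setNames(as.numeric(var_load), names(var_load)))),
      error = function(e) NA_real_)
    list(mutations = muts, assoc = assoc, cmdt_load = cmdt_load,
         var_load = var_load, rho = rho)
  })
  tsv(ma$assoc, "mutation_association.tsv")

  ## cohort summary
  n_t <- length(dm$cohort$tumor_samples)
  summary <- data.frame(
    cancer_type = dm$cohort$cancer_type,
    n_tumor_samples = n_t,
    n_normal_samples = length(dm$cohort$normal_samples),
    n_cmdt_calls = nrow(calls),
    n_unique_cmdt = length(unique(calls$transcript_id)),
    median_cmdt_per_sample = stats::median(as.numeric(ma$cmdt_load)),
    total_disrupted_ppi = nrow(imp$dis$records),
    mean_disrupted_ppi_per_sample =
      cohort_disruption_means(nrow(imp$dis$records), n_t),
    cmdt_mutation_load_spearman = ma$rho,
    proximity_control_p = if (is.null(imp$ctrl)) NA_real_ else
      imp$ctrl$p_value)
  tsv(summary, "cohort_summary.tsv")
  loads <- data.frame(sample_id = names(ma$cmdt_load),
                      cmdt_load = as.numeric(ma$cmdt_load),
                      variant_load = as.numeric(ma$var_load))
  tsv(loads, "sample_loads.tsv")

  invisible(list(network = nb$network, tumor_mdt = dm$tumor_mdt,
                 normal_mdt = dm$normal_mdt, cmdt = calls,
                 recurrence = recurrence, disruptions = imp$dis,
                 nds = imp$nds, proximity = imp$prox,
                 proximity_control = imp$ctrl, enrichment = enr,
                 association = ma$assoc, summary = summary, loads = loads))
}
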