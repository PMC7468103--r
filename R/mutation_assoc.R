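# region classes counted as cis to a gene
CIS_REGIONS <- c("promoter_core", "promoter_domain", "utr5", "cds",
                 "splice_site", "utr3")

#' Split cohort samples into mutated and wildtype groups per transcript
#'
#' A sample is Mutated for transcript t when at least one mutation record
#' exists for t's gene in that sample with a cis region class (promoter
#' core/domain, 5'UTR, coding sequence, splice site, 3'UTR); all other
#' cohort samples are Wildtype. Assignment depends only on the set of
#' records, not their order.
#'
#' @param mat an [expression_matrix()].
#' @param mutations mutation record table ([read_mutation_table()]).
#' @param samples the cancer type's sample ids.
#' @return named list (by transcript id) of lists with `mutated` and
#'   `wildtype` character vectors of sample ids.
#' @export
assign_groups <- function(mat, mutations, samples) {
  mut <- mutations[mutations$sample_id %in% samples &
                     mutations$region_class %in% CIS_REGIONS, , drop = FALSE]
  mut_by_gene <- lapply(split(mut$sample_id, mut$gene_id), unique)
  gene <- mat$transcript_to_gene
  out <- lapply(rownames(mat$tpm), function(tx) {
    m <- mut_by_gene[[gene[[tx]]]]
    if (is.null(m)) m <- character()
    list(mutated = sort(m), wildtype = sort(setdiff(samples, m)))
  })
  names(out) <- rownames(mat$tpm)
  out
}

#' Test transcript expression against cis-mutation status
#'
#' For each transcript with at least `min_mutated` mutated samples, a
#' two-sided Wilcoxon rank-sum test compares TPM between the Mutated and
#' Wildtype groups; p-values are BH-adjusted over all tested transcripts of
#' the cancer type. Transcripts with an empty group, with no expression in
#' one of the groups, or with zero variance across both groups are excluded
#' before testing.
#'
#' @param mat an [expression_matrix()].
#' @param groups per-transcript group assignment ([assign_groups()]).
#' @param samples the cancer type's sample ids.
#' @param min_mutated minimum number of mutated samples (default 5).
#' @param q_threshold significance threshold on the q-value (default 0.01).
#' @return data.frame with `transcript_id`, `gene_id`, `n_mutated`,
#'   `n_wildtype`, `statistic`, `p_value`, `q_value`, `direction` (sign of
#'   the mutated-minus-wildtype median difference), `significant`.
#' @export
test_association <- function(mat, groups, samples, min_mutated = 5L,
                             q_threshold = 0.01) {
  rows <- list()
  for (tx in names(groups)) {
    gm <- intersect(groups[[tx]]$mutated, samples)
    gw <- intersect(groups[[tx]]$wildtype, samples)
    if (length(gm) < min_mutated || !length(gw)) next
    xm <- mat$tpm[tx, gm]; xw <- mat$tpm[tx, gw]
    if (!any(xm > 0) || !any(xw > 0)) next
    if (stats::var(c(xm, xw)) == 0) next
    exact <- length(xm) <= 8L && length(xw) <= 8L &&
      !any(duplicated(c(xm, xw)))
    w <- suppressWarnings(stats::wilcox.test(xm, xw, exact = exact,
                                             correct = !exact))
    rows[[length(rows) + 1L]] <- data.frame(
      transcript_id = tx, gene_id = mat$transcript_to_gene[[tx]],
      n_mutated = length(gm), n_wildtype = length(gw),
      statistic = unname(w$statistic), p_value = w$p.value,
      direction = sign(stats::median(xm) - stats::median(xw)),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(transcript_id = character(), gene_id = character(),
               n_mutated = integer(), n_wildtype = integer(),
               statistic = numeric(), p_value = numeric(),
               direction = numeric())
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$q_value <= q_threshold
  rownames(out) <- NULL
  out
}

#' Rank correlation between per-sample cMDT load and mutation load
#'
#' Spearman rank correlation (average ranks for ties) of the number of cMDT
#' calls per sample against the number of variants per sample, aligned by
#' sample id.
#'
#' @param cmdt_counts named numeric vector of cMDT counts per sample.
#' @param variant_counts named numeric vector of variant counts per sample.
#' @return Spearman correlation coefficient.
#' @export
load_correlation <- function(cmdt_counts, variant_counts) {
  shared <- intersect(names(cmdt_counts), names(variant_counts))
  if (length(shared) < 3L) stop("need at least 3 aligned samples")
  stats::cor(cmdt_counts[shared], variant_counts[shared],
             method = "spearman")
}
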