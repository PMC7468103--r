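# Expression floors below which a top-ranked transcript is treated as noise.
# The tumor floor (2 TPM) corresponds to the background-expression ceiling of
# olfactory receptor transcripts in bulk RNA-seq; the normal floor is ten-fold
# lower so that low-expressed normal dominance is still visible when testing
# tumor calls for cancer specificity.
MIN_TPM_TUMOR <- 2.0
MIN_TPM_NORMAL <- 0.2
DOMINANCE_FOLD <- 2.0

.mdt_floor <- function(cohort_role) {
  switch(cohort_role, tumor = MIN_TPM_TUMOR, normal = MIN_TPM_NORMAL,
         stop("cohort_role must be 'tumor' or 'normal'"))
}

#' Identify most dominant transcripts (MDT) in one sample
#'
#' Within each gene, transcripts are ranked by TPM; the top transcript is the
#' gene's MDT when its TPM is at least `fold` times the second-ranked
#' transcript's TPM and at least the cohort noise floor (2 TPM for tumor
#' samples, 0.2 for normal). A single-transcript gene has second-ranked TPM
#' 0, so only the floor applies. Equal top TPMs fail the fold rule, so no
#' MDT is emitted.
#'
#' @param mat an [expression_matrix()].
#' @param sample_id sample to evaluate.
#' @param cohort_role `"tumor"` or `"normal"`; selects the TPM floor.
#' @param fold dominance fold requirement (default 2).
#' @param min_tpm override of the role-specific TPM floor.
#' @return data.frame with one row per gene that has an MDT: `sample_id`,
#'   `gene_id`, `transcript_id`, `tpm`, `second_tpm`, `cohort_role`.
#' @export
identify_mdt <- function(mat, sample_id, cohort_role = c("tumor", "normal"),
                         fold = DOMINANCE_FOLD, min_tpm = NULL) {
  cohort_role <- match.arg(cohort_role)
  if (!sample_id %in% colnames(mat$tpm))
    stop("unknown sample: ", sample_id)
  if (is.null(min_tpm)) min_tpm <- .mdt_floor(cohort_role)
  x <- stats::setNames(mat$tpm[, sample_id], rownames(mat$tpm))
  gene <- mat$transcript_to_gene
  ord <- order(gene, -x, names(x))
  g <- gene[ord]; v <- x[ord]; tx <- names(x)[ord]
  first <- !duplicated(g)
  # second-ranked value: the entry right after each gene's first, when it
  # belongs to the same gene
  idx1 <- which(first)
  idx2 <- idx1 + 1L
  second <- ifelse(idx2 <= length(g) & g[pmin(idx2, length(g))] == g[idx1],
                   v[pmin(idx2, length(g))], 0)
  top <- v[idx1]
  keep <- top >= fold * second & top >= min_tpm & top > 0
  data.frame(sample_id = rep(sample_id, sum(keep)),
             gene_id = unname(g[idx1][keep]),
             transcript_id = tx[idx1][keep], tpm = unname(top[keep]),
             second_tpm = unname(second[keep]),
             cohort_role = rep(cohort_role, sum(keep)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Identify MDT for every sample of a matrix
#'
#' @inheritParams identify_mdt
#' @param samples samples to evaluate; default all columns.
#' @return row-bound data.frame of [identify_mdt()] results.
#' @export
identify_mdt_all <- function(mat, cohort_role = c("tumor", "normal"),
                             samples = colnames(mat$tpm),
                             fold = DOMINANCE_FOLD, min_tpm = NULL) {
  cohort_role <- match.arg(cohort_role)
  do.call(rbind, lapply(samples, identify_mdt, mat = mat,
                        cohort_role = cohort_role, fold = fold,
                        min_tpm = min_tpm))
}

#' Relative expression of all transcripts
#'
#' Relative expression of transcript t in sample s is TPM(t, s) divided by
#' the summed TPM of all transcripts of t's gene in s; it is undefined
#' (`NA`) when the gene sum is 0. Defined values of one gene in one sample
#' lie in [0, 1] and sum to 1.
#'
#' @param mat an [expression_matrix()].
#' @return numeric matrix of the same shape as `mat$tpm` with `NA` where
#'   undefined.
#' @export
relative_expression_matrix <- function(mat) {
  gene <- mat$transcript_to_gene
  gsum <- rowsum(mat$tpm, gene)[gene, , drop = FALSE]
  rel <- mat$tpm / gsum
  rel[gsum == 0] <- NA_real_
  dimnames(rel) <- dimnames(mat$tpm)
  rel
}

#' Relative expression of one transcript in one sample
#'
#' @inheritParams relative_expression_matrix
#' @param transcript_id,sample_id coordinates to evaluate.
#' @return list with `value` (numeric, `NA` when undefined) and `defined`
#'   (logical).
#' @export
compute_relative_expression <- function(mat, transcript_id, sample_id) {
  if (!transcript_id %in% rownames(mat$tpm))
    stop("unknown transcript: ", transcript_id)
  gene <- mat$transcript_to_gene[[transcript_id]]
  members <- names(mat$transcript_to_gene)[mat$transcript_to_gene == gene]
  total <- sum(mat$tpm[members, sample_id])
  if (total == 0) return(list(value = NA_real_, defined = FALSE))
  list(value = unname(mat$tpm[transcript_id, sample_id] / total),
       defined = TRUE)
}

# exact two-sided binomial p at p0 = 0.5 by the minimum-likelihood rule:
# sum the probabilities of all outcomes no more likely than the observed one
# (identical to stats::binom.test); at p0 = 0.5 the distribution is
# symmetric, so this equals the doubled smaller tail capped at 1.
.binom_two_sided <- function(k, n) {
  if (n == 0L) return(1)
  d <- stats::dbinom(0:n, n, 0.5)
  sum(d[d <= d[k + 1L] * (1 + 1e-7)])
}

#' Sign test of a cancer relative expression against a normal cohort
#'
#' Counts how many matched normal samples have strictly lower
#' (`n_higher`: cancer above normal) or strictly higher (`n_lower`) relative
#' expression than the cancer sample; exact ties drop out of both counts.
#' The counts go into an exact two-sided binomial test with success
#' probability 0.5; with no informative normal values the p-value is 1.
#'
#' @param cancer_rel relative expression of the MDT in the cancer sample.
#' @param normal_rels defined relative expressions of the same transcript
#'   across the matched normal cohort.
#' @param alternative `"min-likelihood"` (default; exact binomial as in
#'   [stats::binom.test()]) or `"double-tail"` (twice the smaller tail,
#'   capped at 1).
#' @return list with `n_higher`, `n_lower`, `p_value`.
#' @export
sign_test_mdt <- function(cancer_rel, normal_rels,
                          alternative = c("min-likelihood", "double-tail")) {
  alternative <- match.arg(alternative)
  if (length(normal_rels) == 0L) stop("empty normal cohort")
  normal_rels <- normal_rels[!is.na(normal_rels)]
  n_higher <- sum(cancer_rel > normal_rels)
  n_lower <- sum(cancer_rel < normal_rels)
  n <- n_higher + n_lower
  p <- if (n == 0L) 1
  else if (alternative == "min-likelihood") .binom_two_sided(n_higher, n)
  else min(1, 2 * min(stats::pbinom(n_higher, n, 0.5),
                      stats::pbinom(n_higher - 1L, n, 0.5,
                                    lower.tail = FALSE)))
  list(n_higher = n_higher, n_lower = n_lower, p_value = p)
}

#' Call cancer-specific MDT (cMDT) against a matched normal cohort
#'
#' A tumor MDT qualifies as cancer-specific when all four criteria hold:
#' \enumerate{
#'   \item its transcript is never an MDT in any normal sample of the
#'     configured scope (`uniqueness_scope`);
#'   \item its gene has an MDT (of any transcript identity) in at least 50
#'     percent of the matched normal samples;
#'   \item its relative expression differs significantly from the matched
#'     normal cohort: sign test per tumor MDT, Benjamini-Hochberg adjustment
#'     over all tumor MDT of the cancer type, q-value below `q_threshold`;
#'   \item its relative expression exceeds the median of the transcript's
#'     defined relative expressions across the matched normal cohort.
#' }
#'
#' @param tumor_mdts MDT table for the tumor cohort
#'   ([identify_mdt_all()] with role `"tumor"`).
#' @param normal_mdts MDT table for the normal compendium (role
#'   `"normal"`); used for criteria 1 and 2.
#' @param tumor_mat,normal_mat the tumor and matched-normal
#'   [expression_matrix()] objects.
#' @param cohort a [cohort_pair()]; normal samples define the matched
#'   cohort for criteria 2-4.
#' @param q_threshold FDR threshold on the sign-test q-value (default 0.01).
#' @param uniqueness_scope `"all_normals"` (default): criterion 1 checks
#'   every sample present in `normal_mdts`; `"matched"`: only the matched
#'   cohort's samples.
#' @param min_normal_mdt_fraction fraction of matched normal samples whose
#'   gene must have an MDT (criterion 2; default 0.5).
#' @return data.frame of cMDT calls: `sample_id`, `gene_id`,
#'   `transcript_id`, `rel_expr`, `normal_median_rel_expr`, `n_higher`,
#'   `n_lower`, `p_value`, `q_value`.
#' @export
call_cmdt <- function(tumor_mdts, normal_mdts, tumor_mat, normal_mat,
                      cohort, q_threshold = 0.01,
                      uniqueness_scope = c("all_normals", "matched"),
                      min_normal_mdt_fraction = 0.5) {
  uniqueness_scope <- match.arg(uniqueness_scope)
  normals <- intersect(cohort$normal_samples, colnames(normal_mat$tpm))
  if (length(normals) < 1L) stop("matched normal cohort is empty")
  cand <- tumor_mdts[tumor_mdts$sample_id %in% cohort$tumor_samples, ,
                     drop = FALSE]
  empty <- data.frame(sample_id = character(), gene_id = character(),
                      transcript_id = character(), rel_expr = numeric(),
                      normal_median_rel_expr = numeric(),
                      n_higher = integer(), n_lower = integer(),
                      p_value = numeric(), q_value = numeric())
  if (nrow(cand) == 0L) return(empty)

  scope_mdts <- if (uniqueness_scope == "matched")
    normal_mdts[normal_mdts$sample_id %in% normals, , drop = FALSE]
  else normal_mdts
  normal_mdt_tx <- unique(scope_mdts$transcript_id)

  matched_mdts <- normal_mdts[normal_mdts$sample_id %in% normals, ,
                              drop = FALSE]
  # per gene: number of matched normal samples with an MDT of any identity
  gene_mdt_n <- tapply(matched_mdts$sample_id, matched_mdts$gene_id,
                       function(s) length(unique(s)))

  rel_t <- relative_expression_matrix(tumor_mat)
  rel_n <- relative_expression_matrix(normal_mat)[, normals, drop = FALSE]

  n_higher <- integer(nrow(cand)); n_lower <- integer(nrow(cand))
  p <- numeric(nrow(cand)); relx <- numeric(nrow(cand))
  nmed <- numeric(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    tx <- cand$transcript_id[i]
    relx[i] <- rel_t[tx, cand$sample_id[i]]
    nr <- if (tx %in% rownames(rel_n)) rel_n[tx, ] else numeric()
    nr <- nr[!is.na(nr)]
    nmed[i] <- if (length(nr)) stats::median(nr) else NA_real_
    if (length(nr) == 0L || is.na(relx[i])) {
      n_higher[i] <- 0L; n_lower[i] <- 0L; p[i] <- 1
    } else {
      st <- sign_test_mdt(relx[i], nr)
      n_higher[i] <- st$n_higher; n_lower[i] <- st$n_lower
      p[i] <- st$p_value
    }
  }
  # one FDR family per cancer type: all tested tumor MDT of this cohort
  q <- stats::p.adjust(p, method = "BH")

  c1 <- !(cand$transcript_id %in% normal_mdt_tx)
  frac <- as.numeric(gene_mdt_n[cand$gene_id]) / length(normals)
  c2 <- !is.na(frac) & frac >= min_normal_mdt_fraction
  c3 <- q < q_threshold
  c4 <- !is.na(nmed) & !is.na(relx) & relx > nmed
  keep <- c1 & c2 & c3 & c4
  out <- data.frame(sample_id = cand$sample_id, gene_id = cand$gene_id,
                    transcript_id = cand$transcript_id, rel_expr = relx,
                    normal_median_rel_expr = nmed, n_higher = n_higher,
                    n_lower = n_lower, p_value = p, q_value = q,
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Recurrence of cMDT calls within a cohort
#'
#' Summarises cMDT calls per (gene, transcript): in how many tumor samples
#' the switch recurs and which transcripts reach 100 percent of the cohort.
#' Given calls from several cohorts (list input), transcripts called in only
#' one cancer type are flagged cancer-type-specific.
#'
#' @param calls cMDT call table from [call_cmdt()], or a named list of such
#'   tables (one per cancer type).
#' @param cohort a [cohort_pair()] (single-cohort input) or list of them
#'   matching `calls`.
#' @return data.frame with `cancer_type`, `gene_id`, `transcript_id`,
#'   `n_samples`, `frequency` (percent of cohort), `always_present`,
#'   and `cancer_type_specific` (NA for single-cohort input).
#' @export
recurrent_cmdt <- function(calls, cohort) {
  single <- is.data.frame(calls)
  if (single) { calls <- list(calls); cohort <- list(cohort) }
  tabs <- mapply(function(cl, co) {
    if (nrow(cl) == 0L)
      return(data.frame(cancer_type = character(), gene_id = character(),
                        transcript_id = character(), n_samples = integer(),
                        frequency = numeric()))
    key <- paste(cl$gene_id, cl$transcript_id, sep = "\r")
    cnt <- tapply(cl$sample_id, key, function(s) length(unique(s)))
    ks <- strsplit(names(cnt), "\r", fixed = TRUE)
    data.frame(cancer_type = co$cancer_type,
               gene_id = vapply(ks, `[`, "", 1L),
               transcript_id = vapply(ks, `[`, "", 2L),
               n_samples = as.integer(cnt),
               frequency = 100 * as.integer(cnt) / length(co$tumor_samples),
               stringsAsFactors = FALSE)
  }, calls, cohort, SIMPLIFY = FALSE)
  out <- do.call(rbind, tabs)
  out$always_present <- out$frequency >= 100
  if (single || length(tabs) < 2L) {
    out$cancer_type_specific <- NA
  } else {
    n_types <- tapply(out$cancer_type, out$transcript_id,
                      function(x) length(unique(x)))
    out$cancer_type_specific <- as.integer(n_types[out$transcript_id]) == 1L
  }
  out <- out[order(-out$frequency, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mean disrupted interactions per sample for printed cohort totals
#'
#' Given per-cohort totals of disrupted protein-protein interactions and the
#' cohort sizes, returns the mean number of disrupted interactions per
#' sample, the per-cohort summary statistic used in cohort-level reports.
#'
#' @param total_disrupted numeric vector of per-cohort totals.
#' @param n_samples integer vector of cohort sizes.
#' @return numeric vector of per-sample means.
#' @export
cohort_disruption_means <- function(total_disrupted, n_samples) {
  if (any(n_samples <= 0)) stop("cohort sizes must be positive")
  total_disrupted / n_samples
}
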