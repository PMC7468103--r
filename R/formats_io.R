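# The six functional region classes recognised in mutation tables.
REGION_CLASSES <- c("promoter_core", "promoter_domain", "utr5", "cds",
                    "splice_site", "utr3")

#' Construct an expression matrix object
#'
#' Container for a transcripts x samples TPM matrix together with the
#' transcript-to-gene and (partial) transcript-to-protein mappings that the
#' rest of the pipeline needs. Invariants are enforced at construction:
#' unique transcript and sample ids, finite non-negative TPM values, and a
#' gene for every transcript.
#'
#' @param tpm numeric matrix, rows = transcripts, columns = samples, with
#'   dimnames set. Values are TPM (transcripts per million).
#' @param transcript_to_gene named character vector mapping every transcript
#'   id in `tpm` to a gene id.
#' @param transcript_to_protein named character vector mapping transcript ids
#'   to protein ids; may cover only a subset (NA for unmapped transcripts).
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `tpm`, `transcript_to_gene`, `transcript_to_protein`.
#' @export
expression_matrix <- function(tpm, transcript_to_gene,
                              transcript_to_protein = NULL) {
  if (!is.matrix(tpm) || !is.numeric(tpm))
    stop("tpm must be a numeric matrix")
  if (is.null(rownames(tpm)) || is.null(colnames(tpm)))
    stop("tpm must have transcript rownames and sample colnames")
  if (nrow(tpm) == 0L) stop("no transcripts")
  dup_t <- rownames(tpm)[duplicated(rownames(tpm))]
  if (length(dup_t))
    stop("duplicate transcript id(s): ", paste(unique(dup_t), collapse = ", "))
  dup_s <- colnames(tpm)[duplicated(colnames(tpm))]
  if (length(dup_s))
    stop("duplicate sample id(s): ", paste(unique(dup_s), collapse = ", "))
  tpm[is.na(tpm)] <- 0
  if (any(!is.finite(tpm))) stop("non-finite TPM value")
  if (any(tpm < 0)) stop("negative TPM value")
  missing_gene <- setdiff(rownames(tpm), names(transcript_to_gene))
  if (length(missing_gene))
    stop("transcript(s) without gene mapping: ",
         paste(utils::head(missing_gene, 5L), collapse = ", "))
  t2g <- transcript_to_gene[rownames(tpm)]
  if (anyNA(t2g)) stop("NA gene id in mapping")
  if (is.null(transcript_to_protein)) {
    t2p <- stats::setNames(rep(NA_character_, nrow(tpm)), rownames(tpm))
  } else {
    t2p <- transcript_to_protein[rownames(tpm)]
    names(t2p) <- rownames(tpm)
  }
  structure(list(tpm = tpm, transcript_to_gene = t2g,
                 transcript_to_protein = t2p),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d transcripts x %d samples, %d genes\n",
              nrow(x$tpm), ncol(x$tpm),
              length(unique(x$transcript_to_gene))))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$tpm)

#' Read a transcript-level TPM matrix with its identifier maps
#'
#' The expression file is a TSV whose header row holds sample ids and whose
#' first column holds transcript ids; remaining cells are TPM values. Missing
#' values (`NA` or empty cells) are coerced to 0 TPM. The id-map file is a
#' TSV with columns `transcript_id`, `gene_id` and optionally `protein_id`.
#'
#' @param path path to the expression TSV.
#' @param id_maps path to the transcript/gene/protein mapping TSV.
#' @param strict if `TRUE` (default) transcripts absent from the mapping are
#'   an error; if `FALSE` they are dropped with a message.
#' @return An [expression_matrix()] object.
#' @export
read_expression_matrix <- function(path, id_maps, strict = TRUE) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (nrow(raw) == 0L) stop("no transcripts in ", path)
  tx <- raw[[1L]]
  dup <- tx[duplicated(tx)]
  if (length(dup))
    stop("duplicate transcript id(s): ", paste(unique(dup), collapse = ", "))
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  is_na <- is.na(cells) | cells == "" | toupper(cells) == "NA"
  vals <- suppressWarnings(as.numeric(cells))
  bad <- !is_na & is.na(vals)
  if (any(bad))
    stop("non-numeric TPM cell(s), e.g. '", cells[which(bad)[1L]], "'")
  vals[is_na] <- 0
  if (any(vals < 0)) stop("negative TPM value in ", path)
  tpm <- matrix(vals, nrow = nrow(raw),
                dimnames = list(tx, colnames(raw)[-1L]))

  maps <- utils::read.delim(id_maps, header = TRUE, sep = "\t",
                            colClasses = "character")
  need <- c("transcript_id", "gene_id")
  if (!all(need %in% colnames(maps)))
    stop("id_maps must have columns transcript_id and gene_id")
  unmapped <- setdiff(tx, maps$transcript_id)
  if (length(unmapped)) {
    if (strict)
      stop("transcript(s) missing from id map: ",
           paste(utils::head(unmapped, 5L), collapse = ", "),
           if (length(unmapped) > 5L) sprintf(" (+%d more)",
                                              length(unmapped) - 5L))
    message("dropping ", length(unmapped), " unmapped transcript(s)")
    tpm <- tpm[setdiff(tx, unmapped), , drop = FALSE]
  }
  t2g <- stats::setNames(maps$gene_id, maps$transcript_id)
  t2p <- if ("protein_id" %in% colnames(maps)) {
    p <- maps$protein_id
    p[p == ""] <- NA_character_
    stats::setNames(p, maps$transcript_id)
  } else NULL
  expression_matrix(tpm, t2g, t2p)
}

#' Write an expression matrix back to TSV
#'
#' Inverse of the expression part of [read_expression_matrix()]; values are
#' written with full precision so a load/write/load round trip is exact.
#'
#' @param mat an `ExpressionMatrix`.
#' @param path output TSV path.
#' @export
write_expression_matrix <- function(mat, path) {
  df <- data.frame(transcript_id = rownames(mat$tpm),
                   mat$tpm, check.names = FALSE)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a scored protein-protein interaction edge list
#'
#' Accepts a TSV with columns `protein_a`, `protein_b`, `combined_score`.
#' Two score dialects are auto-detected: integer scores on 0-999 (divided by
#' 1000) and real scores already on 0-1; any score above 1 switches the whole
#' file to the integer dialect. Self-loops are dropped (with a message giving
#' the count), duplicate rows in either orientation are collapsed keeping the
#' maximum score, and edges are stored once with the lexicographically
#' smaller protein first.
#'
#' @param path edge list TSV.
#' @param min_score minimum combined score on the 0-1 scale; edges strictly
#'   below it are excluded. Default 0.9 (high-confidence edges only).
#' @return data.frame with columns `protein_a`, `protein_b`,
#'   `combined_score`, sorted by protein pair.
#' @export
read_interaction_edges <- function(path, min_score = 0.9) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "character", "character"))
  colnames(df)[1:3] <- c("protein_a", "protein_b", "combined_score")
  score <- suppressWarnings(as.numeric(df$combined_score))
  if (anyNA(score))
    stop("malformed score: '", df$combined_score[which(is.na(score))[1L]], "'")
  if (any(score < 0)) stop("malformed score: negative value")
  if (any(score > 1)) {
    if (any(score > 999)) stop("malformed score: above 999")
    score <- score / 1000
  }
  self <- df$protein_a == df$protein_b
  if (any(self)) {
    message("dropped ", sum(self), " self-loop row(s)")
    df <- df[!self, , drop = FALSE]
    score <- score[!self]
  }
  a <- pmin(df$protein_a, df$protein_b)
  b <- pmax(df$protein_a, df$protein_b)
  key <- paste(a, b, sep = "\r")
  best <- tapply(score, key, max)
  keys <- strsplit(names(best), "\r", fixed = TRUE)
  out <- data.frame(protein_a = vapply(keys, `[`, "", 1L),
                    protein_b = vapply(keys, `[`, "", 2L),
                    combined_score = as.numeric(best),
                    stringsAsFactors = FALSE)
  out <- out[out$combined_score >= min_score, , drop = FALSE]
  out <- out[order(out$protein_a, out$protein_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file of amino-acid sequences keyed by protein id.
#' @return named character vector of sequences.
#' @export
read_protein_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  seqs <- as.character(aa)
  # keep only the first whitespace-delimited token of each header
  names(seqs) <- sub("\\s.*$", "", names(aa))
  if (anyDuplicated(names(seqs)))
    stop("duplicate protein id in FASTA ", path)
  seqs
}

#' Write protein sequences to FASTA
#' @param seqs named character vector of amino-acid sequences.
#' @param path output path.
#' @export
write_protein_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}

#' Read a domain-instance annotation table
#'
#' TSV with columns `protein_id`, `domain_id`, `start`, `end` (1-based
#' inclusive residue coordinates). Each instance's amino-acid sequence is
#' extracted from the supplied protein sequences and bounds are validated
#' against sequence length.
#'
#' @param path annotation TSV.
#' @param proteins named character vector of protein sequences (the proteins
#'   the coordinates refer to).
#' @return data.frame with columns `instance_id`, `protein_id`, `domain_id`,
#'   `start`, `end`, `sequence`.
#' @export
read_domain_table <- function(path, proteins) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "character",
                                         "integer", "integer"))
  colnames(df)[1:4] <- c("protein_id", "domain_id", "start", "end")
  unknown <- setdiff(df$protein_id, names(proteins))
  if (length(unknown))
    stop("domain annotation for unknown protein(s): ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  len <- nchar(proteins[df$protein_id])
  if (any(df$start < 1L | df$start > df$end | df$end > len))
    stop("domain coordinates out of protein bounds")
  df$sequence <- substr(proteins[df$protein_id], df$start, df$end)
  df$instance_id <- paste(df$protein_id, df$domain_id, df$start, df$end,
                          sep = ":")
  df[, c("instance_id", "protein_id", "domain_id", "start", "end",
         "sequence")]
}

#' Read a physical domain-domain interaction table
#'
#' TSV with two columns of domain family ids; pairs are unordered, stored
#' once with the lexicographically smaller id first, duplicates removed.
#'
#' @param path DDI TSV.
#' @return data.frame with columns `domain_a`, `domain_b`.
#' @export
read_ddi_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  a <- pmin(df[[1L]], df[[2L]])
  b <- pmax(df[[1L]], df[[2L]])
  out <- unique(data.frame(domain_a = a, domain_b = b,
                           stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' members. Used both for pathway gene sets and the cancer census list.
#'
#' @param path GMT file.
#' @return named list of character vectors of member ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, "", 1L)
  if (anyDuplicated(names(sets))) stop("duplicate gene-set name in ", path)
  sets
}

#' Write gene sets in GMT format
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description optional per-set description (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  lines <- mapply(function(nm, members, desc) {
    paste(c(nm, desc, members), collapse = "\t")
  }, names(sets), sets, rep_len(description, length(sets)))
  writeLines(lines, path)
  invisible(path)
}

# classify a variant row by its ref/alt alleles
.variant_class <- function(ref, alt) {
  ifelse(nchar(ref) != nchar(alt), "indel",
         ifelse(nchar(ref) == 1L, "snv", "mnv"))
}

#' Read a per-sample variant table against functional-region annotations
#'
#' Variants come as a TSV with columns `sample_id`, `chrom`, `pos`, `ref`,
#' `alt` (positions 1-based); regions as a BED-like TSV with columns
#' `chrom`, `start`, `end`, `gene_id`, `region_class` (0-based half-open
#' coordinates, converted once at load). Runs of adjacent same-sample SNVs
#' are first joined into multi-nucleotide variants (MNVs); indels never
#' merge. Each variant then yields one record per overlapped functional
#' region; variants outside every functional region are discarded.
#'
#' @param path variant TSV.
#' @param regions BED-like functional-region TSV.
#' @return data.frame of mutation records: `sample_id`, `gene_id`,
#'   `region_class`, `variant_class`, `chrom`, `pos`.
#' @export
read_mutation_table <- function(path, regions) {
  var <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = c("character", "character", "integer",
                                          "character", "character"))
  colnames(var)[1:5] <- c("sample_id", "chrom", "pos", "ref", "alt")
  reg <- utils::read.delim(regions, header = TRUE, sep = "\t",
                           colClasses = c("character", "integer", "integer",
                                          "character", "character"))
  colnames(reg)[1:5] <- c("chrom", "start", "end", "gene_id", "region_class")
  bad <- setdiff(unique(reg$region_class), REGION_CLASSES)
  if (length(bad))
    stop("unknown region_class label(s): ", paste(bad, collapse = ", "))
  ord <- order(reg$chrom, reg$start, reg$end)
  if (!identical(ord, seq_len(nrow(reg)))) {
    warning("region file not sorted; sorting internally")
    reg <- reg[ord, , drop = FALSE]
  }

  var$variant_class <- .variant_class(var$ref, var$alt)
  var <- merge_adjacent_snvs(var)
  if (nrow(var) == 0L)
    return(data.frame(sample_id = character(), gene_id = character(),
                      region_class = character(), variant_class = character(),
                      chrom = character(), pos = integer()))

  # variant footprint [pos, pos + nchar(ref) - 1], 1-based inclusive;
  # BED regions become [start + 1, end] after conversion
  vgr <- GenomicRanges::GRanges(var$chrom,
                                IRanges::IRanges(var$pos,
                                                 var$pos + nchar(var$ref) - 1L))
  rgr <- GenomicRanges::GRanges(reg$chrom,
                                IRanges::IRanges(reg$start + 1L, reg$end))
  hits <- GenomicRanges::findOverlaps(vgr, rgr)
  vi <- S4Vectors::queryHits(hits)
  ri <- S4Vectors::subjectHits(hits)
  out <- data.frame(sample_id = var$sample_id[vi],
                    gene_id = reg$gene_id[ri],
                    region_class = reg$region_class[ri],
                    variant_class = var$variant_class[vi],
                    chrom = var$chrom[vi],
                    pos = var$pos[vi],
                    stringsAsFactors = FALSE)
  out <- unique(out)
  rownames(out) <- NULL
  out
}

#' Join maximal runs of adjacent same-sample SNVs into MNVs
#'
#' Two SNVs merge when they share a sample and chromosome and their positions
#' are consecutive; merging is applied to maximal runs. Indels and existing
#' MNVs are left untouched.
#'
#' @param var data.frame with columns `sample_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `variant_class`.
#' @return data.frame of the same shape with merged rows.
#' @export
merge_adjacent_snvs <- function(var) {
  snv <- var$variant_class == "snv"
  keep <- var[!snv, , drop = FALSE]
  s <- var[snv, , drop = FALSE]
  if (nrow(s) > 1L) {
    s <- s[order(s$sample_id, s$chrom, s$pos), , drop = FALSE]
    new_run <- c(TRUE, !(s$sample_id[-1L] == s$sample_id[-nrow(s)] &
                           s$chrom[-1L] == s$chrom[-nrow(s)] &
                           s$pos[-1L] == s$pos[-nrow(s)] + 1L))
    run <- cumsum(new_run)
    merged <- do.call(rbind, lapply(split(s, run), function(g) {
      data.frame(sample_id = g$sample_id[1L], chrom = g$chrom[1L],
                 pos = g$pos[1L],
                 ref = paste(g$ref, collapse = ""),
                 alt = paste(g$alt, collapse = ""),
                 variant_class = if (nrow(g) > 1L) "mnv" else "snv",
                 stringsAsFactors = FALSE)
    }))
    s <- merged
  }
  out <- rbind(keep[, c("sample_id", "chrom", "pos", "ref", "alt",
                        "variant_class")],
               s[, c("sample_id", "chrom", "pos", "ref", "alt",
                     "variant_class")])
  out <- out[order(out$sample_id, out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Define a matched tumor/normal cohort pair
#'
#' @param cancer_type label for the tumor cohort.
#' @param tumor_samples character vector of tumor sample ids.
#' @param normal_tissue label for the matched normal tissue.
#' @param normal_samples character vector of normal sample ids.
#' @return list of class `CohortPair`.
#' @export
cohort_pair <- function(cancer_type, tumor_samples, normal_tissue,
                        normal_samples) {
  tumor_samples <- unique(tumor_samples)
  normal_samples <- unique(normal_samples)
  if (!length(tumor_samples) || !length(normal_samples))
    stop("tumor and normal sample sets must be non-empty")
  if (length(intersect(tumor_samples, normal_samples)))
    stop("tumor and normal sample sets must be disjoint")
  structure(list(cancer_type = cancer_type, tumor_samples = tumor_samples,
                 normal_tissue = normal_tissue,
                 normal_samples = normal_samples),
            class = "CohortPair")
}
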