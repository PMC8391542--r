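#' Filter thresholds for the CNV cascade
#'
#' Bundles the thresholds of the filtering criteria: Bayes factor, call size,
#' gene-based population allele frequency (with a minimum database sample
#' size), and the recurrence rules of the novel-CNV screen. Boundary semantics
#' follow the stated exclusion rules literally: only BF *smaller than* 1, size
#' *smaller than* 100 bp and frequency *greater than* 0.01 are excluded, so
#' boundary values are kept.
#'
#' @param min_bf Minimum Bayes factor kept (calls below are excluded).
#' @param min_size_bp Minimum call size in bp kept.
#' @param max_pop_af Maximum eligible population frequency kept (gene-based).
#' @param min_db_sample_size Minimum database cohort size for a frequency
#'   record to be eligible.
#' @param max_control_fraction Maximum fraction of family controls carrying a
#'   gene's CNVs in the novel screen (strict: the fraction must be below this).
#' @param min_patient_count Minimum number of distinct patient carriers in the
#'   novel screen ("more than three" = at least 4).
#' @return An object of class `filter_thresholds`.
#' @export
filter_thresholds <- function(min_bf = 1, min_size_bp = 100, max_pop_af = 0.01,
                              min_db_sample_size = 100,
                              max_control_fraction = 0.01,
                              min_patient_count = 4L) {
  stopifnot(min_bf >= 0, min_size_bp >= 0, max_pop_af >= 0, max_pop_af <= 1,
            min_db_sample_size >= 0, max_control_fraction >= 0,
            max_control_fraction <= 1, min_patient_count >= 0)
  structure(list(min_bf = min_bf, min_size_bp = min_size_bp,
                 max_pop_af = max_pop_af,
                 min_db_sample_size = min_db_sample_size,
                 max_control_fraction = max_control_fraction,
                 min_patient_count = as.integer(min_patient_count)),
            class = "filter_thresholds")
}

#' Bayes-factor filter
#'
#' Keeps calls whose log10 Bayes factor is at least `min_bf`; only calls with
#' BF smaller than the threshold are excluded.
#'
#' @param calls Call data.frame with a `bayes_factor` column.
#' @param thresholds A [filter_thresholds()].
#' @return The surviving calls.
#' @export
filter_by_bf <- function(calls, thresholds = filter_thresholds()) {
  stopifnot(all(is.finite(calls$bayes_factor)))
  calls[calls$bayes_factor >= thresholds$min_bf, , drop = FALSE]
}

#' Size filter
#'
#' Keeps calls of size at least `min_size_bp` (size = end - start); small
#' calls are unreliable for exon read-depth callers.
#'
#' @inheritParams filter_by_bf
#' @return The surviving calls.
#' @export
filter_by_size <- function(calls, thresholds = filter_thresholds()) {
  size <- if ("size" %in% names(calls)) calls$size else calls$end - calls$start
  calls[size >= thresholds$min_size_bp, , drop = FALSE]
}

#' Annotate calls with overlapped gene exons
#'
#' Assigns each call to every gene with at least one exon overlapping
#' `[start, end)` (1 bp of exon overlap suffices; exome data carry no
#' intron-only evidence) and writes the annotation as `GENE_a-b` (first-last
#' overlapped exon index; `GENE_a` when a single exon), comma-separated over
#' genes. Calls overlapping no target get an empty annotation; they are
#' retained but take no part in gene-based stages.
#'
#' @param calls Call data.frame with `chrom`, `start`, `end`.
#' @param targets Exon target data.frame.
#' @return `calls` with an `exon_annotation` column.
#' @export
annotate_genes <- function(calls, targets) {
  if (nrow(calls) == 0) {
    calls$exon_annotation <- character(0)
    return(calls)
  }
  call_gr <- GenomicRanges::GRanges(
    calls$chrom, IRanges::IRanges(calls$start + 1L, calls$end))
  tgt_gr <- GenomicRanges::GRanges(
    targets$chrom, IRanges::IRanges(targets$start + 1L, targets$end))
  hits <- GenomicRanges::findOverlaps(call_gr, tgt_gr)
  ann <- character(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    sel <- S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == i]
    ann[i] <- if (length(sel) == 0) "" else annotation_string(targets[sel, ])
  }
  calls$exon_annotation <- ann
  calls
}

#' Genes named by a call's exon annotation
#'
#' Parses `GENE_a-b` annotation strings back into the set of gene symbols per
#' call. Used by every gene-based stage so that externally supplied call
#' tables (with printed annotation strings) work without target definitions.
#'
#' @param annotation Character vector of `exon_annotation` strings.
#' @return A list (one element per call) of character vectors of genes.
#' @export
annotation_genes <- function(annotation) {
  lapply(annotation, function(a) {
    if (is.na(a) || a == "") return(character(0))
    parts <- trimws(strsplit(a, ",")[[1]])
    unique(sub("_[^_]*$", "", parts))
  })
}

#' Gene-based maximum allele frequency filter
#'
#' Implements gene-based rarity filtering against population CNV-frequency
#' records: records from cohorts smaller than `min_db_sample_size` are
#' ignored; per gene, the maximum over all remaining frequencies (overall and
#' East-Asian where present, across databases) is taken; genes whose maximum
#' exceeds `max_pop_af` are excluded together with their calls. Genes with no
#' eligible record are retained. A call annotated to several genes survives
#' if at least one of its genes survives; unannotated calls pass through.
#'
#' @param calls Annotated call data.frame.
#' @param popfreq Population-frequency data.frame (`gene`, `database`,
#'   `sample_size`, `freq_het_loss`, `freq_het_loss_east_asia`).
#' @param thresholds A [filter_thresholds()].
#' @return A list with `calls` (survivors) and `genes` (a data.frame per gene:
#'   `gene`, `max_pop_af` — NA when no eligible record — and `excluded`).
#' @export
gene_max_af <- function(calls, popfreq, thresholds = filter_thresholds()) {
  gene_sets <- annotation_genes(calls$exon_annotation)
  genes <- sort(unique(unlist(gene_sets)))
  max_af <- vapply(genes, gene_max_pop_af, numeric(1),
                   popfreq = popfreq,
                   min_n = thresholds$min_db_sample_size)
  excluded <- !is.na(max_af) & max_af > thresholds$max_pop_af
  gene_tab <- data.frame(gene = genes, max_pop_af = unname(max_af),
                         excluded = unname(excluded),
                         stringsAsFactors = FALSE)
  bad <- genes[excluded]
  keep <- vapply(gene_sets, function(g) {
    length(g) == 0 || any(!g %in% bad)
  }, logical(1))
  list(calls = calls[keep, , drop = FALSE], genes = gene_tab)
}

# max eligible frequency for one gene, NA when no eligible record exists
gene_max_pop_af <- function(gene, popfreq, min_n = 100) {
  if (is.null(popfreq) || nrow(popfreq) == 0) return(NA_real_)
  rec <- popfreq[popfreq$gene == gene & popfreq$sample_size >= min_n, ,
                 drop = FALSE]
  vals <- c(rec$freq_het_loss, rec$freq_het_loss_east_asia)
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) NA_real_ else max(vals)
}

#' Count distinct CNVs
#'
#' Counts equivalence classes of calls under (chrom, start, end, type) —
#' repeated occurrences of the same event across samples collapse to one.
#'
#' @param calls Call data.frame.
#' @return Integer count of distinct CNVs.
#' @export
count_distinct <- function(calls) {
  if (nrow(calls) == 0) return(0L)
  nrow(unique(calls[, c("chrom", "start", "end", "type")]))
}

#' Gene-based recurrence counts in patients and controls
#'
#' For every annotated gene, counts the distinct affected (patient) and
#' unaffected (control) samples carrying at least one call overlapping the
#' gene. A sample with several calls in one gene is counted once.
#'
#' @param calls Annotated call data.frame.
#' @param pedigrees Pedigree data.frame with `sample_id` and `affected`.
#' @return A data.frame per gene: `gene`, `patient_count`, `control_count`.
#' @export
count_recurrence <- function(calls, pedigrees) {
  unknown <- setdiff(unique(calls$sample_id), pedigrees$sample_id)
  if (length(unknown) > 0)
    stop("sample(s) absent from pedigree: ", paste(unknown, collapse = ", "))
  gene_sets <- annotation_genes(calls$exon_annotation)
  long <- data.frame(
    gene = unlist(gene_sets),
    sample_id = rep(calls$sample_id, lengths(gene_sets)),
    stringsAsFactors = FALSE)
  long <- unique(long)
  if (nrow(long) == 0)
    return(data.frame(gene = character(), patient_count = integer(),
                      control_count = integer(), stringsAsFactors = FALSE))
  long$affected <- pedigrees$affected[match(long$sample_id,
                                            pedigrees$sample_id)]
  agg <- stats::aggregate(cbind(patient_count = affected,
                                control_count = !affected) ~ gene,
                          data = long, FUN = sum)
  agg <- agg[order(agg$gene), ]
  rownames(agg) <- NULL
  agg$patient_count <- as.integer(agg$patient_count)
  agg$control_count <- as.integer(agg$control_count)
  agg
}
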