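#' Default candidate-gene list
#'
#' Genes with prior evidence in scoliosis or somitogenesis: the 16p11.2 dosage
#' gene TBX6, the Notch pathway members NOTCH2, DLL3, MESP2, LFNG, HES7 and
#' RIPPLY2, the somitogenesis transcription factors TBXT and SOX9, and the
#' idiopathic-scoliosis-associated DSCAM and SNTG1.
#'
#' @return Character vector of gene symbols.
#' @export
default_candidate_genes <- function() {
  c("TBX6", "NOTCH2", "DSCAM", "SNTG1",
    "DLL3", "MESP2", "LFNG", "HES7", "RIPPLY2", "TBXT", "SOX9")
}

#' Candidate-gene screen
#'
#' Restricts patient calls to those overlapping a candidate gene, applies the
#' Bayes-factor and gene-based population-frequency filters (the size filter
#' is deliberately bypassed on this path: single-exon hits in a candidate
#' gene are worth manual review even below the genome-wide size cutoff), and
#' reports one row per (candidate gene, call) with the inheritance pattern
#' and the gene's frequency summary.
#'
#' @param calls Annotated call data.frame (patients and relatives).
#' @param pedigrees Pedigree data.frame.
#' @param candidates Character vector of candidate genes
#'   (default [default_candidate_genes()]).
#' @param popfreq Population-frequency table (NULL skips the AF filter).
#' @param thresholds A [filter_thresholds()].
#' @param overlap_rule Passed to [classify_inheritance_all()].
#' @return A data.frame sorted by gene then sample: `gene`, `sample_id`,
#'   `type`, `chrom`, `start`, `end`, `size`, `bayes_factor`, `reads_ratio`,
#'   `exon_annotation`, `inheritance`, `max_pop_af`.
#' @export
candidate_gene_screen <- function(calls, pedigrees,
                                  candidates = default_candidate_genes(),
                                  popfreq = NULL,
                                  thresholds = filter_thresholds(),
                                  overlap_rule = "gene") {
  if (length(candidates) == 0 || nrow(calls) == 0) return(empty_screen())
  kept <- filter_by_bf(calls, thresholds)
  kept <- classify_inheritance_all(kept, pedigrees, all_calls = calls,
                                   overlap_rule = overlap_rule)
  patients <- pedigrees$sample_id[pedigrees$affected]
  rows <- list()
  for (gene in sort(unique(candidates))) {
    af <- gene_max_pop_af(gene, popfreq, thresholds$min_db_sample_size)
    if (!is.na(af) && af > thresholds$max_pop_af) next
    hit <- vapply(annotation_genes(kept$exon_annotation),
                  function(g) gene %in% g, logical(1)) &
      kept$sample_id %in% patients
    if (!any(hit)) next
    sub <- kept[hit, , drop = FALSE]
    sub <- sub[order(sub$sample_id), , drop = FALSE]
    rows[[length(rows) + 1L]] <- data.frame(
      gene = gene, sample_id = sub$sample_id, type = sub$type,
      chrom = sub$chrom, start = sub$start, end = sub$end, size = sub$size,
      bayes_factor = sub$bayes_factor, reads_ratio = sub$reads_ratio,
      exon_annotation = sub$exon_annotation, inheritance = sub$inheritance,
      max_pop_af = af, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) return(empty_screen())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

empty_screen <- function() {
  data.frame(gene = character(), sample_id = character(), type = character(),
             chrom = character(), start = integer(), end = integer(),
             size = integer(), bayes_factor = numeric(),
             reads_ratio = numeric(), exon_annotation = character(),
             inheritance = character(), max_pop_af = numeric(),
             stringsAsFactors = FALSE)
}

#' Recessive (patient-unique homozygous) CNV screen
#'
#' Composition of [detect_recessive()] on patients and controls,
#' [patient_unique_homozygous()] to drop genes with control homozygous
#' carriers, and [classify_inheritance_all()] for the inheritance column.
#' Rows are grouped by gene, then sample.
#'
#' @param calls Annotated call data.frame for the whole cohort.
#' @param pedigrees Pedigree data.frame.
#' @param popfreq Optional frequency table used only to report each gene's
#'   maximum eligible heterozygous-loss frequency.
#' @param thresholds A [filter_thresholds()].
#' @param hom_threshold Strict reads-ratio bound for homozygosity.
#' @return Screen rows as in [candidate_gene_screen()], plus
#'   `sibling_absent`.
#' @export
recessive_screen <- function(calls, pedigrees, popfreq = NULL,
                             thresholds = filter_thresholds(),
                             hom_threshold = 0.1) {
  patients <- pedigrees$sample_id[pedigrees$affected]
  hom <- detect_recessive(calls, hom_threshold)
  hom_pat <- hom[hom$sample_id %in% patients, , drop = FALSE]
  hom_ctl <- hom[!hom$sample_id %in% patients, , drop = FALSE]
  uniq <- patient_unique_homozygous(hom_pat, hom_ctl)
  if (nrow(uniq) == 0) return(empty_screen())
  uniq <- classify_inheritance_all(uniq, pedigrees, all_calls = calls)
  genes <- sort(unique(unlist(annotation_genes(uniq$exon_annotation))))
  rows <- list()
  for (gene in genes) {
    hit <- vapply(annotation_genes(uniq$exon_annotation),
                  function(g) gene %in% g, logical(1))
    sub <- uniq[hit, , drop = FALSE]
    sub <- sub[order(sub$sample_id), , drop = FALSE]
    rows[[length(rows) + 1L]] <- data.frame(
      gene = gene, sample_id = sub$sample_id, type = sub$type,
      chrom = sub$chrom, start = sub$start, end = sub$end, size = sub$size,
      bayes_factor = sub$bayes_factor, reads_ratio = sub$reads_ratio,
      exon_annotation = sub$exon_annotation, inheritance = sub$inheritance,
      max_pop_af = gene_max_pop_af(gene, popfreq,
                                   thresholds$min_db_sample_size),
      sibling_absent = sub$sibling_absent, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Novel-CNV enrichment rule on gene-level recurrence counts
#'
#' A gene is reported when (i) more than three distinct patients carry a CNV
#' overlapping it (`patient_count >= min_patient_count`, default 4), (ii) the
#' fraction of family controls carrying one is strictly below
#' `max_control_fraction` (with 125 controls, 1/125 = 0.8% passes and 2/125 =
#' 1.6% fails the "<1%" rule), and (iii) the gene's maximum eligible
#' population frequency does not exceed `max_pop_af` (genes without an
#' eligible record pass).
#'
#' @param gene_groups Data.frame with `gene`, `patient_count`,
#'   `control_count`; any extra columns are carried through.
#' @param n_controls Total number of family controls.
#' @param popfreq Population-frequency table (NULL: criterion (iii) passes).
#' @param thresholds A [filter_thresholds()].
#' @return The reported rows of `gene_groups`, with a `max_pop_af` column,
#'   sorted by gene.
#' @export
novel_enrichment <- function(gene_groups, n_controls, popfreq = NULL,
                             thresholds = filter_thresholds()) {
  if (nrow(gene_groups) == 0) return(gene_groups)
  af <- vapply(gene_groups$gene, gene_max_pop_af, numeric(1),
               popfreq = popfreq, min_n = thresholds$min_db_sample_size)
  keep <- gene_groups$patient_count >= thresholds$min_patient_count &
    gene_groups$control_count / n_controls < thresholds$max_control_fraction &
    (is.na(af) | af <= thresholds$max_pop_af)
  out <- gene_groups[keep, , drop = FALSE]
  out$max_pop_af <- unname(af[keep])
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Novel-CNV screen from a cohort call set
#'
#' Two-pass discovery mirroring family-based designs: candidate genes are
#' discovered among patients from complete families (both parents assayed —
#' quintets, quartets, trios), then recurrence counts are updated with the
#' remaining patients (duos, singletons) before [novel_enrichment()] is
#' applied. For pure thresholding the two passes select the same genes as a
#' single pass; the discovery flag is kept for design parity.
#'
#' @param calls Annotated, BF- and size-filtered call data.frame.
#' @param pedigrees Pedigree data.frame.
#' @param popfreq Population-frequency table.
#' @param thresholds A [filter_thresholds()].
#' @return Report rows: `gene`, `type`, `chrom`, `size_min`, `size_max`,
#'   `patient_count`, `control_count`, `max_pop_af`.
#' @export
novel_screen <- function(calls, pedigrees, popfreq = NULL,
                         thresholds = filter_thresholds()) {
  patients <- pedigrees$sample_id[pedigrees$affected]
  complete <- pedigrees$sample_id[
    pedigrees$affected &
      !is.na(pedigrees$father_id) & !is.na(pedigrees$mother_id) &
      pedigrees$father_id %in% pedigrees$sample_id &
      pedigrees$mother_id %in% pedigrees$sample_id]
  n_controls <- sum(!pedigrees$affected)
  gene_sets <- annotation_genes(calls$exon_annotation)
  discovery_genes <- unique(unlist(
    gene_sets[calls$sample_id %in% complete]))
  counts <- count_recurrence(calls, pedigrees)
  counts <- counts[counts$gene %in% discovery_genes, , drop = FALSE]
  hits <- novel_enrichment(counts, n_controls, popfreq, thresholds)
  if (nrow(hits) == 0) {
    return(data.frame(gene = character(), type = character(),
                      chrom = character(), size_min = integer(),
                      size_max = integer(), patient_count = integer(),
                      control_count = integer(), max_pop_af = numeric(),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_len(nrow(hits)), function(i) {
    gene <- hits$gene[i]
    hit <- vapply(gene_sets, function(g) gene %in% g, logical(1)) &
      calls$sample_id %in% patients
    sub <- calls[hit, , drop = FALSE]
    data.frame(gene = gene,
               type = paste(sort(unique(sub$type)), collapse = ","),
               chrom = sub$chrom[1],
               size_min = min(sub$size), size_max = max(sub$size),
               patient_count = hits$patient_count[i],
               control_count = hits$control_count[i],
               max_pop_af = hits$max_pop_af[i], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Relative copy-number quantification from qPCR Ct values (2^-ddCt)
#'
#' For each measurement, dCt = Ct(target) - Ct(reference locus); ddCt =
#' dCt(sample) - dCt(calibrator); relative quantity = 2^-ddCt, and the copy
#' estimate doubles it (autosomal diploid calibrator). A quantity near 0.5
#' therefore indicates a heterozygous deletion, near 1 a normal locus, near
#' 1.5 a single-copy gain.
#'
#' @param measurements Data.frame with `sample_id`, `target_locus`,
#'   `ct_target`, `ct_reference` (triplicate means).
#' @param calibrator Sample id used as ddCt baseline (per target locus).
#' @return `measurements` with `delta_ct`, `delta_delta_ct`,
#'   `relative_quantity` and `copy_estimate` columns.
#' @export
qpcr_relative_quantity <- function(measurements, calibrator) {
  stopifnot(all(measurements$ct_target > 0),
            all(measurements$ct_reference > 0))
  if (!calibrator %in% measurements$sample_id)
    stop("calibrator sample not found: ", calibrator)
  measurements$delta_ct <- measurements$ct_target - measurements$ct_reference
  ddct <- numeric(nrow(measurements))
  for (locus in unique(measurements$target_locus)) {
    sel <- measurements$target_locus == locus
    base <- measurements$delta_ct[sel &
                                    measurements$sample_id == calibrator]
    if (length(base) == 0)
      stop("calibrator sample not found for target locus ", locus)
    ddct[sel] <- measurements$delta_ct[sel] - base[1]
  }
  measurements$delta_delta_ct <- ddct
  measurements$relative_quantity <- 2^(-ddct)
  measurements$copy_estimate <- 2 * measurements$relative_quantity
  measurements
}
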