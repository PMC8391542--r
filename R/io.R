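#' Read a 6-column PED pedigree file
#'
#' Whitespace-delimited, no header: family, sample, father, mother, sex
#' (1 = male, 2 = female, other = unknown), phenotype (2 = affected). Parent
#' id "0" means unknown and becomes NA.
#'
#' @param path PED file path.
#' @return Pedigree data.frame (see [generate_pedigrees()]).
#' @export
read_ped <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(lengths(fields) != 6L)
  if (length(bad) > 0)
    stop("malformed PED line ", bad[1], ": expected 6 fields, found ",
         lengths(fields)[bad[1]])
  m <- do.call(rbind, fields)
  data.frame(
    family_id = m[, 1], sample_id = m[, 2],
    father_id = ifelse(m[, 3] == "0", NA_character_, m[, 3]),
    mother_id = ifelse(m[, 4] == "0", NA_character_, m[, 4]),
    sex = c("1" = "male", "2" = "female")[m[, 5]],
    affected = m[, 6] == "2", stringsAsFactors = FALSE,
    row.names = NULL
  ) |> (\(d) { d$sex[is.na(d$sex)] <- "unknown"; d })()
}

#' Write pedigrees as PED
#'
#' @param pedigrees Pedigree data.frame.
#' @param path Output path.
#' @export
write_ped <- function(pedigrees, path) {
  sex <- c(male = "1", female = "2", unknown = "0")[pedigrees$sex]
  lines <- paste(pedigrees$family_id, pedigrees$sample_id,
                 ifelse(is.na(pedigrees$father_id), "0", pedigrees$father_id),
                 ifelse(is.na(pedigrees$mother_id), "0", pedigrees$mother_id),
                 sex, ifelse(pedigrees$affected, "2", "1"), sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read exon targets from BED
#'
#' 4-column BED (chrom, start, end, name) with names `GENE_exonIndex`;
#' 0-based half-open coordinates. Output is sorted by chromosome and start.
#'
#' @param path BED file path.
#' @return Exon target data.frame.
#' @export
read_targets <- function(path) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "start", "end", "name"),
                           stringsAsFactors = FALSE)
  if (any(bed$end <= bed$start))
    stop("BED interval with end <= start at line ",
         which(bed$end <= bed$start)[1])
  targets <- data.frame(
    chrom = bed$chrom, start = bed$start, end = bed$end,
    gene = sub("_[^_]*$", "", bed$name),
    exon_index = as.integer(sub(".*_", "", bed$name)),
    stringsAsFactors = FALSE)
  targets <- targets[order(chrom_rank(targets$chrom), targets$start), ]
  rownames(targets) <- NULL
  targets
}

#' Write exon targets as BED
#'
#' @param targets Exon target data.frame.
#' @param path Output path.
#' @export
write_targets <- function(targets, path) {
  lines <- paste(targets$chrom, targets$start, targets$end,
                 paste0(targets$gene, "_", targets$exon_index), sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read an exon read-count matrix from TSV
#'
#' First column `exon_id`, one integer column per sample.
#'
#' @param path TSV path.
#' @return Integer matrix, exons x samples.
#' @export
read_counts <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- tab[[1]]
  m
}

#' Write an exon read-count matrix as TSV
#'
#' @param counts Integer matrix, exons x samples.
#' @param path Output path.
#' @export
write_counts <- function(counts, path) {
  tab <- data.frame(exon_id = rownames(counts), counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a CNV call table (TSV with header)
#'
#' Columns as produced by [call_cnvs()]; extra columns pass through.
#'
#' @param path TSV path.
#' @return Call data.frame.
#' @export
read_calls <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
}

#' @rdname read_calls
#' @param calls Call data.frame.
#' @export
write_calls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read / write a population CNV-frequency table (TSV with header)
#'
#' Columns `gene`, `database`, `sample_size`, `freq_het_loss`,
#' `freq_het_loss_east_asia` (NA when unavailable).
#'
#' @param path TSV path.
#' @return Frequency data.frame.
#' @export
read_popfreq <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
}

#' @rdname read_popfreq
#' @param popfreq Frequency data.frame.
#' @export
write_popfreq <- function(popfreq, path) {
  utils::write.table(popfreq, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a qPCR Ct table (TSV with header)
#'
#' Columns `sample_id`, `target_locus`, `ct_target`, `ct_reference`
#' (triplicate means).
#'
#' @param path TSV path.
#' @return Measurement data.frame for [qpcr_relative_quantity()].
#' @export
read_qpcr <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
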