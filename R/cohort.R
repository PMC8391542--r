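#' Cohort specification for the synthetic family simulator
#'
#' Describes a family-structured exome cohort: how many quintets (patient + 4
#' unaffected members), quartets (+3), trios (+2 parents), duos (+1 parent) and
#' singleton patients to generate, plus the count-noise parameters. The default
#' composition is the congenital-hemivertebrae study design of 67 patients with
#' 125 participating relatives (2 quintets, 14 quartets, 33 trios, 9 duos, 9
#' singletons).
#'
#' @param n_quintets,n_quartets,n_trios,n_duos,n_singletons Non-negative family
#'   counts.
#' @param mean_depth Expected read count on a diploid exon of average length.
#' @param depth_dispersion Negative-binomial overdispersion of per-exon counts
#'   (variance = mu + dispersion * mu^2); 0 gives Poisson noise. The default
#'   0.01 (variance twice Poisson at 100x) reflects the residual
#'   sample-to-sample noise left after reference matching, the regime exon
#'   read-depth callers are designed for; exon-to-exon capture efficiency
#'   differences cancel between test and reference and are not simulated.
#' @param mismap_rate Background mis-mapping rate: a fraction of the diploid
#'   expectation added to every exon regardless of copy number, so homozygous
#'   deletions can show small nonzero observed/expected ratios rather than
#'   exactly 0. Default 0.
#' @param seed Integer random seed used by the generators.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_quintets = 2L, n_quartets = 14L, n_trios = 33L,
                        n_duos = 9L, n_singletons = 9L,
                        mean_depth = 100, depth_dispersion = 0.01,
                        mismap_rate = 0, seed = 1L) {
  counts <- c(n_quintets, n_quartets, n_trios, n_duos, n_singletons)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("family counts must be non-negative integers")
  if (mean_depth <= 0) stop("mean_depth must be > 0")
  if (depth_dispersion < 0) stop("depth_dispersion must be >= 0")
  if (mismap_rate < 0) stop("mismap_rate must be >= 0")
  structure(list(
    n_quintets = as.integer(n_quintets), n_quartets = as.integer(n_quartets),
    n_trios = as.integer(n_trios), n_duos = as.integer(n_duos),
    n_singletons = as.integer(n_singletons),
    mean_depth = mean_depth, depth_dispersion = depth_dispersion,
    mismap_rate = mismap_rate, seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Generate family pedigrees
#'
#' Builds one family per requested unit with exactly one affected child (the
#' patient). Quintets and quartets consist of the patient, both parents, and
#' two or one unaffected siblings; trios add both parents; duos add one parent
#' (the mother, by convention); singletons are the patient alone. Sample ids
#' are `<FAM>P` (patient), `<FAM>F`/`<FAM>M` (father/mother), `<FAM>S1`,
#' `<FAM>S2` (siblings).
#'
#' @param spec A [cohort_spec()].
#' @return A data.frame of pedigree records with columns `family_id`,
#'   `sample_id`, `father_id`, `mother_id`, `sex` (`male`/`female`/`unknown`),
#'   `affected` (logical). Unknown parents are `NA`.
#' @export
generate_pedigrees <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  kinds <- rep(c("quintet", "quartet", "trio", "duo", "singleton"),
               c(spec$n_quintets, spec$n_quartets, spec$n_trios,
                 spec$n_duos, spec$n_singletons))
  rows <- vector("list", length(kinds))
  for (i in seq_along(kinds)) {
    fam <- sprintf("F%03d", i)
    kind <- kinds[i]
    pid <- paste0(fam, "P")
    p_sex <- sample(c("male", "female"), 1L)
    has_father <- kind %in% c("quintet", "quartet", "trio")
    has_mother <- kind %in% c("quintet", "quartet", "trio", "duo")
    fa <- if (has_father) paste0(fam, "F") else NA_character_
    mo <- if (has_mother) paste0(fam, "M") else NA_character_
    out <- data.frame(
      family_id = fam, sample_id = pid, father_id = fa, mother_id = mo,
      sex = p_sex, affected = TRUE, stringsAsFactors = FALSE
    )
    if (has_father)
      out <- rbind(out, data.frame(family_id = fam, sample_id = fa,
                                   father_id = NA_character_, mother_id = NA_character_,
                                   sex = "male", affected = FALSE))
    if (has_mother)
      out <- rbind(out, data.frame(family_id = fam, sample_id = mo,
                                   father_id = NA_character_, mother_id = NA_character_,
                                   sex = "female", affected = FALSE))
    n_sibs <- switch(kind, quintet = 2L, quartet = 1L, 0L)
    if (n_sibs > 0L) {
      for (s in seq_len(n_sibs)) {
        out <- rbind(out, data.frame(
          family_id = fam, sample_id = paste0(fam, "S", s),
          father_id = fa, mother_id = mo,
          sex = sample(c("male", "female"), 1L), affected = FALSE))
      }
    }
    rows[[i]] <- out
  }
  ped <- do.call(rbind, rows)
  rownames(ped) <- NULL
  ped
}

#' Generate non-overlapping exon targets
#'
#' Lays out `n_genes` genes along autosomes, each with a uniformly drawn number
#' of exons and exon lengths, separated by inter-exon gaps. Targets are 0-based
#' half-open intervals, sorted and non-overlapping within a chromosome.
#'
#' @param n_genes Number of genes.
#' @param exons_per_gene_range Integer range (min, max) of exons per gene.
#' @param exon_len_range Range of exon lengths in bp.
#' @param gap_range Range of gaps between consecutive exons in bp; the gap
#'   between genes is 10x the drawn value.
#' @param seed Random seed.
#' @param genes_per_chrom Genes placed per chromosome before moving to the next.
#' @return A data.frame with columns `chrom`, `start`, `end`, `gene`,
#'   `exon_index` (1-based within gene).
#' @export
generate_exon_targets <- function(n_genes, exons_per_gene_range = c(2L, 30L),
                                  exon_len_range = c(80L, 300L),
                                  gap_range = c(500L, 5000L), seed = 1L,
                                  genes_per_chrom = 10L) {
  stopifnot(n_genes >= 1,
            all(exons_per_gene_range >= 1), all(exon_len_range >= 1),
            all(gap_range >= 1))
  set.seed(seed)
  runi <- function(rng) if (rng[1] == rng[2]) rng[1] else sample(rng[1]:rng[2], 1L)
  rows <- list()
  pos <- 10000L
  chrom_i <- 1L
  for (g in seq_len(n_genes)) {
    if (g > 1L && (g - 1L) %% genes_per_chrom == 0L) {
      chrom_i <- chrom_i + 1L
      pos <- 10000L
    }
    gene <- sprintf("G%03d", g)
    n_ex <- runi(exons_per_gene_range)
    for (e in seq_len(n_ex)) {
      len <- runi(exon_len_range)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = paste0("chr", chrom_i), start = pos, end = pos + len,
        gene = gene, exon_index = e, stringsAsFactors = FALSE)
      pos <- pos + len + runi(gap_range)
    }
    pos <- pos + 10L * runi(gap_range)
  }
  targets <- do.call(rbind, rows)
  targets <- targets[order(chrom_rank(targets$chrom), targets$start), ]
  rownames(targets) <- NULL
  targets
}

# numeric ordering of chr1..chr22 then others, so "chr10" sorts after "chr9"
chrom_rank <- function(chrom) {
  num <- suppressWarnings(as.numeric(sub("^chr", "", chrom)))
  num[is.na(num)] <- 1000 + as.integer(factor(chrom[is.na(num)]))
  num
}

#' Implant ground-truth CNVs into a cohort
#'
#' Places `n_events` CNV events, each spanning 1-30 whole exons of a single
#' gene, into randomly chosen patients. Heterozygous events (copy 1 deletions
#' or copy 3 duplications) may be de novo or inherited from one parent, in
#' which case the identical event is added to that parent's truth set.
#' Homozygous deletions (copy 0) are always de novo and placed only in
#' patients, supporting recessive-recovery testing. No gene hosts more than
#' one event.
#'
#' @param pedigrees Pedigree data.frame from [generate_pedigrees()].
#' @param targets Exon targets from [generate_exon_targets()].
#' @param n_events Number of events (must not exceed the number of genes).
#' @param het_fraction Fraction of deletion events that are heterozygous
#'   (copy 1) rather than homozygous (copy 0).
#' @param de_novo_fraction Fraction of heterozygous events that are de novo;
#'   the rest are inherited (paternal/maternal at random among assayed
#'   parents). Patients without assayed parents receive de novo events.
#' @param dup_fraction Fraction of events that are duplications (copy 3).
#' @param max_exons Maximum exons spanned by one event.
#' @param seed Random seed.
#' @return A data.frame of truth records: `sample_id`, `chrom`, `start`, `end`,
#'   `gene`, `type` (`deletion`/`duplication`), `copy_number` (0/1/3), `origin`
#'   (`de_novo`/`paternal`/`maternal`); inherited events appear twice, once for
#'   the patient and once for the carrier parent.
#' @export
implant_cnvs <- function(pedigrees, targets, n_events, het_fraction = 0.8,
                         de_novo_fraction = 0.5, dup_fraction = 0.25,
                         max_exons = 30L, seed = 1L) {
  stopifnot(nrow(targets) > 0)
  genes <- unique(targets$gene)
  if (n_events > length(genes))
    stop("n_events (", n_events, ") exceeds the number of available genes (",
         length(genes), ")")
  set.seed(seed)
  patients <- pedigrees$sample_id[pedigrees$affected]
  ev_genes <- sample(genes, n_events)
  rows <- list()
  for (gene in ev_genes) {
    ex <- targets[targets$gene == gene, ]
    ex <- ex[order(ex$exon_index), ]
    span <- sample(seq_len(min(max_exons, nrow(ex))), 1L)
    first <- sample(seq_len(nrow(ex) - span + 1L), 1L)
    seg <- ex[first:(first + span - 1L), ]
    pid <- if (length(patients) == 1L) patients else sample(patients, 1L)
    is_dup <- stats::runif(1) < dup_fraction
    if (is_dup) {
      type <- "duplication"; cn <- 3L
    } else {
      type <- "deletion"
      cn <- if (stats::runif(1) < het_fraction) 1L else 0L
    }
    ped_row <- pedigrees[pedigrees$sample_id == pid, ]
    parents <- c(paternal = ped_row$father_id, maternal = ped_row$mother_id)
    parents <- parents[!is.na(parents)]
    origin <- "de_novo"
    if (cn != 0L && length(parents) > 0L && stats::runif(1) >= de_novo_fraction) {
      side <- if (length(parents) == 1L) 1L else sample(length(parents), 1L)
      origin <- names(parents)[side]
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = unname(parents[side]), chrom = seg$chrom[1],
        start = min(seg$start), end = max(seg$end), gene = gene,
        type = type, copy_number = cn, origin = "de_novo",
        stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = pid, chrom = seg$chrom[1],
      start = min(seg$start), end = max(seg$end), gene = gene,
      type = type, copy_number = cn, origin = origin,
      stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, rows)
  rownames(truth) <- NULL
  truth
}

#' Simulate an exon read-count matrix
#'
#' Draws one count per sample and exon from a negative-binomial (Poisson-gamma)
#' model. The expectation is `mean_depth * (c/2) * L`, where `c` is the
#' sample's copy number at the exon (2 unless a truth record overlaps) and `L`
#' is the exon length divided by the mean exon length — standard capture
#' behaviour where longer exons attract proportionally more reads. A
#' `mismap_rate` fraction of the diploid expectation is added to every exon,
#' so copy-0 exons keep a small positive expectation when the rate is nonzero.
#'
#' @param pedigrees Pedigree data.frame; one matrix column per sample.
#' @param targets Exon targets; one row per exon, identified as
#'   `<gene>_<exon_index>`.
#' @param truth Truth CNV data.frame from [implant_cnvs()] (or NULL for a
#'   CNV-free cohort).
#' @param spec A [cohort_spec()]; supplies depth, dispersion, mis-mapping rate
#'   and seed.
#' @return An integer matrix, exons x samples, with exon ids as rownames.
#' @export
simulate_read_counts <- function(pedigrees, targets, truth, spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  samples <- pedigrees$sample_id
  exon_id <- paste0(targets$gene, "_", targets$exon_index)
  lf <- (targets$end - targets$start) / mean(targets$end - targets$start)
  cn <- matrix(2, nrow = nrow(targets), ncol = length(samples),
               dimnames = list(exon_id, samples))
  if (!is.null(truth) && nrow(truth) > 0) {
    for (k in seq_len(nrow(truth))) {
      hit <- targets$chrom == truth$chrom[k] &
        targets$start < truth$end[k] & targets$end > truth$start[k]
      cn[hit, truth$sample_id[k]] <- truth$copy_number[k]
    }
  }
  mu <- spec$mean_depth * lf * (cn / 2) + spec$mean_depth * lf * spec$mismap_rate
  n <- length(mu)
  counts <- if (spec$depth_dispersion > 0) {
    stats::rnbinom(n, mu = mu, size = 1 / spec$depth_dispersion)
  } else {
    stats::rpois(n, mu)
  }
  matrix(as.integer(counts), nrow = nrow(targets), ncol = length(samples),
         dimnames = list(exon_id, samples))
}

#' Generate a companion population CNV-frequency table
#'
#' Emulates DGV- and gnomAD-SV-style records of heterozygous-loss frequency per
#' gene. Implanted genes always receive rare frequencies (< 0.01 in every
#' record); a configurable fraction of the remaining background genes is
#' "common" (frequency in `background_af_range`, above the 0.01 exclusion
#' threshold) so the allele-frequency filter has something to remove; and a
#' fraction of background genes additionally receives a small-cohort record
#' (sample_size < 100) with an inflated frequency, which frequency filtering
#' must ignore under the minimum-sample-size rule.
#'
#' @param targets Exon targets (gene universe).
#' @param implanted_genes Character vector of genes carrying implanted CNVs.
#' @param background_af_range Frequency range for common background genes.
#' @param common_fraction Fraction of background genes made common.
#' @param smalln_fraction Fraction of background genes given an extra
#'   ineligible (sample_size 50) record.
#' @param seed Random seed.
#' @return A data.frame with columns `gene`, `database` (`DGV-like` /
#'   `gnomAD-like`), `sample_size`, `freq_het_loss`,
#'   `freq_het_loss_east_asia` (NA for DGV-like records).
#' @export
generate_popfreq_table <- function(targets, implanted_genes = character(),
                                   background_af_range = c(0.02, 0.2),
                                   common_fraction = 0.2,
                                   smalln_fraction = 0.1, seed = 1L) {
  set.seed(seed)
  genes <- unique(targets$gene)
  background <- setdiff(genes, implanted_genes)
  n_common <- round(common_fraction * length(background))
  common <- if (n_common > 0) sample(background, n_common) else character()
  rows <- list()
  for (gene in genes) {
    if (gene %in% common) {
      f_dgv <- stats::runif(1, background_af_range[1], background_af_range[2])
      f_gnm <- stats::runif(1, background_af_range[1], background_af_range[2])
    } else {
      f_dgv <- stats::runif(1, 0, 0.005)
      f_gnm <- stats::runif(1, 0, 0.005)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      gene = gene, database = "DGV-like",
      sample_size = sample(500:20000, 1L),
      freq_het_loss = f_dgv, freq_het_loss_east_asia = NA_real_,
      stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      gene = gene, database = "gnomAD-like",
      sample_size = 10847L,
      freq_het_loss = f_gnm,
      freq_het_loss_east_asia = f_gnm * stats::runif(1),
      stringsAsFactors = FALSE)
    if (!gene %in% implanted_genes && stats::runif(1) < smalln_fraction) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene = gene, database = "DGV-like", sample_size = 50L,
        freq_het_loss = stats::runif(1, 0.02, 0.5),
        freq_het_loss_east_asia = NA_real_, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
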