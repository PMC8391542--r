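#' Build an aggregated reference profile
#'
#' Sums the per-exon counts of the chosen reference (control) samples and fits
#' the two emission parameters used for calling: `phi`, the expected fraction
#' of a test sample's reads among test + reference reads at each exon, and
#' `rho`, the beta-binomial overdispersion. The stored `phi` is estimated per
#' exon from the aggregate of all non-reference samples and documents the
#' pooled test/reference balance; at call time [call_cnvs()] re-estimates a
#' single per-sample phi from the test sample's own count totals, which stray
#' CNV exons barely perturb. `rho` is fitted by method of moments on a
#' half/half split of the reference samples (reference versus reference, so
#' copy-number signal cannot inflate it), floored at 1e-4.
#'
#' Exons whose summed reference count is zero are masked: they carry no
#' information about relative depth and are excluded from calling.
#'
#' @param counts Integer matrix, exons x samples (from
#'   [simulate_read_counts()] or [read_counts()]).
#' @param reference_ids Character vector of reference sample ids (>= 1),
#'   present among the matrix columns.
#' @return An object of class `reference_profile`: `reference_sample_ids`,
#'   `ref_count` (per-exon sum), `phi`, `rho`, `masked` (logical per exon),
#'   `test_total_sum` (pooled total count of the non-reference samples, used
#'   to rescale `phi` to a single sample at call time).
#' @export
build_reference <- function(counts, reference_ids) {
  stopifnot(is.matrix(counts), length(reference_ids) >= 1)
  missing_ids <- setdiff(reference_ids, colnames(counts))
  if (length(missing_ids) > 0)
    stop("unknown reference sample id(s): ", paste(missing_ids, collapse = ", "))
  ref <- counts[, reference_ids, drop = FALSE]
  ref_count <- as.numeric(rowSums(ref))
  masked <- ref_count == 0
  if (any(masked))
    warning(sum(masked), " exon(s) with zero total reference count masked")
  test_ids <- setdiff(colnames(counts), reference_ids)
  if (length(test_ids) > 0) {
    test_total <- as.numeric(rowSums(counts[, test_ids, drop = FALSE]))
    phi <- ifelse(test_total + ref_count > 0,
                  test_total / (test_total + ref_count), NA_real_)
    test_total_sum <- sum(counts[, test_ids, drop = FALSE])
  } else {
    phi <- rep(NA_real_, nrow(counts))
    test_total_sum <- NA_real_
  }
  rho <- fit_rho(ref)
  structure(list(
    reference_sample_ids = reference_ids,
    ref_count = stats::setNames(ref_count, rownames(counts)),
    phi = stats::setNames(phi, rownames(counts)),
    rho = rho,
    masked = stats::setNames(masked, rownames(counts)),
    test_total_sum = test_total_sum
  ), class = "reference_profile")
}

# Method-of-moments overdispersion from a reference-vs-reference split.
# For exon i with split counts (a_i, b_i), n_i = a_i + b_i, the fraction
# a_i/n_i has variance p(1-p)/n * (1 + (n-1) rho) under a beta-binomial.
fit_rho <- function(ref, floor = 1e-4) {
  if (ncol(ref) < 2) return(floor)
  half <- seq_len(ncol(ref)) <= ncol(ref) / 2
  a <- rowSums(ref[, half, drop = FALSE])
  b <- rowSums(ref[, !half, drop = FALSE])
  n <- a + b
  keep <- n > 1
  if (!any(keep)) return(floor)
  a <- a[keep]; n <- n[keep]
  p_bar <- sum(a) / sum(n)
  if (p_bar <= 0 || p_bar >= 1) return(floor)
  v <- (a / n - p_bar)^2
  rho_i <- (v * n / (p_bar * (1 - p_bar)) - 1) / (n - 1)
  max(mean(rho_i), floor)
}

#' Beta-binomial emission log-likelihood
#'
#' Log P(x | x + r) under a beta-binomial whose success fraction is the
#' copy-number-adjusted `phi`: for copy state `c`, the test sample is expected
#' to contribute `phi' = (c/2) phi / ((c/2) phi + (1 - phi))` of the combined
#' test + reference reads. Diploid (`c = 2`) gives `phi' = phi`. For `c = 0`
#' the adjustment uses a small leakage copy number instead of 0 so that stray
#' mis-mapped reads never yield `-Inf`.
#'
#' @param x Test-sample count(s) per exon.
#' @param r Reference count(s) per exon.
#' @param phi Expected diploid test fraction(s), in (0,1).
#' @param rho Beta-binomial overdispersion (>= 0; 0 reduces to binomial).
#' @param copy_state Copy number in {0, 1, 2, 3}.
#' @param leakage Effective copy number substituted for 0 (default 0.02).
#' @return Log-likelihood, vectorized over exons.
#' @export
emission_loglik <- function(x, r, phi, rho, copy_state, leakage = 0.02) {
  stopifnot(all(x >= 0), all(r >= 0), copy_state %in% c(0, 1, 2, 3))
  c_eff <- if (copy_state == 0) leakage else copy_state
  phi2 <- adjust_phi(phi, c_eff)
  n <- x + r
  if (any(n == 0)) stop("emission undefined where x + r == 0 (mask such exons)")
  if (rho <= 0) return(stats::dbinom(x, n, phi2, log = TRUE))
  a <- phi2 * (1 - rho) / rho
  b <- (1 - phi2) * (1 - rho) / rho
  lchoose(n, x) + lbeta(x + a, n - x + b) - lbeta(a, b)
}

# copy-number adjustment of the expected test-read fraction
adjust_phi <- function(phi, c_eff) {
  (c_eff / 2) * phi / ((c_eff / 2) * phi + (1 - phi))
}

# Viterbi decoding over hidden copy states (deletion=1, diploid=2, dup=3
# copies). emat: n x 3 matrix of emission log-likelihoods, columns in state
# order (del, dip, dup). Returns the maximum-probability state path.
viterbi_path <- function(emat, transition_prob = 1e-4, cnv_exit_prob = 0.2) {
  t <- transition_prob; q <- cnv_exit_prob
  trans <- log(rbind(
    del = c(1 - q, q,      0),
    dip = c(t / 2, 1 - t,  t / 2),
    dup = c(0,     q,      1 - q)))
  init <- log(c(t / 2, 1 - t, t / 2))
  n <- nrow(emat)
  delta <- matrix(-Inf, n, 3)
  back <- matrix(0L, n, 3)
  delta[1, ] <- init + emat[1, ]
  if (n > 1) for (i in 2:n) {
    for (s in 1:3) {
      cand <- delta[i - 1, ] + trans[, s]
      back[i, s] <- which.max(cand)
      delta[i, s] <- cand[back[i, s]] + emat[i, s]
    }
  }
  path <- integer(n)
  path[n] <- which.max(delta[n, ])
  if (n > 1) for (i in (n - 1):1) path[i] <- back[i + 1, path[i + 1]]
  c("deletion", "diploid", "duplication")[path]
}

#' Segment observed/expected reads ratio
#'
#' Ratio of the observed test reads over a segment to the reads expected from
#' the reference profile: `sum(x) / sum(phi * (x + r))`. Approximately 0.5 for
#' a heterozygous loss, below 0.1 for a homozygous loss, near 1.5 for a
#' single-copy gain.
#'
#' @param x,r,phi Per-exon test counts, reference counts and expected diploid
#'   test fractions over the segment.
#' @return The ratio (>= 0).
#' @export
compute_reads_ratio <- function(x, r, phi) {
  expected <- sum(phi * (x + r))
  if (expected <= 0) stop("expected segment total is zero")
  sum(x) / expected
}

#' Segment Bayes factor
#'
#' log10 likelihood ratio of the called copy state over the diploid null,
#' summed over the segment's exons. Values above 1 are taken as strong
#' evidence for the CNV; the value can be negative when the data favour the
#' null.
#'
#' @inheritParams compute_reads_ratio
#' @param rho Beta-binomial overdispersion.
#' @param copy_state Alternative-hypothesis copy number (0, 1 or 3).
#' @param leakage Leakage copy number for state 0 (see [emission_loglik()]).
#' @return log10 Bayes factor.
#' @export
compute_bayes_factor <- function(x, r, phi, rho, copy_state, leakage = 0.02) {
  stopifnot(length(x) >= 1)
  alt <- sum(emission_loglik(x, r, phi, rho, copy_state, leakage))
  null <- sum(emission_loglik(x, r, phi, rho, 2))
  (alt - null) / log(10)
}

#' Call CNVs for one test sample
#'
#' Decodes hidden copy states (deletion / diploid / duplication) across the
#' ordered exons of each chromosome by maximum-probability path, then reports
#' each maximal non-diploid run as a call. Call boundaries are the first
#' exon's start and the last exon's end. Deletions are refined to homozygous
#' (copy 0) when the segment observed/expected ratio falls below
#' `hom_threshold`, otherwise heterozygous (copy 1); the Bayes factor is
#' computed against the refined state.
#'
#' @param test_sample Sample id (a column of `counts`).
#' @param counts Exon x sample count matrix; rownames `<gene>_<exon_index>`
#'   matching `targets`.
#' @param profile A [build_reference()] profile.
#' @param targets Exon target data.frame supplying coordinates and gene
#'   annotation.
#' @param transition_prob Per-exon-boundary probability of leaving the diploid
#'   state (split equally between deletion and duplication).
#' @param cnv_exit_prob Probability of returning to diploid from a CNV state.
#' @param hom_threshold Reads-ratio threshold below which a deletion is called
#'   homozygous.
#' @param leakage Leakage copy number for homozygous emission.
#' @return A data.frame of calls: `sample_id`, `type`, `chrom`, `start`,
#'   `end`, `size`, `copy_state`, `bayes_factor`, `reads_ratio`,
#'   `exon_annotation` (`GENE_a-b` per overlapped gene, comma-separated).
#' @export
call_cnvs <- function(test_sample, counts, profile, targets,
                      transition_prob = 1e-4, cnv_exit_prob = 0.2,
                      hom_threshold = 0.1, leakage = 0.02) {
  stopifnot(inherits(profile, "reference_profile"))
  if (!test_sample %in% colnames(counts))
    stop("unknown test sample: ", test_sample)
  if (test_sample %in% profile$reference_sample_ids)
    warning("test sample ", test_sample,
            " is part of the reference set; calling anyway")
  exon_id <- paste0(targets$gene, "_", targets$exon_index)
  if (!all(exon_id %in% rownames(counts)))
    stop("targets contain exons absent from the count matrix")
  x_all <- counts[exon_id, test_sample]
  r_all <- as.numeric(profile$ref_count[exon_id])
  # Single per-sample phi from count totals. A per-exon estimate from the
  # pooled test samples absorbs the carriers' own CNVs at exactly the exons
  # under test (diluting the evidence in small cohorts); totals are perturbed
  # only by the few CNV exons, so the constant estimate is nearly unbiased
  # while exon-to-exon capture variation cancels between x and r.
  usable <- !profile$masked[exon_id] & (x_all + r_all) > 0
  phi_s <- sum(x_all[usable]) / sum(x_all[usable] + r_all[usable])
  phi_all <- rep(phi_s, length(x_all))
  ord <- order(chrom_rank(targets$chrom), targets$start)
  calls <- list()
  for (chr in unique(targets$chrom[ord])) {
    idx <- ord[targets$chrom[ord] == chr]
    idx <- idx[usable[idx]]
    if (length(idx) == 0) next
    x <- x_all[idx]; r <- r_all[idx]; phi <- phi_all[idx]
    emat <- cbind(
      emission_loglik(x, r, phi, profile$rho, 1),
      emission_loglik(x, r, phi, profile$rho, 2),
      emission_loglik(x, r, phi, profile$rho, 3))
    path <- viterbi_path(emat, transition_prob, cnv_exit_prob)
    rl <- rle(path)
    seg_end <- cumsum(rl$lengths)
    seg_start <- seg_end - rl$lengths + 1L
    for (s in seq_along(rl$values)) {
      if (rl$values[s] == "diploid") next
      seg <- idx[seg_start[s]:seg_end[s]]
      sx <- x_all[seg]; sr <- r_all[seg]; sphi <- phi_all[seg]
      ratio <- compute_reads_ratio(sx, sr, sphi)
      type <- rl$values[s]
      cs <- if (type == "deletion") {
        if (ratio < hom_threshold) 0L else 1L
      } else 3L
      bf <- compute_bayes_factor(sx, sr, sphi, profile$rho, cs, leakage)
      seg_t <- targets[seg, ]
      calls[[length(calls) + 1L]] <- data.frame(
        sample_id = test_sample, type = type, chrom = chr,
        start = min(seg_t$start), end = max(seg_t$end),
        size = max(seg_t$end) - min(seg_t$start),
        copy_state = cs, bayes_factor = bf, reads_ratio = ratio,
        exon_annotation = annotation_string(seg_t),
        stringsAsFactors = FALSE)
    }
  }
  if (length(calls) == 0) return(empty_calls())
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}

# "GENE_a-b" (or "GENE_a") per gene, in positional order of the segment exons
annotation_string <- function(seg_targets) {
  parts <- vapply(unique(seg_targets$gene), function(g) {
    ex <- seg_targets$exon_index[seg_targets$gene == g]
    if (min(ex) == max(ex)) paste0(g, "_", min(ex))
    else paste0(g, "_", min(ex), "-", max(ex))
  }, character(1))
  paste(parts, collapse = ",")
}

empty_calls <- function() {
  data.frame(sample_id = character(), type = character(), chrom = character(),
             start = integer(), end = integer(), size = integer(),
             copy_state = integer(), bayes_factor = numeric(),
             reads_ratio = numeric(), exon_annotation = character(),
             stringsAsFactors = FALSE)
}

#' Call CNVs for every non-reference sample
#'
#' Convenience wrapper running [call_cnvs()] over all samples not in the
#' reference set and row-binding the results.
#'
#' @inheritParams call_cnvs
#' @param samples Samples to call; defaults to all columns of `counts` outside
#'   the reference set.
#' @param ... Passed to [call_cnvs()].
#' @return Combined call data.frame.
#' @export
call_cohort <- function(counts, profile, targets, samples = NULL, ...) {
  if (is.null(samples))
    samples <- setdiff(colnames(counts), profile$reference_sample_ids)
  out <- lapply(samples, call_cnvs, counts = counts, profile = profile,
                targets = targets, ...)
  res <- do.call(rbind, out)
  if (is.null(res)) empty_calls() else res
}
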