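#' Classify the inheritance pattern of one patient call
#'
#' A parent "carries" a patient's variant when that parent has a call of the
#' same type that either shares an annotated gene with the patient call
#' (`overlap_rule = "gene"`, the default — inherited calls may differ in
#' boundaries between family members) or reciprocally overlaps it by at least
#' `min_reciprocal` (`overlap_rule = "interval"`). With both parents assayed:
#' neither carries = de novo; exactly the father = paternal; exactly the
#' mother = maternal; both = biparental. When either parent is not assayed
#' the pattern is not determined. Unaffected siblings, when assayed, are
#' additionally checked and their carrier status reported.
#'
#' @param patient_call One-row call data.frame for an affected sample.
#' @param all_calls Call data.frame for the whole cohort (parents' and
#'   siblings' calls are looked up here).
#' @param pedigrees Pedigree data.frame.
#' @param overlap_rule `"gene"` (default) or `"interval"`.
#' @param min_reciprocal Minimum reciprocal overlap for interval mode.
#' @return A list: `pattern` (one of `de_novo`, `paternal`, `maternal`,
#'   `biparental`, `not_determined`), `sibling_checked` (any unaffected
#'   sibling assayed), `sibling_absent` (no assayed sibling carries it;
#'   NA when none assayed).
#' @export
classify_inheritance <- function(patient_call, all_calls, pedigrees,
                                 overlap_rule = c("gene", "interval"),
                                 min_reciprocal = 0.5) {
  overlap_rule <- match.arg(overlap_rule)
  stopifnot(nrow(patient_call) == 1)
  ped <- pedigrees[pedigrees$sample_id == patient_call$sample_id, ]
  if (nrow(ped) != 1)
    stop("sample absent from pedigree: ", patient_call$sample_id)
  if (!ped$affected)
    stop("inheritance is classified for affected samples only: ",
         patient_call$sample_id)

  assayed <- function(id) !is.na(id) && id %in% pedigrees$sample_id
  carries <- function(id) {
    theirs <- all_calls[all_calls$sample_id == id &
                          all_calls$type == patient_call$type, , drop = FALSE]
    if (nrow(theirs) == 0) return(FALSE)
    if (overlap_rule == "gene") {
      mine <- annotation_genes(patient_call$exon_annotation)[[1]]
      if (length(mine) == 0) return(FALSE)
      any(vapply(annotation_genes(theirs$exon_annotation),
                 function(g) any(g %in% mine), logical(1)))
    } else {
      same_chr <- theirs[theirs$chrom == patient_call$chrom, , drop = FALSE]
      if (nrow(same_chr) == 0) return(FALSE)
      ov <- pmin(same_chr$end, patient_call$end) -
        pmax(same_chr$start, patient_call$start)
      w_mine <- patient_call$end - patient_call$start
      w_theirs <- same_chr$end - same_chr$start
      any(ov >= min_reciprocal * w_mine & ov >= min_reciprocal * w_theirs)
    }
  }

  sibs <- pedigrees$sample_id[
    pedigrees$family_id == ped$family_id & !pedigrees$affected &
      !is.na(pedigrees$father_id) & !is.na(pedigrees$mother_id) &
      pedigrees$sample_id != ped$sample_id]
  sib_checked <- length(sibs) > 0
  sib_absent <- if (sib_checked) !any(vapply(sibs, carries, logical(1)))
                else NA

  if (!assayed(ped$father_id) || !assayed(ped$mother_id))
    return(list(pattern = "not_determined", sibling_checked = sib_checked,
                sibling_absent = sib_absent))
  fa <- carries(ped$father_id)
  mo <- carries(ped$mother_id)
  pattern <- if (fa && mo) "biparental" else if (fa) "paternal" else
    if (mo) "maternal" else "de_novo"
  list(pattern = pattern, sibling_checked = sib_checked,
       sibling_absent = sib_absent)
}

#' Classify inheritance for a table of patient calls
#'
#' Runs [classify_inheritance()] on every affected-sample call and appends
#' `inheritance` (report labels `De novo`, `Paternal`, `Maternal`,
#' `Biparental`, `N.D.`), `sibling_checked` and `sibling_absent` columns.
#'
#' @param calls Call data.frame (affected samples' rows are classified;
#'   rows of unaffected samples get NA columns).
#' @param all_calls Call set in which relatives' carrier status is looked up;
#'   defaults to `calls`. Pass the unfiltered cohort call set when `calls`
#'   is a filtered subset, so that a parent's call that did not survive the
#'   same filter still counts as carriage.
#' @inheritParams classify_inheritance
#' @return `calls` with the three added columns.
#' @export
classify_inheritance_all <- function(calls, pedigrees, all_calls = calls,
                                     overlap_rule = c("gene", "interval"),
                                     min_reciprocal = 0.5) {
  overlap_rule <- match.arg(overlap_rule)
  labels <- c(de_novo = "De novo", paternal = "Paternal",
              maternal = "Maternal", biparental = "Biparental",
              not_determined = "N.D.")
  n <- nrow(calls)
  calls$inheritance <- rep(NA_character_, n)
  calls$sibling_checked <- rep(NA, n)
  calls$sibling_absent <- rep(NA, n)
  if (n == 0) return(calls)
  affected_ids <- pedigrees$sample_id[pedigrees$affected]
  for (i in seq_len(n)) {
    if (!calls$sample_id[i] %in% affected_ids) next
    res <- classify_inheritance(calls[i, , drop = FALSE], all_calls,
                                pedigrees, overlap_rule, min_reciprocal)
    calls$inheritance[i] <- labels[[res$pattern]]
    calls$sibling_checked[i] <- res$sibling_checked
    calls$sibling_absent[i] <- res$sibling_absent
  }
  calls
}

#' Detect homozygous (recessive) deletion calls
#'
#' Returns the deletion calls whose observed/expected reads ratio is strictly
#' below `hom_threshold` — complete loss of both copies leaves at most stray
#' mis-mapped reads, so the segment ratio collapses towards 0.
#'
#' @param calls Call data.frame with `type` and `reads_ratio`.
#' @param hom_threshold Strict upper bound on the ratio (default 0.1).
#' @return The homozygous deletion calls.
#' @export
detect_recessive <- function(calls, hom_threshold = 0.1) {
  stopifnot(!any(is.na(calls$reads_ratio)))
  calls[calls$type == "deletion" & calls$reads_ratio < hom_threshold, ,
        drop = FALSE]
}

#' Patient-unique homozygous calls
#'
#' Removes patient homozygous calls in genes where any control also carries a
#' homozygous call (gene-level matching): shared homozygous losses are benign
#' copy-number polymorphisms, not recessive candidates.
#'
#' @param hom_patient_calls Annotated homozygous calls of affected samples.
#' @param hom_control_calls Annotated homozygous calls of unaffected samples.
#' @return The patient calls whose genes carry no control homozygous call.
#' @export
patient_unique_homozygous <- function(hom_patient_calls, hom_control_calls) {
  if (nrow(hom_patient_calls) == 0 || nrow(hom_control_calls) == 0)
    return(hom_patient_calls)
  control_genes <- unique(unlist(
    annotation_genes(hom_control_calls$exon_annotation)))
  keep <- vapply(annotation_genes(hom_patient_calls$exon_annotation),
                 function(g) length(g) > 0 && !any(g %in% control_genes),
                 logical(1))
  hom_patient_calls[keep, , drop = FALSE]
}
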