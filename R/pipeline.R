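#' Run the full CNV analysis pipeline
#'
#' Orchestrates simulate (optional) -> reference build -> per-sample calling
#' -> genome-wide filtering (BF, size) -> gene-based AF filtering ->
#' inheritance classification -> the three report surfaces (candidate-gene
#' screen, patient-unique recessive screen, novel-CNV enrichment). The
#' candidate path applies BF and AF filters but bypasses the size filter.
#' All intermediate tables, the three reports and a run log with the seed,
#' thresholds and per-stage survivor counts are written to `out_dir`.
#'
#' @param config A named list (or path to a YAML file holding one) with
#'   elements:
#'   \describe{
#'     \item{out_dir}{output directory (created if needed).}
#'     \item{seed}{integer seed for the simulation branch.}
#'     \item{cohort}{list of [cohort_spec()] arguments (simulation branch).}
#'     \item{simulate}{list of simulation parameters: `n_genes`,
#'       `n_events`, `het_fraction`, `de_novo_fraction`, `dup_fraction`.}
#'     \item{counts, targets, ped, popfreq}{paths to pre-computed inputs
#'       (used instead of simulation when all four are given).}
#'     \item{reference_samples}{reference sample ids; defaults to the first
#'       4 unaffected samples free of implanted CNVs.}
#'     \item{candidates}{candidate gene symbols
#'       (default [default_candidate_genes()]).}
#'     \item{thresholds}{list of [filter_thresholds()] arguments.}
#'     \item{transition_prob}{per-exon CNV transition probability.}
#'   }
#' @return Invisibly, a list with `calls`, `filtered_calls`,
#'   `candidate_report`, `recessive_report`, `novel_report`, `log` (the
#'   per-stage survivor counts) and the paths written.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out_dir <- config$out_dir %||% stop("config$out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  thresholds <- do.call(filter_thresholds, config$thresholds %||% list())
  transition_prob <- config$transition_prob %||% 1e-4
  log <- list(seed = config$seed %||% NA_integer_,
              thresholds = unclass(thresholds))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  if (!is.null(config$counts) && !is.null(config$targets) &&
      !is.null(config$ped)) {
    counts <- stage("load", read_counts(config$counts))
    targets <- stage("load", read_targets(config$targets))
    ped <- stage("load", read_ped(config$ped))
    popfreq <- if (!is.null(config$popfreq))
      stage("load", read_popfreq(config$popfreq)) else NULL
    truth <- NULL
  } else {
    sim <- config$simulate %||% list()
    spec_args <- config$cohort %||% list()
    spec_args$seed <- config$seed %||% spec_args$seed %||% 1L
    spec <- do.call(cohort_spec, spec_args)
    ped <- stage("simulate", generate_pedigrees(spec))
    targets <- stage("simulate", generate_exon_targets(
      n_genes = sim$n_genes %||% 40L, seed = spec$seed))
    truth <- stage("simulate", implant_cnvs(
      ped, targets, n_events = sim$n_events %||% 10L,
      het_fraction = sim$het_fraction %||% 0.8,
      de_novo_fraction = sim$de_novo_fraction %||% 0.5,
      dup_fraction = sim$dup_fraction %||% 0.25, seed = spec$seed))
    counts <- stage("simulate", simulate_read_counts(ped, targets, truth, spec))
    popfreq <- stage("simulate", generate_popfreq_table(
      targets, implanted_genes = unique(truth$gene), seed = spec$seed))
    write_ped(ped, file.path(out_dir, "pedigree.ped"))
    write_targets(targets, file.path(out_dir, "targets.bed"))
    write_counts(counts, file.path(out_dir, "counts.tsv"))
    write_calls(truth, file.path(out_dir, "truth_cnvs.tsv"))
    write_popfreq(popfreq, file.path(out_dir, "popfreq.tsv"))
  }

  reference_ids <- config$reference_samples %||% {
    carriers <- if (is.null(truth)) character() else unique(truth$sample_id)
    pool <- setdiff(ped$sample_id[!ped$affected], carriers)
    if (length(pool) < 4) stop("fewer than 4 CNV-free controls for reference")
    pool[1:4]
  }
  profile <- stage("reference", build_reference(counts, reference_ids))

  calls <- stage("call", call_cohort(counts, profile, targets,
                                     transition_prob = transition_prob))
  calls <- stage("annotate", annotate_genes(calls, targets))
  write_calls(calls, file.path(out_dir, "calls.tsv"))
  log$n_calls <- nrow(calls)
  log$n_distinct <- count_distinct(calls)

  # genome-wide path: BF -> size -> gene-based AF
  bf_kept <- stage("filter_bf", filter_by_bf(calls, thresholds))
  log$n_after_bf <- nrow(bf_kept)
  size_kept <- stage("filter_size", filter_by_size(bf_kept, thresholds))
  log$n_after_size <- nrow(size_kept)
  af_res <- stage("filter_af", gene_max_af(size_kept, popfreq, thresholds))
  filtered <- af_res$calls
  log$n_after_af <- nrow(filtered)
  write_calls(filtered, file.path(out_dir, "calls_filtered.tsv"))

  inh <- stage("inherit",
               classify_inheritance_all(filtered, ped, all_calls = calls))
  write_calls(inh, file.path(out_dir, "calls_inheritance.tsv"))

  candidates <- config$candidates %||% default_candidate_genes()
  candidate_report <- stage("prioritize", candidate_gene_screen(
    calls, ped, candidates, popfreq, thresholds))
  recessive_report <- stage("prioritize", recessive_screen(
    calls, ped, popfreq, thresholds))
  novel_report <- stage("prioritize", novel_screen(
    filtered, ped, popfreq, thresholds))
  write_calls(candidate_report, file.path(out_dir, "report_candidate.tsv"))
  write_calls(recessive_report, file.path(out_dir, "report_recessive.tsv"))
  write_calls(novel_report, file.path(out_dir, "report_novel.tsv"))
  log$n_candidate_rows <- nrow(candidate_report)
  log$n_recessive_rows <- nrow(recessive_report)
  log$n_novel_genes <- nrow(novel_report)

  log_lines <- c(
    paste0("seed: ", log$seed),
    paste0("thresholds: ", paste(names(log$thresholds),
                                 unlist(log$thresholds), sep = "=",
                                 collapse = " ")),
    paste0("reference_samples: ", paste(reference_ids, collapse = ",")),
    paste0("calls: ", log$n_calls, " (", log$n_distinct, " distinct)"),
    paste0("after_bf: ", log$n_after_bf),
    paste0("after_size: ", log$n_after_size),
    paste0("after_af: ", log$n_after_af),
    paste0("candidate_rows: ", log$n_candidate_rows),
    paste0("recessive_rows: ", log$n_recessive_rows),
    paste0("novel_genes: ", log$n_novel_genes))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))

  invisible(list(calls = calls, filtered_calls = filtered,
                 candidate_report = candidate_report,
                 recessive_report = recessive_report,
                 novel_report = novel_report,
                 truth = truth, pedigrees = ped, targets = targets,
                 popfreq = popfreq, profile = profile, log = log,
                 out_dir = out_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
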