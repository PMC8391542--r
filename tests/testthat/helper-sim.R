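# Shared small-cohort builders for caller tests.

# Two-family cohort (one quartet, one trio) with one het deletion of `span`
# exons implanted in the trio patient F002P; returns everything a calling
# test needs.
sim_het_del <- function(seed, span = 4L, mean_depth = 100,
                        depth_dispersion = 0.01) {
  spec <- cohort_spec(n_quintets = 0, n_quartets = 1, n_trios = 1,
                      n_duos = 0, n_singletons = 0, mean_depth = mean_depth,
                      depth_dispersion = depth_dispersion, seed = seed)
  ped <- generate_pedigrees(spec)
  targets <- generate_exon_targets(15, exons_per_gene_range = c(6L, 12L),
                                   seed = seed)
  gene <- unique(targets$gene)[7]
  ex <- targets[targets$gene == gene, ][2:(1 + span), ]
  truth <- data.frame(sample_id = "F002P", chrom = ex$chrom[1],
                      start = min(ex$start), end = max(ex$end), gene = gene,
                      type = "deletion", copy_number = 1L, origin = "de_novo")
  counts <- simulate_read_counts(ped, targets, truth, spec)
  refs <- setdiff(ped$sample_id[!ped$affected], "F002P")[1:4]
  profile <- suppressWarnings(build_reference(counts, refs))
  list(spec = spec, ped = ped, targets = targets, truth = truth,
       counts = counts, refs = refs, profile = profile)
}

# deterministic CNV-free reference/test setup on a fixed exon grid
sim_flat <- function(seed, n_samples = 6, n_exons = 120, mean_depth = 100,
                     depth_dispersion = 0.01) {
  spec <- cohort_spec(0, 0, 0, 0, n_samples, mean_depth = mean_depth,
                      depth_dispersion = depth_dispersion, seed = seed)
  ped <- generate_pedigrees(spec)
  targets <- generate_exon_targets(n_exons / 6, c(6L, 6L), seed = seed)
  counts <- simulate_read_counts(ped, targets, NULL, spec)
  list(spec = spec, ped = ped, targets = targets, counts = counts)
}

# convert truth records into idealized ("perfect caller") call rows
truth_to_calls <- function(truth, targets) {
  calls <- data.frame(
    sample_id = truth$sample_id, type = truth$type, chrom = truth$chrom,
    start = truth$start, end = truth$end, size = truth$end - truth$start,
    copy_state = truth$copy_number,
    bayes_factor = 10, reads_ratio = ifelse(truth$copy_number == 0, 0,
                                            truth$copy_number / 2),
    stringsAsFactors = FALSE)
  annotate_genes(calls, targets)
}
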