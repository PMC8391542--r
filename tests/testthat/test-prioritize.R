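test_that("candidate screen reproduces the published 12-call table", {
  ped <- read_ped(fixture("cohort.ped"))
  calls <- read_calls(fixture("candidate_calls.tsv"))
  pf <- read_popfreq(fixture("candidate_popfreq.tsv"))
  rep1 <- candidate_gene_screen(calls, ped, popfreq = pf)
  expect_equal(nrow(rep1), 12)
  expect_equal(sort(unique(rep1$gene)),
               c("DSCAM", "NOTCH2", "SNTG1", "TBX6"))
  expect_equal(length(unique(rep1$sample_id)), 12)
  expect_equal(sum(rep1$gene == "TBX6"), 4)
  # inheritance labels match the published patterns
  want <- c(CS018 = "De novo", CS036 = "De novo", CS050 = "Paternal",
            CS053 = "N.D.", CS064 = "N.D.", CS033 = "N.D.",
            CS043 = "De novo", CS048 = "De novo", CS059 = "N.D.",
            CS071 = "De novo", CS078 = "N.D.", CS081 = "N.D.")
  expect_equal(rep1$inheritance, unname(want[rep1$sample_id]))
  # the 71 bp single-exon call survives this path (no size filter here)
  expect_true(71 %in% rep1$size)
  # sorted by gene then sample
  expect_equal(order(rep1$gene, rep1$sample_id), seq_len(nrow(rep1)))
})

test_that("candidate screen honours its filters and degenerate inputs", {
  ped <- read_ped(fixture("cohort.ped"))
  calls <- read_calls(fixture("candidate_calls.tsv"))
  pf <- read_popfreq(fixture("candidate_popfreq.tsv"))
  # empty candidate list
  expect_equal(nrow(candidate_gene_screen(calls, ped,
                                          candidates = character(),
                                          popfreq = pf)), 0)
  # a candidate gene with AF above threshold is dropped entirely
  pf2 <- rbind(pf, data.frame(gene = "DSCAM", database = "gnomAD-like",
                              sample_size = 10847, freq_het_loss = 0.02,
                              freq_het_loss_east_asia = NA))
  rep2 <- candidate_gene_screen(calls, ped, popfreq = pf2)
  expect_false("DSCAM" %in% rep2$gene)
  expect_equal(nrow(rep2), 7)
  # a low-BF candidate call is dropped
  calls2 <- calls
  calls2$bayes_factor[calls2$sample_id == "CS033"] <- 0.5
  expect_equal(nrow(candidate_gene_screen(calls2, ped, popfreq = pf)), 11)
  # control rows never appear in the report
  expect_false("CS050F" %in%
                 candidate_gene_screen(calls, ped, popfreq = pf)$sample_id)
})

test_that("recessive screen reproduces the published 8-patient table", {
  ped <- read_ped(fixture("cohort.ped"))
  calls <- read_calls(fixture("recessive_calls.tsv"))
  rep2 <- recessive_screen(calls, ped)
  expect_equal(nrow(rep2), 8)
  expect_equal(sort(unique(rep2$gene)), c("DHX40", "FAM138C", "NBPF20"))
  expect_equal(length(unique(rep2$sample_id)), 8)
  expect_equal(sum(rep2$gene == "DHX40"), 6)
  # the shared patient/control homozygous gene is excluded
  expect_false("ZNF992" %in% rep2$gene)
  # heterozygous DHX40 calls (ratio >= 0.1) in patients number 4
  het <- calls[calls$reads_ratio >= 0.1 &
                 grepl("DHX40", calls$exon_annotation) &
                 calls$sample_id %in% ped$sample_id[ped$affected], ]
  expect_equal(nrow(het), 4)
  # published inheritance labels, including starred sibling-absent rows
  dhx <- rep2[rep2$gene == "DHX40", ]
  expect_equal(dhx$inheritance[match(c("CS004", "CS035", "CS043", "CS050",
                                       "CS053", "CS057"), dhx$sample_id)],
               c("N.D.", "N.D.", "De novo", "De novo", "N.D.", "De novo"))
  expect_true(all(dhx$sibling_absent[dhx$sample_id %in%
                                       c("CS043", "CS050")]))
  expect_true(rep2$sibling_absent[rep2$gene == "FAM138C"])
})

test_that("recessive screen survivor counts match a brute-force recount", {
  ped <- read_ped(fixture("cohort.ped"))
  calls <- read_calls(fixture("recessive_calls.tsv"))
  rep2 <- recessive_screen(calls, ped)
  # oracle: filter-by-filter recount written independently of the pipeline
  patients <- ped$sample_id[ped$affected]
  is_hom <- calls$type == "deletion" & calls$reads_ratio < 0.1
  ctl_genes <- unique(unlist(annotation_genes(
    calls$exon_annotation[is_hom & !calls$sample_id %in% patients])))
  n_expect <- 0L
  for (i in which(is_hom & calls$sample_id %in% patients)) {
    g <- annotation_genes(calls$exon_annotation[i])[[1]]
    if (!any(g %in% ctl_genes)) n_expect <- n_expect + 1L
  }
  expect_equal(nrow(rep2), n_expect)
  expect_equal(nrow(recessive_screen(calls[calls$reads_ratio >= 0.1, ], ped)),
               0)
})

test_that("novel enrichment keeps the 14 published genes and drops decoys", {
  groups <- utils::read.delim(fixture("novel_gene_counts.tsv"),
                              stringsAsFactors = FALSE)
  pf <- read_popfreq(fixture("novel_popfreq.tsv"))
  hits <- novel_enrichment(groups, n_controls = 125, popfreq = pf)
  expect_equal(nrow(hits), 14)
  expect_equal(sort(hits$gene),
               sort(c("LRRC40", "SCN7A", "MME", "NAE1", "TBX6", "DHX40",
                      "GMCL1", "MYSM1", "RASA2", "NSMAF", "MNS1", "PHKB",
                      "SPO11", "ABCA6")))
  # each decoy fails exactly its designed criterion
  expect_false(any(c("ZZZAA", "ZZZBB", "ZZZCC") %in% hits$gene))
  expect_equal(hits$patient_count[hits$gene == "DHX40"], 10L)
  expect_equal(hits$control_count[hits$gene == "DHX40"], 1L)
  # boundary: 3 patients is not "more than three"
  expect_false("ZZZAA" %in%
                 novel_enrichment(groups, 125, pf)$gene)
  # 2/125 = 1.6% fails the <1% control rule; 1/125 = 0.8% passes
  expect_true(all(hits$control_count / 125 < 0.01))
  # NAE1 passes because its only DGV record is below the sample-size floor
  expect_true(is.na(hits$max_pop_af[hits$gene == "NAE1"]) ||
                hits$max_pop_af[hits$gene == "NAE1"] <= 0.01)
})

test_that("novel screen finds implanted recurrent patient-only genes", {
  # end-to-end on perfect calls: a gene implanted in >=4 patients, absent
  # from controls and from the frequency table, must always be reported
  ped <- generate_pedigrees(cohort_spec(0, 2, 6, 0, 0, seed = 71))
  targets <- generate_exon_targets(12, seed = 71)
  gene <- unique(targets$gene)[5]
  ex <- targets[targets$gene == gene, ]
  patients <- ped$sample_id[ped$affected][1:5]
  truth <- data.frame(sample_id = patients, chrom = ex$chrom[1],
                      start = min(ex$start), end = max(ex$end), gene = gene,
                      type = "deletion", copy_number = 1L,
                      origin = "de_novo", stringsAsFactors = FALSE)
  calls <- truth_to_calls(truth, targets)
  pf <- generate_popfreq_table(targets, gene, seed = 71)
  hits <- novel_screen(calls, ped, pf)
  expect_true(gene %in% hits$gene)
  expect_equal(hits$patient_count[hits$gene == gene], 5L)
  expect_equal(hits$control_count[hits$gene == gene], 0L)
  # with only 3 carriers the gene drops out
  hits3 <- novel_screen(calls[1:3, ], ped, pf)
  expect_false(gene %in% hits3$gene)
})

test_that("ddCt quantification obeys its identities", {
  meas <- data.frame(
    sample_id = c("CAL", "S1", "S2", "S3"),
    target_locus = "NOTCH2",
    ct_target = c(25, 26, 24, 27),
    ct_reference = c(25, 25, 25, 25), stringsAsFactors = FALSE)
  res <- qpcr_relative_quantity(meas, calibrator = "CAL")
  # ddCt 0 -> quantity 1, copy 2; ddCt 1 -> 0.5 (het deletion); ddCt -1 -> 2
  expect_equal(res$relative_quantity, c(1, 0.5, 2, 0.25))
  expect_equal(res$copy_estimate, c(2, 1, 4, 0.5))
  # strictly decreasing in ddCt; doubling quantity means ddCt -1
  expect_true(all(diff(res$relative_quantity[order(res$delta_delta_ct)]) < 0))
  expect_equal(res$delta_delta_ct[res$relative_quantity == 2], -1)
  expect_error(qpcr_relative_quantity(meas, "MISSING"), "calibrator")
  # per-locus calibration
  meas2 <- rbind(meas, within(meas, target_locus <- "DSCAM"))
  res2 <- qpcr_relative_quantity(meas2, "CAL")
  expect_equal(res2$relative_quantity[res2$target_locus == "DSCAM"],
               c(1, 0.5, 2, 0.25))
})
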