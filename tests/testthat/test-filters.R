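make_calls <- function(bf, size, ann = NULL, sample = NULL, type = "deletion") {
  n <- max(length(bf), length(size), length(ann), length(sample))
  data.frame(
    sample_id = if (is.null(sample)) paste0("S", seq_len(n)) else sample,
    type = rep_len(type, n), chrom = "1",
    start = 1000L + seq_len(n), end = 1000L + seq_len(n) + size,
    size = rep_len(size, n), bayes_factor = rep_len(bf, n),
    reads_ratio = 0.5,
    exon_annotation = if (is.null(ann)) "" else rep_len(ann, n),
    stringsAsFactors = FALSE)
}

test_that("BF and size filters keep their boundaries", {
  th <- filter_thresholds()
  calls <- make_calls(bf = c(0.99, 1.00, 4.62, -2), size = 200)
  kept <- filter_by_bf(calls, th)
  expect_equal(kept$bayes_factor, c(1.00, 4.62))

  calls2 <- make_calls(bf = 5, size = c(99, 100, 187, 71))
  kept2 <- filter_by_size(calls2, th)
  expect_equal(kept2$size, c(100, 187))

  expect_equal(nrow(filter_by_bf(calls[0, ], th)), 0)
})

test_that("published candidate BF values all survive the BF filter", {
  calls <- make_calls(bf = c(4.62, 8.46, 4.65, 6.02, 5.8, 5.45, 6.1, 6.37,
                             644, 754, 690, 645), size = 200)
  expect_equal(nrow(filter_by_bf(calls, filter_thresholds())), 12)
})

test_that("BF/size/AF filters commute and are idempotent", {
  targets <- generate_exon_targets(12, seed = 53)
  ped <- generate_pedigrees(cohort_spec(0, 0, 3, 0, 2, seed = 53))
  truth <- implant_cnvs(ped, targets, 8, seed = 53)
  pf <- generate_popfreq_table(targets, truth$gene, common_fraction = 0.4,
                               seed = 53)
  set.seed(53)
  calls <- annotate_genes(data.frame(
    sample_id = sample(ped$sample_id, 30, replace = TRUE),
    type = sample(c("deletion", "duplication"), 30, replace = TRUE),
    chrom = sample(targets$chrom, 30, replace = TRUE),
    start = 0L, end = 0L, size = 0L,
    bayes_factor = stats::runif(30, -1, 8),
    reads_ratio = stats::runif(30, 0, 1.6),
    stringsAsFactors = FALSE), targets)
  # random target-anchored intervals with varying sizes
  idx <- sample(nrow(targets), 30, replace = TRUE)
  calls$start <- targets$start[idx]
  calls$end <- calls$start + sample(c(50, 150, 2000), 30, replace = TRUE)
  calls$size <- calls$end - calls$start
  calls <- annotate_genes(calls[, setdiff(names(calls), "exon_annotation")],
                          targets)
  th <- filter_thresholds()

  apply_af <- function(x) gene_max_af(x, pf, th)$calls
  orders <- list(
    function(x) apply_af(filter_by_size(filter_by_bf(x, th), th)),
    function(x) filter_by_bf(filter_by_size(apply_af(x), th), th),
    function(x) filter_by_size(apply_af(filter_by_bf(x, th)), th))
  results <- lapply(orders, function(f) f(calls))
  for (k in 2:length(results)) {
    expect_equal(results[[1]][order(results[[1]]$start), ],
                 results[[k]][order(results[[k]]$start), ],
                 ignore_attr = TRUE)
  }
  # idempotence and monotone shrinkage
  once <- orders[[1]](calls)
  expect_equal(orders[[1]](once), once, ignore_attr = TRUE)
  expect_lte(nrow(once), nrow(calls))
  # empty frequency table leaves calls untouched
  expect_equal(gene_max_af(calls, pf[0, ], th)$calls, calls,
               ignore_attr = TRUE)
})

test_that("exon annotation reports first-last overlapped exon per gene", {
  targets <- data.frame(
    chrom = "1", start = c(100, 300, 500, 700, 2000),
    end = c(200, 400, 600, 800, 2100),
    gene = c(rep("GENEA", 4), "GENEB"), exon_index = c(1:4, 1L),
    stringsAsFactors = FALSE)
  calls <- data.frame(
    sample_id = "S1", type = "deletion", chrom = "1",
    start = c(100, 520, 900), end = c(800, 560, 1500),
    stringsAsFactors = FALSE)
  ann <- annotate_genes(calls, targets)
  expect_equal(ann$exon_annotation, c("GENEA_1-4", "GENEA_3", ""))
  # call spanning both genes lists both
  wide <- data.frame(sample_id = "S1", type = "deletion", chrom = "1",
                     start = 150, end = 2050, stringsAsFactors = FALSE)
  expect_equal(annotate_genes(wide, targets)$exon_annotation,
               "GENEA_1-4,GENEB_1")
})

test_that("annotation strings parse back into gene sets", {
  genes <- annotation_genes(c("NOTCH2_1-4", "DSCAM_25",
                              "SPN_2,AC009133.19_2-3,CTD-2574D22.6_1-2",
                              "CORO1A_2-3,CORO1A_4-10", ""))
  expect_equal(genes[[1]], "NOTCH2")
  expect_equal(genes[[2]], "DSCAM")
  expect_equal(genes[[3]], c("SPN", "AC009133.19", "CTD-2574D22.6"))
  expect_equal(genes[[4]], "CORO1A")
  expect_equal(genes[[5]], character(0))
})

test_that("gene-based AF filter takes the max over eligible records only", {
  th <- filter_thresholds()
  calls <- make_calls(bf = 5, size = rep(200, 3),
                      ann = c("GENEA_1", "GENEB_1", "GENEC_1"))
  pf <- data.frame(
    gene = c("GENEA", "GENEA", "GENEB", "GENEC"),
    database = c("DGV-like", "gnomAD-like", "DGV-like", "DGV-like"),
    sample_size = c(1000, 10847, 1000, 50),
    freq_het_loss = c(0.0037, 0.00037, 0.02, 0.5),
    freq_het_loss_east_asia = c(NA, 0, NA, NA), stringsAsFactors = FALSE)
  res <- gene_max_af(calls, pf, th)
  # GENEA max 0.0037 retained; GENEB 0.02 excluded; GENEC only small-n, kept
  expect_equal(res$genes$max_pop_af[res$genes$gene == "GENEA"], 0.0037)
  expect_true(res$genes$excluded[res$genes$gene == "GENEB"])
  expect_true(is.na(res$genes$max_pop_af[res$genes$gene == "GENEC"]))
  expect_equal(sort(unlist(annotation_genes(res$calls$exon_annotation))),
               c("GENEA", "GENEC"))
  # East-Asian field participates in the max
  pf2 <- data.frame(gene = "GENEA", database = "gnomAD-like",
                    sample_size = 10847, freq_het_loss = 0.001,
                    freq_het_loss_east_asia = 0.05, stringsAsFactors = FALSE)
  res2 <- gene_max_af(calls[1, ], pf2, th)
  expect_true(res2$genes$excluded[1])
})

test_that("distinct-CNV counting collapses repeated events", {
  calls <- make_calls(bf = 5, size = 200, sample = paste0("S", 1:5))
  calls$start <- 1000L; calls$end <- 1200L
  expect_equal(count_distinct(calls), 1L)
  calls$type <- c("deletion", "deletion", "duplication", "deletion",
                  "deletion")
  expect_equal(count_distinct(calls), 2L)
  # randomized fixture against a hash-set oracle
  set.seed(59)
  rnd <- data.frame(
    sample_id = sample(letters, 200, TRUE),
    type = sample(c("deletion", "duplication"), 200, TRUE),
    chrom = sample(c("1", "2"), 200, TRUE),
    start = sample(1:20, 200, TRUE) * 100L, stringsAsFactors = FALSE)
  rnd$end <- rnd$start + sample(c(100L, 300L), 200, TRUE)
  oracle <- length(unique(paste(rnd$chrom, rnd$start, rnd$end, rnd$type)))
  expect_equal(count_distinct(rnd), oracle)
})

test_that("gene recurrence counts distinct carriers by affection status", {
  ped <- data.frame(
    family_id = c("FA", "FA", "FB", "FC"),
    sample_id = c("P1", "C1", "P2", "P3"),
    father_id = NA_character_, mother_id = NA_character_,
    sex = "unknown", affected = c(TRUE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE)
  calls <- make_calls(bf = 5, size = 200,
                      sample = c("P1", "P1", "C1", "P2"),
                      ann = c("GENEA_1", "GENEA_2", "GENEA_1", "GENEB_1"))
  rec <- count_recurrence(calls, ped)
  # P1 counted once for GENEA despite two calls
  expect_equal(rec$patient_count[rec$gene == "GENEA"], 1L)
  expect_equal(rec$control_count[rec$gene == "GENEA"], 1L)
  expect_equal(rec$patient_count[rec$gene == "GENEB"], 1L)
  expect_error(count_recurrence(make_calls(bf = 5, size = 1, sample = "ZZ",
                                           ann = "GENEA_1"), ped),
               "ZZ")
  # randomized fixture equals the nested-loop oracle
  set.seed(61)
  big <- make_calls(bf = 5, size = 200,
                    sample = sample(ped$sample_id, 50, TRUE),
                    ann = sample(c("GENEA_1", "GENEB_2", "GENEC_1-3"), 50,
                                 TRUE))
  expect_equal(count_recurrence(big, ped), recount_oracle(big, ped),
               ignore_attr = TRUE)
})
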