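# Independent oracles, written against the model definitions rather than the
# package implementation.

# Beta-binomial log pmf evaluated directly from the rising-factorial form of
# the binomial-beta mixture, P(x | n) = C(n,x) (a)_x (b)_{n-x} / (a+b)_n,
# accumulated term by term in log space (no lbeta/lgamma shortcut).
bb_logpmf_oracle <- function(x, n, mu, rho) {
  if (rho <= 0) return(stats::dbinom(x, n, mu, log = TRUE))
  a <- mu * (1 - rho) / rho
  b <- (1 - mu) * (1 - rho) / rho
  rising <- function(z, k) if (k == 0) 0 else sum(log(z + 0:(k - 1)))
  lchoose(n, x) + rising(a, x) + rising(b, n - x) - rising(a + b, n)
}

# copy-number adjustment of the expected test fraction, restated from scratch
phi_adjust_oracle <- function(phi, c) (c / 2) * phi / ((c / 2) * phi + 1 - phi)

# Exhaustive maximum-probability state path over all 3^n paths, using the
# same chain parameterization as the decoder but enumerated brute-force.
exhaustive_path_oracle <- function(emat, transition_prob = 1e-4,
                                   cnv_exit_prob = 0.2) {
  t <- transition_prob; q <- cnv_exit_prob
  trans <- log(rbind(c(1 - q, q, 0),
                     c(t / 2, 1 - t, t / 2),
                     c(0, q, 1 - q)))
  init <- log(c(t / 2, 1 - t, t / 2))
  n <- nrow(emat)
  grid <- as.matrix(expand.grid(rep(list(1:3), n)))
  score <- apply(grid, 1, function(path) {
    s <- init[path[1]] + emat[1, path[1]]
    if (n > 1) for (i in 2:n)
      s <- s + trans[path[i - 1], path[i]] + emat[i, path[i]]
    s
  })
  c("deletion", "diploid", "duplication")[grid[which.max(score), ]]
}

# brute-force per-gene recurrence recount by nested loops
recount_oracle <- function(calls, pedigrees) {
  genes <- unique(unlist(annotation_genes(calls$exon_annotation)))
  out <- data.frame(gene = sort(genes), patient_count = 0L,
                    control_count = 0L, stringsAsFactors = FALSE)
  for (k in seq_len(nrow(out))) {
    carriers <- character()
    for (i in seq_len(nrow(calls))) {
      g <- annotation_genes(calls$exon_annotation[i])[[1]]
      if (out$gene[k] %in% g) carriers <- c(carriers, calls$sample_id[i])
    }
    carriers <- unique(carriers)
    aff <- pedigrees$affected[match(carriers, pedigrees$sample_id)]
    out$patient_count[k] <- sum(aff)
    out$control_count[k] <- sum(!aff)
  }
  out
}

fixture <- function(f) system.file("extdata", f, package = "famcnv")
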