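# Shared fixtures and small independent oracles for the test suite.

# adjusted Rand index from the contingency table (independent of any
# clustering package)
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- sum(tab)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (maxi - expected)
}

# trace with two programmed bumps peaking at given multiples of baseline
two_bump_trace <- function(peak1 = 2, peak2 = 2, baseline = 1,
                           t_peak1 = 0.5, t_peak2 = 4.5, width = 0.3) {
  times <- seq(-4 / 6, 8, by = 1 / 6)
  v <- rep(baseline, length(times))
  post <- times >= 0
  bump <- function(t, tp) exp(-(t - tp)^2 / (2 * width^2))
  v[post] <- baseline * (1 + (peak1 - 1) * bump(times[post], t_peak1) +
                           (peak2 - 1) * bump(times[post], t_peak2))
  cell_trace("fix", times, v)
}

# toy six-gene DEG table: one gene failing each filter criterion, one
# passing all, one failing two
toy_deg_table <- function() {
  data.frame(
    gene_id = paste0("g", 1:6),
    condition = "sustained",
    biotype = c("protein_coding", "protein_coding", "protein_coding",
                "lincRNA", "protein_coding", "pseudogene"),
    fdr = c(0.001, 0.2, 0.01, 0.01, 0.02, 0.5),
    max_group_mean = c(5, 5, 5, 5, 0.5, 0.2),
    log2fc_2h = c(2.0, 2.0, 0.5, 2.0, 2.0, 0.1),
    log2fc_4h = c(0.1, 0.1, 0.2, 0.1, 0.4, 0.0),
    log2fc_6h = c(0.0, 0.3, 0.9, 0.3, 0.1, 0.2),
    log2fc_8h = c(0.2, 0.2, 0.4, 0.6, 0.3, 0.1),
    stringsAsFactors = FALSE
  )
}
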