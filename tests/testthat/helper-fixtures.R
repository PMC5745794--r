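# Shared fixtures, built in code.

const_model <- function(N = 1e4, mu = 7e-9, rec = 0) {
  demographic_model(
    epochs = data.frame(deme = 1, t_start = 0, size = N),
    n_demes = 1, mutation_rate = mu, recombination_rate = rec
  )
}

two_deme_model <- function(N1 = 2e4, N2 = 2e4, t_div = 2e4, N_anc = 2e4,
                           mw = NULL, mu = 7e-9, rec = 0) {
  demographic_model(
    epochs = data.frame(deme = c(1, 2), t_start = 0, size = c(N1, N2)),
    n_demes = 2, divergence_time = t_div, ancestral_size = N_anc,
    migration_windows = mw, mutation_rate = mu, recombination_rate = rec
  )
}

# tiny deterministic panel: explicit matrix
toy_panel <- function() {
  m <- rbind(
    c(1L, 0L, 1L, 0L),
    c(1L, 0L, 0L, 1L),
    c(0L, 1L, 0L, 0L),
    c(0L, 0L, 0L, 1L)
  )
  hap_panel(m, c(10L, 20L, 30L, 40L), 100L, c("Y", "Y", "N", "N"))
}

# brute-force sliding-window density oracle: a position is bad iff some
# length-`window` span (inclusive ends) holds more than max_snps SNPs and
# contains it
density_oracle <- function(pos, max_snps = 3, window = 10) {
  bad <- rep(FALSE, length(pos))
  if (!length(pos)) return(pos)
  for (s in (min(pos) - window):max(pos)) {
    inw <- which(pos >= s & pos <= s + window - 1)
    if (length(inw) > max_snps) bad[inw] <- TRUE
  }
  pos[!bad]
}

# site records with all annotations passing the default thresholds
passing_records <- function(n, chrom = "1") {
  tibble::tibble(
    chrom = chrom, pos = seq_len(n) * 100L, ref = "A", alt = "T",
    variant_class = "snp", Q = 50, MQ = 40, QD = 20,
    ReadPosRankSum = 0, DP = 20, FS = 1
  )
}
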