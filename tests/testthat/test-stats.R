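test_that("nucleotide diversity matches pairwise-difference enumeration", {
  # 4 haplotypes, one SNP at frequency 2/4, L = 10:
  # mean pairwise difference = (# discordant pairs)/(# pairs) = 4/6 = 2/3
  m <- matrix(c(1L, 1L, 0L, 0L), 4, 1)
  p <- hap_panel(m, 5L, 10L, rep("A", 4))
  pi_hand <- (4 / 6) / 10
  res <- nucleotide_diversity(p, 10, 10)
  expect_equal(res$pi, pi_hand)
  expect_equal(res$pi, 2 * 0.5 * 0.5 * (4 / 3) / 10)
  # monomorphic panel: pi = 0 everywhere (simulate-free: zero-SNP panel)
  p0 <- hap_panel(matrix(integer(), 4, 0), integer(), 100L, rep("A", 4))
  expect_true(all(nucleotide_diversity(p0, 100, 100)$pi == 0))
})

test_that("diversity requires at least two haplotypes", {
  expect_error(hap_panel(matrix(0L, 1, 0), integer(), 10L, "A") |>
                 nucleotide_diversity(10, 10), ">= 2")
  expect_error(hap_panel(matrix(0L, 1, 0), integer(), 10L, "A") |>
                 watterson_theta(10, 10), ">= 2")
})

test_that("Watterson's theta uses the harmonic divisor", {
  # n = 2: a_1 = 1 -> theta = S / L
  m <- matrix(c(0L, 1L), 2, 5)
  p <- hap_panel(m, c(1L, 3L, 5L, 7L, 9L), 1000L, c("A", "B"))
  expect_equal(watterson_theta(p, 1000, 1000)$theta_w, 5 / 1000)
  # S = 0
  p0 <- hap_panel(matrix(integer(), 2, 0), integer(), 1000L, c("A", "B"))
  expect_equal(watterson_theta(p0, 1000, 1000)$theta_w, 0)
  # n = 10 uses a_9 = 2.828968...
  m10 <- matrix(0L, 10, 3)
  m10[1, ] <- 1L
  p10 <- hap_panel(m10, c(10L, 20L, 30L), 100L, rep("A", 10))
  a9 <- sum(1 / 1:9)
  expect_equal(watterson_theta(p10, 100, 100)$theta_w, 3 / (a9 * 100))
  expect_equal(round(a9, 4), 2.829)
})

test_that("window tiling covers the sequence within bounds", {
  for (L in c(50, 1999, 20000)) {
    w <- coalsweep:::tile_windows(L, 1000, 300)
    expect_equal(w$start[1], 1)
    expect_true(all(w$end <= L))
    expect_equal(max(w$end), L)
    covered <- rep(FALSE, L)
    for (i in seq_len(nrow(w))) covered[w$start[i]:w$end[i]] <- TRUE
    expect_true(all(covered))
  }
  expect_error(coalsweep:::tile_windows(100, 10, 20), "step")
})

test_that("Hudson FST behaves at its analytic anchors", {
  # identical allele frequencies in both demes: FST -> -1/(n-1), i.e. ~0
  # up to the small-sample correction of the within term
  n_per <- 50
  mk_col <- function(k) c(rep(1L, k), rep(0L, n_per - k))
  m <- do.call(cbind, lapply(c(10, 25, 40), function(k) {
    c(mk_col(k), mk_col(k))  # deme B mirrors deme A exactly
  }))
  pp <- hap_panel(m, c(10L, 20L, 30L), 100L, rep(c("A", "B"), each = n_per))
  expect_equal(hudson_fst(pp, 100, 100)$fst, 1 - n_per / (n_per - 1),
               tolerance = 1e-12)
  expect_lt(abs(hudson_fst(pp, 100, 100)$fst), 0.05)
  # fixed difference -> 1
  m2 <- rbind(matrix(0L, 4, 1), matrix(1L, 4, 1))
  p2 <- hap_panel(m2, 50L, 100L, rep(c("A", "B"), each = 4))
  expect_equal(hudson_fst(p2, 100, 100)$fst, 1)
  # no between-deme diversity -> flagged NA
  p3 <- hap_panel(rbind(c(1L), c(0L), c(1L), c(0L)), 5L, 10L,
                  c("A", "A", "B", "B"))
  expect_true(is.finite(hudson_fst(p3, 10, 10)$fst))
  expect_error(hudson_fst(toy_panel(), 100, 100, demes = c("Y", "Z")),
               "demes")
})

test_that("random deme labels centre FST at zero", {
  p <- simulate_panel(const_model(N = 2e4, mu = 2e-8), 16, 5e4, seed = 12,
                      with_recombination = FALSE)
  set.seed(99)
  fsts <- vapply(1:60, function(i) {
    labs <- sample(rep(c("A", "B"), each = 8))
    q <- hap_panel(p$matrix, p$positions, p$sequence_length, labs)
    hudson_fst(q, 5e4, 5e4)$fst
  }, double(1))
  expect_lt(abs(mean(fsts, na.rm = TRUE)), 0.02)
})

test_that("joint SFS conserves the SNP count and folds correctly", {
  # 1 SNP at count (2 of 10, 0 of 8): single nonzero cell of value 1
  m <- rbind(matrix(rep(c(1L, 1L, rep(0L, 8)), 1), 10, 1),
             matrix(0L, 8, 1))
  p <- hap_panel(m, 7L, 50L, c(rep("Y", 10), rep("N", 8)))
  sfs <- joint_folded_sfs(p)
  expect_equal(sum(sfs$counts), 1)
  expect_equal(sfs$counts[3, 1], 1)  # (2, 0)
  # folding conservation on a simulated panel
  p2 <- simulate_panel(two_deme_model(mu = 2e-8), c(6, 4), 3e4, seed = 5,
                       with_recombination = FALSE)
  unf <- joint_folded_sfs(p2, fold = FALSE)
  fol <- joint_folded_sfs(p2, fold = TRUE)
  expect_equal(sum(unf$counts[!unf$mask]), ncol(p2$matrix))
  expect_equal(sum(fol$counts[!fol$mask]), ncol(p2$matrix))
  # complementary cells land together
  expect_equal(sum(fol$counts), sum(unf$counts))
})

test_that("private SNP classification matches brute force", {
  p <- toy_panel()
  res <- private_snp_counts(p)
  # brute force per site
  brute <- c(Y = 0L, N = 0L)
  n <- nrow(p$matrix)
  for (s in seq_len(ncol(p$matrix))) {
    col <- p$matrix[, s]
    minor <- if (sum(col) <= n - sum(col)) 1L else 0L
    carriers <- p$pop_labels[col == minor]
    if (length(unique(carriers)) == 1)
      brute[unique(carriers)] <- brute[unique(carriers)] + 1L
  }
  expect_equal(setNames(res$n_private, res$population), brute)
  # allele present in both demes is private to neither
  m <- cbind(c(1L, 0L, 1L, 0L))
  pb <- hap_panel(m, 5L, 10L, c("Y", "Y", "N", "N"))
  expect_equal(private_snp_counts(pb)$n_private, c(0L, 0L))
})

test_that("saturation curve is monotone and exact at the full panel", {
  p <- simulate_panel(const_model(N = 2e4, mu = 2e-8), 10, 3e4, seed = 8,
                      with_recombination = FALSE)
  sat <- snp_saturation(p, c(2, 4, 6, 10), replicates = 20, seed = 2)
  expect_true(all(diff(sat$mean_s) >= 0))
  expect_equal(sat$mean_s[sat$subsample_size == 10], ncol(p$matrix))
  expect_equal(sat$sd_s[sat$subsample_size == 10], 0)
  expect_error(snp_saturation(p, 11), "<=")
})

test_that("pair subsampling matches the hypergeometric inclusion formula", {
  p <- simulate_panel(const_model(N = 2e4, mu = 2e-8), 12, 3e4, seed = 21,
                      with_recombination = FALSE)
  n <- 12
  cc <- colSums(p$matrix)
  # P(site polymorphic in a random pair) = 2 c (n-c) / (n (n-1))
  expected <- sum(2 * cc * (n - cc) / (n * (n - 1)))
  sat <- snp_saturation(p, 2, replicates = 400, seed = 3)
  se <- sat$sd_s / sqrt(400)
  expect_lt(abs(sat$mean_s - expected), 4 * se + 1)
})

test_that("Tajima-like balance: E[pi] matches E[theta_w] under neutrality", {
  vals <- vapply(1:200, function(i) {
    p <- simulate_panel(const_model(N = 1e4, mu = 2e-8), 8, 3e4,
                        seed = 7000 + i, with_recombination = FALSE)
    c(nucleotide_diversity(p, 3e4, 3e4)$pi, watterson_theta(p, 3e4, 3e4)$theta_w)
  }, double(2))
  d <- mean(vals[1, ] - vals[2, ])
  se <- sd(vals[1, ] - vals[2, ]) / sqrt(ncol(vals))
  expect_lt(abs(d), 3 * se + 1e-6)
  expect_true(all(vals >= 0))
})

test_that("SFS text round-trip preserves counts and mask", {
  p <- simulate_panel(two_deme_model(mu = 2e-8), c(5, 4), 3e4, seed = 9,
                      with_recombination = FALSE)
  sfs <- joint_folded_sfs(p)
  f <- withr::local_tempfile(fileext = ".txt")
  write_sfs(sfs, f)
  sfs2 <- read_sfs(f)
  expect_equal(sfs2$counts, sfs$counts)
  expect_equal(sfs2$mask, sfs$mask)
  expect_equal(sfs2$sample_sizes, sfs$sample_sizes)
  expect_equal(sfs2$folded, sfs$folded)
})
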