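test_that("default map carries 32 markers on 5 chromosomes", {
  map <- genetic_map()
  expect_equal(nrow(map), 32)
  expect_equal(length(unique(map$chr)), 5)
  expect_true(all(tapply(map$pos, map$chr, function(p) !is.unsorted(p))))
})

test_that("the flowering-time truth matches its design targets", {
  tr <- flowering_qtl_model()
  a <- tr$qtls$additive
  # parental homozygote span equals the parental mean difference
  expect_equal(2 * sum(a), 50.33 - 24.87)
  expect_equal(tr$mean, (50.33 + 24.87) / 2)
  # drop-one PVEs at 1:2:1 equilibrium equal the published fractions
  v_tot <- sum(a^2 / 2) + tr$residual_sd^2
  expect_equal(a[1]^2 / 2 / v_tot, 0.609, tolerance = 1e-10)
  expect_equal(a[2]^2 / 2 / v_tot, 0.216, tolerance = 1e-10)
  expect_error(flowering_qtl_model(pve = c(0.7, 0.4)), "sum")
})

test_that("F2 genotypes segregate 1:2:1", {
  cross <- simulate_f2(600, genetic_map(), flowering_qtl_model(), seed = 3)
  for (j in seq_len(ncol(cross$genotypes))) {
    obs <- table(factor(cross$genotypes[, j], levels = 0:2))
    gof <- stats::chisq.test(obs, p = c(0.25, 0.5, 0.25))
    expect_gt(gof$p.value, 0.01 / 32)  # Bonferroni across markers
  }
})

test_that("cross simulation is reproducible and respects the map span", {
  a <- simulate_f2(30, genetic_map(), flowering_qtl_model(), seed = 11)
  b <- simulate_f2(30, genetic_map(), flowering_qtl_model(), seed = 11)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$phenotypes, b$phenotypes)
  bad <- qtl_model(tibble::tibble(chr = "chr1", pos = 500, additive = 1),
                   residual_sd = 1)
  expect_error(simulate_f2(10, genetic_map(), bad, seed = 1), "span")
})

test_that("Haley-Knott at a fully informative marker equals marker ANOVA", {
  cross <- simulate_f2(120, genetic_map(), flowering_qtl_model(), seed = 21)
  lodc <- interval_mapping(cross, step = 0)
  y <- cross$phenotypes
  n <- length(y)
  for (j in c(1, 9, 20)) {
    g <- factor(cross$genotypes[, j], levels = 0:2)
    fit <- lm(y ~ g)
    rss0 <- sum((y - mean(y))^2)
    lod_anova <- (n / 2) * log10(rss0 / sum(residuals(fit)^2))
    row <- which(lodc$chr == cross$map$chr[j] &
                   abs(lodc$pos - cross$map$pos[j]) < 1e-8)
    expect_equal(lodc$lod[row], lod_anova, tolerance = 1e-8)
  }
})

test_that("null phenotypes stay below the permutation threshold", {
  null_truth <- qtl_model(
    tibble::tibble(chr = "chr1", pos = 50, additive = 0), residual_sd = 1)
  below <- 0
  for (s in 1:10) {
    cross <- simulate_f2(86, genetic_map(), null_truth, seed = 400 + s)
    mx <- glance(interval_mapping(cross))$max_lod
    thr <- permutation_threshold(cross, n_perm = 200, seed = 500 + s)
    if (mx < thr) below <- below + 1
  }
  expect_gte(below, 8)
})

test_that("a planted large-effect QTL is located on the right chromosome", {
  hits <- 0
  truth <- flowering_qtl_model()
  for (s in 1:50) {
    cross <- simulate_f2(86, genetic_map(), truth, seed = 1300 + s)
    g <- glance(interval_mapping(cross))
    if (g$chr == "chr2") hits <- hits + 1
  }
  expect_gte(hits, 45)
})

test_that("LOD is invariant to affine phenotype transforms", {
  cross <- simulate_f2(80, genetic_map(), flowering_qtl_model(), seed = 31)
  l1 <- interval_mapping(cross)
  cross2 <- cross
  cross2$phenotypes <- 3.5 * cross$phenotypes - 100
  l2 <- interval_mapping(cross2)
  expect_equal(l1$lod, l2$lod, tolerance = 1e-10)
})

test_that("permutation threshold behaves as a quantile in alpha", {
  cross <- simulate_f2(86, genetic_map(), flowering_qtl_model(), seed = 41)
  thr5 <- permutation_threshold(cross, n_perm = 200, alpha = 0.05, seed = 1)
  thr1 <- permutation_threshold(cross, n_perm = 200, alpha = 0.01, seed = 1)
  thr100 <- permutation_threshold(cross, n_perm = 200, alpha = 1, seed = 1)
  expect_gt(thr1, thr5)
  expect_equal(as.numeric(thr100), min(attr(thr5, "max_lods")))
  expect_error(permutation_threshold(cross, n_perm = 10), "100")
})

test_that("PVE closed form and drop-one estimates are calibrated", {
  expect_equal(pve_from_lod(0, 100), 0)
  expect_equal(pve_from_lod(5, 100), 1 - 10^(-0.1))
  expect_equal(round(pve_from_lod(5, 100), 3), 0.206)
  # unbiasedness at n = 1000 (truth positions, 50 seeds)
  truth <- flowering_qtl_model()
  est <- vapply(1:50, function(s) {
    cross <- simulate_f2(1000, genetic_map(), truth, seed = 600 + s)
    pv <- variance_explained(cross, truth$qtls[, c("chr", "pos")])
    pv$pve
  }, double(2))
  expect_lt(abs(mean(est[1, ]) - 60.9), 5)
  expect_lt(abs(mean(est[2, ]) - 21.6), 5)
})

test_that("haplotype association matches exact enumeration and has power", {
  # identical groups -> p ~ 1
  same <- haplotype_association(rep(c(1, 2, 3), 2),
                                rep(c("a", "b"), each = 3))
  expect_gt(same$p_value, 0.9)
  # {1,2,3} vs {10,11,12}: extreme rank-sum; exact two-sided p = 2/20 = 0.1
  toy <- haplotype_association(c(1, 2, 3, 10, 11, 12),
                               rep(c("a", "b"), each = 3))
  expect_equal(toy$p_value, 0.1)
  expect_equal(toy$statistic, 0)  # W at its minimum
  # shifted Gaussians (2 sd, n = 49/49): essentially always significant
  sig <- vapply(1:20, function(s) {
    set.seed(4000 + s)
    haplotype_association(c(rnorm(49), rnorm(49, 2)),
                          rep(c("a", "b"), each = 49))$p_value
  }, double(1))
  expect_true(all(sig < 0.001))
  expect_error(haplotype_association(1:4, rep("a", 4)), "two")
})

test_that("candidate filtering keeps amino-acid-changing variants by gene", {
  v <- tibble::tibble(
    pos = c(5, 10, 20, 30, 40, 50, 60, 70, 80, 90),
    gene = paste0("g", c(1, 1, 2, 3, 4, 5, 6, 7, 8, 9)),
    effect = c("missense", "synonymous", "missense", "intergenic",
               "missense", "synonymous", "missense", "intron",
               "synonymous", "missense")
  )
  out <- candidate_filter(v, interval = c(1, 75))
  expect_equal(sort(out$gene), c("g1", "g2", "g4", "g6"))
  empty <- candidate_filter(v[v$effect == "synonymous", ])
  expect_equal(nrow(empty), 0)
})

test_that("cross CSV round-trip preserves data", {
  cross <- simulate_f2(25, genetic_map(), flowering_qtl_model(), seed = 51,
                       missing_rate = 0.05)
  stem <- withr::local_tempfile()
  write_cross_csv(cross, stem)
  back <- read_cross_csv(stem)
  expect_equal(unname(back$genotypes), unname(cross$genotypes))
  expect_equal(back$phenotypes, cross$phenotypes)
  expect_equal(back$map$pos, cross$map$pos)
})
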