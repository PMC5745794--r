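test_that("hard filters evaluate each rule as hand-checked", {
  recs <- passing_records(5)
  recs$QD[3] <- 9.9
  out <- apply_hard_filters(recs, filter_config())
  expect_equal(nrow(out$records), 4)
  expect_equal(out$tally$n_failed[out$tally$rule == "QD"], 1L)
  expect_false(300 %in% out$records$pos)

  # FS threshold depends on variant class
  recs2 <- passing_records(2)
  recs2$FS <- 150
  recs2$variant_class <- c("indel", "snp")
  out2 <- apply_hard_filters(recs2, filter_config())
  expect_equal(out2$records$variant_class, "indel")

  # empty input
  out3 <- apply_hard_filters(passing_records(0), filter_config())
  expect_equal(nrow(out3$records), 0)
  expect_equal(sum(out3$tally$n_failed), 0)
})

test_that("missing annotations pass their rule and are tallied separately", {
  recs <- passing_records(3)
  recs$ReadPosRankSum[2] <- NA
  out <- apply_hard_filters(recs, filter_config())
  expect_equal(nrow(out$records), 3)
  expect_equal(
    out$tally$n_failed[out$tally$rule == "missing_ReadPosRankSum"], 1L)
})

test_that("hard filtering is idempotent and rejects unsorted input", {
  recs <- passing_records(6)
  recs$Q[2] <- 5
  once <- apply_hard_filters(recs, filter_config())
  twice <- apply_hard_filters(once$records, filter_config())
  expect_equal(twice$records, once$records)
  expect_equal(sum(twice$tally$n_failed[1:6]), 0)
  expect_error(apply_hard_filters(recs[c(3, 1, 2), ], filter_config()),
               "sorted")
})

test_that("density filter matches the brute-force span oracle", {
  expect_equal(density_filter(c(100, 102, 104, 106)), integer(0))
  expect_equal(density_filter(c(100, 102, 104, 200)),
               c(100, 102, 104, 200))
  expect_equal(density_filter(55), 55)
  set.seed(31)
  for (i in 1:25) {
    pos <- sort(sample.int(200, 40))
    expect_equal(density_filter(pos), density_oracle(pos))
  }
  # idempotence (self-commutation)
  for (i in 1:10) {
    pos <- sort(sample.int(100, 25))
    once <- density_filter(pos)
    expect_equal(density_filter(once), once)
  }
})

test_that("density thinning keeps the allowed number per cluster", {
  thinned <- density_filter(c(100, 102, 104, 106), action = "thin")
  expect_equal(thinned, c(100, 102, 104))
})

test_that("call-rate filter counts called samples and drops multiallelics", {
  recs <- tibble::tibble(
    chrom = "1", pos = 1:3, alt = c("T", "T,G", "T"),
    variant_class = "snp",
    n_called = c(219L, 221L, 218L)
  )
  out <- biallelic_callrate_filter(recs, 219)
  expect_equal(out$pos, 1L)
  # genotype list-column route: 221 samples, 2 missing -> kept at 219
  gt <- rep(0L, 221); gt[1:2] <- NA
  recs2 <- tibble::tibble(chrom = "1", pos = 1L, alt = "T",
                          variant_class = "snp", genotypes = list(gt))
  expect_equal(nrow(biallelic_callrate_filter(recs2, 219)), 1)
  gt3 <- rep(0L, 221); gt3[1:3] <- NA
  recs3 <- tibble::tibble(chrom = "1", pos = 1L, alt = "T",
                          variant_class = "snp", genotypes = list(gt3))
  expect_equal(nrow(biallelic_callrate_filter(recs3, 219)), 0)
})

test_that("noncoding subset follows the BED half-open convention", {
  recs <- tibble::tibble(chrom = "1", pos = c(100L, 150L))
  expect_equal(
    subset_noncoding(recs, tibble::tibble(chrom = "1", start = 99, end = 100))$pos,
    150L)
  expect_equal(
    subset_noncoding(recs, tibble::tibble(chrom = "1", start = 100, end = 200))$pos,
    integer(0))
  # pos 100 vs (101, 200]: kept
  expect_equal(
    subset_noncoding(tibble::tibble(chrom = "1", pos = 100L),
                     tibble::tibble(chrom = "1", start = 101, end = 200))$pos,
    100L)
  expect_equal(subset_noncoding(recs, tibble::tibble(chrom = character(),
                                                     start = double(),
                                                     end = double())),
               recs)
  expect_error(
    subset_noncoding(recs, tibble::tibble(chrom = "1", start = 10, end = 10)),
    "malformed")
})

test_that("independent site-wise rules commute", {
  recs <- passing_records(8)
  recs$Q[2] <- 1
  recs$MQ[5] <- 1
  expect_error(filter_config(mq_min = -Inf), "finite")
  a <- apply_hard_filters(recs, filter_config())$records
  # applying the full filter after a partial pass changes nothing
  b <- apply_hard_filters(a, filter_config())$records
  expect_equal(a, b)
})

test_that("panel -> VCF -> panel round-trip is exact", {
  p <- simulate_panel(two_deme_model(mu = 2e-8), c(4, 3), 2e4, seed = 3,
                      with_recombination = FALSE)
  f <- withr::local_tempfile(fileext = ".vcf")
  write_panel_vcf(p, f)
  q <- read_panel_vcf(f)
  expect_identical(q$matrix, p$matrix)
  expect_identical(q$positions, p$positions)
  expect_identical(q$pop_labels, p$pop_labels)
  expect_identical(q$sequence_length, p$sequence_length)
  # and the flat text format
  f2 <- withr::local_tempfile(fileext = ".txt")
  write_panel_flat(p, f2)
  q2 <- read_panel_flat(f2)
  expect_identical(q2$matrix, p$matrix)
  expect_identical(q2$positions, p$positions)
})

test_that("site records parse from VCF with annotations", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
    "1\t100\t.\tA\tT\t45\t.\tMQ=32;QD=12.5;DP=20;FS=2.1\tGT\t0/0\t1/1",
    "1\t200\t.\tAC\tA\t50\t.\tMQ=30;QD=11\tGT\t0/1\t./.",
    "1\t300\t.\tG\tC,T\t60\t.\tMQ=35\tGT\t0/1\t0/2"
  ), f)
  recs <- read_site_records(f)
  expect_equal(recs$variant_class, c("snp", "indel", "snp"))
  expect_equal(recs$Q, c(45, 50, 60))
  expect_equal(recs$MQ, c(32, 30, 35))
  expect_equal(recs$n_called, c(2L, 1L, 2L))
  expect_true(is.na(recs$FS[2]))
})
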