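# Variant-record handling and hard site filters.
#
# Site records are plain tibbles (one row per site) with columns:
#   chrom, pos, ref, alt, variant_class ("snp"/"indel"),
#   annotation columns Q, MQ, QD, ReadPosRankSum, DP, FS (NA when absent),
#   and a list-column `genotypes` (integer per-sample calls, NA = missing)
#   or a plain `n_called`/`n_alt_alleles` summary, depending on source.
# Coordinates are 1-based inclusive (VCF convention); BED intervals are
# 0-based half-open and converted at the boundary only.

#' Hard-filter configuration
#'
#' Thresholds for GATK-style site annotations, SNP cluster density and
#' per-site call rate. Defaults reproduce a conservative resequencing
#' pipeline: Q >= 30, MQ >= 20, QD >= 10, ReadPosRankSum >= -8, DP >= 3,
#' FS <= 10 for SNPs and <= 200 for indels, no more than 3 SNPs in any 10-bp
#' span, and (when applied) a minimum number of called samples.
#'
#' @param q_min,mq_min,qd_min,rprs_min,dp_min Lower thresholds.
#' @param fs_max_snp,fs_max_indel Upper FS thresholds by variant class.
#' @param density_max_snps,density_window SNP-cluster rule: any window of
#'   `density_window` bp holding more than `density_max_snps` SNPs is a
#'   cluster.
#' @param min_called_samples Minimum non-missing genotypes per site.
#' @return A list of class `filter_config`.
#' @examples
#' filter_config()
#' @export
filter_config <- function(q_min = 30, mq_min = 20, qd_min = 10,
                          rprs_min = -8.0, dp_min = 3,
                          fs_max_snp = 10.0, fs_max_indel = 200.0,
                          density_max_snps = 3, density_window = 10,
                          min_called_samples = 219) {
  if (density_window < 1) abort("density_window must be >= 1")
  vals <- list(q_min = q_min, mq_min = mq_min, qd_min = qd_min,
               rprs_min = rprs_min, dp_min = dp_min,
               fs_max_snp = fs_max_snp, fs_max_indel = fs_max_indel,
               density_max_snps = density_max_snps,
               density_window = density_window,
               min_called_samples = min_called_samples)
  if (!all(vapply(vals, function(v) is.numeric(v) && is.finite(v), logical(1))))
    abort("all thresholds must be finite numbers")
  structure(vals, class = "filter_config")
}

#' Apply annotation hard filters to site records
#'
#' Keeps records passing every annotation rule; a missing annotation passes
#' its rule (the GATK VariantFiltration behaviour — e.g. ReadPosRankSum is
#' undefined at sites with only homozygous calls) and such soft passes are
#' tallied separately. FS is compared against the SNP or indel threshold
#' according to `variant_class`. Filtering is idempotent.
#'
#' @param records A tibble of site records sorted by (`chrom`, `pos`), with
#'   columns `pos`, `variant_class` and any of `Q`, `MQ`, `QD`,
#'   `ReadPosRankSum`, `DP`, `FS`.
#' @param cfg A [filter_config()].
#' @return A list: `records` (passing rows) and `tally`, a tibble
#'   `rule`/`n_failed` (plus `missing_<rule>` soft-pass counts); the per-rule
#'   failure counts sum to at least the number of rejected records (a record
#'   can fail several rules).
#' @examples
#' recs <- tibble::tibble(
#'   chrom = "1", pos = 1:3, variant_class = "snp",
#'   Q = c(50, 10, 50), MQ = 30, QD = 15, ReadPosRankSum = 0, DP = 10, FS = 1
#' )
#' apply_hard_filters(recs, filter_config())$tally
#' @export
apply_hard_filters <- function(records, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0) {
    return(list(records = records,
                tally = tibble::tibble(rule = character(), n_failed = integer())))
  }
  if (is.unsorted(order(records$chrom, records$pos)) ||
      any(unlist(tapply(records$pos, records$chrom, is.unsorted))))
    abort("records must be sorted by (chrom, pos)")
  get <- function(col) if (col %in% names(records)) records[[col]] else
    rep(NA_real_, nrow(records))
  cls <- tolower(records$variant_class %||% "snp")
  fs_max <- ifelse(cls == "indel", cfg$fs_max_indel, cfg$fs_max_snp)
  rules <- list(
    Q = get("Q") >= cfg$q_min,
    MQ = get("MQ") >= cfg$mq_min,
    QD = get("QD") >= cfg$qd_min,
    ReadPosRankSum = get("ReadPosRankSum") >= cfg$rprs_min,
    DP = get("DP") >= cfg$dp_min,
    FS = get("FS") <= fs_max
  )
  miss <- lapply(rules, is.na)
  pass <- Reduce(`&`, lapply(rules, function(r) r | is.na(r)))
  tally <- dplyr::bind_rows(
    tibble::tibble(
      rule = names(rules),
      n_failed = unname(vapply(rules, function(r) sum(!r, na.rm = TRUE),
                               integer(1)))
    ),
    tibble::tibble(
      rule = paste0("missing_", names(rules)),
      n_failed = unname(vapply(miss, sum, integer(1)))
    )
  )
  list(records = records[pass, , drop = FALSE], tally = tally)
}

#' SNP cluster (density) filter on positions
#'
#' Implements the "no more than `max_snps` SNPs within `window` bp" rule:
#' every SNP lying in any span of `window` consecutive bp (endpoints
#' inclusive) that contains more than `max_snps` SNPs is removed — the whole
#' offending cluster is dropped, not thinned. Idempotent. Set
#' `action = "thin"` to instead keep the first `max_snps` SNPs of each
#' cluster.
#'
#' @param positions Strictly increasing bp positions.
#' @param max_snps,window Density rule parameters (defaults 3 SNPs / 10 bp).
#' @param action `"remove"` (default) drops whole clusters; `"thin"` keeps
#'   `max_snps` per cluster.
#' @return The kept positions.
#' @examples
#' density_filter(c(100, 102, 104, 106))  # all four fall in one 7-bp span
#' density_filter(c(100, 102, 104, 200))
#' @export
density_filter <- function(positions, max_snps = 3, window = 10,
                           action = c("remove", "thin")) {
  action <- match.arg(action)
  if (length(positions) <= max_snps) return(positions)
  if (any(diff(positions) <= 0)) abort("positions must be strictly increasing")
  bad <- rep(FALSE, length(positions))
  # a violating span is witnessed by max_snps + 1 SNPs whose extremes lie
  # within window - 1 bp of each other
  k <- max_snps + 1
  for (i in seq_len(length(positions) - k + 1)) {
    j <- i + k - 1
    if (positions[j] - positions[i] <= window - 1) {
      if (action == "remove") {
        bad[i:j] <- TRUE
      } else {
        bad[(i + max_snps):j] <- TRUE
      }
    }
  }
  positions[!bad]
}

#' Biallelic call-rate filter
#'
#' Keeps biallelic SNPs genotyped in at least `min_called` samples. Records
#' must carry either a list-column `genotypes` (per-sample integer calls,
#' `NA` = missing) or an integer column `n_called`; multi-allelic records
#' (column `alt` holding comma-separated alternates) are removed regardless
#' of call rate.
#'
#' @param records A tibble of site records.
#' @param min_called Minimum called samples (default 219).
#' @return The filtered tibble.
#' @examples
#' recs <- tibble::tibble(
#'   chrom = "1", pos = 1:2, alt = c("T", "T,G"),
#'   variant_class = "snp", n_called = c(220, 221)
#' )
#' biallelic_callrate_filter(recs, 219)
#' @export
biallelic_callrate_filter <- function(records, min_called = 219) {
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0) return(records)
  biallelic <- if ("alt" %in% names(records)) {
    !grepl(",", records$alt, fixed = TRUE)
  } else {
    rep(TRUE, nrow(records))
  }
  is_snp <- tolower(records$variant_class %||% "snp") == "snp"
  n_called <- if ("n_called" %in% names(records)) {
    records$n_called
  } else if ("genotypes" %in% names(records)) {
    vapply(records$genotypes, function(g) sum(!is.na(g)), integer(1))
  } else {
    abort("records need a genotypes list-column or an n_called column")
  }
  records[biallelic & is_snp & n_called >= min_called, , drop = FALSE]
}

#' Keep records outside coding intervals
#'
#' Removes records whose position falls inside any coding interval. Record
#' positions are 1-based; interval rows carry BED-style `start`/`end`
#' numbers and are applied conservatively at the boundary: base `pos` is
#' covered when `start <= pos <= end`, so both the base after `start`
#' (the usual BED half-open reading) and a base equal to `start` are
#' masked.
#'
#' @param records A tibble with a `pos` column (and optionally `chrom`).
#' @param coding_intervals A tibble with BED columns `start`, `end`
#'   (0-based half-open; optionally `chrom`), merged and sorted.
#' @return Records outside every interval.
#' @examples
#' recs <- tibble::tibble(chrom = "1", pos = c(100, 150))
#' bed <- tibble::tibble(chrom = "1", start = 99, end = 100)
#' subset_noncoding(recs, bed)  # base 100 is covered, base 150 kept
#' @export
subset_noncoding <- function(records, coding_intervals) {
  records <- tibble::as_tibble(records)
  iv <- tibble::as_tibble(coding_intervals)
  if (nrow(iv) == 0) return(records)
  if (any(iv$start >= iv$end)) abort("malformed interval: start >= end")
  has_chrom <- "chrom" %in% names(records) && "chrom" %in% names(iv)
  covered <- rep(FALSE, nrow(records))
  split_iv <- if (has_chrom) split(iv, iv$chrom) else list(all = iv)
  for (ch in names(split_iv)) {
    ividx <- split_iv[[ch]]
    rsel <- if (has_chrom) records$chrom == ch else rep(TRUE, nrow(records))
    if (!any(rsel)) next
    pos <- records$pos[rsel]
    # conservative boundary rule: covered iff start <= pos <= end
    hit <- vapply(pos, function(p) any(ividx$start <= p & p <= ividx$end),
                  logical(1))
    covered[rsel] <- hit
  }
  records[!covered, , drop = FALSE]
}

#' Read a BED file of intervals
#'
#' @param path BED path (>= 3 columns, no header).
#' @return A tibble `chrom`, `start`, `end` (0-based half-open).
#' @export
read_bed <- function(path) {
  df <- readr::read_tsv(path, col_names = FALSE, progress = FALSE,
                        show_col_types = FALSE)
  df <- df[, 1:3]
  names(df) <- c("chrom", "start", "end")
  df$chrom <- as.character(df$chrom)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df
}

#' Read a two-column population map
#'
#' @param path TSV with columns sample, population (no header).
#' @return A tibble `sample`, `population`.
#' @export
read_pop_map <- function(path) {
  readr::read_tsv(path, col_names = c("sample", "population"),
                  col_types = "cc", progress = FALSE)
}

#' Read site records from a VCF
#'
#' Parses a (possibly annotation-carrying) VCF into the site-record tibble
#' used by the filter functions: one row per site with `chrom`, `pos`,
#' `ref`, `alt`, `variant_class`, the INFO annotations `Q` (QUAL column),
#' `MQ`, `QD`, `ReadPosRankSum`, `DP`, `FS` (NA when absent) and an
#' `n_called` summary plus a `genotypes` list-column of allele dosages.
#'
#' @param path VCF path (uncompressed).
#' @return A tibble of site records.
#' @export
read_site_records <- function(path) {
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  n_rec <- nrow(fix)
  if (n_rec == 0) {
    return(tibble::tibble(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          variant_class = character()))
  }
  info_num <- function(key) {
    out <- suppressWarnings(
      as.numeric(vcfR::extract.info(v, element = key))
    )
    if (length(out) != n_rec) rep(NA_real_, n_rec) else out
  }
  alt <- fix[, "ALT"]
  ref <- fix[, "REF"]
  cls <- vapply(seq_len(n_rec), function(i) {
    alts <- strsplit(alt[i], ",", fixed = TRUE)[[1]]
    if (nchar(ref[i]) == 1 && all(nchar(alts) == 1)) "snp" else "indel"
  }, character(1))
  gt_list <- if (ncol(v@gt) > 1) {
    gt_raw <- vcfR::extract.gt(v, element = "GT")
    lapply(seq_len(n_rec), function(i) {
      vapply(strsplit(gt_raw[i, ], "[/|]"), function(x) {
        x[x == "."] <- NA
        a <- suppressWarnings(as.integer(x))
        if (anyNA(a)) NA_integer_ else sum(a)
      }, integer(1))
    })
  } else {
    rep(list(integer(0)), n_rec)
  }
  tibble::tibble(
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    ref = ref, alt = alt, variant_class = cls,
    Q = suppressWarnings(as.numeric(fix[, "QUAL"])),
    MQ = info_num("MQ"), QD = info_num("QD"),
    ReadPosRankSum = info_num("ReadPosRankSum"),
    DP = info_num("DP"), FS = info_num("FS"),
    n_called = vapply(gt_list, function(g) sum(!is.na(g)), integer(1)),
    genotypes = gt_list
  )
}
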