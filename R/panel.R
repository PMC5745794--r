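#' Construct a haplotype panel
#'
#' A haplotype panel is a phased binary haplotype-by-site matrix with physical
#' positions and a population label per haplotype — the working representation
#' of a resequencing panel of selfing strains, each strain contributing one
#' haplotype.
#'
#' @param matrix Integer 0/1 matrix, haplotypes in rows, segregating sites in
#'   columns. Every column must be polymorphic.
#' @param positions Strictly increasing 1-based bp positions, one per column.
#' @param sequence_length Length of the simulated/represented sequence in bp.
#' @param pop_labels Character vector, one label per haplotype row.
#' @return An object of class `hap_panel`.
#' @examples
#' hap_panel(matrix(c(0, 1, 0, 1), 2), c(10, 20), 100, c("A", "B"))
#' @export
hap_panel <- function(matrix, positions, sequence_length, pop_labels) {
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "integer"
  positions <- as.integer(positions)
  if (ncol(matrix) != length(positions))
    abort("positions must have one entry per matrix column")
  if (nrow(matrix) != length(pop_labels))
    abort("pop_labels must have one entry per matrix row")
  if (length(positions) && (any(diff(positions) <= 0)))
    abort("positions must be strictly increasing")
  if (length(positions) &&
      (min(positions) < 1 || max(positions) > sequence_length))
    abort("positions must lie in [1, sequence_length]")
  if (!all(matrix %in% c(0L, 1L))) abort("matrix entries must be 0/1")
  if (ncol(matrix)) {
    cs <- colSums(matrix)
    if (any(cs == 0L | cs == nrow(matrix)))
      abort("every column must be polymorphic")
  }
  structure(
    list(
      matrix = matrix,
      positions = positions,
      sequence_length = as.integer(sequence_length),
      pop_labels = as.character(pop_labels)
    ),
    class = "hap_panel"
  )
}

#' @export
print.hap_panel <- function(x, ...) {
  cat(sprintf("<hap_panel> %d haplotypes x %d segregating sites over %s bp\n",
              nrow(x$matrix), ncol(x$matrix),
              format(x$sequence_length, big.mark = ",")))
  tab <- table(x$pop_labels)
  cat("  populations:",
      paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.hap_panel <- function(x) dim(x$matrix)

#' Long-format view of a haplotype panel
#'
#' @param x A `hap_panel`.
#' @param ... Unused.
#' @return A tibble with columns `haplotype`, `population`, `position`,
#'   `allele`.
#' @importFrom tibble as_tibble
#' @export
as_tibble.hap_panel <- function(x, ...) {
  if (ncol(x$matrix) == 0) {
    return(tibble::tibble(haplotype = integer(), population = character(),
                          position = integer(), allele = integer()))
  }
  tibble::tibble(
    haplotype = rep(seq_len(nrow(x$matrix)), times = ncol(x$matrix)),
    population = rep(x$pop_labels, times = ncol(x$matrix)),
    position = rep(x$positions, each = nrow(x$matrix)),
    allele = as.integer(x$matrix)
  )
}

#' Simulate a haplotype panel under a demographic model
#'
#' Draws a sample genealogy under the structured coalescent implied by
#' `model` (piecewise sizes, divergence, migration windows), places mutations
#' by an infinite-sites approximation (Poisson with rate mu per bp per
#' generation along branches; positions uniform, collisions re-drawn) and
#' returns the resulting 0/1 haplotype matrix. With
#' `with_recombination = TRUE` a Hudson-style ancestral recombination graph is
#' simulated so linkage disequilibrium decays with physical distance.
#'
#' @param model A [demographic_model()].
#' @param n_per_deme Haplotype sample sizes: length 1 for one-deme models,
#'   length 2 (deme 1, deme 2) for two-deme models.
#' @param length Sequence length in bp.
#' @param seed Integer seed; identical seeds give identical panels.
#' @param with_recombination Simulate recombination at the model's
#'   `recombination_rate`? Default `TRUE`.
#' @param pop_names Labels used for the two demes (default `"popY"`,
#'   `"popN"`).
#' @return A [hap_panel()].
#' @examples
#' m <- demographic_model(
#'   epochs = data.frame(deme = 1, t_start = 0, size = 1e4),
#'   n_demes = 1
#' )
#' simulate_panel(m, 5, 1e4, seed = 1, with_recombination = FALSE)
#' @export
simulate_panel <- function(model, n_per_deme, length, seed,
                           with_recombination = TRUE,
                           pop_names = c("popY", "popN")) {
  stopifnot(inherits(model, "demographic_model"))
  if (length < 1) abort("length must be >= 1")
  n_per_deme <- as.integer(n_per_deme)
  if (any(n_per_deme < 1)) abort("need at least one haplotype per deme")
  if (model$n_demes == 1 && length(n_per_deme) != 1)
    abort("a one-deme model takes a single sample size")
  if (model$n_demes == 2 && length(n_per_deme) != 2)
    abort("a two-deme model takes two sample sizes; got one")
  n1 <- n_per_deme[1]
  n2 <- if (model$n_demes == 2) n_per_deme[2] else 0L
  args <- model_cpp_args(model)
  rec <- if (isTRUE(with_recombination)) model$recombination_rate else 0
  set.seed(seed)
  res <- .panel_cpp(n1, n2, length, model$mutation_rate, rec,
                    args$t_div, args$d1_t, args$d1_N, args$d2_t, args$d2_N,
                    args$anc_t, args$anc_N, args$mig_t0, args$mig_t1,
                    args$m12, args$m21)
  ord <- order(res$positions)
  labels <- c(rep(pop_names[1], n1), rep(pop_names[2], n2))
  hap_panel(
    matrix = res$geno[, ord, drop = FALSE],
    positions = res$positions[ord],
    sequence_length = length,
    pop_labels = labels
  )
}

#' Simulate a set of independent null panels
#'
#' Generates `n_datasets` independent panels under one model, for
#' sweep-cutoff calibration or parametric bootstrapping. Per-dataset seeds are
#' derived deterministically from the master seed, so any single replicate is
#' reproducible in isolation.
#'
#' @inheritParams simulate_panel
#' @param n_datasets Number of panels.
#' @return A list of [hap_panel()] objects.
#' @examples
#' m <- demographic_model(
#'   epochs = data.frame(deme = 1, t_start = 0, size = 1e4), n_demes = 1
#' )
#' panels <- simulate_null_set(m, 3, 1e4, 4, seed = 7,
#'                             with_recombination = FALSE)
#' length(panels)
#' @export
simulate_null_set <- function(model, n_datasets, length, n_per_deme, seed,
                              with_recombination = TRUE,
                              pop_names = c("popY", "popN")) {
  if (n_datasets < 1) abort("n_datasets must be >= 1")
  lapply(seq_len(n_datasets), function(i) {
    simulate_panel(model, n_per_deme, length, seed = derive_seed(seed, i),
                   with_recombination = with_recombination,
                   pop_names = pop_names)
  })
}

# ---- panel import/export -----------------------------------------------------

#' Export a haplotype panel as a minimal VCF
#'
#' Writes a VCF v4.2 with phased GT-only haploid calls on a single
#' pseudo-contig, one sample per haplotype. [read_panel_vcf()] reads such a
#' file (or any GT-only haploid VCF) back into a panel; population labels are
#' recovered from the sample names (`<label>_h<i>`).
#'
#' @param panel A [hap_panel()].
#' @param path Output path.
#' @param chrom Contig name.
#' @return `write_panel_vcf()` returns `path` invisibly; `read_panel_vcf()`
#'   returns a [hap_panel()].
#' @examples
#' p <- hap_panel(matrix(c(0, 1, 0, 1), 2), c(10, 20), 100, c("A", "B"))
#' f <- tempfile(fileext = ".vcf")
#' write_panel_vcf(p, f)
#' read_panel_vcf(f)
#' @export
write_panel_vcf <- function(panel, path, chrom = "sim1") {
  stopifnot(inherits(panel, "hap_panel"))
  samples <- sprintf("%s_h%d", panel$pop_labels, seq_along(panel$pop_labels))
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", chrom, panel$sequence_length),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  gt <- apply(panel$matrix, 2, as.character)
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(panel$matrix))
  body <- vapply(seq_along(panel$positions), function(j) {
    paste(c(chrom, panel$positions[j], ".", "A", "T", ".", "PASS", ".", "GT",
            gt[, j]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_panel_vcf
#' @export
read_panel_vcf <- function(path) {
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  # haploid phased calls: keep the first allele of any ploidy notation
  gt <- apply(gt_raw, c(1, 2), function(g) as.integer(sub("[/|].*$", "", g)))
  samples <- colnames(gt_raw)
  pos <- as.integer(vcfR::getPOS(v))
  contig <- grep("^##contig=", v@meta, value = TRUE)
  seq_len_bp <- if (length(contig)) {
    as.integer(sub(".*length=([0-9]+).*", "\\1", contig[1]))
  } else {
    max(pos)
  }
  ord <- order(pos)
  gt <- unname(t(gt))
  hap_panel(
    matrix = gt[, ord, drop = FALSE],
    positions = pos[ord],
    sequence_length = seq_len_bp,
    pop_labels = sub("_h[0-9]+$", "", samples)
  )
}

#' Flat text export of a haplotype panel
#'
#' A simple two-part text format: a header line
#' `#haplotypes n length L`, a line of population labels, a line of
#' positions, then one row of 0/1 alleles per haplotype.
#'
#' @inheritParams write_panel_vcf
#' @return `write_panel_flat()` returns `path` invisibly; `read_panel_flat()`
#'   a [hap_panel()].
#' @export
write_panel_flat <- function(panel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#haplotypes %d length %d", nrow(panel$matrix),
                     panel$sequence_length), con)
  writeLines(paste(panel$pop_labels, collapse = "\t"), con)
  writeLines(paste(panel$positions, collapse = "\t"), con)
  for (i in seq_len(nrow(panel$matrix)))
    writeLines(paste(panel$matrix[i, ], collapse = ""), con)
  invisible(path)
}

#' @rdname write_panel_flat
#' @export
read_panel_flat <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1], " ")[[1]]
  len <- as.integer(hdr[4])
  labels <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  pos <- as.integer(strsplit(lines[3], "\t", fixed = TRUE)[[1]])
  mat <- do.call(rbind, lapply(lines[-(1:3)], function(l) {
    as.integer(strsplit(l, "")[[1]])
  }))
  hap_panel(mat, pos, len, labels)
}
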