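#' Define a one- or two-deme demographic model
#'
#' A demographic model describes, backwards in time, piecewise-constant
#' diploid effective sizes for one or two demes, an optional divergence event
#' at which the two demes merge into a single ancestral deme, and timed
#' migration windows during which lineages switch demes. It is the input to
#' [simulate_panel()], [expected_sfs()] and the demographic fitting functions.
#'
#' Conventions: all times are in generations before present; sizes are diploid
#' effective sizes (pairwise coalescence rate \eqn{1/2N} per generation,
#' appropriate when highly selfing strains are sampled as single haplotypes);
#' migration rates are backwards-in-time per-lineage per-generation
#' deme-switch probabilities (`m12` = a deme-1 lineage moves to deme 2, which
#' forwards in time is gene flow from deme 2 into deme 1). Deme 1 is the
#' focal/derived population throughout the package (popY in the built-in
#' templates), deme 2 the reference population (popN).
#'
#' @param epochs A data frame with columns `deme` (1 or 2), `t_start`
#'   (generations before present; each deme needs a row with `t_start = 0`)
#'   and `size` (diploid Ne). The size of a deme at time `t` is the `size` of
#'   its epoch with the largest `t_start <= t`.
#' @param n_demes 1 or 2.
#' @param divergence_time Generations before present at which the two demes
#'   merge (backwards in time) into the ancestral deme. Required when
#'   `n_demes = 2`.
#' @param ancestral_size Diploid Ne of the ancestral deme.
#' @param migration_windows `NULL`, or a data frame with columns `t_start`,
#'   `t_end` (generations, `0 <= t_start < t_end <= divergence_time`), `m12`
#'   and `m21` (per-generation migration fractions in `[0, 1)`).
#' @param mutation_rate Per-bp per-generation mutation rate.
#' @param recombination_rate Per-bp per-generation recombination rate
#'   (3.6e-8 corresponds to 3.6 cM/Mb).
#' @param generation_years Years per generation, used only by
#'   [years_from_generations()].
#' @param migration_units Either `"fraction"` (default: `m12`/`m21` are
#'   per-generation per-lineage rates) or `"migrants"` (they are numbers of
#'   migrant lineages per generation, `2Nm`, converted to fractions using the
#'   receiving deme's size in the window).
#' @param label Optional model name.
#'
#' @return An object of class `demographic_model`.
#' @examples
#' m <- demographic_model(
#'   epochs = data.frame(deme = c(1, 2), t_start = 0, size = c(5e4, 2e4)),
#'   divergence_time = 6e4, ancestral_size = 1.5e5
#' )
#' m
#' @export
demographic_model <- function(epochs,
                              n_demes = 2,
                              divergence_time = NULL,
                              ancestral_size = NULL,
                              migration_windows = NULL,
                              mutation_rate = 7e-9,
                              recombination_rate = 3.6e-8,
                              generation_years = 1,
                              migration_units = c("fraction", "migrants"),
                              label = NULL) {
  migration_units <- match.arg(migration_units)
  if (!n_demes %in% c(1L, 2L)) abort("n_demes must be 1 or 2")
  epochs <- tibble::as_tibble(epochs)
  stopifnot(all(c("deme", "t_start", "size") %in% names(epochs)))
  epochs <- dplyr::arrange(epochs, .data$deme, .data$t_start)
  if (any(epochs$size <= 0)) abort("all deme sizes must be > 0")
  for (d in seq_len(n_demes)) {
    ts <- epochs$t_start[epochs$deme == d]
    if (length(ts) == 0 || ts[1] != 0)
      abort(sprintf("deme %d needs an epoch starting at t = 0", d))
    if (anyDuplicated(ts)) abort("duplicated epoch start times")
  }
  if (n_demes == 2L) {
    if (is.null(divergence_time) || is.null(ancestral_size))
      abort("two-deme models need divergence_time and ancestral_size")
    if (divergence_time <= 0 || ancestral_size <= 0)
      abort("divergence_time and ancestral_size must be > 0")
  } else {
    divergence_time <- Inf
    ancestral_size <- NULL
    migration_windows <- NULL
  }
  if (!is.null(migration_windows) && nrow(migration_windows) > 0) {
    mw <- tibble::as_tibble(migration_windows)
    stopifnot(all(c("t_start", "t_end", "m12", "m21") %in% names(mw)))
    if (any(mw$t_start < 0 | mw$t_start >= mw$t_end | mw$t_end > divergence_time))
      abort("migration windows must satisfy 0 <= t_start < t_end <= divergence_time")
    if (any(mw$m12 < 0 | mw$m21 < 0))
      abort("migration rates must be >= 0")
    if (migration_units == "fraction" &&
        any(mw$m12 >= 1 | mw$m21 >= 1))
      abort("migration fractions must lie in [0, 1)")
    migration_windows <- dplyr::arrange(mw, .data$t_start)
  } else {
    migration_windows <- tibble::tibble(
      t_start = double(), t_end = double(), m12 = double(), m21 = double()
    )
  }
  if (mutation_rate < 0 || recombination_rate < 0)
    abort("mutation and recombination rates must be >= 0")
  if (generation_years <= 0) abort("generation_years must be > 0")
  structure(
    list(
      n_demes = as.integer(n_demes),
      epochs = epochs,
      divergence_time = divergence_time,
      ancestral_size = ancestral_size,
      migration_windows = migration_windows,
      mutation_rate = mutation_rate,
      recombination_rate = recombination_rate,
      generation_years = generation_years,
      migration_units = migration_units,
      label = label
    ),
    class = "demographic_model"
  )
}

#' @export
print.demographic_model <- function(x, ...) {
  cat("<demographic_model>", x$label %||% "", "\n")
  cat("  demes:", x$n_demes, "\n")
  for (d in seq_len(x$n_demes)) {
    e <- x$epochs[x$epochs$deme == d, ]
    cat(sprintf("  deme %d sizes: %s (from t = %s)\n", d,
                paste(format(e$size, big.mark = ","), collapse = ", "),
                paste(format(e$t_start, big.mark = ","), collapse = ", ")))
  }
  if (x$n_demes == 2) {
    cat(sprintf("  divergence: t = %s into N_anc = %s\n",
                format(x$divergence_time, big.mark = ","),
                format(x$ancestral_size, big.mark = ",")))
    if (nrow(x$migration_windows))
      cat(sprintf("  migration windows: %d\n", nrow(x$migration_windows)))
  }
  cat(sprintf("  mu = %.3g /bp/gen, r = %.3g /bp/gen, g = %g yr\n",
              x$mutation_rate, x$recombination_rate, x$generation_years))
  invisible(x)
}

# Effective (fraction-unit) migration windows, converting 2Nm if requested.
effective_migration <- function(model) {
  mw <- model$migration_windows
  if (nrow(mw) == 0 || model$migration_units == "fraction") return(mw)
  # migrants -> fractions: rate per lineage = M / (2 N_receiving)
  m12 <- m21 <- numeric(nrow(mw))
  for (k in seq_len(nrow(mw))) {
    tm <- (mw$t_start[k] + mw$t_end[k]) / 2
    m12[k] <- mw$m12[k] / (2 * deme_size_at(model, 1, tm))
    m21[k] <- mw$m21[k] / (2 * deme_size_at(model, 2, tm))
  }
  mw$m12 <- m12
  mw$m21 <- m21
  mw
}

deme_size_at <- function(model, deme, t) {
  if (model$n_demes == 2 && t >= model$divergence_time) return(model$ancestral_size)
  e <- model$epochs[model$epochs$deme == deme, ]
  e$size[max(which(e$t_start <= t))]
}

# Flattened arguments for the C++ engines.
model_cpp_args <- function(model) {
  e1 <- model$epochs[model$epochs$deme == 1, ]
  e2 <- model$epochs[model$epochs$deme == 2, ]
  mw <- effective_migration(model)
  two <- model$n_demes == 2
  list(
    t_div = if (two) model$divergence_time else Inf,
    d1_t = e1$t_start, d1_N = e1$size,
    d2_t = if (nrow(e2)) e2$t_start else 0,
    d2_N = if (nrow(e2)) e2$size else 1,
    anc_t = if (two) model$divergence_time else 0,
    anc_N = if (two) model$ancestral_size else 1,
    mig_t0 = mw$t_start, mig_t1 = mw$t_end,
    m12 = mw$m12, m21 = mw$m21
  )
}

#' Built-in two-population demographic model templates
#'
#' Returns the four competing demographic scenarios for the divergence of the
#' Yangtze River basin population (popY, deme 1) from the north-western China
#' population (popN, deme 2) of *Arabidopsis thaliana*: M1, clean split with
#' no gene flow; M2, one post-divergence migration window; M3, continuous
#' migration from the divergence to the present; M4, two asymmetric migration
#' windows. M4 carries the published best-fit parameter vector (divergence
#' 61,409 generations ago from an ancestral population of 179,724; popN
#' 26,959 then 45,617 from 7,169 generations ago; popY 78,454 then 45,089
#' from 7,543 generations ago; gene-flow windows 18,652–14,307 and 8,440–7,660
#' generations ago). The other models share the divergence/size skeleton and
#' leave the migration structure free. All templates use mu = 7e-9 per bp per
#' generation, r = 3.6 cM/Mb and a one-year generation time.
#'
#' The migration *rates* of the two windows are not published; the templates
#' default to weak asymmetric flow (backward rates 2e-5 from popY, 5e-6 from
#' popN per generation).
#'
#' @param migration_units `"fraction"` (per-generation rates, default) or
#'   `"migrants"` (2Nm); see [demographic_model()].
#' @return A named list of four `demographic_model` objects (`M1`–`M4`).
#' @examples
#' mods <- yangtze_demographic_models()
#' mods$M4
#' @export
yangtze_demographic_models <- function(migration_units = "fraction") {
  epochs <- tibble::tibble(
    deme = c(1, 1, 2, 2),
    t_start = c(0, 7543, 0, 7169),
    size = c(45089, 78454, 45617, 26959)
  )
  t_div <- 61409
  n_anc <- 179724
  m_out <- 2e-5   # backward rate, popY lineage -> popN
  m_in <- 5e-6    # backward rate, popN lineage -> popY
  conv <- function(m, N) if (migration_units == "migrants") m * 2 * N else m
  base <- function(mw, label) {
    demographic_model(
      epochs = epochs, n_demes = 2, divergence_time = t_div,
      ancestral_size = n_anc, migration_windows = mw,
      mutation_rate = 7e-9, recombination_rate = 3.6e-8,
      generation_years = 1, migration_units = migration_units, label = label
    )
  }
  w <- function(t0, t1) tibble::tibble(
    t_start = t0, t_end = t1,
    m12 = conv(m_out, 45089), m21 = conv(m_in, 45617)
  )
  list(
    M1 = base(NULL, "M1: isolation, no gene flow"),
    M2 = base(w(14307, 18652), "M2: one migration window"),
    M3 = base(w(0, t_div), "M3: continuous migration"),
    M4 = base(dplyr::bind_rows(w(14307, 18652), w(7660, 8440)),
              "M4: two asymmetric migration windows (best fit)")
  )
}

# ---- named-parameter access used by the fitting machinery --------------------

#' Get or set named model parameters
#'
#' The fitting functions address a model's free parameters by name:
#' `t_div`, `n_anc`, `n<d>_e<k>` (size of deme `d` in its `k`-th epoch, `e1`
#' most recent), `t<d>_e<k>` (start time of epoch `k >= 2`), and per migration
#' window `k`: `m12_w<k>`, `m21_w<k>`, `tw<k>_start`, `tw<k>_end`.
#'
#' @param model A `demographic_model`.
#' @param params Named numeric vector of parameter values to set.
#' @return `model_params()` returns a named numeric vector;
#'   `set_model_params()` returns the updated model.
#' @examples
#' m <- yangtze_demographic_models()$M4
#' model_params(m)[c("t_div", "n_anc")]
#' m2 <- set_model_params(m, c(t_div = 50000))
#' @export
model_params <- function(model) {
  out <- c()
  if (model$n_demes == 2)
    out <- c(t_div = model$divergence_time, n_anc = model$ancestral_size)
  for (d in seq_len(model$n_demes)) {
    e <- model$epochs[model$epochs$deme == d, ]
    for (k in seq_len(nrow(e))) {
      out[sprintf("n%d_e%d", d, k)] <- e$size[k]
      if (k > 1) out[sprintf("t%d_e%d", d, k)] <- e$t_start[k]
    }
  }
  mw <- model$migration_windows
  for (k in seq_len(nrow(mw))) {
    out[sprintf("m12_w%d", k)] <- mw$m12[k]
    out[sprintf("m21_w%d", k)] <- mw$m21[k]
    out[sprintf("tw%d_start", k)] <- mw$t_start[k]
    out[sprintf("tw%d_end", k)] <- mw$t_end[k]
  }
  out
}

#' @rdname model_params
#' @export
set_model_params <- function(model, params) {
  stopifnot(is.numeric(params), !is.null(names(params)))
  for (nm in names(params)) {
    v <- unname(params[[nm]])
    if (nm == "t_div") {
      model$divergence_time <- v
    } else if (nm == "n_anc") {
      model$ancestral_size <- v
    } else if (grepl("^n[12]_e[0-9]+$", nm)) {
      d <- as.integer(substr(nm, 2, 2))
      k <- as.integer(sub("^n[12]_e", "", nm))
      idx <- which(model$epochs$deme == d)
      if (k > length(idx)) abort(paste("no such epoch:", nm))
      model$epochs$size[idx[k]] <- v
    } else if (grepl("^t[12]_e[0-9]+$", nm)) {
      d <- as.integer(substr(nm, 2, 2))
      k <- as.integer(sub("^t[12]_e", "", nm))
      idx <- which(model$epochs$deme == d)
      if (k > length(idx) || k < 2) abort(paste("no such epoch time:", nm))
      model$epochs$t_start[idx[k]] <- v
    } else if (grepl("^m(12|21)_w[0-9]+$", nm)) {
      k <- as.integer(sub("^m(12|21)_w", "", nm))
      col <- substr(nm, 1, 3)
      if (k > nrow(model$migration_windows)) abort(paste("no such window:", nm))
      model$migration_windows[[col]][k] <- v
    } else if (grepl("^tw[0-9]+_(start|end)$", nm)) {
      k <- as.integer(sub("^tw([0-9]+)_.*$", "\\1", nm))
      col <- paste0("t_", sub("^tw[0-9]+_", "", nm))
      if (k > nrow(model$migration_windows)) abort(paste("no such window:", nm))
      model$migration_windows[[col]][k] <- v
    } else {
      abort(paste("unknown model parameter:", nm))
    }
  }
  # migration can only operate while the demes are separate: when a proposed
  # divergence time undercuts a window, clip the window (drop it if empty)
  if (model$n_demes == 2 && nrow(model$migration_windows)) {
    mw <- model$migration_windows
    mw$t_end <- pmin(mw$t_end, model$divergence_time)
    mw <- mw[mw$t_start < mw$t_end, , drop = FALSE]
    model$migration_windows <- mw
  }
  # re-validate
  demographic_model(
    epochs = model$epochs, n_demes = model$n_demes,
    divergence_time = if (model$n_demes == 2) model$divergence_time else NULL,
    ancestral_size = model$ancestral_size,
    migration_windows = if (nrow(model$migration_windows)) model$migration_windows else NULL,
    mutation_rate = model$mutation_rate,
    recombination_rate = model$recombination_rate,
    generation_years = model$generation_years,
    migration_units = model$migration_units,
    label = model$label
  )
}

#' Read or write a demographic model as a YAML config file
#'
#' @param model A `demographic_model`.
#' @param path File path.
#' @return `write_model_config()` returns `path` invisibly;
#'   `read_model_config()` returns a `demographic_model`.
#' @examples
#' f <- tempfile(fileext = ".yml")
#' write_model_config(yangtze_demographic_models()$M1, f)
#' read_model_config(f)
#' @export
write_model_config <- function(model, path) {
  obj <- list(
    label = model$label,
    n_demes = model$n_demes,
    epochs = lapply(seq_len(nrow(model$epochs)), function(i) as.list(model$epochs[i, ])),
    divergence_time = if (is.finite(model$divergence_time)) model$divergence_time,
    ancestral_size = model$ancestral_size,
    migration_windows = lapply(
      seq_len(nrow(model$migration_windows)),
      function(i) as.list(model$migration_windows[i, ])
    ),
    mutation_rate = model$mutation_rate,
    recombination_rate = model$recombination_rate,
    generation_years = model$generation_years,
    migration_units = model$migration_units
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  obj <- yaml::read_yaml(path)
  demographic_model(
    epochs = dplyr::bind_rows(lapply(obj$epochs, tibble::as_tibble)),
    n_demes = obj$n_demes,
    divergence_time = obj$divergence_time,
    ancestral_size = obj$ancestral_size,
    migration_windows = if (length(obj$migration_windows))
      dplyr::bind_rows(lapply(obj$migration_windows, tibble::as_tibble)),
    mutation_rate = obj$mutation_rate,
    recombination_rate = obj$recombination_rate,
    generation_years = obj$generation_years,
    migration_units = obj$migration_units %||% "fraction",
    label = obj$label
  )
}
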