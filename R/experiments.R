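#' Default drive-frequency ladder (s^-1)
#'
#' The seven drive angular frequencies of the sweep experiment, from
#' 1e11 s^-1 down to 1e8 s^-1 plus the constant-force baseline omega = 0.
#'
#' @return Numeric vector of angular frequencies.
#' @export
default_omega_ladder <- function()
  c(1e11, 5e10, 1e10, 5e9, 1e9, 1e8, 0)

#' Assemble an experiment configuration
#'
#' Composes a sequence source, optional edits, a drive specification, and
#' integration settings into one object consumed by the experiment
#' drivers. Exactly one of `sequence`, `fasta`, `synthetic` must be given.
#'
#' @param sequence A ready-made `dna_sequence`.
#' @param fasta Path to a FASTA file (first record used).
#' @param synthetic List with `n`, and optionally `gc_fraction` and `seed`,
#'   passed to [random_sequence()].
#' @param omega_ladder Drive angular frequencies for sweeps (s^-1).
#' @param F0 Drive amplitude (J).
#' @param variant RHS variant, as in [build_system()].
#' @param settings An `integration_settings`; default: t_end = 5e-9 s at
#'   dt = 1e-14 s.
#' @param transient_cutoff Transient cutoff for summaries (s).
#' @param substitution_omega Drive frequency for the block-substitution
#'   battery (s^-1).
#' @param edits Named list of block edits, each
#'   `list(start =, length =, base =)`; `NULL` means the standard battery
#'   of centered blocks (40A, 40T, 40G, 40C, 100A) sized to the sequence.
#' @param params A `param_table`.
#' @param outdir Optional output directory for [generate_report()].
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(sequence = NULL, fasta = NULL, synthetic = NULL,
                              omega_ladder = default_omega_ladder(),
                              F0 = 0.5e-22,
                              variant = "as_printed",
                              settings = integration_settings(t_end = 5e-9),
                              transient_cutoff = 0.5e-9,
                              substitution_omega = 1e8,
                              edits = NULL,
                              params = default_param_table(),
                              outdir = NULL) {
  sources <- c(!is.null(sequence), !is.null(fasta), !is.null(synthetic))
  if (sum(sources) != 1L)
    stop("give exactly one of `sequence`, `fasta`, `synthetic`")
  if (any(omega_ladder < 0)) stop("omega ladder values must be >= 0")
  seq <- if (!is.null(sequence)) {
    stopifnot(inherits(sequence, "dna_sequence")); sequence
  } else if (!is.null(fasta)) {
    read_fasta(fasta)
  } else {
    do.call(random_sequence, synthetic)
  }
  structure(list(sequence = seq, omega_ladder = omega_ladder, F0 = F0,
                 variant = variant, settings = settings,
                 transient_cutoff = transient_cutoff,
                 substitution_omega = substitution_omega,
                 edits = edits, params = params, outdir = outdir),
            class = "experiment_config")
}

simulate_one <- function(config, seq, omega) {
  sys <- build_system(seq, params = config$params,
                      force = force_spec(F0 = config$F0, omega = omega),
                      variant = config$variant)
  traj <- integrate_duplex(sys, config$settings)
  run_summary(traj, transient_cutoff = config$transient_cutoff)
}

#' Drive-frequency sweep
#'
#' Simulates the configured sequence once per ladder frequency and reports
#' each run's post-transient amplitude and dominant frequency together
#' with the relative deviation of that frequency from the omega = 0
#' (constant force) run, which serves as the internal reference for the
#' drive-independence comparison. omega = 0 is appended to the ladder if
#' absent.
#'
#' @param config An `experiment_config`.
#' @return A list with `summaries` (named list of `run_summary`) and
#'   `table` (data frame: omega, amplitude, dominant_frequency,
#'   rel_dev_vs_const, status).
#' @export
run_frequency_sweep <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  ladder <- config$omega_ladder
  if (!0 %in% ladder) ladder <- c(ladder, 0)
  summaries <- list()
  status <- character(length(ladder))
  for (i in seq_along(ladder)) {
    om <- ladder[i]
    res <- tryCatch(simulate_one(config, config$sequence, om),
                    error = function(e) e)
    if (inherits(res, "error")) {
      status[i] <- conditionMessage(res)
    } else {
      status[i] <- "ok"
      summaries[[sprintf("omega_%g", om)]] <- res
    }
  }
  get_f <- function(om) {
    s <- summaries[[sprintf("omega_%g", om)]]
    if (is.null(s)) NA_real_ else s$dominant_frequency
  }
  f0 <- get_f(0)
  tab <- data.frame(
    omega = ladder,
    amplitude = vapply(ladder, function(om) {
      s <- summaries[[sprintf("omega_%g", om)]]
      if (is.null(s)) NA_real_ else s$amplitude
    }, numeric(1)),
    dominant_frequency = vapply(ladder, get_f, numeric(1)),
    status = status)
  tab$rel_dev_vs_const <- if (is.finite(f0) && f0 > 0)
    abs(tab$dominant_frequency - f0) / f0 else NA_real_
  list(summaries = summaries, table = tab)
}

standard_edit_battery <- function(n) {
  blocks <- list(`40A` = c(40L, "A"), `40T` = c(40L, "T"),
                 `40G` = c(40L, "G"), `40C` = c(40L, "C"),
                 `100A` = c(100L, "A"))
  blocks <- Filter(function(b) as.integer(b[1L]) <= n, blocks)
  lapply(blocks, function(b) {
    len <- as.integer(b[1L])
    list(start = centered_block_start(n, len), length = len, base = b[2L])
  })
}

#' Homopolymer block-substitution battery
#'
#' Simulates the unedited sequence and each edited variant at a fixed
#' drive frequency (default omega = 1e8 s^-1), reporting per-variant
#' post-transient amplitudes (under all three estimators, as a sensitivity
#' check), dominant frequencies, amplitude ratios against the unedited
#' run, the full pairwise ratio matrix, and the ordering of variants by
#' amplitude.
#'
#' @param config An `experiment_config`. `config$edits` may name the
#'   variants explicitly; by default the centered 40A/40T/40G/40C/100A
#'   battery sized to the sequence is used.
#' @return A list with `summaries`, `table`, `ratio_matrix` (default
#'   estimator), and `ordering` (variant names, largest amplitude first).
#' @export
run_substitution_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  seq <- config$sequence
  edits <- config$edits
  if (is.null(edits)) edits <- standard_edit_battery(length(seq))
  variants <- c(list(unedited = NULL), edits)
  om <- config$substitution_omega
  summaries <- list()
  rows <- list()
  for (nm in names(variants)) {
    ed <- variants[[nm]]
    sq <- if (is.null(ed)) seq else
      substitute_region(seq, ed$start, ed$length, ed$base)
    sm <- simulate_one(config, sq, om)
    summaries[[nm]] <- sm
    amps <- vapply(c("half_range", "rms", "max_abs"), function(m)
      amplitude(sm$series, method = m), numeric(1))
    rows[[nm]] <- data.frame(
      variant = nm, omega = om,
      amplitude = amps[["half_range"]],
      amplitude_rms = amps[["rms"]],
      amplitude_max_abs = amps[["max_abs"]],
      dominant_frequency = sm$dominant_frequency)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab$ratio_vs_unedited <- tab$amplitude / tab$amplitude[tab$variant == "unedited"]
  nm <- tab$variant
  rm_ <- outer(tab$amplitude, tab$amplitude, "/")
  dimnames(rm_) <- list(nm, nm)
  ordering <- nm[order(tab$amplitude, decreasing = TRUE)]
  list(summaries = summaries, table = tab, ratio_matrix = rm_,
       ordering = ordering)
}

#' Write report files for a set of runs
#'
#' Writes `summary.tsv` (one row per run), `ratio_matrix.tsv` (pairwise
#' amplitude ratios, only when there is more than one run), and optionally
#' `mean_deviation.png`, the classic stacked presentation of the chain-1
#' mean angular deviation curves with per-run vertical offsets. Output is
#' deterministic: identical inputs give byte-identical tables.
#'
#' @param summaries Named list of `run_summary` objects.
#' @param out Output directory (created if missing).
#' @param plot Logical; also write the offset trajectory plot.
#' @return Character vector of the files written, invisibly.
#' @export
generate_report <- function(summaries, out, plot = FALSE) {
  if (length(summaries) < 1L) stop("need at least one run summary")
  stopifnot(all(vapply(summaries, inherits, logical(1), "run_summary")))
  if (is.null(names(summaries)) || any(!nzchar(names(summaries))))
    names(summaries) <- sprintf("run%d", seq_along(summaries))
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)

  tab <- do.call(rbind, lapply(names(summaries), function(nm) {
    s <- summaries[[nm]]
    m <- s$metadata
    data.frame(run = nm, sequence = m$sequence_id, n = m$n,
               omega = m$omega, F0 = m$F0, variant = m$variant,
               amplitude = s$amplitude,
               dominant_frequency = s$dominant_frequency)
  }))
  f <- file.path(out, "summary.tsv")
  utils::write.table(tab, f, sep = "\t", row.names = FALSE, quote = FALSE)
  written <- c(written, f)

  if (length(summaries) > 1L) {
    amps <- vapply(summaries, `[[`, numeric(1), "amplitude")
    rm_ <- outer(amps, amps, "/")
    dimnames(rm_) <- list(names(summaries), names(summaries))
    f <- file.path(out, "ratio_matrix.tsv")
    utils::write.table(data.frame(run = rownames(rm_), rm_, check.names = FALSE),
                       f, sep = "\t", row.names = FALSE, quote = FALSE)
    written <- c(written, f)
  }

  if (isTRUE(plot)) {
    f <- file.path(out, "mean_deviation.png")
    grDevices::png(f, width = 1200, height = 200 + 160 * length(summaries),
                   res = 120)
    on.exit(grDevices::dev.off(), add = TRUE)
    spans <- vapply(summaries, function(s)
      diff(range(s$series$values)), numeric(1))
    off <- 1.2 * max(spans, na.rm = TRUE)
    graphics::plot(NA, xlim = range(summaries[[1L]]$series$times),
                   ylim = c(-off * 0.6, off * (length(summaries) - 0.4)),
                   xlab = "t (s)", ylab = "mean phi1 (rad, offset per run)",
                   yaxt = "n")
    for (i in seq_along(summaries)) {
      s <- summaries[[i]]$series
      graphics::lines(s$times, s$values - mean(s$values) + (i - 1) * off)
      graphics::text(s$times[1L], (i - 1) * off + 0.35 * off,
                     names(summaries)[i], adj = 0, cex = 0.8)
    }
    written <- c(written, f)
  }
  invisible(written)
}
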