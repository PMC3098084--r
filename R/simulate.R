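#' Configuration for a synthetic two-channel experiment
#'
#' Describes a common-reference two-channel microarray study with two known
#' classes of samples, class-discriminating genes, and the artifacts that the
#' pre-processing stages are designed to remove: intensity-dependent dye bias,
#' print-tip block offsets, additive background, flagged spots, missing values
#' and duplicate spots.
#'
#' @param n_samples_per_class Integer pair: samples in class A and class B.
#' @param n_genes Number of distinct genes on the array.
#' @param n_de_genes Number of genes differentially expressed between the two
#'   classes (0 allowed).
#' @param de_effect Mean between-class difference in true log2-ratio (M) for
#'   the differentially expressed genes, in log2 units; must be >= 0.
#' @param dye_bias_amplitude Amplitude of the intensity-dependent additive M
#'   offset (log2 units); 0 disables dye bias.
#' @param n_printtip_blocks Number of print-tip blocks on the array.
#' @param block_offset_sd SD of the per-array, per-block additive M offset
#'   (log2 units).
#' @param background_mean Mean of the additive spot background (intensity
#'   units, both channels).
#' @param noise_sd Spot-level M noise SD (log2 units).
#' @param flag_rate Fraction of spots flagged per array, in \[0, 1).
#' @param missing_rate Fraction of additional spots missing completely at
#'   random per array, in \[0, 1).
#' @param duplicate_fraction Fraction of genes printed as two spots sharing a
#'   gene ID, in \[0, 1).
#' @param seed Integer RNG seed; the whole experiment is reproducible from it.
#' @return An object of class \code{sim_config}.
#' @details Defaults emulate published common-reference cancer studies of
#'   40-133 samples on arrays of several thousand spots: 60 samples split
#'   30/30, 8000 genes with 5\% differentially expressed at a 1 log2-unit
#'   shift, a 0.3 log2-unit dye-bias curve over 16 print-tip blocks, and 2\%
#'   each of flagged and randomly missing spots.
#' @export
sim_config <- function(n_samples_per_class = c(30, 30),
                       n_genes = 8000,
                       n_de_genes = 400,
                       de_effect = 1.0,
                       dye_bias_amplitude = 0.3,
                       n_printtip_blocks = 16,
                       block_offset_sd = 0.1,
                       background_mean = 80,
                       noise_sd = 0.4,
                       flag_rate = 0.02,
                       missing_rate = 0.02,
                       duplicate_fraction = 0.05,
                       seed = 1) {
  cfg <- list(n_samples_per_class = as.integer(n_samples_per_class),
              n_genes = as.integer(n_genes),
              n_de_genes = as.integer(n_de_genes),
              de_effect = de_effect,
              dye_bias_amplitude = dye_bias_amplitude,
              n_printtip_blocks = as.integer(n_printtip_blocks),
              block_offset_sd = block_offset_sd,
              background_mean = background_mean,
              noise_sd = noise_sd,
              flag_rate = flag_rate,
              missing_rate = missing_rate,
              duplicate_fraction = duplicate_fraction,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(length(cfg$n_samples_per_class) == 2,
            all(cfg$n_samples_per_class >= 1),
            cfg$n_genes >= 1, cfg$n_de_genes >= 0,
            cfg$n_de_genes <= cfg$n_genes,
            cfg$de_effect >= 0, cfg$dye_bias_amplitude >= 0,
            cfg$n_printtip_blocks >= 1, cfg$block_offset_sd >= 0,
            cfg$background_mean >= 0, cfg$noise_sd >= 0)
  for (f in c("flag_rate", "missing_rate", "duplicate_fraction"))
    if (cfg[[f]] < 0 || cfg[[f]] >= 1)
      stop(sprintf("%s must lie in [0, 1)", f))
  if (cfg$flag_rate + cfg$missing_rate >= 0.5)
    stop("flag_rate + missing_rate >= 0.5: every sample would exceed the 50% ",
         "missing-value filter and filtration would remove all samples")
  invisible(cfg)
}

#' Generate a synthetic common-reference experiment
#'
#' Simulates one two-channel scan per sample. Per gene, a reference-channel
#' intensity is drawn from a log-normal; the sample channel equals the
#' reference times \code{2^M}, where the observed M is the true class-dependent
#' log2-ratio plus dye bias, a per-array print-tip block offset and spot noise.
#' An additive background is added to both channels. Flagged spots and spots
#' missing completely at random have their foreground zeroed so that they are
#' recovered as missing by \code{\link{compute_ma}}.
#'
#' @param config A \code{\link{sim_config}}.
#' @return An object of class \code{sim_experiment}: a list with \code{scans}
#'   (one \code{array_scan} per sample), \code{true_labels} (factor with
#'   levels \code{A}, \code{B}), \code{de_genes} (IDs of the planted
#'   differentially expressed genes) and \code{config}.
#' @details The dye bias is \eqn{b(A) = amplitude\,(\sin(2\pi (A - A_{min}) /
#'   (A_{max}-A_{min})) + 0.5\,(A - \bar A)/(A_{max}-A_{min}))}: a smooth
#'   curved trend in the MA-plane of the kind MA-loess is designed to remove.
#'   Differentially expressed genes are shifted by \code{+de_effect/2} in
#'   class A and \code{-de_effect/2} in class B (half up-, half down-regulated
#'   by sign of gene), so the expected between-class difference in true M is
#'   \code{de_effect}.
#' @export
simulate_experiment <- function(config) {
  validate_sim_config(config)
  withr_seed(config$seed, simulate_experiment_impl(config))
}

simulate_experiment_impl <- function(cfg) {
  n_a <- cfg$n_samples_per_class[1]
  n_b <- cfg$n_samples_per_class[2]
  n_samples <- n_a + n_b
  labels <- factor(rep(c("A", "B"), c(n_a, n_b)), levels = c("A", "B"))
  gene_ids <- sprintf("G%05d", seq_len(cfg$n_genes))

  # planted class structure: first n_de genes DE, alternating direction
  de_idx <- seq_len(cfg$n_de_genes)
  direction <- rep_len(c(1, -1), cfg$n_de_genes)
  delta <- numeric(cfg$n_genes)
  delta[de_idx] <- direction * cfg$de_effect

  # spot layout: duplicates appended as extra spots sharing the gene ID
  n_dup <- floor(cfg$duplicate_fraction * cfg$n_genes)
  dup_gene <- if (n_dup > 0) sample.int(cfg$n_genes, n_dup) else integer(0)
  spot_gene <- c(seq_len(cfg$n_genes), dup_gene)     # gene index per spot
  n_spots <- length(spot_gene)
  block <- rep(seq_len(cfg$n_printtip_blocks), length.out = n_spots)
  block <- sort(block)                               # contiguous blocks
  per_block <- tabulate(block, nbins = cfg$n_printtip_blocks)
  row_in_block <- unlist(lapply(per_block, seq_len), use.names = FALSE)

  # reference channel intensity per gene (shared across arrays)
  ref_gene <- 2^stats::rnorm(cfg$n_genes, mean = 10, sd = 1.5)
  ref <- ref_gene[spot_gene]
  sample_ids <- sprintf("S%03d", seq_len(n_samples))

  scans <- vector("list", n_samples)
  for (s in seq_len(n_samples)) {
    m_true <- delta[spot_gene] * (if (labels[s] == "A") 0.5 else -0.5)
    a_ideal <- 0.5 * (log2(ref * 2^m_true) + log2(ref))
    rng <- range(a_ideal)
    span <- max(rng[2] - rng[1], .Machine$double.eps)
    bias <- cfg$dye_bias_amplitude *
      (sin(2 * pi * (a_ideal - rng[1]) / span) +
         0.5 * (a_ideal - mean(a_ideal)) / span)
    block_off <- stats::rnorm(cfg$n_printtip_blocks, 0, cfg$block_offset_sd)
    m_obs <- m_true + bias + block_off[block] +
      stats::rnorm(n_spots, 0, cfg$noise_sd)
    fg_green <- ref
    fg_red <- ref * 2^m_obs
    bg <- function() {
      if (cfg$background_mean <= 0) rep(0, n_spots)
      else stats::rgamma(n_spots, shape = 4, scale = cfg$background_mean / 4)
    }
    bg_red <- bg(); bg_green <- bg()
    flagged <- stats::runif(n_spots) < cfg$flag_rate
    mcar <- stats::runif(n_spots) < cfg$missing_rate
    fg_red <- fg_red + bg_red
    fg_green <- fg_green + bg_green
    fg_red[mcar] <- 0
    fg_green[mcar] <- 0
    scans[[s]] <- array_scan(gene_id = gene_ids[spot_gene],
                             block = block,
                             row = row_in_block,
                             column = rep(1L, n_spots),
                             fg_red = fg_red, bg_red = bg_red,
                             fg_green = fg_green, bg_green = bg_green,
                             flagged = flagged,
                             sample_id = sample_ids[s])
  }
  structure(list(scans = scans,
                 true_labels = stats::setNames(labels, sample_ids),
                 de_genes = gene_ids[de_idx],
                 config = cfg),
            class = "sim_experiment")
}

#' @export
print.sim_experiment <- function(x, ...) {
  cat(sprintf("Synthetic two-channel experiment: %d samples (%s), %d spots, %d DE genes\n",
              length(x$scans),
              paste(table(x$true_labels), collapse = "/"),
              nrow(x$scans[[1]]$spots), length(x$de_genes)))
  invisible(x)
}

#' Write a synthetic experiment to scan files
#'
#' Writes one GPR-like tab-separated file per sample (columns \code{Block},
#' \code{Row}, \code{Column}, \code{ID}, \code{F635}, \code{B635},
#' \code{F532}, \code{B532}, \code{Flags}) plus a two-column \code{labels.tsv}
#' (sample_id, class). Files round-trip losslessly through
#' \code{\link{read_gpr}} and \code{\link{read_labels}}.
#'
#' @param experiment A \code{sim_experiment}.
#' @param directory Output directory (created if absent).
#' @return Invisibly, the vector of files written.
#' @export
write_scans <- function(experiment, directory) {
  stopifnot(inherits(experiment, "sim_experiment"))
  if (length(experiment$scans) == 0) stop("experiment contains no scans")
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (scan in experiment$scans) {
    path <- file.path(directory, paste0(scan$sample_id, ".gpr"))
    df <- data.frame(Block = scan$spots$block,
                     Row = scan$spots$row,
                     Column = scan$spots$column,
                     ID = scan$spots$gene_id,
                     F635 = scan$spots$fg_red,
                     B635 = scan$spots$bg_red,
                     F532 = scan$spots$fg_green,
                     B532 = scan$spots$bg_green,
                     Flags = ifelse(scan$spots$flagged, -50L, 0L))
    ok <- tryCatch({
      utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
      TRUE
    }, error = function(e) stop(sprintf("failed writing '%s': %s", path,
                                        conditionMessage(e))))
    files <- c(files, path)
  }
  lab_path <- file.path(directory, "labels.tsv")
  utils::write.table(data.frame(sample_id = names(experiment$true_labels),
                                class = as.character(experiment$true_labels)),
                     lab_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(files, lab_path))
}
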