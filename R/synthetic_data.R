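## Seeded synthetic fixtures with the statistical structure the analysis
## assumes: a random genome with planted DR3 motifs, true binding sites
## shared by variable numbers of cell types, per-sample summit jitter,
## log-normal fold enrichments and motif presence logistic in FE.
##
## All randomness flows from one seed: simulate_dataset() seeds the RNG
## once and draws in the documented order genome -> truth -> samples. The
## individual generator functions draw from the current RNG state.

#' Configuration of the synthetic-data generator
#'
#' Defaults emulate the study conditions of a six-cell-type VDR ChIP-seq
#' meta-analysis: sharing probabilities following the observed cell-type
#' specificity proportions (75.61% of sites in one cell type, 21.12% in
#' two, ... 0.18% in all six), stimulated/unstimulated state probabilities
#' following the observed unique-stimulated / unique-unstimulated / common
#' partition (59.9 / 27.6 / 12.5%), summit jitter of up to 5 bp matching
#' the +/- 10 bp consensus accuracy regime, log-normal fold enrichments
#' around 4, and DR3 motif presence whose probability is logistic in FE so
#' that high-FE peaks are motif-rich and low-FE peaks are not.
#'
#' @param seed integer RNG seed.
#' @param n_chroms number of chromosomes.
#' @param chrom_length chromosome length, bp.
#' @param base_composition background base probabilities (A, C, G, T).
#' @param n_true_sites number of true binding sites.
#' @param min_spacing minimal distance between true sites, bp; must exceed
#'   the motif length plus twice the summit jitter.
#' @param K_cell_types number of cell types.
#' @param cell_types cell type labels (length `K_cell_types`).
#' @param sharing_distribution probability that a site is active in k cell
#'   types, k = 1..K; normalised internally. `NULL` uses the observed
#'   six-cell-type proportions.
#' @param p_stim_only,p_unstim_only,p_both state probabilities per active
#'   (site, cell type); normalised internally.
#' @param summit_jitter maximal absolute integer summit jitter, bp.
#' @param fe_meanlog,fe_sdlog log-normal fold-enrichment parameters.
#' @param stim_fe_multiplier FE multiplier for stimulated samples.
#' @param motif_a,motif_b logistic motif model: P(motif | FE) =
#'   plogis(motif_a + motif_b * FE).
#' @param motif_fidelity total probability mass on the consensus base(s)
#'   when emitting each planted motif position.
#' @param peak_halfwidth half-width of emitted peak intervals, bp.
#' @param q_value constant -log10(q) written to emitted peaks (above the
#'   FDR presence cutoff; the q model itself is out of scope).
#' @return an object of class `sim_config`.
#' @export
simulation_config <- function(seed = 1L, n_chroms = 1L, chrom_length = 1e6,
                              base_composition = rep(0.25, 4),
                              n_true_sites = 200L, min_spacing = 400L,
                              K_cell_types = 6L, cell_types = NULL,
                              sharing_distribution = NULL,
                              p_stim_only = 0.599, p_unstim_only = 0.276,
                              p_both = 0.125,
                              summit_jitter = 5L,
                              fe_meanlog = log(4), fe_sdlog = 0.5,
                              stim_fe_multiplier = 1.5,
                              motif_a = -3, motif_b = 0.8,
                              motif_fidelity = 0.99,
                              peak_halfwidth = 150L, q_value = 5) {
  if (n_chroms < 1L) stop("n_chroms must be >= 1")
  if (chrom_length < 1L) stop("chrom_length must be >= 1")
  if (is.null(cell_types))
    cell_types <- paste0("cell", LETTERS[seq_len(K_cell_types)]) else
    stopifnot(length(cell_types) == K_cell_types)
  if (is.null(sharing_distribution)) {
    ref <- c(0.7561, 0.2112, 0.0200, 0.0076, 0.0031, 0.0018)
    sharing_distribution <- if (K_cell_types <= 6L) ref[seq_len(K_cell_types)]
                            else c(ref, rep(0.001, K_cell_types - 6L))
  }
  stopifnot(length(sharing_distribution) == K_cell_types,
            all(sharing_distribution >= 0), sum(sharing_distribution) > 0)
  sharing_distribution <- sharing_distribution / sum(sharing_distribution)
  states <- c(stim_only = p_stim_only, unstim_only = p_unstim_only,
              both = p_both)
  stopifnot(all(states >= 0), sum(states) > 0)
  states <- states / sum(states)
  if (min_spacing <= 15L + 2L * summit_jitter)
    stop("min_spacing must exceed motif length + 2 * summit_jitter")
  stopifnot(motif_fidelity > 0.25, motif_fidelity <= 0.997,
            summit_jitter >= 0, n_true_sites >= 1)
  structure(list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
                 chrom_length = as.integer(chrom_length),
                 base_composition = base_composition / sum(base_composition),
                 n_true_sites = as.integer(n_true_sites),
                 min_spacing = as.integer(min_spacing),
                 K_cell_types = as.integer(K_cell_types),
                 cell_types = cell_types,
                 sharing_distribution = sharing_distribution,
                 state_probs = states,
                 summit_jitter = as.integer(summit_jitter),
                 fe_meanlog = fe_meanlog, fe_sdlog = fe_sdlog,
                 stim_fe_multiplier = stim_fe_multiplier,
                 motif_a = motif_a, motif_b = motif_b,
                 motif_fidelity = motif_fidelity,
                 peak_halfwidth = as.integer(peak_halfwidth),
                 q_value = q_value),
            class = "sim_config")
}

#' Generate a random genome
#'
#' I.i.d. bases at the configured composition. Draws from the current RNG
#' state; [simulate_dataset()] seeds it.
#'
#' @param config a [simulation_config()].
#' @return a `DNAStringSet` named `chr1`, `chr2`, ...
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  seqs <- vapply(seq_len(config$n_chroms), function(i) {
    paste(sample(c("A", "C", "G", "T"), config$chrom_length, replace = TRUE,
                 prob = config$base_composition), collapse = "")
  }, character(1))
  g <- Biostrings::DNAStringSet(seqs)
  names(g) <- paste0("chr", seq_len(config$n_chroms))
  g
}

## spaced positions on [margin, L - margin): sorted draws plus forced gaps
.spaced_positions <- function(n, L, spacing, margin) {
  avail <- L - 2L * margin - (n - 1L) * spacing
  if (avail < n)
    stop("cannot place ", n, " sites with spacing ", spacing,
         " on a chromosome of length ", L)
  u <- sort(sample.int(avail, n, replace = FALSE))
  margin + u + (seq_len(n) - 1L) * spacing
}

#' Generate the site truth table
#'
#' Places `n_true_sites` positions spaced at least `min_spacing` apart
#' (distributed across chromosomes proportional to length), draws per site
#' the number k of active cell types from `sharing_distribution` and a
#' uniform k-subset of cell types, per active (site, cell type) a state
#' among stimulated-only / unstimulated-only / both, one log-normal fold
#' enrichment per site, and plants a motif with probability
#' `plogis(motif_a + motif_b * FE)` at a uniformly chosen strand.
#'
#' @param config a [simulation_config()].
#' @return an object of class `sim_truth`: `sites` data frame (site_id,
#'   chrom, position, fe, n_cells, motif, motif_start, motif_strand) and
#'   `activity` data frame (site_id, cell_type, state).
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_true_sites
  per <- diff(round(seq(0, n, length.out = config$n_chroms + 1L)))
  margin <- 600L
  pos_list <- lapply(seq_len(config$n_chroms), function(i) {
    if (per[i] == 0L) return(integer(0))
    .spaced_positions(per[i], config$chrom_length, config$min_spacing, margin)
  })
  chrom <- rep(paste0("chr", seq_len(config$n_chroms)), per)
  position <- unlist(pos_list)

  K <- config$K_cell_types
  k_active <- sample.int(K, n, replace = TRUE, prob = config$sharing_distribution)
  fe <- stats::rlnorm(n, config$fe_meanlog, config$fe_sdlog)
  motif <- stats::runif(n) < stats::plogis(config$motif_a + config$motif_b * fe)
  strand <- ifelse(stats::runif(n) < 0.5, "+", "-")

  act <- vector("list", n)
  for (i in seq_len(n)) {
    cells <- sort(sample.int(K, k_active[i]))
    state <- sample(names(config$state_probs), k_active[i], replace = TRUE,
                    prob = config$state_probs)
    act[[i]] <- data.frame(site_id = i, cell_type = config$cell_types[cells],
                           state = state, stringsAsFactors = FALSE)
  }
  sites <- data.frame(
    site_id = seq_len(n), chrom = chrom, position = position, fe = fe,
    n_cells = k_active, motif = motif,
    motif_start = ifelse(motif, position - 7L, NA_integer_),
    motif_strand = ifelse(motif, strand, NA_character_),
    stringsAsFactors = FALSE
  )
  structure(list(sites = sites, activity = do.call(rbind, act)),
            class = "sim_truth")
}

## draw one motif instance from the PWM columns; fidelity = match_prob
.emit_motif <- function(pwm) {
  bases <- c("A", "C", "G", "T")
  paste(vapply(seq_len(pwm$length), function(j) {
    sample(bases, 1L, prob = pwm$probs[, j])
  }, character(1)), collapse = "")
}

#' Render per-sample peak calls and the motif-edited genome
#'
#' Writes each planted motif into the genome (bases drawn from the DR3 PWM
#' built at `motif_fidelity`, reverse-complemented for minus-strand sites)
#' and emits, for every (cell type, state) sample, one peak per site the
#' sample is active at: summit = true position + integer jitter uniform on
#' `[-summit_jitter, +summit_jitter]`, interval = summit +/-
#' `peak_halfwidth`, FE as drawn (times `stim_fe_multiplier` for
#' stimulated samples) and a constant -log10(q) above the FDR cutoff.
#'
#' @param truth a [generate_truth()] result.
#' @param genome the un-edited genome from [generate_genome()].
#' @param config the [simulation_config()].
#' @return list with `genome` (edited `DNAStringSet`) and `samples` (list
#'   of `2 * K` [sample_set()] objects, stimulated then unstimulated per
#'   cell type; samples without any active site have zero peaks).
#' @export
render_samples <- function(truth, genome, config) {
  stopifnot(inherits(truth, "sim_truth"), inherits(config, "sim_config"))
  pwm <- pwm_from_iupac("RGGTCANNGRGTTCA", match_prob = config$motif_fidelity,
                        name = "DR3_planted")
  sites <- truth$sites
  planted <- which(sites$motif)
  if (length(planted)) {
    seqs <- vapply(planted, function(i) {
      s <- .emit_motif(pwm)
      if (sites$motif_strand[i] == "-") .revcomp(s) else s
    }, character(1))
    for (cc in unique(sites$chrom[planted])) {
      sel <- planted[sites$chrom[planted] == cc]
      at <- IRanges::IRanges(start = sites$motif_start[sel] + 1L,
                             width = pwm$length)
      genome[[cc]] <- Biostrings::replaceAt(
        genome[[cc]], at, Biostrings::DNAStringSet(seqs[match(sel, planted)]))
    }
  }

  act <- truth$activity
  samples <- list()
  for (ct in config$cell_types) {
    for (stim in c(TRUE, FALSE)) {
      want <- if (stim) c("stim_only", "both") else c("unstim_only", "both")
      ids <- act$site_id[act$cell_type == ct & act$state %in% want]
      sid <- paste0(ct, if (stim) "_stim" else "_unstim")
      if (length(ids)) {
        sub <- sites[match(sort(ids), sites$site_id), , drop = FALSE]
        jit <- sample.int(2L * config$summit_jitter + 1L, nrow(sub),
                          replace = TRUE) - config$summit_jitter - 1L
        summit <- sub$position + jit
        fe <- sub$fe * if (stim) config$stim_fe_multiplier else 1
        pk <- data.frame(
          chrom = sub$chrom,
          start = pmax(0L, summit - config$peak_halfwidth),
          end = summit + config$peak_halfwidth,
          name = sprintf("%s_site%d", sid, sub$site_id),
          score = 0, strand = ".",
          fold_enrichment = fe, neg_log10_p = -1,
          neg_log10_q = config$q_value, summit = summit,
          stringsAsFactors = FALSE
        )
      } else {
        pk <- .empty_peaks()
      }
      samples[[sid]] <- sample_set(sid, ct, stim, pk)
    }
  }
  list(genome = genome, samples = samples)
}

## an empty, schema-correct peak frame
.empty_peaks <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             name = character(), score = numeric(), strand = character(),
             fold_enrichment = numeric(), neg_log10_p = numeric(),
             neg_log10_q = numeric(), summit = integer(),
             stringsAsFactors = FALSE)
}

#' Generate a complete synthetic dataset
#'
#' Seeds the RNG once from `config$seed` and draws in the order genome ->
#' truth -> samples, so two runs with the same configuration are
#' byte-identical. Optionally writes `genome.fa`, one narrowPeak per
#' sample, `truth_sites.tsv`, `truth_activity.tsv` and a YAML echo of the
#' configuration to `out_dir`.
#'
#' @param config a [simulation_config()].
#' @param out_dir optional output directory (created if needed).
#' @return list with `config`, `genome` (motif-edited `DNAStringSet`),
#'   `truth` (`sim_truth`), `samples` (list of [sample_set()]) and
#'   `out_dir`.
#' @export
simulate_dataset <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  genome <- generate_genome(config)
  truth <- generate_truth(config)
  rendered <- render_samples(truth, genome, config)
  out <- list(config = config, genome = rendered$genome, truth = truth,
              samples = rendered$samples, out_dir = out_dir)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    Biostrings::writeXStringSet(rendered$genome,
                                file.path(out_dir, "genome.fa"))
    for (s in rendered$samples)
      write_narrowpeak(s$peaks,
                       file.path(out_dir, paste0(s$sample_id, ".narrowPeak")))
    write.table(truth$sites, file.path(out_dir, "truth_sites.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(truth$activity, file.path(out_dir, "truth_activity.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (requireNamespace("yaml", quietly = TRUE)) {
      cfg <- config
      class(cfg) <- NULL
      yaml::write_yaml(cfg, file.path(out_dir, "config.yaml"))
    }
  }
  out
}
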