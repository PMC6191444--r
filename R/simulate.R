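#' Simulation configuration
#'
#' Bundles every parameter of the synthetic genome, binding-track and
#' peptide-table generators. Defaults describe the desk-scale study system:
#' a 6-Mb toy genome (3 chromosomes of 2 Mb), a 10-state chromatin annotation
#' on 1-kb tiles, two binding factors plus two acetylation marks, a planted
#' 3-fold acetylation gain at a minority of sites under knockdown, 150-bp
#' fragments and two replicates per condition.
#'
#' @param seed Integer master seed; every downstream draw derives from it.
#' @param chrom_lengths Numeric vector of chromosome lengths (bp).
#' @param n_states Number of chromatin states (Markov chain on 1-kb tiles).
#' @param state_tile Tile width for the state chain, bp.
#' @param state_stay Self-transition probability of the state chain
#'   (controls segment run lengths; 0.85 gives ~6.7-kb mean segments).
#' @param state_weights Peak-placement weight per state; `NULL` means weight
#'   `promoter_weight` for `promoter_state` and 1 elsewhere — the planted
#'   positive control for state-enrichment analysis.
#' @param promoter_state Index of the promoter/enhancer-like state peaks
#'   prefer.
#' @param promoter_weight Placement enrichment toward `promoter_state`.
#' @param n_genes Number of gene models; lengths lognormal, minimum 2 kb,
#'   placed non-overlapping with a 6.5-kb flank margin so meta-gene flanks
#'   stay on-chromosome.
#' @param n_peaks Peaks per factor.
#' @param peak_width_meanlog,peak_width_sdlog Lognormal peak-width
#'   parameters (default median ~500 bp).
#' @param factors Names of the four simulated tracks: two binding factors
#'   and two acetylation marks (last two receive the planted differential
#'   sites).
#' @param shared_fraction Fraction of peaks shared between the paired
#'   factors (factor B reuses factor A locations; the second mark reuses the
#'   first mark's locations exactly).
#' @param n_differential_sites Number of acetylation peaks whose signal is
#'   multiplied by `effect_fold` under knockdown.
#' @param effect_fold Planted fold change, default 3; 1 disables the
#'   planted effect (conditions become exchangeable).
#' @param replicates Replicates per condition.
#' @param reads_per_sample Reads per replicate before library-size jitter.
#' @param fragment_length Fragment length for read extension, bp.
#' @param frip Fraction of reads falling in peaks (rest uniform background).
#' @param nb_dispersion Negative-binomial dispersion of replicate peak
#'   counts (0.02 models highly reproducible native-ChIP replicates); 0
#'   gives Poisson replicates.
#' @param libsize_jitter Relative half-width of the uniform library-size
#'   jitter (0.2 = +/-20%), exercising normalization.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              chrom_lengths = c(chr1 = 2e6, chr2 = 2e6, chr3 = 2e6),
                              n_states = 10L,
                              state_tile = 1000L,
                              state_stay = 0.85,
                              state_weights = NULL,
                              promoter_state = 3L,
                              promoter_weight = 5,
                              n_genes = 300L,
                              n_peaks = 300L,
                              peak_width_meanlog = log(500),
                              peak_width_sdlog = 0.3,
                              factors = c("factor_A", "factor_B",
                                          "H3K27ac", "H2A.Zac"),
                              shared_fraction = 0.8,
                              n_differential_sites = 30L,
                              effect_fold = 3,
                              replicates = 2L,
                              reads_per_sample = 1e5,
                              fragment_length = 150L,
                              frip = 0.4,
                              nb_dispersion = 0.02,
                              libsize_jitter = 0.2) {
  if (effect_fold < 1) stop("effect_fold must be >= 1")
  if (n_differential_sites > n_peaks)
    stop("cannot plant more differential sites than peaks")
  if (is.null(state_weights)) {
    state_weights <- rep(1, n_states)
    state_weights[promoter_state] <- promoter_weight
  }
  stopifnot(length(state_weights) == n_states, all(state_weights > 0),
            frip > 0, frip < 1, nb_dispersion >= 0)
  structure(as.list(environment()), class = "simulation_config")
}

# Deterministic sub-seed derivation: keeps all intermediate products
# below 2^53 so the modular arithmetic is exact in doubles.
derive_seed <- function(seed, k) {
  a <- (as.numeric(seed) %% 2147483647) + 1
  x <- (a * 48271) %% 2147483647
  as.integer(((x + k) * 48271) %% 2147483647)
}

#' Simulate a genome with planted ground truth
#'
#' Generates the full study scaffold: a chromatin-state segmentation from a
#' first-order Markov chain over 1-kb tiles (run-length merged), stranded
#' gene models, peak sets for two binding factors and two acetylation marks
#' (placed preferentially in the promoter-like state, with paired factors
#' sharing a configurable fraction of locations), and a set of acetylation
#' peaks designated as differential under knockdown.
#'
#' @param cfg A [simulation_config].
#' @return A list with elements `assembly` ([genome_assembly]) and `truth`,
#'   itself a list: `state_segments` (GRanges, `state` mcol),
#'   `genes` (stranded GRanges, named), `peaks` (named list of GRanges with
#'   per-peak intensity in `score`), `differential_sites` (GRanges with
#'   `fold` mcol, a subset of the shared acetylation peaks) and
#'   `state_weights`.
#' @export
simulate_genome <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(derive_seed(cfg$seed, 1L))
  asm <- genome_assembly(names(cfg$chrom_lengths), cfg$chrom_lengths)

  ## chromatin states: sticky Markov chain on tiles, then run-length merged
  seg_list <- lapply(asm$chrom_names, function(ch) {
    len <- asm$chrom_lengths[[ch]]
    n_tiles <- ceiling(len / cfg$state_tile)
    states <- integer(n_tiles)
    states[1] <- sample.int(cfg$n_states, 1L)
    for (i in seq_len(n_tiles - 1L)) {
      if (runif(1) < cfg$state_stay) {
        states[i + 1L] <- states[i]
      } else {
        states[i + 1L] <- sample(setdiff(seq_len(cfg$n_states), states[i]), 1L)
      }
    }
    r <- rle(states)
    ends0 <- pmin(cumsum(r$lengths) * cfg$state_tile, len)
    starts0 <- c(0, head(ends0, -1L))
    data.table(chrom = ch, start = starts0, end = ends0, state = r$values)
  })
  seg <- rbindlist(seg_list)
  state_segments <- interval_set(seg$chrom, seg$start, seg$end, asm)
  mcols(state_segments)$state <- seg$state

  ## gene models: non-overlapping, flank margin keeps meta-gene windows inside
  margin <- 6500
  min_len <- 2000
  genes <- vector("list", cfg$n_genes)
  occupied <- GRanges(seqinfo = as_seqinfo(asm))
  placed <- 0L
  attempts <- 0L
  while (placed < cfg$n_genes) {
    attempts <- attempts + 1L
    if (attempts > cfg$n_genes * 200L)
      stop("configuration error: cannot pack ", cfg$n_genes,
           " genes into the genome")
    ch <- sample(asm$chrom_names, 1L, prob = asm$chrom_lengths)
    len <- round(min(max(rlnorm(1, log(5000), 0.5), min_len), 30000))
    hi <- asm$chrom_lengths[[ch]] - margin - len
    if (hi <= margin) next
    s0 <- floor(runif(1, margin, hi))
    cand <- interval_set(ch, s0, s0 + len, asm,
                         strand = sample(c("+", "-"), 1L))
    if (length(findOverlaps(cand, occupied, ignore.strand = TRUE)) > 0) next
    placed <- placed + 1L
    genes[[placed]] <- cand
    occupied <- c(occupied, unstrand(cand))
  }
  genes <- sort(do.call(c, genes), ignore.strand = TRUE)
  names(genes) <- sprintf("gene%04d", seq_along(genes))

  ## peak placement: choose a state segment with prob ~ width x state weight,
  ## then drop the peak uniformly inside it (trimmed to the segment if the
  ## segment is shorter), so placement frequencies follow the weights exactly
  seg_w <- as.numeric(width(state_segments)) *
    cfg$state_weights[mcols(state_segments)$state]
  place_peaks <- function(n) {
    idx <- sample.int(length(state_segments), n, replace = TRUE, prob = seg_w)
    wid <- round(pmin(pmax(
      rlnorm(n, cfg$peak_width_meanlog, cfg$peak_width_sdlog), 150),
      2000))
    segs <- state_segments[idx]
    s1 <- start(segs); e1 <- end(segs)
    wid <- pmin(wid, e1 - s1 + 1L)
    ps <- floor(s1 + runif(n) * (e1 - s1 + 1L - wid))
    gr <- GRanges(seqnames(segs), IRanges(start = ps, width = wid),
                  seqinfo = as_seqinfo(asm))
    mcols(gr)$score <- rlnorm(n, 0, 0.5)   # relative peak intensity
    mcols(gr)$state <- mcols(segs)$state
    sort(gr)
  }
  peaks <- list()
  peaks[[cfg$factors[1]]] <- place_peaks(cfg$n_peaks)
  ## paired binding factor: shared locations jittered, remainder fresh
  n_sh <- round(cfg$shared_fraction * cfg$n_peaks)
  sh <- sort(sample.int(cfg$n_peaks, n_sh))
  b_shared <- suppressWarnings(
    trim(shift(peaks[[cfg$factors[1]]][sh], round(runif(n_sh, -100, 100)))))
  mcols(b_shared)$score <- rlnorm(n_sh, 0, 0.5)
  b_new <- place_peaks(cfg$n_peaks - n_sh)
  peaks[[cfg$factors[2]]] <- sort(c(b_shared, b_new))
  ## acetylation marks: the second mark reuses the first's shared subset
  ## exactly (same nucleosomes), remainder fresh
  peaks[[cfg$factors[3]]] <- place_peaks(cfg$n_peaks)
  sh_ac <- sort(sample.int(cfg$n_peaks, n_sh))
  ac_shared <- peaks[[cfg$factors[3]]][sh_ac]
  mcols(ac_shared)$score <- rlnorm(n_sh, 0, 0.5)
  ac_new <- place_peaks(cfg$n_peaks - n_sh)
  peaks[[cfg$factors[4]]] <- sort(c(ac_shared, ac_new))

  ## planted differential sites: a subset of the shared acetylation peaks,
  ## so both marks respond at the same loci
  diff_idx <- sort(sample(sh_ac, min(cfg$n_differential_sites, n_sh)))
  differential_sites <- peaks[[cfg$factors[3]]][diff_idx]
  mcols(differential_sites) <- NULL
  mcols(differential_sites)$fold <- rep(cfg$effect_fold,
                                        length(differential_sites))

  list(assembly = asm,
       truth = list(state_segments = state_segments,
                    genes = genes,
                    peaks = peaks,
                    differential_sites = differential_sites,
                    state_weights = cfg$state_weights))
}

#' Simulate replicate read-start tables for one factor and condition
#'
#' Read surrogates are (chrom, pos, strand) tables: `pos` is the 0-based
#' 5' end of the read, to be extended to `cfg$fragment_length` downstream.
#' Reads are a mixture of uniform background and peak-concentrated signal;
#' peaks overlapping a planted differential site have their intensity
#' multiplied by the site's fold under the knockdown condition. Replicate
#' peak counts are negative-binomially dispersed and library sizes jittered.
#'
#' @param sim Result of [simulate_genome()].
#' @param cfg The same [simulation_config].
#' @param condition `"control"` or `"knockdown"`.
#' @param factor Which track to simulate (a name in `cfg$factors`); default
#'   the first acetylation mark.
#' @return Named list (`rep1`, `rep2`, ...) of `data.table`s with columns
#'   `chrom`, `pos`, `strand`; each carries its library size as attribute
#'   `n_reads`.
#' @export
simulate_counts <- function(sim, cfg, condition = c("control", "knockdown"),
                            factor = cfg$factors[3]) {
  condition <- match.arg(condition)
  stopifnot(factor %in% names(sim$truth$peaks))
  asm <- sim$assembly
  pk <- sim$truth$peaks[[factor]]
  fct_i <- match(factor, cfg$factors)
  cond_i <- match(condition, c("control", "knockdown"))
  is_mark <- fct_i >= 3L
  fold <- rep(1, length(pk))
  if (is_mark && condition == "knockdown") {
    hit <- overlapsAny(pk, sim$truth$differential_sites)
    fold[hit] <- cfg$effect_fold
  }
  w <- mcols(pk)$score
  base_share <- w / sum(w)          # unchanged-peak shares
  L <- cfg$fragment_length
  half <- floor(L / 2)

  out <- list()
  for (r in seq_len(cfg$replicates)) {
    set.seed(derive_seed(cfg$seed, 7919L * fct_i + 101L * cond_i + r))
    eff <- round(cfg$reads_per_sample *
                   runif(1, 1 - cfg$libsize_jitter, 1 + cfg$libsize_jitter))
    n_peak_reads_exp <- eff * cfg$frip
    mu <- n_peak_reads_exp * base_share * fold
    cnt <- if (cfg$nb_dispersion > 0) {
      rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion)
    } else {
      rpois(length(mu), mu)
    }
    n_bg <- round(eff * (1 - cfg$frip))
    ## background centers uniform over the genome
    bg_ch <- sample(asm$chrom_names, n_bg, replace = TRUE,
                    prob = asm$chrom_lengths)
    bg_center <- floor(runif(n_bg) * asm$chrom_lengths[bg_ch])
    ## peak centers uniform within their peak
    pk_idx <- rep.int(seq_along(pk), cnt)
    pk_ch <- as.character(seqnames(pk))[pk_idx]
    pk_center <- floor(start(pk)[pk_idx] - 1 +
                         runif(length(pk_idx)) * width(pk)[pk_idx])
    ch <- c(bg_ch, pk_ch)
    center <- c(bg_center, pk_center)
    str <- sample(c("+", "-"), length(ch), replace = TRUE)
    pos <- ifelse(str == "+", center - half, center + half)
    pos <- pmax(0, pmin(pos, asm$chrom_lengths[ch] - 1))
    dt <- data.table(chrom = ch, pos = as.integer(pos), strand = str)
    setorder(dt, chrom, pos)
    attr(dt, "n_reads") <- nrow(dt)
    out[[paste0("rep", r)]] <- dt
  }
  out
}

#' Simulate a peptide isoform area table
#'
#' Emulates an exported MS1 chromatogram-area table for histone peptides:
#' each peptide carries several modification isoforms with known ground-truth
#' percentages. Optionally, one isoform pair per designated peptide is
#' isobaric: the two members share a single MS1 area (their summed
#' abundance) and each carries three unique MS2 fragment integrals
#' proportional to its true share, with multiplicative noise.
#'
#' @param n_peptides Number of peptides.
#' @param isobaric_pairs Number of peptides carrying one coeluting isobaric
#'   isoform pair (`<= n_peptides`).
#' @param seed Integer seed.
#' @param n_samples Number of samples (columns are long-format rows here).
#' @param n_isoforms Isoforms per peptide (>= 2; isobaric peptides use the
#'   last two isoforms as the coeluting pair).
#' @param noise_sd Multiplicative lognormal noise sd on areas and fragment
#'   integrals; 0 gives exact noiseless tables.
#' @param true_percent Optional numeric vector of length `n_isoforms`
#'   (summing to 100) forced as the ground truth for every peptide; `NULL`
#'   draws one composition per peptide and sample.
#' @return A `data.table` with columns `sample_id`, `histone`, `peptide`,
#'   `modification`, `isobaric_group`, `ms1_area`, `frag1..frag3`, plus an
#'   attribute `truth` (`data.table` of planted percentages).
#' @export
simulate_peptide_table <- function(n_peptides, isobaric_pairs = 0L, seed = 1L,
                                   n_samples = 1L, n_isoforms = 3L,
                                   noise_sd = 0, true_percent = NULL) {
  stopifnot(n_peptides >= isobaric_pairs, isobaric_pairs >= 0,
            n_isoforms >= 2)
  set.seed(derive_seed(seed, 33L))
  iso_names <- c("unmod", paste0("mod", seq_len(n_isoforms - 1L)))
  rows <- list(); truth <- list()
  for (s in seq_len(n_samples)) {
    smp <- sprintf("S%d", s)
    for (p in seq_len(n_peptides)) {
      pep <- sprintf("pep%02d", p)
      if (is.null(true_percent)) {
        g <- rgamma(n_isoforms, shape = 2)
        pct <- 100 * g / sum(g)
      } else {
        stopifnot(length(true_percent) == n_isoforms)
        pct <- 100 * true_percent / sum(true_percent)
      }
      total <- rlnorm(1, log(1e6), 0.3)
      abund <- total * pct / 100
      isob <- p <= isobaric_pairs
      grp <- if (isob) paste0(pep, "_grp") else NA_character_
      # one triplet of fragment-ion base intensities per coeluting pair, so
      # averaged integrals are exactly proportional to the split at zero noise
      fr_base <- if (isob) rlnorm(3, log(1e4), 0.5) else NULL
      for (i in seq_len(n_isoforms)) {
        in_pair <- isob && i >= n_isoforms - 1L
        if (in_pair) {
          pair_total <- sum(abund[(n_isoforms - 1L):n_isoforms])
          # shared MS1 peak: one noise draw per pair, reused by both members
          if (i == n_isoforms - 1L)
            shared_ms1 <- pair_total * exp(rnorm(1, 0, noise_sd))
          ms1 <- shared_ms1
          split_i <- abund[i] / pair_total
          fr <- fr_base * split_i * exp(rnorm(3, 0, noise_sd))
        } else {
          ms1 <- abund[i] * exp(rnorm(1, 0, noise_sd))
          fr <- rep(NA_real_, 3)
        }
        rows[[length(rows) + 1L]] <- data.table(
          sample_id = smp, histone = "H3", peptide = pep,
          modification = iso_names[i],
          isobaric_group = if (in_pair) grp else NA_character_,
          ms1_area = ms1, frag1 = fr[1], frag2 = fr[2], frag3 = fr[3])
        truth[[length(truth) + 1L]] <- data.table(
          sample_id = smp, peptide = pep, modification = iso_names[i],
          true_percent = pct[i])
      }
    }
  }
  out <- rbindlist(rows)
  attr(out, "truth") <- rbindlist(truth)
  out
}
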