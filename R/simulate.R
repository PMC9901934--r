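#' Planted activity model for simulated libraries
#'
#' Defines the ground-truth relative activity (RA) assigned to every
#' genotype in a simulated co-transcriptional cleavage experiment. The
#' model is structure-aware: mutations at catalytic positions abolish
#' activity and admit no rescue; mutations that break a base pair in a stem
#' are strongly deleterious; mutations at loop positions (or stem mutations
#' that leave the pair Watson-Crick or wobble) are mild; a second mutation
#' that restores pairing at a broken pair multiplies activity back up
#' (positive epistasis); and a double that disrupts two pairs of the same
#' stem is penalized beyond multiplicative expectation (negative epistasis).
#'
#' @param wt_fc Fraction cleaved of the unmutated reference, in `[0, 1]`.
#' @param stem_single_effect RA factor for a single mutation that breaks a
#'   base pair. Either a scalar or a named vector keyed by region name
#'   (unnamed regions fall back to the `""` entry or the mean).
#' @param loop_single_effect RA factor for a single mutation at an unpaired
#'   position, or a paired position where the mutated pair is still
#'   Watson-Crick or G:U.
#' @param catalytic_effect RA factor for any mutation at a catalytic
#'   position; applied with no compensatory rescue.
#' @param compensatory_bonus RA multiplier (>= 1) applied when a double
#'   mutant at the two partners of one base pair leaves a Watson-Crick or
#'   G:U pair.
#' @param double_disruption_penalty RA multiplier (<= 1) applied when a
#'   double mutant disrupts two distinct base pairs of the same region.
#' @param noise_sd Standard deviation of optional log-scale jitter applied
#'   to every non-wild-type genotype's RA.
#' @return An object of class `activity_model`.
#' @export
activity_model <- function(wt_fc = 0.9,
                           stem_single_effect = 0.2,
                           loop_single_effect = 0.8,
                           catalytic_effect = 0,
                           compensatory_bonus = 25,
                           double_disruption_penalty = 0.5,
                           noise_sd = 0) {
  stopifnot(wt_fc >= 0, wt_fc <= 1,
            all(stem_single_effect >= 0), all(stem_single_effect <= 1),
            loop_single_effect >= 0, loop_single_effect <= 1,
            catalytic_effect >= 0, catalytic_effect <= 1,
            compensatory_bonus >= 1,
            double_disruption_penalty > 0, double_disruption_penalty <= 1,
            noise_sd >= 0)
  structure(as.list(environment()), class = "activity_model")
}

# Per-position context: region name ("" if unpaired), partner position
# (NA if unpaired), catalytic flag.
position_context <- function(ref) {
  L <- ref_length(ref)
  region <- rep("", L)
  partner <- rep(NA_integer_, L)
  for (rg in ref$paired_regions) {
    for (k in seq_len(nrow(rg$pairs))) {
      i <- rg$pairs[k, 1]; j <- rg$pairs[k, 2]
      region[i + 1] <- rg$name; region[j + 1] <- rg$name
      partner[i + 1] <- j; partner[j + 1] <- i
    }
  }
  list(region = region, partner = partner,
       catalytic = (seq_len(L) - 1L) %in% ref$catalytic)
}

stem_effect_for <- function(model, region_name) {
  s <- model$stem_single_effect
  if (length(s) == 1 && is.null(names(s))) return(unname(s))
  if (region_name %in% names(s)) return(unname(s[region_name]))
  if ("" %in% names(s)) return(unname(s[""]))
  mean(s)
}

# RA factor of one substitution (position 0-based, alt base).
single_ra_factor <- function(ref, model, ctx, pos, alt) {
  if (ctx$catalytic[pos + 1]) return(model$catalytic_effect)
  pj <- ctx$partner[pos + 1]
  if (is.na(pj)) return(model$loop_single_effect)
  # mutated pair: orient as (5' base, 3' base)
  other <- ref_base(ref, pj)
  if (pos < pj) ok <- is_watson_crick(alt, other) || is_wobble(alt, other)
  else          ok <- is_watson_crick(other, alt) || is_wobble(other, alt)
  if (ok) model$loop_single_effect else stem_effect_for(model, ctx$region[pos + 1])
}

#' Assign ground-truth activity to the wild type and all single and double
#' mutants
#'
#' @param ref A `ribozyme_reference`.
#' @param model An [activity_model()].
#' @return Tibble with columns `genotype`, `order`, `true_ra` (clamped so
#'   that `true_fc = true_ra * wt_fc` lies in `[0, 1]`) and `true_fc`.
#' @export
assign_ground_truth <- function(ref, model) {
  ctx <- position_context(ref)
  singles <- enumerate_single_mutants(ref)
  sp <- lapply(singles, parse_genotype)
  sfac <- vapply(sp, function(p)
    single_ra_factor(ref, model, ctx, p$positions, p$alts), 0)
  names(sfac) <- singles

  doubles <- enumerate_double_mutants(ref)
  dp <- matrix(unlist(lapply(doubles, function(g) {
    p <- parse_genotype(g); c(p$positions, match(p$alts, RNA_BASES))
  })), ncol = 4, byrow = TRUE)
  p1 <- dp[, 1]; p2 <- dp[, 2]
  a1 <- RNA_BASES[dp[, 3]]; a2 <- RNA_BASES[dp[, 4]]
  f1 <- sfac[sprintf("%d:%s", p1, a1)]
  f2 <- sfac[sprintf("%d:%s", p2, a2)]
  dra <- f1 * f2

  cat1 <- ctx$catalytic[p1 + 1]; cat2 <- ctx$catalytic[p2 + 1]
  reg1 <- ctx$region[p1 + 1]; reg2 <- ctx$region[p2 + 1]
  part1 <- ctx$partner[p1 + 1]
  no_rescue <- cat1 | cat2

  # same-pair doubles: pairing restored or preserved -> bonus
  same_pair <- !is.na(part1) & part1 == p2
  pair_str <- paste0(a1, a2)  # p1 < p2 so a1 is the 5' base
  restored <- same_pair & (pair_str %in% c(WC_PAIRS, GU_PAIRS))
  idx <- restored & !no_rescue
  dra[idx] <- pmin(f1[idx] * f2[idx] * model$compensatory_bonus, 1)

  # two distinct pairs of the same region both disrupted -> extra penalty
  same_region <- !same_pair & reg1 != "" & reg1 == reg2
  if (any(same_region)) {
    broke <- function(p, a) {
      pj <- ctx$partner[p + 1]
      other <- ref_base(ref, pj)
      if (p < pj) !(is_watson_crick(a, other) || is_wobble(a, other))
      else        !(is_watson_crick(other, a) || is_wobble(other, a))
    }
    w <- which(same_region & !no_rescue)
    both_broken <- vapply(w, function(i)
      broke(p1[i], a1[i]) && broke(p2[i], a2[i]), TRUE)
    dra[w[both_broken]] <- dra[w[both_broken]] * model$double_disruption_penalty
  }

  out <- tibble::tibble(
    genotype = c("WT", singles, doubles),
    order = c(0L, rep(1L, length(singles)), rep(2L, length(doubles))),
    true_ra = c(1, unname(sfac), unname(dra))
  )
  if (model$noise_sd > 0) {
    jit <- exp(stats::rnorm(nrow(out) - 1, 0, model$noise_sd))
    out$true_ra[-1] <- out$true_ra[-1] * jit
  }
  out$true_fc <- pmin(pmax(out$true_ra * model$wt_fc, 0), 1)
  out$true_ra <- out$true_fc / model$wt_fc
  out
}

#' Simulation configuration for a doped-library sequencing run
#'
#' Emulates a doped-oligonucleotide mutagenesis library: at every position a
#' read carries the reference base with probability `doping_rate` and each
#' of the three alternatives with probability `(1 - doping_rate) / 3`.
#'
#' @param doping_rate Per-position wild-type retention probability.
#' @param n_reads Reads per replicate (scalar, or one value per replicate).
#' @param n_replicates Number of replicates.
#' @param seed Integer seed; identical configurations give byte-identical
#'   output.
#' @param error_rate Per-base sequencing error probability.
#' @param tso_lengths Lengths of the four template-switching-oligo pads that
#'   stagger the sequencing frame; pads are drawn once per simulation,
#'   seeded, and cycled read by read.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(doping_rate = 0.97, n_reads = 1e5,
                              n_replicates = 3, seed = 1,
                              error_rate = 0,
                              tso_lengths = c(3, 4, 5, 6)) {
  stopifnot(doping_rate > 0, doping_rate <= 1,
            all(n_reads >= 1), n_replicates >= 1,
            error_rate >= 0, error_rate < 1,
            length(tso_lengths) >= 1)
  alt_rate <- (1 - doping_rate) / 3
  n_reads <- rep(as.integer(n_reads), length.out = n_replicates)
  structure(list(doping_rate = doping_rate, alt_rate = alt_rate,
                 n_reads = n_reads, n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed), error_rate = error_rate,
                 tso_lengths = as.integer(tso_lengths)),
            class = "simulation_config")
}

# Draw the four TSO pads. A pad whose sequence equals the leader's
# 3'-terminal bases of the same length would make a cleaved read look
# uncleaved, so such pads are rejected and redrawn (the experimental TSOs
# are likewise designed to be distinguishable from the cleavage product).
draw_tso_pads <- function(leader, tso_lengths) {
  vapply(tso_lengths, function(len) {
    repeat {
      pad <- paste(sample(RNA_BASES, len, replace = TRUE), collapse = "")
      suffix <- substr(leader, nchar(leader) - len + 1, nchar(leader))
      if (!identical(pad, suffix)) return(pad)
    }
  }, "")
}

# L x n character matrix of per-position multinomial draws.
draw_base_matrix <- function(ref, config, n) {
  L <- ref_length(ref)
  refb <- ref_base(ref, 0:(L - 1))
  M <- matrix("", nrow = L, ncol = n)
  for (i in seq_len(L)) {
    others <- setdiff(RNA_BASES, refb[i])
    M[i, ] <- sample(c(refb[i], others), n, replace = TRUE,
                     prob = c(config$doping_rate, rep(config$alt_rate, 3)))
  }
  M
}

# Genotype strings for the columns of a draw matrix.
matrix_genotypes <- function(M, refb) {
  diffs <- M != refb
  geno <- rep("WT", ncol(M))
  ind <- which(diffs, arr.ind = TRUE)
  if (nrow(ind) > 0) {
    tok <- sprintf("%d:%s", ind[, 1] - 1L, M[ind])
    by_read <- split(tok, ind[, 2])
    geno[as.integer(names(by_read))] <-
      vapply(by_read, paste, "", collapse = ",")
  }
  geno
}

#' Sample genotypes from the doped-library model
#'
#' Independent per-position multinomial draws; genotypes of any order can
#' result. Uses the current RNG state.
#'
#' @param ref A `ribozyme_reference`.
#' @param config A [simulation_config()].
#' @param n Number of genotypes to draw.
#' @return Character vector of `n` genotype strings.
#' @export
sample_genotypes <- function(ref, config, n) {
  refb <- ref_base(ref, 0:(ref_length(ref) - 1))
  matrix_genotypes(draw_base_matrix(ref, config, n), refb)
}

#' Simulate sequencing reads for a doped ribozyme library
#'
#' For each replicate, draws `n_reads` genotypes from the doping model,
#' decides cleavage per molecule as Bernoulli(true FC), and writes one
#' FASTQ per replicate. Each read is `pad + [leader if uncleaved] +
#' mutated ribozyme sequence`, with the four seeded TSO pads cycled read by
#' read, written in DNA alphabet with constant quality `I`. Ground truth
#' (true FC per genotype and the per-replicate sampled cleaved/uncleaved
#' tallies) is written alongside the reads.
#'
#' @param ref A `ribozyme_reference`.
#' @param truth Ground-truth table from [assign_ground_truth()]. Genotypes
#'   of order three or more receive the product of their constituent
#'   single-mutant factors, clamped to `[0, 1]`.
#' @param config A [simulation_config()].
#' @param outdir Output directory (created if needed); set to `NULL` to
#'   skip writing files.
#' @return List with `fastq` (paths per replicate), `truth`, `sampled`
#'   (tibble: genotype, replicate, n_cleaved, n_uncleaved), and `pads`.
#' @export
simulate_reads <- function(ref, truth, config, outdir = NULL) {
  set.seed(config$seed)
  L <- ref_length(ref)
  refb <- ref_base(ref, 0:(L - 1))
  pads <- draw_tso_pads(ref$leader, config$tso_lengths)

  fc_map <- stats::setNames(truth$true_fc, truth$genotype)
  single_fac <- truth$true_ra[match(enumerate_single_mutants(ref),
                                    truth$genotype)]
  names(single_fac) <- enumerate_single_mutants(ref)
  wt_fc <- unname(fc_map["WT"])

  fc_for <- function(geno) {
    fc <- unname(fc_map[geno])
    miss <- is.na(fc)
    if (any(miss)) {  # order >= 3: multiplicative in single factors
      fc[miss] <- vapply(geno[miss], function(g) {
        subs <- strsplit(g, ",", fixed = TRUE)[[1]]
        min(max(prod(single_fac[subs]) * wt_fc, 0), 1)
      }, 0)
    }
    fc
  }

  if (!is.null(outdir)) dir.create(outdir, recursive = TRUE,
                                   showWarnings = FALSE)
  fastq_paths <- character(config$n_replicates)
  sampled <- vector("list", config$n_replicates)

  for (rep_i in seq_len(config$n_replicates)) {
    n <- config$n_reads[rep_i]
    M <- draw_base_matrix(ref, config, n)
    geno <- matrix_genotypes(M, refb)
    fc <- fc_for(geno)
    cleaved <- stats::runif(n) < fc
    mutseq <- do.call(paste0, asplit(M, 1))
    pad <- pads[((seq_len(n) - 1L) %% length(pads)) + 1L]
    reads <- ifelse(cleaved, paste0(pad, mutseq),
                    paste0(pad, ref$leader, mutseq))
    if (config$error_rate > 0) reads <- apply_seq_errors(reads,
                                                         config$error_rate)
    reads <- chartr("U", "T", reads)

    sampled[[rep_i]] <- tibble::tibble(genotype = geno,
                                       replicate = sprintf("rep%d", rep_i),
                                       cleaved = cleaved) %>%
      dplyr::count(.data$genotype, .data$replicate, .data$cleaved) %>%
      tidyr::pivot_wider(names_from = "cleaved", values_from = "n",
                         values_fill = 0L) %>%
      dplyr::rename_with(~ c("TRUE" = "n_cleaved",
                             "FALSE" = "n_uncleaved")[.x],
                         dplyr::any_of(c("TRUE", "FALSE")))
    for (col in c("n_cleaved", "n_uncleaved")) {
      if (!col %in% names(sampled[[rep_i]])) sampled[[rep_i]][[col]] <- 0L
    }

    if (!is.null(outdir)) {
      fp <- file.path(outdir, sprintf("rep%d.fastq", rep_i))
      dna <- Biostrings::DNAStringSet(reads)
      names(dna) <- sprintf("r%d_%06d", rep_i, seq_len(n))
      qual <- Biostrings::BStringSet(strrep("I", nchar(reads)))
      Biostrings::writeXStringSet(dna, fp, format = "fastq",
                                  qualities = qual)
      fastq_paths[rep_i] <- fp
    }
  }

  sampled <- dplyr::bind_rows(sampled) %>%
    dplyr::select(dplyr::all_of(c("genotype", "replicate",
                                  "n_cleaved", "n_uncleaved")))

  if (!is.null(outdir)) {
    readr::write_tsv(truth, file.path(outdir, "truth_fc.tsv"))
    readr::write_tsv(sampled, file.path(outdir, "sampled_counts.tsv"))
    yaml::write_yaml(c(unclass(config), list(pads = pads),
                       reference = ref$name),
                     file.path(outdir, "config.yaml"))
  }

  list(fastq = fastq_paths, truth = truth, sampled = sampled, pads = pads)
}

# Per-base substitution errors on read strings (RNA alphabet).
apply_seq_errors <- function(reads, error_rate) {
  n_err <- stats::rbinom(length(reads), nchar(reads), error_rate)
  hit <- which(n_err > 0)
  for (i in hit) {
    ch <- strsplit(reads[i], "")[[1]]
    pos <- sample.int(length(ch), n_err[i])
    ch[pos] <- vapply(ch[pos],
                      function(b) sample(setdiff(RNA_BASES, b), 1), "")
    reads[i] <- paste(ch, collapse = "")
  }
  reads
}
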