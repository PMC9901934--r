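#' Planted compensatory pairs of a reference under an activity model
#'
#' The double mutants at the two partners of one base pair whose resulting
#' pair is Watson-Crick or G:U wobble, excluding catalytic positions —
#' exactly the genotypes the simulator's activity model rewards with the
#' compensatory bonus.
#'
#' @param ref A `ribozyme_reference`.
#' @param wc_only Keep only Watson-Crick-restoring doubles.
#' @return Character vector of genotype strings.
#' @export
compensatory_pairs <- function(ref, wc_only = FALSE) {
  ctx <- position_context(ref)
  out <- character(0)
  allowed <- if (wc_only) WC_PAIRS else c(WC_PAIRS, GU_PAIRS)
  for (rg in ref$paired_regions) {
    for (k in seq_len(nrow(rg$pairs))) {
      i <- rg$pairs[k, 1]; j <- rg$pairs[k, 2]
      if (ctx$catalytic[i + 1] || ctx$catalytic[j + 1]) next
      alts_i <- setdiff(RNA_BASES, ref_base(ref, i))
      alts_j <- setdiff(RNA_BASES, ref_base(ref, j))
      for (ai in alts_i) for (aj in alts_j) {
        if (paste0(ai, aj) %in% allowed) {
          out <- c(out, sprintf("%d:%s,%d:%s", i, ai, j, aj))
        }
      }
    }
  }
  out
}

#' Run a full simulate-and-recover experiment
#'
#' Generates a doped-library sequencing run under a planted activity model,
#' pushes it through the complete pipeline (variant calling, cleavage
#' classification, activity, epistasis, sigma filter), and summarizes how
#' well the planted quantities were recovered.
#'
#' At the default depth a double mutant is sampled only a handful of times
#' per replicate, so the activity table is built in pooled-count mode with
#' a minimum depth of one read; singles-level summaries are unaffected
#' (singles are a few hundred reads deep) and doubles stay analyzable.
#'
#' @param ref A `ribozyme_reference`.
#' @param model An [activity_model()].
#' @param config A [simulation_config()].
#' @param outdir Where the simulated run is written (default: a temporary
#'   directory).
#' @param min_reads,pool_replicates Passed to [activity_table()].
#' @return List with the pipeline tables (`truth`, `counts`, `activity`,
#'   `epistasis`, `report`s) and a `metrics` list: planted and recovered
#'   wild-type FC, single/double coverage fractions, single-mutant RA
#'   RMSE, and compensatory-pair recovery (epsilon sign and filter
#'   survival).
#' @export
run_recovery_experiment <- function(ref, model, config,
                                    outdir = tempfile("simrun"),
                                    min_reads = 1,
                                    pool_replicates = TRUE) {
  truth <- assign_ground_truth(ref, model)
  sim <- simulate_reads(ref, truth, config, outdir = outdir)
  counted <- lapply(seq_len(config$n_replicates), function(i)
    count_reads(sim$fastq[i], ref, replicate = sprintf("rep%d", i)))
  counts <- dplyr::bind_rows(lapply(counted, `[[`, "counts"))
  reports <- lapply(counted, `[[`, "report")

  act <- activity_table(counts, min_reads = min_reads,
                        pool_replicates = pool_replicates)
  eps <- filter_epistasis(epistasis_table(act))

  singles <- enumerate_single_mutants(ref)
  doubles <- enumerate_double_mutants(ref)
  observed <- unique(counts$genotype)

  st <- act %>% dplyr::filter(.data$order == 1L) %>%
    dplyr::left_join(truth, by = "genotype")
  comp <- compensatory_pairs(ref)
  ec <- eps %>% dplyr::filter(.data$genotype %in% comp)

  wt_fc_hat <- act$mean_fc[act$genotype == "WT"]
  wt_reads <- act$total_reads[act$genotype == "WT"]

  metrics <- list(
    planted_wt_fc = model$wt_fc,
    recovered_wt_fc = wt_fc_hat,
    wt_reads = wt_reads,
    single_coverage = mean(singles %in% observed),
    double_coverage = mean(doubles %in% observed),
    n_doubles_missing = sum(!doubles %in% observed),
    single_ra_rmse = sqrt(mean((st$mean_ra - st$true_ra)^2)),
    n_compensatory = length(comp),
    n_compensatory_measured = nrow(ec),
    n_compensatory_eps_positive = sum(ec$epsilon > 0),
    n_compensatory_unfiltered = sum(!ec$filtered),
    total_reads = sum(vapply(reports, `[[`, 0, "total")),
    mapped_reads = sum(vapply(reports, `[[`, 0, "mapped"))
  )
  list(ref = ref, model = model, config = config, truth = truth,
       sim = sim, counts = counts, reports = reports, activity = act,
       epistasis = eps, compensatory = comp, metrics = metrics)
}
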