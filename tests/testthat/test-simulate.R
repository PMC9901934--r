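test_that("ground truth plants the intended activity structure", {
  ref <- toy_ref()                       # stem G:C,G:C,C:G; catalytic pos 4
  model <- activity_model(wt_fc = 0.9, stem_single_effect = 0.2,
                          loop_single_effect = 0.8, catalytic_effect = 0,
                          compensatory_bonus = 25)
  truth <- assign_ground_truth(ref, model)
  tr <- function(g) truth$true_ra[truth$genotype == g]
  fc <- function(g) truth$true_fc[truth$genotype == g]

  expect_equal(fc("WT"), 0.9)
  expect_equal(tr("4:A"), 0)             # catalytic: abolished
  # position 0 (G) pairs with 8 (C): G->A gives A:C, G->U gives U:C, broken
  expect_equal(tr("0:A"), 0.2)
  expect_equal(tr("0:U"), 0.2)
  # position 2 (C) pairs with 6 (G): C->U gives U:G wobble, structure kept
  expect_equal(tr("2:U"), 0.8)
  expect_equal(tr("5:C"), 0.8)           # unpaired loop position

  # compensatory: break C:G at (2,6) both ways, restore A:U -> back to 1
  expect_equal(tr("2:A"), 0.2)
  expect_equal(tr("6:U"), 0.2)
  expect_equal(tr("2:A,6:U"), min(0.2 * 0.2 * 25, 1))
  # planted epistasis of that pair is log(1/(0.2*0.2)) = log(25)
  expect_equal(log(tr("2:A,6:U") / (tr("2:A") * tr("6:U"))), log(25))
  # no rescue through a catalytic position
  expect_equal(tr("4:A,5:C"), 0)
  # two distinct pairs of one stem broken -> extra penalty
  expect_equal(tr("0:A,7:A"), 0.2 * 0.2 * model$double_disruption_penalty)
  # mutations in different contexts multiply
  expect_equal(tr("0:A,5:C"), 0.2 * 0.8)
  # FC always within [0,1]
  expect_true(all(truth$true_fc >= 0 & truth$true_fc <= 1))
})

test_that("doped sampling follows the per-position multinomial model", {
  ref <- read_reference(ribodms_reference_file("twister"))
  L <- ref_length(ref)
  cfg <- simulation_config(n_reads = 1e5, seed = 3)
  set.seed(cfg$seed)
  g <- sample_genotypes(ref, cfg, 1e5)
  ord <- genotype_order(g)
  p_wt <- 0.97^L
  p_1 <- L * 0.03 * 0.97^(L - 1)
  # within 3 binomial SD of the closed forms
  for (k in list(c(0, p_wt), c(1, p_1))) {
    obs <- mean(ord == k[1])
    expect_lt(abs(obs - k[2]), 3 * sqrt(k[2] * (1 - k[2]) / 1e5))
  }
  # doping_rate = 1 -> always wild type
  cfg1 <- simulation_config(doping_rate = 1, n_reads = 10, seed = 1)
  expect_true(all(sample_genotypes(ref, cfg1, 50) == "WT"))
  # invariant: doping + 3 * alt = 1
  expect_equal(cfg$doping_rate + 3 * cfg$alt_rate, 1)
})

test_that("read emission is deterministic, conserved and truthful", {
  ref <- toy_ref()
  truth <- assign_ground_truth(ref, activity_model(wt_fc = 0.8))
  cfg <- simulation_config(n_reads = 2000, n_replicates = 2, seed = 42)
  d1 <- tempfile(); d2 <- tempfile()
  s1 <- simulate_reads(ref, truth, cfg, outdir = d1)
  s2 <- simulate_reads(ref, truth, cfg, outdir = d2)
  # identical config => byte-identical FASTQ and truth tables
  for (i in 1:2) {
    expect_identical(readLines(s1$fastq[i]), readLines(s2$fastq[i]))
  }
  expect_identical(s1$sampled, s2$sampled)
  # conservation: total emitted reads per replicate
  for (i in 1:2) {
    n <- length(Biostrings::readDNAStringSet(s1$fastq[i], format = "fastq"))
    expect_equal(n, 2000)
    tal <- dplyr::filter(s1$sampled, replicate == paste0("rep", i))
    expect_equal(sum(tal$n_cleaved + tal$n_uncleaved), 2000)
  }
  # truth TSV and config echo written alongside reads
  expect_true(file.exists(file.path(d1, "truth_fc.tsv")))
  expect_true(file.exists(file.path(d1, "config.yaml")))
})

test_that("cleavage states are sampled at the planted fraction", {
  ref <- acgu_ref()
  # FC(wt) = 1 -> every wild-type read lacks the leader
  truth <- tibble::tibble(genotype = "WT", order = 0L,
                          true_ra = 1, true_fc = 1)
  cfg <- simulation_config(doping_rate = 1, n_reads = 200,
                           n_replicates = 1, seed = 5)
  sim <- simulate_reads(ref, truth, cfg, outdir = NULL)
  expect_equal(sum(sim$sampled$n_uncleaved), 0)
  # FC = 0 -> every read keeps the leader
  truth$true_fc <- 0
  sim0 <- simulate_reads(ref, truth, cfg, outdir = NULL)
  expect_equal(sum(sim0$sampled$n_cleaved), 0)
  # intermediate FC within 3 binomial SD
  truth$true_fc <- 0.6
  cfgn <- simulation_config(doping_rate = 1, n_reads = 1e5,
                            n_replicates = 1, seed = 6)
  simn <- simulate_reads(ref, truth, cfgn, outdir = NULL)
  obs <- simn$sampled$n_cleaved / 1e5
  expect_lt(abs(obs - 0.6), 3 * sqrt(0.6 * 0.4 / 1e5))
})

test_that("TSO pads cycle with the documented lengths and avoid the leader suffix", {
  ref <- toy_ref()
  truth <- assign_ground_truth(ref, activity_model())
  cfg <- simulation_config(n_reads = 40, n_replicates = 1, seed = 9)
  sim <- simulate_reads(ref, truth, cfg, outdir = NULL)
  expect_equal(nchar(sim$pads), c(3L, 4L, 5L, 6L))
  for (pad in sim$pads) {
    suffix <- substr(ref$leader, nchar(ref$leader) - nchar(pad) + 1,
                     nchar(ref$leader))
    expect_false(identical(pad, suffix))
  }
})
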