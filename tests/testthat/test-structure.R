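# Independent oracle: rebuild the mutated sequence, inspect every pair of
# the region that contains a substituted position, and count mismatches.
oracle_category <- function(region, g, ref) {
  p <- parse_genotype(g)
  rpos <- sort(as.vector(region$pairs))
  if (!all(p$positions %in% rpos)) return("not_in_region")
  mut <- apply_genotype(ref, g)
  n_mm <- 0
  for (k in seq_len(nrow(region$pairs))) {
    i <- region$pairs[k, 1]; j <- region$pairs[k, 2]
    if (!(i %in% p$positions) && !(j %in% p$positions)) next
    pr <- paste0(substr(mut, i + 1, i + 1), substr(mut, j + 1, j + 1))
    if (!pr %in% c("AU", "UA", "GC", "CG", "GU", "UG")) n_mm <- n_mm + 1
  }
  c("WC_GU", "one_mismatch", "two_mismatch")[n_mm + 1]
}

test_that("mismatch categorization matches the defining examples", {
  # one G:C pair; both partners mutated to A and U -> restored WC
  ref <- ribozyme_reference("t", "GAAC",
                            paired_regions = parse_structure("(..)", "P1"))
  expect_equal(classify_double_mutants(ref$paired_regions$P1,
                                       "0:A,3:U", ref), "WC_GU")
  # two pairs (G:C, A:U) in one helix
  ref3 <- ribozyme_reference("t3", "GAAAUC",
                             paired_regions = parse_structure("((..))", "P1"))
  # pairs: (0,5) G:C and (1,4) A:U
  expect_equal(classify_double_mutants(ref3$paired_regions$P1,
                                       "0:A,1:G", ref3), "one_mismatch")
  expect_equal(classify_double_mutants(ref3$paired_regions$P1,
                                       "0:A,4:C", ref3), "two_mismatch")
  expect_equal(classify_double_mutants(ref3$paired_regions$P1,
                                       "0:A,2:G", ref3), "not_in_region")
})

test_that("categorization agrees with brute force on all shipped references", {
  for (ref in shipped_refs()) {
    for (rg in ref$paired_regions) {
      rpos <- region_positions(rg)
      pos_pairs <- utils::combn(rpos, 2)
      # subsample large regions to keep the sweep quick but exhaustive in alts
      take <- seq_len(ncol(pos_pairs))
      if (length(take) > 40) {
        set.seed(1); take <- sample(take, 40)
      }
      for (ci in take) {
        p1 <- pos_pairs[1, ci]; p2 <- pos_pairs[2, ci]
        alts1 <- setdiff(c("A", "C", "G", "U"),
                         substr(ref$sequence, p1 + 1, p1 + 1))
        alts2 <- setdiff(c("A", "C", "G", "U"),
                         substr(ref$sequence, p2 + 1, p2 + 1))
        for (a1 in alts1) for (a2 in alts2) {
          g <- sprintf("%d:%s,%d:%s", p1, a1, p2, a2)
          expect_equal(classify_double_mutants(rg, g, ref),
                       oracle_category(rg, g, ref), info = g)
        }
      }
    }
  }
})

test_that("every in-region double maps to exactly one category", {
  ref <- read_reference(ribodms_reference_file("hammerhead"))
  doubles <- enumerate_double_mutants(ref)
  for (rg in ref$paired_regions) {
    cats <- classify_double_mutants(rg, doubles, ref)
    expect_true(all(cats %in% c("WC_GU", "one_mismatch", "two_mismatch",
                                "not_in_region")))
    rpos <- region_positions(rg)
    in_region <- vapply(strsplit(doubles, ","), function(m) {
      all(as.integer(sub(":.*", "", m)) %in% rpos)
    }, TRUE)
    expect_true(all(cats[in_region] != "not_in_region"))
    expect_true(all(cats[!in_region] == "not_in_region"))
  }
})

test_that("on-diagonal means Watson-Crick restoring, wobble goes off", {
  # single G:C pair: of the 9 partner doubles exactly 3 restore WC
  ref <- ribozyme_reference("t", "GAAC",
                            paired_regions = parse_structure("(..)", "P1"))
  doubles <- enumerate_double_mutants(ref)
  eps <- tibble::tibble(genotype = doubles,
                        mut_i = sub(",.*", "", doubles),
                        mut_j = sub(".*,", "", doubles),
                        ra_i = 0.2, ra_j = 0.2, ra_ij = 0.2,
                        epsilon = 0)
  pair_doubles <- doubles[grepl("^0:.*,3:", doubles)]
  oo <- on_off_diagonal_split(ref$paired_regions$P1, eps, ref)
  expect_length(oo$on, 3)                 # A:U, U:A, C:G
  expect_length(oo$off, length(pair_doubles) - 3)
  # all epsilon equal -> both means zero
  expect_equal(oo$mu_on, 0)
  expect_equal(oo$mu_off, 0)
  # empty on-diagonal set is reported, not an error: restrict records to a
  # wobble-restoring double only
  eps_wobble <- eps[eps$genotype == "0:U,3:G", ]  # U:G, not Watson-Crick
  oo2 <- on_off_diagonal_split(ref$paired_regions$P1, eps_wobble, ref)
  expect_length(oo2$on, 0)
  expect_length(oo2$off, 1)
  expect_true(is.null(oo2$test))
})

test_that("duplex free energies reproduce hand-summed nearest-neighbor values", {
  # two stacked G:C pairs: init + one GC/GC stack
  ref <- ribozyme_reference("t", "GGAACC",
                            paired_regions = parse_structure("((..))", "P1"))
  dg <- duplex_mfe(ref$paired_regions$P1, ref)
  expect_equal(dg$delta_g, 4.10 - 3.30)
  # two stacked A:U pairs: init + AU/AU stack + two terminal AU penalties
  ref2 <- ribozyme_reference("t", "AAAAUU",
                             paired_regions = parse_structure("((..))", "P1"))
  expect_equal(duplex_mfe(ref2$paired_regions$P1, ref2)$delta_g,
               4.10 - 0.90 + 0.50 + 0.50)
  # single pair: initiation and terminal penalty only
  ref3 <- ribozyme_reference("t", "GAAC",
                             paired_regions = parse_structure("(..)", "P1"))
  expect_equal(duplex_mfe(ref3$paired_regions$P1, ref3)$delta_g, 4.10)
  # non-pairable combination errors
  ref4 <- ribozyme_reference("t", "UAAU",
                             paired_regions = parse_structure("(..)", "P1"))
  expect_error(duplex_mfe(ref4$paired_regions$P1, ref4), "non-pairable")

  # strand-swap symmetry: describing the same duplex from the other
  # strand's side gives the same energy
  refA <- ribozyme_reference("t", "GACAAAAGUC",
                             paired_regions = parse_structure("(((....)))",
                                                              "P1"))
  refB <- ribozyme_reference("t", "GUCAAAAGAC",
                             paired_regions = parse_structure("(((....)))",
                                                              "P1"))
  dgA <- duplex_mfe(refA$paired_regions$P1, refA)
  dgB <- duplex_mfe(refB$paired_regions$P1, refB)
  expect_equal(dgA$delta_g, dgB$delta_g)
  expect_equal(dgA$strand5, dgB$strand3)
  expect_equal(dgA$strand3, dgB$strand5)
})

test_that("stability correlation behaves on collinear and degenerate input", {
  ref <- read_reference(ribodms_reference_file("hairpin"))
  en <- region_energies(ref)
  expect_equal(nrow(en), 3)
  # construct single-mutant RAs exactly linear in each region's delta G
  singles <- enumerate_single_mutants(ref)
  pos <- as.integer(sub(":.*", "", singles))
  ra <- rep(0.5, length(singles))
  for (k in seq_len(nrow(en))) {
    rpos <- region_positions(ref$paired_regions[[en$region[k]]])
    ra[pos %in% rpos] <- 1 + 0.05 * en$delta_g[k]
  }
  act <- tibble::tibble(genotype = c("WT", singles),
                        order = c(0L, rep(1L, length(singles))),
                        mean_ra = c(1, ra), mean_fc = 0.5,
                        n_replicates = 3L, total_reads = 1000L)
  sc <- stability_correlation(en, act, ref)
  expect_false(sc$degenerate)
  expect_equal(sc$r, 1, tolerance = 1e-9)  # medians rise with delta G
  # flipping the construction flips the sign
  act2 <- act
  act2$mean_ra[-1] <- 1 - 0.05 * (act$mean_ra[-1] - 1) / 0.05
  sc2 <- stability_correlation(en, act2, ref)
  expect_equal(sc2$r, -1, tolerance = 1e-9)
  # constant medians are degenerate, not an error
  act3 <- act; act3$mean_ra[-1] <- 0.4
  expect_true(stability_correlation(en, act3, ref)$degenerate)
  # fewer than three usable regions errors
  expect_error(stability_correlation(en[1:2, ], act, ref), "at least 3")
})

test_that("structure report summarizes regions and catalytic rescue", {
  ref <- toy_ref()
  model <- activity_model(wt_fc = 0.8)
  truth <- assign_ground_truth(ref, model)
  act <- tibble::tibble(genotype = truth$genotype, order = truth$order,
                        mean_ra = truth$true_ra,
                        mean_fc = truth$true_fc,
                        n_replicates = 3L, total_reads = 1000L)
  eps <- filter_epistasis(epistasis_table(act))
  rep <- structure_report(ref, act, eps, drop_filtered = FALSE)
  expect_equal(rep$regions$region, "P1")
  # planted ordering of category means on noiseless truth
  expect_gt(rep$regions$mean_eps_wc_gu, rep$regions$mean_eps_one_mismatch)
  expect_gt(rep$regions$mean_eps_one_mismatch,
            rep$regions$mean_eps_two_mismatch)
  # catalytic_effect = 0 admits no rescued double
  expect_equal(rep$catalytic$n_rescued, 0)
  expect_equal(rep$catalytic$max_ra, 0)
  # per-position vector has length L
  expect_length(rep$per_position_mean_ra, ref_length(ref))
  # empty region list still yields activity summaries
  ref_plain <- ribozyme_reference("p", ref$sequence, leader = ref$leader)
  rep2 <- structure_report(ref_plain, act, eps)
  expect_equal(nrow(rep2$regions), 0)
  expect_length(rep2$per_position_mean_ra, ref_length(ref))
})
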