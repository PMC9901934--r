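test_that("dot-bracket parsing recovers helices and pseudoknot layers", {
  r <- parse_structure("((..))", "P1")
  expect_length(r, 1)
  expect_equal(unname(r$P1$pairs), matrix(c(0L, 1L, 5L, 4L), ncol = 2))

  r2 <- parse_structure("([)]", c("A", "B"))
  expect_equal(unname(r2$A$pairs), matrix(c(0L, 2L), ncol = 2))
  expect_equal(unname(r2$B$pairs), matrix(c(1L, 3L), ncol = 2))

  # two helices in one layer split at the stacking break
  r3 <- parse_structure("((..((...))..))", c("H1", "H2"))
  expect_equal(nrow(r3$H1$pairs), 2)
  expect_equal(nrow(r3$H2$pairs), 2)
  expect_equal(unname(r3$H2$pairs[1, ]), c(4L, 10L))

  expect_error(parse_structure("((.)", "P1"), "unbalanced '\\('")
  expect_error(parse_structure("(].)", c("a", "b")), "unbalanced '\\]'")
  expect_error(parse_structure("((..))", c("P1", "P2")), "1 helices")
})

test_that("mutant-space enumeration matches 3L and 9L(L-1)/2", {
  # the five study lengths and their printed mutant counts
  printed <- list(cpeb3 = c(69, 207, 21114), hdv = c(87, 261, 33669),
                  twister = c(48, 144, 10152), hairpin = c(71, 213, 22365),
                  hammerhead = c(45, 135, 8910))
  for (nm in names(printed)) {
    ref <- read_reference(ribodms_reference_file(nm))
    expect_equal(ref_length(ref), printed[[nm]][1])
    s <- enumerate_single_mutants(ref)
    d <- enumerate_double_mutants(ref)
    expect_length(s, printed[[nm]][2])
    expect_length(d, printed[[nm]][3])
    expect_false(anyDuplicated(s) > 0)
    expect_false(anyDuplicated(d) > 0)
  }
  # brute force over the full substitution grid at small L
  ref <- ribozyme_reference("t", "ACGUA")
  d <- enumerate_double_mutants(ref)
  grid <- expand.grid(p1 = 0:4, p2 = 0:4, a1 = c("A", "C", "G", "U"),
                      a2 = c("A", "C", "G", "U"),
                      stringsAsFactors = FALSE)
  rb <- strsplit("ACGUA", "")[[1]]
  grid <- grid[grid$p1 < grid$p2 & grid$a1 != rb[grid$p1 + 1] &
                 grid$a2 != rb[grid$p2 + 1], ]
  expect_equal(length(d), nrow(grid))
  expect_setequal(d, sprintf("%d:%s,%d:%s", grid$p1, grid$a1,
                             grid$p2, grid$a2))
  expect_length(enumerate_single_mutants(ribozyme_reference("x", "A")), 3)
  expect_length(enumerate_double_mutants(ribozyme_reference("x", "AC")), 9)
})

test_that("applying a genotype and diffing back round-trips", {
  ref <- acgu_ref()
  expect_equal(apply_genotype(ref, "WT"), "ACGU")
  expect_equal(apply_genotype(ref, "0:G"), "GCGU")
  expect_error(apply_genotype(ref, "0:A"), "equals the reference")
  expect_error(apply_genotype(ref, "7:A"), "outside")
  expect_error(genotype(c(1, 1), c("A", "C")), "distinct")

  set.seed(11)
  ref2 <- read_reference(ribodms_reference_file("twister"))
  for (g in sample(enumerate_double_mutants(ref2), 25)) {
    expect_equal(diff_genotype(ref2, apply_genotype(ref2, g)), g)
  }
  expect_equal(diff_genotype(ref2, ref2$sequence), "WT")
})

test_that("shipped reference definitions are internally consistent", {
  refs <- shipped_refs()
  names(refs) <- vapply(refs, function(r) r$name, "")
  for (ref in refs) {
    pos <- unlist(lapply(ref$paired_regions, region_positions))
    expect_false(anyDuplicated(pos) > 0)      # pairs disjoint across regions
    expect_true(all(pos >= 0 & pos < ref_length(ref)))
  }
  # region inventories and stated stem sizes
  sizes <- function(ref) vapply(ref$paired_regions,
                                function(r) nrow(r$pairs), 0L)
  expect_setequal(names(refs$cpeb3_synthetic$paired_regions),
                  c("P1", "P2", "P3", "P4", "T1"))
  expect_equal(sizes(refs$cpeb3_synthetic)[["P3"]], 3L)
  expect_equal(sizes(refs$cpeb3_synthetic)[["T1"]], 1L)
  expect_equal(sizes(refs$hdv_synthetic)[["P4"]], 14L)
  expect_equal(sizes(refs$hdv_synthetic)[["T1"]], 2L)
  expect_equal(sizes(refs$twister_synthetic)[["T1"]], 4L)
  expect_setequal(names(refs$hammerhead_synthetic$paired_regions),
                  c("P1", "P2"))
  # catalytic identities, figure numbering = position + display_offset
  cat_base <- function(ref) {
    vapply(ref$catalytic, function(p) substr(ref$sequence, p + 1, p + 1), "")
  }
  expect_equal(refs$cpeb3_synthetic$catalytic + 1, 57)     # C57
  expect_equal(cat_base(refs$cpeb3_synthetic), "C")
  expect_equal(refs$hdv_synthetic$catalytic + 1, 75)       # C75
  expect_equal(cat_base(refs$hdv_synthetic), "C")
  expect_equal(refs$twister_synthetic$catalytic + 1, c(1, 39))
  expect_equal(cat_base(refs$twister_synthetic), c("A", "G"))
  expect_equal(refs$hammerhead_synthetic$catalytic + 1, c(25, 39))
  expect_equal(cat_base(refs$hammerhead_synthetic), c("G", "G"))
  # CPEB3 T1 is the non-canonical U:U pair
  t1 <- refs$cpeb3_synthetic$paired_regions$T1$pairs
  expect_equal(substr(refs$cpeb3_synthetic$sequence, t1[1] + 1, t1[1] + 1), "U")
  expect_equal(substr(refs$cpeb3_synthetic$sequence, t1[2] + 1, t1[2] + 1), "U")
})

test_that("reference validation rejects malformed definitions", {
  expect_error(ribozyme_reference("x", "ACGX"), "outside A/C/G/U")
  expect_error(
    ribozyme_reference("x", "ACGU", paired_regions = list(
      list(name = "P1", pairs = matrix(c(0L, 5L), ncol = 2)))),
    "outside")
  expect_error(
    ribozyme_reference("x", "ACGUAA", paired_regions = list(
      list(name = "P1", pairs = matrix(c(0L, 5L), ncol = 2)),
      list(name = "P2", pairs = matrix(c(0L, 4L), ncol = 2)))),
    "more than one base pair")
  # T accepted on input, normalized to U
  expect_equal(ribozyme_reference("x", "acgt")$sequence, "ACGU")
})
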