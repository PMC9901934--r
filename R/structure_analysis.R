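#' Mismatch category of a double mutant within a paired region
#'
#' A double mutant whose two substituted positions are both base-paired
#' positions of the region is categorized by the number of its touched
#' pairs left as mismatches after mutation: `"WC_GU"` (none: every touched
#' pair is Watson-Crick or G:U wobble), `"one_mismatch"`, or
#' `"two_mismatch"`. Doubles with any position outside the region's paired
#' positions (including doubles spanning two different regions) are
#' `"not_in_region"`.
#'
#' @param region A paired region (`list(name, pairs)`).
#' @param genotypes Character vector of order-2 genotype strings.
#' @param ref A `ribozyme_reference`.
#' @return Character vector of categories.
#' @export
classify_double_mutants <- function(region, genotypes, ref) {
  rpos <- region_positions(region)
  vapply(genotypes, function(g) {
    p <- parse_genotype(g)
    if (length(p$positions) != 2) {
      stop("classification applies to order-2 genotypes only", call. = FALSE)
    }
    if (!all(p$positions %in% rpos)) return("not_in_region")
    mutated <- stats::setNames(p$alts, p$positions)
    touched <- region$pairs[region$pairs[, 1] %in% p$positions |
                            region$pairs[, 2] %in% p$positions, ,
                            drop = FALSE]
    n_mm <- 0L
    for (k in seq_len(nrow(touched))) {
      i <- touched[k, 1]; j <- touched[k, 2]
      b5 <- if (as.character(i) %in% names(mutated))
        mutated[[as.character(i)]] else ref_base(ref, i)
      b3 <- if (as.character(j) %in% names(mutated))
        mutated[[as.character(j)]] else ref_base(ref, j)
      if (!(is_watson_crick(b5, b3) || is_wobble(b5, b3))) n_mm <- n_mm + 1L
    }
    c("WC_GU", "one_mismatch", "two_mismatch")[n_mm + 1L]
  }, "", USE.NAMES = FALSE)
}

#' Mismatch categories of in-region doubles for every region
#'
#' @param epistasis Tibble from [epistasis_table()] (optionally after
#'   [filter_epistasis()]).
#' @param ref A `ribozyme_reference`.
#' @param drop_filtered Drop records flagged by the sigma filter (only if a
#'   `filtered` column is present).
#' @return Tibble with `region`, `genotype`, `category`, `epsilon`, one row
#'   per (region, in-region double).
#' @export
category_epsilon <- function(epistasis, ref, drop_filtered = TRUE) {
  if (drop_filtered && "filtered" %in% names(epistasis)) {
    epistasis <- epistasis %>% dplyr::filter(!.data$filtered)
  }
  rows <- lapply(ref$paired_regions, function(rg) {
    cat <- classify_double_mutants(rg, epistasis$genotype, ref)
    keep <- cat != "not_in_region"
    tibble::tibble(region = rg$name,
                   genotype = epistasis$genotype[keep],
                   category = cat[keep],
                   epsilon = epistasis$epsilon[keep])
  })
  dplyr::bind_rows(rows)
}

#' Split in-region epistasis into on- and off-diagonal distributions
#'
#' On-diagonal doubles are those at the two partner positions of one base
#' pair whose resulting pair is Watson-Crick (a compensatory base-pair
#' swap); wobble-restoring and all other in-region doubles are
#' off-diagonal. In the position-major heatmap, Watson-Crick-restoring
#' doubles of a stem lie on its anti-diagonal (unless the original pair is
#' non-canonical, as for a U:U pseudoknot pair).
#'
#' @param region A paired region.
#' @param epistasis Tibble from [epistasis_table()] (optionally filtered).
#' @param ref A `ribozyme_reference`.
#' @param drop_filtered Drop sigma-flagged records when present.
#' @return List with `on`, `off` (epsilon vectors), `mu_on`, `mu_off`, and
#'   `test` (Mann-Whitney result, `NULL` when either side is empty).
#' @export
on_off_diagonal_split <- function(region, epistasis, ref,
                                  drop_filtered = TRUE) {
  if (drop_filtered && "filtered" %in% names(epistasis)) {
    epistasis <- epistasis %>% dplyr::filter(!.data$filtered)
  }
  rpos <- region_positions(region)
  muts <- strsplit(epistasis$genotype, ",", fixed = TRUE)
  p1 <- vapply(muts, function(m) as.integer(sub(":.*", "", m[1])), 0L)
  p2 <- vapply(muts, function(m) as.integer(sub(":.*", "", m[2])), 0L)
  a1 <- vapply(muts, function(m) sub(".*:", "", m[1]), "")
  a2 <- vapply(muts, function(m) sub(".*:", "", m[2]), "")
  in_region <- p1 %in% rpos & p2 %in% rpos
  partner <- stats::setNames(c(region$pairs[, 2], region$pairs[, 1]),
                             c(region$pairs[, 1], region$pairs[, 2]))
  same_pair <- in_region &
    !is.na(partner[as.character(p1)]) &
    partner[as.character(p1)] == p2
  on <- same_pair & paste0(a1, a2) %in% WC_PAIRS
  eps_on <- epistasis$epsilon[on]
  eps_off <- epistasis$epsilon[in_region & !on]
  test <- if (length(eps_on) > 0 && length(eps_off) > 0) {
    compare_distributions(eps_on, eps_off)
  } else NULL
  list(on = eps_on, off = eps_off,
       mu_on = if (length(eps_on)) mean(eps_on) else NA_real_,
       mu_off = if (length(eps_off)) mean(eps_off) else NA_real_,
       test = test)
}

#' Per-region structure report
#'
#' Assembles, per paired region: the duplex free energy, the median
#' single-mutant RA, counts and mean epsilon per mismatch category with
#' Mann-Whitney p-values between adjacent categories, and the on-/
#' off-diagonal means and test. Also reports the per-position mean
#' single-mutant RA vector and a catalytic-rescue check: the maximum RA
#' among double mutants touching a catalytic position, which should stay
#' below `rescue_threshold` because catalytic residues admit no
#' compensatory rescue.
#'
#' @param ref A `ribozyme_reference`.
#' @param activity Activity table from [activity_table()].
#' @param epistasis Tibble from [epistasis_table()], ideally after
#'   [filter_epistasis()].
#' @param rescue_threshold RA above which a catalytic double would count as
#'   rescued (default 0.5).
#' @param drop_filtered Drop sigma-flagged records from distribution
#'   summaries.
#' @return List with `regions` (tibble), `categories` (long tibble from
#'   [category_epsilon()]), `per_position_mean_ra`, `catalytic` (list), and
#'   `energies`.
#' @export
structure_report <- function(ref, activity, epistasis,
                             rescue_threshold = 0.5,
                             drop_filtered = TRUE) {
  energies <- suppressWarnings(region_energies(ref))
  cats <- category_epsilon(epistasis, ref, drop_filtered = drop_filtered)
  singles <- activity %>% dplyr::filter(.data$order == 1L)
  pos1 <- vapply(strsplit(singles$genotype, ":", fixed = TRUE),
                 function(x) as.integer(x[1]), 0L)

  cat_order <- c("two_mismatch", "one_mismatch", "WC_GU")
  rows <- lapply(ref$paired_regions, function(rg) {
    rc <- cats %>% dplyr::filter(.data$region == rg$name)
    mean_eps <- vapply(cat_order, function(cc) {
      v <- rc$epsilon[rc$category == cc]
      if (length(v)) mean(v) else NA_real_
    }, 0)
    n_eps <- vapply(cat_order, function(cc) sum(rc$category == cc), 0L)
    p_adj <- vapply(seq_len(2), function(i) {
      a <- rc$epsilon[rc$category == cat_order[i]]
      b <- rc$epsilon[rc$category == cat_order[i + 1]]
      if (length(a) && length(b)) compare_distributions(b, a)$p
      else NA_real_
    }, 0)
    oo <- on_off_diagonal_split(rg, epistasis, ref,
                                drop_filtered = drop_filtered)
    med_ra <- {
      sel <- pos1 %in% region_positions(rg)
      if (any(sel)) stats::median(singles$mean_ra[sel]) else NA_real_
    }
    tibble::tibble(
      region = rg$name, n_pairs = nrow(rg$pairs),
      delta_g = energies$delta_g[energies$region == rg$name],
      median_single_ra = med_ra,
      n_two_mismatch = n_eps[1], n_one_mismatch = n_eps[2],
      n_wc_gu = n_eps[3],
      mean_eps_two_mismatch = mean_eps[1],
      mean_eps_one_mismatch = mean_eps[2],
      mean_eps_wc_gu = mean_eps[3],
      p_one_vs_two = p_adj[1], p_wc_vs_one = p_adj[2],
      mu_on = oo$mu_on, mu_off = oo$mu_off,
      p_on_off = if (!is.null(oo$test)) oo$test$p else NA_real_
    )
  })

  doubles <- activity %>% dplyr::filter(.data$order == 2L)
  touches_cat <- function(g) {
    any(parse_genotype(g)$positions %in% ref$catalytic)
  }
  cat_doubles <- doubles[vapply(doubles$genotype, touches_cat, TRUE), ]
  catalytic <- list(
    n_doubles = nrow(cat_doubles),
    max_ra = if (nrow(cat_doubles)) max(cat_doubles$mean_ra) else NA_real_,
    n_rescued = sum(cat_doubles$mean_ra > rescue_threshold),
    rescue_threshold = rescue_threshold
  )

  list(regions = dplyr::bind_rows(rows),
       categories = cats,
       per_position_mean_ra = per_position_mean_single_ra(activity, ref),
       catalytic = catalytic,
       energies = energies)
}
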