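#' Fraction cleaved
#'
#' `FC = N_clv / (N_clv + N_unclv)`, the proportion of molecules of a
#' genotype that self-cleaved. Undefined (NA) when no reads were observed.
#'
#' @param n_clv,n_unclv Non-negative read counts (vectorized).
#' @return Numeric vector of fractions in `[0, 1]`.
#' @export
fraction_cleaved <- function(n_clv, n_unclv) {
  stopifnot(all(n_clv >= 0, na.rm = TRUE), all(n_unclv >= 0, na.rm = TRUE))
  tot <- n_clv + n_unclv
  ifelse(tot > 0, n_clv / tot, NA_real_)
}

#' Relative activity
#'
#' `RA = FC / FC_wt`, a genotype's fraction cleaved normalized to the
#' wild type measured in the same replicate. Values above 1 are permitted.
#'
#' @param fc Fraction cleaved of the genotype.
#' @param fc_wt Fraction cleaved of the wild type (> 0).
#' @return Numeric vector of non-negative ratios.
#' @export
relative_activity <- function(fc, fc_wt) {
  if (any(!is.na(fc_wt) & fc_wt <= 0)) {
    stop("wild-type fraction cleaved is zero; replicate unusable",
         call. = FALSE)
  }
  fc / fc_wt
}

#' Per-genotype activity table averaged over replicates
#'
#' Computes per-replicate FC and RA from cleavage counts and averages RA
#' arithmetically across the replicates in which the genotype passed the
#' depth threshold. Replicate observations with fewer than
#' `min_reads` reads are dropped; genotypes left with no usable replicate
#' are excluded and reported in the `excluded` attribute. With
#' `pool_replicates = TRUE` counts are summed across replicates before FC
#' is computed (one pooled pseudo-replicate), which is preferable when
#' per-replicate depth is very low.
#'
#' @param counts Tibble from [count_reads()] (or the simulator's sampled
#'   tallies): columns `genotype`, `replicate`, `n_cleaved`, `n_uncleaved`.
#' @param min_reads Minimum reads per genotype per replicate for that
#'   replicate's RA to count (default 10).
#' @param pool_replicates Pool counts across replicates before computing
#'   FC/RA.
#' @return Tibble with `genotype`, `order`, `mean_ra`, `mean_fc`,
#'   `n_replicates`, `total_reads`; attribute `excluded` lists dropped
#'   genotypes, attribute `per_replicate` holds the long per-replicate
#'   FC/RA table.
#' @export
activity_table <- function(counts, min_reads = 10, pool_replicates = FALSE) {
  stopifnot(all(c("genotype", "replicate", "n_cleaved", "n_uncleaved")
                %in% names(counts)))
  if (pool_replicates) {
    counts <- counts %>%
      dplyr::group_by(.data$genotype) %>%
      dplyr::summarise(n_cleaved = sum(.data$n_cleaved),
                       n_uncleaved = sum(.data$n_uncleaved),
                       .groups = "drop") %>%
      dplyr::mutate(replicate = "pooled")
  }
  per_rep <- counts %>%
    dplyr::mutate(depth = .data$n_cleaved + .data$n_uncleaved,
                  fc = fraction_cleaved(.data$n_cleaved, .data$n_uncleaved))
  wt <- per_rep %>%
    dplyr::filter(.data$genotype == "WT") %>%
    dplyr::select(dplyr::all_of(c("replicate", "fc"))) %>%
    dplyr::rename(fc_wt = "fc")
  if (nrow(wt) == 0 || any(is.na(wt$fc_wt)) || any(wt$fc_wt <= 0)) {
    stop("wild type unobserved (or FC = 0) in some replicate; ",
         "cannot normalize", call. = FALSE)
  }
  per_rep <- per_rep %>%
    dplyr::left_join(wt, by = "replicate") %>%
    dplyr::mutate(ra = relative_activity(.data$fc, .data$fc_wt),
                  usable = .data$depth >= min_reads)

  out <- per_rep %>%
    dplyr::filter(.data$usable) %>%
    dplyr::group_by(.data$genotype) %>%
    dplyr::summarise(mean_ra = mean(.data$ra),
                     mean_fc = mean(.data$fc),
                     n_replicates = dplyr::n(),
                     total_reads = sum(.data$depth),
                     .groups = "drop") %>%
    dplyr::mutate(order = genotype_order(.data$genotype)) %>%
    dplyr::select(dplyr::all_of(c("genotype", "order", "mean_ra", "mean_fc",
                                  "n_replicates", "total_reads"))) %>%
    dplyr::arrange(.data$order, .data$genotype)

  excluded <- setdiff(unique(counts$genotype), out$genotype)
  attr(out, "excluded") <- excluded
  attr(out, "per_replicate") <- per_rep
  out
}

#' Per-position mean single-mutant relative activity
#'
#' Position `p` maps to the mean of `mean_ra` over the three single mutants
#' at `p` (those present in the table).
#'
#' @param activity Activity table from [activity_table()].
#' @param ref A `ribozyme_reference`.
#' @return Numeric vector of length `L` (NA where no single mutant was
#'   measured), named by 0-based position.
#' @export
per_position_mean_single_ra <- function(activity, ref) {
  L <- ref_length(ref)
  singles <- activity %>% dplyr::filter(.data$order == 1L)
  pos <- vapply(strsplit(singles$genotype, ":", fixed = TRUE),
                function(x) as.integer(x[1]), 0L)
  out <- rep(NA_real_, L)
  if (nrow(singles) > 0) {
    m <- tapply(singles$mean_ra, pos, mean)
    out[as.integer(names(m)) + 1L] <- as.numeric(m)
  }
  stats::setNames(out, 0:(L - 1))
}

#' Class-average fraction cleaved for wild type, singles and doubles
#'
#' Unweighted arithmetic means of replicate-mean FC per mutational order,
#' the summary printed in read-depth tables. Set `weight_by_depth = TRUE`
#' for read-weighted means.
#'
#' @param activity Activity table from [activity_table()].
#' @param weight_by_depth Weight genotypes by their total read depth.
#' @return Named numeric vector `c(wt =, singles =, doubles =)`; classes
#'   with no genotypes are NA.
#' @export
mutant_class_average_fc <- function(activity, weight_by_depth = FALSE) {
  avg <- function(d) {
    if (nrow(d) == 0) return(NA_real_)
    if (weight_by_depth) sum(d$mean_fc * d$total_reads) / sum(d$total_reads)
    else mean(d$mean_fc)
  }
  c(wt = avg(dplyr::filter(activity, .data$order == 0L)),
    singles = avg(dplyr::filter(activity, .data$order == 1L)),
    doubles = avg(dplyr::filter(activity, .data$order == 2L)))
}
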