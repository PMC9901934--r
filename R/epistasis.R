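#' Pairwise epistasis on the multiplicative scale
#'
#' `epsilon = log( RA_ij / (RA_i * RA_j) )`: the log-scale deviation of a
#' double mutant's relative activity from the product of its constituent
#' singles'. Zero is the additivity point; positive values mean the double
#' mutant is more active than expected (for example a restored base pair),
#' negative values less. All three RAs are floored at a small positive
#' constant before taking logs so that zero-count genotypes give large but
#' finite values.
#'
#' @param ra_i,ra_j Single-mutant relative activities.
#' @param ra_ij Double-mutant relative activity.
#' @param floor Positive lower bound applied to each RA (default `1e-3`).
#' @param base Log base (default natural).
#' @return Numeric vector of epistasis values.
#' @export
epistasis_value <- function(ra_i, ra_j, ra_ij, floor = 1e-3,
                            base = exp(1)) {
  stopifnot(floor > 0)
  log(pmax(ra_ij, floor) / (pmax(ra_i, floor) * pmax(ra_j, floor)),
      base = base)
}

#' Epistasis records for all measured double mutants
#'
#' Joins every order-2 genotype in the activity table to its two
#' constituent single mutants and computes epsilon. Records where a
#' constituent single was not measured are dropped (reported via the
#' `missing_singles` attribute).
#'
#' @param activity Activity table from [activity_table()].
#' @param floor RA floor for [epistasis_value()].
#' @param base Log base.
#' @return Tibble with `genotype`, `mut_i`, `mut_j`, `ra_i`, `ra_j`,
#'   `ra_ij`, `epsilon`.
#' @export
epistasis_table <- function(activity, floor = 1e-3, base = exp(1)) {
  singles <- activity %>% dplyr::filter(.data$order == 1L)
  ra_single <- stats::setNames(singles$mean_ra, singles$genotype)
  doubles <- activity %>% dplyr::filter(.data$order == 2L)
  muts <- strsplit(doubles$genotype, ",", fixed = TRUE)
  out <- tibble::tibble(
    genotype = doubles$genotype,
    mut_i = vapply(muts, `[`, "", 1),
    mut_j = vapply(muts, `[`, "", 2),
    ra_ij = doubles$mean_ra
  ) %>%
    dplyr::mutate(ra_i = unname(ra_single[.data$mut_i]),
                  ra_j = unname(ra_single[.data$mut_j]))
  missing <- is.na(out$ra_i) | is.na(out$ra_j)
  dropped <- out$genotype[missing]
  out <- out[!missing, ]
  out$epsilon <- epistasis_value(out$ra_i, out$ra_j, out$ra_ij,
                                 floor = floor, base = base)
  out <- out %>%
    dplyr::select(dplyr::all_of(c("genotype", "mut_i", "mut_j", "ra_i",
                                  "ra_j", "ra_ij", "epsilon")))
  attr(out, "missing_singles") <- dropped
  out
}

#' Flag unreliable epistasis values (sigma filter)
#'
#' Builds the pooled distribution of differences
#' `d = RA_ij - RA_k` over every double mutant and each of its constituent
#' singles `k`, takes its standard deviation `sigma`, and flags a record
#' when the double's RA is within `c * sigma` of a constituent single's RA
#' (combiner `"either"`, the default) or of both (`"both"`). A flagged
#' epsilon is considered indistinguishable from a no-interaction
#' measurement artifact and is set aside by downstream distribution
#' summaries.
#'
#' @param epistasis Tibble from [epistasis_table()].
#' @param c_sigma Multiplier on sigma (default 1).
#' @param combiner `"either"` (flag when either difference is small) or
#'   `"both"`.
#' @return The input with logical `filtered` and numeric `sigma_used`
#'   columns added.
#' @export
filter_epistasis <- function(epistasis, c_sigma = 1,
                             combiner = c("either", "both")) {
  combiner <- match.arg(combiner)
  d_i <- epistasis$ra_ij - epistasis$ra_i
  d_j <- epistasis$ra_ij - epistasis$ra_j
  d_all <- c(d_i, d_j)
  if (length(d_all) < 2) {
    warning("fewer than two differences; sigma undefined, nothing filtered")
    epistasis$filtered <- FALSE
    epistasis$sigma_used <- NA_real_
    return(epistasis)
  }
  sigma <- stats::sd(d_all)
  small_i <- abs(d_i) < c_sigma * sigma
  small_j <- abs(d_j) < c_sigma * sigma
  epistasis$filtered <- if (combiner == "either") small_i | small_j
                        else small_i & small_j
  epistasis$sigma_used <- sigma
  epistasis
}

#' Double-mutant relative-activity heatmap matrix
#'
#' A `3L x 3L` matrix over all single mutations, ordered position-major and
#' A<C<G<U within position (reference base skipped). Off-diagonal cells
#' hold the mean RA of the corresponding double mutant; diagonal cells hold
#' the single-mutant RA; cells pairing two mutations at the same position
#' are impossible genotypes and stay `NA`, as do unmeasured doubles.
#'
#' @param activity Activity table from [activity_table()].
#' @param ref A `ribozyme_reference`.
#' @return Numeric matrix with dimnames `"pos:alt"`; attribute
#'   `fill_fraction` is the share of possible cells (valid diagonal and
#'   off-diagonal) that are populated.
#' @export
build_heatmap_matrix <- function(activity, ref) {
  axis <- enumerate_single_mutants(ref)
  n <- length(axis)
  M <- matrix(NA_real_, n, n, dimnames = list(axis, axis))
  singles <- activity %>% dplyr::filter(.data$order == 1L)
  idx <- match(singles$genotype, axis)
  M[cbind(idx, idx)] <- singles$mean_ra
  doubles <- activity %>% dplyr::filter(.data$order == 2L)
  if (nrow(doubles) > 0) {
    muts <- strsplit(doubles$genotype, ",", fixed = TRUE)
    i <- match(vapply(muts, `[`, "", 1), axis)
    j <- match(vapply(muts, `[`, "", 2), axis)
    M[cbind(i, j)] <- doubles$mean_ra
    M[cbind(j, i)] <- doubles$mean_ra
  }
  L <- ref_length(ref)
  possible <- n + 9 * L * (L - 1)  # diagonal + both triangles
  attr(M, "fill_fraction") <- sum(!is.na(M)) / possible
  M
}
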