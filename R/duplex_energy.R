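#' Nearest-neighbor duplex parameters
#'
#' Loads the embedded stacking free-energy table (Turner-rules RNA
#' parameters at 37 degrees C: Watson-Crick stacks from Xia et al. 1998,
#' G.U wobble stacks from Mathews et al. 1999) together with the duplex
#' initiation, terminal AU/GU and symmetry terms.
#'
#' @return List with `stacks` (named numeric, keys `"pair1|pair2"`),
#'   `init`, `terminal_au`, `symmetry` (kcal/mol).
#' @export
nn_parameters <- function() {
  if (!is.null(.nn_cache$params)) return(.nn_cache$params)
  path <- system.file("extdata", "nn_stack_dg37.tsv", package = "ribodms",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  params <- list(
    stacks = stats::setNames(tab$dg37, paste(tab$pair1, tab$pair2,
                                             sep = "|")),
    init = 4.10,
    terminal_au = 0.50,
    symmetry = 0.43
  )
  .nn_cache$params <- params
  params
}
.nn_cache <- new.env(parent = emptyenv())

PAIRABLE <- c("AU", "UA", "GC", "CG", "GU", "UG")

#' Minimum free energy of a paired region treated as a duplex
#'
#' The region is split into its two strands, keeping only the base-paired
#' nucleotides (loop nucleotides are discarded): the 5' strand reads the
#' `pos5` bases in helix order, the 3' strand the `pos3` bases. The free
#' energy at 37 degrees C is the duplex initiation plus the sum of
#' nearest-neighbor stacking terms over consecutive pairs, plus terminal
#' AU/GU penalties at the two helix ends and the symmetry correction for
#' self-complementary duplexes. A single-pair region gets initiation and
#' terminal penalties only. Terminal-loop contributions are deliberately
#' ignored so internal and terminal stems are comparable.
#'
#' @param region A paired region (`list(name, pairs)`).
#' @param ref A `ribozyme_reference`.
#' @return List with `region`, `n_pairs`, `delta_g` (kcal/mol),
#'   `strand5`, `strand3`.
#' @export
duplex_mfe <- function(region, ref) {
  pairs <- region$pairs
  stopifnot(nrow(pairs) >= 1)
  b5 <- ref_base(ref, pairs[, 1])
  b3 <- ref_base(ref, pairs[, 2])
  ptype <- paste0(b5, b3)
  bad <- !(ptype %in% PAIRABLE)
  if (any(bad)) {
    stop(sprintf(
      "region %s: non-pairable combination %s at pair (%d, %d)",
      region$name, ptype[which(bad)[1]],
      pairs[which(bad)[1], 1], pairs[which(bad)[1], 2]), call. = FALSE)
  }
  par <- nn_parameters()
  dg <- par$init
  if (nrow(pairs) > 1) {
    keys <- paste(ptype[-length(ptype)], ptype[-1], sep = "|")
    dg <- dg + sum(par$stacks[keys])
  }
  weak <- c("AU", "UA", "GU", "UG")
  dg <- dg + par$terminal_au * (ptype[1] %in% weak) +
    par$terminal_au * (ptype[length(ptype)] %in% weak)
  strand5 <- paste(b5, collapse = "")
  strand3 <- paste(rev(b3), collapse = "")  # read 5'->3' on its own strand
  if (identical(strand5, strand3)) dg <- dg + par$symmetry
  list(region = region$name, n_pairs = nrow(pairs),
       delta_g = unname(dg), strand5 = strand5, strand3 = strand3)
}

#' Duplex free energies for all paired regions of a reference
#'
#' Regions containing a non-canonical pair (for example a U:U pseudoknot
#' pair) have no nearest-neighbor duplex energy; they get `NA` with a
#' warning rather than an error.
#'
#' @param ref A `ribozyme_reference`.
#' @return Tibble with `region`, `n_pairs`, `delta_g`.
#' @export
region_energies <- function(ref) {
  rows <- lapply(ref$paired_regions, function(rg) {
    res <- tryCatch(duplex_mfe(rg, ref), error = function(e) {
      warning(conditionMessage(e), call. = FALSE)
      list(region = rg$name, n_pairs = nrow(rg$pairs), delta_g = NA_real_)
    })
    tibble::tibble(region = res$region, n_pairs = res$n_pairs,
                   delta_g = res$delta_g)
  })
  dplyr::bind_rows(rows)
}

#' Correlation of paired-region stability with single-mutant effects
#'
#' For each paired region, the median replicate-mean RA over all single
#' mutants at the region's base-paired positions is compared with the
#' region's duplex free energy by Pearson correlation.
#'
#' @param energies Tibble from [region_energies()] (rows with `NA`
#'   `delta_g` are dropped).
#' @param activity Activity table from [activity_table()].
#' @param ref A `ribozyme_reference`.
#' @return List with `data` (region, delta_g, median_single_ra), `r`, `p`,
#'   and `degenerate` (TRUE when a correlation could not be computed, for
#'   example constant medians).
#' @export
stability_correlation <- function(energies, activity, ref) {
  singles <- activity %>% dplyr::filter(.data$order == 1L)
  pos <- vapply(strsplit(singles$genotype, ":", fixed = TRUE),
                function(x) as.integer(x[1]), 0L)
  med <- vapply(ref$paired_regions, function(rg) {
    sel <- pos %in% region_positions(rg)
    if (!any(sel)) return(NA_real_)
    stats::median(singles$mean_ra[sel])
  }, 0)
  data <- energies %>%
    dplyr::mutate(median_single_ra = unname(med[.data$region])) %>%
    dplyr::filter(!is.na(.data$delta_g), !is.na(.data$median_single_ra))
  if (nrow(data) < 3) {
    stop("need at least 3 regions with defined energy and activity",
         call. = FALSE)
  }
  if (stats::sd(data$median_single_ra) == 0 ||
      stats::sd(data$delta_g) == 0) {
    return(list(data = data, r = NA_real_, p = NA_real_,
                degenerate = TRUE))
  }
  ct <- stats::cor.test(data$delta_g, data$median_single_ra,
                        method = "pearson")
  list(data = data, r = unname(ct$estimate), p = ct$p.value,
       degenerate = FALSE)
}
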