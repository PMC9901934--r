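#' Call the genotype of reads by sliding-window comparison
#'
#' Slides a window of reference length over each read and keeps the offset
#' with the fewest mismatches, ties broken by the smallest offset. The
#' mismatching positions and identities become the genotype. Only
#' substitutions are modelled; a read whose best window still exceeds
#' `max_muts` mismatches is unassigned.
#'
#' @param reads Character vector of read sequences (T normalized to U).
#' @param ref A `ribozyme_reference`.
#' @param max_muts Maximum mutations for assignment (the analysis universe
#'   is 2).
#' @param report_cap Mismatch counts up to this value still get a genotype
#'   string so that higher-order reads can be tallied, even though they are
#'   not assigned.
#' @return Tibble with one row per read: `offset` (bases 5' of the matched
#'   window; `NA` for short reads), `n_mismatch`, `genotype` (`NA` when not
#'   identifiable), `assigned`, and `reason` (`"ok"`, `"short"` or
#'   `"too_many_mutations"`).
#' @export
call_variants <- function(reads, ref, max_muts = 2, report_cap = 8) {
  reads <- chartr("Tt", "UU", toupper(reads))
  res <- cpp_call_variants(reads, ref$sequence, as.integer(report_cap))
  offset <- res$offset
  short <- offset < 0
  offset[short] <- NA_integer_
  geno <- res$genotype
  geno[geno == ""] <- NA_character_
  assigned <- !short & !is.na(res$mismatch) & res$mismatch <= max_muts
  tibble::tibble(
    offset = offset,
    n_mismatch = res$mismatch,
    genotype = geno,
    assigned = assigned,
    reason = dplyr::case_when(short ~ "short",
                              !assigned ~ "too_many_mutations",
                              TRUE ~ "ok")
  )
}

#' Classify called reads as cleaved or uncleaved
#'
#' A read is uncleaved when the 5' leader (the cleavage product) is present
#' immediately 5' of the matched window: the leader's 3'-terminal
#' `k = min(nchar(leader), offset)` bases must match the `k` bases
#' preceding the window with at most `max_mismatch` mismatches. Any other
#' preceding sequence (for example only a TSO pad) means the molecule
#' self-cleaved. Reads with `offset = 0` carry no evidence of a leader and
#' are classified cleaved.
#'
#' @param reads Character vector of read sequences.
#' @param offsets Integer window offsets from [call_variants()].
#' @param ref A `ribozyme_reference`.
#' @param max_mismatch Mismatches tolerated in the leader match (default 0,
#'   exact).
#' @return Logical vector: `TRUE` = cleaved; `NA` where `offsets` is `NA`.
#' @export
classify_cleavage <- function(reads, offsets, ref, max_mismatch = 0) {
  if (length(reads) == 0) return(logical(0))
  reads <- chartr("Tt", "UU", toupper(reads))
  leader <- ref$leader
  nl <- nchar(leader)
  k <- pmin(nl, offsets)
  prefix <- substring(reads, offsets - k + 1, offsets)
  suffix <- substring(leader, nl - k + 1, nl)
  if (max_mismatch == 0) {
    uncleaved <- !is.na(k) & k > 0 & prefix == suffix
  } else {
    mm <- mapply(function(a, b) {
      if (is.na(a) || nchar(a) == 0) return(Inf)
      sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    }, prefix, suffix)
    uncleaved <- !is.na(k) & k > 0 & mm <= max_mismatch
  }
  out <- !uncleaved
  out[is.na(offsets)] <- NA
  out
}

#' Count cleaved and uncleaved reads per genotype
#'
#' One pass over a FASTQ (or FASTA) file: each read is assigned a genotype
#' by [call_variants()], classified by [classify_cleavage()], and
#' aggregated into per-genotype cleaved/uncleaved counts. Totals are
#' conserved: mapped plus unassigned equals the number of input reads.
#'
#' @param path FASTQ file (`.gz` accepted), or a character vector of read
#'   sequences.
#' @param ref A `ribozyme_reference`.
#' @param replicate Replicate label recorded in the output.
#' @param max_muts Maximum mutations for assignment.
#' @param format `"fastq"` or `"fasta"` (ignored when `path` is a vector of
#'   sequences).
#' @param max_mismatch_leader Mismatches tolerated in the leader match.
#' @return List with `counts` (tibble: genotype, replicate, n_cleaved,
#'   n_uncleaved, ordered by genotype) and `report` (a `mapping_report`
#'   list: totals, per-order tallies, unassigned reasons).
#' @export
count_reads <- function(path, ref, replicate = "rep1", max_muts = 2,
                        format = c("fastq", "fasta"),
                        max_mismatch_leader = 0) {
  format <- match.arg(format)
  if (length(path) == 1 && file.exists(path)) {
    reads <- as.character(Biostrings::readDNAStringSet(path, format = format))
  } else {
    reads <- as.character(path)
  }
  total <- length(reads)
  calls <- call_variants(reads, ref, max_muts = max_muts)
  cleaved <- classify_cleavage(reads, calls$offset, ref,
                               max_mismatch = max_mismatch_leader)

  keep <- calls$assigned
  counts <- tibble::tibble(genotype = calls$genotype[keep],
                           cleaved = cleaved[keep]) %>%
    dplyr::count(.data$genotype, .data$cleaved) %>%
    tidyr::pivot_wider(names_from = "cleaved", values_from = "n",
                       values_fill = 0L) %>%
    dplyr::rename_with(~ c("TRUE" = "n_cleaved",
                           "FALSE" = "n_uncleaved")[.x],
                       dplyr::any_of(c("TRUE", "FALSE")))
  for (col in c("n_cleaved", "n_uncleaved")) {
    if (!col %in% names(counts)) counts[[col]] <- 0L
  }
  counts <- counts %>%
    dplyr::mutate(replicate = replicate) %>%
    dplyr::select(dplyr::all_of(c("genotype", "replicate",
                                  "n_cleaved", "n_uncleaved"))) %>%
    dplyr::arrange(.data$genotype)

  order_known <- !is.na(calls$genotype)
  per_order <- table(genotype_order(calls$genotype[order_known]))
  report <- structure(list(
    total = total,
    mapped = sum(keep),
    # Two readings of "total mapped": only reads inside the analysis
    # universe (<= max_muts), or any read whose best window was
    # identifiable including higher orders.
    mapped_incl_higher_order = sum(order_known),
    per_order = as.list(per_order),
    unassigned = total - sum(keep),
    reasons = as.list(table(calls$reason[!keep]))
  ), class = "mapping_report")
  stopifnot(report$mapped + report$unassigned == total)
  list(counts = counts, report = report)
}

#' @export
print.mapping_report <- function(x, ...) {
  cat("<mapping_report>\n")
  cat("  total reads     :", x$total, "\n")
  cat("  mapped (<= max) :", x$mapped, "\n")
  cat("  incl. higher ord:", x$mapped_incl_higher_order, "\n")
  cat("  unassigned      :", x$unassigned, "\n")
  if (length(x$per_order)) {
    cat("  per order       :",
        paste(sprintf("%s=%s", names(x$per_order), unlist(x$per_order)),
              collapse = ", "), "\n")
  }
  if (length(x$reasons)) {
    cat("  reasons         :",
        paste(sprintf("%s=%s", names(x$reasons), unlist(x$reasons)),
              collapse = ", "), "\n")
  }
  invisible(x)
}
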