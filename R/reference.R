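#' Ribozyme reference definitions
#'
#' A `ribozyme_reference` holds everything downstream analyses need to know
#' about one self-cleaving ribozyme construct: the ribozyme sequence, the
#' 5' leader (the cleavage product that remains attached only on uncleaved
#' molecules), the secondary-structure annotation as a set of named paired
#' regions, and the catalytic positions.
#'
#' Coordinates are 0-based and anchored at the cleavage site: position 0 is
#' the first ribozyme nucleotide 3' of the scissile phosphate. Published
#' figures use assorted 1-based numbering schemes, so each definition
#' carries a `display_offset` such that `position + display_offset`
#' reproduces the figure-style label.
#'
#' @param name Construct label.
#' @param sequence Ribozyme sequence (A/C/G/U; T is accepted and
#'   normalized to U).
#' @param leader 5' leader sequence retained on uncleaved molecules.
#' @param paired_regions List of paired regions as returned by
#'   [parse_structure()], or `NULL` for an unannotated reference.
#' @param catalytic Integer vector of 0-based catalytic positions.
#' @param display_offset Integer added to internal positions when printing
#'   figure-style labels.
#'
#' @return An object of class `ribozyme_reference`.
#' @export
ribozyme_reference <- function(name, sequence, leader = "",
                               paired_regions = NULL,
                               catalytic = integer(0),
                               display_offset = 1L) {
  ref <- structure(
    list(
      name = as.character(name),
      sequence = normalize_rna(sequence),
      leader = normalize_rna(leader),
      paired_regions = paired_regions %||% list(),
      catalytic = as.integer(sort(unique(catalytic))),
      display_offset = as.integer(display_offset)
    ),
    class = "ribozyme_reference"
  )
  validate_reference(ref)
  ref
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize a nucleotide string to the RNA alphabet
#'
#' Uppercases and converts T to U; rejects any other letter.
#'
#' @param x Character scalar.
#' @return Character scalar over A/C/G/U.
#' @export
normalize_rna <- function(x) {
  x <- chartr("t", "u", toupper(as.character(x)))
  x <- chartr("T", "U", x)
  if (nchar(x) > 0 && grepl("[^ACGU]", x)) {
    stop("sequence contains letters outside A/C/G/U/T: ", x, call. = FALSE)
  }
  x
}

validate_reference <- function(ref) {
  L <- nchar(ref$sequence)
  if (L < 1) stop("reference sequence is empty", call. = FALSE)
  all_pos <- integer(0)
  for (rg in ref$paired_regions) {
    p <- rg$pairs
    if (!is.matrix(p) || ncol(p) != 2) {
      stop("region ", rg$name, ": pairs must be a two-column matrix",
           call. = FALSE)
    }
    if (any(p < 0) || any(p >= L)) {
      stop("region ", rg$name, ": pair positions outside [0, L)",
           call. = FALSE)
    }
    if (any(p[, 1] >= p[, 2])) {
      stop("region ", rg$name, ": pos5 must be < pos3 in every pair",
           call. = FALSE)
    }
    all_pos <- c(all_pos, as.vector(p))
  }
  if (anyDuplicated(all_pos)) {
    stop("a position appears in more than one base pair across regions",
         call. = FALSE)
  }
  if (any(ref$catalytic < 0 | ref$catalytic >= L)) {
    stop("catalytic positions outside [0, L)", call. = FALSE)
  }
  invisible(ref)
}

#' @export
print.ribozyme_reference <- function(x, ...) {
  cat("<ribozyme_reference> ", x$name, "\n", sep = "")
  cat("  length      : ", nchar(x$sequence), " nt\n", sep = "")
  cat("  leader      : ", nchar(x$leader), " nt\n", sep = "")
  rg <- vapply(x$paired_regions,
               function(r) sprintf("%s(%d bp)", r$name, nrow(r$pairs)), "")
  cat("  regions     : ", paste(rg, collapse = ", "), "\n", sep = "")
  cat("  catalytic   : ",
      paste(x$catalytic + x$display_offset, collapse = ", "),
      " (figure numbering)\n", sep = "")
  invisible(x)
}

#' Length of the ribozyme sequence
#' @param ref A `ribozyme_reference`.
#' @return Integer length in nucleotides.
#' @export
ref_length <- function(ref) nchar(ref$sequence)

# All 0-based positions involved in base pairs of one region.
region_positions <- function(region) sort(as.vector(region$pairs))

#' Parse a multi-layer dot-bracket annotation into paired regions
#'
#' The annotation uses one bracket alphabet per pairing layer: `()` for the
#' nested secondary structure and `[]`, `{}`, `<>` for pseudoknot layers.
#' Within each layer, a maximal run of stacked pairs (pos5 ascending by one
#' while pos3 descends by one) forms one helix; each helix becomes one
#' paired region and receives the next label from `region_labels`, assigned
#' in order of the helix's outermost 5' position.
#'
#' @param annotation Dot-bracket string; dots mark unpaired positions.
#' @param region_labels Character vector of region names, one per helix, in
#'   5'-to-3' order of the helix openings.
#' @return Named list of paired regions, each a `list(name, pairs)` with
#'   `pairs` an ordered (outermost-to-innermost) two-column 0-based matrix.
#' @export
#' @examples
#' parse_structure("((..))", "P1")
parse_structure <- function(annotation, region_labels) {
  layers <- list(c("(", ")"), c("[", "]"), c("{", "}"), c("<", ">"))
  chars <- strsplit(annotation, "")[[1]]
  known <- c(".", unlist(layers))
  bad <- setdiff(unique(chars), known)
  if (length(bad) > 0) {
    stop("unknown structure characters: ", paste(bad, collapse = " "),
         call. = FALSE)
  }
  all_pairs <- NULL
  for (ly in layers) {
    stack <- integer(0)
    pairs <- NULL
    for (i in seq_along(chars)) {
      if (chars[i] == ly[1]) {
        stack <- c(stack, i - 1L)
      } else if (chars[i] == ly[2]) {
        if (length(stack) == 0) {
          stop(sprintf("unbalanced '%s' at position %d", ly[2], i - 1L),
               call. = FALSE)
        }
        pairs <- rbind(pairs, c(stack[length(stack)], i - 1L))
        stack <- stack[-length(stack)]
      }
    }
    if (length(stack) > 0) {
      stop(sprintf("unbalanced '%s' at position %d", ly[1],
                   stack[length(stack)]), call. = FALSE)
    }
    all_pairs <- rbind(all_pairs, pairs)
  }
  if (is.null(all_pairs)) {
    if (length(region_labels) != 0) {
      stop("no pairs found but region labels supplied", call. = FALSE)
    }
    return(list())
  }
  all_pairs <- all_pairs[order(all_pairs[, 1]), , drop = FALSE]
  # split into helices: consecutive stacked pairs stay together
  helix_id <- cumsum(c(1, diff(all_pairs[, 1]) != 1 |
                          diff(all_pairs[, 2]) != -1))
  helices <- split.data.frame(all_pairs, helix_id)
  helices <- helices[order(vapply(helices, function(h) h[1, 1], 0))]
  if (length(helices) != length(region_labels)) {
    stop(sprintf("annotation contains %d helices but %d labels supplied",
                 length(helices), length(region_labels)), call. = FALSE)
  }
  regions <- lapply(seq_along(helices), function(i) {
    m <- as.matrix(helices[[i]])
    dimnames(m) <- list(NULL, c("pos5", "pos3"))
    list(name = region_labels[i], pairs = m)
  })
  names(regions) <- region_labels
  regions
}

#' Read a ribozyme reference definition file
#'
#' Definition files are YAML with fields `name`, `sequence`, `leader`,
#' `structure` (multi-layer dot-bracket), `regions` (helix labels in
#' 5'-to-3' order), `catalytic` (0-based positions) and `display_offset`.
#'
#' @param path Path to a YAML definition file.
#' @return A `ribozyme_reference`.
#' @export
read_reference <- function(path) {
  y <- yaml::read_yaml(path)
  seqn <- normalize_rna(y$sequence)
  regions <- list()
  if (!is.null(y$structure)) {
    if (nchar(y$structure) != nchar(seqn)) {
      stop("structure annotation length differs from sequence length in ",
           path, call. = FALSE)
    }
    regions <- parse_structure(y$structure, unlist(y$regions))
  }
  ribozyme_reference(
    name = y$name,
    sequence = seqn,
    leader = y$leader %||% "",
    paired_regions = regions,
    catalytic = unlist(y$catalytic) %||% integer(0),
    display_offset = y$display_offset %||% 1L
  )
}

#' Import a sequence-only reference from FASTA
#'
#' Convenience importer for references without structure annotation.
#'
#' @param path FASTA file; the first record is used.
#' @param leader Leader sequence (not part of the FASTA record).
#' @return A `ribozyme_reference` with no paired regions.
#' @export
reference_from_fasta <- function(path, leader = "") {
  ss <- Biostrings::readBStringSet(path)
  ribozyme_reference(
    name = names(ss)[1],
    sequence = as.character(ss[[1]]),
    leader = leader
  )
}

#' Reference definitions shipped with the package
#'
#' Returns the path of one of the five synthetic reference definitions
#' (`cpeb3`, `hdv`, `twister`, `hairpin`, `hammerhead`). These are
#' constructed stand-ins: they reproduce the published lengths, region
#' inventories, stem sizes and catalytic numbering of the five study
#' constructs, but not the actual nucleotide sequences.
#'
#' @param which One of `"cpeb3"`, `"hdv"`, `"twister"`, `"hairpin"`,
#'   `"hammerhead"`.
#' @return File path to the YAML definition.
#' @export
ribodms_reference_file <- function(which = c("cpeb3", "hdv", "twister",
                                             "hairpin", "hammerhead")) {
  which <- match.arg(which)
  system.file("extdata", paste0(which, "_synthetic.yaml"),
              package = "ribodms", mustWork = TRUE)
}

# ---- genotypes ------------------------------------------------------------

#' Build a canonical genotype string
#'
#' Genotypes are sets of substitutions relative to the reference, written
#' `"pos:alt"` joined by commas with positions ascending (0-based); the
#' wild type is `"WT"`.
#'
#' @param positions Integer vector of 0-based positions.
#' @param alts Character vector of alternative bases, same length.
#' @param ref Optional `ribozyme_reference`; when supplied, substitutions
#'   are checked against it (position range, alt differs from reference).
#' @return Canonical genotype string.
#' @export
genotype <- function(positions, alts, ref = NULL) {
  stopifnot(length(positions) == length(alts))
  if (length(positions) == 0) return("WT")
  positions <- as.integer(positions)
  alts <- toupper(as.character(alts))
  if (anyDuplicated(positions)) {
    stop("positions within one genotype must be distinct", call. = FALSE)
  }
  if (!all(alts %in% RNA_BASES)) {
    stop("alternative bases must be A/C/G/U", call. = FALSE)
  }
  if (!is.null(ref)) {
    L <- ref_length(ref)
    if (any(positions < 0 | positions >= L)) {
      stop("substitution position outside [0, L)", call. = FALSE)
    }
    refb <- ref_base(ref, positions)
    if (any(refb == alts)) {
      stop("alternative base equals the reference base at position ",
           paste(positions[refb == alts], collapse = ", "), call. = FALSE)
    }
  }
  o <- order(positions)
  paste(sprintf("%d:%s", positions[o], alts[o]), collapse = ",")
}

#' Parse a genotype string
#' @param g Genotype string (`"WT"` or `"pos:alt[,pos:alt]"`).
#' @return List with integer `positions` and character `alts`.
#' @export
parse_genotype <- function(g) {
  if (identical(g, "WT") || identical(g, "")) {
    return(list(positions = integer(0), alts = character(0)))
  }
  parts <- strsplit(g, ",", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^([0-9]+):([ACGU])$", parts))
  if (any(lengths(m) != 3)) stop("malformed genotype string: ", g,
                                 call. = FALSE)
  list(
    positions = as.integer(vapply(m, `[`, "", 2)),
    alts = vapply(m, `[`, "", 3)
  )
}

#' Number of substitutions in a genotype
#' @param g Character vector of genotype strings.
#' @return Integer vector of mutation orders (0 for `"WT"`).
#' @export
genotype_order <- function(g) {
  ifelse(g == "WT" | g == "", 0L,
         vapply(strsplit(g, ",", fixed = TRUE), length, 0L))
}

# Reference base(s) at 0-based positions.
ref_base <- function(ref, positions) {
  vapply(positions + 1L, function(i) substr(ref$sequence, i, i), "")
}

#' Apply a genotype to the reference sequence
#'
#' @param ref A `ribozyme_reference`.
#' @param g Genotype string.
#' @return Mutated sequence (same length as the reference).
#' @export
apply_genotype <- function(ref, g) {
  p <- parse_genotype(g)
  s <- ref$sequence
  L <- nchar(s)
  if (length(p$positions) == 0) return(s)
  if (any(p$positions < 0 | p$positions >= L)) {
    stop("substitution position outside [0, L)", call. = FALSE)
  }
  refb <- ref_base(ref, p$positions)
  if (any(refb == p$alts)) {
    stop("alternative base equals the reference base", call. = FALSE)
  }
  ch <- strsplit(s, "")[[1]]
  ch[p$positions + 1L] <- p$alts
  paste(ch, collapse = "")
}

#' Recover a genotype by diffing a sequence against the reference
#'
#' @param ref A `ribozyme_reference`.
#' @param seq Sequence of the same length as the reference.
#' @return Canonical genotype string.
#' @export
diff_genotype <- function(ref, seq) {
  seq <- normalize_rna(seq)
  if (nchar(seq) != ref_length(ref)) {
    stop("sequence length differs from reference", call. = FALSE)
  }
  a <- strsplit(ref$sequence, "")[[1]]
  b <- strsplit(seq, "")[[1]]
  idx <- which(a != b)
  genotype(idx - 1L, b[idx])
}

#' Enumerate all single mutants
#'
#' Every position takes each of the three non-reference bases, ordered
#' position-major with bases A<C<G<U.
#'
#' @param ref A `ribozyme_reference`.
#' @return Character vector of 3L genotype strings.
#' @export
enumerate_single_mutants <- function(ref) {
  L <- ref_length(ref)
  refb <- ref_base(ref, 0:(L - 1))
  unlist(lapply(seq_len(L) - 1L, function(p) {
    sprintf("%d:%s", p, setdiff(RNA_BASES, refb[p + 1]))
  }))
}

#' Enumerate all double mutants
#'
#' All unordered pairs of distinct positions with each combination of
#' non-reference bases: 9 L (L-1) / 2 genotypes.
#'
#' @param ref A `ribozyme_reference`.
#' @return Character vector of genotype strings.
#' @export
enumerate_double_mutants <- function(ref) {
  L <- ref_length(ref)
  if (L < 2) stop("need L >= 2 for double mutants", call. = FALSE)
  refb <- ref_base(ref, 0:(L - 1))
  alts <- lapply(seq_len(L), function(i) setdiff(RNA_BASES, refb[i]))
  out <- vector("list", L * (L - 1) / 2)
  k <- 1L
  for (p1 in 0:(L - 2)) {
    for (p2 in (p1 + 1):(L - 1)) {
      grid <- expand.grid(a2 = alts[[p2 + 1]], a1 = alts[[p1 + 1]],
                          stringsAsFactors = FALSE)
      out[[k]] <- sprintf("%d:%s,%d:%s", p1, grid$a1, p2, grid$a2)
      k <- k + 1L
    }
  }
  unlist(out)
}
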