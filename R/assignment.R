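# Parental-copy assignment: each reconstructed insertion is genotyped at
# diagnostic SNP positions in the reverse-transcriptase (RT) domain — the
# most conserved part of the element — and assigned to the donor copy (or
# ambiguity set) whose alleles it matches.

#' Construct a diagnostic SNP panel
#'
#' @param rt_reference DNA string: one donor's RT segment, used as the
#'   coordinate frame
#' @param positions 0-based offsets of the diagnostic positions within
#'   `rt_reference` (16 or more)
#' @param alleles matrix of bases, rows = donors (rownames = donor ids),
#'   columns = positions
#' @return panel object (list, class `diagnostic_panel`)
#' @export
diagnostic_panel <- function(rt_reference, positions, alleles) {
  stopifnot(is.matrix(alleles), ncol(alleles) == length(positions),
            !is.null(rownames(alleles)))
  if (any(positions < 0 | positions >= nchar(rt_reference)))
    stop("diagnostic positions outside the RT reference")
  p <- list(rt_reference = rt_reference, positions = as.integer(positions),
            alleles = alleles)
  class(p) <- "diagnostic_panel"
  p
}

#' Locate the RT segment within a consensus
#'
#' Best local alignment (match +1, mismatch -1, gap open -2, extend -1) of
#' the RT reference within the consensus; the reverse complement is tried
#' when the forward orientation fails. Returns NULL when alignment identity
#' is below 80% (e.g. a 5'-truncated insert lacking the RT).
#'
#' @param consensus DNA string
#' @param rt_reference DNA string
#' @return list(start0, end0 (consensus coords), orientation, alignment) or
#'   NULL
#' @export
locate_rt <- function(consensus, rt_reference) {
  if (nchar(consensus) < nchar(rt_reference) / 2) return(NULL)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  try_one <- function(subject, orientation) {
    pa <- Biostrings::pairwiseAlignment(
      pattern = rt_reference, subject = subject, type = "local",
      substitutionMatrix = mat, gapOpening = 1, gapExtension = 1)
    ap <- as.character(Biostrings::alignedPattern(pa))
    as_ <- as.character(Biostrings::alignedSubject(pa))
    cols <- nchar(ap)
    ident <- sum(strsplit(ap, "")[[1]] == strsplit(as_, "")[[1]]) / cols
    # identity over the full RT reference, so clipped local hits cannot pass
    ident_full <- ident * cols / nchar(rt_reference)
    if (ident_full < 0.8) return(NULL)
    list(start0 = Biostrings::start(Biostrings::subject(pa)) - 1L,
         end0 = Biostrings::end(Biostrings::subject(pa)),
         orientation = orientation, identity = ident,
         pattern_start0 = Biostrings::start(Biostrings::pattern(pa)) - 1L,
         aligned_pattern = ap, aligned_subject = as_)
  }
  hit <- try_one(consensus, "forward")
  if (is.null(hit)) hit <- try_one(reverse_complement(consensus), "reverse")
  hit
}

#' Genotype a located RT segment at the diagnostic positions
#'
#' @param located result of [locate_rt()]
#' @param panel a [diagnostic_panel()]
#' @return character vector of bases over panel positions; NA where the
#'   position is deleted or not covered by the alignment
#' @export
genotype_diagnostics <- function(located, panel) {
  out <- rep(NA_character_, length(panel$positions))
  if (is.null(located)) return(out)
  ap <- strsplit(located$aligned_pattern, "")[[1]]
  as_ <- strsplit(located$aligned_subject, "")[[1]]
  rt_pos <- located$pattern_start0 - 1L   # 0-based position in rt_reference
  lookup <- setNames(seq_along(panel$positions), panel$positions)
  for (j in seq_along(ap)) {
    if (ap[j] != "-") {
      rt_pos <- rt_pos + 1L
      key <- as.character(rt_pos)
      if (!is.na(lookup[key])) {
        base <- as_[j]
        out[lookup[key]] <- if (base == "-") NA_character_ else base
      }
    }
  }
  out
}

#' Assign a genotype vector to its donor (or ambiguity set)
#'
#' Per-donor agreement is counted over covered (non-NA) positions; the
#' donor set is every donor attaining the maximum. Unassigned when fewer
#' than `min_covered` positions are readable or the best match fraction
#' falls below `min_match_frac`.
#'
#' @param genotype character vector over panel positions (NA = unknown)
#' @param panel a [diagnostic_panel()]
#' @param min_covered minimum readable positions
#' @param min_match_frac minimum best-match fraction
#' @return list(donor_set, matches (named counts), covered)
#' @export
assign_donor <- function(genotype, panel, min_covered = 8L,
                         min_match_frac = 0.9) {
  covered <- which(!is.na(genotype))
  matches <- apply(panel$alleles, 1, function(row)
    sum(row[covered] == genotype[covered]))
  if (length(covered) < min_covered ||
      max(matches) / length(covered) < min_match_frac) {
    return(list(donor_set = character(0), matches = matches,
                covered = length(covered)))
  }
  list(donor_set = names(matches)[matches == max(matches)],
       matches = matches, covered = length(covered))
}

#' Assign every consensus to its parental donor
#'
#' @param consensuses named character vector (tei_id -> consensus DNA)
#' @param panel a [diagnostic_panel()]
#' @param min_covered minimum readable diagnostic positions
#' @param min_match_frac minimum best-match fraction
#' @return list of assignment results (one per TEI)
#' @export
assign_parents <- function(consensuses, panel, min_covered = 8L,
                           min_match_frac = 0.9) {
  lapply(consensuses, function(cns) {
    hit <- locate_rt(cns, panel$rt_reference)
    g <- genotype_diagnostics(hit, panel)
    assign_donor(g, panel, min_covered, min_match_frac)
  })
}

#' Summarize donor assignments
#'
#' Ambiguous TEIs (donor set of size > 1) are counted in a separate
#' "shared" category rather than split fractionally; TEIs with an empty
#' donor set are "unassigned".
#'
#' @param results list from [assign_parents()] (or of [assign_donor()]
#'   results)
#' @param donors donor ids defining the count table (defaults to the donors
#'   seen in `results`)
#' @return list(per_donor = named counts, shared, unassigned, total)
#' @export
summarize_assignments <- function(results, donors = NULL) {
  donors <- donors %||% unique(unlist(lapply(results, function(r)
    names(r$matches))))
  per_donor <- setNames(rep(0L, length(donors)), donors)
  shared <- 0L; unassigned <- 0L
  for (r in results) {
    n <- length(r$donor_set)
    if (n == 0) unassigned <- unassigned + 1L
    else if (n == 1) per_donor[r$donor_set] <- per_donor[r$donor_set] + 1L
    else shared <- shared + 1L
  }
  list(per_donor = per_donor, shared = shared, unassigned = unassigned,
       total = length(results))
}
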