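#' In-silico tryptic digestion
#'
#' Cleaves C-terminal to lysine (K) or arginine (R) except when the next
#' residue is proline (P), then emits every fragment carrying 0 to
#' `missed_cleavages` internal cleavage sites, filtered to a length window
#' typical of MS-observable tryptic peptides.
#'
#' @param protein_seq Amino-acid sequence (character scalar).
#' @param missed_cleavages Maximum number of internal missed cleavage sites.
#' @param min_len,max_len Peptide length window in residues (inclusive).
#' @return A tibble: `peptide`, `start_res`, `end_res` (1-based inclusive
#'   positions in the protein), `n_missed`.
#' @export
#' @examples
#' tryptic_digest("MKRDEK", missed_cleavages = 0, min_len = 1)
tryptic_digest <- function(protein_seq, missed_cleavages = 2,
                           min_len = 6, max_len = 45) {
  stopifnot(is.character(protein_seq), length(protein_seq) == 1L,
            nzchar(protein_seq))
  aa <- strsplit(protein_seq, "")[[1]]
  n <- length(aa)
  cut_after <- which(aa %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & aa[pmin(cut_after + 1L, n)] != "P"]
  bounds <- c(0L, cut_after, n)
  frag_start <- bounds[-length(bounds)] + 1L
  frag_end <- bounds[-1]
  nf <- length(frag_start)
  rows <- list_rbind(map(seq_len(nf), function(i) {
    jmax <- min(nf, i + missed_cleavages)
    tibble(
      peptide = substring(protein_seq, frag_start[i], frag_end[i:jmax]),
      start_res = frag_start[i],
      end_res = frag_end[i:jmax],
      n_missed = seq.int(i, jmax) - i
    )
  }))
  filter(rows, end_res - start_res + 1L >= min_len,
         end_res - start_res + 1L <= max_len)
}

#' Match observed peptides against candidate proteins
#'
#' Exact substring search of each observed peptide against each candidate
#' protein; every occurrence is reported, together with how much of it falls
#' inside the candidate's circRNA-unique region.
#'
#' @param observed_peptides Character vector of peptide sequences, or a data
#'   frame with a `peptide` column.
#' @param candidates A tibble with `circ_id`, `protein_seq`, `unique_start`,
#'   `unique_end` (as produced by [select_orfs()] / [derive_unique_region()]).
#' @param min_overlap Minimum number of residues inside the unique region for
#'   a match to count as unique-region evidence.
#' @param il_equivalent Treat isoleucine and leucine as indistinguishable
#'   (both mapped to I before matching); default `FALSE` (exact matching).
#' @return A tibble of class `peptide_matches`: `peptide`, `circ_id`,
#'   `start_res`, `end_res`, `overlap_len`, `overlaps_unique`.
#' @export
match_peptides <- function(observed_peptides, candidates, min_overlap = 5,
                           il_equivalent = FALSE) {
  peps <- if (is.data.frame(observed_peptides)) observed_peptides$peptide
          else observed_peptides
  peps <- unique(peps)
  norm <- function(s) if (il_equivalent) gsub("L", "I", s, fixed = TRUE) else s
  out <- list_rbind(map(seq_len(nrow(candidates)), function(i) {
    prot <- candidates$protein_seq[i]
    prot_n <- norm(prot)
    us <- candidates$unique_start[i]
    ue <- candidates$unique_end[i]
    list_rbind(map(peps, function(pep) {
      hit <- gregexpr(norm(pep), prot_n, fixed = TRUE)[[1]]
      if (hit[1] == -1L) return(NULL)
      s <- as.integer(hit)
      e <- s + nchar(pep) - 1L
      ov <- pmax(0L, pmin(e, ue) - pmax(s, us) + 1L)
      tibble(peptide = pep, circ_id = candidates$circ_id[i],
             start_res = s, end_res = e, overlap_len = ov,
             overlaps_unique = ov >= min_overlap)
    }))
  }))
  if (is.null(out) || nrow(out) == 0) {
    out <- tibble(peptide = character(), circ_id = character(),
                  start_res = integer(), end_res = integer(),
                  overlap_len = integer(), overlaps_unique = logical())
  }
  class(out) <- c("peptide_matches", class(out))
  attr(out, "min_overlap") <- min_overlap
  out
}

#' Aggregate peptide evidence into per-candidate verdicts
#'
#' A candidate is validated when at least one observed peptide overlaps its
#' unique region by the configured minimum. Coverage is the union of matched
#' residue intervals divided by the protein length (overlapping matches are
#' not double-counted).
#'
#' @param matches Output of [match_peptides()].
#' @param candidates The candidate tibble given to [match_peptides()].
#' @return A tibble: `circ_id`, `n_peptides_total`, `n_unique_peptides`,
#'   `coverage_fraction`, `validated` — one row per candidate.
#' @export
evaluate_validation <- function(matches, candidates) {
  per <- map(seq_len(nrow(candidates)), function(i) {
    id <- candidates$circ_id[i]
    aa <- nchar(candidates$protein_seq[i])
    m <- filter(matches, circ_id == id)
    cov <- if (nrow(m) == 0L) 0 else {
      ir <- IRanges::reduce(IRanges::IRanges(m$start_res, m$end_res))
      sum(IRanges::width(ir)) / aa
    }
    tibble(
      circ_id = id,
      n_peptides_total = length(unique(m$peptide)),
      n_unique_peptides = length(unique(m$peptide[m$overlaps_unique])),
      coverage_fraction = cov,
      validated = any(m$overlaps_unique)
    )
  })
  list_rbind(per)
}
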