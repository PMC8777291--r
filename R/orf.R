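#' Find junction-spanning open reading frames on circular templates
#'
#' Scans the sense strand of one or more mature circular RNA sequences for
#' ATG-initiated open reading frames whose codon span crosses the back-splice
#' junction (the joint between the last and the first base of the mature
#' sequence) at least once. The scan is implemented on a `(max_wraps + 1)`-fold
#' concatenation of the sequence, so translation may traverse the circle
#' several times (rolling-circle translation). ORFs that never meet an in-frame
#' stop codon within `max_wraps` traversals are reported with
#' `stop_found = FALSE` and are excluded from downstream selection by
#' [select_orf()].
#'
#' Candidate filtering follows three rules: the ORF must cross the junction
#' (`n_wraps >= 1`), must terminate at an in-frame stop codon to count as a
#' regular candidate, and must encode at least `min_aa` residues (stop codon
#' excluded). The default `min_aa = 101` encodes the "more than 100 amino acid
#' residues" rule as a strict inequality.
#'
#' @param templates A character vector of circular sequences (optionally named
#'   by circRNA id), or a data frame with columns `circ_id` and `mature_seq`.
#' @param min_aa Minimum protein length in residues (stop excluded). Must be
#'   >= 1.
#' @param max_wraps Maximum number of full traversals of the circle during
#'   translation.
#' @param include_rolling Keep ORFs with no in-frame stop (`stop_found =
#'   FALSE`) in the output. They are never selected by [select_orf()].
#'
#' @return A tibble with one row per ORF candidate: `circ_id`, `start_pos`
#'   (1-based position of the A of ATG on the mature sequence), `frame`
#'   (`(start_pos - 1) %% 3`), `aa_length`, `protein_seq`, `n_wraps` (junction
#'   crossings of the codon span, stop codon included), `stop_found`,
#'   `junction_residue_index` (first residue whose codon contains or follows
#'   the junction; clamped to the last residue when only the stop codon
#'   crosses), and the default unique region `unique_start`/`unique_end`
#'   (`[junction_residue_index, aa_length]`; see [derive_unique_region()] for
#'   the parent-aware refinement).
#' @seealso [select_orf()], [derive_unique_region()]
#' @export
#' @examples
#' find_junction_orfs("TAAGCAATGGCA", min_aa = 2)
find_junction_orfs <- function(templates, min_aa = 101, max_wraps = 4,
                               include_rolling = TRUE) {
  if (min_aa < 1) {
    abort("`min_aa` must be >= 1", class = "circpept_domain_error")
  }
  if (is.data.frame(templates)) {
    seqs <- setNames(templates$mature_seq, templates$circ_id)
  } else {
    seqs <- templates
    if (is.null(names(seqs))) {
      names(seqs) <- if (length(seqs) == 1L) "circ" else
        paste0("circ_", seq_along(seqs))
    }
  }
  check_dna_alphabet(seqs, "circular template")
  out <- imap(seqs, function(s, id) {
    scan_circular_template(s, id, min_aa = min_aa, max_wraps = max_wraps)
  })
  res <- list_rbind(out)
  if (!include_rolling && nrow(res) > 0) res <- filter(res, stop_found)
  res
}

# Scan a single circular template. Returns the candidate tibble (possibly
# zero rows).
scan_circular_template <- function(seq, id, min_aa, max_wraps) {
  L <- nchar(seq)
  empty <- tibble(
    circ_id = character(), start_pos = integer(), frame = integer(),
    aa_length = integer(), protein_seq = character(), n_wraps = integer(),
    stop_found = logical(), junction_residue_index = integer(),
    unique_start = integer(), unique_end = integer()
  )
  if (L < 3L) return(empty)
  unrolled <- strrep(seq, max_wraps + 1L)
  max_nt <- (max_wraps + 1L) * L
  # Start codons anywhere on the circle (the ATG may itself cross the
  # junction), one start per circular position.
  m <- gregexpr("ATG", substr(unrolled, 1L, min(max_nt, L + 2L)),
                fixed = TRUE)[[1]]
  starts <- as.integer(m[m > 0L & m <= L])
  if (length(starts) == 0L) return(empty)

  rows <- map(starts, function(p) {
    codon_starts <- seq.int(p, max_nt - 2L, by = 3L)
    codons <- substring(unrolled, codon_starts, codon_starts + 2L)
    stop_idx <- which(codons %in% STOP_CODONS)[1L]
    if (!is.na(stop_idx)) {
      aa_len <- stop_idx - 1L
      end_nt <- p + 3L * stop_idx - 1L
      found <- TRUE
    } else {
      aa_len <- length(codons)
      end_nt <- p + 3L * aa_len - 1L
      found <- FALSE
    }
    wraps <- (end_nt - 1L) %/% L
    if (wraps < 1L || aa_len < min_aa) return(NULL)
    prot <- if (aa_len > 0L) {
      aa <- Biostrings::GENETIC_CODE[codons[seq_len(aa_len)]]
      aa[is.na(aa)] <- "X"
      paste(aa, collapse = "")
    } else ""
    jri <- max(1L, min(aa_len, as.integer(ceiling((L + 2L - p) / 3))))
    tibble(
      circ_id = id, start_pos = p, frame = (p - 1L) %% 3L,
      aa_length = aa_len, protein_seq = prot, n_wraps = as.integer(wraps),
      stop_found = found, junction_residue_index = jri,
      unique_start = jri, unique_end = aa_len
    )
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty)
  # De-duplicate rotation-equivalent reports (same circular start, same
  # protein); starts are already restricted to one circle so this is a guard.
  distinct(list_rbind(rows), start_pos, protein_seq, .keep_all = TRUE)
}

#' Select the reported ORF for one circular template
#'
#' Among stop-terminated junction-spanning candidates of a single template,
#' returns the one with the fewest amino acid residues ("least amino acid
#' residues" rule). Ties are broken by smallest `start_pos`, then by
#' lexicographically smallest `protein_seq`. Rolling candidates
#' (`stop_found = FALSE`) are never selected.
#'
#' @param candidates A tibble of candidates from [find_junction_orfs()], all
#'   from one template.
#' @return A one-row tibble, or a zero-row tibble when no stop-terminated
#'   candidate exists.
#' @export
select_orf <- function(candidates) {
  if (nrow(candidates) > 0 && length(unique(candidates$circ_id)) > 1L) {
    abort("`candidates` mixes several circ_ids; use select_orfs()",
          class = "circpept_domain_error")
  }
  eligible <- filter(candidates, stop_found)
  if (nrow(eligible) == 0L) return(eligible)
  head(arrange(eligible, aa_length, start_pos, protein_seq), 1L)
}

#' Select one ORF per circRNA
#'
#' Applies [select_orf()] within each `circ_id` group.
#'
#' @param candidates A tibble of candidates from [find_junction_orfs()].
#' @return A tibble with at most one row per `circ_id`.
#' @export
select_orfs <- function(candidates) {
  if (nrow(candidates) == 0L) return(filter(candidates, stop_found))
  candidates %>%
    group_by(circ_id) %>%
    group_split() %>%
    map(select_orf) %>%
    list_rbind()
}

#' Derive the circRNA-unique protein region
#'
#' The unique region is the portion of a circRNA-encoded protein that cannot
#' be attributed to the linear parent protein — typically the junction-crossing
#' C-terminal part. Without a parent, the region is
#' `[junction_residue_index, aa_length]`. With a parent, the region starts at
#' the last residue position whose C-terminal suffix is absent from the parent
#' as an exact substring (suffix absence is monotone, so this is the boundary
#' between parent-attributable and novel sequence), extended leftwards to
#' include the junction residue when that lies earlier. The region is always
#' non-empty for junction-spanning candidates.
#'
#' @param candidate A one-row tibble from [find_junction_orfs()] /
#'   [select_orf()] (needs `protein_seq` and `junction_residue_index`).
#' @param parent_protein Amino-acid sequence of the linear parent protein, or
#'   `NULL` when unknown.
#' @return The candidate row with `unique_start` and `unique_end` set.
#' @export
derive_unique_region <- function(candidate, parent_protein = NULL) {
  stopifnot(nrow(candidate) == 1L)
  prot <- candidate$protein_seq
  aa <- nchar(prot)
  jri <- candidate$junction_residue_index
  u <- jri
  if (!is.null(parent_protein) && !is.na(parent_protein) &&
      nzchar(parent_protein)) {
    absent <- vapply(seq_len(aa), function(k) {
      !grepl(substr(prot, k, aa), parent_protein, fixed = TRUE)
    }, logical(1))
    if (any(absent)) {
      u <- min(max(which(absent)), jri)
    }
  }
  candidate$unique_start <- as.integer(u)
  candidate$unique_end <- as.integer(aa)
  candidate
}

#' In-silico PCR on a circular template with divergent primers
#'
#' Locates the forward primer as an exact match on the circular sense strand
#' and the reverse primer's reverse complement downstream on the circle, and
#' returns the shortest product running from the forward primer's 5' end
#' around the circle to the reverse primer's 5' end. Products longer than the
#' circle are impossible and yield no result. `spans_junction` is `TRUE` when
#' the product crosses the back-splice joint (including a product covering the
#' full circle).
#'
#' @param template Circular sequence (character scalar).
#' @param fwd_primer,rev_primer Primer sequences, 5'->3', each >= 10 nt.
#' @return A one-row tibble (`product_length`, `spans_junction`, `fwd_start`,
#'   `rev_site_start`), or `NULL` when either primer has no exact site.
#'   Multiple primer sites raise an ambiguity error listing all products.
#' @export
in_silico_circular_pcr <- function(template, fwd_primer, rev_primer) {
  if (nchar(fwd_primer) < 10 || nchar(rev_primer) < 10) {
    abort("primers must be at least 10 nt", class = "circpept_domain_error")
  }
  check_dna_alphabet(c(template, fwd_primer, rev_primer), "PCR input")
  L <- nchar(template)
  doubled <- strrep(template, 2L)
  circular_sites <- function(pat) {
    hit <- gregexpr(pat, substr(doubled, 1L, min(2L * L, L + nchar(pat) - 1L)),
                    fixed = TRUE)[[1]]
    as.integer(hit[hit > 0L & hit <= L])
  }
  fsites <- circular_sites(fwd_primer)
  rsites <- circular_sites(revcomp(rev_primer))
  if (length(fsites) == 0L || length(rsites) == 0L) return(NULL)
  nf <- nchar(fwd_primer)
  nr <- nchar(rev_primer)
  prods <- list_rbind(map(fsites, function(f) {
    list_rbind(map(rsites, function(r) {
      r2 <- r
      while (r2 < f + nf) r2 <- r2 + L   # rev site must lie downstream
      e <- r2 + nr - 1L
      len <- e - f + 1L
      if (len > L) return(NULL)
      tibble(product_length = len,
             spans_junction = e > L || len == L,
             fwd_start = f, rev_site_start = r)
    }))
  }))
  if (is.null(prods) || nrow(prods) == 0L) return(NULL)
  if (nrow(prods) > 1L) {
    abort(paste0("ambiguous primer sites; products of length ",
                 paste(sort(prods$product_length), collapse = ", "), " nt"),
          class = "circpept_ambiguity_error")
  }
  prods
}

#' Design a junction-spanning divergent primer pair
#'
#' Picks primers from a circular template so that the in-silico product has a
#' requested length and crosses the back-splice junction — the design check
#' behind divergent qPCR primers, which amplify the circular isoform only.
#'
#' @param template Circular sequence.
#' @param product_length Desired product length in nt (`> 2 * primer_len`,
#'   `<=` circle length).
#' @param primer_len Primer length in nt.
#' @return A one-row tibble with `fwd_primer`, `rev_primer`,
#'   `expected_length`.
#' @export
design_divergent_primers <- function(template, product_length = 203,
                                     primer_len = 20) {
  L <- nchar(template)
  if (product_length > L || product_length < 2 * primer_len + 1) {
    abort("product_length must fit the circle and both primers",
          class = "circpept_domain_error")
  }
  doubled <- strrep(template, 2L)
  # Start the product in the second half so that it wraps across L -> 1.
  f <- L - (product_length %/% 2L) + 1L
  e <- f + product_length - 1L
  fwd <- substr(doubled, f, f + primer_len - 1L)
  rev <- revcomp(substr(doubled, e - primer_len + 1L, e))
  tibble(fwd_primer = fwd, rev_primer = rev,
         expected_length = as.integer(product_length))
}
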