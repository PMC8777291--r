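library(dplyr)
library(tibble)

# Independent oracles used to check the package's core algorithms. These are
# deliberately written with different mechanics than the implementation
# (per-base modular walking instead of string concatenation, pair-counting
# instead of rank sums, stats::p.adjust for BH).

# Junction-ORF oracle: walk the circle base by base from every circular ATG,
# translating codons with explicit modular arithmetic and junction
# bookkeeping.
oracle_junction_orfs <- function(seq, min_aa, max_wraps = 4,
                                 require_wrap = TRUE) {
  L <- nchar(seq)
  ch <- strsplit(seq, "")[[1]]
  codon_at <- function(pos) {
    paste(ch[((pos - 1 + 0:2) %% L) + 1], collapse = "")
  }
  stops <- c("TAA", "TAG", "TGA")
  max_nt <- (max_wraps + 1) * L
  res <- list()
  for (p in seq_len(L)) {
    if (codon_at(p) != "ATG") next
    k <- 0L
    found <- FALSE
    prot <- character()
    end_nt <- p - 1L
    repeat {
      cpos <- p + 3L * k
      if (cpos + 2L > max_nt) {
        end_nt <- p + 3L * k - 1L
        break
      }
      cod <- codon_at(cpos)
      if (cod %in% stops) {
        found <- TRUE
        end_nt <- cpos + 2L
        break
      }
      prot <- c(prot, unname(Biostrings::GENETIC_CODE[cod]))
      k <- k + 1L
    }
    wraps <- (end_nt - 1L) %/% L
    aa <- length(prot)
    if ((wraps >= 1 || !require_wrap) && aa >= min_aa) {
      res[[length(res) + 1]] <- tibble::tibble(
        start_pos = p, aa_length = aa,
        protein_seq = paste(prot, collapse = ""),
        n_wraps = as.integer(wraps), stop_found = found
      )
    }
  }
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0) {
    out <- tibble::tibble(start_pos = integer(), aa_length = integer(),
                          protein_seq = character(), n_wraps = integer(),
                          stop_found = logical())
  }
  dplyr::arrange(out, start_pos)
}

# Exact Mann-Whitney two-sided p by enumeration over value splits, with U
# computed by pair counting (not ranks).
oracle_mw_p <- function(a, b) {
  vals <- c(a, b)
  n1 <- length(a)
  n <- length(vals)
  ustat <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  u_obs <- ustat(a, b)
  mu <- n1 * length(b) / 2
  cols <- utils::combn(n, n1)
  us <- apply(cols, 2, function(ix) ustat(vals[ix], vals[-ix]))
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_protein <- function(n) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y"), n, replace = TRUE),
        collapse = "")
}

# A small hand-built annotation: one plus-strand gene with three exons
# (5'UTR in exon 1, 3'UTR in exon 3), one minus-strand gene, on chrT
# (length 10000).
toy_annotation <- function() {
  ann <- dplyr::bind_rows(
    # gene_plus: exons [101,400] [701,1100] [1401,1800]
    tibble::tibble(type = "gene", start = 101L, end = 1800L, strand = "+",
                   gene_id = "gene_plus"),
    tibble::tibble(type = "exon",
                   start = c(101L, 701L, 1401L), end = c(400L, 1100L, 1800L),
                   strand = "+", gene_id = "gene_plus"),
    tibble::tibble(type = "five_prime_UTR", start = 101L, end = 250L,
                   strand = "+", gene_id = "gene_plus"),
    tibble::tibble(type = "CDS",
                   start = c(251L, 701L, 1401L), end = c(400L, 1100L, 1600L),
                   strand = "+", gene_id = "gene_plus"),
    tibble::tibble(type = "three_prime_UTR", start = 1601L, end = 1800L,
                   strand = "+", gene_id = "gene_plus"),
    # gene_minus: exons [3001,3300] [3601,3900]; 3'UTR left, 5'UTR right
    tibble::tibble(type = "gene", start = 3001L, end = 3900L, strand = "-",
                   gene_id = "gene_minus"),
    tibble::tibble(type = "exon", start = c(3001L, 3601L),
                   end = c(3300L, 3900L), strand = "-",
                   gene_id = "gene_minus"),
    tibble::tibble(type = "three_prime_UTR", start = 3001L, end = 3120L,
                   strand = "-", gene_id = "gene_minus"),
    tibble::tibble(type = "CDS", start = c(3121L, 3601L),
                   end = c(3300L, 3780L), strand = "-",
                   gene_id = "gene_minus"),
    tibble::tibble(type = "five_prime_UTR", start = 3781L, end = 3900L,
                   strand = "-", gene_id = "gene_minus")
  )
  ann <- dplyr::mutate(ann, seqid = "chrT")
  ann <- dplyr::select(ann, seqid, type, start, end, strand, gene_id)
  attr(ann, "seqlengths") <- c(chrT = 10000L)
  ann
}

toy_calls <- function(chrom, start, end, strand = "+") {
  tibble::tibble(circ_id = paste0(chrom, ":", start, "|", end),
                 chrom = chrom, start = start, end = end, strand = strand)
}
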