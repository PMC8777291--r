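#' Simulation configuration for the two-group circRNA study design
#'
#' Bundles and validates every knob of the synthetic-data generator, which
#' emulates a Sham-vs-BOO (bladder outlet obstruction) two-group design:
#' 8 Sham and 7 BOO samples by default, negative-binomial back-splice junction
#' counts with planted fold changes, a fraction of circRNAs carrying a planted
#' junction-spanning ORF, and a proteomics layer in which a subset of the
#' ORF-bearing circRNAs shows a sign-consistent protein change plus detectable
#' unique-region peptides.
#'
#' @param n_chrom Number of chromosomes in the toy genome.
#' @param chrom_length Chromosome length in nucleotides.
#' @param n_genes Total number of genes (round-robin across chromosomes).
#' @param n_circ Number of circRNA back-splice events.
#' @param origin_mix Named proportions over origin classes (must sum to 1).
#'   `exon_other` cannot be placed under the simulator's gene model (every
#'   exon base is annotated CDS or UTR) and must stay 0.
#' @param coding_fraction Proportion of circRNAs given a planted
#'   junction-spanning ORF of more than 100 residues.
#' @param consistent_fraction Proportion of coding circRNAs whose protein
#'   change is planted sign-consistent with their circRNA change.
#' @param n_sham,n_boo Samples per group (each >= 2).
#' @param log2fc_planted Planted circRNA effect size (log2).
#' @param protein_log2fc Planted protein effect size (log2) for consistent
#'   candidates; its magnitude must exceed `log2(1.5)`.
#' @param nb_dispersion Negative-binomial dispersion of junction counts; 0
#'   means the Poisson limit.
#' @param protein_sigma Log-normal noise sd (log2 scale) of protein
#'   abundances.
#' @param background_de_fraction Fraction of non-coding circRNAs given a
#'   planted (sign-balanced) fold change, emulating the broad differential
#'   expression seen at the circRNA layer.
#' @param peptide_detect_prob Probability that each theoretical tryptic
#'   peptide of an expressed candidate appears in the observed peptide list.
#' @param decoy_factor Background (decoy) proteins per candidate protein.
#' @param noise_free Deterministic outputs: counts are rounded means and
#'   protein abundances exact group means. Used for exact end-to-end recovery
#'   checks.
#' @param min_aa Minimum planted ORF length in residues.
#' @param seed Master seed; every stage derives its own sub-seed from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_chrom = 4, chrom_length = 600000, n_genes = 80,
                       n_circ = 200,
                       origin_mix = c(CDS = 0.40, `5UTR` = 0.10,
                                      `3UTR` = 0.08, exon_other = 0,
                                      intron = 0.16, antisense = 0.10,
                                      intergenic = 0.16),
                       coding_fraction = 0.10, consistent_fraction = 0.60,
                       n_sham = 8, n_boo = 7,
                       log2fc_planted = 2, protein_log2fc = 1,
                       nb_dispersion = 0.1, protein_sigma = 0.2,
                       background_de_fraction = 0.30,
                       peptide_detect_prob = 0.5, decoy_factor = 5,
                       noise_free = FALSE, min_aa = 101, seed = 1) {
  cfg <- list(
    n_chrom = as.integer(n_chrom), chrom_length = as.integer(chrom_length),
    n_genes = as.integer(n_genes), n_circ = as.integer(n_circ),
    origin_mix = origin_mix, coding_fraction = coding_fraction,
    consistent_fraction = consistent_fraction,
    n_sham = as.integer(n_sham), n_boo = as.integer(n_boo),
    log2fc_planted = log2fc_planted, protein_log2fc = protein_log2fc,
    nb_dispersion = nb_dispersion, protein_sigma = protein_sigma,
    background_de_fraction = background_de_fraction,
    peptide_detect_prob = peptide_detect_prob,
    decoy_factor = decoy_factor, noise_free = isTRUE(noise_free),
    min_aa = as.integer(min_aa), seed = as.integer(seed)
  )
  props <- c(cfg$coding_fraction, cfg$consistent_fraction,
             cfg$background_de_fraction, cfg$peptide_detect_prob,
             cfg$origin_mix)
  if (any(props < 0 | props > 1)) {
    abort("all proportions must lie in [0, 1]",
          class = "circpept_config_error")
  }
  if (!isTRUE(all.equal(sum(cfg$origin_mix), 1))) {
    abort("origin_mix must sum to 1", class = "circpept_config_error")
  }
  if (!all(names(cfg$origin_mix) %in% ORIGIN_CLASSES)) {
    abort(paste0("origin_mix names must be among: ",
                 paste(ORIGIN_CLASSES, collapse = ", ")),
          class = "circpept_config_error")
  }
  if (cfg$n_sham < 2 || cfg$n_boo < 2) {
    abort("need at least two samples per group",
          class = "circpept_config_error")
  }
  if (cfg$n_chrom < 1 || cfg$chrom_length < 1000) {
    abort("genome too small", class = "circpept_config_error")
  }
  if (abs(cfg$protein_log2fc) <= log2(1.5) && cfg$consistent_fraction > 0) {
    abort("`protein_log2fc` must exceed log2(1.5) in magnitude for consistent candidates",
          class = "circpept_config_error")
  }
  structure(cfg, class = "sim_config")
}

# sample() without the scalar-x surprise.
safe_sample <- function(v, n = 1L) {
  if (length(v) == 1L) rep(v, n) else sample(v, n)
}

#' Generate the toy reference genome and annotation
#'
#' Emits `n_chrom` random chromosomes and `n_genes` non-overlapping genes.
#' Every gene has 2-4 exons separated by introns, a 5' UTR at the start of its
#' first exon, CDS through the middle, and a 3' UTR at the end of its last
#' exon (mirrored for minus-strand genes). Deterministic given the config
#' seed.
#'
#' @param config A [sim_config()].
#' @return A list with `genome` (named character vector) and `annotation`
#'   (tibble with `seqid`, `type`, `start`, `end`, `strand`, `gene_id`; the
#'   chromosome lengths are attached as attribute `seqlengths`).
#' @export
generate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(stage_seed(config$seed, 1L), {
    chroms <- paste0("chr", seq_len(config$n_chrom))
    genome <- setNames(
      vapply(chroms, function(x) random_dna(config$chrom_length),
             character(1)),
      chroms
    )
    cursors <- setNames(rep(1L, config$n_chrom), chroms)
    feats <- list()
    if (config$n_genes > 0) {
      for (i in seq_len(config$n_genes)) {
        chrom <- chroms[(i - 1L) %% config$n_chrom + 1L]
        gap <- safe_sample(1500:3000)
        gstart <- cursors[[chrom]] + gap
        strand <- if (i %% 2L == 0L) "-" else "+"
        g <- build_gene_model(gstart, strand,
                              gene_id = sprintf("gene_%03d", i),
                              seqid = chrom)
        gend <- max(g$end)
        if (gend > config$chrom_length - 100L) {
          abort("chrom_length too small to place n_genes",
                class = "circpept_sizing_error")
        }
        cursors[[chrom]] <- gend
        feats[[i]] <- g
      }
    }
    annotation <- if (length(feats) > 0) list_rbind(feats) else
      tibble(seqid = character(), type = character(), start = integer(),
             end = integer(), strand = character(), gene_id = character())
    attr(annotation, "seqlengths") <-
      setNames(rep(config$chrom_length, config$n_chrom), chroms)
    list(genome = genome, annotation = annotation)
  })
}

# One gene's feature rows. The genomic layout is built left to right; for
# minus-strand genes the UTR sides are mirrored (3' UTR genomically left).
build_gene_model <- function(gstart, strand, gene_id, seqid) {
  k <- safe_sample(2:4)
  utr5 <- safe_sample(400:600)
  utr3 <- safe_sample(400:600)
  cds_first <- safe_sample(200:400)
  cds_last <- safe_sample(200:400)
  cds_mid <- if (k > 2) safe_sample(250:550, k - 2L) else integer(0)
  introns <- safe_sample(450:900, k - 1L)
  left_utr <- if (strand == "+") utr5 else utr3
  right_utr <- if (strand == "+") utr3 else utr5
  exon_len <- c(left_utr + cds_first,
                cds_mid,
                cds_last + right_utr)
  ex_start <- integer(k)
  ex_end <- integer(k)
  pos <- gstart
  for (j in seq_len(k)) {
    ex_start[j] <- pos
    ex_end[j] <- pos + exon_len[j] - 1L
    pos <- ex_end[j] + (if (j < k) introns[j] else 0L) + 1L
  }
  gend <- ex_end[k]
  cds_start <- c(ex_start[1] + left_utr, if (k > 2) ex_start[2:(k - 1)])
  cds_end <- c(ex_end[1], if (k > 2) ex_end[2:(k - 1)])
  cds_start <- c(cds_start, ex_start[k])
  cds_end <- c(cds_end, ex_start[k] + cds_last - 1L)
  left_utr_type <- if (strand == "+") "five_prime_UTR" else "three_prime_UTR"
  right_utr_type <- if (strand == "+") "three_prime_UTR" else "five_prime_UTR"
  bind_rows(
    tibble(type = "gene", start = gstart, end = gend),
    tibble(type = "mRNA", start = gstart, end = gend),
    tibble(type = "exon", start = ex_start, end = ex_end),
    tibble(type = "CDS", start = cds_start, end = cds_end),
    tibble(type = left_utr_type, start = ex_start[1],
           end = ex_start[1] + left_utr - 1L),
    tibble(type = right_utr_type, start = ex_end[k] - right_utr + 1L,
           end = ex_end[k])
  ) %>%
    mutate(seqid = seqid, strand = strand, gene_id = gene_id) %>%
    select(seqid, type, start, end, strand, gene_id)
}
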