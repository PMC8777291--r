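#' Generate circRNA back-splice events with planted ORFs and ground truth
#'
#' Places `n_circ` back-splice events on the reference so that
#' [classify_origin()] reproduces the requested `origin_mix` class for each
#' event. For coding events the genome itself is edited within the back-splice
#' span so that the mature circular sequence contains exactly one
#' junction-spanning ORF of at least `min_aa` residues (and no other start
#' codon anywhere on the circle), which makes the planted protein recoverable
#' by running the unmodified downstream pipeline on the emitted genome. Event
#' spans are kept pairwise disjoint so edits cannot collide.
#'
#' The ground-truth table also fixes the planted expression effects: every
#' coding circRNA receives a (sign-balanced) circRNA fold change of
#' `log2fc_planted`; `consistent_fraction` of the coding circRNAs additionally
#' receive a protein fold change of the same sign (`protein_log2fc`); and
#' `background_de_fraction` of the non-coding circRNAs receive a sign-balanced
#' circRNA fold change, emulating broad differential expression.
#'
#' @param reference Output of [generate_reference()].
#' @param config The [sim_config()] used for the reference.
#' @return A list: `genome` (edited copy), `calls` (tibble `circ_id`, `chrom`,
#'   `start`, `end`, `strand`), `truth` (tibble `circ_id`, `is_coding`,
#'   `protein_seq`, `circ_log2fc`, `protein_log2fc`, `is_consistent`, plus the
#'   planted ORF geometry `orf_start_pos`, `junction_residue_index`,
#'   `unique_start`, `unique_end`), and `annotation` (passed through).
#' @export
generate_circ_events <- function(reference, config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(stage_seed(config$seed, 2L), {
    ann <- reference$annotation
    genome <- reference$genome
    n <- config$n_circ
    cnt <- largest_remainder(config$origin_mix, n)
    classes <- rep(names(cnt), cnt)
    if (any(classes == "exon_other")) {
      abort("exon_other events cannot be placed: every simulated exon base is annotated CDS or UTR",
            class = "circpept_placement_error")
    }
    genic <- c("CDS", "5UTR", "3UTR", "intron", "antisense")
    if (config$n_genes == 0 && any(classes %in% genic)) {
      abort("genic origin classes requested but the reference has no genes",
            class = "circpept_placement_error")
    }
    classes <- sample(classes)
    n_coding <- round(config$coding_fraction * n)
    coding_idx <- sort(safe_sample(seq_len(n), n_coding))
    genes <- arrange(filter(ann, type == "gene"), seqid, start)
    # Only planted (coding) spans must stay pairwise disjoint — and no event
    # may overlap a planted span — so genome edits cannot collide and every
    # planted circle keeps its guaranteed ORF. Non-coding events may overlap
    # each other freely, but ids must stay unique.
    used_coding <- list()
    used_ids <- character(0)
    events <- vector("list", n)
    for (i in seq_len(n)) {
      cls <- classes[i]
      coding <- i %in% coding_idx
      ev <- NULL
      for (try in seq_len(300L)) {
        cand <- try_place_event(cls, coding, ann, genes, config, used_coding)
        if (is.null(cand)) next
        id <- paste0(cand$chrom, ":", cand$start, "|", cand$end)
        if (id %in% used_ids) next
        ev <- cand
        break
      }
      if (is.null(ev)) {
        abort(paste0("could not place a ", cls,
                     " event after bounded retries"),
              class = "circpept_placement_error")
      }
      if (coding) {
        used_coding[[ev$chrom]] <- rbind(used_coding[[ev$chrom]],
                                         c(ev$start, ev$end))
      }
      used_ids <- c(used_ids, paste0(ev$chrom, ":", ev$start, "|", ev$end))
      events[[i]] <- ev
    }
    calls <- list_rbind(map(events, function(ev) {
      tibble(circ_id = paste0(ev$chrom, ":", ev$start, "|", ev$end),
             chrom = ev$chrom, start = ev$start, end = ev$end,
             strand = ev$strand)
    }))
    # Plant ORFs for coding events by editing the emitted genome copy.
    truth_rows <- vector("list", n)
    for (i in seq_len(n)) {
      ev <- events[[i]]
      id <- calls$circ_id[i]
      if (i %in% coding_idx) {
        iv <- circ_intervals(ev$chrom, ev$start, ev$end, ev$class,
                             ev$gene_id, ann)
        m <- sum(iv$end - iv$start + 1)
        pl <- plant_orf(m, config$min_aa)
        genome <- write_mature(genome, ev$chrom, iv, ev$strand, pl$seq)
        truth_rows[[i]] <- tibble(
          circ_id = id, is_coding = TRUE, protein_seq = pl$protein,
          orf_start_pos = pl$start_pos,
          junction_residue_index = pl$jri,
          unique_start = pl$jri, unique_end = pl$aa
        )
      } else {
        truth_rows[[i]] <- tibble(
          circ_id = id, is_coding = FALSE, protein_seq = "",
          orf_start_pos = NA_integer_, junction_residue_index = NA_integer_,
          unique_start = NA_integer_, unique_end = NA_integer_
        )
      }
    }
    truth <- list_rbind(truth_rows)
    # Planted expression effects.
    truth$circ_log2fc <- 0
    truth$protein_log2fc <- NA_real_
    truth$is_consistent <- FALSE
    if (n_coding > 0) {
      signs <- rep(c(1, -1), length.out = n_coding)
      truth$circ_log2fc[coding_idx] <- signs * config$log2fc_planted
      truth$protein_log2fc[coding_idx] <- 0
      n_cons <- round(config$consistent_fraction * n_coding)
      cons <- coding_idx[safe_sample(seq_len(n_coding), n_cons)]
      truth$is_consistent[cons] <- TRUE
      truth$protein_log2fc[cons] <-
        sign(truth$circ_log2fc[cons]) * abs(config$protein_log2fc)
    }
    noncoding_idx <- setdiff(seq_len(n), coding_idx)
    n_bg <- round(config$background_de_fraction * length(noncoding_idx))
    if (n_bg > 0) {
      bg <- safe_sample(noncoding_idx, n_bg)
      truth$circ_log2fc[bg] <- rep(c(1, -1), length.out = n_bg) *
        config$log2fc_planted
    }
    list(genome = genome, calls = calls, truth = truth, annotation = ann)
  })
}

largest_remainder <- function(mix, n) {
  target <- mix / sum(mix) * n
  cnt <- floor(target)
  rem <- n - sum(cnt)
  if (rem > 0) {
    o <- order(target - cnt, decreasing = TRUE)
    cnt[o[seq_len(rem)]] <- cnt[o[seq_len(rem)]] + 1
  }
  cnt
}

span_free <- function(used, chrom, s, e) {
  u <- used[[chrom]]
  if (is.null(u)) return(TRUE)
  !any(s <= u[, 2] & e >= u[, 1])
}

# One placement attempt; NULL on failure (caller retries).
try_place_event <- function(cls, coding, ann, genes, config, used) {
  win <- if (coding) c(380L, 800L) else c(120L, 800L)
  if (cls == "intergenic") {
    chrom <- safe_sample(paste0("chr", seq_len(config$n_chrom)))
    g <- filter(genes, seqid == chrom)
    gaps <- interval_gaps(g$start, g$end, 50L, config$chrom_length - 50L)
    gaps <- gaps[gaps$end - gaps$start + 1 >= win[1], , drop = FALSE]
    if (nrow(gaps) == 0) return(NULL)
    gp <- gaps[safe_sample(seq_len(nrow(gaps))), ]
    m <- safe_sample(win[1]:min(win[2], gp$end - gp$start + 1))
    s <- gp$start + safe_sample(0:(gp$end - gp$start + 1 - m))
    ev <- list(chrom = chrom, start = s, end = s + m - 1L,
               strand = safe_sample(c("+", "-")), gene_id = NA_character_,
               class = "intergenic")
  } else {
    if (nrow(genes) == 0) return(NULL)
    gr <- genes[safe_sample(seq_len(nrow(genes))), ]
    pos <- switch(cls,
      CDS = place_in_cds(gr, ann, win),
      `5UTR` = place_in_utr(gr, ann, "five_prime_UTR", win),
      `3UTR` = place_in_utr(gr, ann, "three_prime_UTR", win),
      intron = place_in_intron(gr, ann, win),
      antisense = place_antisense(gr, win)
    )
    if (is.null(pos)) return(NULL)
    strand <- if (cls == "antisense") setdiff(c("+", "-"), gr$strand) else
      gr$strand
    ev <- list(chrom = gr$seqid, start = pos[1], end = pos[2],
               strand = strand, gene_id = gr$gene_id, class = cls)
  }
  if (!span_free(used, ev$chrom, ev$start, ev$end)) return(NULL)
  ev
}

interval_gaps <- function(starts, ends, lo, hi) {
  if (length(starts) == 0) return(tibble(start = lo, end = hi))
  o <- order(starts)
  starts <- starts[o]
  ends <- ends[o]
  gs <- c(lo, ends + 51L)
  ge <- c(starts - 51L, hi)
  keep <- ge - gs + 1 > 0
  tibble(start = gs[keep], end = ge[keep])
}

# Both endpoints inside CDS; mature length (over exon intersections) lands in
# the window. Single-exon and two-exon spans are tried in random order.
place_in_cds <- function(gene_row, ann, win) {
  gf <- filter(ann, gene_id == gene_row$gene_id)
  ex <- arrange(filter(gf, type == "exon"), start)
  cds <- arrange(filter(gf, type == "CDS"), start)
  k <- nrow(ex)
  cds_of_exon <- map(seq_len(k), function(a) {
    filter(cds, start >= ex$start[a], end <= ex$end[a])
  })
  pairs <- expand.grid(a = seq_len(k), b = seq_len(k))
  pairs <- pairs[pairs$a <= pairs$b, , drop = FALSE]
  pairs <- pairs[sample(nrow(pairs)), , drop = FALSE]
  for (r in seq_len(nrow(pairs))) {
    a <- pairs$a[r]; b <- pairs$b[r]
    ca <- cds_of_exon[[a]]; cb <- cds_of_exon[[b]]
    if (nrow(ca) == 0 || nrow(cb) == 0) next
    if (a == b) {
      len <- ca$end[1] - ca$start[1] + 1
      lo <- win[1]; hi <- min(win[2], len)
      if (lo > hi) next
      m <- safe_sample(lo:hi)
      s <- ca$start[1] + safe_sample(0:(len - m))
      return(c(s, s + m - 1L))
    }
    mid <- if (b - a > 1) sum(ex$end[(a + 1):(b - 1)] - ex$start[(a + 1):(b - 1)] + 1) else 0L
    len_a <- ex$end[a] - ca$start[1] + 1        # CDS runs to the exon end
    len_b <- cb$end[nrow(cb)] - ex$start[b] + 1 # CDS starts at the exon start
    lo <- max(win[1], mid + 2L)
    hi <- min(win[2], mid + len_a + len_b)
    if (lo > hi) next
    m <- safe_sample(lo:hi)
    r1 <- safe_sample(max(1L, m - mid - len_b):min(len_a, m - mid - 1L))
    s <- ex$end[a] - r1 + 1L
    e <- ex$start[b] + (m - mid - r1) - 1L
    return(c(s, e))
  }
  NULL
}

place_in_utr <- function(gene_row, ann, utr_type, win) {
  u <- filter(ann, gene_id == gene_row$gene_id, type == utr_type)
  if (nrow(u) == 0) return(NULL)
  len <- u$end[1] - u$start[1] + 1
  lo <- win[1]; hi <- min(win[2], len)
  if (lo > hi) return(NULL)
  m <- safe_sample(lo:hi)
  s <- u$start[1] + safe_sample(0:(len - m))
  c(s, s + m - 1L)
}

place_in_intron <- function(gene_row, ann, win) {
  ex <- arrange(filter(ann, gene_id == gene_row$gene_id, type == "exon"),
                start)
  if (nrow(ex) < 2) return(NULL)
  ints <- tibble(start = ex$end[-nrow(ex)] + 1L, end = ex$start[-1] - 1L)
  ints <- ints[sample(nrow(ints)), , drop = FALSE]
  for (r in seq_len(nrow(ints))) {
    len <- ints$end[r] - ints$start[r] + 1
    lo <- win[1]; hi <- min(win[2], len)
    if (lo > hi) next
    m <- safe_sample(lo:hi)
    s <- ints$start[r] + safe_sample(0:(len - m))
    return(c(s, s + m - 1L))
  }
  NULL
}

place_antisense <- function(gene_row, win) {
  len <- gene_row$end - gene_row$start + 1
  lo <- win[1]; hi <- min(win[2], len)
  if (lo > hi) return(NULL)
  m <- safe_sample(lo:hi)
  s <- gene_row$start + safe_sample(0:(len - m))
  c(s, s + m - 1L)
}

# Build a circular sequence of length m whose ONLY start codon initiates a
# junction-spanning ORF of P residues ending at an in-frame TAA. Strategy:
# write the ORF codons across the junction, then replace the G of every other
# ATG trigram on the circle with C — a substitution that can neither create a
# new ATG nor a stop codon, so the planted ORF is provably unique.
plant_orf <- function(m, min_aa) {
  p_max <- min(140L, (m - 6L) %/% 3L - 1L)
  if (p_max < min_aa) {
    abort("mature sequence too short for the requested ORF",
          class = "circpept_sizing_error")
  }
  p_len <- safe_sample(min_aa:p_max)
  pre <- safe_sample(3:30)                    # codons before the junction
  start <- m - 3L * pre + 1L
  bases <- strsplit(random_dna(m), "")[[1]]
  pool <- setdiff(names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"],
                  "ATG")
  codons <- c("ATG", sample(pool, p_len - 1L, replace = TRUE), "TAA")
  body <- seq_len(p_len - 1L)
  codons[1L + body[body %% 20L == 0L]] <- "AAA"  # lysine anchors for trypsin
  for (k in seq_along(codons)) {
    idx <- ((start - 1L + (k - 1L) * 3L + 0:2) %% m) + 1L
    bases[idx] <- strsplit(codons[k], "")[[1]]
  }
  for (p in seq_len(m)) {
    if (p == start) next
    idx <- ((p - 1L + 0:2) %% m) + 1L
    if (bases[idx[1]] == "A" && bases[idx[2]] == "T" && bases[idx[3]] == "G") {
      bases[idx[3]] <- "C"
    }
  }
  codseq <- vapply(seq_len(p_len), function(k) {
    idx <- ((start - 1L + (k - 1L) * 3L + 0:2) %% m) + 1L
    paste(bases[idx], collapse = "")
  }, character(1))
  list(seq = paste(bases, collapse = ""),
       protein = paste(Biostrings::GENETIC_CODE[codseq], collapse = ""),
       start_pos = start, jri = pre + 1L, aa = p_len)
}

# Write a mature circular sequence back into the genome through its genomic
# sub-intervals (reverse-complemented for minus-strand events).
write_mature <- function(genome, chrom, iv, strand, mature) {
  full <- if (!is.na(strand) && strand == "-") revcomp(mature) else mature
  stopifnot(sum(iv$end - iv$start + 1) == nchar(full))
  cs <- genome[[chrom]]
  off <- 0L
  for (j in seq_len(nrow(iv))) {
    w <- iv$end[j] - iv$start[j] + 1L
    substr(cs, iv$start[j], iv$end[j]) <- substr(full, off + 1L, off + w)
    off <- off + w
  }
  genome[[chrom]] <- cs
  genome
}
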