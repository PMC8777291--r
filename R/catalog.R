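ORIGIN_CLASSES <- c("CDS", "5UTR", "3UTR", "exon_other", "intron",
                    "antisense", "intergenic")

#' Parse circRNA identifiers of the form "chrom:start|end"
#'
#' Coordinates are 1-based inclusive, matching the GFF3 convention used
#' throughout the package.
#'
#' @param x Character vector of ids such as `"chr14:44496991|44498906"`.
#' @return A tibble with `circ_id`, `chrom`, `start`, `end`.
#' @export
#' @examples
#' parse_circ_id("chr14:44496991|44498906")
parse_circ_id <- function(x) {
  m <- stringr::str_match(x, "^(.+):([0-9]+)\\|([0-9]+)$")
  if (any(is.na(m[, 1]))) {
    abort(paste0("malformed circRNA id: ",
                 paste(x[is.na(m[, 1])], collapse = ", ")),
          class = "circpept_parse_error")
  }
  start <- as.numeric(m[, 3])
  end <- as.numeric(m[, 4])
  if (any(start > end)) {
    abort("circRNA id has start > end", class = "circpept_coordinate_error")
  }
  tibble(circ_id = x, chrom = m[, 2], start = start, end = end)
}

known_chroms <- function(annotation) {
  union(names(attr(annotation, "seqlengths") %||% character()),
        unique(annotation$seqid))
}

# Feature type at a genomic point within one gene: CDS > 5UTR > 3UTR > other.
site_type <- function(feats, pos) {
  at <- feats$type[feats$start <= pos & feats$end >= pos]
  if ("CDS" %in% at) "CDS"
  else if ("five_prime_UTR" %in% at) "5UTR"
  else if ("three_prime_UTR" %in% at) "3UTR"
  else "other"
}

classify_one <- function(chrom, s, e, st, annotation) {
  feats <- filter(annotation, seqid == chrom)
  genes <- filter(feats, type == "gene", start <= e, end >= s)
  strand_known <- !is.na(st) && st %in% c("+", "-")
  genes <- arrange(genes, gene_id)
  same <- if (strand_known) filter(genes, strand == st) else genes
  # 1. Both back-splice sites inside exons of one same-strand gene.
  for (gid in same$gene_id) {
    gf <- filter(feats, gene_id == gid, type != "gene")
    ex <- filter(gf, type == "exon")
    s_in <- any(ex$start <= s & ex$end >= s)
    e_in <- any(ex$start <= e & ex$end >= e)
    if (s_in && e_in) {
      types <- c(site_type(gf, s), site_type(gf, e))
      cls <- if ("CDS" %in% types) "CDS"
             else if ("5UTR" %in% types) "5UTR"
             else if ("3UTR" %in% types) "3UTR"
             else "exon_other"
      return(list(class = cls, gene_id = gid))
    }
  }
  # 2. Fully inside a same-strand gene without the exon rule -> intron class.
  inside <- filter(same, start <= s, end >= e)
  if (nrow(inside) > 0) {
    return(list(class = "intron", gene_id = inside$gene_id[1]))
  }
  # 3. Overlapping a gene only on the opposite strand -> antisense.
  if (strand_known && nrow(same) == 0 && nrow(genes) > 0) {
    return(list(class = "antisense", gene_id = genes$gene_id[1]))
  }
  list(class = "intergenic", gene_id = NA_character_)
}

#' Classify the genomic origin of circRNA events
#'
#' Assigns each back-splice event exactly one origin class by a fixed
#' precedence: if both back-splice sites fall inside exons of a same-strand
#' gene, the class is the highest-precedence feature type found at the two
#' sites (CDS > 5'UTR > 3'UTR, plain exon otherwise); else a record fully
#' inside a same-strand gene is intronic; else a record overlapping a gene
#' only on the opposite strand is antisense; everything else is intergenic.
#' Records with unknown strand are classified against genes of either strand.
#'
#' @param calls A data frame with `circ_id`, `chrom`, `start`, `end`,
#'   `strand` (`+`, `-`, or `NA`/`.` for unknown).
#' @param annotation Annotation tibble (see [read_annotation()]) with columns
#'   `seqid`, `type`, `start`, `end`, `strand`, `gene_id`.
#' @return `calls` with `origin_class` (factor over the seven classes) and
#'   `gene_id` columns added.
#' @export
classify_origin <- function(calls, annotation) {
  kc <- known_chroms(annotation)
  missing_chrom <- setdiff(unique(calls$chrom), kc)
  if (length(missing_chrom) > 0) {
    abort(paste0("chromosome(s) absent from annotation: ",
                 paste(missing_chrom, collapse = ", ")),
          class = "circpept_lookup_error")
  }
  res <- pmap(list(calls$chrom, calls$start, calls$end,
                   as.character(calls$strand)),
              function(c, s, e, st) classify_one(c, s, e, st, annotation))
  calls$origin_class <- factor(map_chr(res, "class"), levels = ORIGIN_CLASSES)
  calls$gene_id <- map_chr(res, "gene_id")
  calls
}

# Genomic sub-intervals whose concatenation gives the mature sequence of one
# event (genomic order). Exonic classes splice on the classifying gene's
# exons; all other classes use the raw span.
circ_intervals <- function(chrom, s, e, origin_class, gene_id, annotation) {
  if (origin_class %in% c("CDS", "5UTR", "3UTR", "exon_other")) {
    ex <- filter(annotation, seqid == chrom, gene_id == !!gene_id,
                 type == "exon", start <= e, end >= s)
    if (nrow(ex) == 0) {
      abort("exonic circRNA overlaps no exon of its gene",
            class = "circpept_internal_error")
    }
    tibble(start = pmax(ex$start, s), end = pmin(ex$end, e)) %>%
      distinct() %>%
      arrange(start, end)
  } else {
    tibble(start = s, end = e)
  }
}

#' Extract mature circular sequences
#'
#' For exonic origin classes the mature sequence is the concatenation of the
#' annotated exonic segments inside the back-splice span in transcript order
#' (reverse-complemented for minus-strand events); other classes use the raw
#' genomic span. Position 1 of the result is the back-splice acceptor side,
#' so it abuts the last position across the junction. Unknown strand is
#' treated as plus.
#'
#' @param calls Classified calls from [classify_origin()].
#' @param genome Named character vector of chromosome sequences (or a
#'   `Biostrings::DNAStringSet`).
#' @param annotation Annotation tibble.
#' @return `calls` with `mature_seq` and `mature_length` columns added.
#' @export
extract_circ_sequence <- function(calls, genome, annotation) {
  genome <- as_genome_vector(genome)
  seqs <- map_chr(seq_len(nrow(calls)), function(i) {
    iv <- circ_intervals(calls$chrom[i], calls$start[i], calls$end[i],
                         as.character(calls$origin_class[i]),
                         calls$gene_id[i], annotation)
    chrom_seq <- genome[[calls$chrom[i]]]
    s <- paste(substring(chrom_seq, iv$start, iv$end), collapse = "")
    st <- as.character(calls$strand[i])
    if (!is.na(st) && st == "-") revcomp(s) else s
  })
  calls$mature_seq <- seqs
  calls$mature_length <- nchar(seqs)
  calls
}

#' Build a circRNA catalog
#'
#' Convenience wrapper: [classify_origin()] followed by
#' [extract_circ_sequence()].
#'
#' @inheritParams classify_origin
#' @inheritParams extract_circ_sequence
#' @return A tibble of class `circ_catalog`.
#' @export
build_catalog <- function(calls, genome, annotation) {
  out <- calls %>%
    classify_origin(annotation) %>%
    extract_circ_sequence(genome, annotation)
  class(out) <- c("circ_catalog", class(out))
  out
}

#' Summarize a circRNA catalog
#'
#' Produces the three standard catalog summaries: a histogram of mature
#' sequence lengths (100-nt bins by default, last bin open-ended above
#' 3000 nt), counts per origin class, and — when differential-expression
#' results are supplied — per-chromosome counts of significantly up- and
#' down-regulated events.
#'
#' @param catalog A `circ_catalog` (needs `mature_length`, `origin_class`,
#'   `chrom`, `circ_id`).
#' @param de Optional [de_test()] result keyed by `feature_id` = `circ_id`.
#' @param bin_width Histogram bin width in nt.
#' @param open_end Lengths above this go into the open-ended last bin.
#' @return A list of class `circ_catalog_summary` with tibbles
#'   `length_histogram`, `origin_counts`, `chrom_updown`.
#' @export
summarize_catalog <- function(catalog, de = NULL, bin_width = 100,
                              open_end = 3000) {
  breaks <- c(seq(0, open_end, by = bin_width), Inf)
  nb <- length(breaks) - 1L
  labels <- c(sprintf("[%d,%d)", breaks[seq_len(nb - 1L)],
                      breaks[seq_len(nb - 1L) + 1L]),
              sprintf(">%d", open_end))
  bins <- cut(catalog$mature_length, breaks = breaks, labels = labels,
              right = FALSE, include.lowest = TRUE)
  length_histogram <- as_tibble(table(bin = bins), .name_repair = "minimal")
  names(length_histogram) <- c("bin", "count")
  origin_counts <- as_tibble(table(origin_class = catalog$origin_class))
  names(origin_counts) <- c("origin_class", "count")
  if (!is.null(de) && nrow(de) > 0) {
    sig <- de %>%
      filter(significant) %>%
      select(feature_id, direction) %>%
      left_join(select(as_tibble(catalog), circ_id, chrom),
                by = c(feature_id = "circ_id"))
    chrom_updown <- sig %>%
      dplyr::count(chrom, direction) %>%
      tidyr::pivot_wider(names_from = direction, values_from = n,
                         values_fill = 0L)
    for (col in c("up", "down")) {
      if (!col %in% names(chrom_updown)) chrom_updown[[col]] <- 0L
    }
    chrom_updown <- select(chrom_updown, chrom, up, down) %>% arrange(chrom)
  } else {
    chrom_updown <- tibble(chrom = character(), up = integer(),
                           down = integer())
  }
  structure(list(length_histogram = length_histogram,
                 origin_counts = origin_counts,
                 chrom_updown = chrom_updown),
            class = "circ_catalog_summary")
}

as_genome_vector <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    setNames(as.character(genome), names(genome))
  } else {
    genome
  }
}
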