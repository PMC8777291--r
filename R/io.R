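#' Read a genome FASTA
#'
#' @param path FASTA file.
#' @return Named character vector of chromosome sequences.
#' @export
read_genome <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write a genome FASTA
#'
#' @param genome Named character vector (or `DNAStringSet`).
#' @param path Output file.
#' @export
write_genome <- function(genome, path) {
  x <- Biostrings::DNAStringSet(as_genome_vector(genome))
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Read a GFF3 annotation
#'
#' Imports gene/mRNA/exon/CDS/five_prime_UTR/three_prime_UTR features
#' (1-based inclusive coordinates) into the flat annotation tibble used
#' throughout the package. Each feature must carry a `gene_id` attribute (the
#' writer emits one).
#'
#' @param path GFF3 file.
#' @return Annotation tibble (`seqid`, `type`, `start`, `end`, `strand`,
#'   `gene_id`) with chromosome lengths in attribute `seqlengths` when the
#'   file declares `##sequence-region` pragmas.
#' @export
read_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  ann <- tibble(
    seqid = as.character(GenomicRanges::seqnames(gr)),
    type = as.character(gr$type),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    gene_id = if (!is.null(gr$gene_id)) as.character(gr$gene_id)
              else NA_character_
  )
  sl <- GenomeInfoDb::seqlengths(gr)
  if (any(!is.na(sl))) {
    attr(ann, "seqlengths") <- sl[!is.na(sl)]
  }
  ann
}

#' Write the annotation tibble as GFF3
#'
#' @param annotation Annotation tibble.
#' @param path Output file.
#' @export
write_annotation <- function(annotation, path) {
  sl <- attr(annotation, "seqlengths")
  if (nrow(annotation) == 0) {
    lines <- "##gff-version 3"
    if (!is.null(sl)) {
      lines <- c(lines, sprintf("##sequence-region %s 1 %d", names(sl), sl))
    }
    writeLines(lines, path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = annotation$seqid,
    ranges = IRanges::IRanges(annotation$start, annotation$end),
    strand = annotation$strand,
    type = annotation$type,
    gene_id = annotation$gene_id,
    # toy CDS features are written in frame; phase is always 0
    phase = ifelse(annotation$type == "CDS", 0L, NA_integer_)
  )
  if (!is.null(sl)) {
    GenomeInfoDb::seqlevels(gr) <- names(sl)
    GenomeInfoDb::seqlengths(gr) <- sl
  }
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a circRNA call table
#'
#' Accepts two dialects: the package's own layout (`circ_id`, `chrom`,
#' `start`, `end`, `strand`, then one column of junction counts per sample)
#' and a CIRI v2-style layout (`circRNA_ID`, `chr`, `circRNA_start`,
#' `circRNA_end`, `junction_reads`, `strand`; extra columns ignored).
#'
#' @param path TSV file.
#' @return Calls tibble in the package layout.
#' @export
read_circ_calls <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if ("circRNA_ID" %in% names(x)) {
    out <- tibble(
      circ_id = x$circRNA_ID,
      chrom = x$chr,
      start = as.numeric(x$circRNA_start),
      end = as.numeric(x$circRNA_end),
      strand = if ("strand" %in% names(x)) x$strand else NA_character_
    )
    if ("junction_reads" %in% names(x)) {
      out$junction_reads <- x$junction_reads
    }
    return(out)
  }
  need <- c("circ_id", "chrom", "start", "end", "strand")
  if (!all(need %in% names(x))) {
    abort(paste0("call table must contain columns: ",
                 paste(need, collapse = ", ")),
          class = "circpept_parse_error")
  }
  x
}

#' Write a simulated study to plain-text files
#'
#' Emits `genome.fa`, `annotation.gff3`, `circ_calls.tsv` (ids, coordinates,
#' strand, per-sample junction counts), `protein_abundance.tsv`,
#' `peptides.tsv` (one peptide per row, source withheld), `protein_map.tsv`
#' and `truth.json`. Byte-stable given an identical study.
#'
#' @param study A `boo_study` from [simulate_boo_study()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_genome(study$genome, file.path(dir, "genome.fa"))
  write_annotation(study$annotation, file.path(dir, "annotation.gff3"))
  readr::write_tsv(study$calls, file.path(dir, "circ_calls.tsv"))
  readr::write_tsv(study$abundance, file.path(dir, "protein_abundance.tsv"))
  readr::write_tsv(study$peptides, file.path(dir, "peptides.tsv"))
  readr::write_tsv(study$protein_map, file.path(dir, "protein_map.tsv"))
  jsonlite::write_json(study$truth, file.path(dir, "truth.json"),
                       digits = NA, na = "null")
  invisible(dir)
}

#' Read a simulated study back from disk
#'
#' @param dir Directory written by [write_simulation()].
#' @return A list with `genome`, `annotation`, `calls`, `abundance`,
#'   `peptides`, `protein_map`, `truth`.
#' @export
read_simulation <- function(dir) {
  truth <- as_tibble(jsonlite::read_json(file.path(dir, "truth.json"),
                                         simplifyVector = TRUE))
  list(
    genome = read_genome(file.path(dir, "genome.fa")),
    annotation = read_annotation(file.path(dir, "annotation.gff3")),
    calls = read_circ_calls(file.path(dir, "circ_calls.tsv")),
    abundance = readr::read_tsv(file.path(dir, "protein_abundance.tsv"),
                                show_col_types = FALSE, progress = FALSE),
    peptides = readr::read_tsv(file.path(dir, "peptides.tsv"),
                               show_col_types = FALSE, progress = FALSE),
    protein_map = readr::read_tsv(file.path(dir, "protein_map.tsv"),
                                  show_col_types = FALSE, progress = FALSE),
    truth = truth
  )
}
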