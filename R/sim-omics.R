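#' Simulate the junction-read count matrix
#'
#' Draws per-sample back-splice junction read counts for every circRNA in the
#' truth table. Baseline means are log-uniform on `[10, 5000]`; features with
#' a planted fold change have their BOO-group mean scaled by
#' `2^circ_log2fc`. Counts are negative-binomial with dispersion
#' `nb_dispersion` (Poisson in the `nb_dispersion = 0` limit; exact rounded
#' means when `noise_free`).
#'
#' @param truth Truth table from [generate_circ_events()].
#' @param config The [sim_config()].
#' @return A tibble: `circ_id` plus one integer column per sample
#'   (`Sham_1..n_sham`, `BOO_1..n_boo`).
#' @export
simulate_counts <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(stage_seed(config$seed, 3L), {
    n <- nrow(truth)
    mu <- exp(runif(n, log(10), log(5000)))
    mu_boo <- mu * 2^truth$circ_log2fc
    draw <- function(m, ns) {
      if (config$noise_free) {
        matrix(round(m), nrow = n, ncol = ns)
      } else if (config$nb_dispersion <= 0) {
        matrix(rpois(n * ns, rep(m, ns)), nrow = n)
      } else {
        matrix(rnbinom(n * ns, mu = rep(m, ns),
                       size = 1 / config$nb_dispersion), nrow = n)
      }
    }
    sham <- draw(mu, config$n_sham)
    boo <- draw(mu_boo, config$n_boo)
    out <- cbind(sham, boo)
    colnames(out) <- c(paste0("Sham_", seq_len(config$n_sham)),
                       paste0("BOO_", seq_len(config$n_boo)))
    dplyr::bind_cols(tibble(circ_id = truth$circ_id),
                     as_tibble(as.data.frame(out)))
  })
}

AA_ALPHABET20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                   "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Simulate the proteomics layer: abundances and observed peptides
#'
#' Builds a relative protein-abundance table for every planted candidate
#' protein plus `decoy_factor` times as many background (decoy) proteins whose
#' tryptic peptides are disjoint from all candidates. Consistent candidates
#' carry a planted protein fold change of the same sign as their circRNA
#' change; all abundances get log-normal noise (`protein_sigma` on the log2
#' scale; exact means when `noise_free`). The observed peptide list is the
#' union of the theoretical tryptic peptides ([tryptic_digest()] defaults) of
#' every candidate and decoy, each retained with probability
#' `peptide_detect_prob`; every consistent candidate is guaranteed at least
#' one retained peptide overlapping its unique region (a semi-tryptic
#' unique-region peptide is added in the rare case where no fully tryptic
#' peptide overlaps it).
#'
#' @param truth Truth table from [generate_circ_events()].
#' @param config The [sim_config()].
#' @return A list: `abundance` (tibble `protein_id` + sample columns),
#'   `peptides` (tibble with a single `peptide` column, sorted, deduplicated),
#'   `protein_map` (tibble `circ_id`, `protein_id`), `decoy_proteins`
#'   (tibble `protein_id`, `protein_seq`).
#' @export
simulate_proteomics <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  cand <- filter(truth, is_coding)
  if (nrow(cand) == 0 && config$consistent_fraction > 0) {
    abort("need at least one coding circRNA when consistent_fraction > 0",
          class = "circpept_domain_error")
  }
  withr::with_seed(stage_seed(config$seed, 4L), {
    nc <- nrow(cand)
    protein_map <- tibble(
      circ_id = cand$circ_id,
      protein_id = sprintf("CIRCPROT_%03d", seq_len(max(nc, 0)))
    )
    # Decoy background proteins, peptide-disjoint from every candidate.
    nd <- config$decoy_factor * nc
    decoys <- character(0)
    if (nd > 0) {
      decoys <- vapply(seq_len(nd), function(i) {
        for (try in 1:20) {
          s <- paste(sample(AA_ALPHABET20, safe_sample(150:400),
                            replace = TRUE), collapse = "")
          peps <- tryptic_digest(s)$peptide
          hit <- any(vapply(peps, function(p) {
            any(stringr::str_detect(cand$protein_seq, stringr::fixed(p)))
          }, logical(1)))
          if (!hit) return(s)
        }
        abort("could not build a peptide-disjoint decoy",
              class = "circpept_internal_error")
      }, character(1))
    }
    prot_ids <- c(protein_map$protein_id,
                  sprintf("DECOY_%03d", seq_len(nd)))
    prot_lfc <- c(ifelse(is.na(cand$protein_log2fc), 0,
                         cand$protein_log2fc),
                  rep(0, nd))
    np <- length(prot_ids)
    base <- exp(runif(np, log(50), log(2000)))
    mean_boo <- base * 2^prot_lfc
    noise <- function(m, ns) {
      if (config$noise_free || config$protein_sigma <= 0) {
        matrix(m, nrow = np, ncol = ns)
      } else {
        matrix(m * 2^rnorm(np * ns, 0, config$protein_sigma), nrow = np)
      }
    }
    ab <- cbind(noise(base, config$n_sham), noise(mean_boo, config$n_boo))
    colnames(ab) <- c(paste0("Sham_", seq_len(config$n_sham)),
                      paste0("BOO_", seq_len(config$n_boo)))
    abundance <- dplyr::bind_cols(tibble(protein_id = prot_ids),
                                  as_tibble(as.data.frame(ab)))
    # Observed peptide list.
    observed <- character(0)
    for (i in seq_len(nc)) {
      dig <- tryptic_digest(cand$protein_seq[i])
      keep <- runif(nrow(dig)) < config$peptide_detect_prob
      if (cand$is_consistent[i]) {
        ov <- pmax(0L, pmin(dig$end_res, cand$unique_end[i]) -
                     pmax(dig$start_res, cand$unique_start[i]) + 1L)
        uniq_ok <- ov >= 5L
        if (!any(keep & uniq_ok)) {
          if (any(uniq_ok)) {
            keep[which(uniq_ok)[1]] <- TRUE
          } else {
            semi <- substr(cand$protein_seq[i], cand$unique_start[i],
                           min(cand$unique_start[i] + 11L,
                               cand$unique_end[i]))
            observed <- c(observed, semi)
          }
        }
      }
      observed <- c(observed, dig$peptide[keep])
    }
    for (i in seq_along(decoys)) {
      dig <- tryptic_digest(decoys[i])
      keep <- runif(nrow(dig)) < config$peptide_detect_prob
      observed <- c(observed, dig$peptide[keep])
    }
    peptides <- tibble(peptide = sort(unique(observed)))
    list(abundance = abundance, peptides = peptides,
         protein_map = protein_map,
         decoy_proteins = tibble(
           protein_id = sprintf("DECOY_%03d", seq_len(nd)),
           protein_seq = decoys))
  })
}

#' Run the full synthetic study generator
#'
#' Chains [generate_reference()], [generate_circ_events()],
#' [simulate_counts()] and [simulate_proteomics()] into one self-contained
#' study object. Identical configs (including the seed) give byte-identical
#' results.
#'
#' @param config A [sim_config()].
#' @return A list of class `boo_study`: `config`, `genome`, `annotation`,
#'   `calls` (with per-sample junction counts appended), `counts`, `truth`,
#'   `abundance`, `peptides`, `protein_map`, `decoy_proteins`.
#' @export
simulate_boo_study <- function(config = sim_config()) {
  ref <- generate_reference(config)
  ev <- generate_circ_events(ref, config)
  counts <- simulate_counts(ev$truth, config)
  prot <- simulate_proteomics(ev$truth, config)
  calls <- left_join(ev$calls, counts, by = "circ_id")
  structure(list(
    config = config, genome = ev$genome, annotation = ref$annotation,
    calls = calls, counts = counts, truth = ev$truth,
    abundance = prot$abundance, peptides = prot$peptides,
    protein_map = prot$protein_map, decoy_proteins = prot$decoy_proteins
  ), class = "boo_study")
}

#' @export
print.boo_study <- function(x, ...) {
  cat("Synthetic two-group circRNA study\n")
  cat(sprintf("  %d circRNAs (%d coding, %d consistent), %d + %d samples\n",
              nrow(x$truth), sum(x$truth$is_coding),
              sum(x$truth$is_consistent),
              x$config$n_sham, x$config$n_boo))
  cat(sprintf("  genome: %d chromosome(s) x %d nt; %d proteins in abundance table\n",
              x$config$n_chrom, x$config$chrom_length, nrow(x$abundance)))
  invisible(x)
}
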