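TIER_LEVELS <- c("peptide-validated", "expression-consistent", "predicted")

#' Combine circRNA DE, protein DE, ORF selection and peptide evidence
#'
#' Emits one row per circRNA with a selected junction-spanning ORF and assigns
#' a tier: `predicted` (ORF only), `expression-consistent` (circRNA
#' significant at FC>2 & p<0.05, mapped protein significant at FC>1.5 &
#' p<0.05, and both changes in the same direction), or `peptide-validated`
#' (expression-consistent and at least one unique-region peptide observed).
#' A circRNA whose id is missing from a DE table or from the protein map is
#' reported as `predicted` with a missing-layer annotation rather than
#' raising an error.
#'
#' @param de_circ [de_test()] result for the circRNA layer (`feature_id` =
#'   `circ_id`).
#' @param de_protein [de_test()] result for the protein layer (`feature_id` =
#'   `protein_id`).
#' @param orf_selection Selected ORFs from [select_orfs()].
#' @param verdicts Per-candidate verdicts from [evaluate_validation()].
#' @param protein_map Two-column tibble `circ_id`, `protein_id` linking the
#'   layers.
#' @return A tibble of class `circ_candidates`: `circ_id`, `circ_log2fc`,
#'   `circ_p`, `protein_id`, `protein_log2fc`, `protein_p`,
#'   `direction_consistent`, `validated_by_peptides`, `tier`,
#'   `missing_layer`, plus the ORF geometry columns.
#' @export
cross_omics_candidates <- function(de_circ, de_protein, orf_selection,
                                   verdicts, protein_map) {
  orf <- select(orf_selection, circ_id, start_pos, aa_length, protein_seq,
                junction_residue_index, unique_start, unique_end)
  dc <- tibble(circ_id = de_circ$feature_id,
               circ_log2fc = de_circ$log2fc, circ_p = de_circ$p_value,
               circ_significant = de_circ$significant)
  dp <- tibble(protein_id = de_protein$feature_id,
               protein_log2fc = de_protein$log2fc,
               protein_p = de_protein$p_value,
               protein_significant = de_protein$significant)
  v <- select(verdicts, circ_id, validated)
  out <- orf %>%
    left_join(dc, by = "circ_id") %>%
    left_join(protein_map, by = "circ_id") %>%
    left_join(dp, by = "protein_id") %>%
    left_join(v, by = "circ_id")
  out <- out %>%
    mutate(
      missing_layer = case_when(
        is.na(circ_p) & is.na(protein_p) ~ "circRNA+protein",
        is.na(circ_p) ~ "circRNA",
        is.na(protein_p) ~ "protein",
        TRUE ~ "none"
      ),
      direction_consistent = !is.na(circ_p) & !is.na(protein_p) &
        sign(circ_log2fc) == sign(protein_log2fc) & circ_log2fc != 0,
      expression_consistent = direction_consistent &
        isTRUE_vec(circ_significant) & isTRUE_vec(protein_significant),
      validated_by_peptides = isTRUE_vec(validated),
      tier = factor(case_when(
        expression_consistent & validated_by_peptides ~ "peptide-validated",
        expression_consistent ~ "expression-consistent",
        TRUE ~ "predicted"
      ), levels = TIER_LEVELS)
    ) %>%
    select(circ_id, circ_log2fc, circ_p, protein_id, protein_log2fc,
           protein_p, direction_consistent, validated_by_peptides, tier,
           missing_layer, start_pos, aa_length, protein_seq,
           junction_residue_index, unique_start, unique_end)
  class(out) <- c("circ_candidates", class(out))
  out
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Write the integrated report bundle
#'
#' Emits `candidates.tsv` (rows sorted by tier, then decreasing
#' `|circ_log2fc|`) and `summary.json` (counts per tier, DE counts per
#' direction per layer, and the catalog summaries). Byte-identical output for
#' identical inputs.
#'
#' @param candidates [cross_omics_candidates()] result.
#' @param catalog_summary [summarize_catalog()] result.
#' @param de_circ,de_protein The two [de_test()] tables.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(candidates, catalog_summary, de_circ, de_protein,
                         dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ordered <- arrange(candidates, tier, desc(abs(circ_log2fc)), circ_id)
  readr::write_tsv(ordered, file.path(dir, "candidates.tsv"))
  de_counts <- function(de) {
    list(up = sum(de$direction == "up"),
         down = sum(de$direction == "down"),
         significant = sum(de$significant),
         tested = nrow(de))
  }
  summary <- list(
    candidates = list(
      total = nrow(candidates),
      per_tier = as.list(table(candidates$tier))
    ),
    de = list(circRNA = de_counts(de_circ), protein = de_counts(de_protein)),
    catalog = list(
      origin_counts = catalog_summary$origin_counts,
      length_histogram = catalog_summary$length_histogram,
      chrom_updown = catalog_summary$chrom_updown
    )
  )
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Run the full discovery pipeline on a study
#'
#' Chains catalog construction, TPM normalization, circRNA and protein
#' differential expression, junction-spanning ORF prediction and selection,
#' peptide matching and validation, and cross-omics integration — the same
#' stages a real analysis would run on CIRI calls plus an iTRAQ abundance
#' table.
#'
#' @param study A `boo_study` (or the list from [read_simulation()]).
#' @param fc_circ,fc_protein Fold-change thresholds per layer.
#' @param alpha Significance level on raw p-values.
#' @param test Test for [de_test()] (`"welch"` or `"mannwhitney"`).
#' @param min_aa,max_wraps ORF rules (see [find_junction_orfs()]).
#' @param min_overlap Unique-region evidence rule (see [match_peptides()]).
#' @return A list of class `boo_pipeline`: `catalog`, `tpm`, `de_circ`,
#'   `de_protein`, `orfs`, `selected_orfs`, `matches`, `verdicts`,
#'   `candidates`, `catalog_summary`.
#' @export
run_boo_pipeline <- function(study, fc_circ = 2, fc_protein = 1.5,
                             alpha = 0.05, test = "welch",
                             min_aa = 101, max_wraps = 4, min_overlap = 5) {
  catalog <- build_catalog(
    select(study$calls, circ_id, chrom, start, end, strand),
    study$genome, study$annotation
  )
  count_cols <- setdiff(names(study$calls),
                        c("circ_id", "chrom", "start", "end", "strand"))
  counts <- select(study$calls, circ_id, all_of(count_cols))
  tpm <- compute_tpm(counts, setNames(catalog$mature_length, catalog$circ_id))
  de_circ <- de_test(tpm, fc_threshold = fc_circ, alpha = alpha, test = test,
                     layer = "circRNA")
  de_protein <- de_test(study$abundance, fc_threshold = fc_protein,
                        alpha = alpha, test = test, layer = "protein")
  orfs <- find_junction_orfs(select(catalog, circ_id, mature_seq),
                             min_aa = min_aa, max_wraps = max_wraps)
  selected <- select_orfs(orfs)
  matches <- match_peptides(study$peptides, selected,
                            min_overlap = min_overlap)
  verdicts <- evaluate_validation(matches, selected)
  candidates <- cross_omics_candidates(de_circ, de_protein, selected,
                                       verdicts, study$protein_map)
  catalog_summary <- summarize_catalog(catalog, de_circ)
  structure(list(
    catalog = catalog, tpm = tpm, de_circ = de_circ,
    de_protein = de_protein, orfs = orfs, selected_orfs = selected,
    matches = matches, verdicts = verdicts, candidates = candidates,
    catalog_summary = catalog_summary
  ), class = "boo_pipeline")
}

#' @export
print.boo_pipeline <- function(x, ...) {
  cat("circRNA-encoded protein discovery pipeline\n")
  cat(sprintf("  %d circRNAs; %d DE (%d up / %d down)\n",
              nrow(x$catalog), sum(x$de_circ$significant),
              sum(x$de_circ$direction == "up"),
              sum(x$de_circ$direction == "down")))
  cat(sprintf("  %d proteins; %d DE (%d up / %d down)\n",
              nrow(x$de_protein), sum(x$de_protein$significant),
              sum(x$de_protein$direction == "up"),
              sum(x$de_protein$direction == "down")))
  tiers <- table(x$candidates$tier)
  cat(sprintf("  ORF-bearing circRNAs: %d (%s)\n", nrow(x$candidates),
              paste(names(tiers), tiers, sep = ": ", collapse = ", ")))
  invisible(x)
}
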