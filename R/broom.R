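# broom-style accessors for the package's result objects.

#' Tidy a differential-expression result
#'
#' @param x A `circ_de` tibble.
#' @param ... Ignored.
#' @return A plain tibble (one row per feature).
#' @export
tidy.circ_de <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "circ_de")
  out
}

#' One-row summary of a differential-expression result
#'
#' @param x A `circ_de` tibble.
#' @param ... Ignored.
#' @return A one-row tibble: layer, thresholds, feature counts per direction.
#' @export
glance.circ_de <- function(x, ...) {
  tibble(
    layer = attr(x, "layer") %||% "unspecified",
    fc_threshold = attr(x, "fc_threshold"),
    alpha = attr(x, "alpha"),
    test = attr(x, "test"),
    n_features = nrow(x),
    n_significant = sum(x$significant),
    n_up = sum(x$direction == "up"),
    n_down = sum(x$direction == "down")
  )
}

#' Tidy a catalog summary into one long tibble
#'
#' @param x A `circ_catalog_summary`.
#' @param ... Ignored.
#' @return A tibble with columns `summary`, `key`, `count` (the chromosome
#'   table contributes one row per chromosome and direction).
#' @export
tidy.circ_catalog_summary <- function(x, ...) {
  bind_rows(
    mutate(rename(x$length_histogram, key = bin), summary = "length",
           key = as.character(key)),
    mutate(rename(x$origin_counts, key = origin_class), summary = "origin",
           key = as.character(key)),
    x$chrom_updown %>%
      tidyr::pivot_longer(c(up, down), names_to = "direction",
                          values_to = "count") %>%
      mutate(summary = "chrom", key = paste(chrom, direction, sep = ":")) %>%
      select(key, count, summary)
  ) %>%
    select(summary, key, count)
}

#' One-row summary of a full pipeline run
#'
#' @param x A `boo_pipeline` from [run_boo_pipeline()].
#' @param ... Ignored.
#' @return A one-row tibble with the headline counts of every stage.
#' @export
glance.boo_pipeline <- function(x, ...) {
  tiers <- table(x$candidates$tier)
  tibble(
    n_circ = nrow(x$catalog),
    n_circ_de = sum(x$de_circ$significant),
    n_circ_up = sum(x$de_circ$direction == "up"),
    n_circ_down = sum(x$de_circ$direction == "down"),
    n_protein = nrow(x$de_protein),
    n_protein_de = sum(x$de_protein$significant),
    n_protein_up = sum(x$de_protein$direction == "up"),
    n_protein_down = sum(x$de_protein$direction == "down"),
    n_orf_candidates = nrow(x$candidates),
    n_expression_consistent =
      sum(x$candidates$tier != "predicted"),
    n_peptide_validated = as.integer(tiers[["peptide-validated"]])
  )
}
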