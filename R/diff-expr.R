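#' Benjamini-Hochberg step-up q-values
#'
#' Standard step-up adjustment: with p-values sorted increasingly,
#' `q_(i) = min_{j >= i} p_(j) * m / j`, clipped to 1 and returned in the
#' input order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    abort("p-values must lie in [0, 1]", class = "circpept_domain_error")
  }
  m <- length(p_values)
  o <- order(p_values, decreasing = TRUE)
  q <- numeric(m)
  q[o] <- pmin(1, cummin(p_values[o] * m / (m:1)))
  q
}

#' Mann-Whitney U test (exact for small samples)
#'
#' Two-sided Mann-Whitney U comparison of two groups. When the combined size
#' is at most `exact_max` (default 16, covering a 7-vs-8 design), the null
#' distribution of U is obtained by full enumeration of all group assignments
#' of the observed ranks (ties handled through midranks), and the two-sided
#' p-value is `P(|U - mu| >= |U_obs - mu|)` with `mu = n1 * n2 / 2`. Larger
#' samples use the normal approximation with tie correction (no continuity
#' correction).
#'
#' @param group_a,group_b Numeric vectors, each non-empty.
#' @param exact_max Largest combined sample size for exact enumeration.
#' @return A one-row tibble: `U` (statistic for `group_a`), `p_value`,
#'   `exact` (logical).
#' @export
mann_whitney <- function(group_a, group_b, exact_max = 16L) {
  n1 <- length(group_a)
  n2 <- length(group_b)
  if (n1 == 0L || n2 == 0L) {
    abort("both groups must be non-empty", class = "circpept_domain_error")
  }
  r <- rank(c(group_a, group_b))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  n <- n1 + n2
  if (n <= exact_max) {
    picks <- combn(n, n1)
    w <- colSums(matrix(r[picks], nrow = n1))
    u_all <- w - n1 * (n1 + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
    exact <- TRUE
  } else {
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u_obs - mu) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    exact <- FALSE
  }
  tibble(U = u_obs, p_value = p, exact = exact)
}

#' Transcripts-per-million normalization
#'
#' Per sample, each feature's count is divided by its length in kilobases to
#' give a rate, and rates are rescaled to sum to one million.
#'
#' @param counts A data frame whose first column identifies features and whose
#'   remaining columns are per-sample non-negative counts.
#' @param feature_lengths Feature lengths in nucleotides: a numeric vector
#'   named by feature id, or a two-column data frame (id, length).
#' @return A tibble of the same shape with TPM values; every sample column
#'   sums to 1e6.
#' @export
compute_tpm <- function(counts, feature_lengths) {
  id_col <- names(counts)[1]
  ids <- counts[[1]]
  if (is.data.frame(feature_lengths)) {
    feature_lengths <- setNames(feature_lengths[[2]], feature_lengths[[1]])
  }
  len <- feature_lengths[ids]
  if (any(is.na(len)) || any(len <= 0)) {
    abort("every feature needs a positive length",
          class = "circpept_domain_error")
  }
  mat <- as.matrix(counts[-1])
  if (any(mat < 0)) {
    abort("counts must be non-negative", class = "circpept_domain_error")
  }
  rate <- mat / (len / 1000)
  tot <- colSums(rate)
  if (any(tot == 0)) {
    abort("a sample column is all zero; TPM undefined",
          class = "circpept_normalization_error")
  }
  tpm <- sweep(rate, 2, tot, "/") * 1e6
  out <- as_tibble(as.data.frame(tpm))
  out <- tibble(!!id_col := ids) %>% dplyr::bind_cols(out)
  out
}

#' Infer Sham/BOO group labels from sample names
#'
#' @param sample_ids Character vector of sample names such as `Sham_1`,
#'   `BOO_3`.
#' @return A tibble with `sample_id` and `group` (factor Sham/BOO).
#' @export
sample_groups <- function(sample_ids) {
  grp <- dplyr::case_when(
    stringr::str_detect(sample_ids, stringr::regex("^sham", ignore_case = TRUE)) ~ "Sham",
    stringr::str_detect(sample_ids, stringr::regex("^boo", ignore_case = TRUE)) ~ "BOO",
    TRUE ~ NA_character_
  )
  if (any(is.na(grp))) {
    abort("sample names must start with 'Sham' or 'BOO' (or supply groups explicitly)",
          class = "circpept_domain_error")
  }
  tibble(sample_id = sample_ids, group = factor(grp, levels = c("Sham", "BOO")))
}

#' Two-group differential expression with fold-change and p-value thresholds
#'
#' Per feature: group means on the input scale, `log2fc = log2((mean_BOO +
#' pseudocount) / (mean_Sham + pseudocount))`, a p-value from the configured
#' test on `log2(x + pseudocount)` (Welch's t by default, Mann-Whitney as an
#' alternative), Benjamini-Hochberg q-values, and a significance call that
#' requires the linear fold change to STRICTLY exceed `fc_threshold` in either
#' direction together with `p < alpha`. The circRNA layer uses
#' `fc_threshold = 2`, the protein layer `1.5`.
#'
#' @param mat A data frame, first column feature ids, remaining columns
#'   per-sample values (counts, TPM, or abundances; non-negative).
#' @param groups A tibble (`sample_id`, `group`) with levels Sham/BOO, or
#'   `NULL` to infer from sample names via [sample_groups()]. At least two
#'   samples per group are required.
#' @param fc_threshold Linear fold-change threshold, strict inequality.
#' @param alpha Significance level on the raw p-value.
#' @param test `"welch"` or `"mannwhitney"`.
#' @param pseudocount Added before ratios and logs.
#' @param layer Optional label ("circRNA" or "protein") stored as an
#'   attribute.
#' @return A tibble of class `circ_de`: `feature_id`, `mean_sham`, `mean_boo`,
#'   `log2fc`, `p_value`, `q_value`, `direction` (up/down/none), `significant`.
#' @export
de_test <- function(mat, groups = NULL, fc_threshold = 2, alpha = 0.05,
                    test = c("welch", "mannwhitney"), pseudocount = 1,
                    layer = NULL) {
  test <- match.arg(test)
  sample_ids <- names(mat)[-1]
  if (is.null(groups)) groups <- sample_groups(sample_ids)
  grp <- setNames(as.character(groups$group), groups$sample_id)[sample_ids]
  if (any(is.na(grp))) {
    abort("every sample column needs a group label",
          class = "circpept_domain_error")
  }
  sham_cols <- which(grp == "Sham") + 1L
  boo_cols <- which(grp == "BOO") + 1L
  if (length(sham_cols) < 2L || length(boo_cols) < 2L) {
    abort("need at least two samples per group",
          class = "circpept_domain_error")
  }
  x <- as.matrix(mat[, sham_cols, drop = FALSE])
  y <- as.matrix(mat[, boo_cols, drop = FALSE])
  if (any(x < 0) || any(y < 0)) {
    abort("expression values must be non-negative",
          class = "circpept_domain_error")
  }
  mean_sham <- rowMeans(x)
  mean_boo <- rowMeans(y)
  ratio <- (mean_boo + pseudocount) / (mean_sham + pseudocount)
  lfc <- log2(ratio)
  lx <- log2(x + pseudocount)
  ly <- log2(y + pseudocount)
  p <- vapply(seq_len(nrow(mat)), function(i) {
    a <- lx[i, ]
    b <- ly[i, ]
    if (test == "welch") {
      # Degenerate (constant) data make the t statistic undefined: call the
      # feature null when the group means agree and extreme otherwise.
      pv <- tryCatch(t.test(a, b)$p.value, error = function(e) NaN)
      if (!is.finite(pv)) {
        pv <- if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
      }
      pv
    } else {
      mann_whitney(a, b)$p_value
    }
  }, numeric(1))
  q <- bh_fdr(p)
  passes_fc <- ratio > fc_threshold | ratio < 1 / fc_threshold
  sig <- passes_fc & p < alpha
  out <- tibble(
    feature_id = mat[[1]],
    mean_sham = mean_sham, mean_boo = mean_boo,
    log2fc = lfc, p_value = p, q_value = q,
    direction = dplyr::if_else(sig, dplyr::if_else(lfc > 0, "up", "down"),
                               "none"),
    significant = sig
  )
  class(out) <- c("circ_de", class(out))
  attr(out, "fc_threshold") <- fc_threshold
  attr(out, "alpha") <- alpha
  attr(out, "test") <- test
  attr(out, "layer") <- layer %||% "unspecified"
  out
}
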