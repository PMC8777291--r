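test_that("BH step-up matches hand-derived examples and dominates p", {
  expect_equal(bh_fdr(0.05), 0.05)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(21)
  for (i in 1:50) {
    p <- runif(sample(1:100, 1))
    q <- bh_fdr(p)
    expect_true(all(q >= p - 1e-12))
    expect_true(all(q <= 1))
    expect_equal(q, stats::p.adjust(p, method = "BH"))
  }
  expect_error(bh_fdr(c(0.5, 1.2)), class = "circpept_domain_error")
})

test_that("exact Mann-Whitney matches full enumeration", {
  res <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)
  expect_equal(res$p_value, 0.1)
  expect_true(res$exact)
  # identical multisets -> p = 1
  expect_equal(mann_whitney(c(1, 2, 5), c(1, 2, 5))$p_value, 1)
  set.seed(22)
  for (sizes in list(c(2, 2), c(3, 3), c(3, 5), c(4, 4), c(5, 6), c(7, 8))) {
    a <- sample(1:6, sizes[1], replace = TRUE)  # ties likely
    b <- sample(1:6, sizes[2], replace = TRUE)
    expect_equal(mann_whitney(a, b)$p_value, oracle_mw_p(a, b))
  }
  expect_error(mann_whitney(numeric(0), 1:3),
               class = "circpept_domain_error")
})

test_that("large-sample Mann-Whitney matches the tie-corrected normal approximation", {
  set.seed(23)
  a <- sample(1:10, 20, replace = TRUE)
  b <- sample(2:11, 15, replace = TRUE)
  res <- mann_whitney(a, b)
  expect_false(res$exact)
  ref <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                             correct = FALSE))
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("TPM normalization is exact on forced examples", {
  m <- tibble(id = c("a", "b"), s1 = c(10, 10))
  # equal counts, equal lengths -> 500k each
  eq <- compute_tpm(m, c(a = 500, b = 500))
  expect_equal(eq$s1, c(5e5, 5e5))
  # single feature -> 1e6 regardless of count
  one <- compute_tpm(tibble(id = "a", s1 = 7, s2 = 9000), c(a = 123))
  expect_equal(unlist(one[1, -1], use.names = FALSE), c(1e6, 1e6))
  # 2:1 rate ratio
  two <- compute_tpm(m, c(a = 1000, b = 2000))
  expect_equal(two$s1, c(2e6 / 3, 1e6 / 3), tolerance = 1e-9)
  # all-zero sample is undefined
  expect_error(compute_tpm(tibble(id = c("a", "b"), s1 = c(0, 0)),
                           c(a = 100, b = 100)),
               class = "circpept_normalization_error")
})

test_that("TPM columns always sum to one million", {
  set.seed(24)
  for (i in 1:20) {
    nf <- sample(2:50, 1)
    ns <- sample(2:10, 1)
    counts <- as_tibble(matrix(rpois(nf * ns, 50) + 1, nrow = nf),
                        .name_repair = ~ paste0("s", seq_len(ns)))
    counts <- bind_cols(tibble(id = paste0("f", seq_len(nf))), counts)
    lens <- setNames(sample(100:3000, nf), counts$id)
    tpm <- compute_tpm(counts, lens)
    expect_equal(unname(colSums(as.matrix(tpm[-1]))), rep(1e6, ns),
                 tolerance = 1e-6)
  }
})

test_that("de_test applies strict fold-change and p thresholds", {
  grp <- sample_groups(c(paste0("Sham_", 1:3), paste0("BOO_", 1:3)))
  # identical groups: null result
  m <- tibble(id = "f1", Sham_1 = 5, Sham_2 = 6, Sham_3 = 7,
              BOO_1 = 5, BOO_2 = 6, BOO_3 = 7)
  r <- de_test(m, grp)
  expect_equal(r$log2fc, 0)
  expect_false(r$significant)
  # group means exactly 2x apart are never significant under strict ">2"
  m2 <- tibble(id = "f1", Sham_1 = 100, Sham_2 = 100, Sham_3 = 100,
               BOO_1 = 200, BOO_2 = 200, BOO_3 = 200)
  r2 <- de_test(m2, grp, fc_threshold = 2, pseudocount = 0)
  expect_equal(2^r2$log2fc, 2)
  expect_false(r2$significant)
  # constant-zero feature: p = 1, direction none
  m3 <- tibble(id = "f1", Sham_1 = 0, Sham_2 = 0, Sham_3 = 0,
               BOO_1 = 0, BOO_2 = 0, BOO_3 = 0)
  r3 <- de_test(m3, grp)
  expect_equal(r3$p_value, 1)
  expect_equal(r3$direction, "none")
  # q-values dominate p-values
  set.seed(25)
  m4 <- as_tibble(matrix(rpois(50 * 6, 40), nrow = 50),
                  .name_repair = ~ c(paste0("Sham_", 1:3), paste0("BOO_", 1:3)))
  m4 <- bind_cols(tibble(id = paste0("f", 1:50)), m4)
  r4 <- de_test(m4, grp)
  expect_true(all(r4$q_value >= r4$p_value - 1e-12))
  # no feature with mean ratio within the threshold is ever flagged
  ratio <- (r4$mean_boo + 1) / (r4$mean_sham + 1)
  inside <- ratio <= 2 & ratio >= 0.5
  expect_false(any(r4$significant[inside]))
})

test_that("planted effects are recovered with high power and controlled errors", {
  set.seed(26)
  grp <- sample_groups(c(paste0("Sham_", 1:8), paste0("BOO_", 1:7)))
  hits <- nulls <- c()
  for (s in 1:3) {
    planted <- c(rep(TRUE, 20), rep(FALSE, 180))
    mu <- rep(1000, 200)
    mat <- cbind(
      matrix(rpois(200 * 8, mu), nrow = 200),
      matrix(rpois(200 * 7, mu * ifelse(planted, 4, 1)), nrow = 200)
    )
    tb <- bind_cols(tibble(id = paste0("f", 1:200)),
                    as_tibble(as.data.frame(mat),
                              .name_repair = ~ grp$sample_id))
    de <- de_test(tb, grp, fc_threshold = 2)
    hits <- c(hits, sum(de$significant[planted]))
    nulls <- c(nulls, mean(de$significant[!planted]))
  }
  expect_true(all(hits >= 18))
  expect_true(all(nulls <= 0.05))
})

test_that("the Mann-Whitney option plugs into de_test", {
  grp <- sample_groups(c(paste0("Sham_", 1:4), paste0("BOO_", 1:4)))
  m <- tibble(id = "f1",
              Sham_1 = 1, Sham_2 = 2, Sham_3 = 3, Sham_4 = 4,
              BOO_1 = 101, BOO_2 = 102, BOO_3 = 103, BOO_4 = 104)
  r <- de_test(m, grp, test = "mannwhitney")
  expect_equal(r$p_value, oracle_mw_p(log2(1:4 + 1), log2(101:104 + 1)))
  expect_true(r$significant)
})
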