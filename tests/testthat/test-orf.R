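test_that("the worked micro-template yields exactly one junction-crossing ORF", {
  res <- find_junction_orfs("TAAGCAATGGCA", min_aa = 2)
  expect_equal(nrow(res), 1L)
  expect_equal(res$start_pos, 7L)
  expect_equal(res$protein_seq, "MA")
  expect_equal(res$aa_length, 2L)
  expect_equal(res$n_wraps, 1L)
  expect_true(res$stop_found)
})

test_that("ORFs that do not cross the junction are rejected at any length", {
  # ATG..stop entirely inside positions 1..L: never reported.
  res <- find_junction_orfs("ATGGCATAACCC", min_aa = 1)
  expect_equal(nrow(filter(res, stop_found)), 0L)
  # The oracle without the junction requirement does see it.
  orc <- oracle_junction_orfs("ATGGCATAACCC", min_aa = 1, require_wrap = FALSE)
  expect_equal(nrow(orc), 1L)
  expect_equal(orc$protein_seq, "MA")
})

test_that("the >100-residue rule is a strict boundary", {
  set.seed(7)
  # Planted circles with ORFs of exactly 100 and exactly 101 residues.
  p100 <- circpept:::plant_orf(309, min_aa = 100)
  expect_equal(p100$aa, 100L)
  expect_equal(nrow(find_junction_orfs(p100$seq, min_aa = 101)), 0L)
  expect_equal(nrow(find_junction_orfs(p100$seq, min_aa = 100)), 1L)
  p101 <- circpept:::plant_orf(312, min_aa = 101)
  expect_equal(p101$aa, 101L)
  res <- find_junction_orfs(p101$seq, min_aa = 101)
  expect_equal(nrow(res), 1L)
  expect_equal(res$protein_seq, p101$protein)
  expect_equal(res$aa_length, 101L)
})

test_that("find_junction_orfs matches the modular-walking oracle on random circles", {
  set.seed(11)
  for (i in 1:60) {
    L <- sample(30:300, 1)
    s <- random_dna_str(L)
    imp <- find_junction_orfs(s, min_aa = 10) %>%
      select(start_pos, aa_length, protein_seq, n_wraps, stop_found) %>%
      arrange(start_pos)
    orc <- oracle_junction_orfs(s, min_aa = 10)
    expect_equal(as.data.frame(imp), as.data.frame(orc))
  }
})

test_that("dropping the junction requirement can only enlarge the candidate set", {
  set.seed(12)
  larger <- 0L
  for (i in 1:30) {
    s <- random_dna_str(sample(60:300, 1))
    with_j <- oracle_junction_orfs(s, min_aa = 5, require_wrap = TRUE)
    without <- oracle_junction_orfs(s, min_aa = 5, require_wrap = FALSE)
    expect_gte(nrow(without), nrow(with_j))
    larger <- larger + (nrow(without) > nrow(with_j))
  }
  expect_gt(larger, 0L)  # the filter actually removes something sometimes
})

test_that("reported proteins start with M and contain no internal stop", {
  set.seed(13)
  for (i in 1:20) {
    res <- find_junction_orfs(random_dna_str(sample(60:300, 1)), min_aa = 5)
    res <- filter(res, stop_found)
    if (nrow(res) > 0) {
      expect_true(all(substr(res$protein_seq, 1, 1) == "M"))
      expect_false(any(grepl("*", res$protein_seq, fixed = TRUE)))
      expect_true(all(res$n_wraps >= 1))
      expect_true(all(res$junction_residue_index >= 1 &
                        res$junction_residue_index <= res$aa_length))
    }
  }
})

test_that("select_orf applies the least-residue rule with documented tie-breaks", {
  cand <- tibble(
    circ_id = "c1", start_pos = c(5L, 40L, 11L), frame = 0L,
    aa_length = c(150L, 120L, 200L),
    protein_seq = c("X", "Y", "Z"), n_wraps = 1L, stop_found = TRUE,
    junction_residue_index = 1L, unique_start = 1L,
    unique_end = c(150L, 120L, 200L)
  )
  expect_equal(select_orf(cand)$aa_length, 120L)
  # tie on length -> smallest start_pos
  tie <- mutate(cand, aa_length = 120L)
  expect_equal(select_orf(tie)$start_pos, 5L)
  # single candidate -> itself
  expect_equal(select_orf(cand[2, ]), cand[2, ])
  # rolling candidates are never selected
  expect_equal(nrow(select_orf(mutate(cand, stop_found = FALSE))), 0L)
  # mixed templates are a usage error
  expect_error(select_orf(mutate(cand, circ_id = c("a", "b", "b"))),
               class = "circpept_domain_error")
  # selection is minimal among stop-found candidates
  set.seed(14)
  for (i in 1:10) {
    res <- find_junction_orfs(random_dna_str(250), min_aa = 3)
    sel <- select_orf(res)
    if (nrow(sel) == 1) {
      expect_equal(sel$aa_length, min(filter(res, stop_found)$aa_length))
    }
  }
})

test_that("unique region defaults to the junction-to-C-terminus span", {
  cand <- tibble(circ_id = "c", start_pos = 1L, frame = 0L, aa_length = 10L,
                 protein_seq = "MKLVRSAWYD", n_wraps = 1L, stop_found = TRUE,
                 junction_residue_index = 3L, unique_start = 3L,
                 unique_end = 10L)
  out <- derive_unique_region(cand, NULL)
  expect_equal(c(out$unique_start, out$unique_end), c(3L, 10L))
})

test_that("unique region against a parent protein starts at the suffix boundary", {
  cand <- tibble(circ_id = "c", start_pos = 1L, frame = 0L, aa_length = 7L,
                 protein_seq = "MKLVRSA", n_wraps = 1L, stop_found = TRUE,
                 junction_residue_index = 6L, unique_start = 6L,
                 unique_end = 7L)
  # Parent contains "MKLV", "SA" and "A" but not "RSA": the shortest absent
  # suffix is "RSA" (position 5); the junction residue (6) lies inside it.
  out <- derive_unique_region(cand, "GGMKLVGGSAGG")
  expect_equal(c(out$unique_start, out$unique_end), c(5L, 7L))
  # junction residue earlier than the suffix boundary extends the region
  cand2 <- mutate(cand, junction_residue_index = 2L)
  out2 <- derive_unique_region(cand2, "GGMKLVGGSAGG")
  expect_equal(out2$unique_start, 2L)
  # protein fully contained in the parent -> fallback [jri, aa]
  out3 <- derive_unique_region(cand, paste0("XX", "MKLVRSA", "YY"))
  expect_equal(c(out3$unique_start, out3$unique_end), c(6L, 7L))
})

test_that("unique-region start satisfies the suffix-absence boundary property", {
  set.seed(15)
  for (i in 1:40) {
    prot <- random_protein(sample(8:30, 1))
    parent <- random_protein(sample(20:80, 1))
    jri <- sample(seq_len(nchar(prot)), 1)
    cand <- tibble(circ_id = "c", start_pos = 1L, frame = 0L,
                   aa_length = nchar(prot), protein_seq = prot,
                   n_wraps = 1L, stop_found = TRUE,
                   junction_residue_index = jri,
                   unique_start = jri, unique_end = nchar(prot))
    u <- derive_unique_region(cand, parent)$unique_start
    aa <- nchar(prot)
    expect_true(u >= 1 && u <= aa)
    expect_true(u <= jri)  # always includes the junction residue
    contained <- grepl(prot, parent, fixed = TRUE)
    if (!contained && u < jri) {
      # u is the largest absent-suffix start (clipped by jri): the suffix at
      # u is absent and the one at u+1 (if any, and if not clipped) present.
      expect_false(grepl(substr(prot, u, aa), parent, fixed = TRUE))
      if (u + 1 <= aa) {
        expect_true(grepl(substr(prot, u + 1, aa), parent, fixed = TRUE))
      }
    }
  }
})

test_that("circular PCR finds junction-spanning products of divergent primers", {
  set.seed(16)
  s <- random_dna_str(100)
  fwd <- substr(s, 1, 20)
  rev <- circpept:::revcomp(substr(s, 81, 100))
  res <- in_silico_circular_pcr(s, fwd, rev)
  # unique sites assumed; regenerate would be needed on collision (none here)
  expect_equal(res$product_length, 100L)
  expect_true(res$spans_junction)
  # absent primer -> no product
  expect_null(in_silico_circular_pcr(s, strrep("A", 20), rev))
  # short primers are a usage error
  expect_error(in_silico_circular_pcr(s, "ATGC", rev),
               class = "circpept_domain_error")
})

test_that("designed divergent primers round-trip through circular PCR", {
  set.seed(17)
  s <- random_dna_str(400)
  pr <- design_divergent_primers(s, product_length = 203)
  res <- in_silico_circular_pcr(s, pr$fwd_primer, pr$rev_primer)
  expect_equal(res$product_length, 203L)
  expect_true(res$spans_junction)
})
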