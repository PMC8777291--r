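small_cfg <- function(...) {
  args <- list(n_chrom = 2, chrom_length = 120000, n_genes = 16, n_circ = 40,
               coding_fraction = 0.2, consistent_fraction = 0.5, seed = 101)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

test_that("the reference generator is deterministic and honours bounds", {
  cfg <- sim_config(n_chrom = 2, chrom_length = 50000, n_genes = 10, seed = 1)
  r1 <- generate_reference(cfg)
  r2 <- generate_reference(cfg)
  expect_identical(r1, r2)
  ann <- r1$annotation
  genes <- filter(ann, type == "gene")
  expect_equal(nrow(genes), 10)
  # every exon lies within its gene and within chromosome bounds
  ex <- filter(ann, type == "exon")
  for (i in seq_len(nrow(ex))) {
    g <- filter(genes, gene_id == ex$gene_id[i])
    expect_true(ex$start[i] >= g$start && ex$end[i] <= g$end)
    expect_true(ex$start[i] >= 1 && ex$end[i] <= cfg$chrom_length)
  }
  # each gene has >= 2 exons and CDS/UTR sub-features
  per_gene <- ann %>% filter(type != "gene", type != "mRNA") %>%
    group_by(gene_id) %>%
    summarise(n_exon = sum(type == "exon"),
              has_cds = any(type == "CDS"),
              has_utr5 = any(type == "five_prime_UTR"),
              has_utr3 = any(type == "three_prime_UTR"))
  expect_true(all(per_gene$n_exon >= 2))
  expect_true(all(per_gene$has_cds & per_gene$has_utr5 & per_gene$has_utr3))
  # genes on the same strand never overlap (they never overlap at all here)
  for (chr in unique(genes$seqid)) {
    g <- arrange(filter(genes, seqid == chr), start)
    if (nrow(g) > 1) expect_true(all(g$start[-1] > g$end[-nrow(g)]))
  }
})

test_that("an empty gene set still yields a genome", {
  cfg <- sim_config(n_chrom = 1, chrom_length = 20000, n_genes = 0,
                    n_circ = 5,
                    origin_mix = c(intergenic = 1), coding_fraction = 0,
                    seed = 3)
  ref <- generate_reference(cfg)
  expect_equal(nrow(ref$annotation), 0)
  expect_equal(nchar(ref$genome[["chr1"]]), 20000)
  # intergenic-only events still place
  ev <- generate_circ_events(ref, cfg)
  expect_equal(nrow(ev$calls), 5)
})

test_that("a genome too small for the gene load raises a sizing error", {
  cfg <- sim_config(n_chrom = 1, chrom_length = 9000, n_genes = 10, seed = 1)
  expect_error(generate_reference(cfg), class = "circpept_sizing_error")
})

test_that("emitted events reproduce the requested origin mix through the classifier", {
  cfg <- small_cfg()
  ref <- generate_reference(cfg)
  ev <- generate_circ_events(ref, cfg)
  got <- classify_origin(ev$calls, ref$annotation)
  expect_equal(as.vector(table(got$origin_class)),
               as.vector(circpept:::largest_remainder(cfg$origin_mix,
                                                      cfg$n_circ)))
  # all-CDS request
  cfg2 <- sim_config(n_chrom = 2, chrom_length = 120000, n_genes = 16,
                     n_circ = 50, origin_mix = c(CDS = 1),
                     coding_fraction = 0.1, seed = 5)
  ref2 <- generate_reference(cfg2)
  ev2 <- generate_circ_events(ref2, cfg2)
  got2 <- classify_origin(ev2$calls, ref2$annotation)
  expect_true(all(got2$origin_class == "CDS"))
})

test_that("exon_other events are rejected as unplaceable", {
  cfg <- sim_config(n_chrom = 1, chrom_length = 60000, n_genes = 6,
                    n_circ = 10, origin_mix = c(exon_other = 1), seed = 1)
  expect_error(generate_circ_events(generate_reference(cfg), cfg),
               class = "circpept_placement_error")
})

test_that("coding_fraction = 0 plants nothing", {
  cfg <- small_cfg(coding_fraction = 0, consistent_fraction = 0)
  ev <- generate_circ_events(generate_reference(cfg), cfg)
  expect_equal(sum(ev$truth$is_coding), 0)
  expect_true(all(ev$truth$protein_seq == ""))
})

test_that("planted proteins round-trip through extraction, ORF scan and selection", {
  cfg <- small_cfg()
  ref <- generate_reference(cfg)
  ev <- generate_circ_events(ref, cfg)
  coding <- filter(ev$truth, is_coding)
  expect_gt(nrow(coding), 0)
  catalog <- build_catalog(ev$calls, ev$genome, ref$annotation)
  for (i in seq_len(nrow(coding))) {
    rec <- filter(catalog, circ_id == coding$circ_id[i])
    cand <- find_junction_orfs(rec$mature_seq, min_aa = 101)
    sel <- select_orf(mutate(cand, circ_id = rec$circ_id))
    expect_equal(nrow(sel), 1)
    expect_equal(sel$protein_seq, coding$protein_seq[i])
    expect_equal(sel$junction_residue_index,
                 coding$junction_residue_index[i])
    expect_gte(sel$aa_length, 101)
  }
})

test_that("truth is internally consistent", {
  cfg <- small_cfg()
  tr <- generate_circ_events(generate_reference(cfg), cfg)$truth
  cons <- filter(tr, is_consistent)
  expect_true(all(cons$is_coding))
  expect_true(all(sign(cons$circ_log2fc) == sign(cons$protein_log2fc)))
  expect_true(all(2^abs(cons$circ_log2fc) > 2))
  expect_true(all(2^abs(cons$protein_log2fc) > 1.5))
})

test_that("count simulation has the right shape, support and planted effects", {
  cfg <- small_cfg()
  tr <- tibble(circ_id = paste0("c", 1:200),
               circ_log2fc = rep(c(0, 2), each = 100))
  cnt <- simulate_counts(tr, cfg)
  expect_equal(dim(cnt), c(200L, 1L + cfg$n_sham + cfg$n_boo))
  m <- as.matrix(cnt[-1])
  expect_true(all(m >= 0))
  expect_true(all(m == floor(m)))
  # determinism
  expect_identical(cnt, simulate_counts(tr, cfg))
  # null features have group mean ratios centred at 1 (Poisson limit)
  cfg0 <- small_cfg(nb_dispersion = 0)
  cnt0 <- simulate_counts(tibble(circ_id = paste0("c", 1:200),
                                 circ_log2fc = 0), cfg0)
  sham <- rowMeans(as.matrix(cnt0[, 2:9]))
  boo <- rowMeans(as.matrix(cnt0[, 10:16]))
  expect_equal(mean(boo / sham), 1, tolerance = 0.1)
  # planted log2fc = 2 gives a mean ratio near 4 in the Poisson limit
  cnt2 <- simulate_counts(tibble(circ_id = paste0("c", 1:200),
                                 circ_log2fc = 2), cfg0)
  sham2 <- rowMeans(as.matrix(cnt2[, 2:9]))
  boo2 <- rowMeans(as.matrix(cnt2[, 10:16]))
  expect_equal(mean(boo2 / sham2), 4, tolerance = 0.4)
})

test_that("full peptide detection reproduces the theoretical digest exactly once", {
  cfg <- small_cfg(peptide_detect_prob = 1)
  ev <- generate_circ_events(generate_reference(cfg), cfg)
  prot <- simulate_proteomics(ev$truth, cfg)
  cand <- filter(ev$truth, is_coding)
  theo <- unique(unlist(lapply(cand$protein_seq,
                               function(s) tryptic_digest(s)$peptide)))
  obs <- prot$peptides$peptide
  expect_true(all(theo %in% obs))
  expect_equal(anyDuplicated(obs), 0L)
  # every consistent candidate has at least one unique-region peptide
  sel <- select(cand, circ_id, protein_seq, unique_start, unique_end)
  matches <- match_peptides(prot$peptides, sel, min_overlap = 5)
  verd <- evaluate_validation(matches, sel)
  cons_ids <- filter(ev$truth, is_consistent)$circ_id
  expect_true(all(filter(verd, circ_id %in% cons_ids)$validated))
})

test_that("the whole study is byte-deterministic given one config", {
  cfg <- sim_config(n_chrom = 1, chrom_length = 80000, n_genes = 10,
                    n_circ = 20, coding_fraction = 0.2, seed = 77)
  s1 <- simulate_boo_study(cfg)
  s2 <- simulate_boo_study(cfg)
  expect_identical(s1, s2)
})
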