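test_that("family profiles are seeded, divergent and validated", {
  p <- build_profiles(1, family_labels = c("famA", "famB", "famC"),
                      domain_length = 90, inter_family_divergence = 0.4)
  expect_equal(p$family_labels, c("famA", "famB", "famC"))
  expect_true(all(nchar(p$domain_consensus) == 90))
  # every pair differs at >= 18 of 90 sites (half the divergence target)
  for (a in 1:2) for (b in (a + 1):3) {
    da <- strsplit(p$domain_consensus[[a]], "")[[1]]
    db <- strsplit(p$domain_consensus[[b]], "")[[1]]
    expect_gte(sum(da != db), 18)
  }
  expect_identical(build_profiles(1), build_profiles(1))
  expect_false(identical(build_profiles(1), build_profiles(2)))
  expect_error(build_profiles(1, family_labels = "famA"), "two families")
  expect_error(build_profiles(1, inter_family_divergence = 0),
               "between 0 and 1")
  expect_error(build_profiles(1, inter_family_divergence = 1),
               "between 0 and 1")
})

test_that("synthesized genes satisfy their class truth on the final protein", {
  profiles <- build_profiles(11)
  set.seed(601)
  for (class in c("inhibitory", "activating", "soluble")) {
    for (nd in c(2L, 6L)) {
      g <- synthesize_gene(profiles, "famC", nd, class,
                           within_divergence = 0.15,
                           gene_id = paste0(class, nd))
      expect_equal(g$n_ig_domains, nd)
      expect_length(g$domain_truth, nd)
      # coding sequence translates back to the protein (independent
      # translation route)
      prot <- as.character(Biostrings::translate(
        Biostrings::DNAString(g$cds), no.init.codon = TRUE))
      expect_equal(sub("\\*$", "", prot), g$protein)
      # cross-implementation check: the classifier module recovers the
      # class from the final protein
      expect_equal(classify_receptor(g$protein)$class_call, g$class_label)
      if (class == "soluble") {
        expect_null(g$tm_truth)
        expect_null(predict_tm(g$protein))
      } else {
        tm_seq <- substr(g$protein, g$tm_truth[1] + 1, g$tm_truth[2])
        expect_equal(grepl("R", tm_seq), class == "activating")
      }
    }
  }
})

test_that("zero within-family divergence reproduces the consensus exactly", {
  profiles <- build_profiles(12)
  set.seed(602)
  g <- synthesize_gene(profiles, "famA", 2L, "inhibitory",
                       within_divergence = 0)
  for (d in g$domain_truth) {
    expect_equal(substr(g$protein, d[1] + 1, d[2]),
                 unname(profiles$domain_consensus["famA"]))
  }
})

test_that("gene synthesis validates its preconditions", {
  profiles <- build_profiles(13)
  expect_error(synthesize_gene(profiles, "famZ", 2L, "soluble"), "family")
  expect_error(synthesize_gene(profiles, "famA", 3L, "soluble"),
               "2, 4 or 6")
  expect_error(synthesize_gene(profiles, "famA", 2L, "soluble",
                               within_divergence = 0.3), "half")
})

test_that("fixtures carry a consistent truth annotation", {
  spec <- data.frame(family = c("famA", "famB"), n_domains = c(2L, 2L),
                     class = c("inhibitory", "soluble"),
                     expressed = c(TRUE, FALSE), n = c(2L, 2L))
  fx <- build_fixture(gene_spec = spec, decoy_orf_count = 3L, seed = 603)
  expect_equal(nrow(fx$orfs), 7L)
  expect_equal(sum(fx$orfs$ig_domain), 4L)
  expect_equal(nrow(fx$truth_table), 4L)
  # every feature lies within its contig
  for (i in seq_len(nrow(fx$orfs))) {
    ctg <- fx$contigs[[fx$orfs$contig_id[i]]]
    expect_gte(fx$orfs$start[i], 0)
    expect_lte(fx$orfs$end[i], nchar(ctg))
  }
  expect_true(all(c("+", "-") %in% fx$orfs$strand))
  # decoy-free fixture: every ORF is an Ig gene
  fx0 <- build_fixture(gene_spec = spec, decoy_orf_count = 0L, seed = 604)
  expect_true(all(fx0$orfs$ig_domain))
  # placed ORFs are exactly what discovery finds
  found <- do.call(rbind, lapply(names(fx$contigs), function(ci) {
    find_orfs(fx$contigs[[ci]], 100, contig_id = ci)
  }))
  expect_equal(nrow(found), nrow(fx$orfs))
})

test_that("fixture generation is byte-deterministic", {
  spec <- data.frame(family = "famA", n_domains = 2L, class = "inhibitory",
                     expressed = TRUE, n = 2L)
  f1 <- build_fixture(gene_spec = spec, decoy_orf_count = 2L, seed = 605)
  f2 <- build_fixture(gene_spec = spec, decoy_orf_count = 2L, seed = 605)
  expect_identical(f1$contigs, f2$contigs)
  expect_identical(f1$orfs, f2$orfs)
  expect_identical(f1$truth_table, f2$truth_table)
  d1 <- tempfile(); d2 <- tempfile()
  write_fixture(f1, d1); write_fixture(f2, d2)
  for (f in c("contigs.fa", "truth.gff3", "truth_table.tsv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("simulated reads respect length, provenance and error model", {
  spec <- data.frame(family = "famA", n_domains = c(2L, 2L),
                     class = "inhibitory", expressed = c(TRUE, FALSE),
                     n = c(1L, 1L))
  fx <- build_fixture(gene_spec = spec, decoy_orf_count = 0L, seed = 606)
  rd <- simulate_reads(fx, depth = 10, error_rate = 0, seed = 607)
  expect_true(all(nchar(rd$seq) == 36))
  expressed_ids <- fx$truth_table$gene_id[fx$truth_table$expressed]
  expect_true(all(rd$transcript_id %in% expressed_ids))
  # zero depth gives zero reads
  expect_equal(nrow(simulate_reads(fx, depth = 0, seed = 1)), 0L)
  # read count follows depth * length / read_length in expectation
  g <- fx$genes[[which(fx$truth_table$expressed)]]
  expected_n <- 10 * nchar(g$cds) / 36
  expect_lt(abs(nrow(rd) - expected_n) / expected_n, 0.35)
  # determinism
  expect_identical(rd, simulate_reads(fx, depth = 10, error_rate = 0,
                                      seed = 607))
  expect_error(simulate_reads(fx, error_rate = 0.5), "error_rate")
})

test_that("read errors are binomial with the configured rate", {
  spec <- data.frame(family = "famA", n_domains = 4L, class = "soluble",
                     expressed = TRUE, n = 1L)
  fx <- build_fixture(gene_spec = spec, decoy_orf_count = 0L, seed = 608)
  rd <- simulate_reads(fx, depth = 250, error_rate = 0.01, seed = 609)
  expect_gt(nrow(rd), 5000)
  g <- fx$genes[[1]]
  mm <- vapply(seq_len(nrow(rd)), function(i) {
    true <- substr(g$cds, rd$true_pos[i] + 1, rd$true_pos[i] + 36)
    obs <- if (rd$strand[i] == "-") {
      as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(rd$seq[i])))
    } else rd$seq[i]
    sum(strsplit(true, "")[[1]] != strsplit(obs, "")[[1]])
  }, numeric(1))
  # binomial expectation: 36 * 0.01 = 0.36 mismatches per read
  expect_equal(mean(mm), 0.36, tolerance = 0.1)
})

test_that("a warning and zero reads result when nothing is expressed", {
  spec <- data.frame(family = "famA", n_domains = 2L, class = "inhibitory",
                     expressed = FALSE, n = 1L)
  fx <- build_fixture(gene_spec = spec, decoy_orf_count = 0L, seed = 610)
  expect_warning(rd <- simulate_reads(fx, depth = 5, seed = 1),
                 "no expressed")
  expect_equal(nrow(rd), 0L)
})
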