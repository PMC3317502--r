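set.seed(701)
REF <- paste(sample(c("A", "C", "G", "T"), 360, replace = TRUE),
             collapse = "")
IDX <- build_read_index(c(tx1 = REF))

test_that("exact substrings map with full score; the score formula gates acceptance", {
  r <- substr(REF, 100, 135)
  pl <- map_read(r, IDX, 2)
  expect_equal(pl$position, 99L)
  expect_equal(pl$mismatches, 0L)
  expect_equal(pl$score, 36)
  expect_equal(pl$strand, "+")
  # three mismatches: score 36 - 3*(1+2) = 27 < 29 at cost 2 (unmapped),
  # 36 - 3*(1+1) = 30 >= 29 at cost 1 (mapped)
  ch <- strsplit(r, "")[[1]]
  for (i in c(5, 15, 25)) ch[i] <- setdiff(c("A", "C", "G", "T"), ch[i])[1]
  r3 <- paste(ch, collapse = "")
  expect_null(map_read(r3, IDX, 2))
  p3 <- map_read(r3, IDX, 1)
  expect_equal(p3$mismatches, 3L)
  expect_equal(p3$score, 30)
  # N never matches
  expect_null(map_read(strrep("N", 36), IDX, 2))
  # reverse-complement reads map on the minus strand at the same locus
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(r)))
  prc <- map_read(rc, IDX, 2)
  expect_equal(prc$strand, "-")
  expect_equal(prc$position, 99L)
})

test_that("placement search agrees with an exhaustive scan oracle", {
  set.seed(702)
  refs <- c(a = paste(sample(c("A", "C", "G", "T"), 300, TRUE),
                      collapse = ""),
            b = paste(sample(c("A", "C", "G", "T"), 250, TRUE),
                      collapse = ""))
  idx <- build_read_index(refs)
  oracle <- function(read, cost) {
    L <- nchar(read)
    cutoff <- ceiling(0.8 * L)
    out <- list()
    for (ri in seq_along(refs)) for (strand in c("+", "-")) {
      rs <- if (strand == "+") read else
        as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(read)))
      a <- utf8ToInt(rs)
      ref <- refs[[ri]]
      for (p in seq_len(nchar(ref) - L + 1)) {
        b <- utf8ToInt(substr(ref, p, p + L - 1))
        mm <- sum(a != b | a == 78 | b == 78)
        sc <- L - (1 + cost) * mm
        if (sc >= cutoff) {
          out[[length(out) + 1]] <- data.frame(ref = ri, pos = p - 1L,
                                               strand = strand, mm = mm,
                                               sc = sc)
        }
      }
    }
    if (!length(out)) return(NULL)
    d <- do.call(rbind, out)
    d[order(-d$sc, d$ref, d$pos, d$strand), ][1, ]
  }
  for (k in 1:120) {
    src <- sample(1:2, 1)
    p <- sample(nchar(refs[[src]]) - 35, 1)
    ch <- strsplit(substr(refs[[src]], p, p + 35), "")[[1]]
    ne <- sample(0:4, 1)
    if (ne) {
      for (i in sample(36, ne)) ch[i] <- sample(c("A", "C", "G", "T", "N"),
                                                1)
    }
    rd <- paste(ch, collapse = "")
    if (sample(c(TRUE, FALSE), 1)) {
      rd <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(rd)))
    }
    cost <- sample(1:2, 1)
    mine <- map_read(rd, idx, cost)
    ora <- oracle(rd, cost)
    expect_equal(is.null(mine), is.null(ora))
    if (!is.null(mine)) {
      expect_equal(mine$reference_id, names(refs)[ora$ref])
      expect_equal(mine$position, ora$pos)
      expect_equal(mine$strand, ora$strand)
      expect_equal(mine$mismatches, ora$mm)
      expect_equal(mine$score, ora$sc)
    }
  }
})

test_that("positional coverage accumulates depth exactly", {
  starts <- seq(0, 360 - 36, by = 12)
  reads <- setNames(substring(REF, starts + 1, starts + 36),
                    paste0("t", starts))
  pl <- map_reads(reads, c(tx1 = REF), 2)
  depth <- positional_coverage(pl, 360)
  # interior bases are tiled three deep; read-bases are conserved
  expect_true(all(depth[37:324] == 3))
  expect_equal(sum(depth), nrow(pl) * 36)
  expect_equal(positional_coverage(pl[0, , drop = FALSE], 100),
               integer(100))
  bad <- data.frame(position = 350L)
  expect_error(positional_coverage(bad, 360), "overhangs")
})

test_that("coverage reports apply the strict more-than-99-percent rule", {
  full <- rep(2L, 500)
  r <- coverage_report(full, "tx")
  expect_equal(r$percent_mapped, 100)
  expect_true(r$expressed)
  half <- c(rep(1L, 250), rep(0L, 250))
  r2 <- coverage_report(half, "tx")
  expect_equal(r2$percent_mapped, 50)
  expect_false(r2$expressed)
  # exactly 99.0 percent is NOT expressed (strict inequality)
  d99 <- c(rep(1L, 990), rep(0L, 10))
  r3 <- coverage_report(d99, "tx")
  expect_equal(r3$percent_mapped, 99)
  expect_false(r3$expressed)
  expect_true(coverage_report(c(rep(1L, 991), rep(0L, 9)))$expressed)
  expect_error(coverage_report(integer(0)), "positive length")
})

test_that("error-free deep reads fully cover expressed transcripts only", {
  spec <- data.frame(family = c("famA", "famB"), n_domains = 2L,
                     class = "inhibitory", expressed = c(TRUE, FALSE),
                     n = 1L)
  fx <- build_fixture(gene_spec = spec, decoy_orf_count = 0L, seed = 703)
  rd <- simulate_reads(fx, depth = 30, error_rate = 0, seed = 704)
  refs <- setNames(vapply(fx$genes, `[[`, character(1), "cds"),
                   vapply(fx$genes, `[[`, character(1), "gene_id"))
  ec <- call_expression(rd, refs)
  on <- ec$reports[ec$reports$reference_id ==
                     fx$truth_table$gene_id[fx$truth_table$expressed], ]
  off <- ec$reports[ec$reports$reference_id ==
                      fx$truth_table$gene_id[!fx$truth_table$expressed], ]
  expect_equal(on$percent_mapped, 100)
  expect_true(on$expressed)
  # no cross-mapping between families at default divergence
  expect_equal(off$percent_mapped, 0)
  expect_false(off$expressed)
})

test_that("re-mapping at cost 1 never lowers coverage relative to cost 2", {
  spec <- data.frame(family = "famA", n_domains = c(2L, 4L),
                     class = "inhibitory", expressed = TRUE, n = 1L)
  fx <- build_fixture(gene_spec = spec, decoy_orf_count = 0L, seed = 705)
  rd <- simulate_reads(fx, depth = 4, error_rate = 0.01, seed = 706)
  refs <- setNames(vapply(fx$genes, `[[`, character(1), "cds"),
                   vapply(fx$genes, `[[`, character(1), "gene_id"))
  ec <- call_expression(rd, refs, cost_initial = 2, cost_rescue = 1)
  merged <- merge(ec$reports_initial, ec$reports, by = "reference_id",
                  suffixes = c("_c2", "_c1"))
  expect_true(all(merged$percent_mapped_c1 >= merged$percent_mapped_c2))
  # cost-1 placements are a superset of cost-2 placements
  expect_gte(nrow(ec$placements), nrow(ec$placements_initial))
})
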