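test_that("p-distance worked examples hold exactly", {
  r <- p_distance("ACDEF", "ACDEF")
  expect_equal(r$distance, 0)
  expect_equal(r$compared_sites, 5L)
  expect_equal(p_distance("ACDEF", "ACDKF")$distance, 0.2)
  r3 <- p_distance("A-DEF", "ACDKL")
  expect_equal(r3$distance, 0.5)
  expect_equal(r3$compared_sites, 4L)
  # all-missing pair is flagged, not an exception
  r0 <- p_distance("--X", "AC-")
  expect_false(r0$defined)
  expect_equal(r0$compared_sites, 0L)
})

test_that("p-distance matches the column-count oracle on random gapped pairs", {
  set.seed(301)
  for (k in 1:300) {
    n <- sample(5:60, 1)
    a <- paste(sample(c(AA20, "-", "X"), n, replace = TRUE,
                      prob = c(rep(1, 20), 3, 1)), collapse = "")
    b <- paste(sample(c(AA20, "-", "X"), n, replace = TRUE,
                      prob = c(rep(1, 20), 3, 1)), collapse = "")
    mine <- p_distance(a, b)
    ora <- oracle_p_distance(a, b)
    expect_equal(mine$distance, ora$distance)
    expect_equal(mine$compared_sites, ora$compared_sites)
    # metric properties
    expect_equal(p_distance(a, a)$distance,
                 if (oracle_p_distance(a, a)$compared_sites) 0 else
                   NA_real_)
    expect_equal(p_distance(b, a)$distance, mine$distance)
    if (!is.na(mine$distance)) {
      expect_gte(mine$distance, 0)
      expect_lte(mine$distance, 1)
    }
  }
})

test_that("the distance matrix equals brute-force pairwise recomputation", {
  set.seed(302)
  rows <- vapply(1:50, function(i) {
    paste(sample(c(AA20, "-", "X"), 40, replace = TRUE,
                 prob = c(rep(1, 20), 2, 1)), collapse = "")
  }, character(1))
  names(rows) <- paste0("s", 1:50)
  dm <- distance_matrix(rows)
  expect_true(isSymmetric(dm$d))
  expect_equal(unname(diag(dm$d)), rep(0, 50))
  for (i in sample(50, 12)) for (j in sample(50, 12)) {
    if (i == j) next
    ora <- oracle_p_distance(rows[[i]], rows[[j]])
    expect_equal(unname(dm$d[i, j]), ora$distance)
    expect_equal(unname(dm$sites[i, j]), ora$compared_sites)
  }
})

test_that("NJ closed forms hold for two and three taxa", {
  d2 <- matrix(c(0, .4, .4, 0), 2, dimnames = list(c("a", "b"),
                                                   c("a", "b")))
  t2 <- nj_tree(d2)
  expect_equal(sort(t2$tip.label), c("a", "b"))
  expect_equal(unname(t2$edge.length), c(0.2, 0.2))
  d3 <- matrix(c(0, .3, .5, .3, 0, .6, .5, .6, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- nj_tree(d3)
  pend <- function(tr, lab) tr$edge.length[tr$edge[, 2] ==
                                             which(tr$tip.label == lab)]
  expect_equal(pend(t3, "a"), (0.3 + 0.5 - 0.6) / 2)
  expect_equal(pend(t3, "b"), (0.3 + 0.6 - 0.5) / 2)
  expect_equal(pend(t3, "c"), (0.5 + 0.6 - 0.3) / 2)
  expect_error(nj_tree(matrix(0, 1, 1)), "at least two")
})

test_that("NJ recovers additive trees exactly and matches least squares", {
  set.seed(303)
  for (k in 1:30) {
    case <- random_additive_case(sample(5:8, 1))
    fit <- nj_tree(case$D)
    expect_equal(ape::dist.topo(ape::unroot(fit), ape::unroot(case$tree)),
                 expected = structure(0, class = NULL), ignore_attr = TRUE)
    Dfit <- ape::cophenetic.phylo(fit)[rownames(case$D), colnames(case$D)]
    expect_lt(max(abs(Dfit - case$D)), 1e-9)
  }
  # n = 5: agreement with brute-force least squares over all 15 topologies
  for (k in 1:10) {
    case <- random_additive_case(5)
    fit <- nj_tree(case$D)
    ls <- oracle_ls_5leaf(case$D)
    expect_lt(ls$rss, 1e-18)
    fit_splits <- tree_cherry_splits(fit)
    for (s in ls$splits) {
      expect_true(paste(s, collapse = ",") %in% names(fit_splits))
    }
  }
})

test_that("NJ output is invariant to input label order", {
  set.seed(304)
  case <- random_additive_case(7)
  perm <- sample(rownames(case$D))
  f1 <- nj_tree(case$D)
  f2 <- nj_tree(case$D[perm, perm])
  expect_equal(ape::dist.topo(ape::unroot(f1), ape::unroot(f2)),
               expected = 0, ignore_attr = TRUE)
})

test_that("NJ matches the reference implementation on noisy matrices", {
  set.seed(305)
  for (k in 1:10) {
    case <- random_additive_case(sample(6:10, 1))
    D <- case$D + matrix(runif(length(case$D), 0, 0.02),
                         nrow(case$D))
    D <- (D + t(D)) / 2
    diag(D) <- 0
    mine <- nj_tree(D)
    ref <- ape::nj(as.dist(D))
    expect_equal(ape::dist.topo(ape::unroot(mine), ape::unroot(ref)),
                 expected = 0, ignore_attr = TRUE)
  }
})

test_that("star alignment projects onto anchor coordinates", {
  set.seed(306)
  cons <- random_protein(90)
  prof <- build_pssm(cons, "famA")
  aln <- build_domain_alignment(c(q1 = cons, q2 = cons), prof)
  expect_equal(aln$column_count, 90L)
  expect_false(any(grepl("-", aln$rows)))
  # a 3-residue deletion appears as exactly 3 gap columns
  del <- paste0(substr(cons, 1, 40), substr(cons, 44, 90))
  aln2 <- build_domain_alignment(c(q1 = cons, q2 = del), prof)
  expect_equal(sum(strsplit(aln2$rows[["q2"]], "")[[1]] == "-"), 3L)
  # insertions relative to the anchor are dropped and counted
  ins <- paste0(substr(cons, 1, 45), "WWW", substr(cons, 46, 90))
  aln3 <- build_domain_alignment(c(q1 = cons, q2 = ins), prof)
  expect_equal(nchar(aln3$rows[["q2"]]), 90L)
  expect_equal(unname(aln3$dropped_insertions[["q2"]]), 3L)
  expect_error(build_domain_alignment(c(q1 = cons), prof), "two sequences")
})

test_that("bootstrap gives full support to an unambiguous split and is seeded", {
  rows <- c(a1 = strrep("AC", 15), a2 = strrep("AC", 15),
            b1 = strrep("CA", 15), b2 = strrep("CA", 15))
  aln <- igrec:::as_domain_alignment(rows)
  for (reps in c(10L, 100L)) {
    bt <- bootstrap_supports(aln, reps, seed = 42)
    sup <- attr(bt, "supports")
    expect_length(sup, 1L)
    expect_equal(unname(sup), 100)
  }
  b1 <- bootstrap_supports(aln, 50, seed = 7)
  b2 <- bootstrap_supports(aln, 50, seed = 7)
  expect_identical(attr(b1, "supports"), attr(b2, "supports"))
  # supports bounded on noisy data
  set.seed(307)
  noisy <- vapply(1:6, function(i) random_protein(40), character(1))
  names(noisy) <- paste0("t", 1:6)
  bn <- bootstrap_supports(igrec:::as_domain_alignment(noisy), 30, seed = 1)
  sup <- attr(bn, "supports")
  expect_true(all(sup >= 0 & sup <= 100))
})

test_that("fewer than four leaves yields a tree without supports", {
  rows <- c(a = strrep("A", 20), b = strrep("C", 20), c = strrep("D", 20))
  bt <- bootstrap_supports(igrec:::as_domain_alignment(rows), 10, seed = 1)
  expect_length(attr(bt, "supports"), 0L)
})

test_that("majority consensus counts bipartitions correctly", {
  set.seed(308)
  base <- ape::rtree(6, rooted = FALSE)
  trees <- list(base, base, base)
  cm <- majority_consensus(trees, 50)
  expect_equal(ape::dist.topo(ape::unroot(cm), ape::unroot(base)),
               expected = 0, ignore_attr = TRUE)
  expect_true(all(cm$node.label[-1] == 100))
  # a split present in 2 of 3 trees at threshold 50 is kept, labelled 66.7
  t1 <- ape::read.tree(text = "((a,b),(c,d),e);")
  t2 <- ape::read.tree(text = "((a,b),(c,e),d);")
  t3 <- ape::read.tree(text = "((a,e),(c,d),b);")
  cons <- majority_consensus(list(t1, t2, t3), 50)
  expect_true(66.7 %in% cons$node.label)
  # the ab split occurs twice and is retained; bipartition keys are
  # canonicalised to the side not containing the smallest label ("a")
  keys <- igrec:::tree_bipartitions(cons)
  ab_key <- paste(sort(setdiff(cons$tip.label, c("a", "b"))),
                  collapse = "\r")
  expect_true(ab_key %in% keys)
  # agreement with the reference consensus implementation
  set.seed(309)
  rts <- lapply(1:5, function(i) ape::rtree(7, rooted = FALSE))
  for (i in 2:5) rts[[i]]$tip.label <- rts[[1]]$tip.label
  mine <- majority_consensus(rts, 50)
  ref <- ape::consensus(rts, p = 0.50001)
  expect_equal(ape::dist.topo(ape::unroot(mine), ape::unroot(ref)),
               expected = 0, ignore_attr = TRUE)
  expect_error(majority_consensus(list(t1), 40), "at least 50")
  t_bad <- ape::read.tree(text = "((a,b),(c,x),e);")
  expect_error(majority_consensus(list(t1, t_bad), 50), "leaf set")
})

test_that("family assignment recovers simulated truth", {
  set.seed(310)
  profiles <- build_profiles(881, inter_family_divergence = 0.4)
  refs <- reference_domains(profiles, 3, divergence = 0.1, seed = 882)
  truth <- sample(profiles$family_labels, 100, replace = TRUE)
  queries <- vapply(seq_along(truth), function(i) {
    mutate_seq(profiles$domain_consensus[[truth[i]]], 0.1)
  }, character(1))
  names(queries) <- sprintf("r%03d|d1", seq_along(queries))
  fa <- assign_family(queries, refs$sequences, refs$families)
  acc <- mean(fa$domains$assigned_family == truth)
  expect_gte(acc, 0.95)
  # self-match: a family consensus is assigned its own family
  cons_q <- setNames(profiles$domain_consensus[1], "self|d1")
  fa_self <- assign_family(cons_q, refs$sequences, refs$families)
  expect_equal(fa_self$domains$assigned_family,
               profiles$family_labels[1])
  expect_gt(fa_self$domains$margin, 0)
})

test_that("equidistant queries are unassigned; chimeras are flagged", {
  refs <- c(fa1 = strrep("A", 30), fb1 = strrep("C", 30))
  fams <- c("famA", "famB")
  # exactly equidistant between the two references
  q <- setNames(paste0(strrep("A", 15), strrep("C", 15)), "q|d1")
  fa <- assign_family(q, refs, fams)
  expect_equal(fa$domains$assigned_family, "unassigned")
  # receptor with one domain from each family is chimeric
  qs <- c("r1|d1" = strrep("A", 30), "r1|d2" = strrep("C", 30))
  fa2 <- assign_family(qs, refs, fams)
  expect_equal(fa2$receptors$family_call, "unassigned") # 1-1 vote tie
  expect_true(fa2$receptors$chimeric)
  expect_error(assign_family(q, refs, character(0)), "family label")
})
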