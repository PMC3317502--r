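# Shared fixtures and independent oracles used across the test files.
# Oracles are deliberately naive re-derivations, kept separate from the
# implementation paths they check.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_protein <- function(n, alphabet = AA20) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

mutate_seq <- function(s, rate, alphabet = AA20) {
  a <- strsplit(s, "")[[1]]
  hit <- runif(length(a)) < rate
  a[hit] <- vapply(a[hit], function(z) sample(setdiff(alphabet, z), 1),
                   character(1))
  paste(a, collapse = "")
}

# Naive quadratic global-alignment score (linear gap penalty).
naive_nw_score <- function(a, b, match = 2, mismatch = -1, gap = -2) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  dp <- matrix(0, n + 1, m + 1)
  dp[1, ] <- gap * (0:m); dp[, 1] <- gap * (0:n)
  for (i in 1:n) for (j in 1:m) {
    s <- if (ca[i] == cb[j]) match else mismatch
    dp[i + 1, j + 1] <- max(dp[i, j] + s, dp[i, j + 1] + gap,
                            dp[i + 1, j] + gap)
  }
  dp[n + 1, m + 1]
}

# Direct column-count p-distance oracle.
oracle_p_distance <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  ok <- !(ca %in% c("-", "X")) & !(cb %in% c("-", "X"))
  if (!sum(ok)) return(list(distance = NA_real_, compared_sites = 0L))
  list(distance = sum(ca[ok] != cb[ok]) / sum(ok),
       compared_sites = sum(ok))
}

# Brute-force six-frame ORF scanner (codon-by-codon).
oracle_find_orfs <- function(seq, min_aa) {
  len <- nchar(seq)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    for (f in 0:2) {
      pos <- seq(f + 1, len - 2, by = 3)
      pos <- pos[pos + 2 <= len]
      if (!length(pos)) next
      cods <- substring(s, pos, pos + 2)
      stop_idx <- which(cods %in% c("TAA", "TAG", "TGA"))
      prev <- 0
      for (e in stop_idx) {
        st <- which(cods == "ATG")
        st <- st[st > prev & st < e]
        if (length(st)) {
          a <- min(st)
          if (e - a >= min_aa) {
            aa <- paste(vapply(a:(e - 1), function(q) {
              cod <- cods[q]
              if (grepl("N", cod)) "X" else
                as.character(Biostrings::translate(Biostrings::DNAString(cod),
                                                   no.init.codon = TRUE))
            }, character(1)), collapse = "")
            if (strand == "+") {
              c0 <- pos[a] - 1; c1 <- pos[e] + 2
            } else {
              c0 <- len - (pos[e] + 2); c1 <- len - pos[a] + 1
            }
            out[[length(out) + 1]] <- data.frame(
              start = c0, end = c1, strand = strand, protein = aa,
              stringsAsFactors = FALSE)
          }
        }
        prev <- e
      }
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), protein = character(0)))
  }
  df <- do.call(rbind, out)
  df[order(df$start, df$strand, df$end), , drop = FALSE]
}

# Exhaustive window scorer for domain scanning (no overlap resolution).
oracle_window_scores <- function(protein, profile) {
  aa <- strsplit(protein, "")[[1]]
  L <- profile$length
  n_win <- length(aa) - L + 1
  if (n_win < 1) return(numeric(0))
  vapply(seq_len(n_win), function(w) {
    sum(vapply(seq_len(L), function(o) {
      a <- aa[w + o - 1]
      if (a %in% colnames(profile$matrix)) profile$matrix[o, a] else
        mean(profile$matrix[o, ])
    }, numeric(1)))
  }, numeric(1))
}

# Exhaustive 6-residue window ITIM check.
oracle_itim_positions <- function(protein, tail_start) {
  n <- nchar(protein)
  hits <- integer(0)
  if (n - tail_start < 6) return(hits)
  for (p in (tail_start + 1):(n - 5)) {
    w <- strsplit(substr(protein, p, p + 5), "")[[1]]
    if (w[1] %in% c("V", "L", "S", "N") && w[3] == "Y" &&
        w[6] %in% c("L", "V")) {
      hits <- c(hits, p - 1)
    }
  }
  hits
}

# All 15 unrooted binary topologies on 5 leaves, as split sets; least-
# squares branch fit via the path design matrix.
oracle_ls_5leaf <- function(D) {
  labels <- rownames(D)
  stopifnot(length(labels) == 5)
  pairs <- t(combn(5, 2))
  # a 5-leaf unrooted binary tree has two cherries; enumerate by the
  # unordered pair of cherries {A,B}, {C,D} with E attached centrally
  combos <- list()
  for (ab in combn(5, 2, simplify = FALSE)) {
    rest <- setdiff(1:5, ab)
    for (cd in combn(rest, 2, simplify = FALSE)) {
      key <- paste(sort(c(paste(sort(ab), collapse = ","),
                          paste(sort(cd), collapse = ","))), collapse = "|")
      combos[[key]] <- list(ab = ab, cd = cd, e = setdiff(rest, cd))
    }
  }
  best <- NULL
  for (cmb in combos) {
    # edges: 5 pendant + 2 internal (ab-cherry stem, cd-cherry stem)
    # path matrix rows follow `pairs`
    X <- matrix(0, nrow(pairs), 7)
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      X[r, i] <- 1; X[r, j] <- 1
      in_ab <- c(i %in% cmb$ab, j %in% cmb$ab)
      in_cd <- c(i %in% cmb$cd, j %in% cmb$cd)
      if (xor(in_ab[1], in_ab[2])) X[r, 6] <- 1
      if (xor(in_cd[1], in_cd[2])) X[r, 7] <- 1
    }
    y <- D[pairs]
    beta <- qr.solve(X, y)
    rss <- sum((X %*% beta - y)^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(rss = rss, combo = cmb, beta = beta,
                   splits = list(sort(labels[cmb$ab]), sort(labels[cmb$cd])))
    }
  }
  best
}

# Internal (non-trivial) splits of an unrooted 5-leaf phylo tree, each as a
# sorted pair of labels (the smaller side).
tree_cherry_splits <- function(tree) {
  n <- length(tree$tip.label)
  splits <- list()
  bp <- ape::prop.part(tree)
  labs <- attr(bp, "labels")
  for (p in bp) {
    side <- sort(labs[p])
    other <- sort(setdiff(labs, side))
    small <- if (length(side) <= length(other)) side else other
    if (length(small) >= 2 && length(small) <= n - 2) {
      splits[[paste(small, collapse = ",")]] <- small
    }
  }
  splits
}

# Small helper: build an additive distance matrix from a random unrooted
# tree with positive branch lengths.
random_additive_case <- function(ntip) {
  tr <- ape::rtree(ntip, rooted = FALSE)
  tr$edge.length <- runif(length(tr$edge.length), 0.05, 1)
  D <- ape::cophenetic.phylo(tr)
  ord <- sort(rownames(D))
  list(tree = tr, D = D[ord, ord])
}
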