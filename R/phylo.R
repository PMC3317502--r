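# Phylogenetic engine: pairwise-deletion amino-acid p-distances,
# neighbour-joining (Saitou & Nei 1987), bootstrap bipartition supports
# (Felsenstein 1985) and majority-rule consensus, plus the distance-based
# family assignment built on top of them.

#' Stack domain sequences into anchor coordinates (star alignment)
#'
#' Each sequence is globally aligned to the anchor consensus with
#' [nw_align()] and projected onto the anchor's columns. Deletions relative
#' to the anchor appear as `-`; insertions relative to the anchor are
#' dropped (the per-sequence dropped-residue counts are retained).
#'
#' @param domain_seqs Named character vector of at least two amino-acid
#'   sequences.
#' @param anchor A `domain_profile` (from [build_pssm()]) whose consensus
#'   defines the common coordinate frame, or a plain character scalar.
#' @return An object of class `domain_alignment`: list with `labels`, `rows`
#'   (named equal-length strings), `column_count` and `dropped_insertions`.
#' @export
build_domain_alignment <- function(domain_seqs, anchor) {
  if (length(domain_seqs) < 2L) stop("need at least two sequences")
  if (any(!nzchar(domain_seqs))) stop("empty sequence in input")
  if (is.null(names(domain_seqs))) {
    names(domain_seqs) <- paste0("seq", seq_along(domain_seqs))
  }
  cons <- if (inherits(anchor, "domain_profile")) anchor$consensus else anchor
  L <- nchar(cons)
  rows <- character(length(domain_seqs))
  dropped <- integer(length(domain_seqs))
  for (k in seq_along(domain_seqs)) {
    al <- nw_align(cons, domain_seqs[[k]])
    ca <- split_chars(al$aligned_a)
    cb <- split_chars(al$aligned_b)
    anchor_col <- ca != "-"
    rows[k] <- paste_chars(cb[anchor_col])
    dropped[k] <- sum(!anchor_col & cb != "-")
  }
  names(rows) <- names(domain_seqs)
  names(dropped) <- names(domain_seqs)
  structure(list(labels = names(domain_seqs), rows = rows,
                 column_count = L, dropped_insertions = dropped),
            class = "domain_alignment")
}

#' @export
print.domain_alignment <- function(x, ...) {
  cat("Domain alignment: ", length(x$labels), " sequences x ",
      x$column_count, " columns (", sum(x$dropped_insertions),
      " inserted residues dropped)\n", sep = "")
  invisible(x)
}

# Build a domain_alignment directly from already-aligned equal-length rows.
as_domain_alignment <- function(rows) {
  lens <- unique(nchar(rows))
  if (length(lens) != 1L) stop("rows must have equal length")
  if (is.null(names(rows))) names(rows) <- paste0("seq", seq_along(rows))
  structure(list(labels = names(rows), rows = rows, column_count = lens,
                 dropped_insertions = setNames(integer(length(rows)),
                                               names(rows))),
            class = "domain_alignment")
}

#' Pairwise-deletion amino-acid p-distance between two aligned rows
#'
#' Columns where either row carries a gap (`-`) or missing residue (`X`)
#' are skipped; the distance is the fraction of the remaining (compared)
#' columns at which the rows differ.
#'
#' @param row_a,row_b Equal-length aligned strings.
#' @return List with `distance` (fraction, `NA` when no columns are
#'   comparable), `compared_sites` and `defined`.
#' @examples
#' p_distance("A-DEF", "ACDKL") # distance 0.5 over 4 compared sites
#' @export
p_distance <- function(row_a, row_b) {
  ca <- split_chars(row_a)
  cb <- split_chars(row_b)
  if (length(ca) != length(cb)) stop("rows must have equal length")
  ok <- !(ca %in% c("-", "X")) & !(cb %in% c("-", "X"))
  n <- sum(ok)
  if (n == 0L) {
    return(list(distance = NA_real_, compared_sites = 0L, defined = FALSE))
  }
  list(distance = sum(ca[ok] != cb[ok]) / n, compared_sites = n,
       defined = TRUE)
}

#' All-vs-all pairwise-deletion p-distance matrix
#'
#' @param aln A `domain_alignment` (or named character vector of
#'   equal-length rows).
#' @return Object of class `p_dist_matrix`: list with `labels`, `d`
#'   (symmetric distance matrix, `NA` where undefined), `sites` (symmetric
#'   compared-site counts) and `defined` (TRUE when every pair has at least
#'   one compared site).
#' @export
distance_matrix <- function(aln) {
  if (!inherits(aln, "domain_alignment")) aln <- as_domain_alignment(aln)
  rows <- aln$rows
  n <- length(rows)
  if (n < 2L) stop("need at least two rows")
  chars <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  valid <- !(chars == "-" | chars == "X")
  storage.mode(valid) <- "double"
  sites <- valid %*% t(valid)
  # matches via one-hot residue indicators restricted to valid positions
  matches <- matrix(0, n, n)
  for (a in unique(as.vector(chars))) {
    if (a %in% c("-", "X")) next
    ind <- (chars == a) * valid
    matches <- matches + ind %*% t(ind)
  }
  d <- (sites - matches) / sites
  d[sites == 0] <- NA_real_
  diag(d) <- 0
  sites_int <- matrix(as.integer(round(sites)), n, n)
  dimnames(d) <- list(aln$labels, aln$labels)
  dimnames(sites_int) <- dimnames(d)
  structure(list(labels = aln$labels, d = d, sites = sites_int,
                 defined = !anyNA(d)),
            class = "p_dist_matrix")
}

#' @export
print.p_dist_matrix <- function(x, ...) {
  cat("p-distance matrix over ", length(x$labels), " sequences",
      if (!x$defined) " (contains undefined pairs)", "\n", sep = "")
  invisible(x)
}

#' Neighbour-joining tree from a distance matrix
#'
#' Classic neighbour joining: at each step the pair minimising
#' `Q(i,j) = (n-2) d(i,j) - sum_k d(i,k) - sum_k d(j,k)` is joined, branch
#' lengths follow the standard two-term formula (negative lengths clamped
#' to zero) and the matrix is reduced with
#' `d(u,k) = (d(i,k) + d(j,k) - d(i,j)) / 2`. Ties in Q are broken by the
#' lexicographically smallest pair of cluster labels (each cluster labelled
#' by its smallest member leaf), making the topology deterministic.
#'
#' @param dm A `p_dist_matrix` (must have no undefined entries) or a plain
#'   symmetric matrix with dimnames.
#' @return An unrooted tree of class `phylo` (ape), stored rooted at the
#'   final three-way (or for n = 2, two-way) join.
#' @export
nj_tree <- function(dm) {
  if (inherits(dm, "p_dist_matrix")) {
    if (!dm$defined) stop("distance matrix contains undefined pairs")
    d <- dm$d
  } else {
    d <- as.matrix(dm)
  }
  n <- nrow(d)
  if (n < 2L) stop("need at least two sequences")
  labels <- rownames(d) %||% paste0("t", seq_len(n))
  edges <- matrix(integer(0), 0L, 2L)
  edge_len <- numeric(0)
  node_id <- seq_len(n)          # phylo node id per active cluster
  minlab <- labels               # smallest member leaf label per cluster
  next_internal <- n + 1L
  add_edge <- function(parent, child, len) {
    edges <<- rbind(edges, c(parent, child))
    edge_len <<- c(edge_len, max(0, len))
  }
  while (length(node_id) > 3L) {
    m <- length(node_id)
    R <- rowSums(d)
    Q <- (m - 2) * d - outer(R, R, "+")
    Q[lower.tri(Q, diag = TRUE)] <- Inf
    minQ <- min(Q)
    cand <- which(Q == minQ, arr.ind = TRUE)
    if (nrow(cand) > 1L) {
      la <- pmin(minlab[cand[, 1]], minlab[cand[, 2]])
      lb <- pmax(minlab[cand[, 1]], minlab[cand[, 2]])
      cand <- cand[order(la, lb)[1], , drop = FALSE]
    }
    i <- cand[1, 1]; j <- cand[1, 2]
    li <- d[i, j] / 2 + (R[i] - R[j]) / (2 * (m - 2))
    lj <- d[i, j] - li
    u <- next_internal
    next_internal <- next_internal + 1L
    add_edge(u, node_id[i], li)
    add_edge(u, node_id[j], lj)
    dnew <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    node_id <- c(node_id[keep], u)
    minlab <- c(minlab[keep], min(minlab[c(i, j)]))
  }
  center <- next_internal
  if (length(node_id) == 3L) {
    x1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
    x2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
    x3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
    add_edge(center, node_id[1], x1)
    add_edge(center, node_id[2], x2)
    add_edge(center, node_id[3], x3)
  } else {
    add_edge(center, node_id[1], d[1, 2] / 2)
    add_edge(center, node_id[2], d[1, 2] / 2)
  }
  n_internal <- center - n
  # remap internal ids so the final center becomes the root node n+1
  remap <- c(seq_len(n), rep(NA_integer_, n_internal))
  internal_old <- seq.int(n + 1L, center)
  internal_new <- c(seq.int(n + 2L, length.out = n_internal - 1L),
                    n + 1L) # shift creation order up, center becomes root
  remap[internal_old] <- internal_new
  edges <- matrix(remap[edges], ncol = 2L)
  tree <- structure(list(edge = edges, edge.length = edge_len,
                         tip.label = labels, Nnode = n_internal),
                    class = "phylo")
  ape::reorder.phylo(tree, "cladewise")
}

# ---- bipartitions ----------------------------------------------------------

# Canonical key for the leaf bipartition induced by each internal edge of an
# unrooted tree: the clade side not containing the alphabetically smallest
# tip, as a sorted label string. Returns a character vector named by the
# phylo node number under each internal (non-root) node.
tree_bipartitions <- function(tree) {
  n <- length(tree$tip.label)
  if (tree$Nnode < 2L) return(setNames(character(0), character(0)))
  ref <- min(tree$tip.label)
  clades <- clade_tips(tree)
  root <- n + 1L
  nodes <- setdiff(as.integer(names(clades)), root)
  keys <- vapply(nodes, function(v) {
    tips <- clades[[as.character(v)]]
    side <- if (ref %in% tips) setdiff(tree$tip.label, tips) else tips
    paste(sort(side), collapse = "\r")
  }, character(1))
  names(keys) <- nodes
  # drop trivial splits (empty or singleton sides cannot occur for internal
  # nodes of a binary tree, but guard anyway)
  sizes <- vapply(strsplit(keys, "\r", fixed = TRUE), length, integer(1))
  keys[sizes >= 2L & sizes <= n - 2L]
}

# Tip labels under each internal node (postorder accumulation).
clade_tips <- function(tree) {
  n <- length(tree$tip.label)
  tips <- vector("list", n + tree$Nnode)
  for (v in seq_len(n)) tips[[v]] <- tree$tip.label[v]
  ord <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(ord))) {
    p <- ord[k, 1]; ch <- ord[k, 2]
    tips[[p]] <- c(tips[[p]], tips[[ch]])
  }
  internal <- seq.int(n + 1L, n + tree$Nnode)
  out <- tips[internal]
  names(out) <- internal
  out
}

#' Bootstrap supports for a neighbour-joining tree
#'
#' Builds the NJ tree of the full alignment, then for each replicate
#' resamples alignment columns with replacement, recomputes the
#' pairwise-deletion distance matrix and NJ tree, and records which leaf
#' bipartitions of the original tree are present. Supports are percentages
#' of replicates containing each internal-edge bipartition. Replicates whose
#' resampled matrix has undefined pairs are redrawn (count recorded in
#' attribute `redrawn`).
#'
#' @param aln A `domain_alignment`.
#' @param n_replicates Number of bootstrap replicates (protocol default 1000).
#' @param seed Integer seed; identical seeds give identical supports.
#' @return The original-data NJ `phylo` tree with `node.label` carrying the
#'   support percentage for each non-root internal node (`NA` for the root)
#'   and attribute `supports` (named by bipartition key).
#' @export
bootstrap_supports <- function(aln, n_replicates = 1000L, seed = 1L) {
  stopifnot(n_replicates >= 1L)
  if (length(aln$labels) < 2L) stop("need at least two sequences")
  base_dm <- distance_matrix(aln)
  if (!base_dm$defined) stop("alignment has pairs with no compared sites")
  tree <- nj_tree(base_dm)
  keys <- tree_bipartitions(tree)
  if (length(aln$labels) < 4L || length(keys) == 0L) {
    tree$node.label <- rep(NA_real_, tree$Nnode)
    attr(tree, "supports") <- setNames(numeric(0), character(0))
    attr(tree, "redrawn") <- 0L
    return(tree)
  }
  chars <- do.call(rbind, strsplit(aln$rows, "", fixed = TRUE))
  counts <- setNames(numeric(length(keys)), keys)
  redrawn <- 0L
  with_seed(seed, {
    for (r in seq_len(n_replicates)) {
      repeat {
        cols <- sample.int(aln$column_count, aln$column_count,
                           replace = TRUE)
        rep_rows <- apply(chars[, cols, drop = FALSE], 1L, paste,
                          collapse = "")
        names(rep_rows) <- aln$labels
        dm <- distance_matrix(as_domain_alignment(rep_rows))
        if (dm$defined) break
        redrawn <- redrawn + 1L
      }
      rep_keys <- tree_bipartitions(nj_tree(dm))
      hit <- keys %in% rep_keys
      counts[hit] <- counts[hit] + 1
    }
  })
  supports <- 100 * counts / n_replicates
  node_support <- rep(NA_real_, tree$Nnode)
  n <- length(tree$tip.label)
  km <- tree_bipartitions(tree)
  node_support[as.integer(names(km)) - n] <- supports[km]
  tree$node.label <- node_support
  attr(tree, "supports") <- supports
  attr(tree, "redrawn") <- redrawn
  tree
}

#' Majority-rule consensus of trees on one leaf set
#'
#' Retains exactly the bipartitions occurring in strictly more than
#' `threshold` percent of the input trees (compatible by construction for
#' thresholds of at least 50) and labels each retained internal node with
#' the bipartition's percentage frequency.
#'
#' @param trees List of `phylo` trees on identical leaf sets.
#' @param threshold Percentage in \[50, 100\].
#' @return A `phylo` tree (possibly multifurcating, no branch lengths) with
#'   `node.label` frequencies.
#' @export
majority_consensus <- function(trees, threshold = 50) {
  if (threshold < 50) stop("threshold must be at least 50")
  leafsets <- lapply(trees, function(t) sort(t$tip.label))
  if (length(unique(vapply(leafsets, paste, character(1),
                           collapse = "\r"))) != 1L) {
    stop("trees must share an identical leaf set")
  }
  labels <- leafsets[[1]]
  n <- length(labels)
  all_keys <- unlist(lapply(trees, function(t) unique(tree_bipartitions(t))))
  tab <- table(all_keys)
  freq <- 100 * as.numeric(tab) / length(trees)
  keep <- freq > threshold
  clades <- strsplit(names(tab)[keep], "\r", fixed = TRUE)
  freqs <- freq[keep]
  ref <- min(labels)
  # orient every kept split as the clade not containing the reference leaf
  clades <- lapply(clades, function(cl) {
    if (ref %in% cl) setdiff(labels, cl) else cl
  })
  build_consensus_phylo(labels, clades, round(freqs, 1))
}

# Assemble a (possibly multifurcating) phylo from nested clades.
build_consensus_phylo <- function(labels, clades, freqs) {
  n <- length(labels)
  ord <- order(-vapply(clades, length, integer(1)))
  clades <- clades[ord]
  freqs <- freqs[ord]
  n_node <- 1L + length(clades)
  node_of_clade <- n + 1L + seq_along(clades) # root is n+1
  # parent of each clade: smallest strictly containing clade, else root
  parent_node <- rep(n + 1L, length(clades))
  for (k in seq_along(clades)) {
    for (j in rev(seq_len(k - 1L))) {
      if (all(clades[[k]] %in% clades[[j]]) &&
          length(clades[[j]]) > length(clades[[k]])) {
        parent_node[k] <- node_of_clade[j]
        break
      }
    }
  }
  edges <- matrix(integer(0), 0L, 2L)
  for (k in seq_along(clades)) {
    edges <- rbind(edges, c(parent_node[k], node_of_clade[k]))
  }
  # each tip hangs off the smallest clade containing it (else the root)
  for (t in seq_len(n)) {
    best <- 0L
    parent <- n + 1L
    for (k in seq_along(clades)) {
      if (labels[t] %in% clades[[k]] && length(clades[[k]]) >
          0L && (best == 0L ||
                 length(clades[[k]]) < length(clades[[best]]))) {
        best <- k
        parent <- node_of_clade[k]
      }
    }
    edges <- rbind(edges, c(parent, t))
  }
  tree <- structure(list(edge = edges, tip.label = labels,
                         Nnode = n_node,
                         node.label = c(NA_real_, freqs)),
                    class = "phylo")
  ape::reorder.phylo(tree, "cladewise")
}

# ---- family assignment -----------------------------------------------------

#' Assign Ig domains and receptors to reference families
#'
#' For each query domain the mean pairwise-deletion p-distance to every
#' family's reference rows is computed in the shared alignment frame. The
#' nearest family is assigned when the margin (second-best minus best mean
#' distance) reaches `ambiguity_margin`; otherwise the domain is
#' `unassigned`. Receptors take the majority family over their assigned
#' domains (ties or no assigned domain give `unassigned`) and are flagged
#' chimeric when their assigned domains span two or more families.
#'
#' @param query_aln `domain_alignment` (or named rows) of query domains.
#' @param reference_aln `domain_alignment` (or named rows) of reference
#'   domains, in the same coordinate frame as the queries.
#' @param reference_families Character vector of family labels, one per
#'   reference row.
#' @param ambiguity_margin Minimum distance margin for a confident call.
#' @param receptor_of Optional character vector mapping each query row to a
#'   receptor id (defaults to the query label up to the last `|`).
#' @return List of class `family_assignment` with `domains` (one row per
#'   query: mean distance per family, `best_family`, `margin`,
#'   `assigned_family`) and `receptors` (`receptor_id`, `family_call`,
#'   `vote_fraction`, `chimeric`).
#' @export
assign_family <- function(query_aln, reference_aln, reference_families,
                          ambiguity_margin = 0.05, receptor_of = NULL) {
  if (!inherits(query_aln, "domain_alignment")) {
    query_aln <- as_domain_alignment(query_aln)
  }
  if (!inherits(reference_aln, "domain_alignment")) {
    reference_aln <- as_domain_alignment(reference_aln)
  }
  if (length(reference_families) != length(reference_aln$labels)) {
    stop("one family label per reference row is required")
  }
  fams <- sort(unique(reference_families))
  if (length(fams) < 1L || any(!nzchar(fams))) {
    stop("reference set must carry non-empty family labels")
  }
  if (query_aln$column_count != reference_aln$column_count) {
    stop("queries and references must share one coordinate frame")
  }
  qn <- length(query_aln$labels)
  meand <- matrix(NA_real_, qn, length(fams),
                  dimnames = list(query_aln$labels, fams))
  for (q in seq_len(qn)) {
    for (f in seq_along(fams)) {
      refs <- reference_aln$rows[reference_families == fams[f]]
      ds <- vapply(refs, function(r) {
        p_distance(query_aln$rows[[q]], r)$distance
      }, numeric(1))
      ds <- ds[!is.na(ds)]
      meand[q, f] <- if (length(ds)) mean(ds) else NA_real_
    }
  }
  best_fam <- character(qn)
  margin <- numeric(qn)
  assigned <- character(qn)
  for (q in seq_len(qn)) {
    v <- meand[q, ]
    if (all(is.na(v))) {
      best_fam[q] <- NA_character_
      margin[q] <- NA_real_
      assigned[q] <- "unassigned"
      next
    }
    o <- order(v)
    best_fam[q] <- fams[o[1]]
    margin[q] <- if (length(fams) > 1L) v[o[2]] - v[o[1]] else Inf
    assigned[q] <- if (margin[q] >= ambiguity_margin) fams[o[1]] else
      "unassigned"
  }
  domains <- data.frame(domain_id = query_aln$labels,
                        as.data.frame(meand, row.names = NULL),
                        best_family = best_fam, margin = margin,
                        assigned_family = assigned,
                        stringsAsFactors = FALSE)
  names(domains)[seq_along(fams) + 1L] <- paste0("dist_", fams)
  if (is.null(receptor_of)) {
    receptor_of <- sub("\\|[^|]*$", "", query_aln$labels)
  }
  receptors <- do.call(rbind, lapply(split(seq_len(qn), receptor_of),
                                     function(ix) {
    calls <- assigned[ix]
    calls <- calls[calls != "unassigned"]
    if (length(calls) == 0L) {
      return(data.frame(family_call = "unassigned", vote_fraction = NA_real_,
                        chimeric = FALSE, stringsAsFactors = FALSE))
    }
    tab <- sort(table(calls), decreasing = TRUE)
    tied <- sum(tab == tab[1]) > 1L
    data.frame(
      family_call = if (tied) "unassigned" else names(tab)[1],
      vote_fraction = as.numeric(tab[1]) / length(calls),
      chimeric = length(tab) > 1L,
      stringsAsFactors = FALSE
    )
  }))
  receptors <- data.frame(receptor_id = rownames(receptors), receptors,
                          row.names = NULL, stringsAsFactors = FALSE)
  structure(list(domains = domains, receptors = receptors,
                 ambiguity_margin = ambiguity_margin),
            class = "family_assignment")
}

#' @export
print.family_assignment <- function(x, ...) {
  cat("Family assignment: ", nrow(x$domains), " domains, ",
      nrow(x$receptors), " receptors\n", sep = "")
  print(table(x$receptors$family_call))
  invisible(x)
}
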