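# Candidate-gene discovery: six-frame ORF finding on contigs and Ig-domain
# detection on the predicted proteins with windowed PSSM log-odds scoring.
# Together these implement the ORF -> Ig-domain filtering funnel.

#' Find open reading frames on a contig
#'
#' Scans all six reading frames for ATG-to-stop spans encoding at least
#' `min_aa_length` amino acids (stop excluded). Nested ORFs sharing a stop
#' codon report only the longest (i.e. the most 5' start per stop). Codons
#' containing `N` are treated as neither start nor stop and translate to `X`.
#'
#' @param contig Character scalar of DNA (A/C/G/T/N), or a named character
#'   vector of length 1 whose name is used as the contig id.
#' @param min_aa_length Minimum protein length in residues (stop removed).
#' @param contig_id Contig identifier; defaults to the name of `contig`.
#' @return A data.frame with one row per ORF: `orf_id`, `contig_id`, `start`,
#'   `end` (0-based half-open, contig coordinates, stop codon included),
#'   `strand`, `frame` and `protein`. Rows are ordered by contig position,
#'   then `+` before `-` at equal start.
#' @export
find_orfs <- function(contig, min_aa_length = 100L, contig_id = NULL) {
  if (is.null(contig_id)) contig_id <- names(contig) %||% "contig"
  seq <- toupper(unname(contig))
  if (grepl("[^ACGTN]", seq)) {
    stop("contig contains non-nucleotide characters other than N")
  }
  len <- nchar(seq)
  res <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp(seq)
    starts <- find_all(s, "ATG")
    stop_pos <- sort(unlist(lapply(STOP_CODONS, find_all, x = s)))
    for (frame in 0:2) {
      fs <- starts[(starts - 1L) %% 3L == frame]
      fe <- stop_pos[(stop_pos - 1L) %% 3L == frame]
      if (length(fs) == 0L || length(fe) == 0L) next
      prev_stop <- 0L
      si <- 1L
      for (e in fe) {
        # earliest start after the previous in-frame stop gives the longest
        # ORF ending at this stop
        while (si <= length(fs) && fs[si] <= prev_stop) si <- si + 1L
        if (si <= length(fs) && fs[si] < e) {
          a <- fs[si]
          n_aa <- (e - a) %/% 3L
          if (n_aa >= min_aa_length) {
            # local (strand) 1-based [a, e+2] -> contig 0-based half-open
            if (strand == "+") {
              c0 <- a - 1L
              c1 <- e + 2L
            } else {
              c0 <- len - (e + 2L)
              c1 <- len - a + 1L
            }
            res[[length(res) + 1L]] <- list(
              contig_id = contig_id, start = c0, end = c1,
              strand = strand, frame = frame,
              protein = translate_dna(substr(s, a, e - 1L))
            )
          }
        }
        prev_stop <- e
      }
    }
  }
  if (length(res) == 0L) {
    return(data.frame(orf_id = character(0), contig_id = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), frame = integer(0),
                      protein = character(0), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, lapply(res, as.data.frame, stringsAsFactors = FALSE))
  df <- df[order(df$start, df$strand, df$end), , drop = FALSE]
  df <- data.frame(
    orf_id = sprintf("%s_orf%03d", contig_id, seq_len(nrow(df))),
    df, row.names = NULL, stringsAsFactors = FALSE
  )
  df
}

# 1-based start positions of all (possibly overlapping) occurrences of a
# fixed trinucleotide in x.
find_all <- function(x, pattern) {
  hits <- gregexpr(pattern, x, fixed = TRUE)[[1]]
  if (hits[1] == -1L) integer(0) else as.integer(hits)
}

#' Build a position-specific scoring matrix from aligned examples
#'
#' Log-odds are taken against a uniform background over the 20 standard
#' residues, with pseudocount smoothing:
#' `entry(i, a) = ln((count(i, a) + pc/20) / (n + pc)) - ln(1/20)`.
#'
#' @param aligned_examples Character vector of equal-length amino-acid
#'   sequences (no gaps).
#' @param family Family label attached to the profile.
#' @param pseudocount Positive smoothing mass distributed over residues.
#' @return An object of class `domain_profile`: list with `family`, `matrix`
#'   (length x 20 log-odds, columns in `AA_ALPHABET` order), `length` and
#'   `consensus` (per-column argmax residue).
#' @export
build_pssm <- function(aligned_examples, family = "fam", pseudocount = 1) {
  if (length(aligned_examples) < 1L) stop("need at least one example")
  if (pseudocount <= 0) stop("pseudocount must be positive")
  lens <- nchar(aligned_examples)
  if (length(unique(lens)) != 1L) stop("examples must all have equal length")
  L <- lens[1]
  n <- length(aligned_examples)
  chars <- do.call(rbind, strsplit(aligned_examples, "", fixed = TRUE))
  counts <- vapply(AA_ALPHABET, function(a) colSums(chars == a),
                   numeric(L))
  if (L == 1L) counts <- matrix(counts, nrow = 1L,
                                dimnames = list(NULL, AA_ALPHABET))
  mat <- log((counts + pseudocount / 20) / (n + pseudocount)) - log(1 / 20)
  consensus <- paste_chars(AA_ALPHABET[max.col(mat, ties.method = "first")])
  structure(list(family = family, matrix = mat, length = L,
                 consensus = consensus),
            class = "domain_profile")
}

#' @export
print.domain_profile <- function(x, ...) {
  cat("Domain profile '", x$family, "': ", x$length, " columns, self-score ",
      sprintf("%.1f", profile_self_score(x)), "\n", sep = "")
  invisible(x)
}

#' Maximum attainable window score of a profile
#'
#' The sum of per-column log-odds maxima; the score a profile assigns to
#' its own consensus.
#'
#' @param profile A `domain_profile`.
#' @return Numeric self-score.
#' @export
profile_self_score <- function(profile) {
  sum(apply(profile$matrix, 1L, max))
}

#' Default score threshold for domain scanning
#'
#' Half the mean profile self-score (sum of per-column log-odds maxima)
#' across the supplied profiles. Random proteins score near zero under
#' uniform-background log-odds, so half self-score separates true domains
#' from background decisively at the package's divergence defaults.
#'
#' @param profiles List of `domain_profile` objects.
#' @return Numeric threshold.
#' @export
default_domain_threshold <- function(profiles) {
  0.5 * mean(vapply(profiles, profile_self_score, numeric(1)))
}

#' Scan a protein for Ig-domain profile hits
#'
#' Scores every window of profile length against every family profile.
#' Windows whose best family score reaches `score_threshold` are candidate
#' hits; overlapping candidates are resolved greedily by descending score
#' (ties by leftmost start) and the retained hits are reported left to right.
#' Ambiguous residues (`X`) score as the per-column mean.
#'
#' @param protein Non-empty amino-acid string.
#' @param profiles List of `domain_profile` objects of equal length.
#' @param score_threshold Minimum best-family window score; `NULL` uses
#'   [default_domain_threshold()].
#' @param protein_id Identifier recorded on each hit.
#' @return data.frame with `protein_id`, `aa_start`, `aa_end` (0-based
#'   half-open residue interval), `best_family`, `score`, and one
#'   `score_<family>` column per profile. Zero rows if the protein is
#'   shorter than the profiles.
#' @export
scan_domains <- function(protein, profiles, score_threshold = NULL,
                         protein_id = "protein") {
  if (!nzchar(protein)) stop("protein must be non-empty")
  if (inherits(profiles, "domain_profile")) profiles <- list(profiles)
  L <- unique(vapply(profiles, function(p) p$length, integer(1)))
  if (length(L) != 1L) stop("profiles must all have the same length")
  if (is.null(score_threshold)) {
    score_threshold <- default_domain_threshold(profiles)
  }
  fams <- vapply(profiles, function(p) p$family, character(1))
  empty <- data.frame(protein_id = character(0), aa_start = integer(0),
                      aa_end = integer(0), best_family = character(0),
                      score = numeric(0), stringsAsFactors = FALSE)
  P <- nchar(protein)
  if (P < L) return(empty)
  aa <- split_chars(protein)
  idx <- match(aa, AA_ALPHABET) # NA for X or other ambiguity
  n_win <- P - L + 1L
  scores <- matrix(0, n_win, length(profiles))
  for (k in seq_along(profiles)) {
    mat <- profiles[[k]]$matrix
    col_mean <- rowMeans(mat)
    acc <- numeric(n_win)
    for (off in seq_len(L)) {
      ix <- idx[off:(off + n_win - 1L)]
      v <- mat[cbind(off, ix)]
      v[is.na(ix)] <- col_mean[off]
      acc <- acc + v
    }
    scores[, k] <- acc
  }
  best <- apply(scores, 1L, max)
  best_fam <- fams[max.col(scores, ties.method = "first")]
  keep <- which(best >= score_threshold)
  if (length(keep) == 0L) return(empty)
  # greedy non-overlap resolution: descending score, ties leftmost
  ord <- keep[order(-best[keep], keep)]
  chosen <- integer(0)
  for (w in ord) {
    if (!any(abs(chosen - w) < L)) chosen <- c(chosen, w)
  }
  chosen <- sort(chosen)
  out <- data.frame(
    protein_id = protein_id,
    aa_start = chosen - 1L,
    aa_end = chosen - 1L + L,
    best_family = best_fam[chosen],
    score = best[chosen],
    stringsAsFactors = FALSE
  )
  sc <- as.data.frame(scores[chosen, , drop = FALSE])
  names(sc) <- paste0("score_", fams)
  cbind(out, sc)
}

#' Keep candidate ORFs whose proteins contain Ig-domain hits
#'
#' @param orfs data.frame from [find_orfs()] (any rows with an `orf_id`).
#' @param hits data.frame of domain hits whose `protein_id` values reference
#'   `orfs$orf_id`.
#' @return The subset of `orfs` with at least one hit, in the original order,
#'   with attribute `funnel` carrying `c(input = ..., retained = ...)`.
#' @export
filter_ig_candidates <- function(orfs, hits) {
  keep <- orfs$orf_id %in% unique(hits$protein_id)
  out <- orfs[keep, , drop = FALSE]
  attr(out, "funnel") <- c(input = nrow(orfs), retained = nrow(out))
  out
}
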