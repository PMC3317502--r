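# Synthetic receptor-gene fixtures with known truth: family profiles,
# single genes, whole genome-like bundles (contigs + decoy ORFs + truth
# annotation) and simulated short expression reads. Every downstream stage
# of the pipeline is validated against the truth recorded here.

SIGNAL_POOL <- c("S", "T", "A", "G", "P", "Q", "N")
STALK_POOL  <- c("S", "T", "P", "E", "K", "G", "D", "Q")
TAIL_POOL   <- c("S", "T", "E", "K", "Q", "N", "P", "G", "D", "H", "A")
TM_POOL     <- c("L", "I", "V", "F", "A", "M")
TM_LENGTH   <- 21L
SIGNAL_LENGTH <- 20L
STALK_LENGTH <- 10L
TAIL_LENGTH <- 30L

#' Build a set of related family consensus profiles
#'
#' Families are simulated as descendants of one random ancestral Ig-domain
#' consensus: each family consensus mutates the ancestor at a per-site rate
#' of half the requested inter-family divergence, giving expected pairwise
#' family divergence close to `inter_family_divergence`. Any family pair
#' differing at fewer than `inter_family_divergence / 2` of sites triggers
#' regeneration of the later family.
#'
#' @param seed Integer seed; output is a deterministic function of it.
#' @param family_labels At least two unique family names.
#' @param domain_length Consensus length in residues (at least 30).
#' @param inter_family_divergence Target divergence fraction in (0, 1).
#' @return Object of class `family_profiles`: list with `family_labels`,
#'   `domain_consensus` (named character), `domain_length`,
#'   `inter_family_divergence`, `generation_seed`.
#' @export
build_profiles <- function(seed, family_labels = c("famA", "famB", "famC"),
                           domain_length = 90L,
                           inter_family_divergence = 0.4) {
  if (length(family_labels) < 2L) stop("need at least two families")
  if (anyDuplicated(family_labels)) stop("family labels must be unique")
  if (domain_length < 30L) stop("domain_length must be at least 30")
  if (inter_family_divergence <= 0 || inter_family_divergence >= 1) {
    stop("inter_family_divergence must lie strictly between 0 and 1")
  }
  min_diff <- inter_family_divergence / 2
  cons <- with_seed(seed, {
    ancestor <- paste_chars(sample(AA_ALPHABET, domain_length,
                                   replace = TRUE))
    out <- character(length(family_labels))
    for (k in seq_along(family_labels)) {
      for (attempt in 1:100) {
        cand <- mutate_protein(ancestor, inter_family_divergence / 2)
        ok <- k == 1L ||
          all(vapply(out[seq_len(k - 1L)], function(prev) {
            diff_fraction(cand, prev) >= min_diff
          }, logical(1)))
        if (ok) break
        if (attempt == 100L) stop("could not satisfy divergence invariant")
      }
      out[k] <- cand
    }
    out
  })
  names(cons) <- family_labels
  structure(list(family_labels = family_labels, domain_consensus = cons,
                 domain_length = domain_length,
                 inter_family_divergence = inter_family_divergence,
                 generation_seed = seed),
            class = "family_profiles")
}

#' @export
print.family_profiles <- function(x, ...) {
  cat("Family profiles: ", paste(x$family_labels, collapse = ", "),
      " (domain length ", x$domain_length, ", inter-family divergence ",
      x$inter_family_divergence, ")\n", sep = "")
  invisible(x)
}

#' Single-example PSSMs for each family consensus
#'
#' @param profiles A `family_profiles` object.
#' @param pseudocount Passed to [build_pssm()].
#' @return Named list of `domain_profile` objects.
#' @export
profile_pssms <- function(profiles, pseudocount = 1) {
  out <- lapply(profiles$family_labels, function(f) {
    build_pssm(profiles$domain_consensus[[f]], family = f,
               pseudocount = pseudocount)
  })
  names(out) <- profiles$family_labels
  out
}

#' Generate reference domain sequences for family assignment
#'
#' @param profiles A `family_profiles` object.
#' @param n_per_family Reference sequences per family.
#' @param divergence Per-site mutation rate from the family consensus.
#' @param seed Integer seed.
#' @return List with `sequences` (named character, ids `<family>_ref<i>`)
#'   and `families` (label per sequence).
#' @export
reference_domains <- function(profiles, n_per_family = 3L,
                              divergence = 0.1, seed = 1L) {
  with_seed(seed, {
    seqs <- character(0)
    fams <- character(0)
    for (f in profiles$family_labels) {
      for (i in seq_len(n_per_family)) {
        seqs <- c(seqs, setNames(
          mutate_protein(profiles$domain_consensus[[f]], divergence),
          sprintf("%s_ref%d", f, i)))
        fams <- c(fams, f)
      }
    }
    list(sequences = seqs, families = fams)
  })
}

# Generator-side truth checks, implemented independently of the classifier
# module so the classifier can be validated against generated truth.
has_tm_window <- function(protein, window = 19L, threshold = 1.6) {
  aa <- split_chars(protein)
  if (length(aa) < window) return(FALSE)
  h <- unname(KD_HYDROPATHY[aa])
  h[is.na(h)] <- 0
  cs <- cumsum(c(0, h))
  means <- (cs[(window + 1L):length(cs)] - cs[1:(length(cs) - window)]) /
    window
  any(means >= threshold)
}

has_itim <- function(segment) {
  grepl(ITIM_REGEX, segment)
}

# 0-based end of the hydropathy segment the window detector would report
# (highest-peak run, ties to the most C-terminal), or NA when none passes.
tm_span_end <- function(protein, window = 19L, threshold = 1.6) {
  aa <- split_chars(protein)
  if (length(aa) < window) return(NA_integer_)
  h <- unname(KD_HYDROPATHY[aa])
  h[is.na(h)] <- 0
  cs <- cumsum(c(0, h))
  means <- (cs[(window + 1L):length(cs)] - cs[1:(length(cs) - window)]) /
    window
  pass <- means >= threshold
  if (!any(pass)) return(NA_integer_)
  r <- rle(pass)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  peak <- vapply(runs, function(k) max(means[starts[k]:ends[k]]),
                 numeric(1))
  best <- runs[which(peak == max(peak))]
  best <- best[length(best)]
  ends[best] + window - 1L
}

#' Synthesize one receptor gene with known truth
#'
#' Protein layout: signal peptide, `n_domains` mutated copies of the family
#' consensus, a stalk, a transmembrane block of 21 strongly hydrophobic
#' residues (omitted for soluble receptors; carrying one arginine for
#' activating receptors) and a cytoplasmic tail. Inhibitory tails carry an
#' implanted ITIM (`[V/L/S/N] x Y x x [L/V]`); activating and soluble tails
#' are drawn from a tyrosine-free residue pool. The final mutated protein
#' is re-checked against the class truth (transmembrane window present or
#' absent, tail motif present or absent, transmembrane arginine) and
#' resampled until it matches, so truth holds on the emitted sequence, not
#' merely by intent.
#'
#' Uses the current RNG stream; wrap calls in a seeded context for
#' reproducibility.
#'
#' @param profiles A `family_profiles` object.
#' @param family Family label present in `profiles`.
#' @param n_domains 2, 4 or 6 Ig domains.
#' @param class_label One of `"inhibitory"`, `"activating"`, `"soluble"`.
#' @param within_divergence Per-site domain mutation rate; must be below
#'   half the profiles' inter-family divergence.
#' @param gene_id Identifier for the gene.
#' @param max_attempts Resampling budget before failing.
#' @return Object of class `synthetic_gene`: list with `gene_id`, `family`,
#'   `n_ig_domains`, `class_label`, `protein`, `cds` (back-translated, with
#'   terminal stop codon), `domain_truth` (list of 0-based half-open
#'   residue intervals), `tm_truth` (interval or NULL) and `expressed`
#'   (filled by [build_fixture()]).
#' @export
synthesize_gene <- function(profiles, family, n_domains, class_label,
                            within_divergence = 0.15, gene_id = "gene",
                            max_attempts = 50L) {
  if (!family %in% profiles$family_labels) stop("unknown family: ", family)
  if (!n_domains %in% c(2L, 4L, 6L)) stop("n_domains must be 2, 4 or 6")
  class_label <- match.arg(class_label,
                           c("inhibitory", "activating", "soluble"))
  if (within_divergence >= profiles$inter_family_divergence / 2) {
    stop("within_divergence must be below half the inter-family divergence")
  }
  cons <- profiles$domain_consensus[[family]]
  L <- profiles$domain_length
  for (attempt in seq_len(max_attempts)) {
    signal <- paste_chars(c("M", sample(SIGNAL_POOL, SIGNAL_LENGTH - 1L,
                                        replace = TRUE)))
    domains <- vapply(seq_len(n_domains), function(i) {
      mutate_protein(cons, within_divergence)
    }, character(1))
    stalk <- paste_chars(sample(STALK_POOL, STALK_LENGTH, replace = TRUE))
    soluble <- class_label == "soluble"
    tm <- if (soluble) "" else {
      block <- sample(TM_POOL, TM_LENGTH, replace = TRUE)
      if (class_label == "activating") {
        block[sample(5:(TM_LENGTH - 5L), 1L)] <- "R"
      }
      paste_chars(block)
    }
    tail_res <- sample(TAIL_POOL, TAIL_LENGTH, replace = TRUE)
    if (class_label == "inhibitory") {
      # keep the motif clear of the membrane-proximal tail residues that a
      # hydropathy window anchored in the TM block can still span
      pos <- sample(13:(TAIL_LENGTH - 5L), 1L)
      motif <- c(sample(c("V", "L", "S", "N"), 1L),
                 sample(TAIL_POOL, 1L), "Y",
                 sample(TAIL_POOL, 2L, replace = TRUE),
                 sample(c("L", "V"), 1L))
      tail_res[pos:(pos + 5L)] <- motif
    }
    tail <- paste_chars(tail_res)
    protein <- paste0(signal, paste(domains, collapse = ""), stalk, tm, tail)
    ecto_end <- SIGNAL_LENGTH + n_domains * L + STALK_LENGTH
    tm_truth <- if (soluble) NULL else c(ecto_end, ecto_end + TM_LENGTH)
    tail_seq <- substr(protein, ecto_end + nchar(tm) + 1L, nchar(protein))
    detected_end <- tm_span_end(protein)
    ok <- if (soluble) {
      !has_tm_window(protein)
    } else if (class_label == "inhibitory") {
      # the motif must survive tail scanning downstream of the detected
      # hydropathy segment, not merely of the generated block
      !is.na(detected_end) &&
        has_itim(substr(protein, detected_end + 1L, nchar(protein)))
    } else {
      !is.na(detected_end) && grepl("R", tm, fixed = TRUE) &&
        !has_itim(tail_seq)
    }
    if (ok) {
      domain_truth <- lapply(seq_len(n_domains), function(i) {
        s <- SIGNAL_LENGTH + (i - 1L) * L
        c(s, s + L)
      })
      return(structure(list(
        gene_id = gene_id, family = family, n_ig_domains = n_domains,
        class_label = class_label, protein = protein,
        cds = backtranslate(protein), domain_truth = domain_truth,
        tm_truth = tm_truth, expressed = NA
      ), class = "synthetic_gene"))
    }
  }
  stop("could not realise class '", class_label, "' for gene ", gene_id,
       " within ", max_attempts, " attempts")
}

#' @export
print.synthetic_gene <- function(x, ...) {
  cat(sprintf("Synthetic gene %s: %s, %d Ig domains, %s, %d aa\n",
              x$gene_id, x$family, x$n_ig_domains, x$class_label,
              nchar(x$protein)))
  invisible(x)
}

#' Default fixture composition
#'
#' Twenty-six Ig-receptor genes mirroring the repertoire structure this
#' package targets: sixteen LILR-like receptors (seven inhibitory, four
#' activating, five soluble; a mix of 2- and 4-domain architectures), six
#' KIR-like two-domain receptors (not expressed, providing the
#' non-LILR-like fraction of the candidate funnel) and four PIR-like
#' six-domain receptors.
#'
#' @return data.frame with columns `family`, `n_domains`, `class`,
#'   `expressed`, `n`.
#' @export
default_gene_spec <- function() {
  data.frame(
    family = c("famA", "famA", "famA", "famA", "famA", "famB", "famB",
               "famC"),
    n_domains = c(4L, 2L, 4L, 2L, 4L, 2L, 2L, 6L),
    class = c("inhibitory", "inhibitory", "activating", "soluble",
              "soluble", "inhibitory", "activating", "inhibitory"),
    expressed = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, TRUE),
    n = c(4L, 3L, 4L, 3L, 2L, 3L, 3L, 4L),
    stringsAsFactors = FALSE
  )
}

#' Build a genome-like fixture bundle
#'
#' Generates the requested receptor genes and decoy ORFs (valid open
#' reading frames whose products carry no Ig-domain material), places them
#' without overlap on `n_contigs` contigs on both strands separated by
#' AT-only spacers (which contain stop codons in all six frames and no
#' start codons, so open reading frames never bridge placements), and
#' verifies by re-scanning that the contigs contain exactly the placed
#' ORFs at the fixture's minimum ORF length, regenerating any placement
#' that spawns a spurious ORF.
#'
#' @param gene_spec data.frame as in [default_gene_spec()].
#' @param decoy_orf_count Number of non-Ig decoy ORFs.
#' @param intergenic_length Spacer length between placements (>= 24 nt).
#' @param seed Integer seed governing the whole bundle.
#' @param profiles Optional `family_profiles`; built from the seed when
#'   omitted.
#' @param n_contigs Number of contigs to distribute placements over.
#' @param min_orf_aa Minimum ORF length (residues) the fixture guarantees
#'   to be clean at; also the discovery default.
#' @param within_divergence Per-site domain mutation rate for genes.
#' @return Object of class `ig_fixture`: list with `contigs` (named DNA
#'   strings), `genes` (list of `synthetic_gene` with placements),
#'   `orfs` (truth features for genes and decoys, with `ig_domain` flag),
#'   `truth_table`, `profiles` and `params`.
#' @export
build_fixture <- function(gene_spec = default_gene_spec(),
                          decoy_orf_count = 51L,
                          intergenic_length = 300L,
                          seed = 1L,
                          profiles = NULL,
                          n_contigs = 3L,
                          min_orf_aa = 100L,
                          within_divergence = 0.15) {
  if (sum(gene_spec$n) < 1L) stop("gene_spec must request at least one gene")
  if (decoy_orf_count < 0L) stop("decoy_orf_count must be non-negative")
  if (intergenic_length < 24L) stop("intergenic_length must be at least 24")
  if (is.null(profiles)) {
    profiles <- build_profiles(derive_seed(seed, 1L))
  }
  pssms <- profile_pssms(profiles)
  threshold <- default_domain_threshold(pssms)
  with_seed(derive_seed(seed, 2L), {
    # expand the spec into per-gene rows
    rows <- gene_spec[rep(seq_len(nrow(gene_spec)), gene_spec$n), , drop = FALSE]
    n_genes <- nrow(rows)
    gene_ids <- sprintf("gene%02d", seq_len(n_genes))
    genes <- lapply(seq_len(n_genes), function(k) {
      g <- synthesize_gene(profiles, rows$family[k], rows$n_domains[k],
                           rows$class[k], within_divergence, gene_ids[k])
      g$expressed <- rows$expressed[k]
      g
    })
    make_decoy <- function(id) {
      for (attempt in 1:50) {
        len <- sample(seq(min_orf_aa + 10L, min_orf_aa + 60L), 1L)
        prot <- paste_chars(c("M", sample(AA_ALPHABET, len - 1L,
                                          replace = TRUE)))
        if (nrow(scan_domains(prot, pssms, threshold)) == 0L) {
          return(list(decoy_id = id, protein = prot,
                      cds = backtranslate(prot)))
        }
      }
      stop("could not generate a domain-free decoy ORF")
    }
    decoys <- lapply(sprintf("decoy%02d", seq_len(decoy_orf_count)),
                     make_decoy)
    segments <- c(
      lapply(genes, function(g) list(id = g$gene_id, cds = g$cds,
                                     is_gene = TRUE)),
      lapply(decoys, function(d) list(id = d$decoy_id, cds = d$cds,
                                      is_gene = FALSE))
    )
    ord <- sample.int(length(segments))
    segments <- segments[ord]
    strands <- sample(c("+", "-"), length(segments), replace = TRUE)
    if (length(unique(strands)) == 1L && length(strands) > 1L) {
      strands[1] <- setdiff(c("+", "-"), strands[1])
    }
    contig_of <- rep(seq_len(n_contigs), length.out = length(segments))
    spacer <- substr(strrep("TTAA", ceiling(intergenic_length / 4) + 1L),
                     1L, intergenic_length)
    assemble <- function() {
      contigs <- setNames(rep("", n_contigs),
                          sprintf("contig%d", seq_len(n_contigs)))
      feats <- list()
      for (k in seq_along(segments)) {
        ci <- contig_of[k]
        s <- segments[[k]]$cds
        if (strands[k] == "-") s <- revcomp(s)
        start <- nchar(contigs[ci]) + intergenic_length
        contigs[ci] <- paste0(contigs[ci], spacer, s)
        feats[[k]] <- data.frame(
          feature_id = segments[[k]]$id,
          contig_id = names(contigs)[ci],
          start = start, end = start + nchar(s),
          strand = strands[k],
          ig_domain = segments[[k]]$is_gene,
          stringsAsFactors = FALSE
        )
      }
      contigs <- vapply(contigs, function(x) paste0(x, spacer), character(1))
      list(contigs = contigs, feats = do.call(rbind, feats))
    }
    for (round in 1:30) {
      asm <- assemble()
      spurious <- character(0)
      for (ci in names(asm$contigs)) {
        found <- find_orfs(asm$contigs[[ci]], min_orf_aa, contig_id = ci)
        truth <- asm$feats[asm$feats$contig_id == ci, , drop = FALSE]
        key_f <- paste(found$start, found$end, found$strand)
        key_t <- paste(truth$start, truth$end, truth$strand)
        if (!all(key_t %in% key_f)) {
          stop("internal error: placed ORF not recovered on ", ci)
        }
        extra <- which(!(key_f %in% key_t))
        for (e in extra) {
          ov <- truth$feature_id[truth$start < found$end[e] &
                                   truth$end > found$start[e]]
          spurious <- c(spurious, ov)
        }
      }
      if (length(spurious) == 0L) break
      # regenerate every placement implicated in a spurious ORF
      for (id in unique(spurious)) {
        k <- which(vapply(segments, function(s) s$id, character(1)) == id)
        if (grepl("^gene", id)) {
          gi <- which(gene_ids == id)
          g <- synthesize_gene(profiles, rows$family[gi], rows$n_domains[gi],
                               rows$class[gi], within_divergence, id)
          g$expressed <- rows$expressed[gi]
          genes[[gi]] <- g
          segments[[k]]$cds <- g$cds
        } else {
          d <- make_decoy(id)
          di <- which(vapply(decoys, function(x) x$decoy_id,
                             character(1)) == id)
          decoys[[di]] <- d
          segments[[k]]$cds <- d$cds
        }
      }
      if (round == 30L) stop("could not build a spurious-ORF-free fixture")
    }
    feats <- asm$feats[order(asm$feats$contig_id, asm$feats$start), ,
                       drop = FALSE]
    rownames(feats) <- NULL
    # record placements on the gene objects
    for (gi in seq_along(genes)) {
      f <- feats[feats$feature_id == genes[[gi]]$gene_id, ]
      genes[[gi]]$placement <- list(contig_id = f$contig_id,
                                    start = f$start, end = f$end,
                                    strand = f$strand)
    }
    truth_table <- data.frame(
      gene_id = vapply(genes, `[[`, character(1), "gene_id"),
      family = vapply(genes, `[[`, character(1), "family"),
      class = vapply(genes, `[[`, character(1), "class_label"),
      n_domains = vapply(genes, `[[`, integer(1), "n_ig_domains"),
      expressed = vapply(genes, `[[`, logical(1), "expressed"),
      stringsAsFactors = FALSE
    )
    structure(list(
      contigs = asm$contigs, genes = genes, decoys = decoys, orfs = feats,
      truth_table = truth_table, profiles = profiles,
      params = list(gene_spec = gene_spec, decoy_orf_count = decoy_orf_count,
                    intergenic_length = intergenic_length, seed = seed,
                    n_contigs = n_contigs, min_orf_aa = min_orf_aa,
                    within_divergence = within_divergence)
    ), class = "ig_fixture")
  })
}

#' @export
print.ig_fixture <- function(x, ...) {
  cat(sprintf(paste0("Ig-receptor fixture: %d genes + %d decoy ORFs on %d",
                     " contigs (%d kb), seed %d\n"),
              length(x$genes), length(x$decoys), length(x$contigs),
              round(sum(nchar(x$contigs)) / 1000), x$params$seed))
  print(x$truth_table[, c("family", "class", "expressed")] |>
          (\(d) table(d$family, d$class))())
  invisible(x)
}

#' Simulate fixed-length expression reads from expressed transcripts
#'
#' Reads are drawn uniformly from the coding sequences of expressed genes,
#' on both strands, with per-transcript counts Poisson-distributed around
#' `depth * transcript_length / read_length` and independent per-base
#' substitution errors at `error_rate`.
#'
#' @param bundle An `ig_fixture`.
#' @param depth Expected per-base coverage depth of expressed transcripts.
#' @param read_length Read length in bases (protocol default 36).
#' @param error_rate Per-base substitution probability (< 0.25).
#' @param seed Integer seed.
#' @return data.frame with `read_id`, `seq`, `transcript_id`, `true_pos`
#'   (0-based on the transcript), `strand`. Zero rows (with a warning)
#'   when no transcript is expressed.
#' @export
simulate_reads <- function(bundle, depth = 12, read_length = 36L,
                           error_rate = 0.01, seed = 1L) {
  if (error_rate < 0 || error_rate >= 0.25) {
    stop("error_rate must lie in [0, 0.25)")
  }
  expressed <- Filter(function(g) isTRUE(g$expressed), bundle$genes)
  empty <- data.frame(read_id = character(0), seq = character(0),
                      transcript_id = character(0), true_pos = integer(0),
                      strand = character(0), stringsAsFactors = FALSE)
  if (length(expressed) == 0L) {
    warning("no expressed transcripts; returning zero reads")
    return(empty)
  }
  min_len <- min(vapply(expressed, function(g) nchar(g$cds), integer(1)))
  if (read_length > min_len) {
    stop("read_length exceeds the shortest expressed transcript")
  }
  with_seed(seed, {
    out <- lapply(expressed, function(g) {
      len <- nchar(g$cds)
      n <- stats::rpois(1L, depth * len / read_length)
      if (n == 0L) return(empty)
      # edge-clamped start sampling: draw from the padded interval and
      # clamp, so expected per-base depth is uniform out to the transcript
      # ends (plain uniform starts leave terminal bases undercovered)
      pos <- sample.int(len + read_length - 1L, n, replace = TRUE) -
        read_length
      pos <- pmin(pmax(pos, 0L), len - read_length)
      strand <- sample(c("+", "-"), n, replace = TRUE)
      seqs <- substring(g$cds, pos + 1L, pos + read_length)
      flip <- strand == "-"
      seqs[flip] <- vapply(seqs[flip], revcomp, character(1))
      if (error_rate > 0) {
        seqs <- vapply(seqs, function(s) {
          b <- split_chars(s)
          hit <- stats::runif(length(b)) < error_rate
          if (any(hit)) {
            b[hit] <- vapply(b[hit], function(x) {
              sample(setdiff(c("A", "C", "G", "T"), x), 1L)
            }, character(1))
          }
          paste_chars(b)
        }, character(1), USE.NAMES = FALSE)
      }
      data.frame(read_id = sprintf("%s_r%05d", g$gene_id, seq_len(n)),
                 seq = unname(seqs), transcript_id = g$gene_id,
                 true_pos = pos, strand = strand, stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, out)
    rownames(df) <- NULL
    df
  })
}
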