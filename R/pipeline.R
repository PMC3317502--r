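# End-to-end orchestration: fixture generation, ORF/Ig-domain discovery,
# phylogenetic family assignment, novelty screening, structural
# classification and expression calling, with funnel counts and
# reproducibility metadata.

#' Default pipeline configuration
#'
#' Stage parameters default to the published analysis protocol where one
#' exists: 1000 bootstrap replicates, a 95 percent identity threshold for
#' redundancy, 36-base reads, mismatch costs 2 then 1, and the strict
#' more-than-99-percent expression rule. Remaining defaults are the
#' package's own documented choices.
#'
#' @param seed Master seed; every stochastic stage draws a sub-seed from it.
#' @param ... Named overrides for any configuration entry.
#' @return List of class `igrec_config`.
#' @export
pipeline_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    # fixture
    gene_spec = default_gene_spec(),
    decoy_orf_count = 51L,
    intergenic_length = 300L,
    n_contigs = 3L,
    within_divergence = 0.15,
    inter_family_divergence = 0.4,
    # discovery
    min_aa_length = 100L,
    domain_threshold = NULL, # NULL = half mean profile self-score
    # phylogenetics
    bootstrap_replicates = 1000L,
    n_reference_per_family = 3L,
    reference_divergence = 0.1,
    ambiguity_margin = 0.05,
    # redundancy
    identity_threshold = 95,
    # structure
    tm_window = 19L,
    tm_threshold = 1.6,
    # expression
    read_length = 36L,
    depth = 12,
    error_rate = 0.01,
    cost_initial = 2,
    cost_rescue = 1,
    expression_threshold = 99,
    stages = c("discovery", "phylo", "redundancy", "structure", "coverage")
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0L) {
    stop("unknown configuration entries: ", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "igrec_config")
}

#' @export
print.igrec_config <- function(x, ...) {
  cat("igrec pipeline configuration (seed ", x$seed, "):\n", sep = "")
  for (nm in setdiff(names(x), "gene_spec")) {
    cat(sprintf("  %-24s %s\n", nm, paste(format(x[[nm]]), collapse = " ")))
  }
  invisible(x)
}

# Construct annotated companion sequences from a fixture so the novelty
# stage has subjects exercising all three verdict branches: a co-located
# duplicate, a co-located alternative-transcript candidate (identical
# domains, diverged elsewhere) and a relocated identical copy.
annotated_companions <- function(fixture, seed) {
  genes <- Filter(function(g) g$n_ig_domains >= 2L, fixture$genes)
  picks <- with_seed(seed, sample(seq_along(genes), min(3L, length(genes))))
  kinds <- c("duplicate", "alt_transcript", "relocated")
  out <- list()
  with_seed(derive_seed(seed, 1L), {
    for (k in seq_along(picks)) {
      g <- genes[[picks[k]]]
      kind <- kinds[k]
      prot <- g$protein
      placement <- g$placement
      if (kind == "alt_transcript") {
        # keep every Ig domain verbatim; resample the scaffold regions so
        # whole-sequence identity drops well below the threshold
        aa <- split_chars(prot)
        in_domain <- logical(length(aa))
        for (d in g$domain_truth) in_domain[(d[1] + 1L):d[2]] <- TRUE
        aa[!in_domain] <- sample(AA_ALPHABET, sum(!in_domain),
                                 replace = TRUE)
        prot <- paste_chars(aa)
      } else if (kind == "relocated") {
        placement <- list(contig_id = "annotated_scaffold",
                          start = placement$start, end = placement$end,
                          strand = placement$strand)
      }
      out[[k]] <- list(
        id = sprintf("ann%02d_%s", k, kind),
        seq = prot,
        placement = placement,
        domains = vapply(g$domain_truth, function(d) {
          substr(prot, d[1] + 1L, d[2])
        }, character(1)),
        source_gene = g$gene_id, kind = kind
      )
    }
  })
  out
}

#' Run the full receptor characterisation pipeline
#'
#' Stages run in order: fixture generation, ORF discovery and Ig-domain
#' filtering, phylogenetic family assignment (with an NJ bootstrap tree
#' over all domains), novelty screening against annotated companions,
#' structural classification and expression calling. All randomness
#' derives from `config$seed`; reruns with the same configuration are
#' bit-identical.
#'
#' @param config An `igrec_config` from [pipeline_config()].
#' @param out_dir Optional directory for TSV/JSON/GFF3/newick/FASTA/FASTQ
#'   reports.
#' @return Object of class `igrec_run`; see Details.
#' @details The returned list carries `config`, `fixture`, `orfs`, `hits`,
#'   `candidates`, `assignment`, `tree`, `redundancy`, `classification`,
#'   `expression`, `dossiers` and `funnel`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "igrec_config"))
  stages <- config$stages
  t0 <- Sys.time()
  log_stage <- function(name, n_in, n_out) {
    message(sprintf("[igrec] %-10s in=%-5s out=%-5s elapsed=%.1fs",
                    name, n_in, n_out,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }

  profiles <- build_profiles(
    derive_seed(config$seed, 1L),
    inter_family_divergence = config$inter_family_divergence)
  fixture <- build_fixture(
    gene_spec = config$gene_spec,
    decoy_orf_count = config$decoy_orf_count,
    intergenic_length = config$intergenic_length,
    seed = config$seed, profiles = profiles,
    n_contigs = config$n_contigs,
    min_orf_aa = config$min_aa_length,
    within_divergence = config$within_divergence)
  log_stage("fixture", nrow(fixture$truth_table), length(fixture$contigs))

  run <- list(config = config, fixture = fixture)
  funnel <- list()

  # ---- discovery ----
  orfs <- do.call(rbind, lapply(names(fixture$contigs), function(ci) {
    find_orfs(fixture$contigs[[ci]], config$min_aa_length, contig_id = ci)
  }))
  pssms <- profile_pssms(profiles)
  threshold <- config$domain_threshold %||% default_domain_threshold(pssms)
  hits <- do.call(rbind, lapply(seq_len(nrow(orfs)), function(i) {
    scan_domains(orfs$protein[i], pssms, threshold,
                 protein_id = orfs$orf_id[i])
  }))
  candidates <- filter_ig_candidates(orfs, hits)
  funnel$n_orfs <- nrow(orfs)
  funnel$n_ig_candidates <- nrow(candidates)
  run$orfs <- orfs
  run$hits <- hits
  run$candidates <- candidates
  log_stage("discovery", nrow(orfs), nrow(candidates))
  if (!"discovery" %in% stages) {
    stop("the discovery stage cannot be disabled; downstream stages depend on it")
  }

  cand_hits <- hits[hits$protein_id %in% candidates$orf_id, , drop = FALSE]
  domain_seqs <- character(0)
  domain_receptor <- character(0)
  for (i in seq_len(nrow(cand_hits))) {
    pid <- cand_hits$protein_id[i]
    prot <- candidates$protein[match(pid, candidates$orf_id)]
    dom <- substr(prot, cand_hits$aa_start[i] + 1L, cand_hits$aa_end[i])
    k <- sum(domain_receptor == pid) + 1L
    domain_seqs <- c(domain_seqs, setNames(dom, sprintf("%s|d%d", pid, k)))
    domain_receptor <- c(domain_receptor, pid)
  }

  # ---- phylogenetic family assignment ----
  if ("phylo" %in% stages && length(domain_seqs) >= 2L) {
    refs <- reference_domains(profiles, config$n_reference_per_family,
                              config$reference_divergence,
                              derive_seed(config$seed, 3L))
    anchor <- pssms[[1]]
    aln <- build_domain_alignment(c(refs$sequences, domain_seqs), anchor)
    ref_aln <- as_domain_alignment(aln$rows[names(refs$sequences)])
    query_aln <- as_domain_alignment(aln$rows[names(domain_seqs)])
    assignment <- assign_family(query_aln, ref_aln, refs$families,
                                config$ambiguity_margin,
                                receptor_of = domain_receptor)
    tree <- bootstrap_supports(aln, config$bootstrap_replicates,
                               derive_seed(config$seed, 4L))
    run$assignment <- assignment
    run$tree <- tree
    funnel$n_family_assigned <-
      sum(assignment$receptors$family_call != "unassigned")
    log_stage("phylo", length(domain_seqs), funnel$n_family_assigned)
  }

  # ---- redundancy ----
  if ("redundancy" %in% stages) {
    subjects <- annotated_companions(fixture, derive_seed(config$seed, 5L))
    queries <- lapply(seq_len(nrow(candidates)), function(i) {
      oid <- candidates$orf_id[i]
      dom <- unname(domain_seqs[domain_receptor == oid])
      list(id = oid, seq = candidates$protein[i],
           placement = list(contig_id = candidates$contig_id[i],
                            start = candidates$start[i],
                            end = candidates$end[i]),
           domains = dom)
    })
    verdicts <- redundancy_screen(queries, subjects,
                                  config$identity_threshold)
    run$redundancy <- verdicts
    run$annotated <- subjects
    summ <- attr(verdicts, "summary")
    funnel$n_novel <- sum(summ$verdict == "novel")
    log_stage("redundancy", nrow(candidates), funnel$n_novel)
  }

  # ---- structural classification ----
  if ("structure" %in% stages) {
    classification <- classify_receptors(
      setNames(candidates$protein, candidates$orf_id),
      window = config$tm_window, threshold = config$tm_threshold)
    run$classification <- classification
    funnel$class_counts <- as.list(table(classification$class))
    log_stage("structure", nrow(candidates), nrow(classification))
  }

  # ---- expression ----
  if ("coverage" %in% stages) {
    reads <- simulate_reads(fixture, depth = config$depth,
                            read_length = config$read_length,
                            error_rate = config$error_rate,
                            seed = derive_seed(config$seed, 6L))
    refs_nt <- setNames(vapply(seq_len(nrow(candidates)), function(i) {
      s <- substr(fixture$contigs[[candidates$contig_id[i]]],
                  candidates$start[i] + 1L, candidates$end[i])
      if (candidates$strand[i] == "-") s <- revcomp(s)
      s
    }, character(1)), candidates$orf_id)
    expression <- call_expression(reads, refs_nt,
                                  cost_initial = config$cost_initial,
                                  cost_rescue = config$cost_rescue,
                                  expression_threshold =
                                    config$expression_threshold,
                                  read_length = config$read_length)
    run$reads <- reads
    run$expression <- expression
    funnel$n_expressed <- sum(expression$reports$expressed)
    log_stage("coverage", nrow(reads), funnel$n_expressed)
  }

  # ---- dossiers ----
  dossiers <- data.frame(candidate_id = candidates$orf_id,
                         contig_id = candidates$contig_id,
                         start = candidates$start, end = candidates$end,
                         strand = candidates$strand,
                         stringsAsFactors = FALSE)
  dossiers$n_ig_domains <- vapply(dossiers$candidate_id, function(id) {
    sum(cand_hits$protein_id == id)
  }, integer(1))
  if (!is.null(run$assignment)) {
    rr <- run$assignment$receptors
    m <- match(dossiers$candidate_id, rr$receptor_id)
    dossiers$family_call <- rr$family_call[m]
    dossiers$chimeric <- rr$chimeric[m]
  }
  if (!is.null(run$redundancy)) {
    summ <- attr(run$redundancy, "summary")
    m <- match(dossiers$candidate_id, summ$query_id)
    dossiers$novelty <- summ$verdict[m]
  }
  if (!is.null(run$classification)) {
    m <- match(dossiers$candidate_id, run$classification$protein_id)
    dossiers$class_call <- run$classification$class[m]
  }
  if (!is.null(run$expression)) {
    m <- match(dossiers$candidate_id, run$expression$reports$reference_id)
    dossiers$percent_mapped <- run$expression$reports$percent_mapped_int[m]
    dossiers$expressed <- run$expression$reports$expressed[m]
  }
  run$dossiers <- dossiers
  run$funnel <- funnel
  class(run) <- "igrec_run"

  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.igrec_run <- function(x, ...) {
  cat("igrec pipeline run (seed ", x$config$seed, ")\n", sep = "")
  cat("  ORFs found:          ", x$funnel$n_orfs, "\n")
  cat("  Ig-domain candidates:", x$funnel$n_ig_candidates, "\n")
  if (!is.null(x$funnel$n_family_assigned)) {
    cat("  family assigned:     ", x$funnel$n_family_assigned, "\n")
  }
  if (!is.null(x$funnel$n_novel)) {
    cat("  novel:               ", x$funnel$n_novel, "\n")
  }
  if (!is.null(x$funnel$class_counts)) {
    cc <- unlist(x$funnel$class_counts)
    cat("  classes:             ",
        paste(names(cc), cc, sep = "=", collapse = ", "), "\n")
  }
  if (!is.null(x$funnel$n_expressed)) {
    cat("  expressed:           ", x$funnel$n_expressed, "\n")
  }
  invisible(x)
}

#' Write all pipeline reports to a run directory
#'
#' @param run An `igrec_run`.
#' @param out_dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_fixture(run$fixture, file.path(out_dir, "fixture"))
  write_tsv(run$orfs, file.path(out_dir, "orfs.tsv"))
  rtracklayer::export(
    features_to_granges(data.frame(feature_id = run$orfs$orf_id,
                                   run$orfs[, -1], stringsAsFactors = FALSE)),
    file.path(out_dir, "orfs.gff3"), format = "gff3")
  write_tsv(run$hits, file.path(out_dir, "domain_hits.tsv"))
  if (!is.null(run$assignment)) {
    write_tsv(run$assignment$domains, file.path(out_dir,
                                                "domain_assignment.tsv"))
    write_tsv(run$assignment$receptors, file.path(out_dir,
                                                  "receptor_assignment.tsv"))
  }
  if (!is.null(run$tree)) {
    tr <- run$tree
    tr$node.label <- ifelse(is.na(tr$node.label), "",
                            sprintf("%d", round(tr$node.label)))
    ape::write.tree(tr, file.path(out_dir, "domains_nj_bootstrap.nwk"))
  }
  if (!is.null(run$redundancy)) {
    write_tsv(run$redundancy, file.path(out_dir, "redundancy.tsv"))
  }
  if (!is.null(run$classification)) {
    write_tsv(run$classification, file.path(out_dir, "classification.tsv"))
  }
  if (!is.null(run$expression)) {
    write_tsv(run$expression$reports, file.path(out_dir, "coverage.tsv"))
    write_reads_fastq(run$reads, file.path(out_dir, "reads.fq"))
  }
  write_tsv(run$dossiers, file.path(out_dir, "dossiers.tsv"))
  jsonlite::write_json(run$funnel, file.path(out_dir, "funnel.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  cfg <- run$config
  cfg$gene_spec <- NULL
  jsonlite::write_json(unclass(cfg), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' Summarise a repertoire from pipeline dossiers
#'
#' @param dossiers data.frame from an `igrec_run` (or the run itself).
#' @return List with `by_class`, `by_family`, `by_expressed` count tables
#'   and `n` (total dossiers). Class counts always sum to `n`.
#' @export
summarize_repertoire <- function(dossiers) {
  if (inherits(dossiers, "igrec_run")) dossiers <- dossiers$dossiers
  if (is.null(dossiers) || nrow(dossiers) == 0L) {
    stop("no dossiers to summarise")
  }
  out <- list(n = nrow(dossiers))
  if ("class_call" %in% names(dossiers)) {
    out$by_class <- table(dossiers$class_call)
  }
  if ("family_call" %in% names(dossiers)) {
    out$by_family <- table(dossiers$family_call)
  }
  if ("expressed" %in% names(dossiers)) {
    out$by_expressed <- table(dossiers$expressed)
  }
  out
}
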