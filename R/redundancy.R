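# Novelty adjudication: is a candidate a duplicate of, an alternative
# transcript of, or distinct from a previously annotated sequence? Evidence
# combines global percent identity, chromosomal overlap and identical Ig
# domains, codified into one total decision rule.

#' Overlap length of two contig intervals
#'
#' @param a,b Lists (or vectors) with `contig_id`, `start`, `end`
#'   (0-based half-open). Vectors are interpreted as `c(start, end)` on a
#'   shared contig.
#' @return Overlap in bp; 0 for different contigs or abutting intervals.
#' @export
interval_overlap <- function(a, b) {
  norm <- function(x) {
    if (is.list(x)) {
      list(contig = as.character(x$contig_id %||% "contig"),
           start = as.numeric(x$start), end = as.numeric(x$end))
    } else {
      list(contig = "contig", start = as.numeric(x[1]),
           end = as.numeric(x[2]))
    }
  }
  a <- norm(a); b <- norm(b)
  if (a$end < a$start || b$end < b$start) stop("interval end before start")
  if (a$contig != b$contig) return(0L)
  as.integer(max(0, min(a$end, b$end) - max(a$start, b$start)))
}

#' Count query domains identical to at least one subject domain
#'
#' Two domains are identical when their pairwise-deletion p-distance is
#' exactly zero (every compared column matches) in the shared alignment
#' frame.
#'
#' @param query_domains,subject_domains Character vectors of equal-length
#'   aligned domain rows.
#' @return Number of query domains with an identical subject partner.
#' @export
identical_domain_pairs <- function(query_domains, subject_domains) {
  if (length(query_domains) == 0L || length(subject_domains) == 0L) {
    return(0L)
  }
  sum(vapply(query_domains, function(q) {
    any(vapply(subject_domains, function(s) {
      pd <- p_distance(q, s)
      pd$defined && pd$distance == 0
    }, logical(1)))
  }, logical(1)))
}

#' Adjudicate novelty of a query sequence against an annotated subject
#'
#' Decision rule (identity threshold 95 percent by default):
#' * `duplicate` - identity at or above the threshold AND the loci overlap;
#' * `alt_transcript_candidate` - the loci overlap, identity is below the
#'   threshold, but every query Ig domain is identical to a subject domain
#'   (two transcripts plausibly from one gene);
#' * `novel` - everything else, including high identity at non-overlapping
#'   loci (paralogous copies at different positions are distinct sequences).
#'
#' @param query,subject Lists with `seq` (amino-acid string), `placement`
#'   (list with `contig_id`, `start`, `end`) and optionally `domains`
#'   (aligned domain rows for the identical-domain criterion).
#' @param identity_threshold Percent identity cut (protocol default 95).
#' @return A one-row data.frame: `query_id`, `subject_id`,
#'   `percent_identity`, `overlap_bp`, `identical_domain_count`,
#'   `all_domains_identical`, `verdict`.
#' @export
novelty_verdict <- function(query, subject, identity_threshold = 95) {
  pid <- percent_identity(query$seq, subject$seq)
  ov <- interval_overlap(query$placement, subject$placement)
  qd <- query$domains %||% character(0)
  sd <- subject$domains %||% character(0)
  idc <- identical_domain_pairs(qd, sd)
  all_ident <- length(qd) > 0L && idc == length(qd)
  verdict <- if (pid >= identity_threshold && ov > 0L) {
    "duplicate"
  } else if (ov > 0L && all_ident) {
    "alt_transcript_candidate"
  } else {
    "novel"
  }
  data.frame(query_id = query$id %||% "query",
             subject_id = subject$id %||% "subject",
             percent_identity = pid, overlap_bp = ov,
             identical_domain_count = idc,
             all_domains_identical = all_ident,
             verdict = verdict, stringsAsFactors = FALSE)
}

#' Compare every query against every annotated subject
#'
#' @param queries,subjects Lists of records as in [novelty_verdict()].
#' @param identity_threshold Percent identity cut.
#' @return data.frame of all pairwise verdicts, plus a per-query summary
#'   attribute `summary` taking the strongest evidence against novelty
#'   (duplicate > alt_transcript_candidate > novel).
#' @export
redundancy_screen <- function(queries, subjects, identity_threshold = 95) {
  if (length(subjects) == 0L) {
    ids <- vapply(queries, function(q) q$id %||% "query", character(1))
    out <- data.frame(query_id = character(0), subject_id = character(0),
                      percent_identity = numeric(0), overlap_bp = integer(0),
                      identical_domain_count = integer(0),
                      all_domains_identical = logical(0),
                      verdict = character(0), stringsAsFactors = FALSE)
    attr(out, "summary") <- data.frame(query_id = ids, verdict = "novel",
                                       stringsAsFactors = FALSE)
    return(out)
  }
  rows <- list()
  for (q in queries) {
    for (s in subjects) {
      rows[[length(rows) + 1L]] <- novelty_verdict(q, s, identity_threshold)
    }
  }
  out <- do.call(rbind, rows)
  rank <- c(novel = 1L, alt_transcript_candidate = 2L, duplicate = 3L)
  summ <- do.call(rbind, lapply(split(out, out$query_id), function(d) {
    data.frame(query_id = d$query_id[1],
               verdict = d$verdict[which.max(rank[d$verdict])],
               stringsAsFactors = FALSE)
  }))
  rownames(summ) <- NULL
  attr(out, "summary") <- summ
  out
}
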