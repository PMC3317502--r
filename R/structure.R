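# Structural classification of receptor proteins: transmembrane segment
# detection by Kyte-Doolittle hydropathy, ITIM motif scanning in the
# cytoplasmic tail, transmembrane arginine detection, and the combined
# inhibitory / activating / soluble call.

# ITIM consensus: [V/L/S/N] x Y x x [L/V], a 6-residue window.
ITIM_REGEX <- "[VLSN].Y..[LV]"

#' Predict a single transmembrane segment by sliding-window hydropathy
#'
#' Kyte-Doolittle hydropathy is averaged over sliding windows; the maximal
#' run of consecutive windows whose mean reaches `threshold` is reported,
#' extended to its full residue span. When several runs pass, the run with
#' the highest window mean wins; exact ties resolve to the most C-terminal
#' run (type I receptors carry their true transmembrane helix near the
#' C-terminus, so this avoids mistaking an N-terminal signal peptide for
#' the membrane anchor).
#'
#' @param protein Non-empty amino-acid string.
#' @param window Window width in residues.
#' @param threshold Minimum mean hydropathy for a window to pass.
#' @return A list with `aa_start`, `aa_end` (0-based half-open residue
#'   interval) and `mean_hydropathy` (best window mean inside the segment),
#'   or `NULL` when no window passes (including proteins shorter than the
#'   window).
#' @export
predict_tm <- function(protein, window = 19L, threshold = 1.6) {
  if (!nzchar(protein)) stop("protein must be non-empty")
  aa <- split_chars(protein)
  n <- length(aa)
  if (n < window) return(NULL)
  h <- unname(KD_HYDROPATHY[aa])
  h[is.na(h)] <- 0 # ambiguous residues are hydropathy-neutral
  wm <- stats::filter(h, rep(1 / window, window), sides = 1)
  wm <- as.numeric(wm[window:n]) # wm[i] = mean over residues i..i+window-1
  pass <- wm >= threshold
  if (!any(pass)) return(NULL)
  r <- rle(pass)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  peak <- vapply(runs, function(k) max(wm[starts[k]:ends[k]]), numeric(1))
  best <- runs[which(peak == max(peak))]
  best <- best[length(best)] # ties: most C-terminal run
  s_win <- starts[best]
  e_win <- ends[best]
  list(aa_start = s_win - 1L,
       aa_end = e_win - 1L + window,
       mean_hydropathy = max(wm[s_win:e_win]))
}

#' Scan a cytoplasmic tail for ITIM motifs
#'
#' Reports every 6-residue window at or after `tail_start` matching the
#' ITIM consensus `[V/L/S/N] x Y x x [L/V]`, overlapping matches included,
#' left to right.
#'
#' @param protein Amino-acid string.
#' @param tail_start 0-based residue position where the cytoplasmic tail
#'   begins (0 scans the whole protein).
#' @return data.frame with `position` (0-based window start),
#'   `matched_text` and `variant` (e.g. `"VxYxxL"`).
#' @export
scan_itims <- function(protein, tail_start = 0L) {
  n <- nchar(protein)
  if (tail_start > n) stop("tail_start beyond protein length")
  empty <- data.frame(position = integer(0), matched_text = character(0),
                      variant = character(0), stringsAsFactors = FALSE)
  if (n - tail_start < 6L) return(empty)
  starts <- seq.int(tail_start + 1L, n - 5L) # 1-based window starts
  win <- substring(protein, starts, starts + 5L)
  hit <- grepl(paste0("^", ITIM_REGEX, "$"), win)
  if (!any(hit)) return(empty)
  data.frame(
    position = starts[hit] - 1L,
    matched_text = win[hit],
    variant = paste0(substr(win[hit], 1L, 1L), "xYxx",
                     substr(win[hit], 6L, 6L)),
    stringsAsFactors = FALSE
  )
}

#' Does the transmembrane segment contain an arginine?
#'
#' Activating Ig-like receptors carry a charged arginine inside the
#' transmembrane helix that recruits ITAM-bearing adaptors.
#'
#' @param protein Amino-acid string.
#' @param tm Transmembrane segment as returned by [predict_tm()].
#' @return TRUE iff at least one `R` lies within `[aa_start, aa_end)`.
#' @export
tm_arginine <- function(protein, tm) {
  if (is.null(tm)) stop("tm_arginine requires a transmembrane segment")
  seg <- substr(protein, tm$aa_start + 1L, tm$aa_end)
  grepl("R", seg, fixed = TRUE)
}

#' Classify a receptor as inhibitory, activating, soluble or unclassified
#'
#' Decision rule: no transmembrane segment gives `soluble`; a transmembrane
#' segment plus at least one cytoplasmic-tail ITIM gives `inhibitory`; a
#' transmembrane segment, no tail ITIM and a transmembrane arginine gives
#' `activating`; the remaining combination (membrane-anchored, no signalling
#' feature) is `unclassified`. ITIMs are only scanned C-terminal of the
#' transmembrane segment; for soluble candidates motif matches anywhere in
#' the chain are reported separately as non-signalling matches and do not
#' affect the call.
#'
#' @param protein Non-empty amino-acid string.
#' @param protein_id Identifier carried into the result.
#' @param window,threshold Hydropathy parameters for [predict_tm()].
#' @return Object of class `receptor_classification`: list with
#'   `protein_id`, `tm` (or NULL), `itims`, `nonsignalling_itims`,
#'   `tm_arginine` and `class_call`.
#' @export
classify_receptor <- function(protein, protein_id = "protein",
                              window = 19L, threshold = 1.6) {
  tm <- predict_tm(protein, window = window, threshold = threshold)
  if (is.null(tm)) {
    out <- list(protein_id = protein_id, tm = NULL,
                itims = scan_itims(protein, nchar(protein)),
                nonsignalling_itims = scan_itims(protein, 0L),
                tm_arginine = NA, class_call = "soluble")
    return(structure(out, class = "receptor_classification"))
  }
  itims <- scan_itims(protein, tm$aa_end)
  has_r <- tm_arginine(protein, tm)
  call <- if (nrow(itims) > 0L) "inhibitory"
          else if (has_r) "activating"
          else "unclassified"
  structure(list(protein_id = protein_id, tm = tm, itims = itims,
                 nonsignalling_itims = scan_itims(protein, 0L),
                 tm_arginine = has_r, class_call = call),
            class = "receptor_classification")
}

#' @export
print.receptor_classification <- function(x, ...) {
  tm_txt <- if (is.null(x$tm)) "no TM" else
    sprintf("TM %d-%d", x$tm$aa_start, x$tm$aa_end)
  cat(sprintf("%s: %s, %d ITIM(s), TM arginine: %s -> %s\n",
              x$protein_id, tm_txt, nrow(x$itims),
              ifelse(is.na(x$tm_arginine), "-", x$tm_arginine),
              x$class_call))
  invisible(x)
}

#' Classify a set of receptor proteins
#'
#' @param proteins Named character vector of amino-acid sequences.
#' @param window,threshold Hydropathy parameters for [predict_tm()].
#' @return data.frame with one row per protein: `protein_id`, `tm_start`,
#'   `tm_end` (NA when soluble), `n_itims`, `itim_variants`
#'   (comma-separated), `tm_arginine` and `class`.
#' @export
classify_receptors <- function(proteins, window = 19L, threshold = 1.6) {
  ids <- names(proteins) %||% paste0("protein", seq_along(proteins))
  rows <- lapply(seq_along(proteins), function(k) {
    cl <- classify_receptor(proteins[[k]], ids[k], window, threshold)
    data.frame(
      protein_id = ids[k],
      tm_start = if (is.null(cl$tm)) NA_integer_ else cl$tm$aa_start,
      tm_end = if (is.null(cl$tm)) NA_integer_ else cl$tm$aa_end,
      n_itims = nrow(cl$itims),
      itim_variants = paste(unique(cl$itims$variant), collapse = ","),
      tm_arginine = cl$tm_arginine,
      class = cl$class_call,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
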