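#' Penalty scheme for plant miRNA target scoring
#'
#' The classical plant small-RNA target rules: mismatches cost 1, G:U wobbles
#' 0.5, gaps 2, with penalties doubled in the 5' seed-proximal region (miRNA
#' positions 2-13), and a reporting cutoff of 4.
#'
#' @param mismatch,gu,gap per-event penalties.
#' @param double_from,double_to miRNA positions with doubled penalties.
#' @param cutoff maximum reportable score.
#' @return list of scoring constants.
#' @export
target_scheme <- function(mismatch = 1, gu = 0.5, gap = 2,
                          double_from = 2L, double_to = 13L, cutoff = 4) {
  list(mismatch = mismatch, gu = gu, gap = gap,
       double_from = double_from, double_to = double_to, cutoff = cutoff)
}

# pairing state of miRNA base m (5'->3') against target base t (the base it
# faces in the antiparallel duplex): WC match, G:U wobble, or mismatch
pair_state <- function(m, t) {
  wc <- c(A = "T", C = "G", G = "C", T = "A")
  ifelse(t == wc[m], "match",
         ifelse((m == "G" & t == "T") | (m == "T" & t == "G"),
                "GU", "mismatch"))
}

#' Score a miRNA against one candidate target site
#'
#' Aligns the miRNA (5'->3') antiparallel against a target site: miRNA
#' position k faces site position `length(site) - k + 1`. With
#' `gap_in = "none"` the site must have the miRNA's length; `"target"` allows
#' one unpaired (bulged) site base (site one longer), `"mirna"` one unpaired
#' miRNA base (site one shorter). Penalties follow `scheme`, doubled when the
#' penalized miRNA position (for a target bulge: the following miRNA
#' position) lies in the seed-proximal window.
#'
#' @param mirna miRNA sequence, 5'->3' (20-24 nt).
#' @param site target site sequence, 5'->3'.
#' @param scheme see [target_scheme()].
#' @param gap_in `"none"`, `"target"`, or `"mirna"`; where a single gap may
#'   sit. For gapped modes every gap position is tried and the best kept.
#' @return object of class `target_alignment`: list with `mirna`, `site`,
#'   `score`, `states` (per miRNA position: match/GU/mismatch/gap),
#'   `site_pos` (site position facing each miRNA position, NA at a gap), and
#'   `gap` (description of the gap, if any).
#' @export
score_target <- function(mirna, site, scheme = target_scheme(),
                         gap_in = c("none", "target", "mirna")) {
  gap_in <- match.arg(gap_in)
  m <- strsplit(norm_dna(mirna, allow_n = FALSE), "")[[1]]
  s <- strsplit(norm_dna(site, allow_n = FALSE), "")[[1]]
  L <- length(m)
  weight <- ifelse(seq_len(L) >= scheme$double_from &
                     seq_len(L) <= scheme$double_to, 2, 1)
  pen <- c(match = 0, GU = scheme$gu, mismatch = scheme$mismatch)

  ungapped <- function(mv, sv, mpos) {
    st <- unname(pair_state(mv, rev(sv)))
    list(states = st, score = sum(pen[st] * weight[mpos]))
  }

  if (gap_in == "none") {
    if (length(s) != L) stop("ungapped site must match the miRNA length")
    a <- ungapped(m, s, seq_len(L))
    out <- list(mirna = paste(m, collapse = ""), site = paste(s, collapse = ""),
                score = a$score, states = a$states,
                site_pos = rev(seq_len(L)), gap = NULL)
  } else if (gap_in == "mirna") {
    if (length(s) != L - 1L) stop("site must be one shorter than the miRNA")
    best <- NULL
    for (g in seq_len(L)) {
      mpos <- setdiff(seq_len(L), g)
      a <- ungapped(m[mpos], s, mpos)
      sc <- a$score + scheme$gap * weight[g]
      if (is.null(best) || sc < best$score) {
        states <- character(L); states[g] <- "gap"; states[mpos] <- a$states
        sp <- rep(NA_integer_, L); sp[mpos] <- rev(seq_len(L - 1L))
        best <- list(score = sc, states = states, site_pos = sp,
                     gap = list(where = "mirna", position = g))
      }
    }
    out <- c(list(mirna = paste(m, collapse = ""),
                  site = paste(s, collapse = "")), best)
  } else {
    if (length(s) != L + 1L) stop("site must be one longer than the miRNA")
    best <- NULL
    # site position g (counted 3'->5' in duplex orientation) is bulged out;
    # the doubling weight uses the miRNA position following the bulge
    for (g in seq_len(L + 1L)) {
      spos <- setdiff(seq_len(L + 1L), L + 2L - g)  # 5'->3' site index bulged
      a <- ungapped(m, s[spos], seq_len(L))
      wpos <- min(g, L)
      sc <- a$score + scheme$gap * weight[wpos]
      if (is.null(best) || sc < best$score) {
        sp <- rev(spos)
        best <- list(score = sc, states = a$states, site_pos = sp,
                     gap = list(where = "target", position = L + 2L - g))
      }
    }
    out <- c(list(mirna = paste(m, collapse = ""),
                  site = paste(s, collapse = "")), best)
  }
  class(out) <- "target_alignment"
  out
}

#' @export
print.target_alignment <- function(x, ...) {
  cat("miRNA 5'-", x$mirna, "-3'  score ", format(x$score), "\n", sep = "")
  sym <- c(match = "|", GU = "o", mismatch = " ", gap = "-")
  cat("      ", paste(sym[x$states], collapse = ""), "\n", sep = "")
  cat("site  3'-", paste(rev(strsplit(x$site, "")[[1]]), collapse = ""),
      "-5'\n", sep = "")
  invisible(x)
}

#' Scan transcripts for miRNA target sites
#'
#' Slides every window of the miRNA's length (and, when `gaps = TRUE`, one
#' shorter and one longer for single-gap alignments) over each transcript and
#' reports alignments scoring at or below the cutoff, sorted by score then
#' coordinate. Ungapped windows are scanned first; single-gap alignments are
#' additional candidate windows, not replacements.
#'
#' @param mirnas named character vector of mature miRNA sequences (20-24 nt).
#' @param transcripts named character vector of transcript sequences, or a
#'   FASTA path.
#' @param scheme see [target_scheme()].
#' @param gaps allow a single gap (default TRUE).
#' @return data.frame: `mirna`, `transcript`, `start`, `end` (1-based site
#'   coordinates), `score`, `cleavage_5p`, `cleavage_3p` (transcript positions
#'   flanking the predicted cut, NA when indeterminate), plus the alignment
#'   in the `alignments` attribute (list of `target_alignment`).
#' @export
scan_transcriptome <- function(mirnas, transcripts, scheme = target_scheme(),
                               gaps = TRUE) {
  if (is.character(transcripts) && length(transcripts) == 1L &&
      file.exists(transcripts)) {
    transcripts <- read_fasta(transcripts)
  }
  stopifnot(!is.null(names(mirnas)))
  rows <- list(); alns <- list()
  for (mi in names(mirnas)) {
    mseq <- norm_dna(mirnas[[mi]], allow_n = FALSE)
    L <- nchar(mseq)
    if (L < 20L || L > 24L) stop("miRNA ", mi, " is not 20-24 nt")
    for (tx in names(transcripts)) {
      tseq <- norm_dna(transcripts[[tx]], allow_n = FALSE)
      cand <- .scan_targets_cpp(mseq, tseq, scheme$mismatch, scheme$gu,
                                scheme$gap, scheme$double_from,
                                scheme$double_to, scheme$cutoff, gaps)
      for (j in seq_len(nrow(cand))) {
        start <- cand$start[j]; w <- cand$width[j]
        gap_in <- if (w == L) "none" else if (w < L) "mirna" else "target"
        site <- substr(tseq, start, start + w - 1L)
        al <- score_target(mseq, site, scheme, gap_in = gap_in)
        stopifnot(abs(al$score - cand$score[j]) < 1e-9)
        cl <- tryCatch(predict_cleavage(al, site_start = start),
                       error = function(e) c(NA_integer_, NA_integer_))
        rows[[length(rows) + 1L]] <- data.frame(
          mirna = mi, transcript = tx, start = start,
          end = start + w - 1L, score = al$score,
          cleavage_5p = cl[1], cleavage_3p = cl[2],
          stringsAsFactors = FALSE)
        alns[[length(alns) + 1L]] <- al
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mirna = character(0), transcript = character(0),
               start = integer(0), end = integer(0), score = numeric(0),
               cleavage_5p = integer(0), cleavage_3p = integer(0),
               stringsAsFactors = FALSE)
  ord <- order(out$score, out$mirna, out$transcript, out$start)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "alignments") <- alns[ord]
  out
}

#' Predict the miRNA-guided cleavage site of a target alignment
#'
#' Plant miRNA-guided cleavage falls between the target bases pairing miRNA
#' positions 10 and 11 (counted from the miRNA 5' end). Because the duplex is
#' antiparallel, transcript coordinates descend as miRNA positions ascend.
#' The prediction is independent of how much transcript flanks the site.
#'
#' @param alignment a [score_target()] result.
#' @param site_start 1-based transcript coordinate of the site's first base
#'   (default 1: coordinates relative to the site itself).
#' @return integer vector of the two adjacent transcript positions flanking
#'   the cut, in ascending order.
#' @export
predict_cleavage <- function(alignment, site_start = 1L) {
  sp <- alignment$site_pos
  if (length(sp) < 11L) stop("miRNA shorter than 11 nt")
  p10 <- sp[10L]; p11 <- sp[11L]
  if (is.na(p10) || is.na(p11) || abs(p10 - p11) != 1L) {
    stop("indeterminate site: gap spans miRNA positions 10-11")
  }
  sort(c(p10, p11)) + site_start - 1L
}
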