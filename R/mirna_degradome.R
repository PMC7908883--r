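#' miRNA target scoring and degradome cleavage evidence
#'
#' Targets are scored by antiparallel complementarity between the miRNA
#' (read 5'->3') and a transcript window, with per-position penalties:
#' mismatch 1, G:U wobble 0.5, gap 1, every penalty doubled at miRNA
#' positions 2-13 (the seed/central region). Alignments scoring above the
#' retention cutoff are removed. miRNA-guided cleavage cuts the transcript
#' opposite miRNA position 10; degradome 5'-end counts at that position
#' grade the evidence on the 0-4 T-plot scale.
#'
#' @name mirna_degradome
NULL

#' Default duplex penalty scheme
#'
#' @return list: `mismatch`, `gu`, `gap` penalties, `core_multiplier`, and
#'   `core_range` (miRNA positions where penalties are multiplied).
#' @export
duplex_penalties <- function() {
  list(mismatch = 1, gu = 0.5, gap = 1, core_multiplier = 2, core_range = 2:13)
}

.norm_rna <- function(x) {
  x <- toupper(x)
  x <- gsub("T", "U", x)
  if (grepl("[^ACGU]", x)) stop("invalid nucleotide characters in: ", substr(x, 1, 20))
  x
}

# state of one miRNA base paired with one target base (both 5'->3' reading,
# pairing is antiparallel so the caller reverses the window)
.pair_state <- function(mir, targ) {
  wc <- (mir == "A" & targ == "U") | (mir == "U" & targ == "A") |
        (mir == "G" & targ == "C") | (mir == "C" & targ == "G")
  gu <- (mir == "G" & targ == "U") | (mir == "U" & targ == "G")
  ifelse(wc, "match", ifelse(gu, "GU", "mismatch"))
}

.position_weight <- function(pos, pen) {
  ifelse(pos %in% pen$core_range, pen$core_multiplier, 1)
}

.score_states <- function(states, positions, pen) {
  base <- c(match = 0, GU = pen$gu, mismatch = pen$mismatch, gap = pen$gap)
  sum(base[states] * .position_weight(positions, pen))
}

#' Score a miRNA:target duplex
#'
#' The window is a transcript subsequence read 5'->3'; it pairs
#' antiparallel, so miRNA position i faces window position W - i + 1.
#' Windows of the miRNA length are scored ungapped; windows one base
#' shorter/longer are scored with a single gap (all placements tried, best
#' kept), which respects the at-most-one-consecutive-gap rule.
#'
#' @param mirna_seq miRNA sequence 5'->3' (RNA or DNA alphabet).
#' @param window_seq target window 5'->3', length within miRNA length +/- 1.
#' @param penalties see [duplex_penalties()].
#' @return list: `score`, `states` (per miRNA position: match/mismatch/GU/
#'   gap), `mirna_len`.
#' @export
score_duplex <- function(mirna_seq, window_seq, penalties = duplex_penalties()) {
  mir <- strsplit(.norm_rna(mirna_seq), "")[[1]]
  win <- strsplit(.norm_rna(window_seq), "")[[1]]
  L <- length(mir); W <- length(win)
  rw <- rev(win)  # rw[i] faces miRNA position i in the ungapped case
  if (W == L) {
    states <- .pair_state(mir, rw)
    return(list(score = .score_states(states, seq_len(L), penalties),
                states = states, mirna_len = L))
  }
  if (abs(W - L) > 1) stop("window length must be within 1 of the miRNA length")
  best <- NULL
  if (W == L - 1) {
    # one unpaired miRNA base (gap in target) at position g
    for (g in seq_len(L)) {
      states <- character(L)
      positions <- seq_len(L)
      states[g] <- "gap"
      rest <- setdiff(seq_len(L), g)
      states[rest] <- .pair_state(mir[rest], rw[seq_len(L - 1)])
      sc <- .score_states(states, positions, penalties)
      if (is.null(best) || sc < best$score) best <- list(score = sc, states = states, mirna_len = L)
    }
  } else {
    # one unpaired target base (gap in miRNA) between miRNA positions;
    # the gap column takes the position index of the preceding miRNA base
    for (g in seq_len(W)) {
      mir_idx <- c(seq_len(g - 1), NA, seq(g, L))  # length W, NA = gap column
      states <- ifelse(is.na(mir_idx), "gap",
                       .pair_state(mir[ifelse(is.na(mir_idx), 1, mir_idx)], rw))
      positions <- ifelse(is.na(mir_idx), pmax(g - 1, 1), mir_idx)
      sc <- .score_states(states, positions, penalties)
      if (is.null(best) || sc < best$score) best <- list(score = sc, states = states, mirna_len = L)
    }
  }
  best
}

#' Scan a transcript for miRNA target sites
#'
#' Every ungapped window of the miRNA length is scored; alignments with
#' score <= `score_max` are retained (boundary inclusive) and sorted by
#' score then position. The predicted cleavage site is the transcript
#' position pairing miRNA position 10 (cut between positions 10 and 11).
#'
#' @param mirna_seq miRNA sequence 5'->3'.
#' @param transcript_seq transcript sequence 5'->3' (length >= miRNA).
#' @param score_max retention cutoff (default 4.5).
#' @param penalties see [duplex_penalties()].
#' @return data.table: `start`, `end` (0-based half-open window), `score`,
#'   `cleavage_site` (0-based transcript position).
#' @export
scan_transcript <- function(mirna_seq, transcript_seq, score_max = 4.5,
                            penalties = duplex_penalties()) {
  mir <- strsplit(.norm_rna(mirna_seq), "")[[1]]
  tx <- strsplit(.norm_rna(transcript_seq), "")[[1]]
  L <- length(mir); n <- length(tx)
  if (n < L) stop("transcript shorter than miRNA")
  nwin <- n - L + 1
  # window matrix: rows = windows, col j = target base facing miRNA position j
  # (antiparallel: miRNA position j faces window offset L - j)
  idx <- outer(seq_len(nwin) - 1, L - seq_len(L), `+`) + 1
  targ <- matrix(tx[idx], nrow = nwin)
  pen_base <- matrix(0, nwin, L)
  for (j in seq_len(L)) {
    st <- .pair_state(rep(mir[j], nwin), targ[, j])
    pen_base[, j] <- c(match = 0, GU = penalties$gu, mismatch = penalties$mismatch)[st]
  }
  w <- .position_weight(seq_len(L), penalties)
  scores <- as.numeric(pen_base %*% w)
  keep <- which(scores <= score_max)
  out <- data.table(
    start = keep - 1L,
    end = keep - 1L + L,
    score = scores[keep],
    cleavage_site = keep - 1L + L - 10L
  )
  setorder(out, score, start)
  out[]
}

#' Grade degradome cleavage evidence (T-plot categories)
#'
#' With c = the 5'-end count at the predicted cleavage site, M = the maximum
#' count on the transcript and med = the median over positions with at least
#' one read: category none if c = 0; 4 if c = 1; 0 if c > 1 and c is the
#' unique maximum; 1 if c > 1 and c equals a shared maximum; 2 if
#' 1 < c < M and c > med; 3 if 1 < c <= med.
#'
#' @param cleavage_site 0-based transcript position of the predicted cut.
#' @param counts non-negative integer vector of 5'-end read counts per
#'   transcript position (position 1 = transcript position 0).
#' @return list: `category` (`"0".."4"` or `"none"`), `count_at_site`,
#'   `max_count`, `median_occupied`.
#' @export
grade_cleavage <- function(cleavage_site, counts) {
  if (any(counts < 0) || any(counts != floor(counts))) stop("counts must be non-negative integers")
  i <- cleavage_site + 1L
  if (i < 1L || i > length(counts)) stop("cleavage site outside the degradome profile")
  c_site <- counts[i]
  M <- max(counts)
  med <- if (any(counts >= 1)) median(counts[counts >= 1]) else NA_real_
  category <- if (c_site == 0) "none"
    else if (c_site == 1) "4"
    else if (c_site == M && sum(counts == M) == 1) "0"
    else if (c_site == M) "1"
    else if (c_site > med) "2"
    else "3"
  list(category = category, count_at_site = c_site, max_count = M,
       median_occupied = med)
}

#' Predict targets and grade their degradome support
#'
#' @param mirna_seq miRNA sequence.
#' @param transcripts named character vector of transcript sequences.
#' @param profiles named list: transcript id -> integer count vector (one
#'   per transcript position).
#' @param score_max retention cutoff (default 4.5).
#' @return data.table: `transcript_id`, `start`, `end`, `score`,
#'   `cleavage_site`, `count_at_site`, `category`.
#' @export
predict_targets <- function(mirna_seq, transcripts, profiles, score_max = 4.5) {
  out <- lapply(names(transcripts), function(id) {
    hits <- scan_transcript(mirna_seq, transcripts[[id]], score_max = score_max)
    if (!nrow(hits)) return(NULL)
    prof <- profiles[[id]]
    graded <- lapply(hits$cleavage_site, function(site) {
      if (is.null(prof)) return(list(category = "none", count_at_site = NA_integer_))
      grade_cleavage(site, prof)
    })
    cbind(data.table(transcript_id = id), hits,
          data.table(count_at_site = vapply(graded, function(g) as.integer(g$count_at_site), integer(1)),
                     category = vapply(graded, `[[`, "", "category")))
  })
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) {
    return(data.table(transcript_id = character(), start = integer(), end = integer(),
                      score = numeric(), cleavage_site = integer(),
                      count_at_site = integer(), category = character()))
  }
  rbindlist(out)
}
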