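# Semi-global alignment and approximate-matching primitives shared by the
# scanner. Pairwise alignment is delegated to Biostrings; the edit-distance
# anchor scan is an in-package dynamic program so its tie-breaks are fully
# specified and oracle-testable.

# Scoring over ACGTN: match +1, mismatch -1, N matches nothing (incl. N-N).
.subst_matrix <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      b <- c("A", "C", "G", "T", "N")
      mm <- matrix(-1, 5, 5, dimnames = list(b, b))
      diag(mm) <- 1
      mm["N", "N"] <- -1
      m <<- mm
    }
    m
  }
})

#' Fit a pattern semi-globally into a subject sequence
#'
#' Aligns the whole of `pattern` against the best-fitting substring of
#' `subject` (free end gaps on the subject only), the standard "glocal"
#' fit used to place a gene or gene domain inside a longer spacer.
#'
#' @param pattern,subject character scalars (ACGTN).
#' @return list with `start`, `end` (0-based half-open interval on the
#'   subject), `score`, `nmatch`, `identity` (= matches / pattern length)
#'   and the gapped alignment strings `aln_pattern`, `aln_subject`.
#' @keywords internal
semiglobal_fit <- function(pattern, subject) {
  a <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(pattern), Biostrings::DNAString(subject),
    type = "global-local", substitutionMatrix = .subst_matrix(),
    gapOpening = 2, gapExtension = 1
  )
  list(
    start = BiocGenerics::start(Biostrings::subject(a)) - 1L,
    end = BiocGenerics::end(Biostrings::subject(a)),
    score = BiocGenerics::score(a),
    nmatch = Biostrings::nmatch(a),
    identity = Biostrings::nmatch(a) / nchar(pattern),
    aln_pattern = as.character(Biostrings::alignedPattern(a)),
    aln_subject = as.character(Biostrings::alignedSubject(a))
  )
}

#' Fit several patterns into one subject in a single call
#'
#' Vectorized variant of [semiglobal_fit()] without the gapped strings;
#' used for per-domain annotation where only intervals and identities are
#' needed.
#'
#' @param patterns named character vector.
#' @param subject character scalar.
#' @return data.frame with one row per pattern: `name`, `start`, `end`
#'   (0-based half-open on the subject), `score`, `nmatch`, `identity`.
#' @keywords internal
semiglobal_fit_many <- function(patterns, subject) {
  a <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(unname(patterns)), Biostrings::DNAString(subject),
    type = "global-local", substitutionMatrix = .subst_matrix(),
    gapOpening = 2, gapExtension = 1
  )
  data.frame(
    name = names(patterns),
    start = BiocGenerics::start(Biostrings::subject(a)) - 1L,
    end = BiocGenerics::end(Biostrings::subject(a)),
    score = BiocGenerics::score(a),
    nmatch = Biostrings::nmatch(a),
    identity = Biostrings::nmatch(a) / nchar(patterns),
    stringsAsFactors = FALSE
  )
}

#' Count alignment matches within pattern-coordinate intervals
#'
#' Walks a gapped pairwise alignment column by column and counts exact
#' matches whose *pattern* position falls in each requested interval.
#' Used to check that the acceptor-stem domains of a functional-gene hit
#' are individually well matched.
#'
#' @param aln_pattern,aln_subject gapped alignment strings of equal length.
#' @param intervals list of 0-based half-open `c(start, end)` intervals in
#'   pattern coordinates.
#' @return integer vector of match counts, one per interval.
#' @keywords internal
matches_in_pattern_intervals <- function(aln_pattern, aln_subject, intervals) {
  pv <- chars(aln_pattern); sv <- chars(aln_subject)
  stopifnot(length(pv) == length(sv))
  counts <- integer(length(intervals))
  ppos <- 0L  # number of pattern chars consumed so far
  for (k in seq_along(pv)) {
    if (pv[k] == "-") next
    match_here <- pv[k] != "N" && pv[k] == sv[k]
    if (match_here) {
      for (i in seq_along(intervals)) {
        if (ppos >= intervals[[i]][1] && ppos < intervals[[i]][2]) {
          counts[i] <- counts[i] + 1L
        }
      }
    }
    ppos <- ppos + 1L
  }
  counts
}

#' Edit distance of a pattern to substrings ending at every text position
#'
#' Semi-global pattern-matching dynamic program (free start, free end in the
#' text): entry j of the result is the minimum Levenshtein distance between
#' `pattern` and any substring of `text` ending at 0-based half-open end j.
#' The inner insertion recursion is vectorized with a cumulative-minimum
#' identity, so the loop runs over pattern rows only.
#'
#' @param text,pattern character scalars (ACGTN); N mismatches everything.
#' @return integer vector of length `nchar(text)`.
#' @keywords internal
edit_end_costs <- function(text, pattern) {
  tv <- chars(text); pv <- chars(pattern)
  n <- length(tv); m <- length(pv)
  if (n == 0L) return(integer(0))
  prev <- rep(0L, n + 1L)             # row 0: match may start anywhere
  steps <- 0:n
  for (i in seq_len(m)) {
    subc <- as.integer(tv != pv[i] | tv == "N" | pv[i] == "N")
    tmp <- pmin(prev[1:n] + subc,     # diagonal (substitution / match)
                prev[2:(n + 1L)] + 1L) # up (pattern char unmatched)
    # left moves cost 1 each: D[i, j] = min_k<=j (tmp'_k + (j - k))
    prev <- cummin(c(i, tmp) - steps) + steps
  }
  as.integer(prev[-1L])
}

# For a candidate match end (0-based half-open), recover the best start by
# enumerating substring lengths within the edit budget; ties break to the
# smallest start (leftmost).
.best_start_for_end <- function(text, pattern, end0, max_edits) {
  m <- nchar(pattern)
  lens <- seq(max(1L, m - max_edits), min(end0, m + max_edits))
  if (length(lens) == 0L) return(NULL)
  starts <- end0 - lens
  subs <- vapply(starts, function(s) substr0(text, s, end0), character(1))
  d <- as.integer(adist(pattern, subs))
  best <- min(d)
  list(start = min(starts[d == best]), cost = best)
}

#' Locally optimal approximate occurrences of a pattern
#'
#' Finds all non-overlapping occurrences of `pattern` in `text` with edit
#' distance at most `max_edits`. Candidate end points come from the
#' semi-global DP ([edit_end_costs()]); the best start per end is recovered
#' by bounded enumeration; candidates are then selected greedily,
#' best-score-first with ties broken to the leftmost start.
#'
#' @param text,pattern character scalars.
#' @param max_edits integer >= 0.
#' @return data.frame with columns `start`, `end` (0-based half-open) and
#'   `edits`, sorted by `start`. Zero rows when nothing matches.
#' @keywords internal
approx_matches <- function(text, pattern, max_edits) {
  stopifnot(max_edits >= 0)
  empty <- data.frame(start = integer(0), end = integer(0), edits = integer(0))
  if (nchar(text) == 0L) return(empty)
  costs <- edit_end_costs(text, pattern)
  ends <- which(costs <= max_edits)      # 1-based index == 0-based h.o. end
  if (length(ends) == 0L) return(empty)
  # enumerate only lengths within the achieved cost (|L - m| <= d is forced
  # for an optimal match), so recovered starts do not depend on the budget
  # and the selected anchor set grows monotonically with max_edits
  cand <- lapply(ends, function(e) {
    b <- .best_start_for_end(text, pattern, e, costs[e])
    data.frame(start = b$start, end = e, edits = costs[e])
  })
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand$edits, cand$start, cand$end), , drop = FALSE]
  sel <- cand[0, , drop = FALSE]
  for (r in seq_len(nrow(cand))) {
    row <- cand[r, ]
    clash <- any(overlaps_vec(sel$start, sel$end, row$start, row$end))
    if (!clash) sel <- rbind(sel, row)
  }
  sel <- sel[order(sel$start), , drop = FALSE]
  rownames(sel) <- NULL
  sel
}

# vectorized overlap test against one interval
overlaps_vec <- function(starts, ends, s, e) {
  if (length(starts) == 0L) return(logical(0))
  starts < e & s < ends
}
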