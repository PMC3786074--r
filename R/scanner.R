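# Scanner: locate the functional trnF gene in a trnL-F spacer, then walk the
# region immediately 5' of it for decayed tandem pseudogene copies. Copies
# are found by edit-distance anchoring on the anticodon arm (the most
# conserved element), segmented at ATT(G)n bordering motifs, and annotated
# domain by domain against the reference.

#' Scanner parameter set
#'
#' All thresholds used by [scan_sequence()] and its sub-operations, with the
#' package defaults. Every value can be overridden here or via a YAML config
#' file on the command line.
#'
#' @param min_identity minimum identity for the functional-gene hit
#'   (matches / gene length), default 0.90.
#' @param min_stem_matches per-acceptor-stem minimum exact matches within
#'   the functional-gene alignment (functional genes have stems; pseudogene
#'   copies lack them), default 5 of 7.
#' @param anchor_max_edits edit-distance budget for anticodon-arm anchors,
#'   default 3 (for the 17-nt arm).
#' @param border_budget substitutions tolerated in the ATT core of the
#'   bordering motif, default 1.
#' @param lookback how far (nt) upstream of an anchor to look for a
#'   bordering motif, default 40.
#' @param flank5 fixed 5' flank (nt) used when no bordering motif is found,
#'   default 15.
#' @param tail3 3' extension (nt) after the last anchor when no functional
#'   gene bounds the array, default 30.
#' @param min_domain_identity per-domain identity threshold for
#'   [annotate_copy()], default 0.70.
#' @param repeat_units simple-repeat units searched inside copies, default
#'   AT, AAT, ATT, AATCC.
#' @param min_units minimum consecutive units for a tandem run, default 2.
#' @param promoter_mm mismatch budget per promoter hexamer, default 1.
#' @param promoter_spacer allowed gap (nt) between the -35 and -10
#'   elements, default \code{c(12, 25)}.
#' @param max_upstream maximal extent (nt) of the upstream region scanned
#'   for copies, default 600.
#' @param copy_length_range observed copy-length envelope (bp); lengths
#'   outside it raise a warning on the copy, never a rejection. Default
#'   \code{c(32, 73)}.
#' @param scan_downstream also look for anchors 3' of the functional gene
#'   and report them as warnings, default `FALSE`.
#' @return named list of class `scan_params`.
#' @export
scan_params <- function(min_identity = 0.90, min_stem_matches = 5L,
                        anchor_max_edits = 3L, border_budget = 1L,
                        lookback = 40L, flank5 = 15L, tail3 = 30L,
                        min_domain_identity = 0.70,
                        repeat_units = c("AT", "AAT", "ATT", "AATCC"),
                        min_units = 2L, promoter_mm = 1L,
                        promoter_spacer = c(12L, 25L), max_upstream = 600L,
                        copy_length_range = c(32L, 73L),
                        scan_downstream = FALSE) {
  p <- list(
    min_identity = min_identity, min_stem_matches = as.integer(min_stem_matches),
    anchor_max_edits = as.integer(anchor_max_edits),
    border_budget = as.integer(border_budget), lookback = as.integer(lookback),
    flank5 = as.integer(flank5), tail3 = as.integer(tail3),
    min_domain_identity = min_domain_identity,
    repeat_units = toupper(repeat_units), min_units = as.integer(min_units),
    promoter_mm = as.integer(promoter_mm),
    promoter_spacer = as.integer(promoter_spacer),
    max_upstream = as.integer(max_upstream),
    copy_length_range = as.integer(copy_length_range),
    scan_downstream = isTRUE(scan_downstream)
  )
  stopifnot(p$min_identity > 0, p$min_identity <= 1,
            p$min_domain_identity > 0, p$min_domain_identity <= 1,
            p$anchor_max_edits >= 0, p$border_budget >= 0,
            p$lookback > 0, p$flank5 >= 0,
            length(p$promoter_spacer) == 2L,
            p$promoter_spacer[1] <= p$promoter_spacer[2],
            length(p$copy_length_range) == 2L)
  structure(p, class = "scan_params")
}

#' Construct a spacer sequence record
#'
#' @param id unique sequence identifier.
#' @param seq nucleotide string.
#' @param taxon taxon label (free text), default the id.
#' @param source provenance (accession or "synthetic").
#' @return object of class `spacer_sequence`.
#' @export
spacer_sequence <- function(id, seq, taxon = id, source = "unknown") {
  seq <- sanitize_dna(seq)
  if (nchar(seq) == 0L) stop("empty sequence for '", id, "'")
  structure(list(id = id, taxon = taxon, seq = seq, source = source),
            class = "spacer_sequence")
}

#' Locate the functional trnF gene in a spacer
#'
#' Semi-globally fits the full reference gene against both strands of the
#' spacer. A hit is reported only when overall identity reaches
#' `min_identity` *and* both acceptor-stem domains align with at least
#' `min_stem_matches` exact matches — pseudogene copies lack the acceptor
#' stems, so the stem check separates the one functional gene from its
#' decayed upstream duplicates.
#'
#' @param spacer a [spacer_sequence()] or nucleotide string.
#' @param ref a [trnf_reference()].
#' @param min_identity identity threshold in (0, 1], default 0.90.
#' @param min_stem_matches per-stem exact-match minimum, default 5.
#' @return `NULL` when no acceptable hit exists, else a list with
#'   `start`, `end` (0-based half-open, on the strand scanned), `identity`,
#'   `strand` (`"+"` or `"-"` relative to the input), and `stem_matches`.
#' @export
find_functional_gene <- function(spacer, ref, min_identity = 0.90,
                                 min_stem_matches = 5L) {
  stopifnot(min_identity > 0, min_identity <= 1)
  seq <- if (inherits(spacer, "spacer_sequence")) spacer$seq else sanitize_dna(spacer)
  if (nchar(seq) < nchar(ref$gene_seq)) return(NULL)
  fits <- list(`+` = semiglobal_fit(ref$gene_seq, seq),
               `-` = semiglobal_fit(ref$gene_seq, revcomp(seq)))
  strand <- if (fits[["-"]]$score > fits[["+"]]$score) "-" else "+"
  fit <- fits[[strand]]
  if (fit$identity < min_identity) return(NULL)
  stems <- matches_in_pattern_intervals(
    fit$aln_pattern, fit$aln_subject,
    list(ref$domains$ACC5, ref$domains$ACC3)
  )
  if (any(stems < min_stem_matches)) return(NULL)
  list(start = fit$start, end = fit$end, identity = fit$identity,
       strand = strand, stem_matches = stems)
}

#' Find anticodon-arm anchors in an upstream region
#'
#' Every pseudogene copy retains (at least part of) the anticodon domain,
#' so approximate occurrences of the reference anticodon arm serve as copy
#' anchors. Returns all locally optimal, non-overlapping occurrences with
#' edit distance at most `max_edits` (greedy best-score-first selection,
#' ties to the leftmost start), sorted by start.
#'
#' @param upstream nucleotide string (the region 5' of the functional gene).
#' @param ref a [trnf_reference()].
#' @param max_edits edit budget, default 3.
#' @return data.frame with columns `start`, `end` (0-based half-open) and
#'   `edits`.
#' @export
find_anchors <- function(upstream, ref, max_edits = 3L) {
  arm <- domain_seq(ref, "ANTICODON")
  approx_matches(sanitize_dna(upstream), arm, max_edits)
}

# Find ATT(G)n bordering-motif candidates in [from, to) of `text`:
# an ATT core (<= budget substitutions) followed by >= 1 G. Returns a
# data.frame sorted so the preferred candidate (fewest core mismatches,
# then nearest to `to`) comes first.
.border_candidates <- function(text, from, to, budget) {
  win_end <- min(nchar(text), to + 0L)
  if (win_end - from < 4L) {
    return(data.frame(start = integer(0), end = integer(0),
                      g_run = integer(0), mismatches = integer(0),
                      text = character(0)))
  }
  win <- substr0(text, from, win_end)
  mm <- hamming_scan(win, "ATT")
  tv <- chars(win)
  n <- length(tv)
  cand <- list()
  for (i in seq_along(mm)) {
    p0 <- from + i - 1L                      # 0-based core start in text
    if (mm[i] > budget) next
    gpos <- i + 3L                            # 1-based pos after core in win
    if (gpos > n || tv[gpos] != "G") next
    g_run <- 0L
    while (gpos + g_run <= n && tv[gpos + g_run] == "G") g_run <- g_run + 1L
    m_end <- p0 + 3L + g_run
    if (p0 + 4L > to) next                    # core+first G must precede `to`
    cand[[length(cand) + 1L]] <- data.frame(
      start = p0, end = m_end, g_run = g_run, mismatches = mm[i],
      text = substr0(text, p0, m_end)
    )
  }
  if (length(cand) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      g_run = integer(0), mismatches = integer(0),
                      text = character(0)))
  }
  out <- do.call(rbind, cand)
  out[order(out$mismatches, -out$start), , drop = FALSE]
}

#' Segment the upstream region into pseudogene-copy intervals
#'
#' One copy interval per anchor. The 5' cut of a copy is the start of its
#' bordering ATT(G)n motif when one occurs within `lookback` nt upstream of
#' the anchor (candidates ranked by core mismatches, then proximity), else
#' a fixed `flank5` before the anchor. The 3' cut is the next copy's 5'
#' cut; the last copy ends at `end_limit` (the functional-gene start) when
#' `abut_end` is `TRUE`, else `tail3` nt after its anchor.
#'
#' @param upstream nucleotide string.
#' @param anchors data.frame from [find_anchors()] (sorted, non-overlapping).
#' @param border_budget substitutions tolerated in the ATT core, default 1.
#' @param lookback,flank5,tail3 see [scan_params()].
#' @param end_limit 0-based half-open end bound for the last copy; defaults
#'   to `nchar(upstream)`.
#' @param abut_end does `end_limit` mark the functional-gene start
#'   (`TRUE`, default) or merely the end of available sequence?
#' @return list with `intervals` (data.frame `start`, `end`) and `borders`
#'   (list, per copy: `NULL` or a border-motif record).
#' @export
segment_copies <- function(upstream, anchors, border_budget = 1L,
                           lookback = 40L, flank5 = 15L, tail3 = 30L,
                           end_limit = nchar(upstream), abut_end = TRUE) {
  upstream <- sanitize_dna(upstream)
  n_cp <- nrow(anchors)
  if (n_cp == 0L) {
    return(list(intervals = data.frame(start = integer(0), end = integer(0)),
                borders = list()))
  }
  stopifnot(!is.unsorted(anchors$start, strictly = TRUE))
  cuts5 <- integer(n_cp)
  borders <- vector("list", n_cp)
  prev_floor <- 0L
  for (i in seq_len(n_cp)) {
    a_start <- anchors$start[i]
    from <- max(prev_floor, a_start - lookback)
    cand <- .border_candidates(upstream, from, a_start, border_budget)
    if (nrow(cand) > 0L) {
      b <- cand[1, ]
      cuts5[i] <- b$start
      borders[[i]] <- list(interval = c(b$start, b$end), text = b$text,
                           g_run = b$g_run, mismatches = b$mismatches)
    } else {
      cuts5[i] <- max(prev_floor, a_start - flank5)
      borders[i] <- list(NULL)
    }
    prev_floor <- anchors$end[i]   # next copy cannot cut into this anchor
  }
  ends <- c(cuts5[-1L],
            if (abut_end) end_limit else min(end_limit, anchors$end[n_cp] + tail3))
  iv <- data.frame(start = cuts5, end = ends)
  if (any(iv$end <= iv$start) ||
      (n_cp > 1L && any(iv$start[-1L] < iv$end[-n_cp]))) {
    stop("internal error: copy segmentation produced overlapping or empty intervals")
  }
  list(intervals = iv, borders = borders)
}

#' Annotate a pseudogene copy against the reference domains
#'
#' Each of the five reference domains is fitted semi-globally (free end
#' gaps on the copy) into `copy_seq`; a domain hit is emitted when
#' identity (matches / domain length) reaches `min_domain_identity`.
#' Hits are then trimmed to mutual non-overlap in the precedence order
#' ANTICODON > DDOM > TDOM > ACC5 > ACC3 — the anticodon domain is the most
#' conserved element, the D-domain more conserved than the T-domain, and
#' acceptor-stem residues are rare.
#'
#' @param copy_seq nucleotide string of one copy.
#' @param ref a [trnf_reference()].
#' @param min_domain_identity identity threshold, default 0.70.
#' @return data.frame of domain hits sorted by start: `label`, `start`,
#'   `end` (0-based half-open on the copy), `identity`, `score`.
#' @export
annotate_copy <- function(copy_seq, ref, min_domain_identity = 0.70) {
  if (!is.character(copy_seq) || length(copy_seq) != 1L || nchar(copy_seq) == 0L) {
    stop("copy_seq must be a nonempty nucleotide string")
  }
  copy_seq <- sanitize_dna(copy_seq)
  doms <- setNames(vapply(DOMAIN_LABELS, domain_seq, character(1), ref = ref),
                   DOMAIN_LABELS)
  fits <- semiglobal_fit_many(doms, copy_seq)
  fits <- fits[fits$identity >= min_domain_identity, , drop = FALSE]
  precedence <- c("ANTICODON", "DDOM", "TDOM", "ACC5", "ACC3")
  fits <- fits[order(match(fits$name, precedence)), , drop = FALSE]
  kept <- fits[0, , drop = FALSE]
  occ <- data.frame(start = integer(0), end = integer(0))
  for (r in seq_len(nrow(fits))) {
    h <- fits[r, ]
    s <- h$start; e <- h$end
    # clip against already-claimed intervals; keep the largest free segment
    for (k in seq_len(nrow(occ))) {
      if (!overlaps0(s, e, occ$start[k], occ$end[k])) next
      left <- c(s, min(e, occ$start[k]))
      right <- c(max(s, occ$end[k]), e)
      seg <- if (diff(left) >= diff(right)) left else right
      s <- seg[1]; e <- seg[2]
      if (e <= s) break
    }
    if (e <= s) next
    h$start <- s; h$end <- e
    kept <- rbind(kept, h)
    occ <- rbind(occ, data.frame(start = s, end = e))
  }
  out <- data.frame(label = kept$name, start = kept$start, end = kept$end,
                    identity = kept$identity, score = kept$score,
                    stringsAsFactors = FALSE)
  out[order(out$start), , drop = FALSE]
}

#' Detect perfect simple tandem repeats inside a copy
#'
#' Finds all maximal runs of at least `min_units` consecutive perfect
#' repetitions of each unit (runs of different units may overlap; a run is
#' maximal when it cannot be extended by a full unit on either side).
#'
#' @param copy_seq nucleotide string.
#' @param units repeat units, default AT, AAT, ATT, AATCC.
#' @param min_units minimum unit count, default 2.
#' @return data.frame with columns `unit`, `start` (0-based), `n_units`.
#' @export
detect_internal_repeats <- function(copy_seq,
                                    units = c("AT", "AAT", "ATT", "AATCC"),
                                    min_units = 2L) {
  copy_seq <- sanitize_dna(copy_seq)
  tv <- chars(copy_seq)
  n <- length(tv)
  res <- list()
  for (u in toupper(units)) {
    L <- nchar(u)
    if (n < L * min_units) next
    hit <- hamming_scan(copy_seq, u) == 0L       # unit occurrence per start
    nh <- length(hit)
    i <- 1L
    while (i <= nh) {
      if (hit[i]) {
        k <- 1L
        while (i + k * L <= nh && hit[i + k * L]) k <- k + 1L
        # i + k*L <= nh failed or next unit absent -> run of k units
        extendable_left <- i - L >= 1L && hit[i - L]
        if (k >= min_units && !extendable_left) {
          res[[length(res) + 1L]] <- data.frame(unit = u, start = i - 1L,
                                                n_units = k)
        }
        if (!extendable_left) i <- i + k * L else i <- i + 1L
        next
      }
      i <- i + 1L
    }
  }
  if (length(res) == 0L) {
    return(data.frame(unit = character(0), start = integer(0),
                      n_units = integer(0)))
  }
  out <- do.call(rbind, res)
  out <- out[order(out$start, out$unit), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect sigma70-type promoter element pairs
#'
#' Scans for the -35 (`TTGACA`) and -10 (`GAGGAT`) hexamers with up to
#' `max_mismatch_per_element` substitutions each, and reports every pairing
#' in which the -10 element follows the -35 element at a gap within
#' `spacer_range`.
#'
#' @param region nucleotide string.
#' @param max_mismatch_per_element mismatch budget per hexamer, default 1.
#' @param spacer_range allowed gap `c(min, max)` in nt, default
#'   \code{c(12, 25)}.
#' @return data.frame sorted by -35 start: `m35_start`, `m35_end`,
#'   `m35_mismatches`, `m10_start`, `m10_end`, `m10_mismatches`,
#'   `spacer_len` (0-based half-open intervals).
#' @export
detect_promoters <- function(region, max_mismatch_per_element = 1L,
                             spacer_range = c(12L, 25L)) {
  region <- sanitize_dna(region)
  empty <- data.frame(m35_start = integer(0), m35_end = integer(0),
                      m35_mismatches = integer(0), m10_start = integer(0),
                      m10_end = integer(0), m10_mismatches = integer(0),
                      spacer_len = integer(0))
  mm35 <- hamming_scan(region, "TTGACA")
  mm10 <- hamming_scan(region, "GAGGAT")
  p35 <- which(mm35 <= max_mismatch_per_element) - 1L
  p10 <- which(mm10 <= max_mismatch_per_element) - 1L
  if (length(p35) == 0L || length(p10) == 0L) return(empty)
  rows <- list()
  for (a in p35) {
    gaps <- p10 - (a + 6L)
    ok <- which(gaps >= spacer_range[1] & gaps <= spacer_range[2])
    for (j in ok) {
      b <- p10[j]
      rows[[length(rows) + 1L]] <- data.frame(
        m35_start = a, m35_end = a + 6L, m35_mismatches = mm35[a + 1L],
        m10_start = b, m10_end = b + 6L, m10_mismatches = mm10[b + 1L],
        spacer_len = b - (a + 6L)
      )
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$m35_start, out$m10_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan one spacer sequence for the trnF gene and its pseudogene array
#'
#' Orchestrates the full per-sequence pipeline: functional-gene location
#' (both strands) — restriction to the upstream region — anticodon-arm
#' anchoring — bordering-motif segmentation — per-copy domain annotation
#' and simple-repeat detection — promoter detection 5' of the first copy.
#' Promoter-like element pairs found *within* the copy array are reported
#' as warnings, never as promoter hits (in Solanaceae the repeats insert
#' strictly after the promoter elements).
#'
#' @param spacer a [spacer_sequence()] (a plain string is accepted and
#'   wrapped).
#' @param ref a [trnf_reference()]; the packaged default when `NULL`.
#' @param params a [scan_params()] list.
#' @return object of class `scan_result`: list with `sequence_id`, `taxon`,
#'   `source`, `seq_length`, `strand_used`, `functional_gene` (`NULL` or
#'   list `interval`, `identity`), `copies` (list of per-copy records:
#'   `ordinal`, `interval`, `length_bp`, `border`, `hits`,
#'   `internal_repeats`), `promoters` (data.frame), `copy_number`,
#'   `warnings`. All coordinates are 0-based half-open on the scanned
#'   strand (`strand_used` records a flip).
#' @examples
#' ref <- load_reference()
#' cfg <- sim_config(sub_rate = 0, indel_rate = 0)
#' sp <- generate_spacer("Example taxon", 3, cfg, ref, seed = 7)
#' res <- scan_sequence(sp$spacer, ref)
#' res$copy_number
#' @export
scan_sequence <- function(spacer, ref = NULL, params = scan_params()) {
  if (is.character(spacer)) spacer <- spacer_sequence("seq1", spacer)
  stopifnot(inherits(spacer, "spacer_sequence"))
  if (is.null(ref)) ref <- load_reference()
  if (!inherits(params, "scan_params")) params <- do.call(scan_params, params)
  seq <- spacer$seq
  if (nchar(seq) < nchar(ref$gene_seq)) {
    stop("scan error: spacer '", spacer$id, "' (", nchar(seq),
         " nt) is shorter than the reference gene")
  }
  warnings <- character(0)
  gene <- find_functional_gene(spacer, ref, params$min_identity,
                               params$min_stem_matches)
  strand_used <- "+"
  if (!is.null(gene) && gene$strand == "-") {
    seq <- revcomp(seq)
    strand_used <- "-"
  }
  if (is.null(gene)) {
    warnings <- c(warnings, "functional trnF gene not found")
    up_end <- nchar(seq)
  } else {
    up_end <- gene$start
  }
  up_start <- max(0L, up_end - params$max_upstream)
  upstream <- substr0(seq, up_start, up_end)

  anchors <- find_anchors(upstream, ref, params$anchor_max_edits)
  seg <- segment_copies(upstream, anchors,
                        border_budget = params$border_budget,
                        lookback = params$lookback, flank5 = params$flank5,
                        tail3 = params$tail3,
                        end_limit = nchar(upstream),
                        abut_end = !is.null(gene))
  copies <- vector("list", nrow(seg$intervals))
  for (i in seq_along(copies)) {
    s0 <- seg$intervals$start[i] + up_start
    e0 <- seg$intervals$end[i] + up_start
    cseq <- substr0(seq, s0, e0)
    hits <- annotate_copy(cseq, ref, params$min_domain_identity)
    reps <- detect_internal_repeats(cseq, params$repeat_units, params$min_units)
    len <- e0 - s0
    if (len < params$copy_length_range[1] || len > params$copy_length_range[2]) {
      warnings <- c(warnings, sprintf(
        "copy %d length %d bp outside the observed range [%d, %d]",
        i, len, params$copy_length_range[1], params$copy_length_range[2]))
    }
    border <- seg$borders[[i]]
    if (!is.null(border)) {
      border$interval <- border$interval + up_start
    }
    copies[[i]] <- list(ordinal = i, interval = c(s0, e0), length_bp = len,
                        border = border, hits = hits, internal_repeats = reps)
  }
  first_copy_start <- if (length(copies) > 0L) copies[[1]]$interval[1] else up_end
  promoters <- detect_promoters(substr0(seq, 0L, first_copy_start),
                                params$promoter_mm, params$promoter_spacer)
  if (length(copies) > 0L) {
    array_start <- copies[[1]]$interval[1]
    array_end <- copies[[length(copies)]]$interval[2]
    inside <- detect_promoters(substr0(seq, array_start, array_end),
                               params$promoter_mm, params$promoter_spacer)
    if (nrow(inside) > 0L) {
      warnings <- c(warnings, sprintf(
        "%d promoter-like element pair(s) inside the copy array (expected only 5' of the first copy)",
        nrow(inside)))
    }
  }
  if (params$scan_downstream && !is.null(gene) && gene$end < nchar(seq)) {
    down <- find_anchors(substr0(seq, gene$end, nchar(seq)), ref,
                         params$anchor_max_edits)
    if (nrow(down) > 0L) {
      warnings <- c(warnings, sprintf(
        "%d anticodon-arm anchor(s) 3' of the functional gene (not counted as copies)",
        nrow(down)))
    }
  }
  res <- structure(list(
    sequence_id = spacer$id, taxon = spacer$taxon, source = spacer$source,
    seq_length = nchar(seq), strand_used = strand_used,
    functional_gene = if (is.null(gene)) NULL else
      list(interval = c(gene$start, gene$end), identity = gene$identity),
    copies = copies, promoters = promoters,
    copy_number = length(copies), warnings = warnings
  ), class = "scan_result")
  validate_scan_result(res)
  res
}

# Structural invariants asserted on every scan result.
validate_scan_result <- function(res) {
  stopifnot(res$copy_number == length(res$copies))
  if (res$copy_number > 0L) {
    iv <- t(vapply(res$copies, `[[`, numeric(2), "interval"))
    stopifnot(all(diff(iv[, 1]) > 0),                 # sorted by start
              all(iv[, 2] > iv[, 1]))                 # nonempty
    if (res$copy_number > 1L) {
      stopifnot(all(iv[-1L, 1] >= iv[-res$copy_number, 2]))  # disjoint
    }
    if (!is.null(res$functional_gene)) {
      stopifnot(all(iv[, 2] <= res$functional_gene$interval[1]))
    }
    if (nrow(res$promoters) > 0L) {
      stopifnot(all(res$promoters$m10_end <= iv[1, 1]))
    }
    for (cp in res$copies) {
      stopifnot(cp$length_bp == cp$interval[2] - cp$interval[1])
      if (nrow(cp$hits) > 1L) stopifnot(!is.unsorted(cp$hits$start))
    }
  }
  invisible(res)
}

#' @export
print.scan_result <- function(x, ...) {
  cat("trnL-F spacer scan: ", x$sequence_id, " (", x$taxon, ", ",
      x$seq_length, " nt, strand ", x$strand_used, ")\n", sep = "")
  if (is.null(x$functional_gene)) {
    cat("  functional trnF gene: not found\n")
  } else {
    iv <- x$functional_gene$interval
    cat(sprintf("  functional trnF gene: [%d, %d) identity %.3f\n",
                iv[1], iv[2], x$functional_gene$identity))
  }
  cat("  pseudogene copies: ", x$copy_number, "\n", sep = "")
  for (cp in x$copies) {
    cat(sprintf("    #%d [%d, %d) %d bp  border=%s  domains=%s\n",
                cp$ordinal, cp$interval[1], cp$interval[2], cp$length_bp,
                if (is.null(cp$border)) "-" else cp$border$text,
                paste(cp$hits$label, collapse = "+")))
  }
  cat("  promoter pairs 5' of array: ", nrow(x$promoters), "\n", sep = "")
  for (w in x$warnings) cat("  warning: ", w, "\n", sep = "")
  invisible(x)
}

#' Scan a batch of spacer sequences
#'
#' @param spacers list of [spacer_sequence()] objects.
#' @param ref a [trnf_reference()]; packaged default when `NULL`.
#' @param params a [scan_params()] list.
#' @return list of `scan_result` objects (named by sequence id).
#' @export
scan_batch <- function(spacers, ref = NULL, params = scan_params()) {
  if (is.null(ref)) ref <- load_reference()
  out <- lapply(spacers, scan_sequence, ref = ref, params = params)
  names(out) <- vapply(out, `[[`, character(1), "sequence_id")
  out
}
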