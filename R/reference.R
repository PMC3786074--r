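# Structural model of the trnF(GAA) gene: the search template for both the
# functional gene and the decayed pseudogene copies. The gene is tiled into
# five contiguous cloverleaf domains:
#
#   ACC5 | DDOM | ANTICODON | TDOM | ACC3
#
# ACC5/ACC3 are the 5'/3' halves of the acceptor stem, DDOM and TDOM the D-
# and T-arms, and ANTICODON the anticodon arm (17 nt: 5-nt stem, 7-nt loop
# centred on the anticodon triplet, 5-nt stem) or, optionally, just the
# 7-nt loop.

#' Decompose a trnF gene sequence into cloverleaf domains
#'
#' Deterministic tiling rule: `ANTICODON` is a window centred on the
#' anticodon triplet (17 nt in `"arm"` mode, 7 nt in `"loop"` mode),
#' `ACC5` the first `stem_length` nt, `ACC3` the last `stem_length` nt,
#' `DDOM` everything between `ACC5` and `ANTICODON`, and `TDOM` everything
#' between `ANTICODON` and `ACC3`. Intervals are clipped to the sequence
#' and must all be nonempty.
#'
#' @param gene_seq nucleotide string (coding strand).
#' @param anticodon_triplet 3-mer, default `"GAA"` (phenylalanine).
#' @param mode `"arm"` (17-nt anticodon arm, default) or `"loop"` (7 nt).
#' @param stem_length acceptor-stem length in nt, default 7.
#' @return named list of `c(start, end)` 0-based half-open intervals in
#'   canonical order ACC5, DDOM, ANTICODON, TDOM, ACC3.
#' @examples
#' ref <- load_reference()
#' decompose_trnf(ref$gene_seq)
#' @export
decompose_trnf <- function(gene_seq, anticodon_triplet = "GAA",
                           mode = c("arm", "loop"), stem_length = 7L) {
  mode <- match.arg(mode)
  gene_seq <- sanitize_dna(gene_seq)
  n <- nchar(gene_seq)
  occ <- gregexpr(anticodon_triplet, gene_seq, fixed = TRUE)[[1]]
  if (identical(as.integer(occ[1]), -1L)) {
    stop("anticodon triplet '", anticodon_triplet,
         "' not found in gene sequence")
  }
  occ0 <- as.integer(occ) - 1L
  if (length(occ0) > 1L) {
    centre <- (n - nchar(anticodon_triplet)) / 2
    occ0 <- occ0[which.min(abs(occ0 - centre))]
    warning("anticodon triplet occurs ", length(occ), " times; ",
            "using the occurrence closest to the sequence midpoint")
  }
  half <- if (mode == "arm") 7L else 2L   # window = triplet +/- half
  a_start <- max(0L, occ0 - half)
  a_end <- min(n, occ0 + 3L + half)
  d <- list(
    ACC5 = c(0L, min(stem_length, a_start)),
    DDOM = c(min(stem_length, a_start), a_start),
    ANTICODON = c(a_start, a_end),
    TDOM = c(a_end, max(a_end, n - stem_length)),
    ACC3 = c(max(a_end, n - stem_length), n)
  )
  widths <- vapply(d, function(x) x[2] - x[1], integer(1))
  if (any(widths <= 0L)) {
    stop("degenerate domain tiling (empty ",
         paste(names(widths)[widths <= 0L], collapse = ", "),
         "); gene too short for this anticodon position")
  }
  d
}

#' Construct a trnF reference model
#'
#' @param gene_seq nucleotide string of the trnF gene, coding strand.
#' @param domains optional precomputed domain tiling (as returned by
#'   [decompose_trnf()]); computed from `anticodon_triplet` when `NULL`.
#' @param anticodon_triplet anticodon 3-mer, default `"GAA"`.
#' @param source_id free-text provenance (accession and span, or
#'   "synthetic").
#' @param mode anticodon window mode, see [decompose_trnf()].
#' @return object of class `trnf_reference`: list with `gene_seq`,
#'   `domains`, `anticodon_triplet`, `source_id`.
#' @export
trnf_reference <- function(gene_seq, domains = NULL,
                           anticodon_triplet = "GAA",
                           source_id = "unspecified",
                           mode = c("arm", "loop")) {
  mode <- match.arg(mode)
  gene_seq <- sanitize_dna(gene_seq)
  n <- nchar(gene_seq)
  if (n < 60L || n > 100L) {
    stop("gene_seq length ", n, " outside the plausible tRNA gene range [60, 100]")
  }
  if (is.null(domains)) {
    domains <- decompose_trnf(gene_seq, anticodon_triplet, mode = mode)
  }
  # validate tiling: contiguous, canonical order, anticodon inside its window
  if (!identical(names(domains), DOMAIN_LABELS)) {
    stop("domains must be named ", paste(DOMAIN_LABELS, collapse = ", "),
         " in canonical order")
  }
  pos <- 0L
  for (lab in DOMAIN_LABELS) {
    iv <- domains[[lab]]
    if (iv[1] != pos || iv[2] <= iv[1]) {
      stop("domain tiling is not contiguous at ", lab)
    }
    pos <- iv[2]
  }
  if (pos != n) stop("domain tiling does not cover the gene sequence")
  arm <- substr0(gene_seq, domains$ANTICODON[1], domains$ANTICODON[2])
  if (!grepl(anticodon_triplet, arm, fixed = TRUE)) {
    stop("anticodon triplet not contained in the ANTICODON interval")
  }
  structure(
    list(gene_seq = gene_seq, domains = domains,
         anticodon_triplet = anticodon_triplet, source_id = source_id),
    class = "trnf_reference"
  )
}

#' @export
print.trnf_reference <- function(x, ...) {
  cat("trnF reference model (", x$source_id, ")\n", sep = "")
  cat("  gene: ", nchar(x$gene_seq), " nt, anticodon ",
      x$anticodon_triplet, "\n", sep = "")
  for (lab in names(x$domains)) {
    iv <- x$domains[[lab]]
    cat(sprintf("  %-9s [%3d, %3d)  %s\n", lab, iv[1], iv[2],
                substr0(x$gene_seq, iv[1], iv[2])))
  }
  invisible(x)
}

# domain sequence accessor
domain_seq <- function(ref, label) {
  iv <- ref$domains[[label]]
  substr0(ref$gene_seq, iv[1], iv[2])
}

#' Load a trnF reference model
#'
#' With no arguments, returns the packaged default: a synthetic 73-nt
#' tRNA-Phe(GAA) template with the canonical cloverleaf layout and a curated
#' domain decomposition, shipped with the package so that nothing is
#' downloaded. With a record, extracts the gene from the given span.
#'
#' @param record `NULL` (packaged default), a `genbank_record` (see
#'   [read_genbank()]), a `spacer_sequence`, or a plain nucleotide string.
#' @param span 1-based inclusive `c(start, end)` of the gene within the
#'   record; when `NULL` and the record carries a trnF tRNA feature
#'   annotation, that feature's location is used.
#' @param strand `"+"` or `"-"`; on `"-"` the extracted sequence is
#'   reverse-complemented before decomposition.
#' @param anticodon_triplet anticodon 3-mer, default `"GAA"`.
#' @param mode anticodon window mode, see [decompose_trnf()].
#' @return a [trnf_reference()] object.
#' @examples
#' load_reference()
#' @export
load_reference <- function(record = NULL, span = NULL, strand = c("+", "-"),
                           anticodon_triplet = "GAA",
                           mode = c("arm", "loop")) {
  strand <- match.arg(strand)
  mode <- match.arg(mode)
  if (is.null(record)) {
    fa <- system.file("extdata", "trnF_gene_synthetic.fasta",
                      package = "trnfscan", mustWork = TRUE)
    sc <- system.file("extdata", "trnF_gene_synthetic_domains.json",
                      package = "trnfscan", mustWork = TRUE)
    seqs <- Biostrings::readDNAStringSet(fa)
    side <- jsonlite::read_json(sc, simplifyVector = TRUE)
    domains <- lapply(side$domains, as.integer)[DOMAIN_LABELS]
    return(trnf_reference(as.character(seqs[[1]]), domains = domains,
                          anticodon_triplet = side$anticodon_triplet,
                          source_id = side$source_id))
  }
  seq <- if (is.character(record)) {
    record
  } else if (inherits(record, "genbank_record")) {
    record$sequence
  } else if (inherits(record, "spacer_sequence")) {
    record$seq
  } else {
    stop("unsupported record type: ", paste(class(record), collapse = "/"))
  }
  seq <- sanitize_dna(seq)
  if (is.null(span) && inherits(record, "genbank_record")) {
    feat <- record$features
    hit <- which(feat$type == "tRNA" &
                   (grepl("trnF", feat$gene %||% "", ignore.case = TRUE) |
                      grepl("Phe", feat$product %||% "", ignore.case = TRUE)))
    if (length(hit) == 0L) stop("record has no trnF tRNA feature and no span was given")
    span <- c(feat$start[hit[1]], feat$end[hit[1]])
    if (identical(feat$strand[hit[1]], "-")) strand <- "-"
  }
  if (is.null(span)) stop("span is required for unannotated records")
  span <- as.integer(span)
  if (span[1] > span[2]) stop("coordinate error: span start exceeds span end")
  if (span[1] < 1L || span[2] > nchar(seq)) {
    stop("coordinate error: span [", span[1], ", ", span[2],
         "] outside record of length ", nchar(seq))
  }
  if (span[2] - span[1] + 1L < 60L) stop("span shorter than 60 nt")
  gene <- substr(seq, span[1], span[2])
  if (strand == "-") gene <- revcomp(gene)
  if (!grepl(anticodon_triplet, gene, fixed = TRUE)) {
    stop("reference-validation error: extracted sequence lacks the anticodon triplet")
  }
  src <- if (inherits(record, "genbank_record")) {
    paste0(record$accession %||% record$name, ":", span[1], "-", span[2], "(", strand, ")")
  } else {
    paste0("span:", span[1], "-", span[2], "(", strand, ")")
  }
  trnf_reference(gene, anticodon_triplet = anticodon_triplet,
                 source_id = src, mode = mode)
}
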