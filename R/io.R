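# Format readers and writers: FASTA and GenBank flat files in, GFF3 and
# TSV out, plus the packaged Solanaceae copy-number survey fixture. GFF3 is
# handled through rtracklayer/GenomicRanges; the GenBank flat-file parser
# is a minimal in-package reader (sequence, simple feature locations) since
# no installed package parses GenBank flat files from disk.

#' Read spacer sequences from FASTA or GenBank flat files
#'
#' @param path input file.
#' @param format `"fasta"` (default) or `"genbank"`.
#' @param span optional 1-based inclusive `c(start, end)` restricting every
#'   record to a subregion (e.g. a reference-genome spacer locus).
#' @return list of [spacer_sequence()] objects. FASTA ids are the first
#'   whitespace-delimited header token; the remainder of the header, when
#'   present, becomes the taxon label. An empty file yields an empty list
#'   with a warning.
#' @export
read_sequences <- function(path, format = c("fasta", "genbank"), span = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read '", path, "'")
  if (format == "fasta") {
    if (file.size(path) == 0L) {
      warning("empty file: ", path)
      return(list())
    }
    set <- Biostrings::readDNAStringSet(path)
    if (length(set) == 0L) {
      warning("no records in ", path)
      return(list())
    }
    out <- vector("list", length(set))
    for (i in seq_along(set)) {
      header <- names(set)[i]
      id <- sub("\\s.*$", "", header)
      taxon <- trimws(sub("^\\S+\\s*", "", header))
      if (taxon == "") taxon <- id
      seq <- as.character(set[[i]])
      if (!is.null(span)) seq <- .slice_span(seq, span, id)
      out[[i]] <- spacer_sequence(id, seq, taxon = taxon, source = id)
    }
    return(out)
  }
  recs <- read_genbank(path)
  if (length(recs) == 0L) {
    warning("no records in ", path)
    return(list())
  }
  lapply(recs, function(r) {
    seq <- r$sequence
    id <- r$accession %||% r$name
    if (!is.null(span)) seq <- .slice_span(seq, span, id)
    spacer_sequence(id, seq, taxon = r$organism %||% id, source = id)
  })
}

.slice_span <- function(seq, span, id) {
  span <- as.integer(span)
  if (span[1] > span[2]) stop("coordinate error: reversed span for '", id, "'")
  if (span[1] < 1L || span[2] > nchar(seq)) {
    stop("coordinate error: span outside record '", id, "'")
  }
  substr(seq, span[1], span[2])
}

#' Parse a GenBank flat file
#'
#' Minimal reader for GenBank flat files: LOCUS name, ACCESSION,
#' DEFINITION, ORGANISM, the ORIGIN sequence, and FEATURES with simple
#' `start..end` / `complement(start..end)` locations plus `/gene` and
#' `/product` qualifiers. Multi-record files (separated by `//`) are
#' supported; joined or fuzzy locations are not.
#'
#' @param path GenBank flat file.
#' @return list of `genbank_record` objects: lists with `name`,
#'   `accession`, `definition`, `organism`, `sequence`, and `features`
#'   (data.frame `type`, `start`, `end` (1-based inclusive), `strand`,
#'   `gene`, `product`).
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) return(list())
  rec_end <- grep("^//\\s*$", lines)
  if (length(rec_end) == 0L) rec_end <- length(lines)
  starts <- c(1L, head(rec_end, -1L) + 1L)
  recs <- list()
  for (k in seq_along(rec_end)) {
    block <- lines[starts[k]:rec_end[k]]
    if (!any(grepl("^LOCUS", block))) next
    recs[[length(recs) + 1L]] <- .parse_genbank_record(block, path)
  }
  recs
}

.parse_genbank_record <- function(block, path) {
  locus <- grep("^LOCUS", block, value = TRUE)
  if (length(locus) == 0L) stop("malformed GenBank file ", path, ": no LOCUS line")
  name <- strsplit(trimws(sub("^LOCUS", "", locus[1])), "\\s+")[[1]][1]
  getfield <- function(tag) {
    i <- grep(paste0("^", tag), block)
    if (length(i) == 0L) return(NULL)
    trimws(sub(paste0("^", tag), "", block[i[1]]))
  }
  accession <- getfield("ACCESSION")
  if (!is.null(accession)) accession <- strsplit(accession, "\\s+")[[1]][1]
  definition <- getfield("DEFINITION")
  org_i <- grep("^\\s*ORGANISM", block)
  organism <- if (length(org_i) > 0L) {
    trimws(sub("^\\s*ORGANISM", "", block[org_i[1]]))
  } else NULL
  # ORIGIN sequence
  o <- grep("^ORIGIN", block)
  sequence <- ""
  if (length(o) > 0L) {
    seq_lines <- block[(o[1] + 1L):length(block)]
    seq_lines <- seq_lines[!grepl("^//", seq_lines)]
    sequence <- sanitize_dna(gsub("[0-9 ]", "", paste(seq_lines, collapse = "")))
  }
  # FEATURES table
  f <- grep("^FEATURES", block)
  features <- data.frame(type = character(0), start = integer(0),
                         end = integer(0), strand = character(0),
                         gene = character(0), product = character(0))
  if (length(f) > 0L) {
    fend <- if (length(o) > 0L) o[1] - 1L else length(block)
    flines <- block[(f[1] + 1L):fend]
    key_i <- grep("^ {5}\\S", flines)
    for (j in seq_along(key_i)) {
      i0 <- key_i[j]
      i1 <- if (j < length(key_i)) key_i[j + 1L] - 1L else length(flines)
      toks <- strsplit(trimws(flines[i0]), "\\s+")[[1]]
      if (length(toks) < 2L) {
        stop("malformed GenBank file ", path, ": bad feature line '",
             flines[i0], "'")
      }
      loc <- toks[2]
      strand <- if (grepl("complement", loc)) "-" else "+"
      m <- regmatches(loc, regexec("(\\d+)\\.\\.(\\d+)", loc))[[1]]
      if (length(m) < 3L) next   # joined/fuzzy locations skipped
      qual <- paste(flines[i0:i1], collapse = " ")
      getq <- function(q) {
        mm <- regmatches(qual, regexec(paste0("/", q, '="([^"]*)"'), qual))[[1]]
        if (length(mm) >= 2L) mm[2] else NA_character_
      }
      features <- rbind(features, data.frame(
        type = toks[1], start = as.integer(m[2]), end = as.integer(m[3]),
        strand = strand, gene = getq("gene"), product = getq("product")))
    }
  }
  structure(list(name = name, accession = accession,
                 definition = definition, organism = organism,
                 sequence = sequence, features = features),
            class = "genbank_record")
}

#' Write spacer sequences to FASTA
#'
#' @param spacers list of [spacer_sequence()] objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_spacers_fasta <- function(spacers, path) {
  set <- Biostrings::DNAStringSet(vapply(spacers, `[[`, character(1), "seq"))
  names(set) <- vapply(spacers, function(s) {
    if (identical(s$taxon, s$id)) s$id else paste(s$id, s$taxon)
  }, character(1))
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

# Build the GFF3 feature set for one scan result as a GRanges. Internal
# 0-based half-open coordinates become 1-based inclusive; minus-strand
# scans are mapped back to the plus strand of the input record.
.result_granges <- function(res) {
  L <- res$seq_length
  flip <- identical(res$strand_used, "-")
  conv <- function(iv) {
    if (flip) c(L - iv[2] + 1L, L - iv[1]) else c(iv[1] + 1L, iv[2])
  }
  strand <- if (flip) "-" else "+"
  rows <- list()
  add <- function(type, iv, id, parent = NA_character_, name = NA_character_,
                  extra = NA_character_) {
    p <- conv(iv)
    rows[[length(rows) + 1L]] <<- data.frame(
      start = p[1], end = p[2], type = type, ID = id, Parent = parent,
      Name = name, Note = extra, stringsAsFactors = FALSE)
  }
  pid <- function(...) paste(c(res$sequence_id, ...), collapse = ":")
  if (!is.null(res$functional_gene)) {
    add("gene", res$functional_gene$interval, pid("trnF"), name = "trnF",
        extra = sprintf("identity=%.3f", res$functional_gene$identity))
  }
  for (cp in res$copies) {
    cid <- pid(sprintf("psc%d", cp$ordinal))
    add("pseudogene", cp$interval, cid,
        name = sprintf("trnF_pseudogene_copy_%d", cp$ordinal))
    if (!is.null(cp$border)) {
      add("sequence_motif", cp$border$interval, paste0(cid, ":border"),
          parent = cid, name = "ATTG_border",
          extra = sprintf("g_run=%d;core_mismatches=%d", cp$border$g_run,
                          cp$border$mismatches))
    }
    for (h in seq_len(nrow(cp$hits))) {
      add("sequence_feature",
          cp$hits$start[h] + cp$interval[1] + c(0L, cp$hits$end[h] - cp$hits$start[h]),
          paste0(cid, ":dom", h), parent = cid, name = cp$hits$label[h],
          extra = sprintf("identity=%.3f", cp$hits$identity[h]))
    }
    for (r in seq_len(nrow(cp$internal_repeats))) {
      rep_r <- cp$internal_repeats[r, ]
      w <- nchar(rep_r$unit) * rep_r$n_units
      add("repeat_region",
          cp$interval[1] + rep_r$start + c(0L, w),
          paste0(cid, ":rep", r), parent = cid,
          name = sprintf("(%s)%d", rep_r$unit, rep_r$n_units))
    }
  }
  for (p in seq_len(nrow(res$promoters))) {
    pr <- res$promoters[p, ]
    add("regulatory_region", c(pr$m35_start, pr$m35_end),
        pid(sprintf("prom%d_35", p)), name = "minus35",
        extra = sprintf("mismatches=%d", pr$m35_mismatches))
    add("regulatory_region", c(pr$m10_start, pr$m10_end),
        pid(sprintf("prom%d_10", p)), name = "minus10",
        extra = sprintf("mismatches=%d;spacer_len=%d", pr$m10_mismatches,
                        pr$spacer_len))
  }
  if (length(rows) == 0L) return(NULL)
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = res$sequence_id,
    ranges = IRanges::IRanges(df$start, df$end),
    strand = strand)
  gr$type <- df$type
  gr$ID <- df$ID
  gr$Name <- df$Name
  gr$Note <- df$Note
  gr$Parent <- IRanges::CharacterList(
    lapply(df$Parent, function(p) if (is.na(p)) character(0) else p))
  gr
}

#' Write scan results to GFF3
#'
#' Feature types: `gene` (functional trnF), `pseudogene` (each copy) with
#' `Parent`-linked subfeatures (`sequence_motif` for the bordering motif,
#' `sequence_feature` for domain hits, `repeat_region` for simple tandem
#' repeats), and `regulatory_region` for promoter elements. Coordinates
#' are 1-based inclusive on the plus strand of the input record; scans
#' performed on the reverse strand carry strand `-`.
#'
#' @param results a `scan_result` or list of them.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(results, path) {
  if (inherits(results, "scan_result")) results <- list(results)
  grs <- Filter(Negate(is.null), lapply(unname(results), .result_granges))
  gr <- if (length(grs) == 0L) GenomicRanges::GRanges() else
    suppressWarnings(do.call(c, grs))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a GFF3 file back as a GRanges
#'
#' Thin wrapper over `rtracklayer::import` used for round-trip checks.
#'
#' @param path GFF3 file.
#' @return `GRanges` with `type`, `ID`, `Name`, `Parent` columns.
#' @export
read_gff3 <- function(path) {
  rtracklayer::import(path, format = "gff3")
}

#' Write the per-sequence copy-number table
#'
#' @param results list of `scan_result` objects.
#' @param path output TSV; columns `id`, `taxon`, `accession`,
#'   `copy_number`, `warnings` (semicolon-joined).
#' @return the table, invisibly.
#' @export
write_copy_table <- function(results, path) {
  if (inherits(results, "scan_result")) results <- list(results)
  tab <- do.call(rbind, lapply(results, function(r) {
    data.frame(id = r$sequence_id, taxon = r$taxon, accession = r$source,
               copy_number = r$copy_number,
               warnings = paste(r$warnings, collapse = "; "))
  }))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}

#' Read a taxon states table
#'
#' @param path TSV with columns `taxon` and `copy_number`.
#' @return data.frame.
#' @export
read_states <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("taxon", "copy_number") %in% names(df))) {
    stop("states table must have columns 'taxon' and 'copy_number'")
  }
  df
}

#' Load the packaged Solanaceae trnF pseudogene survey table
#'
#' The published family-wide survey of trnF pseudogene copy numbers
#' (taxon, GenBank accession, tribe, copy number, footnote marks), shipped
#' verbatim — including the apparent `Jalotmata` misprint — together with
#' the one-entry genus-spelling corrections table. Corrections are only
#' applied where explicitly requested (e.g. in [genus_of()]), so the
#' printed artifact and its biological reading stay separable.
#'
#' @return object of class `table1_fixture`: list with `rows` (data.frame
#'   `taxon`, `accession`, `tribe`, `copy_number`, `footnotes`) and
#'   `corrections` (named character vector).
#' @examples
#' t1 <- load_table1()
#' nrow(t1$rows)
#' length(unique(genus_of(t1$rows$taxon, t1$corrections)))
#' @export
load_table1 <- function() {
  path <- system.file("extdata", "solanaceae_trnF_survey.tsv",
                      package = "trnfscan", mustWork = TRUE)
  rows <- read.delim(path, stringsAsFactors = FALSE,
                     colClasses = c(copy_number = "integer"))
  rows$footnotes[is.na(rows$footnotes)] <- ""
  stopifnot(!anyNA(rows$copy_number),
            all(rows$copy_number >= 1L), all(rows$copy_number <= 7L),
            !anyDuplicated(rows$accession))
  structure(list(rows = rows, corrections = c(Jalotmata = "Jaltomata")),
            class = "table1_fixture")
}

#' Per-taxon copy-number states from the packaged survey table
#'
#' @return data.frame with `taxon` and `copy_number`, suitable for
#'   [character_map()].
#' @export
fixture_states <- function() {
  load_table1()$rows[, c("taxon", "copy_number")]
}

#' Fetch GenBank records over the network (optional helper)
#'
#' Downloads nucleotide records from NCBI efetch as a GenBank flat file.
#' Entirely optional: nothing in the package or its tests requires network
#' access; all analyses run against local files or packaged fixtures.
#'
#' @param accessions character vector of accessions.
#' @param path destination file.
#' @return `path` invisibly, or an error when offline.
#' @export
fetch_genbank <- function(accessions, path) {
  url <- paste0(
    "https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi",
    "?db=nuccore&rettype=gb&retmode=text&id=",
    paste(accessions, collapse = ","))
  utils::download.file(url, path, quiet = TRUE)
  invisible(path)
}
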