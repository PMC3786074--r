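# Planted-truth simulator: builds trnL-F spacer sequences with a known
# functional trnF gene, 0-7 upstream tandem pseudogene copies with ATT(G)n
# borders, optional sigma70-type promoter pair and simple-repeat tract, and
# i.i.d. substitution/indel decay. Every planted feature is recorded in a
# truth table so the scanner can be tested closed-loop without downloads.

#' Simulation configuration
#'
#' @param n_taxa number of taxa in a generated dataset, default 12.
#' @param n_positive number of taxa carrying pseudogene copies; default
#'   two thirds of `n_taxa` (rounded).
#' @param copy_number_dist distribution of copy numbers for positive taxa:
#'   `"uniform"` (uniform on 1..7, default) or `"table1"` (the empirical
#'   copy-number frequencies of the packaged Solanaceae survey fixture).
#' @param domain_menu list of domain subsets a copy may be composed of
#'   (canonical order is imposed). Default: DDOM+ANTICODON, ANTICODON+TDOM,
#'   DDOM+ANTICODON+TDOM — every copy retains the anticodon domain (the
#'   most conserved element) and none retains the acceptor stems.
#' @param menu_weights sampling weights for `domain_menu`.
#' @param sub_rate per-site substitution probability, default 0.02.
#' @param indel_rate per-site indel probability (insertion or deletion with
#'   equal chance; geometric length, mean 2), default 0.005.
#' @param grun_range ATT(G)n border G-run length range, default 1..4
#'   (uniform).
#' @param promoter plant a -35/-10 promoter pair 5' of the array? Default
#'   `TRUE`.
#' @param promoter_spacer gap (nt) between the -35 and -10 hexamers,
#'   default 17.
#' @param background_gc GC fraction of random background, default 0.32
#'   (AT-rich plastid intergenic composition).
#' @param bg_len_range length range of the 5' background segment,
#'   default 80..160.
#' @param gap_len_range length range of the segment between promoter and
#'   first copy, default 20..60.
#' @param repeat_tract insert a simple AT/AAT tandem tract into the gap
#'   segment? Default `TRUE`.
#' @param linker_len length of the linker between the last copy and the
#'   functional gene, default 0 (the tandem array directly abuts the gene).
#' @param tail_len_range length range of the 3' tail after the gene,
#'   default 10..30.
#' @param scenario tree scenario for [generate_dataset()]:
#'   `"single_origin"` (positives form one clade, default) or
#'   `"scattered"` (positives placed at random tips).
#' @return named list of class `sim_config`.
#' @export
sim_config <- function(n_taxa = 12L, n_positive = NULL,
                       copy_number_dist = c("uniform", "table1"),
                       domain_menu = list(c("DDOM", "ANTICODON"),
                                          c("ANTICODON", "TDOM"),
                                          c("DDOM", "ANTICODON", "TDOM")),
                       menu_weights = c(0.35, 0.25, 0.40),
                       sub_rate = 0.02, indel_rate = 0.005,
                       grun_range = c(1L, 4L), promoter = TRUE,
                       promoter_spacer = 17L, background_gc = 0.32,
                       bg_len_range = c(80L, 160L),
                       gap_len_range = c(20L, 60L), repeat_tract = TRUE,
                       linker_len = 0L, tail_len_range = c(10L, 30L),
                       scenario = c("single_origin", "scattered")) {
  copy_number_dist <- match.arg(copy_number_dist)
  scenario <- match.arg(scenario)
  if (is.null(n_positive)) n_positive <- max(1L, round(2 * n_taxa / 3))
  cfg <- list(
    n_taxa = as.integer(n_taxa), n_positive = as.integer(n_positive),
    copy_number_dist = copy_number_dist,
    domain_menu = lapply(domain_menu, function(m) {
      m <- match.arg(m, DOMAIN_LABELS, several.ok = TRUE)
      DOMAIN_LABELS[DOMAIN_LABELS %in% m]   # canonical order
    }),
    menu_weights = menu_weights, sub_rate = sub_rate,
    indel_rate = indel_rate, grun_range = as.integer(grun_range),
    promoter = isTRUE(promoter), promoter_spacer = as.integer(promoter_spacer),
    background_gc = background_gc, bg_len_range = as.integer(bg_len_range),
    gap_len_range = as.integer(gap_len_range),
    repeat_tract = isTRUE(repeat_tract), linker_len = as.integer(linker_len),
    tail_len_range = as.integer(tail_len_range), scenario = scenario
  )
  stopifnot(cfg$sub_rate >= 0, cfg$sub_rate <= 1,
            cfg$indel_rate >= 0, cfg$indel_rate <= 1,
            length(cfg$domain_menu) == length(cfg$menu_weights),
            all(vapply(cfg$domain_menu, length, integer(1)) > 0L),
            cfg$n_positive <= cfg$n_taxa,
            cfg$grun_range[1] >= 1L)
  structure(cfg, class = "sim_config")
}

# i.i.d. site-wise decay: substitutions, then insertions/deletions with
# geometric(mean 2) lengths. Returns the mutated string.
mutate_seq <- function(x, sub_rate, indel_rate, gc = 0.32) {
  if (sub_rate == 0 && indel_rate == 0) return(x)
  v <- chars(x)
  n <- length(v)
  if (sub_rate > 0) {
    hit <- runif(n) < sub_rate
    for (i in which(hit)) {
      v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1L)
    }
  }
  if (indel_rate > 0) {
    hit <- which(runif(n) < indel_rate)
    if (length(hit) > 0L) {
      pieces <- character(0)
      pos <- 1L
      for (i in hit) {
        if (i < pos) next
        len <- rgeom(1L, 0.5) + 1L
        if (runif(1) < 0.5) {                       # deletion of len sites
          pieces <- c(pieces, paste(v[pos:i][-length(v[pos:i])], collapse = ""))
          pos <- min(n + 1L, i + len)
        } else {                                    # insertion after site i
          pieces <- c(pieces, paste(v[pos:i], collapse = ""),
                      random_dna(len, gc))
          pos <- i + 1L
        }
      }
      if (pos <= n) pieces <- c(pieces, paste(v[pos:n], collapse = ""))
      return(paste(pieces, collapse = ""))
    }
  }
  paste(v, collapse = "")
}

# Background sampler, rejection-screened so that no anticodon-arm anchor
# (scanner default edit budget) occurs by chance: planted copies must be
# the only anchors for the truth table to be complete.
clean_background <- function(n, ref, gc = 0.32, max_edits = 3L,
                             max_tries = 25L) {
  if (n <= 0L) return("")
  arm <- domain_seq(ref, "ANTICODON")
  for (k in seq_len(max_tries)) {
    bg <- random_dna(n, gc)
    if (nrow(approx_matches(bg, arm, max_edits)) == 0L) return(bg)
  }
  stop("could not sample anchor-free background after ", max_tries, " tries")
}

#' Generate one decayed pseudogene copy
#'
#' Concatenates the chosen reference domains in canonical order, prepends a
#' sampled ATT(G)n bordering motif, and applies site-wise
#' substitution/indel decay. Uses R's global RNG stream (seed it with
#' `set.seed()` for reproducibility).
#'
#' @param ref a [trnf_reference()].
#' @param composition character vector of domain labels (nonempty subset
#'   of ACC5, DDOM, ANTICODON, TDOM, ACC3).
#' @param cfg a [sim_config()].
#' @return list with `seq` (the copy string, border included), `truth`
#'   (list: `composition`, `border_len` (pre-decay), `pristine` — the copy
#'   before decay).
#' @export
generate_copy <- function(ref, composition, cfg = sim_config()) {
  stopifnot(length(composition) > 0L, all(composition %in% DOMAIN_LABELS))
  composition <- DOMAIN_LABELS[DOMAIN_LABELS %in% composition]
  g <- sample(seq(cfg$grun_range[1], cfg$grun_range[2]), 1L)
  border <- paste0("ATT", strrep("G", g))
  core <- paste(vapply(composition, domain_seq, character(1), ref = ref),
                collapse = "")
  pristine <- paste0(border, core)
  seq <- mutate_seq(pristine, cfg$sub_rate, cfg$indel_rate, cfg$background_gc)
  list(seq = seq,
       truth = list(composition = composition, border_len = nchar(border),
                    pristine = pristine))
}

#' Generate one spacer sequence with a planted pseudogene array
#'
#' Layout 5' to 3': random background — optional -35/(spacer)/-10 promoter
#' pair — gap segment (optionally with a simple-repeat tract) — `c` tandem
#' copies — linker — intact functional trnF gene — tail. All realized
#' intervals are recorded in the truth record. Deterministic given `seed`.
#'
#' @param taxon taxon label.
#' @param c_copies copy number in 0..7.
#' @param cfg a [sim_config()].
#' @param ref a [trnf_reference()]; packaged default when `NULL`.
#' @param seed optional integer seed (sets the global RNG).
#' @param id sequence id, default derived from the taxon.
#' @return list with `spacer` (a [spacer_sequence()]) and `truth` (list:
#'   `gene` interval, `copies` data.frame with `ordinal`, `start`, `end`,
#'   `border_start`, `border_end`, `composition`; `promoter` intervals or
#'   `NULL`; `tract` interval or `NULL`). Intervals 0-based half-open.
#' @export
generate_spacer <- function(taxon, c_copies, cfg = sim_config(), ref = NULL,
                            seed = NULL, id = NULL) {
  stopifnot(c_copies >= 0L, c_copies <= 7L)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(ref)) ref <- load_reference()
  if (is.null(id)) id <- gsub("[^A-Za-z0-9]+", "_", taxon)
  gc <- cfg$background_gc
  parts <- character(0)
  pos <- 0L
  truth <- list(gene = NULL, copies = NULL, promoter = NULL, tract = NULL)
  push <- function(s) {
    parts[[length(parts) + 1L]] <<- s
    pos <<- pos + nchar(s)
  }
  push(clean_background(sample(seq(cfg$bg_len_range[1], cfg$bg_len_range[2]), 1L),
                        ref, gc))
  if (cfg$promoter) {
    p35 <- c(pos, pos + 6L); push("TTGACA")
    push(clean_background(cfg$promoter_spacer, ref, gc))
    p10 <- c(pos, pos + 6L); push("GAGGAT")
    truth$promoter <- list(m35 = p35, m10 = p10)
  }
  gap_len <- sample(seq(cfg$gap_len_range[1], cfg$gap_len_range[2]), 1L)
  if (cfg$repeat_tract) {
    unit <- sample(c("AT", "AAT"), 1L)
    k <- sample(3:6, 1L)
    tract <- strrep(unit, k)
    pre <- sample.int(max(1L, gap_len - 5L), 1L)
    push(clean_background(pre, ref, gc))
    truth$tract <- c(pos, pos + nchar(tract)); push(tract)
    push(clean_background(max(0L, gap_len - pre), ref, gc))
  } else {
    push(clean_background(gap_len, ref, gc))
  }
  if (c_copies > 0L) {
    rows <- vector("list", c_copies)
    for (i in seq_len(c_copies)) {
      comp_i <- sample.int(length(cfg$domain_menu), 1L, prob = cfg$menu_weights)
      cp <- generate_copy(ref, cfg$domain_menu[[comp_i]], cfg)
      rows[[i]] <- data.frame(
        ordinal = i, start = pos, end = pos + nchar(cp$seq),
        border_start = pos, border_end = pos + cp$truth$border_len,
        composition = paste(cp$truth$composition, collapse = "+")
      )
      push(cp$seq)
    }
    truth$copies <- do.call(rbind, rows)
  } else {
    truth$copies <- data.frame(ordinal = integer(0), start = integer(0),
                               end = integer(0), border_start = integer(0),
                               border_end = integer(0),
                               composition = character(0))
  }
  if (cfg$linker_len > 0L) push(clean_background(cfg$linker_len, ref, gc))
  truth$gene <- c(pos, pos + nchar(ref$gene_seq))
  push(ref$gene_seq)
  push(clean_background(sample(seq(cfg$tail_len_range[1], cfg$tail_len_range[2]), 1L),
                        ref, gc))
  list(spacer = spacer_sequence(id, paste(parts, collapse = ""),
                                taxon = taxon, source = "synthetic"),
       truth = truth)
}

# Copy-number sampler for positive taxa.
.sample_copy_numbers <- function(n, dist) {
  if (dist == "uniform") return(sample(1:7, n, replace = TRUE))
  tab <- table(factor(fixture_states()$copy_number, levels = 1:7))
  sample(1:7, n, replace = TRUE, prob = as.numeric(tab))
}

# Random rooted pure-birth tree over the given labels.
.pure_birth_tree <- function(labels) {
  n <- length(labels)
  if (n == 1L) stop("need at least 2 taxa for a tree")
  tr <- ape::rphylo(n, birth = 1, death = 0)
  tr$tip.label <- gsub(" ", "_", labels)
  tr
}

#' Generate a full synthetic dataset
#'
#' One spacer per taxon (positives with 1-7 copies, negatives with the
#' functional gene only), a ground-truth table, a per-taxon states table,
#' and a random rooted pure-birth tree. Under the `"single_origin"`
#' scenario the positive taxa are constrained to a single clade; under
#' `"scattered"` they are placed at random tips. Deterministic given
#' `seed`.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed.
#' @param ref a [trnf_reference()]; packaged default when `NULL`.
#' @param dir optional output directory; when given, writes
#'   `spacers.fasta`, `truth.tsv`, `states.tsv` and `tree.nwk` there.
#' @return list with `spacers` (list of [spacer_sequence()]), `truth`
#'   (named list of per-sequence truth records), `states` (data.frame
#'   `taxon`, `copy_number`), `tree` (`phylo`), and `files` (paths, when
#'   `dir` was given).
#' @export
generate_dataset <- function(cfg = sim_config(), seed = 1L, ref = NULL,
                             dir = NULL) {
  set.seed(seed)
  if (is.null(ref)) ref <- load_reference()
  n <- cfg$n_taxa
  taxa <- sprintf("Simulatia species%02d", seq_len(n))
  pos_idx <- seq_len(cfg$n_positive)   # first n_positive taxa are positive
  copy_n <- integer(n)
  copy_n[pos_idx] <- .sample_copy_numbers(length(pos_idx), cfg$copy_number_dist)
  spacers <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    g <- generate_spacer(taxa[i], copy_n[i], cfg, ref)
    spacers[[i]] <- g$spacer
    truth[[i]] <- g$truth
  }
  names(truth) <- vapply(spacers, `[[`, character(1), "id")
  names(spacers) <- names(truth)
  states <- data.frame(taxon = taxa, copy_number = copy_n)
  # tree: positives form a clade under single_origin, random tips otherwise
  if (cfg$scenario == "single_origin") {
    neg <- taxa[-pos_idx]
    if (length(neg) >= 2L && length(pos_idx) >= 2L) {
      tpos <- .pure_birth_tree(taxa[pos_idx])
      tneg <- .pure_birth_tree(c(neg, "ATTACH"))
      where <- which(tneg$tip.label == "ATTACH")
      tree <- ape::bind.tree(tneg, tpos, where = where)
    } else {
      tree <- .pure_birth_tree(taxa)
    }
  } else {
    tree <- .pure_birth_tree(sample(taxa))
  }
  out <- list(spacers = spacers, truth = truth, states = states, tree = tree)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    fa <- file.path(dir, "spacers.fasta")
    write_spacers_fasta(spacers, fa)
    tt <- file.path(dir, "truth.tsv")
    write.table(truth_table(out), tt, sep = "\t", quote = FALSE,
                row.names = FALSE)
    st <- file.path(dir, "states.tsv")
    write.table(states, st, sep = "\t", quote = FALSE, row.names = FALSE)
    nw <- file.path(dir, "tree.nwk")
    ape::write.tree(tree, nw)
    out$files <- c(fasta = fa, truth = tt, states = st, tree = nw)
  }
  out
}

#' Flatten a dataset's truth records into one table
#'
#' @param dataset result of [generate_dataset()].
#' @return data.frame with one row per planted feature: `id`, `taxon`,
#'   `feature` (gene / copy / promoter_35 / promoter_10 / tract), `start`,
#'   `end` (0-based half-open), `ordinal`, `composition`.
#' @export
truth_table <- function(dataset) {
  rows <- list()
  add <- function(id, taxon, feature, iv, ordinal = NA_integer_,
                  composition = NA_character_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      id = id, taxon = taxon, feature = feature,
      start = iv[1], end = iv[2], ordinal = ordinal,
      composition = composition)
  }
  for (id in names(dataset$truth)) {
    tr <- dataset$truth[[id]]
    taxon <- dataset$spacers[[id]]$taxon
    add(id, taxon, "gene", tr$gene)
    if (!is.null(tr$promoter)) {
      add(id, taxon, "promoter_35", tr$promoter$m35)
      add(id, taxon, "promoter_10", tr$promoter$m10)
    }
    if (!is.null(tr$tract)) add(id, taxon, "tract", tr$tract)
    for (r in seq_len(nrow(tr$copies))) {
      add(id, taxon, "copy",
          c(tr$copies$start[r], tr$copies$end[r]),
          ordinal = tr$copies$ordinal[r],
          composition = tr$copies$composition[r])
    }
  }
  do.call(rbind, rows)
}
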