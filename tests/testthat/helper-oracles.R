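# Independent brute-force oracles and small construction helpers. Every
# oracle recomputes the quantity from first principles (exhaustive
# enumeration, utils::adist, regular expressions) without touching the
# package's own algorithmic path.

# --- approximate matching -------------------------------------------------

# Exhaustive sliding-window oracle for locally optimal non-overlapping
# approximate occurrences: per end, minimum adist over all window lengths,
# leftmost minimal start; then the same greedy (cost, start) selection.
oracle_approx_matches <- function(text, pattern, max_edits) {
  n <- nchar(text); m <- nchar(pattern)
  empty <- data.frame(start = integer(0), end = integer(0), edits = integer(0))
  if (n == 0L) return(empty)
  cand <- list()
  for (e in seq_len(n)) {
    lens <- seq(max(1L, m - max_edits), min(e, m + max_edits))
    if (length(lens) == 0L) next
    subs <- vapply(lens, function(L) substr(text, e - L + 1L, e), character(1))
    d <- as.integer(adist(pattern, subs))
    dmin <- min(d)
    if (dmin > max_edits) next
    starts <- e - lens
    cand[[length(cand) + 1L]] <- data.frame(
      start = min(starts[d == dmin]), end = e, edits = dmin)
  }
  if (length(cand) == 0L) return(empty)
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand$edits, cand$start, cand$end), , drop = FALSE]
  sel <- cand[0, , drop = FALSE]
  for (r in seq_len(nrow(cand))) {
    row <- cand[r, ]
    if (!any(sel$start < row$end & row$start < sel$end)) sel <- rbind(sel, row)
  }
  sel <- sel[order(sel$start), , drop = FALSE]
  rownames(sel) <- NULL
  sel
}

# --- tandem repeats -------------------------------------------------------

# Regex oracle: maximal perfect tandem runs via greedy leftmost matching.
oracle_tandem_runs <- function(text, units, min_units = 2L) {
  rows <- list()
  for (u in toupper(units)) {
    re <- sprintf("(?:%s){%d,}", u, min_units)
    m <- gregexpr(re, text, perl = TRUE)[[1]]
    if (identical(as.integer(m[1]), -1L)) next
    lens <- attr(m, "match.length")
    for (i in seq_along(m)) {
      n_full <- lens[i] %/% nchar(u)   # greedy regex stops at partial unit
      rows[[length(rows) + 1L]] <- data.frame(
        unit = u, start = as.integer(m[i]) - 1L, n_units = n_full)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(unit = character(0), start = integer(0),
                      n_units = integer(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$unit), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# --- promoter pairing -----------------------------------------------------

oracle_promoter_pairs <- function(region, budget = 1L, spacer = c(12L, 25L)) {
  n <- nchar(region)
  ham <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  hits <- function(pat) {
    out <- integer(0)
    for (s in seq_len(max(0L, n - 5L))) {
      if (ham(substr(region, s, s + 5L), pat) <= budget) out <- c(out, s - 1L)
    }
    out
  }
  p35 <- hits("TTGACA"); p10 <- hits("GAGGAT")
  rows <- list()
  for (a in p35) for (b in p10) {
    gap <- b - (a + 6L)
    if (gap >= spacer[1] && gap <= spacer[2]) {
      rows[[length(rows) + 1L]] <- c(a, b)
    }
  }
  if (length(rows) == 0L) return(matrix(integer(0), ncol = 2))
  do.call(rbind, rows)
}

# --- parsimony ------------------------------------------------------------

# Exhaustive minimum over all internal 0/1 labelings.
oracle_min_changes <- function(tree, states01) {
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  labs <- gsub("_", " ", tree$tip.label)
  leaf <- as.integer(states01[labs] > 0L)
  best <- Inf
  for (code in 0:(2^nnode - 1L)) {
    internal <- as.integer(intToBits(code))[seq_len(nnode)]
    lab <- c(leaf, internal)
    cost <- sum(lab[tree$edge[, 1]] != lab[tree$edge[, 2]])
    best <- min(best, cost)
  }
  as.integer(best)
}

# --- tree construction ----------------------------------------------------

# Pectinate (ladder) rooted tree over the given labels, fully resolved.
ladder_tree <- function(labels) {
  labels <- gsub(" ", "_", labels)
  nwk <- Reduce(function(a, b) paste0("(", a, ",", b, ")"), labels)
  ape::read.tree(text = paste0(nwk, ";"))
}

# Random rooted topology with polytomies (each internal node has 2-4
# children), labelled by `labels`.
random_polytomy_tree <- function(labels) {
  labels <- gsub(" ", "_", labels)
  build <- function(xs) {
    if (length(xs) == 1L) return(xs)
    k <- min(length(xs), sample(2:4, 1L))
    groups <- split(xs, sort(rep_len(seq_len(k), length(xs))))
    paste0("(", paste(vapply(groups, build, character(1)), collapse = ","), ")")
  }
  ape::read.tree(text = paste0(build(sample(labels)), ";"))
}

# Random ACGT string, AT-rich by default.
rand_dna <- function(n, gc = 0.32) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Substitute positions (1-based) of a string with given bases.
subst_at <- function(x, pos, base) {
  v <- strsplit(x, "")[[1]]
  v[pos] <- base
  paste(v, collapse = "")
}
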