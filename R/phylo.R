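# Character mapping of pseudogene presence onto rooted trees: Hartigan-Fitch
# small parsimony (exact minimum-change count, polytomies allowed), Dollo
# single-gain reconstruction, and delimitation of the pseudogene-defined
# clade with its genus census.

# normalize taxon labels for matching: newick files carry underscores
norm_label <- function(x) gsub("_", " ", trimws(x))

#' Bind copy-number states to a rooted tree
#'
#' @param states named integer vector or data.frame (`taxon`,
#'   `copy_number`): copy number per taxon, 0 = pseudogene absent, `NA` =
#'   unknown (excluded, not treated as absent).
#' @param tree rooted `phylo` tree; tip labels are matched to taxa after
#'   translating underscores to spaces.
#' @return object of class `character_map`: list with `tree` (pruned to
#'   the taxa that have states), `states` (named, tree order),
#'   `dropped_tips`, `missing_states`. Taxa present in the tree without a
#'   state (or with `NA`) are pruned with a warning.
#' @export
character_map <- function(states, tree) {
  if (is.data.frame(states)) {
    states <- setNames(states$copy_number, states$taxon)
  }
  stopifnot(inherits(tree, "phylo"))
  names(states) <- norm_label(names(states))
  tips <- norm_label(tree$tip.label)
  have <- tips %in% names(states) & !is.na(states[tips])
  dropped <- tree$tip.label[!have]
  if (length(dropped) > 0L) {
    warning("pruning ", length(dropped),
            " tip(s) without a recorded state: ",
            paste(head(dropped, 5L), collapse = ", "),
            if (length(dropped) > 5L) ", ..." else "")
    tree <- ape::drop.tip(tree, dropped)
    tips <- norm_label(tree$tip.label)
  }
  if (is.null(tree) || ape::Ntip(tree) < 2L) {
    stop("fewer than 2 tips remain after pruning")
  }
  missing_states <- setdiff(names(states), tips)
  st <- setNames(as.integer(states[tips]), tips)
  if (any(st < 0L, na.rm = TRUE)) stop("copy numbers must be >= 0")
  structure(list(tree = tree, states = st, dropped_tips = dropped,
                 missing_states = missing_states),
            class = "character_map")
}

# children lists per node from an edge matrix
.children_of <- function(tree) {
  n_all <- ape::Ntip(tree) + tree$Nnode
  ch <- vector("list", n_all)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; c <- tree$edge[e, 2]
    ch[[p]] <- c(ch[[p]], c)
  }
  ch
}

#' Minimum number of binary state changes on a rooted tree
#'
#' Exact small-parsimony count for a binary character by Hartigan's
#' generalization of the Fitch algorithm, valid on multifurcating trees:
#' at each internal node the state set is the set of states carried by the
#' maximal number of children, and the cost grows by (number of children
#' minus that maximum).
#'
#' @param tree rooted `phylo` tree (polytomies allowed).
#' @param states named 0/1 vector covering every tip (matched by label,
#'   underscores equal spaces); copy numbers > 1 are binarized to 1.
#' @return integer: the minimum number of state changes.
#' @export
fitch_min_changes <- function(tree, states) {
  stopifnot(inherits(tree, "phylo"))
  names(states) <- norm_label(names(states))
  tips <- norm_label(tree$tip.label)
  if (!all(tips %in% names(states)) || anyNA(states[tips])) {
    stop("input error: every leaf must carry a 0/1 state")
  }
  st <- as.integer(states[tips] > 0L)
  ntip <- ape::Ntip(tree)
  n_all <- ntip + tree$Nnode
  ch <- .children_of(tree)
  tr <- ape::reorder.phylo(tree, "postorder")
  # sets[v, ] = c(has0, has1)
  sets <- matrix(FALSE, n_all, 2L)
  sets[cbind(seq_len(ntip), st + 1L)] <- TRUE
  cost <- 0L
  parents <- unique(tr$edge[, 1])
  for (v in parents) {
    kids <- ch[[v]]
    n0 <- sum(sets[kids, 1L]); n1 <- sum(sets[kids, 2L])
    m <- max(n0, n1)
    sets[v, ] <- c(n0 == m, n1 == m)
    cost <- cost + length(kids) - m
  }
  as.integer(cost)
}

#' Dollo reconstruction: single gain, minimal losses
#'
#' Under a Dollo model the character is gained exactly once — at the most
#' recent common ancestor of the state-1 leaves — and subsequently lost.
#' Losses are the maximal all-zero subtrees descending from the gain node.
#'
#' @param tree rooted `phylo` tree.
#' @param states named 0/1 vector covering every tip (copy numbers are
#'   binarized).
#' @return list with `gain_node` (ape node id; a tip id when only one leaf
#'   is positive), `n_losses`, and `clade_tips` (tip labels under the gain
#'   node).
#' @export
dollo_reconstruction <- function(tree, states) {
  stopifnot(inherits(tree, "phylo"))
  names(states) <- norm_label(names(states))
  tips <- norm_label(tree$tip.label)
  if (!all(tips %in% names(states)) || anyNA(states[tips])) {
    stop("input error: every leaf must carry a 0/1 state")
  }
  st <- as.integer(states[tips] > 0L)
  pos_tips <- which(st == 1L)
  if (length(pos_tips) == 0L) stop("input error: no leaf carries state 1")
  ntip <- ape::Ntip(tree)
  if (length(pos_tips) == 1L) {
    return(list(gain_node = pos_tips, n_losses = 0L,
                clade_tips = tree$tip.label[pos_tips]))
  }
  gain <- ape::getMRCA(tree, pos_tips)
  n_all <- ntip + tree$Nnode
  ch <- .children_of(tree)
  # positive-leaf counts per subtree (postorder accumulation)
  tr <- ape::reorder.phylo(tree, "postorder")
  poscount <- integer(n_all)
  poscount[seq_len(ntip)] <- st
  for (v in unique(tr$edge[, 1])) {
    poscount[v] <- sum(poscount[ch[[v]]])
  }
  # maximal zero subtrees under the gain node: zero nodes with a
  # positive-containing parent inside the gain clade
  in_clade <- logical(n_all)
  in_clade[gain] <- TRUE
  # preorder sweep to flag descendants of gain
  tr_pre <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(tr_pre$edge))) {
    p <- tr_pre$edge[e, 1]; c <- tr_pre$edge[e, 2]
    if (in_clade[p]) in_clade[c] <- TRUE
  }
  parent <- integer(n_all)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  losses <- 0L
  for (v in seq_len(n_all)) {
    if (v == gain || !in_clade[v]) next
    if (poscount[v] == 0L && poscount[parent[v]] > 0L) losses <- losses + 1L
  }
  clade_tips <- tree$tip.label[which(in_clade[seq_len(ntip)])]
  list(gain_node = gain, n_losses = losses, clade_tips = clade_tips)
}

#' Extract genus names from taxon labels
#'
#' The genus is the first whitespace- or underscore-delimited token of the
#' label, optionally corrected through a misspelling table before counting.
#'
#' @param taxa character vector of taxon labels.
#' @param corrections named character vector mapping misspelled genus to
#'   the correct genus (e.g. `c(Jalotmata = "Jaltomata")`).
#' @return character vector of genus names (same length as `taxa`).
#' @export
genus_of <- function(taxa, corrections = NULL) {
  g <- vapply(strsplit(norm_label(taxa), "\\s+"), `[[`, character(1), 1L)
  if (!is.null(corrections) && length(corrections) > 0L) {
    hit <- g %in% names(corrections)
    g[hit] <- unname(corrections[g[hit]])
  }
  g
}

#' Delimit the pseudogene-defined clade
#'
#' Binarizes the copy-number states, computes the Fitch minimum-change
#' count (single origin means exactly one change), reconstructs the gain
#' node and losses under the Dollo model, and censuses the genera of the
#' clade subtended by the gain node.
#'
#' @param cm a [character_map()].
#' @param corrections genus-spelling corrections passed to [genus_of()];
#'   defaults to the packaged table (`Jalotmata` -> `Jaltomata`).
#' @return object of class `clade_report`: list with `gain_node`,
#'   `n_gains` (the Fitch count), `n_losses_dollo`, `clade_taxa`,
#'   `clade_genera` (sorted unique), `single_origin` (`n_gains == 1`).
#' @export
delimit_clade <- function(cm, corrections = load_table1()$corrections) {
  stopifnot(inherits(cm, "character_map"))
  bin <- setNames(as.integer(cm$states > 0L), names(cm$states))
  n_gains <- fitch_min_changes(cm$tree, bin)
  dollo <- dollo_reconstruction(cm$tree, bin)
  taxa <- norm_label(dollo$clade_tips)
  structure(list(
    gain_node = dollo$gain_node, n_gains = n_gains,
    n_losses_dollo = dollo$n_losses, clade_taxa = taxa,
    clade_genera = sort(unique(genus_of(taxa, corrections))),
    single_origin = n_gains == 1L
  ), class = "clade_report")
}

#' @export
print.clade_report <- function(x, ...) {
  cat("pseudogene clade report\n")
  cat("  minimum gains (Fitch): ", x$n_gains,
      if (x$single_origin) "  [single origin]" else "", "\n", sep = "")
  cat("  Dollo losses under gain node: ", x$n_losses_dollo, "\n", sep = "")
  cat("  clade: ", length(x$clade_taxa), " taxa, ",
      length(x$clade_genera), " genera\n", sep = "")
  invisible(x)
}

#' Annotate a tree with copy numbers and the gain node
#'
#' Decorates tip labels with their copy number (`label|n=3`) and labels
#' the gain node `PSI_GAIN`, so the result serializes losslessly to newick
#' through `ape::write.tree()`.
#'
#' @param cm a [character_map()].
#' @param report the [delimit_clade()] report produced from `cm`.
#' @return list with `tree` (decorated `phylo`) and `table` (data.frame
#'   `taxon`, `copy_number`, `in_clade`).
#' @export
annotate_tree <- function(cm, report) {
  stopifnot(inherits(cm, "character_map"), inherits(report, "clade_report"))
  tree <- cm$tree
  ntip <- ape::Ntip(tree)
  labs <- norm_label(tree$tip.label)
  cn <- cm$states[labs]
  tree$tip.label <- paste0(gsub(" ", "_", labs), "|n=", cn)
  if (is.null(tree$node.label)) {
    tree$node.label <- rep("", tree$Nnode)
  }
  if (report$gain_node > ntip) {
    tree$node.label[report$gain_node - ntip] <- "PSI_GAIN"
  }
  list(tree = tree,
       table = data.frame(taxon = labs, copy_number = unname(cn),
                          in_clade = labs %in% report$clade_taxa))
}
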