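# Species-overlap orthology: an internal node is a duplication iff the
# species sets of (any two of) its children intersect; orthologs of a query
# are the leaves whose LCA with the query is a speciation node.

#' Label gene-tree nodes as speciation or duplication by species overlap
#'
#' A post-order pass computes each node's species set; an internal node is a
#' duplication iff any two of its children's species sets intersect
#' (equivalently, the children's set sizes sum to more than the union size),
#' and a speciation otherwise.
#'
#' @param tree Rooted \code{phylo}.
#' @param species_map Named character vector mapping every leaf to a species.
#' @return A `labeled_tree`: list with `tree`, `species` (per leaf),
#'   `events` (per internal node, `"speciation"`/`"duplication"`) and
#'   `species_sets` (per node).
#' @export
label_events <- function(tree, species_map) {
  unmapped <- setdiff(tree$tip.label, names(species_map))
  if (length(unmapped)) {
    stop("gene ", unmapped[1L], " has no species mapping")
  }
  n_tip <- ape::Ntip(tree)
  n_all <- n_tip + tree$Nnode
  sets <- vector("list", n_all)
  species <- unname(species_map[tree$tip.label])
  for (i in seq_len(n_tip)) sets[[i]] <- species[i]
  ch <- tree_children(tree)
  events <- character(tree$Nnode)
  for (node in postorder_nodes(tree)) {
    if (node <= n_tip) next
    child_sets <- sets[ch[[node]]]
    u <- unique(unlist(child_sets, use.names = FALSE))
    sets[[node]] <- u
    dup <- sum(lengths(child_sets)) > length(u)
    events[node - n_tip] <- if (dup) "duplication" else "speciation"
  }
  structure(list(tree = tree,
                 species = stats::setNames(species, tree$tip.label),
                 events = events, species_sets = sets),
            class = "labeled_tree")
}

#' @export
print.labeled_tree <- function(x, ...) {
  cat("Labeled gene tree:", ape::Ntip(x$tree), "leaves,",
      sum(x$events == "duplication"), "duplication and",
      sum(x$events == "speciation"), "speciation nodes\n")
  invisible(x)
}

#' Orthologs and paralogs of a query leaf
#'
#' For each non-query leaf g, the relation is read off the event at
#' LCA(query, g): ortholog iff it is a speciation node. The table is sorted
#' by (relation, species, gene id).
#'
#' @param labeled A `labeled_tree` from [label_events()].
#' @param query_id Leaf label of the query.
#' @return Data frame with columns `gene_id`, `species_id`, `relation`
#'   (`"ortholog"`/`"paralog"`) and `lca_event`.
#' @export
orthologs_of <- function(labeled, query_id) {
  tree <- labeled$tree
  n_tip <- ape::Ntip(tree)
  q <- match(query_id, tree$tip.label)
  if (is.na(q)) stop("query leaf ", query_id, " absent from the tree")
  parent <- rep(NA_integer_, n_tip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  tipsets <- clade_tip_sets(tree)
  # walk rootward from the query: leaves first covered by an ancestor have
  # their LCA with the query at that ancestor
  covered <- query_id
  rows <- list()
  node <- parent[q]
  while (!is.na(node)) {
    event <- labeled$events[node - n_tip]
    new <- setdiff(tipsets[[node]], covered)
    if (length(new)) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = new,
        species_id = unname(labeled$species[new]),
        relation = if (event == "speciation") "ortholog" else "paralog",
        lca_event = event, stringsAsFactors = FALSE)
      covered <- c(covered, new)
    }
    node <- parent[node]
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab)) {
    tab <- data.frame(gene_id = character(0), species_id = character(0),
                      relation = character(0), lca_event = character(0))
  }
  tab[order(tab$relation, tab$species_id, tab$gene_id), , drop = FALSE]
}

#' Write an ortholog table as TSV
#'
#' @param table Data frame from [orthologs_of()].
#' @param path Output path.
#' @export
write_ortholog_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
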