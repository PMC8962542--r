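# Placing a query into a pre-computed (sub)tree: extend the MSA with the
# query, scan every edge for the minimum-parsimony attachment, root split
# subtrees on their outgroup, and graft subtrees back via the supertree.

FULL_MASK <- bitwShiftL(1L, 20L) - 1L

#' Align a query into a reference MSA (keep-length)
#'
#' The query is globally aligned against the per-column residue-frequency
#' profile of the reference MSA (expected BLOSUM62 score per column, affine
#' gaps: open 11, extend 1). Query-only insertion states are discarded so
#' reference columns are preserved byte-identically.
#'
#' @param query Protein sequence (>= 10 residues).
#' @param sub_msa Named character vector: the reference alignment.
#' @param query_id Id for the query row.
#' @return An `extended_msa`: list with `ref` (untouched input), `query_id`
#'   and `query_row` (aligned to the reference columns).
#' @export
add_to_msa <- function(query, sub_msa, query_id = "query") {
  query <- validate_query(query)
  validate_msa(sub_msa, "reference MSA")
  mat <- msa_matrix(sub_msa)
  C <- ncol(mat)
  letters21 <- c(AA_RESIDUES, "X")
  # column frequency profile over residues (gaps weight 0, occupancy kept
  # in the denominator so sparse columns score low and attract gaps)
  code <- match(mat, letters21)
  freq <- matrix(0, length(letters21), C)
  pos <- which(!is.na(code))
  col_j <- ((pos - 1L) %/% nrow(mat)) + 1L
  for (r in seq_along(letters21)) {
    sel <- code[pos] == r
    if (any(sel)) {
      tab <- tabulate(col_j[sel], nbins = C)
      freq[r, ] <- tab
    }
  }
  freq <- freq / nrow(mat)
  B <- blosum62()[letters21, letters21]
  q_chars <- strsplit(query, "")[[1]]
  S <- B[match(q_chars, letters21), , drop = FALSE] %*% freq
  map <- .profile_nw(S, 11, 1)
  row <- rep("-", C)
  row[map > 0L] <- q_chars[map[map > 0L]]
  structure(list(ref = sub_msa, query_id = query_id,
                 query_row = paste(row, collapse = "")),
            class = "extended_msa")
}

# bitmask encoding of residue characters (gap / X = any state)
char_masks <- function(chars) {
  idx <- match(chars, AA_RESIDUES)
  m <- bitwShiftL(1L, idx - 1L)
  m[is.na(idx)] <- FULL_MASK
  m
}

# columns that are parsimony-informative among the given rows: at least two
# residues (gaps/X ignored) each present at least twice
informative_columns <- function(mat) {
  apply(mat, 2, function(col) {
    col <- col[col != "-" & col != "X"]
    if (length(col) < 4L) return(FALSE)
    tab <- table(col)
    sum(tab >= 2L) >= 2L
  })
}

# render the tree as newick with the query attached midway along the edge
# into `edge_child`; new node carries no support label
newick_attach <- function(tree, edge_child, qid, pendant) {
  ch <- tree_children(tree)
  n_tip <- ape::Ntip(tree)
  elen <- tree$edge.length
  inc <- rep(NA_real_, n_tip + tree$Nnode)
  inc[tree$edge[, 2]] <- elen
  labels <- tree$node.label
  fmt <- function(x) format(x, digits = 12, scientific = FALSE, trim = TRUE)
  render <- function(v, with_len = TRUE) {
    if (v <= n_tip) {
      core <- tree$tip.label[v]
    } else {
      lab <- if (!is.null(labels)) labels[v - n_tip] else ""
      if (is.na(lab)) lab <- ""
      core <- paste0("(", paste(vapply(ch[[v]], render, character(1)),
                                collapse = ","), ")", lab)
    }
    if (v == edge_child) {
      half <- inc[v] / 2
      core <- paste0("(", core, ":", fmt(half), ",", qid, ":", fmt(pendant),
                     ")")
      if (with_len) return(paste0(core, ":", fmt(half)))
      return(core)
    }
    if (with_len && !is.na(inc[v])) return(paste0(core, ":", fmt(inc[v])))
    core
  }
  paste0(render(tree_root(tree), with_len = FALSE), ";")
}

# p-distance between two aligned rows (positions where both are residues)
p_distance <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  ok <- av != "-" & bv != "-" & av != "X" & bv != "X"
  if (!any(ok)) return(0)
  mean(av[ok] != bv[ok])
}

# smallest descendant tip label per node (deterministic edge naming)
min_tip_labels <- function(tree) {
  sets <- clade_tip_sets(tree)
  vapply(sets, function(s) sort(s)[1L], character(1))
}

#' Place a query on a reference tree by exhaustive parsimony edge scan
#'
#' Every edge of the rooted reference tree is tried as the attachment point;
#' the attachment is scored by total Fitch parsimony cost over the
#' parsimony-informative columns of the extended alignment (residues only,
#' gaps ignored). The query joins the minimum-cost edge at its midpoint with
#' a pendant branch length equal to the normalized p-distance to its nearest
#' leaf. Ties are broken by the edge topologically closest to the best-hit
#' representative's leaf, then by the lexicographically smallest descendant
#' label of the edge's child.
#'
#' @param ext An `extended_msa` from [add_to_msa()].
#' @param tree Reference \code{phylo}; its leaves must all have rows in
#'   `ext$ref`.
#' @param best_rep Optional gene id of the best search hit (tie-break
#'   anchor).
#' @return List with `tree` (query inserted), `score` (parsimony cost of the
#'   chosen attachment) and `edge_child` (node below the chosen edge).
#' @export
place_in_tree <- function(ext, tree, best_rep = NULL) {
  if (!all(tree$tip.label %in% names(ext$ref))) {
    stop("tree leaves missing from the extended MSA: ",
         setdiff(tree$tip.label, names(ext$ref))[1L])
  }
  qid <- ext$query_id
  rows <- c(ext$ref[tree$tip.label], stats::setNames(ext$query_row, qid))
  mat <- msa_matrix(rows)
  keep <- informative_columns(mat)
  n_tip <- ape::Ntip(tree)
  n_all <- n_tip + tree$Nnode
  q_node <- n_all + 1L
  x_node <- n_all + 2L
  if (any(keep)) {
    sub <- mat[, keep, drop = FALSE]
    L <- ncol(sub)
    masks <- matrix(FULL_MASK, L, n_all + 2L)
    for (i in seq_len(n_tip)) masks[, i] <- char_masks(sub[i, ])
    masks[, q_node] <- char_masks(sub[n_tip + 1L, ])
    storage.mode(masks) <- "integer"
    base_children <- tree_children(tree)
    base_post <- postorder_nodes(tree)
    costs <- numeric(nrow(tree$edge))
    for (e in seq_len(nrow(tree$edge))) {
      p <- tree$edge[e, 1]; c_node <- tree$edge[e, 2]
      children <- base_children
      children[[p]][children[[p]] == c_node] <- x_node
      children[[x_node]] <- c(c_node, q_node)
      children[[q_node]] <- integer(0)
      pos <- match(p, base_post)
      post <- append(base_post, x_node, after = pos - 1L)
      costs[e] <- .fitch_cost(children, post, masks)
    }
  } else {
    costs <- numeric(nrow(tree$edge))  # no signal: every edge cost 0
  }
  best_edges <- which(costs == min(costs))
  if (length(best_edges) > 1L) {
    if (!is.null(best_rep) && best_rep %in% tree$tip.label) {
      unit <- tree
      unit$edge.length <- rep(1, nrow(tree$edge))
      topo <- node_dists_from(unit, match(best_rep, tree$tip.label))
      d <- topo[tree$edge[best_edges, 2]]
      best_edges <- best_edges[d == min(d)]
    }
    if (length(best_edges) > 1L) {
      lab <- min_tip_labels(tree)[tree$edge[best_edges, 2]]
      best_edges <- best_edges[order(lab)][1L]
    }
  }
  e <- best_edges[1L]
  leaf_rows <- ext$ref[tree$tip.label]
  pd <- vapply(leaf_rows, p_distance, numeric(1), b = ext$query_row)
  pendant <- min(pd)
  out <- parse_newick(newick_attach(tree, tree$edge[e, 2], qid, pendant))
  list(tree = out, score = min(costs), edge_child = tree$edge[e, 2])
}

#' Root a tree on an outgroup leaf and remove it
#'
#' The tree is rerooted on the outgroup's pendant edge, the outgroup leaf is
#' deleted, and the resulting degree-2 node is suppressed with its two
#' incident branch lengths summed.
#'
#' @param tree \code{phylo} containing the outgroup leaf.
#' @param outgroup_id Leaf label of the outgroup.
#' @return Rooted \code{phylo} without the outgroup.
#' @export
root_on_outgroup <- function(tree, outgroup_id) {
  if (!outgroup_id %in% tree$tip.label) {
    stop("outgroup ", outgroup_id, " absent from the tree")
  }
  if (ape::Ntip(tree) == 2L) {
    return(ape::drop.tip(tree, outgroup_id, collapse.singles = TRUE))
  }
  rooted <- ape::root(tree, outgroup = outgroup_id, resolve.root = TRUE,
                      edgelabel = TRUE)
  ape::drop.tip(rooted, outgroup_id, collapse.singles = TRUE)
}

# core newick of a member tree (no trailing ';'); single genes stay bare ids
member_core <- function(tree_or_label) {
  if (is.character(tree_or_label)) return(tree_or_label)
  sub(";$", "", write_newick(tree_or_label))
}

#' Graft a placed subtree back into its full family tree
#'
#' Each subtree-id leaf of the supertree is replaced by that subtree's
#' member tree (the queried subtree uses `placed_subtree`, already rooted and
#' stripped of its outgroup); the contracted supertree edge lengths are kept
#' on the grafted boundary edges.
#'
#' @param placed_subtree Rooted \code{phylo} of the queried subtree's members
#'   plus the query leaf.
#' @param split A `split_family` (see [split_large_tree()]).
#' @param subtree_id Id of the subtree `placed_subtree` corresponds to.
#' @return Full family \code{phylo} including the query.
#' @export
graft <- function(placed_subtree, split, subtree_id) {
  if (!split$is_split) return(placed_subtree)
  if (!subtree_id %in% names(split$subtrees)) {
    stop("unknown subtree id ", subtree_id)
  }
  text <- write_newick(split$supertree)
  for (s in split$subtrees) {
    if (s$id == subtree_id) {
      core <- member_core(placed_subtree)
    } else if (length(s$members) == 1L) {
      core <- s$members
    } else {
      core <- member_core(ape::drop.tip(s$tree, s$outgroup,
                                        collapse.singles = TRUE))
    }
    text <- sub(paste0("(?<=[(,])", s$id, "(?=[:,);])"), core, text,
                perl = TRUE)
  }
  parse_newick(text)
}

#' Search a query against a database and return placed trees with orthologs
#'
#' Composes the full pipeline: profile search with sensitive retry, MSA
#' extension, parsimony placement, outgroup rooting and supertree grafting
#' for split families, and species-overlap orthology labeling. One result is
#' returned per candidate tree, ordered by candidate e-value.
#'
#' @param query Protein sequence.
#' @param db A `shoot_db`.
#' @param cfg A [search_config()].
#' @param query_id Id used for the query leaf (prefixed with `query_` if it
#'   collides with a database gene).
#' @param query_species Species id of the query, when known; defaults to a
#'   private species so the query never overlaps database species.
#' @return A `shoot_result`: list with `status`, `query_id` and `results`
#'   (one placed result per candidate).
#' @export
shoot_search <- function(query, db, cfg = search_config(),
                         query_id = "query", query_species = NA) {
  query <- validate_query(query)
  all_genes <- unlist(lapply(db$families, function(f) names(f$group$seqs)),
                      use.names = FALSE)
  if (query_id %in% all_genes) query_id <- paste0("query_", query_id)
  cands <- search_with_retry(query, db, cfg)
  sensitive <- attr(cands, "sensitive_pass")
  if (nrow(cands) == 0L) {
    return(structure(list(status = "no homologs found", query_id = query_id,
                          results = list()),
                     class = "shoot_result"))
  }
  q_species <- if (is.na(query_species)) "__query__" else query_species
  results <- vector("list", nrow(cands))
  for (i in seq_len(nrow(cands))) {
    fam <- cands$family[i]; sid <- cands$subtree[i]
    f <- db$families[[fam]]
    s <- f$split$subtrees[[sid]]
    ext <- add_to_msa(query, s$msa, query_id)
    placed <- place_in_tree(ext, s$tree, best_rep = cands$rep_id[i])
    if (f$split$is_split) {
      rooted <- root_on_outgroup(placed$tree, s$outgroup)
      full <- graft(rooted, f$split, sid)
    } else {
      full <- placed$tree
    }
    map <- c(db$species_map,
             stats::setNames(q_species, query_id))
    labeled <- label_events(full, map)
    orth <- orthologs_of(labeled, query_id)
    results[[i]] <- structure(
      list(tree = full, query_id = query_id, family = fam, subtree = sid,
           evalue = cands$evalue[i], placement_score = placed$score,
           sensitive_pass = sensitive, orthologs = orth),
      class = "placed_result")
  }
  structure(list(status = "ok", query_id = query_id, results = results),
            class = "shoot_result")
}

#' @export
print.placed_result <- function(x, ...) {
  cat("Placement of", x$query_id, "in family", x$family,
      sprintf("(subtree %s, e-value %.3g, parsimony score %d)\n",
              x$subtree, x$evalue, as.integer(x$placement_score)))
  n_orth <- sum(x$orthologs$relation == "ortholog")
  cat("  tree:", ape::Ntip(x$tree), "leaves |", n_orth, "orthologs,",
      nrow(x$orthologs) - n_orth, "paralogs\n")
  invisible(x)
}

#' @export
print.shoot_result <- function(x, ...) {
  cat("phyloshoot search for", x$query_id, "-", x$status, "\n")
  for (r in x$results) print(r)
  invisible(x)
}
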