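# Small tree helpers shared across modules. All trees are ape "phylo"
# objects; node numbering follows ape (tips 1..n, root n+1).

with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# children[[node]] = integer vector of child node ids (empty for tips)
tree_children <- function(tree) {
  n_all <- ape::Ntip(tree) + tree$Nnode
  ch <- rep(list(integer(0)), n_all)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1]
    ch[[p]] <- c(ch[[p]], tree$edge[i, 2])
  }
  ch
}

tree_root <- function(tree) ape::Ntip(tree) + 1L

# postorder node sequence (children before parents)
postorder_nodes <- function(tree) {
  edges <- ape::reorder.phylo(tree, "postorder")$edge
  c(edges[, 2][!duplicated(edges[, 2])], tree_root(tree))
}

# tips (labels) descending from each node; list indexed by node id
clade_tip_sets <- function(tree) {
  n_tip <- ape::Ntip(tree)
  n_all <- n_tip + tree$Nnode
  sets <- vector("list", n_all)
  for (i in seq_len(n_tip)) sets[[i]] <- tree$tip.label[i]
  ch <- tree_children(tree)
  for (node in postorder_nodes(tree)) {
    if (node > n_tip) {
      sets[[node]] <- unlist(sets[ch[[node]]], use.names = FALSE)
    }
  }
  sets
}

# branch-length distance from `node` to every node (single-source, tree walk)
node_dists_from <- function(tree, node) {
  n_all <- ape::Ntip(tree) + tree$Nnode
  len <- if (is.null(tree$edge.length)) rep(0, nrow(tree$edge)) else tree$edge.length
  ends <- c(tree$edge[, 2], tree$edge[, 1])
  starts <- c(tree$edge[, 1], tree$edge[, 2])
  lens <- c(len, len)
  ord <- order(starts)
  ends <- ends[ord]; lens <- lens[ord]
  first <- match(seq_len(n_all), starts[ord])
  degree <- tabulate(starts, nbins = n_all)
  dist <- rep(NA_real_, n_all)
  dist[node] <- 0
  queue <- integer(n_all)
  queue[1L] <- node
  head_i <- 1L; tail_i <- 1L
  while (head_i <= tail_i) {
    cur <- queue[head_i]; head_i <- head_i + 1L
    if (degree[cur] == 0L) next
    idx <- first[cur]:(first[cur] + degree[cur] - 1L)
    for (j in idx) {
      v <- ends[j]
      if (is.na(dist[v])) {
        dist[v] <- dist[cur] + lens[j]
        tail_i <- tail_i + 1L
        queue[tail_i] <- v
      }
    }
  }
  dist
}

# MRCA of a set of tip labels
mrca_of_tips <- function(tree, tips) {
  idx <- match(tips, tree$tip.label)
  if (anyNA(idx)) stop("unknown tip label")
  if (length(idx) == 1L) return(idx)
  ape::getMRCA(tree, idx)
}

# named character msa -> character matrix (rows = ids)
msa_matrix <- function(msa) {
  mat <- do.call(rbind, strsplit(unname(unclass(msa)), ""))
  rownames(mat) <- names(msa)
  mat
}

matrix_msa <- function(mat) {
  stats::setNames(apply(mat, 1, paste, collapse = ""), rownames(mat))
}
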