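# Synthetic gene families with known evolutionary history: a Yule species
# tree, duplication-loss gene trees, Poisson/JC-like 20-state sequences with
# no indels (so the true MSA is the raw sequences), and ground-truth
# ortholog/cherry tables for the evaluation harness.

#' Simulation parameters
#'
#' @param seed Master seed; all randomness flows from it.
#' @param n_species Number of species (>= 3).
#' @param tree_height Expected root-to-tip path length of the species tree,
#'   in substitutions per site.
#' @param dup_rate,loss_rate Per-lineage duplication/loss rates, events per
#'   unit branch length.
#' @param n_families Number of gene families to simulate.
#' @param seq_len Alignment length in columns (>= 50).
#' @param rate_range Range of the uniform per-family rate multiplier applied
#'   to gene-tree branch lengths before sequence simulation.
#' @param support One of `"fixed100"` (all internal supports 100, the
#'   noiseless regime) or `"uniform"` (supports drawn uniformly on 50..100).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 17L, n_species = 12L, tree_height = 0.5,
                       dup_rate = 0.3, loss_rate = 0, n_families = 50L,
                       seq_len = 300L, rate_range = c(1, 1),
                       support = c("fixed100", "uniform")) {
  stopifnot(n_species >= 3L, seq_len >= 50L, dup_rate >= 0, loss_rate >= 0,
            tree_height > 0)
  structure(list(seed = as.integer(seed), n_species = as.integer(n_species),
                 tree_height = tree_height, dup_rate = dup_rate,
                 loss_rate = loss_rate, n_families = as.integer(n_families),
                 seq_len = as.integer(seq_len), rate_range = rate_range,
                 support = match.arg(support)),
            class = "sim_config")
}

sim_species_tree_impl <- function(cfg) {
  tr <- ape::rphylo(cfg$n_species, birth = 1, death = 0)
  tr$tip.label <- paste0("sp", seq_len(cfg$n_species))
  tr$node.label <- NULL
  depths <- node_dists_from(tr, tree_root(tr))[seq_len(cfg$n_species)]
  tr$edge.length <- tr$edge.length * cfg$tree_height / mean(depths)
  tr
}

#' Simulate a species tree
#'
#' Yule (pure-birth) tree on `n_species` tips, branch lengths rescaled so
#' the mean root-to-tip path equals `tree_height`. Deterministic under
#' `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return A rooted \code{phylo}.
#' @export
sim_species_tree <- function(cfg) {
  with_seed(cfg$seed, sim_species_tree_impl(cfg))
}

# one gene lineage evolving toward species-tree node `sp_node` with `rem`
# branch length remaining; returns a nested-list gene subtree or NULL (lost)
evolve_lineage <- function(sp, ch, blen, tips, sp_node, rem, dup, loss) {
  total <- dup + loss
  wait <- if (total > 0) stats::rexp(1, total) else Inf
  if (wait < rem) {
    if (stats::runif(1) < dup / total) {
      left <- evolve_lineage(sp, ch, blen, tips, sp_node, rem - wait, dup, loss)
      right <- evolve_lineage(sp, ch, blen, tips, sp_node, rem - wait, dup, loss)
      kids <- Filter(Negate(is.null), list(left, right))
      if (length(kids) == 0L) return(NULL)
      if (length(kids) == 1L) {
        kids[[1L]]$len <- kids[[1L]]$len + wait
        return(kids[[1L]])
      }
      return(list(event = "D", children = kids, len = wait))
    }
    return(NULL)  # loss
  }
  node <- gene_at_species_node(sp, ch, blen, tips, sp_node, dup, loss)
  if (is.null(node)) return(NULL)
  node$len <- node$len + rem
  node
}

gene_at_species_node <- function(sp, ch, blen, tips, sp_node, dup, loss) {
  if (sp_node <= tips) {
    return(list(species = sp$tip.label[sp_node], len = 0))
  }
  kids <- list()
  for (c_node in ch[[sp_node]]) {
    sub <- evolve_lineage(sp, ch, blen, tips, c_node, blen[c_node], dup, loss)
    if (!is.null(sub)) kids <- c(kids, list(sub))
  }
  if (length(kids) == 0L) return(NULL)
  if (length(kids) == 1L) return(kids[[1L]])
  list(event = "S", children = kids, len = 0)
}

gene_tree_newick <- function(node) {
  if (!is.null(node$species)) {
    return(paste0(node$name, ":", format(node$len, digits = 12,
                                         scientific = FALSE)))
  }
  paste0("(", paste(vapply(node$children, gene_tree_newick, character(1)),
                    collapse = ","),
         ")", node$event, ":",
         format(node$len, digits = 12, scientific = FALSE))
}

name_gene_leaves <- function(node, prefix, counter_env) {
  if (!is.null(node$species)) {
    sp <- node$species
    counter_env$counts[[sp]] <- (counter_env$counts[[sp]] %||% 0L) + 1L
    node$name <- paste0(prefix, sp, "_", counter_env$counts[[sp]])
    return(node)
  }
  node$children <- lapply(node$children, name_gene_leaves, prefix = prefix,
                          counter_env = counter_env)
  node
}

`%||%` <- function(a, b) if (is.null(a)) b else a

sim_gene_tree_impl <- function(species_tree, dup, loss, prefix = "") {
  ch <- tree_children(species_tree)
  blen <- rep(NA_real_, ape::Ntip(species_tree) + species_tree$Nnode)
  blen[species_tree$edge[, 2]] <- species_tree$edge.length
  tips <- ape::Ntip(species_tree)
  for (attempt in seq_len(1000L)) {
    root <- gene_at_species_node(species_tree, ch, blen, tips,
                                 tree_root(species_tree), dup, loss)
    if (is.null(root) || !is.null(root$species)) next
    env <- new.env(); env$counts <- list()
    root <- name_gene_leaves(root, prefix, env)
    nwk <- paste0(gene_tree_newick(root), ";")
    # strip root branch length for a clean rooted tree
    tree <- parse_newick(sub(":[0-9.eE+-]+;$", ";", nwk))
    if (ape::Ntip(tree) < 2L) next
    flags <- tree$node.label == "D"
    tree$node.label <- NULL
    species_map <- stats::setNames(
      sub("_[0-9]+$", "", sub(paste0("^", prefix), "", tree$tip.label)),
      tree$tip.label)
    return(list(tree = tree, duplication = flags, species_map = species_map))
  }
  stop("gene family simulation failed to produce >= 2 surviving genes")
}

#' Simulate a duplication-loss gene tree along a species tree
#'
#' Gene lineages walk root-to-tip down the species tree; along each species
#' branch a lineage duplicates at rate `dup_rate` and is lost at rate
#' `loss_rate`. Surviving lineages at species tips become genes named
#' `<species>_<index>`. Families with fewer than 2 surviving genes are
#' rejected and resampled.
#'
#' @param species_tree Rooted \code{phylo}.
#' @param dup_rate,loss_rate Event rates per unit branch length.
#' @param seed Integer seed.
#' @param prefix Optional prefix for gene names (database-wide uniqueness).
#' @return List with `tree` (\code{phylo}), `duplication` (logical per
#'   internal node) and `species_map`.
#' @export
sim_gene_tree <- function(species_tree, dup_rate, loss_rate, seed,
                          prefix = "") {
  with_seed(seed, sim_gene_tree_impl(species_tree, dup_rate, loss_rate,
                                     prefix))
}

sim_sequences_impl <- function(gene_tree, cfg) {
  L <- cfg$seq_len
  n_tip <- ape::Ntip(gene_tree)
  n_all <- n_tip + gene_tree$Nnode
  seqs <- vector("list", n_all)
  root <- tree_root(gene_tree)
  seqs[[root]] <- sample.int(20L, L, replace = TRUE)
  edges <- ape::reorder.phylo(gene_tree, "cladewise")$edge
  lens <- ape::reorder.phylo(gene_tree, "cladewise")$edge.length
  for (i in seq_len(nrow(edges))) {
    parent_seq <- seqs[[edges[i, 1]]]
    b <- lens[i]
    hit <- stats::runif(L) < (1 - exp(-b))
    child <- parent_seq
    if (any(hit)) {
      # jump to a uniformly random different residue
      shift <- sample.int(19L, sum(hit), replace = TRUE)
      child[hit] <- ((child[hit] - 1L + shift) %% 20L) + 1L
    }
    seqs[[edges[i, 2]]] <- child
  }
  out <- vapply(seq_len(n_tip), function(i) {
    paste(AA_RESIDUES[seqs[[i]]], collapse = "")
  }, character(1))
  names(out) <- gene_tree$tip.label
  tree <- gene_tree
  tree$node.label <- if (cfg$support == "fixed100") {
    rep("100", tree$Nnode)
  } else {
    as.character(sample(50:100, tree$Nnode, replace = TRUE))
  }
  if (tree$Nnode >= 1L) tree$node.label[1L] <- ""  # root carries no support
  list(seqs = out, msa = out, tree = tree)
}

#' Simulate protein sequences along a gene tree
#'
#' The root sequence is uniform over the 20 residues; along each branch of
#' length b every site substitutes with probability `1 - exp(-b)` to a
#' uniformly random different residue. There are no indels, so the true
#' alignment equals the raw sequences. Internal-node supports are assigned
#' per `cfg$support`.
#'
#' @param gene_tree Rooted \code{phylo} with branch lengths.
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @return List with `seqs`, `msa` (identical) and `tree` (supports set).
#' @export
sim_sequences <- function(gene_tree, cfg, seed = cfg$seed) {
  with_seed(seed, sim_sequences_impl(gene_tree, cfg))
}

true_ortholog_pairs <- function(tree, duplication) {
  n_tip <- ape::Ntip(tree)
  if (n_tip < 2L) {
    return(data.frame(gene1 = character(0), gene2 = character(0)))
  }
  m <- ape::mrca(tree)
  pairs <- which(upper.tri(m), arr.ind = TRUE)
  lca <- m[pairs]
  speciation <- !duplication[lca - n_tip]
  data.frame(
    gene1 = pmin(tree$tip.label[pairs[, 1]], tree$tip.label[pairs[, 2]]),
    gene2 = pmax(tree$tip.label[pairs[, 1]], tree$tip.label[pairs[, 2]]),
    stringsAsFactors = FALSE)[speciation, , drop = FALSE]
}

#' Generate a complete build fixture with ground truth
#'
#' Writes per-family `<fam>.fa`, `<fam>.aln.fa` and `<fam>.nwk` plus
#' `species_map.tsv` in the builder's input layout, and a `truth/` directory
#' holding per-family event-labeled trees (internal labels `D`/`S`) and the
#' true ortholog pair table. Everything is re-readable by the I/O layer and
#' byte-reproducible under `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory.
#' @param force Overwrite a non-empty `dir`.
#' @return Invisibly, a list with the species tree, per-family truth and
#'   `dir`.
#' @export
make_fixture <- function(cfg, dir, force = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) > 0L && !force) {
    stop("output directory ", dir, " exists and is not empty (use force)")
  }
  dir.create(file.path(dir, "truth"), recursive = TRUE, showWarnings = FALSE)
  truth <- with_seed(cfg$seed, {
    sp_tree <- sim_species_tree_impl(cfg)
    fams <- list()
    species_map <- character(0)
    orth_rows <- list()
    for (i in seq_len(cfg$n_families)) {
      fam <- sprintf("fam%03d", i)
      g <- sim_gene_tree_impl(sp_tree, cfg$dup_rate, cfg$loss_rate,
                              prefix = paste0(fam, "_"))
      mult <- stats::runif(1, cfg$rate_range[1], cfg$rate_range[2])
      g$tree$edge.length <- g$tree$edge.length * mult
      sq <- sim_sequences_impl(g$tree, cfg)
      write_fasta(sq$seqs, file.path(dir, paste0(fam, ".fa")))
      write_fasta(sq$msa, file.path(dir, paste0(fam, ".aln.fa")))
      writeLines(write_newick(sq$tree), file.path(dir, paste0(fam, ".nwk")))
      events_tree <- g$tree
      events_tree$node.label <- ifelse(g$duplication, "D", "S")
      writeLines(write_newick(events_tree),
                 file.path(dir, "truth", paste0(fam, ".events.nwk")))
      orth <- true_ortholog_pairs(g$tree, g$duplication)
      if (nrow(orth)) {
        orth_rows[[fam]] <- cbind(family = fam, orth)
      }
      species_map <- c(species_map, g$species_map)
      fams[[fam]] <- list(tree = sq$tree, duplication = g$duplication,
                          species_map = g$species_map,
                          ortholog_pairs = orth, seqs = sq$seqs)
    }
    write_species_map(species_map, file.path(dir, "species_map.tsv"))
    orth_tab <- if (length(orth_rows)) do.call(rbind, orth_rows) else
      data.frame(family = character(0), gene1 = character(0),
                 gene2 = character(0))
    utils::write.table(orth_tab, file.path(dir, "truth", "orthologs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(write_newick(sp_tree),
               file.path(dir, "truth", "species_tree.nwk"))
    list(species_tree = sp_tree, families = fams, dir = dir)
  })
  invisible(truth)
}

#' Read a fixture/groups directory into homolog groups
#'
#' Expects per-family `<fam>.fa`, `<fam>.aln.fa`, `<fam>.nwk` files as
#' written by [make_fixture()].
#'
#' @param dir Directory of per-family input files.
#' @return Named list of [homolog_group()] objects.
#' @export
read_groups_dir <- function(dir) {
  fams <- sort(sub("\\.nwk$", "", basename(
    list.files(dir, pattern = "\\.nwk$"))))
  if (length(fams) == 0L) stop("no <family>.nwk files in ", dir)
  groups <- lapply(fams, function(fam) {
    homolog_group(fam,
                  seqs = read_fasta(file.path(dir, paste0(fam, ".fa"))),
                  msa = read_fasta(file.path(dir, paste0(fam, ".aln.fa"))),
                  tree = parse_newick(readLines(
                    file.path(dir, paste0(fam, ".nwk")))))
  })
  stats::setNames(groups, fams)
}

#' Read the ground-truth tables written by [make_fixture()]
#'
#' @param dir Fixture directory.
#' @return List with `species_tree`, per-family `events` trees (with
#'   duplication flags) and the `ortholog_pairs` table.
#' @export
read_fixture_truth <- function(dir) {
  tdir <- file.path(dir, "truth")
  if (!dir.exists(tdir)) stop("no truth/ directory under ", dir)
  fams <- sort(sub("\\.events\\.nwk$", "", basename(
    list.files(tdir, pattern = "\\.events\\.nwk$"))))
  events <- lapply(fams, function(fam) {
    tree <- parse_newick(readLines(file.path(tdir,
                                             paste0(fam, ".events.nwk"))))
    flags <- tree$node.label == "D"
    tree$node.label <- NULL
    list(tree = tree, duplication = flags)
  })
  names(events) <- fams
  orth <- utils::read.delim(file.path(tdir, "orthologs.tsv"),
                            colClasses = "character")
  list(species_tree = parse_newick(readLines(
         file.path(tdir, "species_tree.nwk"))),
       events = events, ortholog_pairs = orth)
}
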