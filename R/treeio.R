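# File formats and on-disk database layout: FASTA (sequences, MSAs), Newick
# (gene trees, subtrees, supertrees), TSV (species map, profile table), JSON
# (manifest, build parameters).

AA_RESIDUES <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

#' Read a protein FASTA file
#'
#' Sequence ids are the first whitespace-delimited token of each header; the
#' remainder of the header is retained in the `"descriptions"` attribute.
#' Sequences are uppercased. Record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences, in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  headers <- names(set)
  ids <- vapply(strsplit(headers, "[ \t]+"), `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate id ", ids[duplicated(ids)][1L], " in ", path)
  }
  desc <- sub("^[^ \t]+[ \t]*", "", headers)
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  names(desc) <- ids
  attr(seqs, "descriptions") <- desc
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector (ids to sequences; may contain gaps).
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::AAStringSet(unname(unclass(seqs)))
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, filepath = path, width = 80L)
  invisible(path)
}

#' Parse a Newick tree string
#'
#' Supports are read from bare internal-node labels (IQ-TREE style, integers
#' 0-100). Missing branch lengths default to 0. The returned tree is an ape
#' \code{phylo} object.
#'
#' @param text A Newick string (single tree, terminated by `;`).
#' @return A \code{phylo} object.
#' @export
parse_newick <- function(text) {
  text <- trimws(text)
  # ape can silently mis-parse malformed strings; validate bracket balance
  # and termination first so errors carry a character offset.
  chars <- strsplit(text, "")[[1]]
  depth <- cumsum((chars == "(") - (chars == ")"))
  if (any(depth < 0L)) {
    stop("newick parse error: unmatched ')' at offset ", which(depth < 0L)[1L])
  }
  semis <- which(chars == ";")
  if (length(semis) && semis[1L] < length(chars)) {
    stop("newick parse error: trailing garbage after ';' at offset ",
         semis[1L] + 1L)
  }
  if (length(depth) && depth[length(depth)] != 0L) {
    stop("newick parse error: ", depth[length(depth)],
         " unclosed '(' at offset ", length(chars))
  }
  if (!endsWith(text, ";")) {
    stop("newick parse error: missing terminal ';' at offset ", nchar(text))
  }
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) stop("newick parse error: ", conditionMessage(e)))
  if (is.null(tree)) stop("newick parse error: unreadable tree")
  if (is.null(tree$edge.length)) {
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  tree$edge.length[is.na(tree$edge.length)] <- 0
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate leaf label ", tree$tip.label[duplicated(tree$tip.label)][1L])
  }
  if (any(tree$edge.length < 0)) stop("negative branch length in tree")
  tree
}

#' Write a tree as a Newick string
#'
#' Inverse of [parse_newick()]: topology, labels, branch lengths and supports
#' (node labels) round-trip losslessly.
#'
#' @param tree A \code{phylo} object.
#' @return A Newick string.
#' @export
write_newick <- function(tree) {
  ape::write.tree(tree, digits = 12)
}

#' Integer supports from a tree's internal-node labels
#'
#' @param tree A \code{phylo} object.
#' @return Integer vector of length `tree$Nnode` (NA where absent/non-numeric).
#' @export
tree_supports <- function(tree) {
  if (is.null(tree$node.label)) return(rep(NA_integer_, tree$Nnode))
  suppressWarnings(as.integer(tree$node.label))
}

validate_msa <- function(msa, what = "MSA") {
  if (length(msa) == 0L) stop(what, " is empty")
  lens <- nchar(msa)
  if (length(unique(lens)) != 1L) {
    stop(what, " rows have unequal lengths (", min(lens), "-", max(lens), ")")
  }
  if (anyDuplicated(names(msa))) {
    stop("duplicate id ", names(msa)[duplicated(names(msa))][1L], " in ", what)
  }
  bad <- grepl(paste0("[^", paste(AA_RESIDUES, collapse = ""), "X-]"), msa)
  if (any(bad)) {
    stop(what, " row ", names(msa)[bad][1L],
         " contains characters outside the amino-acid alphabet, 'X' and '-'")
  }
  invisible(msa)
}

validate_gene_tree <- function(tree, what = "gene tree") {
  if (!inherits(tree, "phylo")) stop(what, " is not a phylo object")
  if (!ape::is.rooted(tree)) stop(what, " must be rooted")
  if (anyDuplicated(tree$tip.label)) stop(what, " has duplicate leaf labels")
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0)) {
    stop(what, " has negative branch lengths")
  }
  invisible(tree)
}

#' Read a gene-to-species map (TSV: gene_id <TAB> species_id)
#'
#' @param path Path to a two-column TSV with no header.
#' @return Named character vector mapping gene id to species id.
#' @export
read_species_map <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, colClasses = "character",
                           col.names = c("gene_id", "species_id"))
  if (any(!nzchar(tab$species_id))) stop("empty species id in ", path)
  if (anyDuplicated(tab$gene_id)) {
    stop("duplicate gene id ", tab$gene_id[duplicated(tab$gene_id)][1L])
  }
  stats::setNames(tab$species_id, tab$gene_id)
}

write_species_map <- function(map, path) {
  utils::write.table(data.frame(names(map), unname(map)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

MANIFEST_FORMAT <- "phyloshoot-db"

db_paths <- function(root, fam = NULL) {
  p <- list(
    manifest = file.path(root, "manifest.json"),
    params = file.path(root, "params.json"),
    species_map = file.path(root, "species_map.tsv"),
    profiles = file.path(root, "profiles.tsv"),
    families = file.path(root, "families")
  )
  if (!is.null(fam)) {
    fd <- file.path(root, "families", fam)
    p$fam_dir <- fd
    p$seqs <- file.path(fd, "seqs.fa")
    p$msa <- file.path(fd, "msa.fa")
    p$tree <- file.path(fd, "tree.nwk")
    p$split <- file.path(fd, "split.json")
    p$subtrees <- file.path(fd, "subtrees")
    p$supertree <- file.path(fd, "supertree.nwk")
  }
  p
}

#' Save a built database to disk
#'
#' Writes the directory layout: a JSON manifest and build-parameter record,
#' the species map and profile table as TSV, and per-family FASTA/Newick
#' files (plus subtree alignments/trees and a supertree for split families).
#'
#' @param db A `shoot_db` object (see [build_database()]).
#' @param path Output directory (created; must not already hold a database).
#' @return `path`, invisibly.
#' @export
save_database <- function(db, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  p <- db_paths(path)
  jsonlite::write_json(
    list(format = MANIFEST_FORMAT, version = 1L,
         families = names(db$families)),
    p$manifest, auto_unbox = TRUE, pretty = TRUE)
  jsonlite::write_json(db$params, p$params, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  write_species_map(db$species_map, p$species_map)
  utils::write.table(db$profiles, p$profiles, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  for (fam in names(db$families)) {
    f <- db$families[[fam]]
    fp <- db_paths(path, fam)
    dir.create(fp$fam_dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(f$group$seqs, fp$seqs)
    write_fasta(f$group$msa, fp$msa)
    writeLines(write_newick(f$group$tree), fp$tree)
    split_info <- list(
      is_split = f$split$is_split,
      subtrees = lapply(f$split$subtrees, function(s) {
        list(id = s$id,
             outgroup = if (is.na(s$outgroup)) NULL else s$outgroup,
             members = s$members)
      }))
    jsonlite::write_json(split_info, fp$split, auto_unbox = TRUE, pretty = TRUE)
    if (f$split$is_split) {
      dir.create(fp$subtrees, showWarnings = FALSE)
      for (s in f$split$subtrees) {
        writeLines(write_newick(s$tree),
                   file.path(fp$subtrees, paste0(s$id, ".nwk")))
        write_fasta(s$msa, file.path(fp$subtrees, paste0(s$id, ".aln.fa")))
      }
      writeLines(write_newick(f$split$supertree), fp$supertree)
    }
  }
  invisible(path)
}

#' Load a database from disk
#'
#' @param path Database directory written by [save_database()] /
#'   [build_database()].
#' @return A `shoot_db` object.
#' @export
load_database <- function(path) {
  p <- db_paths(path)
  if (!file.exists(p$manifest)) stop("not a phyloshoot database: ", path)
  manifest <- jsonlite::read_json(p$manifest, simplifyVector = TRUE)
  if (!identical(manifest$format, MANIFEST_FORMAT)) {
    stop("not a phyloshoot database: ", path)
  }
  params <- jsonlite::read_json(p$params, simplifyVector = TRUE)
  species_map <- read_species_map(p$species_map)
  profiles <- utils::read.delim(p$profiles, header = FALSE,
                                colClasses = "character",
                                col.names = c("rep_id", "family", "subtree"))
  fams <- list()
  for (fam in manifest$families) {
    fp <- db_paths(path, fam)
    if (!dir.exists(fp$fam_dir)) stop("family directory missing: ", fam)
    group <- homolog_group(fam,
                           seqs = read_fasta(fp$seqs),
                           msa = read_fasta(fp$msa),
                           tree = parse_newick(readLines(fp$tree)))
    split_info <- jsonlite::read_json(fp$split, simplifyVector = FALSE)
    if (isTRUE(split_info$is_split)) {
      subtrees <- lapply(split_info$subtrees, function(s) {
        list(id = s$id,
             members = as.character(unlist(s$members)),
             outgroup = if (is.null(s$outgroup)) NA_character_ else s$outgroup,
             tree = parse_newick(readLines(
               file.path(fp$subtrees, paste0(s$id, ".nwk")))),
             msa = read_fasta(file.path(fp$subtrees, paste0(s$id, ".aln.fa"))))
      })
      names(subtrees) <- vapply(subtrees, `[[`, character(1), "id")
      split <- list(family = fam, is_split = TRUE, subtrees = subtrees,
                    supertree = parse_newick(readLines(fp$supertree)))
    } else {
      split <- unsplit_family(group)
    }
    class(split) <- "split_family"
    fams[[fam]] <- list(group = group, split = split)
  }
  new_shoot_db(fams, species_map, profiles, params, path)
}

#' Construct a homolog group
#'
#' A homolog group bundles one gene family: its protein sequences, MSA and
#' rooted gene tree over the same gene ids.
#'
#' @param id Family id.
#' @param seqs,msa Named character vectors over the same ids.
#' @param tree Rooted \code{phylo} with the same ids as tip labels.
#' @return A `homolog_group` object.
#' @export
homolog_group <- function(id, seqs, msa, tree) {
  validate_msa(msa, paste0("MSA of ", id))
  validate_gene_tree(tree, paste0("tree of ", id))
  if (!setequal(names(seqs), names(msa)) ||
      !setequal(names(seqs), tree$tip.label)) {
    stop("family ", id, ": sequence ids, MSA rows and tree leaves disagree")
  }
  if (length(seqs) < 2L) stop("family ", id, " has fewer than 2 genes")
  structure(list(id = id, seqs = seqs, msa = msa, tree = tree,
                 n = length(seqs)),
            class = "homolog_group")
}

#' @export
print.homolog_group <- function(x, ...) {
  cat("Homolog group", x$id, "with", x$n, "genes,",
      nchar(x$msa[[1]]), "alignment columns\n")
  invisible(x)
}

new_shoot_db <- function(families, species_map, profiles, params,
                         path = NULL) {
  structure(list(families = families, species_map = species_map,
                 profiles = profiles, params = params, path = path),
            class = "shoot_db")
}

#' @export
print.shoot_db <- function(x, ...) {
  n_genes <- sum(vapply(x$families, function(f) f$group$n, numeric(1)))
  n_split <- sum(vapply(x$families, function(f) f$split$is_split, logical(1)))
  cat("phyloshoot database:", length(x$families), "families,",
      n_genes, "genes,", nrow(x$profiles), "profile representatives\n")
  cat("  split families:", n_split, "| species:",
      length(unique(x$species_map)), "\n")
  if (!is.null(x$path)) cat("  path:", x$path, "\n")
  invisible(x)
}
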