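# Assigning a query protein to candidate (sub)trees: local alignment against
# the representative-sequence profiles, BLAST-like e-values, and the
# ambiguity-ratio rule for considering secondary trees.

# gapped BLOSUM62 Karlin-Altschul constants (gap open 11, extend 1)
KA_LAMBDA <- 0.267
KA_K <- 0.041

blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Search configuration
#'
#' @param evalue_cutoff Hits with a larger e-value are discarded.
#' @param ambiguity_ratio A secondary tree is also considered when its best
#'   hit's e-value is below `ambiguity_ratio` times the overall best e-value.
#' @param sensitive_retry Rerun with the heuristic prefilter disabled when
#'   the first pass finds nothing.
#' @param max_candidates Cap on the number of candidate trees returned.
#' @param engine Search engine; only the dependency-free `"builtin"`
#'   Smith-Waterman engine ships with the package.
#' @return A `search_config` list.
#' @export
search_config <- function(evalue_cutoff = 1e-3, ambiguity_ratio = 1e10,
                          sensitive_retry = TRUE, max_candidates = 5L,
                          engine = "builtin") {
  stopifnot(evalue_cutoff > 0, ambiguity_ratio >= 1)
  if (!identical(engine, "builtin")) {
    stop("engine '", engine, "' is not available: this build ships only ",
         "the builtin Smith-Waterman engine; install the external tool ",
         "and drive it through its own tabular output if you need it")
  }
  structure(list(evalue_cutoff = evalue_cutoff,
                 ambiguity_ratio = ambiguity_ratio,
                 sensitive_retry = isTRUE(sensitive_retry),
                 max_candidates = as.integer(max_candidates),
                 engine = engine),
            class = "search_config")
}

validate_query <- function(query) {
  if (!nzchar(query)) stop("empty query sequence")
  query <- toupper(query)
  if (grepl(paste0("[^", paste(AA_RESIDUES, collapse = ""), "X]"), query)) {
    stop("query contains characters outside the amino-acid alphabet and 'X'")
  }
  if (nchar(query) < 10L) stop("query shorter than 10 residues")
  query
}

kmer_set <- function(seq, k = 4L) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, seq_len(n - k + 1L), k:n))
}

#' Smith-Waterman search of a query against representative sequences
#'
#' Local alignment (BLOSUM62, gap open 11, extend 1) of the query against
#' each representative. Raw scores S are converted to bit scores
#' `S' = (lambda*S - ln K)/ln 2` with the gapped Karlin-Altschul constants
#' (lambda = 0.267, K = 0.041) and to e-values `E = m*n*2^-S'` where m is the
#' query length and n the total residue count of the representative set.
#' At default sensitivity a representative is only aligned when it shares at
#' least one exact 4-mer with the query; `sensitive = TRUE` disables this
#' prefilter and aligns everything.
#'
#' @param query Protein sequence (string, >= 10 residues).
#' @param representatives Named character vector of representative sequences.
#' @param rep_index Optional data frame (`rep_id`, `family`, `subtree`)
#'   resolving each representative; defaults to one pseudo-family.
#' @param sensitive Disable the 4-mer prefilter.
#' @return Data frame of hits (`rep_id`, `family`, `subtree`, `evalue`,
#'   `bitscore`, `score`) sorted by ascending e-value, then descending bit
#'   score, then id.
#' @export
builtin_search <- function(query, representatives, rep_index = NULL,
                           sensitive = FALSE) {
  query <- validate_query(query)
  if (length(representatives) == 0L) stop("empty representative set")
  if (is.null(rep_index)) {
    rep_index <- data.frame(rep_id = names(representatives), family = "db",
                            subtree = "db_s1", stringsAsFactors = FALSE)
  }
  n_total <- sum(nchar(representatives))
  m <- nchar(query)
  cand <- names(representatives)
  if (!sensitive) {
    qk <- kmer_set(query)
    keep <- vapply(representatives, function(s) {
      any(kmer_set(s) %in% qk)
    }, logical(1))
    cand <- cand[keep]
  }
  if (length(cand) == 0L) {
    return(data.frame(rep_id = character(0), family = character(0),
                      subtree = character(0), evalue = numeric(0),
                      bitscore = numeric(0), score = numeric(0)))
  }
  subj <- Biostrings::AAStringSet(gsub("-", "", representatives[cand]))
  scores <- Biostrings::pairwiseAlignment(
    subj, Biostrings::AAString(query), type = "local",
    substitutionMatrix = blosum62(), gapOpening = 11, gapExtension = 1,
    scoreOnly = TRUE)
  bits <- (KA_LAMBDA * scores - log(KA_K)) / log(2)
  evalue <- m * n_total * 2^(-bits)
  idx <- match(cand, rep_index$rep_id)
  hits <- data.frame(rep_id = cand,
                     family = rep_index$family[idx],
                     subtree = rep_index$subtree[idx],
                     evalue = evalue, bitscore = bits, score = scores,
                     stringsAsFactors = FALSE)
  hits[order(hits$evalue, -hits$bitscore, hits$rep_id), , drop = FALSE]
}

#' Candidate (sub)trees from a hit list
#'
#' Hits above the e-value cutoff are dropped. The best remaining hit fixes
#' the primary (family, subtree); the best hit of every other (family,
#' subtree) whose e-value is below `best_e * ambiguity_ratio` is also kept.
#' Candidates are ordered by their best e-value and capped at
#' `cfg$max_candidates`.
#'
#' @param hits Data frame as returned by [builtin_search()].
#' @param cfg A [search_config()].
#' @return Data frame (`family`, `subtree`, `evalue`, `rep_id`), possibly
#'   empty ("no assignment").
#' @export
assign_trees <- function(hits, cfg = search_config()) {
  empty <- data.frame(family = character(0), subtree = character(0),
                      evalue = numeric(0), rep_id = character(0))
  if (nrow(hits) == 0L) return(empty)
  hits <- hits[hits$evalue <= cfg$evalue_cutoff, , drop = FALSE]
  if (nrow(hits) == 0L) return(empty)
  key <- paste(hits$family, hits$subtree, sep = "\r")
  best <- hits[!duplicated(key), , drop = FALSE]  # hits sorted: first is best
  best_e <- best$evalue[1L]
  thr <- if (best_e == 0) .Machine$double.xmin * cfg$ambiguity_ratio
         else best_e * cfg$ambiguity_ratio
  keep <- best$evalue < thr | seq_len(nrow(best)) == 1L
  best <- best[keep, , drop = FALSE]
  best <- utils::head(best, cfg$max_candidates)
  data.frame(family = best$family, subtree = best$subtree,
             evalue = best$evalue, rep_id = best$rep_id,
             stringsAsFactors = FALSE)
}

db_representatives <- function(db) {
  reps <- character(0)
  for (f in db$families) reps <- c(reps, f$group$seqs)
  prof <- db$profiles
  stats::setNames(reps[prof$rep_id], prof$rep_id)
}

#' Search with a sensitive retry pass
#'
#' Runs [builtin_search()] at default sensitivity; when no candidate tree
#' survives [assign_trees()] and `cfg$sensitive_retry` is set, the search is
#' rerun with the prefilter disabled (every representative fully aligned).
#'
#' @param query Protein sequence.
#' @param db A `shoot_db`.
#' @param cfg A [search_config()].
#' @return Candidate data frame as from [assign_trees()], with attribute
#'   `sensitive_pass` flagging whether the retry pass produced it.
#' @export
search_with_retry <- function(query, db, cfg = search_config()) {
  reps <- db_representatives(db)
  hits <- builtin_search(query, reps, db$profiles, sensitive = FALSE)
  cands <- assign_trees(hits, cfg)
  sensitive <- FALSE
  if (nrow(cands) == 0L && cfg$sensitive_retry) {
    hits <- builtin_search(query, reps, db$profiles, sensitive = TRUE)
    cands <- assign_trees(hits, cfg)
    sensitive <- nrow(cands) > 0L
  }
  attr(cands, "sensitive_pass") <- sensitive
  cands
}
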