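# Lightweight phylogenetics: p-distances, NJ trees, Newick I/O, monophyly.

#' Pairwise p-distance matrix from an alignment
#'
#' Proportion of differing sites per sequence pair; sites with a gap or
#' ambiguous base in either sequence of a pair are excluded for that pair.
#'
#' @param msa Equal-length aligned sequences (named character,
#'   `DNAStringSet` or FASTA path).
#' @return Symmetric numeric matrix with a zero diagonal.
#' @export
p_distance_matrix <- function(msa) {
  mat <- msa_matrix(msa)
  n <- nrow(mat)
  valid <- matrix(mat %in% DNA_BASES4, n, ncol(mat))
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      comp <- valid[i, ] & valid[j, ]
      if (!any(comp)) {
        stop("no comparable sites between '", rownames(mat)[i], "' and '",
             rownames(mat)[j], "'", call. = FALSE)
      }
      d[i, j] <- d[j, i] <- mean(mat[i, comp] != mat[j, comp])
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ agglomeration (Q criterion, via ape); negative branch lengths
#' are clamped to zero with the deficit moved to an adjacent branch so path
#' lengths are approximately preserved.
#'
#' @param d Symmetric distance matrix or `dist` with at least 3 taxa.
#' @return A `phylo` tree with non-negative branch lengths.
#' @export
nj_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) < 3L) {
    stop("neighbor joining needs >= 3 taxa", call. = FALSE)
  }
  tr <- ape::nj(stats::as.dist(d))
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    deficit <- -tr$edge.length[e]
    tr$edge.length[e] <- 0
    parent <- tr$edge[e, 1L]
    adj <- which(tr$edge[, 2L] == parent)
    if (!length(adj)) adj <- setdiff(which(tr$edge[, 1L] == parent), e)[1L]
    tr$edge.length[adj[1L]] <- tr$edge.length[adj[1L]] + deficit
  }
  tr
}

#' Is a set of leaves monophyletic (unrooted sense)?
#'
#' True iff some edge of the unrooted tree bipartitions the leaves into
#' exactly the given subset and its complement; singletons and the full leaf
#' set are trivially monophyletic.
#'
#' @param tree A `phylo` or Newick.
#' @param leaves Character vector of tip labels (non-empty subset).
#' @return Logical scalar.
#' @export
is_monophyletic <- function(tree, leaves) {
  tree <- as_phylo(tree)
  tips <- tree$tip.label
  bad <- setdiff(leaves, tips)
  if (length(bad)) stop("unknown leaf/leaves: ", paste(bad, collapse = ", "), call. = FALSE)
  if (!length(leaves)) stop("`leaves` must be non-empty", call. = FALSE)
  target <- sort(unique(leaves))
  if (length(target) == 1L || length(target) == length(tips)) return(TRUE)

  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  inset <- tips %in% target
  cnt <- integer(nn); tot <- integer(nn)
  cnt[seq_len(ntip)] <- as.integer(inset)
  tot[seq_len(ntip)] <- 1L
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
    cnt[par] <- cnt[par] + cnt[ch]
    tot[par] <- tot[par] + tot[ch]
  }
  k <- length(target)
  # a clade equal to the subset, or to its complement, marks the bipartition
  any((cnt == k & tot == k) | (cnt == 0L & tot == ntip - k))
}

#' Per-region monophyly of species labels
#'
#' For each annotated region, builds an NJ tree from the p-distances of the
#' region sub-alignment and tests whether each species' taxa form a clade.
#' Regions without variable sites carry no phylogenetic signal and are
#' reported as non-monophyletic with `no_signal = TRUE`.
#'
#' @param msa Aligned sequences; columns 0-based.
#' @param species Species labels as in [diagnostic_sites()].
#' @param regions Annotation tibble (`region`, `start`, `end`; 0-based
#'   half-open, e.g. an operon template's annotation) or a named list of
#'   intervals.
#' @return Tibble `region`, `species`, `n_taxa`, `monophyletic`,
#'   `no_signal`, `n_variable_sites`.
#' @export
monophyly_report <- function(msa, species, regions) {
  mat <- msa_matrix(msa)
  sp <- norm_species(species, rownames(mat))
  if (inherits(regions, "operon_template")) regions <- regions$annotation
  if (is.data.frame(regions)) {
    rlist <- setNames(purrr::map(seq_len(nrow(regions)),
                                 function(i) c(regions$start[i], regions$end[i])),
                      regions$region)
  } else {
    rlist <- regions
  }
  levels <- unique(sp)
  rows <- list()
  for (rn in names(rlist)) {
    iv <- as_interval(rlist[[rn]], rn)
    sub <- mat[, seq.int(iv["start"] + 1L, iv["end"]), drop = FALSE]
    nvar <- sum(apply(sub, 2L, function(col) {
      length(unique(col[col %in% DNA_BASES4])) >= 2L
    }))
    if (nvar == 0L || nrow(sub) < 3L) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        region = rn, species = levels,
        n_taxa = as.integer(table(sp)[levels]),
        monophyletic = FALSE, no_signal = TRUE, n_variable_sites = nvar)
      next
    }
    seqs <- setNames(apply(sub, 1L, paste, collapse = ""), rownames(mat))
    tr <- nj_tree(p_distance_matrix(seqs))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      region = rn, species = levels,
      n_taxa = as.integer(table(sp)[levels]),
      monophyletic = vapply(levels, function(s) {
        is_monophyletic(tr, names(sp)[sp == s])
      }, logical(1)),
      no_signal = FALSE, n_variable_sites = nvar)
  }
  dplyr::bind_rows(rows)
}

#' Read and write Newick trees
#' @param x A `phylo` (for writing) or a Newick string/file (for reading).
#' @param path Optional output file for [write_newick()].
#' @return `read_newick` returns a `phylo`; `write_newick` a Newick string
#'   (invisibly when writing to file).
#' @export
read_newick <- function(x) as_phylo(x)

#' @rdname read_newick
#' @export
write_newick <- function(x, path = NULL) {
  stopifnot(inherits(x, "phylo"))
  s <- ape::write.tree(x)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}
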