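# Shared fixtures, built in code at test time.

# compact operon (2220 bp exon) for fast unit tests
small_template <- function(introns = NULL, seed = 11L) {
  build_operon_template(
    c("18S" = 600, ITS1 = 120, "5.8S" = 80, ITS2 = 120, "28S" = 900,
      IGS = 400),
    introns = introns, seed = seed)
}

# the paper-scale operon geometry (7660 bp exon)
std_template <- function(introns = NULL, seed = 101L) {
  build_operon_template(
    c("18S" = 1800, ITS1 = 200, "5.8S" = 160, ITS2 = 200, "28S" = 3300,
      IGS = 2000),
    introns = introns, seed = seed)
}

# a template carrying two introns, one per host gene
intron_template <- function(seed = 21L) {
  small_template(
    introns = tibble::tibble(
      label = c("18S:i1", "28S:i1"), host_region = c("18S", "28S"),
      offset = c(300L, 500L), length = c(400L, 350L)),
    seed = seed)
}

quick_cfg <- function(..., chrom_length = 6000L,
                      locus_lengths = c(mcm7 = 1500L, rpb1 = 1500L,
                                        rpb2 = 1500L)) {
  simulation_config(chrom_length = chrom_length,
                    locus_lengths = locus_lengths, ...)
}

# map a simulated read set back against one operon copy + single-copy contigs
map_back <- function(template, genome, reads, ...) {
  sc <- setdiff(names(genome), c("rdna_tandem", "contaminant"))
  map_reads(reads, c(operon = unname(template$sequence), genome[sc]), ...)
}

# brute-force depth recount: one position at a time from alignment records
naive_depth <- function(alignments, refname, L) {
  a <- dplyr::filter(alignments$alignments, .data$mapped,
                     .data$reference_name == refname)
  depth <- integer(L)
  for (i in seq_len(nrow(a))) {
    span <- seq.int(a$start[i] + 1L, min(a$start[i] + a$aligned_length[i], L))
    depth[span] <- depth[span] + 1L
  }
  depth
}

# brute-force Fitch oracle: minimum changes over every ancestral labeling
brute_fitch <- function(tree, states) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- ape::Ntip(tree)
  nint <- tree$Nnode
  st <- states[tree$tip.label]
  parents <- tree$edge[, 1] - ntip        # internal index of each edge parent
  children <- tree$edge[, 2]
  best <- Inf
  for (mask in 0:(2^nint - 1)) {
    lab <- c(st, as.integer(intToBits(mask))[seq_len(nint)])
    child_lab <- lab[children]
    par_lab <- lab[ntip + parents]
    best <- min(best, sum(child_lab != par_lab))
  }
  as.integer(best)
}

# brute-force Dollo oracle: smallest set of loss edges below the single gain
# (at the MRCA of present leaves) that explains the leaf states
brute_dollo <- function(tree, states) {
  st <- states[tree$tip.label]
  present <- which(st == 1L)
  ntip <- ape::Ntip(tree)
  if (length(present) == 0L || length(present) == ntip) return(0L)
  mrca <- if (length(present) == 1L) present else ape::getMRCA(tree, present)

  # edges and leaf-ancestry inside the gained clade
  nn <- ntip + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  in_clade <- rep(FALSE, nn)
  in_clade[mrca] <- TRUE
  for (e in rev(seq_len(nrow(po$edge)))) {
    if (in_clade[po$edge[e, 1]]) in_clade[po$edge[e, 2]] <- TRUE
  }
  edges <- which(in_clade[po$edge[, 1]])
  # ancestry matrix: leaf x edge (is the edge on the leaf's path from mrca?)
  anc <- matrix(FALSE, ntip, length(edges))
  for (k in seq_along(edges)) {
    sub <- po$edge[edges[k], 2]
    below <- rep(FALSE, nn); below[sub] <- TRUE
    for (e in rev(seq_len(nrow(po$edge)))) {
      if (below[po$edge[e, 1]]) below[po$edge[e, 2]] <- TRUE
    }
    anc[, k] <- below[seq_len(ntip)]
  }
  clade_leaves <- in_clade[seq_len(ntip)]
  target <- st == 0L  # leaves that must be hit by >= 1 loss edge (in clade)
  best <- Inf
  for (mask in 0:(2^length(edges) - 1)) {
    sel <- as.logical(intToBits(mask))[seq_along(edges)]
    hit <- if (any(sel)) rowSums(anc[, sel, drop = FALSE]) > 0 else rep(FALSE, ntip)
    ok <- all(hit[clade_leaves] == target[clade_leaves])
    if (ok) best <- min(best, sum(sel))
  }
  as.integer(best)
}

all_binary_states <- function(tips) {
  n <- length(tips)
  lapply(0:(2^n - 1), function(m) {
    setNames(as.integer(intToBits(m))[seq_len(n)], tips)
  })
}
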