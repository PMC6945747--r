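# Species-set simulation: operon sequences evolved on a tree with planted
# diagnostic sites and intron presence/absence histories.

#' Simulate a species set of operon sequences on a phylogeny
#'
#' Evolves the exon sequence of an operon template down a species tree by
#' per-branch substitutions with region-specific rates (a conserved-18S /
#' variable-spacer profile by default), plants a fixed number of
#' species-diagnostic sites on columns that are invariant after background
#' evolution (so the recorded truth is exact), toggles intron presence along
#' branches, and expands each species tip into `n_taxa_per_species` taxa.
#'
#' Because the substitution process is indel-free, the per-taxon exon
#' sequences are mutually aligned by construction and are returned as the
#' alignment; the per-taxon operon sequences additionally carry the introns
#' each taxon possesses.
#'
#' @param tree Species tree: a `phylo` object, Newick string or file. Tip
#'   labels are the species names.
#' @param template An `operon_template` (its introns define the intron
#'   characters).
#' @param n_taxa_per_species Taxa sampled per species.
#' @param diagnostic_sites_per_species Fixed private substitutions planted
#'   per species inside `diagnostic_regions`.
#' @param intron_event_rate Per-branch probability that an intron's presence
#'   state toggles.
#' @param root_intron_state Presence state of every intron at the root.
#' @param region_rates Named per-site, per-branch substitution probabilities
#'   for each operon region (branch lengths are ignored).
#' @param diagnostic_regions Regions eligible for planted diagnostic sites.
#' @param within_species_rate Per-site substitution probability applied
#'   independently to each taxon on top of its species sequence. Non-zero
#'   values can erode fixation at planted sites; the default keeps species
#'   internally invariant.
#' @param seed Integer seed.
#'
#' @return A list of class `species_set` with elements `alignment` (named
#'   character, exon sequences; alignment columns are 0-based and coincide
#'   with exon-template coordinates), `operons` (sequences with introns),
#'   `taxa` (tibble `taxon`, `species`), `intron_matrix` (an
#'   `intron_presence_matrix`), `events` (tibble `intron`, `n_events` of
#'   simulated toggles), `diagnostic_truth` (tibble `species`, `position`,
#'   `ref_base`, `alt_base`), `species_tree` and `taxa_tree` (`phylo`).
#' @export
simulate_species_set <- function(tree, template,
                                 n_taxa_per_species = 3L,
                                 diagnostic_sites_per_species = 3L,
                                 intron_event_rate = 0.05,
                                 root_intron_state = TRUE,
                                 region_rates = c("18S" = 0, "ITS1" = 0.003,
                                                  "5.8S" = 0.0005,
                                                  "ITS2" = 0.003,
                                                  "28S" = 0.001,
                                                  "IGS" = 0.005),
                                 diagnostic_regions = c("ITS1", "ITS2"),
                                 within_species_rate = 0,
                                 seed = 1L) {
  tree <- as_phylo(tree)
  stopifnot(inherits(template, "operon_template"))
  if (ape::Ntip(tree) < 2L) stop("tree must have >= 2 leaves", call. = FALSE)
  if (intron_event_rate < 0 || intron_event_rate > 1) {
    stop("intron_event_rate must be in [0, 1]", call. = FALSE)
  }

  ex <- exon_template(template)
  ann <- ex$annotation
  L <- nchar(ex$sequence)
  region_of <- rep(ann$region, ann$end - ann$start)
  if (!all(OPERON_REGIONS %in% names(region_rates))) {
    stop("region_rates must name all six operon regions", call. = FALSE)
  }
  site_rate <- unname(region_rates[region_of])

  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  root <- ntip + 1L
  po <- ape::reorder.phylo(tree, "postorder")
  edges <- po$edge[rev(seq_len(nrow(po$edge))), , drop = FALSE] # preorder

  labels <- template$introns$label

  withr::with_seed(as.integer(seed), {
    node_seq <- vector("list", ntip + nnode)
    node_seq[[root]] <- seq_chars(ex$sequence)
    intron_state <- matrix(root_intron_state, nrow = ntip + nnode,
                           ncol = length(labels),
                           dimnames = list(NULL, labels))
    n_events <- setNames(integer(length(labels)), labels)
    for (e in seq_len(nrow(edges))) {
      par <- edges[e, 1L]; ch <- edges[e, 2L]
      chars <- node_seq[[par]]
      hit <- which(runif(L) < site_rate)
      if (length(hit)) chars[hit] <- other_base(chars[hit])
      node_seq[[ch]] <- chars
      if (length(labels)) {
        flip <- runif(length(labels)) < intron_event_rate
        intron_state[ch, ] <- xor(intron_state[par, ], flip)
        n_events <- n_events + flip
      }
    }

    species <- tree$tip.label
    sp_seq <- lapply(seq_len(ntip), function(i) node_seq[[i]])
    names(sp_seq) <- species

    # plant diagnostic sites on columns invariant across all species
    diag_iv <- lapply(diagnostic_regions, function(r) {
      iv <- region_interval(ann, r); seq.int(iv["start"] + 1L, iv["end"])
    })
    cand <- unlist(diag_iv)
    spmat <- do.call(rbind, sp_seq)
    invariant <- cand[apply(spmat[, cand, drop = FALSE], 2L,
                            function(col) length(unique(col)) == 1L)]
    need <- diagnostic_sites_per_species * length(species)
    if (length(invariant) < need) {
      stop("not enough invariant columns in diagnostic regions to plant ",
           need, " diagnostic sites", call. = FALSE)
    }
    chosen <- invariant[sample.int(length(invariant), need)]
    diag_truth <- tibble::tibble(
      species = rep(species, each = diagnostic_sites_per_species),
      position = as.integer(chosen - 1L),
      ref_base = NA_character_, alt_base = NA_character_)
    for (i in seq_len(nrow(diag_truth))) {
      sp <- diag_truth$species[i]; at <- diag_truth$position[i] + 1L
      ref <- sp_seq[[sp]][at]
      alt <- other_base(ref)
      sp_seq[[sp]][at] <- alt
      diag_truth$ref_base[i] <- ref
      diag_truth$alt_base[i] <- alt
    }

    # expand species into taxa
    taxon_species <- rep(species, each = n_taxa_per_species)
    taxon_names <- paste0(taxon_species, "_",
                          rep(seq_len(n_taxa_per_species), length(species)))
    taxa <- tibble::tibble(species = taxon_species, taxon = taxon_names)
    aln <- character(nrow(taxa))
    for (i in seq_len(nrow(taxa))) {
      chars <- sp_seq[[taxa$species[i]]]
      if (within_species_rate > 0) {
        hit <- which(runif(L) < within_species_rate)
        if (length(hit)) chars[hit] <- other_base(chars[hit])
      }
      aln[i] <- chars_to_seq(chars)
    }
    names(aln) <- taxa$taxon
  })

  # per-taxon operons with the introns their species carries
  sp_states <- intron_state[seq_len(ntip), , drop = FALSE]
  rownames(sp_states) <- tree$tip.label
  operons <- vapply(seq_len(nrow(taxa)), function(i) {
    present <- labels[sp_states[taxa$species[i], ]]
    insert_introns(aln[i], template, present)
  }, character(1))
  names(operons) <- taxa$taxon

  im <- tibble::as_tibble(sp_states[taxa$species, , drop = FALSE])
  im <- dplyr::bind_cols(tibble::tibble(taxon = taxa$taxon), im)
  class(im) <- c("intron_presence_matrix", class(im))

  structure(list(
    alignment = aln, operons = operons,
    taxa = taxa[, c("taxon", "species")],
    intron_matrix = im,
    events = tibble::tibble(intron = labels, n_events = unname(n_events)),
    diagnostic_truth = diag_truth,
    species_tree = tree,
    taxa_tree = expand_species_tree(tree, taxa)),
    class = "species_set")
}

#' @export
print.species_set <- function(x, ...) {
  cat("<species_set>", nrow(x$taxa), "taxa,",
      length(unique(x$taxa$species)), "species,",
      nrow(x$events), "intron character(s)\n")
  invisible(x)
}

# replace each species tip of `tree` by a zero-length polytomy of its taxa
expand_species_tree <- function(tree, taxa) {
  tr <- tree
  if (is.null(tr$edge.length)) tr$edge.length <- rep(1, nrow(tr$edge))
  s <- ape::write.tree(tr)
  for (sp in tr$tip.label) {
    tx <- taxa$taxon[taxa$species == sp]
    rep_str <- paste0("(", paste0(tx, ":0", collapse = ","), ")")
    pat <- paste0("([(,])", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", sp), ":")
    s2 <- sub(pat, paste0("\\1", rep_str, ":"), s)
    if (identical(s2, s)) stop("failed to expand species tip '", sp, "'", call. = FALSE)
    s <- s2
  }
  ape::read.tree(text = s)
}
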