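# Intron presence/absence detection and minimum gain/loss counting.

#' Transfer operon annotation onto an assembled query operon
#'
#' Globally aligns a query operon against an annotated (typically
#' intron-free) reference template with affine gap penalties, projects the
#' region boundaries through the alignment, and reports query-only
#' insertions of at least `min_intron_length` bp falling strictly inside the
#' 18S or 28S as candidate introns.
#'
#' @param query Query operon sequence (character scalar).
#' @param reference An `operon_template` serving as the annotated reference.
#' @param min_intron_length Minimum insertion length called as a candidate
#'   intron (shorter insertions are treated as alignment artifacts).
#' @param min_identity Minimum identity over aligned reference positions;
#'   below this the transfer is refused as unreliable.
#' @param gap_opening,gap_extension Affine gap penalties for the alignment.
#' @return An object of class `annotation_transfer`: `annotation` (tibble of
#'   projected regions in query coordinates), `candidate_introns` (tibble
#'   `host_region`, `ref_site`, `query_start`, `query_end`, `length`),
#'   `identity`, and `deleted_ref` (tibble of reference segments absent from
#'   the query, used for unknown calls).
#' @export
transfer_annotation <- function(query, reference, min_intron_length = 50L,
                                min_identity = 0.70, gap_opening = 10,
                                gap_extension = 0.5) {
  stopifnot(inherits(reference, "operon_template"))
  query <- toupper(query)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = FALSE)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(query), Biostrings::DNAString(reference$sequence),
    type = "global", substitutionMatrix = mat,
    gapOpening = gap_opening, gapExtension = gap_extension)
  qa <- seq_chars(as.character(Biostrings::alignedPattern(al)))
  sa <- seq_chars(as.character(Biostrings::alignedSubject(al)))

  qgap <- qa == "-"
  sgap <- sa == "-"
  qpos <- cumsum(!qgap)           # query position (1-based) at each column
  rpos <- cumsum(!sgap)           # reference position (1-based)

  both <- !qgap & !sgap
  identity <- sum(qa[both] == sa[both]) / sum(both)
  if (identity < min_identity) {
    stop(sprintf(paste0("annotation transfer unreliable: alignment identity ",
                        "%.2f below %.2f"), identity, min_identity),
         call. = FALSE)
  }

  # query coordinate aligned at each reference position (NA where deleted)
  L <- nchar(reference$sequence)
  qat <- rep(NA_integer_, L)
  qat[rpos[both]] <- qpos[both]

  ann <- reference$annotation
  proj <- purrr::map(seq_len(nrow(ann)), function(i) {
    rr <- seq.int(ann$start[i] + 1L, ann$end[i])
    qq <- qat[rr]
    if (all(is.na(qq))) {
      return(tibble::tibble(region = ann$region[i], start = NA_integer_,
                            end = NA_integer_))
    }
    tibble::tibble(region = ann$region[i],
                   start = min(qq, na.rm = TRUE) - 1L,
                   end = max(qq, na.rm = TRUE))
  })
  proj <- dplyr::bind_rows(proj)

  # query-only insertion runs
  runs <- rle(sgap)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  cand <- list()
  for (i in seq_along(runs$values)) {
    if (!runs$values[i] || runs$lengths[i] < min_intron_length) next
    ref_site <- rpos[starts[i]]    # ref position after which insertion falls
    host <- ann$region[ann$start < ref_site & ref_site < ann$end]
    if (!length(host) || !host %in% c("18S", "28S")) next
    qs <- qpos[starts[i]] - 1L     # 0-based query start of the insertion
    cand[[length(cand) + 1L]] <- tibble::tibble(
      host_region = host, ref_site = ref_site, query_start = qs,
      query_end = qs + runs$lengths[i], length = runs$lengths[i])
  }
  cand <- if (length(cand)) dplyr::bind_rows(cand) else {
    tibble::tibble(host_region = character(), ref_site = integer(),
                   query_start = integer(), query_end = integer(),
                   length = integer())
  }

  del <- rle(is.na(qat))
  dend <- cumsum(del$lengths)
  dstart <- dend - del$lengths + 1L
  deleted <- tibble::tibble(start = dstart[del$values] - 1L,
                            end = dend[del$values])

  structure(list(annotation = proj, candidate_introns = cand,
                 identity = identity, deleted_ref = deleted,
                 reference_annotation = ann), class = "annotation_transfer")
}

#' @export
print.annotation_transfer <- function(x, ...) {
  cat(sprintf("<annotation_transfer> identity %.3f, %d candidate intron(s)\n",
              x$identity, nrow(x$candidate_introns)))
  print(x$annotation)
  invisible(x)
}

#' Junction motif catalog for the introns of a template
#'
#' For every intron of an annotated template, records its insertion site in
#' exon coordinates together with `flank` bp of exon sequence on each side
#' of the junction and the terminal `flank` bp of the intron itself. The
#' concatenated flanks form the intron-absent junction sequence searched for
#' in raw reads.
#'
#' @param template An `operon_template` carrying introns.
#' @param flank Flank length in bp (default 30).
#' @return Tibble with one row per intron: `label`, `host_region`, `site`
#'   (exon coordinate), `upstream`, `downstream`, `intron_5p`, `intron_3p`,
#'   `flank`.
#' @export
intron_catalog <- function(template, flank = 30L) {
  stopifnot(inherits(template, "operon_template"))
  if (!nrow(template$introns)) {
    stop("template has no introns to catalog", call. = FALSE)
  }
  ex <- exon_template(template)$sequence
  sites <- intron_sites_exon(template)
  up <- substr(rep(ex, nrow(sites)), pmax(1L, sites$site - flank + 1L), sites$site)
  down <- substr(rep(ex, nrow(sites)), sites$site + 1L, sites$site + flank)
  iseq <- template$introns$sequence
  tibble::tibble(
    label = sites$label, host_region = sites$host_region, site = sites$site,
    upstream = up, downstream = down,
    intron_5p = substr(iseq, 1L, pmin(nchar(iseq), flank)),
    intron_3p = substr(iseq, pmax(1L, nchar(iseq) - flank + 1L), nchar(iseq)),
    flank = as.integer(flank))
}

#' @rdname intron_catalog
#' @param label Intron label to extract as a single junction motif.
#' @export
junction_motif <- function(template, label, flank = 30L) {
  cat_ <- intron_catalog(template, flank)
  row <- cat_[cat_$label == label, , drop = FALSE]
  if (!nrow(row)) stop("no intron labelled '", label, "'", call. = FALSE)
  row
}

#' Call intron presence from a transferred annotation
#'
#' Present when a candidate intron insertion falls within `tolerance` bp of
#' the catalogued site; unknown when the site lies in a reference segment
#' with no aligned query sequence; absent when the junction is contiguous.
#'
#' @param transfer An `annotation_transfer` (query vs the intron-free
#'   reference).
#' @param catalog An intron catalog from [intron_catalog()].
#' @param tolerance Site-matching tolerance in bp.
#' @return Tibble `label`, `state` (factor present/absent/unknown).
#' @export
intron_presence_from_assembly <- function(transfer, catalog, tolerance = 10L) {
  stopifnot(inherits(transfer, "annotation_transfer"))
  cand <- transfer$candidate_introns
  del <- transfer$deleted_ref
  state <- vapply(seq_len(nrow(catalog)), function(i) {
    s <- catalog$site[i]
    if (nrow(cand) && any(abs(cand$ref_site - s) <= tolerance)) return("present")
    near <- c(s, s + 1L)  # exon bases flanking the junction (1-based ref pos)
    in_del <- nrow(del) && any(near[1] > del$start & near[1] <= del$end |
                                 near[2] > del$start & near[2] <= del$end)
    if (in_del) "unknown" else "absent"
  }, character(1))
  tibble::tibble(label = catalog$label,
                 state = factor(state, levels = c("present", "absent", "unknown")))
}

#' Search raw reads for intron-junction support
#'
#' A read supports *absence* when it contains the exon-exon junction window
#' (`min_span` bp on each side of the insertion point) with at most
#' `max_mismatches` mismatches; it supports *presence* when it likewise
#' spans either exon/intron boundary. Both strands are searched.
#'
#' @param reads A `read_set`, character vector, `DNAStringSet` or FASTQ
#'   path.
#' @param motif One row of an intron catalog (see [junction_motif()]).
#' @param min_span Bases required on each side of a junction.
#' @param max_mismatches Mismatch tolerance within the spanned window.
#' @return Tibble with `absence_support` and `presence_support` read counts.
#' @export
junction_motif_support <- function(reads, motif, min_span = 10L,
                                   max_mismatches = 2L) {
  rd <- reads_to_vector(reads)
  if (min_span > motif$flank) {
    stop("motif flanks are shorter than min_span", call. = FALSE)
  }
  up_end <- substr(motif$upstream, nchar(motif$upstream) - min_span + 1L,
                   nchar(motif$upstream))
  down_start <- substr(motif$downstream, 1L, min_span)
  if (min(nchar(motif$intron_5p), nchar(motif$intron_3p)) < min_span) {
    stop("intron flanks are shorter than min_span", call. = FALSE)
  }
  absence_core <- paste0(up_end, down_start)
  presence_cores <- c(
    paste0(up_end, substr(motif$intron_5p, 1L, min_span)),
    paste0(substr(motif$intron_3p, nchar(motif$intron_3p) - min_span + 1L,
                  nchar(motif$intron_3p)), down_start))

  subject <- Biostrings::DNAStringSet(unname(rd))
  count_support <- function(patterns) {
    hit <- rep(FALSE, length(subject))
    for (p in patterns) {
      for (pp in c(p, revcomp(p))) {
        hit <- hit | Biostrings::vcountPattern(
          pp, subject, max.mismatch = max_mismatches) > 0L
      }
    }
    sum(hit)
  }
  tibble::tibble(absence_support = count_support(absence_core),
                 presence_support = count_support(presence_cores))
}

# ---- parsimony ------------------------------------------------------------

prep_states <- function(tree, states, prune_unknown) {
  tree <- as_phylo(tree)
  st <- norm_states(states)
  tips <- tree$tip.label
  known <- intersect(tips, names(st)[!is.na(st)])
  missing <- setdiff(tips, known)
  if (length(missing)) {
    if (!prune_unknown) {
      stop("no state for leaf/leaves: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    if (length(known) < 2L) {
      return(list(tree = NULL, states = st[known]))
    }
    tree <- ape::drop.tip(tree, missing)
  }
  list(tree = tree, states = st[tree$tip.label])
}

#' Minimum number of state changes of a binary character (Fitch parsimony)
#'
#' Unit-cost small parsimony of a presence/absence character on a rooted or
#' unrooted, binary or multifurcating tree (computed by the Sankoff dynamic
#' program, which handles polytomies exactly). The count is independent of
#' root placement.
#'
#' @param tree A `phylo` object or Newick string/file.
#' @param states Named vector (tip label -> state): logical, 0/1, or
#'   "present"/"absent". `NA` marks an unknown state.
#' @param prune_unknown Drop leaves with missing/unknown states instead of
#'   erroring.
#' @return Integer minimum number of changes.
#' @examples
#' tr <- ape::read.tree(text = "((A,B),(C,D));")
#' fitch_min_changes(tr, c(A = 1, B = 1, C = 0, D = 0)) # 1
#' @export
fitch_min_changes <- function(tree, states, prune_unknown = FALSE) {
  pp <- prep_states(tree, states, prune_unknown)
  if (is.null(pp$tree)) return(0L)
  tree <- pp$tree
  st <- pp$states
  ntip <- ape::Ntip(tree)
  if (ntip < 2L) return(0L)
  po <- ape::reorder.phylo(tree, "postorder")
  nn <- ntip + tree$Nnode
  big <- nn + 1
  cost <- matrix(0, nrow = nn, ncol = 2L)
  cost[seq_len(ntip), 1L] <- ifelse(st == 0L, 0, big)
  cost[seq_len(ntip), 2L] <- ifelse(st == 1L, 0, big)
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
    c0 <- min(cost[ch, 1L], cost[ch, 2L] + 1)
    c1 <- min(cost[ch, 2L], cost[ch, 1L] + 1)
    cost[par, 1L] <- cost[par, 1L] + c0
    cost[par, 2L] <- cost[par, 2L] + c1
  }
  root <- ntip + 1L
  as.integer(min(cost[root, ]))
}

#' Minimum losses under single-gain (Dollo) parsimony
#'
#' Assumes the intron is gained at most once, at the most recent common
#' ancestor of the leaves where it is present, and counts the minimum number
#' of loss events needed below that ancestor (each maximal all-absent
#' subtree costs one loss). Leaves outside the gained clade were never
#' gained and cost nothing.
#'
#' @inheritParams fitch_min_changes
#' @return Integer minimum number of losses.
#' @export
dollo_min_losses <- function(tree, states, prune_unknown = FALSE) {
  pp <- prep_states(tree, states, prune_unknown)
  if (is.null(pp$tree)) return(0L)
  tree <- pp$tree
  st <- pp$states
  ntip <- ape::Ntip(tree)
  present <- which(st == 1L)
  if (length(present) == 0L || length(present) == ntip) return(0L)
  mrca <- if (length(present) == 1L) present else ape::getMRCA(tree, present)

  po <- ape::reorder.phylo(tree, "postorder")
  nn <- ntip + tree$Nnode
  all_absent <- rep(TRUE, nn)
  all_absent[seq_len(ntip)] <- st == 0L
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
    all_absent[par] <- all_absent[par] && all_absent[ch]
  }
  # membership of the gained clade
  in_clade <- rep(FALSE, nn)
  in_clade[mrca] <- TRUE
  for (e in rev(seq_len(nrow(po$edge)))) {
    par <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
    if (in_clade[par]) in_clade[ch] <- TRUE
  }
  losses <- 0L
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
    if (in_clade[par] && all_absent[ch] && !all_absent[par]) {
      losses <- losses + 1L
    }
  }
  losses
}

#' Per-intron event counts on a tree
#'
#' Scores every intron character of a presence/absence matrix on a tree,
#' reporting the Fitch minimum-change count, the Dollo minimum-loss count,
#' and whether the pattern is explicable by a single event.
#'
#' @param matrix An `intron_presence_matrix` (tibble with a `taxon` column
#'   and one logical/0-1/NA column per intron) or an equivalent data frame.
#' @param tree A `phylo` or Newick; must contain every matrix taxon. Tree
#'   tips without a matrix row are pruned.
#' @param prune_unknown Drop taxa with unknown state for a character
#'   (default) instead of erroring.
#' @return Tibble with one row per intron: `intron`, `n_present`,
#'   `n_absent`, `n_unknown`, `fitch_changes`, `dollo_losses`,
#'   `single_event` (`fitch_changes <= 1`).
#' @export
event_report <- function(matrix, tree, prune_unknown = TRUE) {
  m <- tibble::as_tibble(matrix)
  if (!"taxon" %in% names(m)) stop("matrix needs a `taxon` column", call. = FALSE)
  tree <- as_phylo(tree)
  missing <- setdiff(m$taxon, tree$tip.label)
  if (length(missing)) {
    stop("taxa absent from tree: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(tree$tip.label, m$taxon)
  if (length(extra)) tree <- ape::drop.tip(tree, extra)

  introns <- setdiff(names(m), "taxon")
  rows <- purrr::map(introns, function(lb) {
    st <- setNames(as.integer(as.logical(m[[lb]])), m$taxon)
    fc <- fitch_min_changes(tree, st, prune_unknown = prune_unknown)
    dl <- dollo_min_losses(tree, st, prune_unknown = prune_unknown)
    tibble::tibble(intron = lb,
                   n_present = sum(st == 1L, na.rm = TRUE),
                   n_absent = sum(st == 0L, na.rm = TRUE),
                   n_unknown = sum(is.na(st)),
                   fitch_changes = fc, dollo_losses = dl,
                   single_event = fc <= 1L)
  })
  dplyr::bind_rows(rows)
}

#' Read / write an intron presence matrix as TSV ({1, 0, ?})
#'
#' @param matrix An `intron_presence_matrix`.
#' @param path TSV file (taxa in rows, introns in columns).
#' @return For the reader, an `intron_presence_matrix` with logical cells
#'   (`NA` for `?`).
#' @export
write_intron_matrix <- function(matrix, path) {
  m <- tibble::as_tibble(matrix)
  for (cl in setdiff(names(m), "taxon")) {
    m[[cl]] <- dplyr::case_when(is.na(m[[cl]]) ~ "?",
                                as.logical(m[[cl]]) ~ "1", TRUE ~ "0")
  }
  readr::write_tsv(m, path)
  invisible(path)
}

#' @rdname write_intron_matrix
#' @export
read_intron_matrix <- function(path) {
  m <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(.default = "c"))
  for (cl in setdiff(names(m), "taxon")) {
    m[[cl]] <- dplyr::case_when(m[[cl]] == "?" ~ NA, m[[cl]] == "1" ~ TRUE,
                                TRUE ~ FALSE)
  }
  class(m) <- c("intron_presence_matrix", class(m))
  m
}
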