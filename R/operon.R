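# Operon templates: the annotated nrDNA repeat unit used throughout the
# simulator and the annotation-transfer machinery.

#' Canonical region order of the nuclear ribosomal operon
#'
#' The repeat unit is modelled as six contiguous regions in fixed order:
#' 18S, ITS1, 5.8S, ITS2, 28S and the intergenic spacer (IGS). Introns may be
#' inserted strictly inside the 18S or 28S genes.
#'
#' @export
OPERON_REGIONS <- c("18S", "ITS1", "5.8S", "ITS2", "28S", "IGS")

normalize_intron_spec <- function(introns) {
  if (is.null(introns) || (is.data.frame(introns) && nrow(introns) == 0L)) {
    return(tibble::tibble(label = character(), host_region = character(),
                          offset = integer(), sequence = character()))
  }
  it <- tibble::as_tibble(introns)
  if (!all(c("label", "host_region", "offset") %in% names(it))) {
    stop("intron spec needs columns label, host_region, offset", call. = FALSE)
  }
  if (anyDuplicated(it$label)) stop("intron labels must be unique", call. = FALSE)
  if (!"sequence" %in% names(it)) it$sequence <- NA_character_
  if (!"length" %in% names(it)) it$length <- NA_integer_
  it
}

#' Build an annotated ribosomal operon template
#'
#' Generates a random DNA repeat unit with the canonical 18S-ITS1-5.8S-ITS2-
#' 28S-IGS architecture and optional introns inserted inside the 18S or 28S.
#' All coordinates are 0-based half-open. The result is the reference object
#' consumed by the genome simulator, the read mapper and annotation transfer.
#'
#' @param region_lengths Named vector of exon lengths in bp for all six
#'   regions in [OPERON_REGIONS].
#' @param introns Optional data frame with columns `label`, `host_region`
#'   (one of `"18S"`, `"28S"`), `offset` (0-based insertion point within the
#'   host exon, strictly inside it) and either `sequence` or `length` (a
#'   random intron of that length is generated).
#' @param seed Integer seed; the template is deterministic given its inputs.
#'
#' @return An object of class `operon_template`: a list with `sequence`,
#'   `annotation` (tibble `region`, `start`, `end`), `introns` (tibble with
#'   absolute `start`/`end` in template coordinates), and the per-region
#'   exon sequences.
#' @examples
#' tpl <- build_operon_template(
#'   c(`18S` = 1800, ITS1 = 200, `5.8S` = 160, ITS2 = 200, `28S` = 3300,
#'     IGS = 2000))
#' nchar(tpl$sequence) # 7660
#' @export
build_operon_template <- function(region_lengths, introns = NULL, seed = 1L) {
  if (!setequal(names(region_lengths), OPERON_REGIONS)) {
    stop("region_lengths must name exactly: ",
         paste(OPERON_REGIONS, collapse = ", "), call. = FALSE)
  }
  region_lengths <- as.integer(region_lengths[OPERON_REGIONS])
  names(region_lengths) <- OPERON_REGIONS
  if (any(region_lengths <= 0L)) stop("region lengths must be positive", call. = FALSE)

  it <- normalize_intron_spec(introns)
  for (i in seq_len(nrow(it))) {
    host <- it$host_region[i]
    if (!host %in% c("18S", "28S")) {
      stop("intron '", it$label[i], "': host_region must be 18S or 28S",
           call. = FALSE)
    }
    off <- it$offset[i]
    if (is.na(off) || off < 1L || off > region_lengths[[host]] - 1L) {
      stop("intron '", it$label[i],
           "': insertion offset lies outside its host region", call. = FALSE)
    }
  }

  withr::with_seed(seed, {
    exon_seqs <- lapply(region_lengths, random_dna)
    if (nrow(it)) {
      need <- is.na(it$sequence)
      it$sequence[need] <- vapply(it$length[need], random_dna, character(1))
    }
  })
  it$length <- nchar(it$sequence)

  asm <- assemble_operon(exon_seqs, it)
  structure(
    list(sequence = asm$sequence, annotation = asm$annotation,
         introns = asm$introns, exon_sequences = exon_seqs,
         region_lengths = region_lengths, seed = seed),
    class = "operon_template")
}

assemble_operon <- function(exon_seqs, introns_tbl) {
  pieces <- character()
  ann <- vector("list", length(OPERON_REGIONS))
  intr <- list()
  cursor <- 0L
  for (ri in seq_along(OPERON_REGIONS)) {
    rg <- OPERON_REGIONS[ri]
    exon <- exon_seqs[[rg]]
    ex_len <- nchar(exon)
    ints <- introns_tbl[introns_tbl$host_region == rg, , drop = FALSE]
    ints <- ints[order(ints$offset), , drop = FALSE]
    rstart <- cursor
    last <- 0L
    for (i in seq_len(nrow(ints))) {
      off <- as.integer(ints$offset[i])
      if (off > last) pieces <- c(pieces, substr(exon, last + 1L, off))
      cursor <- cursor + (off - last)
      iseq <- ints$sequence[i]
      intr[[length(intr) + 1L]] <- tibble::tibble(
        label = ints$label[i], host_region = rg, offset = off,
        length = nchar(iseq), start = cursor, end = cursor + nchar(iseq),
        sequence = iseq)
      pieces <- c(pieces, iseq)
      cursor <- cursor + nchar(iseq)
      last <- off
    }
    pieces <- c(pieces, substr(exon, last + 1L, ex_len))
    cursor <- cursor + (ex_len - last)
    ann[[ri]] <- tibble::tibble(region = rg, start = rstart, end = cursor)
  }
  introns <- if (length(intr)) dplyr::bind_rows(intr) else {
    tibble::tibble(label = character(), host_region = character(),
                   offset = integer(), length = integer(), start = integer(),
                   end = integer(), sequence = character())
  }
  list(sequence = paste(pieces, collapse = ""),
       annotation = dplyr::bind_rows(ann), introns = introns)
}

#' @export
print.operon_template <- function(x, ...) {
  cat("<operon_template> ", nchar(x$sequence), " bp, ",
      nrow(x$introns), " intron(s)\n", sep = "")
  print(x$annotation)
  invisible(x)
}

#' Intron-free version of an operon template
#'
#' Drops all introns, yielding the exon-only repeat unit (the analogue of an
#' intron-poor yeast reference operon used to anchor annotation transfer).
#'
#' @param template An `operon_template`.
#' @return An `operon_template` without introns; coordinates are exon
#'   coordinates.
#' @export
exon_template <- function(template) {
  stopifnot(inherits(template, "operon_template"))
  asm <- assemble_operon(template$exon_sequences, normalize_intron_spec(NULL))
  structure(
    list(sequence = asm$sequence, annotation = asm$annotation,
         introns = asm$introns, exon_sequences = template$exon_sequences,
         region_lengths = template$region_lengths, seed = template$seed),
    class = "operon_template")
}

# exon-coordinate insertion site of each intron of a template
intron_sites_exon <- function(template) {
  ex_ann <- exon_template(template)$annotation
  st <- setNames(ex_ann$start, ex_ann$region)
  tibble::tibble(label = template$introns$label,
                 host_region = template$introns$host_region,
                 site = st[template$introns$host_region] + template$introns$offset)
}

# rebuild an operon sequence from an exon sequence (same exon coordinates as
# the template) plus the subset of template introns that are present
insert_introns <- function(exon_seq, template, labels) {
  sites <- intron_sites_exon(template)
  keep <- template$introns$label %in% labels
  if (!any(keep)) return(exon_seq)
  ord <- order(sites$site[keep], decreasing = TRUE)
  seqs <- template$introns$sequence[keep][ord]
  at <- sites$site[keep][ord]
  out <- exon_seq
  for (i in seq_along(at)) {
    out <- paste0(substr(out, 1L, at[i]), seqs[i],
                  substr(out, at[i] + 1L, nchar(out)))
  }
  out
}

#' Interval spanned by named operon regions
#'
#' @param annotation An annotation tibble (`region`, `start`, `end`) or an
#'   `operon_template`.
#' @param regions Character vector of region names; must be contiguous in the
#'   canonical order (e.g. `c("ITS1", "5.8S", "ITS2")`).
#' @return Named integer `c(start, end)`, 0-based half-open.
#' @export
region_interval <- function(annotation, regions) {
  ann <- if (inherits(annotation, "operon_template")) annotation$annotation else annotation
  bad <- setdiff(regions, ann$region)
  if (length(bad)) stop("unknown region(s): ", paste(bad, collapse = ", "), call. = FALSE)
  idx <- sort(match(regions, ann$region))
  if (any(diff(idx) != 1L)) stop("regions must be contiguous", call. = FALSE)
  c(start = ann$start[idx[1]], end = ann$end[idx[length(idx)]])
}

#' The ITS barcode interval (ITS1 + 5.8S + ITS2) of an annotation
#' @inheritParams region_interval
#' @return Named integer `c(start, end)`, 0-based half-open.
#' @export
its_interval <- function(annotation) {
  region_interval(annotation, c("ITS1", "5.8S", "ITS2"))
}
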