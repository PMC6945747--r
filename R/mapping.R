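# Read placement: internal gapless seed-and-extend mapper plus SAM import.

reads_to_vector <- function(reads) {
  if (inherits(reads, "read_set")) {
    out <- c(reads$reads$read1, reads$reads$read2)
    names(out) <- c(paste0(reads$reads$id, "/1"), paste0(reads$reads$id, "/2"))
    return(out)
  }
  as_named_seqs(reads, "reads")
}

#' Map reads to references with a gapless seed-and-extend mapper
#'
#' Each read is placed, on either strand, at the position with maximal exact
#' k-mer seed support and extended without gaps; ties are broken by smallest
#' reference position, then forward strand. Reads whose best placement
#' exceeds `max_mismatch_fraction` mismatches (ambiguous bases count as
#' mismatches) are flagged unmapped. The mapper is substitution-only by
#' design: it serves simulated indel-free reads, while externally aligned
#' real data enters through [read_sam()].
#'
#' @param reads A `read_set`, named character vector, `DNAStringSet`, or
#'   FASTA/FASTQ path.
#' @param reference Reference sequences (named character, `DNAStringSet` or
#'   FASTA path). Reads are placed against all references jointly.
#' @param k Seed length (exact-match k-mer), default 21.
#' @param max_mismatch_fraction Maximum tolerated mismatch fraction.
#' @return An object of class `read_alignments`: list with `alignments`
#'   (tibble `read_id`, `reference_name`, `start` 0-based, `strand`,
#'   `aligned_length`, `n_mismatch`, `mapped`) and `mismatches` (tibble
#'   `read_id`, `reference_name`, `pos`, `base` — the read base oriented to
#'   the reference), plus the reference sequences.
#' @export
map_reads <- function(reads, reference, k = 21L, max_mismatch_fraction = 0.1) {
  rd <- reads_to_vector(reads)
  ref <- as_named_seqs(reference, "reference")
  if (!length(ref) || any(!nzchar(ref))) stop("reference is empty", call. = FALSE)
  if (k > max(nchar(rd))) stop("seed length k exceeds the read length", call. = FALSE)

  res <- cpp_map_reads(unname(rd), unname(ref), as.integer(k),
                       max_mismatch_fraction)
  aln <- tibble::tibble(
    read_id = names(rd),
    reference_name = names(ref)[res$ref],
    start = res$start,
    strand = c("-", NA, "+")[res$strand + 2L],
    aligned_length = res$aligned_length,
    n_mismatch = res$n_mismatch,
    mapped = res$mapped)
  mm <- tibble::tibble(
    read_id = names(rd)[res$mm_read],
    reference_name = names(ref)[res$mm_ref],
    pos = res$mm_pos,
    base = res$mm_base)
  structure(list(alignments = aln, mismatches = mm, reference = ref,
                 k = k, max_mismatch_fraction = max_mismatch_fraction),
            class = "read_alignments")
}

#' @export
print.read_alignments <- function(x, ...) {
  cat("<read_alignments>", sum(x$alignments$mapped), "mapped /",
      nrow(x$alignments), "reads on", length(x$reference), "reference(s)\n")
  invisible(x)
}

#' Import alignments from a SAM file
#'
#' Reads a text SAM file (via Rsamtools), drops unmapped records, and
#' reconciles CIGAR strings and MD tags into per-base mismatch records under
#' the package's gapless convention: positions stay reference-based,
#' `aligned_length` is the reference span consumed by the alignment, and
#' indels contribute no mismatches. When the MD tag is absent, mismatches are
#' recomputed from the read sequence against `reference`.
#'
#' @param path SAM file with a header.
#' @param reference Optional reference sequences; required for pileups and
#'   for mismatch recovery without MD tags.
#' @return A `read_alignments` object.
#' @export
read_sam <- function(path, reference = NULL) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "@")) {
    stop("SAM parse error: missing header", call. = FALSE)
  }
  body <- which(!startsWith(lines, "@"))
  for (i in body) {
    if (length(strsplit(lines[i], "\t", fixed = TRUE)[[1]]) < 11L) {
      stop("SAM parse error at line ", i, ": fewer than 11 fields", call. = FALSE)
    }
  }
  ref <- if (!is.null(reference)) as_named_seqs(reference, "reference") else NULL

  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "strand", "cigar", "seq"),
    tag = "MD")
  b <- Rsamtools::scanBam(bam, param = p)[[1]]

  keep <- !bitwAnd(b$flag, 4L)
  qname <- b$qname[keep]
  rname <- as.character(b$rname[keep])
  pos0 <- b$pos[keep] - 1L
  strand <- as.character(b$strand[keep])
  cigar <- b$cigar[keep]
  seqs <- as.character(b$seq[keep])
  md <- b$tag$MD[keep]

  n <- length(qname)
  alen <- integer(n)
  mm_list <- vector("list", n)
  for (i in seq_len(n)) {
    ops <- cigar_ops(cigar[i])
    alen[i] <- sum(ops$len[ops$op %in% c("M", "=", "X", "D", "N")])
    blocks <- cigar_blocks(ops)
    mm_list[[i]] <- if (!is.null(md) && !is.na(md[i])) {
      md_mismatches(md[i], blocks, pos0[i], seqs[i])
    } else if (!is.null(ref)) {
      seq_mismatches(blocks, pos0[i], seqs[i], ref[[rname[i]]])
    } else {
      stop("MD tag absent for read '", qname[i],
           "'; supply `reference` to recover mismatches", call. = FALSE)
    }
  }

  aln <- tibble::tibble(
    read_id = qname, reference_name = rname, start = pos0, strand = strand,
    aligned_length = alen,
    n_mismatch = vapply(mm_list, nrow, integer(1)),
    mapped = TRUE)
  mm <- dplyr::bind_rows(purrr::map2(
    mm_list, seq_len(n),
    function(m, i) if (nrow(m)) dplyr::mutate(m, read_id = qname[i],
                                              reference_name = rname[i]) else NULL))
  if (is.null(mm) || !nrow(mm)) {
    mm <- tibble::tibble(read_id = character(), reference_name = character(),
                         pos = integer(), base = character())
  } else {
    mm <- mm[, c("read_id", "reference_name", "pos", "base")]
  }
  structure(list(alignments = aln, mismatches = mm, reference = ref,
                 k = NA_integer_, max_mismatch_fraction = NA_real_),
            class = "read_alignments")
}

cigar_ops <- function(cigar) {
  m <- gregexpr("[0-9]+[MIDNSHP=X]", cigar)[[1]]
  toks <- regmatches(cigar, list(m))[[1]]
  list(len = as.integer(sub("[A-Z=]$", "", toks)),
       op = sub("^[0-9]+", "", toks))
}

# matched blocks: (ref offset, read offset, length) for M/=/X runs
cigar_blocks <- function(ops) {
  refoff <- 0L; readoff <- 0L
  out <- list()
  for (i in seq_along(ops$op)) {
    op <- ops$op[i]; len <- ops$len[i]
    if (op %in% c("M", "=", "X")) {
      out[[length(out) + 1L]] <- c(refoff, readoff, len)
      refoff <- refoff + len; readoff <- readoff + len
    } else if (op %in% c("D", "N")) {
      refoff <- refoff + len
    } else if (op %in% c("I", "S")) {
      readoff <- readoff + len
    }
  }
  do.call(rbind, out)
}

# read offset (1-based) aligned to a given ref offset (0-based), or NA
block_read_pos <- function(blocks, ref_off) {
  for (i in seq_len(nrow(blocks))) {
    b <- blocks[i, ]
    if (ref_off >= b[1] && ref_off < b[1] + b[3]) {
      return(b[2] + (ref_off - b[1]) + 1L)
    }
  }
  NA_integer_
}

md_mismatches <- function(md, blocks, start0, seq) {
  toks <- regmatches(md, gregexpr("[0-9]+|\\^[A-Z]+|[A-Z]", md))[[1]]
  ref_off <- 0L
  out <- list()
  for (t in toks) {
    if (grepl("^[0-9]+$", t)) {
      ref_off <- ref_off + as.integer(t)
    } else if (startsWith(t, "^")) {
      ref_off <- ref_off + nchar(t) - 1L
    } else {
      rp <- block_read_pos(blocks, ref_off)
      base <- if (is.na(rp)) "N" else substr(seq, rp, rp)
      out[[length(out) + 1L]] <- tibble::tibble(
        pos = start0 + ref_off, base = toupper(base))
      ref_off <- ref_off + 1L
    }
  }
  if (length(out)) dplyr::bind_rows(out) else {
    tibble::tibble(pos = integer(), base = character())
  }
}

seq_mismatches <- function(blocks, start0, seq, refseq) {
  out <- list()
  for (i in seq_len(nrow(blocks))) {
    b <- blocks[i, ]
    rd <- toupper(substr(seq, b[2] + 1L, b[2] + b[3]))
    rf <- toupper(substr(refseq, start0 + b[1] + 1L, start0 + b[1] + b[3]))
    rdc <- seq_chars(rd); rfc <- seq_chars(rf)
    bad <- which(rdc != rfc)
    if (length(bad)) {
      out[[length(out) + 1L]] <- tibble::tibble(
        pos = start0 + b[1] + bad - 1L, base = rdc[bad])
    }
  }
  if (length(out)) dplyr::bind_rows(out) else {
    tibble::tibble(pos = integer(), base = character())
  }
}

#' Expand operon regions by a symmetric buffer
#'
#' Returns the interval spanning the requested regions extended by `buffer`
#' bp on each side and clipped to the reference bounds — the protocol used to
#' map reads back to the ITS with flanking context so reads straddling the
#' region boundaries are retained.
#'
#' @inheritParams region_interval
#' @param buffer Buffer in bp on each side (e.g. 600).
#' @param reference_length Length used for clipping; defaults to the
#'   annotation's total span.
#' @return Named integer `c(start, end)`, 0-based half-open.
#' @examples
#' ann <- tibble::tibble(region = c("18S", "ITS", "28S"),
#'                       start = c(0, 1800, 2360), end = c(1800, 2360, 11000))
#' extract_region_with_buffer(ann, "ITS", 600) # [1200, 2960)
#' @export
extract_region_with_buffer <- function(annotation, regions, buffer,
                                       reference_length = NULL) {
  ann <- if (inherits(annotation, "operon_template")) annotation$annotation else annotation
  iv <- region_interval(ann, regions)
  if (buffer < 0) stop("buffer must be non-negative", call. = FALSE)
  reflen <- reference_length %||% max(ann$end)
  c(start = max(0L, as.integer(iv["start"] - buffer)),
    end = min(as.integer(reflen), as.integer(iv["end"] + buffer)))
}
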