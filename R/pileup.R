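# Per-position pileups, depths and consensus calling.

#' Build a per-position pileup from alignments
#'
#' Produces one row per reference position with the depth, per-base counts
#' and majority-rule consensus (ties broken in A < C < G < T < N order).
#' Non-mismatching read bases are attributed to the reference base, so the
#' base counts always sum to the depth.
#'
#' @param alignments A `read_alignments` object.
#' @param reference Reference sequences; defaults to those stored in
#'   `alignments`.
#' @return A tibble of class `pileup_tbl` with columns `reference_name`,
#'   `pos` (0-based), `depth`, `A`, `C`, `G`, `T`, `N` and `consensus`
#'   (`NA` where depth is 0).
#' @export
build_pileup <- function(alignments, reference = NULL) {
  stopifnot(inherits(alignments, "read_alignments"))
  ref <- if (!is.null(reference)) as_named_seqs(reference, "reference") else alignments$reference
  if (is.null(ref)) stop("reference sequences are required for a pileup", call. = FALSE)

  aln <- dplyr::filter(alignments$alignments, .data$mapped)
  mm <- alignments$mismatches
  out <- vector("list", length(ref))
  for (ri in seq_along(ref)) {
    rn <- names(ref)[ri]
    L <- nchar(ref[[ri]])
    a <- aln[aln$reference_name == rn, , drop = FALSE]

    depth <- integer(L)
    if (nrow(a)) {
      s <- a$start + 1L
      e <- pmin(a$start + a$aligned_length, L) + 1L
      delta <- tabulate(s, nbins = L + 1L) - tabulate(e, nbins = L + 1L)
      depth <- as.integer(cumsum(delta[seq_len(L)]))
    }

    counts <- matrix(0L, nrow = L, ncol = 5L,
                     dimnames = list(NULL, BASE_COLS))
    m <- mm[mm$reference_name == rn, , drop = FALSE]
    mm_tot <- integer(L)
    if (nrow(m)) {
      tab <- dplyr::count(m, .data$pos, .data$base)
      bi <- match(tab$base, BASE_COLS)
      bi[is.na(bi)] <- 5L
      counts[cbind(tab$pos + 1L, bi)] <- counts[cbind(tab$pos + 1L, bi)] + tab$n
      tot <- dplyr::count(m, .data$pos)
      mm_tot[tot$pos + 1L] <- tot$n
    }
    refidx <- match(seq_chars(toupper(ref[[ri]])), BASE_COLS)
    refidx[is.na(refidx)] <- 5L
    counts[cbind(seq_len(L), refidx)] <-
      counts[cbind(seq_len(L), refidx)] + (depth - mm_tot)

    cons <- BASE_COLS[max.col(counts, ties.method = "first")]
    cons[depth == 0L] <- NA_character_
    out[[ri]] <- tibble::tibble(
      reference_name = rn, pos = seq_len(L) - 1L, depth = depth,
      A = counts[, 1], C = counts[, 2], G = counts[, 3], T = counts[, 4],
      N = counts[, 5], consensus = cons)
  }
  pu <- dplyr::bind_rows(out)
  class(pu) <- c("pileup_tbl", class(pu))
  pu
}

pileup_subset <- function(pileup, interval = NULL, reference = NULL) {
  refs <- unique(pileup$reference_name)
  if (is.null(reference)) {
    if (length(refs) > 1L && !is.null(interval)) {
      stop("pileup covers several references; supply `reference`", call. = FALSE)
    }
    reference <- refs
  }
  pu <- pileup[pileup$reference_name %in% reference, , drop = FALSE]
  if (!is.null(interval)) {
    iv <- as_interval(interval)
    pu <- pu[pu$pos >= iv["start"] & pu$pos < iv["end"], , drop = FALSE]
    if (!nrow(pu)) stop("interval covers no pileup positions", call. = FALSE)
  }
  pu
}

#' Mean read depth over an interval
#'
#' Arithmetic mean of per-position depth, zero-depth positions included.
#'
#' @param pileup A pileup tibble from [build_pileup()].
#' @param interval Optional 0-based half-open `c(start, end)`; default spans
#'   the whole reference.
#' @param reference Reference name when the pileup covers several.
#' @return One-row tibble with `mean_depth` and `positions_used`.
#' @export
mean_depth <- function(pileup, interval = NULL, reference = NULL) {
  pu <- pileup_subset(pileup, interval, reference)
  tibble::tibble(mean_depth = mean(pu$depth), positions_used = nrow(pu))
}

#' Consensus sequence(s) from a pileup
#'
#' Per-position majority bases; zero-depth positions emit `N`.
#'
#' @param pileup A pileup tibble.
#' @return Named character vector, one sequence per reference.
#' @export
consensus_sequence <- function(pileup) {
  if (!nrow(pileup)) stop("pileup is empty", call. = FALSE)
  sp <- split(pileup, pileup$reference_name)
  out <- vapply(sp, function(p) {
    chars_to_seq(dplyr::coalesce(p$consensus[order(p$pos)], "N"))
  }, character(1))
  out[unique(pileup$reference_name)]
}

#' Write a pileup as TSV
#' @param pileup A pileup tibble.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_pileup_tsv <- function(pileup, path) {
  readr::write_tsv(as.data.frame(pileup), path)
  invisible(path)
}

#' Read a pileup written by [write_pileup_tsv()]
#' @param path TSV file.
#' @return A pileup tibble.
#' @export
read_pileup_tsv <- function(path) {
  pu <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          reference_name = "c", consensus = "c",
                          .default = "i"))
  pu <- tibble::as_tibble(pu)
  class(pu) <- c("pileup_tbl", class(pu))
  pu
}
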