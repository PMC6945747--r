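# Intragenomic per-site variance, variance bins, and the comparison of
# polymorphic sites against species-diagnostic barcode positions.

VARIANCE_BINS <- c("none", "<1%_nonzero", "1-9%", ">10%")

#' Per-site variance from base counts
#'
#' The fraction of reads at a site that differ from the consensus base:
#' `(depth - max base count) / depth`. Undefined (an error) at depth 0.
#'
#' @param counts Named numeric vector of base counts (e.g.
#'   `c(A = 90, G = 10)`).
#' @return A fraction in `[0, 1 - 1/depth]`.
#' @examples
#' site_variance(c(A = 90, G = 10)) # 0.10
#' @export
site_variance <- function(counts) {
  depth <- sum(counts)
  if (depth <= 0) stop("depth is zero: site variance is undefined", call. = FALSE)
  (depth - max(counts)) / depth
}

#' Classify variance values into the four reporting bins
#'
#' Bins: `"none"` (exactly 0), `"<1%_nonzero"` (0, 0.01), `"1-9%"`
#' (`[0.01, 0.10]`; the upper bound is closed so the partition is
#' exhaustive) and `">10%"` ((0.10, 1]). `NA` (uncovered sites) stays `NA`.
#'
#' @param variance Numeric vector of variance fractions.
#' @return Factor with levels `none`, `<1%_nonzero`, `1-9%`, `>10%`.
#' @export
classify_variance <- function(variance) {
  bin <- dplyr::case_when(
    is.na(variance) ~ NA_character_,
    variance == 0 ~ "none",
    variance < 0.01 ~ "<1%_nonzero",
    variance <= 0.10 ~ "1-9%",
    TRUE ~ ">10%")
  factor(bin, levels = VARIANCE_BINS)
}

#' Per-position variance profile over a pileup interval
#'
#' @inheritParams mean_depth
#' @return A tibble of class `variance_profile` with `reference_name`, `pos`
#'   (0-based), `depth`, `variance` (`NA` at depth 0) and `bin`.
#' @export
variance_profile <- function(pileup, interval = NULL, reference = NULL) {
  pu <- pileup_subset(pileup, interval, reference)
  cnt <- as.matrix(pu[, BASE_COLS])
  variance <- ifelse(pu$depth > 0,
                     (pu$depth - apply(cnt, 1L, max)) / pu$depth,
                     NA_real_)
  out <- tibble::tibble(reference_name = pu$reference_name, pos = pu$pos,
                        depth = pu$depth, variance = variance,
                        bin = classify_variance(variance))
  class(out) <- c("variance_profile", class(out))
  out
}

#' Count covered sites per variance bin
#'
#' @param profile A `variance_profile`.
#' @return Tibble with `bin` and `n` over covered positions.
#' @export
bin_summary <- function(profile) {
  covered <- profile[!is.na(profile$variance), , drop = FALSE]
  tab <- table(factor(covered$bin, levels = VARIANCE_BINS))
  tibble::tibble(bin = factor(VARIANCE_BINS, levels = VARIANCE_BINS),
                 n = as.integer(tab))
}

#' Write a variance profile as TSV
#' @param profile A `variance_profile`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_variance_tsv <- function(profile, path) {
  readr::write_tsv(as.data.frame(profile), path)
  invisible(path)
}

msa_matrix <- function(msa) {
  msa <- as_named_seqs(msa, "msa")
  if (length(unique(nchar(msa))) != 1L) {
    stop("alignment is ragged: sequences differ in length", call. = FALSE)
  }
  mat <- do.call(rbind, strsplit(toupper(msa), "", fixed = TRUE))
  rownames(mat) <- names(msa)
  mat
}

norm_species <- function(species, taxa) {
  if (is.data.frame(species)) {
    species <- setNames(species$species, species$taxon)
  }
  miss <- setdiff(taxa, names(species))
  if (length(miss)) {
    stop("no species label for taxa: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  species[taxa]
}

#' Identify species-diagnostic alignment columns
#'
#' A column is *fixed* for a species when every member carries the same
#' unambiguous base (any gap or N makes the species non-fixed there). A
#' column is diagnostic for a species pair when both species are fixed for
#' different bases; the column-level `diagnostic` flag requires fixation in
#' every species plus segregation between at least two of them.
#'
#' @param msa Equal-length aligned sequences (named character,
#'   `DNAStringSet`, or FASTA path). Columns are indexed 0-based.
#' @param species Species labels: a named vector `taxon -> species` or a
#'   tibble with columns `taxon` and `species`. At least two species.
#' @return An object of class `diagnostic_sites`: `sites` (tibble `column`,
#'   `segregating`, `fixed_all_species`, `diagnostic`) and `pairs` (tibble of
#'   diagnostic columns per species pair with the fixed bases).
#' @export
diagnostic_sites <- function(msa, species) {
  mat <- msa_matrix(msa)
  sp <- norm_species(species, rownames(mat))
  levels <- unique(sp)
  if (length(levels) < 2L) stop("need >= 2 species", call. = FALSE)
  L <- ncol(mat)

  fixed <- matrix(NA_character_, nrow = length(levels), ncol = L,
                  dimnames = list(levels, NULL))
  for (s in levels) {
    sub <- mat[sp == s, , drop = FALSE]
    first <- sub[1L, ]
    same <- colSums(sub != matrix(first, nrow(sub), L, byrow = TRUE)) == 0L
    clean <- colSums(matrix(!(sub %in% DNA_BASES4), nrow(sub), L)) == 0L
    fx <- ifelse(same & clean, first, NA_character_)
    fixed[s, ] <- fx
  }
  n_fixed <- colSums(!is.na(fixed))
  n_distinct <- apply(fixed, 2L, function(col) length(unique(col[!is.na(col)])))
  sites <- tibble::tibble(
    column = seq_len(L) - 1L,
    segregating = n_fixed >= 2L & n_distinct >= 2L,
    fixed_all_species = n_fixed == length(levels),
    diagnostic = n_fixed == length(levels) & n_distinct >= 2L)

  pairs <- list()
  cmb <- utils::combn(levels, 2L)
  for (j in seq_len(ncol(cmb))) {
    a <- cmb[1L, j]; b <- cmb[2L, j]
    hit <- which(!is.na(fixed[a, ]) & !is.na(fixed[b, ]) &
                   fixed[a, ] != fixed[b, ])
    if (length(hit)) {
      pairs[[length(pairs) + 1L]] <- tibble::tibble(
        column = hit - 1L, species_a = a, species_b = b,
        base_a = unname(fixed[a, hit]), base_b = unname(fixed[b, hit]))
    }
  }
  pairs <- if (length(pairs)) dplyr::bind_rows(pairs) else {
    tibble::tibble(column = integer(), species_a = character(),
                   species_b = character(), base_a = character(),
                   base_b = character())
  }
  structure(list(sites = sites, pairs = pairs, species = levels,
                 n_taxa = nrow(mat)), class = "diagnostic_sites")
}

#' @export
print.diagnostic_sites <- function(x, ...) {
  cat("<diagnostic_sites>", sum(x$sites$diagnostic), "diagnostic /",
      nrow(x$sites), "columns across", length(x$species), "species\n")
  invisible(x)
}

#' @export
tidy.diagnostic_sites <- function(x, ...) x$sites

#' @export
glance.diagnostic_sites <- function(x, ...) {
  tibble::tibble(n_columns = nrow(x$sites),
                 n_diagnostic = sum(x$sites$diagnostic),
                 n_segregating = sum(x$sites$segregating),
                 n_species = length(x$species), n_taxa = x$n_taxa)
}

#' Cross-tabulate polymorphic pileup sites against diagnostic columns
#'
#' Classifies every covered pileup position as polymorphic (variance above
#' `threshold`) or not and as falling on a diagnostic alignment column or
#' not, yielding the 2x2 overlap table used to ask whether intragenomic
#' variation coincides with the sites that separate species.
#'
#' @param profile A `variance_profile`.
#' @param diagnostics A `diagnostic_sites` object.
#' @param coordinate_map Optional tibble `position`, `column` mapping pileup
#'   positions (0-based) to alignment columns (0-based). Identity by default.
#'   Positions without a mapping are skipped with a warning.
#' @param threshold Variance above which a site counts as polymorphic
#'   (default 0.01, the floor of the 1-9% bin).
#' @return An object of class `overlap_report`: `table` (tibble
#'   `polymorphic`, `diagnostic`, `n`), `sites` (per-position detail) and
#'   `n_unmapped`.
#' @export
overlap_report <- function(profile, diagnostics, coordinate_map = NULL,
                           threshold = 0.01) {
  stopifnot(inherits(diagnostics, "diagnostic_sites"))
  covered <- profile[!is.na(profile$variance), , drop = FALSE]
  if (is.null(coordinate_map)) {
    col <- covered$pos
  } else {
    col <- coordinate_map$column[match(covered$pos, coordinate_map$position)]
  }
  known <- !is.na(col) & col %in% diagnostics$sites$column
  n_unmapped <- sum(!known)
  if (n_unmapped > 0L) {
    warning(n_unmapped, " pileup position(s) had no alignment column and were skipped",
            call. = FALSE)
  }
  covered <- covered[known, , drop = FALSE]
  col <- col[known]

  diag_cols <- diagnostics$sites$column[diagnostics$sites$diagnostic]
  sites <- tibble::tibble(
    position = covered$pos, column = col, variance = covered$variance,
    polymorphic = covered$variance > threshold,
    diagnostic = col %in% diag_cols)
  tab <- tidyr::complete(
    dplyr::count(sites, .data$polymorphic, .data$diagnostic),
    polymorphic = c(FALSE, TRUE), diagnostic = c(FALSE, TRUE),
    fill = list(n = 0L))
  structure(list(table = tab, sites = sites, threshold = threshold,
                 n_unmapped = n_unmapped), class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("<overlap_report> threshold", x$threshold, "\n")
  print(x$table)
  invisible(x)
}

#' @export
tidy.overlap_report <- function(x, ...) x$table

#' @export
glance.overlap_report <- function(x, ...) {
  n <- function(p, d) x$table$n[x$table$polymorphic == p & x$table$diagnostic == d]
  tibble::tibble(n_polymorphic = sum(x$sites$polymorphic),
                 n_diagnostic = sum(x$sites$diagnostic),
                 n_overlap = n(TRUE, TRUE), n_unmapped = x$n_unmapped,
                 threshold = x$threshold)
}
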