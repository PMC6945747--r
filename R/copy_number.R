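# Copy-number estimation from nrDNA / single-copy depth ratios.

#' Estimate nrDNA operon copy number from depth ratios
#'
#' For each single-copy locus, the ratio of the nrDNA mean depth to the
#' locus mean depth approximates the number of tandem operon copies; the
#' estimate is the mean of the per-locus ratios and its SD is the sample
#' standard deviation across loci (n - 1 denominator).
#'
#' @param pileup A pileup tibble covering the nrDNA reference and the
#'   single-copy loci.
#' @param nrdna Reference name of the (single-copy) operon reference.
#' @param loci Character vector of single-copy reference names.
#' @param nrdna_interval Optional interval over which nrDNA depth is
#'   averaged (0-based half-open); whole reference by default.
#' @param locus_intervals Optional named list of intervals per locus.
#' @param exclude Optional interval or list of intervals masked out of the
#'   nrDNA average (e.g. an ambiguous 5' IGS repeat segment).
#' @return An object of class `copy_number_estimate` with per-locus ratios,
#'   the mean and SD, and the nrDNA mean depth. Loci with zero depth are
#'   excluded and reported; if the nrDNA depth is zero the estimate is 0
#'   with a warning.
#' @examples
#' \dontrun{
#' est <- estimate_copy_number(pu, nrdna = "operon",
#'                             loci = c("mcm7", "rpb1", "rpb2", "chrom_1"))
#' glance(est)
#' }
#' @export
estimate_copy_number <- function(pileup, nrdna, loci, nrdna_interval = NULL,
                                 locus_intervals = NULL, exclude = NULL) {
  if (!nrdna %in% pileup$reference_name) {
    stop("nrDNA reference '", nrdna, "' not in pileup", call. = FALSE)
  }
  missing_loci <- setdiff(loci, pileup$reference_name)
  if (length(missing_loci)) {
    stop("loci not in pileup: ", paste(missing_loci, collapse = ", "), call. = FALSE)
  }

  nr <- pileup_subset(pileup, nrdna_interval, nrdna)
  if (!is.null(exclude)) {
    if (!is.list(exclude)) exclude <- list(exclude)
    for (iv in exclude) {
      iv <- as_interval(iv, "exclude")
      nr <- nr[!(nr$pos >= iv["start"] & nr$pos < iv["end"]), , drop = FALSE]
    }
    if (!nrow(nr)) stop("exclusion mask removed every nrDNA position", call. = FALSE)
  }
  nr_mean <- mean(nr$depth)

  locus_mean <- vapply(loci, function(lc) {
    iv <- if (!is.null(locus_intervals)) locus_intervals[[lc]] else NULL
    mean(pileup_subset(pileup, iv, lc)$depth)
  }, numeric(1))

  used <- locus_mean > 0
  if (!any(used)) stop("all single-copy loci have zero depth", call. = FALSE)
  if (nr_mean == 0) {
    warning("nrDNA reference has zero depth; copy number estimated as 0",
            call. = FALSE)
  }
  ratios <- ifelse(used, nr_mean / locus_mean, NA_real_)

  per_locus <- tibble::tibble(locus = loci, mean_depth = unname(locus_mean),
                              ratio = unname(ratios), used = unname(used))
  structure(list(
    per_locus = per_locus,
    nrdna_mean_depth = nr_mean,
    nrdna_positions = nrow(nr),
    mean_copy_number = mean(ratios[used]),
    sd_copy_number = stats::sd(ratios[used]),
    loci_used = loci[used], loci_excluded = loci[!used]),
    class = "copy_number_estimate")
}

#' @export
print.copy_number_estimate <- function(x, ...) {
  cat(sprintf("<copy_number_estimate> %.1f (SD = %.1f) from %d locus ratio(s); nrDNA depth %.1fx\n",
              x$mean_copy_number, x$sd_copy_number, length(x$loci_used),
              x$nrdna_mean_depth))
  invisible(x)
}

#' @export
tidy.copy_number_estimate <- function(x, ...) x$per_locus

#' @export
glance.copy_number_estimate <- function(x, ...) {
  tibble::tibble(mean_copy_number = x$mean_copy_number,
                 sd_copy_number = x$sd_copy_number,
                 nrdna_mean_depth = x$nrdna_mean_depth,
                 n_loci = length(x$loci_used))
}

#' Run the full copy-number pipeline on one simulated genome
#'
#' Builds a genome from the template and config, simulates paired reads,
#' maps all reads jointly against a single operon reference copy plus the
#' single-copy contigs (so reads from every tandem copy collapse onto one
#' reference, which is what makes depth proportional to copy number), builds
#' the pileup, and estimates copy number.
#'
#' @param template An `operon_template`.
#' @param cfg A `simulation_config`.
#' @param read_seed Seed for the read-sampling stage; defaults to
#'   `cfg$seed`.
#' @param k,max_mismatch_fraction Mapper settings, see [map_reads()].
#' @return List with `estimate` (a `copy_number_estimate`), `pileup`,
#'   `truth` and `config`.
#' @export
run_copy_number_sim <- function(template, cfg, read_seed = NULL, k = 21L,
                                max_mismatch_fraction = 0.1) {
  g <- build_genome(template, cfg)
  rs <- simulate_paired_reads(g$genome, cfg, seed = read_seed %||% cfg$seed,
                              truth = g$truth)
  single_copy <- setdiff(names(g$genome), c("rdna_tandem", "contaminant"))
  ref <- c(operon = template$sequence, g$genome[single_copy])
  aln <- map_reads(rs, ref, k = k,
                   max_mismatch_fraction = max_mismatch_fraction)
  pu <- build_pileup(aln)
  est <- estimate_copy_number(pu, nrdna = "operon", loci = single_copy)
  list(estimate = est, pileup = pu, truth = rs$truth, config = cfg)
}

#' Sweep copy-number recovery across configurations
#'
#' @param template An `operon_template`.
#' @param cfgs List of `simulation_config` objects.
#' @param ... Passed to [run_copy_number_sim()].
#' @return Tibble with one row per config: `true_copy_number`, `estimate`,
#'   `sd`, `relative_error`, `nrdna_mean_depth`.
#' @export
copy_number_sweep <- function(template, cfgs, ...) {
  if (inherits(cfgs, "simulation_config")) cfgs <- list(cfgs)
  rows <- purrr::map(cfgs, function(cfg) {
    res <- run_copy_number_sim(template, cfg, ...)
    est <- res$estimate
    tibble::tibble(
      true_copy_number = cfg$copy_number,
      estimate = est$mean_copy_number,
      sd = est$sd_copy_number,
      relative_error = abs(est$mean_copy_number - cfg$copy_number) /
        cfg$copy_number,
      nrdna_mean_depth = est$nrdna_mean_depth)
  })
  dplyr::bind_rows(rows)
}
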