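# Tandem-repeat genome and paired-end read simulator with full ground truth.

#' Simulation configuration
#'
#' Bundles and validates all simulator parameters. Defaults emulate the
#' HiSeq-style sequencing design the package is built around: 100-bp
#' paired-end reads with a 350-bp insert, a 0.1% per-base substitution error
#' rate, and 50-fold target depth on single-copy sequence.
#'
#' @param copy_number Number of tandem operon copies in the simulated genome.
#' @param per_copy_variant_rate Per-site probability that a copy carries a
#'   private random substitution relative to the template.
#' @param intragenomic_variants Optional data frame of planted intragenomic
#'   variants with columns `position` (0-based template coordinate),
#'   `fraction` (fraction of copies carrying the variant; realized as
#'   `round(fraction * copy_number)` copies drawn without replacement) and
#'   optionally `base` (alternate base; chosen automatically if `NA`).
#' @param read_length,insert_mean,insert_sd Read and fragment geometry in bp.
#' @param error_rate Per-base substitution error probability in reads.
#' @param coverage_target Expected fold depth on single-copy sequence.
#' @param contaminant_fraction Fraction of read pairs drawn from an unrelated
#'   contaminant contig (a photobiont-like bystander genome).
#' @param chrom_length Length of the large single-copy contig (bp).
#' @param locus_lengths Named lengths of the short single-copy gene contigs
#'   (stand-ins for MCM7, RPB1 and RPB2).
#' @param contaminant_length Length of the contaminant contig (bp).
#' @param seed Integer seed controlling every random choice downstream.
#'
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(copy_number = 20L,
                              per_copy_variant_rate = 0,
                              intragenomic_variants = NULL,
                              read_length = 100L,
                              insert_mean = 350L,
                              insert_sd = 35,
                              error_rate = 0.001,
                              coverage_target = 50,
                              contaminant_fraction = 0,
                              chrom_length = 50000L,
                              locus_lengths = c(mcm7 = 2000L, rpb1 = 2500L,
                                                rpb2 = 2500L),
                              contaminant_length = 10000L,
                              seed = 1L) {
  copy_number <- as.integer(copy_number)
  if (is.na(copy_number) || copy_number < 1L) {
    stop("copy_number must be a positive integer", call. = FALSE)
  }
  if (error_rate < 0 || error_rate >= 1) stop("error_rate must be in [0, 1)", call. = FALSE)
  if (contaminant_fraction < 0 || contaminant_fraction >= 1) {
    stop("contaminant_fraction must be in [0, 1)", call. = FALSE)
  }
  if (per_copy_variant_rate < 0 || per_copy_variant_rate >= 1) {
    stop("per_copy_variant_rate must be in [0, 1)", call. = FALSE)
  }
  if (insert_mean < read_length) stop("insert_mean must be >= read_length", call. = FALSE)
  if (is.null(names(locus_lengths)) || any(!nzchar(names(locus_lengths)))) {
    stop("locus_lengths must be named", call. = FALSE)
  }
  iv <- intragenomic_variants
  if (!is.null(iv)) {
    iv <- tibble::as_tibble(iv)
    if (!all(c("position", "fraction") %in% names(iv))) {
      stop("intragenomic_variants needs columns position, fraction", call. = FALSE)
    }
    if (!"base" %in% names(iv)) iv$base <- NA_character_
    if (any(iv$fraction <= 0 | iv$fraction > 1)) {
      stop("variant fractions must be in (0, 1]", call. = FALSE)
    }
  }
  structure(list(
    copy_number = copy_number,
    per_copy_variant_rate = per_copy_variant_rate,
    intragenomic_variants = iv,
    read_length = as.integer(read_length),
    insert_mean = as.integer(insert_mean),
    insert_sd = insert_sd,
    error_rate = error_rate,
    coverage_target = coverage_target,
    contaminant_fraction = contaminant_fraction,
    chrom_length = as.integer(chrom_length),
    locus_lengths = setNames(as.integer(locus_lengths), names(locus_lengths)),
    contaminant_length = as.integer(contaminant_length),
    seed = as.integer(seed)), class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("<simulation_config> copy_number =", x$copy_number,
      "| reads", x$read_length, "bp /", x$insert_mean, "bp insert",
      "| error", x$error_rate, "| coverage", x$coverage_target, "x\n")
  invisible(x)
}

#' Build a tandem-repeat genome with ground truth
#'
#' Assembles a synthetic nuclear genome around an operon template: one contig
#' (`rdna_tandem`) carrying `copy_number` tandem copies of the template, each
#' independently mutated at `per_copy_variant_rate` and additionally carrying
#' any planted intragenomic variants; three short single-copy gene contigs;
#' one large single-copy contig (`chrom_1`); and, when
#' `contaminant_fraction > 0`, an unrelated contaminant contig. Every planted
#' difference is recorded in the returned truth record.
#'
#' @param template An `operon_template`.
#' @param cfg A `simulation_config`.
#' @return A list with `genome` (named character vector of contigs) and
#'   `truth` (class `truth_record`: `true_copy_number`, `copy_variants`
#'   tibble with 0-based copy indices and template positions, and
#'   `intron_states`).
#' @export
build_genome <- function(template, cfg) {
  stopifnot(inherits(template, "operon_template"),
            inherits(cfg, "simulation_config"))
  tpl_chars <- seq_chars(template$sequence)
  L <- length(tpl_chars)
  cn <- cfg$copy_number

  withr::with_seed(cfg$seed, {
    loci <- vapply(cfg$locus_lengths, random_dna, character(1))
    chrom <- random_dna(cfg$chrom_length)
    contaminant <- if (cfg$contaminant_fraction > 0) {
      random_dna(cfg$contaminant_length)
    } else NULL

    # planted intragenomic variants: carriers drawn without replacement
    planted <- cfg$intragenomic_variants
    planted_rows <- list()
    if (!is.null(planted) && nrow(planted)) {
      for (i in seq_len(nrow(planted))) {
        p0 <- as.integer(planted$position[i])
        if (p0 < 0L || p0 >= L) stop("planted variant position out of range", call. = FALSE)
        ref <- tpl_chars[p0 + 1L]
        alt <- planted$base[i]
        if (is.na(alt)) alt <- other_base(ref)
        if (identical(alt, ref)) {
          stop("planted variant at position ", p0,
               " matches the reference base", call. = FALSE)
        }
        ncarry <- round(planted$fraction[i] * cn)
        if (ncarry < 1L) next
        carriers <- sample.int(cn, ncarry)
        planted_rows[[length(planted_rows) + 1L]] <- tibble::tibble(
          copy = carriers - 1L, position = p0, ref_base = ref,
          alt_base = alt, planted = TRUE)
      }
    }
    planted_tbl <- if (length(planted_rows)) dplyr::bind_rows(planted_rows) else NULL
    planted_pos <- unique(planted_tbl$position)

    pool <- setdiff(seq_len(L), planted_pos + 1L)
    copies <- character(cn)
    var_rows <- vector("list", cn)
    for (ci in seq_len(cn)) {
      chars <- tpl_chars
      k <- rbinom(1L, length(pool), cfg$per_copy_variant_rate)
      if (k > 0L) {
        at <- sort(sample(pool, k))
        alt <- other_base(chars[at])
        var_rows[[ci]] <- tibble::tibble(
          copy = ci - 1L, position = at - 1L, ref_base = chars[at],
          alt_base = alt, planted = FALSE)
        chars[at] <- alt
      }
      if (!is.null(planted_tbl)) {
        mine <- planted_tbl[planted_tbl$copy == ci - 1L, , drop = FALSE]
        if (nrow(mine)) chars[mine$position + 1L] <- mine$alt_base
      }
      copies[ci] <- chars_to_seq(chars)
    }
  })

  copy_variants <- dplyr::bind_rows(c(var_rows, list(planted_tbl)))
  if (nrow(copy_variants)) {
    copy_variants <- dplyr::arrange(copy_variants, .data$copy, .data$position)
  }

  genome <- c(list(rdna_tandem = paste(copies, collapse = "")),
              as.list(loci), list(chrom_1 = chrom))
  if (!is.null(contaminant)) genome$contaminant <- contaminant
  genome <- unlist(genome)

  intron_states <- if (nrow(template$introns)) {
    tidyr::expand_grid(copy = seq_len(cn) - 1L, label = template$introns$label) |>
      dplyr::mutate(present = TRUE)
  } else {
    tibble::tibble(copy = integer(), label = character(), present = logical())
  }

  truth <- structure(list(
    true_copy_number = cn, template_length = L,
    copy_variants = copy_variants, intron_states = intron_states,
    read_origins = NULL), class = "truth_record")
  list(genome = genome, truth = truth)
}

#' Simulate Illumina-style paired-end reads
#'
#' Draws fragments uniformly along each contig, weighting contigs by length
#' so the tandem-repeat contig receives proportionally more pairs; the number
#' of pairs is chosen so the expected depth on single-copy sequence matches
#' `coverage_target`. Mate 2 is reverse-complemented. Substitution errors are
#' i.i.d. at `error_rate`. Output is byte-deterministic given the seed.
#'
#' @param genome Named character vector of contigs (from [build_genome()]).
#' @param cfg A `simulation_config`.
#' @param seed Seed for read sampling; defaults to `cfg$seed`. Pass distinct
#'   seeds to draw replicate read sets from the same genome.
#' @param truth Optional `truth_record` to be augmented with read origins.
#' @return A list of class `read_set`: `reads` (tibble `id`, `read1`,
#'   `read2`), `origins` (tibble `read_id`, `contig`, `start`, `strand`,
#'   `is_contaminant`; 0-based starts) and, when supplied, the updated
#'   `truth`.
#' @export
simulate_paired_reads <- function(genome, cfg, seed = cfg$seed, truth = NULL) {
  stopifnot(inherits(cfg, "simulation_config"))
  genome <- as_named_seqs(genome, "genome")
  rl <- cfg$read_length
  lens <- nchar(genome)
  genomic <- setdiff(names(genome), "contaminant")

  short <- genomic[lens[genomic] < cfg$insert_mean]
  if (length(short)) {
    warning("skipping contig(s) shorter than the mean insert: ",
            paste(short, collapse = ", "), call. = FALSE)
    genomic <- setdiff(genomic, short)
  }
  if (!length(genomic)) stop("no contig is long enough to sequence", call. = FALSE)

  G <- sum(lens[genomic])
  n_pairs <- max(1L, as.integer(round(cfg$coverage_target * G / (2 * rl))))
  cf <- cfg$contaminant_fraction
  n_cont <- 0L
  if (cf > 0) {
    if (!"contaminant" %in% names(genome)) {
      stop("contaminant_fraction > 0 but genome has no contaminant contig",
           call. = FALSE)
    }
    n_cont <- as.integer(round(n_pairs * cf / (1 - cf)))
  }

  withr::with_seed(as.integer(seed), {
    ctg <- c(sample(genomic, n_pairs, replace = TRUE,
                    prob = lens[genomic]),
             rep("contaminant", n_cont))
    n <- length(ctg)
    clen <- lens[ctg]
    frag <- pmin(pmax(round(rnorm(n, cfg$insert_mean, cfg$insert_sd)), rl), clen)
    start <- floor(runif(n) * (clen - frag + 1))
    r1 <- substring(genome[ctg], start + 1L, start + rl)
    r2 <- revcomp(substring(genome[ctg], start + frag - rl + 1L, start + frag))

    if (cfg$error_rate > 0) {
      allreads <- c(r1, r2)
      total <- 2L * n * rl
      nerr <- rbinom(1L, total, cfg$error_rate)
      if (nerr > 0L) {
        gidx <- sample.int(total, nerr)
        ridx <- (gidx - 1L) %/% rl + 1L
        off <- (gidx - 1L) %% rl + 1L
        cur <- substr(allreads[ridx], off, off)
        alt <- other_base(cur)
        for (i in seq_len(nerr)) {
          substr(allreads[ridx[i]], off[i], off[i]) <- alt[i]
        }
        r1 <- allreads[seq_len(n)]
        r2 <- allreads[n + seq_len(n)]
      }
    }
  })

  pid <- sprintf("sim_%06d", seq_along(ctg))
  origins <- tibble::tibble(
    read_id = c(paste0(pid, "/1"), paste0(pid, "/2")),
    contig = rep(ctg, 2L),
    start = as.integer(c(start, start + frag - rl)),
    strand = rep(c("+", "-"), each = length(ctg)),
    is_contaminant = rep(ctg == "contaminant", 2L))

  if (!is.null(truth)) truth$read_origins <- origins
  structure(list(
    reads = tibble::tibble(id = pid, read1 = unname(r1), read2 = unname(r2)),
    origins = origins, read_length = rl, truth = truth),
    class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat("<read_set>", nrow(x$reads), "pairs of", x$read_length, "bp reads\n")
  invisible(x)
}

#' Write a read set as a paired FASTQ file pair
#'
#' Files are written as `<prefix>_1.fastq` and `<prefix>_2.fastq` with
#' Phred+33 qualities fixed at Q40 (base qualities are never used downstream).
#'
#' @param reads A `read_set`.
#' @param prefix Output path prefix.
#' @return Invisibly, the two file paths.
#' @export
write_paired_fastq <- function(reads, prefix) {
  stopifnot(inherits(reads, "read_set"))
  paths <- paste0(prefix, c("_1.fastq", "_2.fastq"))
  for (m in 1:2) {
    ss <- Biostrings::DNAStringSet(reads$reads[[paste0("read", m)]])
    names(ss) <- paste0(reads$reads$id, "/", m)
    qual <- Biostrings::BStringSet(strrep("I", Biostrings::width(ss)))
    Biostrings::writeXStringSet(ss, paths[m], format = "fastq", qualities = qual)
  }
  invisible(paths)
}

#' Write contigs as FASTA
#' @param genome Named character vector of sequences.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(as_named_seqs(genome, "genome"))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Serialize a truth record to JSON
#' @param truth A `truth_record`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "truth_record"))
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a truth record back from JSON
#' @param path JSON file written by [write_truth_json()].
#' @return A `truth_record`.
#' @export
read_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("copy_variants", "intron_states", "read_origins")) {
    if (!is.null(x[[f]])) x[[f]] <- tibble::as_tibble(x[[f]])
  }
  structure(x, class = "truth_record")
}

#' Read / write a simulation configuration as YAML
#' @param path YAML file.
#' @return For `read_sim_config`, a `simulation_config`.
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (!is.null(x$intragenomic_variants)) {
    x$intragenomic_variants <- dplyr::bind_rows(lapply(
      x$intragenomic_variants, tibble::as_tibble))
  }
  if (!is.null(x$locus_lengths)) x$locus_lengths <- unlist(x$locus_lengths)
  do.call(simulation_config, x)
}

#' @rdname read_sim_config
#' @param cfg A `simulation_config`.
#' @export
write_sim_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "simulation_config"))
  x <- unclass(cfg)
  if (!is.null(x$intragenomic_variants)) {
    x$intragenomic_variants <- purrr::transpose(as.list(x$intragenomic_variants))
  }
  x$locus_lengths <- as.list(x$locus_lengths)
  yaml::write_yaml(x, path)
  invisible(path)
}
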