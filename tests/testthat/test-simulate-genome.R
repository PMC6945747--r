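test_that("a single unmutated copy reproduces the template exactly", {
  tpl <- small_template()
  cfg <- quick_cfg(copy_number = 1, per_copy_variant_rate = 0, seed = 1)
  g <- build_genome(tpl, cfg)
  expect_identical(g$genome[["rdna_tandem"]], tpl$sequence)
  expect_equal(nrow(g$truth$copy_variants), 0)
  expect_equal(g$truth$true_copy_number, 1)
  expect_setequal(names(g$genome), c("rdna_tandem", "mcm7", "rpb1", "rpb2",
                                     "chrom_1"))
})

test_that("planted variant fractions are realized as rounded copy counts", {
  tpl <- std_template()
  cfg <- simulation_config(
    copy_number = 20, per_copy_variant_rate = 0,
    intragenomic_variants = tibble::tibble(position = 1900, fraction = 0.10,
                                           base = NA),
    seed = 5)
  g <- build_genome(tpl, cfg)
  cv <- g$truth$copy_variants
  expect_equal(nrow(cv), 2)            # 0.10 x 20 copies
  expect_true(all(cv$position == 1900))
  expect_true(all(cv$planted))
  expect_true(all(cv$copy >= 0 & cv$copy < 20))

  # the genome itself carries the variant in exactly those copies
  L <- nchar(tpl$sequence)
  carried <- vapply(0:19, function(ci) {
    substr(g$genome[["rdna_tandem"]], ci * L + 1901, ci * L + 1901)
  }, character(1))
  expect_equal(sum(carried != substr(tpl$sequence, 1901, 1901)), 2)
  expect_setequal(which(carried == cv$alt_base[1]) - 1L, cv$copy)
})

test_that("a planted variant equal to the reference base errors", {
  tpl <- small_template()
  ref <- substr(tpl$sequence, 101, 101)
  cfg <- quick_cfg(copy_number = 10,
                   intragenomic_variants = tibble::tibble(
                     position = 100, fraction = 0.5, base = ref),
                   seed = 1)
  expect_error(build_genome(tpl, cfg), "matches the reference")
})

test_that("truth record exactly reproduces the diffs of every tandem copy", {
  tpl <- small_template()
  cfg <- quick_cfg(copy_number = 20, per_copy_variant_rate = 0.001, seed = 9)
  g <- build_genome(tpl, cfg)
  L <- nchar(tpl$sequence)
  tchars <- strsplit(tpl$sequence, "")[[1]]
  recount <- list()
  for (ci in 0:19) {
    cchars <- strsplit(substr(g$genome[["rdna_tandem"]], ci * L + 1,
                              (ci + 1) * L), "")[[1]]
    at <- which(cchars != tchars)
    if (length(at)) {
      recount[[length(recount) + 1L]] <- tibble::tibble(
        copy = ci, position = at - 1L, ref_base = tchars[at],
        alt_base = cchars[at])
    }
  }
  recount <- dplyr::bind_rows(recount)
  truth <- dplyr::arrange(g$truth$copy_variants[, names(recount)],
                          copy, position)
  expect_equal(as.data.frame(recount), as.data.frame(truth))
  # planted-rate sanity: ~ 20 * L * 0.001 variants, within 4 binomial SDs
  expected <- 20 * L * 0.001
  expect_lt(abs(nrow(truth) - expected), 4 * sqrt(expected) + 1)
})

test_that("read simulation is byte-deterministic given the seed", {
  tpl <- small_template()
  cfg <- quick_cfg(copy_number = 3, coverage_target = 4, seed = 42)
  g <- build_genome(tpl, cfg)
  rs1 <- simulate_paired_reads(g$genome, cfg)
  rs2 <- simulate_paired_reads(g$genome, cfg)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_paired_fastq(rs1, f1)
  write_paired_fastq(rs2, f2)
  expect_identical(readLines(paste0(f1, "_1.fastq")),
                   readLines(paste0(f2, "_1.fastq")))
  expect_identical(readLines(paste0(f1, "_2.fastq")),
                   readLines(paste0(f2, "_2.fastq")))
  rs3 <- simulate_paired_reads(g$genome, cfg, seed = 43)
  expect_false(identical(rs1$reads$read1, rs3$reads$read1))
})

test_that("error-free reads are exact substrings at their recorded origins", {
  tpl <- small_template()
  cfg <- quick_cfg(copy_number = 2, coverage_target = 3, error_rate = 0,
                   seed = 3)
  g <- build_genome(tpl, cfg)
  rs <- simulate_paired_reads(g$genome, cfg, truth = g$truth)
  ori <- rs$origins
  expect_equal(nrow(ori), 2 * nrow(rs$reads))
  expect_equal(anyDuplicated(ori$read_id), 0)
  reads <- setNames(c(rs$reads$read1, rs$reads$read2),
                    c(paste0(rs$reads$id, "/1"), paste0(rs$reads$id, "/2")))
  idx <- sample(seq_len(nrow(ori)), 200)
  for (i in idx) {
    src <- substr(g$genome[[ori$contig[i]]], ori$start[i] + 1,
                  ori$start[i] + cfg$read_length)
    obs <- reads[[ori$read_id[i]]]
    if (ori$strand[i] == "-") src <- riboperon:::revcomp(src)
    expect_identical(obs, src)
  }
})

test_that("realized single-copy depth tracks the coverage target", {
  tpl <- small_template()
  cfg <- quick_cfg(copy_number = 5, coverage_target = 50, chrom_length = 20000,
                   seed = 13)
  g <- build_genome(tpl, cfg)
  rs <- simulate_paired_reads(g$genome, cfg, truth = g$truth)
  on_chrom <- dplyr::filter(rs$origins, contig == "chrom_1")
  realized <- nrow(on_chrom) * cfg$read_length / 20000
  expect_lt(abs(realized - 50) / 50, 0.10)
})

test_that("contaminant reads appear at the requested fraction and are flagged", {
  tpl <- small_template()
  cfg <- quick_cfg(copy_number = 2, coverage_target = 10,
                   contaminant_fraction = 0.05, seed = 8)
  g <- build_genome(tpl, cfg)
  expect_true("contaminant" %in% names(g$genome))
  rs <- simulate_paired_reads(g$genome, cfg, truth = g$truth)
  frac <- mean(rs$origins$is_contaminant)
  expect_lt(abs(frac - 0.05), 0.02)
})

test_that("contigs shorter than the insert are skipped with a warning", {
  tpl <- small_template()
  cfg <- quick_cfg(copy_number = 2, coverage_target = 2,
                   locus_lengths = c(mcm7 = 1500, tiny = 200), seed = 2)
  g <- build_genome(tpl, cfg)
  expect_warning(rs <- simulate_paired_reads(g$genome, cfg), "tiny")
  expect_false("tiny" %in% rs$origins$contig)
})

test_that("truth and config round-trip through JSON and YAML", {
  tpl <- small_template()
  cfg <- quick_cfg(copy_number = 4, per_copy_variant_rate = 0.002,
                   intragenomic_variants = tibble::tibble(
                     position = 700, fraction = 0.25, base = NA),
                   seed = 77)
  g <- build_genome(tpl, cfg)
  tf <- withr::local_tempfile(fileext = ".json")
  write_truth_json(g$truth, tf)
  back <- read_truth_json(tf)
  expect_equal(back$true_copy_number, 4)
  expect_equal(as.data.frame(back$copy_variants),
               as.data.frame(g$truth$copy_variants))
  yf <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cfg, yf)
  cfg2 <- read_sim_config(yf)
  expect_equal(cfg2$copy_number, cfg$copy_number)
  expect_equal(cfg2$locus_lengths, cfg$locus_lengths)
  expect_equal(as.data.frame(cfg2$intragenomic_variants),
               as.data.frame(cfg$intragenomic_variants))
})
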