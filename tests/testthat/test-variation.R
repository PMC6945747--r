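test_that("site variance follows its definition, including ties and depth 0", {
  expect_equal(site_variance(c(A = 100)), 0)
  expect_equal(site_variance(c(A = 90, G = 10)), 0.10)
  expect_equal(site_variance(c(A = 50, G = 50)), 0.50)
  expect_error(site_variance(c(A = 0, C = 0)), "undefined")
})

test_that("variance bins partition (0,1] with the stated boundaries", {
  v <- c(0, 0.0049, 0.005, 0.0099999, 0.01, 0.05, 0.09, 0.10, 0.100001,
         0.12, 1)
  bins <- classify_variance(v)
  expect_equal(as.character(bins),
               c("none", "<1%_nonzero", "<1%_nonzero", "<1%_nonzero",
                 "1-9%", "1-9%", "1-9%", "1-9%", ">10%", ">10%", ">10%"))
  expect_true(all(!is.na(bins)))
  expect_true(is.na(classify_variance(NA_real_)))
})

test_that("clean unpolymorphic coverage yields an all-none profile", {
  tpl <- small_template()
  cfg <- quick_cfg(copy_number = 1, coverage_target = 20, error_rate = 0,
                   seed = 51)
  g <- build_genome(tpl, cfg)
  rs <- simulate_paired_reads(g$genome, cfg)
  pu <- build_pileup(map_back(tpl, g$genome, rs))
  vp <- variance_profile(pu, interval = its_interval(tpl),
                         reference = "operon")
  bs <- bin_summary(vp)
  expect_equal(bs$n[bs$bin != "none"], rep(0L, 3))
  expect_gt(bs$n[bs$bin == "none"], 0)
})

test_that("a planted 10%-of-copies variant is recovered at ~10% variance", {
  tpl <- small_template()
  pos <- unname(its_interval(tpl)["start"]) + 37L
  cfg <- quick_cfg(copy_number = 20, error_rate = 0, coverage_target = 15,
                   intragenomic_variants = tibble::tibble(
                     position = pos, fraction = 0.10, base = NA),
                   seed = 52)
  g <- build_genome(tpl, cfg)
  rs <- simulate_paired_reads(g$genome, cfg)
  pu <- build_pileup(map_back(tpl, g$genome, rs))
  vp <- variance_profile(pu, interval = its_interval(tpl),
                         reference = "operon")
  at <- vp[vp$pos == pos, ]
  expect_gt(at$depth, 100)
  ci <- stats::binom.test(round(at$variance * at$depth), at$depth)$conf.int
  expect_true(ci[1] <= 0.10 && 0.10 <= ci[2])
  expect_true(all(vp$variance[vp$pos != pos] == 0, na.rm = TRUE))
})

test_that("with errors only, the mean variance sits at the error floor", {
  tpl <- small_template()
  cfg <- quick_cfg(copy_number = 10, error_rate = 0.001, coverage_target = 30,
                   seed = 53)
  g <- build_genome(tpl, cfg)
  rs <- simulate_paired_reads(g$genome, cfg)
  pu <- build_pileup(map_back(tpl, g$genome, rs))
  vp <- variance_profile(pu, interval = its_interval(tpl),
                         reference = "operon")
  # with no planted variants every non-consensus base is a sequencing error,
  # so the expected per-site variance equals the error rate
  v <- vp$variance[!is.na(vp$variance)]
  se <- sd(v) / sqrt(length(v))
  expect_lt(abs(mean(v) - 0.001), 3 * se + 5e-4)
  bs <- bin_summary(vp)
  frac_low <- sum(bs$n[bs$bin %in% c("none", "<1%_nonzero")]) / sum(bs$n)
  expect_gte(frac_low, 0.95)
})

test_that("diagnostic sites are exactly the fixed, segregating columns", {
  msa <- c(a1 = "AAAAA", a2 = "AAAAA", b1 = "AACAA", b2 = "AACAA")
  sp <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  ds <- diagnostic_sites(msa, sp)
  expect_equal(ds$sites$column[ds$sites$diagnostic], 2L)
  expect_equal(sum(ds$sites$diagnostic), 1L)
  expect_equal(nrow(ds$pairs), 1L)
  expect_equal(ds$pairs$base_a, "A")
  expect_equal(ds$pairs$base_b, "C")

  # shared polymorphism is not diagnostic
  msa2 <- c(a1 = "AAAAA", a2 = "AACAA", b1 = "AACAA", b2 = "AAAAA")
  ds2 <- diagnostic_sites(msa2, sp)
  expect_equal(sum(ds2$sites$diagnostic), 0L)

  # a gap or N anywhere in a species breaks fixation there
  msa3 <- c(a1 = "AANAA", a2 = "AAAAA", b1 = "AACAA", b2 = "AACAA")
  ds3 <- diagnostic_sites(msa3, sp)
  expect_equal(sum(ds3$sites$diagnostic), 0L)
  expect_false(ds3$sites$fixed_all_species[3])

  expect_error(diagnostic_sites(c(a = "AA", b = "AAA"),
                                c(a = "A", b = "B")), "ragged")
  expect_error(diagnostic_sites(msa, c(a1 = "A", a2 = "A", b1 = "A",
                                       b2 = "A")), ">= 2 species")
})

test_that("simulated diagnostic sites are recovered exactly without background noise", {
  tpl <- small_template()
  ss <- simulate_species_set(
    "((Rsp1,Rsp2),(Rsp3,Rsp4));", tpl, n_taxa_per_species = 3,
    diagnostic_sites_per_species = 3, intron_event_rate = 0,
    region_rates = c("18S" = 0, ITS1 = 0, "5.8S" = 0, ITS2 = 0,
                     "28S" = 0, IGS = 0),
    seed = 7)
  ds <- diagnostic_sites(ss$alignment, ss$taxa)
  expect_setequal(ds$sites$column[ds$sites$diagnostic],
                  ss$diagnostic_truth$position)
  expect_equal(nrow(ss$diagnostic_truth), 12L)
  expect_equal(anyDuplicated(ss$diagnostic_truth$position), 0L)
})

test_that("overlap report cross-tabulates polymorphic and diagnostic sites", {
  prof <- tibble::tibble(
    reference_name = "operon", pos = 0:9, depth = 100L,
    variance = c(0, 0, 0.2, 0, 0, 0.15, 0, 0, 0, 0))
  prof$bin <- classify_variance(prof$variance)
  msa <- c(a1 = "AAAAACAAAA", a2 = "AAAAACAAAA",
           b1 = "AAAAAGAAAA", b2 = "AAAAAGAAAA")
  ds <- diagnostic_sites(msa, c(a1 = "A", a2 = "A", b1 = "B", b2 = "B"))

  rep1 <- overlap_report(prof, ds)
  n <- function(p, d) rep1$table$n[rep1$table$polymorphic == p &
                                     rep1$table$diagnostic == d]
  expect_equal(n(TRUE, TRUE), 1L)   # variant right on the diagnostic column
  expect_equal(n(TRUE, FALSE), 1L)  # variant on a non-diagnostic column
  expect_equal(n(FALSE, FALSE), 8L)

  # no polymorphic sites -> zero overlap
  prof0 <- dplyr::mutate(prof, variance = 0)
  rep0 <- overlap_report(prof0, ds)
  expect_equal(sum(rep0$table$n[rep0$table$polymorphic]), 0L)

  # positions without a column mapping are skipped with a warning
  cmap <- tibble::tibble(position = 0:8, column = 0:8)
  expect_warning(rep2 <- overlap_report(prof, ds, coordinate_map = cmap),
                 "skipped")
  expect_equal(rep2$n_unmapped, 1L)
  expect_equal(glance(rep2)$n_overlap, 1L)
})

test_that("planted minor-allele fractions are recovered across their range", {
  # 100 read-resampling replicates per fraction at ~300x. The exact binomial
  # CI has nominal coverage >= 95%, so the replicate coverage count is
  # Bin(100, p >= 0.95); 90 is below its 1st percentile and unbiasedness is
  # checked separately against the Monte Carlo standard error.
  tpl <- small_template()
  pos <- unname(its_interval(tpl)["start"]) + 61L
  for (f in c(0.05, 0.10, 0.25)) {
    cfg <- quick_cfg(copy_number = 20, coverage_target = 15, error_rate = 0,
                     intragenomic_variants = tibble::tibble(
                       position = pos, fraction = f, base = NA),
                     seed = round(1000 * f))
    g <- build_genome(tpl, cfg)
    sc <- setdiff(names(g$genome), c("rdna_tandem", "contaminant"))
    ref <- c(operon = unname(tpl$sequence), g$genome[sc])
    covered <- logical(100)
    obs <- numeric(100)
    for (r in 1:100) {
      rs <- simulate_paired_reads(g$genome, cfg, seed = 5000L + r)
      vp <- variance_profile(build_pileup(map_reads(rs, ref)),
                             reference = "operon")
      at <- vp[vp$pos == pos, ]
      obs[r] <- at$variance
      ci <- stats::binom.test(round(at$variance * at$depth),
                              at$depth)$conf.int
      covered[r] <- ci[1] <= f && f <= ci[2]
    }
    expect_gte(mean(covered), 0.90)
    expect_lt(abs(mean(obs) - f), 3 * sd(obs) / 10 + 0.002)
  }
})
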