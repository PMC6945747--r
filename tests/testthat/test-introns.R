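test_that("annotation transfer is the identity on an identical query", {
  ex <- exon_template(intron_template())
  tr <- transfer_annotation(ex$sequence, ex)
  expect_equal(tr$identity, 1)
  expect_equal(as.data.frame(tr$annotation), as.data.frame(ex$annotation))
  expect_equal(nrow(tr$candidate_introns), 0L)
  expect_equal(nrow(tr$deleted_ref), 0L)
})

test_that("an inserted intron is recovered as a candidate with shifted boundaries", {
  ex <- exon_template(small_template())
  withr::with_seed(31, ins <- riboperon:::random_dna(500))
  site <- 250L  # inside the 600-bp 18S
  query <- paste0(substr(ex$sequence, 1, site), ins,
                  substr(ex$sequence, site + 1, nchar(ex$sequence)))
  tr <- transfer_annotation(query, ex)
  cand <- tr$candidate_introns
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$host_region, "18S")
  expect_equal(cand$length, 500L)
  expect_lte(abs(cand$ref_site - site), 5L)
  # regions downstream of the 18S shift by the intron length
  downstream <- tr$annotation$region != "18S"
  expect_equal(tr$annotation$start[downstream],
               ex$annotation$start[downstream] + 500L)
})

test_that("short insertions are not called introns and poor homology errors", {
  ex <- exon_template(small_template())
  withr::with_seed(32, {
    ins <- riboperon:::random_dna(30)
    junk <- riboperon:::random_dna(nchar(ex$sequence))
  })
  query <- paste0(substr(ex$sequence, 1, 300), ins,
                  substr(ex$sequence, 301, nchar(ex$sequence)))
  tr <- transfer_annotation(query, ex)
  expect_equal(nrow(tr$candidate_introns), 0L)
  expect_error(transfer_annotation(junk, ex), "unreliable")
})

test_that("assembly-based presence calls recover simulated intron states", {
  tpl <- intron_template()
  ex <- exon_template(tpl)
  catalog <- intron_catalog(tpl)
  ss <- simulate_species_set("((A,B),(C,D));", tpl, n_taxa_per_species = 1,
                             intron_event_rate = 0.4, seed = 13)
  m <- ss$intron_matrix
  for (tx in ss$taxa$taxon) {
    tr <- transfer_annotation(ss$operons[[tx]], ex)
    calls <- intron_presence_from_assembly(tr, catalog)
    truth <- unname(unlist(m[m$taxon == tx, catalog$label]))
    expect_equal(as.character(calls$state),
                 ifelse(truth, "present", "absent"),
                 info = tx)
    # recovered boundaries within 5 bp of the planted sites
    if (nrow(tr$candidate_introns)) {
      d <- vapply(tr$candidate_introns$ref_site, function(s) {
        min(abs(catalog$site - s))
      }, numeric(1))
      expect_true(all(d <= 5))
    }
  }
})

test_that("junction search classifies constructed reads and clean simulations", {
  tpl <- intron_template()
  motif <- junction_motif(tpl, "18S:i1")
  junction_read <- paste0(motif$upstream, motif$downstream)
  boundary_read <- paste0(motif$upstream, substr(motif$intron_5p, 1, 30))
  sup <- junction_motif_support(c(a = junction_read, b = boundary_read),
                                motif)
  expect_gte(sup$absence_support, 1L)
  expect_gte(sup$presence_support, 1L)
  # reverse-complemented junction reads are also found
  rc <- riboperon:::revcomp(junction_read)
  sup_rc <- junction_motif_support(c(a = rc), motif)
  expect_equal(sup_rc$absence_support, 1L)

  # intron present in every copy, error-free reads: no absence support
  cfg <- quick_cfg(copy_number = 4, coverage_target = 25, error_rate = 0,
                   seed = 41)
  g <- build_genome(tpl, cfg)
  rs <- simulate_paired_reads(g$genome, cfg, truth = g$truth)
  sup_sim <- junction_motif_support(rs, motif)
  expect_equal(sup_sim$absence_support, 0L)
  expect_gt(sup_sim$presence_support, 0L)

  expect_error(junction_motif_support(c(a = junction_read), motif,
                                      min_span = 60), "min_span")
})

test_that("Fitch counts match trivial cases and the exhaustive oracle", {
  tr4 <- ape::read.tree(text = "((A,B),(C,D));")
  expect_equal(fitch_min_changes(tr4, c(A = 1, B = 1, C = 1, D = 1)), 0L)
  expect_equal(fitch_min_changes(tr4, c(A = 1, B = 1, C = 0, D = 0)), 1L)
  expect_equal(fitch_min_changes(tr4, c(A = 1, B = 0, C = 1, D = 0)), 2L)
  expect_error(fitch_min_changes(tr4, c(A = 1, B = 1, C = 0)), "D")
  expect_equal(fitch_min_changes(tr4, c(A = 1, B = 1, C = 0),
                                 prune_unknown = TRUE), 1L)

  tips <- paste0("t", 1:5)
  withr::with_seed(71, trees <- lapply(1:6, function(i) ape::rtree(5, tip.label = tips)))
  states <- all_binary_states(tips)
  for (tr in trees) {
    for (st in states) {
      expect_equal(fitch_min_changes(tr, st), brute_fitch(tr, st))
    }
  }
})

test_that("Fitch counts agree with phangorn and survive re-rooting", {
  skip_if_not_installed("phangorn")
  tips <- paste0("t", 1:8)
  withr::with_seed(72, {
    trees <- lapply(1:4, function(i) ape::rtree(8, tip.label = tips))
    states <- lapply(1:25, function(i) setNames(sample(0:1, 8, TRUE), tips))
  })
  for (tr in trees) {
    for (st in states) {
      pd <- phangorn::phyDat(matrix(st[tr$tip.label], ncol = 1,
                                    dimnames = list(tr$tip.label, NULL)),
                             type = "USER", levels = 0:1)
      expect_equal(fitch_min_changes(tr, st),
                   as.integer(phangorn::fitch(tr, pd)))
      # invariance under re-rooting at every internal node
      for (node in (ape::Ntip(tr) + 2):(ape::Ntip(tr) + tr$Nnode)) {
        rerooted <- ape::root(tr, node = node, resolve.root = TRUE)
        expect_equal(fitch_min_changes(rerooted, st), fitch_min_changes(tr, st))
      }
    }
  }
})

test_that("Dollo losses match trivial cases and brute-force enumeration", {
  tr8 <- ape::read.tree(text = "(((A,B),(C,D)),((E,F),(G,H)));")
  all1 <- setNames(rep(1, 8), LETTERS[1:8])
  expect_equal(dollo_min_losses(tr8, all1), 0L)
  one0 <- all1; one0["C"] <- 0
  expect_equal(dollo_min_losses(tr8, one0), 1L)
  # two absent leaves in separate clades: two independent losses
  two0 <- all1; two0[c("C", "G")] <- 0
  expect_equal(dollo_min_losses(tr8, two0), 2L)
  # an absent cherry is a single loss
  cherry0 <- all1; cherry0[c("A", "B")] <- 0
  expect_equal(dollo_min_losses(tr8, cherry0), 1L)

  tips <- paste0("t", 1:6)
  withr::with_seed(73, trees <- lapply(1:3, function(i) ape::rtree(6, tip.label = tips)))
  for (tr in trees) {
    for (st in all_binary_states(tips)) {
      expect_equal(dollo_min_losses(tr, st), brute_dollo(tr, st))
    }
  }
})

test_that("Fitch is bounded by the single-gain event count", {
  tips <- paste0("t", 1:7)
  withr::with_seed(74, {
    trees <- lapply(1:3, function(i) ape::rtree(7, tip.label = tips))
    states <- lapply(1:40, function(i) setNames(sample(0:1, 7, TRUE), tips))
  })
  for (tr in trees) {
    for (st in states) {
      expect_lte(fitch_min_changes(tr, st),
                 dollo_min_losses(tr, st) + 1L)
    }
  }
})

test_that("event reports flag single-event intron patterns", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  m <- tibble::tibble(taxon = c("A", "B", "C", "D"),
                      i_all = c(TRUE, TRUE, TRUE, TRUE),
                      i_tip = c(FALSE, TRUE, TRUE, TRUE),
                      i_conv = c(TRUE, FALSE, FALSE, TRUE),
                      i_unknown = c(TRUE, TRUE, NA, TRUE))
  rep <- event_report(m, tr)
  expect_equal(rep$fitch_changes[rep$intron == "i_all"], 0L)
  expect_true(rep$single_event[rep$intron == "i_all"])
  expect_equal(rep$fitch_changes[rep$intron == "i_tip"], 1L)
  expect_true(rep$single_event[rep$intron == "i_tip"])
  expect_equal(rep$fitch_changes[rep$intron == "i_conv"], 2L)
  expect_false(rep$single_event[rep$intron == "i_conv"])
  expect_equal(rep$n_unknown[rep$intron == "i_unknown"], 1L)

  bad <- dplyr::mutate(m, taxon = c("A", "B", "C", "Z"))
  expect_error(event_report(bad, tr), "Z")
})

test_that("intron matrices round-trip through the {1,0,?} TSV format", {
  m <- tibble::tibble(taxon = c("A", "B"), i1 = c(TRUE, FALSE),
                      i2 = c(NA, TRUE))
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_intron_matrix(m, tf)
  raw <- readr::read_tsv(tf, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  expect_equal(raw$i1, c("1", "0"))
  expect_equal(raw$i2, c("?", "1"))
  back <- read_intron_matrix(tf)
  expect_equal(back$i1, c(TRUE, FALSE))
  expect_equal(back$i2, c(NA, TRUE))
})

test_that("read-based and assembly-based calls agree on error-free genomes", {
  tpl <- intron_template()
  ex <- exon_template(tpl)
  motif <- junction_motif(tpl, "28S:i1")

  # genome without the introns: junction reads support absence only,
  # matching the assembly-level 'absent' call
  cfg <- quick_cfg(copy_number = 3, coverage_target = 30, error_rate = 0,
                   seed = 45)
  g0 <- build_genome(ex, cfg)
  rs0 <- simulate_paired_reads(g0$genome, cfg)
  sup0 <- junction_motif_support(rs0, motif)
  expect_gt(sup0$absence_support, 0L)
  expect_equal(sup0$presence_support, 0L)
  calls0 <- intron_presence_from_assembly(
    transfer_annotation(ex$sequence, ex), intron_catalog(tpl))
  expect_true(all(calls0$state == "absent"))

  # genome with the introns: the reverse
  g1 <- build_genome(tpl, cfg)
  rs1 <- simulate_paired_reads(g1$genome, cfg)
  sup1 <- junction_motif_support(rs1, motif)
  expect_equal(sup1$absence_support, 0L)
  expect_gt(sup1$presence_support, 0L)
  calls1 <- intron_presence_from_assembly(
    transfer_annotation(tpl$sequence, ex), intron_catalog(tpl))
  expect_true(all(calls1$state == "present"))
})
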