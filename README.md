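# riboperon

Characterizing the nuclear ribosomal (nrDNA) tandem repeat from short-read
sequencing data — for mycologists, lichenologists and barcoding researchers
who want to know how many operon copies a genome carries, how much the
copies differ, and what that means for the ITS barcode.

The nrDNA operon (18S–ITS1–5.8S–ITS2–28S plus the intergenic spacer) is
repeated in tandem. Mapping all reads against a **single** reference copy
collapses the array onto one coordinate system, which turns two hard
questions into pileup arithmetic:

* **Copy number.** With mean depths \(\bar d\), the per-locus ratio
  \(\hat c_\ell = \bar d_{\mathrm{nrDNA}} / \bar d_\ell\) over single-copy
  loci \(\ell\) (*MCM7*, *RPB1*, *RPB2* stand-ins and larger single-copy
  contigs) estimates the repeat count; the package reports
  \(\mathrm{mean} \pm \mathrm{SD}\) across loci.
* **Intragenomic variation.** Per site,
  \(v = (\text{depth} - \text{count of consensus base}) / \text{depth}\),
  binned as 0, (0, 1%), [1%, 10%], (10%, 1]. A variant carried by a fraction
  *f* of copies surfaces as a site with \(v \approx f\).
* **Intron turnover.** Presence/absence of 18S/28S introns is called from
  assembled operons (annotation transfer with candidate-insertion detection)
  and from raw reads (junction-motif search), then scored on a phylogeny by
  Fitch (minimum changes, two-state Sankoff) and Dollo (single gain, minimum
  losses) parsimony.
* **Barcode diagnostics.** Alignment columns fixed for different bases in
  different species are contrasted with intragenomically polymorphic pileup
  sites in a 2×2 overlap report.

A ground-truthed simulator (tandem-repeat genomes, Illumina-style paired
reads, species sets evolved on a tree with planted diagnostic sites and
intron histories) makes every stage verifiable without touching real data,
and a gapless Rcpp seed-and-extend mapper plus a SAM importer provide the
alignment substrate.

## Worked example

```r
library(riboperon)

tpl <- build_operon_template(
  c(`18S` = 1800, ITS1 = 200, `5.8S` = 160, ITS2 = 200, `28S` = 3300,
    IGS = 2000))                       # 7,660-bp repeat unit
cfg <- simulation_config(
  copy_number = 12, coverage_target = 30, seed = 7,
  intragenomic_variants = tibble::tibble(position = 1900, fraction = 0.25))

res <- run_copy_number_sim(tpl, cfg)   # genome -> reads -> map -> pileup
res$estimate
#> <copy_number_estimate> 11.5 (SD = 0.2) from 4 locus ratio(s); nrDNA depth 354.3x

variance_profile(res$pileup, interval = its_interval(tpl),
                 reference = "operon") |>
  dplyr::filter(variance > 0.05)
#> # A tibble: 1 × 5
#>   reference_name   pos depth variance bin
#>   <chr>          <int> <int>    <dbl> <fct>
#> 1 operon          1900   339    0.263 >10%
```

The true copy number (12) is recovered as 11.5 ± 0.2 — the small downward
bias comes from reads spanning two tandem copies, which have no gapless
placement on a single-copy reference — and the variant planted in 25% of
copies is the only ITS site above the error floor, at a variance consistent
with its planted fraction. `tidy()`, `glance()` and `autoplot()` methods are
available for the estimate, diagnostic-site and overlap objects, and
`event_report()` tabulates per-intron Fitch/Dollo event counts on a tree.

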