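# phenomescape

Interactive genome-by-phenome "landscapes" from GWAS summary statistics,
for researchers exploring **pleiotropy**: which loci move several traits
at once, and how strongly.

A Manhattan plot is "many variants – one phenotype"; a PheWAS plot is "one
variant – many phenotypes". phenomescape builds the full
"many variants × many phenotypes" view as a 3D landscape — genomic
position on the x-axis, association significance −log₁₀(p) on the y-axis,
an ordered phenotype axis in z — from nothing but per-trait
summary-statistics files (no individual-level genotypes anywhere).

At the **entire-genome level**, only the per-chromosome maximum

&nbsp;&nbsp;&nbsp;&nbsp;ŝ₍c,t₎ = argmax₍s : chr(s)=c₎ −log₁₀ p₍s,t₎

is plotted per phenotype *t*. At the **single-chromosome level** each
chromosome is partitioned into base-pair interval segments (fixed 1 Mb
bins by default, or LD-block intervals from a BED file); a segment is
shown only if some phenotype peaks strictly above the minimum significant
threshold (−log₁₀(p) > 6 by default), and within a shown segment the
highest peak per phenotype is plotted. Both levels support **sectional
views**: half-open significance strata [lo, hi) that partition the y-axis
exactly. Companion modules map peak SNPs to genes by windowed interval
overlap (100 kb default), run LD analytics from summary statistics alone —
LD neighbours of a lead (r² ≥ 0.75 and D′ ≥ 0.75 by default), mutual LD
across traits, the linked-SNP proportion, recursive LD **thinning**
(clumping without genotypes) and an A/B/C(depth) concordance
categorizer — and export regional summary statistics in a layout
consumable by multi-trait colocalization tools. P-values are parsed from
their string form, so values far below the double-precision underflow
limit (e.g. `1.6e-320` → 319.7959) survive exactly.

## Worked example

Everything below runs offline on the package's own synthetic generator,
which plants known loci (including a pleiotropic APOE-like constellation
in segment 45 of chromosome 19 with a buried secondary signal) into
background noise:

```r
library(phenomescape)

sim  <- simulate_summary(seed = 1)                 # 4 traits, 22 autosomes
recs <- lapply(names(sim$files), function(p)
  read_summary_file(sim$files[[p]], sim$column_map, p))
tab  <- harmonize(recs, sim$phenotypes)

grid <- chromosome_peaks(tab, 19, fixed_bins(), threshold_min = 6.5)
grid
#> <bin_peak_grid> chr19: 1 retained segment(s) x 4 phenotype(s), 4 non-empty cell(s); threshold_min=6.5, stratum [0,Inf)
grid$cells[, .(segment, phenotype, snp_id, pos, neglog10p)]
#>    segment phenotype            snp_id      pos neglog10p
#> 1:      45       HDL     rs_lead_19_45 45411941 25.000000
#> 2:      45       LDL     rs_lead_19_45 45411941 60.000000
#> 3:      45        TC     rs_lead_19_45 45411941 40.000000
#> 4:      45      TRIG rs_lead_19_45_sec 45650000  2.779281
```

Only segment 45 survives the 6.5 cut-off. Three traits peak at the same
lead SNP — the pleiotropic signal — while TRIG's best record in the
retained segment sits at background level (cells below the floor are still
shown once a segment is retained; the floor governs retention only). The
heatmap projection of the same grid:

```r
heatmap_projection(landscape_figure(grid))
#>          HDL LDL     TRIG TC
#> chr19:45  25  60 2.779281 40
```

LD thinning exposes the independent signal buried under the LDL peak, and
the categorizer reproduces a locus-concordance audit against externally
reported SNPs:

```r
be  <- ld_backend_table(sim$ld_table)              # PLINK .ld-style table
seg <- tab[tab$chrom == 19 & tab$phenotype == "LDL" &
             floor((tab$pos - 1) / 1e6) == 45]

thin_snps(seg, be, depth = 2)[, .(snp_id, pos, neglog10p)]
#>               snp_id      pos neglog10p
#> 1:     rs_lead_19_45 45411941        60
#> 2: rs_lead_19_45_sec 45650000        55

cell <- grid$cells[phenotype == "LDL"]
categorize_locus("rs_lead_19_45",      cell, seg, be)$category  # "A"
categorize_locus("rs_lead_19_45_sat1", cell, seg, be)$category  # "B"
categorize_locus("rs_lead_19_45_sec",  cell, seg, be)  # C, level 2

ld_neighbors(be, "rs_lead_19_45", seg$snp_id,
             significant_ids = seg$snp_id[seg$neglog10p > 6.5])
#> <ld_set> lead rs_lead_19_45: 5 linked SNP(s) at r2 >= 0.75 & D' >= 0.75 [offline-table]
```

`linked_proportion()` of that set is 0.5: of the 10 SNPs above the
significance threshold in the segment, 5 are in LD with the lead.
Finally, gene annotation, a self-contained interactive HTML figure and a
colocalization-ready regional export:

```r
gm <- load_gene_intervals(sim$genes_bed)           # 4-column BED
map_snp_to_genes(gm, 19, 45411941)                 # "GENE19_45"
write_figure(landscape_figure(grid, genes = gm), "chr19.html")
export_region(tab, region_selection(19, segment = 45), "region.tsv")
```

A thin command-line wrapper over the same functions ships in
`inst/scripts/phenomescape-cli.R` (`prepare`, `plot`, `export`, `thin`,
`simulate` subcommands; `Rscript inst/scripts/phenomescape-cli.R` prints
usage).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the full pipeline from scratch at the demonstration
parameters — simulates the stated synthetic world for the given seed,
ingests and harmonizes the summary files, builds the entire-genome peaks
and the per-chromosome peak grids (1 Mb bins, 6.5 cut-off), runs LD
thinning and lead categorization on every planted locus, writes the
interactive HTML figures and the regional export, and logs each measured
result — then writes the JSON report to `--out`.
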