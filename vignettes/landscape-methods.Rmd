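---
title: "Methods: genome-by-phenome landscapes from GWAS summary statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome-by-phenome landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenomescape)
```

## The problem and the model

A Manhattan plot shows many variants against one phenotype; a PheWAS plot
shows one variant against many phenotypes. When the question is
pleiotropy — which loci move *several* traits — neither is enough.
phenomescape builds the "many variants × many phenotypes" object directly:
a 3D landscape with genomic position on the x-axis, association
significance $-\log_{10}(p)$ on the y-axis, and the ordered set of
phenotypes on the z-axis, explorable at two levels.

**Entire-genome level.** For each autosome $c \in \{1,\dots,22\}$ and each
phenotype $t$, only the single most significant SNP

$$\hat{s}_{c,t} = \arg\max_{s \,:\, \mathrm{chr}(s)=c} \; -\log_{10} p_{s,t}$$

is plotted. Nothing else survives, which is what makes a 2.5M-SNP × many-
trait dataset legible at a glance. No significance floor applies at this
level; de-cluttering comes entirely from the per-chromosome maximum.

**Single-chromosome level.** The chosen chromosome is partitioned into
base-pair interval segments — fixed-width bins (default $10^6$ bp, so
segment $k$ covers positions $[k\cdot 10^6 + 1,\ (k+1)\cdot 10^6]$ and
"region 45" means 45,000,001–46,000,000 bp) or population LD blocks read
from a BED file. A segment is *retained* only if some phenotype peaks
strictly above the minimum significant threshold there
($-\log_{10}(p) > \tau$, default $\tau = 6$); within a retained segment the
single highest peak per phenotype is plotted. Note the asymmetry, which is
deliberate: the floor governs *segment retention only*. Once a segment is
retained, the best record of every phenotype is displayed even when it sits
below the floor — the landscape shows what each trait does at a locus that
matters for at least one trait.

**Sectional view.** Either level can be restricted to a significance
stratum $[\ell, h)$ on the y-axis. The interval is half-open so that
adjacent strata partition the axis exactly: the results of a disjoint cover
of strata, merged cell-wise by maximum, reproduce the unstratified view (a
property the test suite checks). A published-style ">100" section is
`stratum(100)` = $[100, \infty)$.

## Ingestion and extreme p-values

Summary files are harmonized once into a single long-format table
(phenotype, snp_id, chrom, pos, neglog10p, effect, effect_type, se,
allele1, allele2), sorted by (chrom, pos, phenotype), with a stable
user-supplied phenotype order that becomes the z-axis. Non-autosomal
records are dropped with a count; duplicate (snp_id, chrom, pos) rows
within one file collapse to the most significant with a warning; nothing is
imputed for SNPs absent from a phenotype's file.

Lipid-scale GWAS produce p-values far below the smallest positive double
(~4.9e-324): `as.numeric("1.6e-320")` survives but denormalizes, and
anything smaller underflows to 0 and would plot as $\infty$.
`parse_pvalue()` therefore splits mantissa and exponent from the *string*
and computes $-\log_{10}(m\cdot 10^{-k}) = k - \log_{10} m$, which is exact
to ~1e-15 at any exponent. The suite pins this against an
arbitrary-precision oracle to 1e-9 down to $p = 10^{-350}$.

Effect sizes are stored as given with an `effect_type` flag (`beta` or
`OR`); odds ratios are never log-transformed, because the effect-size plot
displays the published quantity. Missing se/alleles are allowed and render
as an `NA` sentinel in hover payloads.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| bin width | 1,000,000 | bp | fixed-mode segment size |
| `threshold_min` | 6 | $-\log_{10}(p)$ | segment retention floor (strict >) |
| stratum | $[0, \infty)$ | $-\log_{10}(p)$ | sectional view bounds (half-open) |
| `r2_min`, `dprime_min` | 0.75, 0.75 | $r^2$, $D'$ | LD display set membership ($\geq$) |
| category-B LD | 0.75, 0.75 | $r^2$, $D'$ | concordance match (strict >) |
| `gene window` | 100,000 | bp | SNP-to-gene interval expansion |
| thinning `depth` | 1 (3 for categorization) | — | independent signals to expose |

The demonstration configuration for a four-trait lipid analysis is a 6.5
cut-off with 1 Mb bins; `scripts/acceptance.R` runs exactly that. The two
different LD comparisons are intentional: display sets use "reaching" the
threshold ($\geq$), the concordance audit uses strict inequality — each
matches its own definition.

## LD analytics without genotypes

All LD operations go through a backend contract (query: lead + candidates
→ pairwise $r^2$, $D'$). The offline backend reads a PLINK `.ld`-style
table and symmetrizes it; a REST stub records an Ensembl-compatible
endpoint but raises a typed `ld_backend_unavailable` condition when
queried, letting callers degrade to an "LD: NA" display — the tested core
performs no network I/O. SNPs unknown to the backend count as *not in LD*:
conservative, and they can still surface via thinning.

* `ld_neighbors()` — members must pass **both** thresholds (conjunction).
* `mutual_ld()` — intersection of per-phenotype member sets; shared tag
  SNPs across traits.
* `linked_proportion()` — |members ∩ significant| / |significant|; the 0/0
  case returns `NA`, never 0, because "no significant SNPs" is not "none
  linked".
* `thin_snps()` — greedy clumping from summary statistics: take the
  segment maximum, remove it and everything in LD with it (significant or
  not — an interpretation, since removal scope is otherwise ambiguous),
  recurse to the requested depth. Depth 1 is by construction identical to
  the displayed segment peak, and output leads are pairwise non-linked.
* `categorize_locus()` — the concordance ladder used to audit the
  landscape against externally reported lead SNPs: **A** exact match to
  the displayed peak; **B** strict LD with it; **C(k)** surfaced at
  thinning depth $k \le$ `depth_max` (default 3, the level reported in
  brackets); otherwise unmatched with a reason.

## Gene annotation and the gene view

SNP-to-gene mapping is interval overlap against a user-supplied 4-column
BED, with every interval expanded by the window on both sides; all
overlapping genes are reported nearest-first and hover payloads join them
with ";" rather than truncating. Annotation is a file, not a live BioMart
query, to keep analyses reproducible and tests hermetic.

The graded heatmap is scaled by the in-view maximum, so a strong peak can
visually mask a neighbouring signal that is merely genome-wide significant.
The gene view counters this: a *binary* gene × phenotype matrix (1 iff the
phenotype has any above-threshold SNP mapping to the gene) rendered with
uniform brightness. Lowering the threshold can only turn 0s into 1s —
checked as a monotonicity property.

## Figures

`landscape_figure()` produces a renderer-independent specification: one
trace per phenotype in the table's z order, each point carrying the full
nine-field hover payload plus gene symbols; missing cells produce gaps,
never interpolation or zero-fill (that is also why the landscape is
per-phenotype ribbons rather than a fitted surface — a surface would
invent data across holes). `heatmap_projection()` is the z-perpendicular
projection with `NA` as the missing-cell sentinel, kept distinct from 0
since $-\log_{10}(p) = 0$ is a real value. The HTML writer embeds the
figure JSON and an inlined renderer in one self-contained file (opens
offline; the data payload is byte-identical across runs); static export
writes PDF/PNG/SVG. Every test asserts on the specification, never on
pixels.

## Regional export

`export_region()` writes one wide TSV per region: a row per SNP present in
at least one phenotype, then per-phenotype (beta, se, neglog10p) triplets.
Multi-trait colocalization tools consume aligned per-trait effect/se
vectors, so this layout feeds them directly; SNPs missing in some
phenotype keep blank cells and the consumer decides on complete-case
filtering. The layout is documented in `#` header lines of the file and
`read_region()` re-imports it losslessly.

## The synthetic world

The generator emits what the method is designed to consume: per-phenotype
summary files over all 22 autosomes with block-structured planted signals.
Its defaults are a stated world, fixed once:

* 4 phenotypes (a four-trait lipid panel is the canonical use case);
* 500 background SNPs per chromosome with $-\log_{10}(p)$ uniform on
  [0, 3] — capped at half the retention floor so every retained segment is
  planted by construction (a stress variant raises the cap to 7 for
  retention-robustness tests);
* the default locus set: a pleiotropic locus in segment 45 of chromosome
  19 affecting three of four traits (emulating the APOE-region
  constellation), a buried secondary independent signal there, and
  single-trait loci on other chromosomes;
* strong satellites drawn at $r^2, D' \in [0.80, 0.98]$ (strictly above
  both thresholds), weak ones in [0.05, 0.50], secondary↔primary
  $r^2 < 0.1$; satellite significance rides 3–8 units below its lead.

Planted $-\log_{10}(p)$ values are generated directly and written exactly
as declared; files still print p as scientific-notation strings with a
10-digit mantissa, so re-parsing exercises the extreme-value path
(including planted leads beyond 1e-300). A secondary signal carries its
declared significance only in its `secondary_phenotypes` (default: the
first affected phenotype) and must sit strictly below the primary lead
there; otherwise it would displace the primary as the displayed peak in
the weaker phenotypes and the planted truth would contradict itself.

What a green test establishes: peak selection, retention, strata algebra,
LD-set logic, thinning and categorization are exact on data whose truth is
known. What it does not: real summary statistics have allele-frequency-
dependent effect distributions, polygenic background exceeding the [0, 3]
cap, LD that decays continuously rather than splitting into strong/weak
halos, and cross-study allele inconsistencies — none of which the
generator emulates, and the first phase makes no attempt to harmonize
alleles across studies (a stated non-goal).

## Numerical choices and degenerate inputs

* Tie-breaking for equal significance: smaller position, then
  lexicographically smaller SNP id — outputs must be deterministic to be
  testable.
* Retention is strict (`> threshold_min`); a segment peaking exactly at
  the floor is omitted.
* BED inputs (LD blocks, genes) are 0-based half-open and converted to
  the internal 1-based closed convention in exactly one place per module;
  positions in blocks-mode gaps are excluded from binned views (counted)
  but kept in the whole-genome view.
* Empty results are valid states, not errors: a chromosome with no
  retained segment renders an empty grid (with a message), an empty
  figure writes a valid HTML file; but an empty *region export* errors,
  because a file with no rows silently poisons downstream colocalization.
* p = 0, p < 0, p > 1 are hard errors naming the element; unparseable
  numerics are dropped-and-counted instead, since a single bad row should
  not kill a 2.5M-row ingest.

## Scaling note for the bundled checks

The 20-seed end-to-end planted-truth check runs the full pipeline per seed
but with 200 background SNPs per chromosome instead of the default 500,
purely to keep the suite inside its time budget; planted structure,
thresholds and seeds are those of the stated world.

## Known limitations

* No multiple-testing adjustment, sample-size weighting or p-value
  integration: the tool visualizes, it does not re-test.
* No allele harmonization or genome-build liftover across input studies.
* The REST LD backend is a contract plus stub; live population LD requires
  network access and is deliberately outside the tested core.
* Colocalization and local genetic-correlation analyses are downstream
  consumers of the regional export, not features.

## A worked session

```{r example, eval = FALSE}
sim <- simulate_summary(seed = 1)                  # the stated world
recs <- lapply(names(sim$files), function(p)
  read_summary_file(sim$files[[p]], sim$column_map, p))
tab <- harmonize(recs, sim$phenotypes)

genome <- genome_peaks(tab)                        # 22 x 4 peak records
grid <- chromosome_peaks(tab, 19, fixed_bins(), threshold_min = 6.5)
retained_segments(grid)                            # 45

be <- ld_backend_table(sim$ld_table)
seg <- tab[tab$chrom == 19 & tab$phenotype == "LDL" &
             floor((tab$pos - 1) / 1e6) == 45]
thin_snps(seg, be, depth = 2)$snp_id               # primary + buried lead

gm <- load_gene_intervals(sim$genes_bed)
write_figure(landscape_figure(grid, genes = gm), "chr19.html")
export_region(tab, region_selection(19, segment = 45), "region.tsv")
```
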