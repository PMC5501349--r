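# middlemarks

Middle-down mass spectrometry of combinatorial histone marks under
metabolic labeling, in R.

Histone PTMs act in combination on the same tail, and bottom-up proteomics
destroys that connectivity. Middle-down MS analyzes the intact GluC-released
histone H3 N-terminal tail (residues 1–50), so each identification is a full
**proteoform** — a complete, site-resolved set of me1/me2/me3/ac marks.
`middlemarks` implements the computational side of that workflow for two
metabolic labels:

- **heavy-KR (SILAC) sequence labeling** — K(¹³C₆,¹⁵N₂)/R(¹³C₆,¹⁵N₄) shift
  the 8 K + 7 R of the H3 1–50 tail by 134.17 Da (16.77 m/z at 8+),
  separating old from newly synthesized histones;
- **heavy-methyl (¹³CD₃) labeling** — every methyl deposited after the
  medium switch is +4.0222 Da; a k-fold methylation with h heavy methyls is
  written `me-k:h` (e.g. `K27me3:1`), and *hybrid* marks (0 < h < k) flag
  sites that gained methylation on top of a pre-existing state.

The package provides, per module:

- a proteoform model (masses from frozen monoisotopic constants; ETD c/z•
  fragment ladders obeying `c_i + z_(n−i) = M + 1.007824`; the compact
  notation grammar `K14acK27me2:2`);
- a spectrum search: composition-first candidate enumeration inside a
  2.1 Da precursor window, greedy fragment matching at 0.01 Da (below the
  0.0364 Da trimethyl/acetyl difference), and an isoScale-style
  localization filter that accepts a placement only if every co-isolated
  isobaric rival is contradicted by a matched site-determining ion within
  30 ppm;
- **FIRR** quantification: the summed MS/MS intensity of a mixed spectrum is
  split among isobaric proteoforms by non-negative least squares over their
  site-determining fragment-ion intensities (exact at zero noise), then
  normalized to relative abundances per (tail, channel, sample);
- combinatorial analytics: single-mark deconvolution, heavy-methyl turnover
  fractions, hybrid-mark ranking, pairwise interplay scores
  `log2(F_ab / (F_a·F_b))`, replicate correlation and CV;
- a seed-deterministic synthetic-spectra generator with ground truth
  (isobaric co-isolation, log-normal intensity noise, peak dropout, ppm
  jitter, exact incomplete-incorporation distributions, and a heavy-methyl
  labeling time course);
- an MGF dialect for deconvoluted neutral masses, TSV tables, a YAML run
  configuration, and a small CLI (`inst/cli/middlemarks`, subcommands
  `simulate | search | quantify | analyze | pipeline | template`).

## Worked example

Simulate a four-form mixture on the H3 tail (three of the forms isobaric
pairs/partners within the search window), search and filter the spectra,
and quantify with FIRR splitting — all from the packaged demo config:

```r
library(middlemarks)
cfg <- read_run_config(system.file("extdata", "demo_config.yaml",
                                   package = "middlemarks"))
res <- run_pipeline(cfg, "demo_out", quiet = TRUE)
res$quant
#>      tail   proteoform channel sample intensity relative_abundance
#> 1 H3_1-50                light   demo  16375559            0.19687
#> 2 H3_1-50 K14me1K27me1   light   demo   2386478            0.02869
#> 3 H3_1-50       K14me2   light   demo  13147568            0.15806
#> 4 H3_1-50        K27ac   light   demo    860682            0.01035
#> 5 H3_1-50       K27me2   light   demo   2386478            0.02869
#> 6 H3_1-50       K27me3   light   demo  12054916            0.14493
#> 7 H3_1-50  K9me1K14me1   light   demo   1189006            0.01429
#> 8 H3_1-50        K9me2   light   demo  34779351            0.41812
```

The configured truth is K9me2 = 0.40, K14me2 = 0.25, K27me3 = 0.15,
unmodified = 0.20, simulated with 10% fragment-intensity CV, 5% peak
dropout and 2 ppm mass jitter. The pipeline recovers 0.418 / 0.158 / 0.145 /
0.197 from a single spectrum per isobaric group; the remaining few percent
are noise assigned to isobaric alternatives (e.g. `K14me1K27me1`), a
documented single-spectrum effect. At zero noise the recovery is exact, and
relative abundances always sum to 1 within each (tail, channel, sample).

Downstream, on the same table:

```r
single_mark_table(res$quant)   # per-mark deconvolution, e.g. K9me2 0.418
heavy_fraction(res$quant)      # 0 here: no heavy-methyl channel in the demo
```

A heavy-methyl time course with ground truth comes straight from the
generator:

```r
tc <- simulate_emt_timecourse(times = 0:2, lambda = 2.0, seed = 1)
vapply(tc, heavy_fraction, numeric(1))   # day0 = 0, rising with time
hybrid_marks(tc$day1)                    # me2:1 / me3:1 / me3:2 ranking
interplay(tc$day1, "K27me3:*", "K36me2:*")
```

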