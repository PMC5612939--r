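# rrntraits

Trait-based analysis of microbial communities built on ribosomal RNA
operon (rrn) copy numbers. Bacterial genomes carry 1–15 rrn copies, and
copy number tracks a growth-strategy trade-off: low-copy taxa grow
slowly but efficiently, high-copy taxa grow fast but wastefully. Summed
over a community and weighted by relative abundance, the trait becomes a
single number per sample whose trajectory through time reveals which
strategy dominates each stage of succession — for instance during
biofilm formation in streams of contrasting trophic state.

The package is aimed at microbial ecologists with genus-annotated 16S
OTU tables who want to move from composition to growth strategy.

## What it computes

For a count table (OTUs × samples), an OTU → genus taxonomy and a
genus-level copy-number lookup:

- **Assignment.** Each OTU inherits its genus's mean copy number,
  rounded half-up to the nearest integer and clamped into [1, 15].
  Unassignable OTUs are reported, not dropped.
- **Binning.** Low copy number (LCN): rrn 1–3. High copy number (HCN):
  rrn 4–15.
- **Community aggregation**, per sample, over renormalized assigned
  abundances $p_i$ with copy numbers $r_i$:
  - class abundances $\mathrm{LCN} = \sum_{r_i \le 3} p_i$,
    $\mathrm{HCN} = \sum_{r_i \ge 4} p_i$, and their ratio HCN:LCN;
  - community-weighted mean $\mathrm{CWM} = \sum_i p_i r_i$ and the
    unweighted mean over taxa present;
  - genera counts per class and their ratio.
- **Succession trajectories**: replicate mean ± sd per time point,
  split into an initial (≤ 25 d, configurable) and a late phase.
- **Growth kinetics**: lag phase $\lambda$ and maximum growth rate
  $\mu_{\max}$ from bulk cell counts via the Zwietering logistic
  $f(t) = A \,/\, \big(1 + \exp(\tfrac{4\mu_{\max}}{A}(\lambda - t) + 2)\big)$,
  and OLS regressions of the trait ratio on either parameter with 95%
  confidence bands.
- **Inference**: a migrant-pool resampling null for the community mean
  copy number (150 OTUs × 1000 draws by default, add-one empirical p),
  one-way ANOVA with Tukey HSD, Mann–Whitney U with an exact
  enumeration path at small n, Bonferroni correction.
- **Synthetic data**: a seeded Dirichlet-multinomial generator of
  genus-structured succession and stream-comparison datasets with known
  ground truth, plus noisy logistic growth curves, so the full pipeline
  is testable without any external download.

Supporting I/O: TSV readers/writers for count tables, sample metadata,
taxonomy and lookup tables; without-replacement rarefaction; relative
abundance with optional subsetting and renormalization. A small
synthetic lookup spanning rrn 1–15 ships in
`inst/extdata/rrn_lookup_synthetic.tsv`.

## Worked example

```r
library(rrntraits)

sim  <- generate_succession(succession_config(), seed = 42)
prof <- trait_profiles(sim$tables$eutrophic, sim$taxonomy, sim$lookup)
trajectory(prof, "ratio_hcn_lcn", phase_cut = 25)
#>   time_days      mean         sd n   phase
#> 1         4 1.1030324 0.12414687 3 initial
#> 2         8 0.9851610 0.10805573 3 initial
#> 3        12 0.7914493 0.13783214 3 initial
#> 4        18 0.7820545 0.16788022 3 initial
#> 5        25 0.7709619 0.12576401 3 initial
#> 6        32 0.6503806 0.07645459 3    late
#> 7        39 0.6586949 0.11020899 3    late
#> 8        45 0.6815393 0.13060597 3    late
```

Each row is one sampling day: `mean` and `sd` are the HCN:LCN abundance
ratio across the three replicate flumes. The simulated eutrophic regime
starts HCN-enriched (ratio ≈ 1.1 at day 4, i.e. high- and low-copy taxa
about equally abundant) and decays toward its unboosted composition
(≈ 0.65–0.68 after day 25), the qualitative signature of fast growers
dominating early succession and efficient growers taking over.

Genera-count ratios work directly from replicate-mean counts, e.g. with
34.3 HCN and 97.4 LCN genera:

```r
genera_ratio(34.3, 97.4)
#> [1] 0.3521561
```

A command-line wrapper over the same functions is installed at
`system.file("cli", "rrntraits.R", package = "rrntraits")` with
subcommands `rarefy`, `assign`, `traits`, `growth`, `nulltest` and
`simulate`; every seeded invocation is bit-reproducible.

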