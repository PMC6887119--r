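# threadscan

`threadscan` is an R package for the computational analyses that surround a
question in translation initiation: how mRNA is threaded across the solvent
side of the 40S ribosomal subunit — along the four helices of the ES6S
region of 18S rRNA (A: nt 681–735, B: 740–793, C–D: 795–864, E: 865–910) —
before it reaches the decoding channel, and what blocking that path does to
scanning and to genome-wide translation. It is aimed at RNA biologists and
bioinformaticians working with crosslink-sequencing, polysome profiling and
in vitro translation kinetics.

The package covers six connected analyses, each with a seeded synthetic-data
generator carrying ground truth, so every statistical claim in the test
suite is checked against planted parameters:

1. **RT-stop crosslink mapping.** In an RTTS (reverse-transcriptase
   termination site) assay, reverse transcription arrests one nucleotide 3′
   of a crosslink adduct, so a read whose 5′ end maps at position *p* on
   18S rRNA reports a contact at *p − 1*. `call_rt_stops()` tallies these
   per-nucleotide, `top_sites()` ranks them (descending count, ties by
   ascending position), `annotate_site()` places them on the ES6S helix
   map, `region_fraction()` measures concentration in nt 700–910, and
   `compare_profiles()` contrasts two libraries with a pseudocount.

2. **Translation-efficiency quantification.** From monosomal/polysomal
   count matrices with ERCC spike-ins: median-of-ratios size factors on
   spike-in rows (`size_factors()`), per-gene TE = (polysomal + ½) /
   (monosomal + ½) over replicate means (`compute_te()`), log2 FC TE =
   log2(TE_control / TE_treated) so positive = translation reduced
   (`fc_te()`), an empirical-Bayes moderated t on per-replicate log2 TE
   with BH adjustment (`test_te_change()`), and classification at the
   asymmetric thresholds FC TE > 1 (TE_down) / < −0.7 (TE_up) at
   p-adj < 0.05 (`classify_te()`). `te_pipeline()` runs the whole chain.

3. **5′ UTR features.** Length, GC, G-quadruplex scanning for
   (G≥3 N1–12)×4 and the weak G2 variant (`scan_g4()`), (GGC/A)≥4 tandem
   repeats (`scan_ggc_repeats()`), a Nussinov maximum-base-pair structure
   proxy (`structure_score()`), 5′ TOP flagging (`flag_top()`), plus the
   group statistics: exact/normal Mann-Whitney U (`mannwhitney_u()`),
   Pearson χ² motif enrichment (`motif_enrichment()`), and feature PCA
   (`feature_pca()`).

4. **Scanning kinetics.** Full-translation time (FTT) — the onset of
   detectable reporter activity in a continuous luciferase recording — by
   baseline + 3·SD thresholding and linear-phase x-intercept
   (`estimate_ftt()`), and the FTT-vs-5′UTR-length slope
   (`ftt_linearity()`).

5. **Drug synergy.** Median-effect fits fa/(1−fa) = (d/Dm)^m
   (`median_effect_fit()`) and the Chou–Talalay combination index
   CI = d1/D1 + d2/D2 (`combination_index()`): CI < 1 synergy, = 1
   additivity, > 1 antagonism.

6. **Solvent-side geometry.** A linear mRNA path model (4.5 Å per base,
   position +11 at the entry channel; `path_distance()`) and a perfect
   antiparallel oligo–rRNA duplex finder modelling RNase H protection
   (`map_oligo_duplex()`).

## Worked example

```r
library(threadscan)

## --- RT-stop mapping on a simulated RTTS library ---------------------
sim <- gen_rtts_reads(rtts_sim_spec(
  planted_sites = data.frame(position = c(802, 850, 871),
                             intensity = c(300, 500, 200)),
  background_rate = 0.5, seed = 42))
prof <- call_rt_stops(sim$alignments, "18S", 1869)
prof
#> RT-stop profile on 18S (1869 nt): 1934 site events from 1934 reads
top <- top_sites(prof, 3)
top$helix <- annotate_site(top$position)
top
#>   position count   helix
#> 1      850   520 ES6S_CD
#> 2      802   288 ES6S_CD
#> 3      871   193  ES6S_E
region_fraction(prof)   # share of events inside nt 700-910
#> [1] 0.57
```

The three planted sites come back as the top three, each assigned to its
helix; the remaining events are the uniform background, which is why the
nt 700–910 share is 0.57 rather than ~1.

```r
## --- TE pipeline on a simulated polysome-profiling experiment --------
fc <- c(rep(2, 50), rep(0, 450))   # 50 genes with TE reduced 4-fold
cs  <- gen_count_matrix(count_sim_spec(n_genes = 500,
                                       planted_log2_fc_te = fc, seed = 42))
tab <- te_pipeline(cs$counts, cs$design)
table(tab$class)
#>   TE_down     TE_up unchanged
#>        44         1       505
head(tab[tab$class == "TE_down", c("gene_id", "log2_fc_te", "p_adj")], 3)
#>     gene_id log2_fc_te       p_adj
#> 1 gene_0001   2.424863 0.003488246
#> 2 gene_0002   2.221331 0.011123631
#> 4 gene_0004   2.185162 0.008081540
```

44 of the 50 planted genes are classified `TE_down` (the totals include
the 50 spike-in rows, all `unchanged`); estimated log2 FC TE centres on
the planted value of 2.

```r
## --- scanning kinetics and synergy -----------------------------------
gless <- gen_luc_curve(curve_sim_spec(onset_time = 9.5,
                                      sampling_interval = 3))$curve
estimate_ftt(gless)
#> FTT = 9.50 min (onset 12.00 min, threshold 50)

dr  <- gen_dose_response(2, 1.8, c(0.5, 1, 2, 4, 8))
fit <- median_effect_fit(dr$dose, dr$fa)
fit
#> median-effect fit: Dm = 2, m = 1.8 (n = 5, rss = 5.25e-31)
```

The FTT estimator recovers the 9.5-min planted onset exactly from a
noiseless 3-min-sampled recording, and the median-effect fit returns the
generating (Dm, m) to machine precision.

## Command line

`inst/cli/threadscan.R` exposes subcommands `synth`, `rtts`, `te`, `utr`,
`ftt`, `synergy`, `geometry` and `duplex`; see the header of that script
for the options of each.
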