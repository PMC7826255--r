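# editrace

Quantification of CRISPR–Cas9 RNP editing outcomes from amplicon deep
sequencing, with repair-pathway classification and repair-kinetics analysis.

## The scientific problem

When a Cas9 ribonucleoprotein cuts a locus, three DNA repair pathways race
to resolve the break:

- **NHEJ** (non-homologous end joining) is fast and produces small indels —
  above all a +1 insertion duplicating the nucleotide immediately 5′ of the
  cut (the −4 base before the PAM). The −4 base sets the insertion bias:
  a −4 T drives +1 insertions to ~27% of edits, A ~10%, C/G only 3–5%.
- **MMEJ** (microhomology-mediated end joining) is slow and deletes the
  sequence between short repeats flanking the cut; junctions carry 2–16 nt
  of microhomology (MH), and longer deletions form more slowly
  (T₅₀ ≈ 18–24 h versus ≈ 6–8 h for +1 NHEJ, where T₅₀ is the time to half
  of a pattern's maximal frequency).
- **HDR** (homology-directed repair), available when a donor template with
  homology arms is supplied, installs a precise insert at the cut with
  intermediate kinetics (T₅₀ ≈ 15 h).

Because each cell keeps whichever repair finishes first, the kinetics
determine the competition: an HDR donor strongly suppresses slow long MMEJ
deletions (the >10 bp bin drops by ~55–74%) while leaving fast +1 NHEJ
nearly untouched. `editrace` is for researchers analysing such amplicon
experiments (editing efficiency, outcome spectra, MMEJ/NHEJ/HDR splits,
T₅₀, pattern dispersion, donor competition) and for method developers who
need a fully synthetic, statistically realistic test bed.

## What is in the package

| Stage | Functions |
|---|---|
| Read merging / demultiplexing | `merge_pairs()`, `demultiplex()`, `barcode_table()` |
| Indel calling | `call_sample()`, `align_to_reference()`, `editing_efficiency()`, `top_n_patterns()` |
| Repair classification | `microhomology()`, `is_plus1_duplication()`, `classify_allele()`, `classify_sample()`, `categorize()` |
| Kinetics | `time_course()`, `check_eligibility()`, `fit_t50()`, `kinetics_by_category()`, `summarize_t50()` |
| Statistics | `gini_top_n()`, `relative_frequencies()`, `competition_delta()`, `competition_test()`, `pearson_r2()`, `compare_external_predictions()` |
| Synthetic data | `random_amplicon()`, `build_outcome_model()`, `simulate_locus()`, `reads_from_frequencies()`, `race_occupancy()`, `run_locus_pipeline()`, `fixture_bcl11a_fig3()` |
| Orchestration | `run_pipeline()`, `editrace_cli()` (subcommands `simulate merge demux call classify kinetics stats report`) |

The T₅₀ estimator fits the saturation model `f(t) = F_max·(1 − 2^(−t/T50))`
(so `f(T50) = F_max/2`) with an interpolation fallback; the simulator
implements the repair race as per-outcome completion times
`t = delay_class + Exp(rate)` with the earliest outcome claiming the cell.
See the methods vignette (`vignettes/repair-race-methods.Rmd`) for the model,
its calibration to published editing biases and class T₅₀s, and its limits.

## Worked example

Simulate one T-cell locus with a −4 T, run the full pipeline on its reads,
and look at the outcome spectrum:

```r
library(editrace)
amp <- random_amplicon(seed = 5, minus4 = "T")
cfg <- sim_config(seed = 2, cell_profile = "T", depth = 5000,
                  timepoints = 48, editable_fraction = 0.4)
set.seed(2)
model <- build_outcome_model(amp, config = cfg)
res <- run_locus_pipeline(amp, model, cfg, seed = 11)
s <- res$samples[["48"]]
s
#> <sample_table> sim_amp [donor_absent, t=48h]: 5000 reads, 32 alleles, efficiency 0.380
head(relative_frequencies(s)[, c("signature", "share", "repair_class",
                                 "subtype")], 5)
#>   signature      share repair_class        subtype
#> 1   I:119:T 0.26923077         NHEJ +T duplication
#> 2 D:119-120 0.05742887         NHEJ             -1
#> 3   I:120:A 0.05268704         NHEJ             +A
#> 4 D:101-116 0.05163330         MMEJ   MH=4 del -15
#> 5 D:116-122 0.04162276         MMEJ    MH=2 del -6
```

38% of reads are edited (the locus's editable fraction was 0.4, minus
sampling), the +T duplication is the top pattern at 26.9% of edits
(the generator's calibrated share for a −4 T in T cells is 27%), and the
MMEJ deletions carry their junction microhomologies in the `subtype` label.
Adding an HDR donor and comparing matched samples:

```r
donor <- donor_spec("GGATCCGTTAACTAG")
set.seed(3); m1 <- build_outcome_model(amp, donor = donor, config = cfg)
r1 <- run_locus_pipeline(amp, m1, cfg, seed = 22)
competition_delta(res$samples[[1]], r1$samples[[1]])
#>          bin share_no_donor share_donor      delta
#> 1         -1     0.04936061  0.04413856 -0.1057939
#> 2 -10 to -30     0.35682864  0.10366721 -0.7094762
#> 3   -6 to -9     0.14542199  0.04464649 -0.6929867
#> 4         +1     0.44838875  0.40674523 -0.0928737
```

The donor removes ~71% of the long (−10 to −30) MMEJ share at this locus but
under 10% of the +1 NHEJ share — the kinetic competition in action.

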