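# extscan

Identification and classification of **extensins (EXTs)** — plant
cell-wall hydroxyproline-rich glycoproteins — in predicted proteomes.

EXTs are defined by repeated **Ser-Pro₍ₙ₎ motifs** (a serine followed by
n ≥ 3 prolines; the prolines are hydroxylated and glycosylated in vivo)
and often carry **Tyr-X-Tyr (YXY)** cross-linking motifs. extscan screens
an amino-acid FASTA for candidates with two or more SP_n runs, gathers
motif, structural-region and domain-homology evidence, and assigns each
candidate to one of seven classes — classical, short (< 200 aa), LRX
(leucine-rich repeat extensin), PERK (extensin-like receptor kinase), FH
(formin-homolog), long chimeric (> 2,000 aa) and other chimeric — or
calls it a *potential EXT*. It also computes the class-level statistics
of interest in comparative surveys: the class census, pooled
SP₃/SP₄/SP₅₊ repeat-type frequencies, and mean YXY counts in classical
vs non-classical EXTs.

Everything runs offline: signal peptides, transmembrane segments and GPI
ω-sites come from documented heuristics (with a TSV adapter so real
SignalP/big-PI output can override them), and the BLAST evidence step is
replaced by exact Smith–Waterman alignment (BLOSUM62, affine gaps 11/1)
against a bundled, user-replaceable reference set. A seeded synthetic
proteome generator with planted ground truth makes the entire pipeline
testable without downloads. See `vignettes/extscan-methods.Rmd` for the
model, parameter defaults and design rationale.

## Worked example

Scan a bundled stand-in sequence (constructed to the published
per-protein counts of the *B. distachyon* classical EXT Bradi3g10280 —
files under `inst/extdata/` are labelled synthetic):

```r
library(extscan)
prot <- read_proteome(system.file("extdata",
          "worked_examples_synthetic.fasta", package = "extscan"))
prof <- motif_profile(prot$sequence[1], prot$id[1])
prof$counts
#>           SP3           SP4       SP5PLUS           YXY AGP_DIPEPTIDE
#>            11             3             0             0             0
#>        CUSTOM
#>             0
is_candidate(prof)
#> [1] TRUE
nrow(scan_pattern(prot$sequence[1], "QAAA"))
#> [1] 19
```

11 SP₃ and 3 SP₄ runs (so ≥ 2 SP_n runs: a candidate EXT) and 19 QAAA
repeats — the counts reported for this protein.

Run the full pipeline on a synthetic proteome with planted truth:

```r
sim <- generate_proteome(generator_spec(seed = 1))   # 100 proteins
tab <- classify_proteome(sim$records)
class_census(tab)
#> Proteins screened: 100
#> Candidates (>= 2 SP_n runs): 80
#> Determined EXTs: 70
#>   CLASSICAL       10
#>   SHORT           10
#>   LRX             10
#>   PERK            10
#>   FH_EXT          10
#>   LONG_CHIMERIC   10
#>   OTHER_CHIMERIC  10
#>   POTENTIAL       10
#>   NON_EXT         20
round(spn_frequencies(tab), 3)   # pooled over classical EXTs
#> f_sp3 f_sp4 f_sp5
#> 0.233 0.662 0.104
round(mean_yxy(tab), 1)
#>    mean_classical mean_nonclassical
#>              16.9               2.1
```

All 100 planted labels are recovered; SP₄ dominates the repeat pool
(66%, inside the 56–80% range reported for classical EXTs across
genomes) and YXY motifs concentrate in classical EXTs (mean 16.9 vs 2.1),
the generator's rendering of the published contrast.

## Command line

```sh
Rscript -e 'extscan::ext_cli()' simulate  --outdir sim --seed 1
Rscript -e 'extscan::ext_cli()' scan      --input sim/synthetic_proteome.fasta --outdir scan
Rscript -e 'extscan::ext_cli()' classify  --input sim/synthetic_proteome.fasta --outdir cls
Rscript -e 'extscan::ext_cli()' summarize --input cls/classification.tsv --outdir sum
```

`scan` writes a per-protein motif TSV and a GFF3 motif track; `classify`
writes the classification TSV (id, label, lengths, motif counts, region
and homology evidence, rule trace); `summarize` writes the census and
statistics report. Every run writes a `manifest.json` with the tool
version, config hash and input checksums. Thresholds come from
`--config key=value` files mirroring `classifier_config()`.

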