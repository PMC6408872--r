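# amatox

Genome mining and molecular-evolution analysis of the amanitin biosynthesis
genes of lethal mushrooms (*Amanita*, *Galerina*, *Lepiota*).

α-Amanitin is a ribosomally synthesized bicyclic octapeptide. Its pathway
needs two genes: an MSDIN-family gene encoding a short precursor peptide
(leader | core | follower, the core flanked by prolines) and a prolyl
oligopeptidase (*POPB*) that cleaves the precursor at both prolines and
macrocyclizes the 7–10-residue core. The pathway occurs in three distantly
related agaric families — the classic fingerprint of horizontal gene
transfer (HGT). `amatox` implements the full analytical chain for making
that argument from an assembled genome:

* **Mining** — a leader-peptide PWM scan over six-frame ORFs (optionally
  spliced across one GT..AG intron) finds MSDIN genes; a splice-aware
  dynamic-programming aligner (Rcpp) reassembles multi-exon POP gene models
  from a homolog CDS; gene models export as GFF3.
* **Genotype → chemotype** — elemental formulas and monoisotopic masses of
  cyclic cores with the amatoxin modification set (tryptathionine −2H, four
  hydroxylations and a sulfoxide, +5O), matched to MS1 peaks at
  |ppm| = 10⁶·(obs−calc)/calc ≤ 10.
* **HGT evidence** — monophyly/bipartition conflict against the species
  tree; the approximately-unbiased (AU) test via multiscale RELL bootstrap
  (scales 0.5–1.4, AU = 1 − Φ(d − c) from the fit
  qnorm(1 − BP_r) = d√r + c/√r); duplication–loss vs
  duplication–transfer–loss reconciliation (undated DP; Notung costs
  1.5/3.0/1.0); NG86 dN/dS with Jukes–Cantor correction and
  housekeeping/toxin distance ratios.
* **Synthetic data** — seeded generators (planted toxin genes, species/gene
  trees with transfers, GTR+Γ sequence evolution, noisy peak lists) so
  every stage is testable against known truth.

## Worked example

The mined *Lepiota* precursor decomposes under the proline rule, and its
cyclic core plus the amatoxin modification set reproduces the α-amanitin
mass chemistry:

```r
library(amatox)

extract_core("MDANATRLPIWGIGCNPWTPESVNDTLTKDLS")
#> MSDIN precursor (32 aa): MDANATRLP | IWGIGCNP | WTPESVNDTLTKDLS  core 10-17

f <- apply_mods(peptide_formula("IWGIGCNP", "cyclic"), mod_set("amatoxin"))
format_formula(f)
#> [1] "C39H54N10O14S"
monoisotopic_mass(f)
#> [1] 918.3542
adduct_mz(monoisotopic_mass(f))     # [M+H]+, hydrogen-atom convention
#> [1] 919.362
```

The core is the octapeptide released between the leader's terminal proline
(residue 9) and the next proline (residue 17); its decorated cyclic formula
C39H54N10O14S has neutral monoisotopic mass 918.3542 Da and a singly
protonated ion at m/z 919.3620 — a measured peak at 919.3614 matches it at
−0.65 ppm, well inside the 10 ppm window.

Reconciliation against a species tree separates transfer from
duplication-plus-loss:

```r
st  <- parse_newick("((A,B),C);")
gt  <- parse_newick("((a,c),b);")   # gene tree conflicting with the species tree
map <- c(a = "A", b = "B", c = "C")
compare_models(gt, st, map)$dl
#> DL reconciliation: score 4.5 (dups 1, transfers 0, losses 3)
compare_models(gt, st, map)$dtl
#> DTL reconciliation: score 3.0 (dups 0, transfers 1, losses 0; optimal solutions 1)
```

A single transfer (score 3.0) beats duplication plus three losses
(score 4.5), so the conflict is HGT-favored.

End-to-end runs go through `run_pipeline()`, which takes a YAML config (or
list) naming the stage inputs and writes a machine-readable `report.json`;
see `vignettes/amatox-methods.Rmd` for the models, parameter choices and
their rationale.

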