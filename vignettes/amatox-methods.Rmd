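---
title: "Mining and evolutionary analysis of amanitin biosynthesis genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining and evolutionary analysis of amanitin biosynthesis genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amatox)
```

# The scientific problem

Lethal agarics in three distantly related genera — *Amanita*
(Amanitaceae), *Galerina* (Strophariaceae) and *Lepiota* (Agaricaceae) —
produce α-amanitin, a bicyclic octapeptide that inhibits RNA polymerase II.
The toxin is ribosomally synthesized: a short MSDIN-family gene encodes a
25–45 aa precursor peptide (leader | core | follower), and a specialized
prolyl oligopeptidase (POPB) cleaves the precursor at its two prolines and
macrocyclizes the 7–10 aa core. The disjunct taxonomic distribution of this
two-gene pathway is the classic signature of horizontal gene transfer
(HGT).

`amatox` implements the complete analytical chain used to argue that case
from an assembled genome:

1. **Genome summary** — contig N50/N90, GC content, GC-skew tracks.
2. **Gene mining** — a leader-peptide profile scan over six-frame ORFs
   (optionally spliced across one GT..AG intron) finds MSDIN candidates; a
   splice-aware aligner reassembles multi-exon POP gene models from a
   homolog CDS.
3. **Genotype → chemotype** — the mined core is turned into an elemental
   formula and monoisotopic mass (with amatoxin modifications) and matched
   against MS1 peaks at ppm tolerance.
4. **HGT evidence** — monophyly and bipartition conflicts against the
   species tree; the approximately-unbiased (AU) topology test on
   constrained alternatives; duplication–loss (DL) versus
   duplication–transfer–loss (DTL) reconciliation; NG86 dN/dS and
   housekeeping/toxin distance ratios.
5. **Synthetic data** — seeded generators for every input, so each stage is
   testable against known truth without downloads.

# Peptide chemistry

A linear peptide's formula is the sum of its in-chain residue formulas plus
one water; head-to-tail cyclization removes that water. The amatoxin
decoration is applied as a named modification set: the tryptathionine
Trp–Cys bridge (−2 H), four hydroxylations (+4 O) and one sulfoxide (+1 O),
i.e. a net −2H +5O. Applied to cyclo(IWGIGCNP) this yields
C~39~H~54~N~10~O~14~S:

```{r}
f <- apply_mods(peptide_formula("IWGIGCNP", "cyclic"), mod_set("amatoxin"))
format_formula(f)
monoisotopic_mass(f)
```

The modification set is fixed by formula arithmetic, not inferred
biochemistry: it is exactly the elemental difference between the unmodified
cyclic core (C~39~H~56~N~10~O~9~S) and the α-amanitin formula.

Two numerical conventions matter:

* **Adduct mass.** `adduct_mz()` adds the hydrogen-*atom* monoisotopic mass
  (1.0078250 Da) per charge by default, which reproduces the conventional
  reported \[M+H\]^+^ arithmetic for these toxins; the physically stricter proton
  mass (1.0072765 Da) is available via `proton = TRUE`. The two differ by
  one electron mass (≈ 0.5 ppm at *m/z* 919), below a 10 ppm matching
  tolerance either way.
* **Match tolerance.** `match_peaks()` uses |ppm| ≤ 10 by default, the
  conventional high-resolution MS1 criterion. Every (peak, candidate) pair
  within tolerance is reported; nothing is greedily assigned.

# MSDIN mining

The leader peptide is the conserved part of an MSDIN precursor (MSDIN in
*Amanita*, MFDTN in *Galerina*, M-DAN in *Lepiota*), so the miner is a
position weight matrix over the first `leader_len` residues (default 5),
trained with a Laplace pseudocount and scored in log2-odds bits against a
uniform background. The reporting threshold is the minimum training-set
score minus a 1-bit margin — permissive enough for one-residue drift,
strict enough that random GC-matched sequence essentially never passes
(tested property: ≥ 96 % of random contigs yield zero hits).

`extract_core()` implements the POPB cleavage rule: the core is the 7–10 aa
segment between the leader's terminal proline and the next proline,
inclusive. When several proline pairs qualify, the pair whose leader length
is closest to 9 wins (ties to the shorter leader, then the nearer
downstream proline); 9 is the canonical leader length in this family.

`scan_orfs()` translates every ATG..stop reading frame on both strands,
optionally re-assembled across one canonical GT..AG intron (default length
40–200 bp; fungal introns are short), and keeps candidates that pass the
leader threshold *and* decompose under the proline rule. A genuine
intron-bearing gene usually supports several spliced interpretations with
identical leader scores — without transcript or homolog evidence these are
genuinely indistinguishable, so the miner reports all distinct candidate
models, ranked by score, then by precursor length closest to the canonical
34 aa, then by position; `mine_loci()` groups them into loci. Exact exon
boundaries are subsequently fixed the way gene structures are determined in
practice: by aligning a CDS against the locus with `spliced_align()`.

`spliced_align()` is an affine-gap semi-global dynamic program (CDS aligned
end-to-end, genomic flanks free) with an intron state that opens only at
GT, closes only at AG, costs a fixed penalty (default −10) and nothing per
base, with a minimum intron length (default 40 bp). No maximum intron
length is enforced by the recursion; the penalty structure makes spurious
giant introns unprofitable. Ties prefer the leftmost intron start, making
the output deterministic. The implementation is in C++ (Rcpp); an
exhaustive intron-placement enumeration verifies it on small instances in
the test suite.

# Phylogenetic machinery

Distances (`nucleotide_distance()`, JC or K80 with pairwise deletion),
neighbor joining, and GTR+Γ(+I) likelihood (`log_likelihood()`,
`optimize_ml()`) delegate to the standard implementations in `ape` and
`phangorn` behind stable package interfaces; the test suite independently
verifies the likelihood against brute-force summation over ancestral states
on small trees. The discrete gamma uses 4 mean-of-quantile categories, the
common RAxML/MrBayes convention. Gaps are missing data. Tree search is NJ +
NNI hill-climbing (`nni_search()`) with optional clade constraints that are
never violated during search — a deliberate simplification of full
ML search; on the simulation scales used here (8 taxa, ≥ 2000 sites) it
recovers the generating topology reliably, and the AU test consumes fixed
candidate topologies anyway.

# The AU test

`rell_bootstrap()` resamples site log-likelihood columns at Consel's ten
canonical scale factors 0.5–1.4 (B replicates per scale, default 10,000;
ties for the per-replicate maximum are split equally).
`au_pvalue()` fits the multiscale curve qnorm(1 − BP~r~) = d√r + c/√r by
weighted least squares (weights from the binomial variance of BP) and
returns AU = 1 − Φ(d − c). Degenerate cases follow the boundary rules: BP
identically 1 → AU 1; identically 0 → AU 0; fewer than three informative
scales → the proportion nearest scale 1, with a warning. Under the
symmetric two-tree null the rejection rate at α = 0.05 calibrates to
0.04–0.05 in simulation (the acceptance suite re-runs this with 1000
replicates, B = 1000, 300 sites). Published AU values of order 10^−86^ are
beyond any finite bootstrap's resolution; what this implementation
reproduces is the decision pattern — best tree AU ≈ 1, constrained
alternatives rejected.

# Reconciliation

`lca_reconcile_dl()` is the classical LCA mapping (optimal for
duplication–loss costs): a gene node is a duplication when it maps to the
same species vertex as one of its children; losses are counted from the
depth differences along each child's mapping path, minus one traversed
speciation for speciation nodes.

`dtl_reconcile()` is a dynamic program over gene nodes × species vertices
on an *undated* species tree. Events: speciation (free), duplication,
transfer — the recipient may be any vertex incomparable to the donor (no
ancestor/descendant transfers) — and one loss per species edge a gene
lineage descends through without its sister copy. Default costs are the
Notung defaults (duplication 1.5, transfer 3.0, loss 1.0), which also
reproduce the published score arithmetic (5 dups + 31 losses → 38.5;
5 transfers + 9 losses → 24.0). Ties prefer fewer transfers, then a fixed
vertex order; the count of cost-co-optimal solutions is reported. The DP is
verified against exhaustive scenario enumeration on all 5-leaf gene × 3-leaf
species instances and sampled 4 × 4 instances.

# Rates and distance ratios

`ng86()` implements Nei–Gojobori (1986) counting: per-position synonymous
site fractions (changes to stop codons count as nonsynonymous), difference
counts averaged over all orderings of multi-position codon changes with
paths through stops discarded (falling back to unrestricted paths in the
rare all-blocked case), Jukes–Cantor correction, and saturation flags at
p ≥ 3/4. This substitutes a counting estimator for codeml's ML estimates;
the downstream claims it supports are ratio and ordering claims (dS ≫ dN;
housekeeping distances 2–6× toxin-gene distances), which are robust to that
choice. `genus_distance_ratios()` computes mean cross-genus corrected
distances per locus and the housekeeping/toxin fold ratio — near 1 for
vertical inheritance, ≫ 1 when the toxin locus moved recently.

# Synthetic data: what it emulates, and what it does not

All generators are pure functions of their parameters and a seed.

* `plant_msdin_contig()` — iid background DNA at a target GC (default 0.49,
  the assembly-level value for this genome), GC-biased reverse translation,
  one optional GT..AG intron (default 40–120 bp) at a uniform position in
  the CDS, random strand and position. Followers are sampled without
  prolines so the planted decomposition is unique; real followers can
  contain prolines, which the leader-length prior resolves. No repeats,
  no codon-usage table, no UTRs: composition is all the miner sees, so
  composition is all the generator models.
* `simulate_gene_tree()` — chronological birth–death of gene lineages
  inside an ultrametric Yule species tree. Transfers are *replacing*
  (the resident copy dies), matching the single-copy observation for POPB,
  and recipients exclude the donor's direct sister branch: a replacing
  sister transfer is topologically identical to vertical descent, and the
  HGT being emulated crosses families. Truth distinguishes all events from
  *surviving* events (a later transfer can erase an earlier one);
  recovery claims are scored against surviving events.
* `evolve_codon_pair()` — a minimal ω-scaled codon process (single-
  nucleotide steps, stops forbidden), adequate for testing a counting
  estimator, not a substitute for a full codon model.
* `synth_peaks()` — Gaussian ppm noise (default σ = 2 ppm, comfortably
  inside the 10 ppm match window) plus uniform decoys excluded from ±3σ
  windows around true masses.

Passing tests on these generators shows the algorithms are correct under
their stated models; it does not certify performance on real genomes with
repeats, misassembly, non-canonical splice sites or RT drift in mass
calibration.

# Problem sizes used by the test suite

Simulation sizes are the package's own choices, balancing statistical
resolution against run time: miner recovery uses 100 contigs of 1.5 kb;
the AU acceptance check uses 8 taxa × 5000 sites × 20 seeds with B = 2000
per scale, and the null calibration 1000 replicates at 300 sites with
B = 1000; reconciliation recovery uses a 10-taxon species tree across 60
seeds, and the study-scale check a 31-taxon tree; distance-ratio replay
uses 6 taxa × 1000 sites × 100 seeds; DP-versus-brute-force enumeration
covers all 105 five-leaf gene topologies against all three-leaf species
topologies, plus sampled 4 × 4 instances.

Two design details of the AU and ratio checks deserve a note. First, the
AU check's generating trees have their internal branches floored at 0.05
substitutions/site and its rival topologies are pairwise distinct: an NNI
alternative across a near-zero internal branch is statistically equivalent
to the truth, and an unbiased topology test *should not* reject it, so
rejection can only be demanded of alternatives that cross an identifiable
branch. Second, the distance-ratio replay places the housekeeping locus at
realistic rpb2-scale divergence (cross-genus path distances 0.30–0.57
substitutions/site) and the transferred toxin locus at 0.11–0.13, giving
true fold-ratios of 2.7–4.4 — inside the 2–6× band reported for these
genera; saturated housekeeping distances would make the Jukes–Cantor
estimator, not the biology, the limiting factor.

# Known limitations

* Only coding-region introns are modeled; UTR exons require transcript
  evidence and are out of scope.
* Bayesian posteriors are not reproduced; nonparametric bootstrap supports
  stand in where supports are needed.
* The DTL model is undated; time-consistency of transfer scenarios is not
  enforced, as in common undated reconciliation practice.
* Amino-acid model likelihoods are not part of the supported surface; the
  analyses here run on nucleotide alignments.
* I and L share an elemental formula and are indistinguishable by mass.
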