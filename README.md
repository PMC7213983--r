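# calgevo

Desk-scale analysis toolkit for studying how the calgranulin family of
innate-immune proteins (S100A8, S100A9, S100A12 and the avian MRP126)
evolved its functional repertoire: antimicrobial activity of the A8/A9
heterocomplex, pro-inflammatory TLR4 activation by A9, and resistance to
proteolytic degradation. The package implements the computational layer of
such a study — ancestral sequence reconstruction robustness analysis,
gel-densitometry proteolysis kinetics, equilibrium unfolding thermodynamics,
and the two functional-assay normalizations — together with synthetic-data
generators that carry known ground truth, so every stage can be exercised
and validated without laboratory data.

## Who this is for

Molecular evolutionists and protein biochemists who want a tested,
scriptable version of the standard analyses around ancestral protein
resurrection: checking how robust a reconstructed ancestor is to statistical
and topological uncertainty, mapping a binary phenotype onto a phylogeny by
parsimony, and fitting the kinetic and thermodynamic models used to
characterize resurrected proteins.

## The models

**Marginal ancestral reconstruction.** For a rooted tree with branch lengths
in expected substitutions/site, per-site marginal posteriors
P(ancestral state a | tip data) are computed at every internal node by the
pruning (inside/outside) recursion under a 20-state equal-rates amino-acid
model with uniform equilibrium frequencies (optional discrete-gamma rate
mixing). The ML ancestor takes the argmax state per site.

**altAll alternative ancestors.** At every site where the second-best state
has posterior probability strictly greater than 0.20, that state is
substituted into the ML sequence, producing a "worst-case" ancestor whose
phenotype can be compared with the ML ancestor's.

**Topology robustness.** All (2n−3)!! rooted binary leaf-labeled topologies
over a set of clades are enumerated in canonical Newick form (15 for the
four calgranulin clades), and per-topology ancestors are compared with the
reference by Hamming distance and by whether their differing sites fall
inside the ML-vs-altAll set.

**Fitch parsimony.** Minimum state changes and compatible ancestral state
sets for a binary trait (e.g. proteolytically resistant vs susceptible)
via the intersection/union bottom-up pass.

**Proteolysis kinetics.** Fraction of intact protein from gel densitometry
(linear flanking-background subtraction, normalization to the undigested
t = 0 band) is fit globally across replicates as f(t) = A₀·e^(−kt);
parameter uncertainties are square roots of the covariance diagonal.

**Two-state unfolding (linear extrapolation model).**

    y(x) = [b_f + m_f·x + (b_u + m_u·x)·K(x)] / [1 + K(x)],
    K(x) = exp(−(ΔG − m·x)/RT)

with R = 0.001987 kcal·K⁻¹·mol⁻¹, T = 298.15 K, midpoint C_m = ΔG/m, and
sd(C_m) from the (ΔG, m) covariance. Unfolding kinetics after a denaturant
spike are fit as a single exponential with a dead-time flag.

**Assay normalizations.** Growth inhibition = 100 × (OD_treated −
OD_blank)/(OD_untreated − OD_blank) at 7 h (or 12 h); NF-κB induction =
(r − r_LPS+PB)/(r_LPS − r_LPS+PB) with r = firefly/renilla, so LPS maps to 1
and LPS + polymyxin B to 0 on every plate.

## Worked example

```r
library(calgevo)

tree <- ape::read.tree(text = "((A:0.05,B:0.05):0.05,(C:0.05,D:0.05):0.05);")
sim  <- simulate_msa(tree, 100, seed = 1)      # known true ancestors
rec  <- marginal_asr(tree, sim$alignment)
rec
#> Marginal ASR result: 3 internal node(s), 100 sites, 0 gap site(s) skipped

build_altall(rec$posteriors[["node5"]], rec$ml[["node5"]])
#> Ancestor reconstruction (100 sites)
#>   average posterior probability of ML states: 0.946
#>   altAll substitutions (PP > 0.2): 8 site(s)

d <- simulate_decay_data(k = 0.3, times = seq(0, 10, length.out = 10),
                         seed = 1)
fit_exponential_decay(d)
#> Exponential decay fit: A0 = 1.026 +/- 0.01, k = 0.3094 +/- 0.0053 /min (n = 30)

den <- simulate_denaturation(dG = 8, m = 1.6, seed = 1, noise_sd = 0.15)
fit_two_state(den$x_molar, den$signal_mdeg)
#> Two-state unfolding fit: dG = 8.198 +/- 0.223 kcal/mol,
#>   m = 1.630 +/- 0.045 kcal/mol/M, Cm = 5.029 +/- 0.013 M
```

The average posterior probability (0.946) is the mean over sites of the ML
state's posterior — the standard confidence summary for a reconstruction.
The 8 altAll substitutions are the sites ambiguous enough (runner-up
PP > 0.20) that a worst-case ancestor differs there. The decay fit recovers
the generating rate 0.3 min⁻¹ within its reported uncertainty, and the
unfolding fit recovers ΔG = 8 kcal/mol, m = 1.6 kcal·mol⁻¹·M⁻¹ and the
midpoint C_m = ΔG/m = 5 M.

Whole-pipeline runs are driven by a config:

```r
run_pipeline(default_config(outdir = "run1", seed = 1))
```

writing per-stage CSVs, `summary.json` and a log; a thin CLI wrapper lives
at `inst/cli/calgevo.R`.

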