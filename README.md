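# mutmech

Pathogenicity scoring and molecular-mechanism inference for missense
variants (amino acid substitutions), with positive-unlabeled (PU)
machine learning throughout.

## Who this is for

Computational biologists and method developers who want a desk-scale,
fully self-contained implementation of the modeling framework behind
ensemble missense pathogenicity predictors: no external corpora,
alignments or web services are required — a synthetic-fixture module
generates realistic stand-ins for every input, so the whole pipeline
builds, trains and tests offline.

## The model

Given a protein sequence *s* and a substitution *XiY* (residue *X* at
1-based position *i* replaced by *Y*):

**General score.** Six categories of features are extracted for
(*s*, *XiY*): sequence context, substitution deltas over fixed
physicochemical scales, PSSM-derived scores, predicted conservation,
homolog count profiles, and changes in predicted structural/functional
properties. After two-sample *t*-test feature selection (*p* < 0.01),
z-scoring and PCA at 99% retained variance, a bagged ensemble of 30
feed-forward networks (one hidden layer of 4 tanh units, tanh output
rescaled to [0,1]) is trained with resilient propagation, each member on
a class-balanced bootstrap with a 25% validation holdout and stopping
rules (optimal epoch / 1000 epochs / 500 validation checks). The general
score is the mean of the 30 member scores.

**Property scores.** For each protein property *p* (PTM sites, secondary
structure, binding, ...), a PU window classifier scores positions
*i* − 5 … *i* + 5 on the wild-type and on the mutated sequence; raw
scores become posteriors Pr(*P* = 1 | ·) by Elkan–Noto scaling plus a
prior-matching adjustment. Then

    Pr(loss of p | s, XiY) = Pr(P=1 | s) · (1 − Pr(P=1 | s_XiY))
    Pr(gain of p | s, XiY) = (1 − Pr(P=1 | s)) · Pr(P=1 | s_XiY)

The property score is max(loss, gain); with uninformative posteriors
(both 0.5) it equals 0.25, the baseline for implicating the property.
Each call carries an empirical p-value (*r* + 1)/(*n* + 1) against a
pool of scores from putatively neutral substitutions, and calls are
ranked by descending property score.

**Supporting machinery.** Mann–Whitney ROC/AUC with a two-sided
label-noise correction `(A_obs − (ρ⁺+ρ⁻)/2) / (1 − ρ⁺ − ρ⁻)`;
CD-HIT-style greedy identity clustering and per-cluster k-fold CV;
a 25-residue fragment redundancy filter; AlphaMax-style mixture
proportion (class prior) estimation from score distributions; FPR-
calibrated thresholds and the enrichment statistic
E = (d_f − n_f)/(d_f + n_f) with one-sided Fisher tests and
Benjamini–Hochberg correction.

## Worked example

```r
library(mutmech)

# a fully synthetic world: proteome, planted property sites, variants
cfg <- fixture_config(n_proteins = 40L, length_mean = 150,
                      n_pathogenic = 120L, n_unlabeled = 240L, seed = 202L)
fx  <- generate_fixture(cfg)

bundle <- train_bundle(fx$proteins, fx$variants, fx$sites,
                       seed = 202L, n_members = 5L)

# variant 3 is a planted pathogenic substitution that destroys a
# phosphorylation-like S[TP] motif
fx$variants[3, c("protein_id", "token", "label")]
#>   protein_id token      label
#> 3    prot015   S7W pathogenic

rep <- predict_variants(bundle, fx$proteins, fx$variants[3, , drop = FALSE])[[1]]
rep$general_score
#> [1] 0.9737781
head(rep$mechanisms, 3)
#>          property direction property_score empirical_p focal_position
#> 1 phosphorylation      loss    1.000000000  0.07883817              7
#> 2          strand      gain    0.016846361  0.08298755              9
#> 3   glycosylation      gain    0.005143421  0.14107884              7
```

The variant gets a general score near 1, and the top-ranked mechanism
is exactly the planted one: loss of the phosphorylation-like property
at the substituted position, with a property score of 1.0 — far above
the 0.25 baseline at which a property is considered implicated. The
noise-corrected AUC of an observed AUC of 0.877 under 2.8%/5.8% label
noise:

```r
100 * corrected_auc(0.877, 0.028, 0.058)
#> [1] 91.24726
```

## Command line

```sh
mutmech simulate --seed 5 --out-dir fx
mutmech train    --fasta fx/proteome.fasta --variants fx/variants.tsv \
                 --sites fx/sites.tsv --model model.rds --seed 5
mutmech predict  --fasta fx/proteome.fasta --variants fx/variants.tsv \
                 --model model.rds --out report.tsv
```

Also available: `evaluate` (per-protein or per-cluster k-fold CV),
`estimate-priors` (mixture proportions from score files), `enrich`
(top-3 mechanism case/control comparison).

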