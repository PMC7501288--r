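# absomics

Absolute multi-omics quantification for microbial communities: convert
relative metatranscriptomic and metaproteomic measurements into absolute
molecule counts per sample, integrate the two layers per
metagenome-assembled genome (MAG), and quantify how protein levels track
RNA levels over a community's life cycle.

The package is aimed at microbiome researchers who have MAG-resolved
expression tables — spike-in-normalized RNA-seq read counts and label-free
(LFQ) protein intensities — and want population-level answers in absolute
units: how many transcript and protein molecules per sample, what is the
protein-to-RNA ratio of each population, and how linearly does the
proteome follow the transcriptome over time.

## The quantification model

**Transcripts (RNA spike-in).** A known dose of an internal-standard
transcript (I_M molecules of length I_Nt) is added to a fixed aliquot of
each sample before extraction. Read yield is proportional to nucleotide
mass, so the total transcriptome size follows from the spike-in's read
share, and RPKM converts to molecules:

    ΣT_Nt = I_M × I_Nt × ΣT_R / I_R
    T_M,i = (RPKM_i / 10⁹) × ΣT_Nt

with ΣT_R the transcriptome-mapped reads and I_R the spike-in reads.
Aliquot counts are multiplied by the aliquot factor (10 for a 6 ml aliquot
of a 60 ml sample) to reconstruct the whole-sample count.

**Proteins (total protein approach).** LFQ intensities become mass
fractions, molar fractions through the molecular weight, and copy numbers
through the sample's protein mass:

    Total protein_i  = LFQ_i / ΣLFQ
    Concentration_i  = Total protein_i / MW_i          [mol/g]
    Copy number_i    = Concentration_i × Detected protein mass × N_A

The Bradford assay measures *all* protein, but only the identified MS
signal is quantified, so the total mass is corrected by the
intensity-weighted mass share of identified peaks:

    Detected mass = Total mass × Σ_id (BPI_i × Mass_i) / Σ_all (BPI_j × Mass_j)

**Integration and dynamics.** ORFs are grouped at 100 % sequence identity
(ORF-groups); entries with zero unique hits are removed, values are
log10(x+1)-transformed, minimum-expression thresholds applied (10⁵
transcripts, 10⁸ proteins), outlier samples screened by PCA, and only
ORFs that are singletons in *both* layers are paired. On the paired data
the package computes protein-to-RNA ratio distributions per MAG, gene-wise
Pearson correlations of RNA and protein over time, per-time-point fits of
the monomial model

    Protein = a · RNA^k   ⇔   log₁₀(protein) = a + k·log₁₀(RNA)

whose slope k ("linearity") says how a change in RNA is reflected in
protein (k = 1: a doubling of RNA doubles protein; k = 0.5: a doubling of
RNA gives a ~40 % protein increase), cubic k(t) trajectories per MAG, and
Kendall τ-b rank preservation of KO functional-category abundances across
the metagenome, metatranscriptome and metaproteome.

A ground-truthed synthetic community generator
(`generate_community()`, `simulate_mt_observation()`,
`simulate_mp_observation()`) emulates the whole observation process —
log-normal expression, monomial RNA→protein coupling, multinomial read
sampling with spike-in, LFQ proportional to protein mass with partial
detection, a peak table with a controlled identified fraction — so every
stage is testable against known truth.

## Worked example

The `analysis/` scripts run the whole workflow on the default synthetic
community (7 MAGs — six bacterial, one archaeal methanogen — 150 ORFs
each, 7 time points 13–43 h in triplicate):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_quantify.R
Rscript analysis/03_integrate.R
Rscript analysis/04_dynamics.R
```

Stage 2 prints the per-sample totals recovered from the simulated raw
tables:

```
transcripts per sample: mean 5.81e+11 (range 5.28e+11 - 6.28e+11)
proteins per sample:    mean 2.64e+14 (range 1.52e+14 - 4.68e+14)
detected/total protein mass: 0.29 - 0.54
```

and stage 4 the population-resolved dynamics:

```
protein-to-RNA ratio medians at 18 h:
        mag_id n_genes    median
1        CLOS1     138  715.9316
2        COPR1     132  702.9803
3        METH1     131 7468.0226
...
8 all_bacteria     791  738.7552
gene-wise RNA-protein PCC: median 0.31 over 1007 ORFs
monomial fits: 49 MAG x time cells; k range 0.20 - 0.87
```

The bacterial populations sit at a few hundred protein molecules per
transcript while the archaeon (METH1) is an order of magnitude higher —
the domain-level contrast the ratio analysis is designed to expose. The
median gene-wise correlation of 0.31 shows that transcript changes
translate only weakly into protein changes, which is why the per-time
monomial fits (k well below 1, declining over time for most populations)
carry the dynamic signal. All tables land under `results/`.

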