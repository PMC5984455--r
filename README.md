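# epitempo

Temporal analysis of the m⁶A epitranscriptome from MeRIP-seq data.

N6-methyladenosine (m⁶A) is a reversible mRNA modification whose
deposition changes over developmental time. MeRIP-seq (m⁶A-seq)
measures it by sequencing an antibody-enriched (IP) library alongside
an input library: regions where IP coverage exceeds input coverage —
peaks — mark methylated transcript segments. `epitempo` implements the
comparative analyses such a study needs downstream of peak calling,
for a design with several developmental stages (here P7/P14/P21/P60)
in two conditions (wild type and demethylase knockout), one paired
IP/input library pair per stage and condition:

- **Read preprocessing** — adapter removal by locating `AGATCGGAAG`
  with at most two mismatched bases, 3′ trimming of bases below Q20,
  and retention of reads longer than 70 nt with more than 70% of bases
  above Q25.
- **Peak enrichment scoring** — for peak *i* in library *j*, with *A*
  IP reads on the peak, *B* total unique mapped IP reads, *C* the peak
  length, and *D*, *E* the input analogues:

  a = A·10⁹/(B·C)  (IP FPKM),  b = D·10⁹/(E·C)  (input FPKM),  c = a/b  (enrichment score)

  Reads are counted over peaks with coverageBed semantics (same
  strand, ≥ 50% of the read overlapping, split reads by block).
  Peaks are retained when FDR < 0.05, IP FPKM > 1 and enrichment
  score > 1.5 (all strict).
- **Temporal comparison** — a strand-aware merged peak atlas across
  stages (mergeBed semantics); ON switches (peak absent at a stage,
  present at the next) and OFF switches (the reverse); continuously
  methylated RNAs (CMRs, ≥ 1 retained peak at every stage) and
  stage-specifically methylated RNAs (SMRs, methylated at exactly one
  stage).
- **Differential methylation** — WT-vs-KO log₂ fold change of
  enrichment scores with Fisher's exact test and BH correction
  (hyper/hypo at FDR < 0.05 and |log₂FC| > 1), plus gain/loss calls
  for peaks methylated in exactly one condition.
- **Metagene profiles** — peak positions on the longest transcript of
  each gene; 5′UTR/CDS/3′UTR each split into 100 equal bins; and peak
  counts over five regions where the start and stop codon regions are
  300-nt windows centered on the codons.
- **Methylation–expression correlation** — per-RNA Pearson r between
  4-stage enrichment scores and FPKM; high-confidence pairs at
  |r| > 0.95 and P < 0.05 (expressed transcripts: FPKM > 0.2).
- **Synthetic data generator** — a MeRIP-seq simulator with planted
  methylation classes, enrichment factors, switching schedules,
  knockout perturbations and expression trajectories, used to validate
  every stage end to end.

## Worked example

```r
library(epitempo)

study <- simulate_study(sim_config(seed = 1))   # 1,000 genes, 4 stages, WT+KO
run <- run_pipeline(study)
print(run)
```

On the default study this prints (abridged):

```
  retained peaks per sample:
KO_P14 KO_P21 KO_P60  KO_P7 WT_P14 WT_P21 WT_P60  WT_P7
   546    554    500    505    555    561    508    504
  switches:            OFF  ON
            P14-P21    100 106
            P21-P60    104  51
            P7-P14      58 109
  classes:
   CMR  SMR:P7  SMR:P14  SMR:P21  SMR:P60  other  unmethylated
   353      53       49       54       42    209            0
  DMR categories:
   gain hyper  hypo  loss unchanged
     56    49    44    55       356
  correlation screen:  positive 76   negative 32
```

Each number is a recovered quantity over the synthetic study: per-stage
retained peaks, ON/OFF switch events per adjacent-stage transition,
RNA methylation classes, WT-vs-KO differential-methylation categories
at P7, and the count of RNAs whose expression tracks (or opposes)
their methylation across stages. Comparing against the planted truth:

```r
evaluate_recovery(run, study$truth)
# class_f1 0.92, switch_sensitivity 0.95, dmr_accuracy 0.99,
# region_recovery 1.00, spearman_factor_score 0.93, corr_sign_recovery 1.00
```

The numbered scripts under `analysis/` run the same steps as a
narrative workflow (simulation, preprocessing, quantification,
temporal classes and DMRs, metagene profiles, correlation screen) and
write their tables under `results/`.

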