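# echinoNMR

Chemometric analysis of ¹H NMR metabolomic profiles of sea urchin
(*Paracentrotus lividus*) gonads, in two arms:

* **Polar arm — sex discrimination.** Processed frequency-domain spectra of
  aqueous (polar) gonad extracts are windowed (11.0 to −0.5 ppm), referenced
  to TSP, masked (residual water, standard), and modelled by **PLS-LDA**:
  partial least squares latent variables computed with the NIPALS algorithm,
  followed by linear discriminant analysis on the latent scores. Model
  complexity and performance are assessed by stratified k-fold
  cross-validation and Monte Carlo cross-validation (misclassification
  error, sensitivity, specificity, rank-based AUC), with VIP scores
  summarizing variable influence. Candidate markers are then ranked by
  **Subwindow Permutation Analysis (SPA)** on the curated 72-resonance
  peak-height table: Monte Carlo PLS-LDA sub-models on random sample and
  variable subsets, each variable scored by a one-sided Mann–Whitney
  comparison of prediction errors with and without permuting its held-out
  values, reported as `COSS = −log10(p)` (p < 0.05 ⇔ COSS > 1.30).
* **Apolar arm — lipid indices.** Spectra of CDCl₃ (apolar) extracts are
  integrated over the diagnostic regions A–J and the narrow DHA-sensitive
  F′ window (2.37–2.40 ppm), and a balance-equation system converts the
  integrals into mol% of unsaturated (n), saturated (s), ω-3 (ω₃) and DHA
  (h) acyl chains: with T = (A+B)/3 total chains,
  `ω₃ = 100·A/(A+B)`, `h = 100·(F′/2)/T`, `n = 100·(E/4)/T`, `s = 100 − n`.
  Internal constraints (0 ≤ h ≤ ω₃ ≤ n ≤ 100, non-negative integrals,
  olefinic/allylic consistency) drive automated QC flagging; QC-filtered
  batches are summarized per sex (median/IQR, exact Mann–Whitney) and
  benchmarked against published fish-oil reference ranges.

Because raw cohort data of this kind are typically available only on
request, the package ships a first-class **synthetic spectrum generator**
(Lorentzian multiplets at the curated shifts, log-normal inter-individual
variation, per-sex fold changes, known lipid compositions) so that every
stage is testable against ground truth.

## Worked example

```r
library(echinoNMR)
rc <- run_config(mode = "full", seed = 42,
                 cohort = cohort_config(seed = 42, grid_points = 8192,
                                        noise_sd = 0.3),
                 A_max = 6, k = 7, mccv_reps = 100,
                 spa = spa_config(n_iter = 500, seed = 42))
rep <- run_polar_arm(rc)    # simulate 23 M / 14 F, model, validate, SPA
rep$cv; rep$mccv
head(rep$spa[order(-rep$spa$coss), ], 5)
```

```
<cv_result:kfold> optLV=1 error_min=0.0000 sens=1.0000 spec=1.0000 auc=1.0000 (n=37)
<cv_result:mccv> optLV=1 error_min=0.0275 sens=0.9300 spec=0.9980 auc=0.9953 (n=800)
 variable delta_ppm                  metabolite      p_value      coss selected
       33    3.5648                     Glycine 1.072094e-13 12.969767     TRUE
       32    3.5101  Choline-related (probable) 2.029226e-11 10.692670     TRUE
       25    3.2488 Trimethylamine oxide (TMAO) 1.572290e-10  9.803467     TRUE
       24    3.2298                     Betaine 1.343792e-06  5.871668     TRUE
        8    1.4715                     Alanine 7.757519e-06  5.110277     TRUE
```

The seeded glycine effect is recovered as the top-ranked marker (COSS ≈ 13),
the default synthetic cohort separates almost perfectly under validation
(MCCV error ≈ 2.8%), and 14 of the 72 curated resonances pass the nominal
p < 0.05 criterion. The neighbouring 3.5101 ppm feature ranks high because
its extraction window sits on the flank of the strong glycine singlet —
exactly the kind of crowded-region behaviour seen in real spectra.

```r
repa <- run_apolar_arm(rc)  # integrate, solve, QC, summarize
repa$summary$summary[, c("index", "median", "female_median", "male_median", "p_value")]
repa$summary$benchmark
```

```
   index    median female_median male_median      p_value
 n_unsat 63.820856     58.353392   66.664436 2.439668e-06
   s_sat 36.179144     41.646608   33.335564 2.439668e-06
  omega3 21.139172     19.390630   21.936556 5.200653e-06
     dha  1.783891      1.613371    1.865589 4.478500e-06
  index batch_median ref_low ref_high ref_median     position
    dha     1.783891     7.0     19.2       14.0  below_range
 omega3    21.139172    20.9     35.7       26.7 within_range
```

The recovered batch medians match the generating per-sex compositions, DHA
sits an order of magnitude below the fish-oil reference range while total
ω-3 overlaps its lower edge — the expected signature for sea urchin gonad
lipids.

A thin command-line wrapper is available at `inst/scripts/echino-nmr`
(subcommands `simulate`, `polar`, `apolar`, `full`; see `cli_entry()`).

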