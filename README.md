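# crkscan

Genome-wide identification and classification of cysteine-rich
receptor-like kinases (CRKs) — the plant receptor family defined by the
extracellular DUF26 domain (Pfam PF01657; Gnk2 / Stress-antifungal,
with the conserved C-X8-C-X2-C motif).

`crkscan` is aimed at plant comparative genomicists running gene-family
surveys from domain-scanner output. It takes protein FASTA, GFF3 gene
models and precomputed Pfam-Scan / InterProScan hit tables and
produces, per genome and across genomes:

* **Candidate identification** — every protein with a DUF26 hit passing
  the evidence rule (scanner significance flag, or E-value ≤ 1e-3;
  optional InterPro cross-validation against IPR002902/IPR038408).
* **Domain architectures** — overlapping scanner hits resolved to one
  ordered, disjoint architecture per protein (best hit by bit score →
  E-value → position → name; deterministic and idempotent).
* **Three class labels per gene**:
  1. *major class* — run-collapsed signature, e.g.
     `Stress-antifungal–Pkinase-tyr–DUF3403`;
  2. *subclass* — full repeat-aware signature, e.g.
     `Stress-antifungal__Stress-antifungal__DUF3403`;
  3. *nomenclature* — a reversible grammar name
     `⟨sd|dd|td|qd⟩⟨CRRSP|CRK|CRdK⟩⟨suffixes⟩`, where the prefix counts
     DUF26 repeats, the core records kinase content, and suffix letters
     encode decoy domains (D = DUF3403, F = FYVE, P = PRIMA1,
     S = sugar transporter, dS = doubled sugar transporter).
* **Protein statistics** — length, molecular weight (average masses),
  net charge (Henderson–Hasselbalch), isoelectric point (bisection of
  the monotone charge curve), Kyte–Doolittle GRAVY.
* **Genome organisation** — per-chromosome densities, tandem clusters
  (boundary gap ≤ 250 kb, ≤ 8 intervening genes, transitive closure),
  terminal-arm localization (midpoint within 25% of either end).
* **Cross-species summaries** — class × species count matrices, shared
  and species-specific classes, largest-class totals, orthogroup
  percentage arithmetic.

A synthetic-proteome generator with planted architectures, tandem
clusters and scanner noise (and independently computed truth labels)
makes the whole pipeline testable without downloading any proteome.

## Worked example

```r
library(crkscan)

# one protein: FYVE + two DUF26 repeats + a tyrosine kinase
arch <- toy_architecture(c("FYVE", "Stress-antifungal",
                           "Stress-antifungal", "Pkinase-tyr"))
classify_major(arch)
#> [1] "FYVE–Stress-antifungal–Pkinase-tyr"
classify_subclass(arch)
#> [1] "FYVE__Stress-antifungal__Stress-antifungal__Pkinase-tyr"
classify_nomenclature(arch)
#> [1] "ddCRKF"
```

The name reads: *dd* = two DUF26 repeats, *CRK* = kinase present,
*F* = FYVE decoy. `parse_nomenclature("ddCRKF")` recovers
`(2, CRK, F)`.

A full synthetic survey at the default study conditions (five species,
437 family genes) runs in a couple of seconds:

```r
r <- end_to_end_recovery(sim_config(seed = 42))
r[c("candidate_precision", "candidate_recall", "major_agreement",
    "subclass_agreement", "nomenclature_agreement", "clusters_recovered")]
#> all 1 — every planted label and cluster is recovered exactly

fs <- summarize_family(r$assignments, "major")
fs
#> <crk_family_summary> scheme: major | 9 classes x 5 species | grand total 437
largest_class_total(fs)
#> $class [1] "Stress-antifungal–Pkinase-tyr–DUF3403"   $total [1] 234
```

(With seed 42 the sampler draws 9 of the 11 template classes; the
kinase + DUF3403 class dominates, mirroring the configured class
frequencies.)

```r
compute_stats("MKVLLDERRKYACDEFGHIK")
#>   length molecular_weight   charge isoelectric_point  gravy
#> 1     20          2.45177 1.188321          8.521851 -0.715
```

A thin CLI wrapper is installed at `inst/cli/crkscan`
(`crkscan simulate|identify|classify|stats|clusters|summarize|all`),
writing stage TSVs plus a `manifest.json` that records parameters and
per-stage in/out counts.

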