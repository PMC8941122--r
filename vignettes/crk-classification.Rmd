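---
title: "Identifying and classifying DUF26 receptor-like kinases with crkscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying and classifying DUF26 receptor-like kinases with crkscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crkscan)
```

## The biological problem

Cysteine-rich receptor-like kinases (CRKs) are a plant receptor family
defined by one or more extracellular DUF26 domains (Pfam PF01657; also
called Gnk2 or Stress-antifungal), which carry the conserved
C-X8-C-X2-C cysteine motif and mediate antifungal and stress
responses.  A canonical CRK couples the DUF26 ectodomain to an
intracellular protein kinase; DUF26 proteins without a kinase are
secreted (CRRSPs).  Genome-wide surveys of the family proceed from
domain-scanner output (Pfam-Scan, InterProScan) rather than raw
sequence: every protein with acceptable DUF26 evidence is a family
candidate, its remaining domain hits define an ordered architecture,
and architectures are binned into classes.

`crkscan` implements that survey as a tested pipeline: candidate
filtering, overlap resolution, architecture building, three
classification schemes, protein physicochemical statistics,
chromosomal organisation (density, tandem clusters, terminal arms),
and cross-species summary tables — all driven either by real scanner
output or by a synthetic-proteome generator with planted ground truth.

## From scanner output to architectures

Hits arrive as a table of `(protein, domain, start, end, E-value,
bit score, significance)` rows, with every label normalized through a
configurable alias table (the literature mixes "DUF 26", "DUF26",
"Gnk2" and "Stress-antifungal" freely; all map to one canonical
label, and unknown labels map to `Other` with a warning rather than
being dropped).  Coordinates are 1-based inclusive throughout, the
convention shared by GFF3 and Pfam-Scan; interval arithmetic converts
transiently where needed.

**Candidate filter.** A protein is a CRK candidate when it carries at
least one Stress-antifungal hit passing the evidence rule: the
scanner's curated significance flag when available, otherwise an
E-value ceiling of `1e-3`.  The ceiling is deliberately conservative —
curated gathering thresholds are the scanner's own notion of
significance, and the E-value path only exists for tables that lack
the flag.  When InterPro evidence is present, candidates can further
be required to carry an accepted DUF26 accession (IPR002902 or its
superfamily IPR038408).  The default mode is `either`: requiring both
would reject proteins annotated under only one of the two entries,
and the two accessions describe the same domain at different
granularity.

**Overlap resolution.** Scanners routinely match one region twice.
Two hits conflict when their reciprocal overlap exceeds a fraction
(default 0.3) of the longer hit; among conflicting hits exactly one
survives, chosen by a total priority order — higher bit score, then
lower E-value, then leftmost start, then domain name — which makes
the output deterministic.  Small residual overlaps at or below the
fraction are treated as boundary jitter and trimmed from the
lower-priority hit (a hit fully consumed by trimming is dropped), so
the final architecture is strictly non-overlapping and the operation
is idempotent.

**Fragment merging is off by default.** `merge_fragmented()` can
bridge two same-domain hits separated by a short gap (its own default
bridges 30 residues), which repairs split HMM matches.  The pipeline
nevertheless does *not* apply it by default: with alignment
coordinates alone, a split fragment is indistinguishable from a
genuine tandem DUF26 repeat separated by a short linker, and repeat
counts are precisely what the subclass and nomenclature schemes
measure.  Collapsing a double-DUF26 architecture into a single-DUF26
one silently moves a gene from `ddCRK` to `sdCRK`.  Users who trust
their scanner's fragmentation behaviour can opt in via
`merge_max_gap`.

## The three classification schemes

Given an architecture — the N-to-C sequence of domain labels —
`crkscan` assigns three labels of increasing resolution.  Signal
peptide and transmembrane annotations, when present, are excluded
from all three: they define the CRK/CRRSP/PDLP topological split in
the wider literature, not the domain-content classes computed here.

1. **Major class** (`classify_major`): the label sequence with
   *consecutive* runs collapsed, joined with "–".  Collapse is
   run-wise, not full deduplication, because the family's class
   catalog itself distinguishes alternating patterns
   (`Stress-antifungal–Pkinase-tyr–Stress-antifungal–Pkinase-tyr`)
   from their collapsed counterparts — full dedup would merge classes
   the catalog keeps apart.
2. **Subclass** (`classify_subclass`): the full ordered sequence with
   all repeats, joined with `"__"`.  Scheme 2 therefore refines
   scheme 1 — equal subclass strings force equal major strings — and
   duplicating any element in place changes scheme 2 but never
   scheme 1 (both are property-tested).
3. **Nomenclature** (`classify_nomenclature`): a compact reversible
   name `prefix + core + suffixes`.  The prefix encodes the DUF26
   repeat count (`sd`/`dd`/`td`/`qd` for 1–4); the core is `CRRSP`
   (no kinase), `CRK` (canonical kinase present) or `CRdK` (canonical
   plus fungal-type kinase); each decoy domain appends one letter
   (`D` = DUF3403, `F` = FYVE, `P` = PRIMA1, `S` = sugar transporter,
   `dS` for a doubled sugar transporter) in N-to-C order of first
   occurrence.

Decisions where the naming convention is genuinely underdetermined:

* Repeat counts above four produce an explicit numeric prefix
  (`"5d"`, `"6d"`, ...) plus an `extended_prefix` flag instead of an
  error or an invented name — unexpected architectures should surface,
  not crash or masquerade.
* A fungal-type kinase *without* a canonical kinase yields `CRRSP`,
  since `CRdK` denotes the combination; such architectures are rare
  and visible through the subclass string.
* Decoy N-/C-terminal position is recorded in the assignment's
  `decoys` metadata but does not alter the name: the published class
  names themselves are not consistently side-sensitive.
* Multiple distinct decoys concatenate their letters in first-
  occurrence order — a deterministic rule covering combinations the
  catalog never shows.

`parse_nomenclature()` inverts the grammar on its image, and the
round-trip identity is tested on the full 19-class catalog and on
random architectures.

```{r classify-example}
arch <- toy_architecture(c("FYVE", "Stress-antifungal",
                           "Stress-antifungal", "Pkinase-tyr"))
classify_major(arch)
classify_subclass(arch)
classify_nomenclature(arch)
parse_nomenclature("ddCRKF")
```

## Physicochemical statistics

`compute_stats()` reports length, molecular weight, net charge,
isoelectric point and GRAVY per protein.  The constants are explicit,
editable TSV files: free amino-acid average masses (summed minus one
water per peptide bond; average, not monoisotopic, matching the kDa
conventions of family surveys), the Kyte–Doolittle hydropathy scale,
and an EMBOSS-style pKa set.  Charge is a Henderson–Hasselbalch sum —
each ionizable group's term is strictly decreasing in pH, so the net
charge curve crosses zero once and the pI bisection (tolerance 0.002
pH units on 0–14) is guaranteed to converge.  Charge is reported at
pH 7.0 by default; both the pH and all three tables are parameters,
because published "charge" and "pI" columns rarely state their
constants and cross-study comparison needs them pinned.  `X`
residues are excluded from the mass/GRAVY averages with a warning;
other non-standard letters are errors naming the offending position.

## Genome organisation

Tandem-cluster detection links two *consecutive* family members on a
chromosome when the gap between their nearest gene boundaries is at
most `max_gap_bp` (default 250 kb — the conventional tandem-array
criterion in plant gene-family surveys) and, when the full gene set
is available, at most `max_intervening` (default 8) non-family genes
lie between them; clusters are the transitive closure and singletons
are not reported.  Boundary distance is used rather than midpoints so
very long genes do not inflate distances.  Terminal-arm membership
uses each gene's midpoint against a fraction (default 0.25) of the
chromosome length from either end: a single unambiguous point per
gene, which also makes the statistic invariant under coordinate
mirroring (tested).  These thresholds are declared package defaults,
not inferences: qualitative statements like "found in clusters on
the terminal arms" are only reproducible once the criterion is
pinned down and configurable.

## The synthetic-proteome generator

`generate_dataset()` emits a FASTA proteome, GFF3 gene models, a
clean hit table, chromosome lengths and a truth table.  Its defaults
are the study conditions of a five-species cotton survey: family
sizes 60/74/65/120/118, architecture templates drawn from the
major-class catalog at the published class-total frequencies, 13
chromosomes per species with a threefold gene-density weight on
Chr06, and one planted 3-gene tandem cluster per species at 10 kb
spacing.  Domain spans are realistic (DUF26 90–110 aa, kinases
250–290 aa, decoys 60–120 aa, linkers 10–40 aa) so coordinate
arithmetic is genuinely exercised; sequences themselves are uniform
random residues, because the pipeline consumes scanner output and
never infers domains from sequence.  `inject_noise()` adds the two
scanner artifacts the pipeline must withstand: overlapping duplicate
hits with strictly lower bit scores (overlap resolution must remove
them) and sub-threshold DUF26 hits on non-family decoy proteins
(candidate filtering must reject them).

Truth labels are computed by a deliberately separate, simpler rule
implementation inside the generator — never by calling the
classification functions — so agreement between pipeline and truth is
a genuine cross-validation, not a tautology.
`end_to_end_recovery()` runs generate → filter → resolve → build →
classify → summarize → cluster-detect and reports candidate
precision/recall, per-scheme label agreement and planted-cluster
recovery; all are 1.0 on clean and duplicate-noise data.

What the generator does *not* emulate: realistic HMM score
distributions, sequence-level domain motifs, pseudogenes, fractured
gene models, or evolutionary duplication along a species tree.
Passing recovery tests therefore demonstrates the correctness of the
pipeline's logic on well-formed scanner output, not robustness to
every artifact of real proteome annotation.

## Problem sizes and determinism

The package's own test and acceptance runs use the catalog fixtures
(11 + 19 architectures), synthetic families of a few hundred proteins
(up to the full 437-gene five-species configuration), 10,000-gene
uniform placements for the terminal-arm binomial check, and
brute-force oracles on instances of at most 6 hits or 10 genes —
sizes at which exhaustive enumeration is exact and runs in seconds.
All randomness flows through a single integer seed (`sim_config`,
`run_config`, the acceptance script's `--seed`), and fixed seeds make
generated files byte-identical, which the tests assert.

## Known limitations

* The published full-scale per-class counts depend on specific
  proteome assemblies and a Pfam release; `crkscan` reproduces the
  classification *logic* and the in-paper arithmetic, not those
  external scans.
* Phylogenetic clade assignment (and the prior literature's
  CRK_I/CRK_II split, which requires tree inference) is out of scope.
* The Pfam-Scan parser targets the common `pfam_scan.pl` column
  layout; exotic dialects should be converted to the canonical hit
  TSV first.
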