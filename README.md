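# glycolib

Open spectral library search for intact N-linked glycopeptides from HCD
MS/MS spectra.

## Who it is for

Glycoproteomics workflows that already produce identifications of
**deglycopeptides** (PNGase F leaves a deamidated Asn; HCD-pd-MS3 leaves a
HexNAc stub) and want to identify the **intact glycopeptides** in the
corresponding HCD MS/MS runs — assigning peptide and glycan composition
together from a single spectrum, with one joint false discovery rate.

## The method

1. **Library.** Replicate deglycopeptide spectra with the same
   identification are merged into a consensus, blended with the theoretical
   b/y spectrum by a factor θ, repositioned at theoretical m/z, stripped of
   the deglycosylation artifact (glycosylated Asn re-encoded as `J`), and
   augmented with the trimannosyl-core Y0–Y5 ion ladder at 40% relative
   intensity. Each target spectrum gets one decoy: sequon triplets held in
   place, all other residues reversed, b/y peaks moved accordingly, Y ions
   and precursor unchanged.
2. **Search.** Query spectra are gated on the HexNAc diagnostic oxonium ion
   at 138.054953 Th, deisotoped, stripped of 25 oxonium ions and capped at
   6 peaks per 100 Th. A candidate is any (library spectrum, glycan) pair
   with `|M_lib + M_glycan − M_query|` inside the precursor tolerance.
   Candidates are scored with

   ```
   score = DPS × PS
   DPS   = Σ_matched I_Q I_L / (‖I_Q‖ ‖I_L‖)
   PS    = −log10 Σ_{j=k}^{n} C(n,j) P^j (1−P)^(n−j)
   P     = 1 − (1−p)^m,   p = 2·pro_tol / mz_range
   ```

   where `n` is the number of query peaks with relative intensity ≥ 0.05
   within the 12 most intense, `k` of which match the candidate's `m`
   annotated peaks. Score ties are broken by smaller precursor mass error.
3. **FDR.** Rank-1 matches are filtered by score with `FDR = D/T`
   (decoy/target counts), reported as monotonized q-values. Validation
   utilities reproduce the rank-distribution and falsified-spectra
   (+10 m/z) null checks.

## Worked example

```r
library(glycolib)

fx  <- generateFixtureSet(fixtureConfig(nPeptides = 25L, nTrueQueries = 40L,
                                        nNoiseQueries = 20L, seed = 7L))
lib <- buildSpectralLibrary(fx$libraryIdentifications, fx$librarySpectra)
lib
#> SpectralLibrary: 25 targets + 25 decoys

res <- searchAll(fx$queries, lib, fx$glycanDb, searchConfig())
fdr <- estimateFdr(res$gpsms, level = 0.01)
head(fdr$accepted[, c("query_id", "peptide", "glycan", "charge",
                      "ppm_error", "dps", "ps", "score", "qvalue")], 3)
#>     query_id       peptide glycan charge ppm_error       dps       ps    score qvalue
#> 25 query0009 NNJFSHGSVCDNR H4N3F1      4 -3.021187 0.6055876 35.60168 21.55993      0
#> 59 query0021   AGJQTENMEPK H8N3S1      4  1.322422 0.5797808 36.43689 21.12541      0
#> 19 query0007 NCFTJVTSWNWQK   H4N4      4  1.212612 0.5857835 35.60168 20.85488      0
```

Each accepted row is a glycopeptide-spectrum match: the `J` in the peptide
marks the glycosylation site, `glycan` is the inferred composition
(H = Hex, N = HexNAc, F = Fuc, S = NeuAc, G = NeuGc), `ppm_error` the
precursor mass error after explaining the glycan, and `score = dps × ps`.
Of the 41 matches accepted at 1% FDR here, 40 are exactly the planted
(peptide, glycan) pairs.

A command-line front-end wraps the same pipeline:

```sh
CLI=$(Rscript -e 'cat(system.file("scripts", "glycolib", package = "glycolib"))')
Rscript $CLI make-fixtures  --out fx --seed 9
Rscript $CLI build-library  --ids fx/identifications.tsv --mgf fx/library_spectra.mgf --out lib
Rscript $CLI search         --library lib --glycans fx/glycans.txt --queries fx/queries.mgf --out out
Rscript $CLI validate       --library lib --glycans fx/glycans.txt --queries fx/queries.mgf --out val
```

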