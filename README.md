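# npenum

Enumeration of hypothetical modular natural products and benchmarking of
chemical similarity methods.

## What problem this solves

Nonribosomal peptides, polyketides and NRP/PK hybrids are assembled by
enzymatic assembly lines from discrete monomers and decorated by tailoring
enzymes. Deciding whether two structures come from the same biosynthetic
family is a core task in natural-product genome mining and dereplication —
but benchmarks built from real molecules cannot say which *similarity
method* is best, because family ground truth is scarce and biased. `npenum`
manufactures ground truth instead:

1. **Enumerate** a library of hypothetical scaffolds: random monomer
   sequences (20 proteinogenic amino acids, 45 nonproteinogenic amino
   acids, 26 polyketide units at all valid β-oxidation states, 23 starter
   units) condensed into valence-valid structures, optionally tailored
   (macrocyclization, halogenation, O-glycosylation with a 69-sugar
   library, thiazole/oxazole formation, N-methylation).
2. **Modify** each scaffold into a derivative of the same in-silico
   assembly line, by substituting monomers and/or adding, removing, or
   moving tailoring reactions.
3. **Compare** every modified structure against the whole original library
   with 17 two-dimensional fingerprints (circular ECFP0–6/FCFP0–6,
   MACCS, E-state, privileged-substructure key sets, four topological
   path variants, LINGO) using the Tanimoto coefficient
   T(A,B) = |A ∩ B| / |A ∪ B|.

A *correct match* means the derivative is strictly more similar to its true
parent than to every other library member; the per-method fraction of
correct matches, over repeated libraries, is the benchmark score. Rank
records keep tie counts, and rank-based statistics (Brunner–Munzel tests,
Kendall radius trend, Bonferroni helper) compare methods across repeats.

## Worked example

```r
library(npenum)

cfg <- preset_config("proteinogenic", seed = 42, repeats = 2,
                     library_size = 20,
                     methods = c("ECFP0", "ECFP6", "FCFP6",
                                 "KlekotaRoth", "LINGO", "EState"))
res <- run_experiment(cfg)
print(res)
#> <experiment: 2 repeats x 20 structures, 6 methods>
#>   ECFP6              100.00% (se 0.00)
#>   FCFP6              100.00% (se 0.00)
#>   LINGO               95.00% (se 0.00)
#>   KlekotaRoth         90.00% (se 5.00)
#>   ECFP0               45.00% (se 15.00)
#>   EState              45.00% (se 15.00)
res$comparisons[["ECFP6"]]
#> [1] 800
```

Two repeats of a 20-structure library were generated (linear peptides of
4–15 residues), one amino acid was substituted in each structure, and each
derivative was ranked against all 20 originals — hence 2 × 20² = 800
Tanimoto comparisons per method. High-diameter circular fingerprints
retrieve essentially every parent; the radius-0 circular fingerprint and
the E-state atom-type fingerprint tie with many decoys and score far lower
under the strict tie rule. `write_outputs(res, "results/")` writes the rank
distribution, accuracy tables (strict and tie-adjusted), a config echo and
a checksummed manifest; fixed seeds give byte-identical files.

Presets cover the full study design (`preset_names()`): linear NRP / PK /
hybrid alphabets, starter units, fixed sizes, macrocyclic libraries,
glycosylation, the complex tailored-hybrid experiment, and the random-bond
stress test. A thin command-line wrapper is included:

```sh
Rscript inst/cli/npenum.R --preset complex --seed 42 \
    --repeats 100 --library-size 100 --out results/
```

See the vignette (`vignettes/enumerating-hypothetical-natural-products.Rmd`)
for the scaffold model, tailoring chemistry, fingerprint definitions, tie
semantics, and known limitations.

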