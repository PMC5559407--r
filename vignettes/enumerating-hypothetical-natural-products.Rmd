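---
title: "Enumerating hypothetical modular natural products and benchmarking chemical similarity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Enumerating hypothetical modular natural products and benchmarking chemical similarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npenum)
```

## The problem

Modular natural products -- nonribosomal peptides (NRPs), polyketides (PKs)
and their hybrids -- are assembled by enzymatic assembly lines from discrete
monomers and then decorated by tailoring enzymes (macrocyclization,
glycosylation, halogenation, heterocyclization to thiazoles/oxazoles,
N-methylation).  A recurring cheminformatic task is to decide whether two
structures belong to the same biosynthetic family.  Because ground truth for
real molecules is scarce, `npenum` builds it synthetically: it enumerates
random but biosynthetically plausible scaffolds, derives from each one a
*modified* structure from the same in silico assembly line (by substituting
monomers and editing tailoring reactions), and then asks each of 17
two-dimensional fingerprint methods whether Tanimoto similarity can match
every derivative back to its true parent inside a library of decoys.  The
fraction of correct matches is the benchmark quantity.

## Scaffold model

A polymer is an ordered list of monomers.  Every monomer exposes a **head**
(the acyl carbon that condenses onto the next residue) and, except for
starter units, a **tail** (the nucleophile: the amine nitrogen for amino
acids, the alpha carbon for ketide units, the hydroxyl oxygen for
alpha-hydroxy acids).  Condensation forms one single bond per junction,
deleting the head's leaving hydroxyl and one tail hydrogen -- a net loss of
H2O -- which yields amides, C-C ketide junctions and esters from one rule.
Residue 1 keeps a free tail (the N-terminus), residue *n* a free head (the
C-terminal acid).  Starter units have no tail and therefore occupy only
position 1.

Monomer tables are TSVs whose SMILES carry atom maps (`:1` head, `:2` tail)
as the attachment annotation.  Structures are kept kekulized internally;
aromaticity is perceived with a Hueckel-style rule over fused ring systems
(all ring atoms sp2-capable and 4n+2 pi electrons over the system).
Stereochemistry is not modelled: every fingerprint in scope is
stereo-insensitive, and dropping it makes 2D-degenerate sugars and amino
acids explicit rather than hidden.

### Monomer alphabets

* **Proteinogenic** -- the standard 20 amino acids.
* **Nonproteinogenic** -- 45 modified amino acids reconstructed from the
  published category description (beta-hydroxylated, beta-methylated,
  alpha-keto acids, beta-amino acids, and other common modified amino
  acids), with a 32-member core subset used by the NRP/hybrid presets.  The
  exact identities of the original set are not published in the main text,
  so this set is the package's own reconstruction (hence the `_synthetic`
  file name).  Alpha-keto acids are shipped at their incorporation-competent
  alpha-hydroxy oxidation state, so they form ester junctions
  (depsipeptides), which keeps the single condensation rule valid.
* **Polyketide** -- 7 extender units (malonate, methylmalonate,
  ethylmalonate, methoxymalonate, propionate, isobutyrate,
  2-methylbutyrate) expanded over the beta-position oxidation states
  (ketone, hydroxyl, enoyl, fully reduced).  The enoyl state needs a
  hydrogen at the alpha carbon, so the two doubly alpha-substituted units
  (isobutyrate, 2-methylbutyrate) lose it: 7 x 4 - 2 = 26 monomers, with no
  tunable pruning rule.  In the free-monomer form the oxidation state lives
  on the head carbon together with its leaving hydroxyl, which makes the
  hydroxyl state a formal aldehyde hydrate (gem-diol) and the enoyl state an
  enol; both are valence-valid formal devices that become the ordinary
  beta-hydroxy and alpha,beta-unsaturated chain motifs once condensed.
  Methylmalonate and propionate coincide as 2D structures after
  decarboxylative incorporation; both are kept, so libraries may contain
  coincidentally identical structures (ties are handled pessimistically, see
  below).
* **Starters** -- 23 units (4 fatty, 13 aromatic, 3 alicyclic, 3 small),
  again a reconstruction of the published breakdown.
* **Sugars** -- 69 distinct 2D pyranoses (hexoses and deoxy sugars with
  amino, N-methylamino and O-methyl decorations) generated systematically;
  used by O-glycosylation.

## Tailoring reactions

Site rules, applied to the current structure:

* **Cyclization**: the free N-terminal amine plus every sp3-carbon-bound
  hydroxyl, each attacking the C-terminal carboxyl (macrolactam /
  macrolactone, -H2O).  Hydroxyls on carbons bearing a double-bonded oxygen
  (acids) and on the C-terminal carbon itself are excluded.  One
  cyclization per scaffold.
* **Halogenation**: any non-backbone carbon with an available hydrogen;
  chlorine or bromine with equal probability (-H, +Cl/Br).
* **O-glycosylation**: any sp2- or sp3-carbon-bound hydroxyl (phenols
  included, acid hydroxyls excluded); a uniformly chosen sugar from the
  69-member library condenses through its anomeric carbon (+sugar -H2O).
  Sugars attached earlier expose new hydroxyls and can be glycosylated
  further.
* **Thiazole/oxazole formation**: every serine/cysteine-type residue at
  position >= 2 whose preceding junction is an intact amide; the side-chain
  heteroatom attacks the preceding backbone carbonyl, and cyclodehydration
  plus oxidation gives the aromatic azole (net -H2O -H2).  Position 1 has
  no preceding carbonyl and is never proposed; adjacent residues may both
  cyclize (bis-azoles).
* **N-methylation**: every backbone amide nitrogen from amino-acid residues
  that still carries a hydrogen (+CH2).  Azole formation consumes the
  nitrogen and removes it from the pool.

Reaction plans use the weight convention `halogenation 0.5` (probability)
vs `halogenation 2` (count); an attempt with no available site is a logged
no-op.  Plan entries execute in the order given -- no canonical reaction
order is imposed.  The random-bond stress test adds single bonds between
uniformly chosen non-bonded atom pairs that can each surrender a hydrogen,
emulating tailoring chemistry that violates retrobiosynthetic logic.

## Modified structures

Each original scaffold records its tailoring reactions as replayable
records whose sites are stored as stable provenance (residue plus
within-residue atom ordinal, or the key of the record whose atoms they
modified).  A modified structure is derived by

1. substituting `n_substitutions` positions -- never residues involved in a
   tailoring reaction; starter-class replacements only at position 1; the
   replacement always differs from the incumbent; positions rotate
   round-robin so each substitutable position is used once before any is
   reused;
2. re-condensing and replaying the tailoring records; and
3. optionally editing tailorings: additions follow plan semantics, removals
   delete a uniformly chosen record of the kind and revert it chemically,
   site moves revert and re-execute at a different uniformly chosen valid
   site (a logged no-op when none exists).  Reverting a record also reverts
   anything chemically built on the atoms it introduced (a halogen on a
   removed sugar disappears with it).

## Similarity methods

Seventeen fingerprints are registered, all compared with the Tanimoto
coefficient (bit vectors: intersection over union; LINGO multisets: sum of
minimum counts over sum of maximum counts; two empty fingerprints score 1).

* **Circular** ECFP0/2/4/6 and FCFP0/2/4/6: a native Morgan implementation
  (iterative neighbourhood hashing, FNV-1a, folded to 1024 bits).  ECFP
  seeds each atom with the standard invariants (element, heavy degree,
  hydrogen count, charge, ring flag, bond-order sum); FCFP seeds with six
  pharmacophoric features (H-bond donor/acceptor, positively/negatively
  ionizable, aromatic, halogen) perceived by the package's own rules.  The
  numeral is the environment *diameter* in bonds.
* **Topological** path fingerprints in four typing variants (default,
  extended, hybridization, graph-only): all simple paths up to 7 bonds,
  canonical orientation, hashed to 1024 bits.  Graph-only ignores bond
  orders entirely, so benzene and cyclohexane coincide.
* **Substructure keys**: MACCS (via OpenBabel), E-state atom types
  (element, hydrogen count and bond-pattern typing of every atom), and two
  *synthetic* privileged-fragment key sets standing in for the published
  Klekota-Roth (4860 keys) and PubChem (881 keys) collections, which are
  not redistributable here.  The stand-ins mine linear fragments from a
  deterministic corpus -- every packaged building block plus the dipeptides
  and diketides they form -- and keep fragments that recur in at least two
  corpus molecules but not in more than 90% of them, ranked by corpus
  frequency and capped at the published dimensionality.  For the
  Klekota-Roth stand-in the fragment labels carry element, aromaticity,
  ring membership and hydrogen count, and the fragment length (8 bonds) is
  the smallest bound whose mined vocabulary reaches the published key
  count.  These sets emulate the *character* of the originals (privileged
  substructures of biologically derived molecules); their absolute
  accuracies are their own.
* **LINGO**: the multiset of length-4 substrings of the canonical SMILES
  (OpenBabel canonicalization, used everywhere in the package) with all
  ring-closure digits normalized to 0; strings shorter than 4 yield one
  whole-string gram.

External methods (e.g. retrobiosynthetic scorers) can be registered as
pairwise callables; none is implemented here.

## Ranking, ties, and what the accuracy means

For every modified structure the Tanimoto coefficient to each of the 100
originals (its own parent included) is computed, and a correct match
requires the parent similarity to *strictly* exceed every competitor.
Ranks are reported pessimistically (1 + number strictly greater + number
tied), and tie counts are recorded so the data can be re-read under other
conventions.  `accuracy_summary()` therefore reports two columns: the
strict fraction, and the expected fraction under uniform tie resolution
(a parent tied with *t* competitors is credited 1/(1+t)), which is what an
implementation that breaks ties by sort order measures on average.  The
two readings differ dramatically for coarse atom-type-level fingerprints
(radius-0 circular, E-state), whose Tanimoto values tie exactly across
many library members, and are identical for discriminative methods -- worth
keeping in mind when comparing accuracy figures across implementations
whose tie conventions are unstated.

## Statistics

Per-repeat accuracies are the sampling unit.  Methods are compared with the
Brunner-Munzel test (independent form with Satterthwaite degrees of
freedom, validated against the classic worked example; a paired-rank form
studentizes the mean combined-rank difference across repeats).  A
Bonferroni helper divides the significance level by the number of
comparisons (0.05/17 = 0.0029).  The radius trend for circular
fingerprints is Kendall's tau-b between radius (0, 1, 2, 3 for diameters
0/2/4/6, both families pooled) and per-repeat accuracy, optionally
excluding the radius-0 members.

## Reproducibility and problem sizes

One master seed drives everything; per-repeat child seeds are drawn up
front so repeats are individually reproducible, and fixed-seed runs write
byte-identical output files (rank distribution, accuracy tables, YAML
config echo and manifest with MD5 checksums).  The published design is 100
repeats x 100 structures; the packaged acceptance script and test suite run
20 repeats x 100 structures, which leaves per-method accuracy standard
errors under one percentage point, and widen reproduction bands from +/-5
to +/-7 percentage points accordingly.

## Known limitations

* The generator emulates linear/cyclic modular assembly only -- no branched
  (terpene- or aminoglycoside-like) connectivity, no stereochemistry, no
  tailoring-enzyme regioselectivity beyond the site rules above.  Passing
  benchmarks here say how well fingerprints separate *this* kind of
  combinatorial chemical space, not how they behave on real natural-product
  collections.
* The nonproteinogenic, starter and sugar alphabets are reconstructions of
  the published category counts, not transcriptions of the original
  supplementary tables; absolute accuracies that depend on those alphabets
  shift with the exact member identities.
* The Klekota-Roth and PubChem key sets are synthetic stand-ins (above).
* Radius-0 circular and E-state accuracies are tie-dominated and depend
  strongly on the invariant granularity and the tie convention of the
  implementation; the strict-rule numbers reported here are pessimistic by
  construction.
* FCFP pharmacophore perception follows this package's own donor/acceptor/
  ionizability rules; sub-point orderings between ECFP and FCFP at equal
  diameter are toolkit-specific.
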