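---
title: "Linking compound collections to disease maps: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking compound collections to disease maps: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmaplink)
```

# The problem

Custom databases of candidate therapeutics — compounds assembled from the
literature and from high-throughput screens for one disease context — need
to be connected to disease maps before they can support mechanism-of-action
reasoning: which map entities does a compound interact with, which targets
do two compounds share, and which compounds hit a selected entity. The two
sides speak different identifier languages. Compounds are identified by
InChIKey, SMILES, CAS registry number, PubChem CID and free-text synonyms;
map entities are SBML species with display names and (in
CellDesigner-annotated maps) a species class. Interaction knowledge comes
from heterogeneous sources that each key on a different identifier: CAS
numbers on one side, InChIKeys or PubChem CIDs plus official gene symbols
on the other.

`cmaplink`'s job is the harmonization and the bookkeeping: resolve every
interaction row to a compound of the collection, normalize the target side
to uppercase official gene symbols, keep only interactions whose target
exists in the map, and materialize the result as a pair of mutually
transposed JSON mappings that any downstream viewer (or the query functions
here) can consume without re-deriving anything.

# The data model

**Compound collection.** One record per compound: an opaque, unique
`compound_id` (the collection's own accession), optional InChIKey
(validated against the 14-10-1 uppercase block shape), optional SMILES
(kept verbatim), optional CAS number (validated against the
2–7-digit/2-digit/1-digit pattern), optional positive PubChem CID, and a
non-empty ordered synonym list whose first entry is the display name.
Malformed *optional* identifiers are dropped field-wise with a warning
rather than rejecting the record: collections routinely contain compounds
synthesized for one study that have partial or no standard identifiers, and
losing the whole record would silently shrink the searchable space. A
missing, empty or duplicated `compound_id` is, by contrast, a hard error —
everything downstream keys on it.

**Interaction record.** The normalized assertion `(compound_id,
gene_symbol, source, evidence)`. Gene symbols are trimmed and uppercased at
resolution time; the original spelling is not preserved, since matching
against the map is by uppercase symbol equality. Interaction *types*
(e.g. a CTD `InteractionActions` string) are not filtered on; they ride
along verbatim in the evidence field.

**Entity index.** One entity per SBML species with its display name,
compartment, and a class coarsened from the CellDesigner annotation:
PROTEIN-like classes (including receptors, ion channels and truncated
proteins) map to PROTEIN, GENE to GENE, RNA and antisense RNA to RNA, and
everything else — simple molecules, ions, complexes, unannotated plain-SBML
species — to OTHER. Complexes are deliberately kept as single OTHER
entities; expanding them into members would require annotation the SBML
core does not carry. The *gene-like* universe (GENE ∪ PROTEIN ∪ RNA) is
the default matching space.

**Link index.** `forward`: compound → sorted map-covered target symbols,
with compounds that have no map-covered target omitted entirely (queries
report "no targets" by absence, which keeps the file small); `reverse`: one
key per map gene-like symbol — even untargeted ones, so coverage is
computable from the file alone — mapping to the sorted targeting compound
ids. The defining invariant is transpose consistency,
`g ∈ forward[c] ⇔ c ∈ reverse[g]`, which is enforced at construction,
re-verified whenever an index is read back from disk, and violated only by
hand-edited files (the reader then refuses to load and names a witness
pair).

# Matching rules and their rationale

- **Synonym search** is exact, case-insensitive, whitespace-trimmed token
  match. Substring search exists behind an explicit `contains` flag.
  Exact-by-default keeps results deterministic and auditable; fuzzy or
  edit-distance matching is not implemented because a wrong compound match
  propagates silently into every downstream overlay.
- **Identifier search** compares verbatim strings (CID as a string).
  SMILES equality is literal: two different valid SMILES spellings of the
  same molecule do *not* match. Canonicalization would require a
  cheminformatics toolkit at runtime and is out of scope for the core; the
  InChIKey exists precisely to be the canonical structure key.
- **ChEMBL-style keys** are classified by shape — all digits ⇒ PubChem
  CID, the 14-10-1 uppercase pattern ⇒ InChIKey — and unclassifiable keys
  are skipped with a log count rather than guessed at.
- **Compound-to-map matching** is by uppercase name/alias equality between
  interaction gene symbols and map display names. Identifier-based
  matching through SBML CV-term annotations (e.g. HGNC accessions) would
  be more robust where maps carry them, and the entity index is structured
  so such a matcher could be added; name equality is the default because
  it is the only rule every SBML map supports.
- **Cross-source merge** deduplicates on the (compound, gene) pair. The
  first source's tag wins the `source` field; all contributing source
  names are folded into the evidence string, so provenance is never lost,
  and merging is idempotent.

No organism filter is applied to interaction rows: the table dialects carry
no organism column, and asserting one would be invention.

# Degenerate inputs and numerical choices

- Empty query strings, missing files, missing required columns, empty
  collections and species-free maps are typed errors (`cmap_input_error`,
  `cmap_format_error`, `cmap_validation_error`); resolution failures and
  empty query results are *data*, not errors.
- A map whose gene-like universe is empty cannot be indexed (validation
  error) — every downstream quantity would be 0/0.
- Coverage is defined as `nCovered / nGeneEntities` over reverse-index
  keys; with a non-empty universe the denominator is positive by
  construction.
- All lists in the index are sorted ascending (radix order, i.e. plain
  byte order independent of locale) and duplicate-free; JSON output uses
  sorted keys, two-space indentation and a pinned-timestamp option, which
  together make builds byte-reproducible — the determinism contract the
  tests assert with file checksums.
- Ties need no break rules anywhere: every aggregation is a set union or
  intersection followed by a total lexicographic sort.

# The synthetic fixture generator

`generateFixture()` emulates the *shape* of the real inputs: a compound CSV
with format-valid identifiers, the two interaction dialects, and a
CellDesigner-annotated SBML map with `nGenes` PROTEIN species plus two
OTHER species (so class filtering is always exercised). Ground truth is
planted explicitly: each (compound, gene) slot carries an interaction with
probability `interactionDensity`; each interaction is redirected to a
unique synthetic off-map symbol with probability `offmapGeneFraction` (the
build must drop exactly these) and emitted in both dialects with
probability `duplicateSourceFraction` (the merge must collapse exactly
these). The defaults (density 0.2, off-map 0.1, duplicate 0.1) reflect the
sparse many-compounds/few-shared-targets structure typical of screening
collections, where most compounds have a handful of annotated targets and
a minority of assertions point outside any given map; the property tests
additionally sweep density over the full [0, 1] range, so nothing depends
on the default.

What the generator does *not* emulate: realistic target-degree
distributions (hub genes), chemically meaningful SMILES or InChIKeys
(`.syntheticInchikeys()` draws random letter blocks — no pipeline step
interprets InChIKey chemistry), synonym collisions between compounds,
organism mixtures, or the real databases' column quirks beyond the
documented dialects. Passing the planted-truth suite therefore
demonstrates that the plumbing — parsing, resolution, merging, filtering,
transposition, serialization — is exact; it does not validate the
biological content of any particular export.

The test and acceptance workloads use up to 200 compounds × 100 map genes
per fixture and 100 random fixtures per sweep — comfortably past the size
of a typical curated collection-to-map linkage while keeping the whole
suite fast; correctness is size-independent set algebra, so scale adds
confidence against indexing mistakes, not new behavior.

# Open design decisions

Several behaviors were genuinely underdetermined and are fixed as follows:

- **Compare operates at symbol level.** The intersection of two compounds'
  target sets is computed on symbols, then fanned out to entities. The
  alternative — intersecting entity sets — gives the same result whenever
  both compounds' symbols fan out identically, and symbol level matches
  how the reverse index is keyed.
- **Entity fan-out is total.** A symbol present in several compartments
  highlights *all* matching entities, and `nTargets` counts entities, not
  symbols, because a per-compartment pin is the unit a map viewer renders.
- **Filtering happens at build time.** The forward file contains only
  map-covered pairs, and the drop count is reported at build. Query-time
  filtering would keep the files map-independent but make every consumer
  re-implement the intersection.
- **Reverse search defaults to gene-like entities.** Whether metabolites
  should be reverse-searchable is ambiguous; `geneLikeOnly = FALSE` at
  build time widens the reverse universe to every named species for users
  who want it.
- **Unknown compound in a forward query is a soft empty result**, while an
  unknown *entity* in the reverse search is an error: the former is a
  search box, the latter is a click on a concrete map element, so a miss
  there indicates a stale index or wrong map.

# Limitations

- Name-equality matching inherits every inconsistency between a map's
  display names and official gene symbols; a map labeled with protein
  complex names will under-match.
- The index is a snapshot: its header records the map checksum, source
  table names, timestamp and tool version so staleness is *detectable*,
  but no refresh machinery is included.
- Live retrieval from PubChem/ChEMBL/CTD is out of scope; the package
  consumes local exports in the two documented dialects.
- SMILES verbatim equality (above) means identifier search by SMILES is
  reliable only within a collection that stores one canonical spelling.

# Session info

```{r}
sessionInfo()
```
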