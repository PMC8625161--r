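# cmaplink

Link application-specific compound collections to SBML disease maps.

Drug-discovery groups that run high-throughput screens usually keep their
candidate therapeutics in a custom, use-case-specific database rather than
(only) in generic resources such as PubChem — newly synthesized compounds
often have no entry anywhere else. Disease maps, curated systems-biology
networks of the molecular interactions relevant to one disease (encoded as
SBML/CellDesigner and typically hosted on platforms such as MINERVA), are a
natural place to interpret those screens: which entities does a lead
compound hit, where do two leads overlap, which compounds hit a pathway of
interest?

`cmaplink` provides the data backbone for that linkage:

1. **Identifier harmonization** — a compound collection keyed by an opaque
   `compound_id`, carrying InChIKey (14-10-1 hash blocks), SMILES, CAS
   registry number, PubChem CID and a synonym list, searchable by
   case-insensitive synonym or exact identifier.
2. **Interaction aggregation** — chemical–gene interaction tables in two
   TSV dialects: a CTD-style export keyed by CAS number, and a ChEMBL-style
   export keyed by InChIKey or PubChem CID with the official gene symbol
   already resolved. Rows are resolved against the collection, gene symbols
   normalized to uppercase official symbols, and records deduplicated on
   the (compound, gene) pair across sources.
3. **Map filtering and the bidirectional index** — interactions are
   intersected with the map's gene-like entities (CellDesigner classes
   PROTEIN/GENE/RNA) and materialized as two mutually transposed JSON
   files: `compound2genes.json` (compound → map-covered target symbols) and
   `gene2compounds.json` (every map gene symbol → targeting compounds,
   possibly empty). For every compound `c` and gene `g`:
   `g ∈ forward[c] ⇔ c ∈ reverse[g]`.
4. **Queries** — `targetsOf()` (compound → highlighted map entities),
   `commonTargets()` (symbol-level intersection of two compounds' target
   sets), `compoundsFor()` (reverse search from a selected map entity), and
   `mapCoverage()` (fraction of the map's gene universe hit by ≥ 1
   compound: `coverage = |{g : reverse[g] ≠ ∅}| / |genes in map|`).

A synthetic fixture generator (`fixtureSpec()`, `generateFixture()`) plants
a known (compound, gene) truth set — including off-map and
duplicated-across-source interactions — so the whole pipeline is testable
hermetically, and a CLI (`inst/cli/cmaplink.R`) wires everything into shell
subcommands.

## Worked example

The shipped demo collection holds three candidate compounds (curcumin,
ivacaftor, genistein) with their real published identifiers, synthetic
interaction rows in both dialects, and a toy CFTR map with CFTR present in
two compartments:

```r
library(cmaplink)
demo <- system.file("extdata", "demo", package = "cmaplink")

db <- loadCompoundDb(file.path(demo, "compounds.csv"), "csv")
findCompounds("curcumin", db)
#> DataFrame with 1 row and 6 columns
#>   compound_id               inchikey                 smiles  cas_number
#> 1     CAND001 VFLDPWHFBUODDF-FCXRP.. COC1=CC(C=CC(=O)CC(=..    458-37-7
#>   pubchem_cid                                      names
#> 1      969516 Curcumin,Diferuloylmethane,Turmeric yellow

pl <- runPipeline(c(compounds = file.path(demo, "compounds.csv"),
                    ctd = file.path(demo, "ctd_interactions.tsv"),
                    chembl = file.path(demo, "chembl_interactions.tsv"),
                    map = file.path(demo, "cftr_map.xml")),
                  timestamp = "2026-01-01T00:00:00Z")
pl$link
#> LinkIndex: 3 compounds -> 3 map genes (2 covered), 2 dropped
#>   built: 2026-01-01T00:00:00Z | tool: 0.1.0

targetsOf("CAND001", pl$link, pl$entityIndex)
#> TargetHighlightSet: targets of CAND001
#>   2 symbols, 3 entities highlighted

compoundsFor("sp_cftr_er", pl$link, pl$entityIndex)
#> [1] "CAND001" "CAND002" "CAND003"

mapCoverage(pl$link, pl$entityIndex)
#> CoverageReport: 2 / 3 gene entities covered (66.7%), 3 compounds mapped
```

Reading the numbers: curcumin's two map-covered symbols (CFTR, HSP90AA1)
highlight three entities because CFTR appears in two compartments; the two
"dropped" interactions point at genes (KEAP1, ESR1) that are not in this
map; all three compounds hit the CFTR species, and 2 of the map's 3
gene-like symbols are covered by at least one compound.

The same pipeline from a shell:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","cmaplink.R",package="cmaplink"))')" \
  build --compounds compounds.csv --ctd ctd.tsv --chembl chembl.tsv \
        --map map.xml --index-dir out/
```

Subcommands: `build`, `search`, `targets-of`, `compare`, `compounds-for`,
`coverage`, `make-fixture`. Exit codes: 0 success (including empty
results), 2 user/input error, 3 index integrity error.

## Vignette

`vignettes/linking-compounds-to-disease-maps.Rmd` describes the data model,
the matching and normalization rules, the fixture generator's design and
its limitations relative to real exports.
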