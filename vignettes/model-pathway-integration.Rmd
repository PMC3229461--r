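---
title: "Integrating kinetic models with pathway data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrating kinetic models with pathway data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbpathdb)
```

# The problem

Kinetic systems-biology models (SBML documents, BioModels-style) and
biochemical pathway databases (KEGG-style) describe overlapping biology in
structurally incompatible ways: a model's *species* is a pool of a chemical
entity in a compartment, while the pathway side has *molecular entities*;
a model's *reaction* corresponds to a pathway *process entity*; a whole
model usually corresponds to (part of) a *pathway*.  Curated SBML models
carry the bridge in their RDF annotation blocks: qualifier-tagged MIRIAM
URNs (`urn:miriam:kegg.compound:C00074`) that name the external entity a
component *is*, *is a version of*, or *is homologous to*.

`sbpathdb` keeps the two sides in **separate tables** and connects them
exclusively through explicit mapping tables derived from those annotations.
This loose coupling means no curation ever happens at integration time:
a link that cannot be resolved produces no row, and mapping never creates
or modifies an entity on either side.  The package ingests SBML Level 2
documents, extracts their annotation links, loads a pathway source from a
documented TSV dialect, builds the mapping and annotation tables inside an
embedded SQLite store, and answers browse/queries over the result —
including ontology descendant queries accelerated by a path-labeling
scheme.

# The relational model

Every model-side record extends a common base (`Sbase`) carrying four
fields: `metaId`, `sboTerm`, free-text `notes` and the **verbatim**
`annotation` XML.  Keeping the raw annotation makes extraction repeatable
and auditable.  Internal ids are opaque and independent of the source
document; because SBML ids are often the only meaningful name an element
has, every identified element also keeps its `sbmlId`.  In deterministic
mode (used for fixtures and reproducible stores) internal ids are derived
from (data source, model, kind, SBML id); the default mode generates fresh
opaque ids.

Other schema decisions worth stating:

* **Units.** SBML base units (`mole`, `litre`, `second`, ...) are seeded as
  unit-definition rows with an absent model id *before* any ingest; user
  units belong to a model and must be composed of base units only — a user
  unit built on another user unit is a validation error.
* **Math.** MathML is stored as whitespace-canonicalized text and never
  evaluated; simulation is out of scope.  Identifiers inside expressions
  are classified (species / parameter / compartment / function) and
  function references carry the target function-definition id, so
  rate-law provenance survives relational storage.
* **Defaults.** Missing optional attributes stay absent (`NA`), except
  where the SBML specification defines a default (`reversible = TRUE`,
  species `constant = FALSE`, stoichiometry 1): storing spec-defined
  defaults keeps queries honest without inventing data.
* **Cascade deletes.** Every foreign key cascades; deleting a model removes
  its species, reactions, participants, kinetic laws, events, rules, links
  and all mapping rows in one sweep, verified by a full foreign-key check.
* **Dimension caching.** Twelve small enumerated tables (participant
  roles, rule types, ...) are mirrored in memory and rebuilt on any write;
  the cache is a pure optimization, and the suite asserts query results
  are identical with it on or off.

# Qualifiers and MIRIAM parsing

A URN splits on the last colon: namespace (normalised to lower case,
since the standard writes namespaces in lower case) and identifier
(case-preserved — KEGG and GO ids are case-significant).  Percent-escapes
in the identifier are decoded exactly once, so `GO%3A0006096` becomes
`GO:0006096` and a reconstructed URN re-parses to the same pair.

The qualifier dimension is pre-filled with eleven names (`is`,
`isDescribedBy`, `encodes`, `hasPart`, `hasVersion`, `isEncodedBy`,
`isHomologTo`, `isPartOf`, `isVersionOf`, `occursIn`, `unknown`); the
remaining standard qualifiers (`hasTaxon`, `hasProperty`, `isPropertyOf`,
`isDerivedFrom`) are accepted and inserted on first use, and anything else
classifies as `unknown` while keeping the family (`bqbiol:` biology,
`bqmodel:` model) of its prefix.  Both `bqbiol:is` and `bqmodel:is` map to
the single qualifier name `is`, with the family recorded separately.
Annotation extraction is deliberately forgiving: unparseable RDF or
non-MIRIAM resources are skipped with a warning, never fatally — ingest
must survive messy real-world annotations.

# NodeCodes labeling for descendant/ancestor queries

Browsing "models by GO term" needs all descendants of a term; iterating
the graph per query does work proportional to the result's neighbourhood
on every call.  Instead the store precomputes **NodeCodes**: add a virtual
source whose only code is the empty string and make all roots its
children; processing nodes in FIFO topological order, each node's code set
is completed before it propagates, and for every code $x$ of a node, its
$i$-th child (0-based, siblings in lexicographic id order) receives the
code $x.i$.  Each code names exactly one source-to-node path, so

* $v$ is a strict descendant of $u$ **iff** some code of $u$ is a proper
  component-wise prefix of some code of $v$;
* the ancestors of $t$ are read off the code→node map by enumerating the
  proper prefixes of $t$'s codes;
* $|NC(v)|$ equals the number of distinct root paths to $v$.

Three numerical/representation choices matter:

* **Delimited components, not digit concatenation.** With ten or more
  children, concatenated digits would make child 1 a false prefix of child
  10; codes here are integer components joined with `.`, and the prefix
  test is component-wise.
* **Topological FIFO rather than plain breadth-first order.** In a DAG,
  plain BFS can dequeue a node before all its parents have contributed
  codes; FIFO processing of nodes whose in-degree has drained preserves
  the breadth-first flavour while guaranteeing complete code sets.
* **Explosion guard.** The total number of codes equals the total number
  of root paths, which explodes on dense DAGs; labeling aborts with a
  clear error beyond a configurable cap (default $10^7$).  Ontology-like
  graphs — sparse, shallow, mostly single-parent — stay far below it.

The iterative traversal is retained as the baseline oracle:
`run_query_benchmark()` refuses to time methods whose result sets differ,
and the suite checks labeled answers against an independent
transitive-closure oracle as well.  The scaling property we assert is
structural, not wall-clock: labeled queries perform **zero** adjacency
traversals regardless of selectivity, while the iterative method must
visit at least every node it returns, so its work grows at least linearly
with result size.  (Published timings for this trade-off are hardware- and
ontology-version-specific, so the package tests the property rather than
any millisecond value.)

# Synthetic fixtures and what they do (not) show

The generator emulates a BioModels-style corpus: `floor(coverage ×
entities)` planted links per model (the rounding rule is part of the
contract, making ledgers exact), URNs in the exact MIRIAM grammar with
encoded colons, a configurable fraction of links pointing at identifiers
absent from the pathway source, and an aligned pathway source built from
the matched identifiers so the expected mapping rows are decidable from
the ledger alone.  Defaults — 10 models of 8 species and 6 reactions, 50%
KEGG coverage on species and reactions, 25% ChEBI/EC coverage, pathway
links on 80% of models, GO on 90%, taxonomy on all, 10% unmatched links —
mirror the annotation density of a small, well-curated corpus.

Scale choices in the test suite: the labeling property runs on a
20,000-node ontology-like DAG (about the size of a GO subontology) with
1,000 sampled query terms; oracle equivalence runs on 100 random DAGs up
to 2,000 nodes with full per-node checks below 100 nodes and sampled
checks above; the path-count law is checked exhaustively for $n \le 12$
where brute-force path enumeration is cheap.

What passing these tests does **not** show about real data: the generator
plants syntactically perfect annotations, so it cannot detect robustness
gaps against malformed RDF beyond the hand-built messy cases in the unit
tests; its stoichiometry and rate laws are biologically meaningless; and
its identifier universe is tiny, so hash/index performance at
database scale is untested.

# Open design points resolved

* The compartment-classification hierarchy and its dictionary have no
  stated initial population; they are seeded only from fixtures.
* Which result columns the built-in queries print is documented for only
  one of them (the species-name/role column of the pathway-reactions
  query); the other column choices here are the package's own.
* EC annotations referencing numbers absent from the loaded EC table are
  skipped and logged, mirroring the explicit skip rule for unknown GO
  terms — both tables are foreign-key targets, and mapping must not
  create entities.
* A species mapped to the same entity under two different qualifiers
  keeps both rows: the qualifier is part of the mapping's meaning
  ("perfect match" vs "partial match"), so collapsing would lose
  information.
* Reactome links are extracted and stored but produce no mapping rows
  (there is no Reactome-side store to map into).
* The GO-link flag of the coverage report counts any GO link by default;
  when a set of biological-process terms is supplied the flag is
  restricted to it, since a bare GO id does not reveal its subontology.

# Known limitations

SBML Levels 1 and 3 and CellML are not parsed; layout is stored as opaque
text; MathML equality is textual canonicalization only (two algebraically
equal rate laws in different forms count as different flux expressions);
the pathway-source dialect covers exactly the entities the mappings and
queries touch, not a full metabolic-pathways schema; and relabeling after
graph edits requires a full rebuild.
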