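---
title: "Methods: LLM gene-set interpretation and its evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: LLM gene-set interpretation and its evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genesetlm)
```

# The problem

Functional enrichment analysis interprets an experimental gene set by
statistical overlap with curated reference sets (Gene Ontology terms and the
like). It is precise but bounded by the reference database: a gene set whose
common function is documented only in the literature, not in GO, returns
nothing useful. A large language model can instead *synthesize* a functional
hypothesis — a short process name, an analysis essay, and a self-confidence
score — from its embedded literature knowledge. `genesetlm` implements such
an LLM naming pipeline together with the evaluation machinery needed to
trust it: semantic-similarity calibration against an ontology's name corpus,
a contamination benchmark of the confidence score, a native enrichment
baseline, and a PubMed citation loop that attaches checkable evidence to
essay statements.

# The naming pipeline

The prompt is organized in seven ordered sections (`prompt_config()`):
system content, task instructions, confidence-score instructions, format
instructions, analytical approach, a one-shot worked example (a pancreatic
development gene set), and the terminal user-input slot into which
`build_prompt()` substitutes the comma-separated gene symbols. The sections
ship verbatim; the source table shows them as one undelimited block, so the
split into named sections follows the block's order and the sentences
establishing the zero-confidence refusal ("System of unrelated proteins",
score 0.00) stay at the end of the analytical-approach section to preserve
that order. Decoding defaults are temperature 0.0, seed 42 and a 1,000-token
response cap.

Responses are parsed by `parse_response()` from the required header
`Process: <name> (<score>)`. The parser tolerates markdown bolding and
leading whitespace, takes the first matching line, clamps out-of-range
scores into [0, 1] with a warning, and splits the remaining essay into
paragraphs on blank lines. Even at temperature 0 the response *text* varies
between live calls; reproducibility is therefore anchored in the response
cache (`llm_cache()`), keyed by model id, prompt digest and decoding
parameters — the first response obtained is the unit of record. Backends are
a two-field contract (`llm_backend()`), so the scripted test double
(`scripted_llm()`, keyed on a fingerprint of the sorted gene list so prompt
edits do not invalidate scripts) and the live chat-API adapter are
interchangeable.

# Ontology handling

`parse_obo()` reads OBO 1.2/1.4 `[Term]` stanzas and keeps `is_a` and, by
default, `part_of` edges as parent links. The source work does not state
which relations its descendant aggregation traversed; following standard GO
practice both are kept, and the `relations` argument makes the choice
explicit. Obsolete terms are retained (so lookups resolve) but carry no
edges and are excluded from sampling pools and calibration corpora. A term's
effective gene set (`aggregate_genes()`) is the union of its direct
annotations with those of all descendants. Term selection
(`filter_and_sample_terms()`) applies the inclusive 3–100 aggregated-size
band before uniform seeded sampling. Annotations load from GAF 2.x (column
3 symbol, column 5 term) or a two-column TSV; no evidence-code filter is
applied by default (the reference pipeline states none), with an allowlist
available.

# Semantic-similarity calibration

A proposed name is compared to the curated name by cosine similarity of
sentence embeddings (`name_similarity()`). The raw score is hard to
interpret, so `calibrate()` recomputes the similarity of the proposed name
to *every other* non-obsolete term name in the target's branch and
`percentile_rank()` expresses the actual score as the percentage of
background names that are *strictly less* similar — ties do not count, which
matches the defining gloss of the percentile ("the percentage of names that
are less similar"). The best-matching corpus name is searched over the full
pool including the target itself.

`classify_naming()` partitions outcomes: `not_named` when the annotation
carried confidence 0; `recovered` at or above the 95th percentile;
`generalized` when the best-matching name belongs to a proper ancestor of
the target term (the pattern where the model proposes a broader but correct
concept); `other` otherwise. The ancestor rule is applied with no additional
similarity floor — the source describes the generalization check only
through a worked example, and the floor-free reading is the minimal one.

The embedding backend is pluggable. Real runs use a biomedical sentence
encoder (SapBERT); because its pooling convention is not stated in the
source, CLS pooling is the documented assumption and a ±0.02 tolerance on
two-decimal scores is the corresponding uncertainty. The offline test double
(`hash_embedder()`) is a token-hash bag vector: identical strings embed
identically (cosine exactly 1) and token-disjoint strings are orthogonal up
to hash collisions in the 512-dimension table. Buckets are taken from the
low-order digits of the rolling token digest, because the digest is
near-sequential for tokens differing only in their final character and
high-order bucketing would alias them.

# Confidence benchmark

For each benchmarked term three conditions are generated
(`make_contaminated_set()`): *real* (the full aggregated set), *mix5050*
(half term genes, half background) and *random* (all genes drawn from the
pool of every annotated gene). Design choices where the source is silent:

* Contaminants are drawn from `pool \ term`, so the stated 50% contamination
  is exact rather than approximate; odd sizes keep `floor(n/2)` term genes.
* The random condition samples the *full* pool, so term genes may re-enter
  by chance — that is what "randomly selected from background" means.
* Set size always equals the origin term's aggregated size.

Confidence scores are binned (`bin_confidence()`) as `not_assigned` = {0},
`low` = (0, 0.80), `medium` = [0.80, 0.87), `high` = [0.87, 1.00]. The
published caption writes the low bin as "0.01–0.79" because scores print at
two decimals; it is read as the open interval (0, 0.80) so that continuous
scores such as 0.005 remain binned. Condition distributions are compared
with a chi-squared test of homogeneity without continuity correction,
dropping bins with zero marginal total before computing degrees of freedom;
score lists can alternatively be compared with a two-sided Mann-Whitney U.

# Enrichment baseline

The baseline the LLM is compared against is a native over-representation
test: per-term upper-tail hypergeometric p-value, Benjamini-Hochberg
step-up correction across all tested terms (those sharing at least one gene
with the query), Jaccard index as effect size, and the decision rule
*annotated iff* the best term has adjusted p ≤ 0.05 and JI ≥ 0.1, with the
best term being the significant term of largest JI (ties: smaller adjusted
p, then lexicographic id). The original analysis called the Enrichr web
service, whose background universe and testing multiplicity are not exactly
recoverable; this package defaults the universe to the union of library
genes and makes it configurable, and documents that printed p-values from
the original are therefore not reproduction targets.

# Citation module

`cite_paragraph()` composes five steps per essay paragraph: LLM keyword
extraction (at least one gene symbol and one function keyword, at most three
keywords, else the paragraph is skipped with an `unknown` sentinel); PubMed
query assembly `(genes OR'd) AND (keywords OR'd)` over title/abstract;
relevance-sorted search (retmax 20 by default); re-ranking by the number of
distinct query genes mentioned in the abstract (case-insensitive, word
boundaries); and an LLM support verdict on each of the top three — only
verdict-supported publications are attached, and verdicts are never
fabricated from unparsable replies. The two prompts are shipped as editable
templates: the source shows them only as a figure, so the defaults are
reconstructions of the described behaviour and are flagged as such.

# The synthetic world and what green tests establish

`make_toy_ontology()` emulates the *structural* features the pipeline
depends on — an acyclic multi-rooted term DAG with unique names, direct
annotations whose aggregates fall inside the 3–100 band, and an annotated
gene pool much larger than any single aggregate (terms grow in disjoint
root families over a gene pool ≥ 500, mirroring a real branch where the
background dwarfs any size-banded term). It does not emulate GO's scale,
its term-size power law, semantic relatedness between real term names, or
real LLM behaviour. A green end-to-end test therefore establishes that the
pipeline's plumbing, statistics and decision rules are correct and
deterministic — not that any particular LLM names gene sets well; that
judgment requires live queries, which the harness supports but no offline
test claims.

Numerical conventions worth knowing: percentile ties resolve downward
(strictly-less counting); identical strings short-circuit to cosine exactly
1.0 rather than relying on floating-point division; the hypergeometric tail
uses the exact distribution function; BH adjustment is order-aligned with
its input and verified against both hand tables and the stock
implementation; chi-squared tables must retain at least two populated bins
or the comparison errors rather than returning a meaningless statistic.

# Limitations

* The real-embedder reproduction of printed similarity values needs the
  SapBERT weights (a one-time online download) and so runs only as an
  optional live job; offline suites exercise the contract with mocks.
* Headline percentages from the original evaluation (73% confident
  recovery, 87% zero-confidence on random sets, the 300-set 'omics
  contingency) require paid live queries over hundreds of GO terms and are
  out of the offline acceptance surface by design.
* The live PubMed and chat-API adapters are thin and untested by the suite;
  they share contracts with the canned fixtures, which is where correctness
  is enforced.
* Identifier normalization (symbol aliasing, species mapping) is out of
  scope: gene symbols are matched as given, case-preserved.
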