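---
title: "Methods: disclosure-controlled OMOP extraction and exact federated GLMs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disclosure-controlled OMOP extraction and exact federated GLMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fedomop)
```

This vignette is the package's own account of what it computes, the
assumptions behind each component, and the choices made where the design was
genuinely open. Nothing stated here goes beyond what the test suite and
`scripts/acceptance.R` themselves compute.

## 1. The federated GLM and why it is exact

The package fits GLMs (binomial with logit link, gaussian with identity
link) by iteratively reweighted least squares. At the current coefficient
vector $\beta_t$ each site computes, on its own rows,

$$ A_k = X_k^\top W_k X_k, \qquad b_k = X_k^\top W_k z_k, $$

with $\mu = \mathrm{logit}^{-1}(X\beta_t)$, $W = \mathrm{diag}(\mu(1-\mu))$
and working response $z = X\beta_t + (y-\mu)/(\mu(1-\mu))$ for the binomial
family ($W = I$, $z = y$ for gaussian). The client solves
$(\sum_k A_k)\,\beta_{t+1} = \sum_k b_k$. Because matrix sums over disjoint
row blocks are exactly the pooled quantities, the federated iteration *is*
the pooled iteration; the fits agree to floating-point summation order
(measured at ~1e-13 relative on the 20,000-person study in
`scripts/acceptance.R`). A single-site federation and the pooled fitter
share one code path (`irls_drive()`), so their results are bit-identical.

Numerical choices:

* **Initialization** $\beta_0 = 0$. For the binomial family this is the
  usual neutral start ($\mu = 1/2$ everywhere); no data-dependent
  initialization is needed because the binomial log-likelihood is concave.
* **Convergence** on relative deviance change,
  $|d_t - d_{t-1}|/(|d_t| + 0.1) < 10^{-8}$, at most 25 iterations. The
  deviance reported for binary outcomes is $-2\sum[y\log\mu +
  (1-y)\log(1-\mu)]$. The gaussian-identity normal equations are solved in
  a single step and the fit reports one iteration, since the weights do not
  depend on $\beta$.
* **Inference** is Wald: $\mathrm{SE} = \sqrt{\mathrm{diag}((\sum_k
  A_k)^{-1})}$ at the final $\beta$, odds ratios $e^\beta$, confidence
  intervals $e^{\beta \pm z_{0.975}\mathrm{SE}}$, two-sided normal
  p-values. Wald intervals are symmetric on the log-odds scale, which is
  the convention for reporting OR (CI 95%) tables; likelihood-ratio or
  profile intervals are not implemented.
* **Missing data**: rows with any `NA` among the model variables are
  dropped *at each site* before the design matrix is formed. Wide pivots
  create `NA` cells by construction (a person without an event of a concept
  has no value to place), so a complete-case rule at the modelling boundary
  is required for a well-defined design; analysts who want
  absence-as-zero semantics should build indicator variables first
  (`build_indicator_dataset()` does exactly this).
* **Rank deficiency**: a singular summed information matrix raises an error
  naming the collinear columns (identified by QR pivoting) rather than
  silently dropping terms.

What a site releases per iteration — $A_k$ (p×p), $b_k$ (length p),
deviance, n — is fixed-shape and row-free. Two safeguards gate the release:
the site's complete-case sample must be zero or at least the subset
threshold, and the parameters/observations ratio must not exceed a
configured limit (default 0.33). Both refusals are opaque: the error names
the site, never the count.

## 2. Disclosure control over relational data

Classical disclosure thresholds assume one row per individual. OMOP data is
relational: one person generates many rows across many tables, so the unit
that must be counted is the *unique person*, not the row. The package
enforces one rule everywhere: a non-zero unique-person count below the
configured subset threshold is disclosive.

* Zero passes. An empty subset reveals only absence, and the threshold is
  defined as a minimum *non-zero* count.
* Equality passes: "falls below" is strict.
* The rule is applied to the concept catalog (`list_concepts`), to every
  concept inside an extraction (concepts are screened both on the full
  table and again after cohort restriction, which can push a concept below
  threshold), and to every assembled table before it is bound to a session
  symbol.
* The default threshold is 5. No authoritative default exists — deployments
  configure per-site strictness — so 5 was chosen as a conservative,
  commonly used small-cell suppression value, and it is a required
  configuration knob (`disclosure_settings`, `--subset-threshold`), not a
  constant.

The end-to-end property the tests verify: after any pipeline run at
threshold $k$, a brute-force recount over every exposed catalog entry and
dataset finds no non-zero distinct-person count below $k$, and raising $k$
never adds catalog entries.

## 3. Schema introspection without a fixed CDM layout

CDM versions move tables and columns around, so the package classifies
columns at runtime purely from OMOP's naming conventions, in precedence
order: exact `person_id` → person link; suffix `_concept_id` → vocabulary
link; suffix `_id` whose stem names a table → foreign key; suffix `_date` /
`_datetime` → date; name containing `value` → value; anything else →
`other`. Three deliberate codifications, since no authoritative pattern
rules exist:

* Foreign-key stems match table names exactly (case-insensitively):
  `visit_occurrence_id` → `visit_occurrence`. No pluralization heuristics.
  A table's own primary key (`note_id` in `note`) yields no edge.
* `_id` columns with no matching table are classified `other` and preserved
  untouched — they may reference tables the site did not load.
* Concept links are *not* graph edges. Vocabulary translation is a lookup
  into the `concept` table, not a join-path concern, and treating it as an
  edge would make every domain table adjacent through `concept` and distort
  shortest join paths.

Join paths (`resolve_join_path`) are shortest paths over the undirected
edge set, with deterministic lexicographic tie-breaking, checked against an
independent breadth-first-search oracle in the tests.

The DBMS-specific surface is a three-function seam (list tables, list
columns, quote identifier) dispatched through DBI, with SQLite as the one
embedded dialect shipped. All generated SQL is a single `SELECT` with every
literal bound as a parameter; person/concept id lists are batched at 999
placeholders (a common DBMS limit) with results concatenated and re-ordered
by primary key, so batch size is unobservable. Row order is not part of the
extraction contract; equivalence is defined and tested on multisets.

## 4. Transformation choices

* **Wide pivot naming**: `<sanitized concept name>.<attribute>[.<k>]`, with
  the occurrence index $k$ assigned chronologically by the table's date
  column (primary key breaking ties) and omitted when a concept never
  repeats. Name collisions between distinct concept ids are disambiguated
  with an `_<concept_id>` suffix. No naming standard exists for
  occurrence-indexed wide columns; this scheme is this package's
  codification and is documented for cross-implementation comparison.
* **Provenance**: every wide column records (concept id, source attribute,
  occurrence index), making the pivot reversible; the tests check that
  non-`NA` cells equal surviving source events (conservation) and that
  un-pivoting recovers the long table.
* **Time-point completion** inserts, for each person, `NA` entries at every
  time point observed for anyone else, so all persons share the union of
  observed time points; the operation is idempotent and leaves original
  entries untouched.
* **Default date column**: first match among `*_start_date`, `*_date`,
  `*_datetime` in schema order — OMOP domain tables differ in which they
  carry.
* **Merging** is a left join anchored on the cohort table (right-only
  persons are dropped), mirroring the workflow where a first extraction
  defines the cohort and later extractions are forced to its person set via
  `build_cohort_filter()`. The filter object holds the ids but prints only
  their count, so cohort membership never appears in client-visible text.
* `NA` is the single missing sentinel, serialized as an empty field in CSV.

## 5. The synthetic generator: what it emulates and what it does not

Real multicenter OMOP databases used to validate this kind of tooling are
restricted-access, so the package ships a generator with a known ground
truth instead. It emulates the structural features the pipeline exercises:
a `person` table with demographics; domain tables (`condition_occurrence`,
`observation`) holding one row per positive indicator with dates uniform
over 2015–2020; a longitudinal `measurement` series on a fixed quarterly
grid with missing-at-random gaps (default 4 time points, 20% missingness);
and a `concept` vocabulary covering every id used, with synthetic ids in
OMOP's local-concept range (≥ 2,000,000,000) and real ids where they are
standard (8507/8532 gender, 317009 asthma, 9191 "Positive").

The default `copd_demo` scenario draws a binary COPD outcome from a
logistic model over four independent binary predictors — tobacco use,
vitamin D deficiency, history of asthma, history of rheumatoid arthritis —
with generating odds ratios 6.43, 6.14, 20.02 and 8.22, used as calibration
constants so the simulated effect sizes match those reported for these
predictors in the clinical literature. Prevalences (0.25, 0.10, 0.12,
0.03) and the baseline log-odds (−4, i.e. ~1.8% baseline risk) are the
package's own choices, picked once for epidemiological plausibility.
Predictors are independent by default so the generating model is exactly
the marginal logistic model and recovery tests are unambiguous; an
exchangeable-correlation knob exists but is off by default.

What the generator does **not** emulate: confounding structure, visit/
provider/cost tables, realistic vocabulary hierarchies, inter-site
heterogeneity in coding practice, or vocabulary-version drift between
sites. Passing tests therefore demonstrate the correctness of extraction,
disclosure logic and the pooled≡federated identity — which are structural
and algebraic claims — but not robustness to messy real-world coding, and
unit harmonization across sites is explicitly out of scope.

`partition_sites()` shuffles persons with a seed and deals them round-robin
(sizes differing by at most one), replicating the vocabulary to every site;
events follow their person. The three-site split mirrors the standard
single-server-versus-three-server validation design.

## 6. Problem sizes used in validation

The shipped validation runs use: the pooled-vs-federated identity at
n = 20,000 over 3 sites; payload additivity at n = 2,000, p = 5, over 50
random partitions; confidence-interval coverage and bias over 200
replicates at n = 5,000 (coverage observed ≈ 0.95, within the
[0.90, 0.985] acceptance band; mean absolute bias of the log-OR estimates
< 0.05 — dominated by the rheumatoid-arthritis term, whose 3% prevalence
makes it the noisiest); disclosure recounts at thresholds 2, 5 and 10;
pushdown equivalence over 100 random filters at three batch sizes; and
reference agreement against `stats::glm.fit` (epsilon 1e-12) on 20 random
logistic instances, with coefficients matching to better than 1e-8. These
sizes were chosen so each property is measured well inside the regime where
its failure would be visible.

## 7. Known limitations

* One embedded SQL dialect (SQLite). The dialect seam (table/column listing
  and identifier quoting through DBI) is where other engines would plug in,
  but none is shipped.
* In-process federation only: sites are R objects, not network services.
  Transport security (TLS, token auth) is deployment infrastructure, not
  method, and is deliberately absent.
* Two GLM families, additive terms, no interactions/offsets/weights; no
  survival or mixed models.
* Disclosure control implements the unique-person subset threshold and the
  GLM parameters/observations ratio; other filter families (string
  patterns, differencing attacks across repeated queries) are out of scope.
* Concept translation trusts each site's local vocabulary; reconciling
  vocabulary versions across sites is a data-harmonization task upstream of
  this package.
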