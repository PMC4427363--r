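---
title: "Mining indirect opinions from drug reviews"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining indirect opinions from drug reviews}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opinionkb)
library(dplyr)
```

## The problem

Patients reviewing a drug rarely write "this drug is good". They write "it
cleared my acne" or "lips were chapped": the opinion about the drug is
*indirect*, carried by the effect the drug had on something else, and usually
*implicit* — there is no opinion word for a sentiment lexicon to find. In
drug-review corpora roughly three quarters of opinionated sentences are of
this kind, so a system that only handles direct opinions discards most of the
signal.

`opinionkb` models an indirect opinion as a quadruple

> (*effective entity*, *affected entity*, *effect relation*, *polarity*)

for example `(accutane, acne, clear, positive)` — and builds, from structured
reviews with separate benefits/side-effects fields, two resources: a
polarity-tagged corpus of indirect-opinion sentences and a deduplicated
knowledge base of quadruples (the *OpinionKB*), plus frequent semantic-type
and semantic-group polarity patterns mined from it. New sentences are then
classified by exact KB lookup with pattern backoff.

## Pipeline

`build_opinion_resources()` runs six stages. Each is exported on its own, so
any stage can be inspected or replaced.

**1. Preprocessing** (`prep_reviews()`). Fields are sentence-segmented;
compound sentences are split at clause-level "and"/"but" coordination (the
conjunction is kept on the second clause for polarity propagation later);
coordinated noun phrases are *not* split, so "palpitations, confusion, and
muscle weakness" stays one unit with three affected entities. Imperatives
(leading base-form verb, no subject) and conditionals (clause-initial
"if"/"unless", or a conditional modal) are discarded: they express
instructions and hypotheticals, not experienced effects. Subject-position
deictics ("it", "this drug") are replaced by the nearest preceding drug
mention, falling back to the review's drug; gendered pronouns are left in
place and flagged, because a drug antecedent would be wrong more often than
not. The bundled tagger is a closed-lexicon rule tagger adequate for review
vocabulary; `tagger =` accepts any engine with the same lexicon layout.

**2. Affected-group selection** (`compute_sgf_iof()`,
`select_affected_groups()`). Entity mentions are typed against a UMLS-style
lexicon (type codes like `sosy` inside groups like `DISO`). Which groups can
serve as *affected* entities is not hard-coded: every mention is replaced by
its semantic group, and each group is scored against a mixed-topic background
(restaurant/product opinions) by SGF-IOF,

$$w(sg) = \frac{n_{sg,d}}{\sum_k n_{k,d}}\;
  \ln\!\frac{\alpha \sum_k n_k}{n_{sg}},$$

the group's frequency in the drug-review subset times the log-inverse of its
frequency in the whole opinion set. Groups with $w \ge \theta$ are kept.
Defaults $\alpha = 0.4$ and $\theta = 0.084$ are the tuned operating point of
the method; the log base is natural (any base rescales all weights uniformly,
so it is a documented convention rather than a free parameter). Effective
entities are always drug-typed (`phsu` by default).

**3. Complete-opinion extraction** (`extract_complete_opinions()`). For units
with both entity roles, the bundled positional rules take the nearest typed
mention before the main verb as subject and typed mentions after it as
objects; passives reverse the mapping. No constraint is placed on the verb
itself. A raising construction ("is supposed to alleviate") contributes the
embedded verb as the relation.

**4. Incomplete-opinion extraction.** Most opinions lack the drug mention
("Cleared my skin within a month"). Candidate subjects are the noun-phrase
heads of all preceding units plus the drug name (the drug alone for a
review's first unit). A four-stage filter cascade decides each candidate,
each stage consulted only when all earlier ones abstained:

1. *triple store* — the candidate with the highest conditional probability
   $P(c \mid v, e) = \#t\langle c,v,e\rangle / \sum_k \#t\langle
   c_k,v,e\rangle$ over a counted open-IE triple store wins; the sentence is
   accepted only when the winner is drug-typed. Ties break toward drug-typed,
   then more recent candidates. A zero denominator abstains.
2. *CompIndi* — accept if $(drug, v, e)$ already occurs among the extracted
   complete quadruples (drug-specific by default; `any_drug` switches this).
3. *DomainKB* — accept if $(v, e)$ matches a curated record of the drug's
   known effects/side effects (records without a relation verb match any
   verb).
4. *frequency* — accept if the tuple $(v,\, \text{semantic type of } e)$
   occurs strictly more than 3 times across the whole candidate batch. The
   pool is computed over the full batch first, so decisions are order-independent.

Bare phrases ("Very dry skin", "Clearing of acne") are handled by the
ADJ+NOUN, NOUN+NOUN and NOUN-of-NOUN patterns: the descriptor tuple
(descriptor, affected semantic type) is accepted on a DomainKB match, or — if
unseen — when its pooled support strictly exceeds $\beta = 3$. Bare negated
or quantified nouns ("no acne", "less acne") carry no descriptor to pool, so
they are accepted only on a DomainKB term match; their shifters are handed to
the polarity stage.

**5. Polarity detection** (`assign_polarities()`). In order, with earlier
sources never overwritten:

* *DomainKB*: a known effect is positive, a known side effect negative, at
  confidence 1; valence shifters then apply — each in-scope negation (same
  clause, up to 4 tokens before the verb or descriptor) flips the polarity,
  and a decrease-quantifier over an undesirable entity yields positive
  (mirrored for increase/desirable).
* *prior*: bare negated/quantified phrases unknown to the KB take their base
  from the lexicon's desirability prior (DISO terms default undesirable), so
  "no acne" is positive. This source is the package's own addition: the
  shifter there scopes over the entity, not over a drug–effect relation,
  so neither the KB nor the field structure is the right evidence.
* *conjunction*: "and"-linked clauses share a polarity, "but"-linked clauses
  oppose, propagated to fixpoint; pre-tagged inconsistent pairs are left
  alone and logged.
* *structure*: every remaining occurrence votes by its field (benefits
  positive, side effects negative; comment-field occurrences vote by the
  review rating, $\ge 4$ positive, $\le 2$ negative, 3 abstains). Opinions
  with at least 3 voting occurrences take the argmax confidence degree
  $CD(o,p) = C^p/C$ — this is what rescues opinions written into the wrong
  field — and singletons fall back to their own field's basic rule. Where
  conjunction propagation and the structure rule would disagree, the earlier
  stage has already won; the conflict log records such pairs.

**6. Resources.** `build_opinion_kb()` deduplicates tagged quadruples by
case-insensitive key; polarity conflicts keep the higher-confidence side and
exact ties drop the key. `mine_patterns()` substitutes entities by semantic
types, keeps combinations supported by more than 3 KB entries with an
unambiguous majority polarity, then re-substitutes types by groups over the
retained type patterns (so group support counts entries that survived the
type level — a deliberate consequence of the two-stage definition).
`classify_quadruples()` answers new quadruples by KB lookup, then type
patterns, then group patterns; `classify_reviews()` applies this to raw
reviews, skipping the incomplete-opinion filtering as test-time use assumes
every sentence is an opinion.

## What the synthetic fixtures emulate

The review corpora the method was developed on are not redistributable, so
`generate_fixtures()` builds a druglib-style corpus from sentence templates,
with exact planted ground truth. The defaults are the study conditions: 200
reviews; 73% of opinion slots indirect; 93% of indirect opinions incomplete
(the 21-complete/286-incomplete split of the manual corpus); half of the
incomplete ones bare phrases; missing-subject sentences resolvable by the
triple store 53% of the time, the remainder split over the CompIndi, DomainKB
and frequency routes 12:28:7 (the reported shares of the four filters);
negation and quantifier phrases at 10% each (the method names both as
frequent, without rates); field noise 0 by default. Every extraction route —
complete SVO, pronoun-resolved subjects, active missing-subject, passive,
all three phrase patterns, bare shifters, and/but compounds — is exercised,
and each incomplete sentence is constructed with the resources its designated
cascade stage needs (a triple, a complete-anchor sentence, a DomainKB record,
or enough repetitions to clear the frequency bound). Negation phrases are
planted only in the benefits field ("no acne"): a negated *desirable* entity
would need semantic groups (physiology) that the templates otherwise never
use, which would distort group selection.

Template generation buys exact ground truth at the price of linguistic
variety: no misspellings, no ellipsis, no vocabulary outside the closed
lexicon, and field noise as the only annotation noise. Passing the recovery
tests therefore shows the *machinery* is faithful — cascade order, strict
thresholds, shifter algebra, CD arithmetic — not that the bundled tagger
would parse free-form web text; on real data the pluggable tagger, resolver
and triple store should be backed by full engines.

## Numerical choices and degenerate inputs

* Strict bounds throughout: frequency filter and pattern support accept at
  `> 3`, phrase support at `> beta`; support exactly 3 is rejected.
* Metrics with zero denominators are `NA`, never 0; percentages are exact
  internally and rounded to 2 decimals only for display.
* Subject-score ties: drug-typed first, then recency. Pattern polarity ties
  drop the pattern; KB-key polarity ties drop the key; both are logged.
* An empty group selection, an empty review file and an empty KB are legal
  and produce empty results with a warning where the spec of the operation
  calls for one.
* Problem sizes in the test suite (10–200 reviews) keep the full suite and
  the acceptance script to a few minutes on one CPU; 200 reviews is the size
  of the development set the method was tuned on and is where the binomial
  rate checks have power.

## Worked example

```{r example, eval = FALSE}
fix <- generate_fixtures(sim_config(seed = 1, n_reviews = 200,
  field_noise_rate = 0, triple_support_rate = 1))
res <- build_opinion_resources(
  fix$reviews, fix$domain_kb, fix$store, fix$lexicon, fix$background
)
res
evaluate_run(res$quadruples, fix$truth)
autoplot(res$weights)      # SGF-IOF group selection
glance(res$kb)             # OpinionKB composition
```

## Known limitations

The bundled tagger, pronoun resolver and subject/object rules are intentionally
small; they are interfaces, not contributions. Only binary polarity is
modelled (no neutral/mixed class, no intensity, no sarcasm). Multi-drug
interaction statements, aspect/holder/time slots, and spell correction are out
of scope. The desirability prior lives in the lexicon and defaults by semantic
group, which is coarse: a desirable DISO-group term would need an explicit
prior entry.
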