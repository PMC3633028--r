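---
title: "Stable explicit-rule classification of patient cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stable explicit-rule classification of patient cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stablerules)
```

## The problem

Clinical stratification models are only useful if clinicians can read them.
`stablerules` works with classifiers made of explicit if-then rules over
categorical and ordered risk factors, such as

```
if NBhypo in {High} and INSS in {2, 3, 4} and Age in {>=1} then Outcome = Poor
```

Rule-based models of this kind are attractive in oncology because each rule
is a clinical statement that can be audited against prior knowledge. Their
weakness is *instability*: retraining on a slightly perturbed cohort can
produce different rules, which undermines clinical confidence. This package
implements a full workflow around that weakness — induce rules, measure each
rule's stability under repeated cross-validation, identify the individual
patients who cause instability, remove them, and iterate until every rule of
the classifier is perfectly stable.

## Rules and their statistics

A dataset is a set of $n$ pairs $(x_i, y_i)$ where $x$ collects $d$
attributes, each **nominal** (finite unordered value set) or **ordered**
(interval of the real line), and $y$ is one of $q$ class labels. A rule's
premise is a conjunction of conditions, at most one per attribute after
normalization: thresholds $x_j > \lambda$, $x_j \le \mu$ or
$\lambda < x_j \le \mu$ on ordered attributes, membership
$x_j \in \{\alpha, \delta, \ldots\}$ on nominal ones. The empty conjunction
is true, so a rule with no premise covers everything.

Against a dataset, a rule $r$ predicting class $c$ has confusion counts: TP
and FP are the numbers of class-$c$ and other-class instances satisfying the
premise, FN and TN their complements. From them:

$$C(r) = \frac{TP}{TP+FN}, \qquad E(r) = \frac{FP}{TN+FP}, \qquad
  P(r) = \frac{TP}{TP+FP}.$$

Covering $C$ is the fraction of the target class the rule reaches, error $E$
the fraction of the other classes it wrongly captures, precision $P$ the
purity of what it captures. A zero denominator (for example an empty target
class) yields 0 with the statistic's name recorded in an `undefined` field
rather than an error, so downstream products over many rules stay total
while the degenerate case remains diagnosable.

**Prediction.** A pattern takes the consequence of the satisfied rule with
the highest covering; if no rule fires the answer is the reserved label
`NC` (not classified). The source procedure specifies only
"highest covering"; exact ties are broken by higher precision and then by
rule order, a documented choice needed for determinism.

**Conflicts.** Two rules conflict when some pattern of the full attribute
domain satisfies both premises while their consequences differ.
`conflict_pairs()` intersects premises attribute by attribute (member-set
intersection; interval intersection against the schema bounds, intervals
half-open $(\lambda, \mu]$ as in the condition grammar) and reports a pair
iff the intersection is satisfiable, together with a derived `NC` rule whose
premise is that intersection. On the four published final rules for
neuroblastoma outcome this reproduces exactly the two printed conflicting
pairs and their two printed `NC` rules.

**Relevance.** Removing a condition $c$ from $r$ gives a weaker rule $r'$
with $E(r') \ge E(r)$; the increase $R(c) = E(r') - E(r)$ measures the
condition's contribution. (The alternative $P(r) - P(r')$ form can go
negative, which is why the error-difference form is used.) Per attribute,

$$R_j = 1 - \prod_k \big(1 - P(r_k)\,R(c_{kl})\big)$$

over the rules containing a condition on $x_j$ — optionally restricted to
the rules predicting one class. Both factors live in $[0,1]$, so
$R_j \in [0,1]$; a rule with undefined precision (it covers nothing)
contributes a neutral factor.

## Rule induction

The induction engine is a bottom-up *aggregative* learner: it grows rules by
clustering same-class instances rather than by recursively splitting the
data as decision trees do. The published workflow ran a commercial
implementation whose internals are not public; the reconstruction here
honors every stated constraint — bottom-up aggregation, condition-count
minimization, a per-rule training-error cap (default 0%), and full covering
of the training set — with the following concrete algorithm:

1. Ordered attributes are discretized first. Candidate cutpoints sit at
   midpoints between consecutive sorted values whose class composition
   differs; cutpoints are merged, weakest first, until the class-proportion
   gap across every survivor is at least `min_class_distance` (default
   20%). The named method is "attribute driven incremental discretization
   with a minimum distance between classes of 20%", whose internals are
   likewise unpublished; the class-proportion-gap reading here is an
   interpretation, flagged as such. Induced interval endpoints are
   restricted to these cutpoints.
2. For each class, every *distinct attribute profile* held by a class
   instance seeds a maximally specific premise (each attribute pinned to the
   seed's value or discretization bin). The premise is weakened one
   admissible step at a time — drop a condition, add one value to a member
   set, extend an interval by one bin — always taking the step with the
   largest gain in covered class instances subject to
   $E(r) \le$ `max_training_error`; equal gains prefer dropping a whole
   condition, then attribute order. Gain climbing is interleaved to a joint
   fixpoint with zero-gain condition drops, because a drop that gains
   nothing by itself (its extra region is empty) routinely unlocks further
   admissible gains.
3. The resulting pool of maximal candidate rules is deduplicated, and a
   covering subset is selected greedily: most newly covered class instances
   first, ties by total covering, then fewer conditions, then rule text.

Step 3 is a deliberate design choice. Seeding from the first uncovered
instance in dataset order — the more literal covering loop — makes the
*emitted set* of rules depend on instance order, so cross-validation
classifiers trained on 90% subsamples carry order-dependent redundant rules
whose stability plateaus below 1 even on perfectly clean data, and the
stabilization loop below can then never terminate. Profile-complete seeding
plus canonical selection makes induction invariant to instance order
(strictly stronger than the determinism the procedure requires) while
remaining bottom-up and aggregative.

A duplicated profile carried by both classes cannot satisfy a 0% error
bound. Its instances are covered by flagged maximally specific rules, and
the profile is reported in the classifier's `contradictory_profiles` — the
direct feed for the third instability cause below.

## Stability under repeated cross-validation

`run_cv()` performs $n$ independent stratified $m$-fold cross-validations
(defaults $5 \times 10$), inducing one classifier per held-out fold: $N = n
\cdot m = 50$ classifiers. Two rules are *occurrences* of the same rule when
they have the same consequence and distance $d < \varepsilon$ for a distance
metric $d$. The metric is left unspecified by the source, which also writes
the stability denominator inconsistently ($b/(n+m)$ against prose counting
50 classifiers); this implementation defines

* $d(r_1, r_2) = 1 - $ Jaccard similarity of the two covered-instance sets
  on the full reference dataset (semantic, scale-free; rules that behave
  alike are the same occurrence regardless of spelling), with
  $\varepsilon = 0.05$ as a configurable default, and
* $\text{Stability}(r) = b/N$ where $b$ is the number of the $N = n \cdot m$
  classifiers containing at least one occurrence of $r$.

Stability 1 means the rule reappears in every classifier. A classifier is
*stable* when every rule has stability at least $1-\nu$; $\nu$ defaults to
0 because the published loop runs until each rule reaches exactly 1.

**Core rules.** Same-consequence rules pooled across the $N$ classifiers are
clustered by single linkage under $d < \varepsilon$ (the cheapest reading of
"identify similar rules", documented as a choice); each cluster's Core rule
takes the attribute-wise intersection of its component premises, dropping
clusters whose intersection is unsatisfiable. A Core rule is therefore at
least as specific as each component, so its covered set is contained in
every component's. Its aggregated stability is the fraction of classifiers
contributing at least one component; the source says only that Core
stability is computed "from the component stabilities", and the
contributing-classifier fraction is the reading used here. Each Core rule
also records which classifiers its components came from.

## Diagnosing and purging instability

Three causes of instability are screened over the Core rules:

1. **Low-covering unstable rules** (`low_covering_unstable`): a rule with
   stability below $1-\nu$ and covering at most `s_cov` (default 0.1)
   exists only when its few supporting instances all fall in the training
   split. The instances it covers *exclusively* — no stable rule covers
   them — are flagged; instances shared with stable rules keep their
   support.
2. **Near-duplicate rules** (`near_duplicate_rule`): two same-consequence
   rules $r_k, r_h$ with $1 \le |H(r_k) \setminus H(r_h)| \le$ `s_diff`
   (default 1), where $H$ is the covered set. The learner generates both
   rules only when the difference instances are in the training set, so
   those instances are flagged. The strict "$< s$, e.g. $s = 1$" reading
   would make the difference empty, contradicting the surrounding text
   about "the instances in $H(r')$", hence the inclusive bound. The pair
   must additionally have been generated together in at least one
   cross-validation classifier (the definition is stated over two rules of
   one classifier $g(x)$): without this, mutually exclusive variants of one
   rule — which never co-occur — would flag an innocent instance.
3. **Ambiguous profiles** (`ambiguous_profile`): a group of instances with
   one shared full attribute profile but more than one outcome label. Which
   class the learner assigns them depends only on the chance imbalance
   between training and test splits, so the whole group is flagged.

`stabilize()` wires these into the iterative loop: induce on the current
dataset, assess stability over $5\times10$ CV, stop when every rule reaches
$1-\nu$ *and* induction met its error contract on every rule (a reported
contradictory profile counts as instability even if its flagged rules
recur in every fold — it is exactly cause 3 waiting to be purged);
otherwise build Core rules, diagnose, remove the flagged instances from the
full dataset (never inside CV folds), and start a new iteration. A safety
cap (`max_iterations`, default 10) and an error on an empty diagnosis under
persisting instability guard against infinite loops; both raise a condition
carrying the full per-iteration log. On success every returned rule has
stability $\ge 1-\nu$, re-running stabilization on the returned dataset is
an identity, and no remaining instance satisfies any conflict-pair witness
premise.

For independent validation, `purge_matched()` mirrors the matched deletion
applied to a held-out cohort: every test instance whose full attribute
profile equals that of a removed training instance is dropped before
`performance_metrics()` is computed.

## Significance and performance

`fisher_rule_test()` tests each rule's 2×2 table (premise satisfied ×
class membership) with Fisher's exact test, one-sided for enrichment of the
rule's own consequence class — this orientation matches the per-class label
switching the procedure describes for poor-outcome rules; a two-sided
variant is available. `performance_metrics()` reports accuracy, recall,
precision, specificity and NPV with the good-outcome class as positive;
`NC` predictions are counted separately and score as errors by default
(conservative headline numbers), with `exclude_nc = TRUE` as the option.

## The synthetic cohort generator

The study cohorts behind the published tables are not deposited, so the
package ships a generator that emulates their structure and provides ground
truth for recovery tests. `generate_cohort()` draws attribute vectors from
declared marginals (optionally conditional on one earlier attribute),
assigns outcomes by the first matching planted rule (else a background
class), optionally flips labels at a noise rate, and finally overwrites
reserved profiles with *ambiguous groups* (one profile, fixed size, exact
class split) and *singleton injections* (a unique profile carrying a
contradicting label). Reserved profiles are excluded from the random draw,
so the planted counts are exact and singletons are genuinely unique; all
generators are pure functions of (spec, seed).

`nb_cohort_spec()` is the default, 182-instance, four-risk-factor cohort:
INSS stage 1/2/3/4/4s at 23/13/13/38/13%, Age at diagnosis under one year
47%, MYCN amplified 16%, dichotomized hypoxia signature High 25%, outcomes
planted by a four-rule final classifier (stage-4 and high-hypoxia stage-2–4
older patients poor outcome, low-hypoxia MYCN-normal and non-stage-4
MYCN-normal patients good outcome), one 24-instance ambiguous group
(low-hypoxia, stage 4, MYCN-normal, ≥1 year; split 12/12) and one
singleton. Age, MYCN and NBhypo are drawn *conditionally on stage*: 4s is
an infant stage, stages 3–4 affect older children, amplification is
confined to stage 4 (42%), high hypoxia to stages 3 (60%) and 4 (45%) —
each row solved so the marginals above are preserved. The conditionals are
there for two reasons. Clinically, these risk factors are strongly
associated, not independent. Statistically, a classifier can only be fully
stabilizable if every stratum that supports or blocks one of its rules is
populated well above the cross-validation holdout size; under independent
draws at $n = 182$ several such strata have expected counts of 2–6, a
chance realization of one or two instances makes some fold's rule swallow
or shrink a whole stage, and none of the three causes can attribute that to
an instance — the loop then (correctly) refuses to converge. A cohort whose
stabilization *does* terminate with every rule at stability 1, as the
published one did, necessarily has the well-populated-strata property, so
the generator reproduces it.

Known limitations, which bound what passing tests say about real data: the
generator produces no missing values, no continuous raw covariates (ordered
attributes are sampled from finite value pools), label noise independent of
the attributes, and a poor-outcome fraction (~25%) close to but not equal
to the published 28% because the planted rules, not a free parameter,
determine it. The singleton injections are constructed to force their own
rule in the default cohort; with `ambiguous_size = 0` the first-iteration
stage-4 rule is no longer held specific by the ambiguous profile and can
absorb a singleton through a one-value stage extension, after which the
instance is not attributable — recovery claims are therefore made for
cohorts containing both noise types.

`generate_expression()` and `kmeans_dichotomize()` cover the upstream step
that turns a numeric signature into a categorical risk factor: a
samples × probes two-group Gaussian matrix (default 62 probes), clustered
by Lloyd-style k-means with Manhattan distance, component-wise median
centers, at most 500 iterations, and deterministic initialization from the
first $k$ rows so that instance order is preserved and reruns are
identical. This k-means is hand-written: no installed implementation offers
Manhattan distance with order-preserving initialization. The sum of
within-cluster distances is reported for each candidate $k$; every
candidate additionally warm-starts from the previous solution (its centers
plus the worst-fit row) and the lower-cost fit is kept, which guarantees
the curve is monotone non-increasing so the elbow at the true group count
is readable. Elbow selection is reported, not automated.

## Numerical choices and degenerate inputs

* Zero denominators in C/E/P and in performance metrics return 0 with an
  `undefined` marker, never an error or NaN.
* Rule distance between two rules with empty covered sets is 0 if their
  premises are symbolically identical, incomparable (`NA`) otherwise.
* Contradictory conditions on one attribute (empty intersection) are a
  parse/normalization error; unsatisfiable Core-rule clusters are dropped.
* Ordered-attribute satisfiability is decided against the schema bounds
  with half-open $(\lambda, \mu]$ intervals throughout.
* `classify` ties: covering, then precision, then rule order.
* Fold assignment, cohort generation and expression generation consume
  seeds through an RNG-state-preserving wrapper, so library calls do not
  disturb the caller's random stream.

## Problem sizes

The shipped tests run the full loop at the default cohort size ($n = 182$;
the 200-instance variant for the cross-validation bookkeeping check),
20-seed recovery sweeps for the parameter-recovery property, 100-case
randomized sweeps for the relevance bound, and oracle comparisons (exact
enumeration for Fisher tables, full-grid enumeration for conflicts,
per-instance loops for confusion counts) at 25–60 instances — sizes chosen
so the entire suite completes in about a minute while every check runs at
the same structural scale as the study it emulates.
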