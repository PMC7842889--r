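---
title: "Methods: sustainability scoring, state comparisons, and document classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sustainability scoring, state comparisons, and document classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sorsustain)
```

# The problem

When the federal government distributes time-limited grants — here, State
Opioid Response (SOR) awards supporting medications for opioid use disorder
(MOUD), overdose reversal, prevention, and recovery services — a central
question is whether the funded services will survive the end of the grant.
`sorsustain` implements a complete, testable pipeline for assessing
*sustainability planning* in such grant applications: a human-coding rubric
and its summary arithmetic, comparisons of responding vs non-responding
states, ordinal regression screens of state-level predictors, and automated
document classification from text features. Because the underlying
application documents are confidential, the package also ships a synthetic
generator that reproduces the statistical structure of both the corpus and
the state covariate table, so that every stage can be exercised and
validated end to end.

# The sustainability rubric

Each application is coded for whether it discusses sustainability at all
and for three criteria: **funding** (a credible post-grant funding source:
Medicaid waiver, private insurance, billing codes, existing funding
streams), **policies** (new policies, partnerships or regulations that
outlast the grant), and **quality monitoring** (explicit post-grant quality
or evaluation infrastructure). The grade is

| coding | grade |
|---|---|
| all three criteria met | 5 |
| exactly two met | 4 |
| exactly one met | 3 |
| sustainability discussed, no definite plans | 2 |
| no mention of sustainability | 1 |

equivalently `grade = 2 + (#criteria)` when at least one criterion is met.
A met criterion is by definition a sustainability discussion, so a coding
with a criterion met but `mentioned = FALSE` is rejected as inadmissible;
nine admissible codings exist and `score_from_criteria()` is total over
them. The judgment of *whether* a criterion is met is expert work; the
package deliberately takes the boolean outcome as input rather than
attempting to parse it from text (the automated route is the classifier,
and it targets the dichotomized scale, not the criteria).

Multi-coder grades are resolved by `consensus_check()`: a supplied human
consensus wins; otherwise the median is used with even-count ties broken
toward the **lower** grade and the result flagged as a fallback. The
lower tie-break is deliberately conservative — when coders disagree, the
automatic resolution must not overclaim sustainability.

`summarize_corpus()` keeps percentages unrounded internally and rounds to
one decimal only at the report layer. One subtlety discovered in testing:
the published marginal counts for the criteria are not jointly consistent
with the grade distribution (the three criterion counts sum to 39, while
the grades imply 37 met-criterion slots), so `corpus_from_counts()`
reproduces marginals, not a joint coding.

# Text features

`tokenize()` lowercases, splits sentences on `.`/`!`/`?` followed by
whitespace, and extracts word tokens on non-alphanumeric boundaries,
keeping internal hyphens and apostrophes ("state-funded" is one token).
"Text length" means **token count** throughout: the long-word and
words-per-sentence features are token-based, so normalizing counts by
tokens keeps every frequency on one scale.

Keyword categories are counted by exact-token matching with **no
stemming** — the lexicon lists inflected variants explicitly (e.g.
*sustaining, sustainment, sustainability, beyond funding*) — and multiword
terms must appear as consecutive tokens in order. Matching is greedy,
longest-first, non-overlapping, so a term contained in an already-matched
phrase is not double-counted. The packaged lexicon carries the seed terms
named for each category; the full supplementary keyword lists are not
public, and users with access can load them via `load_lexicon()`.
Consequently, published per-category word counts are not reproducible
here: they require both the full lists and the confidential corpus.

Stylistic features: function words are counted against a packaged,
user-replaceable closed-class list (articles, prepositions, auxiliaries);
long words are tokens with more than six letters; future tense is detected
as `will`/`shall`/`going to` followed by a token that is not an article or
preposition. Auxiliaries are allowed as the continuation so that passive
and progressive futures ("will be sustained") count — a detector that
demanded a content word immediately after the modal would miss exactly the
constructions these documents use most.

# State covariate comparisons

`run_battery()` compares SOR-providing vs non-providing states variable by
variable with per-variable complete-case handling:

* **Welch (unequal-variance) t-test** for continuous covariates, from raw
  data or from printed summaries (`welch_t_from_summary()`). The Welch
  form, not the pooled form, reproduces the published p-values from the
  published group summaries (e.g. uninsured: 0.056), which is how the
  choice was fixed.
* **Population is compared on the log scale** (its distribution across
  states is heavily right-skewed). A log-scale test cannot be recomputed
  from arithmetic-scale printed summaries, and the package says so rather
  than silently substituting.
* **Yates continuity-corrected chi-square** for the two policy flags; the
  corrected form reproduces the published Medicaid-expansion p-value
  (0.173) from its printed counts, the uncorrected form does not.
* **Two-group Poisson rate comparison** with exposure offsets
  (closed-form Wald on the log rate ratio, `SE = sqrt(1/e1 + 1/e2)`) for
  count variables. Only the two-group contrast is needed, so this is a
  closed form rather than a general regression fitter.

With ~15 tests at n = 50 there is real multiplicity but little power, so
rather than adjusting p-values the battery is accompanied by the **p-p
diagnostic** (`pp_envelope()`): the observed ordered p-values are plotted
against rank-wise envelopes of the order statistics of k iid Uniform(0,1)
variables, obtained by Monte Carlo with a recorded seed (default 10,000
draws; coverage 0.95). The i-th order statistic is Beta(i, k−i+1), and the
closed form serves as the *test oracle* for the simulated envelope — the
shipped implementation simulates because the envelope is defined by
simulation, and the tests verify the simulation against the Beta quantiles
(within 0.01 at 100,000 draws).

The two study-design power statements are implemented exactly:
`power_t_two_sample()` uses the noncentral t distribution
(`ncp = d * sqrt(n1 n2 / (n1 + n2))`); at d = 0.8, n = (34, 16),
alpha = 0.05 it gives 0.734, consistent with the quoted "70% power" (the
quoted "0.5 t-test" is read as alpha = 0.05). `power_two_proportions()`
uses the pooled-variance-under-the-null normal approximation, which gives
0.701 at (0.20, 0.55) with the same sizes; the arcsine formulation gives
~0.69 and was not chosen because the pooled form lands on the quoted
figure exactly.

# Ordinal regression machinery

The sustainability grade is ordinal, so the central model is the
**cumulative-logit (proportional-odds) model**

$$\mathrm{logit}\, P(Y \le j \mid x) = \theta_j - x'\beta,
\qquad j = 1, \dots, K-1,$$

with increasing thresholds θ and a single β shared across all splits of
the 1–5 scale. The sign convention is chosen so that **positive β means
higher covariate values push toward higher sustainability grades**.
Covariates enter in raw units (no standardization): reported coefficients
are per unit — per prescription per 100 people, per percentage point —
which is how effect sizes in this literature are read.

`fit_cumulative_logit()` is fitted by Newton iteration on the analytic
gradient, with the observed information obtained by central finite
differences of that gradient. Each step is **halved** until the
log-likelihood does not decrease and the thresholds remain strictly
increasing, so the log-likelihood trace is monotone by construction (and
asserted in tests). Starting values are the empirical cumulative logits
with β = 0 — for the intercept-only model these are already the MLE.
Convergence: relative log-likelihood change below 1e-10 or 100
iterations. Standard errors come from the inverse observed information at
the optimum. Separation is detected heuristically (|β| > 15, or exploding
or non-finite SEs); when flagged, Wald SEs are suppressed and the
univariate screen substitutes a likelihood-ratio test against the
intercept-only model — mirroring how zero-cell outcomes must be handled in
practice. The fitter is validated against `MASS::polr` (coefficients and
SEs to ~1e-4) and, on binary outcomes, against `fit_logistic()` (which
delegates to `stats::glm` and adds the same separation flagging).

The multivariable recipe (`stepwise_model()`) follows the screening
pipeline exactly: univariate Wald screens; entry of covariates with
p ≤ 0.20; **collinearity pruning** at |r| > 0.9, keeping the
earlier-listed member of each offending pair (resolved greedily in
priority order, so in a transitive triple the highest-priority variable
survives); then **backward elimination** removing the largest-Wald-p
covariate while it exceeds the stay level 0.05, refitting each step and
recording the removal trace. Wald (not LRT) is used at each removal step
for consistency with the univariate screens; the stay level 0.05 matches
the significance level used everywhere else in the analysis.

# Document classification

With only ~34 documents, learning five grade classes is hopeless, so the
scale is dichotomized: grades 4–5 ("high", a real sustainability plan) vs
1–3 ("low"). Evaluation is **exhaustive leave-one-out cross-validation**:
every document is predicted from a model trained on the remaining n−1, so
accuracy is a multiple of 1/n and the procedure is deterministic given
data and specification. (The description of one-at-a-time random holdouts
is ambiguous between exhaustive LOOCV and repeated random holdout;
exhaustive LOOCV is implemented as the default and `random_holdout()` is
provided as the option.) A fold whose training set degenerates to one
class predicts that class and is flagged.

Two families are provided:

* **Multinomial naive Bayes**, written from scratch: class score =
  log prior + Σ count · log(smoothed class term probability), Laplace
  pseudo-count 1.0 by default. It consumes **raw keyword counts**, not
  length-normalized frequencies — the multinomial likelihood is a model of
  counts. Ties break toward "low", again the conservative direction. The
  implementation is verified against exact posterior enumeration on small
  instances.
* **Soft-margin kernel classifier** (radial or linear kernel, cost C),
  delegated to `e1071::svm` behind a pluggable-backend contract; it
  consumes the normalized feature vectors. `cost_grid_search()` evaluates
  LOOCV accuracy over a cost grid on (0, 1] in steps of 0.01 — zero is
  excluded because a soft-margin cost must be strictly positive — and
  returns the full curve with smallest-cost tie-breaking.

Published corpus accuracies (82% naive Bayes, 78% tuned linear SVM, etc.)
are properties of the confidential corpus and are **not** targets here;
the reproducible properties are those provable on synthetic corpora:
perfect accuracy under strong class separation, and majority-baseline
behavior under label permutation. On the permutation null, note that mean
LOOCV accuracy sits slightly *below* the majority baseline — the held-out
document's class is always underrepresented in its training fold, the
standard LOOCV pessimism — so the permutation test bands use the
permutation distribution's own spread.

# The synthetic generator

`gen_corpus()` emulates exactly the structure the analysis assumes and
nothing more: a latent grade per document (default distribution = the
published grade counts (3, 8, 11, 10, 2)/34); negative-binomial token
lengths (default mean 1500, dispersion 8 — grant narratives are long, and
negative-binomial lengths avoid a degenerate equal-length corpus);
filler tokens from a synthetic vocabulary; and per-category keyword
injections drawn Binomial(length, rate(category, grade)) and written over
random free positions. Default rates put the expected per-category counts
at the published corpus means for a 1500-token document, with the
sustainability-category rate tilted linearly in grade (×0.7 at grade 1 to
×1.3 at grade 5) so that keyword density carries the grade signal.
Criteria codings are drawn by inverting the rubric (grade g ≥ 3 means g−2
criteria chosen at random), so re-scoring the emitted codings reproduces
the drawn grades exactly — a construction-level invariant the tests
assert. What the generator does **not** emulate: English syntax, topical
coherence, discourse structure, or correlations between style features
and grade. Passing tests therefore demonstrate the machinery's
correctness on corpora with the assumed statistical structure, not
classifier performance on real grant prose.

`gen_state_table()` draws covariates from a Gaussian copula: normal
marginals (clipped to [0, 100]) for percent-type covariates, lognormal
marginals with matching mean and SD for the strongly right-skewed
positive scales (population, admission and death rates, dollars, clinic
rates), and thresholded latent normals for the two policy flags. The
default moments are the published SOR-state column; the only published
correlation (0.94 between misuse at ages 12+ and 26+) is built into the
default correlation matrix, identity elsewhere — the full matrix was
never published, so this is a documented modeling choice. Grades come
from the cumulative-logit model applied to the **standardized latent
scores**, so the generator's β is a per-SD log-odds; this keeps effect
sizes meaningful across covariates whose raw units span seven orders of
magnitude. Recovery tests fit on the standardized scores for exactly that
reason.

`gen_null_pvalues()` draws k seeded iid uniforms — the simulated null of
the p-p diagnostic.

# Numerical choices and degenerate inputs

* Newton tolerance 1e-10 (relative log-likelihood), max 100 iterations,
  up to 40 step-halvings; singular information falls back to a tiny ridge.
* Yates statistic truncates at zero when the correction exceeds
  |ad − bc| (matching the standard implementation).
* Zero-margin 2×2 tables, zero-event Poisson comparisons, empty p-value
  sets, empty documents, and single-class training sets are all rejected
  or flagged rather than silently producing numbers.
* Naive Bayes tie detection uses an absolute log-score tolerance of 1e-9;
  exact ties go to "low".
* All seeded helpers save and restore the caller's RNG state.

# Problem sizes used in the test suite

The suite exercises the machinery at sizes chosen to make the relevant
asymptotics visible while staying desk-scale: parameter recovery and
copula checks at n = 2000 states; the Wald screen's type-I error over
1000 null replicates at n = 50 states; the p-p envelope against Beta
quantiles at 100,000 simulations; classifier benchmarks on 34–60 document
corpora with 200–300-token documents (the generator's 1500-token default
is used in the analysis scripts; tests shorten documents because token
length does not change any tested property, only runtime).

# Known limitations

* The rubric's criterion booleans are inputs; no attempt is made to
  extract them from text.
* The battery's Poisson route is a two-group closed form, not a general
  Poisson regression.
* Published regression coefficients and classifier accuracies require the
  confidential corpus and full state dataset and are out of scope; the
  published MOUD-coverage comparison (p = 0.988) is not reproducible from
  its printed counts by any chi-square variant, and is reported as such.
* The proportional-odds assumption is imposed, not tested; with ~34–50
  units a formal test would be uninformative anyway.
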