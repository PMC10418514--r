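---
title: "Matching patients to clinical trials: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matching patients to clinical trials: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trialmatchr)
```

## The problem

Recruiting for a clinical trial — or finding a trial for a patient — means
checking a free-text patient summary against the free-text inclusion and
exclusion criteria of thousands of candidate trials. trialmatchr implements
a three-stage pipeline for the patient-centric direction of this task:

1. **Retrieval**: generate a ranked list of medical keywords from the
   patient note, retrieve trials per keyword with a lexical and a dense
   retriever, and fuse the per-keyword rankings into one candidate list.
2. **Matching**: for each candidate trial, ask a language-model backend to
   assess the patient against every criterion individually, producing an
   explanation, the IDs of supporting sentences, and an eligibility label.
3. **Ranking**: aggregate the criterion labels into trial-level scores and
   rank (or exclude) the candidates.

Every model call goes through one pluggable backend contract, so the whole
pipeline runs — and is tested — against a deterministic rule-driven oracle
with no network access or model weights.

## Stage 1: keyword-fused hybrid retrieval

A backend call turns the note into up to `max_keywords = 32` keywords,
deduplicated case-insensitively and treated as importance-ordered: the
first keyword is the most important. Each keyword $w_i$ is issued to each
retriever, and trial $t_j$'s fused score is

$$ s_j \;=\; \sum_{\mathrm{Ret}} \sum_{i=1}^{K}
   \frac{1}{\,i \cdot \big(\mathrm{Rank}(\mathrm{Ret}, w_i, t_j) + C\big)\,}, $$

a reciprocal-rank fusion across retrievers with an extra $1/i$ decay across
keywords, with $C = 20$ by default. Two numerical choices matter here:

* **Absent trials contribute zero.** When $t_j$ is missing from a
  (retriever, keyword) ranking, that term is 0 rather than being assigned
  a sentinel rank of depth + 1. The alternative would make scores depend
  on the configured retrieval depth, which is an implementation knob, not
  part of the model. The per-keyword depth defaults to 1000 and is
  configurable.
* **Ties break by ascending trial ID** — everywhere in the package — so
  runs are bit-reproducible.

The lexical retriever is BM25 with $k_1 = 1.5$, $b = 0.75$, tokenization
by lowercasing and splitting on non-alphanumeric characters, and the
non-negative inverse document frequency
$\log\!\big(1 + (N - \mathrm{df} + 0.5)/(\mathrm{df} + 0.5)\big)$. The
non-negative variant is used because single-keyword queries against small
corpora frequently contain terms present in more than half the documents,
where the classical signed idf would produce negative scores and make the
"score > 0 means retrieved" convention ambiguous.

The dense retriever is a contract — anything that scores a (query, trial
text) pair — and its default implementation is a deterministic
hashed bag-of-words cosine. That default exists so the hybrid fusion path
is fully exercisable in tests; it is **not** a trained semantic encoder,
and retrieval quality with it reflects token overlap only.

## Stage 2: criterion-level matching

Each trial side (inclusion, exclusion) is assessed in one backend call; a
side with no criteria makes no call. Labels come from side-specific closed
sets: `included` / `not included` / `not enough information` /
`not applicable` for inclusion criteria, and `excluded` / `not excluded` /
`not enough information` / `not applicable` for exclusion criteria —
exclusion criteria are phrased too heterogeneously ("Pregnancy",
"Pregnant patients will be excluded") for entailment-style labels to
transfer cleanly, which is why the sets are eligibility-oriented.

The prompt numbers the criteria and the patient sentences (sentence IDs
are 0-based, a convention fixed once in the data model and used in
prompts, parsed responses and stored assessments alike) and requests JSON
with, per criterion, the explanation *first*, then sentence IDs, then the
label, so the label is grounded in generated reasoning. Criteria are
passed verbatim with no normalization. Responses are strictly validated:
a label outside the side's set, a missing criterion, or malformed JSON
triggers a re-send of the identical prompt (temperature 0) up to 3 times
before a terminal error that carries the raw response. Out-of-range
sentence IDs are rejected in strict mode and dropped with a logged warning
in lenient mode. Responses covering only a subset of criteria are treated
as parse failures (strict retry) rather than partially accepted.

## Stage 3: aggregation and ranking

With $M$ inclusion and $N$ exclusion labels and
$M' = M - \#\mathrm{not\,applicable}$ (similarly $N'$), the six linear
features are the label fractions per side, e.g.
$\%\,\mathrm{met\ inclusion} = \#\mathrm{included} / M'$. When a
denominator is zero the three fractions of that side are defined as 0, so
a fully-not-applicable side neither rewards nor penalizes a trial. The
"not enough information" fractions are computed and exported for analysis
but do not enter the combination score.

A second backend call produces trial-level aggregates: a general relevance
$R \in [0, 100]$ and an eligibility score $S$ with $|S| \le R$ (a patient
cannot be more decisively eligible than they are relevant). Backend values
violating these constraints are **clamped** to the nearest feasible value
with a logged warning rather than rejected: the constraints are
restrictions on a score scale, and clamping keeps long pipeline runs total
under imperfect backends while the log preserves auditability. The
combination score is

$$ \mathrm{combination} = \%\,\mathrm{met\ incl}
   - \mathbb{1}[\%\,\mathrm{unmet\ incl} > 0]
   - \mathbb{1}[\%\,\mathrm{met\ excl} > 0]
   + R/100 + S/100. $$

The division by 100 puts the two aggregate terms on the same $[-1, 1]$
scale as the percentage features; comparability of magnitudes is the
rationale, and `normalize_llm = FALSE` switches to raw aggregates for
users who want the un-normalized variant. Single-feature ranking keys are
oriented so that higher always means more eligible.

Baseline scorers (dual-encoder similarity means over criterion vectors,
and NLI-label-mapped criterion predictions combined as
$\%\mathrm{met\,incl} - \%\mathrm{unmet\,incl} - \%\mathrm{met\,excl} +
\%\mathrm{unmet\,excl}$ for ranking) are provided behind encoder
contracts with hashed-projection defaults; the NLI `neutral` label maps to
`not enough information`, leaving `not applicable` unreachable from NLI
output. Dual-encoder dot products are raw by default, with a normalized
(cosine) encoder available; an empty criterion side contributes a mean of
0.

## Evaluation protocol

Trial-level judgments are three-level: `eligible` maps to relevance grade
2, `excluded` and `potential` to 1, `irrelevant` and unlabeled pairs to 0.
Metrics:

* `recall@k` — summed top-k grades over the summed grades of the whole
  labeled collection for that patient;
* `ndcg@k` — standard graded NDCG with $\log_2(x+1)$ discounts; a patient
  whose ideal DCG is zero contributes 0 (logged);
* `p@k` — **graded and normalized**: summed top-k grades divided by
  $2k$. This is deliberately not classical binary precision; with ten
  eligible trials in the top 10 it equals 1, with ten `potential` trials
  it equals 0.5;
* `auroc` — Mann–Whitney with midrank ties, for the trial-*excluding*
  task: positive class is the `excluded` label, negative is `eligible`,
  and `potential`/`irrelevant`/unlabeled pairs are dropped. Run scores
  rank by eligibility, so `evaluate_run()` negates them for this metric.

Rank metrics are macro-averaged with equal patient weight, as per-topic
means are reported in retrieval evaluations.

## The synthetic cohort and its oracle

`generate_cohort()` emulates the *structure* of public patient-trial
matching collections: short sentence-segmented patient narratives, a
shared pool of trials with explicit criterion lists, a per-patient mix of
eligible / excluded / potential / irrelevant labeled trials, and a large
unlabeled remainder (mirroring pooled judgment). Each trial targets a
unique synthetic condition and carries three inclusion criteria (age,
diagnosis, a serum-marker threshold) and one exclusion criterion (history
of a comorbid syndrome). Facts are planted as template sentences, so

* every decisive criterion label is witnessed by a sentence actually
  present in the note (audited at construction time), and
* trial-level labels follow from criterion labels by a fixed precedence:
  any `excluded` label makes the pair excluded; otherwise a majority of
  `not enough information` makes it irrelevant; otherwise any remaining
  uncertainty (or an unmet inclusion criterion) makes it potential;
  otherwise eligible.

The default scale is 20 patients × 200 trials with 10 eligible, 6
excluded, 2 potential and 2 explicitly-irrelevant labeled trials per
patient — enough eligible trials that a perfect ranking saturates the
top-10 window, so the noiseless end-to-end expectation is exact, while
keeping a full pipeline run under a minute on one CPU. All generator
randomness is hash-derived from the seed, making cohorts byte-identical
across runs and independent of the global RNG.

The oracle backend answers keyword requests with the planted condition
terms, matching requests with the ground-truth labels and witness
sentences, and aggregation requests with a fixed map from the true
trial-level label — eligible (90, 80), excluded (80, −80), potential
(70, 10), irrelevant (10, 0) — chosen so the noiseless combination score
separates the label classes deterministically (optional seeded jitter
respects the score constraints and is off by default). Label noise flips
each matching label independently to a uniformly chosen *different*
same-side label with probability `noise_rate`; flips are hash-keyed per
(patient, trial, side, criterion), so the noisy stream is reproducible
and order-independent.

**What passing tests do and do not show.** The synthetic text is
template-generated: vocabulary overlap between notes and trials is exact,
criteria are short and atomic, and there is no negation ambiguity,
abbreviation noise, or clinical reasoning beyond token-level facts.
Perfect recovery under the noiseless oracle validates the *plumbing and
arithmetic* of the pipeline — fusion, parsing, aggregation, ranking,
metrics — not the clinical competence of any real backend. Noise-sweep
behavior shows the scoring degrades gracefully with label errors; it says
nothing about the error *structure* of a particular model.

## Other numerical and interface choices

* Sentence segmentation is a deterministic rule (split after
  sentence-final punctuation followed by whitespace), so decimals in lab
  values never split; abbreviations like "Dr." do, which is acceptable
  for the note styles targeted and keeps segmentation dependency-free and
  reproducible.
* Criteria blocks split on headers (`inclusion criteria` /
  `exclusion criteria`, case-insensitive) and newlines only — never on
  sentence punctuation, because criteria routinely contain internal
  periods in thresholds. Each bullet line is one criterion; nested
  "all of the following" structures are deliberately not flattened
  further.
* Qrels files use configurable integer-code maps (default: 2 eligible,
  1 excluded, 0 irrelevant); the four-label synthetic cohort is written
  with an extended map adding 3 = potential.
* The backend cache key is the exact (backend id, purpose, temperature,
  prompt) tuple — no digest, so collisions are impossible — persisted as
  append-only JSONL for diffability.
* Test and acceptance problem sizes: oracle-equivalence checks run
  hundreds of random instances at up to 20 trials and 5 keywords;
  end-to-end checks use the default 20 × 200 cohort; the reproducibility
  check uses 6 × 40. These sizes are the package's chosen trade-off
  between statistical resolution and a test suite that stays fast enough
  to run on every change.

## Known limitations

* No real language-model adapter is bundled; `make_backend()` is the
  integration point and the repository's tests never require network
  access.
* The dense retriever and baseline encoders are hashed-projection stubs;
  reproducing published numbers for trained encoders is out of scope.
* Inputs are single free-text summaries: no structured EHR fields,
  longitudinal notes, or multi-modal data.
* Criterion-level explanation *quality* is not evaluated — only label
  agreement and sentence-ID validity are checked.
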