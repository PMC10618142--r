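# ashn

Interpretable screening of postpartum-depression risk from a user's
collection of short social-media posts.

## The problem

Postpartum depression is common and under-detected. Screening
questionnaires (here the PDSS, a 0–63 score) label a mother as control
(score < 11) or depressed (score > 29), but the behavioural trail — dozens of
short posts per user — is where early warning signs live. Plain deep-text
classifiers can label users but cannot say *why*. `ashn` implements an
attribute selection hybrid network: a user-level classifier whose evidence is
forced through four psychologically motivated views of each post, so the
model's softmax weights double as its explanation. It is written for
mental-health informatics researchers who need a classifier, an attribution
report, and a fully synthetic test bed in one package.

## The model

Each post's tokens are embedded and encoded by a CNN (convolution +
max-over-time) into $\mathbf{x}$. Five attribute vectors are computed per
post:

| | view | mechanism |
|---|---|---|
| $\mathbf{a}_0$ | raw content | linear projection of $\mathbf{x}$ |
| $\mathbf{a}_1$ | psycholinguistic style | GRU over the 48-tag part-of-speech one-hot sequence |
| $\mathbf{a}_2$ | sentiment | GRU over 3-way lexicon polarity one-hots |
| $\mathbf{a}_3$ | depressive symptoms | $\mathbf{Y}=\mathrm{softmax}(\mathbf{x}\mathbf{W}\mathbf{E}_i)$ against a 9-row symptom matrix built from 76 DSM-5 keywords; $\tanh(\mathrm{MLP}(\mathbf{Y}))$ |
| $\mathbf{a}_4$ | rumination | $\mathbf{f}=\mathrm{softmax}(\mathbf{x}\cdot\mathbf{X}_{\text{others}}^\top)$, sorted profile through $\tanh(\mathrm{MLP}(\cdot))$ |

Fusion weights $\mathbf{w}=\mathrm{softmax}(\mathrm{MLP}(\mathbf{x}))$ give the
post vector $\mathbf{p}'=\sum_{i=0}^4 w_i\mathbf{a}_i$; post-level attention
$a=\mathrm{softmax}(\mathbf{p}'\mathbf{W}\mathbf{v})$ aggregates a user's posts
into $\mathbf{o}=\sum_i a_i\mathbf{p}'_i$, and an MLP + sigmoid yields the
depressed-class probability. Training is Adam with L2 and gradient-norm
clipping on user-level binary cross-entropy, on a reverse-mode autodiff
engine built into the package (gradients are verified against finite
differences in the tests). A bidirectional-GRU baseline shares the attention
and classifier. The package also ships the cohort pipeline (cleaning, length
filters, score-based grouping), the linguistic layers (tokenizer, 48-tag rule
tagger, sentiment and symptom lexicons, vocabulary, frequency tables),
evaluation metrics with attention/attribution reports, and a seeded synthetic
corpus generator with an exact injection audit.

## Worked example

```r
library(ashn)

corp <- simulate_corpus(simulate_config(n_users = 20L, posts_per_user_mean = 20,
                                        posts_per_user_sd = 3, seed = 42L))
corp
#> ashn cohort: 20 users (10 depressed, 10 control), 408 posts

sp  <- split_cohort(corp$cohort, 0.2, seed = 42L)
fit <- ashn(sp$train, ashn_config_demo(epochs = 6L, sample_posts = 20L,
                                       a4_len = 20L, seed = 42L))
fit
#> Attribute selection hybrid network (attribute model)
#>   users: 16   vocabulary: 246 ids   epochs: 6
#>   training loss: 0.6913 -> 0.4610

ev <- evaluate(fit, sp$test)
sprintf("precision %.3f recall %.3f accuracy %.3f F1 %.3f AUC %.3f",
        ev$precision, ev$recall, ev$accuracy, ev$f1, ev$auc)
#> "precision 1.000 recall 1.000 accuracy 1.000 F1 1.000 AUC 1.000"
```

The training loss falls from chance (0.69 ≈ log 2) as the network learns the
injected signals, and the four held-out users are classified perfectly —
the generator's default knobs (negative-token rate 0.40 vs 0.10, symptom
keywords 0.15 vs 0.01, rumination 0.30 vs 0.05) are strong by design.
Interpretation comes from the same prediction objects:

```r
rank_posts_by_attention(ev$predictions[[1]], k = 3)
#> u0001_p020 u0001_p003 u0001_p017
#>     0.1421     0.1283     0.1156
```

— the three posts of this user the model leaned on most, with their attention
weights. The attribution report averages each attribute's fusion weight by
outcome class and attention stratum (top/bottom 20% of each user's posts):

```r
head(attribute_weight_report(ev$predictions), 5)
#>    outcome attention attribute mean_weight n_posts
#> 11      TN      high        a0      0.6123       7
#> 12      TN      high        a1      0.1339       7
#> 13      TN      high        a2      0.1887       7
#> 14      TN      high        a3      0.0313       7
#> 15      TN      high        a4      0.0339       7
```

Word-frequency tables (the word-cloud view) come straight off the cohort:

```r
frequency_table(unlist(lapply(corp$cohort[1:10], `[[`, "posts"),
                       recursive = FALSE), top_k = 5)
#>     word count polarity
#> 1      i   523  neutral
#> 2     my   197  neutral
#> 3     me    77  neutral
#> 4 myself    68  neutral
#> 5  visit    50  neutral
```

A thin command-line front end over the same functions lives in
`inst/cli/ashn.R` (`simulate`, `clean`, `wordfreq`, `train`, `evaluate`,
`interpret`).

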