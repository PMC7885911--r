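# topicsift

Unsupervised extraction of clinically relevant documents and granular
clinical topics from large, noisy short-text corpora such as social-media
posts.

During a public-health emergency, healthcare professionals (HCPs) share
front-line observations on platforms like Twitter — but those posts are a
tiny minority buried in noise that reuses the same clinical vocabulary.
`topicsift` finds them without any manual labeling by alternating two
unsupervised components: LDA topic modeling, which groups documents by
content, and clinical-concept relevance scoring, which ranks those groups
by how enriched their concepts are among kept versus discarded documents.
It is aimed at public-health surveillance and biomedical text-mining
researchers, and at anyone who needs an interpretable, auditable filter
for a corpus too large to label.

## The method

Starting from a raw corpus **D⁽⁰⁾**, a credential heuristic over author
profiles (name/handle/bio containing "MD", "Dr", "epidemiolog\*", …)
keeps HCP-authored documents, giving **D⁽¹⁾**. Each filtering iteration
*i* then:

1. fits a *k*-topic LDA model on D⁽ⁱ⁾ (collapsed Gibbs sampling), giving
   the document–topic matrix θ;
2. scores each concept trigger word *c* by its per-document rate ratio

   Rel(c; A, B) = (f_A(c)/|A| + ε) / ((f_B(c) − f_A(c))/(|B| − |A|) + ε),

   with (A, B) = (D⁽¹⁾, D⁽⁰⁾) at i = 1 and (D⁽ⁱ⁾, D⁽¹⁾) afterwards;
   concepts with Rel(c; D⁽¹⁾, D⁽⁰⁾) < 1 are removed once up front;
3. scores each topic by the θ-weighted mean of its documents' summed
   concept relevance, and keeps topics scoring at least
   (S_max − S_min)·τ + S_min;
4. keeps documents whose relevant-topic mass reaches the uniform baseline
   Σ_{t∈R} θ[t,m] ≥ r/k, and iterates.

Because there is no labeled ground truth on real platforms, the package
also ships a synthetic-corpus generator with planted topics, credentialed
authors, vocabulary overlap between clinical and mundane content, and
known relevance labels, so the whole pipeline is measurable end to end.
Time-windowed analysis (2-week windows, 1-week overlap) surfaces emerging
"micro-trends", and n-gram enrichment tables show which phrases the
filter concentrates.

## Worked example

```r
library(topicsift)

g   <- generate_corpus(generator_spec(n_docs = 2000, seed = 1))
cfg <- pipeline_config(k = 20, tau = 0.25, max_iterations = 3,
                       lexicon = g$lexicon, seed = 1,
                       stop_topic_fraction = 1)
run <- run_pipeline(g$corpus, cfg, verbose = TRUE)
#> iteration 1: D1 (M=789) -> kept 424 docs, r=12/20 topics [19, 59.2]
#> iteration 2: D2 (M=424) -> kept 260 docs, r=13/20 topics [88.1, 102]
#> iteration 3: D3 (M=260) -> kept 168 docs, r=15/20 topics [42.3, 48.3]

truth_metrics(run$d1$doc_id,    g$truth)$precision  # 0.584
truth_metrics(run$final$doc_id, g$truth)$precision  # 1.000

cat(head(report(run, n_words = 6, n_topics = 3), 5), sep = "\n")
#> Corpus trajectory: D1=789 -> D2=424 -> D3=260 -> 168 documents
#> Iteration 1 (D1, M=789): r=12 relevant topics, scores [18.97, 59.19]
#>   topic   1  score    59.1944  [relevant]    clin016 clin088 clin172 clin076 clin106 clin049
#>   topic   4  score    57.7695  [relevant]    clin016 clin088 clin079 clin116 clin102 clin184
#>   topic  11  score    57.4493  [relevant]    clin116 clin176 clin056 clin104 clin140 clin023
```

Of the 2,000 generated documents, 517 are truly relevant. The author
heuristic keeps 789 documents at 58% precision; three filtering rounds
remove 79% of them and end at 100% precision — the filter discards noise
by credentialed authors that shares clinical vocabulary, which is exactly
the hard case. The report ranks each iteration's topics by relevance
score with their top words (here synthetic `clin…`/`gen…` tokens).

A command-line front end wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "topicsift.R", package = "topicsift"))')
Rscript $CLI synth  --out-dir demo --n-docs 2000 --seed 1
Rscript $CLI run    --corpus demo/corpus.jsonl --lexicon demo/lexicon.tsv \
                    --out-dir demo_run --seed 1
Rscript $CLI enrich --corpus demo_run/final_corpus.jsonl \
                    --reference demo/corpus.jsonl --out demo_enrich.tsv
Rscript $CLI report --run-dir demo_run
```

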