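# medner

Hybrid named entity recognition for Chinese electronic medical records
(EMRs), in R.

Clinical narratives in Chinese EMRs carry five kinds of entity that
downstream applications need located and categorized exactly: **anatomy**
(解剖部位), **surgery** (手术), **drug** (药物), **independent symptom**
(独立症状) and **symptom description** (症状描述). The text has no
whitespace word boundaries, mentions are frequently abbreviated on repeat
(a tagger may label 左附件区 correctly once and miss 左附件 two sentences
later), and neural taggers make systematic boundary errors (贝伐 for
贝伐珠单抗). `medner` implements the full hybrid recipe for this problem:

* a **character-level BiLSTM-CRF** sequence tagger over BIO tags
  (`k = 11`: one `O` plus `B-`/`I-` per category), trained by maximizing
  the CRF log-likelihood

  score(X, y) = Σᵢ A[yᵢ₋₁, yᵢ] + Σᵢ P[i, yᵢ],  log P(y|X) = score(X, y) − log Σ_y′ exp score(X, y′)

  with a (k+2)×(k+2) transition matrix A (START/STOP augmented), exact
  log-space forward recursions and Viterbi decoding;
* an **Attention-BiLSTM-CRF** variant that adds document-level attention
  between the encoder and the CRF: pairwise scores
  s(xᵢ, xⱼ) = (xᵢ−xⱼ)ᵀ W (xᵢ−xⱼ) over character embeddings (W initialized
  to −I), row-softmax weights a_ij, global context G = ÃH, and emissions
  from tanh([G; H]) — built to keep repeated mentions tagged consistently
  across a document;
* three **auxiliary correction passes**: entity boundary auto-correction
  against an entity base tallied from training annotations, drug-dictionary
  leftmost-longest rectification/extraction (CPT-11 beats CPT), and
  boundary rules (strip trailing 旁; merge orientation prefixes/suffixes
  into anatomy; merge 术/手术 into surgery; gazetteer extraction of missed
  anatomy/surgery mentions);
* **strict entity-level evaluation** (exact span + category, micro-averaged
  P/R/F1) and a **document-level consistency rate**;
* a **seeded synthetic EMR generator** so the whole system is trainable and
  testable with no external download, plus readers/writers for the
  tagged-item (`name<TAB>start<TAB>end<TAB>category`), CoNLL-style BIO and
  word2vec text formats.

The neural core (LSTM backpropagation through time, attention backward,
CRF forward-backward) is implemented in base R with BLAS matrix kernels;
all gradients are checked against finite differences and all CRF scores
against brute-force path enumeration in the test suite. See
`vignettes/medner-methods.Rmd` for the model, the design decisions and the
generator's scope.

## Worked example

Train the attention variant on a synthetic corpus, post-process its
predictions with the companion entity base and drug dictionary, and score
strictly:

```r
library(medner)

synth <- generate_corpus(generator_config(n_docs = 60, seed = 42))
train <- synth$documents[1:45]
test  <- synth$documents[46:60]

model <- medner(train, variant = "attention_bilstm_crf",
                control = medner_control(dim = 32, hidden = 32,
                                         epochs = 12, seed = 1))
print(model)
#> Medical NER tagger (attention_bilstm_crf)
#>   vocabulary: 210 characters; embedding dim 32; hidden 32/direction
#>   trained 12 epochs on 304 sentences; final mean sentence NLL 2.106

preds <- predict(model, test)
post  <- postprocess_corpus(preds, test, base = synth$entity_base,
                            dict = synth$drug_dictionary,
                            rules = default_rules())
strict_prf(test, post)
#> Strict entity-level scores (%)
#>               Entity      P      R     F1 tp fp fn
#>              anatomy 100.00 100.00 100.00 15  0  0
#>              surgery 100.00  95.24  97.56 20  0  1
#>                 drug  93.75 100.00  96.77 15  1  0
#>  symptom_description 100.00 100.00 100.00 11  0  0
#>  independent_symptom 100.00 100.00 100.00 17  0  0
#>                total  98.73  98.73  98.73 78  1  1

consistency_rate(post)
#> [1] 1
```

The table mirrors the strict index: per category and in total, precision
(share of predicted entities that exactly match a gold span and category),
recall (share of gold entities recovered) and their harmonic mean, as
percentages. The consistency rate of 1 says that every surface string
predicted more than once within a document received a single category.
Individual documents come back as entity tables:

```r
doc <- test[[1]]
post[[doc$doc_id]]
#>   name start end            category
#> 1 膀胱     4   6             anatomy
#> 2 肿大    13  15 symptom_description
#> 3 钝痛    21  23 symptom_description
#> 4 头晕    28  30 independent_symptom
```

Offsets are 0-based, half-open character positions into `doc$text`, the
same convention as the tagged-item annotation files.

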