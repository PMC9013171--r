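---
title: "Mining a medical knowledge graph and answering questions over it"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining a medical knowledge graph and answering questions over it}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Clinical free text — admission notes, examination reports — holds a dense
web of factual statements: a disease presents a symptom, requires a test, a
test yields a finding, a finding indicates a disease, a disease is treated
with a drug. `medkgqa` implements an end-to-end route from such text to a
question-answering system: semi-supervised annotation from small seed
lists, neural extractors trained on those annotations, fusion of the raw
extractions into a consistent knowledge graph, and a memory-network reader
that answers single-fact questions against the graph.

The ontology is deliberately coarse: five entity classes (Disease, Symptom,
Treatment, Test, Result) and five typed relations (`hasSymptom`,
`needsTest`, `hasTestResult`, `needsTreatment`, `hasResult`), plus a
`DataGrounding` data property tying qualitative Result entities to numeric
measurement standards. Coarse classes are what lay users of a medical QA
service ask about; a UMLS-grade taxonomy would add cost without serving
those questions.

Text is processed at the character level: tokens are atomic symbols, never
segmented words. The bundled synthetic corpus mirrors this with atomic
pseudo-word tokens, which keeps every algorithm language-agnostic while
preserving the character-level processing regime.

# Bootstrapping annotation

Annotation starts from seed lists (a handful of known entities per type,
and a few known relation triples) and alternates two moves until a fixed
point:

1. **Pattern mining.** Around every seed occurrence, the 1–3 tokens to the
   left and right form candidate patterns: every left x right combination
   and every one-sided context. For relations, the context string between a
   co-occurring seed pair (with at most one boundary token on each side) is
   segmented by bidirectional maximum matching over a dictionary that
   includes the extracted entities, filtered by a stop list and a
   document-frequency floor, and every substring of the remaining word
   sequence is a candidate pattern.
2. **Instance mining.** Each pattern is scored by

   * support — the fraction of its extractions that are already seeds,
   * per-type confidence — the fraction of its extracted seeds carrying
     each type,
   * reliability — `w * support + (1 - w) * max confidence`.

   Patterns scoring at least 0.7 are validated and their extractions become
   candidates; patterns in `[0.3, 0.7)` get a second chance through search
   validation: a top-K retrieval oracle returns a hit count `|H|`, and
   candidates with `|H| / K >= 0.3` go to a human-judgment channel.
   Candidates found in the dictionary oracle are accepted outright.

The external checks are a pluggable oracle interface. Two implementations
ship: a static dictionary, and the synthetic generator's ledger (which
plays both the encyclopedia and the human judge in tests). Seed sets only
grow, so termination on a finite corpus is guaranteed; a hard iteration cap
guards pathological configurations and flags truncation.

Values the published method leaves open were fixed once here: the
reliability mixing weight `w = 0.5`, the retrieval depth `K = 10`, the
candidate length cap of 10 tokens with a same-sentence constraint,
confidence defined as 0 when a pattern extracts no seeds, and acceptance at
exact threshold equality (0.7 and 0.3 are accepted, not merely exceeded).

# Neural extractors

**Entity tagger.** A character-level BiLSTM-CRF over a BIOES x type label
scheme (21 labels). Token embeddings are co-trained with the encoder. The
cell update carries a *context bridge*: at positions where a validated
mined pattern matches the surrounding tokens exactly, the pattern's tokens
(cropped/padded to eight slots, leftmost and rightmost kept) are embedded,
concatenated, linearly projected to the cell dimension, and added to the
cell state through a learned elementwise gate
`p_t = sigmoid(W_pi [H_prev, x_t] + W_pc c_prev + b_p)`. With no matching
pattern the cell reduces exactly to a standard LSTM cell. The projection is
the minimal reconciliation of the eight-embedding concatenation with the
cell dimension and is trained with everything else. Among multiple matching
patterns the longest total context wins, then the higher reliability score,
then lexicographic order. The CRF layer is trained by exact forward
backward gradients; decoding is Viterbi under the BIOES legality mask with
ties broken toward the lowest label index.

**Relation classifier.** A text CNN over the pattern word sequence with the
entity slots masked: one convolution layer (16 kernels, window 5 over the
full word-vector dimension — the published default; an alternative preset
uses a kernel of half the sequence width by half the vector height, kept
because both geometries appear in the published description), tanh
activation, max pooling, then concatenation with a *paragraph context
vector* and a 128-unit fully connected softmax. Word vectors are
pre-trained (skip-gram with negative sampling) and fine-tuned; max pooling
makes full co-training unproductive, which is why pre-train-then-fine-tune
is the default here. Paragraph vectors are trained per record by predicting
the record's words; for unseen paragraphs only the new paragraph vector is
updated while the word table stays frozen.

At inference an entity pair's context substrings are each classified and
aggregated by maximum class probability. A NONE decision is made when no
substring clears a probability floor (default 0.5). To make that floor
meaningful the training mix includes a small fraction (10%) of blank
`<ENT> unk ... <ENT>` inputs trained toward the uniform distribution, which
pins the no-evidence response at the class prior. All neural models run on
a small reverse-mode autodiff engine written for this package; its
gradients are verified against finite differences in the test suite.

# Knowledge fusion

Raw extractions are noisy and redundant. Fusion has two phases, in this
order (so alias mention counts pool before supportability is computed):

1. **Entity alignment.** Same-type surface forms are compared by cosine
   similarity; at or above 0.7 they merge automatically, in `[0.3, 0.7)` a
   human/oracle judges, below 0.3 they stay separate. Merges close
   transitively; each cluster is named by its most frequent surface form.
   The similarity space concatenates (a) the distributional entity vector —
   the mean of skip-gram token embeddings, weight 0.3 — and (b) an L2
   normalized character n-gram (3–4 plus whole-token) count vector of the
   surface form, weight 0.7. The surface component carries the
   compositional signal that places a misspelled variant next to its
   canonical form (the character-composition effect that makes co-trained
   character vectors work well on real clinical text); the distributional
   component ties forms used in the same contexts. The weights were fixed
   at design time: variant surface forms share most of their characters, so
   the surface term should dominate, while a pure surface match would merge
   lexically close but distinct entities.
2. **Consistency analysis.** A tuple's supportability confidence is its
   extraction count divided by its subject entity's mention count (subject
   mentions, matching the worked 74/379 arithmetic). At or above 0.7 the
   tuple is retained, in `[0.3, 0.7)` an oracle judges, below 0.3 it is
   dropped. Tuples sharing subject and object but differing in relation
   conflict; the higher-confidence one survives, ties go to the oracle.

# The memory-network reader

The fused graph is loaded into an explicit memory: rows sharing subject and
relation merge into one tuple whose object is a set, tuples are sorted, and
each is encoded by an LSTM over its element vectors (subject embedding,
relation one-hot — `hasSymptom` first, `needsTest` second, the rest in
schema order — then the objects in sorted order). Questions pass the same
encoder over their extracted entities, inferred relation and a learned
question-word placeholder. Intent is detected from marker words by a rule
table in document order.

Candidate memories are found by binary search over an entity index
(subject or object position both match), then ranked by *region-affinity
attention*: every question patch is compared to every memory patch by
normalized cosine, each row of the similarity matrix is softmaxed, and the
score is a learned combination `W * [mean, sum, max]` of the attention
matrix. The best memory's entity of the intent type is decoded as the
answer (a trained linear decoder scores candidates against the joint
question-plus-memory vector when several qualify; the most frequent
intent-type entity among the top memories is a flagged fallback) and slotted
into a per-intent sentence template.

Training is two-phase. Phase one trains the encoder, decoder and attention
weights with a margin ranking loss (margin 0.2, five negatives per
positive; negative memories and answers share no entity with the question
or answer — both similarity terms read the joint vector as
`[question, memory]`). Phase two replays the training questions, increments
a usage counter whenever a memory supports a correct answer, and trains the
generalization module — a two-layer perceptron over
`[input similarity, usage normalized by total queries, entity count,
relation one-hot]` — to predict which memories are useful. Rules map
utility values to operations: question inputs above a similarity floor use
the memory to answer; duplicated knowledge replaces the old slot when the
new utility exceeds the old; a clean command forgets slots below the usage
floor.

# The synthetic study

The generator is the package's ground truth. It draws a KB over the schema
(entity surface forms of 1–3 tokens with random syllable heads; a degree
cap of 2 tuples per entity in the default study, reflecting how sparse
fused clinical graphs are in practice), renders records whose statement
counts follow a shifted Poisson with mean 3.3 (matching typical clinical
records; only the mean is pinned down, the Poisson shape is a modeling
choice), instantiates statements from per-relation templates whose
left/mid/right contexts mimic the surface patterns the miner expects, and
logs every insertion. Noise corrupts a stated fraction of entity mentions
by a single-token substitution, logged as (canonical, variant) alias pairs
— exactly what alignment must undo. QA pairs ask one side of a tuple,
restricted to tuples whose answer is uniquely determined by the KB (the
single-fact regime the evaluation rules assume); answer documents mention
the answer three times against at most one distractor mention and express a
single relation type, so the majority-labeling rule recovers the intended
answer.

What the generator does *not* emulate: real lexical variety (templates are
few and clean), semantic ambiguity between entity types, cross-sentence
relations, multi-hop questions, and class imbalance. Passing the bundled
tests therefore demonstrates that the machinery is implemented correctly
and recovers planted structure under controlled noise — not that the
published F1 numbers on real clinical Chinese corpora would be reproduced.

**Problem sizes.** The bundled experiments use a 12-entity-per-type,
5-tuples-per-relation KB, 120–150 records (about 400–500 statements), 150–250
QA pairs, and scaled-down network dimensions (16-unit embeddings/hidden
state for the tagger, 24-dimensional word vectors, 8 kernels). The
published dimension presets (512/200 embeddings/hidden, 100-dimensional
word vectors, 16 kernels, 128 FC units, batch 16 with a 50-sentence
alternative) remain the documented defaults of the config constructors.
These sizes were chosen so the complete study — three noise conditions end
to end — runs on a single CPU in minutes while leaving every acceptance
margin comfortably wide.

# Numerical choices and degenerate inputs

* CRF partition function in log space; gradients by forward-backward;
  Viterbi ties to the lowest label index.
* Gradient-norm clipping (5.0) is on by default; Adam throughout.
* Empty paragraphs vectorize to a flagged zero vector; zero-norm attention
  patches are excluded with a warning; cosine similarity on a zero vector
  is an error, and entities absent from the embedding vocabulary are
  skipped as negatives rather than silently compared.
* Frequency ties in test-set labeling drop the document; unknown-intent
  questions fall back to the best memory's subject type, flagged.
* Single-sided entity patterns bound their candidates by length cap and
  sentence end; their scores, not special cases, filter the junk.

# Limitations

The oracle interface abstracts web search and human validation; the
shipped implementations answer from a dictionary or the generator ledger,
so live-noise behavior of search validation is untested. The alignment
vector space is tuned to single-token substitution noise; paraphrase-level
aliasing would need a stronger distributional component. The reader
answers single-fact questions only; multi-disease and multi-hop questions
are out of scope.
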