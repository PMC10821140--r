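---
title: "Contrastive SMILES representation learning: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contrastive SMILES representation learning: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A molecule does not have one SMILES string: every depth-first traversal of
its graph yields a different, equally valid writing.  Language models
trained on a single canonical writing per molecule see only one projection
of the underlying graph, which encourages memorization of surface syntax
(high validity, poor novelty).  `molcontrast` implements a three-part
remedy:

1. **Contrastive pre-training.**  Two randomized writings of the same
   molecule form a positive pair; the other writings in the batch are
   negatives.  A shared token embedding, transformer encoder `f(.)` and MLP
   projection head `g(.)` are trained with the NT-Xent loss
   \[
   \ell_{i,j} = -\log \frac{\exp(\mathrm{sim}(z_i, z_j)/\tau)}
        {\sum_{k \ne i} \exp(\mathrm{sim}(z_i, z_k)/\tau)},
   \]
   where `sim` is cosine similarity on the projected vectors and a batch of
   N molecules holds 2N views, giving 2(N-1) negatives per anchor.  The
   reported loss is the mean of \(\ell_{i,j}\) over all 2N anchors (the
   SimCLR convention, which keeps magnitudes batch-size independent).
2. **Generation.**  A GPT-style causal transformer decoder over SMILES
   tokens (masked self-attention, position-wise feed-forward with the exact
   GELU `x * pnorm(x)`), optionally initialized with the pre-trained token
   embedding, frozen or unfrozen.
3. **Compound-protein interaction.**  Two independent transformer encoders
   (molecule tokens; one token per amino-acid letter), mean-pooled,
   concatenated and mapped by a single linear layer to two logits.  The
   pre-trained embedding transfers into the molecule encoder only.

## Parameters that matter

| knob | default | why |
|---|---|---|
| temperature `tau` | 0.1 | sharpness of the softmax over negatives; 0.1 is the value reported to work best for molecular data |
| embedding dim | 256 | the "word vector" width of the reference setting |
| contrastive batch | 16 molecules (32 views) | reference setting |
| decoder `d_ff` | 1024 | reference setting (4 x 256) |
| learning rate | grid {1e-4, 3e-4, 1e-3, 3e-3, 1e-2} | the protocol prescribes a validation-selected grid over [1e-4, 1e-2] without naming the grid points; these five log-spaced values realize it |
| epochs / patience | 100 / 10 | early stopping on validation loss, best checkpoint kept |
| batch size (CPI) | 128 | reference setting |
| unique@K | K = 10000 | MOSES convention |
| fingerprint | Morgan counts, radius 2, 2048 bins | see below |

Desk-scale tests use 2 layers / 2 heads and widths of 16-64: the
architecture is identical, only capacity is scaled to a CPU-minute budget.

## Design choices where the design was open

* **Tokenization.**  Regex-style SMILES tokens: bracket atoms `[...]`,
  two-letter elements (`Cl`, `Br`) and `%nn` ring closures are single
  tokens, everything else one character.  Reversible, standard for SMILES
  language models.  Specials `pad=0, bos=1, eos=2, unk=3` are reserved at
  the front of every vocabulary so ids are stable across experiments.
* **Pooling.**  Token-level encoder outputs are mean-pooled over non-pad
  positions.  It is the simplest padding-invariant reduction and no CLS
  token is part of the reference description.
* **Projection head.**  Hidden 256 / output 128, linear-ReLU-linear; the
  SimCLR convention.
* **View pairs.**  The two writings are drawn independently and may
  coincide for small molecules; coincidences are kept (a "hard positive"),
  not resampled.  Training pairs are re-enumerated every epoch to maximize
  augmentation diversity; validation pairs are fixed across epochs so the
  early-stopping criterion compares like with like.
* **Molecule identity.**  Canonical-form string equality is the identity
  predicate everywhere (uniqueness, novelty, round-trips), because
  generated candidates are canonicalized before comparison.
* **Sampling for evaluation.**  Multinomial sampling at temperature 1.0 is
  the default for distribution-learning metrics; uniqueness and novelty are
  degenerate under beam search, which is nevertheless implemented (and
  width 1 is greedy decoding) since it is part of the reference protocol.
* **Start token.**  A dedicated `bos` symbol rather than a literal carbon
  atom; strictly more general.
* **Dropout** is exposed on the two residual branches but defaults to 0:
  no rate is stated in the reference protocol, and at desk scale the toy
  grammars are small enough that regularization only slows the capacity
  checks (memorization probes) the tests rely on.
* **Positional embeddings** are learned and are *not* transferred with the
  token embedding: the transfer contract covers the embedding layer only.
* **Config files** are JSON rather than YAML: the supported runtime
  guarantees `jsonlite` only.  The CLI otherwise matches the planned
  surface (flags override file values; unknown keys are errors).
* **Protein encoding** is one token per amino-acid letter (max 1000,
  truncated); substructure/BPE vocabularies belong to other architectures.
* **Encoders in the CPI model** are independent (no weight sharing) with a
  shared hyperparameter block; the description names two encoders and one
  final linear map, nothing more.

## The fingerprint behind Tanimoto values

The reference similarity values for the case-study panel
(`load_case_study_pairs()`) are not reproduced by plain Morgan *bit*
vectors (pair 1 gives 0.974).  A sweep over standard fingerprints (Morgan
bits r2/r3, Morgan counts, FCFP, MACCS, RDKit path, atom-pair, torsion)
shows that hashed Morgan radius-2 **count** fingerprints (2048 bins)
reproduce the panel: 0.958, 0.957, 0.956, 0.957, 0.952, 0.952.  They are
therefore the package default; `fingerprint_spec("morgan_bits")` restores
the binary variant.  The same sweep reveals that the published panel's QED
and SAScore entries for rows 3 and 4 are transposed relative to the
molecule listing (the LogP column is not); the accessor documentation and
the acceptance script record the mapping used.

## What the synthetic data emulates — and what it does not

`make_toy_smiles_corpus()` assembles molecules from ten aromatic cores and
two substituent pools (amides, ureas, piperazines, morpholines, ethers;
atoms restricted to C/N/O/F/S/Cl, rings of at most 7 atoms), giving ~3200
raw combinations of which roughly 60% fall inside the 250-350 Da / LogP <=
3.5 lead-like window.  This emulates the *format* and coarse property
range of lead-like libraries, not their scale or chemical breadth: a green
generation test shows the pipeline learns a non-trivial SMILES grammar end
to end, not that it would reach benchmark numbers on millions of real
lead-like molecules.

`make_toy_cpi_dataset()` plants a learnable conjunction: label 1 iff the
molecule contains a fluorine token AND the protein contains a fixed 6-mer
motif, with negatives spread over the three non-signal combinations and an
optional label-flip noise rate (default 0, i.e. a noiseless stated world).
Background residues are drawn with natural (Swiss-Prot-like) amino-acid
frequencies and the motif (`WCWHWC`) is deliberately rich in the rare
residues W and C.  This matters: against a *uniform* background, an exact
6-mer is statistically invisible to mean-pooled encoders at ~1600 training
records (every motif letter is common, so partial matches saturate the
pooled features), and the classifier plateaus around F1 0.87 — violating
the fixture's stated purpose of being learnable.  Rare-residue enrichment
is also the more realistic choice, and restores clean separability.
A rule-based oracle (`cpi_signal_oracle()`) scores F1 = 1 on noise-free
data by construction, bounding what the trained classifier can achieve;
at flip rate q the oracle's precision and recall both fall to ~(1-q).
Real interaction data have no such clean closed-form signal; a green CPI
test establishes that the dual-encoder learns a cross-modal conjunction,
not biological affinity.

## Numerical choices

* Backpropagation through every layer is hand-derived and is checked
  against central finite differences in the test suite (relative tolerance
  1e-4); layer norm uses eps = 1e-5, attention masking uses an additive
  -1e30 before the softmax, softmax rows are max-shifted.
* The NT-Xent gradient flows through the cosine normalization
  (`dZ = (dA - A * rowSums(dA * A)) / ||a||`); zero-norm projections are an
  error rather than silently clipped.
* AdamW uses beta = (0.9, 0.999), eps = 1e-8, decoupled weight decay 0.01;
  frozen parameters are excluded from both the update and the decay.
* `unique@K` with fewer than K valid molecules falls back to all valid
  molecules; precision/recall with empty denominators report 0 with an
  explicit `undefined` flag.
* Internal diversity follows the printed formula exactly: ordered pairs
  including self-pairs, `1/|S|^2` normalization — not the strict
  upper-triangle variant.  Reports round to 3 decimals but always carry the
  raw values.
* Randomized enumeration is made seedable by shuffling atom numbering with
  a dedicated RNG stream per (molecule, draw) before writing, since the
  toolkit's own random-writing flag takes no seed.
* Kekulized vs aromatic writings: enumeration follows the toolkit's
  default aromatic output.

## Known limitations

* Pure-R training: minutes per desk-scale model, not suitable for corpora
  beyond ~10^4 molecules.  The RDKit bridge costs one Python start-up per
  batched call (~1 s), which the session-level cache amortizes.
* No stereochemistry-aware augmentation, no SELFIES/InChI, no conditional
  generation, no multi-GPU or mixed precision.
* The validation loss during pre-training uses fixed view pairs; an
  alternative (resampled validation views) would estimate the same
  quantity with more variance.
* Published CPI benchmark results on real datasets are out of scope here;
  the classifier's acceptance rests on the planted-signal world above.
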