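# Shared fixtures, built in code and cached per test run so that expensive
# artifacts (RDKit calls, tiny trained models) are constructed once.

.fix <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fix[[key]])) .fix[[key]] <- builder()
  .fix[[key]]
}

toy_corpus_100 <- function() cached("toy100", function() make_toy_smiles_corpus(100, seed = 101))

toy_corpus_60 <- function() cached("toy60", function() make_toy_smiles_corpus(60, seed = 202))

# tiny desk-scale configs used by the unit tests (2 layers / 2 heads);
# overrides win over the tiny defaults
tiny_config <- function(constructor, defaults) {
  function(...) do.call(constructor, utils::modifyList(defaults, list(...)))
}

tiny_contrastive_config <- tiny_config(contrastive_config, list(
  embed_dim = 16L, encoder_layers = 2L, attention_heads = 2L, d_ff = 32L,
  proj_hidden_dim = 16L, proj_out_dim = 8L, batch_molecules = 8L,
  max_epochs = 2L, patience = 2L, learning_rate = 1e-3, max_len = 90L))

tiny_decoder_config <- tiny_config(decoder_config, list(
  n_blocks = 2L, d_model = 16L, d_ff = 32L, attention_heads = 2L,
  batch_size = 8L, max_epochs = 2L, patience = 2L, learning_rate = 1e-3,
  max_len = 90L))

tiny_cpi_config <- tiny_config(cpi_config, list(
  n_layers = 1L, d_model = 16L, d_ff = 32L, attention_heads = 2L,
  max_len = 90L, protein_max_len = 60L, batch_size = 32L, max_epochs = 2L,
  patience = 2L, learning_rate = 1e-3))

# one tiny pre-trained contrastive checkpoint shared across test files
tiny_contrastive_ckpt <- function() {
  cached("ctr_ckpt", function() {
    pretrain_contrastive(toy_corpus_60(), tiny_contrastive_config(),
                         seed = 7, verbose = FALSE)
  })
}

# a generator trained to memorize a single molecule (40 copies)
memorizer_ckpt <- function() {
  cached("memo_ckpt", function() {
    corpus <- rep("COc1ccc(NC(=O)N2CCCC2)cc1", 40)
    cfg <- decoder_config(n_blocks = 2L, d_model = 24L, d_ff = 48L,
                          attention_heads = 2L, batch_size = 8L,
                          max_epochs = 40L, patience = 40L,
                          learning_rate = 3e-3, max_len = 60L)
    train_generator(corpus, cfg, seed = 9, verbose = FALSE)
  })
}

expect_close <- function(actual, expected, tol) {
  expect_true(all(abs(actual - expected) <= tol),
              label = sprintf("|%s - %s| <= %s", toString(round(actual, 6)),
                              toString(expected), tol))
}
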