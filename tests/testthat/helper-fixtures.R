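# fixtures are built in code at test time; nothing is read from disk

# handmade corpus with known labels and dedup targets
toy_corpus <- function() {
  corpus(data.frame(
    record_id = paste0("r", 1:6),
    title = c("Cognitive relapse model", "Behavioural theory study",
              "Diathesis stress follow up", "Unrelated imaging work",
              "Another unrelated record", "Third unrelated record"),
    abstract = c("relapse onset cognitive theory prospective cohort",
                 "behavioural activation relapse prospective",
                 "stress vulnerability relapse recurrence cohort",
                 "imaging voxel brain scanner acquisition",
                 "soil microbiome sequencing survey",
                 "galaxy cluster lensing survey"),
    label = c("relevant", "relevant", "relevant",
              "irrelevant", "irrelevant", "irrelevant"),
    stringsAsFactors = FALSE
  ))
}

# linearly separable bag-of-words toy: relevant records use a disjoint
# vocabulary from irrelevant ones
separable_toy <- function(n_rel = 8, n_irr = 24) {
  rel_text <- replicate(n_rel, paste(
    sample(c("relapse", "cognitive", "onset", "recurrence", "vulnerability"),
           12, replace = TRUE), collapse = " "))
  irr_text <- replicate(n_irr, paste(
    sample(c("galaxy", "soil", "voxel", "lensing", "microbiome", "scanner"),
           12, replace = TRUE), collapse = " "))
  corpus(data.frame(
    record_id = sprintf("t%03d", seq_len(n_rel + n_irr)),
    title = c(rep("relevant topic", n_rel), rep("other topic", n_irr)),
    abstract = c(rel_text, irr_text),
    label = c(rep("relevant", n_rel), rep("irrelevant", n_irr)),
    stringsAsFactors = FALSE
  ))
}

# small synthetic fixture for engine tests (cheap; not the study defaults)
small_synth <- function(seed = 1, n = 300, prevalence = 0.05, topic_mix = 0.5,
                        vocab = 500, len = 60, ...) {
  generate_corpus(synthetic_corpus_spec(
    n_records = n, prevalence = prevalence, vocab_size = vocab,
    topic_mix = topic_mix, abstract_length_mean = len, seed = seed, ...))
}

# dense feature matrix wrapper for tests that need signed narrow features
dense_features <- function(corp, d = 8, seed = 1) {
  set.seed(seed)
  m <- matrix(stats::rnorm(nrow(corp) * d), nrow(corp), d)
  rownames(m) <- corp$record_id
  load_precomputed_dense(m, corp)
}
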