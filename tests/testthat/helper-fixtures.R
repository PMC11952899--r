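# Shared fixtures, built once per test run and cached. Sizes are scaled
# down from the generator defaults where a test only needs the structure,
# not the statistical power.

.fixtures <- new.env(parent = emptyenv())

# small proteome with planted signal for fast structural tests
small_proteome <- function() {
  if (is.null(.fixtures$small_pr))
    .fixtures$small_pr <- generate_proteome(
      granule_sim_config(n_tier = c(60L, 20L, 20L, 20L), n_background = 400L),
      seed = 11L)
  .fixtures$small_pr
}

# learning set + features + fitted model on the small proteome
small_model_bundle <- function() {
  if (is.null(.fixtures$bundle)) {
    pr <- small_proteome()
    ls <- assemble_learning_set(pr$tiers, pr$records, "PBSG", "==1", seed = 3L)
    recs <- pr$records[c(ls$positives, ls$negatives)]
    labs <- rep(c(1L, 0L), c(length(ls$positives), length(ls$negatives)))
    vocab <- build_vocabulary(recs[labs == 1L])
    feats <- build_feature_table(recs, vocab)
    model <- granule_fit(feats, labs, vocabulary = vocab, ntree = 200L, seed = 5L)
    .fixtures$bundle <- list(proteome = pr, set = ls, records = recs,
                             labels = labs, vocab = vocab, features = feats,
                             model = model)
  }
  .fixtures$bundle
}

# default-condition proteome (generator defaults), cached for the
# acceptance blocks that need the full study conditions
default_proteome <- function(seed = 101L) {
  key <- paste0("def_", seed)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- generate_proteome(granule_sim_config(), seed = seed)
  .fixtures[[key]]
}

write_temp_fasta <- function(lines) {
  path <- tempfile(fileext = ".fasta")
  writeLines(lines, path)
  path
}

write_temp_edges <- function(df) {
  path <- tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
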