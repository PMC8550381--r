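Synthetic example inputs (generated, not empirical): a 12-tip pure-birth
tree and a matching trait table in the package's CSV schema
(species,total_length_cm,body_depth_pct,ecotype,farming; empty = missing).

  tr <- read_tree(system.file("extdata", "example_tree.nwk",
                              package = "traitsse"))
  tt <- read_trait_table(system.file("extdata", "example_traits.csv",
                                     package = "traitsse"), tr)
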