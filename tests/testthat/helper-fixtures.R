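# small hand-checkable trees used across tests
tree2 <- function() read_tree("(A:1,B:1);")
tree3 <- function() read_tree("((A:1,B:1):1,C:2);")
tree4 <- function() read_tree("((A:1,B:1):1,(C:1,D:1):1);")
tree6 <- function() read_tree("(((A:1,B:1):1,(C:1,D:1):1):1,(E:2,F:2):1);")

# equal-branch star tree with n tips (single polytomous root)
star_tree <- function(n, len = 1) {
  read_tree(paste0("(", paste0(letters[seq_len(n)], ":", len,
                               collapse = ","), ");"))
}

# quick pure-birth tree via ape, relabelled deterministically
yule_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rphylo(n, birth = 1, death = 0)
  tr$tip.label <- paste0("t", seq_len(n))
  tr
}

sml_alphabet <- c("S", "M", "L")
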