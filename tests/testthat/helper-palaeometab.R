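# naive GLS oracle: explicit inversion of V, no whitening/QR
naive_gls_beta <- function(X, y, V) {
  Vi <- solve(V)
  solve(t(X) %*% Vi %*% X) %*% t(X) %*% Vi %*% y
}

relabel_tips <- function(tree, prefix) {
  tree$tip.label <- paste0(prefix, seq_along(tree$tip.label))
  tree
}

# simulated two-clade ultrametric tree with disjoint labels, height 2 * h
two_clade_tree <- function(n_per_clade, lambda_cfg = sim_config(n_tips = n_per_clade),
                           h = 100) {
  a <- relabel_tips(simulate_tree(lambda_cfg, n_per_clade), "a")
  b <- relabel_tips(simulate_tree(lambda_cfg, n_per_clade), "b")
  graft_clades(a, b, 2 * h)
}

named_xy <- function(traits) {
  list(x = stats::setNames(traits$log_mass, traits$species),
       y = stats::setNames(traits$log_lifespan, traits$species))
}
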