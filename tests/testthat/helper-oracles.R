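# Independent brute-force oracles used to cross-check the implementations.

# Mann-Whitney pair count by full enumeration of all n1*n2 pairs
oracle_mw_u1 <- function(a, b) {
  sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
}

# Exact two-sided signed-rank p by literal enumeration of all 2^n sign
# assignments (n <= ~14), independent of the package's convolution
oracle_signed_rank_p <- function(differences) {
  d <- differences[differences != 0]
  n <- length(d)
  r <- rank(abs(d), ties.method = "average")
  w_plus <- sum(r[d > 0])
  s_obs <- min(w_plus, sum(r) - w_plus)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w <- as.vector(signs %*% r)
  mean(pmin(w, sum(r) - w) <= s_obs)
}

# packaged fixture bundle, loaded once per test file
fixture_bundle <- function() {
  tab <- neosex_karyotypes()
  tree <- read_species_tree(neosex_fixture_path("tree"))
  units <- find_system_clusters(tree,
                                stats::setNames(tab$system, tab$species_key))
  pairs <- build_pairs(tree, units,
                       read_pair_config(neosex_fixture_path("pairs")))
  list(tab = tab, tree = tree, units = units, pairs = pairs)
}

# random karyotype-table data frame for property tests
random_karyotab <- function(n) {
  two_n <- 2L * sample(5:30, n, replace = TRUE)
  nf <- vapply(two_n, function(k) sample(k:(2L * k), 1L), 0L)
  df <- data.frame(
    order = rep("o", n), family = rep("f", n),
    genus = sprintf("g%03d", seq_len(n)),
    species = rep("sp", n),
    female_2n = two_n, male_2n = two_n,
    female_nf = nf, male_nf = nf,
    female_frac_acro = (2 * two_n - nf) / two_n,
    male_frac_acro = (2 * two_n - nf) / two_n,
    system = sample(c("X1X2Y", "XY1Y2"), n, replace = TRUE),
    source = rep("synthetic", n), stringsAsFactors = FALSE)
  df$species_key <- make_species_key(df$genus, df$species)
  df$valid <- rep(TRUE, n)
  class(df) <- c("karyotab", "data.frame")
  df
}
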