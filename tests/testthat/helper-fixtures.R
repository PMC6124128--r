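# Shared fixtures, built in code.

# Six-tip, two-clade taxonomy with hand-enumerable node heights.
# Clade A: C = 0.8, L_c = 3; clade B: C = 0.4, L_c = 3.
# b1 and b2 share an identical full path (tie case).
fixture_taxonomy <- function() {
  taxonomy <- data.frame(
    tip_id = c("a1", "a2", "a3", "b1", "b2", "b3"),
    language_code = paste0("l", 1:6),
    clade_id = c("A", "A", "A", "B", "B", "B"),
    path = c("x|x1|x1a", "x|x1|x1b", "x|x2",
             "y|y1|y1a", "y|y1|y1a", "y|y2|y2a"),
    sample_level = c(3L, 3L, 2L, 3L, 3L, 3L))
  clades <- data.frame(
    clade_id = c("A", "B"),
    relative_height = c(0.8, 0.4),
    max_level = c(3L, 3L),
    n_languages = c(3L, 3L))
  list(taxonomy = taxonomy, clades = clades)
}

# Hand-enumerated MRCA heights for the fixture (root height 1).
# Within-clade node heights follow (L_c - L_s) * C / L_c; the b1/b2 tie
# node sits at C / (2 L_c) = 0.4/6.
fixture_mrca_heights <- function() {
  h <- matrix(0, 6, 6, dimnames = list(
    c("a1", "a2", "a3", "b1", "b2", "b3"),
    c("a1", "a2", "a3", "b1", "b2", "b3")))
  h["a1", "a2"] <- h["a2", "a1"] <- 0.8 / 3        # node x1, level 2
  h["a1", "a3"] <- h["a3", "a1"] <- 2 * 0.8 / 3    # node x,  level 1
  h["a2", "a3"] <- h["a3", "a2"] <- 2 * 0.8 / 3
  h["b1", "b2"] <- h["b2", "b1"] <- 0.4 / 6        # tie node
  h["b1", "b3"] <- h["b3", "b1"] <- 2 * 0.4 / 3    # node y,  level 1
  h["b2", "b3"] <- h["b3", "b2"] <- 2 * 0.4 / 3
  h[1:3, 4:6] <- 1                                  # cross-clade: root
  h[4:6, 1:3] <- 1
  diag(h) <- 0
  h
}

# Brute-force phylogenetic similarity: pairwise MRCA enumeration using
# ape primitives only (independent of vcv.phylo used in the package).
oracle_phylo_similarity <- function(tree) {
  n <- length(tree$tip.label)
  depth <- max(ape::node.depth.edgelength(tree))
  node_h <- depth - ape::node.depth.edgelength(tree) # height above tips
  P <- matrix(1, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      m <- ape::getMRCA(tree, c(tree$tip.label[i], tree$tip.label[j]))
      P[i, j] <- P[j, i] <- 1 - node_h[m] / depth
    }
  }
  P
}

# Independent multivariate-normal log density (no Cholesky sharing with
# the implementation): determinant() + solve().
oracle_mvn_loglik <- function(y, mu, Sigma) {
  n <- length(y)
  r <- y - mu
  ld <- as.numeric(determinant(Sigma, logarithm = TRUE)$modulus)
  -0.5 * (n * log(2 * pi) + ld + sum(r * solve(Sigma, r)))
}

# small random dataset for regression tests
random_dataset <- function(n, k = 1, seed = 1) {
  set.seed(seed)
  X <- cbind(1, matrix(rnorm(n * k), n, k))
  colnames(X) <- c("(Intercept)", paste0("x", seq_len(k)))
  beta <- rnorm(k + 1)
  y <- as.numeric(X %*% beta + rnorm(n))
  list(y = y, X = X, beta = beta)
}

# random symmetric positive-definite matrix
random_spd <- function(n, seed = 1) {
  set.seed(seed)
  A <- matrix(rnorm(n * n), n)
  crossprod(A) / n + diag(0.5, n)
}
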