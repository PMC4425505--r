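# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

BASES <- c("A", "C", "G", "T")

# --- brute-force constrained entropy maximisation (dual ascent) -------------
# States are all 4^L sequences, position 1 fastest-varying (same enumeration
# as the package, but the solver is an exponential-family dual optimiser, not
# IPF). constraints: list of sorted position vectors; targets: list of
# probability arrays over the subsets.
brute_force_maxent <- function(L, constraints, targets) {
  n_states <- 4^L
  cells <- 0:(n_states - 1)
  feat <- list()
  tvec <- numeric(0)
  for (ci in seq_along(constraints)) {
    S <- constraints[[ci]]
    key <- rep(0L, n_states)
    for (k in seq_along(S)) {
      key <- key + ((cells %/% 4^(S[k] - 1)) %% 4) * 4^(k - 1)
    }
    for (cell in 0:(4^length(S) - 1)) {
      feat[[length(feat) + 1]] <- as.numeric(key == cell)
      tvec <- c(tvec, as.vector(targets[[ci]])[cell + 1])
    }
  }
  FM <- do.call(cbind, feat)
  fn <- function(lam) {
    u <- as.vector(FM %*% lam)
    m <- max(u)
    log(sum(exp(u - m))) + m - sum(lam * tvec)
  }
  gr <- function(lam) {
    u <- as.vector(FM %*% lam)
    p <- exp(u - max(u)); p <- p / sum(p)
    as.vector(crossprod(FM, p)) - tvec
  }
  opt <- optim(rep(0, ncol(FM)), fn, gr, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-16))
  u <- as.vector(FM %*% opt$par)
  p <- exp(u - max(u))
  p / sum(p)
}

# marginal array of a full-table distribution p on subset S (enumeration as
# above); direct summation loop, independent of the package
oracle_marginal <- function(p, L, S) {
  cells <- 0:(length(p) - 1)
  key <- rep(0L, length(p))
  for (k in seq_along(S)) {
    key <- key + ((cells %/% 4^(S[k] - 1)) %% 4) * 4^(k - 1)
  }
  out <- numeric(4^length(S))
  for (i in seq_along(p)) out[key[i] + 1] <- out[key[i] + 1] + p[i]
  array(out, dim = rep(4, length(S)))
}

# --- permutation one-way ANOVA ----------------------------------------------
perm_anova_p <- function(values, groups, B = 20000) {
  f_stat <- function(v, g) {
    gm <- tapply(v, g, mean); gn <- tapply(v, g, length)
    ssb <- sum(gn * (gm - mean(v))^2)
    ssw <- sum((v - gm[as.character(g)])^2)
    k <- length(gm); n <- length(v)
    (ssb / (k - 1)) / (ssw / (n - k))
  }
  obs <- f_stat(values, groups)
  hits <- 0
  for (b in seq_len(B)) {
    if (f_stat(sample(values), groups) >= obs) hits <- hits + 1
  }
  hits / B
}

# --- direct Jukes-Cantor 2-taxon simulator ----------------------------------
# Per site: ancestor uniform; each lineage substitutes with the JC transition
# probabilities at distance t.
jc_pair_sim <- function(n_sites, t_each) {
  p_same <- 1 / 4 + 3 / 4 * exp(-4 * t_each / 3)
  anc <- sample(BASES, n_sites, replace = TRUE)
  evolve <- function(x) {
    flip <- runif(n_sites) > p_same
    x[flip] <- vapply(x[flip],
                      function(b) sample(setdiff(BASES, b), 1), character(1))
    x
  }
  list(a = evolve(anc), b = evolve(anc))
}

# plug-in mutual information (bits) between two character vectors
plugin_mi <- function(a, b) {
  tab <- table(a, b) / length(a)
  pa <- rowSums(tab); pb <- colSums(tab)
  s <- 0
  for (i in seq_along(pa)) for (j in seq_along(pb)) {
    if (tab[i, j] > 0) s <- s + tab[i, j] * log2(tab[i, j] / (pa[i] * pb[j]))
  }
  s
}

# random additive tree -> exact leaf-to-leaf distance matrix (via ape)
random_additive_matrix <- function(n_leaves) {
  tr <- ape::rtree(n_leaves, br = function(k) runif(k, 0.05, 1))
  list(tree = tr, D = stats::cophenetic(tr))
}

# small locus fixture shared across tests
test_locus <- function(seed = 101, ...) generate_locus(seed = seed, ...)

# targets drawn as exact marginals of a random distribution q, so constraint
# sets are consistent by construction
random_constraint_problem <- function(L, extra_pairs = 1) {
  q <- rgamma(4^L, 1); q <- q / sum(q)
  constraints <- as.list(seq_len(L))
  all_pairs <- utils::combn(L, 2, simplify = FALSE)
  constraints <- c(constraints, sample(all_pairs, extra_pairs))
  constraints <- lapply(constraints, sort)
  targets <- lapply(constraints, function(S) oracle_marginal(q, L, S))
  list(q = q, constraints = constraints, targets = targets)
}

fit_from_problem <- function(L, prob, ...) {
  marg <- structure(list(constraints = prob$constraints,
                         tables = prob$targets, L = L, n = NA,
                         pseudocount = 0),
                    class = "motif_marginals")
  fit_maxent(marg, ...)
}
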