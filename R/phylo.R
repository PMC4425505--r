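# --- Tamura-Nei (TN93) substitution machinery -------------------------------
# Base order A, C, G, T throughout. alpha1: purine transitions (A<->G),
# alpha2: pyrimidine transitions (C<->T), beta: transversions.

tn93_rate_matrix <- function(freqs, alpha1, alpha2, beta, normalize = TRUE) {
  stopifnot(length(freqs) == 4, all(freqs > 0))
  Q <- matrix(0, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    transition_pur <- (i == 1 && j == 3) || (i == 3 && j == 1)
    transition_pyr <- (i == 2 && j == 4) || (i == 4 && j == 2)
    rate <- if (transition_pur) alpha1 else if (transition_pyr) alpha2 else beta
    Q[i, j] <- rate * freqs[j]
  }
  diag(Q) <- -rowSums(Q)
  if (normalize) {
    mu <- -sum(freqs * diag(Q))   # expected substitutions per unit time
    Q <- Q / mu
  }
  Q
}

# Eigen-decomposition of a reversible Q via the symmetrizing similarity
# transform; returns pieces for fast P(t) = U exp(D t) U^{-1}.
tn93_eigen <- function(Q, freqs) {
  s <- sqrt(freqs)
  S <- diag(s) %*% Q %*% diag(1 / s)
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  list(U = diag(1 / s) %*% e$vectors, Uinv = t(e$vectors) %*% diag(s),
       values = e$values)
}

tn93_transition_prob <- function(ed, t) {
  P <- ed$U %*% diag(exp(ed$values * t)) %*% ed$Uinv
  P[P < 0] <- 0
  P / rowSums(P)
}

# --- Pairwise deletion and distance estimation -------------------------------

#' Columns usable for one sequence pair (pairwise deletion)
#'
#' Any non-A/C/G/T character — gaps and IUPAC ambiguity codes alike — makes a
#' column unusable for the pair; columns are removed per pair independently.
#'
#' @param a,b Aligned sequence strings of equal length.
#' @return Integer vector of usable column indices (1-based).
#' @export
pairwise_usable_sites <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  ca <- strsplit(toupper(a), "")[[1]]
  cb <- strsplit(toupper(b), "")[[1]]
  which(ca %in% DNA_BASES & cb %in% DNA_BASES)
}

# 4x4 site-pattern count table for a pair, over usable columns
pair_pattern_counts <- function(ca, cb) {
  ok <- ca %in% DNA_BASES & cb %in% DNA_BASES
  table(factor(ca[ok], levels = DNA_BASES), factor(cb[ok], levels = DNA_BASES))
}

# log composite likelihood of one pair's pattern counts at distance t under
# TN93 with the given frequencies and rate ratios (beta = 1 reference)
pair_loglik <- function(counts, t, ed, freqs) {
  P <- tn93_transition_prob(ed, t)
  M <- freqs * P                 # joint probability of (i, j) at distance t
  sum(counts * log(pmax(M, 1e-300)))
}

#' Composite-likelihood TN93 distances with pairwise deletion
#'
#' Estimates pairwise evolutionary distances (substitutions per site) under
#' the Tamura-Nei model with rate parameters shared across all pairs: the two
#' transition/transversion ratios are estimated once by maximising the
#' composite (summed pairwise) log-likelihood, and each pair's distance then
#' maximises that pair's likelihood under the shared parameters. Alignment
#' columns with gaps or ambiguity codes are removed per pair (pairwise
#' deletion). With `composition_correction = TRUE` (default) each pair's
#' likelihood uses the pair's own empirical base frequencies, accommodating
#' composition bias between sequences; otherwise alignment-wide pooled
#' frequencies are used. Pairs whose distance estimate runs into the
#' saturation bound are flagged inestimable (`NA`), never silently clamped.
#'
#' @param alignment Named character vector of equal-length aligned sequences,
#'   or a path to an aligned multi-FASTA.
#' @param composition_correction Use per-pair empirical base frequencies
#'   (default `TRUE`).
#' @param max_distance Saturation bound in substitutions per site; estimates
#'   beyond it are flagged inestimable (default 10).
#' @param outer_iter Alternating-maximisation sweeps between shared rate
#'   parameters and per-pair distances (default 4).
#' @return An `mcl_distances` object: `distances` (symmetric matrix, NA =
#'   inestimable), `n_sites` (per-pair usable columns), `params` (shared
#'   rate ratios and pooled frequencies), `flagged` (inestimable pairs).
#' @export
mcl_distances <- function(alignment, composition_correction = TRUE,
                          max_distance = 10, outer_iter = 4) {
  if (length(alignment) == 1 && file.exists(alignment)) {
    alignment <- read_fasta(alignment)
  }
  taxa <- names(alignment)
  n <- length(alignment)
  if (n < 2) abort("need at least two sequences")
  if (length(unique(nchar(alignment))) != 1) abort("rows differ in length")
  chars <- lapply(alignment, function(s) strsplit(toupper(s), "")[[1]])

  pairs <- utils::combn(n, 2)
  counts <- vector("list", ncol(pairs))
  pair_freqs <- vector("list", ncol(pairs))
  n_sites <- matrix(0L, n, n, dimnames = list(taxa, taxa))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    tab <- pair_pattern_counts(chars[[i]], chars[[j]])
    counts[[k]] <- unclass(tab)
    m <- sum(tab)
    if (m == 0) abort(sprintf("pair (%s, %s) has no usable sites", taxa[i], taxa[j]))
    n_sites[i, j] <- n_sites[j, i] <- m
    f <- (rowSums(tab) + colSums(tab)) / (2 * m)
    pair_freqs[[k]] <- pmax(f, 1e-6) / sum(pmax(f, 1e-6))
  }
  pooled <- Reduce(`+`, counts)
  pf <- (rowSums(pooled) + colSums(pooled)) / (2 * sum(pooled))
  pooled_freqs <- pmax(pf, 1e-6) / sum(pmax(pf, 1e-6))
  freqs_of <- function(k) if (composition_correction) pair_freqs[[k]] else pooled_freqs

  upper <- max_distance * 1.5
  dists <- rep(0.1, ncol(pairs))
  kappa <- c(2, 2)   # alpha1/beta, alpha2/beta
  eds <- NULL
  build_eds <- function(kp) {
    lapply(seq_len(ncol(pairs)), function(k) {
      f <- freqs_of(k)
      tn93_eigen(tn93_rate_matrix(f, kp[1], kp[2], 1), f)
    })
  }
  for (sweep in seq_len(outer_iter)) {
    eds <- build_eds(kappa)
    dists <- vapply(seq_len(ncol(pairs)), function(k) {
      if (sum(counts[[k]] * (1 - diag(4))) == 0) return(0)  # identical pair
      optimize(function(t) pair_loglik(counts[[k]], t, eds[[k]], freqs_of(k)),
               c(1e-9, upper), maximum = TRUE, tol = 1e-10)$maximum
    }, numeric(1))
    obj <- function(logk) {
      kp <- exp(logk)
      e2 <- build_eds(kp)
      -sum(vapply(seq_len(ncol(pairs)), function(k) {
        pair_loglik(counts[[k]], max(dists[k], 1e-9), e2[[k]], freqs_of(k))
      }, numeric(1)))
    }
    opt <- optim(log(kappa), obj, method = "Nelder-Mead",
                 control = list(maxit = if (sweep == outer_iter) 200 else 60,
                                reltol = 1e-8))
    kappa <- exp(opt$par)
  }
  eds <- build_eds(kappa)
  dists <- vapply(seq_len(ncol(pairs)), function(k) {
    if (sum(counts[[k]] * (1 - diag(4))) == 0) return(0)
    optimize(function(t) pair_loglik(counts[[k]], t, eds[[k]], freqs_of(k)),
             c(1e-9, upper), maximum = TRUE, tol = 1e-12)$maximum
  }, numeric(1))

  D <- matrix(0, n, n, dimnames = list(taxa, taxa))
  flagged <- character(0)
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    d <- dists[k]
    if (d > max_distance) {
      D[i, j] <- D[j, i] <- NA_real_
      flagged <- c(flagged, paste(taxa[i], taxa[j], sep = " ~ "))
    } else {
      D[i, j] <- D[j, i] <- d
    }
  }
  structure(list(distances = D, n_sites = n_sites,
                 params = list(kappa_purine = kappa[1],
                               kappa_pyrimidine = kappa[2],
                               pooled_freqs = pooled_freqs,
                               composition_correction = composition_correction),
                 flagged = flagged),
            class = "mcl_distances")
}

#' @export
print.mcl_distances <- function(x, ...) {
  cat("<mcl_distances> ", nrow(x$distances), " taxa; kappa(purine) = ",
      signif(x$params$kappa_purine, 4), ", kappa(pyrimidine) = ",
      signif(x$params$kappa_pyrimidine, 4), "\n", sep = "")
  if (length(x$flagged)) {
    cat("  inestimable pairs:", paste(x$flagged, collapse = "; "), "\n")
  }
  invisible(x)
}

#' Tidy pairwise distances into a long tibble
#'
#' @param x An `mcl_distances` object.
#' @param ... Unused.
#' @return Tibble with one row per unordered taxon pair: `taxon_a`,
#'   `taxon_b`, `distance`, `n_sites`.
#' @export
tidy.mcl_distances <- function(x, ...) {
  taxa <- rownames(x$distances)
  idx <- utils::combn(length(taxa), 2)
  tibble(taxon_a = taxa[idx[1, ]], taxon_b = taxa[idx[2, ]],
         distance = x$distances[t(idx)],
         n_sites = x$n_sites[t(idx)])
}

#' One-row summary of a distance estimation
#'
#' @param x An `mcl_distances` object.
#' @param ... Unused.
#' @return One-row tibble: taxon count, shared rate ratios, flagged pairs.
#' @export
glance.mcl_distances <- function(x, ...) {
  tibble(n_taxa = nrow(x$distances),
         kappa_purine = x$params$kappa_purine,
         kappa_pyrimidine = x$params$kappa_pyrimidine,
         composition_correction = x$params$composition_correction,
         n_inestimable = length(x$flagged))
}

# --- Neighbor-Joining --------------------------------------------------------

#' Build an unrooted Neighbor-Joining tree
#'
#' Saitou-Nei agglomeration with the Q criterion and Studier-Keppler branch
#' lengths. Deterministic: ties in the Q matrix break at the lexicographically
#' lowest active-index pair. Negative branch lengths are reported as computed
#' unless `clamp_negative = TRUE`.
#'
#' @param D A symmetric distance matrix with taxon dimnames, or an
#'   `mcl_distances` object.
#' @param clamp_negative Clamp negative branch lengths to zero
#'   (default `FALSE`).
#' @return An unrooted `phylo` tree (ape) with branch lengths.
#' @export
neighbor_joining <- function(D, clamp_negative = FALSE) {
  if (inherits(D, "mcl_distances")) D <- D$distances
  D <- as.matrix(D)
  if (anyNA(D)) {
    abort("distance matrix has inestimable entries; remove those taxa or impute before tree building")
  }
  n <- nrow(D)
  if (n < 3) abort("need at least 3 taxa")
  labels <- rownames(D) %||% paste0("t", seq_len(n))
  fmt <- function(x) sprintf("%.15g", if (clamp_negative) max(x, 0) else x)
  node_str <- as.list(labels)
  active <- seq_len(n)
  d <- D
  while (length(active) > 3) {
    m <- length(active)
    r <- rowSums(d[active, active])
    best <- c(NA_integer_, NA_integer_); best_q <- Inf
    for (ii in 1:(m - 1)) for (jj in (ii + 1):m) {
      q <- (m - 2) * d[active[ii], active[jj]] - r[ii] - r[jj]
      if (q < best_q - 1e-12) { best_q <- q; best <- c(ii, jj) }
    }
    i <- active[best[1]]; j <- active[best[2]]
    li <- d[i, j] / 2 + (r[best[1]] - r[best[2]]) / (2 * (m - 2))
    lj <- d[i, j] - li
    new_str <- paste0("(", node_str[[i]], ":", fmt(li), ",",
                      node_str[[j]], ":", fmt(lj), ")")
    du <- (d[i, active] + d[j, active] - d[i, j]) / 2
    d <- rbind(cbind(d, 0), 0)
    u <- nrow(d)
    d[u, active] <- du; d[active, u] <- du; d[u, u] <- 0
    node_str[[u]] <- new_str
    active <- c(setdiff(active, c(i, j)), u)
  }
  a <- active[1]; b <- active[2]; cc <- active[3]
  la <- (d[a, b] + d[a, cc] - d[b, cc]) / 2
  lb <- (d[a, b] + d[b, cc] - d[a, cc]) / 2
  lc <- (d[a, cc] + d[b, cc] - d[a, b]) / 2
  newick <- paste0("(", node_str[[a]], ":", fmt(la), ",",
                   node_str[[b]], ":", fmt(lb), ",",
                   node_str[[cc]], ":", fmt(lc), ");")
  ape::read.tree(text = newick)
}

#' Total branch length of a tree
#'
#' Sum over all branches, negative branches included as computed; the
#' negative part is reported separately as an attribute.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @return The sum of branch lengths, with attribute `negative_sum` (the sum
#'   of negative branches only).
#' @export
total_branch_length <- function(tree) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  s <- sum(tree$edge.length)
  attr(s, "negative_sum") <- sum(tree$edge.length[tree$edge.length < 0])
  s
}

#' Write / read Newick trees
#'
#' Thin wrappers over ape's Newick writer/parser. Branch lengths are rounded
#' to 8 decimals on write; a write/read round trip preserves topology and
#' branch lengths to that printed precision.
#'
#' @param tree A `phylo` tree.
#' @param path Output file; if `NULL`, the Newick string is returned.
#' @param digits Decimal places for branch lengths (default 8).
#' @return `write_newick`: the Newick string (invisibly if written to file).
#'   `read_newick`: a `phylo` tree.
#' @export
write_newick <- function(tree, path = NULL, digits = 8) {
  tr <- tree
  if (!is.null(tr$edge.length)) tr$edge.length <- round(tr$edge.length, digits)
  s <- ape::write.tree(tr)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}

#' @rdname write_newick
#' @param x A Newick string or a path to a Newick file.
#' @export
read_newick <- function(x) {
  txt <- if (file.exists(x)) paste(readLines(x), collapse = "") else x
  tr <- tryCatch(ape::read.tree(text = txt),
                 error = function(e) NULL)
  if (is.null(tr)) {
    abort(paste0("malformed Newick string: ", substr(txt, 1, 60)))
  }
  tr
}
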