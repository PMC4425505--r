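#' Motif specification for a splice-site model
#'
#' Fixes the motif length and the obligate dinucleotide with its offsets
#' within the motif. Defaults follow the classical splice-site windows:
#' donors are 9-mers (3 exonic + 6 intronic bases) with GT at motif positions
#' 4-5; acceptors are 23-mers (20 intronic + 3 exonic) with AG at positions
#' 19-20.
#'
#' @param kind `"donor"` or `"acceptor"`.
#' @param length Motif length L.
#' @param dinucleotide Obligate dinucleotide (e.g. `"GT"`).
#' @param offsets Length-2 integer vector: motif positions of the obligate
#'   dinucleotide (1-based, contiguous).
#' @return A `motif_spec` object.
#' @export
motif_spec <- function(kind = c("donor", "acceptor"), length = NULL,
                       dinucleotide = NULL, offsets = NULL) {
  kind <- match.arg(kind)
  if (is.null(length)) length <- if (kind == "donor") 9L else 23L
  if (is.null(dinucleotide)) dinucleotide <- if (kind == "donor") "GT" else "AG"
  if (is.null(offsets)) offsets <- if (kind == "donor") c(4L, 5L) else c(19L, 20L)
  stopifnot(all(offsets >= 1), all(offsets <= length),
            diff(offsets) == 1L, nchar(dinucleotide) == 2L)
  structure(list(kind = kind, length = as.integer(length),
                 dinucleotide = dinucleotide, offsets = as.integer(offsets)),
            class = "motif_spec")
}

#' Default constraint set: position singletons plus adjacent pairs
#'
#' @param L Motif length.
#' @param order 1 for singletons only, 2 (default) to add adjacent pairs.
#' @return List of integer position vectors.
#' @export
default_constraints <- function(L, order = 2) {
  cs <- as.list(seq_len(L))
  if (order >= 2 && L >= 2) {
    cs <- c(cs, lapply(seq_len(L - 1L), function(i) c(i, i + 1L)))
  }
  cs
}

#' Empirical marginal tables for a constraint set
#'
#' Computes, for each position subset in the constraint set, the joint
#' empirical frequency table over the training motifs. A pseudocount is added
#' per cell of every maximal subset (one not contained in a larger subset);
#' subsets contained in a larger one are derived by marginalising that
#' subset's table, so that overlapping constraints stay mutually consistent.
#'
#' @param motifs Character vector of training sequences, all of length L over
#'   A/C/G/T (or a path to a FASTA file).
#' @param constraints List of integer position vectors (see
#'   [default_constraints()]).
#' @param pseudocount Pseudocount per cell of each maximal subset's table
#'   (default 0.5).
#' @return A `motif_marginals` object: constraint positions, probability
#'   tables, motif length and training-set size.
#' @export
empirical_marginals <- function(motifs, constraints, pseudocount = 0.5) {
  if (length(motifs) == 1 && file.exists(motifs)) motifs <- read_fasta(motifs)
  motifs <- toupper(unname(motifs))
  L <- nchar(motifs[1])
  bad <- which(nchar(motifs) != L | grepl("[^ACGT]", motifs))
  if (length(bad)) {
    abort(paste0("rejected sequences (length mismatch or ambiguous base): ",
                 paste(head(bad, 20), collapse = ", "),
                 if (length(bad) > 20) " ..." else ""))
  }
  constraints <- lapply(constraints, function(s) sort(as.integer(s)))
  stopifnot(all(unlist(constraints) >= 1), all(unlist(constraints) <= L))
  M <- do.call(rbind, strsplit(motifs, ""))
  n <- length(motifs)
  keys <- vapply(constraints, paste, character(1), collapse = ",")
  is_maximal <- vapply(seq_along(constraints), function(i) {
    !any(vapply(seq_along(constraints), function(j) {
      j != i && length(constraints[[j]]) > length(constraints[[i]]) &&
        all(constraints[[i]] %in% constraints[[j]])
    }, logical(1)))
  }, logical(1))
  count_table <- function(S) {
    facs <- lapply(S, function(p) factor(M[, p], levels = DNA_BASES))
    tab <- do.call(table, facs)
    array(as.numeric(tab), dim = rep(4L, length(S)),
          dimnames = rep(list(DNA_BASES), length(S)))
  }
  tables <- vector("list", length(constraints))
  for (i in which(is_maximal)) {
    tab <- count_table(constraints[[i]]) + pseudocount
    tables[[i]] <- tab / sum(tab)
  }
  for (i in which(!is_maximal)) {
    parent <- which(vapply(seq_along(constraints), function(j) {
      j != i && is_maximal[j] && all(constraints[[i]] %in% constraints[[j]])
    }, logical(1)))[1]
    pos_in_parent <- match(constraints[[i]], constraints[[parent]])
    tables[[i]] <- apply(tables[[parent]], pos_in_parent, sum)
    if (length(constraints[[i]]) == 1) {
      tables[[i]] <- array(tables[[i]], dim = 4L, dimnames = list(DNA_BASES))
    }
  }
  structure(list(constraints = constraints, tables = setNames(tables, keys),
                 L = L, n = n, pseudocount = pseudocount),
            class = "motif_marginals")
}

# index (1-based) of each state's configuration of positions S, for all 4^L
# states enumerated with position 1 as the fastest-varying digit
subset_keys <- function(L, S) {
  n_states <- 4L^L
  cells <- 0:(n_states - 1L)
  key <- integer(n_states)
  for (k in seq_along(S)) {
    digit <- (cells %/% 4L^(S[k] - 1L)) %% 4L
    key <- key + digit * 4L^(k - 1L)
  }
  key + 1L
}

#' Fit a maximum-entropy motif model by iterative proportional fitting
#'
#' Finds the distribution of maximal entropy over fixed-length motifs whose
#' marginals on the constraint subsets match the given targets. For motifs of
#' length L <= 9 the full probability table over 4^L states is fitted by
#' iterative proportional fitting (IPF). Longer motifs (e.g. 23-mer
#' acceptors) use a first-order chain factorisation built from the
#' adjacent-pair marginals, which is the exact maximum-entropy solution when
#' the constraint subsets form a chain of adjacent pairs.
#'
#' @param marginals A `motif_marginals` object from [empirical_marginals()],
#'   or any list with the same fields (targets must be mutually consistent on
#'   shared positions).
#' @param spec Optional [motif_spec()] carried as metadata (required by
#'   [scan_candidates()]).
#' @param max_iter Maximum IPF sweeps (default 500).
#' @param tol Convergence tolerance on the maximum absolute marginal residual
#'   (default 1e-8).
#' @param consistency_tol Maximum tolerated disagreement between overlapping
#'   constraint targets before the fit is refused (default 1e-6).
#' @return A `maxent_model` with fit diagnostics (`iterations`,
#'   `max_residual`, `converged`, `entropy_bits`).
#' @export
fit_maxent <- function(marginals, spec = NULL, max_iter = 500, tol = 1e-8,
                       consistency_tol = 1e-6) {
  cs <- marginals$constraints
  tabs <- marginals$tables
  L <- marginals$L
  covered <- sort(unique(unlist(cs)))
  if (!identical(covered, seq_len(L))) {
    abort("every motif position must be covered by at least one constraint")
  }
  # consistency of shared positions across constraints
  single_from <- function(i, p) {
    apply_dims <- match(p, cs[[i]])
    tab <- tabs[[i]]
    if (length(cs[[i]]) == 1) as.vector(tab) else apply(tab, apply_dims, sum)
  }
  for (p in covered) {
    holders <- which(vapply(cs, function(s) p %in% s, logical(1)))
    if (length(holders) > 1) {
      ref <- single_from(holders[1], p)
      for (h in holders[-1]) {
        if (max(abs(single_from(h, p) - ref)) > consistency_tol) {
          abort(paste0("fit error: inconsistent marginals at position ", p))
        }
      }
    }
  }
  if (L <= 9) {
    n_states <- 4L^L
    keylist <- lapply(cs, function(S) subset_keys(L, S))
    targets <- lapply(tabs, as.vector)
    p <- rep(1 / n_states, n_states)
    iter <- 0L
    max_res <- Inf
    while (iter < max_iter) {
      iter <- iter + 1L
      for (ci in seq_along(cs)) {
        cur <- as.vector(rowsum(p, keylist[[ci]]))
        fac <- ifelse(cur > 0, targets[[ci]] / cur, 0)
        p <- p * fac[keylist[[ci]]]
      }
      max_res <- max(vapply(seq_along(cs), function(ci) {
        max(abs(as.vector(rowsum(p, keylist[[ci]])) - targets[[ci]]))
      }, numeric(1)))
      if (max_res < tol) break
    }
    ent <- -sum(ifelse(p > 0, p * log2(p), 0))
    structure(list(spec = spec, constraints = cs, representation = "table",
                   prob = p, L = L,
                   diagnostics = list(iterations = iter, max_residual = max_res,
                                      converged = max_res < tol,
                                      entropy_bits = ent)),
              class = "maxent_model")
  } else {
    pair_idx <- vapply(seq_len(L - 1L), function(i) {
      hit <- which(vapply(cs, function(s) identical(s, c(i, i + 1L)), logical(1)))
      if (!length(hit)) {
        abort("chain factorisation requires every adjacent-pair constraint")
      }
      hit[1]
    }, integer(1))
    start <- apply(tabs[[pair_idx[1]]], 1, sum)
    trans <- lapply(seq_len(L - 1L), function(i) {
      joint <- tabs[[pair_idx[i]]]
      sweep(joint, 1, rowSums(joint), "/")
    })
    # chain entropy: H(X1) + sum H(X_{i+1} | X_i), in bits
    h <- -sum(start * log2(start))
    marg <- start
    for (i in seq_len(L - 1L)) {
      joint <- marg * trans[[i]]
      h <- h - sum(ifelse(joint > 0, joint * log2(trans[[i]]), 0))
      marg <- colSums(joint)
    }
    structure(list(spec = spec, constraints = cs, representation = "chain",
                   start = start, trans = trans, L = L,
                   diagnostics = list(iterations = 0L, max_residual = 0,
                                      converged = TRUE, entropy_bits = h)),
              class = "maxent_model")
  }
}

#' @export
print.maxent_model <- function(x, ...) {
  d <- x$diagnostics
  cat("<maxent_model> L =", x$L, "| representation:", x$representation,
      "|", length(x$constraints), "constraints\n")
  cat(sprintf("  iterations %d, max marginal residual %.3g, converged: %s, entropy %.3f bits\n",
              d$iterations, d$max_residual, d$converged, d$entropy_bits))
  invisible(x)
}

#' Tidy a maximum-entropy model: one row per constraint
#'
#' @param x A `maxent_model`.
#' @param ... Unused.
#' @return Tibble with constraint positions and subset size.
#' @export
tidy.maxent_model <- function(x, ...) {
  tibble(constraint = vapply(x$constraints, paste, character(1), collapse = ","),
         size = lengths(x$constraints))
}

#' One-row fit summary of a maximum-entropy model
#'
#' @param x A `maxent_model`.
#' @param ... Unused.
#' @return One-row tibble of the fit diagnostics.
#' @export
glance.maxent_model <- function(x, ...) {
  as_tibble(x$diagnostics[c("iterations", "max_residual", "converged",
                            "entropy_bits")])
}

seq_to_state <- function(x, L) {
  d <- match(strsplit(x, "")[[1]], DNA_BASES) - 1L
  sum(d * 4L^(seq_len(L) - 1L)) + 1L
}

model_prob <- function(model, x) {
  if (model$representation == "table") {
    model$prob[seq_to_state(x, model$L)]
  } else {
    b <- match(strsplit(x, "")[[1]], DNA_BASES)
    p <- model$start[b[1]]
    for (i in seq_len(model$L - 1L)) p <- p * model$trans[[i]][b[i], b[i + 1L]]
    p
  }
}

background_prob <- function(background, x, L) {
  b <- match(strsplit(x, "")[[1]], DNA_BASES)
  if (is.null(background)) return(0.25^L)
  if (is.matrix(background)) {
    stopifnot(nrow(background) == 4, ncol(background) == L)
    prod(background[cbind(b, seq_len(L))])
  } else {
    stopifnot(length(background) == 4)
    prod(background[b])
  }
}

#' Score candidate splice sites as log-odds splicing strengths
#'
#' The splicing strength of an L-mer x is `log2(P_model(x) / P_bg(x))`,
#' where the background is an independent-position base distribution
#' (uniform by default). A model identical to the background scores 0
#' everywhere.
#'
#' @param model A fitted [fit_maxent()] model or an imported score table
#'   ([import_score_table()]).
#' @param x Character vector of L-mers to score.
#' @param background `NULL` (uniform), a length-4 base distribution
#'   (A, C, G, T), or a 4 x L matrix of per-position distributions.
#' @param ... Passed to methods.
#' @return Numeric vector of scores in bits.
#' @export
score_site <- function(model, x, background = NULL, ...) {
  UseMethod("score_site")
}

#' @rdname score_site
#' @export
score_site.maxent_model <- function(model, x, background = NULL, ...) {
  vapply(toupper(x), function(xi) {
    if (nchar(xi) != model$L) {
      abort(paste0("sequence length ", nchar(xi), " != motif length ", model$L))
    }
    if (grepl("[^ACGT]", xi)) {
      abort(paste0("score undefined: ambiguous base in '", xi, "'"))
    }
    log2(model_prob(model, xi) / background_prob(background, xi, model$L))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Import a published splice-site score table
#'
#' Reads a two-column whitespace/tab-separated file (`kmer score`, with or
#' without a header line) mapping every L-mer to its published splicing
#' strength, so externally trained donor/acceptor models can be used for
#' scoring without retraining.
#'
#' @param path Path to the table.
#' @param spec A [motif_spec()] describing the motif the table scores.
#' @return A `maxent_score_table` usable with [score_site()] and
#'   [scan_candidates()].
#' @export
import_score_table <- function(path, spec) {
  d <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                         col.names = c("kmer", "score"))
  if (identical(tolower(d$kmer[1]), "kmer")) d <- d[-1, ]
  d$score <- as.numeric(d$score)
  if (any(is.na(d$score))) abort("malformed score table: non-numeric scores")
  env <- new.env(parent = emptyenv(), size = nrow(d))
  for (i in seq_len(nrow(d))) assign(toupper(d$kmer[i]), d$score[i], envir = env)
  structure(list(env = env, L = unique(nchar(d$kmer)), spec = spec),
            class = "maxent_score_table")
}

#' @rdname score_site
#' @export
score_site.maxent_score_table <- function(model, x, background = NULL, ...) {
  vapply(toupper(x), function(xi) {
    if (nchar(xi) != model$L) {
      abort(paste0("sequence length ", nchar(xi), " != table k-mer length ", model$L))
    }
    if (!exists(xi, envir = model$env, inherits = FALSE)) {
      abort(paste0("k-mer '", xi, "' absent from the imported score table"))
    }
    get(xi, envir = model$env)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Scan a sequence for candidate splice-site windows
#'
#' Scores every window of the model's length that carries the obligate
#' dinucleotide (GT for donors, AG for acceptors) at the spec's offsets;
#' windows lacking it — e.g. a donor disrupted by a G-to-T substitution —
#' are omitted.
#'
#' @param model A `maxent_model` or `maxent_score_table` whose `spec` is a
#'   [motif_spec()].
#' @param sequence A single sequence string to scan.
#' @param background Background distribution; see [score_site()].
#' @return Tibble with columns `start` (1-based window start), `window`,
#'   `score`. Empty (with a warning) if the sequence is shorter than L.
#' @export
scan_candidates <- function(model, sequence, background = NULL) {
  spec <- model$spec
  if (is.null(spec)) abort("model carries no motif_spec; pass one to the fit")
  L <- spec$length
  sequence <- toupper(sequence)
  empty <- tibble(start = integer(), window = character(), score = numeric())
  if (nchar(sequence) < L) {
    warn("sequence shorter than the motif length; nothing to scan")
    return(empty)
  }
  starts <- seq_len(nchar(sequence) - L + 1L)
  windows <- substring(sequence, starts, starts + L - 1L)
  has_site <- substr(windows, spec$offsets[1], spec$offsets[2]) == spec$dinucleotide
  clean <- !grepl("[^ACGT]", windows)
  keep <- has_site & clean
  if (!any(keep)) return(empty)
  tibble(start = starts[keep], window = windows[keep],
         score = score_site(model, windows[keep], background = background))
}

# L-mer window of a splice site in the reference, read on the transcribed
# strand; `off` is the motif offset the site's G aligns to.
site_window <- function(sequence, position, strand, L, off) {
  if (strand == "+") {
    s0 <- position - (off - 1L); e0 <- s0 + L
    if (s0 < 0 || e0 > nchar(sequence)) abort("coordinate error: site window off reference")
    subseq0(sequence, s0, e0)
  } else {
    s0 <- position - (L - off); e0 <- s0 + L
    if (s0 < 0 || e0 > nchar(sequence)) abort("coordinate error: site window off reference")
    revcomp(subseq0(sequence, s0, e0))
  }
}

#' Rank a gene model's splice sites by predicted splicing strength
#'
#' Extracts each labelled site's motif window from the reference (donor:
#' exonic + intronic bases around GT; acceptor: intronic + exonic bases
#' around AG, all read on the transcribed strand), scores donors with the
#' donor model and acceptors with the acceptor model, and ranks sites within
#' each kind. Tied scores break by ascending genomic position.
#'
#' @param gm A [gene_model()] with reference sequence.
#' @param donor_model,acceptor_model Fitted models or imported score tables;
#'   each must carry a [motif_spec()].
#' @param donor_background,acceptor_background Backgrounds for [score_site()].
#' @return A `site_ranking` tibble: `label`, `kind`, `position`, `window`,
#'   `score`, `rank` (within kind).
#' @export
rank_locus_sites <- function(gm, donor_model, acceptor_model,
                             donor_background = NULL,
                             acceptor_background = NULL) {
  if (is.null(gm$sequence)) abort("gene model has no reference sequence")
  rows <- purrr::map_dfr(seq_len(nrow(gm$sites)), function(i) {
    s <- gm$sites[i, ]
    model <- if (s$kind == "donor") donor_model else acceptor_model
    bg <- if (s$kind == "donor") donor_background else acceptor_background
    spec <- model$spec
    off <- if (s$kind == "donor") spec$offsets[1] else spec$offsets[2]
    w <- site_window(gm$sequence, s$position, gm$strand, spec$length, off)
    tibble(label = s$label, kind = s$kind, position = s$position, window = w,
           score = score_site(model, w, background = bg))
  })
  out <- rows %>%
    dplyr::arrange(.data$kind, dplyr::desc(.data$score), .data$position) %>%
    dplyr::group_by(.data$kind) %>%
    dplyr::mutate(rank = dplyr::row_number()) %>%
    dplyr::ungroup()
  class(out) <- c("site_ranking", class(out))
  out
}
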