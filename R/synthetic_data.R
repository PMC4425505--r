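# Nucleotide insert encoding the 16-residue peptide of the X3 variant.
# Codon 4 (CAG, Gln) supplies the AG dinucleotide of the nested X4 acceptor.
X3_INSERT_NT <- "ATCACCTACCAGCTGGACGGCTGGCCAACAGACACGCTCACCACACAG"

#' Generate a synthetic locus with an alternative exon and competing acceptors
#'
#' Builds a reference sequence plus matching [gene_model()] that mirrors the
#' layout of a cassette exon (E9A) between two constitutive exons (E9, E10):
#' a shared donor GT_E9, three alternative acceptors AG_E9A-2/-3/-4 that
#' differ only in the 5' edge they give the cassette exon, the cassette's own
#' donor GT_E9A, and the downstream acceptor AG_E10. The X3 form of the
#' cassette exon is 48 nt and encodes the peptide ITYQLDGWPTDTLTTQ; the X2
#' and X4 forms are 54 nt and 36 nt.
#'
#' `create_donor` models the single thymine-to-guanine substitution that
#' creates the cassette donor: when `TRUE` the dinucleotide at the E9A donor
#' position is GT and the model carries the four variants (skip, X2, X3, X4);
#' when `FALSE` the same position reads TT, and the model carries only the
#' skip variant (the sequence is otherwise identical for a given seed).
#'
#' Donor sites get a consensus exonic/intronic context (CAG|GTAAGT); each
#' acceptor gets a polypyrimidine tract whose length is configurable, planted
#' only where it does not collide with coding or site sequence (the X4
#' acceptor sits inside the X3 insert, so its context is fixed by the coding
#' sequence).
#'
#' @param create_donor Logical; create the cassette-exon donor GT (default
#'   `TRUE`).
#' @param composition Background base composition (A, C, G, T); must sum
#'   to 1.
#' @param e9_length,e10_length,intron1_length,intron2_length,pad Segment
#'   lengths in nucleotides.
#' @param acceptor_pyrimidines Named integer vector: number of pyrimidines to
#'   plant upstream of each acceptor's AG.
#' @param seed Optional RNG seed; the same seed yields byte-identical output.
#' @return A list with `sequence` (named character vector of length 1, the
#'   reference) and `model` (a validated [gene_model()] with the sequence
#'   attached).
#' @export
generate_locus <- function(create_donor = TRUE,
                           composition = rep(0.25, 4),
                           e9_length = 120, e10_length = 150,
                           intron1_length = 300, intron2_length = 300,
                           pad = 100,
                           acceptor_pyrimidines = c("AG_E9A-2" = 10,
                                                    "AG_E9A-3" = 4,
                                                    "AG_E9A-4" = 0,
                                                    "AG_E10" = 16),
                           seed = NULL) {
  stopifnot(length(composition) == 4, abs(sum(composition) - 1) < 1e-8,
            all(composition >= 0))
  if (e9_length < 10 || e10_length < 10 || pad < 25 ||
      intron1_length < 60 || intron2_length < 60) {
    abort("config error: segments too short to host splice sites and contexts")
  }
  with_seed(seed, {
    e9_start <- pad
    e9_end <- e9_start + e9_length
    s2 <- e9_end + intron1_length          # E9A-2 exon start
    e9a_end <- s2 + 54L
    s3 <- e9a_end - 48L
    s4 <- e9a_end - 36L
    e10_start <- e9a_end + 2L + intron2_length
    e10_end <- e10_start + e10_length
    total <- e10_end + pad

    chars <- sample(DNA_BASES, total, replace = TRUE, prob = composition)
    reserved <- logical(total)
    plant <- function(pos0, s, force = TRUE) {
      idx <- pos0 + seq_len(nchar(s))     # 1-based indices for 0-based pos0
      keep <- if (force) rep(TRUE, length(idx)) else !reserved[idx]
      chars[idx[keep]] <<- strsplit(s, "")[[1]][keep]
      reserved[idx] <<- TRUE
    }
    plant(s3, X3_INSERT_NT)                               # cassette coding seq
    plant(e9_end - 3L, "CAGGTAAGT")                       # GT_E9 + context
    plant(e9a_end - 3L,
          if (create_donor) "CAGGTAAGT" else "CAGTTAAGT") # GT_E9A or TT
    acc_pos <- c("AG_E9A-2" = s2 - 1L, "AG_E9A-3" = s3 - 1L,
                 "AG_E9A-4" = s4 - 1L, "AG_E10" = e10_start - 1L)
    for (lab in names(acc_pos)) {
      p <- acc_pos[[lab]]
      plant(p - 1L, "AG")
      npy <- acceptor_pyrimidines[[lab]] %||% 0
      if (npy > 0) {
        py <- paste(sample(c("C", "T"), npy, replace = TRUE), collapse = "")
        plant(p - 1L - npy, py, force = FALSE)
      }
    }
    seqstr <- paste(chars, collapse = "")

    exons <- tibble(
      name = c("E9", "E9A-2", "E9A-3", "E9A-4", "E10"),
      start = c(e9_start, s2, s3, s4, e10_start),
      end = c(e9_end, e9a_end, e9a_end, e9a_end, e10_end)
    )
    sites <- tibble(
      label = c("GT_E9", "GT_E9A", "AG_E9A-2", "AG_E9A-3", "AG_E9A-4", "AG_E10"),
      kind = c("donor", "donor", rep("acceptor", 4)),
      position = c(e9_end, e9a_end, unname(acc_pos))
    )
    variants <- list(skip = c("E9", "E10"),
                     X2 = c("E9", "E9A-2", "E10"),
                     X3 = c("E9", "E9A-3", "E10"),
                     X4 = c("E9", "E9A-4", "E10"))
    if (!create_donor) {
      sites <- sites[sites$label != "GT_E9A", ]
      exons <- exons[!grepl("^E9A", exons$name), ]
      variants <- variants["skip"]
    }
    gm <- gene_model("locus_synthetic", "+", exons, sites, variants,
                     sequence = seqstr)
    validate_gene_model(gm)
    list(sequence = setNames(seqstr, "locus_synthetic"), model = gm)
  })
}

#' Simulate junction-supporting read counts for one sample group
#'
#' Draws, per replicate, a multinomial (or Dirichlet-multinomial) vector of
#' junction-supporting read counts over the discriminating splice events of a
#' gene model.
#'
#' @param gm A [gene_model()].
#' @param proportions Named numeric vector of variant proportions (must name
#'   variants present in `gm`, sum to 1, all non-negative).
#' @param depth Total junction reads per replicate.
#' @param n_replicates Number of replicates.
#' @param group Group label attached to every replicate (e.g. `"E17"`).
#' @param dispersion Dirichlet concentration; `Inf` (default) gives a pure
#'   multinomial, finite values add across-replicate overdispersion
#'   (replicate proportions drawn from Dirichlet(`dispersion * proportions`)).
#' @param seed Optional RNG seed.
#' @return A junction table: tibble with columns `chrom`, `intron_start`,
#'   `intron_end`, `strand`, `count`, `sample`, `group`.
#' @export
simulate_junction_reads <- function(gm, proportions, depth = 5000,
                                    n_replicates = 6, group = "group1",
                                    dispersion = Inf, seed = NULL) {
  cat <- event_catalog(gm)
  if (!all(names(proportions) %in% cat$variant)) {
    abort(paste0("config error: proportions name variants absent from the model: ",
                 paste(setdiff(names(proportions), cat$variant), collapse = ", ")))
  }
  stopifnot(abs(sum(proportions) - 1) < 1e-8, all(proportions >= 0), depth >= 1)
  cat <- cat[match(names(proportions), cat$variant), ]
  with_seed(seed, {
    purrr::map_dfr(seq_len(n_replicates), function(r) {
      p <- if (is.finite(dispersion)) {
        as.vector(rdirichlet(1, dispersion * proportions))
      } else proportions
      counts <- as.vector(rmultinom(1, size = depth, prob = p))
      tibble(chrom = cat$chrom, intron_start = cat$intron_start,
             intron_end = cat$intron_end, strand = cat$strand,
             count = counts, sample = sprintf("%s_rep%02d", group, r),
             group = group)
    })
  })
}

#' Simulate a training set of fixed-length sequence motifs
#'
#' Samples motif sequences with independent per-position base distributions,
#' optionally overridden by jointly-sampled position pairs (to plant pairwise
#' dependencies that a maximum-entropy model with pair constraints can pick
#' up).
#'
#' @param n Number of sequences.
#' @param length Motif length L.
#' @param base_probs Either `NULL` (uniform), a length-4 vector used at every
#'   position, or a 4 x L matrix of per-position distributions (rows A,C,G,T).
#' @param pair_dependencies Optional list; each element a list with
#'   `positions` (length-2 integer) and `table` (4 x 4 joint probability
#'   matrix, rows = first position, cols = second).
#' @param seed Optional RNG seed.
#' @return Character vector of `n` motif sequences.
#' @export
simulate_motif_set <- function(n, length, base_probs = NULL,
                               pair_dependencies = NULL, seed = NULL) {
  L <- as.integer(length)
  probs <- if (is.null(base_probs)) {
    matrix(0.25, 4, L)
  } else if (is.matrix(base_probs)) {
    stopifnot(nrow(base_probs) == 4, ncol(base_probs) == L)
    base_probs
  } else {
    stopifnot(length(base_probs) == 4)
    matrix(base_probs, 4, L)
  }
  if (any(abs(colSums(probs) - 1) > 1e-8)) {
    abort("config error: per-position distributions must each sum to 1")
  }
  with_seed(seed, {
    m <- vapply(seq_len(L),
                function(j) sample(DNA_BASES, n, replace = TRUE, prob = probs[, j]),
                character(n))
    m <- matrix(m, nrow = n)
    for (dep in pair_dependencies) {
      ij <- dep$positions
      tab <- dep$table
      stopifnot(length(ij) == 2, all(ij >= 1), all(ij <= L),
                all(dim(tab) == c(4, 4)), abs(sum(tab) - 1) < 1e-8)
      cell <- sample(16L, n, replace = TRUE, prob = as.vector(tab))
      m[, ij[1]] <- DNA_BASES[(cell - 1L) %% 4L + 1L]
      m[, ij[2]] <- DNA_BASES[(cell - 1L) %/% 4L + 1L]
    }
    apply(m, 1, paste, collapse = "")
  })
}

#' Simulate a multiple sequence alignment on a tree under TN93
#'
#' Evolves sequences site-independently along a (given or randomly drawn)
#' tree under the Tamura-Nei substitution model, using exact per-branch
#' transition probabilities from the eigen-decomposition of the normalized
#' rate matrix. Branch lengths are in expected substitutions per site.
#'
#' @param n_taxa Number of taxa (ignored when `tree` is given).
#' @param length Alignment length in sites.
#' @param tree Optional `phylo` tree with branch lengths; when `NULL` a
#'   random binary topology is drawn and branch lengths sampled uniformly
#'   from `branch_range`.
#' @param base_freqs Stationary base frequencies (A, C, G, T).
#' @param alpha1,alpha2,beta Purine-transition, pyrimidine-transition and
#'   transversion rate parameters; all equal plus uniform frequencies gives
#'   the Jukes-Cantor model.
#' @param branch_range Range for random branch lengths.
#' @param seed Optional RNG seed.
#' @return A list with `tree` (`phylo`) and `alignment` (named character
#'   vector, one equal-length sequence per taxon).
#' @export
simulate_alignment <- function(n_taxa = NULL, length = 1000, tree = NULL,
                               base_freqs = rep(0.25, 4),
                               alpha1 = 1, alpha2 = 1, beta = 1,
                               branch_range = c(0.02, 0.5), seed = NULL) {
  stopifnot(all(c(alpha1, alpha2, beta) > 0), length >= 1,
            abs(sum(base_freqs) - 1) < 1e-8)
  with_seed(seed, {
    if (is.null(tree)) {
      if (is.null(n_taxa) || n_taxa < 2) {
        abort("config error: need n_taxa >= 2 (or an explicit tree)")
      }
      tree <- ape::rtree(n_taxa, rooted = TRUE,
                         br = function(k) runif(k, branch_range[1], branch_range[2]))
    } else {
      if (!ape::is.binary(tree)) abort("config error: tree must be binary")
      if (is.null(tree$edge.length)) abort("config error: tree lacks branch lengths")
    }
    Q <- tn93_rate_matrix(base_freqs, alpha1, alpha2, beta)
    ed <- tn93_eigen(Q, base_freqs)
    n_tip <- length(tree$tip.label)
    n_node <- n_tip + tree$Nnode
    seqs <- vector("list", n_node)
    root <- n_tip + 1L
    seqs[[root]] <- sample.int(4L, length, replace = TRUE, prob = base_freqs)
    tr <- stats::reorder(tree, "cladewise")  # parents precede children
    edges <- tr$edge
    lens <- tr$edge.length
    for (e in seq_len(nrow(edges))) {
      par <- edges[e, 1]; child <- edges[e, 2]
      P <- tn93_transition_prob(ed, lens[e])
      parent_seq <- seqs[[par]]
      child_seq <- integer(length)
      for (b in 1:4) {
        idx <- which(parent_seq == b)
        if (length(idx)) {
          child_seq[idx] <- sample.int(4L, length(idx), replace = TRUE,
                                       prob = P[b, ])
        }
      }
      seqs[[child]] <- child_seq
    }
    aln <- vapply(seq_len(n_tip),
                  function(i) paste(DNA_BASES[seqs[[i]]], collapse = ""),
                  character(1))
    list(tree = tree, alignment = setNames(aln, tree$tip.label))
  })
}

#' Simulate fluorescence line scans across inhibitory synapses
#'
#' Generates 1-D three-channel intensity profiles (VIAAT, HA, gephyrin) with
#' Gaussian cluster peaks. The VIAAT channel marks cluster positions; the HA
#' and gephyrin peak amplitudes are coupled according to `mode`:
#' `"congruent"` (gephyrin amplitude equals the HA amplitude),
#' `"independent"` (amplitudes drawn independently), or `"partial"` (a
#' `partial_weight` mixture of the two). Intensities get independent
#' truncated-Gaussian noise per channel and are clipped to the 8-bit range
#' 0-255 and rounded to integer grey levels.
#'
#' @param n_scans Number of scans.
#' @param clusters_per_scan Planted clusters per scan.
#' @param pixel_size Pixel size in micrometres (default 0.165).
#' @param scan_length Scan length in micrometres.
#' @param min_spacing Minimum spacing between cluster centres (micrometres);
#'   violating geometry is a config error.
#' @param margin Dead zone at each scan end where no cluster is planted.
#' @param mode Channel coupling: `"congruent"`, `"independent"` or
#'   `"partial"`.
#' @param partial_weight Mixing weight for `"partial"` (1 = congruent).
#' @param viaat_amplitude VIAAT peak amplitude (grey levels).
#' @param amplitude_range Range of HA (and independent gephyrin) peak
#'   amplitudes.
#' @param peak_sd Gaussian peak standard deviation (micrometres).
#' @param baseline Baseline intensity added to every channel.
#' @param noise_sd Additive Gaussian noise SD (0 = noiseless).
#' @param seed Optional RNG seed.
#' @return A tibble with columns `scan_id`, `position_um`, `viaat`, `ha`,
#'   `gephyrin`; the pixel size is attached as attribute `pixel_size` and the
#'   true cluster centres as attribute `true_centers`.
#' @export
simulate_line_scans <- function(n_scans = 6, clusters_per_scan = 5,
                                pixel_size = 0.165, scan_length = 20,
                                min_spacing = 2, margin = 1.5,
                                mode = c("congruent", "independent", "partial"),
                                partial_weight = 0.5,
                                viaat_amplitude = 200,
                                amplitude_range = c(80, 200),
                                peak_sd = 0.25, baseline = 3,
                                noise_sd = 0, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(pixel_size > 0, peak_sd > 0,
            viaat_amplitude >= 0, viaat_amplitude <= 255,
            all(amplitude_range >= 0), all(amplitude_range <= 255))
  span <- scan_length - 2 * margin
  seg <- span / clusters_per_scan
  if (seg < min_spacing) {
    abort("config error: clusters cannot satisfy min_spacing on this scan length")
  }
  with_seed(seed, {
    x <- seq(0, scan_length, by = pixel_size)
    out <- purrr::map_dfr(seq_len(n_scans), function(s) {
      jit <- (seg - min_spacing) / 2
      centers <- margin + (seq_len(clusters_per_scan) - 0.5) * seg +
        runif(clusters_per_scan, -jit, jit)
      a_ha <- runif(clusters_per_scan, amplitude_range[1], amplitude_range[2])
      a_ind <- runif(clusters_per_scan, amplitude_range[1], amplitude_range[2])
      a_geph <- switch(mode,
                       congruent = a_ha,
                       independent = a_ind,
                       partial = partial_weight * a_ha + (1 - partial_weight) * a_ind)
      bump <- function(amps) {
        y <- rep(baseline, length(x))
        for (k in seq_along(centers)) {
          y <- y + amps[k] * exp(-(x - centers[k])^2 / (2 * peak_sd^2))
        }
        y
      }
      v <- bump(rep(viaat_amplitude, clusters_per_scan))
      h <- bump(a_ha)
      g <- bump(a_geph)
      if (noise_sd > 0) {
        v <- v + rnorm(length(x), 0, noise_sd)
        h <- h + rnorm(length(x), 0, noise_sd)
        g <- g + rnorm(length(x), 0, noise_sd)
      }
      clip <- function(y) round(pmin(pmax(y, 0), 255))
      tibble(scan_id = sprintf("scan%03d", s), position_um = x,
             viaat = clip(v), ha = clip(h), gephyrin = clip(g),
             .center = list(centers))
    })
    centers <- lapply(split(out$.center, out$scan_id), function(z) z[[1]])
    out$.center <- NULL
    attr(out, "pixel_size") <- pixel_size
    attr(out, "true_centers") <- centers
    out
  })
}
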