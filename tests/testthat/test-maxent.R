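test_that("empirical marginals reflect the training set", {
  # identical sequences: every marginal is a point mass (no pseudocount)
  m <- empirical_marginals(rep("ACGT", 4), default_constraints(4),
                           pseudocount = 0)
  expect_equal(as.vector(m$tables[["1"]]), c(1, 0, 0, 0))
  expect_equal(m$tables[["2,3"]]["C", "G"], 1)
  expect_equal(sum(m$tables[["2,3"]]), 1)

  # obligate GT makes the (4,5) pair table a point mass on (G,T)
  mot <- simulate_motif_set(200, 9, seed = 41)
  mot <- paste0(substr(mot, 1, 3), "GT", substr(mot, 6, 9))
  mgt <- empirical_marginals(mot, default_constraints(9), pseudocount = 0)
  expect_equal(mgt$tables[["4,5"]]["G", "T"], 1)

  # uniform training data gives near-uniform singletons
  mu <- empirical_marginals(simulate_motif_set(10000, 5, seed = 42),
                            default_constraints(5))
  for (j in 1:5) {
    expect_true(all(abs(as.vector(mu$tables[[as.character(j)]]) - 0.25) < 0.02))
  }

  expect_error(empirical_marginals(c("ACGT", "ACGTA"), list(1L)), "rejected")
  expect_error(empirical_marginals(c("ACGN"), list(1L)), "rejected")
})

test_that("singleton-only maxent is the independent product (PWM)", {
  mot <- simulate_motif_set(500, 4, base_probs = c(0.4, 0.3, 0.2, 0.1),
                            seed = 43)
  marg <- empirical_marginals(mot, default_constraints(4, order = 1))
  fit <- fit_maxent(marg)
  singles <- lapply(1:4, function(j) as.vector(marg$tables[[as.character(j)]]))
  prod_table <- Reduce(function(a, b) outer(a, b), singles)
  expect_lt(max(abs(fit$prob - as.vector(prod_table))), 1e-12)

  # and scores equal the classical PWM log-odds, exactly
  bg <- c(0.3, 0.3, 0.2, 0.2)
  xs <- simulate_motif_set(20, 4, seed = 44)
  pwm <- sapply(xs, function(x) {
    b <- match(strsplit(x, "")[[1]], BASES)
    sum(log2(mapply(function(j, bi) singles[[j]][bi], 1:4, b) / bg[b]))
  })
  expect_equal(score_site(fit, xs, background = bg), unname(pwm))
})

test_that("uniform marginals give the uniform model with entropy 2L bits", {
  prob <- list(constraints = default_constraints(3),
               targets = lapply(default_constraints(3), function(S) {
                 array(1 / 4^length(S), dim = rep(4, length(S)))
               }))
  fit <- fit_from_problem(3, prob)
  expect_lt(max(abs(fit$prob - 1 / 64)), 1e-12)
  expect_equal(glance(fit)$entropy_bits, 6, tolerance = 1e-9)
})

test_that("IPF matches brute-force constrained entropy maximisation (L = 3)", {
  set.seed(45)
  for (rep in 1:20) {
    prob <- random_constraint_problem(3, extra_pairs = sample(1:2, 1))
    fit <- fit_from_problem(3, prob, tol = 1e-12, max_iter = 2000)
    oracle <- brute_force_maxent(3, prob$constraints, prob$targets)
    tv <- sum(abs(fit$prob - oracle)) / 2
    expect_lt(tv, 1e-6)
    # maximal entropy among constraint-satisfying distributions: q itself
    # satisfies the constraints, so the fit cannot have lower entropy
    h_fit <- -sum(fit$prob * log2(pmax(fit$prob, 1e-300)))
    h_q <- -sum(prob$q * log2(pmax(prob$q, 1e-300)))
    expect_gte(h_fit, h_q - 1e-9)
  }
})

test_that("adding constraints never increases entropy", {
  set.seed(46)
  q <- rgamma(64, 1); q <- q / sum(q)
  cs1 <- as.list(1:3)
  cs2 <- c(cs1, list(c(1L, 2L)))
  cs3 <- c(cs2, list(c(2L, 3L)))
  hs <- sapply(list(cs1, cs2, cs3), function(cs) {
    prob <- list(constraints = cs,
                 targets = lapply(cs, function(S) oracle_marginal(q, 3, S)))
    glance(fit_from_problem(3, prob, tol = 1e-12, max_iter = 2000))$entropy_bits
  })
  expect_true(all(diff(hs) <= 1e-9))
})

test_that("IPF reproduces its target marginals (fixed-point diagnostics)", {
  mot <- simulate_motif_set(1000, 6, base_probs = c(0.4, 0.2, 0.2, 0.2),
                            seed = 47)
  fit <- fit_maxent(empirical_marginals(mot, default_constraints(6)))
  expect_true(glance(fit)$converged)
  expect_lt(glance(fit)$max_residual, 1e-8)
})

test_that("score_site is a log2 odds against the background", {
  # model equal to background scores zero everywhere
  prob <- list(constraints = as.list(1:2),
               targets = list(array(c(0.4, 0.3, 0.2, 0.1), 4),
                              array(rep(0.25, 4), 4)))
  fit <- fit_from_problem(2, prob)
  bg <- matrix(c(0.4, 0.3, 0.2, 0.1, rep(0.25, 4)), nrow = 4)
  for (x in c("AA", "CT", "GG", "TC")) {
    expect_equal(score_site(fit, x, background = bg), 0, tolerance = 1e-10)
  }
  # 1-mer toy: P_model(A) = 0.5 vs P_bg(A) = 0.25 is exactly 1 bit
  p1 <- list(constraints = list(1L),
             targets = list(array(c(0.5, 0.3, 0.1, 0.1), 4)))
  f1 <- fit_from_problem(1, p1)
  expect_equal(score_site(f1, "A"), log2(0.5 / 0.25))
  expect_error(score_site(f1, "N"), "ambiguous")
})

test_that("long-motif chain factorisation matches its pair constraints", {
  mot <- simulate_motif_set(2000, 23, seed = 48)
  mot <- paste0(substr(mot, 1, 18), "AG", substr(mot, 21, 23))
  marg <- empirical_marginals(mot, default_constraints(23))
  fit <- fit_maxent(marg, spec = motif_spec("acceptor"))
  expect_equal(fit$representation, "chain")
  # implied pair marginals equal the targets
  marg_i <- fit$start
  for (i in 1:22) {
    joint <- marg_i * fit$trans[[i]]
    target <- marg$tables[[paste(i, i + 1, sep = ",")]]
    expect_lt(max(abs(joint - target)), 1e-12)
    marg_i <- colSums(joint)
  }
  # probabilities normalise: random sample of scored sequences is finite
  sc <- score_site(fit, mot[1:5])
  expect_true(all(is.finite(sc)))
})

test_that("scanning honours the obligate dinucleotide and matches score_site", {
  mot <- simulate_motif_set(800, 9, seed = 49)
  mot <- paste0(substr(mot, 1, 3), "GT", substr(mot, 6, 9))
  fit <- fit_maxent(empirical_marginals(mot, default_constraints(9)),
                    spec = motif_spec("donor"))
  seq_tt <- paste0("CCCCCCCCCC", "CAG", "TT", "AAGTCCCC", "CCCCCCCCCC")
  hits_tt <- scan_candidates(fit, seq_tt)
  # the TT window is omitted (disrupted donor)
  expect_false(any(substr(hits_tt$window, 4, 5) != "GT"))
  seq_gt <- sub("CAGTTAAGT", "CAGGTAAGT", seq_tt)
  hits_gt <- scan_candidates(fit, seq_gt)
  expect_true(any(hits_gt$start == 11))
  expect_false(any(hits_tt$start == 11))
  # windowing consistency: every scanned score equals score_site on the window
  expect_equal(hits_gt$score, score_site(fit, hits_gt$window))
  expect_warning(out <- scan_candidates(fit, "ACGT"), "shorter")
  expect_equal(nrow(out), 0)
})

test_that("locus site ranking reproduces planted strengths and breaks ties by position", {
  loc <- test_locus()
  gm <- loc$model
  don <- simulate_motif_set(1500, 9, seed = 50)
  don <- paste0(substr(don, 1, 3), "GT", substr(don, 6, 9))
  acc <- simulate_motif_set(1500, 23, seed = 51)
  acc <- paste0(substr(acc, 1, 18), "AG", substr(acc, 21, 23))
  dm <- fit_maxent(empirical_marginals(don, default_constraints(9)),
                   spec = motif_spec("donor"))
  am <- fit_maxent(empirical_marginals(acc, default_constraints(23)),
                   spec = motif_spec("acceptor"))
  rk <- rank_locus_sites(gm, dm, am)
  expect_equal(nrow(rk), 6)
  expect_setequal(rk$kind, c("donor", "acceptor"))
  expect_equal(sort(rk$rank[rk$kind == "donor"]), 1:2)
  expect_equal(sort(rk$rank[rk$kind == "acceptor"]), 1:4)
  # every window truly carries its obligate dinucleotide
  expect_true(all(substr(rk$window[rk$kind == "donor"], 4, 5) == "GT"))
  expect_true(all(substr(rk$window[rk$kind == "acceptor"], 19, 20) == "AG"))

  # planted strengths: acceptor trained on a pyrimidine-rich tract ranks the
  # strong-tract AG_E10 above the tract-less AG_E9A-4
  py <- simulate_motif_set(2000, 23, base_probs = {
    m <- matrix(0.25, 4, 23)
    m[, 3:18] <- c(0.05, 0.45, 0.05, 0.45)  # C/T rich tract
    m
  }, seed = 52)
  py <- paste0(substr(py, 1, 18), "AG", substr(py, 21, 23))
  am2 <- fit_maxent(empirical_marginals(py, default_constraints(23)),
                    spec = motif_spec("acceptor"))
  rk2 <- rank_locus_sites(gm, dm, am2)
  acc_scores <- rk2[rk2$kind == "acceptor", ]
  expect_lt(acc_scores$rank[acc_scores$label == "AG_E10"],
            acc_scores$rank[acc_scores$label == "AG_E9A-4"])

  # identical windows tie and order by genomic position
  seqrep <- paste0("AAAA", "CAGGTAAGT", "CCCC", "CAGGTAAGT", "AAAA")
  gmt <- gene_model(
    "twin", "+",
    tibble::tibble(name = c("x1", "x2", "x3"),
                   start = c(0, 15, 30), end = c(7, 20, 31)),
    tibble::tibble(label = c("d_a", "d_b"), kind = "donor",
                   position = c(7, 20)),
    list(skip = "x1"),
    sequence = seqrep)
  rkt <- rank_locus_sites(gmt, dm, am)
  expect_equal(rkt$score[1], rkt$score[2])
  expect_lt(rkt$position[rkt$rank == 1], rkt$position[rkt$rank == 2])
})

test_that("imported score tables score by lookup", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("AAA\t1.25", "ACG\t-0.5", "TTT\t6.33", "TTA\t0.1"), path)
  st <- import_score_table(path, motif_spec("donor", length = 3,
                                            dinucleotide = "TT",
                                            offsets = c(1, 2)))
  expect_equal(score_site(st, c("TTT", "ACG")), c(6.33, -0.5))
  expect_error(score_site(st, "GGG"), "absent")
  hits <- scan_candidates(st, "CATTTAC")
  expect_true("TTT" %in% hits$window)
  expect_equal(hits$score[hits$window == "TTT"], 6.33)
})
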