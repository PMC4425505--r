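#' Assign junction-supporting reads to splice events
#'
#' Matches each junction record to the catalog event whose intron coordinates
#' agree within `tolerance` base pairs (both edges) on the same chromosome
#' and strand, and sums supporting-read counts per sample. Junctions matching
#' no event accumulate under `variant = "unassigned"`; a junction matching
#' two or more events at the given tolerance is an error.
#'
#' @param junctions Junction table: tibble/data frame with columns `chrom`,
#'   `intron_start`, `intron_end`, `strand`, `count`, `sample` and optionally
#'   `group` (0-based half-open intron coordinates).
#' @param catalog Event catalog from [event_catalog()].
#' @param tolerance Maximum per-edge coordinate mismatch in bp (default 0,
#'   i.e. exact splice coordinates).
#' @return Tidy event counts: tibble with columns `sample`, `group`,
#'   `variant`, `count`, one row per sample x (variant + "unassigned").
#' @export
count_events <- function(junctions, catalog, tolerance = 0) {
  stopifnot(tolerance >= 0)
  junctions <- as_tibble(junctions)
  if (!"group" %in% names(junctions)) junctions$group <- NA_character_
  if (any(junctions$count < 0)) abort("negative supporting-read count")
  if (any(junctions$intron_start >= junctions$intron_end)) {
    abort("junction with intron_start >= intron_end")
  }
  variant_of <- character(nrow(junctions))
  for (i in seq_len(nrow(junctions))) {
    hit <- which(catalog$chrom == junctions$chrom[i] &
                   catalog$strand == junctions$strand[i] &
                   abs(catalog$intron_start - junctions$intron_start[i]) <= tolerance &
                   abs(catalog$intron_end - junctions$intron_end[i]) <= tolerance)
    if (length(hit) > 1) {
      abort(sprintf(
        "ambiguity error: junction %s:%d-%d(%s) matches events %s at tolerance %d",
        junctions$chrom[i], junctions$intron_start[i], junctions$intron_end[i],
        junctions$strand[i], paste(catalog$variant[hit], collapse = ", "),
        tolerance))
    }
    variant_of[i] <- if (length(hit) == 1) catalog$variant[hit] else "unassigned"
  }
  junctions$variant <- variant_of
  grid <- tidyr::expand_grid(
    dplyr::distinct(junctions, .data$sample, .data$group),
    variant = c(catalog$variant, "unassigned")
  )
  junctions %>%
    dplyr::group_by(.data$sample, .data$group, .data$variant) %>%
    dplyr::summarise(count = sum(.data$count), .groups = "drop") %>%
    dplyr::right_join(grid, by = c("sample", "group", "variant")) %>%
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0L)) %>%
    dplyr::arrange(.data$sample, .data$variant)
}

#' Per-sample relative splice-variant frequencies
#'
#' Converts event counts to relative frequencies
#' f_v = count_v / sum of counts over the catalog events; reads in the
#' `"unassigned"` bucket are excluded from the denominator.
#'
#' @param counts Tidy event counts from [count_events()] (columns `sample`,
#'   `group`, `variant`, `count`).
#' @return Tibble with columns `sample`, `group`, `variant`, `count`,
#'   `frequency` (unassigned rows dropped).
#' @export
relative_frequencies <- function(counts) {
  counts <- as_tibble(counts)
  assigned <- dplyr::filter(counts, .data$variant != "unassigned")
  totals <- assigned %>%
    dplyr::group_by(.data$sample) %>%
    dplyr::summarise(total = sum(.data$count), .groups = "drop")
  bad <- totals$sample[totals$total == 0]
  if (length(bad)) {
    abort(paste0("undefined-frequency error: zero assigned reads in sample(s) ",
                 paste(bad, collapse = ", ")))
  }
  assigned %>%
    dplyr::left_join(totals, by = "sample") %>%
    dplyr::mutate(frequency = .data$count / .data$total) %>%
    dplyr::select(-"total")
}

#' Summarise variant frequencies per group
#'
#' Per-group, per-variant mean and sample standard deviation (n - 1
#' denominator) of the per-replicate frequencies; groups of size 1 report
#' `NA` for the SD rather than 0.
#'
#' @param freqs Output of [relative_frequencies()].
#' @return A `splice_frequency_table`: tibble with columns `group`,
#'   `variant`, `mean`, `sd`, `n`.
#' @export
summarize_groups <- function(freqs) {
  out <- freqs %>%
    dplyr::group_by(.data$group, .data$variant) %>%
    dplyr::summarise(mean = mean(.data$frequency),
                     sd = sd(.data$frequency),
                     n = dplyr::n(), .groups = "drop")
  class(out) <- c("splice_frequency_table", class(out))
  out
}

#' Compare inclusion-variant frequencies by ANOVA with Bonferroni post hoc
#'
#' One-way ANOVA of per-replicate frequencies across the inclusion variants,
#' followed by pairwise two-sample t tests (pooled variance by default,
#' Welch optionally) with Bonferroni multiplication of raw p values, capped
#' at 1. Significance marks: `*` at p < 0.05, `***` at p < 0.001.
#'
#' @param freqs Output of [relative_frequencies()] (one group, or pre-filter
#'   to the group of interest).
#' @param variants Variants to compare (default the three inclusion
#'   variants X2, X3, X4).
#' @param welch Use Welch's t (unequal variances) instead of the pooled-
#'   variance test. Default `FALSE`.
#' @return A `variant_comparison` object; see [tidy.variant_comparison()] and
#'   [glance.variant_comparison()].
#' @export
compare_variants <- function(freqs, variants = c("X2", "X3", "X4"),
                             welch = FALSE) {
  d <- dplyr::filter(as_tibble(freqs), .data$variant %in% variants)
  missing <- setdiff(variants, unique(d$variant))
  if (length(missing)) {
    abort(paste0("no data for variant(s) ", paste(missing, collapse = ", ")))
  }
  nrep <- d %>% dplyr::count(.data$variant)
  if (any(nrep$n < 2)) abort("need >= 2 replicates per variant")
  d$variant <- factor(d$variant, levels = variants)
  within_var <- d %>%
    dplyr::group_by(.data$variant) %>%
    dplyr::summarise(v = var(.data$frequency), .groups = "drop")
  degenerate <- all(within_var$v == 0)
  fit <- aov(frequency ~ variant, data = d)
  an <- summary(fit)[[1]]
  anova_tbl <- tibble(
    statistic = if (degenerate) NA_real_ else an[["F value"]][1],
    df1 = an[["Df"]][1], df2 = an[["Df"]][2],
    p.value = if (degenerate) NA_real_ else an[["Pr(>F)"]][1],
    degenerate = degenerate
  )
  pairs <- utils::combn(variants, 2, simplify = FALSE)
  m <- length(pairs)
  pw <- purrr::map_dfr(pairs, function(pr) {
    a <- d$frequency[d$variant == pr[1]]
    b <- d$frequency[d$variant == pr[2]]
    if (var(a) == 0 && var(b) == 0) {
      # t test degenerates for constant samples: equal means are a perfect
      # null, different means a sure difference
      same <- isTRUE(all.equal(mean(a), mean(b)))
      tt <- list(statistic = if (same) 0 else Inf,
                 parameter = length(a) + length(b) - 2,
                 p.value = if (same) 1 else 0)
    } else {
      tt <- t.test(a, b, var.equal = !welch)
    }
    tibble(variant_a = pr[1], variant_b = pr[2],
           estimate = mean(a) - mean(b),
           statistic = unname(tt$statistic), df = unname(tt$parameter),
           p.raw = tt$p.value, p.adj = min(1, tt$p.value * m))
  })
  pw$mark <- dplyr::case_when(pw$p.adj < 0.001 ~ "***",
                              pw$p.adj < 0.05 ~ "*",
                              TRUE ~ "")
  structure(list(anova = anova_tbl, pairwise = pw,
                 method = if (welch) "welch" else "pooled",
                 n_comparisons = m),
            class = "variant_comparison")
}

#' @export
print.variant_comparison <- function(x, ...) {
  a <- x$anova
  cat("Variant comparison (one-way ANOVA + Bonferroni post hoc, ",
      x$method, " t tests)\n", sep = "")
  if (isTRUE(a$degenerate)) {
    cat("  ANOVA: F undefined (zero within-group variance in all groups)\n")
  } else {
    cat(sprintf("  ANOVA: F(%d, %d) = %.4g, p = %.3g\n",
                a$df1, a$df2, a$statistic, a$p.value))
  }
  print(as.data.frame(x$pairwise), digits = 4)
  invisible(x)
}

#' Tidy a variant comparison
#'
#' @param x A `variant_comparison` from [compare_variants()].
#' @param ... Unused.
#' @return Tibble of pairwise comparisons with Bonferroni-adjusted p values
#'   and significance marks.
#' @export
tidy.variant_comparison <- function(x, ...) x$pairwise

#' One-row summary of a variant comparison (the ANOVA)
#'
#' @param x A `variant_comparison` from [compare_variants()].
#' @param ... Unused.
#' @return One-row tibble with the ANOVA F statistic, degrees of freedom and
#'   p value.
#' @export
glance.variant_comparison <- function(x, ...) x$anova
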