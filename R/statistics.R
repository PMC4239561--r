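# Summary statistics across fractionation-resistance levels: category hit
# counts Hit(F,C), normalized proportions P(F,C), per-stratum mean
# expression E(F,C), expression-bin proportions P_B(F), and the trend
# regressions that classify categories as fractionation-resistant or
# fractionation-prone.

ns_term_sets <- function(dag, namespace) {
  names(dag$namespace)[dag$namespace == namespace]
}

# logical vector: is each set annotated (>= 1 term) in the namespace?
sets_in_namespace <- function(sets, ann, namespace, dag) {
  ns_terms <- ns_term_sets(dag, namespace)
  vapply(ann$set_terms[sets$set_id],
         function(tt) any(tt %in% ns_terms), logical(1))
}

category_namespace <- function(dag, category) {
  if (!category %in% names(dag$namespace)) {
    stop("unknown category term: ", category)
  }
  ns <- dag$namespace[[category]]
  if (!category %in% top_level_categories(dag, ns)) {
    stop(category, " is not a top-level category of ", ns)
  }
  ns
}

#' Category hit counts by fractionation-resistance level
#'
#' `Hit(F, C)` counts the homology sets at resistance level `F` whose
#' propagated annotation includes top-level category `C`. Counting is
#' set-level and deduplicated: a set contributes at most 1 per category no
#' matter how many member genes hit it. Only sets annotated in the
#' category's namespace participate.
#'
#' @param sets Homology-set tibble with `F` computed.
#' @param ann An `annotation_map` from [annotate_sets()].
#' @param dag A `go_dag`.
#' @param category Top-level category term id.
#' @return Named integer vector over the F levels present among
#'   participating sets (zero counts included).
#' @export
hit_counts <- function(sets, ann, dag, category) {
  ns <- category_namespace(dag, category)
  part <- sets_in_namespace(sets, ann, ns, dag) & !is.na(sets$F)
  f <- sets$F[part]
  hit <- vapply(ann$set_terms[sets$set_id[part]],
                function(tt) category %in% tt, logical(1))
  levels_f <- sort(unique(f))
  counts <- vapply(levels_f, function(fl) sum(hit[f == fl]), integer(1))
  stats::setNames(counts, levels_f)
}

#' Full hit table for one namespace
#'
#' One row per (top-level category, F level) over the complete grid of
#' categories and F levels observed among the namespace-annotated sets.
#'
#' @inheritParams hit_counts
#' @param namespace GO namespace to tabulate.
#' @return Tibble with columns `namespace`, `category`, `F`, `hits`.
#' @export
category_hit_table <- function(sets, ann, dag, namespace) {
  cats <- top_level_categories(dag, namespace)
  part <- sets_in_namespace(sets, ann, namespace, dag) & !is.na(sets$F)
  f <- sets$F[part]
  terms <- ann$set_terms[sets$set_id[part]]
  levels_f <- sort(unique(f))
  rows <- lapply(cats, function(cc) {
    hit <- vapply(terms, function(tt) cc %in% tt, logical(1))
    tibble::tibble(
      namespace = namespace, category = cc, F = levels_f,
      hits = vapply(levels_f, function(fl) sum(hit[f == fl]), integer(1))
    )
  })
  do.call(rbind, rows)
}

#' Normalized category proportions P(F, C)
#'
#' `P(F, C) = Hit(F, C) / sum over C' of Hit(F, C')`, the sum running over
#' all top-level categories of the same namespace. Because most homology
#' sets fractionate back to single copy, raw hit counts fall steeply with
#' F; the normalized proportions make categories comparable across F.
#' Strata whose total is zero get `P = NA` (missing, not zero).
#'
#' @param hit_table Tibble from [category_hit_table()] (one or more
#'   namespaces).
#' @return `hit_table` with a `P` column added.
#' @export
normalized_proportions <- function(hit_table) {
  key <- interaction(hit_table$namespace, hit_table$F, drop = TRUE)
  totals <- as.vector(tapply(hit_table$hits, key, sum)[key])
  hit_table$P <- ifelse(totals > 0, hit_table$hits / totals, NA_real_)
  hit_table
}

#' Per-gene expression table for stratified analyses
#'
#' Joins the gene index of a homology-set collection with per-gene maximum
#' expression, keeping only genes that have expression data and (when a
#' top-percent filter result is supplied) survive the filter. Genes inherit
#' `F` from their set.
#'
#' @param sets Homology-set tibble with `F` computed.
#' @param per_gene_max Named numeric vector from [max_expression()].
#' @param retained Optional character vector of gene ids surviving
#'   [filter_top_percent()].
#' @param pseudocount Pseudocount for [log_expression()].
#' @return Tibble with columns `gene_id`, `species_id`, `set_id`, `F`,
#'   `max_rpkm`, `log_max`.
#' @export
gene_expression_table <- function(sets, per_gene_max, retained = NULL,
                                  pseudocount = 1) {
  idx <- gene_index(sets)
  keep <- idx$gene_id %in% names(per_gene_max)
  if (!is.null(retained)) keep <- keep & idx$gene_id %in% retained
  idx <- idx[keep, , drop = FALSE]
  idx$max_rpkm <- unname(per_gene_max[idx$gene_id])
  idx$log_max <- log_expression(idx$max_rpkm, pseudocount)
  idx
}

#' Expression profile by fractionation-resistance level
#'
#' For each F stratum of the selected genes: the stratum size, the mean
#' expression `E(F, C)` (arithmetic mean of unlogged post-filter per-gene
#' maximum RPKM), and the expression-bin proportions
#' `P_B(F) = n(bin B, F) / n(F)` computed on the log scale.
#'
#' @param genes Tibble from [gene_expression_table()].
#' @param scheme A [bin_scheme()] spanning the genes' `log_max`.
#' @param ann Optional `annotation_map`, required when `category` is given.
#' @param category Optional top-level category term id restricting the
#'   genes (via their inherited set-level annotation); NULL means all
#'   genes.
#' @return Tibble with columns `category`, `F`, `n`, `E`, and one
#'   `bin_<i>` proportion column per bin. Empty strata are absent
#'   (missing, not zero-filled).
#' @export
expression_profile <- function(genes, scheme, ann = NULL, category = NULL) {
  label <- if (is.null(category)) "all_genes" else category
  if (!is.null(category)) {
    stopifnot(!is.null(ann))
    keep <- vapply(ann$gene_terms[genes$gene_id],
                   function(tt) category %in% tt, logical(1))
    genes <- genes[keep, , drop = FALSE]
  }
  bins <- assign_bins(genes$log_max, scheme)
  levels_f <- sort(unique(genes$F))
  rows <- lapply(levels_f, function(fl) {
    sel <- genes$F == fl
    props <- tabulate(bins[sel] + 1L, nbins = scheme$n_bins) / sum(sel)
    row <- tibble::tibble(category = label, F = fl, n = sum(sel),
                          E = mean(genes$max_rpkm[sel]))
    row[paste0("bin_", seq_len(scheme$n_bins) - 1L)] <- as.list(props)
    row
  })
  if (!length(rows)) {
    out <- tibble::tibble(category = character(0), F = integer(0),
                          n = integer(0), E = numeric(0))
    out[paste0("bin_", seq_len(scheme$n_bins) - 1L)] <-
      rep(list(numeric(0)), scheme$n_bins)
    return(out)
  }
  do.call(rbind, rows)
}

trend_result <- function(category, slope, p_value, n, alpha) {
  verdict <- if (is.na(slope) || is.na(p_value) || p_value >= alpha) {
    "not_significant"
  } else if (slope > 0) "resistant" else if (slope < 0) "prone" else {
    "not_significant"
  }
  tibble::tibble(category = category, slope = slope, p_value = p_value,
                 n = n, verdict = verdict)
}

#' Functional fractionation trend of a category
#'
#' Ordinary least squares of the set-level membership indicator (1 if the
#' set's propagated annotation includes the category, else 0) on F, over
#' all homology sets annotated in the category's namespace — the
#' per-observation regression whose fitted means reproduce the plotted
#' P(F, C) summary points. A category with a significantly positive slope
#' is fractionation-resistant (its share of survivors grows with F); a
#' negative one is fractionation-prone.
#'
#' @inheritParams hit_counts
#' @param alpha Two-sided significance level; default 0.05.
#' @return One-row tibble: `category`, `slope`, `p_value`, `n`, `verdict`
#'   (`resistant`, `prone` or `not_significant`). Degenerate inputs
#'   (constant F or constant membership) give `p_value = 1`.
#' @export
functional_trend_test <- function(sets, ann, dag, category, alpha = 0.05) {
  ns <- category_namespace(dag, category)
  part <- sets_in_namespace(sets, ann, ns, dag) & !is.na(sets$F)
  x <- sets$F[part]
  y <- as.numeric(vapply(ann$set_terms[sets$set_id[part]],
                         function(tt) category %in% tt, logical(1)))
  ols_trend(category, x, y, alpha, cluster = NULL)
}

#' Expression trend of a category across fractionation levels
#'
#' Ordinary least squares of per-gene log expression on F over all
#' (post-filter) genes in the category. Genes of one homology set share a
#' latent expression level and an F value, so standard errors are
#' cluster-robust by homology set by default (`cluster = TRUE`); the slope
#' itself is the plain OLS slope either way.
#'
#' @param genes Tibble from [gene_expression_table()].
#' @param ann Optional `annotation_map` (needed when `category` is given).
#' @param category Optional top-level category term id; NULL means all
#'   genes.
#' @param alpha Two-sided significance level; default 0.05.
#' @param cluster Use set-clustered (CR1) standard errors; default TRUE.
#' @return One-row tibble as in [functional_trend_test()].
#' @export
expression_trend_test <- function(genes, ann = NULL, category = NULL,
                                  alpha = 0.05, cluster = TRUE) {
  label <- if (is.null(category)) "all_genes" else category
  if (!is.null(category)) {
    stopifnot(!is.null(ann))
    keep <- vapply(ann$gene_terms[genes$gene_id],
                   function(tt) category %in% tt, logical(1))
    genes <- genes[keep, , drop = FALSE]
  }
  ols_trend(label, genes$F, genes$log_max, alpha,
            cluster = if (cluster) genes$set_id else NULL)
}

ols_trend <- function(label, x, y, alpha, cluster = NULL) {
  n <- length(x)
  if (n < 3L || length(unique(x)) < 2L || length(unique(y)) < 2L) {
    return(trend_result(label, NA_real_, 1, n, alpha))
  }
  fit <- stats::lm(y ~ x)
  if (is.null(cluster)) {
    co <- summary(fit)$coefficients
  } else {
    vc <- sandwich::vcovCL(fit, cluster = cluster, type = "HC1")
    co <- lmtest::coeftest(fit, vcov. = vc)
  }
  trend_result(label, co["x", 1L], co["x", 4L], n, alpha)
}

#' Logistic model of per-species duplicate retention
#'
#' Estimates the retention model underlying the fractionation pattern: for
#' each homology set and species, the species either kept the duplicate
#' (>= `duplicate_threshold` copies) or collapsed to singleton, modelled as
#' a binomial GLM with logit link on `log10(expression proxy + pseudocount)`
#' plus indicators for the set's top-level categories in one namespace.
#' The expression proxy should approximate the set's underlying expression
#' level; the per-set mean of per-gene tissue-mean RPKM is recommended for
#' model fitting (multiplicative tissue noise nearly cancels in the mean),
#' while the max-over-tissues rule remains the summary for the descriptive
#' profiles.
#'
#' @param sets Homology-set tibble with `F` computed.
#' @param ann `annotation_map` from [annotate_sets()].
#' @param dag A `go_dag`.
#' @param expr Named numeric per-gene expression vector; a set's proxy is
#'   the mean over its member genes present in `expr`. Sets with no
#'   expressed gene, or unannotated in `namespace`, are dropped.
#' @param namespace Namespace whose top-level categories enter the model.
#' @param duplicate_threshold Copy count defining "retained in duplicate".
#' @param pseudocount Pseudocount inside the log10.
#' @return List with `coefficients` (tibble: `term`, `estimate`,
#'   `std_error`, `statistic`, `p_value`; the expression effect is the
#'   `log10_expression` row), `n_sets`, and the fitted `glm` object.
#' @export
fit_retention_model <- function(sets, ann, dag, expr,
                                namespace = "biological_process",
                                duplicate_threshold = 2L, pseudocount = 1) {
  sp <- species_panel(sets)
  part <- sets_in_namespace(sets, ann, namespace, dag)
  idx <- gene_index(sets)
  idx <- idx[idx$gene_id %in% names(expr), , drop = FALSE]
  e_hat <- tapply(unname(expr[idx$gene_id]), idx$set_id, mean)
  part <- part & sets$set_id %in% names(e_hat)
  dat <- sets[part, , drop = FALSE]
  succ <- vapply(dat$members,
                 function(m) sum(lengths(m) >= duplicate_threshold),
                 integer(1))
  x <- log10(unname(e_hat[dat$set_id]) + pseudocount)
  cats <- top_level_categories(dag, namespace)
  cat_mat <- vapply(cats, function(cc) {
    as.numeric(vapply(ann$set_terms[dat$set_id],
                      function(tt) cc %in% tt, logical(1)))
  }, numeric(nrow(dat)))
  colnames(cat_mat) <- paste0("cat_", gsub(":", "_", cats, fixed = TRUE))
  # drop categories with no variation (all-0 or all-1 columns)
  keep_cat <- apply(cat_mat, 2L, function(col) length(unique(col)) > 1L)
  df <- data.frame(log10_expression = x, cat_mat[, keep_cat, drop = FALSE],
                   check.names = FALSE)
  fit <- stats::glm(
    cbind(succ, length(sp) - succ) ~ .,
    family = stats::binomial(), data = df
  )
  co <- summary(fit)$coefficients
  list(
    coefficients = tibble::tibble(
      term = rownames(co), estimate = co[, 1L], std_error = co[, 2L],
      statistic = co[, 3L], p_value = co[, 4L]
    ),
    n_sets = nrow(dat),
    fit = fit
  )
}
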