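toy_analysis <- function() {
  dag <- load_obo(toy_path("ontology.obo"))
  sets <- compute_F(read_homology_sets(toy_path("homology_sets.tsv")))
  hits <- read_gene_annotations(toy_path("annotations.tsv"))
  ann <- annotate_sets(sets, hits, dag)
  list(dag = dag, sets = sets, ann = ann)
}

test_that("hit counting is set-level and deduplicated", {
  t <- toy_analysis()
  # s10 hits "response to stimulus" via gene-level hits on two leaf terms
  # of the same branch and still counts once
  resp <- hit_counts(t$sets, t$ann, t$dag, "GO:0050896")
  expect_equal(resp, c(`1` = 1L, `2` = 3L, `3` = 0L, `4` = 1L))
  met <- hit_counts(t$sets, t$ann, t$dag, "GO:0008152")
  expect_equal(met, c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 0L))
  expect_error(hit_counts(t$sets, t$ann, t$dag, "GO:0006979"),
               "not a top-level category")
  expect_error(hit_counts(t$sets, t$ann, t$dag, "GO:9999999"),
               "unknown category")
  # single-set sanity: one F=2 set hitting a category
  one <- compute_F(homology_sets(
    "solo", list(list(A = c("x1", "x2"), B = "x3"))
  ))
  ann1 <- annotate_sets(one, list(x1 = "GO:1001001", x3 = "GO:1001001"),
                        toy_go_dag())
  expect_equal(hit_counts(one, ann1, toy_go_dag(), "GO:1001000"),
               c(`2` = 1L))
})

test_that("hit counts match the brute-force double loop on random cohorts", {
  set.seed(61)
  for (i in 1:20) {
    mini <- random_mini_cohort(30L)
    ann <- annotate_sets(mini$sets, mini$gene_hits, mini$dag)
    for (cc in top_level_categories(mini$dag, "biological_process")) {
      expect_equal(
        hit_counts(mini$sets, ann, mini$dag, cc),
        oracle_hit_counts(mini$sets, ann$set_terms, mini$dag, cc)
      )
    }
  }
})

test_that("normalized proportions divide by the namespace total per F", {
  t <- toy_analysis()
  tab <- normalized_proportions(
    category_hit_table(t$sets, t$ann, t$dag, "biological_process")
  )
  # hand-normalized worked example
  get_p <- function(cat, f) tab$P[tab$category == cat & tab$F == f]
  expect_equal(get_p("GO:0008152", 1), 0.5)
  expect_equal(get_p("GO:0050896", 2), 0.75)
  expect_equal(get_p("GO:0008152", 3), 1)
  expect_equal(get_p("GO:0050896", 4), 1)
  # one-category namespace: P = 1 wherever populated
  mf <- normalized_proportions(
    category_hit_table(t$sets, t$ann, t$dag, "molecular_function")
  )
  expect_true(all(mf$P[mf$hits > 0] == 1))
  # zero-total strata are missing, not zero
  cc <- normalized_proportions(
    category_hit_table(t$sets, t$ann, t$dag, "cellular_component")
  )
  expect_equal(nrow(cc), 0L)

  # symmetry: two categories with equal hits split 50/50
  sym <- tibble::tibble(namespace = "biological_process",
                        category = rep(c("c1", "c2"), each = 2),
                        F = rep(1:2, 2), hits = c(3L, 5L, 3L, 5L))
  expect_equal(normalized_proportions(sym)$P, rep(0.5, 4))
})

test_that("P(F, C) is invariant to duplicating every homology set", {
  set.seed(71)
  mini <- random_mini_cohort(25L)
  ann <- annotate_sets(mini$sets, mini$gene_hits, mini$dag)
  tab1 <- normalized_proportions(
    category_hit_table(mini$sets, ann, mini$dag, "biological_process")
  )
  k <- 3L
  big <- mini$sets[rep(seq_len(nrow(mini$sets)), k), ]
  big$set_id <- paste0(big$set_id, "_", rep(seq_len(k), each = nrow(mini$sets)))
  st <- rep(ann$set_terms, k)
  names(st) <- big$set_id
  ann_big <- structure(list(set_terms = st, gene_terms = ann$gene_terms),
                       class = "annotation_map")
  tab_k <- normalized_proportions(
    category_hit_table(big, ann_big, mini$dag, "biological_process")
  )
  expect_equal(tab_k$hits, k * tab1$hits)
  expect_equal(tab_k$P, tab1$P)
})

test_that("E(F, C) is the plain mean of per-gene maxima in the stratum", {
  t <- toy_analysis()
  pgm <- max_expression(read_expression(toy_path("expression.tsv")))
  genes <- gene_expression_table(t$sets, pgm)
  scheme <- bin_scheme(genes$log_max, n_bins = 8L)
  prof <- expression_profile(genes, scheme)
  # hand-computed stratum means of maxima
  expect_equal(prof$E[prof$F == 1], 7)       # (1 + 8 + 12) / 3
  expect_equal(prof$E[prof$F == 2], 5.6)     # (7 + 2 + 9 + 6 + 4) / 5
  expect_equal(prof$E[prof$F == 3], 2)       # (4 + 0) / 2
  expect_equal(prof$E[prof$F == 4], 17.5)    # (30 + 5) / 2
  expect_equal(prof$n, c(3L, 5L, 2L, 2L))
  # the zero-RPKM gene sits alone with s02A1 in stratum F = 3; only it
  # lands in the lowest expression block
  expect_equal(prof$bin_0[prof$F == 3], 0.5)
  # per-stratum bin proportions sum to one
  bins <- as.matrix(prof[, grep("^bin_", names(prof))])
  expect_equal(unname(rowSums(bins)), rep(1, nrow(prof)))
  # single-gene and two-gene strata behave as simple averages
  solo <- genes[genes$gene_id %in% c("s04A1"), ]
  expect_equal(expression_profile(solo, scheme)$E, 1)
})

test_that("stratum means match a brute-force group mean on random cohorts", {
  set.seed(83)
  for (i in 1:10) {
    mini <- random_mini_cohort(40L)
    genes <- gene_expression_table(mini$sets, mini$expr)
    if (!nrow(genes)) next
    scheme <- bin_scheme(genes$log_max, n_bins = 5L)
    prof <- expression_profile(genes, scheme)
    for (f in prof$F) {
      expect_equal(prof$E[prof$F == f],
                   mean(genes$max_rpkm[genes$F == f]))
    }
    expect_equal(sum(prof$n), nrow(genes))
  }
})

test_that("trend verdicts follow slope sign and significance", {
  set.seed(5)
  dag <- toy_go_dag()
  # construction: membership strictly increasing with F
  n <- 120L
  f <- rep(1:4, each = n / 4)
  member <- stats::runif(n) < (f / 5)
  dup <- function(i, sp, yes) {
    paste0("c", i, "_", sp, seq_len(if (yes) 2L else 1L))
  }
  sets <- homology_sets(sprintf("c%03d", 1:n),
                        lapply(seq_len(n), function(i) {
                          list(A = dup(i, "a", f[i] >= 2L),
                               B = dup(i, "b", f[i] >= 3L),
                               C = dup(i, "c", f[i] >= 4L))
                        }))
  sets <- compute_F(sets)
  expect_identical(sets$F, f)
  hits <- lapply(seq_len(n), function(i) {
    if (member[i]) c("GO:1001001") else c("GO:1002001")
  })
  names(hits) <- vapply(sets$members, function(m) m$A[1], character(1))
  ann <- annotate_sets(sets, hits, dag)
  res <- functional_trend_test(sets, ann, dag, "GO:1001000")
  expect_gt(res$slope, 0)
  expect_equal(res$verdict, "resistant")

  # genes with log-expression strictly increasing in F
  genes <- tibble::tibble(
    gene_id = paste0("g", 1:80), set_id = paste0("s", 1:80),
    F = rep(1:4, each = 20),
    max_rpkm = NA_real_, log_max = rep(1:4, each = 20) + rnorm(80, 0, 0.1)
  )
  et <- expression_trend_test(genes)
  expect_gt(et$slope, 0)
  expect_equal(et$verdict, "resistant")
})

test_that("degenerate regressions report p = 1 and no verdict", {
  genes <- tibble::tibble(gene_id = paste0("g", 1:10),
                          set_id = paste0("s", 1:10),
                          F = rep(2L, 10), max_rpkm = 1:10,
                          log_max = log10(1:10 + 1))
  res <- expression_trend_test(genes) # constant F
  expect_equal(res$p_value, 1)
  expect_equal(res$verdict, "not_significant")
  cc_dag <- toy_go_dag()
  # constant membership: nobody hits the category
  sets <- compute_F(homology_sets(
    c("d1", "d2", "d3", "d4"),
    list(list(A = c("q1", "q2")), list(A = "q3"), list(A = "q4"),
         list(A = c("q5", "q6")))
  ))
  ann <- annotate_sets(sets, list(q1 = "GO:1001001", q3 = "GO:1001001",
                                  q4 = "GO:1001001", q5 = "GO:1001001"),
                       cc_dag)
  res2 <- functional_trend_test(sets, ann, cc_dag, "GO:1002000")
  expect_equal(res2$p_value, 1)
  expect_equal(res2$verdict, "not_significant")
})

test_that("the retention GLM recovers the generative effects", {
  cfg <- simulation_config(n_sets = 1500L, seed = 424)
  co <- simulate_cohort(cfg)
  sets <- compute_F(co$sets)
  ann <- annotate_sets(sets, co$gene_hits, co$dag)
  fit <- fit_retention_model(sets, ann, co$dag,
                             expr = rowMeans(co$expression))
  co_tab <- fit$coefficients
  b <- co_tab[co_tab$term == "log10_expression", ]
  expect_lt(abs(b$estimate - cfg$expression_effect), 3 * b$std_error)
  a_res <- co_tab[co_tab$term == "cat_GO_1002000", ]
  expect_gt(a_res$estimate, 0)
  a_pro <- co_tab[co_tab$term == "cat_GO_1001000", ]
  expect_lt(a_pro$estimate, 0)
})
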