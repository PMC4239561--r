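# Forward simulator of duplicate retention after a whole-genome doubling:
# homology sets over a small species panel, category- and
# expression-dependent per-species loss, log-normal expression with
# per-tissue noise, and a toy three-namespace GO DAG. Emits the exact file
# dialects the reader functions consume, so every pipeline stage is
# testable without external data.

#' Build a small three-namespace GO DAG for simulation
#'
#' Each namespace gets one root, `n_categories` top-level categories and
#' `leaves_per_category` leaf terms under each category (depth 3). The
#' second leaf of every category attaches via `part_of`, the rest via
#' `is_a`, so both propagation relations are exercised.
#'
#' @param n_categories Top-level categories per namespace; default 4.
#' @param leaves_per_category Leaf terms per category; default 2.
#' @return A `go_dag`.
#' @export
toy_go_dag <- function(n_categories = 4L, leaves_per_category = 2L) {
  ns_labels <- c("biological-like process", "cellular-like component",
                 "molecular-like function")
  name <- character(0); namespace <- character(0)
  parents <- list(); partof <- list()
  for (i in seq_along(GO_NAMESPACES)) {
    root <- sprintf("GO:%d000000", i)
    name[root] <- ns_labels[i]
    namespace[root] <- GO_NAMESPACES[i]
    parents[[root]] <- character(0)
    partof[[root]] <- character(0)
    for (j in seq_len(n_categories)) {
      cat_id <- sprintf("GO:%d00%d000", i, j)
      name[cat_id] <- sprintf("%s category %d", GO_NAMESPACES[i], j)
      namespace[cat_id] <- GO_NAMESPACES[i]
      parents[[cat_id]] <- root
      partof[[cat_id]] <- character(0)
      for (k in seq_len(leaves_per_category)) {
        leaf <- sprintf("GO:%d00%d00%d", i, j, k)
        name[leaf] <- sprintf("%s leaf %d.%d", GO_NAMESPACES[i], j, k)
        namespace[leaf] <- GO_NAMESPACES[i]
        parents[[leaf]] <- cat_id
        partof[[leaf]] <- if (k == 2L) cat_id else character(0)
      }
    }
  }
  new_go_dag(name, namespace, parents, partof)
}

#' Simulation configuration for a synthetic fractionation cohort
#'
#' Defaults describe the study conditions the package is validated under:
#' three species descended from one doubling event (each set starts with
#' two copies per species), per-species independent loss with retention
#' probability `plogis(baseline_retention + sum of category effects +
#' expression_effect * log10(e + 1))`, latent per-set RPKM `e` drawn
#' log-normal, and multiplicative log-normal tissue noise.
#'
#' @param n_sets Number of homology sets; default 2000.
#' @param species Species panel; default three species.
#' @param n_categories,leaves_per_category Passed to [toy_go_dag()].
#' @param category_effects Named numeric: retention log-odds offsets for
#'   top-level category term ids. The default makes biological-process
#'   category 2 resistant (+1, a "response to stimulus"-like class) and
#'   category 1 prone (-1, a "metabolic process"-like class).
#' @param expression_effect Retention log-odds per unit log10(RPKM + 1);
#'   default 0.8.
#' @param baseline_retention Retention log-odds at zero expression outside
#'   any offset category; default -2 (most sets return to singleton, as in
#'   real panels).
#' @param meanlog,sdlog Log-normal parameters of latent per-set RPKM;
#'   defaults 2 and 1.5 (median ~7 RPKM with a heavy right tail).
#' @param n_tissues Tissues/conditions in the emitted expression matrix;
#'   default 6.
#' @param tissue_noise_sd SD of multiplicative log-normal tissue noise (on
#'   the natural-log scale); default 0.3.
#' @param min_hits,max_hits Range of leaf-term annotations per set;
#'   default 1 to 3.
#' @param seed Integer seed; fully determines the cohort.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_sets = 2000L,
                              species = c("spA", "spB", "spC"),
                              n_categories = 4L,
                              leaves_per_category = 2L,
                              category_effects = c("GO:1002000" = 1,
                                                   "GO:1001000" = -1),
                              expression_effect = 0.8,
                              baseline_retention = -2,
                              meanlog = 2,
                              sdlog = 1.5,
                              n_tissues = 6L,
                              tissue_noise_sd = 0.3,
                              min_hits = 1L,
                              max_hits = 3L,
                              seed = 1L) {
  stopifnot(n_sets >= 1L, sdlog > 0, tissue_noise_sd >= 0,
            min_hits >= 1L, max_hits >= min_hits, length(species) >= 1L)
  structure(
    list(n_sets = as.integer(n_sets), species = species,
         n_categories = as.integer(n_categories),
         leaves_per_category = as.integer(leaves_per_category),
         category_effects = category_effects,
         expression_effect = expression_effect,
         baseline_retention = baseline_retention,
         meanlog = meanlog, sdlog = sdlog,
         n_tissues = as.integer(n_tissues),
         tissue_noise_sd = tissue_noise_sd,
         min_hits = as.integer(min_hits), max_hits = as.integer(max_hits),
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Simulate a synthetic fractionation cohort
#'
#' For each homology set: draw 1-3 leaf-term annotations (their top-level
#' ancestors define the set's categories), a latent expression level, and
#' per-species independent duplicate retention with probability
#' `plogis(alpha0 + sum(alpha_C) + beta * log10(e + 1))`; a species that
#' loses the duplicate collapses to a single copy. Every retained gene gets
#' per-tissue RPKM equal to the set's latent level times multiplicative
#' log-normal noise, and each direct leaf annotation is attached to one
#' randomly chosen member gene (set-level propagation must recover it).
#'
#' @param config A [simulation_config()].
#' @return A `synthetic_cohort`: list with `sets` (homology-set tibble, `F`
#'   unset), `expression` (gene x tissue RPKM matrix), `gene_hits` (direct
#'   gene annotations), `dag`, `truth` (per-set latent level, retention
#'   probability, realized F and categories) and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_sets
  sp <- config$species
  s <- length(sp)
  dag <- toy_go_dag(config$n_categories, config$leaves_per_category)
  has_child <- unique(unlist(dag$parents, use.names = FALSE))
  leaves <- sort(setdiff(names(dag$name), has_child))
  leaf_cats <- lapply(leaves, function(l) {
    anc <- ancestors(dag, l)
    intersect(anc, top_level_categories(dag, dag$namespace[[l]]))
  })
  names(leaf_cats) <- leaves

  set_id <- sprintf("HS%05d", seq_len(n))
  n_hits <- sample(seq.int(config$min_hits, config$max_hits), n,
                   replace = TRUE)
  hits <- lapply(n_hits, function(k) sample(leaves, k))
  eff <- config$category_effects
  alpha_sum <- vapply(hits, function(tt) {
    cats <- unique(unlist(leaf_cats[tt], use.names = FALSE))
    sum(eff[intersect(cats, names(eff))])
  }, numeric(1))

  e <- stats::rlnorm(n, config$meanlog, config$sdlog)
  p_retain <- stats::plogis(
    config$baseline_retention + alpha_sum +
      config$expression_effect * log10(e + 1)
  )
  retain <- matrix(stats::runif(n * s) < p_retain, nrow = n)

  a_ids <- outer(set_id, sp, function(si, pj) paste0(si, "_", pj, "_a"))
  b_ids <- outer(set_id, sp, function(si, pj) paste0(si, "_", pj, "_b"))
  members <- vector("list", n)
  for (i in seq_len(n)) {
    m <- vector("list", s)
    names(m) <- sp
    for (j in seq_len(s)) {
      m[[j]] <- if (retain[i, j]) c(a_ids[i, j], b_ids[i, j]) else a_ids[i, j]
    }
    members[[i]] <- m
  }

  # direct hits go on one random member gene each
  picks <- vector("list", n)
  for (i in seq_len(n)) {
    g <- unlist(members[[i]], use.names = FALSE)
    picks[[i]] <- g[sample.int(length(g), length(hits[[i]]),
                               replace = TRUE)]
  }
  gene_hits_gene <- unlist(picks, use.names = FALSE)
  gene_hits_term <- unlist(hits, use.names = FALSE)
  gene_hits <- lapply(
    split(gene_hits_term, gene_hits_gene)[unique(gene_hits_gene)], unique
  )

  all_genes <- unlist(members, use.names = FALSE)
  genes_per_set <- vapply(members, function(m) sum(lengths(m)), integer(1))
  e_gene <- rep(e, genes_per_set)
  tt <- config$n_tissues
  expr <- e_gene * matrix(
    exp(stats::rnorm(length(all_genes) * tt, 0, config$tissue_noise_sd)),
    nrow = length(all_genes)
  )
  dimnames(expr) <- list(all_genes, paste0("tissue", seq_len(tt)))

  truth <- tibble::tibble(
    set_id = set_id,
    latent_rpkm = e,
    p_retain = p_retain,
    F_true = as.integer(rowSums(retain)) + 1L,
    categories = vapply(hits, function(tth) {
      paste(sort(unique(unlist(leaf_cats[tth], use.names = FALSE))),
            collapse = ",")
    }, character(1))
  )

  structure(
    list(sets = homology_sets(set_id, members, species = sp),
         expression = expr, gene_hits = gene_hits, dag = dag,
         truth = truth, config = config),
    class = "synthetic_cohort"
  )
}

fmt_num <- function(x) {
  formatC(x, digits = 17, format = "g")
}

#' Write a synthetic cohort as pipeline input files
#'
#' Emits `homology_sets.tsv`, `annotations.tsv`, `expression.tsv` and
#' `ontology.obo` in the dialects the reader functions consume, plus a
#' `truth.tsv` sidecar of generative parameters. Numeric cells carry full
#' double precision, so files from one seed are byte-identical across
#' runs and round-trip exactly through the readers.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- species_panel(cohort$sets)

  cells <- vapply(cohort$sets$members, function(m) {
    paste(vapply(m[sp], paste, character(1), collapse = ","), collapse = "\t")
  }, character(1))
  writeLines(
    c(paste(c("set_id", sp), collapse = "\t"),
      paste(cohort$sets$set_id, cells, sep = "\t")),
    file.path(dir, "homology_sets.tsv")
  )

  gh <- cohort$gene_hits
  writeLines(
    paste(rep(names(gh), lengths(gh)), unlist(gh, use.names = FALSE),
          sep = "\t"),
    file.path(dir, "annotations.tsv")
  )

  ex <- cohort$expression
  writeLines(
    c(paste(c("gene_id", colnames(ex)), collapse = "\t"),
      paste(rownames(ex),
            apply(ex, 1L, function(r) paste(fmt_num(r), collapse = "\t")),
            sep = "\t")),
    file.path(dir, "expression.tsv")
  )

  write_obo(cohort$dag, file.path(dir, "ontology.obo"))

  tr <- cohort$truth
  writeLines(
    c("set_id\tlatent_rpkm\tp_retain\tF_true\tcategories",
      paste(tr$set_id, fmt_num(tr$latent_rpkm), fmt_num(tr$p_retain),
            tr$F_true, tr$categories, sep = "\t")),
    file.path(dir, "truth.tsv")
  )
  invisible(dir)
}

#' Ground-truth report of a simulated cohort
#'
#' One row per top-level category of the effect namespace: the true
#' retention log-odds offset, the number of sets carrying the category,
#' and the realized per-species duplicate-retention rate among them.
#' Categories with no assigned set are flagged missing. The generative
#' expression effect is repeated in the `beta` column.
#'
#' @param cohort A `synthetic_cohort`.
#' @param namespace Namespace whose categories are reported; default
#'   biological_process.
#' @return Tibble: `category`, `alpha`, `n_sets`, `retention_rate`,
#'   `missing`, `beta`.
#' @export
ground_truth_report <- function(cohort, namespace = "biological_process") {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  cats <- top_level_categories(cohort$dag, namespace)
  eff <- cohort$config$category_effects
  set_cats <- strsplit(cohort$truth$categories, ",", fixed = TRUE)
  f_true <- cohort$truth$F_true
  s <- length(species_panel(cohort$sets))
  rows <- lapply(cats, function(cc) {
    in_cat <- vapply(set_cats, function(x) cc %in% x, logical(1))
    n_cc <- sum(in_cat)
    tibble::tibble(
      category = cc,
      alpha = if (cc %in% names(eff)) unname(eff[[cc]]) else 0,
      n_sets = n_cc,
      retention_rate = if (n_cc) mean((f_true[in_cat] - 1L) / s) else
        NA_real_,
      missing = n_cc == 0L,
      beta = cohort$config$expression_effect
    )
  })
  do.call(rbind, rows)
}
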