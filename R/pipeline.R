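# End-to-end orchestration: read (or simulate) the four inputs, compute F,
# propagate annotation, reduce and filter expression, tabulate the summary
# statistics and trend tests, and write deterministic tidy output tables
# plus a machine-readable manifest.

#' Run configuration for the fractionation pipeline
#'
#' Exactly one of the real-input paths block (`homology`, `obo`,
#' `annotations`, `expression`) or `simulation` must be given.
#'
#' @param homology,obo,annotations,expression Paths to the four input
#'   files (real mode).
#' @param simulation A [simulation_config()] (synthetic mode).
#' @param duplicate_threshold Copy count defining "in duplicate".
#' @param filter_percent Top-expression percentage removed; default 1.
#' @param n_bins Expression bins; default 8.
#' @param pseudocount Log pseudocount; default 1.
#' @param alpha Significance level for trend verdicts; default 0.05.
#' @param outdir Output directory.
#' @param seed Integer seed; in synthetic mode overrides the simulation
#'   config's seed so one value drives the whole run.
#' @return A `run_config` list.
#' @export
run_config <- function(homology = NULL, obo = NULL, annotations = NULL,
                       expression = NULL, simulation = NULL,
                       duplicate_threshold = 2L, filter_percent = 1,
                       n_bins = 8L, pseudocount = 1, alpha = 0.05,
                       outdir = "fracres_out", seed = 1L) {
  real <- !vapply(list(homology, obo, annotations, expression), is.null,
                  logical(1))
  if (!is.null(simulation) && any(real)) {
    stop("give either input paths or a simulation config, not both")
  }
  if (is.null(simulation) && !all(real)) {
    stop("real mode needs all four input paths ",
         "(homology, obo, annotations, expression)")
  }
  if (!is.null(simulation)) {
    stopifnot(inherits(simulation, "simulation_config"))
    simulation$seed <- as.integer(seed)
  }
  structure(
    list(homology = homology, obo = obo, annotations = annotations,
         expression = expression, simulation = simulation,
         duplicate_threshold = as.integer(duplicate_threshold),
         filter_percent = filter_percent, n_bins = as.integer(n_bins),
         pseudocount = pseudocount, alpha = alpha, outdir = outdir,
         seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Read a run configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [run_config()]; a `simulation`
#' mapping is passed to [simulation_config()].
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
run_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulation)) {
    y$simulation <- do.call(simulation_config, y$simulation)
  }
  do.call(run_config, y)
}

with_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Analyze a cohort held in memory
#'
#' The computational core of [run_pipeline()]: computes F, propagates
#' annotation, reduces expression to per-gene maxima, applies the
#' top-percent filter, and produces the normalized category profiles,
#' per-F expression profiles, and functional plus expression trend tests
#' for every top-level category of every namespace present.
#'
#' @param sets Homology-set tibble (F may be unset).
#' @param gene_hits Named list of direct gene annotations.
#' @param dag A `go_dag`.
#' @param expression Gene x condition RPKM matrix.
#' @param duplicate_threshold,filter_percent,n_bins,pseudocount,alpha See
#'   [run_config()].
#' @return List: `sets` (with F), `annotation`, `genes` (post-filter gene
#'   table), `scheme`, `category_profiles`, `expression_profiles`,
#'   `trend_results`, `f_counts`.
#' @export
analyze_cohort <- function(sets, gene_hits, dag, expression,
                           duplicate_threshold = 2L, filter_percent = 1,
                           n_bins = 8L, pseudocount = 1, alpha = 0.05) {
  sets <- compute_F(sets, duplicate_threshold)
  ann <- annotate_sets(sets, gene_hits, dag)
  pgm <- max_expression(expression)
  filt <- filter_top_percent(pgm, filter_percent)
  genes <- gene_expression_table(sets, pgm, retained = filt$retained,
                                 pseudocount = pseudocount)
  scheme <- bin_scheme(genes$log_max, n_bins = n_bins)

  namespaces <- intersect(GO_NAMESPACES, names(dag$roots))
  cat_prof <- do.call(rbind, lapply(namespaces, function(ns) {
    normalized_proportions(category_hit_table(sets, ann, dag, ns))
  }))

  expr_prof <- expression_profile(genes, scheme)
  fun_trends <- list()
  expr_trends <- list(all_genes = cbind(
    tibble::tibble(namespace = NA_character_, kind = "expression"),
    expression_trend_test(genes, alpha = alpha)
  ))
  for (ns in namespaces) {
    for (cc in top_level_categories(dag, ns)) {
      fun_trends[[cc]] <- cbind(
        tibble::tibble(namespace = ns, kind = "functional"),
        functional_trend_test(sets, ann, dag, cc, alpha = alpha)
      )
      expr_prof <- rbind(expr_prof,
                         expression_profile(genes, scheme, ann, cc))
      expr_trends[[cc]] <- cbind(
        tibble::tibble(namespace = ns, kind = "expression"),
        expression_trend_test(genes, ann, cc, alpha = alpha)
      )
    }
  }
  trend_results <- rbind(
    do.call(rbind, unname(fun_trends)),
    do.call(rbind, unname(expr_trends))
  )
  f_counts <- as.data.frame(table(F = sets$F), stringsAsFactors = FALSE)
  f_counts <- tibble::tibble(F = as.integer(f_counts$F),
                             n_sets = as.integer(f_counts$Freq))

  list(sets = sets, annotation = ann, dag = dag, genes = genes,
       scheme = scheme,
       category_profiles = cat_prof, expression_profiles = expr_prof,
       trend_results = trend_results, f_counts = f_counts,
       filter = filt)
}

write_tsv_det <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], fmt_num)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
}

#' Run the full fractionation-resistance pipeline
#'
#' Stages: load (or simulate and re-read) the four inputs, compute F,
#' propagate GO annotation, reduce/filter/bin expression, compute the
#' summary statistics and trend tests, and write
#' `category_profiles.tsv`, `expression_profiles.tsv`,
#' `trend_results.tsv`, `f_counts.tsv` and `manifest.json` (all
#' parameters, seed and input checksums) to the output directory. In
#' synthetic mode the simulated inputs are first written under
#' `<outdir>/inputs/` and then read back through the regular readers, so
#' a synthetic run exercises the same path as a real one. Identical
#' config and inputs produce byte-identical outputs; any stage error
#' aborts with a stage-tagged message and removes partial outputs.
#'
#' @param config A [run_config()].
#' @return Invisibly, the [analyze_cohort()] result list, with
#'   `outdir` attached.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  outdir <- config$outdir
  created <- !dir.exists(outdir)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  outputs <- file.path(outdir, c("category_profiles.tsv",
                                 "expression_profiles.tsv",
                                 "trend_results.tsv", "f_counts.tsv",
                                 "manifest.json", "run.log"))
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, paste0(...))
  on_fail_cleanup <- function() {
    unlink(outputs[file.exists(outputs)])
    if (!is.null(config$simulation)) {
      unlink(file.path(outdir, "inputs"), recursive = TRUE)
    }
    if (created) unlink(outdir, recursive = TRUE)
  }
  tryCatch({
    if (!is.null(config$simulation)) {
      cohort <- with_stage("simulate", simulate_cohort(config$simulation))
      indir <- file.path(outdir, "inputs")
      with_stage("simulate", write_cohort(cohort, indir))
      paths <- list(
        homology = file.path(indir, "homology_sets.tsv"),
        obo = file.path(indir, "ontology.obo"),
        annotations = file.path(indir, "annotations.tsv"),
        expression = file.path(indir, "expression.tsv")
      )
      note("stage simulate: ", config$simulation$n_sets,
           " sets, seed ", config$simulation$seed)
    } else {
      paths <- config[c("homology", "obo", "annotations", "expression")]
    }
    for (p in paths) {
      if (!file.exists(p)) stop("[stage read] input file missing: ", p,
                                call. = FALSE)
    }
    sets <- with_stage("read", read_homology_sets(paths$homology))
    dag <- with_stage("read", load_obo(paths$obo))
    gene_hits <- with_stage("read", read_gene_annotations(paths$annotations))
    expr <- with_stage("read", read_expression(paths$expression))
    note("stage read: ", nrow(sets), " sets, ", length(dag$name),
         " GO terms, ", nrow(expr), " expressed genes")

    res <- with_stage("analyze", analyze_cohort(
      sets, gene_hits, dag, expr,
      duplicate_threshold = config$duplicate_threshold,
      filter_percent = config$filter_percent, n_bins = config$n_bins,
      pseudocount = config$pseudocount, alpha = config$alpha
    ))
    note("stage analyze: removed ", length(res$filter$removed),
         " genes by top-", config$filter_percent, "% filter")

    with_stage("write", {
      write_tsv_det(res$category_profiles, outputs[1L])
      write_tsv_det(res$expression_profiles, outputs[2L])
      write_tsv_det(res$trend_results, outputs[3L])
      write_tsv_det(res$f_counts, outputs[4L])
      manifest <- list(
        parameters = config[c("duplicate_threshold", "filter_percent",
                              "n_bins", "pseudocount", "alpha", "seed")],
        mode = if (is.null(config$simulation)) "real" else "synthetic",
        simulation = if (is.null(config$simulation)) NULL else
          unclass(config$simulation),
        input_md5 = as.list(stats::setNames(
          unname(tools::md5sum(unlist(paths))), basename(unlist(paths))
        )),
        output_tables = basename(outputs[1:4])
      )
      jsonlite::write_json(manifest, outputs[5L], auto_unbox = TRUE,
                           digits = NA, pretty = TRUE, null = "null")
      note("stage write: 4 tables + manifest")
      writeLines(log_lines, outputs[6L])
    })
    res$outdir <- outdir
    invisible(res)
  }, error = function(e) {
    on_fail_cleanup()
    stop(e)
  })
}

#' Summarize a pipeline output directory
#'
#' Reads the result tables back and reports homology-set counts per
#' fractionation level and the lists of fractionation-resistant and
#' fractionation-prone categories. Never alters the analysis tables.
#'
#' @param outdir Directory written by [run_pipeline()].
#' @param quiet Suppress printing; default FALSE.
#' @return List with `f_counts`, `resistant`, `prone`,
#'   `not_significant` (functional verdicts) and `expression_trends`.
#' @export
report_run <- function(outdir, quiet = FALSE) {
  need <- file.path(outdir, c("category_profiles.tsv",
                              "expression_profiles.tsv",
                              "trend_results.tsv", "f_counts.tsv"))
  miss <- need[!file.exists(need)]
  if (length(miss)) stop("missing output table: ", basename(miss)[1L])
  trends <- utils::read.delim(need[3L], sep = "\t")
  f_counts <- utils::read.delim(need[4L], sep = "\t")
  fun <- trends[trends$kind == "functional", , drop = FALSE]
  out <- list(
    f_counts = tibble::as_tibble(f_counts),
    resistant = fun$category[fun$verdict == "resistant"],
    prone = fun$category[fun$verdict == "prone"],
    not_significant = fun$category[fun$verdict == "not_significant"],
    expression_trends = tibble::as_tibble(
      trends[trends$kind == "expression", , drop = FALSE]
    )
  )
  if (!quiet) {
    cat("Homology sets per fractionation-resistance level:\n")
    for (i in seq_len(nrow(f_counts))) {
      cat(sprintf("  F = %d: %d sets\n", f_counts$F[i], f_counts$n_sets[i]))
    }
    cat("Fractionation-resistant categories: ",
        paste(out$resistant, collapse = ", "), "\n", sep = "")
    cat("Fractionation-prone categories: ",
        paste(out$prone, collapse = ", "), "\n", sep = "")
  }
  invisible(out)
}
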