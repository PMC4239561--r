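# Independent brute-force oracles and random-instance generators shared by
# the unit and acceptance suites. Oracles deliberately use a different
# style (explicit loops, igraph reachability) from the implementation.

oracle_F <- function(members, threshold = 2L) {
  n <- 0L
  for (sp in names(members)) {
    if (length(members[[sp]]) >= threshold) n <- n + 1L
  }
  n + 1L
}

random_members <- function(n_species = 3L, max_copies = 3L,
                           prefix = "g") {
  sp <- paste0("sp", seq_len(n_species))
  m <- lapply(seq_len(n_species), function(j) {
    k <- sample(0:max_copies, 1L)
    if (k == 0L) character(0) else paste0(prefix, "_", sp[j], "_", seq_len(k))
  })
  names(m) <- sp
  m
}

# reachability oracle over parent edges (child -> parent), via igraph
oracle_ancestors <- function(dag, term_id) {
  edges <- do.call(rbind, lapply(names(dag$parents), function(id) {
    if (length(dag$parents[[id]])) cbind(id, dag$parents[[id]])
  }))
  g <- igraph::graph_from_data_frame(
    as.data.frame(edges, stringsAsFactors = FALSE),
    vertices = names(dag$name)
  )
  sort(names(igraph::subcomponent(g, term_id, mode = "out")))
}

# random single-namespace DAG built directly; node i > 1 picks 1-2 parents
# among nodes 1..(i-1), so acyclicity holds by construction
random_dag <- function(n_terms) {
  ids <- sprintf("GO:%07d", seq_len(n_terms))
  parents <- vector("list", n_terms)
  parents[[1L]] <- character(0)
  for (i in seq_len(n_terms)[-1L]) {
    k <- sample(1:min(2L, i - 1L), 1L)
    parents[[i]] <- sample(ids[seq_len(i - 1L)], k)
  }
  names(parents) <- ids
  fracres:::new_go_dag(
    stats::setNames(paste("term", seq_len(n_terms)), ids),
    stats::setNames(rep("biological_process", n_terms), ids),
    parents
  )
}

# igraph reachability for every term, graph built once
oracle_all_ancestors <- function(dag) {
  edges <- do.call(rbind, lapply(names(dag$parents), function(id) {
    if (length(dag$parents[[id]])) cbind(id, dag$parents[[id]])
  }))
  g <- igraph::graph_from_data_frame(
    as.data.frame(edges, stringsAsFactors = FALSE),
    vertices = names(dag$name)
  )
  out <- lapply(names(dag$name), function(id) {
    sort(names(igraph::subcomponent(g, id, mode = "out")))
  })
  names(out) <- names(dag$name)
  out
}

# nested-loop propagation oracle: union over member genes of ancestor
# closures of their direct hits
oracle_set_terms <- function(sets, gene_hits, dag) {
  anc <- oracle_all_ancestors(dag)
  out <- list()
  for (i in seq_len(nrow(sets))) {
    terms <- character(0)
    for (sp in names(sets$members[[i]])) {
      for (g in sets$members[[i]][[sp]]) {
        for (t in gene_hits[[g]]) {
          terms <- union(terms, anc[[t]])
        }
      }
    }
    out[[sets$set_id[i]]] <- sort(terms)
  }
  out
}

oracle_hit_counts <- function(sets, set_terms, dag, category) {
  ns <- dag$namespace[[category]]
  ns_terms <- names(dag$namespace)[dag$namespace == ns]
  counts <- integer(0)
  for (i in seq_len(nrow(sets))) {
    tt <- set_terms[[sets$set_id[i]]]
    if (!any(tt %in% ns_terms)) next # not annotated in this namespace
    f <- as.character(sets$F[i])
    if (is.na(counts[f])) counts[f] <- 0L
    if (category %in% tt) counts[f] <- counts[f] + 1L
  }
  counts[order(as.integer(names(counts)))]
}

# small random cohort for the statistics oracles: a toy DAG plus random
# membership, F, and expression
random_mini_cohort <- function(n_sets = 20L, n_species = 3L) {
  dag <- toy_go_dag(n_categories = 3L, leaves_per_category = 2L)
  has_child <- unique(unlist(dag$parents, use.names = FALSE))
  leaves <- sort(setdiff(names(dag$name), has_child))
  ids <- sprintf("m%03d", seq_len(n_sets))
  members <- lapply(ids, function(id)
    random_members(n_species, prefix = id))
  # force global gene uniqueness via the per-set prefix
  sets <- homology_sets(ids, members)
  sets <- compute_F(sets)
  idx <- gene_index(sets)
  gene_hits <- list()
  if (nrow(idx)) {
    annotated <- idx$gene_id[stats::runif(nrow(idx)) < 0.6]
    gene_hits <- lapply(
      stats::setNames(annotated, annotated),
      function(g) sample(leaves, sample(1:2, 1L))
    )
  }
  expr <- stats::setNames(round(stats::rlnorm(nrow(idx), 1, 1), 4),
                          idx$gene_id)
  list(sets = sets, gene_hits = gene_hits, dag = dag, expr = expr)
}

toy_path <- function(file) {
  system.file("extdata", "toy", file, package = "fracres", mustWork = TRUE)
}
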