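# Gene Ontology support: OBO parsing, the term DAG, ancestor closure
# ("true-path" propagation), and homology-set level annotation.

GO_NAMESPACES <- c("biological_process", "cellular_component",
                   "molecular_function")

new_go_dag <- function(name, namespace, parents, partof = NULL) {
  ids <- names(name)
  stopifnot(identical(ids, names(namespace)), identical(ids, names(parents)))
  if (length(bad <- setdiff(unique(namespace), GO_NAMESPACES))) {
    stop("unknown GO namespace: ", paste(bad, collapse = ", "))
  }
  if (length(bad <- setdiff(unlist(parents, use.names = FALSE), ids))) {
    stop("parent term not defined: ", paste(unique(bad), collapse = ", "))
  }
  for (id in ids) {
    if (id %in% parents[[id]]) stop("self-referential parent: ", id)
    pns <- namespace[parents[[id]]]
    if (length(pns) && any(pns != namespace[[id]])) {
      stop("parent edge crosses namespaces at term ", id)
    }
  }
  assert_acyclic(parents)
  rootless <- ids[lengths(parents) == 0L]
  roots <- character(0)
  for (ns in unique(namespace)) {
    r <- rootless[namespace[rootless] == ns]
    if (length(r) != 1L) {
      stop("namespace ", ns, " must have exactly one root, found ",
           length(r))
    }
    roots[ns] <- r
  }
  if (is.null(partof)) partof <- stats::setNames(vector("list", 0), NULL)
  structure(
    list(name = name, namespace = namespace, parents = parents,
         partof = partof, roots = roots, cache = new.env(parent = emptyenv())),
    class = "go_dag"
  )
}

# Kahn-style peeling; anything left over sits on a cycle.
assert_acyclic <- function(parents) {
  remaining <- parents
  if (!length(remaining)) return(invisible(TRUE))
  repeat {
    free <- names(remaining)[lengths(remaining) == 0L]
    if (!length(free)) break
    remaining <- remaining[!names(remaining) %in% free]
    if (!length(remaining)) return(invisible(TRUE))
    remaining <- lapply(remaining, setdiff, y = free)
  }
  stop("cycle detected in ontology involving: ",
       paste(utils::head(names(remaining), 5L), collapse = ", "))
}

#' Load a Gene Ontology DAG from an OBO 1.2 flat file
#'
#' Captures `is_a` and `relationship: part_of` edges as parent links (the
#' relations along which annotation propagates under the GO true-path rule);
#' `regulates`-type relationships are ignored and obsolete terms are
#' dropped. The graph is checked for acyclicity, within-namespace parentage,
#' and a single root per namespace.
#'
#' @param path Path to the OBO file.
#' @return A `go_dag` object: named vectors `name` and `namespace` (one
#'   entry per term id), a `parents` list, a `partof` list (the subset of
#'   parent edges declared via part_of), and per-namespace `roots`.
#' @export
load_obo <- function(path) {
  lines <- readLines(path)
  # inline OBO comments follow " ! "
  lines <- sub("\\s*!.*$", "", lines)
  stanza_starts <- grep("^\\[", lines)
  term_starts <- which(lines == "[Term]")
  if (!length(term_starts)) stop("no [Term] stanzas in ", path)
  bounds <- c(stanza_starts, length(lines) + 1L)
  ids <- character(0); nms <- character(0); nss <- character(0)
  parents <- list(); partof <- list()
  for (s in term_starts) {
    end <- min(bounds[bounds > s]) - 1L
    body <- lines[seq.int(s + 1L, length.out = max(end - s, 0L))]
    body <- body[nzchar(trimws(body))]
    key <- sub(":.*$", "", body)
    val <- trimws(sub("^[^:]+:", "", body))
    if (any(key == "is_obsolete" & val == "true")) next
    id <- val[key == "id"][1L]
    if (is.na(id)) stop("[Term] stanza without id in ", path)
    ns <- val[key == "namespace"][1L]
    if (is.na(ns) || !ns %in% GO_NAMESPACES) {
      stop("term ", id, " has unknown namespace: ",
           if (is.na(ns)) "<missing>" else ns)
    }
    isa <- val[key == "is_a"]
    rel <- val[key == "relationship"]
    po <- sub("^part_of\\s+", "", rel[grepl("^part_of\\s", rel)])
    ids <- c(ids, id)
    nms <- c(nms, val[key == "name"][1L])
    nss <- c(nss, ns)
    parents[[id]] <- unique(c(isa, po))
    partof[[id]] <- unique(po)
  }
  if (anyDuplicated(ids)) stop("duplicate term id: ", ids[duplicated(ids)][1L])
  names(nms) <- ids
  names(nss) <- ids
  # edges pointing at obsolete (dropped) terms are discarded
  parents <- lapply(parents, intersect, y = ids)
  partof <- lapply(partof, intersect, y = ids)
  new_go_dag(nms, nss, parents[ids], partof[ids])
}

#' Write a GO DAG to an OBO 1.2 flat file
#'
#' Terms are emitted sorted by id, with `is_a` lines for plain parent edges
#' and `relationship: part_of` lines for part_of edges, so identical DAGs
#' produce byte-identical files.
#'
#' @param dag A `go_dag`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(dag, path) {
  out <- c("format-version: 1.2", "")
  for (id in sort(names(dag$name))) {
    po <- dag$partof[[id]]
    isa <- setdiff(dag$parents[[id]], po)
    out <- c(
      out, "[Term]",
      paste0("id: ", id),
      paste0("name: ", dag$name[[id]]),
      paste0("namespace: ", dag$namespace[[id]]),
      if (length(isa)) paste0("is_a: ", sort(isa), " ! ",
                              dag$name[sort(isa)]),
      if (length(po)) paste0("relationship: part_of ", sort(po), " ! ",
                             dag$name[sort(po)]),
      ""
    )
  }
  writeLines(out, path)
  invisible(path)
}

#' Ancestor closure of a GO term
#'
#' Reflexive transitive closure over parent links: the term itself plus
#' every term above it in the hierarchy. Under the true-path rule a gene
#' annotated to a term is implicitly annotated to all of these. Parent
#' edges never cross namespaces, so the closure stays within the term's
#' namespace.
#'
#' @param dag A `go_dag`.
#' @param term_id Term accession present in `dag`.
#' @return Sorted character vector of term ids, including `term_id`.
#' @export
ancestors <- function(dag, term_id) {
  if (!term_id %in% names(dag$name)) stop("unknown term: ", term_id)
  hit <- get0(term_id, envir = dag$cache, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  seen <- character(0)
  frontier <- term_id
  while (length(frontier)) {
    seen <- c(seen, frontier)
    frontier <- setdiff(
      unique(unlist(dag$parents[frontier], use.names = FALSE)), seen
    )
  }
  res <- sort(unique(seen))
  assign(term_id, res, envir = dag$cache)
  res
}

#' Mutually exclusive top-level categories of a namespace
#'
#' The depth-1 children of a namespace root (e.g. "metabolic process",
#' "response to stimulus" under the biological-process root). These are the
#' categories used for enrichment-by-fractionation analyses.
#'
#' @param dag A `go_dag`.
#' @param namespace One of `"biological_process"`, `"cellular_component"`,
#'   `"molecular_function"`.
#' @return Character vector of term ids, sorted by id (possibly empty).
#' @export
top_level_categories <- function(dag, namespace) {
  namespace <- match.arg(namespace, GO_NAMESPACES)
  if (!namespace %in% names(dag$roots)) {
    stop("namespace absent from DAG: ", namespace)
  }
  root <- dag$roots[[namespace]]
  ids <- names(dag$parents)
  sort(ids[vapply(dag$parents, function(p) root %in% p, logical(1))])
}

#' Read a gene-to-GO annotation table
#'
#' Two tab-separated columns, one pair per line, no header:
#' `gene_id<TAB>term_id`.
#'
#' @param path Path to the TSV file.
#' @return Named list mapping gene id to a character vector of directly
#'   annotated term ids.
#' @export
read_gene_annotations <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(stats::setNames(list(), character(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2L)) {
    stop("annotation lines must be 'gene_id<TAB>term_id': ", path)
  }
  gene <- vapply(parts, `[`, character(1), 1L)
  term <- vapply(parts, `[`, character(1), 2L)
  lapply(split(term, gene)[unique(gene)], unique)
}

#' Propagate GO annotation over the hierarchy and across homology sets
#'
#' A homology set inherits every term hit by any of its member genes,
#' expanded to the full ancestor closure (true-path rule); each member gene
#' then inherits the whole set-level term set back, the propagation used
#' when analyses run on individual genes.
#'
#' @param sets Homology-set tibble.
#' @param gene_hits Named list mapping gene id to directly annotated term
#'   ids (as from [read_gene_annotations()]). Gene ids absent from `sets`
#'   are ignored with a warning; terms absent from `dag` are an error.
#' @param dag A `go_dag`.
#' @return An `annotation_map`: list with `set_terms` (named list, one
#'   sorted term vector per set, empty for unannotated sets) and
#'   `gene_terms` (named list over all genes of `sets`, inheriting their
#'   set's terms).
#' @export
annotate_sets <- function(sets, gene_hits, dag) {
  idx <- gene_index(sets)
  gene2set <- stats::setNames(idx$set_id, idx$gene_id)
  unknown <- setdiff(names(gene_hits), names(gene2set))
  if (length(unknown)) {
    warning("ignoring ", length(unknown),
            " annotated gene id(s) absent from the homology sets")
    gene_hits <- gene_hits[setdiff(names(gene_hits), unknown)]
  }
  hit_terms <- unique(unlist(gene_hits, use.names = FALSE))
  closures <- lapply(hit_terms, ancestors, dag = dag)
  names(closures) <- hit_terms
  # direct hits per set, then one closure union per set
  set_direct <- split(
    unlist(gene_hits, use.names = FALSE),
    rep(gene2set[names(gene_hits)], lengths(gene_hits))
  )
  set_terms <- stats::setNames(
    rep(list(character(0)), nrow(sets)), sets$set_id
  )
  set_terms[names(set_direct)] <- lapply(
    set_direct,
    function(tt) sort(unique(unlist(closures[unique(tt)], use.names = FALSE)))
  )
  gene_terms <- set_terms[gene2set]
  names(gene_terms) <- names(gene2set)
  structure(list(set_terms = set_terms, gene_terms = gene_terms),
            class = "annotation_map")
}
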