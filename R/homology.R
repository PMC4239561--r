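# Homology sets: groups of genes across species descending from one
# ancestral gene at a shared whole-genome multiplication event, and the
# fractionation-resistance level F computed from them.

#' Construct a homology-set collection
#'
#' A homology set groups the genes, across a panel of species, that descend
#' from a single ancestral gene at a shared whole-genome doubling (or
#' tripling) event. After the event each lineage loses duplicated copies
#' independently ("fractionation"), so a species may retain zero, one, or
#' several copies of the ancestral gene.
#'
#' @param set_id Character vector of unique set identifiers.
#' @param members List parallel to `set_id`; each element a named list
#'   mapping a species id to a character vector of retained gene ids
#'   (possibly empty).
#' @param species Ordered character vector giving the species panel.
#'   Defaults to the union of species names seen in `members`.
#'
#' @return A tibble with columns `set_id`, `members` (list column) and `F`
#'   (integer, `NA` until [compute_F()] is called). The species panel is
#'   stored in the `"species"` attribute.
#' @export
#' @examples
#' hs <- homology_sets(
#'   "anc1",
#'   list(list(spA = c("a1", "a2"), spB = "b1")),
#'   species = c("spA", "spB")
#' )
#' compute_F(hs)$F
homology_sets <- function(set_id, members, species = NULL) {
  set_id <- as.character(set_id)
  if (anyDuplicated(set_id)) {
    stop("duplicate set_id: ", set_id[duplicated(set_id)][1L])
  }
  if (length(members) != length(set_id)) {
    stop("`members` must be parallel to `set_id`")
  }
  seen <- unique(unlist(lapply(members, names), use.names = FALSE))
  if (is.null(species)) {
    species <- seen
  } else if (length(bad <- setdiff(seen, species))) {
    stop("unknown species: ", paste(bad, collapse = ", "))
  }
  genes <- unlist(members, use.names = FALSE)
  if (anyDuplicated(genes)) {
    stop(
      "gene_id assigned to more than one homology set / species: ",
      genes[duplicated(genes)][1L]
    )
  }
  # normalise: every set carries every species, empty vector for full loss
  members <- lapply(members, function(m) {
    m <- lapply(m, as.character)
    missing <- setdiff(species, names(m))
    m[missing] <- list(character(0))
    m[species]
  })
  out <- tibble::tibble(set_id = set_id, members = members, F = NA_integer_)
  attr(out, "species") <- species
  out
}

#' Read homology sets from a tab-separated table
#'
#' Expected layout: header `set_id<TAB>species1<TAB>species2...`; one row per
#' homology set; each species cell holds comma-separated retained gene ids,
#' or is empty when the lineage lost all copies.
#'
#' @param path Path to the TSV file.
#' @param species Optional ordered species panel. When given, the file's
#'   species columns must match it exactly (an unknown column is an error).
#' @return A homology-set tibble as produced by [homology_sets()], with `F`
#'   unset.
#' @export
read_homology_sets <- function(path, species = NULL) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty homology-set file (no header): ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  if (length(header) < 2L || header[1L] != "set_id") {
    stop("homology-set header must be 'set_id<TAB><species>...': ", path)
  }
  file_species <- header[-1L]
  if (!is.null(species)) {
    if (length(bad <- setdiff(file_species, species))) {
      stop("unknown species column: ", paste(bad, collapse = ", "))
    }
    if (length(miss <- setdiff(species, file_species))) {
      stop("species missing from file: ", paste(miss, collapse = ", "))
    }
  } else {
    species <- file_species
  }
  rows <- fields[-1L]
  rows <- rows[vapply(rows, function(f) any(nzchar(f)), logical(1))]
  parse_cell <- function(cell) {
    if (is.na(cell) || !nzchar(cell)) return(character(0))
    g <- strsplit(cell, ",", fixed = TRUE)[[1L]]
    g <- trimws(g)
    g[nzchar(g)]
  }
  ncol <- length(header)
  members <- vector("list", length(rows))
  ids <- character(length(rows))
  for (i in seq_along(rows)) {
    f <- rows[[i]]
    length(f) <- ncol # pad trailing empty cells
    ids[i] <- f[1L]
    m <- lapply(f[-1L], parse_cell)
    names(m) <- file_species
    members[[i]] <- m[species]
  }
  homology_sets(ids, members, species = species)
}

species_panel <- function(sets) {
  sp <- attr(sets, "species")
  if (is.null(sp)) {
    sp <- unique(unlist(lapply(sets$members, names), use.names = FALSE))
  }
  sp
}

#' Compute the fractionation-resistance level F of each homology set
#'
#' For each set, `N` is the number of species that still hold the ancestral
#' gene in duplicate (at least `duplicate_threshold` retained copies), and
#' the fractionation-resistance level is `F = N + 1`. A set reduced to a
#' single copy (or none) in every species has `F = 1`; with `S` species `F`
#' ranges over `1..S + 1`.
#'
#' @param sets Homology-set tibble from [homology_sets()] or
#'   [read_homology_sets()].
#' @param duplicate_threshold Minimum retained copy count for a species to
#'   count as "in duplicate". Must be >= 2; the default 2 also counts
#'   lineages retaining three copies after an ancestral triplication.
#' @return `sets` with the `F` column filled (integer).
#' @export
compute_F <- function(sets, duplicate_threshold = 2L) {
  duplicate_threshold <- as.integer(duplicate_threshold)
  if (is.na(duplicate_threshold) || duplicate_threshold < 2L) {
    stop("duplicate_threshold must be an integer >= 2")
  }
  sets$F <- vapply(
    sets$members,
    function(m) sum(lengths(m) >= duplicate_threshold) + 1L,
    integer(1)
  )
  sets
}

#' Per-gene index of a homology-set collection
#'
#' Flattens the collection to one row per retained gene, the view used by
#' the expression analyses (which operate on individual genes rather than
#' whole homology sets).
#'
#' @param sets Homology-set tibble.
#' @return A tibble with columns `gene_id`, `species_id`, `set_id`, and `F`
#'   (NA if [compute_F()] has not run).
#' @export
gene_index <- function(sets) {
  n_per_sp <- lapply(sets$members, lengths)
  n_per_set <- vapply(n_per_sp, sum, integer(1))
  tibble::tibble(
    gene_id = as.character(unlist(sets$members, use.names = FALSE)),
    species_id = unlist(
      mapply(function(m, n) rep(names(m), n), sets$members, n_per_sp,
             SIMPLIFY = FALSE),
      use.names = FALSE
    ),
    set_id = rep(sets$set_id, n_per_set),
    F = rep(sets$F, n_per_set)
  )
}
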