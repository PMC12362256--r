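#' Taxonomy trees
#'
#' A taxonomy tree organises the count-table features (its leaves) under
#' named clades at the canonical ranks kingdom, phylum, class, order,
#' family, genus, species. CAT permutes the leaf set `L(t)` of a chosen
#' node `t`, so the tree's job is to map taxon names to leaf feature sets.
#'
#' The tree is stored as a node table (id, parent, rank, name) plus a
#' leaf-to-feature bijection. Unnamed intermediate ranks (empty `g__`
#' segments and the like) are kept as anonymous placeholder nodes so the
#' rank ladder stays intact under every leaf.
#'
#' @name taxonomy
NULL

TAX_RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus",
               "species")
RANK_PREFIXES <- c(k = "kingdom", p = "phylum", c = "class", o = "order",
                   f = "family", g = "genus", s = "species")

#' Build a taxonomy tree from lineage strings
#'
#' @param lineages A data frame with two columns: feature id and a
#'   semicolon-delimited lineage with Greengenes/QIIME rank prefixes
#'   (`k__...; p__...; ...`). Empty rank segments are allowed and become
#'   anonymous placeholder nodes.
#' @return A `taxonomy` object.
#' @examples
#' tax <- build_taxonomy(data.frame(
#'   feature = c("f1", "f2"),
#'   lineage = c("k__B; p__F; c__C1", "k__B; p__F; c__C2")
#' ))
#' leaf_descendants(tax, "F")
#' @export
build_taxonomy <- function(lineages) {
  stopifnot(is.data.frame(lineages), ncol(lineages) >= 2)
  feats <- as.character(lineages[[1]])
  lins <- as.character(lineages[[2]])
  dup <- duplicated(feats)
  if (any(dup)) {
    d <- feats[dup][1]
    if (length(unique(lins[feats == d])) > 1) {
      abort(sprintf("feature '%s' is assigned two different lineages", d))
    }
    abort(sprintf("feature '%s' appears twice in the taxonomy file", d))
  }

  ids <- new.env(parent = emptyenv())
  parent <- integer(0); name <- character(0); rank <- character(0)
  add_node <- function(p, nm, rk) {
    parent[[length(parent) + 1L]] <<- p
    name[[length(name) + 1L]] <<- nm
    rank[[length(rank) + 1L]] <<- rk
    length(parent)
  }
  root <- add_node(NA_integer_, NA_character_, "root")

  for (i in seq_along(feats)) {
    segs <- trimws(strsplit(lins[i], ";", fixed = TRUE)[[1]])
    segs <- segs[segs != ""]
    cur <- root
    key <- ""
    last_rank <- 0L
    for (seg in segs) {
      if (!grepl("^[kpcofgs]__", seg)) {
        abort(sprintf("malformed lineage segment '%s' for feature '%s'",
                      seg, feats[i]))
      }
      rk <- RANK_PREFIXES[[substr(seg, 1, 1)]]
      ri <- match(rk, TAX_RANKS)
      if (ri <= last_rank) {
        abort(sprintf(
          "rank prefixes out of canonical order in lineage for feature '%s'",
          feats[i]
        ))
      }
      last_rank <- ri
      nm <- sub("^[kpcofgs]__", "", seg)
      key <- paste0(key, "|", seg)
      id <- ids[[key]]
      if (is.null(id)) {
        id <- add_node(cur, if (nzchar(nm)) nm else NA_character_, rk)
        ids[[key]] <- id
      }
      cur <- id
    }
    add_node(cur, feats[i], "leaf")
  }

  nodes <- tibble::tibble(
    id = seq_along(parent), parent = unlist(parent),
    name = unlist(name), rank = unlist(rank)
  )
  structure(list(nodes = nodes), class = "taxonomy")
}

#' Read a taxonomy assignment file
#'
#' Two tab-separated columns: feature id, lineage string
#' (`k__...; p__...; ...` dialect). `#` comment lines are ignored.
#'
#' @param path File path.
#' @return A [taxonomy] object.
#' @export
read_taxonomy <- function(path) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE,
                        col_types = readr::cols(.default = "c"))
  build_taxonomy(df)
}

#' @export
print.taxonomy <- function(x, ...) {
  n <- x$nodes
  cat(sprintf(
    "<taxonomy> %d leaves, %d named internal nodes\n",
    sum(n$rank == "leaf"), sum(!is.na(n$name) & n$rank != "leaf")
  ))
  invisible(x)
}

#' Feature leaves of the full taxonomy
#' @param tax A [taxonomy] object.
#' @return Character vector of feature ids (leaves), in insertion order.
#' @export
taxonomy_leaves <- function(tax) {
  tax$nodes$name[tax$nodes$rank == "leaf"]
}

# children index: list mapping node id -> integer vector of child ids
tax_children <- function(tax) {
  split(tax$nodes$id[-1], factor(tax$nodes$parent[-1],
                                 levels = tax$nodes$id))
}

# leaf feature ids below node `id` (inclusive if the node is itself a leaf)
tax_leafset <- function(tax, id) {
  ch <- tax_children(tax)
  out <- character(0)
  stack <- id
  while (length(stack)) {
    cur <- stack[[1]]; stack <- stack[-1]
    if (tax$nodes$rank[cur] == "leaf") {
      out <- c(out, tax$nodes$name[cur])
    } else {
      stack <- c(ch[[cur]], stack)
    }
  }
  out
}

# Resolve a taxon reference to a single node id. Accepts a bare name, a
# rank-qualified "family:Name" or greengenes-style "f__Name", or a feature id.
resolve_taxon <- function(tax, taxon) {
  n <- tax$nodes
  rank_filter <- NULL
  name <- taxon
  if (grepl("^[kpcofgs]__", taxon)) {
    rank_filter <- RANK_PREFIXES[[substr(taxon, 1, 1)]]
    name <- sub("^[kpcofgs]__", "", taxon)
  } else if (grepl(":", taxon, fixed = TRUE)) {
    parts <- strsplit(taxon, ":", fixed = TRUE)[[1]]
    if (!parts[1] %in% c(TAX_RANKS, "leaf")) {
      abort(sprintf("unknown rank qualifier '%s'", parts[1]))
    }
    rank_filter <- parts[1]
    name <- paste(parts[-1], collapse = ":")
  }
  hits <- which(!is.na(n$name) & n$name == name)
  if (!is.null(rank_filter)) hits <- hits[n$rank[hits] == rank_filter]
  if (length(hits) == 0) {
    near <- unique(n$name[!is.na(n$name)])
    near <- near[agrepl(name, near, max.distance = 0.25)]
    abort(sprintf(
      "unknown taxon '%s'%s", taxon,
      if (length(near)) {
        paste0("; near matches: ", paste(head(near, 5), collapse = ", "))
      } else ""
    ))
  }
  if (length(hits) > 1) {
    abort(sprintf(
      "taxon name '%s' is ambiguous (ranks: %s); qualify it as 'rank:name'",
      name, paste(unique(n$rank[hits]), collapse = ", ")
    ))
  }
  hits
}

#' Leaf features descending from a taxon
#'
#' Returns `L(t)`: the set of leaf feature ids below (or equal to) the
#' named node — the unit of counts that [cat_test()] permutes.
#'
#' @param tax A [taxonomy] object.
#' @param taxon A node name; if the name occurs at several ranks, qualify it
#'   as `"family:Name"` or `"f__Name"`. A leaf feature id returns itself.
#' @return Character vector of feature ids.
#' @export
leaf_descendants <- function(tax, taxon) {
  tax_leafset(tax, resolve_taxon(tax, taxon))
}

#' Summarise named taxa at one rank
#'
#' @param tax A [taxonomy] object.
#' @param rank One of kingdom, phylum, class, order, family, genus, species.
#' @return A tibble with columns `taxon`, `rank`, `n_leaves`.
#' @export
taxa_at_rank <- function(tax, rank) {
  rank <- arg_match0(rank, TAX_RANKS)
  n <- tax$nodes
  ids <- n$id[n$rank == rank & !is.na(n$name)]
  tibble::tibble(
    taxon = n$name[ids],
    rank = rank,
    n_leaves = vapply(ids, function(i) length(tax_leafset(tax, i)),
                      integer(1))
  )
}

# rank of the node a taxon reference resolves to
taxon_rank <- function(tax, taxon) {
  tax$nodes$rank[resolve_taxon(tax, taxon)]
}
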