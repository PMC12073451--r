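#' Hypergeometric overrepresentation p-value
#'
#' Upper-tail probability `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`:
#' the chance that a random query of size `n` drawn from a universe of `N`
#' compounds overlaps a pathway of size `K` in at least `k` compounds.
#' Computed by exact summation of the hypergeometric mass.
#'
#' @param hits Observed overlap k (0 <= k <= min(K, n)).
#' @param pathway_size Pathway member count K.
#' @param query_size Mapped query size n.
#' @param universe_size Background universe size N (K, n <= N).
#' @return The p-value in (0, 1]; `hits = 0` gives exactly 1.
#' @export
ora_pvalue <- function(hits, pathway_size, query_size, universe_size) {
  k <- hits; K <- pathway_size; n <- query_size; N <- universe_size
  if (any(c(k, K, n, N) < 0) || K > N || n > N || k > min(K, n)) {
    stop("inconsistent hypergeometric sizes", call. = FALSE)
  }
  if (k <= 0) return(1)
  p <- sum(stats::dhyper(seq(k, min(K, n)), K, N - K, n))
  min(p, 1)
}

#' Topology impact of a hit set via relative betweenness centrality
#'
#' Betweenness centrality (shortest-path, unit edge weights,
#' endpoint-exclusive, undirected) is computed for every member of the
#' pathway graph, normalized to relative centralities summing to one (when
#' all centralities are zero, e.g. an edgeless pathway, every node gets
#' `1/|V|`), and summed over the hit nodes. The impact therefore lies in
#' \[0, 1\], with 1 when every member is hit.
#'
#' @param pathway list with `members` (character vector) and `edges` (list
#'   of length-2 character vectors, or a 2-column matrix; may be empty).
#' @param hits Character vector of hit compound ids; must be members.
#' @return Impact value in \[0, 1\].
#' @export
pathway_impact <- function(pathway, hits) {
  members <- pathway$members
  if (!all(hits %in% members)) {
    stop("hit node(s) not members of the pathway: ",
         paste(setdiff(hits, members), collapse = ", "), call. = FALSE)
  }
  if (!length(hits)) return(0)
  edges <- pathway$edges
  if (is.list(edges)) edges <- do.call(rbind, lapply(edges, unlist))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(members), name = members)
  if (!is.null(edges) && nrow(edges)) {
    bad <- setdiff(unique(c(edges)), members)
    if (length(bad)) {
      stop("edge endpoint(s) outside the member set: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    g <- igraph::add_edges(g, t(edges))
  }
  bc <- igraph::betweenness(g, directed = FALSE, weights = NA)
  rbc <- if (sum(bc) == 0) rep(1 / length(members), length(members)) else {
    bc / sum(bc)
  }
  names(rbc) <- members
  sum(rbc[hits])
}

validate_library <- function(lib) {
  stopifnot(is.list(lib), !is.null(lib$universe), !is.null(lib$pathways))
  if (!length(lib$universe)) stop("empty compound universe", call. = FALSE)
  for (pw in lib$pathways) {
    if (is.null(pw$name) || !length(pw$members)) {
      stop("each pathway needs a name and members", call. = FALSE)
    }
    if (!all(pw$members %in% lib$universe)) {
      stop("pathway '", pw$name, "' has members outside the universe",
           call. = FALSE)
    }
    if (length(pw$members) > length(lib$universe)) {
      stop("pathway larger than universe", call. = FALSE)
    }
  }
  structure(lib, class = "pathway_library")
}

#' Read / write a pathway library as JSON
#'
#' Format: `{"universe": [...], "pathways": [{"name": ..., "members":
#' [...], "edges": [[a, b], ...]}]}`. The packaged demo library
#' (`demo_pathway_library.json`) is a synthetic, hand-shaped stand-in for a
#' fruit-fly KEGG metabolite library: pathway names and sizes mirror the
#' amino-acid pathways typical of such analyses, members mix real
#' metabolite names with filler compound ids, and edges are plausible
#' reaction chains. It supports format and algorithm tests; it is not KEGG
#' content.
#'
#' @param path JSON path; `NULL` loads the packaged demo library.
#' @return A validated `pathway_library`.
#' @export
read_pathway_library <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "demo_pathway_library.json",
                        package = "cemetab", mustWork = TRUE)
  }
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lib <- list(
    universe = vapply(raw$universe, as.character, character(1)),
    pathways = lapply(raw$pathways, function(pw) {
      list(name = pw$name,
           members = vapply(pw$members, as.character, character(1)),
           edges = lapply(pw$edges, function(e) {
             vapply(e, as.character, character(1))
           }))
    })
  )
  validate_library(lib)
}

#' @rdname read_pathway_library
#' @param lib A `pathway_library`.
#' @export
write_pathway_library <- function(lib, path) {
  jsonlite::write_json(
    list(universe = lib$universe,
         pathways = lapply(lib$pathways, function(pw) {
           list(name = pw$name, members = pw$members,
                edges = pw$edges)
         })),
    path, auto_unbox = TRUE
  )
  invisible(path)
}

#' Generate a random pathway library
#'
#' Draws `n_pathways` member sets from a synthetic compound universe and
#' connects each with a random spanning tree plus extra edges. Useful for
#' property tests and planted-enrichment simulations. Uses the current RNG
#' state.
#'
#' @param n_pathways Number of pathways (default 20).
#' @param universe_size Universe size (default 200).
#' @param size_range Pathway size range (default 8 to 32).
#' @param extra_edge_frac Extra edges per pathway as a fraction of members.
#' @return A `pathway_library`.
#' @export
simulate_pathway_library <- function(n_pathways = 20L, universe_size = 200L,
                                     size_range = c(8L, 32L),
                                     extra_edge_frac = 0.3) {
  universe <- sprintf("cpd_%03d", seq_len(universe_size))
  pathways <- lapply(seq_len(n_pathways), function(i) {
    sz <- sample(seq(size_range[1], size_range[2]), 1L)
    members <- sample(universe, sz)
    edges <- lapply(seq_len(sz - 1L), function(j) {
      c(members[sample.int(j, 1L)], members[j + 1L])  # random tree
    })
    n_extra <- round(extra_edge_frac * sz)
    for (e in seq_len(n_extra)) {
      pair <- sample(members, 2L)
      edges[[length(edges) + 1L]] <- pair
    }
    list(name = sprintf("pathway_%02d", i), members = members, edges = edges)
  })
  validate_library(list(universe = universe, pathways = pathways))
}

#' Pathway overrepresentation analysis of a query metabolite set
#'
#' Maps the query onto the library universe (unmapped compounds are
#' reported and excluded from the query size), computes the hypergeometric
#' upper-tail p-value and topology impact for every pathway with at least
#' one hit, and returns the results sorted by ascending p-value. A pathway
#' is flagged significant when `p < p_cutoff` and its impact is greater
#' than zero.
#'
#' @param query Character vector of query compound ids.
#' @param library A `pathway_library`.
#' @param p_cutoff Significance threshold (default 0.05).
#' @return data.frame `pathway`, `total`, `hits`, `p_value`, `impact`,
#'   `significant`, sorted by p-value; unmapped query compounds in the
#'   `unmapped` attribute.
#' @export
analyze_pathways <- function(query, library, p_cutoff = 0.05) {
  library <- validate_library(unclass(library))
  query <- unique(query)
  mapped <- intersect(query, library$universe)
  unmapped <- setdiff(query, library$universe)
  n <- length(mapped)
  N <- length(library$universe)
  rows <- lapply(library$pathways, function(pw) {
    hit_set <- intersect(mapped, pw$members)
    if (!length(hit_set)) return(NULL)
    data.frame(
      pathway = pw$name, total = length(pw$members), hits = length(hit_set),
      p_value = ora_pvalue(length(hit_set), length(pw$members), n, N),
      impact = pathway_impact(pw, hit_set),
      stringsAsFactors = FALSE
    )
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(pathway = character(0), total = integer(0), hits = integer(0),
               p_value = numeric(0), impact = numeric(0))
  }
  out <- out[order(out$p_value, out$pathway), , drop = FALSE]
  out$significant <- out$p_value < p_cutoff & out$impact > 0
  rownames(out) <- NULL
  attr(out, "unmapped") <- unmapped
  attr(out, "query_size") <- n
  out
}
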