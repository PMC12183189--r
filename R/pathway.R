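# Topology-aware pathway analysis: hypergeometric over-representation of
# a hit list within pathway member sets, pathway impact from relative
# betweenness centrality of the hit nodes, Benjamini-Hochberg FDR across
# pathways, and the dominance filter combining all three.

#' Define a pathway
#'
#' @param id pathway identifier.
#' @param name human-readable name.
#' @param members character vector of member compound ids (non-empty).
#' @param edges two-column matrix or data frame of undirected edges over
#'   the members (may be empty).
#' @return Object of class `pathway_definition`.
#' @export
pathway_definition <- function(id, name = id, members, edges = NULL) {
  members <- unique(as.character(members))
  if (!length(members)) stop("pathway needs >= 1 member", call. = FALSE)
  if (is.null(edges) || NROW(edges) == 0L) {
    edges <- matrix(character(0), ncol = 2L)
  } else {
    edges <- as.matrix(edges)[, 1:2, drop = FALSE]
    mode(edges) <- "character"
    if (!all(edges %in% members)) {
      stop("pathway '", id, "': edges reference non-member compounds",
           call. = FALSE)
    }
  }
  structure(list(id = id, name = name, members = members, edges = edges),
            class = "pathway_definition")
}

#' Upper-tail hypergeometric p-value
#'
#' `P(X >= k)` for the overlap `X` between a hit list of size `n` and a
#' pathway of size `m` drawn from a universe of size `N`.
#'
#' @param N universe size.
#' @param m pathway size.
#' @param n hit-list size.
#' @param k observed overlap.
#' @return The upper-tail probability.
#' @export
hypergeom_p <- function(N, m, n, k) {
  if (m > N || n > N || k > min(m, n) || k < 0) {
    stop("inconsistent hypergeometric counts (need k <= min(m, n) <= N)",
         call. = FALSE)
  }
  phyper(k - 1, m, N - m, n, lower.tail = FALSE)
}

#' Relative betweenness-centrality node weights
#'
#' Betweenness centrality of each pathway member on the pathway graph,
#' normalised so the weights sum to 1 over the pathway.  Members absent
#' from the edge list (isolated nodes) receive the uniform floor weight
#' `1/|members|` before normalisation; if every node has zero
#' betweenness (e.g. a single edge), weights are uniform.
#'
#' @param pw a [pathway_definition()].
#' @return Named numeric vector of weights summing to 1.
#' @export
node_importance <- function(pw) {
  stopifnot(inherits(pw, "pathway_definition"))
  m <- length(pw$members)
  if (m == 1L) {
    w <- 1
    names(w) <- pw$members
    return(w)
  }
  w <- setNames(numeric(m), pw$members)
  if (nrow(pw$edges)) {
    g <- igraph::graph_from_edgelist(pw$edges, directed = FALSE)
    bet <- igraph::betweenness(g, directed = FALSE)
    w[names(bet)] <- bet
    isolated <- setdiff(pw$members, igraph::V(g)$name)
  } else {
    isolated <- pw$members
  }
  if (sum(w) == 0 && length(isolated) == 0L) {
    # connected (or multi-component) graph where no node lies on a
    # shortest path between two others: fall back to uniform weights
    w[] <- 1 / m
    return(w)
  }
  w[isolated] <- 1 / m
  w / sum(w)
}

#' Pathway impact of a hit list
#'
#' Sum of the relative betweenness weights of the pathway members matched
#' by the hit list; lies in `[0, 1]` and is monotone in the hit set.
#'
#' @param pw a [pathway_definition()].
#' @param hits character vector of hit compound ids.
#' @return Impact score in `[0, 1]`.
#' @export
pathway_impact <- function(pw, hits) {
  w <- node_importance(pw)
  sum(w[names(w) %in% hits])
}

#' Pathway over-representation and impact analysis
#'
#' For each pathway: the upper-tail hypergeometric p-value of the overlap
#' between the hit list and the pathway members (within the universe),
#' the Benjamini-Hochberg FDR across pathways, and the
#' betweenness-centrality impact of the hits.
#'
#' @param pathways list of [pathway_definition()] objects.
#' @param hits character vector of significant compounds (subset of
#'   `universe`).
#' @param universe character vector of all measured compounds.
#' @return Data frame sorted by p-value with columns `id`, `name`, `N`,
#'   `m`, `n`, `k`, `p`, `fdr`, `impact`.
#' @export
enrich <- function(pathways, hits, universe) {
  hits <- unique(hits)
  universe <- unique(universe)
  off <- setdiff(hits, universe)
  if (length(off)) {
    stop("hits not in the universe: ", paste(off, collapse = ", "),
         call. = FALSE)
  }
  N <- length(universe)
  n <- length(hits)
  rows <- lapply(pathways, function(pw) {
    mem <- intersect(pw$members, universe)
    m <- length(mem)
    k <- length(intersect(mem, hits))
    data.frame(id = pw$id, name = pw$name, N = N, m = m, n = n, k = k,
               p = if (m) hypergeom_p(N, m, n, k) else 1,
               impact = pathway_impact(pw, hits),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p)
  out <- out[order(out$p), c("id", "name", "N", "m", "n", "k", "p", "fdr",
                             "impact")]
  rownames(out) <- NULL
  out
}

#' Dominance filter on enrichment results
#'
#' Flags pathways that dominate the response: `-log10(p) > logp_gate`,
#' `impact > impact_gate`, and `fdr < fdr_gate` (defaults 2, 0.1, 0.1).
#'
#' @param results data frame from [enrich()].
#' @param logp_gate,impact_gate,fdr_gate the gates.
#' @return `results` with a logical `dominant` column.
#' @export
dominance_filter <- function(results, logp_gate = 2, impact_gate = 0.1,
                             fdr_gate = 0.1) {
  stopifnot(all(c("p", "impact", "fdr") %in% names(results)))
  results$dominant <- -log10(results$p) > logp_gate &
    results$impact > impact_gate & results$fdr < fdr_gate
  results
}

#' Read pathway member sets from a GMT file
#'
#' Standard tab-separated GMT: one pathway per line, fields are id,
#' description, then member ids.
#'
#' @param path GMT file path.
#' @param edges optional data frame from [read_edge_list()] supplying the
#'   pathway graphs.
#' @return List of [pathway_definition()] objects.
#' @export
read_gmt <- function(path, edges = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) {
      stop("malformed GMT line (need id, description, >= 1 member): ", ln,
           call. = FALSE)
    }
    ed <- NULL
    if (!is.null(edges)) {
      sub <- edges[edges$pathway == f[1], c("node_a", "node_b"),
                   drop = FALSE]
      if (nrow(sub)) ed <- sub
    }
    pathway_definition(id = f[1], name = f[2], members = f[-(1:2)],
                       edges = ed)
  })
}

#' Read a pathway edge list
#'
#' Tab-separated with columns `pathway`, `node_a`, `node_b`.
#'
#' @param path TSV file path.
#' @return Data frame with those columns.
#' @export
read_edge_list <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("pathway", "node_a", "node_b") %in% names(df)))
  df
}
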