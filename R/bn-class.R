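#' Directed acyclic graphs over named nodes
#'
#' A `dag` stores a node set and a per-node parent list, and is validated to
#' be acyclic with no self-loops or duplicate edges. It is the structural
#' half of a Bayesian network.
#'
#' @param nodes character vector of node names.
#' @param edges data.frame (or 2-column matrix) with columns `from`, `to`;
#'   may be empty.
#' @return An object of class `"dag"`.
#' @export
dag <- function(nodes, edges = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node name")
  parents <- stats::setNames(rep(list(character()), length(nodes)), nodes)
  if (!is.null(edges) && NROW(edges) > 0L) {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    names(edges)[1:2] <- c("from", "to")
    for (i in seq_len(nrow(edges))) {
      f <- as.character(edges$from[i]); t <- as.character(edges$to[i])
      if (!f %in% nodes || !t %in% nodes)
        stop("edge endpoint not a node: ", f, " -> ", t)
      if (f == t) stop("self-loop at ", f)
      if (f %in% parents[[t]]) stop("duplicate edge ", f, " -> ", t)
      parents[[t]] <- c(parents[[t]], f)
    }
  }
  g <- structure(list(nodes = nodes, parents = parents), class = "dag")
  if (is.null(topo_sort(g))) stop("graph is cyclic")
  g
}

#' @export
print.dag <- function(x, ...) {
  e <- dag_edges(x)
  cat(sprintf("<dag> %d nodes, %d edges\n", length(x$nodes), nrow(e)))
  if (nrow(e))
    cat(" ", paste(sprintf("%s -> %s", e$from, e$to), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname dag
#' @param x a `dag` or `bayes_net`.
#' @return `dag_edges()`: data.frame with columns `from`, `to`.
#' @export
dag_edges <- function(x) {
  p <- if (inherits(x, "bayes_net")) lapply(x$nodes, `[[`, "parents")
       else x$parents
  from <- unlist(p, use.names = FALSE)
  to <- rep(names(p), lengths(p))
  data.frame(from = as.character(from), to = as.character(to),
             stringsAsFactors = FALSE)
}

#' Topological order of a DAG
#'
#' @param g a `dag` (or a named list of parent vectors).
#' @return Character vector of nodes in topological order, or `NULL` if the
#'   graph is cyclic.
#' @export
topo_sort <- function(g) {
  parents <- if (inherits(g, "dag")) g$parents
             else if (inherits(g, "bayes_net")) lapply(g$nodes, `[[`, "parents")
             else g
  nodes <- names(parents)
  indeg <- lengths(parents)
  order <- character(0)
  remaining <- nodes
  while (length(remaining)) {
    free <- remaining[indeg[remaining] == 0L]
    if (!length(free)) return(NULL)
    order <- c(order, free)
    remaining <- setdiff(remaining, free)
    for (n in remaining)
      indeg[n] <- length(setdiff(parents[[n]], order))
  }
  order
}

#' Construct a discrete Bayesian network
#'
#' A `bayes_net` couples a DAG with one conditional probability table per
#' node. Each CPT is an array whose first dimension ranges over the child's
#' states and whose remaining dimensions range over the parents' states (in
#' parent-list order); every column over the child dimension sums to 1.
#'
#' @param nodes named list; each element is a list with `states` (character
#'   vector of state labels), `parents` (character vector, possibly empty)
#'   and `cpt` (numeric array as described above; for a root node a plain
#'   probability vector over states is accepted).
#' @return An object of class `"bayes_net"`.
#' @export
bayes_net <- function(nodes) {
  stopifnot(is.list(nodes), length(nodes) > 0L, !is.null(names(nodes)))
  for (nm in names(nodes)) {
    nd <- nodes[[nm]]
    if (is.null(nd$states) || length(nd$states) < 2L)
      stop("node '", nm, "' needs at least 2 states")
    nd$states <- as.character(nd$states)
    nd$parents <- as.character(nd$parents %||% character())
    bad <- setdiff(nd$parents, names(nodes))
    if (length(bad)) stop("parent '", bad[1L], "' of '", nm, "' is not a node")
    r <- length(nd$states)
    pdims <- vapply(nodes[nd$parents],
                    function(p) length(as.character(p$states)), integer(1))
    want <- c(r, unname(pdims))
    cpt <- nd$cpt
    if (is.null(dim(cpt))) {
      if (length(cpt) != prod(want))
        stop("CPT of '", nm, "' has length ", length(cpt),
             ", expected ", prod(want))
      cpt <- array(as.numeric(cpt), dim = want)
    }
    if (!identical(as.integer(dim(cpt)), as.integer(want)))
      stop("CPT of '", nm, "' has wrong dimensions")
    m <- matrix(cpt, nrow = r)
    if (any(m < -1e-12) || any(abs(colSums(m) - 1) > 1e-9))
      stop("CPT columns of '", nm, "' must be probabilities summing to 1")
    dimnames(cpt) <- c(list(nd$states),
                       lapply(nodes[nd$parents],
                              function(p) as.character(p$states)))
    nd$cpt <- cpt
    nodes[[nm]] <- nd
  }
  net <- structure(list(nodes = nodes), class = "bayes_net")
  if (is.null(topo_sort(net))) stop("network structure is cyclic")
  net
}

#' @export
print.bayes_net <- function(x, ...) {
  e <- dag_edges(x)
  cat(sprintf("<bayes_net> %d nodes, %d edges\n", length(x$nodes), nrow(e)))
  for (nm in names(x$nodes)) {
    nd <- x$nodes[[nm]]
    cat(sprintf("  %s [%s]%s\n", nm, paste(nd$states, collapse = ","),
                if (length(nd$parents))
                  paste0(" <- ", paste(nd$parents, collapse = ", "))
                else ""))
  }
  invisible(x)
}

#' @rdname dag
#' @export
bn_dag <- function(x) {
  stopifnot(inherits(x, "bayes_net"))
  dag(names(x$nodes), dag_edges(x))
}

#' Serialize a Bayesian network to JSON
#'
#' The JSON document lists, per node, its state labels, parent list and CPT
#' (flattened in array order: child state fastest, then parents in order).
#' `read_bn_json(write_bn_json(net))` reconstructs an identical network.
#'
#' @param net a [bayes_net()].
#' @param path output file path.
#' @export
write_bn_json <- function(net, path) {
  stopifnot(inherits(net, "bayes_net"))
  doc <- list(nodes = lapply(names(net$nodes), function(nm) {
    nd <- net$nodes[[nm]]
    list(name = nm, states = as.list(nd$states),
         parents = as.list(nd$parents),
         cpt = as.numeric(nd$cpt))
  }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_bn_json
#' @return `read_bn_json()`: a [bayes_net()].
#' @export
read_bn_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$nodes)) stop("malformed network document: no 'nodes'")
  nodes <- list()
  for (nd in doc$nodes) {
    if (is.null(nd$name) || is.null(nd$states) || is.null(nd$cpt))
      stop("malformed node entry in ", path)
    nodes[[nd$name]] <- list(
      states = vapply(nd$states, as.character, character(1)),
      parents = if (length(nd$parents))
        vapply(nd$parents, as.character, character(1)) else character(),
      cpt = vapply(nd$cpt, as.numeric, numeric(1)))
  }
  bayes_net(nodes)
}

#' Export a network structure as Graphviz DOT
#'
#' @param net a [bayes_net()] or [dag()].
#' @return A single DOT document string with one `->` line per directed
#'   edge.
#' @export
export_dot <- function(net) {
  e <- dag_edges(net)
  nodes <- if (inherits(net, "bayes_net")) names(net$nodes) else net$nodes
  paste0("digraph bn {\n",
         paste0("  \"", nodes, "\";\n", collapse = ""),
         paste0(sprintf("  \"%s\" -> \"%s\";\n", e$from, e$to),
                collapse = ""),
         "}\n")
}
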