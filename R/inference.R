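# Factors for variable elimination: scope (node names), dims, and a table
# of nonnegative reals in array order (first scope variable fastest).

new_factor <- function(scope, dims, table) {
  stopifnot(length(table) == prod(dims), all(is.finite(table)),
            all(table >= -1e-15))
  list(scope = scope, dims = as.integer(dims), table = as.numeric(table))
}

# strides of each scope variable within the factor's flat table
f_strides <- function(f) {
  s <- cumprod(c(1L, f$dims))[seq_along(f$dims)]
  stats::setNames(s, f$scope)
}

# pointwise product over the union scope
factor_product <- function(a, b) {
  scope <- union(a$scope, b$scope)
  dims <- integer(length(scope))
  dims[match(a$scope, scope)] <- a$dims
  dims[match(b$scope, scope)] <- b$dims
  total <- prod(dims)
  cell <- 0:(total - 1L)
  stride_u <- cumprod(c(1L, dims))[seq_along(dims)]
  state <- lapply(seq_along(scope), function(v)
    (cell %/% stride_u[v]) %% dims[v])
  idx_into <- function(f) {
    st <- f_strides(f)
    i <- rep_len(0L, total)
    for (v in f$scope)
      i <- i + state[[match(v, scope)]] * st[[v]]
    i + 1L
  }
  new_factor(scope, dims, a$table[idx_into(a)] * b$table[idx_into(b)])
}

# sum a variable out of a factor
factor_marginalize <- function(f, var) {
  k <- match(var, f$scope)
  if (is.na(k)) return(f)
  arr <- array(f$table, dim = f$dims)
  perm <- c(setdiff(seq_along(f$dims), k), k)
  arr <- aperm(arr, perm)
  out <- rowSums(matrix(arr, ncol = f$dims[k]))
  new_factor(f$scope[-k], f$dims[-k], out)
}

# condition a factor on observed states (drops observed variables)
factor_reduce <- function(f, evidence_idx) {
  hit <- intersect(f$scope, names(evidence_idx))
  if (!length(hit)) return(f)
  keep_state <- lapply(f$scope, function(v)
    if (v %in% hit) evidence_idx[[v]] else seq_len(f$dims[match(v, f$scope)]))
  arr <- array(f$table, dim = f$dims)
  sub <- do.call(`[`, c(list(arr), keep_state, list(drop = FALSE)))
  keep <- !(f$scope %in% hit)
  new_factor(f$scope[keep], f$dims[keep], as.numeric(sub))
}

#' Exact posterior query by variable elimination
#'
#' Computes `P(target | evidence)` exactly: every CPT becomes a factor,
#' factors are conditioned on the evidence, all remaining non-target
#' variables are summed out by sum-product elimination in a min-degree
#' order, and the result is normalized. Equivalent to full joint
#' enumeration on any network.
#'
#' @param net a [bayes_net()].
#' @param target node to query.
#' @param evidence named list or vector of observed states (state labels,
#'   or state indices); must not include `target`.
#' @param elim_order optional explicit elimination order (a permutation of
#'   the non-target, non-evidence nodes); the posterior is identical for
#'   every valid order. Default: min-degree heuristic.
#' @return An object of class `"posterior"`: `node` and `probabilities`
#'   (named numeric vector summing to 1).
#' @export
query <- function(net, target, evidence = list(), elim_order = NULL) {
  stopifnot(inherits(net, "bayes_net"))
  if (!target %in% names(net$nodes)) stop("unknown node: ", target)
  evidence <- as.list(evidence)
  if (target %in% names(evidence))
    stop("query node must not appear in the evidence")
  ev_idx <- list()
  for (nm in names(evidence)) {
    if (!nm %in% names(net$nodes)) stop("unknown evidence node: ", nm)
    st <- as.character(evidence[[nm]])
    k <- match(st, net$nodes[[nm]]$states)
    if (is.na(k)) stop("state '", st, "' is not a state of '", nm, "'")
    ev_idx[[nm]] <- k
  }
  factors <- lapply(names(net$nodes), function(nm) {
    nd <- net$nodes[[nm]]
    scope <- c(nm, nd$parents)
    dims <- vapply(net$nodes[scope], function(x) length(x$states),
                   integer(1))
    factor_reduce(new_factor(scope, dims, as.numeric(nd$cpt)), ev_idx)
  })
  to_eliminate <- setdiff(names(net$nodes), c(target, names(ev_idx)))
  if (!is.null(elim_order)) {
    if (!setequal(elim_order, to_eliminate))
      stop("elim_order must be a permutation of the non-target, ",
           "non-evidence nodes")
    elim_order <- as.character(elim_order)
  }
  # min-degree elimination order on the factor interaction graph, unless
  # an explicit order is supplied
  while (length(to_eliminate)) {
    v <- if (!is.null(elim_order)) {
      elim_order[match(TRUE, elim_order %in% to_eliminate)]
    } else {
      degree <- vapply(to_eliminate, function(v) {
        nb <- unique(unlist(lapply(factors, function(f)
          if (v %in% f$scope) f$scope else NULL)))
        length(setdiff(nb, v))
      }, integer(1))
      to_eliminate[order(degree, to_eliminate)][1L]
    }
    touch <- vapply(factors, function(f) v %in% f$scope, logical(1))
    if (any(touch)) {
      joint <- Reduce(factor_product, factors[touch])
      factors <- c(factors[!touch], list(factor_marginalize(joint, v)))
    }
    to_eliminate <- setdiff(to_eliminate, v)
  }
  res <- Reduce(factor_product, factors)
  # any residual scalar factors have empty scope; res scope is target only
  stopifnot(identical(res$scope, target))
  z <- sum(res$table)
  if (z <= 0) stop("impossible evidence: zero probability under the network")
  structure(list(node = target,
                 probabilities = stats::setNames(res$table / z,
                                                 net$nodes[[target]]$states)),
            class = "posterior")
}

#' @export
print.posterior <- function(x, ...) {
  cat(sprintf("<posterior> P(%s | evidence):\n", x$node))
  print(round(x$probabilities, 4))
  invisible(x)
}

#' Predictive disease probability
#'
#' The posterior mass on the disease node's "present" state given observed
#' risk-factor states (cause-to-effect reasoning).
#'
#' @param net a [bayes_net()].
#' @param disease binary disease node.
#' @param evidence named list of observed states (see [query()]).
#' @param yes_state state label counted as disease present; defaults to
#'   the node's second state.
#' @return Numeric scalar `P(disease = yes | evidence)`.
#' @export
predictive_probability <- function(net, disease, evidence = list(),
                                   yes_state = NULL) {
  stopifnot(inherits(net, "bayes_net"))
  states <- net$nodes[[disease]]$states
  if (length(states) != 2L) stop("disease node must be binary")
  if (is.null(yes_state)) yes_state <- states[2L]
  if (!yes_state %in% states) stop("unknown disease state: ", yes_state)
  unname(query(net, disease, evidence)$probabilities[[yes_state]])
}

#' Diagnostic profile of a clamped disease node
#'
#' Effect-to-cause reasoning: the disease node is clamped to a state and
#' every other node's posterior is compared with its prior. The reported
#' `delta` is the signed change in probability (percentage points / 100)
#' per state.
#'
#' @param net a [bayes_net()].
#' @param disease binary disease node.
#' @param state clamped state; defaults to the node's second state.
#' @return data.frame: node, state, prior, posterior, delta.
#' @export
diagnostic_profile <- function(net, disease, state = NULL) {
  stopifnot(inherits(net, "bayes_net"))
  states <- net$nodes[[disease]]$states
  if (length(states) != 2L) stop("disease node must be binary")
  if (is.null(state)) state <- states[2L]
  others <- setdiff(names(net$nodes), disease)
  ev <- stats::setNames(list(state), disease)
  rows <- lapply(others, function(nd) {
    prior <- query(net, nd)$probabilities
    post <- query(net, nd, ev)$probabilities
    data.frame(node = nd, state = names(prior), prior = unname(prior),
               posterior = unname(post), delta = unname(post - prior),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify a record by its disease posterior
#'
#' Computes the predictive probability from whatever subset of non-disease
#' nodes the record observes — absent variables are simply marginalized
#' out by exact inference, so incomplete records need no imputation — and
#' thresholds it.
#'
#' @param net a [bayes_net()].
#' @param disease binary disease node.
#' @param record named list/vector of observed states for any subset of
#'   the non-disease nodes.
#' @param threshold classification cut-off on the posterior (default 0.5).
#' @param yes_state see [predictive_probability()].
#' @return list with `label` (`yes_state` or the complementary state) and
#'   `probability`.
#' @export
classify <- function(net, disease, record, threshold = 0.5,
                     yes_state = NULL) {
  states <- net$nodes[[disease]]$states
  if (is.null(yes_state)) yes_state <- states[2L]
  record <- as.list(record)
  record <- record[setdiff(names(record), disease)]
  p <- predictive_probability(net, disease, record, yes_state)
  list(label = if (p > threshold) yes_state
               else setdiff(states, yes_state),
       probability = p)
}
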