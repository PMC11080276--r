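#' Maximum-likelihood conditional probability tables
#'
#' Fits one CPT per node of a learned DAG from discrete training data by
#' pure maximum likelihood: `theta = N_jk / N_j`, with no smoothing by
#' default, so structural zeros print as exact 0.000 entries. Parent
#' configurations never observed in training receive the uniform row (so
#' downstream inference stays defined) and are flagged with a warning.
#' State vocabularies default to the factor levels (or sorted unique codes)
#' seen in the data; pass `states` explicitly when the data may not exhibit
#' every declared state.
#'
#' @param g a [dag()].
#' @param train discrete data.frame containing every node column.
#' @param states optional named list of state-label vectors per node.
#' @param smooth additive pseudo-count per cell (default 0 = pure MLE).
#' @return A [bayes_net()]; each node additionally carries `config_n`, the
#'   per-parent-configuration sample count.
#' @export
fit_cpts <- function(g, train, states = NULL, smooth = 0) {
  stopifnot(inherits(g, "dag"), is.data.frame(train))
  if (!nrow(train)) stop("empty training set")
  dm <- as_discrete_matrix(train, g$nodes)
  if (!is.null(states)) {
    for (nd in g$nodes) {
      if (is.null(states[[nd]])) next
      want <- as.character(states[[nd]])
      if (!all(dm$levels[[nd]] %in% want))
        stop("data for '", nd, "' contains undeclared states")
      remap <- match(dm$levels[[nd]], want)
      dm$m[, nd] <- remap[dm$m[, nd]]
      dm$levels[[nd]] <- want
      dm$nlev[[nd]] <- length(want)
    }
  }
  empty_cfg <- character()
  nodes <- list()
  for (nd in g$nodes) {
    pa <- g$parents[[nd]]
    r <- dm$nlev[[nd]]
    q <- prod(dm$nlev[pa])
    if (length(pa)) {
      conf <- rep_len(1L, nrow(dm$m))
      stride <- 1L
      for (p in pa) {
        conf <- conf + (dm$m[, p] - 1L) * stride
        stride <- stride * dm$nlev[[p]]
      }
    } else conf <- rep_len(1L, nrow(dm$m))
    counts <- matrix(tabulate(dm$m[, nd] + r * (conf - 1L), nbins = r * q),
                     nrow = r)
    counts <- counts + smooth
    Nj <- colSums(counts)
    theta <- counts
    for (j in seq_len(q)) {
      if (Nj[j] > 0) theta[, j] <- counts[, j] / Nj[j]
      else {
        theta[, j] <- 1 / r
        empty_cfg <- c(empty_cfg, nd)
      }
    }
    nodes[[nd]] <- list(states = dm$levels[[nd]], parents = pa,
                        cpt = array(theta, dim = c(r, dm$nlev[pa])),
                        config_n = Nj)
  }
  if (length(empty_cfg))
    warning("unobserved parent configuration(s) for node(s) ",
            paste(unique(empty_cfg), collapse = ", "),
            ": uniform rows substituted")
  bayes_net(nodes)
}

#' Prior marginal distribution of every node
#'
#' The no-evidence marginal of each node, computed by exact inference.
#'
#' @param net a [bayes_net()].
#' @return Named list of probability vectors (named by state).
#' @export
prior_marginals <- function(net) {
  stopifnot(inherits(net, "bayes_net"))
  lapply(stats::setNames(names(net$nodes), names(net$nodes)),
         function(nd) query(net, nd)$probabilities)
}
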