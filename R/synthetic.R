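#' Simulate a case-control cohort from group profiles
#'
#' Marginal-matching simulation: within each group, categorical variables
#' are drawn independently from their profile marginals and continuous
#' variables from normals truncated at 0 (mean/SD profiles) or log-normals
#' matched to the median and quartile ratio (median/quartile profiles).
#' Dependence between variables enters only through group membership, which
#' is what group-level marginal summaries can support; use
#' [generate_from_bn()] when a known joint distribution is required.
#'
#' Each group draws from its own seeded substream (a fixed offset from
#' `seed`), so adding or reordering groups does not perturb the others.
#'
#' @param profiles named list of [group_profile()] objects.
#' @param seed integer seed; the same seed always yields the same table.
#' @return A data.frame with one row per subject, a `group` column, and all
#'   profile variables; exactly `sum(n)` rows, no missing cells.
#' @export
generate_case_control <- function(profiles, seed = 1L) {
  stopifnot(is.list(profiles), length(profiles) > 0L)
  blocks <- vector("list", length(profiles))
  for (g in seq_along(profiles)) {
    pr <- profiles[[g]]
    stopifnot(inherits(pr, "group_profile"))
    set.seed((as.integer(seed) + 7919L * g) %% 2147483647L)
    n <- pr$n
    cols <- list(group = rep(pr$group, n))
    for (nm in names(pr$categorical)) {
      p <- pr$categorical[[nm]]
      cols[[nm]] <- as.integer(sample(names(p), n, replace = TRUE, prob = p))
    }
    for (nm in names(pr$continuous)) {
      cs <- pr$continuous[[nm]]
      if (!is.null(cs$mean)) {
        x <- stats::rnorm(n, cs$mean, cs$sd)
        # physical floor at 0: resample the (rare) negative draws
        while (any(bad <- x < 0))
          x[bad] <- stats::rnorm(sum(bad), cs$mean, cs$sd)
      } else {
        mulog <- log(cs$median)
        sdlog <- if (cs$p75 > cs$p25)
          log(cs$p75 / cs$p25) / (2 * stats::qnorm(0.75)) else 0
        x <- stats::rlnorm(n, mulog, sdlog)
      }
      cols[[nm]] <- round(x, 2)
    }
    blocks[[g]] <- as.data.frame(cols, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}

#' Declare a ground-truth network for recovery testing
#'
#' Wraps a [bayes_net()] as sampling truth together with the name of its
#' (binary) disease node, for use with [generate_from_bn()] and the
#' structure/parameter recovery tests.
#'
#' @param net a [bayes_net()].
#' @param disease name of a binary node of `net`.
#' @return An object of class `"ground_truth_net"`.
#' @export
ground_truth_net <- function(net, disease) {
  stopifnot(inherits(net, "bayes_net"), disease %in% names(net$nodes))
  if (length(net$nodes[[disease]]$states) != 2L)
    stop("disease node '", disease, "' must be binary")
  structure(list(net = net, disease = disease), class = "ground_truth_net")
}

#' Forward-sample records from a Bayesian network
#'
#' Ancestral sampling: nodes are visited in topological order and each is
#' drawn from its CPT row given its sampled parents. Deterministic for a
#' fixed seed.
#'
#' @param truth a [bayes_net()] or [ground_truth_net()].
#' @param n number of records.
#' @param seed integer seed.
#' @return A data.frame of factors, one column per node, levels equal to the
#'   node's states.
#' @export
generate_from_bn <- function(truth, n, seed = 1L) {
  net <- if (inherits(truth, "ground_truth_net")) truth$net else truth
  stopifnot(inherits(net, "bayes_net"), n > 0)
  ord <- topo_sort(net)
  if (is.null(ord)) stop("cyclic structure cannot be sampled")
  set.seed(as.integer(seed) %% 2147483647L)
  n <- as.integer(n)
  drawn <- list()  # per node: integer state index per record
  for (nm in ord) {
    nd <- net$nodes[[nm]]
    r <- length(nd$states)
    probs <- matrix(nd$cpt, nrow = r)  # r x (parent configurations)
    if (length(nd$parents)) {
      conf <- rep_len(1L, n)
      stride <- 1L
      for (p in nd$parents) {
        conf <- conf + (drawn[[p]] - 1L) * stride
        stride <- stride * length(net$nodes[[p]]$states)
      }
    } else {
      conf <- rep_len(1L, n)
    }
    cum <- apply(probs, 2, cumsum)              # r x q
    u <- stats::runif(n)
    ge <- t(cum[, conf, drop = FALSE]) >= u - 1e-15   # n x r
    drawn[[nm]] <- max.col(ge, ties.method = "first")
  }
  out <- lapply(names(net$nodes), function(nm)
    factor(net$nodes[[nm]]$states[drawn[[nm]]],
           levels = net$nodes[[nm]]$states))
  stats::setNames(as.data.frame(out, stringsAsFactors = TRUE),
                  names(net$nodes))
}
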