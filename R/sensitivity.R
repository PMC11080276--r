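#' Variance reduction of a target node by one finding
#'
#' Netica-style sensitivity: with the binary target valued as a 0/1
#' indicator, the prior variance is `V = p(1-p)` with `p = P(target =
#' yes)`; learning the finding's state `f` leaves conditional variance
#' `V_f = p_f(1-p_f)` with `p_f = P(target = yes | finding = f)`. The
#' reported quantity is the expected variance reduction as a percentage of
#' the prior variance, `100 (V - sum_f P(f) V_f) / V`. It is 0 exactly
#' when the finding is independent of the target under the network and 100
#' when the finding determines it. All probabilities come from exact
#' inference.
#'
#' @param net a [bayes_net()].
#' @param target binary target node.
#' @param finding a different node of the network.
#' @param yes_state target state counted as 1 (default: second state).
#' @return Percentage in `[0, 100]`, or `NA` if the prior variance is 0.
#' @export
variance_reduction <- function(net, target, finding, yes_state = NULL) {
  stopifnot(inherits(net, "bayes_net"))
  states <- net$nodes[[target]]$states
  if (length(states) != 2L) stop("target node must be binary")
  if (identical(target, finding)) stop("finding must differ from target")
  if (is.null(yes_state)) yes_state <- states[2L]
  p <- query(net, target)$probabilities[[yes_state]]
  v <- p * (1 - p)
  if (v <= 0) {
    warning("degenerate prior for '", target, "': variance reduction ",
            "not available")
    return(NA_real_)
  }
  pf <- query(net, finding)$probabilities
  ev <- 0
  for (st in names(pf)) {
    if (pf[[st]] <= 0) next
    pcond <- query(net, target,
                   stats::setNames(list(st), finding))$probabilities[[yes_state]]
    ev <- ev + pf[[st]] * pcond * (1 - pcond)
  }
  min(100, max(0, 100 * (v - ev) / v))
}

#' Sensitivity ranking of all findings for a target
#'
#' [variance_reduction()] for every non-target node, sorted in descending
#' order (ties broken by node name). Optionally also reports the mutual
#' information between finding and target (Netica's entropy reduction,
#' in bits) as a secondary column.
#'
#' @param net a [bayes_net()].
#' @param target binary target node.
#' @param include_mi add a `mutual_information` column (default `FALSE`).
#' @param yes_state see [variance_reduction()].
#' @return data.frame of class `"sensitivity_report"`: variable,
#'   variance_reduction_pct, rank (and optionally mutual_information).
#' @export
sensitivity_table <- function(net, target, include_mi = FALSE,
                              yes_state = NULL) {
  findings <- setdiff(names(net$nodes), target)
  vr <- vapply(findings, function(f)
    variance_reduction(net, target, f, yes_state), numeric(1))
  out <- data.frame(variable = findings,
                    variance_reduction_pct = unname(vr),
                    stringsAsFactors = FALSE)
  if (include_mi) {
    out$mutual_information <- vapply(findings, function(f) {
      pf <- query(net, f)$probabilities
      pt <- query(net, target)$probabilities
      mi <- 0
      for (st in names(pf)) {
        if (pf[[st]] <= 0) next
        pc <- query(net, target,
                    stats::setNames(list(st), f))$probabilities
        for (ts in names(pc)) {
          if (pc[[ts]] <= 0 || pt[[ts]] <= 0) next
          mi <- mi + pf[[st]] * pc[[ts]] * log2(pc[[ts]] / pt[[ts]])
        }
      }
      max(0, mi)
    }, numeric(1))
  }
  out <- out[order(-out$variance_reduction_pct, out$variable), ,
             drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("sensitivity_report", "data.frame")
  out
}
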