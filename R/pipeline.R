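#' Full risk-factor network analysis for one disease
#'
#' Runs the complete pipeline for one case group against the controls:
#'
#' 1. univariate screening at `alpha` ([screen_variables()]);
#' 2. forward stepwise logistic selection by likelihood ratio
#'    ([stepwise_forward_lr()]) on the screened variables;
#' 3. discretization of continuous variables ([discretize()]) and addition
#'    of a binary disease node (states `no`/`yes`) named after the case
#'    group;
#' 4. a stratified train/test split ([train_test_split()]);
#' 5. tabu-search BIC structure learning over the selected variables plus
#'    the disease node, under the epidemiological default constraints
#'    ([default_constraints()]) unless overridden;
#' 6. maximum-likelihood CPTs ([fit_cpts()]) with the codebook's full
#'    state vocabularies;
#' 7. hold-out evaluation ([evaluate_bn()]) and variance-reduction
#'    sensitivity analysis ([sensitivity_table()]).
#'
#' @param cohort encoded cohort data.frame (see [encode_dataset()]) with a
#'   `group` column.
#' @param case_group case-group label; becomes the disease node name.
#' @param cb a [codebook()].
#' @param seed integer seed driving the split (structure learning is
#'   deterministic given the training data).
#' @param alpha univariate screening threshold.
#' @param p_enter,p_remove stepwise entry/removal thresholds.
#' @param train_fraction training fraction of the split.
#' @param constraints [edge_constraints()]; default: no edges into
#'   immutable characteristics.
#' @param params [search_params()] for the tabu search.
#' @param threshold classification cut-off.
#' @param control_group control-group label.
#' @return list of class `"bn_disease_model"`: `screening`, `stepwise`,
#'   `selected`, `split`, `structure` (scored DAG), `net`, `evaluation`,
#'   `sensitivity`, `disease`.
#' @export
bn_disease_model <- function(cohort, case_group, cb = default_codebook(),
                             seed = 1L, alpha = 0.05, p_enter = 0.05,
                             p_remove = 0.10, train_fraction = 0.7,
                             constraints = NULL, params = search_params(),
                             threshold = 0.5, control_group = "control") {
  scr <- screen_variables(cohort, case_group, cb, alpha,
                          control_group = control_group)
  sw <- stepwise_forward_lr(cohort, case_group, scr$selected, cb,
                            p_enter, p_remove,
                            control_group = control_group)
  selected <- sw$selected
  if (!length(selected))
    stop("stepwise selection retained no variables; no network to learn")
  sub <- cohort[cohort$group %in% c(control_group, case_group), ,
                drop = FALSE]
  disc <- discretize(sub, cb)
  disease <- case_group
  disc[[disease]] <- ifelse(disc$group == case_group, "yes", "no")
  split <- train_test_split(disc, train_fraction, seed)
  nodes <- c(selected, disease)
  if (is.null(constraints)) constraints <- default_constraints(nodes)
  sd <- tabu_search(split$train, nodes, constraints, params)
  states <- lapply(stats::setNames(nodes, nodes), function(nd) {
    if (nd == disease) return(c("no", "yes"))
    spec <- cb$variables[[nd]]
    if (spec$kind == "categorical") as.character(sort(spec$states))
    else as.character(sort(spec$bin_codes))
  })
  net <- suppressWarnings(fit_cpts(sd$dag, split$train, states = states))
  ev <- evaluate_bn(net, split$test, disease, threshold)
  sens <- sensitivity_table(net, disease)
  structure(list(screening = scr, stepwise = sw, selected = selected,
                 split = split, structure = sd, net = net,
                 evaluation = ev, sensitivity = sens, disease = disease),
            class = "bn_disease_model")
}

#' @export
print.bn_disease_model <- function(x, ...) {
  cat(sprintf("<bn_disease_model> %s: %d variables selected -> %d-node net\n",
              x$disease, length(x$selected), length(x$net$nodes)))
  print(x$evaluation$metrics)
  print(x$evaluation$roc)
  invisible(x)
}
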