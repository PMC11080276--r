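# Shared fixtures and independent oracles, all built in code.

# two-node net A -> D with hand-computable posteriors
toy_net_2 <- function() {
  bayes_net(list(
    A = list(states = c("0", "1"), parents = character(), cpt = c(0.7, 0.3)),
    D = list(states = c("no", "yes"), parents = "A",
             cpt = c(0.8, 0.2, 0.2, 0.8))))
}

chain_net <- function() {
  bayes_net(list(
    A = list(states = c("0", "1"), parents = character(), cpt = c(0.4, 0.6)),
    B = list(states = c("0", "1"), parents = "A",
             cpt = c(0.9, 0.1, 0.1, 0.9)),
    C = list(states = c("0", "1"), parents = "B",
             cpt = c(0.85, 0.15, 0.2, 0.8))))
}

vstruct_net <- function() {
  bayes_net(list(
    A = list(states = c("0", "1"), parents = character(), cpt = c(0.5, 0.5)),
    B = list(states = c("0", "1"), parents = character(), cpt = c(0.5, 0.5)),
    C = list(states = c("0", "1"), parents = c("A", "B"),
             cpt = c(0.9, 0.1, 0.5, 0.5, 0.5, 0.5, 0.1, 0.9))))
}

# 8-node strong-signal ground truth: every conditional probability is 0.1
# or 0.9 and the CPDAG is fully compelled (two v-structures + Meek closure).
# Each v-structure pairs a chain node with a marginally independent root so
# the instance is well-conditioned for score-based recovery.
strong8_net <- function() {
  or_cpt <- function() c(0.9, 0.1,  0.1, 0.9,  0.1, 0.9,  0.1, 0.9)
  bayes_net(list(
    A = list(states = c("0", "1"), parents = character(), cpt = c(0.5, 0.5)),
    B = list(states = c("0", "1"), parents = character(), cpt = c(0.5, 0.5)),
    C = list(states = c("0", "1"), parents = c("A", "B"), cpt = or_cpt()),
    D = list(states = c("0", "1"), parents = "C", cpt = c(0.9, 0.1, 0.1, 0.9)),
    E = list(states = c("0", "1"), parents = "D", cpt = c(0.1, 0.9, 0.9, 0.1)),
    F = list(states = c("0", "1"), parents = character(), cpt = c(0.5, 0.5)),
    G = list(states = c("0", "1"), parents = c("E", "F"), cpt = or_cpt()),
    H = list(states = c("0", "1"), parents = "G", cpt = c(0.9, 0.1, 0.1, 0.9))))
}

# net embedding the published CAD conditional probability table:
# P(CAD = yes | age, smoke, SBP) for 3 x 4 x 2 parent configurations
cad_printed_net <- function() {
  p_yes <- array(0, dim = c(3, 4, 2))   # age x smoke x sbp
  p_yes[, , 1] <- matrix(c(0.018, 0.383, 0.774,
                           0.021, 0.400, 0.619,
                           0.235, 0.556, 0.902,
                           0.000, 0.666, 0.824), nrow = 3)
  p_yes[, , 2] <- matrix(c(0.040, 0.482, 0.863,
                           0.000, 0.875, 0.958,
                           0.333, 0.778, 0.933,
                           0.000, 0.750, 0.826), nrow = 3)
  cpt <- array(0, dim = c(2, 3, 4, 2))
  cpt[1, , , ] <- 1 - p_yes
  cpt[2, , , ] <- p_yes
  bayes_net(list(
    age = list(states = c("18-44", "45-59", "60~"), parents = character(),
               cpt = c(1, 1, 1) / 3),
    smoke = list(states = c("never", "occasionally", "often", "quitting"),
                 parents = character(), cpt = rep(0.25, 4)),
    sbp = list(states = c("normal", "abnormal"), parents = character(),
               cpt = c(0.5, 0.5)),
    CAD = list(states = c("no", "yes"), parents = c("age", "smoke", "sbp"),
               cpt = as.numeric(cpt))))
}

# random DAG over n binary nodes with random CPTs (for inference oracles)
random_binary_net <- function(n_nodes, seed, edge_prob = 0.4) {
  set.seed(seed)
  nm <- LETTERS[seq_len(n_nodes)]
  nodes <- list()
  for (i in seq_len(n_nodes)) {
    pa <- nm[seq_len(i - 1L)][stats::runif(i - 1L) < edge_prob]
    q <- 2^length(pa)
    p1 <- stats::runif(q, 0.05, 0.95)
    nodes[[nm[i]]] <- list(states = c("0", "1"), parents = pa,
                           cpt = as.numeric(rbind(1 - p1, p1)))
  }
  bayes_net(nodes)
}

# ORACLE: full-joint enumeration. Returns a data.frame with one row per
# joint state (columns = node states as labels) and a `prob` column.
joint_enumeration <- function(net) {
  nodes <- names(net$nodes)
  grids <- lapply(net$nodes, function(nd) nd$states)
  grid <- expand.grid(grids, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  prob <- rep(1, nrow(grid))
  for (nm in nodes) {
    nd <- net$nodes[[nm]]
    ci <- match(grid[[nm]], nd$states)
    if (length(nd$parents)) {
      conf <- rep_len(1L, nrow(grid))
      stride <- 1L
      for (p in nd$parents) {
        conf <- conf + (match(grid[[p]], net$nodes[[p]]$states) - 1L) * stride
        stride <- stride * length(net$nodes[[p]]$states)
      }
    } else conf <- rep_len(1L, nrow(grid))
    r <- length(nd$states)
    flat <- as.numeric(nd$cpt)
    prob <- prob * flat[ci + r * (conf - 1L)]
  }
  grid$prob <- prob
  grid
}

# ORACLE: P(target | evidence) by summing the enumerated joint
enum_posterior <- function(net, target, evidence = list()) {
  j <- joint_enumeration(net)
  keep <- rep(TRUE, nrow(j))
  for (nm in names(evidence))
    keep <- keep & j[[nm]] == as.character(evidence[[nm]])
  j <- j[keep, ]
  states <- net$nodes[[target]]$states
  p <- vapply(states, function(s) sum(j$prob[j[[target]] == s]), numeric(1))
  p / sum(p)
}

# ORACLE: all DAGs on the given nodes (enumerate orientation of each pair,
# filter acyclic); 25 DAGs for 3 nodes
all_dags <- function(nodes) {
  pairs <- t(utils::combn(nodes, 2))
  k <- nrow(pairs)
  out <- list()
  for (code in seq_len(3^k) - 1L) {
    digits <- (code %/% 3^(seq_len(k) - 1L)) %% 3L
    edges <- data.frame(from = character(), to = character())
    for (i in seq_len(k)) {
      if (digits[i] == 1L)
        edges <- rbind(edges, data.frame(from = pairs[i, 1], to = pairs[i, 2]))
      if (digits[i] == 2L)
        edges <- rbind(edges, data.frame(from = pairs[i, 2], to = pairs[i, 1]))
    }
    g <- tryCatch(dag(nodes, edges), error = function(e) NULL)
    if (!is.null(g)) out[[length(out) + 1L]] <- g
  }
  out
}

# small encoded cohort for fast pipeline-stage tests
small_cohort <- function(seed = 42) {
  pr <- reference_profiles()
  shrink <- function(p, n) { p$n <- n; p }
  pr$control <- shrink(pr$control, 250)
  pr$T2DM <- shrink(pr$T2DM, 250)
  pr$CAD <- shrink(pr$CAD, 200)
  pr$comorbidity <- shrink(pr$comorbidity, 150)
  generate_case_control(pr, seed = seed)
}
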