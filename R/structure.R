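# Internal: coerce a fully discrete data.frame to a 1-based integer matrix
# plus per-column level vocabularies (factor levels, or sorted unique codes).
as_discrete_matrix <- function(data, nodes = names(data)) {
  bad <- setdiff(nodes, names(data))
  if (length(bad)) stop("node absent from data: ", bad[1L])
  levels <- vector("list", length(nodes))
  names(levels) <- nodes
  m <- matrix(0L, nrow(data), length(nodes), dimnames = list(NULL, nodes))
  for (j in seq_along(nodes)) {
    x <- data[[nodes[j]]]
    if (is.factor(x)) {
      levels[[j]] <- levels(x)
      m[, j] <- as.integer(x)
    } else {
      lv <- sort(unique(x))
      levels[[j]] <- as.character(lv)
      m[, j] <- match(x, lv)
    }
    if (anyNA(m[, j])) stop("missing value in column '", nodes[j], "'")
    if (length(levels[[j]]) < 1L) stop("empty column '", nodes[j], "'")
  }
  list(m = m, levels = levels, nlev = lengths(levels))
}

# Internal: BIC family score for one child given a parent set.
# log-likelihood term sum_jk N_jk log(N_jk / N_j) minus (log n)/2 * q(r-1);
# families whose parent-configuration count exceeds 2^20 score -Inf.
family_score_bic <- function(dm, child, parents, penalty = TRUE) {
  r <- dm$nlev[[child]]
  q <- prod(dm$nlev[parents])
  if (q * r > 2^20) return(-Inf)
  ci <- dm$m[, child]
  if (length(parents)) {
    conf <- rep_len(1L, nrow(dm$m))
    stride <- 1L
    for (p in parents) {
      conf <- conf + (dm$m[, p] - 1L) * stride
      stride <- stride * dm$nlev[[p]]
    }
  } else conf <- rep_len(1L, nrow(dm$m))
  counts <- tabulate(ci + r * (conf - 1L), nbins = r * q)
  N <- matrix(counts, nrow = r)
  Nj <- colSums(N)
  pos <- N > 0
  ll <- sum(N[pos] * (log(N[pos]) - rep(log(pmax(Nj, 1)), each = r)[pos]))
  if (!penalty) return(ll)
  ll - log(nrow(dm$m)) / 2 * q * (r - 1)
}

#' BIC score of a DAG on discrete data
#'
#' The Bayesian information criterion in its decomposable form: per node
#' family, the maximized multinomial log-likelihood of the child given its
#' parents minus `(log n)/2` times the family's free-parameter count
#' `q (r - 1)` (with `r` child states and `q` parent configurations).
#' Higher is better. `0 log 0` is taken as 0.
#'
#' @param g a [dag()] whose nodes are columns of `data`.
#' @param data fully discrete data.frame (factors or integer codes).
#' @param penalty set `FALSE` for the log-likelihood-only score.
#' @return An object of class `"scored_dag"`: the `dag`, the total `score`,
#'   and the per-family score vector `family_scores`.
#' @export
bic_score <- function(g, data, penalty = TRUE) {
  stopifnot(inherits(g, "dag"))
  dm <- as_discrete_matrix(data, g$nodes)
  fs <- vapply(g$nodes, function(nd)
    family_score_bic(dm, nd, g$parents[[nd]], penalty), numeric(1))
  structure(list(dag = g, score = sum(fs), family_scores = fs),
            class = "scored_dag")
}

#' @export
print.scored_dag <- function(x, ...) {
  cat(sprintf("<scored_dag> score = %.4f\n", x$score))
  print(x$dag)
  invisible(x)
}

#' Expert edge constraints
#'
#' @param whitelist,blacklist data.frames with columns `from`, `to` (either
#'   may be `NULL`). Whitelisted edges are forced present (never deleted or
#'   reversed); blacklisted edges are never added. The two sets must be
#'   disjoint and the whitelist alone acyclic.
#' @return An object of class `"edge_constraints"`.
#' @export
edge_constraints <- function(whitelist = NULL, blacklist = NULL) {
  norm <- function(x) {
    if (is.null(x) || NROW(x) == 0L)
      return(data.frame(from = character(), to = character(),
                        stringsAsFactors = FALSE))
    x <- as.data.frame(x, stringsAsFactors = FALSE)
    names(x)[1:2] <- c("from", "to")
    x$from <- as.character(x$from); x$to <- as.character(x$to)
    unique(x[c("from", "to")])
  }
  wl <- norm(whitelist); bl <- norm(blacklist)
  key <- function(d) paste(d$from, d$to, sep = "\r")
  if (length(intersect(key(wl), key(bl))))
    stop("whitelist and blacklist overlap")
  if (nrow(wl)) {
    nodes <- unique(c(wl$from, wl$to))
    dag(nodes, wl)  # errors if the whitelist alone is cyclic
  }
  structure(list(whitelist = wl, blacklist = bl),
            class = "edge_constraints")
}

#' Default epidemiological constraint set
#'
#' Blacklists every edge into the immutable-characteristic nodes present in
#' `nodes` (age, sex, area/region, and family-history nodes): fixed
#' attributes cannot be effects of other variables. This is the standard
#' encoding of expert prior knowledge for risk-factor networks and is fully
#' overridable.
#'
#' @param nodes node names of the learning problem.
#' @param immutable the nodes protected from incoming edges.
#' @return An [edge_constraints()] object.
#' @export
default_constraints <- function(nodes,
                                immutable = c("age", "sex", "area",
                                              "fhx_dm", "fhx_cad")) {
  targets <- intersect(immutable, nodes)
  if (!length(targets)) return(edge_constraints())
  bl <- expand.grid(from = nodes, to = targets, stringsAsFactors = FALSE)
  bl <- bl[bl$from != bl$to, ]
  edge_constraints(blacklist = bl)
}

# Internal: is there a directed path from `from` to `to`?
# `skip` optionally names one edge (from_, to_) to ignore.
has_path <- function(parents, from, to, skip = NULL) {
  children <- stats::setNames(rep(list(character()), length(parents)),
                              names(parents))
  for (nd in names(parents))
    for (p in parents[[nd]]) {
      if (!is.null(skip) && p == skip[1L] && nd == skip[2L]) next
      children[[p]] <- c(children[[p]], nd)
    }
  frontier <- from
  visited <- character()
  while (length(frontier)) {
    nd <- frontier[1L]; frontier <- frontier[-1L]
    if (nd == to) return(TRUE)
    if (nd %in% visited) next
    visited <- c(visited, nd)
    frontier <- c(frontier, children[[nd]])
  }
  FALSE
}

#' Enumerate legal single-edge moves
#'
#' All additions, deletions and reversals of one edge that keep the graph
#' acyclic and satisfy the constraints: blacklisted edges are never added
#' (or created by reversal), whitelisted edges are never deleted or
#' reversed. Moves are returned in the deterministic tie-break order (move
#' type, then source, then target).
#'
#' @param g a [dag()].
#' @param constraints an [edge_constraints()] or `NULL`.
#' @return data.frame with columns `type` (`"add"`/`"delete"`/`"reverse"`),
#'   `from`, `to`.
#' @export
legal_moves <- function(g, constraints = NULL) {
  stopifnot(inherits(g, "dag"))
  wl_key <- bl_key <- character()
  if (!is.null(constraints)) {
    wl_key <- paste(constraints$whitelist$from, constraints$whitelist$to,
                    sep = "\r")
    bl_key <- paste(constraints$blacklist$from, constraints$blacklist$to,
                    sep = "\r")
  }
  nodes <- sort(g$nodes)
  moves <- list()
  # additions
  for (f in nodes) for (t in nodes) {
    if (f == t || f %in% g$parents[[t]] || t %in% g$parents[[f]]) next
    if (paste(f, t, sep = "\r") %in% bl_key) next
    if (has_path(g$parents, t, f)) next
    moves[[length(moves) + 1L]] <- c("add", f, t)
  }
  e <- dag_edges(g)
  if (nrow(e)) e <- e[order(e$from, e$to), ]
  # deletions
  for (i in seq_len(nrow(e))) {
    f <- e$from[i]; t <- e$to[i]
    if (paste(f, t, sep = "\r") %in% wl_key) next
    moves[[length(moves) + 1L]] <- c("delete", f, t)
  }
  # reversals
  for (i in seq_len(nrow(e))) {
    f <- e$from[i]; t <- e$to[i]
    if (paste(f, t, sep = "\r") %in% wl_key) next
    if (paste(t, f, sep = "\r") %in% bl_key) next
    if (has_path(g$parents, f, t, skip = c(f, t))) next
    moves[[length(moves) + 1L]] <- c("reverse", f, t)
  }
  out <- as.data.frame(do.call(rbind, moves), stringsAsFactors = FALSE)
  if (!nrow(out)) return(data.frame(type = character(), from = character(),
                                    to = character()))
  names(out) <- c("type", "from", "to")
  out[order(out$type, out$from, out$to), , drop = FALSE]
}

#' Tabu-search parameters
#'
#' @param tenure iterations a reversed move stays forbidden (default 10).
#' @param max_iter iteration cap (default 1000).
#' @param window stop after this many consecutive non-improving iterations
#'   (default 50).
#' @param seed integer seed (the search itself is deterministic; the seed
#'   is recorded for provenance).
#' @return An object of class `"search_params"`.
#' @export
search_params <- function(tenure = 10L, max_iter = 1000L, window = 50L,
                          seed = 1L) {
  stopifnot(tenure >= 1, max_iter >= 1, window >= 1)
  structure(list(tenure = as.integer(tenure),
                 max_iter = as.integer(max_iter),
                 window = as.integer(window), seed = as.integer(seed)),
            class = "search_params")
}

move_key <- function(type, from, to) paste(type, from, to, sep = "\r")
inverse_move <- function(type, from, to) {
  switch(type,
         add = c("delete", from, to),
         delete = c("add", from, to),
         reverse = c("reverse", to, from))
}

#' Learn a DAG by tabu search over the BIC score
#'
#' Greedy local search over the add/delete/reverse neighborhood with a tabu
#' list of inverse moves: each iteration applies the best-scoring legal
#' move that is not tabu (aspiration: a tabu move is admitted if it beats
#' the best score seen so far), then places its inverse on the tabu list
#' for `tenure` iterations. The search starts from the whitelist-only
#' graph and returns the best-scoring DAG encountered. Equal-scoring moves
#' are broken by (type, source, target) order, so the search is
#' deterministic for fixed data.
#'
#' @param data fully discrete data.frame.
#' @param nodes columns to model (default all).
#' @param constraints an [edge_constraints()] or `NULL`.
#' @param params a [search_params()].
#' @param penalty `FALSE` for log-likelihood-only scoring.
#' @return A `"scored_dag"` (see [bic_score()]) of the best DAG found.
#' @export
tabu_search <- function(data, nodes = names(data), constraints = NULL,
                        params = search_params(), penalty = TRUE) {
  stopifnot(inherits(params, "search_params"))
  dm <- as_discrete_matrix(data, nodes)
  cache <- new.env(parent = emptyenv())
  fam <- function(child, parents) {
    key <- paste(child, paste(sort(parents), collapse = ","), sep = "|")
    got <- cache[[key]]
    if (!is.null(got)) return(got)
    cache[[key]] <- family_score_bic(dm, child, parents, penalty)
    cache[[key]]
  }
  wl <- if (!is.null(constraints)) constraints$whitelist else NULL
  current <- dag(nodes, wl)
  cur_fs <- vapply(nodes, function(nd) fam(nd, current$parents[[nd]]),
                   numeric(1))
  cur_score <- sum(cur_fs)
  best <- current; best_score <- cur_score
  tabu_until <- new.env(parent = emptyenv())
  stall <- 0L
  for (iter in seq_len(params$max_iter)) {
    mv <- legal_moves(current, constraints)
    if (!nrow(mv)) break
    deltas <- numeric(nrow(mv))
    for (i in seq_len(nrow(mv))) {
      f <- mv$from[i]; t <- mv$to[i]
      deltas[i] <- switch(mv$type[i],
        add = fam(t, c(current$parents[[t]], f)) - cur_fs[[t]],
        delete = fam(t, setdiff(current$parents[[t]], f)) - cur_fs[[t]],
        reverse = (fam(t, setdiff(current$parents[[t]], f)) - cur_fs[[t]]) +
                  (fam(f, c(current$parents[[f]], t)) - cur_fs[[f]]))
    }
    keys <- move_key(mv$type, mv$from, mv$to)
    is_tabu <- vapply(keys, function(k) {
      u <- tabu_until[[k]]; !is.null(u) && u >= iter
    }, logical(1))
    admissible <- !is_tabu | (cur_score + deltas > best_score + 1e-12)
    if (!any(admissible)) { stall <- stall + 1L
                            if (stall >= params$window) break else next }
    cand <- which(admissible)
    pick <- cand[which.max(deltas[cand])]  # first max in tie-break order
    type <- mv$type[pick]; f <- mv$from[pick]; t <- mv$to[pick]
    if (type == "add") {
      current$parents[[t]] <- c(current$parents[[t]], f)
      cur_fs[[t]] <- fam(t, current$parents[[t]])
    } else if (type == "delete") {
      current$parents[[t]] <- setdiff(current$parents[[t]], f)
      cur_fs[[t]] <- fam(t, current$parents[[t]])
    } else {
      current$parents[[t]] <- setdiff(current$parents[[t]], f)
      current$parents[[f]] <- c(current$parents[[f]], t)
      cur_fs[[t]] <- fam(t, current$parents[[t]])
      cur_fs[[f]] <- fam(f, current$parents[[f]])
    }
    cur_score <- sum(cur_fs)
    inv <- inverse_move(type, f, t)
    tabu_until[[move_key(inv[1L], inv[2L], inv[3L])]] <-
      iter + params$tenure
    if (cur_score > best_score + 1e-12) {
      best_score <- cur_score
      best <- current
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= params$window) break
    }
  }
  fs <- vapply(nodes, function(nd) fam(nd, best$parents[[nd]]), numeric(1))
  structure(list(dag = best, score = best_score, family_scores = fs),
            class = "scored_dag")
}

#' Stratified train/test split
#'
#' Randomly partitions the cohort into a training and a test set,
#' stratified by the `group` column: each stratum contributes
#' `floor(fraction * n)` training rows. The two sets are disjoint and
#' exhaustive, and the split is reproducible for a fixed seed.
#'
#' @param cohort data.frame with a `group` column.
#' @param fraction training fraction in (0, 1) (default 0.7).
#' @param seed integer seed.
#' @return list with data.frames `train` and `test`.
#' @export
train_test_split <- function(cohort, fraction = 0.7, seed = 1L) {
  stopifnot(is.data.frame(cohort), "group" %in% names(cohort),
            fraction > 0, fraction < 1)
  set.seed(as.integer(seed) %% 2147483647L)
  train_idx <- integer()
  for (g in unique(cohort$group)) {
    idx <- which(cohort$group == g)
    if (length(idx) < 2L) stop("stratum '", g, "' has fewer than 2 rows")
    k <- floor(fraction * length(idx))
    train_idx <- c(train_idx, sort(sample(idx, k)))
  }
  train_idx <- sort(train_idx)
  list(train = cohort[train_idx, , drop = FALSE],
       test = cohort[setdiff(seq_len(nrow(cohort)), train_idx), ,
                     drop = FALSE])
}

#' Markov-equivalence class of a DAG
#'
#' The completed partially directed graph (CPDAG): the skeleton with
#' exactly the compelled edges directed — v-structure arcs plus the
#' orientations forced by the Meek closure rules.
#'
#' @param g a [dag()].
#' @return An object of class `"cpdag"`: `nodes`, `directed` (data.frame
#'   from/to) and `undirected` (data.frame of unordered pairs, smaller name
#'   first), plus a canonical string `key` for equality comparison.
#' @export
cpdag <- function(g) {
  stopifnot(inherits(g, "dag"))
  nodes <- g$nodes
  n <- length(nodes)
  idx <- stats::setNames(seq_len(n), nodes)
  # adjacency marks: A[i,j] = 1 if i-j present with an arrowhead at j
  # allowed; undirected edges have A[i,j] = A[j,i] = 1
  A <- matrix(0L, n, n, dimnames = list(nodes, nodes))
  for (t in nodes) for (f in g$parents[[t]]) {
    A[idx[f], idx[t]] <- 1L
    A[idx[t], idx[f]] <- 1L
  }
  adjacent <- function(i, j) A[i, j] == 1L || A[j, i] == 1L
  orient <- function(i, j) { A[i, j] <<- 1L; A[j, i] <<- 0L }
  # v-structures of the original DAG are compelled
  for (t in nodes) {
    pa <- g$parents[[t]]
    if (length(pa) < 2L) next
    for (ai in seq_along(pa)) for (bi in seq_along(pa)) {
      if (ai >= bi) next
      a <- pa[ai]; b <- pa[bi]
      if (!adjacent(idx[a], idx[b])) {
        orient(idx[a], idx[t]); orient(idx[b], idx[t])
      }
    }
  }
  directed <- function(i, j) A[i, j] == 1L && A[j, i] == 0L
  undirected <- function(i, j) A[i, j] == 1L && A[j, i] == 1L
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (!undirected(i, j)) next
      # R1: k -> i, i - j, k and j nonadjacent  =>  i -> j
      for (k in seq_len(n)) {
        if (directed(k, i) && !adjacent(k, j)) {
          orient(i, j); changed <- TRUE; break
        }
      }
      if (!undirected(i, j)) next
      # R2: i -> k -> j and i - j  =>  i -> j
      for (k in seq_len(n)) {
        if (directed(i, k) && directed(k, j)) {
          orient(i, j); changed <- TRUE; break
        }
      }
      if (!undirected(i, j)) next
      # R3: i - k1 -> j, i - k2 -> j, k1 and k2 nonadjacent  =>  i -> j
      ks <- which(vapply(seq_len(n), function(k)
        undirected(i, k) && directed(k, j), logical(1)))
      done <- FALSE
      if (length(ks) >= 2L) {
        for (a in ks) for (b in ks) {
          if (a < b && !adjacent(a, b)) {
            orient(i, j); changed <- TRUE; done <- TRUE; break
          }
        }
      }
      if (done) next
    }
    if (!changed) break
  }
  dir_e <- und_e <- list()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (directed(i, j))
      dir_e[[length(dir_e) + 1L]] <- c(nodes[i], nodes[j])
    if (i < j && undirected(i, j))
      und_e[[length(und_e) + 1L]] <- c(nodes[i], nodes[j])
  }
  dd <- if (length(dir_e)) {
    d <- as.data.frame(do.call(rbind, dir_e), stringsAsFactors = FALSE)
    names(d) <- c("from", "to"); d[order(d$from, d$to), ]
  } else data.frame(from = character(), to = character())
  ud <- if (length(und_e)) {
    d <- as.data.frame(do.call(rbind, und_e), stringsAsFactors = FALSE)
    names(d) <- c("a", "b"); d[order(d$a, d$b), ]
  } else data.frame(a = character(), b = character())
  parts <- c(if (nrow(dd)) paste0(dd$from, ">", dd$to),
             if (nrow(ud)) paste0(ud$a, "-", ud$b))
  key <- paste(parts, collapse = ";")
  structure(list(nodes = nodes, directed = dd, undirected = ud, key = key),
            class = "cpdag")
}

#' @export
print.cpdag <- function(x, ...) {
  cat(sprintf("<cpdag> %d nodes, %d compelled, %d reversible\n",
              length(x$nodes), nrow(x$directed), nrow(x$undirected)))
  if (nrow(x$directed))
    cat("  ", paste(sprintf("%s -> %s", x$directed$from, x$directed$to),
                    collapse = ", "), "\n")
  if (nrow(x$undirected))
    cat("  ", paste(sprintf("%s - %s", x$undirected$a, x$undirected$b),
                    collapse = ", "), "\n")
  invisible(x)
}

#' @export
`==.cpdag` <- function(e1, e2) identical(e1$key, e2$key)
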