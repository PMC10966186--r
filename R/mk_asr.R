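#' Parameters of the two-state Mk model
#'
#' Continuous-time Markov model of the binary thermophysiology character,
#' state 0 = ectothermy, state 1 = endothermy. Rates are per Myr, so fitted
#' values depend on the tree's dating. `ER` constrains the two rates equal;
#' `ARD` leaves them free. The root prior is either flat (1/2, 1/2) or the
#' chain's stationary distribution.
#'
#' @param q01 Rate ectothermy -> endothermy, per Myr (>= 0).
#' @param q10 Rate endothermy -> ectothermy; must equal `q01` under `ER`.
#' @param model_form `"ER"` (default) or `"ARD"`.
#' @param root_prior `"flat"` (default) or `"stationary"`.
#' @return An `mk_params` object.
#' @export
mk_params <- function(q01, q10 = q01, model_form = c("ER", "ARD"),
                      root_prior = c("flat", "stationary")) {
  model_form <- match.arg(model_form)
  root_prior <- match.arg(root_prior)
  stopifnot(is.numeric(q01), length(q01) == 1L, is.finite(q01), q01 >= 0,
            is.numeric(q10), length(q10) == 1L, is.finite(q10), q10 >= 0)
  if (model_form == "ER" && q01 != q10) {
    stop("ER model requires q01 == q10")
  }
  structure(list(q01 = q01, q10 = q10, model_form = model_form,
                 root_prior = root_prior),
            class = "mk_params")
}

#' @export
print.mk_params <- function(x, ...) {
  cat(sprintf("<mk_params> %s, q01 = %g, q10 = %g /Myr, root prior %s\n",
              x$model_form, x$q01, x$q10, x$root_prior))
  if (!is.null(attr(x, "loglik"))) {
    cat(sprintf("  log-likelihood at fit: %.6f\n", attr(x, "loglik")))
  }
  invisible(x)
}

root_prior_vec <- function(params) {
  s <- params$q01 + params$q10
  if (params$root_prior == "stationary" && s > 0) {
    c(params$q10, params$q01) / s
  } else {
    c(0.5, 0.5)
  }
}

#' Transition probability matrix of the two-state chain
#'
#' Closed form: with `s = q01 + q10` and stationary frequencies
#' `pi = (q10, q01)/s`, `P(t) = Pi + (I - Pi) * exp(-s t)` where `Pi` has
#' `pi` in both rows. For the equal-rates model this reduces to
#' `P_stay(t) = (1 + exp(-2 q t)) / 2`. `P(0)` is the identity; rows always
#' sum to one.
#'
#' @param t Duration in Myr, `t >= 0`.
#' @param params [mk_params()].
#' @return A 2x2 row-stochastic matrix, rows/cols ordered (0, 1).
#' @export
transition_probability <- function(t, params) {
  stopifnot(inherits(params, "mk_params"))
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t) || t < 0) {
    stop("t must be a non-negative duration, got ", t)
  }
  s <- params$q01 + params$q10
  if (s == 0) return(diag(2))
  p0 <- params$q10 / s  # stationary weight of state 0
  p1 <- params$q01 / s
  e <- exp(-s * t)
  matrix(c(p0 + p1 * e, p0 * (1 - e),
           p1 * (1 - e), p1 + p0 * e),
         nrow = 2L,
         dimnames = list(c("0", "1"), c("0", "1")))
}

# normalize tip states to a named 0/1 integer vector over the tree's tips
resolve_tip_states <- function(tree, states) {
  if (is.data.frame(states)) states <- stats::setNames(states$state, states$taxon)
  if (is.character(states)) {
    lut <- c(ectothermy = 0L, endothermy = 1L, "0" = 0L, "1" = 1L)
    states <- stats::setNames(lut[states], names(states))
  }
  miss <- setdiff(tree$tip.label, names(states))
  if (length(miss)) stop("missing tip state(s): ", paste(miss, collapse = ", "))
  st <- as.integer(states[tree$tip.label])
  if (anyNA(st) || !all(st %in% c(0L, 1L))) {
    bad <- tree$tip.label[which(is.na(st) | !(st %in% c(0L, 1L)))[1L]]
    stop("unrecognized state for tip ", bad)
  }
  stats::setNames(st, tree$tip.label)
}

# per-edge transition matrices, edges in the order of phy$edge
edge_pmats <- function(tree, params) {
  el <- tree$edge.length
  if (is.null(el)) stop("tree has no branch durations")
  if (any(el <= 0)) stop("branch durations must be strictly positive")
  lapply(el, transition_probability, params = params)
}

# Felsenstein post-order pass. Returns list(down = n x 2 matrix of scaled
# conditional likelihoods, logscale = per-node log scaling, loglik).
pruning_pass <- function(tree, st, params) {
  n <- ape::Ntip(tree)
  nn <- n + tree$Nnode
  P <- edge_pmats(tree, params)
  down <- matrix(1, nn, 2L)
  down[cbind(seq_len(n), 2L - st[tree$tip.label])] <- 0  # one-hot tips
  logscale <- numeric(nn)
  ed <- ape::reorder.phylo(tree, "postorder")$edge
  eo <- match(paste(ed[, 1L], ed[, 2L]), paste(tree$edge[, 1L], tree$edge[, 2L]))
  for (k in seq_len(nrow(ed))) {
    p <- ed[k, 1L]; ch <- ed[k, 2L]
    msg <- P[[eo[k]]] %*% down[ch, ]
    down[p, ] <- down[p, ] * msg
    logscale[p] <- logscale[p] + logscale[ch]
    m <- max(down[p, ])
    if (m > 0 && (m < 1e-200 || m > 1e200)) {
      down[p, ] <- down[p, ] / m
      logscale[p] <- logscale[p] + log(m)
    }
  }
  root <- n + 1L
  lik <- sum(root_prior_vec(params) * down[root, ])
  list(down = down, logscale = logscale,
       loglik = log(lik) + logscale[root], P = P)
}

#' Log-likelihood of tip states under the Mk model
#'
#' Felsenstein pruning over the time-scaled tree, with the root conditional
#' likelihoods combined under the model's root prior. Rescaled per node, so
#' it is safe on large trees.
#'
#' @param tree Time-scaled `phylo` (positive branch durations in Myr).
#' @param states Named vector over tips: 0/1, or
#'   `"ectothermy"`/`"endothermy"`, or a data.frame `taxon,state`.
#' @param params [mk_params()].
#' @return The log-likelihood (a single number).
#' @export
tree_log_likelihood <- function(tree, states, params) {
  st <- resolve_tip_states(tree, states)
  pruning_pass(tree, st, params)$loglik
}

#' Maximum-likelihood estimate of the Mk transition rate(s)
#'
#' Optimizes [tree_log_likelihood()] over log-rates (positivity is implicit)
#' within \[1e-8, 100\] per Myr: golden-section/parabolic search for `ER`,
#' L-BFGS-B for `ARD`. If all tips share one state there is no signal for a
#' rate and the estimate is pinned to the lower bound with a warning.
#'
#' @param tree Time-scaled `phylo`.
#' @param states Tip states (see [tree_log_likelihood()]).
#' @param model_form `"ER"` or `"ARD"`.
#' @param root_prior `"flat"` or `"stationary"`.
#' @param bounds Rate search interval, per Myr.
#' @return An [mk_params()] with attributes `loglik`.
#' @export
fit_rate_ml <- function(tree, states, model_form = c("ER", "ARD"),
                        root_prior = c("flat", "stationary"),
                        bounds = c(1e-8, 100)) {
  model_form <- match.arg(model_form)
  root_prior <- match.arg(root_prior)
  st <- resolve_tip_states(tree, states)
  if (length(unique(st)) == 1L) {
    warning("all tips share one state; rate pinned to the lower bound")
    par <- mk_params(bounds[1L], bounds[1L],
                     model_form = model_form, root_prior = root_prior)
    attr(par, "loglik") <- tree_log_likelihood(tree, st, par)
    return(par)
  }
  lb <- log(bounds)
  if (model_form == "ER") {
    f <- function(lq) {
      q <- exp(lq)
      -pruning_pass(tree, st, mk_params(q, q, "ER", root_prior))$loglik
    }
    opt <- stats::optimize(f, interval = lb, tol = 1e-10)
    # optimize() never evaluates the interval ends; snap if boundary is better
    cand <- c(opt$minimum, lb)
    vals <- c(opt$objective, f(lb[1L]), f(lb[2L]))
    best <- cand[which.min(vals)]
    q <- exp(best)
    par <- mk_params(q, q, "ER", root_prior)
    attr(par, "loglik") <- -min(vals)
  } else {
    f <- function(lq) {
      -pruning_pass(tree, st, mk_params(exp(lq[1L]), exp(lq[2L]),
                                        "ARD", root_prior))$loglik
    }
    opt <- stats::optim(c(mean(lb), mean(lb)), f, method = "L-BFGS-B",
                        lower = lb[1L], upper = lb[2L],
                        control = list(factr = 1e3))
    par <- mk_params(exp(opt$par[1L]), exp(opt$par[2L]), "ARD", root_prior)
    attr(par, "loglik") <- -opt$value
  }
  par
}

#' Marginal ancestral-state probabilities at every node
#'
#' For each node, the posterior probability of ectothermy and endothermy
#' given all tip states, marginalizing over every other node. Computed with
#' one post-order (Felsenstein) and one pre-order pass, which is the
#' algorithmic equivalent of rerooting the tree at each node in turn and
#' combining the subtree conditional likelihoods with the root prior.
#' Tips retain probability 1 on their observed state.
#'
#' @param tree Time-scaled `phylo`.
#' @param states Tip states (see [tree_log_likelihood()]).
#' @param params [mk_params()], typically from [fit_rate_ml()].
#' @return A `(Ntip + Nnode) x 2` matrix, columns `p_ecto`, `p_endo`, rows in
#'   ape node order; every row sums to 1. The tree log-likelihood is attached
#'   as attribute `loglik`.
#' @export
marginal_asr <- function(tree, states, params) {
  st <- resolve_tip_states(tree, states)
  n <- ape::Ntip(tree)
  nn <- n + tree$Nnode
  root <- n + 1L
  pp <- pruning_pass(tree, st, params)
  down <- pp$down
  P <- pp$P

  # pre-order "outside" partials: up[v, s] ~ P(data outside subtree(v), state v = s)
  up <- matrix(0, nn, 2L)
  up[root, ] <- root_prior_vec(params)
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  preord_edges <- ape::reorder.phylo(tree, "cladewise")$edge
  eo <- match(paste(preord_edges[, 1L], preord_edges[, 2L]),
              paste(tree$edge[, 1L], tree$edge[, 2L]))
  for (k in seq_len(nrow(preord_edges))) {
    e <- eo[k]
    v <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    sib_msg <- c(1, 1)
    for (e2 in children[[as.character(v)]]) {
      if (e2 == e) next
      sib_msg <- sib_msg * as.vector(P[[e2]] %*% down[tree$edge[e2, 2L], ])
    }
    up[ch, ] <- as.vector(t(P[[e]]) %*% (up[v, ] * sib_msg))
    m <- max(up[ch, ])
    if (m > 0) up[ch, ] <- up[ch, ] / m   # marginals are normalized per node
  }

  w <- up * down
  marg <- w / rowSums(w)
  colnames(marg) <- c("p_ecto", "p_endo")
  rownames(marg) <- node_label_vector(tree)
  attr(marg, "loglik") <- pp$loglik
  marg
}

#' Exhaustive-marginalization oracle for ancestral states
#'
#' Enumerates all `2^Nnode` assignments of states to internal nodes, weights
#' each by root prior times the product of branch transition probabilities to
#' the fixed tip states, and marginalizes per node. Exponential cost: refuses
#' trees with more than 12 internal nodes. Exists as an independent check of
#' [marginal_asr()].
#'
#' @inheritParams marginal_asr
#' @return Same shape as [marginal_asr()].
#' @export
brute_force_asr <- function(tree, states, params) {
  st <- resolve_tip_states(tree, states)
  n <- ape::Ntip(tree)
  k <- tree$Nnode
  if (k > 12L) stop("too many internal nodes for exhaustive enumeration: ", k)
  root <- n + 1L
  P <- edge_pmats(tree, params)
  prior <- root_prior_vec(params)

  grid <- as.matrix(expand.grid(rep(list(0:1), k)))  # 2^k x k, node n+j in col j
  state_of <- function(node) {
    if (node <= n) rep(st[[tree$tip.label[node]]], nrow(grid)) else grid[, node - n]
  }
  wt <- prior[grid[, 1L] + 1L]  # root = node n+1 = column 1
  for (e in seq_len(nrow(tree$edge))) {
    sp <- state_of(tree$edge[e, 1L])
    sc <- state_of(tree$edge[e, 2L])
    wt <- wt * P[[e]][cbind(sp + 1L, sc + 1L)]
  }
  marg <- matrix(0, n + k, 2L, dimnames = list(node_label_vector(tree),
                                               c("p_ecto", "p_endo")))
  marg[cbind(seq_len(n), st[tree$tip.label] + 1L)] <- 1
  z <- sum(wt)
  for (j in seq_len(k)) {
    p1 <- sum(wt[grid[, j] == 1L]) / z
    marg[n + j, ] <- c(1 - p1, p1)
  }
  attr(marg, "loglik") <- log(z)
  marg
}

#' Stable labels for every node of a tree
#'
#' Tips keep their labels; internal nodes keep their Newick labels where
#' present and non-empty, otherwise get `"node<ape number>"`. Used to key
#' per-node results consistently across an ensemble sharing one topology.
#'
#' @param tree A `phylo`.
#' @return Character vector of length `Ntip + Nnode` in ape node order.
#' @export
node_label_vector <- function(tree) {
  n <- ape::Ntip(tree)
  lab <- tree$node.label
  if (is.null(lab)) lab <- rep("", tree$Nnode)
  fallback <- paste0("node", n + seq_len(tree$Nnode))
  lab <- ifelse(is.na(lab) | lab == "", fallback, lab)
  c(tree$tip.label, lab)
}
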