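#' Couple a tree with one trait value per tip
#'
#' @param tree a rooted `phylo` tree with non-negative branch lengths.
#' @param values named numeric vector, one finite value per tip; names must
#'   match the tip labels.
#' @return An object of class `phylo_trait`: list with `tree` and `values`
#'   (reordered to tip-label order).
#' @export
phylo_trait <- function(tree, values) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("branch lengths must be >= 0")
  if (is.null(names(values))) stop("values must be named by tip label")
  if (!setequal(names(values), tree$tip.label)) {
    stop("tip labels of values and tree differ")
  }
  values <- values[tree$tip.label]
  if (!all(is.finite(values))) stop("trait values must be finite")
  structure(list(tree = tree, values = values), class = "phylo_trait")
}

#' @export
print.phylo_trait <- function(x, ...) {
  cat("phylo_trait:", length(x$values), "tips; trait range",
      paste(signif(range(x$values), 4), collapse = " - "), "\n")
  invisible(x)
}

#' Prepare tip values from per-sample counts
#'
#' Maps per-sample polymorphism counts onto the tips of a phylogeny:
#' samples absent from the tree are dropped, multiple samples on one tip are
#' averaged (arithmetic mean), and tips separated by zero patristic distance
#' are collapsed into a single tip carrying the mean of all their
#' contributing samples. Tree tips without any sample are pruned.
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @param counts named numeric vector of per-sample counts.
#' @param tip_map optional named character vector mapping sample names to
#'   tip labels (defaults to using sample names as tip labels directly).
#' @return A [phylo_trait()] on the pruned tree.
#' @export
prepare_tips <- function(tree, counts, tip_map = NULL) {
  stopifnot(inherits(tree, "phylo"), is.numeric(counts))
  tips_of <- if (is.null(tip_map)) names(counts) else
    unname(tip_map[names(counts)])
  keep <- !is.na(tips_of) & tips_of %in% tree$tip.label
  if (sum(keep) < 2L) {
    stop("fewer than two samples map onto tips of the tree")
  }
  counts <- counts[keep]; tips_of <- tips_of[keep]
  used_tips <- unique(tips_of)
  pruned <- ape::keep.tip(tree, used_tips)
  # collapse tips at zero patristic distance (union-find over zero pairs)
  D <- stats::cophenetic(pruned)
  labs <- pruned$tip.label
  comp <- seq_along(labs)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  for (i in seq_along(labs)) for (j in seq_len(i - 1L)) {
    if (D[labs[i], labs[j]] == 0) {
      comp[find(i)] <- find(j)
    }
  }
  roots <- vapply(seq_along(labs), find, integer(1))
  values <- numeric(0)
  reps <- character(0)
  for (g in unique(roots)) {
    members <- labs[roots == g]
    rep_tip <- members[1]
    values[rep_tip] <- mean(counts[tips_of %in% members])
    reps <- c(reps, rep_tip)
  }
  if (length(reps) < length(labs)) pruned <- ape::keep.tip(pruned, reps)
  phylo_trait(pruned, values[pruned$tip.label])
}

# Laplacian machinery for squared-change parsimony. The objective
# sum_edges (x_u - x_v)^2 / w_e is a quadratic form in all node states;
# minimizing over internal states given tip values is a linear solve.
# Returns R (internal states = R %*% y) and the Schur complement S
# (minimized score = y' S y), plus ape's internal node ids.
.scp_system <- function(tree, weighted = FALSE) {
  n <- ape::Ntip(tree)
  m <- tree$Nnode
  N <- n + m
  w <- if (weighted) tree$edge.length else rep(1, nrow(tree$edge))
  if (weighted && any(w <= 0)) {
    stop("weighted squared-change parsimony requires all branch lengths > 0; ",
         "collapse zero-length branches first")
  }
  A <- matrix(0, N, N)
  iw <- 1 / w
  A[tree$edge] <- iw
  A[tree$edge[, c(2, 1)]] <- iw
  L <- diag(rowSums(A)) - A
  tips <- seq_len(n)
  internal <- (n + 1L):N
  LII <- L[internal, internal, drop = FALSE]
  LIT <- L[internal, tips, drop = FALSE]
  R <- solve(LII, -LIT)
  S <- L[tips, tips, drop = FALSE] + L[tips, internal, drop = FALSE] %*% R
  list(R = R, S = S, internal = internal, n_tips = n)
}

#' Squared-change parsimony ancestral states
#'
#' Assigns internal-node states minimizing the sum of squared changes along
#' branches, optionally dividing each squared change by the branch length
#' (weighted parsimony). The minimization is solved exactly as a linear
#' system. The default is unweighted, which is robust to zero-length
#' branches.
#'
#' @param phylo a [phylo_trait()].
#' @param weighted divide squared changes by branch lengths (requires all
#'   branch lengths > 0).
#' @return An object of class `scp_result`: list with `node_states` (named
#'   by ape's internal node numbers) and `scp_length` (the minimized score;
#'   0 iff all tip values are equal).
#' @examples
#' tr <- ape::read.tree(text = "((a:1,b:1):1,c:1);")
#' scp_ancestral_states(phylo_trait(tr, c(a = 0, b = 0, c = 3)))
#' @export
scp_ancestral_states <- function(phylo, weighted = FALSE) {
  stopifnot(inherits(phylo, "phylo_trait"))
  sys <- .scp_system(phylo$tree, weighted)
  y <- phylo$values
  states <- drop(sys$R %*% y)
  names(states) <- sys$internal
  len <- max(0, drop(y %*% sys$S %*% y))
  structure(list(node_states = states, scp_length = len, weighted = weighted),
            class = "scp_result")
}

#' Permutation test of phylogenetic signal in tree length
#'
#' Compares the observed squared-change parsimony tree length with the
#' distribution of lengths obtained by permuting tip values uniformly across
#' tips. The reported p-value is the fraction of permutations with a tree
#' length strictly shorter than the observed one; a count of zero is printed
#' as `< 1/n_perm`. When every tip value is equal the statistic is
#' degenerate and the test carries no signal.
#'
#' @param phylo a [phylo_trait()] with at least 3 tips.
#' @param n_perm number of permutations (default 10000).
#' @param seed optional integer seed.
#' @param weighted use branch-length-weighted parsimony.
#' @return An object of class `perm_signal_test`: list with `perm_p`,
#'   `n_shorter`, `n_perm` and `observed_length`.
#' @export
permutation_signal_test <- function(phylo, n_perm = 10000L, seed = NULL,
                                    weighted = FALSE) {
  stopifnot(inherits(phylo, "phylo_trait"))
  if (length(phylo$values) < 3L) stop("need at least 3 tips")
  .seed_guard(seed)
  sys <- .scp_system(phylo$tree, weighted)
  y <- unname(phylo$values)
  obs <- max(0, drop(y %*% sys$S %*% y))
  Yp <- vapply(seq_len(n_perm), function(i) sample(y), numeric(length(y)))
  lens <- colSums((sys$S %*% Yp) * Yp)
  eps <- 1e-9 * max(1, abs(obs))
  n_shorter <- sum(lens < obs - eps)
  structure(list(perm_p = n_shorter / n_perm, n_shorter = n_shorter,
                 n_perm = n_perm, observed_length = obs),
            class = "perm_signal_test")
}

#' @export
print.perm_signal_test <- function(x, ...) {
  p <- if (x$n_shorter == 0L) paste0("< ", format(1 / x$n_perm)) else
    format(x$perm_p)
  cat("permutation signal test: observed tree length",
      signif(x$observed_length, 6), "; P", p,
      paste0("(", x$n_shorter, "/", x$n_perm, " permutations shorter)\n"))
  invisible(x)
}

#' Pagel's lambda branch-length transformation
#'
#' Scales the phylogenetic covariances between taxa by `lambda` while
#' leaving each taxon's variance (root-to-tip distance) unchanged:
#' internal branches are multiplied by `lambda` and terminal branches
#' extended to preserve tip depths. `lambda = 1` leaves the tree unchanged;
#' `lambda = 0` yields a star phylogeny (phylogenetic independence).
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @param lambda value in `[0, 1]`.
#' @return The transformed `phylo`.
#' @export
lambda_transform <- function(tree, lambda) {
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]")
  depths <- ape::node.depth.edgelength(tree)
  n <- ape::Ntip(tree)
  out <- tree
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    parent <- tree$edge[e, 1]
    if (child <= n) {
      out$edge.length[e] <- depths[child] - lambda * depths[parent]
    } else {
      out$edge.length[e] <- lambda * tree$edge.length[e]
    }
  }
  out
}

# Profiled Brownian-motion log-likelihood given a fixed covariance V:
# the root state is the GLS mean and sigma^2 its ML estimate.
.bm_profile <- function(V, y) {
  n <- length(y)
  ch <- tryCatch(chol(V), error = function(e)
    stop("singular phylogenetic covariance matrix"))
  logdet <- 2 * sum(log(diag(ch)))
  solve_chol <- function(b) backsolve(ch, forwardsolve(t(ch), b))
  one <- rep(1, n)
  Vi1 <- solve_chol(one)
  Viy <- solve_chol(y)
  root <- sum(one * Viy) / sum(one * Vi1)
  r <- y - root
  s2 <- drop(r %*% solve_chol(r)) / n
  if (s2 <= 0) stop("trait variance is zero; Brownian likelihood undefined")
  logL <- -0.5 * (n * log(2 * pi * s2) + logdet + n)
  list(root = root, sigma2 = s2, logL = logL)
}

#' Maximum-likelihood estimate of Pagel's lambda
#'
#' Fits a Brownian-motion model whose covariance off-diagonals are scaled by
#' lambda, profiling out the rate and the root state and maximizing over
#' `lambda` in `[0, 1]` by bounded one-dimensional optimization (tolerance
#' 1e-8, with the interval endpoints checked explicitly). Also returns the
#' log-likelihood with lambda held at zero (phylogenetic independence), the
#' null of the likelihood-ratio test.
#'
#' @param phylo a [phylo_trait()] with at least 4 tips.
#' @return List with `lambda_hat`, `logL_lambda`, `logL_zero`, `sigma2_hat`
#'   and `root_hat`.
#' @export
fit_lambda <- function(phylo) {
  stopifnot(inherits(phylo, "phylo_trait"))
  y <- unname(phylo$values)
  if (length(y) < 4L) stop("need at least 4 tips")
  V <- ape::vcv(phylo$tree)
  dV <- diag(V)
  f <- function(lambda) {
    Vl <- lambda * V
    diag(Vl) <- dV
    .bm_profile(Vl, y)$logL
  }
  opt <- stats::optimize(f, c(0, 1), maximum = TRUE, tol = 1e-8)
  cand <- c(opt$maximum, 0, 1)
  ll <- c(opt$objective, f(0), f(1))
  best <- which.max(ll)
  lambda_hat <- cand[best]
  Vl <- lambda_hat * V
  diag(Vl) <- dV
  prof <- .bm_profile(Vl, y)
  list(lambda_hat = lambda_hat, logL_lambda = ll[best], logL_zero = ll[2],
       sigma2_hat = prof$sigma2, root_hat = prof$root)
}

#' Likelihood-ratio test for phylogenetic signal
#'
#' Compares the maximized lambda model against the constrained lambda = 0
#' model with a one-degree-of-freedom chi-square test.
#'
#' @param logL_lambda log-likelihood of the unconstrained (lambda estimated)
#'   model.
#' @param logL_zero log-likelihood with lambda fixed at 0.
#' @return List with `lrt_stat` (`2 * (logL_lambda - logL_zero)`) and
#'   `lrt_p` (upper-tail chi-square, 1 df).
#' @examples
#' lrt_lambda(-594.192, -597.863)  # stat 7.342, p ~ 0.0067
#' @export
lrt_lambda <- function(logL_lambda, logL_zero) {
  stat <- 2 * (logL_lambda - logL_zero)
  if (stat < -1e-9) stop("logL_lambda < logL_zero: models are nested, ",
                         "the unconstrained likelihood cannot be smaller")
  stat <- max(stat, 0)
  list(lrt_stat = stat,
       lrt_p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Maximum-likelihood Brownian-motion fit from multiple starts
#'
#' Estimates the Brownian rate and root state on a (typically
#' lambda-transformed) tree by maximizing the multivariate-normal likelihood
#' from `n_starts` random starting points, always including the analytic
#' GLS solution as one start; the best likelihood wins.
#'
#' @param phylo a [phylo_trait()] with at least 3 tips; the tree should
#'   already carry any lambda transformation.
#' @param n_starts number of random starts (default 100).
#' @param seed optional integer seed.
#' @return List with `sigma2_hat`, `root_hat`, `logL`, `n_starts`.
#' @export
fit_bm <- function(phylo, n_starts = 100L, seed = NULL) {
  stopifnot(inherits(phylo, "phylo_trait"))
  y <- unname(phylo$values)
  if (length(y) < 3L) stop("need at least 3 tips")
  if (stats::var(y) == 0) {
    return(list(sigma2_hat = 0, root_hat = y[1], logL = Inf,
                n_starts = n_starts))
  }
  .seed_guard(seed)
  V <- ape::vcv(phylo$tree)
  n <- length(y)
  ch <- chol(V)
  logdet <- 2 * sum(log(diag(ch)))
  solve_chol <- function(b) backsolve(ch, forwardsolve(t(ch), b))
  negll <- function(par) {
    root <- par[1]; s2 <- exp(par[2])
    r <- y - root
    0.5 * (n * log(2 * pi * s2) + logdet + drop(r %*% solve_chol(r)) / s2)
  }
  analytic <- .bm_profile(V, y)
  starts <- rbind(c(analytic$root, log(analytic$sigma2)),
                  cbind(stats::runif(n_starts, min(y) - stats::sd(y),
                                     max(y) + stats::sd(y)),
                        log(analytic$sigma2) + stats::runif(n_starts, -3, 3)))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- stats::optim(starts[i, ], negll, method = "Nelder-Mead")
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  list(sigma2_hat = exp(best$par[2]), root_hat = best$par[1],
       logL = -best$value, n_starts = n_starts)
}

#' Simulate Brownian motion on a tree with reflecting bounds
#'
#' Draws Brownian increments branch by branch from the root towards the
#' tips; a state crossing a bound is reflected back inside (not truncated),
#' so with the default lower bound of zero, simulated counts stay
#' non-negative.
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @param sigma2 Brownian rate (>= 0).
#' @param root root state (must lie within the bounds).
#' @param lower,upper reflecting bounds (defaults 0 and `Inf`).
#' @param n_sims number of simulated trait vectors (default 10000).
#' @param seed optional integer seed.
#' @return Numeric matrix, tips x simulations, rownames = tip labels.
#' @export
simulate_bm_bounded <- function(tree, sigma2, root, lower = 0, upper = Inf,
                                n_sims = 10000L, seed = NULL) {
  if (sigma2 < 0) stop("sigma2 must be >= 0")
  if (root < lower || root > upper) stop("root must lie within the bounds")
  .seed_guard(seed)
  tree_cw <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  n <- ape::Ntip(tree)
  N <- n + tree$Nnode
  states <- matrix(NA_real_, N, n_sims)
  root_node <- n + 1L
  states[root_node, ] <- root
  reflect <- function(x) {
    repeat {
      below <- x < lower
      if (any(below)) x[below] <- 2 * lower - x[below]
      above <- is.finite(upper) & x > upper
      if (any(above)) x[above] <- 2 * upper - x[above]
      if (!any(x < lower | x > upper)) return(x)
    }
  }
  for (e in seq_len(nrow(tree_cw$edge))) {
    p <- tree_cw$edge[e, 1]; child <- tree_cw$edge[e, 2]
    sdv <- sqrt(sigma2 * tree_cw$edge.length[e])
    inc <- if (sdv > 0) stats::rnorm(n_sims, 0, sdv) else 0
    states[child, ] <- reflect(states[p, ] + inc)
  }
  out <- states[seq_len(n), , drop = FALSE]
  rownames(out) <- tree$tip.label
  out
}

#' Per-clade extremeness of ancestral states against simulations
#'
#' For every internal node, compares the squared-change parsimony ancestral
#' state of the observed data with the distribution of ancestral states
#' reconstructed from simulated trait vectors on the same tree. The number
#' of simulations more extreme than the observed state is counted in the
#' direction of the observed deviation (strictly greater when the observed
#' state lies above the simulation mean, strictly smaller otherwise; set
#' `two_sided = TRUE` to count both tails). The Bonferroni critical count is
#' `floor(n_sims * alpha / n_clades)` with `n_clades` the number of internal
#' nodes: a clade with that many or fewer more-extreme simulations rejects
#' the hypothesis of no divergence from the fitted Brownian model.
#'
#' @param phylo a [phylo_trait()] with the observed values.
#' @param sims simulation matrix from [simulate_bm_bounded()] on the same
#'   tree (rownames must match the tip labels).
#' @param alpha family-wise error rate (default 0.05).
#' @param weighted use branch-length-weighted parsimony.
#' @param two_sided count both tails.
#' @return A data.frame of class `clade_test` with one row per internal
#'   node: `node`, `observed_state`, `direction`, `n_more_extreme`,
#'   `significant`; attributes `bonferroni_critical`, `n_sims`, `alpha`,
#'   `n_clades`.
#' @export
clade_extremeness <- function(phylo, sims, alpha = 0.05, weighted = FALSE,
                              two_sided = FALSE) {
  stopifnot(inherits(phylo, "phylo_trait"))
  if (!is.matrix(sims) || is.null(rownames(sims)) ||
      !setequal(rownames(sims), phylo$tree$tip.label)) {
    stop("sims do not match the tree's tips")
  }
  sims <- sims[phylo$tree$tip.label, , drop = FALSE]
  sys <- .scp_system(phylo$tree, weighted)
  obs <- drop(sys$R %*% phylo$values)
  sim_states <- sys$R %*% sims
  mu <- rowMeans(sim_states)
  direction <- ifelse(obs >= mu, "high", "low")
  n_high <- rowSums(sim_states > obs)
  n_low <- rowSums(sim_states < obs)
  n_more <- if (two_sided) n_high + n_low else
    ifelse(direction == "high", n_high, n_low)
  n_sims <- ncol(sims)
  n_clades <- length(obs)
  crit <- floor(n_sims * alpha / n_clades)
  out <- data.frame(node = sys$internal, observed_state = obs,
                    direction = direction,
                    n_more_extreme = as.integer(n_more),
                    significant = n_more <= crit)
  rownames(out) <- NULL
  structure(out, bonferroni_critical = crit, n_sims = n_sims, alpha = alpha,
            n_clades = n_clades, class = c("clade_test", "data.frame"))
}

#' Bonferroni critical simulation count
#'
#' `floor(n_sims * alpha / n_clades)`: the largest number of more-extreme
#' simulations at which a clade still rejects no-divergence under a
#' Bonferroni correction across clades.
#'
#' @param n_sims number of simulations.
#' @param alpha family-wise error rate.
#' @param n_clades number of clades tested.
#' @return Integer critical count.
#' @examples
#' bonferroni_critical(10000, 0.05, 53)  # 9
#' @export
bonferroni_critical <- function(n_sims, alpha, n_clades) {
  as.integer(floor(n_sims * alpha / n_clades))
}
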