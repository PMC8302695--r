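#' Maximum-likelihood parameterization of a linear-Gaussian network
#'
#' For each node, ordinary least squares of the node on its parents yields
#' the intercept and edge coefficients; the residual variance is the ML
#' estimate RSS/n (not RSS/(n-k)), floored at 1e-12 so interpolating fits
#' keep a finite log-likelihood. Parents are stored in canonical node order,
#' making fitted objects (and their serializations) reproducible.
#'
#' @param dag a `bn_dag`.
#' @param data `feature_table` or numeric matrix covering the DAG nodes; n
#'   must exceed the largest family's parameter count.
#' @return object of class `lgbn`: the DAG plus, per node, `intercept`,
#'   named `coef` vector and `sigma2`.
#' @export
fit_mle <- function(dag, data) {
  x <- if (inherits(data, "feature_table")) data$values else as.matrix(data)
  if (!all(dag$nodes %in% colnames(x))) stop("data columns must cover dag nodes")
  n <- nrow(x)
  params <- stats::setNames(vector("list", length(dag$nodes)), dag$nodes)
  for (node in dag$nodes) {
    pa <- dag_parents(dag, node)
    if (n <= length(pa) + 1L) stop("too few samples for family of ", node)
    Z <- cbind(1, x[, pa, drop = FALSE])
    q <- qr(Z)
    if (q$rank < ncol(Z)) {
      stop(sprintf("collinear parents in family of node '%s' (%s)",
                   node, paste(pa, collapse = ", ")))
    }
    beta <- qr.coef(q, x[, node])
    res <- x[, node] - Z %*% beta
    params[[node]] <- list(
      intercept = unname(beta[1L]),
      coef = stats::setNames(unname(beta[-1L]), pa),
      sigma2 = max(sum(res^2) / n, 1e-12)
    )
  }
  structure(list(dag = dag, params = params, n = n), class = "lgbn")
}

#' @export
print.lgbn <- function(x, ...) {
  cat(sprintf("<lgbn> %d nodes, %d edges, fitted on n = %d\n",
              length(x$dag$nodes), nrow(x$dag$edges), x$n))
  invisible(x)
}

#' Mean and covariance implied by a linear-Gaussian network
#'
#' Solves the structural equations x = c + W x + e for the joint mean and
#' covariance: mu = (I - W)^-1 c, Sigma = (I - W)^-1 D (I - W)^-T with D the
#' diagonal of residual variances. Works for fitted networks ([fit_mle()])
#' and for ground-truth SEMs ([build_template_sem()]).
#'
#' @param model an `lgbn` or `ground_truth_sem`.
#' @return list with `mean` (named vector) and `cov` (symmetric PSD matrix).
#' @export
implied_moments <- function(model) {
  if (inherits(model, "ground_truth_sem")) model <- sem_as_lgbn(model)
  stopifnot(inherits(model, "lgbn"))
  nodes <- model$dag$nodes
  p <- length(nodes)
  W <- matrix(0, p, p, dimnames = list(nodes, nodes))  # W[child, parent]
  intercepts <- numeric(p)
  D <- numeric(p)
  for (i in seq_len(p)) {
    pr <- model$params[[nodes[i]]]
    intercepts[i] <- pr$intercept
    D[i] <- pr$sigma2
    if (length(pr$coef)) W[i, names(pr$coef)] <- pr$coef
  }
  IW <- diag(p) - W
  mu <- solve(IW, intercepts)
  Sinv <- solve(IW)
  Sigma <- Sinv %*% diag(D, p) %*% t(Sinv)
  Sigma <- (Sigma + t(Sigma)) / 2
  dimnames(Sigma) <- list(nodes, nodes)
  list(mean = stats::setNames(mu, nodes), cov = Sigma)
}

#' Predict node values from a fitted network
#'
#' Two prediction mechanisms are offered because the choice is a genuine
#' modeling decision: `"parents"` (the default) evaluates each target's
#' local regression, intercept + sum(coef * evidence\[parent\]), and requires
#' every parent of every target to be observed; `"joint"` forms the
#' multivariate Gaussian implied by the network and returns the conditional
#' mean of the targets given all observed evidence (works with any evidence
#' pattern, including none). Reports produced by the pipeline always record
#' which method was used.
#'
#' @param bn an `lgbn`.
#' @param evidence named numeric vector of observed node values (may be
#'   empty for `method = "joint"`).
#' @param targets character vector of nodes to predict.
#' @param method `"parents"` or `"joint"`.
#' @return named numeric vector of predictions, one per target.
#' @export
predict_nodes <- function(bn, evidence, targets,
                          method = c("parents", "joint")) {
  method <- match.arg(method)
  stopifnot(inherits(bn, "lgbn"))
  if (!all(targets %in% bn$dag$nodes)) stop("unknown target node")
  evidence <- unlist(evidence)
  if (method == "parents") {
    out <- vapply(targets, function(node) {
      pr <- bn$params[[node]]
      pa <- names(pr$coef)
      missing <- setdiff(pa, names(evidence))
      if (length(missing)) {
        stop(sprintf("method = 'parents' requires parent(s) of '%s': %s",
                     node, paste(missing, collapse = ", ")))
      }
      pr$intercept + sum(pr$coef * evidence[pa])
    }, numeric(1))
    return(out)
  }
  mom <- implied_moments(bn)
  obs <- intersect(setdiff(names(evidence), targets), bn$dag$nodes)
  if (!length(obs)) return(mom$mean[targets])
  S_to <- mom$cov[targets, obs, drop = FALSE]
  S_oo <- mom$cov[obs, obs, drop = FALSE]
  adj <- S_to %*% solve(S_oo, evidence[obs] - mom$mean[obs])
  stats::setNames(mom$mean[targets] + drop(adj), targets)
}
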