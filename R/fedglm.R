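#' Specify a GLM for pooled or federated fitting
#'
#' Additive terms with an implicit intercept; two families are supported,
#' binomial with logit link and gaussian with identity link. The convergence
#' criterion is the relative change in deviance between IRLS iterations,
#' \code{|dev_t - dev_{t-1}| / (|dev_t| + 0.1) < tolerance}.
#'
#' @param outcome Outcome column name.
#' @param predictors Character vector of predictor column names (may be
#'   empty for an intercept-only model).
#' @param family \code{"binomial_logit"} or \code{"gaussian_identity"}.
#' @param tolerance Positive convergence tolerance on relative deviance
#'   change.
#' @param max_iterations Maximum IRLS iterations.
#' @return An object of class \code{glm_spec}.
#' @export
glm_spec <- function(outcome, predictors = character(),
                     family = c("binomial_logit", "gaussian_identity"),
                     tolerance = 1e-8, max_iterations = 25L) {
  family <- match.arg(family)
  stopifnot(tolerance > 0, max_iterations >= 1L)
  structure(list(outcome = outcome, predictors = predictors, family = family,
                 tolerance = tolerance, max_iterations = max_iterations),
            class = "glm_spec")
}

#' Turn a formula into a glm_spec
#'
#' Accepts the additive mini-language \code{outcome ~ pred1 + pred2 + ...}
#' (implicit intercept; no interactions, offsets or transformations).
#'
#' @param formula A formula.
#' @param family,tolerance,max_iterations Passed to [glm_spec()].
#' @return A \code{glm_spec}.
#' @export
as_glm_spec <- function(formula, family = "binomial_logit",
                        tolerance = 1e-8, max_iterations = 25L) {
  stopifnot(inherits(formula, "formula"), length(formula) == 3L)
  terms <- stats::terms(formula)
  if (any(attr(terms, "order") > 1L))
    stop("only additive terms are supported", call. = FALSE)
  glm_spec(outcome = all.vars(formula[[2]]),
           predictors = attr(terms, "term.labels"),
           family = family, tolerance = tolerance,
           max_iterations = max_iterations)
}

#' One site's IRLS sufficient statistics at a given coefficient vector
#'
#' The per-iteration quantities of iteratively reweighted least squares are
#' sums over rows, so they decompose exactly over any partition of the data:
#' a site returns only its information matrix \eqn{X^T W X}, score
#' \eqn{X^T W z}, deviance and row count, and the client solves the summed
#' normal equations. For the binomial-logit family
#' \eqn{\mu = 1/(1+e^{-X\beta})}, \eqn{W = diag(\mu(1-\mu))},
#' \eqn{z = X\beta + (y-\mu)/(\mu(1-\mu))} and the deviance is
#' \eqn{-2\sum[y \log\mu + (1-y)\log(1-\mu)]}; for gaussian-identity,
#' \eqn{W = I}, \eqn{z = y} and the deviance is the residual sum of squares.
#'
#' @param X Numeric n x p design matrix (including the intercept column).
#' @param y Numeric outcome vector; must be 0/1 for the binomial family.
#' @param beta Current coefficient vector, length p.
#' @param family \code{"binomial_logit"} or \code{"gaussian_identity"}.
#' @return List with \code{info} (p x p), \code{score} (length p),
#'   \code{deviance} and \code{n}.
#' @export
irls_local_contribution <- function(X, y, beta,
                                    family = c("binomial_logit",
                                               "gaussian_identity")) {
  family <- match.arg(family)
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), ncol(X) == length(beta))
  eta <- drop(X %*% beta)
  if (family == "binomial_logit") {
    if (!all(y %in% c(0, 1)))
      stop("binomial outcome must be coded 0/1", call. = FALSE)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    dev <- -2 * sum(y * log(mu) + (1 - y) * log1p(-mu))
  } else {
    w <- rep(1, length(y))
    z <- y
    dev <- sum((y - eta)^2)
  }
  list(info = crossprod(X, X * w), score = drop(crossprod(X, w * z)),
       deviance = dev, n = length(y))
}

# Core IRLS driver. `payload_fun(beta)` must return the summed sufficient
# statistics over all data; the same driver therefore serves the pooled fit
# (one block) and the federated fit (sum of site payloads), making the two
# bit-identical by construction of the arithmetic path.
irls_drive <- function(payload_fun, p, colnames_p, spec) {
  beta <- rep(0, p)
  # identity link with unit weights solves exactly in a single step
  one_step <- spec$family == "gaussian_identity"
  dev_prev <- NULL
  converged <- FALSE
  iters <- 0L
  repeat {
    agg <- payload_fun(beta)
    dev <- agg$deviance
    if (!is.null(dev_prev) &&
        abs(dev - dev_prev) / (abs(dev) + 0.1) < spec$tolerance) {
      converged <- TRUE
      break
    }
    if (one_step && iters == 1L) { converged <- TRUE; break }
    if (iters >= spec$max_iterations) break
    beta <- solve_information(agg$info, agg$score, colnames_p)
    iters <- iters + 1L
    dev_prev <- dev
  }
  # `agg` holds the statistics evaluated at the final beta
  se <- sqrt(diag(solve(agg$info)))
  list(beta = beta, se = se, deviance = agg$deviance, info = agg$info,
       iterations = iters, converged = converged, n = agg$n)
}

solve_information <- function(info, score, colnames_p) {
  qr_i <- qr(info)
  if (qr_i$rank < ncol(info)) {
    bad <- colnames_p[qr_i$pivot[(qr_i$rank + 1):ncol(info)]]
    stop(sprintf("information matrix is singular; collinear column(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  drop(solve(info, score))
}

finish_glm_result <- function(fit, spec, term_names, n_sites) {
  est <- stats::setNames(fit$beta, term_names)
  se <- stats::setNames(fit$se, term_names)
  z975 <- stats::qnorm(0.975)
  zval <- est / se
  pval <- 2 * stats::pnorm(-abs(zval))
  res <- list(coefficients = est, standard_errors = se,
              p_values = stats::setNames(pval, term_names),
              deviance = fit$deviance,
              vcov = solve(fit$info),
              iterations = fit$iterations, converged = fit$converged,
              n_total = fit$n, n_sites = n_sites, spec = spec)
  if (spec$family == "binomial_logit") {
    res$odds_ratios <- exp(est)
    res$ci_low <- exp(est - z975 * se)
    res$ci_high <- exp(est + z975 * se)
  }
  dimnames(res$vcov) <- list(term_names, term_names)
  structure(res, class = "fedglm")
}

# Build the design matrix for a spec from a person-level data frame,
# complete-case over the model variables.
model_matrix_for <- function(data, spec) {
  vars <- c(spec$outcome, spec$predictors)
  missing_vars <- setdiff(vars, names(data))
  if (length(missing_vars))
    stop(sprintf("missing model column(s): %s",
                 paste(missing_vars, collapse = ", ")), call. = FALSE)
  d <- data[, vars, drop = FALSE]
  d <- d[stats::complete.cases(d), , drop = FALSE]
  X <- matrix(1, nrow(d), 1L + length(spec$predictors))
  for (j in seq_along(spec$predictors))
    X[, j + 1L] <- as.numeric(d[[spec$predictors[j]]])
  colnames(X) <- c("(Intercept)", spec$predictors)
  list(X = X, y = as.numeric(d[[spec$outcome]]))
}

#' Fit a GLM on pooled (single-site) data
#'
#' Runs the same IRLS driver as [fed_fit()] on one block of data, so a
#' single-site federated fit and the pooled fit follow literally the same
#' arithmetic path. Serves as the in-repo oracle for the federated identity
#' and is itself validated against \code{stats::glm} in the test suite.
#'
#' @param X Design matrix \emph{without} intercept handling -- pass either a
#'   full design matrix with intercept as first column, or use the
#'   \code{data} interface.
#' @param y Outcome vector.
#' @param spec A [glm_spec()]; only family/tolerance/max_iterations are used
#'   when X and y are given directly.
#' @param data Alternative to X/y: a person-level data frame from which the
#'   design is built per the spec (complete-case on model variables).
#' @return A \code{fedglm} object (see [fed_fit()]).
#' @export
pooled_glm_fit <- function(X = NULL, y = NULL, spec, data = NULL) {
  if (!is.null(data)) {
    mm <- model_matrix_for(data, spec)
    X <- mm$X; y <- mm$y
  }
  X <- as.matrix(X)
  term_names <- colnames(X)
  if (is.null(term_names))
    term_names <- c("(Intercept)",
                    if (ncol(X) > 1) paste0("x", seq_len(ncol(X) - 1L)))
  fit <- irls_drive(function(beta)
    irls_local_contribution(X, y, beta, spec$family),
    p = ncol(X), colnames_p = term_names, spec = spec)
  finish_glm_result(fit, spec, term_names, n_sites = 1L)
}

#' Fit a GLM across federated sites from aggregate payloads only
#'
#' Each IRLS iteration broadcasts the current coefficients to every site,
#' receives each site's information matrix, score vector, deviance and row
#' count (nothing row-level), sums them elementwise and solves
#' \eqn{(\sum X^T W X)\,\beta_{t+1} = \sum X^T W z}. Because those sums are
#' algebraically identical to the pooled quantities, the federated fit equals
#' the pooled fit on the union of the sites' data. Standard errors are
#' \eqn{\sqrt{diag((\sum X^T W X)^{-1})}} at convergence; odds ratios, Wald
#' 95\% confidence intervals and two-sided normal p-values are reported for
#' the binomial family.
#'
#' @param sites List of [create_site()] servers holding the symbol.
#' @param symbol Name of the server-side person-level table (from
#'   [site_assign_dataset()]).
#' @param spec A [glm_spec()] or a formula (converted with [as_glm_spec()]).
#' @param family Family used when \code{spec} is a formula.
#' @return Object of class \code{fedglm} with coefficients, standard errors,
#'   odds ratios and CI bounds (binomial), p-values, deviance, iteration
#'   count, convergence flag and total observation count.
#' @seealso [pooled_glm_fit()], [site_aggregate()]
#' @export
fed_fit <- function(sites, symbol, spec, family = "binomial_logit") {
  if (inherits(spec, "formula")) spec <- as_glm_spec(spec, family = family)
  stopifnot(inherits(spec, "glm_spec"), length(sites) >= 1L)
  term_names <- c("(Intercept)", spec$predictors)
  p <- length(term_names)
  payload_fun <- function(beta) {
    total <- NULL
    for (s in sites) {
      pl <- site_aggregate(s, list(symbol = symbol, spec = spec,
                                   beta = beta))
      total <- if (is.null(total)) {
        list(info = pl$info_matrix, score = pl$score_vector,
             deviance = pl$deviance, n = pl$n_obs)
      } else {
        list(info = total$info + pl$info_matrix,
             score = total$score + pl$score_vector,
             deviance = total$deviance + pl$deviance,
             n = total$n + pl$n_obs)
      }
    }
    total
  }
  fit <- irls_drive(payload_fun, p = p, colnames_p = term_names, spec = spec)
  finish_glm_result(fit, spec, term_names, n_sites = length(sites))
}

# ---- methods ---------------------------------------------------------------

#' @export
print.fedglm <- function(x, digits = 4, ...) {
  cat(sprintf("Federated GLM (%s), %d site%s, n = %d\n", x$spec$family,
              x$n_sites, if (x$n_sites == 1) "" else "s", x$n_total))
  print(round(x$coefficients, digits))
  if (!x$converged) cat("Warning: IRLS did not converge\n")
  invisible(x)
}

#' @export
summary.fedglm <- function(object, ...) {
  tab <- data.frame(
    estimate = object$coefficients,
    std_error = object$standard_errors,
    z = object$coefficients / object$standard_errors,
    p_value = object$p_values)
  if (!is.null(object$odds_ratios)) {
    tab$odds_ratio <- object$odds_ratios
    tab$ci_low <- object$ci_low
    tab$ci_high <- object$ci_high
  }
  structure(list(table = tab, deviance = object$deviance,
                 iterations = object$iterations,
                 converged = object$converged, n_total = object$n_total,
                 family = object$spec$family, n_sites = object$n_sites),
            class = "summary.fedglm")
}

#' @export
print.summary.fedglm <- function(x, digits = 4, ...) {
  cat(sprintf("Federated GLM summary (%s), %d site(s)\n", x$family,
              x$n_sites))
  print(round(x$table, digits))
  cat(sprintf("deviance %.4f on n = %d; %d IRLS iteration(s); converged: %s\n",
              x$deviance, x$n_total, x$iterations, x$converged))
  invisible(x)
}

#' @export
coef.fedglm <- function(object, ...) object$coefficients

#' @export
vcov.fedglm <- function(object, ...) object$vcov

#' @export
confint.fedglm <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(object$coefficients - z * object$standard_errors,
              object$coefficients + z * object$standard_errors)
  colnames(ci) <- paste0(100 * c((1 - level) / 2, 1 - (1 - level) / 2), " %")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' Predict from a federated GLM fit
#'
#' @param object A \code{fedglm} fit.
#' @param newdata Data frame containing the model's predictor columns.
#' @param type \code{"link"} for the linear predictor or \code{"response"}
#'   for the mean scale.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.fedglm <- function(object, newdata,
                           type = c("link", "response"), ...) {
  type <- match.arg(type)
  spec <- object$spec
  X <- matrix(1, nrow(newdata), 1L + length(spec$predictors))
  for (j in seq_along(spec$predictors))
    X[, j + 1L] <- as.numeric(newdata[[spec$predictors[j]]])
  eta <- drop(X %*% object$coefficients)
  if (type == "response" && spec$family == "binomial_logit")
    stats::plogis(eta)
  else eta
}
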