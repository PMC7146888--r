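#' Fit a K-component Gaussian mixture with observation-specific variances
#'
#' EM fit of the meta-QTL clustering model: projected peak positions `x_i`
#' are modelled as draws from K candidate loci with means `mu_k`, mixed with
#' weights `w_k`, where each observation keeps its own fixed standard
#' deviation `sd_i` derived from its projected confidence interval. Only the
#' K means and K-1 free weights are estimated (p = 2K - 1 parameters).
#'
#' E step: responsibilities `r_ik` proportional to `w_k * phi(x_i; mu_k, sd_i)`.
#' M step: `mu_k` is the responsibility- and precision-weighted mean
#' `sum(r_ik x_i / sd_i^2) / sum(r_ik / sd_i^2)`; `w_k = mean_i(r_ik)`.
#' Convergence when the log-likelihood improves by less than `tol` or after
#' `max_iter` iterations. The fit is restarted `n_restarts` times from
#' K-quantile initialisations with seeded jitter and the best valid restart is
#' kept; a restart is invalid if any component degenerates (weight below
#' `1/(10n)`) or ends up empty under hard assignment.
#'
#' @param x Numeric vector of positions (cM).
#' @param sd Positive per-observation standard deviations (cM), recycled if
#'   length 1.
#' @param K Number of components, `1 <= K <= length(x)`.
#' @param seed Integer seed making the restarts deterministic.
#' @param n_restarts Number of seeded restarts.
#' @param max_iter,tol EM stopping rule.
#' @return An object of class `qtl_mixture`: list with `K`, `means` (sorted
#'   ascending), `weights`, `loglik`, `n`, `assignments` (argmax posterior),
#'   `trace` (per-iteration log-likelihood of the winning restart),
#'   `converged`, `x`, `sd`; or `NULL` when no restart yields a valid model.
#' @export
fit_mixture <- function(x, sd, K, seed = 1, n_restarts = 10,
                        max_iter = 1000, tol = 1e-8) {
  n <- length(x)
  if (length(sd) == 1) sd <- rep(sd, n)
  stopifnot(length(sd) == n, all(sd > 0))
  if (K < 1 || K > n) stop("K must satisfy 1 <= K <= n")

  ## all restart jitter drawn up front so the fit is a pure function of seed
  withr_seed <- function(expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
  }
  spread <- max(stats::sd(x), min(sd))
  if (!is.finite(spread) || spread == 0) spread <- min(sd)
  jitter <- withr_seed(matrix(stats::rnorm(n_restarts * K, 0, spread / 4),
                              nrow = n_restarts))
  jitter[1, ] <- 0  # first restart is the plain quantile start

  base_means <- as.numeric(stats::quantile(x, probs = (seq_len(K) - 0.5) / K,
                                           names = FALSE, type = 7))
  prec <- 1 / sd^2
  best <- NULL
  for (r in seq_len(n_restarts)) {
    mu <- sort(base_means + jitter[r, ])
    w <- rep(1 / K, K)
    trace <- numeric(0)
    ll_old <- -Inf
    converged <- FALSE
    degenerate <- FALSE
    for (iter in seq_len(max_iter)) {
      ld <- vapply(seq_len(K), function(k) {
        stats::dnorm(x, mu[k], sd, log = TRUE) + log(w[k])
      }, numeric(n))
      ld <- matrix(ld, nrow = n)
      m <- apply(ld, 1, max)
      lse <- m + log(rowSums(exp(ld - m)))
      ll <- sum(lse)
      if (!is.finite(ll)) { degenerate <- TRUE; break }
      trace <- c(trace, ll)
      resp <- exp(ld - lse)
      if (is.finite(ll_old) && abs(ll - ll_old) < tol) { converged <- TRUE; break }
      ll_old <- ll
      mu <- colSums(resp * x * prec) / colSums(resp * prec)
      w <- colMeans(resp)
      ## a component losing all responsibility mass collapses the M step
      if (any(!is.finite(mu)) || any(w <= 0)) { degenerate <- TRUE; break }
    }
    if (degenerate) next
    assignments <- max.col(ld, ties.method = "first")
    valid <- all(w >= 1 / (10 * n)) &&
      length(unique(assignments)) == K &&
      all(is.finite(mu))
    if (valid && (is.null(best) || ll > best$loglik)) {
      ord <- order(mu)
      best <- list(K = K, means = mu[ord], weights = w[ord], loglik = ll,
                   n = n, assignments = match(assignments, ord),
                   trace = trace, converged = converged, x = x, sd = sd)
    }
  }
  if (is.null(best)) return(NULL)
  structure(best, class = "qtl_mixture")
}

#' @export
print.qtl_mixture <- function(x, ...) {
  cat("Gaussian mixture fit: K =", x$K, ", n =", x$n,
      ", logLik =", format(x$loglik, digits = 6), "\n")
  cat("  means (cM):", paste(format(x$means, digits = 4), collapse = ", "), "\n")
  cat("  weights:   ", paste(format(x$weights, digits = 3), collapse = ", "), "\n")
  invisible(x)
}

## classification log-likelihood: mixture density evaluated under hard
## (argmax-posterior) assignments
classification_loglik <- function(model) {
  z <- model$assignments
  sum(log(model$weights[z]) +
        stats::dnorm(model$x, model$means[z], model$sd, log = TRUE))
}

#' Information criteria for a fitted mixture
#'
#' Computes the five criteria used for model-order selection, with
#' `p = 2K - 1` free parameters (K means, K-1 weights; the per-observation
#' variances are data, not parameters):
#' `AIC = -2 lnL + 2p`; `AICc = AIC + 2p(p+1)/(n-p-1)` (NA when
#' `n - p - 1 <= 0`, in which case it abstains from the vote);
#' `AIC3 = -2 lnL + 3p`; `BIC = -2 lnL + p ln(n)`; and the approximate weight
#' of evidence `AWE = -2 lnL_c + 2p(3/2 + ln n)`, where `lnL_c` is the
#' classification log-likelihood under hard assignments.
#'
#' @param model A `qtl_mixture` object.
#' @return Named numeric vector `c(AIC, AICc, AIC3, BIC, AWE)`.
#' @export
information_criteria <- function(model) {
  stopifnot(inherits(model, "qtl_mixture"))
  n <- model$n
  p <- 2 * model$K - 1
  m2ll <- -2 * model$loglik
  aic <- m2ll + 2 * p
  aicc <- if (n - p - 1 > 0) aic + 2 * p * (p + 1) / (n - p - 1) else NA_real_
  llc <- classification_loglik(model)
  c(AIC = aic,
    AICc = aicc,
    AIC3 = m2ll + 3 * p,
    BIC = m2ll + p * log(n),
    AWE = -2 * llc + 2 * p * (3 / 2 + log(n)))
}

## modal vote with ties broken towards the smallest K (parsimony)
modal_k <- function(votes, fallback = 1L) {
  votes <- votes[!is.na(votes)]
  if (length(votes) == 0) return(as.integer(fallback))
  tallied <- table(votes)
  top <- as.integer(names(tallied)[tallied == max(tallied)])
  min(top)
}

#' Select the number of loci by a vote over five criteria
#'
#' Each available criterion votes for the candidate K at which it is minimal;
#' the chosen K is the modal vote, with ties broken towards the smallest K
#' (parsimony). An unavailable criterion value (e.g. AICc when
#' `n - p - 1 <= 0`) abstains for that candidate.
#'
#' @param models List of `qtl_mixture` objects (NULL entries, from invalid
#'   fits, are dropped).
#' @return List with `model` (the chosen fit), `K`, `votes` (named integer
#'   vector per criterion) and `criteria` (tibble of criterion values per K).
#' @export
select_model <- function(models) {
  models <- Filter(Negate(is.null), models)
  if (length(models) == 0) stop("no candidate models")
  ks <- vapply(models, function(m) as.integer(m$K), integer(1))
  crit <- t(vapply(models, information_criteria, numeric(5)))
  colnames(crit) <- c("AIC", "AICc", "AIC3", "BIC", "AWE")
  votes <- vapply(colnames(crit), function(cn) {
    v <- crit[, cn]
    if (all(is.na(v))) return(NA_integer_)
    ks[which.min(v)]  # which.min ignores NA; first minimum wins
  }, integer(1))
  chosen_k <- modal_k(votes, fallback = min(ks))
  criteria <- tibble::tibble(K = ks)
  for (cn in colnames(crit)) criteria[[cn]] <- crit[, cn]
  list(model = models[[which(ks == chosen_k)[1]]], K = chosen_k,
       votes = votes, criteria = criteria)
}
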