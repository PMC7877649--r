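#' Cumulative link mixed model specification
#'
#' Fixed terms are names over the coded predictors
#' (`sententiality`, `predictability`, `script_type`, `position`,
#' `familiarity`) and `:`-interactions of them. Random terms are given
#' per grouping factor (`subject`, `item`) as `"(Intercept)"` plus
#' fixed-term names; random effects are modeled as independent
#' (uncorrelated intercepts and slopes), one variance per term.
#' The link is the cumulative logit; categorical predictors are sum-coded
#' (-1, +1) and familiarity is the pooled z-score, both applied by
#' [prepare_design()].
#'
#' @param fixed character vector of fixed-effect terms.
#' @param random named list, e.g.
#'   `list(subject = c("(Intercept)", "sententiality"), item = "(Intercept)")`.
#' @return A `clmm_spec`.
#' @export
#' @examples
#' clmm_spec(c("sententiality", "predictability",
#'             "sententiality:predictability"),
#'           random = list(subject = "(Intercept)", item = "(Intercept)"))
clmm_spec <- function(fixed, random = list()) {
  fixed <- unique(as.character(fixed))
  for (g in names(random)) {
    if (!g %in% c("subject", "item")) {
      stop("unknown grouping factor: ", g, call. = FALSE)
    }
    extra <- setdiff(setdiff(random[[g]], "(Intercept)"), fixed)
    if (length(extra)) {
      # slopes for predictors outside the fixed part are allowed but must
      # still name known columns; checked at design time
    }
  }
  structure(list(fixed = fixed, random = random), class = "clmm_spec")
}

#' The final model of the acceptability case study
#'
#' Fixed effects Sententiality, Predictability, ScriptFamiliarity,
#' Position, Sententiality:Predictability and
#' Predictability:ScriptFamiliarity; by-subject and by-item random
#' intercepts and Sententiality slopes (the package's independent
#' random-effect reduction of the study's full structure).
#'
#' @return A `clmm_spec`.
#' @export
final_rating_spec <- function() {
  clmm_spec(
    fixed = c("sententiality", "predictability", "familiarity", "position",
              "sententiality:predictability", "predictability:familiarity"),
    random = list(subject = c("(Intercept)", "sententiality"),
                  item = c("(Intercept)", "sententiality"))
  )
}

#' The full model the backward selection starts from
#'
#' All five main effects, all two-way interactions among
#' Sententiality, Predictability, ScriptType and ScriptFamiliarity, the
#' Position main effect, and the
#' Sententiality:Predictability:ScriptFamiliarity three-way interaction.
#'
#' @inheritParams final_rating_spec
#' @param random random structure, defaulting to the one of
#'   [final_rating_spec()].
#' @return A `clmm_spec`.
#' @export
full_rating_spec <- function(random = list(
    subject = c("(Intercept)", "sententiality"),
    item = c("(Intercept)", "sententiality"))) {
  mains <- c("sententiality", "predictability", "script_type",
             "familiarity", "position")
  pairs <- c("sententiality:predictability", "sententiality:script_type",
             "sententiality:familiarity", "predictability:script_type",
             "predictability:familiarity", "script_type:familiarity")
  clmm_spec(c(mains, pairs, "sententiality:predictability:familiarity"),
            random = random)
}

#' Prepare a rating table for model fitting
#'
#' Drops control rows, sum-codes the categorical predictors (-1 for
#' sentence / predictable / two_participant, +1 for fragment /
#' unpredictable / adapted), z-scores familiarity over the available
#' values (pooled across subjects and scenarios), sets missing
#' familiarity to the z-scale mean 0 with a `familiarity_missing` flag,
#' and passes position through as numeric.
#'
#' @param table a rating table (schema of [sample_ratings()]).
#' @return A `clmm_design` data frame with columns `rating`, `subject`,
#'   `item`, the coded predictors, and `familiarity_missing`; attributes
#'   `n_familiarity_missing` and `familiarity_zero_variance`.
#' @export
prepare_design <- function(table) {
  d <- table[!(table$is_control %in% TRUE), , drop = FALSE]
  if (nrow(d) == 0L) stop("no experimental rows", call. = FALSE)
  if (!all(d$rating %in% 1:7)) {
    stop("ratings must be integers 1..7", call. = FALSE)
  }
  for (col in c("sententiality", "predictability")) {
    if (length(unique(d[[col]])) < 2L) {
      stop("predictor '", col, "' has a level absent entirely",
           call. = FALSE)
    }
  }
  out <- data.frame(
    rating = as.integer(d$rating),
    subject = factor(d$subject),
    item = factor(d$item),
    sententiality = code_sent(d$sententiality),
    predictability = code_pred(d$predictability),
    stringsAsFactors = FALSE)
  out$script_type <- if ("script_type" %in% names(d) &&
                         !all(is.na(d$script_type)))
    code_stype(d$script_type) else 0
  out$position <- if ("position" %in% names(d)) as.numeric(d$position) else 0

  fam_raw <- if ("familiarity_raw" %in% names(d)) d$familiarity_raw else
    rep(NA_real_, nrow(d))
  zero_var <- FALSE
  if (all(is.na(fam_raw))) {
    fam <- rep(0, nrow(d))
  } else {
    s <- sd(fam_raw, na.rm = TRUE)
    if (is.na(s) || s == 0) {
      warning("familiarity has zero variance; z-transform undefined, ",
              "using 0", call. = FALSE)
      zero_var <- TRUE
      fam <- rep(0, nrow(d))
    } else {
      fam <- (fam_raw - mean(fam_raw, na.rm = TRUE)) / s
      fam[is.na(fam)] <- 0
    }
  }
  out$familiarity <- fam
  out$familiarity_missing <- is.na(fam_raw)
  attr(out, "n_familiarity_missing") <- sum(is.na(fam_raw))
  attr(out, "familiarity_zero_variance") <- zero_var
  class(out) <- c("clmm_design", "data.frame")
  out
}

# ---- likelihood machinery ---------------------------------------------

design_matrices <- function(design, spec) {
  cols <- as.list(design[c("sententiality", "predictability", "script_type",
                           "position", "familiarity")])
  X <- do.call(cbind, lapply(spec$fixed, function(t) term_value(t, cols)))
  if (is.null(X)) X <- matrix(0, nrow(design), 0) else
    colnames(X) <- spec$fixed

  Z_cols <- list(); term_of <- integer(0); term_names <- character(0)
  for (g in names(spec$random)) {
    lev <- design[[g]]
    nlev <- nlevels(lev)
    for (t in spec$random[[g]]) {
      x <- if (t == "(Intercept)") rep(1, nrow(design)) else
        term_value(t, cols)
      M <- matrix(0, nrow(design), nlev)
      M[cbind(seq_len(nrow(design)), as.integer(lev))] <- x
      Z_cols[[length(Z_cols) + 1L]] <- M
      term_names <- c(term_names, paste0(g, "_", if (t == "(Intercept)")
        "intercept" else t))
      term_of <- c(term_of, rep(length(term_names), nlev))
    }
  }
  Z <- if (length(Z_cols)) do.call(cbind, Z_cols) else
    matrix(0, nrow(design), 0)
  list(X = X, Z = Z, term_of = term_of,
       term_names = unique(term_names))
}

# Log-likelihood, gradient and Hessian of the cumulative-logit model in
# the joint parameter xi = (theta, beta, b), penalized by the Gaussian
# random-effect prior. Thresholds enter directly (ordering maintained by
# step-halving in the Newton loop).
clogit_joint <- function(xi, y, K, X, Z, prec) {
  nth <- K - 1L
  p <- ncol(X); q <- ncol(Z)
  theta <- xi[seq_len(nth)]
  beta <- xi[nth + seq_len(p)]
  b <- xi[nth + p + seq_len(q)]
  if (is.unsorted(theta, strictly = TRUE)) return(list(value = -Inf))
  eta <- drop(X %*% beta) + (if (q) drop(Z %*% b) else 0)

  up <- ifelse(y < K, theta[pmin(y, nth)] - eta, Inf)
  lo <- ifelse(y > 1L, theta[pmax(y - 1L, 1L)] - eta, -Inf)
  F1 <- plogis(up); F0 <- plogis(lo)
  pr <- F1 - F0
  if (any(pr <= 0)) return(list(value = -Inf))
  value <- sum(log(pr)) - 0.5 * sum(prec * b^2)
  list(value = value, theta = theta, beta = beta, b = b, eta = eta,
       up = up, lo = lo, F1 = F1, F0 = F0, pr = pr)
}

clogit_grad_hess <- function(st, y, K, X, Z, prec) {
  nth <- K - 1L
  n <- length(y); p <- ncol(X); q <- ncol(Z)
  g1 <- ifelse(is.finite(st$up), dlogis(st$up), 0)
  g0 <- ifelse(is.finite(st$lo), dlogis(st$lo), 0)
  h1 <- g1 * (1 - 2 * st$F1)   # f'(a) for the logistic
  h0 <- g0 * (1 - 2 * st$F0)
  u1 <- g1 / st$pr
  u0 <- -g0 / st$pr
  w11 <- h1 / st$pr - u1^2
  w00 <- -h0 / st$pr - u0^2
  w10 <- g1 * g0 / st$pr^2

  # D1 = [T1 | -X | -Z], D0 = [T0 | -X | -Z] with T1/T0 threshold
  # indicator blocks; assembled densely (problem sizes are small).
  T1 <- matrix(0, n, nth); T0 <- matrix(0, n, nth)
  i1 <- which(y < K); T1[cbind(i1, y[i1])] <- 1
  i0 <- which(y > 1L); T0[cbind(i0, y[i0] - 1L)] <- 1
  XZ <- cbind(X, Z)
  D1 <- cbind(T1, -XZ); D0 <- cbind(T0, -XZ)

  grad <- drop(crossprod(D1, u1) + crossprod(D0, u0))
  H <- crossprod(D1 * w11, D1) + crossprod(D0 * w00, D0) +
    crossprod(D1 * w10, D0) + crossprod(D0 * w10, D1)
  if (q) {
    bi <- nth + p + seq_len(q)
    grad[bi] <- grad[bi] - prec * st$b
    H[cbind(bi, bi)] <- H[cbind(bi, bi)] - prec
  }
  list(grad = grad, hess = H)
}

# Newton maximization of the penalized joint log-likelihood with step
# halving; returns the mode, its value, and the Hessian blocks.
newton_joint <- function(xi0, y, K, X, Z, prec, tol = 1e-8,
                         max_iter = 50L) {
  xi <- xi0
  st <- clogit_joint(xi, y, K, X, Z, prec)
  if (!is.finite(st$value)) stop("infeasible start", call. = FALSE)
  for (it in seq_len(max_iter)) {
    gh <- clogit_grad_hess(st, y, K, X, Z, prec)
    step <- tryCatch(solve(gh$hess, gh$grad),
                     error = function(e) NULL)
    if (is.null(step)) {
      ridge <- max(abs(diag(gh$hess))) * 1e-8 + 1e-10
      step <- solve(gh$hess - diag(ridge, nrow(gh$hess)), gh$grad)
    }
    # maximization: Hessian is negative definite at the mode
    alpha <- 1
    repeat {
      cand <- xi - alpha * step
      st_new <- clogit_joint(cand, y, K, X, Z, prec)
      if (is.finite(st_new$value) && st_new$value >= st$value - 1e-12) break
      alpha <- alpha / 2
      if (alpha < 1e-10) { st_new <- st; cand <- xi; break }
    }
    improved <- st_new$value - st$value
    xi <- cand; st <- st_new
    if (abs(improved) < tol && max(abs(gh$grad)) < 1e-4) break
  }
  gh <- clogit_grad_hess(st, y, K, X, Z, prec)
  list(xi = xi, value = st$value, state = st, grad = gh$grad,
       hess = gh$hess)
}

#' Fit a cumulative link mixed model (Laplace approximation)
#'
#' Maximizes the cumulative-logit mixed likelihood: for candidate
#' random-effect SDs, the thresholds, fixed effects and random effects
#' are profiled out by a damped Newton solve of the penalized joint
#' log-likelihood (thresholds initialized at the marginal category
#' logits, coefficients at zero), and the marginal likelihood is
#' approximated by the Laplace method at that mode; the outer optimizer
#' (`nlminb` on the log-SD scale) maximizes the Laplace criterion.
#' Random effects are independent (uncorrelated intercepts and slopes).
#' The fit is deterministic: fixed starting values, fixed optimizer
#' settings, no randomness.
#'
#' @param design a `clmm_design` from [prepare_design()].
#' @param spec a [clmm_spec()].
#' @param start_log_sd starting value for every log-SD; default `log(0.5)`.
#' @return A `clmm_fit`: list with `coefficients` (data frame `term`,
#'   `estimate`, `se`, `z`, `p`), `thresholds`, `random_sd` (named),
#'   `loglik` (Laplace), `n`, `converged`, `spec`, `design` (kept for
#'   nested refits), and `message`.
#' @export
#' @examples
#' tab <- sample_ratings(rating_sim_spec(n_subjects = 12, n_items = 8,
#'   random_sds = c(subject_intercept = 0.5, item_intercept = 0.3)),
#'   seed = 2)
#' des <- prepare_design(tab)
#' sp <- clmm_spec(c("sententiality", "predictability"),
#'   random = list(subject = "(Intercept)", item = "(Intercept)"))
#' fit_clmm(des, sp)
fit_clmm <- function(design, spec, start_log_sd = log(0.5)) {
  stopifnot(inherits(design, "clmm_design"), inherits(spec, "clmm_spec"))
  y <- design$rating
  K <- 7L
  obs <- sort(unique(y))
  # unobserved end categories would leave their thresholds free; collapse
  y <- match(y, obs)
  K <- length(obs)
  mats <- design_matrices(design, spec)
  X <- mats$X; Z <- mats$Z
  p <- ncol(X); q <- ncol(Z); r <- length(mats$term_names)
  nth <- K - 1L

  freq <- cumsum(tabulate(y, K) / length(y))
  theta0 <- qlogis(pmin(pmax(freq[seq_len(nth)], 1e-6), 1 - 1e-6))
  theta0 <- cummax(theta0 + seq_len(nth) * 1e-8)
  xi0 <- c(theta0, rep(0, p + q))

  cache <- new.env()
  cache$xi <- xi0
  laplace <- function(log_sd) {
    sd_term <- exp(log_sd)
    prec <- if (q) 1 / sd_term[mats$term_of]^2 else numeric(0)
    sol <- newton_joint(cache$xi, y, K, X, Z, prec)
    cache$xi <- sol$xi
    if (q) {
      bi <- nth + p + seq_len(q)
      Hbb <- -sol$hess[bi, bi, drop = FALSE]
      ld <- determinant(Hbb, logarithm = TRUE)$modulus
      # log-marginal: penalized joint at mode - 0.5 log|Sigma| - 0.5 log|Hbb|
      val <- sol$value - sum(log(sd_term[mats$term_of])) - 0.5 * as.numeric(ld)
    } else {
      val <- sol$value
    }
    attr(val, "sol") <- sol
    val
  }

  if (r > 0L) {
    obj <- function(ls) -as.numeric(laplace(ls))
    opt <- nlminb(rep(start_log_sd, r), obj,
                  lower = rep(log(1e-4), r), upper = rep(log(20), r),
                  control = list(rel.tol = 1e-8, iter.max = 200L))
    log_sd <- opt$par
    converged <- opt$convergence == 0
    message <- opt$message
  } else {
    log_sd <- numeric(0)
    converged <- TRUE
    message <- "no random effects"
  }
  final <- laplace(log_sd)
  sol <- attr(final, "sol")

  est <- sol$xi[nth + seq_len(p)]
  # SEs from the joint Hessian (variance parameters held at their
  # estimates); the b block propagates random-effect uncertainty.
  cov_all <- tryCatch(solve(-sol$hess), error = function(e) {
    ridge <- max(abs(diag(sol$hess))) * 1e-8
    solve(-(sol$hess - diag(ridge, nrow(sol$hess))))
  })
  se <- sqrt(pmax(diag(cov_all)[nth + seq_len(p)], 0))
  zv <- est / se
  coefs <- data.frame(term = spec$fixed, estimate = unname(est),
                      se = unname(se), z = unname(zv),
                      p = 2 * stats::pnorm(-abs(unname(zv))),
                      stringsAsFactors = FALSE)
  thresholds <- unname(sol$xi[seq_len(nth)])
  if (any(diff(thresholds) <= 0)) converged <- FALSE

  structure(list(
    coefficients = coefs,
    thresholds = thresholds,
    random_sd = setNames(exp(log_sd), mats$term_names),
    loglik = as.numeric(final),
    n = length(y),
    n_fixed = p,
    converged = converged,
    message = message,
    spec = spec,
    design = design,
    ranef = setNames(sol$xi[nth + p + seq_len(q)], NULL),
    categories = obs
  ), class = "clmm_fit")
}

#' @export
print.clmm_fit <- function(x, ...) {
  cat("Cumulative link mixed model (Laplace), logit link\n")
  cat(sprintf("  n = %d, logLik = %.2f%s\n", x$n, x$loglik,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  if (length(x$random_sd)) {
    cat("  random-effect SDs:\n")
    for (nm in names(x$random_sd)) {
      cat(sprintf("    %-28s %.3f\n", nm, x$random_sd[[nm]]))
    }
  }
  cat("  fixed effects:\n")
  cf <- x$coefficients
  for (i in seq_len(nrow(cf))) {
    cat(sprintf("    %-36s %8.3f  (SE %.3f)\n", cf$term[i], cf$estimate[i],
                cf$se[i]))
  }
  cat("  thresholds:", paste(sprintf("%.2f", x$thresholds),
                             collapse = " "), "\n")
  invisible(x)
}

#' Predicted category probabilities
#'
#' Fixed-effects-only predictions (random effects at zero) for each row
#' of the fit's design; rows sum to 1.
#'
#' @param object a `clmm_fit`.
#' @param ... unused.
#' @return Matrix `n x K` of category probabilities.
#' @export
predict_probs <- function(object, ...) {
  stopifnot(inherits(object, "clmm_fit"))
  mats <- design_matrices(object$design, object$spec)
  eta <- drop(mats$X %*% object$coefficients$estimate)
  th <- c(-Inf, object$thresholds, Inf)
  P <- vapply(seq_len(length(th) - 1L), function(k) {
    plogis(th[k + 1L] - eta) - plogis(th[k] - eta)
  }, numeric(length(eta)))
  colnames(P) <- object$categories
  P
}

#' Likelihood-ratio test between nested CLMM fits
#'
#' @param full,reduced `clmm_fit`s on the same data with the same random
#'   structure; `reduced`'s fixed terms must be a subset of `full`'s.
#' @return List with `chisq` (`2 * (logLik_full - logLik_reduced)`,
#'   floored at 0), `df` (parameter difference) and `p`.
#' @export
lr_test <- function(full, reduced) {
  stopifnot(inherits(full, "clmm_fit"), inherits(reduced, "clmm_fit"))
  if (!all(reduced$spec$fixed %in% full$spec$fixed)) {
    stop("models are not nested (reduced has terms absent from full)",
         call. = FALSE)
  }
  if (!identical(full$spec$random, reduced$spec$random)) {
    stop("random structures differ; LR test requires the same structure",
         call. = FALSE)
  }
  if (full$n != reduced$n) stop("fits use different data", call. = FALSE)
  df <- full$n_fixed - reduced$n_fixed
  chisq <- max(0, 2 * (full$loglik - reduced$loglik))
  p <- if (df == 0L) 1 else pchisq(chisq, df, lower.tail = FALSE)
  list(chisq = chisq, df = df, p = p)
}

term_components <- function(t) strsplit(t, ":", fixed = TRUE)[[1L]]

# Marginality: a term may be dropped only if no retained term strictly
# contains it.
droppable_terms <- function(fixed) {
  Filter(function(t) {
    comp <- term_components(t)
    !any(vapply(fixed, function(o) {
      oc <- term_components(o)
      length(oc) > length(comp) && all(comp %in% oc)
    }, logical(1)))
  }, fixed)
}

#' Backward model selection by likelihood-ratio tests
#'
#' Starting from the full fixed structure, iteratively refits without
#' each droppable term (marginality respected: a term is droppable only
#' when no retained interaction contains it), removes the least
#' significant term whose LR p-value is at or above `alpha`, and repeats
#' until every droppable term is significant. The random structure is
#' held fixed throughout. `alpha = 0` retains the full model; `alpha >= 1`
#' removes every droppable term.
#'
#' @param design a `clmm_design`.
#' @param full_spec the starting [clmm_spec()].
#' @param alpha significance level; default 0.05.
#' @return List with `spec` (final), `fit` (final `clmm_fit`) and
#'   `trail` (data frame `step`, `term`, `chisq`, `df`, `p`, `dropped`).
#' @export
backward_select <- function(design, full_spec, alpha = 0.05) {
  stopifnot(inherits(full_spec, "clmm_spec"))
  trail <- data.frame(step = integer(0), term = character(0),
                      chisq = numeric(0), df = integer(0), p = numeric(0),
                      dropped = logical(0))
  spec <- full_spec
  fit <- fit_clmm(design, spec)
  step <- 0L
  repeat {
    if (alpha <= 0) break
    cands <- droppable_terms(spec$fixed)
    if (!length(cands)) break
    step <- step + 1L
    tests <- lapply(cands, function(t) {
      red <- clmm_spec(setdiff(spec$fixed, t), random = spec$random)
      rf <- fit_clmm(design, red)
      c(list(term = t, fit = rf), lr_test(fit, rf))
    })
    ps <- vapply(tests, function(x) x$p, numeric(1))
    worst <- which.max(ps)
    drop_it <- alpha >= 1 || ps[worst] >= alpha
    trail <- rbind(trail, data.frame(
      step = step, term = tests[[worst]]$term,
      chisq = tests[[worst]]$chisq, df = tests[[worst]]$df,
      p = ps[worst], dropped = drop_it))
    if (!drop_it) break
    spec <- clmm_spec(setdiff(spec$fixed, tests[[worst]]$term),
                      random = spec$random)
    fit <- tests[[worst]]$fit
    if (!length(spec$fixed)) break
  }
  list(spec = spec, fit = fit, trail = trail)
}
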