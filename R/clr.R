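## Conditional logistic regression for 1:M matched strata.
## The conditional likelihood per stratum s with case i(s) is
##   L_s = exp(x_i(s) beta) / sum_{j in s} exp(x_j beta),
## maximized by Newton-Raphson with analytic score and Hessian.

prepare_strata <- function(x, y, strata) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  y <- as.integer(y)
  if (length(y) != nrow(x) || length(strata) != nrow(x))
    stop("x, y and strata must have matching lengths")
  grp <- as.integer(factor(strata))
  sizes <- tabulate(grp)
  cases <- as.vector(rowsum(y, grp))
  if (any(sizes < 2L)) stop("every stratum must have at least 2 members")
  if (any(cases != 1L)) stop("every stratum must have exactly one case")
  list(x = x, y = y, grp = grp, n_strata = max(grp))
}

clr_eval <- function(beta, x, y, grp, n_strata, derivatives = TRUE) {
  eta <- drop(x %*% beta)
  m <- vapply(split(eta, grp), max, 0)          # per-stratum max (log-sum-exp)
  e <- exp(eta - m[grp])
  s <- as.vector(rowsum(e, grp))
  loglik <- sum(eta[y == 1L]) - sum(m + log(s))
  if (!derivatives) return(list(loglik = loglik))
  p <- e / s[grp]
  score <- drop(crossprod(x, y - p))
  xp <- x * p
  s1 <- rowsum(xp, grp)
  info <- crossprod(x, xp) - crossprod(s1)      # observed information (-Hessian)
  list(loglik = loglik, score = score, info = info, p = p)
}

#' Conditional log-likelihood of matched strata
#'
#' Evaluates the exact conditional log-likelihood for 1:M matched strata
#' (exactly one case per stratum), numerically stabilized with a per-stratum
#' log-sum-exp. At `beta = 0` this equals `sum(log(1/size_s))`; for a single
#' stratum with case exposure 1 and M controls at 0 it is
#' `beta - log(exp(beta) + M)`.
#'
#' @param beta coefficient vector.
#' @param x design matrix (or vector for a single covariate).
#' @param y 0/1 case indicator.
#' @param strata stratum identifiers.
#' @return The conditional log-likelihood (a scalar, always <= 0).
#' @export
conditional_loglik <- function(beta, x, y, strata) {
  d <- prepare_strata(x, y, strata)
  if (length(beta) != ncol(d$x))
    stop("length(beta) must equal ncol(x)")
  clr_eval(beta, d$x, d$y, d$grp, d$n_strata, derivatives = FALSE)$loglik
}

#' Fit conditional logistic regression by Newton-Raphson
#'
#' Maximizes the exact conditional likelihood of 1:M matched strata with
#' Newton-Raphson (analytic score and Hessian, step halving). Covariates that
#' are constant within every stratum (the matching variables) cancel from the
#' conditional likelihood; they are detected and dropped with a message.
#' Standard errors come from the inverse observed information; convergence
#' requires a relative log-likelihood change below `tol_loglik` and a maximum
#' absolute score below `tol_score`. (Quasi-)complete separation is flagged
#' when a coefficient exceeds `beta_guard` on the within-stratum standardized
#' scale while its Wald z falls below `z_guard`: a diverging coefficient whose
#' information has collapsed has no finite maximum-likelihood estimate. The
#' z condition keeps strongly identified but collinear terms (e.g. apparent
#' temperature and its square, whose individual standardized coefficients are
#' legitimately large) from being misflagged.
#'
#' @param x design matrix or vector.
#' @param y 0/1 case indicator (one case per stratum).
#' @param strata stratum identifiers.
#' @param init optional starting values (default 0).
#' @param max_iter,tol_loglik,tol_score,beta_guard,z_guard numerical controls.
#' @return An object of class `clr_fit`: coefficients, `se`, `vcov`,
#'   `loglik`, `loglik_null`, `aic`, `or`/`ci_lo`/`ci_hi`/`p` per term (Wald,
#'   95%), `lr_stat`/`lr_p` (likelihood-ratio test against the null),
#'   `converged`, `iterations`, `n_strata`, `dropped` (names of dropped
#'   within-stratum-constant columns).
#' @examples
#' set.seed(1)
#' x <- rnorm(400); strat <- rep(1:100, each = 4)
#' y <- as.integer(sequence(rep(4, 100)) == 1)
#' fit <- fit_clr(x, y, strat)
#' or_ci(fit)
#' @export
fit_clr <- function(x, y, strata, init = NULL, max_iter = 50L,
                    tol_loglik = 1e-10, tol_score = 1e-6, beta_guard = 10,
                    z_guard = 3) {
  d <- prepare_strata(x, y, strata)
  x <- d$x
  # within-stratum centering identifies constant (matched) covariates
  ctr <- x - apply(x, 2, function(cl) stats::ave(cl, d$grp))
  const <- apply(abs(ctr), 2, max) < 1e-12
  if (any(const)) {
    message("dropping within-stratum-constant column(s): ",
            paste(colnames(x)[const], collapse = ", "))
    x <- x[, !const, drop = FALSE]
    ctr <- ctr[, !const, drop = FALSE]
  }
  if (ncol(x) == 0L)
    stop("flat likelihood: no covariate varies within strata")
  qrc <- qr(ctr)
  if (qrc$rank < ncol(x)) {
    bad <- colnames(x)[-qrc$pivot[seq_len(qrc$rank)]]
    stop("rank-deficient design; drop column(s): ", paste(bad, collapse = ", "))
  }
  sds <- apply(ctr, 2, stats::sd)

  beta <- if (is.null(init)) rep(0, ncol(x)) else as.numeric(init)
  ev <- clr_eval(beta, x, d$y, d$grp, d$n_strata)
  loglik_null <- clr_eval(rep(0, ncol(x)), x, d$y, d$grp, d$n_strata,
                          derivatives = FALSE)$loglik
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    delta <- tryCatch(solve(ev$info, ev$score),
                      error = function(e) stop("singular information matrix (separation or degenerate design)"))
    step <- 1
    repeat {
      cand <- beta + step * delta
      ev_new <- clr_eval(cand, x, d$y, d$grp, d$n_strata)
      if (ev_new$loglik >= ev$loglik - 1e-12 || step < 1e-8) break
      step <- step / 2
    }
    rel_change <- abs(ev_new$loglik - ev$loglik) / (abs(ev$loglik) + 1e-12)
    beta <- cand
    ev <- ev_new
    big <- abs(beta * sds) > beta_guard
    if (any(big)) {
      se_cur <- sqrt(diag(solve(ev$info)))
      if (any(big & abs(beta / se_cur) < z_guard))
        stop("complete or quasi-complete separation: coefficient diverging")
    }
    if (rel_change < tol_loglik && max(abs(ev$score)) < tol_score) {
      converged <- TRUE
      break
    }
  }
  vc <- solve(ev$info)
  se <- sqrt(diag(vc))
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))
  zq <- stats::qnorm(0.975)
  lr <- 2 * (ev$loglik - loglik_null)
  structure(
    list(coef = stats::setNames(beta, colnames(x)),
         se = stats::setNames(se, colnames(x)), vcov = vc,
         loglik = ev$loglik, loglik_null = loglik_null,
         aic = -2 * ev$loglik + 2 * length(beta),
         or = exp(beta), ci_lo = exp(beta - zq * se), ci_hi = exp(beta + zq * se),
         p = p, lr_stat = lr,
         lr_p = stats::pchisq(lr, df = length(beta), lower.tail = FALSE),
         converged = converged, iterations = iter, n_strata = d$n_strata,
         dropped = colnames(d$x)[const]),
    class = "clr_fit"
  )
}

#' @export
print.clr_fit <- function(x, digits = 3, ...) {
  cat(sprintf("conditional logistic regression: %d strata, loglik %.4f, AIC %.2f%s\n",
              x$n_strata, x$loglik, x$aic,
              if (!x$converged) " (NOT converged)" else ""))
  tab <- data.frame(coef = x$coef, se = x$se, OR = x$or,
                    lo95 = x$ci_lo, hi95 = x$ci_hi, p = signif(x$p, 3))
  print(round(tab, digits))
  invisible(x)
}

#' Odds ratio with 95% confidence interval for a fitted term
#'
#' Rescales a fitted log-odds coefficient to a reporting unit (e.g. per
#' 10 ug/m3 with `scale = 10`): OR = exp(scale * beta), the Wald 95% CI is
#' exp(scale * (beta +/- 1.959964 se)), and the two-sided Wald p-value is
#' scale-invariant.
#'
#' @param fit a converged [fit_clr()] object.
#' @param term term name or index (default the first term).
#' @param scale exposure units per reported OR (default 1).
#' @return list with `or`, `lo`, `hi`, `p`.
#' @export
or_ci <- function(fit, term = 1L, scale = 1) {
  stopifnot(inherits(fit, "clr_fit"))
  if (!fit$converged) stop("fit did not converge; no OR reported")
  b <- fit$coef[term]; s <- fit$se[term]
  if (any(is.na(b))) stop("unknown term: ", term)
  zq <- stats::qnorm(0.975)
  list(or = exp(scale * b),
       lo = exp(scale * (b - zq * s)),
       hi = exp(scale * (b + zq * s)),
       p = unname(2 * stats::pnorm(-abs(b / s))))
}

#' Screen candidate effect modifiers
#'
#' Each candidate group is added to the base model in its own conditional
#' logistic regression run; a modifier is retained when its term's two-sided
#' Wald p-value is at or below `p_screen` (default 0.09). In `"interaction"`
#' mode the exposure-by-modifier product term is screened instead of the
#' modifier's own term. Groups whose fit fails (e.g. a modifier constant
#' within all strata after matching) are skipped with the error recorded.
#'
#' @param x_base base-model design matrix (exposure plus confounders).
#' @param y 0/1 case indicator.
#' @param strata stratum identifiers.
#' @param modifier_groups named list of groups; each group is a named list /
#'   data.frame / matrix of candidate modifier columns.
#' @param p_screen retention threshold (default 0.09).
#' @param mode `"main"` screens the modifier's own term, `"interaction"` the
#'   exposure x modifier term.
#' @param exposure exposure column of `x_base` used to build interactions
#'   (name or index; default the first column).
#' @return data.frame with columns `group`, `modifier`, `p`, `retained`;
#'   attribute `errors` lists skipped groups.
#' @export
screen_effect_modifiers <- function(x_base, y, strata, modifier_groups,
                                    p_screen = 0.09,
                                    mode = c("main", "interaction"),
                                    exposure = 1L) {
  mode <- match.arg(mode)
  stopifnot(p_screen > 0, p_screen < 1)
  x_base <- as.matrix(x_base)
  if (is.null(colnames(x_base))) colnames(x_base) <- paste0("x", seq_len(ncol(x_base)))
  res <- list(); errs <- list()
  for (g in names(modifier_groups)) {
    grp_cols <- as.matrix(as.data.frame(modifier_groups[[g]]))
    test_cols <- grp_cols
    if (mode == "interaction") {
      test_cols <- grp_cols * x_base[, exposure]
      colnames(test_cols) <- paste0(colnames(grp_cols), ":exposure")
      test_cols <- cbind(grp_cols, test_cols)
    }
    fit <- tryCatch(suppressMessages(fit_clr(cbind(x_base, test_cols), y, strata)),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      errs[[g]] <- conditionMessage(fit)
      next
    }
    keep_names <- if (mode == "main") colnames(grp_cols) else
      paste0(colnames(grp_cols), ":exposure")
    pv <- fit$p[match(keep_names, names(fit$coef))]
    if (anyNA(pv))   # term(s) dropped as within-stratum constant
      errs[[g]] <- paste("modifier term(s) constant within strata:",
                         paste(keep_names[is.na(pv)], collapse = ", "))
    res[[g]] <- data.frame(group = g, modifier = colnames(grp_cols),
                           p = unname(pv),
                           retained = unname(!is.na(pv) & pv <= p_screen),
                           stringsAsFactors = FALSE)
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(group = character(), modifier = character(),
               p = numeric(), retained = logical())
  rownames(out) <- NULL
  attr(out, "errors") <- errs
  out
}
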