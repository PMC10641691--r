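#' Incidence matrix mapping observations to effect levels
#'
#' @param ids character/factor vector, one entry per observation.
#' @param levels the effect levels (columns); defaults to the unique values
#'   of `ids` in order of appearance.
#' @return 0/1 matrix of dimension `length(ids) x length(levels)`.
#' @export
incidence <- function(ids, levels = NULL) {
  ids <- as.character(ids)
  if (is.null(levels)) levels <- unique(ids)
  j <- match(ids, levels)
  if (anyNA(j)) {
    stop("ids missing from the supplied levels: ",
         paste(utils::head(unique(ids[is.na(j)]), 3), collapse = ", "))
  }
  Z <- matrix(0, length(ids), length(levels),
              dimnames = list(NULL, levels))
  Z[cbind(seq_along(ids), j)] <- 1
  Z
}

.term_VC <- function(term, n) {
  Z <- term$Z; K <- term$K
  if (is.null(Z) && is.null(K)) stop("random term needs Z and/or K")
  if (is.null(Z)) {
    if (nrow(K) != n) stop("K without Z must be n x n")
    list(V = K, C = K, q = ncol(K), kdiag = diag(K),
         labels = colnames(K) %||% as.character(seq_len(ncol(K))))
  } else if (is.null(K)) {
    list(V = tcrossprod(Z), C = Z, q = ncol(Z), kdiag = rep(1, ncol(Z)),
         labels = colnames(Z) %||% as.character(seq_len(ncol(Z))))
  } else {
    C <- Z %*% K
    list(V = tcrossprod(C, Z), C = C, q = ncol(K), kdiag = diag(K),
         labels = colnames(K) %||% as.character(seq_len(ncol(K))))
  }
}

#' REML estimation of variance components for mixed models with
#' arbitrary relationship matrices
#'
#' Fits `y = X beta + sum_k Z_k u_k + e` with `u_k ~ N(0, sigma2_k K_k)` and
#' `e ~ N(0, sigma2_e I)` by restricted maximum likelihood. With a single
#' random term the profile likelihood is maximized on the spectral
#' decomposition of `Z K Z'` (fast and robust, used for ABLUP/GBLUP/HBLUP
#' individual-tree models); with several terms average-information (AI) REML
#' is used, falling back to an expectation-maximization step whenever the AI
#' update leaves the parameter space or decreases the likelihood. Variance
#' components are kept above a small positive bound (`1e-8 * var(y)`), so
#' null components converge to the boundary rather than exactly zero.
#' Solutions (BLUE/BLUP) and prediction error variances are computed at the
#' converged components from the mixed-model equations in their
#' variance-matrix form.
#'
#' @param y numeric response vector.
#' @param X fixed-effect design matrix (default: intercept only).
#' @param random named list of random terms; each term is a list with `Z`
#'   (incidence matrix, `NULL` for identity) and `K` (covariance/relationship
#'   matrix, `NULL` for identity). See [incidence()].
#' @param init optional named starting values for the variance components
#'   (terms then `"residual"`).
#' @param tol convergence tolerance on the change in restricted
#'   log-likelihood, default 1e-8.
#' @param max_iter maximum iterations, default 200.
#' @param compute_pev compute prediction error variances (adds one dense
#'   solve per term), default TRUE.
#' @param verbose print the iteration trace.
#' @return object of class `reml_fit` with elements `components` (named,
#'   includes `residual`), `component_se`, `logLik`, `converged`,
#'   `iterations`, `beta`, `random` (per term: `u` named solutions and `pev`),
#'   `trace`.
#' @export
reml_estimate <- function(y, X = NULL, random, init = NULL, tol = 1e-8,
                          max_iter = 200, compute_pev = TRUE,
                          verbose = FALSE) {
  y <- as.numeric(y)
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  if (qr(X)$rank < ncol(X)) X <- X[, qr(X)$pivot[seq_len(qr(X)$rank)], drop = FALSE]
  if (n < ncol(X) + 2) stop("too few observations for the fixed effects")
  if (is.null(names(random)) || any(names(random) == "")) {
    stop("random terms must be named")
  }
  terms <- lapply(random, .term_VC, n = n)
  vy <- stats::var(y)
  lb <- 1e-8 * vy
  ub <- 1e4 * vy
  nt <- length(terms)
  theta <- if (!is.null(init)) {
    pmin(pmax(as.numeric(init[c(names(terms), "residual")]), lb), ub)
  } else rep(vy / (nt + 1), nt + 1)
  names(theta) <- c(names(terms), "residual")

  if (nt == 1L) {
    res <- .reml_eigen(y, X, terms[[1]]$V, theta, lb, ub, tol, verbose)
  } else {
    res <- .reml_ai(y, X, lapply(terms, `[[`, "V"), theta, lb, ub, tol,
                    max_iter, verbose)
  }
  theta <- res$theta
  sol <- .reml_solutions(y, X, terms, theta, compute_pev = compute_pev)
  structure(list(components = theta, component_se = res$se,
                 logLik = res$logLik, converged = res$converged,
                 iterations = res$iterations, beta = sol$beta,
                 random = sol$random, n = n, trace = res$trace,
                 method = if (nt == 1L) "eigen-profile" else "ai-reml"),
            class = "reml_fit")
}

# restricted log-likelihood pieces for diagonalized single-term models
.reml_eigen <- function(y, X, V1, theta, lb, ub, tol, verbose) {
  E <- eigen(V1, symmetric = TRUE)
  lam <- pmax(E$values, 0)
  U <- E$vectors
  yt <- crossprod(U, y)
  Xt <- crossprod(U, X)
  negll <- function(lpar) {
    s <- exp(lpar)
    d <- s[1] * lam + s[2]
    Xd <- Xt / d
    M <- crossprod(Xt, Xd)
    cM <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(cM)) return(1e10)
    xy <- crossprod(Xd, yt)
    b <- backsolve(cM, forwardsolve(t(cM), xy))
    ypy <- sum(yt^2 / d) - sum(xy * b)
    0.5 * (sum(log(d)) + 2 * sum(log(diag(cM))) + ypy)
  }
  opt <- stats::optim(log(theta), negll, method = "L-BFGS-B",
                      lower = log(lb), upper = log(ub),
                      control = list(factr = 1e4, maxit = 200))
  th <- exp(opt$par)
  names(th) <- names(theta)
  se <- tryCatch({
    H <- stats::optimHess(opt$par, negll)
    J <- diag(th)  # d theta / d log theta
    cov <- J %*% solve(H) %*% J
    sqrt(pmax(diag(cov), 0))
  }, error = function(e) rep(NA_real_, 2))
  names(se) <- names(theta)
  if (verbose) message("eigen-profile REML: logL = ", -opt$value,
                       " after ", opt$counts[1], " evaluations")
  list(theta = th, se = se, logLik = -opt$value,
       converged = opt$convergence == 0, iterations = opt$counts[[1]],
       trace = NULL)
}

.reml_ai <- function(y, X, Vlist, theta, lb, ub, tol, max_iter, verbose) {
  n <- length(y)
  nt <- length(Vlist)
  restll <- function(th) {
    V <- diag(th[nt + 1], n)
    for (k in seq_len(nt)) V <- V + th[k] * Vlist[[k]]
    cV <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(cV)) return(list(ll = -Inf))
    Vinv <- chol2inv(cV)
    W <- Vinv %*% X
    M <- crossprod(X, W)
    cM <- chol(M)
    Minv <- chol2inv(cM)
    P <- Vinv - W %*% Minv %*% t(W)
    Py <- P %*% y
    ll <- -0.5 * (2 * sum(log(diag(cV))) + 2 * sum(log(diag(cM))) +
                    sum(y * Py))
    list(ll = ll, P = P, Py = Py)
  }
  cur <- restll(theta)
  if (!is.finite(cur$ll)) stop("starting values give a singular V")
  trace <- data.frame(iter = 0, logLik = cur$ll,
                      t(theta))
  converged <- FALSE
  it <- 0
  se <- rep(NA_real_, nt + 1)
  for (it in seq_len(max_iter)) {
    P <- cur$P; Py <- cur$Py
    Fm <- matrix(0, n, nt + 1)
    trPV <- numeric(nt + 1)
    for (k in seq_len(nt)) {
      Fm[, k] <- Vlist[[k]] %*% Py
      trPV[k] <- sum(P * Vlist[[k]])
    }
    Fm[, nt + 1] <- Py
    trPV[nt + 1] <- sum(diag(P))
    score <- -0.5 * (trPV - as.numeric(crossprod(Py, Fm)))
    AI <- 0.5 * crossprod(Fm, P %*% Fm)
    # active set: components pinned at the lower bound stay there while the
    # restricted likelihood still pushes them down
    held <- theta <= lb * 1.01 & score < 0
    newtheta <- NULL
    if (!all(held)) {
      AIf <- AI[!held, !held, drop = FALSE]
      scl <- mean(diag(AIf))
      # Levenberg-style damping handles the near-singular AI matrices that
      # arise when components are weakly identified (e.g. additive vs
      # dominance in predominantly full-sib data)
      for (damp in c(0, 1e-4, 1e-2, 1) * scl) {
        step <- tryCatch(solve(AIf + diag(damp, nrow(AIf)), score[!held]),
                         error = function(e) NULL)
        if (is.null(step)) next
        for (h in 0:8) {  # step halving with projection onto the bounds
          cand <- theta
          cand[!held] <- theta[!held] + step / 2^h
          cand[held] <- lb
          cand <- pmin(pmax(cand, lb), ub)
          trial <- restll(cand)
          if (is.finite(trial$ll) && trial$ll >= cur$ll - 1e-10) {
            newtheta <- cand; newfit <- trial; break
          }
        }
        if (!is.null(newtheta)) break
      }
    }
    if (is.null(newtheta)) {  # EM fallback step
      qk <- rep(n, nt + 1)
      em <- theta + theta^2 * (as.numeric(crossprod(Py, Fm)) - trPV) / qk
      cand <- pmin(pmax(em, lb), ub)
      trial <- restll(cand)
      if (!is.finite(trial$ll)) break
      newtheta <- cand; newfit <- trial
    }
    dll <- newfit$ll - cur$ll
    oldtheta <- theta
    theta <- newtheta; cur <- newfit
    trace <- rbind(trace, data.frame(iter = it, logLik = cur$ll, t(theta)))
    if (verbose) message("iter ", it, " logL ", format(cur$ll), " theta ",
                         paste(format(theta, digits = 4), collapse = " "))
    relchange <- max(abs(newtheta - oldtheta) / pmax(oldtheta, lb))
    if (abs(dll) < tol || relchange < 1e-8) { converged <- TRUE; break }
  }
  se <- tryCatch(sqrt(pmax(diag(solve(AI)), 0)), error = function(e) se)
  names(se) <- names(theta)
  if (!converged) {
    warning("AI-REML did not converge in ", max_iter,
            " iterations (|dlogL| last = ", format(abs(dll)), ")")
  }
  list(theta = theta, se = se, logLik = cur$ll, converged = converged,
       iterations = it, trace = trace)
}

.reml_solutions <- function(y, X, terms, theta, compute_pev = TRUE) {
  n <- length(y)
  V <- diag(theta[["residual"]], n)
  for (k in seq_along(terms)) V <- V + theta[[k]] * terms[[k]]$V
  Vinv <- chol2inv(chol(V))
  W <- Vinv %*% X
  M <- solve(crossprod(X, W))
  beta <- as.numeric(M %*% crossprod(W, y))
  names(beta) <- colnames(X)
  P <- Vinv - W %*% M %*% t(W)
  Py <- P %*% y
  rand <- list()
  for (k in seq_along(terms)) {
    tk <- terms[[k]]
    u <- as.numeric(theta[[k]] * crossprod(tk$C, Py))
    names(u) <- tk$labels
    pev <- NULL
    if (compute_pev) {
      PC <- P %*% tk$C
      pev <- theta[[k]] * tk$kdiag - theta[[k]]^2 * colSums(tk$C * PC)
      names(pev) <- tk$labels
    }
    rand[[names(terms)[k]]] <- list(u = u, pev = pev)
  }
  list(beta = beta, random = rand)
}

#' @export
print.reml_fit <- function(x, ...) {
  cat("REML fit (", x$method, "), n = ", x$n,
      if (x$converged) ", converged" else ", NOT converged", "\n", sep = "")
  cat("logLik:", format(x$logLik), "\n")
  cat("variance components:\n")
  print(round(rbind(estimate = x$components, se = x$component_se), 6))
  invisible(x)
}

#' Solve Henderson's mixed-model equations at fixed variance components
#'
#' Builds and solves
#' \deqn{\begin{pmatrix} X'X & X'Z \\ Z'X & Z'Z + K^{-1}\lambda \end{pmatrix}
#'       \begin{pmatrix} \hat\beta \\ \hat u \end{pmatrix} =
#'       \begin{pmatrix} X'y \\ Z'y \end{pmatrix}}
#' with `lambda = sigma2_e / sigma2_u` per term. Prediction error variances
#' are the diagonal of the random-effect block of the inverse coefficient
#' matrix times `sigma2_e`.
#'
#' @param y response vector.
#' @param X fixed design matrix (default intercept).
#' @param random named list of terms: each a list with `Z` (incidence,
#'   `NULL` for identity), `Kinv` (inverse covariance, `NULL` for identity)
#'   and `variance` (the term's variance component).
#' @param residual_variance residual variance.
#' @return list with `beta`, and per term `u` and `pev`.
#' @export
solve_mme <- function(y, X = NULL, random, residual_variance) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  Zs <- list(); Pen <- list(); labs <- list()
  for (nm in names(random)) {
    tm <- random[[nm]]
    Z <- tm$Z
    q <- if (!is.null(Z)) ncol(Z) else if (!is.null(tm$Kinv)) ncol(tm$Kinv) else
      stop("term ", nm, " needs Z or Kinv")
    if (is.null(Z)) Z <- diag(n)
    Kinv <- tm$Kinv %||% diag(q)
    lam <- residual_variance / tm$variance
    Zs[[nm]] <- Z
    Pen[[nm]] <- Kinv * lam
    labs[[nm]] <- colnames(Z) %||% (if (!is.null(tm$Kinv)) colnames(tm$Kinv) else NULL) %||%
      as.character(seq_len(q))
  }
  Z <- do.call(cbind, Zs)
  p <- ncol(X); qtot <- ncol(Z)
  Cmat <- matrix(0, p + qtot, p + qtot)
  Cmat[1:p, 1:p] <- crossprod(X)
  Cmat[1:p, p + 1:qtot] <- crossprod(X, Z)
  Cmat[p + 1:qtot, 1:p] <- t(Cmat[1:p, p + 1:qtot])
  ZZ <- crossprod(Z)
  offs <- c(0, cumsum(vapply(Zs, ncol, 1L)))
  for (k in seq_along(Zs)) {
    idx <- (offs[k] + 1):offs[k + 1]
    ZZ[idx, idx] <- ZZ[idx, idx] + Pen[[k]]
  }
  Cmat[p + 1:qtot, p + 1:qtot] <- ZZ
  rhs <- c(crossprod(X, y), crossprod(Z, y))
  Cinv <- tryCatch(solve(Cmat), error = function(e) {
    stop("singular MME coefficient matrix (rank ", qr(Cmat)$rank, " of ",
         nrow(Cmat), ")", call. = FALSE)
  })
  sol <- as.numeric(Cinv %*% rhs)
  out <- list(beta = stats::setNames(sol[1:p], colnames(X)))
  for (k in seq_along(Zs)) {
    idx <- p + (offs[k] + 1):offs[k + 1]
    u <- stats::setNames(sol[idx], labs[[k]])
    pev <- stats::setNames(diag(Cinv)[idx] * residual_variance, labs[[k]])
    out[[names(Zs)[k]]] <- list(u = u, pev = pev)
  }
  out
}

#' Narrow- and broad-sense heritability from variance components
#'
#' `h2_narrow = additive / (additive + dominance + residual)` and
#' `h2_broad = (additive + dominance) / (additive + dominance + residual)`,
#' with the dominance component zero for additive-only models. Block (and
#' any other design) variances are excluded from the denominator.
#'
#' @param components named numeric vector containing `additive`, `residual`
#'   and optionally `dominance`; other entries (e.g. `block`) are ignored.
#' @return list with `h2_narrow` and `h2_broad`.
#' @export
heritability <- function(components) {
  va <- components[["additive"]]
  vd <- if ("dominance" %in% names(components)) components[["dominance"]] else 0
  if (is.na(vd)) vd <- 0
  ve <- components[["residual"]]
  denom <- va + vd + ve
  if (denom <= 0) stop("zero total variance in heritability denominator")
  list(h2_narrow = va / denom, h2_broad = (va + vd) / denom)
}

#' De-regress estimated breeding values
#'
#' `dEBV = EBV / r2` with `r2` the reliability (squared accuracy) of each
#' EBV. Parental-average effects are not removed.
#'
#' @param ebv numeric vector of EBVs.
#' @param reliability reliabilities in `(0, 1]`, recycled if scalar.
#' @return vector of de-regressed EBVs.
#' @export
deregress <- function(ebv, reliability) {
  if (any(reliability <= 0) || any(reliability > 1)) {
    stop("reliabilities must be in (0, 1]")
  }
  ebv / reliability
}

#' Reliability of breeding values from prediction error variance
#'
#' `r2 = 1 - PEV / sigma2_a`, truncated into `[0, 1]`.
#'
#' @param pev prediction error variances.
#' @param sigma2_a additive genetic variance.
#' @return reliabilities in `[0, 1]`.
#' @export
reliability <- function(pev, sigma2_a) {
  pmin(pmax(1 - pev / sigma2_a, 0), 1)
}
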