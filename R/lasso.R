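## Lasso-path regression of regional peak density.
##
## The lasso solves min_b 0.5 ||y - X b||^2 + lambda ||b||_1 on a
## standardized design (columns centered, unit L2 norm; response
## centered).  The least-angle regression homotopy with the lasso
## modification traces the exact piecewise-linear solution path in
## lambda: between knots the active coefficients move linearly, a
## variable enters when its absolute correlation with the residual
## reaches the common active-set level, and leaves when its coefficient
## crosses zero.  The covariance test assigns each entry event a
## statistic that is asymptotically Exp(1) under the null that all
## signal variables are already in the model.

#' Build a standardized design matrix for peak-density regression
#'
#' The response is the peak count per window, scaled to peaks per nominal
#' window width (partial terminal windows are scaled by their true width)
#' and centered.  Covariates are the per-window basepair fraction of each
#' feature set and the per-window mean of each site-level track, each
#' centered and scaled to unit Euclidean norm.  Constant covariates are
#' dropped with a warning.
#'
#' @param peaks `GRanges` of peaks.
#' @param windows `GRanges` from [make_windows()].
#' @param feature_sets Named list of `GRanges`; covariate = fraction of
#'   window covered.
#' @param tracks Named list of `GRanges` with `score`; covariate = mean
#'   score of sites in window (`NA`-free windows imputed with the track
#'   mean).
#' @param log_response Use `log1p` of the scaled count instead.
#' @return A `DesignMatrix` list: `X` (n x p, standardized), `y`
#'   (centered), `names`, `n`, `p`, plus the centring/scaling constants.
#' @export
build_design <- function(peaks, windows, feature_sets = list(),
                         tracks = list(), log_response = FALSE) {
  nominal <- max(BiocGenerics::width(windows))
  counts <- GenomicRanges::countOverlaps(windows, peaks,
                                         ignore.strand = TRUE)
  dens <- counts / BiocGenerics::width(windows) * nominal
  if (log_response) dens <- log1p(dens)
  cols <- list()
  for (nm in names(feature_sets)) {
    f <- GenomicRanges::reduce(feature_sets[[nm]], ignore.strand = TRUE)
    hits <- GenomicRanges::findOverlaps(windows, f, ignore.strand = TRUE)
    ov <- BiocGenerics::width(IRanges::pintersect(
      windows[S4Vectors::queryHits(hits)], f[S4Vectors::subjectHits(hits)],
      ignore.strand = TRUE))
    bp <- rep(0, length(windows))
    agg <- tapply(ov, S4Vectors::queryHits(hits), sum)
    bp[as.integer(names(agg))] <- agg
    cols[[nm]] <- bp / BiocGenerics::width(windows)
  }
  for (nm in names(tracks)) {
    tr <- tracks[[nm]]
    v <- S4Vectors::mcols(tr)$score
    hits <- GenomicRanges::findOverlaps(tr, windows, ignore.strand = TRUE)
    m <- rep(NA_real_, length(windows))
    agg <- tapply(v[S4Vectors::queryHits(hits)],
                  S4Vectors::subjectHits(hits), mean)
    m[as.integer(names(agg))] <- agg
    m[is.na(m)] <- mean(v)
    cols[[nm]] <- m
  }
  if (length(cols) < 2)
    stop("need at least 2 covariates")
  standardize_design(do.call(cbind, cols), dens)
}

#' Standardize a raw design matrix and response
#'
#' @param x Numeric matrix (n x p) of raw covariates.
#' @param y Numeric response of length n.
#' @return A `DesignMatrix` list (see [build_design()]).
#' @export
standardize_design <- function(x, y) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  ctr <- colMeans(x)
  xc <- sweep(x, 2, ctr)
  nrm <- sqrt(colSums(xc^2))
  keep <- nrm > 1e-12
  if (!all(keep)) {
    warning("dropping constant covariate(s): ",
            paste(colnames(x)[!keep], collapse = ", "))
    xc <- xc[, keep, drop = FALSE]
    nrm <- nrm[keep]
  }
  if (ncol(xc) < 2) stop("fewer than 2 usable covariates")
  xs <- sweep(xc, 2, nrm, "/")
  structure(list(X = xs, y = y - mean(y), names = colnames(xs),
                 n = nrow(xs), p = ncol(xs), centers = ctr[keep],
                 scales = nrm, y_center = mean(y)),
            class = "DesignMatrix")
}

#' Lasso solution path by least-angle regression
#'
#' Computes every knot of the lasso path (lambda strictly decreasing from
#' `max |X'y|` to 0), with the lasso modification: variables can leave
#' the active set when a coefficient crosses zero.  Between knots the
#' coefficients are linear in lambda; [lasso_at_lambda()] interpolates.
#'
#' @param design A `DesignMatrix` from [build_design()] /
#'   [standardize_design()], or a plain standardized matrix (then `y`
#'   must be given).
#' @param y Centered response when `design` is a bare matrix.
#' @param max_steps Cap on the number of path events (default: run to
#'   lambda = 0).
#' @return A `LassoPath` list: `lambda` (knots, first is lambda_max with
#'   all-zero coefficients), `beta` (p x length(lambda)), `action`
#'   (+j entry / -j drop at each knot after the first), `entries`
#'   (data frame of entry events: variable, knot index, lambda), `names`.
#' @export
lars_lasso_path <- function(design, y = NULL, max_steps = Inf) {
  if (is.list(design)) { X <- design$X; y <- design$y }
  else X <- as.matrix(design)
  n <- nrow(X); p <- ncol(X)
  if (n < 2) stop("need n >= 2")
  vnames <- colnames(X)
  if (is.null(vnames)) vnames <- paste0("x", seq_len(p))
  G <- crossprod(X)          # p x p Gram, fine at the tens-of-covariates scale
  c_all <- drop(crossprod(X, y))
  lam <- max(abs(c_all))
  active <- integer(0)
  beta <- numeric(p)
  lambda_knots <- lam
  beta_knots <- list(beta)
  action <- integer(0)
  eps <- 1e-10
  if (lam < eps) {
    return(structure(list(lambda = c(lam, 0), beta = cbind(beta, beta),
                          action = 0L, entries = data.frame(
                            variable = integer(), knot = integer(),
                            lambda = numeric()), names = vnames),
                     class = "LassoPath"))
  }
  first <- which.max(abs(c_all))
  pending_entry <- first
  blocked <- integer(0)
  step <- 0
  while (lam > eps && step < max_steps) {
    step <- step + 1
    if (!is.null(pending_entry)) {
      cand <- c(active, pending_entry)
      if (rcond_psd(G[cand, cand, drop = FALSE]) < 1e-12) {
        warning("rank-deficient active set; skipping covariate ",
                vnames[pending_entry])
        blocked <- c(blocked, pending_entry)
        pending_entry <- NULL
        ## knot recorded for this event is withdrawn: nothing changed there
        if (length(lambda_knots) > 1) {
          lambda_knots <- lambda_knots[-length(lambda_knots)]
          beta_knots <- beta_knots[-length(beta_knots)]
        }
      } else {
        active <- cand
        action <- c(action, pending_entry)
        pending_entry <- NULL
      }
    }
    if (!length(active)) break
    s_A <- sign(c_all[active])
    d_A <- solve(G[active, active, drop = FALSE], s_A)
    a_all <- drop(G[, active, drop = FALSE] %*% d_A)
    inactive <- setdiff(seq_len(p), c(active, blocked))
    ## entry times (gamma = lam - lambda_event)
    gamma_entry <- rep(Inf, p); side <- rep(NA, p)
    for (j in inactive) {
      g1 <- (lam - c_all[j]) / (1 - a_all[j])
      g2 <- (lam + c_all[j]) / (1 + a_all[j])
      for (g in c(g1, g2)) {
        if (is.finite(g) && g > eps && g < gamma_entry[j]) gamma_entry[j] <- g
      }
    }
    ## drop times
    gamma_drop <- rep(Inf, length(active))
    gd <- -beta[active] / d_A
    gamma_drop[is.finite(gd) & gd > eps] <- gd[is.finite(gd) & gd > eps]
    g_ent <- if (length(inactive)) min(gamma_entry[inactive]) else Inf
    g_drp <- if (length(active)) min(gamma_drop) else Inf
    gamma <- min(g_ent, g_drp, lam)
    new_lam <- lam - gamma
    beta[active] <- beta[active] + gamma * d_A
    c_all <- c_all - gamma * a_all
    lam <- new_lam
    if (gamma == g_drp && g_drp <= g_ent && lam > eps) {
      k <- which.min(gamma_drop)
      dropped <- active[k]
      beta[dropped] <- 0
      active <- active[-k]
      action <- c(action, -dropped)
      lambda_knots <- c(lambda_knots, lam)
      beta_knots[[length(beta_knots) + 1]] <- beta
    } else if (gamma == g_ent && lam > eps) {
      j <- inactive[which.min(gamma_entry[inactive])]
      pending_entry <- j
      lambda_knots <- c(lambda_knots, lam)
      beta_knots[[length(beta_knots) + 1]] <- beta
    } else {
      ## reached lambda = 0 (or max_steps): record terminal knot
      lambda_knots <- c(lambda_knots, max(lam, 0))
      beta_knots[[length(beta_knots) + 1]] <- beta
      break
    }
  }
  B <- do.call(cbind, beta_knots)
  rownames(B) <- vnames
  ## entry events: knot index where the variable's segment starts
  ent_at <- which(action > 0)
  entries <- data.frame(variable = action[ent_at], knot = ent_at,
                        lambda = lambda_knots[ent_at])
  action_full <- c(action, rep(0L, max(0, length(lambda_knots) -
                                         length(action))))
  structure(list(lambda = lambda_knots, beta = B,
                 action = action_full[seq_along(lambda_knots)],
                 entries = entries, names = vnames),
            class = "LassoPath")
}

rcond_psd <- function(M) {
  if (!length(M)) return(1)
  ev <- tryCatch(eigen(M, symmetric = TRUE, only.values = TRUE)$values,
                 error = function(e) c(0, 1))
  if (max(ev) <= 0) return(0)
  max(min(ev), 0) / max(ev)
}

#' @export
print.LassoPath <- function(x, ...) {
  cat(sprintf("Lasso path: %d knots, lambda %.4g ... %.4g\n",
              length(x$lambda), x$lambda[1], x$lambda[length(x$lambda)]))
  if (nrow(x$entries))
    cat("entry order:",
        paste(x$names[x$entries$variable], collapse = ", "), "\n")
  invisible(x)
}

#' Interpolate the lasso solution at a given lambda
#'
#' The path is piecewise linear in lambda, so the exact solution at any
#' lambda is a linear interpolation between the bracketing knots.
#'
#' @param path A `LassoPath`.
#' @param lambda Penalty value (>= 0).
#' @return Numeric coefficient vector.
#' @export
lasso_at_lambda <- function(path, lambda) {
  lam <- path$lambda
  if (lambda >= lam[1]) return(path$beta[, 1])
  k <- length(lam)
  if (lambda <= lam[k]) return(path$beta[, k])
  i <- max(which(lam >= lambda))
  if (lam[i] == lam[i + 1]) return(path$beta[, i + 1])
  w <- (lam[i] - lambda) / (lam[i] - lam[i + 1])
  (1 - w) * path$beta[, i] + w * path$beta[, i + 1]
}

#' Estimate the noise variance for the covariance test
#'
#' Full-model OLS residual variance when `n > p + 1` (the centered design
#' absorbs the intercept, hence `n - p - 1` degrees of freedom); otherwise
#' the residual variance at the saturated end of the path.
#'
#' @param design A `DesignMatrix`.
#' @param path Optional precomputed `LassoPath` (used by the fallback).
#' @return Positive scalar estimate of the noise variance.
#' @export
estimate_sigma2 <- function(design, path = NULL) {
  X <- design$X; y <- design$y
  n <- nrow(X); p <- ncol(X)
  if (n > p + 1) {
    fit <- stats::lm.fit(X, y)
    s2 <- sum(fit$residuals^2) / (n - p - 1)
  } else {
    if (is.null(path)) path <- lars_lasso_path(design)
    b <- path$beta[, ncol(path$beta)]
    df <- sum(b != 0) + 1
    if (n <= df) stop("cannot estimate noise variance: n <= df at path end")
    s2 <- sum((y - X %*% b)^2) / (n - df)
  }
  if (s2 <= 0) stop("degenerate response: estimated noise variance is 0")
  s2
}

#' Covariance test along the lasso path
#'
#' For the k-th entry event at knot `lambda_k` with next knot
#' `lambda_{k+1}`, the statistic is
#' `T_k = (<y, X b(lambda_{k+1})> - <y, X_A b_A(lambda_{k+1})>) / sigma2`,
#' where `b` is the path solution and `b_A` the lasso fitted on the
#' previously active set A alone, evaluated at the same `lambda_{k+1}`.
#' Under the null that A already contains all signal variables, `T_k` is
#' asymptotically Exp(1); `p = exp(-T_k)`.
#'
#' @param path A `LassoPath`.
#' @param design The `DesignMatrix` it was fitted on.
#' @param sigma2 Noise variance; estimated via [estimate_sigma2()] when
#'   omitted.
#' @return `data.frame` with one row per entry event: `rank`, `variable`,
#'   `name`, `lambda`, `T`, `p_value`.
#' @export
covariance_test <- function(path, design, sigma2 = NULL) {
  if (is.null(sigma2)) sigma2 <- estimate_sigma2(design, path)
  X <- design$X; y <- design$y
  ent <- path$entries
  out <- data.frame(rank = integer(), variable = integer(),
                    name = character(), lambda = numeric(),
                    T = numeric(), p_value = numeric())
  if (!nrow(ent)) return(out)
  for (k in seq_len(nrow(ent))) {
    knot <- ent$knot[k]
    lam_next <- path$lambda[min(knot + 1, length(path$lambda))]
    b_full <- lasso_at_lambda(path, lam_next)
    fit_full <- drop(y %*% (X %*% b_full))
    ## active set just before this entry: replay events up to the knot
    A <- integer(0)
    for (a in path$action[seq_len(knot - 1)]) {
      if (a > 0) A <- union(A, a) else if (a < 0) A <- setdiff(A, -a)
    }
    if (length(A)) {
      sub <- list(X = X[, A, drop = FALSE], y = y)
      sub_path <- lars_lasso_path(sub)
      b_A <- lasso_at_lambda(sub_path, lam_next)
      fit_A <- drop(y %*% (sub$X %*% b_A))
    } else fit_A <- 0
    Tk <- (fit_full - fit_A) / sigma2
    out <- rbind(out, data.frame(
      rank = k, variable = ent$variable[k],
      name = path$names[ent$variable[k]], lambda = ent$lambda[k],
      T = Tk, p_value = stats::pexp(Tk, lower.tail = FALSE)))
  }
  out
}

#' Ordered covariate-entry report
#'
#' @param path A `LassoPath`.
#' @param design Its `DesignMatrix`.
#' @param alpha Significance level for the entry count (default 0.05).
#' @param sigma2 Optional noise variance override.
#' @return List with `table` (rank, name, lambda, T, p_value) and
#'   `n_significant` at `alpha`.
#' @export
entry_report <- function(path, design, alpha = 0.05, sigma2 = NULL) {
  ct <- covariance_test(path, design, sigma2 = sigma2)
  list(table = ct[, c("rank", "name", "lambda", "T", "p_value")],
       n_significant = sum(ct$p_value <= alpha, na.rm = TRUE),
       alpha = alpha)
}
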