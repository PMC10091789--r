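#' Constant-coefficient additive-hazards regression (Lin-Ying estimator)
#'
#' Fits the semiparametric additive-hazards model
#' \deqn{\lambda(t \mid Z) = \lambda_0(t) + \beta' Z,}
#' with time-constant coefficients, by the closed-form least-squares
#' estimating equation over risk sets
#' \deqn{\hat\beta = A^{-1} b, \quad
#'   A = \sum_i \int Y_i(t)\,(Z_i - \bar Z(t))(Z_i - \bar Z(t))'\,dt, \quad
#'   b = \sum_i \int (Z_i - \bar Z(t))\,dN_i(t),}
#' where \eqn{\bar Z(t)} is the at-risk covariate mean. The variance is the
#' robust sandwich \eqn{A^{-1} B A^{-1}} with
#' \eqn{B = \sum_i \int (Z_i-\bar Z)(Z_i-\bar Z)' dN_i}. Coefficients are
#' per-year hazard differences. The implementation aggregates risk sets over
#' unique observed times (exact, no binning) and is O(n p^2 + m p^2) after
#' sorting.
#'
#' @param time Positive follow-up times (years).
#' @param status Event indicator (0/1).
#' @param X Numeric covariate matrix (no intercept; the baseline hazard is
#'   profiled out).
#' @return An object of class `lin_ying`: list with `coefficients`, `se`,
#'   `vcov`, `z`, `p`, `n`, `person_years`, `n_events`.
#' @export
lin_ying_fit <- function(time, status, X) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  p <- ncol(X)
  n <- nrow(X)
  nm <- colnames(X) %||% paste0("x", seq_len(p))
  stopifnot(length(time) == n, length(status) == n, p >= 1L)
  if (anyNA(time) || anyNA(status) || anyNA(X))
    stop("missing values in time, status or covariates")
  if (any(time <= 0)) stop("follow-up times must be strictly positive")
  status <- as.numeric(status)
  if (sum(status) < 1) stop("no events in subset")
  ## collinearity check against the implicit baseline column
  q1 <- qr(cbind(1, X))
  if (q1$rank < p + 1L) {
    bad <- setdiff(seq_len(p) + 1L, q1$pivot[seq_len(q1$rank)])
    stop("singular design; collinear column(s): ",
         paste(nm[bad - 1L], collapse = ", "))
  }

  ord <- order(time)
  time <- time[ord]; status <- status[ord]; X <- X[ord, , drop = FALSE]
  grp <- cumsum(c(1L, diff(time) > 0))        # unique-time index, ascending
  m <- grp[n]
  ut <- time[!duplicated(grp)]

  idx <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  i1 <- idx[, 1]; i2 <- idx[, 2]
  ZZ <- X[, i1, drop = FALSE] * X[, i2, drop = FALSE]

  cnt <- tabulate(grp, m)
  S1t <- rowsum(X, grp, reorder = FALSE)
  S2t <- rowsum(ZZ, grp, reorder = FALSE)
  ev <- status == 1
  gev <- grp[ev]
  d <- as.vector(rowsum(status, grp, reorder = FALSE))
  E1 <- matrix(0, m, p); E2 <- matrix(0, m, length(i1))
  if (any(ev)) {
    rows <- unique(gev)                        # sorted: grp nondecreasing
    E1[rows, ] <- rowsum(X[ev, , drop = FALSE], gev, reorder = FALSE)
    E2[rows, ] <- rowsum(ZZ[ev, , drop = FALSE], gev, reorder = FALSE)
  }
  rm(ZZ)

  revcumsum <- function(M) {
    M <- as.matrix(M)
    if (nrow(M) == 1L) return(M)
    out <- apply(M[nrow(M):1, , drop = FALSE], 2, cumsum)
    out[nrow(M):1, , drop = FALSE]
  }
  nk <- as.vector(revcumsum(cnt))
  S1 <- revcumsum(S1t)
  S2 <- revcumsum(S2t)
  Zbar <- S1 / nk
  dt <- diff(c(0, ut))

  vech_A <- colSums(dt * (S2 - S1[, i1, drop = FALSE] *
                            S1[, i2, drop = FALSE] / nk))
  b <- colSums(E1 - d * Zbar)
  vech_B <- colSums(E2 -
                      E1[, i1, drop = FALSE] * Zbar[, i2, drop = FALSE] -
                      Zbar[, i1, drop = FALSE] * E1[, i2, drop = FALSE] +
                      d * Zbar[, i1, drop = FALSE] * Zbar[, i2, drop = FALSE])

  unvech <- function(v) {
    M <- matrix(0, p, p)
    M[cbind(i1, i2)] <- v
    M[cbind(i2, i1)] <- v
    M
  }
  A <- unvech(vech_A)
  B <- unvech(vech_B)
  Ainv <- tryCatch(solve(A), error = function(e)
    stop("singular risk-set information matrix; check design columns: ",
         paste(nm, collapse = ", ")))
  beta <- drop(Ainv %*% b)
  V <- Ainv %*% B %*% Ainv
  se <- sqrt(pmax(diag(V), 0))
  names(beta) <- names(se) <- nm
  dimnames(V) <- list(nm, nm)
  structure(list(coefficients = beta, se = se, vcov = V,
                 z = beta / se, p = z_p(beta, se),
                 n = n, person_years = sum(time),
                 n_events = sum(status)),
            class = "lin_ying")
}

#' @export
print.lin_ying <- function(x, ...) {
  cat(sprintf(
    "Lin-Ying additive hazards fit: n=%d, events=%d, person-years=%.0f\n",
    x$n, x$n_events, x$person_years))
  print(data.frame(coef_per_year = signif(x$coefficients, 4),
                   se = signif(x$se, 4), z = round(x$z, 2),
                   p = signif(x$p, 3)))
  invisible(x)
}

#' Fit additive hazards on an analysis-table subset
#'
#' Thin wrapper around [lin_ying_fit()] that selects the follow-up columns
#' for one outcome, restricts to a treatment subset, excludes prior-disease
#' patients for that outcome and rows with missing predictors, and fits the
#' listed predictor columns.
#'
#' @param rows Analysis table.
#' @param outcome Outcome label (uses `<outcome>_time` / `<outcome>_event`).
#' @param predictors Character vector of predictor column names.
#' @param subset `"treated"`, `"untreated"` or `"all"`.
#' @return A `lin_ying` fit with `subset` and `outcome` recorded.
#' @export
fit_additive_hazards <- function(rows, outcome, predictors,
                                 subset = c("all", "treated", "untreated")) {
  subset <- match.arg(subset)
  tc <- paste0(outcome, "_time"); ec <- paste0(outcome, "_event")
  pc <- paste0(outcome, "_prior")
  need <- c(tc, ec, predictors)
  miss <- setdiff(need, names(rows))
  if (length(miss)) stop_config("missing column(s): ",
                                paste(miss, collapse = ", "))
  keep <- switch(subset, all = rep(TRUE, nrow(rows)),
                 treated = rows$treated == 1L,
                 untreated = rows$treated == 0L)
  if (pc %in% names(rows)) keep <- keep & rows[[pc]] != 1L
  keep <- keep & stats::complete.cases(rows[, need, drop = FALSE])
  sub <- rows[keep, , drop = FALSE]
  if (!nrow(sub)) stop("empty subset '", subset, "' for outcome ", outcome)
  fit <- lin_ying_fit(sub[[tc]], sub[[ec]],
                      as.matrix(sub[, predictors, drop = FALSE]))
  fit$subset <- subset
  fit$outcome <- outcome
  fit
}
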