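## Two-step system GMM for the dynamic node-level model.
##
## The model is
##   y_it = sum_l theta_l y_{i,t-l} + b1 year + b2 IPxyear
##          + b3 Npatients + b4 Charlson + FE_i + eps_it.
## First-differencing removes the fixed effect but correlates the lagged
## outcome with the differenced error, so the differenced equations are
## instrumented by deeper lagged *levels* of y; following Blundell and Bond
## the system adds the level equations instrumented by the lagged first
## *difference* of y, which restores identification when y is persistent.
## Estimation is one-step with the standard initial weighting (tridiagonal
## block for the differenced equations, identity for the level equations),
## then two-step with the weighting rebuilt from first-step residuals, with
## the Windmeijer finite-sample correction of the two-step standard errors.

#' GMM estimation specification
#'
#' @param instrument_lag_min,instrument_lag_max Range of lag depths of the
#'   outcome *levels* used as instruments for the differenced equations
#'   (`lag_min` must be >= 2: levels dated t-2 and deeper are uncorrelated
#'   with the differenced error when the idiosyncratic error is serially
#'   uncorrelated).
#' @param two_step Re-weight with first-step residuals (default `TRUE`).
#' @param windmeijer_correction Apply the finite-sample correction to the
#'   two-step standard errors (default `TRUE`; uncorrected two-step SEs are
#'   known to be severely downward biased).
#' @param collapse_instruments Collapse the per-period instrument columns to
#'   one column per lag depth, curbing instrument proliferation in short
#'   wide panels.
#' @param n_y_lags Number of outcome lags in the model equation.
#' @return List of class `coop_gmm_spec`.
#' @export
gmm_spec <- function(instrument_lag_min = 2L, instrument_lag_max = 5L,
                     two_step = TRUE, windmeijer_correction = TRUE,
                     collapse_instruments = FALSE, n_y_lags = 1L) {
  if (instrument_lag_min < 2L) {
    stop("`instrument_lag_min` must be >= 2 (shallower levels are correlated ",
         "with the differenced error)", call. = FALSE)
  }
  if (instrument_lag_max < instrument_lag_min) {
    stop("`instrument_lag_max` must be >= `instrument_lag_min`", call. = FALSE)
  }
  if (n_y_lags < 1L) stop("`n_y_lags` must be >= 1", call. = FALSE)
  structure(list(instrument_lag_min = as.integer(instrument_lag_min),
                 instrument_lag_max = as.integer(instrument_lag_max),
                 two_step = isTRUE(two_step),
                 windmeijer_correction = isTRUE(windmeijer_correction),
                 collapse_instruments = isTRUE(collapse_instruments),
                 n_y_lags = as.integer(n_y_lags)),
            class = "coop_gmm_spec")
}

#' Default estimation specifications per outcome
#'
#' Instrument lag ranges default to 4:11 for degree (with two outcome lags),
#' 6:11 for the eigenvector ranking and 3:14 for the betweenness ranking.
#'
#' @return Named list of [gmm_spec()]s for `degree`, `ev_rank`, `be_rank`.
#' @export
default_gmm_specs <- function() {
  list(degree = gmm_spec(4L, 11L, n_y_lags = 2L),
       ev_rank = gmm_spec(6L, 11L, n_y_lags = 1L),
       be_rank = gmm_spec(3L, 14L, n_y_lags = 1L))
}

## Symmetric pseudo-inverse via eigendecomposition; returns rank info.
pinv_sym <- function(M, tol = 1e-11) {
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  keep <- e$values > tol * max(abs(e$values), .Machine$double.eps)
  inv_vals <- ifelse(keep, 1 / e$values, 0)
  list(inv = e$vectors %*% (inv_vals * t(e$vectors)),
       rank = sum(keep), n = ncol(M))
}

GMM_COVARIATES <- c("year_index", "ip_year", "n_patients", "mean_charlson")

## Normalize the panel into the internal estimation layout.
prepare_gmm_panel <- function(panel, spec) {
  dt <- as.data.table(panel)
  if (!"year_index" %in% names(dt)) {
    if (!"year" %in% names(dt)) stop("panel needs `year` or `year_index`",
                                     call. = FALSE)
    dt[, year_index := year - min(year) + 1L]
  }
  if (!"ip_year" %in% names(dt)) {
    if (!"ip" %in% names(dt)) stop("panel needs `ip_year` or `ip`", call. = FALSE)
    dt[, ip_year := as.numeric(ip) * year_index]
  }
  lagcols <- paste0("y_lag", seq_len(spec$n_y_lags))
  if (!all(lagcols %in% names(dt))) {
    if (!"year" %in% names(dt)) dt[, year := year_index]
    dt <- add_lags(dt[, setdiff(names(dt),
                                grep("^y_lag", names(dt), value = TRUE)),
                      with = FALSE], spec$n_y_lags)
  }
  miss <- setdiff(c("practice_id", "y", GMM_COVARIATES, lagcols), names(dt))
  if (length(miss)) {
    stop("panel is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  xcols <- c(lagcols, GMM_COVARIATES)
  keep <- unique(c("practice_id", "year_index", "y", xcols))
  dt <- dt[, keep, with = FALSE]
  if (anyDuplicated(dt[, .(practice_id, year_index)])) {
    stop("panel has duplicated (practice, year) rows", call. = FALSE)
  }
  setorder(dt, practice_id, year_index)
  dt[, complete := complete.cases(.SD), .SDcols = c("y", xcols)]
  list(dt = dt, xcols = xcols, lagcols = lagcols)
}

#' Build the system-GMM instrument matrix
#'
#' Constructs the stacked instrument matrix for the differenced and level
#' equations: outcome levels `y[t - lag_max .. t - lag_min]` instrument each
#' differenced equation (one column per period and lag depth, zeros where
#' unavailable, or one column per depth when collapsed); the lagged first
#' difference of the outcome instruments each level equation; the exogenous
#' covariates instrument themselves (differenced in the differenced block,
#' levels in the level block).
#'
#' @param panel Panel data (see [assemble_panel()] or
#'   [generate_panel_from_model()]).
#' @param spec A [gmm_spec()].
#' @return List with the sparse instrument matrix `Z` (rows: differenced
#'   equations then level equations), design `X` and response `y` aligned
#'   with `Z`'s rows, the row bookkeeping (`rows`), the initial weighting
#'   inner matrix `H`, column labels, and counts.
#' @export
build_instruments <- function(panel, spec = gmm_spec()) {
  stopifnot(inherits(spec, "coop_gmm_spec"))
  prep <- prepare_gmm_panel(panel, spec)
  dt <- prep$dt
  xcols <- prep$xcols
  n_param <- length(xcols)

  setkey(dt, practice_id, year_index)
  prev <- dt[.(dt$practice_id, dt$year_index - 1L), which = TRUE]
  diff_ok <- dt$complete & !is.na(prev) & dt$complete[pmax(prev, 1L)]
  diff_ok[is.na(prev)] <- FALSE
  d_idx <- which(diff_ok)         # rows of dt acting as differenced equations
  l_idx <- which(dt$complete)     # rows acting as level equations
  if (length(d_idx) == 0L) {
    stop("no usable differenced equations: every practice-year lacks the ",
         "required lags; panel too short or too gappy", call. = FALSE)
  }
  Xmat <- as.matrix(dt[, xcols, with = FALSE])
  X_d <- Xmat[d_idx, , drop = FALSE] - Xmat[prev[d_idx], , drop = FALSE]
  y_d <- dt$y[d_idx] - dt$y[prev[d_idx]]
  X_l <- Xmat[l_idx, , drop = FALSE]
  y_l <- dt$y[l_idx]

  n_d <- length(d_idx)
  n_l <- length(l_idx)
  rows <- list(
    diff = data.table(row = seq_len(n_d), id = dt$practice_id[d_idx],
                      t = dt$year_index[d_idx]),
    level = data.table(row = n_d + seq_len(n_l), id = dt$practice_id[l_idx],
                       t = dt$year_index[l_idx])
  )

  ## y-level lookup (any observed y can serve as an instrument)
  ylev <- dt[!is.na(y), .(practice_id, year_index, y)]
  setkey(ylev, practice_id, year_index)
  get_y <- function(ids, ts) ylev[.(ids, ts), y]

  t_min <- min(dt$year_index)
  trip_i <- integer(0); trip_j <- integer(0); trip_x <- numeric(0)
  labels <- character(0)
  ncol_z <- 0L
  push <- function(rows_i, vals, label) {
    ok <- !is.na(vals) & vals != 0
    ncol_z <<- ncol_z + 1L
    labels[ncol_z] <<- label
    trip_i <<- c(trip_i, rows_i[ok])
    trip_j <<- c(trip_j, rep.int(ncol_z, sum(ok)))
    trip_x <<- c(trip_x, vals[ok])
  }

  ## GMM-style instruments for the differenced equations
  lag_rng <- seq.int(spec$instrument_lag_min, spec$instrument_lag_max)
  if (spec$collapse_instruments) {
    for (l in lag_rng) {
      vals <- get_y(rows$diff$id, rows$diff$t - l)
      push(rows$diff$row, vals, sprintf("d.y.lag%d", l))
    }
  } else {
    for (tt in sort(unique(rows$diff$t))) {
      sub <- rows$diff[t == tt]
      for (l in lag_rng) {
        if (tt - l < t_min) next
        vals <- get_y(sub$id, rep.int(tt - l, nrow(sub)))
        if (all(is.na(vals) | vals == 0)) next
        push(sub$row, vals, sprintf("d.y.t%d.lag%d", tt, l))
      }
    }
  }
  n_gmm_diff <- ncol_z

  ## lagged first differences instrument the level equations
  dy <- get_y(rows$level$id, rows$level$t - 1L) -
    get_y(rows$level$id, rows$level$t - 2L)
  if (spec$collapse_instruments) {
    push(rows$level$row, dy, "l.dy.lag1")
  } else {
    for (tt in sort(unique(rows$level$t))) {
      sel <- rows$level$t == tt
      if (all(is.na(dy[sel]) | dy[sel] == 0)) next
      push(rows$level$row[sel], dy[sel], sprintf("l.dy.t%d", tt))
    }
  }
  n_gmm_lev <- ncol_z - n_gmm_diff

  ## exogenous covariates instrument themselves, block by block
  for (v in GMM_COVARIATES) {
    push(rows$diff$row, X_d[, v], sprintf("d.x.%s", v))
  }
  for (v in GMM_COVARIATES) {
    push(rows$level$row, X_l[, v], sprintf("l.x.%s", v))
  }

  Z <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                            dims = c(n_d + n_l, ncol_z))
  colnames(Z) <- labels

  ## initial weighting inner matrix: tridiagonal on the differenced block
  ## (var 2, adjacent-period cov -1 under iid errors), identity on levels
  hi <- c(seq_len(n_d), n_d + seq_len(n_l))
  hj <- hi
  hx <- c(rep(2, n_d), rep(1, n_l))
  dd <- rows$diff
  for (iid in unique(dd$id)) {
    sub <- dd[id == iid][order(t)]
    if (nrow(sub) > 1L) {
      adj <- which(diff(sub$t) == 1L)
      if (length(adj)) {
        hi <- c(hi, sub$row[adj], sub$row[adj + 1L])
        hj <- c(hj, sub$row[adj + 1L], sub$row[adj])
        hx <- c(hx, rep(-1, 2L * length(adj)))
      }
    }
  }
  H <- Matrix::sparseMatrix(i = hi, j = hj, x = hx,
                            dims = c(n_d + n_l, n_d + n_l))

  list(Z = Z, X = rbind(X_d, X_l), y = c(y_d, y_l), H = H, rows = rows,
       xcols = xcols, n_diff = n_d, n_level = n_l,
       n_instruments = ncol_z, n_gmm_diff = n_gmm_diff,
       n_gmm_level = n_gmm_lev, n_exog = 2L * length(GMM_COVARIATES),
       spec = spec)
}

#' Fit the dynamic panel model by two-step system GMM
#'
#' Estimates the dynamic fixed-effects model of a cooperation indicator by
#' the Blundell-Bond system estimator and computes the full diagnostic
#' battery: Windmeijer-corrected two-step standard errors, the Sargan
#' overidentification test, Arellano-Bond AR(1)/AR(2) tests on the
#' differenced residuals, the joint Wald test, and a pseudo R-squared (the
#' squared correlation between observed and model-predicted outcome levels).
#' Estimation is deterministic for a fixed panel.
#'
#' @param panel Practice-year panel ([assemble_panel()] or
#'   [generate_panel_from_model()]).
#' @param spec A [gmm_spec()].
#' @return Object of class `coop_gmm`: coefficients, `se`, `vcov`, residual
#'   vectors, instrument counts, and `sargan`, `ar1`, `ar2`, `wald`,
#'   `pseudo_r2` entries.
#' @export
fit_system_gmm <- function(panel, spec = gmm_spec()) {
  iv <- build_instruments(panel, spec)
  Z <- iv$Z; X <- iv$X; yv <- iv$y; H <- iv$H
  k <- ncol(X); p <- iv$n_instruments
  if (p < k) stop("under-identified: ", p, " instruments for ", k,
                  " parameters", call. = FALSE)
  n_rows <- nrow(X)
  ids_all <- c(iv$rows$diff$id, iv$rows$level$id)
  id_levels <- sort(unique(ids_all))
  ind <- match(ids_all, id_levels)
  N <- length(id_levels)
  if (iv$n_level < k) stop("too few usable observations", call. = FALSE)

  XZ <- as.matrix(Matrix::crossprod(X, Z))            # k x p (X'Z)
  Zy <- as.numeric(Matrix::crossprod(Z, yv))          # p
  ZHZ <- as.matrix(Matrix::crossprod(Z, H %*% Z))     # p x p

  w1 <- pinv_sym(ZHZ)
  if (w1$rank < w1$n) {
    message("fit_system_gmm: initial weighting matrix is rank deficient (",
            w1$rank, "/", w1$n, "); using a pseudo-inverse - consider ",
            "collapsing instruments or narrowing the lag range")
  }
  W1 <- w1$inv
  solve_theta <- function(W) {
    K <- XZ %*% W %*% t(XZ)
    kk <- pinv_sym(K)
    if (kk$rank < k) {
      stop("singular moment cross-product: regressors collinear after ",
           "instrumenting; reduce the model or widen the instrument set",
           call. = FALSE)
    }
    as.numeric(kk$inv %*% (XZ %*% (W %*% Zy)))
  }
  theta1 <- solve_theta(W1)
  u1 <- yv - as.numeric(X %*% theta1)

  ## per-individual moment contributions: columns of t(Z) %*% Ui
  ind_mat <- function(vals) {
    Matrix::sparseMatrix(i = seq_len(n_rows), j = ind, x = vals,
                         dims = c(n_rows, N))
  }
  Mu1 <- as.matrix(Matrix::crossprod(Z, ind_mat(u1)))  # p x N
  S1 <- Mu1 %*% t(Mu1)

  degenerate <- sum(u1^2) / n_rows < 1e-20
  if (!spec$two_step || degenerate) {
    theta <- theta1
    u <- u1
    M1 <- pinv_sym(XZ %*% W1 %*% t(XZ))$inv
    V <- if (degenerate) matrix(0, k, k)
         else M1 %*% XZ %*% W1 %*% S1 %*% W1 %*% t(XZ) %*% M1  # robust 1-step
    W_used <- W1
    two_step_done <- FALSE
  } else {
    w2 <- pinv_sym(S1)
    if (w2$rank < w2$n) {
      message("fit_system_gmm: two-step weighting matrix is rank deficient (",
              w2$rank, "/", w2$n, "); using a pseudo-inverse - consider ",
              "collapsing instruments (instrument count ", p,
              " vs ", N, " individuals)")
    }
    W2 <- w2$inv
    theta <- solve_theta(W2)
    u <- yv - as.numeric(X %*% theta)
    M2 <- pinv_sym(XZ %*% W2 %*% t(XZ))$inv
    V2 <- M2
    if (spec$windmeijer_correction) {
      Mu2 <- as.matrix(Matrix::crossprod(Z, ind_mat(u)))
      Zu2 <- rowSums(Mu2)
      M1 <- pinv_sym(XZ %*% W1 %*% t(XZ))$inv
      V1 <- M1 %*% XZ %*% W1 %*% S1 %*% W1 %*% t(XZ) %*% M1
      D <- matrix(0, k, k)
      G2 <- M2 %*% XZ %*% W2                           # k x p
      for (j in seq_len(k)) {
        Mxj <- as.matrix(Matrix::crossprod(Z, ind_mat(X[, j])))
        dS <- Mxj %*% t(Mu1) + Mu1 %*% t(Mxj)          # -dS/dtheta_j
        D[, j] <- as.numeric(G2 %*% (dS %*% (W2 %*% Zu2)))
      }
      V <- V2 + D %*% V2 + V2 %*% t(D) + D %*% V1 %*% t(D)
    } else {
      V <- V2
    }
    W_used <- W2
    two_step_done <- TRUE
  }
  V <- (V + t(V)) / 2
  names(theta) <- iv$xcols
  se <- sqrt(pmax(diag(V), 0))
  names(se) <- iv$xcols
  if (abs(theta[1L]) >= 1) {
    warning("estimated lag-1 coefficient has modulus >= 1: ",
            "nonstationary dynamics", call. = FALSE)
  }

  res <- structure(list(
    coefficients = theta, se = se, vcov = V,
    theta_onestep = stats::setNames(theta1, iv$xcols),
    residuals = u, residuals_diff = u[seq_len(iv$n_diff)],
    residuals_level = u[iv$n_diff + seq_len(iv$n_level)],
    fitted_level = as.numeric(iv$X[iv$n_diff + seq_len(iv$n_level), ,
                                   drop = FALSE] %*% theta),
    y_level = yv[iv$n_diff + seq_len(iv$n_level)],
    n_obs = iv$n_level, n_obs_diff = iv$n_diff,
    n_nodes = N, n_instruments = p,
    n_parameters = k,
    instrument_description = sprintf(
      "Lags %d:%d%s; %d diff-GMM + %d level-GMM + %d IV columns",
      spec$instrument_lag_min, spec$instrument_lag_max,
      if (spec$collapse_instruments) " (collapsed)" else "",
      iv$n_gmm_diff, iv$n_gmm_level, iv$n_exog),
    W = W_used, XZ = XZ, Zy = Zy, S1 = S1,
    rows = iv$rows, ind = ind, id_levels = id_levels, Z = Z, X = X,
    two_step = two_step_done,
    windmeijer = spec$windmeijer_correction && two_step_done,
    spec = spec, degenerate = degenerate
  ), class = "coop_gmm")

  res$sargan <- tryCatch(sargan_test(res), error = function(e) NULL)
  res$ar1 <- tryCatch(ar_test(res, 1L), error = function(e) NULL)
  res$ar2 <- tryCatch(ar_test(res, 2L), error = function(e) NULL)
  res$wald <- tryCatch(wald_test(res), error = function(e) NULL)
  res$pseudo_r2 <- tryCatch(pseudo_r2(res), error = function(e) NA_real_)
  res
}

#' Sargan-Hansen overidentification test
#'
#' J statistic of the GMM objective at the estimate, chi-square with
#' degrees of freedom equal to the instrument count minus the parameter
#' count. Rejection signals that the instruments are not jointly exogenous.
#'
#' @param result A `coop_gmm` fit.
#' @return List `(statistic, df, p)`.
#' @export
sargan_test <- function(result) {
  stopifnot(inherits(result, "coop_gmm"))
  df <- result$n_instruments - result$n_parameters
  if (df < 1L) {
    stop("Sargan test undefined: model is just-identified (",
         result$n_instruments, " instruments, ", result$n_parameters,
         " parameters)", call. = FALSE)
  }
  g <- as.numeric(Matrix::crossprod(result$Z, result$residuals))
  stat <- as.numeric(t(g) %*% result$W %*% g)
  list(statistic = stat, df = df, p = pchisq(stat, df, lower.tail = FALSE))
}

#' Arellano-Bond autocorrelation test
#'
#' Tests serial correlation of order `order` in the *differenced* residuals
#' against a standard normal reference. Under a serially uncorrelated level
#' error, AR(1) in differences is expected to be significantly negative and
#' AR(2) to be absent; AR(2) rejection invalidates the t-2 level
#' instruments. The variance accounts for parameter estimation following the
#' original construction.
#'
#' @param result A `coop_gmm` fit.
#' @param order 1 or 2.
#' @return List `(z, p)` with the two-sided p-value.
#' @export
ar_test <- function(result, order = 1L) {
  stopifnot(inherits(result, "coop_gmm"), order %in% c(1L, 2L))
  dd <- result$rows$diff
  e <- result$residuals_diff
  if (result$degenerate || all(abs(e) < 1e-10)) {
    stop("AR(", order, ") statistic undefined: residuals are identically zero",
         call. = FALSE)
  }
  ## q = residual lagged `order` periods within individual, aligned to rows
  key <- paste(dd$id, dd$t)
  lag_key <- paste(dd$id, dd$t - order)
  q <- e[match(lag_key, key)]
  q[is.na(q)] <- 0
  w <- sum(q * e)
  ## per-individual overlap q_i'e_i, aligned with the moment individual index
  idx_d <- match(dd$id, result$id_levels)
  s_full <- numeric(result$n_nodes)
  agg <- rowsum(q * e, group = idx_d)
  s_full[as.integer(rownames(agg))] <- agg[, 1L]
  d0 <- sum(s_full^2)
  ## estimation-effect corrections
  Xd <- result$X[seq_len(result$n_obs_diff), , drop = FALSE]
  b <- as.numeric(t(Xd) %*% q)                        # k
  ## c = sum_i (Z_i' u_i) (q_i' e_i)
  Mu <- as.matrix(Matrix::crossprod(
    result$Z, Matrix::sparseMatrix(i = seq_along(result$residuals),
                                   j = result$ind, x = result$residuals,
                                   dims = c(length(result$residuals),
                                            result$n_nodes))))
  cvec <- as.numeric(Mu %*% s_full)
  Kinv <- pinv_sym(result$XZ %*% result$W %*% t(result$XZ))$inv
  G <- Kinv %*% result$XZ %*% result$W                # k x p
  v <- d0 - 2 * as.numeric(t(b) %*% G %*% cvec) +
    as.numeric(t(b) %*% result$vcov %*% b)
  if (!is.finite(v) || v <= 0) v <- d0                # fall back, conservative
  if (v == 0) {
    stop("AR(", order, ") statistic undefined: zero variance", call. = FALSE)
  }
  z <- w / sqrt(v)
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' Joint Wald test of the slope coefficients
#'
#' Chi-square test that all model coefficients are jointly zero, with
#' degrees of freedom equal to the number of coefficients.
#'
#' @param result A `coop_gmm` fit.
#' @return List `(statistic, df, p)`.
#' @export
wald_test <- function(result) {
  stopifnot(inherits(result, "coop_gmm"))
  th <- result$coefficients
  vc <- pinv_sym(result$vcov)
  if (vc$rank < length(th)) {
    stop("Wald test undefined: singular coefficient covariance", call. = FALSE)
  }
  stat <- as.numeric(t(th) %*% vc$inv %*% th)
  list(statistic = stat, df = length(th),
       p = pchisq(stat, length(th), lower.tail = FALSE))
}

#' Pseudo R-squared of a system-GMM fit
#'
#' Squared Pearson correlation between the observed outcome levels and the
#' model-predicted levels (fixed effects excluded), the goodness-of-fit
#' measure analogous to OLS R-squared.
#'
#' @param result A `coop_gmm` fit.
#' @param panel Unused; accepted for call-site symmetry.
#' @return Proportion in `[0, 1]`.
#' @export
pseudo_r2 <- function(result, panel = NULL) {
  stopifnot(inherits(result, "coop_gmm"))
  obs <- result$y_level
  fit <- result$fitted_level
  if (result$degenerate && isTRUE(all.equal(obs, fit))) return(1)
  if (sd(obs) == 0 || sd(fit) == 0) {
    stop("pseudo R-squared undefined: zero variance in observed or fitted ",
         "values", call. = FALSE)
  }
  cor(obs, fit)^2
}

sig_marks <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
    ifelse(p < 0.05, "*", ifelse(p < 0.1, ".", ""))))
}

#' @export
print.coop_gmm <- function(x, digits = 3, ...) {
  cat("System GMM (", if (x$two_step) "two-step" else "one-step",
      if (x$windmeijer) ", Windmeijer-corrected SEs" else "", ")\n", sep = "")
  zval <- x$coefficients / ifelse(x$se > 0, x$se, NA)
  pval <- 2 * pnorm(-abs(zval))
  tab <- data.frame(
    coefficient = signif(x$coefficients, digits),
    se = signif(x$se, digits),
    z = round(zval, 2),
    p = signif(pval, 2),
    ` ` = sig_marks(pval), check.names = FALSE)
  print(tab)
  cat(sprintf("#Obs %d   nodes %d   instruments %d (%s)\n",
              x$n_obs, x$n_nodes, x$n_instruments, x$instrument_description))
  if (!is.null(x$sargan)) {
    cat(sprintf("Sargan test: chisq(%d) %.2f (p-value: %.2g)\n",
                x$sargan$df, x$sargan$statistic, x$sargan$p))
  }
  if (!is.null(x$ar1)) {
    cat(sprintf("Autocorrelation test (1): normal %.2f (p-value: %.2g)\n",
                x$ar1$z, x$ar1$p))
  }
  if (!is.null(x$ar2)) {
    cat(sprintf("Autocorrelation test (2): normal %.2f (p-value: %.2g)\n",
                x$ar2$z, x$ar2$p))
  }
  if (!is.null(x$wald)) {
    cat(sprintf("Wald test for coefficients: chisq(%d) %.2f (p-value: %.2g)\n",
                x$wald$df, x$wald$statistic, x$wald$p))
  }
  if (is.finite(x$pseudo_r2)) cat(sprintf("R2 corr(y, yhat)^2: %.2f\n", x$pseudo_r2))
  invisible(x)
}

#' Serialize a GMM result to JSON
#'
#' Machine-readable companion of the printed report: coefficients, standard
#' errors, diagnostics, counts and the instrument description.
#'
#' @param result A `coop_gmm` fit.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_gmm_json <- function(result, file) {
  zval <- result$coefficients / ifelse(result$se > 0, result$se, NA)
  out <- list(
    coefficients = as.list(result$coefficients),
    se = as.list(result$se),
    p = as.list(2 * pnorm(-abs(zval))),
    n_obs = result$n_obs, n_nodes = result$n_nodes,
    n_instruments = result$n_instruments,
    residual_vector_length = length(result$residuals),
    sargan = result$sargan, ar1 = result$ar1, ar2 = result$ar2,
    wald = result$wald, pseudo_r2 = result$pseudo_r2,
    instruments = result$instrument_description,
    two_step = result$two_step, windmeijer = result$windmeijer
  )
  jsonlite::write_json(out, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file)
}
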