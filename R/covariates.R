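## Covariate preparation: penalised-least-squares smoothing of yearly series
## and assembly of the standardised design matrix. Covariate order is fixed:
## log(nmr), log(lbw), anc4, csec, edu, log(gni).

design_columns <- function() c("log_nmr", "log_lbw", "anc4", "csec", "edu", "log_gni")

second_diff_matrix <- function(n) {
  if (n < 3) return(matrix(0, 0, n))
  D <- matrix(0, n - 2, n)
  for (i in seq_len(n - 2)) D[i, i:(i + 2)] <- c(1, -2, 1)
  D
}

#' Smooth a yearly covariate series
#'
#' Penalised least squares with a second-difference roughness penalty,
#' evaluated on the full year grid: minimises
#' `sum_obs (f_t - y_t)^2 + lambda * sum (Delta^2 f)^2`. Constant and linear
#' series are reproduced exactly (they span the penalty null space); gaps
#' are interpolated and edges extrapolated linearly. The penalty weight is
#' chosen by leave-one-out cross-validation over a log-spaced grid unless
#' supplied.
#'
#' @param y observed values (NAs allowed at unobserved years).
#' @param years years of `y` (default consecutive).
#' @param grid full year grid on which to evaluate (default `years`).
#' @param lambda fixed penalty weight; `NULL` selects by LOOCV.
#' @return numeric vector on `grid`, with attribute `"lambda"`.
#' @export
smooth_covariate_series <- function(y, years = seq_along(y) - 1L + 2000L,
                                    grid = years, lambda = NULL) {
  keep <- is.finite(y)
  if (sum(keep) < 2) stop("at least 2 observed years are required", call. = FALSE)
  yobs <- y[keep]; yrs <- years[keep]
  if (!all(yrs %in% grid)) stop("observed years must lie on the grid", call. = FALSE)
  n <- length(grid)
  obs_idx <- match(yrs, grid)
  w <- numeric(n); w[obs_idx] <- 1
  y0 <- numeric(n); y0[obs_idx] <- yobs
  D <- second_diff_matrix(n)
  P <- crossprod(D)

  fit_for <- function(lam) {
    M <- diag(w, n) + lam * P
    ## With <3 grid points P is empty; ridge-free interpolation handles it.
    f <- tryCatch(solve(M, w * y0), error = function(e) NULL)
    if (is.null(f)) return(NULL)
    H <- solve(M)[, obs_idx, drop = FALSE]   # columns map obs to fitted values
    list(f = f, hdiag = H[cbind(obs_idx, seq_along(obs_idx))])
  }

  if (is.null(lambda)) {
    lgrid <- 10^seq(-3, 7, length.out = 41)
    best <- NULL; best_cv <- Inf; best_lam <- NA_real_
    for (lam in lgrid) {
      ft <- fit_for(lam)
      if (is.null(ft)) next
      h <- pmin(ft$hdiag, 1 - 1e-10)
      cv <- sum(((yobs - ft$f[obs_idx]) / (1 - h))^2)
      ## <= prefers the larger (smoother) lambda on ties, e.g. linear series
      if (cv <= best_cv + 1e-12) { best_cv <- cv; best <- ft; best_lam <- lam }
    }
    if (is.null(best)) stop("smoother failed for all penalty weights", call. = FALSE)
    f <- best$f; lambda <- best_lam
  } else {
    ft <- fit_for(lambda)
    if (is.null(ft)) stop("singular smoothing system", call. = FALSE)
    f <- ft$f
  }
  attr(f, "lambda") <- lambda
  f
}

#' Smooth selected columns of a covariate table
#'
#' Applies [smooth_covariate_series()] per country to the named columns.
#' By default only the household-survey-derived coverage indicators (`anc4`,
#' `csec`) are smoothed.
#'
#' @param cov `sbr_covariates`.
#' @param vars columns to smooth.
#' @param lambda optional fixed penalty weight (otherwise LOOCV per series).
#' @return covariate table with smoothed columns (fractions clamped to
#'   \[0, 1\]).
#' @export
smooth_covariate_table <- function(cov, vars = c("anc4", "csec"), lambda = NULL) {
  for (ct in unique(cov$country_code)) {
    sel <- cov$country_code == ct
    yrs <- cov$year[sel]
    for (v in vars) {
      sm <- smooth_covariate_series(cov[[v]][sel], years = yrs, grid = yrs,
                                    lambda = lambda)
      if (v %in% c("anc4", "csec")) sm <- pmin(pmax(sm, 0), 1)
      cov[[v]][sel] <- as.numeric(sm)
    }
  }
  cov
}

#' Build the standardised design matrix
#'
#' Applies the fixed transforms (logs of nmr, lbw, gni) and standardises
#' each column to mean 0, unit variance over the pooled country-year sample.
#' The centring/scaling constants are retained so the matrix is exactly
#' reproducible from the raw table via [apply_design_scaler()].
#'
#' @param cov complete (smoothed) covariate table.
#' @param countries,years estimation grid; defaults to the table's grid.
#' @return object of class `sbr_design`: list with `X` (matrix, rows in
#'   country-major, year-minor order), `index` (country/year per row),
#'   `center`, `scale`, `countries`, `years`.
#' @export
build_design_matrix <- function(cov, countries = sort(unique(cov$country_code)),
                                years = sort(unique(cov$year))) {
  key <- paste(cov$country_code, cov$year)
  want <- as.vector(t(outer(countries, years, paste)))
  m <- match(want, key)
  if (anyNA(m)) {
    stop("missing covariate cell(s): ", paste(utils::head(want[is.na(m)], 5),
                                              collapse = ", "), call. = FALSE)
  }
  cv <- cov[m, ]
  raw <- cbind(log_nmr = log(cv$nmr), log_lbw = log(cv$lbw), anc4 = cv$anc4,
               csec = cv$csec, edu = cv$edu, log_gni = log(cv$gni))
  ctr <- colMeans(raw)
  scl <- apply(raw, 2, stats::sd)
  zero <- which(scl < 1e-12)
  if (length(zero))
    stop("degenerate design: zero variance in column(s) ",
         paste(design_columns()[zero], collapse = ", "), call. = FALSE)
  X <- sweep(sweep(raw, 2, ctr), 2, scl, "/")
  index <- data.frame(country_code = rep(countries, each = length(years)),
                      year = rep(years, times = length(countries)))
  rownames(X) <- paste(index$country_code, index$year, sep = "_")
  structure(list(X = X, index = index, center = ctr, scale = scl,
                 countries = countries, years = years),
            class = "sbr_design")
}

#' Re-apply a stored design scaler to a raw covariate table
#' @param cov raw covariate table on the same grid.
#' @param design an `sbr_design` holding the transform constants.
#' @return the standardised matrix (identical to `design$X` for the table it
#'   was built from).
#' @export
apply_design_scaler <- function(cov, design) {
  key <- paste(cov$country_code, cov$year)
  want <- paste(design$index$country_code, design$index$year)
  m <- match(want, key)
  if (anyNA(m)) stop("covariate table does not cover the design grid", call. = FALSE)
  cv <- cov[m, ]
  raw <- cbind(log_nmr = log(cv$nmr), log_lbw = log(cv$lbw), anc4 = cv$anc4,
               csec = cv$csec, edu = cv$edu, log_gni = log(cv$gni))
  X <- sweep(sweep(raw, 2, design$center), 2, design$scale, "/")
  rownames(X) <- rownames(design$X)
  X
}

#' Invert the standardisation of a design matrix
#' @param X standardised matrix.
#' @param design `sbr_design` with the stored constants.
#' @return matrix on the transformed (pre-standardisation) scale.
#' @export
invert_design_scaler <- function(X, design) {
  sweep(sweep(X, 2, design$scale, "*"), 2, design$center, "+")
}

#' Write smoothed covariates and their scaler
#' @param design `sbr_design`.
#' @param cov the (smoothed) covariate table the design was built from.
#' @param dir output directory; writes `covariates_smoothed.csv` and
#'   `design_scaler.json`.
#' @export
write_design <- function(design, cov, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_covariate_table(cov, file.path(dir, "covariates_smoothed.csv"))
  jsonlite::write_json(list(center = as.list(design$center),
                            scale = as.list(design$scale)),
                       file.path(dir, "design_scaler.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
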