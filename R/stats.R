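#' Robust univariate linear regression
#'
#' Iteratively reweighted least squares with Tukey bisquare weights (tuning
#' constant 4.685) and MAD residual scale, the standard robust-regression
#' configuration for shape-measure analyses. The engine is [MASS::rlm()];
#' coefficients, robust standard errors and two-sided t-based p-values
#' (df = n - p) are returned. Falls back to ordinary least squares when the
#' fit is exact (zero residual scale), where the robust weights are
#' undefined.
#'
#' @param y numeric outcome vector.
#' @param X design matrix including the intercept column.
#' @return an object of class `tv_regression`: data.frame with one row per
#'   column of `X`: `term`, `beta`, `se`, `t`, `p`.
#' @export
robust_fit <- function(y, X) {
  X <- as.matrix(X)
  if (is.null(colnames(X)))
    colnames(X) <- c("(Intercept)", paste0("x", seq_len(ncol(X) - 1)))
  if (nrow(X) <= ncol(X))
    stop("need more observations than design columns")
  if (anyNA(y) || anyNA(X)) stop("missing values in y or X")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  df <- nrow(X) - ncol(X)
  ls0 <- stats::lm.fit(X, y)
  exact <- mad(ls0$residuals) < 1e-10 * max(1, sd(y))
  fit <- if (exact) NULL else tryCatch(
    MASS::rlm(X, y, psi = MASS::psi.bisquare, c = 4.685,
              scale.est = "MAD", maxit = 100, acc = 1e-8),
    error = function(e) NULL)
  if (is.null(fit) || !is.finite(summary_scale(fit))) {
    beta <- ls0$coefficients
    s2 <- sum(ls0$residuals^2) / max(df, 1)
    se <- sqrt(diag(chol2inv(qr.R(qrX))) * s2)
    if (exact) se[] <- 0
  } else {
    sm <- summary(fit, method = "XtX")
    beta <- sm$coefficients[, "Value"]
    se <- sm$coefficients[, "Std. Error"]
  }
  tval <- ifelse(se > 0, beta / se, ifelse(abs(beta) < 1e-12, 0, Inf))
  p <- 2 * pt(-abs(tval), df)
  p[tval == 0 & se == 0] <- 1
  structure(data.frame(term = colnames(X), beta = unname(beta),
                       se = unname(se), t = unname(tval), p = unname(p),
                       row.names = NULL),
            class = c("tv_regression", "data.frame"))
}

summary_scale <- function(fit) {
  s <- fit$s
  if (is.null(s) || is.na(s) || s <= 0) NA_real_ else s
}

#' Vertex-wise robust regression of deformity maps
#'
#' Fits the robust regression at every template vertex, with the named
#' predictor and the remaining design columns as covariates, and adjusts
#' the predictor's p-values for multiple comparisons across vertices with
#' the Benjamini-Hochberg false discovery rate.
#'
#' @param deformities subjects x vertices matrix of signed deformities
#'   (mm), rows aligned with `design`.
#' @param design data.frame of per-subject covariates (no intercept
#'   column; one is added).
#' @param predictor name of the design column whose effect is mapped.
#' @param covariates names of adjustment columns; defaults to all other
#'   columns of `design`.
#' @return data.frame with one row per vertex: `vertex`, `beta`, `se`,
#'   `p`, `q`.
#' @export
vertexwise_regression <- function(deformities, design, predictor,
                                  covariates = setdiff(names(design),
                                                       predictor)) {
  deformities <- as.matrix(deformities)
  design <- as.data.frame(design)
  if (!predictor %in% names(design))
    stop("predictor '", predictor, "' not in design")
  if (nrow(deformities) != nrow(design))
    stop("deformity rows and design rows differ")
  if (anyNA(deformities) || anyNA(design[c(predictor, covariates)]))
    stop("missing values in deformities or design")
  xcols <- c(predictor, covariates)
  X <- cbind(`(Intercept)` = 1, as.matrix(design[xcols]))
  if (sd(design[[predictor]]) == 0)
    stop("predictor '", predictor, "' has zero variance")
  if (nrow(X) < ncol(X) + 5)
    stop("need at least ", ncol(X) + 5, " subjects for ", ncol(X),
         " design columns")
  nv <- ncol(deformities)
  beta <- se <- p <- numeric(nv)
  for (v in seq_len(nv)) {
    r <- robust_fit(deformities[, v], X)
    beta[v] <- r$beta[2]
    se[v] <- r$se[2]
    p[v] <- r$p[2]
  }
  data.frame(vertex = seq_len(nv), beta = beta, se = se, p = p,
             q = p.adjust(p, method = "BH"))
}

#' Scalar shape-measure regressions for a cohort
#'
#' Runs the robust regression of each supplied shape measure (e.g. volume,
#' average/anterior/posterior width, asymmetry) on a predictor with
#' covariate adjustment, returning the predictor's coefficient, standard
#' error and p-value per measure.
#'
#' @param measures data.frame of per-subject shape measures (columns are
#'   outcomes).
#' @param design data.frame of per-subject covariates.
#' @param predictor name of the design column of interest.
#' @param covariates adjustment columns (default: all others).
#' @return data.frame with one row per measure: `measure`, `beta`, `se`,
#'   `p`.
#' @export
measure_regressions <- function(measures, design, predictor,
                                covariates = setdiff(names(design),
                                                     predictor)) {
  X <- cbind(`(Intercept)` = 1,
             as.matrix(as.data.frame(design)[c(predictor, covariates)]))
  out <- lapply(names(measures), function(m) {
    r <- robust_fit(measures[[m]], X)
    data.frame(measure = m, beta = r$beta[2], se = r$se[2], p = r$p[2])
  })
  do.call(rbind, out)
}
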