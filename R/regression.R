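#' Covariate-adjusted parcel-wise regression ("obesity maps")
#'
#' The phenotype map at the core of the pipeline is built by ordinary
#' least squares of per-parcel cortical thickness on BMI plus a shared
#' covariate roster (age, sex, imaging site, education, socioeconomic
#' status, optionally scan date). The map value for a parcel is the
#' t-statistic of the BMI coefficient; two-sided p-values come from the t
#' distribution with residual degrees of freedom, and Benjamini-Hochberg
#' adjustment runs across parcels.
#'
#' Categorical covariates (character/factor columns, and `sex`/`site`
#' always) enter as indicator terms; numeric covariates enter linearly;
#' `Date` columns are converted to numeric days. Single-level factors are
#' dropped with a notice rather than breaking the design.
#'
#' @name obesity_map
NULL

# Build the fixed-effect design matrix for thickness ~ bmi + covariates.
# Returns list(X, dropped) where dropped names degenerate covariates.
build_design <- function(subjects, covariates) {
  dat <- data.frame(bmi = as.numeric(subjects$bmi))
  dropped <- character(0)
  for (cv in covariates) {
    if (!cv %in% names(subjects)) stop("covariate not in table: ", cv)
    col <- subjects[[cv]]
    if (inherits(col, "Date")) col <- as.numeric(col)
    if (is.character(col) || is.factor(col) || cv %in% c("sex", "site")) {
      col <- factor(col)
      if (nlevels(droplevels(col)) < 2L) {
        message("covariate '", cv, "' has a single level; dropped")
        dropped <- c(dropped, cv)
        next
      }
      dat[[cv]] <- droplevels(col)
    } else {
      dat[[cv]] <- as.numeric(col)
    }
  }
  X <- stats::model.matrix(~ ., data = dat)
  list(X = X, dropped = dropped)
}

#' Fit the BMI term for a single parcel
#'
#' Ordinary least squares of one parcel's thickness on BMI and the
#' covariate roster; returns the BMI coefficient, its t-statistic and the
#' two-sided p-value.
#'
#' @param subjects subject table containing a thickness column named
#'   `parcel`.
#' @param parcel parcel_id naming the thickness column.
#' @param covariates character vector of covariate column names
#'   (default none).
#' @return list with `beta` (mm per BMI unit), `se`, `t`, `p`, `df`,
#'   `n`.
#' @export
fit_parcel_regression <- function(subjects, parcel, covariates = character(0)) {
  if (!parcel %in% names(subjects)) stop("no thickness column for parcel ", parcel)
  des <- build_design(subjects, covariates)
  ols_bmi_term(des$X, as.numeric(subjects[[parcel]]), parcel)
}

# Core OLS on a prebuilt design; y may be a matrix (one column per parcel).
ols_bmi_term <- function(X, y, label = NULL) {
  y <- as.matrix(y)
  n <- nrow(X)
  p_model <- ncol(X)
  if (n <= p_model) stop("too few subjects (", n, ") for ",
                         p_model, " model terms")
  qr_x <- qr(X)
  if (qr_x$rank < p_model) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):p_model]]
    stop("rank-deficient design; collinear terms: ",
         paste(bad, collapse = ", "))
  }
  coefs <- qr.coef(qr_x, y)
  resid <- y - X %*% coefs
  df <- n - p_model
  sigma2 <- colSums(resid^2) / df
  # (X'X)^-1 from the R factor; account for possible column pivoting
  xtx_inv <- chol2inv(qr.R(qr_x))
  j <- match(match("bmi", colnames(X)), qr_x$pivot)
  se <- sqrt(sigma2 * xtx_inv[j, j])
  beta <- coefs[match("bmi", colnames(X)), ]
  bad_var <- sigma2 <= 1e-10 * pmax(colMeans(y^2), .Machine$double.xmin)
  if (ncol(y) == 1L && bad_var) {
    stop("zero residual variance", if (!is.null(label)) paste0(" for parcel ", label))
  }
  t <- beta / se
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  if (ncol(y) == 1L) {
    list(beta = unname(beta), se = unname(se), t = unname(t),
         p = unname(p), df = df, n = n)
  } else {
    list(beta = beta, se = se, t = t, p = p, df = df, n = n,
         zero_var = bad_var)
  }
}

#' Build an obesity map over all parcels
#'
#' Applies [fit_parcel_regression()] with one shared covariate roster to
#' every parcel of the parcellation, collects BMI t-values into a
#' [parcel_map()] and adjusts p-values across parcels by
#' Benjamini-Hochberg. A parcel whose fit degenerates (zero residual
#' variance) is masked with a warning rather than aborting the map.
#'
#' @param subjects filtered subject table with one thickness column per
#'   parcel_id.
#' @param parcellation the parcellation the thickness columns refer to.
#' @param covariates character vector of covariate names.
#' @return object of class `obesity_map`: fields `tmap` (parcel_map of
#'   t-values), `beta`, `se`, `p`, `q`, `df`, `n_subjects`, `covariates`.
#' @export
build_obesity_map <- function(subjects, parcellation,
                              covariates = character(0)) {
  stopifnot(inherits(parcellation, "spherical_parcellation"))
  ids <- parcellation$parcel_id
  miss_cols <- setdiff(ids, names(subjects))
  if (length(miss_cols)) {
    stop("subject table lacks thickness columns for: ",
         paste(utils::head(miss_cols, 5L), collapse = ", "))
  }
  Y <- as.matrix(subjects[, ids, drop = FALSE])
  if (anyNA(Y)) stop("missing thickness values among included subjects")
  des <- build_design(subjects, covariates)
  fit <- ols_bmi_term(des$X, Y)
  t <- fit$t; beta <- fit$beta; se <- fit$se; p <- fit$p
  if (any(fit$zero_var)) {
    warning("zero residual variance; masking parcels: ",
            paste(ids[fit$zero_var], collapse = ", "))
    t[fit$zero_var] <- NA_real_
    beta[fit$zero_var] <- NA_real_
    p[fit$zero_var] <- NA_real_
  }
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- bh_fdr(p[ok])
  names(q) <- ids
  structure(
    list(tmap = parcel_map(parcellation, stats::setNames(t, ids)),
         beta = stats::setNames(beta, ids), se = stats::setNames(se, ids),
         p = stats::setNames(p, ids), q = q, df = fit$df,
         n_subjects = fit$n,
         covariates = setdiff(covariates, des$dropped)),
    class = "obesity_map")
}

#' @export
print.obesity_map <- function(x, ...) {
  cat("obesity_map:", length(x$beta), "parcels, n =", x$n_subjects,
      "subjects, covariates:",
      if (length(x$covariates)) paste(x$covariates, collapse = ", ") else "(none)",
      "\n  t range [", round(min(x$tmap$value, na.rm = TRUE), 2), ",",
      round(max(x$tmap$value, na.rm = TRUE), 2), "],",
      sum(x$q < 0.05, na.rm = TRUE), "parcels with q < 0.05\n")
  invisible(x)
}

#' Write an obesity map (TSV + JSON sidecar)
#'
#' The t-map goes to a two-column parcel-map TSV; beta/p/q, the subject
#' count and the covariate roster go to a JSON sidecar next to it.
#'
#' @param x an `obesity_map`.
#' @param path TSV output path; the sidecar is `<path>.json`.
#' @export
write_obesity_map <- function(x, path) {
  write_parcel_map(x$tmap, path)
  write_sidecar(list(
    beta = as.list(x$beta), se = as.list(x$se), p = as.list(x$p),
    q = as.list(x$q), df = x$df, n_subjects = x$n_subjects,
    covariates = x$covariates), paste0(path, ".json"))
  invisible(path)
}
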