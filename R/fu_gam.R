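#' Transformation ladder towards normality
#'
#' Applies progressively more powerful transformations to unbound
#' fractions (identity, then log10, square root, fourth root — the
#' published order) and returns the first whose Shapiro-Wilk test does not
#' reject normality at `alpha`. If no rung passes, the fourth root is
#' returned (the terminal choice used for all species in the source
#' analysis). Note the order follows the printed sequence even though the
#' square root is conventionally a milder transformation than the
#' logarithm.
#'
#' @param values unbound fractions in (0, 1\], length >= 3.
#' @param alpha Shapiro-Wilk significance level (default 0.05).
#' @return list with `values` (transformed), `transform_name` (one of
#'   `"none"`, `"log10"`, `"sqrt"`, `"fourth_root"`), and `shapiro_p`
#'   (named vector of p-values for the rungs evaluated).
#' @examples
#' set.seed(1)
#' transform_ladder(pmin(pmax(rnorm(30, 0.5, 0.1), 1e-3), 1))$transform_name
#' @export
transform_ladder <- function(values, alpha = 0.05) {
  if (length(values) < 3L) {
    stop("need at least 3 values for a normality test", call. = FALSE)
  }
  if (any(is.na(values)) || any(values <= 0) || any(values > 1)) {
    stop("values must be unbound fractions in (0, 1]", call. = FALSE)
  }
  rungs <- list(none = identity,
                log10 = log10,
                sqrt = sqrt,
                fourth_root = function(x) x^0.25)
  pvals <- c()
  for (nm in names(rungs)) {
    tv <- rungs[[nm]](values)
    if (any(!is.finite(tv))) {
      warning("skipping '", nm, "' transform: non-finite values")
      next
    }
    p <- tryCatch(stats::shapiro.test(tv)$p.value, error = function(e) 0)
    pvals[nm] <- p
    if (p > alpha) {
      return(list(values = tv, transform_name = nm, shapiro_p = pvals))
    }
  }
  list(values = values^0.25, transform_name = "fourth_root",
       shapiro_p = pvals)
}

#' Additive model of molecular predictors of the unbound fraction
#'
#' Fits a penalized-spline generalized additive model of the (fourth-root
#' transformed) unbound fraction on molecular weight, LogD at the species
#' plasma pH, pKa, and molecular charge:
#' \code{fu^(1/4) ~ s(mw, k = 4) + s(logd, k = 4) + s(pka, k = 4) + charge},
#' with a gamma error distribution and log link. Continuous predictors get
#' thin-plate smooths with basis dimension `k`; charge is a 4-level factor
#' (cationic, anionic, zwitterionic, neutral) and enters parametrically
#' (a factor cannot be smoothed). The response transform is chosen by
#' [transform_ladder()] unless fixed via `transform`. Smoothing parameters
#' are selected by generalized cross-validation.
#'
#' @param data data.frame with columns `fu` (unbound fraction in (0, 1]),
#'   `mw`, `logd`, `pka`, and `charge_class` (or `speciation` from which
#'   charge is derived).
#' @param species species id recorded in the fit report.
#' @param k basis dimension for each smooth (default 4, appropriate for
#'   panels under ~100 compounds).
#' @param transform `NULL` to select via the ladder, or one of `"none"`,
#'   `"log10"`, `"sqrt"`, `"fourth_root"`.
#' @param charge_mapping speciation-to-charge mapping, see
#'   [charge_class()].
#' @return object of class `fu_gam_fit`: a list with `species_id`,
#'   `transform_name`, `predictor_significance` (named p-values),
#'   `smooth_edf`, `basis_dim_k`, `r2_adj`, `deviance_explained_pct`,
#'   `family`, `smoothing_selection`, `charge_mapping`, `dropped_terms`,
#'   `n`, and the underlying `mgcv` fit in `$fit`.
#' @export
fit_fu_gam <- function(data, species = "unspecified", k = 4,
                       transform = NULL,
                       charge_mapping = c("default", "group_counts")) {
  charge_mapping <- match.arg(charge_mapping)
  needed <- c("fu", "mw", "logd", "pka")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0L) {
    stop("data lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"charge_class" %in% names(data)) {
    if (!"speciation" %in% names(data)) {
      stop("data lacks column(s): charge_class (or speciation)",
           call. = FALSE)
    }
    data$charge_class <- charge_class(data$speciation,
                                      mapping = charge_mapping)
  }
  data <- data[stats::complete.cases(data[, c(needed, "charge_class")]), ]
  if (nrow(data) < 20L) {
    stop("need >= 20 complete rows to fit the additive model (have ",
         nrow(data), ")", call. = FALSE)
  }

  if (is.null(transform)) {
    ladder <- transform_ladder(data$fu)
    transform <- ladder$transform_name
    data$fu_t <- ladder$values
  } else {
    transform <- match.arg(transform,
                           c("none", "log10", "sqrt", "fourth_root"))
    data$fu_t <- switch(transform, none = data$fu, log10 = log10(data$fu),
                        sqrt = sqrt(data$fu), fourth_root = data$fu^0.25)
  }
  if (any(data$fu_t <= 0)) {
    stop("transformed response must be positive for the gamma family ",
         "(transform '", transform, "' produced non-positive values)",
         call. = FALSE)
  }
  data$charge_class <- factor(data$charge_class)

  smooth_terms <- c("mw", "logd", "pka")
  dropped <- character(0)
  for (term in smooth_terms) {
    if (length(unique(data[[term]])) < k + 1L) {
      warning("predictor '", term, "' has too few unique values for a ",
              "k = ", k, " smooth; term dropped")
      dropped <- c(dropped, term)
    }
  }
  smooth_terms <- setdiff(smooth_terms, dropped)
  rhs <- paste(sprintf("s(%s, k = %d)", smooth_terms, k), collapse = " + ")
  if (nlevels(droplevels(data$charge_class)) > 1L) {
    rhs <- paste(rhs, "+ charge_class")
  } else {
    warning("charge has a single level; term dropped")
    dropped <- c(dropped, "charge_class")
  }
  fit <- mgcv::gam(stats::as.formula(paste("fu_t ~", rhs)),
                   family = stats::Gamma(link = "log"), data = data,
                   method = "GCV.Cp")
  sm <- summary(fit)
  sig <- stats::setNames(as.numeric(sm$s.table[, "p-value"]),
                         sub("^s\\((.*)\\)$", "\\1",
                             rownames(sm$s.table)))
  if (!"charge_class" %in% dropped && nrow(sm$pTerms.table) > 0L) {
    sig["charge"] <- as.numeric(sm$pTerms.table["charge_class", "p-value"])
  }
  edf <- stats::setNames(as.numeric(sm$s.table[, "edf"]),
                         sub("^s\\((.*)\\)$", "\\1",
                             rownames(sm$s.table)))
  structure(list(species_id = species,
                 transform_name = transform,
                 predictor_significance = sig,
                 smooth_edf = edf,
                 basis_dim_k = k,
                 r2_adj = as.numeric(sm$r.sq),
                 deviance_explained_pct = 100 * as.numeric(sm$dev.expl),
                 family = "gamma, log link",
                 smoothing_selection = "GCV.Cp",
                 charge_mapping = charge_mapping,
                 dropped_terms = dropped,
                 n = nrow(data),
                 fit = fit),
            class = "fu_gam_fit")
}

#' @export
print.fu_gam_fit <- function(x, ...) {
  cat("Additive model of unbound fraction (", x$species_id, ")\n", sep = "")
  cat("  response transform:", x$transform_name,
      "| family:", x$family, "\n")
  cat("  n =", x$n, "| k =", x$basis_dim_k,
      "| smoothing:", x$smoothing_selection, "\n")
  cat(sprintf("  deviance explained: %.1f%% | adj. R-sq: %.3f\n",
              x$deviance_explained_pct, x$r2_adj))
  cat("  term p-values:\n")
  for (nm in names(x$predictor_significance)) {
    cat(sprintf("    %-6s %.4g\n", nm, x$predictor_significance[nm]))
  }
  invisible(x)
}

#' Check smooth basis dimensions against estimated degrees of freedom
#'
#' A smooth whose estimated degrees of freedom approach the maximum
#' allowed by its basis (`k - 1`) may be under-parameterized. A term is
#' adequate when `edf < frac * (k - 1)`.
#'
#' @param fit a `fu_gam_fit` from [fit_fu_gam()].
#' @param frac adequacy fraction of `k - 1` (default 0.9).
#' @return data.frame `term`, `edf`, `k`, `adequate`.
#' @export
check_basis_dimension <- function(fit, frac = 0.9) {
  stopifnot(inherits(fit, "fu_gam_fit"))
  data.frame(term = names(fit$smooth_edf),
             edf = as.numeric(fit$smooth_edf),
             k = fit$basis_dim_k,
             adequate = as.numeric(fit$smooth_edf) <
               frac * (fit$basis_dim_k - 1),
             stringsAsFactors = FALSE)
}

#' Permutation p-value for one model term
#'
#' Model-agnostic significance check usable for cross-implementation
#' comparison: the reduction in residual deviance attributable to `term`
#' is compared with its null distribution obtained by refitting after
#' permuting that predictor's values, everything else held fixed.
#'
#' @param data data as for [fit_fu_gam()].
#' @param term one of `"mw"`, `"logd"`, `"pka"`, `"charge_class"`.
#' @param n_perm number of permutations (>= 1000 recommended).
#' @param seed RNG seed for the permutations.
#' @param ... passed to [fit_fu_gam()] (e.g. `transform`).
#' @return one-sided permutation p-value with the add-one correction.
#' @export
gam_term_permutation_p <- function(data, term, n_perm = 1000, seed = 1,
                                   ...) {
  stopifnot(term %in% c("mw", "logd", "pka", "charge_class"))
  if (!"charge_class" %in% names(data) && "speciation" %in% names(data)) {
    data$charge_class <- charge_class(data$speciation)
  }
  dev_drop <- function(d) {
    f <- fit_fu_gam(d, ...)$fit
    stat_null <- f$null.deviance
    stat_null - stats::deviance(f)
  }
  observed <- dev_drop(data)
  set.seed(seed)
  exceed <- 0L
  for (i in seq_len(n_perm)) {
    d <- data
    d[[term]] <- sample(d[[term]])
    if (dev_drop(d) >= observed) exceed <- exceed + 1L
  }
  (exceed + 1) / (n_perm + 1)
}
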