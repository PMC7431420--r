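#' Specify a regression model for the analysis suite
#'
#' A thin container tying a (possibly mixed) model formula to its error
#' structure and to the focal fixed-effect term whose coefficient serves as
#' the permutation statistic. Binary and proportion responses use binomial
#' errors, counts Poisson, and continuous responses Gaussian errors with an
#' identity or log link.
#'
#' @param name short analysis label.
#' @param formula model formula; random effects in `lme4` syntax.
#' @param family one of `"binomial"`, `"poisson"`, `"gaussian"`.
#' @param link link function; defaults to the family's canonical link
#'   (`"log"` is the supported alternative for gaussian).
#' @param focal_term name of the fixed-effect term whose coefficient is the
#'   statistic of interest.
#' @param data_filter free-text description of the rows the analysis uses.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(name, formula, family = c("binomial", "poisson",
                                                 "gaussian"),
                       link = NULL, focal_term, data_filter = NULL) {
  family <- match.arg(family)
  link <- link %||% switch(family, binomial = "logit", poisson = "log",
                           gaussian = "identity")
  ok <- switch(family,
               binomial = link == "logit",
               poisson = link == "log",
               gaussian = link %in% c("identity", "log"))
  if (!ok) stop("unsupported family/link combination: ", family, "/", link)
  fixed <- attr(terms(lme4::nobars(formula)), "term.labels")
  if (!focal_term %in% c(fixed, "1")) {  # "1": intercept-only reduced model
    stop("focal_term '", focal_term, "' is not among the fixed terms")
  }
  structure(list(name = name, formula = formula, family = family,
                 link = link, focal_term = focal_term,
                 data_filter = data_filter),
            class = "model_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.deparse1 <- function(x) paste(deparse(x), collapse = " ")

# drop fixed factor/character terms with fewer than 2 observed levels
# (e.g. a single study year in a subset); the focal term is never dropped
.drop_constant_factors <- function(fixed_formula, data, focal_term) {
  labs <- attr(terms(fixed_formula), "term.labels")
  keep <- vapply(labs, function(tm) {
    if (tm == focal_term) return(TRUE)
    vars <- intersect(all.vars(stats::reformulate(tm)), names(data))
    all(vapply(vars, function(v) {
      is.numeric(data[[v]]) || length(unique(data[[v]])) >= 2L
    }, logical(1)))
  }, logical(1))
  if (all(keep)) return(fixed_formula)
  message("dropping single-level fixed term(s): ",
          paste(labs[!keep], collapse = ", "))
  if (!any(keep)) {
    return(stats::as.formula(paste(.deparse1(fixed_formula[[2L]]), "~ 1")))
  }
  stats::reformulate(labs[keep], response = fixed_formula[[2L]])
}

.spec_family <- function(spec) {
  switch(spec$family,
         binomial = binomial(),
         poisson = poisson(),
         gaussian = gaussian(link = spec$link))
}

.response_values <- function(formula, data) {
  v <- eval(formula[[2L]], data, environment(formula))
  if (is.matrix(v)) v[, 1L] / pmax(rowSums(v), 1) else as.numeric(v)
}

#' Fit a model specification
#'
#' Mixed models are fitted by maximum likelihood (`REML = FALSE`) so that
#' likelihood-ratio comparisons between nested fits are valid. Random
#' terms whose grouping factor has fewer than two levels in the data are
#' dropped with a message (downgrading to a fixed-effects GLM when none
#' remain), and `mixed = FALSE` forces the fixed-effects GLM directly —
#' the documented fallback used inside permutation replicates for speed
#' and robustness. A constant response is flagged degenerate and fitted as
#' intercept-only, with zero slopes for the remaining terms.
#'
#' @param spec a [model_spec()].
#' @param data data.frame with the model variables.
#' @param mixed fit random effects where present (default TRUE).
#' @return object of class `model_fit`: `spec`, `fit` (the underlying
#'   `glm`/`merMod`), `coefficients` (data.frame term/estimate/se),
#'   `log_likelihood`, `df`, `converged`, `singular`, `degenerate`,
#'   `is_mixed`, `n_obs`.
#' @export
fit_model <- function(spec, data, mixed = TRUE) {
  stopifnot(inherits(spec, "model_spec"))
  fam <- .spec_family(spec)
  formula <- spec$formula
  bars <- lme4::findbars(formula)
  fixed_formula <- lme4::nobars(formula)
  data <- data[complete.cases(data[, intersect(all.vars(fixed_formula),
                                               names(data)), drop = FALSE]),
               , drop = FALSE]
  fixed_formula <- .drop_constant_factors(fixed_formula, data,
                                          spec$focal_term)
  if (length(bars) > 0L && mixed) {
    grp_ok <- vapply(bars, function(b) {
      g <- all.vars(b[[3L]])
      all(vapply(g, function(v) length(unique(data[[v]])) >= 2L, logical(1)))
    }, logical(1))
    if (!all(grp_ok)) {
      message("dropping random term(s) with <2 grouping levels: ",
              paste(vapply(bars[!grp_ok], deparse, character(1)),
                    collapse = ", "))
      bars <- bars[grp_ok]
    }
    if (length(bars) == 0L) formula <- fixed_formula
    else formula <- stats::reformulate(
      c(attr(terms(fixed_formula), "term.labels"),
        paste0("(", vapply(bars, .deparse1, character(1)), ")")),
      response = fixed_formula[[2L]],
      intercept = attr(terms(fixed_formula), "intercept") == 1L)
  } else {
    formula <- fixed_formula
    bars <- list()
  }
  use_mixed <- length(bars) > 0L && mixed

  y <- .response_values(fixed_formula, data)
  degenerate <- length(unique(y)) < 2L
  if (degenerate) {
    int_formula <- stats::as.formula(
      paste(deparse(fixed_formula[[2L]]), "~ 1"))
    fit <- glm(int_formula, family = fam, data = data)
    fixed_terms <- colnames(model.matrix(fixed_formula, data))
    co <- data.frame(term = fixed_terms,
                     estimate = c(coef(fit)[1L],
                                  rep(0, length(fixed_terms) - 1L)),
                     se = NA_real_, stringsAsFactors = FALSE)
    return(structure(list(spec = spec, fit = fit, coefficients = co,
                          log_likelihood = as.numeric(logLik(fit)),
                          df = attr(logLik(fit), "df"),
                          converged = TRUE, singular = FALSE,
                          degenerate = TRUE, is_mixed = FALSE,
                          n_obs = nrow(data)), class = "model_fit"))
  }

  singular <- FALSE
  if (use_mixed) {
    fitter <- if (spec$family == "gaussian" && spec$link == "identity") {
      function() lme4::lmer(formula, data = data, REML = FALSE)
    } else {
      function() lme4::glmer(formula, data = data, family = fam)
    }
    fit <- tryCatch(suppressMessages(suppressWarnings(fitter())),
                    error = function(e) NULL)
    if (is.null(fit)) {
      # mixed fit failed outright: documented fallback to fixed-effects GLM
      message("mixed fit failed for '", spec$name,
              "'; falling back to fixed-effects GLM")
      fit <- glm(fixed_formula, family = fam, data = data)
      use_mixed <- FALSE
    } else {
      singular <- lme4::isSingular(fit)
    }
  } else {
    fit <- suppressWarnings(glm(formula, family = fam, data = data))
  }

  if (use_mixed) {
    sm <- suppressWarnings(summary(fit))$coefficients
    co <- data.frame(term = rownames(sm), estimate = sm[, 1L],
                     se = sm[, 2L], stringsAsFactors = FALSE)
    conv_msgs <- fit@optinfo$conv$lme4$messages
    converged <- is.null(conv_msgs) || length(conv_msgs) == 0L
  } else {
    sm <- summary(fit)$coefficients
    co <- data.frame(term = rownames(sm), estimate = sm[, 1L],
                     se = sm[, 2L], stringsAsFactors = FALSE)
    converged <- isTRUE(fit$converged)
  }
  rownames(co) <- NULL
  structure(list(spec = spec, fit = fit, coefficients = co,
                 log_likelihood = as.numeric(logLik(fit)),
                 df = attr(logLik(fit), "df"),
                 converged = converged, singular = singular,
                 degenerate = FALSE, is_mixed = use_mixed,
                 n_obs = nrow(data)),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("model_fit '%s' (%s/%s, %s): n = %d, logLik = %.2f%s%s\n",
              x$spec$name, x$spec$family, x$spec$link,
              if (x$is_mixed) "mixed" else "GLM", x$n_obs,
              x$log_likelihood,
              if (x$singular) ", singular" else "",
              if (x$degenerate) ", degenerate" else ""))
  print(x$coefficients, row.names = FALSE)
  invisible(x)
}

#' Coefficient of the focal term
#'
#' Returns the fitted coefficient for the specification's focal term; for factor
#' focal terms the first matching contrast coefficient is used.
#'
#' @param fit a `model_fit`.
#' @return numeric scalar.
#' @export
focal_estimate <- function(fit) {
  focal <- fit$spec$focal_term
  co <- fit$coefficients
  hit <- which(co$term == focal)
  if (length(hit) == 0L) hit <- which(startsWith(co$term, focal))
  if (length(hit) == 0L) stop("focal term '", focal, "' not in fit")
  co$estimate[hit[1L]]
}

#' Likelihood-ratio test between nested fits
#'
#' Chi-square is twice the log-likelihood difference, floored at zero,
#' with degrees of freedom equal to the difference in parameter counts.
#' Both fits must be maximum-likelihood fits on the same rows, with the
#' reduced model's fixed terms a subset of the full model's.
#'
#' @param full,reduced `model_fit` objects.
#' @return object of class `lrt_result`: `chi_sq`, `df`, `p`.
#' @export
lrt <- function(full, reduced) {
  if (full$n_obs != reduced$n_obs) {
    stop("LRT requires both models fitted to the same rows")
  }
  tf <- attr(terms(lme4::nobars(full$spec$formula)), "term.labels")
  tr <- attr(terms(lme4::nobars(reduced$spec$formula)), "term.labels")
  if (!all(tr %in% tf)) {
    stop("reduced model is not nested in the full model")
  }
  df <- full$df - reduced$df
  if (df < 0L) stop("reduced model has more parameters than the full model")
  chi <- max(0, 2 * (full$log_likelihood - reduced$log_likelihood))
  p <- if (df == 0L) 1 else pchisq(chi, df = df, lower.tail = FALSE)
  structure(list(chi_sq = chi, df = df, p = p), class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT: chi-sq = %.3f, df = %d, p = %.4g\n",
              x$chi_sq, x$df, x$p))
  invisible(x)
}

#' Variance inflation factors of a fixed-effects design
#'
#' VIF_j = 1 / (1 - R^2_j), with R^2_j from the least-squares regression of
#' design column j on all other (non-intercept) columns. Perfectly
#' collinear columns report `Inf`.
#'
#' @param formula fixed-effects formula (random terms, if any, ignored).
#' @param data data.frame.
#' @return named numeric vector of VIFs, one per design column.
#' @export
compute_vif <- function(formula, data) {
  X <- model.matrix(lme4::nobars(formula), data)
  icpt <- which(colnames(X) == "(Intercept)")
  has_icpt <- length(icpt) > 0L
  Z <- if (has_icpt) X[, -icpt, drop = FALSE] else X
  if (ncol(Z) < 2L) stop("VIF needs at least two non-intercept terms")
  out <- setNames(numeric(ncol(Z)), colnames(Z))
  for (j in seq_len(ncol(Z))) {
    yj <- Z[, j]
    Xj <- Z[, -j, drop = FALSE]
    if (has_icpt) Xj <- cbind(`(Intercept)` = 1, Xj)
    fitj <- stats::lm.fit(Xj, yj)
    tss <- sum((yj - mean(yj))^2)
    rss <- sum(fitj$residuals^2)
    r2 <- if (tss == 0) 1 else 1 - rss / tss
    out[j] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  out
}
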