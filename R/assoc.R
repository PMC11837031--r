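#' Per-IDP association models
#'
#' `fit_linear_assoc()` fits ordinary least squares
#' `outcome ~ idp + covariates` and returns the IDP coefficient with its
#' standard error, t statistic and two-sided p-value. With all numeric
#' variables quantile-normalised upstream, the coefficient reads as the SD
#' change in the outcome per SD of the IDP.
#'
#' `fit_ordinal_assoc()` fits a proportional-odds logistic model of an
#' ordered outcome on the IDP and covariates by maximum likelihood
#' ([MASS::polr]). The returned coefficient is the log-odds of a higher
#' (more severe) category per SD of the IDP; its exponential is an odds
#' ratio. The p-value is Wald-based by default; `p_type = "lr"` uses a
#' likelihood-ratio test against the model without the IDP.
#'
#' Rows with missing values in any variable are dropped (complete-case per
#' fit); `n_used` records what remained.
#'
#' @param outcome Numeric outcome vector.
#' @param idp Numeric IDP vector of the same length.
#' @param covariates Optional data.frame/matrix of covariates.
#' @param idp_name,modality Labels carried into the result.
#' @return A one-row tibble: `idp_name`, `modality`, `beta`, `se`,
#'   `statistic`, `p_raw`, `n_used`.
#' @examples
#' x <- rnorm(100)
#' fit_linear_assoc(2 * x + rnorm(100), x)
#' @export
fit_linear_assoc <- function(outcome, idp, covariates = NULL,
                             idp_name = "idp", modality = NA_character_) {
  df <- assemble_model_frame(outcome, idp, covariates)
  n_par <- ncol(df)                 # intercept + idp + covariates
  if (nrow(df) <= n_par + 2L) {
    stop("too few complete cases for a linear fit", call. = FALSE)
  }
  qr_x <- qr(stats::model.matrix(~ ., df[-1]))
  if (qr_x$rank < ncol(qr_x$qr)) {
    bad <- colnames(qr_x$qr)[qr_x$pivot[seq(qr_x$rank + 1L, ncol(qr_x$qr))]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  fit <- stats::lm(outcome ~ ., data = df)
  cf <- summary(fit)$coefficients["idp", ]
  tibble::tibble(idp_name = idp_name, modality = modality,
                 beta = cf[["Estimate"]], se = cf[["Std. Error"]],
                 statistic = cf[["t value"]], p_raw = cf[["Pr(>|t|)"]],
                 n_used = nrow(df))
}

#' @rdname fit_linear_assoc
#' @param diagnosis Ordered factor outcome.
#' @param p_type `"wald"` (default) or `"lr"`.
#' @export
fit_ordinal_assoc <- function(diagnosis, idp, covariates = NULL,
                              idp_name = "idp", modality = NA_character_,
                              p_type = c("wald", "lr")) {
  p_type <- match.arg(p_type)
  if (!is.ordered(diagnosis)) {
    stop("`diagnosis` must be an ordered factor", call. = FALSE)
  }
  df <- assemble_model_frame(diagnosis, idp, covariates)
  df$outcome <- droplevels(df$outcome)
  if (nlevels(df$outcome) < 2) {
    stop("outcome has a single observed level: ordinal fit undefined",
         call. = FALSE)
  }
  if (nlevels(df$outcome) == 2) {
    # two observed levels: the proportional-odds model reduces to ordinary
    # logistic regression on the upper level
    df$y01 <- as.integer(df$outcome == levels(df$outcome)[2])
    fit <- stats::glm(y01 ~ . - outcome, data = df, family = stats::binomial)
    cf <- summary(fit)$coefficients
    beta <- cf["idp", "Estimate"]
    se <- cf["idp", "Std. Error"]
    dev_drop <- function() {
      fit0 <- stats::glm(y01 ~ . - outcome - idp, data = df,
                         family = stats::binomial)
      fit0$deviance - fit$deviance
    }
  } else {
    fit <- tryCatch(
      MASS::polr(outcome ~ ., data = df, method = "logistic", Hess = TRUE),
      error = function(e) {
        stop("proportional-odds fit failed: ", conditionMessage(e),
             call. = FALSE)
      })
    cf <- summary(fit)$coefficients
    beta <- cf["idp", "Value"]
    se <- cf["idp", "Std. Error"]
    dev_drop <- function() {
      fit0 <- MASS::polr(outcome ~ . - idp, data = df, method = "logistic")
      fit0$deviance - fit$deviance
    }
  }
  if (!is.finite(se) || se > 50 || abs(beta) > 25) {
    stop("proportional-odds fit is degenerate (likely complete separation: ",
         sprintf("beta = %.2f, se = %.2f)", beta, se), call. = FALSE)
  }
  p <- if (p_type == "wald") {
    2 * stats::pnorm(-abs(beta / se))
  } else {
    stats::pchisq(dev_drop(), df = 1, lower.tail = FALSE)
  }
  tibble::tibble(idp_name = idp_name, modality = modality,
                 beta = beta, se = se, statistic = beta / se, p_raw = p,
                 n_used = nrow(df))
}

assemble_model_frame <- function(outcome, idp, covariates) {
  if (length(outcome) != length(idp)) {
    stop("`outcome` and `idp` differ in length", call. = FALSE)
  }
  df <- data.frame(outcome = outcome, idp = as.numeric(idp))
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != length(idp)) {
      stop("`covariates` row count does not match", call. = FALSE)
    }
    if (any(names(covariates) %in% c("outcome", "idp"))) {
      stop("covariates may not be named `outcome` or `idp`", call. = FALSE)
    }
    df <- cbind(df, covariates)
  }
  df[stats::complete.cases(df), , drop = FALSE]
}
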