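# Expression -> drug-sensitivity imputation: a ridge regression of
# dose-response AUC (lower = more sensitive) on standardized gene
# expression, with the penalty chosen by cross-validation, plus a
# differential-sensitivity screen contrasting predicted AUCs of sensitive
# and resistant clones.

#' Fit an expression-to-AUC ridge model and predict new samples
#'
#' Genes are standardized using training statistics only (stored and
#' re-applied to the new samples); the ridge penalty is selected by k-fold
#' cross-validation over a log-spaced grid. Predictions are returned on the
#' AUC scale. A constant response yields an intercept-only model with a
#' warning.
#'
#' @param x_train Training expression, genes x cell lines
#'   ([expression_matrix()] or log2 matrix).
#' @param auc Per-line response (area under the dose-response curve; lower
#'   values mean higher sensitivity), length `ncol(x_train)`.
#' @param x_new Expression of the samples to predict (genes x samples);
#'   must share >= 10 genes with the training matrix.
#' @param nfolds Cross-validation folds (default 5).
#' @param lambda Optional penalty grid; default `10^seq(2, -5, length 60)`.
#' @param seed Optional seed for the fold assignment (for reproducibility).
#' @return List with `predictions` (named, AUC scale) and `model` (class
#'   `sensitivity_model`: gene-scale coefficients, intercept, chosen
#'   penalty, training gene list).
#' @export
fit_and_predict <- function(x_train, auc, x_new, nfolds = 5, lambda = NULL,
                            seed = NULL) {
  xt <- expr_values(x_train)
  xn <- expr_values(x_new)
  if (length(auc) != ncol(xt))
    stop_bad_arg("`auc` must have one response per training line")
  if (!all(is.finite(auc))) stop_bad_arg("responses must be finite")
  genes <- intersect(rownames(xt), rownames(xn))
  if (length(genes) < 10L)
    stop_bad_arg("need >= 10 shared genes between training and new data; ",
                 "got ", length(genes))
  xt <- xt[genes, , drop = FALSE]
  xn <- xn[genes, , drop = FALSE]

  mu <- rowMeans(xt)
  sd <- sqrt(row_vars(xt))
  ok <- sd > 1e-8
  scale_rows <- function(m) {
    z <- (m - mu) / ifelse(ok, sd, 1)
    z[!ok, ] <- 0
    z
  }
  zt <- scale_rows(xt)
  zn <- scale_rows(xn)

  if (stats::sd(auc) == 0) {
    warning("constant response: returning an intercept-only model")
    model <- structure(list(intercept = auc[1],
                            coefficients = stats::setNames(
                              rep(0, length(genes)), genes),
                            lambda = NA_real_, genes = genes,
                            center = mu, scale = ifelse(ok, sd, 1)),
                       class = "sensitivity_model")
    return(list(predictions = stats::setNames(rep(auc[1], ncol(xn)),
                                              colnames(xn)),
                model = model))
  }

  lambda <- lambda %||% 10^seq(2, -5, length.out = 60)
  if (!is.null(seed)) {
    fit <- with_substream(seed, "ridge_cv",
                          glmnet::cv.glmnet(t(zt), auc, alpha = 0,
                                            lambda = lambda, nfolds = nfolds,
                                            standardize = FALSE))
  } else {
    fit <- glmnet::cv.glmnet(t(zt), auc, alpha = 0, lambda = lambda,
                             nfolds = nfolds, standardize = FALSE)
  }
  beta_z <- as.numeric(stats::coef(fit, s = "lambda.min"))[-1]
  intercept_z <- as.numeric(stats::coef(fit, s = "lambda.min"))[1]
  pred <- as.numeric(stats::predict(fit, newx = t(zn), s = "lambda.min"))
  model <- structure(list(intercept = intercept_z,
                          coefficients = stats::setNames(beta_z, genes),
                          lambda = fit$lambda.min, genes = genes,
                          center = mu, scale = ifelse(ok, sd, 1)),
                     class = "sensitivity_model")
  list(predictions = stats::setNames(pred, colnames(xn)), model = model)
}

#' @export
print.sensitivity_model <- function(x, ...) {
  cat(sprintf("sensitivity_model: %d genes, lambda = %s\n",
              length(x$genes),
              if (is.na(x$lambda)) "NA (intercept-only)"
              else format(x$lambda, digits = 3)))
  invisible(x)
}

#' Differential-sensitivity screen between sensitive and resistant clones
#'
#' Two-sample Student t test per drug on predicted AUCs of the sensitive
#' versus resistant replicate groups, with Benjamini-Hochberg adjustment
#' across drugs. The t statistic is signed as `mean(resistant) -
#' mean(sensitive)`, so negative values indicate drugs the resistant clones
#' are predicted to be *more* sensitive to (lower AUC), flagged
#' `"resistant-selective"`.
#'
#' @param pred_s,pred_r Matrices of predicted AUCs, drugs x replicates
#'   (>= 2 replicates per group), with matching drug rownames.
#' @return Data frame with columns `drug`, `t`, `p`, `p_adj`, `direction`
#'   (`"resistant-selective"`, `"sensitive-selective"` or `"none"`),
#'   `mean_sensitive`, `mean_resistant`.
#' @export
differential_sensitivity <- function(pred_s, pred_r) {
  pred_s <- as.matrix(pred_s); pred_r <- as.matrix(pred_r)
  if (!identical(rownames(pred_s), rownames(pred_r)))
    stop_bad_arg("the two prediction matrices must share drug rownames")
  if (ncol(pred_s) < 2L || ncol(pred_r) < 2L)
    stop_bad_arg("need >= 2 replicates (or imputation draws) per group")
  n1 <- ncol(pred_s); n2 <- ncol(pred_r)
  m1 <- rowMeans(pred_s); m2 <- rowMeans(pred_r)
  v1 <- row_vars(pred_s); v2 <- row_vars(pred_r)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  diff <- m2 - m1
  t <- ifelse(se > 0, diff / se,
              ifelse(diff == 0, 0, sign(diff) * Inf))
  df <- n1 + n2 - 2
  p <- pmax(2 * stats::pt(-abs(t), df), .Machine$double.xmin)
  out <- data.frame(drug = rownames(pred_s), t = t, p = p,
                    p_adj = stats::p.adjust(p, method = "BH"),
                    direction = ifelse(m2 < m1, "resistant-selective",
                                       ifelse(m2 > m1,
                                              "sensitive-selective", "none")),
                    mean_sensitive = m1, mean_resistant = m2,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
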