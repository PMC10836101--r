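# Gaussian naive Bayes with fixed equal priors, written from scratch:
# the study's sole learning machine. Per class and feature, a Gaussian is
# fit by maximum likelihood (unbiased variance); the posterior assumes
# class-conditional independence, so every variable contributes linearly
# and equally in log-likelihood terms. Computation is in log space with a
# variance floor for numerical safety on near-constant (e.g. clipped)
# features.

#' Fit a Gaussian naive Bayes model
#'
#' @param table a feature table (tibble with a `group` column).
#' @param features character vector of feature column names.
#' @param priors named numeric prior probabilities per class; default fixed
#'   0.5 / 0.5 regardless of class imbalance.
#' @param positive the class whose posterior is returned as the ROC score
#'   (default `"FXS"`).
#' @param var_floor absolute variance floor; the applied floor is
#'   `max(var_floor, 1e-9 * pooled feature variance)`.
#' @return object of class `nbc_model`: per-class, per-feature means and
#'   variances plus the priors.
#' @export
nbc_fit <- function(table, features, priors = NULL, positive = "FXS",
                    var_floor = 1e-12) {
  classes <- sort(unique(as.character(table$group)))
  if (length(classes) != 2) stop_fx("need exactly 2 classes, got %d", length(classes))
  if (!positive %in% classes) stop_fx("positive class '%s' absent from table", positive)
  missing_f <- setdiff(features, names(table))
  if (length(missing_f) > 0)
    stop_fx("feature(s) absent from table: %s", paste(missing_f, collapse = ", "))
  X <- as.matrix(table[, features, drop = FALSE])
  if (any(!is.finite(X))) stop_fx("missing or non-finite feature values; no imputation")

  if (is.null(priors)) priors <- stats::setNames(c(0.5, 0.5), classes)
  priors <- priors[classes]
  if (abs(sum(priors) - 1) > 1e-9) stop_fx("priors must sum to 1")

  mu <- s2 <- matrix(0, 2, length(features),
                     dimnames = list(classes, features))
  for (cl in classes) {
    Xc <- X[table$group == cl, , drop = FALSE]
    if (nrow(Xc) < 2) stop_fx("class '%s' has fewer than 2 samples", cl)
    mu[cl, ] <- colMeans(Xc)
    s2[cl, ] <- apply(Xc, 2, stats::var)
  }
  pooled <- apply(X, 2, stats::var)
  floor_v <- pmax(var_floor, 1e-9 * pooled)
  if (any(s2 < floor_v))
    warning(sprintf("variance floored for %d class-feature cell(s)",
                    sum(s2 < floor_v)), call. = FALSE)
  s2 <- pmax(s2, rep(floor_v, each = 2))
  structure(list(classes = classes, positive = positive, priors = priors,
                 mean = mu, var = s2, features = features),
            class = "nbc_model")
}

#' Posterior probability of the positive class
#'
#' `p(c | x) = pi_c prod_f N(x_f; mu_cf, var_cf)` normalized over classes,
#' computed via log-sum-exp.
#'
#' @param model an [nbc_fit()] model.
#' @param x numeric matrix (rows = observations, columns matching
#'   `model$features`), or a feature table containing those columns.
#' @return numeric vector in (0, 1): posterior of the positive class.
#' @export
nbc_posterior <- function(model, x) {
  if (is.data.frame(x)) x <- as.matrix(x[, model$features, drop = FALSE])
  if (is.null(dim(x))) x <- matrix(x, nrow = 1, dimnames = list(NULL, model$features))
  if (any(!is.finite(x))) stop_fx("non-finite feature values")
  ll <- matrix(0, nrow(x), 2, dimnames = list(NULL, model$classes))
  for (cl in model$classes) {
    z2 <- sweep(sweep(x, 2, model$mean[cl, ], `-`)^2, 2, model$var[cl, ], `/`)
    ll[, cl] <- log(model$priors[cl]) -
      0.5 * rowSums(sweep(z2, 2, log(2 * pi * model$var[cl, ]), `+`))
  }
  m <- pmax(ll[, 1], ll[, 2])
  lse <- m + log(exp(ll[, 1] - m) + exp(ll[, 2] - m))
  exp(ll[, model$positive] - lse)
}

#' Predicted class labels
#'
#' Argmax of the posterior; an exact tie (posterior 0.5) goes to the
#' non-positive (control) class by documented convention.
#'
#' @inheritParams nbc_posterior
#' @return character vector of class labels.
#' @export
nbc_predict <- function(model, x) {
  p <- nbc_posterior(model, x)
  negative <- setdiff(model$classes, model$positive)
  ifelse(p > 0.5, model$positive, negative)
}

#' Serialize / restore a model as human-readable text
#'
#' Key-value header (classes, priors, positive class) followed by a
#' per-class, per-feature table of means and variances, for audit.
#'
#' @param model an `nbc_model`.
#' @param path file path.
#' @return `read_nbc` returns the model; `write_nbc` returns `path`
#'   invisibly.
#' @export
write_nbc <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("classes: ", paste(model$classes, collapse = ",")),
    paste0("positive: ", model$positive),
    paste0("priors: ", paste(formatC(model$priors, format = "g", digits = 17),
                             collapse = ","))), con)
  writeLines("class\tfeature\tmean\tvariance", con)
  for (cl in model$classes) for (f in model$features)
    writeLines(paste(cl, f,
                     formatC(model$mean[cl, f], format = "g", digits = 17),
                     formatC(model$var[cl, f], format = "g", digits = 17),
                     sep = "\t"), con)
  invisible(path)
}

#' @rdname write_nbc
#' @export
read_nbc <- function(path) {
  lines <- readLines(path)
  classes <- strsplit(sub("classes: ", "", lines[1]), ",")[[1]]
  positive <- sub("positive: ", "", lines[2])
  priors <- stats::setNames(as.numeric(strsplit(sub("priors: ", "", lines[3]), ",")[[1]]),
                            classes)
  body <- utils::read.delim(text = lines[-(1:3)], check.names = FALSE)
  features <- unique(body$feature)
  mu <- s2 <- matrix(0, 2, length(features), dimnames = list(classes, features))
  for (i in seq_len(nrow(body))) {
    mu[body$class[i], body$feature[i]] <- body$mean[i]
    s2[body$class[i], body$feature[i]] <- body$variance[i]
  }
  structure(list(classes = classes, positive = positive, priors = priors,
                 mean = mu, var = s2, features = features),
            class = "nbc_model")
}
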