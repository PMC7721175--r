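# Per-technology logistic-regression SV filters and the combined model.
# Features: SV type (one-hot), normalized junction reads and spanning pairs,
# SV size, normalized local coverage, and (linked-read model only) normalized
# GEM count.  Numeric features are log1p-transformed before fitting; the fit
# is unpenalized maximum likelihood with a weak-ridge fallback when the tiny
# synthetic training sets separate perfectly.

NUMERIC_FEATURES <- c("jr_norm", "sp_norm", "size", "local_coverage_norm",
                      "gem_norm")
RIDGE_LAMBDA <- 1e-3   # fallback penalty per observation, documented constant

#' Assemble classifier feature vectors
#'
#' One vector per SV of the target technology.  SR vectors omit `gem_norm`;
#' `UNK`-type SVs are excluded (the filter is trained on the four resolved
#' types only); translocation size is encoded 0.
#'
#' @param svs SV (merged) call table with `id`, `sv_type`, `size`.
#' @param requant requantification table ([requantify_svs]) keyed by `sv_id`.
#' @param annotation annotation table ([annotate_svs]) keyed by `sv_id` with
#'   `local_coverage_norm`.
#' @param gem GEM table ([gem_quantify_svs]); required iff
#'   `technology = "LR"`.
#' @param technology `"SR"` or `"LR"`.
#' @param labels optional data.frame `sv_id`, `label`
#'   (`POSITIVE`/`NEGATIVE`).
#' @return data.frame of feature vectors: `sv_id`, `sv_type`, numeric
#'   features, optional `label`.
#' @export
build_features <- function(svs, requant, annotation, gem = NULL,
                           technology = c("SR", "LR"), labels = NULL) {
  technology <- match.arg(technology)
  svs <- as.data.frame(svs)
  svs <- svs[svs$sv_type %in% c("DEL", "DUP", "INV", "TRA"), , drop = FALSE]
  take <- function(tab, col, what) {
    i <- match(svs$id, tab$sv_id)
    if (anyNA(i)) {
      stop("missing ", what, " for SV(s): ",
           paste(svs$id[is.na(i)], collapse = ", "))
    }
    tab[[col]][i]
  }
  fv <- data.frame(
    sv_id = svs$id,
    sv_type = factor(svs$sv_type, levels = c("DEL", "DUP", "INV", "TRA")),
    jr_norm = take(requant, "jr_norm", "requantification"),
    sp_norm = take(requant, "sp_norm", "requantification"),
    size = ifelse(svs$sv_type == "TRA", 0, svs$size),
    local_coverage_norm = take(annotation, "local_coverage_norm", "annotation"),
    stringsAsFactors = FALSE)
  if (technology == "LR") {
    if (is.null(gem)) stop("LR features require a GEM table")
    fv$gem_norm <- take(gem, "gem_norm", "GEM quantification")
  }
  if (!is.null(labels)) {
    i <- match(fv$sv_id, labels$sv_id)
    if (anyNA(i)) stop("missing label for SV(s): ",
                       paste(fv$sv_id[is.na(i)], collapse = ", "))
    fv$label <- labels$label[i]
  }
  num <- intersect(NUMERIC_FEATURES, names(fv))
  bad <- !vapply(fv[num], function(x) all(is.finite(x) & x >= 0), logical(1))
  if (any(bad)) stop("non-finite or negative feature(s): ",
                     paste(num[bad], collapse = ", "))
  rownames(fv) <- NULL
  fv
}

feature_matrix <- function(features) {
  num <- intersect(NUMERIC_FEATURES, names(features))
  X <- cbind(`(Intercept)` = 1,
             sv_typeDUP = as.numeric(features$sv_type == "DUP"),
             sv_typeINV = as.numeric(features$sv_type == "INV"),
             sv_typeTRA = as.numeric(features$sv_type == "TRA"))
  for (f in num) X <- cbind(X, log1p(features[[f]]))
  colnames(X) <- c("(Intercept)", "sv_typeDUP", "sv_typeINV", "sv_typeTRA", num)
  X
}

# Ridge-penalized logistic IRLS (intercept unpenalized); used when plain ML
# separates.  Returns coefficients and penalized-information standard errors.
ridge_logistic <- function(X, y, lambda) {
  p <- ncol(X)
  pen <- diag(rep(lambda * nrow(X), p)); pen[1, 1] <- 0
  beta <- rep(0, p)
  for (it in 1:100) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    H <- crossprod(X, X * w) + pen
    beta_new <- drop(solve(H, crossprod(X, w * z)))
    if (max(abs(beta_new - beta)) < 1e-10) { beta <- beta_new; break }
    beta <- beta_new
  }
  eta <- drop(X %*% beta)
  w <- pmax(stats::plogis(eta) * (1 - stats::plogis(eta)), 1e-10)
  V <- solve(crossprod(X, X * w) + pen)
  list(coef = stats::setNames(beta, colnames(X)),
       se = stats::setNames(sqrt(diag(V)), colnames(X)))
}

fit_logistic <- function(X, y) {
  df <- as.data.frame(X[, -1, drop = FALSE])
  df$.y <- y
  fit <- suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial()))
  sep <- !fit$converged || any(abs(stats::coef(fit)) > 15, na.rm = TRUE) ||
    anyNA(stats::coef(fit))
  if (sep) {
    r <- ridge_logistic(X, y, RIDGE_LAMBDA)
    list(coef = r$coef, se = r$se, ridge = TRUE,
         loglik = sum(y * log(stats::plogis(drop(X %*% r$coef))) +
                        (1 - y) * log(1 - stats::plogis(drop(X %*% r$coef)))))
  } else {
    cf <- stats::coef(fit)
    names(cf) <- colnames(X)
    se <- sqrt(diag(stats::vcov(fit)))
    names(se) <- colnames(X)
    list(coef = cf, se = se, ridge = FALSE, loglik = as.numeric(stats::logLik(fit)))
  }
}

#' Train a per-technology logistic SV filter
#'
#' The labelled set is split 70:30 (stratified by label) into training and
#' test data; the model is fit by unpenalized maximum likelihood on the
#' training split (no class re-weighting — the filter is trained on
#' unbalanced data as-is), and test performance (sensitivity, FDR, accuracy
#' at the 60% threshold) is reported as the mean over 10 bootstrap resamples
#' of the test split.  Deterministic for a fixed seed.
#'
#' @param features labelled feature table from [build_features] (>= 20 rows,
#'   both classes present).
#' @param technology `"SR"` or `"LR"`.
#' @param seed integer seed for the split and the resamples.
#' @param split training fraction (default 0.7).
#' @param resamples bootstrap resamples of the test set (default 10).
#' @param threshold posterior-probability cutoff (default 0.6, strict).
#' @return an object of class `sv_logit_model`.
#' @export
train_model <- function(features, technology = c("SR", "LR"), seed = 1L,
                        split = 0.7, resamples = 10, threshold = 0.6) {
  technology <- match.arg(technology)
  if (is.null(features$label)) stop("features must be labelled")
  if (nrow(features) < 20) stop("need >= 20 labelled examples")
  y <- as.integer(features$label == "POSITIVE")
  if (length(unique(y)) < 2) stop("both classes must be present")
  X <- feature_matrix(features)
  withr::with_seed(as.integer(seed), {
    idx_pos <- which(y == 1); idx_neg <- which(y == 0)
    tr <- c(sample(idx_pos, floor(split * length(idx_pos))),
            sample(idx_neg, floor(split * length(idx_neg))))
    te <- setdiff(seq_along(y), tr)
    fit <- fit_logistic(X[tr, , drop = FALSE], y[tr])
    prob_te <- stats::plogis(drop(X[te, , drop = FALSE] %*% fit$coef))
    mets <- vapply(seq_len(resamples), function(b) {
      bi <- sample(seq_along(te), replace = TRUE)
      pred <- prob_te[bi] > threshold
      truth <- y[te][bi] == 1
      tp <- sum(pred & truth); fp <- sum(pred & !truth)
      fn <- sum(!pred & truth); tn <- sum(!pred & !truth)
      c(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
        fdr = if (tp + fp > 0) fp / (tp + fp) else NA_real_,
        accuracy = (tp + tn) / length(bi))
    }, numeric(3))
  })
  structure(list(
    technology = technology, coefficients = fit$coef, se = fit$se,
    ridge = fit$ridge, loglik = fit$loglik, threshold = threshold,
    feature_names = colnames(X),
    test_metrics = rowMeans(mets, na.rm = TRUE),
    train_meta = list(split = split, resamples = resamples, seed = seed,
                      n_train = length(tr), n_test = length(te),
                      n_pos = sum(y), n_neg = sum(y == 0))),
    class = "sv_logit_model")
}

#' @export
print.sv_logit_model <- function(x, ...) {
  cat("Logistic SV filter (", x$technology, "), threshold >",
      x$threshold, if (x$ridge) " [ridge fallback]", "\n", sep = "")
  print(round(x$coefficients, 4))
  cat("test metrics (mean over", x$train_meta$resamples, "bootstrap resamples):\n")
  print(round(x$test_metrics, 4))
  invisible(x)
}

#' Predict with a trained SV filter
#'
#' @param object an `sv_logit_model`.
#' @param newdata feature table from [build_features] with the schema the
#'   model was trained on.
#' @param type `"class"` (default) for `POSITIVE`/`NEGATIVE` at the model's
#'   strict threshold (probability must *exceed* 60%), or `"prob"` for the
#'   fitted probability.
#' @param ... unused.
#' @return character vector of classes or numeric probabilities, named by
#'   `sv_id`.
#' @export
predict.sv_logit_model <- function(object, newdata, type = c("class", "prob"),
                                   ...) {
  type <- match.arg(type)
  X <- feature_matrix(newdata)
  if (!identical(colnames(X), object$feature_names)) {
    stop("feature schema mismatch: model expects ",
         paste(object$feature_names, collapse = ", "))
  }
  p <- stats::plogis(drop(X %*% object$coefficients))
  names(p) <- newdata$sv_id
  if (type == "prob") return(p)
  ifelse(p > object$threshold, "POSITIVE", "NEGATIVE")
}

#' Combined-model decision
#'
#' The combined filter keeps an SV when it is predicted by both technologies
#' (COMMON), or accepted by the short-read model, or accepted by the
#' linked-read model (union rule).
#'
#' @param category `COMMON`, `ONLY_SR` or `ONLY_LR` (vectorized).
#' @param sr_pred,lr_pred per-SV model predictions (`POSITIVE`/`NEGATIVE`,
#'   `NA` where not applicable).
#' @return character vector `POSITIVE`/`NEGATIVE`.
#' @export
combined_predict <- function(category, sr_pred = NA, lr_pred = NA) {
  n <- max(length(category), length(sr_pred), length(lr_pred))
  category <- rep_len(category, n)
  sr_pred <- rep_len(sr_pred, n); lr_pred <- rep_len(lr_pred, n)
  pos <- category == "COMMON" |
    (!is.na(sr_pred) & sr_pred == "POSITIVE") |
    (!is.na(lr_pred) & lr_pred == "POSITIVE")
  ifelse(pos, "POSITIVE", "NEGATIVE")
}

#' Feature importance from |t| statistics
#'
#' `importance_j = |coef_j / SE_j|`, linearly rescaled so the largest equals
#' 100 (the intercept is not a feature and is excluded).
#'
#' @param model an `sv_logit_model`.
#' @return named numeric vector of scaled importances.
#' @export
feature_importance <- function(model) {
  cf <- model$coefficients[-1]; se <- model$se[-1]
  if (any(!is.finite(se)) || any(se == 0)) stop("singular fit: no standard errors")
  t_abs <- abs(cf / se)
  if (max(t_abs) == 0) return(stats::setNames(rep(0, length(t_abs)), names(t_abs)))
  100 * t_abs / max(t_abs)
}

mcfadden_r2 <- function(X, y, cols) {
  Xs <- X[, c(1L, cols), drop = FALSE]
  f <- fit_logistic(Xs, y)
  if (!is.finite(f$loglik)) return(NA_real_)
  p0 <- mean(y)
  ll0 <- sum(y * log(p0) + (1 - y) * log(1 - p0))
  1 - f$loglik / ll0
}

#' Dominance analysis of the SV filter features
#'
#' General-dominance weights: for each feature, the incremental McFadden
#' pseudo-R-squared it contributes when added to a subset model, averaged
#' over subsets of each size and then over sizes.  The SV-type one-hot block
#' is treated as a single grouped feature.  Weights sum to the full model's
#' McFadden R-squared.  Subsets whose fit does not converge are excluded with
#' a warning and the averages re-normalized.
#'
#' @param features labelled feature table from [build_features].
#' @return named numeric vector of general-dominance weights (named by
#'   feature group), with the full-model R-squared as attribute `full_r2`.
#' @export
dominance_analysis <- function(features) {
  if (is.null(features$label)) stop("features must be labelled")
  y <- as.integer(features$label == "POSITIVE")
  X <- feature_matrix(features)
  groups <- list(sv_type = 2:4)
  num <- intersect(NUMERIC_FEATURES, colnames(X))
  for (f in num) groups[[f]] <- match(f, colnames(X))
  ## drop the type group if only one type present (constant columns)
  if (all(X[, 2:4] == 0) || length(unique(features$sv_type)) < 2) {
    groups$sv_type <- NULL
  }
  p <- length(groups)
  if (p > 10) stop("dominance analysis supports at most 10 features")
  r2 <- new.env()
  key <- function(s) paste0("k", paste(sort(s), collapse = ","))
  get_r2 <- function(s) {
    k <- key(s)
    if (!is.null(r2[[k]])) return(r2[[k]])
    v <- if (length(s) == 0) 0 else
      mcfadden_r2(X, y, unlist(groups[s], use.names = FALSE))
    r2[[k]] <- v
    v
  }
  gnames <- names(groups)
  weights <- stats::setNames(numeric(p), gnames)
  dropped <- FALSE
  for (j in seq_len(p)) {
    per_size <- numeric(p)
    for (k in 0:(p - 1)) {
      others <- setdiff(seq_len(p), j)
      subs <- if (k == 0) list(integer(0))
        else if (length(others) == 1) list(others)   # combn(scalar, k) trap
        else utils::combn(others, k, simplify = FALSE)
      inc <- vapply(subs, function(s) {
        a <- get_r2(c(s, j)); b <- get_r2(s)
        a - b
      }, numeric(1))
      if (anyNA(inc)) { dropped <- TRUE; inc <- inc[!is.na(inc)] }
      per_size[k + 1] <- mean(inc)
    }
    weights[j] <- mean(per_size)
  }
  if (dropped) {
    warning("non-convergent subset fit(s) excluded; weights re-normalized")
    full <- get_r2(seq_len(p))
    weights <- weights * full / sum(weights)
  }
  attr(weights, "full_r2") <- get_r2(seq_len(p))
  weights
}

#' Serialize / restore a trained model as JSON
#'
#' @param model an `sv_logit_model`.
#' @param path JSON path.
#' @return `path` invisibly; `read_model` returns the model.
#' @export
write_model <- function(model, path) {
  jsonlite::write_json(list(
    technology = model$technology,
    coefficients = as.list(model$coefficients),
    se = as.list(model$se), ridge = model$ridge,
    threshold = model$threshold, feature_names = model$feature_names,
    transform = "log1p on numeric features",
    train_meta = model$train_meta,
    test_metrics = as.list(model$test_metrics)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    technology = j$technology,
    coefficients = unlist(j$coefficients), se = unlist(j$se),
    ridge = j$ridge, threshold = j$threshold,
    feature_names = j$feature_names, loglik = NA_real_,
    test_metrics = unlist(j$test_metrics), train_meta = j$train_meta),
    class = "sv_logit_model")
}
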