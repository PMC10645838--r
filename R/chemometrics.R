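#' Pareto scaling
#'
#' Centers each variable and divides it by the square root of its sample
#' standard deviation — the usual compromise for chromatographic intensity
#' tables, shrinking the dominance of intense bands while keeping unit
#' structure (each scaled column's variance equals the original column's
#' standard deviation). Zero-variance columns carry no information and are
#' dropped with a warning.
#'
#' @param x numeric matrix or data.frame, samples in rows.
#' @return scaled matrix with attributes `center`, `scale` and `dropped`
#'   (names of removed zero-variance columns).
#' @export
pareto_scale <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("Pareto scaling needs at least two samples")
  sds <- apply(x, 2, stats::sd)
  zero <- sds < .Machine$double.eps^0.5
  if (all(zero)) stop("all columns have zero variance")
  if (any(zero)) {
    warning("dropping zero-variance column(s): ",
            paste(colnames(x)[zero], collapse = ", "))
    x <- x[, !zero, drop = FALSE]
    sds <- sds[!zero]
  }
  ctr <- colMeans(x)
  out <- sweep(sweep(x, 2, ctr), 2, sqrt(sds), "/")
  attr(out, "center") <- ctr
  attr(out, "scale") <- sqrt(sds)
  attr(out, "dropped") <- names(zero)[zero]
  out
}

#' Principal component analysis of a scaled matrix
#'
#' Thin wrapper around [stats::prcomp()] on an already-scaled matrix (no
#' further centering), reporting per-component and cumulative explained
#' variance shares.
#'
#' @param x scaled numeric matrix (e.g. from [pareto_scale()]).
#' @param n_components number of components to keep (at most the matrix
#'   rank).
#' @return object of class `pca_model`: `scores`, `loadings` (orthonormal
#'   columns), `r2x`, `r2x_cum`.
#' @export
fit_pca <- function(x, n_components = 2) {
  x <- as.matrix(x)
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2
  rank <- sum(ev > max(ev) * 1e-12)
  if (n_components > rank) {
    stop("n_components (", n_components, ") exceeds the matrix rank (",
         rank, ")")
  }
  keep <- seq_len(n_components)
  r2x <- ev[keep] / sum(ev)
  structure(list(scores = pc$x[, keep, drop = FALSE],
                 loadings = pc$rotation[, keep, drop = FALSE],
                 r2x = r2x, r2x_cum = cumsum(r2x)),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat("<pca_model>", ncol(x$scores), "components; R2X:",
      paste(sprintf("%.3f", x$r2x), collapse = " "),
      sprintf("(cum %.3f)\n", x$r2x_cum[length(x$r2x_cum)]))
  invisible(x)
}

# Single-response O-PLS core (NIPALS): removes n_orth components of X
# variation orthogonal to y, then fits one predictive component on the
# filtered matrix. y is the centered +/-1 class code.
opls_core <- function(X, y, n_orth) {
  p <- ncol(X)
  Wo <- Po <- matrix(0, p, 0)
  Xf <- X
  for (k in seq_len(n_orth)) {
    w <- drop(crossprod(Xf, y))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    tt <- drop(Xf %*% w)
    pp <- drop(crossprod(Xf, tt)) / sum(tt^2)
    wo <- pp - sum(w * pp) * w
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-12) break  # no orthogonal variation left
    wo <- wo / nwo
    to <- drop(Xf %*% wo)
    po <- drop(crossprod(Xf, to)) / sum(to^2)
    Xf <- Xf - outer(to, po)
    Wo <- cbind(Wo, wo)
    Po <- cbind(Po, po)
  }
  w <- drop(crossprod(Xf, y))
  nw <- sqrt(sum(w^2))
  if (nw < 1e-12) {
    w <- rep(0, p); tt <- rep(0, nrow(X)); q <- 0
  } else {
    w <- w / nw
    tt <- drop(Xf %*% w)
    q <- sum(y * tt) / sum(tt^2)
  }
  list(w = w, q = q, t = tt, Wo = Wo, Po = Po, Xf = Xf)
}

opls_predict_scores <- function(fit, Xnew) {
  Xn <- as.matrix(Xnew)
  ko <- ncol(fit$Wo)
  for (k in seq_len(ko)) {
    to <- drop(Xn %*% fit$Wo[, k])
    Xn <- Xn - outer(to, fit$Po[, k])
  }
  t_pred <- drop(Xn %*% fit$w)
  list(t = t_pred, y_hat = t_pred * fit$q)
}

# Stratified fold assignment: within each class, samples are shuffled under
# the seed and dealt round-robin, so folds are reproducible bit-exactly.
make_cv_folds <- function(labels, k, seed) {
  with_seed(seed, {
    fold <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- if (length(idx) > 1) sample(idx) else idx
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

label_code <- function(labels) {
  f <- factor(labels)
  if (nlevels(f) != 2) {
    stop("OPLS-DA needs exactly two classes; found ", nlevels(f))
  }
  y <- ifelse(as.integer(f) == 2, 1, -1)
  list(y = y - mean(y), levels = levels(f))
}

opls_q2 <- function(X, y, n_orth, fold) {
  press <- 0
  for (f in unique(fold)) {
    test <- fold == f
    if (all(test) || !any(test)) next
    fit <- opls_core(X[!test, , drop = FALSE], y[!test], n_orth)
    pr <- opls_predict_scores(fit, X[test, , drop = FALSE])
    press <- press + sum((y[test] - pr$y_hat)^2)
  }
  ssy <- sum(y^2)
  list(q2 = 1 - press / ssy, press = press, ssy = ssy)
}

#' Two-class OPLS-DA on a scaled band table
#'
#' Fits an orthogonal-projections-to-latent-structures discriminant model
#' with one predictive component after removal of `n_orth` components of
#' variation orthogonal to the class contrast. Predictive ability Q2 comes
#' from stratified k-fold cross-validation with a seeded, reproducible fold
#' assignment; S-plot coordinates are the covariance and correlation of every
#' scaled variable with the predictive score.
#'
#' @param x scaled numeric matrix (samples in rows), e.g. from
#'   [pareto_scale()].
#' @param labels two-class factor or character vector, one entry per row.
#' @param n_orth number of orthogonal components to remove (default 1).
#' @param cv_folds cross-validation folds (default 7).
#' @param seed seed for the fold assignment (default 1).
#' @param q2_min,p_max validity thresholds recorded on the model and used for
#'   the pass/fail flag in reports (defaults 0.40 and 0.05).
#' @return object of class `opls_model`: predictive scores `t` and weights,
#'   orthogonal scores/loadings, `r2y`, `q2`, `s_plot` (per-variable
#'   covariance/correlation), class levels and the CV bookkeeping needed by
#'   [permutation_test()] and [cv_anova()].
#' @export
fit_oplsda <- function(x, labels, n_orth = 1, cv_folds = 7, seed = 1,
                       q2_min = 0.40, p_max = 0.05) {
  X <- as.matrix(x)
  code <- label_code(labels)
  tab <- table(labels)
  if (any(tab < 3)) {
    warning("class(es) with fewer than 3 samples: ",
            paste(names(tab)[tab < 3], collapse = ", "),
            "; cross-validation will be unstable")
  }
  y <- code$y
  fit <- opls_core(X, y, n_orth)
  y_hat <- fit$t * fit$q
  ssy <- sum(y^2)
  r2y <- 1 - sum((y - y_hat)^2) / ssy
  fold <- make_cv_folds(labels, min(cv_folds, nrow(X)), seed)
  cv <- opls_q2(X, y, n_orth, fold)
  t_sd <- stats::sd(fit$t)
  s_cov <- drop(crossprod(X, fit$t)) / (nrow(X) - 1)
  s_cor <- if (t_sd > 0) {
    s_cov / (apply(X, 2, stats::sd) * t_sd)
  } else rep(NA_real_, ncol(X))
  structure(list(
    t = fit$t, w = fit$w, q = fit$q,
    t_orth = if (ncol(fit$Wo)) X %*% fit$Wo else matrix(0, nrow(X), 0),
    w_orth = fit$Wo, p_orth = fit$Po,
    n_orth = n_orth, cv_folds = cv_folds, seed = seed, fold = fold,
    r2y = r2y, q2 = cv$q2, press = cv$press, ssy = ssy,
    s_plot = data.frame(variable = colnames(X) %||%
                          paste0("V", seq_len(ncol(X))),
                        covariance = s_cov, correlation = s_cor,
                        row.names = NULL),
    levels = code$levels, n = nrow(X),
    q2_min = q2_min, p_max = p_max
  ), class = "opls_model")
}

#' @export
print.opls_model <- function(x, ...) {
  cat(sprintf("<opls_model> 1 predictive + %d orthogonal component(s), n = %d\n",
              x$n_orth, x$n))
  cat(sprintf("  classes: %s (-) vs %s (+)\n", x$levels[1], x$levels[2]))
  cat(sprintf("  R2Y = %.3f, Q2 = %.3f (%d-fold CV)%s\n", x$r2y, x$q2,
              x$cv_folds,
              if (x$q2 >= x$q2_min) "  [Q2 criterion met]" else ""))
  invisible(x)
}

#' Permutation test of an OPLS-DA model
#'
#' Class labels are permuted `n_perm` times; for each permutation the model
#' is refitted and cross-validated exactly as the original, and the p-value
#' is `(1 + #\{Q2_perm >= Q2_observed\}) / (n_perm + 1)` — the smallest
#' attainable p at 100 permutations is 1/101.
#'
#' @param model a fitted [fit_oplsda()] model.
#' @param x the scaled matrix the model was fitted on.
#' @param labels the original class labels.
#' @param n_perm number of permutations (default 100).
#' @param seed seed for the permutation stream (default 1); results are
#'   bit-reproducible under a fixed seed.
#' @return list with `perm_p`, `q2_observed` and the vector `q2_perm`.
#' @export
permutation_test <- function(model, x, labels, n_perm = 100, seed = 1) {
  if (n_perm < 1) stop("n_perm must be at least 1")
  X <- as.matrix(x)
  q2_perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    lab_p <- sample(labels)
    code <- label_code(lab_p)
    fold <- make_cv_folds(lab_p, min(model$cv_folds, nrow(X)), model$seed)
    opls_q2(X, code$y, model$n_orth, fold)$q2
  }, numeric(1)))
  list(perm_p = (1 + sum(q2_perm >= model$q2)) / (n_perm + 1),
       q2_observed = model$q2, q2_perm = q2_perm)
}

#' CV-ANOVA significance of an OPLS-DA model
#'
#' F-test comparing the cross-validated predictive residuals against the
#' total class variance, in the cross-validated-residual ANOVA formulation:
#' F = ((SSY - PRESS)/K) / (PRESS/(N - K - 1)) with K = 1 + n_orth model
#' components and N samples. Models that predict no better than the mean
#' (PRESS >= SSY) get p = 1.
#'
#' @param model a fitted [fit_oplsda()] model.
#' @return p-value in `[0, 1]`.
#' @export
cv_anova <- function(model) {
  K <- 1 + model$n_orth
  df2 <- model$n - K - 1
  if (df2 <= 0) stop("too few samples for CV-ANOVA with ", K, " components")
  if (model$ssy < .Machine$double.eps) {
    warning("degenerate response (zero class variance); p = 1")
    return(1)
  }
  if (model$press >= model$ssy) return(1)
  f_stat <- ((model$ssy - model$press) / K) / (model$press / df2)
  stats::pf(f_stat, K, df2, lower.tail = FALSE)
}

#' Select discriminant bands from the S-plot
#'
#' Variables whose absolute covariance and absolute correlation with the
#' predictive score both clear their thresholds, signed by the class they are
#' enriched in.
#'
#' @param model a fitted [fit_oplsda()] model.
#' @param cov_thresh minimum `|covariance|` (default 0: keep all).
#' @param corr_thresh minimum `|correlation|` (default 0.8).
#' @return data.frame `variable`, `rf` (parsed from `rf_`-style names, else
#'   `NA`), `covariance`, `correlation`, `enriched_in` (class level).
#' @export
select_discriminant_bands <- function(model, cov_thresh = 0,
                                      corr_thresh = 0.8) {
  sp <- model$s_plot
  keep <- abs(sp$covariance) >= cov_thresh &
    !is.na(sp$correlation) & abs(sp$correlation) >= corr_thresh
  out <- sp[keep, , drop = FALSE]
  out$rf <- suppressWarnings(as.numeric(sub("^rf_", "", out$variable)))
  out$enriched_in <- ifelse(out$covariance > 0, model$levels[2],
                            model$levels[1])
  out[order(-abs(out$covariance)),
      c("variable", "rf", "covariance", "correlation", "enriched_in")]
}

# Anchor calibration: known band identities on the plate. Migration distance
# falls with polymer size: fructose DP-1 at Rf 0.57, sucrose DP-2 at 0.51,
# the DP-3 kestose band at 0.40, and DP-11 at 0.09, the last countable band.
RF_ANCHORS <- data.frame(rf = c(0.57, 0.51, 0.40, 0.09), dp = c(1, 2, 3, 11))

#' Calibrate Rf values to degree of polymerization
#'
#' Monotone-decreasing piecewise-linear interpolation through the plate's
#' anchor bands (DP-1 at Rf 0.57, DP-2 at 0.51, DP-3 at 0.40, DP-11 at 0.09),
#' rounded to the nearest integer DP. Rf values above the fructose anchor
#' clamp to DP 1; values below 0.09 lie in the application-point zone where
#' bands are no longer countable and are returned as `NA` with label
#' `">11 (application point)"`.
#'
#' @param rf numeric vector of retention factors in (0, 1).
#' @return integer vector of DPs (`NA` for the application point), with a
#'   `label` attribute giving the printable form of each entry.
#' @examples
#' rf_to_dp(c(0.57, 0.51, 0.40, 0.09, 0.05))
#' @export
rf_to_dp <- function(rf) {
  if (any(rf <= 0 | rf >= 1)) {
    stop("Rf values must lie strictly within (0, 1)")
  }
  dp_num <- stats::approx(x = RF_ANCHORS$rf, y = RF_ANCHORS$dp, xout = rf,
                          rule = 2)$y
  out <- as.integer(round_half_up(dp_num))
  below <- rf < min(RF_ANCHORS$rf)
  out[below] <- NA_integer_
  labels <- ifelse(below, ">11 (application point)", as.character(out))
  attr(out, "label") <- labels
  out
}
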