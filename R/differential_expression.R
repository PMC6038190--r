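# Self-contained negative-binomial two-group Wald differential expression:
# median-of-ratios size factors, method-of-moments dispersions shrunk toward
# a 1/mu trend, per-feature NB GLM fits with covariates, BH adjustment and
# the |log2FC| >= 0.6 / padj < 0.1 deregulation call.

#' Median-of-ratios size factors
#'
#' Per-sample normalisation constants: for each feature expressed in every
#' sample, the ratio of its count to its across-sample geometric mean is
#' formed; a sample's size factor is the median of these ratios. Scaling a
#' sample's column by c scales its factor by c exactly.
#'
#' @param counts Non-negative count matrix, features x samples.
#' @return Positive numeric vector of per-sample size factors.
#' @export
size_factors <- function(counts) {
  stopifnot(is.matrix(counts), all(counts >= 0))
  logc <- log(counts)
  loggeo <- rowMeans(logc)
  use <- is.finite(loggeo)
  if (!any(use)) {
    stop("no feature has nonzero counts in all samples; cannot normalise")
  }
  sf <- apply(logc[use, , drop = FALSE], 2L, function(lc) {
    exp(stats::median(lc - loggeo[use]))
  })
  stats::setNames(sf, colnames(counts))
}

#' Specify a two-group contrast with additive covariates
#'
#' @param contrast Name of the sample-sheet column holding the two-level
#'   factor to test (e.g. `group` for CTRL vs PD, or `cell_type` for a
#'   differentiation comparison). The coefficient reported is second level
#'   vs first, levels taken in order of appearance in the sheet.
#' @param covariates Character vector of additional sample-sheet columns
#'   entered additively (e.g. `sex`, `passage`, `neuronal_content`).
#'   Categorical covariates are dummy-coded against their first level in
#'   sheet order.
#' @return A `design_spec` list.
#' @export
design_spec <- function(contrast, covariates = character(0)) {
  stopifnot(is.character(contrast), length(contrast) == 1L)
  structure(list(contrast = contrast, covariates = covariates),
            class = "design_spec")
}

# Build the model matrix; the contrast coefficient is the last column.
build_design_matrix <- function(sheet, design) {
  cols <- c(design$covariates, design$contrast)
  miss <- setdiff(cols, names(sheet))
  if (length(miss) > 0L) {
    stop("sample sheet lacks column(s): ", paste(miss, collapse = ", "))
  }
  dat <- sheet[, cols, drop = FALSE]
  for (v in cols) {
    if (is.factor(dat[[v]])) {
      dat[[v]] <- droplevels(dat[[v]])
    } else if (is.character(dat[[v]]) || is.logical(dat[[v]])) {
      dat[[v]] <- factor(dat[[v]], levels = unique(as.character(dat[[v]])))
    }
  }
  g <- dat[[design$contrast]]
  if (!is.factor(g) || nlevels(droplevels(g)) != 2L) {
    stop("contrast '", design$contrast, "' must have exactly 2 observed levels")
  }
  if (any(table(g) < 2L)) stop("need >= 2 samples per contrast level")
  fml <- stats::as.formula(paste("~", paste(cols, collapse = " + ")))
  X <- stats::model.matrix(fml, data = dat)
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  # move the contrast column last
  ccol <- grep(paste0("^", design$contrast), colnames(X))
  X <- X[, c(setdiff(seq_len(ncol(X)), ccol), ccol), drop = FALSE]
  attr(X, "contrast_levels") <- levels(droplevels(g))
  X
}

#' Per-feature NB dispersion by moments with trend shrinkage
#'
#' For each feature, a method-of-moments dispersion is computed from
#' size-factor-normalised counts pooled within the contrast levels (so
#' planted group differences do not inflate the estimate):
#' `alpha = (var - mean) / mean^2`, combined across levels with df weights.
#' A mean-dispersion trend `alpha(mu) = a1/mu + a0` is then fitted by robust
#' regression over features with positive raw estimates, and each feature's
#' dispersion is shrunk 50/50 toward the trend on the log scale, floored at
#' 1e-8. With fewer than 10 usable features the trend step is skipped and
#' raw (floored) moments are used.
#'
#' @param counts Count matrix, features x samples.
#' @param sf Size factors from [size_factors()].
#' @param group Factor (or coercible) of contrast levels per sample.
#' @return Numeric vector of per-feature dispersions.
#' @export
estimate_dispersions <- function(counts, sf, group) {
  stopifnot(is.matrix(counts), length(sf) == ncol(counts),
            length(group) == ncol(counts))
  group <- droplevels(factor(group))
  nc <- sweep(counts, 2L, sf, "/")
  mu <- rowMeans(nc)
  lv <- levels(group)
  acc <- numeric(nrow(counts))
  wacc <- numeric(nrow(counts))
  for (j in seq_along(lv)) {
    sel <- group == lv[j]
    n_l <- sum(sel)
    if (n_l < 2L) next
    m_l <- rowMeans(nc[, sel, drop = FALSE])
    v_l <- apply(nc[, sel, drop = FALSE], 1L, stats::var)
    a_l <- ifelse(m_l > 0, (v_l - m_l) / m_l^2, NA_real_)
    ok_l <- is.finite(a_l)
    w <- n_l - 1L
    acc <- acc + ifelse(ok_l, a_l, 0) * w
    wacc <- wacc + ok_l * w
  }
  raw <- ifelse(wacc > 0, acc / wacc, NA_real_)
  raw[!is.finite(raw)] <- NA_real_
  usable <- !is.na(raw) & raw > 0 & mu > 0
  floor_a <- 1e-8
  if (sum(usable) >= 10L) {
    fit <- tryCatch(
      MASS::rlm(raw[usable] ~ I(1 / mu[usable]), maxit = 50),
      error = function(e) NULL
    )
    if (!is.null(fit) && all(is.finite(stats::coef(fit)))) {
      a0 <- max(stats::coef(fit)[1], floor_a)
      a1 <- max(stats::coef(fit)[2], 0)
    } else {
      a0 <- max(stats::median(raw[usable]), floor_a)
      a1 <- 0
    }
    trend <- pmax(a1 / pmax(mu, 1e-8) + a0, floor_a)
    alpha <- exp(0.5 * log(pmax(raw, floor_a)) + 0.5 * log(trend))
    alpha[is.na(raw)] <- trend[is.na(raw)]
  } else {
    alpha <- pmax(raw, floor_a)
    alpha[is.na(raw)] <- floor_a
  }
  pmax(alpha, floor_a)
}

# One NB GLM fit with fixed dispersion via iteratively reweighted least
# squares; returns coefficient vector, SEs (natural-log scale) and a
# convergence flag.
fit_nb_glm <- function(y, X, offset, alpha, maxit = 50L, tol = 1e-8) {
  p <- ncol(X)
  eta <- log(pmax(y, 0.5)) - offset
  beta <- tryCatch(qr.coef(qr(X), eta), error = function(e) rep(NA_real_, p))
  if (anyNA(beta)) return(list(converged = FALSE))
  delta <- Inf
  for (it in seq_len(maxit)) {
    eta <- pmin(pmax(drop(X %*% beta) + offset, -30), 30)
    mu <- exp(eta)
    w <- mu / (1 + alpha * mu)
    z <- (eta - offset) + (y - mu) / mu
    XtW <- t(X * w)
    beta_new <- tryCatch(solve(XtW %*% X, XtW %*% z),
                         error = function(e) NULL)
    if (is.null(beta_new) || any(!is.finite(beta_new))) {
      return(list(converged = FALSE))
    }
    delta <- max(abs(beta_new - beta))
    beta <- drop(beta_new)
    if (delta < tol) break
  }
  eta <- pmin(pmax(drop(X %*% beta) + offset, -30), 30)
  mu <- exp(eta)
  w <- mu / (1 + alpha * mu)
  info <- t(X * w) %*% X
  cov <- tryCatch(solve(info), error = function(e) NULL)
  if (is.null(cov) || any(!is.finite(diag(cov))) || any(diag(cov) <= 0)) {
    return(list(converged = FALSE))
  }
  list(converged = delta < 1e-4, beta = beta, se = sqrt(diag(cov)))
}

#' Negative-binomial Wald differential expression
#'
#' Fits, per feature, an NB log-linear model with `log(size factor)` offsets
#' and tests the contrast coefficient with a Wald z-test (two-sided normal).
#' Features with zero counts in every sample, and features whose fit does
#' not converge, are reported with status `untested` and excluded from the
#' BH adjustment.
#'
#' @param counts Integer count matrix, features x samples.
#' @param sheet Sample sheet data frame; rows aligned to `counts` columns
#'   (matched by `sample_id` when present).
#' @param design A [design_spec()].
#' @param dispersions Optional per-feature dispersions; estimated via
#'   [estimate_dispersions()] when `NULL`.
#' @return A `pirsig_de` data frame: `feature_id`, `base_mean` (mean of
#'   normalised counts), `log2fc` (contrast coefficient, log2), `se`,
#'   `stat` (Wald z), `p`, `padj` (BH over tested features), `status`.
#' @export
nb_wald <- function(counts, sheet, design, dispersions = NULL) {
  stopifnot(is.matrix(counts), inherits(design, "design_spec"))
  if (!is.null(sheet$sample_id) && !is.null(colnames(counts))) {
    if (!setequal(sheet$sample_id, colnames(counts))) {
      stop("sample sheet ids do not match count matrix columns")
    }
    sheet <- sheet[match(colnames(counts), sheet$sample_id), , drop = FALSE]
  }
  X <- build_design_matrix(sheet, design)
  sf <- size_factors(counts)
  nc <- sweep(counts, 2L, sf, "/")
  base_mean <- rowMeans(nc)
  nonzero <- rowSums(counts) > 0
  group <- sheet[[design$contrast]]
  if (is.null(dispersions)) {
    dispersions <- rep(NA_real_, nrow(counts))
    dispersions[nonzero] <- estimate_dispersions(
      counts[nonzero, , drop = FALSE], sf, group)
  }
  offset <- log(sf)
  n <- nrow(counts)
  log2fc <- se <- stat <- p <- rep(NA_real_, n)
  status <- ifelse(nonzero, "tested", "untested")
  k <- ncol(X)
  # finite-sample correction for the plug-in dispersion: alpha is estimated
  # from the within-level residuals, which carry m - g degrees of freedom
  # (m samples, g contrast levels); the naive Wald SE treats alpha as known
  # and is inflated by sqrt(m / (m - g)) to compensate
  g <- nlevels(droplevels(factor(group)))
  se_infl <- sqrt(ncol(counts) / (ncol(counts) - g))
  for (i in which(nonzero)) {
    fit <- fit_nb_glm(counts[i, ], X, offset, dispersions[i])
    if (!isTRUE(fit$converged)) {
      status[i] <- "untested"
      next
    }
    log2fc[i] <- fit$beta[k] / log(2)
    se[i] <- fit$se[k] / log(2) * se_infl
    stat[i] <- log2fc[i] / se[i]
    p[i] <- 2 * stats::pnorm(-abs(stat[i]))
  }
  res <- data.frame(
    feature_id = if (is.null(rownames(counts))) paste0("f", seq_len(n))
                 else rownames(counts),
    base_mean = base_mean,
    log2fc = log2fc, se = se, stat = stat, p = p,
    padj = bh_adjust(replace(p, status != "tested", NA_real_)),
    status = status,
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(res, "contrast_levels") <- attr(X, "contrast_levels")
  attr(res, "size_factors") <- sf
  class(res) <- c("pirsig_de", "data.frame")
  res
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment; `NA` entries (untested features) are excluded
#' from the adjustment and returned as `NA`.
#'
#' @param p Numeric vector of raw p-values in \[0, 1\], `NA` allowed.
#' @return Vector of adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Call deregulated features
#'
#' The deregulation rule: a feature is called when |log2FC| >= `lfc_min`
#' (inclusive) and adjusted p < `padj_max` (strict).
#'
#' @param res A `pirsig_de` result.
#' @param lfc_min Minimum absolute log2 fold change (default 0.6).
#' @param padj_max Adjusted-p cutoff, exclusive (default 0.1).
#' @return A `pirsig_call` list with character vectors `up` and `down`.
#' @export
call_deregulated <- function(res, lfc_min = 0.6, padj_max = 0.1) {
  stopifnot(inherits(res, "pirsig_de"), lfc_min > 0, padj_max > 0)
  ok <- res$status == "tested" & !is.na(res$padj) & res$padj < padj_max
  structure(list(
    up = res$feature_id[ok & res$log2fc >= lfc_min],
    down = res$feature_id[ok & res$log2fc <= -lfc_min]
  ), class = "pirsig_call")
}

#' Log2 transform of normalised counts
#'
#' `log2(count / size_factor + pseudocount)`; a light-weight stand-in for a
#' regularised log that preserves the rank structure clustering and
#' top-variable selection rely on.
#'
#' @param counts Count matrix.
#' @param sf Size factors.
#' @param pseudocount Added before the log (default 1).
#' @return Numeric matrix, same dimensions as `counts`.
#' @export
log_transform <- function(counts, sf, pseudocount = 1) {
  stopifnot(all(sf > 0), length(sf) == ncol(counts))
  log2(sweep(counts, 2L, sf, "/") + pseudocount)
}

#' Top-N most variable features
#'
#' @param log_matrix Log-transformed matrix from [log_transform()].
#' @param n Number of features (default 2000); ties broken by feature id,
#'   `n` above the feature count returns all.
#' @return Character vector of feature ids.
#' @export
top_variable <- function(log_matrix, n = 2000L) {
  stopifnot(n >= 1L)
  rv <- apply(log_matrix, 1L, stats::var)
  ids <- rownames(log_matrix)
  ord <- order(-rv, ids)
  ids[ord][seq_len(min(n, length(ids)))]
}

#' Top-N differentially expressed features by adjusted p-value
#'
#' @param res A `pirsig_de` result.
#' @param n Number of features (default 100). Sorted by (padj, raw p, id);
#'   untested features are excluded.
#' @return Character vector of feature ids.
#' @export
top_de <- function(res, n = 100L) {
  stopifnot(inherits(res, "pirsig_de"), n >= 1L)
  tested <- res[res$status == "tested" & !is.na(res$padj), , drop = FALSE]
  ord <- order(tested$padj, tested$p, tested$feature_id)
  tested$feature_id[ord][seq_len(min(n, nrow(tested)))]
}

#' Top-N most abundant deregulated features and their count share
#'
#' Among called (up or down) features, takes the `n` with the largest base
#' mean and, when counts are supplied, reports the fraction of each
#' sample's normalised counts carried by those features — the "how much of
#' the piRNA pool do the top deregulated species represent" statistic.
#'
#' @param res A `pirsig_de` result.
#' @param call A `pirsig_call` from [call_deregulated()].
#' @param n Number of features (default 20).
#' @param counts Optional count matrix for the share computation.
#' @param sf Optional size factors (defaults to those stored on `res`).
#' @return List with `feature_ids` and `count_share` (per-sample named
#'   vector, or `NULL` when `counts` is absent; all-zero when no feature is
#'   called).
#' @export
top_abundant_de <- function(res, call, n = 20L, counts = NULL, sf = NULL) {
  stopifnot(inherits(res, "pirsig_de"), inherits(call, "pirsig_call"))
  called <- union(call$up, call$down)
  sub <- res[res$feature_id %in% called, , drop = FALSE]
  ord <- order(-sub$base_mean, sub$feature_id)
  ids <- sub$feature_id[ord][seq_len(min(n, nrow(sub)))]
  share <- NULL
  if (!is.null(counts)) {
    if (is.null(sf)) sf <- attr(res, "size_factors")
    if (is.null(sf)) sf <- size_factors(counts)
    nc <- sweep(counts, 2L, sf, "/")
    share <- if (length(ids) == 0L) {
      stats::setNames(numeric(ncol(counts)), colnames(counts))
    } else {
      colSums(nc[ids, , drop = FALSE]) / colSums(nc)
    }
  }
  list(feature_ids = ids, count_share = share)
}
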