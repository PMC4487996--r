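orthonorm_contrasts <- function(k) {
  cm <- stats::contr.helmert(k)
  sweep(cm, 2, sqrt(colSums(cm^2)), `/`)
}

#' Repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Fits the fully within-subject ANOVA for a complete balanced table (one
#' value per subject and cell; duplicate rows per cell are averaged first).
#' For every within-subject effect the F statistic is computed from
#' orthonormalized contrast scores, and the Greenhouse-Geisser epsilon from
#' the covariance of those scores, so that two-level effects have epsilon
#' exactly 1. Corrected p-values use the epsilon-scaled degrees of freedom.
#'
#' @param data data frame in long format.
#' @param dv name of the dependent-variable column.
#' @param within character vector of within-subject factor column names.
#' @param subject name of the subject column.
#' @return An object of class `rm_anova` with a `table` data frame (`effect`,
#'   `df1`, `df2`, `F`, `eps`, `p`, `p_uncorrected`), cell and marginal
#'   means, and the internals needed by [tukey_hsd()].
#' @examples
#' d <- expand.grid(subject = 1:8, a = c("x", "y"))
#' d$y <- rnorm(nrow(d)) + (d$a == "x")
#' fit <- rm_anova(d, dv = "y", within = "a")
#' fit$table
#' @export
rm_anova <- function(data, dv, within, subject = "subject") {
  for (cl in c(dv, within, subject))
    if (!cl %in% names(data)) stop_bad_arg("column not found: ", cl)
  facs <- lapply(within, function(f) sort(unique(as.character(data[[f]]))))
  names(facs) <- within
  k <- vapply(facs, length, integer(1))
  subjects <- sort(unique(as.character(data[[subject]])))
  n <- length(subjects)
  p <- prod(k)

  cells <- do.call(expand.grid,
                   c(facs, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE))
  cell_id <- do.call(paste, c(cells, sep = "\r"))
  row_id <- do.call(paste, c(lapply(within, function(f)
    as.character(data[[f]])), sep = "\r"))
  Y <- matrix(NA_real_, n, p)
  cnt <- matrix(0L, n, p)
  si <- match(as.character(data[[subject]]), subjects)
  ci <- match(row_id, cell_id)
  if (anyNA(ci)) stop_bad_arg("rows with unknown factor combination")
  v <- data[[dv]]
  for (r in base::seq_along(v)) {
    if (is.na(Y[si[r], ci[r]])) Y[si[r], ci[r]] <- 0
    Y[si[r], ci[r]] <- Y[si[r], ci[r]] + v[r]
    cnt[si[r], ci[r]] <- cnt[si[r], ci[r]] + 1L
  }
  if (any(cnt == 0L)) stop_bad_arg("missing cells: design must be complete")
  Y <- Y / cnt

  effects <- unlist(lapply(base::seq_along(within), function(m)
    utils::combn(within, m, simplify = FALSE)), recursive = FALSE)
  tab <- list()
  internals <- list()
  for (ef in effects) {
    # effect factors get orthonormal contrasts, the others a plain mean
    mats <- lapply(within, function(f)
      if (f %in% ef) orthonorm_contrasts(k[[f]])
      else matrix(1 / k[[f]], k[[f]], 1))
    M <- Reduce(kronecker, rev(mats))
    Z <- Y %*% M
    q <- ncol(Z)
    zbar <- colMeans(Z)
    ss_eff <- n * sum(zbar^2)
    ss_err <- sum(sweep(Z, 2, zbar, `-`)^2)
    df1 <- q
    df2 <- q * (n - 1)
    Fv <- (ss_eff / df1) / (ss_err / df2)
    S <- stats::cov(Z)
    eps <- if (q == 1) 1 else (sum(diag(S)))^2 / (q * sum(S^2))
    p_unc <- stats::pf(Fv, df1, df2, lower.tail = FALSE)
    p_gg <- stats::pf(Fv, df1 * eps, df2 * eps, lower.tail = FALSE)
    nm <- paste(ef, collapse = ":")
    tab[[nm]] <- data.frame(effect = nm, df1 = df1, df2 = df2, F = Fv,
                            eps = eps, p = p_gg, p_uncorrected = p_unc,
                            stringsAsFactors = FALSE)
    internals[[nm]] <- list(factors = ef, ms_err = ss_err / df2, df_err = df2)
  }
  cell_means <- cbind(cells, mean = colMeans(Y))
  marginals <- lapply(stats::setNames(within, within), function(f)
    tapply(colMeans(Y), cells[[f]], mean))
  structure(list(table = do.call(rbind, c(tab, make.row.names = FALSE)),
                 cell_means = cell_means, marginal_means = marginals,
                 Y = Y, cells = cells, k = k, n = n, within = within,
                 internals = internals),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA (n = %d subjects)\n", x$n))
  tb <- x$table
  tb$F <- round(tb$F, 3)
  tb$eps <- round(tb$eps, 3)
  tb$p <- signif(tb$p, 3)
  tb$p_uncorrected <- signif(tb$p_uncorrected, 3)
  print(tb, row.names = FALSE)
  invisible(x)
}

#' Tukey HSD post-hoc comparisons for a fitted within-subject effect
#'
#' Compares the cell means of `effect` (marginalized over the other factors)
#' with the studentized-range distribution, using the effect's own
#' within-subject error term and `n` = number of subjects.
#'
#' @param fit an [rm_anova()] object.
#' @param effect effect name as it appears in `fit$table$effect`.
#' @return Data frame of pairwise comparisons: `cell_a`, `cell_b`, `diff`,
#'   `q`, `p`.
#' @export
tukey_hsd <- function(fit, effect) {
  stopifnot(inherits(fit, "rm_anova"))
  if (!effect %in% names(fit$internals))
    stop_bad_arg("effect not fitted: ", effect)
  info <- fit$internals[[effect]]
  mats <- lapply(fit$within, function(f)
    if (f %in% info$factors) diag(fit$k[[f]])
    else matrix(1 / fit$k[[f]], fit$k[[f]], 1))
  A <- Reduce(kronecker, rev(mats))
  Ycell <- fit$Y %*% A
  keep <- vapply(fit$within, function(f) f %in% info$factors, logical(1))
  labs <- do.call(expand.grid,
                  c(lapply(fit$within[keep], function(f)
                    sort(unique(as.character(fit$cells[[f]])))),
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE))
  lab <- do.call(paste, c(labs, sep = "."))
  means <- colMeans(Ycell)
  kk <- length(means)
  se <- sqrt(info$ms_err / fit$n)
  out <- list()
  for (i in base::seq_len(kk - 1)) for (j in (i + 1):kk) {
    qv <- abs(means[i] - means[j]) / se
    out[[length(out) + 1]] <- data.frame(
      cell_a = lab[i], cell_b = lab[j], diff = means[i] - means[j], q = qv,
      p = stats::ptukey(qv, kk, info$df_err, lower.tail = FALSE),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
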