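#' Pooled (weighted) sample covariance of two groups
#'
#' \eqn{S = ((n_1 - 1) S_1 + (n_2 - 1) S_2) / (n_1 + n_2 - 2)} with
#' \eqn{S_1, S_2} the per-group sample covariances (divisor \eqn{n - 1}).
#'
#' @param X1,X2 numeric matrices, one row per observation, columns aligned
#'   (same relative seconds).
#' @return p x p pooled covariance matrix.
#' @export
pooled_covariance <- function(X1, X2) {
  X1 <- as.matrix(X1); X2 <- as.matrix(X2)
  n1 <- nrow(X1); n2 <- nrow(X2)
  if (ncol(X1) != ncol(X2)) {
    vmr_abort("groups must have the same number of columns", "vmr_validation_error")
  }
  if (n1 + n2 < 3 || (n1 < 2 && n2 < 2)) {
    vmr_abort("need at least 3 observations overall and 2 in one group",
              "vmr_insufficient_data")
  }
  S1 <- if (n1 >= 2) stats::cov(X1) else matrix(0, ncol(X1), ncol(X1))
  S2 <- if (n2 >= 2) stats::cov(X2) else matrix(0, ncol(X2), ncol(X2))
  ((n1 - 1) * S1 + (n2 - 1) * S2) / (n1 + n2 - 2)
}

#' Two-sample Hotelling's T-squared test on activity profiles
#'
#' Compares two groups of p-dimensional activity vectors (typically the
#' per-second Burst Duration over a 30-s window). The statistic is
#' \deqn{T^2 = \frac{n_1 n_2}{n_1 + n_2}
#'   (\bar X^{(1)} - \bar X^{(2)})' S^{-1} (\bar X^{(1)} - \bar X^{(2)})}
#' with \eqn{S} the pooled sample covariance. Under the null of equal mean
#' vectors, \eqn{F = \frac{n_1 + n_2 - p - 1}{p (n_1 + n_2 - 2)} T^2}
#' follows an F distribution with \eqn{p} and \eqn{n_1 + n_2 - p - 1}
#' degrees of freedom; the p-value is its upper tail. For p = 1 the
#' statistic reduces to the squared pooled-variance two-sample t statistic.
#'
#' The test assumes a common covariance in the two groups (no
#' Behrens-Fisher variant is offered). A singular pooled covariance is a
#' hard error by default, naming zero-variance columns; an opt-in ridge
#' regularization \eqn{S + \epsilon I} is available but changes the null
#' distribution and is intended for exploration only.
#'
#' @param X1,X2 numeric matrices (rows = observations); vectors are treated
#'   as single-column matrices.
#' @param ridge optional non-negative scalar added to the diagonal of S
#'   (default \code{0} = off).
#' @return object of class \code{vmr_hotelling}: \code{t2}, \code{f_stat},
#'   \code{df1} (= p), \code{df2} (= n1 + n2 - p - 1), \code{p_value},
#'   \code{n1}, \code{n2}, \code{p_dim}, \code{mean_diff},
#'   \code{pooled_cov}.
#' @export
hotelling_t2 <- function(X1, X2, ridge = 0) {
  X1 <- as.matrix(X1); X2 <- as.matrix(X2)
  n1 <- nrow(X1); n2 <- nrow(X2); p <- ncol(X1)
  if (ncol(X2) != p) vmr_abort("groups must have the same dimension", "vmr_validation_error")
  df2 <- n1 + n2 - p - 1
  if (df2 < 1) {
    vmr_abort(sprintf(
      "dimension p=%d exceeds what n1=%d, n2=%d support (need n1+n2-p-1 >= 1); shorten the window or pool more observations",
      p, n1, n2), "vmr_dimension_error")
  }
  S <- pooled_covariance(X1, X2)
  if (ridge > 0) S <- S + diag(ridge, p)
  d <- colMeans(X1) - colMeans(X2)
  sol <- tryCatch(solve(S, d), error = function(e) NULL)
  if (is.null(sol) || !all(is.finite(sol)) || rcond_sym(S) < .Machine$double.eps * 100) {
    zv <- which(diag(S) <= 0)
    msg <- if (length(zv) > 0) {
      paste0("singular pooled covariance; zero-variance column(s): ",
             paste(colnames(S)[zv] %||% zv, collapse = ", "))
    } else {
      "singular pooled covariance (collinear columns)"
    }
    vmr_abort(paste0(msg, "; consider a sub-interval, or opt-in ridge regularization"),
              "vmr_singular_covariance")
  }
  t2 <- as.numeric((n1 * n2 / (n1 + n2)) * crossprod(d, sol))
  f_stat <- (df2 / (p * (n1 + n2 - 2))) * t2
  p_value <- stats::pf(f_stat, p, df2, lower.tail = FALSE)
  structure(list(t2 = t2, f_stat = f_stat, df1 = p, df2 = df2,
                 p_value = p_value, n1 = n1, n2 = n2, p_dim = p,
                 mean_diff = d, pooled_cov = S),
            class = "vmr_hotelling")
}

rcond_sym <- function(S) {
  ev <- tryCatch(eigen(S, symmetric = TRUE, only.values = TRUE)$values,
                 error = function(e) c(0, 1))
  lo <- min(ev); hi <- max(abs(ev))
  if (hi <= 0) return(0)
  if (lo <= 0) return(0)
  lo / hi
}

#' @export
print.vmr_hotelling <- function(x, ...) {
  cat("Two-sample Hotelling's T-squared test\n")
  cat(sprintf("  T2 = %.4f, F = %.4f on (%d, %d) df, p = %.4g\n",
              x$t2, x$f_stat, x$df1, x$df2, x$p_value))
  cat(sprintf("  n1 = %d, n2 = %d, dimension p = %d\n", x$n1, x$n2, x$p_dim))
  invisible(x)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values: with the m raw p-values sorted ascending,
#' \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} m / j}, capped at 1, returned in
#' the original order. Delegates to \code{stats::p.adjust(method = "BH")}
#' after validating the inputs.
#'
#' @param p_values numeric vector of raw p-values in [0, 1].
#' @return adjusted p-values, same length and order.
#' @export
fdr_adjust <- function(p_values) {
  if (any(!is.finite(p_values) | p_values < 0 | p_values > 1)) {
    vmr_abort("p-values must lie in [0, 1]", "vmr_validation_error")
  }
  stats::p.adjust(p_values, method = "BH")
}

battery_filter <- function(windows, filter) {
  keep <- rep(TRUE, nrow(windows$meta))
  if (!is.null(filter)) {
    for (f in names(filter)) {
      if (!f %in% names(windows$meta)) {
        vmr_abort(paste0("filter field not in metadata: ", f), "vmr_schema_error")
      }
      keep <- keep & windows$meta[[f]] %in% filter[[f]]
    }
  }
  keep
}

#' Pairwise Hotelling T-squared battery with FDR control
#'
#' Runs one \code{\link{hotelling_t2}} per group pair and window tag, and
#' adjusts all p-values of the invocation as a single Benjamini-Hochberg
#' family. Observation unit is the (animal, event) vector, i.e. biological
#' and technical repeats pooled within a group are treated as independent
#' samples; when several trials are pooled this risks pseudoreplication
#' (repeated measures of the same animals inflate the effective n), which
#' is flagged with a warning.
#'
#' @param windows a \code{vmr_windows} object.
#' @param group_field metadata field defining the groups (e.g.
#'   \code{"strain"}).
#' @param window_tags list of window specifications (each \code{"pre"},
#'   \code{"post"}, \code{"full"} or \code{c(from, to)} relative seconds).
#' @param comparisons \code{"all"} for all unordered pairs of observed
#'   levels, or a list of length-2 character vectors.
#' @param filter optional named list restricting rows, e.g.
#'   \code{list(stage_dpf = 6, stimulus = "on", trial_index = 1)}.
#' @param warn_pooling warn about pseudoreplication when multiple trials
#'   are pooled (default TRUE).
#' @return data.frame of class \code{vmr_pairwise}: \code{group_a, group_b,
#'   window, n1, n2, p_dim, t2, f_stat, df1, df2, p_raw, p_adj}.
#' @export
pairwise_battery <- function(windows, group_field = "strain",
                             window_tags = list("pre", "post"),
                             comparisons = "all", filter = NULL,
                             warn_pooling = TRUE) {
  keep <- battery_filter(windows, filter)
  meta <- windows$meta[keep, , drop = FALSE]
  if (!group_field %in% names(meta)) {
    vmr_abort(paste0("group field not in metadata: ", group_field), "vmr_schema_error")
  }
  g <- as.character(meta[[group_field]])
  levs <- unique(g)
  if (identical(comparisons, "all")) {
    comparisons <- utils::combn(sort(levs), 2, simplify = FALSE)
  }
  if (warn_pooling && length(unique(meta$trial_index)) > 1) {
    vmr_warn(paste0("multiple trials pooled as independent observations; ",
                    "repeated measures of the same animals may pseudoreplicate"),
             "vmr_pseudoreplication_warning")
  }
  tag_label <- function(w) if (is.character(w)) w else sprintf("%d:%d", w[1], w[2])
  rows <- list()
  for (w in window_tags) {
    V <- window_matrix(windows, w)[keep, , drop = FALSE]
    for (pair in comparisons) {
      i1 <- g == pair[1]; i2 <- g == pair[2]
      if (sum(i1) < 2 || sum(i2) < 2) {
        vmr_abort(sprintf("group '%s' has fewer than 2 observations",
                          pair[which.min(c(sum(i1), sum(i2)))]),
                  "vmr_insufficient_data")
      }
      h <- hotelling_t2(V[i1, , drop = FALSE], V[i2, , drop = FALSE])
      rows[[length(rows) + 1L]] <- data.frame(
        group_a = pair[1], group_b = pair[2], window = tag_label(w),
        n1 = h$n1, n2 = h$n2, p_dim = h$p_dim, t2 = h$t2, f_stat = h$f_stat,
        df1 = h$df1, df2 = h$df2, p_raw = h$p_value)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- fdr_adjust(out$p_raw)
  attr(out, "fdr_family") <- "all tests of this invocation (Benjamini-Hochberg)"
  class(out) <- c("vmr_pairwise", "data.frame")
  out
}

#' Before-vs-after comparisons within each group
#'
#' For each level of \code{group_field}, tests the pre-change window
#' against the post-change window of the same observations with
#' \code{\link{hotelling_t2}} (two-sample form, matching the profile-battery
#' convention), with one FDR family over the invocation.
#'
#' @inheritParams pairwise_battery
#' @param window_a,window_b the two windows compared (default pre vs post).
#' @return data.frame like \code{\link{pairwise_battery}} with
#'   \code{group_a = group_b = } the group level and \code{window} =
#'   \code{"window_a vs window_b"}.
#' @export
prepost_battery <- function(windows, group_field = "strain",
                            window_a = "pre", window_b = "post",
                            filter = NULL, warn_pooling = TRUE) {
  keep <- battery_filter(windows, filter)
  meta <- windows$meta[keep, , drop = FALSE]
  g <- as.character(meta[[group_field]])
  if (warn_pooling && length(unique(meta$trial_index)) > 1) {
    vmr_warn("multiple trials pooled as independent observations",
             "vmr_pseudoreplication_warning")
  }
  Va <- window_matrix(windows, window_a)[keep, , drop = FALSE]
  Vb <- window_matrix(windows, window_b)[keep, , drop = FALSE]
  tag <- function(w) if (is.character(w)) w else sprintf("%d:%d", w[1], w[2])
  rows <- list()
  for (lev in sort(unique(g))) {
    idx <- g == lev
    h <- hotelling_t2(Va[idx, , drop = FALSE], Vb[idx, , drop = FALSE])
    rows[[length(rows) + 1L]] <- data.frame(
      group_a = lev, group_b = lev,
      window = paste(tag(window_a), "vs", tag(window_b)),
      n1 = h$n1, n2 = h$n2, p_dim = h$p_dim, t2 = h$t2, f_stat = h$f_stat,
      df1 = h$df1, df2 = h$df2, p_raw = h$p_value)
  }
  out <- do.call(rbind, rows)
  out$p_adj <- fdr_adjust(out$p_raw)
  class(out) <- c("vmr_pairwise", "data.frame")
  out
}
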