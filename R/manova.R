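#' Build an ordered treatment-coded design for multi-factor models
#'
#' Constructs the model matrix for an ordered list of categorical main
#' effects and interactions, using treatment contrasts (first level as
#' reference) and preserving the given term order, which matters because
#' all fits in this package use sequential (order-of-entry) sums of
#' squares. Well location enters as a plain factor over observed wells
#' (up to 96 levels).
#'
#' Columns that are aliased within a term (linearly dependent on columns
#' already in the design) are dropped and recorded; a term that is aliased
#' in its entirety raises an error naming it.
#'
#' @param metadata data.frame of factor variables (one row per
#'   observation), e.g. the \code{meta} component of a \code{vmr_windows}
#'   object.
#' @param terms character vector of term labels in fitting order, e.g.
#'   \code{c("well", "bio_rep", "strain", "stage_dpf", "strain:stage_dpf")}.
#'   Each interaction's constituent main effects must precede it.
#' @return object of class \code{vmr_design}: \code{X} (full-column-rank
#'   model matrix including intercept), \code{assign} (term index per
#'   column, 0 = intercept), \code{terms}, \code{levels} (level dictionary
#'   per variable), \code{dropped} (aliased columns removed).
#' @export
build_design <- function(metadata, terms) {
  vars <- unique(unlist(strsplit(terms, ":", fixed = TRUE)))
  miss <- setdiff(vars, names(metadata))
  if (length(miss) > 0) {
    vmr_abort(paste0("term variable(s) not in metadata: ", paste(miss, collapse = ", ")),
              "vmr_schema_error")
  }
  dat <- as.data.frame(metadata[, vars, drop = FALSE])
  for (v in vars) {
    dat[[v]] <- factor(dat[[v]])
    if (nlevels(dat[[v]]) < 2) {
      vmr_abort(paste0("factor '", v, "' is constant in the data"),
                "vmr_degenerate_factor")
    }
  }
  for (i in seq_along(terms)) {
    parts <- strsplit(terms[i], ":", fixed = TRUE)[[1]]
    if (length(parts) > 1) {
      missing_mains <- setdiff(parts, terms[seq_len(i - 1)])
      if (length(missing_mains) > 0) {
        vmr_abort(sprintf("interaction '%s' requires main effect(s) %s earlier in the term list",
                          terms[i], paste(missing_mains, collapse = ", ")),
                  "vmr_validation_error")
      }
    }
  }
  fml <- stats::as.formula(paste("~", paste(terms, collapse = " + ")))
  tt <- stats::terms(fml, keep.order = TRUE)
  X <- stats::model.matrix(tt, data = dat,
                           contrasts.arg = lapply(dat, function(f) "contr.treatment"))
  asgn <- attr(X, "assign")
  qrX <- qr(X)
  dropped <- character(0)
  if (qrX$rank < ncol(X)) {
    drop_idx <- sort(qrX$pivot[(qrX$rank + 1):ncol(X)])
    lost_terms <- unique(asgn[drop_idx])
    whole <- lost_terms[vapply(lost_terms, function(k) all(which(asgn == k) %in% drop_idx),
                               logical(1))]
    if (length(whole) > 0) {
      vmr_abort(paste0("term(s) fully aliased with earlier terms: ",
                       paste(terms[whole], collapse = ", ")), "vmr_aliasing_error")
    }
    dropped <- colnames(X)[drop_idx]
    X <- X[, -drop_idx, drop = FALSE]
    asgn <- asgn[-drop_idx]
  }
  structure(list(X = X, assign = asgn, terms = terms,
                 levels = lapply(dat, levels), dropped = dropped,
                 n = nrow(X)),
            class = "vmr_design")
}

#' Pillai-Bartlett trace
#'
#' \eqn{V = \mathrm{tr}\,[H (H + E)^{-1}]} for a hypothesis SSCP matrix H
#' and error SSCP matrix E. V sums the explained-variance shares across
#' discriminant directions and is bounded by \eqn{\min(p, q)}.
#'
#' @param H,E symmetric p x p SSCP matrices with H + E positive definite.
#' @return the trace statistic V.
#' @export
pillai_trace <- function(H, E) {
  HE <- H + E
  ch <- tryCatch(chol(HE), error = function(e) NULL)
  if (is.null(ch)) vmr_abort("H + E is not positive definite", "vmr_singular_covariance")
  sum(diag(chol2inv(ch) %*% H))
}

#' Approximate F test for the Pillai-Bartlett trace
#'
#' With \eqn{s = \min(p, q)}, \eqn{m = (|p - q| - 1)/2} and
#' \eqn{n' = (v - p - 1)/2}:
#' \deqn{F = \frac{2n' + s + 1}{2m + s + 1} \cdot
#'   \frac{V/s}{1 - V/s}}
#' on \eqn{s(2m + s + 1)} and \eqn{s(2n' + s + 1)} degrees of freedom.
#'
#' @param V Pillai trace.
#' @param p response dimension.
#' @param q hypothesis degrees of freedom of the term.
#' @param v error degrees of freedom.
#' @return list \code{f}, \code{df1}, \code{df2}, \code{p_value}.
#' @export
pillai_approx_f <- function(V, p, q, v) {
  s <- min(p, q)
  m <- (abs(p - q) - 1) / 2
  np <- (v - p - 1) / 2
  df1 <- s * (2 * m + s + 1)
  df2 <- s * (2 * np + s + 1)
  f <- ((2 * np + s + 1) / (2 * m + s + 1)) * (V / s) / (1 - V / s)
  list(f = f, df1 = df1, df2 = df2,
       p_value = stats::pf(f, df1, df2, lower.tail = FALSE))
}

#' Multi-factor MANOVA with sequential SSCP decomposition
#'
#' Fits the multivariate linear model of \code{Y} on the ordered design and
#' decomposes the model SSCP sequentially: the hypothesis SSCP of term k is
#' the increment in fitted SSCP when term k enters after terms 1..k-1
#' (Type I sums of squares, so the term order of the design is part of the
#' model). Each term is tested with the Pillai-Bartlett trace
#' \eqn{V = \mathrm{tr}[H (H + E)^{-1}]} against the common error SSCP E
#' and its approximate F.
#'
#' The increments are computed from a single orthogonal (QR) decomposition
#' of the design matrix rather than normal equations, which keeps them
#' stable for designs with many-level factors such as 96-well location.
#' By construction \eqn{\sum_k H_k + E} equals the total centered SSCP.
#'
#' @param Y numeric n x p response matrix (rows match the design).
#' @param design a \code{\link{build_design}} result.
#' @return object of class \code{vmr_manova}: data.frame \code{table}
#'   (term, pillai, approx_f, df1, df2, p_value, q, order_index), list
#'   \code{H} of per-term SSCP matrices, \code{E}, error df \code{v},
#'   \code{n_obs}, \code{p_dim}, \code{total_sscp}.
#' @export
manova_fit <- function(Y, design) {
  Y <- as.matrix(Y)
  if (nrow(Y) != design$n) {
    vmr_abort("response rows do not match the design", "vmr_validation_error")
  }
  p <- ncol(Y)
  X <- design$X
  v <- nrow(Y) - ncol(X)
  if (v < p) {
    vmr_abort(sprintf(
      "error df (%d) below response dimension (%d); shorten the window or reduce terms",
      v, p), "vmr_response_dimension_error")
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X) || !identical(qrX$pivot, seq_len(ncol(X)))) {
    vmr_abort("design matrix is rank deficient; rebuild with build_design",
              "vmr_aliasing_error")
  }
  # coordinates of Y in the orthonormal column basis of X, in entry order
  qty <- qr.qty(qrX, Y)[seq_len(ncol(X)), , drop = FALSE]
  E <- crossprod(qr.resid(qrX, Y))
  K <- length(design$terms)
  H <- vector("list", K)
  rows <- vector("list", K)
  for (k in seq_len(K)) {
    idx <- which(design$assign == k)
    Hk <- crossprod(qty[idx, , drop = FALSE])
    Hk <- (Hk + t(Hk)) / 2
    q <- length(idx)
    V <- pillai_trace(Hk, E)
    ft <- pillai_approx_f(V, p, q, v)
    H[[k]] <- Hk
    rows[[k]] <- data.frame(term = design$terms[k], pillai = V,
                            approx_f = ft$f, df1 = ft$df1, df2 = ft$df2,
                            p_value = ft$p_value, q = q, order_index = k)
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  total <- crossprod(sweep(Y, 2, colMeans(Y)))
  structure(list(table = table, H = H, E = (E + t(E)) / 2, v = v,
                 n_obs = nrow(Y), p_dim = p, total_sscp = total,
                 ss_type = "sequential (Type I), order as given"),
            class = "vmr_manova")
}

#' @export
print.vmr_manova <- function(x, digits = 4, ...) {
  cat(sprintf("Multi-factor MANOVA (Pillai-Bartlett trace), n = %d, p = %d\n",
              x$n_obs, x$p_dim))
  cat(sprintf("Sums of squares: %s; error df = %d\n", x$ss_type, x$v))
  tb <- x$table
  tb$pillai <- round(tb$pillai, digits)
  tb$approx_f <- round(tb$approx_f, digits)
  tb$p_value <- signif(tb$p_value, digits)
  print(tb[, c("term", "pillai", "approx_f", "df1", "df2", "p_value")],
        row.names = FALSE)
  invisible(x)
}

#' Default VMR model term lists
#'
#' The ordered factor lists used for windowed VMR activity: location
#' (well), biological repeat, strain, stage, technical repeat (trial) and
#' light stimulus, followed by the interactions among the biological and
#' treatment factors. Location and biological repeat enter as main effects
#' only: plate position effects (illumination non-uniformity) and
#' collection-day effects are taken as invariant across strains, stages,
#' trials and stimuli, so their interactions are excluded by default.
#'
#' @param include_stimulus include the light-stimulus factor and its
#'   interactions (use \code{FALSE} when fitting one stimulus type alone).
#' @return character vector of terms in fitting order.
#' @export
default_vmr_terms <- function(include_stimulus = TRUE) {
  base <- c("well", "bio_rep", "strain", "stage_dpf", "trial_index")
  inter <- c("strain:stage_dpf", "strain:trial_index", "stage_dpf:trial_index")
  if (include_stimulus) {
    base <- c(base, "stimulus")
    inter <- c("strain:stage_dpf", "strain:trial_index", "strain:stimulus",
               "stage_dpf:trial_index", "stage_dpf:stimulus",
               "trial_index:stimulus")
  }
  c(base, inter)
}

#' MANOVA on a windowed activity set
#'
#' Convenience wrapper: builds the response matrix from the windows (the
#' full concatenated pre+post profile, or the pre or post window alone),
#' builds the ordered design from the window metadata, and fits
#' \code{\link{manova_fit}}.
#'
#' @param windows a \code{vmr_windows} object.
#' @param terms ordered term list (default \code{\link{default_vmr_terms}},
#'   with stimulus terms included only when both stimulus types are
#'   present).
#' @param response \code{"full"}, \code{"pre"} or \code{"post"}.
#' @param filter optional named list restricting rows (as in
#'   \code{\link{pairwise_battery}}).
#' @return a \code{vmr_manova} object.
#' @export
manova_windows <- function(windows, terms = NULL,
                           response = c("full", "pre", "post"),
                           filter = NULL) {
  response <- match.arg(response)
  keep <- battery_filter(windows, filter)
  meta <- windows$meta[keep, , drop = FALSE]
  if (is.null(terms)) {
    terms <- default_vmr_terms(include_stimulus = length(unique(meta$stimulus)) > 1)
  }
  Y <- window_matrix(windows, response)[keep, , drop = FALSE]
  manova_fit(Y, build_design(meta, terms))
}
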