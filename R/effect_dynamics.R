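#' Sequential ANOVA with eta-squared effect sizes
#'
#' Univariate multi-factor ANOVA of a single response on an ordered design,
#' with sequential (Type I) sums of squares — the p = 1 case of the
#' package's MANOVA machinery — and per-term effect size
#' \eqn{\eta^2 = SS_{effect} / SS_{total}}, the proportion of response
#' variance attributed to the term. \eqn{SS_{total}} is the centered total
#' sum of squares, so the per-term \eqn{\eta^2} values plus the residual
#' share partition 1 exactly.
#'
#' A constant response (zero total SS) yields \eqn{\eta^2 = 0} for every
#' term, with a warning.
#'
#' @param y numeric response vector.
#' @param design a \code{\link{build_design}} result with matching rows.
#' @return data.frame: \code{term} (including \code{"residual"}),
#'   \code{ss}, \code{df}, \code{eta_squared}; attribute \code{ss_total}.
#' @export
anova_eta_squared <- function(y, design) {
  y <- as.numeric(y)
  if (length(y) != design$n) {
    vmr_abort("response length does not match the design", "vmr_validation_error")
  }
  ss_total <- sum((y - mean(y))^2)
  X <- design$X
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    vmr_abort("design matrix is rank deficient; rebuild with build_design",
              "vmr_aliasing_error")
  }
  qty <- qr.qty(qrX, matrix(y))[seq_len(ncol(X)), 1]
  ss_res <- sum(qr.resid(qrX, y)^2)
  K <- length(design$terms)
  ss <- vapply(seq_len(K), function(k) sum(qty[design$assign == k]^2), numeric(1))
  df <- vapply(seq_len(K), function(k) sum(design$assign == k), numeric(1))
  if (ss_total <= 0) {
    vmr_warn("constant response: all eta-squared set to 0", "vmr_constant_response")
    eta <- rep(0, K); eta_res <- 0
  } else {
    eta <- ss / ss_total; eta_res <- ss_res / ss_total
  }
  out <- data.frame(term = c(design$terms, "residual"),
                    ss = c(ss, ss_res),
                    df = c(df, design$n - ncol(X)),
                    eta_squared = c(eta, eta_res))
  attr(out, "ss_total") <- ss_total
  out
}

#' Per-second effect-size dynamics
#'
#' For each relative second of the windowed set (one stimulus type at a
#' time; On and Off responses are never mixed in one fit), fits the ordered
#' multi-factor ANOVA on that second's Burst Duration and reports each
#' term's \eqn{\eta^2}. The resulting time courses show when, relative to
#' the light change, each experimental factor explains activity variance.
#'
#' The same sequential-SS convention and term order as the MANOVA module
#' are used, so at every second the \eqn{\eta^2} values are a true
#' partition of the response variance.
#'
#' @param windows a \code{vmr_windows} object.
#' @param terms ordered term list (default
#'   \code{default_vmr_terms(include_stimulus = FALSE)}).
#' @param stimulus \code{"on"} or \code{"off"}: which light transition to
#'   analyze.
#' @param filter optional named list restricting rows further.
#' @return long-form data.frame of class \code{vmr_dynamics}:
#'   \code{stimulus, rel_second, term, ss, df, eta_squared}, plus
#'   per-second \code{ss_total} and \code{n} columns.
#' @export
dynamic_effect_timecourse <- function(windows, terms = NULL,
                                      stimulus = c("on", "off"),
                                      filter = NULL) {
  stimulus <- match.arg(stimulus)
  keep <- battery_filter(windows, filter) & windows$meta$stimulus == stimulus
  if (!any(keep)) {
    vmr_abort(paste0("no windows for stimulus '", stimulus, "'"),
              "vmr_validation_error")
  }
  meta <- windows$meta[keep, , drop = FALSE]
  if (is.null(terms)) terms <- default_vmr_terms(include_stimulus = FALSE)
  design <- build_design(meta, terms)
  V <- windows$values[keep, , drop = FALSE]
  rows <- list()
  for (j in seq_along(windows$rel_seconds)) {
    y <- V[, j]
    tab <- withCallingHandlers(
      anova_eta_squared(y, design),
      vmr_constant_response = function(w) invokeRestart("muffleWarning"))
    rows[[j]] <- data.frame(stimulus = stimulus,
                            rel_second = windows$rel_seconds[j],
                            term = tab$term, ss = tab$ss, df = tab$df,
                            eta_squared = tab$eta_squared,
                            ss_total = attr(tab, "ss_total"),
                            n = nrow(V))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("vmr_dynamics", "data.frame")
  out
}
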