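#' Random consistency index table
#'
#' Tabulated random index (RI) used in the AHP consistency ratio, for matrix
#' orders 1 to 30. Orders 1 and 2 are 0 by convention (a 1x1 or 2x2
#' reciprocal matrix is always consistent); orders 3 to 30 are the published
#' reference values used by this pipeline.
#'
#' @return Named numeric vector, names "1".."30".
#' @export
ri_table <- function() {
  ri <- c(0, 0,
          0.52, 0.89, 1.12, 1.26, 1.36, 1.41, 1.46,
          1.49, 1.52, 1.54, 1.56, 1.58, 1.59, 1.5943,
          1.6064, 1.6133, 1.6207, 1.6292, 1.6383, 1.6403, 1.6462,
          1.6497, 1.6556, 1.6587, 1.6631, 1.6670, 1.6693, 1.6724)
  names(ri) <- as.character(1:30)
  ri
}

#' Validate a pairwise comparison matrix
#'
#' Checks that the matrix is square, positive, has a unit diagonal, and is
#' reciprocally symmetric (`a_ij = 1/a_ji` within 1e-9).
#'
#' @param m Numeric matrix.
#' @return The matrix, invisibly classed `pairwise_matrix`.
#' @export
pairwise_matrix <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) {
    s2s_error("pairwise matrix must be square", "s2s_invalid_matrix")
  }
  if (any(!is.finite(m)) || any(m <= 0)) {
    s2s_error("pairwise matrix entries must be positive and finite",
              "s2s_invalid_matrix")
  }
  if (any(abs(diag(m) - 1) > 1e-9)) {
    s2s_error("pairwise matrix diagonal must be 1", "s2s_invalid_matrix")
  }
  if (any(abs(m * t(m) - 1) > 1e-9)) {
    s2s_error("pairwise matrix must satisfy a_ij = 1/a_ji (within 1e-9)",
              "s2s_invalid_matrix")
  }
  invisible(structure(m, class = c("pairwise_matrix", class(m))))
}

#' Build a perfectly consistent pairwise matrix from weights
#'
#' Returns the matrix `a_ij = w_i / w_j`, which is exactly consistent:
#' solving it recovers `w` (normalized), with principal eigenvalue equal to
#' the order and zero consistency index.
#'
#' @param weights Positive weights.
#' @return A `pairwise_matrix`.
#' @export
make_consistent_matrix <- function(weights) {
  if (any(!is.finite(weights)) || any(weights <= 0)) {
    s2s_error("weights must be positive", "s2s_domain_error")
  }
  pairwise_matrix(outer(weights, weights, "/"))
}

#' Solve an AHP judgment matrix
#'
#' Computes the priority weights as the principal eigenvector (power
#' iteration to a 1e-12 tolerance, normalized to sum to one), the maximum
#' eigenvalue via the Rayleigh quotient, and the consistency diagnostics:
#' CI = (lambda_max - n)/(n - 1), RI from [ri_table()], CR = CI/RI, with the
#' matrix judged consistent when CR < 0.1.
#'
#' @param m A pairwise comparison matrix (validated with
#'   [pairwise_matrix()]).
#' @param max_iter Power-iteration cap.
#' @return Object of class `ahp_result`: list with `weights`, `lambda_max`,
#'   `ci`, `ri`, `cr`, `consistent`, `n`, `iterations`.
#' @export
#' @examples
#' ahp_solve(make_consistent_matrix(c(0.477, 0.152, 0.082, 0.288)))
ahp_solve <- function(m, max_iter = 10000) {
  m <- unclass(pairwise_matrix(m))
  n <- nrow(m)
  w <- rep(1 / n, n)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    w1 <- as.numeric(m %*% w)
    w1 <- w1 / sum(w1)
    if (max(abs(w1 - w)) < 1e-12 || iter >= max_iter) {
      w <- w1
      break
    }
    w <- w1
  }
  lambda_max <- mean(as.numeric(m %*% w) / w)
  ci <- if (n >= 2) (lambda_max - n) / (n - 1) else 0
  ri_all <- ri_table()
  if (n > length(ri_all)) {
    s2s_error(sprintf("no random index tabulated for order %d", n),
              "s2s_domain_error")
  }
  ri <- unname(ri_all[as.character(n)])
  cr <- if (n >= 3) ci / ri else 0
  structure(list(weights = w, lambda_max = lambda_max, ci = ci, ri = ri,
                 cr = cr, consistent = cr < 0.1, n = n, iterations = iter),
            class = "ahp_result")
}

#' @export
print.ahp_result <- function(x, ...) {
  cat(sprintf("<ahp_result> n = %d, lambda_max = %.4f, CI = %.4f, RI = %.3f, CR = %.4f (%s)\n",
              x$n, x$lambda_max, x$ci, x$ri, x$cr,
              if (x$consistent) "consistent, CR < 0.1" else "NOT consistent"))
  cat("weights:", paste(sprintf("%.4f", x$weights), collapse = ", "), "\n")
  invisible(x)
}

#' Percentage weights from an AHP feature vector
#'
#' Each entry divided by the sum of the vector, as a percentage rounded to
#' three decimals (the presentation convention of the worked example).
#'
#' @param v Positive feature-vector entries.
#' @return Numeric vector of percentages.
#' @export
#' @examples
#' weights_from_feature_vector(c(1.908, 0.609, 0.329, 1.154))[1] # 47.7
weights_from_feature_vector <- function(v) {
  if (any(!is.finite(v)) || any(v <= 0)) {
    s2s_error("feature-vector entries must be positive", "s2s_domain_error")
  }
  round(v / sum(v) * 100, 3)
}

#' AHP consistency index
#'
#' `CI = (lambda_max - n)/(n - 1)`, rounded to `digits` decimals (3 by
#' default, the worked example's presentation; use `digits = NULL` for the
#' raw value).
#'
#' @param lambda_max Principal eigenvalue.
#' @param n Matrix order (>= 2).
#' @param digits Rounding digits, or `NULL`.
#' @return The consistency index.
#' @export
#' @examples
#' consistency_index(4.067, 4) # 0.022
consistency_index <- function(lambda_max, n, digits = 3) {
  if (!is.finite(n) || n < 2) {
    s2s_error("consistency index requires order n >= 2", "s2s_domain_error")
  }
  ci <- (lambda_max - n) / (n - 1)
  if (is.null(digits)) ci else round(ci, digits)
}

#' AHP consistency ratio
#'
#' `CR = CI / RI(n)`, rounded to `digits` decimals. Orders 1 and 2 return 0
#' with a message (such matrices are always consistent).
#'
#' @param ci Consistency index.
#' @param n Matrix order.
#' @param ri RI lookup table (defaults to [ri_table()]).
#' @param digits Rounding digits, or `NULL`.
#' @return The consistency ratio.
#' @export
#' @examples
#' consistency_ratio(0.022, 4) # 0.025
consistency_ratio <- function(ci, n, ri = ri_table(), digits = 3) {
  if (!is.finite(n) || n < 1) {
    s2s_error("order n must be at least 1", "s2s_domain_error")
  }
  if (n < 3) {
    message("orders 1-2 are always consistent; CR defined as 0")
    return(0)
  }
  if (!as.character(n) %in% names(ri)) {
    s2s_error(sprintf("no random index tabulated for order %d", n),
              "s2s_domain_error")
  }
  cr <- ci / unname(ri[as.character(n)])
  if (is.null(digits)) cr else round(cr, digits)
}

#' Survey response rates
#'
#' Recovery rate (returned/sent) and effective rate (valid/sent), as
#' percentages rounded to one decimal.
#'
#' @param sent,returned,valid Questionnaire counts with
#'   `0 <= valid <= returned <= sent`, `sent > 0`.
#' @return Named numeric vector `c(recovery, effective)`.
#' @export
#' @examples
#' response_rates(500, 457, 437) # 91.4, 87.4
response_rates <- function(sent, returned, valid) {
  sent <- unname(sent); returned <- unname(returned); valid <- unname(valid)
  if (!is.finite(sent) || sent <= 0 || valid < 0 || valid > returned ||
      returned > sent) {
    s2s_error("counts must satisfy 0 <= valid <= returned <= sent, sent > 0",
              "s2s_domain_error")
  }
  c(recovery = round(returned / sent * 100, 1),
    effective = round(valid / sent * 100, 1))
}
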