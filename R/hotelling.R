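#' Per-trial response-signed radial noise vectors
#'
#' Builds the vectors entering the profile-level Hotelling tests: each
#' trial's radial average of its raw noise field (same center, bins and
#' inducer exclusion as [radial_average()]), signed +1 when the response was
#' "present" and -1 when "absent". When the four stimulus-response cells
#' have equal sizes, the sample mean of these vectors equals exactly one
#' quarter of the radial classification-image profile, which anchors the
#' construction to the classification image.
#'
#' @param run a `detection_run`.
#' @return A numeric matrix (trials x bins) of class `trial_vectors`.
#' @export
trial_vectors <- function(run) {
  stopifnot(inherits(run, "detection_run"))
  sgn <- ifelse(run$trials$response == "present", 1, -1)
  v <- run$radial * sgn
  class(v) <- c("trial_vectors", class(v))
  v
}

# Shared guard: invertible, well-conditioned covariance.
solve_cov <- function(S, xbar, what) {
  rc <- rcond(S)
  if (!is.finite(rc) || rc < 1e-12)
    stop(what, " covariance matrix is numerically singular ",
         "(reciprocal condition number ", format(rc, digits = 3),
         "); collect more trials or merge bins")
  solve(S, xbar)
}

hotelling_result <- function(t2, f, df1, df2) {
  structure(list(t2 = t2, f = f, df1 = df1, df2 = df2,
                 p = pf(f, df1, df2, lower.tail = FALSE)),
            class = "hotelling_result")
}

#' Single-sample Hotelling T-squared test
#'
#' Tests the mean of multivariate observations against zero:
#' `T^2 = n * xbar' S^-1 xbar` with the sample covariance S, converted to
#' `F = T^2 (n - p) / (p (n - 1))` on `(p, n - p)` degrees of freedom. With
#' the 99-bin radial profiles this reproduces the reference degrees of
#' freedom (e.g. df2 = 9901 at n = 10,000 and 29,901 at n = 30,000).
#'
#' @param V numeric matrix, observations in rows (n > p required).
#' @return An object of class `hotelling_result`: `t2`, `f`, `df1`, `df2`,
#'   `p`.
#' @export
hotelling_one_sample <- function(V) {
  V <- unclass(as.matrix(V))
  n <- nrow(V); p <- ncol(V)
  if (n <= p)
    stop("need more observations (n = ", n, ") than dimensions (p = ", p,
         ")")
  xbar <- colMeans(V)
  S <- cov(V)
  t2 <- n * sum(xbar * solve_cov(S, xbar, "sample"))
  f <- t2 * (n - p) / (p * (n - 1))
  hotelling_result(t2, f, df1 = p, df2 = n - p)
}

#' Independent two-sample Hotelling T-squared test
#'
#' Tests the difference of two multivariate means with the pooled
#' covariance:
#' `T^2 = (n1 n2/(n1+n2)) d' Sp^-1 d`, `F = T^2 (n1+n2-p-1)/(p (n1+n2-2))`
#' on `(p, n1+n2-p-1)` degrees of freedom.
#'
#' @param V1,V2 numeric matrices with matching column dimension.
#' @return A `hotelling_result`.
#' @export
hotelling_two_sample <- function(V1, V2) {
  V1 <- unclass(as.matrix(V1)); V2 <- unclass(as.matrix(V2))
  if (ncol(V1) != ncol(V2)) stop("samples must share dimension")
  n1 <- nrow(V1); n2 <- nrow(V2); p <- ncol(V1)
  if (n1 + n2 <= p + 1)
    stop("need n1 + n2 > p + 1 for the two-sample test")
  d <- colMeans(V1) - colMeans(V2)
  Sp <- ((n1 - 1) * cov(V1) + (n2 - 1) * cov(V2)) / (n1 + n2 - 2)
  t2 <- (n1 * n2 / (n1 + n2)) * sum(d * solve_cov(Sp, d, "pooled"))
  f <- t2 * (n1 + n2 - p - 1) / (p * (n1 + n2 - 2))
  hotelling_result(t2, f, df1 = p, df2 = n1 + n2 - p - 1L)
}

#' Format a Hotelling p value in table style
#'
#' @param p a p value.
#' @param floor values below this print as "<floor".
#' @return A character scalar.
#' @export
format_p <- function(p, floor = 1e-4) {
  if (p < floor) paste0("<", format(floor)) else format(round(p, 4))
}

#' @export
print.hotelling_result <- function(x, ...) {
  cat(sprintf("<hotelling_result> T2 = %.2f, F(%d, %d) = %.2f, p %s\n",
              x$t2, x$df1, x$df2, x$f,
              if (x$p < 1e-4) "< 0.0001" else sprintf("= %.4f", x$p)))
  invisible(x)
}
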