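#' @importFrom rlang abort warn inform %||% .data
#' @importFrom stats dnorm lm optim quantile rnorm runif rexp sd uniroot var coef
#' @importFrom utils head tail
NULL

# numerical floor used wherever a variance or hazard value must stay positive
.EPS <- 1e-10

clamp_pos <- function(x, eps = .EPS) pmax(x, eps)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# symmetrize and clamp eigenvalues of a small covariance matrix
spd_repair <- function(Q, eps = .EPS) {
  Q <- (Q + t(Q)) / 2
  e <- eigen(Q, symmetric = TRUE)
  vals <- pmax(e$values, eps)
  Q <- e$vectors %*% (vals * t(e$vectors))
  (Q + t(Q)) / 2
}

# 2x2 inverse, closed form
inv2 <- function(M) {
  d <- M[1, 1] * M[2, 2] - M[1, 2] * M[2, 1]
  matrix(c(M[2, 2], -M[2, 1], -M[1, 2], M[1, 1]), 2, 2) / d
}
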