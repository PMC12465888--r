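# Small numerical helpers shared across modules.

logit <- function(p) log(p) - log1p(-p)

sigmoid <- function(x) 1 / (1 + exp(-x))

# log(1 + exp(x)) without overflow for large |x|
softplus <- function(x) {
  out <- pmax(x, 0)
  out + log1p(exp(-abs(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_snvae <- function(...) stop(..., call. = FALSE)

as_dense <- function(x) {
  if (inherits(x, "Matrix")) as.matrix(x) else x
}

#' @importFrom Matrix Matrix
as_sparse <- function(x) {
  if (!inherits(x, "Matrix")) x <- Matrix::Matrix(x, sparse = TRUE)
  # normalize to general numeric column-compressed storage
  methods::as(methods::as(methods::as(x, "dMatrix"), "generalMatrix"),
              "CsparseMatrix")
}

# leaky rectifier used by optional hidden layers
leaky_relu <- function(x, slope = 0.01) {
  ifelse(x > 0, x, slope * x)
}

leaky_relu_grad <- function(x, slope = 0.01) {
  ifelse(x > 0, 1, slope)
}
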