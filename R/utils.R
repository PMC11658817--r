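`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

#' @keywords internal
assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    stop2(sprintf("`%s` must be a finite number in [%s, %s]", name, lower, upper))
  invisible(x)
}

# activation functions (sigma in the attention layers) and their derivatives
activation_fun <- function(name) {
  switch(name,
    elu = function(z) ifelse(z > 0, z, expm1(z)),
    relu = function(z) pmax(z, 0),
    identity = function(z) z,
    stop2("unknown activation: ", name)
  )
}

activation_grad <- function(name) {
  switch(name,
    elu = function(z) ifelse(z > 0, 1, exp(z)),
    relu = function(z) (z > 0) * 1,
    identity = function(z) array(1, dim(z)),
    stop2("unknown activation: ", name)
  )
}

# (i, j, x) triplets of the nonzero entries of a (possibly dense) matrix
sparse_triplets <- function(Wm) {
  M <- Matrix::Matrix(Wm, sparse = TRUE)
  # symmetric inputs coerce to dsCMatrix, whose triplets cover only one
  # triangle; force the general representation so every entry is listed
  M <- methods::as(methods::as(M, "generalMatrix"), "TsparseMatrix")
  df <- Matrix::summary(M)
  list(i = df$i, j = df$j, x = df$x)
}

# numerically stable log(sigmoid(x)) = -log(1 + exp(-x))
log_sigmoid <- function(x) {
  ifelse(x >= 0, -log1p(exp(-x)), x - log1p(exp(x)))
}
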