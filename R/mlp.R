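# Small multi-layer perceptron regressor trained by L-BFGS with analytic
# backpropagation gradients. Written in-package because the hyperparameter
# grid requires one or two hidden layers with relu/tanh activations and an L2
# weight penalty, a combination no installed R package exposes.

mlp_sizes <- function(p, hidden) c(p, hidden, 1L)

mlp_pack <- function(W, b) c(unlist(W), unlist(b))

mlp_unpack <- function(par, sizes) {
  L <- length(sizes) - 1
  W <- vector("list", L); b <- vector("list", L)
  off <- 0
  for (l in seq_len(L)) {
    nw <- sizes[l] * sizes[l + 1]
    W[[l]] <- matrix(par[off + seq_len(nw)], sizes[l], sizes[l + 1])
    off <- off + nw
  }
  for (l in seq_len(L)) {
    b[[l]] <- par[off + seq_len(sizes[l + 1])]
    off <- off + sizes[l + 1]
  }
  list(W = W, b = b)
}

mlp_act <- function(Z, activation) {
  if (activation == "relu") pmax(Z, 0) else tanh(Z)
}

mlp_act_grad <- function(Z, A, activation) {
  if (activation == "relu") (Z > 0) * 1 else 1 - A^2
}

# Loss and gradient in one pass: 0.5 * MSE + 0.5 * alpha * ||W||^2 / n
# (biases unpenalized).
mlp_loss_grad <- function(par, X, y, sizes, activation, alpha) {
  n <- nrow(X)
  L <- length(sizes) - 1
  th <- mlp_unpack(par, sizes)
  A <- vector("list", L + 1); Z <- vector("list", L)
  A[[1]] <- X
  for (l in seq_len(L)) {
    Z[[l]] <- A[[l]] %*% th$W[[l]] + rep(th$b[[l]], each = n)
    A[[l + 1]] <- if (l < L) mlp_act(Z[[l]], activation) else Z[[l]]
  }
  r <- as.vector(A[[L + 1]]) - y
  loss <- 0.5 * mean(r^2) +
    0.5 * alpha * sum(vapply(th$W, function(w) sum(w^2), numeric(1))) / n
  gW <- vector("list", L); gb <- vector("list", L)
  delta <- matrix(r / n, ncol = 1)
  for (l in L:1) {
    gW[[l]] <- crossprod(A[[l]], delta) + alpha * th$W[[l]] / n
    gb[[l]] <- colSums(delta)
    if (l > 1)
      delta <- (delta %*% t(th$W[[l]])) * mlp_act_grad(Z[[l - 1]], A[[l]], activation)
  }
  list(value = loss, grad = mlp_pack(gW, gb))
}

#' Fit a small multi-layer perceptron regressor
#'
#' Feedforward network with one or two hidden layers, relu or tanh hidden
#' activation and a linear output, minimizing `0.5 * MSE` plus an L2 weight
#' penalty by L-BFGS with analytic gradients. Weights are initialized with
#' seeded Glorot-uniform draws, so fits are deterministic given `seed`.
#'
#' @param X numeric feature matrix (rows = samples).
#' @param y numeric target vector.
#' @param hidden integer vector of hidden layer sizes (e.g. `c(4)` or
#'   `c(3, 3)`).
#' @param activation `"relu"` or `"tanh"`.
#' @param alpha L2 penalty on the weights (biases are not penalized).
#' @param seed seed for the weight initialization.
#' @param maxit maximum L-BFGS iterations.
#' @return An object of class `mlp_model`.
#' @export
mlp_fit <- function(X, y, hidden, activation = c("relu", "tanh"),
                    alpha = 1e-3, seed = 0, maxit = 200) {
  activation <- match.arg(activation)
  X <- as.matrix(X)
  sizes <- mlp_sizes(ncol(X), as.integer(hidden))
  par0 <- with_seed(seed, {
    L <- length(sizes) - 1
    W <- lapply(seq_len(L), function(l) {
      lim <- sqrt(6 / (sizes[l] + sizes[l + 1]))
      matrix(stats::runif(sizes[l] * sizes[l + 1], -lim, lim),
             sizes[l], sizes[l + 1])
    })
    b <- lapply(seq_len(L), function(l) numeric(sizes[l + 1]))
    mlp_pack(W, b)
  })
  # optim calls fn and gr separately; cache the shared forward/backward pass
  cache <- new.env(parent = emptyenv())
  evalpt <- function(par) {
    if (!is.null(cache$par) && identical(par, cache$par)) return(cache$res)
    res <- mlp_loss_grad(par, X, y, sizes, activation, alpha)
    cache$par <- par; cache$res <- res
    res
  }
  opt <- stats::optim(par0,
                      fn = function(p) evalpt(p)$value,
                      gr = function(p) evalpt(p)$grad,
                      method = "L-BFGS-B",
                      control = list(maxit = maxit, factr = 1e3))
  structure(
    list(par = opt$par, sizes = sizes, activation = activation,
         alpha = alpha, value = opt$value, convergence = opt$convergence),
    class = "mlp_model"
  )
}

#' @rdname mlp_fit
#' @param object fitted `mlp_model`.
#' @param newdata matrix of samples to predict.
#' @param ... unused.
#' @export
predict.mlp_model <- function(object, newdata, ...) {
  A <- as.matrix(newdata)
  th <- mlp_unpack(object$par, object$sizes)
  L <- length(object$sizes) - 1
  for (l in seq_len(L)) {
    Z <- A %*% th$W[[l]] + rep(th$b[[l]], each = nrow(A))
    A <- if (l < L) mlp_act(Z, object$activation) else Z
  }
  as.vector(A)
}
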