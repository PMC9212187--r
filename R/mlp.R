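#' Training configuration for Levenberg-Marquardt backpropagation
#'
#' The classical Marquardt damping schedule: start at `mu0`, multiply by
#' `mu_increase` whenever a proposed step fails to reduce the squared
#' error, divide by `mu_decrease` on acceptance; stop at `max_epochs`,
#' when the infinity norm of the gradient drops below `grad_tol`, or when
#' `mu` escalates past `mu_max` without an acceptable step.
#'
#' @param mu0 Initial damping (default 1e-3).
#' @param mu_increase,mu_decrease Damping factors (> 1; default 10).
#' @param mu_max Damping ceiling (default 1e10).
#' @param max_epochs Maximum LM iterations (default 100).
#' @param grad_tol Gradient infinity-norm stopping tolerance (default 1e-7).
#'
#' @return A `train_config` list.
#' @export
train_config <- function(mu0 = 1e-3, mu_increase = 10, mu_decrease = 10,
                         mu_max = 1e10, max_epochs = 100, grad_tol = 1e-7) {
  stopifnot(mu0 > 0, mu_increase > 1, mu_decrease > 1, mu_max > mu0,
            max_epochs >= 0, grad_tol > 0)
  structure(list(mu0 = mu0, mu_increase = mu_increase,
                 mu_decrease = mu_decrease, mu_max = mu_max,
                 max_epochs = as.integer(max_epochs), grad_tol = grad_tol),
            class = "train_config")
}

n_params <- function(layer_sizes) {
  nin <- layer_sizes[1]; h1 <- layer_sizes[2]; h2 <- layer_sizes[3]
  h1 * nin + h1 + h2 * h1 + h2 + h2 + 1L
}

#' Initialise a two-hidden-layer perceptron
#'
#' Architecture: `n_inputs -> tanh(10) -> tanh(10) -> logistic(1)`.
#' Weights and biases are drawn uniformly in `[-0.5, 0.5]` from the seeded
#' generator, so the same seed always yields the same model.
#'
#' @param n_inputs Number of input features (>= 1).
#' @param seed Integer RNG seed.
#' @param hidden Sizes of the two hidden layers (default `c(10, 10)`).
#'
#' @return An `mlp_model` with fields `layer_sizes` and the flat parameter
#'   vector `params`.
#' @export
init_mlp <- function(n_inputs, seed = 1L, hidden = c(10L, 10L)) {
  stopifnot(n_inputs >= 1, length(hidden) == 2, all(hidden >= 1))
  layer_sizes <- c(as.integer(n_inputs), as.integer(hidden), 1L)
  p <- n_params(layer_sizes)
  params <- with_seed(seed, runif(p, -0.5, 0.5))
  structure(list(layer_sizes = layer_sizes, params = params, seed = seed),
            class = "mlp_model")
}

#' @export
print.mlp_model <- function(x, ...) {
  cat(sprintf("<mlp_model> %s (%d parameters)\n",
              paste(x$layer_sizes, collapse = "-"),
              length(x$params)))
  invisible(x)
}

check_X <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$layer_sizes[1]) {
    abort(sprintf("Input has %d columns but the model expects %d.",
                  ncol(X), model$layer_sizes[1]))
  }
  storage.mode(X) <- "double"
  X
}

#' Forward pass and class prediction
#'
#' The score is the logistic output of the network; the label is 1 exactly
#' when the score is strictly greater than 0.5.
#'
#' @param object An `mlp_model`.
#' @param X Matrix (rows = subjects) with `n_inputs` columns.
#' @param ... Unused.
#'
#' @return A tibble with columns `score` and `label`.
#' @export
predict.mlp_model <- function(object, X, ...) {
  X <- check_X(object, X)
  ls <- object$layer_sizes
  score <- as.numeric(.mlp_forward_cpp(object$params, ls[1], ls[2], ls[3], X))
  tibble::tibble(score = score, label = as.integer(score > 0.5))
}

#' Error Jacobian of an MLP
#'
#' Returns the Jacobian `J = d e / d x` of the error vector `e = y - a`
#' with respect to the flat parameter vector, computed by backpropagating
#' the layer sensitivities, together with `e` itself.  `H = J'J` and
#' `G = J'e` are the Gauss-Newton Hessian approximation and gradient used
#' by the LM update.
#'
#' @inheritParams predict.mlp_model
#' @param model An `mlp_model`.
#' @param y 0/1 targets.
#' @return List with `J` (n x p) and `e` (length n).
#' @export
mlp_jacobian <- function(model, X, y) {
  X <- check_X(model, X)
  ls <- model$layer_sizes
  .mlp_jacobian_cpp(model$params, ls[1], ls[2], ls[3], X, as.numeric(y))
}

# Levenberg-Marquardt direction -(J'J + mu I)^{-1} J'e; kept as a plain R
# formula so the update rule can be checked on scalar toys.
lm_direction <- function(J, e, mu) {
  J <- as.matrix(J)
  H <- crossprod(J)
  G <- crossprod(J, e)
  -solve(H + mu * diag(nrow(H)), G)[, 1]
}

#' One Levenberg-Marquardt step
#'
#' Proposes `x - (J'J + mu I)^{-1} J'e`; if the squared error decreases
#' the step is accepted and `mu` is divided by `mu_decrease`, otherwise
#' `mu` is multiplied by `mu_increase` and the step is retried, up to
#' `mu_max`.  An accepted step never increases the objective.
#'
#' @inheritParams mlp_jacobian
#' @param state List with the current damping `mu` (e.g.
#'   `list(mu = cfg$mu0)`).
#' @param cfg A [train_config()].
#' @return List with the updated `model`, `state` (fields `mu`, `F`,
#'   `accepted`, `converged`).
#' @export
lmbp_step <- function(model, X, y, state, cfg = train_config()) {
  X <- check_X(model, X)
  ls <- model$layer_sizes
  res <- .lmbp_step_cpp(model$params, ls[1], ls[2], ls[3], X, as.numeric(y),
                        state$mu, cfg$mu_increase, cfg$mu_decrease,
                        cfg$mu_max, cfg$grad_tol)
  model$params <- as.numeric(res$x)
  list(model = model,
       state = list(mu = res$mu, F = res$F, accepted = res$accepted,
                    converged = res$converged))
}

#' Train an MLP with Levenberg-Marquardt backpropagation
#'
#' Repeats [lmbp_step()] until `max_epochs`, the gradient tolerance, or
#' the damping ceiling is reached.  The recorded objective history
#' `F(x) = e'e` is non-increasing over accepted steps.
#'
#' @inheritParams mlp_jacobian
#' @param cfg A [train_config()].
#' @return An `mlp_fit`: the trained model plus `history` (F per epoch),
#'   `epochs`, `converged`, and the final `mse`.
#' @export
train_mlp <- function(model, X, y, cfg = train_config()) {
  X <- check_X(model, X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y))
  ls <- model$layer_sizes
  res <- .lmbp_train_cpp(model$params, ls[1], ls[2], ls[3], X, y,
                         cfg$mu0, cfg$mu_increase, cfg$mu_decrease,
                         cfg$mu_max, cfg$max_epochs, cfg$grad_tol)
  model$params <- as.numeric(res$x)
  structure(
    list(model = model, history = as.numeric(res$history),
         epochs = res$epochs, converged = res$converged,
         mse = tail(as.numeric(res$history), 1) / length(y),
         n_train = length(y), cfg = cfg),
    class = "mlp_fit"
  )
}

#' @export
print.mlp_fit <- function(x, ...) {
  cat(sprintf("<mlp_fit> %d epochs, final MSE %.4g%s\n", x$epochs, x$mse,
              if (isTRUE(x$converged)) " (converged)" else ""))
  invisible(x)
}

#' @export
predict.mlp_fit <- function(object, X, ...) predict(object$model, X, ...)

#' Tidy the training history of an MLP fit
#' @param x An `mlp_fit`.
#' @param ... Unused.
#' @return Tibble with `epoch` (0 = initial) and the objective `F`.
#' @export
tidy.mlp_fit <- function(x, ...) {
  tibble::tibble(epoch = seq_along(x$history) - 1L, F = x$history)
}

#' One-row summary of an MLP fit
#' @param x An `mlp_fit`.
#' @param ... Unused.
#' @export
glance.mlp_fit <- function(x, ...) {
  tibble::tibble(epochs = x$epochs, mse = x$mse,
                 converged = isTRUE(x$converged), n_train = x$n_train,
                 n_params = length(x$model$params))
}

#' Serialize / restore an MLP model as flat JSON
#' @param model An `mlp_model` (or the model inside an `mlp_fit`).
#' @param path File path.
#' @rdname mlp_io
#' @export
write_mlp <- function(model, path) {
  if (inherits(model, "mlp_fit")) model <- model$model
  stopifnot(inherits(model, "mlp_model"))
  jsonlite::write_json(
    list(layer_sizes = model$layer_sizes, params = model$params,
         seed = model$seed),
    path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname mlp_io
#' @export
read_mlp <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(layer_sizes = as.integer(obj$layer_sizes),
                 params = as.numeric(obj$params),
                 seed = obj$seed),
            class = "mlp_model")
}
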