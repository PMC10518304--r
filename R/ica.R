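# Extended-Infomax independent component analysis (natural-gradient
# maximum-likelihood with sub/super-Gaussian source switching by kurtosis
# sign) and EOG-correlation-based ocular component removal.

#' Fit extended-Infomax ICA
#'
#' Sphering (PCA whitening) followed by batch natural-gradient extended
#' Infomax: `W <- W + lr * (I - K*tanh(u) u' - u u') W` with `K = diag(k_i)`,
#' `k_i = +1` for super-Gaussian and `-1` for sub-Gaussian sources, the sign
#' re-estimated from the excess kurtosis of the current activations. The
#' learning rate anneals when the gradient norm grows; a diverging run is
#' restarted at half the rate. Deterministic given `seed`.
#'
#' @param data numeric matrix channels x samples, or a
#'   [continuous_recording()] (then `channels` selects the channels to
#'   unmix, defaulting to all but `eog_exclude`).
#' @param seed integer seed (kurtosis-probe subsampling).
#' @param max_iter maximum gradient iterations.
#' @param tol convergence tolerance on the natural-gradient norm.
#' @param lrate initial learning rate.
#' @param max_samples the unmixing matrix is estimated on an evenly spaced
#'   subsample of at most this many time points (full-resolution data are
#'   kept for activation scoring and removal).
#' @param channels channel labels to unmix when `data` is a recording.
#' @param eog_exclude label(s) dropped by default when `data` is a recording.
#' @return an `ica_model`: `unmixing` / `mixing` (components x channels and
#'   back), `center`, `signs` (sub/super-Gaussian), `converged` (a
#'   non-converged fit is flagged, with a warning, not an error), `data`
#'   (the full-resolution matrix the model was fitted to).
#' @export
fit_extended_infomax <- function(data, seed = 1, max_iter = 500, tol = 1e-7,
                                 lrate = 0.1, max_samples = 20000L,
                                 channels = NULL, eog_exclude = "EOG") {
  if (inherits(data, "continuous_recording")) {
    sel <- channels %||% setdiff(rownames(data$data), eog_exclude)
    X <- data$data[sel, , drop = FALSE]
  } else X <- data
  nc <- nrow(X)
  stop_if_not(nc >= 2, "need at least 2 channels")
  mu <- rowMeans(X)
  Xc <- X - mu
  if (ncol(Xc) > max_samples) {
    Xs <- Xc[, round(seq(1, ncol(Xc), length.out = max_samples)), drop = FALSE]
  } else Xs <- Xc
  N <- ncol(Xs)
  stop_if_not(N > nc^2, "too few samples for the number of channels")

  C <- tcrossprod(Xs) / N
  eg <- eigen(C, symmetric = TRUE)
  if (min(eg$values) < max(eg$values) * 1e-10) {
    stop("rank-deficient data: remove duplicated or silent channels",
         call. = FALSE)
  }
  sph <- eg$vectors %*% diag(1 / sqrt(eg$values), nc) %*% t(eg$vectors)
  Xw <- sph %*% Xs

  set.seed(seed)
  W <- diag(nc); I <- diag(nc)
  signs <- rep(1, nc)
  prev <- NULL; ng <- Inf
  for (it in seq_len(max_iter)) {
    u <- W %*% Xw
    y <- tanh(u)
    if (it %% 5 == 1) {
      signs <- ifelse(rowMeans(u^4) / rowMeans(u^2)^2 - 3 > 0, 1, -1)
    }
    G <- I - tcrossprod(y * signs, u) / N - tcrossprod(u) / N
    W <- W + lrate * G %*% W
    ng <- max(abs(G))
    if (ng < tol) break
    if (!is.finite(ng) || max(abs(W)) > 1e8) {
      lrate <- lrate / 2
      W <- diag(nc); prev <- NULL; signs <- rep(1, nc)
      next
    }
    if (!is.null(prev) && ng > prev * 1.2) lrate <- lrate * 0.9
    prev <- ng
  }
  converged <- ng < tol
  if (!converged) {
    warning(sprintf("extended Infomax did not converge (gradient %.2e after %d iterations)",
                    ng, it))
  }
  unmixing <- W %*% sph
  structure(list(unmixing = unmixing, mixing = solve(unmixing), center = mu,
                 signs = signs, converged = converged, iterations = it,
                 gradient = ng, channel_labels = rownames(X), data = X),
            class = "ica_model")
}

ica_activations <- function(model, X = NULL) {
  X <- X %||% model$data
  model$unmixing %*% (X - model$center)
}

#' Flag ocular components by EOG correlation
#'
#' Components whose activation correlates with the simultaneously recorded
#' EOG trace at `|r| >= threshold` are flagged as ocular. An automatic,
#' reproducible stand-in for manual EOG-guided component selection.
#'
#' @param model an `ica_model`.
#' @param eog_trace EOG samples aligned with the data the model was fitted
#'   to.
#' @param threshold absolute correlation cut-off.
#' @return integer vector of flagged component indices (possibly empty).
#' @export
identify_ocular_components <- function(model, eog_trace, threshold = 0.7) {
  acts <- ica_activations(model)
  stop_if_not(length(eog_trace) == ncol(acts),
              "EOG trace not aligned with the fitted data")
  if (sd(eog_trace) == 0) return(integer())
  r <- abs(as.numeric(cor(t(acts), eog_trace)))
  which(r >= threshold)
}

#' Reconstruct a recording with flagged components removed
#'
#' Zeroes the flagged components and back-projects; channels outside the
#' model (e.g. EOG) are passed through unchanged. With no flags the output
#' equals the input to numerical precision.
#'
#' @param rec a [continuous_recording()].
#' @param model an `ica_model` fitted to (a channel subset of) `rec`.
#' @param flagged integer component indices to remove.
#' @return the cleaned [continuous_recording()].
#' @export
remove_components <- function(rec, model, flagged) {
  X <- rec$data[model$channel_labels, , drop = FALSE]
  S <- model$unmixing %*% (X - model$center)
  keep <- setdiff(seq_len(nrow(S)), flagged)
  Xc <- model$mixing[, keep, drop = FALSE] %*% S[keep, , drop = FALSE] +
    model$center
  out <- rec$data
  out[model$channel_labels, ] <- Xc
  continuous_recording(out, rec$sampling_rate, rec$events)
}
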