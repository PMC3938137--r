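## Probabilistic PCA: x = W z + mu + eps with z ~ N(0, I) and isotropic
## noise eps ~ N(0, sigma2 I), fitted by EM. Missing entries are treated as
## latent variables in the E-step (jointly Gaussian with z), so the
## observed-data log-likelihood is non-decreasing across iterations. The
## feature means mu are fixed at the per-feature means of the observed
## entries, which keeps the EM updates exact in the presence of missing
## data.

#' Fit probabilistic PCA by EM, tolerating missing values
#'
#' @param data an [ExpressionDataset-class]; features are probes (rows),
#'   samples are columns. `NA` intensities are treated as missing
#'   observations.
#' @param n_components number of latent components, strictly less than
#'   `min(n_features, n_samples)`.
#' @param max_iter maximum EM iterations, default 500.
#' @param tol relative log-likelihood change below which EM stops, default
#'   1e-8.
#' @param seed integer seed for the random loading initialization
#'   (small-variance Gaussian noise; reproducible by construction).
#' @return a [PpcaModel-class] with loadings (features x components), the
#'   feature mean vector, the noise variance, posterior mean scores for all
#'   samples (samples x components) and the log-likelihood trace.
#' @export
fitPpca <- function(data, n_components, max_iter = 500, tol = 1e-8,
                    seed = 1) {
  X <- intensities(data)          # d features x N samples
  d <- nrow(X); N <- ncol(X); q <- as.integer(n_components)
  if (q >= min(d, N)) stop("n_components must be < min(n_features, n_samples)")
  if (any(rowSums(!is.na(X)) == 0))
    stop("feature(s) missing in all samples: ",
         paste(head(rownames(X)[rowSums(!is.na(X)) == 0], 5), collapse = ", "))
  if (any(colSums(!is.na(X)) == 0))
    stop("every sample must retain >= 1 observed feature")
  mu <- rowMeans(X, na.rm = TRUE)
  Y <- X - mu
  obs <- !is.na(Y)
  set.seed(as.integer(seed))
  W <- matrix(rnorm(d * q, sd = 0.1), d, q)
  sigma2 <- max(var(as.vector(Y), na.rm = TRUE) / 2, 1e-4)
  ll_trace <- numeric(0)
  scores <- matrix(0, N, q)
  for (iter in seq_len(max_iter)) {
    A <- matrix(0, d, q)          # sum over n of E[(x_n - mu) z_n']
    B <- matrix(0, q, q)          # sum over n of E[z_n z_n']
    resid <- 0                    # accumulates observed-data pieces
    ll <- 0
    EzL <- vector("list", N)
    CzL <- vector("list", N)
    for (nidx in seq_len(N)) {
      o <- obs[, nidx]
      yo <- Y[o, nidx]
      Wo <- W[o, , drop = FALSE]
      Mq <- sigma2 * diag(q) + crossprod(Wo)
      Mi <- solve(Mq)
      Ez <- drop(Mi %*% crossprod(Wo, yo))
      Cz <- sigma2 * Mi
      Ezz <- Cz + tcrossprod(Ez)
      EzL[[nidx]] <- Ez; CzL[[nidx]] <- Cz
      scores[nidx, ] <- Ez
      # observed-data log-likelihood via the Woodbury identity
      no <- sum(o)
      quad <- (sum(yo^2) - sum((crossprod(Wo, yo)) * (Mi %*% crossprod(Wo, yo)))) / sigma2
      logdet <- (no - q) * log(sigma2) + determinant(Mq, logarithm = TRUE)$modulus
      ll <- ll - 0.5 * (no * log(2 * pi) + as.numeric(logdet) + quad)
      # sufficient statistics; missing rows use the old loadings
      A[o, ] <- A[o, ] + tcrossprod(yo, Ez)
      if (any(!o))
        A[!o, ] <- A[!o, ] + W[!o, , drop = FALSE] %*% Ezz
      B <- B + Ezz
    }
    ll_trace <- c(ll_trace, ll)
    Wnew <- A %*% solve(B)
    s2 <- 0
    for (nidx in seq_len(N)) {
      o <- obs[, nidx]
      yo <- Y[o, nidx]
      Ez <- EzL[[nidx]]
      Ezz <- CzL[[nidx]] + tcrossprod(Ez)
      Wo <- Wnew[o, , drop = FALSE]
      s2 <- s2 + sum(yo^2) - 2 * sum(yo * (Wo %*% Ez)) +
        sum(diag(crossprod(Wo) %*% Ezz))
      if (any(!o)) {
        Dm <- W[!o, , drop = FALSE] - Wnew[!o, , drop = FALSE]
        s2 <- s2 + sum((Dm %*% Ezz) * Dm) + sum(!o) * sigma2
      }
    }
    sigma2_new <- max(s2 / (N * d), 1e-12)
    converged <- iter > 1 &&
      abs(ll - ll_trace[iter - 1]) < tol * (abs(ll_trace[iter - 1]) + 1e-12)
    # a noise variance at the floor means a (near-)exact low-rank fit:
    # the likelihood diverges and further EM steps are pure numerics
    if (sigma2_new <= 2e-12) converged <- TRUE
    W <- Wnew
    sigma2 <- sigma2_new
    if (converged) break
  }
  # final E-step so the reported scores match the reported parameters
  for (nidx in seq_len(N)) {
    o <- obs[, nidx]
    Wo <- W[o, , drop = FALSE]
    Mi <- solve(sigma2 * diag(q) + crossprod(Wo))
    scores[nidx, ] <- drop(Mi %*% crossprod(Wo, Y[o, nidx]))
  }
  dimnames(W) <- list(rownames(X), paste0("PC", seq_len(q)))
  dimnames(scores) <- list(colnames(X), paste0("PC", seq_len(q)))
  methods::new("PpcaModel", loadings = W, center = mu, sigma2 = sigma2,
               scores = scores, loglik = ll_trace,
               converged = isTRUE(converged))
}

#' Two-dimensional embedding of samples with class labels
#'
#' Emits the first two posterior score components per sample together with
#' a class label -- the data behind group-separation scatter displays.
#'
#' @param model a [PpcaModel-class] with >= 2 components.
#' @param labels named vector mapping sample to class label (unmapped
#'   samples get `NA`).
#' @return data.frame with columns `sample`, `PC1`, `PC2`, `label`.
#' @export
projectScores <- function(model, labels = NULL) {
  if (ncol(model@scores) < 2L) stop("model needs >= 2 components")
  s <- model@scores
  lab <- if (is.null(labels)) rep(NA_character_, nrow(s))
         else as.character(labels[rownames(s)])
  data.frame(sample = rownames(s), PC1 = s[, 1], PC2 = s[, 2], label = lab,
             row.names = NULL, stringsAsFactors = FALSE)
}
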