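# Internal helpers shared across modules.

.stopf <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "plvmotif_error", "error", "condition")))
}

.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# `seed` is forced first: a lazily supplied expression that itself consumes
# the caller's RNG stream must draw before the stream state is captured.
.with_seed <- function(seed, code) {
  force(seed)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed %% (.Machine$integer.max - 1L)))
  force(code)
}

# Expand one master seed into `n` independent sub-stream seeds (all < 2^31).
.seed_streams <- function(seed, n) {
  .with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Residual sum of squares of each column of Y about the column space of Q
# (Q orthonormal).
.rss <- function(Y, Q) {
  pmax(colSums(Y^2) - colSums(crossprod(Q, Y)^2), 0)
}

# Sex-adjusted group F statistics for all columns of Y at once, plus a
# Freedman-Lane permutation ensemble: residuals of the sex-only model are
# permuted over whole subjects and added back to the reduced-model fit.
# Returns F_obs (length L) and F_perm (n_perm x L).
.perm_F_ensemble <- function(Y, group, sex, n_perm, seed) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  stopifnot(length(group) == n, length(sex) == n)
  Xf <- stats::model.matrix(~ sex + group)
  Xr <- stats::model.matrix(~ sex)
  Qf <- qr.Q(qr(Xf))
  Qr <- qr.Q(qr(Xr))
  df1 <- ncol(Xf) - ncol(Xr)
  df2 <- n - ncol(Xf)
  fstat <- function(Ym) {
    rf <- .rss(Ym, Qf)
    rr <- .rss(Ym, Qr)
    Fv <- ((rr - rf) / df1) / (rf / df2)
    Fv[!is.finite(Fv)] <- 0
    Fv
  }
  constant <- apply(Y, 2, function(y) diff(range(y)) == 0)
  F_obs <- fstat(Y)
  fit_r <- Qr %*% crossprod(Qr, Y)
  E <- Y - fit_r
  F_perm <- NULL
  if (n_perm > 0) {
    F_perm <- matrix(0, n_perm, ncol(Y))
    .with_seed(seed, {
      for (b in seq_len(n_perm)) {
        idx <- sample.int(n)
        F_perm[b, ] <- fstat(fit_r + E[idx, , drop = FALSE])
      }
    })
  }
  list(F_obs = F_obs, F_perm = F_perm, df1 = df1, df2 = df2,
       constant = constant)
}

# Cohen's d with the pooled standard deviation, oriented as bd - control.
.cohens_d <- function(x_bd, x_control) {
  n1 <- length(x_bd)
  n2 <- length(x_control)
  pooled <- sqrt(((n1 - 1) * stats::var(x_bd) + (n2 - 1) * stats::var(x_control)) /
                   (n1 + n2 - 2))
  if (!is.finite(pooled) || pooled == 0) {
    .stopf("plvmotif_undefined_effect", "pooled standard deviation is zero; effect size undefined")
  }
  (mean(x_bd) - mean(x_control)) / pooled
}
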