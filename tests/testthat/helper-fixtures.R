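# Shared fixtures and independent oracles used across the suite.

# Small, fast phantom grid for unit tests (acceptance checks use the
# default 128 x 128 x 32 grid).
small_spec <- function(...) {
  phantom_spec(dim = c(64L, 64L, 24L), ...)
}

# Build a t2_map directly from an array of values (NA = invalid), on an
# arbitrary affine. Lets tests probe ROI logic without a dual-echo fit.
t2_map_from_array <- function(vals, affine = diag(4)) {
  valid <- !is.na(vals)
  structure(list(t2 = volumetric_image(vals, affine), valid = valid),
            class = "t2_map")
}

# A simple box-shaped label mask.
box_mask <- function(dim, from, to, label = 1L, affine = diag(4)) {
  vox <- array(0L, dim = dim)
  vox[from[1]:to[1], from[2]:to[2], from[3]:to[3]] <- label
  label_mask(vox, affine)
}

# Rotation matrix about an arbitrary axis (Rodrigues), as a rigid 4x4.
rigid_about <- function(axis, angle, translation = c(0, 0, 0)) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
  out <- diag(4)
  out[1:3, 1:3] <- R
  out[1:3, 4] <- translation
  out
}

# Brute-force per-voxel pull-back resampling oracle: for every reference
# voxel, map its center world coordinate back through the transform and
# source affine, round, and sample. Deliberately scalar (one voxel at a
# time) so it shares no code path with resample_mask().
oracle_resample <- function(mask, transform, reference) {
  d_ref <- dim(reference$voxels)
  d_src <- dim(mask$voxels)
  inv_t <- solve(transform)
  inv_a <- solve(mask$affine)
  out <- array(0L, dim = d_ref)
  for (k in seq_len(d_ref[3])) for (j in seq_len(d_ref[2])) for (i in seq_len(d_ref[1])) {
    w <- reference$affine %*% c(i - 1, j - 1, k - 1, 1)
    s <- inv_a %*% (inv_t %*% w)
    si <- round(s[1:3]) + 1
    if (all(si >= 1) && all(si <= d_src)) {
      out[i, j, k] <- mask$voxels[si[1], si[2], si[3]]
    }
  }
  out
}

# Brute-force per-voxel neighbourhood erosion oracle.
oracle_erode <- function(vox, mode = "in-plane-2D", slice_axis = 3L) {
  d <- dim(vox)
  if (mode == "in-plane-2D") {
    inplane <- setdiff(1:3, slice_axis)
    offs <- expand.grid(a = -1:1, b = -1:1)
    offsets <- lapply(seq_len(nrow(offs)), function(r) {
      o <- c(0L, 0L, 0L); o[inplane] <- c(offs$a[r], offs$b[r]); o
    })
  } else {
    offsets <- list(c(0, 0, 0), c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                    c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  }
  out <- array(0L, dim = d)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    lab <- vox[i, j, k]
    if (lab == 0L) next
    keep <- TRUE
    for (o in offsets) {
      p <- c(i, j, k) + o
      if (any(p < 1) || any(p > d) || vox[p[1], p[2], p[3]] != lab) {
        keep <- FALSE
        break
      }
    }
    if (keep) out[i, j, k] <- lab
  }
  out
}

# Independent maximizer of the binomial log-likelihood (BFGS with analytic
# gradient on centered features, mapped back), used to cross-check the
# IRLS fit.
oracle_logistic <- function(X, y) {
  mu <- colMeans(X)
  sc <- apply(X, 2, sd)
  Xc <- sweep(sweep(X, 2, mu), 2, sc, "/")
  X1 <- cbind(1, Xc)
  nll <- function(beta) {
    eta <- as.vector(X1 %*% beta)
    sum(log1p(exp(eta))) - sum(y * eta)
  }
  grad <- function(beta) {
    eta <- as.vector(X1 %*% beta)
    as.vector(t(X1) %*% (1 / (1 + exp(-eta)) - y))
  }
  fit <- optim(rep(0, ncol(X1)), nll, grad, method = "BFGS",
               control = list(maxit = 5000, reltol = 1e-16))
  # polish: restart until the solution stops moving
  for (i in 1:5) {
    refit <- optim(fit$par, nll, grad, method = "BFGS",
                   control = list(maxit = 5000, reltol = 1e-16))
    if (max(abs(refit$par - fit$par)) < 1e-12) {
      fit <- refit
      break
    }
    fit <- refit
  }
  beta <- fit$par
  slopes <- beta[-1] / sc
  c(beta[1] - sum(slopes * mu), slopes)
}

# Exhaustive cutoff oracle: evaluate the misclassification loss at every
# midpoint between adjacent order statistics of the combined sample that
# lies between the class medians, and return the minimizing midpoint.
# Tail fractions come from order statistics (findInterval on the sorted
# samples), an algorithm independent of the grid search it checks.
oracle_cutoff <- function(gm, csf) {
  lo <- median(gm)
  hi <- median(csf)
  cand <- sort(unique(c(gm, csf)))
  mids <- (head(cand, -1) + cand[-1]) / 2
  mids <- mids[mids >= lo & mids <= hi]
  gm_s <- sort(gm)
  csf_s <- sort(csf)
  loss <- (length(gm) - findInterval(mids, gm_s)) / length(gm) +
    findInterval(mids, csf_s) / length(csf)
  list(cutoff = mids[which.min(loss)], loss = min(loss))
}
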