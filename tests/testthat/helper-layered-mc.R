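# Independent layered-slab Monte Carlo reference, written against the
# textbook description of photon-packet transport in a stack of laterally
# infinite layers with matched refractive indices. Vectorized plain R; no
# voxel grid, no shared code with the package kernel. Returns diffuse
# reflectance and transmittance per launched packet with standard errors.
layered_mc_reference <- function(layers, n_photons, seed,
                                 max_iter = 100000L) {
  # layers: data.frame(thickness_cm, mua, mus, g); photons enter at z = 0
  # moving +z. Albedo weighting, no roulette, matched boundaries.
  set.seed(seed)
  bounds <- c(0, cumsum(layers$thickness_cm))
  zmax <- bounds[length(bounds)]
  n <- n_photons
  z <- numeric(n)
  ux <- numeric(n); uy <- numeric(n); uz <- rep(1, n)
  w <- rep(1, n)
  alive <- rep(TRUE, n)
  tau <- -log(runif(n))
  Rw <- numeric(n)  # per-photon weight escaping the top
  Tw <- numeric(n)  # per-photon weight escaping the bottom

  layer_of <- function(zz) pmin(pmax(findInterval(zz, bounds,
                                                  left.open = FALSE), 1L),
                                nrow(layers))
  it <- 0L
  while (any(alive)) {
    it <- it + 1L
    if (it > max_iter) stop("layered reference exceeded iteration cap")
    i <- which(alive)
    li <- layer_of(z[i])
    mua <- layers$mua[li]; mus <- layers$mus[li]
    mut <- mua + mus
    s <- tau[i] / mut
    # distance to the layer boundary along the current direction
    up <- uz[i] > 0
    zb <- ifelse(up, bounds[li + 1L], bounds[li])
    db <- ifelse(abs(uz[i]) < 1e-12, Inf, (zb - z[i]) / uz[i])
    db[db < 0] <- 0

    cross <- s > db
    # photons crossing a boundary: advance, spend optical depth, maybe exit
    ci <- i[cross]
    if (length(ci)) {
      dbc <- db[cross]
      lic <- li[cross]
      z[ci] <- z[ci] + uz[ci] * dbc * (1 + 1e-12) + 1e-12 * sign(uz[ci])
      tau[ci] <- tau[ci] - dbc * mut[cross]
      out_top <- z[ci] <= 0
      out_bot <- z[ci] >= zmax
      Rw[ci[out_top]] <- w[ci[out_top]]
      Tw[ci[out_bot]] <- w[ci[out_bot]]
      alive[ci[out_top | out_bot]] <- FALSE
    }
    # photons interacting inside the layer: move, absorb, scatter
    ai <- i[!cross]
    if (length(ai)) {
      sa <- s[!cross]
      z[ai] <- z[ai] + uz[ai] * sa
      albedo <- (mus / mut)[!cross]
      w[ai] <- w[ai] * albedo
      g <- layers$g[layer_of(z[ai])]
      x1 <- runif(length(ai)); x2 <- runif(length(ai))
      ct <- ifelse(abs(g) < 1e-12, 2 * x1 - 1,
                   (1 + g^2 - ((1 - g^2) / (1 - g + 2 * g * x1))^2) /
                     (2 * g))
      ct <- pmin(1, pmax(-1, ct))
      st <- sqrt(1 - ct^2)
      phi <- 2 * pi * x2
      cp <- cos(phi); sp <- sin(phi)
      nearz <- abs(uz[ai]) > 0.99999
      den <- sqrt(pmax(1e-30, 1 - uz[ai]^2))
      nux <- ifelse(nearz, st * cp,
                    st * (ux[ai] * uz[ai] * cp - uy[ai] * sp) / den +
                      ux[ai] * ct)
      nuy <- ifelse(nearz, st * sp,
                    st * (uy[ai] * uz[ai] * cp + ux[ai] * sp) / den +
                      uy[ai] * ct)
      nuz <- ifelse(nearz, ct * sign(uz[ai]),
                    -st * cp * den + uz[ai] * ct)
      nrm <- sqrt(nux^2 + nuy^2 + nuz^2)
      ux[ai] <- nux / nrm; uy[ai] <- nuy / nrm; uz[ai] <- nuz / nrm
      tau[ai] <- -log(runif(length(ai)))
      # packets of negligible weight that cannot escape numerically
      dead <- w[ai] < 1e-12
      alive[ai[dead]] <- FALSE
    }
  }
  list(R = sum(Rw) / n, T = sum(Tw) / n,
       R_se = sqrt(max(0, sum(Rw^2) / n - (sum(Rw) / n)^2) / n),
       T_se = sqrt(max(0, sum(Tw^2) / n - (sum(Tw) / n)^2) / n))
}
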