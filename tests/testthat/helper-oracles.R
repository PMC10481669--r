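# Independent oracles. These deliberately share no solver code with the
# package: the boundary-value problem is discretized by trapezoidal
# collocation and solved with a damped Newton iteration on the full
# nonlinear system; morphometry oracles are plain loops.

# Trapezoidal-collocation solution of the osmotic/Darcy BVP.
# States u = rho*w and p on an oracle grid of n points starting at
# rho0 + offset_frac*(L - rho0); unknown x = (u_1..u_n, p_1..p_n).
collocation_solve <- function(geom, params, n = 241L, offset_frac = 2e-3,
                              tol = 1e-10, max_iter = 60L) {
  rho_g <- geom$rho_um * 1e-6
  A_g <- geom$A_per_um * 1e6
  tau <- attr(geom, "tau")
  K_g <- 8 * params$mu * tau^2 /
    (geom$eps_bc * (geom$r_bc_um * 1e-6)^2 * geom$f)
  rho0 <- rho_g[1]; L <- rho_g[length(rho_g)]
  a <- rho0 + offset_frac * (L - rho0)
  rho <- seq(a, L, length.out = n)
  A <- approx(rho_g, A_g, rho, rule = 2)$y
  K <- approx(rho_g, K_g, rho, rule = 2)$y
  gvec <- if (length(params$g) == 1) rep(params$g, n) else
    approx(rho_g, params$g, rho, rule = 2)$y
  RT <- params$R * params$T
  c0 <- params$c0; kap <- params$kappa; pL <- params$pL

  # G on the oracle grid (from rho0, trapezoid with a leading segment)
  intg <- rho * gvec
  G <- (a - rho0) * (rho0 * gvec[1] + intg[1]) / 2 +
    c(0, cumsum(diff(rho) * (intg[-1] + intg[-n]) / 2))

  c_star <- function(p0) {
    aa <- kap * A[1] * RT
    bb <- -kap * A[1] * (RT * c0 + p0)
    (-bb + sqrt(bb^2 + 4 * aa * gvec[1])) / (2 * aa)
  }

  fu <- function(u, p) {
    cc <- ifelse(u > 0, G / u, c0)
    rho * kap * A * (RT * (cc - c0) - p)
  }
  fp <- function(u) -K * u / rho

  # nondimensionalize: u in units of u_ref, p in units of pL, and the
  # collocation residuals likewise, so the Newton system is well-scaled
  u_ref <- max(G) / c0
  h <- diff(rho)
  resid_s <- function(xs) {
    u <- xs[1:n] * u_ref; p <- xs[(n + 1):(2 * n)] * pL
    Fu <- fu(u, p); Fp <- fp(u)
    c(
      (u[1] - (a - rho0) * rho0 * kap * A[1] *
         (RT * (c_star(p[1]) - c0) - p[1])) / u_ref,
      (u[-1] - u[-n] - h / 2 * (Fu[-1] + Fu[-n])) / u_ref,
      (p[n] - pL) / pL,
      (p[-1] - p[-n] - h / 2 * (Fp[-1] + Fp[-n])) / pL
    )
  }

  # initial guess: concentration near c0, pressure flat slightly above pL
  xs <- c(G / (c0 + pL / RT + 1) / u_ref, rep(1.2, n))
  for (it in seq_len(max_iter)) {
    F0 <- resid_s(xs)
    if (max(abs(F0)) < tol) break
    J <- matrix(0, 2 * n, 2 * n)
    for (j in seq_len(2 * n)) {
      dx <- max(abs(xs[j]), 1e-3) * 1e-7
      xp <- xs; xp[j] <- xp[j] + dx
      J[, j] <- (resid_s(xp) - F0) / dx
    }
    step <- tryCatch(solve(J, -F0), error = function(e) NULL)
    if (is.null(step)) stop("oracle Newton: singular Jacobian")
    lam <- 1
    repeat {
      xn <- xs + lam * step
      xn[1:n] <- pmax(xn[1:n], 1e-16)
      Fn <- resid_s(xn)
      if (max(abs(Fn)) < max(abs(F0)) || lam < 1e-4) break
      lam <- lam / 2
    }
    xs <- xn
  }
  if (max(abs(resid_s(xs))) >= tol) {
    stop("oracle Newton did not converge")
  }
  list(rho = rho, u = xs[1:n] * u_ref, p = xs[(n + 1):(2 * n)] * pL, G = G,
       iterations = it)
}

# Brute-force per-zone morphometry by explicit loops (no igraph, no dplyr).
brute_zone_stats <- function(net, n_zones = 11L) {
  nodes <- as.data.frame(net$nodes)
  edges <- as.data.frame(net$edges)
  lm <- net$landmarks
  span <- lm$pv_radius_um - lm$cv_radius_um
  zone_of <- function(x, y) {
    t <- (sqrt((x - lm$cv_center_um[1])^2 + (y - lm$cv_center_um[2])^2) -
            lm$cv_radius_um) / span
    min(max(floor(t * n_zones), 0), n_zones - 1)
  }
  nz <- vapply(seq_len(nrow(nodes)),
               function(i) zone_of(nodes$x_um[i], nodes$y_um[i]), numeric(1))
  ez <- vapply(seq_len(nrow(edges)), function(e) {
    i <- which(nodes$id == edges$from[e]); j <- which(nodes$id == edges$to[e])
    zone_of((nodes$x_um[i] + nodes$x_um[j]) / 2,
            (nodes$y_um[i] + nodes$y_um[j]) / 2)
  }, numeric(1))
  elen <- vapply(seq_len(nrow(edges)), function(e) {
    i <- which(nodes$id == edges$from[e]); j <- which(nodes$id == edges$to[e])
    sqrt((nodes$x_um[i] - nodes$x_um[j])^2 +
           (nodes$y_um[i] - nodes$y_um[j])^2 +
           (nodes$z_um[i] - nodes$z_um[j])^2)
  }, numeric(1))
  deg <- vapply(nodes$id,
                function(id) sum(edges$from == id) + sum(edges$to == id),
                numeric(1))

  # connected components of a set of edges, by label propagation
  n_components <- function(eidx) {
    ids <- unique(c(edges$from[eidx], edges$to[eidx]))
    lab <- seq_along(ids)
    repeat {
      changed <- FALSE
      for (e in eidx) {
        i <- match(edges$from[e], ids); j <- match(edges$to[e], ids)
        m <- min(lab[i], lab[j])
        if (lab[i] != m || lab[j] != m) { lab[i] <- m; lab[j] <- m
          changed <- TRUE }
      }
      if (!changed) break
    }
    length(unique(lab))
  }

  breaks <- seq(lm$cv_radius_um, lm$pv_radius_um, length.out = n_zones + 1)
  out <- NULL
  for (z in seq_len(n_zones) - 1) {
    sel <- which(ez == z)
    vtis <- (net$sector_angle_rad / 2) *
      (breaks[z + 2]^2 - breaks[z + 1]^2) * net$tissue_depth_um
    vol <- sum(pi * edges$radius_um[sel]^2 * elen[sel])
    len <- sum(elen[sel])
    if (length(sel)) {
      mr <- sum(edges$radius_um[sel] * elen[sel]) / len
      s2v <- sum(2 * pi * edges$radius_um[sel] * elen[sel]) / vtis * 1e9
      conn <- 1 / n_components(sel)
      jpl <- sum(deg[nz == z] >= 3) / len
    } else {
      mr <- NA; s2v <- NA; conn <- NA; jpl <- NA
    }
    # crossings of the zone's CV-side boundary
    if (z == 0) {
      cross <- 0
      barea <- net$sector_angle_rad * breaks[1] * net$tissue_depth_um / 1e6
    } else {
      cross <- 0
      for (e in seq_len(nrow(edges))) {
        zi <- nz[which(nodes$id == edges$from[e])]
        zj <- nz[which(nodes$id == edges$to[e])]
        if (min(zi, zj) < z && max(zi, zj) >= z) cross <- cross + 1
      }
      barea <- net$sector_angle_rad * breaks[z + 1] *
        net$tissue_depth_um / 1e6
    }
    out <- rbind(out, data.frame(
      zone = z, mean_radius_um = mr,
      volume_fraction_pct = 100 * vol / vtis,
      surface_to_volume_um2_mm3 = s2v, connectivity = conn,
      crossings_per_mm2 = cross / barea, junctions_per_um = jpl,
      network_volume_um3 = vol))
  }
  out
}

# Brute-force per-shell geometry reduction (loops, no tapply)
brute_network_geometry <- function(net, n_shells = 11L) {
  nodes <- as.data.frame(net$nodes)
  edges <- as.data.frame(net$edges)
  lm <- net$landmarks
  breaks <- seq(lm$cv_radius_um, lm$pv_radius_um, length.out = n_shells + 1)
  eps <- A <- rb <- numeric(n_shells)
  volsum <- lensum <- lrsum <- surfsum <- numeric(n_shells)
  for (e in seq_len(nrow(edges))) {
    i <- which(nodes$id == edges$from[e]); j <- which(nodes$id == edges$to[e])
    mx <- (nodes$x_um[i] + nodes$x_um[j]) / 2
    my <- (nodes$y_um[i] + nodes$y_um[j]) / 2
    rho <- sqrt((mx - lm$cv_center_um[1])^2 + (my - lm$cv_center_um[2])^2)
    s <- min(max(findInterval(rho, breaks, rightmost.closed = TRUE), 1),
             n_shells)
    l <- sqrt((nodes$x_um[i] - nodes$x_um[j])^2 +
                (nodes$y_um[i] - nodes$y_um[j])^2 +
                (nodes$z_um[i] - nodes$z_um[j])^2)
    r <- edges$radius_um[e]
    volsum[s] <- volsum[s] + pi * r^2 * l
    surfsum[s] <- surfsum[s] + 2 * pi * r * l
    lensum[s] <- lensum[s] + l
    lrsum[s] <- lrsum[s] + l * r
  }
  for (s in seq_len(n_shells)) {
    v <- (net$sector_angle_rad / 2) *
      (breaks[s + 1]^2 - breaks[s]^2) * net$tissue_depth_um
    eps[s] <- volsum[s] / v
    A[s] <- surfsum[s] / v
    rb[s] <- if (lensum[s] > 0) lrsum[s] / lensum[s] else NA
  }
  list(eps = eps, A = A, r_bc = rb)
}
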