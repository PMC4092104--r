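#' Deformable-contour (snake) parameters
#'
#' Weights for the closed parametric contour evolved under internal
#' smoothness forces and the external GVF force. Internal forces are applied
#' implicitly (the classic pentadiagonal system), external forces explicitly.
#'
#' @param alpha Elasticity (first-derivative) weight, `>= 0`.
#' @param beta Rigidity (second-derivative) weight, `>= 0`.
#' @param gamma Time step of the evolution, `> 0`.
#' @param kappa External (GVF) force weight, `>= 0`.
#' @param tol Mean vertex displacement (px) below which the contour is
#'   declared converged.
#' @param max_iter Iteration cap; contours hitting it are flagged
#'   `converged = FALSE` and excluded from morphometry by default.
#' @param n_vertices Number of contour vertices (`>= 8`), resampled to
#'   uniform spacing every iteration.
#' @return An object of class `snake_params`.
#' @export
snake_params <- function(alpha = 0.1, beta = 0.05, gamma = 1.0, kappa = 1.0,
                         tol = 0.05, max_iter = 500, n_vertices = 64) {
  stopifnot(alpha >= 0, beta >= 0, gamma > 0, kappa >= 0, tol > 0,
            max_iter >= 1, n_vertices >= 8)
  structure(
    list(alpha = alpha, beta = beta, gamma = gamma, kappa = kappa,
         tol = tol, max_iter = as.integer(max_iter),
         n_vertices = as.integer(n_vertices)),
    class = "snake_params"
  )
}

# (I + gamma * (alpha*K2 + beta*K4))^-1 for a closed contour of n vertices;
# K2/K4 are the circulant second/fourth difference penalty matrices.
snake_system_inverse <- function(n, alpha, beta, gamma) {
  idx <- function(k) ((seq_len(n) - 1 + k) %% n) + 1
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    A[i, idx(-2)[i]] <- beta
    A[i, idx(-1)[i]] <- -alpha - 4 * beta
    A[i, i] <- 2 * alpha + 6 * beta
    A[i, idx(1)[i]] <- -alpha - 4 * beta
    A[i, idx(2)[i]] <- beta
  }
  solve(diag(n) + gamma * A)
}

# Bilinear interpolation of matrix M at fractional (r, c); coordinates are
# clamped to the domain.
bilinear_at <- function(M, r, c) {
  H <- nrow(M); W <- ncol(M)
  r <- pmin(pmax(r, 1), H); c <- pmin(pmax(c, 1), W)
  r0 <- pmin(floor(r), H - 1); c0 <- pmin(floor(c), W - 1)
  fr <- r - r0; fc <- c - c0
  M[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    M[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    M[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    M[cbind(r0 + 1, c0 + 1)] * fr * fc
}

# Resample a closed polygon to n vertices at uniform arc length.
resample_closed <- function(V, n) {
  Vc <- rbind(V, V[1, , drop = FALSE])
  seg <- sqrt(diff(Vc[, 1])^2 + diff(Vc[, 2])^2)
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total < 1e-12) return(matrix(rep(V[1, ], each = n), n, 2))
  t_new <- seq(0, total, length.out = n + 1)[seq_len(n)]
  cbind(stats::approx(s, Vc[, 1], xout = t_new)$y,
        stats::approx(s, Vc[, 2], xout = t_new)$y)
}

#' Evolve a seeded contour to the adipocyte boundary
#'
#' Step 2 of the segmentation algorithm: a closed contour initialized as a
#' small circle at the seed inflates under the GVF external force until it
#' locks onto the edge ridge at the lumen/ECM interface. Internal forces are
#' integrated implicitly; vertices are resampled to uniform spacing every
#' iteration; evolution stops when mean vertex displacement drops below
#' `params$tol` or after `params$max_iter` iterations.
#'
#' @param seed Numeric `(row, col)` of the initializing seed (must lie inside
#'   the field domain).
#' @param field A `vector_field` from [compute_gvf()], the refinement force.
#' @param params A [snake_params] object.
#' @param init_radius Radius (px) of the initial circle. The default 3 px
#'   suits small fields; the pipeline passes `0.7 x` the seed's
#'   distance-transform value so that large lumina start within the GVF
#'   capture range of their boundary.
#' @param approach_field Optional [normalize_field()] version of `field`.
#'   When supplied, evolution runs in two phases: an approach phase on the
#'   normalized field (unit speed everywhere, so the contour inflates out of
#'   weak-force interiors) that ends when the enclosed area stalls, then a
#'   refinement phase on the raw field, whose force crosses zero linearly at
#'   the edge crest and converges below `tol`.
#' @return An object of class `cell_contour`: `vertices` (closed polygon,
#'   `n x 2` matrix of `(row, col)`), `seed`, `converged`, `iterations`,
#'   `area_px` (enclosed pixel count), `degenerate`.
#' @export
evolve_contour <- function(seed, field, params = snake_params(), init_radius = 3,
                           approach_field = NULL) {
  stopifnot(inherits(field, "vector_field"), inherits(params, "snake_params"))
  H <- nrow(field$u); W <- ncol(field$u)
  if (seed[1] < 1 || seed[1] > H || seed[2] < 1 || seed[2] > W) {
    stop("seed lies outside the field domain", call. = FALSE)
  }
  n <- params$n_vertices
  th <- seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
  V <- cbind(seed[1] + init_radius * sin(th), seed[2] + init_radius * cos(th))
  V[, 1] <- pmin(pmax(V[, 1], 1), H)
  V[, 2] <- pmin(pmax(V[, 2], 1), W)

  P <- snake_system_inverse(n, params$alpha, params$beta, params$gamma)
  gk <- params$gamma * params$kappa
  step <- function(V, fld) {
    fr <- bilinear_at(fld$u, V[, 1], V[, 2])
    fc <- bilinear_at(fld$v, V[, 1], V[, 2])
    Vn <- P %*% cbind(V[, 1] + gk * fr, V[, 2] + gk * fc)
    Vn[, 1] <- pmin(pmax(Vn[, 1], 1), H)
    Vn[, 2] <- pmin(pmax(Vn[, 2], 1), W)
    Vn
  }
  iter <- 0L

  if (!is.null(approach_field)) {
    # inflate at unit speed until the enclosed area stalls
    area_hist <- shoelace_area(V)
    check_every <- 10L
    while (iter < params$max_iter) {
      iter <- iter + 1L
      V <- resample_closed(step(V, approach_field), n)
      if (iter %% check_every == 0L) {
        a <- shoelace_area(V)
        if (abs(a - area_hist) < 0.005 * max(a, 1)) break
        area_hist <- a
      }
    }
  }

  converged <- FALSE
  while (iter < params$max_iter) {
    iter <- iter + 1L
    Vn <- step(V, field)
    disp <- mean(sqrt(rowSums((Vn - V)^2)))
    V <- resample_closed(Vn, n)
    if (disp < params$tol) { converged <- TRUE; break }
  }
  in_poly <- polygon_pixels(V, H, W)
  area_px <- length(in_poly)
  structure(
    list(vertices = V, seed = as.numeric(seed[1:2]), converged = converged,
         iterations = iter, area_px = area_px, degenerate = area_px == 0),
    class = "cell_contour"
  )
}

# Unsigned polygon area by the shoelace formula.
shoelace_area <- function(V) {
  r <- V[, 1]; c <- V[, 2]
  rn <- c(r[-1], r[1]); cn <- c(c[-1], c[1])
  abs(sum(r * cn - rn * c)) / 2
}

# Linear indices (into an H x W matrix) of pixel centers strictly inside a
# closed polygon, by the even-odd (crossing-number) rule.
polygon_pixels <- function(V, H, W) {
  r0 <- max(1L, floor(min(V[, 1]))); r1 <- min(H, ceiling(max(V[, 1])))
  c0 <- max(1L, floor(min(V[, 2]))); c1 <- min(W, ceiling(max(V[, 2])))
  if (r1 < r0 || c1 < c0) return(integer(0))
  rows <- r0:r1; cols <- c0:c1
  pr <- rep(rows, times = length(cols))
  pc <- rep(cols, each = length(rows))
  inside <- rep(FALSE, length(pr))
  nv <- nrow(V)
  j <- nv
  for (i in seq_len(nv)) {
    ri <- V[i, 1]; ci <- V[i, 2]; rj <- V[j, 1]; cj <- V[j, 2]
    crosses <- ((ri > pr) != (rj > pr)) &
      (pc < (cj - ci) * (pr - ri) / (rj - ri) + ci)
    inside <- xor(inside, crosses & (ri != rj))
    j <- i
  }
  idx <- which(inside)
  (pc[idx] - 1L) * H + pr[idx]
}

point_in_polygon <- function(V, r, c) {
  nv <- nrow(V); inside <- FALSE; j <- nv
  for (i in seq_len(nv)) {
    ri <- V[i, 1]; ci <- V[i, 2]; rj <- V[j, 1]; cj <- V[j, 2]
    if ((ri > r) != (rj > r) &&
        c < (cj - ci) * (r - ri) / (rj - ri) + ci) inside <- !inside
    j <- i
  }
  inside
}

#' Resolve overlapping contours into an exclusive label raster
#'
#' Rasterizes every contour; a pixel claimed by two or more contours goes to
#' the contour whose seed is nearest (ties to the lower cell id). Each cell's
#' region is then reduced to the connected component containing its seed;
#' cells whose seed falls outside their resolved region are dropped with a
#' message.
#'
#' @param contours List of `cell_contour` objects from one slide.
#' @param dim Integer `(H, W)` of the slide raster.
#' @return Integer label matrix (`0` = unclaimed), one positive label per
#'   surviving cell, with attribute `dropped` (integer ids of dropped cells).
#' @export
resolve_overlaps <- function(contours, dim) {
  H <- dim[1]; W <- dim[2]
  lab <- matrix(0L, H, W)
  if (length(contours) == 0) return(lab)
  best_d2 <- matrix(Inf, H, W)
  for (i in seq_along(contours)) {
    ct <- contours[[i]]
    idx <- polygon_pixels(ct$vertices, H, W)
    if (length(idx) == 0) next
    pr <- ((idx - 1L) %% H) + 1L
    pc <- ((idx - 1L) %/% H) + 1L
    d2 <- (pr - ct$seed[1])^2 + (pc - ct$seed[2])^2
    win <- d2 < best_d2[idx]   # strict: earlier (lower) id keeps ties
    lab[idx[win]] <- i
    best_d2[idx[win]] <- d2[win]
  }
  dropped <- integer(0)
  for (i in seq_along(contours)) {
    reg <- lab == i
    if (!any(reg)) { dropped <- c(dropped, i); next }
    sr <- round(contours[[i]]$seed[1]); sc <- round(contours[[i]]$seed[2])
    comp <- EBImage::bwlabel(reg)
    seed_comp <- comp[sr, sc]
    if (seed_comp == 0) {
      lab[reg] <- 0L
      dropped <- c(dropped, i)
      message("cell ", i, " dropped: seed outside its resolved region")
    } else if (max(comp) > 1) {
      lab[reg & comp != seed_comp] <- 0L
    }
  }
  attr(lab, "dropped") <- dropped
  lab
}

#' Write a label raster as a 16-bit grayscale TIFF
#'
#' @param labels Integer label matrix (0 = no cell).
#' @param path Output `.tif(f)` path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Write contour polygons to CSV
#'
#' One row per vertex: `cell_id, vertex_idx, row, col`.
#'
#' @param contours List of `cell_contour` objects.
#' @param path Output `.csv` path.
#' @return `path`, invisibly.
#' @export
write_contours <- function(contours, path) {
  df <- purrr::imap_dfr(contours, function(ct, i) {
    tibble::tibble(cell_id = i, vertex_idx = seq_len(nrow(ct$vertices)),
                   row = ct$vertices[, 1], col = ct$vertices[, 2])
  })
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
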