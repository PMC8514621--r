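# Internal machinery for the 3D Zernike basis on the unit ball:
# radial polynomial coefficients, solid-harmonic monomial expansions,
# and the cached monomial-coefficient tensor used by the fast moment path.
#
# Conventions (shared by the fast path and the pointwise oracle):
#   Z_nlm(r, theta, phi) = R_nl(r) * Y_lm(theta, phi)
#   R_nl orthonormal with weight r^2 on [0,1]:  int_0^1 R_nl R_n'l r^2 dr = delta
#   Y_lm orthonormal complex spherical harmonics, Condon-Shortley phase.
# Moments are C_nlm = int_{|r|<=1} f(r) conj(Z_nlm) dr, discretised as a
# Riemann sum over voxel centers inside the unit ball.

# generalized binomial coefficient choose(a, k) for real a
gchoose <- function(a, k) {
  if (k == 0L) return(1)
  prod(a - seq_len(k) + 1) / factorial(k)
}

#' @noRd
# Coefficients c_j of R_nl(r) = sum_j c_j r^(l + 2j), j = 0..(n-l)/2.
# Closed form via Jacobi polynomials: R_nl(r) = sqrt(2n+3) r^l P_s^(0,l+1/2)(2r^2-1),
# with s = (n-l)/2 and P expanded through its hypergeometric sum.
radial_coeffs <- function(n, l) {
  stopifnot(n >= l, (n - l) %% 2L == 0L)
  s <- (n - l) %/% 2L
  cf <- numeric(s + 1L)
  for (j in 0:s) {
    base <- choose(s, j) * gchoose(s + l + 0.5, s - j)
    for (i in 0:(s - j)) {
      cf[j + i + 1L] <- cf[j + i + 1L] +
        base * choose(s - j, i) * (-1)^(s - j - i)
    }
  }
  sqrt(2 * n + 3) * cf
}

# Pointwise evaluation of R_nl at radii r via the Jacobi three-term
# recurrence (independent of radial_coeffs; used by the oracle).
radial_eval <- function(n, l, r) {
  s <- (n - l) %/% 2L
  tt <- 2 * r^2 - 1
  beta <- l + 0.5
  if (s == 0L) {
    P <- rep(1, length(r))
  } else {
    Pm2 <- rep(1, length(r))
    Pm1 <- ((beta + 2) * tt - beta) / 2
    P <- Pm1
    if (s >= 2L) {
      for (k in 2:s) {
        ab <- beta          # alpha = 0
        c1 <- 2 * k * (k + ab) * (2 * k + ab - 2)
        c2 <- (2 * k + ab - 1) * ((2 * k + ab) * (2 * k + ab - 2) * tt - ab^2)
        c3 <- 2 * (k - 1) * (k + beta - 1) * (2 * k + ab)
        P <- (c2 * Pm1 - c3 * Pm2) / c1
        Pm2 <- Pm1
        Pm1 <- P
      }
    }
  }
  sqrt(2 * n + 3) * r^l * P
}

# Associated Legendre P_l^m(x) for m >= 0, Condon-Shortley phase included,
# evaluated by the standard upward recursion (oracle path).
assoc_legendre <- function(l, m, x) {
  stopifnot(m >= 0, l >= m)
  somx2 <- sqrt(pmax(0, 1 - x^2))
  pmm <- rep(1, length(x))
  if (m > 0) {
    fact <- 1
    for (i in 1:m) {
      pmm <- -pmm * fact * somx2
      fact <- fact + 2
    }
  }
  if (l == m) return(pmm)
  pmmp1 <- x * (2 * m + 1) * pmm
  if (l == m + 1L) return(pmmp1)
  pll <- pmmp1
  for (ll in (m + 2):l) {
    pll <- (x * (2 * ll - 1) * pmmp1 - (ll + m - 1) * pmm) / (ll - m)
    pmm <- pmmp1
    pmmp1 <- pll
  }
  pll
}

# Complex spherical harmonic Y_lm at (cos theta, phi), any m
sph_harm_eval <- function(l, m, costheta, phi) {
  am <- abs(m)
  nlm <- sqrt((2 * l + 1) / (4 * pi) * exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
  y <- nlm * assoc_legendre(l, am, costheta) * exp(1i * am * phi)
  if (m < 0) y <- (-1)^am * Conj(y)
  y
}

## ---- sparse monomial polynomials -------------------------------------------
## A polynomial in (x, y, z) is a list(idx, coef) with complex coef and
## exponents packed in base 64: idx = ex*4096 + ey*64 + ez (max order 46 < 64).

POLY_BASE <- 64L

poly_agg <- function(idx, coef) {
  if (length(idx) == 0L) return(list(idx = integer(0), coef = complex(0)))
  re <- rowsum(Re(coef), idx)
  im <- rowsum(Im(coef), idx)
  out_idx <- as.integer(rownames(re))
  out_coef <- complex(real = re[, 1L], imaginary = im[, 1L])
  keep <- Mod(out_coef) > 0
  list(idx = out_idx[keep], coef = out_coef[keep])
}

# multinomial expansion of (x^2 + y^2 + z^2)^k
rsq_power_poly <- function(k) {
  idx <- integer(0)
  coef <- numeric(0)
  for (a in 0:k) for (b in 0:(k - a)) {
    cc <- k - a - b
    idx <- c(idx, 2L * a * 4096L + 2L * b * 64L + 2L * cc)
    coef <- c(coef, exp(lfactorial(k) - lfactorial(a) - lfactorial(b) - lfactorial(cc)))
  }
  list(idx = idx, coef = as.complex(coef))
}

# monomial expansion of the solid harmonic r^l Y_lm for any m
solid_harm_poly <- function(l, m) {
  am <- abs(m)
  nlm <- sqrt((2 * l + 1) / (4 * pi) * exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
  idx_all <- integer(0)
  coef_all <- complex(0)
  p <- 0:am
  xy_idx <- (am - p) * 4096L + p * 64L
  xy_coef <- choose(am, p) * (1i)^p
  for (k in 0:((l - am) %/% 2L)) {
    a_k <- 2^(-l) * (-1)^k * choose(l, k) * choose(2 * l - 2 * k, l) *
      exp(lfactorial(l - 2 * k) - lfactorial(l - 2 * k - am))
    rk <- rsq_power_poly(k)
    z_pow <- l - 2L * k - am
    idx <- as.vector(outer(xy_idx, rk$idx, "+")) + z_pow
    coef <- as.vector(outer(xy_coef, rk$coef, "*")) * a_k
    idx_all <- c(idx_all, idx)
    coef_all <- c(coef_all, coef)
  }
  out <- poly_agg(idx_all, nlm * (-1)^am * coef_all)
  if (m < 0) out$coef <- (-1)^am * Conj(out$coef)
  out
}

# monomial expansion of conj(Z_nlm)
zernike_conj_poly <- function(n, l, m) {
  sh <- solid_harm_poly(l, m)
  rc <- radial_coeffs(n, l)
  idx_all <- integer(0)
  coef_all <- complex(0)
  for (j in seq_along(rc)) {
    if (rc[j] == 0) next
    q <- j - 1L                      # power l + 2q -> extra factor (r^2)^q
    rq <- rsq_power_poly(q)
    idx <- as.vector(outer(rq$idx, sh$idx, "+"))
    coef <- as.vector(outer(rq$coef, sh$coef, "*")) * rc[j]
    idx_all <- c(idx_all, idx)
    coef_all <- c(coef_all, coef)
  }
  out <- poly_agg(idx_all, coef_all)
  out$coef <- Conj(out$coef)
  out
}

## ---- cached coefficient tensor ---------------------------------------------

.zern_cache <- new.env(parent = emptyenv())

# All (n, l, m) combinations up to order_max, (n, l) lexicographic,
# l <= n with n - l even, m = -l..l.
zernike_index_table <- function(order_max) {
  n_out <- integer(0); l_out <- integer(0); m_out <- integer(0)
  for (n in 0:order_max) {
    for (l in seq(n %% 2L, n, by = 2L)) {
      mm <- (-l):l
      n_out <- c(n_out, rep.int(n, length(mm)))
      l_out <- c(l_out, rep.int(l, length(mm)))
      m_out <- c(m_out, mm)
    }
  }
  data.frame(n = n_out, l = l_out, m = m_out)
}

# per-(n,l,m) list of flat indices into the geometric-moment array of
# dim (order_max+1)^3 plus complex coefficients; cached per order_max
zernike_coeff_tensor <- function(order_max) {
  key <- as.character(order_max)
  if (!is.null(.zern_cache[[key]])) return(.zern_cache[[key]])
  idx_tab <- zernike_index_table(order_max)
  L1 <- order_max + 1L
  terms <- vector("list", nrow(idx_tab))
  for (i in seq_len(nrow(idx_tab))) {
    pz <- zernike_conj_poly(idx_tab$n[i], idx_tab$l[i], idx_tab$m[i])
    ex <- pz$idx %/% 4096L
    ey <- (pz$idx %/% 64L) %% 64L
    ez <- pz$idx %% 64L
    terms[[i]] <- list(flat = (ex + 1L) + ey * L1 + ez * L1 * L1,
                       coef = pz$coef)
  }
  out <- list(index = idx_tab, terms = terms)
  .zern_cache[[key]] <- out
  out
}

# Geometric (monomial) moments M[r+1, s+1, t+1] = sum_v f_v x^r y^s z^t vol,
# by separable tensor contraction; the grid must already be masked to the ball.
geometric_moments <- function(grid, order_max) {
  d <- dim(grid)[1L]
  cc <- -1 + (seq_len(d) - 0.5) * (2 / d)
  L1 <- order_max + 1L
  P <- outer(cc, 0:order_max, "^")
  T1 <- crossprod(P, matrix(grid, d, d * d))          # (L1) x (j,k)
  T1 <- array(T1, c(L1, d, d))
  T2 <- array(0, c(L1, L1, d))
  for (r in seq_len(L1)) T2[r, , ] <- crossprod(P, T1[r, , ])
  T3 <- matrix(T2, L1 * L1, d) %*% P                  # (r,s) x t
  array(T3, c(L1, L1, L1)) * (2 / d)^3
}

# mask voxel centers strictly outside the unit ball
mask_unit_ball <- function(grid) {
  d <- dim(grid)[1L]
  key <- paste0("mask", d)
  msk <- .zern_cache[[key]]
  if (is.null(msk)) {
    cc <- -1 + (seq_len(d) - 0.5) * (2 / d)
    r2 <- outer(outer(cc^2, cc^2, "+"), cc^2, "+")
    msk <- r2 <= 1
    .zern_cache[[key]] <- msk
  }
  grid[!msk] <- 0
  grid
}
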